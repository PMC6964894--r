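# Readers and writers: long-format trajectory CSV, ranked-result TSV and
# the flat key-value run configuration used by the command-line interface.

#' Read trajectories from long-format CSV
#'
#' Expects a delimited text file with header columns `timestamp`
#' (seconds), `object_id`, `x`, `y` (metres), one row per object per
#' sample. Each object's timestamps must form a complete uniform grid; the
#' sample interval is inferred from consecutive timestamps. Validation
#' failures name the offending file row.
#'
#' @param path Path to the CSV file.
#' @param sep Field separator, `","` by default.
#' @return Named list of [trajectory()] objects (a "recording").
#' @export
read_trajectories <- function(path, sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("timestamp", "object_id", "x", "y")
  if (!all(needed %in% names(df)))
    stop("missing column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  if (nrow(df) == 0L) return(stats::setNames(list(), character(0)))
  df$object_id <- as.character(df$object_id)
  for (col in c("timestamp", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric or non-finite '%s' in file row %d",
                   col, bad[1L] + 1L))  # +1 for the header line
    df[[col]] <- v
  }
  df$.row <- seq_len(nrow(df)) + 1L
  dup <- duplicated(df[, c("timestamp", "object_id")])
  if (any(dup))
    stop(sprintf("duplicate (timestamp, object_id) pair in file row %d",
                 df$.row[which(dup)[1L]]))
  out <- lapply(split(df, df$object_id), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    if (nrow(d) > 1L) {
      dt <- diff(d$timestamp)
      if (any(dt <= 0))
        stop(sprintf("non-increasing timestamps for object '%s'",
                     d$object_id[1L]))
      if (diff(range(dt)) > 1e-9)
        stop(sprintf(
          "non-uniform sampling for object '%s' near file row %d",
          d$object_id[1L], d$.row[which.max(abs(dt - dt[1L])) + 1L]))
      si <- stats::median(dt)
    } else {
      si <- 1  # single sample: interval unknowable, use 1 s
    }
    trajectory(d$object_id[1L], cbind(d$x, d$y), si)
  })
  out[order(names(out))]
}

#' Write a recording to long-format CSV
#'
#' Inverse of [read_trajectories()]: timestamps are `i * sample_interval`
#' for sample index i (0-based), printed with enough digits to round-trip.
#'
#' @param recording Named list of [trajectory()] objects.
#' @param path Output path.
#' @export
write_trajectories <- function(recording, path) {
  rows <- lapply(recording, function(tr) {
    n <- n_samples(tr)
    data.frame(
      timestamp = (seq_len(n) - 1L) * tr$sample_interval,
      object_id = tr$object_id,
      x = tr$positions[, 1L], y = tr$positions[, 2L],
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$timestamp, df$object_id), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("timestamp,object_id,x,y", con)
  if (!is.null(df) && nrow(df) > 0L)
    writeLines(sprintf("%.17g,%s,%.17g,%.17g",
                       df$timestamp, df$object_id, df$x, df$y), con)
  invisible(path)
}

#' Write ranked matches as TSV
#'
#' Columns: `rank`, `start_index`, `end_index`, `start_seconds`,
#' `raw_cost`, `normalized_distance` (6 decimals), `permutation` (`.` when
#' roles were not permuted). Ordering follows the input ranks, so output is
#' deterministic.
#'
#' @param results A `qtc_matches` data.frame.
#' @param path Output path (or `""` for standard output).
#' @export
write_results <- function(results, path) {
  check_ranked(results)
  header <- paste(c("rank", "start_index", "end_index", "start_seconds",
                    "raw_cost", "normalized_distance", "permutation"),
                  collapse = "\t")
  perm <- results$permutation
  if (is.null(perm)) perm <- rep(NA_character_, nrow(results))
  perm[is.na(perm)] <- "."
  lines <- sprintf("%d\t%d\t%d\t%.6f\t%g\t%.6f\t%s",
                   results$rank, results$start_index, results$end_index,
                   results$start_seconds, results$raw_cost,
                   results$normalized, perm)
  writeLines(c(header, lines), if (nzchar(path)) path else stdout())
  invisible(path)
}

#' Read a ranked-results TSV back
#'
#' @param path Path written by [write_results()].
#' @return A `qtc_matches` data.frame (distances at printed precision).
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "normalized_distance"] <- "normalized"
  df$permutation[df$permutation == "."] <- NA_character_
  class(df) <- c("qtc_matches", "data.frame")
  df
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Keys mirror the command-line flag names with `-` replaced by
#' `_`. Values stay character; the CLI coerces them.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1L)) != 3L)
  if (length(bad) > 0L)
    stop("malformed config line: ", lines[bad[1L]])
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, function(m) gsub("-", "_", m[2L]),
                         character(1L)))
}
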