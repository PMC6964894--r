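# Reference-fragment matching: slide candidate windows over the recording,
# encode each one, rank by normalized distance to the reference, filter
# overlapping survivors greedily and return the top-k; optionally minimise
# over role permutations of a chosen subset of the moving objects.

#' All role assignments of a permutable id set
#'
#' Enumerates every bijection from the permutable reference roles onto the
#' permutable window objects, identity first, in lexicographic order of the
#' assignment. Used by [match_reference()] when `permutable_ids` is
#' non-empty; exported for inspection.
#'
#' @param ids Character vector of permutable moving object ids.
#' @return List of named character vectors; each maps reference role ->
#'   window object id.
#' @examples
#' length(role_permutations(c("P1", "P2", "P3")))  # 6
#' @export
role_permutations <- function(ids) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n == 0L) return(list(stats::setNames(character(0), character(0))))
  perm_idx <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      out <- c(out, lapply(perm_idx(v[-k]), function(p) c(v[k], p)))
    out
  }
  lapply(perm_idx(seq_len(n)), function(p) stats::setNames(ids[p], ids))
}

format_permutation <- function(mapping) {
  changed <- names(mapping)[mapping != names(mapping)]
  if (length(changed) == 0L) return("identity")
  paste(paste0(names(mapping), "=", mapping), collapse = ",")
}

# half-open interval overlap on original-resolution sample indices
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

#' Match a reference fragment against all sliding windows of a recording
#'
#' The reference window `[ref_start, ref_start + ref_length)` is extracted,
#' downsampled and encoded once. Every fully contained candidate window
#' (starts 0, stride, 2*stride, ...) is then downsampled, encoded and scored
#' by its normalized alignment distance to the reference. Windows that share
#' any original-resolution sample with the reference window are excluded —
#' otherwise the reference would trivially occupy rank 1. Results are sorted
#' by ascending normalized distance with earlier start index breaking ties.
#'
#' When `permutable_ids` is non-empty, each window is scored under every
#' role assignment of those objects ([role_permutations()]) and the minimum
#' is kept, so a pattern performed by other players than the reference ones
#' is still recognised. Static anchors are never permuted.
#'
#' @param recording Named list of [trajectory()] objects.
#' @param object_ids Moving-object roster, in order.
#' @param ref_start,ref_length Reference window (0-based start, samples).
#' @param window Candidate window length in samples; defaults to
#'   `ref_length`. Must be >= 2 * `downsample_factor` so that at least two
#'   samples survive downsampling.
#' @param stride Step between candidate starts, in samples.
#' @param downsample_factor Temporal reduction applied to reference and
#'   candidates alike (see [downsample_fragment()]).
#' @param epsilon Dead-band in metres for the relation characters.
#' @param scheme Substitution-cost scheme ([cost_scheme()]).
#' @param statics List of [static_point()] anchors added to every fragment.
#' @param permutable_ids Subset of `object_ids` whose roles may be swapped.
#' @return A data.frame of class `qtc_matches` with columns `rank`,
#'   `start_index`, `end_index` (half-open, original resolution),
#'   `start_seconds`, `raw_cost`, `normalized`, `permutation`.
#' @seealso [filter_non_overlapping()], [top_k()]
#' @export
match_reference <- function(recording, object_ids, ref_start, ref_length,
                            window = ref_length, stride = 10,
                            downsample_factor = 1, epsilon = 0,
                            scheme = qtc_chain_scheme(), statics = list(),
                            permutable_ids = character(0)) {
  object_ids <- as.character(object_ids)
  permutable_ids <- as.character(permutable_ids)
  downsample_factor <- as.integer(downsample_factor)
  window <- as.integer(window); stride <- as.integer(stride)
  if (downsample_factor < 1L) stop("'downsample_factor' must be >= 1")
  if (window < 2L * downsample_factor)
    stop("'window' must be at least 2 * downsample_factor")
  if (length(setdiff(permutable_ids, object_ids)) > 0L)
    stop("'permutable_ids' must be a subset of the moving 'object_ids'")
  static_ids <- vapply(statics, function(s) s$point_id, character(1L))
  if (length(intersect(permutable_ids, static_ids)) > 0L)
    stop("static points cannot be permuted")

  ref <- make_fragment(recording, object_ids, ref_start, ref_length, statics)
  ref_seq <- encode_sequence(downsample_fragment(ref, downsample_factor),
                             epsilon)

  ns <- min(vapply(recording[object_ids], n_samples, integer(1L)))
  if (window > ns) stop("recording shorter than one candidate window")
  starts <- seq.int(0L, by = stride,
                    length.out = count_windows(ns, window, stride))
  ref_end <- ref_start + ref_length
  starts <- starts[!vapply(starts, function(s)
    intervals_overlap(s, s + window, ref_start, ref_end), logical(1L))]

  perms <- if (length(permutable_ids) > 0L) role_permutations(permutable_ids)
           else NULL

  score_window <- function(s) {
    if (is.null(perms)) {
      frag <- make_fragment(recording, object_ids, s, window, statics)
      al <- normalized_distance(
        encode_sequence(downsample_fragment(frag, downsample_factor),
                        epsilon),
        ref_seq, scheme)
      return(list(raw = al$raw_cost, norm = al$normalized,
                  perm = NA_character_))
    }
    best <- NULL
    for (mp in perms) {
      # reference role r reads the window positions of object mp[r]
      ids <- object_ids
      src <- ids
      src[match(names(mp), ids)] <- mp
      frag <- make_fragment(recording, src, s, window, statics)
      # relabel: roster order stays object_ids, positions come from src
      frag$moving <- stats::setNames(
        Map(function(tr, id) trajectory(id, tr$positions,
                                        tr$sample_interval),
            frag$moving, ids),
        ids)
      al <- normalized_distance(
        encode_sequence(downsample_fragment(frag, downsample_factor),
                        epsilon),
        ref_seq, scheme)
      if (is.null(best) || al$normalized < best$norm)
        best <- list(raw = al$raw_cost, norm = al$normalized,
                     perm = format_permutation(mp))
    }
    best
  }

  scored <- lapply(starts, score_window)
  res <- data.frame(
    start_index = as.integer(starts),
    end_index = as.integer(starts) + window,
    start_seconds = as.numeric(starts) *
      recording[[object_ids[1L]]]$sample_interval,
    raw_cost = vapply(scored, function(x) x$raw, numeric(1L)),
    normalized = vapply(scored, function(x) x$norm, numeric(1L)),
    permutation = vapply(scored, function(x) x$perm, character(1L)),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$normalized, res$start_index), , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  class(res) <- c("qtc_matches", "data.frame")
  res
}

#' Match allowing role permutations between players
#'
#' Convenience wrapper around [match_reference()] that requires a non-empty
#' permutable set.
#'
#' @inheritParams match_reference
#' @return A `qtc_matches` data.frame; the `permutation` column records the
#'   minimising role assignment per window.
#' @export
match_with_permutations <- function(recording, object_ids, ref_start,
                                    ref_length, permutable_ids = object_ids,
                                    ...) {
  if (length(permutable_ids) == 0L)
    stop("'permutable_ids' must be non-empty")
  match_reference(recording, object_ids, ref_start, ref_length,
                  permutable_ids = permutable_ids, ...)
}

check_ranked <- function(ranked) {
  stopifnot(is.data.frame(ranked))
  needed <- c("rank", "start_index", "end_index", "normalized")
  if (!all(needed %in% names(ranked)))
    stop("'ranked' must carry columns ", paste(needed, collapse = ", "))
  if (nrow(ranked) > 0L && !identical(as.integer(ranked$rank),
                                      seq_len(nrow(ranked))))
    stop("'ranked' must be sorted with contiguous ranks starting at 1")
  invisible(ranked)
}

#' Greedy non-overlap filtering of ranked matches
#'
#' Scans the ranked list from rank 1 and keeps a window only when it shares
#' no original-resolution sample with any better-ranked kept window;
#' survivors are re-ranked contiguously. This removes the near-duplicate
#' windows a small stride inevitably produces around each genuine match.
#'
#' @param ranked A `qtc_matches` data.frame sorted by rank.
#' @return The surviving rows, re-ranked from 1.
#' @export
filter_non_overlapping <- function(ranked) {
  check_ranked(ranked)
  keep <- logical(nrow(ranked))
  kept_s <- integer(0); kept_e <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    s <- ranked$start_index[i]; e <- ranked$end_index[i]
    if (!any(s < kept_e & kept_s < e)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
    }
  }
  out <- ranked[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Best k surviving matches
#'
#' @param ranked A ranked (and typically non-overlap-filtered)
#'   `qtc_matches` data.frame.
#' @param k Number of results to keep (>= 1).
#' @return The first `min(k, nrow)` rows.
#' @export
top_k <- function(ranked, k) {
  check_ranked(ranked)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1")
  utils::head(ranked, k)
}

#' @export
print.qtc_matches <- function(x, ...) {
  cat(sprintf("<%d ranked candidate fragment(s)>\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}
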