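# QTC_B encoding: discrete qualitative relations between pairs of objects,
# per-interval relation matrices and the matrix sequence describing a
# fragment.
#
# For an ordered pair (k, l) and the interval t1 -> t2, the relation of k
# with respect to l is '-' when k moves towards l's position at t1, '+' when
# it moves away from it, and '0' otherwise. Characters are coded internally
# as integers -1, 0, +1.

QTC_CHARS <- c("-", "0", "+")

code_to_char <- function(code) QTC_CHARS[code + 2L]
char_to_code <- function(ch) {
  code <- match(ch, QTC_CHARS) - 2L
  if (anyNA(code)) stop("invalid QTC character; must be one of '-', '0', '+'")
  code
}

#' QTC_B relation of one object with respect to another
#'
#' Classifies the movement of object k over one inter-sample interval
#' relative to the position of object l at the interval start: `'-'` if k
#' moves towards it, `'+'` if away, `'0'` if neither. Formally, with
#' Euclidean distance d, let `delta = d(k_t2, l_t1) - d(k_t1, l_t1)`;
#' the result is `'-'` when `delta < -epsilon`, `'+'` when
#' `delta > epsilon`, and `'0'` otherwise.
#'
#' @param pos_k_t1,pos_k_t2 Numeric length-2 positions of the moving object
#'   at the interval start and end.
#' @param pos_l_t1 Position of the other object at the interval start.
#' @param epsilon Non-negative dead-band in metres within which a distance
#'   change counts as `'0'`. The default 0 is the canonical definition;
#'   a small positive value (~0.05 m) absorbs tracking jitter.
#' @return One of `"-"`, `"0"`, `"+"`.
#' @examples
#' qtc_character(c(0, 0), c(1, 0), c(5, 0))  # "-"
#' qtc_character(c(0, 0), c(0, 1), c(5, 0))  # "+"
#' @export
qtc_character <- function(pos_k_t1, pos_k_t2, pos_l_t1, epsilon = 0) {
  stopifnot(length(pos_k_t1) == 2L, length(pos_k_t2) == 2L,
            length(pos_l_t1) == 2L)
  if (!all(is.finite(c(pos_k_t1, pos_k_t2, pos_l_t1))))
    stop("positions must be finite")
  if (!is.finite(epsilon) || epsilon < 0)
    stop("'epsilon' must be >= 0")
  delta <- sqrt(sum((pos_k_t2 - pos_l_t1)^2)) -
    sqrt(sum((pos_k_t1 - pos_l_t1)^2))
  code_to_char((delta > epsilon) - (delta < -epsilon))
}

# Informative pairs of a roster: every unordered pair with at least one
# moving member; static-static pairs carry no information and are excluded.
informative_pairs <- function(n_moving, n_static) {
  n <- n_moving + n_static
  if (n_moving < 1L) stop("at least one moving object is required")
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- idx[, 1L] <= n_moving  # i < j, so i moving <=> pair informative
  cbind(i = as.integer(idx[keep, 1L]), j = as.integer(idx[keep, 2L]))
}

# positions of every roster member as a list of n x 2 matrices
# (statics replicated to constant rows)
roster_positions <- function(fragment) {
  n <- n_samples(fragment)
  c(lapply(fragment$moving, function(tr) tr$positions),
    lapply(fragment$statics, function(s)
      matrix(s$position, nrow = n, ncol = 2L, byrow = TRUE)))
}

# integer relation codes for all intervals at once:
# rows = intervals, columns = (pair1 fwd, pair1 rev, pair2 fwd, ...)
interval_codes <- function(fragment, epsilon = 0) {
  if (!is.finite(epsilon) || epsilon < 0) stop("'epsilon' must be >= 0")
  n <- n_samples(fragment)
  if (n < 2L) stop("a fragment needs at least 2 samples to encode")
  pos <- roster_positions(fragment)
  pairs <- informative_pairs(length(fragment$moving),
                             length(fragment$statics))
  t1 <- seq_len(n - 1L); t2 <- t1 + 1L
  codes <- matrix(0L, nrow = n - 1L, ncol = 2L * nrow(pairs))
  edist <- function(a, b) sqrt(rowSums((a - b)^2))
  classify <- function(delta)
    as.integer((delta > epsilon) - (delta < -epsilon))
  for (p in seq_len(nrow(pairs))) {
    pi <- pos[[pairs[p, 1L]]]; pj <- pos[[pairs[p, 2L]]]
    d0 <- edist(pi[t1, , drop = FALSE], pj[t1, , drop = FALSE])
    # i with respect to j: i's movement against j's start-of-interval anchor
    codes[, 2L * p - 1L] <-
      classify(edist(pi[t2, , drop = FALSE], pj[t1, , drop = FALSE]) - d0)
    # j with respect to i
    d0r <- edist(pj[t1, , drop = FALSE], pi[t1, , drop = FALSE])
    codes[, 2L * p] <-
      classify(edist(pj[t2, , drop = FALSE], pi[t1, , drop = FALSE]) - d0r)
  }
  list(pairs = pairs, codes = codes)
}

#' QTC relation matrix for one inter-sample interval
#'
#' For every informative object pair (at least one member moving) the matrix
#' holds the two-character cell: first the relation of the pair's first
#' object with respect to the second, then the reverse. A static anchor's
#' own character is always `'0'`.
#'
#' @param fragment A `qtc_fragment` with >= 2 samples.
#' @param interval_index 0-based interval index
#'   (interval i spans samples i and i + 1).
#' @param epsilon Dead-band in metres, see [qtc_character()].
#' @return An object of class `qtc_matrix`.
#' @seealso [qtc_cell()] to look a cell up by object ids.
#' @export
qtc_matrix <- function(fragment, interval_index, epsilon = 0) {
  stopifnot(inherits(fragment, "qtc_fragment"))
  interval_index <- as.integer(interval_index)
  n_int <- n_samples(fragment) - 1L
  if (is.na(interval_index) || interval_index < 0L ||
      interval_index >= n_int)
    stop(sprintf("'interval_index' must be in [0, %d)", n_int))
  enc <- interval_codes(fragment, epsilon)
  roster <- fragment_roster(fragment)
  new_qtc_matrix(c(roster$moving, roster$static), length(roster$moving),
                 enc$pairs, enc$codes[interval_index + 1L, ])
}

new_qtc_matrix <- function(objects, n_moving, pairs, codes_row) {
  structure(
    list(objects = objects, n_moving = n_moving, pairs = pairs,
         chars = matrix(code_to_char(codes_row), ncol = 2L, byrow = TRUE)),
    class = "qtc_matrix"
  )
}

#' Look up one cell of a QTC matrix
#'
#' @param m A `qtc_matrix`.
#' @param id_a,id_b Object ids of the pair.
#' @return Character vector of length 2: the relation of `id_a` with respect
#'   to `id_b`, then the reverse.
#' @export
qtc_cell <- function(m, id_a, id_b) {
  stopifnot(inherits(m, "qtc_matrix"))
  ia <- match(id_a, m$objects); ib <- match(id_b, m$objects)
  if (is.na(ia) || is.na(ib)) stop("unknown object id")
  if (ia == ib) stop("a cell needs two distinct objects")
  swap <- ia > ib
  p <- which(m$pairs[, 1L] == min(ia, ib) & m$pairs[, 2L] == max(ia, ib))
  if (length(p) != 1L)
    stop("no cell for this pair (static-static pairs are not stored)")
  cell <- m$chars[p, ]
  if (swap) rev(cell) else cell
}

#' @export
print.qtc_matrix <- function(x, ...) {
  cat(sprintf("<QTC matrix: %d objects, %d cells>\n",
              length(x$objects), nrow(x$pairs)))
  lab <- apply(x$pairs, 1L, function(p)
    paste0(x$objects[p[1L]], "|", x$objects[p[2L]]))
  cat(paste0("  ", lab, ": ", x$chars[, 1L], x$chars[, 2L]), sep = "\n")
  invisible(x)
}

#' Encode a fragment as a QTC matrix sequence
#'
#' Transforms a fragment of m samples into its sequence of m - 1 relation
#' matrices, one per inter-sample interval, which is the representation all
#' distance computations operate on.
#'
#' @inheritParams qtc_matrix
#' @return An object of class `qtc_sequence` with one matrix per interval.
#' @examples
#' rec <- list(P1 = trajectory("P1", cbind(0:10, 0), 0.04),
#'             P2 = trajectory("P2", cbind(10:0, 0), 0.04))
#' s <- encode_sequence(make_fragment(rec, c("P1", "P2"), 0, 11))
#' length(s)  # 10
#' @export
encode_sequence <- function(fragment, epsilon = 0) {
  stopifnot(inherits(fragment, "qtc_fragment"))
  enc <- interval_codes(fragment, epsilon)
  roster <- fragment_roster(fragment)
  structure(
    list(objects = c(roster$moving, roster$static),
         n_moving = length(roster$moving),
         n_static = length(roster$static),
         pairs = enc$pairs, codes = enc$codes,
         start_index = fragment$start_index,
         downsample_factor =
           if (is.null(fragment$downsample_factor)) 1L
           else fragment$downsample_factor,
         sample_interval = fragment$sample_interval),
    class = "qtc_sequence"
  )
}

#' @export
length.qtc_sequence <- function(x) nrow(x$codes)

#' @export
print.qtc_sequence <- function(x, ...) {
  cat(sprintf(
    "<QTC sequence: %d matrices, %d moving + %d static objects>\n",
    length(x), x$n_moving, x$n_static))
  invisible(x)
}

#' Extract one matrix of a sequence
#'
#' @param seq A `qtc_sequence`.
#' @param interval_index 0-based interval index.
#' @return A `qtc_matrix`.
#' @export
sequence_matrix <- function(seq, interval_index) {
  stopifnot(inherits(seq, "qtc_sequence"))
  i <- as.integer(interval_index)
  if (is.na(i) || i < 0L || i >= length(seq))
    stop("interval index out of range")
  new_qtc_matrix(seq$objects, seq$n_moving, seq$pairs, seq$codes[i + 1L, ])
}

#' Plain-text serialization of a QTC sequence
#'
#' One line per interval; each cell rendered as `idA|idB:xy` with the pair
#' in lexicographic id order and x, y the two relation characters. The
#' format is bit-exact across platforms and intended for inspection and
#' debugging.
#'
#' @param seq A `qtc_sequence`.
#' @return Character vector, one element per interval.
#' @export
format_qtc_sequence <- function(seq) {
  stopifnot(inherits(seq, "qtc_sequence"))
  if (length(seq) == 0L) return(character(0))
  id_a <- seq$objects[seq$pairs[, 1L]]
  id_b <- seq$objects[seq$pairs[, 2L]]
  flip <- id_a > id_b
  lab <- ifelse(flip, paste0(id_b, "|", id_a), paste0(id_a, "|", id_b))
  ord <- order(lab)
  vapply(seq_len(length(seq)), function(t) {
    row <- seq$codes[t, ]
    fwd <- code_to_char(row[seq(1L, length(row), by = 2L)])
    rev_ <- code_to_char(row[seq(2L, length(row), by = 2L)])
    x <- ifelse(flip, rev_, fwd)
    y <- ifelse(flip, fwd, rev_)
    paste0(lab[ord], ":", x[ord], y[ord], collapse = " ")
  }, character(1L))
}

# check that two sequences describe the same roster
check_same_roster <- function(a, b) {
  if (!identical(a$objects, b$objects) || a$n_moving != b$n_moving ||
      a$n_static != b$n_static)
    stop("sequences must share an identical object roster")
  invisible(TRUE)
}
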