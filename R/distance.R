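# Distances between QTC matrix sequences: conceptual-distance substitution
# costs, the alignment (Levenshtein) distance with insertions/deletions at
# the maximum substitution cost, its normalized [0, 1] form, the
# substitution-only pairwise baseline, and a threshold-aborted variant.

#' Construct a substitution-cost scheme
#'
#' A cost scheme maps every pair of QTC characters to a non-negative
#' substitution cost. It must be a metric over the three symbols: zero on
#' the diagonal, symmetric, and satisfying the triangle inequality.
#'
#' @param char_distance 3x3 numeric matrix with rows and columns named
#'   `-`, `0`, `+`.
#' @param description Short label for the scheme.
#' @return An object of class `qtc_cost_scheme`.
#' @seealso [qtc_chain_scheme()] for the default conceptual-distance scheme.
#' @export
cost_scheme <- function(char_distance, description = "custom") {
  m <- as.matrix(char_distance)
  if (!identical(dim(m), c(3L, 3L)))
    stop("'char_distance' must be a 3x3 matrix")
  if (is.null(dimnames(m))) dimnames(m) <- list(QTC_CHARS, QTC_CHARS)
  m <- m[QTC_CHARS, QTC_CHARS]
  if (any(!is.finite(m)) || any(m < 0))
    stop("costs must be finite and non-negative")
  if (any(diag(m) != 0)) stop("identical characters must cost 0")
  if (!isTRUE(all.equal(m, t(m)))) stop("costs must be symmetric")
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    if (m[i, j] > m[i, k] + m[k, j] + 1e-12)
      stop("costs must satisfy the triangle inequality")
  structure(list(char_distance = m, d_max = max(m),
                 indel_policy = "max-substitution",
                 description = description),
            class = "qtc_cost_scheme")
}

#' Default conceptual-distance cost scheme
#'
#' Substitution costs follow the conceptual neighbourhood chain
#' `'-' <-> '0' <-> '+'`: adjacent symbols cost 1, the two extremes cost 2,
#' identical symbols cost 0. Costs are small integers, so all raw distances
#' are integer-valued and platform-reproducible.
#'
#' @return A `qtc_cost_scheme`.
#' @export
qtc_chain_scheme <- function() {
  m <- abs(outer(-1:1, -1:1, "-"))
  dimnames(m) <- list(QTC_CHARS, QTC_CHARS)
  cost_scheme(m, "conceptual neighbourhood chain - <-> 0 <-> +")
}

#' @export
print.qtc_cost_scheme <- function(x, ...) {
  cat(sprintf("<cost scheme: %s; indel = max substitution>\n",
              x$description))
  print(x$char_distance)
  invisible(x)
}

#' Substitution cost between two QTC characters
#'
#' @param a,b Characters among `"-"`, `"0"`, `"+"`.
#' @param scheme A [cost_scheme()]; defaults to the conceptual
#'   neighbourhood chain.
#' @return Non-negative cost.
#' @examples
#' character_distance("-", "+")  # 2
#' @export
character_distance <- function(a, b, scheme = qtc_chain_scheme()) {
  stopifnot(inherits(scheme, "qtc_cost_scheme"))
  ia <- match(a, QTC_CHARS); ib <- match(b, QTC_CHARS)
  if (anyNA(ia) || anyNA(ib))
    stop("invalid QTC character; must be one of '-', '0', '+'")
  unname(scheme$char_distance[cbind(ia, ib)])
}

#' Alignment cost between two QTC matrices
#'
#' Sum over all informative pairs of the substitution costs of both
#' characters of the cell. Identical matrices cost 0.
#'
#' @param m1,m2 `qtc_matrix` objects over identical rosters.
#' @inheritParams character_distance
#' @return Non-negative cost.
#' @export
matrix_cost <- function(m1, m2, scheme = qtc_chain_scheme()) {
  stopifnot(inherits(m1, "qtc_matrix"), inherits(m2, "qtc_matrix"))
  if (!identical(m1$objects, m2$objects) || !identical(m1$pairs, m2$pairs))
    stop("matrices must share an identical object roster")
  sum(character_distance(as.vector(m1$chars), as.vector(m2$chars), scheme))
}

#' Maximum possible single-matrix substitution cost for a roster
#'
#' With P informative pairs (all pairs except static-static), two
#' characters per cell and maximal character distance d_max, the maximum
#' substitution cost is `P * 2 * d_max`. Insertions and deletions of whole
#' matrices are charged at this cost.
#'
#' @param n_moving Number of moving objects (>= 1).
#' @param n_static Number of static anchor points.
#' @inheritParams character_distance
#' @return The maximum substitution cost (also the indel cost).
#' @examples
#' max_matrix_cost(2, 0)  # 4
#' max_matrix_cost(2, 4)  # 36
#' @export
max_matrix_cost <- function(n_moving, n_static = 0,
                            scheme = qtc_chain_scheme()) {
  stopifnot(inherits(scheme, "qtc_cost_scheme"))
  n_moving <- as.integer(n_moving); n_static <- as.integer(n_static)
  if (is.na(n_moving) || n_moving < 1L)
    stop("at least one moving object is required")
  if (is.na(n_static) || n_static < 0L) stop("'n_static' must be >= 0")
  p <- choose(n_moving + n_static, 2) - choose(n_static, 2)
  p * 2 * scheme$d_max
}

# -- internal fast paths over the integer code matrices ----------------------

# la x lb matrix of substitution costs between all matrix pairs of two
# sequences; vectorized lookup over the 3x3 character-cost table
code_cost_matrix <- function(codes_a, codes_b, tab) {
  la <- nrow(codes_a); lb <- nrow(codes_b)
  s <- matrix(0, la, lb)
  for (k in seq_len(ncol(codes_a)))
    s <- s + tab[codes_a[, k] + 2L, codes_b[, k] + 2L, drop = FALSE]
  s
}

seq_indel_cost <- function(seq, scheme)
  max_matrix_cost(seq$n_moving, seq$n_static, scheme)

check_comparable <- function(seq_a, seq_b) {
  stopifnot(inherits(seq_a, "qtc_sequence"), inherits(seq_b, "qtc_sequence"))
  check_same_roster(seq_a, seq_b)
}

# full dynamic program; returns final cell, or the exceeded marker (NA)
# as soon as the smallest entry of a row exceeds `cutoff` (every alignment
# path crosses every row with non-decreasing cost, so the row minimum is a
# valid lower bound on the final distance)
levenshtein_dp <- function(s, indel, cutoff = Inf) {
  la <- nrow(s); lb <- ncol(s)
  prev <- (0:lb) * indel
  if (la == 0L || lb == 0L) {
    d <- max(la, lb) * indel
    return(if (d > cutoff) NA_real_ else d)
  }
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1L)
    cur[1L] <- i * indel
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j] + s[i, j],      # substitute
                         prev[j + 1L] + indel,   # delete from a
                         cur[j] + indel)         # insert from b
    }
    if (min(cur) > cutoff) return(NA_real_)
    prev <- cur
  }
  d <- prev[lb + 1L]
  if (d > cutoff) NA_real_ else d
}

#' Levenshtein distance between two QTC matrix sequences
#'
#' Minimum total cost over all alignments of the two sequences, where
#' substituting one matrix for another costs their [matrix_cost()] and
#' inserting or deleting a matrix costs the roster's maximum substitution
#' cost ([max_matrix_cost()]). Because indels are allowed, sequences of
#' different lengths — movements performed at different speeds — can be
#' compared. Computed by dynamic programming over the full alignment table.
#'
#' @param seq_a,seq_b `qtc_sequence` objects over identical rosters.
#' @inheritParams character_distance
#' @return Raw alignment cost (non-negative; integer-valued under the
#'   default scheme).
#' @export
qtc_levenshtein <- function(seq_a, seq_b, scheme = qtc_chain_scheme()) {
  check_comparable(seq_a, seq_b)
  stopifnot(inherits(scheme, "qtc_cost_scheme"))
  s <- code_cost_matrix(seq_a$codes, seq_b$codes, scheme$char_distance)
  levenshtein_dp(s, seq_indel_cost(seq_a, scheme))
}

#' Threshold-aborted Levenshtein distance
#'
#' Identical to [qtc_levenshtein()] but abandons the computation as soon as
#' the distance provably exceeds `threshold`, a large saving when screening
#' many candidate fragments of which most are dissimilar.
#'
#' @inheritParams qtc_levenshtein
#' @param threshold Non-negative cost cutoff.
#' @return List with `raw_cost` (the exact distance, or `NA` when
#'   exceeded) and logical `exceeded`. When `exceeded` is `FALSE` the
#'   returned cost equals [qtc_levenshtein()].
#' @export
qtc_levenshtein_cutoff <- function(seq_a, seq_b, threshold,
                                   scheme = qtc_chain_scheme()) {
  check_comparable(seq_a, seq_b)
  stopifnot(inherits(scheme, "qtc_cost_scheme"))
  if (!is.finite(threshold) || threshold < 0)
    stop("'threshold' must be >= 0")
  s <- code_cost_matrix(seq_a$codes, seq_b$codes, scheme$char_distance)
  d <- levenshtein_dp(s, seq_indel_cost(seq_a, scheme), cutoff = threshold)
  list(raw_cost = d, exceeded = is.na(d))
}

#' Normalized alignment distance between two QTC matrix sequences
#'
#' Divides the raw alignment cost by the maximum possible distance,
#' `max(length_a, length_b) * c_max` with `c_max` the roster's maximum
#' single-matrix substitution cost, yielding a relative distance in
#' [0, 1]: 0 for identical relative movements, 1 for maximally different
#' ones. Two empty sequences have distance 0 by convention.
#'
#' @inheritParams qtc_levenshtein
#' @return An object of class `qtc_alignment` with elements `raw_cost`,
#'   `normalized`, `length_a`, `length_b`, `c_max`.
#' @export
normalized_distance <- function(seq_a, seq_b, scheme = qtc_chain_scheme()) {
  check_comparable(seq_a, seq_b)
  la <- length(seq_a); lb <- length(seq_b)
  c_max <- seq_indel_cost(seq_a, scheme)
  if (la == 0L && lb == 0L) {
    raw <- 0; norm <- 0
  } else {
    raw <- qtc_levenshtein(seq_a, seq_b, scheme)
    norm <- raw / (max(la, lb) * c_max)
  }
  structure(list(raw_cost = raw, normalized = norm,
                 length_a = la, length_b = lb, c_max = c_max),
            class = "qtc_alignment")
}

#' @export
print.qtc_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment: raw %g, normalized %.6f (lengths %d vs %d, c_max %g)>\n",
    x$raw_cost, x$normalized, x$length_a, x$length_b, x$c_max))
  invisible(x)
}

#' Pairwise-comparison distance (substitution-only baseline)
#'
#' Sums the matrix costs of position-aligned matrix pairs with no
#' insertions or deletions allowed. Defined only for equal-length
#' sequences. Since the position-aligned path is one admissible alignment,
#' this baseline is always >= the Levenshtein distance; the gap widens when
#' the same movements are performed at different speeds.
#'
#' @inheritParams qtc_levenshtein
#' @return Raw cost of the position-aligned comparison.
#' @export
pairwise_distance <- function(seq_a, seq_b, scheme = qtc_chain_scheme()) {
  check_comparable(seq_a, seq_b)
  stopifnot(inherits(scheme, "qtc_cost_scheme"))
  if (length(seq_a) != length(seq_b))
    stop("pairwise comparison requires equal-length sequences")
  if (length(seq_a) == 0L) return(0)
  tab <- scheme$char_distance
  tot <- 0
  for (k in seq_len(ncol(seq_a$codes)))
    tot <- tot + sum(tab[cbind(seq_a$codes[, k] + 2L,
                               seq_b$codes[, k] + 2L)])
  tot
}

#' Subset the matrices of a QTC sequence
#'
#' @param x A `qtc_sequence`.
#' @param i Index vector over intervals (1-based, as usual for R
#'   subscripts); may produce an empty sequence.
#' @param ... Ignored.
#' @return A `qtc_sequence` over the same roster.
#' @export
`[.qtc_sequence` <- function(x, i, ...) {
  out <- x
  out$codes <- x$codes[i, , drop = FALSE]
  out
}
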