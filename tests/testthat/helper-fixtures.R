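# Shared fixtures: small recordings, seeded random fragments on an integer
# grid (so all three relation characters occur), and a brute-force
# alignment oracle independent of the dynamic program.

# simple deterministic recording of linearly moving objects
h_line_recording <- function(n = 20, rate = 25) {
  list(
    P1 = trajectory("P1", cbind(seq_len(n), 0), 1 / rate),
    P2 = trajectory("P2", cbind(rev(seq_len(n)), 0), 1 / rate),
    P3 = trajectory("P3", cbind(0, seq_len(n)), 1 / rate)
  )
}

# fragment whose objects walk on an integer grid with steps in {-1, 0, 1};
# zero steps make the '0' character common, exercising all three symbols
h_grid_fragment <- function(seed, n, n_moving = 2, n_static = 0) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rec <- stats::setNames(lapply(seq_len(n_moving), function(i) {
    xy <- cbind(cumsum(sample(-1:1, n, replace = TRUE)),
                cumsum(sample(-1:1, n, replace = TRUE)))
    trajectory(paste0("M", i), xy + 10 * i, 0.04)
  }), paste0("M", seq_len(n_moving)))
  statics <- lapply(seq_len(n_static), function(i)
    static_point(paste0("S", i), sample(-20:20, 1), sample(-20:20, 1)))
  make_fragment(rec, names(rec), 0, n, statics)
}

h_grid_sequence <- function(seed, n_intervals, n_moving = 2, n_static = 0)
  encode_sequence(h_grid_fragment(seed, n_intervals + 1L,
                                  n_moving, n_static))

# Brute-force minimum alignment cost: every alignment of two sequences is a
# monotone matching of positions plus indels for the unmatched ones, so
# enumerating all monotone matchings (feasible for lengths <= 5) and taking
# the cheapest is an oracle independent of the dynamic program.
h_oracle_alignment <- function(seq_a, seq_b, scheme = qtc_chain_scheme()) {
  la <- length(seq_a); lb <- length(seq_b)
  indel <- max_matrix_cost(seq_a$n_moving, seq_a$n_static, scheme)
  sub <- matrix(0, max(la, 1L), max(lb, 1L))
  for (i in seq_len(la)) for (j in seq_len(lb))
    sub[i, j] <- matrix_cost(sequence_matrix(seq_a, i - 1L),
                             sequence_matrix(seq_b, j - 1L), scheme)
  best <- (la + lb) * indel  # match nothing
  for (m in seq_len(min(la, lb))) {
    ia <- utils::combn(la, m); ib <- utils::combn(lb, m)
    for (ca in seq_len(ncol(ia))) for (cb in seq_len(ncol(ib))) {
      cost <- sum(sub[cbind(ia[, ca], ib[, cb])]) +
        (la + lb - 2 * m) * indel
      if (cost < best) best <- cost
    }
  }
  best
}
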