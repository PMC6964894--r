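# Substitution costs, alignment distances and their properties.

test_that("chain costs follow the conceptual neighbourhood", {
  expect_equal(character_distance("-", "-"), 0)
  expect_equal(character_distance("-", "0"), 1)
  expect_equal(character_distance("0", "+"), 1)
  expect_equal(character_distance("-", "+"), 2)
  expect_error(character_distance("x", "0"), "invalid QTC character")
})

test_that("cost_scheme enforces the metric axioms on symbols", {
  expect_error(cost_scheme(matrix(1, 3, 3)), "cost 0")
  bad_sym <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(cost_scheme(bad_sym), "symmetric")
  bad_tri <- matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3, 3)
  expect_error(cost_scheme(bad_tri), "triangle")
  sc <- cost_scheme(matrix(c(0, 2, 3, 2, 0, 2, 3, 2, 0), 3, 3), "wide")
  expect_equal(sc$d_max, 3)
  expect_equal(character_distance("-", "0", sc), 2)
})

test_that("matrix cost sums character distances over all cells", {
  fr <- h_grid_fragment(17, n = 10, n_moving = 3, n_static = 1)
  s <- encode_sequence(fr)
  for (pair in list(c(1, 1), c(1, 4), c(2, 7))) {
    m1 <- sequence_matrix(s, pair[1]); m2 <- sequence_matrix(s, pair[2])
    # brute-force cell-by-cell oracle
    expected <- sum(mapply(function(a, b) character_distance(a, b),
                           as.vector(m1$chars), as.vector(m2$chars)))
    expect_equal(matrix_cost(m1, m2), expected)
  }
  expect_equal(matrix_cost(sequence_matrix(s, 3), sequence_matrix(s, 3)), 0)
})

test_that("a single one-step character difference costs 1", {
  rec <- list(A = trajectory("A", cbind(c(0, 1, 1), 0), 0.04),
              B = trajectory("B", cbind(rep(5, 3), 0), 0.04))
  s <- encode_sequence(make_fragment(rec, c("A", "B"), 0, 3))
  # interval 1: A approaches B ('-'); interval 2: A stationary ('0')
  expect_equal(matrix_cost(sequence_matrix(s, 0), sequence_matrix(s, 1)), 1)
})

test_that("max_matrix_cost counts informative pairs", {
  expect_equal(max_matrix_cost(2, 0), 4)
  expect_equal(max_matrix_cost(2, 4), 36)   # 15 - 6 = 9 pairs
  expect_equal(max_matrix_cost(3, 1), 24)   # 6 pairs
  expect_error(max_matrix_cost(0, 4), "moving")
})

test_that("Levenshtein identity, forced indels and duplication", {
  s <- h_grid_sequence(23, 12, n_moving = 2, n_static = 1)
  expect_equal(qtc_levenshtein(s, s), 0)

  empty <- s[integer(0)]
  c_max <- max_matrix_cost(2, 1)
  expect_equal(qtc_levenshtein(empty, s), 12 * c_max)
  expect_equal(qtc_levenshtein(s, empty), 12 * c_max)

  dup <- s[c(1:5, 5, 6:12)]
  expect_equal(qtc_levenshtein(s, dup), c_max)
  expect_equal(qtc_levenshtein(s, dup), h_oracle_alignment(s, dup))
})

test_that("sequences over different rosters cannot be compared", {
  a <- h_grid_sequence(1, 5, n_moving = 2)
  b <- h_grid_sequence(1, 5, n_moving = 3)
  expect_error(qtc_levenshtein(a, b), "roster")
})

test_that("dynamic program equals exhaustive alignment enumeration", {
  set.seed(91)
  for (rep in 1:60) {
    la <- sample(0:5, 1); lb <- sample(1:5, 1)
    base <- h_grid_sequence(1000 + rep, 6, n_moving = 2)
    other <- h_grid_sequence(5000 + rep, 6, n_moving = 2)
    a <- base[seq_len(la)]
    b <- other[seq_len(lb)]
    expect_equal(qtc_levenshtein(a, b), h_oracle_alignment(a, b),
                 info = sprintf("rep %d (la=%d, lb=%d)", rep, la, lb))
  }
})

test_that("the distance is a metric on short sequences", {
  set.seed(92)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    x <- h_grid_sequence(100 + rep, n)
    y <- h_grid_sequence(300 + rep, sample(2:6, 1))
    z <- h_grid_sequence(500 + rep, sample(2:6, 1))
    dxy <- qtc_levenshtein(x, y)
    dyx <- qtc_levenshtein(y, x)
    dxz <- qtc_levenshtein(x, z)
    dzy <- qtc_levenshtein(z, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, dyx)
    expect_lte(dxy, dxz + dzy + 1e-9)
    expect_equal(qtc_levenshtein(x, x), 0)
    # identity of indiscernibles: 0 iff the code matrices agree
    if (dxy == 0) expect_identical(x$codes, y$codes)
    if (identical(dim(x$codes), dim(y$codes)) &&
        !identical(x$codes, y$codes))
      expect_gt(dxy, 0)
  }
})

test_that("normalized distance lies in [0, 1] with both ends attained", {
  set.seed(93)
  for (rep in 1:40) {
    a <- h_grid_sequence(700 + rep, sample(1:30, 1),
                         n_moving = sample(2:3, 1))
    b <- h_grid_sequence(900 + rep, sample(1:30, 1), n_moving = a$n_moving)
    al <- normalized_distance(a, b)
    expect_gte(al$normalized, 0)
    expect_lte(al$normalized, 1)
    # normalization soundness: raw never exceeds the denominator
    expect_lte(al$raw_cost, max(al$length_a, al$length_b) * al$c_max)
  }
  s <- h_grid_sequence(55, 9)
  expect_equal(normalized_distance(s, s)$normalized, 0)
  expect_equal(normalized_distance(s[integer(0)], s)$normalized, 1)
  e <- s[integer(0)]
  expect_equal(normalized_distance(e, e)$normalized, 0)
})

test_that("appending identical matrices never increases the distance", {
  set.seed(94)
  for (rep in 1:20) {
    a <- h_grid_sequence(1300 + rep, 6)
    b <- h_grid_sequence(1500 + rep, 6)
    tail_seq <- h_grid_sequence(1700 + rep, 4)
    a2 <- a; a2$codes <- rbind(a$codes, tail_seq$codes)
    b2 <- b; b2$codes <- rbind(b$codes, tail_seq$codes)
    expect_lte(qtc_levenshtein(a2, b2), qtc_levenshtein(a, b))
  }
})

test_that("pairwise baseline bounds the Levenshtein distance from above", {
  set.seed(95)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    a <- h_grid_sequence(2100 + rep, n)
    b <- h_grid_sequence(2300 + rep, n)
    expect_lte(qtc_levenshtein(a, b), pairwise_distance(a, b))
  }
  a <- h_grid_sequence(1, 5)
  expect_equal(pairwise_distance(a, a), 0)
  expect_error(pairwise_distance(a, a[1:3]), "equal-length")
})

test_that("a speed-warped copy is closer under alignment than pairwise", {
  # same spatial path, one matrix duplicated and one dropped: length is
  # preserved but the shared intervals shift by one position
  s <- h_grid_sequence(61, 20)
  warped <- s[c(1, 1:9, 11:20)]
  expect_equal(length(warped), length(s))
  lev <- qtc_levenshtein(s, warped)
  pw <- pairwise_distance(s, warped)
  expect_gt(lev, 0)
  expect_lt(lev, pw)
})

test_that("the aborted computation agrees with the full one", {
  s <- h_grid_sequence(71, 8)
  t <- h_grid_sequence(72, 8)
  d <- qtc_levenshtein(s, t)
  got <- qtc_levenshtein_cutoff(s, t, threshold = d)
  expect_false(got$exceeded)
  expect_equal(got$raw_cost, d)
  expect_true(qtc_levenshtein_cutoff(s, t, threshold = 0)$exceeded)
  expect_false(qtc_levenshtein_cutoff(s, s, threshold = 0)$exceeded)
  expect_error(qtc_levenshtein_cutoff(s, t, threshold = -1), ">= 0")

  set.seed(96)
  for (rep in 1:30) {
    a <- h_grid_sequence(2500 + rep, sample(2:10, 1))
    b <- h_grid_sequence(2700 + rep, sample(2:10, 1))
    full <- qtc_levenshtein(a, b)
    thr <- sample(0:ceiling(max(1, full * 1.5)), 1)
    got <- qtc_levenshtein_cutoff(a, b, thr)
    if (full <= thr) {
      expect_false(got$exceeded)
      expect_equal(got$raw_cost, full)
    } else {
      expect_true(got$exceeded)
    }
  }
})
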