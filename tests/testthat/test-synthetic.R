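# Synthetic generators: runs, walks, transforms, time warps and scenes.

test_that("straight_run covers the expected distance", {
  still <- straight_run(c(3, 4), c(1, 0), speed = 0, n = 10)
  expect_true(all(still$positions[, 1] == 3 & still$positions[, 2] == 4))

  run <- straight_run(c(0, 0), c(1, 0), speed = 8, n = 500, rate = 25)
  steps <- sqrt(rowSums(diff(run$positions)^2))
  expect_equal(unique(round(steps, 12)), 0.32)
  expect_equal(sum(steps), 159.68)
  expect_error(straight_run(c(0, 0), c(0, 0), speed = 1, n = 5),
               "non-zero")
})

test_that("parallel runs towards an anchor read '-' at every interval", {
  rec <- list(
    A = straight_run(c(10, 30), c(1, 0), 7, 50, object_id = "A"),
    B = straight_run(c(10, 38), c(1, 0), 7, 50, object_id = "B"))
  goal <- static_point("goal", 105, 34)
  s <- encode_sequence(make_fragment(rec, c("A", "B"), 0, 50,
                                     statics = list(goal)))
  for (id in c("A", "B")) {
    cells <- vapply(seq_len(length(s)) - 1L, function(t)
      qtc_cell(sequence_matrix(s, t), id, "goal")[1], character(1))
    expect_true(all(cells == "-"))
  }
})

test_that("random walks are seed-reproducible and stay in bounds", {
  w1 <- random_walk(5, c(50, 30), 10000, step_sigma = 0.5,
                    bounds = c(0, 105, 0, 68))
  w2 <- random_walk(5, c(50, 30), 10000, step_sigma = 0.5,
                    bounds = c(0, 105, 0, 68))
  expect_identical(w1$positions, w2$positions)
  expect_true(all(w1$positions[, 1] >= 0 & w1$positions[, 1] <= 105))
  expect_true(all(w1$positions[, 2] >= 0 & w1$positions[, 2] <= 68))

  frozen <- random_walk(5, c(50, 30), 10, step_sigma = 0)
  expect_true(all(frozen$positions[, 1] == 50))

  w3 <- random_walk(6, c(50, 30), 100, step_sigma = 0.5)
  expect_false(identical(w1$positions[1:100, ], w3$positions))
})

test_that("transform_fragment applies the similarity transform", {
  fr <- h_grid_fragment(21, n = 10, n_moving = 2, n_static = 1)
  idt <- transform_fragment(fr)
  expect_equal(idt$moving$M1$positions, fr$moving$M1$positions)

  tf <- transform_fragment(fr, translation = c(3, -4), rotation = pi / 2,
                           scale = 2)
  p0 <- fr$moving$M1$positions[1, ]
  expect_equal(unname(tf$moving$M1$positions[1, ]),
               unname(c(-2 * p0[2] + 3, 2 * p0[1] - 4)),
               tolerance = 1e-12)
  # statics stay put unless asked
  expect_equal(tf$statics$S1$position, fr$statics$S1$position)
  expect_error(transform_fragment(fr, scale = 0), "> 0")
})

test_that("a translated copy is identical without statics, not with them", {
  # diagonal motion translated across the far corner's bisecting line
  rec <- list(
    A = straight_run(c(15, 15), c(1, 1), 6, 10, object_id = "A"),
    B = straight_run(c(19, 15), c(1, 1), 6, 10, object_id = "B"))
  free <- make_fragment(rec, c("A", "B"), 0, 10)
  anchored <- make_fragment(rec, c("A", "B"), 0, 10,
                            statics = field_corner_statics())
  moved_free <- transform_fragment(free, translation = c(55, 30))
  moved_anchored <- transform_fragment(anchored, translation = c(55, 30))
  expect_equal(qtc_levenshtein(encode_sequence(moved_free),
                               encode_sequence(free)), 0)
  expect_gt(qtc_levenshtein(encode_sequence(moved_anchored),
                            encode_sequence(anchored)), 0)
})

test_that("encoding commutes with similarity transforms", {
  # 1e-9 dead-band absorbs the rounding of rotated coordinates
  for (seed in 1:5) {
    fr <- h_grid_fragment(seed, n = 15, n_moving = 3)
    tf <- transform_fragment(fr, translation = c(seed, -seed),
                             rotation = seed / 3, scale = 1 + seed / 7)
    expect_identical(encode_sequence(tf, 1e-9)$codes,
                     encode_sequence(fr, 1e-9)$codes)
  }
})

test_that("time_warp repeats and decimates along the same path", {
  fr <- h_grid_fragment(33, n = 20)
  idt <- time_warp(fr, list(list(range = c(1, 20), factor = 1)))
  expect_identical(idt$moving$M1$positions, fr$moving$M1$positions)

  slow <- time_warp(fr, list(list(range = c(5, 8), factor = 2)))
  expect_equal(n_samples(slow), 24)
  expect_true(all(slow$moving$M1$positions %in% fr$moving$M1$positions))

  fast <- time_warp(fr, list(list(range = c(1, 10), factor = 1 / 2)))
  expect_equal(n_samples(fast), 15)
  expect_identical(fast$moving$M1$positions[1:5, ],
                   fr$moving$M1$positions[c(1, 3, 5, 7, 9), ])

  expect_error(time_warp(fr, list(list(range = c(9, 5), factor = 2))),
               "invalid or empty")
  expect_error(time_warp(fr, list(list(range = c(1, 5), factor = 2.5))),
               "integer")
})

test_that("warped fragments are nearer under alignment than pairwise", {
  # same spatial path, slowed early and sped up late to keep the length;
  # needs relations that vary over time, otherwise the shift is free
  for (seed in 1:8) {
    fr <- h_grid_fragment(seed, 40)
    warped <- time_warp(fr, list(list(range = c(5, 8), factor = 2),
                                 list(range = c(21, 28), factor = 1 / 2)))
    expect_equal(n_samples(warped), n_samples(fr))
    a <- encode_sequence(fr); b <- encode_sequence(warped)
    lev <- qtc_levenshtein(a, b)
    pw <- pairwise_distance(a, b)
    expect_gt(lev, 0)
    expect_lt(lev, pw)
  }
})

test_that("scenes are reproducible with annotated planted windows", {
  s1 <- soccer_scene(seed = 77, duration = 30, motif_length = 200,
                     n_exact = 1, n_transformed = 1, align = 25)
  s2 <- soccer_scene(seed = 77, duration = 30, motif_length = 200,
                     n_exact = 1, n_transformed = 1, align = 25)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$annotation), 2)
  expect_true(all(s1$annotation$start_index %% 25 == 0))
  expect_equal(s1$annotation$end_index - s1$annotation$start_index,
               c(200, 200))

  none <- soccer_scene(seed = 78, duration = 10, motif_length = 100,
                       n_exact = 0, n_transformed = 0)
  expect_equal(nrow(none$annotation), 0)
  expect_equal(n_samples(none$recording$P1), 250)

  expect_error(soccer_scene(seed = 1, duration = 4, motif_length = 200),
               "longer than")
})

test_that("generators leave the global RNG state alone", {
  set.seed(1234)
  before <- .Random.seed
  invisible(random_walk(99, c(10, 10), 50, 0.2))
  invisible(soccer_scene(seed = 99, duration = 10, motif_length = 100,
                         n_exact = 1, n_transformed = 1, align = 10))
  expect_identical(.Random.seed, before)
})
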