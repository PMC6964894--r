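# Seeded synthetic trajectory and scene generators. These emulate
# pitch-constrained 25 Hz player tracking — straight runs, direction
# changes, random-walk traffic, positional noise — so every other module
# has a reproducible, self-contained input with known ground truth.

#' Straight constant-speed run
#'
#' @param start Length-2 start position (metres).
#' @param direction Length-2 direction vector (need not be normalised, but
#'   must be non-zero unless `speed` is 0).
#' @param speed Speed in m/s (>= 0).
#' @param n Number of samples (>= 2).
#' @param rate Sampling rate in Hz.
#' @param object_id Identifier for the resulting trajectory.
#' @return A [trajectory()].
#' @examples
#' tr <- straight_run(c(0, 0), c(1, 0), speed = 8, n = 500, rate = 25)
#' @export
straight_run <- function(start, direction, speed, n, rate = 25,
                         object_id = "runner") {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2")
  if (speed < 0) stop("'speed' must be >= 0")
  nd <- sqrt(sum(direction^2))
  if (speed > 0 && nd == 0) stop("'direction' must be non-zero")
  u <- if (nd > 0) direction / nd else c(0, 0)
  step <- speed / rate
  i <- seq_len(n) - 1L
  trajectory(object_id,
             cbind(start[1L] + i * step * u[1L],
                   start[2L] + i * step * u[2L]),
             1 / rate)
}

#' Seeded bounded random walk
#'
#' Gaussian steps reflected at the rectangular bounds, reproducible per
#' seed. Models undirected background traffic rather than purposeful play.
#'
#' @param seed Integer seed (local to this call; the global RNG state is
#'   untouched).
#' @param start Length-2 start position, inside `bounds`.
#' @param n Number of samples (>= 2).
#' @param step_sigma Standard deviation of each coordinate step (metres).
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param object_id Identifier for the resulting trajectory.
#' @param rate Sampling rate in Hz.
#' @return A [trajectory()].
#' @export
random_walk <- function(seed, start, n, step_sigma,
                        bounds = c(0, 105, 0, 68), object_id = "walker",
                        rate = 25) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2")
  if (step_sigma < 0) stop("'step_sigma' must be >= 0")
  if (length(bounds) != 4L || bounds[1L] >= bounds[2L] ||
      bounds[3L] >= bounds[4L])
    stop("'bounds' must be c(xmin, xmax, ymin, ymax) with xmin < xmax")
  if (start[1L] < bounds[1L] || start[1L] > bounds[2L] ||
      start[2L] < bounds[3L] || start[2L] > bounds[4L])
    stop("'start' must lie inside 'bounds'")
  steps <- local_rng(seed, function()
    matrix(stats::rnorm(2L * (n - 1L), sd = step_sigma), ncol = 2L))
  xs <- reflect_cumsum(start[1L], steps[, 1L], bounds[1L], bounds[2L])
  ys <- reflect_cumsum(start[2L], steps[, 2L], bounds[3L], bounds[4L])
  trajectory(object_id, cbind(xs, ys), 1 / rate)
}

# run `fn` under a private RNG state seeded with `seed`
local_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# cumulative positions with reflection at [lo, hi]
reflect_cumsum <- function(start, steps, lo, hi) {
  pos <- numeric(length(steps) + 1L)
  pos[1L] <- start
  width <- hi - lo
  for (i in seq_along(steps)) {
    p <- pos[i] + steps[i]
    # fold into [lo, lo + 2 * width) then reflect the upper half
    p <- lo + abs((p - lo) %% (2 * width))
    if (p > hi) p <- 2 * hi - p
    pos[i + 1L] <- p
  }
  pos
}

#' Similarity-transform a fragment
#'
#' Applies `scale * R(rotation) %*% x + translation` to every moving
#' position. Static anchors stay fixed by default, so translating the
#' players changes their relations to the anchors (the mechanism by which
#' anchors encode field location); set `transform_statics = TRUE` to move
#' the whole frame instead.
#'
#' @param fragment A `qtc_fragment`.
#' @param translation Length-2 vector (metres).
#' @param rotation Angle in radians, counter-clockwise about the origin.
#' @param scale Positive scale factor.
#' @param transform_statics Transform static anchor points too?
#' @return A transformed `qtc_fragment`.
#' @export
transform_fragment <- function(fragment, translation = c(0, 0),
                               rotation = 0, scale = 1,
                               transform_statics = FALSE) {
  stopifnot(inherits(fragment, "qtc_fragment"))
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  rot <- matrix(c(cos(rotation), sin(rotation),
                  -sin(rotation), cos(rotation)), 2L, 2L)
  apply_tf <- function(xy)
    sweep(scale * (xy %*% t(rot)), 2L, -translation)
  moving <- lapply(fragment$moving, function(tr)
    trajectory(tr$object_id, apply_tf(tr$positions), tr$sample_interval))
  statics <- fragment$statics
  if (transform_statics)
    statics <- lapply(statics, function(s) {
      p <- drop(apply_tf(matrix(s$position, 1L)))
      static_point(s$point_id, p[1L], p[2L])
    })
  out <- new_fragment(moving, statics, fragment$start_index)
  out$downsample_factor <- fragment$downsample_factor
  out
}

#' Re-time a fragment by integer sample repetition or decimation
#'
#' Emulates the same spatial path performed at locally different speeds:
#' within each given segment, a factor f >= 2 (integer) repeats every
#' sample f times (slower), while a factor 1/f keeps every f-th sample
#' (faster). Because samples are repeated or dropped rather than
#' interpolated, the warped fragment revisits exactly the original
#' coordinates, which isolates speed effects from interpolation noise.
#'
#' @param fragment A `qtc_fragment`.
#' @param segment_factors List of `list(range = c(first, last), factor)`
#'   entries with 1-based inclusive sample ranges; samples outside every
#'   range keep factor 1. Ranges must not overlap.
#' @return A re-timed `qtc_fragment` (generally of different length).
#' @export
time_warp <- function(fragment, segment_factors) {
  stopifnot(inherits(fragment, "qtc_fragment"))
  n <- n_samples(fragment)
  reps <- rep(1, n)
  dec <- rep(1L, n)  # decimation period per sample
  for (sf in segment_factors) {
    rg <- sf$range; f <- sf$factor
    if (length(rg) != 2L || rg[1L] < 1L || rg[2L] > n || rg[1L] > rg[2L])
      stop("invalid or empty segment range")
    if (!is.finite(f) || f <= 0) stop("factors must be positive")
    idx <- seq.int(rg[1L], rg[2L])
    if (f >= 1) {
      if (f != round(f)) stop("slow-down factors must be integers")
      reps[idx] <- f
    } else {
      inv <- 1 / f
      if (abs(inv - round(inv)) > 1e-9)
        stop("speed-up factors must be 1/k with integer k")
      dec[idx] <- as.integer(round(inv))
    }
  }
  keep <- logical(n)
  phase <- 0L; period <- 1L
  for (i in seq_len(n)) {
    if (dec[i] != period) { period <- dec[i]; phase <- 0L }
    keep[i] <- phase %% period == 0L
    phase <- phase + 1L
  }
  idx_out <- rep(which(keep), times = reps[keep])
  if (length(idx_out) < 2L)
    stop("warped fragment would have fewer than 2 samples")
  moving <- lapply(fragment$moving, function(tr)
    trajectory(tr$object_id, tr$positions[idx_out, , drop = FALSE],
               tr$sample_interval))
  out <- new_fragment(moving, fragment$statics, fragment$start_index)
  out$downsample_factor <- fragment$downsample_factor
  out
}

# deterministic two-player motif: a parallel sprint that breaks into a
# defensive turn halfway, the shape of a typical attack-then-retreat action
motif_run_and_turn <- function(n, rate = 25, ids = c("P1", "P2")) {
  n1 <- n %/% 2L
  n2 <- n - n1
  mk <- function(start, id) {
    leg1 <- straight_run(start, c(1, 0.25), speed = 7.5, n = n1 + 1L,
                         rate = rate, object_id = id)
    p_turn <- leg1$positions[n1 + 1L, ]
    leg2 <- straight_run(p_turn, c(-1, 0.1), speed = 5.5, n = n2,
                         rate = rate, object_id = id)
    trajectory(id, rbind(leg1$positions[seq_len(n1), , drop = FALSE],
                         leg2$positions), 1 / rate)
  }
  stats::setNames(list(mk(c(20, 25), ids[1L]), mk(c(20, 33), ids[2L])), ids)
}

#' Generate a synthetic tracked scene with planted motif copies
#'
#' Builds a recording of `n_players` random-walk trajectories on a bounded
#' field and plants copies of a deterministic two-player "sprint and turn
#' back" motif at known windows: `n_exact` pure translations (identical
#' relative movements) and `n_transformed` rotated/scaled copies with
#' positional noise of standard deviation `noise_sigma`. The first planted
#' window is the natural reference for retrieval experiments. The side-car
#' annotation gives each planted window and its transform, for scoring
#' retrieval against ground truth.
#'
#' @param seed Integer seed controlling every random choice.
#' @param n_players Number of moving objects (>= 2; the motif occupies the
#'   first two).
#' @param duration Scene length in seconds.
#' @param rate Sampling rate in Hz.
#' @param field `c(length, width)` in metres.
#' @param motif_length Motif window length in samples.
#' @param n_exact,n_transformed Planted copy counts (including the
#'   reference occurrence among the exact copies).
#' @param noise_sigma Positional noise added to transformed copies
#'   (metres).
#' @param walk_sigma Step standard deviation of the background walks
#'   (metres per sample).
#' @param align Planted start indices are rounded to multiples of this
#'   (so a matching stride can hit them exactly).
#' @return List with `recording` (named list of trajectories) and
#'   `annotation` (data.frame `motif_id`, `start_index`, `end_index`,
#'   `transform`).
#' @export
soccer_scene <- function(seed, n_players = 2, duration = 240, rate = 25,
                         field = c(105, 68), motif_length = 500,
                         n_exact = 3, n_transformed = 2,
                         noise_sigma = 0.05, walk_sigma = 0.15,
                         align = 10) {
  n_players <- as.integer(n_players)
  if (n_players < 2L) stop("the scene needs at least 2 players")
  n <- as.integer(round(duration * rate))
  motif_length <- as.integer(motif_length)
  if (motif_length > n) stop("motif longer than the scene duration")
  n_plant <- n_exact + n_transformed
  ids <- paste0("P", seq_len(n_players))
  bounds <- c(0, field[1L], 0, field[2L])

  recording <- stats::setNames(lapply(seq_len(n_players), function(i)
    random_walk(seed * 1000L + i,
                start = c(field[1L] * (0.2 + 0.6 * (i %% 2)),
                          field[2L] * (0.25 + 0.5 * ((i %/% 2) %% 2))),
                n = n, step_sigma = walk_sigma, bounds = bounds,
                object_id = ids[i], rate = rate)), ids)

  annotation <- data.frame(motif_id = character(0),
                           start_index = integer(0),
                           end_index = integer(0),
                           transform = character(0),
                           stringsAsFactors = FALSE)
  if (n_plant > 0L) {
    motif <- motif_run_and_turn(motif_length, rate, ids[1:2])
    # evenly spread, aligned, mutually disjoint planting slots
    gap <- (n - motif_length) / max(1L, n_plant - 1L)
    if (n_plant > 1L && gap < motif_length)
      stop("too many planted copies for the scene duration")
    starts <- as.integer(align * floor((seq_len(n_plant) - 1L) * gap /
                                         align))
    tf_params <- local_rng(seed + 777L, function() list(
      rot = stats::runif(n_plant, -pi, pi),
      scl = stats::runif(n_plant, 0.7, 1.3),
      noise = lapply(seq_len(n_plant), function(p)
        lapply(1:2, function(m)
          matrix(stats::rnorm(2L * motif_length, sd = noise_sigma),
                 ncol = 2L))),
      shift = matrix(stats::runif(2L * n_plant, 0.25, 0.75), ncol = 2L)))
    frag0 <- new_fragment(motif, list(), 0L)
    for (p in seq_len(n_plant)) {
      exact <- p <= n_exact
      if (exact) {
        fr <- frag0
        label <- "translation"
      } else {
        fr <- transform_fragment(frag0, rotation = tf_params$rot[p],
                                 scale = tf_params$scl[p])
        label <- sprintf("rot=%.3f,scale=%.3f,noise=%.3g",
                         tf_params$rot[p], tf_params$scl[p], noise_sigma)
      }
      # one rigid translation per copy, clamped so the whole copy stays on
      # the field (keeps exact copies exactly translation-equivalent)
      all_xy <- do.call(rbind, lapply(fr$moving, function(tr) tr$positions))
      bb_lo <- apply(all_xy, 2L, min); bb_hi <- apply(all_xy, 2L, max)
      centre <- (bb_lo + bb_hi) / 2
      target <- tf_params$shift[p, ] * field
      half <- (bb_hi - bb_lo) / 2
      target <- pmin(pmax(target, half), field - half)
      shift <- target - centre
      for (m in 1:2) {
        xy <- sweep(fr$moving[[m]]$positions, 2L, -shift)
        if (!exact) xy <- xy + tf_params$noise[[p]][[m]]
        xy[, 1L] <- pmin(pmax(xy[, 1L], 0), field[1L])
        xy[, 2L] <- pmin(pmax(xy[, 2L], 0), field[2L])
        tr <- recording[[ids[m]]]
        tr$positions[starts[p] + seq_len(motif_length), ] <- xy
        recording[[ids[m]]] <- tr
      }
      annotation <- rbind(annotation, data.frame(
        motif_id = sprintf("motif_%02d", p),
        start_index = starts[p],
        end_index = starts[p] + motif_length,
        transform = label,
        stringsAsFactors = FALSE))
    }
  }
  list(recording = recording, annotation = annotation)
}
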