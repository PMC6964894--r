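# Trajectory and fragment data model: uniformly sampled 2-D tracks of
# identified moving objects, optional static anchor points, and the
# sliding-window / downsampling machinery that generates candidate fragments.

#' Construct a trajectory
#'
#' A trajectory is the ordered, uniformly sampled sequence of 2-D positions
#' (metres) of one identified moving object, e.g. a tracked player.
#'
#' @param object_id Identifier of the moving object (coerced to character).
#' @param positions Two-column numeric matrix (or data.frame) of x, y
#'   coordinates in metres, one row per sample; all values must be finite.
#' @param sample_interval Seconds between consecutive samples (> 0).
#' @return An object of class `qtc_trajectory`.
#' @examples
#' tr <- trajectory("P1", cbind(x = 0:4, y = 0), sample_interval = 0.04)
#' n_samples(tr)
#' @export
trajectory <- function(object_id, positions, sample_interval) {
  object_id <- as.character(object_id)
  if (length(object_id) != 1L || is.na(object_id) || !nzchar(object_id))
    stop("'object_id' must be a single non-empty identifier")
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("'positions' must have exactly two columns (x, y)")
  storage.mode(positions) <- "double"
  if (nrow(positions) < 1L)
    stop("'positions' must contain at least one sample")
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite")
  sample_interval <- as.numeric(sample_interval)
  if (length(sample_interval) != 1L || !is.finite(sample_interval) ||
      sample_interval <= 0)
    stop("'sample_interval' must be a single positive number of seconds")
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(
    list(object_id = object_id, positions = positions,
         sample_interval = sample_interval),
    class = "qtc_trajectory"
  )
}

#' Number of samples in a trajectory or fragment
#'
#' @param x A `qtc_trajectory` or `qtc_fragment`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "qtc_trajectory")) return(nrow(x$positions))
  if (inherits(x, "qtc_fragment")) return(nrow(x$moving[[1L]]$positions))
  stop("'x' must be a qtc_trajectory or qtc_fragment")
}

#' @export
print.qtc_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d samples @ %g s>\n",
              x$object_id, n_samples(x), x$sample_interval))
  invisible(x)
}

#' Construct a static anchor point
#'
#' Static points (e.g. the four field corners) do not move during a fragment.
#' Adding them to a fragment's roster anchors the otherwise purely relative
#' movement description to fixed locations, making it sensitive to where on
#' the field (and at what scale) a pattern occurs.
#'
#' @param point_id Identifier (coerced to character).
#' @param x,y Coordinates in metres; must be finite.
#' @return An object of class `qtc_static`.
#' @examples
#' static_point("corner_SW", 0, 0)
#' @export
static_point <- function(point_id, x, y) {
  point_id <- as.character(point_id)
  if (length(point_id) != 1L || is.na(point_id) || !nzchar(point_id))
    stop("'point_id' must be a single non-empty identifier")
  pos <- c(as.numeric(x), as.numeric(y))
  if (length(pos) != 2L || !all(is.finite(pos)))
    stop("static point coordinates must be two finite numbers")
  structure(list(point_id = point_id, position = c(x = pos[1L], y = pos[2L])),
            class = "qtc_static")
}

#' @export
print.qtc_static <- function(x, ...) {
  cat(sprintf("<static point '%s' at (%g, %g)>\n",
              x$point_id, x$position[1L], x$position[2L]))
  invisible(x)
}

#' Four field-corner static points
#'
#' Convenience roster of anchors at the corners of a pitch of given size,
#' the default being the common 105 m x 68 m soccer field.
#'
#' @param length,width Field dimensions in metres.
#' @return List of four `qtc_static` points.
#' @export
field_corner_statics <- function(length = 105, width = 68) {
  if (!is.finite(length) || !is.finite(width) || length <= 0 || width <= 0)
    stop("field dimensions must be positive")
  list(static_point("corner_SW", 0, 0),
       static_point("corner_SE", length, 0),
       static_point("corner_NW", 0, width),
       static_point("corner_NE", length, width))
}

validate_fragment <- function(frag) {
  if (length(frag$moving) < 1L)
    stop("a fragment needs at least one moving trajectory")
  ns <- vapply(frag$moving, n_samples, integer(1L))
  if (length(unique(ns)) != 1L)
    stop("all moving trajectories must have the same number of samples")
  si <- vapply(frag$moving, function(tr) tr$sample_interval, numeric(1L))
  if (diff(range(si)) > 1e-12)
    stop("all moving trajectories must share one sample interval")
  ids <- c(vapply(frag$moving, function(tr) tr$object_id, character(1L)),
           vapply(frag$statics, function(s) s$point_id, character(1L)))
  if (anyDuplicated(ids))
    stop("object ids must be unique across moving and static members")
  invisible(frag)
}

new_fragment <- function(moving, statics, start_index) {
  names(moving) <- vapply(moving, function(tr) tr$object_id, character(1L))
  names(statics) <- vapply(statics, function(s) s$point_id, character(1L))
  frag <- structure(
    list(start_index = as.integer(start_index), moving = moving,
         statics = statics,
         sample_interval = moving[[1L]]$sample_interval),
    class = "qtc_fragment"
  )
  validate_fragment(frag)
  frag
}

#' Extract a fragment from a recording
#'
#' A fragment is the movement of a chosen set of objects during one
#' well-defined time window, plus any static anchor points; it is the unit
#' of comparison throughout the package. Sample indices are 0-based and the
#' window is half-open: samples `start, ..., start + length - 1` are taken.
#'
#' @param recording Named list of [trajectory()] objects (one full-match
#'   track per object), as returned by [read_trajectories()].
#' @param object_ids Character vector of ids to include, in roster order.
#' @param start 0-based sample index of the window start.
#' @param length Number of samples in the window (>= 1; >= 2 before
#'   encoding).
#' @param statics List of [static_point()] anchors attached to the fragment.
#' @return An object of class `qtc_fragment`.
#' @examples
#' rec <- list(P1 = trajectory("P1", cbind(0:99, 0), 0.04))
#' fr <- make_fragment(rec, "P1", start = 10, length = 5)
#' n_samples(fr)
#' @export
make_fragment <- function(recording, object_ids, start, length,
                          statics = list()) {
  object_ids <- as.character(object_ids)
  missing_ids <- setdiff(object_ids, names(recording))
  if (length(missing_ids) > 0L)
    stop("unknown object id(s): ", paste(missing_ids, collapse = ", "))
  start <- as.integer(start); length <- as.integer(length)
  if (is.na(start) || start < 0L) stop("'start' must be >= 0")
  if (is.na(length) || length < 1L) stop("'length' must be >= 1")
  ns <- vapply(recording[object_ids], n_samples, integer(1L))
  if (any(start + length > ns))
    stop(sprintf(
      "window [%d, %d) out of range: recording has %d samples",
      start, start + length, min(ns)))
  idx <- seq.int(start + 1L, start + length)
  moving <- lapply(recording[object_ids], function(tr) {
    trajectory(tr$object_id, tr$positions[idx, , drop = FALSE],
               tr$sample_interval)
  })
  new_fragment(moving, statics, start)
}

#' @export
print.qtc_fragment <- function(x, ...) {
  cat(sprintf(
    "<fragment: %d moving, %d static, %d samples @ %g s, start %d>\n",
    length(x$moving), length(x$statics), n_samples(x), x$sample_interval,
    x$start_index))
  invisible(x)
}

#' Reduce the temporal resolution of a fragment
#'
#' Keeps every `factor`-th sample starting from the first (relative indices
#' 0, factor, 2*factor, ...), dropping any trailing remainder, and multiplies
#' the sample interval accordingly. Coarsening the resolution both speeds up
#' the distance computations and damps tracking noise.
#'
#' @param fragment A `qtc_fragment`.
#' @param factor Positive integer downsampling factor; 1 is the identity.
#' @return A `qtc_fragment` at the reduced resolution. Its `start_index`
#'   (original-resolution samples) is unchanged; the factor is recorded in
#'   the `downsample_factor` element.
#' @examples
#' rec <- list(P1 = trajectory("P1", cbind(0:499, 0), 0.04))
#' fr <- make_fragment(rec, "P1", 0, 500)
#' n_samples(downsample_fragment(fr, 10))  # 50
#' @export
downsample_fragment <- function(fragment, factor) {
  stopifnot(inherits(fragment, "qtc_fragment"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be a positive integer")
  if (factor == 1L) {
    out <- fragment
  } else {
    keep <- seq.int(1L, n_samples(fragment), by = factor)
    moving <- lapply(fragment$moving, function(tr) {
      trajectory(tr$object_id, tr$positions[keep, , drop = FALSE],
                 tr$sample_interval * factor)
    })
    out <- new_fragment(moving, fragment$statics, fragment$start_index)
  }
  prior <- fragment$downsample_factor
  out$downsample_factor <- if (is.null(prior)) factor else prior * factor
  out
}

#' Number of fully contained sliding windows
#'
#' Windows of `window` samples start at indices 0, stride, 2*stride, ... and
#' must fit entirely within the recording; there is no partial trailing
#' window.
#'
#' @param n_samples Recording length in samples.
#' @param window Window length in samples (<= `n_samples`).
#' @param stride Step between window starts in samples (>= 1).
#' @return `floor((n_samples - window) / stride) + 1`.
#' @examples
#' count_windows(144086, 500, 10)  # 14359
#' @export
count_windows <- function(n_samples, window, stride) {
  n_samples <- as.double(n_samples); window <- as.double(window)
  stride <- as.double(stride)
  if (any(is.na(c(n_samples, window, stride))))
    stop("arguments must be numeric")
  if (stride < 1) stop("'stride' must be >= 1")
  if (window < 1) stop("'window' must be >= 1")
  if (window > n_samples)
    stop("'window' must not exceed 'n_samples'")
  as.integer(floor((n_samples - window) / stride) + 1)
}

#' Generate all sliding-window fragments of a recording
#'
#' @inheritParams make_fragment
#' @inheritParams count_windows
#' @return List of `qtc_fragment` in start-index order; its length equals
#'   [count_windows()].
#' @examples
#' rec <- list(P1 = trajectory("P1", cbind(0:24, 0), 0.04))
#' frs <- slide_windows(rec, "P1", window = 10, stride = 5)
#' vapply(frs, function(f) f$start_index, integer(1))  # 0 5 10 15
#' @export
slide_windows <- function(recording, object_ids, window, stride,
                          statics = list()) {
  ns <- min(vapply(recording[as.character(object_ids)], n_samples,
                   integer(1L)))
  k <- count_windows(ns, window, stride)
  starts <- seq.int(0L, by = as.integer(stride), length.out = k)
  lapply(starts, function(s)
    make_fragment(recording, object_ids, s, window, statics))
}

# roster ids of a fragment, moving first then static
fragment_roster <- function(fragment) {
  list(moving = names(fragment$moving), static = names(fragment$statics))
}
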