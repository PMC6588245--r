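#' Construct a multi-marker trajectory series
#'
#' The central container of the package: an array of 3-D marker positions
#' over time, together with the sampling rate and the lab's axis convention.
#' All downstream steps (event detection, segmentation, concatenation,
#' nonlinear analysis) operate on this object.
#'
#' @param positions numeric array of dimension `frames x markers x 3`,
#'   positions in metres. A `frames x 3` matrix is accepted for a single
#'   marker.
#' @param rate sampling frequency in Hz (> 0).
#' @param marker_names character vector of unique marker labels, one per
#'   marker, in column order.
#' @param vertical_axis which of the three coordinates is vertical
#'   (1, 2 or 3). Defaults to 3, the common Z-up optical-mocap convention.
#' @param source free-text provenance string.
#'
#' @return An object of class `trajectory_series` with fields `positions`,
#'   `rate`, `marker_names`, `vertical_axis`, `source`.
#' @export
trajectory_series <- function(positions, rate, marker_names = NULL,
                              vertical_axis = 3L, source = "") {
  if (is.matrix(positions)) {
    positions <- array(positions, dim = c(nrow(positions), 1L, ncol(positions)))
  }
  if (!is.array(positions) || length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("`positions` must be a frames x markers x 3 array", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  nm <- dim(positions)[2]
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(nm))
  marker_names <- as.character(marker_names)
  if (length(marker_names) != nm)
    stop("length(marker_names) must equal the number of markers", call. = FALSE)
  if (anyDuplicated(marker_names))
    stop("marker names must be unique", call. = FALSE)
  vertical_axis <- as.integer(vertical_axis)
  if (!vertical_axis %in% 1:3)
    stop("`vertical_axis` must be 1, 2 or 3", call. = FALSE)
  if (dim(positions)[1] < 1L || nm < 1L)
    stop("need at least 1 frame and 1 marker", call. = FALSE)
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions contain missing or non-finite values; apply a gap policy at load time",
         call. = FALSE)
  structure(
    list(positions = positions, rate = rate, marker_names = marker_names,
         vertical_axis = vertical_axis, source = as.character(source)[1]),
    class = "trajectory_series"
  )
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("<trajectory_series> %d frames x %d markers @ %g Hz (%.2f s)\n",
              n_frames(x), n_markers(x), x$rate, n_frames(x) / x$rate))
  cat(sprintf("  markers: %s\n", paste(utils::head(x$marker_names, 8), collapse = ", ")))
  cat(sprintf("  vertical axis: %d%s\n", x$vertical_axis,
              if (nzchar(x$source)) paste0("  source: ", x$source) else ""))
  invisible(x)
}

#' Number of frames / markers in a trajectory series
#' @param series a `trajectory_series`.
#' @return integer count.
#' @export
n_frames <- function(series) dim(series$positions)[1]

#' @rdname n_frames
#' @export
n_markers <- function(series) dim(series$positions)[2]

#' Extract a frame range as a new trajectory series
#'
#' Half-open frame interval `[from, to)` in 0-based frame indices, the
#' indexing convention used throughout the package.
#'
#' @param series a `trajectory_series`.
#' @param from,to 0-based half-open frame range.
#' @return a `trajectory_series` with `to - from` frames.
#' @export
slice_frames <- function(series, from, to) {
  nf <- n_frames(series)
  if (from < 0 || to > nf || to <= from)
    stop(sprintf("invalid frame range [%d, %d) for %d frames", from, to, nf),
         call. = FALSE)
  out <- series
  out$positions <- series$positions[(from + 1L):to, , , drop = FALSE]
  out
}

#' Extract one coordinate of one marker as a numeric vector
#'
#' @param series a `trajectory_series`.
#' @param marker marker name.
#' @param axis coordinate index 1..3; defaults to the series' vertical axis.
#' @return numeric vector of length `n_frames(series)`.
#' @export
marker_coordinate <- function(series, marker, axis = series$vertical_axis) {
  m <- match(marker, series$marker_names)
  if (is.na(m)) stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  series$positions[, m, axis]
}

#' Construct a marker weight map for pose matching
#'
#' Weights in `[0, 1]` control each marker's contribution to the pose
#' distance used during concatenation. Practitioners put high weights on
#' bony landmarks and on markers near the analysed heel, and low weights
#' on soft-tissue markers.
#'
#' @param weights named numeric vector, marker name -> weight in `[0, 1]`.
#' @return object of class `weight_map`.
#' @export
weight_map <- function(weights) {
  w <- unlist(weights)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("weights must be a named vector (marker name -> weight)", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("all weights must lie in [0, 1]", call. = FALSE)
  if (!any(w > 0))
    stop("at least one weight must be strictly positive", call. = FALSE)
  structure(list(weights = w), class = "weight_map")
}

#' Resolve a weight map against a trajectory series
#'
#' Returns the per-marker weight vector in the series' marker order.
#' Passing `NULL` yields uniform unit weights.
#'
#' @param weights a `weight_map`, a named numeric vector, or `NULL`.
#' @param series a `trajectory_series`.
#' @param default weight for markers absent from the map.
#' @return numeric vector of length `n_markers(series)`.
#' @export
resolve_weights <- function(weights, series, default = 1.0) {
  if (is.null(weights)) return(rep(default, n_markers(series)))
  if (!inherits(weights, "weight_map")) weights <- weight_map(weights)
  w <- weights$weights
  unknown <- setdiff(names(w), series$marker_names)
  if (length(unknown))
    stop(sprintf("weight map names unknown to the series: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- rep(default, n_markers(series))
  idx <- match(names(w), series$marker_names)
  out[idx] <- unname(w)
  if (!any(out > 0)) stop("resolved weights are all zero", call. = FALSE)
  out
}
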