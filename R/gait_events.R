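#' Detect right-foot heel strikes from marker vertical velocity
#'
#' Concretisation of the stable-foot-velocity family of gait-event
#' detectors: the marker's vertical velocity is computed by central
#' differences (on a lightly smoothed copy used for detection only — the
#' data handed on to concatenation and nonlinear analysis remain
#' unfiltered). A heel strike is the frame where vertical velocity crosses
#' from below `-eps` back to `>= -eps` at the end of the swing-phase
#' descent, with `eps` = 2% of the peak absolute vertical velocity.
#' Candidates closer together than `min_cycle_s` are merged, keeping the
#' one with the lower vertical position (ties to the earlier frame).
#'
#' @param series a [trajectory_series()].
#' @param marker event marker name (default `"RHEE"`).
#' @param min_cycle_s shortest plausible gait cycle (s).
#' @param smooth_window moving-average width (frames) for the detection
#'   velocity; 1 disables smoothing.
#' @return object of class `gait_events`: list with `hs_frames` (0-based,
#'   strictly increasing), `marker`, `method`.
#' @export
detect_heel_strikes <- function(series, marker = "RHEE", min_cycle_s = 0.4,
                                smooth_window = 5L) {
  z <- marker_coordinate(series, marker)
  nf <- length(z)
  if (nf / series$rate <= 2 * min_cycle_s)
    stop("series shorter than two minimum gait cycles", call. = FALSE)
  if (diff(range(z)) == 0)
    stop("constant vertical trajectory: no gait events detectable", call. = FALSE)

  zs <- moving_average(z, as.integer(smooth_window))
  v <- central_diff(zs) * series$rate
  eps <- 0.02 * max(abs(v))
  if (eps == 0) stop("zero vertical velocity everywhere", call. = FALSE)

  # A candidate heel strike is the first upward crossing of -eps after a
  # deep swing descent (velocity below 20% of the peak downward velocity);
  # arming on the descent peak rejects the noise-level crossings that occur
  # while the foot rests near the floor.
  arm_level <- 0.2 * max(-v)
  armed <- FALSE
  cand <- integer(0)
  for (k in seq_len(nf)) {
    if (v[k] < -arm_level) armed <- TRUE
    else if (armed && v[k] >= -eps) {
      cand <- c(cand, k)
      armed <- FALSE
    }
  }
  if (length(cand) < 2L)
    stop("fewer than 2 heel-strike candidates detected", call. = FALSE)

  # The symmetric detection kernel (moving average + central difference)
  # delays the crossing at a descent-to-plateau kink by about its
  # half-width; re-centre the events by that known group delay.
  delay <- as.integer(smooth_window) %/% 2L + 1L
  cand <- pmax(cand - delay, 1L)

  min_gap <- min_cycle_s * series$rate
  keep <- integer(0)
  cur <- cand[1]
  for (k in cand[-1]) {
    if (k - cur >= min_gap) {
      keep <- c(keep, cur)
      cur <- k
    } else if (z[k] < z[cur]) { # merge: keep the lower heel position
      cur <- k
    }
  }
  keep <- c(keep, cur)
  if (length(keep) < 2L)
    stop("fewer than 2 heel strikes after merging", call. = FALSE)

  structure(list(hs_frames = keep - 1L,  # to 0-based
                 marker = marker, method = "vertical_velocity_crossing"),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel strikes of %s (%s)\n",
              length(x$hs_frames), x$marker, x$method))
  invisible(x)
}

#' Differentiate a trajectory series
#'
#' Central-difference velocity in m/s (one-sided differences at the first
#' and last frame); the frame count is preserved so events indexed on the
#' position series remain valid on the velocity series.
#'
#' @param series a [trajectory_series()] with at least 3 frames.
#' @return a `trajectory_series` of velocities.
#' @export
to_velocity <- function(series) {
  nf <- n_frames(series)
  if (nf < 3L) stop("need at least 3 frames to differentiate", call. = FALSE)
  out <- series
  for (k in seq_len(n_markers(series))) {
    for (a in 1:3) {
      out$positions[, k, a] <- central_diff(series$positions[, k, a]) * series$rate
    }
  }
  out$source <- paste0(series$source, " [velocity]")
  out
}

# derivative in units of 1/frame; one-sided at the ends
central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d
}

#' Export gait events as JSON
#'
#' Writes frame indices (0-based) and event times in seconds.
#'
#' @param events a `gait_events` object.
#' @param rate sampling rate used to convert frames to seconds.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
save_events <- function(events, rate, path) {
  jsonlite::write_json(
    list(marker = events$marker, method = events$method,
         hs_frames = events$hs_frames, hs_seconds = events$hs_frames / rate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
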