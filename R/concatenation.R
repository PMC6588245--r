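#' Cubic transition interpolation coefficient
#'
#' The blend weight applied to the outgoing segment at frame `j` of an
#' `n`-frame transition window:
#' `alpha(j) = 2((j+1)/n)^3 - 3((j+1)/n)^2 + 1`.
#' It decreases strictly from just below 1 at `j = 0` to exactly 0 at
#' `j = n - 1`, handing the pose over smoothly to the incoming segment.
#'
#' @param j 0-based frame index within the window, `0 <= j <= n-1`.
#'   Vectorised.
#' @param n window length in frames (>= 2).
#' @return numeric blend coefficient(s) in `[0, 1)`.
#' @export
alpha_coefficient <- function(j, n) {
  if (n < 2L) stop("window length n must be >= 2", call. = FALSE)
  if (any(j < 0) || any(j > n - 1L))
    stop("j must lie in [0, n-1]", call. = FALSE)
  u <- (j + 1) / n
  2 * u^3 - 3 * u^2 + 1
}

#' Rigid alignment in the horizontal plane
#'
#' The alignment group of the pose distance: a rotation `theta` about the
#' vertical axis followed by a horizontal translation `t`. Vertical
#' coordinates are never modified.
#'
#' @param theta rotation angle (rad).
#' @param t length-2 horizontal translation (m).
#' @return object of class `rigid_transform_2d`.
#' @export
rigid_transform_2d <- function(theta = 0, t = c(0, 0)) {
  stopifnot(length(theta) == 1L, length(t) == 2L)
  structure(list(theta = theta, t = as.numeric(t)), class = "rigid_transform_2d")
}

#' @rdname rigid_transform_2d
#' @param transform a `rigid_transform_2d`.
#' @export
invert_transform <- function(transform) {
  ct <- cos(-transform$theta); st <- sin(-transform$theta)
  rigid_transform_2d(-transform$theta,
                     c(-(ct * transform$t[1] - st * transform$t[2]),
                       -(st * transform$t[1] + ct * transform$t[2])))
}

#' Apply a horizontal rigid transform to a position array
#'
#' @param positions `frames x markers x 3` array (or any array whose last
#'   dimension indexes the 3 coordinates).
#' @param transform a [rigid_transform_2d()].
#' @param vertical_axis index of the vertical coordinate (left untouched).
#' @return transformed array of the same shape.
#' @export
apply_transform <- function(positions, transform, vertical_axis = 3L) {
  h <- setdiff(1:3, vertical_axis)
  ct <- cos(transform$theta); st <- sin(transform$theta)
  x <- positions[, , h[1], drop = FALSE]
  y <- positions[, , h[2], drop = FALSE]
  out <- positions
  out[, , h[1]] <- ct * x - st * y + transform$t[1]
  out[, , h[2]] <- st * x + ct * y + transform$t[2]
  out
}

# Closed-form weighted alignment of two point clouds under rotation about
# the vertical axis + horizontal translation. ax/ay/av etc. are flattened
# point coordinate vectors (horizontal 1, horizontal 2, vertical) with one
# weight per point. Minimises sum w ||a - (R b + t)||^2; the vertical
# residual (a_v - b_v) enters the distance but is untouched by the motion.
fit_transform_core <- function(ax, ay, av, bx, by, bv, w) {
  sw <- sum(w)
  amx <- sum(w * ax) / sw; amy <- sum(w * ay) / sw
  bmx <- sum(w * bx) / sw; bmy <- sum(w * by) / sw
  axc <- ax - amx; ayc <- ay - amy
  bxc <- bx - bmx; byc <- by - bmy
  C <- sum(w * (axc * bxc + ayc * byc))
  S <- sum(w * (ayc * bxc - axc * byc))
  theta <- if (C == 0 && S == 0) 0 else atan2(S, C)
  ct <- cos(theta); st <- sin(theta)
  horiz <- sum(w * (axc^2 + ayc^2 + bxc^2 + byc^2)) - 2 * sqrt(C^2 + S^2)
  dist <- max(0, horiz) + sum(w * (av - bv)^2)
  list(theta = theta,
       t = c(amx - (ct * bmx - st * bmy), amy - (st * bmx + ct * bmy)),
       distance = dist)
}

#' Optimal rigid alignment between two pose windows
#'
#' Finds the rotation about the vertical axis and horizontal translation
#' minimising the weighted squared pose distance
#' `sum_m sum_j w_m || p_mj - T p'_mj ||^2` jointly over all frames and
#' markers of the window pair (closed-form weighted 2-D point-cloud
#' alignment). Vertical components contribute to the distance but are not
#' modified by the transform.
#'
#' @param window_a,window_b `n x M x 3` position arrays with matching
#'   dimensions and marker order; `window_a` is the reference.
#' @param weights per-marker weight vector of length `M` (see
#'   [resolve_weights()]).
#' @param vertical_axis vertical coordinate index.
#' @param per_frame if `TRUE`, an independent transform is fitted to every
#'   frame of the window and only the summed distance is meaningful (the
#'   returned transform is the whole-window fit); the default fits one
#'   rigid motion to the whole window, which is also what gets applied
#'   when blending.
#' @return list with `transform` (a [rigid_transform_2d()]) and `distance`
#'   (weighted squared distance at the optimum, m^2).
#' @export
optimal_transform <- function(window_a, window_b, weights,
                              vertical_axis = 3L, per_frame = FALSE) {
  da <- dim(window_a); db <- dim(window_b)
  if (!identical(da, db))
    stop("window dimensions differ", call. = FALSE)
  n <- da[1]; M <- da[2]
  if (length(weights) != M) stop("need one weight per marker", call. = FALSE)
  if (!any(weights > 0)) stop("all weights are zero", call. = FALSE)
  h <- setdiff(1:3, vertical_axis)
  wvec <- rep(weights, each = n)
  ax <- as.vector(window_a[, , h[1]]); ay <- as.vector(window_a[, , h[2]])
  av <- as.vector(window_a[, , vertical_axis])
  bx <- as.vector(window_b[, , h[1]]); by <- as.vector(window_b[, , h[2]])
  bv <- as.vector(window_b[, , vertical_axis])
  fit <- fit_transform_core(ax, ay, av, bx, by, bv, wvec)
  if (per_frame) {
    dist <- 0
    for (j in seq_len(n)) {
      idx <- j + n * (seq_len(M) - 1L)
      dist <- dist + fit_transform_core(ax[idx], ay[idx], av[idx],
                                        bx[idx], by[idx], bv[idx],
                                        weights)$distance
    }
    fit$distance <- dist
  }
  list(transform = rigid_transform_2d(fit$theta, fit$t),
       distance = fit$distance)
}

#' Pose-distance profile between the tail of one segment and all windows
#' of the next
#'
#' The matching window `C1n` is the last `n` frames of `seg_a`; for every
#' candidate offset `v` in `[0, N - n]` (0-based, inclusive; `N` frames in
#' `seg_b`) the weighted squared pose distance after optimal rigid
#' alignment of `seg_b[v : v+n)` onto `C1n` is recorded.
#'
#' @param seg_a,seg_b consecutive [trajectory_series()] segments with
#'   identical marker sets.
#' @param n transition window length (frames); the package default is
#'   `round(rate / 3)`, about a third of a second.
#' @param weights per-marker weights (length `n_markers`) or `NULL` for
#'   uniform.
#' @param per_frame compute the distance with an independent per-frame
#'   alignment (diagnostic alternative; the applied motion is always the
#'   whole-window fit).
#' @return object of class `transition_candidates`: list with `profile`
#'   (distances, index `v + 1`), `transforms` (whole-window fit per `v`),
#'   `n`, `mode`.
#' @export
distance_profile <- function(seg_a, seg_b, n = round(seg_a$rate / 3),
                             weights = NULL, per_frame = FALSE) {
  if (!identical(seg_a$marker_names, seg_b$marker_names))
    stop("segments have different marker sets", call. = FALSE)
  n <- as.integer(n)
  La <- n_frames(seg_a); N <- n_frames(seg_b)
  if (La < n || N < n)
    stop(sprintf("segment shorter than the %d-frame window", n), call. = FALSE)
  va <- seg_a$vertical_axis
  h <- setdiff(1:3, va)
  w <- if (is.null(weights)) rep(1, n_markers(seg_a)) else weights
  if (!any(w > 0)) stop("all weights are zero", call. = FALSE)
  wvec <- rep(w, each = n)

  wa <- seg_a$positions[(La - n + 1L):La, , , drop = FALSE]
  ax <- as.vector(wa[, , h[1]]); ay <- as.vector(wa[, , h[2]])
  av <- as.vector(wa[, , va])
  BX <- seg_b$positions[, , h[1], drop = TRUE]
  BY <- seg_b$positions[, , h[2], drop = TRUE]
  BV <- seg_b$positions[, , va, drop = TRUE]
  if (is.null(dim(BX))) { BX <- cbind(BX); BY <- cbind(BY); BV <- cbind(BV) }

  n_cand <- N - n + 1L
  profile <- numeric(n_cand)
  transforms <- vector("list", n_cand)
  M <- n_markers(seg_a)
  for (vi in seq_len(n_cand)) {
    rows <- vi:(vi + n - 1L)
    bx <- as.vector(BX[rows, ]); by <- as.vector(BY[rows, ])
    bv <- as.vector(BV[rows, ])
    fit <- fit_transform_core(ax, ay, av, bx, by, bv, wvec)
    if (per_frame) {
      d <- 0
      for (j in seq_len(n)) {
        idx <- j + n * (seq_len(M) - 1L)
        d <- d + fit_transform_core(ax[idx], ay[idx], av[idx],
                                    bx[idx], by[idx], bv[idx], w)$distance
      }
      fit$distance <- d
    }
    profile[vi] <- fit$distance
    transforms[[vi]] <- rigid_transform_2d(fit$theta, fit$t)
  }
  structure(list(profile = profile, transforms = transforms, n = n,
                 mode = if (per_frame) "per_frame" else "window"),
            class = "transition_candidates")
}

#' Select the transition offset from a pose-distance profile
#'
#' Chooses the first local minimum of `D(v)`: the smallest `v` with
#' `D(v-1) > D(v) <= D(v+1)`. The left boundary `v = 0` qualifies only
#' when `D(0) < D(1)` *and* `D(0)` is the global minimum: with segments
#' cut at gait events the best alignments sit near `v = cycle - n`, which
#' leaves `v = 0` on a slope descending towards the unreachable negative
#' offsets — a boundary dip that is not a pose match unless it actually
#' attains the minimum (as in the exact-overlap case, where `D(0) = 0`).
#' A profile with no qualifying point (e.g. monotonically decreasing)
#' falls back to the global minimum and the choice is flagged.
#'
#' `depth_frac < 1` additionally requires a local minimum to be deep:
#' `D(v) <= Dmin + depth_frac * (Dmax - Dmin)`. Gait pose profiles are
#' bimodal — genuine matches sit orders of magnitude below the shallow
#' structural dips produced by components with sub-stride periodicity
#' (e.g. the twice-per-stride trunk bob), and a shallow dip is not a pose
#' match. [concatenate_all()] uses `depth_frac = 0.25` for this reason;
#' the default 1 applies the plain first-local-minimum rule.
#'
#' @param candidates a `transition_candidates` from [distance_profile()].
#' @param depth_frac qualifying depth as a fraction of the profile range.
#' @return object of class `transition_choice`: list with `v` (0-based
#'   offset), `n`, `distance`, `transform`, `profile`, `fallback`, `mode`.
#' @export
select_transition <- function(candidates, depth_frac = 1) {
  profile <- candidates$profile
  if (!length(profile)) stop("empty distance profile", call. = FALSE)
  np <- length(profile)
  deep_enough <- profile <= min(profile) +
    depth_frac * (max(profile) - min(profile))
  i <- NA_integer_
  if (np == 1L || (np >= 2L && profile[1] < profile[2] &&
                   profile[1] <= min(profile))) {
    i <- 1L
  } else if (np >= 3L) {
    for (k in 2:(np - 1L)) {
      if (profile[k - 1L] > profile[k] && profile[k] <= profile[k + 1L] &&
          deep_enough[k]) {
        i <- k
        break
      }
    }
  }
  fallback <- is.na(i)
  if (fallback) i <- which.min(profile)
  structure(list(v = i - 1L, n = candidates$n, distance = profile[i],
                 transform = candidates$transforms[[i]], profile = profile,
                 fallback = fallback, mode = candidates$mode),
            class = "transition_choice")
}

#' Blend two segments over the chosen transition window
#'
#' The selected rigid transform is applied to all of `seg_b` from frame
#' `v` onward; the last `n` frames of `seg_a` are then cross-faded into
#' the aligned window `seg_b[v : v+n)` using [alpha_coefficient()]
#' (`alpha` weighting `seg_a`, reaching 0 at the final window frame), and
#' the transformed remainder of `seg_b` follows. The output has exactly
#' `L_a + N - v - n` frames.
#'
#' @param seg_a,seg_b the two segments.
#' @param choice a `transition_choice` produced from this pair.
#' @return a [trajectory_series()] of the joined pair.
#' @export
blend_pair <- function(seg_a, seg_b, choice) {
  if (!identical(seg_a$marker_names, seg_b$marker_names))
    stop("segments have different marker sets", call. = FALSE)
  n <- choice$n; v <- choice$v
  La <- n_frames(seg_a); N <- n_frames(seg_b)
  if (v < 0 || v + n > N) stop("choice offset out of range for seg_b", call. = FALSE)
  va <- seg_a$vertical_axis

  b_tail <- seg_b$positions[(v + 1L):N, , , drop = FALSE]
  b_tail <- apply_transform(b_tail, choice$transform, va)

  alpha <- alpha_coefficient(0:(n - 1L), n)
  a_win <- seg_a$positions[(La - n + 1L):La, , , drop = FALSE]
  b_win <- b_tail[1:n, , , drop = FALSE]
  blend <- a_win * alpha + b_win * (1 - alpha)  # recycles along frames

  out <- array(0, dim = c(La + N - v - n, n_markers(seg_a), 3L))
  if (La > n) out[1:(La - n), , ] <- seg_a$positions[1:(La - n), , ]
  out[(La - n + 1L):La, , ] <- blend
  if (v + n < N) out[(La + 1L):(La + N - v - n), , ] <- b_tail[(n + 1L):(N - v), , ]

  trajectory_series(out, rate = seg_a$rate, marker_names = seg_a$marker_names,
                    vertical_axis = va,
                    source = paste0(seg_a$source, " + ", seg_b$source))
}

#' Concatenate all segments of a segment set into one continuous series
#'
#' Left-fold of [distance_profile()], [select_transition()] and
#' [blend_pair()] over the segment list: the joined result of segments 1
#' and 2 becomes the outgoing series for segment 3, and so on. A set with
#' `k` segments yields `k - 1` transitions.
#'
#' @param segments a `segment_set` from [cut_series()], or a plain list of
#'   [trajectory_series()].
#' @param n transition window length (frames); default `round(rate / 3)`.
#' @param weights per-marker weight vector or `NULL` for uniform.
#' @param per_frame use the per-frame alignment mode for the distance
#'   profile (the applied motion is still one rigid transform per joint).
#' @param depth_frac depth qualification passed to [select_transition()];
#'   the default 0.25 rejects shallow structural dips (sub-stride
#'   pseudo-matches) while keeping every genuine pose match.
#' @return list with `series` (the concatenated [trajectory_series()]) and
#'   `transitions` (list of `transition_choice`, one per joint).
#' @export
concatenate_all <- function(segments, n = NULL, weights = NULL,
                            per_frame = FALSE, depth_frac = 0.25) {
  segs <- if (inherits(segments, "segment_set")) segments$segments else segments
  if (!length(segs)) stop("no segments to concatenate", call. = FALSE)
  if (is.null(n)) n <- as.integer(round(segs[[1]]$rate / 3))
  out <- segs[[1]]
  transitions <- list()
  if (length(segs) > 1L) {
    for (i in 2:length(segs)) {
      res <- tryCatch({
        cand <- distance_profile(out, segs[[i]], n = n, weights = weights,
                                 per_frame = per_frame)
        choice <- select_transition(cand, depth_frac = depth_frac)
        # 0-based output frame where this blend window starts; later joints
        # never move it, so it locates the joint in the final series
        choice$joint_frame <- n_frames(out) - as.integer(n)
        list(series = blend_pair(out, segs[[i]], choice), choice = choice)
      }, error = function(e)
        stop(sprintf("joint %d: %s", i - 1L, conditionMessage(e)), call. = FALSE))
      out <- res$series
      transitions[[i - 1L]] <- res$choice
    }
  }
  list(series = out, transitions = transitions)
}
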