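#' Keep/exclude cycle cutting schemes
#'
#' A cut scheme walks the detected gait cycles from the first heel strike:
#' keep `c_in` consecutive cycles as one segment, discard the next `c_ex`
#' cycles, and repeat until the end of the recording; a trailing group with
#' fewer than `c_in` complete cycles is dropped. This simulates interrupted
#' overground recordings from a continuous one.
#'
#' Presets mirror the three standard conditions: `cut1001` = (10, 1),
#' `cut0803` = (8, 3), `cut0605` = (6, 5).
#'
#' @param c_in cycles kept per segment (>= 1).
#' @param c_ex cycles excluded between segments (>= 0).
#' @param name label for reports.
#' @return object of class `cut_scheme`.
#' @export
cut_scheme <- function(c_in, c_ex, name = sprintf("cut%02d%02d", c_in, c_ex)) {
  c_in <- as.integer(c_in); c_ex <- as.integer(c_ex)
  if (c_in < 1L) stop("c_in must be >= 1", call. = FALSE)
  if (c_ex < 0L) stop("c_ex must be >= 0", call. = FALSE)
  structure(list(c_in = c_in, c_ex = c_ex, name = name), class = "cut_scheme")
}

#' @rdname cut_scheme
#' @export
cut_presets <- function() {
  list(cut1001 = cut_scheme(10L, 1L, "cut1001"),
       cut0803 = cut_scheme(8L, 3L, "cut0803"),
       cut0605 = cut_scheme(6L, 5L, "cut0605"))
}

#' Cut a continuous series into short segments by gait cycles
#'
#' Cycles are the half-open frame intervals between consecutive heel
#' strikes; frames before the first and after the last heel strike are
#' discarded. Each segment spans exactly `c_in` consecutive cycles,
#' i.e. the frame range `[HS_first, HS_after_last)`.
#'
#' @param series a [trajectory_series()].
#' @param events a `gait_events` object for `series`.
#' @param scheme a [cut_scheme()].
#' @return object of class `segment_set`: list with `segments` (list of
#'   `trajectory_series`), `frame_ranges` (2-column matrix of 0-based
#'   half-open source ranges), `scheme`, and cycle bookkeeping
#'   (`n_cycles_total`, `n_kept`, `n_skipped`, `n_dropped`).
#' @export
cut_series <- function(series, events, scheme) {
  hs <- events$hs_frames
  n_cycles <- length(hs) - 1L
  if (n_cycles < scheme$c_in)
    stop("not enough gait cycles for a single segment", call. = FALSE)

  ranges <- NULL
  kept <- 0L; skipped <- 0L
  c <- 0L  # 0-based index of next unconsumed cycle
  repeat {
    if (c + scheme$c_in > n_cycles) break
    ranges <- rbind(ranges, c(hs[c + 1L], hs[c + scheme$c_in + 1L]))
    kept <- kept + scheme$c_in
    c <- c + scheme$c_in
    # skip the exclusion block only when another full segment follows it;
    # otherwise the remaining tail counts as dropped
    if (c + scheme$c_ex + scheme$c_in > n_cycles) break
    skipped <- skipped + scheme$c_ex
    c <- c + scheme$c_ex
  }
  dropped <- n_cycles - kept - skipped
  if (nrow(ranges) < 2L)
    warning("cycle walk produced a single segment")

  segments <- lapply(seq_len(nrow(ranges)), function(i)
    slice_frames(series, ranges[i, 1], ranges[i, 2]))
  structure(list(segments = segments, frame_ranges = ranges, scheme = scheme,
                 n_cycles_total = n_cycles, n_kept = kept,
                 n_skipped = skipped, n_dropped = dropped),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %s: %d segments (%d cycles kept, %d skipped, %d dropped)\n",
              x$scheme$name, length(x$segments), x$n_kept, x$n_skipped, x$n_dropped))
  invisible(x)
}

#' Crop several series to their common (shortest) length
#'
#' Keeps frames from the start of each series; the order of the list is
#' preserved. Used so that every concatenation condition enters nonlinear
#' analysis with an identical frame count.
#'
#' @param series_list non-empty list of [trajectory_series()].
#' @return list of `trajectory_series`, all of the minimum input length.
#' @export
crop_common <- function(series_list) {
  if (!length(series_list)) stop("empty series list", call. = FALSE)
  n_min <- min(vapply(series_list, n_frames, integer(1)))
  lapply(series_list, function(s)
    if (n_frames(s) == n_min) s else slice_frames(s, 0L, n_min))
}
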