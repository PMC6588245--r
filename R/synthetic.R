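#' Benchmark signals with known dynamics
#'
#' Three scalar test signals spanning the predictability spectrum used to
#' validate nonlinear stability/regularity estimators: a deterministic sine
#' (zero divergence, zero entropy), the chaotic Lorenz attractor
#' (intermediate), and Gaussian white noise (maximal irregularity).
#'
#' @param freq sine frequency in Hz; must be below the Nyquist rate.
#' @param rate sampling frequency in Hz.
#' @param n number of samples (>= 2).
#' @param amplitude,phase sine amplitude and phase (radians).
#' @return numeric vector of length `n`.
#' @export
gen_sine <- function(freq, rate, n, amplitude = 1, phase = 0) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (freq <= 0 || freq >= rate / 2)
    stop(sprintf("freq = %g Hz violates 0 < freq < rate/2 = %g Hz (aliasing)",
                 freq, rate / 2), call. = FALSE)
  k <- seq_len(n) - 1L
  amplitude * sin(2 * pi * freq * k / rate + phase)
}

#' @rdname gen_sine
#' @param sd standard deviation of the Gaussian noise (> 0).
#' @param seed RNG seed; identical seeds give identical series.
#' @export
gen_white_noise <- function(n, sd = 1, seed = NULL) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  with_local_seed(seed, stats::rnorm(n, 0, sd))
}

#' @rdname gen_sine
#' @param dt integration time step (> 0).
#' @param sigma,rho,beta Lorenz parameters; defaults are the classical
#'   chaotic regime (10, 28, 8/3).
#' @param transient integration steps discarded before recording.
#' @details The Lorenz series is the x-coordinate of a 4th-order
#'   Runge-Kutta integration started from a seeded random state near the
#'   attractor, with the first `transient` steps discarded.
#' @export
gen_lorenz <- function(n, dt = 0.01, sigma = 10, rho = 28, beta = 8 / 3,
                       seed = NULL, transient = 1000L) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  state <- with_local_seed(seed, c(stats::runif(1, -10, 10),
                                   stats::runif(1, -15, 15),
                                   stats::runif(1, 15, 35)))
  deriv <- function(s) c(sigma * (s[2] - s[1]),
                         s[1] * (rho - s[3]) - s[2],
                         s[1] * s[2] - beta * s[3])
  out <- numeric(n)
  total <- n + transient
  for (i in seq_len(total)) {
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state)))
      stop("Lorenz integration diverged (non-finite state)", call. = FALSE)
    if (i > transient) out[i - transient] <- state[1]
  }
  out
}

#' Generate a cohort of distinct synthetic walkers
#'
#' Emulates a subject pool for reliability analyses: each walker draws its
#' own gait parameters from realistic between-subject ranges (stride-time
#' CV 0.015-0.045 with the cohort centred on 0.03, mean cycle duration
#' 1.1-1.3 s, peak heel lift 0.12-0.18 m). Between-subject spread is what
#' makes an intraclass correlation meaningful — for a pool of identical
#' walkers the true between-subject variance is zero and the ICC of any
#' estimator degenerates towards zero.
#'
#' @param n_subjects number of walkers.
#' @param n_cycles gait cycles per walker.
#' @param seed cohort seed; per-walker seeds are derived from it
#'   deterministically.
#' @param amplitude_gain motion amplitude multiplier applied to every
#'   walker (perturbation emulation).
#' @param rate sampling frequency (Hz).
#' @return named list of [trajectory_series()] (`S1`, `S2`, ...); the
#'   drawn `walker_spec`s are attached as attribute `"specs"`.
#' @export
walker_cohort <- function(n_subjects, n_cycles = 300L, seed = 1L,
                          amplitude_gain = 1.0, rate = 100) {
  draws <- with_local_seed(seed, list(
    cv = stats::runif(n_subjects, 0.015, 0.045),
    cyc = stats::runif(n_subjects, 1.1, 1.3),
    h = stats::runif(n_subjects, 0.12, 0.18)))
  out <- vector("list", n_subjects)
  specs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    # derived per-walker seed, kept inside 32-bit integer range
    sub_seed <- as.integer((as.double(seed) * 1000 + i) %% 2147483629)
    specs[[i]] <- walker_spec(n_cycles = n_cycles, mean_cycle_s = draws$cyc[i],
                              cycle_cv = draws$cv[i],
                              step_height_m = draws$h[i],
                              amplitude_gain = amplitude_gain,
                              seed = sub_seed)
    out[[i]] <- gen_walker(specs[[i]], rate = rate)$series
  }
  names(out) <- paste0("S", seq_len(n_subjects))
  attr(out, "specs") <- specs
  out
}

#' Specification of the synthetic walker rig
#'
#' Parameters of the quasi-periodic multi-marker "walker" used as a
#' stand-in for treadmill walking recordings: a right-heel marker whose
#' vertical coordinate lifts smoothly during swing and pins to a floor
#' level during stance, plus a set of rigidly co-moving auxiliary markers
#' that exercise the weighted pose matching.
#'
#' Defaults emulate steady healthy adult walking at a mocap lab: 1.2 s mean
#' cycle duration, 3% cycle-time variability, 0.15 m peak heel lift, and
#' 0.5 mm additive marker noise (typical optical system precision).
#'
#' @param n_cycles number of gait cycles (>= 2).
#' @param mean_cycle_s mean cycle duration in seconds.
#' @param cycle_cv coefficient of variation of cycle durations (0 <= cv < 0.5).
#' @param step_height_m peak heel lift during swing (m).
#' @param floor_m stance-phase vertical heel level (m).
#' @param n_aux_markers auxiliary rigid-offset markers (the heel is added
#'   on top of these).
#' @param noise_sd_m SD of additive white measurement noise (m).
#' @param amplitude_gain multiplies every marker's motion about its static
#'   baseline; emulates amplitude-changing perturbations such as weighted
#'   or bodyweight-supported walking.
#' @param seed RNG seed.
#' @return object of class `walker_spec`.
#' @export
walker_spec <- function(n_cycles = 300L, mean_cycle_s = 1.2, cycle_cv = 0.03,
                        step_height_m = 0.15, floor_m = 0.03,
                        n_aux_markers = 7L, noise_sd_m = 5e-4,
                        amplitude_gain = 1.0, seed = 1L) {
  spec <- list(n_cycles = as.integer(n_cycles), mean_cycle_s = mean_cycle_s,
               cycle_cv = cycle_cv, step_height_m = step_height_m,
               floor_m = floor_m, n_aux_markers = as.integer(n_aux_markers),
               noise_sd_m = noise_sd_m, amplitude_gain = amplitude_gain,
               seed = as.integer(seed))
  if (spec$n_cycles < 2L) stop("n_cycles must be >= 2", call. = FALSE)
  if (spec$mean_cycle_s <= 0) stop("mean_cycle_s must be > 0", call. = FALSE)
  if (spec$cycle_cv < 0 || spec$cycle_cv >= 0.5)
    stop("cycle_cv must lie in [0, 0.5)", call. = FALSE)
  if (spec$noise_sd_m < 0) stop("noise_sd_m must be >= 0", call. = FALSE)
  if (spec$amplitude_gain <= 0) stop("amplitude_gain must be > 0", call. = FALSE)
  structure(spec, class = "walker_spec")
}

#' Generate a synthetic multi-marker walking recording
#'
#' Cycle durations are drawn i.i.d. Gaussian with mean `mean_cycle_s` and
#' CV `cycle_cv` (truncated at half the mean). Each cycle is 60% stance
#' (heel vertical pinned at `floor_m`) and 40% swing, during which the heel
#' lifts along the smooth compact bump `16 u^2 (1-u)^2` (zero value and
#' slope at both ends), so successive strides converge to the same floor
#' level the way a real heel marker does. Horizontal coordinates follow a
#' smooth quasi-periodic sway; auxiliary markers sit at fixed rigid offsets
#' from a common moving origin. Measurement noise is i.i.d. Gaussian and is
#' added after the `amplitude_gain` scaling, so the noiseless vertical
#' range scales exactly with the gain.
#'
#' @param spec a [walker_spec()].
#' @param rate sampling frequency in Hz.
#' @return a list with `series` (a [trajectory_series()]; the heel marker
#'   is named `"RHEE"`) and `true_hs` (0-based ground-truth heel-strike
#'   frames, i.e. each cycle start).
#' @export
gen_walker <- function(spec, rate = 100) {
  if (!inherits(spec, "walker_spec")) stop("`spec` must be a walker_spec", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  with_local_seed(spec$seed, {
    dur <- stats::rnorm(spec$n_cycles, spec$mean_cycle_s,
                        spec$cycle_cv * spec$mean_cycle_s)
    dur <- pmax(dur, spec$mean_cycle_s / 2)
    cyc_frames <- pmax(4L, as.integer(round(dur * rate)))
    starts <- cumsum(c(0L, cyc_frames[-length(cyc_frames)]))
    nf <- sum(cyc_frames)

    # continuous gait phase: 0 at each heel strike, 1 at the next
    phase <- numeric(nf)
    for (c in seq_len(spec$n_cycles)) {
      idx <- starts[c] + seq_len(cyc_frames[c])
      phase[idx] <- (seq_len(cyc_frames[c]) - 1L) / cyc_frames[c]
    }
    cum_phase <- (findInterval(seq_len(nf) - 1L, starts) - 1L) + phase

    stance_frac <- 0.6
    bump <- function(u) 16 * u^2 * (1 - u)^2
    swing_u <- pmax(0, (phase - stance_frac) / (1 - stance_frac))
    heel_z <- spec$step_height_m * bump(swing_u)          # 0 during stance
    # all rhythmic components are 1-stride periodic (one gait cycle = one
    # stride), the trunk bobs twice per stride; a slow whole-body drift,
    # common to every marker, emulates treadmill station-keeping
    heel_x <- 0.06 * sin(2 * pi * cum_phase)              # fore-aft per stride
    heel_y <- 0.02 * sin(2 * pi * cum_phase + pi / 3)     # ml, per stride

    org_x <- 0.015 * sin(2 * pi * cum_phase + pi / 2)
    org_y <- 0.025 * sin(2 * pi * cum_phase)              # ml sway per stride
    org_z <- 0.02 * sin(4 * pi * cum_phase)               # 2 bobs per stride
    drift_x <- 0.03 * sin(2 * pi * cum_phase / 40)        # slow common drift
    drift_y <- 0.02 * sin(2 * pi * cum_phase / 25)

    n_mark <- spec$n_aux_markers + 1L
    pos <- array(0, dim = c(nf, n_mark, 3L))
    base <- matrix(0, n_mark, 3L)
    base[1, ] <- c(0, 0, spec$floor_m)                    # heel static level
    dyn <- array(0, dim = c(nf, n_mark, 3L))
    dyn[, 1, 1] <- heel_x + drift_x
    dyn[, 1, 2] <- heel_y + drift_y
    dyn[, 1, 3] <- heel_z
    if (spec$n_aux_markers > 0L) {
      off <- cbind(stats::runif(spec$n_aux_markers, -0.25, 0.25),
                   stats::runif(spec$n_aux_markers, -0.25, 0.25),
                   stats::runif(spec$n_aux_markers, 0.4, 1.6))
      for (k in seq_len(spec$n_aux_markers)) {
        base[k + 1L, ] <- off[k, ]
        dyn[, k + 1L, 1] <- org_x + drift_x
        dyn[, k + 1L, 2] <- org_y + drift_y
        dyn[, k + 1L, 3] <- org_z
      }
    }
    for (k in seq_len(n_mark)) {
      for (a in 1:3) {
        pos[, k, a] <- base[k, a] + spec$amplitude_gain * dyn[, k, a]
      }
    }
    if (spec$noise_sd_m > 0)
      pos <- pos + array(stats::rnorm(length(pos), 0, spec$noise_sd_m), dim = dim(pos))

    names <- c("RHEE", if (spec$n_aux_markers > 0L)
      paste0("AUX", seq_len(spec$n_aux_markers)))
    list(series = trajectory_series(pos, rate = rate, marker_names = names,
                                    vertical_axis = 3L, source = "gen_walker"),
         true_hs = starts)
  })
}
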