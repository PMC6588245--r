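#' Embedding parameters for state-space reconstruction
#'
#' @param tau time lag in frames (>= 1).
#' @param dim embedding dimension (>= 1).
#' @return object of class `embedding_params`.
#' @export
embedding_params <- function(tau, dim) {
  tau <- as.integer(tau); dim <- as.integer(dim)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  structure(list(tau = tau, dim = dim), class = "embedding_params")
}

#' Delay-embed a scalar series
#'
#' Point `i` is `(u(i), u(i+tau), ..., u(i+(dim-1)tau))`; the number of
#' points is `length(u) - (dim-1)*tau`.
#'
#' @param x numeric series.
#' @param params an [embedding_params()].
#' @return numeric matrix, one embedded point per row.
#' @export
delay_embed <- function(x, params) {
  tau <- params$tau; dim <- params$dim
  npts <- length(x) - (dim - 1L) * tau
  if (npts < 1L)
    stop("series too short for this embedding", call. = FALSE)
  out <- matrix(0, npts, dim)
  for (k in seq_len(dim)) out[, k] <- x[(1L + (k - 1L) * tau):(npts + (k - 1L) * tau)]
  out
}

#' Select the embedding lag by average mutual information
#'
#' Histogram-based mutual information (equal-width bins) between `u(t)`
#' and `u(t+lag)`, evaluated for lags `1..max_lag`; the first local
#' minimum of the profile selects the lag. Two regularisations stabilise
#' the estimator: (1) the profile is averaged over `dither_reps` seeded
#' uniform dithers of two bin widths, which recovers the smooth
#' continuous-MI profile for quantised or noise-free signals whose joint
#' support is a measure-zero curve (a noiseless sampled sine, say, has
#' only one atom per distinct phase, leaving the raw histogram profile
#' flat with quantisation jitter); (2) the averaged profile is smoothed
#' with a symmetric 3-point moving average before minimum selection. Both
#' are no-ops in effect for ordinarily noisy data, whose intrinsic noise
#' dwarfs the dither. If the smoothed profile has no local minimum,
#' `max_lag` is returned with `fallback = TRUE`.
#'
#' @param x numeric series.
#' @param max_lag largest lag examined (frames).
#' @param bins number of equal-width histogram bins.
#' @param smooth width of the moving average applied to the profile
#'   before minimum selection; 1 disables smoothing.
#' @param dither_reps number of seeded dither replicates averaged
#'   (deterministic; 0 disables dithering).
#' @return list with `tau`, `ami` (averaged profile in nats, index =
#'   lag), and `fallback`.
#' @export
ami_lag <- function(x, max_lag = 200L, bins = 64L, smooth = 3L,
                    dither_reps = 8L) {
  n <- length(x)
  if (n <= 2L * max_lag)
    stop("series must be longer than 2*max_lag", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) stop("constant series: AMI undefined", call. = FALSE)
  bin_ix <- function(v) {
    i <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
    pmin.int(pmax.int(i, 1L), bins)
  }
  if (dither_reps > 0L) {
    w <- 2 * diff(rng) / bins  # dither amplitude: two bin widths
    ami <- 0
    for (rep in seq_len(dither_reps)) {
      xd <- with_local_seed(rep, x + stats::runif(n, -w / 2, w / 2))
      ami <- ami + cpp_ami_profile(bin_ix(xd), bins, as.integer(max_lag))
    }
    ami <- ami / dither_reps
  } else {
    ami <- cpp_ami_profile(bin_ix(x), bins, as.integer(max_lag))
  }
  i <- first_local_min(moving_average(ami, as.integer(smooth)))
  list(tau = if (is.na(i)) max_lag else as.integer(i),
       ami = ami, fallback = is.na(i))
}

#' Select the embedding dimension by false nearest neighbours
#'
#' For each candidate dimension `d`, the fraction of nearest neighbours
#' (Euclidean, Theiler-excluded) that are "false" — separated mainly by
#' the next delay coordinate (`rtol` distance-ratio test) or lonely
#' relative to the attractor size (`atol` test) — is computed; the
#' smallest `d` whose fraction falls below `threshold` is selected. If no
#' dimension qualifies the result saturates at `max_dim` with
#' `saturated = TRUE` (typical for stochastic signals).
#'
#' @param x numeric series.
#' @param tau embedding lag (frames).
#' @param max_dim largest dimension tried.
#' @param rtol distance-ratio criterion threshold.
#' @param atol loneliness criterion threshold (in series-SD units).
#' @param threshold acceptable false-neighbour fraction.
#' @param theiler temporal exclusion window (frames); defaults to `tau`.
#' @param n_ref number of reference points scored (evenly spaced
#'   subsample; neighbour search is always over all points).
#' @return list with `dim`, `fractions` (per candidate dimension) and
#'   `saturated`.
#' @export
fnn_dim <- function(x, tau, max_dim = 12L, rtol = 15, atol = 2,
                    threshold = 0.01, theiler = tau, n_ref = 1000L) {
  n <- length(x)
  if (n - max_dim * tau < 10L)
    stop("series too short for FNN up to max_dim", call. = FALSE)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("constant series: FNN undefined", call. = FALSE)
  fractions <- rep(NA_real_, max_dim)
  for (d in seq_len(max_dim)) {
    npts <- n - d * tau
    refs <- if (npts <= n_ref) seq_len(npts) - 1L else
      unique(as.integer(round(seq(0, npts - 1L, length.out = n_ref))))
    fractions[d] <- cpp_fnn_fraction(x, tau, d, rtol, atol,
                                     as.integer(theiler), refs, sigma)
    if (!is.na(fractions[d]) && fractions[d] < threshold) {
      return(list(dim = d, fractions = fractions[seq_len(d)], saturated = FALSE))
    }
  }
  list(dim = as.integer(max_dim), fractions = fractions, saturated = TRUE)
}

#' Select both embedding parameters (AMI lag, FNN dimension)
#'
#' @param x numeric series.
#' @param max_lag,bins passed to [ami_lag()].
#' @param max_dim,rtol,atol,threshold,n_ref passed to [fnn_dim()].
#' @return an [embedding_params()] with attributes `ami_fallback` and
#'   `fnn_saturated`.
#' @export
select_embedding <- function(x, max_lag = 200L, bins = 64L, max_dim = 12L,
                             rtol = 15, atol = 2, threshold = 0.01,
                             n_ref = 1000L) {
  a <- ami_lag(x, max_lag = max_lag, bins = bins)
  f <- fnn_dim(x, tau = a$tau, max_dim = max_dim, rtol = rtol, atol = atol,
               threshold = threshold, n_ref = n_ref)
  p <- embedding_params(a$tau, f$dim)
  attr(p, "ami_fallback") <- a$fallback
  attr(p, "fnn_saturated") <- f$saturated
  p
}

#' Settings for the Wolf Lyapunov estimator
#'
#' Defaults follow the standard prescription for gait data: divergence
#' tracked over 3 consecutive points, a noise floor of 1e-4 (data units)
#' and a maximal attractor probe of one tenth of the input data range.
#'
#' @param evolve_steps samples over which each divergence is tracked.
#' @param min_sep noise floor: smallest separation considered real
#'   (data units).
#' @param max_sep_fraction maximal probe length as a fraction of the data
#'   range.
#' @param theiler temporal exclusion window in frames; `NULL` defaults to
#'   `dim * tau` at estimation time.
#' @return object of class `wolf_params`.
#' @export
wolf_params <- function(evolve_steps = 3L, min_sep = 1e-4,
                        max_sep_fraction = 0.1, theiler = NULL) {
  if (evolve_steps < 1L) stop("evolve_steps must be >= 1", call. = FALSE)
  if (min_sep <= 0) stop("min_sep must be > 0", call. = FALSE)
  if (max_sep_fraction <= 0 || max_sep_fraction > 1)
    stop("max_sep_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(evolve_steps = as.integer(evolve_steps), min_sep = min_sep,
                 max_sep_fraction = max_sep_fraction, theiler = theiler),
            class = "wolf_params")
}

#' Largest Lyapunov exponent by Wolf's fiducial-trajectory algorithm
#'
#' Tracks the divergence of a reference trajectory from its nearest
#' admissible neighbour in the delay-embedded state space, accumulating
#' `ln(d'/d)` over `evolve_steps`-sample stretches and replacing the
#' neighbour (minimising the change of orientation) whenever the
#' separation exceeds the maximal probe length. The result is in nats per
#' sample; multiply by the sampling rate for nats per second.
#'
#' @param x numeric series.
#' @param params an [embedding_params()].
#' @param wolf a [wolf_params()].
#' @return largest Lyapunov exponent (nats/sample).
#' @export
wolf_lye <- function(x, params, wolf = wolf_params()) {
  rng <- diff(range(x))
  if (rng <= 0) stop("constant series: Lyapunov exponent undefined", call. = FALSE)
  theiler <- if (is.null(wolf$theiler)) params$dim * params$tau else wolf$theiler
  cpp_wolf_lye(x, params$tau, params$dim, wolf$evolve_steps,
               wolf$min_sep, wolf$max_sep_fraction * rng, as.integer(theiler))
}

#' Settings for delayed sample entropy
#'
#' @param r_fraction matching tolerance as a fraction of the series SD
#'   (default 0.2).
#' @return object of class `sampen_params`.
#' @export
sampen_params <- function(r_fraction = 0.2) {
  if (r_fraction <= 0) stop("r_fraction must be > 0", call. = FALSE)
  structure(list(r_fraction = r_fraction), class = "sampen_params")
}

#' Delayed sample entropy
#'
#' Sample entropy generalised to a delayed embedding: template vectors are
#' built with lag `tau` and dimension `dim`; `B` counts template pairs
#' within Chebyshev tolerance `r = r_fraction * SD` at length `dim`, `A`
#' the same at length `dim + 1` (self-matches excluded), and
#' `SE = -ln(A/B)`. With `tau = 1` this reduces to standard sample
#' entropy. Zero match counts never degrade silently to 0: `A = 0` (no
#' matches at length `dim + 1`) yields `+Inf` with attribute
#' `undefined = TRUE` and a warning — the series is more irregular than
#' the tolerance can resolve; `B = 0` (no matches even at length `dim`,
#' typical for stochastic signals at a saturated embedding dimension)
#' likewise yields `+Inf`, flagged and warned.
#'
#' @param x numeric series.
#' @param params an [embedding_params()].
#' @param sampen a [sampen_params()].
#' @return sample entropy in nats, with attribute `counts = c(A, B)`.
#' @export
sample_entropy <- function(x, params, sampen = sampen_params()) {
  sdx <- stats::sd(x)
  if (sdx == 0) stop("constant series: sample entropy undefined", call. = FALSE)
  r <- sampen$r_fraction * sdx
  cnt <- cpp_sampen_counts(x, params$dim, params$tau, r)
  A <- cnt[1]; B <- cnt[2]
  if (A == 0) {
    warning(sprintf(
      "no template matches at length %s (A = 0%s): sample entropy undefined, reporting +Inf",
      if (B == 0) sprintf("%d", params$dim) else sprintf("%d", params$dim + 1L),
      if (B == 0) ", B = 0" else ""))
    se <- Inf
    attr(se, "undefined") <- TRUE
  } else {
    se <- -log(A / B)
  }
  attr(se, "counts") <- c(A = A, B = B)
  se
}

#' Stability and regularity measures of one scalar series
#'
#' Convenience wrapper: selects the embedding (AMI lag, FNN dimension)
#' and computes both the Wolf largest Lyapunov exponent and delayed
#' sample entropy with the package defaults.
#'
#' @param x numeric series (typically a vertical heel trajectory).
#' @param params an [embedding_params()]; `NULL` (default) re-estimates
#'   the embedding from `x` via [select_embedding()].
#' @param wolf a [wolf_params()].
#' @param sampen a [sampen_params()].
#' @param ... passed to [select_embedding()].
#' @return list with `lye` (nats/sample), `se` (nats), `params`, `flags`.
#' @export
nonlinear_measures <- function(x, params = NULL, wolf = wolf_params(),
                               sampen = sampen_params(), ...) {
  if (is.null(params)) params <- select_embedding(x, ...)
  se <- sample_entropy(x, params, sampen)
  list(lye = wolf_lye(x, params, wolf),
       se = as.numeric(se),
       params = params,
       flags = list(ami_fallback = isTRUE(attr(params, "ami_fallback")),
                    fnn_saturated = isTRUE(attr(params, "fnn_saturated")),
                    se_undefined = isTRUE(attr(se, "undefined"))))
}
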