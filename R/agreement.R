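#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed, single-measure, consistency ICC:
#' `(BMS - EMS) / (BMS + (k-1) EMS)` from the two-way ANOVA decomposition
#' (subjects x conditions, k = 2 conditions here). The model is fitted
#' with [stats::aov()].
#'
#' @param ratings numeric matrix, subjects in rows, the two compared
#'   conditions in columns; no missing cells.
#' @return ICC(3,1) in (-1, 1].
#' @export
icc_3_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  ns <- nrow(ratings); k <- ncol(ratings)
  if (k != 2L) stop("exactly 2 conditions expected", call. = FALSE)
  if (ns < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(ratings)) stop("missing cells not allowed", call. = FALSE)
  if (stats::var(as.vector(ratings)) == 0)
    stop("zero variance: ICC undefined", call. = FALSE)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(ns), k)),
                   rater = factor(rep(seq_len(k), each = ns)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  bms <- ms[1]; ems <- ms[3]
  if (bms + (k - 1) * ems == 0)
    stop("zero variance: ICC undefined", call. = FALSE)
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Standard error of measurement
#'
#' `SEM = SD_pooled * sqrt(1 - ICC)` with the SD taken over all cells of
#' the ratings matrix; the relative SEM divides by the grand mean of both
#' conditions (flagged `NA` when the grand mean is zero).
#'
#' @param ratings subjects x 2 matrix.
#' @param icc intraclass correlation (<= 1); computed from `ratings` via
#'   [icc_3_1()] when omitted.
#' @return list with `sem` and `relative_sem`.
#' @export
sem_measure <- function(ratings, icc = icc_3_1(ratings)) {
  if (icc > 1) stop("icc must be <= 1", call. = FALSE)
  ratings <- as.matrix(ratings)
  sd_pooled <- stats::sd(as.vector(ratings))
  sem <- sd_pooled * sqrt(1 - icc)
  gm <- mean(ratings)
  rel <- if (gm == 0) { warning("grand mean is zero; relative SEM undefined"); NA_real_ }
         else sem / gm
  list(sem = sem, relative_sem = rel)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = x_i - y_i`; systematic error (bias) is `mean(d)`,
#' random error the 95% limits of agreement `bias +/- 1.96 SD(d)`. 95%
#' confidence intervals use Student t: `bias +/- t_{n-1} SD/sqrt(n)` for
#' the bias and `loa +/- t_{n-1} sqrt(3/n) SD` for each limit.
#'
#' @param x,y paired measurements of equal length (n >= 2).
#' @return object of class `bland_altman`: list with `n`, `bias`,
#'   `loa_low`, `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa_low <- bias - 1.96 * sdd
  loa_high <- bias + 1.96 * sdd
  tq <- stats::qt(0.975, n - 1L)
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  structure(list(n = n, bias = bias, loa_low = loa_low, loa_high = loa_high,
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_low = loa_low + c(-1, 1) * tq * se_loa,
                 ci_loa_high = loa_high + c(-1, 1) * tq * se_loa,
                 means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d  bias = %.4g [%.4g, %.4g]\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LoA = [%.4g, %.4g]\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' Paired effect size with pooled standard deviation
#'
#' `d = (mean_1 - mean_2) / s` with
#' `s = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param group_1,group_2 numeric vectors (>= 2 values each).
#' @return list with `d`, `mean_1`, `mean_2`, `pooled_sd`.
#' @export
cohens_d_pooled <- function(group_1, group_2) {
  n1 <- length(group_1); n2 <- length(group_2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group", call. = FALSE)
  s <- sqrt(((n1 - 1) * stats::var(group_1) + (n2 - 1) * stats::var(group_2)) /
              (n1 + n2 - 2))
  if (s == 0) stop("zero pooled SD: effect size undefined", call. = FALSE)
  list(d = (mean(group_1) - mean(group_2)) / s,
       mean_1 = mean(group_1), mean_2 = mean(group_2), pooled_sd = s)
}

#' Coefficient of variation of effect sizes
#'
#' `100 * SD(es) / |mean(es)|` (sample SD), used to quantify how stable an
#' effect size is across cutting conditions.
#'
#' @param es_values numeric vector of effect sizes (>= 2 values).
#' @return percent CoV; `NA` with a warning when the mean is zero.
#' @export
cov_of_es <- function(es_values) {
  if (length(es_values) < 2L) stop("need >= 2 effect sizes", call. = FALSE)
  m <- mean(es_values)
  if (m == 0) { warning("mean effect size is zero; CoV undefined"); return(NA_real_) }
  100 * stats::sd(es_values) / abs(m)
}

#' Full agreement report between two measurement conditions
#'
#' Bundles ICC(3,1), SEM and Bland-Altman statistics for a paired set of
#' measurements (e.g. a nonlinear measure on the uninterrupted series vs
#' the same measure on a concatenated variant).
#'
#' @param x,y paired measurements (x = reference condition).
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(x, y) {
  ratings <- cbind(x, y)
  icc <- icc_3_1(ratings)
  sem <- sem_measure(ratings, icc)
  ba <- bland_altman(x, y)
  structure(c(list(icc = icc, sem = sem$sem, relative_sem = sem$relative_sem),
              unclass(ba)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  ICC(3,1) = %.3f  SEM = %.4g (relative %.3g)\n",
              x$icc, x$sem, x$relative_sem))
  cat(sprintf("  bias = %.4g  LoA = [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
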