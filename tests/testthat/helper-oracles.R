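# Fixtures and independent oracles used across the suite.

# random trajectory series
make_random_series <- function(frames = 100, markers = 3, rate = 100,
                               seed = 1) {
  set.seed(seed)
  trajectory_series(array(rnorm(frames * markers * 3),
                          dim = c(frames, markers, 3L)),
                    rate = rate,
                    marker_names = paste0("M", seq_len(markers)))
}

# Brute-force delayed sample-entropy pair counts: plain double loop over
# all template pairs, no sorting, no early exit.
sampen_bruteforce <- function(x, m, tau, r) {
  n <- length(x)
  nt <- n - m * tau
  if (nt < 2) return(c(A = 0, B = 0))
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      idx <- seq(0, (m - 1) * tau, by = tau)
      if (max(abs(x[i + idx] - x[j + idx])) <= r) {
        B <- B + 1L
        if (abs(x[i + m * tau] - x[j + m * tau]) <= r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

# Brute-force minimisation of the weighted pose distance over a rotation
# grid, solving the translation in closed form per angle. Windows are
# n x M x 3 arrays, weights per marker, vertical axis fixed at 3.
transform_bruteforce <- function(wa, wb, w, theta_step = 1e-3) {
  n <- dim(wa)[1]; M <- dim(wa)[2]
  wvec <- rep(w, each = n)
  ax <- as.vector(wa[, , 1]); ay <- as.vector(wa[, , 2])
  bx <- as.vector(wb[, , 1]); by <- as.vector(wb[, , 2])
  dv2 <- sum(wvec * (as.vector(wa[, , 3]) - as.vector(wb[, , 3]))^2)
  sw <- sum(wvec)
  best <- Inf
  for (theta in seq(-pi, pi, by = theta_step)) {
    ct <- cos(theta); st <- sin(theta)
    rx <- ct * bx - st * by
    ry <- st * bx + ct * by
    tx <- sum(wvec * (ax - rx)) / sw
    ty <- sum(wvec * (ay - ry)) / sw
    d <- sum(wvec * ((ax - rx - tx)^2 + (ay - ry - ty)^2)) + dv2
    if (d < best) best <- d
  }
  best
}

# ICC(3,1) from explicit two-way ANOVA sums of squares (independent of
# stats::aov).
icc31_sums_of_squares <- function(ratings) {
  ratings <- as.matrix(ratings)
  ns <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- ns * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (ns - 1)
  ems <- ss_err / ((ns - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

# Benettin two-trajectory estimate of the largest Lyapunov exponent of the
# Lorenz system (nats per unit time): integrate a pair of trajectories
# with RK4, renormalising the separation to d0 every few steps.
lorenz_lambda1_oracle <- function(total_time = 200, dt = 0.01, d0 = 1e-8,
                                  renorm_every = 10L, seed = 42) {
  deriv <- function(s) c(10 * (s[2] - s[1]),
                         s[1] * (28 - s[3]) - s[2],
                         s[1] * s[2] - 8 / 3 * s[3])
  rk4 <- function(s) {
    k1 <- deriv(s); k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2); k4 <- deriv(s + dt * k3)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  set.seed(seed)
  a <- c(runif(1, -10, 10), runif(1, -15, 15), runif(1, 15, 35))
  for (i in 1:2000) a <- rk4(a)          # settle onto the attractor
  b <- a + c(d0, 0, 0)
  n_steps <- round(total_time / dt)
  sum_log <- 0
  for (i in seq_len(n_steps)) {
    a <- rk4(a); b <- rk4(b)
    if (i %% renorm_every == 0) {
      d <- sqrt(sum((a - b)^2))
      sum_log <- sum_log + log(d / d0)
      b <- a + (b - a) * (d0 / d)
    }
  }
  sum_log / (n_steps * dt)
}
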