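test_that("alpha coefficient matches its closed form and endpoint behaviour", {
  for (n in c(2, 3, 33, 100)) {
    a <- alpha_coefficient(0:(n - 1), n)
    expect_equal(a[n], 0)                       # j = n-1
    expect_true(all(diff(a) < 0))               # strictly decreasing
  }
  expect_equal(alpha_coefficient(0, 33), 2 * (1 / 33)^3 - 3 * (1 / 33)^2 + 1,
               tolerance = 1e-12)
  expect_equal(alpha_coefficient(0, 33), 0.997301, tolerance = 1e-6)
  # (j+1)/n = 1/2 -> smoothstep midpoint
  expect_equal(alpha_coefficient(4, 10), 0.5)
  expect_error(alpha_coefficient(10, 10), "j must")
})

test_that("optimal transform recovers a known rigid motion and is exact on identity", {
  set.seed(5)
  wa <- array(rnorm(10 * 4 * 3), dim = c(10, 4, 3))
  w <- c(1, 0.5, 0.2, 1)

  fit0 <- optimal_transform(wa, wa, w)
  expect_lt(fit0$distance, 1e-12)
  expect_equal(fit0$transform$theta, 0)
  expect_equal(fit0$transform$t, c(0, 0))

  tf <- rigid_transform_2d(30 * pi / 180, c(0.5, -0.2))
  wb <- apply_transform(wa, tf, vertical_axis = 3)
  fit <- optimal_transform(wa, wb, w)
  # recovered transform inverts the applied one
  expect_equal(fit$transform$theta, -tf$theta, tolerance = 1e-10)
  expect_lt(fit$distance, 1e-10)
  back <- apply_transform(wb, fit$transform, 3)
  expect_lt(max(abs(back - wa)), 1e-10)

  expect_error(optimal_transform(wa, wb, rep(0, 4)), "zero")
  expect_error(optimal_transform(wa, wb[1:5, , , drop = FALSE], w), "differ")
})

test_that("closed-form distance matches the brute-force rotation-grid oracle", {
  set.seed(17)
  for (i in 1:10) {
    wa <- array(rnorm(6 * 3 * 3), dim = c(6, 3, 3))
    wb <- array(rnorm(6 * 3 * 3), dim = c(6, 3, 3))
    w <- runif(3, 0.1, 1)
    closed <- optimal_transform(wa, wb, w)$distance
    brute <- transform_bruteforce(wa, wb, w)
    expect_lte(closed, brute + 1e-6 * max(brute, 1))
  }
})

test_that("rigid transforms invert to identity and leave the vertical axis alone", {
  tf <- rigid_transform_2d(1.234, c(-0.3, 2.2))
  set.seed(3)
  pos <- array(rnorm(5 * 2 * 3), dim = c(5, 2, 3))
  round_trip <- apply_transform(apply_transform(pos, tf, 3),
                                invert_transform(tf), 3)
  expect_lt(max(abs(round_trip - pos)), 1e-12)
  expect_identical(apply_transform(pos, tf, 3)[, , 3], pos[, , 3])
  # vertical axis 1 variant
  expect_identical(apply_transform(pos, tf, 1)[, , 1], pos[, , 1])
})

test_that("distance profile is non-negative, group-invariant and linear in weights", {
  g <- gen_walker(walker_spec(n_cycles = 8, seed = 13))
  seg_a <- slice_frames(g$series, 0, 300)
  seg_b <- slice_frames(g$series, 250, 650)
  w <- c(1, runif(n_markers(seg_a) - 1, 0.2, 1))

  prof <- distance_profile(seg_a, seg_b, n = 33, weights = w)
  expect_true(all(prof$profile >= 0))

  # invariance under the alignment group applied to seg_b
  tf <- rigid_transform_2d(runif(1, -pi, pi), runif(2, -2, 2))
  seg_b_moved <- seg_b
  seg_b_moved$positions <- apply_transform(seg_b$positions, tf, 3)
  prof2 <- distance_profile(seg_a, seg_b_moved, n = 33, weights = w)
  expect_lt(max(abs(prof2$profile - prof$profile)) /
              max(prof$profile), 1e-8)

  # doubling all weights doubles every D(v)
  prof3 <- distance_profile(seg_a, seg_b, n = 33, weights = 2 * w)
  expect_equal(prof3$profile, 2 * prof$profile, tolerance = 1e-12)

  expect_error(distance_profile(seg_a, slice_frames(seg_b, 0, 10), n = 33),
               "shorter")
})

test_that("transition selection follows the first-local-minimum rule", {
  cand <- function(p) structure(list(profile = p,
                                     transforms = rep(list(rigid_transform_2d()),
                                                      length(p)),
                                     n = 5L, mode = "window"),
                                class = "transition_candidates")
  ch <- select_transition(cand(c(5, 3, 4, 1, 2)))
  expect_equal(ch$v, 1L)
  expect_false(ch$fallback)
  expect_equal(ch$distance, 3)

  ch2 <- select_transition(cand(c(5, 4, 3, 2, 1)))   # strictly decreasing
  expect_equal(ch2$v, 4L)
  expect_true(ch2$fallback)

  ch3 <- select_transition(cand(c(2, 2, 1)))         # plateau start skipped
  expect_equal(ch3$v, 2L)

  ch4 <- select_transition(cand(c(0, 1, 2)))         # boundary minimum
  expect_equal(ch4$v, 0L)
  expect_false(ch4$fallback)

  expect_error(select_transition(cand(numeric(0))), "empty")
})

test_that("exact-overlap blending is a splice identity with the exact length", {
  g <- gen_walker(walker_spec(n_cycles = 10, seed = 23))
  S <- g$series
  n <- 33L; k <- 500L
  seg_a <- slice_frames(S, 0, k)
  seg_b <- slice_frames(S, k - n, n_frames(S))
  cand <- distance_profile(seg_a, seg_b, n = n)
  ch <- select_transition(cand)
  expect_equal(ch$v, 0L)
  expect_lt(ch$distance, 1e-10)
  out <- blend_pair(seg_a, seg_b, ch)
  expect_equal(n_frames(out), n_frames(S))
  expect_lt(max(abs(out$positions - S$positions)), 1e-9)

  # blended frame at j = n-1 equals the transformed seg_b frame (alpha = 0)
  ch_forced <- ch; ch_forced$v <- 40L
  out2 <- blend_pair(seg_a, seg_b, ch_forced)
  b_tail <- apply_transform(seg_b$positions, ch_forced$transform, 3)
  expect_equal(out2$positions[k, , ], b_tail[40 + n, , ])
  # output length formula L_a + N - v - n
  expect_equal(n_frames(out2), k + n_frames(seg_b) - 40L - n)
})

test_that("output length formula holds exactly on random inputs", {
  set.seed(77)
  for (i in 1:20) {
    La <- sample(40:120, 1); N <- sample(40:120, 1); n <- sample(2:30, 1)
    a <- make_random_series(frames = La, markers = 2, seed = i)
    b <- make_random_series(frames = N, markers = 2, seed = i + 1000)
    ch <- select_transition(distance_profile(a, b, n = n))
    out <- blend_pair(a, b, ch)
    expect_identical(n_frames(out), La + N - as.integer(ch$v) - n)
  }
})

test_that("chained concatenation reconstructs a series from exact-overlap segments", {
  g <- gen_walker(walker_spec(n_cycles = 12, seed = 29))
  S <- g$series
  n <- 33L
  cuts <- c(0L, 400L, 800L, n_frames(S))
  segs <- list(slice_frames(S, 0, cuts[2]),
               slice_frames(S, cuts[2] - n, cuts[3]),
               slice_frames(S, cuts[3] - n, cuts[4]))
  res <- concatenate_all(segs, n = n)
  expect_equal(length(res$transitions), 2L)
  for (tr in res$transitions) expect_lt(tr$distance, 1e-10)
  expect_equal(n_frames(res$series), n_frames(S))
  expect_lt(max(abs(res$series$positions - S$positions)), 1e-9)

  single <- concatenate_all(segs[1], n = n)
  expect_identical(single$series$positions, segs[[1]]$positions)
  expect_equal(length(single$transitions), 0L)
})

test_that("concatenating a cut walker introduces no teleportation artefacts", {
  g <- gen_walker(walker_spec(n_cycles = 40, seed = 37))
  ev <- detect_heel_strikes(g$series)
  set <- cut_series(g$series, ev, cut_scheme(6, 5))
  res <- concatenate_all(set, n = 33)
  z <- g$series$positions[, 1, ]
  step_orig <- max(sqrt(rowSums(diff(z)^2)))
  zc <- res$series$positions[, 1, ]
  step_cat <- max(sqrt(rowSums(diff(zc)^2)))
  expect_lte(step_cat, 1.5 * step_orig)
})

test_that("per-frame distance mode is never below the single-transform distance", {
  g <- gen_walker(walker_spec(n_cycles = 6, seed = 41))
  seg_a <- slice_frames(g$series, 0, 200)
  seg_b <- slice_frames(g$series, 150, 500)
  p1 <- distance_profile(seg_a, seg_b, n = 20)
  p2 <- distance_profile(seg_a, seg_b, n = 20, per_frame = TRUE)
  # a per-frame optimum can only lower each frame's residual
  expect_true(all(p2$profile <= p1$profile + 1e-10))
  expect_equal(p2$mode, "per_frame")
})
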