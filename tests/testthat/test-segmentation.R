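fake_events <- function(hs) structure(list(hs_frames = as.integer(hs),
                                           marker = "RHEE", method = "fixture"),
                                      class = "gait_events")

test_that("keep/skip walk reproduces the hand-enumerated cutting patterns", {
  # 34 heel strikes = 33 cycles, 10 frames per cycle
  hs <- seq(0, by = 10, length.out = 34)
  s <- make_random_series(frames = 400, markers = 2)
  ev <- fake_events(hs)

  set1001 <- cut_series(s, ev, cut_scheme(10, 1))
  # cycles [0..9], [11..20], [22..31]; cycle 32 dropped
  expect_equal(nrow(set1001$frame_ranges), 3L)
  expect_equal(set1001$frame_ranges[, 1], c(0, 110, 220))
  expect_equal(set1001$frame_ranges[, 2], c(100, 210, 320))
  expect_equal(set1001$n_kept, 30L)
  expect_equal(set1001$n_skipped, 2L)
  expect_equal(set1001$n_dropped, 1L)

  # 11 cycles, scheme (6,5): a single segment of cycles [0..5]
  ev11 <- fake_events(seq(0, by = 10, length.out = 12))
  expect_warning(set0605 <- cut_series(s, ev11, cut_scheme(6, 5)),
                 "single segment")
  expect_equal(set0605$frame_ranges, rbind(c(0, 60)))
  expect_equal(set0605$n_dropped, 5L)
})

test_that("a scheme with no exclusion tiles all complete cycles", {
  hs <- cumsum(c(0, sample(8:12, 20, replace = TRUE)))
  s <- make_random_series(frames = max(hs) + 1, markers = 1)
  set <- cut_series(s, fake_events(hs), cut_scheme(4, 0))
  expect_equal(set$n_skipped, 0L)
  expect_equal(set$n_kept + set$n_dropped, 20L)
  # kept segments abut exactly
  expect_equal(set$frame_ranges[-1, 1], set$frame_ranges[-nrow(set$frame_ranges), 2])
})

test_that("cycle conservation holds for random event lists and schemes", {
  set.seed(31)
  s <- make_random_series(frames = 3000, markers = 1)
  for (i in 1:25) {
    n_ev <- sample(8:40, 1)
    hs <- sort(sample(0:2999, n_ev))
    c_in <- sample(1:8, 1); c_ex <- sample(0:6, 1)
    sch <- cut_scheme(c_in, c_ex)
    if (n_ev - 1 < c_in) {
      expect_error(cut_series(s, fake_events(hs), sch), "not enough")
    } else {
      set <- suppressWarnings(cut_series(s, fake_events(hs), sch))
      expect_equal(set$n_kept + set$n_skipped + set$n_dropped,
                   set$n_cycles_total)
      expect_true(all(diff(as.vector(t(set$frame_ranges))) >= 0))
      expect_true(all(vapply(set$segments, n_frames, integer(1)) ==
                        set$frame_ranges[, 2] - set$frame_ranges[, 1]))
    }
  }
})

test_that("crop_common truncates to the shortest series, preserving order", {
  lens <- c(100, 90, 95)
  lst <- lapply(seq_along(lens), function(i)
    make_random_series(frames = lens[i], markers = 2, seed = i))
  out <- crop_common(lst)
  expect_equal(vapply(out, n_frames, integer(1)), c(90, 90, 90))
  expect_equal(out[[1]]$positions, lst[[1]]$positions[1:90, , , drop = FALSE])

  one <- crop_common(lst[2])
  expect_identical(one[[1]], lst[[2]])

  eq <- crop_common(lst[c(2, 2)])
  expect_identical(eq[[1]]$positions, lst[[2]]$positions)
  expect_error(crop_common(list()), "empty")
})
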