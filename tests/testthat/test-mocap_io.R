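test_that("CSV/TSV round-trip is the identity to below 1e-9 m", {
  s <- make_random_series(frames = 100, markers = 4, seed = 7)
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    save_series(s, path, dialect)
    s2 <- load_series(path, dialect)
    expect_lt(max(abs(s2$positions - s$positions)), 1e-9)
    expect_identical(s2$marker_names, s$marker_names)
    expect_equal(s2$rate, s$rate)
  }
})

test_that("writing to a directory path is an I/O error", {
  s <- make_random_series(frames = 3)
  expect_error(save_series(s, withr::local_tempdir()), "directory")
})

test_that("gap policy: reject by default, linear_fill interpolates interior gaps only", {
  s <- make_random_series(frames = 5, markers = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  save_series(s, path)
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   check.names = FALSE)
  df_na <- df; df_na[3, "M1_Y"] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("# rate: 100", path2)
  suppressWarnings(write.table(df_na, path2, sep = ",", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  expect_error(load_series(path2, "csv"), "gap_policy")
  expect_message(s2 <- load_series(path2, "csv", gap_policy = "linear_fill"),
                 "interpolated 1")
  # filled value is the mean of its two neighbours
  expect_equal(s2$positions[3, 1, 2],
               (s$positions[2, 1, 2] + s$positions[4, 1, 2]) / 2)

  df_lead <- df; df_lead[1, "M2_Z"] <- NA
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("# rate: 100", path3)
  suppressWarnings(write.table(df_lead, path3, sep = ",", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  expect_error(load_series(path3, "csv", gap_policy = "linear_fill"),
               "leading/trailing")
})

test_that("incomplete marker coordinate triplets are a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate: 100", "M1_X,M1_Y", "0.1,0.2", "0.3,0.4"), path)
  expect_error(load_series(path, "csv"), "incomplete")
})

test_that("trajectory_series validation is total over malformed inputs", {
  good <- array(0, dim = c(4, 2, 3))
  expect_error(trajectory_series(good, rate = 0), "rate")
  expect_error(trajectory_series(good, rate = 100, marker_names = c("A", "A")),
               "unique")
  expect_error(trajectory_series(good, rate = 100, marker_names = "A"),
               "number of markers")
  bad <- good; bad[2, 1, 3] <- NA
  expect_error(trajectory_series(bad, rate = 100), "missing")
  expect_error(trajectory_series(array(0, dim = c(4, 2, 2)), rate = 100),
               "frames x markers x 3")
  set.seed(42)
  for (i in 1:20) {
    s <- make_random_series(frames = sample(2:50, 1),
                            markers = sample(1:6, 1), seed = i)
    expect_false(anyNA(s$positions))
    expect_true(s$rate > 0)
    expect_equal(length(s$marker_names), n_markers(s))
  }
})

test_that("weight maps resolve with defaults and reject bad configs", {
  s <- make_random_series(markers = 4)  # markers M1..M4
  path <- withr::local_tempfile(fileext = ".json")

  jsonlite::write_json(list(default = 1.0, weights = setNames(list(), character(0))),
                       path, auto_unbox = TRUE)
  expect_equal(load_weights(path, s), rep(1, 4))

  jsonlite::write_json(list(default = 0.5, weights = list(M1 = 1.0, M3 = 0.2)),
                       path, auto_unbox = TRUE)
  expect_equal(load_weights(path, s), c(1.0, 0.5, 0.2, 0.5))

  jsonlite::write_json(list(weights = list(M1 = 1.5)), path, auto_unbox = TRUE)
  expect_error(load_weights(path, s), "\\[0, 1\\]")

  jsonlite::write_json(list(weights = list(NOPE = 0.5)), path, auto_unbox = TRUE)
  expect_error(load_weights(path, s), "unknown")

  expect_error(weight_map(c(M1 = 0, M2 = 0)), "strictly positive")
})
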