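test_that("breath series CSV round-trips and rejects malformed input", {
  tt <- cumsum(runif(50, 1.5, 2.5))
  b <- breath_series(tt, runif(50, 1, 3), runif(50, 1, 3),
                     ve = runif(50, 30, 80), power = rep(150, 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_breaths(b, path)
  b2 <- read_breaths(path)
  expect_equal(b2$t, b$t, tolerance = 1e-6)
  expect_equal(b2$vo2, b$vo2, tolerance = 1e-6)
  expect_equal(b2$vco2, b$vco2, tolerance = 1e-6)
  expect_equal(b2$power, b$power, tolerance = 1e-6)

  # comment header and extra columns are tolerated
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# exported by analyzer", "t_s,vo2_l_min,vco2_l_min,hr_bpm",
               "0,1.0,0.9,120", "2,1.1,1.0,121"), path2)
  expect_equal(nrow(read_breaths(path2)), 2L)

  # reversed time names the offending rows
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,vo2_l_min,vco2_l_min", "10,1,1", "5,1,1", "1,1,1"), path3)
  expect_error(read_breaths(path3), "strictly increasing")

  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines("t_s,vo2_l_min,vco2_l_min", path4)
  expect_error(read_breaths(path4), "no breaths")

  path5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,vo2_l_min", "0,1"), path5)
  expect_error(read_breaths(path5), "vco2_l_min")
})

test_that("uniform resampling interpolates linearly and preserves integrals", {
  b <- breath_series(seq(0, 100, 2), rep(2, 51), rep(1.8, 51))
  rs <- resample_uniform(b, 1)
  expect_true(all(abs(rs$vo2 - 2) < 1e-12))
  expect_equal(range(rs$t), range(b$t))

  b2 <- breath_series(c(0, 10), c(1, 2), c(1, 2))
  rs2 <- resample_uniform(b2, 5)
  expect_equal(rs2$vo2[rs2$t == 5], 1.5)

  # resampled exponential integral within 0.5% of the closed form
  tau <- 30; A <- 2; T <- 300
  b3 <- series_from_fn(function(t) A * (1 - exp(-t / tau)), T, dt = 2)
  got <- accumulated_vo2(resample_uniform(b3, 1), 0, T)
  want <- A * (T - tau * (1 - exp(-T / tau))) / 60
  expect_lt(abs(got - want) / want, 0.005)

  expect_error(resample_uniform(breath_series(0, 1, 1)), "at least 2")
})

test_that("last-window mean is time-weighted and ignores earlier breaths", {
  b <- breath_series(seq(0, 120, 2), rep(2.99, 61), rep(2.7, 61))
  expect_equal(mean_last_window(b, 30), 2.99, tolerance = 1e-9)

  # linear ramp with slope k ending at v averages to v - k*window/2
  k <- 0.01; v_end <- 3
  b2 <- series_from_fn(function(t) v_end - k * (300 - t), 300)
  expect_equal(mean_last_window(b2, 30), v_end - k * 30 / 2, tolerance = 1e-6)

  expect_error(mean_last_window(breath_series(seq(0, 20, 2), rep(1, 11),
                                              rep(1, 11)), 30), "shorter")

  # invariance to adding breaths before the window
  base <- breath_series(seq(100, 200, 2), rep(2.5, 51), rep(2, 51))
  padded <- breath_series(c(seq(0, 98, 2), seq(100, 200, 2)),
                          c(runif(50, 0, 5), rep(2.5, 51)),
                          c(runif(50, 0, 5), rep(2, 51)))
  expect_equal(mean_last_window(padded, 30), mean_last_window(base, 30),
               tolerance = 1e-12)
})

test_that("accumulated VO2 matches closed forms and is additive", {
  b <- breath_series(seq(0, 120, 2), rep(3, 61), rep(2.7, 61))
  expect_equal(accumulated_vo2(b, 0, 120), 6, tolerance = 1e-9)

  # 2(1 - exp(-t/30)) over 300 s
  b2 <- series_from_fn(function(t) 2 * (1 - exp(-t / 30)), 300)
  want <- 2 * (300 - 30 * (1 - exp(-10))) / 60
  expect_lt(abs(accumulated_vo2(b2, 0, 300) - want) / want, 0.002)

  # additivity over adjacent windows
  left <- accumulated_vo2(b2, 0, 150)
  right <- accumulated_vo2(b2, 150, 300)
  expect_equal(left + right, accumulated_vo2(b2, 0, 300), tolerance = 1e-9)
  expect_gte(left, 0)

  expect_error(accumulated_vo2(b, 50, 50), "t_start < t_end")
  expect_error(accumulated_vo2(b, 0, 500), "outside")
})

test_that("isotime is the shorter exhaustion time and rejects non-positive input", {
  expect_equal(isotime(298.3, 400.0), 298.3)
  expect_equal(isotime(100, 100), 100)
  expect_error(isotime(-1, 50), "positive")
  expect_error(isotime(120, 0), "positive")
})

test_that("series truncation cuts at isotime with interpolation", {
  b <- breath_series(seq(0, 100, 2), seq(1, 3, length.out = 51), rep(2, 51))
  tr <- truncate_series(b, 51)
  expect_equal(max(tr$t), 51)
  expect_equal(tr$vo2[nrow(tr)],
               stats::approx(b$t, b$vo2, xout = 51)$y)
  expect_error(truncate_series(b, 500), "outside")
})
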