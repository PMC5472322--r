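off_fixture <- c(vo2base = 0.35, a1 = 1.0, tau1 = 54.9, a2 = 0.3,
                 tau2 = 400, delta = 5)

fixture_series <- function(noise_sd = 0, seed = NULL, t_end = 600) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, t_end, 1)
  v <- eval_off_kinetics(tt, off_fixture[["vo2base"]], off_fixture[["a1"]],
                         off_fixture[["tau1"]], off_fixture[["a2"]],
                         off_fixture[["tau2"]], off_fixture[["delta"]])
  if (noise_sd > 0) v <- v + rnorm(length(tt), 0, noise_sd)
  v <- pmax(v, 0)
  breath_series(tt, v, 0.9 * v)
}

test_that("off-kinetics fitting is self-inverse on noiseless data", {
  f <- fit_off_kinetics(fixture_series())
  expect_true(f$converged)
  for (nm in names(off_fixture))
    expect_equal(f[[nm]], off_fixture[[nm]], tolerance = 5e-4)
  expect_lt(f$rss, 1e-8)
})

test_that("a degenerate slow component collapses to zero amplitude", {
  tt <- seq(0, 600, 1)
  v <- eval_off_kinetics(tt, 0.35, 1.0, 54.9, 0, 400, 5)
  f <- fit_off_kinetics(breath_series(tt, v, 0.9 * v))
  expect_equal(f$a1, 1.0, tolerance = 0.01)
  expect_equal(f$tau1, 54.9, tolerance = 0.5)
  expect_lte(f$a2, 0.01)
})

test_that("short recovery windows are rejected", {
  expect_error(fit_off_kinetics(fixture_series(t_end = 200)), "300 s")
})

test_that("the optional two-delay variant fits the shared-delay truth", {
  f <- fit_off_kinetics(fixture_series(), per_component_delay = TRUE)
  expect_true(f$converged)
  expect_equal(f$a1, 1.0, tolerance = 0.01)
  expect_equal(f$tau1, 54.9, tolerance = 0.5)
})

test_that("alactic energy is the fast-component O2 volume times 20.9", {
  expect_equal(alactic_energy(1.0, 60), 20.9, tolerance = 1e-12)
  expect_equal(alactic_energy(1.1, 49.8), 1.1 * 49.8 / 60 * 20.9,
               tolerance = 1e-12)  # ~19.08 kJ
  expect_equal(alactic_energy(0, 50), 0)
  expect_error(alactic_energy(-1, 50), ">= 0")
  expect_error(alactic_energy(1, 0), "> 0")
})

test_that("lactate accumulation is peak minus rest", {
  lac <- lactate_series(c(60, 180, 300), c(9.9, 9.1, 8.0), pre_exercise = 1.5)
  expect_equal(lactate_accumulation(lac), 8.4, tolerance = 1e-12)
  flat <- lactate_series(c(60, 180), c(1.5, 1.5), pre_exercise = 1.5)
  expect_equal(lactate_accumulation(flat), 0)
  expect_error(lactate_series(numeric(0), numeric(0), 1.5), "at least one")
})

test_that("lactic energy converts lactate to an O2 equivalent", {
  expect_equal(lactic_energy(1, 100), 0.3 * 20.9, tolerance = 1e-12)  # 6.27
  expect_equal(lactic_energy(8.4, 74.1), 8.4 * 3 * 74.1 / 1000 * 20.9,
               tolerance = 1e-12)  # ~39.03 kJ
  expect_equal(lactic_energy(0, 80), 0)
  expect_error(lactic_energy(-0.1, 80), ">= 0")
})

test_that("the alternative MAOD sums its components and guards convergence", {
  f <- fit_off_kinetics(fixture_series())
  lac <- lactate_series(c(60, 180, 300), c(9.9, 9.1, 8.0), pre_exercise = 1.5)
  est <- compute_maod_alt(f, lac, body_mass = 74.1)
  expect_equal(est$total_kj,
               est$components$alactic_kj + est$components$lactic_kj,
               tolerance = 1e-12)
  expect_equal(est$components$alactic_kj, alactic_energy(f$a1, f$tau1),
               tolerance = 1e-12)
  expect_equal(est$components$lactic_kj, lactic_energy(8.4, 74.1),
               tolerance = 1e-12)

  bad <- structure(list(a1 = 1, tau1 = 50, converged = FALSE),
                   class = "off_kinetics_fit")
  expect_error(compute_maod_alt(bad, lac, 74.1), "converge")
})

test_that("group means of totals equal sums of component group means", {
  # linearity of the mean: holds exactly for any per-participant table
  set.seed(4)
  al <- rnorm(9, 18.4, 2.7); la <- rnorm(9, 38.1, 7.1)
  expect_equal(mean(al + la), mean(al) + mean(la), tolerance = 1e-12)
})
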