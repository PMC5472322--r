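test_that("participant truths are deterministic, centred and validated", {
  expect_identical(make_participant(7), make_participant(7))

  bm <- vapply(1:300, function(i) make_participant(i)$body_mass, numeric(1))
  expect_lt(abs(mean(bm) - 74.1), 1.3)  # se of the mean ~0.4 kg

  vp <- vapply(1:300, function(i) make_participant(i)$vo2peak, numeric(1))
  expect_lt(abs(mean(vp) - 2.99), 0.08)

  expect_error(make_participant(1, overrides = list(ge_true = 1.5)), "ge_true")
  expect_error(make_participant(1, overrides = list(not_a_field = 1)),
               "not_a_field")

  tr <- make_participant(11)
  expect_true(tr$get_vo2 > 0 && tr$get_vo2 < tr$vo2peak)
  expect_true(tr$off_params[["tau2"]] > tr$off_params[["tau1"]])
  expect_true(tr$ge_true > 0 && tr$ge_true < 1)

  # overriding ge_true re-solves the demand slope so the warm-up GE matches
  tr2 <- make_participant(11, overrides = list(ge_true = 0.21))
  expect_equal(tr2$ge_true, 0.21)
  expect_true(abs(tr2$demand_slope - tr$demand_slope) > 0)
})

test_that("constant-load bouts hit the hyperbolic limit and the steady state", {
  tr <- make_participant(3, overrides = list(cp = 165, w_prime = 19300,
                                             noise_sd = 0))
  pla <- study_condition("placebo")
  caf <- study_condition("caffeine")

  trial <- simulate_constant_load(tr, pla, power = 231, to_exhaustion = TRUE)
  expect_equal(trial$time_to_exhaustion, 19300 / 66, tolerance = 1e-12)

  expect_error(simulate_constant_load(tr, pla, power = 150,
                                      to_exhaustion = TRUE),
               "no finite hyperbolic limit")

  # below GET, noiseless: terminal VO2 equals the linear demand
  p_sub <- round(0.8 * tr$get_power)
  sub <- simulate_constant_load(tr, pla, power = p_sub, max_duration = 600)
  d <- tr$demand_intercept + tr$demand_slope * p_sub
  expect_equal(utils::tail(sub$breaths$vo2, 1), d, tolerance = 1e-6)
  expect_true(is.na(sub$time_to_exhaustion))

  # caffeine (+CP) prolongs the Delta-80-like bout at the same power
  t_caf <- simulate_constant_load(tr, caf, power = 231,
                                  to_exhaustion = TRUE)$time_to_exhaustion
  expect_gt(t_caf, trial$time_to_exhaustion)
})

test_that("generated off-transients and lactate follow the stated model exactly", {
  tr <- make_participant(9, overrides = list(noise_sd = 0))
  pla <- study_condition("placebo")
  p120 <- round((1.2 * tr$vo2peak - tr$demand_intercept) / tr$demand_slope)
  trial <- simulate_constant_load(tr, pla, p120, to_exhaustion = TRUE,
                                  supramaximal = TRUE)
  op <- tr$off_params
  want <- eval_off_kinetics(trial$off_breaths$t, op[["vo2base"]], op[["a1"]],
                            op[["tau1"]], op[["a2"]], op[["tau2"]],
                            op[["delta"]])
  expect_equal(trial$off_breaths$vo2, want, tolerance = 1e-12)

  # lactate peak is affine in the generated anaerobic energy with the
  # truth slope, across different W' (hence different bout durations)
  pk <- function(wp) {
    t2 <- make_participant(9, overrides = list(noise_sd = 0, w_prime = wp))
    x <- simulate_constant_load(t2, pla, p120, to_exhaustion = TRUE,
                                supramaximal = TRUE)
    c(peak = max(x$lactate$samples$la) - t2$lactate_rest,
      kj = x$truth_energetics$anaerobic_kj)
  }
  a <- pk(15000); b <- pk(22000)
  expect_equal(a[["peak"]] / a[["kj"]], tr$lactate_per_kj, tolerance = 1e-9)
  expect_equal(b[["peak"]] / b[["kj"]], tr$lactate_per_kj, tolerance = 1e-9)
})

test_that("crossover studies cover 7 workloads x 2 conditions reproducibly", {
  s <- simulate_crossover_study(9, seed = 5)
  expect_length(s$trials, 9 * 7 * 2)
  expect_equal(nrow(s$index), 126)

  s2 <- simulate_crossover_study(9, seed = 5)
  expect_identical(s$index, s2$index)
  expect_identical(s$trials[[17]]$breaths, s2$trials[[17]]$breaths)

  # supramaximal protocol carries recovery and lactate; Delta-10 does not
  p120 <- study_trial(s, 1, "p120", "caffeine")
  d10 <- study_trial(s, 1, "d10", "caffeine")
  expect_false(is.null(p120$off_breaths))
  expect_false(is.null(p120$lactate))
  expect_null(d10$off_breaths)
  expect_null(d10$lactate)

  # exhaustion times satisfy the hyperbolic model exactly for every
  # supra-CP bout and condition
  for (k in which(!is.na(s$index$time_to_exhaustion))) {
    row <- s$index[k, ]
    tr <- s$truths[[row$participant]]
    cond <- s$conditions[[row$condition]]
    expect_equal(row$time_to_exhaustion *
                   (row$power - tr$cp - cond$cp_shift),
                 tr$w_prime + cond$w_prime_shift, tolerance = 1e-9)
  }
})

test_that("incremental tests ramp power linearly and plateau at VO2peak", {
  tr <- make_participant(3, overrides = list(noise_sd = 0))
  inc <- simulate_incremental(tr, start_power = 50, ramp = 25, seed = 2)
  expect_equal(inc$power, 50 + 25 * inc$t / 60, tolerance = 1e-9)
  expect_equal(mean_last_window(inc, 30), tr$vo2peak, tolerance = 0.01)
})
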