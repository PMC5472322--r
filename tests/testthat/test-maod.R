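test_that("demand line is exact OLS", {
  # collinear points recover the line exactly with R2 = 1
  pts <- data.frame(power = c(100, 150, 200, 250), vo2 = 0.5 + 0.01 * c(100, 150, 200, 250))
  line <- fit_demand_line(pts)
  expect_equal(line$slope, 0.01, tolerance = 1e-12)
  expect_equal(line$intercept, 0.5, tolerance = 1e-12)
  expect_equal(line$r2, 1, tolerance = 1e-12)

  # noisy points match the normal equations to 1e-10
  set.seed(20)
  pts2 <- data.frame(power = c(110, 140, 180, 210, 230))
  pts2$vo2 <- 0.45 + 0.011 * pts2$power + rnorm(5, 0, 0.08)
  line2 <- fit_demand_line(pts2)
  oracle <- ols_normal_equations(pts2$power, pts2$vo2)
  expect_equal(line2$slope, oracle[["slope"]], tolerance = 1e-10)
  expect_equal(line2$intercept, oracle[["intercept"]], tolerance = 1e-10)
  expect_true(line2$r2 >= 0 && line2$r2 <= 1)

  expect_error(fit_demand_line(data.frame(power = 100, vo2 = 1.5)), "2 distinct")
  expect_error(fit_demand_line(data.frame(power = c(100, 100),
                                          vo2 = c(1.5, 1.6))), "2 distinct")
})

test_that("supramaximal demand extrapolates the line over the bout", {
  line <- fit_demand_line(data.frame(power = c(100, 200),
                                     vo2 = 0.3 + 0.012 * c(100, 200)))
  expect_equal(supramaximal_demand(line, 300, 131), 3.9 * 131 / 60,
               tolerance = 1e-9)
  # 60-s duration makes the total numerically equal the demand rate
  expect_equal(supramaximal_demand(line, 300, 60), 3.9, tolerance = 1e-9)
  expect_error(supramaximal_demand(line, 300, 0), "> 0")
})

test_that("MAOD applies the store correction and energy equivalent", {
  est <- compute_maod(7.88, 4.38)
  expect_equal(est$total_kj, (7.88 - 4.38) * 0.9 * 20.9, tolerance = 1e-12)
  expect_equal(est$components$deficit_l, 3.5, tolerance = 1e-12)

  expect_equal(compute_maod(5, 5)$total_kj, 0)
  # correction 0, equivalent 1 returns the raw deficit
  expect_equal(compute_maod(6, 4, store_correction = 0,
                            energy_equiv = 1)$total_kj, 2)
  expect_error(compute_maod(4, 5), "negative deficit")

  # linear in the energy equivalent, affine in the store correction
  base <- compute_maod(7, 4, energy_equiv = 20.9)$total_kj
  expect_equal(compute_maod(7, 4, energy_equiv = 41.8)$total_kj, 2 * base,
               tolerance = 1e-12)
  c0 <- compute_maod(7, 4, store_correction = 0)$total_kj
  c5 <- compute_maod(7, 4, store_correction = 0.5)$total_kj
  cq <- compute_maod(7, 4, store_correction = 0.25)$total_kj
  expect_equal(cq, (c0 + c5) / 2, tolerance = 1e-12)
})

test_that("the MAOD matrix separates demand and criterion-bout conditions", {
  # identical submaximal VO2 in both conditions: CAF-CAF equals CAF-PLA
  mk <- function(cl) list(
    fake_trial("d10", cl, 120, 1.7), fake_trial("d20", cl, 140, 1.9),
    fake_trial("d40", cl, 170, 2.2), fake_trial("d50", cl, 185, 2.35),
    fake_trial("d80", cl, 230, 2.8, duration = 400, tte = 400),
    fake_trial("p120", cl, 300, 2.9, duration = 130, tte = 130))
  mm <- maod_matrix(c(mk("caffeine"), mk("placebo")))
  expect_equal(mm$estimates$caf_caf$total_kj, mm$estimates$caf_pla$total_kj,
               tolerance = 1e-9)
  expect_equal(mm$estimates$caf_caf$total_kj, mm$estimates$pla_pla$total_kj,
               tolerance = 1e-9)
  expect_equal(mm$isotime_d80, 400)

  missing <- c(mk("caffeine")[-3], mk("placebo"))
  expect_error(maod_matrix(missing), "d40/caffeine")
})

test_that("on generator trials the three variants differ only via the bout", {
  s <- simulate_crossover_study(2, seed = 21)
  keep <- s$index$pos[s$index$participant == 1]
  mm <- maod_matrix(s$trials[keep])
  # submaximal generation is condition-independent in distribution, so the
  # two demand lines are close; CAF-CAF and CAF-PLA share the criterion
  # bout and differ only via those lines
  e <- mm$estimates
  expect_lt(abs(e$caf_caf$total_kj - e$caf_pla$total_kj),
            0.2 * e$caf_caf$total_kj)
  expect_identical(e$caf_caf$condition, "caffeine")
  expect_identical(e$caf_pla$demand_condition, "placebo")
  expect_identical(e$pla_pla$condition, "placebo")
})

test_that("noiseless MAOD recovers the generator's corrected O2 deficit", {
  tr <- make_participant(5, overrides = list(noise_sd = 0, slow_amp = 0))
  conds <- list(caffeine = study_condition("caffeine"),
                placebo = study_condition("placebo"))
  fr <- c(d10 = 0.1, d20 = 0.2, d40 = 0.4, d50 = 0.5, d80 = 0.8)
  pw <- round(c(
    vapply(fr, function(f) (delta_target(tr$get_vo2, tr$vo2peak, f) -
                              tr$demand_intercept) / tr$demand_slope,
           numeric(1)),
    p120 = (1.2 * tr$vo2peak - tr$demand_intercept) / tr$demand_slope))
  trials <- list()
  for (cl in names(conds)) for (wl in names(pw)) {
    t <- simulate_constant_load(tr, conds[[cl]], pw[[wl]], 600,
                                to_exhaustion = wl %in% c("d80", "p120"),
                                seed = 33, supramaximal = (wl == "p120"))
    attr(t, "intensity") <- wl
    trials[[length(trials) + 1L]] <- t
  }
  mm <- maod_matrix(trials)
  p120 <- trials[[which(vapply(trials, function(x) attr(x, "intensity"),
                               character(1)) == "p120" &
                          vapply(trials, function(x) x$condition$label,
                                 character(1)) == "caffeine")]]
  want <- p120$truth_energetics$deficit_l * 0.9 * 20.9
  expect_lt(abs(mm$estimates$caf_caf$total_kj - want) / want, 0.02)
})
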