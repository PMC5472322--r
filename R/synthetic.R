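# Synthetic physiology generator.
#
# Produces breath-by-breath trials, exhaustion times and lactate samples
# from a known ground-truth physiology under a caffeine/placebo crossover,
# so every analysis stage can be checked by parameter recovery. The model:
# linear submaximal VO2-power demand plus a saturating slow component above
# the gas exchange threshold, first-order on-kinetics, biexponential
# off-kinetics, a hyperbolic power-duration relationship (CP, W') governing
# exhaustion, lactate accumulation proportional to anaerobic energy, and
# i.i.d. Gaussian breath noise on the gas channels.

# Fixed generator constants: VCO2/VO2 ratio below GET, the steeper VCO2 vs
# VO2 slope above it, and the ventilatory equivalent for VCO2.
.RER_SUB <- 0.88
.VSLOPE_SUPRA <- 1.35
.VE_PER_VCO2 <- 27

#' Generate a ground-truth participant physiology
#'
#' Draws one participant's true physiological parameters, centred on the
#' group means of a recreationally active male cohort (body mass
#' 74.1 ± 7.0 kg, VO2peak 2.99 ± 0.39 L·min⁻¹, GET near 52% VO2peak,
#' CP near 72% of the Δ80 power, W' near 19.3 kJ). Gross efficiency is
#' derived from the drawn demand line so that the truth fields are
#' mutually consistent: `ge_true` equals external power over metabolic
#' power at the 90% GET warm-up intensity with the generator's sub-GET
#' RER. CP is drawn as a fraction of the Δ80 power so that every
#' to-exhaustion workload lies strictly above CP for any seed.
#'
#' @param seed non-negative integer; draws are deterministic given `seed`.
#' @param overrides named list of truth fields to override after drawing.
#'   Overriding `ge_true` back-solves `demand_slope` so the stated
#'   efficiency is realised; other derived fields (`get_power`) are
#'   recomputed. Values violating an invariant are rejected with an error
#'   naming the field.
#' @return A list of class `participant_truth` with fields `body_mass`
#'   (kg), `vo2peak`, `get_vo2` (L·min⁻¹), `get_power` (W),
#'   `demand_slope` (L·min⁻¹·W⁻¹), `demand_intercept` (L·min⁻¹),
#'   `tau_on` (s), `slow_amp` (L·min⁻¹), `cp` (W), `w_prime` (J),
#'   `ge_true`, `off_params` (named: vo2base, a1, tau1, a2, tau2, delta),
#'   `lactate_rest` (mmol·L⁻¹), `lactate_per_kj` (mmol·L⁻¹·kJ⁻¹),
#'   `noise_sd` (L·min⁻¹), `breath_interval_mean` (s).
#' @examples
#' tr <- make_participant(7)
#' tr$vo2peak
#' @export
make_participant <- function(seed, overrides = list()) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != floor(seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  tr <- list(
    body_mass        = .rnorm_clamped(1, 74.1, 7.0, 50, 110),
    vo2peak          = .rnorm_clamped(1, 2.99, 0.39, 1.8, 4.5),
    demand_intercept = .rnorm_clamped(1, 0.50, 0.05, 0.30, 0.70),
    demand_slope     = .rnorm_clamped(1, 0.0103, 0.0006, 0.008, 0.013),
    tau_on           = .rnorm_clamped(1, 30, 4, 18, 45),
    slow_amp         = .rnorm_clamped(1, 0.25, 0.05, 0.05, 0.45),
    lactate_rest     = .rnorm_clamped(1, 1.4, 0.3, 0.5, 2.5),
    lactate_per_kj   = .rnorm_clamped(1, 0.133, 0.010, 0.09, 0.18),
    noise_sd         = 0.05,
    breath_interval_mean = 2
  )
  tr$get_vo2 <- .rnorm_clamped(1, 0.52, 0.03, 0.42, 0.62) * tr$vo2peak
  w_prime <- .rnorm_clamped(1, 19300, 3000, 9000, 30000)
  cp_frac <- .rnorm_clamped(1, 0.72, 0.06, 0.55, 0.80)
  tr$off_params <- c(
    vo2base = .rnorm_clamped(1, 0.50, 0.05, 0.30, 0.80),
    a1      = .rnorm_clamped(1, 1.05, 0.10, 0.60, 1.60),
    tau1    = .rnorm_clamped(1, 52, 8, 30, 90),
    a2      = .rnorm_clamped(1, 0.30, 0.05, 0.10, 0.60),
    tau2    = .rnorm_clamped(1, 400, 50, 200, 800),
    delta   = .rnorm_clamped(1, 5, 1, 1, 12)
  )
  tr$w_prime <- w_prime

  known <- c(names(tr), "get_power", "cp", "ge_true")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), known)
    if (length(bad))
      stop(sprintf("unknown ParticipantTruth field(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    for (nm in setdiff(names(overrides), c("ge_true", "cp", "get_power")))
      tr[[nm]] <- overrides[[nm]]
  }

  # ge_true override back-solves the demand slope. At the warm-up power
  # P_wu = 0.9·get_power, demand is intercept + 0.9·(get_vo2 - intercept),
  # independent of the slope, so the slope has a closed form.
  if ("ge_true" %in% names(overrides)) {
    ge <- overrides$ge_true
    if (is.numeric(ge) && length(ge) == 1L && ge > 0 && ge < 1) {
      d_wu <- tr$demand_intercept + 0.9 * (tr$get_vo2 - tr$demand_intercept)
      tr$demand_slope <- 0.9 * (tr$get_vo2 - tr$demand_intercept) /
        (ge * d_wu * .metp_coef(.RER_SUB))
    }
    tr$ge_true <- ge
  }

  # derived fields
  tr$get_power <- (tr$get_vo2 - tr$demand_intercept) / tr$demand_slope
  if ("get_power" %in% names(overrides)) tr$get_power <- overrides$get_power
  if (!("ge_true" %in% names(overrides))) {
    p_wu <- 0.9 * tr$get_power
    d_wu <- tr$demand_intercept + tr$demand_slope * p_wu
    tr$ge_true <- p_wu / (d_wu * .metp_coef(.RER_SUB))
  }
  if ("cp" %in% names(overrides)) {
    tr$cp <- overrides$cp
  } else {
    p80 <- (tr$get_vo2 + 0.8 * (tr$vo2peak - tr$get_vo2) - tr$demand_intercept) /
      tr$demand_slope
    # keep every to-exhaustion workload above CP even after a condition's
    # additive CP shift (+25 W) and 1-W power rounding
    tr$cp <- min(cp_frac * p80, p80 - 35)
    # Delta-80 sits in the severe domain: exhaustion there takes minutes,
    # so the hyperbolic limit at that power is kept above 150 s
    tr$w_prime <- max(tr$w_prime, 150 * (p80 - tr$cp))
  }

  .validate_truth(tr)
  structure(tr, class = "participant_truth")
}

# Invariant checks; errors name every offending field.
.validate_truth <- function(tr) {
  bad <- character(0)
  chk <- function(ok, nm, why) if (!isTRUE(ok)) bad <<- c(bad, sprintf("%s (%s)", nm, why))
  chk(tr$body_mass > 0, "body_mass", "must be > 0")
  chk(tr$vo2peak > 0, "vo2peak", "must be > 0")
  chk(tr$get_vo2 > 0 && tr$get_vo2 < tr$vo2peak, "get_vo2", "must be in (0, vo2peak)")
  chk(tr$demand_slope > 0, "demand_slope", "must be > 0")
  chk(tr$demand_intercept >= 0, "demand_intercept", "must be >= 0")
  chk(tr$get_power > 0, "get_power", "must be > 0")
  chk(tr$tau_on > 0, "tau_on", "must be > 0")
  chk(tr$slow_amp >= 0, "slow_amp", "must be >= 0")
  chk(tr$cp > 0, "cp", "must be > 0")
  chk(tr$w_prime > 0, "w_prime", "must be > 0")
  chk(is.numeric(tr$ge_true) && tr$ge_true > 0 && tr$ge_true < 1,
      "ge_true", "must be in (0, 1)")
  op <- tr$off_params
  chk(op[["tau1"]] > 0, "off_params.tau1", "must be > 0")
  chk(op[["tau2"]] > op[["tau1"]], "off_params.tau2", "must exceed tau1")
  chk(op[["a1"]] >= 0 && op[["a2"]] >= 0, "off_params.a1/a2", "must be >= 0")
  chk(op[["vo2base"]] >= 0, "off_params.vo2base", "must be >= 0")
  chk(op[["delta"]] >= 0, "off_params.delta", "must be >= 0")
  chk(tr$lactate_rest >= 0, "lactate_rest", "must be >= 0")
  chk(tr$lactate_per_kj >= 0, "lactate_per_kj", "must be >= 0")
  chk(tr$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(tr$breath_interval_mean > 0, "breath_interval_mean", "must be > 0")
  if (length(bad))
    stop(sprintf("invalid ParticipantTruth field(s): %s", paste(bad, collapse = "; ")),
         call. = FALSE)
  invisible(tr)
}

#' @export
print.participant_truth <- function(x, ...) {
  cat(sprintf(
    "participant_truth: %.1f kg, VO2peak %.2f L/min, GET %.2f L/min @ %.0f W, CP %.0f W, W' %.0f J, GE %.3f\n",
    x$body_mass, x$vo2peak, x$get_vo2, x$get_power, x$cp, x$w_prime, x$ge_true))
  invisible(x)
}

#' Define a study condition
#'
#' A crossover arm. The condition acts on the physiology only through
#' additive shifts of CP and W' (the submaximal VO2 response is
#' condition-independent, matching a crossover in which the treatment
#' affected the power-duration parameters but not submaximal VO2).
#'
#' @param label `"caffeine"` or `"placebo"`.
#' @param cp_shift additive CP shift in W (default +25 for caffeine, 0
#'   for placebo).
#' @param w_prime_shift additive W' shift in J (default -3000 for
#'   caffeine, 0 for placebo).
#' @return A list of class `study_condition`.
#' @export
study_condition <- function(label = c("placebo", "caffeine"),
                            cp_shift = if (label == "caffeine") 25 else 0,
                            w_prime_shift = if (label == "caffeine") -3000 else 0) {
  label <- match.arg(label)
  structure(list(label = label, cp_shift = cp_shift,
                 w_prime_shift = w_prime_shift),
            class = "study_condition")
}

# demand (L·min⁻¹) at time t for a constant-load bout: linear demand plus
# a slow component ramping linearly to slow_amp over 180 s, applied only
# above the GET power.
.demand_constant <- function(truth, power, t) {
  d <- truth$demand_intercept + truth$demand_slope * power
  if (power > truth$get_power)
    d <- d + truth$slow_amp * pmin(t, 180) / 180
  rep_len(d, length(t))
}

# Jittered breath timestamps over [0, t_end].
.breath_times <- function(t_end, truth) {
  n_max <- ceiling(t_end / max(truth$breath_interval_mean - 0.5, 0.1)) + 2L
  gaps <- stats::runif(n_max, truth$breath_interval_mean - 0.5,
                       truth$breath_interval_mean + 0.5)
  bt <- cumsum(c(0, gaps))
  bt[bt <= t_end]
}

# Turn noiseless 1-Hz model channels into jittered, noisy breaths.
.model_to_breaths <- function(tt, vo2_m, vco2_m, power, truth) {
  bt <- .breath_times(utils::tail(tt, 1) - tt[1], truth) + tt[1]
  vo2 <- stats::approx(tt, vo2_m, xout = bt)$y
  vco2 <- stats::approx(tt, vco2_m, xout = bt)$y
  if (truth$noise_sd > 0) {
    vo2 <- vo2 + stats::rnorm(length(bt), 0, truth$noise_sd)
    vco2 <- vco2 + stats::rnorm(length(bt), 0, truth$noise_sd)
  }
  vo2 <- pmax(vo2, 0); vco2 <- pmax(vco2, 0)
  ve <- .VE_PER_VCO2 * vco2
  pw <- if (length(power) == 1L) rep(power, length(bt)) else
    stats::approx(tt, power, xout = bt)$y
  breath_series(t = bt, vo2 = vo2, vco2 = vco2, ve = ve, power = pw)
}

# VCO2 as a piecewise-linear function of VO2: slope .RER_SUB below the GET
# VO2, steeper slope above it (the v-slope breakpoint).
.vco2_of_vo2 <- function(vo2, get_vo2) {
  ifelse(vo2 <= get_vo2, .RER_SUB * vo2,
         .RER_SUB * get_vo2 + .VSLOPE_SUPRA * (vo2 - get_vo2))
}

#' Simulate an incremental (ramp) test
#'
#' Power rises linearly from `start_power` at `ramp` W·min⁻¹. VO2 tracks
#' the linear demand of the instantaneous power through first-order
#' kinetics with time constant `tau_on`, capped at `vo2peak`; VCO2 rises
#' disproportionately above the GET VO2. The test ends `dwell` seconds
#' after the demand first reaches `vo2peak`, emulating the terminal
#' plateau before volitional exhaustion.
#'
#' @param truth a [make_participant()] truth.
#' @param start_power starting power in W (default 50).
#' @param ramp ramp rate in W·min⁻¹ (default 25), must be > 0.
#' @param seed integer RNG seed for breath jitter and noise.
#' @param dwell seconds of capped-VO2 plateau before termination
#'   (default 180).
#' @return A [breath_series()] with a `power` channel `start + ramp·t/60`.
#' @export
simulate_incremental <- function(truth, start_power = 50, ramp = 25, seed = 1,
                                 dwell = 180) {
  stopifnot(inherits(truth, "participant_truth"))
  if (!is.numeric(ramp) || ramp <= 0) stop("ramp must be > 0", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  p_cap <- (truth$vo2peak - truth$demand_intercept) / truth$demand_slope
  t_cap <- max(0, 60 * (p_cap - start_power) / ramp)
  t_end <- t_cap + dwell
  tt <- seq(0, t_end, by = 1)
  pw <- start_power + ramp * tt / 60
  target <- pmin(truth$demand_intercept + truth$demand_slope * pw, truth$vo2peak)
  v <- numeric(length(tt))
  v[1] <- min(truth$demand_intercept + truth$demand_slope * start_power,
              truth$vo2peak)
  decay <- exp(-1 / truth$tau_on)
  for (k in seq_along(tt)[-1]) v[k] <- target[k] + (v[k - 1] - target[k]) * decay
  vco2_m <- .vco2_of_vo2(v, truth$get_vo2)
  .model_to_breaths(tt, v, vco2_m, pw, truth)
}

#' Simulate a constant-load trial
#'
#' Demand is `demand_intercept + demand_slope·power`, plus the slow
#' component above the GET power; VO2 follows
#' `min(demand(t), vo2peak)·(1 - exp(-t/tau_on))` plus breath noise. When
#' `to_exhaustion = TRUE` and the condition-shifted power exceeds CP, the
#' bout ends at the hyperbolic limit
#' `t_lim = (w_prime + w_prime_shift)/(power - (cp + cp_shift))`. For the
#' supramaximal protocol the 10-min recovery off-transient is generated
#' exactly from the truth's biexponential off-kinetics parameters, and
#' post-exercise lactate peaks at
#' `lactate_rest + lactate_per_kj × anaerobic energy (kJ)`.
#'
#' @param truth a [make_participant()] truth.
#' @param condition a [study_condition()].
#' @param power external power in W, > 0.
#' @param max_duration bout duration in s when not to exhaustion
#'   (default 600).
#' @param to_exhaustion if `TRUE`, end at the hyperbolic time limit.
#' @param seed integer RNG seed for this trial's stream.
#' @param supramaximal if `TRUE`, also generate the recovery
#'   off-transient and lactate samples (the MAOD_ALT protocol).
#' @return A list of class `simulated_trial`: `breaths`,
#'   `time_to_exhaustion` (s or `NA`), `off_breaths`, `lactate`, `truth`,
#'   `condition`, `power`, and `truth_energetics` (the generator-side
#'   O2 deficit in L, anaerobic energy in kJ, and the mechanical
#'   anaerobic-work analogue in kJ).
#' @export
simulate_constant_load <- function(truth, condition, power, max_duration = 600,
                                   to_exhaustion = FALSE, seed = 1,
                                   supramaximal = FALSE) {
  stopifnot(inherits(truth, "participant_truth"),
            inherits(condition, "study_condition"))
  if (!is.numeric(power) || power <= 0) stop("power must be > 0", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  tte <- NA_real_
  if (to_exhaustion) {
    cp_eff <- truth$cp + condition$cp_shift
    w_eff <- truth$w_prime + condition$w_prime_shift
    if (power <= cp_eff)
      stop(sprintf("power %.0f W <= effective CP %.0f W: no finite hyperbolic limit",
                   power, cp_eff), call. = FALSE)
    tte <- w_eff / (power - cp_eff)
    t_end <- tte
  } else {
    t_end <- max_duration
  }
  tt <- seq(0, t_end, by = 1)
  if (utils::tail(tt, 1) < t_end - 1e-9) tt <- c(tt, t_end)
  d_tot <- .demand_constant(truth, power, tt)
  vo2_m <- pmin(d_tot, truth$vo2peak) * (1 - exp(-tt / truth$tau_on))
  vco2_m <- .vco2_of_vo2(vo2_m, truth$get_vo2)
  breaths <- .model_to_breaths(tt, vo2_m, vco2_m, power, truth)

  # generator-side (noiseless) energetics for this bout
  deficit_l <- pracma::trapz(tt, d_tot - vo2_m) / 60
  anaerobic_kj <- deficit_l * 20.9
  mech_kj <- pracma::trapz(tt, power - truth$ge_true * vo2_m * .metp_coef(1.0)) / 1000

  off_breaths <- NULL
  lactate <- NULL
  if (supramaximal) {
    # the off-transient is the truth's biexponential evaluated exactly at
    # the breath times (no grid interpolation), plus breath noise
    ot <- .breath_times(600, truth)
    op <- truth$off_params
    off_m <- eval_off_kinetics(ot, op[["vo2base"]], op[["a1"]], op[["tau1"]],
                               op[["a2"]], op[["tau2"]], op[["delta"]])
    off_vco2 <- .RER_SUB * off_m
    if (truth$noise_sd > 0) {
      off_m <- pmax(off_m + stats::rnorm(length(ot), 0, truth$noise_sd), 0)
      off_vco2 <- pmax(off_vco2 + stats::rnorm(length(ot), 0, truth$noise_sd), 0)
    }
    off_breaths <- breath_series(t = ot, vo2 = off_m, vco2 = off_vco2,
                                 ve = .VE_PER_VCO2 * off_vco2,
                                 power = rep(0, length(ot)))
    la_peak <- truth$lactate_rest + truth$lactate_per_kj * anaerobic_kj
    la <- truth$lactate_rest + (la_peak - truth$lactate_rest) * c(1.0, 0.90, 0.78)
    lactate <- lactate_series(t = c(60, 180, 300), la = la,
                              pre_exercise = truth$lactate_rest)
  }
  structure(list(breaths = breaths, time_to_exhaustion = tte,
                 off_breaths = off_breaths, lactate = lactate, truth = truth,
                 condition = condition, power = power,
                 truth_energetics = list(deficit_l = deficit_l,
                                         anaerobic_kj = anaerobic_kj,
                                         mech_anaerobic_kj = mech_kj)),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("simulated_trial: %s @ %.0f W, %s%s\n", x$condition$label, x$power,
              if (is.na(x$time_to_exhaustion)) sprintf("%.0f s fixed", max(x$breaths$t))
              else sprintf("exhaustion at %.1f s", x$time_to_exhaustion),
              if (!is.null(x$off_breaths)) " (+recovery, +lactate)" else ""))
  invisible(x)
}

#' Simulate a two-condition crossover study
#'
#' For each participant, all seven workloads are generated under both
#' conditions: Delta-10/20/40/50 as fixed 10-min bouts, and Delta-80,
#' 100% and 120% VO2peak to exhaustion; the 120% bout carries the
#' recovery off-transient and lactate samples. A 5-min warm-up at 90%
#' GET power is generated per participant and condition for the gross
#' efficiency method. One master seed fans out to per-trial streams by
#' (participant, workload, condition), so the study is reproducible and
#' trials are independent.
#'
#' @param n_participants number of participants, >= 2.
#' @param seed master integer seed.
#' @param caffeine,placebo the two [study_condition()] arms.
#' @return A list of class `crossover_study`: `truths` (per participant),
#'   `trials` (flat list of [simulate_constant_load()] results, each with
#'   attributes `participant` and `intensity`), `warmups` (nested list
#'   `[[participant]][[condition]]`), and `index` (data.frame of
#'   participant, condition, intensity, power, time-to-exhaustion and
#'   position in `trials`).
#' @export
simulate_crossover_study <- function(n_participants, seed = 1,
                                     caffeine = study_condition("caffeine"),
                                     placebo = study_condition("placebo")) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop("need at least 2 participants", call. = FALSE)
  n <- as.integer(n_participants)
  fracs <- c(d10 = 0.1, d20 = 0.2, d40 = 0.4, d50 = 0.5, d80 = 0.8)
  conds <- list(caffeine = caffeine, placebo = placebo)
  truths <- vector("list", n)
  trials <- list()
  warmups <- vector("list", n)
  idx <- list()
  for (i in seq_len(n)) {
    truths[[i]] <- make_participant(.stream_seed(seed, i, "truth"))
    tr <- truths[[i]]
    powers <- c(
      vapply(fracs, function(f)
        (delta_target(tr$get_vo2, tr$vo2peak, f) - tr$demand_intercept) /
          tr$demand_slope, numeric(1)),
      p100 = (tr$vo2peak - tr$demand_intercept) / tr$demand_slope,
      p120 = (1.2 * tr$vo2peak - tr$demand_intercept) / tr$demand_slope)
    powers <- round(powers)
    warmups[[i]] <- list()
    for (cl in names(conds)) {
      for (wl in names(powers)) {
        exh <- wl %in% c("d80", "p100", "p120")
        trial <- simulate_constant_load(
          tr, conds[[cl]], power = powers[[wl]],
          max_duration = 600, to_exhaustion = exh,
          seed = .stream_seed(seed, i, wl, cl),
          supramaximal = (wl == "p120"))
        attr(trial, "participant") <- i
        attr(trial, "intensity") <- wl
        trials[[length(trials) + 1L]] <- trial
        idx[[length(idx) + 1L]] <- data.frame(
          participant = i, condition = cl, intensity = wl,
          power = powers[[wl]], time_to_exhaustion = trial$time_to_exhaustion,
          pos = length(trials))
      }
      warmups[[i]][[cl]] <- simulate_constant_load(
        tr, conds[[cl]], power = round(0.9 * tr$get_power),
        max_duration = 300, to_exhaustion = FALSE,
        seed = .stream_seed(seed, i, "warmup", cl))
    }
  }
  structure(list(truths = truths, trials = trials, warmups = warmups,
                 index = do.call(rbind, idx), conditions = conds),
            class = "crossover_study")
}

#' @export
print.crossover_study <- function(x, ...) {
  cat(sprintf("crossover_study: %d participants, %d trials (+%d warm-ups)\n",
              length(x$truths), length(x$trials), 2L * length(x$truths)))
  invisible(x)
}

#' Extract one trial from a crossover study
#'
#' @param study a [simulate_crossover_study()] result.
#' @param participant participant number.
#' @param intensity one of `"d10"`, `"d20"`, `"d40"`, `"d50"`, `"d80"`,
#'   `"p100"`, `"p120"`.
#' @param condition `"caffeine"` or `"placebo"`.
#' @return The matching `simulated_trial`.
#' @export
study_trial <- function(study, participant, intensity, condition) {
  stopifnot(inherits(study, "crossover_study"))
  m <- study$index
  pos <- m$pos[m$participant == participant & m$intensity == intensity &
                 m$condition == condition]
  if (length(pos) != 1L)
    stop(sprintf("no trial for participant %s, %s, %s",
                 participant, intensity, condition), call. = FALSE)
  study$trials[[pos]]
}

#' Write a participant truth as a JSON sidecar
#'
#' @param truth a [make_participant()] truth.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "participant_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
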