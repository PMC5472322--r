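# Alternative MAOD: biexponential VO2 off-kinetics (EPOC), the alactic
# component A1·tau1, and the lactic component from blood lactate
# accumulation at 3 mL O2 per kg body mass per mmol·L⁻¹.

#' Evaluate the biexponential off-kinetics model
#'
#' `VO2(t) = vo2base + a1·exp(-(t - delta)/tau1) + a2·exp(-(t - delta)/tau2)`
#' for `t >= delta`, with a shared time delay `delta`; components 1 and 2
#' are the fast (EPOC fast) and slow terms. Before the delay the curve
#' holds its onset value `vo2base + a1 + a2` (the delayed-onset
#' convention: without it the delay merely rescales the amplitudes by
#' `exp(delta/tau)` and is not identifiable).
#'
#' @param t time since exercise end, s.
#' @param vo2base baseline VO2 at the end of recovery, L·min⁻¹.
#' @param a1,a2 fast/slow amplitudes, L·min⁻¹.
#' @param tau1,tau2 fast/slow time constants, s, `tau1 < tau2`.
#' @param delta shared time delay, s.
#' @return VO2 at `t` in L·min⁻¹.
#' @export
eval_off_kinetics <- function(t, vo2base, a1, tau1, a2, tau2, delta = 0) {
  td <- pmax(t - delta, 0)
  vo2base + a1 * exp(-td / tau1) + a2 * exp(-td / tau2)
}

#' Fit biexponential off-kinetics to a recovery series
#'
#' Bounded Levenberg-Marquardt nonlinear least squares on the 1-Hz
#' resampled off-transient. Identifiability of the two components is
#' enforced by the bounds `tau1` in [10, 120] s and `tau2` in
#' [120, 1200] s; `delta` in [0, 30] s is shared between the terms, and
#' amplitudes lie in [0, 5] L·min⁻¹. Initial guesses: `vo2base` = mean of
#' the last 60 s, `a1` = first-sample VO2 minus that baseline,
#' `tau1` = 40 s, `a2 = a1/4`, `tau2` = 400 s, `delta` = 5 s.
#'
#' @param off_series recovery [breath_series()] with t = 0 at exercise
#'   end, spanning at least 300 s.
#' @param per_component_delay if `TRUE`, fit independent delays for the
#'   fast and slow terms (non-default variant).
#' @return A list of class `off_kinetics_fit`: `vo2base`, `a1`, `tau1`,
#'   `a2`, `tau2`, `delta` (and `delta2` for the two-delay variant),
#'   `rss`, `converged`, `n`.
#' @export
fit_off_kinetics <- function(off_series, per_component_delay = FALSE) {
  stopifnot(inherits(off_series, "breath_series"))
  if (off_series$t[nrow(off_series)] - off_series$t[1] < 300)
    stop("off-transient must span at least 300 s", call. = FALSE)
  rs <- resample_uniform(off_series, 1)
  df <- data.frame(t = rs$t, vo2 = rs$vo2)
  base0 <- mean(df$vo2[df$t >= max(df$t) - 60])
  a10 <- max(df$vo2[1] - base0, 0.2)
  start <- list(vo2base = max(base0, 0.01), a1 = min(a10, 5), tau1 = 40,
                a2 = min(max(a10 / 4, 0.01), 5), tau2 = 400, delta = 5)
  lower <- c(vo2base = 0, a1 = 0, tau1 = 10, a2 = 0, tau2 = 120, delta = 0)
  upper <- c(vo2base = 5, a1 = 5, tau1 = 120, a2 = 5, tau2 = 1200, delta = 30)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-12)
  if (per_component_delay) {
    form <- vo2 ~ vo2base + a1 * exp(-pmax(t - delta, 0) / tau1) +
      a2 * exp(-pmax(t - delta2, 0) / tau2)
    start$delta2 <- 5
    lower <- c(lower, delta2 = 0); upper <- c(upper, delta2 = 30)
  } else {
    form <- vo2 ~ vo2base + a1 * exp(-pmax(t - delta, 0) / tau1) +
      a2 * exp(-pmax(t - delta, 0) / tau2)
  }
  # retry from perturbed starts if the initial gradient is singular
  fit <- NULL
  for (k in 0:4) {
    st <- start
    if (k > 0) {
      st$tau1 <- min(max(start$tau1 * (1 + 0.3 * k * c(1, -1)[k %% 2 + 1]), 12), 110)
      st$a2 <- min(start$a2 * (1 + 0.5 * k), 5)
      st$tau2 <- min(max(start$tau2 + 80 * k, 130), 1100)
      st$delta <- min(start$delta + k, 25)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st, lower = lower,
                        upper = upper, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- c(start, list(rss = NA_real_, converged = FALSE, n = nrow(df)))
    return(structure(out, class = "off_kinetics_fit"))
  }
  cf <- as.list(stats::coef(fit))
  out <- c(cf, list(rss = sum(stats::resid(fit)^2),
                    converged = isTRUE(fit$convInfo$isConv), n = nrow(df)))
  structure(out, class = "off_kinetics_fit")
}

#' @export
print.off_kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "off-kinetics fit%s: vo2base %.3f, A1 %.3f L/min, tau1 %.1f s, A2 %.3f, tau2 %.0f s, delta %.1f s (rss %.4g)\n",
    if (!x$converged) " [NOT converged]" else "",
    x$vo2base, x$a1, x$tau1, x$a2, x$tau2, x$delta, x$rss))
  invisible(x)
}

#' Alactic energy from the EPOC fast component
#'
#' The alactic (phosphagen) component is the fast-component O2 volume
#' `A1·tau1` (amplitude in L·min⁻¹ times seconds gives `A1·tau1/60`
#' litres), converted at `energy_equiv` kJ per litre.
#'
#' @param a1 fast amplitude, L·min⁻¹, >= 0.
#' @param tau1 fast time constant, s, > 0.
#' @param energy_equiv kJ·L⁻¹ O2 (default 20.9).
#' @return Alactic energy in kJ.
#' @examples
#' alactic_energy(1.0, 60)  # 1 L O2 -> 20.9 kJ
#' @export
alactic_energy <- function(a1, tau1, energy_equiv = 20.9) {
  if (!is.numeric(a1) || a1 < 0) stop("a1 must be >= 0", call. = FALSE)
  if (!is.numeric(tau1) || tau1 <= 0) stop("tau1 must be > 0", call. = FALSE)
  a1 * (tau1 / 60) * energy_equiv
}

#' Blood lactate accumulation
#'
#' Difference between the highest post-exercise plasma lactate and the
#' pre-exercise (resting) concentration.
#'
#' @param lactate a [lactate_series()].
#' @return Delta-lactate in mmol·L⁻¹.
#' @export
lactate_accumulation <- function(lactate) {
  stopifnot(inherits(lactate, "lactate_series"))
  if (nrow(lactate$samples) < 1L) stop("no post-exercise samples", call. = FALSE)
  max(lactate$samples$la) - lactate$pre_exercise
}

#' Lactic energy from lactate accumulation
#'
#' Each mmol·L⁻¹ of lactate accumulation is equivalent to
#' `o2_per_mm` mL O2 per kg body mass (default 3), converted at
#' `energy_equiv` kJ per litre O2.
#'
#' @param delta_la lactate accumulation, mmol·L⁻¹, >= 0.
#' @param body_mass kg, > 0.
#' @param o2_per_mm mL O2 per kg per mmol·L⁻¹ (default 3).
#' @param energy_equiv kJ·L⁻¹ O2 (default 20.9).
#' @return Lactic energy in kJ.
#' @export
lactic_energy <- function(delta_la, body_mass, o2_per_mm = 3, energy_equiv = 20.9) {
  if (!is.numeric(delta_la) || delta_la < 0)
    stop("delta_la must be >= 0 (peak below rest?)", call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be > 0", call. = FALSE)
  delta_la * o2_per_mm * body_mass / 1000 * energy_equiv
}

#' Alternative MAOD (EPOC fast component + lactate O2 equivalent)
#'
#' Sums the alactic component (`A1·tau1` from the converged off-kinetics
#' fit) and the lactic component (lactate-accumulation O2 equivalent).
#' The slow EPOC term (A2, tau2) is estimated but carries no energy.
#'
#' @param fit a converged [fit_off_kinetics()] result.
#' @param lactate a [lactate_series()].
#' @param body_mass kg.
#' @param energy_equiv kJ·L⁻¹ O2 (default 20.9).
#' @param condition label recorded on the estimate.
#' @return An [energy_estimate()] with method `"MAOD_ALT"` and components
#'   `alactic_kj`, `lactic_kj`.
#' @export
compute_maod_alt <- function(fit, lactate, body_mass, energy_equiv = 20.9,
                             condition = NA_character_) {
  stopifnot(inherits(fit, "off_kinetics_fit"))
  if (!isTRUE(fit$converged))
    stop("off-kinetics fit did not converge", call. = FALSE)
  al <- alactic_energy(fit$a1, fit$tau1, energy_equiv)
  la <- lactic_energy(lactate_accumulation(lactate), body_mass,
                      energy_equiv = energy_equiv)
  energy_estimate("MAOD_ALT", total_kj = al + la,
                  components = list(alactic_kj = al, lactic_kj = la),
                  condition = condition)
}
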