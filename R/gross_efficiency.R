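# Gross efficiency method: metabolic power from VO2 and RER, gross
# efficiency from the warm-up, and the supramaximal anaerobic work
# integral.

#' Metabolic power from VO2 and RER
#'
#' `MetP (W) = VO2 (L·min⁻¹) × (4940·RER + 16040)/60`.
#'
#' @param vo2 oxygen uptake, L·min⁻¹, >= 0 (vectorised).
#' @param rer respiratory exchange ratio (VCO2/VO2), inside
#'   `rer_guard`.
#' @param rer_guard physiological bounds for RER (default `c(0.6, 1.3)`).
#' @return Metabolic power in W.
#' @examples
#' metabolic_power(1, 1)  # 349.667 W
#' @export
metabolic_power <- function(vo2, rer, rer_guard = c(0.6, 1.3)) {
  if (any(vo2 < 0)) stop("vo2 must be >= 0", call. = FALSE)
  if (any(rer < rer_guard[1]) || any(rer > rer_guard[2]))
    stop(sprintf("RER outside physiological guard [%.2f, %.2f]",
                 rer_guard[1], rer_guard[2]), call. = FALSE)
  vo2 * .metp_coef(rer)
}

#' Gross efficiency from the warm-up bout
#'
#' GE is external power divided by metabolic power, with VO2 and RER
#' taken as last-30-s averages of the warm-up (performed at an intensity
#' below the GET, typically 90% GET, so that RER < 1.00). When the mean
#' RER is >= 1.00 the estimate is returned with `rer_valid = FALSE` and a
#' warning; downstream anaerobic-work computation refuses such an
#' estimate unless forced.
#'
#' @param warmup warm-up [breath_series()] of at least 30 s.
#' @param external_power external power during the warm-up, W, > 0.
#' @return A list of class `efficiency_estimate`: `ge`, `warmup_vo2`,
#'   `warmup_rer`, `warmup_power`, `rer_valid`.
#' @export
gross_efficiency_from_warmup <- function(warmup, external_power) {
  stopifnot(inherits(warmup, "breath_series"))
  if (!is.numeric(external_power) || external_power <= 0)
    stop("external_power must be > 0", call. = FALSE)
  vo2 <- mean_last_window(warmup, 30, "vo2")
  vco2 <- mean_last_window(warmup, 30, "vco2")
  rer <- vco2 / vo2
  rer_valid <- rer < 1.00
  if (!rer_valid)
    warning(sprintf("warm-up RER %.2f >= 1.00: gross efficiency unreliable", rer),
            call. = FALSE)
  ge <- external_power / metabolic_power(vo2, rer)
  if (rer_valid && !(ge > 0 && ge < 1))
    stop(sprintf("implausible gross efficiency %.3f", ge), call. = FALSE)
  structure(list(ge = ge, warmup_vo2 = vo2, warmup_rer = rer,
                 warmup_power = external_power, rer_valid = rer_valid),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("gross efficiency %.3f (warm-up %.0f W, VO2 %.2f L/min, RER %.2f%s)\n",
              x$ge, x$warmup_power, x$warmup_vo2, x$warmup_rer,
              if (!x$rer_valid) ", RER INVALID" else ""))
  invisible(x)
}

#' Anaerobic work over a supramaximal bout (gross-efficiency method)
#'
#' Metabolic power during the supramaximal bout is estimated from VO2(t)
#' assuming RER = 1.00; the aerobic mechanical power is `GE × MetP(t)`
#' (GE assumed stable above the GET), and the anaerobic mechanical power
#' is the external power minus the aerobic part, integrated over the bout
#' from t = 0. Negative instantaneous anaerobic power late in the bout is
#' integrated as-is (clamping would bias the total upward).
#'
#' @param supra supramaximal [breath_series()] covering the full bout.
#' @param external_power external power, W.
#' @param ge an [gross_efficiency_from_warmup()] estimate or a plain
#'   number in (0, 1).
#' @param rer_supra RER assumed during the supramaximal bout
#'   (default 1.00).
#' @param force compute even when the GE estimate has
#'   `rer_valid = FALSE`.
#' @return An [energy_estimate()] with method `"GE_WORK"` and components
#'   `aerobic_kj`, `anaerobic_kj` (total = anaerobic work).
#' @param condition label recorded on the estimate.
#' @export
anaerobic_work <- function(supra, external_power, ge, rer_supra = 1.00,
                           force = FALSE, condition = NA_character_) {
  stopifnot(inherits(supra, "breath_series"))
  if (inherits(ge, "efficiency_estimate")) {
    if (!ge$rer_valid && !force)
      stop("gross efficiency estimate has rer_valid = FALSE; use force = TRUE to override",
           call. = FALSE)
    ge <- ge$ge
  }
  if (!is.numeric(ge) || ge <= 0 || ge >= 1)
    stop("ge must be in (0, 1)", call. = FALSE)
  rs <- resample_uniform(supra, 1)
  aero_w <- ge * metabolic_power(rs$vo2, rer_supra)
  an_w <- external_power - aero_w
  an_kj <- pracma::trapz(rs$t, an_w) / 1000
  aero_kj <- pracma::trapz(rs$t, aero_w) / 1000
  energy_estimate("GE_WORK", total_kj = an_kj,
                  components = list(anaerobic_kj_integral = an_kj,
                                    aerobic_kj_integral = aero_kj,
                                    ge = ge),
                  condition = condition)
}
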