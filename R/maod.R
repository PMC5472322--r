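# Traditional maximal accumulated oxygen deficit (MAOD): submaximal
# VO2-power regression, supramaximal demand extrapolation, accumulated-VO2
# subtraction, 10% body-store correction and energy conversion.

#' Construct an energy estimate
#'
#' Container for one anaerobic-capacity value in kJ with its method tag
#' and component breakdown.
#'
#' @param method one of `"MAOD"`, `"MAOD_ALT"`, `"CP_WPRIME"`, `"GE_WORK"`.
#' @param total_kj total energy in kJ.
#' @param components named list of component energies/quantities.
#' @param condition condition of the criterion (supramaximal) bout.
#' @param demand_condition condition of the submaximal demand estimation,
#'   or `"n/a"` for methods without one.
#' @return A list of class `energy_estimate`.
#' @export
energy_estimate <- function(method = c("MAOD", "MAOD_ALT", "CP_WPRIME", "GE_WORK"),
                            total_kj, components = list(),
                            condition = NA_character_,
                            demand_condition = "n/a") {
  method <- match.arg(method)
  kj <- names(components)[endsWith(names(components), "_kj")]
  if (length(kj) >= 2L) {
    s <- sum(unlist(components[kj]))
    if (abs(s - total_kj) > 1e-6 * max(1, abs(total_kj)))
      stop("total_kj must equal the sum of its _kj components", call. = FALSE)
  }
  structure(list(method = method, total_kj = total_kj, components = components,
                 condition = condition, demand_condition = demand_condition),
            class = "energy_estimate")
}

#' @export
print.energy_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f kJ (%s%s)\n", x$method, x$total_kj, x$condition,
              if (!identical(x$demand_condition, "n/a"))
                paste0(", demand: ", x$demand_condition) else ""))
  if (length(x$components))
    cat("  components:",
        paste(sprintf("%s=%.3f", names(x$components), unlist(x$components)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Fit the submaximal VO2-power demand line
#'
#' Ordinary least squares of end-bout VO2 on power across the submaximal
#' trials. Points are equally weighted. The Delta-80 point must already be
#' the isotime VO2 (caller contract; see [maod_matrix()]).
#'
#' @param points data.frame with columns `power` (W) and `vo2`
#'   (L·min⁻¹), at least two distinct powers.
#' @param condition_of_submax condition label under which the submaximal
#'   bouts were performed.
#' @return A list of class `demand_line`: `slope`, `intercept`, `r2`,
#'   `n_points`, `condition_of_submax`.
#' @export
fit_demand_line <- function(points, condition_of_submax = NA_character_) {
  if (!is.data.frame(points) || !all(c("power", "vo2") %in% names(points)))
    stop("points must be a data.frame with columns power, vo2", call. = FALSE)
  if (nrow(points) < 2L || length(unique(points$power)) < 2L)
    stop("need at least 2 distinct powers", call. = FALSE)
  fit <- stats::lm(vo2 ~ power, data = points)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((points$vo2 - mean(points$vo2))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_points = nrow(points),
                 condition_of_submax = condition_of_submax),
            class = "demand_line")
}

#' @export
print.demand_line <- function(x, ...) {
  cat(sprintf("demand_line (%s): VO2 = %.4f + %.5f x power, R2 = %.3f, n = %d\n",
              x$condition_of_submax, x$intercept, x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Total supramaximal oxygen demand by linear extrapolation
#'
#' Extrapolates the submaximal demand line to the supramaximal power and
#' multiplies by the bout duration: `(slope·power + intercept)·duration/60`
#' litres of oxygen.
#'
#' @param line a [fit_demand_line()] result.
#' @param power supramaximal power in W (above the fitted range).
#' @param duration bout duration (time to exhaustion) in s, > 0.
#' @return Estimated total O2 demand in litres.
#' @export
supramaximal_demand <- function(line, power, duration) {
  stopifnot(inherits(line, "demand_line"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  (line$slope * power + line$intercept) * duration / 60
}

#' Maximal accumulated oxygen deficit
#'
#' `MAOD (kJ) = (demand - accumulated) × (1 - store_correction) ×
#' energy_equiv`: the O2 deficit is reduced by 10% for the contribution
#' of body oxygen stores and converted at 20.9 kJ per litre O2.
#'
#' @param total_demand estimated total O2 demand in L.
#' @param accumulated measured accumulated VO2 in L,
#'   `0 <= accumulated <= total_demand`.
#' @param store_correction fraction of the deficit attributed to body O2
#'   stores (default 0.10).
#' @param energy_equiv energy equivalent in kJ·L⁻¹ O2 (default 20.9).
#' @param condition,demand_condition labels recorded on the estimate.
#' @return An [energy_estimate()] with method `"MAOD"` and component
#'   `deficit_l` (uncorrected deficit in litres).
#' @examples
#' compute_maod(7.88, 4.38)$total_kj  # 65.8 kJ
#' @export
compute_maod <- function(total_demand, accumulated, store_correction = 0.10,
                         energy_equiv = 20.9, condition = NA_character_,
                         demand_condition = "n/a") {
  if (!is.numeric(total_demand) || !is.numeric(accumulated) || accumulated < 0)
    stop("demand and accumulated VO2 must be non-negative numbers", call. = FALSE)
  if (accumulated > total_demand)
    stop("negative deficit: accumulated VO2 exceeds estimated demand (mis-specified demand line?)",
         call. = FALSE)
  deficit <- total_demand - accumulated
  energy_estimate("MAOD",
                  total_kj = deficit * (1 - store_correction) * energy_equiv,
                  components = list(deficit_l = deficit),
                  condition = condition, demand_condition = demand_condition)
}

# Summary VO2 of one submaximal trial: last-30-s mean, with the Delta-80
# bout truncated at isotime first.
.submax_point <- function(trial, t_iso = NULL) {
  b <- trial$breaths
  if (!is.null(t_iso) && t_iso < max(b$t)) b <- truncate_series(b, t_iso)
  data.frame(power = trial$power, vo2 = mean_last_window(b, 30))
}

#' The three cross-condition MAOD variants for one participant
#'
#' Computes MAOD_CAF-CAF (caffeine supramaximal bout, caffeine demand
#' line), MAOD_CAF-PLA (caffeine bout, placebo demand line) and
#' MAOD_PLA-PLA (placebo bout, placebo demand line). The demand line per
#' condition uses the five submaximal bouts Delta-10..Delta-80, with the
#' Delta-80 VO2 evaluated at isotime (the shorter of the two conditions'
#' Delta-80 exhaustion times); the accumulated VO2 and duration always
#' come from the stated supramaximal (120% VO2peak) bout.
#'
#' @param trials list of `simulated_trial`-like objects for one
#'   participant, each carrying attributes `intensity` (one of `d10`,
#'   `d20`, `d40`, `d50`, `d80`, `p120`) and a `condition$label`; both
#'   conditions' submaximal sets and 120% bouts must be present.
#' @return A list of class `maod_matrix`: `estimates` (named list
#'   `caf_caf`, `caf_pla`, `pla_pla` of [energy_estimate()]s),
#'   `demand_lines` (per condition), `isotime_d80` (s).
#' @export
maod_matrix <- function(trials) {
  lab <- vapply(trials, function(x) x$condition$label, character(1))
  int <- vapply(trials, function(x) {
    v <- attr(x, "intensity"); if (is.null(v)) NA_character_ else v
  }, character(1))
  need <- expand.grid(intensity = c("d10", "d20", "d40", "d50", "d80", "p120"),
                      condition = c("caffeine", "placebo"),
                      stringsAsFactors = FALSE)
  have <- paste(int, lab)
  missing <- need[!paste(need$intensity, need$condition) %in% have, ]
  if (nrow(missing))
    stop(sprintf("missing required bout(s): %s",
                 paste(sprintf("%s/%s", missing$intensity, missing$condition),
                       collapse = ", ")), call. = FALSE)
  pick <- function(i, c) trials[[which(int == i & lab == c)[1]]]

  t_iso <- isotime(pick("d80", "caffeine")$time_to_exhaustion,
                   pick("d80", "placebo")$time_to_exhaustion)
  lines <- lapply(c(caffeine = "caffeine", placebo = "placebo"), function(cl) {
    pts <- rbind(
      do.call(rbind, lapply(c("d10", "d20", "d40", "d50"),
                            function(i) .submax_point(pick(i, cl)))),
      .submax_point(pick("d80", cl), t_iso = t_iso))
    fit_demand_line(pts, condition_of_submax = cl)
  })

  one <- function(sup_cond, dem_cond) {
    sup <- pick("p120", sup_cond)
    tte <- sup$time_to_exhaustion
    if (is.na(tte)) tte <- max(sup$breaths$t)
    dem <- supramaximal_demand(lines[[dem_cond]], sup$power, tte)
    acc <- accumulated_vo2(sup$breaths, 0, min(tte, max(sup$breaths$t)))
    compute_maod(dem, acc, condition = sup_cond, demand_condition = dem_cond)
  }
  structure(list(estimates = list(caf_caf = one("caffeine", "caffeine"),
                                  caf_pla = one("caffeine", "placebo"),
                                  pla_pla = one("placebo", "placebo")),
                 demand_lines = lines, isotime_d80 = t_iso),
            class = "maod_matrix")
}

#' @export
print.maod_matrix <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("MAOD matrix (kJ): CAF-CAF %.2f, CAF-PLA %.2f, PLA-PLA %.2f (isotime D80 %.1f s)\n",
              e$caf_caf$total_kj, e$caf_pla$total_kj, e$pla_pla$total_kj,
              x$isotime_d80))
  invisible(x)
}
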