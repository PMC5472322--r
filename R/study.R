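# Study-level pipeline: apply the four anaerobic-capacity methods to every
# participant of a crossover study and assemble a tidy results table for
# the statistical comparisons.

#' MAOD variants for every participant of a study
#'
#' Runs [maod_matrix()] per participant.
#'
#' @param study a [simulate_crossover_study()] result (or any list with
#'   the same shape).
#' @return data.frame: `participant`, `variant` (`caf_caf`, `caf_pla`,
#'   `pla_pla`), `total_kj`.
#' @export
maod_study <- function(study) {
  stopifnot(inherits(study, "crossover_study"))
  out <- lapply(seq_along(study$truths), function(i) {
    keep <- study$index$pos[study$index$participant == i]
    mm <- maod_matrix(study$trials[keep])
    data.frame(participant = i,
               variant = names(mm$estimates),
               total_kj = vapply(mm$estimates, `[[`, numeric(1), "total_kj"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Critical-power parameters per participant and condition
#'
#' Fits the three power-duration models to the Delta-80, 100% and 120%
#' VO2peak exhaustion trials of each condition and keeps the model with
#' the lowest W' standard error.
#'
#' @param study a [simulate_crossover_study()] result.
#' @return data.frame: `participant`, `condition`, `model`, `cp` (W),
#'   `w_prime` (J), `see_w_prime` (J).
#' @export
cp_study <- function(study) {
  stopifnot(inherits(study, "crossover_study"))
  rows <- list()
  for (i in seq_along(study$truths)) {
    for (cl in names(study$conditions)) {
      tr <- lapply(c("d80", "p100", "p120"), function(w)
        study_trial(study, i, w, cl))
      pts <- power_duration_points(
        vapply(tr, `[[`, numeric(1), "power"),
        vapply(tr, `[[`, numeric(1), "time_to_exhaustion"))
      sel <- cp_analysis(pts, condition = cl)$selected
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, condition = cl, model = sel$model, cp = sel$cp,
        w_prime = sel$w_prime, see_w_prime = sel$see_w_prime)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alternative MAOD per participant and condition
#'
#' Fits the off-kinetics of the 120% VO2peak recovery and combines the
#' alactic and lactic components.
#'
#' @param study a [simulate_crossover_study()] result.
#' @return data.frame: `participant`, `condition`, `total_kj`,
#'   `alactic_kj`, `lactic_kj`, `a1`, `tau1`, `converged`.
#' @export
maod_alt_study <- function(study) {
  stopifnot(inherits(study, "crossover_study"))
  rows <- list()
  for (i in seq_along(study$truths)) {
    for (cl in names(study$conditions)) {
      trial <- study_trial(study, i, "p120", cl)
      fit <- fit_off_kinetics(trial$off_breaths)
      est <- compute_maod_alt(fit, trial$lactate,
                              body_mass = study$truths[[i]]$body_mass,
                              condition = cl)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, condition = cl, total_kj = est$total_kj,
        alactic_kj = est$components$alactic_kj,
        lactic_kj = est$components$lactic_kj,
        a1 = fit$a1, tau1 = fit$tau1, converged = fit$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gross-efficiency anaerobic work per participant and condition
#'
#' Gross efficiency from each condition's warm-up, anaerobic work from
#' the 120% VO2peak bout assuming RER = 1.00.
#'
#' @param study a [simulate_crossover_study()] result.
#' @return data.frame: `participant`, `condition`, `ge`, `total_kj`.
#' @export
ge_study <- function(study) {
  stopifnot(inherits(study, "crossover_study"))
  rows <- list()
  for (i in seq_along(study$truths)) {
    for (cl in names(study$conditions)) {
      wu <- study$warmups[[i]][[cl]]
      eff <- gross_efficiency_from_warmup(wu$breaths, wu$power)
      trial <- study_trial(study, i, "p120", cl)
      est <- anaerobic_work(trial$breaths, trial$power, eff, condition = cl)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, condition = cl, ge = eff$ge, total_kj = est$total_kj)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run all four anaerobic-capacity methods on a crossover study
#'
#' @param study a [simulate_crossover_study()] result.
#' @return A list of class `study_results`: `maod` ([maod_study()]),
#'   `maod_alt` ([maod_alt_study()]), `cp` ([cp_study()]), `ge`
#'   ([ge_study()]), and `ac_table` — a long data.frame (`participant`,
#'   `condition`, `method`, `total_kj`) of the per-condition AC
#'   estimates (MAOD variants mapped to their supramaximal-bout
#'   condition: `caf_caf` to caffeine, `pla_pla` to placebo).
#' @export
analyze_study <- function(study) {
  maod <- maod_study(study)
  alt <- maod_alt_study(study)
  cp <- cp_study(study)
  ge <- ge_study(study)
  ac <- rbind(
    data.frame(participant = maod$participant[maod$variant == "caf_caf"],
               condition = "caffeine", method = "MAOD",
               total_kj = maod$total_kj[maod$variant == "caf_caf"]),
    data.frame(participant = maod$participant[maod$variant == "pla_pla"],
               condition = "placebo", method = "MAOD",
               total_kj = maod$total_kj[maod$variant == "pla_pla"]),
    data.frame(participant = alt$participant, condition = alt$condition,
               method = "MAOD_ALT", total_kj = alt$total_kj),
    data.frame(participant = cp$participant, condition = cp$condition,
               method = "CP_WPRIME", total_kj = cp$w_prime / 1000),
    data.frame(participant = ge$participant, condition = ge$condition,
               method = "GE_WORK", total_kj = ge$total_kj))
  rownames(ac) <- NULL
  structure(list(maod = maod, maod_alt = alt, cp = cp, ge = ge,
                 ac_table = ac), class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  agg <- stats::aggregate(total_kj ~ method + condition, data = x$ac_table, mean)
  cat("study_results — group-mean AC (kJ):\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
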