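# Critical power: three two-parameter power-duration models fitted to
# (power, time-to-exhaustion) points, with model selection by the lowest
# standard error of W'.

#' Power-duration points
#'
#' @param power powers in W, > 0.
#' @param t_lim times to exhaustion in s, > 0.
#' @return data.frame with columns `power`, `t_lim` and `work`
#'   (`power·t_lim`, J).
#' @export
power_duration_points <- function(power, t_lim) {
  if (length(power) != length(t_lim))
    stop("power and t_lim must have equal length", call. = FALSE)
  if (any(power <= 0) || any(t_lim <= 0))
    stop("power and t_lim must be > 0", call. = FALSE)
  data.frame(power = power, t_lim = t_lim, work = power * t_lim)
}

#' Fit one critical-power model
#'
#' The three algebraically equivalent two-parameter models:
#' * `hyperbolic`: `t = W'/(P - CP)`, nonlinear least squares in t;
#' * `linear_work_time`: `W = W' + CP·t`, OLS of work on time;
#' * `linear_power_inv_time`: `P = W'/t + CP`, OLS of power on 1/t.
#'
#' On noiseless hyperbolic data all three recover (CP, W') exactly; under
#' noise they weight errors differently. Standard errors of W' and CP
#' come from the OLS parameter covariance for the linear forms and from
#' the Jacobian-based linearised covariance at the optimum for the
#' hyperbolic form.
#'
#' @param points a [power_duration_points()] data.frame with at least 3
#'   points (2 points leave the standard error undefined) and distinct
#'   durations.
#' @param model one of `"hyperbolic"`, `"linear_work_time"`,
#'   `"linear_power_inv_time"`.
#' @return A list of class `cp_fit`: `model`, `cp` (W), `w_prime` (J),
#'   `see_w_prime` (J), `see_cp` (W), `rss` (model units squared),
#'   `valid`.
#' @export
fit_cp <- function(points, model = c("hyperbolic", "linear_work_time",
                                     "linear_power_inv_time")) {
  model <- match.arg(model)
  if (!all(c("power", "t_lim") %in% names(points)))
    stop("points must have columns power, t_lim", call. = FALSE)
  if (nrow(points) < 3L)
    stop("SEE undefined with fewer than 3 points", call. = FALSE)
  if (length(unique(points$t_lim)) < 2L || length(unique(points$power)) < 2L)
    stop("degenerate points: need distinct durations and powers", call. = FALSE)
  p <- points$power; t <- points$t_lim; w <- p * t
  if (model == "linear_work_time") {
    fit <- stats::lm(w ~ t)
    cf <- suppressWarnings(summary(fit))$coefficients
    out <- list(cp = cf[2, 1], w_prime = cf[1, 1],
                see_cp = cf[2, 2], see_w_prime = cf[1, 2],
                rss = sum(stats::resid(fit)^2))
  } else if (model == "linear_power_inv_time") {
    it <- 1 / t
    fit <- stats::lm(p ~ it)
    cf <- suppressWarnings(summary(fit))$coefficients
    out <- list(cp = cf[1, 1], w_prime = cf[2, 1],
                see_cp = cf[1, 2], see_w_prime = cf[2, 2],
                rss = sum(stats::resid(fit)^2))
  } else {
    # start from the inverse-of-time linearisation
    lin <- stats::lm(p ~ I(1 / t))
    st <- list(w_prime = max(unname(stats::coef(lin)[2]), 1),
               cp = min(max(unname(stats::coef(lin)[1]), 1), min(p) - 1e-6))
    fit <- tryCatch(
      minpack.lm::nlsLM(t ~ w_prime / (power - cp),
                        data = data.frame(t = t, power = p), start = st,
                        lower = c(w_prime = 0, cp = 0),
                        upper = c(w_prime = Inf, cp = min(p) - 1e-9),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit))
      return(structure(list(model = model, cp = NA_real_, w_prime = NA_real_,
                            see_w_prime = NA_real_, see_cp = NA_real_,
                            rss = NA_real_, valid = FALSE), class = "cp_fit"))
    cf <- suppressWarnings(summary(fit))$coefficients
    out <- list(cp = cf["cp", 1], w_prime = cf["w_prime", 1],
                see_cp = cf["cp", 2], see_w_prime = cf["w_prime", 2],
                rss = sum(stats::resid(fit)^2))
  }
  out$model <- model
  out$valid <- is.finite(out$cp) && is.finite(out$w_prime) &&
    out$cp > 0 && out$w_prime > 0
  structure(out[c("model", "cp", "w_prime", "see_w_prime", "see_cp",
                  "rss", "valid")], class = "cp_fit")
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf("cp_fit [%s]%s: CP %.1f W (SEE %.2f), W' %.0f J (SEE %.1f), rss %.4g\n",
              x$model, if (!x$valid) " [invalid]" else "",
              x$cp, x$see_cp, x$w_prime, x$see_w_prime, x$rss))
  invisible(x)
}

#' Select the critical-power model with the lowest W' standard error
#'
#' Invalid fits (non-positive parameters or failed convergence) are
#' excluded with a warning. Standard errors equal within a relative
#' 1e-9 are treated as tied and broken in the fixed order
#' linear_power_inv_time, linear_work_time, hyperbolic.
#'
#' @param fits list of [fit_cp()] results (typically the three models).
#' @return The selected `cp_fit`.
#' @export
select_cp_model <- function(fits) {
  pref <- c("linear_power_inv_time", "linear_work_time", "hyperbolic")
  ok <- vapply(fits, function(f) isTRUE(f$valid) && is.finite(f$see_w_prime),
               logical(1))
  if (any(!ok)) {
    if (!any(ok)) stop("no valid critical-power fit", call. = FALSE)
    warning(sprintf("excluding invalid fit(s): %s",
                    paste(vapply(fits[!ok], `[[`, character(1), "model"),
                          collapse = ", ")), call. = FALSE)
    fits <- fits[ok]
  }
  see <- vapply(fits, `[[`, numeric(1), "see_w_prime")
  tied <- see <= min(see) + 1e-9 * (1 + min(see))
  cand <- fits[tied]
  ord <- order(match(vapply(cand, `[[`, character(1), "model"), pref))
  cand[[ord[1]]]
}

#' Fit all three models and select one
#'
#' Convenience wrapper: fits the hyperbolic, work-time and
#' power-inverse-time models and applies [select_cp_model()].
#'
#' @param points a [power_duration_points()] data.frame.
#' @return A list: `fits` (all three), `selected` (the chosen `cp_fit`),
#'   and `w_prime_kj` — W' of the selected model as an
#'   [energy_estimate()] with method `"CP_WPRIME"`.
#' @param condition label recorded on the energy estimate.
#' @export
cp_analysis <- function(points, condition = NA_character_) {
  models <- c("linear_power_inv_time", "linear_work_time", "hyperbolic")
  fits <- lapply(models, function(m) fit_cp(points, m))
  sel <- select_cp_model(fits)
  est <- energy_estimate("CP_WPRIME", total_kj = sel$w_prime / 1000,
                         components = list(w_prime_j = sel$w_prime,
                                           cp_w = sel$cp),
                         condition = condition)
  list(fits = fits, selected = sel, w_prime_kj = est)
}
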