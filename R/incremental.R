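# Incremental (ramp) test analysis: VO2peak, automated gas exchange
# threshold detection, and Delta-based workload prescription.

#' Peak oxygen uptake from a ramp test
#'
#' VO2peak is the average VO2 over the last 30 s of the test.
#'
#' @param series a [breath_series()] of at least 30 s.
#' @return VO2peak in L·min⁻¹.
#' @export
compute_vo2peak <- function(series) mean_last_window(series, window = 30)

#' Detect the gas exchange threshold (v-slope breakpoint)
#'
#' Automates the v-slope criterion — the first disproportionate increase
#' of VCO2 relative to VO2 — as a continuous two-segment linear
#' regression of VCO2 on VO2. Every interior candidate breakpoint on the
#' 1-Hz resampled series is scanned and the one minimising the total SSE
#' is chosen; the first and last 10% of samples are excluded to avoid
#' edge artifacts. The GET power is read from the power trace at the time
#' the (lightly smoothed) VO2 first reaches the breakpoint VO2.
#'
#' This is a single-criterion automation of what is classically a
#' multi-criterion visual call (ventilatory equivalents and end-tidal
#' pressures are not implemented), and reports should flag it as such.
#'
#' @param series a [breath_series()] from a ramp test with at least 60 s
#'   of data and a `power` channel.
#' @return A list of class `get_result`: `get_vo2` (L·min⁻¹),
#'   `get_power` (W), `confidence` (1 - SSE_2seg/SSE_1seg), `slope_below`,
#'   `slope_above`.
#' @export
detect_get <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  if (series$t[nrow(series)] - series$t[1] < 60)
    stop("need at least 60 s of ramp data", call. = FALSE)
  rs <- resample_uniform(series, 1)
  x <- rs$vo2; y <- rs$vco2
  n <- length(x)
  lo <- ceiling(0.10 * n); hi <- floor(0.90 * n)
  cand <- sort(unique(x[lo:hi]))
  cand <- cand[cand > min(x) & cand < max(x)]
  if (length(cand) < 3L) stop("too few candidate breakpoints", call. = FALSE)
  sse1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  best <- list(sse = Inf)
  for (cb in cand) {
    h <- pmax(x - cb, 0)
    fit <- stats::lm(y ~ x + h)
    sse <- sum(stats::resid(fit)^2)
    if (sse < best$sse) best <- list(sse = sse, cb = cb, coef = stats::coef(fit))
  }
  b1 <- best$coef[["x"]]; b2 <- best$coef[["h"]]
  if (!is.finite(b2) || b2 <= 0)
    stop("no GET detected: no disproportionate VCO2 rise", call. = FALSE)
  get_vo2 <- best$cb
  # time at which smoothed VO2 first reaches the breakpoint
  vo2_s <- stats::filter(rs$vo2, rep(1 / 9, 9), sides = 2)
  vo2_s[is.na(vo2_s)] <- rs$vo2[is.na(vo2_s)]
  k <- which(vo2_s >= get_vo2)[1]
  get_power <- if (!is.null(rs$power) && !is.na(k)) rs$power[k] else NA_real_
  structure(list(get_vo2 = get_vo2, get_power = get_power,
                 confidence = 1 - best$sse / sse1,
                 slope_below = b1, slope_above = b1 + b2),
            class = "get_result")
}

#' @export
print.get_result <- function(x, ...) {
  cat(sprintf("GET: %.2f L/min @ %.0f W (confidence %.3f; v-slope %.2f -> %.2f)\n",
              x$get_vo2, x$get_power, x$confidence, x$slope_below, x$slope_above))
  invisible(x)
}

#' Delta-based VO2 target
#'
#' The Delta-x intensity is the GET VO2 plus `fraction` of the interval
#' between GET and VO2peak: `get_vo2 + fraction·(vo2peak - get_vo2)`.
#'
#' @param get_vo2,vo2peak L·min⁻¹, with `get_vo2 < vo2peak`.
#' @param fraction non-negative Delta fraction (0.1 for Delta-10, ...).
#' @return Target VO2 in L·min⁻¹.
#' @export
delta_target <- function(get_vo2, vo2peak, fraction) {
  if (!is.numeric(fraction) || any(fraction < 0))
    stop("fraction must be >= 0", call. = FALSE)
  if (get_vo2 >= vo2peak) stop("require get_vo2 < vo2peak", call. = FALSE)
  get_vo2 + fraction * (vo2peak - get_vo2)
}

#' Power prescription for a VO2 target
#'
#' Inverts the incremental VO2-power line to prescribe a workload,
#' rounded to the nearest watt.
#'
#' @param result an `incremental_result` from [analyze_incremental()], or
#'   a list with a `vo2_power_line` element `c(slope, intercept)`.
#' @param target_vo2 target VO2 in L·min⁻¹.
#' @return Power in W.
#' @export
power_for_target <- function(result, target_vo2) {
  line <- result$vo2_power_line
  if (is.null(line)) stop("result lacks a vo2_power_line", call. = FALSE)
  slope <- line[[1]]; intercept <- line[[2]]
  if (!is.numeric(slope) || slope <= 0) stop("line slope must be > 0", call. = FALSE)
  round((target_vo2 - intercept) / slope)
}

#' Full incremental-test summary
#'
#' Computes VO2peak, the GET (via [detect_get()]), the maximal power
#' reached, and a VO2-power line fitted by OLS over the ramp region where
#' VO2 is still below 95% of VO2peak (skipping the first 60 s). Because
#' VO2 lags power during a ramp, the fitted line's intercept absorbs the
#' kinetic lag; the line is intended for workload prescription, not as a
#' steady-state demand estimate.
#'
#' @param series ramp-test [breath_series()] with a `power` channel.
#' @return A list of class `incremental_result`: `vo2peak`, `get_vo2`,
#'   `get_power`, `max_power`, `vo2_power_line` (slope, intercept), `get`.
#' @export
analyze_incremental <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  if (is.null(series$power)) stop("series lacks a power channel", call. = FALSE)
  vo2peak <- compute_vo2peak(series)
  g <- detect_get(series)
  rs <- resample_uniform(series, 1)
  sel <- rs$t >= 60 & rs$vo2 < 0.95 * vo2peak
  if (sum(sel) < 10L) stop("too little sub-peak ramp data for the VO2-power line",
                           call. = FALSE)
  fit <- stats::lm(vo2 ~ power, data = rs[sel, ])
  res <- list(vo2peak = vo2peak, get_vo2 = g$get_vo2, get_power = g$get_power,
              max_power = max(series$power),
              vo2_power_line = c(slope = unname(stats::coef(fit)[2]),
                                 intercept = unname(stats::coef(fit)[1])),
              get = g)
  if (!(res$get_vo2 < res$vo2peak))
    stop("invalid incremental result: GET VO2 not below VO2peak", call. = FALSE)
  structure(res, class = "incremental_result")
}
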