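#' Construct a breath-by-breath gas-exchange series
#'
#' A `breath_series` holds one bout's time-stamped gas-exchange samples:
#' time (s), oxygen uptake and carbon dioxide output (L·min⁻¹), and
#' optionally ventilation (L·min⁻¹) and external power (W). Time is
#' t = 0 at bout onset; off-transient (recovery) series use t = 0 at
#' exercise end.
#'
#' @param t numeric, sample times in seconds, strictly increasing.
#' @param vo2 numeric, oxygen uptake in L·min⁻¹, non-negative.
#' @param vco2 numeric, carbon dioxide output in L·min⁻¹, non-negative.
#' @param ve optional numeric, minute ventilation in L·min⁻¹.
#' @param power optional numeric, external power in W (constant or ramp).
#' @return A data.frame of class `breath_series` with columns
#'   `t`, `vo2`, `vco2` and, when supplied, `ve` and `power`.
#' @examples
#' b <- breath_series(t = 0:10, vo2 = rep(1.2, 11), vco2 = rep(1.0, 11))
#' @export
breath_series <- function(t, vo2, vco2, ve = NULL, power = NULL) {
  t <- as.numeric(t); vo2 <- as.numeric(vo2); vco2 <- as.numeric(vco2)
  n <- length(t)
  if (n == 0L) stop("no breaths", call. = FALSE)
  if (length(vo2) != n || length(vco2) != n)
    stop("channels must have equal length", call. = FALSE)
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("time must be strictly increasing; offending rows: %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(vo2)) || any(!is.finite(vco2)))
    stop("non-finite values in breath series", call. = FALSE)
  if (any(vo2 < 0) || any(vco2 < 0))
    stop("vo2 and vco2 must be non-negative", call. = FALSE)
  out <- data.frame(t = t, vo2 = vo2, vco2 = vco2)
  if (!is.null(ve)) {
    if (length(ve) != n) stop("channels must have equal length", call. = FALSE)
    out$ve <- as.numeric(ve)
  }
  if (!is.null(power)) {
    if (length(power) != n) stop("channels must have equal length", call. = FALSE)
    out$power <- as.numeric(power)
  }
  class(out) <- c("breath_series", "data.frame")
  out
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("breath_series: %d breaths over %.1f s", nrow(x), diff(range(x$t))))
  if (!is.null(x$power)) cat(sprintf(", power %.0f-%.0f W", min(x$power), max(x$power)))
  cat("\n")
  invisible(x)
}

#' Read / write a breath series as CSV
#'
#' The on-disk schema has columns `t_s`, `vo2_l_min`, `vco2_l_min` and
#' optionally `ve_l_min`, `power_w`. Readers tolerate extra columns and
#' comment lines starting with `#`.
#'
#' @param path file path.
#' @return `read_breaths` returns a [breath_series()].
#' @export
read_breaths <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no breaths", call. = FALSE)
  for (col in c("t_s", "vo2_l_min", "vco2_l_min"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  breath_series(t = df$t_s, vo2 = df$vo2_l_min, vco2 = df$vco2_l_min,
                ve = if ("ve_l_min" %in% names(df)) df$ve_l_min,
                power = if ("power_w" %in% names(df)) df$power_w)
}

#' @rdname read_breaths
#' @param series a [breath_series()].
#' @export
write_breaths <- function(series, path) {
  stopifnot(inherits(series, "breath_series"))
  out <- data.frame(t_s = series$t, vo2_l_min = series$vo2,
                    vco2_l_min = series$vco2)
  if (!is.null(series$ve)) out$ve_l_min <- series$ve
  if (!is.null(series$power)) out$power_w <- series$power
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Resample a breath series onto a uniform time grid
#'
#' Linear interpolation of every channel onto the grid
#' `seq(t[1], t[n], by = dt)`; the final sample time is appended when the
#' grid does not land on it, so both endpoints are preserved. Resampling
#' to 1 Hz is performed before any windowed average or integration so that
#' irregular breath timing does not weight the statistics.
#'
#' @param series a [breath_series()] with at least two breaths.
#' @param dt grid step in seconds (default 1).
#' @return A [breath_series()] on the uniform grid.
#' @export
resample_uniform <- function(series, dt = 1.0) {
  stopifnot(inherits(series, "breath_series"))
  if (nrow(series) < 2L) stop("need at least 2 breaths to resample", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  grid <- seq(series$t[1], series$t[nrow(series)], by = dt)
  if (utils::tail(grid, 1) < series$t[nrow(series)] - 1e-9)
    grid <- c(grid, series$t[nrow(series)])
  interp <- function(y) stats::approx(series$t, y, xout = grid)$y
  breath_series(t = grid, vo2 = interp(series$vo2), vco2 = interp(series$vco2),
                ve = if (!is.null(series$ve)) interp(series$ve),
                power = if (!is.null(series$power)) interp(series$power))
}

#' Time-weighted mean over the final window of a series
#'
#' The canonical summary VO2 of a submaximal bout (and VO2peak at the end
#' of a ramp test) is the average over the last 30 s.
#'
#' @param series a [breath_series()].
#' @param window window length in seconds (default 30).
#' @param channel channel to average, `"vo2"`, `"vco2"` or `"ve"`.
#' @return Time-weighted mean of the channel over
#'   `[t_end - window, t_end]`, in the channel's units.
#' @export
mean_last_window <- function(series, window = 30, channel = "vo2") {
  stopifnot(inherits(series, "breath_series"))
  if (!is.numeric(window) || window <= 0) stop("window must be positive", call. = FALSE)
  dur <- series$t[nrow(series)] - series$t[1]
  if (dur < window - 1e-9)
    stop(sprintf("series duration %.1f s shorter than window %.1f s", dur, window),
         call. = FALSE)
  y <- series[[channel]]
  if (is.null(y)) stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  t_end <- series$t[nrow(series)]
  grid <- seq(t_end - window, t_end, by = min(1, window / 2))
  if (utils::tail(grid, 1) < t_end - 1e-9) grid <- c(grid, t_end)
  yy <- stats::approx(series$t, y, xout = grid)$y
  pracma::trapz(grid, yy) / (t_end - grid[1])
}

#' Accumulated oxygen uptake over a time window
#'
#' Trapezoidal integral of VO2 (L·min⁻¹) over seconds, divided by 60, so
#' the result is litres of oxygen. The series is linearly interpolated to
#' a 1-s grid over the window before integrating.
#'
#' @param series a [breath_series()].
#' @param t_start,t_end integration limits in seconds,
#'   `series start <= t_start < t_end <= series end`.
#' @return Accumulated VO2 in litres.
#' @examples
#' b <- breath_series(t = seq(0, 120, 2), vo2 = rep(3, 61), vco2 = rep(3, 61))
#' accumulated_vo2(b, 0, 120)  # 6 L
#' @export
accumulated_vo2 <- function(series, t_start, t_end) {
  stopifnot(inherits(series, "breath_series"))
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_start >= t_end)
    stop("require t_start < t_end", call. = FALSE)
  if (t_start < series$t[1] - 1e-9 || t_end > series$t[nrow(series)] + 1e-9)
    stop("integration window outside series", call. = FALSE)
  grid <- seq(t_start, t_end, by = 1)
  if (utils::tail(grid, 1) < t_end - 1e-9) grid <- c(grid, t_end)
  yy <- stats::approx(series$t, series$vo2, xout = grid, rule = 2)$y
  pracma::trapz(grid, yy) / 60
}

#' Isotime between two matched exhaustion trials
#'
#' The shorter of two times to exhaustion. Condition comparisons of the
#' same workload are made at isotime so that both series are truncated to
#' the same elapsed exercise duration.
#'
#' @param t_a,t_b positive times to exhaustion in seconds.
#' @return `min(t_a, t_b)` in seconds.
#' @export
isotime <- function(t_a, t_b) {
  if (!is.numeric(t_a) || !is.numeric(t_b) || t_a <= 0 || t_b <= 0)
    stop("times to exhaustion must be positive", call. = FALSE)
  min(t_a, t_b)
}

#' Truncate a breath series at a given time
#'
#' Keeps breaths with `t <= t_cut`, appending an interpolated sample at
#' exactly `t_cut` when it falls between breaths. Used to evaluate a
#' longer bout at isotime.
#'
#' @param series a [breath_series()].
#' @param t_cut cut time in seconds, inside the series span.
#' @return A [breath_series()] ending at `t_cut`.
#' @export
truncate_series <- function(series, t_cut) {
  stopifnot(inherits(series, "breath_series"))
  if (t_cut <= series$t[1] || t_cut > series$t[nrow(series)] + 1e-9)
    stop("t_cut outside series", call. = FALSE)
  keep <- series$t <= t_cut + 1e-9
  out <- series[keep, , drop = FALSE]
  if (utils::tail(out$t, 1) < t_cut - 1e-9) {
    pad <- lapply(setdiff(names(series), "t"), function(ch)
      stats::approx(series$t, series[[ch]], xout = t_cut)$y)
    names(pad) <- setdiff(names(series), "t")
    out <- rbind(out, cbind(data.frame(t = t_cut), as.data.frame(pad)))
  }
  class(out) <- c("breath_series", "data.frame")
  rownames(out) <- NULL
  out
}

#' Construct a blood-lactate sample series
#'
#' Post-exercise plasma lactate samples with the pre-exercise (resting)
#' concentration. Sample times are seconds relative to exercise end.
#'
#' @param t numeric, sample times (s after exercise end).
#' @param la numeric, plasma lactate concentrations (mmol·L⁻¹), >= 0.
#' @param pre_exercise resting concentration (mmol·L⁻¹).
#' @return A list of class `lactate_series` with elements `samples`
#'   (data.frame `t`, `la`) and `pre_exercise`.
#' @export
lactate_series <- function(t, la, pre_exercise) {
  t <- as.numeric(t); la <- as.numeric(la)
  if (length(t) != length(la)) stop("t and la must have equal length", call. = FALSE)
  if (length(la) < 1L) stop("need at least one post-exercise sample", call. = FALSE)
  if (any(la < 0) || pre_exercise < 0)
    stop("lactate concentrations must be non-negative", call. = FALSE)
  structure(list(samples = data.frame(t = t, la = la),
                 pre_exercise = as.numeric(pre_exercise)),
            class = "lactate_series")
}

#' Read / write a lactate series as CSV (columns `t_s`, `la_mmol_l`;
#' the pre-exercise sample is the row with `t_s < 0` or a `# pre=` header).
#'
#' @param path file path.
#' @return `read_lactate` returns a [lactate_series()].
#' @export
read_lactate <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("t_s", "la_mmol_l"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  pre <- df$la_mmol_l[df$t_s < 0]
  post <- df[df$t_s >= 0, , drop = FALSE]
  if (length(pre) != 1L) stop("expected exactly one pre-exercise row (t_s < 0)",
                              call. = FALSE)
  lactate_series(post$t_s, post$la_mmol_l, pre_exercise = pre)
}

#' @rdname read_lactate
#' @param lac a [lactate_series()].
#' @export
write_lactate <- function(lac, path) {
  stopifnot(inherits(lac, "lactate_series"))
  out <- rbind(data.frame(t_s = -60, la_mmol_l = lac$pre_exercise),
               data.frame(t_s = lac$samples$t, la_mmol_l = lac$samples$la))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
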