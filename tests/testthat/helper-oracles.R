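# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths: closed forms,
# normal equations and sum-of-squares partitions written from definitions.

# Two-parameter OLS via the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# One-way within-subject ANOVA from the definitional SS partition.
rm1_brute_force <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss_cond = ss_cond, ss_err = ss_err)
}

# Two-way fully within-subject ANOVA from the definitional partition.
rm2_brute_force <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  gm <- mean(arr)
  m_s <- apply(arr, 1, mean); m_a <- apply(arr, 2, mean); m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean); m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + gm)^2)
  err_a <- b * sum((m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + gm)^2)
  err_b <- a * sum((m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + gm)^2)
  resid <- arr
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    resid[i, j, k] <- arr[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - gm
  err_ab <- sum(resid^2)
  fstat <- function(ss, df1, err, df2) {
    f <- (ss / df1) / (err / df2)
    list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  list(A = fstat(ss_a, a - 1, err_a, (a - 1) * (n - 1)),
       B = fstat(ss_b, b - 1, err_b, (b - 1) * (n - 1)),
       AB = fstat(ss_ab, (a - 1) * (b - 1), err_ab, (a - 1) * (b - 1) * (n - 1)),
       ss = c(A = ss_a, B = ss_b, AB = ss_ab),
       err = c(A = err_a, B = err_b, AB = err_ab))
}

# Exhaustive two-segment breakpoint scan over a fine grid of breakpoint
# values (independent of the package's candidate construction).
breakpoint_brute_force <- function(x, y, grid) {
  best <- c(sse = Inf, bp = NA)
  for (bp in grid) {
    h <- pmax(x - bp, 0)
    sse <- sum(stats::resid(stats::lm(y ~ x + h))^2)
    if (sse < best["sse"]) best <- c(sse = sse, bp = bp)
  }
  best[["bp"]]
}

# Noiseless breath series from an arbitrary vo2(t) function, 1-s spacing.
series_from_fn <- function(fn, t_end, dt = 1, rer = 0.9) {
  tt <- seq(0, t_end, by = dt)
  v <- fn(tt)
  breath_series(t = tt, vo2 = v, vco2 = rer * v)
}

# Minimal trial-like object accepted by maod_matrix(): constant-VO2
# breaths with the given condition label, intensity tag and power.
fake_trial <- function(intensity, condition, power, vo2, duration = 600,
                       tte = NA_real_) {
  tt <- seq(0, duration, by = 2)
  b <- breath_series(tt, rep(vo2, length(tt)), rep(0.9 * vo2, length(tt)))
  tr <- list(breaths = b, condition = list(label = condition), power = power,
             time_to_exhaustion = tte)
  attr(tr, "intensity") <- intensity
  tr
}
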