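# Paired and repeated-measures comparisons of anaerobic-capacity
# estimates across conditions and methods. Classical univariate
# within-subject ANOVA (no sphericity correction) and Bonferroni
# adjustment, alpha = 0.05 two-sided throughout.

.comparison_result <- function(design, statistic, df, p, effects = NULL,
                               posthoc = NULL) {
  structure(list(design = design, statistic = statistic, df = df, p = p,
                 effects = effects, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df (%s), p = %.4g\n", x$design, x$statistic,
              paste(x$df, collapse = ", "), x$p))
  if (!is.null(x$effects)) for (nm in names(x$effects)) {
    e <- x$effects[[nm]]
    cat(sprintf("  %s: F = %.4g, df (%d, %d), p = %.4g\n", nm, e$F,
                e$df[1], e$df[2], e$p))
  }
  if (!is.null(x$posthoc) && nrow(x$posthoc))
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("  post-hoc %s: p_adj = %.4g\n", x$posthoc$pair[i],
                  x$posthoc$p_adjusted[i]))
  invisible(x)
}

#' Paired t test
#'
#' Classical two-sided paired t on within-participant differences.
#' All-zero differences (x identical to y) return t = 0, p = 1; constant
#' non-zero differences leave t undefined and raise an error.
#'
#' @param x,y per-participant values under the two conditions, paired by
#'   position, length >= 2.
#' @return A `comparison_result` with design `"paired_t"`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(.comparison_result("paired_t", 0, n - 1L, 1))
    stop("zero-variance non-zero differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .comparison_result("paired_t", unname(tt$statistic), unname(tt$parameter),
                     tt$p.value)
}

# Long-format within-subject data from a participants x conditions matrix.
.rm_long <- function(m) {
  if (any(!is.finite(m))) stop("missing cells in repeated-measures data",
                               call. = FALSE)
  data.frame(y = as.vector(m),
             subj = factor(rep(seq_len(nrow(m)), ncol(m))),
             cond = factor(rep(colnames(m) %||% seq_len(ncol(m)),
                               each = nrow(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# F with the 0/0 convention: zero effect SS reports F = 0, p = 1.
.safe_f <- function(ss_eff, df_eff, ss_err, df_err) {
  if (ss_eff < 1e-12) return(list(F = 0, p = 1, df = c(df_eff, df_err)))
  f <- (ss_eff / df_eff) / (ss_err / df_err)
  list(F = f, p = stats::pf(f, df_eff, df_err, lower.tail = FALSE),
       df = c(df_eff, df_err))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test of a condition factor with k levels measured on
#' every participant, with `(k-1, (k-1)(n-1))` degrees of freedom and no
#' sphericity correction. Bonferroni-adjusted pairwise paired t tests are
#' reported post hoc.
#'
#' @param m numeric matrix, participants in rows, conditions in columns
#'   (k >= 2, n >= 2), complete.
#' @return A `comparison_result` with design `"rm_anova_1w"` and a
#'   `posthoc` data.frame (`pair`, `p`, `p_adjusted`).
#' @export
rm_anova_oneway <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 participants", call. = FALSE)
  d <- .rm_long(m)
  fit <- stats::aov(y ~ cond + Error(subj/cond), data = d)
  tab <- summary(fit)[["Error: subj:cond"]][[1]]
  ss_eff <- tab["cond", "Sum Sq"]; ss_err <- tab["Residuals", "Sum Sq"]
  res <- .safe_f(ss_eff, tab["cond", "Df"], ss_err, tab["Residuals", "Df"])
  combs <- utils::combn(ncol(m), 2)
  lev <- colnames(m) %||% as.character(seq_len(ncol(m)))
  ph <- data.frame(
    pair = apply(combs, 2, function(j) paste(lev[j], collapse = " vs ")),
    p = apply(combs, 2, function(j) {
      dd <- m[, j[1]] - m[, j[2]]
      if (stats::sd(dd) == 0) return(if (mean(dd) == 0) 1 else NA_real_)
      stats::t.test(m[, j[1]], m[, j[2]], paired = TRUE)$p.value
    }))
  ph$p_adjusted <- bonferroni(ph$p)
  .comparison_result("rm_anova_1w", res$F, res$df, res$p,
                     effects = list(cond = res), posthoc = ph)
}

#' Two-way repeated-measures ANOVA
#'
#' Both factors within-subject on a complete crossed design. Standard
#' univariate partition: each effect (A, B, A:B) is tested against its
#' own interaction-with-subject error stratum; no sphericity correction.
#'
#' @param arr 3-dimensional numeric array, `participants x A x B`, with
#'   dimnames for the factor levels (optional).
#' @return A `comparison_result` with design `"rm_anova_2w"`; `effects`
#'   holds `A`, `B` and `A:B`, and the headline statistic is the
#'   interaction.
#' @export
rm_anova_twoway <- function(arr) {
  if (length(dim(arr)) != 3L)
    stop("arr must be a 3-d array: participants x factorA x factorB",
         call. = FALSE)
  if (any(!is.finite(arr))) stop("missing cells in repeated-measures data",
                                 call. = FALSE)
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  if (n < 2L || a < 2L || b < 2L)
    stop("need >= 2 participants and >= 2 levels per factor", call. = FALSE)
  dn <- dimnames(arr)
  d <- data.frame(
    y = as.vector(arr),
    subj = factor(rep(seq_len(n), a * b)),
    A = factor(rep(rep(dn[[2]] %||% seq_len(a), each = n), b)),
    B = factor(rep(dn[[3]] %||% seq_len(b), each = n * a)))
  fit <- stats::aov(y ~ A * B + Error(subj / (A * B)), data = d)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    .safe_f(tab[term, "Sum Sq"], tab[term, "Df"],
            tab["Residuals", "Sum Sq"], tab["Residuals", "Df"])
  }
  effects <- list("A" = pick("Error: subj:A", "A"),
                  "B" = pick("Error: subj:B", "B"),
                  "A:B" = pick("Error: subj:A:B", "A:B"))
  inter <- effects[["A:B"]]
  .comparison_result("rm_anova_2w", inter$F, inter$df, inter$p,
                     effects = effects)
}

#' Bonferroni adjustment
#'
#' Elementwise `min(1, p·m)`.
#'
#' @param pvals p values in [0, 1].
#' @param m number of comparisons (default `length(pvals)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0L) return(numeric(0))
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "bonferroni", n = max(m, length(pvals)))
}
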