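#' Independent-samples (Welch) t-test with effect size
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (Student's form via `var_equal = TRUE`), two-sided p, and
#' Cohen's d on the pooled standard deviation. When both samples are
#' constant with equal means, `t = 0, p = 1`; constant with unequal
#' means degenerates to `p = 0`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance Student form (default FALSE).
#' @return A one-row data.frame: `t`, `df`, `p`, `effect` (Cohen's d),
#'   `mean_x`, `mean_y`, `significant`.
#' @export
two_sample_test <- function(x, y, alpha = 0.05, var_equal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) /
             (length(x) + length(y) - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    t_stat <- if (same) 0 else sign(mean(x) - mean(y)) * Inf
    p <- if (same) 1 else 0
    res <- data.frame(t = t_stat, df = NA_real_, p = p, effect = d,
                      mean_x = mean(x), mean_y = mean(y),
                      significant = p < alpha)
    return(res)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, effect = d,
             mean_x = mean(x), mean_y = mean(y),
             significant = ht$p.value < alpha)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row data.frame: `r`, `p`, `n`, `defined` (FALSE when a
#'   vector has zero variance, in which case `r` is `NA`).
#' @export
correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3")
  }
  if (!all(is.finite(c(x, y)))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(r = NA_real_, p = NA_real_, n = length(x),
                      defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x),
             defined = TRUE)
}
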