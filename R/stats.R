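#' Breast-average permittivity of a reconstructed image
#'
#' @param image A `recon_image`.
#' @param mask Logical breast mask.
#' @return Mean permittivity over the mask.
#' @export
breast_average <- function(image, mask) {
  if (!any(mask)) stop("empty mask")
  mean(image$epsilon_map[mask])
}

#' Normalized left-right difference
#'
#' Difference of the two breast averages in one view, normalized to their
#' mean: `delta = (L - R) / ((L + R)/2)`.
#'
#' @param eps_left,eps_right Breast-average permittivities (> 0).
#' @return Signed normalized difference.
#' @export
normalized_difference <- function(eps_left, eps_right) {
  if (any(eps_left <= 0) || any(eps_right <= 0))
    stop("breast averages must be positive")
  (eps_left - eps_right) / ((eps_left + eps_right) / 2)
}

#' Contralateral ratio
#'
#' Ratio of the higher to the lower of the two breast averages in one view;
#' the study's detection statistic (approximately 1.05 for healthy subjects
#' and 1.15 for cancer patients in the CC view).
#'
#' @param eps_a,eps_b Breast-average permittivities (> 0).
#' @return Ratio `>= 1`.
#' @export
contralateral_ratio <- function(eps_a, eps_b) {
  if (any(eps_a <= 0) || any(eps_b <= 0))
    stop("breast averages must be positive")
  pmax(eps_a, eps_b) / pmin(eps_a, eps_b)
}

stat_result <- function(statistic, value, df1, df2, p, degenerate = FALSE) {
  structure(
    list(statistic = statistic, value = value, df1 = df1, df2 = df2,
         p_value = p, significant = is.finite(p) && p < 0.05,
         degenerate = degenerate),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g (df %s, %s), p = %.4g%s\n", x$statistic, x$value,
              format(x$df1), format(x$df2), x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA over two or more groups, fitted with
#' [stats::aov()].
#'
#' @param groups List of numeric vectors, one per group.
#' @return A `stat_result` with the F statistic, degrees of freedom and
#'   p-value. Zero within-group variance with distinct means is flagged
#'   degenerate (`F = Inf`, `p = 0`).
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (df2 < 1L) stop("no within-group degrees of freedom")
  tab <- summary(stats::aov(y ~ g))[[1L]]
  ssw <- tab["Residuals", "Sum Sq"]
  if (ssw <= .Machine$double.eps * sum(y^2) && tab["g", "Sum Sq"] > 0)
    return(stat_result("F", Inf, df1, df2, 0, degenerate = TRUE))
  stat_result("F", tab["g", "F value"], df1, df2, tab["g", "Pr(>F)"])
}

#' Pooled-variance two-sample t-test
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param two_tailed Report a two-tailed p-value (default).
#' @return A `stat_result` with t, df and p. Zero pooled variance is flagged
#'   degenerate.
#' @export
two_sample_t <- function(a, b, two_tailed = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- length(a) + length(b) - 2L
    if (mean(a) == mean(b)) return(stat_result("t", 0, df, NA, 1))
    return(stat_result("t", Inf * sign(mean(a) - mean(b)), df, NA, 0,
                       degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE,
                      alternative = if (two_tailed) "two.sided" else "greater")
  stat_result("t", unname(tt$statistic), unname(tt$parameter), NA, tt$p.value)
}

#' Two-way analysis of variance (Type-II sums of squares)
#'
#' Fits `response ~ group * view` and tests both main effects and their
#' interaction with Type-II sums of squares (via [car::Anova()]),
#' appropriate for the unbalanced healthy/cancer design.
#'
#' @param data Data frame with the response and two factor columns.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @return Data frame with one row per term (`factor_a`, `factor_b`,
#'   interaction): sum of squares, df, F and p.
#' @export
two_way_anova <- function(data, response, factor_a = "group",
                          factor_b = "view") {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("each factor needs at least 2 levels")
  cells <- table(fa, fb)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factor_a,
                 rownames(cells)[empty[1L]], factor_b,
                 colnames(cells)[empty[2L]]))
  }
  d <- data.frame(y = data[[response]], A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = d)
  an <- car::Anova(fit, type = 2)
  terms <- c("A", "B", "A:B")
  data.frame(
    term = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":")),
    sum_sq = an[terms, "Sum Sq"],
    df = an[terms, "Df"],
    F_value = an[terms, "F value"],
    p_value = an[terms, "Pr(>F)"],
    row.names = NULL
  )
}
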