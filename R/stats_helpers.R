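#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`) with input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop2("'p' must be probabilities in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-way ANOVA gated pairwise t-tests
#'
#' Performs a one-way ANOVA F-test; only if its p-value is below `alpha`
#' are all pairwise two-sided t-tests run, with Bonferroni multiplication
#' (capped at 1) over the number of comparisons performed. Groups with
#' zero variance at n = 2 trigger a warning and the Welch form is used for
#' their pairs.
#'
#' @param value numeric measurements.
#' @param group group labels (>= 2 groups, >= 2 values each).
#' @param alpha ANOVA gate, default 0.05.
#' @param welch use Welch (unequal-variance) pairwise t-tests; default
#'   TRUE.
#' @return list with `anova_p`, `performed` (logical), `pairwise`
#'   (data frame: group1, group2, p, p_bonferroni; NULL when not
#'   performed).
#' @export
anova_then_pairwise <- function(value, group, alpha = 0.05, welch = TRUE) {
  f <- factor(group)
  if (nlevels(f) < 2L) stop2("need >= 2 groups")
  if (any(table(f) < 2L)) stop2("every group needs >= 2 values")
  fit <- aov(value ~ f)
  a_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (a_p >= alpha)
    return(list(anova_p = a_p, performed = FALSE, pairwise = NULL))
  zero_var <- vapply(split(value, f), function(v) var(v) == 0, logical(1))
  if (any(zero_var & table(f) == 2))
    warn2("group(s) with zero variance at n = 2; Welch form used")
  lv <- levels(f)
  pairs <- utils::combn(lv, 2)
  rows <- apply(pairs, 2, function(pr) {
    p <- t.test(value[f == pr[1]], value[f == pr[2]],
                var.equal = !welch)$p.value
    data.frame(group1 = pr[1], group2 = pr[2], p = p)
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(tab$p * ncol(pairs), 1)
  list(anova_p = a_p, performed = TRUE, pairwise = tab)
}

#' Welch two-sample t-test p-value
#'
#' Two-sided t statistic with Satterthwaite degrees of freedom. Two
#' zero-variance groups with equal means return p = 1.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return two-sided p-value.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop2("need >= 2 values per group")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(1)
    return(0)
  }
  t.test(x, y, var.equal = FALSE)$p.value
}
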