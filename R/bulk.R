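#' Filter lowly expressed genes from bulk counts
#'
#' Keeps genes whose count strictly exceeds `min_count` in at least
#' `min_fraction` of all samples (defaults: exceeds 5 in at least 50%).
#'
#' @param counts genes x samples integer matrix.
#' @param min_count count that must be exceeded, default 5.
#' @param min_fraction minimal fraction of samples, default 0.5.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 5, min_fraction = 0.5) {
  counts <- as.matrix(counts)
  assert_fraction(min_fraction, "min_fraction")
  keep <- rowMeans(counts > min_count) >= min_fraction
  if (!any(keep)) stop2("no genes survive the expression filter")
  counts[keep, , drop = FALSE]
}

#' Log counts per million
#'
#' `y = log2((count + prior) / (libsize + 2 * prior) * 1e6)` with library
#' sizes taken as column sums. Optionally attaches simplified
#' mean-variance precision weights (a LOWESS trend of the quarter-root
#' residual standard deviation against mean log-count, used as
#' `trend^-4`); weights are off by default because the downstream
#' competitive test consumes ranking statistics.
#'
#' @param counts genes x samples matrix.
#' @param prior prior count, default 0.5.
#' @param weights logical; compute precision weights (requires
#'   `conditions`).
#' @param conditions per-sample condition labels, needed for the residual
#'   trend when `weights = TRUE`.
#' @return real matrix of log-CPM values; if `weights = TRUE`, a
#'   `"weights"` attribute of the same shape.
#' @export
logcpm <- function(counts, prior = 0.5, weights = FALSE, conditions = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop2("library sizes must be > 0")
  y <- t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
  if (weights) {
    if (is.null(conditions)) stop2("'conditions' needed for weights")
    f <- factor(conditions)
    fit <- vapply(levels(f), function(l)
      rowMeans(y[, f == l, drop = FALSE]), numeric(nrow(y)))
    resid <- y - fit[, as.integer(f)]
    df <- ncol(y) - nlevels(f)
    s <- sqrt(rowSums(resid^2) / df)
    amean <- rowMeans(y)
    lw <- stats::lowess(amean, sqrt(s), f = 0.5)
    trend <- stats::approx(lw$x, lw$y, xout = amean, rule = 2)$y
    trend <- pmax(trend, 1e-3)
    w <- matrix(rep(trend^-4, ncol(y)), nrow(y), ncol(y),
                dimnames = dimnames(y))
    attr(y, "weights") <- w
  }
  y
}

# Newton inversion of the trigamma function (solve trigamma(y) = x)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group fit
#'
#' Per gene, an ordinary two-group linear fit gives the log2 fold-change
#' `b_g`, unscaled standard error `u = sqrt(1/nA + 1/nB)`, residual sd
#' `s_g` and residual df `d_g`. The prior `(d0, s0^2)` is estimated by
#' moment matching on `log s_g^2` (digamma/trigamma inversion of the
#' scaled-F model `s_g^2 ~ s0^2 F(d_g, d0)`); posterior variances shrink
#' towards the prior as `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and the
#' moderated t is `b / (s~ u)` on `d0 + d` df.
#'
#' @param y genes x samples log-expression matrix (see [logcpm()]).
#' @param conditions per-sample condition labels.
#' @param contrast length-2 character: `c(test, reference)`; the effect is
#'   `mean(test) - mean(reference)`.
#' @param d0 optionally impose the prior df (e.g. `Inf` for complete
#'   shrinkage); `NULL` estimates it.
#' @return object of class `ranking_stats`: list with a per-gene `table`
#'   (gene, b, u, s, d, s_tilde, t, df_total) and scalars `d0`, `s02`.
#' @export
fit_moderated_t <- function(y, conditions, contrast, d0 = NULL) {
  y <- as.matrix(y)
  f <- as.character(conditions)
  if (length(contrast) != 2L || !all(contrast %in% f))
    stop2("'contrast' must name two condition levels present in 'conditions'")
  iA <- which(f == contrast[1]); iB <- which(f == contrast[2])
  nA <- length(iA); nB <- length(iB)
  if (nA < 2L || nB < 2L) stop2("need >= 2 samples per contrasted condition")
  yA <- y[, iA, drop = FALSE]; yB <- y[, iB, drop = FALSE]
  b <- rowMeans(yA) - rowMeans(yB)
  d <- nA + nB - 2L
  rss <- rowSums((yA - rowMeans(yA))^2) + rowSums((yB - rowMeans(yB))^2)
  s2 <- rss / d
  u <- sqrt(1 / nA + 1 / nB)
  bad <- !is.finite(s2) | s2 < 0
  if (any(bad)) {
    warn2(sum(bad), " gene(s) with undefined residual variance excluded")
    y <- y[!bad, , drop = FALSE]; b <- b[!bad]; s2 <- s2[!bad]
  }
  # moment matching on log s2: e = log s2 - digamma(d/2) + log(d/2)
  zero <- s2 <= 0
  if (any(zero)) s2[zero] <- min(s2[s2 > 0], 1e-8)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  if (is.null(d0)) {
    ev <- var(e) - trigamma(d / 2)
    if (!is.finite(ev) || ev <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(ev)
    }
  }
  if (is.infinite(d0)) {
    # no excess variability in log s2: complete shrinkage to the mean variance
    s02 <- mean(s2)
    s_tilde2 <- rep(s02, length(s2))
  } else {
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s_tilde2 <- (d0 * s02 + d * s2) / (d0 + d)
  }
  # total df cannot exceed the pooled residual df across all genes
  df_total <- min(d0 + d, length(s2) * d)
  if (is.infinite(d0))
    message("prior df estimated as infinite; total df capped at ",
            df_total)
  s_tilde <- sqrt(s_tilde2)
  tstat <- b / (s_tilde * u)
  structure(list(
    table = data.frame(gene = rownames(y), b = b, u = u, s = sqrt(s2),
                       d = d, s_tilde = s_tilde, t = tstat,
                       df_total = df_total, row.names = NULL),
    d0 = d0, s02 = s02, contrast = contrast), class = "ranking_stats")
}

#' Moderated t-test relative to a fold-change threshold
#'
#' Tests whether `|b_g|` exceeds `tau` (a TREAT-style threshold test):
#' with `se = s~ u`, `t_r = (|b| - tau)/se` and `t_l = (|b| + tau)/se`,
#' the p-value is `P(T > t_r) + P(T > t_l)` for `T ~ t_{d0+d}`. At
#' `tau = 0` this reduces to the ordinary two-sided moderated t-test. The
#' reported statistic is `sign(b) * t_r` — the ranking statistic used by
#' the competitive enrichment test.
#'
#' @param stats a `ranking_stats` object.
#' @param tau log2 fold-change threshold, default `log2(1.2)`.
#' @return the `ranking_stats` with columns `t_treat`, `p` added to its
#'   table; `t_treat` replaces `t` as the ranking statistic downstream.
#' @export
treat_test <- function(stats, tau = log2(1.2)) {
  stopifnot(inherits(stats, "ranking_stats"))
  if (tau < 0) stop2("'tau' must be >= 0")
  tb <- stats$table
  se <- tb$s_tilde * tb$u
  t_r <- (abs(tb$b) - tau) / se
  t_l <- (abs(tb$b) + tau) / se
  p <- pt(t_r, tb$df_total, lower.tail = FALSE) +
    pt(t_l, tb$df_total, lower.tail = FALSE)
  stats$table$t_treat <- sign(tb$b) * t_r
  stats$table$p <- pmin(p, 1)
  stats$tau <- tau
  stats
}

#' Competitive pre-ranked gene-set test
#'
#' Tests, for each signature, whether the mean per-gene ranking statistic
#' inside the set differs from the mean outside, inflating the standard
#' error by `VIF = 1 + (m - 1) * rho` to account for inter-gene
#' correlation. With pooled two-group variance `sigma^2` over all `G`
#' statistics, `z = delta / sqrt(sigma^2 (VIF/m + 1/(G-m)))` is referred
#' to a t distribution on `G - 2` df, two-sided. At `rho = 0` this is
#' exactly the pooled two-sample t-test between in-set and out-set
#' statistics.
#'
#' @param stat named numeric vector of per-gene ranking statistics (e.g.
#'   the signed TREAT statistic from [treat_test()]).
#' @param sets named list of [gene_signature()] objects.
#' @param rho assumed inter-gene correlation, default 0.01.
#' @return object of class `enrichment_table`: data frame with columns
#'   `signature`, `klass`, `size`, `delta`, `direction`, `p`.
#' @export
camera_pr <- function(stat, sets, rho = 0.01) {
  if (is.null(names(stat))) stop2("'stat' must be named by gene")
  if (rho < 0 || rho >= 1) stop2("'rho' must be in [0, 1)")
  G <- length(stat)
  rows <- list()
  for (s in sets) {
    idx <- names(stat) %in% s$genes
    m <- sum(idx)
    if (m < 2L || m >= G) {
      warn2("signature '", s$name, "' skipped (", m,
            " measured genes after intersection)")
      next
    }
    sin <- stat[idx]; sout <- stat[!idx]
    delta <- mean(sin) - mean(sout)
    sigma2 <- ((m - 1) * var(sin) + (G - m - 1) * var(sout)) / (G - 2)
    vif <- 1 + (m - 1) * rho
    se <- sqrt(sigma2 * (vif / m + 1 / (G - m)))
    z <- delta / se
    p <- 2 * pt(-abs(z), df = G - 2)
    rows[[s$name]] <- data.frame(
      signature = s$name, klass = s$klass, size = m, delta = delta,
      direction = if (delta > 0) "up" else "down", p = p)
  }
  if (length(rows) == 0L) stop2("no testable signature")
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("enrichment_table", "data.frame"))
}

#' BH adjustment and signed log10 p-values
#'
#' Adjusts the raw competitive-test p-values across all signatures tested
#' for one contrast (Benjamini-Hochberg), then reports
#' `log10(adj p) * (-1 if direction is up else +1)` so positive values
#' indicate upward enrichment. Values beyond `clip` in magnitude are
#' rounded to the nearest limit.
#'
#' @param table an `enrichment_table` from [camera_pr()].
#' @param clip positive clipping limit for `|signed log10 p|`, default 10.
#' @return the table with columns `adj_p`, `signed_log10p`,
#'   `signed_clipped` added.
#' @export
adjust_and_sign <- function(table, clip = 10) {
  stopifnot(inherits(table, "enrichment_table"))
  if (clip <= 0) stop2("'clip' must be > 0")
  table$adj_p <- p.adjust(table$p, method = "BH")
  signed <- log10(table$adj_p) * ifelse(table$direction == "up", -1, 1)
  table$signed_log10p <- signed
  table$signed_clipped <- pmin(pmax(signed, -clip), clip)
  table
}

#' Bulk signature-enrichment pipeline for one contrast
#'
#' Chains [filter_genes()], [logcpm()], [fit_moderated_t()],
#' [treat_test()], [camera_pr()] and [adjust_and_sign()].
#'
#' @param counts genes x samples count matrix.
#' @param conditions per-sample condition labels.
#' @param contrast `c(test, reference)` condition pair.
#' @param sets named list of [gene_signature()] objects.
#' @param tau,rho,clip see the stage functions.
#' @param min_count,min_fraction see [filter_genes()].
#' @return list with `stats` (`ranking_stats`) and `enrichment`
#'   (`enrichment_table`).
#' @export
enrich_bulk <- function(counts, conditions, contrast, sets,
                        tau = log2(1.2), rho = 0.01, clip = 10,
                        min_count = 5, min_fraction = 0.5) {
  filtered <- filter_genes(counts, min_count, min_fraction)
  y <- logcpm(filtered)
  st <- fit_moderated_t(y, conditions, contrast)
  st <- treat_test(st, tau = tau)
  stat <- setNames(st$table$t_treat, st$table$gene)
  enr <- camera_pr(stat, sets, rho = rho)
  enr <- adjust_and_sign(enr, clip = clip)
  list(stats = st, enrichment = enr)
}
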