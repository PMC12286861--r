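#' Binarize a barcode count matrix
#'
#' Entry is 1 iff the raw barcode count is greater than zero. All-zero
#' barcode columns are retained but reported.
#'
#' @param raw cells x barcodes non-negative count matrix.
#' @return cells x barcodes 0/1 integer matrix.
#' @export
binarize_barcodes <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop2("barcode counts must be non-negative")
  out <- (raw > 0) * 1L
  dimnames(out) <- dimnames(raw)
  empty <- colSums(out) == 0
  if (any(empty))
    warn2(sum(empty), " barcode column(s) have no detections: ",
          paste(colnames(out)[empty], collapse = ", "))
  out
}

# Firth-penalized logistic regression by Newton iteration on the
# penalized score U(b) + X' (h * (1/2 - mu)); used when plain glm
# separates. Returns list(coef, loglik_penalized, deviance_penalized).
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    XtWX <- crossprod(X, XW)
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R)) XtWX <- XtWX + diag(1e-8, ncol(X))
    # hat diagonal only: h_i = W_i x_i' (X'WX)^{-1} x_i
    h <- W * rowSums((X %*% solve(XtWX)) * X)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- solve(XtWX, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta); mu <- plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu)) +
    0.5 * determinant(crossprod(X, X * mu * (1 - mu)))$modulus
  list(coef = beta, loglik = drop(ll))
}

#' Likelihood-ratio association between barcode detection and signature
#'
#' Fits a logistic regression of the per-cell barcode-detection indicator
#' on `signature + sample` (full model) and on `sample` alone (reduced),
#' both by iteratively reweighted least squares; the p-value is the upper
#' chi-squared tail of the deviance difference on
#' `(signature levels - 1)` df. With `outcome = "any"` the indicator is
#' "any barcode detected" (the default, matching clonal-labelling
#' analyses); `outcome = barcode name` tests a single barcode.
#'
#' @param bm binarized cells x barcodes matrix (see [binarize_barcodes()]).
#' @param signature per-cell signature labels.
#' @param sample per-cell sample ids.
#' @param outcome `"any"` or one barcode column name.
#' @param firth use Firth-penalized fits (for separated data); the LRT is
#'   then on penalized likelihoods.
#' @return object of class `association_result`: list with `lrt`, `df`,
#'   `p`, `deviance_full`, `deviance_reduced`, `outcome`.
#' @export
test_signature_association <- function(bm, signature, sample,
                                       outcome = "any", firth = FALSE) {
  bm <- as.matrix(bm)
  if (!all(bm %in% c(0, 1))) stop2("'bm' must be binary; see binarize_barcodes()")
  y <- if (identical(outcome, "any")) as.integer(rowSums(bm) > 0)
       else {
         if (!outcome %in% colnames(bm)) stop2("unknown barcode: ", outcome)
         as.integer(bm[, outcome])
       }
  sig <- droplevels(factor(signature)); sam <- droplevels(factor(sample))
  if (nlevels(sig) < 2L) stop2("need >= 2 signature levels")
  one_sample <- nlevels(sam) < 2L
  df <- data.frame(y = y, signature = sig, sample = sam)
  form_full <- if (one_sample) y ~ signature else y ~ signature + sample
  form_red <- if (one_sample) y ~ 1 else y ~ sample
  if (firth) {
    Xf <- stats::model.matrix(form_full, df)
    Xr <- stats::model.matrix(form_red, df)
    ff <- firth_logistic(Xf, y); fr <- firth_logistic(Xr, y)
    lrt <- max(0, 2 * (ff$loglik - fr$loglik))
    dev_f <- -2 * ff$loglik; dev_r <- -2 * fr$loglik
  } else {
    ff <- suppressWarnings(stats::glm(form_full, binomial(), df))
    fr <- suppressWarnings(stats::glm(form_red, binomial(), df))
    if (!ff$converged || any(abs(coef(ff)) > 15, na.rm = TRUE))
      stop2("apparent complete separation in the logistic fit; retry with ",
            "firth = TRUE")
    lrt <- max(0, fr$deviance - ff$deviance)
    dev_f <- ff$deviance; dev_r <- fr$deviance
  }
  dfree <- nlevels(sig) - 1L
  structure(list(lrt = lrt, df = dfree,
                 p = pchisq(lrt, dfree, lower.tail = FALSE),
                 deviance_full = dev_f, deviance_reduced = dev_r,
                 outcome = outcome, firth = firth),
            class = "association_result")
}

#' Exact conditional test for two binomial proportions
#'
#' Conditions on the total number of successes `x = xA + xB`: under the
#' null of equal rates, `xA ~ Binomial(x, nA / (nA + nB))`. The two-sided
#' p-value sums all outcomes with probability at most that of the
#' observed one (the minimum-likelihood rule), capped at 1.
#'
#' @param xA,nA successes and trials in group A.
#' @param xB,nB successes and trials in group B.
#' @return two-sided p-value.
#' @export
binomial_proportion_test <- function(xA, nA, xB, nB) {
  if (nA <= 0 || nB <= 0) stop2("'nA' and 'nB' must be > 0")
  if (xA < 0 || xA > nA || xB < 0 || xB > nB)
    stop2("counts must satisfy 0 <= x <= n")
  x <- xA + xB
  if (x == 0) return(1)
  binom.test(xA, x, p = nA / (nA + nB))$p.value
}

#' Wilson score interval for a proportion
#'
#' `centre = (x + z^2/2) / (n + z^2)` with half-width
#' `z * sqrt(phat (1 - phat) / n + z^2 / (4 n^2)) / (1 + z^2 / n)`,
#' clipped to `[0, 1]`. With `brown = TRUE`, extreme counts
#' (`x <= 3` or `n - x <= 3`) use the one-sided Poisson (gamma) bound on
#' the affected side — the boundary modification recommended for small
#' success counts.
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `> 0`.
#' @param level confidence level, default 0.95.
#' @param brown apply the small-count boundary modification.
#' @return length-2 numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, level = 0.95, brown = FALSE) {
  if (n <= 0) stop2("'n' must be > 0")
  if (x < 0 || x > n) stop2("'x' must satisfy 0 <= x <= n")
  assert_fraction(level, "level", open0 = TRUE, open1 = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  phat <- x / n
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo <- max(0, centre - half); hi <- min(1, centre + half)
  if (brown) {
    a <- 1 - level
    if (x >= 1 && x <= 3) lo <- qgamma(a / 2, x) / n
    if ((n - x) >= 1 && (n - x) <= 3) hi <- 1 - qgamma(a / 2, n - x) / n
  }
  c(lower = lo, upper = hi)
}

#' Per-signature barcode detection proportions with Wilson intervals
#'
#' @param bm binarized cells x barcodes matrix.
#' @param signature per-cell signature labels.
#' @param level confidence level.
#' @return data frame: signature, n, detected, proportion, lower, upper.
#' @export
detection_proportions <- function(bm, signature, level = 0.95) {
  bm <- as.matrix(bm)
  det <- rowSums(bm) > 0
  out <- lapply(split(det, signature), function(d) {
    ci <- wilson_interval(sum(d), length(d), level)
    data.frame(n = length(d), detected = sum(d),
               proportion = mean(d), lower = ci[1], upper = ci[2])
  })
  cbind(data.frame(signature = names(out)),
        do.call(rbind, c(out, list(make.row.names = FALSE))))
}
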