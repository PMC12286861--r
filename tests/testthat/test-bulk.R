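test_that("gene filter keeps genes exceeding the count floor in enough samples", {
  cnt <- rbind(kept = c(6, 6, 0, 0),
               boundary = c(5, 5, 5, 5),
               low = c(1, 0, 0, 0))
  colnames(cnt) <- paste0("s", 1:4)
  out <- filter_genes(cnt)
  expect_identical(rownames(out), "kept")       # 2/4 samples exceed 5
  expect_error(filter_genes(cnt["low", , drop = FALSE]), "survive")
})

test_that("log-CPM matches the closed form and is scale-stable", {
  cnt <- matrix(c(0, 10, 100, 1e6 - 110), 4, 1,
                dimnames = list(paste0("g", 1:4), "s1"))
  y <- logcpm(cnt)
  expect_equal(y["g1", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # doubling counts and library leaves y invariant up to the prior term
  y2 <- logcpm(cnt * 2)
  expect_equal(y2[-1, 1], y[-1, 1], tolerance = 0.01)
  # weights path returns finite inverse-variance weights
  cnt2 <- matrix(rpois(600, 50), 100, 6)
  rownames(cnt2) <- paste0("g", 1:100); colnames(cnt2) <- paste0("s", 1:6)
  yw <- logcpm(cnt2, weights = TRUE, conditions = rep(c("A", "B"), each = 3))
  expect_true(all(is.finite(attr(yw, "weights"))))
})

test_that("empirical-Bayes moderation matches limma and recovers planted priors", {
  skip_if_not_installed("limma")
  set.seed(21)
  y <- matrix(rnorm(500 * 6), 500, 6,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  cond <- rep(c("A", "B"), each = 3)
  st <- fit_moderated_t(y, cond, c("A", "B"))
  des <- cbind(A = as.numeric(cond == "A"), B = as.numeric(cond == "B"))
  fit <- limma::lmFit(y, des)
  fit <- limma::contrasts.fit(fit, c(1, -1))
  eb <- limma::eBayes(fit)
  expect_equal(st$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(st$s02, eb$s2.prior, tolerance = 1e-6)
  expect_equal(unname(st$table$t), unname(eb$t[, 1]), tolerance = 1e-8)

  # parameter recovery: variances from the scaled-chi-square model
  set.seed(22)
  d0_true <- 8; s02_true <- 2; d <- 4; G <- 5000
  sigma2 <- d0_true * s02_true / rchisq(G, d0_true)
  s2 <- sigma2 * rchisq(G, d) / d
  # feed synthetic residuals through the fit: construct y with these s2
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  d0_hat <- 2 * mimetect:::trigamma_inverse(ev)
  s02_hat <- exp(mean(e) + digamma(d0_hat / 2) - log(d0_hat / 2))
  expect_lt(abs(d0_hat - d0_true) / d0_true, 0.15)
  expect_lt(abs(s02_hat - s02_true) / s02_true, 0.15)

  # degenerate: equal variances push the prior df to infinity
  yk <- matrix(rnorm(6 * 6), 6, 6, dimnames = list(paste0("g", 1:6), NULL))
  yk <- yk - rowMeans(yk[, 1:3]) %o% c(1, 1, 1, 0, 0, 0) -
    rowMeans(yk[, 4:6]) %o% c(0, 0, 0, 1, 1, 1)
  scale_to <- sqrt(2 / rowSums(yk^2))
  yk <- yk * scale_to
  stc <- fit_moderated_t(yk + 1, cond, c("A", "B"))
  expect_identical(stc$d0, Inf)
  expect_equal(unname(stc$table$s_tilde^2), rep(stc$s02, 6), tolerance = 1e-9)
  # imposed d0 = Inf collapses every variance to the prior
  sti <- fit_moderated_t(y, cond, c("A", "B"), d0 = Inf)
  expect_true(all(abs(sti$table$s_tilde^2 - sti$s02) < 1e-12))
})

test_that("threshold test reduces to the moderated t at tau 0 and matches quadrature", {
  skip_if_not_installed("limma")
  set.seed(23)
  y <- matrix(rnorm(300 * 8), 300, 8,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:8)))
  cond <- rep(c("A", "B"), each = 4)
  st0 <- treat_test(fit_moderated_t(y, cond, c("A", "B")), tau = 0)
  p_plain <- 2 * pt(-abs(st0$table$t), st0$table$df_total)
  expect_lt(max(abs(st0$table$p - p_plain)), 1e-12)

  # limma::treat agreement at the default threshold
  des <- cbind(A = as.numeric(cond == "A"), B = as.numeric(cond == "B"))
  fit <- limma::contrasts.fit(limma::lmFit(y, des), c(1, -1))
  tr <- limma::treat(fit, lfc = log2(1.2))
  st <- treat_test(fit_moderated_t(y, cond, c("A", "B")), tau = log2(1.2))
  expect_equal(unname(st$table$p), unname(tr$p.value[, 1]), tolerance = 1e-10)

  # single-gene case against numeric integration of the t density
  b <- 1; se <- 0.25; df <- 10; tau <- 0.263
  t_r <- (abs(b) - tau) / se; t_l <- (abs(b) + tau) / se
  q1 <- integrate(function(u) dt(u, df), t_r, Inf, rel.tol = 1e-12)$value
  q2 <- integrate(function(u) dt(u, df), t_l, Inf, rel.tol = 1e-12)$value
  expect_equal(t_r, 2.948, tolerance = 1e-3)
  expect_equal(t_l, 5.052, tolerance = 1e-3)
  stats1 <- structure(list(table = data.frame(
    gene = "g", b = b, u = 1, s = se, d = df, s_tilde = se, t = b / se,
    df_total = df)), class = "ranking_stats")
  out <- treat_test(stats1, tau = tau)
  expect_equal(out$table$p, q1 + q2, tolerance = 1e-10)
  # p non-decreasing in tau
  taus <- seq(0, 1, by = 0.1)
  ps <- vapply(taus, function(tv) treat_test(stats1, tv)$table$p, numeric(1))
  expect_true(all(diff(ps) >= -1e-15))
})

test_that("competitive set test matches its reduction oracles and limma", {
  set.seed(25)
  stat <- setNames(rnorm(200), paste0("g", 1:200))
  sets <- list(gene_signature("up", paste0("g", 1:20)))
  # rho = 0 reduces to a pooled two-sample t-test
  cp0 <- camera_pr(stat, sets, rho = 0)
  tt <- t.test(stat[1:20], stat[21:200], var.equal = TRUE)
  expect_lt(abs(cp0$p - tt$p.value), 1e-10)
  # invariance to adding a constant
  cp_shift <- camera_pr(stat + 5, sets, rho = 0)
  expect_equal(cp0$p, cp_shift$p, tolerance = 1e-10)
  # manual formula trace on the 8-statistic example
  s8 <- setNames(c(2.0, 1.5, 0.1, -0.2, 0.3, -1.0, 0.05, -0.3),
                 paste0("g", 1:8))
  set8 <- list(gene_signature("s", c("g1", "g2")))
  m <- 2; G <- 8; rho <- 0.01
  delta <- mean(s8[1:2]) - mean(s8[3:8])
  sigma2 <- ((m - 1) * var(s8[1:2]) + (G - m - 1) * var(s8[3:8])) / (G - 2)
  se <- sqrt(sigma2 * ((1 + (m - 1) * rho) / m + 1 / (G - m)))
  p_hand <- 2 * pt(-abs(delta / se), G - 2)
  expect_equal(camera_pr(s8, set8, rho = 0.01)$p, p_hand, tolerance = 1e-12)
  # delta = 0 exactly -> p = 1
  sym <- setNames(c(1, -1, 1, -1, 2, -2), paste0("g", 1:6))
  cps <- camera_pr(sym, list(gene_signature("z", c("g1", "g2"))), rho = 0)
  expect_equal(cps$p, 1)
  skip_if_not_installed("limma")
  lp <- limma::cameraPR(stat, list(up = paste0("g", 1:20)),
                        inter.gene.cor = 0.01)
  expect_equal(camera_pr(stat, sets, rho = 0.01)$p, lp$PValue, tolerance = 1e-10)
  # undersized sets are skipped with a warning
  expect_warning(
    camera_pr(stat, list(gene_signature("tiny", "g1"),
                         gene_signature("ok", paste0("g", 1:5)))),
    "skipped")
})

test_that("BH signing and clipping follow the reporting conventions", {
  tb <- structure(data.frame(
    signature = c("a", "b", "c", "d"), klass = "mimetic", size = 10,
    delta = c(1, -1, 1, -1), direction = c("up", "down", "up", "down"),
    p = c(0.01, 0.02, 0.03, 0.04)),
    class = c("enrichment_table", "data.frame"))
  out <- adjust_and_sign(tb, clip = 10)
  expect_equal(out$adj_p, rep(0.04, 4))  # BH step-up on (.01,.02,.03,.04)
  expect_equal(out$signed_log10p,
               log10(0.04) * c(-1, 1, -1, 1))
  # adj p = 1 maps to 0 either direction
  tb1 <- tb; tb1$p <- rep(1, 4)
  expect_true(all(adjust_and_sign(tb1)$signed_log10p == 0))
  # clipping
  tb2 <- tb; tb2$p <- c(1e-15, 0.5, 0.5, 0.5)
  out2 <- adjust_and_sign(tb2, clip = 10)
  expect_equal(out2$signed_clipped[1], 10)
  expect_gt(out2$signed_log10p[1], 10)  # unclipped exceeds the limit
  # single hypothesis: BH leaves p unchanged
  expect_equal(adjust_and_sign(tb[1, ])$adj_p, 0.01)
})
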