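# Dirichlet-multinomial log-likelihood, vectorized over samples.
# theta = c(alpha[-ref], beta[-ref][free], log_gamma); x = 0/1 condition
# indicator per sample; free_beta: logical over non-reference types
# (FALSE = beta fixed at 0)
dm_loglik <- function(theta, counts, x, ref, free_beta) {
  K <- ncol(counts)
  nf <- K - 1L
  alpha <- numeric(K); beta <- numeric(K)
  alpha[-ref] <- theta[seq_len(nf)]
  beta[-ref][free_beta] <- theta[nf + seq_len(sum(free_beta))]
  gamma <- exp(theta[length(theta)])
  eta <- outer(x, beta) + rep(alpha, each = length(x))   # samples x K
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta) / rowSums(exp(eta))
  A <- gamma * p
  n <- rowSums(counts)
  sum(lgamma(gamma) - lgamma(n + gamma)) +
    sum(lgamma(counts + A) - lgamma(A))
}

# analytic gradient of dm_loglik in the same parameterization
dm_grad <- function(theta, counts, x, ref, free_beta) {
  K <- ncol(counts)
  nf <- K - 1L
  alpha <- numeric(K); beta <- numeric(K)
  alpha[-ref] <- theta[seq_len(nf)]
  beta[-ref][free_beta] <- theta[nf + seq_len(sum(free_beta))]
  gamma <- exp(theta[length(theta)])
  eta <- outer(x, beta) + rep(alpha, each = length(x))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta) / rowSums(exp(eta))
  A <- gamma * p
  Tm <- digamma(counts + A) - digamma(A)          # samples x K
  pT <- rowSums(p * Tm)
  deta <- gamma * p * (Tm - pT)                   # dLL/deta, samples x K
  dalpha <- colSums(deta)[-ref]
  dbeta <- colSums(deta * x)[-ref][free_beta]
  n <- rowSums(counts)
  dlg <- gamma * sum(digamma(gamma) - digamma(n + gamma) + pT)
  c(dalpha, dbeta, dlg)
}

fit_dm_optim <- function(counts, x, ref, free_beta, n_restarts = 3L,
                         seed = 1L, warm = NULL) {
  K <- ncol(counts)
  nf <- K - 1L
  npar <- nf + sum(free_beta) + 1L
  # empirical-logit start for alpha
  props <- sweep(counts + 0.5, 1, rowSums(counts + 0.5), "/")
  mp <- colMeans(props)
  alpha0 <- log(mp / mp[ref])
  starts <- list(c(alpha0[-ref], rep(0, sum(free_beta)), log(20)))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  set.seed(derive_seed(seed, "dm_restarts"))
  for (r in seq_len(n_restarts - 1L))
    starts[[length(starts) + 1L]] <-
      c(alpha0[-ref] + rnorm(nf, 0, 0.3),
        rnorm(sum(free_beta), 0, 0.3),
        log(20) + rnorm(1, 0, 1))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, function(th) -dm_loglik(th, counts, x, ref, free_beta),
            gr = function(th) -dm_grad(th, counts, x, ref, free_beta),
            method = "L-BFGS-B",
            lower = c(rep(-15, npar - 1L), log(1e-2)),
            upper = c(rep(15, npar - 1L), log(1e6)),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop2("Dirichlet-multinomial fit failed to converge after ", n_restarts,
          " restarts (reference '", colnames(counts)[ref], "')")
  best
}

#' Dirichlet-multinomial compositional fit with one reference type
#'
#' Models per-sample cell-type counts as Dirichlet-multinomial with
#' composition `p_k(x) proportional to exp(alpha_k + beta_k x)` (the
#' reference type fixed at `alpha_r = beta_r = 0`) and precision `gamma`,
#' where `x` is the 0/1 condition indicator. Each non-reference type's
#' condition effect is tested by a likelihood-ratio test of `beta_k = 0`
#' (constrained refit), BH-adjusted across types; a type is flagged
#' changed at adjusted p below `fdr`.
#'
#' @param counts samples x cell-types integer matrix (row sums > 0).
#' @param condition per-sample factor with exactly 2 levels; the second
#'   level is coded `x = 1`.
#' @param reference cell-type column name used as reference.
#' @param fdr FDR level for the changed flag, default 0.05.
#' @param seed seed for optimizer restarts.
#' @return object of class `composition_fit`: list with `table` (type,
#'   alpha, beta, lrt, p, adj_p, changed), `gamma`, `reference`,
#'   `loglik`.
#' @export
fit_dm <- function(counts, condition, reference, fdr = 0.05, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) <= 0)) stop2("every sample needs > 0 cells")
  f <- factor(condition)
  if (nlevels(f) != 2L) stop2("'condition' must have exactly 2 levels")
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warn2("cell type(s) absent in all samples excluded: ",
          paste(colnames(counts)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
  }
  if (!reference %in% colnames(counts))
    stop2("reference '", reference, "' not among cell types")
  ref <- match(reference, colnames(counts))
  K <- ncol(counts)
  x <- as.integer(f) - 1L
  free_all <- rep(TRUE, K - 1L)
  full <- fit_dm_optim(counts, x, ref, free_all, seed = seed)
  ll_full <- -full$value
  nf <- K - 1L
  alpha <- beta <- numeric(K)
  alpha[-ref] <- full$par[seq_len(nf)]
  beta[-ref] <- full$par[nf + seq_len(nf)]
  gamma <- exp(full$par[length(full$par)])
  types <- colnames(counts)
  lrt <- p <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (k == ref) next
    fb <- free_all
    pos <- match(k, setdiff(seq_len(K), ref))
    fb[pos] <- FALSE
    warm <- full$par[-(nf + pos)]
    red <- fit_dm_optim(counts, x, ref, fb, seed = seed + k, warm = warm)
    lrt[k] <- max(0, 2 * (ll_full - (-red$value)))
    p[k] <- pchisq(lrt[k], df = 1, lower.tail = FALSE)
  }
  adj <- rep(NA_real_, K)
  adj[-ref] <- p.adjust(p[-ref], method = "BH")
  structure(list(
    table = data.frame(type = types, alpha = alpha, beta = beta,
                       lrt = lrt, p = p, adj_p = adj,
                       changed = !is.na(adj) & adj < fdr, row.names = NULL),
    gamma = gamma, reference = reference, loglik = ll_full,
    fdr = fdr), class = "composition_fit")
}

#' Multi-reference compositional consensus
#'
#' Runs [fit_dm()] once per candidate reference and declares a cell type
#' overall changed only when a strict majority of the successful
#' reference models flag it. The final reference is the one whose model
#' flags the fewest changes (ties broken lexically, with a message) —
#' the most conservative anchor for reporting.
#'
#' @param counts samples x cell-types integer matrix.
#' @param condition per-sample 2-level factor.
#' @param references character vector (>= 2) of candidate reference types.
#' @param fdr,seed passed to [fit_dm()].
#' @return object of class `composition_consensus`: list with `table`
#'   (type, n_flagged, n_models, overall_changed), `fits` (per-reference
#'   `composition_fit`s), `final_reference`.
#' @export
consensus_over_references <- function(counts, condition, references,
                                      fdr = 0.05, seed = 1L) {
  counts <- as.matrix(counts)
  if (length(references) < 2L) stop2("need >= 2 candidate references")
  fits <- list()
  for (r in references) {
    fit <- tryCatch(fit_dm(counts, condition, r, fdr = fdr, seed = seed),
                    error = function(e) {
                      warn2("reference '", r, "' dropped: ",
                            conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) fits[[r]] <- fit
  }
  if (length(fits) < 2L) stop2("fewer than 2 reference fits succeeded")
  types <- colnames(counts)
  n_models <- length(fits)
  flags <- sapply(fits, function(f)
    setNames(f$table$changed, f$table$type)[types])
  flags[is.na(flags)] <- FALSE
  n_flagged <- rowSums(flags)
  overall <- n_flagged > n_models / 2
  n_changes <- vapply(fits, function(f) sum(f$table$changed, na.rm = TRUE),
                      integer(1))
  cand <- names(fits)[n_changes == min(n_changes)]
  if (length(cand) > 1L)
    message("final-reference tie broken lexically among: ",
            paste(sort(cand), collapse = ", "))
  structure(list(
    table = data.frame(type = types, n_flagged = n_flagged,
                       n_models = n_models, overall_changed = overall,
                       row.names = NULL),
    fits = fits, final_reference = sort(cand)[1]),
    class = "composition_consensus")
}

#' Aggregate cell calls into a samples x cell-types count table
#'
#' @param calls a `call_result` (see [call_cells()]).
#' @param sample per-cell sample labels, aligned with `calls$calls$cell`.
#' @return samples x cell-types integer matrix.
#' @export
composition_counts <- function(calls, sample) {
  stopifnot(inherits(calls, "call_result"))
  tab <- table(sample = sample, type = calls$calls$label)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}
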