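#' Rank genes within each cell
#'
#' Converts a cells x genes count matrix into per-cell descending
#' expression ranks (1 = highest expression). Ties — ubiquitous in sparse
#' UMI data — are broken by a seeded random permutation, so each cell's
#' ranks are an exact permutation of `1..G` and reruns with the same seed
#' are identical.
#'
#' @param counts cells x genes non-negative matrix (dense or sparse).
#' @param tie_seed integer seed for tie-breaking.
#' @return object of class `ranked_expression`: list with `ranks`
#'   (cells x genes integer matrix), `tie_seed`, `n_genes`.
#' @export
rank_genes_per_cell <- function(counts, tie_seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop2("'counts' must be non-negative")
  n <- nrow(counts); G <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell_%05d", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene_%04d", seq_len(G))
  zero_cells <- rowSums(counts) == 0
  if (any(zero_cells))
    warn2(sum(zero_cells), " cell(s) have all-zero counts; their ranks are ",
          "pure tie-break noise")
  set.seed(derive_seed(tie_seed, "rank_ties"))
  ranks <- matrix(0L, n, G, dimnames = dimnames(counts))
  for (i in seq_len(n)) {
    ord <- order(-counts[i, ], sample.int(G))
    ranks[i, ord] <- seq_len(G)
  }
  structure(list(ranks = ranks, tie_seed = as.integer(tie_seed), n_genes = G),
            class = "ranked_expression")
}

# area under the recovery curve for one signature, normalized by the
# maximal achievable area; positions = signature-gene ranks for one cell
auc_from_positions <- function(positions, K, n_s) {
  hit <- positions[positions <= K]
  num <- sum(K - hit + 1)
  den <- if (K >= n_s) n_s * (n_s + 1) / 2 + n_s * (K - n_s)
         else K * (K + 1) / 2
  num / den
}

#' Rank-AUC score of a signature in each cell
#'
#' The AUCell-style statistic: for each cell, the recovery curve
#' `R(k) = #\{signature genes with rank <= k\}` is accumulated over the top
#' `K = ceiling(top_fraction * G)` ranks and its area is normalized by the
#' maximal achievable area (all measured signature genes occupying the top
#' ranks). The score is 1 when every measured signature gene sits in the
#' top `n_s` ranks, and 0 when none is in the top `K`.
#'
#' @param ranks a [rank_genes_per_cell()] result.
#' @param sig a [gene_signature()].
#' @param top_fraction fraction of the ranking considered, default 0.05.
#' @return numeric vector of per-cell AUCs in `[0, 1]`, named by cell.
#' @export
score_auc <- function(ranks, sig, top_fraction = 0.05) {
  stopifnot(inherits(ranks, "ranked_expression"))
  assert_fraction(top_fraction, "top_fraction", open0 = TRUE)
  G <- ranks$n_genes
  K <- as.integer(ceiling(top_fraction * G))
  measured <- intersect(sig$genes, colnames(ranks$ranks))
  if (length(measured) == 0L)
    stop2("no gene of signature '", sig$name, "' is measured")
  pos <- ranks$ranks[, measured, drop = FALSE]
  n_s <- length(measured)
  apply(pos, 1L, auc_from_positions, K = K, n_s = n_s)
}

#' Score a collection of signatures in every cell
#'
#' Convenience wrapper: ranks genes once, scores every signature, and
#' attaches the z-standardized companion matrix.
#'
#' @param counts cells x genes count matrix.
#' @param signatures named list of [gene_signature()] objects.
#' @param top_fraction see [score_auc()].
#' @param tie_seed see [rank_genes_per_cell()].
#' @return object of class `score_table`: list with `auc` and `z`
#'   (cells x signatures matrices), `top_fraction`, `n_genes`, `n_s`
#'   (measured signature sizes), `tie_seed`.
#' @export
score_signatures <- function(counts, signatures, top_fraction = 0.05,
                             tie_seed = 1L) {
  ranks <- rank_genes_per_cell(counts, tie_seed = tie_seed)
  auc <- vapply(signatures, function(s) score_auc(ranks, s, top_fraction),
                numeric(nrow(ranks$ranks)))
  if (is.null(dim(auc))) auc <- matrix(auc, nrow = 1,
                                       dimnames = list(rownames(ranks$ranks),
                                                       names(signatures)))
  n_s <- vapply(signatures, function(s)
    length(intersect(s$genes, colnames(ranks$ranks))), integer(1))
  out <- structure(list(auc = auc, z = NULL, top_fraction = top_fraction,
                        n_genes = ranks$n_genes, n_s = n_s,
                        tie_seed = as.integer(tie_seed)),
                   class = "score_table")
  standardize_scores(out)
}

#' Z-standardize a score table
#'
#' Per signature (column), centres by the mean AUC across cells and scales
#' by the population (divide-by-n) standard deviation. Constant columns
#' get z = 0 with a warning. Idempotent: re-standardizing replaces `z`
#' from the unchanged `auc`.
#'
#' @param scores a `score_table`.
#' @return the `score_table` with its `z` matrix filled in.
#' @export
standardize_scores <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  auc <- scores$auc
  if (nrow(auc) < 2L) stop2("need at least 2 cells to standardize")
  n <- nrow(auc)
  mu <- colMeans(auc)
  sdp <- sqrt(colMeans(sweep(auc, 2, mu)^2))  # population sd
  zero <- sdp <= 0
  if (any(zero))
    warn2("constant AUC column(s) ", paste(colnames(auc)[zero], collapse = ", "),
          "; z set to 0")
  sdp[zero] <- 1
  z <- sweep(sweep(auc, 2, mu), 2, sdp, "/")
  z[, zero] <- 0
  scores$z <- z
  scores
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d cells x %d signatures (top_fraction %.3f, G = %d)\n",
              nrow(x$auc), ncol(x$auc), x$top_fraction, x$n_genes))
  invisible(x)
}
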