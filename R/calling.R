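#' Apply manual AUC thresholds
#'
#' A cell is eligible for a signature iff its AUC is at or above that
#' signature's threshold (closed boundary). Thresholds are chosen manually
#' from per-signature AUC histograms (see [plot_auc_histograms()]); every
#' scored signature must have one.
#'
#' @param scores a `score_table`.
#' @param thresholds named numeric vector of per-signature minimal AUCs in
#'   `[0, 1]`.
#' @return logical cells x signatures eligibility matrix.
#' @export
apply_thresholds <- function(scores, thresholds) {
  stopifnot(inherits(scores, "score_table"))
  sigs <- colnames(scores$auc)
  extra <- setdiff(names(thresholds), sigs)
  if (length(extra))
    warn2("threshold(s) for unscored signature(s) ignored: ",
          paste(extra, collapse = ", "))
  miss <- setdiff(sigs, names(thresholds))
  if (length(miss))
    stop2("no threshold for signature(s): ", paste(miss, collapse = ", "))
  if (any(thresholds < 0 | thresholds > 1))
    stop2("thresholds must lie in [0, 1]")
  elig <- sweep(scores$auc, 2, thresholds[sigs], ">=")
  storage.mode(elig) <- "logical"
  elig
}

#' Resolve multi-signature cells to one exclusive label
#'
#' For each cell with at least one eligible signature, computes the cell's
#' quantile rank within each eligible signature's AUC distribution — the
#' fraction of all cells with strictly smaller AUC, i.e. how far right the
#' cell sits on that signature's histogram — and picks the signature with
#' the highest quantile. Ties go to the larger z-standardized AUC; any
#' remaining exact tie is broken by lexical signature order with a
#' warning. Cells with no eligible signature are `"unassigned"`.
#'
#' @param scores a `score_table`.
#' @param eligibility logical matrix from [apply_thresholds()].
#' @return object of class `call_result`: list with `calls` (data frame:
#'   cell, label, quantile, z, n_eligible) and `eligibility`.
#' @export
disambiguate_calls <- function(scores, eligibility) {
  stopifnot(inherits(scores, "score_table"))
  if (!identical(dim(eligibility), dim(scores$auc)))
    stop2("eligibility matrix not conformal with scores")
  auc <- scores$auc; z <- scores$z
  n <- nrow(auc)
  # quantile rank: fraction of cells with strictly smaller AUC, per column
  qr <- apply(auc, 2L, function(col) (rank(col, ties.method = "min") - 1) / n)
  rownames(qr) <- rownames(auc)
  labels <- rep("unassigned", n)
  best_q <- best_z <- rep(NA_real_, n)
  lex_ties <- 0L
  for (i in seq_len(n)) {
    el <- which(eligibility[i, ])
    if (length(el) == 0L) next
    q <- qr[i, el]
    top <- el[q == max(q)]
    if (length(top) > 1L) {
      zi <- z[i, top]
      top <- top[zi == max(zi)]
      if (length(top) > 1L) {
        lex_ties <- lex_ties + 1L
        top <- top[order(colnames(auc)[top])]
      }
    }
    j <- top[1L]
    labels[i] <- colnames(auc)[j]
    best_q[i] <- qr[i, j]; best_z[i] <- z[i, j]
  }
  if (lex_ties > 0L)
    warn2(lex_ties, " cell(s) resolved by lexical signature order")
  structure(list(
    calls = data.frame(cell = rownames(auc), label = labels,
                       quantile = best_q, z = best_z,
                       n_eligible = rowSums(eligibility),
                       row.names = NULL),
    eligibility = eligibility), class = "call_result")
}

#' Collapse signature labels into unified populations
#'
#' Renames labels inside each merge group to the group label (e.g.
#' `Tuft1`/`Tuft2` to `Tuft`, `Skin_basal`/`Skin_keratinized` to `Skin`,
#' whose thresholded calls identify overlapping cell sets). Cell counts
#' are conserved.
#'
#' @param calls a `call_result`.
#' @param merge_groups named list: group label -> character vector of
#'   member labels. Groups must be disjoint.
#' @return the `call_result` with labels renamed.
#' @export
merge_signatures <- function(calls, merge_groups = list()) {
  stopifnot(inherits(calls, "call_result"))
  if (length(merge_groups) == 0L) return(calls)
  members <- unlist(merge_groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop2("merge groups overlap: ",
          paste(unique(members[duplicated(members)]), collapse = ", "))
  map <- rep(names(merge_groups), lengths(merge_groups))
  names(map) <- members
  hit <- calls$calls$label %in% members
  calls$calls$label[hit] <- map[calls$calls$label[hit]]
  calls
}

#' Score, threshold, disambiguate and merge in one call
#'
#' @param counts cells x genes count matrix.
#' @param signatures named list of [gene_signature()] objects.
#' @param thresholds named per-signature AUC thresholds.
#' @param merge_groups see [merge_signatures()].
#' @param top_fraction,tie_seed see [score_signatures()].
#' @return a `call_result` with the `score_table` attached as `$scores`.
#' @export
call_cells <- function(counts, signatures, thresholds, merge_groups = list(),
                       top_fraction = 0.05, tie_seed = 1L) {
  scores <- score_signatures(counts, signatures, top_fraction, tie_seed)
  elig <- apply_thresholds(scores, thresholds)
  res <- disambiguate_calls(scores, elig)
  res <- merge_signatures(res, merge_groups)
  res$scores <- scores
  res
}

#' Proportion of cells with detectable expression of a gene
#'
#' A gene is detectable in a cell iff its count is greater than zero. The
#' 95% interval is the Wilson score interval.
#'
#' @param counts cells x genes count matrix.
#' @param cells character or integer subset of cells (non-empty).
#' @param gene single gene id present in `counts`.
#' @param level confidence level, default 0.95.
#' @return list with `proportion`, `lower`, `upper`, `n`, `x`.
#' @export
expression_proportion <- function(counts, cells, gene, level = 0.95) {
  counts <- as.matrix(counts)
  if (!gene %in% colnames(counts)) stop2("gene '", gene, "' not in matrix")
  sub <- counts[cells, gene, drop = TRUE]
  if (length(sub) == 0L) stop2("empty cell subset")
  x <- sum(sub > 0); n <- length(sub)
  ci <- wilson_interval(x, n, level = level)
  list(proportion = x / n, lower = unname(ci[1]), upper = unname(ci[2]),
       n = n, x = x)
}

#' Per-signature AUC histograms to support manual threshold choice
#'
#' @param scores a `score_table`.
#' @param file optional SVG path; when given the panel is written there.
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @return invisibly, the list of `hist` objects.
#' @export
plot_auc_histograms <- function(scores, file = NULL, breaks = 50) {
  stopifnot(inherits(scores, "score_table"))
  sigs <- colnames(scores$auc)
  if (!is.null(file)) grDevices::svg(file, width = 10,
                                     height = 2.5 * ceiling(length(sigs) / 4))
  op <- graphics::par(mfrow = c(ceiling(length(sigs) / 4), min(4, length(sigs))),
                      mar = c(3, 3, 2, 0.5))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  out <- lapply(sigs, function(s)
    graphics::hist(scores$auc[, s], breaks = breaks, main = s,
                   xlab = "AUC", col = "grey80", border = NA))
  invisible(out)
}
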