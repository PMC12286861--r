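#' MAD-based droplet QC filter
#'
#' Excludes droplets with low total UMI (strictly below `umi_min`), high
#' mitochondrial fraction (strictly above `mito_max`), or detected-gene
#' counts / complexity (detected genes over total UMI) beyond the stated
#' number of raw (unscaled) median absolute deviations from the median.
#' Medians and MADs are computed per sample when a `sample` column is
#' present. A zero MAD skips that rule with a warning.
#'
#' @param qc data frame with columns `total_umi`, `mito_fraction`,
#'   `detected_genes`, and optionally `sample` and `cell`.
#' @param umi_min minimal total UMI (default 500; `< 500` excluded).
#' @param mito_max maximal mitochondrial fraction (default 0.05; `> 5%`
#'   excluded).
#' @param genes_mads MADs allowed for detected genes, default 1.
#' @param complexity_mads MADs allowed for complexity, default 3.
#' @param scaled_mad use the 1.4826 normal-consistency factor; default
#'   FALSE (raw MAD).
#' @return the input with columns `complexity`, `pass_umi`, `pass_mito`,
#'   `pass_genes`, `pass_complexity`, `keep` added.
#' @export
mad_filter <- function(qc, umi_min = 500, mito_max = 0.05, genes_mads = 1,
                       complexity_mads = 3, scaled_mad = FALSE) {
  need <- c("total_umi", "mito_fraction", "detected_genes")
  miss <- setdiff(need, names(qc))
  if (length(miss)) stop2("'qc' lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(qc$total_umi)) || any(!is.finite(qc$mito_fraction)) ||
      any(!is.finite(qc$detected_genes)))
    stop2("QC covariates must be finite")
  qc$complexity <- qc$detected_genes / qc$total_umi
  grp <- if ("sample" %in% names(qc)) qc$sample else rep("all", nrow(qc))
  cst <- if (scaled_mad) 1.4826 else 1
  qc$pass_umi <- qc$total_umi >= umi_min
  qc$pass_mito <- qc$mito_fraction <= mito_max
  qc$pass_genes <- TRUE
  qc$pass_complexity <- TRUE
  for (g in unique(grp)) {
    idx <- grp == g
    for (var in c("detected_genes", "complexity")) {
      v <- qc[[var]][idx]
      med <- median(v)
      madv <- median(abs(v - med)) * cst
      nm <- if (var == "detected_genes") "pass_genes" else "pass_complexity"
      k <- if (var == "detected_genes") genes_mads else complexity_mads
      if (madv <= 0) {
        warn2("MAD of ", var, " is 0 in sample '", g, "'; rule skipped")
        next
      }
      qc[[nm]][idx] <- abs(v - med) <= k * madv
    }
  }
  qc$keep <- qc$pass_umi & qc$pass_mito & qc$pass_genes & qc$pass_complexity
  qc
}

# total within-cluster sum of squares of an embedding under given labels
wcss <- function(embedding, labels) {
  sum(vapply(split(seq_len(nrow(embedding)), labels), function(idx) {
    sub <- embedding[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

#' Silhouette sweep over candidate clusterings
#'
#' Computes the mean silhouette width (Euclidean distances in the
#' embedding; singleton clusters take silhouette 0, with a warning) and
#' the total within-cluster sum of squares for each candidate clustering,
#' and selects the clustering maximizing mean silhouette.
#'
#' @param embedding cells x dims numeric matrix.
#' @param clusterings named list of per-cell label vectors (unique names;
#'   every clustering needs >= 2 clusters).
#' @return object of class `clustering_eval`: list with `table`
#'   (parameter, k, mean_silhouette, wcss), `selected` (name of the best
#'   clustering), `labels` (the selected labels).
#' @export
silhouette_sweep <- function(embedding, clusterings) {
  embedding <- as.matrix(embedding)
  if (is.null(names(clusterings)) || anyDuplicated(names(clusterings)))
    stop2("'clusterings' must have unique names")
  D <- dist(embedding)
  rows <- lapply(names(clusterings), function(nm) {
    lab <- clusterings[[nm]]
    if (length(lab) != nrow(embedding))
      stop2("clustering '", nm, "' has wrong length")
    f <- factor(lab)
    if (nlevels(f) < 2L)
      stop2("clustering '", nm, "' has fewer than 2 clusters")
    if (any(table(f) == 1L))
      warn2("clustering '", nm, "' has singleton cluster(s); silhouette 0 used")
    sil <- cluster::silhouette(as.integer(f), D)
    data.frame(parameter = nm, k = nlevels(f),
               mean_silhouette = mean(sil[, "sil_width"]),
               wcss = wcss(embedding, f))
  })
  tab <- do.call(rbind, rows)
  best <- tab$parameter[which.max(tab$mean_silhouette)]
  structure(list(table = tab, selected = best,
                 labels = clusterings[[best]]),
            class = "clustering_eval")
}

#' Baseline k-means clusterings for a parameter sweep
#'
#' @param embedding cells x dims matrix.
#' @param ks integer vector of cluster counts.
#' @param seed seed for k-means initialisation.
#' @return named list of label vectors (names `k<k>`), suitable for
#'   [silhouette_sweep()].
#' @export
kmeans_sweep <- function(embedding, ks = 2:8, seed = 1L) {
  set.seed(derive_seed(seed, "kmeans"))
  out <- lapply(ks, function(k)
    kmeans(embedding, centers = k, nstart = 10)$cluster)
  setNames(out, paste0("k", ks))
}
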