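#' Construct a gene signature
#'
#' @param name signature label (unique within a collection).
#' @param genes character vector of gene ids (non-empty; deduplicated).
#' @param klass signature class: `"canonical"` (TEC compartment),
#'   `"mimetic"`, or `"background"` (unrelated cell types used as a
#'   specificity control).
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes,
                           klass = c("mimetic", "canonical", "background")) {
  klass <- match.arg(klass)
  genes <- unique(as.character(genes))
  if (length(genes) < 1L) stop2("'genes' must be non-empty")
  structure(list(name = as.character(name), genes = genes, klass = klass),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s [%s], %d genes\n",
              x$name, x$klass, length(x$genes)))
  invisible(x)
}

#' Derive population signatures from a differential-expression table
#'
#' Filters a per-population DE table to the genes passing all three
#' criteria: adjusted P strictly below `max_adj_p`, absolute log2
#' fold-change strictly above `min_abs_log2fc`, and expression in at least
#' `min_pct` of the population's cells. One signature per population;
#' populations with no surviving gene are dropped with a warning.
#'
#' @param de data frame with columns `gene`, `log2fc`, `adj_p`,
#'   `pct_expressed`, `population`.
#' @param max_adj_p,min_abs_log2fc,min_pct filtering thresholds; the
#'   defaults (0.01, 1, 0.10) are the standard marker-derivation settings.
#' @param klass class tag applied to the derived signatures.
#' @return named list of [gene_signature()] objects.
#' @export
derive_signatures <- function(de, max_adj_p = 0.01, min_abs_log2fc = 1,
                              min_pct = 0.10, klass = "mimetic") {
  if (!is.data.frame(de) || nrow(de) == 0L)
    stop2("'de' must be a non-empty data frame")
  need <- c("gene", "log2fc", "adj_p", "pct_expressed", "population")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop2("'de' lacks column(s): ", paste(miss, collapse = ", "))
  assert_fraction(max_adj_p, "max_adj_p", open0 = TRUE)
  assert_fraction(min_pct, "min_pct")
  if (!is.finite(min_abs_log2fc) || min_abs_log2fc < 0)
    stop2("'min_abs_log2fc' must be >= 0")
  if (any(de$adj_p < 0 | de$adj_p > 1)) stop2("adj_p outside [0, 1]")
  keep <- de$adj_p < max_adj_p & abs(de$log2fc) > min_abs_log2fc &
    de$pct_expressed >= min_pct
  out <- list()
  for (pop in unique(de$population)) {
    g <- de$gene[keep & de$population == pop]
    if (anyDuplicated(de$gene[de$population == pop]))
      stop2("duplicate gene ids within population '", pop, "'")
    if (length(g) == 0L) {
      warn2("population '", pop, "' has no genes passing the filters; dropped")
    } else {
      out[[pop]] <- gene_signature(pop, g, klass = klass)
    }
  }
  out
}

#' Select size-matched background signatures
#'
#' Retains candidate signatures whose gene count lies within the closed
#' interval from `(1 - slack)` times the smallest focal signature to
#' `(1 + slack)` times the largest, i.e. up to 10% fewer or 10% more genes
#' than the focal extremes at the default slack. Retained signatures are
#' re-tagged `klass = "background"`.
#'
#' @param candidates list of [gene_signature()] candidates.
#' @param focal list of focal (canonical + mimetic) signatures defining the
#'   size interval.
#' @param slack interval slack, default 0.10.
#' @param universe optional character vector of measured genes; when given,
#'   candidate gene sets are intersected with it before the size filter.
#' @return named list of retained background signatures (possibly empty,
#'   with a warning).
#' @export
select_background_sets <- function(candidates, focal, slack = 0.10,
                                   universe = NULL) {
  if (length(focal) == 0L) stop2("'focal' must be non-empty")
  assert_fraction(slack, "slack")
  sizes <- vapply(focal, function(s) length(s$genes), integer(1))
  lo <- (1 - slack) * min(sizes)
  hi <- (1 + slack) * max(sizes)
  out <- list()
  for (s in candidates) {
    g <- s$genes
    if (!is.null(universe)) g <- intersect(g, universe)
    if (length(g) >= lo && length(g) <= hi && length(g) > 0L)
      out[[s$name]] <- gene_signature(s$name, g, klass = "background")
  }
  if (length(out) == 0L)
    warn2("no candidate signatures fall in the background size interval [",
          format(lo), ", ", format(hi), "]")
  out
}

#' Transfer a signature across species by orthology
#'
#' Replaces each source gene by all of its orthologues (many-to-many
#' relationships expanded), deduplicates, and reports how many source genes
#' had no orthologue.
#'
#' @param sig a [gene_signature()].
#' @param map data frame with columns `source_gene`, `target_gene`
#'   (unique pairs; many-to-many allowed).
#' @return the translated [gene_signature()] (same name and class).
#' @export
map_orthologs <- function(sig, map) {
  if (!is.data.frame(map) || nrow(map) == 0L)
    stop2("'map' must be a non-empty data frame")
  need <- c("source_gene", "target_gene")
  if (!all(need %in% names(map)))
    stop2("'map' needs columns source_gene, target_gene")
  hit <- map$source_gene %in% sig$genes
  unmapped <- setdiff(sig$genes, map$source_gene)
  if (length(unmapped))
    warn2(length(unmapped), " gene(s) of signature '", sig$name,
          "' have no orthologue and were dropped")
  targets <- unique(map$target_gene[hit])
  if (length(targets) == 0L)
    stop2("no gene of signature '", sig$name, "' maps to the target species")
  gene_signature(sig$name, targets, klass = sig$klass)
}
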