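#' Assemble the signature-enrichment heat-map matrix
#'
#' Rows are signatures ordered canonical, then mimetic, then background
#' (alphabetical within class); columns are contrasts. Cell values are the
#' clipped signed log10 adjusted p-values; signatures skipped in a
#' contrast appear as `NA` (explicit missing), never as 0.
#'
#' @param tables named list of `enrichment_table`s (one per contrast,
#'   after [adjust_and_sign()]).
#' @param clip clipping limit applied to the signed values, default 10.
#' @return object of class `heatmap_spec`: list with `matrix`
#'   (signatures x contrasts), `clip`, `klass` (per-row class).
#' @export
build_heatmap <- function(tables, clip = 10) {
  if (is.null(names(tables))) stop2("'tables' must be named by contrast")
  if (clip <= 0) stop2("'clip' must be > 0")
  klass_map <- list()
  for (tb in tables) {
    stopifnot(inherits(tb, "enrichment_table"))
    for (i in seq_len(nrow(tb))) {
      s <- tb$signature[i]; k <- tb$klass[i]
      if (!is.null(klass_map[[s]]) && klass_map[[s]] != k)
        stop2("signature '", s, "' has contradictory class across contrasts")
      klass_map[[s]] <- k
    }
  }
  sigs <- names(klass_map)
  kl <- unlist(klass_map)
  ord <- order(match(kl, c("canonical", "mimetic", "background")), sigs)
  sigs <- sigs[ord]; kl <- kl[ord]
  M <- matrix(NA_real_, length(sigs), length(tables),
              dimnames = list(sigs, names(tables)))
  for (cn in names(tables)) {
    tb <- tables[[cn]]
    signed <- if ("signed_log10p" %in% names(tb)) tb$signed_log10p
              else stop2("run adjust_and_sign() first")
    M[tb$signature, cn] <- pmin(pmax(signed, -clip), clip)
  }
  structure(list(matrix = M, clip = clip, klass = setNames(kl, sigs)),
            class = "heatmap_spec")
}

#' Render a heat-map spec to SVG (and TSV)
#'
#' Uses a symmetric diverging colour scale anchored at 0; missing entries
#' stay blank. The underlying matrix can be written alongside so the
#' figure is machine-checkable.
#'
#' @param spec a `heatmap_spec`.
#' @param file SVG output path.
#' @param tsv optional TSV path for the matrix.
#' @return `file`, invisibly.
#' @export
plot_heatmap <- function(spec, file, tsv = NULL) {
  stopifnot(inherits(spec, "heatmap_spec"))
  M <- spec$matrix
  if (!is.null(tsv))
    write_tsv(data.frame(signature = rownames(M), klass = spec$klass, M,
                         check.names = FALSE),
              tsv, meta = list(clip = spec$clip))
  grDevices::svg(file, width = 2 + ncol(M) * 0.6, height = 1 + nrow(M) * 0.25)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mar = c(4, 10, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)),
                  t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  zlim = c(-spec$clip, spec$clip), col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(M)), colnames(M), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(M)), rev(rownames(M)), las = 2, cex.axis = 0.6)
  invisible(file)
}

#' Per-gene statistic positions for signature line panels
#'
#' For each signature, the positions of its genes' ranking statistics on
#' a shared axis, annotated with the signed log10 adjusted p from the
#' enrichment table — the data behind one-line-per-gene signature panels.
#'
#' @param stats a `ranking_stats` (after [treat_test()]).
#' @param sigs named list of [gene_signature()] objects.
#' @param enrichment optional `enrichment_table` supplying annotations.
#' @return data frame: signature, gene, t, annotation.
#' @export
gene_line_panel <- function(stats, sigs, enrichment = NULL) {
  stopifnot(inherits(stats, "ranking_stats"))
  stat <- setNames(stats$table$t_treat %||% stats$table$t, stats$table$gene)
  ann <- if (!is.null(enrichment))
    setNames(enrichment$signed_log10p, enrichment$signature) else NULL
  rows <- lapply(sigs, function(s) {
    g <- intersect(s$genes, names(stat))
    if (length(g) == 0L) stop2("signature '", s$name, "' has no measured gene")
    data.frame(signature = s$name, gene = g, t = unname(stat[g]),
               annotation = if (!is.null(ann)) unname(ann[s$name]) else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
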