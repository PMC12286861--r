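#' Read a count matrix from disk
#'
#' Supports a MatrixMarket directory (`matrix.mtx` genes x cells, with
#' `genes.tsv` and `cells.tsv` one id per line, the 10x layout) or a dense
#' TSV (genes in rows, header of cell/sample ids). The internal
#' orientation is cells x genes for single-cell matrices read from an MTX
#' directory; TSV tables are returned as stored (genes x samples).
#'
#' @param path directory (mtx_dir) or file (tsv).
#' @param format `"mtx_dir"` or `"tsv"`.
#' @return numeric matrix with unique dimnames.
#' @export
load_counts <- function(path, format = c("mtx_dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv"); cf <- file.path(path, "cells.tsv")
    for (f in c(mtx, gf, cf)) if (!file.exists(f)) stop2("missing file: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf); cells <- readLines(cf)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop2(sprintf("dimension mismatch: matrix %d x %d vs %d genes, %d cells",
                    nrow(m), ncol(m), length(genes), length(cells)))
    if (anyDuplicated(genes)) stop2("duplicate gene id(s) in ", gf)
    if (anyDuplicated(cells)) stop2("duplicate cell id(s) in ", cf)
    dimnames(m) <- list(genes, cells)
    t(m)
  } else {
    if (!file.exists(path)) stop2("missing file: ", path)
    tab <- read.delim(path, check.names = FALSE, comment.char = "#")
    ids <- tab[[1]]
    if (anyDuplicated(ids)) stop2("duplicate gene id(s) in ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) stop2("duplicate sample id(s) in ", path)
    m
  }
}

#' Write a cells x genes count matrix as a MatrixMarket directory
#'
#' Written genes x cells on disk (`matrix.mtx` + `genes.tsv` +
#' `cells.tsv`), the conventional orientation.
#'
#' @param counts cells x genes matrix.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a GMT signature collection
#'
#' Each line: name, description, then one or more gene ids,
#' tab-separated. The class tag is parsed from a description of the form
#' `klass=<canonical|mimetic|background>` when present, else `klass`
#' applies.
#'
#' @param path GMT file.
#' @param klass default class for signatures without a tagged description.
#' @return named list of [gene_signature()] objects with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path, klass = "mimetic") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- list(); desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop2("malformed GMT line ", i, ": need name, description, >= 1 gene")
    kl <- klass
    if (grepl("^klass=", parts[2]))
      kl <- sub("^klass=", "", parts[2])
    sigs[[parts[1]]] <- gene_signature(parts[1], parts[-(1:2)], klass = kl)
    desc[parts[1]] <- parts[2]
  }
  attr(sigs, "descriptions") <- desc
  sigs
}

#' Write a signature collection as GMT
#'
#' Descriptions default to `klass=<class>` so the class survives a round
#' trip.
#'
#' @param sigs named list of [gene_signature()] objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  desc <- attr(sigs, "descriptions")
  lines <- vapply(sigs, function(s) {
    d <- desc[s$name] %||% NA_character_
    if (is.na(d)) d <- paste0("klass=", s$klass)
    paste(c(s$name, d, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as TSV with a metadata preamble
#'
#' @param x data frame.
#' @param path output file.
#' @param meta named list written as `# key: value` header lines.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
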