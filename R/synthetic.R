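#' Describe a simulated cell population
#'
#' A population is a named group of cells occupying a fixed fraction of the
#' dataset, whose marker genes are elevated multiplicatively on the
#' negative-binomial mean. The `wave` tag marks whether the population is
#' present from embryonic stages (`"early"`, e.g. muscle-, ciliated-,
#' goblet- or ionocyte-like mimetic cells) or appears only postnatally
#' (`"late"`, e.g. enterohepatic- or skin-like), mirroring the two
#' successive waves of mimetic-cell development.
#'
#' @param name population label.
#' @param frequency fraction of cells in `(0, 1]`.
#' @param marker_genes character vector of marker gene ids (non-empty).
#' @param marker_log2fc mean log2 fold-elevation of marker genes over the
#'   baseline mean; must be `>= 0`.
#' @param wave `"early"` or `"late"`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, frequency, marker_genes, marker_log2fc = 0,
                            wave = c("early", "late")) {
  wave <- match.arg(wave)
  assert_fraction(frequency, "frequency", open0 = TRUE)
  if (length(marker_genes) < 1L) stop2("'marker_genes' must be non-empty")
  if (marker_log2fc < 0) stop2("'marker_log2fc' must be >= 0")
  structure(list(name = as.character(name), frequency = frequency,
                 marker_genes = as.character(marker_genes),
                 marker_log2fc = marker_log2fc, wave = wave),
            class = "population_spec")
}

#' Simulation configuration for synthetic UMI data
#'
#' Parameters of the negative-binomial count model: per-gene baseline means
#' are gamma-distributed around `baseline_mean`, each cell carries a
#' log-normal library-size factor with sigma `library_size_spread`, and
#' population markers scale the mean by `2^marker_log2fc`.
#'
#' @param n_cells,n_genes dimensions of the simulated matrix.
#' @param baseline_mean mean of the per-gene baseline NB mean (UMI scale).
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param library_size_spread sigma of the log-normal per-cell library factor.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param populations list of [population_spec()] objects whose frequencies
#'   sum to 1.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells, n_genes, baseline_mean = 0.2,
                       dispersion = 2, library_size_spread = 0.3,
                       seed = 1L, populations) {
  assert_count(n_cells, "n_cells"); assert_count(n_genes, "n_genes")
  if (baseline_mean <= 0) stop2("'baseline_mean' must be > 0")
  if (dispersion <= 0) stop2("'dispersion' must be > 0")
  if (library_size_spread < 0) stop2("'library_size_spread' must be >= 0")
  if (missing(populations) || length(populations) == 0L)
    stop2("'populations' must be a non-empty list of population_spec")
  ok <- vapply(populations, inherits, logical(1), "population_spec")
  if (!all(ok)) stop2("all 'populations' must be population_spec objects")
  freqs <- vapply(populations, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop2("population frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop2("population names must be unique")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed), populations = populations),
            class = "sim_config")
}

# Deterministic largest-remainder allocation of n cells to frequencies.
allocate_cells <- function(n, freqs, names) {
  exp_n <- n * freqs
  low <- which(exp_n < 1)
  if (length(low))
    stop2("expected cell count < 1 for population(s): ",
          paste(names[low], collapse = ", "))
  base <- floor(exp_n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exp_n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  setNames(as.integer(base), names)
}

#' Simulate a single-cell UMI count matrix with planted populations
#'
#' Draws negative-binomial UMI counts for `n_cells` cells over `n_genes`
#' genes. Cells are allocated to populations deterministically (largest
#' remainder), then shuffled; marker genes of a population have their NB
#' mean multiplied by `2^marker_log2fc` in cells of that population.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (cells x genes integer matrix, dimnames
#'   `cell_*` / `gene_*`) and `truth` (list with `cell_labels`, a named
#'   character vector, plus the per-gene baseline means and library
#'   factors used).
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "single_cell"))
  pops <- config$populations
  nm <- vapply(pops, `[[`, character(1), "name")
  freqs <- vapply(pops, `[[`, numeric(1), "frequency")
  n_per <- allocate_cells(config$n_cells, freqs, nm)
  labels <- sample(rep(nm, times = n_per))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  cells <- sprintf("cell_%05d", seq_len(config$n_cells))
  names(labels) <- cells

  # per-gene baseline means: gamma with shape 1 (exponential) keeps a
  # realistic long right tail of expression levels
  base_mu <- stats::rgamma(config$n_genes, shape = 1, rate = 1 / config$baseline_mean)
  base_mu <- pmax(base_mu, 1e-4)
  names(base_mu) <- genes
  # marker genes are, by definition, genes expressed at usable levels in
  # their population: floor their baseline at the nominal mean so the
  # planted fold-elevation acts on a detectable transcript
  all_markers <- unique(unlist(lapply(pops, `[[`, "marker_genes")))
  all_markers <- intersect(all_markers, genes)
  base_mu[all_markers] <- pmax(base_mu[all_markers], config$baseline_mean)
  libf <- rlnorm(config$n_cells, 0, config$library_size_spread)

  # log2 fold matrix only for marker rows of each population
  counts <- matrix(0L, config$n_cells, config$n_genes,
                   dimnames = list(cells, genes))
  for (p in pops) {
    bad <- setdiff(p$marker_genes, genes)
    if (length(bad))
      stop2("population '", p$name, "' references unknown gene(s): ",
            paste(head(bad, 5), collapse = ", "))
  }
  fold <- matrix(1, config$n_cells, config$n_genes, dimnames = list(cells, genes))
  for (p in pops) {
    idx <- labels == p$name
    fold[idx, p$marker_genes] <- 2^p$marker_log2fc
  }
  mu <- (libf * fold) * rep(base_mu, each = config$n_cells)
  counts[] <- rnbinom(length(mu), size = config$dispersion, mu = mu)
  list(counts = counts,
       truth = list(cell_labels = labels, base_mu = base_mu,
                    lib_factors = setNames(libf, cells)))
}

#' Simulate bulk RNA-seq counts with condition-specific signature shifts
#'
#' Generates a genes x samples negative-binomial count table. Genes
#' belonging to a shifted signature have their expected counts multiplied
#' by `2^log2fc` in samples of the shifted condition.
#'
#' @param config a [sim_config()] (supplies `n_genes`, `baseline_mean`,
#'   `dispersion`, `library_size_spread`, `seed`).
#' @param conditions character vector of condition labels.
#' @param signatures named list of gene-id vectors (or [gene_signature()]
#'   objects) that `shifts` refers to.
#' @param shifts data frame with columns `signature`, `condition`,
#'   `log2fc`; an empty (zero-row) frame gives a null dataset.
#' @param n_replicates replicates per condition (>= 2).
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (data frame: sample, condition).
#' @export
simulate_bulk <- function(config, conditions, signatures = list(),
                          shifts = NULL, n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  assert_count(n_replicates, "n_replicates", min = 2L)
  if (is.null(shifts))
    shifts <- data.frame(signature = character(), condition = character(),
                         log2fc = numeric())
  set.seed(derive_seed(config$seed, "bulk"))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  sig_genes <- lapply(signatures, function(s)
    if (inherits(s, "gene_signature")) s$genes else as.character(s))
  for (i in seq_len(nrow(shifts))) {
    sg <- sig_genes[[shifts$signature[i]]]
    if (is.null(sg)) stop2("unknown signature in shifts: ", shifts$signature[i])
    miss <- setdiff(sg, genes)
    if (length(miss))
      stop2("signature '", shifts$signature[i], "' has gene(s) absent from ",
            "the simulated universe: ", paste(head(miss, 5), collapse = ", "))
  }
  samples <- data.frame(
    sample = sprintf("%s_rep%d", rep(conditions, each = n_replicates),
                     rep(seq_len(n_replicates), length(conditions))),
    condition = rep(conditions, each = n_replicates))
  # bulk libraries are deep: scale baseline means up so typical genes pass
  # the count filter
  base_mu <- stats::rgamma(config$n_genes, shape = 1.5,
                           rate = 1.5 / (config$baseline_mean * 500))
  base_mu <- pmax(base_mu, 0.05)
  names(base_mu) <- genes
  libf <- rlnorm(nrow(samples), 0, config$library_size_spread)
  fold <- matrix(1, config$n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample))
  for (i in seq_len(nrow(shifts))) {
    cols <- samples$condition == shifts$condition[i]
    fold[sig_genes[[shifts$signature[i]]], cols] <-
      fold[sig_genes[[shifts$signature[i]]], cols] * 2^shifts$log2fc[i]
  }
  mu <- fold * outer(base_mu, libf)
  counts <- matrix(rnbinom(length(mu), size = config$dispersion * 5, mu = mu),
                   config$n_genes, nrow(samples),
                   dimnames = dimnames(fold))
  list(counts = counts, samples = samples)
}

#' Simulate clonal lineage barcodes
#'
#' Each barcode belongs to one clone; a clone spans a set of populations
#' (its `sharing` entry, recycled over barcodes). A barcode is present in
#' every cell of its clone's populations, thinned by an independent
#' Bernoulli detection step.
#'
#' @param truth the `truth` component of [simulate_single_cell()] output
#'   (uses `cell_labels`).
#' @param n_barcodes number of barcodes.
#' @param sharing list of character vectors of population names; entry `i`
#'   defines the populations spanned by clone `i` (recycled).
#' @param detection_rate probability in `(0, 1]` that a truly present
#'   barcode is observed.
#' @param seed integer seed.
#' @return cells x barcodes 0/1 integer matrix with a
#'   `"clone_populations"` attribute.
#' @export
simulate_barcodes <- function(truth, n_barcodes, sharing,
                              detection_rate = 1, seed = 1L) {
  assert_fraction(detection_rate, "detection_rate", open0 = TRUE)
  labels <- truth$cell_labels
  known <- unique(labels)
  for (s in sharing) {
    bad <- setdiff(s, known)
    if (length(bad))
      stop2("sharing set references unknown population(s): ",
            paste(bad, collapse = ", "))
  }
  set.seed(derive_seed(seed, "barcodes"))
  clones <- rep(seq_along(sharing), length.out = n_barcodes)
  bc <- matrix(0L, length(labels), n_barcodes,
               dimnames = list(names(labels),
                               sprintf("bc_%03d", seq_len(n_barcodes))))
  for (j in seq_len(n_barcodes)) {
    in_clone <- labels %in% sharing[[clones[j]]]
    det <- rbinom(sum(in_clone), 1L, detection_rate)
    bc[in_clone, j] <- det
  }
  attr(bc, "clone_populations") <- sharing[clones]
  bc
}

#' Simulate a cTEC/mTEC ratio time course with a known nadir
#'
#' The expected ratio is a convex quadratic in age with its minimum at
#' `nadir_age`, falling from a high perinatal value to the nadir and
#' rising again — the shape of the cortical/medullary compartment ratio
#' over early life. Gaussian noise of sd `noise_sd` is added; one animal
#' per row.
#'
#' @param nadir_age age (days) of the true minimum; must lie inside
#'   `age_range`.
#' @param n_mice number of animals (>= 10, so cross-validated smoothing is
#'   meaningful downstream).
#' @param noise_sd sd of the additive Gaussian noise, on the ratio scale.
#' @param age_range length-2 numeric, days.
#' @param seed integer seed.
#' @param depth,base curve depth (value at the far end of `age_range`
#'   minus the minimum) and the minimum ratio.
#' @return data frame with columns `age`, `ratio` and attribute
#'   `"truth"` (nadir_age, depth, base).
#' @export
simulate_timecourse <- function(nadir_age, n_mice = 60L, noise_sd = 0.2,
                                age_range = c(0, 56), seed = 1L,
                                depth = 4, base = 0.8) {
  assert_count(n_mice, "n_mice", min = 10L)
  if (nadir_age <= age_range[1] || nadir_age >= age_range[2])
    stop2("'nadir_age' must lie strictly inside 'age_range'")
  if (noise_sd < 0) stop2("'noise_sd' must be >= 0")
  set.seed(derive_seed(seed, "timecourse"))
  age <- seq(age_range[1], age_range[2], length.out = n_mice)
  # smooth convex curve with minimum `base` at the nadir and value
  # `base + depth` at both ends of the age range: a quadratic in a
  # rationally warped age coordinate, so the perinatal fall of the ratio
  # is steep (cortical excess at birth) and the post-nadir recovery
  # gentle, with no curvature kink at the vertex
  hl <- nadir_age - age_range[1]; hr <- age_range[2] - nadir_age
  B <- (hr - hl) / (hr + hl); A <- hl * (1 + B)
  w <- (age - nadir_age) / (A + B * (age - nadir_age))
  mu <- base + depth * w^2
  ratio <- mu + rnorm(n_mice, 0, noise_sd)
  out <- data.frame(age = age, ratio = ratio)
  attr(out, "truth") <- list(nadir_age = nadir_age, depth = depth, base = base)
  out
}

#' Default synthetic TEC population layout
#'
#' Four canonical TEC populations (early progenitor, postnatal progenitor,
#' cTEC-like, mTEC/Aire-stage-like) plus eleven rare mimetic populations at
#' 0.5--2% each, with disjoint marker blocks. Frequencies for the mimetic
#' populations are placeholders chosen in the realistic rare range; they
#' are fully configurable.
#'
#' @param n_genes gene universe size (marker blocks are carved from it).
#' @param markers_per_pop marker genes per population.
#' @param marker_log2fc marker effect size (log2).
#' @return list of [population_spec()] objects.
#' @export
default_tec_populations <- function(n_genes = 2000L, markers_per_pop = 30L,
                                    marker_log2fc = 3) {
  mims <- c("muscle", "ciliated", "goblet", "ionocyte", "tuft", "microfold",
            "neuroendocrine", "pancreatic", "lung_basal", "enterohepatic",
            "skin")
  wave <- ifelse(mims %in% c("enterohepatic", "skin"), "late", "early")
  mim_freq <- rep(c(0.005, 0.01, 0.02), length.out = length(mims))
  canon <- c("early_progenitor", "postnatal_progenitor", "cTEC", "mTEC")
  canon_freq <- rep((1 - sum(mim_freq)) / length(canon), length(canon))
  names <- c(canon, mims)
  freqs <- c(canon_freq, mim_freq)
  waves <- c(rep("early", length(canon)), wave)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  need <- length(names) * markers_per_pop
  if (need > n_genes) stop2("n_genes too small for disjoint marker blocks")
  out <- vector("list", length(names))
  for (i in seq_along(names)) {
    blk <- genes[((i - 1) * markers_per_pop + 1):(i * markers_per_pop)]
    out[[i]] <- population_spec(names[i], freqs[i], blk,
                                marker_log2fc = marker_log2fc,
                                wave = waves[i])
  }
  out
}

#' Marker signatures matching a population layout
#'
#' @param populations list of [population_spec()] objects.
#' @param klass_map optional named character vector population -> class;
#'   defaults to `canonical` for the canonical TEC populations of
#'   [default_tec_populations()] and `mimetic` otherwise.
#' @return named list of [gene_signature()] objects.
#' @export
population_signatures <- function(populations, klass_map = NULL) {
  canon <- c("early_progenitor", "postnatal_progenitor", "cTEC", "mTEC")
  out <- lapply(populations, function(p) {
    kl <- if (!is.null(klass_map) && p$name %in% names(klass_map))
      klass_map[[p$name]]
    else if (p$name %in% canon) "canonical" else "mimetic"
    gene_signature(p$name, p$marker_genes, klass = kl)
  })
  setNames(out, vapply(populations, `[[`, character(1), "name"))
}
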