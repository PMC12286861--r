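#' Suggested synthetic-run threshold configuration
#'
#' Thresholds remain a manual, config-driven choice; this constant is the
#' configuration used for the package's synthetic study conditions (marker
#' blocks at log2FC 3, top fraction 0.05), where population AUCs separate
#' cleanly from the background near 0.05.
#'
#' @param signatures named list of signatures to cover.
#' @param value threshold applied to every signature, default 0.3.
#' @return named numeric vector.
#' @export
uniform_thresholds <- function(signatures, value = 0.3) {
  setNames(rep(value, length(signatures)), names(signatures))
}

#' End-to-end synthetic run with planted ground truth
#'
#' Simulates a single-cell dataset with canonical and rare mimetic TEC
#' populations, bulk data with condition-specific signature shifts, clonal
#' barcodes, and a ratio time course; then runs scoring, calling,
#' composition consensus, barcode association, fate probabilities and
#' nadir detection, writing all outputs plus a reproducibility manifest
#' (parameters, derived seeds, output hashes) to `out_dir`.
#'
#' @param out_dir output directory (created).
#' @param seed global seed; every stage derives its own stream from it.
#' @param n_cells,n_genes single-cell matrix size.
#' @param marker_log2fc planted marker effect size.
#' @param threshold AUC calling threshold for all signatures.
#' @param n_traj_cells cells subsampled for the trajectory stage (dense
#'   eigendecomposition).
#' @param late_shift log2 fold depletion of late-wave signatures in the
#'   embryonic bulk condition.
#' @return list with components `truth`, `calls`, `precision`, `recall`,
#'   `enrichment`, `heatmap`, `consensus`, `association`, `fate`,
#'   `jaccard`, `nadir`, `manifest_path`.
#' @export
run_synthetic_pipeline <- function(out_dir, seed = 1L, n_cells = 5000L,
                                   n_genes = 2000L, marker_log2fc = 3,
                                   threshold = 0.3, n_traj_cells = 500L,
                                   late_shift = -1.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pops <- default_tec_populations(n_genes, marker_log2fc = marker_log2fc)
  sigs <- population_signatures(pops)
  cfg <- sim_config(n_cells, n_genes, seed = derive_seed(seed, "sc"),
                    populations = pops)

  sim <- simulate_single_cell(cfg)
  calls <- call_cells(sim$counts, sigs, uniform_thresholds(sigs, threshold),
                      tie_seed = derive_seed(seed, "ties"))
  pr <- calling_precision_recall(calls, sim$truth$cell_labels,
                                 mimetic_names(pops))
  write_tsv(calls$calls, file.path(out_dir, "calls.tsv"))

  # bulk: late-wave signatures depleted in the embryonic condition
  late <- vapply(pops, function(p) p$wave == "late", logical(1))
  late_sigs <- vapply(pops[late], `[[`, character(1), "name")
  shifts <- data.frame(signature = late_sigs, condition = "embryonic",
                       log2fc = late_shift)
  bcfg <- sim_config(n_cells = 10L, n_genes = n_genes,
                     seed = derive_seed(seed, "bulkcfg"), populations = pops)
  bulk <- simulate_bulk(bcfg, conditions = c("embryonic", "postnatal"),
                        signatures = sigs, shifts = shifts, n_replicates = 4L)
  enr <- enrich_bulk(bulk$counts, bulk$samples$condition,
                     contrast = c("embryonic", "postnatal"), sets = sigs)
  hm <- build_heatmap(list(embryonic_vs_postnatal = enr$enrichment))
  write_tsv(enr$enrichment, file.path(out_dir, "enrichment.tsv"))
  plot_heatmap(hm, file.path(out_dir, "heatmap.svg"),
               tsv = file.path(out_dir, "heatmap.tsv"))

  # composition: split cells into synthetic animals, two (null) conditions
  set.seed(derive_seed(seed, "samples"))
  sample_id <- sample(rep(sprintf("m%02d", 1:8), length.out = n_cells))
  comp <- composition_counts(calls, sample_id)
  cond <- ifelse(as.integer(sub("m", "", rownames(comp))) <= 4, "A", "B")
  refs <- intersect(c("early_progenitor", "postnatal_progenitor", "cTEC",
                      "mTEC", "unassigned"), colnames(comp))
  cons <- consensus_over_references(comp, cond, refs,
                                    seed = derive_seed(seed, "dm"))
  write_tsv(cons$table, file.path(out_dir, "composition_consensus.tsv"))

  # lineage: one clone spans the postnatal progenitor and the
  # enterohepatic mimetic population
  bc <- simulate_barcodes(sim$truth, n_barcodes = 20L,
                          sharing = list(c("postnatal_progenitor",
                                           "enterohepatic")),
                          detection_rate = 0.6,
                          seed = derive_seed(seed, "bc"))
  # most populations have zero detections, so the fit separates; use the
  # penalized (Firth) likelihood
  assoc <- test_signature_association(bc, sim$truth$cell_labels, sample_id,
                                      firth = TRUE)
  write_tsv(data.frame(lrt = assoc$lrt, df = assoc$df, p = assoc$p),
            file.path(out_dir, "barcode_association.tsv"))

  # trajectory on a subsample, rooted at the top early-progenitor cell
  set.seed(derive_seed(seed, "traj"))
  sub <- sort(sample.int(n_cells, min(n_traj_cells, n_cells)))
  sub_scores <- calls$scores
  sub_scores$auc <- sub_scores$auc[sub, , drop = FALSE]
  sub_scores$z <- sub_scores$z[sub, , drop = FALSE]
  graph <- knn_graph(sub_scores$z, k = 15L)
  root <- rownames(sub_scores$auc)[which.max(sub_scores$auc[, "early_progenitor"])]
  pt <- diffusion_pseudotime(graph, root)
  kern <- build_combined_kernel(graph, pt)
  terms <- select_terminal_cells(sub_scores, c("mTEC", "cTEC"), n_per = 10L)
  fate <- absorption_probabilities(kern, terms)
  jac <- fate_overlap_jaccard(fate, threshold = 0.5)
  write_tsv(data.frame(cell = rownames(fate), unclass(fate),
                       check.names = FALSE),
            file.path(out_dir, "fate.tsv"))

  # time course and nadir
  tc <- simulate_timecourse(nadir_age = 21, n_mice = 60L, noise_sd = 0.4,
                            seed = derive_seed(seed, "tc"))
  model <- select_span_cv(tc$age, tc$ratio, seed = derive_seed(seed, "cv"))
  nadir <- find_nadir(model)
  write_tsv(data.frame(age = tc$age, ratio = tc$ratio),
            file.path(out_dir, "timecourse.tsv"))

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest", outputs)]
  manifest <- list(
    seed = seed,
    parameters = list(n_cells = n_cells, n_genes = n_genes,
                      marker_log2fc = marker_log2fc, threshold = threshold,
                      late_shift = late_shift, n_traj_cells = n_traj_cells),
    precision = pr$precision, recall = pr$recall,
    selected_span = model$selected_span, nadir = nadir$x_min,
    hashes = as.list(tools::md5sum(sort(outputs))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(truth = sim$truth, calls = calls, precision = pr$precision,
       recall = pr$recall, enrichment = enr$enrichment, heatmap = hm,
       consensus = cons, association = assoc, fate = fate, jaccard = jac,
       nadir = nadir, selected_span = model$selected_span,
       manifest_path = manifest_path)
}

#' Names of the mimetic populations in a population layout
#'
#' @param populations list of [population_spec()] objects.
#' @return character vector (populations outside the canonical four).
#' @export
mimetic_names <- function(populations) {
  canon <- c("early_progenitor", "postnatal_progenitor", "cTEC", "mTEC")
  setdiff(vapply(populations, `[[`, character(1), "name"), canon)
}

#' Precision and recall of mimetic-cell calls against planted truth
#'
#' Restricted to the mimetic populations: a call counts as a true
#' positive when a cell labelled with a mimetic signature truly belongs
#' to that population.
#'
#' @param calls a `call_result`.
#' @param truth_labels named per-cell true population labels.
#' @param mimetic character vector of mimetic population names.
#' @return list with `precision`, `recall`, `confusion` (called x true
#'   table).
#' @export
calling_precision_recall <- function(calls, truth_labels, mimetic) {
  called <- setNames(calls$calls$label, calls$calls$cell)
  truth <- truth_labels[names(called)]
  tp <- sum(called %in% mimetic & called == truth)
  fp <- sum(called %in% mimetic & called != truth)
  fn <- sum(truth %in% mimetic & called != truth)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       confusion = table(called = called, true = truth))
}
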