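# shared fixtures and independent oracles, all built in code

# brute-force recovery-curve AUC: enumerate R(k) explicitly
oracle_auc <- function(sig_ranks, K, n_s) {
  R <- vapply(seq_len(K), function(k) sum(sig_ranks <= k), numeric(1))
  sum(R) / sum(pmin(seq_len(K), n_s))
}

# two-population config used across modules
tiny_config <- function(n_cells = 400, n_genes = 200, seed = 11,
                        log2fc = 3) {
  pops <- list(
    population_spec("bulkpop", 0.9, sprintf("gene_%04d", 1:20),
                    marker_log2fc = log2fc),
    population_spec("rarepop", 0.1, sprintf("gene_%04d", 21:40),
                    marker_log2fc = log2fc))
  sim_config(n_cells, n_genes, seed = seed, populations = pops)
}

tiny_signatures <- function() {
  list(bulkpop = gene_signature("bulkpop", sprintf("gene_%04d", 1:20),
                                klass = "canonical"),
       rarepop = gene_signature("rarepop", sprintf("gene_%04d", 21:40),
                                klass = "mimetic"))
}

# random score_table for property checks
random_score_table <- function(n_cells, sigs, seed = 1) {
  set.seed(seed)
  auc <- matrix(runif(n_cells * length(sigs)), n_cells,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)), sigs))
  st <- structure(list(auc = auc, z = NULL, top_fraction = 0.05,
                       n_genes = 100L, n_s = setNames(rep(10L, length(sigs)),
                                                      sigs),
                       tie_seed = 1L), class = "score_table")
  standardize_scores(st)
}
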