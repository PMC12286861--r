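# mimetect

Detection and quantification of **thymic mimetic epithelial cells** in bulk
and single-cell transcriptomic data.

Mimetic cells are rare medullary thymic epithelial cells (mTECs) that
transcriptionally imitate peripheral cell types — muscle, ionocyte, goblet,
ciliated, enterohepatic, skin, tuft, microfold, neuroendocrine, pancreatic
and lung-basal cells — and thereby present tissue-restricted antigens for
central tolerance. They make up well under a few percent of the thymic
epithelium, so routine differential-abundance tools struggle with them.
`mimetect` implements the specialised statistical machinery this problem
needs, end to end, with a synthetic-data generator carrying planted ground
truth so every stage can be validated without any external download.

## What the package computes

**Per-cell rank-AUC signature scoring.** For a cell whose genes are ranked
by decreasing expression (seeded random tie-breaks), a signature with
`n_s` measured genes is scored by the area under its recovery curve
`R(k) = #{signature genes with rank <= k}` over the top
`K = ceil(top_fraction * G)` ranks, normalised by the maximal achievable
area:

```
AUC = sum_{k=1..K} R(k) / sum_{k=1..K} min(k, n_s)
```

Cells become eligible for every signature whose manual AUC threshold they
meet; a multi-eligible cell is assigned to the signature for which it sits
furthest right in that signature's AUC distribution (highest quantile
rank), with ties broken by the z-standardised AUC. Overlapping Tuft and
Skin sub-signatures can be collapsed into unified labels.

**Competitive bulk enrichment.** Genes are filtered (count > 5 in at least
half the samples), log-CPM transformed, and fitted gene-wise with an
empirical-Bayes moderated two-group model whose prior `(d0, s0^2)` is
estimated by digamma/trigamma moment matching. A fold-change-threshold
(TREAT-style) test at `tau = log2(1.2)` yields the signed ranking
statistic, and each signature is tested competitively against the rest of
the genome with a variance-inflation factor `VIF = 1 + (m - 1) * rho` for
inter-gene correlation. Results are reported as
`log10(BH-adjusted p) * (-1 if enriched upward)`, clipped for heat-map
display. Size-matched background signatures (within 10% of the focal size
range) provide the specificity control, and signatures can be transferred
across species through many-to-many orthology maps.

**Compositional differential abundance.** Per-sample cell-type counts are
modelled as Dirichlet-multinomial with composition
`p_k(x) proportional to exp(alpha_k + beta_k x)` (a chosen reference type
pinned at zero) and precision `gamma`; each type's condition effect is
assessed by likelihood-ratio test with BH adjustment. The model is re-run
with every major population as the reference, a type is declared *overall
changed* only when a strict majority of reference models flag it, and the
final reported reference is the one flagging the fewest changes.

**Lineage barcodes.** Barcode counts are binarised; association between
barcode detection and signature labels is a logistic-regression
likelihood-ratio test (`signature + sample` vs `sample`), with a
Firth-penalised fallback for separated data. Proportions carry Wilson
score intervals; pairs of proportions are compared with an exact
conditional binomial test.

**Fate probabilities.** Diffusion pseudotime from a root cell (the highest
early-progenitor AUC), a combined transition kernel
`P = lambda * P_pt + (1 - lambda) * P_conn` mixing a
pseudotime-directed kernel with the connectivity kernel, terminal cells
picked as the top signature scorers per population, and absorption
probabilities from the fundamental-matrix solve `(I - Q) F = R`. Fate
overlap is summarised by Jaccard indices of high-probability cell sets.

**QC and smoothing.** Droplet filters combine fixed cut-offs (UMI >= 500,
mitochondrial fraction <= 5%) with per-sample raw-MAD rules on detected
genes and complexity; clustering parameters are chosen by mean silhouette
width. The cTEC/mTEC ratio time course is smoothed by LOESS with the span
selected from 0.4–0.9 (step 0.01) by ten-fold cross-validation, and the
nadir is the grid argmin of the fitted curve with a pointwise 95% band.

## Worked example

```r
library(mimetect)

# --- synthetic thymus: 4 canonical populations + 11 rare mimetic ones ---
pops <- default_tec_populations(n_genes = 1200)
sigs <- population_signatures(pops)
cfg  <- sim_config(n_cells = 2000, n_genes = 1200, seed = 42,
                   populations = pops)
sim  <- simulate_single_cell(cfg)

# --- score, threshold, disambiguate ---
calls <- call_cells(sim$counts, sigs, uniform_thresholds(sigs, 0.3),
                    tie_seed = 1)
head(sort(table(calls$calls$label), decreasing = TRUE), 8)
#>     early_progenitor                 cTEC postnatal_progenitor
#>                  430                  422                  403
#>                 mTEC           unassigned           lung_basal
#>                  402                  110                   40
#>            microfold               goblet
#>                   40                   39

calling_precision_recall(calls, sim$truth$cell_labels,
                         mimetic_names(pops))[c("precision", "recall")]
#> $precision [1] 1        $recall [1] 0.9708333
```

Mimetic calls are exact (precision 1.00) and nearly complete (recall
0.97) against the planted labels. Bulk enrichment on a two-condition
dataset in which the late-wave enterohepatic and skin signatures are
depleted embryonically:

```r
shifts <- data.frame(signature = c("enterohepatic", "skin"),
                     condition = "embryonic", log2fc = -1.5)
bulk <- simulate_bulk(cfg, c("embryonic", "postnatal"), sigs, shifts,
                      n_replicates = 4)
enr <- enrich_bulk(bulk$counts, bulk$samples$condition,
                   contrast = c("embryonic", "postnatal"), sets = sigs)
head(enr$enrichment[order(enr$enrichment$adj_p), ], 4)
#>        signature   klass size direction    adj_p signed_log10p
#>    enterohepatic mimetic   30      down 5.35e-63       -62.271
#>             skin mimetic   29      down 3.06e-59       -58.515
#>        microfold mimetic   30        up 4.50e-01         0.346
#>       lung_basal mimetic   29        up 4.50e-01         0.346
```

The two planted depletions dominate (signed log10 adjusted p of -62 and
-59, negative = depleted); all unshifted signatures sit near zero. The
ratio time course:

```r
tc <- simulate_timecourse(nadir_age = 21, n_mice = 60, noise_sd = 0.4,
                          seed = 1)
model <- select_span_cv(tc$age, tc$ratio, seed = 1)
nadir <- find_nadir(model)
#> selected span 0.40; nadir at day 20.50 (fit 1.07, 95% band 0.86-1.28)
```

The cross-validated smoother places the minimum half a day from the
planted nadir at day 21 — the transition point between early- and
postnatal-progenitor dominance.

`run_synthetic_pipeline(out_dir, seed)` chains all stages (scoring,
calling, enrichment heat-map, composition consensus, barcode association,
fate probabilities, nadir) and writes a manifest with parameter and
output hashes for bit-reproducibility.

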