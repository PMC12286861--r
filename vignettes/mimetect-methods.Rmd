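---
title: "Statistical methods for detecting thymic mimetic cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for detecting thymic mimetic cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimetect)
```

# The problem

Thymic mimetic cells — medullary thymic epithelial cells (mTECs) that
adopt the transcriptional programme of a peripheral cell type — occur at
frequencies of a fraction of a percent. Three statistical difficulties
follow. First, per-cell identification must work from small gene sets in
sparse UMI data, where most expression values are tied at zero. Second,
cohort-level comparisons (across ages, genotypes or species) are easier
to run on bulk RNA-seq of sorted epithelium, which demands a competitive
enrichment framework with honest specificity controls rather than
per-cell calls. Third, changes in the abundance of a rare type inside a
fixed-size compartment are compositional: an expansion of one population
mechanically depresses all others, so differential abundance must be
anchored to reference populations, and conclusions should not hinge on
which reference was picked.

`mimetect` implements one coherent pipeline for these tasks plus the
supporting machinery around them (lineage-barcode association, fate
probabilities, droplet QC, time-course smoothing), and ships a
synthetic-data generator with planted ground truth that the entire test
suite runs against.

# Per-cell scoring and calling

## Rank-AUC statistic

Each cell's genes are ranked by decreasing expression. Because UMI data
are mostly ties (zeros), ties are broken by a seeded random permutation,
making every cell's ranks an exact permutation of `1..G` and reruns
bit-identical. This choice — rather than average ranks — keeps the
recovery-curve statistic exactly equal to its combinatorial definition,
so a brute-force enumeration oracle can check it to machine precision
(the suite does so on 1,000 random instances at `1e-12`).

A signature with `n_s` measured genes is scored by the area under its
recovery curve over the top `K = ceiling(top_fraction * G)` ranks,
normalised by the maximal achievable area, so scores are comparable
across signature sizes: 1 means all measured signature genes occupy the
top `n_s` ranks; 0 means none is in the top `K`. The statistic depends
only on ranks, hence is invariant under any monotone transform of
expression (normalisation-free). `top_fraction` defaults to 0.05, the
convention for this family of scores; results are sensitive to it, so it
is recorded in every output.

## Thresholds, disambiguation, merging

Calling thresholds are deliberately manual and config-driven: each
signature's AUC histogram (see `plot_auc_histograms()`) is inspected and
a minimal AUC recorded. The package does not fit mixture models to
choose thresholds automatically — on rare populations those fits are
exactly as fragile as the populations are rare. The boundary is closed
(`AUC >= threshold`).

A cell meeting several thresholds is assigned by *quantile rank*: for
each eligible signature, the fraction of all cells with strictly smaller
AUC. This formalises "further right on the histogram" in a way that is
comparable across signatures with different AUC scales. Ties fall back
to the z-standardised AUC, then to lexical signature order (logged); the
z-standardisation uses the population (divide-by-`n`) standard
deviation, so z columns have exactly unit sd — the choice only matters
for tie-breaking, never for ordering within a signature. Overlapping
sub-signatures (Tuft1/Tuft2, Skin basal/keratinized) can be merged into
unified labels after calling; counts are conserved.

# Bulk competitive enrichment

Genes with counts above 5 in at least half of all samples are kept, then
log-CPM transformed with a prior count of 0.5. The gene-wise two-group
model is moderated empirically: with residual variances `s_g^2` on `d`
degrees of freedom, the prior `(d0, s0^2)` solves the moment equations
of the scaled-F model `s_g^2 ~ s0^2 F(d, d0)` on the log scale
(digamma/trigamma inversion, Newton); posterior variances are
`(d0 s0^2 + d s_g^2) / (d0 + d)`. Two conventions follow the cited
moderated-t methodology and are verified against an independent
implementation in the test suite: when the log-variances show no excess
spread the prior df is infinite and the prior variance is the arithmetic
mean of the `s_g^2`; the total df is capped at the pooled residual df.

The ranking statistic is the fold-change-threshold (TREAT-style) t: for
threshold `tau` (default `log2(1.2)`, i.e. requiring ~20% change),
`p = P(T > (|b|-tau)/se) + P(T > (|b|+tau)/se)`, reported with sign
`sign(b)`. At `tau = 0` this collapses to the ordinary two-sided
moderated t — an identity the suite asserts at `1e-12`.

The competitive test asks whether a signature's statistics exceed the
rest of the genome's, with the standard error inflated by
`VIF = 1 + (m-1) rho` for inter-gene correlation (`rho` defaults to
0.01, the convention for this test; at `rho = 0` it is exactly the
pooled two-sample t-test, asserted at `1e-10`). P-values are BH-adjusted
jointly across all canonical, mimetic and background signatures of one
contrast, and reported as `log10(adj p)`, negated for upward enrichment,
clipped at a configurable limit (default 10) for heat-map display.
Missing signatures render as missing, never as zero.

Background signatures are size-matched: candidates whose gene count lies
within a closed interval from 10% below the smallest focal signature to
10% above the largest are retained. Intersecting candidates with the
measured gene universe *before* the size filter is available via the
`universe` argument (off unless supplied, since the raw-size rule is the
simpler and stricter reading). Orthology transfer for cross-species
comparisons expands many-to-many maps and drops unmapped genes with a
count of how many.

Simplifications, stated plainly: mean-variance precision weights are
implemented in reduced form (a LOWESS trend of residual sd against mean
log-count, used as inverse fourth-power weights) and are **off by
default** — the competitive test consumes ranking statistics, whose
ordering the weights barely move at bulk depths. The robust (winsorised)
variant of the variance moderation is not implemented; the standard
moment-matching is used.

# Compositional consensus

Counts of called cells per sample and type are modelled as
Dirichlet-multinomial: composition
`p_k(x) proportional to exp(alpha_k + beta_k x)` with the reference type
pinned at zero and a common precision `gamma`. Each non-reference
`beta_k` is tested by likelihood-ratio against the constrained refit,
with BH adjustment across types and a 0.05 FDR for the "changed" flag
(the credibility level of the Bayesian original is not stated anywhere
usable, so a conventional FDR stands in; the flag is named `changed`,
not "credible", to keep that distinction visible).

The estimator is maximum likelihood by L-BFGS-B on
`(alpha, beta, log gamma)` with an analytic gradient and seeded
restarts, warm-starting each constrained refit from the full fit. This
replaces a hand-rolled alternating Newton scheme: the likelihood is
smooth and low-dimensional, and a quasi-Newton method with restarts is
the more robust standard tool.

The consensus logic is preserved exactly: the model is fitted once per
candidate reference; a type is *overall changed* only if strictly more
than half of the successful fits flag it; the final reported reference
is the fit flagging the fewest changes (ties lexical, logged). Null
calibration is checked by label permutations on overdispersed null data
pooled across datasets; the pooled LRT p-values pass a
Kolmogorov-Smirnov uniformity check at distance 0.1. At very small
sample counts (around six samples per condition) the LRT is visibly
conservative — a known small-sample property of dispersion-estimating
models, worth remembering when interpreting borderline calls.

# Lineage barcodes

Barcode presence is binarised at count > 0. The association between
detection and signature is a likelihood-ratio test between logistic
models `detected ~ signature + sample` and `detected ~ sample`
(`stats::glm`, i.e. iteratively reweighted least squares), on
`levels - 1` df. Complete separation — inevitable when a clone is
confined to a few populations — is detected and reported with advice to
use `firth = TRUE`, which switches both fits to Firth-penalised
likelihood (Newton iteration with the hat-diagonal score correction) and
takes the LRT on penalised likelihoods. The per-barcode outcome mode
(`outcome = "<barcode>"`) supports clone-sharing analyses; the default
"any barcode" mode matches overall labelling-efficiency comparisons.

Proportions are reported with Wilson score intervals; a `brown = TRUE`
flag substitutes the one-sided Poisson bound on the affected side for
extreme counts (<= 3 successes or failures), the boundary modification
recommended for small counts. Two proportions are compared exactly:
conditional on the success total, the first group's count is binomial
with probability `nA/(nA+nB)` under the null, and the two-sided p-value
sums all outcomes no more probable than the observed one (delegated to
`stats::binom.test`, which implements precisely this rule; the suite
checks it against exhaustive enumeration).

# Trajectory fate probabilities

The neighbour graph uses union-kNN adjacency with Gaussian-kernel
connectivities (bandwidth = median kNN distance), symmetrised by
maximum. Diffusion pseudotime from a chosen root (the cell with the
highest early-progenitor AUC) uses the symmetrised random-walk
operator's eigenpairs with weights `lambda/(1-lambda)`; the
decomposition is dense, with the leading 15 non-trivial components
retained by default, which is appropriate for graphs up to a few
thousand cells — subsample first for larger data.

The pseudotime kernel directs each cell's neighbour mass forward in
pseudotime through a logistic gate `sigma(kappa (t_j - t_i))`; the
complementary, against-time mass is kept as the probability of staying
put. This convention keeps rows summing to one *without* renormalising
away the directional information: as `kappa` grows, backward moves
vanish into self-loops instead of being silently redistributed forward.
`kappa` defaults to the reciprocal raw median absolute deviation of
neighbour pseudotime differences; the mixture weight `lambda` on the
directed kernel defaults to 0.8, leaving 0.2 on the undirected
connectivity kernel to keep the chain well connected. Both are recorded
in the kernel object.

Terminal cells are the `n_per` top scorers per population (overlaps
between populations abort, since they indicate non-separable
signatures). Fate probabilities solve the absorbing-chain system
`(I - Q) F = R` and aggregate absorbing columns by population; rows sum
to one exactly when absorption is certain, and the suite pins the
gambler's-ruin closed form `i/10` on an 11-node chain at `1e-8`.
Intermediate (non-terminal, non-transient-of-interest) states never
appear as fate columns by construction. Fate overlap uses the Jaccard
index of cells above a configurable probability threshold (default 0.5,
above which overlap between two fates is impossible for a single row —
pick lower thresholds to see shared fates).

# QC and clustering selection

Droplets are excluded for total UMI strictly below 500, mitochondrial
fraction strictly above 5%, or detected genes / complexity (detected
genes over total UMI) beyond 1 and 3 raw median absolute deviations from
the median respectively. The MAD is raw (unscaled) by default — the
1.4826 consistency factor is a flag — and medians are computed per
sample when a sample column is present, since depth differs by library.
A zero MAD disables that rule with a warning rather than excluding
everything. Clustering parameters are chosen to maximise mean silhouette
width (Euclidean, singleton clusters scored 0 with a warning), with
total within-cluster sum of squares reported alongside for subcluster
decisions; the clustering algorithm itself is pluggable — any named list
of label vectors — with a seeded k-means sweep bundled as the baseline.

# Time-course smoothing

LOESS fitting is delegated to `stats::loess` (local linear, tricube
weights, exact "direct" surface); the package adds what the analysis
actually needs: span selection by seeded ten-fold cross-validation over
the grid 0.4 to 0.9 in steps of 0.01 (ties to the smaller span, logged),
nadir location as the argmin of the fitted curve on a 0.25-day grid, and
a pointwise 95% band from the smoother's standard errors. Predictions
outside the observed age range are refused. Degree 1 is the default;
degree 2 is available by flag. A boundary minimum (monotone trend)
returns with a warning rather than an error.

# The synthetic-data generator

The generator exists so that every downstream stage has a testable
ground truth; its defaults are fixed study conditions, not tuning knobs.

*Single cell*: negative-binomial UMI counts (mean/size parameterisation,
size 2), per-gene exponential baseline means around 0.2, per-cell
log-normal library factors (sigma 0.3). Cells are allocated to
populations by largest remainder — deterministic, so rare populations
are never lost to sampling — and shuffled. Marker genes act
multiplicatively (`2^log2fc`, default 3) on the NB mean; marker
baselines are floored at the nominal mean, since a marker plantable on a
never-expressed gene would be a contradiction in terms. The default
layout has four canonical TEC populations and eleven mimetic ones at
0.5–2% — frequencies in the realistic rare range, configurable, with
enterohepatic and skin tagged as the late wave.

*Bulk*: the same NB machinery at depth (baseline scaled 500-fold,
tighter dispersion), with signature-by-condition multiplicative shifts.

*Barcodes*: each barcode belongs to a clone spanning a population set;
presence in every cell of those populations is thinned by a Bernoulli
detection rate.

*Time course*: a smooth convex curve with its minimum at the nadir age,
built as a quadratic in a rationally warped age coordinate so that the
ratio falls steeply from birth (cortical excess) and recovers gently
after weaning, reaching `base + depth` at both ends of the age range.
The warp keeps the curve infinitely differentiable: a piecewise-scaled
quadratic has a curvature kink at the vertex that visibly biases the
local-linear smoother's argmin, and a symmetric parabola puts the steep
limb on the wrong side of the nadir.

What the generator does **not** emulate — ambient RNA, doublets, batch
effects, cell-cycle structure, realistic gene-gene correlation — bounds
what green tests mean: they demonstrate that the statistics are
implemented correctly and recover planted effects at realistic sizes,
not that any particular real dataset will behave as cleanly. Thresholds
in particular must be re-derived per dataset from the AUC histograms.

All generators derive per-stream seeds from one global seed, so modules
are independently reproducible; identical seeds give bit-identical
output.

# Problem sizes used by the test suite

The suite was sized to be thorough yet quick: the planted-recovery run
uses 5,000 cells by 2,000 genes; null calibration uses 20 bulk
simulations, 200 composition label permutations pooled over four
datasets, and 200 lineage simulations; nadir recovery uses 50 seeds at
60 animals each; the AUC oracle runs 1,000 random instances. The whole
suite completes in under two minutes on one CPU, and
`scripts/acceptance.R` in about one.

# Known limitations

* The trajectory stage is dense-linear-algebra bound; beyond a few
  thousand cells, subsample (as `run_synthetic_pipeline()` does).
* The compositional LRT is conservative at very small sample counts.
* Signature thresholds are manual by design; the package will not
  invent them.
* Bulk designs are two-group contrasts only — no covariates, batch
  terms or random effects.
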