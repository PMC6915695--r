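---
title: "Deconvoluting drug targets from proteome signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting drug targets from proteome signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdecon)
```

## The idea

Any lethal treatment pushes a cell toward a broadly shared death and
stress program, so the raw fold change of a protein under one compound is
a poor guide to that compound's mechanism. The discriminating signal is
*specificity*: how a protein responds to one compound relative to how it
responds to everything else. `sigdecon` operationalizes this two ways,
which usefully cross-check each other:

* a univariate statistic — the protein's mean log2 fold change under the
  compound minus the median of its per-compound mean fold changes under
  all other compounds (`fitexp_specificity()`); and
* a multivariate model — one-vs-rest OPLS-DA (`build_contrast()`), whose
  single predictive component absorbs exactly the between-class
  (compound-vs-rest) variation while orthogonal components absorb
  within-class structure such as the shared death program.

Both assume all signatures were acquired at a *normalized biological
endpoint* (each compound at its LC50, same treatment time): with the
amount of dying held constant, what differs between signatures is *how*
the cells die, which is what mechanism-of-action inference needs.

## Normalization chain

Starting from per-channel reporter intensities of a multiplexed
experiment (`abundance_table`):

1. **QC filter** (`filter_proteins()`): drop contaminant and
   reverse-database entries and proteins with fewer than 2 unique
   peptides (the conventional evidence floor; tunable).
2. **Channel-median equalization** (`median_normalize()`): each channel
   is scaled so the median of its positive intensities equals the grand
   median of the channel medians. This removes per-channel loading
   differences. Zero intensity is treated as *missing*, never as a true
   zero — standard practice for isobaric quantification, where a zero
   reporter means "not observed", and a choice that matters because a
   true zero would otherwise drag channel medians and control means.
3. **log2 fold change vs control** (`compute_log2fc()`): each intensity
   is divided by the arithmetic mean of the experiment's control
   channels, per protein, then log2-transformed. The mean is taken on
   the intensity scale (not the mean of logs), reading "mean of the
   control replicates" literally.
4. **Median centering** (`global_median_center()`): by default the
   median of each *sample column* is subtracted, so every replicate's
   median log fold change is exactly zero. A single-offset whole-matrix
   mode is available (`mode = "global"`). The per-column default was a
   genuine design call: it stabilizes each replicate individually, which
   is what one wants when samples come from many multiplexed batches,
   and it cannot change which proteins exceed any cutoff relative to
   their column's median. Users preferring one global offset (which
   preserves between-sample median differences) can switch modes.
5. **Merging** (`merge_experiments()`): `"complete"` keeps proteins
   quantified in every sample of every experiment (the multivariate
   models require a complete matrix); `"union"` keeps everything with
   explicit gaps.

The whole chain is scale-equivariant: multiplying all raw intensities of
a plex by any constant leaves the final matrix unchanged, because the
constant cancels in the log ratio. The test suite asserts this at 1e-9.

## PLS, OPLS-DA and their conventions

`fit_pls()` is single-response NIPALS: per component `w ∝ Xᵀy` (unit
norm), `t = Xw`, `p = Xᵀt/(tᵀt)`, `c = yᵀt/(tᵀt)`, deflate `X` by
`tpᵀ`. `fit_oplsda()` runs the orthogonal-signal-correction loop
described in the README and then fits the predictive component on the
deflated matrix. Everything is deterministic given the input; there is
no random initialization.

Conventions that required a decision:

* **Scaling** (`scale_matrix()`): unit-variance scaling with mean
  centering is the default, with pareto (`/√sd`) and center-only
  selectable. UV is the de-facto chemometrics default and makes loadings
  comparable across proteins of very different abundance variance.
  Constant columns cannot be scaled; they are flagged, excluded from
  modeling, and reported in the model's `excluded` field.
* **Class encoding**: contrasted compound = 1, everything else = 0, then
  centered. The heavy imbalance (3 replicates vs the whole panel) is
  deliberately *not* reweighted — the one-vs-rest paradigm treats the
  panel as the reference population, and reweighting would inflate the
  contrasted class's noise.
* **Sign convention**: the predictive component is flipped so the
  contrasted class has a positive mean score. Positive predictive
  loading therefore always reads "specifically up-regulated".
* **Orthogonal-component count**: a fixed count (default 1) for
  reproducibility, or `"auto"`, which adds components while seven-fold
  Q² improves by more than 0.01 (capped at 5) and stops gracefully when
  no orthogonal variation remains.
* **Ties**: every ranking breaks ties by accession order, so outputs are
  bit-stable under row permutation of the input.

**Q² cross-validation** (`cross_validate_q2()`): samples are split into
seven folds (fewer only if there are fewer samples), stratified by class,
assigned venetian-blind within each class after a seed-driven shuffle.
The shuffle uses a small self-contained linear-congruential permutation
so that fold assignment never perturbs the caller's RNG stream. Each fold
refit includes re-estimating the column centers/scales on the training
folds only — skipping that step leaks the held-out samples into the
preprocessing and inflates Q². PRESS accumulates squared errors of the
predicted class value; Q² = 1 − PRESS/SS on the centered class vector.
Q² ≤ R²Y is asserted on every fit in the test suite. A fold can lose a
class only when a class has fewer members than folds; stratification
makes the training set always retain both classes.

**VIP** (`compute_vip()`): `VIPⱼ = √(p · Σₐ SSYₐ (wₐⱼ/‖wₐ‖)² / Σₐ SSYₐ)`
summed over predictive *and* orthogonal components, with SSYₐ the
Y-variance explained by component *a*. Orthogonal components explain
essentially none, so they contribute negligibly — but they are included,
reading the "summed over all components, weighted by the Y variation"
definition literally. How commercial implementations weight orthogonal
components in their total-VIP variant is not publicly specified, so
VIP-based rank orders may differ slightly from theirs; the predictive
loading ranking does not suffer from this ambiguity, and both orderings
are exported (`rank_up`/`rank_down` and `rank_vip`).

## Contrast rankings

`build_contrast()` excludes vehicle controls from *both* classes: the
contrast is compound vs other compounds, not compound vs vehicle —
contrasting against vehicle would re-admit the generic death response
that the whole design works to cancel. Gross outlier compounds (e.g. a
detergent-like compound that remodels half the proteome) are excluded by
listing them in `contrast_spec(excluded_compounds=)`; exclusion is a
deliberate, manual decision after inspection (`pca_screen()` helps),
never automatic. The ranking table carries the predictive loading
(signed specificity coordinate), the orthogonal coordinate magnitude
(`√Σ p⊥²`; candidates near the x-axis are the cleanest), VIP, the
univariate specificity, the mean log2 fold change vs control, and dense
up/down ranks. Whether one reads the candidates off the loading or off
VIP is genuinely underdetermined; both are provided, and on planted-truth
simulations they agree on the top candidates.

`merge_cell_lines()` intersects the complete proteins of each cell
line's matrix and stacks samples, so a contrast treats all cell lines'
replicates of the compound as one class; shared targets then outrank
cell-line-private ones, which the test suite demonstrates on constructed
data.

## Panel-size minimization

`panel_size_curve()` asks how many contrasting compounds are needed: for
each panel size *n* it draws (default) 50 seeded random panels, fits a
PLS-DA (not OPLS-DA — with panels this small, orthogonal-component
estimation is underdetermined; 2 components by default) of the compound
against the panel, and records the known target's rank by absolute
first-component loading among proteins regulated in the target's known
direction (supplied by the caller), plus the rank among all proteins. On
simulated screens with the generator's default effect sizes the mean
rank drops steeply over the first handful of contrasting compounds and
floors near rank 1 by about 8 — which is why the package's trend tests
examine sizes 1–8; beyond the floor, additional compounds neither help
nor hurt much, and occasional non-monotonicity at the full panel is
sampling noise around a saturated rank.

## Clustering and PCA screening

Compound clustering collapses replicates to per-compound mean signatures
and clusters on 1 − Pearson distance. Average linkage is the default —
a middle ground chosen because nothing stronger is implied by
"correlation-based hierarchical clustering"; complete linkage and
Euclidean distance are selectable. Protein clustering is the same on
rows with a flat cut (default `k = 15`; the criterion that would justify
one specific k is not derivable, so k is an explicit parameter).
`cluster_engagement()` produces the per-cluster mean regulation values a
radar plot displays. `pca_screen()` counts principal components of the
compound-mean signatures holding at least 1% of variance (a screen for
how many orthogonal response programs the panel spans).

## The synthetic generator

`simulate_screen()` emulates, per protein and sample on the log2 scale:
a log-normal abundance baseline (`baseline_mean = 20`, `baseline_sd =
2`, i.e. intensities around 10⁶ — the standard assumption for proteomics
intensities, documented here as an assumption, not a claim); planted
compound-specific target effects (default 2.0 log2 units, the magnitude
of a convincing specific regulation); a shared death/stress response
(10% of proteins, per-protein magnitude ≈ 0.8 ± 0.3, 75% up-regulated)
scaled per compound by a log-normal factor (`sdlog = 0.4`) so that
generic proteins are regulated under almost all compounds — exactly the
nuisance the specificity machinery must cancel; co-regulation modules
(10 clusters, within-cluster correlation 0.5, SD 0.25); replicate noise
(SD 0.25, a typical replicate CV for isobaric quantification);
per-protein per-plex batch offsets (SD 0.1); per-channel loading offsets
(SD 0.1, removed by median normalization); and per-plex dropout (a
protein missing in a whole plex with probability `dropout_prob`),
reproducing how missingness accumulates when plexes are merged. Treated
samples are laid out replicate-major so one compound's replicates land
in different plexes, and every plex carries its own vehicle control.

What it does **not** emulate: peptide-level sampling and protein
inference, isotope impurity interference between channels,
abundance-dependent missingness (dropout is uniform per plex),
ratio compression, or correlations between target identity and
abundance. Passing recovery tests on this generator therefore shows the
statistical machinery is sound under the stated noise model — not that
any particular real screen will behave as cleanly.

Determinism: the whole simulation is a pure function of `sim_config()`
including its `seed`; byte-identical outputs are asserted in the tests.

## Problem sizes and numerical tolerances

The test and acceptance workloads use the `"tiny"` preset (200 proteins;
9–50 compounds × 3 replicates) — large enough for stable rank statistics
(e.g. 100 screens of 49 decoy compounds + 1 contrasted compound for
recovery rates, 40 in the acceptance script; 12 random panels per size
across 5 seeds for trend tests) while keeping the full suite under a
minute. Algebraic identities are asserted tightly (unit weight norms and
score orthogonality at 1e-9/1e-6, Σ VIP² = p at 1e-6, NIPALS vs an
independent straight-loop oracle at 1e-8, chain equivariance at 1e-9);
statistical properties are asserted as designed bounds (≥95% top-1
recovery, permutation-null Q² ≤ 0 in ≥90% of 50 permutations, Spearman
trend p < 0.01). Degenerate inputs fail loudly and specifically:
all-zero channels, missing control channels, missing-value matrices fed
to the models, constant columns/signatures, rank-exceeding component
requests, infeasible plex layouts and empty cell-line intersections all
raise errors naming the offending object.

## Known limitations

* Proteins not quantified in the contrasted samples are invisible; the
  complete-case merge can be aggressive for large panels, and targets
  of low abundance (kinases especially) may simply be absent.
* If a compound's primary target is not expressed in the profiled cell
  line, the model reports downstream/off-target responders instead; the
  method cannot tell the difference.
* The specificity logic assumes the panel is diverse: a panel dominated
  by one mechanism makes that mechanism "generic" and suppresses its
  markers for every member.
* Q² on 3-vs-many contrasts is noisy (3 positive samples spread over 7
  folds); it is a sanity check rather than a model-selection criterion,
  and `n_ortho = "auto"` is deliberately conservative (ΔQ² > 0.01).
* VIP's treatment of orthogonal components follows the literal summed
  definition; other implementations may order mid-list proteins
  slightly differently.
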