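---
title: "Hierarchical masked networks for multi-omics score prediction: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical masked networks for multi-omics score prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic cohorts do and do not emulate, the numerical
choices, and the known limitations. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The selection pipeline

The network's connectivity is derived, not assumed. Starting from a
genotype dosage matrix and per-feature genomic annotations:

1. **Genotype QC.** Samples and SNPs above a missing-call-rate ceiling
   (default 5% each) are removed, then SNPs with minor allele frequency
   below 5% or a Hardy-Weinberg exact-test p below 1e-6. The
   Hardy-Weinberg test is the exact conditional test: given the observed
   allele counts, the p-value sums the probabilities of all heterozygote
   counts no more probable than the observed one. A widely used printed
   form of this protocol states the missingness and HWE directions
   inverted ("missing call rate > 95% excluded", "HWE p > 1e-6
   removed"); read literally those rules discard almost nothing and the
   equilibrium-consistent SNPs respectively, so the package defaults to
   the conventional directions and exposes `literal_qc_directions` for
   comparability.
2. **Per-SNP scans and intersection.** Simple linear regression of each
   assessment score on additive dosage, two-sided t test, Bonferroni
   adjustment over tested SNPs (`BH` and `none` available), and retention
   of SNPs significant in *every* assessment at `gwas_adjusted_alpha`.
   The default alpha is 0.01 on the adjusted scale; sources differ on
   whether 0.01 or 1e-8 was used at cohort scale, and 0.01 is the one
   compatible with desk-scale power. Covariate residualization is
   available but off by default (no covariates are named for the scan in
   the protocol this mirrors).
3. **Window linking.** CpGs on the same chromosome within `window_bp`
   (default 1 Mb, boundary inclusive — "within" is read inclusively, and
   co-located features at distance 0 are linked) of a retained SNP.
4. **Promoter mapping.** Strand-aware TSS200 (1–200 bp upstream of the
   TSS) and TSS1500 (201–1500 bp) membership gates gene retention. By
   default the CpG candidate set is the within-window set and promoter
   membership then selects genes; `strict_cpg_promoter` demands both
   conditions on the CpG up front (the two readings differ in the source
   material and are both available).
5. **GO enrichment.** One-sided hypergeometric tail per term on the
   retained gene set against the probe-mapped universe,
   Benjamini-Hochberg by default (`bonferroni`, `none` available),
   threshold 0.05. Contributing genes of enriched terms become
   probe→term edges.
6. **Pruning.** Iterated to a fixed point: SNPs need an outgoing CpG
   edge, CpGs an incoming SNP edge and an outgoing probe edge, probes an
   incoming CpG edge. GO-connectedness of probes is *not* required by
   default (the bypass carries unannotated probes);
   `require_go_connected` turns it on.

## The network

With masks `M1` (SNP × CpG), `M2` (CpG × probe), `M3` (probe × term),
the hierarchical stages are

- `Y1 = act(X_snp (M1 ⊙ W1) + B1)`
- `Y2 = act(g(X_cpg) ⊙ Y1 + B2)` — multiplicative coupling of the
  feature-scaled methylation input with upstream genetic signal,
- `Y3 = act(g(X_expr) / max(f(Y2, M2), ε) + B3)` — division-based
  attenuation: promoter methylation signal suppresses the expression
  pathway,
- `Y4 = act(f(Y3, M3))` — GO-term aggregation with no new input,

where `g` is the identity-masked diagonal map giving each raw feature one
trainable weight. The ambiguous piecewise "additive vs decremental"
combination rule is resolved as elementwise product for the
amplifying case and elementwise division for the attenuating case,
matching the concrete layer equations. A fully connected bypass chain
(20 nodes per stage; the first reads the first available omics input
directly, later stages read the previous bypass concatenated with that
stage's output) runs alongside, and `[Y4, bypass]` feeds four
batch-norm → dense(128, ReLU, L2) → dropout(0.7) blocks, a 20-node
bottleneck, demographic concatenation, one more block, and a linear
output. Batch norm uses momentum 0.9 and epsilon 0.005; weights use
variance-scaling initialization, computed per-unit on the masked fan-in
for masked layers (the source is silent there).

Variants for ablation: `fully_connected` (all-ones masks),
`randomized` (edge counts preserved, positions redrawn uniformly over
the whole matrix; a degree-preserving row shuffle is available — which
of the three schemes the original used is not stated),
`hierarchy_only` (dense stages concatenated in layer order, no
elementwise coupling), `drop_snp`/`drop_cpg`/`drop_expr` (modality
removed and neighbors rewired: dropping the CpG layer feeds `Y1` to the
division stage directly; dropping expression composes `M2 M3` into a
CpG→term mask — the rewiring rules are this package's construction, the
source states only that modalities were removed), `no_go` (`Y3`
straight to the head), and `pgnn` (all omics concatenated into one
input sparsely wired to a term-width layer through composed
feature→gene→term annotation, identical head).

### Numerical choices

- **Division clamp.** `denominator_epsilon` defaults to 1e-2. With ReLU
  omics activations the denominator is *exactly zero* whenever a unit is
  inactive, so the clamp bounds the attenuation gain at `1/ε`. An
  earlier 1e-6 default produced gains of 1e6 and occasional wild
  test-set predictions (three orders of magnitude off the score scale)
  from denominators that were healthy on the training split only; 1e-2
  caps the gain at 100× and removes those excursions. The count of
  clamped activations is a useful instability telemetry if you lower ε.
- **Optimizer.** Adam, learning rate 3e-3, minibatch 64, squared-error
  loss plus L2 (1e-4) on weight matrices (masked weights decay only
  inside the mask so masked-out entries stay exactly inert). At 1e-3
  the validation loss is still clearly decreasing when the epoch budget
  (500) ends, i.e. the early-stopping protocol returns an under-trained
  model; 3e-3 converges within it. Smaller batches destabilize the
  division stage.
- **Protocol.** One 70/30 train/test split fixed by the config seed and
  shared by every variant and baseline (the comparison protocol this
  mirrors states all models used the same split); 20% of training held
  out for early stopping (patience 20, best parameters restored); three
  repeats that re-randomize initialization and minibatch order — not the
  split — so variant comparisons are paired. Metrics are mean ± sd of
  test MAE and MSE over repeats.
- **Degenerate inputs.** Constant-dosage SNPs are flagged untestable
  with p = 1; constant expression features min-max-normalize to 0.5 with
  a warning; zero-total intensity cells become missing beta values and
  are counted; zero-variance vectors in correlation analyses are
  excluded and logged. HWE probability ties are compared with a 1e-7
  relative guard, the conventional floating-point tolerance for this
  test.

## Interpretation

DeepLIFT with the Rescale rule, run in eval mode (frozen batch-norm
statistics, no dropout). Linear ops propagate multipliers like
gradients; elementwise nonlinearities use the finite-difference slope
between actual and reference activations (derivative fallback below
1e-7 input difference); products use the exact symmetric split
`Δ(ab) = (b+b₀)/2·Δa + (a+a₀)/2·Δb`; the clamp-plus-reciprocal is one
composed unit. This makes sum-to-delta hold to machine precision, which
the suite checks at 1e-4. The reference is the training-set mean per
feature by default (all-zeros by flag) — the source names the algorithm
but not the reference. Per-feature scores are means of absolute
per-sample contributions (signed means are also emitted; which the
source averaged is not stated). Percentile ranks are computed within
each molecular layer, and the Sankey export keeps a link only when both
endpoints are in the layer's top-k *and* the edge exists in the relation
map, so every displayed flow satisfies the spatial-functional
constraints.

## The synthetic cohorts

`simulate_cohort()` plants `n_causal_cascades` SNP→CpG→gene cascades on
one linear chromosome (multi-chromosome placement sits behind the
annotation interface): the causal CpG lies in its gene's promoter, the
causal SNP within the cis window of the CpG. Genotypes are
Binomial(2, MAF); methylation is simulated on the logit scale
(baseline + slope × centered dosage + noise) and mapped through the
logistic function, which preserves the beta-value range without
truncation artifacts; each causal gene has a latent transcriptional
activity `base − meth_expr_effect · (β − mean β)`, and its probe
measures that activity plus assay noise. The latent cognitive score is
the standardized causal-activity combination scaled to
`score_heritability` of variance, plus a small demographic component and
noise; four bounded assessment scores are monotone transforms of the
latent score plus independent per-test noise. The errors-in-variables
structure matters: because the score depends on the *activity* rather
than the measured probe value, upstream methylation and genotype carry
information beyond measured expression, which is exactly the premise of
a hierarchical integration model. Diagnosis is CN for the top latent
tertile and CI otherwise (approximating the roughly one-third CN
composition of the cohort this emulates, without modeling diagnosis
clinically), and the plasma p-Tau proxy is a noisy decreasing monotone
transform of the latent score mapped through an exponential to a
pg/mL-like scale, so rank-based analyses recover the designed signs.

Default conditions (500 samples; 200 SNPs, 300 CpGs, 100 genes/probes,
30 GO terms; 8 cascades; MAF in (0.2, 0.5); meQTL slope 2 logits per
allele; methylation→expression slope −3 per beta unit; heritability 0.7;
per-test noise sd 0.25) were fixed from a power analysis: the implied
SNP–score correlation is roughly `sqrt(h²/K)` times the SNP–activity
correlation (≈ 0.23 at these values), giving a per-scan non-centrality
around 5 at n = 500 — comfortably above the Bonferroni threshold for
0.01 over 200 SNPs — so most planted SNPs should survive the four-scan
intersection. The tests use these defaults; smaller configurations
(150–200 samples, 40–90 features per layer) appear where only
mechanics, not power, are under test.

What the generator does **not** emulate: linkage disequilibrium,
population stratification, hidden confounders, batch effects, CpG-island
clustering of null CpGs, multiple probes per gene, or realistic GO-term
overlap structure. Passing recovery tests therefore show that the
pipeline recovers the signals it models, under clean-data assumptions —
not that it is robust to the correlation structure of real cohorts.

## Known limitations

- **Connectivity ablations are nearly neutral at desk scale.** After
  selection, the desk-scale cohorts retain layers of only ~6–10 nodes,
  and the fully connected head downstream of `Y4` can re-mix any wiring
  of so few nodes. The biological, randomized and fully connected masks
  then bound comparable information, and per-repeat test-MSE differences
  are of the same order as repeat-to-repeat noise, so the *ordering* of
  biological vs randomized MSE is unstable from seed to seed (the
  acceptance script reports the measured ordering and percentage change
  at the chosen seed rather than asserting a direction). The wide-layer
  regime of real cohorts — tens of thousands of CpGs against hundreds of
  samples, where sparse curated wiring is the difference between an
  estimable model and an overparameterized one — is outside what these
  cohorts can demonstrate.
- The division-based coupling is intrinsically delicate: its benefit
  hinges on the clamp and the omics activation (ReLU by default; tanh
  and sigmoid available). Sigmoid bounds the denominator away from
  large gains and may suit noisier data.
- Demographics are standardized on the full cohort before splitting; at
  these sample sizes the leaked means/sds are negligible, but a strictly
  nested pipeline would standardize within training folds.
- p-Tau serves both as a demographic input (default on, matching the
  six-feature block this mirrors) and as the anchor of the correlation
  analyses; `prepare_model_data(include_ptau = FALSE)` avoids the
  circularity when both are used together.
- Exact permutation p-values for Spearman correlations are computed for
  n ≤ 9 without ties; tied or larger samples use midranks with the t
  approximation, which is what the correlation tables of typical cohort
  analyses use.
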