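---
title: "Methods: detecting sex-biased genes and miRNAs in monosex embryos"
author: "sexdimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting sex-biased genes and miRNAs in monosex embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdimorph)
```

# The experimental setting

Monosex broods — all-female embryos from sex-reversed ΔXX sires, all-male
embryos from YY "supermale" sires — make gender a known, pool-level factor
from the moment of fertilization. `sexdimorph` implements the statistics
of a screen built on that design: two-color expression arrays and small-RNA
libraries of male and female embryo pools at 2, 5 and 9 days post
fertilization (dpf), followed up by qPCR and by sequence analysis of a
candidate master gene. This vignette explains each model, the tunable
parameters, the numerical choices, and what the synthetic data do and do
not establish.

# Two-color expression arrays

## Normalization

Each array hybridizes a male against a female pool in opposite dyes.
Working on the M–A representation (M = log2 R/G, A = mean log intensity):

* `loess_normalize()` subtracts a tricube-weighted local **linear**
  regression of M on A (the classical scatterplot smoother, computed by
  `stats::lowess`). Defaults: `span = 0.3` (the fraction of probes in each
  local window — small enough to track curvature of dye chemistry, large
  enough to be insensitive to differential expression), `iterations = 0`
  (no robustness re-weighting, so the fit is the plain local least-squares
  solution that the package's oracle tests reproduce), and the standard
  1%-of-range interpolation grid (`delta = NULL`; exact evaluation at
  every point is available with `delta = 0` and is what the tests use).
* `aquantile_normalize()` forces the distribution of A to be identical
  across arrays (each rank is replaced by the cross-array mean at that
  rank; `limma::normalizeQuantiles`), leaving within-array M untouched.
* `split_single_channel()` reconstructs per-channel intensities
  (red = A + M/2, green = A − M/2) so that every hybridized sample is one
  observation. The intraspot correlation between the two channels of a
  spot is **not** modelled; the dye factor in the linear model absorbs the
  mean dye effect. This is a documented simplification: standard
  generalized-least-squares single-channel machinery would weight
  contrasts slightly differently.
* `collapse_replicates()` represents replicated probes by their per-sample
  median (mean of the two middle values for even groups).

Non-positive intensities are set missing probe-wise per array (with a
logged count); probes missing in more than 20% of samples
(`max_missing = 0.2`) are dropped, the remainder are refit on their
observed samples.

## Per-probe model and gender least-squares means

Each probe is fit by ordinary least squares with fixed effects slide,
array, dye, gender, sire nested within gender, dpf and dam, all in
sum-to-zero coding, so the least-squares mean of a gender is the balanced
marginal mean. The nested sire coding uses within-gender sum-to-zero
dummies (a sire only exists inside one gender: ΔXX sires give all-female
broods, YY sires all-male). Because both channels of an array share a
slide and an embryonic age, slide and dpf are linear combinations of the
array effects in the single-channel design: the fit uses the minimum-norm
(pseudoinverse) solution, reports which coefficients are aliased, and the
gender contrast — a within-array comparison — remains estimable. p-values
come from the t distribution with the residual degrees of freedom; the
normal approximation is never used. Zero residual variance is flagged
(`degenerate`) and reported as p = 0 for a non-zero contrast rather than
NaN.

## Multiplicity

Sorting the *N* per-probe p-values ascending, the **empirical FDR** at
rank *i* is the expected-to-observed ratio

> fdr(i) = E(i) / i, with E(i) = N · p(i),

capped at 1, with tied p-values sharing the largest rank of their block
(the conservative choice). The raw ratio is reported as such; a step-up
monotone variant (running minimum from the largest p) is available behind
`monotone_fdr = TRUE`, default off. The **Poisson family-wise
probability** for expectation E is 1 − e^(−E), which is bounded by
min(1, E) and approaches the classical Bonferroni bound N·p as E → 0.

A consequence worth stating explicitly: "FDR ≤ 0.05" does *not* mean zero
false calls. Once *k* strong probes occupy the first ranks, a null probe
is admitted at rank k+1 whenever its p-value is below 0.05·(k+1)/N, and
with tens of thousands of probes a few such nulls are expected. On
full-size synthetic experiments (43,210 probes × 56 samples, 59 planted
4-fold probes, noise SD 0.2) the significant set therefore typically
contains all 59 planted probes plus on the order of three nulls — the
5% false-discovery budget being spent, not a defect. The acceptance suite
measures exactly this behavior.

Gender-difference profiles per dpf (used by `profile_correlations()`) are
computed as raw female-minus-male means of the normalized single-channel
matrix at each age, since the additive model deliberately has no
gender × dpf interaction.

# Small-RNA deviation test

Reads are counted for a mature or star arm iff they start within
[arm start − 2, arm start + 5] on the precursor; a read eligible for both
arms goes to the nearer start, ties to the mature arm. A (miRNA, dpf)
pair is tested only if both gender libraries have ≥ 4 raw reads
(`min_reads = 4`; the filter also guarantees positivity, so no pseudocount
is added). After RPM normalization, the deviation d = log2(F/M) of each
tested miRNA is standardized against the mean and SD of all tested
deviations **at that dpf** (the three ages are analyzed separately;
median/MAD standardization is available behind `robust = TRUE`), and
|z| ≥ 4 (`z_threshold = 4`) is called sex-biased in either direction, with
per-tail normal probability Φ(−4) = 3.17 × 10⁻⁵. The empirical tail FDR
compares the realized number of exceedances with 2Φ(−4) times the number
of tests, per dpf and pooled. Ratios are reported female/male on the
natural scale.

The test assumes the null deviations are approximately normal. That holds
when the log-ratio noise is dominated by components shared across the
abundance range; strongly heteroscedastic count noise (very shallow
libraries) fattens the tails and inflates 4-SD exceedances — one reason
the ≥ 4-read filter matters.

# miRNA–target concordance

Target prediction is upstream input (the published screen intersected two
external predictors); `find_seed_matches()` is only a labelled
convenience utility scanning for exact seed complements in a 3′ region,
defaulting to 2,482 nt — the third quartile of known tilapia 3′UTR
lengths — when the annotated UTR is unknown. A (miRNA, gene) pair is
concordant iff the directions are opposite. The sign test is the
one-sided binomial tail P(X ≥ k), X ~ Bin(n, ½); the perfect-concordance
case is (½)ⁿ. Because printed tables truncate rather than round,
`concordance_report()` carries both full precision (0.015625 for six of
six) and a 3-decimal truncated display value (0.015). Genes probed at
multiple genomic locations are scored per probe.

# Deletion consequence prediction

`infer_deletion()` aligns variant to reference globally with affine gaps
(match +2, mismatch −3, gap open 10, gap extend 0.5 — parameters chosen to
favor one long gap over scattered gaps, which is the right prior for a
deletion screen between near-identical paralogs). The largest gap run is
the deletion; a second gap within 50% of its length raises an ambiguity
error rather than a silent guess; alignments under 80% identity are
rejected. Substitutions are listed separately. All coordinates are
1-based inclusive.

`predict_consequence()` translates reference and variant from the model's
frame offset with the standard genetic code. Deleted residues are
reference residues with no counterpart, novel residues are variant
residues with none, computed as the residues outside the longest common
prefix and the longest common suffix of the two proteins — a definition
that handles in-frame deletions (downstream protein preserved) and
junction codons (counted deleted + novel only when the junction changes
the residue) uniformly; for frameshifts the variant tail is read in the
shifted frame to the first stop (or flagged `runthrough`). The annotated
stop is `stop_disrupted` when frameshifted, deleted, or never reached.
Domain loss reports the overlap fraction of each domain with the affected
region (the deletion itself, plus everything downstream of the junction
for frameshifts). Deletion lengths ≡ 2 (mod 3), like the 233 bp case that
motivates the module, are always frameshifts.

`marker_sex_concordance()` scores male-and-carrier / female-and-noncarrier
agreement with a one-sided binomial tail at rate ½.

# qPCR quantification

Standard curves are ordinary least squares of Ct on log10 quantity
(≥ 3 distinct dilutions required; a flat series is a non-amplifying error,
not a curve). Input amounts are IA = 10^((Ct − intercept)/slope); IA is
computed per well and then averaged across replicates — not
mean-Ct-then-IA — because the comparison to the curve is defined per
reaction. Normalization divides the target's mean IA by the reference
gene's (gapdh for cDNA, rpp30 for genomic DNA). The female/male fold
change averages within timepoints first, then across, so unbalanced
sampling does not weight ages unequally. Copy-number ratios run the same
computation on gDNA and attach a Welch t-test between sexes; the test
behind group comparisons is an assumption of this package (the original
screen does not name one). No outlier wells are removed by default.

# What the synthetic generators emulate

* `generate_microarray_experiment()`: 43,210 probes × 28 arrays
  (56 samples) by default; per-channel log2 intensity = probe baseline
  N(8, 1) + scalar level effects of slide/array/dye/sire/dam/dpf (SD
  `effect_sd`, default = `noise_sd` so normalization and model fitting are
  non-trivially exercised) + planted gender effect ± log2(FC)/2 + N(0,
  `noise_sd` = 0.2) noise, with a polynomial intensity-dependent dye bias
  (default 0.3 − 0.05·(A − 8)) folded into M for loess to remove. Planted
  fold changes are log-uniform in `fc_range` (default 1.2–4.2, the range
  reported for real embryos) with random direction. Families (sire × dam)
  are assigned to arrays at random from the seeded generator — a
  deterministic assignment would alias the nested sire factor with
  array × dye parity.
* `generate_mirna_libraries()`: six libraries (2 genders × 3 dpf) of
  negative-binomial counts (dispersion 0.02; Poisson at 0) around
  library-scaled expected RPM (log2 RPM ~ N(5, 1.5²)), with a shared
  log-normal biological fluctuation (SD 0.35 log2) per (miRNA, library)
  that makes null deviations approximately normal — the structure the
  z-test assumes and that real deviations show. Default library size 2 ×
  10⁷ reads, a mild scale-down of real embryo libraries (21–32 million).
  Planted miRNAs (default 9: two at all three ages, two at two, five at
  one) get a female-side offset of `effect_sd_units` (default 8) times the
  analytic null SD at their designated ages.
* `generate_cds_with_deletion()`, `generate_qpcr_run()`,
  `generate_genotype_table()`: random start/sense/stop CDS with a
  configured excision and brute-force-translated truth; Ct tables from the
  linear curve model; genotype tables of exact composition, shuffled.

All generators are pure functions of their configuration including the
seed, restore the caller's RNG state, and return truth tables computed
from the generated raw data.

What passing on synthetic data does **not** show: real arrays have
correlated probe effects, spatial artifacts and intraspot correlation;
real small-RNA libraries have mapping multi-hits, adapter artifacts and
abundance-dependent dispersion beyond a single NB parameter; real 3′UTRs
are not uniform random sequence. The synthetic suite validates the
statistics and the plumbing, not the biology of any particular dataset.

# Problem sizes and determinism

The test suite exercises reduced designs (hundreds to a few thousand
probes, 100–700 miRNAs) for speed, plus full-size 43,210 × 56 expression
experiments in the acceptance checks — one such run takes a few seconds,
and the recovery checks use 20 seeds each. `run_pipeline()` writes a
manifest (package version, seed, parameters, per-stage record counts)
sufficient to reproduce any run byte-for-byte.

# Known limitations

* The single-channel simplification ignores intraspot correlation
  (see above); contrast standard errors are those of OLS.
* The empirical FDR is the raw expected/observed ratio by design;
  it is not monotone in p unless `monotone_fdr = TRUE`.
* `infer_deletion()` targets the one-big-deletion regime; multiple
  comparable deletions are an explicit error, not a reconstruction.
* Residue bookkeeping at deletion junctions follows the common
  prefix/suffix definition; alternative alignments of repetitive
  junction sequence can be defensible and would differ by ±1.
* De-novo miRNA discovery, energy-based target prediction, PCA and
  clustering visualizations are out of scope; annotations and predicted
  pairs are inputs.
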