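---
title: "A translational blood-biomarker workflow: models, calibration and design notes"
author: "TransMark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A translational blood-biomarker workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TransMark)
```

## The scientific problem

Chronic neuropathic back pain (CNBP) lacks an objective diagnostic test.
A translational strategy screens whole-blood transcripts for
case/control differential expression in patients, triages the hits with
external evidence, and asks whether the surviving candidates are also
perturbed in the dorsal horn of the rat spinal-nerve-ligation (SNL)
model — if so, the molecule is a candidate *translational* biomarker
(TIMP1 being the flagship example, measurable as blood mRNA, rat
transcript and plasma protein). TransMark implements every
computational step of that workflow as tested, reusable functions, and
ships calibrated synthetic-data generators so each estimator can be
validated against known ground truth.

## The pipeline stage by stage

### Differential-expression screen and refinement gate

Expression is analysed on log2 scale. Per gene the two groups are
compared with a one-way ANOVA, which for two groups is algebraically
the pooled-variance two-sided t test (F = t²) — the test suite asserts
this identity against an independent `aov()` route. The signed fold
change is `2^(mean case − mean control)`, reported with magnitude ≥ 1
and an up/down flag (ties break upward). The primary screen keeps
fold change ≥ 1.2 and p ≤ 0.05, both boundaries inclusive.

The refinement gate then assigns each screened gene to one of three
acceptance branches, in precedence order:

* **A** — p ≤ 0.005 and FC ≥ 1.5 (stringency alone);
* **B** — external evidence (prior-correlation analysis or literature)
  with 0.005 < p ≤ 0.05 and FC ≥ 1.5;
* **C** — external evidence with p ≤ 0.005 and FC in [1.2, 1.5).

The intervals are half-open exactly where needed to make the branches
disjoint. Whether branch C truly requires external evidence is
ambiguous in the published wording; both genes that land there in the
curated panel carry literature support and the parallel sentence
structure suggests evidence is required, so the default demands it,
with `branchCRequiresEvidence = FALSE` preserving the permissive
reading. No multiple-testing correction is applied at this stage (the
original workflow applied none); a Benjamini–Hochberg column is
emitted for information only. On the curated 15-gene human panel the
gate accepts everything with branch composition A = 6, B = 7, C = 2 — a
tally hand-derived from the printed values before implementation and
frozen in the acceptance tests.

### Prior-correlation analysis over a two-colour compendium

Heterogeneous two-colour microarray experiments report per-gene log2
ratios, and different platforms carry different gene sets. Pearson
correlations are therefore computed per gene pair over exactly the
experiments where both genes are present (`use = "pairwise.complete.obs"`).
Pairs with fewer than `minPairs` co-presences are *undefined*, never
zero; the default `minPairs = 6` keeps coefficients from being driven
by two- or three-point artifacts (no minimum is published, so this is
an artifact convention). Module detection thresholds the correlation
graph and enumerates maximal cliques exactly (via igraph) — exact
enumeration is affordable at the tens-of-genes scale this analysis
targets and beats heuristics. A module's report also lists
same-direction genes whose mean correlation against the module is
≤ −threshold: the genes "usually negatively correlated" with the module
in prior experiments despite being co-regulated in the disease data.
The threshold itself is a parameter with no published default.

### qPCR relative quantification and geNorm stability

With amplification efficiency E, `RQ(g, s) = E^(mean Cq_g − Cq(g, s))`
(mean-calibrator convention; fold changes and p-values are invariant to
the calibrator, the choice is cosmetic but fixed for reproducibility).
E defaults to 2 since no per-assay efficiencies are published.
Technical replicates are arithmetically averaged with a max-spread QC
flag at 0.5 cycles. Normalized relative quantities divide by the
per-sample geometric mean of the reference genes, after which the
reference geomean is exactly 1 in every sample.

geNorm stability: for candidates j, k the pairwise variation `V_jk` is
the SD over samples of `log2(RQ_j/RQ_k)`; `M_j` is the mean of `V_jk`
over all partners, and the CV is the SD/mean of the candidate's
quantities after normalization by the geomean of all candidates.
Shared per-sample scale (RNA input) cancels in both statistics. The
classic iterative ranking (drop the worst, recompute) is also
reported. Group comparisons use a two-sided unpaired t test on log2
values (equal-variance by default, matching the analysis convention of
log-transformed normalized quantities; Welch selectable).

### ddPCR Poisson quantification

A droplet is negative only if it received zero template molecules, so
with occupancy λ (mean copies per droplet) the positive fraction is
`1 − exp(−λ)`. Replicate wells are pooled (summed positives and totals)
before inversion: `λ = −ln(1 − positives/total)`, and copies per
reaction is `λ × reactionVolume / dropletVolume`. The droplet volume
constant defaults to 0.85 nL — the convention for the droplet generator
this models, as the instrument's nominal volume is not published — and
the reaction volume to 20 µL. Saturated wells (all positive) are
flagged undefined; zero positives is a valid zero. Absolute copies are
normalized by the geometric mean of the reference genes' copies
(Rpl13a and Ubc in the rat validation design), and group statistics
run on the normalized copies per reaction.

### Plasma ELISA and nonparametric statistics

The standard curve is a four-parameter logistic
`A(x) = D + (A0 − D)/(1 + (x/C)^B)` — the immunoassay standard, chosen
because the kit's own curve model is unstated; a near-linear regime
test confirms agreement with linear interpolation in the limit. The
curve is fitted by Levenberg–Marquardt least squares and inverted
analytically; replicate absorbances are inverted individually, flagged
if outside the asymptotes, and averaged on the *concentration* scale so
curve nonlinearity does not bias duplicate means. The default dilution
factor 20 reflects 10 µl plasma diluted to 200 µl.

Group comparisons use the Mann–Whitney U test — exact when the combined
n is ≤ 25 and tie-free (the clinical group sizes of 10–12 sit inside
that range), tie-corrected normal approximation otherwise — and the
Kruskal–Wallis test with tie correction for the three-group analysis.
The protein/mRNA association is a Pearson correlation on the raw
concentration scale (the published scale is unstated; raw is the
default). Covariates: sex via unpaired t test; age via one-way ANOVA
over decade bins by default, since no age model is printed, with a
continuous-age regression F test selectable.

### Cross-species concordance

The human panel joins the rat results through an explicit, hand-curated
ortholog map (no automatic inference — the original comparisons were
hand-picked, e.g. CASP5→Casp4). A pair is *concordant* when both
directions agree and both p-values pass the significance threshold
(default 0.05); rat effects in the same direction with p in
(0.05, 0.10] raise a separate *trend* flag, deliberately never folded
into significance so informal language does not become a decision
rule. Unmapped or unanalysable genes are *untestable*. No formal
concordance criterion is published; these defaults are declared
artifact conventions.

## What the generators emulate, and how they are calibrated

All generators take explicit integer seeds (no hidden global RNG
state) and are byte-deterministic.

**Compendium** — presence/absence is Bernoulli per gene × experiment;
within a planted module, genes load on a single shared latent factor
per experiment with loading `sign·√r`, the simplest exchangeable
structure whose expected pairwise correlation is exactly
`sign_i·sign_j·r`. Anti-correlated genes (the negative blocks of a
correlation heatmap) are planted with negative loading signs.

**Blood expression** — 10 cases vs 10 controls by default, matching the
clinical design; planted signed fold changes on log2 scale with
Gaussian residuals.

**qPCR** — `Cq = baseCq − log_E(quantity × sizeFactor) + noise`: the
per-sample size factor is shared across genes (what multi-reference
normalization removes) and noise is per-gene, in cycles. The Timp1
preset plants the published SNL/sham ratio 2.19 with sham n = 8 and
SNL n = 10.

**Reference-gene panel** — 12 candidates, 18 samples. Two stable genes
(Atp5b, Ubc) share noise scale σ_s and ten others have 2σ_s. With
E = 2, cycles are log2 units, so the expected pairwise variation is
`c4(18)·√(σ_j² + σ_k²)` where c4 is the small-sample unbiasing constant
of the Gaussian sample SD, and the expected stability of a stable gene
is

$$E[M_s] = \frac{c_4(18)\,\sigma_s\,(\sqrt{2} + 10\sqrt{5})}{11}.$$

σ_s is solved so this equals the published calibration target
M = 0.419. The same geometry implies a stable-gene CV of normalized
quantities of ≈ 0.145 — matching the published companion value without
any additional tuning, which is a reassuring consistency check on the
2:1 noise ratio chosen for the unstable candidates.

**ddPCR** — true copies per reaction per sample (lognormal biological
spread in the rat preset), then per-well binomial droplet counts with
positive probability `1 − exp(−λ)`.

**Plasma** — three groups at the published summary statistics (control
157.3 ± 33.2 ng/ml n = 10; CNBP 278.4 ± 131.4 n = 10; CIBP
147.8 ± 75.55 n = 12). The default family is a zero-truncated normal;
because truncation shifts the mean of a wide distribution (the CNBP
group would otherwise be biased upward by ≈ 5.6 ng/ml), the preset
*location is defined as the mean of the truncated distribution* and
the underlying Gaussian mean is solved numerically — so simulated
group means are centred on the printed values. The published range
statistics hint at right skew, so a lognormal family is selectable;
neither is claimed as the true data-generating family. Paired
whole-blood mRNA is planted on the pooled paired subjects (controls +
CNBP, n = 20) by mixing the standardized concentrations with
independent noise at the published correlation 0.68, on the raw scale.

**ELISA plate** — subjects' diluted concentrations pushed through a
known 4PL curve with duplicate wells and optional absorbance noise.

What the generators deliberately do **not** emulate: array
hybridization/probe-level noise, batch effects, compendium
normalization, amplification-curve shapes, droplet gating from raw
fluorescence, plate-layout effects or inter-plate drift. Passing
recovery tests therefore demonstrates that the *estimators* are
correct and calibrated under clean generative assumptions — not that
the workflow is robust to instrument-level artifacts.

## Numerical and degenerate-input conventions

* Pairwise correlations on zero-variance subsets are undefined (NA)
  and flagged, never errors; undefined entries cannot support module
  membership.
* Genes with zero within-group variance in both groups get an
  undefined p-value, flagged, not dropped.
* qPCR/ddPCR genes with fewer than two quantifiable samples per group
  are reported as "not analysable" rather than silently omitted, and
  surface as "untestable" in the concordance report.
* Saturated ddPCR wells are undefined; zero positives is a valid zero.
* Ties in the Mann–Whitney test always force the corrected
  approximation; tie-free small samples use the exact distribution.
* The ELISA inverse is only evaluated strictly between the fitted
  asymptotes; out-of-range replicates are flagged and excluded from
  the duplicate mean.

## Problem sizes in the test and acceptance suites

The suites are sized to the study's own designs: plasma recovery runs
200–300 replicate panels of the clinical group sizes, the correlation
recovery 500 panels of 20 paired subjects, the qPCR recovery 200
replicates of the 8 + 10 animal design, the geNorm calibration 100
replicates of the 12-gene × 18-sample panel, and the null-calibration
checks 1000 simulated datasets. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping the
whole suite fast.

## Known limitations

* The proprietary error-propagation model of commercial qPCR analysis
  software is not reproduced; technical replicates are averaged before
  quantification (a documented deviation).
* The refinement gate consumes literature flags as given; it performs
  no text mining.
* Compendium input is assumed pre-normalized; no normalization of
  two-colour arrays is implemented.
* Published clinical p-values depend on the unpublished raw data; they
  are treated as fixture inputs and calibration targets, not as
  quantities this package claims to reproduce from raw measurements.
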