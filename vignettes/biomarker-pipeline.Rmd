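---
title: "Indirect biomarker discovery and serum panel modeling with lcmspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect biomarker discovery and serum panel modeling with lcmspanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmspanel)
```

## The problem

Blood-based markers that flag early lung cancer are hard to find directly in
serum or plasma: a handful of highly abundant proteins dominates those
matrices. The *indirect* strategy implemented here discovers candidates
where tumor proteins are concentrated — resected tumor tissue, cultured
cancer cell lines, and the serum-free conditioned medium into which cultured
cells shed and secrete proteins — and only then verifies the survivors by
immunoassay in case/control serum. `lcmspanel` implements that computational
pipeline end to end, together with a synthetic-data module that generates
every input with known ground truth, so each stage can be validated by
parameter recovery rather than by eyeballing.

The pipeline stages are:

1. **Ion-map alignment.** Each LC/MS run yields an *ion map*: a peak list of
   (m/z, retention time, charge, intensity). Maps are aligned on
   (m/z, RT, z), retention times are normalized in two steps (a primary
   affine warp anchored on spiked internal-standard peptides, then a
   secondary monotone refinement against the cross-map consensus of common
   features), and intensities are normalized by per-map offsets on the log2
   scale.
2. **Candidate discovery.** Tumor/control peptide-ion ratios are screened at
   a strict four-fold gate; flagged peptides are aggregated per protein and
   the prioritization criteria applied: more than one distinct differential
   peptide, more than one malignant sample, median cancer:control ratio
   above 4, and secreted or cell-membrane localization.
3. **Platform integration.** Candidates from the three discovery systems are
   unioned into a membership table, partitioned into the seven Venn regions,
   and summarized against a static protein-class annotation snapshot.
4. **Serum verification and panel modeling.** Marker-level case/control
   statistics (median, IQR, two-sample Kolmogorov–Smirnov, single-marker
   AUC), then a multi-marker panel: logistic regression of disease status on
   the marker concentrations under an elastic-net penalty, with the penalty
   weight chosen by bootstrap resampling and maximization of the mean
   out-of-bag AUC.

## The models, and the choices behind them

### Peptide observability

The discovery chemistry captures cysteine-containing peptides (thiol-tag
enrichment) and N-glycosylated peptides (hydrazide capture). The simulator
encodes this as an eligibility rule on the in-silico tryptic digest
(cleavage after K/R except before P): a peptide of length 5–25 is observable
iff it carries a cysteine or the sequon N-X-S/T with X ≠ P. The sequon is the
standard N-glycosylation motif; the X ≠ P exclusion is the textbook reading
of a motif statement that does not spell it out.

### The ion-map noise model

No public raw data accompany the reference cohorts, so the generator uses a
feature-level model chosen for realism and analytic tractability rather than
instrument fidelity:

* a monotone per-map RT drift `rt_obs = a + b·rt + c·rt²` (defaults keep the
  warp strictly increasing across the gradient);
* a per-map log2 intensity offset (sample loading / ionization scale);
* multiplicative log-normal intensity noise (`noise_sd` on the log2 scale,
  default 0.25);
* a detection floor (default 500 counts) and missing-at-random dropout
  (default 5%).

Reference retention times are a deterministic function of peptide
hydropathy, so all maps share a common latent coordinate without sharing RNG
state. What the simulator deliberately does **not** model: raw spectra,
isotope envelopes, chromatographic peak shapes, co-elution interference, or
chimeric identifications. Passing recovery tests therefore demonstrates that
the alignment/discovery logic is correct under feature-level noise — not that
it would survive raw-signal artifacts.

### Alignment numerics

*Primary warp*: ordinary least squares of reference RT on observed RT over
the matched internal standards (≥ 2 anchors required). *Secondary
refinement*: iterate {match features, compute per-group consensus RT, refit
each map's warp as a monotone piecewise-linear map (quantile-binned medians,
isotonic regression on the knots) from raw RT to consensus}; the iteration
keeps the best (median absolute residual) warp set and stops after at most a
few rounds. *Matching*: ions are partitioned by charge and by m/z gaps
larger than the tolerance, then grouped within a partition by merging the
closest compatible pairs first (ppm distance, RT breaking ties); a merge
must keep one ion per map and the group within both tolerances. Processing
closest pairs first is what resolves an ambiguous competitor in favor of the
minimal combined distance; tests verify the result against exhaustive
enumeration on small instances. Defaults — 10 ppm, 1.0 min — are
configuration, not dogma; the reference method states no tolerances.

*Intensity normalization* reads "minimizing the sum of the differences
between each ion's intensity and its cross-map mean" as least squares on
log2 intensities — the standard reading for multiplicative MS intensity
error — and solves for per-map additive offsets by alternating closed-form
updates (tolerance 1e-10, ≤ 100 iterations; offsets centered to sum to
zero; missing cells excluded, never imputed). An L1 variant (medians) is
available via `alignment_config(normalization = "L1_log")`. Offsets are
computed per experiment (the set of maps passed in); the caller decides
whether that is a platform, a pair, or everything.

### Discovery rules

The fold gate is strict (`ratio > 4`): a ratio of exactly 4.0 fails.
"Multiple" peptides/samples is read as ≥ 2. Censored ratios — tumor observed,
control below the detection floor — enter at their lower bound
`tumor / floor`, which keeps genuinely on/off markers. One caveat discovered
during validation and worth stating plainly: under missing-at-random
dropout, a technically dropped control peak is indistinguishable from true
censoring and the lower bound (typically ≫ 4) flags the peptide. The
parameter-recovery experiments therefore run with censoring-driven
missingness only (`dropout_rate = 0`); with nonzero random dropout the null
pass-rate is dominated by this channel, which is a property of the censoring
rule itself, not of the filters. Protein aggregation pools all differential
peptide ratios into one median by default (`method = "pooled"`); a
median-of-per-sample-medians variant is available.

The question of whether the 4× screen applies at the ion level before
identification *and* again at the protein level is resolved as: both. The
ion gate lives in `flag_differential_peptides()`, the protein gate in
`apply_prioritization_filters()`.

### The discovery fixture

`generate_discovery_fixture()` ships a fixed membership table of 179
markers over three platforms with region counts {exactly one: 57/27/24,
exactly two: 30/12/15, all three: 14}. The per-platform totals (113, 86,
65), the grand total, the triple overlap (14), and the cell-line ∩
conditioned-medium overlap (29, read as including the triple: 15 + 14)
determine all regions except the split of the two tissue-pair regions, whose
sum is 42; the (30, 12) split is an arbitrary fixed choice so downstream
counts are stable. Nine of the 29 cell-line/conditioned-medium markers carry
a `resolved_same_cell_line` flag; per-line provenance is not recomputable
from published information, so this is fixture metadata. The companion
annotation table is synthetic: 141/179 markers classified (79%), with the
most common classes at their reported frequencies. Reported percentages use
round-half-up, which is how the printed fractions (60%, 8%, 31%, 79%)
reproduce exactly.

### Serum cohort calibration

Marker concentrations are log-normal. Given a group's printed median and
interquartile range, the calibration is

* `meanlog = ln(median)`
* `sdlog = (ln Q3 − ln Q1) / (2 · qnorm(0.75))`

A two-parameter log-normal cannot reproduce an *asymmetric* (Q1, median,
Q3) triple exactly; what is exact is the median and the geometric quartile
ratio Q3/Q1, and the tests assert precisely that. One marker (CYFRA 21-1,
control group) has Q1 printed as 0.00 — a quartile pinned at the assay
floor — so its scale is calibrated from the upper half-width alone,
`sdlog = (ln Q3 − ln median)/qnorm(0.75)`. Marker–marker correlation
defaults to independence (published tables give marginals only) and is
configurable via a PSD correlation matrix on the log scale. Demographics
(age, sex, pack-years, stage, histology mix) follow the verification-cohort
table; case lesion sizes are log-normal around 2.8 cm and coupled to each
case's latent marker burden so that panel scores correlate with lesion size,
qualitatively mirroring the reported behavior.

### Panel modeling

The panel minimizes, on internally standardized predictors with an
unpenalized intercept,

$$\frac{1}{n}\sum_i \big[\log(1 + e^{\eta_i}) - y_i \eta_i\big]
 \;+\; \lambda\Big(\alpha\lVert\beta\rVert_1
 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big),$$

solved by IRLS with cyclic coordinate descent (compiled core; the
soft-threshold update produces exact zeros, which is what drops a marker
from the panel). The 1/n likelihood scaling makes λ comparable across
sample sizes. Coefficients are reported back on the concentration scale.
Concentrations enter untransformed by default, mirroring the reference
regression on ng/mL; `train_panel(log_transform = TRUE)` fits natural-log
concentrations instead, which is the right scale for strongly skewed
markers. The mixing parameter α is not stated by the reference procedure;
the default is 0.5.

λ is chosen by bootstrap out-of-bag AUC: resample n subjects with
replacement, fit the penalty path on the in-bag sample (warm starts down the
grid), score the out-of-bag subjects, and average the OOB AUC per λ across
draws (the reference procedure uses 10,000 draws; everything here is
config-reducible). The chosen λ attains the maximal mean OOB AUC, ties
resolved toward the larger (more parsimonious) λ. Draws whose out-of-bag
set is single-class are skipped and counted. The λ grid is deliberately
coarse — 15 log-spaced points from the all-zero boundary down to 1% of
it — because the mean OOB AUC is flat over long stretches of the path and an
argmax over many near-tied points is dominated by Monte Carlo noise rather
than by the systematic shrinkage benefit. The expected out-of-bag fraction
is $(1-1/n)^n \approx e^{-1} \approx 0.368$ of subjects per draw
(equivalently, the expected fraction of distinct in-bag subjects is
$1-(1-1/n)^n \approx 0.632$); the tests verify this identity at n = 283.

Two properties of this selection procedure deserve emphasis. First, it
*can* discard a no-signal marker: in the packaged recovery experiment
(n = 283; eight informative markers with standardized log-odds 0.6 and
pairwise log-scale correlation 0.7, reflecting how strongly serum tumor
markers co-vary; one independent pure-noise marker; α = 0.5; 500 bootstrap
draws) the selected panel zeroes the noise marker in 10 of 10 seeded runs,
the analogue of a nine-marker panel shrinking to eight. The experiment fits
log concentrations because its generating signal is log-linear; fitting the
raw scale would confound skewness misspecification with selection behavior.
Second, it has an intrinsic blind spot: out-of-bag subjects come from the
same cohort, so a *dataset-level* spurious correlation between a noise
marker and the outcome is shared by in-bag and out-of-bag subjects and
cannot be rejected by this procedure — only an external cohort can. The
zero rate is therefore a property of both the method and the cohort size.

ROC machinery uses the rank (Mann–Whitney) AUC with mid-rank tie handling;
sensitivity-at-specificity reports only achievable operating points (no
interpolation), so a quoted (sensitivity, specificity) pair always
corresponds to an actual threshold. KS statistics use the asymptotic
two-sample test; quantiles are linear-interpolation (type 7).

## Reproducibility and problem sizes

Every generator takes an explicit seed and derives per-stage sub-seeds, so
`run_pipeline()` is bit-identical under a fixed configuration, and writers
stamp artifacts with the package version, seed and configuration hash. The
packaged experiments use deliberately modest sizes chosen to exercise every
code path at full statistical strength: discovery recovery uses 500-protein
proteomes across 3 tumor/control pairs and 10 seeds; calibration checks draw
100,000 subjects per group; the panel experiments use n = 283 with 500–1,000
bootstrap draws. All are configuration values, and all scale up by changing
one argument.

## Known limitations

* Feature-level simulation only; no raw-signal artifacts (see above).
* Identifications are taken as given: one peptide, one protein. Shared
  peptides and protein inference are out of scope, as is multiple-testing
  control at the discovery stage (the reference screen applies none).
* The censored-ratio rule converts missing-at-random control dropouts into
  apparent on/off markers; interpret censored candidates accordingly.
* The published clinical AUCs (training 0.913, bootstrap-validated 0.903,
  test 0.775/0.745/0.799) derive from unpublished subject-level data and are
  quoted here only as context; nothing in this package claims to reproduce
  them, and the simulated-cohort AUCs that the pipeline prints measure the
  simulation, not the clinical studies.
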