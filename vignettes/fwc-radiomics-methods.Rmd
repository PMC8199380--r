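---
title: "Fractional water content radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional water content radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwctex)
```

## The quantity under study

Two-point Dixon MRI separates the proton signal into co-registered
water-only and fat-only images. The fractional water content of a pixel is

$$\mathrm{FWC} = \frac{W}{W + F},$$

the complement of the clinically familiar signal fat fraction
($\mathrm{FWC} = 1 - \mathrm{FF}$). It is dimensionless, bounded in
$[0, 1]$, and invariant to global intensity scaling, which makes it a
parametric map suitable for texture analysis across scanners and
acquisitions. Pixels with zero total signal (air, background) carry no
information about the ratio: `compute_fwc_map()` flags them invalid and
every downstream statistic excludes them, rather than zero-filling, which
would bias location statistics such as the mean and the mean of positive
pixels.

## Filtration-histogram texture analysis

`extract_feature_set()` implements the two-stage filtration-histogram
approach. First the FWC map is band-pass filtered with a
Laplacian-of-Gaussian (LoG) kernel whose physical scale is set by the
spatial scale factor (SSF, in mm): fine (2 mm), medium (3–5 mm) and coarse
(6 mm) texture, plus the unfiltered map (SSF 0). Then six first-order
statistics are computed over the ROI pixels of the filtered map: mean,
sample SD, histogram entropy, mean of positive pixels (MPP), skewness and
kurtosis — $6 \times 6 = 36$ features per ROI.

Several details of commercial implementations are proprietary and
unpublished, so this package fixes them explicitly and records them in the
feature-table metadata:

* **SSF-to-sigma mapping.** $\sigma_{px} = \mathrm{SSF}_{mm} /
  \text{pixel spacing}_{mm}$ per axis, so SSF is the characteristic
  feature size in physical units on any grid (anisotropic spacing is
  supported).
* **Kernel discretisation.** The analytic LoG is sampled to a truncation
  radius of $4\sigma$ and then mean-subtracted, making the discrete
  weight sum exactly zero: a constant field is annihilated exactly, and
  adding a constant to an image provably changes only the unfiltered
  mean. With the standard negative-centre sign convention, *water-poor*
  foci in a high-FWC tumour produce positive filter responses — they are
  the "bright objects" whose number and intensity the MPP statistic
  tracks.
* **Boundary policy.** The whole image is filtered under mirror
  (reflect) padding *before* masking. Masking first would turn the ROI
  boundary into an artificial step edge whose ring response dominates
  every scale.
* **Entropy binning.** Shannon entropy in bits over a 64-bin equal-width
  histogram spanning the ROI's own min–max range. This makes entropy
  invariant to intensity scaling and shifts; a constant ROI has entropy
  0 by convention.
* **Shape statistics.** Adjusted Fisher–Pearson skewness and adjusted
  *excess* kurtosis (normal = 0). Each statistic is `NA` when its
  definition fails (SD needs $n \ge 2$, skewness $n \ge 3$, kurtosis
  $n \ge 4$, all three need nonzero spread; MPP needs at least one
  positive value). Missing features are excluded pairwise downstream.
* **Numerical zero.** The FFT convolution leaves round-off of order
  $10^{-16}$; filtered magnitudes below $10^{-11} \times
  \max|\text{field}|$ are snapped to zero so that analytically-zero
  responses are reported as exactly zero.

## The synthetic cohort generator

No imaging data are shipped; `simulate_cohort()` generates the entire
study — Dixon pairs, two operators' ROI contours, a clinical table and a
mutation panel — reproducibly from a seed. Its default configuration *is*
the study design the pipeline targets: 30 patients, one axial slice each,
0.78 mm pixels, lesion FWC plateau 0.88.

Each patient carries a latent heterogeneity driver $z \sim N(0,1)$ that
expresses itself only through tumour structure: the number (0–8) and depth
(peak $\Delta\mathrm{FWC} \approx -0.14$ to $-0.42$) of Gaussian
water-poor pockets (1.5–3.5 mm radius) superimposed on the plateau. The
pockets emulate necrotic/fibrotic foci; they pull single-pixel FWC values
far below the plateau and the ROI-mean FWC to roughly 0.75, a compromise:
shallower or smaller pockets would keep the ROI mean nearer the plateau
but leave too little coarse-scale structure for the texture chain to
detect. The lesion outline is a thresholded low-pass noise blob with a
radial bias (so outlines are smooth, random and meaningfully jitterable),
and the plateau decays into the surrounding tissue over a ~2 px Gaussian
skirt rather than a knife edge. The FWC design is converted back to a
consistent water/fat pair ($W = \mathrm{FWC}\cdot S$,
$F = (1-\mathrm{FWC})\cdot S$, constant total signal $S$ inside the body,
zero outside), and independent truncated Gaussian noise is added to each
channel — so noise propagates into the ratio the way Dixon channel noise
does, rather than being painted onto the FWC directly.

The driver is then coupled to the non-imaging data:

* **TLG** via a Gaussian copula. The config parameter
  `tlg_texture_coupling` (default $-0.55$) targets the *measured* rank
  correlation between coarse-scale MPP and TLG. The imaging chain
  (pocket placement randomness, lesion geometry, channel noise, ROI
  jitter) attenuates the driver's rank signal by a factor of about 0.85
  under default settings, so the latent copula correlation is
  strengthened by that factor (capped at 0.95) before the usual
  normal-to-Spearman conversion $\rho_n = 2\sin(\pi\rho_s/6)$.
* **Survival**: exponential event times with log hazard ratio
  `hazard_log_hr` (default 1.5) for the high-driver half, administrative
  censoring at the 32-month study horizon plus uniform early censoring
  at rate `censoring_rate`.
* **Mutation burden**: Poisson counts with mean 7 for low-driver (good
  prognosis) patients and 1.5 for high-driver patients, realised as
  specific calls over a fixed 12-gene colorectal panel and restricted to
  a 12-patient profiled subset. Drawing the count first and then the
  genes keeps the count distribution Poisson while leaving every
  per-gene 2×2 table well defined.

Operator ROIs are the truth outline under morphological jitter: an
integer translation up to `roi_jitter_px` and a random one-pixel
dilation/erosion, giving inter-operator Dice coefficients around
0.85–0.95 — agreement high enough that most features pass ICC QC, as a
standardised contouring protocol would produce.

What the generator does **not** emulate: real Dixon reconstruction
artefacts (bias fields, water–fat swaps), anatomic context, 3D structure,
non-exponential hazards, and any realistic joint distribution of SUV/ADC
metrics (they are drawn from plausible marginals, with SUV loosely tied
to TLG). Passing tests therefore demonstrate that the *pipeline* is
correct and well calibrated, not that the biological effect sizes are
realistic.

## The four statistical stages

**Inter-operator QC.** `icc_two_way()` is the two-way random-effects,
absolute-agreement, single-measure ICC(2,1) from the ANOVA mean-squares
decomposition — the agreement form, so a systematic offset between
operators counts against reproducibility. Features with ICC ≤ 0.75 are
dropped (> 0.9 is graded excellent); survivors are replaced by the
per-patient operator mean. Features with fewer than three complete pairs
or zero variance are unevaluable and dropped with a log message.

**Correlation screening.** Spearman rank correlation (average ranks for
ties, t-approximation p-values) of each retained feature against six
functional metrics (SUVmax, SUVmean, TLG, ADC mean/skewness/kurtosis),
with Benjamini–Hochberg step-up control at FDR 0.1. The BH family is
per-metric by default — features form one family per functional metric —
with global pooling available via `scope = "global"`; the choice is
recorded in the report.

**Survival.** Each marker is dichotomised at the admissible threshold
(midpoints between consecutive distinct values leaving at least
`min_group_frac` = 10% of subjects per side, to exclude degenerate 1-vs-29
splits) that minimises the two-group log-rank p-value. The minimum p is
exploratory — it is not corrected for the threshold search, and the report
says so. The multivariate stage then takes the *best* univariately
significant marker of each family (texture, FDG uptake, ADC), forms all
pairwise 0/1 interaction products, and runs forward-stepwise Cox
selection: at each step the score (Rao) statistic of every excluded
candidate is evaluated at the current partial-likelihood optimum (Efron
ties), and the largest enters while its 1-df score p is below 0.05.
Interactions may enter without main effects — an interaction-only model is
a legitimate outcome. Monotone likelihood (complete separation) is
detected by runaway coefficients and flagged rather than hidden.

**Mutation association.** Groups are defined by the most significant
prognostic texture marker (smallest log-rank p; ties broken toward the
coarsest SSF, then alphabetical statistic). The per-patient mutation count
difference is tested by a two-sided Mann–Whitney U: exact (a
shift-algorithm enumeration of the conditional U distribution, ties by
midranks) for combined $n \le 12$, tie-corrected normal approximation
otherwise. Per-gene 2×2 tables get a two-tailed Fisher exact test.

## Numerical and degenerate-input policy

* Thresholding an all-zero image is an error (there is no signal to
  delineate), as is an ROI that covers no valid pixels.
* A cohort generated with no pockets, no noise, no jitter and uniform
  surroundings is processed to completion: all filtered features are
  exactly degenerate (SD 0, entropy 0, MPP missing), QC marks every
  feature unevaluable, and the downstream stages run on the functional
  metrics alone.
* All Monte-Carlo behaviour is seed-derived: one config seed fans out to
  per-patient, per-operator and per-stage streams, so identical
  configurations reproduce bit-identical cohorts.

## Problem sizes used in the test-suite

The packaged checks run the generator at the scales the statistics need:
single cohorts of 10–30 patients on 48–64 px slices for structural and
end-to-end checks; 50 replicates of 200-patient cohorts for the
coupling-recovery and Cox-recovery checks; 100 replicates for ICC
recovery; 200 replicates for mutation-test power; and 1000 replicate
null cohorts (tables only, no images) for type-I-error calibration of the
Spearman, log-rank and Mann–Whitney stages. Exhaustive-enumeration
oracles cover every 2×2 Fisher table up to total count 20 and
Mann–Whitney instances up to combined $n = 12$.

## Known limitations

* The texture defaults (truncation radius, entropy bins, kurtosis
  convention) are reasonable reconstructions of unpublished commercial
  choices; absolute feature values will not match other implementations,
  although their qualitative behaviour does.
* The optimal-cutpoint survival p-values are optimistically biased by
  construction; the package reports them as exploratory and applies no
  cross-validation or split-sample correction.
* Single-slice 2D analysis only; no volumetric kernels.
* The attenuation constant in the TLG copula is calibrated for the
  default imaging settings; configurations far from the defaults will
  realise a somewhat different measured coupling than the target.
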