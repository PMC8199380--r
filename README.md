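# fwctex

Fractional water content (FWC) radiomics for two-point Dixon MRI, with
the full downstream association pipeline used in pilot PET/MRI oncology
studies — built for imaging scientists who want the whole chain, from
water/fat images to radiogenomic tables, reproducible and testable
without access to clinical data.

## What it computes

The two-point Dixon sequence yields co-registered water-only (W) and
fat-only (F) images. The package builds the parametric map

    FWC = W / (W + F)        (= 1 − signal fat fraction)

and runs **filtration-histogram texture analysis** on it: the map is
band-pass filtered with a Laplacian-of-Gaussian kernel at spatial scale
factors SSF = 2 (fine), 3–5 (medium) and 6 mm (coarse), plus the
unfiltered map (SSF 0); six first-order statistics (mean, SD, entropy,
MPP = mean of positive pixels, skewness, kurtosis) of the ROI histogram
at each scale give 36 features per ROI. The statistical pipeline then
mirrors a pilot-study design:

1. **Inter-operator QC** — ICC(2,1) between two ROI drawers per feature;
   features with ICC ≤ 0.75 are dropped, survivors averaged.
2. **Correlation screening** — Spearman r_s of each retained feature
   against SUVmax, SUVmean, TLG and ADC mean/skewness/kurtosis, with
   Benjamini–Hochberg control at FDR 0.1.
3. **Survival** — optimal-cutpoint Kaplan–Meier dichotomisation
   (minimum log-rank p over admissible splits), then forward-stepwise
   Cox selection over the best marker per family and their pairwise
   interactions, with score statistics reported for excluded terms.
4. **Radiogenomics** — Mann–Whitney test on per-patient mutation counts
   between the prognostic groups of the best texture marker, and
   per-gene 2×2 Fisher exact tests.

A seed-reproducible synthetic cohort generator (`simulate_cohort()`)
emulates the whole study — Dixon slices with water-poor tumour pockets,
operator contours, clinical and mutation tables — including the couplings
the pipeline is designed to detect (texture–TLG rank correlation,
texture-linked hazard, prognosis-linked mutation burden). See the
methods vignette (`vignettes/fwc-radiomics-methods.Rmd`) for the model
and every tunable default.

## Worked example

```r
library(fwctex)
library(dplyr)

cohort   <- simulate_cohort(cohort_config(seed = 1))
analysis <- run_full_analysis(cohort)
analysis
#> <fwc_analysis>
#>   QC: 30/36 features retained (ICC > 0.75)
#>   Correlation: 21 BH-significant tests at q = 0.1
#>   Survival: 15/36 markers significant at alpha = 0.05
#>   Cox: 3 term(s) included
#>   Mutations (skewness_ssf4): medians 6 vs 0, p = 0.25
```

30 of the 36 texture features show good inter-operator agreement and
survive QC. Screening the survivors against the functional imaging
metrics:

```r
tidy(analysis$correlations) |>
  filter(metric == "tlg", bh_significant) |>
  arrange(r_s) |>
  head(5)
#> # A tibble: 5 × 6
#>   feature       metric    r_s         p     n bh_significant
#>   <chr>         <chr>   <dbl>     <dbl> <int> <lgl>
#> 1 skewness_ssf0 tlg    -0.709 0.0000116    30 TRUE
#> 2 entropy_ssf0  tlg    -0.504 0.00448      30 TRUE
#> 3 sd_ssf2       tlg    -0.457 0.0112       30 TRUE
#> 4 mpp_ssf5      tlg    -0.447 0.0285       24 TRUE
#> 5 sd_ssf0       tlg    -0.445 0.0137       30 TRUE
```

Heterogeneity-sensitive FWC features correlate *negatively* with total
lesion glycolysis — more heterogeneous (water-pocketed) tumours carry
lower TLG in this cohort, the direction the generator was configured to
produce (target coarse-MPP/TLG coupling −0.55). `tidy(analysis$survival)`
lists each marker's optimal threshold, group sizes and log-rank p;
`analysis$cox` holds the forward-selected Cox model with hazard ratios
and 95% CIs for included terms and score statistics for the rest;
`analysis$mutations` holds the count test and the per-gene Fisher
tables. `autoplot(analysis$icc)`, `autoplot(analysis$correlations)`,
`plot_fwc_map()` and `plot_km()` draw the standard figures.

A thin CLI wrapping the same functions ships in `inst/cli/fwctex`
(subcommands `simulate`, `fwc`, `texture`, `analyze`, `run`).

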