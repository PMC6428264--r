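# srmsig

Targeted SRM quantification and multi-protein response-signature
assessment in R.

## The problem

Translating a tissue biomarker signature from discovery proteomics into
a clinically usable assay means re-measuring a handful of proteins by
selected reaction monitoring (SRM) with stable-isotope-dilution
standards — typically in formalin-fixed, paraffin-embedded (FFPE) tumor
material — and asking whether the signature still separates treatment
responders from non-responders. `srmsig` implements that workflow as a
tested pipeline for anyone developing or auditing such an assay:

1. **Quantification.** For each peptide measurement, the light/heavy
   peak-area ratio is formed either as the median over per-transition
   ratios (fresh-frozen convention) or as the summed-area ratio over all
   product ions (FFPE convention), then converted to an absolute
   concentration: with a spike of $S$ fmol heavy standard in $L$ µg
   lysate,
   $c = r \cdot S \cdot 1000 / L \;\; \text{amol/µg}.$
   Replicates are summarized by the median; proteins are the median of
   their detected peptides.
2. **Assay qualification.** From a dilution series, each level's
   back-calculated amount ($\hat{a} = r \times$ fixed counterpart) gives
   a replicate %CV and %accuracy error. The LOD is the lowest level from
   which every level upward passes (CV and accuracy error < 20% under
   FFPE rules, < 25% under fresh-frozen rules); the LLOQ is the next
   level above the LOD (FFPE) or 3 × LOD (fresh-frozen).
3. **Below-LLOQ imputation.** A censored peptide value is drawn from
   Uniform(0, LLOQ); when more than one peptide of a protein is missing
   in the same measurement, each such cell receives a second draw from
   Normal(mean = its uniform draw, CV 25%). Deterministic group-median
   variants support classifier training and blinded application.
4. **Signature scoring.** The combined measure is a signed sum of
   protein concentrations,
   $\text{score} = \text{CLIC3} + \text{GM2A} + \text{OAT} + \text{PADI3} - \text{DPYSL2}$
   (5-protein) or $\text{GM2A} + \text{OAT} - \text{DPYSL2}$
   (3-protein), DPYSL2 entering negatively because it moves in the
   opposite direction in responders. A threshold calibrated on labelled
   samples (midpoint of the class medians by default, Youden optional)
   classifies a sample as responder iff its score exceeds it;
   sensitivity, specificity, PPV, NPV and accuracy are reported.

A seeded synthetic-data generator produces transition tables,
calibration series and labelled cohorts with the statistical structure
this analysis assumes (triplicates, log-normal noise, left-censoring,
per-protein effect sizes), so the entire pipeline is testable without
any instrument data.

## Worked example

```r
library(srmsig)

# a cohort of 10 responders / 19 non-responders under the default panel
cohort <- generate_cohort(cohort_design(seed = 1))
res <- run_signature_pipeline(cohort, lloq = 100, impute_seed = 1)
res$performance
#> # A tibble: 1 × 10
#>      tp    fp    tn    fn sensitivity specificity   ppv   npv accuracy     n
#>   <int> <int> <int> <int>       <dbl>       <dbl> <dbl> <dbl>    <dbl> <int>
#> 1    10     0    19     0         100         100   100   100      100    29
```

All 10 responders and 19 non-responders are correctly classified at the
calibrated threshold on this seed: at the default effect sizes the
combined measure separates the groups well.

```r
# qualify a peptide assay from its 14-point FFPE dilution series
series <- generate_calibration(calibration_design("ffpe", seed = 1))
qualify_assay(series, "ffpe")
#> <assay_qualification> peptide [ffpe]
#>   LOD 0.025 fmol, LLOQ 0.04253 fmol
#>   log-log curve: slope 0.998, R^2 0.9996 (14 levels)
```

With 8% replicate noise and no background floor, every level of the
25 amol – 25 fmol curve passes the 20% CV/accuracy criteria, so the LOD
is the lowest point (25 amol) and the LLOQ the level above it
(42.5 amol); the log-log slope near 1 confirms linearity.

## Scope

The package covers ratio-based quantitation onward. Peak integration,
spectral processing, discovery-stage search and SVM training are out of
scope; externally derived linear weights can be evaluated by passing a
named weight vector wherever a signature definition is accepted.
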