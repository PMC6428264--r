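---
title: "Methods: SRM quantification and signature assessment in srmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRM quantification and signature assessment in srmsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmsig)
```

## The measurement model

Stable-isotope-dilution SRM quantifies a peptide by comparing the
chromatographic peak areas of its endogenous ("light") form against a
spiked synthetic heavy-labelled standard of known amount. Because the
two forms are chemically identical, their relative response is taken as
unity: the light/heavy area ratio $r$ times the spike amount is the
endogenous amount on column, and dividing by the lysate amount analyzed
gives a concentration,

$$c \;=\; r \cdot \frac{S_\text{fmol} \times 1000}{L_{\mu g}} \quad
\text{amol}/\mu\text{g lysate}.$$

Two ratio conventions are implemented because the two tissue platforms
process transitions differently:

* `median_of_transitions` — the median over per-transition light/heavy
  ratios (fresh-frozen convention; robust when individual transitions
  are interfered);
* `all_product_ions` — the ratio of summed light areas to summed heavy
  areas over matched product ions (FFPE convention; appropriate at low
  signal, where per-ion ratios are unstable and a zero ion still
  carries information in the sums).

The two rules agree exactly whenever all transitions share one true
ratio; light and heavy ions are matched by the rank of their product
m/z within each label, since the isotope shift preserves ion order.

Technical replicates are summarized by the **median**, and proteins by
the **median of their detected peptides**. Aggregation by median (rather
than mean) is this package's choice — the convention at the replicate
level is rarely stated in assay reports — because it tolerates a single
aberrant injection (`summarize_replicates(c(10, 12, 200))` returns 12,
where a mean would return 74) and matches the median-based style of the
rest of the pipeline. The same reasoning covers the open question of how
a two-peptide protein (CLIC3 here) is combined: median and mean coincide
at two values.

## Assay qualification

A dilution series titrates one label over a wide range against a fixed
amount of the counterpart. Back-calculation multiplies each measured
ratio by the fixed amount — the fitted curve is *diagnostic only*,
because unit relative response makes interpolation unnecessary. Each
level then has a replicate %CV and a %accuracy error
($100\,|\bar{\hat a} - a|/a$), and:

* **FFPE rules** — a level passes when CV and accuracy error are both
  below 20% (recovery within 80–120%); the LLOQ is the nominal amount
  of the level immediately above the LOD.
* **Fresh-frozen rules** — the threshold is 25%, and LLOQ = 3 × LOD.

The LOD is the *lowest level from which every higher level also passes*
(contiguity). Whether isolated failing levels above a passing one were
tolerated in practice is ambiguous; requiring contiguity means a
spuriously clean low level amid failing neighbours cannot become the
LOD, reading "lowest quantifiable concentration" as the start of the
quantifiable range. A level with a single replicate has no CV and fails
by policy. If no level starts a passing run — or, under FFPE rules, the
LOD sits at the top level so no level remains for the LLOQ — the assay
is flagged not quantifiable rather than given a fabricated limit.

LOD/LLOQ are stored in fmol spiked and converted to amol/µg through the
sample's lysate amount at application time (`lloq_amol_per_ug()`), so
one qualification serves samples analyzed at different loads.

## Below-LLOQ imputation

Non-detection in this assay is informative: values are missing because
the analyte sits below the LLOQ, not at random. The stochastic
imputation therefore draws each censored peptide value uniformly on
(0, LLOQ). When more than one peptide of the same protein is missing in
one (sample, replicate) measurement, every such cell receives a second
draw from a normal centred on its uniform draw with a CV of 0.25,
adding the extra spread expected of concentrations this low. Two
choices deserve note:

* The conditional second draw is applied to **every** missing peptide
  of the affected protein-measurement, not only to the ones beyond the
  first — the symmetric reading of an ambiguous rule; peptides are
  exchangeable and there is no principled first peptide.
* Non-positive second draws are **resampled** rather than truncated:
  concentrations must be positive, and at CV 0.25 the probability of a
  non-positive normal draw is $\Phi(-4) \approx 3\times10^{-5}$, so
  resampling leaves the distribution essentially untouched.
* Imputation operates **per replicate measurement** at peptide level
  and flows through the standard roll-up; "per measurement" is read as
  per injection, the finest grain at which a value can be missing.

The deterministic variants — group-median for training data, the
average of the two training group medians for blinded application —
operate on the protein matrix and are idempotent on complete matrices.

## Signature scoring and classification

The combined measure is a weighted sum of protein concentrations on the
raw amol/µg scale with unit weights, DPYSL2 negative (it falls in
responders while the other four rise):
CLIC3 + GM2A + OAT + PADI3 − DPYSL2, or GM2A + OAT − DPYSL2 for the
three consistently quantified proteins. Scores are deliberately *not*
log-transformed by default: the measure is defined as a sum of
concentrations, and transforming would change what is being validated.

No construction for the classification threshold accompanies the
signature, so the package makes one: the **midpoint of the two class
medians**, chosen for robustness at cohort sizes of 10–30 where an
ROC-optimal cut overfits badly. Youden's J maximization over the
training scores is available as an alternative (`method = "youden"`;
ties resolve to the lowest threshold, and perfectly separated classes
yield the midpoint of the gap). Scores exactly at the threshold are
called non-responders — the conservative clinical default, avoiding
overcalled response. Cross-validation stratifies folds by class,
calibrates the threshold (and any group-median imputation) on the
training part only, and applies blinded imputation to held-out samples.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the *statistical* structure the analysis
assumes: per-sample true protein concentrations drawn log-normally
around group medians; responder medians scaled by per-protein fold
ratios (defaults 1.07–1.92, DPYSL2 inverted — the reported effect-size
range of the five-protein signature); triplicate injections with
multiplicative technical noise; left-censoring of per-replicate peptide
concentrations below the LLOQ, emitted as absent light transitions;
and ratio-consistent transition areas given the spike (5 fmol) and
lysate (1 µg) amounts.

Defaults are fixed once as the study conditions: 10 responders vs 19
non-responders; replicate CV 10% (matching a reported median
inter-peptide %CV near 9); biological CV 25% (not derivable from
published group medians — a typical between-tumor spread for abundance
data; log-normal guarantees positivity); LLOQ 100 amol/µg (the quoted
sensitivity scale of the FFPE assay); base concentrations placing
DPYSL2, OAT and GM2A well above the LLOQ and CLIC3/PADI3 below it, so
the latter two are censored in roughly 60–90% of measurements, as seen
in clinical FFPE cohorts.

The generator does **not** simulate chromatography, spectral
interference, matrix effects, batch drift, or fixation chemistry, and
peptides of a protein are equimolar by construction (real digests show
peptide-specific recovery). Passing tests therefore demonstrate that the
pipeline's inference is correct *under its own assumptions*, not that
the assay performs identically on real tissue.

`generate_calibration()` similarly produces replicate ratios with
multiplicative noise plus an additive amount-scale floor
(`noise_floor · |N(0,1)|`) that breaks the lowest levels' CV and
accuracy, emulating signal decay near chemical background. The presets
mirror the two qualification formats: 25 amol–25 fmol in 14 points
against 5 fmol fixed heavy (FFPE, forward curve), 1.5 amol–100 fmol in
12 points against 50 fmol fixed light (fresh-frozen, reversed curve),
with 3 replicates per level (a replicate count unstated in assay
descriptions; 2 is the minimum for a CV, 3 matches the triplicate
convention elsewhere).

## Numerical and degenerate-input conventions

* Zero is a measured area; missing is an empty cell. A computable ratio
  of 0 is a value, not a non-detection.
* A zero heavy signal makes the ratio missing (with a warning), never
  infinite.
* Correlations of constant peptide profiles are reported `NA`, not 0.
* Performance rates with empty denominators (e.g., PPV with no positive
  calls) are `NA`.
* All generator and imputation output is a pure function of
  (inputs, seed); the session RNG stream is left undisturbed.

## Problem sizes in the test suite

The suite validates distributional claims by Monte Carlo at sizes
chosen to make the checks sharp but quick: 10⁴ draws for the imputation
oracles (standard error of the uniform mean ≈ 0.29 amol/µg), 200
randomized series for the LOD/LLOQ scan equivalence, 100 seeded cohorts
at the 10/19 design for end-to-end recovery, and 50 seeds for
expectation-level monotonicity checks. The null (effect size 1)
cross-validation check uses a balanced 20 + 20 cohort, where the
chance-level accuracy of an unbiased threshold rule coincides with the
majority-class rate; in an unbalanced cohort a midpoint-threshold
classifier sits near 50% regardless of the class split, below the
majority rate by construction rather than through any defect.

## Known limitations

* The tidy long transition schema is this package's contract; vendor
  exports (e.g., wide Skyline reports) need a reshaping shim.
* The threshold rule is a reconstruction; published classification
  metrics depend on an unstated threshold and need not be reproduced
  exactly by any particular rule.
* SVM feature selection and re-training are out of scope; the combined
  measure is the supported classifier, with a hook for externally
  supplied linear weights.
* LOD/LLOQ qualification assumes unit relative response of the isotope
  pair; weighted regression schemes (1/x, 1/x²) are not implemented.
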