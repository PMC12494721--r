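---
title: "Methods: drift correction, plate-matched hit calling and growth concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift correction, plate-matched hit calling and growth concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminescreen)
```

## Scope and data model

`aminescreen` analyses plate-based screens in which gut bacteria are grown
anaerobically in 96-well plates in the presence of a xenobiotic library
(one compound per well, typically at 20 µM; 50 µM for sweeteners), with
10–13 DMSO solvent controls and one tetracycline control per plate and two
biological replicates prepared on separate days. Two readouts are
processed: stationary-phase 595 nm absorbance (growth) and targeted
LC-MS/MS amine concentrations acquired in multi-plate batches whose
acquisition order matters (signal drift). The pipeline starts at
concentrations: vendor calibration from external standards is upstream and
out of scope. Tables are long/tidy — one row per measured well (× amine
metabolite) — because acquisition order is a first-class variable.

## Growth processing

Raw absorbance is blank-subtracted and corrected for the compound's own
background absorbance (some xenobiotics are coloured), multiplied by the
instrument calibration factor 5, and clipped at 0 (strong inhibition plus
noise can push readings slightly below blank). Fold changes divide by the
median OD of the plate's DMSO controls. Fold changes strictly above 1.5
are set to missing: increases that large come from cell aggregation
confounding the OD reading (a known behaviour of *R. gnavus*), not from
real growth stimulation. The blank is taken per plate, with a run-level
value as fallback; the compound-background column defaults to 0 with a
logged notice when absent.

## Signal-drift correction

Per batch × species × metabolite:

1. **Outlier fences.** Sample wells (experimental + controls; never
   standards, blanks or QC injections) outside
   $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ (linear-interpolation
   quartiles) are excluded from the fit, so genuinely perturbed wells do
   not drag the trend. Fewer than 4 finite values → no masking, warning.
2. **Radius-neighbour trend.** The trend at acquisition index $t$ is the
   unweighted mean of included values with $|t' - t| \le r$ ($r = 20$;
   30 for dose–response batches, where fewer distinct samples populate the
   axis). Uniform weights are the radius-neighbour regressor's
   conventional default. Positions with an empty
   neighbourhood inherit the trend at the nearest included position, ties
   resolving to the earlier acquisition position — a deterministic choice
   the method description leaves open.
3. **Ratio correction.** $\tilde y = (y / \hat f(t)) \cdot m$, where $m$
   is the screen-wide median of that metabolite's raw concentrations over
   experimental samples (read of "median compound concentration across the
   entire screen" as compound-treated wells; configurable to include
   controls), then clipped at 0.01 µM to remove zeros and negatives.

The trend is fit per metabolite, not jointly: baseline concentrations
differ by orders of magnitude between amines (35–1100 µM), so a joint fit
would be dominated by the most abundant one.

## Hit calling

Per replicate, $z = (\tilde y - \text{ref}) / s_{\text{DMSO}}$ with
ref = plate-wide median of corrected concentrations (default) and
$s_{\text{DMSO}}$ the sample (n−1) SD of the plate's DMSO controls; an
alternative `dmso_median` reference mode is provided because results are
also described relative to plate-matched DMSO controls — on a mostly
inactive plate the two references nearly coincide. Plates with fewer than
3 finite DMSO values or zero spread are flagged and yield missing
z-scores. P-values use the standard-normal survival function, two-sided by
default (`2·SF(|z|)`), and are Benjamini–Hochberg adjusted within each
species × metabolite, separately per replicate. The hit rule is the
conjunction: $p_{\mathrm{adj}} < 0.05$ in both replicates, consistent
direction, $|\text{mean log2 FC}| > 0.32$ (fold change outside roughly
0.8–1.25).

**Concordance.** A hit is growth-concordant when
$|\text{mean growth FC} - \text{mean metabolite FC}| < 0.25$, strictly, on
the linear fold-change scale (the classification is described in terms of
raw fold changes; a log2 variant would change the boundary cases). When
growth is artifact-filtered in both replicates the label is missing, never
imputed.

## Downstream summaries

- **Enrichment**: two-sided Fisher's exact test per therapeutic class,
  BH-adjusted across classes within each stratum (species × metabolite ×
  direction × concordance, or pooled); "positively enriched" = class hit
  frequency above background. Direction filtering is presentation, not
  testing, so it happens downstream of this function.
- **Hit rates**: active compounds (≥1 hit anywhere) / class size.
- **Cross-species correlation**: Pearson r with two-sided p over
  pairwise-complete per-compound mean responses.
- **Dose–response**: a dose counts as "stimulated" with dual-replicate
  $p_{\mathrm{adj}} < 0.05$ and mean FC > 1 (the fold-change threshold is
  optional here — the read-out names only the significance criterion);
  fractions are over compounds tested at every level, and a per-compound
  `monotone` flag is TRUE when |mean log2 FC| is non-decreasing in dose.
- **QC**: per plate × metabolite CV of corrected DMSO concentrations
  (sample SD / mean) and per species × metabolite Pearson correlation of
  the two replicates' per-compound corrected concentrations.

## The synthetic screen

The generator emits the stated world the pipeline was designed for, as a
deterministic function of one seed: 1772 compounds (1518 drugs, 166
pesticides, 47 industrial chemicals, 41 sweeteners), four species with
their measured amines, two replicates, 10–13 DMSO controls and one
tetracycline control per plate, acquisition batches with blocks of 12
sample injections interleaved with blank and QC injections and a 6-level
standard dilution series, baseline concentrations drawn log-uniformly from
35–1100 µM, multiplicative lognormal noise at CV 9.4%, smooth
low-frequency multiplicative drift with amplitude 0.2 (a centred,
rescaled sum of three random cosine harmonics — the real drift shape is
not documented, only that a ratio-based local-trend correction removes
it), lognormal plate effects (σ = 0.1, a simulation choice), growth OD
artifacts at rate 7.7% drawn per compound × species (artifacts were
observed to be largely replicate-consistent) and inflating the OD to
fold changes of 1.7–3 without touching metabolite values.

Spike-ins: 5% of compound × species pairs perturb one randomly chosen
metabolite by |log2 FC| = 1 (sign 50:50), and with probability 0.66 the
effect is growth-coupled. Coupled growth fold changes are capped at 1.4:
a "concordant" two-fold growth gain would exceed the 1.5 artifact
threshold and be deleted by the pipeline's own filter, so growth gains
beyond ~1.4 are outside the observable world by construction. Ground-truth
concordance labels are computed from the capped growth fold change, so
truth and observable data stay consistent; a consequence is that up-going
coupled effects are truly non-concordant (|1.4 − 2| ≥ 0.25), and the
realised concordant fraction among hits is ≈ 1/3 rather than the coupling
probability.

What a green synthetic test does **not** establish: real LC-MS drift need
not be smooth or low-frequency (injector failures are step changes), real
effect sizes are not a single two-fold spike, real noise is not exactly
lognormal, and compound annotations correlate with activity in real
libraries (here they are independent, which is what makes the permutation
calibration test meaningful).

## Numerical choices and degenerate inputs

- Quartiles: linear interpolation (R type 7), matching the conventional
  boxplot definition used for the fences.
- BH is implemented directly from the step-up definition (with `n` = the
  number of non-missing p-values) and cross-checked in tests against both
  a brute-force oracle and `stats::p.adjust`.
- The windowed trend uses a sorted cumulative-sum sweep
  (O(n log n)); on constant data it agrees with the constant to ~1 ulp,
  which is why "zero DMSO spread" flags compare against exact 0 only for
  genuinely identical inputs.
- DMSO SD is the sample (n−1) SD; plates flagged when it is 0 or fewer
  than 3 DMSO values are finite.
- OD clipped at 0; corrected concentrations clipped at 0.01 µM; artifact
  comparison is strictly `> 1.5`; concordance strictly `< 0.25`.
- Missing values propagate: artifact-filtered growth serialises as an
  empty CSV field, never a sentinel.

## Calibration caveat

With 10–13 DMSO controls per plate, the z-statistic divides by an SD
estimated with ~9–12 degrees of freedom, so its null distribution has
t-like tails rather than N(0, 1): the per-test rejection rate at nominal
unadjusted p < 0.05 is ≈ 0.075–0.078 on null screens (analytically,
$P(|t_{10}| > 1.96) = 0.078$). This is a property of the plate-matched
z-score method itself, not of the implementation. The operative screening
criterion — BH adjustment, dual-replicate agreement in significance and
direction, and the fold-change threshold — is far stricter, and the null
dual-replicate hit rate is ≈ 0 (< 0.005 asserted). Anyone re-using the
per-replicate unadjusted p-values alone should expect this mild
anticonservativeness.

## Known limitations

- No cross-batch modelling (each batch is corrected independently; QC
  samples are deliberately excluded from the fit rather than anchoring
  it).
- The z-test assumes the plate reference is effect-free; a plate dense in
  true effects shifts the plate median and attenuates z (the
  `dmso_median` mode avoids this at the cost of a noisier reference).
- Dose–response compound selection ("varied growth response") is
  qualitative in origin; the package takes an explicit compound list.
- Reproducing the deposited screen's printed totals requires the deposited
  raw tables, which are not bundled; all quantitative claims here are
  computed from the synthetic world by the test suite and acceptance
  script.
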