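# aminescreen

Analysis pipeline for high-throughput screens of xenobiotic effects on
amine production by gut bacteria.

## The problem

Gut bacteria such as *Escherichia coli*, *Klebsiella aerogenes*,
*Clostridium sporogenes* and *Ruminococcus gnavus* decarboxylate amino
acids into biogenic amines (cadaverine, putrescine, histamine, tryptamine,
2-phenylethylamine) that act on the host. Screens that expose these
bacteria to a large xenobiotic library — drugs, pesticides, industrial
chemicals, sweeteners — on 96-well plates, then read out growth (595 nm
absorbance) and amine concentrations (targeted LC-MS/MS), need a
statistical pipeline that copes with LC-MS signal drift, plate effects and
optical-density artifacts before any hit can be believed. `aminescreen`
implements that pipeline for screens laid out with 10–13 DMSO
(solvent-only) controls and one tetracycline control per plate and two
biological replicates per compound, plus a synthetic screen generator with
known ground truth so the whole chain is testable without instrument data.

## The method

For each acquisition batch, species and metabolite, raw concentrations
\(y_i\) ordered by acquisition index \(t_i\) are corrected for signal
drift:

1. Outliers are masked with standard boxplot fences
   \([Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]\).
2. A trend \(\hat f(t)\) is fit as a radius-neighbour local regression
   (uniform weights, radius 20 index units; 30 for dose–response batches),
   excluding standards, blanks and QC injections.
3. Corrected concentration: \(\tilde y_i = (y_i / \hat f(t_i)) \cdot
   \mathrm{median}(y)\) over the whole screen, clipped at 0.01 µM.

Hits are called per compound × species × metabolite from plate-matched
z-scores

\[ z = \frac{\tilde y - \mathrm{median}_{\text{plate}}(\tilde y)}
            {\mathrm{sd}_{\text{DMSO}}(\tilde y)} , \qquad
   p = 2\,\Phi(-|z|) , \]

with Benjamini–Hochberg adjustment within each species × metabolite per
replicate. A triple is a **hit** when \(p_{\mathrm{adj}} < 0.05\) in both
biological replicates, both replicates agree in direction, and
\(|\overline{\log_2 \mathrm{FC}}| > 0.32\). Growth fold changes (OD
relative to the plate DMSO median, after blank/background subtraction, ×5
calibration and clipping at 0; values > 1.5 removed as aggregation
artifacts) classify each hit as **growth-concordant** when
\(|\overline{\mathrm{FC}}_{\text{growth}} -
\overline{\mathrm{FC}}_{\text{metabolite}}| < 0.25\). Downstream summaries
cover Fisher-exact therapeutic-class enrichment, per-class hit rates,
cross-species Pearson response correlations, dose–response stimulation
fractions with monotonicity flags, and QC metrics (DMSO CV, replicate
correlation).

## Worked example

```r
library(aminescreen)

scenario <- simulation_scenario(rng_seed = 1)   # 1772 compounds, 4 species
sim <- generate_screen(scenario)
res <- run_screen_pipeline(sim$measurements, sim$growth, screen_config())

sum(res$hits$is_hit)        # 369  hit triples
res$qc$median_cv            # 0.0923  median DMSO coefficient of variation

truth <- sim$truth$effects
m <- dplyr::inner_join(res$hits, truth,
                       by = c("compound_id", "species", "metabolite"))
sum(m$is_hit & m$true_hit) / sum(m$true_hit)   # 0.984  sensitivity
```

The simulated screen spikes 5% of compound × species pairs with a
two-fold effect (|log2 FC| = 1) under 9.4% lognormal measurement noise,
±20% signal drift and 7.7% OD artifacts; the pipeline recovers 98% of the
spiked effects with a realised false-discovery proportion of 0.003, and the
corrected DMSO controls sit at the noise floor (CV ≈ 0.09).

## Acceptance script

`scripts/acceptance.R` re-simulates the full-scale screen from a seed, runs
the complete pipeline (normalisation, hit calling, concordance, enrichment,
QC), prints the recovery summary and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
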