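# mmpscreen

Analytics for plate-based JC-10 mitochondrial membrane potential (MMP)
screens and their downstream validation assays.

Phenotypic screens for mitochondrial modulators — for example in
astrocytes derived from Rett-syndrome patient iPSCs — read out the MMP as
the ratio of JC-10 red (590 nm, aggregate) to green (520 nm, monomer)
emission, F590/F520, in 96-well plates: a higher ratio means a more
polarized, healthier membrane, and the screen looks for treatments that
move mutant cells back toward the wild type. `mmpscreen` provides the
full analysis chain for such screens, plus the quantifications used to
validate primary hits, for bench scientists and analysts who have plate
tables, images, ROI traces, or reconstructions and need calibrated,
reproducible numbers:

* **Screen model** — plate CSV ingestion with layout validation,
  intra-plate normalization against the wild-type control mean (so
  normalized WT wells average exactly 1 per plate), and duplicate-well
  aggregation with CV reporting.
* **Quality control** — per-plate Z'-factor,
  `1 − 3(σ_pos + σ_neg)/|μ_pos − μ_neg|`, computed WT vs. untreated
  mutant wells, and screen-level duplicate-CV summaries with the CV < 15%
  acceptability flag.
* **Hit calling** — a from-scratch EM fit of a two-component Gaussian
  mixture (with BIC model selection, deterministic multi-quantile
  initialization, and a fixed-mass uniform outlier component for
  robustness to the hits themselves), a bimodal/unimodal classifier, and
  the distribution-appropriate `μ + 2σ` hit rule: dominant-component
  statistics for bimodal screens, pooled statistics for unimodal ones.
* **Ratiometric imaging** — Otsu/fixed-threshold cell segmentation,
  per-cell F590/F520 as the ratio of channel means, per-image summaries.
* **Mitochondrial morphometry** — aspect ratio and form factor
  (`P²/4πA`, circle = 1) from binary masks via image moments and
  corner-corrected boundary tracing.
* **Calcium transients** — robust baseline/noise estimation, event
  detection with valley splitting, per-cell and group statistics
  (% oscillating, amplitude and frequency mean ± SEM).
* **Neurite morphology** — SWC ingestion, total dendritic length,
  terminal points, Sholl profiles.
* **Synthetic data** — seeded generators for every input above,
  calibrated to published summary statistics and carrying complete
  ground truth for recovery testing.

## Worked example

Generate a synthetic 1,134-compound drug screen with 20 planted rescuing
compounds, then run the full pipeline:

```r
library(mmpscreen)

screen <- gen_drug_screen(seed = 42)
screen$dataset
#> <screen_dataset: drug screen, 26 plates, 2476 wells, 1134 treatments>

pipe <- run_screen_pipeline(screen$dataset, seed = 42)
pipe$qc
#> <screen_qc_report: 26 plates, Z' in [0.133, 0.479]>
#>   duplicate CV: mean 7.75%, median 7.49%, 84.2% < 10%, all < 15%: TRUE
pipe$assessment
#> <modality: bimodal (dBIC=416.8, min weight=0.092, separation=5.59)>
pipe$assessment$fit2
#> <mixture_fit k=2, loglik=776.250, BIC=-1517.33, converged in 43 iter>
#>   comp 1: weight 0.0924, mean 0.2222, sd 0.0909
#>   comp 2: weight 0.9076, mean 0.7310, sd 0.0817
pipe$result
#> <hit_call_result: rule gmm_component, threshold 0.9065, 20 hits>
```

Reading the output: every plate's Z'-factor sits in a usable window and
every duplicate pair reproduces within 15% CV, so the assay passes QC.
The normalized values form two clearly separated populations — a small
low-response cluster near 0.22 and a dominant non-responder component at
mean 0.731, SD 0.082, weight 0.91 — so hits are called against the
dominant component: threshold 0.731 + 2 × 0.088 ≈ 0.907 (the SD used by
the rule is re-estimated with a censoring correction; see the methods
vignette), recovering exactly the 20 planted rescuers
(`pipe$result$hits`).

The validation-assay modules work the same way. A mutant-like population
of 363 five-minute Fluo-4 traces (28% oscillating, 1.44 transients/min,
peak F/F0 2.95):

```r
mt <- gen_calcium_traces(363, p_oscillating = 0.28, rate_per_min = 1.44,
                         amplitude_mean = 2.95, seed = 42)
analyze_traces(mt$traces, "MT")$group
#> <group_summary MT: 363 cells, 27.8% oscillating,
#>   amplitude 2.94 +/- 0.02, frequency 1.39 +/- 0.05 /min>
```

## Package layout

```
R/                      screen model, QC, hit calling, image quantification,
                        calcium events, neurite morphology, generators
tests/testthat/         unit, property and end-to-end recovery tests
scripts/acceptance.R    headline-number reproduction script
vignettes/              methods vignette (model, parameters, design choices)
```
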