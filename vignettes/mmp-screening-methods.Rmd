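---
title: "Methods: plate-based MMP screening analytics and synthetic validation"
author: "mmpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based MMP screening analytics and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpscreen)
```

# Scope

`mmpscreen` implements the analytics of a JC-10 ratiometric mitochondrial
membrane potential (MMP) screening platform: 96-well plate normalization
and duplicate aggregation, Z'-factor and CV quality control,
distribution-aware hit calling built on a from-scratch EM fit of a
two-component Gaussian mixture, and the downstream validation
quantifications (per-cell F590/F520 ratiometry, mitochondrial aspect
ratio and form factor, spontaneous calcium transient statistics, neurite
morphology). Because the platform's raw screen data are not public, every
analysis path is exercised end-to-end on seeded synthetic data whose
statistical structure matches the published summary statistics, with full
ground truth for recovery testing.

# The screening model

## Normalization and replicate structure

Each well carries two fluorescence intensities; the readout is the ratio
F590/F520 (JC-10 aggregate over monomer emission), which rises with
membrane polarization. Wells are normalized by the arithmetic mean ratio
of the untreated wild-type (WT) control wells *on the same physical
plate*, making the per-plate mean of normalized WT wells exactly 1 and
removing plate-to-plate intensity scale. Same-plate (rather than
batch-level) referencing was chosen because the screen's plates carry
their own WT controls precisely to absorb plate effects; the
normalization is provably invariant to any common rescaling of a plate's
intensities.

Treatments run on duplicate plates. Replicates are averaged and their
coefficient of variation, $CV = 100\,s/\bar x$ with the sample SD
($n-1$), is the reproducibility statistic; treatments observed on a
single plate are kept but flagged, never dropped.

## Quality control

Per plate, the assay window is summarized by the Z'-factor
$$Z' = 1 - \frac{3(\sigma_{WT} + \sigma_{MT})}{|\mu_{WT} - \mu_{MT}|},$$
computed on normalized ratios from the WT (positive) and untreated mutant
(MT, negative) control wells. FCCP-treated wells, which collapse the MMP
entirely, are carried as an assay-range control but deliberately excluded
from the Z' window: the screen looks for compounds moving MT toward WT,
and a zero-MMP control would inflate the apparent window. Z' is reported,
not enforced — no plate is discarded on a low value.

## Distribution-aware hit calling

The hit rule is "at least 2 SD above a reference mean" (inclusive), with
the reference chosen by the shape of the screen's value distribution:

* **unimodal** screens use the pooled sample mean and SD;
* **bimodal** screens use the dominant high-response mixture component,
  because pooled statistics under population mixing inflate the variance
  and hide real effects.

Modality is decided by fitting $k = 1$ and $k = 2$ Gaussian mixtures and
requiring, for a bimodal call, all three of: BIC improvement above 10
(a decisive model-selection margin on the usual evidence scale),
smaller component weight at least 0.05 (a non-negligible minor
population), and mode separation $|\mu_2 - \mu_1| / \max(\sigma_1,
\sigma_2) \ge 2$.

### The EM fitter

`fit_gmm()` is a standard univariate EM with log-space E-steps, a
monotonicity assertion on the log-likelihood at every iteration, an SD
floor of $10^{-4}$ against variance collapse (with seeded
random-responsibility restarts), tolerance $10^{-8}$ on the relative
log-likelihood change, and at most 500 iterations. $k = 1$ returns the
closed-form MLE. Initialization is deterministic: moment splits of the
sample at the 0.5, 0.1, 0.25, 0.75 and 0.9 quantiles, keeping the
highest-likelihood converged fit. The multi-quantile start matters: a
median split alone reliably traps EM in a bulk-splitting local optimum
when one component carries ~90% of the mass, as it does here.

### Robustness to the hits themselves

A subtlety drives two further design choices. Candidate rescuers sit far
to the right of the background distribution; a plain two-component MLE
prefers to "spend" one component as a broad catch-all covering both the
low-response cluster and those right outliers, which destroys the
modality diagnostics. The screening fits therefore add a **uniform
outlier component** with a small *fixed* mass (0.02, in the tradition of
the noise component of model-based clustering): extreme values are
absorbed at a flat density instead of distorting the background
Gaussians. The mass is fixed, not estimated, because a freely estimated
mass also bites into the bulk tails and shrinks the fitted SDs. With the
fixed mass, points beyond roughly 3.3 SD of the dominant component are
discounted while the bulk is untouched.

Second, when hits are called with the dominant-component rule, the
component's mean and SD are re-estimated from its member values
(maximum-responsibility assignment) by **right-truncated Gaussian
maximum likelihood** inside a self-consistent loop: fit using only
members below the current threshold, with an explicit truncation
correction at the cut, and update the threshold until it is stable. The
rationale: the upper flank of the background component is exactly where
rescuing treatments separate from it, so the observed component support
may be right-censored; ignoring that censoring biases the fitted SD — and
hence the $\mu + 2\sigma$ cutoff — downward by several percent, enough to
misclassify borderline wells. On uncensored data the correction vanishes
and the estimate coincides with the component MLE. The loop is seeded
from the fitted component parameters (never outlier-inflated), so it
cannot latch onto a spurious high fixed point.

No multiple-testing correction is applied at the primary screening stage;
false positives are expected to be eliminated by downstream biological
validation, which is the platform's stated practice.

# Validation assays

## Ratiometric imaging

Cells are segmented by thresholding the summed two-channel intensity
(Otsu by default; a fixed threshold is available) and labeling
8-connected components of at least 50 px. The per-cell readout is the
*ratio of channel means* over the cell's pixels — robust to near-zero
green pixels, unlike a mean of per-pixel ratios — and the per-image
summary is the unweighted mean over cells, matching per-field averaging
of confirmatory confocal data.

## Mitochondrial morphometry

Objects are 8-connected components of at least 4 px in a binary mask.
Axis lengths are $4\sqrt{\lambda}$ for the eigenvalues $\lambda$ of the
second central moment matrix of the pixel set, with the 1/12 pixel
variance term so one-pixel-wide objects keep a positive minor axis;
aspect ratio AR = major/minor. The perimeter is the boundary polygon
length from Moore-neighbor tracing through pixel centers (diagonal steps
$\sqrt 2$) with the Vossepoel–Smeulders corner deduction of 0.091 per
direction change, which removes the ~5% chain-length overestimate on
smooth outlines while leaving straight-edged shapes nearly exact; a
rasterized disc of radius 20 px measures FF = 1.00. Form factor is
defined as $FF = P^2 / (4\pi A)$ — 1 for a circle, larger for elongated
or complex outlines — so mitochondrial fragmentation *reduces* both AR
and FF. (Some literature uses the reciprocal convention; the direction
here is chosen so "reduced FF" corresponds to fragmentation.) FF of
few-pixel objects is underestimated by the center-polygon convention;
metrics are meaningful for objects comfortably above the 4 px floor.

## Calcium transients

Traces are fluorescence time series sampled at 1 frame per 2 s. The
baseline F0 is the 10th percentile of the trace; the analysis readout is
peak F/F0 per event. Detection estimates the noise scale from the median
absolute frame-to-frame difference (transients evolve over several
frames, so first differences are noise-dominated), then sigma-clips to
the baseline frames and re-estimates center and scale; an event is at
least 2 consecutive frames above center $+ 3\sigma$, runs closer than
4 s are merged, and a merged run containing several transients in quick
succession is split at significant valleys (a fall and rise of more than
$3\sigma$ with peaks at least 4 s apart) — without the splitting step,
transients arriving faster than the decay time are systematically fused
and the recovered event rate is biased low by tens of percent. A cell is
"oscillating" when it shows at least 2 events. All of these are explicit
arguments with the defaults above. Group statistics report the
percentage of oscillating cells over all cells, and amplitude/frequency
mean ± SEM over oscillating cells only.

## Neurite morphology

Reconstructions are standard 7-column SWC trees. Total dendritic length
sums straight parent–child segments (no radius weighting); terminal
points are childless non-root nodes; the Sholl profile counts, per
radius, the segments whose endpoint distances from the soma straddle the
sphere (counted once per segment, the endpoint-straddle convention). All
metrics are invariant under rigid motion of the coordinates.

# The synthetic data generators

Every input the pipeline consumes can be generated with a seed and full
ground truth; generators are pure functions of configuration plus seed
(bit-reproducible).

**Screens.** The drug screen emulates 1,134 compounds on 13 duplicated
96-well plates (88 treatments per plate; 3 WT, 3 MT and 2 FCCP control
wells in the last column), with background normalized ratios drawn from
a two-component Gaussian mixture: dominant component
$\mathcal N(0.734, 0.085^2)$ with weight 0.91, and a low-response
component *moment-matched* at run time so the pooled mixture reproduces
mean 0.687 and SD 0.173 (the closed-form match gives
$\mu_{low} = 0.2118$, $\sigma_{low} = 0.1064$; verified against a
Monte-Carlo oracle in the test suite). The siRNA screen emulates 336
genes on duplicated plates of 80 treatments with 4 WT and 4 MT controls,
background $\mathcal N(0.710, 0.084^2)$ plus a configurable right tail
(default: 5% of draws shifted up by 0.10 — the tail's true shape is not
characterized quantitatively anywhere, so this is a stated assumption).
Background draws are rejection-sampled below a cap (0.90 drug / 0.87
siRNA) so that planted-rescuer counts are exact: 20 drug rescuers
uniform in [0.95, 1.20] and 9 siRNA rescuers in [0.95, 1.10]. The cap is
a deliberate departure from pure mixture sampling used for planted-truth
recovery runs; calibration checks disable it.

Control wells are constructed rather than merely sampled: each plate
draws a target Z' uniformly inside the published per-screen band
(0.09–0.51 drug, 0.302–0.370 siRNA, with a small interior margin) and
builds control wells from standardized Gaussian patterns with exact zero
mean and unit sample SD, scaled so the plate's realized Z' equals the
target and the normalized WT mean is exactly 1. Duplicate wells are
$v(1 \pm \delta)$ with $\delta$ set by a per-treatment CV drawn from a
lognormal (median 7.6%, log-SD 0.3) truncated at 14.5% — so every
duplicate CV is below the 15% acceptability cutoff by construction.
(The published CV summary — mean 8.5, median 7.6, 83.2% below 10, all
below 15 — is jointly unattainable for any smooth two-parameter family;
this lognormal matches the median, the sub-10 fraction and the hard cap,
at a mean of ~7.9.) These constructions mean plate-level QC statistics
land in the published bands by design; what remains genuinely random is
everything the analysis must recover: treatment values, mixture
structure, planted hits, and noise.

**Images, masks, traces, trees.** Ratio images are non-overlapping discs
with green intensity 200 a.u., red = ratio × green, and 2% Gaussian
channel noise on a near-zero background. Mitochondrial masks are
non-touching rasterized ellipses with known semi-axes. Calcium traces
plant a Bernoulli oscillation flag per cell and, for oscillating cells,
a Poisson number of double-exponential transients (rise 1 s, decay 6 s)
at uniform times thinned to a 12 s minimum spacing — transients closer
than a few decay constants are not resolvable at 2 s sampling, and
unconstrained times would fuse ~9% of events, biasing the recovered rate
below its target by more than the recovery tolerance. Peak F/F0 values
are Normal truncated at 1.2 (safely above the detection floor so
amplitude recovery is unbiased); baseline noise is 1.5% of baseline.
Neuron trees grow a single trunk from the soma and then branch into two
children with probability 0.6 per level, with segment lengths Normal(40,
8) µm truncated at 1 µm; the truth records exact totals.

# What the synthetic validation does and does not show

Passing recovery tests demonstrates that the analysis correctly inverts
the generative model it was tested against at the published sample sizes:
mixture parameters within ±0.015 on a 1,134-value screen, planted hit
counts, pooled moments, Table-style calcium group statistics within a
few percent, and exact neurite metrics. Real screens differ in ways the
generators deliberately do not model: spatial plate effects (edge wells,
gradients), compound toxicity and fluorescence interference, segmentation
errors on touching cells or out-of-focus fields, photobleaching and
drift in calcium recordings, and reconstruction errors in tracing. The
package reports QC that would surface several of these (Z', CV,
per-plate control statistics) but does not correct for them — by design,
since the platform it models applies no such corrections either.

# Problem sizes and runtime

The default validation exercises the full published sizes — 1,134
compounds on 26 plates, 336 genes on 10 plates, 363 five-minute traces
at 151 frames, 96-well layouts — because all of them run in seconds in
plain R; the complete test suite finishes in well under a minute, and
the acceptance script in a few seconds. Property-style suites use 50
seeded replicates at n = 500 for mixture recovery and 100 seeded traces
for detection recall, sizes at which the Monte-Carlo error of the
checked quantities is comfortably below the asserted tolerances.

# Known limitations

* The mixture machinery is univariate and limited to $k \le 2$ plus the
  outlier component — exactly the screening use case, not a general
  mixture toolbox.
* The hit threshold depends on fitted quantities; its sampling
  variability (a few thousandths of a normalized ratio at n ≈ 1,100) is
  visible when the background is artificially truncated just below the
  cutoff, which is why the censored-ML re-estimate exists. Screens whose
  background genuinely extends past the cutoff need no such care.
* Per-cell imaging treats 2-D fields only; there is no 3-D segmentation,
  nuclear counting, or vendor-format ingestion (CSV/TIFF/SWC are the
  contracts).
* Calcium event detection assumes positive-going transients on a stable
  baseline; it does not model drift or bleaching.
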