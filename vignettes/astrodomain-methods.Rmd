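---
title: "Methods: synapse quantification and astrocytic-domain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synapse quantification and astrocytic-domain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrodomain)
```

## What this package computes

`astrodomain` quantifies structural synapses in multi-channel fluorescence
micrographs and asks how their density is distributed across the territory
("domain") of single astrocytes. Two measurements are central:

1. **Bipartite synapse density.** A bipartite synapse is a presynaptic
   punctum (e.g. vGLUT1 or vGAT) whose binarised footprint is covered by
   postsynaptic foreground (HOMER1, GEPHYRIN) over at least a fraction 0.33
   of its area. Densities are reported per square micrometre of analysed
   field.
2. **Domain density distribution.** Around an operator-supplied astrocyte
   core, 17 square bins of 27 µm side are placed on five Sholl-like
   concentric circles — one "center" bin plus four bins each at 30
   ("close"), 60 ("mid"), 90 ("distant"), and 120 µm ("out"). Per-bin
   postsynaptic densities, averaged within each circle, give the ordered
   center→out sequence called the synapse density distribution. The total
   sampled area is 17 × 27² = 12,393 µm²; the center+close+mid bins
   (9 bins, 6,561 µm²) constitute the astrocytic domain proper, matching a
   domain circle of radius 71 µm (half of the ~142 µm human domain
   diameter reported in the comparative literature).

Because raw clinical micrographs are not distributable, every stage is
exercised against a synthetic-scene generator with exact ground truth; the
generator is first-class, tested code, not a fixture.

## The synthetic-scene generator

Scenes are square 16-bit fields. Puncta of each channel follow a
homogeneous Poisson process with rate `density_per_um2`; each punctum is
rendered as an isotropic 2D Gaussian spot with `sigma = radius / 2`,
truncated at 3σ, at the channel amplitude. A configurable fraction of
presynaptic puncta (`coloc_fraction`) receives a matched postsynaptic
partner whose centroid is jittered isotropically (`coloc_jitter_um`,
default 0.08 µm) and whose radius is drawn independently — pre- and
postsynaptic markers are distinct proteins, so sizes should not be
correlated. Matched partners are appended on top of the post channel's own
(unpaired) Poisson puncta, so `coloc_fraction` controls colocalization
without altering the presynaptic density.

The background model is an additive offset (default 800) plus Gaussian
read noise (SD 250) plus sparse large faint blobs (5 × 10⁻⁴ µm⁻²,
radii 1.5–4 µm at 15 % of channel amplitude) rendered into all channels,
mimicking residual tissue autofluorescence. The study the pipeline targets
does not quantify its background or noise levels, so these defaults are
free parameters chosen to look like post-quenching human cortical tissue;
they are configurable and logged in every run.

Domain scenes modulate the postsynaptic rate by a piecewise-linear radial
profile of the distance to the core (linear interpolation between knots,
constant beyond the last), simulated by thinning of the envelope process.
A channel named `astro` renders the astrocyte body as a bright annulus
around an empty core centre; a `ptau` channel places its puncta under a
Gaussian annular weight peaking 20 µm from the core, a plaque-like corona.

Determinism: one master seed; every channel, the pair stream, the blob
stream, and every per-channel noise field draw from deterministically
derived sub-streams. Ground truth is drawn on different sub-streams than
rendering noise, so truth is bit-stable under any rendering change,
including clipping at the 16-bit ceiling (the clipped-pixel fraction is
reported, never silently absorbed).

Geometry note: the nominal acquisition settings of the emulated study
(50 µm at 0.049 µm/px; 212 µm at 0.052 µm/px) do not form integer pixel
grids. The generator therefore defaults to 1024 px × 0.049 µm
(50.176 µm) and, for domain work, 4080 px × 0.052 µm (212.16 µm), and
validates the grid at 10⁻⁶ relative tolerance.

**What the generator does not emulate:** spatially structured neuropil
background, depth-dependent attenuation in 50 µm sections, chromatic
shift, astrocyte-to-astrocyte overdispersion beyond Poisson sampling, and
anisotropic point-spread functions. Tests passing on these scenes
demonstrate correctness of the measurement chain under its stated model,
not robustness to every tissue artifact.

## The pre-processing chain

Each channel runs, in this fixed order: rolling-ball background
subtraction → difference-of-Gaussians bandpass → median despeckle →
3×3 sharpen → Yen threshold. The order is pinned by tests. Defaults
(`preprocess_params()`): ball radius 50 px, pass band 3–40 px, 3×3
median, sharpen kernel centre 12 / neighbours −1 normalised by 4, 256
histogram bins — ImageJ-convention values, all configurable because the
original macro's numeric settings are unpublished; every pipeline run
records the values used.

Numerical choices worth knowing:

* **Rolling ball** is implemented as grayscale opening with a flat disc
  (EBImage morphology; intensities are rescaled through [0, 1], which is
  exact since erosion/dilation commute with positive scaling).
* **Bandpass** is a DoG with σ = small/2 and large/2, separable Gaussian
  convolution with symmetric reflection padding, truncated at 3σ; output
  clipped at 0 to preserve the non-negativity invariant.
* **Yen threshold.** The criterion is maximised over all boundaries of a
  256-bin histogram. Binning normalises intensities over
  [min, 0.999-quantile] with an overflow top bin rather than plain
  min-max: on preprocessed puncta fields a handful of coincident-spot
  pixels otherwise stretch the range, squash the informative histogram
  into a few bins, and intermittently drive the criterion's argmax to a
  threshold that masks nearly everything. Quantiles are affine-equivariant,
  so mask invariance under monotone affine rescaling is preserved. The
  mask rule is strictly "greater than threshold" (deterministic ties).
* **Noise floor.** If no pixel of the signed DoG exceeds 6 robust
  (MAD-scaled) noise SDs, the field is treated as signal-free and the mask
  is empty. The maximum of ~10⁶ correlated noise pixels stays below ~5
  SDs while rendered puncta sit near 100, so the guard separates cleanly;
  it is what makes empty scenes yield empty masks instead of a Yen split
  of pure noise.
* Excluded pixels (soma mask) pass through every operator untouched and
  can never become foreground.

## Puncta detection and bipartite calling

Detection labels 8-connected foreground components (pinned against a
flood-fill oracle), keeps components whose area lies within the size
filter (default 0.1–2.0 µm², configurable and always logged; the
original tool's limits are unpublished), keeps border-touching components,
and drops puncta whose centroid falls in the excluded mask. Density is
count over non-excluded area.

The overlap fraction of a presynaptic punctum is the share of its pixels
that are foreground in the postsynaptic mask — the presynaptic area is
the denominator, which makes the presynaptic count a hard upper bound for
pairs. A pair is emitted at fraction ≥ 0.33; the reported partner is the
postsynaptic component contributing the most overlapping pixels, ties
broken by the lowest id. By default the raw postsynaptic foreground is
used; a flag switches to size-filtered postsynaptic puncta for users who
want both channels filtered symmetrically.

### Known calibration: ~20 % undercount at 0.4 puncta/µm²

On clean synthetic scenes at 0.4 puncta/µm² the detected density is a
stable ~0.80 of truth. The loss is not noise: Yen places its threshold at
roughly a tenth of a single-spot peak on background-subtracted scenes, so
single-spot footprints have radius ≈ 0.22–0.27 µm, and any two puncta
whose footprints touch merge into one 8-connected component — an
expected merged fraction of about 2λπR² ≈ 15–20 %. Splitting would
require watershed-style separation, which is outside the
connected-component contract of this pipeline, or sub-diffraction spot
sizes. The undercount is uniform across bins and cohorts (tested), so
relative comparisons — the scientific content of the workflow — are
unaffected; absolute densities should be read with this calibration in
mind.

## Domain layout decisions

* The four bins of each ring sit at the cardinal directions (+x, −x, +y,
  −y), axis-aligned. The source imagery is ambiguous about angles; the
  cardinal choice is symmetric, deterministic and non-overlapping at the
  given spacings, and the angle set is configurable.
* Class distances are core-to-bin-centre distances — the only reading
  under which 27 µm bins nearly tile adjacent rings.
* Soma exclusion radius defaults to 7.5 µm (typical protoplasmic
  astrocyte soma); the imaged study excludes somatic signal without
  stating a radius. Logged in every run.
* Bins clipped by the field edge are normalised by their in-field valid
  area; bins entirely outside are flagged missing and omitted from their
  class mean (never imputed as zero, which would bias edge astrocytes
  downward). A 212 µm field cannot contain the out ring of a centred
  core at all — the cohort simulations therefore use a 280.8 µm
  synthetic field so all 17 bins are observable, while the extraction
  code handles clipping for real-geometry images.
* The point-process path (`bin_counts`) computes the soma-circle/bin
  overlap on a fixed 400² grid (deterministic, ≈10⁻⁴ relative accuracy);
  the image path counts pixels.

## Statistical workflow

Two-group comparisons are gated by Shapiro–Wilk at α = 0.05: Welch's
unequal-variance t-test when both samples pass, two-sided Mann–Whitney U
otherwise (exactness follows `stats::wilcox.test`: exact for n < 50
without ties). Multi-group: one-way ANOVA with Tukey HSD; bin-level domain
densities: two-way fixed-effects ANOVA (cohort × distance class) with a
Brown–Forsythe Levene check (centre = median), followed by Games–Howell
pairwise comparisons for unequal variances — per pair, SE =
√(s₁²/n₁ + s₂²/n₂), Welch–Satterthwaite df, p and confidence limits from
the studentized-range distribution with q = |Δ|√2/SE (base R's `ptukey`
/ `qtukey`; at k = 2 this reproduces Welch's p to ~10⁻⁹, tested).
Games–Howell output uses the standard domain-analysis table schema
(groups, mean difference, standard error, t-value, df, p, CI limits).

Within-cohort distributions use a repeated-measures one-way ANOVA across
the five distance classes with the low-bias effect size
ω² = df·(MS_class − MS_err) / (SS_total + MS_subject). Negative ω²
estimates are reported as computed — clipping at zero would bias
meta-analytic use. Degenerate input with zero class effect is defined as
F = 0, p = 1 (the 0/0 case of identical class profiles). Paired post hocs
use Holm–Šidák: the i-th smallest p becomes 1 − (1 − p)^(m−i+1), with
step-down monotonicity enforcement and capping at 1.

Trait correlations treat the neuropil-thread grade (ordinal 0–5) as
numeric in Pearson's R, mirroring the emulated analysis; Spearman is
available behind a flag.

Calibration is tested, not assumed: each test's null rejection rate over
2000 simulated replicates must land in [0.035, 0.065] (the exact
Mann–Whitney at n = 10/10 achieves ~0.043 due to discreteness), two-way
ANOVA p-values are KS-uniform under the null, and repeated-measures power
matches the noncentral-F prediction within Monte-Carlo error.

## Problem sizes used by the tests and acceptance script

Detection calibration runs twenty ~25 µm fields at the native
0.049 µm/px; cohort simulations use the point-process path (no rendering)
at n = 12 astrocytes per cohort, λ = 0.25 µm⁻² postsynaptic density, 50
replicates for the astrocytic-plaque-vs-control two-way ANOVA contrast and
20 for the tufted-astrocyte close-vs-out paired contrast; type-I rates use
2000 null replicates per test. These sizes were chosen so the whole suite
gives stable Monte-Carlo estimates on a single CPU.

## Known limitations

Absolute densities carry the ~0.80 detection calibration described above.
The generator's realism gaps (structured neuropil background, section
artifacts) mean Yen thresholds on real tissue will sit relatively higher
than on synthetic scenes. Astrocyte cores are operator-provided points, as
in the emulated workflow — no automatic core segmentation. Bin-level
observations within an astrocyte are treated as exchangeable replicates by
the two-way ANOVA (no mixed-effects modelling of astrocyte clustering);
the repeated-measures branch operates on astrocyte-level class means and
is the safer inference where clustering matters.
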