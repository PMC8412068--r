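# astrodomain

Quantification of bipartite synapse densities and astrocytic-domain
synapse-density distributions from multi-channel fluorescence micrographs,
with the full statistical workflow and a ground-truth synthetic-scene
generator — an R re-implementation, as a tested and reusable pipeline, of
the image-analysis and statistics chain used to study synapse loss around
tau-bearing astrocytes (tufted astrocytes, astrocytic plaques) in primary
4R tauopathies.

## The measurements

**Bipartite synapse density.** Pre- and postsynaptic marker channels
(e.g. vGLUT1/HOMER1 for excitatory, vGAT/GEPHYRIN for inhibitory
synapses) are binarised by the chain *rolling-ball background subtraction
→ difference-of-Gaussians bandpass → median despeckle → sharpen → Yen
threshold*, followed by 8-connected, size-filtered puncta detection. A
presynaptic punctum with overlap fraction

    overlap = (pre pixels ∩ post foreground) / (pre pixels)  ≥  0.33

counts as a bipartite synapse; densities are puncta per µm² of analysed
area.

**Astrocytic-domain distribution.** Around an astrocyte core, 17 square
bins of 27 µm side sample five Sholl-like concentric circles — 1 bin at
the core and 4 bins each at 30, 60, 90, 120 µm ("center", "close",
"mid", "distant", "out"), 12,393 µm² in total, of which the 9
center+close+mid bins (6,561 µm²) form the astrocytic domain proper
(radius ≈ 71 µm, half the ~142 µm human domain diameter). Per-bin
postsynaptic densities, averaged per circle with the soma excluded, give
the ordered center→out "synapse density distribution".

**Statistics.** Shapiro–Wilk-gated two-group tests (Welch t / exact
Mann–Whitney U), Holm–Šidák step-down correction, one-way ANOVA + Tukey
HSD, two-way ANOVA with Brown–Forsythe Levene check, Games–Howell post
hoc for unequal variances (studentized-range p and CIs on
Welch–Satterthwaite df), repeated-measures one-way ANOVA with ω² effect
size, and Pearson trait–density correlations against the packaged
neuropathological trait counts.

Because the underlying clinical micrographs are not distributable, the
package ships a synthetic-scene generator (Poisson puncta rendered as
Gaussian spots over noise + autofluorescence blobs, controllable true
colocalization fraction, radial density profiles around an astrocyte
core) so every stage runs against exact ground truth. See the methods
vignette (`vignettes/astrodomain-methods.Rmd`) for the model, parameter
defaults, numerical choices, and known limitations.

## Worked example

```r
library(astrodomain)

# a 20 x 20 um two-channel field, every presynaptic punctum matched
cfg <- scene_config(
  field_size_um = 20, pixel_size_um = 0.1,
  channels = list(channel_spec("pre", 0.4), channel_spec("post", 0.2)),
  coloc_fraction = 1, coloc_jitter_um = 0, seed = 7)
sim <- generate_scene(cfg)
sim
#> <sim_scene> 389 true puncta over 2 channel(s); clipped fraction 0
#> <fl_scene> 2 channel(s) [pre, post], 200 x 200 px, 0.1 um/px

params <- field_params(preprocess = preprocess_params(
  background_radius_px = 20, bandpass_large_px = 20))
quantify_field(sim, params, source = "s1")$record[, 4:9]
#>   pre_density post_density bipartite_density n_pre n_post n_pairs
#> 1       0.275        0.385             0.275   110    154     110
```

Every detected presynaptic punctum is paired (`bipartite_density` equals
`pre_density`), as forced by full colocalization with zero jitter. The
detected 0.275/µm² against a true 0.38/µm² reflects the documented
~0.8 detection calibration at these densities (nearby puncta merge under
a single connected component; see the vignette).

The domain side in three lines:

```r
layout <- build_bin_layout(core_center_um = c(140.4, 140.4))
nrow(layout); layout_total_area_um2(layout)
#> [1] 17
#> [1] 12393
```

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study on synthetic
cohorts and write tidy tables to `results/`:

| script | what it does |
|---|---|
| `01_simulate_fields.R`  | 3 cohorts × 5 two-channel fields with known colocalization (Ctrl 0.55, PSP 0.35, CBD 0.50); writes TIFFs + ground truth |
| `02_quantify_synapses.R`| per-field densities and bipartite calls; cohort comparisons vs control |
| `03_domain_distributions.R` | 4 astrocyte cohorts × 12 domains under control-, TA- and AP-like radial profiles; per-bin densities and center→out distributions |
| `04_statistics.R`       | two-way ANOVA + Levene + Games–Howell table, per-cohort RM-ANOVA with ω², trait correlations |

`run_pipeline()` exposes the same stages behind one configuration (R list
or YAML; see `demo_run_config()`), validating thresholds before any
computation and writing a manifest with the seed, every parameter in
force, and a parameter hash.

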