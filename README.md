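# groovealign

Quantifies how substrate architecture at the scale of hundreds of
micrometres steers self-assembled microcapillary-like structures in
confocal fluorescence images. Endothelial/osteoblast co-cultures grown on
grooved or ridged bioceramic substrates form CD31⁺ vessel-like networks;
groovealign measures, per sample, whether those networks align with the
grooves and whether they form inside them:

* **DOA — Degree of Alignment**: from the 2-D Fourier power spectrum of the
  background-subtracted maximum projection, an orientation histogram
  w(θ), θ ∈ [−90°, 90°) with the groove axis at 0°, and

  DOA = w̄(0° ± 2°) / w̄(90° ± 2°).

  DOA = 1 means random alignment.

* **DOC — Degree of Containment**: from the segmented mask (Phansalkar local
  threshold, particles < 400 µm² removed), the vertically averaged signal
  s(x) across the sample, compared against groove intervals detected from
  the stack's own depth profile:

  DOC = (∫groove s dx / Lgroove) / (∫outside s dx / Loutside).

  DOC = 1 means a spatially uniform distribution.

The package implements the full analysis chain — substrate geometry models,
a synthetic confocal stack generator with ground truth, image preparation
(projection, rotation/crop, rolling-ball background subtraction,
auto-contrast, local thresholding, particle filtering), orientation
analysis, depth-profile groove detection, and nonparametric group
comparison (Kruskal–Wallis with Dunn's post-hoc test) — as tidyverse-style
functions returning tibbles.

## Worked example

Simulate a co-culture on small deep grooves (330 µm wide, 300 µm deep,
630 µm periodicity) with strongly aligned, fully groove-contained
filaments, then run both analysis paths:

```r
library(groovealign)

sim <- generate_coculture_stack("small_deep", n_filaments = 40,
                                alignment_kappa = 16, containment_prob = 1,
                                seed = 101)
sim$stack
#> <image_stack> 1200 x 1050 px, 10 slices | 2.3917 um/px, dz 38.89 um

cfg <- pipeline_config(design = "small_deep", alignment_kappa = 16,
                       containment_prob = 1, seed = 101)
res <- run_pipeline(cfg, sim$stack)
dplyr::select(res$report, design, doa, doc, n_grooves)
#> # A tibble: 1 × 4
#>   design       doa   doc n_grooves
#>   <chr>      <dbl> <dbl>     <int>
#> 1 small_deep  14.8  7.90         5
```

A DOA of 14.8 says the CD31 signal runs overwhelmingly along the groove
axis; a DOC of 7.9 says the average signal density inside the five detected
grooves is 7.9× that outside. An isotropic, uncontained culture measures
DOA ≈ 1 and DOC ≈ 1. The detected intervals, orientation histogram, signal
and depth profiles travel with the result (`res$grooves`, `res$histogram`,
`res$signal_profile`, `res$depth_profile`) and have plot helpers
(`plot_profile(res$depth_profile, res$grooves)`,
`autoplot(res$histogram)`); `simulate_study()` + `summarize_groups()` +
`kruskal_dunn()` reproduce the full seven-architecture × 3-replicate study
design, and `plot_group_summary()` draws the mean ± SEM panel with the
y = 1 reference lines.

A thin command-line front end with `simulate` / `directionality` /
`grooves` / `doc` / `compare` / `run-all` subcommands is in
`inst/cli/groovealign.R`.

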