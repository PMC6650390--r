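# nkwell3d

Quantitative analysis of natural killer (NK) cell migration and
cytotoxicity in 3D collagen-filled microwells, from two-channel
time-lapse confocal z-stacks (or from track tables directly). The
package is aimed at quantitative immunologists and image analysts who
need per-cell, per-time-point measures of lymphocyte motility and
NK–target killing in a 3D matrix — together with a full synthetic-data
path (trajectory simulator + volume renderer with ground truth) for
validating every stage without raw imaging data.

## What it computes

**Segmentation and linking.** Cells are detected per frame by a
difference-of-Gaussians bandpass (σ = 1 and 3 px, divided by 8 in z),
thresholded at 0.02, split by an h-minima (h = 0.15) watershed, hole-
filled, and size-filtered (≥ 5 voxels), after temporal-minimum background
subtraction. Detections are linked by exact frame-to-frame assignment
under an anisotropic Brownian motion model (σ = 6 voxels in xy, 0.5 in
z), with appearance/disappearance probabilities of 0.001 and no gap
closing.

**Migration modes.** For each track (≥ 1 h, no z jumps > 40 µm), a
centred 25-point sliding window yields the local mean squared
displacement

```
MSD(t_n) = 1/(N−n) Σ_i |r_{i+n} − r_i|²,   t_n = n Δt
```

whose first 6 lags are fitted for the motility coefficient `M`
(`MSD = 6 M t`) and the anomalous exponent `α` (`MSD ∝ t^α`). After a
5-point rolling average, each instant is classified as **TMAP**
(transient migration arrest, `M < 4.9 µm²/min` — the Stokes–Einstein
value for a passive 8-µm sphere in water at 37 °C), **directed**
(`α > 1.5` for ≥ 10 consecutive points), or **random**. Per-track and
population summaries include mean speed, the duration-corrected
displacement `‖r_end − r_1‖/d_tot · √t_tot`, mode fractions, transitions
per hour, and the mean mode dwell time.

**NK–target interactions.** Contact episodes are maximal runs with
centre-to-centre distance strictly below 20 µm to a live target; target
death is called from sustained loss of fluorescence (or ground truth),
outcomes are assigned within a configurable attribution window, and
durations are compared between cytolytic and non-cytolytic contacts with
a Mann–Whitney U test.

## Worked example

```r
library(nkwell3d)

cfg <- run_config(seed = 1L,
                  sim = simulation_config(n_nk = 30, n_target = 8,
                                          duration = 540, seed = 1L))
res <- run_pipeline(cfg, "run1")
pop <- res$migration$population
round(c(mean_speed = pop$mean_speed, frac_tmap = pop$frac_tmap,
        frac_random = pop$frac_random, frac_directed = pop$frac_directed,
        dwell_min = pop$dwell_mean_min), 2)
#>    mean_speed     frac_tmap   frac_random frac_directed     dwell_min
#>          4.65          0.27          0.39          0.34         94.39
res$interactions$stats$cytolytic_fraction
#> [1] 0.5
report("run1")   # PNG figures + report_summary.csv in run1/
```

The simulated cohort moves at ~4.7 µm/min on average (the assay reports
3.2 ± 1.7 µm/min for primary human NK cells), splits its time roughly
evenly across the three migration modes, dwells ~94 min in a mode before
switching (30 tracks' estimate of the configured 106 min mean), and half
of its NK–target contacts are cytolytic — the regime reported for the
real assay.

A command-line interface wrapping the same functions ships at
`inst/cli/nkwell3d.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nkwell3d.R", package="nkwell3d"))')" \
    run --config run.yaml --out outdir
```

with subcommands `simulate`, `render`, `segment`, `link`, `depthprofile`,
`compare-tracks`, `analyze-migration`, `analyze-interactions`, `run`,
`report`.

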