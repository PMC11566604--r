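# glianet

Astrocyte–neuron network analysis for dual-color multi-fiber photometry.

## The problem

Dual-color multi-fiber photometry records population Ca²⁺ activity from
astrocytes (GCaMP6f, 470 nm excitation) and neurons (jRGECO1a, 560 nm)
simultaneously in several brain regions (S1, M1, CA1) of freely behaving
mice, alongside a 30 Hz behavior video. Turning those raw fluorescence
streams into science requires a chain of standard but fiddly steps, each of
which this package implements and tests:

1. **Normalization** — per-ROI raw signal F<sub>raw</sub>, a moving-window
   baseline F<sub>baseline</sub>, then

   ΔF/F = (F<sub>raw</sub> − F<sub>baseline</sub>) / F<sub>baseline</sub>,
   z = (ΔF/F − mean(ΔF/F)) / sd(ΔF/F)

2. **Transient detection and event-aligned kinetics** — onset, peak, end,
   duration of Ca²⁺ transients; latency/peak-time/valley-time relative to
   movement onsets or footshocks; astrocyte–neuron paired timing
   differences (astrocytic responses lag neuronal ones by seconds, and the
   astrocytic peak precedes a neuronal Ca²⁺ valley).
3. **Behavior quantification** — binarized video frames, largest-component
   mouse delineation, a body-size-normalized movement index
   (symmetric-difference pixels / body area), stationary vs movement state
   segmentation with movement onsets, arena trajectories.
4. **Connectivity** — state-conditioned inter-regional Spearman matrices per
   cell type, astro–neuron lagged cross-correlation per region, and
   connectivity graphs on stereotaxic (AP/ML) node positions.
5. **Prediction** — lagged-feature random-forest regression of astrocytic
   activity from neuronal activity with blocked cross-validation, reported
   as variance explained.
6. **Statistics** — Wilcoxon signed-rank / rank-sum tests with Z statistics,
   mean ± SEM summaries.

Because the kind of raw recordings this pipeline targets are not publicly
deposited, the package ships a **synthetic recording generator**
(`sim_config()`, `simulate_recording()`, `render_behavior_video()`,
`render_fiber_bundle_frames()`) whose defaults encode the studied
phenomenology: astrocytic movement-response latency 2.47 s / peak 5.66 s vs
neuronal 0.42 s / 1.07 s, footshock kinetics (1.05/0.20 s latencies,
8.05/6.24 s durations), a neuronal valley 1.5 s (movement) or 3.35 s
(footshock) after the astrocytic peak, astrocytic durations mostly > 20 s vs
neuronal mostly < 20 s, stationary microdomain events at one tenth of the
movement amplitude, and shared inter-regional drive that is much stronger
during movement. Every recording comes with full ground truth, so each
analysis stage is validated by parameter recovery.

## Worked example: recover movement-evoked kinetics

```r
library(glianet)

mv <- recover_event_kinetics("movement", n_trials = 20, seed = 1)
mv$astro$summary
#> # A tibble: 5 × 4
#>   metric         mean      sem     n
#>   <chr>         <dbl>    <dbl> <int>
#> 1 latency_s      2.52  0.00457    19
#> 2 peak_time_s    5.88  0.114      19
#> 3 peak_z         4.58  0.0947     19
#> 4 duration_s    34.3   1.10       19
#> 5 valley_time_s NA    NA           0

mv$paired$summary
#> # A tibble: 3 × 4
#>   metric                         mean     sem     n
#>   <chr>                         <dbl>   <dbl> <int>
#> 1 latency_diff_s                 2.11 0.00702    19
#> 2 peak_diff_s                    4.75 0.113      19
#> 3 astro_peak_to_neuron_valley_s  1.32 0.117      19
```

The generator injected a 2.47 s astrocytic onset latency and a 5.66 s peak
time; the full pipeline (session simulation → ΔF/F and z-scoring → movement
onsets re-derived from the movement index → event-triggered ensembles →
per-trial kinetics) reads back 2.52 s and 5.88 s. The paired summary shows
the astrocytic response lagging the neuronal one by 2.11 s in onset and
4.75 s at the peak, and the astrocytic peak preceding the neuronal valley by
1.32 s (injected: 1.50 s). One of the 20 bouts fell too close to the session
edge and was dropped (n = 19).

Detection-level statistics on a default free-behavior session show the
duration dichotomy between the two cell types:

```r
sim  <- simulate_recording(sim_config(duration_s = 1800, regions = "M1", seed = 7))
proc <- process_traces(sim$traces, sim$rate_hz)
ev   <- detect_transients(proc$z[proc$channel == "astro"], 30)
transient_stats(ev, 1800)[c("frequency_per_min", "fraction_over_20s")]
#> $frequency_per_min
#> [1] 0.1666667
#> $fraction_over_20s
#> [1] 0.8
```

An end-to-end run from a YAML configuration:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "glianet")
report <- run_pipeline(cfg, outdir = tempfile())
report$manifest
```

Result objects come with broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 visualizations (event-triggered averages
with SEM ribbons, connectivity heat maps and stereotaxic graphs,
cross-correlograms, movement-state overlays).

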