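---
title: "Methods: signal model, measurement definitions, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, measurement definitions, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the analysis model behind glianet, the tunable
parameters and their defaults, the design of the synthetic recording
generator, and the numerical decisions that were genuinely open. Nothing
here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Signal model and normalization

Fiber photometry measures bulk fluorescence of a genetically encoded
calcium indicator through an implanted fiber; each (region, channel) pair
yields one raw trace F~raw~ at 30 Hz, the mean pixel intensity inside the
corresponding disc of the fiber-bundle image (`extract_roi_traces()`).
Normalization follows the standard two-step form:

* **Baseline** — `moving_baseline()` computes a centered moving mean with
  edge windows truncated to the available samples (a trailing variant is
  provided for online-style processing). The default window is **90 s**.
  This was an open choice: the window must sit well above the longest
  transients it should preserve, and below the photobleaching timescale.
  Astrocytic transients here routinely exceed 20–35 s, so a window
  comparable to that length would subtract the events themselves and split
  long transients in two; 90 s (about three times the typical astrocytic
  event) preserves them while still tracking a bleaching time constant of
  ~20 min.
* **ΔF/F** = (F~raw~ − F~baseline~) / F~baseline~. Non-positive baselines
  indicate invalid fluorescence input and raise an error rather than being
  patched.
* **z-score** = (ΔF/F − mean) / sd with the *population* (1/n) standard
  deviation over the normalization span (default: the full session), so the
  unit-variance invariant holds exactly. Whole-session z-scoring is the
  default because the correlation analyses operate on whole sessions; a
  per-trial span can be passed instead.

Sample indexing is 0-based in time (`time_s = (i − 1) / rate_hz`) and all
intervals are half-open `[start, end)`.

## Transient detection

`detect_transients()` seeds an event wherever z ≥ θ~on~ (default 2) holds
for at least `min_dur_s` (1 s), extends the event back to the preceding
upward crossing of θ~off~ (0.5) and forward until z falls below θ~off~, and
merges events separated by less than 0.5 s. Peaks take the earliest sample
on ties, for determinism. These operating points are package choices (the
upstream acquisition software does not document any), set so that the
kinetic scales of interest — second-scale latencies, 5–35 s durations — are
resolvable at the generator's default signal-to-noise ratio; all are
arguments.

## Event-aligned kinetics

`build_ensemble()` cuts `[event − pre_s, event + post_s)` windows around
movement onsets or footshocks, drops trials without a full window (no
padding — padding would bias the SEM), and optionally subtracts each
trial's pre-window mean. `response_metrics()` then measures per trial, on a
lightly smoothed copy (0.2 s moving mean):

* **peak**: maximum within `(0, peak_window_s]` — 15 s for astrocytes, 5 s
  for neurons, matching their kinetic scales;
* **responder gate**: trials whose peak stays below θ~resp~ = 2 z are
  non-responders and are excluded from summaries (this naturally reproduces
  slightly different n per metric across panels);
* **latency**: first crossing of a *fraction of the trial peak* (default
  0.15) sustained for 0.33 s. A fixed absolute threshold was considered and
  is available (`latency_mode = "absolute"`), but session z-scoring divides
  by the total signal sd, which depends on how event-rich the session is —
  an absolute criterion therefore measures later on event-dense sessions.
  The fraction-of-peak criterion is invariant to that scale, which is what
  makes parameter recovery work at ±0.1–0.3 s tolerances;
* **duration**: from the latency crossing to the response end. The end is
  found by walking supra-threshold runs (threshold 0.10 of peak) forward
  from the peak, bridging sub-threshold dips shorter than 2 s and ignoring
  unsustained (< 0.33 s) noise blips. The bridge exists because the
  neuronal valley (below) legitimately undercuts any end threshold in the
  middle of the response;
* **valley** (neurons): argmin within `(peak, peak + 15 s]`.

`paired_differences()` reports astro − neuron latency and peak-time
differences (positive = astrocyte later) and the neuronal-valley minus
astrocytic-peak interval (positive = valley follows peak).

## Behavior video

Frames are binarized (fixed threshold or per-frame Otsu split; the Otsu
implementation takes the midpoint of the between-class-variance plateau so
well-separated modes are split down the middle), the largest connected
component is the mouse (EBImage's labeling), invalid frames are
interpolated (gaps over 1 s are an error), and the movement index is the
symmetric-difference pixel count between consecutive masks divided by the
mean body area — the simplest body-size-normalized posture-change measure
consistent with "movement relative to body size". States are segmented by
thresholding that index (θ = 0.05, sustained ≥ 1 s, gaps < 0.5 s bridged);
movement onsets additionally require ≥ 3 s of preceding quiescence. These
thresholds are package decisions, not published values, and are all
configurable.

## Connectivity and prediction

State-conditioned series concatenate the samples inside all segments of one
state, identically indexed across regions. Inter-regional association uses
Spearman rank correlation (`stats::cor`, average ranks on ties); undefined
entries from constant series are flagged NA, never imputed. Astro–neuron
association uses Pearson cross-correlation over integer-sample lags within
±10 s (positive lag = astrocyte follows neuron); the reported value is the
peak over lags, with a zero-lag mode for sensitivity checks, because a
single unlagged coefficient would understate an association whose sign
convention the timing results themselves motivate. Correlations are
computed on the 30 Hz z traces without downsampling or extra smoothing.

Prediction uses a random forest (ranger, 100 trees, fixed seed,
single-threaded for determinism) on lagged neuronal features (0–10 s in 1 s
steps) with **blocked** 5-fold cross-validation — contiguous time folds —
because shuffled folds leak across the autocorrelation of these signals and
inflate variance explained. Variance explained is pooled over held-out
predictions, `1 − SSE/SST`, which is stable for short folds where per-fold
R² is noisy; it can be negative for useless models.

Wilcoxon tests delegate the p-value to `stats::wilcox.test` (exact in the
small-sample, tie-free regime; normal approximation with tie correction
otherwise) and add the continuity-corrected Z deviate, which the base
function does not report. No multiple-testing correction is applied
anywhere; the pipeline report records that.

## The synthetic generator

`simulate_recording()` builds, per region and channel, a latent signal
`events + shared drive + noise`, then
`F_raw = F0 · (1 + gain · signal) · bleach(t)` with a single-exponential
bleach (20% amplitude, τ = 1200 s) and additive Gaussian noise (σ = 0.25
latent units). Behavior comes from a two-state renewal process (stationary
gaps of `min_quiescence + Exp` followed by truncated-normal bouts) with a
smooth random-walk trajectory at ~8 cm/s inside a 40 × 40 cm arena;
behavior video renders a dark 4 × 2.5 cm ellipse on a bright floor at a
scaled-down 160 × 90 resolution by default (the full 1280 × 720 is one
config field away, but desk-scale tests do not need it).

**Event kernel.** Each behavioral trigger (movement onset, footshock)
launches one astrocytic and one neuronal transient per region. The kernel
is zero until the configured onset latency, rises to the configured
amplitude exactly at the configured peak time, and returns to zero at
onset + duration. Rise and decay are warped inverse-smoothstep segments,
which are steep at onset, peak and termination. This shape was chosen over
the more conventional difference-of-exponentials deliberately: a
double-exponential's gradual foot means a threshold (or
fraction-of-peak) crossing lands hundreds of milliseconds after the
nominal onset, so the generator's own latency parameter could not be read
back out at the tolerances the timing analyses need. With steep edges,
onset, peak and end are recoverable regardless of the downstream
normalization scale — the generator's parameters are then genuine ground
truth for the whole measurement chain.

Defaults encode the studied phenomenology: movement-evoked astrocytic
kinetics (latency 2.47 s, peak 5.66 s, duration 35 ± 5 s, amplitude 8),
neuronal kinetics (0.42 s, 1.07 s, 8 ± 2 s, amplitude 6), and a neuronal
**valley** — a subtractive Gaussian dip (depth 5, sd 0.3 s) centered 1.50 s
after each astrocytic peak. The footshock preset switches to the
sensory-stimulation kinetics (astro 1.05/1.67/8.05 s; neuron
0.20/0.99/6.24 s; valley offset 3.35 s) and delivers 0.6 mA, 1 s shocks
every 5 min, four per session. The dip is deliberately narrower than a
naive reading of the timing figures might suggest: at the footshock
geometry the valley sits *inside* the neuronal response, and a wide dip of
detectable depth would swallow the response tail and make the duration
unmeasurable; a sd of 0.3 s leaves a resolvable rebound. Stationary periods
carry astrocytic *microdomain* events at one tenth of the movement
amplitude (rate 0.3/min, duration 25 ± 5 s — long enough that the
ground-truth duration dichotomy, ≥ 80% of astrocytic events over 20 s,
holds across all astrocytic events).

**Shared drive.** A smooth (0.5 s Gaussian-filtered) unit-variance process
is mixed into every astro/neuron channel with weight √c, plus a private
component with weight √(1 − c), where c is 0.85 during movement and 0.3
during stationary states. The drive therefore has exactly the configured
inter-channel correlation per state, and both the inter-regional and the
astro–neuron associations are higher during movement. Optional GFP/mCherry
control channels carry only noise and bleach.

**Trial-structure presets.** The movement-timing preset uses one long
session (~150 s per trial, i.e. ~50 min for 20 trials, matching the scale
of real sessions) with 90 s minimum quiescence so the slow astrocytic
responses never overlap; the astrocytic event duty cycle stays near 0.25,
which keeps movement responses well above the detection gate after
session-level z-scoring. The footshock preset runs five 4-shock sessions
with consecutive seeds (a five-animal, four-trial design). The
connectivity preset uses 300 s sessions with 2 bouts/min so both states
have ample samples.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: hemodynamic and motion artifacts (no
isosbestic channel is modeled or needed), indicator nonlinearity and
saturation, biophysical Ca²⁺ dynamics (no IP₃ signaling, no spiking),
heterogeneous per-event kinetics beyond amplitude/duration jitter,
photon shot noise (available as an option, off by default), and any
behavior richer than the binary stationary/movement distinction. One known
gap matters for interpretation: movement-evoked astrocytic tails extend
into following stationary segments and are shared across regions, so
recovered stationary correlations sit above the configured drive coupling;
the state *ordering* — the scientific claim — is robustly reproduced, the
absolute stationary level is not.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
desk scale: single-region sessions of 5–50 min at 30 Hz (9 × 10³–10⁵
samples per channel), 20-trial recovery experiments, 20-session state
contrasts, 240 s of 160 × 90 video, and 200-case randomized oracle sweeps
for the moving mean, Spearman, transient detection and both Wilcoxon tests.
Every stochastic component draws from an explicitly seeded generator;
identical configurations produce byte-identical recordings, and the
prediction stage pins ranger's seed and thread count so variance explained
is reproducible to the last bit.
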