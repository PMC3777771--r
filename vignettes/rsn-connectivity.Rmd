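---
title: "Resting-state-network PLI connectivity: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state-network PLI connectivity: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megrsn)
```

## The scientific problem

Source-space MEG gives one reconstructed time series per cortical region of
interest (ROI). The question this package addresses is longitudinal: does
functional connectivity *within* literature-defined resting-state networks
(RSNs) change between two measurement occasions (T1 before and T2 after an
intervention), and does the per-subject connectivity change correlate with
the change in cognitive performance?

The connectivity statistic is the **phase lag index** (PLI). For two signals
with instantaneous phase difference $\Delta\phi(t_k)$, $k = 1 \dots N_s$,

$$\mathrm{PLI} = \left| \left\langle \mathrm{sign}\,
\sin \Delta\phi(t_k) \right\rangle \right|,$$

with $\Delta\phi$ taken in $[-\pi, \pi]$ and $\langle\cdot\rangle$ the mean
over samples. PLI is 0 for no consistent nonzero-lag phase relation and 1
for total synchronization at a fixed nonzero lag. Its defining virtue is
insensitivity to volume conduction: an instantaneously mixed (zero-lag)
copy of a source produces a phase difference concentrated at exactly 0 or
$\pi$, where $\mathrm{sign}\sin$ contributes nothing. For a symmetric
$2\times 2$ zero-lag mixing with off-diagonal $\varepsilon$, the invariance
is in fact sample-exact: writing $z_a, z_b$ for the analytic signals,
mixing maps $\mathrm{Im}(z_a \bar z_b) \mapsto
(1-\varepsilon^2)\,\mathrm{Im}(z_a \bar z_b)$, so every
$\mathrm{sign}\sin\Delta\phi$ sample — and hence the PLI — is unchanged
whenever $|\varepsilon| < 1$. The test suite exploits this identity.

## Pipeline

1. **Decimation** (`downsample_ts()`): recordings acquired at 1250 Hz are
   decimated by 4 to 312.5 Hz behind an anti-alias low-pass. All band
   filtering is defined relative to the post-decimation rate; this order
   makes the canonical epoch arithmetic come out exactly
   (4096 samples at 312.5 Hz = 13.1072 s).
2. **Representative voxel per ROI** (`select_representative_voxel()`): when
   a ROI is represented by several candidate voxel series, the one with
   maximal pseudo-Z in the analysis band is kept. Under a unity noise
   covariance the beamformer pseudo-Z reduces to band-limited signal
   variance, which is what `pseudo_z()` computes; the retained series is
   the broad-band one, so each band's analysis re-filters from it.
3. **Band filtering** (`band_filter()`): six canonical bands — delta
   0.5–4, theta 4–8, lower alpha 8–10, upper alpha 10–13, beta 13–30,
   lower gamma 30–48 Hz. The filter applies the *squared Butterworth
   band-pass magnitude* (order 4) in the frequency domain: amplitude
   response identical to a forward–backward Butterworth, phase response
   exactly zero. We chose the spectral form after finding that direct-form
   order-8 recursions visibly distort narrow bands at high sampling rates
   (an in-band 9 Hz tone filtered at 1250 Hz lost >20% amplitude through a
   time-domain two-pass filter), which matters in a pipeline whose entire
   downstream analysis is phase-based. The cost is the implicit
   circularity of FFT filtering; its wrap-around transients live in the
   recording edges, which the PLI edge trim discards.
4. **Epoching** (`segment_epochs()`): five non-overlapping 4096-sample
   epochs taken consecutively from the recording start. Human epoch
   selection exists to avoid artifacts; synthetic recordings have none, so
   consecutive blocks are taken, and an explicit `starts` argument
   reproduces any manual selection.
5. **PLI matrices** (`pli_matrix()`): analytic-signal phase per channel and
   epoch (FFT Hilbert transform), then the sign–sin mean over all unordered
   channel pairs. Per-epoch PLIs are averaged across epochs rather than
   estimated on concatenated epochs (concatenation splices discontinuous
   phases; both modes are available via `epoch_mode`). Five percent of
   samples are trimmed from each epoch edge before averaging, against
   Hilbert edge effects; `sign(0) = 0`, which pins the self-pair PLI at
   exactly 0; the diagonal is stored as 0 and excluded from every mean.
6. **RSN restriction** (`summarize_rsns()`): the mean PLI over a network's
   *within-network* unordered pairs only. The 78-label cortical registry
   and the four default networks (DMN, left/right frontoparietal, executive
   control) ship as an editable YAML config; memberships follow published
   anatomical descriptions mapped to atlas labels and are deliberately
   data, not code, because network definitions vary between sources.
7. **Inference** (`run_full_inference()`): per band, global mean PLI T1 vs
   T2; per band and network, Wilcoxon signed-rank tests with
   Benjamini–Hochberg FDR at $q = 0.05$ applied *within each band's family
   of network tests* (the global tests form their own family); and for each
   FDR-surviving (band, network) cell, post-hoc Kendall tau-b correlations
   between per-subject $\Delta$PLI and all six cognitive-domain delta
   scores, uncorrected, as post-hoc analyses are reported.

### Statistical conventions

* Wilcoxon signed-rank: differences are $T1 - T2$, zero differences
  dropped, average ranks for ties, tie-corrected variance. A group increase
  at T2 therefore reports a negative z. The p-value is exact (full
  enumeration of sign assignments, computed by convolution) for
  $n \le 15$; beyond that a continuity-corrected normal approximation is
  used. The worst-case gap between the corrected approximation and the
  exact p is 0.035 at $n = 5$ and shrinks with $n$; the uncorrected gap
  would be 0.127, which is why the correction is on by default while the
  reported z stays the plain standardized statistic.
* Kendall tau-b with tie correction; exact p from the inversion-count
  distribution for tie-free $n \le 10$, tie-corrected normal approximation
  otherwise.
* FDR: Benjamini–Hochberg step-up, chosen as the field default where the
  procedure is not further specified. Families are per band: the four
  network tests of one band are corrected together, never pooled across
  bands. With one strong p-value (e.g. 0.003) and weak companions, an
  effect survives in its own band while equally-sized raw p-values of
  0.027 in *other* bands' families do not — the asymmetric survival
  pattern typical of this family structure.

## The synthetic cohort generator

No recordings are distributed with studies of this design, so validation
runs on a simulator whose ground truth is known by construction. The
source model is deliberately the simplest structure that exposes exactly
what the PLI measures:

* **Narrowband carriers.** Each component is band-limited Gaussian noise
  built in the frequency domain (i.i.d. complex Gaussian coefficients on
  the in-band bins), giving a one-sided spectrum whose analytic signal is
  available exactly; rotating it by $e^{-i\theta}$ shifts the instantaneous
  phase by precisely $\theta$ at every sample.
* **Coupling.** A pair shares a fraction `coupling` of component variance:
  $a = \sqrt{c}\,\mathrm{Re}(z) + \sqrt{1-c}\,x_a + \sigma w_a$, and $b$
  likewise with $z e^{-i\theta}$. At $c = 1, \sigma = 0$ the phase
  difference is constant ($\mathrm{PLI} = 1$ for $\theta \notin \{0,
  \pi\}$); at $c = 0$ the pair is independent.
* **Networks.** Every network has one shared component per recording;
  member $i$ of $m$ uses phase offset $\theta_i = (i - \tfrac12)\pi/m$, so
  all within-network pairwise lags lie strictly inside $(0, \pi)$ — no
  pair is accidentally zero-lag.
* **Volume-conduction surrogate.** `apply_mixing()` multiplies each time
  sample by a fixed matrix — instantaneous mixing with no temporal shift,
  the mechanism PLI is designed to ignore.

### Calibration

The map from coupling fraction to expected PLI has no closed form, so it
was calibrated once by Monte Carlo — 300 replicates per cell of a grid over
coupling and pairwise lag at the standard geometry (4096-sample epochs,
312.5 Hz, 8–10 Hz carrier, unit noise) — and frozen as a constant table
(`network_pli_from_coupling()`, `coupling_for_network_pli()`). Injecting a
target mean network PLI inverts the table by root finding. Two properties
of the map matter in practice:

* It has a **finite-sample null floor**: with 4096-sample epochs in a
  2 Hz-wide band the expected PLI of *independent* sources is ≈ 0.14,
  because narrowband phase differences decorrelate on the 1/bandwidth
  timescale and the absolute value of a noisy mean is biased upward.
  Observed resting-state PLI values of 0.1–0.2 in narrow bands should be
  read with this floor in mind. Below the floor, coupling targets clamp
  to 0.
* The floor (and hence the low end of the map) **depends on epoch
  length**; the table is calibrated at 4096 samples, and shorter epochs
  raise the floor. Cohorts generated at other geometries still order
  correctly in coupling, but the absolute baseline target is only exact at
  the calibration geometry.

### Cohort defaults and what they emulate

`cohort_spec()` defaults describe the emulated study: 10 subjects, two
occasions, five 4096-sample epochs at 312.5 Hz, baseline mean network PLI
0.2 (a typical narrowband resting-state value, above the null floor) with
between-subject SD 0.02 shared across occasions, and — when effects are
requested — a T2-only increase of the affected networks' mean PLI with
target 0.05. Subject heterogeneity multiplies the injected change by a
lognormal factor (log-SD 0.6, mean 1): some subjects change a lot, some
barely, which is exactly the between-subject spread that a
connectivity–cognition correlation needs to exist. Cognitive deltas are
`link × (subject's true ΔPLI) + N(0, 0.25)` in z-score units for linked
domains (default: verbal memory at 40 z per unit ΔPLI, i.e. ≈ 2 z for the
average injected change) and pure noise elsewhere. The link/noise ratio was
fixed by a replicate-simulation oracle so that, conditional on the network
effect being detected, the verbal-memory tau is positive in ≥ 95% of
replicates; weaker links make the sign test of the post-hoc correlation
uninformative at $n = 10$.

What the generator does **not** emulate: 1/f spectral background, sensor
forward/inverse modeling, head geometry, artifacts, non-Gaussian cognitive
noise, and any dependence of cognition on baseline connectivity (only on
its change). Passing tests therefore demonstrate that the pipeline
recovers what it is defined to recover under a known narrowband
phase-coupling model — not that real MEG effects of this size would be
detected at these rates.

## Numerical choices

* FFT-domain zero-phase filtering (see above); epochs are cut after
  filtering the full recording, so interior epochs carry no filter
  transients at all.
* Analytic signal by the one-sided-spectrum FFT method; phases per epoch.
* 5% edge trim per epoch side before the sign–sin mean (Hilbert edge
  effects decay within ≈ 1/bandwidth, ~200 samples here).
* Degenerate inputs fail loudly: all-zero series have no phase; zero
  epochs have no PLI; singleton ROI subsets have no within-network pairs;
  matrices in differing label orders are rejected rather than silently
  reindexed (`realign_matrix()` is the explicit remedy).
* Exact-test enumeration uses convolution over a half-unit rank grid
  (handles average ranks); the Kendall exact distribution uses the
  Mahonian-number recursion.
* `sign(0) = 0` everywhere, which also makes the duplicated-channel PLI
  exactly 0 rather than length-dependent.

## Validation problem sizes

The test suite validates end-to-end behaviour at sizes chosen to keep the
full run comfortably reproducible on one CPU: null calibration uses 200
cohorts of 10 subjects on a 6-ROI single-network atlas with 2 × 2048-sample
epochs; effect recovery uses 40 cohorts at the full standard geometry
(5 × 4096 @ 312.5 Hz) on a 20-ROI four-network atlas, compared against a
400-replicate simulation oracle; the oracle equivalence checks (direct PLI
formula, brute-force subset means, exhaustive Wilcoxon enumeration,
pair-count tau, step-up FDR) are exact and cheap. The 78-ROI registry is
exercised where arithmetic, not signal processing, is the point.

## Known limitations

* RSN memberships are a literature-faithful approximation mapped onto
  atlas labels; where a study's exact membership table is available it
  should be supplied as a config file, which is authoritative.
* The coupling calibration is geometry-specific at its low end (see
  above).
* The multi-subtest cognitive aggregation (mean of T1-standardized subtest
  scores; "overall" as the mean over all standardized subtests) is one
  defensible convention among several; published composite columns
  computed under unknown conventions will not reproduce exactly.
* PLI discards zero-lag coupling by design; genuinely instantaneous
  neuronal coupling is invisible to this pipeline, and the finite-sample
  floor makes very weak coupling indistinguishable from none at short
  recording lengths.

## A worked example

```{r example, eval = FALSE}
library(megrsn)

atlas <- load_rsn_config()
spec <- cohort_spec(n_subjects = 10, effect_networks = "DMN",
                    effect_size = 0.05, seed = 1)
cohort <- generate_cohort(spec, atlas)

conn <- cohort_connectivity(cohort, bands = "lower_alpha")
summaries <- summarize_rsns(conn, atlas$networks, include_global = TRUE)
report <- run_full_inference(summaries, cohort$cognition)
report
glance(report)
plot_rsn_change(summaries, networks = "DMN")
```
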