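---
title: "Phase-lag-index networks and minimum spanning trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index networks and minimum spanning trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmst)
```

## What this package computes

`eegmst` analyses multichannel resting-state EEG as a functional network and
asks whether the network's *topology* — not its connectivity strength or its
spectral power — differs between a patient group and controls, and whether it
tracks a clinical disability covariate (the inverted ALSFRS-R scale,
`48 - ALSFRS-R`, so 0 is healthy). The motivating application is amyotrophic
lateral sclerosis, where the working hypothesis is that the resting-state
network drifts from a centralized, star-like organization toward a
decentralized, line-like one as disability grows.

The chain of analysis is:

1. **Preprocess**: common-average re-reference (a configurable set of frontal
   channels is excluded from the reference but still re-referenced), drop bad
   channels, cut the first `n` non-overlapping epochs, zero-phase band-pass
   filter into delta `[1,4)`, theta `[4,8)`, alpha `[8,13)` and beta
   `[13,30)` Hz.
2. **Connectivity**: the phase lag index (PLI) for every channel pair and
   epoch,
   \[ \mathrm{PLI} = \bigl| \langle \operatorname{sign}
      \sin(\Delta\phi(t)) \rangle_t \bigr| \in [0,1], \]
   where \(\Delta\phi\) is the instantaneous phase difference from the
   analytic signal. Because \(\operatorname{sign}\sin\) is zero at phase
   differences of exactly 0 or \(\pi\), PLI discards the zero-lag coupling
   that instantaneous volume conduction produces.
3. **Topology**: the minimum spanning tree (MST) of each epoch's PLI matrix
   with link weight \(1-\mathrm{PLI}\) (Kruskal's algorithm), summarised by
   leaf fraction \(L/N\), diameter (longest shortest path, in units of
   \(N-1\) links), degree divergence \(\kappa = \langle k^2\rangle/\langle
   k\rangle\), and tree hierarchy \(T_h = L/(2 M B_{\max})\) with
   \(M = N-1\) and \(B_{\max}\) the maximum betweenness centrality
   normalized by \((N-1)(N-2)/2\). MST dissimilarity against a reference
   tree — the MST of the control-average PLI matrix — is
   \(1 - |\text{shared edges}|/(N-1)\).
4. **Power control**: Welch relative band power, to check that topology
   differences are not secondary to power differences.
5. **Statistics**: two-sided Mann-Whitney group tests with
   Benjamini-Hochberg FDR across the four bands, pooled-SD Cohen's d, and
   patients-only Spearman correlations with disability, at subject level and
   at single-epoch level.

No public EEG dataset accompanies the study design this package implements,
so the package carries a first-class synthetic-cohort generator with known
ground truth; every pipeline stage is validated against it.

## The synthetic cohort generator

Each subject is a spanning tree of phase-coupled oscillators. The topology
comes from a one-parameter star-to-path family: `shift = 0` is a star
(hub = channel 1), `shift = 1` the path `1-2-...-n`, and intermediate shifts
re-chain the fraction `shift` of the star's leaves in index order — a
deterministic construction, so cohorts are bit-reproducible from their seed.
Controls sit at `shift = 0.1`; a patient with disability `d` (drawn
uniformly from 4-40) sits at `shift = 0.3 + 0.6 * d/48`, clipped to [0,1].
These three numbers are conventions, not fits: the study the design emulates
reports no usable effect-size anchor, so they were chosen once to give a
clearly detectable but not saturated effect, and are not tuned thereafter.

The signal model is a stochastic-frequency phase oscillator network:

* channel *i* carries `cos(theta_i(t))` with instantaneous frequency
  wandering (AR(1), stationary SD 5% of the carrier bandwidth) around a
  centre frequency drawn from the central half of the carrier band
  (default 16-24 Hz, i.e. mid-beta);
* along every tree edge the two phases are pulled diffusively toward an
  offset of `phase_lag`, with Kuramoto-style degree normalization so hubs
  are steered by the mean of their neighbours' demands;
* each phase also diffuses (`phase_noise_sd`, default 0.25 rad/sample), so
  locking is imperfect and the phase-offset jitter *accumulates with tree
  distance* — this is what gives the MST a gradient to recover: PLI is
  highest on true edges and decays away from them;
* white measurement noise (`noise_sd`) is added per channel, and an
  instantaneous mixing matrix with exponential falloff in channel-index
  distance (`exp(-|i-j|/spread)`) emulates volume conduction. The mixing is
  purely real and same-sample, so it can only create 0-or-\(\pi\) phase
  relations — exactly the regime PLI discards; tests verify that mixing
  independent sources never lifts PLI above its null.

**Why `phase_lag = pi/3`.** A constant per-edge lag accumulates along paths:
at tree distance *k* the expected offset is *k* times the lag. For a lag of
\(\pi/4\), distance-2 pairs sit at \(\pi/2\) — the point where PLI is
*maximal* — so second neighbours would systematically outscore true edges
and chain topologies would be unrecoverable by construction. Multiples of
\(\pi/3\) are always either a full \(\pi/3\) away from the blind points
\(\{0, \pi\}\) or exactly on them, so with jitter growing in distance the
true edges strictly dominate. \(\pi/3\) is therefore the default; any other
value away from 0 and \(\pi\) can be configured.

**What the generator does not emulate**: electrode geometry (the mixing is
index-based, not forward-modelled), eye-blink/muscle artifacts (epochs are
clean by construction, so the "first n epochs" selection rule is exact
rather than an artifact-avoidance heuristic), 1/f background spectra, and
any ALS electrophysiology beyond the topology-shift abstraction. Passing
tests on this generator therefore demonstrate that the *pipeline* recovers
known coupling topology and its group/covariate structure through
realistic narrowband, volume-conducted signals — they are not evidence
about clinical EEG itself.

## Numerical and procedural conventions

The study design this package follows leaves several choices unstated;
each is a documented, configurable default here, echoed into the JSON run
manifest so any run can be reproduced from its outputs alone.

* **Filter realization**: Butterworth band-pass of design order 4 applied
  forward-backward (`filtfilt`; zero phase, effective magnitude order 8),
  after epoch cutting. Odd-reflection padding suppresses edge transients;
  an optional `edge_discard` (default 0) additionally trims epoch edges
  before phase estimation. A tone at a band's geometric-mean frequency
  retains more than 95% amplitude; a tone an octave outside either edge
  keeps less than 10%.
* **Band edges** are half-open `[low, high)`, so the shared 4/8/13 Hz
  boundaries belong to exactly one band and the four relative powers sum
  to one.
* **PLI conventions**: `sign(0) = 0`, so identical channels (and exact
  zero-lag pairs) score exactly 0; PLI is computed per epoch, never on
  concatenated epochs; flat channels yield a warning and PLI 0 rather than
  an error, keeping cohort runs alive.
* **MST determinism**: Kruskal with candidate edges ordered by (weight,
  smaller index, larger index). PLI ties are rare but reproducibility of
  trees should not depend on them.
* **Diameter normalization**: link-count diameter divided by `N - 1`
  (a path scores 1); switchable to raw link counts. The normalized scale
  matches the magnitude of group differences the emulated study reports.
* **Hierarchy normalization**: \(B_{\max}\) uses betweenness divided by
  \((N-1)(N-2)/2\), which makes a star hub's betweenness exactly 1 and the
  star's hierarchy exactly 0.5 — the usual anchor for "optimal" trees.
* **Subject-level aggregation**: per-epoch trees are built first and their
  metrics averaged (epoch-level metrics demonstrably carry the signal, and
  averaging metrics preserves them); building one tree from the epoch-mean
  matrix is available as `aggregation = "mean_matrix"`.
* **Welch settings**: 512-sample (2 s) segments, 50% overlap, Hamming
  taper; relative-power denominator `[1, 30)` Hz, the union of the four
  analysed bands (switchable).
* **Mann-Whitney**: exact enumeration when the smaller group has at most 8
  observations and there are no ties, otherwise the normal approximation
  with continuity and tie corrections. Both U and the first group's rank
  sum are reported, since statistics packages disagree on which to print.
* **Cohen's d** uses the pooled SD with `n - 1` denominators. (The printed
  effect sizes in the emulated study's tables are not consistent with any
  standard d formula given their printed means and SDs; this package makes
  no attempt to reproduce them.)
* **FDR family**: the four frequency bands, per outcome; post-hoc MST
  metric tests within a band are reported uncorrected, mirroring the
  two-stage test-then-decompose design.
* **Correlations** use patients only (controls carry no ALSFRS-R score).
  Single-epoch correlations treat each epoch as a point; their p-values are
  computed at the inflated n and carry an explicit non-independence flag.

## Problem sizes used in validation

The packaged test-suite cohorts run at reduced scale so the full suite
completes in minutes: 12 channels at 128 Hz with four 256-sample epochs for
the 100-cohort effect-recovery study, and 8 channels with two 256-sample
epochs for the 200-cohort null-calibration study. The study-scale defaults
(61 channels at 256 Hz, four 2048-sample epochs, 21 patients vs 16
controls) are exercised in the tests by running one full-scale subject
through the connectivity stage, and are the defaults in the `analysis/`
scripts, which run the whole cohort at that scale. Structural checks are exhaustive rather than
sampled where feasible: all 16,807 labelled 7-node trees for the hierarchy
bounds, all 1,296 labelled 6-node trees as the MST oracle, all group
assignments for the exact Mann-Whitney path.

## A small worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_patients = 21, n_controls = 16,
                    n_channels = 12, fs = 128,
                    n_epochs = 4, epoch_length = 512, seed = 42)
cfg <- run_config(spec, n_epochs = 4, epoch_length = 512,
                  welch_segment = 256)
res <- run_pipeline(cfg)

subset(res$group_tests, outcome == "leaf_fraction" & band == "beta")
subset(res$correlations, outcome == "leaf_fraction" & band == "beta")
```

On this seed the beta-band leaf fraction separates the groups (patients
below controls, FDR-significant) and correlates negatively with disability
among patients, while delta/theta/alpha — where the generator places no
coupling — stay null. The `analysis/` scripts run the same workflow at full
study scale and write the result tables and figures under `results/`.

## Known limitations

* The generator's group effect is an abstraction (one topology family, one
  carrier band); it cannot calibrate absolute effect sizes against clinical
  data, only directions and detectability.
* PLI discards genuine zero-lag neurophysiological coupling along with
  volume conduction; this is inherent to the measure, not to the
  implementation.
* Single-epoch correlation p-values ignore within-subject dependence by
  design (flagged in the output); treat them as descriptive.
* Source reconstruction, artifact modelling, and longitudinal analysis are
  out of scope.
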