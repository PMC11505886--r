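---
title: "Microstate network dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate network dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microdyn` implements an analysis chain that links EEG microstates —
brief quasi-stable scalp potential topographies, conventionally labelled
A–D — to the dynamics of the functional brain networks active during
each of them: phase-locking connectivity, weighted graph topology,
synchronizability, network controllability, and pinning-control node
ranking. Because clinical task EEG of this kind is not freely
redistributable, the package ships a synthetic cohort generator with
full ground truth, and every stage of the chain is tested against that
ground truth or against independent brute-force oracles. This vignette
documents the models, the tunable parameters, and the places where the
design was genuinely open.

## The analysis chain

1. **Preprocessing.** Average reference; zero-phase windowed-sinc
   (Hamming) FIR band-pass 0.5–60 Hz with a 49–51 Hz notch; theta-band
   (4–7 Hz) extraction for the phase stage.
2. **Microstates.** Global field power (GFP) — the per-sample population
   standard deviation across electrodes; scalp maps at GFP local maxima
   are pooled across all subjects of both groups and clustered with a
   polarity-invariant modified k-means into four templates, matched to
   the canonical A–D axes; every sample is then backfitted to the
   template with the highest absolute spatial correlation; coverage,
   occurrence, mean duration and GFP contribution are computed per
   class from the label run-lengths.
3. **Phase-locking networks.** Channel-wise analytic-signal phases of
   the theta-band signal (FFT construction of the Hilbert transform);
   for each microstate class, the phase-locking value
   `PLV_ij = |mean_t exp(i(phi_i - phi_j))|` over that class's samples
   gives one weighted 60×60 network per subject per class.
4. **Network dynamics.** Weighted clustering coefficient (geometric-mean
   triangle intensity), characteristic path length and efficiencies on
   edge cost `1/w`, small-worldness against weight-shuffled surrogates,
   and the Laplacian eigenratio `M = lambda_2 / lambda_max` as the
   synchronizability index.
5. **Controllability.** Average controllability as the trace of the
   single-node controllability Gramian of the stabilized network;
   modal controllability from the eigen-decomposition of the
   spectrum-scaled network.
6. **Pinning control.** Diagonal feedback gains minimizing
   `lambda_max(A - K)` under a box constraint and an
   importance-weighted gain budget; nodes ranked by gain, the top 10
   pinned, and tiered at gains 1.24 and 1.4.
7. **Statistics.** Welch two-sample tests per class × metric between
   the groups; Pearson correlations between state-D temporal
   parameters and the state-D synchronizability index. No
   multiple-comparison correction is applied by default (matching the
   reference analysis convention); Benjamini–Hochberg per family is
   available via `pipeline_config(fdr = TRUE)` and its state is
   recorded in the report.

## The synthetic generator

`synth_config()` / `make_cohort()` emulate a two-group task-EEG study:

* **Geometry.** A deterministic sunflower-spiral layout on the unit
  disk stands in for a 10-10 montage, with named regions
  (frontal-left/right, central, parietal, occipital). Region-level
  claims ("frontal AC") are made against these named regions rather
  than a specific cap file, so any channel count ≥ 8 works.
* **Topographies.** Four unit-norm, average-referenced maps: two
  diagonal gradients (right-frontal→left-posterior and its mirror), a
  frontal→occipital gradient, and a focal frontal-medial
  difference-of-Gaussians. Pairwise |spatial correlation| stays below
  0.7; a small seeded smooth perturbation keeps the maps generic.
* **Switching.** A 4-state Markov chain; dwell times are geometric with
  the mean set through the self-transition probability
  (`1 - 1/(dwell_ms * fs/1000)`, default 80 ms — in the usual range of
  microstate durations). No empirical transition statistics were
  available to calibrate against, so the chain is uniform off the
  diagonal by default.
* **Signal.** At each sample the scalp map is the active template times
  a theta oscillation (5.5 Hz carrier). Each channel carries a phase
  offset given by an Ornstein–Uhlenbeck process whose amplitude is
  shrunk toward zero by the channel's per-state coupling strength in
  [0, 1]; coupled channels phase-lock, uncoupled channels wander apart.
  White Gaussian noise is added at `snr = 5` (RMS clean signal over
  noise SD). There is no 1/f background — the theta band-pass removes
  spectral shape downstream — and no forward head model, artifacts, or
  volume conduction.
* **Group effects.** The case ("SZ-like") group scales transitions into
  state D by 0.7 (the deficit returns to the self-transition, so other
  states' dwell structure is untouched) and frontal coupling by 0.7.
  These two planted effects propagate to exactly the quantities the
  analysis is supposed to pick up: lower D occurrence/coverage, weaker
  frontal theta locking, hence lower frontal average controllability of
  the state-D network, and — because weakening the strongly coupled
  frontal block makes the weighted network more homogeneous — a
  *higher* Laplacian eigenratio in the case group.

### Calibration of the phase-offset process

Two constraints pin down the offset process. First, the wander must be
slower than the theta filter's impulse response (~1 s for a 1 Hz
transition width): faster jitter is simply filtered out and all
channels collapse onto the common carrier, erasing the planted coupling
contrast. The correlation time is therefore 0.5 s (`phase_jitter_tau =
250` samples). Second, the offset amplitude trades template fidelity
(instantaneous maps are distorted by `cos(phi + delta_c)`) against PLV
contrast. At `phase_jitter_sd = 1.5` rad the pooled-peak clustering
still recovers the planted maps at |r| > 0.95 while coupled/uncoupled
PLV separate cleanly. The quantitative PLV-recovery checks use a
dedicated construct — a single-state recording with state-independent
coupling at 1.0 versus 0.0 and `phase_jitter_sd = 2.5` — because with
state-dependent coupling, spectral leakage across state boundaries
(intrinsic to narrowband filtering of a switching source) blurs the
within-state coupling pattern.

### What passing tests do and do not show

The generator produces stationary oscillatory sources with exact
ground truth; real EEG adds 1/f background, artifacts, volume
conduction (the reference workflow removes it with a surface-Laplacian
transform, out of scope here; `artifact_hook()` marks where ICA/CSD
would sit), inter-subject topography variability, and microstate
syntax beyond a first-order chain. Recovery and calibration results on
synthetic cohorts therefore validate the *estimators and their
wiring*, not the clinical claims.

## Numerical and design choices

* **Segmentation runs on the broadband signal; phases on theta.** A
  4–7 Hz filter has an impulse response far longer than a microstate
  (~80 ms), so backfitting theta-filtered data destroys the label
  sequence. Microstate practice fits maps on the wide band; the
  narrowband step exists for the analytic-signal phase, whose
  narrowband assumption it guarantees.
* **FIR design.** Windowed-sinc, Hamming, order `ceiling(3.3 fs /
  transition)` (transition 1 Hz; ~1650 taps at 500 Hz), applied
  forward–backward with reflect padding of one filter length: zero
  phase, squared magnitude response, so microstate timing is never
  shifted. Samples within half a filter length of each edge (the group
  delay) are excluded from phase analyses via the validity mask, as are
  samples with analytic amplitude below 1e-12 (undefined phase).
* **GFP peaks.** A peak is strictly greater than its predecessor and at
  least its successor (plateaus resolve to their first sample;
  constant series have none); peaks closer than 10 ms are thinned
  keeping the larger. Peak maps are GFP-normalized before clustering so
  the correlation distance is scale-free.
* **Clustering.** Assignment maximizes squared spatial correlation
  (polarity-free); centroids are the leading eigenvector of the
  assigned maps' channel covariance; the objective (explained variance
  weighted by squared GFP) is monotone over iterations; 50 restarts by
  default (20 inside the pipeline), seeded. A–D labels come from an
  exhaustive optimal assignment against the generator's planted maps;
  for real data a published canonical map set would be needed (out of
  scope).
* **Backfitting.** Every sample is labelled independently (the least
  interpretive choice); optional minimum-duration smoothing (runs
  shorter than a threshold merge into the better-fitting neighbour) is
  available but off by default. Zero-variance samples get the first
  class with fit 0.
* **PLV networks.** Phases are computed once on the continuous filtered
  signal and then restricted to each class's samples — concatenating
  segments would create phase discontinuities. A class network needs at
  least 100 samples (`min_len`); below that, PLV's positive bias
  (~`sqrt(pi/(4 Len))`) makes it unreliable and the network is excluded
  from group statistics. The 0.55 display threshold applies to figures
  only; all analyses use the full weighted matrix.
* **Graph metrics.** Edge cost `1/w` (the standard map for similarity
  weights in [0, 1]); Onnela geometric-mean triangle clustering
  (bounded, deterministic); local efficiency as the neighbourhood
  subgraph's global efficiency; `Lp` over finite pairs with a
  disconnected flag; small-worldness against surrogates that keep the
  edge set and shuffle the weights (for a dense PLV graph, degree is
  trivially preserved and the weight distribution is the natural null),
  100 surrogates by default, seeded.
* **Controllability.** The continuous-time Gramian integral diverges
  for a matrix with positive leading eigenvalue, so the network is
  first mapped to `A/(1 + lambda_max) - I` (Hurwitz by construction;
  recorded in the output). The per-node Gramian traces then follow in
  closed form from one eigen-decomposition, and are verified against
  quadrature of the defining integral. For modal controllability the
  spectrum is scaled into (-1, 1) by `1/(1 + max|lambda|)` so
  `1 - lambda_j^2` stays nonnegative.
* **Pinning.** The program — minimize `lambda_max(A - diag(k))` with
  `0 <= k_i <= cs` and `cs - eps <= sum d_i^2 k_i <= cs + eps`,
  `d_i = p_i^a q_i^b` — is convex; it is solved by exponential
  smoothing of the largest eigenvalue (soft-max continuation over
  decreasing temperatures) with L-BFGS-B and an exact final projection
  onto the constraint set, and validated against exhaustive grid search
  on small networks. Importance defaults: `p` = node strength, `q` =
  1 + weighted betweenness (regularized because betweenness is exactly
  zero for many nodes of a dense graph and `q^(-1/2)` would be
  undefined), `a = b = -1/2` — so low-importance nodes receive large
  `d_i` and the budget penalizes spending gain on them. Control
  strength `cs = 2` keeps the gain scale able to express the 1.24/1.4
  tier thresholds; a gain of exactly 1.4 falls in the second tier.
  Ranking ties break by channel index. Gains are computed on the
  group-average network of each class, not per subject.
* **Statistics.** Welch (unequal variance) is the default two-sample
  test, with Student's form behind a flag; Cohen's d on the pooled SD.
  Constant-sample degeneracies resolve to `t = 0, p = 1` (equal means)
  or `p = 0` (unequal).
* **Seeding.** One master seed (`synth_config(seed = )`) drives
  everything: per-subject seeds are drawn from it by one
  `sample.int()` call, and clustering restarts and surrogate shuffles
  take it directly, so a config reproduces its report exactly. The
  generator saves and restores the caller's RNG state.

## Problem sizes

The shipped analysis and the acceptance checks run the study design at
35 subjects per group, 60 channels, 500 Hz, 12 s per recording —
enough for every microstate class to clear the 100-sample PLV floor
(typical class sample counts are near 1000) and for the planted 0.7
multipliers to be detected with margin. Statistical calibration under
the null uses 20 replicate cohorts of 10 subjects per group at 19
channels and 10 s, where each replicate still yields stable per-class
networks. Oracle-equivalence checks run on graphs of up to 8 nodes
(exhaustive enumeration) and 4 nodes (grid search over gain vectors).

## Known limitations

* The Markov chain is first-order; empirical microstate syntax
  (transition asymmetries, long-range dependence) is not modelled.
* Narrowband spectral leakage mixes adjacent states' phase structure
  into each class's network; state-specific coupling is therefore
  recovered qualitatively in the cohort analysis and quantitatively
  only in the single-state construct.
* The broadband filter's notch ringing slightly blurs state
  boundaries: backfit accuracy is ~0.94 on the average-referenced
  signal and ~0.88–0.91 after the full filter chain at `snr = 5`.
* Small-worldness for a complete weighted graph depends entirely on
  the weight-shuffle null; sparser graphs would need a degree-aware
  rewiring null.
* Microstate counts other than four, TAAHC clustering, and other
  connectivity estimators (wPLI, coherence) are out of scope.
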