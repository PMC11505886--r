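# microdyn

EEG microstate brain-network dynamics: segmentation, phase-locking
networks, graph topology, synchronizability, controllability, and
pinning-control node ranking — with a ground-truthed synthetic cohort
generator so the whole chain is testable end to end.

## The problem

Scalp EEG alternates between a handful of quasi-stable potential
topographies ("microstates", canonically A–D) lasting tens of
milliseconds. Task studies of schizophrenia repeatedly find microstate
D — linked to the fronto-parietal attention network — reduced in
patients. What such temporal statistics cannot say by themselves is
*which network dynamics live under each microstate*: how strongly the
channels phase-lock while a state is active, how synchronizable the
resulting network is, and which nodes have the leverage to steer its
state transitions. `microdyn` implements that full analysis for
researchers in network neuroscience and computational psychiatry:

* **Microstates.** Global field power `GFP(t) = sqrt(mean_i (V_i(t) -
  V_mean(t))^2)`; scalp maps at GFP peaks pooled over all subjects,
  clustered by polarity-invariant modified k-means into 4 templates;
  per-sample backfitting by maximal `|corr|`; coverage, occurrence,
  duration, GFP contribution per class.
* **Connectivity.** Theta-band (4–7 Hz) analytic-signal phases;
  per-microstate phase-locking value `PLV_ij = |1/Len * sum_t
  exp(i(phi_i(t) - phi_j(t)))|` over that state's samples: one weighted
  network per subject per class.
* **Topology.** Weighted clustering coefficient Cp, characteristic path
  length Lp, global/local efficiency Eg/Eloc (edge cost `1/w`),
  small-worldness Sw against weight-shuffled surrogates.
* **Synchronizability.** The Laplacian eigenratio `M = lambda_2(L) /
  lambda_max(L)`, `L = D - A`.
* **Controllability.** Average controllability per node k as
  `trace(W_k)`, `W_k = int_0^inf e^{At} B_k B_k' e^{A't} dt` of the
  stabilized network; modal controllability `phi_i = sum_j (1 -
  lambda_j^2) v_ij^2`.
* **Pinning control.** Diagonal feedback gains `K = diag(k)` minimizing
  `lambda_max(A - K)` under `0 <= k_i <= cs` and the importance-weighted
  budget `cs - eps <= sum_i d_i^2 k_i <= cs + eps`, `d_i = p_i^a q_i^b`;
  nodes ranked by gain, top 10 pinned, tiered at 1.24 / 1.4.
* **Statistics.** Welch tests per class × metric between an HC-like and
  an SZ-like group; Pearson correlations between state-D parameters and
  state-D synchronizability.

The study data this kind of analysis targets are not openly
redistributable, so the package's `synth_config()` / `make_cohort()`
generate Markov-switching multichannel theta-band EEG with planted
topographies, coupling structure, and group effects (state-D occurrence
× 0.7, frontal coupling × 0.7 in the case group) — every downstream
estimate can be checked against known truth. See the methods vignette
(`vignettes/microstate-network-dynamics.Rmd`) for models, parameters
and design decisions.

## Worked example

```r
library(microdyn)

cfg <- pipeline_config(synth = synth_config(n_subjects_per_group = 8,
                                            seed = 42),
                       sw_n_rand = 20, pinning = NULL)
rep <- run_pipeline(cfg)

round(rep$templates$canonical_corr, 3)
#> [1] 0.962 0.957 0.980 0.989

gt <- rep$group_tests
gt[gt$class == "D" & gt$metric %in% c("occurrence", "frontal_ac", "sync_M"),
   c("metric", "mean_x", "mean_y", "t", "p")]
#>      metric    mean_x    mean_y         t          p
#>  occurrence 8.8645833 8.3645833  1.163292 0.26659827
#>      sync_M 0.3033722 0.3323413 -1.299995 0.22117580
#>  frontal_ac 0.7400799 0.7053358  2.141355 0.05114912
```

The four fitted templates match the generator's planted A–D maps at
|r| ≥ 0.957. Even at 8 subjects per group the planted effects point the
right way: the SZ-like group has lower state-D occurrence and frontal
average controllability and a higher state-D eigenratio; at the study
scale (35 per group, `analysis/` scripts) they are all strongly
significant — occurrence 9.16 vs 7.99 (t = +5.6), frontal AC 0.742 vs
0.715 (t = +3.5), eigenratio 0.281 vs 0.320 (t = −3.8), and state-D
occurrence correlates negatively with synchronizability (r = −0.34,
n = 70).

## The analysis workflow

Numbered drivers under `analysis/` reproduce the shipped study end to
end; each step prints what it found and writes tidy tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + ground-truth summary
Rscript analysis/02_run_pipeline.R       # full pipeline -> results/pipeline/
Rscript analysis/03_microstate_stats.R   # temporal-parameter contrasts
Rscript analysis/04_network_dynamics.R   # topology, synchronizability
Rscript analysis/05_control_pinning.R    # controllability, pinned nodes
```

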