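# thetareplay

Analysis pipeline for paired CA1 / deep-medial-entorhinal-cortex (dMEC)
extracellular recordings during spatial learning, asking one question: are
the dMEC cells whose spike trains are modulated at theta frequencies
(5–12 Hz) during running the same cells that later coordinate with
hippocampal replay during rest?

The package implements, as tested reusable functions:

* **Theta analysis** — spike-train theta-modulation score (theta-band vs
  20–125 Hz broadband amplitude-envelope ratio of the smoothed
  autocorrelogram) with a 100-permutation spike-time null at the 97.5th
  (or 99th) percentile; CA1 theta-channel selection by theta/delta power;
  per-spike theta phases and Rayleigh phase locking.
* **Behaviour** — linearization of the Z-track (two 190 cm arms + 220 cm
  diagonal → 600 cm, 2 cm bins), directional ratemaps (Gaussian sigma =
  5 bins, speed and zone exclusions), place-cell criteria (≥ 20 contiguous
  supra-mean bins, peak > 1 Hz), Skaggs information, field sizes, dMEC–CA1
  field overlap, task performance.
* **dMEC functional classification** — gridness with a ≥ 30 s
  circular-shift null, head-direction tuning via KL divergence of the
  polar ratemap (> 0.10), border score (> 0.5), other-spatial cells by
  Skaggs information (> 1 bit/spike).
* **Replay** — candidate-event detection from CA1 multi-unit activity
  (1 ms bins, 20 ms smoothing, mean + 3 SD threshold, 40 ms / participation
  filters), Bayesian position decoding in 10 ms bins, and the exhaustive
  straight-line trajectory fit

  R(V, c) = (1/n) Σ_t P(|x(t) − (V·t·T + c)| ≤ d),  d = 30 cm,

  over V ∈ [−50, 50] m/s (0.5 m/s steps, excluding (−2, 2)) and
  c ∈ [−15, 21] m (0.01 m steps), with a field-rotation significance test
  (p < 0.025 per direction).  The compiled search is verified exactly
  against a naive double-loop reference.
* **Coordination** — normalized dMEC participation in candidate events
  (event-time shuffle), dMEC–CA1 replay coherence (the dMEC posterior
  scored along the CA1 best-fit line), cell-identity / field-rotation /
  spike-time shuffle nulls, bootstrapped CDF-AUC statistics (N = 10 000),
  PSTH and ±80 ms time-shift lag analysis, theta-score quartiles, learning
  periods, preplay control.
* **Synthetic sessions** — a generator that plants all of the above
  (place fields, theta-locked spiking and 8 Hz LFP, grid / head-direction /
  border / other-spatial open-field tuning, time-compressed replay events
  with a configurable dMEC lag) with complete ground truth, so every stage
  is validated by parameter recovery.

## Worked example

```r
library(thetareplay)

pr <- run_full_pipeline(seed = 11, n_boot = 10000, max_events = 100)
print(pr)
#> <pipeline_run> seed 11: 40 place cells, 7/16 theta-modulated dMEC, 100 candidate / 91 replay events
#>   theta AUC diff 5.867 (p = 0), non-theta 0.186 (p = 0.2027)
```

Reading the numbers: half the simulated dMEC cells were planted
theta-locked; the permutation test recovered 7 of those 8 (and none of the
others).  Of 100 detected multi-unit events, 91 carried a significant
decoded trajectory.  The theta-modulated stratum's coherence distribution
sits well to the right of its cell-identity shuffle (positive AUC
difference, bootstrap p below 1/10000), while the non-modulated stratum is
indistinguishable from its shuffle — the planted coordination structure,
recovered end to end.  The same run yields the planted +10 ms dMEC lag in
the time-shift curve (`pr$time_shift$best_shift_s` = −0.01: shifting dMEC
spikes back by 10 ms re-aligns them; the PSTH excess-rate centroid sits at
+7.9 ms) and chance-level participation for both strata in the pre-task
rest (`pr$summary$preplay_*_participation` = 1.03 and 0.96).

Lower-level entry points: `theta_modulation_test()`, `spike_phases()`,
`compute_ratemaps()`, `classify_dmec()`, `detect_candidate_events()`,
`bayesian_posterior()`, `fit_trajectory_line()`, `event_significance()`,
`normalized_participation()`, `coherence_score()`, `coherence_null()`,
`auc_compare()`, `stratified_analyses()`.  Sessions round-trip through
`save_session()` / `load_session()` as plain TSV + YAML.  See
`vignettes/methods.Rmd` for the full model description and design
rationale.

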