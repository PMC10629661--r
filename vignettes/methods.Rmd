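---
title: "Methods: theta-modulated entorhinal coordination with hippocampal replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-modulated entorhinal coordination with hippocampal replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the analysis it implements:
the models and procedures, the tunable constants and their defaults, what
the synthetic-session generator does and does not emulate, and the numerical
choices made where the underlying methods left the design open.  It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scientific question

During rest, hippocampal CA1 place cells re-express ("replay")
time-compressed spatial trajectories inside brief multi-unit bursts.  Cells
in the deep layers of the medial entorhinal cortex (dMEC) — the hippocampus'
main cortical output — may or may not take part in these replay
trajectories.  The pipeline asks whether the dMEC cells that lock to the
5–12 Hz hippocampal theta rhythm during running are the ones that later
coordinate with CA1 replay: it scores spike-train theta rhythmicity, splits
the dMEC population into theta-modulated and non-modulated strata, detects
and decodes CA1 replay events, and measures each stratum's participation in
and spatial coherence with the decoded trajectories, against three families
of shuffle nulls.

## Pipeline stages

### Linearized directional ratemaps

The Z-track (two 190 cm arms joined by a 220 cm diagonal) is linearized to
600 cm and binned at 2 cm (300 bins).  The final 10 cm at either end and
5 cm around each corner are excluded, as are samples slower than 3 cm/s.
Dwell and spikes are binned per run direction and smoothed with a Gaussian
kernel (sigma = 5 bins) *before* division; the rate is the ratio of the
smoothed maps.  The methods we follow do not state whether counts and dwell
are smoothed separately or the raw ratio is smoothed; separate smoothing is
the field's standard and is what `compute_ratemaps()` does.  The kernel is
truncated at three sigma and renormalized at the edges so track ends are not
deflated.  Place cells are cells with at least 20 contiguous supra-mean bins
and a peak above 1 Hz; putative interneurons are excluded on rate alone
(CA1 above 5 Hz on track — a package decision, since spike waveforms are not
part of the data model; dMEC above the 7 Hz cap that the theta analysis
already imposes).

### Theta modulation score and permutation test

For each dMEC cell the spike-train autocorrelogram (1 ms bins) is smoothed
with a 20 ms Gaussian, band-passed at 5–12 Hz (theta) and 20–125 Hz
(broadband) with linear-phase FIR filters (Hamming window, three cycles of
the low band edge, applied as centered convolution — exactly zero-phase),
and each band's amplitude envelope taken from the analytic signal.  The
score is the ratio of mean theta to mean broadband envelope within the
±1 s lag window.  Numerical choices:

* the zero-lag bin is replaced by the mean of its ±5 ms neighbours, so the
  self-count delta cannot dominate the broadband envelope;
* the analytic signal is computed on a 2048-sample (±1.024 s) segment of
  the filtered autocorrelogram centered on zero lag.  Because every kernel
  involved has finite support (121-tap smoother, ≤601-tap filters), lags
  beyond ±2.4 s cannot influence the score, so the autocorrelogram is only
  materialized over that range — an exact optimization that makes the
  100-permutation null affordable;
* the null redraws the same number of spike times uniformly within the
  epoch window (a full permutation, not a jitter) and recomputes the score;
  a cell is theta-modulated when its score reaches the 97.5th percentile of
  its own null (99th as the stringent variant).  With a 100-sample null the
  percentile is estimated discretely, so the expected null flag rate is
  slightly above 2.5%; the calibration test bands account for this.

### Theta phase locking

The CA1 LFP channel with the largest theta (5–12 Hz) to delta (2–4 Hz)
Welch-power ratio is filtered in the theta band (same FIR design),
Hilbert-transformed, and each spike (at running speed above 3 cm/s) is
assigned the interpolated instantaneous phase.  Locking is quantified by
the Rayleigh test; following the convention that "a lower value means
stronger locking", group summaries average the Rayleigh *p* value (the raw
resultant length is also stored).  The *p* approximation is Zar's
small-sample formula, which the tests compare against the exp(−n R̄²)
closed form.

### Candidate events, decoding and the trajectory line fit

Pooled CA1 place-cell spikes are binned at 1 ms, smoothed with a 20 ms
Gaussian; periods above mean + 3 SD (statistics taken from the rest epoch)
are candidate events, with boundaries where the signal returns to the mean.
Events shorter than 40 ms or with fewer than max(15% of the population, 5)
active cells are rejected; awake events additionally require mean speed
below 1 cm/s (3 cm/s alternate).

Each event is decoded per 10 ms bin under an independent-Poisson model with
uniform prior, giving a 300 × n posterior per run direction; rates are
floored at 0.01 Hz so no position has zero likelihood, and a trailing
partial bin is dropped.  The trajectory score of a line x = V·t·T + c is
the mean per-bin posterior mass within d = 30 cm of the line, maximized
exhaustively over V ∈ [−50, 50] m/s in 0.5 m/s steps (excluding (−2, 2))
and c ∈ [−15, 21] m in 0.01 m steps.  Implementation notes:

* all corridor predicates are evaluated in integer units of 5 mm, of which
  every grid involved is an exact multiple, so boundary ties are exact and
  the compiled search (`method = "fast"`, a sparse difference-array
  accumulation over intercepts) agrees *exactly* with the direct
  double-loop reference (`method = "naive"`) kept in the package;
* ties resolve to the first cell in scan order (ascending V, then c);
* significance comes from 100 independent circular rotations of each
  ratemap (1 to 299 bins, wrap-around), refitting each; an event is a
  replay trajectory at p < 0.025 per direction (halving 0.05 for the two
  directions).  When both directions are significant the direction with
  the larger R is taken as the event's direction; both are stored.

A property of this null worth knowing: the rotation distribution's
variance includes *between-map-set* variability (each shuffle draws a new
rotated set), while an observed event's score is conditioned on the one
true set.  When an event carries many spikes the posterior is almost
deterministic given the maps, the conditional variance shrinks, and the
observed score can no longer reach the null mixture's extreme tail — the
test becomes conservative.  For realistically sparse events (a handful of
active cells) spike-level noise dominates and the null p value is uniform;
the calibration tests use scrambles at realistic per-cell counts for this
reason.

**Identifiability of (V, c).**  A line of slope V ± ΔV through the same
ridge deviates by only ΔV·T·(n−1)/2 at the event edges; with d = 30 cm this
means every V within roughly ±0.6/(T·(n−1)) m/s of the truth captures the
ridge equally.  For 40–200 ms events that plateau spans more than ±1 m/s,
so V is fundamentally not recoverable to the 0.5 m/s grid there — a
property of the corridor objective, not of the search.  The package's
line-fit validation therefore plants long events (350–500 ms, strong event
spiking) where the plateau narrows and the diffuse posterior mass breaks
the near-ties toward the centered line; recovery there is the test of the
search's correctness.  The intercept is compared against c* + V*·T/2
because the line indexes bins at their start while a bin's spikes center
half a bin later.

### Cross-regional coordination

*Participation.*  Per dMEC cell, the proportion of candidate events with at
least one spike, normalized by the mean of 100 event-time shuffles (each
event shifted by an independent uniform offset within the epoch,
wrapping — the maximally uninformative placement null; the shuffle offset
range is not specified by the source methods, this is the package's
choice).  A value of 1 is chance; a cell is significantly modulated when
its observed value leaves its own shuffle 95% interval.  A spikes-per-event
variant is available (`measure = "rate"`).

*Coherence.*  For each significant CA1 replay event the dMEC posterior is
decoded from the stratum's spikes alone and scored along the *CA1* best-fit
line (same corridor, same integer predicate — so the coherence of the CA1
posterior with its own fit equals the fit's R exactly).  Three nulls:
cell-identity permutation of the ratemaps (needs ≥ 2 cells), independent
field rotations by 10 to 290 bins, and per-cell spike-time rotations within
the event by 5 ms to duration − 5 ms.

*AUC statistic.*  Data and shuffle coherence distributions are compared by
the area under the empirical CDF on a fixed 101-point grid spanning [0, 1].
Higher scores push the CDF right and so *lower* its AUC; the package
reports (shuffle AUC − data AUC) so that more-coherent data is positive.
The data distribution is bootstrapped 10 000 times against the fixed
shuffle AUC; p is the fraction of differences at or below zero.  Strata are
compared by differencing their normalized bootstrap AUC distributions, with
Bonferroni correction across pairs (learning periods, quartiles).

*Timing.*  A PSTH of stratum activity around event midpoints uses 5 ms bins
over ±0.5 s with the baseline taken from the outer ±(0.25–0.5) s flanks
(bin width and baseline window are package choices; the source methods do
not state them).  Because event-locked responses are plateaus, the lag
estimate is the excess-rate centroid within ±100 ms rather than a bare
argmax.  The time-shift analysis recomputes mean coherence after shifting
dMEC spikes by −80…+80 ms in 10 ms steps, over events of at least 80 ms; a
coordination lagging CA1 by L ms peaks at shift −L.

## The synthetic-session generator

`assemble_session()` builds PRE_REST, RUN, REST and OPEN_FIELD epochs with
full ground truth.  What it emulates: Gaussian place fields on the
linearized Z-track (40 CA1 cells, sigma 15 cm, 15 Hz peaks, tiled with
jitter for near-uniform population coverage); dMEC track tuning (periodic
fields for grid cells, one to three fields otherwise), normalized per cell
so the mean track rate matches the observed dMEC range (~1.25 Hz, well
under the 7 Hz inclusion cap); theta-locked spiking as
inhomogeneous Poisson with rate tuning × (1 + m·cos(phase − phase_pref)),
phase-aligned with the generated 8 Hz LFP (theta sinusoid plus pink noise,
two CA1 channels with different theta/delta ratios); laps at 15–35 cm/s
with pauses at ends and corners; rest-period baseline spiking with planted
time-compressed trajectory events (rate 0.25/s, durations 40–200 ms,
speeds ±{3, 5, 8} m/s, intercepts drawn so the trajectory stays on the
track); and open-field foraging (Ornstein-Uhlenbeck walk in a 1 m arena)
with grid fields built from three thresholded cosine plane waves,
von Mises head-direction tuning, exponential border fields and Gaussian
blobs.  Spiking uses exact per-interval Poisson sampling of the
piecewise-constant intensity (equivalent to thinning without rejections).

Coordination structure: under the default `dmec_coordination =
"coordinated"`, theta-locked dMEC cells replay the planted trajectory
through their own tuning with spikes shifted +10 ms; non-locked cells
receive a trajectory-agnostic elevation at half the coordinated drive, so
their participation ends above chance but below the coordinated group (the
ordering observed in vivo), while their coherence stays at chance.  In
PRE_REST the bursts carry no trajectory and dMEC stays at baseline, which
is the preplay null.  Replay event rates, trajectory speeds and per-event
spike counts are not constrained by reported measurements; those defaults
are free parameters chosen at standard rodent-replay values, not claims
about any particular dataset.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: ripple-band LFP structure, CA3→CA1 dynamics, theta
phase precession, behaviour-dependent rate remapping, cluster-cutting
artefacts, and non-Poisson spike-train statistics (bursting,
refractoriness).  Recovery results certify the estimators, not the
biology.

## Open design points, resolved

* **Gridness variant** ("standard" family): annulus from just outside the
  central peak (first radius whose ring minimum is negative) to half the
  autocorrelogram extent in 1-bin steps; score = min(corr at 60°, 120°) −
  max(corr at 30°, 90°, 150°), maximized over outer radii; null from ≥30 s
  circular spike-time shifts, grid iff ≥ 95th percentile.
* **KL directionality** uses the natural log (the 0.10 threshold is a
  nat-scale convention); applied to non-grid cells as the head-direction
  criterion too, which the source states only for grid cells.
* **Classification precedence**: grid/conjunctive > border >
  head-direction > other-spatial (Skaggs > 1 bit/spike) > unclassified;
  the source lists the types but no precedence.
* **Border score** weights the wall-distance term by firing rate (as in
  the score's original definition) and normalizes by half the arena width.
* **Epoch conventions**: time in seconds from session start, half-open
  intervals; positions in cm, the line fit in meters to match the printed
  search grids exactly.
* **LFP interchange** is one plain-text table per channel; everything a
  session contains round-trips through `save_session()`/`load_session()`
  byte-stably.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed, and the pipeline derives
per-stage seeds from one master seed, so identical (config, seed) reproduce
every output bit-exactly.  The validation suite runs at desk scale chosen
to keep estimator noise well below the tested effects: 600 s RUN/REST
epochs with ~130 planted events for the headline pattern; 50 long events
for line-fit recovery; 400 null cells and 200 scrambled events (100-sample
nulls each) for calibration; 100 open-field cells (20 per class, 20 min)
for classification recovery; 500 cells for the Rayleigh null.  These sizes
are the package's validation design; `scripts/acceptance.R` re-runs the
same computations from scratch and writes the resulting numbers as JSON.

## Known limitations

The interneuron rule is rate-only; waveform widths are out of scope.  The
linear mixed-effects replication of the source analyses (animal as random
effect) is intentionally out of scope — the bootstrap machinery carries the
inferential weight here.  Track-based functional classification is a
fallback, not the default.  The deposited-data adapter (the recording
system's native formats) is future work; the interchange format is the
package's own.
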