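---
title: "Models and methods behind persistlick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind persistlick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

persistlick studies how persistent licking — the continuous repetition of a
lick cycle at more than 6 Hz sustained for at least 5 s — is initiated and
terminated, and how prefrontal motor-projecting (MP) neuron populations
relate to it.  The package has two halves: analysis tools for lick rasters
and spike trains (bias statistics, firing-rate estimation, shuffle-based
unit classification, population decoding, connectivity screening), and a
spiking-network model whose output spikes are converted into lick events by
a nine-phase decision rule.  Everything runs on synthetic sessions produced
by the package's own generator, so every analysis stage is testable without
recorded data.  This vignette documents the models, the parameter choices
that matter, and the limits of what the synthetic tests demonstrate.

## Lick-raster statistics

The initiation and termination of *continuous* (rather than discrete)
licking are scored from a simple moving average (SMA) of lick counts: lick
events are counted in 200 ms bins and averaged over the `n = 5` most recent
bins, so steady 6 Hz licking gives SMA = 1.2 exactly.  The initiation bias
is `1/idx`, where `idx` indexes the first SMA sample above 1.2 (6 Hz) after
the delivery onset (DO); samples up to and including the last zero-valued
SMA sample are ignored, so `idx` counts only the samples of the final
non-zero stretch.  If the SMA stays at zero for the whole 6 s horizon, or
never crosses the threshold, the bias is zero.  The termination bias is the
mirror image: `1/idx` at the first SMA below 1 (5 Hz) after the stop anchor,
zero if the SMA never drops.

Two details of the scan are under-determined by the verbal definition and
are fixed here as documented defaults:

* **Warm-up windows.** The first four samples after DO have fewer than five
  bins available.  By default they are averaged over the bins that exist
  (`warmup = "partial"`), which makes immediate 7 Hz licking yield
  `idx = 1` and bias 1; `warmup = "strict"` discards them instead.
* **Window memory.** Initiation windows start at DO (trials with more than
  0.5 Hz of licking in the 3 s before DO can be excluded with
  `exclude_pre_DO = TRUE`, the trial filter used with optogenetic
  silencing).  Termination windows keep pre-anchor memory, because licking
  is ongoing at the stop anchor and the moving average should drain over
  five samples rather than restart.

Both biases are invariant under a uniform time shift of all events, and the
initiation bias is monotone non-increasing in the latency between DO and
the first supra-threshold sample — both properties are exercised in the test
suite.

Locomotor speed follows the rotary-encoder formula
`circumf / (CPR * dt)` with 360 cycles per revolution, and facial activity
is `1 - r` with `r` the Pearson correlation of temporally adjacent
histogram-of-oriented-gradients (HOG) feature vectors (reference HOG
parameterization: 8 orientations, 32 pixels per cell, 1 cell per block).
Frames are supplied as precomputed feature vectors; image-to-HOG conversion
is out of scope.

## Firing-rate estimation

Firing rates come from a Bayesian adaptive kernel smoother: a Gaussian
kernel whose bandwidth adapts per time point,

$$h(t) = \frac{\Gamma(\alpha)}{\Gamma(\alpha+1/2)}
  \frac{\sum_i ((t-t_i)^2/2 + 1/\beta)^{-\alpha}}
       {\sum_i ((t-t_i)^2/2 + 1/\beta)^{-(\alpha+1/2)}},$$

with $\alpha = 4$ and $\beta = n^{4/5}$ ($n$ = spike count).  The
"bandwidth" of an analysis scale (5 ms for the 180 ms peri-lick window,
200 ms for multi-second windows) is interpreted as a lower floor on $h(t)$.
Two properties anchor the implementation: the time integral of the rate
reproduces the spike count within 5% (each kernel integrates to one), and on
stationary Poisson trains the adaptive estimate agrees with a
fixed-bandwidth kernel estimate within 15% RMSE.  Peri-event trial matrices
are estimated per trial from the spikes of that trial's window (padded by
the bandwidth), with $\beta$ taken from the window's own spike count; this
local convention keeps within-window estimates smooth, which is what the
classifier's distribution comparisons assume.  Whole-train smoothing remains
available (`local = FALSE`).

## Unit classification

Valence classification compares the firing rate in the peri-lick window
(LO−100 ms to LO+80 ms, 5 ms bins) of the first four water and first four
quinine lick trials against a pseudo-trial matrix built from the 10 s
baseline: pseudo lick onsets with the real inter-lick intervals are placed
at random in the baseline, the per-bin values are concatenated, shuffled,
and averaged over 1000 repeats.  Distributions of adjacent-bin Euclidean
norms are separated with
$z_{12} = (\mu_1-\mu_2)/\sqrt{\sigma_1^2+\sigma_2^2}$ at threshold 1.29;
rate-peak times are compared per trial with a two-sample t-test (p < 0.05,
the 1.64 criterion); temporal structure is tested by comparing the Frobenius
norm of mean-centred column means against 1000 element-permuted copies (95th
percentile).  The label conjunctions follow the reference table, with two
documented readings: "not greater" means *not significantly greater*
(z ≤ 1.29), and a unit satisfying both the lick and a valence conjunction is
labelled `lick` (listed first).  Because the classification is made on
single trials, the labels are per-session descriptors, not functional cell
types.

Phase classification evaluates the long-window rate (200 ms bandwidth) at
five time points (0.5 s spacing) in 2 s windows around the first water lick
onset and the quinine delivery onset, against 1000 pseudo windows drawn
uniformly from the full (>70 s) train.  The 65%/35% percentile rules are
applied **jointly at all five points** — the strictest reading; an averaged
variant was considered and rejected because the joint rule is the only one
that makes the three class definitions mutually exclusive in practice.  For
the wide terminal-phase control window (4 s) the five points are spaced 1 s.

On 200 untuned Poisson units the suite verifies that false-positive label
assignment stays at or below the rate implied by the thresholds; on
generated tuned units (rate ratio 3, four trials) recovery is at least 80%.
The generator's baseline rate default is 20 Hz — a task-engaged deep-layer
prefrontal unit; at substantially lower rates the peri-lick window holds too
few spikes (about two per trial at 10 Hz) for any classifier built on the
reference statistics to reach that recovery, a floor set by information
content rather than implementation.

## Population decoding and connectivity

Decoding reduces normalized trial-by-feature matrices (rates divided by the
window maximum) with PCA, keeps the smallest dimension count explaining more
than 85% of variance, and trains a linear SVM — the two-class reduction of
an error-correcting-output-codes classifier — on a 50/50 split, repeated 10
times.  Pseudo data (lick onsets re-drawn uniformly over each train's span,
50 repeats, re-normalized per repeat) and label shuffling provide the null
accuracy distribution; time-resolved decoding compares real and shuffled
accuracy distributions per window with a two-sample Kolmogorov-Smirnov test
at p < 0.05.  Trajectory separation is the mean Euclidean distance between
condition trajectories over **all** PC dimensions, which by orthogonality
equals the brute-force distance in the original space (a test asserts this).

The connectivity screen scores putative excitatory edges between spike
trains from the normalized cross-correlogram of a 3 s crop (1 ms bins,
±50 ms window): multi-scale edge filters (peak minus flanks, widths 2-5 ms)
are summed and the maximum over causal delays is the edge score.  Null
scores come from inter-spike-interval shuffling (200 surrogates).  Group
significance uses the fixed percentile schedule on the number of units:
below 10 the comparison is skipped; 10-14 uses the 80th percentile of the
null, 15-19 the 90th, 20-31 the 95th, 32 and above the 99th.

## The MP-network model

The simulator integrates 1000 excitatory and 800 inhibitory conductance-based
Hodgkin-Huxley neurons with Traub-Miles kinetics (threshold offset
−63 mV), exponential synapses (τe = 5 ms, τi = 10 ms, reversals 0/−80 mV)
and presynaptic short-term plasticity: between spikes the release usage
decays (`du/dt = −ω_f u`, ω_f = 3.33 s⁻¹) and the vesicle availability
recovers (`dx/dt = ω_d(1−x)`, ω_d = 2 s⁻¹); at a spike `u` jumps by
`0.6·(1−u)` so a first spike after rest releases with probability exactly
0.6, the transmitted conductance increment is `w·u·x`, and `x` is reduced by
`u·x`.  Weights are uniform in [0, 0.06] nS (excitatory) and [0, 1.5] nS
(inhibitory); connection probabilities are 0.1 and 0.2.  Membrane potentials
start uniformly in [−65, −63] mV.  Integration uses exponential-Euler
updates for the gating variables (from lookup tables) and for the membrane
equation at dt = 0.05 ms; halving dt changes the population rate by less
than 5%, and the integrator aborts with a diagnostic if |V| exceeds 200 mV.

Constants the modelling convention does not fix were calibrated once,
against two constraints — the undriven network must be silent and the driven
network must fire asynchronously and irregularly in its inter-spike-interval
target band (mean ISI 40-60 ms, CV 0.1-0.5 at the default 125 pA drive; see
`scripts/calibrate.R`) — and then frozen:

* **Leak reversal −65 mV.**  With the textbook −60 mV the neurons sit above
  the gating threshold and fire intrinsically, so the model would lick with
  no input at all, contradicting its premise that licking is triggered by
  continuous sensory drive.
* **Cell-to-cell heterogeneity (`het = 0.15`).**  Each neuron's leak
  conductance and effective drive are scaled by independent uniform factors
  in [0.85, 1.15].  A homogeneous network restarts from a silent gap in a
  synchronized oscillation whose pooled-count dispersion blocks the decision
  rule for over a second (the depressed inhibitory resources cannot break
  the synchrony), which distorts the interruption experiment; heterogeneous
  drive spreads the single-neuron rates and desynchronizes the restart
  within about 0.2 s.
* **Drive amplitude 125 pA** — the midpoint of the 50-200 pA operating
  range; the drive is applied to every neuron.

Spikes become licks through the nine-phase decision rule: neurons are
partitioned at random into nine equal pools (the rotational-dynamics
assumption fixes the number of phases but not the assignment); at each
evaluation time — every lick cycle, default 1/6.5 s, which caps the output
lick rate near 6.5 Hz — the cycle ending 280 ms earlier is divided into nine
sub-windows, and a lick is emitted when every pool has a positive spike
count in its own sub-window and the standard deviation of the nine counts is
below 30 (in spikes per pooled sub-window).  The pooled-count reading of the
phase indicator, the millisecond interpretation of the 280 lag, and the
one-cycle evaluation cadence are documented choices.

Two in-silico experiments probe the model.  *Neuron-number
reduction* scales both populations down (preserving the 1000:800 ratio) with
a flexible 1-200 ms input delay and scores ten seeded trials per size;
reduced populations thin the pooled counts and the initiation bias falls.
*Input interruption* uses the fixed 50 ms delay and cuts one or two 200 ms
zero-amplitude gaps into the current.  The gaps default to onsets 1.0 s (and
2.2 s) after DO: an interruption can only affect the *initiation* statistic
if it lands inside the developing initiation window (the SMA threshold
crossing occurs about 1.4 s after DO), so the protocol places the gaps in
that epoch — gaps centred in the 5 s span would fall after the crossing and
leave the statistic untouched by construction.  With the defaults, ten
5-second trials per condition give a mean initiation bias near 20% without
interruption, a roughly 55% relative drop with one gap, and near 5.5% with
two — matching the behaviour the model is meant to exhibit.  Trials are
5 s of simulated time; the bias horizon is clamped to the trial length.

## The synthetic-session generator

Lick rasters are an inhomogeneous renewal process: first lick at
DO + 1.3 s, rate relaxing linearly from the initial-phase peak (7.5 Hz) to
the 6.5 Hz plateau over 3 s, Gaussian inter-lick jitter (SD 10 ms — a free
choice, the interval variability is not otherwise constrained), and a sharp
termination.  Spike trains are piecewise-constant-rate Poisson processes
with ground-truth labels attached; phase-tuned units are elevated in their
window and suppressed in the complementary test window (with a 0.5 s margin
so the long-window smoother does not blur the suppression edge), which is
what the joint percentile rule requires of a recoverable unit.  Sessions are
bit-identical functions of their seed.

What the generator does *not* emulate: bursting and refractory structure in
spike trains (all processes are Poisson given the rate), lick-by-lick
kinematic variability, electrode drift, or correlated noise across units.
Passing the recovery and calibration suites therefore shows that the
statistics behave as specified under their own assumptions — not that the
classifiers are robust to every failure mode of real extracellular data.

## Problem sizes and numerical notes

The test suite runs the interruption experiment at the full reference design
(default network, 10 trials × 5 s per condition) and the classifier
calibration at 200 null units plus 40 tuned units; simulator property tests
(step-halving, amplitude sweeps, silencing) use reduced networks of a few
hundred neurons, which show the same phenomenology.  Degenerate inputs are
handled explicitly: empty spike trains yield all-zero rate traces; all-zero
traces pass through normalization unchanged; zero-variance baselines are
excluded with a message; an empty correlogram or empty reference train makes
an edge not-computable; fewer than two full trial groups skip the trial-bias
test with a message.
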