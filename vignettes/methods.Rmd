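---
title: "Models and methods behind oriplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oriplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriplast)
```

This vignette explains the models and procedures the package implements,
the tunable parameters that matter, what the synthetic-session generator
does and does not emulate, and the numerical and design choices made where
the analysis left room for them. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis problem

Chronic two-photon imaging follows the same population of layer-2/3 V1
neurons across days: an orientation-testing day before (*pre*) and after
(*post*) five intervening days on which a single "repetitive" grating is
shown, in some groups embedded in a rewarded virtual-corridor task. The
pipeline quantifies, per session and across days: how strongly each neuron
is orientation tuned, which neurons qualify as selective, how the selective
population redistributes toward the repetitive orientation, how well
stimulus identity can be decoded from single-trial activity, how behavior
(licking, locomotion) is structured, and which neurons respond to rewards
or to the corridor gratings.

## From raw fluorescence to trial responses

**ΔF/F₀.** Raw ROI traces are normalized per neuron as
(F − F₀)/F₀, with F₀ the 5th percentile of the smoothed trace. Smoothing
is a 60th-order FIR low-pass at 1 Hz applied with zero phase. Two details
are numerical choices of this package: the taps are a Hamming-window
design normalized to exact unit DC gain (so a constant trace maps to
ΔF/F₀ ≡ 0 exactly), and the forward–backward pass is realized as a single
centered pass of the filter's autocorrelation kernel after edge-reflection
padding of 3× the filter order. Reflection padding keeps short traces and
trace edges free of start-up transients; traces shorter than the padding
length are handled by periodic reflection indexing. Neurons whose F₀ comes
out non-positive cannot be normalized; they are flagged, set to `NA`, and
excluded downstream with a warning.

**Trial responses.** For each grating presentation,
r_t(θ_k) = mean ΔF/F₀ over the stimulation period − minimum ΔF/F₀ in the
2-s window preceding stimulus onset. The local-baseline subtraction
absorbs slow drifts and residual calcium from the previous trial. Which
frames constitute "the stimulation period" is a configuration choice
(`stim_period`): the moving-grating phase only (default, used for the
orientation-selectivity analysis), both stationary and moving phases, or
the first 2 s of the moving phase. The decoder path uses the 2-s
convention; the default reconciles the fact that responses during the
stationary and moving phases may differ while the orientation analysis
needs a single, consistently defined response window. Presentations
within 2 s of the recording start have no full pre-window and are skipped
with a warning. Windows are half-open frame intervals `[start, end)` with
0-based frame indexing, and time-valued parameters convert to frames by
flooring seconds × sampling rate — deterministic and conservative.

## Orientation selectivity

Gratings are axial stimuli (θ and θ + 180° are identical), so tuning is
summarized on the doubled-angle circle. With trial-averaged responses
R(θ_k), rectified at zero,

$$ v = \frac{\sum_k R(\theta_k)\, e^{2i\theta_k}}{\sum_k R(\theta_k)},
\qquad \text{peak magnitude} = |v| = 1 - \mathrm{CirVar},
\qquad \text{peak angle} = \tfrac{1}{2}\arg v . $$

Rectification is required for |v| to stay in [0, 1]: the vector weights
must be nonnegative. Negative trial responses are retained in the trial
table (decoders use them unrectified) — only the resultant rectifies. If
all rectified means are zero the tuning is undefined and flagged. Ties in
the preferred orientation (equal maximal R) are broken toward the
orientation closest to the resultant's peak angle, keeping the scalar and
vector summaries consistent.

**The two-criterion selectivity call.** A neuron is selective iff
(1) its peak magnitude exceeds the 25th percentile (linear interpolation)
of its animal's *pre-day* peak magnitudes — the same threshold is reused
on the post day, so day-to-day comparisons are against a fixed floor — and
(2) its trialwise preferred responses exceed the orthogonal-to-preferred
ones (Wilcoxon signed rank across trial pairs, two-sided p < 0.05, with
the preferred mean additionally required to exceed the orthogonal mean).
"Significantly higher" is a directional claim; testing it as a two-tailed
p plus a sign check reproduces it without inventing a one-tailed α. Trials
are paired by repetition index (the j-th presentation of each
orientation). The exact Wilcoxon distribution is used for n ≤ 25 pairs,
the continuity-corrected normal approximation otherwise; fewer than 5
pairs make criterion (2) untestable and the neuron is called not selective
with a flag.

A statistical property of this construction worth knowing: because the
preferred orientation is chosen *post hoc* as the argmax over K = 4
orientation means, criterion (2) on a completely untuned neuron passes
more often than the nominal 2.5% one-directional level — simulation in the
test suite puts the joint false-call rate for untuned populations at
roughly 7–9%. The 25th-percentile floor removes little of this when the
whole population is untuned, since the neurons passing criterion (2) are
precisely those with inflated magnitudes. In realistic mixtures (most
neurons genuinely tuned) the floor sits near the top of the untuned
magnitude distribution and is much more effective.

**Reliability.** The coefficient of variation of the single-repetition
peak magnitudes: repetition j pools the j-th trial of every orientation
into a trialwise tuning curve; CV = SD/mean of those magnitudes. The
pairing of trials into repetitions is one reading of "across trials"; a
bootstrap alternative (resampling trials within orientation) is available
via `method = "bootstrap"`.

**Indices, shift, fates.** R_select/O_select are the proportions of
neurons (of all neurons) selective for the repetitive orientation and its
orthogonal; RO_index = (R−O)/(R+O), undefined (flagged `NA`) at zero
denominator; O_index is the analogous contrast between the two
orientations seen only on testing days. The population shift is the
signed circular difference, on the doubled-angle circle wrapped to
(−90°, 90°], between the two days' population vectors (mean of per-neuron
resultants), with positive sign toward the repetitive orientation. Cell
fates map the (pre, post) selectivity pair to remain / gain / lose /
nonselective; proportions use the chronic-design bases — remain over
pre-day selective neurons, gain over pre-day nonselective neurons, lose
over all neurons.

## Decoders and discriminability

**Template matching.** Each trial's population vector (per-neuron mean
ΔF/F₀ over the condition period, no local-baseline subtraction) is
compared by cosine similarity to per-condition templates. Templates are
leave-one-trial-out means: the held-out trial never contributes to its own
template, avoiding train/test leakage; a single-template variant
(`loo = FALSE`) is available. Similarity ties are broken uniformly at
random under the caller's seed and logged; zero-norm vectors or templates
skip the trial with a warning. Confusion-matrix rows sum to per-condition
trial counts by construction.

**Bayesian maximum likelihood (single neuron).** Per orientation, the
response distribution is approximated as a Gaussian with mean and SD of
the training trials (all but the held-out one); with a uniform prior the
posterior is proportional to the likelihood, and the decoded orientation
maximizes it. The SD is floored at 10⁻⁶ ΔF/F₀ units to prevent degenerate
infinite densities when training responses are identical; floor events are
logged. Per-orientation accuracies are averaged across neurons to the
animal-level summary first, and pre/post changes are taken on those
averages (average-then-difference); the per-neuron table is returned so
the difference-then-average reading can be computed too.

**d′.** |μ₁ − μ₂| / √((σ₁² + σ₂²)/2) with sample variances; scale
invariant, reported as an absolute value.

## Behavior

**Locomotion.** A frame is locomotion iff instantaneous speed ≥ 0.1 cm/s,
0.25-Hz zero-phase low-pass filtered speed ≥ 0.1 cm/s (same FIR design as
the ΔF/F₀ smoother, cutoff changed), and mean speed over a centered 2-s
window ≥ 0.1 cm/s. Inter-locomotion gaps under 500 ms are bridged; frames
less than 3 s after or 0.2 s before locomotion are excluded from the
stationary class, so LMI contrasts clean steady states. The centered
window uses truncated partial windows at the trace edges.

**Licking.** A trial succeeds if at least one lick lands in the success
window — spatially the first 20 cm of the reward zone (120–140 cm on the
default 160-cm corridor), or temporally the first 1.5 s after reward-zone
entry for groups whose corridor is uncoupled from locomotion; the
geometry object carries one of the two windows and dispatch follows.
The SMI divides the observed success rate by its mean under a permutation
null. The null redraws every trial's lick positions uniformly along the
corridor, preserving per-trial counts: this realizes "spatially
indiscriminate licking of the same frequency", the comparison the index is
meant to make, whereas permuting positions within a trial would change
nothing. A circular-shift null (each trial's lick pattern rotated by a
uniform offset), which preserves within-trial lick spacing, is available
behind `scheme = "circular"`. A zero shuffled mean (no licks anywhere)
makes the SMI undefined and flagged — never silently 0 or ∞. Default
rewards delivered on unsuccessful trials do not count toward the success
rate: success requires a self-initiated lick in the window.

## Event classification

**Reward-responsive.** Mean ΔF/F₀ in [−2, −1) s before reward onset vs
[0, 1) s after, paired t test across rewards, p < 0.05 with the post mean
required to exceed the pre mean. The peak response is the maximum of the
reward-triggered *average* trace in ±2 s — computed on the trial-averaged
trace (matching how averaged event-aligned responses are usually
displayed), with the per-reward alternative a one-line change. Rewards
within 2 s of either recording edge are skipped; fewer than 5 usable
rewards make the neuron unclassifiable.

**Corridor-responsive.** Per trial, spatial means in two 25-cm blocks
around the reward-zone onset: [−35, −10) cm (late grating) and [0, 25) cm
(reward zone, stimulus absent). The reward-zone onset is read per trial
from the position at the black-zone epoch onset, so two-corridor sessions
with different zone locations are handled correctly. Responsive means
R_pre significantly greater than R_post (Wilcoxon signed rank, p < 0.001,
direction required): the neuron drops its activity where the stimulus
disappears. Frames are assigned to blocks by the half-open cm interval of
the trial's traversal, pooling repeated visits. Corridor-selective
neurons are responsive to exactly one of two presented corridors.

## The synthetic-session generator

The generator exists so every downstream stage can be validated against
known ground truth; its defaults are the study conditions, not tuning
knobs.

Per neuron, the firing-rate proxy is

$$ \lambda_i(t) = g_i \exp\{\kappa_i(\cos 2(\theta(t)-\phi_i) - 1)\}
 \cdot \mathbf{1}_\text{stim}(t) + \ell_i \mathbf{1}_\text{run}(t)
 + a_i \mathbf{1}_\text{reward}(t), $$

a von Mises tuning profile on the doubled angle (the standard axial
choice, peak-normalized so g is the peak response in ΔF/F₀ units), a
locomotion gain, and a 1-s reward-locked pulse whose duration matches the
classification window it must be detectable in. The drive is convolved
with an exponential calcium kernel (decay 0.6 s, GCaMP6-like; implemented
as a unit-DC-gain leaky integrator so sustained drive plateaus at g), then
placed on a positive per-neuron raw-fluorescence baseline (uniform
80–120 a.u.) with additive Gaussian trace noise — preprocessing must
genuinely recover ΔF/F₀. Optional lognormal per-presentation gain jitter
(`gain_jitter_sdlog`) makes the reliability-CV analysis nontrivial.

Sessions come in two types. *Grating* sessions present each of
{0°, 45°, 90°, 135°} in randomized order (15 presentations per orientation
by default; 2 s stationary + 2 s moving, 5-s gray gaps, 2-s lead-in).
*VR* sessions are corridor traversals (129 trials by default) at per-trial
running speeds ~N(20, 3) cm/s; the grating covers the corridor up to the
reward zone, black walls beyond; licks are placed per trial with
probability ρ (`lick_concentration`, default 0.9) uniformly inside the
success window and otherwise uniformly along the corridor; a reward
follows the first in-window lick, or is delivered at the default location
just beyond the success window on unsuccessful trials. Locomotion is a
two-state Markov chain (mean bouts 5 s running / 10 s stationary,
running speed ~N(8, 2) cm/s).

Parameter defaults chosen once and documented here: 75% of neurons
genuinely tuned (κ = 8, peak gains 0.3–0.8 ΔF/F₀) — consistent with the
high tuned fractions reported for mouse V1 L2/3 and with the
25th-percentile criterion design, which treats the bottom magnitude
quartile as the untuned floor; untuned neurons are visually responsive but
flat across orientations (gains 0.05–0.3); trace noise SD 0.05 ΔF/F₀;
30% locomotion-modulated (gains 0.05–0.2); 30% reward-responsive in VR
sessions (pulse amplitudes 0.2–0.6). The simulation sampling rate is
10 Hz: only relative responses matter downstream, and this keeps
multi-seed experiment fixtures at desk scale. The ground-truth
`is_selective` flag is the deterministic rule κ ≥ 1 and gain ≥ 0.1.

`generate_experiment()` plants per-neuron fates — remain, gain (tuned to
the repetitive orientation on the post day), lose, stable-nonselective —
with κ and gain ramping linearly across the intervening days when
training-day sessions are requested. Single-neuron plasticity effect
sizes are free parameters of the fate specification, not estimates: no
distribution for them is established, so recovery tests should be read as
validating the measurement machinery, not as forecasts of real effect
magnitudes.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: photon shot noise and motion artifacts;
neuropil contamination (traces are assumed decontaminated); spike-level
dynamics and calcium-indicator nonlinearity; slow drifts of baseline or
arousal; correlated noise across neurons; orientation preferences off the
4-point stimulus grid; and cross-day ROI misalignment.

## Validation design and known limitations

The test suite validates each operation against independent oracles
(hand arithmetic, brute-force re-implementations of both decoders,
analytic permutation nulls such as the shuffled success probability
1 − (1 − w/L)^k), property-style invariants (bounds, equivariances, scale
invariances, conservation of trial counts), and end-to-end parameter
recovery on generated experiments (selective-fraction recovery within
±5 percentage points; planted gain fates producing ΔRO > 0 and a positive
population shift; planted null producing |shift| < 3°). False-positive
controls run the reward classifier on stationary noise with unrelated
reward times (expected ≈ 2.5%) and the selectivity call on fully untuned
populations. The untuned-population control deliberately switches
locomotion modulation off: running bouts coinciding with particular
presentations give locomotion-modulated neurons genuine
orientation-correlated drive — a modeled behavioral confound, not a false
positive of the statistical criterion the control checks. As noted above,
the post-hoc choice of the preferred orientation keeps the untuned false-call
rate near 7–9% rather than the naive 2.5 × 0.75 ≈ 1.9%; analyses that need a
calibrated single-neuron error rate should prefer the decoder or d′ paths,
or define the preferred orientation on held-out data.

Problem sizes used by the recovery suites — 200 neurons, 20 trials per
orientation, 40 seeds for recovery, 12 seeds for the untuned control —
are the package's chosen desk-scale study conditions.

Session storage is a directory of tidy CSVs plus JSON metadata
(human-inspectable, bit-exact round trip via 17-significant-digit
serialization). An HDF5 mirror of the same layout is a recognized but
currently unimplemented format name. Group-level inferential statistics
across animals (ANOVA families, cross-group KS tests) are out of scope;
the package stops at per-animal summaries.
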