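---
title: "Estimating spike transmission gain and its plasticity from closed-loop experiments"
author: "spiketrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spike transmission gain and its plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spiketrans)
```

## The measurement problem

A pyramidal cell (PYR) that makes a monosynaptic excitatory contact onto a
parvalbumin-positive (PV) interneuron leaves a signature in the pair's
cross-correlation histogram (CCH): an excess of postsynaptic spikes at
causal lags of a few milliseconds. The **spike transmission gain (STG)**
turns that signature into a physiologically interpretable number — the
expected count of *excess* postsynaptic spikes per presynaptic spike. This
package estimates the STG per epoch, quantifies its change after a
closed-loop stimulation experience, and asks which features of the
experience (assembly structure, millisecond spike timing, excitability
changes) predict that change.

Two confounds must be removed before the CCH peak can be read as
transmission:

1. **Slow co-modulation.** Firing-rate co-fluctuations on tens of
   milliseconds and slower inflate the CCH everywhere. They are estimated by
   a **hollowed median filter** — a running median over neighbouring bins
   that excludes the bin itself — and subtracted. The hollowing keeps the
   narrow monosynaptic peak from contaminating its own baseline;
   truncating the window at the CCH edges avoids padding artifacts.
2. **Presynaptic temporal structure.** Bursts and refractoriness of the
   presynaptic train smear the transmission kernel into the CCH (a doublet
   at 3 ms duplicates the peak at the doublet lag). We model the excess CCH
   as the discrete convolution of the presynaptic autocorrelation kernel
   with the transmission curve and invert it. The kernel is the ACH excess
   over its own hollowed-median baseline with the zero-lag bin set to the
   number of reference spikes (every spike coincides with itself); the
   finite-window Toeplitz system is solved by least squares with a small
   Tikhonov ridge, `lambda = 1e-6 * tr(K'K) / n_bins`. Two properties anchor
   this solver and are enforced by tests: for a flat (Poisson) reference ACH
   the deconvolution is the identity up to scaling, and a curve convolved
   forward with a bursty kernel is recovered with the satellite peak
   suppressed.

The STG is then the area under the causal peak: the maximum bin of the
deconvolved, baseline-subtracted curve inside the monosynaptic ROI
(0 < τ ≤ 5 ms), extended to the left (never past zero lag) and right until
the curve first crosses zero. The **STG change** between the Before and
After epochs is `log2(STG_After / STG_Before)`; +1 is a doubling, −1 a
halving, and the value is undefined (the pair is excluded) when either STG
is non-positive.

## Bin conventions

All correlogram bins are half-open on the left and closed on the right,
`(low, high]`, matching ROI definitions written as `0 < τ ≤ 5` ms. The
0.5-ms grids used for STG and synchrony are *edge-aligned* (zero lag is a
bin edge; the bin containing 2.0 ms is (1.5, 2.0]). The 1-ms grids used for
CCH-difference features are *center-aligned* (an odd number of bins, the
middle bin straddling zero), so that a window of half-width 10 ms slices to
exactly 21 elements. Times are seconds in double precision throughout;
intervals are half-open `[start, end)`.

## Default parameters

| parameter | default | notes |
|---|---|---|
| CCH bin width | 0.5 ms | transmission and synchrony grids |
| CCH window | ±30 ms | also the eligibility count window |
| monosynaptic ROI | 0 < τ ≤ 5 ms | peak search region |
| baseline half-width (STG) | 10 ms | see below |
| baseline half-width (CLE, synchrony, generic) | 5 ms | |
| PSTH / CCH-difference bin | 1 ms | |
| PSTH / CCH-difference window | ±50 ms | |
| connection threshold | p < 0.001 | Poisson excess test |
| eligibility counts | ≥ 400 per epoch | in −30 < τ ≤ 30 ms |
| permutation shuffles | 2000 | two-tailed, +1 correction |
| direction threshold | p < 0.05 | 2.5% chance per direction |

**Why a 10-ms STG baseline half-width.** The hollowed-median half-width is
5 ms for closed-loop efficiency and synchrony but 10 ms for the STG
baseline, and the difference is deliberate. With 0.5-ms bins, a 5-ms half-width gives
a 20-bin window in which the ~6-bin monosynaptic peak occupies nearly a
third of the entries, pushing the "hollowed" median toward the ~70th
percentile of the chance counts. The result is a constant absolute
underestimate of the excess (≈ 0.002 spikes per spike under the default
simulation conditions) that is devastating for weak connections (−25% at a
transmission probability of 0.01). At 10 ms the peak occupies ≤ 15% of the
window and parameter recovery is within 10% across transmission
probabilities 0.01–0.1 (verified by the recovery tests). CLE and synchrony
keep the stated 5 ms.

## The permutation test for STG-change consistency

Per pair, a binary spike-time lag matrix is built from the Before and After
epochs: one row per presynaptic spike, one column per 0.5-ms lag bin over
−30 < τ ≤ 30 ms, entries marking postsynaptic spike occupancy. Summing rows
by the true epoch labels reproduces the two count CCHs; the observed STG
change is computed from them through the same deconvolution path as every
shuffle, so the observed statistic and the null are exactly comparable.
Row labels are then permuted (2000 times by default), both STGs recomputed
per permutation, and the two-tailed p-value is
`(1 + #{|shuffled| ≥ |observed|}) / (n_valid + 1)` — the minimal attainable
p is therefore `1/(n_shuffles + 1)`. Design choices:

- The presynaptic ACH kernel is label-invariant (the combined train), so a
  single solve operator serves all shuffles; per-shuffle ACH recomputation
  would be both unspecified and nearly label-independent here.
- Shuffles in which either partition has no positive causal peak leave the
  log ratio undefined; they are discarded and redrawn, capped at three times
  the requested number of shuffles. The cap was never reached in any
  simulation we ran; pairs weak enough to trigger it routinely would fail
  the eligibility screen first.
- Under the null (constant transmission probability), the per-direction
  flag rate at the two-tailed 0.05 level is the 2.5% chance level; the
  calibration test checks this on 200 simulated null pairs.

## Closed-loop efficiency and light response

The **CLE** measures what fraction of a unit's spikes triggered light: the
excess of the unit's PSTH (1-ms bins) over its hollowed-median baseline,
summed over the pre-onset ROI (−5 ms, 0], divided by the unit's spike count
in the analyzed period, clipped to [0, 1]. With a 3-ms detection delay,
every triggering spike sits exactly 3 ms before an onset, so a perfect
closed loop yields CLE = 1. Even perfect detection yields CLE < 1 at
realistic rates because spikes arriving during the 30-ms stimulus or the
20-ms dead time cannot trigger; the recovery tests therefore use a sparse
(0.5 spk/s) trigger unit, for which the realized CLE approaches the
detection probability.

The **light gain** compares the PSTH rate in the response window
[10, 30) ms after onset with the baseline rate in the 15-ms window ending
15 ms before onset. Two measurement caveats surfaced in simulation and are
worth knowing for real data: at high stimulation density the baseline
window overlaps the tail of the preceding stimulus (closed-loop blanking
makes a "previous onset just beyond the 50-ms minimum gap" configuration
over-represented), biasing the gain down; and the postsynaptic refractory
period compresses the in-stimulus rate slightly. The gain-recovery tests
use sparse stimulation, where the estimate is unbiased within 5%.

## Synchrony

Zero-lag synchrony between two trains is the coincidence count in
−1 ≤ τ ≤ 1 ms of the 0.5-ms CCH divided by the geometric mean of the two
spike counts (`eta_sync`, in [0, 1]); chance coincidences are estimated from
the hollowed-median predictor and subtracted on the same scale
(`delta_eta`, in [−1, 1]). Results are qualitatively stable across bin
widths {0.25, 0.5, 1} ms and ROIs {±0.5, ±1, ±1.5} ms (a parameter-sweep
test asserts sign stability on common-drive pairs).

## Assemblies, CCH differences and prediction

Eligible pairs sharing a postsynaptic unit form a converging assembly.
Peer/non-peer means are computed within a session; when several simulated
sessions are pooled, each pair's non-peer mean comes from its own session.
A caution discovered in simulation: within a *single* session the non-peer
mean is mechanically anticorrelated with the pair's own value (the session
total is fixed, so "everyone else's mean" decreases in one's own assembly
level); pooling independent sessions removes this, which is how the
assembly-signature validation is run.

The **CCH difference** contrasts the pair's conditional-rate CCH with
presynaptic reference spikes during stimuli against the CCH between stimuli
within the Experience epoch; slow excitability changes common to both
periods cancel. Stimulus intervals are the nominal [onset, onset + 30 ms)
span, and no guard period is applied after stimulus offset (configurable).

Prediction uses cross-validated learners with hyperparameters fixed once:
linear SVM with C = 1 for classification, RBF SVR with C = 1 and the kernel
width set by the median heuristic of pairwise training distances for
regression; features are standardized on the training folds only. AUCs are
computed from out-of-fold decision values pooled within a repeat. Fold
schemes: row-level (`random`), whole-assembly (`entire_assembly`; no
assembly spans training and testing) and `subsample_one_per_assembly`.
The timing/rate dissociation manipulates the feature vectors — Z-scoring
removes co-firing ("rate") information, shuffling the 1-ms bin order
removes precise-timing information — and is validated on feature-level
cohorts generated with known structure (see below).

For unstimulated control sessions, the **virtual closed loop** draws a
trigger PYR per assembly and a CLE from a log-normal distribution matched
to the observed trigger-unit quantiles (median 0.054, IQR 0.013–0.184),
selects that fraction of the unit's Experience spikes as virtual triggers,
and applies the 3-ms delay and 50-ms blanking rule. No spikes are altered.

## The synthetic-session generator

`generate_session()` produces sessions with known ground truth:

- PYR trains are stationary renewal processes (exponential gaps plus a 2-ms
  absolute refractory period, hazard inflated so the realized rate equals
  the nominal one), rates drawn from 0.5–5 spk/s.
- PV trains are inhomogeneous Poisson processes built by exact
  superposition: a homogeneous baseline (5–30 spk/s), extra light-driven
  spikes inside stimulus intervals implementing a rate gain (default
  1.56), and Poisson(p) transmission spikes per presynaptic spike placed
  uniformly on a rectangular kernel supported on (0.5, 3.5] ms with
  integral p (pair transmission probabilities drawn log-uniformly from
  0.005–0.2). Superposition is an exact sampler for this rate function, so
  no thinning envelope is needed; the refractory period is enforced on the
  merged train afterwards, which deletes ~`rate × refractory` of spikes and
  is the main source of the small (< 8%) downward bias visible in STG
  recovery at high p.
- The closed loop detects each trigger spike independently with probability
  `detection_prob`, emits an onset 3 ms later, and blanks onsets within
  50 ms (30-ms stimulus + 20-ms dead time) of the previous one. Epochs
  default to 45/55/45 min.
- Plasticity multiplies each pair's transmission probability by an assembly
  factor (or an independent per-pair factor) from the Experience epoch
  onward; the measured Before/After contrast is unaffected by where in the
  Experience the switch occurs, which the generator does not model.
- The generator emulates stationary rates, feed-forward coupling and
  light-gain modulation. It does **not** emulate behavioral state changes,
  theta/ripple structure, common drive between assemblies, PYR light
  rebound, short-term synaptic dynamics or recurrence, so passing tests
  demonstrate estimator correctness under the stated model, not robustness
  to every in vivo confound.

`simulate_assembly_features()` complements the session generator with
feature-level cohorts for classifier validation: `gain_only` vectors carry
class information only in their mean offset (destroyed by Z-scoring,
preserved by bin shuffling) and `latency` vectors only in the position of a
±3-ms bump of fixed energy (preserved by Z-scoring, destroyed by bin
shuffling). Defaults (offset 1 spk/s, bump amplitude 2 spk/s against unit
noise) were chosen once to mimic the magnitude of assembly CCH-difference
structure relative to its bin noise.

## Problem sizes used in validation

The test suite validates at sizes chosen to make every check statistically
meaningful: STG recovery uses 45-min epochs and 20 seeds per transmission
probability; permutation-test calibration uses 200 null pairs with 6-min
Before/After epochs and 1000 shuffles; assembly-signature validation pools
8 sessions of 4 assemblies × 3 pairs per regime with 15-min no-stimulation
epochs; classifier calibration and dissociation use 122-assembly feature
cohorts; determinism runs the full pipeline twice on a 2-assembly,
30-min session.

## Known limitations

- **Shuffle-control AUC spread.** The AUC of a label-shuffled classifier at
  n = 122 has a null standard deviation of at least
  `sqrt((n1+n2+1)/(12 n1 n2))` ≈ 0.052, and pooling out-of-fold decision
  values across folds (whose models were trained with the other folds'
  labels) inflates it to ≈ 0.075 in our measurements — per-fold score
  standardization and stratified folds do not reduce it. About 84% of
  shuffle-control AUCs fall inside [0.4, 0.6], not 95%; a band of ±0.15
  would be needed for 95% coverage at this n. The calibration test records
  this property.
- The deconvolution assumes the transmission kernel is stationary within an
  epoch and confined to the CCH window.
- Degenerate inputs are flagged rather than silently propagated: zero
  expected counts in the Poisson test clip p to the minimum with a warning;
  non-positive STGs or synchrony measures make the corresponding change
  `NA`; constant vectors make Z-scores and rank correlations `NA` with a
  warning.
- Ties in the CCH maximum (eligibility criterion) resolve to the first bin;
  exact-boundary lags are kept in their right-closed bin via a 1e-9
  epsilon, far below any spike-time resolution.
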