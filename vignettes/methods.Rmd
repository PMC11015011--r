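---
title: "Detecting neuronal ensembles and their inactivated members: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neuronal ensembles and their inactivated members: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsembles)
```

## The scientific problem

Two-photon calcium imaging of mouse primary visual cortex during
drifting-grating stimulation yields, after ROI extraction, one raw
fluorescence trace per neuron plus a local neuropil trace, a stimulus
schedule, and behavioral covariates (running speed, whisking energy).
Groups of neurons that fire together repeatedly — neuronal ensembles —
encode stimulus orientation, and during each ensemble event a second,
distinct set of neurons is selectively *inactivated*. `onsembles`
implements the full analysis chain for this setting: fluorescence
preprocessing into binary spike rasters, unsupervised ensemble detection,
classification of activated ("onsemble"), inactivated ("offsemble") and
nonparticipant neurons, transient-kinetics comparison across stimulation
conditions, orientation-tuning quantification, and stimulus decoding. A
synthetic-data generator reproduces the study conditions so that every
stage is testable without recordings.

## Signal model and preprocessing

Each ROI's trace is neuropil-normalized,
$F_{filtered} = (F_{ROI} - F_{neuropil}) / F_{neuropil}$, and judged by its
peak signal-to-noise ratio
$PSNR = 20\log_{10}\!\big(\max(F_{ROI}-F_{neuropil})/\mathrm{sd}(F_{neuropil})\big)$
in dB. ROIs with PSNR strictly above 10 dB (configurable, including the
strictness of the comparison) enter the pipeline. Traces are smoothed by a
moving median, then minimum, then maximum filter with a common 500-ms
window (an odd frame count, centered, truncated at the edges). The
min-then-max pair is a morphological opening: events shorter than the
window are removed while the onset frame of longer transients is
preserved, which is why this filter "works better for preserving timing"
than a plain low-pass.

Spikes are inferred by sparse nonnegative deconvolution under an AR(1)
calcium model ($c_t = \gamma c_{t-1} + s_t$, $s_t \ge 0$, L1 penalty
$\lambda \sum_t s_t$), solved exactly by a pool-adjacent-violators sweep.
Defaults: $\gamma = \exp(-\Delta t/\tau_{ind})$ with $\tau_{ind} = 5.8$ s,
the GCaMP6s transient decay constant measured in this preparation — an
AR(1) model much faster than the indicator (for example a generic 2-s
value) under-predicts every decay and emits a continuous stream of small
spurious spikes; $\lambda$ defaults to a per-trace noise estimate,
$\mathrm{mad}(\Delta y)/\sqrt 2$. The inferred rate is binarized at
$\max(0.04 - 0.002\,PSNR,\ \varepsilon)$. The floor $\varepsilon$ matters:
the linear rule crosses zero at 20 dB, and with a floor near machine
precision any model mismatch (the suppressed-decay switching below,
background drift, smoothing staircases) binarizes to spikes. The default
$\varepsilon = 0.01$ — a few percent of a single-transient amplitude in
inferred-rate units — keeps high-PSNR ROIs usable; it is configurable.

Frame-exact spike recovery through this chain is only well-posed for
transients separated by more than the smoothing window; within dense
within-trial bursts, timing is recovered to within about one frame. The
round-trip test therefore checks sparse spontaneous firing (0.002/frame)
on noiseless traces, where per-neuron Jaccard agreement with the planted
raster exceeds 0.9.

## Transient decay constants by condition

Single transient decays are fit with $decay(t) = a e^{-t/\tau}$ by bounded
nonlinear least squares (Levenberg–Marquardt, log-linear initialization;
fits that end on a bound or fail are flagged). Transients are detected as
local maxima exceeding median + 3 MAD followed by at least 0.5 s of
non-increasing signal (5% tolerance), with the fit window running to the
next rise or 2 s. Decays are assigned to three conditions: *spontaneous*
(clear of any suppressing stimulus), *pre-onset* (the segment of a decay
that ends at the onset of the neuron's suppressing orientation), and
*during* (the continued decay inside the 2-s stimulus). In the synthetic
data an offsemble neuron's decay constant switches from 5.8 s to 2.5 s
while its suppressing stimulus is on, and the condition means separate
accordingly (the faster during-stimulus decay is the signature of active
inhibition).

## Ensemble detection

Detection never sees the stimulus. From the binary raster (neurons x
frames):

1. **Functional network.** Edge between two neurons when their observed
   coactivation count exceeds what independent circular shifts of each
   spike train produce; one-sided exceedance p over 1000 surrogates,
   $\alpha = 0.05$, no multiple-comparison correction by default (a
   Bonferroni option exists).
2. **Population-vector filtering.** In each frame, a spike survives only
   if its neuron has at least one network neighbor active in the same
   frame; isolated spikes are removed and silent frames drop out of the
   analysis entirely.
3. **Clustering.** Pairwise Jaccard similarity between the remaining
   column vectors; Ward linkage (`hclust` `ward.D2`) on the precomputed
   1 − Jaccard dissimilarity — Ward on a non-Euclidean dissimilarity is the
   common dialect of this method and is used knowingly.
4. **Cluster count.** The tree is cut at every k in 2..10 (configurable);
   the selected k maximizes the contrast index — per cluster the mean
   within-cluster similarity minus the mean similarity of members to
   non-members, averaged over clusters with singletons contributing
   within-similarity 1; ties resolve to the smallest k.
5. **Significance.** Per cluster of size m, the observed mean pairwise
   similarity is z-tested against 1000 random draws of m clustered frames;
   clusters with one-sided p < 0.05 are ensembles. Their occurrence
   signals are binary and mutually exclusive by construction, since every
   frame holds at most one cluster label.

`detect_ensembles()` wraps the chain and returns a classed fit with
`print`, `summary` and `plot` methods.

## Participation: EPI and classification

The Ensemble Participation Index of neuron i in ensemble e compares the
fraction of frames the neuron is active during ensemble occurrences with
the fraction outside them:
$$EPI = 2\,\frac{r_{in}}{r_{in} + r_{out}} - 1 \in [-1, 1].$$
+1 means exclusively active during occurrences, −1 exclusively outside
them, 0 equal rates in both states. This rate-modulation reading is the
package default because it is the only normalization that keeps
uninvolved neurons at 0 regardless of how much of the session the
ensemble occupies: the count normalization
$2\,(\text{spikes inside})/(\text{total spikes}) - 1$ (available as
`method = "count"`) pins every neuron near $2 T_{ens}/T - 1 \approx -0.8$
when occurrences cover ~10% of the session, which contradicts both the
anchor interpretations and the classification rule below. The two
definitions coincide whenever occurrences cover exactly half the session.

Significance uses a two-sided Welch t-test with one sample value per
occurrence epoch (fraction of frames active) against one per complementary
epoch. Significant positive EPI = onsemble member, significant negative =
offsemble member, otherwise nonparticipant; degenerate zero-variance cases
are flagged nonparticipants. No correction across neurons by default
(per-neuron p < 0.05, mirroring the per-cell testing convention), with a
`p.adjust` method argument.

A caution for recovery benchmarks: with several planted orientation
ensembles, a neuron tuned to one orientation is *genuinely* rate-modulated
(downward) during another ensemble's occurrences, so its planted
"nonparticipant" label disagrees with its actual behavior and any correct
classifier will call it an offsemble member. Classification recovery is
therefore benchmarked on a single planted ensemble, where the three
classes are behaviorally distinct, and reaches per-class F1 >= 0.9.

## Tuning and decoding

Responses are means of a unit's activity over each 2-s trial, in [0, 1]
for binary units (neurons, ensemble occurrences) and fraction-active group
series alike. Directions theta and theta + 180 are pooled into four
orientations. Selectivity is 1 − CirVar with doubled angles,
$|\sum_k R_k e^{2i\theta_k}| / \sum_k R_k$; significance is a one-sample
Hotelling t² on the doubled-angle response vectors (F reference; a
label-permutation fallback handles singular covariance). Tuning width
comes from bounded nonlinear least squares of
$a\,e^{-(\theta-\theta_{pref})^2/(2\sigma^2)}$ with the orientation
difference wrapped to [−90°, 90°) and bounds $a \in [0,1]$,
$\theta_{pref} \in [-45°, 180°]$, $\sigma \in [1°, 90°]$, multi-started
over the observed orientations and cross-checked against a 1° grid search
in the tests.

Group series (onsemble fraction, offsemble fraction, nonparticipant-tuned
fraction, and the combined ensemble criterion counting active onsemble
plus inactive offsemble members) are analyzed with the same machinery.
For activation probability, "active" means above 0 for binary units; for
fraction-valued group series — where the fraction is almost never exactly
zero — the default criterion is the series' session median (configurable),
a choice this package makes explicitly since none is standard.

Decoding builds one predictor per orientation by scanning every distinct
response value as a cutoff in both inequality directions and keeping the
operating point that maximizes informedness (hit rate − false-alarm rate);
the two directions let anti-responsive offsemble predictors participate
without special-casing. Per trial the firing predictor wins; with zero or
several firing, the largest signed margin beyond threshold decides, with
seeded uniform residual tie-breaks. Accuracy is the diagonal sum of the
4x4 confusion matrix over trials. Neuron-set decoding forms disjoint
random quadruples (one tuned neuron per orientation, as many sets as the
smallest orientation pool) and averages count matrices.

## The removal control

To ask whether offsemble neurons carry orientation information, the
orientation-encoding ensembles (per stimulus orientation, the most
selective significant ensemble) are identified, and either their offsemble
members or an equal number of "least participant" pure nonparticipants
(smallest |EPI|) are removed; detection is re-run on the remainder forcing
the original significant-ensemble count, and the surviving ensembles'
tuning is summarized. Because the rate-modulation EPI classifies
relatively inactivated neurons liberally, the offsemble union can exceed
the pure-nonparticipant pool at a 200-neuron desk scale; the removal count
is therefore the minimum of the two pool sizes in *both* arms (the
offsemble arm removes its most strongly inactivated members first), which
preserves the matched-count contract. Across 20 synthetic sessions the
offsemble arm reduces both the number of orientation-tuned ensembles and
their selectivity relative to the control arm.

## The synthetic generator

The generator is first-class code and defines the study conditions:

* **Schedule.** 8 drifting-grating directions in balanced shuffled blocks,
  2-s stimuli, ISIs uniform on [1, 5] s rounded to whole frames, 80-ms
  effective frame period (3-plane volumetric imaging), sessions starting
  with a blank period; a 5-min session holds at least 48 trials with every
  direction shown at least 6 times. Infeasible requests raise a capacity
  error rather than truncating.
* **Population.** Per ensemble, 20% onsemble and 26% offsemble members;
  a chained `overlap` parameter shares membership between consecutive
  ensembles, and offsembles are drawn preferentially (`off_from_on`) from
  other ensembles' onsemble members — the cross-orientation suppression
  structure in which a neuron can be onsemble of one orientation and
  offsemble of another. Remaining neurons split into orientation-tuned,
  unspecific, interstim and untuned classes.
* **Spiking.** Per-frame Bernoulli; onsemble members at baseline x gain
  during their orientation's trials (with per-neuron trial reliability),
  offsemble members at baseline x suppression, interstim neurons elevated
  only between trials.
* **Calcium.** Each spike adds an instantaneous-rise transient decaying at
  5.8 s, switching to 2.5 s while the neuron's suppressing stimulus is on
  (implemented as a time-varying per-frame decay rate); ROI fluorescence
  adds a shared slowly drifting background scaled by the neuropil
  contamination level plus white noise per channel.
* **Behavior.** Running bouts (uniform 2-8 s) at a target occupancy with
  speeds above/below the 1 cm/s convention; whisking energy elevated
  during running plus extra wakeful bouts.

All randomness flows from one root seed through named substreams
(schedule, population, spikes, noise, behavior), so changing, say, the
noise draw never perturbs the schedule.

Two frozen presets (`synth_regime()`) define the benchmark conditions.
The *clean* regime (sparse 0.002/frame baseline, gain 150, total
suppression, fully reliable members, no incidental tuning classes) is used
for recovery benchmarks, where detection finds the four planted
orientation patterns with frame-label ARI >= 0.9 and all clusters
significant. The *paper* regime (baseline 0.01/frame, gain 25, partial
suppression 0.1, 45% membership overlap, 80% of offsemble slots from other
onsembles, trial reliability 0.8/0.5) reproduces the recording-like
qualitative structure: binary ensemble selectivity above tuned single
neurons, member-fraction groups below single neurons with offsemble
fractions comparable to onsemble fractions, nonparticipant-tuned
populations lowest; tuning widths in the reverse order; and near-perfect
ensemble decoding above averaged neuron quadruples. Spontaneous firing
rates, transient amplitude (0.3 dF/F per spike) and noise levels are free
parameters the recordings do not pin down; the defaults above are
documented once here and not revisited.

What the generator does *not* emulate: pixel-level imaging, motion
artifacts, plane-by-plane timing within a volume, graded orientation
tuning curves at the single-spike level (tuning enters through
ensemble-conditional rates), slow drifts in excitability, and correlated
noise across neurons. Passing tests therefore demonstrate correctness of
the analysis chain under the stated generative model, not performance on
arbitrary real recordings.

## Numerical choices and degenerate inputs

* Frame indices are 0-based half-open intervals on disk, ordinary 1-based
  indexing in memory.
* PSNR of a trace whose peak never exceeds neuropil is −Inf (fails QC);
  zero-variance neuropil is an error.
* Deconvolution subtracts the 8th-percentile baseline before solving;
  outputs below 1e−12 are zeroed exactly.
* Empty frames are excluded from clustering and never assigned to
  ensembles; singleton clusters are excluded from the coherence test with
  a warning; a zero-spread null falls back to an exceedance p-value.
* Decay and tuning fits that end on a parameter bound are flagged, never
  silently returned; the tuning fit's multi-start over observed
  orientations avoids the wrapped-Gaussian local minima.
* Neurons with no spikes have undefined EPI (NA) and are excluded from
  classification; all-still sessions yield NA running-state EPIs and an
  ineligibility flag at the 5%-running-frames rule.
* Problem sizes in the test suite (200 neurons x ~3750 frames for
  recovery runs; 20 seeds of 200-neuron, 200-s sessions for the removal
  comparison; 150-1000 surrogate/null draws where full defaults are not
  needed) were chosen as the smallest sessions that leave the planted
  structure unambiguous.

## Known limitations

* The contrast index and the coactivation-network test are documented
  stand-ins for procedures the source literature delegates to earlier
  work; both are configurable.
* Ward linkage on 1 − Jaccard lacks the variance interpretation Ward has
  in Euclidean space.
* The epoch-based Welch t-test for participation is slightly
  anticonservative for very short occurrence epochs at low rates.
* Decoding deliberately uses no trained classifier; it quantifies the
  information available to a threshold readout, not an upper bound.
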