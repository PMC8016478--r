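---
title: "Detecting and classifying cortical slow-oscillation activity with slowosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying cortical slow-oscillation activity with slowosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowosc)
```

## The problem

Under anesthesia and slow-wave sleep, cortical networks alternate at below
1 Hz between *upstates* — episodes of collective depolarization and vigorous
spiking — and quiescent *downstates*. Detecting these episodes reliably in
extracellular recordings, classifying the units that participate in them,
and characterizing the cells and connections that shape them are recurring
needs in systems neurophysiology. `slowosc` implements one coherent
pipeline for this problem family:

1. **Upstate detection in vivo** from the delta-band local field potential
   (LFP) with dynamic thresholds, confirmed by population spiking.
2. **Upstate detection in vitro** by coincidence between two intracellular
   signals (two membrane potentials, or one membrane potential and its
   gamma-band envelope).
3. **Unit quality control and classification** by trough-to-peak (TP)
   waveform latency, and classification of each unit's response to a
   systemic drug as *activated* or *non-activated*.
4. **Inhibitory-connection detection** from spike-train cross-correlograms
   (CCGs).
5. **Electrophysiological cell typing** from six intrinsic features via PCA
   and a Gaussian-mixture model (GMM) with soft assignment.

Because every stage is a cascade of hard thresholds, the package ships a
synthetic-recording generator that emulates the statistical structure of
such recordings *with known ground truth*, so the whole pipeline is testable
end to end without any experimental data.

## The in vivo upstate detector

The detection signal is the LFP of the channel with the highest baseline
standard deviation (larger deflections give better detection; slow
oscillations are near-synchronous across nearby channels, so channel
position carries little additional information), band-passed to the delta
band (0.5–4 Hz) with a 3rd-order Butterworth applied forward and backward.
Zero-phase filtering matters: a causal filter would lag-shift every detected
boundary.

Two dynamic thresholds are formed,

$$a = m + 1.5\,\sigma, \qquad b = m + 0.8\,\sigma,$$

where $\sigma$ is the standard deviation of the delta-band trace over the
baseline window (the first five minutes of the recording) and $m$ is its
centered 60 s moving median. The median, unlike a moving mean, ignores the
upstates themselves and tracks slow non-stationarities (electrode drift,
state changes). $\sigma$ is computed on the same filtered trace the
thresholds are applied to, so the formula is dimensionally coherent.

Candidates are maximal runs of samples with signal $> a$, processed in this
order:

1. **Deletion** — candidates shorter than 200 ms are removed ("shorter
   than" is strict: a 200 ms candidate survives).
2. **Merging** — consecutive candidates separated by less than 300 ms are
   joined, transitively, left to right.
3. **Splitting** — if the signal inside a candidate dips below $b$ and
   re-crosses it (a down-crossing followed by an up-crossing), the
   candidate is split at the midpoint of the two crossings; $n$ dips
   produce $n$ splits. Fragments are re-checked against the 200 ms minimum.
4. **Confirmation** — population spike activity, pooled across units in
   contiguous 100 ms windows, must exceed its baseline mean by more than
   one baseline SD in at least one window overlapping the candidate.

Per event the package reports duration, peak, and *area* — the integral of
the detection signal above $m$, clipped at zero, over the event
(signal-units·s). Referencing the area to the moving median makes it
invariant to baseline drift.

Deliberate conventions, stated so the rules are bit-reproducible: candidate
thresholding uses strict `>` at $a$; a dip must lie strictly inside the
candidate; with multiple dips each split point is the midpoint of that
dip's crossing pair; "overlap" with a population window means any nonzero
time intersection; the confirmation threshold is *mean + 1σ* of the
baseline population rate (a bare 1σ without centering would be
scale-dependent); baseline σ is never recomputed after drug application.

### Moving-median edges

Within the first and last half-windows the moving median carries the
nearest full-window median outward (constant extension). Exact shrinking
centered windows would cost $O(k^2)$ at a 60 s window and kilohertz rates —
minutes per trace — while differing from constant extension only in the
outer 30 s, where the baseline is stationary by construction.

## The in vitro detector

Intracellular upstates are fast square depolarizations riding on synaptic
noise and upstate-locked gamma. Each input signal is therefore low-passed
at 10 Hz (zero-phase, below the gamma band) before thresholding — without
this, noise fragments each plateau into many sub-200 ms runs which the
deletion step (which precedes merging) would discard wholesale. Delta
band-passing, appropriate for the in vivo LFP, is *not* used here because
its 0.5 Hz high-pass cannot represent a sustained plateau.

The same candidate machinery (thresholds with the in vivo multipliers
1.5/0.8, deletion, merging, splitting) runs independently on both signals,
with σ from the first 60 s of each trace; a candidate from the primary
signal is kept iff it overlaps a candidate from the secondary. For
single-cell recordings the secondary signal is the amplitude envelope
(analytic-signal magnitude) of the 50–250 Hz gamma band, since upstates
carry elevated gamma power.

## Unit quality control and classification

A unit passes QC when

* inter-spike intervals shorter than 2 ms are fewer than 5% of all
  intervals, and
* the estimated fraction of spikes lost below the detection threshold is
  under 15%.

The missing fraction is read from a Gaussian fitted to the spike-amplitude
histogram by least squares, evaluated below the smallest observed
amplitude. The histogram fit (rather than moment matching) is essential:
for a threshold-truncated amplitude distribution the sample moments are
biased into the observed range, while the histogram over that range still
constrains the full Gaussian — an upper-half-normal correctly yields a
missing fraction near 50%. Units with fewer than 50 spikes fail QC
outright; a Gaussian fit to fewer amplitudes is not meaningful.

Units with negative-trough waveforms are classified by TP latency — the
time from the global trough to the subsequent global maximum of the mean
waveform: putative excitatory above 0.55 ms, putative inhibitory below.
The probability-zero tie at exactly 0.55 ms is assigned to the inhibitory
class so the rule is deterministic. The repolarization time is measured
from the post-trough peak to its decay to half amplitude, a criterion
robust to noise in the waveform tail.

A unit is *activated* when its firing rate in the 25 min after drug
injection exceeds the baseline mean by more than 2 baseline SDs for a
cumulative total of at least 5 min. Rates are binned at 60 s; the baseline
is the 10 min preceding the injection; suprathreshold bins need not be
consecutive (the weaker reading of "for at least 5 min", stated
explicitly). All four quantities are configuration fields
(`response_config()`). The decision is invariant to rescaling all rates,
since mean and SD scale together.

## Inhibitory-connection detection

Units with overall rates below 0.3 spikes/s are discarded. For each ordered
pair the CCG is computed in centered 1 ms bins over ±50 ms (bin $c$ covers
$[c-0.5, c+0.5)$ ms), unsmoothed, with the zero-lag bin included. A
screening stage ranks, per presynaptic unit, all pairs by an inhibition
strength score and retains the top 20 for classification; the default
scorer is the relative CCG deficit $1 - \overline{x}_{4\ldots9\,\mathrm{ms}}
/ \overline{x}$, and the scorer is a pluggable function argument so other
screening statistics can be substituted. Screening only prunes candidates
— the scientific decision is the classification rule:

> a connection is inhibitory iff the CCG counts $x$ satisfy
> $x < \mathrm{mean}(x) - \mathrm{sd}(x)$ in at least four consecutive
> bins among the six bins centered at 4–9 ms.

Mean and SD are over the full ±50 ms correlogram. A flat correlogram
(SD = 0) is never inhibitory and is flagged degenerate. No jitter or
shuffle correction is applied; the rule operates on the raw CCG. The ±50 ms
span comfortably contains the test window while giving mean and SD enough
mass to be stable.

## Electrophysiological cell typing

Six intrinsic features — input resistance (MΩ), ΔAHP (mV, the depth of the
after-hyperpolarization below spike threshold), sag (unitless ratio
(peak − steady-state)/peak of the hyperpolarizing deflection), rheobase
(pA), spike width (ms, at half amplitude), and resting potential (mV) —
are z-scored and projected onto the first two principal components.
Z-scoring is necessary: the features span MΩ–pA–mV scales and unscaled PCA
would be dominated by rheobase.

A three-component Gaussian mixture with diagonal, component-specific
covariances is fitted by EM (via `mclust`), initialized from a k-means
partition seeded at the centroid geometry (5, 0), (−15, −15), (−15, 10) —
one cluster on the positive first axis, two on the negative side split by
the second axis. Those coordinates presuppose a feature scaling that is
not recoverable, so the seed triangle is affinely rescaled onto the span of
the projected data; exact numeric reproduction of any particular PCA space
is deliberately not attempted. If a seed captures no points, a
deterministic maximin fallback re-seeds k-means. Components are mapped to
labels by their mean feature signatures: the widest-spike component is
putative excitatory; of the remaining two, the one with higher rheobase
and lower input resistance is fast-spiking (FS), the other low-threshold
spiking (LTS). Fits without genuine three-cluster structure (by BIC
against a single diagonal Gaussian, or with an empty component) are
rejected as degenerate.

Assignment is soft: each cell's posterior over the three components is
computed and the cell is labelled by the maximum posterior only when it
reaches 90%; otherwise it is `unassigned` and intended to be excluded from
downstream analysis. Raising the threshold can only shrink the assigned
set.

## The synthetic-recording generator

`sim_params()` defines the study conditions; all sub-generators derive
child seeds deterministically from one global seed, so identical parameters
give bit-identical data.

* **State sequence.** Alternating down/up dwells from gamma distributions
  (shape > 1 avoids implausibly brief states; hard floors of 0.5/0.3 s are
  enforced by rejection). Defaults: up 0.45 s (shape 16), down 3.5 s
  (shape 4), ≈ 14 upstates/min — a 0.25 Hz cycle, within the sub-1 Hz
  slow-oscillation regime. Two constraints pin this choice: the delta
  band's 0.5 Hz high-pass cannot represent plateaus much longer than
  ~0.65 s, so up-dwells are kept stereotyped; and the baseline σ that sets
  the detection threshold grows with upstate duty, so at duty ≳ 1/3 the
  threshold climbs to ~0.8 of the deflection peak and short upstates fall
  below the 200 ms deletion rule no matter the amplitude.
* **LFP.** Per channel, 1/f background noise (unit SD, spectral exponent
  1), plus a shared per-upstate delta-band deflection and upstate-gated
  gamma, scaled by per-channel gains so channel selection is non-trivial.
  Each upstate's deflection is the zero-phase delta-band response of its
  own boxcar (built from the band's step response), normalized to a fixed
  peak of 5 background SDs — the deflection lives entirely inside the
  detection band, so the detector's filter leaves it essentially unchanged
  and threshold crossings fall near the true edges.
* **Spiking.** Each unit is an inhomogeneous Poisson process with
  piecewise-constant rate: baseline per class (Exc 3, Int 8, activated
  3 spikes/s), × 5 inside upstates, × drug multipliers after drug onset
  (non-activated 0.2, activated 3). Post-drug upstates are additionally
  thinned by the incidence multiplier. Class labels are an exact rounded
  composition of the mixture (randomly permuted), so planted fractions are
  reproduced exactly.
* **Waveforms.** Biphasic raised-cosine templates at 20 kHz with the
  trough and peak planted on sample positions, so measured TP latency
  equals the planted value to within one sample. Excitatory latencies are
  planted above 0.55 ms, inhibitory below, activated intermediate
  (0.40–0.75 ms), giving the bimodal TP distribution with an intermediate
  activated group.
* **Couplings.** Inhibition is implemented by thinning: each postsynaptic
  spike within (delay, delay + window) after any presynaptic spike is
  deleted with the suppression probability, so planted suppression maps
  directly onto a CCG trough at the planted lag (default 5 ms delay, 4 ms
  window, suppression 0.8, 10 spikes/s, 1200 s).
* **Intrinsic features.** Per-class diagonal multivariate normals whose
  means follow the qualitative phenotype profiles (Exc: wide spikes, low
  AHP, low rheobase; FS: low input resistance, high rheobase; LTS: high
  input resistance, sag, and AHP). `simulate_current_steps()` additionally
  builds analytic voltage traces from planted features so the feature
  extractor itself can be validated. `generate_boundary_cohort()` plants
  one cell exactly on the fitted model's decision boundary between the two
  closest components (posterior 0.5 by construction, found by bisection in
  PCA space and mapped back to feature space), providing a deterministic
  one-cell-excluded fixture.
* **Intracellular pairs.** Both membrane potentials depolarize 10 mV
  inside every ground-truth upstate, with independent 1 mV white noise and
  upstate-gated 50–250 Hz activity.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: spike sorting artifacts and drift,
electrode geometry and volume conduction, travelling-wave latencies across
channels, non-Poisson spike statistics (bursting, refractoriness beyond
the QC fixture), state-dependent waveform changes, line noise and movement
artifacts, and biophysical mechanisms of upstate generation. Recovery
figures quantify the *internal consistency* of the rules against the
stated generative structure, not field performance.

## Numerical choices and degenerate inputs

* Filters: 3rd-order Butterworth, forward–backward (`signal::filtfilt`).
* Envelope: analytic-signal magnitude via FFT.
* Band power: Welch periodogram, 4 s Hann segments, 50% overlap —
  resolving 0.5 Hz while averaging noise; bands are half-open `(low,
  high]` so disjoint bands sum exactly to their union. The
  theta band is fixed at 4–12 Hz for rodent LFP summaries.
* Interval arithmetic uses a 1 ns guard so sample-derived durations
  compare exactly at the stated boundaries (199 ms deleted / 200 ms kept;
  299 ms merged / 301 ms not).
* EM convergence: relative log-likelihood change < 1e−6 or 500 iterations.
* Degenerate inputs fail loudly and specifically: recordings shorter than
  the baseline, bands beyond Nyquist, empty spike trains, flat CCGs,
  zero-σ baselines (flagged, not silently passed), mixtures without
  cluster structure, and cells with no rheobase (excluded).

## Problem sizes

The shipped tests run the detector on ten 600 s recordings at 500 Hz, the
equivalence suite on one hundred 100 s signals against a literal
sample-by-sample reference, connectivity on thirty 1200 s pairs, and cell
typing on 48–49-cell cohorts — sizes chosen so the full suite completes in
well under a minute of detector time while leaving the statistical checks
(4 SD Poisson bands, F1 ≥ 0.9, ≤ 5% false positives) meaningful.

## Known limitations

* The detector's boundary accuracy for upstates longer than ~0.65 s is
  limited by the delta band itself; real long upstates will be reported
  with conservative (inward) end times.
* The top-20 screening is per presynaptic unit (following the sorted
  per-unit connectivity-vector reading); a global ranking is a one-line
  scorer change.
* The GMM label map assumes the three phenotypes are present; cohorts
  dominated by one class are rejected rather than force-labelled.
* `area` of an upstate depends on the detection signal's units and is
  meaningful for within-recording contrasts (e.g. pre/post drug), not
  across rigs.

## A minimal run

```{r example, eval = FALSE}
p <- sim_params(seed = 1, drug_onset_s = 300, drug_incidence_mult = 0.1)
rec <- generate_so_recording(p)
ch <- select_detection_channel(rec$lfp, rec$lfp_fs)
pop <- population_rate(rec$trains, 0.1, 0, p$duration_s)
ev <- detect_upstates_invivo(so_ts(rec$lfp[, ch], rec$lfp_fs), pop)
match_intervals(ev, rec$truth$upstate_intervals)$f1
upstate_metrics(ev, c(0, 300))$incidence_per_min      # pre-drug
upstate_metrics(ev, c(300, 600))$incidence_per_min    # post-drug
```

The full pipeline, with tables and a reproducibility manifest, is
`run_pipeline(pipeline_config(...), out_dir)`; see the README for a worked
example with output.
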