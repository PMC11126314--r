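---
title: "Building and evaluating iEEG functional-connectivity pipelines"
author: "ieegfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating iEEG functional-connectivity pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegfc)
```

## The problem

Interictal intracranial EEG (iEEG) networks are built by choosing a
re-referencing scheme and a statistical measure of association between
channel pairs. Both choices vary widely across studies, and they are not
innocuous: the recording (machine) reference is a shared additive signal
on every channel, so uncorrected recordings carry spurious inter-channel
coupling; different association measures respond differently to
incomplete electrode sampling; and the clinical utility of the resulting
networks — for instance, lateralizing the seizure onset zone (SOZ) in
temporal lobe epilepsy — depends on both choices. `ieegfc` implements a
complete benchmark of 48 pre-processing pipelines: {common average (CAR),
bipolar (BR)} references crossed with 24 connectivity methods (Pearson r,
squared Pearson, cross-correlation, and coherence, phase locking value
(PLV) and relative entropy (RE) in seven canonical bands), plus the four
evaluation axes: pipeline similarity and clustering, subsampling
reliability, spurious-correlation simulation, and SOZ lateralization.

## Signal model and cleaning

Recordings are channels x samples voltage matrices (`IEEGRecording`).
Cleaning follows the standard interictal workflow:

* **Notch filter.** Fourth-order IIR Butterworth band-stop centred at
  60 Hz with a 2 Hz stop band, applied forward-backward. The zero-phase
  realization is a deliberate choice: a causal notch would impose a
  montage-dependent phase signature that biases phase-based measures
  (PLV).
* **Band-pass.** Fourth-order Butterworth (order-2 prototype, 4 poles),
  forward-backward. For low sampling rates the ripple band (80-250 Hz)
  exceeds Nyquist; the upper edge is clipped to 0.9 x Nyquist with a
  warning rather than failing, because discarding the band entirely would
  silently change the pipeline enumeration.
* **Artifact rejection.** Two explicit, configurable rules: absolute
  amplitude above `ampThreshUv` (default 500 uV) in more than 1% of
  samples, or 60 Hz band power above `lineRatioThresh` (default 0.5)
  times broadband power. These defaults are pragmatic configuration
  values, not claims about any clinical dataset; both are surfaced as
  arguments and logged in the rejection report.
* **Epoch selection.** Five random non-overlapping 2-minute epochs inside
  a 13:00-15:00 local-time window, drawn by rejection sampling from a
  mandatory seed. Contacts localized to cerebrospinal fluid are excluded
  up front (`tissue = "csf"` implies `retained = FALSE`).

## Montage algebra

CAR subtracts the per-sample mean of the retained grey/white channels;
bipolar referencing pairs each retained contact with the next retained
contact on the same electrode, allowing one skipped (missing) contact by
default (`maxSkip = 1`, so `LA01-LA03` is formed when LA02 was rejected).
Polarity is fixed as lower-index minus higher-index; the sign only matters
for signed Pearson and is documented rather than configurable. Both
montages cancel any signal that is common to all channels exactly, which
is the mathematical basis of the spurious-correlation experiment below.

## Connectivity estimators

All measures are computed in non-overlapping 2-s windows (a 120-s epoch
gives 60 windows) and averaged across windows, then element-wise across
the five epochs. Choices worth calling out:

* **Coherence** averages Hann-tapered auto-/cross-spectra across all
  windows of an epoch before forming |Sxy|^2/(Sxx Syy). This is the one
  place the 2-s windowing cannot be taken literally per window: coherence
  of a single segment is identically 1, so spectra must be pooled. The
  segment length is configurable (the simulation module uses 0.25-s
  segments at 50% overlap).
* **Cross-correlation** takes the maximum absolute normalized
  cross-correlation over lags up to 200 ms, normalized by the window
  standard deviations and the overlap length, so the value lies in
  [0, 1]; the sign is discarded.
* **PLV** uses the analytic-signal phase of the band-passed signal;
  per-window PLV is the modulus of the mean phase-difference phasor.
* **Relative entropy** histograms the two band-passed amplitude
  distributions into 10 equal-width bins spanning the pooled pair range,
  smooths counts by one half, and reports the larger of the two KL
  directions (RE is asymmetric). Bin count, smoothing and log base are
  configuration; the published description of the measure does not pin
  them down. RE is the one measure that ignores temporal structure
  entirely — permuting samples leaves it unchanged — and higher RE means
  *lower* functional connectivity.
* Pairs undefined in every window (zero variance) carry `NA` and are
  dropped from downstream edge vectors.

Scale invariance: Pearson, cross-correlation, coherence and PLV are
invariant to positive per-channel rescaling; RE is not (its histogram
edges move), which is exactly the property the synthetic SOZ planting
exploits.

## Pipeline similarity, clustering, stability, embedding

Edge vectors are extracted in a canonical node order with bipolar nodes
identified by their *anchor* (lower-numbered parent) contact, so CAR and
bipolar networks align on the shared contact set. This anchor
identification is the largest interpretive decision in the package — the
alternative of spreading bipolar values over both parents is isolated
behind the network's `anchors` slot so it can be swapped. Pipeline
similarity is the Pearson correlation of aligned edge vectors per
patient, averaged (plain mean, no Fisher z) across patients.

Clustering is agglomerative with average linkage on 1 - r; the linkage
and distance are our choices since hierarchical clustering alone does not
fix them. Cluster stability follows the bootstrap scheme: reference
clustering on the full cohort mean, patient resampling with replacement
(1000 resamples; 20 during k selection), per-cluster maximum Jaccard
overlap against the reference, averaged over resamples. Resampling
patients (not edges) is our documented reading. The 2-D embedding is an
exact t-SNE (perplexity 10 by default, learning rate 20, 4x early
exaggeration for the first 50 iterations) on 1 - r distances,
deterministic given a seed.

## Subsampling reliability

For each network, a fraction (20/40/60/80%) of channels is removed
uniformly at random, 1000 times, and node strengths (sums of absolute
edge weights; absolute so signed Pearson and RE are comparable) are
recorded for the retained channels. Reliability is R = sigmaT / (sigmaT +
sigmaE), where sigmaE is the strength variance of a channel across the
iterations in which it was retained (averaged over channels) and sigmaT
is the across-channel variance within an iteration (averaged over
iterations). Because channels are removed, no strength exists for a
removed channel in that iteration; conditioning on retained iterations is
our documented choice. In exhaustive mode (small networks) the
enumeration of all subsets is treated as the complete sampling
population, so across-subset variances use the population denominator;
this makes the sampled estimator converge to the exhaustive value.
If both variance components vanish (e.g. all-equal edge weights, where
every equal-sized subset gives every node the same strength), R is
reported as undefined with a warning. Group comparisons use a paired
Wilcoxon signed-rank test (two references) or a Friedman test with
Dunn-Sidak post hoc pairwise z-tests on mean ranks (measures, bands).

## The spurious-correlation experiment

Eight contacts of one depth electrode are simulated as unit-variance
Gaussian white sources plus a shared reference source of variance 1/3,
for 100 trials of 2 s at 512 Hz. The shared term induces pairwise
correlation (1/3)/(1 + 1/3) = 0.25 between observed channels. Closed
forms then predict the whole experiment:

* machine reference, all pairs: 0.25;
* CAR: mean subtraction of n i.i.d. channels induces -1/(n-1) = -0.143;
* bipolar derivatives sharing a parent: corr(s2-s1, s3-s2) = -1/2;
* bipolar derivatives sharing no parent: zero, so the estimate sits at
  the estimator's noise floor.

Magnitude coherence (the square root of magnitude-squared coherence) is
the reported scale for this experiment because it converges to |corr| for
white signals, matching those closed forms; a `squared` flag restores
MSC. The reference variance of 1/3 is the calibration that puts the
machine-reference level at 0.25; Hann 0.25-s segments at 50% overlap
pooled over trials put the zero-coherence floor near 0.027 with roughly
1500 pooled segments. In correlated mode the latent sources receive the
correlation exp(-|i-j|) through the covariance square root (imposed on
the source correlation, not on a mixing matrix; the mixing-matrix variant
of the published simulator is not restated anywhere we can verify, so our
parameterization is calibrated, not claimed identical — its point values
in correlated mode are therefore checked as orderings, not magnitudes).
Paired t-tests between schemes pair strata by sorted position truncated
to the shorter stratum, reproducing the degrees of freedom conventions of
the original analysis (6 bipolar vs 7 original adjacent pairs gives
df = 5).

```{r spurious}
res <- runReferenceSimulation(simConfig(seed = 1))
c(machine = res$machine$overallMean, car = res$car$overallMean,
  bipolarAdjacent = res$bipolar$adjacentMean,
  bipolarNonAdjacent = res$bipolar$nonAdjacentMean)
```

## SOZ lateralization

Only contacts with a mirrored contralateral counterpart (LA01 <-> RA01)
enter the analysis, controlling for anatomical coverage asymmetries.
Hemisphere connectivity is the mean over within-side edges only
(cross-hemisphere edges excluded — averaging "within a lobe" implies
intra-lobe edges; the switch is localized in `hemisphereConnectivity`).
Per pipeline, a paired t-test compares SOZ-side and contralateral values
across patients; p-values are Benjamini-Hochberg adjusted across the
pipeline family (48 by default), and the paired Cohen's d is
mean(diff)/sd(diff).

## The synthetic cohort generator

The generator emulates the study's data model with known ground truth:
mirrored bilateral SEEG montages (<= 3 electrodes x <= 12 contacts per
hemisphere, <= 72 channels), pink 1/f background, band-limited (4-30 Hz)
shared oscillations, exp(-corrDecay x distance) within-electrode
correlation imposed on both components through a covariance square root,
a common pink reference source (default variance one third of the channel
variance, mirroring the simulation calibration), biphasic spike
transients (70 ms sharp + 300 ms slow wave — a morphological stand-in,
not a validated spike model), optional line-noise artifact channels, and
per-channel target SD 50 uV (a typical interictal iEEG scale).

Hemispheric asymmetries are measure-family-targeted so recovery tests can
discriminate pipelines: the RE planting applies per-channel
*multiplicative amplitude gains* (lognormal, `reGainSd`) on the SOZ side.
Constant gains leave every scale-invariant measure (Pearson,
cross-correlation, coherence, PLV) untouched at the pair level while
separating amplitude distributions, hence elevating RE — the same
direction as the clinical finding that RE is higher (connectivity lower)
in the SOZ hemisphere. A `cohGainFactor` scales the oscillatory coupling
on the SOZ side for coupling-targeted plantings. With montages of two
electrodes per hemisphere the gain planting leaks only negligibly into
montage-mixed correlations; a single-electrode hemisphere concentrates
all pairs within one electrode and makes the leakage measurable, which is
why the recovery tests use 2 x 4-contact montages.

For clustering-recovery tests, `simulatePipelineFamilies()` plants the
empirically observed three-family similarity structure (RE pipelines /
CAR non-RE / bipolar non-RE) directly at the edge-vector level with
latent family factors: real iEEG produces that structure through signal
properties no tractable generator reproduces faithfully, so the planted
construction provides exact ground truth for the similarity -> clustering
path while exercising the real alignment and clustering code.

What passing these tests shows — and does not show: the synthetic cohort
has stationary Gaussian-mixture statistics, no sleep/wake structure, no
true epileptic dynamics and no volume conduction; recovery results
validate the estimators and the statistical machinery, not clinical
performance.

## Problem sizes and numerical choices

Test and recovery runs use deliberately small problem sizes chosen as the
package's own test conditions: cohorts of 16 channels (2 electrodes x 4
contacts per hemisphere), two 16-s epochs at 256 Hz, planted gain spread
`reGainSd = 0.07` (producing a medium-to-large paired effect, in the
range reported clinically), 20 patients, 5 generator seeds. Generator
defaults retain the canonical conditions (five 2-minute epochs, 512 Hz).
Numerical details: histogram degenerate ranges (constant signals) return
RE = 0; zero-variance windows are excluded pairwise from window averages;
PLV phasors are normalized with a floor at machine epsilon; the t-SNE
gradient descent uses momentum 0.5 -> 0.8 at iteration 250 with adaptive
gains clipped at 0.01.

## Known limitations

* The RE positivity transform `1/(1+x)` follows a source description
  whose typesetting is ambiguous; it is implemented as the documented
  monotone-decreasing map and exposed via `transformRE`.
* Correlated-mode point values of the reference simulation depend on
  unpublished mixing internals and are validated as orderings only.
* EDF support covers continuous 16-bit recordings with a common integer
  sampling rate; EDF+ annotations are not parsed.
* Directed connectivity (partial directed coherence, Granger causality)
  is deliberately out of scope.
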