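---
title: "Ictal MEG source imaging and band-limited connectivity: methods"
author: "ictalmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ictal MEG source imaging and band-limited connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

Childhood absence epilepsy presents with 3--4 Hz generalized spike--wave
discharges (GSWDs). `ictalmeg` implements an ictal-MEG analysis chain for
comparing children who later respond to antiepileptic drugs with those who
do not: artifact rejection and decomposition of sensor signals into six
frequency bands (1--4, 4--8, 8--12, 12--30, 30--80, 80--250 Hz), automatic
extraction of ictal segments (first spike to last slow wave, at least 3 s),
LCMV beamforming over a volumetric grid, *accumulated source imaging* (ASI)
-- the per-voxel sum of source activity over the segment,
$\mathrm{Asi}(r) = \sum_{t=1}^{n} |Q(r,t)|$ -- predominant-region
assignment via a 13-label atlas, all-pairs virtual-sensor correlation
networks thresholded at the t value of the correlation coefficient,
$T_p = R\sqrt{K-2}/\sqrt{1-R^2}$ at $p<0.05$, and group statistics: Fisher
exact tests of region-by-group contingency tables with Bonferroni
correction across the six bands ($0.05/6 = 0.0083$), plus clinical
mean-$\pm$-SD summaries with equal-variance two-tailed t tests. Because no
recordings of the original cohort are redistributable, the package ships a
synthetic generator with known ground truth, so that every stage is
testable end to end.

## The synthetic generator and what it emulates

`simulate_recording()` places current-dipole sources in a homogeneous
conducting sphere (Sarvas closed form; radial moments are exactly silent)
under a quasi-uniform radial-magnetometer helmet. During seizure windows
each source emits a spike--wave train: a 70 ms biphasic spike followed by a
250 ms half-sine slow wave, repeated at 3 Hz with ~15% per-cycle amplitude
jitter, band-limited to `source_band` (default 1--40 Hz, which covers the
spike transient and the 3 Hz harmonics that give the discharge its energy
in the alpha band). Outside the windows there is only 1/f Gaussian
background at `noise_sd` (default 50 fT per channel). With the default
sensor SNR of 5 the discharge peaks near 2 pT -- the scale of real ictal
GSWDs and safely below the 6 pT artifact criterion. Sources share a common
train in proportion to a `coupling` coefficient, so the pairwise
correlation of source time courses is approximately that coefficient
(generalized discharges being near-synchronous, the default is 0.9; the
underlying synchrony model is a package choice, since inter-source coupling
during seizures is not otherwise constrained).

`make_cohort()` draws one dominant source per patient. Nonresponders place
it in the medial frontal cortex (MFC) with probability 0.7, responders with
probability 0.05, mirroring the 7/11-vs-0/13 contrast the analysis is built
to detect; `cohort_effect(strength = 0)` collapses both groups onto one
placement distribution for null calibration. Clinical covariates are drawn
at cohort scale (onset age discrete uniform on 4--10 y, seizure duration
$\sim \mathcal{N}(14.1, 4.7^2)$ s, follow-up centred on 29 months), and the
medication fields are generated so that `classify_response()` -- not a
stored label -- reproduces the intended group.

What the generator does *not* emulate: realistic anatomy (no MRI, BEM/FEM
head models, or subject-specific atlases), ocular/cardiac artifacts,
head movement, sensor gradiometry, and inter-ictal epochs with
physiological rhythms. Passing recovery tests therefore demonstrate the
correctness and calibration of the algorithms under the stated forward
model, not clinical performance on real recordings.

## Numerical choices

**Zero-phase band filtering.** The band-pass is the squared magnitude
response of a 4th-order analog Butterworth band-pass applied in the
frequency domain with odd-reflection padding. The squared response is
exactly what forward--backward (filtfilt) application of that Butterworth
filter produces, but the FFT route avoids the order-8 IIR polynomial,
which is numerically unstable in double precision for a 1--4 Hz band at
kilohertz rates (its roots cluster at $z = 1$). Bands containing 50 Hz are
additionally notched (2nd-order Butterworth band-stop, 48--52 Hz) so
power-line content never enters the analysis. Passband centre gain is
within a fraction of a percent of unity; the six bands tile 1--250 Hz
white-noise power to within 1%.

**Segment detection.** Spikes are local maxima of the 1--4 Hz global field
power above `median + 5 MAD`; runs of spikes with gaps up to
$1/(f_{\mathrm{SWD}}-1)$ s lasting at least 3 s become segments, ending
where the envelope falls back below threshold after the last spike (the
slow-wave offset). The 1--4 Hz pre-filter is applied *only* inside
detection; band analyses run on the raw segment. The deterministic detector
replaces expert visual marking and presumes discharges occupy a minority of
the recording (the baseline statistic is the median), which matches how
ictal epochs are excerpted in practice.

**Beamformer.** Scalar LCMV with diagonal loading at 5% of the mean sensor
variance. Per voxel the orientation solves a generalized eigenvalue problem
restricted to the non-silent lead-field subspace (the sphere model makes
radial moments silent; voxels with numerically zero lead fields, notably
the sphere centre, are flagged silent and output zero rather than blowing
up the unit-gain weights). The polarity of a reconstructed time course is
arbitrary -- a fixed sign convention makes runs reproducible, but
connection signs between reconstructed sources are only meaningful up to
that convention, which is why recovery tests judge edges on $|R|$.

**ASI accumulation.** The printed accumulation formula sums $Q(r,t)$;
summing a signed oscillatory time course cancels towards zero, so the
package defaults to accumulating $|Q(r,t)|$ and records the mode in every
map (`mode = "signed"` retains literal summation). Accumulation is over
the whole segment; the predominant location is the arg-max voxel (exact
ties broken by atlas priority, then voxel index). A cluster statistic was
considered and deliberately left out: with a 6 mm grid the arg-max is
already stable for the effect sizes of interest.

**Connectivity.** $K$ is the number of time samples of the analysed
segment; no autocorrelation correction is applied (a documented
simplification -- band-limited signals have fewer effective degrees of
freedom, so attained per-pair levels are anticonservative on strongly
autocorrelated data). Pairs are thresholded at $p<0.05$ each with no
correction across pairs; multiplicity is handled across bands at the group
level, as in the study design. All-pairs evaluation over a full ~17,000
voxel grid (~$1.5\times 10^8$ pairs) is disproportionate for routine runs,
so node selection defaults to the ROI's voxels plus the top 1% of ASI
strength, with `top_fraction` available for generic use.

**Group statistics.** `fisher_exact()` is the classical two-sided exact
test (sum of hypergeometric probabilities not exceeding the observed
table's, with a $1+10^{-7}$ tie slack), delegated to `stats::fisher.test`
and cross-checked in the tests against an independent binomial-coefficient
enumeration oracle. The t tests are equal-variance Student tests, the
stated "two-tailed t-test" made concrete. On sparse 11-vs-13 tables the
exact test is strongly conservative: the attained null rate at nominal
$\alpha = 0.05$ under the 0.05 placement probability is about $10^{-3}$,
and null p-values are discrete with most mass at 1. Calibration is
therefore validated as super-uniformity ($P(p \le a) \le a$) against an
exactly enumerated attained rate, not as uniformity of the p distribution.

## Problem sizes

Full-scale conditions are a 275-channel helmet, 6,000 Hz sampling and a
6 mm / ~17,000-voxel grid; every one of these is a parameter. The packaged
simulation studies run at desk scale: 1,000 Hz sampling (all six bands
remain below Nyquist), 24--64 channels, 15--24 mm grids for cohort studies
and a 6 mm grid over a 51 mm sphere for localization-accuracy checks; the
pipeline-recovery study uses 100 simulated 24-patient studies at 24
channels and an 18 mm grid. These sizes are the package's own choices for
routine verification and are stated alongside each result the test-suite
and acceptance script produce.

On the attainable recovery rate: with placement probabilities 0.7 vs 0.05
and 11 vs 13 patients, exact enumeration of both placement binomials puts
the ceiling of the Bonferroni-gated recovery rate at 0.788 under perfect
localization. Measured pipeline recovery lands near 0.85 because sources
placed in frontal voxels adjacent to the MFC box occasionally localize
into it, which raises the effective nonresponder MFC probability more than
the responder one. Both numbers are recomputed, never asserted as
constants.

## Known limitations

* The sphere forward model and box atlas are modelling devices; no claim
  of anatomical fidelity is made.
* The two-step, node-beam source reconstruction of the original software
  chain is not public; the package substitutes a standard LCMV scalar
  beamformer, which is well-posed and consistent with the ASI summation it
  feeds. Results depending on beamformer internals may differ.
* Connection signs of reconstructed sources are convention-dependent (see
  above).
* The group-level *network* comparison (which statistic produced the
  reported ripple-band difference is not specified) is exposed as
  per-patient ROI summary counts that can be fed to any test; the package
  does not claim to reproduce that specific p value.
* Recordings are stored in a self-describing text container rather than a
  binary scientific format; it round-trips bit-exactly and keeps the
  package dependency-free, at the cost of file size.
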