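---
title: "Multiscale EEG biomarkers of consciousness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale EEG biomarkers of consciousness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstates)
```

# Scope

`eegstates` computes the families of resting-state and perturbation-response
EEG biomarkers that are routinely compared across states of consciousness —
wakefulness, sedation and anesthesia, sleep stages, and disorders of
consciousness (minimally conscious state, MCS; unresponsive wakefulness
syndrome, UWS). The package covers six measurement families:

1. **Periodic activity** — windowed power spectral density, relative band
   power and band center frequency for delta (1–4 Hz), alpha (8–13 Hz) and
   low gamma (30–45 Hz), with regional and whole-brain topographic
   summaries.
2. **Aperiodic dynamics** — the autocorrelation window (ACW-50), detrended
   fluctuation analysis (DFA), and the 1/f spectral exponent fit between
   1 and 30 Hz with oscillatory-peak pruning.
3. **Temporal complexity** — Lempel-Ziv (LZ76) complexity, permutation
   entropy, and a disorder × disequilibrium product on the ordinal-pattern
   distribution.
4. **Connectivity and network topology** — permutation cross-mutual
   information (PCMI) and the phase lag index (PLI); proportional
   thresholding; clustering coefficient, characteristic path length and
   small-worldness against degree-preserving null networks; regional PCMI
   summaries over frontal / central / parieto-occipital partitions.
5. **Microstates** — GFP-peak extraction, polarity-invariant (modified)
   K-means, group-level templates, canonical A–D labeling, backfitting, and
   occurrence / duration / coverage statistics.
6. **Perturbation response** — PCA of the trial-averaged TMS-evoked
   response over 0–300 ms and the effective dimensionality (ED) of its
   correlation spectrum.

A seeded synthetic-data generator produces recordings with the statistical
structure each family measures, and a statistics harness reproduces the
group-comparison reporting conventions (paired/independent t, Wilcoxon
signed-rank/rank-sum, Benjamini–Hochberg FDR, four star levels).

# Data model and conventions

A recording is a channels × samples matrix in microvolts with a sampling
rate, ordered channel labels, a free-form state label and a subject id.
Time is in seconds; sample indices exposed to users are 0-based only where
an on-disk format requires it (the epochs' `onset_index`); windows are
half-open `[t0, t1)`. Channel labels follow the 10-20 system where
available, and a deterministic prefix rule partitions any montage into
frontal (`Fp/AF/F`), central (`FC/CP/C/T`) and parieto-occipital
(`TP/PO/P/O`) regions, with unmatched labels set aside as `other`. On the
standard 19-channel montage this yields a 7 / 7 / 5 split.

Because global field power and microstate topographies are
reference-dependent, the microstate pipeline (and any topographic step)
applies an average reference; the spectral, aperiodic, complexity and
connectivity families operate on the data as loaded.

The canonical on-disk format is a tab-separated channels × samples matrix
with a JSON sidecar (`fs`, `channel_labels`, `state_label`, `subject_id`,
plus `onset_index`/`n_trials` for epochs). A minimal 16-bit EDF
reader/writer is provided as a convenience; EDF round trips are exact up to
the 16-bit quantization of each channel's amplitude range.

# The measures

## Spectral features

`compute_psd()` averages modified periodograms over 10-s windows without
overlap (both printed conventions are the defaults; the trailing partial
window is discarded). Each window is mean-detrended to stop DC leakage into
the bins adjacent to 1 Hz, Hann-tapered with standard power normalization
(a rectangular taper is available for exactness checks), and the one-sided
PSD integrates to the signal variance within Parseval tolerance. Relative
band power divides the trapezoidal band integral by the integral over
1–45 Hz — the union span of the three analysis bands; the denominator is a
package choice, stated here because results depend on it. Band center
frequency is the in-band spectral centroid `sum(f P(f)) / sum(P(f))`; an
argmax-peak variant exists behind a flag. The centroid is used as the
default because it is defined for every spectrum and degrades gracefully
when no sharp peak exists.

## Aperiodic features

The **ACW** is the first lag at which the autocorrelation function (biased,
1/n-normalized, so `ACF(0) = 1`) falls strictly below 50% of its peak,
reported in seconds. The crossing is lag-quantized by design — no
sub-sample interpolation — because the definition is stated in lags.
Recordings are scored per 10-s segment and averaged; a segment whose ACF
never crosses within the horizon yields a flagged missing value. For an
AR(1) process with coefficient 0.9 sampled at 100 Hz the expected value is
exactly 7 lags (`0.9^7 < 0.5 < 0.9^6`), i.e. 0.07 s.

**DFA** cumulates the mean-removed signal, removes a least-squares line
from each non-overlapping window at 20 log-spaced scales from 16 samples to
n/4, and reports the slope of log RMS fluctuation against log scale.
White noise sits at 0.5, a random walk at 1.5, and `1/f^chi` noise at
`(chi + 1) / 2`.

The **1/f exponent** is fit in log10–log10 coordinates between 1 and 30 Hz
as a robust line with iterative peak pruning: bins whose positive residuals
exceed 2.5 robust standard deviations (1.4826 × MAD) are flagged as
oscillatory and excluded, and the line is refit until the flagged set
stabilizes (at most 10 iterations). The exponent is the negative slope, so
steeper low-frequency dominance is a larger exponent. The model has no
"knee" term: over 1–30 Hz a single slope is the standard operating regime,
and a knee would be unidentifiable at the 0.1 Hz resolution of 10-s
windows. The fit is applied per channel and averaged afterwards, rather
than fit once on an averaged spectrum.

## Complexity

LZ76 counts the productions of the exhaustive-history parse
(Kaspar–Schuster recursion) of the median-binarized signal (strictly above
the median is 1; ties fall to 0) and normalizes by `n / log_alpha(n)`, the
asymptotic rate of a random sequence. Permutation entropy is the Shannon
entropy of the ordinal-pattern distribution over `log(m!)`, with embedding
`m = 3, tau = 1` by default; patterns are encoded as the lexicographic rank
of the stable argsort, with ties broken by order of occurrence. Both are
exactly invariant under strictly monotone amplitude transforms. The
disorder × disequilibrium product multiplies normalized entropy by the
squared Euclidean distance of the distribution from uniformity; it vanishes
at both extremes (uniform and degenerate) and peaks between order and
randomness. It is computed on the ordinal distribution with `m = 4` by
default — a slightly richer alphabet gives the disequilibrium term more
resolution — and this operationalization is one admissible reading of the
disorder-times-disequilibrium family rather than a uniquely defined
estimator.

## Connectivity and graphs

**PCMI** symbolizes both channels into ordinal patterns and takes the
mutual information between the symbol streams, maximized over signed
cross-lags up to `max_lag` (10 samples by default), with a Miller–Madow
bias correction so independent channels score near zero bits. Maximizing
over the two directions of each lag (rather than averaging them) keeps the
measure symmetric in its arguments while letting a pure delayed copy reach
the self-information ceiling. PCMI is computed broadband by default, with
a band option. **PLI** band-passes with a zero-phase FIR filter (alpha by
default), takes analytic-signal phases, and reports
`|mean(sign(sin(dphi)))|`, which discards zero-lag coupling by
construction.

Graph metrics operate on proportionally thresholded binary graphs: the top
`ceil(density × K)` of the `K = n(n-1)/2` weights are kept, ties broken by
stable index order. The display convention for connection maps is the
strongest 5%; metrics default to density 0.15 and are also emitted across a
0.05–0.30 sweep so no single threshold carries the conclusion. The
clustering coefficient is the mean local triangle density (degree < 2
contributes 0); the characteristic path length is the mean geodesic over
the largest connected component, flagged when the graph is disconnected —
a convention chosen over infinite-path definitions for stability at low
densities. Small-worldness is
`sigma = (C / C_rand) / (L / L_rand)` with null statistics averaged over
100 degree-preserving double-edge-swap rewirings (10 × edges swaps each);
Erdős–Rényi graphs score approximately 1 under this construction, which is
the calibration the acceptance script recomputes. The graph machinery
delegates to igraph; the test suite holds it to exact agreement with
brute-force triangle counting and Floyd–Warshall path lengths on small
graphs.

## Microstates

Clustering is performed on GFP-peak maps only — the standard practice,
since peak maps have the highest topographic signal-to-noise — and
backfitting labels every sample. The modified K-means treats a map and its
negation as identical: assignment maximizes squared spatial correlation and
template updates take the first principal axis of the assigned maps.
Restarts (20 by default) keep the highest global explained variance.
Group-level templates are a second-level clustering of pooled
subject-level templates, computed per clinical group, and then matched
across groups by canonical labeling. The canonical A–D maps are synthetic
dipolar patterns on standard 10-20 coordinates realizing the four classic
orientations (A: left-posterior to right-anterior; B: right-posterior to
left-anterior; C: anterior–posterior; D: central maximum); they are a
stand-in built from those orientation descriptions, not normative data, and
users can substitute their own canonical set. Labeling maximizes total
absolute spatial correlation over all 4! permutations. Backfit smoothing is
off by default (duration statistics are reported as measured); when a
minimum duration is requested, sub-threshold runs are merged whole into the
better-correlated flanking label, which terminates deterministically.
Statistics follow the run-based definitions: occurrence is runs per second,
duration is dwell samples per run, coverage is the dwell fraction of all
samples.

## Evoked response

The trial-averaged, baseline-corrected evoked response is decomposed over
the 0–300 ms post-stimulus window by eigendecomposition of the
channels × channels **correlation** matrix across in-window time points.
The correlation (not covariance) convention is what makes the
eigenvalue-greater-than-1 criterion meaningful: the average eigenvalue is
exactly 1, so "greater than 1" means "more variance than an average
standardized channel". ED is the count of eigenvalues strictly above 1
divided by the fraction of variance they explain; a rank-1 response gives
exactly 1, and ED never falls below the count itself. When no eigenvalue
exceeds 1 the value is 0 with a degeneracy flag rather than an error. ED is
computed on the trial-averaged evoked response per subject.

## Statistics

The harness mirrors the reporting conventions of state-contrast studies:
independent-sample comparisons use Welch t or Wilcoxon rank-sum;
within-subject designs use paired t or Wilcoxon signed-rank, matching
observations by subject id. Benjamini–Hochberg FDR is applied across
whatever family of (feature × channel) cells is passed in one call — family
scoping is deliberately the caller's choice, since published panels differ
in whether they correct across channels, features, or both. The step-up
adjustment is implemented directly and oracle-tested; the hypothesis tests
themselves delegate to the standard R implementations. Stars follow the
four-level convention (0.05, 0.01, 0.001, 0.0001) on adjusted p-values.

# The synthetic generator

The generator exists so that every analysis stage can be tested against
known ground truth. Its components:

* **Colored noise** shapes white Gaussian noise in the frequency domain by
  `f^(-chi/2)`, giving an exact expected log-log slope of `-chi` at
  O(n log n) cost.
* **Oscillations** are Gaussian-envelope narrowband processes (envelope SD
  = bandwidth/2); each channel receives an independent realization, so a
  posterior-weighted alpha rhythm raises posterior band power without
  making every channel pair mutually informative.
* **Coupling** adds a shared latent signal to a channel pair, delayed at
  one end — a construction aimed directly at mutual-information detectors,
  with the delay exercising the PCMI lag search. The latent is mildly
  colored (exponent ≈ 0.5–1 depending on preset) regardless of the
  background: a latent as smooth as a steep 1/f background is nearly
  invisible to ordinal symbolization, which operates on local sample
  rankings.
* **Microstate EEG** activates one template at a time with geometric
  (memoryless) run lengths at the requested mean, random per-segment
  polarity, and a sinusoidal activation envelope bounded away from zero so
  that no in-segment sample is noise-only; a fixed-length option supports
  exact-arithmetic tests. SNR is an RMS ratio.
* **Evoked epochs** build a rank-k mean from orthonormal spatial modes and
  smooth Gaussian-windowed oscillatory time courses confined to the
  post-stimulus window, plus i.i.d. trial noise.

## State presets

Three presets encode, as generator deltas, the directional group contrasts
the pipelines are expected to detect. Relative to the healthy-control-like
preset (`nor`: chi = 1.0, posterior-dominant alpha, modest delta), the
UWS-like preset has chi = 1.8 (longer intrinsic timescales and steeper 1/f),
raised delta and suppressed, flattened alpha, weaker coupling arranged as a
sparse chain with short chords — a topology with no triangle-closing edges
and long graph distances — a prolonged microstate-A dwell time (120 ms vs
80 ms), and a rank-1 evoked response. The `nor` coupling is a
ring-plus-chords-plus-shortcuts graph whose 26 edges exactly fill the 15%
proportional-threshold budget on 19 channels, so the thresholded graph is
clustered with short paths. The MCS-like preset sits between the two
(chi = 1.4, rank-3 evoked response). Because the underlying studies report
box plots rather than effect magnitudes, the preset deltas are chosen once
for reliable detectability at 20 subjects per group, not to match
unpublished magnitudes; cohort generation adds 5% log-normal subject
jitter, reused across states in paired designs.

What the generator does **not** emulate: volume conduction (couplings are
explicit and sparse), artifacts (ocular, muscular, electrode drift),
non-stationarity beyond microstate switching, realistic electrode-level
spatial correlation of background noise, and biophysical dynamics of any
kind. Passing tests on these fixtures therefore demonstrates that each
estimator recovers the statistical structure it targets at realistic
sample sizes and SNR — not that the pipeline is robust to the artifactual
structure of clinical recordings, which is a preprocessing concern outside
this package's scope.

# Numerical choices and degenerate inputs

* PSD windows shorter than the recording raise an error rather than
  padding; a trailing partial window is dropped.
* `fit_aperiodic()` refuses non-positive PSD bins and requires at least 5
  surviving bins; `R^2` is reported on the surviving bins.
* Ordinal symbolization warns when `m!` exceeds n/10 (undersampled
  alphabet); PCMI warns on the joint alphabet analogously.
* Proportional thresholding warns when all weights tie (the selection is
  then purely the stable tie-break).
* Zero-GFP samples are unassigned in backfitting; coverage counts them in
  the denominator.
* All-equal eigenvalues give ED = 0 with a degeneracy flag (strict
  inequality), not an error.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; fixed seeds give bit-identical outputs.

# Problem sizes used by the checks

The bundled checks run at sizes chosen to make their tolerances meaningful
on a single CPU: DFA calibration on 2×10^5 samples over 10 seeds;
small-world calibration on 20 Erdős–Rényi graphs (60 nodes, density 0.2,
100 surrogates each); exponent recovery on 2^16-sample recordings over 10
seeds per condition; and 20 replicate synthetic cohorts of 20 subjects per
state (60-s resting recordings at 100 Hz, 60-s microstate recordings at
250 Hz, 20-trial evoked sets at 1 kHz) for the directional contrasts.

# Known limitations

* The 1/f fitter assumes a single power-law regime over the fit range; no
  knee, and no separation of overlapping broadband components.
* ACW is lag-quantized; at low sampling rates short timescales saturate at
  one lag.
* PCMI's plug-in MI retains upward bias for strongly autocorrelated
  signals even after Miller–Madow correction; comparisons should be made
  at matched recording lengths.
* The canonical A–D maps are analytic stand-ins; label identities on real
  data should be checked against a normative set for the montage in use.
* Graph metrics on proportionally thresholded matrices depend on density;
  the sweep is emitted precisely so that readers can see threshold
  sensitivity.
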