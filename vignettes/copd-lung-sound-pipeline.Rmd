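---
title: "Grading COPD severity from multi-channel lung sounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading COPD severity from multi-channel lung sounds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdls)
```

## The problem

Chronic obstructive pulmonary disease is managed clinically in three
severity tiers -- mild, moderate, severe -- and tier assignment normally
requires spirometry, imaging or blood gas work. Auscultation is cheap and
non-invasive, and COPD patients produce continuous adventitious lung sounds
(wheezes and related phenomena) whose energy concentrates above 400 Hz.
`copdls` implements a complete decision pipeline that grades severity from
multi-channel posterior auscultation recordings alone:

1. **Synchronise and segment.** Each acquisition starts with a deliberate
   cough recorded on all channels; the cough peak aligns the channels and
   segmentation starts at the first inhalation after it. Segments are 15 s
   (60 000 samples at 4000 Hz), spanning two to three respiratory cycles.
2. **Filter and augment.** A 7.5 Hz first-order Butterworth high-pass
   removes DC offset; no low-pass is applied, to preserve the
   high-frequency adventitious band. Minority classes are balanced by
   replicating recordings with additive Gaussian noise
   (`x + 0.06 * N(0,1)`).
3. **Decompose.** Ensemble empirical mode decomposition (EEMD; noise
   standard deviation 0.015, ensemble of 100) splits each channel segment
   into 10 intrinsic mode functions (IMFs); modes beyond the tenth join the
   residual.
4. **Summarise.** Each IMF's Hilbert marginal spectrum `h(w)` -- the
   time-integrated instantaneous amplitude as a function of instantaneous
   frequency -- is reduced to 10 statistics (standard deviation, variance,
   kurtosis, maximum, median, mode, mean, minimum, energy, skewness):
   100 features per channel, 1200 for 12 channels.
5. **Select.** Features are min-max normalized to [0, 1], weighted by the
   multi-class reliefF filter, and negative-weight features dropped.
   Summing the retained weights per auscultation site ranks the channels;
   the classifier sees only the top-n features of the top-ranked channels.
6. **Classify.** A radial-basis SVM, with `(C, gamma)` chosen by stratified
   5-fold grid search on training data only, is evaluated over repeated
   stratified 70/30 splits (1000 by default), reporting accuracy,
   sensitivity, specificity, AUC, F1 and Cohen's kappa with 2.5--97.5
   percentile intervals. Multinomial naive Bayes and gradient-boosted trees
   run under the identical split stream as baselines.

The two clinical contrasts are binary: mild vs. moderate+severe, and
moderate vs. severe (see `binary_task()`).

## EMD and EEMD: numerical choices

EMD sifts an IMF out of the signal by repeatedly subtracting the mean of
the upper and lower extrema envelopes. Several details are left open by the
standard algorithm description and were fixed here as follows:

* **Envelopes.** Natural cubic splines through the local maxima (upper) and
  minima (lower). End effects are controlled by mirroring the two nearest
  extrema about each end of the signal before fitting the spline. Signals
  with fewer than 2 maxima or 2 minima are treated as monotone trends and
  stop the decomposition.
* **Stop criterion.** Sifting stops when the Cauchy criterion
  `sum((m_prev - m_cur)^2) / sum(m_prev^2) < 0.2` is met, with a hard cap
  of 50 sift iterations. The formal IMF conditions (extrema and
  zero-crossing counts differing by at most one, near-zero local mean) are
  folded into this criterion, as is standard practice, rather than tested
  per iteration. Both the threshold and the cap are arguments.
* **EEMD averaging.** Plain averaging of per-member IMFs (no paired
  positive/negative noise realisations). Members yielding fewer than
  `n_imf` modes contribute zeros in the missing modes; surplus modes fold
  into the residual. Reconstruction then differs from the input only by
  the mean of the ensemble noise, giving the RMS bound
  `noise_std / sqrt(ensemble_size)` that the tests check with a 3x margin.
* **Amplitude scale.** The common rule sets the ensemble noise near 0.2
  times the signal standard deviation; the default here is `noise_std =
  0.015` with the input standardised to unit variance first and rescaled
  after (`standardize = TRUE`). The standardisation choice is ours: it
  makes 0.015 meaningful regardless of recording gain. Both knobs are
  exposed.

The sifting core is compiled (Rcpp): an ensemble of 100 decompositions per
channel segment, across 12 channels and many recordings, is far outside
interpreted-loop territory, which is also why the established EMD
implementations in other ecosystems are compiled. The test suite contains
an independent pure-R EMD written against the same algorithm definition;
on autoregressive test signals the two agree to correlation > 0.95 on the
first three modes, and exact completeness (`sum(IMFs) + residual == input`)
is asserted to 1e-9 relative error on random signals.

## Hilbert spectral features

The analytic signal is computed by FFT (negative frequencies zeroed).
Instantaneous frequency is the forward difference of the unwrapped phase,
clipped to `[0, fs/2]`, with the last value repeated so all series keep the
segment length. The marginal spectrum accumulates `amplitude * dt` into
1 Hz bins from 0 to Nyquist (configurable); rebinning conserves total mass
exactly, which the tests assert.

The 10 statistics use population (divisor N) variance, non-excess kurtosis
(`E[((X-mu)/sigma)^4]`, so a Gaussian scores 3) and the matching skewness.
"Energy" is the sum of squared marginal-spectrum amplitudes. The printed
definition of the energy feature mixes time- and frequency-domain limits;
we read it as the total squared spectral amplitude, consistent with its use
as a per-IMF scalar feature, and separately expose the instantaneous energy
density `IE(t) = sum_i amplitude_i(t)^2` (`instantaneous_energy()`). Two
further decisions the definitions leave open: the **mode** of a continuous
amplitude vector is the centre of the tallest histogram bin under
Freedman--Diaconis widths with ties broken toward the lower bin, and the
statistics are computed on the **marginal-spectrum amplitudes** of each IMF
(the sequence "marginal spectrum of each IMF, then statistics per IMF");
`domain = "time"` switches to time-domain IMF statistics for comparison.

## ReliefF and channel ranking

The weight update follows the standard multi-class reliefF of Kononenko:
for each sampled instance, the k nearest hits pull each feature's weight
down by their mean absolute difference and the k nearest misses of every
other class push it up, weighted by `p(C)/(1 - p(class(R)))`. (Published
statements of the update sometimes write the miss term with the hit symbol;
the standard nearest-miss reading is implemented.) Neighbour search uses
Manhattan distance over all normalized features, consistent with the
absolute-difference `diff`; Euclidean is available. Defaults `m = n` (every
instance sampled once, in order -- making the weights deterministic) and
`k = 10` are conventional choices; the reference procedure does not report
its values. With `k = 1`, `m = n` and two balanced classes the update
provably reduces to classic binary relief, and the tests assert equality
with a brute-force relief implementation to 1e-12.

Channel ranking sums the **retained** (non-negative) weights per channel,
following the stated eliminate-then-sum order, and sorts descending with
ties broken by canonical channel-label order so the ranking is
deterministic.

## The synthetic generator

`generate_recording()` emulates exactly the structure the pipeline relies
on, nothing more:

* a 0.3 s broadband **cough burst** (Hann-windowed white noise, 10x the
  breath amplitude) shared across channels near the start -- only its role
  as the early energy maximum matters;
* **breath-cycle noise** on every channel: white noise band-passed to
  100--1000 Hz and amplitude-modulated at the breathing rate (16
  cycles/min default), the simplest signal with a realistic spectral
  spread, as no generative model of healthy lung sounds is prescribed;
* class-dependent sustained **adventitious tones above 400 Hz** added only
  on the class's affected channels (defaults: none for mild, 550 Hz at
  amplitude 0.15 for moderate, 750 Hz at 0.25 for severe, on L1--L4, vs. a
  breath amplitude of 0.2) -- class separation is deliberately controlled
  by this amplitude so tests can set their difficulty;
* a white **noise floor** (amplitude 0.01).

Defaults keep the acquisition protocol's conditions: 12 channels, 4000 Hz,
at least 17 s, cough at 1 s. What the generator does **not** emulate:
crackles and transient adventitious sounds, heart-sound contamination,
sensor coupling differences, inter-subject variability of the breath
spectrum, or any airflow physics. Passing tests therefore demonstrate that
the pipeline's machinery recovers planted spectral structure and
discriminates planted classes; they are not evidence about clinical
recordings, which require the real database through the same WAV adapter
(`read_recording()` on `<subject>_<channel>.wav` files plus a
`labels.csv` manifest).

## Desk-scale problem sizes

The acceptance checks and the heavier tests run the full pipeline at
reduced scale, chosen once as a realistic miniature of the study
conditions: sampling rate 2000 Hz (Nyquist still well above the 750 Hz
planted component), 1.5 s analysis segments, EEMD ensemble of 20, 8
recordings per class, and 100 evaluation splits instead of 1000. The
channel-recovery check plants discriminative energy on L1--L4 at amplitude
0.4 and requires the reliefF ranking to return exactly those four sites as
the top 4 in at least 9 of 10 generator seeds; the classification check
requires >= 95% mean accuracy on the separated classes and chance-level
(40--60%) accuracy under the label-permutation null. The null re-shuffles
the labels before every repeat (`permute_labels = TRUE`): at 16 samples a
single fixed shuffle carries an across-shuffle standard deviation above
ten accuracy points in either direction, whereas averaging one fresh
permutation per repeat estimates chance with a standard error near one
point. The generator's user-facing defaults are not scaled down.

Evaluation itself avoids selection bias: by default `classify_features()`
refits the min-max normalization and the whole reliefF selection chain on
the training 70% of every split and carries the fitted parameters over to
the held-out 30% (this is why the normalizer stores its `(min, max)`
pairs). Selecting features once on all samples before splitting -- the
cheaper protocol, available as `in_split = FALSE` -- overstates accuracy
noticeably at these sample sizes, and pushes the permutation null well
above chance.

## Known limitations

* The "first inhalation after the cough" has no published computational
  definition; `segmentation_start()` uses the first sustained rise of the
  energy envelope after its post-cough trough. It is a stand-in, with the
  windows configurable.
* The zero-phase (forward-backward) default of `highpass()` squares the
  Butterworth magnitude response; the closed-form single-pass response is
  available with `zero_phase = FALSE`.
* Multinomial naive Bayes treats [0,1] features as fractional event
  weights -- the stated baseline model despite continuous inputs; a
  Gaussian variant (`gaussian_nb()`) is provided for the conventional
  treatment.
* Whether hyper-parameter grid search is repeated per split or run once is
  a protocol ambiguity; per-split is the default (`grid_once = TRUE`
  switches), and the reported intervals are percentile intervals across
  splits, the most direct reading of parenthesised ranges.
* The deep-belief-network comparison present in the original study design
  is out of scope here; naive Bayes and gradient-boosted trees are the
  implemented baselines.
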