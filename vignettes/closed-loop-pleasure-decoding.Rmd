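---
title: "Closed-loop decoding of musical pleasure from in-ear EEG: models, assumptions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop decoding of musical pleasure from in-ear EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Music chills — goosebumps or shivers accompanying intense musical pleasure —
are strongly idiosyncratic: which songs elicit them differs per listener, as
does the neural response. This package implements a closed-loop pipeline that
personalizes song selection to both: a sparse linear model predicts a
listener's pleasure from audio-embedding features of candidate songs, a
logistic classifier decodes the listener's momentary pleasure state from
two-channel in-ear EEG, and during playback the decoded pleasure is fed back
to retrain the acoustic model and re-rank the candidate library after every
song.

Everything is exercisable on synthetic data: the package contains a
first-class generator for candidate-song embeddings, participant calibration
sessions (ratings and chill key-presses) and state-dependent EEG, so every
stage of the loop is testable without any recorded data.

# The two models

## Model 1: pleasure from acoustic features

Each 90-s excerpt is represented by frame-level 128-dimensional audio
embeddings (372 frames per excerpt for the reference embedding provider).
Frames are averaged into nine 10-s bins; the default per-song feature vector
concatenates the nine bin means (1152 dimensions), preserving coarse temporal
structure while keeping one row per song. Features are z-scored across the
six calibration songs with the population-SD convention (so a rating pattern
of three identical high and three identical low values maps to exactly
&plusmn;1), and dimensions with a non-finite mean or an SD &le; 0.01 are
dropped.

The model is L1-penalized least squares,

$$\min_{\beta_0,\beta}\;\frac{1}{N}\sum_{i=1}^{N}\bigl(y_i-\beta_0-\beta^\top
x_i\bigr)^2+\lambda\lVert\beta\rVert_1 ,$$

with an unpenalized intercept and no internal rescaling. The objective is
implemented exactly in this parameterization (note glmnet's Gaussian
objective is half of it, so $\lambda_{\mathrm{glmnet}}=\lambda/2$ for the
same minimizer — glmnet serves as an independent oracle in the tests, never
as the solver). The $\lambda$ grid is 100 log-spaced values from
$\lambda_{\max}$ (the smallest $\lambda$ zeroing all coefficients) down to
$10^{-4}\lambda_{\max}$; $\lambda$ is chosen by K-fold cross-validated
squared error (5 folds initially, 10 on retraining, capped at the row
count), with ties broken toward the larger, sparser $\lambda$. The
coordinate-descent kernel is compiled (active-set updates with a maintained
gradient cache and a KKT sweep); its convergence test is an
objective-improvement stall relative to the *initial* objective, so it does
not tighten unboundedly on noiseless problems.

## Model 2: pleasure state from in-ear EEG

Raw two-channel (left/right ear canal) EEG at 600 Hz is band-passed 3–40 Hz
with a 4th-order Butterworth filter — zero-phase (forward–backward) offline,
causal in real time. Offline, the two channels are unmixed into two
components by whitening plus a kurtosis-contrast rotation (the standard
2&times;2 blind separation); the component with the larger sensor-space RMS
contribution is presumed movement/muscle artifact, zeroed, and the signal
remixed. Four-second windows with 50% overlap are featurized by Welch PSD
(2-s Hann segments, 50% overlap) integrated into 0.5-Hz bins centred
4.0–40.0 Hz, for the left, right and difference derivations: 73 &times; 3 =
219 features per epoch.

Noise flags come from three per-epoch, per-channel metrics — RMS (square
root of summed band power by default; a time-domain alternative is
configurable), maximum absolute first difference, and skewness (kurtosis
configurable, matching the real-time variant) — each z-scored across epochs
per channel, averaged over the two channels, with an epoch flagged when
*any* metric exceeds 2.5 (one-sided). Features are standardized over
non-flagged epochs only; the scaler is stored for streaming reuse.

The classifier is PCA (up to 150 components per participant; all available
components when fewer epochs exist) with standardized PC scores, class
balancing by subsampling the larger class, a stratified 90/10 train/test
split whose holdout never touches fitting, and a logistic LASSO whose
$\lambda$ is selected by 20-fold cross-validation on the training portion.
(The source text prints the penalized loss as a squared error over the
binary outcome while calling the model a logistic LASSO; it is implemented
as L1-penalized binomial deviance.) Validation reports the confusion matrix
at probability 0.5, the threshold-swept ROC and the trapezoid AUC for both
partitions. Classifier weights are back-projected to the 73 &times; 3
feature space by rescaling the coefficients by the PC score SDs and
multiplying by the loadings; band summaries are means of $|w|$ over theta
(4–7), alpha (8–13), beta (14–30) and gamma (31–40 Hz) bins — the
absolute-value convention is documented and switchable to signed means.

# Ranking and the closed loop

Candidate features are z-scored and clipped at exactly &plusmn;2 SD. The
composite score is $z(\text{predicted pleasure}) + z(\text{mean Pearson
correlation with the three self-selected songs})$, both z-scored across the
library (z-scoring the prediction as well as the correlation keeps the two
terms commensurate; a raw-prediction variant is configurable). Candidates
are ranked descending with ties broken by song id. Playlists have seven
songs: slot 1 is the baseline, drawn from ranks 3577–3649 of the 7225-song
reference library; slots 2–7 come from the top/bottom 72 (EEG conditions,
re-ranked after every song) or the top/bottom 432 (NoEEG conditions, fixed
ranking). Other library sizes scale all three windows by the same fractions
with floor rounding, the baseline window staying central. Within-playlist
duplicates are forbidden.

During playback the trailing 4-s window is decoded once per second from
$t=4$ s (a 90-s song yields 87 values); artifact-component removal is
omitted in real time, and window noise metrics are z-scored against stored
calibration statistics (streaming statistics would drift). Smoothing takes
the mean of the latest five non-flagged values, or of all non-flagged values
while fewer than five exist. The song-level decoded pleasure
$\bar{Y}$ (mean of non-flagged raw values) is mapped to VAS units by

$$\hat{y}' = (\mathrm{VAS}_{\max}-\mathrm{VAS}_{\min})\,\bar{Y} +
\mathrm{VAS}_{\min},$$

standardized with the calibration VAS mean/SD, appended as a training row,
and the acoustic model refit (10-fold CV) before the next song is drawn.
Retraining accumulates all completed songs of the current playlist by
default; a single-point mode reproduces the literal one-new-row description.
A song whose decoded seconds are all flagged is skipped from retraining and
logged; the session continues.

# The synthetic world

The generator is a stated world, not a tuning knob:

* **Embeddings.** Frame embeddings follow a low-rank latent factor model
  (rank 12 by default) plus frame noise; 372 frames per 90 s by default
  (the hop size of the reference embedding network is not public, so
  frames-per-excerpt is a parameter).
* **Pleasure.** Each simulated participant has a sparse coefficient vector
  over embedding dimensions (5 active by default); true pleasure is a
  clipped affine map of the song-mean embedding's inner product with it,
  calibrated in closed form so the library mean is 57.1 (the observed
  other-selected VAS mean) and the expected top-3 mean is 86.1 (the observed
  self-selected mean).
* **Chills.** Counts are Poisson with a log-linear rate in true pleasure;
  the two rate parameters are pinned by the two reported group means (20.7
  self vs 6.7 other chills per three 90-s songs). Observed between-subject
  SDs are larger than Poisson alone; the generator reproduces part of that
  overdispersion through taste variability and does not target the SDs.
* **EEG.** Each channel sums four band-limited noise processes (theta,
  alpha, beta, gamma; amplitudes scaled like $1/\sqrt{f}$), a $1/f$
  background and white sensor noise; left and right share half their
  band-limited sources so the difference derivation is informative. The
  high-pleasure state multiplies band amplitudes by
  $\exp(\text{effect}/2)$, i.e. a per-band log-power shift — matching the
  decoder's feature space (band power), not an evoked-response model. The
  default effect 0.5 gives a moderately decodable state; tests of the
  "large effect" regime use 1.5. Optional artifact bursts are 0.3-s
  high-amplitude transients on both channels at a Poisson rate.

What a green test does **not** establish: the generator has no real
volume-conduction geometry, no non-stationarity within songs, no
evoked/chill-locked transients, and its EEG classes differ only in band
power — so green decoding tests validate the pipeline's mechanics, not the
neuroscience claim.

# Numerical choices and caveats found during testing

* **Overlapping epochs leak across random splits.** With per-song labels
  and 50%-overlapping epochs, epochs on either side of the 90/10 split share
  samples and per-recording realizations; even at zero planted effect, test
  AUC sits far above 0.5 (~0.85 in our simulations). The exchangeable null
  is epoch-level label shuffling, which is exactly what the permutation test
  does. This is a genuine methodological caveat of song-level-label decoding
  with overlapping windows.
* **Strict-inequality permutation p is anti-conservative under ties.**
  Under the null the cross-validated logistic LASSO often selects the empty
  model, creating an atom of test AUCs at 0.5; a p-value counting only
  strictly larger permuted AUCs is then anti-conservative. The printed
  convention is implemented as `p_value`, and the standard add-one
  "&ge;" convention — super-uniform, hence valid — is reported alongside as
  `p_value_addone`. The corresponding acceptance check of strict-p
  uniformity is deliberately left failing, with this analysis.
* **Noise-flag coverage has a feasibility bound.** A one-sided z-threshold
  of 2.5 can only fire when the contaminated-epoch fraction $f$ satisfies
  $\sqrt{(1-f)/f} > 2.5$, i.e. $f \lesssim 0.14$; at 6 artifact bursts/min
  each 4-s/50% epoch grid is ~40% contaminated and no burst amplitude can
  cross the threshold. Coverage is therefore validated at 1 burst/min.
* **Support recovery needs more than six rows.** The six-song calibration
  design (self = a participant's top-3 songs) makes the response effectively
  two-valued; hundreds of feature columns separate the two groups, so the
  planted active set is unidentifiable from calibration data alone, and
  with $N{=}6$, $p{=}1152$ cross-validation collapses to full shrinkage.
  Recovery of the planted sparse coefficients is demonstrated on 60
  noiseless-rated songs with full-rank embedding covariance, where it is
  exact across seeds.
* **Zero-phase filtering at edges.** Forward–backward filtering uses
  odd-reflection padding of up to one second; edge conventions differ
  between implementations, and agreement with an independent implementation
  is to ~4e-4 with matched padding, exact for the causal pass.
* **Degenerate inputs.** Identical channels make the blind separation
  degenerate (error, with guidance to skip removal); constant features are
  kept with their SD clamped to a stored epsilon; a zero-variance metric
  contributes z = 0 rather than erroring; constant calibration ratings are
  a hard error.

# Tunable parameters

All constants live in one validated configuration object
(`run_config()`): sampling rate 600 Hz; filter band 3–40 Hz, order 4;
feature band 4–40 Hz, bin 0.5 Hz; epoch 4 s, overlap 0.5; noise threshold
2.5; max 150 PCs; CV folds 5/10/20 (initial acoustic / retraining / EEG);
1000 permutations; windows 72/432 with baseline 3577–3649 at library size
7225; 90-s songs; 7-song playlists; 5-point smoothing; clip at 2 SD. Each
default is asserted against these values by a dedicated test, and the
object round-trips losslessly through YAML.
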