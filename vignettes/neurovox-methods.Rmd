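---
title: "Decoding speech from ECoG with a differentiable formant vocoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech from ECoG with a differentiable formant vocoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovox)
```

## The decoding framework

neurovox implements a speech-decoding framework for electrocorticographic
(ECoG) recordings whose centrepiece is a *differentiable* source–filter
speech synthesizer.  Instead of predicting a high-dimensional spectrogram
directly from neural data, a decoder predicts 18 interpretable speech
parameters per 8 ms frame — pitch $f_0^t$, six formant centre frequencies
$f_i^t$ with amplitudes $a_i^t$, a broadband unvoiced filter
$(f_{\hat u}^t, b_{\hat u}^t, a_{\hat u}^t)$, a voicing weight
$\alpha^t \in [0,1]$ and loudness $L^t$ — and the synthesizer renders them
as a magnitude spectrogram:

$$\hat S^t(f) \;=\; L^t\,\bigl[\alpha^t V^t(f) + (1-\alpha^t)\,U^t(f)\bigr] + B(f).$$

The voiced component $V^t = F_{\mathrm v}^t H^t$ filters a harmonic
excitation $H^t$ (up to 80 equal-amplitude harmonics of $f_0$, synthesized
at 16 kHz with the phase accumulated in cycles; harmonics above 8 kHz are
zeroed) through the sum of six formant filters.  Each formant filter is a
shifted and scaled copy of a learned unimodal prototype shape $G_i$:

$$F_i^t(f) = a_i^t\,G_i\!\Bigl(\tfrac{b_i^{\mathrm{proto}}}{b_i^t}(f - f_i^t) + f_i^{\mathrm{proto}}\Bigr),$$

with the bandwidth tied to the centre frequency by a continuous piecewise
relation $b_i^t = b_0 + a\,(f_i^t - f_\theta)_+$.  The unvoiced component
$U^t = F_{\mathrm u}^t N^t$ filters seeded Gaussian white noise through a
broadband filter plus the same six formant filters.  The soft mix by
$\alpha^t$ keeps the whole mapping differentiable, so decoders can be
trained end-to-end through the synthesizer by backpropagation.

Speaker-specific parameters are time-invariant and learned: the 80-sample
prototype shapes for the seven filters, six bandwidth-relation triples,
and a nonnegative background spectrum $B(f)$ with $K$ bins (256 for the
female profile, 512 for the male profile); in total 834 (female) or 1,090
(male) scalars.

Two trainable models share the parameter space:

* the **speech encoder** maps a spectrogram to the 18 parameters;
  together with the synthesizer it forms a speech-to-speech auto-encoder
  whose training also fits the speaker parameters;
* the **ECoG decoders** map a `T × 8 × 8` tensor of z-scored high-gamma
  envelopes to the same parameters.  Three interchangeable backbones are
  provided — a temporal-convolutional ResNet with a 16× temporal
  bottleneck, a 3D shifted-window attention network over 2×2×2 patch
  tokens, and a three-layer LSTM — each in a strictly causal and a
  non-causal variant.

## Training objectives

Training minimizes a weighted sum of four terms.  The modified multi-scale
spectral loss sums absolute and log-magnitude differences on the linear
and an 80-band Mel axis.  The STOI+ intelligibility metric — the mean
Pearson correlation of 30-frame one-third-octave band envelope segments
(15 bands, lowest centre 150 Hz) — enters with its sign flipped and weight
$\lambda_1 = 1.2$.  A supervision loss penalizes squared pitch and formant
(1–4) tracking errors with weights $\beta = (0.1, 0.06, 0.03, 0.02)$ and
overall weight $\lambda_2 = 0.1$.  Decoder training adds a reference loss
against the guidance parameters with $\lambda_3 = 1$ and per-parameter
weights ($\lambda_\alpha = 1.8$, $\lambda_L = 1.5$, $\lambda_{f_1} = 3$,
$\lambda_{\hat f_u} = 10$, …).  All squared-error terms sum over frames.

Two unit conventions deserve note, since the literature leaves them open.
The supervision loss is computed in hertz: its decreasing $\beta_i$
sequence presumes frequency-scaled errors, and the raw Hz² magnitudes give
pitch tracking a strong learning signal.  The reference loss is computed
on the *normalized* parameter scale (frequency channels mapped to their
$[f_\min, f_\max]$ de-normalization ranges, reported in percent), because
its printed per-parameter weights are all of order one and only make sense
for commensurate channels; in raw units a 100 Hz formant error would
outweigh a full-scale voicing error ten-thousand-fold and the voicing,
amplitude and loudness channels would receive essentially no gradient.

Optimization uses Adam (`lr` $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$) by default.  Two schedule refinements matter at small
compute budgets: a *warm-up phase* (fraction `warmup` of the steps) trains
the decoder on the parameter-matching terms only, skipping the synthesizer
pass, before the spectral terms join at a ten-fold reduced rate; and the
returned weights are a Polyak average over the last quarter of the run,
which damps the optimizer jitter that otherwise dominates pitch precision.
Decoder training also installs a closed-form *ridge warm start*: the
linear skip path from a short causal window of electrode context onto the
pre-activation parameter targets is initialized at its ridge-regression
solution, so training begins from an analytically sensible decode and
refines it jointly.  The heads use sigmoid activations de-normalized onto
per-channel frequency ranges, softplus for amplitudes and loudness, and a
sigmoid voicing weight, so every prediction satisfies the parameter
invariants by construction.

The encoder's pitch channel is fed by a classical analysis front end: the
cosine similarity of each spectrum frame against a bank of harmonic comb
templates, plus a pitch track derived from it (argmax with parabolic
refinement, octave-blip rejection by a running median, and interpolation
across frames whose comb margin indicates no voicing evidence).  Learning
pitch purely from raw spectra is possible but needs far more optimization
than formant or amplitude channels; the comb features make the pitch
channel as easy to read out as the others.

## The synthetic study conditions

Because patient recordings cannot ship with the package, a seeded
generator produces the study conditions end to end.  Word-like trials
last 0.5 s (62 frames at 125 frames/s) with alternating voiced/unvoiced
segments (70% voiced), smooth formant target transitions, a broadband
burst in unvoiced segments, and onset/offset loudness ramps.  Pitch
follows a word-level intonation gesture (a rise–fall or fall arc of
15–45 Hz) plus a bounded random walk; during unvoiced segments — where
pitch has no acoustic effect — the contour is carried through by
interpolation, as pitch trackers conventionally do.  Datasets default to
a vocabulary of about one word archetype per eight trials and hold out
one eighth of the trials, mirroring a 350/50 split.

Pseudo-ECoG arises from a linear-lagged generative mapping: each speech
parameter series is normalized by fixed population statistics and mixed
into electrodes of an 8×8 grid.  By default 18 informative electrodes
each own one parameter (with graded importance scales and light
cross-talk), so the full parameter vector is identifiable from the grid;
an 8-electrode mapping exercises the partially identifiable regime used
by the occlusion analysis.  Each electrode *leads* the produced speech by
its lag of 0–3 frames — neural activity precedes the acoustics, as in
motor cortex — so the ECoG-to-speech ground truth remains decodable by
strictly causal models.  Additive Gaussian noise defaults to a standard
deviation of 0.1; the end-to-end recovery analyses use the low-noise
regime (0.02), where the information limit of pitch decoding (the
parameter the spectrogram correlation is most sensitive to) lies well
below 1 Hz.

What passing these synthetic analyses shows — and what it does not: they
verify that the differentiable pipeline is correct (gradients match
finite differences), that the losses implement their definitions, that
causal variants are strictly causal, and that training recovers the
generative parameters when the data contain them.  They do not establish
performance on real cortical recordings, whose noise is neither Gaussian,
stationary, nor linear in the articulatory trajectories.

## Numerical choices

* The harmonic stack is evaluated in closed form via the Dirichlet
  kernel, with a direct 80-term fallback near the phase singularities;
  both paths agree to 1e-8 and the direct sum serves as the reference in
  the tests.
* Spectrograms use a Hann window of 2K samples, hop 128 (125 frames/s),
  magnitudes scaled so a unit-amplitude sinusoid peaks at 1.
* Log terms are floored at 1e-6 of the joint dynamic range; STOI+
  envelope segments with zero variance contribute 0; one-third-octave
  band edges round to the nearest DFT bin with ties broken downward.
* Prototype unimodality is enforced by construction
  (`min(cumsum, reversed cumsum)` of softplus increments, normalized to a
  unit peak), so learned speaker parameters always satisfy the invariant.
* Out-of-range prototype evaluations clamp to the endpoint samples.
* Causal temporal padding replicates the first frame (synthetic past
  only); non-causal padding is symmetric.  In causal mode every
  transposed-convolution upsampling stage is delayed by one latent step
  so outputs depend only on strictly-past latents; together with the
  full-resolution causal skip path this makes the causality contract
  exact (bitwise under the perturbation probe) rather than approximate.
* Masked (rejected) electrodes are zero-filled and flagged through a
  validity channel.

## Problem sizes in the test suite

The packaged analyses run at desk scale, chosen once: auto-encoder
recovery uses 100 trials and 200 training steps; decoder recovery uses
300 trials with 500 steps (LSTM) or 150 steps (ResNet, which starts from
the same ridge warm start); the occlusion analysis uses 80 trials, 400
steps, and mirrors every hyperparameter in its shuffled-model noise
floor.  At these sizes the full suite exercises every module, including
three-seed stochastic checks, in well under half an hour on one CPU.

## Known limitations

* Only grid electrode geometries are supported (strips and depth
  electrodes are not).
* The spectral-gating audio denoiser and the acoustic-contamination audit
  sometimes applied to clinical recordings are out of scope, as are
  anatomical (MNI) projections of contribution maps: contributions are
  reported per grid position.
* The pluggable pitch/formant estimator is a deliberately simple
  reference (autocorrelation pitch, LPC-root formants, comb/cepstrum-style
  spectrogram analysis), not a substitute for a dedicated phonetics tool.
* The pseudo-ECoG generator is a linear-lagged mixing model chosen for
  analytic transparency, not a biophysical simulation of cortical
  dynamics.
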