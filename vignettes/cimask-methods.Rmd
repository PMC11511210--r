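---
title: "Time-frequency masking for cochlear-implant noise reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency masking for cochlear-implant noise reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimask)
```

## The problem

Cochlear-implant (CI) users understand speech well in quiet but struggle in
background noise. A standard remedy is single-channel mask-based speech
enhancement: decompose the noisy signal $y = s + n$ into a time-frequency
(T-F) grid via the short-time Fourier transform (STFT), estimate a per-unit
gain ("mask") with a supervised learner, apply it to the noisy spectrum, and
resynthesize. The choice of *training target* — which mask the network is
taught to produce — changes both intelligibility and quality of the
enhanced speech, and matters even more when the output is subsequently
delivered through a CI, which discards fine spectral structure.

`cimask` implements the full study apparatus around that question: the mask
family, the mixing protocol, a CI simulation (noise vocoder), an MLP mask
estimator, objective metrics for normal and electric hearing, and a
synthetic speech/noise generator so everything is testable without a speech
corpus.

## The mask family

With clean spectrum $S(t,f)$, noise $N(t,f)$, mixture $Y = S + N$, local
SNR $\gamma(t,f) = 10\log_{10}(|S|^2/|N|^2)$ and mixture SNR $s$ (dB):

* **IBM** — $\mathbb{1}[\gamma > LC]$ with $LC = s - 5$ dB. Hard gating.
* **IRM** — $|S|^2 / (|S|^2 + |N|^2)$, the Wiener gain of the local
  speech/noise energy ratio; in $[0,1]$.
* **FFTM** — $|S|/|Y|$; unbounded above as an oracle, clipped at 1.5 when
  used as a training target.
* **PSM** — $\tfrac{|S|}{|Y|}\cos(\theta_S - \theta_Y) = \mathrm{Re}(S/Y)$.
  Algebraically identical to the Optimal Ratio Mask
  $(|S|^2 + \mathrm{Re}(S N^*)) / (|S|^2 + |N|^2 + 2\,\mathrm{Re}(S N^*))$;
  the package tests this identity to $10^{-10}$.
* **cIRM** — the complex gain $M = S / Y$ expressed through its real and
  imaginary parts; applying it by complex multiplication reconstructs the
  clean spectrum exactly wherever $Y \ne 0$. Its real part equals the PSM.
  Oracle-only (unbounded, so not used as a learning target here).
* **QM** — a five-level staircase $\{0, .25, .5, .75, 1\}$ over
  $\gamma$ with thresholds $LC_{1..4} = s - \{8, 6, 4, 2\}$ dB: a quantized
  approximation of the Wiener gain function $\xi/(1+\xi)$,
  $\xi = 10^{\gamma/10}$. At $s = 5$ dB the staircase is symmetric about
  0 dB and stays within 0.35 of the Wiener gain everywhere.
* **PSM+** — hybrid: PSM where it lies in $[0,2]$, the IRM value where the
  PSM is negative (those units still carry magnitude information), and 2
  where the PSM exceeds 2.

Enhancement applies a real mask as
$\hat S = M \cdot |Y| e^{j\theta_Y}$ (noisy phase reuse), or the cIRM by
complex multiplication.

### Numerical conventions

* Analysis: 20 ms Hann frames, 50% overlap, one-sided spectra. Oracle
  masks use a 1024-point zero-padded FFT, estimated masks a 320-point FFT
  (161 bins). Synthesis is weighted overlap-add normalized by the
  accumulated squared window; the interior round-trip error is below
  $10^{-8}$.
* Silent bins carry no speech evidence: division-by-zero bins get mask 0
  (FFTM, PSM, cIRM), and the local SNR is clamped to $\pm 100$ dB (IBM, QM).
* The QM partition is half-open, $[LC_k, LC_{k+1})$, top level at
  $\gamma \ge LC_4$; this makes the staircase a monotone total function of
  local SNR (the equation's printed boundary conditions are internally
  inconsistent, so the tie-break had to be chosen).
* The PSM+ middle condition is read as $0 \le \mathrm{PSM} \le 2$ (its
  printed form contains an evident typo).
* Unbounded oracle masks are not log- or tanh-compressed anywhere.

## Mixing protocol

Noise is cut at a uniformly random offset from the head (training) or tail
(testing) region of the noise recording, truncated to the utterance length,
and scaled so that full-utterance energy gives exactly the requested global
SNR; the clean signal is never rescaled, so it remains the metric
reference, and `mixture - noise == clean` holds exactly. Training mixtures
use $\{-5, 0\}$ dB, test mixtures $\{-5, 0, 5\}$ dB. Speech-shaped noise is
white noise shaped by a 513-tap linear-phase FIR fit (frequency sampling)
to the long-term average spectrum of a reference speech set.

Whether the clean or the noise signal is scaled to reach the target SNR is
an open choice; scaling the noise was chosen to keep the reference fixed.

## The noise vocoder

The CI simulation follows the classic noise-vocoder recipe: pre-emphasis
above 2 kHz (nominally +3 dB/octave — a half-order slope with no rational
realization, so a first-order high shelf rising to the equivalent gain at
Nyquist is used), an eight-channel Butterworth band-pass bank at center
frequencies 366, 526, 757, 1089, 1566, 2252, 3241, 4662 Hz (edges at
geometric means of neighboring centers), full-wave rectification, a 120 Hz
second-order envelope low-pass, remodulation of band-limited white-noise
carriers, summation, and RMS normalization to the input level.

Unstated implementation choices, all exposed in `vocoder_config()`:

* **Band-pass order 8** (4th-order prototype per skirt). With 4th-order
  filters the channel skirts overlap enough that, after carrier
  remodulation, a pure 1 kHz tone re-analyzes with only ~60% of its energy
  in its own channel; 8th order restores clean channel routing (>80%),
  which is also what the tone-routing test asserts. All filters were
  checked for numerical stability at 16 kHz.
* **Full-wave rectification** (|·|): the block-diagram label "RECT" is
  ambiguous; full-wave gives cleaner envelopes at these envelope cutoffs.
* **Carriers** are regenerated per call from `carrier_seed`, making
  vocoding bit-reproducible; clean/enhanced comparisons share carriers.

## Metrics

* **STOI** follows the canonical procedure: resample to 10 kHz, drop
  frames more than 40 dB below the loudest clean frame, 256-sample 50%
  overlap Hann STFT (512-point FFT), 15 one-third-octave bands from
  150 Hz, 384 ms (30-frame) segments, per-band normalization and
  $-15$ dB SDR clipping, then the mean of the clean/degraded band-envelope
  correlations. No R implementation of STOI exists in the dependency
  stack, so it is implemented here and validated by its analytic
  properties (self-score 1, SNR monotonicity, boundedness).
* **NCM**, the CI-oriented intelligibility measure, extracts the eight
  band envelopes with the vocoder's own analysis bank, restricts them to
  the intelligibility-bearing modulation range by resampling to 25 Hz
  (modulations $\le 12.5$ Hz, as is standard for speech-transmission-index
  measures), computes the per-band envelope correlation $r_i$, maps it to
  an apparent SNR $10\log_{10}(r_i^2/(1-r_i^2))$ clipped to $[-15,15]$ dB
  and a transmission index $TI_i = (\mathrm{aSNR}+15)/30$, and averages
  with band-importance weights $W_i$ (uniform by default; the band count
  and weights are unstated in the source procedure, so they are exposed as
  arguments).
* **PESQ** is represented only by the wideband MOS mapping
  $0.999 + 4/(1 + e^{-1.3669\,r + 3.8224})$ applied to a raw P.862 score
  that must come from a reference implementation; the psychoacoustic model
  itself is deliberately out of scope.

## The similarity battery

Vocoded signals are summarized as amplitude histograms with Scott's-rule
bin width $h = 3.49\,\sigma n^{-1/3}$, normalized to probability masses.
The bin grid is computed on the clean (reference) vocoded signal and
*reused* for the mixture/enhanced signal — comparability requires a common
grid, and the battery refuses mismatched edges rather than silently
rebinning. Twenty-two measures across eight families (Minkowski $L_p$,
$L_1$, Intersection, Inner Product, Fidelity, Squared $L_2$, Combinations,
Shannon's Entropy) follow Cha's taxonomy; distances convert to
similarities via $s = 1 - d$, the Shannon's Entropy family is reported as
the raw Kullback-Leibler divergence $\sum_i P_i \ln(P_i/Q_i)$ (with
$P_i = 0$ terms contributing zero and $Q_i$ floored at $10^{-12}$), and a
Pearson correlation between the probability vectors is appended. Family
scores are arithmetic means of member similarities; the aggregation method
is configurable because the tabulated convention is not stated in the
source material. Two members deserve a warning: under Cha's definitions
Motyka self-similarity is $1/2$ (its analytic maximum) and the raw Inner
Product self-similarity is $\sum_i P_i^2$, not 1 — the battery reports the
definitions faithfully rather than renormalizing them.

## The mask estimator

Per frame, 24 log-mel energies are extracted from the noisy mixture
(triangular filters, HTK mel scale, 0-8 kHz), concatenated with
regression deltas (±2 frames) and smoothed along time with an
order-2 auto-regressive moving-average filter:
$y_t = (y_{t-1} + y_{t-2} + x_t + x_{t+1} + x_{t+2})/5$.

The estimator is a multilayer perceptron, fit by `mask_mlp()` and used via
`predict()`. Defaults follow the benchmark recipe: three sigmoid hidden
layers of 1024 units, MSE loss, no dropout, 20 epochs, classical momentum
0.5 switching to 0.9 after epoch 5, and "adaptive gradient descent with
scaling factor 0.0015" — interpreted as AdaGrad-style per-parameter scaling
with base rate 0.0015, since the exact optimizer of the source toolbox is
not recoverable. The output activation is sigmoid when the target range is
inside $[0,1]$ (IBM, IRM, QM) and linear otherwise (FFTM, PSM+); a sigmoid
is refused for out-of-range targets. Targets are spliced into a 5-frame
window, and overlapping context predictions are averaged at inference;
input-frame splicing (`input_context`) is also available, since the source
feature pipeline splices inputs as well. Estimated masks are clipped to the
target's declared range and are soft even for the IBM. Training is
bit-reproducible under the config seed.

## The synthetic corpus

The generator replaces recorded speech so that the full pipeline runs
download-free. Utterances are 3 s by default (typical of the
phonetically balanced sentence corpora this emulates) at 16 kHz: a
harmonic source on a wandering $f_0$ (default 110 Hz, male-like) shaped by
per-syllable formant resonators drawn from a five-vowel table, interleaved
with high-passed unvoiced bursts, under a syllabic (2-8 Hz) Hann envelope.
Babble is a sum of independent synthetic talkers — 20 by default: dense
enough to emulate recorded crowd babble, which is the non-stationary
masker this stands in for, while staying affordable; speech-shaped noise
is the FIR-shaped stationary masker; white noise is flat.

What the generator does *not* emulate: real phonotactics, coarticulation,
prosody, room acoustics, or speaker variability. Passing tests on this
material therefore demonstrates the correctness and internal consistency
of the processing chain and the direction of enhancement effects, not
corpus-level absolute scores; the published score tables for recorded
corpora are reproducible only with that external audio.

## Experiment drivers and desk-scale choices

`run_oracle_eval()` reproduces the ideal-mask feasibility table: per mask,
noise and SNR, the mean/median/sd of STOI over the corpus, with the
unprocessed mixture as baseline; the cIRM row scores exactly 1.0 ± 0.0 by
construction. `run_estimation_eval()` trains one MLP per mask kind on
$\{-5, 0\}$ dB mixtures, evaluates at $\{-5, 0, 5\}$ dB, and emits STOI,
vocoded NCM and similarity tables with best/worst flags ("best" = highest
mean; when the lowest standard deviation disagrees, the mean wins and the
row is tie-flagged). Everything derives from a single top-level seed.

The package's own experiments (tests and the acceptance script) run at
desk scale on one CPU: 10 training and 5 test utterances of 3 s, two noise
kinds, and an MLP of three hidden layers with 512 units, mini-batches of
64, 5-frame input context and per-frame outputs (`context_frames = 1`).
The narrower output was chosen because overlap-averaging of spliced
outputs over-smooths the estimated masks in time at this scale, which
depresses the envelope-correlation (NCM) scores of the enhanced signals;
input-frame context recovers the temporal information instead. With a
corpus-scale training set and network those choices matter much less.

Desk scale has a visible cost on the hardest comparison: the vocoded
mixture keeps a high band-envelope correlation with the vocoded clean
signal (a masker mostly adds a quasi-constant envelope offset, which a
correlation ignores), so *beating the vocoded-mixture NCM baseline*
demands mask estimates with very low gain error. Models trained on the
40 desk-scale mixtures raise STOI for every mask and raise NCM through
the oracle masks to near ceiling, but their estimated masks generally do
not clear the mixture's NCM baseline — a capacity/data limitation of the
small training set, not of the processing chain, and the oracle-bound
tests are there to make exactly that distinction.

## Known limitations

* Raw PESQ cannot be computed without a reference P.862 implementation;
  only the MOS mapping is provided.
* The estimator is a plain MLP by design (the benchmark architecture);
  recurrent/convolutional or complex-valued models are out of scope.
* At desk scale the estimated masks of the hardest conditions (−5 dB
  babble) may not reach the envelope fidelity that a corpus-scale model
  attains; oracle masks bound what estimation can achieve and are the
  right reference point for the processing chain itself.
* The vocoder models envelope extraction only — no electrode interaction,
  current spread, or sine-carrier variant.
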