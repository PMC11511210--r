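#' Specification for a synthetic speech-like utterance
#'
#' The fixture generator stands in for a recorded corpus: utterances are
#' built from a harmonic glottal-like source on a wandering fundamental,
#' shaped by per-syllable formant resonators drawn from a small vowel table,
#' interleaved with unvoiced fricative-like noise bursts, and modulated at a
#' syllabic rate in the 2-8 Hz range. The result has the gross properties
#' the processing chain cares about (harmonicity, formant structure,
#' syllabic envelope, speech-band spectrum) without being perceptually
#' realistic speech.
#'
#' @param duration utterance length in seconds (> 0; default 3, typical of
#'   the phonetically balanced sentence corpora this emulates).
#' @param fs sampling rate in Hz (default 16000).
#' @param f0 base fundamental frequency in Hz, within \[60, 400\]
#'   (default 110, a typical male talker).
#' @param syllable_rate syllables per second (default 4, mid syllabic
#'   range).
#' @param voiced_prob probability a syllable is voiced (default 0.8).
#' @param seed RNG seed; fixes the utterance exactly.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(duration = 3, fs = 16000, f0 = 110,
                       syllable_rate = 4, voiced_prob = 0.8, seed = 1) {
  if (duration <= 0) stop("'duration' must be > 0")
  if (f0 < 60 || f0 > 400) stop("'f0' must lie in [60, 400] Hz")
  if (syllable_rate < 2 || syllable_rate > 8)
    stop("'syllable_rate' must lie in [2, 8] Hz (syllabic range)")
  structure(list(duration = duration, fs = fs, f0 = f0,
                 syllable_rate = syllable_rate, voiced_prob = voiced_prob,
                 seed = seed),
            class = "synth_spec")
}

# formant table (F1, F2, F3 in Hz) for a handful of vowel qualities
synth_vowels <- function() rbind(
  c(730, 1090, 2440),   # /a/
  c(270, 2290, 3010),   # /i/
  c(300,  870, 2240),   # /u/
  c(530, 1840, 2480),   # /e/
  c(660, 1720, 2410)    # /ae/
)

# second-order resonator filter at center f, bandwidth bw
resonate <- function(x, f, bw, fs) {
  r <- exp(-pi * bw / fs)
  a <- c(1, -2 * r * cos(2 * pi * f / fs), r^2)
  g <- (1 - r) * sqrt(1 - 2 * r * cos(4 * pi * f / fs) + r^2)
  as.numeric(signal::filter(g, a, x))
}

#' Synthesize a speech-like utterance
#'
#' @param spec a [synth_spec].
#' @return A [waveform], peak-normalized to 0.5; bit-identical under a
#'   fixed spec seed.
#' @export
synth_utterance <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, synth_utterance_impl(spec))
}

synth_utterance_impl <- function(spec) {
  fs <- spec$fs
  n <- round(spec$duration * fs)
  n_syll <- max(1L, round(spec$duration * spec$syllable_rate))
  bounds <- round(seq(0, n, length.out = n_syll + 1))
  vowels <- synth_vowels()
  y <- numeric(n)
  for (s in seq_len(n_syll)) {
    i0 <- bounds[s] + 1L; i1 <- bounds[s + 1]
    ns <- i1 - i0 + 1L
    if (ns < 8L) next
    if (stats::runif(1) < spec$voiced_prob) {
      # harmonic source: phase-integrated wandering f0, mild 1/k rolloff
      f0 <- spec$f0 * (1 + 0.15 * (stats::runif(1) - 0.5)) *
        (1 + 0.05 * sin(2 * pi * 3 * seq_len(ns) / fs + stats::runif(1) * 2 * pi))
      phase <- 2 * pi * cumsum(f0) / fs
      nharm <- max(3L, floor(4000 / spec$f0))
      src <- numeric(ns)
      for (k in seq_len(nharm)) src <- src + sin(k * phase) / k
      v <- vowels[sample.int(nrow(vowels), 1), ]
      seg <- resonate(src, v[1], 80, fs) + resonate(src, v[2], 90, fs) +
        0.6 * resonate(src, v[3], 120, fs)
    } else {
      # unvoiced burst: high-passed noise at lower level
      hp <- signal::butter(2, 2000 / (fs / 2), type = "high")
      seg <- 0.35 * as.numeric(signal::filter(hp, stats::rnorm(ns)))
    }
    env <- hann_window(ns)
    y[i0:i1] <- y[i0:i1] + seg * env
  }
  peak <- max(abs(y))
  if (peak > 0) y <- y * 0.5 / peak
  waveform(y, fs)
}

#' Synthesize test noise
#'
#' Three noise kinds emulating the maskers used with speech corpora:
#' `"babble_like"` is a sum of independent synthetic utterances from
#' competing talkers (non-stationary), `"ssn_like"` is white noise shaped to
#' the long-term spectrum of a reference speech set via [make_ssn]
#' (stationary), and `"white"` is flat-spectrum noise.
#'
#' @param kind `"babble_like"`, `"ssn_like"` or `"white"`.
#' @param duration noise length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed; fixes the output.
#' @param reference reference speech ([waveform] or list) for
#'   `"ssn_like"`; when `NULL`, a reference set of synthetic utterances is
#'   generated internally.
#' @param n_talkers number of competing talkers for `"babble_like"`
#'   (default 20 — dense enough to emulate recorded crowd babble).
#' @return A [waveform] of the requested duration, RMS-normalized to 0.1.
#' @export
synth_noise <- function(kind = c("babble_like", "ssn_like", "white"),
                        duration = 2, fs = 16000, seed = 1,
                        reference = NULL, n_talkers = 20) {
  kind <- match.arg(kind)
  n <- round(duration * fs)
  y <- switch(kind,
    white = with_seed(seed, stats::rnorm(n)),
    babble_like = {
      acc <- numeric(n)
      for (tk in seq_len(n_talkers)) {
        f0 <- 90 + ((seed + tk * 37) %% 8) * 20   # talker-specific pitch
        u <- synth_utterance(synth_spec(
          duration = duration, fs = fs, f0 = f0,
          syllable_rate = 3 + (tk %% 4), seed = seed * 1000 + tk))
        acc <- acc + u$samples
      }
      acc
    },
    ssn_like = {
      if (is.null(reference))
        reference <- lapply(seq_len(6), function(i)
          synth_utterance(synth_spec(duration = 1, fs = fs, f0 = 90 + 15 * i,
                                     seed = seed * 100 + i)))
      with_seed(seed, make_ssn(reference, n))$samples
    })
  rms <- sqrt(mean(y^2))
  if (rms == 0) stop("degenerate noise realization")
  waveform(y * 0.1 / rms, fs)
}
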