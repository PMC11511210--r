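#' Mix clean speech with noise at a prescribed global SNR
#'
#' The noise is truncated to the clean signal's length and scaled so that
#' `10*log10(sum(clean^2) / sum(noise^2))` equals `snr_db`; the clean signal
#' is left untouched (it remains the metric reference). The exact scaled
#' noise is returned alongside the mixture because the ideal masks need it.
#'
#' @param clean clean-speech [waveform].
#' @param noise noise [waveform], at least as long as `clean` and at the
#'   same sampling rate.
#' @param snr_db global mixture SNR in dB (full-utterance energy, no
#'   voice-activity weighting).
#' @return A list with elements `mixture` and `noise` (both [waveform]s);
#'   `mixture$samples - noise$samples` equals `clean$samples` exactly.
#' @examples
#' cl <- waveform(sin(2 * pi * 300 * (0:3199) / 16000))
#' nz <- waveform(rep_len(c(-1, 1) / 2, 3200))
#' m <- mix_at_snr(cl, nz, -5)
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  clean <- as_waveform(clean); noise <- as_waveform(noise)
  if (clean$fs != noise$fs) stop("sampling rates differ")
  if (length(noise$samples) < length(clean$samples))
    stop("noise (", length(noise$samples),
         " samples) is shorter than clean (", length(clean$samples), ")")
  if (!is.finite(snr_db)) stop("'snr_db' must be finite")
  nz <- noise$samples[seq_along(clean$samples)]
  ec <- sum(clean$samples^2); en <- sum(nz^2)
  if (ec == 0) stop("clean signal is silent: SNR undefined")
  if (en == 0) stop("noise segment is silent: SNR undefined")
  scale <- sqrt(ec / en / 10^(snr_db / 10))
  nz <- nz * scale
  list(mixture = waveform(clean$samples + nz, clean$fs),
       noise = waveform(nz, clean$fs))
}

#' Draw a random contiguous noise cut
#'
#' Emulates the corpus protocol of cutting training noise from the head
#' (first two minutes) of a recording and test noise from its tail (last two
#' minutes): a contiguous segment of `n_samples` is drawn uniformly from the
#' selected region. Randomness comes from R's RNG; fix it with `set.seed()`
#' (or derive it from a pipeline seed) for reproducibility.
#'
#' @param noise source [waveform].
#' @param n_samples cut length in samples.
#' @param region `"head"` or `"tail"`: which end of the recording to cut
#'   from.
#' @param region_s region extent in seconds (default 120); the whole signal
#'   is used when shorter.
#' @return A [waveform] of length `n_samples`.
#' @export
random_cut <- function(noise, n_samples, region = c("head", "tail"),
                       region_s = 120) {
  noise <- as_waveform(noise)
  region <- match.arg(region)
  n <- length(noise$samples)
  reg_len <- min(n, round(region_s * noise$fs))
  if (reg_len < n_samples)
    stop("region (", reg_len, " samples) is shorter than the requested cut (",
         n_samples, ")")
  offset <- if (region == "head") 0L else n - reg_len
  start <- offset + sample.int(reg_len - n_samples + 1L, 1L)
  waveform(noise$samples[start:(start + n_samples - 1L)], noise$fs)
}

#' Synthesize speech-shaped noise (SSN)
#'
#' White noise is spectrally shaped so its long-term average spectrum (LTAS)
#' matches that of a reference speech corpus, giving a stationary masker with
#' speech-like coloration. The shaping filter is a linear-phase FIR fit to
#' the corpus LTAS by frequency sampling.
#'
#' @param reference_speech a [waveform] or list of waveforms defining the
#'   target spectrum.
#' @param n_samples output length in samples.
#' @param fir_len FIR shaping-filter length (odd; default 513).
#' @return A [waveform] of length `n_samples`, RMS-matched to the reference.
#' @export
make_ssn <- function(reference_speech, n_samples, fir_len = 513) {
  if (inherits(reference_speech, "waveform"))
    reference_speech <- list(reference_speech)
  if (length(reference_speech) == 0) stop("empty reference set")
  fs <- reference_speech[[1]]$fs
  ref <- unlist(lapply(reference_speech, function(w) {
    stopifnot(inherits(w, "waveform"))
    if (w$fs != fs) stop("reference sampling rates differ")
    w$samples
  }))
  nfft <- 1024
  psd <- welch_psd(ref, nfft = nfft)
  mag <- sqrt(pmax(psd$psd, 1e-20))
  # frequency-sampling linear-phase FIR: mirror one-sided magnitude, ifft,
  # rotate to center and Hann-taper
  full <- c(mag, rev(mag[2:(length(mag) - 1)]))
  h0 <- Re(stats::fft(full, inverse = TRUE)) / nfft
  h0 <- c(h0[(nfft - (fir_len - 1) / 2 + 1):nfft], h0[1:((fir_len + 1) / 2)])
  h <- h0 * hann_window(fir_len)
  x <- stats::rnorm(n_samples + fir_len)
  y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1))
  y <- y[!is.na(y)][seq_len(n_samples)]
  y <- y * sqrt(mean(ref^2) / mean(y^2))
  waveform(y, fs)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% overlap; used for long-term
#' average spectra and envelope-bandwidth checks.
#'
#' @param x numeric vector or [waveform].
#' @param nfft segment/FFT length (default 1024).
#' @param fs sampling rate for the frequency axis (taken from `x` when it is
#'   a waveform).
#' @return A list with `freq` (Hz) and `psd` (one-sided power density, linear
#'   units).
#' @export
welch_psd <- function(x, nfft = 1024, fs = NULL) {
  if (inherits(x, "waveform")) { if (is.null(fs)) fs <- x$fs; x <- x$samples }
  if (is.null(fs)) fs <- 1
  n <- length(x)
  if (n < nfft) stop("signal shorter than one Welch segment")
  hop <- nfft / 2
  w <- hann_window(nfft)
  nseg <- floor((n - nfft) / hop) + 1
  acc <- numeric(nfft / 2 + 1)
  for (m in seq_len(nseg)) {
    seg <- x[((m - 1) * hop + 1):((m - 1) * hop + nfft)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nfft / 2 + 1)]
  }
  list(freq = (0:(nfft / 2)) * fs / nfft,
       psd = acc / (nseg * sum(w^2)))
}
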