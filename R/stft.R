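#' STFT analysis parameters
#'
#' The package's analysis convention is a 20 ms window with 50% overlap at
#' 16 kHz (frame length 320, hop 160). Ideal (oracle) masks use a zero-padded
#' 1024-point FFT; estimated masks use a 320-point FFT.
#'
#' @param frame_len frame length in samples (default 320 = 20 ms at 16 kHz).
#' @param hop hop size in samples; defaults to 50% overlap.
#' @param fft_len FFT length in samples, `>= frame_len`; frames are
#'   zero-padded when longer than the frame.
#' @param window window identifier; only `"hann"` is provided (it satisfies
#'   the constant-overlap-add condition at 50% overlap).
#' @return An object of class `"stft_params"`.
#' @export
stft_params <- function(frame_len = 320, hop = frame_len / 2,
                        fft_len = frame_len, window = "hann") {
  if (frame_len < 2) stop("'frame_len' must be >= 2")
  if (hop < 1) stop("'hop' must be >= 1")
  if (fft_len < frame_len) stop("'fft_len' must be >= 'frame_len'")
  window <- match.arg(window, "hann")
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 fft_len = as.integer(fft_len), window = window),
            class = "stft_params")
}

# periodic Hann
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

n_frames_for <- function(n, p) floor((n - p$frame_len) / p$hop) + 1L

#' Short-time Fourier transform
#'
#' One-sided complex STFT of a mono waveform. The frame count is
#' `floor((length(x) - frame_len) / hop) + 1`; trailing samples that do not
#' fill a frame are dropped. Frames are Hann-windowed and zero-padded to
#' `fft_len`.
#'
#' @param x a [waveform].
#' @param p an [stft_params] object.
#' @return An object of class `"spectrogram"`: list with `values` (complex
#'   matrix, `fft_len/2 + 1` frequency bins by frames), `params` and `fs`.
#' @seealso [istft()]
#' @export
stft <- function(x, p = stft_params()) {
  x <- as_waveform(x)
  n <- length(x$samples)
  if (n < p$frame_len)
    stop("signal (", n, " samples) is shorter than one frame (",
         p$frame_len, " samples)")
  nf <- n_frames_for(n, p)
  w <- hann_window(p$frame_len)
  idx <- outer(seq_len(p$frame_len), (seq_len(nf) - 1L) * p$hop, `+`)
  frames <- matrix(x$samples[idx], nrow = p$frame_len) * w
  if (p$fft_len > p$frame_len)
    frames <- rbind(frames, matrix(0, p$fft_len - p$frame_len, nf))
  V <- stats::mvfft(frames)
  nb <- p$fft_len / 2 + 1
  structure(list(values = V[seq_len(nb), , drop = FALSE], params = p,
                 fs = x$fs), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d bins x %d frames (frame %d, hop %d, fft %d) @ %g Hz\n",
    nrow(x$values), ncol(x$values), x$params$frame_len, x$params$hop,
    x$params$fft_len, x$fs))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

#' Inverse STFT (weighted overlap-add)
#'
#' Reconstructs a waveform from a one-sided spectrogram by conjugate-symmetric
#' spectrum completion, inverse FFT and windowed overlap-add, normalized by
#' the accumulated squared window. For an unmodified spectrogram the interior
#' of the signal is recovered to well below 1e-8; modified (masked) spectra
#' are resynthesized in the usual WOLA least-squares sense.
#'
#' @param S a `"spectrogram"` from [stft()] (or with modified values of the
#'   same shape).
#' @return A [waveform] of length `(n_frames - 1) * hop + frame_len`.
#' @export
istft <- function(S) {
  stopifnot(inherits(S, "spectrogram"))
  p <- S$params
  if (p$hop > p$frame_len)
    stop("hop (", p$hop, ") exceeds frame length (", p$frame_len,
         "): frames do not overlap-add to full coverage (non-COLA)")
  nb <- nrow(S$values)
  if (nb != p$fft_len / 2 + 1)
    stop("spectrogram has ", nb, " bins; expected fft_len/2 + 1 = ",
         p$fft_len / 2 + 1)
  nf <- ncol(S$values)
  full <- rbind(S$values,
                Conj(S$values[(nb - 1):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / p$fft_len
  frames <- frames[seq_len(p$frame_len), , drop = FALSE]
  w <- hann_window(p$frame_len)
  n_out <- (nf - 1L) * p$hop + p$frame_len
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  for (m in seq_len(nf)) {
    k <- (m - 1L) * p$hop
    rng <- (k + 1L):(k + p$frame_len)
    y[rng] <- y[rng] + frames[, m] * w
    wsum[rng] <- wsum[rng] + w^2
  }
  y <- y / pmax(wsum, 1e-12)
  waveform(y, S$fs)
}

# magnitude / phase helpers used throughout the mask module
spec_mag <- function(S) Mod(S$values)
spec_phase <- function(S) Arg(S$values)

check_same_shape <- function(A, B) {
  if (!identical(dim(A$values), dim(B$values)))
    stop("spectrogram shapes differ: ", paste(dim(A$values), collapse = "x"),
         " vs ", paste(dim(B$values), collapse = "x"))
  invisible(TRUE)
}
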