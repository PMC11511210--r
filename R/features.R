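# mel scale (HTK convention)
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: n_mel x n_bins, for a one-sided fft grid
mel_filterbank <- function(n_mel, fft_len, fs, f_min = 0, f_max = fs / 2) {
  n_bins <- fft_len / 2 + 1
  f <- (0:(n_bins - 1)) * fs / fft_len
  mpts <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mel + 2)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- fpts[m]; ce <- fpts[m + 1]; hi <- fpts[m + 2]
    up <- f >= lo & f <= ce
    dn <- f > ce & f <= hi
    fb[m, up] <- (f[up] - lo) / max(ce - lo, 1e-12)
    fb[m, dn] <- (hi - f[dn]) / max(hi - ce, 1e-12)
  }
  fb
}

# standard regression delta over +/-2 frames, edge frames replicated
delta_features <- function(feat, width = 2) {
  nf <- nrow(feat)
  pad <- feat[c(rep(1, width), seq_len(nf), rep(nf, width)), , drop = FALSE]
  num <- 0
  for (k in seq_len(width))
    num <- num + k * (pad[(width + 1 + k):(width + nf + k), , drop = FALSE] -
                      pad[(width + 1 - k):(width + nf - k), , drop = FALSE])
  num / (2 * sum(seq_len(width)^2))
}

# ARMA temporal smoothing, order m:
# y_t = (y_{t-1} + ... + y_{t-m} + x_t + ... + x_{t+m}) / (2m + 1)
arma_smooth <- function(feat, order = 2) {
  nf <- nrow(feat)
  if (order < 1 || nf <= 2 * order) return(feat)
  y <- feat
  for (t in (order + 1):(nf - order)) {
    y[t, ] <- (colSums(y[(t - order):(t - 1), , drop = FALSE]) +
               colSums(feat[t:(t + order), , drop = FALSE])) / (2 * order + 1)
  }
  y
}

#' Extract log-mel acoustic features from a mixture
#'
#' The estimator's input representation: 24 log-mel spectrogram features per
#' 20 ms frame (50% overlap), concatenated with their delta features (48
#' dimensions total) and smoothed along time with an auto-regressive
#' moving-average filter of order 2.
#'
#' @param mix input (noisy) [waveform].
#' @param params [stft_params] defining the framing; defaults to the
#'   estimation framing (frame 320, hop 160, fft 320).
#' @param n_mel number of mel bands (default 24).
#' @param arma_order ARMA smoothing order (default 2).
#' @return A numeric matrix, frames by `2 * n_mel`, with the feature recipe
#'   attached as attribute `"recipe"`.
#' @export
extract_features <- function(mix, params = stft_params(), n_mel = 24,
                             arma_order = 2) {
  mix <- as_waveform(mix)
  S <- stft(mix, params)
  fb <- mel_filterbank(n_mel, params$fft_len, mix$fs)
  melE <- t(fb %*% (Mod(S$values)^2))          # frames x n_mel
  logmel <- log(melE + 1e-8)
  feat <- cbind(logmel, delta_features(logmel))
  feat <- arma_smooth(feat, arma_order)
  attr(feat, "recipe") <- list(n_mel = n_mel, arma_order = arma_order,
                               frame_len = params$frame_len,
                               hop = params$hop, fft_len = params$fft_len)
  feat
}
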