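#' Short-Time Objective Intelligibility (STOI)
#'
#' The standard STOI procedure: both signals are resampled to 10 kHz,
#' silent frames (more than 40 dB below the loudest clean frame) are
#' removed, a 256-sample / 50%-overlap Hann STFT (512-point FFT) is grouped
#' into 15 one-third-octave bands from 150 Hz, and for every 384 ms segment
#' (30 frames) and band the correlation between the clean band envelope and
#' the normalized, SDR-clipped (-15 dB) degraded envelope is computed. The
#' score is the mean of these intermediate correlations and lies in \[0, 1\]
#' for speech-like material (interpretable as 0-100% intelligibility).
#'
#' @param clean reference clean-speech [waveform].
#' @param estimate degraded / enhanced [waveform] at the same sampling rate;
#'   when lengths differ both are trimmed to the shorter.
#' @return A single numeric STOI score.
#' @references Taal, Hendriks, Heusdens and Jensen (2011), "An algorithm for
#'   intelligibility prediction of time-frequency weighted noisy speech",
#'   IEEE TASLP 19(7).
#' @export
stoi <- function(clean, estimate) {
  clean <- as_waveform(clean); estimate <- as_waveform(estimate)
  if (clean$fs != estimate$fs) stop("sampling rates differ")
  n <- min(length(clean$samples), length(estimate$samples))
  x <- waveform(clean$samples[seq_len(n)], clean$fs)
  y <- waveform(estimate$samples[seq_len(n)], clean$fs)
  fs_i <- 10000
  if (clean$fs != fs_i) {
    x <- resample_wave(x, fs_i)
    y <- resample_wave(y, fs_i)
  }
  N_frame <- 256L; hop <- 128L; nfft <- 512L
  seg_n <- 30L; beta_db <- -15; dyn_range <- 40
  sil <- stoi_remove_silent(x$samples, y$samples, N_frame, hop, dyn_range)
  xs <- sil$x; ys <- sil$y
  if (length(xs) < N_frame + (seg_n - 1L) * hop)
    stop("signals too short for one STOI analysis segment after ",
         "silent-frame removal")
  X <- stoi_stft(xs, N_frame, hop, nfft)
  Y <- stoi_stft(ys, N_frame, hop, nfft)
  obm <- stoi_third_octaves(fs_i, nfft, 15L, 150)
  Xb <- sqrt(obm %*% (Mod(X)^2))   # bands x frames
  Yb <- sqrt(obm %*% (Mod(Y)^2))
  M <- ncol(Xb)
  clip <- 10^(-beta_db / 20)
  d_sum <- 0; d_cnt <- 0L
  for (m in seg_n:M) {
    xm <- Xb[, (m - seg_n + 1L):m, drop = FALSE]
    ym <- Yb[, (m - seg_n + 1L):m, drop = FALSE]
    alpha <- sqrt(rowSums(xm^2) / pmax(rowSums(ym^2), 1e-20))
    ya <- ym * alpha
    yc <- pmin(ya, xm * (1 + clip))
    xc <- xm - rowMeans(xm)
    yc <- yc - rowMeans(yc)
    num <- rowSums(xc * yc)
    den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
    d <- ifelse(den > 0, num / den, 0)
    d_sum <- d_sum + sum(d)
    d_cnt <- d_cnt + length(d)
  }
  d_sum / d_cnt
}

# Hann window matching the reference implementation (symmetric, endpoints
# dropped)
stoi_window <- function(n) 0.5 * (1 - cos(2 * pi * (1:n) / (n + 1)))

stoi_stft <- function(x, N_frame, hop, nfft) {
  w <- stoi_window(N_frame)
  nf <- floor((length(x) - N_frame) / hop) + 1L
  idx <- outer(seq_len(N_frame), (seq_len(nf) - 1L) * hop, `+`)
  frames <- matrix(x[idx], nrow = N_frame) * w
  frames <- rbind(frames, matrix(0, nfft - N_frame, nf))
  V <- stats::mvfft(frames)
  V[seq_len(nfft / 2 + 1), , drop = FALSE]
}

stoi_remove_silent <- function(x, y, N_frame, hop, dyn_range) {
  w <- stoi_window(N_frame)
  nf <- floor((length(x) - N_frame) / hop) + 1L
  starts <- (seq_len(nf) - 1L) * hop
  en <- vapply(starts, function(s)
    20 * log10(sqrt(sum((x[(s + 1):(s + N_frame)] * w)^2)) + 1e-20),
    numeric(1))
  keep <- which(en > max(en) - dyn_range)
  n_out <- (length(keep) - 1L) * hop + N_frame
  xs <- numeric(n_out); ys <- numeric(n_out)
  for (j in seq_along(keep)) {
    src <- starts[keep[j]]
    dst <- (j - 1L) * hop
    rng <- (dst + 1L):(dst + N_frame)
    xs[rng] <- xs[rng] + x[(src + 1):(src + N_frame)] * w
    ys[rng] <- ys[rng] + y[(src + 1):(src + N_frame)] * w
  }
  list(x = xs, y = ys)
}

# one-third-octave band matrix: bands x (nfft/2 + 1)
stoi_third_octaves <- function(fs, nfft, n_bands, f_min) {
  f <- (0:(nfft / 2)) * fs / nfft
  cf <- f_min * 2^((0:(n_bands - 1)) / 3)
  lo <- cf / 2^(1 / 6); hi <- cf * 2^(1 / 6)
  obm <- matrix(0, n_bands, length(f))
  for (j in seq_len(n_bands)) obm[j, f >= lo[j] & f < hi[j]] <- 1
  obm
}

#' Normalized Covariance Measure (NCM)
#'
#' Speech-transmission-index style intelligibility metric for vocoded
#' (cochlear-implant simulated) speech. Per analysis band the normalized
#' covariance `r` between the clean and estimate envelopes gives an apparent
#' SNR `10*log10(r^2 / (1 - r^2))`, clipped to \[-15, 15\] dB, mapped to a
#' transmission index `TI = (aSNR + 15) / 30`; the score is the
#' weighted mean of the band TIs.
#'
#' Both inputs are expected to already be vocoded signals; the band
#' envelopes are extracted with the vocoder's own analysis filterbank
#' ([channel_envelopes]) and then, as is standard for speech-transmission
#' -index measures, restricted to the intelligibility-bearing modulation
#' range by resampling to `env_fs` (default 25 Hz, i.e. modulations up to
#' 12.5 Hz) before the covariance is taken.
#'
#' @param clean_vocoded,estimate_vocoded vocoded [waveform]s of equal length
#'   and rate.
#' @param cfg the [vocoder_config] defining the analysis bands.
#' @param weights band-importance weights `W_i` (length = channel count);
#'   default uniform.
#' @param env_fs envelope sampling rate in Hz for the covariance stage
#'   (default 25).
#' @return A single numeric NCM score in \[0, 1\].
#' @export
ncm <- function(clean_vocoded, estimate_vocoded, cfg = vocoder_config(),
                weights = NULL, env_fs = 25) {
  x <- as_waveform(clean_vocoded); y <- as_waveform(estimate_vocoded)
  if (x$fs != y$fs) stop("sampling rates differ")
  if (length(x$samples) != length(y$samples)) stop("lengths differ")
  ex <- downsample_envelopes(channel_envelopes(x, cfg), x$fs, env_fs)
  ey <- downsample_envelopes(channel_envelopes(y, cfg), y$fs, env_fs)
  if (is.null(weights)) weights <- rep(1, cfg$n_channels)
  if (length(weights) != cfg$n_channels)
    stop("'weights' must have one entry per channel")
  ncm_from_envelopes(ex, ey, weights)
}

# decimate band envelopes by block averaging (boxcar anti-aliasing). An IIR
# anti-alias filter at so low a normalized cutoff (~1e-3) is numerically
# ill-conditioned; block means are exact, stable, and standard for
# modulation-domain (STI-type) envelope processing.
downsample_envelopes <- function(env, fs, env_fs) {
  step <- max(1L, floor(fs / env_fs))
  if (step == 1L) return(env)
  nblk <- floor(ncol(env) / step)
  if (nblk < 2) stop("signal too short for the envelope rate")
  idx <- rep(seq_len(nblk), each = step)
  t(apply(env[, seq_len(nblk * step), drop = FALSE], 1, function(e)
    as.numeric(tapply(e, idx, mean))))
}

# the Eq-chain on given band envelopes (rows = bands):
# r -> apparent SNR -> transmission index -> weighted mean
ncm_from_envelopes <- function(ex, ey, weights = rep(1, nrow(ex))) {
  ti <- rep(NA_real_, nrow(ex))
  for (i in seq_len(nrow(ex))) {
    if (stats::sd(ex[i, ]) == 0 || stats::sd(ey[i, ]) == 0) {
      warning("zero-variance envelope in band ", i, "; band skipped")
      next
    }
    r <- stats::cor(ex[i, ], ey[i, ])
    asnr <- 10 * log10(r^2 / max(1 - r^2, 1e-12))
    asnr <- min(max(asnr, -15), 15)
    ti[i] <- (asnr + 15) / 30
  }
  ok <- !is.na(ti)
  if (!any(ok)) stop("all bands skipped: NCM undefined")
  sum(weights[ok] * ti[ok]) / sum(weights[ok])
}

#' Map a raw PESQ score to wideband MOS
#'
#' The ITU P.862.2 wideband output mapping
#' `MOS = 0.999 + (4.999 - 0.999) / (1 + exp(-1.3669 * raw + 3.8224))`,
#' a strictly increasing logistic onto (0.999, 4.999). The raw P.862 score
#' itself must come from a reference PESQ implementation (its psychoacoustic
#' model is not reproduced here); this function only performs the mapping,
#' so label results accordingly.
#'
#' @param raw raw PESQ model output (vectorized).
#' @return MOS-mapped score(s) in (0.999, 4.999).
#' @export
pesq_mos_map <- function(raw) {
  if (!all(is.finite(raw))) stop("'raw' must be finite")
  0.999 + (4.999 - 0.999) / (1 + exp(-1.3669 * raw + 3.8224))
}
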