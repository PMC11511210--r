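#' @title Time-frequency masks for supervised speech separation
#' @description
#' The mask family operates on aligned one-sided spectrograms of clean speech
#' `S`, noise `N` and their additive mixture `Y = S + N`. Real masks are
#' returned as `"tf_mask"` objects carrying their kind and declared value
#' range; the complex ideal ratio mask is a `"tf_cmask"`. All masks treat
#' silent (zero-magnitude) bins conservatively: silence carries no speech
#' evidence, so division-by-zero bins get mask value 0, and local SNR is
#' clamped to +/-100 dB.
#' @name masks
NULL

new_tf_mask <- function(values, kind, range) {
  structure(list(values = values, kind = kind, range = range),
            class = "tf_mask")
}

#' @export
print.tf_mask <- function(x, ...) {
  cat(sprintf("<tf_mask:%s> %d x %d, declared range [%g, %g], observed [%g, %g]\n",
              x$kind, nrow(x$values), ncol(x$values), x$range[1], x$range[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.tf_cmask <- function(x, ...) {
  cat(sprintf("<tf_cmask:cIRM> %d x %d, Re in [%g, %g], Im in [%g, %g]\n",
              nrow(x$real), ncol(x$real), min(x$real), max(x$real),
              min(x$imag), max(x$imag)))
  invisible(x)
}

#' Local SNR per time-frequency unit
#'
#' `10*log10(|S|^2 / |N|^2)` for every T-F unit, clamped to \[-100, 100\] dB:
#' a silent noise bin gets the +100 dB ceiling, a silent speech bin the
#' -100 dB floor (a bin silent in both is treated as noise-dominated).
#'
#' @param S,N clean-speech and noise spectrograms of identical shape.
#' @param clamp_db magnitude of the degenerate-bin clamp (default 100).
#' @return A numeric matrix of dB values, same shape as the inputs.
#' @export
local_snr <- function(S, N, clamp_db = 100) {
  check_same_shape(S, N)
  es <- spec_mag(S)^2; en <- spec_mag(N)^2
  g <- matrix(-clamp_db, nrow(es), ncol(es))
  both <- es > 0 & en > 0
  g[both] <- 10 * log10(es[both] / en[both])
  g[es > 0 & en == 0] <- clamp_db
  pmin(pmax(g, -clamp_db), clamp_db)
}

#' Ideal Binary Mask
#'
#' 1 where the local SNR strictly exceeds the local criterion, else 0. The
#' local criterion follows the standard rule LC = mixture SNR - 5 dB.
#'
#' @param S,N clean and noise spectrograms.
#' @param mixture_snr_db global SNR of the mixture in dB.
#' @param lc_offset_db offset subtracted from the mixture SNR to form the
#'   local criterion (default 5).
#' @return A `"tf_mask"` with values in \{0, 1\}.
#' @export
ibm <- function(S, N, mixture_snr_db, lc_offset_db = 5) {
  lc <- mixture_snr_db - lc_offset_db
  v <- (local_snr(S, N) > lc) * 1
  new_tf_mask(v, "IBM", c(0, 1))
}

#' Ideal Ratio Mask
#'
#' `|S|^2 / (|S|^2 + |N|^2)` per unit: the Wiener gain of the local
#' speech/noise energy ratio. Bins silent in both signals get 0.
#'
#' @inheritParams ibm
#' @return A `"tf_mask"` with values in \[0, 1\].
#' @export
irm <- function(S, N) {
  check_same_shape(S, N)
  es <- spec_mag(S)^2; en <- spec_mag(N)^2
  tot <- es + en
  v <- ifelse(tot == 0, 0, es / tot)
  new_tf_mask(v, "IRM", c(0, 1))
}

#' Spectral-magnitude (FFT) mask
#'
#' `|S| / |Y|`, the ratio of clean to noisy spectral magnitudes. Unbounded
#' above in its ideal form; the training-target pathway clips at 1.5.
#'
#' @param S,Y clean and noisy spectrograms.
#' @param clip upper clip value (1.5 for the training target), or `NULL` for
#'   the unclipped oracle mask.
#' @return A `"tf_mask"`; range \[0, clip\] or \[0, Inf).
#' @export
fftm <- function(S, Y, clip = NULL) {
  check_same_shape(S, Y)
  my <- spec_mag(Y)
  v <- ifelse(my == 0, 0, spec_mag(S) / my)
  if (!is.null(clip)) {
    v <- pmin(v, clip)
    new_tf_mask(v, "FFTM", c(0, clip))
  } else new_tf_mask(v, "FFTM", c(0, Inf))
}

#' Phase-Sensitive Mask
#'
#' `(|S|/|Y|) * cos(theta_S - theta_Y) = Re(S / Y)`: the magnitude ratio
#' attenuated by the clean/noisy phase difference. Analytically equal to the
#' Optimal Ratio Mask. Unbounded in both directions; bins with `|Y| = 0`
#' get 0.
#'
#' @inheritParams fftm
#' @return A `"tf_mask"`; range (-Inf, Inf).
#' @export
psm <- function(S, Y) {
  check_same_shape(S, Y)
  my <- spec_mag(Y)
  v <- matrix(0, nrow(my), ncol(my))
  nz <- my > 0
  v[nz] <- Re(S$values[nz] / Y$values[nz])
  new_tf_mask(v, "PSM", c(-Inf, Inf))
}

#' Complex Ideal Ratio Mask
#'
#' The complex mask whose complex product with the noisy spectrum returns the
#' clean spectrum exactly:
#' `M_r = (Y_r S_r + Y_i S_i) / (Y_r^2 + Y_i^2)`,
#' `M_i = (Y_r S_i - Y_i S_r) / (Y_r^2 + Y_i^2)`.
#' Its real part equals the PSM. Bins with `|Y| = 0` get 0 in both parts.
#'
#' @inheritParams fftm
#' @return A `"tf_cmask"`: list with `real` and `imag` matrices.
#' @export
cirm <- function(S, Y) {
  check_same_shape(S, Y)
  yr <- Re(Y$values); yi <- Im(Y$values)
  sr <- Re(S$values); si <- Im(S$values)
  den <- yr^2 + yi^2
  mr <- ifelse(den == 0, 0, (yr * sr + yi * si) / den)
  mi <- ifelse(den == 0, 0, (yr * si - yi * sr) / den)
  structure(list(real = mr, imag = mi), class = "tf_cmask")
}

#' Quantized Mask
#'
#' A five-level staircase over local SNR approximating the Wiener Gain
#' Function. With mixture SNR `s`, the thresholds are LC1..LC4 =
#' `s - c(8, 6, 4, 2)` dB and the levels 0, 0.25, 0.5, 0.75, 1 on the
#' half-open partition `[LCk, LCk+1)`, with level 1 for local SNR `>= LC4`.
#'
#' @inheritParams ibm
#' @return A `"tf_mask"` with values in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
qm <- function(S, N, mixture_snr_db) {
  g <- local_snr(S, N)
  lcs <- mixture_snr_db - c(8, 6, 4, 2)
  v <- matrix(findInterval(g, lcs), nrow(g), ncol(g)) / 4
  new_tf_mask(v, "QM", c(0, 1))
}

# staircase on a plain local-SNR grid (used for the Wiener-gain comparison)
qm_of_snr <- function(gamma_db, mixture_snr_db = 5)
  findInterval(gamma_db, mixture_snr_db - c(8, 6, 4, 2)) / 4

#' Wiener gain of a local SNR (dB)
#'
#' `xi / (1 + xi)` with `xi = 10^(gamma_db/10)`; the MMSE-optimal spectral
#' gain that the quantized mask approximates and that the IRM equals on the
#' local-SNR grid.
#'
#' @param gamma_db local SNR in dB (vectorized).
#' @return Gain values in \[0, 1\].
#' @export
wiener_gain <- function(gamma_db) {
  xi <- 10^(gamma_db / 10)
  xi / (1 + xi)
}

#' Hybrid phase-sensitive / ratio mask (PSM+)
#'
#' Per unit: where the PSM is negative the IRM value is used instead (the
#' negative phase-sensitive values still carry magnitude information worth
#' keeping); where the PSM exceeds 2 it is clipped at 2; otherwise the PSM
#' is kept. Values therefore lie in \[0, 2\].
#'
#' @param S,Y,N clean, noisy and noise spectrograms (all aligned).
#' @param clip upper clip (default 2).
#' @return A `"tf_mask"` with values in \[0, `clip`\].
#' @export
psm_plus <- function(S, Y, N, clip = 2) {
  p <- psm(S, Y)$values
  i <- irm(S, N)$values
  v <- ifelse(p < 0, i, pmin(p, clip))
  new_tf_mask(v, "PSMplus", c(0, clip))
}

#' Apply a real mask to a noisy spectrogram
#'
#' The estimated speech spectrum is `M * |Y| * exp(j * theta_Y)`: the mask
#' scales the noisy magnitude and the noisy phase is reused.
#'
#' @param M a `"tf_mask"` (or bare numeric matrix).
#' @param Y noisy spectrogram.
#' @return A `"spectrogram"` ready for [istft()].
#' @export
apply_mask <- function(M, Y) {
  v <- if (inherits(M, "tf_mask")) M$values else M
  if (!identical(dim(v), dim(Y$values))) stop("mask/spectrogram shape mismatch")
  out <- Y
  out$values <- v * Y$values  # real gain times Y == M|Y|e^{j theta_Y}
  out
}

#' Apply a complex mask to a noisy spectrogram
#'
#' Elementwise complex product `(M_r + j M_i) * Y`. With the oracle cIRM this
#' recovers the clean spectrum exactly wherever `Y` is non-zero, and the
#' result keeps the conjugate symmetry needed for a real [istft()] output.
#'
#' @param M a `"tf_cmask"`.
#' @param Y noisy spectrogram.
#' @return A `"spectrogram"`.
#' @export
apply_complex_mask <- function(M, Y) {
  stopifnot(inherits(M, "tf_cmask"))
  if (!identical(dim(M$real), dim(Y$values)))
    stop("mask/spectrogram shape mismatch")
  out <- Y
  out$values <- complex(real = M$real, imaginary = M$imag) * Y$values
  # DC and (even-fft) Nyquist bins of a real signal are real-valued; a
  # complex gain there would break conjugate symmetry, so drop their
  # imaginary part explicitly.
  out$values[1, ] <- complex(real = Re(out$values[1, ]), imaginary = 0)
  nb <- nrow(out$values)
  if (Y$params$fft_len %% 2 == 0)
    out$values[nb, ] <- complex(real = Re(out$values[nb, ]), imaginary = 0)
  out
}

#' Summarize the value distribution of a mask
#'
#' For hard / quantized masks (IBM, QM) exact level fractions are reported;
#' for soft masks a histogram over `nbins` equal-width bins spanning the
#' observed range (plus the declared range when finite).
#'
#' @param M a `"tf_mask"`, or one part of a `"tf_cmask"` as a numeric matrix.
#' @param nbins bin count for soft masks (default 50).
#' @return A list with `breaks` (or `levels`), `counts` and `fractions`.
#' @export
mask_histogram <- function(M, nbins = 50) {
  v <- if (inherits(M, "tf_mask")) as.vector(M$values) else as.vector(M)
  if (length(v) == 0) stop("empty mask")
  kind <- if (inherits(M, "tf_mask")) M$kind else "values"
  if (kind %in% c("IBM", "QM")) {
    lev <- if (kind == "IBM") c(0, 1) else c(0, 0.25, 0.5, 0.75, 1)
    cnt <- vapply(lev, function(l) sum(v == l), numeric(1))
    list(levels = lev, counts = cnt, fractions = cnt / length(v))
  } else {
    rng <- range(v)
    if (inherits(M, "tf_mask") && all(is.finite(M$range)))
      rng <- range(rng, M$range)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
    cnt <- bin_counts(v, breaks)
    list(breaks = breaks, counts = cnt, fractions = cnt / length(v))
  }
}
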