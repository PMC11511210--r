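make_spec <- function(values, fft_len = 64) {
  structure(list(values = values,
                 params = stft_params(frame_len = fft_len, fft_len = fft_len),
                 fs = 16000),
            class = "spectrogram")
}

test_that("local SNR handles plain and degenerate bins", {
  S <- make_spec(matrix(complex(real = c(1, 1, 0, 0), imaginary = 0), 2, 2))
  N <- make_spec(matrix(complex(real = c(1, sqrt(0.1), 1, 0),
                                imaginary = 0), 2, 2))
  g <- local_snr(S, N)
  expect_equal(g[1, 1], 0)          # |S| = |N|
  expect_equal(g[2, 1], 10)         # |S|^2 = 10 |N|^2
  expect_equal(g[1, 2], -100)       # S = 0
  expect_equal(g[2, 2], -100)       # both silent -> noise-dominated
  S2 <- make_spec(matrix(1 + 0i, 1, 1)); N2 <- make_spec(matrix(0i, 1, 1))
  expect_equal(local_snr(S2, N2)[1, 1], 100)  # |N| = 0 ceiling
  expect_error(local_snr(S, S2), "shapes differ")
})

test_that("IBM applies the LC = mixture SNR - 5 rule with strict inequality", {
  # local SNR 3 dB vs LC = 0 (mixture 5 dB) -> 1
  S <- make_spec(matrix(complex(real = 10^(3 / 20), imaginary = 0), 1, 1))
  N <- make_spec(matrix(1 + 0i, 1, 1))
  expect_equal(ibm(S, N, 5)$values[1, 1], 1)
  # local SNR exactly at LC -> 0
  S0 <- make_spec(matrix(1 + 0i, 1, 1))
  expect_equal(ibm(S0, N, 5)$values[1, 1], 0)
  # silent noise -> all ones
  Z <- make_spec(matrix(0i, 1, 1))
  expect_equal(ibm(S, Z, 5)$values[1, 1], 1)
})

test_that("IRM evaluates the energy ratio and stays in [0, 1]", {
  S <- make_spec(matrix(3 + 0i, 1, 1)); N <- make_spec(matrix(0 + 4i, 1, 1))
  expect_equal(irm(S, N)$values[1, 1], 9 / 25)
  Z <- make_spec(matrix(0i, 1, 1))
  expect_equal(irm(S, Z)$values[1, 1], 1)
  expect_equal(irm(Z, N)$values[1, 1], 0)
  expect_equal(irm(Z, Z)$values[1, 1], 0)
  sp <- fix_spec_pair(31)
  v <- irm(sp$S, sp$N)$values
  expect_true(all(v >= 0 & v <= 1))
})

test_that("IRM equals the Wiener gain of the local SNR grid", {
  sp <- fix_spec_pair(32)
  expect_lt(max(abs(irm(sp$S, sp$N)$values -
                    wiener_gain(local_snr(sp$S, sp$N)))), 1e-10)
})

test_that("FFTM clips at 1.5 only when asked", {
  S <- make_spec(matrix(2 + 0i, 1, 1)); Y <- make_spec(matrix(1 + 0i, 1, 1))
  expect_equal(fftm(S, Y, clip = 1.5)$values[1, 1], 1.5)
  expect_equal(fftm(S, Y)$values[1, 1], 2)      # oracle mode unclipped
  expect_equal(fftm(S, S)$values[1, 1], 1)
  sp <- fix_spec_pair(33)
  expect_true(all(fftm(sp$S, sp$Y, clip = 1.5)$values <= 1.5))
})

test_that("PSM matches both of its closed forms", {
  # 90-degree phase difference zeroes the mask regardless of magnitudes
  S <- make_spec(matrix(3 + 0i, 1, 1)); Y <- make_spec(matrix(0 + 2i, 1, 1))
  expect_equal(psm(S, Y)$values[1, 1], 0)
  expect_equal(psm(S, S)$values[1, 1], 1)
  # S = 1, N = j: magnitude/phase form and the ORM energy form agree at 0.5
  S1 <- make_spec(matrix(1 + 0i, 1, 1)); N1 <- make_spec(matrix(0 + 1i, 1, 1))
  Y1 <- make_spec(S1$values + N1$values)
  expect_equal(psm(S1, Y1)$values[1, 1], 0.5)
  orm <- (Mod(S1$values)^2 + Re(S1$values * Conj(N1$values))) /
    (Mod(S1$values)^2 + Mod(N1$values)^2 +
       2 * Re(S1$values * Conj(N1$values)))
  expect_equal(psm(S1, Y1)$values[1, 1], orm[1, 1])
})

test_that("PSM magnitude-cosine form equals the ORM energy form on random spectra", {
  sp <- fix_spec_pair(34, nb = 40, nf = 25)
  p1 <- Mod(sp$S$values) / Mod(sp$Y$values) *
    cos(Arg(sp$S$values) - Arg(sp$Y$values))
  orm <- (Mod(sp$S$values)^2 + Re(sp$S$values * Conj(sp$N$values))) /
    (Mod(sp$S$values)^2 + Mod(sp$N$values)^2 +
       2 * Re(sp$S$values * Conj(sp$N$values)))
  expect_lt(max(abs(p1 - orm)), 1e-10)
  expect_lt(max(abs(psm(sp$S, sp$Y)$values - p1)), 1e-10)
})

test_that("cIRM recovers the clean spectrum and its real part is the PSM", {
  sp <- fix_spec_pair(35)
  M <- cirm(sp$S, sp$Y)
  rec <- apply_complex_mask(M, sp$Y)
  # skip DC/Nyquist rows where conjugate-symmetry repair applies
  inner <- 2:(nrow(rec$values) - 1)
  expect_lt(max(Mod(rec$values[inner, ] - sp$S$values[inner, ])), 1e-12)
  expect_lt(max(abs(M$real - psm(sp$S, sp$Y)$values)), 1e-10)
  My <- cirm(sp$Y, sp$Y)
  expect_lt(max(abs(My$real - 1)), 1e-12)
  expect_lt(max(abs(My$imag)), 1e-12)
})

test_that("QM staircase follows the LC1..LC4 partition with half-open bands", {
  # mixture SNR 5 -> thresholds -3, -1, 1, 3
  mk <- function(g) {  # spectrogram pair with local SNR exactly g dB
    S <- make_spec(matrix(complex(real = 10^(g / 20), imaginary = 0), 1, 1))
    N <- make_spec(matrix(1 + 0i, 1, 1))
    qm(S, N, 5)$values[1, 1]
  }
  expect_equal(mk(-5), 0)
  expect_equal(mk(0), 0.5)
  expect_equal(mk(5), 1)
  # boundaries on an exact local-SNR grid: gamma == LC4 -> top level,
  # gamma == LC1 -> second level (half-open partition)
  expect_equal(cimask:::qm_of_snr(3, 5), 1)
  expect_equal(cimask:::qm_of_snr(-3, 5), 0.25)
  expect_equal(cimask:::qm_of_snr(-3 - 1e-9, 5), 0)
  sp <- fix_spec_pair(36)
  expect_true(all(qm(sp$S, sp$N, 5)$values %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("QM tracks the Wiener gain within 0.35 and is monotone", {
  g <- seq(-30, 30, by = 0.001)
  q <- cimask:::qm_of_snr(g, mixture_snr_db = 5)
  expect_lt(max(abs(q - wiener_gain(g))), 0.35)
  expect_true(all(diff(q) >= 0))
})

test_that("PSM+ substitutes IRM for negative PSM and clips at 2", {
  mk_pair <- function(s, n) {
    S <- make_spec(matrix(s, 1, 1)); N <- make_spec(matrix(n, 1, 1))
    Y <- make_spec(matrix(s + n, 1, 1))
    list(S = S, N = N, Y = Y)
  }
  # opposite-phase noise: PSM < 0, expect the IRM value instead
  a <- mk_pair(1 + 0i, -3 + 0i)
  expect_lt(psm(a$S, a$Y)$values[1, 1], 0)
  expect_equal(psm_plus(a$S, a$Y, a$N)$values[1, 1],
               irm(a$S, a$N)$values[1, 1])
  # partial cancellation: PSM > 2, expect clip at 2
  b <- mk_pair(1 + 0i, -0.6 + 0i)
  expect_gt(psm(b$S, b$Y)$values[1, 1], 2)
  expect_equal(psm_plus(b$S, b$Y, b$N)$values[1, 1], 2)
  # in-range PSM passes through
  c_ <- mk_pair(1 + 0i, -0.2 + 0i)
  expect_equal(psm_plus(c_$S, c_$Y, c_$N)$values[1, 1],
               psm(c_$S, c_$Y)$values[1, 1])
  sp <- fix_spec_pair(37)
  v <- psm_plus(sp$S, sp$Y, sp$N)$values
  expect_true(all(v >= 0 & v <= 2))
})

test_that("mask application reuses the noisy phase and respects trivial masks", {
  sp <- fix_spec_pair(38)
  ones <- cimask:::new_tf_mask(matrix(1, nrow(sp$Y$values),
                                      ncol(sp$Y$values)), "IRM", c(0, 1))
  expect_equal(apply_mask(ones, sp$Y)$values, sp$Y$values)
  zeros <- ones; zeros$values[] <- 0
  expect_true(all(Mod(apply_mask(zeros, sp$Y)$values) == 0))
  idm <- structure(list(real = matrix(1, nrow(sp$Y$values),
                                      ncol(sp$Y$values)),
                        imag = matrix(0, nrow(sp$Y$values),
                                      ncol(sp$Y$values))),
                   class = "tf_cmask")
  expect_equal(apply_complex_mask(idm, sp$Y)$values[2:32, ],
               sp$Y$values[2:32, ])
})

test_that("complex-masked spectrograms resynthesize to real signals", {
  cl <- fix_utterance()
  mx <- fix_mixture(-5)
  p <- stft_params(fft_len = 1024)
  S <- stft(cl, p); Y <- stft(mx$mixture, p)
  out <- istft(apply_complex_mask(cirm(S, Y), Y))
  expect_true(all(is.finite(out$samples)))
  ref <- cimask:::trim_to_frames(cl, p)
  interior <- 321:(length(out$samples) - 320)
  expect_lt(max(abs(out$samples[interior] - ref$samples[interior])), 1e-8)
})

test_that("ideal IRM enhancement improves STOI over the mixture", {
  mx <- fix_mixture(-5)
  p <- stft_params(fft_len = 1024)
  S <- stft(mx$clean, p); N <- stft(mx$noise, p); Y <- stft(mx$mixture, p)
  ref <- cimask:::trim_to_frames(mx$clean, p)
  enhanced <- istft(apply_mask(irm(S, N), Y))
  expect_gt(stoi(ref, enhanced), stoi(ref, mx$mixture))
})

test_that("mask histograms report exact level fractions and full coverage", {
  sp <- fix_spec_pair(39)
  hb <- mask_histogram(ibm(sp$S, sp$N, 0))
  expect_equal(sum(hb$fractions), 1)
  expect_equal(hb$levels, c(0, 1))
  hq <- mask_histogram(qm(sp$S, sp$N, 0))
  expect_equal(length(hq$fractions), 5)
  expect_equal(sum(hq$fractions), 1)
  hf <- mask_histogram(fftm(sp$S, sp$Y), nbins = 20)
  expect_equal(sum(hf$fractions), 1)
  expect_error(mask_histogram(matrix(numeric(0), 0, 0)), "empty")
})
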