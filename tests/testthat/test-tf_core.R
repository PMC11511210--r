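test_that("waveform constructor validates its invariants", {
  expect_s3_class(waveform(rnorm(100)), "waveform")
  expect_error(waveform(c(1, NA)), "finite")
  expect_error(waveform(c(1, Inf)), "finite")
  expect_error(waveform(numeric(0)), "non-empty")
  expect_error(waveform(rnorm(10), fs = -1), "positive")
  expect_equal(waveform(1:4)$fs, 16000)
})

test_that("WAV files round-trip losslessly in float32 and quantized in PCM16", {
  x <- fix_utterance()
  f <- tempfile(fileext = ".wav")
  write_wav(f, x, bits = 32)
  y <- read_wav(f)
  expect_equal(y$fs, x$fs)
  expect_equal(y$samples, x$samples, tolerance = 1e-7)
  write_wav(f, x, bits = 16)
  y16 <- read_wav(f)
  expect_lt(max(abs(y16$samples - x$samples)), 1 / 32768 + 1e-12)
  unlink(f)
})

test_that("stereo WAV input is rejected rather than down-mixed", {
  # hand-build a 2-channel PCM16 file
  f <- tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # 2 channels
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(64000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L, 0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(read_wav(f), "mono")
  expect_error(read_wav(tempfile()), "not found")
  unlink(f)
})

test_that("resampling preserves a tone's frequency", {
  x <- fix_tone(1000, dur = 2, fs = 44100)
  y <- resample_wave(x, 16000)
  expect_equal(y$fs, 16000)
  n <- length(y$samples)
  sp <- Mod(stats::fft(y$samples * hann_window(n)))^2
  peak_hz <- (which.max(sp[1:(n / 2)]) - 1) * 16000 / n
  expect_lt(abs(peak_hz - 1000), 2)
})

test_that("stft follows the 20 ms / 50% overlap convention and frame formula", {
  p <- stft_params()
  expect_equal(p$frame_len, 320L)  # 20 ms at 16 kHz
  expect_equal(p$hop, 160L)        # 50% overlap
  # one-frame boundary case
  S1 <- stft(waveform(rnorm(320)), p)
  expect_equal(ncol(S1$values), 1L)
  expect_equal(nrow(S1$values), 161L)
  # frame-count formula over random lengths
  for (n in with_seed_test(1, sample(320:5000, 20))) {
    S <- stft(waveform(rnorm(n)), p)
    expect_equal(ncol(S$values), floor((n - 320) / 160) + 1)
  }
  expect_error(stft(waveform(rnorm(319)), p), "shorter than one frame")
})

test_that("a pure tone concentrates in the expected FFT bin", {
  S <- stft(fix_tone(1000, dur = 0.5), stft_params(fft_len = 1024))
  mid <- ceiling(ncol(S$values) / 2)
  expect_equal(which.max(Mod(S$values[, mid])) - 1L,
               round(1000 * 1024 / 16000))  # bin 64
  # against a direct DFT of the same windowed frame
  x <- fix_tone(1000, dur = 0.5)$samples
  fr <- x[(160 * (mid - 1) + 1):(160 * (mid - 1) + 320)] * hann_window(320)
  direct <- stats::fft(c(fr, numeric(704)))[1:161]
  expect_equal(S$values[1:161, mid], direct, tolerance = 1e-12)
})

test_that("istft(stft(x)) reconstructs the interior to below 1e-8", {
  for (fft_len in c(320, 1024)) {
    p <- stft_params(fft_len = fft_len)
    x <- with_seed_test(fft_len, waveform(rnorm(4000)))
    y <- istft(stft(x, p))
    interior <- 321:(length(y$samples) - 320)
    expect_lt(max(abs(y$samples[interior] - x$samples[interior])), 1e-8)
  }
})

test_that("istft linearity and degenerate cases", {
  p <- stft_params()
  S <- stft(fix_utterance(), p)
  S2 <- S; S2$values <- 2 * S$values
  expect_equal(istft(S2)$samples, 2 * istft(S)$samples, tolerance = 1e-12)
  Z <- S; Z$values[] <- 0
  expect_true(all(istft(Z)$samples == 0))
  bad <- S; bad$params$hop <- 500L
  expect_error(istft(bad), "non-COLA")
})

test_that("stft is linear in its input", {
  p <- stft_params()
  x <- with_seed_test(2, waveform(rnorm(2000)))
  y <- with_seed_test(3, waveform(rnorm(2000)))
  lhs <- stft(waveform(2.5 * x$samples - 1.25 * y$samples), p)$values
  rhs <- 2.5 * stft(x, p)$values - 1.25 * stft(y, p)$values
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
})
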