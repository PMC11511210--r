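#' Construct a mono waveform
#'
#' A waveform is the unit every stage of the package consumes: a finite 1-D
#' numeric vector of samples (nominal amplitude range \[-1, 1\]) together with
#' its sampling rate in Hz.
#'
#' @param samples numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0); defaults to 16000, the rate the whole
#'   processing chain is designed around.
#' @return An object of class `"waveform"`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' x <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 16000)), 16000)
#' x
#' @export
waveform <- function(samples, fs = 16000) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("'samples' must be finite (no NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(samples = samples, fs = fs), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

as_waveform <- function(x, fs = 16000) {
  if (inherits(x, "waveform")) x else waveform(x, fs)
}

wave_rms <- function(x) sqrt(mean(as_waveform(x)$samples^2))

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files containing 16-bit PCM or 32-bit IEEE float samples.
#' Stereo (or any multi-channel) input is rejected rather than silently
#' down-mixed. PCM16 samples are scaled to \[-1, 1) by 1/32768.
#'
#' @param path path to a `.wav` file.
#' @param fs_target optional sampling rate in Hz; when supplied and different
#'   from the file's rate, the signal is resampled (polyphase FIR).
#' @return A [waveform].
#' @seealso [write_wav()], [resample_wave()]
#' @export
read_wav <- function(path, fs_target = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        fs       = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, size = 2,
                           endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L)
        stop("only mono WAV is supported (file has ", fmt$channels,
             " channels)")
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz / 2L, size = 2,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz / 4L, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits); only PCM16 and float32 are handled")
      }
      if (sz %% 2L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  x <- waveform(samples, fmt$fs)
  if (!is.null(fs_target) && fs_target != fmt$fs)
    x <- resample_wave(x, fs_target)
  x
}

#' Write a mono waveform to a WAV file
#'
#' @param path output path (directory must exist).
#' @param x a [waveform].
#' @param bits 32 (IEEE float, lossless for this package's float pipeline) or
#'   16 (PCM, quantized).
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, x, bits = 32) {
  x <- as_waveform(x)
  if (!bits %in% c(16, 32)) stop("'bits' must be 16 or 32")
  n <- length(x$samples)
  bytes_per <- bits / 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3L else 1L), con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(round(x$fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(x$fs) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x$samples, con, size = 4, endian = "little")
  } else {
    s <- pmin(pmax(round(x$samples * 32768), -32768), 32767)
    writeBin(as.integer(s), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Resample a waveform to a new rate
#'
#' Polyphase FIR resampling (via [signal::resample]) between integer sampling
#' rates; the rational conversion factor is reduced by their GCD.
#'
#' @param x a [waveform].
#' @param fs_target target sampling rate in Hz (integer).
#' @return A [waveform] at `fs_target`.
#' @export
resample_wave <- function(x, fs_target) {
  x <- as_waveform(x)
  if (fs_target == x$fs) return(x)
  f1 <- round(x$fs); f2 <- round(fs_target)
  if (f1 != x$fs || f2 != fs_target)
    stop("resampling requires integer sampling rates")
  g <- gcd_int(f1, f2)
  y <- as.numeric(signal::resample(x$samples, f2 / g, f1 / g))
  waveform(y, fs_target)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
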