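# shared fixtures, built once per test run; everything derives from fixed
# seeds so the suite is deterministic

fix_fs <- 16000

fix_tone <- function(freq = 1000, dur = 1, fs = fix_fs, amp = 1)
  waveform(amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs), fs)

fix_utterance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_utterance(synth_spec(seed = 7))
    cache
  }
})

fix_noise <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_noise("babble_like", duration = 4, seed = 13)
    cache
  }
})

fix_mixture <- local({
  cache <- NULL
  function(snr_db = -5) {
    key <- as.character(snr_db)
    if (is.null(cache[[key]])) {
      cl <- fix_utterance()
      cut <- with_seed_test(5, random_cut(fix_noise(), length(cl$samples)))
      cache[[key]] <<- c(mix_at_snr(cl, cut, snr_db), list(clean = cl))
    }
    cache[[key]]
  }
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# random complex spectrogram pair on a tiny grid, for mask identities
fix_spec_pair <- function(seed, nb = 33, nf = 12, fft_len = 64) {
  with_seed_test(seed, {
    p <- stft_params(frame_len = fft_len, fft_len = fft_len)
    mk <- function() {
      v <- matrix(complex(real = rnorm(nb * nf), imaginary = rnorm(nb * nf)),
                  nb, nf)
      structure(list(values = v, params = p, fs = fix_fs),
                class = "spectrogram")
    }
    S <- mk(); N <- mk()
    Y <- S; Y$values <- S$values + N$values
    list(S = S, N = N, Y = Y)
  })
}
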