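#' Oracle (ideal-mask) evaluation over a corpus
#'
#' For every combination of mask kind, noise kind and SNR, each utterance is
#' mixed with a random noise cut, the ideal mask is computed from the clean
#' and noise spectrograms (oracle knowledge), applied to the mixture,
#' resynthesized, and scored against the clean signal with STOI. The
#' unprocessed mixture is included as the `"Mix"` baseline. Oracle masks use
#' the 1024-point zero-padded FFT convention by default and are unclipped.
#'
#' @param corpus list of clean-speech [waveform]s.
#' @param noises named list of noise [waveform]s (each at least as long as
#'   the longest utterance).
#' @param snr_db vector of mixture SNRs in dB.
#' @param masks mask kinds to evaluate, a subset of
#'   `c("ibm","irm","fftm","psm","qm","psmplus","cirm")`.
#' @param params [stft_params] for mask computation (default: frame 320,
#'   hop 160, fft 1024).
#' @param seed top-level seed; all noise cuts derive from it.
#' @param region noise-cut region passed to [random_cut].
#' @return A data.frame with columns `mask`, `noise`, `snr_db`, `mean`,
#'   `median`, `sd`, `n`, plus per-row best/worst flags, of class
#'   `"oracle_eval"`. The per-utterance scores are attached as attribute
#'   `"scores"`.
#' @export
run_oracle_eval <- function(corpus, noises, snr_db = -5,
                            masks = c("ibm", "irm", "fftm", "psm", "qm",
                                      "psmplus", "cirm"),
                            params = stft_params(fft_len = 1024),
                            seed = 1, region = "head") {
  if (length(corpus) == 0) stop("empty corpus")
  if (is.null(names(noises)) || any(names(noises) == ""))
    stop("'noises' must be a named list")
  known <- c("ibm", "irm", "fftm", "psm", "qm", "psmplus", "cirm")
  if (!all(masks %in% known))
    stop("unknown mask kind(s): ", paste(setdiff(masks, known), collapse = ", "))
  rows <- list(); scores <- list()
  for (nk in names(noises)) for (s in snr_db) {
    per_mask <- matrix(NA_real_, length(corpus), length(masks) + 1,
                       dimnames = list(NULL, c("Mix", masks)))
    for (u in seq_along(corpus)) {
      cl <- corpus[[u]]
      res <- with_seed(seed + 7919 * u + 131 * match(nk, names(noises)) +
                         round(1000 * s), {
        cut <- random_cut(noises[[nk]], length(cl$samples), region = region)
        mix_at_snr(cl, cut, s)
      })
      S <- stft(cl, params); N <- stft(res$noise, params)
      Y <- stft(res$mixture, params)
      ref <- trim_to_frames(cl, params)
      per_mask[u, "Mix"] <- stoi(ref, res$mixture)
      for (mk in masks) {
        Sh <- switch(mk,
          ibm     = apply_mask(ibm(S, N, s), Y),
          irm     = apply_mask(irm(S, N), Y),
          fftm    = apply_mask(fftm(S, Y), Y),
          psm     = apply_mask(psm(S, Y), Y),
          qm      = apply_mask(qm(S, N, s), Y),
          psmplus = apply_mask(psm_plus(S, Y, N), Y),
          cirm    = apply_complex_mask(cirm(S, Y), Y))
        per_mask[u, mk] <- stoi(ref, istft(Sh))
      }
    }
    scores[[paste(nk, s, sep = "@")]] <- per_mask
    for (col in colnames(per_mask)) {
      rows[[length(rows) + 1]] <- data.frame(
        mask = col, noise = nk, snr_db = s,
        mean = mean(per_mask[, col]),
        median = stats::median(per_mask[, col]),
        sd = stats::sd(per_mask[, col]), n = nrow(per_mask),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- flag_best_worst(out, group = c("noise", "snr_db"))
  attr(out, "scores") <- scores
  class(out) <- c("oracle_eval", class(out))
  out
}

# clean reference trimmed to the istft framing extent
trim_to_frames <- function(x, params) {
  nf <- n_frames_for(length(x$samples), params)
  waveform(x$samples[seq_len((nf - 1L) * params$hop + params$frame_len)],
           x$fs)
}

# best = highest mean and lowest sd; when they disagree, the mean wins and
# the row is tie-flagged. Mask rows only ("Mix" is the baseline).
flag_best_worst <- function(df, group) {
  df$best <- FALSE; df$worst <- FALSE; df$tie <- FALSE
  key <- interaction(df[group], drop = TRUE)
  for (g in levels(key)) {
    i <- which(key == g & df$mask != "Mix" &
                 !startsWith(df$mask, "oracle_"))
    if (length(i) < 2) next
    bi <- i[which.max(df$mean[i])]; wi <- i[which.min(df$mean[i])]
    df$best[bi] <- TRUE; df$worst[wi] <- TRUE
    if (df$sd[bi] > min(df$sd[i])) df$tie[bi] <- TRUE
  }
  df
}

#' Estimated-mask evaluation: train MLPs and score enhancement
#'
#' Runs the full supervised-enhancement experiment on a train/test corpus
#' split: for each requested mask kind an MLP ([mask_mlp]) is trained on
#' mixtures of the training utterances at the training SNRs, then the test
#' utterances are mixed at the test SNRs, enhanced with the predicted masks,
#' and scored with STOI (normal hearing), NCM on vocoded signals
#' (cochlear-implant simulation) and the pdf similarity battery on vocoded
#' signals. Training targets use the estimation pathway: FFTM clipped at
#' 1.5, PSM+ clipped at 2, estimation-resolution FFT (default 320). Oracle
#' (ideal-mask) scores on the test set are included when `include_oracle` is
#' `TRUE`, upper-bounding each estimator.
#'
#' @param train_corpus,test_corpus disjoint lists of clean [waveform]s.
#' @param noises named list of noise waveforms.
#' @param masks mask kinds to train, subset of
#'   `c("ibm","irm","fftm","qm","psmplus")`.
#' @param train_snr_db,test_snr_db training and evaluation SNRs in dB.
#' @param params estimation [stft_params] (default frame 320, hop 160,
#'   fft 320).
#' @param mlp an [mlp_config]; training is deterministic given its seed and
#'   `seed`.
#' @param voc a [vocoder_config] for the NCM / similarity stage.
#' @param seed top-level seed governing noise cuts and model training.
#' @param include_oracle also score ideal masks on the test mixtures.
#' @return A list of class `"estimation_eval"` with elements `stoi`, `ncm`
#'   and `similarity` (data.frames in table layout with best/worst flags)
#'   and `models` (the fitted `mask_mlp` objects).
#' @export
run_estimation_eval <- function(train_corpus, test_corpus, noises,
                                masks = c("ibm", "irm", "fftm", "qm",
                                          "psmplus"),
                                train_snr_db = c(-5, 0),
                                test_snr_db = c(-5, 0, 5),
                                params = stft_params(),
                                mlp = mlp_config(),
                                voc = vocoder_config(),
                                seed = 1, include_oracle = TRUE) {
  known <- c("ibm", "irm", "fftm", "qm", "psmplus")
  if (!all(masks %in% known))
    stop("unknown estimated-mask kind(s): ",
         paste(setdiff(masks, known), collapse = ", "))
  for (a in seq_along(train_corpus)) for (b in seq_along(test_corpus))
    if (identical(train_corpus[[a]]$samples, test_corpus[[b]]$samples))
      stop("train and test corpora overlap (train #", a, " == test #", b, ")")

  train_target <- function(mk, S, N, Y, s) switch(mk,
    ibm     = ibm(S, N, s),
    irm     = irm(S, N),
    fftm    = fftm(S, Y, clip = 1.5),
    qm      = qm(S, N, s),
    psmplus = psm_plus(S, Y, N))

  # --- training sets and models, one per mask kind
  feats <- list(); targs <- lapply(masks, function(m) list())
  names(targs) <- masks
  k <- 0L
  for (u in seq_along(train_corpus)) for (nk in names(noises))
    for (s in train_snr_db) {
      cl <- train_corpus[[u]]
      res <- with_seed(seed + 104729 * u + 131 * match(nk, names(noises)) +
                         round(1000 * s), {
        cut <- random_cut(noises[[nk]], length(cl$samples), region = "head")
        mix_at_snr(cl, cut, s)
      })
      S <- stft(cl, params); N <- stft(res$noise, params)
      Y <- stft(res$mixture, params)
      k <- k + 1L
      feats[[k]] <- extract_features(res$mixture, params)
      for (mk in masks) targs[[mk]][[k]] <- train_target(mk, S, N, Y, s)
    }
  models <- lapply(masks, function(mk) {
    cfg <- mlp
    cfg$seed <- mlp$seed + match(mk, known)
    mask_mlp(feats, targs[[mk]], cfg)
  })
  names(models) <- masks

  # --- evaluation on the test split
  conds <- expand.grid(noise = names(noises), snr_db = test_snr_db,
                       stringsAsFactors = FALSE)
  stoi_rows <- list(); ncm_rows <- list(); sim_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    nk <- conds$noise[ci]; s <- conds$snr_db[ci]
    cols <- c("Mix", masks,
              if (include_oracle) paste0("oracle_", masks))
    st <- matrix(NA_real_, length(test_corpus), length(cols),
                 dimnames = list(NULL, cols))
    nc <- st
    sim_acc <- NULL
    for (u in seq_along(test_corpus)) {
      cl <- test_corpus[[u]]
      res <- with_seed(seed + 224737 * u + 131 * match(nk, names(noises)) +
                         round(1000 * s), {
        cut <- random_cut(noises[[nk]], length(cl$samples), region = "tail")
        mix_at_snr(cl, cut, s)
      })
      S <- stft(cl, params); N <- stft(res$noise, params)
      Y <- stft(res$mixture, params)
      ref <- trim_to_frames(cl, params)
      fx <- extract_features(res$mixture, params)
      est <- list(Mix = waveform(res$mixture$samples[
        seq_along(ref$samples)], cl$fs))
      for (mk in masks)
        est[[mk]] <- istft(apply_mask(predict(models[[mk]], fx), Y))
      if (include_oracle) for (mk in masks)
        est[[paste0("oracle_", mk)]] <-
          istft(apply_mask(train_target(mk, S, N, Y, s), Y))
      ref_voc <- vocode(ref, voc)
      ref_pdf <- pdf_histogram(ref_voc)
      ref_env <- downsample_envelopes(channel_envelopes(ref_voc, voc),
                                      ref$fs, 25)
      for (nm in names(est)) {
        st[u, nm] <- stoi(ref, est[[nm]])
        ev <- vocode(est[[nm]], voc)
        nc[u, nm] <- ncm_from_envelopes(
          ref_env,
          downsample_envelopes(channel_envelopes(ev, voc), ev$fs, 25))
        rep_u <- similarity_suite(ref_pdf,
                                  pdf_histogram(ev, edges = ref_pdf$edges))
        fam <- rep_u$families
        if (is.null(sim_acc))
          sim_acc <- array(0, c(length(est), length(fam)),
                           dimnames = list(names(est), names(fam)))
        sim_acc[nm, ] <- sim_acc[nm, ] + fam
      }
    }
    sim_acc <- sim_acc / length(test_corpus)
    for (nm in cols) {
      stoi_rows[[length(stoi_rows) + 1]] <- data.frame(
        mask = nm, noise = nk, snr_db = s, mean = mean(st[, nm]),
        median = stats::median(st[, nm]), sd = stats::sd(st[, nm]),
        n = nrow(st), stringsAsFactors = FALSE)
      ncm_rows[[length(ncm_rows) + 1]] <- data.frame(
        mask = nm, noise = nk, snr_db = s, mean = mean(nc[, nm]),
        median = stats::median(nc[, nm]), sd = stats::sd(nc[, nm]),
        n = nrow(nc), stringsAsFactors = FALSE)
      sim_rows[[length(sim_rows) + 1]] <- data.frame(
        mask = nm, noise = nk, snr_db = s,
        as.list(sim_acc[nm, ]), stringsAsFactors = FALSE)
    }
  }
  out <- list(
    stoi = flag_best_worst(do.call(rbind, stoi_rows),
                           group = c("noise", "snr_db")),
    ncm = flag_best_worst(do.call(rbind, ncm_rows),
                          group = c("noise", "snr_db")),
    similarity = do.call(rbind, sim_rows),
    models = models)
  class(out) <- "estimation_eval"
  out
}

#' @export
print.estimation_eval <- function(x, ...) {
  cat("<estimation_eval>\n-- STOI --\n")
  print(x$stoi[, c("mask", "noise", "snr_db", "mean", "sd", "best", "worst")],
        row.names = FALSE)
  cat("-- NCM (vocoded) --\n")
  print(x$ncm[, c("mask", "noise", "snr_db", "mean", "sd", "best", "worst")],
        row.names = FALSE)
  invisible(x)
}
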