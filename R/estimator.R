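#' MLP estimator configuration
#'
#' Hyperparameters of the multilayer-perceptron mask estimator. The defaults
#' follow the benchmark recipe: three sigmoid hidden layers of 1024 units,
#' mean-squared-error loss, adaptive (AdaGrad-style) gradient descent with
#' scaling factor 0.0015, classical momentum 0.5 switching to 0.9 after
#' epoch 5, 20 epochs, no dropout, and 5-frame output splicing. The output
#' activation is sigmoid when the target mask range lies in \[0, 1\] and
#' linear otherwise.
#'
#' @param hidden_layers number of hidden layers.
#' @param hidden_units units per hidden layer.
#' @param lr_scale adaptive-gradient scaling factor.
#' @param epochs training epochs.
#' @param momentum length-2 vector: initial momentum and the value switched
#'   to after `momentum_switch_epoch`.
#' @param momentum_switch_epoch epoch after which the second momentum value
#'   applies.
#' @param context_frames output splicing window (odd; default 5).
#' @param input_context input-feature splicing window (odd; default 1 =
#'   no input context). The source feature pipeline this recipe follows
#'   splices inputs as well as outputs; enabling it (e.g. 5) widens the
#'   network input to `input_context * 48` dims and markedly improves mask
#'   estimates.
#' @param batch_size mini-batch size.
#' @param output_activation `"auto"`, `"sigmoid"` or `"linear"`.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return An object of class `"mlp_config"`.
#' @export
mlp_config <- function(hidden_layers = 3, hidden_units = 1024,
                       lr_scale = 0.0015, epochs = 20,
                       momentum = c(0.5, 0.9), momentum_switch_epoch = 5,
                       context_frames = 5, input_context = 1,
                       batch_size = 256,
                       output_activation = c("auto", "sigmoid", "linear"),
                       seed = 1) {
  stopifnot(hidden_layers >= 1, hidden_units >= 1, lr_scale > 0, epochs >= 1,
            length(momentum) == 2, momentum_switch_epoch >= 0,
            context_frames %% 2 == 1, input_context %% 2 == 1,
            batch_size >= 1)
  structure(list(hidden_layers = hidden_layers, hidden_units = hidden_units,
                 lr_scale = lr_scale, epochs = epochs, momentum = momentum,
                 momentum_switch_epoch = momentum_switch_epoch,
                 context_frames = context_frames,
                 input_context = input_context, batch_size = batch_size,
                 output_activation = match.arg(output_activation),
                 seed = seed),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# splice each frame's target with its +/-(c-1)/2 neighbors (edge replication):
# frames x bins -> frames x (c * bins)
splice_targets <- function(tg, context) {
  half <- (context - 1L) / 2L
  nf <- nrow(tg)
  idx <- function(off) pmin(pmax(seq_len(nf) + off, 1L), nf)
  do.call(cbind, lapply(-half:half, function(off) tg[idx(off), , drop = FALSE]))
}

# average the overlapping context predictions back to frames x bins
desplice_predictions <- function(pred, context, nbins) {
  half <- (context - 1L) / 2L
  nf <- nrow(pred)
  acc <- matrix(0, nf, nbins); cnt <- matrix(0, nf, nbins)
  for (k in seq_len(context)) {
    off <- k - 1L - half       # prediction block k estimates frame t + off
    cols <- ((k - 1L) * nbins + 1L):(k * nbins)
    t_src <- seq_len(nf)
    t_dst <- t_src + off
    ok <- t_dst >= 1L & t_dst <= nf
    acc[t_dst[ok], ] <- acc[t_dst[ok], ] + pred[t_src[ok], cols]
    cnt[t_dst[ok], ] <- cnt[t_dst[ok], ] + 1
  }
  acc / cnt
}

#' Fit a multilayer-perceptron mask estimator
#'
#' Trains an MLP to map per-frame log-mel features ([extract_features]) to
#' time-frequency mask values. Targets are spliced into a 5-frame window
#' (configurable), so the network jointly predicts each frame's mask and its
#' temporal context; at prediction time the overlapping estimates are
#' averaged. Optimization is mini-batch adaptive gradient descent (AdaGrad
#' per-parameter scaling) with classical momentum and MSE loss. Training is
#' deterministic under the config seed.
#'
#' @param features a feature matrix (frames x dims) or list of matrices, one
#'   per utterance.
#' @param targets matching mask targets: a `"tf_mask"` / numeric matrix
#'   (bins x frames, as produced by the mask constructors) or list thereof.
#' @param cfg an [mlp_config].
#' @param target_range declared range of the target mask, used to select the
#'   output activation and to clip predictions; inferred from a `"tf_mask"`
#'   target or from the data otherwise.
#' @return An object of class `"mask_mlp"` with weights, feature recipe,
#'   normalization statistics and the per-epoch training-loss trace.
#' @seealso [predict.mask_mlp()]
#' @export
mask_mlp <- function(features, targets, cfg = mlp_config(),
                     target_range = NULL) {
  if (is.matrix(features)) features <- list(features)
  if (!is.list(targets) || inherits(targets, "tf_mask")) targets <- list(targets)
  if (length(features) != length(targets))
    stop("features and targets must pair up per utterance")
  kind <- NULL
  if (inherits(targets[[1]], "tf_mask")) {
    kind <- targets[[1]]$kind
    if (is.null(target_range)) target_range <- targets[[1]]$range
  }
  # mask constructors produce bins x frames; the network works frames x bins
  tg <- lapply(targets, function(m)
    if (inherits(m, "tf_mask")) t(m$values) else t(as.matrix(m)))
  for (i in seq_along(tg)) {
    if (nrow(tg[[i]]) != nrow(features[[i]]))
      stop("utterance ", i, ": frame counts differ (features ",
           nrow(features[[i]]), ", targets ", nrow(tg[[i]]), ")")
    if (!all(is.finite(tg[[i]]))) stop("utterance ", i, ": non-finite targets")
  }
  if (is.null(target_range))
    target_range <- range(unlist(lapply(tg, range)))
  out_act <- cfg$output_activation
  if (out_act == "auto")
    out_act <- if (target_range[1] >= 0 && target_range[2] <= 1)
      "sigmoid" else "linear"
  if (out_act == "sigmoid" &&
      (target_range[1] < 0 || target_range[2] > 1))
    stop("sigmoid output incompatible with target range [",
         target_range[1], ", ", target_range[2], "]")
  nbins <- ncol(tg[[1]])
  X <- do.call(rbind, lapply(features, splice_targets,
                             context = cfg$input_context))
  Yt <- do.call(rbind, lapply(tg, splice_targets, context = cfg$context_frames))
  mu <- colMeans(X); sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xn <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  dims <- c(ncol(Xn), rep(cfg$hidden_units, cfg$hidden_layers), ncol(Yt))
  net <- with_seed(cfg$seed,
                   train_mlp_core(Xn, Yt, dims, out_act, cfg))
  structure(list(weights = net$weights, biases = net$biases,
                 loss_trace = net$loss_trace, cfg = cfg,
                 output_activation = out_act, target_range = target_range,
                 target_kind = kind, nbins = nbins,
                 feature_mean = mu, feature_sd = sdev,
                 recipe = attr(features[[1]], "recipe")),
            class = "mask_mlp")
}

train_mlp_core <- function(X, Y, dims, out_act, cfg) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  vW <- vector("list", L); vb <- vector("list", L)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (dims[l] + dims[l + 1]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -r, r),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
    vW[[l]] <- W[[l]] * 0; vb[[l]] <- b[[l]] * 0
    gW[[l]] <- W[[l]] * 0 + 1e-8; gb[[l]] <- b[[l]] * 0 + 1e-8
  }
  n <- nrow(X)
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    mom <- if (ep <= cfg$momentum_switch_epoch) cfg$momentum[1] else
      cfg$momentum[2]
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      A <- vector("list", L + 1)
      A[[1]] <- X[idx, , drop = FALSE]
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (l < L || out_act == "sigmoid") sigmoid(Z) else Z
      }
      err <- A[[L + 1]] - Y[idx, , drop = FALSE]
      ep_loss <- ep_loss + sum(err^2); ep_n <- ep_n + length(err)
      delta <- 2 * err / length(err)
      if (out_act == "sigmoid")
        delta <- delta * A[[L + 1]] * (1 - A[[L + 1]])
      for (l in L:1) {
        dW <- crossprod(A[[l]], delta)
        db <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * A[[l]] * (1 - A[[l]])
        }
        gW[[l]] <- gW[[l]] + dW^2; gb[[l]] <- gb[[l]] + db^2
        vW[[l]] <- mom * vW[[l]] - cfg$lr_scale * dW / sqrt(gW[[l]])
        vb[[l]] <- mom * vb[[l]] - cfg$lr_scale * db / sqrt(gb[[l]])
        W[[l]] <- W[[l]] + vW[[l]]; b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    loss_trace[ep] <- ep_loss / ep_n
  }
  list(weights = W, biases = b, loss_trace = loss_trace)
}

#' @export
print.mask_mlp <- function(x, ...) {
  dims <- c(length(x$feature_mean),
            rep(x$cfg$hidden_units, x$cfg$hidden_layers),
            ncol(x$weights[[length(x$weights)]]))
  cat(sprintf("<mask_mlp> %s, target %s [%g, %g], %s output\n",
              paste(dims, collapse = "-"),
              if (is.null(x$target_kind)) "mask" else x$target_kind,
              x$target_range[1], x$target_range[2], x$output_activation))
  cat(sprintf("  trained %d epochs, MSE %.5f -> %.5f\n",
              length(x$loss_trace), x$loss_trace[1],
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

mlp_forward <- function(model, Xn) {
  A <- Xn
  L <- length(model$weights)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$weights[[l]], 2, model$biases[[l]], "+")
    A <- if (l < L || model$output_activation == "sigmoid") sigmoid(Z) else Z
  }
  A
}

#' Predict a mask from features
#'
#' Runs the fitted MLP on a feature matrix, averages the overlapping 5-frame
#' context predictions per frame, and clips to the target mask's declared
#' range. Estimated masks are soft: even an IBM-trained network outputs
#' continuous values.
#'
#' @param object a fitted [mask_mlp] model.
#' @param features feature matrix from [extract_features] with the same
#'   recipe used in training.
#' @param ... unused.
#' @return A `"tf_mask"` (bins x frames) with kind `"estimated-<kind>"`.
#' @export
predict.mask_mlp <- function(object, features, ...) {
  rec <- attr(features, "recipe")
  if (!is.null(rec) && !is.null(object$recipe) &&
      !identical(rec, object$recipe))
    stop("feature recipe differs from the one used in training")
  features <- splice_targets(features, object$cfg$input_context)
  if (ncol(features) != length(object$feature_mean))
    stop("feature dimension mismatch")
  Xn <- sweep(sweep(features, 2, object$feature_mean), 2, object$feature_sd,
              "/")
  pred <- mlp_forward(object, Xn)
  m <- desplice_predictions(pred, object$cfg$context_frames, object$nbins)
  m <- pmin(pmax(m, object$target_range[1]), object$target_range[2])
  kind <- paste0("estimated-",
                 if (is.null(object$target_kind)) "mask" else
                   object$target_kind)
  new_tf_mask(t(m), kind, object$target_range)
}
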