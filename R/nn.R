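#' Autoencoder-regularized classifier configuration
#'
#' Fully connected network over single 9-feature measurement points: an
#' encoder (9 -> 32 -> latent 9) shared by a mirrored decoder (9 -> 32 -> 9)
#' and a small classification head (9 -> 4 -> 2). Both branches are trained
#' simultaneously with the combined loss [combined_loss()]; the decoder
#' regularizes the latent space and is dropped at inference. Dropout 0.3 is
#' applied to the encoder and classifier hidden layers; hidden layers are
#' ReLU, the latent and both output layers are linear.
#'
#' @param input_dim Number of input features.
#' @param encoder_hidden,decoder_hidden Hidden-layer widths.
#' @param latent_dim Latent-space width.
#' @param clf_hidden Classifier hidden-layer width.
#' @param n_classes Number of classes.
#' @param alpha Reconstruction-loss weight in the combined loss.
#' @param dropout Dropout probability on the two hidden layers.
#' @return Object of class `ae_clf_config`.
#' @export
ae_classifier_config <- function(input_dim = 9, encoder_hidden = 32,
                                 latent_dim = 9, decoder_hidden = 32,
                                 clf_hidden = 4, n_classes = 2,
                                 alpha = 0.3, dropout = 0.3) {
  if (alpha < 0) stop_config("alpha must be >= 0")
  sizes <- c(input_dim, encoder_hidden, latent_dim, decoder_hidden,
             clf_hidden, n_classes)
  if (any(sizes < 1)) stop_config("all layer sizes must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must lie in [0, 1)")
  structure(list(input_dim = input_dim, encoder_hidden = encoder_hidden,
                 latent_dim = latent_dim, decoder_hidden = decoder_hidden,
                 clf_hidden = clf_hidden, n_classes = n_classes,
                 alpha = alpha, dropout = dropout),
            class = "ae_clf_config")
}

#' Total trainable parameter count of the network
#'
#' Sum of weight-matrix and bias-vector sizes over the six dense layers
#' (encoder hidden, latent, decoder hidden, decoder output, classifier
#' hidden, classifier output).
#'
#' @param cfg An [ae_classifier_config()].
#' @return Integer parameter count (1284 under the defaults).
#' @export
nn_param_count <- function(cfg = ae_classifier_config()) {
  p <- nn_init_params(cfg, seed = 0L)
  sum(vapply(p, length, 0L))
}

nn_init_params <- function(cfg, seed) {
  dims <- list(
    enc_w = c(cfg$input_dim, cfg$encoder_hidden),
    lat_w = c(cfg$encoder_hidden, cfg$latent_dim),
    dech_w = c(cfg$latent_dim, cfg$decoder_hidden),
    deco_w = c(cfg$decoder_hidden, cfg$input_dim),
    clfh_w = c(cfg$latent_dim, cfg$clf_hidden),
    clfo_w = c(cfg$clf_hidden, cfg$n_classes))
  with_seed(seed, {
    p <- list()
    for (nm in names(dims)) {
      d <- dims[[nm]]
      p[[nm]] <- matrix(stats::rnorm(prod(d), sd = sqrt(2 / d[1])),
                        nrow = d[1])
      p[[sub("_w$", "_b", nm)]] <- rep(0, d[2])
    }
    p
  })
}

relu <- function(x) (x > 0) * x

# Forward pass. In training mode, inverted-dropout masks are drawn from the
# current RNG; in eval mode the network is deterministic.
nn_forward <- function(params, x, cfg, train = FALSE) {
  n <- nrow(x)
  p <- cfg$dropout
  mask <- function(nc) if (train && p > 0)
    matrix(stats::rbinom(n * nc, 1, 1 - p) / (1 - p), nrow = n)
  else 1

  h1a <- sweep(x %*% params$enc_w, 2, params$enc_b, "+")
  h1 <- relu(h1a); m1 <- mask(ncol(h1)); h1d <- h1 * m1
  z <- sweep(h1d %*% params$lat_w, 2, params$lat_b, "+")
  h3a <- sweep(z %*% params$dech_w, 2, params$dech_b, "+")
  h3 <- relu(h3a)
  xhat <- sweep(h3 %*% params$deco_w, 2, params$deco_b, "+")
  h5a <- sweep(z %*% params$clfh_w, 2, params$clfh_b, "+")
  h5 <- relu(h5a); m5 <- mask(ncol(h5)); h5d <- h5 * m5
  logits <- sweep(h5d %*% params$clfo_w, 2, params$clfo_b, "+")

  list(x = x, h1a = h1a, h1d = h1d, m1 = m1, z = z, h3a = h3a, h3 = h3,
       xhat = xhat, h5a = h5a, h5d = h5d, m5 = m5, logits = logits)
}

# Analytic gradients of the combined loss w.r.t. every parameter.
nn_backward <- function(params, fw, y_int, cfg) {
  n <- nrow(fw$x); d <- ncol(fw$x)
  g <- list()

  dlogits <- ce_grad(fw$logits, y_int)
  g$clfo_w <- crossprod(fw$h5d, dlogits)
  g$clfo_b <- colSums(dlogits)
  dh5 <- (dlogits %*% t(params$clfo_w)) * fw$m5 * (fw$h5a > 0)
  g$clfh_w <- crossprod(fw$z, dh5)
  g$clfh_b <- colSums(dh5)
  dz <- dh5 %*% t(params$clfh_w)

  dxhat <- 2 * cfg$alpha * (fw$xhat - fw$x) / (n * d)
  g$deco_w <- crossprod(fw$h3, dxhat)
  g$deco_b <- colSums(dxhat)
  dh3 <- (dxhat %*% t(params$deco_w)) * (fw$h3a > 0)
  g$dech_w <- crossprod(fw$z, dh3)
  g$dech_b <- colSums(dh3)
  dz <- dz + dh3 %*% t(params$dech_w)

  g$lat_w <- crossprod(fw$h1d, dz)
  g$lat_b <- colSums(dz)
  dh1 <- (dz %*% t(params$lat_w)) * fw$m1 * (fw$h1a > 0)
  g$enc_w <- crossprod(fw$x, dh1)
  g$enc_b <- colSums(dh1)
  g
}

nn_loss_from_forward <- function(fw, y_int, cfg) {
  combined_loss(fw$logits, y_int, fw$xhat, fw$x, cfg$alpha)
}

#' Train the autoencoder-regularized classifier
#'
#' Minibatch Adam on the combined cross-entropy + alpha-weighted
#' reconstruction loss. Gaussian input noise (sigma from the training
#' config) is added to each training batch after normalization; validation
#' and inference inputs are never perturbed. The learning rate decays on a
#' training-loss plateau; early stopping monitors validation macro F1 and
#' restores the best-validation weights. Inputs are expected standardized
#' (see [fit_normalizer()]); train and validation partitions must be
#' recording-disjoint.
#'
#' @param train,val Per-sample views or `list(x =, y =)` with standardized
#'   feature matrices; `val` must be non-empty (early stopping needs it).
#' @param model_cfg An [ae_classifier_config()].
#' @param train_cfg A [train_config()].
#' @return A `trained_classifier` of subclass `ae_nn_classifier`, carrying
#'   the training history (`epoch`, `train_loss`, `val_loss`, `val_f1`,
#'   `lr`).
#' @export
train_ae_nn <- function(train, val, model_cfg = ae_classifier_config(),
                        train_cfg = train_config()) {
  tr <- as_xy(train); va <- as_xy(val)
  if (nrow(va$x) == 0)
    stop_config("validation set is empty; early stopping undefined")
  if (ncol(tr$x) != model_cfg$input_dim)
    stop_config("input_dim %d does not match data (%d features)",
                model_cfg$input_dim, ncol(tr$x))
  y_tr <- as.integer(tr$y)
  classes <- levels(tr$y)

  with_seed(train_cfg$seed, {
    params <- nn_init_params(model_cfg, seed = stats::runif(1) * 1e8)
    opt <- adam_init(params)
    lr <- train_cfg$lr
    plateau <- plateau_tracker(train_cfg$plateau_patience)
    best_f1 <- -Inf; best_params <- params; es_wait <- 0L
    hist <- vector("list", train_cfg$max_epochs)
    n <- nrow(tr$x)

    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = train_cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + train_cfg$batch_size - 1, n)]
        xb <- tr$x[idx, , drop = FALSE]
        if (train_cfg$input_noise_sigma > 0)
          xb <- add_gaussian_noise(xb, train_cfg$input_noise_sigma)
        fw <- nn_forward(params, xb, model_cfg, train = TRUE)
        batch_losses[bi] <- nn_loss_from_forward(fw, y_tr[idx], model_cfg)
        grads <- nn_backward(params, fw, y_tr[idx], model_cfg)
        upd <- adam_step(params, grads, opt, lr, train_cfg$weight_decay)
        params <- upd$params; opt <- upd$state
      }
      train_loss <- mean(batch_losses)

      fw_val <- nn_forward(params, va$x, model_cfg, train = FALSE)
      val_loss <- nn_loss_from_forward(fw_val, as.integer(va$y), model_cfg)
      prob <- softmax_rows(fw_val$logits); colnames(prob) <- classes
      val_f1 <- quick_macro_f1(va$y, prob)

      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, val_f1 = val_f1,
                                  lr = lr)
      if (plateau(train_loss)) lr <- lr * train_cfg$lr_decay_factor

      if (val_f1 > best_f1 + 1e-9) {
        best_f1 <- val_f1; best_params <- params; es_wait <- 0L
      } else {
        es_wait <- es_wait + 1L
        if (es_wait >= train_cfg$early_stopping_patience) break
      }
    }

    structure(list(params = best_params, model_cfg = model_cfg,
                   train_cfg = train_cfg, classes = classes,
                   history = do.call(rbind, hist[!vapply(hist, is.null,
                                                         TRUE)]),
                   best_val_f1 = best_f1),
              class = c("ae_nn_classifier", "trained_classifier"))
  })
}

#' @export
predict_proba.ae_nn_classifier <- function(model, newdata, ...) {
  x <- if (is.data.frame(newdata)) psv_features(newdata) else
    as.matrix(newdata)
  if (ncol(x) != model$model_cfg$input_dim)
    stop_config("input has %d features, model expects %d",
                ncol(x), model$model_cfg$input_dim)
  fw <- nn_forward(model$params, x, model$model_cfg, train = FALSE)
  p <- softmax_rows(fw$logits)
  colnames(p) <- model$classes
  p
}

#' @export
print.ae_nn_classifier <- function(x, ...) {
  cat(sprintf(paste0("Autoencoder-regularized classifier: %d params, ",
                     "%d epochs trained, best val F1 %.3f\n"),
              nn_param_count(x$model_cfg), nrow(x$history), x$best_val_f1))
  invisible(x)
}
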