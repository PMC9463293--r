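# Shared numerical-training machinery for the two neural classifiers:
# softmax/cross-entropy, Adam with decoupled-from-BN L2 weight decay,
# training-loss plateau detection for LR decay, and validation-based
# early stopping.

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of logits (n x K) against integer labels in 1..K.
ce_loss <- function(logits, y_int) {
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  mean(lse - z[cbind(seq_along(y_int), y_int)])
}

# d(mean CE)/d(logits): (softmax - onehot) / n.
ce_grad <- function(logits, y_int) {
  g <- softmax_rows(logits)
  g[cbind(seq_along(y_int), y_int)] <-
    g[cbind(seq_along(y_int), y_int)] - 1
  g / length(y_int)
}

#' Combined classification + reconstruction loss
#'
#' The autoencoder-regularized network is trained end to end with
#' `loss = loss_clf + alpha * loss_ae`, where `loss_clf` is the batch-mean
#' cross-entropy of the classifier logits and `loss_ae` the batch-mean
#' squared reconstruction error of the autoencoder (mean over all entries).
#' The weight `alpha` (default 0.3 in the pipeline) controls how strongly
#' the reconstruction objective regularizes the shared latent space.
#'
#' @param clf_logits Numeric matrix n x K of unnormalized class scores.
#' @param labels Factor or integer vector (1..K) of true classes.
#' @param reconstruction,target_input Numeric matrices n x d of decoded and
#'   original features.
#' @param alpha Non-negative reconstruction weight.
#' @return Scalar loss.
#' @export
combined_loss <- function(clf_logits, labels, reconstruction, target_input,
                          alpha) {
  if (alpha < 0) stop_config("alpha must be >= 0")
  y_int <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  if (nrow(clf_logits) != length(y_int) ||
      !all(dim(reconstruction) == dim(target_input)) ||
      nrow(reconstruction) != nrow(clf_logits))
    stop_config("batch dimensions disagree in combined_loss")
  ce_loss(clf_logits, y_int) + alpha * mean((reconstruction - target_input)^2)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step. L2 weight decay is added to the gradient of weight tensors
# only (names ending in "_w"); biases and batch-norm scale/shift are exempt.
adam_step <- function(params, grads, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && endsWith(nm, "_w"))
      g <- g + weight_decay * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Training schedule for the neural classifiers
#'
#' Adam optimization with an initial learning rate of 0.01 multiplied by 0.1
#' when the training loss plateaus, early stopping on validation macro F1
#' with best-weights restore, a hard cap of 2000 epochs, batch size 16,384
#' and L2 weight decay 0.001. Plateau patience (20 epochs, relative
#' improvement threshold 1e-4) and early-stopping patience (50 epochs) are
#' schedule details of this implementation.
#'
#' @param lr Initial learning rate.
#' @param lr_decay_factor Multiplier applied to the learning rate on a
#'   training-loss plateau.
#' @param plateau_patience Epochs without relative training-loss improvement
#'   before the learning rate is decayed.
#' @param early_stopping_patience Epochs without validation-F1 improvement
#'   before training stops (best weights restored).
#' @param max_epochs Hard epoch cap.
#' @param batch_size Minibatch size.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param input_noise_sigma Std of Gaussian noise added to training inputs
#'   (fully connected network only).
#' @param seed Integer seed for init, shuffling, dropout and input noise.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, lr_decay_factor = 0.1,
                         plateau_patience = 20,
                         early_stopping_patience = 50,
                         max_epochs = 2000, batch_size = 16384,
                         weight_decay = 0.001,
                         input_noise_sigma = 0.1,
                         seed = 1L) {
  if (lr <= 0) stop_config("lr must be positive")
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1)
    stop_config("lr_decay_factor must lie in (0, 1)")
  structure(list(lr = lr, lr_decay_factor = lr_decay_factor,
                 plateau_patience = plateau_patience,
                 early_stopping_patience = early_stopping_patience,
                 max_epochs = max_epochs, batch_size = batch_size,
                 weight_decay = weight_decay,
                 input_noise_sigma = input_noise_sigma,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Plateau tracker for LR decay: decays when the training loss has not
# improved by a relative threshold for `patience` consecutive epochs.
plateau_tracker <- function(patience, rel_threshold = 1e-4) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$wait <- 0L
  function(loss) {
    if (loss < env$best * (1 - rel_threshold) || !is.finite(env$best)) {
      env$best <- loss; env$wait <- 0L
      FALSE
    } else {
      env$wait <- env$wait + 1L
      if (env$wait >= patience) { env$wait <- 0L; TRUE } else FALSE
    }
  }
}

# Macro F1 from probabilities without the full metric set (training-loop
# hot path; no AUROC, so single-class validation folds raise no warnings).
quick_macro_f1 <- function(y, prob) {
  lev <- colnames(prob)
  y <- factor(as.character(y), levels = lev)
  pred <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
  cm <- table(y, pred)
  f1 <- vapply(lev, function(cl) {
    tp <- cm[cl, cl]
    denom <- 2 * tp + (sum(cm[, cl]) - tp) + (sum(cm[cl, ]) - tp)
    if (denom == 0) 0 else 2 * tp / denom
  }, 0)
  mean(f1)
}
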