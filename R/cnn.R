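#' 1D residual CNN configuration
#'
#' Sliding-window convolutional classifier over the multichannel signal:
#' a stem convolution lifting the 9 input channels to 16 feature channels,
#' followed by three residual blocks of two convolutions each (seven
#' convolutional layers in total). Each block starts with stride 2 and
#' doubles the channel count, except the second block which keeps it
#' (16 -> 32 -> 32 -> 64). Kernel size is 7 everywhere; every convolution
#' is followed by 1D batch normalization, ReLU and dropout 0.3; a global
#' average pooling feeds the fully connected output layer. Shortcuts use a
#' kernel-1 stride-matched projection (with batch norm) because stride-2,
#' channel-changing blocks cannot carry a pure identity.
#'
#' @param window Sliding-window length (input temporal size).
#' @param in_channels Input feature channels.
#' @param stem_channels Channels after the stem convolution.
#' @param n_res_blocks Number of residual blocks.
#' @param block_channels Output channels of each block.
#' @param block_stride Stride applied by the first convolution (and the
#'   projection) of every block.
#' @param kernel Convolution kernel size (odd).
#' @param dropout Dropout probability after every convolution.
#' @param n_classes Number of output classes.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(window = 64, in_channels = 9, stem_channels = 16,
                       n_res_blocks = 3, block_channels = c(32, 32, 64),
                       block_stride = 2, kernel = 7, dropout = 0.3,
                       n_classes = 2) {
  if (kernel %% 2 != 1) stop_config("kernel must be odd")
  if (length(block_channels) != n_res_blocks)
    stop_config("block_channels must have one entry per residual block")
  if (window < block_stride^n_res_blocks)
    stop_config("window %d shorter than total downsampling factor %d",
                window, block_stride^n_res_blocks)
  structure(list(window = window, in_channels = in_channels,
                 stem_channels = stem_channels,
                 n_res_blocks = n_res_blocks,
                 block_channels = block_channels,
                 block_stride = block_stride, kernel = kernel,
                 dropout = dropout, n_classes = n_classes),
            class = "cnn_config")
}

#' Temporal lengths through the network
#'
#' @param cfg A [cnn_config()].
#' @return Integer vector: temporal length after the stem and after each
#'   residual block (`64 32 16 8` under the defaults).
#' @export
cnn_forward_trace <- function(cfg = cnn_config()) {
  len <- cfg$window
  out <- len                      # stem is stride 1
  for (i in seq_len(cfg$n_res_blocks)) {
    len <- (len + cfg$block_stride - 1) %/% cfg$block_stride
    out <- c(out, len)
  }
  out
}

#' Number of convolutional layers on the main path
#'
#' Stem plus two per residual block; shortcut projections are shape
#' adapters, not counted.
#'
#' @param cfg A [cnn_config()].
#' @return Integer (7 under the defaults).
#' @export
cnn_conv_layer_count <- function(cfg = cnn_config()) {
  1L + 2L * cfg$n_res_blocks
}

#' Sliding windows over one recording's samples
#'
#' Builds every contiguous length-`window` slice of the signal; a class
#' prediction is attached to the last sample of each window, so the first
#' `window - 1` samples of a recording are never scored. Windows never
#' cross recording boundaries.
#'
#' @param recording_samples Numeric matrix n_channels x T.
#' @param window Window length (>= 1).
#' @return List with `windows` (array n_channels x window x n_windows) and
#'   `targets` (0-based sample indices of each window's last sample). With
#'   `T < window` the batch is empty.
#' @export
make_windows <- function(recording_samples, window) {
  if (window < 1) stop_config("window must be >= 1")
  C <- nrow(recording_samples)
  T_len <- ncol(recording_samples)
  n_win <- max(0L, T_len - window + 1L)
  w <- array(0, c(C, window, n_win))
  if (n_win > 0)
    for (k in seq_len(window))
      w[, k, ] <- recording_samples[, k:(k + n_win - 1), drop = FALSE]
  list(windows = w,
       targets = if (n_win > 0) (window - 1L):(T_len - 1L) else integer())
}

# ---- flat-layout primitives ------------------------------------------------
# Activations travel as plain (channels x time*batch) matrices with the
# temporal length carried alongside; no 3D reshapes on the hot path.

# Column indices of temporal positions `ts` (1-based, within length Tp) for
# every batch element.
flat_cols <- function(ts, Tp, B) {
  rep((0:(B - 1)) * Tp, each = length(ts)) + ts
}

# xm: (C_in, T*B); w: array (C_out, C_in, K). Zero padding both ends,
# output length (T + 2 pad - K) %/% stride + 1. The im2col buffer and the
# matrix products run in compiled code (src/conv1d.cpp); the backward
# kernel rebuilds the buffer from the cached input rather than caching it
# (it is K times the activation size).
conv1d_fw <- function(xm, T_len, B, w, stride, pad) {
  C_out <- dim(w)[1]; K <- dim(w)[3]
  w2 <- w; dim(w2) <- c(C_out, dim(w)[2] * K)
  res <- .conv1d_fw_cpp(xm, T_len, B, w2, K, stride, pad)
  list(y = res$y, T_out = res$T_out,
       cache = list(xm = xm, T_len = T_len, B = B, w2 = w2, K = K,
                    stride = stride, pad = pad))
}

conv1d_bw <- function(dyf, w, cache) {
  res <- .conv1d_bw_cpp(cache$xm, dyf, cache$T_len, cache$B, cache$w2,
                        cache$K, cache$stride, cache$pad)
  dw <- res$dw
  dim(dw) <- dim(w)
  list(dx = res$dx, dw = dw)
}

# Batch-normalization statistics for the current minibatch (train) or the
# running averages (eval); updates the running stats in training mode.
bn_stats <- function(xm, rs, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    N <- ncol(xm)
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * v * N / max(1, N - 1)
  } else {
    mu <- rs$mean; v <- rs$var
  }
  list(mu = mu, ivar = 1 / sqrt(v + eps), rs = rs)
}

# Per-channel batch normalization over the full (time x batch) extent.
bn_fw <- function(xm, g, be, train, rs) {
  st <- bn_stats(xm, rs, train)
  xhat <- (xm - st$mu) * st$ivar
  list(y = g * xhat + be, rs = st$rs,
       cache = list(xhat = xhat, ivar = st$ivar))
}

bn_bw <- function(dy, g, cache) {
  N <- ncol(dy)
  dbe <- rowSums(dy)
  dg <- rowSums(dy * cache$xhat)
  dxhat <- dy * g
  sx <- rowSums(dxhat)
  sxx <- rowSums(dxhat * cache$xhat)
  list(dx = (cache$ivar / N) * (N * dxhat - sx - cache$xhat * sxx),
       dg = dg, dbe = dbe)
}

# Fused ReLU + inverted dropout; the combined multiplicative mask is all
# the backward pass needs.
act_fw <- function(xm, p, train) {
  mask <- (xm > 0)
  if (train && p > 0)
    mask <- mask * ((stats::runif(length(xm)) >= p) / (1 - p))
  list(y = xm * mask, mask = mask)
}

# ---- network ---------------------------------------------------------------

cnn_layer_plan <- function(cfg) {
  plan <- list(list(name = "stem", c_in = cfg$in_channels,
                    c_out = cfg$stem_channels, stride = 1L))
  c_in <- cfg$stem_channels
  for (i in seq_len(cfg$n_res_blocks)) {
    plan[[length(plan) + 1]] <- list(name = sprintf("b%d", i), c_in = c_in,
                                     c_out = cfg$block_channels[i],
                                     stride = cfg$block_stride)
    c_in <- cfg$block_channels[i]
  }
  plan
}

cnn_init_params <- function(cfg, seed) {
  with_seed(seed, {
    p <- list(); rs <- list()
    he <- function(c_out, c_in, k)
      array(stats::rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))),
            c(c_out, c_in, k))
    add_bn <- function(nm, c_out) {
      p[[paste0(nm, "_g")]] <<- rep(1, c_out)
      p[[paste0(nm, "_be")]] <<- rep(0, c_out)
      rs[[nm]] <<- list(mean = rep(0, c_out), var = rep(1, c_out))
    }
    plan <- cnn_layer_plan(cfg)
    st <- plan[[1]]
    p$stem_w <- he(st$c_out, st$c_in, cfg$kernel); add_bn("stem", st$c_out)
    for (blk in plan[-1]) {
      nm <- blk$name
      p[[paste0(nm, "a_w")]] <- he(blk$c_out, blk$c_in, cfg$kernel)
      add_bn(paste0(nm, "a"), blk$c_out)
      p[[paste0(nm, "b_w")]] <- he(blk$c_out, blk$c_out, cfg$kernel)
      add_bn(paste0(nm, "b"), blk$c_out)
      p[[paste0(nm, "p_w")]] <- he(blk$c_out, blk$c_in, 1L)
      add_bn(paste0(nm, "p"), blk$c_out)
    }
    c_last <- cfg$block_channels[cfg$n_res_blocks]
    p$fc_w <- matrix(stats::rnorm(c_last * cfg$n_classes,
                                  sd = sqrt(2 / c_last)), c_last)
    p$fc_b <- rep(0, cfg$n_classes)
    list(params = p, rs = rs)
  })
}

# Forward pass over a window batch x: array (C_in, window, B) or flat
# matrix with dims supplied. Returns logits (B x n_classes), updated
# running stats, and the caches needed for the backward pass.
cnn_forward <- function(params, rs, x, cfg, train = FALSE) {
  d <- dim(x)
  B <- d[3]
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
  pad <- (cfg$kernel - 1L) %/% 2L
  ca <- list()

  bn1 <- function(nm, z) {
    r <- bn_fw(z, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
               train, rs[[nm]])
    rs[[nm]] <<- r$rs
    ca[[paste0(nm, "_bn")]] <<- r$cache
    r$y
  }
  act <- function(nm, z) {
    r <- act_fw(z, cfg$dropout, train)
    ca[[paste0(nm, "_m")]] <<- r$mask
    r$y
  }
  # fused batchnorm + ReLU + dropout (compiled) for conv layers whose BN
  # output goes straight through the activation
  bn_act <- function(nm, z) {
    st <- bn_stats(z, rs[[nm]], train)
    rs[[nm]] <<- st$rs
    keep <- if (train && cfg$dropout > 0) stats::runif(length(z))
            else numeric(0)
    r <- .bn_act_fw_cpp(z, params[[paste0(nm, "_g")]],
                        params[[paste0(nm, "_be")]], st$mu, st$ivar,
                        keep, cfg$dropout)
    ca[[paste0(nm, "_bn")]] <<- list(xhat = r$xhat, ivar = st$ivar)
    ca[[paste0(nm, "_m")]] <<- r$mask
    r$y
  }

  cv <- conv1d_fw(xm, d[2], B, params$stem_w, 1L, pad)
  ca$stem_cv <- cv$cache
  cur <- bn_act("stem", cv$y)
  T_cur <- cv$T_out

  for (i in seq_len(cfg$n_res_blocks)) {
    nm <- sprintf("b%d", i)
    cva <- conv1d_fw(cur, T_cur, B, params[[paste0(nm, "a_w")]],
                     cfg$block_stride, pad)
    ca[[paste0(nm, "a_cv")]] <- cva$cache
    da <- bn_act(paste0(nm, "a"), cva$y)

    cvb <- conv1d_fw(da, cva$T_out, B, params[[paste0(nm, "b_w")]], 1L,
                     pad)
    ca[[paste0(nm, "b_cv")]] <- cvb$cache
    bb <- bn1(paste0(nm, "b"), cvb$y)

    cvp <- conv1d_fw(cur, T_cur, B, params[[paste0(nm, "p_w")]],
                     cfg$block_stride, 0L)
    ca[[paste0(nm, "p_cv")]] <- cvp$cache
    sp <- bn1(paste0(nm, "p"), cvp$y)

    cur <- act(nm, bb + sp)
    T_cur <- cvb$T_out
  }

  # global average pooling over the remaining temporal extent
  C_last <- nrow(cur)
  gap <- matrix(0, C_last, B)
  for (t in seq_len(T_cur))
    gap <- gap + cur[, flat_cols(t, T_cur, B), drop = FALSE]
  gap <- gap / T_cur
  ca$T_last <- T_cur; ca$B <- B

  logits <- sweep(crossprod(gap, params$fc_w), 2, params$fc_b, "+")
  list(logits = logits, gap = gap, rs = rs, caches = ca)
}

cnn_backward <- function(params, fw, dlogits, cfg) {
  ca <- fw$caches
  g <- list()
  g$fc_w <- fw$gap %*% dlogits
  g$fc_b <- colSums(dlogits)

  T_last <- ca$T_last; B <- ca$B
  dgap <- params$fc_w %*% t(dlogits) / T_last   # (C_last, B)
  dcur <- matrix(0, nrow(dgap), T_last * B)
  for (t in seq_len(T_last))
    dcur[, flat_cols(t, T_last, B)] <- dgap

  for (i in rev(seq_len(cfg$n_res_blocks))) {
    nm <- sprintf("b%d", i)
    dz <- dcur * ca[[paste0(nm, "_m")]]   # through dropout + relu

    # shortcut branch: bn_p <- conv_p
    rp <- bn_bw(dz, params[[paste0(nm, "p_g")]], ca[[paste0(nm, "p_bn")]])
    g[[paste0(nm, "p_g")]] <- rp$dg
    g[[paste0(nm, "p_be")]] <- rp$dbe
    cp <- conv1d_bw(rp$dx, params[[paste0(nm, "p_w")]],
                    ca[[paste0(nm, "p_cv")]])
    g[[paste0(nm, "p_w")]] <- cp$dw

    # main branch: bn_b <- conv_b <- (drop+relu, bn_a) <- conv_a
    rb <- bn_bw(dz, params[[paste0(nm, "b_g")]], ca[[paste0(nm, "b_bn")]])
    g[[paste0(nm, "b_g")]] <- rb$dg
    g[[paste0(nm, "b_be")]] <- rb$dbe
    cb <- conv1d_bw(rb$dx, params[[paste0(nm, "b_w")]],
                    ca[[paste0(nm, "b_cv")]])
    g[[paste0(nm, "b_w")]] <- cb$dw

    da <- cb$dx * ca[[paste0(nm, "a_m")]]
    ra <- bn_bw(da, params[[paste0(nm, "a_g")]], ca[[paste0(nm, "a_bn")]])
    g[[paste0(nm, "a_g")]] <- ra$dg
    g[[paste0(nm, "a_be")]] <- ra$dbe
    caa <- conv1d_bw(ra$dx, params[[paste0(nm, "a_w")]],
                     ca[[paste0(nm, "a_cv")]])
    g[[paste0(nm, "a_w")]] <- caa$dw

    dcur <- cp$dx + caa$dx
  }

  ds <- dcur * ca$stem_m
  rs_ <- bn_bw(ds, params$stem_g, ca$stem_bn)
  g$stem_g <- rs_$dg
  g$stem_be <- rs_$dbe
  cs <- conv1d_bw(rs_$dx, params$stem_w, ca$stem_cv)
  g$stem_w <- cs$dw
  g
}

#' Build a window batch from recordings
#'
#' Extracts the analysed contact window of each recording, standardizes the
#' channels with a fitted normalizer, and stacks all sliding windows into
#' one batch, tracking each window's recording id and target sample index.
#'
#' @param recordings List of `recording` objects (consistently filtered).
#' @param window Sliding-window length.
#' @param contact_window_s Analysed prefix of the contact phase in seconds.
#' @param normalizer Optional [fit_normalizer()] result applied per channel.
#' @return List with `x` (array C x window x N), `y` (factor of window
#'   labels), `recording_id`, `target_index` (0-based, within the analysed
#'   window).
#' @export
windows_from_recordings <- function(recordings, window = 64,
                                    contact_window_s = 1.0,
                                    normalizer = NULL) {
  if (length(recordings) == 0)
    stop_config("no recordings supplied")
  parts <- lapply(recordings, function(r) {
    m <- extract_contact_window(r, contact_window_s)
    if (!is.null(normalizer))
      m <- (m - normalizer$mean) / normalizer$sd
    mw <- make_windows(m, window)
    list(x = mw$windows, targets = mw$targets,
         n = length(mw$targets), label = r$class_label,
         id = r$recording_id)
  })
  n_tot <- sum(vapply(parts, `[[`, 0L, "n"))
  C <- nrow(recordings[[1]]$samples)
  if (n_tot == 0)
    return(list(x = array(0, c(C, window, 0)),
                y = factor(character(), stiffness_classes()),
                recording_id = character(), target_index = integer()))
  x <- array(0, c(C, window, n_tot))
  y <- character(n_tot); rid <- character(n_tot); ti <- integer(n_tot)
  at <- 0L
  for (p in parts) {
    if (p$n == 0) next
    x[, , at + seq_len(p$n)] <- p$x
    y[at + seq_len(p$n)] <- p$label
    rid[at + seq_len(p$n)] <- p$id
    ti[at + seq_len(p$n)] <- p$targets
    at <- at + p$n
  }
  list(x = x, y = factor(y, stiffness_classes()),
       recording_id = rid, target_index = ti)
}

#' Train the 1D residual CNN
#'
#' Minibatch Adam on the cross-entropy loss over pooled, shuffled sliding
#' windows from all training recordings. Batch normalization uses batch
#' statistics during training and running averages at inference. The
#' learning rate decays on a training-loss plateau; early stopping monitors
#' validation macro F1 and restores the best-validation weights.
#'
#' @param train,val Window batches from [windows_from_recordings()] (must be
#'   recording-disjoint); `val` non-empty.
#' @param model_cfg A [cnn_config()].
#' @param train_cfg A [train_config()] (`input_noise_sigma` is ignored; the
#'   input perturbation is specific to the fully connected network).
#' @return A `trained_classifier` of subclass `cnn_classifier` with training
#'   history.
#' @export
train_cnn <- function(train, val, model_cfg = cnn_config(),
                      train_cfg = train_config()) {
  if (dim(train$x)[2] != model_cfg$window)
    stop_config("window batch length %d does not match config window %d",
                dim(train$x)[2], model_cfg$window)
  n <- dim(train$x)[3]
  if (dim(val$x)[3] == 0)
    stop_config("validation set is empty; early stopping undefined")
  y_tr <- as.integer(train$y)
  classes <- levels(train$y)

  with_seed(train_cfg$seed, {
    init <- cnn_init_params(model_cfg, seed = stats::runif(1) * 1e8)
    params <- init$params; rs <- init$rs
    opt <- adam_init(params)
    lr <- train_cfg$lr
    plateau <- plateau_tracker(train_cfg$plateau_patience)
    best_f1 <- -Inf; best <- list(params = params, rs = rs); es_wait <- 0L
    hist <- vector("list", train_cfg$max_epochs)

    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = train_cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + train_cfg$batch_size - 1, n)]
        xb <- train$x[, , idx, drop = FALSE]
        fw <- cnn_forward(params, rs, xb, model_cfg, train = TRUE)
        rs <- fw$rs
        batch_losses[bi] <- ce_loss(fw$logits, y_tr[idx])
        grads <- cnn_backward(params, fw, ce_grad(fw$logits, y_tr[idx]),
                              model_cfg)
        upd <- adam_step(params, grads, opt, lr, train_cfg$weight_decay)
        params <- upd$params; opt <- upd$state
      }
      train_loss <- mean(batch_losses)

      vp <- cnn_predict_array(params, rs, val$x, model_cfg, classes)
      val_loss <- ce_loss(log(pmax(vp, 1e-12)), as.integer(val$y))
      val_f1 <- quick_macro_f1(val$y, vp)

      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, val_f1 = val_f1,
                                  lr = lr)
      if (plateau(train_loss)) lr <- lr * train_cfg$lr_decay_factor

      if (val_f1 > best_f1 + 1e-9) {
        best_f1 <- val_f1
        best <- list(params = params, rs = rs)
        es_wait <- 0L
      } else {
        es_wait <- es_wait + 1L
        if (es_wait >= train_cfg$early_stopping_patience) break
      }
    }

    structure(list(params = best$params, bn_stats = best$rs,
                   model_cfg = model_cfg, train_cfg = train_cfg,
                   classes = classes,
                   history = do.call(rbind, hist[!vapply(hist, is.null,
                                                         TRUE)]),
                   best_val_f1 = best_f1),
              class = c("cnn_classifier", "trained_classifier"))
  })
}

# Chunked eval-mode prediction over a window array.
cnn_predict_array <- function(params, rs, xarr, cfg, classes,
                              chunk = 8192L) {
  n <- dim(xarr)[3]
  out <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + chunk - 1L, n)
    fw <- cnn_forward(params, rs, xarr[, , idx, drop = FALSE], cfg,
                      train = FALSE)
    out[idx, ] <- softmax_rows(fw$logits)
    at <- at + chunk
  }
  out
}

#' @export
#' @describeIn predict_proba CNN method: `newdata` is a list of `recording`
#'   objects, a single `recording`, or a window batch from
#'   [windows_from_recordings()]. The returned matrix carries
#'   `recording_id` and `target_index` attributes aligning each prediction
#'   with the last sample of its window; the first `window - 1` samples of
#'   each recording are not scored.
#' @param contact_window_s Analysed prefix of the contact phase (CNN method
#'   only, used when `newdata` holds recordings).
#' @param normalizer Optional normalizer applied to recording channels (CNN
#'   method only).
predict_proba.cnn_classifier <- function(model, newdata, ...,
                                         contact_window_s = 1.0,
                                         normalizer = NULL) {
  wb <- if (is.list(newdata) && !is.null(newdata$x)) newdata
  else {
    recs <- if (inherits(newdata, "recording")) list(newdata) else newdata
    windows_from_recordings(recs, model$model_cfg$window,
                            contact_window_s, normalizer)
  }
  if (dim(wb$x)[1] != model$model_cfg$in_channels)
    stop_config("input has %d channels, model expects %d",
                dim(wb$x)[1], model$model_cfg$in_channels)
  p <- cnn_predict_array(model$params, model$bn_stats, wb$x,
                         model$model_cfg, model$classes)
  attr(p, "recording_id") <- wb$recording_id
  attr(p, "target_index") <- wb$target_index
  p
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf(paste0("1D residual CNN: %d conv layers, window %d, ",
                     "%d epochs trained, best val F1 %.3f\n"),
              cnn_conv_layer_count(x$model_cfg), x$model_cfg$window,
              nrow(x$history), x$best_val_f1))
  invisible(x)
}
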