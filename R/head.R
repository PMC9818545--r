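#' Training configuration for the neural stages
#'
#' Defaults follow the patch-stage recipe: initial learning rate 0.008
#' decayed as lr <- lr / (1 + decay) after every epoch with
#' decay = lr0 / max_epochs, Adam with beta1 = 0.8 and beta2 = 0.99,
#' dropout 0.4, early stopping when validation categorical accuracy fails to
#' improve by more than `early_stop_tol` for `early_stop_patience`
#' consecutive epochs.
#'
#' @param lr0 Initial learning rate.
#' @param max_epochs Maximum training epochs.
#' @param decay Per-epoch learning-rate decay; default `lr0 / max_epochs`.
#' @param early_stop_patience Consecutive non-improving epochs tolerated
#'   before stopping.
#' @param early_stop_tol Minimum improvement of the monitored quantity
#'   counted as progress.
#' @param early_stop_metric What early stopping monitors: `"loss"`
#'   (default; validation cross-entropy, continuous and usable with small
#'   validation sets) or `"accuracy"` (validation categorical accuracy,
#'   whose granularity is 1/n_validation). Training metrics are used when
#'   no validation set is given.
#' @param dropout Dropout probability in the head.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param l2 L2 penalty on the first dense layer's weights.
#' @param seed Integer seed (weight init and dropout masks).
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 0.008, max_epochs = 60L,
                         decay = lr0 / max_epochs,
                         early_stop_patience = 5L, early_stop_tol = 1e-3,
                         early_stop_metric = c("loss", "accuracy"),
                         dropout = 0.4, adam_beta1 = 0.8, adam_beta2 = 0.99,
                         l2 = 1e-4, seed = 1L) {
  early_stop_metric <- match.arg(early_stop_metric)
  structure(list(lr0 = lr0, max_epochs = as.integer(max_epochs),
                 decay = decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_tol = early_stop_tol,
                 early_stop_metric = early_stop_metric, dropout = dropout,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, l2 = l2,
                 seed = as.integer(seed)),
            class = "train_config")
}

# monitored quantity, oriented so larger is better
monitor_value <- function(cfg, train_loss, train_acc, val_loss, val_acc) {
  metric <- if (is.null(cfg$early_stop_metric)) "loss"
            else cfg$early_stop_metric
  if (metric == "loss") {
    if (is.na(val_loss)) -train_loss else -val_loss
  } else {
    if (is.na(val_acc)) train_acc else val_acc
  }
}

#' Construct the fine-tuning head
#'
#' The head placed on top of a backbone's spatial feature map: a conv layer
#' of `n_kernels` 3x3 kernels (stride 1, no padding), 2x2 max pooling
#' (stride 2), global average pooling -- the feature tap, one value per
#' kernel, so 512-dimensional features for the standard head -- then batch
#' normalization, dropout, a 64-unit dense layer with sigmoid activation
#' (He-uniform init, L2 penalty), a 4-unit dense layer and softmax.
#'
#' @param in_channels Backbone output channel count C.
#' @param n_kernels Conv kernel count (feature dimension), default 512.
#' @param n_hidden First dense layer width, default 64.
#' @param n_classes Output classes, default 4.
#' @param init `"he"` (default) for He-uniform weights or `"zero"` for an
#'   all-zero head (useful for smoke checks: zero logits give uniform
#'   probabilities).
#' @param seed Integer seed for the weight draw.
#' @return A `fine_tune_head`.
#' @export
fine_tune_head <- function(in_channels, n_kernels = 512L, n_hidden = 64L,
                           n_classes = 4L, init = c("he", "zero"),
                           seed = 1L) {
  init <- match.arg(init)
  params <- with_seed(derive_seed(seed, 202L), {
    if (init == "zero") {
      list(Wc = matrix(0, 9L * in_channels, n_kernels),
           bc = rep(0, n_kernels),
           W1 = matrix(0, n_kernels, n_hidden), b1 = rep(0, n_hidden),
           W2 = matrix(0, n_hidden, n_classes), b2 = rep(0, n_classes))
    } else {
      list(Wc = he_uniform(9L * in_channels, n_kernels),
           bc = rep(0, n_kernels),
           W1 = he_uniform(n_kernels, n_hidden), b1 = rep(0, n_hidden),
           W2 = he_uniform(n_hidden, n_classes), b2 = rep(0, n_classes))
    }
  })
  structure(list(
    params = params,
    bn = list(gamma = rep(1, n_kernels), beta = rep(0, n_kernels),
              mean = rep(0, n_kernels), var = rep(1, n_kernels)),
    in_channels = as.integer(in_channels), n_kernels = as.integer(n_kernels),
    n_hidden = as.integer(n_hidden), n_classes = as.integer(n_classes),
    trained = FALSE
  ), class = "fine_tune_head")
}

#' @export
print.fine_tune_head <- function(x, ...) {
  cat(sprintf(paste0("<fine_tune_head: conv %d kernels on %d channels, ",
                     "dense %d -> %d, %s>\n"),
              x$n_kernels, x$in_channels, x$n_hidden, x$n_classes,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# conv stage of the head on one feature map: returns GAP features plus the
# caches needed for backprop
head_conv_stage <- function(feature_map, head, want_cache = FALSE) {
  ic <- im2col3(feature_map)
  conv <- sweep(ic$mat %*% head$params$Wc, 2, head$params$bc, "+")
  pool <- maxpool2_mat(conv, ic$h, ic$w)
  gap <- colMeans(pool$out)
  if (!want_cache) return(list(gap = gap))
  list(gap = gap, im2col = ic$mat, pool = pool, n_conv = ic$h * ic$w)
}

# dense stage on a batch of GAP features (inference path: running BN stats,
# no dropout)
head_dense_stage_infer <- function(gap_mat, head) {
  x <- bn_forward_infer(gap_mat, head$bn$gamma, head$bn$beta,
                        head$bn$mean, head$bn$var)
  a1 <- sigmoid(sweep(x %*% head$params$W1, 2, head$params$b1, "+"))
  softmax_rows(sweep(a1 %*% head$params$W2, 2, head$params$b2, "+"))
}

#' Forward pass of the fine-tuning head on one feature map
#'
#' @param feature_map H' x W' x C array from a backbone (spatially at least
#'   4 x 4 so the conv and pooling layers fit).
#' @param head A [fine_tune_head()].
#' @return List with `probabilities` (length-`n_classes` vector summing
#'   to 1) and `features` (the GAP tap, length `n_kernels`).
#' @export
head_forward <- function(feature_map, head) {
  stopifnot(inherits(head, "fine_tune_head"))
  if (dim(feature_map)[3] != head$in_channels) {
    stop(sprintf("feature map has %d channels, head expects %d",
                 dim(feature_map)[3], head$in_channels))
  }
  cs <- head_conv_stage(feature_map, head)
  probs <- head_dense_stage_infer(matrix(cs$gap, nrow = 1), head)
  list(probabilities = as.vector(probs), features = cs$gap)
}

#' Cross-entropy loss
#'
#' -sum(y_true * log(y_pred)) with natural log and an epsilon guard.
#' A uniform 4-class prediction against any one-hot truth costs
#' log(4) ~ 1.3863.
#'
#' @param y_true One-hot vector (or matrix, rows = samples).
#' @param y_pred Probability vector (or matrix) of matching shape.
#' @param eps Guard added inside the log.
#' @return Mean cross-entropy over samples.
#' @export
cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  if (is.vector(y_true)) {
    y_true <- matrix(y_true, nrow = 1)
    y_pred <- matrix(y_pred, nrow = 1)
  }
  mean(-rowSums(y_true * log(pmax(y_pred, eps))))
}

#' Categorical accuracy
#'
#' Fraction of samples whose argmax prediction matches the label; argmax
#' ties break to the lowest class index.
#'
#' @param labels Integer class indices (1-based) or class-name character
#'   vector.
#' @param probs Matrix of probabilities, rows = samples.
#' @return Accuracy in \[0, 1\].
#' @export
categorical_accuracy <- function(labels, probs) {
  if (is.character(labels)) labels <- class_index(labels)
  if (length(labels) == 0) stop("empty input: no samples to score")
  pred <- apply(probs, 1, which.max)
  mean(pred == labels)
}

one_hot <- function(labels, n_classes = 4L) {
  if (is.character(labels)) labels <- class_index(labels)
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), labels)] <- 1
  out
}

#' Train the fine-tuning head on labelled patches
#'
#' Full-batch training with Adam and cross-entropy loss under the
#' lr <- lr / (1 + decay) schedule; early stopping watches validation
#' categorical accuracy and restores the best weights. Tiny backbones train
#' fully together with the head (their conv blocks receive gradients, the
#' pooling branch is a fixed skip); other backbones are frozen and only the
#' head's parameters (conv, batchnorm, dense layers) are trained on their
#' cached embeddings.
#'
#' @param backbone A [backbone()].
#' @param head A [fine_tune_head()] matching the backbone's channels.
#' @param patches Labelled training `patch_record`s (at least one per class
#'   present in the data).
#' @param valid Optional validation `patch_record`s (enables early
#'   stopping).
#' @param cfg A [train_config()].
#' @return List with `head` (trained), `history` (data.frame epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc) and `backbone` (trained for
#'   tiny backbones, otherwise the input backbone).
#' @export
train_head <- function(backbone, head, patches, valid = NULL,
                       cfg = train_config()) {
  stopifnot(inherits(backbone, "backbone"), inherits(head, "fine_tune_head"))
  labels <- vapply(patches, function(p) p$label, character(1))
  val_labels <- if (!is.null(valid) && length(valid) > 0) {
    vapply(valid, function(p) p$label, character(1))
  }
  if (isTRUE(backbone$trainable)) {
    pre <- lapply(patches, function(p) {
      tiny_precompute(p$pixels, backbone$downsample, backbone$conv_channels)
    })
    val_pre <- if (!is.null(valid) && length(valid) > 0) {
      lapply(valid, function(p) {
        tiny_precompute(p$pixels, backbone$downsample,
                        backbone$conv_channels)
      })
    }
    return(train_head_joint(backbone, head, pre, labels, val_pre,
                            val_labels, cfg))
  }
  maps <- lapply(patches, function(p) backbone$embed(p$pixels))
  val_maps <- if (!is.null(valid) && length(valid) > 0) {
    lapply(valid, function(p) backbone$embed(p$pixels))
  }
  fit <- train_head_maps(head, maps, labels, val_maps, val_labels, cfg)
  fit$backbone <- backbone
  fit
}

# core trainer over precomputed backbone feature maps (the pipeline embeds
# each patch once and trains on the cached maps)
train_head_maps <- function(head, maps, labels, val_maps = NULL,
                            val_labels = NULL, cfg = train_config()) {
  if (length(maps) == 0) stop("data error: no training patches")
  y <- one_hot(labels, head$n_classes)
  caches <- lapply(maps, im2col3)
  if (!is.null(val_maps) && length(val_maps) > 0) {
    val_labels <- class_index(val_labels)
    val_y <- one_hot(val_labels, head$n_classes)
  } else {
    val_maps <- NULL
  }
  patches <- maps # for length bookkeeping below
  valid <- val_maps
  n <- length(patches)
  K <- head$n_kernels
  params <- head$params
  bn <- head$bn
  opt <- adam_init(params)
  opt_bn <- adam_init(list(gamma = bn$gamma, beta = bn$beta))
  lr <- cfg$lr0
  history <- NULL
  best <- list(acc = -Inf, params = params, bn = bn)
  stall <- 0L
  rng_seed <- derive_seed(cfg$seed, 303L)
  for (epoch in seq_len(cfg$max_epochs)) {
    # per-patch conv stage
    gap <- matrix(0, n, K)
    pools <- vector("list", n)
    for (i in seq_len(n)) {
      conv <- sweep(caches[[i]]$mat %*% params$Wc, 2, params$bc, "+")
      pools[[i]] <- maxpool2_mat(conv, caches[[i]]$h, caches[[i]]$w)
      gap[i, ] <- colMeans(pools[[i]]$out)
    }
    # batch stage
    bnf <- bn_forward_train(gap, bn$gamma, bn$beta)
    mask <- with_seed(derive_seed(rng_seed, epoch), {
      matrix(stats::runif(n * K) >= cfg$dropout, n, K) / (1 - cfg$dropout)
    })
    dropped <- bnf$out * mask
    z1 <- sweep(dropped %*% params$W1, 2, params$b1, "+")
    a1 <- sigmoid(z1)
    z2 <- sweep(a1 %*% params$W2, 2, params$b2, "+")
    probs <- softmax_rows(z2)
    train_loss <- cross_entropy(y, probs) + cfg$l2 * sum(params$W1^2)
    train_acc <- categorical_accuracy(class_index(labels), probs)
    # backward
    dz2 <- (probs - y) / n
    gW2 <- crossprod(a1, dz2); gb2 <- colSums(dz2)
    da1 <- tcrossprod(dz2, params$W2)
    dz1 <- da1 * a1 * (1 - a1)
    gW1 <- crossprod(dropped, dz1) + 2 * cfg$l2 * params$W1
    gb1 <- colSums(dz1)
    d_dropped <- tcrossprod(dz1, params$W1) * mask
    bnb <- bn_backward(bnf, bn$gamma, d_dropped)
    d_gap <- bnb$dx
    gWc <- matrix(0, nrow(params$Wc), K); gbc <- rep(0, K)
    for (i in seq_len(n)) {
      np <- nrow(pools[[i]]$out)
      d_pool <- matrix(d_gap[i, ] / np, np, K, byrow = TRUE)
      d_conv <- maxpool2_backward(pools[[i]], d_pool,
                                  caches[[i]]$h * caches[[i]]$w)
      gWc <- gWc + crossprod(caches[[i]]$mat, d_conv)
      gbc <- gbc + colSums(d_conv)
    }
    step <- adam_step(params,
                      list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1,
                           W2 = gW2, b2 = gb2),
                      opt, lr, cfg$adam_beta1, cfg$adam_beta2)
    params <- step$params; opt <- step$state
    stepb <- adam_step(list(gamma = bn$gamma, beta = bn$beta),
                       list(gamma = bnb$d_gamma, beta = bnb$d_beta),
                       opt_bn, lr, cfg$adam_beta1, cfg$adam_beta2)
    bn$gamma <- stepb$params$gamma; bn$beta <- stepb$params$beta
    opt_bn <- stepb$state
    # training is full-batch, so the batch statistics are the dataset
    # statistics; inference uses them directly
    bn$mean <- bnf$mu
    bn$var <- bnf$v
    # validation
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(valid) && length(valid) > 0) {
      tmp_head <- head
      tmp_head$params <- params; tmp_head$bn <- bn
      vgap <- t(vapply(val_maps,
                       function(m) head_conv_stage(m, tmp_head)$gap,
                       numeric(K)))
      vprobs <- head_dense_stage_infer(vgap, tmp_head)
      val_loss <- cross_entropy(val_y, vprobs)
      val_acc <- categorical_accuracy(val_labels, vprobs)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = train_loss,
                                train_acc = train_acc,
                                val_loss = val_loss, val_acc = val_acc))
    watch <- monitor_value(cfg, train_loss, train_acc, val_loss, val_acc)
    if (watch > best$acc + cfg$early_stop_tol) {
      best <- list(acc = watch, params = params, bn = bn)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
    lr <- lr / (1 + cfg$decay)
  }
  head$params <- best$params
  head$bn <- best$bn
  head$trained <- TRUE
  list(head = head, history = history)
}

#' Extract GAP features for patches
#'
#' One feature vector per patch per backbone, tapped at the head's global
#' average pooling output (length `head$n_kernels`, 512 for the standard
#' head), order-aligned with the input. Pure: no training state changes.
#'
#' @param backbone A [backbone()].
#' @param head A `fine_tune_head` (trained, or untrained for smoke tests).
#' @param patches List of `patch_record`s.
#' @return A `feature_set`: list with `values` (N x n_kernels matrix),
#'   `patch_ids`, `labels`, `source`.
#' @export
extract_features <- function(backbone, head, patches) {
  vals <- features_from_maps(head, lapply(patches,
                                          function(p) backbone$embed(p$pixels)))
  structure(list(values = vals,
                 patch_ids = vapply(patches, function(p) p$patch_id,
                                    character(1)),
                 labels = vapply(patches, function(p) p$label, character(1)),
                 source = backbone$name),
            class = "feature_set")
}

# Joint trainer: fine-tuning head plus the tiny backbone's conv blocks
# (the backbone trains fully; its pooling branch is a fixed skip). Same
# full-batch Adam schedule, lr decay and early stopping as train_head_maps.
train_head_joint <- function(backbone, head, pre_list, labels,
                             val_pre = NULL, val_labels = NULL,
                             cfg = train_config()) {
  if (length(pre_list) == 0) stop("data error: no training patches")
  ch <- backbone$conv_channels
  y <- one_hot(labels, head$n_classes)
  if (!is.null(val_pre) && length(val_pre) > 0) {
    val_idx <- class_index(val_labels)
    val_y <- one_hot(val_idx, head$n_classes)
  } else {
    val_pre <- NULL
  }
  n <- length(pre_list)
  K <- head$n_kernels
  C_in <- head$in_channels
  params <- c(head$params,
              list(bW1 = backbone$weights$W1, bb1 = backbone$weights$b1,
                   bW2 = backbone$weights$W2, bb2 = backbone$weights$b2))
  bn <- head$bn
  opt <- adam_init(params)
  opt_bn <- adam_init(list(gamma = bn$gamma, beta = bn$beta))
  lr <- cfg$lr0
  history <- NULL
  best <- list(acc = -Inf, params = params, bn = bn)
  stall <- 0L
  rng_seed <- derive_seed(cfg$seed, 303L)
  for (epoch in seq_len(cfg$max_epochs)) {
    bw <- list(W1 = params$bW1, b1 = params$bb1,
               W2 = params$bW2, b2 = params$bb2)
    gap <- matrix(0, n, K)
    caches <- vector("list", n)
    for (i in seq_len(n)) {
      fw <- tiny_forward_conv(pre_list[[i]], bw, ch, want_cache = TRUE)
      head_in <- array(0, dim = c(fw$h, fw$w, C_in))
      head_in[, , seq_len(ch[2])] <- array(fw$map_mat,
                                           dim = c(fw$h, fw$w, ch[2]))
      head_in[, , ch[2] + 1:3] <- pre_list[[i]]$pool
      ic <- im2col3(head_in)
      conv <- sweep(ic$mat %*% params$Wc, 2, params$bc, "+")
      pool <- maxpool2_mat(conv, ic$h, ic$w)
      gap[i, ] <- colMeans(pool$out)
      caches[[i]] <- list(bb = fw$cache, ic = ic, pool = pool,
                          hf = fw$h, wf = fw$w)
    }
    bnf <- bn_forward_train(gap, bn$gamma, bn$beta)
    mask <- with_seed(derive_seed(rng_seed, epoch), {
      matrix(stats::runif(n * K) >= cfg$dropout, n, K) / (1 - cfg$dropout)
    })
    dropped <- bnf$out * mask
    z1 <- sweep(dropped %*% params$W1, 2, params$b1, "+")
    a1 <- sigmoid(z1)
    z2 <- sweep(a1 %*% params$W2, 2, params$b2, "+")
    probs <- softmax_rows(z2)
    train_loss <- cross_entropy(y, probs) + cfg$l2 * sum(params$W1^2)
    train_acc <- categorical_accuracy(class_index(labels), probs)
    dz2 <- (probs - y) / n
    gW2 <- crossprod(a1, dz2); gb2 <- colSums(dz2)
    da1 <- tcrossprod(dz2, params$W2)
    dz1 <- da1 * a1 * (1 - a1)
    gW1 <- crossprod(dropped, dz1) + 2 * cfg$l2 * params$W1
    gb1 <- colSums(dz1)
    d_dropped <- tcrossprod(dz1, params$W1) * mask
    bnb <- bn_backward(bnf, bn$gamma, d_dropped)
    d_gap <- bnb$dx
    gWc <- matrix(0, nrow(params$Wc), K); gbc <- rep(0, K)
    gbW1 <- params$bW1 * 0; gbb1 <- params$bb1 * 0
    gbW2 <- params$bW2 * 0; gbb2 <- params$bb2 * 0
    for (i in seq_len(n)) {
      cc <- caches[[i]]
      np <- nrow(cc$pool$out)
      d_pool <- matrix(d_gap[i, ] / np, np, K, byrow = TRUE)
      d_conv <- maxpool2_backward(cc$pool, d_pool, cc$ic$h * cc$ic$w)
      gWc <- gWc + crossprod(cc$ic$mat, d_conv)
      gbc <- gbc + colSums(d_conv)
      d_head_in <- col2im3(d_conv %*% t(params$Wc), cc$hf, cc$wf, C_in)
      d_map_mat <- matrix(d_head_in[, , seq_len(ch[2])],
                          cc$hf * cc$wf, ch[2])
      gb <- tiny_backward_conv(cc$bb, bw, ch, d_map_mat)
      gbW1 <- gbW1 + gb$W1; gbb1 <- gbb1 + gb$b1
      gbW2 <- gbW2 + gb$W2; gbb2 <- gbb2 + gb$b2
    }
    step <- adam_step(params,
                      list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1,
                           W2 = gW2, b2 = gb2, bW1 = gbW1, bb1 = gbb1,
                           bW2 = gbW2, bb2 = gbb2),
                      opt, lr, cfg$adam_beta1, cfg$adam_beta2)
    params <- step$params; opt <- step$state
    stepb <- adam_step(list(gamma = bn$gamma, beta = bn$beta),
                       list(gamma = bnb$d_gamma, beta = bnb$d_beta),
                       opt_bn, lr, cfg$adam_beta1, cfg$adam_beta2)
    bn$gamma <- stepb$params$gamma; bn$beta <- stepb$params$beta
    opt_bn <- stepb$state
    bn$mean <- bnf$mu
    bn$var <- bnf$v
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(val_pre)) {
      bw_now <- list(W1 = params$bW1, b1 = params$bb1,
                     W2 = params$bW2, b2 = params$bb2)
      tmp_head <- head
      tmp_head$params <- params[c("Wc", "bc", "W1", "b1", "W2", "b2")]
      tmp_head$bn <- bn
      vgap <- t(vapply(val_pre, function(p) {
        head_conv_stage(tiny_map(p, bw_now, ch), tmp_head)$gap
      }, numeric(K)))
      vprobs <- head_dense_stage_infer(vgap, tmp_head)
      val_loss <- cross_entropy(val_y, vprobs)
      val_acc <- categorical_accuracy(val_idx, vprobs)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = train_loss,
                                train_acc = train_acc,
                                val_loss = val_loss, val_acc = val_acc))
    watch <- monitor_value(cfg, train_loss, train_acc, val_loss, val_acc)
    if (watch > best$acc + cfg$early_stop_tol) {
      best <- list(acc = watch, params = params, bn = bn)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
    lr <- lr / (1 + cfg$decay)
  }
  head$params <- best$params[c("Wc", "bc", "W1", "b1", "W2", "b2")]
  head$bn <- best$bn
  head$trained <- TRUE
  trained_bb <- tiny_backbone_from_weights(
    backbone$name,
    list(W1 = best$params$bW1, b1 = best$params$bb1,
         W2 = best$params$bW2, b2 = best$params$bb2),
    backbone$conv_channels, backbone$downsample
  )
  list(head = head, history = history, backbone = trained_bb)
}

# GAP feature matrix from precomputed backbone maps
features_from_maps <- function(head, maps) {
  t(vapply(maps, function(m) head_conv_stage(m, head)$gap,
           numeric(head$n_kernels)))
}

#' Concatenate feature sets across backbones
#'
#' @param feature_sets List of aligned `feature_set`s (same patches, same
#'   order).
#' @return A `feature_set` with per-patch vectors concatenated in the given
#'   backbone order; `source = "concat"`.
#' @export
concat_features <- function(feature_sets) {
  stopifnot(length(feature_sets) >= 1)
  ids <- feature_sets[[1]]$patch_ids
  for (fs in feature_sets[-1]) {
    if (!identical(fs$patch_ids, ids)) {
      stop("alignment error: feature sets cover different patches or orders")
    }
  }
  structure(list(values = do.call(cbind, lapply(feature_sets, `[[`, "values")),
                 patch_ids = ids, labels = feature_sets[[1]]$labels,
                 source = "concat"),
            class = "feature_set")
}
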