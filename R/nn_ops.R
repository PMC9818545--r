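# Internal neural-network primitives used by the fine-tuning head, the tiny
# backbone and the two image-stage networks. Spatial tensors are H x W x C
# arrays; spatial positions are linearized column-major (y fastest), so an
# H x W plane flattens to a length-HW vector exactly as R stores it.

# im2col for a 3x3 valid convolution: rows = output positions, columns
# ordered (dy, dx, channel) with dy fastest matching kernel_matrix()
im2col3 <- function(x) {
  d <- dim(x)
  h2 <- d[1] - 2L; w2 <- d[2] - 2L; C <- d[3]
  if (h2 < 1 || w2 < 1) {
    stop(sprintf("dimension error: spatial map %dx%d smaller than 3x3 kernel",
                 d[1], d[2]))
  }
  cols <- vector("list", 9L * C)
  k <- 1L
  for (ch in seq_len(C)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        cols[[k]] <- as.vector(x[(1 + dy):(h2 + dy), (1 + dx):(w2 + dx), ch])
        k <- k + 1L
      }
    }
  }
  list(mat = matrix(unlist(cols), nrow = h2 * w2), h = h2, w = w2)
}

# He-uniform init for a fan_in x fan_out weight matrix
he_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# 2x2 max pooling (stride 2) over a spatial-major matrix (rows = h*w
# positions, cols = channels); returns pooled matrix + routing info
maxpool2_mat <- function(x, h, w) {
  hp <- h %/% 2L; wp <- w %/% 2L
  if (hp < 1 || wp < 1) stop("dimension error: spatial map too small to pool")
  py <- rep(seq_len(hp), times = wp)
  px <- rep(seq_len(wp), each = hp)
  base_y <- 2L * py - 1L; base_x <- 2L * px - 1L
  idx <- cbind(base_y + (base_x - 1L) * h,
               base_y + 1L + (base_x - 1L) * h,
               base_y + (base_x) * h,
               base_y + 1L + (base_x) * h)
  out <- x[idx[, 1], , drop = FALSE]
  amax <- matrix(1L, nrow(out), ncol(out))
  for (j in 2:4) {
    cand <- x[idx[, j], , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    amax[better] <- j
  }
  list(out = out, amax = amax, idx = idx, h = hp, w = wp)
}

# scatter pooled gradients back to conv positions
maxpool2_backward <- function(pool, d_out, n_positions) {
  dx <- matrix(0, n_positions, ncol(d_out))
  for (j in 1:4) {
    sel <- pool$amax == j
    contrib <- d_out * sel
    dx[pool$idx[, j], ] <- dx[pool$idx[, j], ] + contrib
  }
  dx
}

# 2x2 max pooling over an H x W x C array (used by the tiny backbone)
maxpool2_array <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  p <- maxpool2_mat(m, d[1], d[2])
  array(p$out, dim = c(p$h, p$w, d[3]))
}

# block-mean downsampling of an H x W x C array by an integer factor
block_mean <- function(x, f) {
  d <- dim(x)
  h <- (d[1] %/% f) * f; w <- (d[2] %/% f) * f
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, dim = c(h %/% f, w %/% f, d[3]))
  for (ch in seq_len(d[3])) {
    m <- x[, , ch]
    # average rows within blocks, then columns
    m <- rowsum(m, rep(seq_len(h %/% f), each = f)) / f
    m <- t(rowsum(t(m), rep(seq_len(w %/% f), each = f)) / f)
    out[, , ch] <- m
  }
  out
}

# scatter im2col-space gradients back onto the input array (inverse of
# im2col3's column ordering: dy fastest, then dx, then channel)
col2im3 <- function(d_cols, h, w, C) {
  h2 <- h - 2L; w2 <- w - 2L
  dx_arr <- array(0, dim = c(h, w, C))
  k <- 1L
  for (ch in seq_len(C)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        dx_arr[(1 + dy):(h2 + dy), (1 + dx):(w2 + dx), ch] <-
          dx_arr[(1 + dy):(h2 + dy), (1 + dx):(w2 + dx), ch] +
          matrix(d_cols[, k], h2, w2)
        k <- k + 1L
      }
    }
  }
  dx_arr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax with max-shift stabilisation
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Softmax of a numeric vector
#'
#' @param z Numeric vector of scores.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ---- Adam optimizer ----
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.8, beta2 = 0.99,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- batch normalization over a batch of feature vectors ----
bn_forward_train <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd, mu = mu, v = v)
}

bn_backward <- function(cache, gamma, d_out) {
  n <- nrow(cache$xhat)
  d_xhat <- sweep(d_out, 2, gamma, "*")
  term1 <- d_xhat
  term2 <- matrix(colMeans(d_xhat), n, ncol(d_xhat), byrow = TRUE)
  term3 <- sweep(cache$xhat, 2, colMeans(d_xhat * cache$xhat), "*")
  dx <- sweep(term1 - term2 - term3, 2, cache$inv_sd, "*")
  list(dx = dx,
       d_gamma = colSums(d_out * cache$xhat),
       d_beta = colSums(d_out))
}

bn_forward_infer <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  xhat <- sweep(sweep(x, 2, mean), 2, 1 / sqrt(var + eps), "*")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}
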