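#' Construct a backbone
#'
#' A backbone is the dimension-reduction stage: a deterministic function
#' mapping a 512 x 512 x 3 patch to a spatial feature map (H' x W' x C) that
#' the fine-tuning head is trained on. Backbones are an interface, not a
#' dependency: the package ships a tiny seeded CNN backbone usable without
#' any pretrained weights, and `backbone()` lets callers wrap standard
#' pretrained networks (e.g. VGG-16, VGG-19, Inception-ResNet v2 adapters)
#' when a deep-learning runtime and weights are available.
#'
#' @param name Backbone name.
#' @param embed Function: H x W x 3 array -> H' x W' x C array. Must be
#'   deterministic for fixed weights.
#' @param channels Output channel count C (metadata).
#' @param trainable_depth Number of terminal backbone layers a training
#'   routine may unfreeze (the bundled training keeps backbones frozen; the
#'   field is carried for pretrained adapters, default 4).
#' @return A `backbone` object.
#' @export
backbone <- function(name, embed, channels, trainable_depth = 4L) {
  stopifnot(is.function(embed), channels >= 1)
  structure(list(name = name, embed = embed, channels = as.integer(channels),
                 trainable_depth = as.integer(trainable_depth)),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone %s: %d channels, trainable_depth=%d>\n",
              x$name, x$channels, x$trainable_depth))
  invisible(x)
}

# average input pixels over an hf x wf grid of contiguous blocks (works for
# any input size; used for the backbone's pooling branch)
grid_mean <- function(pixels, hf, wf) {
  d <- dim(pixels)
  ybin <- pmin(hf, 1L + floor((seq_len(d[1]) - 1) * hf / d[1]))
  xbin <- pmin(wf, 1L + floor((seq_len(d[2]) - 1) * wf / d[2]))
  out <- array(0, dim = c(hf, wf, d[3]))
  for (ch in seq_len(d[3])) {
    m <- rowsum(pixels[, , ch], ybin)
    m <- t(rowsum(t(m), xbin))
    out[, , ch] <- m / tcrossprod(tabulate(ybin, hf), tabulate(xbin, wf))
  }
  out
}

#' Tiny seeded CNN backbone
#'
#' A small fixed CNN usable without any pretrained weights: two 3x3 conv +
#' ReLU + 2x2 maxpool blocks (seeded random projections, frozen) over an
#' 8x block-mean downsample, plus an average-pooling branch that places the
#' raw RGB channels, block-averaged onto the output grid, alongside the
#' texture channels. A 512 x 512 x 3 patch embeds to 14 x 14 x 19
#' (16 texture + 3 intensity channels): the pooling branch carries local
#' stain density directly, the conv branch local texture.
#'
#' @param seed Integer seed for the weight draw.
#' @param channels Length-2 integer vector of conv block widths
#'   (default c(8, 16)).
#' @param downsample Initial block-mean factor (default 8).
#' @return A `backbone`.
#' @export
tiny_backbone <- function(seed = 1L, channels = c(8L, 16L), downsample = 8L) {
  weights <- with_seed(derive_seed(seed, 101L), {
    list(W1 = he_uniform(9L * 3L, channels[1]),
         b1 = rep(0, channels[1]),
         W2 = he_uniform(9L * channels[1], channels[2]),
         b2 = rep(0, channels[2]))
  })
  tiny_backbone_from_weights(sprintf("tiny_seed%d", seed), weights,
                             channels, downsample)
}

# assemble a tiny backbone object around a given weight set (also used to
# re-wrap trained weights after joint training)
tiny_backbone_from_weights <- function(name, weights, channels, downsample) {
  embed <- function(pixels) {
    pre <- tiny_precompute(pixels, downsample, channels)
    tiny_map(pre, weights, channels)
  }
  bb <- backbone(name, embed, channels[2] + 3L, trainable_depth = 2L)
  bb$trainable <- TRUE
  bb$weights <- weights
  bb$conv_channels <- channels
  bb$downsample <- downsample
  bb
}

# downsampled conv input plus the fixed pooling branch for one patch
tiny_precompute <- function(pixels, downsample, channels) {
  x0 <- block_mean(pixels, downsample)
  d0 <- dim(x0)
  hf <- ((d0[1] - 2L) %/% 2L - 2L) %/% 2L
  wf <- ((d0[2] - 2L) %/% 2L - 2L) %/% 2L
  if (hf < 1 || wf < 1) stop("dimension error: patch too small for backbone")
  list(x0 = x0, pool = grid_mean(pixels, hf, wf))
}

# forward through the two conv blocks; optionally keep backprop caches
tiny_forward_conv <- function(pre, weights, channels, want_cache = FALSE) {
  ic1 <- im2col3(pre$x0)
  z1 <- sweep(ic1$mat %*% weights$W1, 2, weights$b1, "+")
  m1 <- z1 > 0
  p1 <- maxpool2_mat(z1 * m1, ic1$h, ic1$w)
  x1 <- array(p1$out, dim = c(p1$h, p1$w, channels[1]))
  ic2 <- im2col3(x1)
  z2 <- sweep(ic2$mat %*% weights$W2, 2, weights$b2, "+")
  m2 <- z2 > 0
  p2 <- maxpool2_mat(z2 * m2, ic2$h, ic2$w)
  out <- list(map_mat = p2$out, h = p2$h, w = p2$w)
  if (want_cache) {
    out$cache <- list(ic1 = ic1, m1 = m1, p1 = p1, x1_dim = dim(x1),
                      ic2 = ic2, m2 = m2, p2 = p2)
  }
  out
}

# gradients of the conv blocks given d(map) in matrix form (hf*wf x C2)
tiny_backward_conv <- function(cache, weights, channels, d_map_mat) {
  d_a2 <- maxpool2_backward(cache$p2, d_map_mat,
                            cache$ic2$h * cache$ic2$w)
  d_z2 <- d_a2 * cache$m2
  gW2 <- crossprod(cache$ic2$mat, d_z2)
  gb2 <- colSums(d_z2)
  d_x1 <- col2im3(d_z2 %*% t(weights$W2), cache$x1_dim[1], cache$x1_dim[2],
                  channels[1])
  d_a1 <- maxpool2_backward(cache$p1,
                            matrix(d_x1, cache$x1_dim[1] * cache$x1_dim[2],
                                   channels[1]),
                            cache$ic1$h * cache$ic1$w)
  d_z1 <- d_a1 * cache$m1
  list(W1 = crossprod(cache$ic1$mat, d_z1), b1 = colSums(d_z1),
       W2 = gW2, b2 = gb2)
}

# full backbone map (conv branch + pooling branch) for one precomputed patch
tiny_map <- function(pre, weights, channels) {
  fw <- tiny_forward_conv(pre, weights, channels)
  out <- array(0, dim = c(fw$h, fw$w, channels[2] + 3L))
  out[, , seq_len(channels[2])] <- array(fw$map_mat,
                                         dim = c(fw$h, fw$w, channels[2]))
  out[, , channels[2] + 1:3] <- pre$pool
  out
}

#' Resolve backbone names to backbones
#'
#' `"tiny"` (optionally `"tiny2"`, `"tiny3"`, ... for differently-seeded
#' instances, used when concatenating features across several backbones)
#' resolves to [tiny_backbone()]. Adapters for pretrained networks must be
#' passed as ready-made [backbone()] objects.
#'
#' @param names Character vector of backbone names, or a list of `backbone`
#'   objects (returned unchanged).
#' @param seed Base seed for tiny instances.
#' @return List of `backbone`s.
#' @export
resolve_backbones <- function(names, seed = 1L) {
  if (is.list(names) && all(vapply(names, inherits, logical(1), "backbone"))) {
    return(names)
  }
  lapply(names, function(nm) {
    if (inherits(nm, "backbone")) return(nm)
    m <- regmatches(nm, regexec("^tiny([0-9]*)$", nm))[[1]]
    if (length(m) == 0) {
      stop("unknown backbone '", nm, "'; pass a backbone object for ",
           "pretrained adapters")
    }
    k <- if (m[2] == "") 1L else as.integer(m[2])
    tiny_backbone(seed = derive_seed(seed, k))
  })
}
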