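#' Specify the training-time augmentation stack
#'
#' Three sequential random layers applied to training patches only:
#' Bernoulli horizontal flip, Bernoulli vertical flip, rotation by an angle
#' drawn uniformly from +-`max_rotation_degrees`, then translation by
#' fractions drawn uniformly from +-`max_translation_fraction` of each
#' dimension.
#'
#' @param p_hflip,p_vflip Flip probabilities in \[0, 1\] (default 0.5).
#' @param max_rotation_degrees Rotation bound (default 15).
#' @param max_translation_fraction Translation bound as a fraction of the
#'   patch side, in \[0, 1) (default 0.1).
#' @param fill_mode Border fill for rotation/translation: `"reflect"`
#'   (default) or `"constant"` (fills with `fill_value`).
#' @param fill_value Constant fill value (default 1, i.e. background white).
#' @param seed Integer seed for the draw stream.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(p_hflip = 0.5, p_vflip = 0.5,
                         max_rotation_degrees = 15,
                         max_translation_fraction = 0.1,
                         fill_mode = c("reflect", "constant"),
                         fill_value = 1.0, seed = 1L) {
  fill_mode <- match.arg(fill_mode)
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            max_translation_fraction >= 0, max_translation_fraction < 1)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 max_rotation_degrees = max_rotation_degrees,
                 max_translation_fraction = max_translation_fraction,
                 fill_mode = fill_mode, fill_value = fill_value,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# fold out-of-range 1-based coordinates back into [1, n] by reflection
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  period <- 2 * (n - 1)
  i <- (i - 1) %% period
  i[i < 0] <- i[i < 0] + period
  ifelse(i > (n - 1), period - i, i) + 1
}

# inverse-mapped bilinear warp: rotation about the centre then translation,
# border handled by reflection or constant fill
warp_patch <- function(pixels, angle_deg, ty, tx, fill_mode, fill_value) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  theta <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  # inverse transform: undo translation, then rotate by -theta
  ys <- yy - ty; xs <- xx - tx
  src_y <- cos(theta) * ys + sin(theta) * xs + cy
  src_x <- -sin(theta) * ys + cos(theta) * xs + cx
  y0 <- floor(src_y); x0 <- floor(src_x)
  fy <- src_y - y0; fx <- src_x - x0
  out <- array(fill_value, dim = d)
  if (fill_mode == "reflect") {
    iy0 <- reflect_index(y0, h); iy1 <- reflect_index(y0 + 1, h)
    ix0 <- reflect_index(x0, w); ix1 <- reflect_index(x0 + 1, w)
    valid <- rep(TRUE, length(src_y))
  } else {
    valid <- src_y >= 1 & src_y <= h & src_x >= 1 & src_x <= w
    iy0 <- pmin(pmax(y0, 1), h); iy1 <- pmin(pmax(y0 + 1, 1), h)
    ix0 <- pmin(pmax(x0, 1), w); ix1 <- pmin(pmax(x0 + 1, 1), w)
  }
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  for (ch in seq_len(d[3])) {
    plane <- pixels[, , ch]
    vals <- w00 * plane[cbind(iy0, ix0)] + w01 * plane[cbind(iy0, ix1)] +
            w10 * plane[cbind(iy1, ix0)] + w11 * plane[cbind(iy1, ix1)]
    res <- rep(fill_value, length(vals))
    res[valid] <- vals[valid]
    out[, , ch] <- res
  }
  out
}

#' Apply the augmentation stack to one patch
#'
#' Applies, in order: horizontal flip (prob `p_hflip`), vertical flip
#' (prob `p_vflip`), rotation by a uniform random angle, translation by
#' uniform random fractions. Shape and label are preserved, pixels stay in
#' \[0, 1\] (bilinear interpolation of values already in \[0, 1\]).
#' Deterministic given the RNG state; pass `seed` to fix it locally.
#'
#' @param patch A `patch_record` (or `image_record`).
#' @param spec An [augment_spec()].
#' @param seed Optional integer; when given, draws come from a local RNG
#'   seeded with it, leaving the caller's RNG untouched.
#' @return The patch with augmented pixels.
#' @export
augment_patch <- function(patch, spec, seed = NULL) {
  run <- function() {
    px <- patch$pixels
    if (stats::runif(1) < spec$p_hflip) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (stats::runif(1) < spec$p_vflip) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    angle <- stats::runif(1, -spec$max_rotation_degrees,
                          spec$max_rotation_degrees)
    ty <- stats::runif(1, -spec$max_translation_fraction,
                       spec$max_translation_fraction) * dim(px)[1]
    tx <- stats::runif(1, -spec$max_translation_fraction,
                       spec$max_translation_fraction) * dim(px)[2]
    if (angle != 0 || ty != 0 || tx != 0) {
      px <- warp_patch(px, angle, ty, tx, spec$fill_mode, spec$fill_value)
    }
    px[px < 0] <- 0; px[px > 1] <- 1
    patch$pixels <- px
    patch
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Offline augmentation expansion
#'
#' Produces `k` augmented copies of each training patch (the offline
#' counterpart of on-the-fly augmentation). Copies get `_augN` id suffixes.
#'
#' @param patches List of `patch_record`s.
#' @param spec An [augment_spec()].
#' @param k Copies per patch.
#' @param seed Base seed; copy draws are derived from it deterministically.
#' @return List of original patches followed by augmented copies.
#' @export
augment_expand <- function(patches, spec, k = 1L, seed = spec$seed) {
  out <- patches
  for (j in seq_len(k)) {
    for (i in seq_along(patches)) {
      p <- augment_patch(patches[[i]], spec,
                         seed = derive_seed(seed, i * 17L + j))
      p$patch_id <- paste0(p$patch_id, "_aug", j)
      out[[length(out) + 1]] <- p
    }
  }
  out
}
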