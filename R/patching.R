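#' Enumerate patch-grid offsets
#'
#' Top-left corners of all fixed-size windows at the given stride that fit
#' entirely inside an image, in row-major order. The reference histology
#' geometry (1536 x 2048 image, 512 patch, 256 stride, i.e. 50% overlap)
#' yields 5 x 7 = 35 offsets.
#'
#' @param height,width Image size in pixels.
#' @param patch Patch side length (default 512).
#' @param stride Stride between adjacent patches (default 256).
#' @return Data.frame with 0-based columns `row`, `col`, `y`, `x`,
#'   row-major (all columns of row 0, then row 1, ...).
#' @export
patch_grid <- function(height, width, patch = 512L, stride = 256L) {
  if (patch > height || patch > width) {
    stop(sprintf("patch size %d exceeds image dimensions %dx%d",
                 patch, height, width))
  }
  stopifnot(stride >= 1)
  ys <- seq.int(0L, height - patch, by = stride)
  xs <- seq.int(0L, width - patch, by = stride)
  grid <- expand.grid(col = seq_along(xs) - 1L, row = seq_along(ys) - 1L)
  data.frame(row = grid$row, col = grid$col,
             y = ys[grid$row + 1L], x = xs[grid$col + 1L])
}

new_patch_record <- function(parent_id, row, col, y, x, pixels, label) {
  structure(
    list(patch_id = sprintf("%s_r%d_c%d", parent_id, row, col),
         parent_id = parent_id, row = row, col = col, y = y, x = x,
         pixels = pixels, label = label),
    class = "patch_record"
  )
}

#' @export
print.patch_record <- function(x, ...) {
  cat(sprintf("<patch_record %s: %dx%d at (%d,%d), label=%s>\n",
              x$patch_id, dim(x$pixels)[1], dim(x$pixels)[2],
              x$y, x$x, x$label))
  invisible(x)
}

#' Extract overlapping labelled patches from an image
#'
#' Every patch inherits the parent image's label (label propagation: patches
#' of a cancerous image are all labelled cancerous, accepting label noise for
#' heterogeneous tissue). Ordering matches [patch_grid()]. Margins that do
#' not fit a full window are omitted; nothing is padded.
#'
#' @param image An `image_record`.
#' @param patch,stride Geometry as in [patch_grid()].
#' @return List of `patch_record`s.
#' @export
extract_patches <- function(image, patch = 512L, stride = 256L) {
  d <- dim(image$pixels)
  grid <- patch_grid(d[1], d[2], patch, stride)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    window <- image$pixels[(g$y + 1):(g$y + patch),
                           (g$x + 1):(g$x + patch), , drop = FALSE]
    new_patch_record(image$image_id, g$row, g$col, g$y, g$x, window,
                     image$label)
  })
}
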