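#' Convert RGB transmittance to optical density
#'
#' Beer-Lambert: stain contributions are additive in optical density,
#' OD = -log10((I + eps) / I0). Pixels at the background intensity map to
#' OD ~ 0; a pixel at background/10 maps to OD 1 per channel.
#'
#' @param pixels Array (any shape) of transmittance values in \[0, 1\].
#' @param background_intensity Background (white) intensity I0, > 0.
#' @param eps Small positive guard against log(0).
#' @return Array of optical densities, same shape.
#' @export
rgb_to_od <- function(pixels, background_intensity = 1.0, eps = 1e-6) {
  stopifnot(background_intensity > 0)
  -log10((pixels + eps) / background_intensity)
}

#' Convert optical density back to RGB transmittance
#'
#' Inverse of [rgb_to_od()]: I = I0 * 10^(-OD), clipped to \[0, 1\].
#'
#' @param od Array of optical densities.
#' @param background_intensity Background intensity I0.
#' @return Array of pixel values in \[0, 1\], same shape.
#' @export
od_to_rgb <- function(od, background_intensity = 1.0) {
  out <- background_intensity * 10^(-od)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

new_stain_model <- function(stain_matrix, max_concentrations,
                            background_intensity, parameters = list()) {
  colnames(stain_matrix) <- c("hematoxylin", "eosin")
  structure(
    list(stain_matrix = stain_matrix,
         max_concentrations = max_concentrations,
         background_intensity = background_intensity,
         parameters = parameters),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n  stain matrix (OD, columns H then E):\n")
  print(round(x$stain_matrix, 4))
  cat(sprintf("  max concentrations: %.4f %.4f  (I0 = %g)\n",
              x$max_concentrations[1], x$max_concentrations[2],
              x$background_intensity))
  invisible(x)
}

# exact nonnegative least squares for a 2-column design, vectorized over
# pixels: unconstrained LS first; where a coefficient is negative, compare
# the two single-column boundary fits and keep the lower-residual one.
nnls_two_col <- function(M, od) {
  # od: N x 3, M: 3 x 2 unit columns
  G <- crossprod(M)               # 2 x 2 Gram
  Gi <- solve(G)
  b <- od %*% M                   # N x 2: t(M) od per pixel
  C <- b %*% Gi                   # unconstrained LS
  neg <- C[, 1] < 0 | C[, 2] < 0
  if (any(neg)) {
    b1 <- pmax(b[neg, 1], 0) / G[1, 1]   # fit with eosin = 0
    b2 <- pmax(b[neg, 2], 0) / G[2, 2]   # fit with hematoxylin = 0
    ss <- rowSums(od[neg, , drop = FALSE]^2)
    r1 <- ss - 2 * b1 * b[neg, 1] + b1^2 * G[1, 1]
    r2 <- ss - 2 * b2 * b[neg, 2] + b2^2 * G[2, 2]
    pick1 <- r1 <= r2
    Cn <- cbind(ifelse(pick1, b1, 0), ifelse(pick1, 0, b2))
    C[neg, ] <- Cn
  }
  C
}

# fast path: plain least squares with clipping at zero
ls_clip_two_col <- function(M, od) {
  C <- od %*% M %*% solve(crossprod(M))
  C[C < 0] <- 0
  C
}

solve_concentrations <- function(M, od, method = c("nnls", "ls_clip")) {
  method <- match.arg(method)
  if (method == "nnls") nnls_two_col(M, od) else ls_clip_two_col(M, od)
}

#' Estimate a stain model by the Macenko method
#'
#' Tissue pixels (all OD channels above `od_threshold`) are projected onto
#' the top-2 principal plane of their OD cloud; the hematoxylin and eosin
#' vectors are the directions at the extreme percentile angles of the
#' projected cloud, sign-fixed to nonnegative entries and unit-normalized.
#' Column 1 is the blue-dominant (hematoxylin) vector. Concentrations are
#' solved by nonnegative least squares; `max_concentrations` is the
#' per-stain 99th percentile over tissue pixels.
#'
#' @param pixels H x W x 3 array in \[0, 1\] (or an N x 3 OD-ready matrix
#'   is not accepted -- pass pixels).
#' @param od_threshold Tissue mask OD threshold beta (default 0.15).
#' @param angle_percentile Alpha: extreme angles at the alpha-th and
#'   (100-alpha)-th percentiles (default 1).
#' @param background_intensity Background intensity I0 (default 1.0).
#' @param concentration_method `"nnls"` (default, exact for two stains) or
#'   `"ls_clip"` (plain least squares clipped at 0).
#' @return A `stain_model`.
#' @export
estimate_stains <- function(pixels, od_threshold = 0.15,
                            angle_percentile = 1,
                            background_intensity = 1.0,
                            concentration_method = c("nnls", "ls_clip")) {
  concentration_method <- match.arg(concentration_method)
  od <- rgb_to_od(pixels, background_intensity)
  odm <- matrix(od, ncol = 3)
  tissue <- odm[odm[, 1] > od_threshold & odm[, 2] > od_threshold &
                odm[, 3] > od_threshold, , drop = FALSE]
  if (nrow(tissue) < 2) {
    stop("degenerate input: fewer than 2 tissue pixels above the OD ",
         "threshold (is the image all background?)")
  }
  eig <- eigen(stats::cov(tissue), symmetric = TRUE)
  if (eig$values[2] <= max(eig$values[1], 1) * 1e-9) {
    stop("degenerate OD cloud: rank 1 (single stain); cannot resolve two ",
         "stain vectors")
  }
  V <- eig$vectors[, 1:2]
  V[, colSums(V) < 0] <- -V[, colSums(V) < 0]
  proj <- tissue %*% V
  ang <- atan2(proj[, 2], proj[, 1])
  qa <- stats::quantile(ang, probs = c(angle_percentile / 100,
                                       1 - angle_percentile / 100),
                        names = FALSE)
  vecs <- sapply(qa, function(a) V %*% c(cos(a), sin(a)))
  vecs[vecs < 0] <- 0
  norms <- sqrt(colSums(vecs^2))
  if (any(norms == 0)) stop("degenerate stain direction (zero vector)")
  vecs <- sweep(vecs, 2, norms, "/")
  # hematoxylin is blue-dominant: larger blue-to-red OD ratio
  blue_red <- vecs[3, ] / pmax(vecs[1, ], 1e-12)
  if (blue_red[2] > blue_red[1]) vecs <- vecs[, 2:1]
  conc <- solve_concentrations(vecs, tissue, concentration_method)
  maxc <- pmax(apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE),
               1e-6)
  new_stain_model(vecs, maxc, background_intensity,
                  parameters = list(od_threshold = od_threshold,
                                    angle_percentile = angle_percentile,
                                    concentration_method =
                                      concentration_method))
}

# concentrations for every pixel of an image under a given stain matrix
image_concentrations <- function(pixels, model,
                                 method = "nnls") {
  od <- rgb_to_od(pixels, model$background_intensity)
  solve_concentrations(model$stain_matrix, matrix(od, ncol = 3), method)
}

#' Normalize a patch into a template's stain space
#'
#' Estimates the patch's own stain model, rescales each stain's
#' concentrations by `template$max_concentrations / source$max_concentrations`
#' and reconstructs the pixels through the template stain matrix, mapping the
#' patch into the template's color space.
#'
#' @param patch A `patch_record` (or `image_record`).
#' @param template A `stain_model` (the template patch's model, from
#'   [estimate_stains()]).
#' @param od_threshold,angle_percentile,concentration_method Passed to
#'   [estimate_stains()] for the source model.
#' @param on_degenerate `"error"` (default) or `"passthrough"`: what to do
#'   when the patch's stains cannot be estimated.
#' @return The patch with normalized pixels; label and coordinates preserved.
#' @export
normalize_to_template <- function(patch, template,
                                  od_threshold = 0.15,
                                  angle_percentile = 1,
                                  concentration_method = "nnls",
                                  on_degenerate = c("error", "passthrough")) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(inherits(template, "stain_model"))
  id <- if (!is.null(patch$patch_id)) patch$patch_id else patch$image_id
  source <- tryCatch(
    estimate_stains(patch$pixels, od_threshold, angle_percentile,
                    template$background_intensity, concentration_method),
    error = function(e) {
      if (on_degenerate == "passthrough") NULL
      else stop("stain estimation failed for patch '", id, "': ",
                conditionMessage(e))
    }
  )
  if (is.null(source)) return(patch)
  conc <- image_concentrations(patch$pixels, source, concentration_method)
  conc <- sweep(conc, 2,
                template$max_concentrations / source$max_concentrations, "*")
  od_new <- conc %*% t(template$stain_matrix)
  d <- dim(patch$pixels)
  patch$pixels <- od_to_rgb(array(od_new, dim = d),
                            template$background_intensity)
  patch
}

#' Reconstruct single-stain separation images
#'
#' Rebuilds an image from one concentration channel at a time (hematoxylin
#' only / eosin only), as used to visualise stain unmixing.
#'
#' @param pixels H x W x 3 array in \[0, 1\].
#' @param model A `stain_model` for the image.
#' @return List with `hematoxylin` and `eosin` H x W x 3 arrays.
#' @export
stain_separation <- function(pixels, model) {
  conc <- image_concentrations(pixels, model)
  d <- dim(pixels)
  out <- lapply(1:2, function(s) {
    od <- conc[, s, drop = FALSE] %*% t(model$stain_matrix[, s, drop = FALSE])
    od_to_rgb(array(od, dim = d), model$background_intensity)
  })
  names(out) <- c("hematoxylin", "eosin")
  out
}

#' Persist / restore a stain model as JSON
#'
#' @param model A `stain_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_stain_model` returns the model.
#' @export
write_stain_model <- function(model, path) {
  jsonlite::write_json(
    list(hematoxylin = model$stain_matrix[, 1],
         eosin = model$stain_matrix[, 2],
         max_concentrations = model$max_concentrations,
         background_intensity = model$background_intensity,
         parameters = model$parameters),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- cbind(as.numeric(x$hematoxylin), as.numeric(x$eosin))
  new_stain_model(m, as.numeric(x$max_concentrations),
                  as.numeric(x$background_intensity),
                  as.list(x$parameters))
}
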