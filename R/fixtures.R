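#' Specify a synthetic H&E fixture dataset
#'
#' Fixture images emulate hematoxylin-and-eosin histology through a two-stain
#' Beer-Lambert mixture: pixel = background * 10^(-M C) + noise, where M is a
#' known 3x2 unit-column stain matrix in optical-density space and C holds two
#' nonnegative concentration fields. The hematoxylin field is a sum of
#' Gaussian "nuclei" blobs whose density increases strictly across the four
#' classes (normal < benign < in situ < invasive), so the classes are
#' separable by construction; the eosin field is a smooth low-frequency
#' texture with near-zero regions so near-pure pixels of both stains exist and
#' stain-vector recovery is checkable against ground truth.
#'
#' @param n_per_class Images per class.
#' @param height,width Image size in pixels. The reference geometry is
#'   1536 x 2048; `profile = "small"` selects a fast 512 x 1024 profile.
#' @param profile `"reference"` or `"small"` size preset; explicit
#'   `height`/`width` win.
#' @param stain_matrix_truth 3x2 matrix of unit, non-collinear stain columns
#'   (column 1 hematoxylin, column 2 eosin) in OD space.
#' @param nuclei_density Named per-class expected nuclei count per 512x512
#'   tile; must be strictly increasing in canonical class order.
#' @param blob_radius Length-2 range (pixels) of nuclei Gaussian sd.
#' @param blob_amplitude Length-2 range of nuclei peak hematoxylin
#'   concentration.
#' @param noise_sd Gaussian pixel noise sd (0 disables noise).
#' @param heterogeneous If `TRUE`, cancerous-class blobs are confined to a
#'   random sub-region so some patches of a cancerous image look normal
#'   (label-noise regime).
#' @param seed Integer seed; rendering is deterministic given
#'   (seed, label, index).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_class = 100L,
                         height = NULL, width = NULL,
                         profile = c("reference", "small"),
                         stain_matrix_truth = default_stain_matrix(),
                         nuclei_density = c(normal = 12, benign = 48,
                                            insitu = 110, invasive = 200),
                         blob_radius = c(5, 9),
                         blob_amplitude = c(1.8, 3.0),
                         noise_sd = 0,
                         heterogeneous = FALSE,
                         seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(height)) height <- if (profile == "small") 512L else 1536L
  if (is.null(width)) width <- if (profile == "small") 1024L else 2048L
  M <- stain_matrix_truth
  stopifnot(is.matrix(M), dim(M) == c(3, 2))
  norms <- sqrt(colSums(M^2))
  if (any(abs(norms - 1) > 1e-6)) stop("stain matrix columns must be unit-norm")
  if (abs(sum(M[, 1] * M[, 2])) > 1 - 1e-6) {
    stop("stain matrix columns must be non-collinear")
  }
  dens <- nuclei_density[histo_classes()]
  if (anyNA(dens) || any(diff(dens) <= 0)) {
    stop("nuclei_density must cover all classes and be strictly increasing ",
         "in canonical class order")
  }
  structure(list(
    n_per_class = as.integer(n_per_class), height = as.integer(height),
    width = as.integer(width), stain_matrix_truth = M,
    nuclei_density = dens, blob_radius = blob_radius,
    blob_amplitude = blob_amplitude, noise_sd = noise_sd,
    heterogeneous = isTRUE(heterogeneous), seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Default ground-truth stain matrix for fixtures
#'
#' Unit-norm OD vectors close to standard H&E: hematoxylin blue-dominant,
#' eosin green/red with all entries comfortably above the tissue OD
#' threshold so pure-eosin pixels survive Macenko's tissue mask.
#'
#' @return 3x2 matrix, columns hematoxylin then eosin.
#' @export
default_stain_matrix <- function() {
  m <- cbind(h = c(0.42, 0.60, 0.68), e = c(0.55, 0.75, 0.35))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# deterministic per-image seed from (spec seed, label, index)
fixture_image_seed <- function(seed, label, index) {
  as.integer((abs(seed) %% 100000L * 7919 + class_index(label) * 4217 +
              index * 131) %% 2147483647)
}

# sum-of-Gaussian-blobs field; each blob added over a +-3 sd window
blob_field <- function(height, width, centers_y, centers_x, radii, amps) {
  field <- matrix(0, height, width)
  for (b in seq_along(centers_y)) {
    r <- radii[b]
    half <- ceiling(3 * r)
    y0 <- max(1L, floor(centers_y[b] - half))
    y1 <- min(height, ceiling(centers_y[b] + half))
    x0 <- max(1L, floor(centers_x[b] - half))
    x1 <- min(width, ceiling(centers_x[b] + half))
    if (y0 > y1 || x0 > x1) next
    gy <- exp(-((y0:y1 - centers_y[b])^2) / (2 * r^2))
    gx <- exp(-((x0:x1 - centers_x[b])^2) / (2 * r^2))
    field[y0:y1, x0:x1] <- field[y0:y1, x0:x1] + amps[b] * outer(gy, gx)
  }
  field
}

# smooth eosin texture: low base + a few broad positive Gaussians. The
# field is rescaled to a fixed spatial mean so that eosin mass is constant
# across images: class signal is carried solely by nuclei density, while
# the spatial variation (including near-zero regions) needed for
# stain-vector estimation is preserved.
eosin_field <- function(height, width, n_bumps = 6, mean_mass = 0.30) {
  base <- 0.10
  cy <- stats::runif(n_bumps, 1, height)
  cx <- stats::runif(n_bumps, 1, width)
  sd <- stats::runif(n_bumps, min(height, width) / 6, min(height, width) / 3)
  amp <- stats::runif(n_bumps, 0.25, 0.45)
  f <- matrix(base, height, width)
  for (b in seq_len(n_bumps)) {
    gy <- exp(-((seq_len(height) - cy[b])^2) / (2 * sd[b]^2))
    gx <- exp(-((seq_len(width) - cx[b])^2) / (2 * sd[b]^2))
    f <- f + amp[b] * outer(gy, gx)
  }
  f * (mean_mass / mean(f))
}

#' Render one synthetic H&E image
#'
#' Deterministic given `(spec$seed, label, index)`.
#'
#' @param label Class label.
#' @param spec A [fixture_spec()].
#' @param index Image index within its class (1-based).
#' @return An `image_record` with pixels in \[0, 1\] and
#'   `split = "unassigned"`. The per-image ground truth (stain matrix and
#'   concentration fields) is attached as attribute `"truth"`.
#' @export
render_fixture_image <- function(label, spec, index = 1L) {
  label <- match.arg(label, histo_classes())
  h <- spec$height; w <- spec$width
  with_seed(fixture_image_seed(spec$seed, label, index), {
    tiles <- (h / 512) * (w / 512)
    n_nuclei <- max(1L, round(spec$nuclei_density[[label]] * tiles *
                                stats::runif(1, 0.9, 1.1)))
    if (spec$heterogeneous && label %in% cancerous_classes()) {
      # confine lesion blobs to a random half of the image
      y_rng <- sort(stats::runif(2, 1, h)); x_rng <- c(1, w)
      if (diff(y_rng) < h / 3) y_rng <- c(1, h / 2)
      cy <- stats::runif(n_nuclei, y_rng[1], y_rng[2])
      cx <- stats::runif(n_nuclei, x_rng[1], x_rng[2])
    } else {
      cy <- stats::runif(n_nuclei, 1, h)
      cx <- stats::runif(n_nuclei, 1, w)
    }
    radii <- stats::runif(n_nuclei, spec$blob_radius[1], spec$blob_radius[2])
    amps <- stats::runif(n_nuclei, spec$blob_amplitude[1],
                         spec$blob_amplitude[2])
    c_h <- blob_field(h, w, cy, cx, radii, amps)
    c_e <- eosin_field(h, w)
    M <- spec$stain_matrix_truth
    pixels <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od <- M[ch, 1] * c_h + M[ch, 2] * c_e
      pixels[, , ch] <- 10^(-od)
    }
    if (spec$noise_sd > 0) {
      pixels <- pixels + stats::rnorm(length(pixels), sd = spec$noise_sd)
    }
    pixels[pixels < 0] <- 0
    pixels[pixels > 1] <- 1
    rec <- new_image_record(sprintf("%s_%03d", label, index), pixels, label)
    attr(rec, "truth") <- list(stain_matrix = M, hematoxylin = c_h,
                               eosin = c_e)
    rec
  })
}

#' Generate a labelled fixture dataset
#'
#' @param spec A [fixture_spec()].
#' @return List of `4 * n_per_class` `image_record`s, `n_per_class` per
#'   class, ids encoding label and index.
#' @export
make_fixture_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$n_per_class >= 1)
  recs <- list()
  for (label in histo_classes()) {
    for (i in seq_len(spec$n_per_class)) {
      recs[[length(recs) + 1]] <- render_fixture_image(label, spec, i)
    }
  }
  recs
}

#' Write a fixture dataset to disk as TIFFs plus a manifest
#'
#' @param records List of `image_record`s (e.g. from
#'   [make_fixture_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_fixture_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    paths[i] <- file.path(dir, paste0(records[[i]]$image_id, ".tiff"))
    tiff::writeTIFF(records[[i]]$pixels, paths[i], bits.per.sample = 8L)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(path = basename(paths),
               label = vapply(records, function(r) r$label, character(1))),
    manifest, row.names = FALSE
  )
  invisible(manifest)
}
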