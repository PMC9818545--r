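#' Load a labelled histology image
#'
#' Reads an RGB raster (TIFF or PNG, 8- or 16-bit) and scales pixel values to
#' the unit interval. 8-bit rasters are divided by 255; the readers used here
#' already return values on [0, 1], so a value of 51 in an 8-bit file arrives
#' as 0.2.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param label Class label, one of [histo_classes()].
#' @param image_id Identifier for the record; defaults to the file name
#'   without extension.
#' @return An `image_record`: a list with fields `image_id`, `pixels`
#'   (H x W x 3 array in \[0, 1\]), `label` and `split` (initially
#'   `"unassigned"`).
#' @export
load_image <- function(path, label, image_id = NULL) {
  label <- match.arg(label, histo_classes())
  if (!file.exists(path)) {
    stop("cannot read image, file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported raster format '.", ext, "' for: ", path)
  )
  if (length(dim(pixels)) == 3 && dim(pixels)[3] == 4) {
    pixels <- pixels[, , 1:3, drop = FALSE] # drop alpha
  }
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("not a 3-channel RGB raster: ", path)
  }
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  new_image_record(image_id, pixels, label)
}

new_image_record <- function(image_id, pixels, label,
                             split = "unassigned") {
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         label = label, split = split),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record %s: %dx%dx%d, label=%s, split=%s>\n",
              x$image_id, d[1], d[2], d[3], x$label, x$split))
  invisible(x)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `path,label` defining a labelled image
#' collection. Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns `path` (absolute) and `label`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m))) {
    stop("manifest must have columns 'path' and 'label': ", path)
  }
  bad <- setdiff(unique(m$label), histo_classes())
  if (length(bad) > 0) {
    stop("manifest contains unknown labels: ", paste(bad, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(normalizePath(path)), m$path[rel])
  m[, c("path", "label")]
}

#' Load all images named by a manifest
#'
#' @param manifest Path to a manifest CSV, or a data.frame as returned by
#'   [read_manifest()].
#' @return List of `image_record`s in manifest order.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    load_image(manifest$path[i], manifest$label[i])
  })
}

#' Specify a train/validation/test split
#'
#' @param train_fraction,validation_fraction,test_fraction Nonnegative
#'   fractions summing to 1. Defaults 0.65 / 0.15 / 0.20.
#' @param seed Integer seed making the split deterministic.
#' @param stratified Stratify by class (default `TRUE`), preserving class
#'   balance within each split.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.65, validation_fraction = 0.15,
                       test_fraction = 0.20, seed = 1L, stratified = TRUE) {
  f <- c(train_fraction, validation_fraction, test_fraction)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop("split fractions must be nonnegative and sum to 1")
  }
  structure(list(train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# largest-remainder apportionment of n into parts proportional to fractions;
# ties broken in argument order (train first)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test splits
#'
#' Deterministic given the spec's seed. With stratification each class is
#' apportioned independently by largest remainder, so split sizes match the
#' fractions to within one record per class.
#'
#' @param records List of `image_record`s.
#' @param spec A [split_spec()].
#' @return The records with `split` set; a partition of the input.
#' @export
make_splits <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- vapply(records, function(r) r$label, character(1))
  fractions <- c(spec$train_fraction, spec$validation_fraction,
                 spec$test_fraction)
  names(fractions) <- c("train", "validation", "test")
  groups <- if (spec$stratified) split(seq_along(records), labels)
            else list(all = seq_along(records))
  if (spec$stratified && any(lengths(groups) == 0)) {
    stop("stratified split needs at least one record per class present")
  }
  assignment <- character(length(records))
  with_seed(spec$seed, {
    for (idx in groups) {
      sizes <- apportion(length(idx), fractions)
      shuffled <- idx[sample.int(length(idx))]
      assignment[shuffled] <- rep(names(fractions), times = sizes)
    }
  })
  for (i in seq_along(records)) records[[i]]$split <- assignment[i]
  records
}

#' Merge the validation split into the training split
#'
#' Used before the image-level stage: every validation record is re-labelled
#' as training, test records are untouched, and the record count is conserved.
#'
#' @param records List of split-assigned `image_record`s.
#' @return The records with `split == "validation"` changed to `"train"`.
#' @export
merge_validation_into_train <- function(records) {
  lapply(records, function(r) {
    if (identical(r$split, "validation")) r$split <- "train"
    r
  })
}

#' Persist a split assignment
#'
#' Writes `image_id,label,split` rows so a split can be re-used exactly.
#'
#' @param records Split-assigned records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(records, path) {
  df <- data.frame(
    image_id = vapply(records, function(r) r$image_id, character(1)),
    label = vapply(records, function(r) r$label, character(1)),
    split = vapply(records, function(r) r$split, character(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
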