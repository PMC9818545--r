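# End-to-end orchestration: split -> patch -> stain-normalize -> train
# head(s) -> extract + concatenate features -> classifier bank -> fusion ->
# frequency arrays -> 2-class net -> probability weighting -> 4-class net ->
# evaluation. fit_pipeline() returns a fitted S3 object with print / summary
# / predict methods.

#' Pipeline configuration
#'
#' Aggregates every stage's parameters with the reference defaults:
#' 65/15/20 stratified split, 512/256 patch geometry, Macenko beta 0.15 and
#' alpha 1, flip/rotate/translate augmentation, lr0 0.008 with
#' lr <- lr/(1+decay) decay, Adam beta 0.8/0.99, dropout 0.4, 64-unit dense
#' layer, early-stop patience 5, average fusion rule. All stage seeds derive
#' deterministically from the single global `seed`.
#'
#' @param seed Global seed.
#' @param split List: `train`, `validation`, `test` fractions.
#' @param patch List: `size`, `stride` in pixels.
#' @param stain List: `enabled`, `mode` (`"image"` normalizes each image
#'   once before patching -- the default, since per-patch stain statistics
#'   are noisy when nuclei are sparse -- or `"patch"` for per-patch
#'   normalization), `beta` (OD threshold), `alpha` (angle percentile),
#'   `concentration_method`, `on_degenerate` (`"passthrough"` keeps
#'   un-normalizable inputs unchanged).
#' @param augment List: `enabled`, `k` offline copies per training patch,
#'   plus [augment_spec()] fields.
#' @param backbones Character vector of backbone names (see
#'   [resolve_backbones()]) or list of [backbone()] objects.
#' @param head List: `n_kernels`, `n_hidden`.
#' @param patch_train [train_config()] for the fine-tuning head.
#' @param image_train [train_config()] for the two image-stage networks
#'   (more epochs: the networks are tiny and their inputs nearly one-hot,
#'   so they need a longer schedule at the same lr0).
#' @param ensemble_rule `"average"`, `"product"` or `"maximum"`.
#' @param bank_hyper Classifier hyperparameter overrides (see [fit_bank()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            split = list(train = 0.65, validation = 0.15,
                                         test = 0.20),
                            patch = list(size = 512L, stride = 256L),
                            stain = list(enabled = TRUE, mode = "image",
                                         beta = 0.15, alpha = 1,
                                         concentration_method = "nnls",
                                         on_degenerate = "passthrough"),
                            augment = list(enabled = TRUE, k = 1L,
                                           p_hflip = 0.5, p_vflip = 0.5,
                                           max_rotation_degrees = 15,
                                           max_translation_fraction = 0.1,
                                           fill_mode = "reflect"),
                            backbones = "tiny",
                            head = list(n_kernels = 512L, n_hidden = 64L),
                            patch_train = train_config(),
                            image_train = train_config(max_epochs = 400L),
                            ensemble_rule = "average",
                            bank_hyper = list()) {
  structure(list(seed = as.integer(seed), split = split, patch = patch,
                 stain = stain, augment = augment, backbones = backbones,
                 head = head, patch_train = patch_train,
                 image_train = image_train, ensemble_rule = ensemble_rule,
                 bank_hyper = bank_hyper),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly for configurations built from plain values
#' (backbone objects cannot be serialized and must be re-resolved by name).
#'
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @return `path` invisibly; `read_pipeline_config` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    seed = x$seed, split = x$split, patch = x$patch, stain = x$stain,
    augment = x$augment, backbones = unlist(x$backbones), head = x$head,
    patch_train = do.call(train_config, x$patch_train),
    image_train = do.call(train_config, x$image_train),
    ensemble_rule = x$ensemble_rule,
    bank_hyper = if (is.null(x$bank_hyper)) list() else x$bank_hyper
  )
}

# normalize + (optionally) augment + embed the patches of one image;
# returns per-backbone maps and patch metadata
process_image_patches <- function(record, config, template, backbones,
                                  augment_train = FALSE) {
  stain_on <- isTRUE(config$stain$enabled) && !is.null(template)
  image_mode <- stain_on && identical(config$stain$mode, "image")
  if (image_mode) {
    record <- normalize_to_template(
      record, template, od_threshold = config$stain$beta,
      angle_percentile = config$stain$alpha,
      concentration_method = config$stain$concentration_method,
      on_degenerate = config$stain$on_degenerate
    )
  }
  patches <- extract_patches(record, config$patch$size, config$patch$stride)
  aspec <- do.call(augment_spec,
                   c(config$augment[setdiff(names(config$augment),
                                            c("enabled", "k"))],
                     list(seed = derive_seed(config$seed, 21L))))
  k_aug <- if (augment_train && isTRUE(config$augment$enabled))
             as.integer(config$augment$k) else 0L
  out <- list()
  for (p in patches) {
    if (stain_on && !image_mode) {
      p <- normalize_to_template(
        p, template, od_threshold = config$stain$beta,
        angle_percentile = config$stain$alpha,
        concentration_method = config$stain$concentration_method,
        on_degenerate = config$stain$on_degenerate
      )
    }
    variants <- list(p)
    if (k_aug > 0) {
      for (j in seq_len(k_aug)) {
        a <- augment_patch(p, aspec,
                           seed = derive_seed(config$seed,
                                              1000L + j * 131L +
                                                p$row * 7L + p$col))
        a$patch_id <- paste0(a$patch_id, "_aug", j)
        out_aug <- a
        variants[[length(variants) + 1]] <- out_aug
      }
    }
    for (v in variants) {
      out[[length(out) + 1]] <- list(
        patch_id = v$patch_id, parent_id = v$parent_id, row = v$row,
        col = v$col, label = v$label,
        augmented = !identical(v$patch_id, p$patch_id),
        pre = lapply(backbones, function(bb) backbone_precompute(bb,
                                                                v$pixels))
      )
    }
  }
  out
}

# per-patch cached representation: the downsampled conv input plus pooling
# branch for trainable tiny backbones, the frozen embedding otherwise
backbone_precompute <- function(bb, pixels) {
  if (isTRUE(bb$trainable)) {
    tiny_precompute(pixels, bb$downsample, bb$conv_channels)
  } else {
    list(map = bb$embed(pixels))
  }
}

backbone_map <- function(bb, pre) {
  if (!is.null(pre$map)) pre$map
  else tiny_map(pre, bb$weights, bb$conv_channels)
}

#' Fit the full patch-to-image classification pipeline
#'
#' Executes every stage on a labelled image collection and returns a fitted
#' pipeline object. Splits are assigned (unless the records already carry
#' them), the stain template is the first patch of the first training image,
#' heads are trained per backbone on (augmented) training patches with
#' validation-based early stopping, the classifier bank is fitted on
#' concatenated GAP features, patch probabilities are fused with the
#' configured rule, the validation split is merged into training for the
#' image stage, and the two-stage frequency-array networks are trained.
#'
#' @param records List of `image_record`s (e.g. [load_dataset()] or
#'   [make_fixture_dataset()] output).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, artifacts (split CSV,
#'   template stain model JSON, training histories, patch and image
#'   prediction CSVs, metric reports) are written under it.
#' @param verbose Print one line per stage.
#' @return A `histopatch_pipeline` object; see [predict.histopatch_pipeline()].
#' @export
fit_pipeline <- function(records, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  # ---- split ----
  has_splits <- all(vapply(records, function(r) r$split != "unassigned",
                           logical(1)))
  if (!has_splits) {
    records <- make_splits(records, split_spec(
      config$split$train, config$split$validation, config$split$test,
      seed = derive_seed(config$seed, 1L)
    ))
  }
  splits <- vapply(records, function(r) r$split, character(1))
  labels <- vapply(records, function(r) r$label, character(1))
  ids <- vapply(records, function(r) r$image_id, character(1))
  say("split: %d train / %d validation / %d test",
      sum(splits == "train"), sum(splits == "validation"),
      sum(splits == "test"))
  # ---- stain template: first patch of the first training image ----
  template <- NULL
  if (isTRUE(config$stain$enabled)) {
    first_train <- which(splits == "train")[1]
    tp <- extract_patches(records[[first_train]], config$patch$size,
                          config$patch$stride)[[1]]
    template <- estimate_stains(tp$pixels, config$stain$beta,
                                config$stain$alpha,
                                concentration_method =
                                  config$stain$concentration_method)
    say("stain template from image %s", ids[first_train])
  }
  # ---- per-image patch processing + embedding ----
  backbones <- resolve_backbones(config$backbones,
                                 seed = derive_seed(config$seed, 2L))
  per_image <- vector("list", length(records))
  for (i in seq_along(records)) {
    per_image[[i]] <- process_image_patches(
      records[[i]], config, template, backbones,
      augment_train = splits[i] == "train"
    )
  }
  say("patched %d images (%d patch instances)", length(records),
      sum(lengths(per_image)))
  # ---- flatten ----
  flat <- unlist(per_image, recursive = FALSE)
  flat_split <- rep(splits, lengths(per_image))
  flat_aug <- vapply(flat, `[[`, logical(1), "augmented")
  flat_label <- vapply(flat, `[[`, character(1), "label")
  is_fit <- flat_split == "train"               # originals + augmented
  is_orig <- !flat_aug
  # ---- train heads per backbone ----
  heads <- vector("list", length(backbones))
  histories <- vector("list", length(backbones))
  for (b in seq_along(backbones)) {
    head0 <- fine_tune_head(backbones[[b]]$channels,
                            n_kernels = config$head$n_kernels,
                            n_hidden = config$head$n_hidden,
                            seed = derive_seed(config$seed, 30L + b))
    cfg_b <- config$patch_train
    cfg_b$seed <- derive_seed(config$seed, 40L + b)
    has_val <- any(flat_split == "validation")
    if (isTRUE(backbones[[b]]$trainable)) {
      fit <- train_head_joint(
        backbones[[b]], head0,
        pre_list = lapply(flat[is_fit], function(f) f$pre[[b]]),
        labels = flat_label[is_fit],
        val_pre = if (has_val)
          lapply(flat[flat_split == "validation"], function(f) f$pre[[b]]),
        val_labels = flat_label[flat_split == "validation"],
        cfg = cfg_b
      )
      backbones[[b]] <- fit$backbone
    } else {
      fit <- train_head_maps(
        head0,
        maps = lapply(flat[is_fit], function(f) f$pre[[b]]$map),
        labels = flat_label[is_fit],
        val_maps = if (has_val)
          lapply(flat[flat_split == "validation"],
                 function(f) f$pre[[b]]$map),
        val_labels = flat_label[flat_split == "validation"],
        cfg = cfg_b
      )
    }
    heads[[b]] <- fit$head
    histories[[b]] <- fit$history
    say("head %d/%d (%s): %d epochs, final train acc %.3f", b,
        length(backbones), backbones[[b]]$name, nrow(fit$history),
        fit$history$train_acc[nrow(fit$history)])
  }
  # ---- features ----
  feat_of <- function(sel) {
    do.call(cbind, lapply(seq_along(backbones), function(b) {
      features_from_maps(heads[[b]], lapply(flat[sel], function(f) {
        backbone_map(backbones[[b]], f$pre[[b]])
      }))
    }))
  }
  fit_features <- feat_of(is_fit)
  pred_features <- feat_of(is_orig)
  say("features: %d fit x %d dims, %d predict", nrow(fit_features),
      ncol(fit_features), nrow(pred_features))
  # ---- classifier bank + fusion ----
  bank <- fit_bank(fit_features, flat_label[is_fit],
                   seed = derive_seed(config$seed, 50L),
                   hyper = config$bank_hyper)
  fused <- fuse(predict_bank(bank, pred_features), config$ensemble_rule)
  patch_parent <- rep(ids, vapply(per_image, function(pp)
    sum(!vapply(pp, `[[`, logical(1), "augmented")), integer(1)))
  say("bank fitted; fused patch predictions with rule '%s'",
      config$ensemble_rule)
  # ---- image stage: merge validation into train ----
  image_split <- ifelse(splits == "validation", "train", splits)
  freqs <- lapply(ids, function(id) {
    rows <- patch_parent == id
    build_frequency_array(fused[rows, , drop = FALSE], image_ref = id)
  })
  img_train <- image_split == "train"
  cfg_img <- config$image_train
  cfg_img$seed <- derive_seed(config$seed, 60L)
  two_class <- train_two_class(
    freqs[img_train],
    labels[img_train] %in% cancerous_classes(),
    cfg_img
  )
  p_cancer <- predict_two_class(two_class, freqs)
  freqs <- Map(weight_frequency, freqs, p_cancer)
  cfg_img4 <- cfg_img
  cfg_img4$seed <- derive_seed(config$seed, 61L)
  four_class <- train_four_class(freqs[img_train], labels[img_train],
                                 cfg_img4)
  class_probs <- predict_four_class(four_class, freqs)
  say("image stage trained (2-class final acc %.3f, 4-class %.3f)",
      two_class$history$acc[nrow(two_class$history)],
      four_class$history$acc[nrow(four_class$history)])
  # ---- predictions table ----
  predictions <- data.frame(
    image_id = ids, label = labels, split = splits,
    p_cancer = p_cancer,
    p_normal = class_probs[, 1], p_benign = class_probs[, 2],
    p_insitu = class_probs[, 3], p_invasive = class_probs[, 4],
    pred4 = predicted_classes(class_probs),
    pred2 = ifelse(p_cancer > 0.5, "cancerous", "noncancerous"),
    stringsAsFactors = FALSE
  )
  # ---- evaluation on the test split ----
  evaluation <- evaluate_predictions(predictions, fused, flat_label[is_orig],
                                     patch_parent, splits, ids)
  obj <- structure(list(
    config = config, template = template, backbones = backbones,
    heads = heads, histories = histories, bank = bank,
    two_class = two_class, four_class = four_class,
    predictions = predictions, frequency_arrays = freqs,
    patch_probs = fused, patch_parent = patch_parent,
    patch_labels = flat_label[is_orig],
    evaluation = evaluation,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "histopatch_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(obj, records, out_dir)
  obj
}

# test-split reports at patch level, 2-class and 4-class image level
evaluate_predictions <- function(predictions, fused, patch_labels,
                                 patch_parent, splits, ids) {
  test_ids <- ids[splits == "test"]
  out <- list()
  if (length(test_ids) > 0) {
    pt <- predictions[predictions$split == "test", ]
    out$image_4class <- metrics_report(pt$label, pt$pred4)
    bin <- c("cancerous", "noncancerous")
    out$image_2class <- metrics_report(
      ifelse(pt$label %in% cancerous_classes(), "cancerous", "noncancerous"),
      pt$pred2, classes = bin
    )
    sel <- patch_parent %in% test_ids
    out$patch <- metrics_report(patch_labels[sel],
                                predicted_classes(fused[sel, , drop = FALSE]))
  } else {
    out <- NULL
  }
  out
}

write_pipeline_artifacts <- function(obj, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_split_csv(records, file.path(out_dir, "splits.csv"))
  if (!is.null(obj$template)) {
    write_stain_model(obj$template, file.path(out_dir, "stain_template.json"))
  }
  for (b in seq_along(obj$histories)) {
    utils::write.csv(obj$histories[[b]],
                     file.path(out_dir, sprintf("history_head_%d.csv", b)),
                     row.names = FALSE)
  }
  patch_pred <- data.frame(parent_id = obj$patch_parent,
                           label = obj$patch_labels,
                           obj$patch_probs,
                           pred = predicted_classes(obj$patch_probs))
  names(patch_pred)[3:6] <- paste0("p_", histo_classes())
  utils::write.csv(patch_pred, file.path(out_dir, "patch_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(obj$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  write_pipeline_config(obj$config, file.path(out_dir, "config.yaml"))
  if (!is.null(obj$evaluation)) {
    write_metrics_report(obj$evaluation$image_4class,
                         file.path(out_dir, "report_image_4class.json"))
    write_metrics_report(obj$evaluation$image_2class,
                         file.path(out_dir, "report_image_2class.json"))
    write_metrics_report(obj$evaluation$patch,
                         file.path(out_dir, "report_patch.json"))
  }
  invisible(out_dir)
}

#' @export
print.histopatch_pipeline <- function(x, ...) {
  cat("Patch-based histopathology classification pipeline\n")
  cat(sprintf("  backbones: %s\n",
              paste(vapply(x$backbones, `[[`, character(1), "name"),
                    collapse = ", ")))
  cat(sprintf("  images: %d (%s)\n", nrow(x$predictions),
              paste(sprintf("%s=%d", names(table(x$predictions$split)),
                            table(x$predictions$split)), collapse = ", ")))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  test accuracy: 4-class %.4f, 2-class %.4f, patch %.4f\n",
                x$evaluation$image_4class$overall_accuracy,
                x$evaluation$image_2class$overall_accuracy,
                x$evaluation$patch$overall_accuracy))
  }
  cat(sprintf("  fitted in %.1f s\n", x$runtime_sec))
  invisible(x)
}

#' @export
summary.histopatch_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$evaluation)) {
    cat("\n4-class image report (test split):\n")
    print(object$evaluation$image_4class)
    cat("\n2-class image report (test split):\n")
    print(object$evaluation$image_2class)
  }
  invisible(object)
}

#' Predict image classes for new images
#'
#' Runs the fitted pipeline's inference path on new `image_record`s:
#' patching, stain normalization to the fitted template, backbone + head
#' features, classifier bank, fusion, and the two-stage aggregator.
#'
#' @param object A fitted `histopatch_pipeline`.
#' @param newdata List of `image_record`s (or a single record).
#' @param ... Unused.
#' @return Data.frame with one row per image: `image_id`, `p_cancer`,
#'   per-class probabilities, `pred4`, `pred2`.
#' @export
predict.histopatch_pipeline <- function(object, newdata, ...) {
  if (inherits(newdata, "image_record")) newdata <- list(newdata)
  config <- object$config
  rows <- lapply(newdata, function(rec) {
    pp <- process_image_patches(rec, config, object$template,
                                object$backbones, augment_train = FALSE)
    feats <- do.call(cbind, lapply(seq_along(object$backbones), function(b) {
      features_from_maps(object$heads[[b]], lapply(pp, function(f) {
        backbone_map(object$backbones[[b]], f$pre[[b]])
      }))
    }))
    fused <- fuse(predict_bank(object$bank, feats), config$ensemble_rule)
    ip <- predict_image(fused, object$two_class, object$four_class,
                        image_ref = rec$image_id)
    data.frame(image_id = rec$image_id, p_cancer = ip$cancer_probability,
               p_normal = ip$class_probs[1], p_benign = ip$class_probs[2],
               p_insitu = ip$class_probs[3], p_invasive = ip$class_probs[4],
               pred4 = ip$predicted_class, pred2 = ip$predicted_binary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
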