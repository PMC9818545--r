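random_map <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(runif(h * w * c), dim = c(h, w, c))
}

test_that("the GAP tap emits 512 features regardless of spatial geometry", {
  for (dims in list(c(6, 6, 8), c(14, 14, 16), c(9, 5, 4), c(4, 4, 2))) {
    head <- fine_tune_head(in_channels = dims[3], seed = 2)
    out <- head_forward(random_map(dims[1], dims[2], dims[3]), head)
    expect_length(out$features, 512L)
    expect_length(out$probabilities, 4L)
    expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
    expect_true(all(out$probabilities >= 0))
  }
  tiny <- fine_tune_head(in_channels = 3, n_kernels = 7, seed = 3)
  expect_length(head_forward(random_map(5, 5, 3), tiny)$features, 7L)
  # spatial map smaller than the kernel is a dimension error
  big <- fine_tune_head(in_channels = 2, seed = 4)
  expect_error(head_forward(random_map(2, 2, 2), big), "dimension error")
})

test_that("an all-zero head yields zero features and uniform probabilities", {
  head <- fine_tune_head(in_channels = 4, init = "zero")
  out <- head_forward(random_map(8, 8, 4, seed = 5), head)
  expect_true(all(out$features == 0))
  expect_equal(out$probabilities, rep(0.25, 4), tolerance = 1e-12)
})

test_that("cross-entropy and categorical accuracy match hand values", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(cross_entropy(c(0, 0, 1, 0), rep(0.25, 4)), log(4),
               tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0, 0, 0), c(0.5, 0.5, 1e-12, 1e-12)),
               log(2), tolerance = 1e-9)
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
                 c(0.1, 0.1, 0.7, 0.1), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(categorical_accuracy(c(1L, 2L, 3L, 4L), probs), 0.75)
  expect_equal(categorical_accuracy(c(1L, 2L, 3L), probs[1:3, ]), 1.0)
  expect_equal(categorical_accuracy(c(2L, 3L, 4L, 2L), probs), 0.0)
  expect_error(categorical_accuracy(integer(0), probs[0, , drop = FALSE]),
               "empty")
  # ties break to the lowest class index
  expect_equal(categorical_accuracy(1L, matrix(0.25, 1, 4)), 1.0)
})

test_that("head training learns separable fixture patches above chance", {
  imgs <- class_fixture_images()
  patches <- unlist(lapply(imgs, function(r) {
    extract_patches(r, patch = 256L, stride = 128L)
  }), recursive = FALSE)
  bb <- tiny_backbone(seed = 3, downsample = 4L)
  head <- fine_tune_head(bb$channels, seed = 6)
  fit <- train_head(bb, head, patches,
                    cfg = train_config(max_epochs = 10, seed = 4))
  expect_true(fit$head$trained)
  final_acc <- fit$history$train_acc[nrow(fit$history)]
  expect_gt(final_acc, 0.5) # far above 4-class chance (0.25)
  # learning-rate schedule: lr after one epoch is lr0 / (1 + decay)
  cfg <- train_config(lr0 = 0.008, max_epochs = 10)
  expect_equal(fit$history$lr[1], 0.008)
  expect_equal(fit$history$lr[2], 0.008 / (1 + cfg$decay), tolerance = 1e-12)
})

test_that("training histories are reproducible given the seed", {
  imgs <- class_fixture_images()[c(1, 4)]
  patches <- unlist(lapply(imgs, function(r) {
    extract_patches(r, patch = 256L, stride = 256L)
  }), recursive = FALSE)
  bb <- tiny_backbone(seed = 3, downsample = 4L)
  cfg <- train_config(max_epochs = 4, seed = 9)
  f1 <- train_head(bb, fine_tune_head(bb$channels, seed = 1), patches,
                   cfg = cfg)
  f2 <- train_head(bb, fine_tune_head(bb$channels, seed = 1), patches,
                   cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$head$params, f2$head$params)
})

test_that("feature extraction is pure, aligned, and concatenable", {
  imgs <- class_fixture_images()[1:2]
  patches <- unlist(lapply(imgs, function(r) {
    extract_patches(r, patch = 256L, stride = 256L)
  }), recursive = FALSE)
  patches <- c(patches, patches[1]) # duplicate first patch
  bb1 <- tiny_backbone(seed = 3, downsample = 4L)
  bb2 <- tiny_backbone(seed = 8, downsample = 4L)
  h1 <- fine_tune_head(bb1$channels, n_kernels = 32, seed = 2)
  h2 <- fine_tune_head(bb2$channels, n_kernels = 32, seed = 3)
  fs1 <- extract_features(bb1, h1, patches)
  fs2 <- extract_features(bb2, h2, patches)
  expect_equal(dim(fs1$values), c(length(patches), 32L))
  # duplicate patch gives identical features
  expect_identical(fs1$values[length(patches), ], fs1$values[1, ])
  # permuting inputs permutes outputs identically
  perm <- rev(seq_along(patches))
  fs1p <- extract_features(bb1, h1, patches[perm])
  expect_equal(unname(fs1p$values), unname(fs1$values[perm, ]))
  cc <- concat_features(list(fs1, fs2))
  expect_equal(ncol(cc$values), 64L)
  expect_equal(cc$source, "concat")
  expect_identical(cc$values[, 1:32], fs1$values)
  # misaligned sets refuse to concatenate
  fs_bad <- extract_features(bb2, h2, patches[perm])
  expect_error(concat_features(list(fs1, fs_bad)), "alignment")
})
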