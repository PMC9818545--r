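# Shared fixtures and memoized heavy objects for the test suite.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# light-weight image records (no pixels) for split logic tests
fake_records <- function(n_per_class) {
  recs <- list()
  for (label in histo_classes()) {
    for (i in seq_len(n_per_class)) {
      recs[[length(recs) + 1]] <- structure(
        list(image_id = sprintf("%s_%d", label, i), pixels = NULL,
             label = label, split = "unassigned"),
        class = "image_record"
      )
    }
  }
  recs
}

# one noiseless fixture image per class at the fast 512 x 1024 profile
class_fixture_images <- function() {
  memo("class_images", {
    spec <- fixture_spec(n_per_class = 1, profile = "small", seed = 7)
    lapply(histo_classes(), function(cl) render_fixture_image(cl, spec, 1))
  })
}

fixture_truth_matrix <- function() default_stain_matrix()

# separable 2-D toy features: four Gaussian clusters, one per class
toy_clusters <- function(n_per_class = 10, sd = 0.15, seed = 99) {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  set.seed(seed)
  x <- NULL; labels <- character(0)
  for (k in 1:4) {
    x <- rbind(x, cbind(rnorm(n_per_class, centers[k, 1], sd),
                        rnorm(n_per_class, centers[k, 2], sd)))
    labels <- c(labels, rep(histo_classes()[k], n_per_class))
  }
  list(x = x, labels = labels, centers = centers)
}

# the easy-mode fixture benchmark: one full pipeline fit, memoized so the
# acceptance tests share it
benchmark_records <- function() {
  memo("bench_records", {
    make_fixture_dataset(fixture_spec(n_per_class = 6, profile = "small",
                                      seed = 42))
  })
}

benchmark_pipeline <- function() {
  memo("bench_pipe", {
    fit_pipeline(benchmark_records(), pipeline_config(seed = 42))
  })
}

benchmark_pipeline_rerun <- function() {
  memo("bench_pipe2", {
    fit_pipeline(benchmark_records(), pipeline_config(seed = 42))
  })
}
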