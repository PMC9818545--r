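# build an N x 4 probability matrix whose argmax multiset matches counts
probs_from_counts <- function(counts) {
  rows <- list()
  for (c in 1:4) {
    for (i in seq_len(counts[c])) {
      v <- rep(0.1, 4); v[c] <- 0.7
      rows[[length(rows) + 1]] <- v
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- histo_classes()
  m
}

test_that("frequency arrays count argmax classes and conserve totals", {
  m <- probs_from_counts(c(28, 4, 2, 1))
  f <- build_frequency_array(m, image_ref = "img", expected_total = 35)
  expect_equal(unname(f$counts4), c(28L, 4L, 2L, 1L))
  expect_equal(unname(f$counts2), c(3L, 32L)) # (insitu+invasive, normal+benign)
  expect_equal(sum(f$counts4), f$total)
  expect_equal(sum(f$counts2), f$total)
  all_normal <- build_frequency_array(probs_from_counts(c(35, 0, 0, 0)))
  expect_equal(unname(all_normal$counts4), c(35L, 0L, 0L, 0L))
  # grouping and geometry errors
  expect_error(build_frequency_array(m, parent_ids = rep(c("a", "b"),
                                                         length.out = 35)),
               "grouping error")
  expect_error(build_frequency_array(m[1:10, ], expected_total = 35),
               "geometry error")
})

test_that("probability weighting follows the superclass attention rule", {
  f <- build_frequency_array(probs_from_counts(c(10, 10, 10, 5)))
  expect_equal(unname(weight_frequency(f, 1)$weighted4), c(0, 0, 10, 5))
  expect_equal(unname(weight_frequency(f, 0)$weighted4), c(10, 10, 0, 0))
  f2 <- build_frequency_array(probs_from_counts(c(28, 4, 2, 1)))
  expect_equal(unname(weight_frequency(f2, 0.5)$weighted4),
               c(14, 2, 1, 0.5))
  expect_error(weight_frequency(f, 1.2), "domain error")
  expect_error(weight_frequency(f, -0.1), "domain error")
  # monotonicity: weighted mass moves from non-cancerous to cancerous bins
  ps <- seq(0, 1, by = 0.05)
  w <- t(vapply(ps, function(p) weight_frequency(f2, p)$weighted4,
                numeric(4)))
  expect_true(all(diff(w[, 1]) <= 0) && all(diff(w[, 2]) <= 0))
  expect_true(all(diff(w[, 3]) >= 0) && all(diff(w[, 4]) >= 0))
})

separable_freqs <- function(n_per_class = 8, total = 35, seed = 123) {
  set.seed(seed)
  freqs <- list(); labels <- character(0)
  for (cl in 1:4) {
    for (i in seq_len(n_per_class)) {
      counts <- rep(0L, 4)
      dominant <- sample(30:33, 1)
      counts[cl] <- dominant
      rest <- total - dominant
      others <- setdiff(1:4, cl)
      split <- diff(sort(c(0, sample(0:rest, 2, replace = TRUE), rest)))
      counts[others] <- split[1:3]
      freqs[[length(freqs) + 1]] <-
        build_frequency_array(probs_from_counts(counts))
      labels <- c(labels, histo_classes()[cl])
    }
  }
  list(freqs = freqs, labels = labels)
}

test_that("the 2-class network separates cancerous count arrays", {
  sf <- separable_freqs()
  binary <- sf$labels %in% cancerous_classes()
  model <- train_two_class(sf$freqs, binary, train_config(max_epochs = 400,
                                                          seed = 5))
  p <- predict_two_class(model, sf$freqs)
  expect_gte(mean((p > 0.5) == binary), 0.95)
  # balanced arrays all map to the same probability (softmax scale quirk)
  balanced <- lapply(c(1L, 5L, 17L), function(k) {
    build_frequency_array(probs_from_counts(c(k, 0, k, 0)))
  })
  pb <- predict_two_class(model, balanced)
  expect_equal(max(pb) - min(pb), 0, tolerance = 1e-12)
  # determinism
  model2 <- train_two_class(sf$freqs, binary, train_config(max_epochs = 400,
                                                           seed = 5))
  expect_identical(model$w, model2$w)
  expect_error(train_two_class(sf$freqs, rep(TRUE, length(sf$freqs)),
                               train_config()),
               "both binary classes")
})

test_that("the 4-class network learns dominant-count arrays", {
  sf <- separable_freqs()
  binary <- sf$labels %in% cancerous_classes()
  weighted <- Map(weight_frequency, sf$freqs, ifelse(binary, 0.95, 0.05))
  cfg <- train_config(max_epochs = 400, seed = 6)
  model <- train_four_class(weighted, sf$labels, cfg)
  probs <- predict_four_class(model, weighted)
  expect_equal(rowSums(probs), rep(1, length(weighted)), tolerance = 1e-9)
  expect_gte(mean(predicted_classes(probs) == sf$labels), 0.95)
  model2 <- train_four_class(weighted, sf$labels, cfg)
  expect_identical(predict_four_class(model2, weighted), probs)
  expect_error(train_four_class(weighted[1:8], sf$labels[1:8], cfg),
               "all four classes")
  expect_error(train_four_class(sf$freqs, sf$labels, cfg), "weighted first")
})

test_that("image prediction chains the two stages consistently", {
  sf <- separable_freqs()
  binary <- sf$labels %in% cancerous_classes()
  two <- train_two_class(sf$freqs, binary, train_config(max_epochs = 400,
                                                        seed = 5))
  weighted <- Map(weight_frequency, sf$freqs,
                  predict_two_class(two, sf$freqs))
  four <- train_four_class(weighted, sf$labels,
                           train_config(max_epochs = 400, seed = 6))
  m <- probs_from_counts(c(0, 1, 2, 32)) # confidently invasive
  ip <- predict_image(m, two, four, image_ref = "x")
  expect_s3_class(ip, "image_prediction")
  expect_equal(ip$predicted_class, "invasive")
  expect_equal(ip$predicted_binary, "cancerous")
  expect_equal(ip$predicted_class,
               histo_classes()[which.max(ip$class_probs)])
  expect_equal(sum(ip$class_probs), 1, tolerance = 1e-9)
  # identical patch predictions give identical image predictions
  ip2 <- predict_image(m, two, four, image_ref = "x")
  expect_identical(ip[setdiff(names(ip), "image_ref")],
                   ip2[setdiff(names(ip2), "image_ref")])
  # oracle cancer probability confines errors within the superclass
  for (i in seq_along(sf$freqs)) {
    counts <- sf$freqs[[i]]$counts4
    oracle <- predict_image(probs_from_counts(counts), two, four,
                            p_cancer = as.numeric(binary[i]))
    same_super <- (oracle$predicted_class %in% cancerous_classes()) ==
      binary[i]
    expect_true(same_super)
  }
})

test_that("majority vote reads the dominant count bin", {
  f <- build_frequency_array(probs_from_counts(c(3, 20, 7, 5)))
  expect_equal(majority_vote_class(f), "benign")
  tie <- build_frequency_array(probs_from_counts(c(10, 10, 10, 5)))
  expect_equal(majority_vote_class(tie), "normal") # tie -> lowest index
})
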