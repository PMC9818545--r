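test_that("all five members separate the toy clusters", {
  toy <- toy_clusters()
  bank <- fit_bank(toy$x, toy$labels, seed = 7)
  expect_s3_class(bank, "classifier_bank")
  preds <- predict_bank(bank, toy$x)
  expect_named(preds, bank_members())
  for (nm in bank_members()) {
    p <- preds[[nm]]
    expect_equal(dim(p), c(nrow(toy$x), 4L))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
    acc <- mean(predicted_classes(p) == toy$labels)
    expect_gte(acc, 0.9)
  }
  # probing at the cluster centroids recovers each class for every member
  centroid_preds <- predict_bank(bank, toy$centers)
  for (nm in bank_members()) {
    expect_equal(predicted_classes(centroid_preds[[nm]]), histo_classes())
  }
})

test_that("bank fits are deterministic given the seed", {
  toy <- toy_clusters(n_per_class = 6)
  probe <- toy$x[c(1, 8, 15, 22), ]
  b1 <- fit_bank(toy$x, toy$labels, seed = 3)
  b2 <- fit_bank(toy$x, toy$labels, seed = 3)
  p1 <- predict_bank(b1, probe)
  p2 <- predict_bank(b2, probe)
  for (nm in bank_members()) expect_equal(p1[[nm]], p2[[nm]])
})

test_that("degenerate sample sizes are handled", {
  x <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5))
  labels <- histo_classes()
  bank <- fit_bank(x, labels, seed = 1) # one sample per class: k clamps to n
  preds <- predict_bank(bank, x)
  expect_equal(dim(preds$knn), c(4L, 4L))
  expect_error(fit_bank(x, rep("normal", 4), seed = 1), "at least 2 classes")
  expect_error(predict_bank(structure(list(), class = "list"), x),
               "state error")
})

test_that("fusion rules match an independent brute-force fold", {
  set.seed(31)
  n <- 100
  lists <- lapply(1:5, function(i) {
    m <- matrix(rexp(n * 4), n, 4)
    m <- m / rowSums(m)
    colnames(m) <- histo_classes()
    m
  })
  brute <- function(rule) {
    out <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      for (c in 1:4) {
        vals <- vapply(lists, function(m) m[i, c], numeric(1))
        s <- switch(rule,
                    average = sum(vals) / 5,
                    product = prod(vals),
                    maximum = max(vals))
        out[i, c] <- s
      }
      e <- exp(out[i, ] - max(out[i, ]))
      out[i, ] <- e / sum(e)
    }
    out
  }
  for (rule in c("average", "product", "maximum")) {
    fused <- fuse(lists, rule)
    expect_lt(max(abs(unname(fused) - brute(rule))), 1e-12)
  }
  expect_error(fuse(lists, "median"), "arg")
})

test_that("fusion algebra: agreement, annihilation, tie-breaking", {
  agree <- replicate(5, rbind(c(0.7, 0.2, 0.05, 0.05)), simplify = FALSE)
  for (rule in c("average", "product", "maximum")) {
    expect_equal(predicted_classes(fuse(agree, rule)), "normal")
  }
  # product rule: one member assigning 0 annihilates the class pre-softmax
  lists <- agree
  lists[[3]] <- rbind(c(0, 0.5, 0.25, 0.25))
  scores <- attr(fuse(lists, "product"), "scores")
  expect_equal(scores[1, 1], 0)
  # the worked average example: one-hot disagreement plus three uniforms
  lists <- list(rbind(c(1, 0, 0, 0)), rbind(c(0, 1, 0, 0)),
                rbind(rep(0.25, 4)), rbind(rep(0.25, 4)),
                rbind(rep(0.25, 4)))
  fused <- fuse(lists, "average")
  expect_equal(as.vector(attr(fused, "scores")),
               c(0.35, 0.35, 0.15, 0.15), tolerance = 1e-12)
  expect_equal(predicted_classes(fused), histo_classes()[1]) # tie -> lowest
})

test_that("fusion is equivariant to classifier order and competitive", {
  toy <- toy_clusters(sd = 0.9, seed = 5) # some overlap
  bank <- fit_bank(toy$x, toy$labels, seed = 2)
  preds <- predict_bank(bank, toy$x)
  for (rule in c("average", "product", "maximum")) {
    a <- fuse(preds, rule)
    b <- fuse(preds[c(4, 2, 5, 1, 3)], rule)
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
  member_acc <- vapply(preds, function(p) {
    mean(predicted_classes(p) == toy$labels)
  }, numeric(1))
  fused_acc <- mean(predicted_classes(fuse(preds, "average")) == toy$labels)
  expect_gte(fused_acc, max(member_acc) - 0.05)
})
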