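test_that("confusion matrices tally true/predicted pairs", {
  perfect <- confusion_matrix(histo_classes(), histo_classes())
  expect_equal(unname(diag(perfect)), rep(1L, 4))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  all0 <- confusion_matrix(c("normal", "benign", "insitu", "invasive"),
                           rep("normal", 4))
  expect_equal(unname(colSums(all0)), c(4L, 0L, 0L, 0L))
  # hand-listed pairs
  yt <- c("normal", "normal", "benign", "insitu", "invasive", "invasive")
  yp <- c("normal", "benign", "benign", "invasive", "invasive", "insitu")
  cm <- confusion_matrix(yt, yp)
  expect_equal(cm["normal", "normal"], 1L)
  expect_equal(cm["normal", "benign"], 1L)
  expect_equal(cm["insitu", "invasive"], 1L)
  expect_equal(cm["invasive", "insitu"], 1L)
  expect_equal(sum(cm), 6L)
  expect_error(confusion_matrix(c("normal", "weird"), c("normal", "normal")),
               "label error")
})

test_that("one-vs-rest metrics reproduce hand-tallied values", {
  perfect <- confusion_matrix(histo_classes(), histo_classes())
  for (i in 1:4) {
    expect_equal(unname(precision_recall_f1_accuracy(perfect, i)),
                 rep(1, 4))
  }
  # 2x2 matrix ((3,1),(2,4)) for class 1: TP=3, FP=2, FN=1, TN=4
  cm <- matrix(c(3, 2, 1, 4), 2, 2) # column-major: rows true
  m <- precision_recall_f1_accuracy(cm, 1)
  expect_equal(unname(m["precision"]), 0.6)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["accuracy"]), 0.7)
  # f1 from precision 0.5, recall 1.0 is 2/3
  cm2 <- matrix(c(1, 1, 0, 0), 2, 2)
  m2 <- precision_recall_f1_accuracy(cm2, 1)
  expect_equal(unname(m2["precision"]), 0.5)
  expect_equal(unname(m2["recall"]), 1.0)
  expect_equal(unname(m2["f1"]), 2 / 3, tolerance = 1e-12)
  # 0/0 convention: absent predicted class reports 0 with a warning
  cm3 <- matrix(c(0, 0, 2, 3), 2, 2)
  expect_warning(m3 <- precision_recall_f1_accuracy(cm3, 1), "undefined")
  expect_equal(unname(m3[c("precision", "recall", "f1")]), c(0, 0, 0))
})

test_that("f1 is the harmonic mean: bounded by precision and recall", {
  set.seed(77)
  for (rep in 1:25) {
    cm <- matrix(rpois(16, 4), 4, 4)
    if (sum(cm) == 0) next
    for (i in 1:4) {
      m <- suppressWarnings(precision_recall_f1_accuracy(cm, i))
      expect_lte(m["f1"], max(m["precision"], m["recall"]) + 1e-12)
      expect_gte(m["f1"], min(m["precision"], m["recall"]) - 1e-12)
      if (abs(m["precision"] - m["recall"]) < 1e-12) {
        expect_equal(unname(m["f1"]), unname(m["precision"]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("reports aggregate per-class metrics and overall accuracy", {
  yt <- c("normal", "normal", "benign", "insitu", "invasive", "invasive")
  yp <- c("normal", "benign", "benign", "invasive", "invasive", "insitu")
  rep <- suppressWarnings(metrics_report(yt, yp))
  expect_equal(rep$overall_accuracy, sum(diag(rep$confusion)) / 6)
  expect_equal(rep$n, 6L)
  expect_equal(nrow(rep$per_class), 4L)
  # binary report with custom classes
  repb <- metrics_report(c("cancerous", "noncancerous"),
                         c("cancerous", "noncancerous"),
                         classes = c("cancerous", "noncancerous"))
  expect_equal(repb$overall_accuracy, 1.0)
  path <- tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, rep$overall_accuracy)
})
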