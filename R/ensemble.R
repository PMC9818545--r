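# Patch classification: five classical classifiers over patch features, and
# the average / product / maximum probability-fusion rules.

#' Classifier names used by the bank
#' @return Character vector of member names.
#' @export
bank_members <- function() {
  c("knn", "svm", "random_forest", "adaboost", "xgboost")
}

# ---- SAMME adaptive boosting over shallow trees --------------------------
# Multiclass AdaBoost (SAMME) with depth-2 rpart trees as the weak learner
# (depth-1 stumps cannot emit all four classes).
fit_adaboost <- function(x, y, n_rounds = 200L, maxdepth = 2L) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  n <- nrow(df)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    mis <- pred != y
    err <- sum(w[mis]) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 1 - 1 / K) break
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y),
                 feature_names = setdiff(names(df), ".y")),
            class = "samme_adaboost")
}

predict_adaboost <- function(object, x) {
  df <- as.data.frame(x)
  names(df) <- object$feature_names
  K <- length(object$levels)
  scores <- matrix(0, nrow(df), K, dimnames = list(NULL, object$levels))
  for (m in seq_along(object$stumps)) {
    pred <- predict(object$stumps[[m]], df, type = "class")
    scores[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[m]
  }
  tot <- rowSums(scores)
  zero <- tot <= 0
  probs <- scores / ifelse(tot > 0, tot, 1)
  probs[zero, ] <- 1 / K
  probs
}

# --------------------------------------------------------------------------

#' Fit the five-classifier bank on patch features
#'
#' Members: k-nearest neighbours (class-proportion probabilities, k clamped
#' to the training size), probability-calibrated RBF support-vector machine,
#' random forest, SAMME adaptive boosting over decision stumps, and
#' gradient-boosted trees. All members emit 4-class probability vectors in
#' the canonical class order; all seeds derive from `seed`.
#'
#' @param features A `feature_set` (from [extract_features()] /
#'   [concat_features()]) or a numeric matrix.
#' @param labels Class labels (required when `features` is a matrix).
#' @param seed Integer seed.
#' @param hyper Optional overrides: `k` (neighbours, default 5), `n_trees`
#'   (forest and boosted members, default 200), `xgb_depth` (default 3),
#'   `xgb_eta` (default 0.3).
#' @return A `classifier_bank`.
#' @export
fit_bank <- function(features, labels = NULL, seed = 1L, hyper = list()) {
  if (inherits(features, "feature_set")) {
    labels <- if (is.null(labels)) features$labels else labels
    x <- features$values
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) stop("labels are required")
  if (nrow(x) != length(labels)) stop("features and labels are misaligned")
  present <- intersect(histo_classes(), unique(labels))
  if (length(present) < 2) {
    stop("data error: need at least 2 classes to fit the bank, got ",
         length(present))
  }
  y <- factor(labels, levels = present)
  h <- utils::modifyList(list(k = 5L, n_trees = 200L, xgb_depth = 3L,
                              xgb_eta = 0.3), hyper)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  # standardize features once for all members (distance- and kernel-based
  # members need comparable scales; tree members are scale-invariant)
  scaler <- list(center = colMeans(x),
                 scale = pmax(apply(x, 2, stats::sd), 1e-8))
  x <- sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
  members <- list()
  with_seed(derive_seed(seed, 11L), {
    members$knn <- caret::knn3(x, y, k = min(h$k, nrow(x)))
  })
  with_seed(derive_seed(seed, 12L), {
    members$svm <- tryCatch(
      e1071::svm(x, y, kernel = "radial", probability = TRUE, scale = FALSE),
      error = function(e) e1071::svm(x, y, kernel = "radial", scale = FALSE)
    )
  })
  with_seed(derive_seed(seed, 13L), {
    members$random_forest <- randomForest::randomForest(x, y,
                                                        ntree = h$n_trees)
  })
  with_seed(derive_seed(seed, 14L), {
    members$adaboost <- fit_adaboost(x, y, n_rounds = h$n_trees)
  })
  with_seed(derive_seed(seed, 15L), {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                   nthread = 1L)
    members$xgboost <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = h$xgb_depth, eta = h$xgb_eta, nthread = 1L,
                    seed = derive_seed(seed, 15L)),
      data = dtrain, nrounds = h$n_trees, verbose = 0
    )
  })
  structure(list(members = members, classes = present,
                 feature_names = colnames(x), scaler = scaler,
                 seed = as.integer(seed), hyper = h),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat(sprintf("<classifier_bank: %s; classes %s>\n",
              paste(bank_members(), collapse = ", "),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

# expand a probability matrix over bank classes to the canonical 4 classes
expand_to_canonical <- function(probs, classes) {
  out <- matrix(0, nrow(probs), 4L,
                dimnames = list(NULL, histo_classes()))
  out[, classes] <- probs[, classes, drop = FALSE]
  out
}

#' Per-classifier patch probabilities
#'
#' @param bank A fitted [fit_bank()] result.
#' @param features A `feature_set` or numeric matrix aligned with the bank's
#'   feature space.
#' @return Named list (one element per member of [bank_members()]) of
#'   N x 4 probability matrices in canonical class order, rows summing to 1.
#' @export
predict_bank <- function(bank, features) {
  if (!inherits(bank, "classifier_bank")) {
    stop("state error: 'bank' is not a fitted classifier_bank")
  }
  x <- if (inherits(features, "feature_set")) features$values
       else as.matrix(features)
  colnames(x) <- bank$feature_names
  x <- sweep(sweep(x, 2, bank$scaler$center), 2, bank$scaler$scale, "/")
  cl <- bank$classes
  out <- list()
  out$knn <- predict(bank$members$knn, x, type = "prob")
  sv <- bank$members$svm
  if (!is.null(sv$compprob) && isTRUE(sv$compprob)) {
    p <- predict(sv, x, probability = TRUE)
    out$svm <- attr(p, "probabilities")[, cl, drop = FALSE]
  } else {
    # probability calibration unavailable (degenerate n): hard one-hot
    p <- predict(sv, x)
    out$svm <- one_hot(match(as.character(p), cl), length(cl))
    colnames(out$svm) <- cl
  }
  out$random_forest <- predict(bank$members$random_forest, x, type = "prob")
  out$adaboost <- predict_adaboost(bank$members$adaboost, x)
  xp <- predict(bank$members$xgboost, xgboost::xgb.DMatrix(x, nthread = 1L))
  if (!is.matrix(xp)) xp <- matrix(xp, ncol = length(cl), byrow = TRUE)
  out$xgboost <- matrix(as.vector(xp), ncol = length(cl),
                        dimnames = list(NULL, cl))
  lapply(out, expand_to_canonical, classes = cl)
}

#' Fuse the five classifiers' probabilities
#'
#' Combines aligned per-classifier probability matrices with the average
#' (classwise mean), product, or maximum (elementwise max) rule, then
#' normalizes each fused score vector through a softmax layer.
#'
#' @param per_classifier List of aligned N x 4 probability matrices (e.g.
#'   from [predict_bank()]).
#' @param rule `"average"`, `"product"` or `"maximum"`.
#' @return N x 4 matrix of fused probabilities (rows sum to 1), attribute
#'   `"scores"` carrying the pre-softmax fused scores.
#' @export
fuse <- function(per_classifier, rule = c("average", "product", "maximum")) {
  rule <- match.arg(rule)
  mats <- lapply(per_classifier, as.matrix)
  scores <- switch(rule,
    average = Reduce(`+`, mats) / length(mats),
    product = Reduce(`*`, mats),
    maximum = Reduce(pmax, mats)
  )
  probs <- softmax_rows(scores)
  colnames(probs) <- colnames(mats[[1]])
  attr(probs, "scores") <- scores
  probs
}

#' Hard class predictions from probability rows
#'
#' Argmax per row; ties break to the lowest class index.
#'
#' @param probs N x 4 probability matrix in canonical class order.
#' @return Character vector of class names.
#' @export
predicted_classes <- function(probs) {
  histo_classes()[apply(probs, 1, which.max)]
}
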