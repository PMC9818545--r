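# Patch-to-image aggregation: per-image frequency arrays, the 2-class
# cancerous/non-cancerous network, probability weighting of the counts, and
# the final 4-class network.

#' Build a per-image frequency array from patch predictions
#'
#' Counts the patches of one image whose argmax prediction falls in each
#' class. `counts4` is ordered \[normal, benign, insitu, invasive\];
#' `counts2` is \[cancerous, noncancerous\] = \[insitu + invasive,
#' normal + benign\]. For the reference geometry every image contributes 35
#' patches.
#'
#' @param probs N x 4 probability matrix for the patches of one image
#'   (canonical class order).
#' @param parent_ids Optional parent image id per row; must be a single
#'   image.
#' @param image_ref Image identifier (defaults to the common parent id).
#' @param expected_total If non-NULL, error unless the patch count equals
#'   this (geometry check; 35 for the reference geometry).
#' @return A `frequency_array`: list with `image_ref`, `counts4`, `counts2`,
#'   `total` (and `weighted4` after [weight_frequency()]).
#' @export
build_frequency_array <- function(probs, parent_ids = NULL,
                                  image_ref = NULL, expected_total = NULL) {
  probs <- as.matrix(probs)
  if (!is.null(parent_ids)) {
    u <- unique(parent_ids)
    if (length(u) != 1) {
      stop("grouping error: patch predictions span several images: ",
           paste(u, collapse = ", "))
    }
    if (is.null(image_ref)) image_ref <- u
  }
  if (!is.null(expected_total) && nrow(probs) != expected_total) {
    stop(sprintf("geometry error: image '%s' has %d patch predictions, expected %d",
                 if (is.null(image_ref)) "?" else image_ref,
                 nrow(probs), expected_total))
  }
  pred <- apply(probs, 1, which.max)
  counts4 <- as.integer(tabulate(pred, nbins = 4L))
  names(counts4) <- histo_classes()
  counts2 <- c(cancerous = counts4[["insitu"]] + counts4[["invasive"]],
               noncancerous = counts4[["normal"]] + counts4[["benign"]])
  structure(list(image_ref = image_ref, counts4 = counts4,
                 counts2 = counts2, total = nrow(probs),
                 weighted4 = NULL),
            class = "frequency_array")
}

#' @export
print.frequency_array <- function(x, ...) {
  cat(sprintf("<frequency_array %s: counts4={%s} counts2={%s} total=%d>\n",
              if (is.null(x$image_ref)) "?" else x$image_ref,
              paste(x$counts4, collapse = ","),
              paste(x$counts2, collapse = ","), x$total))
  invisible(x)
}

#' Weight a frequency array by the cancer probability
#'
#' The non-cancerous counts are scaled by (1 - p) and the cancerous counts
#' by p, producing the attention-like weighted array
#' \[normal (1-p), benign (1-p), insitu p, invasive p\] stored in
#' `weighted4` (raw products; the softmax normalization is the input layer
#' of the 4-class network).
#'
#' @param freq A `frequency_array`.
#' @param p_cancer Cancer probability in \[0, 1\].
#' @return The frequency array with `weighted4` and `p_cancer` set.
#' @export
weight_frequency <- function(freq, p_cancer) {
  stopifnot(inherits(freq, "frequency_array"))
  if (!is.finite(p_cancer) || p_cancer < 0 || p_cancer > 1) {
    stop("domain error: p_cancer must lie in [0, 1], got ", p_cancer)
  }
  freq$weighted4 <- as.numeric(freq$counts4) *
    c(1 - p_cancer, 1 - p_cancer, p_cancer, p_cancer)
  names(freq$weighted4) <- histo_classes()
  freq$p_cancer <- p_cancer
  freq
}

# ---- 2-class model: softmax(counts2) -> dense(1, L2) -> sigmoid ----------

two_class_forward <- function(s, w, b) {
  # s: N x 2 softmaxed counts
  sigmoid(as.vector(s %*% w + b))
}

#' Train the 2-class (cancerous vs non-cancerous) image model
#'
#' Architecture: softmax over the 2-bin count array, a single L2-regularized
#' affine output unit, sigmoid activation; trained with binary cross-entropy
#' and Adam. Note the softmax input layer makes the model scale-invariant in
#' the counts: any balanced array (k, k) maps to (0.5, 0.5) and receives the
#' same probability regardless of k.
#'
#' @param freqs List of `frequency_array`s (training images, after the
#'   validation merge).
#' @param labels_binary Logical vector, `TRUE` = cancerous, aligned with
#'   `freqs`.
#' @param cfg A [train_config()]; `l2` penalizes the affine weights.
#' @return A `two_class_model` with fields `w`, `b`, `history`.
#' @export
train_two_class <- function(freqs, labels_binary, cfg = train_config()) {
  stopifnot(length(freqs) == length(labels_binary))
  if (length(unique(labels_binary)) < 2) {
    stop("data error: both binary classes must be present")
  }
  s <- softmax_rows(t(vapply(freqs, function(f) as.numeric(f$counts2),
                             numeric(2))))
  y <- as.numeric(labels_binary)
  params <- with_seed(derive_seed(cfg$seed, 404L), {
    list(w = stats::rnorm(2, sd = 0.1), b = 0)
  })
  opt <- adam_init(params)
  lr <- cfg$lr0
  n <- length(y)
  history <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    p <- two_class_forward(s, params$w, params$b)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
      cfg$l2 * sum(params$w^2)
    dz <- (p - y) / n
    grads <- list(w = as.vector(crossprod(s, dz)) + 2 * cfg$l2 * params$w,
                  b = sum(dz))
    step <- adam_step(params, grads, opt, lr, cfg$adam_beta1, cfg$adam_beta2)
    params <- step$params; opt <- step$state
    acc <- mean((p > 0.5) == (y > 0.5))
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = loss, acc = acc))
    lr <- lr / (1 + cfg$decay)
  }
  structure(list(w = params$w, b = params$b, history = history),
            class = "two_class_model")
}

#' Predict cancer probabilities from frequency arrays
#'
#' @param model A `two_class_model`.
#' @param freqs A `frequency_array` or list of them.
#' @return Numeric vector of probabilities P(cancerous) in \[0, 1\].
#' @export
predict_two_class <- function(model, freqs) {
  if (inherits(freqs, "frequency_array")) freqs <- list(freqs)
  s <- softmax_rows(t(vapply(freqs, function(f) as.numeric(f$counts2),
                             numeric(2))))
  two_class_forward(s, model$w, model$b)
}

# ---- 4-class model: softmax(weighted4) -> dense(4, sigmoid) ->
#      dense(4, softmax) ----------------------------------------------------

four_class_forward <- function(s, params) {
  a1 <- sigmoid(sweep(s %*% params$W1, 2, params$b1, "+"))
  softmax_rows(sweep(a1 %*% params$W2, 2, params$b2, "+"))
}

#' Train the final 4-class image model
#'
#' Architecture: softmax normalization of the weighted 4-bin frequency
#' array, a 4-unit dense layer with sigmoid activation, and a 4-unit dense
#' layer with softmax output; trained with cross-entropy and Adam under the
#' lr <- lr / (1 + decay) schedule.
#'
#' @param freqs List of `frequency_array`s with `weighted4` set (see
#'   [weight_frequency()]).
#' @param labels Class labels aligned with `freqs`; all four classes must be
#'   present.
#' @param cfg A [train_config()].
#' @return A `four_class_model` with `params` and `history`.
#' @export
train_four_class <- function(freqs, labels, cfg = train_config()) {
  stopifnot(length(freqs) == length(labels))
  if (!all(histo_classes() %in% labels)) {
    stop("data error: all four classes must be present to train the ",
         "4-class model")
  }
  if (any(vapply(freqs, function(f) is.null(f$weighted4), logical(1)))) {
    stop("frequency arrays must be weighted first (see weight_frequency)")
  }
  s <- softmax_rows(t(vapply(freqs, function(f) as.numeric(f$weighted4),
                             numeric(4))))
  y <- one_hot(labels, 4L)
  yi <- class_index(labels)
  params <- with_seed(derive_seed(cfg$seed, 505L), {
    list(W1 = he_uniform(4L, 4L), b1 = rep(0, 4),
         W2 = he_uniform(4L, 4L), b2 = rep(0, 4))
  })
  opt <- adam_init(params)
  lr <- cfg$lr0
  n <- length(labels)
  history <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    a1 <- sigmoid(sweep(s %*% params$W1, 2, params$b1, "+"))
    probs <- softmax_rows(sweep(a1 %*% params$W2, 2, params$b2, "+"))
    loss <- cross_entropy(y, probs)
    dz2 <- (probs - y) / n
    da1 <- tcrossprod(dz2, params$W2)
    dz1 <- da1 * a1 * (1 - a1)
    grads <- list(W1 = crossprod(s, dz1), b1 = colSums(dz1),
                  W2 = crossprod(a1, dz2), b2 = colSums(dz2))
    step <- adam_step(params, grads, opt, lr, cfg$adam_beta1, cfg$adam_beta2)
    params <- step$params; opt <- step$state
    acc <- categorical_accuracy(yi, probs)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = loss, acc = acc))
    lr <- lr / (1 + cfg$decay)
  }
  structure(list(params = params, history = history),
            class = "four_class_model")
}

#' Predict 4-class probabilities from weighted frequency arrays
#'
#' @param model A `four_class_model`.
#' @param freqs A weighted `frequency_array` or list of them.
#' @return N x 4 probability matrix in canonical class order.
#' @export
predict_four_class <- function(model, freqs) {
  if (inherits(freqs, "frequency_array")) freqs <- list(freqs)
  s <- softmax_rows(t(vapply(freqs, function(f) as.numeric(f$weighted4),
                             numeric(4))))
  probs <- four_class_forward(s, model$params)
  colnames(probs) <- histo_classes()
  probs
}

#' Image-level prediction from one image's patch predictions
#'
#' Chains the full aggregation: frequency array, cancer probability from the
#' 2-class model, probability weighting of the counts, and class
#' probabilities from the 4-class model. The binary call is cancerous iff
#' the cancer probability exceeds 0.5.
#'
#' @param probs N x 4 patch probability matrix for one image.
#' @param two_class A trained `two_class_model`.
#' @param four_class A trained `four_class_model`.
#' @param image_ref,parent_ids,expected_total Passed to
#'   [build_frequency_array()].
#' @param p_cancer Optional override of the 2-class probability (e.g. an
#'   oracle value for diagnostics); default NULL uses the model.
#' @return An `image_prediction`: list with `image_ref`,
#'   `cancer_probability`, `class_probs` (4-vector summing to 1),
#'   `predicted_class`, `predicted_binary` (`"cancerous"` /
#'   `"noncancerous"`) and the `frequency_array`.
#' @export
predict_image <- function(probs, two_class, four_class, image_ref = NULL,
                          parent_ids = NULL, expected_total = NULL,
                          p_cancer = NULL) {
  freq <- build_frequency_array(probs, parent_ids, image_ref, expected_total)
  p <- if (is.null(p_cancer)) predict_two_class(two_class, freq)
       else p_cancer
  freq <- weight_frequency(freq, p)
  class_probs <- as.vector(predict_four_class(four_class, freq))
  names(class_probs) <- histo_classes()
  structure(list(
    image_ref = freq$image_ref, cancer_probability = p,
    class_probs = class_probs,
    predicted_class = histo_classes()[which.max(class_probs)],
    predicted_binary = if (p > 0.5) "cancerous" else "noncancerous",
    frequency_array = freq
  ), class = "image_prediction")
}

#' @export
print.image_prediction <- function(x, ...) {
  cat(sprintf("<image_prediction %s: %s (p_cancer=%.3f, %s)>\n",
              if (is.null(x$image_ref)) "?" else x$image_ref,
              x$predicted_class, x$cancer_probability, x$predicted_binary))
  invisible(x)
}

#' Majority-vote baseline image prediction
#'
#' The simple alternative to the two-stage aggregator: the image class is
#' the argmax of the 4-bin patch count array (ties to the lowest class
#' index). Provided as a comparison harness.
#'
#' @param freq A `frequency_array`.
#' @return Class name.
#' @export
majority_vote_class <- function(freq) {
  histo_classes()[which.max(freq$counts4)]
}
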