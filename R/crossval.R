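#' Stratified k-fold partition
#'
#' Class-proportional folds: within each class, indices are shuffled with
#' the seed and dealt round-robin, so fold sizes differ by at most one per
#' class. Folds are disjoint and cover every index exactly once.
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `k` integer vectors of test indices.
#' @export
make_stratified_folds <- function(y, k = 10L, seed = 1L) {
  n <- length(y)
  if (k > n) stop_param("k = ", k, " exceeds the number of epochs ", n)
  if (k < 2) stop_param("k must be at least 2")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      grp <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
  })
  lapply(folds, sort)
}

fit_one <- function(spec, x, y, dims) {
  if (inherits(spec, "cnn_spec"))
    p300_cnn(x, y, spec, n_channels = dims[1], n_times = dims[2])
  else if (inherits(spec, "bayes_spec"))
    p300_bayes(x, y, spec)
  else if (inherits(spec, "constant_spec"))
    structure(list(class = spec$class), class = "p300_constant")
  else stop_param("unknown classifier spec of class ",
                  paste(class(spec), collapse = "/"))
}

predict_one <- function(model, x) {
  if (inherits(model, "p300_constant")) {
    pr <- matrix(0, nrow(x), 2)
    pr[, model$class + 1L] <- 1
    colnames(pr) <- c("0", "1")
    pr
  } else predict(model, x, type = "prob")
}

#' Cross-validated P300 detection accuracy
#'
#' Stratified k-fold cross-validation of a P300 detector on one patient's
#' mixed target/non-target epochs. Per fold, the model is trained on the
#' other k-1 folds and predicts the held-out fold; the per-patient detection
#' accuracy is the proportion of correct pooled out-of-fold predictions
#' (the mean of per-fold accuracies is also reported).
#'
#' @param x A `p300_features` or numeric feature matrix.
#' @param y Binary labels; taken from `x` if it is a `p300_features`.
#' @param spec Classifier specification ([cnn_spec()], [bayes_spec()] or
#'   [constant_spec()]).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle; per-fold training seeds derive
#'   from the spec seed and the fold index.
#' @param n_channels,n_times Feature-image dimensions when `x` is a plain
#'   matrix and `spec` is a [cnn_spec()].
#' @return Object of class `p300_cv`: `k`, `folds` (per fold: index,
#'   train/test indices, out-of-fold class-1 probabilities, predictions,
#'   accuracy), pooled `prob`, `pred` and `labels` in row order,
#'   `detection_accuracy` (pooled), `mean_fold_accuracy`, `kind`, `seed`.
#' @export
cross_validate <- function(x, y = NULL, spec = cnn_spec(), k = 10L,
                           seed = 1L, n_channels = NULL, n_times = NULL) {
  r <- resolve_xy(x, y, n_channels, n_times)
  n <- nrow(r$x)
  folds <- make_stratified_folds(r$y, k, seed)
  prob <- rep(NA_real_, n)
  fold_res <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(r$y[train])) < 2L)
      stop_param("training split of fold ", f, " lost a class")
    sp <- spec
    if (!is.null(sp$seed)) sp$seed <- sp$seed + 1000L * f
    model <- fit_one(sp, r$x[train, , drop = FALSE], r$y[train],
                     c(r$n_channels, r$n_times))
    p <- predict_one(model, r$x[test, , drop = FALSE])[, 2]
    prob[test] <- p
    pred <- as.integer(p >= 0.5)
    fold_res[[f]] <- list(fold = f, train = train, test = test,
                          prob = p, pred = pred,
                          accuracy = mean(pred == r$y[test]))
  }
  stopifnot(!anyNA(prob))  # pooled predictions cover every row exactly once
  pred <- as.integer(prob >= 0.5)
  structure(list(k = as.integer(k), folds = fold_res,
                 prob = prob, pred = pred, labels = r$y,
                 detection_accuracy = mean(pred == r$y),
                 mean_fold_accuracy =
                   mean(vapply(fold_res, `[[`, numeric(1), "accuracy")),
                 kind = class(spec)[1], seed = as.integer(seed)),
            class = "p300_cv")
}

#' @export
print.p300_cv <- function(x, ...) {
  cat(sprintf("<p300_cv> %d-fold, %s: detection accuracy %.4f (pooled), %.4f (mean of folds)\n",
              x$k, x$kind, x$detection_accuracy, x$mean_fold_accuracy))
  invisible(x)
}
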