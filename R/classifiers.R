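#' Sample variational-layer weights
#'
#' The reparameterised sampling rule of the Bayesian layers: each weight (or
#' bias) is drawn as `W = noise * softplus(rho) + mu` with
#' `softplus(rho) = log(1 + exp(rho))`, where `mu` is the trainable mean and
#' `rho` the trainable scale parameter. Softplus keeps the sampled standard
#' deviation strictly positive for every finite `rho`; driving `rho` to
#' minus infinity collapses the draw to the deterministic map `W = mu`.
#'
#' @param mu,rho Conformable numeric arrays of means and scale parameters.
#' @param noise Standard-normal draws, conformable with `mu`.
#' @return Sampled weights, same shape as `mu`.
#' @examples
#' sample_bayesian_weights(0, 0, 1)  # log(2)
#' @export
sample_bayesian_weights <- function(mu, rho, noise) {
  if (!all(length(mu) == c(length(rho), length(noise))) ||
      !identical(dim(mu), dim(rho)) || !identical(dim(mu), dim(noise)))
    stop_param("mu, rho and noise must be conformable")
  sp <- ifelse(rho > 30, rho, log1p(exp(rho)))
  noise * sp + mu
}

#' Specification of the convolutional P300 detector
#'
#' Hyperparameters of the spatiotemporal CNN. The training defaults are the
#' published configuration: batch size 16, weight decay 1e-4, dropout 0.3,
#' learning rate 4e-5, 100 epochs, Adam. Architecture: a spatial convolution
#' spanning all channels, a temporal convolution across the spatial maps
#' (each followed by batch normalisation and ReLU), a hidden linear layer
#' with ReLU and dropout, and a 2-unit softmax output.
#'
#' @param n_spatial_filters,n_temporal_filters Number of convolution maps.
#' @param temporal_kernel Temporal kernel length in (decimated) samples.
#' @param hidden Width of the hidden linear layer.
#' @param dropout_rate Dropout probability in (0, 1).
#' @param batch_size Minibatch size.
#' @param weight_decay L2 penalty coefficient.
#' @param learning_rate Adam step size.
#' @param epochs Number of training passes over the data.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @return Object of class `c("cnn_spec", "p300_spec")`.
#' @export
cnn_spec <- function(n_spatial_filters = 8L, n_temporal_filters = 8L,
                     temporal_kernel = 5L, hidden = 32L,
                     dropout_rate = 0.3, batch_size = 16L,
                     weight_decay = 1e-4, learning_rate = 4e-5,
                     epochs = 100L, seed = 1L) {
  if (dropout_rate <= 0 || dropout_rate >= 1)
    stop_param("dropout_rate must be in (0, 1)")
  for (v in list(n_spatial_filters, n_temporal_filters, temporal_kernel,
                 hidden, batch_size, epochs))
    if (!is_count(v) || v < 1) stop_param("sizes must be positive integers")
  structure(list(n_spatial_filters = as.integer(n_spatial_filters),
                 n_temporal_filters = as.integer(n_temporal_filters),
                 temporal_kernel = as.integer(temporal_kernel),
                 hidden = as.integer(hidden),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = c("cnn_spec", "p300_spec"))
}

#' Specification of the variational Bayesian P300 detector
#'
#' A two-layer multilayer perceptron whose weights and biases are sampled on
#' every feedforward pass via [sample_bayesian_weights()], with a
#' standard-normal prior; the training objective adds a
#' `KL(q || N(0, 1))` complexity term weighted by `1/num_batches` to the
#' cross-entropy, shrinking predictive variance. Prediction averages class
#' probabilities over `n_samples` weight draws.
#'
#' @param hidden Hidden-layer width.
#' @param n_samples Weight samples averaged at prediction time.
#' @param batch_size,learning_rate,epochs,seed Training controls (Adam).
#' @return Object of class `c("bayes_spec", "p300_spec")`.
#' @export
bayes_spec <- function(hidden = 64L, n_samples = 10L, batch_size = 16L,
                       learning_rate = 1e-3, epochs = 100L, seed = 1L) {
  for (v in list(hidden, n_samples, batch_size, epochs))
    if (!is_count(v) || v < 1) stop_param("sizes must be positive integers")
  structure(list(hidden = as.integer(hidden),
                 n_samples = as.integer(n_samples),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = c("bayes_spec", "p300_spec"))
}

#' Constant-baseline classifier specification
#'
#' Always predicts the given class with probability one. A reference
#' baseline: pooled cross-validated accuracy of the constant classifier
#' equals the proportion of that class in the data.
#'
#' @param class Predicted class, 0 or 1.
#' @return Object of class `c("constant_spec", "p300_spec")`.
#' @export
constant_spec <- function(class = 1L) {
  if (!class %in% c(0L, 1L)) stop_param("class must be 0 or 1")
  structure(list(class = as.integer(class)),
            class = c("constant_spec", "p300_spec"))
}

# Accept a p300_features or a plain matrix + labels; return list(x, y, dims)
resolve_xy <- function(x, y, n_channels = NULL, n_times = NULL) {
  if (inherits(x, "p300_features")) {
    y <- if (is.null(y)) x$labels else y
    n_channels <- length(x$channels)
    n_times <- x$n_times
    x <- x$x
  }
  if (is.null(y)) stop_param("labels y are required")
  if (!all(y %in% c(0L, 1L))) stop_param("labels must be 0/1")
  if (length(y) != nrow(x)) stop_param("labels must match rows of x")
  if (length(unique(y)) < 2L)
    stop_param("both classes must be present in the training labels")
  list(x = as.matrix(x), y = as.integer(y),
       n_channels = n_channels, n_times = n_times)
}

#' Fit the convolutional P300 detector
#'
#' Trains the spatiotemporal CNN of [cnn_spec()] on epoch feature vectors.
#' Feature rows are reshaped to a channels x time image using the feature
#' provenance (or explicit `n_channels`/`n_times`). Training is fully
#' deterministic given the spec seed.
#'
#' @param x A [build_feature_vectors()] result, or a numeric matrix of
#'   feature rows.
#' @param y Binary labels (1 = P300); taken from `x` when it is a
#'   `p300_features`.
#' @param spec A [cnn_spec()].
#' @param n_channels,n_times Feature-image dimensions when `x` is a plain
#'   matrix (`n_channels * n_times` must equal `ncol(x)`).
#' @return Object of class `c("p300_cnn", "p300_model")` with elements
#'   `params` (weights and batch-norm statistics), `spec`, `dims`, and the
#'   per-epoch training `loss`.
#' @export
p300_cnn <- function(x, y = NULL, spec = cnn_spec(),
                     n_channels = NULL, n_times = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  r <- resolve_xy(x, y, n_channels, n_times)
  if (is.null(r$n_channels) || is.null(r$n_times))
    stop_param("n_channels and n_times are required for a plain matrix")
  if (r$n_channels * r$n_times != ncol(r$x))
    stop_param("feature dimension ", ncol(r$x),
               " does not reshape to ", r$n_channels, " x ", r$n_times)
  if (spec$temporal_kernel > r$n_times)
    stop_param("temporal kernel exceeds the number of time samples")
  fit <- cpp_cnn_fit(r$x, r$y, r$n_channels, r$n_times,
                     spec$n_spatial_filters, spec$n_temporal_filters,
                     spec$temporal_kernel, spec$hidden, spec$dropout_rate,
                     spec$batch_size, spec$weight_decay,
                     spec$learning_rate, spec$epochs, spec$seed)
  structure(list(params = fit[setdiff(names(fit), "loss")],
                 loss = fit$loss, spec = spec,
                 dims = c(n_channels = r$n_channels, n_times = r$n_times),
                 n_train = nrow(r$x)),
            class = c("p300_cnn", "p300_model"))
}

#' Fit the variational Bayesian P300 detector
#'
#' Trains the Bayesian MLP of [bayes_spec()]: every forward pass during
#' training draws fresh weights by the [sample_bayesian_weights()] rule, and
#' the objective combines cross-entropy with the Gaussian-prior complexity
#' term.
#'
#' @inheritParams p300_cnn
#' @param spec A [bayes_spec()].
#' @return Object of class `c("p300_bayes", "p300_model")` with the
#'   variational parameters (`muW1`, `rhoW1`, ...) in `$params`.
#' @export
p300_bayes <- function(x, y = NULL, spec = bayes_spec()) {
  stopifnot(inherits(spec, "bayes_spec"))
  r <- resolve_xy(x, y)
  fit <- cpp_bnn_fit(r$x, r$y, spec$hidden, spec$batch_size,
                     spec$learning_rate, spec$epochs, spec$seed)
  structure(list(params = fit[setdiff(names(fit), "loss")],
                 loss = fit$loss, spec = spec, n_train = nrow(r$x)),
            class = c("p300_bayes", "p300_model"))
}

#' @export
predict.p300_cnn <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "p300_features")) newdata$x else as.matrix(newdata)
  pr <- cpp_cnn_predict(object$params, x, object$dims["n_channels"],
                        object$dims["n_times"], object$spec$temporal_kernel)
  colnames(pr) <- c("0", "1")
  if (type == "class") as.integer(pr[, 2] >= 0.5) else pr
}

# Bayesian prediction averages softmax probabilities over n_samples weight
# draws; the draw stream is seeded, so predictions are reproducible.
#' @export
predict.p300_bayes <- function(object, newdata, type = c("prob", "class"),
                               n_samples = object$spec$n_samples,
                               seed = object$spec$seed, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "p300_features")) newdata$x else as.matrix(newdata)
  pr <- cpp_bnn_predict(object$params, x, n_samples, seed)
  colnames(pr) <- c("0", "1")
  if (type == "class") as.integer(pr[, 2] >= 0.5) else pr
}

#' @export
print.p300_model <- function(x, ...) {
  kind <- if (inherits(x, "p300_cnn")) "spatiotemporal CNN"
          else "variational Bayesian MLP"
  cat(sprintf("<%s> trained on %d epochs", kind, x$n_train))
  if (length(x$loss))
    cat(sprintf(", final training loss %.4f", x$loss[length(x$loss)]))
  cat("\n")
  invisible(x)
}

#' @export
summary.p300_model <- function(object, ...) {
  print(object)
  cat("spec:\n")
  sp <- object$spec
  for (nm in names(sp)) cat(sprintf("  %s: %s\n", nm, format(sp[[nm]])))
  invisible(object)
}

#' @export
coef.p300_model <- function(object, ...) object$params
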