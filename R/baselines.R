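# Comparison classifiers: an MLP sharing the SAE's architecture and forward
# pass (random init + joint backpropagation only, no pretraining), and a
# shrinkage-regularized LDA for the high-dimensional feature vectors.

#' Train the multi-layer perceptron baseline
#'
#' Same layer sizes, transfer functions, input scaling and forward-pass code
#' path as the stacked autoencoder, but randomly initialized and trained by
#' joint backpropagation only (default 1000 iterations, the study setting).
#'
#' @param features An `erp_features`, or a matrix with `labels`.
#' @param layer_sizes Hidden layer sizes.
#' @param iterations Backpropagation iterations.
#' @param seed Integer seed.
#' @param labels Required when `features` is a bare matrix.
#' @param learn_rate,momentum Optimizer settings.
#' @return A `stacked_network` (shares [predict.stacked_network()]).
#' @export
train_mlp <- function(features, layer_sizes = c(130, 100, 50, 20),
                      iterations = 1000, seed, labels = NULL,
                      learn_rate = 0.1, momentum = 0.9) {
  if (inherits(features, "erp_features")) {
    X <- features$values
    labels <- features$labels
  } else {
    X <- features
    if (is.null(labels)) stop("`labels` required with a bare matrix", call. = FALSE)
  }
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("MLP training requires at least two classes present", call. = FALSE)
  }
  sc <- fit_input_scaling(X)
  d <- ncol(X)
  sizes <- vapply(layer_sizes, check_count, integer(1), name = "layer_sizes")
  lv <- levels(labels)

  layers <- vector("list", length(sizes))
  fan_in <- d
  for (k in seq_along(sizes)) {
    layers[[k]] <- with_seed(derive_seed(seed, k),
                             list(W1 = glorot_init(sizes[k], fan_in),
                                  b1 = rep(0, sizes[k]),
                                  W2 = glorot_init(fan_in, sizes[k]),
                                  b2 = rep(0, fan_in)))
    fan_in <- sizes[k]
  }
  soft <- with_seed(derive_seed(seed, 77),
                    list(W = glorot_init(length(lv), sizes[length(sizes)]),
                         b = rep(0, length(lv)), class_levels = lv))
  net <- stacked_network(layers, soft, scaling = sc, input_dim = d)
  hp <- sae_hyperparams(layer_sizes = sizes,
                        finetune_iterations = iterations,
                        learn_rate = learn_rate, momentum = momentum)
  net <- fine_tune(net, X, labels, hp)
  attr(net, "model") <- "mlp"
  net
}

#' Shrinkage-regularized linear discriminant analysis
#'
#' Pooled within-class covariance shrunk toward the identity scaled by the
#' average eigenvalue, with the shrinkage intensity chosen by the analytic
#' (Ledoit-Wolf / Schaefer-Strimmer) estimator, as recommended for
#' high-dimensional ERP feature vectors. The weight vector is the shrunk
#' covariance inverse applied to the class-mean difference; the decision
#' threshold sits at the projected midpoint of the class means (classes are
#' balanced by construction of the trial-set assembly).
#'
#' @param features An `erp_features`, or a matrix with `labels`.
#' @param labels Required when `features` is a bare matrix; binary factor.
#' @param shrinkage Optional intensity in `[0, 1]` overriding the analytic
#'   estimate (0 = classical LDA, 1 = identity-target covariance).
#' @return An `lda_model` with fields `w`, `threshold`,
#'   `shrinkage_intensity`, `class_means`, `class_levels`.
#' @export
train_shrinkage_lda <- function(features, labels = NULL, shrinkage = NULL) {
  if (inherits(features, "erp_features")) {
    X <- features$values
    labels <- features$labels
  } else {
    X <- features
    if (is.null(labels)) stop("`labels` required with a bare matrix", call. = FALSE)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("shrinkage LDA requires exactly two classes present", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  lv <- levels(labels)
  d <- ncol(X)
  n <- nrow(X)
  m0 <- colMeans(X[labels == lv[1], , drop = FALSE])
  m1 <- colMeans(X[labels == lv[2], , drop = FALSE])

  # within-class centered data
  Z <- X
  Z[labels == lv[1], ] <- sweep(X[labels == lv[1], , drop = FALSE], 2, m0)
  Z[labels == lv[2], ] <- sweep(X[labels == lv[2], , drop = FALSE], 2, m1)
  S <- crossprod(Z) / (n - 1)
  nu <- mean(diag(S))

  if (is.null(shrinkage)) {
    # analytic intensity toward nu*I: sum of estimated variances of the
    # covariance entries over the squared distance from the target
    Zbar_F2 <- sum((S * (n - 1) / n)^2)
    ss <- sum(rowSums(Z^2)^2) - n * Zbar_F2     # sum_ij sum_k (z_ijk - zbar_ij)^2
    num <- n / (n - 1)^3 * ss
    den <- sum((S - diag(nu, d))^2)
    gamma <- if (den > 0) min(1, max(0, num / den)) else 1
  } else {
    gamma <- check_scalar(shrinkage, "shrinkage", lower = 0, upper = 1)
  }

  S_shrunk <- (1 - gamma) * S + gamma * diag(nu, d)
  w <- solve(S_shrunk, m1 - m0)
  structure(list(w = as.numeric(w),
                 threshold = sum(w * (m0 + m1)) / 2,
                 shrinkage_intensity = gamma,
                 class_means = rbind(m0, m1),
                 class_levels = lv),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, shrinkage intensity %.4f (%s vs %s)\n",
              length(x$w), x$shrinkage_intensity,
              x$class_levels[1], x$class_levels[2]))
  invisible(x)
}

#' Classify feature vectors with a shrinkage-LDA model
#'
#' Deterministic sign of the projected decision value `w.x - threshold`;
#' points exactly on the boundary break to the first class (non-target).
#'
#' @param object An `lda_model`.
#' @param newdata Matrix rows x features, or an `erp_features`.
#' @param ... Unused.
#' @return List with `class` (factor) and `decision_value` (numeric).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "erp_features")) newdata$values else newdata
  if (!is.matrix(X) || ncol(X) != length(object$w)) {
    stop("`newdata` column count does not match the model", call. = FALSE)
  }
  dv <- as.numeric(X %*% object$w) - object$threshold
  cls <- ifelse(dv > 0, object$class_levels[2], object$class_levels[1])
  list(class = factor(cls, levels = object$class_levels), decision_value = dv)
}
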