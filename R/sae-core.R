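# From-scratch stacked sparse autoencoder: logistic-sigmoid encoder/decoder
# pairs trained greedily with an MSE + L2 + KL-sparsity objective, a softmax
# head, and joint supervised fine-tuning. All training is deterministic
# full-batch gradient descent with momentum and step halving.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Hyperparameters of the stacked sparse autoencoder
#'
#' Defaults follow the study configuration: hidden sizes 130-100-50-20, L2
#' weight decay 0.004, KL sparsity weight 4 with target mean activation 0.2,
#' at most 200 pretraining epochs per autoencoder, 200 softmax iterations and
#' 200 fine-tuning iterations.
#'
#' @param layer_sizes Strictly decreasing hidden-layer sizes.
#' @param l2_weight L2 weight-decay coefficient (biases are not penalized).
#' @param sparsity_weight Weight of the KL sparsity penalty.
#' @param sparsity_target Target mean activation of each hidden unit, in (0,1).
#' @param max_pretrain_epochs Gradient iterations per autoencoder (>= 0).
#' @param softmax_iterations Gradient iterations for the softmax head.
#' @param finetune_iterations Gradient iterations for joint fine-tuning.
#' @param learn_rate Initial gradient-descent step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @return An `sae_hyperparams` list.
#' @export
sae_hyperparams <- function(layer_sizes = c(130, 100, 50, 20),
                            l2_weight = 0.004, sparsity_weight = 4,
                            sparsity_target = 0.2,
                            max_pretrain_epochs = 200,
                            softmax_iterations = 200,
                            finetune_iterations = 200,
                            learn_rate = 0.1, momentum = 0.9) {
  hp <- list(
    layer_sizes = vapply(layer_sizes, check_count, integer(1), name = "layer_sizes"),
    l2_weight = check_scalar(l2_weight, "l2_weight", lower = 0),
    sparsity_weight = check_scalar(sparsity_weight, "sparsity_weight", lower = 0),
    sparsity_target = check_scalar(sparsity_target, "sparsity_target",
                                   lower = 1e-12, upper = 1 - 1e-12),
    max_pretrain_epochs = check_count(max_pretrain_epochs, "max_pretrain_epochs",
                                      positive = FALSE),
    softmax_iterations = check_count(softmax_iterations, "softmax_iterations",
                                     positive = FALSE),
    finetune_iterations = check_count(finetune_iterations, "finetune_iterations",
                                      positive = FALSE),
    learn_rate = check_scalar(learn_rate, "learn_rate", lower = 1e-12),
    momentum = check_scalar(momentum, "momentum", lower = 0, upper = 1 - 1e-12)
  )
  structure(hp, class = "sae_hyperparams")
}

# deterministic monotone optimizer over a named list of parameter arrays:
# momentum step, accepted only if the cost does not increase; otherwise the
# step size is halved and the velocity reset. Guarantees final <= initial.
gd_momentum <- function(par, fn, iterations, learn_rate, momentum) {
  if (iterations == 0L) return(list(par = par, cost = fn(par)$cost, trace = numeric(0)))
  vel <- lapply(par, function(p) p * 0)
  eval_cur <- fn(par)
  trace <- numeric(iterations)
  lr <- learn_rate
  for (it in seq_len(iterations)) {
    g <- eval_cur$grad
    vel <- Map(function(v, gi) momentum * v - lr * gi, vel, g)
    cand <- Map(`+`, par, vel)
    eval_cand <- fn(cand)
    if (eval_cand$cost <= eval_cur$cost + 1e-12 * max(1, abs(eval_cur$cost))) {
      par <- cand
      eval_cur <- eval_cand
    } else {
      lr <- lr / 2
      vel <- lapply(vel, function(v) v * 0)
      if (lr < 1e-14) break
    }
    trace[it] <- eval_cur$cost
  }
  list(par = par, cost = eval_cur$cost, trace = trace)
}

glorot_init <- function(n_out, n_in) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -r, r), n_out, n_in)
}

#' Sparse-autoencoder cost and analytic gradients
#'
#' Objective over a batch of `n` rows:
#' mean per-row squared reconstruction error
#' `+ (l2/2) * (sum W_enc^2 + sum W_dec^2)`
#' `+ beta * sum_j KL(rho || rho_hat_j)`, where `rho_hat_j` is the batch-mean
#' activation of hidden unit `j` and
#' `KL(rho||r) = rho*log(rho/r) + (1-rho)*log((1-rho)/(1-r))`.
#' `rho_hat` is clamped to `[1e-6, 1-1e-6]` (with a warning) to keep the KL
#' term finite. Gradients are exact for the unclamped region.
#'
#' @param layer An `autoencoder_layer` (list with `W1`, `b1`, `W2`, `b2`).
#' @param X Batch matrix, rows x input-dims.
#' @param hyper An [sae_hyperparams()].
#' @return List with `cost`, `grad` (same shapes as the parameters), and the
#'   components `mse`, `l2`, `kl`.
#' @export
ae_cost_grad <- function(layer, X, hyper) {
  if (!is.matrix(X) || nrow(X) < 1L) stop("`X` must be a non-empty matrix", call. = FALSE)
  n <- nrow(X)
  W1 <- layer$W1; b1 <- layer$b1; W2 <- layer$W2; b2 <- layer$b2
  lambda <- hyper$l2_weight; beta <- hyper$sparsity_weight; rho <- hyper$sparsity_target

  H <- sigmoid(sweep(X %*% t(W1), 2, b1, `+`))          # n x h
  Xhat <- sigmoid(sweep(H %*% t(W2), 2, b2, `+`))       # n x d
  R <- Xhat - X

  rho_hat <- colMeans(H)
  clamped <- rho_hat < 1e-6 | rho_hat > 1 - 1e-6
  if (any(clamped)) {
    warning(sprintf("clamping %d hidden-unit mean activation(s) away from {0,1}",
                    sum(clamped)))
    rho_hat <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
  }
  mse <- sum(R^2) / n
  l2 <- (lambda / 2) * (sum(W1^2) + sum(W2^2))
  kl <- sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
  cost <- mse + l2 + beta * kl

  dA2 <- (2 / n) * R * Xhat * (1 - Xhat)                # n x d
  gW2 <- t(dA2) %*% H + lambda * W2
  gb2 <- colSums(dA2)
  sparse_term <- (beta / n) * (-rho / rho_hat + (1 - rho) / (1 - rho_hat))
  dH <- dA2 %*% W2 + matrix(sparse_term, n, length(rho_hat), byrow = TRUE)
  dA1 <- dH * H * (1 - H)
  gW1 <- t(dA1) %*% X + lambda * W1
  gb1 <- colSums(dA1)

  list(cost = cost,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       mse = mse, l2 = l2, kl = beta * kl)
}

#' Train a single sparse autoencoder
#'
#' Random (Glorot-uniform) initialization followed by at most
#' `max_pretrain_epochs` monotone full-batch gradient steps on the
#' [ae_cost_grad()] objective; the final cost never exceeds the initial one.
#'
#' @param X Training batch, rows x input-dims (>= 2 rows).
#' @param hidden_size Hidden-layer size, strictly below the input dimension.
#' @param hyper An [sae_hyperparams()].
#' @param seed Integer seed for the weight initialization.
#' @return An `autoencoder_layer` with fields `W1`, `b1`, `W2`, `b2` and an
#'   attached `cost_trace`.
#' @export
train_autoencoder <- function(X, hidden_size, hyper, seed) {
  if (!is.matrix(X) || nrow(X) < 2L) stop("`X` needs at least 2 rows", call. = FALSE)
  d <- ncol(X)
  hidden_size <- check_count(hidden_size, "hidden_size")
  if (hidden_size >= d) {
    stop("`hidden_size` must be strictly below the input dimensionality",
         call. = FALSE)
  }
  par <- with_seed(seed, list(W1 = glorot_init(hidden_size, d),
                              b1 = rep(0, hidden_size),
                              W2 = glorot_init(d, hidden_size),
                              b2 = rep(0, d)))
  fit <- gd_momentum(par, function(p) ae_cost_grad(p, X, hyper),
                     hyper$max_pretrain_epochs, hyper$learn_rate, hyper$momentum)
  layer <- structure(fit$par, class = "autoencoder_layer")
  attr(layer, "cost_trace") <- fit$trace
  layer
}

#' Encode a batch through an autoencoder's encoding half
#'
#' @param layer An `autoencoder_layer` (or any list with `W1`, `b1`).
#' @param X Batch matrix, rows x input-dims.
#' @return Matrix rows x hidden of sigmoid activations in (0, 1).
#' @export
encode <- function(layer, X) {
  if (!is.matrix(X) || ncol(X) != ncol(layer$W1)) {
    stop("`X` column count must match the layer input dimension", call. = FALSE)
  }
  sigmoid(sweep(X %*% t(layer$W1), 2, layer$b1, `+`))
}

#' Greedy layer-wise pretraining of the autoencoder stack
#'
#' Trains autoencoder k on the data encoded through layers 1..k-1 and
#' returns the layers in order.
#'
#' @param X Training batch, rows x input-dims.
#' @param hyper An [sae_hyperparams()]; `layer_sizes` must be strictly
#'   decreasing and below the input dimension.
#' @param seed Integer seed; per-layer sub-seeds are derived from it.
#' @return List of `autoencoder_layer` objects.
#' @export
train_stack <- function(X, hyper, seed) {
  sizes <- hyper$layer_sizes
  if (any(diff(sizes) >= 0) || sizes[1] >= ncol(X)) {
    stop("`layer_sizes` must be strictly decreasing and below the input dimension",
         call. = FALSE)
  }
  layers <- vector("list", length(sizes))
  cur <- X
  for (k in seq_along(sizes)) {
    layers[[k]] <- train_autoencoder(cur, sizes[k], hyper, derive_seed(seed, k))
    cur <- encode(layers[[k]], cur)
  }
  layers
}

# softmax cost + gradients over parameters list(W (C x h), b (C))
softmax_probs <- function(W, b, H) {
  S <- sweep(H %*% t(W), 2, b, `+`)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

softmax_cost_grad <- function(par, H, Y) {
  n <- nrow(H)
  P <- softmax_probs(par$W, par$b, H)
  cost <- -sum(Y * log(pmax(P, 1e-300))) / n
  dS <- (P - Y) / n
  list(cost = cost, grad = list(W = t(dS) %*% H, b = colSums(dS)))
}

#' Train the supervised softmax output layer
#'
#' Full-batch cross-entropy minimization on encoded representations.
#'
#' @param H Input matrix, rows x hidden-dims.
#' @param labels Per-row class factor; at least two classes must be present.
#' @param iterations Gradient iterations.
#' @param seed Integer seed for initialization.
#' @param learn_rate,momentum Optimizer settings.
#' @return List with `W` (classes x hidden), `b`, and `class_levels`.
#' @export
train_softmax <- function(H, labels, iterations = 200, seed = 1,
                          learn_rate = 0.1, momentum = 0.9) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("softmax training requires at least two classes present", call. = FALSE)
  }
  lv <- levels(labels)
  Y <- outer(as.character(labels), lv, `==`) * 1
  C <- length(lv)
  par <- with_seed(seed, list(W = glorot_init(C, ncol(H)), b = rep(0, C)))
  fit <- gd_momentum(par, function(p) softmax_cost_grad(p, H, Y),
                     check_count(iterations, "iterations", positive = FALSE),
                     learn_rate, momentum)
  c(fit$par, list(class_levels = lv, cost_trace = fit$trace))
}

#' Assemble a stacked network from pretrained parts
#'
#' @param layers List of `autoencoder_layer` objects (encode halves used).
#' @param softmax Output of [train_softmax()].
#' @param scaling Per-column affine input scaling (`list(a, b)`), as stored
#'   by [train_sae()]; `NULL` for identity.
#' @param input_dim Input dimensionality.
#' @return A `stacked_network`.
#' @export
stacked_network <- function(layers, softmax, scaling = NULL, input_dim) {
  if (ncol(softmax$W) != nrow(layers[[length(layers)]]$W1)) {
    stop("softmax input size does not match the last hidden layer", call. = FALSE)
  }
  structure(list(
    layers = lapply(layers, function(l) list(W1 = l$W1, b1 = l$b1)),
    softmax = list(W = softmax$W, b = softmax$b),
    class_levels = softmax$class_levels,
    scaling = scaling,
    architecture = c(input_dim, vapply(layers, function(l) nrow(l$W1), integer(1)),
                     nrow(softmax$W))
  ), class = "stacked_network")
}

#' Architecture string of a stacked network
#' @param network A `stacked_network`.
#' @return E.g. `"209-130-100-50-20-2"` for the default model.
#' @export
architecture_string <- function(network) {
  paste(network$architecture, collapse = "-")
}

#' @export
print.stacked_network <- function(x, ...) {
  cat(sprintf("<stacked_network> %s (%s)\n", architecture_string(x),
              paste(x$class_levels, collapse = "/")))
  invisible(x)
}

apply_scaling <- function(network, X) {
  if (is.null(network$scaling)) return(X)
  sweep(sweep(X, 2, network$scaling$a, `*`), 2, network$scaling$b, `+`)
}

# forward pass storing activations; X is raw (unscaled) input
network_forward <- function(network, X, keep_activations = FALSE) {
  A <- apply_scaling(network, X)
  acts <- if (keep_activations) list(A) else NULL
  for (l in network$layers) {
    A <- sigmoid(sweep(A %*% t(l$W1), 2, l$b1, `+`))
    if (keep_activations) acts <- c(acts, list(A))
  }
  P <- softmax_probs(network$softmax$W, network$softmax$b, A)
  list(probs = P, activations = acts)
}

#' Cross-entropy cost and gradients of the full stacked network
#'
#' Joint backpropagation through every encoder layer and the softmax head;
#' this is the objective minimized during fine-tuning (regularization is
#' applied during pretraining only).
#'
#' @param network A `stacked_network`.
#' @param X Raw input matrix, rows x input-dims.
#' @param labels Per-row class factor matching `network$class_levels`.
#' @return List with `cost` and `grad` (a list mirroring `layers` and
#'   `softmax`).
#' @export
network_cost_grad <- function(network, X, labels) {
  labels <- factor(as.character(labels), levels = network$class_levels)
  if (anyNA(labels)) stop("labels outside the network's class levels", call. = FALSE)
  Y <- outer(as.character(labels), network$class_levels, `==`) * 1
  n <- nrow(X)
  fw <- network_forward(network, X, keep_activations = TRUE)
  acts <- fw$activations            # acts[[1]] scaled input, acts[[k+1]] layer k
  P <- fw$probs
  cost <- -sum(Y * log(pmax(P, 1e-300))) / n

  L <- length(network$layers)
  dS <- (P - Y) / n
  g_soft <- list(W = t(dS) %*% acts[[L + 1]], b = colSums(dS))
  g_layers <- vector("list", L)
  dA <- dS %*% network$softmax$W
  for (k in L:1) {
    H <- acts[[k + 1]]
    dZ <- dA * H * (1 - H)
    g_layers[[k]] <- list(W1 = t(dZ) %*% acts[[k]], b1 = colSums(dZ))
    if (k > 1) dA <- dZ %*% network$layers[[k]]$W1
  }
  list(cost = cost, grad = list(layers = g_layers, softmax = g_soft))
}

# flatten/unflatten network parameters for the shared optimizer
net_par <- function(network) {
  p <- list()
  for (k in seq_along(network$layers)) {
    p[[paste0("W1_", k)]] <- network$layers[[k]]$W1
    p[[paste0("b1_", k)]] <- network$layers[[k]]$b1
  }
  p$W_soft <- network$softmax$W
  p$b_soft <- network$softmax$b
  p
}

net_set_par <- function(network, p) {
  for (k in seq_along(network$layers)) {
    network$layers[[k]]$W1 <- p[[paste0("W1_", k)]]
    network$layers[[k]]$b1 <- p[[paste0("b1_", k)]]
  }
  network$softmax$W <- p$W_soft
  network$softmax$b <- p$b_soft
  network
}

#' Supervised fine-tuning of a stacked network
#'
#' Joint cross-entropy backpropagation through all layers with the shared
#' monotone optimizer; the training loss after fine-tuning never exceeds the
#' loss before. Zero iterations return the network unchanged.
#'
#' @param network A `stacked_network`.
#' @param X Raw training inputs, rows x input-dims.
#' @param labels Per-row class factor.
#' @param hyper An [sae_hyperparams()] providing `finetune_iterations`,
#'   `learn_rate` and `momentum`.
#' @return The fine-tuned `stacked_network`.
#' @export
fine_tune <- function(network, X, labels, hyper) {
  stopifnot(inherits(network, "stacked_network"))
  if (ncol(X) != network$architecture[1]) {
    stop("`X` column count does not match the network input size", call. = FALSE)
  }
  if (hyper$finetune_iterations == 0L) return(network)
  fn <- function(p) {
    net <- net_set_par(network, p)
    cg <- network_cost_grad(net, X, labels)
    gl <- list()
    for (k in seq_along(net$layers)) {
      gl[[paste0("W1_", k)]] <- cg$grad$layers[[k]]$W1
      gl[[paste0("b1_", k)]] <- cg$grad$layers[[k]]$b1
    }
    gl$W_soft <- cg$grad$softmax$W
    gl$b_soft <- cg$grad$softmax$b
    list(cost = cg$cost, grad = gl)
  }
  fit <- gd_momentum(net_par(network), fn, hyper$finetune_iterations,
                     hyper$learn_rate, hyper$momentum)
  out <- net_set_par(network, fit$par)
  attr(out, "finetune_trace") <- fit$trace
  out
}

#' Classify feature vectors with a stacked network
#'
#' Deterministic argmax of the softmax output; exact probability ties break
#' to the lower class index (the first class level, i.e. non-target).
#'
#' @param object A `stacked_network`.
#' @param newdata Matrix rows x input-dims, or an `erp_features`.
#' @param ... Unused.
#' @return List with `class` (factor) and `prob` (rows x classes matrix).
#' @export
predict.stacked_network <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "erp_features")) newdata$values else newdata
  if (!is.matrix(X) || ncol(X) != object$architecture[1]) {
    stop("`newdata` column count does not match the network input size",
         call. = FALSE)
  }
  P <- network_forward(object, X)$probs
  idx <- apply(P, 1, which.max)   # ties resolve to the lower index
  list(class = factor(object$class_levels[idx], levels = object$class_levels),
       prob = P)
}

# per-column affine map of the training features onto [0.1, 0.9]; constant
# columns map to 0.5. Stored in the network and re-applied at inference.
fit_input_scaling <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  a <- ifelse(rng > 0, 0.8 / rng, 0)
  b <- ifelse(rng > 0, 0.1 - a * lo, 0.5)
  list(a = a, b = b)
}

#' Train the full stacked sparse autoencoder classifier
#'
#' End-to-end training at the study design: per-column affine rescaling of
#' the features to `[0.1, 0.9]` (stored for inference), greedy layer-wise
#' pretraining of the autoencoder stack, softmax training on the deepest
#' code, and joint supervised fine-tuning.
#'
#' @param features An `erp_features` (typically unit-norm rows) or a matrix
#'   passed with `labels`.
#' @param hyper An [sae_hyperparams()].
#' @param seed Integer master seed.
#' @param labels Required when `features` is a bare matrix.
#' @return A fine-tuned `stacked_network`.
#' @export
train_sae <- function(features, hyper = sae_hyperparams(), seed,
                      labels = NULL) {
  if (inherits(features, "erp_features")) {
    X <- features$values
    labels <- features$labels
  } else {
    X <- features
    if (is.null(labels)) stop("`labels` required with a bare matrix", call. = FALSE)
  }
  sc <- fit_input_scaling(X)
  Xs <- sweep(sweep(X, 2, sc$a, `*`), 2, sc$b, `+`)
  layers <- train_stack(Xs, hyper, derive_seed(seed, 11))
  H <- Xs
  for (l in layers) H <- encode(l, H)
  soft <- train_softmax(H, labels, hyper$softmax_iterations,
                        derive_seed(seed, 77),
                        hyper$learn_rate, hyper$momentum)
  net <- stacked_network(layers, soft, scaling = sc, input_dim = ncol(X))
  net <- fine_tune(net, X, labels, hyper)
  attr(net, "model") <- "sae"
  net
}
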