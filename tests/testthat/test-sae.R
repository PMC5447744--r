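# Sparse autoencoder core: objective structure, analytic gradients against
# central finite differences, greedy stacking, softmax head, fine-tuning,
# and the prediction contract.

ae_hp <- function(...) sae_hyperparams(layer_sizes = 3, max_pretrain_epochs = 0, ...)

test_that("autoencoder cost vanishes for a perfect sparse reconstruction", {
  # constant 0.5 input with zero weights: H = Xhat = 0.5, rho_hat = rho = 0.5
  hp <- ae_hp(l2_weight = 0, sparsity_weight = 4, sparsity_target = 0.5)
  layer <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
                W2 = matrix(0, 4, 3), b2 = rep(0, 4))
  X <- matrix(0.5, 6, 4)
  out <- ae_cost_grad(layer, X, hp)
  expect_equal(out$cost, 0)
  expect_equal(out$kl, 0)
})

test_that("sparsity penalty is zero iff mean activations hit the target", {
  hp <- ae_hp(l2_weight = 0, sparsity_weight = 2, sparsity_target = 0.3)
  layer <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
                W2 = matrix(0, 4, 3), b2 = rep(0, 4))
  X <- matrix(0.5, 5, 4)
  expect_gt(ae_cost_grad(layer, X, hp)$kl, 0)       # rho_hat = 0.5 != 0.3
  hp2 <- ae_hp(l2_weight = 0, sparsity_weight = 2, sparsity_target = 0.5)
  expect_equal(ae_cost_grad(layer, X, hp2)$kl, 0)
})

test_that("with no regularization the cost reduces to reconstruction MSE", {
  set.seed(40)
  hp <- ae_hp(l2_weight = 0, sparsity_weight = 0)
  X <- matrix(runif(5 * 6, 0.2, 0.8), 5, 6)
  layer <- train_autoencoder(X, 3, hp, seed = 1)
  out <- ae_cost_grad(layer, X, hp)
  expect_equal(out$cost, out$mse)
})

test_that("autoencoder gradients match central finite differences", {
  set.seed(41)
  hp <- ae_hp(l2_weight = 0.01, sparsity_weight = 0.7, sparsity_target = 0.2)
  X <- matrix(runif(5 * 6, 0.1, 0.9), 5, 6)
  layer <- train_autoencoder(X, 3, hp, seed = 2)   # 0 epochs: random init
  cg <- ae_cost_grad(layer, X, hp)
  rel <- max_grad_rel_error(unclass(layer),
                            function(p) ae_cost_grad(p, X, hp)$cost,
                            cg$grad)
  expect_lt(rel, 1e-6)
})

test_that("softmax gradients match central finite differences", {
  set.seed(42)
  H <- matrix(runif(8 * 4), 8, 4)
  Y <- diag(2)[sample(1:2, 8, replace = TRUE), ]
  par <- list(W = matrix(rnorm(2 * 4, sd = 0.3), 2, 4), b = rnorm(2, sd = 0.1))
  cg <- p300sae:::softmax_cost_grad(par, H, Y)
  rel <- max_grad_rel_error(par,
                            function(p) p300sae:::softmax_cost_grad(p, H, Y)$cost,
                            cg$grad)
  expect_lt(rel, 1e-6)
})

test_that("full-network gradients match finite differences on a 5-4-3-2 toy", {
  set.seed(43)
  X <- matrix(rnorm(10 * 5), 10, 5)
  labels <- factor(rep(c("nontarget", "target"), 5),
                   levels = c("nontarget", "target"))
  hp <- sae_hyperparams(layer_sizes = c(4, 3), max_pretrain_epochs = 0,
                        softmax_iterations = 0, finetune_iterations = 0)
  net <- train_sae(X, hp, seed = 3, labels = labels)
  expect_identical(architecture_string(net), "5-4-3-2")
  par <- p300sae:::net_par(net)
  cost_of <- function(p) {
    p300sae:::network_cost_grad(p300sae:::net_set_par(net, p), X, labels)$cost
  }
  cg <- p300sae:::network_cost_grad(net, X, labels)
  grad <- list()
  for (k in seq_along(net$layers)) {
    grad[[paste0("W1_", k)]] <- cg$grad$layers[[k]]$W1
    grad[[paste0("b1_", k)]] <- cg$grad$layers[[k]]$b1
  }
  grad$W_soft <- cg$grad$softmax$W
  grad$b_soft <- cg$grad$softmax$b
  expect_lt(max_grad_rel_error(par, cost_of, grad), 1e-6)
})

test_that("training is monotone, deterministic, and respects zero epochs", {
  set.seed(44)
  X <- matrix(runif(20 * 8, 0.1, 0.9), 20, 8)
  hp <- sae_hyperparams(layer_sizes = 4, max_pretrain_epochs = 50)
  l1 <- train_autoencoder(X, 4, hp, seed = 7)
  l2 <- train_autoencoder(X, 4, hp, seed = 7)
  expect_identical(l1$W1, l2$W1)
  trace <- attr(l1, "cost_trace")
  kept <- trace[trace > 0]
  expect_true(all(diff(kept) <= 1e-9))   # monotone non-increasing cost

  hp0 <- sae_hyperparams(layer_sizes = 4, max_pretrain_epochs = 0)
  init1 <- train_autoencoder(X, 4, hp0, seed = 7)
  init2 <- train_autoencoder(X, 4, hp0, seed = 7)
  expect_identical(init1$W1, init2$W1)
  # initial cost of the trained run is the cost of the init
  expect_gte(ae_cost_grad(init1, X, hp)$cost, ae_cost_grad(l1, X, hp)$cost)

  expect_error(train_autoencoder(X, 8, hp, seed = 1), "strictly below")
  expect_error(train_autoencoder(X[1, , drop = FALSE], 4, hp, seed = 1),
               "at least 2 rows")
})

test_that("a plain autoencoder recovers a rank-2 latent structure", {
  set.seed(45)
  U <- matrix(rnorm(60 * 2), 60, 2)
  V <- matrix(rnorm(2 * 10), 2, 10)
  X <- U %*% V
  X <- 0.2 + 0.6 * (X - min(X)) / (max(X) - min(X))   # squash into (0.2, 0.8)
  hp <- sae_hyperparams(layer_sizes = 2, l2_weight = 0, sparsity_weight = 0,
                        max_pretrain_epochs = 2000, learn_rate = 1)
  layer <- train_autoencoder(X, 2, hp, seed = 9)
  mse <- ae_cost_grad(layer, X, hp)$mse / ncol(X)     # per element
  total_var <- mean(apply(X, 2, var))
  # best rank-2 linear oracle: centered X is exactly rank 2, residual 0
  sv <- svd(scale(X, scale = FALSE))
  expect_lt(sum(sv$d[-(1:2)]^2), 1e-18)
  expect_lt(mse, 0.2 * total_var)
})

test_that("encoding applies the logistic map with the layer parameters", {
  layer <- list(W1 = matrix(0, 3, 2), b1 = rep(0, 3))
  expect_true(all(encode(layer, matrix(rnorm(10), 5, 2)) == 0.5))

  layer2 <- list(W1 = matrix(c(1, -1, 0.5, 2), 2, 2), b1 = c(0.1, -0.2))
  X <- matrix(c(0.3, 0.7, -0.4, 0.2), 2, 2)
  expected <- 1 / (1 + exp(-(X %*% t(layer2$W1) +
                             matrix(layer2$b1, 2, 2, byrow = TRUE))))
  expect_equal(encode(layer2, X), expected)

  big <- encode(layer2, matrix(rnorm(20, sd = 5), 10, 2))
  expect_true(all(big > 0 & big < 1))
  expect_error(encode(layer2, matrix(0, 2, 3)), "input dimension")
})

test_that("greedy stacking trains each layer on the previous encoding", {
  set.seed(46)
  X <- matrix(runif(30 * 16, 0.1, 0.9), 30, 16)
  hp <- sae_hyperparams(layer_sizes = c(8, 5, 3), max_pretrain_epochs = 5)
  stack <- train_stack(X, hp, seed = 4)
  expect_length(stack, 3)
  expect_identical(dim(stack[[1]]$W1), c(8L, 16L))
  expect_identical(dim(stack[[2]]$W1), c(5L, 8L))   # fed by layer-1 output
  expect_identical(dim(stack[[3]]$W1), c(3L, 5L))
  h <- encode(stack[[1]], X)
  expect_identical(ncol(encode(stack[[2]], h)), 5L)

  hp1 <- sae_hyperparams(layer_sizes = 8, max_pretrain_epochs = 5)
  expect_identical(train_stack(X, hp1, seed = 4)[[1]]$W1,
                   train_autoencoder(X, 8, hp1, p300sae:::derive_seed(4, 1))$W1)
  hp_bad <- sae_hyperparams(layer_sizes = c(8, 9), max_pretrain_epochs = 1)
  expect_error(train_stack(X, hp_bad, seed = 1), "strictly decreasing")
})

test_that("softmax head separates separable data and returns probabilities", {
  toy <- toy_features(n_per_class = 25, d = 2, sep = 6, seed = 47)
  soft <- train_softmax(toy$X, toy$labels, iterations = 300, seed = 5)
  P <- p300sae:::softmax_probs(soft$W, soft$b, toy$X)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  pred <- soft$class_levels[apply(P, 1, which.max)]
  expect_identical(mean(pred == as.character(toy$labels)), 1)
  expect_error(train_softmax(toy$X, rep("target", 50), 10, 1), "two classes")
})

test_that("fine-tuning is a no-op at zero iterations and helps validation", {
  toy <- toy_features(n_per_class = 40, d = 6, sep = 4, seed = 48)
  hp <- sae_hyperparams(layer_sizes = c(4, 3), max_pretrain_epochs = 30,
                        softmax_iterations = 50, finetune_iterations = 0)
  net0 <- train_sae(toy$X, hp, seed = 6, labels = toy$labels)
  expect_identical(fine_tune(net0, toy$X, toy$labels, hp), net0)

  holdout <- toy_features(n_per_class = 40, d = 6, sep = 4, seed = 49)
  acc <- function(net) mean(predict(net, holdout$X)$class == holdout$labels)
  hp_ft <- sae_hyperparams(layer_sizes = c(4, 3), max_pretrain_epochs = 30,
                           softmax_iterations = 50, finetune_iterations = 100)
  net1 <- fine_tune(net0, toy$X, toy$labels, hp_ft)
  expect_gte(acc(net1), acc(net0))
  # fine-tuning never increases the training loss
  expect_lte(p300sae:::network_cost_grad(net1, toy$X, toy$labels)$cost,
             p300sae:::network_cost_grad(net0, toy$X, toy$labels)$cost)
})

test_that("prediction is deterministic, tie-broken low, and row-independent", {
  set.seed(50)
  hp <- sae_hyperparams(layer_sizes = c(4, 3), max_pretrain_epochs = 5,
                        softmax_iterations = 5, finetune_iterations = 5)
  toy <- toy_features(n_per_class = 20, d = 6, sep = 3, seed = 51)
  net <- train_sae(toy$X, hp, seed = 8, labels = toy$labels)

  # zeroed softmax gives exact 0.5/0.5 ties -> first level (nontarget)
  net_tie <- net
  net_tie$softmax$W[] <- 0
  net_tie$softmax$b[] <- 0
  pred_tie <- predict(net_tie, toy$X)
  expect_true(all(pred_tie$prob == 0.5))
  expect_true(all(pred_tie$class == "nontarget"))

  perm <- sample(nrow(toy$X))
  p_all <- predict(net, toy$X)
  p_perm <- predict(net, toy$X[perm, ])
  expect_identical(as.character(p_all$class)[perm], as.character(p_perm$class))
  expect_error(predict(net, toy$X[, 1:3]), "input size")
})
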