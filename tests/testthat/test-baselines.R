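# MLP and shrinkage-LDA baselines: shared forward pass with the stacked
# network, classical-LDA and Bayes-rate oracles, and decision-rule contracts.

test_that("MLP echoes its architecture and learns separable data", {
  toy <- toy_features(n_per_class = 30, d = 6, sep = 5, seed = 60)
  mlp <- train_mlp(toy$X, layer_sizes = c(4, 3), iterations = 400, seed = 1,
                   labels = toy$labels)
  expect_identical(architecture_string(mlp), "6-4-3-2")
  acc <- mean(predict(mlp, toy$X)$class == toy$labels)
  expect_gte(acc, 0.95)
  mlp2 <- train_mlp(toy$X, layer_sizes = c(4, 3), iterations = 400, seed = 1,
                    labels = toy$labels)
  expect_identical(mlp, mlp2)
  expect_error(train_mlp(toy$X, c(4, 3), 10, 1,
                         labels = rep("target", nrow(toy$X))), "two classes")
})

test_that("MLP and SAE share the forward-pass code path", {
  toy <- toy_features(n_per_class = 20, d = 6, sep = 3, seed = 61)
  hp <- sae_hyperparams(layer_sizes = c(4, 3), max_pretrain_epochs = 10,
                        softmax_iterations = 20, finetune_iterations = 20)
  sae <- train_sae(toy$X, hp, seed = 2, labels = toy$labels)
  mlp <- train_mlp(toy$X, c(4, 3), iterations = 20, seed = 3, labels = toy$labels)
  # transplant the SAE's parameters into the MLP model object
  mlp$layers <- sae$layers
  mlp$softmax <- sae$softmax
  mlp$scaling <- sae$scaling
  expect_identical(predict(mlp, toy$X), predict(sae, toy$X))
})

test_that("full shrinkage reduces LDA to the class-mean direction", {
  toy <- toy_features(n_per_class = 50, d = 5, sep = 2, seed = 62)
  m <- train_shrinkage_lda(toy$X, toy$labels, shrinkage = 1)
  dm <- colMeans(toy$X[toy$labels == "target", ]) -
        colMeans(toy$X[toy$labels == "nontarget", ])
  cosine <- sum(m$w * dm) / sqrt(sum(m$w^2) * sum(dm^2))
  expect_equal(cosine, 1, tolerance = 1e-12)
})

test_that("zero shrinkage equals classical LDA solved directly", {
  set.seed(63)
  X <- matrix(rnorm(60 * 5), 60, 5)
  X[31:60, ] <- X[31:60, ] + 1
  y <- factor(rep(c("nontarget", "target"), each = 30),
              levels = c("nontarget", "target"))
  m <- train_shrinkage_lda(X, y, shrinkage = 0)
  mu0 <- colMeans(X[1:30, ]); mu1 <- colMeans(X[31:60, ])
  Z <- rbind(sweep(X[1:30, ], 2, mu0), sweep(X[31:60, ], 2, mu1))
  S <- crossprod(Z) / (60 - 1)
  w_ref <- solve(S, mu1 - mu0)                        # closed-form oracle
  expect_equal(m$w, as.numeric(w_ref), tolerance = 1e-10)
  expect_equal(m$threshold, sum(w_ref * (mu0 + mu1)) / 2, tolerance = 1e-10)
})

test_that("shrinkage LDA approaches the Bayes rate on spherical Gaussians", {
  set.seed(64)
  d <- 10; n <- 2000
  draw <- function() {
    X <- rbind(matrix(rnorm(n * d), n, d), matrix(rnorm(n * d), n, d))
    X[1:n, 1] <- X[1:n, 1] - 2
    X[(n + 1):(2 * n), 1] <- X[(n + 1):(2 * n), 1] + 2   # separation 4 sd
    X
  }
  y <- factor(rep(c("nontarget", "target"), each = n),
              levels = c("nontarget", "target"))
  m <- train_shrinkage_lda(draw(), y)
  acc <- mean(predict(m, draw())$class == y)
  bayes <- pnorm(2)                                     # analytic Gaussian oracle
  expect_lt(abs(acc - bayes), 0.02)
})

test_that("analytic shrinkage intensity stays in [0,1] and conditions the estimate", {
  for (s in 1:5) {
    toy <- toy_features(n_per_class = 15, d = 8, sep = 1, seed = 70 + s)
    m <- train_shrinkage_lda(toy$X, toy$labels)
    expect_gte(m$shrinkage_intensity, 0)
    expect_lte(m$shrinkage_intensity, 1)
  }
  toy <- toy_features(n_per_class = 12, d = 8, sep = 1, seed = 65)
  raw <- train_shrinkage_lda(toy$X, toy$labels, shrinkage = 0)
  auto <- train_shrinkage_lda(toy$X, toy$labels)
  # recompute the two covariance estimates to compare conditioning
  lv <- levels(toy$labels)
  Z <- toy$X
  for (l in lv) {
    Z[toy$labels == l, ] <- sweep(toy$X[toy$labels == l, ], 2,
                                  colMeans(toy$X[toy$labels == l, ]))
  }
  S <- crossprod(Z) / (nrow(Z) - 1)
  nu <- mean(diag(S))
  g <- auto$shrinkage_intensity
  S_shrunk <- (1 - g) * S + g * diag(nu, ncol(S))
  expect_lte(kappa(S_shrunk, exact = TRUE), kappa(S, exact = TRUE))
  ev <- eigen(S_shrunk, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)                                  # positive definite
})

test_that("LDA decisions are affine-invariant with a midpoint tie to nontarget", {
  toy <- toy_features(n_per_class = 30, d = 4, sep = 3, seed = 66)
  m <- train_shrinkage_lda(toy$X, toy$labels)
  mid <- (m$class_means[1, ] + m$class_means[2, ]) / 2
  at_mid <- predict(m, matrix(mid, 1))
  expect_equal(at_mid$decision_value, 0, tolerance = 1e-10)
  expect_identical(as.character(at_mid$class), "nontarget")

  shift <- rep(3.7, 4)
  m2 <- train_shrinkage_lda(sweep(toy$X, 2, shift, `+`), toy$labels)
  p1 <- predict(m, toy$X)$class
  p2 <- predict(m2, sweep(toy$X, 2, shift, `+`))$class
  expect_identical(p1, p2)
  expect_error(predict(m, toy$X[, 1:2]), "does not match")
  expect_error(train_shrinkage_lda(toy$X, rep("target", 60)), "two classes")
})

test_that("a hand-computed two-dimensional LDA case matches", {
  # both classes are 2x2 grids: centered points (+-1, +-1), so the pooled
  # covariance is crossprod(Z)/(n-1) = diag(8, 8)/7 and w = S^-1 (4, 0)
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2),
             c(4, 0), c(6, 0), c(4, 2), c(6, 2))
  y <- factor(rep(c("nontarget", "target"), each = 4),
              levels = c("nontarget", "target"))
  m <- train_shrinkage_lda(X, y, shrinkage = 0)
  expect_equal(m$w, c(4 * 7 / 8, 0), tolerance = 1e-12)   # direct arithmetic
  expect_equal(m$threshold, (4 * 7 / 8) * 3, tolerance = 1e-12)
  pred <- predict(m, rbind(c(5, 1), c(1, 1), c(3, 1)))
  expect_identical(as.character(pred$class), c("target", "nontarget", "nontarget"))
})
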