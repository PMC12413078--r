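test_that("loss and penalty terms match their definitions", {
  expect_equal(mse_loss(c(1, -1), c(1, -1)), 0)
  expect_equal(mse_loss(c(0.5, -1), c(1, -1)), 0.125)
  expect_equal(mse_loss(0, 1), 1)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_equal(interpretability_penalty(matrix(c(0.3, -0.1, 0), 1)), 0.10)
  expect_equal(interpretability_penalty(matrix(0, 4, 3)), 0)
  expect_equal(interpretability_penalty(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(resource_penalty(c(0.05, 0.05, -2)), 2)
  expect_equal(resource_penalty(rep(-1, 5)), 0)
  expect_equal(gate_backward_surrogate(0, 1), 0.25) # R2 gradient at phi = 0
})

test_that("total objective combines the terms with the configured weights", {
  cfg <- training_config(lambda1 = 1, lambda2 = 0.005)
  # L = 0.125, R1 = 0.10, R2 = 2 -> 0.125 + 0.10 + 0.01 = 0.235
  scores <- c(0.5, -1); labels <- c(1, -1)
  contrib <- rbind(c(0.3, -0.1, 0), c(0.1, -0.2, sqrt(0.1 - 0.05)))
  # craft contributions with batch-mean sum-of-squares 0.10
  contrib <- matrix(0, 2, 3); contrib[1, ] <- c(0.3, -0.1, 0)
  contrib[2, ] <- c(sqrt(0.1), 0, 0)
  phi <- c(0.05, 0.05, -2)
  expect_equal(total_objective(scores, labels, contrib, phi, cfg), 0.235)
  cfg0 <- training_config(lambda1 = 0, lambda2 = 0)
  expect_equal(total_objective(scores, labels, contrib, phi, cfg0),
               mse_loss(scores, labels))
  cfg_no_r1 <- training_config(lambda1 = 1, lambda2 = 0.005, use_R1 = FALSE)
  expect_equal(total_objective(scores, labels, contrib, phi, cfg_no_r1),
               0.125 + 0.01)
})

test_that("balanced sampler equalizes the class draw and is seeded", {
  labels <- c(rep(1, 226), rep(-1, 774))
  idx <- balanced_sampler(labels, seed = 1, n_draws = 1e5)
  frac <- mean(labels[idx] == 1)
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.52)
  expect_identical(balanced_sampler(labels, seed = 9),
                   balanced_sampler(labels, seed = 9))
  expect_error(balanced_sampler(rep(1, 10), seed = 1), "sampler error")
  # balanced labels: both classes drawn near-uniformly
  lab2 <- rep(c(1, -1), 500)
  idx2 <- balanced_sampler(lab2, seed = 2, n_draws = 2e4)
  expect_lt(abs(mean(lab2[idx2] == 1) - 0.5), 0.02)
})

test_that("compiled gradients match finite differences of the objective", {
  withr::with_seed(42, {
    n <- 8; M <- 3; C <- 4
    X <- matrix(rnorm(n * M), n, M)
    y <- sample(c(-1, 1), n, TRUE)
    m0 <- random_model(M, C, seed = 3, phi = c(0.05, -0.4, 0.7))
    g <- one_step_gradients(m0, X, y, lambda1 = 0.7, lambda2 = 0.3)
    h <- 1e-5
    numgrad <- function(setter) {
      (full_objective(setter(m0, h), X, y, 0.7, 0.3) -
         full_objective(setter(m0, -h), X, y, 0.7, 0.3)) / (2 * h)
    }
    for (j in 1:M) for (c1 in 1:C) {
      expect_equal(g$theta1[c1, j],
                   numgrad(function(m, e) { m$theta1[c1, j] <- m$theta1[c1, j] + e; m }),
                   tolerance = 1e-4)
      expect_equal(g$theta3[c1, j],
                   numgrad(function(m, e) { m$theta3[c1, j] <- m$theta3[c1, j] + e; m }),
                   tolerance = 1e-4)
      for (c2 in 1:C) {
        expect_equal(g$theta2[c1, c2, j],
                     numgrad(function(m, e) { m$theta2[c1, c2, j] <- m$theta2[c1, c2, j] + e; m }),
                     tolerance = 1e-4)
      }
    }
    expect_equal(g$beta0,
                 numgrad(function(m, e) { m$beta0 <- m$beta0 + e; m }),
                 tolerance = 1e-4)
  })
})

test_that("gate logits receive the straight-through surrogate gradient", {
  withr::with_seed(5, {
    n <- 10; M <- 4; C <- 4
    X <- matrix(rnorm(n * M), n, M)
    y <- sample(c(-1, 1), n, TRUE)
    m0 <- random_model(M, C, seed = 7, phi = c(0.3, -0.2, 0.05, 1))
    g <- one_step_gradients(m0, X, y, lambda1 = 0.5, lambda2 = 0.2)
    # independent R computation of the surrogate: dz through the forward
    # (binary-gated) activations, times x, times sigma'(phi), plus the R2
    # term lambda2 * sigma'(phi)
    pr <- predict_scores(m0, X)
    gate <- as.numeric(m0$phi >= 0)
    Z <- sweep(X, 2, gate, "*")
    dout <- matrix(2 / n * (pr$scores - y), n, M) +
      0.5 * 2 / n * pr$contributions
    dpre <- dout * (1 - pr$contributions^2)
    kap <- deepgam:::model_kappas(m0)
    dz <- dpre * (sweep((Z > 0) * 1, 2, kap[1, ], "*") -
                    sweep((Z < 0) * 1, 2, kap[2, ], "*"))
    sgd <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }
    ref <- (colSums(dz * X) + 0.2) * sgd(m0$phi)
    expect_equal(g$phi, ref, tolerance = 1e-6, ignore_attr = TRUE)
    # dead feature (phi = -0.2): no z-path, only the R2 surrogate term
    expect_equal(g$phi[2], 0.2 * sgd(-0.2), tolerance = 1e-9)
    # frozen gates receive nothing
    gf <- one_step_gradients(m0, X, y, freeze_phi = TRUE)
    expect_identical(gf$phi, rep(0, M))
  })
})

test_that("a small full-batch SGD step decreases the MSE", {
  withr::with_seed(11, {
    wins <- 0
    for (rep in 1:20) {
      n <- 30; M <- 3
      X <- matrix(rnorm(n * M), n, M)
      y <- ifelse(X[, 1] + rnorm(n, sd = 0.3) > 0, 1, -1)
      if (length(unique(y)) < 2) next
      m0 <- random_model(M, 8, seed = rep, phi = rep(0.5, M))
      cfg <- training_config(learning_rate = 1e-3, batch_size = n,
                             epochs = 1, lambda1 = 0, lambda2 = 0,
                             weight_decay = 0, C = 8, seed = rep,
                             rebalance = FALSE)
      fit <- train(m0, deepgam_dataset(X, y), NULL, cfg)
      before <- mse_loss(predict_scores(m0, X)$scores, y)
      after <- mse_loss(predict_scores(fit$model, X)$scores, y)
      if (after < before) wins <- wins + 1
    }
    expect_equal(wins, 20)
  })
})

test_that("training is deterministic and records one history row per epoch", {
  ds <- tiny_dataset(80, 5, seed = 21)
  sc <- fit_standardizer(ds)
  std <- apply_standardizer(ds, sc)
  cfg <- training_config(epochs = 7, C = 8, seed = 4)
  f1 <- train(init_model(5, C = 8, seed = 4), std, NULL, cfg)
  f2 <- train(init_model(5, C = 8, seed = 4), std, NULL, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$theta2, f2$model$theta2)
  expect_identical(f1$model$phi, f2$model$phi)
  expect_equal(nrow(f1$history), 7)
  expect_true(all(f1$history$alive_count >= 0 & f1$history$alive_count <= 5))
  expect_true(all(is.na(f1$history$val_f1)))
})

test_that("validation F1 is tracked per epoch when a split is supplied", {
  ds <- tiny_dataset(100, 4, seed = 31)
  sp <- split_dataset(ds, 0.3, seed = 1)
  sc <- fit_standardizer(sp$train)
  cfg <- training_config(epochs = 5, C = 8, seed = 2)
  fit <- train(init_model(4, C = 8, seed = 2),
               apply_standardizer(sp$train, sc),
               apply_standardizer(sp$test, sc), cfg)
  expect_true(all(is.finite(fit$history$val_f1)))
  expect_true(all(fit$history$val_f1 >= 0 & fit$history$val_f1 <= 1))
  # the recorded final-epoch F1 matches an independent evaluation
  te <- apply_standardizer(sp$test, sc)
  rep <- evaluate_scores(predict_scores(fit$model, te$features,
                                        apply_scaler = FALSE)$scores,
                         te$labels)
  expect_equal(fit$history$val_f1[5], rep$f1, tolerance = 1e-12)
})

test_that("R1 shrinks held-out contribution magnitudes in paired runs", {
  wins <- 0
  for (seed in 1:10) {
    sim <- make_classification(300, 2, 4, seed = seed)
    sp <- split_dataset(sim$data, 0.3, seed = seed)
    sc <- fit_standardizer(sp$train)
    tr <- apply_standardizer(sp$train, sc)
    teX <- sweep(sweep(sp$test$features, 2, sc$mean), 2, sc$sd, "/")
    mags <- sapply(c(1, 0), function(l1) {
      cfg <- training_config(epochs = 15, C = 32, lambda1 = l1, seed = seed)
      fit <- train(init_model(6, C = 32, seed = seed), tr, NULL, cfg)
      mean(abs(predict_scores(fit$model, teX)$contributions))
    })
    if (mags[1] < mags[2]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("gate logits decline under resource pressure and histories export", {
  # labels independent of the features: no z-path force, so the resource
  # regularizer's surrogate gradient pushes every logit strictly down
  withr::with_seed(41, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep(c(1, -1), 30)
  })
  ds <- deepgam_dataset(X, y)
  std <- apply_standardizer(ds, fit_standardizer(ds))
  cfg <- training_config(epochs = 10, C = 8, seed = 3)
  fit <- train(init_model(4, C = 8, seed = 3), std, NULL, cfg)
  expect_true(all(fit$model$phi < 0.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_history(fit$history, path)
  back <- read.csv(path)
  expect_equal(back$objective, fit$history$objective, tolerance = 1e-12)
  expect_equal(back$alive_count, fit$history$alive_count)
})
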