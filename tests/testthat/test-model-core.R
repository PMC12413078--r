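test_that("gate forward follows the phi >= 0 rule with the tie alive", {
  expect_equal(gate_forward(0.05), 1)
  expect_equal(gate_forward(-3), 0)
  expect_equal(gate_forward(0), 1)
  expect_equal(gate_forward(c(-0.1, 0.3)), c(0, 1))
  # sigma(0.05) >= 0.5 and sigma(-3) < 0.5 back the rule
  expect_gte(1 / (1 + exp(-0.05)), 0.5)
  expect_lt(1 / (1 + exp(3)), 0.5)
})

test_that("gate surrogate equals the sigmoid derivative times upstream", {
  expect_equal(gate_backward_surrogate(0, 1), 0.25)
  # sigma'(0.05) = sigma(0.05) * (1 - sigma(0.05)) = 0.2498438
  expect_equal(gate_backward_surrogate(0.05, 2), 0.4996876, tolerance = 1e-6)
  # matches central finite differences of sigma over [-10, 10]
  sig <- function(x) 1 / (1 + exp(-x))
  for (phi in seq(-10, 10, by = 0.5)) {
    h <- 1e-6
    fd <- (sig(phi + h) - sig(phi - h)) / (2 * h)
    expect_lt(abs(gate_backward_surrogate(phi, 1) - fd), 1e-6)
  }
  # monotone gate, positive surrogate everywhere
  phis <- seq(-10, 10, length.out = 101)
  expect_true(all(diff(gate_forward(phis)) >= 0))
  expect_true(all(gate_backward_surrogate(phis, 1) > 0))
})

test_that("shape network is zero at zero, bounded, and matches hand traces", {
  net <- list(theta1 = 1, theta2 = matrix(1, 1, 1), theta3 = 1)
  expect_equal(shape_forward(0, net, use_tanh = TRUE), 0)
  expect_equal(shape_forward(0.5, net, use_tanh = TRUE), tanh(0.5))
  expect_equal(shape_forward(0.5, net, use_tanh = TRUE), 0.462117,
               tolerance = 1e-6)
  expect_equal(shape_forward(-2, net, use_tanh = TRUE), 0) # ReLU kills it
  m <- random_model(4, 8, seed = 2)
  for (j in 1:4) {
    expect_equal(shape_forward(0, get_shape_network(m, j)), 0)
  }
})

test_that("collapsed half-line forward equals the direct composition", {
  m <- random_model(6, 16, seed = 5, phi = rep(1, 6))
  z <- seq(-5, 5, length.out = 31)
  for (j in 1:6) {
    net <- get_shape_network(m, j)
    direct <- naive_shape_forward(z, net$theta1, net$theta2, net$theta3)
    X <- matrix(0, length(z), 6); X[, j] <- z
    fast <- predict_scores(m, X)$contributions[, j]
    expect_equal(fast, direct, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("contributions are bounded in (-1, 1) even for extreme inputs", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      C <- sample(c(1, 4, 16), 1)
      m <- random_model(5, C, seed = rep)
      m$theta1 <- m$theta1 * 10
      m$theta3 <- m$theta3 * 10
      X <- matrix(rnorm(100 * 5, sd = 100), 100, 5)
      contrib <- predict_scores(m, X)$contributions
      # the tanh bound; saturation can round to exactly 1 in doubles
      expect_true(all(abs(contrib) <= 1))
      # strictly inside (-1, 1) away from saturation
      plain <- random_model(5, C, seed = rep + 500)
      mod <- predict_scores(plain, matrix(rnorm(50 * 5), 50, 5))
      expect_true(all(abs(mod$contributions) < 1))
    }
  })
})

test_that("forward is additive: score equals beta0 plus the contribution sum", {
  m <- random_model(7, 8, seed = 3)
  m$beta0 <- 0.37
  withr::with_seed(4, {
    for (rep in 1:50) {
      x <- rnorm(7, sd = 3)
      f <- model_forward(x, m)
      expect_identical(f$score, m$beta0 + sum(f$contributions))
      # single-feature decomposition oracle
      parts <- vapply(1:7, function(j) {
        x0 <- rep(0, 7); x0[j] <- x[j]
        sum(model_forward(x0, m)$contributions)
      }, numeric(1))
      expect_equal(f$score, m$beta0 + sum(parts), tolerance = 1e-12)
    }
  })
  expect_error(model_forward(rnorm(3), m), "dimension mismatch")
})

test_that("dead gates contribute exactly zero", {
  m <- random_model(5, 8, seed = 6, phi = c(0.5, -1, 0.2, -0.3, 0))
  x <- rnorm(5, sd = 2)
  f <- model_forward(x, m)
  expect_identical(unname(f$contributions[c(2, 4)]), c(0, 0))
  m$phi <- rep(-1, 5)
  for (rep in 1:5) {
    expect_identical(model_forward(rnorm(5, sd = 10), m)$score, m$beta0)
  }
  # |score - beta0| is bounded by the alive count (tanh bound)
  withr::with_seed(7, {
    for (rep in 1:100) {
      m2 <- random_model(6, 4, seed = rep)
      f2 <- model_forward(rnorm(6, sd = 5), m2)
      expect_lte(abs(f2$score - m2$beta0), sum(m2$phi >= 0))
    }
  })
})

test_that("classification threshold is strict", {
  expect_equal(classify(0.4, 0), 1)
  expect_equal(classify(-0.2, 0), -1)
  expect_equal(classify(0.7, 0.7), -1) # score == t is negative
})

test_that("alive_features ranks by phi descending with index tie-break", {
  m <- random_model(3, 4, seed = 1, phi = c(0.05, -1, 0.3))
  expect_identical(alive_features(m), c(3L, 1L))
  m$phi <- c(-0.2, -3, -0.1)
  expect_identical(alive_features(m), integer(0))
  m$phi <- c(0.2, 0.2, 0.1)
  expect_identical(alive_features(m), c(1L, 2L, 3L))
})

test_that("initialization follows the documented scheme", {
  m <- init_model(99, C = 16, phi_init = 0.05, seed = 1)
  expect_length(alive_features(m), 99)
  expect_true(all(m$theta3 == 0))
  expect_true(all(abs(m$theta1) <= 1))
  expect_true(all(abs(m$theta2) <= 1 / 4))
  expect_identical(m$beta0, 0)
  m2 <- init_model(10, C = 16, phi_init = -0.1, seed = 1)
  expect_length(alive_features(m2), 0)
  expect_identical(init_model(5, C = 8, seed = 42),
                   init_model(5, C = 8, seed = 42))
})

test_that("model save/load round trip is bit-faithful", {
  m <- random_model(4, 8, seed = 12)
  m$beta0 <- exp(1) / 7
  ds <- tiny_dataset(30, 4, seed = 13)
  m$scaler <- fit_standardizer(ds)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$theta1, m$theta1)
  expect_identical(back$theta2, m$theta2)
  expect_identical(back$theta3, m$theta3)
  expect_identical(back$phi, m$phi)
  expect_identical(back$beta0, m$beta0)
  expect_identical(back$mode, m$mode)
  expect_equal(back$scaler$mean, m$scaler$mean)
  expect_equal(back$scaler$sd, m$scaler$sd)
  withr::with_seed(77, {
    for (rep in 1:100) {
      x <- rnorm(4, sd = 3)
      expect_identical(model_forward(x, back)$score, model_forward(x, m)$score)
    }
  })
})

test_that("corrupt or mismatched model files are load errors", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- random_model(2, 4, seed = 1)
  save_model(m, path)
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), path)
  expect_error(load_model(path), "corrupt")
  jsonlite::write_json(list(format = "deepgam-model/999"), path,
                       auto_unbox = TRUE)
  expect_error(load_model(path), "unsupported")
})
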