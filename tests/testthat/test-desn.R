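test_that("reservoir initialization hits the spectral-radius target", {
  lay <- init_reservoir(3, 50, rho = 0.8, seed = 4)
  sr <- max(abs(eigen(lay$W, only.values = TRUE)$values))
  expect_equal(sr, 0.8, tolerance = 1e-6)
  lay2 <- init_reservoir(3, 50, rho = 0.8, seed = 4)
  expect_identical(lay$W, lay2$W)
  expect_identical(lay$W_in, lay2$W_in)
  one <- init_reservoir(1, 1, rho = 0.5, seed = 1)
  expect_equal(abs(as.numeric(one$W)), 0.5)
  expect_error(init_reservoir(1, 5, rho = 1.2), "rho")
})

test_that("the leaky state update matches closed-form evaluation", {
  lay <- init_reservoir(1, 1, rho = 0.5, seed = 1)
  lay$W_in[] <- 1; lay$W[] <- 0.5; lay$alpha <- 0.5
  expect_equal(reservoir_update(lay, 0, 1), tanh(1) * 1 + 0.5 * 0,
               tolerance = 1e-9)
  expect_equal(reservoir_update(lay, 0, 0), 0)
  # alpha = 1 removes the leak entirely
  lay$alpha <- 1
  x <- 0.3
  expect_equal(reservoir_update(lay, x, 1), tanh(1 + 0.5 * x), tolerance = 1e-12)
  # gained variant (gamma != 1): (1 - alpha*gamma) x + gamma f(...)
  lay$alpha <- 0.5; lay$gamma <- 2
  expect_equal(reservoir_update(lay, x, 1),
               (1 - 0.5 * 2) * x + 2 * tanh(1 + 0.5 * x), tolerance = 1e-12)
  expect_error(reservoir_update(lay, c(1, 2), 1), "dimensions")
})

test_that("trajectories match an independent step-by-step loop", {
  cfg <- desn_config(layers = 2, N_res = 15, alpha = 0.7, rho = 0.85,
                     encoding = "sequential", seed = 6)
  model <- phantomnet:::desn_init(cfg, n_in = 10)
  set.seed(8)
  feat <- rnorm(10)
  traj <- run_reservoir(model, feat)
  # oracle: plain arithmetic, scalar input per step, layer 2 fed by layer 1
  l1 <- model$layers[[1]]; l2 <- model$layers[[2]]
  x1 <- numeric(15); x2 <- numeric(15)
  rec <- matrix(0, 10, 30)
  for (t in 1:10) {
    x1 <- (1 - l1$alpha) * x1 + tanh(as.numeric(l1$W_in %*% feat[t] + l1$W %*% x1))
    x2 <- (1 - l2$alpha) * x2 + tanh(as.numeric(l2$W_in %*% x1 + l2$W %*% x2))
    rec[t, ] <- c(x1, x2)
  }
  expect_lt(max(abs(traj$states - rec)), 1e-10)
  expect_equal(traj$final_state, rec[10, ], tolerance = 1e-10)
  # zero feature, zero states stay at the fixed point
  z <- run_reservoir(model, rep(0, 10))
  expect_equal(max(abs(z$states)), 0)
  expect_error(run_reservoir(model, numeric(0)), "empty")
})

test_that("echo-state norms decay geometrically at rate rho under zero input", {
  for (seed in c(1, 2, 3)) {
    lay <- init_reservoir(1, 80, rho = 0.9, alpha = 1, seed = seed)
    set.seed(seed)
    x <- rnorm(80); x <- x / sqrt(sum(x^2)) * 0.1
    norms <- numeric(51); norms[1] <- sqrt(sum(x^2))
    for (t in 1:50) {
      x <- reservoir_update(lay, x, 0)
      norms[t + 1] <- sqrt(sum(x^2))
    }
    # geometric decay over the 50-step window at rate bounded by the
    # spectral radius; single steps may transiently exceed rho because a
    # non-normal W's largest singular value exceeds its spectral radius
    expect_lt((norms[51] / norms[1])^(1 / 50), 0.9 + 1e-6)
    expect_lt(norms[51], norms[1] * 0.9^50 * 10)
  }
})

test_that("closed-form readout solves the least-squares problem", {
  expect_equal(fit_readout(diag(2), diag(2)), diag(2), tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:5) {
    S <- matrix(rnorm(20 * 7), 20, 7)
    Y <- matrix(rnorm(20 * 2), 20, 2)
    W <- fit_readout(S, Y, lambda = 0)
    # independent QR oracle
    W_qr <- t(qr.solve(S, Y))
    expect_lt(max(abs(W - W_qr)), 1e-8)
    # residual orthogonal to the column space
    resid <- Y - S %*% t(W)
    expect_lt(max(abs(crossprod(S, resid))), 1e-8)
  }
  # ridge shrinks the readout norm monotonically
  S <- matrix(rnorm(30 * 10), 30, 10)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(l) {
    sqrt(sum(fit_readout(S, Y, lambda = l)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  # rank-deficient design falls back to the minimum-norm solution
  Sd <- cbind(S[, 1], S[, 1], S[, 2])
  expect_warning(fit_readout(Sd, Y, 0), "rank-deficient")
})

test_that("fitting touches only the readout and interpolates separable data", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 0, 1, 1)
  cfg <- desn_config(layers = 1, N_res = 20, seed = 2)
  m <- desn_fit(X, y, cfg)
  expect_equal(predict(m, X)$label, y)
  expect_equal(m$train_error, 0)
  # same seeds: only W_out differs from a fresh initialization
  fresh <- phantomnet:::desn_init(cfg, 2)
  for (l in 1:1) {
    expect_identical(m$layers[[l]]$W, fresh$layers[[l]]$W)
    expect_identical(m$layers[[l]]$W_in, fresh$layers[[l]]$W_in)
  }
  expect_null(fresh$W_out)
  expect_false(is.null(m$W_out))
  # prediction is deterministic and refuses unfitted models
  expect_identical(predict(m, X), predict(m, X))
  expect_error(predict(fresh, X), "readout")
  # broom-style accessors
  td <- tidy(m)
  expect_equal(nrow(td), length(m$W_out))
  expect_equal(glance(m)$train_error_pct, 0)
})

test_that("repeat encoding presents the whole vector at every step", {
  cfg <- desn_config(layers = 1, N_res = 10, encoding = "repeat",
                     repeat_T = 4, seed = 3)
  model <- phantomnet:::desn_init(cfg, n_in = 5)
  traj <- run_reservoir(model, rnorm(5))
  expect_equal(nrow(traj$states), 4)
  expect_equal(model$layers[[1]]$n_in, 5L)
})
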