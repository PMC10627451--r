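test_that("force terms follow the jet-propulsion formulas", {
  f0 <- compute_forces(c_draws = c(0, 0, 0))
  expect_equal(c(f0$F, f0$G, f0$M_force, f0$A), c(0, 0, 1, 0))
  f1 <- compute_forces(c_draws = c(1, 1, 1))
  expect_equal(c(f1$F, f1$G, f1$M_force, f1$A), c(2, 0, 4, 0))
  # M stays within the speed constants for any c1
  set.seed(1)
  for (rep in 1:50) {
    f <- compute_forces()
    expect_gte(f$M_force, 1)
    expect_lte(f$M_force, 4)
    expect_equal(f$A, f$G / f$M_force)
  }
})

test_that("agent moves follow the food-distance update", {
  f <- compute_forces(c_draws = c(1, 1, 1))
  f$A <- c(0.5, 0.5)
  expect_equal(move_agent(c(1, 1), c(2, 2), f, r_rand = 0.6), c(2.7, 2.7))
  # at the incumbent with A = 0 the agent is stationary
  f0 <- compute_forces(c_draws = c(0, 0, 0))
  expect_equal(move_agent(c(3, 3), c(3, 3), f0, r_rand = 0), c(3, 3))
  # position is continuous (affine) in A for fixed draws
  f$A <- 0.3
  p1 <- move_agent(c(1, 2), c(2, 1), f, r_rand = 0.7)
  f$A <- 0.3 + 1e-6
  p2 <- move_agent(c(1, 2), c(2, 1), f, r_rand = 0.7)
  expect_lt(max(abs(p2 - p1)), 1e-5)
})

test_that("the swarm sweep averages with the updated predecessor", {
  one <- matrix(5, 1, 1)
  expect_equal(swarm_sweep(one), one)
  two <- matrix(c(4, 2), 2, 1)
  expect_equal(as.numeric(swarm_sweep(two, c1_draws = 0)), c(4, 3))
  # sweep uses the predecessor's post-sweep position
  three <- matrix(c(4, 2, 6), 3, 1)
  out <- swarm_sweep(three, c1_draws = c(0, 0))
  expect_equal(as.numeric(out), c(4, 3, 4.5))
  # clamping respects the bounds
  set.seed(2)
  pos <- matrix(rnorm(40, sd = 10), 10, 4)
  cl <- swarm_sweep(pos, lower = rep(-1, 4), upper = rep(1, 4))
  expect_true(all(cl >= -1 & cl <= 1))
})

test_that("the swarm minimizes a quadratic and keeps its invariants", {
  sp <- search_space(c("x", "y"), c(-5, -5), c(5, 5))
  r <- tsa_minimize(function(x) sum(x^2), sp, n_pop = 20, max_iter = 100,
                    seed = 1)
  expect_lte(r$best_fitness, 1e-2)
  expect_true(all(diff(r$history$best_fitness) <= 0))
  expect_true(all(r$final_population >= -5 & r$final_population <= 5))
  # exactly n_pop evaluations per iteration phase
  expect_equal(unique(r$history$evaluations), 20L)
  expect_equal(r$n_evaluations, 20L * 101L)
  # determinism
  r2 <- tsa_minimize(function(x) sum(x^2), sp, n_pop = 20, max_iter = 100,
                     seed = 1)
  expect_identical(r$history, r2$history)
  expect_identical(r$best_position, r2$best_position)
  # population pinned at the optimum stays at fitness 0 from the start
  degenerate <- search_space(c("x", "y"), c(0, 0), c(0, 0))
  rd <- tsa_minimize(function(x) sum(x^2), degenerate, n_pop = 5, max_iter = 3,
                     seed = 2)
  expect_equal(rd$best_fitness, 0)
  expect_equal(rd$history$best_fitness, rep(0, 3))
  # non-finite objective values are quarantined as +Inf
  rn <- tsa_minimize(function(x) if (x[1] > 0) NaN else sum(x^2),
                     search_space("x", -1, 1), n_pop = 6, max_iter = 5, seed = 3)
  expect_true(is.finite(rn$best_fitness))
})

test_that("error-rate fitness is the accuracy complement", {
  expect_equal(error_rate_fitness(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(error_rate_fitness(c(1, 0, 0, 1, 1, 0, 1, 0, 1, 1),
                                  c(0, 1, 1, 1, 1, 0, 1, 0, 1, 1)), 30)
  set.seed(5)
  pred <- sample(0:1, 40, TRUE); truth <- sample(0:1, 40, TRUE)
  acc <- 100 * mean(pred == truth)
  expect_equal(error_rate_fitness(pred, truth) + acc, 100)
  expect_error(error_rate_fitness(integer(0), integer(0)), "non-empty")
})

test_that("hyperparameter tuning improves on the untuned baseline", {
  set.seed(9)
  n <- 60; D <- 8
  X <- matrix(rnorm(n * D), n, D)
  y <- rep(0:1, each = n / 2)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 1.5
  base <- desn_config(layers = 1, N_res = 30, encoding = "repeat",
                      repeat_T = 3, seed = 4)
  # a collapsed space returns exactly that point
  point <- search_space(c("N_res", "alpha", "rho", "input_scaling"),
                        low = c(50, 0.3, 0.5, 1), high = c(50, 0.3, 0.5, 1),
                        integer = c(TRUE, FALSE, FALSE, FALSE))
  tu <- tune_desn(X, y, space = point, n_pop = 3, max_iter = 2,
                  config = base, seed = 11)
  expect_equal(tu$best_params$N_res, 50L)
  expect_equal(tu$best_params$alpha, 0.3)
  # integer dimensions decode within bounds
  sp <- desn_search_space()
  tu2 <- tune_desn(X, y, space = sp, n_pop = 5, max_iter = 4,
                   config = base, seed = 12)
  expect_true(tu2$best_params$N_res >= 20 && tu2$best_params$N_res <= 400)
  expect_true(tu2$best_params$alpha >= 0.05 && tu2$best_params$alpha <= 1)
  # paired comparison on the same internal holdout
  hold_ids <- phantomnet:::with_seed(phantomnet:::derive_seed(12, 523L), {
    unlist(lapply(split(seq_len(n), y), function(ids) {
      sample(ids, size = max(1L, round(0.25 * length(ids))))
    }), use.names = FALSE)
  })
  tr_ids <- setdiff(seq_len(n), hold_ids)
  untuned <- desn_fit(X[tr_ids, ], y[tr_ids], base)
  untuned_err <- error_rate_fitness(predict(untuned, X[hold_ids, ])$label,
                                    y[hold_ids])
  expect_lte(tu2$holdout_error, untuned_err)
  expect_error(tune_desn(X[1:4, ], y[c(1, 2, 31, 32)], n_pop = 2, max_iter = 1,
                         config = base, seed = 1), "holdout")
})
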