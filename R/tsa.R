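# Tunicate swarm algorithm: a population metaheuristic modeling jet
# propulsion (each agent moves relative to the best individual under a
# random force ratio A = G / M) and swarm behavior (averaging with the
# previous agent's updated position), used here for bound-constrained
# minimization of the classifier error rate over DESN hyperparameters.

P_MIN <- 1
P_MAX <- 4

#' Draw the jet-propulsion force terms
#'
#' With fresh uniform draws `c1, c2, c3` in `[0, 1]`: water flow
#' `F = 2 c1`, gravity `G = c2 + c3 - F`, social force
#' `M = P_min + c1 (P_max - P_min)` with speed constants fixed at 1 and 4,
#' and displacement `A = G / M` (element-wise division; `M >= 1` always).
#' Draws come from the current RNG stream; fix it with `set.seed()` or pass
#' `c_draws` explicitly.
#'
#' @param c_draws Optional numeric vector `c(c1, c2, c3)` overriding the
#'   random draws (used by tests and worked examples).
#' @return A `tsa_forces` list with `A`, `G`, `F`, `M_force`, `c1`, `c2`,
#'   `c3`.
#' @export
#' @examples
#' compute_forces(c_draws = c(1, 1, 1)) # F = 2, G = 0, M = 4, A = 0
compute_forces <- function(c_draws = NULL) {
  if (is.null(c_draws)) c_draws <- stats::runif(3)
  stopifnot(length(c_draws) == 3, all(c_draws >= 0 & c_draws <= 1))
  c1 <- c_draws[1]; c2 <- c_draws[2]; c3 <- c_draws[3]
  Fw <- 2 * c1
  G <- c2 + c3 - Fw
  M <- P_MIN + c1 * (P_MAX - P_MIN)
  structure(list(A = G / M, G = G, F = Fw, M_force = M,
                 c1 = c1, c2 = c2, c3 = c3),
            class = "tsa_forces")
}

#' Move one agent toward the best individual
#'
#' The food distance is `PD = X_best - r_rand * X_t` with a single fresh
#' `r_rand` in `[0, 1]` that also decides the branch: the new position is
#' `X_best - A * PD` when `r_rand < 0.5` and `X_best + A * PD` otherwise.
#'
#' @param X_t Current position vector.
#' @param X_best Best-so-far position vector (same length).
#' @param forces A [compute_forces()] result (its `A` may be scalar or
#'   per-dimension).
#' @param r_rand Optional explicit draw in `[0, 1]`; taken from the RNG
#'   stream when `NULL`.
#' @return The proposed new position (unclamped).
#' @export
#' @examples
#' f <- compute_forces(c_draws = c(1, 1, 1))
#' f$A <- c(0.5, 0.5)
#' move_agent(c(1, 1), c(2, 2), f, r_rand = 0.6) # (2.7, 2.7)
move_agent <- function(X_t, X_best, forces, r_rand = NULL) {
  stopifnot(length(X_t) == length(X_best))
  if (is.null(r_rand)) r_rand <- stats::runif(1)
  PD <- X_best - r_rand * X_t
  if (r_rand < 0.5) X_best - forces$A * PD else X_best + forces$A * PD
}

#' Swarm sweep: share position information down the index order
#'
#' Sequentially for `i = 2..N`, agent `i` becomes
#' `(X_i(t) + X_{i-1}(t+1)) / (2 + c1)` with a fresh `c1` per agent, where
#' `X_{i-1}(t+1)` is the predecessor's already-updated position; agent 1 is
#' unchanged. Positions are then clamped to the bounds.
#'
#' @param positions `N x d` matrix of already-moved agent positions.
#' @param lower,upper Per-dimension bounds for the final clamp (optional:
#'   skip clamping when `NULL`).
#' @param c1_draws Optional explicit draws (length `N - 1`) for tests.
#' @return Updated `N x d` position matrix.
#' @export
swarm_sweep <- function(positions, lower = NULL, upper = NULL, c1_draws = NULL) {
  n <- nrow(positions)
  if (n > 1L) {
    if (is.null(c1_draws)) c1_draws <- stats::runif(n - 1L)
    for (i in 2:n) {
      positions[i, ] <- (positions[i, ] + positions[i - 1L, ]) /
        (2 + c1_draws[i - 1L])
    }
  }
  if (!is.null(lower)) {
    for (j in seq_len(ncol(positions))) {
      positions[, j] <- pmin(pmax(positions[, j], lower[j]), upper[j])
    }
  }
  positions
}

#' Define a box-bounded search space
#'
#' @param name Character vector of dimension names.
#' @param low,high Per-dimension bounds (`low <= high`; equal bounds give a
#'   degenerate, fixed dimension).
#' @param integer Logical: decode this dimension by rounding.
#' @return A `search_space` tibble.
#' @export
search_space <- function(name, low, high, integer = FALSE) {
  stopifnot(length(low) == length(name), length(high) == length(name))
  if (any(low > high)) stop("`low` must not exceed `high`.", call. = FALSE)
  integer <- rep_len(integer, length(name))
  structure(tibble::tibble(name = name, low = low, high = high,
                           integer = integer),
            class = c("search_space", class(tibble::tibble())))
}

decode_position <- function(space, position) {
  out <- as.list(position)
  names(out) <- space$name
  for (i in seq_along(out)) {
    if (space$integer[i]) out[[i]] <- as.integer(round(out[[i]]))
  }
  out
}

#' Minimize an objective with the tunicate swarm algorithm
#'
#' Agents start uniform in the bounds; each iteration evaluates the
#' objective, updates the best-so-far individual, moves every agent by jet
#' propulsion relative to the incumbent, applies the swarm sweep, and
#' clamps to the bounds. The incumbent is kept, so the best fitness history
#' is non-increasing. Non-finite objective values are treated as `+Inf`.
#' Fully deterministic for a given `(objective, space, n_pop, max_iter,
#' seed)`.
#'
#' @param objective Function of a numeric position vector returning a
#'   scalar to minimize.
#' @param space A [search_space()], or a 2-column matrix/list of bounds.
#' @param n_pop Population size (>= 1).
#' @param max_iter Iteration count (>= 1).
#' @param seed Integer seed.
#' @return A `tsa_result`: `best_position`, `best_fitness`,
#'   `best_decoded` (with integer dims rounded), `history` tibble
#'   (`iteration`, `best_fitness`, `evaluations`), `n_evaluations`.
#' @export
#' @examples
#' r <- tsa_minimize(function(x) sum(x^2),
#'                   search_space(c("x", "y"), c(-5, -5), c(5, 5)),
#'                   n_pop = 20, max_iter = 50, seed = 1)
#' r$best_fitness
tsa_minimize <- function(objective, space, n_pop = 20L, max_iter = 100L,
                         seed = 1L) {
  if (!inherits(space, "search_space")) {
    b <- as.matrix(space)
    space <- search_space(sprintf("x%d", seq_len(nrow(b))), b[, 1], b[, 2])
  }
  stopifnot(n_pop >= 1, max_iter >= 1)
  d <- nrow(space)
  lower <- space$low; upper <- space$high
  eval_safe <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  with_seed(seed, {
    pos <- matrix(stats::runif(n_pop * d, rep(lower, each = n_pop),
                               rep(upper, each = n_pop)), n_pop, d)
    fitness <- apply(pos, 1, eval_safe)
    n_evals <- n_pop
    best_i <- which.min(fitness)
    best_pos <- pos[best_i, ]
    best_fit <- fitness[best_i]
    hist_fit <- numeric(max_iter)
    hist_evals <- integer(max_iter)
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n_pop)) {
        pos[i, ] <- move_agent(pos[i, ], best_pos, compute_forces())
      }
      pos <- swarm_sweep(pos, lower, upper)
      fitness <- apply(pos, 1, eval_safe)
      n_evals <- n_evals + n_pop
      it_best <- which.min(fitness)
      if (fitness[it_best] < best_fit) {
        best_fit <- fitness[it_best]
        best_pos <- pos[it_best, ]
      }
      hist_fit[it] <- best_fit
      hist_evals[it] <- n_pop
    }
    structure(list(best_position = best_pos, best_fitness = best_fit,
                   best_decoded = decode_position(space, best_pos),
                   history = tibble::tibble(iteration = seq_len(max_iter),
                                            best_fitness = hist_fit,
                                            evaluations = hist_evals),
                   n_evaluations = n_evals, space = space,
                   final_population = pos),
              class = "tsa_result")
  })
}

#' Classifier error rate fitness (percent)
#'
#' The tuning objective: `misclassified / total * 100`; its complement is
#' the accuracy percentage.
#'
#' @param predicted,truth Equal-length label vectors (non-empty).
#' @return Error rate in `[0, 100]`.
#' @export
error_rate_fitness <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    stop("label vectors must be non-empty and of equal length.", call. = FALSE)
  }
  mean(predicted != truth) * 100
}

#' Default DESN hyperparameter search space
#'
#' Four dimensions: reservoir size `N_res` in `[20, 400]` (integer), leaky
#' rate `alpha` in `[0.05, 1]`, spectral radius `rho` in `[0.1, 0.99]`, and
#' `input_scaling` in `[0.1, 2]`.
#'
#' @return A [search_space()].
#' @export
desn_search_space <- function() {
  search_space(name = c("N_res", "alpha", "rho", "input_scaling"),
               low = c(20, 0.05, 0.10, 0.1),
               high = c(400, 1.00, 0.99, 2.0),
               integer = c(TRUE, FALSE, FALSE, FALSE))
}

#' Tune DESN hyperparameters with the tunicate swarm
#'
#' The fitness of a candidate hyperparameter vector is the classification
#' error rate (percent) on a stratified holdout carved out of the training
#' features with a fixed internal seed; after the search the model is
#' refitted on the full training set with the decoded best
#' hyperparameters.
#'
#' @param features Training feature matrix or tibble (see [desn_fit()]).
#' @param labels 0-based training labels.
#' @param space Hyperparameter [search_space()]; defaults to
#'   [desn_search_space()].
#' @param n_pop,max_iter Swarm size and iteration count.
#' @param holdout_fraction Fraction of the training set held out for
#'   fitness evaluation.
#' @param config Base [desn_config()] supplying all non-tuned settings.
#' @param seed Integer seed driving the search and the holdout split.
#' @return A `desn_tuning` list: `best_params` (one-row tibble), `model`
#'   (refitted on all of `features`), `result` (the `tsa_result`), and
#'   `holdout_error` of the best candidate.
#' @export
tune_desn <- function(features, labels, space = desn_search_space(),
                      n_pop = 20L, max_iter = 30L, holdout_fraction = 0.25,
                      config = desn_config(), seed = 1L) {
  X <- feature_matrix(features)
  labels <- as.integer(labels)
  n <- nrow(X)
  hold_ids <- with_seed(derive_seed(seed, 523L), {
    unlist(lapply(split(seq_len(n), labels), function(ids) {
      sample(ids, size = max(1L, round(holdout_fraction * length(ids))))
    }), use.names = FALSE)
  })
  if (any(table(labels[hold_ids]) < 2) || length(unique(labels[hold_ids])) < 2) {
    stop("holdout smaller than 2 samples per class; enlarge the training set.",
         call. = FALSE)
  }
  tr_ids <- setdiff(seq_len(n), hold_ids)
  apply_params <- function(cfg, par) {
    cfg$N_res <- as.integer(max(1, par$N_res))
    cfg$alpha <- min(max(par$alpha, 1e-6), 1)
    cfg$rho <- min(max(par$rho, 1e-6), 0.999)
    cfg$input_scaling <- max(par$input_scaling, 1e-6)
    cfg
  }
  objective <- function(position) {
    par <- decode_position(space, position)
    cfg <- apply_params(config, par)
    m <- desn_fit(X[tr_ids, , drop = FALSE], labels[tr_ids], cfg)
    pred <- predict(m, X[hold_ids, , drop = FALSE])$label
    error_rate_fitness(pred, labels[hold_ids])
  }
  res <- tsa_minimize(objective, space, n_pop = n_pop, max_iter = max_iter,
                      seed = seed)
  best <- res$best_decoded
  final_cfg <- apply_params(config, best)
  model <- desn_fit(X, labels, final_cfg)
  structure(list(best_params = tibble::as_tibble(best), model = model,
                 result = res, holdout_error = res$best_fitness),
            class = "desn_tuning")
}

#' Plot a TSA convergence history
#'
#' @param object A `tsa_result`.
#' @param ... Unused.
#' @return A ggplot of best-so-far fitness against iteration.
#' @method autoplot tsa_result
#' @export
autoplot.tsa_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = "Tunicate swarm convergence") +
    ggplot2::theme_minimal()
}

#' @export
print.tsa_result <- function(x, ...) {
  cat("<tsa_result> best fitness", signif(x$best_fitness, 6), "after",
      x$n_evaluations, "evaluations\n")
  invisible(x)
}
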