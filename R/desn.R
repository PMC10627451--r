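# Deep echo state network classifier. Reservoirs are random, fixed after
# initialization; layers are stacked (each layer's input is the previous
# layer's state); only the linear readout is trained, in closed form by
# pseudo-inverse or ridge regression on [input; final states].

#' Initialize a random reservoir layer
#'
#' Draws sparse uniform internal weights `W`, rescales them so the spectral
#' radius equals `rho`, and draws dense input weights `W_in` uniform in
#' `[-1, 1] * input_scaling`. Weights are fixed after initialization; only
#' the readout of the enclosing model is ever trained. If the sparse draw
#' has spectral radius zero the draw is repeated with a shifted seed (with
#' a message).
#'
#' @param n_in Input dimension.
#' @param N_res Reservoir size (>= 1).
#' @param rho Spectral-radius target in (0, 1).
#' @param alpha Leaky rate in (0, 1].
#' @param gamma Gain (> 0); the gained state update is used when
#'   `gamma != 1`.
#' @param density Fraction of non-zero entries in `W`.
#' @param input_scaling Scale of `W_in`.
#' @param seed Integer seed (same seed, same weights).
#' @return A `reservoir_layer` list.
#' @export
init_reservoir <- function(n_in, N_res, rho = 0.9, alpha = 1, gamma = 1,
                           density = 0.1, input_scaling = 1, seed = 1L) {
  stopifnot(N_res >= 1, rho > 0, rho < 1, alpha > 0, alpha <= 1, gamma > 0)
  draw <- function(s) {
    with_seed(s, {
      W <- matrix(0, N_res, N_res)
      nz <- which(stats::runif(N_res * N_res) < density)
      if (N_res == 1L && length(nz) == 0L) nz <- 1L  # 1x1 must be non-zero
      W[nz] <- stats::runif(length(nz), -0.5, 0.5)
      W_in <- matrix(stats::runif(N_res * n_in, -1, 1) * input_scaling,
                     N_res, n_in)
      list(W = W, W_in = W_in)
    })
  }
  s <- as.integer(seed)
  repeat {
    d <- draw(s)
    sr <- max(abs(eigen(d$W, only.values = TRUE)$values))
    if (sr > 0) break
    message("reservoir draw had spectral radius 0; redrawing with shifted seed")
    s <- derive_seed(s, 1L)
  }
  structure(list(W = d$W * (rho / sr), W_in = d$W_in, W_back = NULL,
                 alpha = alpha, gamma = gamma, rho = rho,
                 input_scaling = input_scaling, n_in = as.integer(n_in),
                 N_res = as.integer(N_res), seed = s),
            class = "reservoir_layer")
}

#' One leaky reservoir state update
#'
#' Default (gain = 1, no feedback):
#' `x(t+1) = (1 - alpha) * x(t) + tanh(W_in u(t+1) + W x(t))`.
#' When `gamma != 1` or feedback weights are present the gained variant
#' `x(t+1) = (1 - alpha*gamma) * x(t) + gamma * tanh(W_in u(t+1) + W x(t) +
#' W_back y(t))` is used instead.
#'
#' @param layer A `reservoir_layer`.
#' @param x_t Current state: numeric vector of length `N_res`, or an
#'   `n x N_res` matrix for a batch of state rows.
#' @param u_next Next input: length `n_in` vector or `n x n_in` matrix.
#' @param y_prev Optional previous output (needed only with feedback).
#' @return Next state, same shape as `x_t`.
#' @export
#' @examples
#' lay <- init_reservoir(1, 1, rho = 0.5, seed = 1)
#' lay$W_in[] <- 1; lay$W[] <- 0.5; lay$alpha <- 0.5
#' reservoir_update(lay, 0, 1) # 0.5*0 + tanh(1) = 0.761594
reservoir_update <- function(layer, x_t, u_next, y_prev = NULL) {
  vec_in <- !is.matrix(x_t)
  x <- if (vec_in) matrix(x_t, 1L) else x_t
  u <- if (!is.matrix(u_next)) matrix(u_next, nrow(x), byrow = TRUE) else u_next
  if (ncol(x) != layer$N_res || ncol(u) != layer$n_in) {
    stop("state/input dimensions do not match the reservoir.", call. = FALSE)
  }
  pre <- tcrossprod(u, layer$W_in) + tcrossprod(x, layer$W)
  if (!is.null(layer$W_back) && !is.null(y_prev)) {
    y <- if (!is.matrix(y_prev)) matrix(y_prev, nrow(x), byrow = TRUE) else y_prev
    pre <- pre + tcrossprod(y, layer$W_back)
  }
  g <- layer$gamma
  out <- if (g != 1 || !is.null(layer$W_back)) {
    (1 - layer$alpha * g) * x + g * tanh(pre)
  } else {
    (1 - layer$alpha) * x + tanh(pre)
  }
  if (vec_in) as.numeric(out) else out
}

#' Deep ESN configuration
#'
#' @param layers Number of stacked reservoirs L (>= 1); layer `l > 1`
#'   receives layer `l-1`'s state as input.
#' @param N_res Reservoir size per layer.
#' @param rho Spectral-radius target in (0, 1).
#' @param alpha Leaky rate in (0, 1].
#' @param gamma Gain.
#' @param density Sparsity of the internal weights.
#' @param input_scaling Input weight scale.
#' @param lambda Ridge regularization of the readout (`0` = pure
#'   pseudo-inverse).
#' @param encoding How a static feature vector enters the network:
#'   `"sequential"` presents one component per step (T = D),
#'   `"repeat"` presents the full vector at each of `repeat_T` steps.
#' @param repeat_T Sequence length for the repeat encoding.
#' @param seed Integer seed for reservoir initialization.
#' @return A `desn_config` list.
#' @export
desn_config <- function(layers = 2L, N_res = 100L, rho = 0.9, alpha = 0.5,
                        gamma = 1, density = 0.1, input_scaling = 1,
                        lambda = 0, encoding = c("sequential", "repeat"),
                        repeat_T = 5L, seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(layers >= 1, lambda >= 0)
  structure(list(layers = as.integer(layers), N_res = as.integer(N_res),
                 rho = rho, alpha = alpha, gamma = gamma, density = density,
                 input_scaling = input_scaling, lambda = lambda,
                 encoding = encoding, repeat_T = as.integer(repeat_T),
                 seed = as.integer(seed)),
            class = "desn_config")
}

desn_init <- function(config, n_in) {
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    lin <- if (l == 1L) {
      if (config$encoding == "sequential") 1L else n_in
    } else config$N_res
    layers[[l]] <- init_reservoir(lin, config$N_res, rho = config$rho,
                                  alpha = config$alpha, gamma = config$gamma,
                                  density = config$density,
                                  input_scaling = config$input_scaling,
                                  seed = derive_seed(config$seed, 17L * l))
  }
  structure(list(config = config, layers = layers, n_in = as.integer(n_in),
                 W_out = NULL, classes = NULL),
            class = "desn_model")
}

# encode an n x D feature matrix as a list of T input matrices for layer 1
desn_encode <- function(config, X) {
  if (config$encoding == "sequential") {
    lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
  } else {
    rep(list(X), config$repeat_T)
  }
}

# batched state run; returns list(final = n x (L*N_res), states = optional
# per-step record when trace = TRUE (then n must be 1))
desn_run <- function(model, X, trace = FALSE) {
  cfg <- model$config
  inputs <- desn_encode(cfg, X)
  n <- nrow(X)
  L <- cfg$layers
  states <- lapply(seq_len(L), function(l) matrix(0, n, cfg$N_res))
  rec <- if (trace) matrix(0, length(inputs), L * cfg$N_res) else NULL
  for (t in seq_along(inputs)) {
    u <- inputs[[t]]
    for (l in seq_len(L)) {
      states[[l]] <- reservoir_update(model$layers[[l]], states[[l]], u)
      u <- states[[l]]
    }
    if (trace) rec[t, ] <- unlist(lapply(states, as.numeric))
  }
  list(final = do.call(cbind, states), states = rec)
}

#' Run the reservoir stack on one feature vector
#'
#' Encodes the static feature as an input sequence (see [desn_config()]),
#' drives the stacked reservoirs from zero initial states, and records the
#' full state trajectory.
#'
#' @param model A `desn_model` (fitted or freshly initialized via
#'   [desn_fit()] / internal initialization).
#' @param feature Numeric feature vector.
#' @return A `state_trajectory`: list with `states` (T x (L*N_res) matrix)
#'   and `final_state` (concatenation of all layers' states at the last
#'   step).
#' @export
run_reservoir <- function(model, feature) {
  stopifnot(inherits(model, "desn_model"))
  if (length(feature) == 0) stop("empty feature vector.", call. = FALSE)
  if (length(feature) != model$n_in) {
    stop("feature length ", length(feature), " does not match model input ",
         model$n_in, ".", call. = FALSE)
  }
  r <- desn_run(model, matrix(feature, 1L), trace = TRUE)
  structure(list(states = r$states, final_state = as.numeric(r$final)),
            class = "state_trajectory")
}

#' Closed-form readout fit
#'
#' Solves `min ||targets - design %*% t(W_out)||_F^2 (+ lambda ||W_out||^2)`
#' for the readout. With `lambda = 0` the minimum-norm pseudo-inverse
#' solution `W_out = t(design^+ %*% targets)` is returned (a warning is
#' issued when the design is rank-deficient); with `lambda > 0` the ridge
#' normal equations are solved, and `lambda -> 0` recovers the
#' pseudo-inverse solution on full-rank designs.
#'
#' @param design `n x p` matrix of per-sample rows `[u; x]` (input joined
#'   with final reservoir states).
#' @param targets `n x K` matrix (one-hot class indicators for
#'   classification).
#' @param lambda Ridge penalty (>= 0).
#' @return `K x p` readout weight matrix.
#' @export
fit_readout <- function(design, targets, lambda = 0) {
  design <- as.matrix(design)
  targets <- as.matrix(targets)
  if (nrow(design) != nrow(targets)) stop("row counts disagree.", call. = FALSE)
  if (lambda == 0) {
    s <- svd(design)
    tol <- max(dim(design)) * max(s$d, 0) * .Machine$double.eps
    rank <- sum(s$d > tol)
    if (rank < min(dim(design))) {
      warning("rank-deficient design; returning the minimum-norm solution.",
              call. = FALSE)
    }
    keep <- s$d > tol
    wt <- s$v[, keep, drop = FALSE] %*%
      ((1 / s$d[keep]) * crossprod(s$u[, keep, drop = FALSE], targets))
    t(wt)
  } else {
    p <- ncol(design)
    wt <- solve(crossprod(design) + diag(lambda, p), crossprod(design, targets))
    t(wt)
  }
}

#' Fit a deep ESN classifier
#'
#' Initializes the reservoir stack from the config seed, runs every
#' training feature through it, and fits the readout on the concatenation
#' `[feature; final states]` against one-hot labels. Reservoir weights are
#' never trained; fitting touches only `W_out`.
#'
#' @param features `n x D` numeric matrix, or a tibble with `f_*` feature
#'   columns (as produced by [extract_features_batch()]).
#' @param labels Integer class labels (0-based), one per row.
#' @param config A [desn_config()].
#' @return A fitted `desn_model`.
#' @export
desn_fit <- function(features, labels, config = desn_config()) {
  X <- feature_matrix(features)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("feature/label sizes disagree.", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes.", call. = FALSE)
  model <- desn_init(config, ncol(X))
  run <- desn_run(model, X)
  design <- cbind(X, run$final)
  Y <- matrix(0, nrow(X), length(classes))
  Y[cbind(seq_len(nrow(X)), match(labels, classes))] <- 1
  model$W_out <- suppressWarnings(fit_readout(design, Y, config$lambda))
  model$classes <- classes
  model$train_error <- {
    sc <- design %*% t(model$W_out)
    pred <- classes[max.col(sc, ties.method = "first")]
    mean(pred != labels) * 100
  }
  model
}

# accept tibbles from extract_features_batch or plain matrices
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.data.frame(features)) {
    fc <- grep("^f_", names(features), value = TRUE)
    if (length(fc) == 0) stop("no f_* feature columns found.", call. = FALSE)
    return(as.matrix(features[, fc]))
  }
  matrix(as.numeric(features), 1L)
}

#' Predict classes with a fitted deep ESN
#'
#' Scores are `W_out [u; x_final]` (identity output activation); the label
#' is the argmax, ties broken toward the lower class index.
#'
#' @param object A fitted `desn_model`.
#' @param newdata Feature matrix/tibble, or a single feature vector.
#' @param ... Unused.
#' @return A tibble with one row per sample: `label` and one `score_<k>`
#'   column per class.
#' @export
predict.desn_model <- function(object, newdata, ...) {
  if (is.null(object$W_out)) {
    stop("model has no fitted readout; call desn_fit() first.", call. = FALSE)
  }
  X <- feature_matrix(newdata)
  run <- desn_run(object, X)
  scores <- cbind(X, run$final) %*% t(object$W_out)
  label <- object$classes[max.col(scores, ties.method = "first")]
  colnames(scores) <- sprintf("score_%d", object$classes)
  out <- tibble::as_tibble(scores)
  out$label <- as.integer(label)
  out
}

#' @export
print.desn_model <- function(x, ...) {
  cat("<desn_model> L =", x$config$layers, "reservoirs x", x$config$N_res,
      "units; rho =", signif(x$config$rho, 3), "alpha =",
      signif(x$config$alpha, 3), "\n")
  if (!is.null(x$W_out)) {
    cat("  fitted readout", nrow(x$W_out), "x", ncol(x$W_out),
        "; training error", signif(x$train_error, 4), "%\n")
  } else cat("  readout not fitted\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the readout weights of a fitted deep ESN
#'
#' @param x A fitted `desn_model`.
#' @param ... Unused.
#' @return Tibble with `class`, `term`, `estimate` for every readout
#'   weight; terms are `u_<j>` for direct input weights and
#'   `x<layer>_<unit>` for reservoir state weights.
#' @method tidy desn_model
#' @export
tidy.desn_model <- function(x, ...) {
  if (is.null(x$W_out)) stop("model not fitted.", call. = FALSE)
  D <- x$n_in
  terms <- c(sprintf("u_%d", seq_len(D)),
             unlist(lapply(seq_len(x$config$layers), function(l) {
               sprintf("x%d_%d", l, seq_len(x$config$N_res))
             })))
  tibble::tibble(
    class = rep(x$classes, times = ncol(x$W_out)),
    term = rep(terms, each = nrow(x$W_out)),
    estimate = as.numeric(x$W_out)
  )
}

#' One-row model summary of a fitted deep ESN
#'
#' @param x A fitted `desn_model`.
#' @param ... Unused.
#' @return One-row tibble: layers, reservoir size, spectral radius, leaky
#'   rate, ridge lambda, readout dimension, training error (percent).
#' @method glance desn_model
#' @export
glance.desn_model <- function(x, ...) {
  tibble::tibble(layers = x$config$layers, N_res = x$config$N_res,
                 rho = x$config$rho, alpha = x$config$alpha,
                 input_scaling = x$config$input_scaling,
                 lambda = x$config$lambda,
                 readout_dim = if (is.null(x$W_out)) NA_integer_ else ncol(x$W_out),
                 train_error_pct = x$train_error %||% NA_real_)
}
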