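# Ghost convolutions: compute m "primary" feature maps with an ordinary
# convolution and derive the remaining m*(s-1) maps with cheap depthwise
# linear operations, for an s-fold reduction in multiply count. Includes
# the analytic cost-ratio model and a small 3-block extractor network that
# turns (masked) images into fixed-length feature vectors.

#' Ghost convolution specification
#'
#' @param M Input channel count.
#' @param N Output map count; must equal `m * s`.
#' @param s Expansion factor (>= 1); `m = N / s` primary maps are computed
#'   by ordinary convolution and the remaining `m * (s - 1)` by cheap
#'   depthwise operations.
#' @param D_k Primary kernel extent (default 3).
#' @param D_F Output spatial extent (used by the cost model; default 32).
#' @param cheap_kernel Depthwise kernel extent of the cheap operation
#'   (default 3).
#' @return A `ghost_spec` list with derived `m`.
#' @export
ghost_spec <- function(M, N, s, D_k = 3L, D_F = 32L, cheap_kernel = 3L) {
  if (s < 1) stop("`s` must be >= 1.", call. = FALSE)
  if (N %% s != 0) {
    stop("`N` (", N, ") is not divisible by `s` (", s, ").", call. = FALSE)
  }
  stopifnot(M >= 1, N >= 1, D_k >= 1, D_F >= 1, cheap_kernel >= 1)
  structure(list(M = as.integer(M), N = as.integer(N), s = as.integer(s),
                 m = as.integer(N / s), D_k = as.integer(D_k),
                 D_F = as.integer(D_F), cheap_kernel = as.integer(cheap_kernel)),
            class = "ghost_spec")
}

ghost_weights_init <- function(spec, seed = NULL) {
  init <- function() {
    cheap <- if (spec$s > 1L) {
      lapply(seq_len(spec$s - 1L), function(j) dwconv_init(spec$cheap_kernel, spec$m))
    } else list()
    list(primary = conv_init(spec$D_k, spec$M, spec$m), cheap = cheap)
  }
  if (is.null(seed)) init() else with_seed(seed, init())
}

#' Apply a ghost convolution to a channel stack
#'
#' The first `m` output maps are an ordinary convolution of the input; map
#' block `j` (for `j = 1..s-1`) applies the `j`-th cheap depthwise operation
#' to the primary maps, so output map `m*j + i` derives from primary map
#' `i`. Output channel count is exactly `N`.
#'
#' @param input Numeric `H x W x M` array (a matrix is taken as `M = 1`).
#' @param spec A [ghost_spec()].
#' @param weights Optional weights from a previous call; when `NULL`, fresh
#'   weights are drawn under `seed`.
#' @param seed Seed for weight initialization when `weights` is `NULL`.
#' @param stride Spatial stride of the primary convolution.
#' @return `H' x W' x N` array with attribute `"weights"`.
#' @export
ghost_conv <- function(input, spec, weights = NULL, seed = 1L, stride = 1L) {
  stopifnot(inherits(spec, "ghost_spec"))
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  d <- dim(input)
  if (d[3] != spec$M) {
    stop("input has ", d[3], " channels but spec expects M = ", spec$M, ".",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- ghost_weights_init(spec, seed)
  fm <- fmap(matrix(input, ncol = d[3]), d[1], d[2], 1L)
  pf <- conv_forward(fm, weights$primary, stride = stride)
  parts <- list(pf$out$x)
  for (j in seq_len(spec$s - 1L)) {
    parts[[j + 1L]] <- dwconv_forward(pf$out, weights$cheap[[j]])$out$x
  }
  out <- array(do.call(cbind, parts), c(pf$out$h, pf$out$w, spec$N))
  attr(out, "weights") <- weights
  out
}

#' Computational cost ratio of standard vs ghost convolution
#'
#' Multiply count of a standard convolution, `D_k^2 * M * D_F^2 * N`,
#' divided by the ghost cost `D_k^2 * M * D_F^2 * m + (s-1) * m * d^2 *
#' D_F^2` where `d` is the cheap kernel extent. The ratio equals 1 at
#' `s = 1` and approaches `s` as `M` grows (with `D_k = d`). The
#' `as_printed` variant drops the `m` multiplicity from the cheap term and
#' uses `D_k` for the cheap kernel — a form sometimes printed that
#' undercounts the cheap operations (each of the `m` primary maps receives
#' its own `s - 1` linear operations), so it overstates the saving at
#' moderate `M`; it is provided for fidelity checks only.
#'
#' @param spec A [ghost_spec()].
#' @param as_printed Use the variant without the `m` factor.
#' @return Positive scalar.
#' @export
#' @examples
#' ghost_cost_ratio(ghost_spec(M = 16, N = 32, s = 2, D_F = 32)) # 1.8824
ghost_cost_ratio <- function(spec, as_printed = FALSE) {
  stopifnot(inherits(spec, "ghost_spec"))
  std <- spec$D_k^2 * spec$M * spec$D_F^2 * spec$N
  cheap <- if (as_printed) {
    (spec$s - 1) * spec$D_k^2 * spec$D_F^2
  } else {
    (spec$s - 1) * spec$m * spec$cheap_kernel^2 * spec$D_F^2
  }
  ghost <- spec$D_k^2 * spec$M * spec$D_F^2 * spec$m + cheap
  std / ghost
}

# ---- feature extractor -----------------------------------------------------

#' Ghost feature extractor configuration
#'
#' Network: 3x3 stem convolution (stride 2) then three ghost blocks with
#' stride-2 primary convolutions, ReLU after every stage, global average
#' pooling to a feature vector whose dimension is the last block's map
#' count (default 64).
#'
#' @param blocks Output map counts of the three ghost blocks.
#' @param stem_channels Stem convolution output channels.
#' @param s Ghost expansion factor shared by all blocks.
#' @param kernel_size,cheap_kernel Primary / cheap kernel extents.
#' @param epochs,learning_rate,batch_size,optimizer Training scalars for
#'   [train_extractor()].
#' @param seed Integer seed.
#' @return A `ghost_config` list with derived `feature_dim`.
#' @export
ghost_config <- function(blocks = c(16L, 32L, 64L), stem_channels = 8L, s = 2L,
                         kernel_size = 3L, cheap_kernel = 3L, epochs = 10L,
                         learning_rate = 1e-3, batch_size = 16L,
                         optimizer = "adam", seed = 1L) {
  if (any(blocks %% s != 0)) stop("every block size must be divisible by `s`.", call. = FALSE)
  structure(list(blocks = as.integer(blocks), stem_channels = as.integer(stem_channels),
                 s = as.integer(s), kernel_size = as.integer(kernel_size),
                 cheap_kernel = as.integer(cheap_kernel), epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 optimizer = optimizer, feature_dim = as.integer(blocks[length(blocks)]),
                 seed = as.integer(seed)),
            class = "ghost_config")
}

ghost_extractor_init <- function(config) {
  with_seed(config$seed, {
    cin <- config$stem_channels
    specs <- list(); wts <- list()
    prev <- cin
    for (i in seq_along(config$blocks)) {
      sp <- ghost_spec(prev, config$blocks[i], config$s, config$kernel_size,
                       cheap_kernel = config$cheap_kernel)
      specs[[i]] <- sp
      wts[[i]] <- ghost_weights_init(sp)
      prev <- config$blocks[i]
    }
    structure(list(config = config,
                   stem = conv_init(config$kernel_size, 1L, cin),
                   blocks = wts, specs = specs,
                   loss_history = tibble::tibble(epoch = integer(), loss = numeric())),
              class = "ghost_extractor")
  })
}

ghost_block_forward <- function(fm, wts, spec) {
  pf <- conv_forward(fm, wts$primary, stride = 2L)
  parts <- list(pf$out$x)
  caches <- vector("list", spec$s - 1L)
  for (j in seq_len(spec$s - 1L)) {
    df <- dwconv_forward(pf$out, wts$cheap[[j]])
    parts[[j + 1L]] <- df$out$x
    caches[[j]] <- df$cache
  }
  pre <- fmap(do.call(cbind, parts), pf$out$h, pf$out$w, fm$b)
  rl <- relu_forward(pre)
  list(out = rl$out,
       cache = list(primary = pf$cache, cheap = caches, relu = rl$cache,
                    m = spec$m, s = spec$s, pf_out = pf$out))
}

ghost_block_backward <- function(d_out, wts, cache) {
  d_pre <- relu_backward(d_out, cache$relu)$d_in
  m <- cache$m
  d_primary_out <- fmap(d_pre$x[, seq_len(m), drop = FALSE],
                        d_pre$h, d_pre$w, d_pre$b)
  gcheap <- vector("list", cache$s - 1L)
  for (j in seq_len(cache$s - 1L)) {
    dj <- fmap(d_pre$x[, m * j + seq_len(m), drop = FALSE], d_pre$h, d_pre$w, d_pre$b)
    db <- dwconv_backward(dj, wts$cheap[[j]], cache$cheap[[j]])
    gcheap[[j]] <- list(w = db$dw, b = db$db)
    d_primary_out$x <- d_primary_out$x + db$d_in$x
  }
  pb <- conv_backward(d_primary_out, wts$primary, cache$primary)
  list(grads = list(primary = list(w = pb$dw, b = pb$db), cheap = gcheap),
       d_in = pb$d_in)
}

ghost_forward <- function(extractor, fm) {
  st <- conv_forward(fm, extractor$stem, stride = 2L)
  r0 <- relu_forward(st$out)
  x <- r0$out
  bcaches <- vector("list", length(extractor$blocks))
  for (i in seq_along(extractor$blocks)) {
    bf <- ghost_block_forward(x, extractor$blocks[[i]], extractor$specs[[i]])
    bcaches[[i]] <- bf$cache
    x <- bf$out
  }
  n_sp <- x$h * x$w
  feats <- colMeans(array(x$x, c(n_sp, x$b, ncol(x$x))))  # B x D
  if (x$b == 1L) feats <- matrix(feats, 1L)
  list(features = feats, cache = list(stem = st$cache, relu0 = r0$cache,
                                      blocks = bcaches, last = x))
}

ghost_backward <- function(d_feats, extractor, cache) {
  x <- cache$last
  n_sp <- x$h * x$w
  # broadcast GAP gradient back over pixels
  dlast <- matrix(0, n_sp * x$b, ncol(x$x))
  for (b in seq_len(x$b)) {
    dlast[(b - 1L) * n_sp + seq_len(n_sp), ] <-
      matrix(d_feats[b, ] / n_sp, n_sp, ncol(x$x), byrow = TRUE)
  }
  d <- fmap(dlast, x$h, x$w, x$b)
  gblocks <- vector("list", length(extractor$blocks))
  for (i in rev(seq_along(extractor$blocks))) {
    bb <- ghost_block_backward(d, extractor$blocks[[i]], cache$blocks[[i]])
    gblocks[[i]] <- bb$grads
    d <- bb$d_in
  }
  d <- relu_backward(d, cache$relu0)$d_in
  sb <- conv_backward(d, extractor$stem, cache$stem)
  list(grads = list(stem = list(w = sb$dw, b = sb$db), blocks = gblocks))
}

#' Train the ghost feature extractor
#'
#' Supervised training with a temporary linear classification head on the
#' binary labels (softmax cross-entropy); the head is discarded afterwards
#' and only the convolutional extractor is returned. With `epochs = 0` the
#' seeded random extractor is returned unchanged — random ghost projections
#' already provide usable features for downstream readouts.
#'
#' @param images List of numeric `H x W` matrices (typically foreground-
#'   masked images), or a `phantom_dataset` (its raw images are used).
#' @param labels Integer vector of 0/1 class labels, one per image.
#' @param config A [ghost_config()].
#' @return A `ghost_extractor` with a recorded `loss_history`.
#' @export
train_extractor <- function(images, labels = NULL, config = ghost_config()) {
  if (inherits(images, "phantom_dataset")) {
    labels <- images$index$label
    images <- lapply(images$samples, function(s) s$image)
  }
  if (length(images) == 0) stop("training set is empty.", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class.", call. = FALSE)
  }
  extractor <- ghost_extractor_init(config)
  if (config$epochs == 0L) return(extractor)
  D <- config$feature_dim
  head <- with_seed(derive_seed(config$seed, 7L), {
    list(w = matrix(stats::rnorm(D * 2L, 0, 1 / sqrt(D)), D, 2L), b = numeric(2L))
  })
  opt <- make_optimizer(config$optimizer, lr = config$learning_rate)
  n <- length(images)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 1000L + ep), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fw <- ghost_forward(extractor, fmap_from_images(images[bt]))
      logits <- fw$features %*% head$w + rep(head$b, each = length(bt))
      p <- softmax_rows(logits)
      y <- labels[bt] + 1L
      pt <- p[cbind(seq_along(bt), y)]
      loss <- mean(-log(pmax(pt, 1e-12)))
      dlogits <- p
      dlogits[cbind(seq_along(bt), y)] <- dlogits[cbind(seq_along(bt), y)] - 1
      dlogits <- dlogits / length(bt)
      ghead <- list(w = crossprod(fw$features, dlogits), b = colSums(dlogits))
      dfeat <- dlogits %*% t(head$w)
      gb <- ghost_backward(dfeat, extractor, fw$cache)
      params <- list(stem = extractor$stem, blocks = extractor$blocks, head = head)
      grads <- list(stem = gb$grads$stem, blocks = gb$grads$blocks, head = ghead)
      flat <- opt$step(flatten_params(params), flatten_params(grads))
      params <- unflatten_params(flat, params)
      extractor$stem <- params$stem
      extractor$blocks <- params$blocks
      head <- params$head
      ep_loss <- ep_loss + loss * length(bt)
    }
    history[ep] <- ep_loss / n
  }
  extractor$loss_history <- tibble::tibble(epoch = seq_len(config$epochs),
                                           loss = history)
  extractor
}

#' Extract a feature vector from one image
#'
#' In `"masked"` mode the image is multiplied element-wise by the binarized
#' foreground of `mask` (any non-zero entry) before the forward pass — the
#' hand-off that ties segmentation to classification. Deterministic.
#'
#' @param image Numeric `H x W` matrix.
#' @param mask Integer mask of the same shape (required in masked mode).
#' @param extractor A `ghost_extractor`.
#' @param mode `"masked"` or `"raw"`.
#' @return Numeric feature vector of length `feature_dim`.
#' @export
extract_features <- function(image, mask = NULL, extractor,
                             mode = c("masked", "raw")) {
  mode <- match.arg(mode)
  if (mode == "masked") {
    if (is.null(mask)) stop("masked mode needs a mask.", call. = FALSE)
    if (!all(dim(mask) == dim(image))) {
      stop("image and mask shapes disagree.", call. = FALSE)
    }
    image <- image * (mask != 0)
  }
  fw <- ghost_forward(extractor, fmap_from_images(list(image)))
  as.numeric(fw$features[1, ])
}

#' Extract features for many images as a tibble
#'
#' @param images List of image matrices.
#' @param masks Optional list of masks (required in masked mode).
#' @param extractor A `ghost_extractor`.
#' @param mode `"masked"` or `"raw"`.
#' @param labels Optional label column.
#' @param batch_size Images per forward pass.
#' @return Tibble with `sample_id`, feature columns `f_1..f_D`, and `label`
#'   when given.
#' @export
extract_features_batch <- function(images, masks = NULL, extractor,
                                   mode = c("masked", "raw"), labels = NULL,
                                   batch_size = 32L) {
  mode <- match.arg(mode)
  n <- length(images)
  if (mode == "masked") {
    stopifnot(!is.null(masks), length(masks) == n)
    images <- lapply(seq_len(n), function(i) images[[i]] * (masks[[i]] != 0))
  }
  D <- extractor$config$feature_dim
  out <- matrix(0, n, D)
  for (start in seq(1L, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    fw <- ghost_forward(extractor, fmap_from_images(images[ids]))
    out[ids, ] <- fw$features
  }
  colnames(out) <- sprintf("f_%d", seq_len(D))
  res <- tibble::as_tibble(out)
  res <- tibble::add_column(res, sample_id = seq_len(n), .before = 1)
  if (!is.null(labels)) res$label <- as.integer(labels)
  res
}

#' @export
print.ghost_extractor <- function(x, ...) {
  cat("<ghost_extractor> stem", x$config$stem_channels, "-> blocks",
      paste(x$config$blocks, collapse = "-"), "(s =", x$config$s,
      ") -> D =", x$config$feature_dim, "\n")
  invisible(x)
}
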