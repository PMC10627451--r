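# W-Net segmentation: two chained U-Nets (the first produces a softmax
# segmentation map, the second refines it, receiving the first's encoder
# features through cross-network skip connections), trained with a combined
# cross-entropy + total-variation loss. Class indices are 0-based
# throughout, matching the mask coding {0 = background, ...}.

#' W-Net configuration
#'
#' @param levels Encoder depth of each U-Net; channels double per level
#'   from `base_channels`, capped at `max_channels` (defaults give the
#'   schedule 8, 16, 32, 64, 128).
#' @param base_channels First-level channel count (default 8).
#' @param max_channels Channel cap (default 128).
#' @param kernel_size Convolution kernel extent (odd; default 3).
#' @param classes Number of segmentation classes K (>= 2).
#' @param epochs,learning_rate,batch_size Training scalars.
#' @param optimizer `"adam"` or `"sgd"` (both stochastic-gradient methods;
#'   Adam is the default at the same base rate).
#' @param lambda_tv Weight of the total-variation term during training;
#'   `"auto"` scales the raw TV sum by `1 / (H * W)` so both loss terms are
#'   per-pixel quantities (see the methods vignette).
#' @param mode `"supervised"` (targets = ground-truth masks) or
#'   `"selftrain"` (targets = the argmax pseudo-mask regenerated from the
#'   current map at every step).
#' @param seed Integer seed for weight initialization and batch order.
#' @return A `wnet_config` list.
#' @export
wnet_config <- function(levels = 5L, base_channels = 8L, max_channels = 128L,
                        kernel_size = 3L, classes = 2L, epochs = 10L,
                        learning_rate = 1e-3, batch_size = 8L,
                        optimizer = "adam", lambda_tv = "auto",
                        mode = c("supervised", "selftrain"), seed = 1L) {
  stopifnot(levels >= 1, classes >= 2, kernel_size %% 2 == 1)
  mode <- match.arg(mode)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 kernel_size = as.integer(kernel_size),
                 classes = as.integer(classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer,
                 lambda_tv = lambda_tv,
                 mode = mode,
                 seed = as.integer(seed)),
            class = "wnet_config")
}

wnet_channels <- function(config) {
  pmin(config$base_channels * 2L^(seq_len(config$levels) - 1L), config$max_channels)
}

# ---- loss operations -------------------------------------------------------

#' Per-pixel softmax normalization of raw class scores
#'
#' Maps an `H x W x K` array of raw scores to per-pixel class probabilities
#' (each pixel's K values are non-negative and sum to one). Monotone in the
#' raw scores at every pixel, so the argmax is preserved.
#'
#' @param raw_scores Numeric `H x W x K` array of finite scores.
#' @return An `H x W x K` probability array.
#' @export
#' @examples
#' softmax_normalize(array(0, c(2, 2, 2)))[1, 1, ] # 0.5 0.5
softmax_normalize <- function(raw_scores) {
  if (!all(is.finite(raw_scores))) stop("raw scores must be finite.", call. = FALSE)
  d <- dim(raw_scores)
  if (length(d) != 3L) stop("`raw_scores` must be an H x W x K array.", call. = FALSE)
  p <- softmax_rows(matrix(raw_scores, ncol = d[3]))
  array(p, d)
}

#' Argmax pseudo segmentation mask
#'
#' Per-pixel argmax over the K channels of a probability map; ties break
#' toward the lower class index. Returns 0-based class indices.
#'
#' @param map `H x W x K` probability array (any per-pixel scores work; the
#'   argmax of a softmax equals the argmax of its input).
#' @return Integer `H x W` matrix with entries in `0:(K-1)`.
#' @export
pseudo_mask <- function(map) {
  d <- dim(map)
  m <- matrix(map, ncol = d[3])
  idx <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(idx), d[1], d[2])
}

#' Cross-entropy segmentation loss
#'
#' Mean over pixels of the negative log-probability assigned to the target
#' class (one-hot targets). Probabilities are clamped at `1e-12` before the
#' logarithm.
#'
#' @param map `H x W x K` probability array.
#' @param target Integer `H x W` matrix of 0-based target classes (a
#'   pseudo-mask or a ground-truth label mask).
#' @return Non-negative scalar.
#' @export
#' @examples
#' p <- array(0.5, c(2, 2, 2))
#' ce_loss(p, matrix(0L, 2, 2)) # -log(0.5)
ce_loss <- function(map, target) {
  d <- dim(map)
  if (!all(dim(target) == d[1:2])) stop("map and target shapes disagree.", call. = FALSE)
  if (any(target < 0 | target >= d[3])) stop("target classes out of range.", call. = FALSE)
  m <- matrix(map, ncol = d[3])
  pt <- m[cbind(seq_len(nrow(m)), as.vector(target) + 1L)]
  mean(-log(pmax(pt, 1e-12)))
}

#' Anisotropic total-variation loss
#'
#' Sum, over channels, of the absolute forward differences along both image
#' axes: `sum |a[i, j+1] - a[i, j]| + sum |a[i+1, j] - a[i, j]|` over all
#' valid offsets. Zero exactly for spatially constant maps; absolutely
#' homogeneous of degree one. Penalizes ragged segmentation maps.
#'
#' @param map `H x W x K` array (or `H x W` matrix, treated as one channel).
#' @return Non-negative scalar.
#' @export
#' @examples
#' tv_loss(matrix(c(0, 0, 1, 1), 2)) # 2: one unit jump in each row
tv_loss <- function(map) {
  if (is.matrix(map)) map <- array(map, c(dim(map), 1L))
  d <- dim(map)
  if (d[1] < 2 || d[2] < 2) {
    stop("total variation needs at least 2 pixels along each axis.", call. = FALSE)
  }
  total <- 0
  for (k in seq_len(d[3])) {
    a <- map[, , k]
    total <- total + sum(abs(a[, -1, drop = FALSE] - a[, -d[2], drop = FALSE])) +
      sum(abs(a[-1, , drop = FALSE] - a[-d[1], , drop = FALSE]))
  }
  total
}

# subgradient of tv_loss wrt the map (sign convention: sign(0) = 0)
tv_grad <- function(map) {
  d <- dim(map)
  g <- array(0, d)
  for (k in seq_len(d[3])) {
    a <- map[, , k]
    sh <- sign(a[, -1, drop = FALSE] - a[, -d[2], drop = FALSE])
    sv <- sign(a[-1, , drop = FALSE] - a[-d[1], , drop = FALSE])
    gk <- matrix(0, d[1], d[2])
    gk[, -1] <- gk[, -1] + sh
    gk[, -d[2]] <- gk[, -d[2]] - sh
    gk[-1, ] <- gk[-1, ] + sv
    gk[-d[1], ] <- gk[-d[1], ] - sv
    g[, , k] <- gk
  }
  g
}

#' Combined W-Net loss
#'
#' `ce_loss(map, target) + lambda_tv * tv_loss(map)`. The default
#' `lambda_tv = 1` is the unweighted sum of the two terms; training uses a
#' per-pixel scaling (see [wnet_config()]).
#'
#' @inheritParams ce_loss
#' @param lambda_tv Non-negative weight of the total-variation term.
#' @return Non-negative scalar.
#' @export
wnet_loss <- function(map, target, lambda_tv = 1) {
  ce_loss(map, target) + lambda_tv * tv_loss(map)
}

# ---- U-Net building blocks -------------------------------------------------

block_init <- function(c_in, c_out, k) {
  list(conv1 = conv_init(k, c_in, c_out), bn1 = bn_init(c_out),
       conv2 = conv_init(k, c_out, c_out), bn2 = bn_init(c_out))
}

block_forward <- function(fm, wts, training) {
  c1 <- conv_forward(fm, wts$conv1)
  b1 <- bn_forward(c1$out, wts$bn1, training)
  wts$bn1 <- b1$par
  r1 <- relu_forward(b1$out)
  c2 <- conv_forward(r1$out, wts$conv2)
  b2 <- bn_forward(c2$out, wts$bn2, training)
  wts$bn2 <- b2$par
  r2 <- relu_forward(b2$out)
  list(out = r2$out, wts = wts,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

block_backward <- function(d_out, wts, cache) {
  d <- relu_backward(d_out, cache$r2)$d_in
  bb2 <- bn_backward(d, wts$bn2, cache$b2)
  cb2 <- conv_backward(bb2$d_in, wts$conv2, cache$c2)
  d <- relu_backward(cb2$d_in, cache$r1)$d_in
  bb1 <- bn_backward(d, wts$bn1, cache$b1)
  cb1 <- conv_backward(bb1$d_in, wts$conv1, cache$c1)
  grads <- list(conv1 = list(w = cb1$dw, b = cb1$db),
                bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv2 = list(w = cb2$dw, b = cb2$db),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta))
  list(grads = grads, d_in = cb1$d_in)
}

unet_init <- function(in_channels, config, cross_channels = NULL) {
  ch <- wnet_channels(config)
  L <- config$levels
  k <- config$kernel_size
  enc <- vector("list", L)
  cin <- in_channels
  for (l in seq_len(L)) {
    enc[[l]] <- block_init(cin, ch[l], k)
    cin <- ch[l]
  }
  dec <- vector("list", max(L - 1L, 0L))
  for (l in seq_len(L - 1L)) {
    extra <- if (is.null(cross_channels)) 0L else cross_channels[l]
    dec[[l]] <- list(up = conv_init(k, ch[l + 1L], ch[l]),
                     block = block_init(ch[l] + ch[l] + extra, ch[l], k))
  }
  final <- list(w = matrix(stats::rnorm(ch[1] * config$classes,
                                        0, 1 / sqrt(ch[1])),
                           ch[1], config$classes),
                b = numeric(config$classes))
  list(enc = enc, dec = dec, final = final)
}

# Forward pass. cross_feats: optional list of fmaps (one per level) to
# concatenate into the decoder (the cross-U skip path).
unet_forward <- function(fm, wts, config, training, cross_feats = NULL) {
  L <- config$levels
  enc_feats <- vector("list", L)
  enc_caches <- vector("list", L)
  pool_caches <- vector("list", L)
  x <- fm
  for (l in seq_len(L)) {
    bf <- block_forward(x, wts$enc[[l]], training)
    wts$enc[[l]] <- bf$wts
    enc_feats[[l]] <- bf$out
    enc_caches[[l]] <- bf$cache
    if (l < L) {
      pl <- maxpool2_forward(bf$out)
      pool_caches[[l]] <- pl$cache
      x <- pl$out
    } else {
      x <- bf$out
    }
  }
  dec_caches <- vector("list", max(L - 1L, 0L))
  for (l in rev(seq_len(L - 1L))) {
    up <- upsample2_forward(x)
    uc <- conv_forward(up$out, wts$dec[[l]]$up)
    parts <- list(uc$out$x, enc_feats[[l]]$x)
    widths <- c(ncol(uc$out$x), ncol(enc_feats[[l]]$x))
    if (!is.null(cross_feats)) {
      parts <- c(parts, list(cross_feats[[l]]$x))
      widths <- c(widths, ncol(cross_feats[[l]]$x))
    }
    cat_fm <- fmap(do.call(cbind, parts), uc$out$h, uc$out$w, uc$out$b)
    bf <- block_forward(cat_fm, wts$dec[[l]]$block, training)
    wts$dec[[l]]$block <- bf$wts
    dec_caches[[l]] <- list(up = up$cache, upconv = uc$cache,
                            widths = widths, block = bf$cache,
                            cat_dims = c(cat_fm$h, cat_fm$w, cat_fm$b))
    x <- bf$out
  }
  logits <- x$x %*% wts$final$w + rep(wts$final$b, each = nrow(x$x))
  probs <- softmax_rows(logits)
  list(probs = fmap(probs, x$h, x$w, x$b), logits = logits, wts = wts,
       cache = list(enc_feats = enc_feats, enc = enc_caches,
                    pool = pool_caches, dec = dec_caches, last = x))
}

# Backward pass from dL/dlogits. extra_enc_grads: optional list of fmaps of
# gradients flowing into this U-Net's encoder features from elsewhere (the
# cross-U skips of a downstream U-Net). Returns parameter grads, gradient
# wrt the input fmap, and nothing else.
unet_backward <- function(d_logits, wts, config, cache, extra_enc_grads = NULL) {
  L <- config$levels
  last <- cache$last
  grads <- list(enc = vector("list", L), dec = vector("list", max(L - 1L, 0L)),
                final = list(w = crossprod(last$x, d_logits),
                             b = colSums(d_logits)))
  d_enc <- vector("list", L)   # accumulated grads wrt encoder features
  if (!is.null(extra_enc_grads)) {
    for (l in seq_len(L)) {
      if (!is.null(extra_enc_grads[[l]])) d_enc[[l]] <- extra_enc_grads[[l]]
    }
  }
  acc <- function(a, b) if (is.null(a)) b else fmap(a$x + b$x, b$h, b$w, b$b)
  d_x <- fmap(d_logits %*% t(wts$final$w), last$h, last$w, last$b)
  d_cross <- if (!is.null(cache$dec) && length(cache$dec) &&
                 length(cache$dec[[1]]$widths) == 3L) vector("list", L) else NULL
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    bb <- block_backward(d_x, wts$dec[[l]]$block, dc$block)
    grads$dec[[l]]$block <- bb$grads
    w <- dc$widths
    dcat <- bb$d_in
    d_u <- fmap(dcat$x[, seq_len(w[1]), drop = FALSE], dcat$h, dcat$w, dcat$b)
    d_skip <- fmap(dcat$x[, w[1] + seq_len(w[2]), drop = FALSE], dcat$h, dcat$w, dcat$b)
    d_enc[[l]] <- acc(d_enc[[l]], d_skip)
    if (length(w) == 3L) {
      d_cross[[l]] <- fmap(dcat$x[, w[1] + w[2] + seq_len(w[3]), drop = FALSE],
                           dcat$h, dcat$w, dcat$b)
    }
    ucb <- conv_backward(d_u, wts$dec[[l]]$up, dc$upconv)
    grads$dec[[l]]$up <- list(w = ucb$dw, b = ucb$db)
    d_x <- upsample2_backward(ucb$d_in, dc$up)$d_in
  }
  # d_x is now the gradient wrt the bottleneck encoder feature via the
  # decoder chain; add any skip/cross accumulation at level L
  d_cur <- acc(d_enc[[L]], d_x)
  d_in <- NULL
  for (l in rev(seq_len(L))) {
    bb <- block_backward(d_cur, wts$enc[[l]], cache$enc[[l]])
    grads$enc[[l]] <- bb$grads
    if (l > 1L) {
      d_pool <- maxpool2_backward(bb$d_in, cache$pool[[l - 1L]])$d_in
      d_cur <- acc(d_enc[[l - 1L]], d_pool)
    } else {
      d_in <- bb$d_in
    }
  }
  list(grads = grads, d_in = d_in, d_cross = d_cross)
}

# ---- W-Net -----------------------------------------------------------------

wnet_init <- function(config, in_channels = 1L) {
  ch <- wnet_channels(config)
  with_seed(config$seed, {
    u1 <- unet_init(in_channels, config)
    u2 <- unet_init(config$classes, config, cross_channels = ch)
    structure(list(config = config, u1 = u1, u2 = u2,
                   in_channels = as.integer(in_channels),
                   loss_history = tibble::tibble(epoch = integer(),
                                                 loss = numeric())),
              class = "wnet_model")
  })
}

wnet_forward <- function(model, fm, training = FALSE) {
  f1 <- unet_forward(fm, model$u1, model$config, training)
  model$u1 <- f1$wts
  f2 <- unet_forward(f1$probs, model$u2, model$config, training,
                     cross_feats = f1$cache$enc_feats)
  model$u2 <- f2$wts
  list(model = model, probs = f2$probs, f1 = f1, f2 = f2)
}

# reflect-pad a matrix up to (hp, wp)
reflect_pad <- function(m, hp, wp) {
  h <- nrow(m); w <- ncol(m)
  if (hp > 2 * h || wp > 2 * w) stop("padding exceeds image size.", call. = FALSE)
  if (hp > h) m <- rbind(m, m[h:(2 * h - hp + 1), , drop = FALSE])
  if (wp > w) m <- cbind(m, m[, w:(2 * w - wp + 1), drop = FALSE])
  m
}

pad_multiple <- function(size, levels) {
  m <- 2L^(levels - 1L)
  as.integer(ceiling(size / m) * m)
}

#' Train a W-Net segmenter
#'
#' Optimizes the combined cross-entropy + total-variation loss over
#' mini-batches. In `"supervised"` mode targets are the phantoms'
#' ground-truth masks (collapsed to binary foreground when `classes = 2`);
#' in `"selftrain"` mode the target is the argmax pseudo-mask regenerated
#' from the current probability map at every step. With `epochs = 0` the
#' seeded initialization is returned unchanged. Images whose side is not a
#' multiple of `2^(levels - 1)` are reflection-padded internally.
#'
#' @param samples A `phantom_dataset` or list of `phantom_sample` objects.
#' @param config A [wnet_config()].
#' @return A `wnet_model` with a `loss_history` tibble (`epoch`, mean
#'   per-batch `loss`).
#' @export
train_wnet <- function(samples, config = wnet_config()) {
  if (inherits(samples, "phantom_dataset")) samples <- samples$samples
  if (length(samples) == 0) stop("training set is empty.", call. = FALSE)
  model <- wnet_init(config)
  if (config$epochs == 0L) return(model)
  h0 <- nrow(samples[[1]]$image); w0 <- ncol(samples[[1]]$image)
  hp <- pad_multiple(h0, config$levels); wp <- pad_multiple(w0, config$levels)
  imgs <- lapply(samples, function(s) reflect_pad(s$image, hp, wp))
  masks <- lapply(samples, function(s) {
    m <- if (config$classes == 2L) binary_foreground(s$mask) else s$mask
    reflect_pad(m, hp, wp)
  })
  lambda <- if (identical(config$lambda_tv, "auto")) 1 / (hp * wp) else config$lambda_tv
  opt <- make_optimizer(config$optimizer, lr = config$learning_rate)
  n <- length(imgs)
  history <- numeric(config$epochs)
  order_seed <- derive_seed(config$seed, 104729L)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(order_seed, ep), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fm <- fmap_from_images(imgs[bt])
      fw <- wnet_forward(model, fm, training = TRUE)
      model <- fw$model
      probs <- fw$probs
      npx <- nrow(probs$x)
      if (config$mode == "supervised") {
        tgt <- unlist(lapply(masks[bt], as.vector), use.names = FALSE)
      } else {
        tgt <- max.col(probs$x, ties.method = "first") - 1L
      }
      pt <- probs$x[cbind(seq_len(npx), tgt + 1L)]
      ce <- mean(-log(pmax(pt, 1e-12)))
      # TV term per sample, channels of the batched map
      parr <- fmap_to_array(probs)   # hp x wp x K x B
      tv <- 0
      dtv <- array(0, dim(parr))
      for (bi in seq_len(dim(parr)[4])) {
        tv <- tv + tv_loss(parr[, , , bi, drop = TRUE])
        dtv[, , , bi] <- tv_grad(array(parr[, , , bi], dim(parr)[1:3]))
      }
      tv <- tv / length(bt)
      loss <- ce + lambda * tv
      # gradient wrt probabilities, then through the softmax
      one_hot_grad <- matrix(0, npx, config$classes)
      one_hot_grad[cbind(seq_len(npx), tgt + 1L)] <-
        -1 / (pmax(pt, 1e-12) * npx)
      dtv_mat <- matrix(aperm(array(dtv, dim(parr)), c(1, 2, 4, 3)),
                        ncol = config$classes) * (lambda / length(bt))
      d_probs <- one_hot_grad + dtv_mat
      d_logits2 <- softmax_rows_backward(d_probs, probs$x)
      b2 <- unet_backward(d_logits2, model$u2, config, fw$f2$cache)
      d_probs1 <- b2$d_in
      d_logits1 <- softmax_rows_backward(d_probs1$x, fw$f1$probs$x)
      b1 <- unet_backward(d_logits1, model$u1, config, fw$f1$cache,
                          extra_enc_grads = b2$d_cross)
      wts <- list(u1 = model$u1, u2 = model$u2)
      grads <- list(u1 = b1$grads, u2 = b2$grads)
      flat <- opt$step(flatten_params(wts), flatten_params(grads))
      wts <- unflatten_params(flat, wts)
      model$u1 <- wts$u1
      model$u2 <- wts$u2
      ep_loss <- ep_loss + loss * length(bt)
    }
    history[ep] <- ep_loss / n
  }
  model$loss_history <- tibble::tibble(epoch = seq_len(config$epochs),
                                       loss = history)
  model
}

#' Segment an image with a trained W-Net
#'
#' Deterministic inference pass: returns the per-pixel probability map and
#' its argmax pseudo-mask, both at the input image's size. Images whose side
#' is not a multiple of `2^(levels - 1)` are reflection-padded and the
#' outputs cropped back.
#'
#' @param image Numeric matrix in `[0, 1]` (or a `phantom_sample`).
#' @param segmenter A `wnet_model` from [train_wnet()].
#' @return List with `prob` (`H x W x K` array) and `mask` (integer
#'   `H x W`, 0-based classes).
#' @export
segment <- function(image, segmenter) {
  stopifnot(inherits(segmenter, "wnet_model"))
  if (inherits(image, "phantom_sample")) image <- image$image
  h0 <- nrow(image); w0 <- ncol(image)
  cfg <- segmenter$config
  hp <- pad_multiple(h0, cfg$levels); wp <- pad_multiple(w0, cfg$levels)
  img <- reflect_pad(image, hp, wp)
  fw <- wnet_forward(segmenter, fmap_from_images(list(img)), training = FALSE)
  parr <- array(fw$probs$x, c(hp, wp, cfg$classes))
  prob <- parr[seq_len(h0), seq_len(w0), , drop = FALSE]
  list(prob = prob, mask = pseudo_mask(prob))
}

#' Segment many images in batches
#'
#' Same inference as [segment()] but runs several images per forward pass.
#'
#' @param images List of equally sized image matrices (or a
#'   `phantom_dataset`).
#' @param segmenter A `wnet_model`.
#' @param batch_size Images per forward pass.
#' @return List of integer pseudo-masks (0-based classes).
#' @export
segment_batch <- function(images, segmenter, batch_size = 16L) {
  if (inherits(images, "phantom_dataset")) {
    images <- lapply(images$samples, function(s) s$image)
  }
  n <- length(images)
  if (n == 0) return(list())
  cfg <- segmenter$config
  h0 <- nrow(images[[1]]); w0 <- ncol(images[[1]])
  hp <- pad_multiple(h0, cfg$levels); wp <- pad_multiple(w0, cfg$levels)
  padded <- lapply(images, reflect_pad, hp = hp, wp = wp)
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    fw <- wnet_forward(segmenter, fmap_from_images(padded[ids]), training = FALSE)
    parr <- fmap_to_array(fw$probs)   # hp x wp x K x B
    for (j in seq_along(ids)) {
      prob <- array(parr[, , , j], dim(parr)[1:3])[seq_len(h0), seq_len(w0), ,
                                                   drop = FALSE]
      out[[ids[j]]] <- pseudo_mask(prob)
    }
  }
  out
}

#' @export
print.wnet_model <- function(x, ...) {
  ch <- wnet_channels(x$config)
  cat("<wnet_model> 2 chained U-Nets, levels =", x$config$levels,
      " channels =", paste(ch, collapse = "-"),
      " classes =", x$config$classes, "\n")
  if (nrow(x$loss_history)) {
    cat("  trained", max(x$loss_history$epoch), "epochs; final loss",
        signif(x$loss_history$loss[nrow(x$loss_history)], 4), "\n")
  } else cat("  untrained (seeded initialization)\n")
  invisible(x)
}
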