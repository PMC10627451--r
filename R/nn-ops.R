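# Low-level neural-network primitives with hand-written backward passes.
#
# Activations travel as "fmap" objects: a (h*w*b) x C matrix whose rows are
# ordered spatial-column-major within each batch element (i fastest, then j,
# then batch block). This keeps per-pixel ops (ReLU, batch norm, 1x1 conv,
# softmax) as plain BLAS-friendly matrix ops; convolution and pooling
# reshape to H x W x B x C arrays internally. All convolutions use odd
# kernels with symmetric zero padding (k-1)/2, so stride 1 preserves the
# spatial size and stride 2 halves it (ceiling division).

fmap <- function(x, h, w, b) list(x = x, h = h, w = w, b = b)

fmap_from_images <- function(images) {
  # images: list of H x W matrices (single channel)
  h <- nrow(images[[1]]); w <- ncol(images[[1]]); b <- length(images)
  fmap(matrix(unlist(images, use.names = FALSE), ncol = 1), h, w, b)
}

fmap_to_array <- function(fm) {
  # returns H x W x C x B
  a <- array(fm$x, c(fm$h, fm$w, fm$b, ncol(fm$x)))
  aperm(a, c(1, 2, 4, 3))
}

# ---- convolution -----------------------------------------------------------

# memo for gather indices: keyed by geometry, reused across batches/epochs
.conv_memo <- new.env(parent = emptyenv())

conv_spatial_index <- function(h, w, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  sp <- matrix(0L, ho * wo, k * k)
  col <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      ii <- (oi - 1L) * stride + 1L + di
      jj <- (oj - 1L) * stride + 1L + dj
      sp[, col] <- ii + hp * (jj - 1L)
      col <- col + 1L
    }
  }
  list(sp = sp, ho = ho, wo = wo, hp = hp, wp = wp)
}

# zero-padded input as a (hp*wp*b*c) vector laid out (i, j, b, c)
pad_input <- function(fm, pad) {
  h <- fm$h; w <- fm$w; b <- fm$b; cc <- ncol(fm$x)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  if (pad == 0L) {
    a <- array(fm$x, c(h, w, b, cc))
  } else {
    a <- array(0, c(hp, wp, b, cc))
    a[pad + seq_len(h), pad + seq_len(w), , ] <- array(fm$x, c(h, w, b, cc))
  }
  a
}

# patch matrix (ho*wo*b) x (k2*c): column blocks per input channel
im2col <- function(fm, k, stride, pad) {
  cc <- ncol(fm$x)
  zp <- pad_input(fm, pad)
  key <- paste(fm$h, fm$w, k, stride, pad, fm$b, sep = "_")
  memo <- .conv_memo[[key]]
  if (is.null(memo)) {
    ci <- conv_spatial_index(fm$h, fm$w, k, stride, pad)
    n_sp <- nrow(ci$sp)
    hwp <- ci$hp * ci$wp
    idx_sb <- ci$sp[rep(seq_len(n_sp), fm$b), , drop = FALSE] +
      rep(hwp * (seq_len(fm$b) - 1L), each = n_sp)
    memo <- list(idx_sb = idx_sb, ci = ci, hwp = hwp)
    .conv_memo[[key]] <- memo
  }
  zpv <- as.vector(zp)
  k2 <- k * k
  hwp <- memo$hwp
  b <- fm$b
  P <- matrix(0, nrow(memo$idx_sb), k2 * cc)
  for (ch in seq_len(cc)) {
    P[, (ch - 1L) * k2 + seq_len(k2)] <- zpv[memo$idx_sb + hwp * b * (ch - 1L)]
  }
  list(P = P, idx_sb = memo$idx_sb, ci = memo$ci, hwp = hwp)
}

# weights: list(w = array(k, k, c_in, c_out), b = numeric(c_out))
conv_init <- function(k, c_in, c_out, gain = sqrt(2)) {
  sd <- gain / sqrt(k * k * c_in)
  list(w = array(stats::rnorm(k * k * c_in * c_out, 0, sd), c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

conv_forward <- function(fm, par, stride = 1L) {
  k <- dim(par$w)[1]
  pad <- (k - 1L) %/% 2L
  ic <- im2col(fm, k, stride, pad)
  wm <- matrix(par$w, ncol = dim(par$w)[4])
  out <- ic$P %*% wm
  out <- out + rep(par$b, each = nrow(out))
  list(out = fmap(out, ic$ci$ho, ic$ci$wo, fm$b),
       cache = list(input = fm, k = k, stride = stride, pad = pad, P = ic$P,
                    idx_sb = ic$idx_sb, ci = ic$ci, hwp = ic$hwp))
}

conv_backward <- function(d_out, par, cache) {
  fm <- cache$input
  k <- cache$k; k2 <- k * k
  cc <- ncol(fm$x)
  dw <- array(crossprod(cache$P, d_out$x), dim(par$w))
  db <- colSums(d_out$x)
  b <- fm$b
  if (cache$stride == 1L) {
    # stride-1 input gradient is a convolution of d_out with the spatially
    # flipped kernel and swapped in/out channels
    w_flip <- aperm(par$w[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
    icb <- im2col(d_out, k, 1L, cache$pad)
    din_mat <- icb$P %*% matrix(w_flip, ncol = cc)
    return(list(dw = dw, db = db, d_in = fmap(din_mat, fm$h, fm$w, b)))
  }
  wm <- matrix(par$w, ncol = dim(par$w)[4])
  dP <- d_out$x %*% t(wm)
  hwp <- cache$hwp
  dzp <- numeric(hwp * b * cc)
  for (ch in seq_len(cc)) {
    off <- hwp * b * (ch - 1L)
    for (kk in seq_len(k2)) {
      ii <- cache$idx_sb[, kk] + off
      dzp[ii] <- dzp[ii] + dP[, (ch - 1L) * k2 + kk]
    }
  }
  dzp <- array(dzp, c(cache$ci$hp, cache$ci$wp, b, cc))
  pad <- cache$pad
  din <- dzp[pad + seq_len(fm$h), pad + seq_len(fm$w), , , drop = FALSE]
  list(dw = dw, db = db,
       d_in = fmap(matrix(din, ncol = cc), fm$h, fm$w, b))
}

# ---- depthwise convolution (ghost cheap operations) ------------------------

dwconv_init <- function(k, cc, gain = sqrt(2)) {
  sd <- gain / sqrt(k * k)
  list(w = matrix(stats::rnorm(k * k * cc, 0, sd), k * k, cc), b = numeric(cc))
}

dwconv_forward <- function(fm, par, stride = 1L) {
  k <- as.integer(sqrt(nrow(par$w)))
  pad <- (k - 1L) %/% 2L
  ic <- im2col(fm, k, stride, pad)
  cc <- ncol(fm$x); k2 <- k * k
  n <- nrow(ic$P)
  out <- matrix(0, n, cc)
  for (ch in seq_len(cc)) {
    out[, ch] <- ic$P[, (ch - 1L) * k2 + seq_len(k2), drop = FALSE] %*% par$w[, ch] + par$b[ch]
  }
  list(out = fmap(out, ic$ci$ho, ic$ci$wo, fm$b),
       cache = list(input = fm, k = k, stride = stride, pad = pad, P = ic$P,
                    idx_sb = ic$idx_sb, ci = ic$ci, hwp = ic$hwp))
}

dwconv_backward <- function(d_out, par, cache) {
  fm <- cache$input
  k <- cache$k; k2 <- k * k
  cc <- ncol(fm$x)
  dw <- matrix(0, k2, cc)
  db <- colSums(d_out$x)
  for (ch in seq_len(cc)) {
    cols <- (ch - 1L) * k2 + seq_len(k2)
    dw[, ch] <- crossprod(cache$P[, cols, drop = FALSE], d_out$x[, ch])
  }
  b <- fm$b
  if (cache$stride == 1L) {
    icb <- im2col(d_out, k, 1L, cache$pad)
    din <- matrix(0, nrow(icb$P), cc)
    for (ch in seq_len(cc)) {
      cols <- (ch - 1L) * k2 + seq_len(k2)
      din[, ch] <- icb$P[, cols, drop = FALSE] %*% rev(par$w[, ch])
    }
    return(list(dw = dw, db = db, d_in = fmap(din, fm$h, fm$w, b)))
  }
  hwp <- cache$hwp
  dzp <- numeric(hwp * b * cc)
  for (ch in seq_len(cc)) {
    dP_c <- tcrossprod(d_out$x[, ch], par$w[, ch])
    off <- hwp * b * (ch - 1L)
    for (kk in seq_len(k2)) {
      ii <- cache$idx_sb[, kk] + off
      dzp[ii] <- dzp[ii] + dP_c[, kk]
    }
  }
  dzp <- array(dzp, c(cache$ci$hp, cache$ci$wp, b, cc))
  pad <- cache$pad
  din <- dzp[pad + seq_len(fm$h), pad + seq_len(fm$w), , , drop = FALSE]
  list(dw = dw, db = db, d_in = fmap(matrix(din, ncol = cc), fm$h, fm$w, b))
}

# ---- pooling / upsampling --------------------------------------------------

maxpool2_forward <- function(fm) {
  h <- fm$h; w <- fm$w
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  cc <- ncol(fm$x); b <- fm$b
  a <- array(fm$x, c(h, w, b, cc))
  i1 <- seq(1L, h, 2L); j1 <- seq(1L, w, 2L)
  x11 <- a[i1, j1, , , drop = FALSE]; x21 <- a[i1 + 1L, j1, , , drop = FALSE]
  x12 <- a[i1, j1 + 1L, , , drop = FALSE]; x22 <- a[i1 + 1L, j1 + 1L, , , drop = FALSE]
  out <- pmax(x11, x21, x12, x22)
  list(out = fmap(matrix(out, ncol = cc), h %/% 2L, w %/% 2L, b),
       cache = list(input = fm))
}

maxpool2_backward <- function(d_out, cache) {
  fm <- cache$input
  h <- fm$h; w <- fm$w; cc <- ncol(fm$x); b <- fm$b
  a <- array(fm$x, c(h, w, b, cc))
  i1 <- seq(1L, h, 2L); j1 <- seq(1L, w, 2L)
  slices <- list(
    list(i1, j1), list(i1 + 1L, j1), list(i1, j1 + 1L), list(i1 + 1L, j1 + 1L)
  )
  vals <- lapply(slices, function(s) a[s[[1]], s[[2]], , , drop = FALSE])
  mx <- pmax(vals[[1]], vals[[2]], vals[[3]], vals[[4]])
  dm <- array(d_out$x, c(h %/% 2L, w %/% 2L, b, cc))
  da <- array(0, c(h, w, b, cc))
  taken <- array(FALSE, dim(mx))
  for (q in 1:4) {
    hit <- (vals[[q]] == mx) & !taken
    da[slices[[q]][[1]], slices[[q]][[2]], , ] <- dm * hit
    taken <- taken | hit
  }
  list(d_in = fmap(matrix(da, ncol = cc), h, w, b))
}

upsample2_forward <- function(fm) {
  h <- fm$h; w <- fm$w; cc <- ncol(fm$x); b <- fm$b
  a <- array(fm$x, c(h, w, b, cc))
  out <- a[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , , drop = FALSE]
  list(out = fmap(matrix(out, ncol = cc), 2L * h, 2L * w, b),
       cache = list(h = h, w = w, b = b, cc = cc))
}

upsample2_backward <- function(d_out, cache) {
  h <- cache$h; w <- cache$w; cc <- cache$cc; b <- cache$b
  da <- array(d_out$x, c(2L * h, 2L * w, b, cc))
  i1 <- seq(1L, 2L * h, 2L); j1 <- seq(1L, 2L * w, 2L)
  din <- da[i1, j1, , , drop = FALSE] + da[i1 + 1L, j1, , , drop = FALSE] +
    da[i1, j1 + 1L, , , drop = FALSE] + da[i1 + 1L, j1 + 1L, , , drop = FALSE]
  list(d_in = fmap(matrix(din, ncol = cc), h, w, b))
}

# ---- batch normalization ---------------------------------------------------

bn_init <- function(cc) {
  list(gamma = rep(1, cc), beta = numeric(cc),
       run_mean = numeric(cc), run_var = rep(1, cc))
}

bn_forward <- function(fm, par, training = TRUE, momentum = 0.1, eps = 1e-5) {
  x <- fm$x
  n <- nrow(x)
  if (training && n > 1L) {
    mu <- colMeans(x)
    va <- colMeans(x * x) - mu^2
    va <- pmax(va, 0)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * va
  } else {
    mu <- par$run_mean
    va <- par$run_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (x - rep(mu, each = n)) * rep(istd, each = n)
  y <- xhat * rep(par$gamma, each = n) + rep(par$beta, each = n)
  list(out = fmap(y, fm$h, fm$w, fm$b), par = par,
       cache = list(xhat = xhat, istd = istd, fm = fm, training = training))
}

bn_backward <- function(d_out, par, cache) {
  dy <- d_out$x
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (cache$training && n > 1L) {
    dxhat <- dy * rep(par$gamma, each = n)
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$istd, each = n)
  } else {
    dx <- dy * rep(par$gamma * cache$istd, each = n)
  }
  list(dgamma = dgamma, dbeta = dbeta,
       d_in = fmap(dx, cache$fm$h, cache$fm$w, cache$fm$b))
}

# ---- pointwise -------------------------------------------------------------

relu_forward <- function(fm) {
  list(out = fmap(pmax(fm$x, 0), fm$h, fm$w, fm$b), cache = list(pos = fm$x > 0))
}

relu_backward <- function(d_out, cache) {
  list(d_in = fmap(d_out$x * cache$pos, d_out$h, d_out$w, d_out$b))
}

# row-wise softmax on a matrix (pixels/samples x classes)
softmax_rows <- function(x) {
  rm <- x[, 1]
  if (ncol(x) > 1L) for (j in 2:ncol(x)) rm <- pmax(rm, x[, j])
  e <- exp(x - rm)
  e / rowSums(e)
}

# gradient through row softmax: given dL/dp, return dL/dlogits
softmax_rows_backward <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

# ---- optimizers ------------------------------------------------------------

# Parameters and gradients are flat named lists of numeric arrays; the
# optimizer closes over per-parameter state.
make_optimizer <- function(kind = c("adam", "sgd"), lr = 1e-3,
                           momentum = 0.9, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  kind <- match.arg(kind)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  step <- function(params, grads) {
    state$t <- state$t + 1L
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      if (kind == "sgd") {
        v <- state[[paste0("v_", nm)]] %||% (g * 0)
        v <- momentum * v - lr * g
        state[[paste0("v_", nm)]] <- v
        params[[nm]] <- params[[nm]] + v
      } else {
        m <- state[[paste0("m_", nm)]] %||% (g * 0)
        v <- state[[paste0("v_", nm)]] %||% (g * 0)
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        state[[paste0("m_", nm)]] <- m
        state[[paste0("v_", nm)]] <- v
        mh <- m / (1 - beta1^state$t)
        vh <- v / (1 - beta2^state$t)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    params
  }
  list(step = step, kind = kind, lr = lr)
}

# flatten/unflatten nested weight lists so optimizers see one flat list;
# unnamed list levels (e.g. per-level encoder blocks) are keyed by index
flatten_params <- function(x, prefix = "") {
  out <- list()
  keys <- names(x) %||% as.character(seq_along(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (is.null(v)) next
    key <- if (prefix == "") keys[i] else paste0(prefix, ".", keys[i])
    if (is.list(v)) out <- c(out, flatten_params(v, key)) else out[[key]] <- v
  }
  out
}

unflatten_params <- function(flat, skeleton, prefix = "") {
  keys <- names(skeleton) %||% as.character(seq_along(skeleton))
  for (i in seq_along(skeleton)) {
    key <- if (prefix == "") keys[i] else paste0(prefix, ".", keys[i])
    if (is.list(skeleton[[i]])) {
      skeleton[[i]] <- unflatten_params(flat, skeleton[[i]], key)
    } else if (!is.null(flat[[key]])) {
      skeleton[[i]] <- flat[[key]]
    }
  }
  skeleton
}
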