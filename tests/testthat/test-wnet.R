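test_that("softmax normalization lands on the per-pixel simplex", {
  z <- array(0, c(2, 2, 2))
  p <- softmax_normalize(z)
  expect_equal(as.numeric(p[1, 1, ]), c(0.5, 0.5))
  z[1, 1, ] <- c(0, log(3))
  p <- softmax_normalize(z)
  expect_equal(as.numeric(p[1, 1, ]), c(0.25, 0.75))
  set.seed(1)
  r <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  p <- softmax_normalize(r)
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-12)
  expect_true(all(p >= 0))
  expect_error(softmax_normalize(array(c(NA, 1), c(1, 1, 2))), "finite")
})

test_that("pseudo-mask is the argmax with ties to the lower class", {
  p <- array(c(0.9, 0.5, 0.1, 0.5), c(1, 2, 2))
  m <- pseudo_mask(p)
  expect_equal(as.vector(m), c(0L, 0L))   # clear argmax and tie case
  # argmax invariance: softmax and any strictly monotone transform
  set.seed(7)
  for (rep in 1:5) {
    r <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
    expect_identical(pseudo_mask(r), pseudo_mask(softmax_normalize(r)))
    expect_identical(pseudo_mask(r), pseudo_mask(tanh(r / 4)))
    expect_identical(pseudo_mask(r), pseudo_mask(2 * r + 1))
  }
})

test_that("cross-entropy loss reproduces hand-computed values", {
  K2 <- function(p) {
    a <- array(0, c(dim(p), 2)); a[, , 1] <- p; a[, , 2] <- 1 - p; a
  }
  perfect <- K2(matrix(1, 3, 3))
  expect_equal(ce_loss(perfect, matrix(0L, 3, 3)), 0)
  half <- K2(matrix(0.5, 4, 7))
  expect_equal(ce_loss(half, matrix(0L, 4, 7)), 0.693147, tolerance = 1e-6)
  two <- K2(matrix(c(1, 0.25), 1, 2))
  expect_equal(ce_loss(two, matrix(0L, 1, 2)), (0 + 1.386294) / 2,
               tolerance = 1e-6)
  # zero probability at the target is clamped, not infinite
  expect_true(is.finite(ce_loss(K2(matrix(0, 2, 2)), matrix(0L, 2, 2))))
  # moving mass toward the target class decreases the loss (1-pixel grid)
  probs <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(probs, function(p) ce_loss(K2(matrix(p, 1, 2)),
                                              matrix(0L, 1, 2)), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("total-variation loss matches enumeration and is homogeneous", {
  expect_equal(tv_loss(array(0.3, c(4, 4, 2))), 0)
  m <- matrix(c(0, 0, 1, 1), 2, 2)    # rows (0,1)/(0,1): one jump per row
  expect_equal(tv_loss(m), 2)
  set.seed(2)
  a <- array(runif(5 * 6 * 2), c(5, 6, 2))
  # independent enumeration over all neighbor pairs
  ref <- 0
  for (k in 1:2) for (i in 1:5) for (j in 1:6) {
    if (i < 5) ref <- ref + abs(a[i + 1, j, k] - a[i, j, k])
    if (j < 6) ref <- ref + abs(a[i, j + 1, k] - a[i, j, k])
  }
  expect_equal(tv_loss(a), ref, tolerance = 1e-12)
  expect_equal(tv_loss(2 * a), 2 * tv_loss(a), tolerance = 1e-12)
  expect_gt(tv_loss(a), 0)
  expect_error(tv_loss(matrix(1, 1, 5)), "2 pixels")
})

test_that("combined loss is the sum of its parts", {
  set.seed(3)
  p <- softmax_normalize(array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  tgt <- matrix(sample(0:1, 16, TRUE), 4, 4)
  expect_equal(wnet_loss(p, tgt), ce_loss(p, tgt) + tv_loss(p), tolerance = 1e-12)
  expect_equal(wnet_loss(p, tgt, lambda_tv = 0), ce_loss(p, tgt), tolerance = 1e-12)
  one_hot <- array(0, c(4, 4, 2)); one_hot[, , 1] <- 1
  expect_equal(wnet_loss(one_hot, matrix(0L, 4, 4)), 0)
})

test_that("the default encoder channel schedule doubles from 8 to 128", {
  model <- phantomnet:::wnet_init(wnet_config())
  sched <- vapply(model$u1$enc, function(b) dim(b$conv1$w)[4], numeric(1))
  expect_equal(sched, c(8, 16, 32, 64, 128))
  # decoder mirrors the schedule back down
  dec <- vapply(model$u1$dec, function(d) dim(d$block$conv1$w)[4], numeric(1))
  expect_equal(dec, c(8, 16, 32, 64))
})

test_that("zero-epoch training returns the seeded initialization", {
  ds <- make_dataset(2, 2, tiny_phantom_config(), seed = 1)
  cfg <- wnet_config(levels = 2, base_channels = 4, max_channels = 8,
                     epochs = 0, seed = 11)
  trained <- train_wnet(ds, cfg)
  init <- phantomnet:::wnet_init(cfg)
  expect_identical(trained$u1, init$u1)
  expect_identical(trained$u2, init$u2)
  expect_error(train_wnet(list(), cfg), "empty")
})

test_that("supervised training reduces the loss and segments held-out phantoms", {
  fx <- small_segmenter()
  hist <- fx$model$loss_history$loss
  expect_lt(hist[length(hist)], hist[1])
  sg <- segment(fx$held_out$samples[[1]], fx$model)
  expect_equal(dim(sg$mask), dim(fx$held_out$samples[[1]]$image))
  expect_lt(max(abs(apply(sg$prob, c(1, 2), sum) - 1)), 1e-6)
  expect_identical(sg$mask, pseudo_mask(sg$prob))
  # inference determinism
  sg2 <- segment(fx$held_out$samples[[1]], fx$model)
  expect_identical(sg$prob, sg2$prob)
  # held-out foreground overlap
  dice <- vapply(fx$held_out$samples, function(s) {
    dice_coefficient(segment(s$image, fx$model)$mask, binary_foreground(s$mask))
  }, numeric(1))
  expect_gt(mean(dice), 0.80)
  # batched inference agrees with one-at-a-time inference
  masks <- segment_batch(lapply(fx$held_out$samples[1:3], `[[`, "image"),
                         fx$model, batch_size = 2)
  expect_identical(masks[[1]], segment(fx$held_out$samples[[1]]$image, fx$model)$mask)
})

test_that("self-training mode runs against its own pseudo-masks", {
  ds <- make_dataset(3, 3, tiny_phantom_config(), seed = 21)
  cfg <- wnet_config(levels = 2, base_channels = 4, max_channels = 8,
                     epochs = 2, batch_size = 6, mode = "selftrain", seed = 2)
  m <- train_wnet(ds, cfg)
  expect_equal(nrow(m$loss_history), 2)
  expect_true(all(is.finite(m$loss_history$loss)))
})

test_that("images are reflection-padded to the pyramid size and cropped back", {
  ds <- make_dataset(2, 2, phantom_config(image_size = 36), seed = 3)
  cfg <- wnet_config(levels = 3, base_channels = 4, max_channels = 8,
                     epochs = 1, batch_size = 4, seed = 2)
  m <- train_wnet(ds, cfg)     # 36 is not a multiple of 4; padding to 40
  sg <- segment(ds$samples[[1]]$image, m)
  expect_equal(dim(sg$mask), c(36, 36))
})
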