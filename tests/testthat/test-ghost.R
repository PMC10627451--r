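test_that("ghost spec enforces N = m * s and positive counts", {
  sp <- ghost_spec(M = 4, N = 8, s = 2)
  expect_equal(sp$m, 4L)
  expect_error(ghost_spec(M = 4, N = 9, s = 2), "divisible")
  expect_error(ghost_spec(M = 4, N = 8, s = 0), ">= 1")
})

test_that("ghost convolution with s = 1 equals a plain convolution oracle", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  sp <- ghost_spec(M = 3, N = 4, s = 1)
  w <- phantomnet:::ghost_weights_init(sp, seed = 9)
  g <- ghost_conv(x, sp, weights = w)
  ref <- naive_conv(x, w$primary$w, w$primary$b)
  expect_equal(dim(g), c(8, 8, 4))
  expect_lt(max(abs(g - ref)), 1e-10)
})

test_that("ghost output splits into primary and cheap map blocks", {
  set.seed(12)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  sp <- ghost_spec(M = 4, N = 8, s = 2)
  w <- phantomnet:::ghost_weights_init(sp, seed = 9)
  g <- ghost_conv(x, sp, weights = w)
  expect_equal(dim(g)[3], 8)
  # identity cheap kernels copy the primaries exactly
  w$cheap[[1]]$w[] <- 0
  w$cheap[[1]]$w[5, ] <- 1       # center tap of the 3x3 kernel
  w$cheap[[1]]$b[] <- 0
  g <- ghost_conv(x, sp, weights = w)
  expect_equal(g[, , 5:8], g[, , 1:4], tolerance = 1e-12)
  # every block of a configured extractor emits m * s maps
  ex <- phantomnet:::ghost_extractor_init(ghost_config(blocks = c(8L, 16L, 32L)))
  for (i in seq_along(ex$specs)) {
    expect_equal(ex$specs[[i]]$m * ex$specs[[i]]$s, ex$specs[[i]]$N)
  }
})

test_that("cost ratio matches explicit integer arithmetic and its limits", {
  sp <- ghost_spec(M = 16, N = 32, s = 2, D_k = 3, D_F = 32, cheap_kernel = 3)
  expect_equal(ghost_cost_ratio(sp), 4718592 / (2359296 + 147456),
               tolerance = 1e-12)
  expect_equal(ghost_cost_ratio(ghost_spec(M = 16, N = 32, s = 1)), 1.0)
  # approaches s for large M; monotone in M for s > 1
  ratios <- vapply(c(8, 32, 128, 1024, 1e4), function(M) {
    ghost_cost_ratio(ghost_spec(M = M, N = 32, s = 2))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios < 2))
  expect_lt(abs(ratios[length(ratios)] - 2) / 2, 0.01)
  # the as-printed variant undercounts the cheap operations, so it always
  # overstates the saving relative to the full cost model
  sp16 <- ghost_spec(M = 16, N = 32, s = 2)
  expect_gt(ghost_cost_ratio(sp16, as_printed = TRUE), ghost_cost_ratio(sp16))
  expect_equal(ghost_cost_ratio(sp16, as_printed = TRUE),
               4718592 / (2359296 + 9216), tolerance = 1e-12)
})

test_that("feature extraction is deterministic with the contracted dimension", {
  fx <- small_extractor()
  s <- fx$data$samples[[1]]
  f1 <- extract_features(s$image, s$mask, fx$extractor)
  f2 <- extract_features(s$image, s$mask, fx$extractor)
  expect_identical(f1, f2)
  expect_length(f1, fx$extractor$config$feature_dim)
  # zero image with zero biases gives a zero feature vector
  ex0 <- phantomnet:::ghost_extractor_init(ghost_config(blocks = c(8L, 16L, 32L),
                                                        stem_channels = 4L))
  ex0$stem$b[] <- 0
  for (i in seq_along(ex0$blocks)) {
    ex0$blocks[[i]]$primary$b[] <- 0
    for (j in seq_along(ex0$blocks[[i]]$cheap)) ex0$blocks[[i]]$cheap[[j]]$b[] <- 0
  }
  z <- extract_features(matrix(0, 32, 32), NULL, ex0, mode = "raw")
  expect_equal(z, rep(0, 32))
  expect_error(extract_features(s$image, s$mask[1:10, 1:10], fx$extractor),
               "disagree")
  expect_error(extract_features(s$image, NULL, fx$extractor, mode = "masked"),
               "mask")
})

test_that("training reduces cross-entropy and separates the classes", {
  fx <- small_extractor()
  hist <- fx$extractor$loss_history$loss
  expect_lt(hist[length(hist)], hist[1])
  # zero-epoch training returns the seeded extractor unchanged
  cfg0 <- ghost_config(blocks = c(8L, 16L, 32L), epochs = 0)
  both <- c(1:5, 101:105)            # five samples from each class
  ex0 <- train_extractor(fx$images[both], fx$data$index$label[both], cfg0)
  expect_identical(ex0$stem, phantomnet:::ghost_extractor_init(cfg0)$stem)
  expect_error(train_extractor(fx$images[1:5], rep(1, 5), ghost_config()),
               "single class")
  # on fresh phantoms, tumor/non-tumor pairs sit farther apart in feature
  # space than same-class pairs, averaged over 20 seeded pairs
  pcfg <- phantom_config(image_size = 64)
  feat_of <- function(label, seed) {
    s <- make_phantom(pcfg, label, seed)
    extract_features(s$image, s$mask, fx$extractor)
  }
  f0 <- t(vapply(3001:3020, function(sd) feat_of(0, sd), numeric(64)))
  f1 <- t(vapply(3001:3020, function(sd) feat_of(1, sd), numeric(64)))
  set.seed(4)
  cross <- replicate(20, sqrt(sum((f1[sample(20, 1), ] - f0[sample(20, 1), ])^2)))
  within <- replicate(20, {
    ij <- sample(20, 2)
    src <- if (runif(1) < 0.5) f0 else f1
    sqrt(sum((src[ij[1], ] - src[ij[2], ])^2))
  })
  expect_gt(mean(cross), mean(within))
})
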