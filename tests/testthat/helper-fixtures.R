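# Shared fixtures and independent oracles. Heavy objects are built once and
# cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_phantom_config <- function(size = 32) phantom_config(image_size = size)

# small trained segmenter shared by the W-Net behavior tests
small_segmenter <- function() {
  fixture("small_segmenter", function() {
    ds <- make_dataset(12, 12, tiny_phantom_config(), seed = 31)
    cfg <- wnet_config(levels = 2, base_channels = 8, max_channels = 16,
                       classes = 2, epochs = 12, batch_size = 8,
                       learning_rate = 3e-3, seed = 5)
    list(model = train_wnet(ds, cfg), data = ds,
         held_out = make_dataset(8, 8, tiny_phantom_config(), seed = 777))
  })
}

# trained ghost extractor on masked 64-pixel phantoms; big enough that the
# extractor generalizes to unseen phantom geometry
small_extractor <- function() {
  fixture("small_extractor", function() {
    ds <- make_dataset(100, 100, phantom_config(image_size = 64), seed = 91)
    imgs <- lapply(ds$samples, function(s) s$image * (s$mask != 0))
    cfg <- ghost_config(epochs = 15, batch_size = 16, learning_rate = 3e-3,
                        seed = 3)
    list(extractor = train_extractor(imgs, ds$index$label, cfg), data = ds,
         images = imgs, config = cfg)
  })
}

# independent dense convolution oracle: direct quadruple loop, zero padding,
# odd kernel, stride 1
naive_conv <- function(input, w, bias) {
  d <- dim(input)                       # H x W x Cin
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  p <- (k - 1) / 2
  out <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- bias[co]
      for (di in seq_len(k)) for (dj in seq_len(k)) for (ci in seq_len(cin)) {
        ii <- i + di - 1 - p; jj <- j + dj - 1 - p
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
          acc <- acc + input[ii, jj, ci] * w[di, dj, ci, co]
        }
      }
      out[i, j, co] <- acc
    }
  }
  out
}
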