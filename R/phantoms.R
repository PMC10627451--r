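# Synthetic CT-like phantom generation: elliptical organ on a dark
# background, with an optional bright circular tumor blob, piecewise-constant
# intensities plus additive Gaussian noise. Stands in for clinical scans so
# the whole pipeline is testable end to end with known ground truth.

#' Phantom generator configuration
#'
#' Defines the geometry and intensity model of the synthetic phantoms: a
#' square grayscale frame containing one axis-aligned elliptical "organ"
#' and, for class-1 samples, one circular "tumor" blob strictly inside the
#' organ. Intensities are piecewise constant (background / organ / tumor)
#' with additive Gaussian noise, clipped to `[0, 1]`.
#'
#' Default geometry scales with `image_size`: organ semi-axes in
#' `[0.22, 0.35] * image_size` and tumor radius in
#' `[0.06, 0.11] * image_size`, so the blob always fits inside the organ
#' with margin. Default intensities (0.05, 0.45, 0.85) are pairwise
#' separated by well over `2 * noise_sigma` at the default
#' `noise_sigma = 0.05`.
#'
#' @param image_size Side length in pixels (square frame), at least 32.
#' @param organ_axes_range Length-2 numeric, pixel bounds for the organ's
#'   semi-axes.
#' @param tumor_radius_range Length-2 numeric, pixel bounds for the tumor
#'   blob radius.
#' @param intensity_levels Named numeric of mean intensities in `[0, 1]`
#'   for `background`, `organ`, `tumor`.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer default seed used when no per-sample seed is given.
#' @return A `phantom_config` list.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 64)
#' s <- make_phantom(cfg, label = 1, seed = 7)
#' table(s$mask)
phantom_config <- function(image_size = 128,
                           organ_axes_range = NULL,
                           tumor_radius_range = NULL,
                           intensity_levels = c(background = 0.05,
                                                organ = 0.45,
                                                tumor = 0.85),
                           noise_sigma = 0.05,
                           seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1L || image_size < 32) {
    stop("`image_size` must be a single number >= 32.", call. = FALSE)
  }
  image_size <- as.integer(image_size)
  if (is.null(organ_axes_range)) {
    organ_axes_range <- round(image_size * c(0.22, 0.35))
  }
  if (is.null(tumor_radius_range)) {
    tumor_radius_range <- pmax(3, round(image_size * c(0.06, 0.11)))
  }
  stopifnot(length(organ_axes_range) == 2, length(tumor_radius_range) == 2,
            length(intensity_levels) == 3)
  if (is.null(names(intensity_levels))) {
    names(intensity_levels) <- c("background", "organ", "tumor")
  }
  if (diff(organ_axes_range) < 0 || diff(tumor_radius_range) < 0) {
    stop("ranges must be increasing (low, high).", call. = FALSE)
  }
  if (tumor_radius_range[2] >= organ_axes_range[1]) {
    stop("tumor radius incompatible with organ axes: max tumor radius (",
         tumor_radius_range[2], ") must be smaller than the minimum organ ",
         "semi-axis (", organ_axes_range[1], ").", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0.", call. = FALSE)
  structure(
    list(image_size = image_size,
         organ_axes_range = as.numeric(organ_axes_range),
         tumor_radius_range = as.numeric(tumor_radius_range),
         intensity_levels = intensity_levels,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Generate a single synthetic phantom
#'
#' Draws one phantom sample deterministically from `(config, label, seed)`:
#' the organ ellipse center is jittered within the central third of the
#' frame, semi-axes are drawn from `organ_axes_range`, and for `label = 1` a
#' circular tumor blob with radius from `tumor_radius_range` is placed
#' strictly inside the organ. The mask codes 0 = background, 1 = organ,
#' 2 = tumor; `label = 1` exactly when the mask contains tumor pixels.
#'
#' @param config A [phantom_config()].
#' @param label Class label, 0 (no tumor) or 1 (tumor present).
#' @param seed Integer seed; the same `(config, label, seed)` triple always
#'   yields a bit-identical sample.
#' @return A `phantom_sample` list with elements `image` (numeric matrix in
#'   `[0, 1]`), `mask` (integer matrix in `{0, 1, 2}`), `label`, and
#'   `geometry` (drawn centers/axes/radius).
#' @export
make_phantom <- function(config = phantom_config(), label, seed = config$seed) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1.", call. = FALSE)
  n <- config$image_size
  lv <- config$intensity_levels
  with_seed(seed, {
    cx <- stats::runif(1, n / 3, 2 * n / 3)
    cy <- stats::runif(1, n / 3, 2 * n / 3)
    a <- runif_in(1, config$organ_axes_range[1], config$organ_axes_range[2])
    b <- runif_in(1, config$organ_axes_range[1], config$organ_axes_range[2])
    xs <- matrix(seq_len(n), n, n)              # row coordinate
    ys <- matrix(seq_len(n), n, n, byrow = TRUE)
    organ <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    mask <- matrix(0L, n, n)
    mask[organ] <- 1L
    geometry <- list(center = c(cx, cy), axes = c(a, b))
    if (label == 1) {
      r <- runif_in(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
      # place the blob center in an ellipse shrunk by (r + 1) per axis so the
      # disc stays strictly inside the organ
      sa <- a - r - 1
      sb <- b - r - 1
      if (sa <= 0 || sb <= 0) {
        stop("tumor radius incompatible with organ axes for this draw.",
             call. = FALSE)
      }
      theta <- stats::runif(1, 0, 2 * pi)
      rho <- sqrt(stats::runif(1)) * 0.95
      tx <- cx + rho * sa * cos(theta)
      ty <- cy + rho * sb * sin(theta)
      tumor <- (xs - tx)^2 + (ys - ty)^2 <= r^2
      if (any(tumor & !organ)) {
        stop("internal error: tumor blob escaped the organ ellipse.", call. = FALSE)
      }
      mask[tumor] <- 2L
      geometry$tumor_center <- c(tx, ty)
      geometry$tumor_radius <- r
    }
    img <- matrix(lv[["background"]], n, n)
    img[mask == 1L] <- lv[["organ"]]
    img[mask == 2L] <- lv[["tumor"]]
    if (config$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask, label = as.integer(label),
                   geometry = geometry, seed = as.integer(seed)),
              class = "phantom_sample")
  })
}

#' Generate a balanced (or arbitrary-count) phantom dataset
#'
#' Produces `n_tumor` class-1 and `n_non_tumor` class-0 samples. Each
#' sample's seed is derived as `seed + index`, so regeneration is
#' reproducible and independent of generation order.
#'
#' @param n_tumor,n_non_tumor Non-negative sample counts per class.
#' @param config A [phantom_config()].
#' @param seed Integer base seed.
#' @return A `phantom_dataset`: list with `samples` (list of
#'   `phantom_sample`) and `index` (a tibble with `sample_id`, `label`,
#'   `seed`).
#' @export
#' @examples
#' ds <- make_dataset(3, 5, phantom_config(image_size = 32), seed = 1)
#' nrow(ds$index)      # 8
#' sum(ds$index$label) # 3
make_dataset <- function(n_tumor, n_non_tumor, config = phantom_config(), seed = 1L) {
  if (n_tumor < 0 || n_non_tumor < 0) {
    stop("sample counts must be non-negative.", call. = FALSE)
  }
  labels <- c(rep(1L, n_tumor), rep(0L, n_non_tumor))
  n <- length(labels)
  seeds <- if (n > 0) vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1)) else integer(0)
  samples <- lapply(seq_len(n), function(i) make_phantom(config, labels[i], seeds[i]))
  structure(
    list(samples = samples,
         index = tibble::tibble(sample_id = seq_len(n), label = labels, seed = seeds),
         config = config),
    class = "phantom_dataset"
  )
}

#' Split specification for train/test partitioning
#'
#' @param train_fraction Fraction of samples assigned to training, in
#'   `(0, 1)`; the study protocol uses the presets 0.8 and 0.6.
#' @param stratified Keep per-class proportions (train count per class is
#'   `round(train_fraction * class size)`).
#' @param seed Integer seed for the shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a phantom dataset into train and test sets
#'
#' Disjoint, exhaustive partition. Under stratification every class
#' contributes `round(train_fraction * class size)` training samples; the
#' assignment is a seeded shuffle, so identical inputs give identical
#' splits.
#'
#' @param dataset A `phantom_dataset` from [make_dataset()].
#' @param spec A [split_spec()] (or a bare train fraction).
#' @return A list with `train` and `test` (both `phantom_dataset`), plus
#'   `train_ids`/`test_ids` into the original sample order.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  if (is.numeric(spec)) spec <- split_spec(train_fraction = spec)
  stopifnot(inherits(dataset, "phantom_dataset"), inherits(spec, "split_spec"))
  idx <- dataset$index
  n <- nrow(idx)
  if (n == 0) stop("cannot split an empty dataset.", call. = FALSE)
  train_ids <- with_seed(spec$seed, {
    if (spec$stratified) {
      if (any(table(idx$label) < 1)) stop("need at least one sample per class.", call. = FALSE)
      unlist(lapply(split(idx$sample_id, idx$label), function(ids) {
        k <- round(spec$train_fraction * length(ids))
        sample(ids, size = k)
      }), use.names = FALSE)
    } else {
      sample(idx$sample_id, size = round(spec$train_fraction * n))
    }
  })
  train_ids <- sort(train_ids)
  test_ids <- setdiff(idx$sample_id, train_ids)
  subset_ds <- function(ids) {
    structure(list(samples = dataset$samples[ids],
                   index = dataset$index[match(ids, dataset$index$sample_id), ],
                   config = dataset$config),
              class = "phantom_dataset")
  }
  list(train = subset_ds(train_ids), test = subset_ds(test_ids),
       train_ids = train_ids, test_ids = test_ids)
}

#' Collapse a 3-level phantom mask to binary foreground
#'
#' Maps organ and tumor labels `{1, 2}` to 1 and background to 0, the
#' coding used by binary segmentation tasks.
#'
#' @param mask Integer matrix in `{0, 1, 2}`.
#' @return Integer matrix in `{0, 1}`.
#' @export
binary_foreground <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask != 0L] <- 1L
  out
}

#' Write a phantom dataset to disk
#'
#' Images are written as 16-bit grayscale PNG, masks as 8-bit PNG with
#' values `{0, 1, 2}`, and an index CSV with columns
#' `sample_id, image_path, mask_path, label, split`.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @param split Optional character vector, one of `"train"`/`"test"` per
#'   sample, recorded in the index.
#' @return The index as a tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir, split = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(dataset$index)
  if (is.null(split)) split <- rep(NA_character_, n)
  img_paths <- file.path("images", sprintf("sample_%04d.png", dataset$index$sample_id))
  msk_paths <- file.path("masks", sprintf("mask_%04d.png", dataset$index$sample_id))
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    write_png16(s$image, file.path(dir, img_paths[i]))
    png::writePNG(s$mask / 255, file.path(dir, msk_paths[i]))
  }
  index <- tibble::tibble(sample_id = dataset$index$sample_id,
                          image_path = img_paths, mask_path = msk_paths,
                          label = dataset$index$label, split = split)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(index)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir Directory containing `index.csv`, `images/`, `masks/`.
#' @return A `phantom_dataset` (geometry metadata is not recoverable from
#'   disk and is absent).
#' @export
read_dataset <- function(dir) {
  index <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(index)), function(i) {
    img <- png::readPNG(file.path(dir, index$image_path[i]))
    msk <- round(png::readPNG(file.path(dir, index$mask_path[i])) * 255)
    storage.mode(msk) <- "integer"
    structure(list(image = img, mask = msk, label = as.integer(index$label[i]),
                   geometry = NULL, seed = NA_integer_),
              class = "phantom_sample")
  })
  structure(list(samples = samples,
                 index = tibble::tibble(sample_id = index$sample_id,
                                        label = as.integer(index$label),
                                        seed = NA_integer_),
                 config = NULL),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset> ", nrow(x$index), " samples (",
      sum(x$index$label == 1), " tumor / ", sum(x$index$label == 0),
      " non-tumor)\n", sep = "")
  invisible(x)
}

#' Plot a phantom sample
#'
#' Renders the grayscale image with the mask boundary classes overlaid as
#' filled contours.
#'
#' @param object A `phantom_sample`.
#' @param show_mask Overlay the label mask (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom_sample
#' @export
autoplot.phantom_sample <- function(object, show_mask = TRUE, ...) {
  n <- nrow(object$image)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(object$image)), each = n),
    y = rep(seq_len(n), times = ncol(object$image)),
    intensity = as.vector(object$image),
    mask = factor(as.vector(object$mask), levels = 0:2,
                  labels = c("background", "organ", "tumor"))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom (label = %d)", object$label),
                  fill = "intensity") +
    ggplot2::theme_minimal()
  if (show_mask) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = as.integer(.data$mask)),
                                   breaks = c(1.5, 2.5), color = "red",
                                   linewidth = 0.3)
  }
  p
}
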