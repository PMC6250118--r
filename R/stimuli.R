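#' Stimulus presentation protocol
#'
#' Timing and encoding constants of one image presentation: the stimulus is
#' shown as Poisson spike trains for `T_input` ms, followed by `T_silence` ms
#' of empty input that lets currents and activities relax; the class readout
#' averages output activity inside `readout_window` (within the stimulus).
#'
#' @param T_input stimulus duration, ms.
#' @param T_silence inter-stimulus silence, ms.
#' @param rate_max firing rate of a maximal-intensity pixel, Hz.
#' @param readout_window `c(start, end)` in ms within the stimulus.
#' @param dt simulation step, ms (must match the network's).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(T_input = 100, T_silence = 100, rate_max = 250,
                              readout_window = c(50, 100), dt = 1) {
  if (T_input <= 0 || T_silence < 0) stop("invalid presentation durations")
  if (!(readout_window[1] >= 0 && readout_window[1] < readout_window[2] &&
        readout_window[2] <= T_input)) {
    stop("readout_window must satisfy 0 <= start < end <= T_input")
  }
  if (rate_max * dt / 1000 > 1) {
    stop("rate_max * dt exceeds one spike per step: not a valid probability")
  }
  structure(
    list(T_input = T_input, T_silence = T_silence, rate_max = rate_max,
         readout_window = readout_window, dt = dt),
    class = "stimulus_protocol"
  )
}

#' Poisson rate coding of an image
#'
#' Each pixel spikes independently at every step with probability
#' `(intensity/255) * rate_max * dt / 1000` — the discrete-time Poisson
#' process whose rate is proportional to pixel intensity, capped at
#' `rate_max` for a fully-on pixel. Only the stimulus window is encoded; the
#' silent window is, by definition, empty.
#'
#' @param image numeric vector of pixel intensities in `[0, 255]`.
#' @param protocol a [stimulus_protocol()].
#' @return binary matrix, pixels x time steps (`T_input / dt` columns).
#' @export
encode_poisson <- function(image, protocol) {
  if (any(image < 0 | image > 255)) stop("pixel intensities must lie in [0, 255]")
  n_steps <- round(protocol$T_input / protocol$dt)
  p <- (image / 255) * protocol$rate_max * protocol$dt / 1000
  m <- matrix(stats::runif(length(image) * n_steps), length(image), n_steps)
  (m < p) + 0
}

#' Specification of a synthetic class-prototype dataset
#'
#' The generator emulates, at desk scale, the structure the network is meant
#' to learn from handwritten digits: each class is a fixed random binary
#' prototype image, and samples are noisy copies of their prototype (pixel
#' flips plus multiplicative intensity jitter). Defaults give a five-class,
#' 16 x 16 task solvable in minutes on one CPU.
#'
#' @param n_classes number of classes `K`.
#' @param image_side side of the square image, pixels.
#' @param prototype_density fraction of active pixels per prototype, in
#'   (0, 1) exclusive.
#' @param noise_flip_prob per-pixel Bernoulli flip probability per sample.
#' @param intensity_jitter width of the multiplicative intensity jitter:
#'   active pixels are scaled by Uniform(1 - jitter, 1).
#' @param n_train_per_class,n_test_per_class samples per class.
#' @param seed integer seed; the dataset is deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 5, image_side = 16,
                           prototype_density = 0.25, noise_flip_prob = 0.05,
                           intensity_jitter = 0.2,
                           n_train_per_class = 200, n_test_per_class = 100,
                           seed = 1L) {
  if (prototype_density <= 0 || prototype_density >= 1) {
    stop("prototype_density must be strictly inside (0, 1)")
  }
  if (noise_flip_prob < 0 || noise_flip_prob > 1) stop("invalid noise_flip_prob")
  if (intensity_jitter < 0 || intensity_jitter > 1) stop("invalid intensity_jitter")
  stopifnot(n_classes >= 2, image_side >= 2,
            n_train_per_class >= 1, n_test_per_class >= 1)
  structure(
    list(n_classes = as.integer(n_classes), image_side = as.integer(image_side),
         prototype_density = prototype_density,
         noise_flip_prob = noise_flip_prob,
         intensity_jitter = intensity_jitter,
         n_train_per_class = as.integer(n_train_per_class),
         n_test_per_class = as.integer(n_test_per_class),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

sample_noisy <- function(proto, spec, n) {
  npix <- length(proto)
  imgs <- matrix(rep(proto, each = n), n, npix)
  flips <- matrix(stats::runif(n * npix) < spec$noise_flip_prob, n, npix)
  imgs[flips] <- 1 - imgs[flips]
  jit <- matrix(stats::runif(n * npix, 1 - spec$intensity_jitter, 1), n, npix)
  imgs * jit * 255
}

#' Generate a synthetic labeled image dataset
#'
#' Draws `n_classes` distinct random binary prototypes, then builds balanced
#' train and test sets of noisy copies (see [synthetic_spec()]).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `snn_dataset` with components `train` and `test`
#'   (each a list of `images` — samples x pixels, intensities 0–255 — and
#'   0-based integer `labels`), plus `prototypes` (classes x pixels, 0/1)
#'   and the `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(derive_seed(spec$seed, "synthetic-data"))
  on.exit(rng$restore(), add = TRUE)
  npix <- spec$image_side^2
  n_active <- max(1L, round(spec$prototype_density * npix))
  protos <- matrix(0, spec$n_classes, npix)
  for (k in seq_len(spec$n_classes)) {
    repeat {
      p <- numeric(npix)
      p[sample.int(npix, n_active)] <- 1
      dup <- k > 1L && any(apply(protos[seq_len(k - 1L), , drop = FALSE], 1,
                                 function(q) all(q == p)))
      if (!dup) break
    }
    protos[k, ] <- p
  }
  make_split <- function(n_per_class) {
    images <- do.call(rbind, lapply(seq_len(spec$n_classes), function(k) {
      sample_noisy(protos[k, ], spec, n_per_class)
    }))
    labels <- rep(seq_len(spec$n_classes) - 1L, each = n_per_class)
    list(images = images, labels = as.integer(labels))
  }
  structure(
    list(train = make_split(spec$n_train_per_class),
         test = make_split(spec$n_test_per_class),
         prototypes = protos, spec = spec),
    class = "snn_dataset"
  )
}

read_be_int <- function(con, n = 1L) {
  readBin(con, "integer", n = n, size = 4L, endian = "big")
}

#' Read an MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX containers (magic `0x00000803` for images,
#' `0x00000801` for labels), transparently decompressing `.gz` files, and
#' checks that the two headers agree on the number of items.
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#' @return a list with `images` (samples x pixels matrix, intensities
#'   0–255), `labels` (0-based integers) and `dim` (`c(rows, cols)`).
#' @export
read_idx <- function(images_path, labels_path) {
  open_bin <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  }
  con <- open_bin(images_path)
  on.exit(close(con), add = TRUE)
  magic <- read_be_int(con)
  if (!identical(magic, 2051L)) {
    stop(sprintf("bad IDX image magic 0x%08x at offset 0 of %s", magic, images_path))
  }
  n_img <- read_be_int(con)
  nrow_px <- read_be_int(con)
  ncol_px <- read_be_int(con)
  npix <- nrow_px * ncol_px
  raw_px <- readBin(con, "raw", n = n_img * npix)
  if (length(raw_px) != n_img * npix) {
    stop(sprintf("truncated IDX image file: expected %d pixel bytes, got %d (offset %d)",
                 n_img * npix, length(raw_px), 16 + length(raw_px)))
  }
  con2 <- open_bin(labels_path)
  on.exit(close(con2), add = TRUE)
  magic2 <- read_be_int(con2)
  if (!identical(magic2, 2049L)) {
    stop(sprintf("bad IDX label magic 0x%08x at offset 0 of %s", magic2, labels_path))
  }
  n_lab <- read_be_int(con2)
  if (n_lab != n_img) {
    stop(sprintf("IDX count mismatch: %d images but %d labels", n_img, n_lab))
  }
  raw_lab <- readBin(con2, "raw", n = n_lab)
  if (length(raw_lab) != n_lab) {
    stop(sprintf("truncated IDX label file: expected %d labels, got %d (offset %d)",
                 n_lab, length(raw_lab), 8 + length(raw_lab)))
  }
  images <- matrix(as.integer(raw_px), nrow = n_img, ncol = npix, byrow = TRUE)
  list(images = images, labels = as.integer(raw_lab), dim = c(nrow_px, ncol_px))
}

#' Write images and labels as an IDX file pair
#'
#' The inverse of [read_idx()]; mainly useful for building small fixtures
#' and exporting synthetic datasets to tools expecting MNIST's container.
#'
#' @param images samples x pixels integer matrix, intensities 0–255.
#' @param labels 0-based integer labels, one per row of `images`.
#' @param dim `c(rows, cols)` of one image.
#' @param images_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_idx <- function(images, labels, dim, images_path, labels_path) {
  stopifnot(nrow(images) == length(labels), prod(dim) == ncol(images))
  con <- file(images_path, "wb")
  writeBin(c(2051L, nrow(images), as.integer(dim)), con, size = 4L, endian = "big")
  writeBin(as.raw(round(t(images))), con)
  close(con)
  con <- file(labels_path, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  close(con)
  invisible(c(images_path, labels_path))
}
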