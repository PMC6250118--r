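#' Training schedule
#'
#' How many images are presented, in which supervision mode, and how often
#' the test accuracy is measured. In `"supervised"` mode every presentation
#' injects the teacher current into the true-class output neuron; in
#' `"partial_unsupervised"` only the first `n_supervised` presentations do
#' (a short supervised initialization, after which learning continues from
#' the same local rules without any teacher); `"unsupervised"` never uses
#' the teacher.
#'
#' @param mode `"supervised"`, `"partial_unsupervised"` or `"unsupervised"`.
#' @param n_train_total number of training presentations.
#' @param n_supervised teacher-driven presentations in partial mode.
#' @param eval_every presentations between test evaluations.
#' @param n_eval test images per evaluation (default: the whole test set).
#' @return an object of class `train_schedule`.
#' @export
train_schedule <- function(mode = c("supervised", "partial_unsupervised", "unsupervised"),
                           n_train_total = 1000,
                           n_supervised = min(400, n_train_total),
                           eval_every = 50,
                           n_eval = NULL) {
  mode <- match.arg(mode)
  if (eval_every < 1) stop("eval_every must be >= 1")
  if (n_supervised > n_train_total) stop("n_supervised must not exceed n_train_total")
  structure(
    list(mode = mode, n_train_total = as.integer(n_train_total),
         n_supervised = as.integer(n_supervised),
         eval_every = as.integer(eval_every),
         n_eval = if (is.null(n_eval)) NULL else as.integer(n_eval)),
    class = "train_schedule"
  )
}

#' Present one image to the network
#'
#' Encodes the image as Poisson spike trains and runs the network for the
#' stimulus window (with the teacher current on the labeled class, if a
#' label is given), then for the silent window with empty input and no
#' teacher. The predicted class is the argmax, over output neurons, of the
#' time-mean instant activity within the protocol's readout window; ties
#' break to the lowest class index. The alternative `"threshold"` readout
#' uses the adaptive thresholds (which track activity) instead.
#'
#' @param net an `snn_network` (modified in place).
#' @param image pixel intensities in `[0, 255]`, length `n_input`.
#' @param label optional 0-based true class; when given, the teacher current
#'   is injected during the stimulus window.
#' @param protocol a [stimulus_protocol()].
#' @param learning apply plasticity (and decay). During the silent window
#'   plasticity additionally requires `net$cfg$learn_in_silence`.
#' @param readout `"activity"` (default) or `"threshold"`.
#' @return list with `prediction` (0-based class), `readout` (per-output
#'   window means) and `output_rates` (window-mean instant activity per
#'   output neuron, spikes/ms).
#' @export
present_image <- function(net, image, label = NULL, protocol,
                          learning = TRUE, readout = c("activity", "threshold")) {
  readout <- match.arg(readout)
  cfg <- net$cfg
  if (length(image) != cfg$layer_sizes[1]) stop("image length must equal n_input")
  if (!is.null(label)) {
    label <- as.integer(label)
    if (label < 0L || label >= cfg$layer_sizes[3]) stop("label out of range [0, K)")
  }
  spikes <- encode_poisson(image, protocol)
  n_stim <- ncol(spikes)
  w0 <- floor(protocol$readout_window[1] / protocol$dt)
  w1 <- floor(protocol$readout_window[2] / protocol$dt)
  n_out <- cfg$layer_sizes[3]
  acc_a <- numeric(n_out)
  acc_r <- numeric(n_out)
  n_win <- 0L
  for (t in seq_len(n_stim)) {
    simulate_step(net, spikes[, t], supervised_target = label, learning = learning)
    if (t > w0 && t <= w1) {
      acc_a <- acc_a + net$output$a
      acc_r <- acc_r + (if (readout == "activity") net$output$a else net$output$V_th)
      n_win <- n_win + 1L
    }
  }
  zero_in <- numeric(cfg$layer_sizes[1])
  silent_learning <- learning && cfg$learn_in_silence
  n_sil <- round(protocol$T_silence / protocol$dt)
  for (t in seq_len(n_sil)) {
    simulate_step(net, zero_in, supervised_target = NULL, learning = silent_learning)
  }
  means <- acc_r / max(n_win, 1L)
  list(prediction = which.max(means) - 1L,
       readout = means,
       output_rates = acc_a / max(n_win, 1L))
}

#' Evaluate classification accuracy with frozen weights
#'
#' Presents each test image without a teacher and with plasticity and decay
#' suspended, then compares the argmax readout with the labels. The entire
#' dynamic state of the network (and the caller's RNG stream) is snapshotted
#' before and restored after, so evaluation is free of side effects and two
#' consecutive evaluations give identical results.
#'
#' @param net an `snn_network`.
#' @param images test images, samples x pixels.
#' @param labels 0-based true classes.
#' @param protocol a [stimulus_protocol()].
#' @param seed seed of the evaluation's private Poisson-encoding stream
#'   (default: derived from the network's configured seed).
#' @param readout passed to [present_image()].
#' @return accuracy as a fraction in `[0, 1]`.
#' @export
evaluate <- function(net, images, labels, protocol,
                     seed = net$cfg$seed, readout = "activity") {
  stopifnot(nrow(images) == length(labels))
  snap <- snapshot_state(net)
  rng <- local_rng(derive_seed(seed, "evaluate"))
  on.exit({ restore_state(net, snap); rng$restore() }, add = TRUE)
  correct <- 0L
  for (i in seq_len(nrow(images))) {
    res <- present_image(net, images[i, ], label = NULL, protocol = protocol,
                         learning = FALSE, readout = readout)
    if (res$prediction == labels[i]) correct <- correct + 1L
  }
  correct / length(labels)
}

#' Train a network on a labeled dataset
#'
#' Presents the training images (shuffled once, deterministically in the
#' network's seed) under the schedule's supervision mode, and measures test
#' accuracy every `eval_every` presentations on a fixed, seeded subset of
#' the test set. All randomness (shuffling, stimulus encoding, evaluation
#' encoding) derives from `net$cfg$seed`, so two runs with the same
#' configuration produce bit-identical learning curves.
#'
#' @param net an `snn_network` (trained in place).
#' @param data an `snn_dataset` from [generate_synthetic()], or any list
#'   with `train$images`, `train$labels`, `test$images`, `test$labels`.
#' @param schedule a [train_schedule()].
#' @param protocol a [stimulus_protocol()].
#' @param verbose print accuracy after each evaluation.
#' @return a list with `curve` — a data.frame of class `learning_curve`
#'   with columns `images_seen` and `accuracy`, carrying the mode and seed
#'   as attributes — and the trained `net`.
#' @export
train <- function(net, data, schedule, protocol, verbose = FALSE) {
  stopifnot(inherits(schedule, "train_schedule"))
  n_train <- nrow(data$train$images)
  if (n_train == 0L) stop("empty training set")
  seed <- net$cfg$seed

  rng <- local_rng(derive_seed(seed, "train-shuffle"))
  order_idx <- sample.int(n_train)
  n_test <- nrow(data$test$images)
  n_eval <- min(if (is.null(schedule$n_eval)) n_test else schedule$n_eval, n_test)
  eval_idx <- sample.int(n_test, n_eval)
  rng$restore()

  idx <- rep(order_idx, length.out = schedule$n_train_total)
  eval_images <- data$test$images[eval_idx, , drop = FALSE]
  eval_labels <- data$test$labels[eval_idx]

  curve_seen <- integer(0)
  curve_acc <- numeric(0)
  rng <- local_rng(derive_seed(seed, "train-encode"))
  on.exit(rng$restore(), add = TRUE)
  for (i in seq_along(idx)) {
    lab <- data$train$labels[idx[i]]
    use_teacher <- switch(schedule$mode,
      supervised = TRUE,
      partial_unsupervised = i <= schedule$n_supervised,
      unsupervised = FALSE
    )
    present_image(net, data$train$images[idx[i], ],
                  label = if (use_teacher) lab else NULL,
                  protocol = protocol, learning = TRUE)
    if (i %% schedule$eval_every == 0L || i == length(idx)) {
      acc <- evaluate(net, eval_images, eval_labels, protocol, seed = seed)
      curve_seen <- c(curve_seen, i)
      curve_acc <- c(curve_acc, acc)
      if (verbose) {
        message(sprintf("  [%s] %d images seen: accuracy %.3f",
                        schedule$mode, i, acc))
      }
    }
  }
  curve <- data.frame(images_seen = unique_keep_last(curve_seen, curve_acc)$x,
                      accuracy = unique_keep_last(curve_seen, curve_acc)$y)
  class(curve) <- c("learning_curve", "data.frame")
  attr(curve, "mode") <- schedule$mode
  attr(curve, "seed") <- seed
  list(curve = curve, net = net)
}

# drop duplicated x (the final forced evaluation may coincide with a
# scheduled one), keeping the last y
unique_keep_last <- function(x, y) {
  keep <- !duplicated(x, fromLast = TRUE)
  list(x = x[keep], y = y[keep])
}
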