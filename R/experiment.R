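# User-facing experiment runner: YAML configuration in, reproducible
# artifacts (curves, checkpoints, trees, manifests) out.

known_config_keys <- list(
  network = c("layer_sizes", "enabled", "alpha", "beta", "gamma", "eta",
              "tau_decay", "lateral_decay_target", "balancing", "I_supervised", "learn_in_silence",
              "seed", "tau_m", "tau_a", "tau_theta", "tau_th", "tau_ref",
              "delta_V_th", "V_th_init", "th_increment_mode", "dt"),
  protocol = c("T_input", "T_silence", "rate_max", "readout_window"),
  data = c("type", "n_classes", "image_side", "prototype_density",
           "noise_flip_prob", "intensity_jitter", "n_train_per_class",
           "n_test_per_class", "images_path", "labels_path",
           "test_images_path", "test_labels_path"),
  schedule = c("mode", "n_train_total", "n_supervised", "eval_every", "n_eval")
)

#' Default experiment configuration
#'
#' The desk-scale synthetic experiment: a five-class 16 x 16 prototype task,
#' a 256-30-5 network with all connection kinds enabled and the standard
#' neuron and learning constants, 100 ms + 100 ms presentations capped at
#' 250 Hz, supervised training for 1000 presentations.
#'
#' @param seed run seed.
#' @return a nested configuration list (sections `network`, `protocol`,
#'   `data`, `schedule`) accepted by [run_experiment()] and
#'   [config_objects()].
#' @export
default_config <- function(seed = 1L) {
  list(
    network = list(
      layer_sizes = c(256L, 30L, 5L),
      enabled = list(output_inhibition = TRUE, hidden_inhibition = TRUE,
                     reciprocal = TRUE),
      tau_m = 20, tau_a = 15, tau_theta = 150, tau_th = 50, tau_ref = 2,
      tau_decay = 10000, lateral_decay_target = -1,
      alpha = 0.1, beta = 0.3, gamma = 0.1, eta = 0.15,
      delta_V_th = 0.1, V_th_init = 5, th_increment_mode = "multiply",
      I_supervised = 30, dt = 1, learn_in_silence = TRUE,
      balancing = list(c_ff_hidden = 1.5, c_ff_output = 2, c_lat_hidden = 150,
                       c_lat_output = 30, c_rec = 400),
      seed = as.integer(seed)
    ),
    protocol = list(T_input = 100, T_silence = 100, rate_max = 250,
                    readout_window = c(50, 100)),
    data = list(type = "synthetic", n_classes = 5L, image_side = 16L,
                prototype_density = 0.25, noise_flip_prob = 0.05,
                intensity_jitter = 0.2, n_train_per_class = 200L,
                n_test_per_class = 100L),
    schedule = list(mode = "supervised", n_train_total = 1000L,
                    n_supervised = 400L, eval_every = 50L)
  )
}

check_config_keys <- function(config) {
  bad_sections <- setdiff(names(config), names(known_config_keys))
  if (length(bad_sections) > 0) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), known_config_keys[[sec]])
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in config section '%s': %s",
                   sec, paste(bad, collapse = ", ")))
    }
  }
  invisible(config)
}

#' Read and validate a YAML experiment configuration
#'
#' Unknown sections or keys raise an error naming them (misspelled options
#' never fall back silently to defaults); omitted keys take the
#' [default_config()] values.
#'
#' @param path YAML file.
#' @return a validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  check_config_keys(user)
  base <- default_config()
  for (sec in names(user)) {
    base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  base
}

#' Instantiate the typed objects described by a configuration list
#'
#' @param config a configuration list ([default_config()] / [read_config()]).
#' @return list with `network_config`, `protocol`, `schedule`, and a
#'   `make_data()` closure generating or loading the configured dataset.
#' @export
config_objects <- function(config) {
  check_config_keys(config)
  nw <- config$network
  sizes <- as.integer(unlist(nw$layer_sizes))
  lp <- function(n) {
    layer_params(N = n, tau_m = nw$tau_m, tau_ref = nw$tau_ref,
                 tau_th = nw$tau_th, delta_V_th = nw$delta_V_th,
                 V_th_init = nw$V_th_init, tau_a = nw$tau_a,
                 tau_theta = nw$tau_theta, dt = nw$dt,
                 th_increment_mode = nw$th_increment_mode)
  }
  ncfg <- network_config(
    layer_sizes = sizes, enabled = unlist(nw$enabled),
    hidden_params = lp(sizes[2]), output_params = lp(sizes[3]),
    input_params = lp(sizes[1]),
    alpha = nw$alpha, beta = nw$beta, gamma = nw$gamma, eta = nw$eta,
    tau_decay = nw$tau_decay, lateral_decay_target = nw$lateral_decay_target,
    balancing = unlist(nw$balancing),
    I_supervised = nw$I_supervised, learn_in_silence = nw$learn_in_silence,
    dt = nw$dt, seed = nw$seed
  )
  pr <- config$protocol
  protocol <- stimulus_protocol(T_input = pr$T_input, T_silence = pr$T_silence,
                                rate_max = pr$rate_max,
                                readout_window = unlist(pr$readout_window),
                                dt = nw$dt)
  sc <- config$schedule
  schedule <- train_schedule(mode = sc$mode, n_train_total = sc$n_train_total,
                             n_supervised = sc$n_supervised,
                             eval_every = sc$eval_every, n_eval = sc$n_eval)
  dc <- config$data
  make_data <- function() {
    if (identical(dc$type, "synthetic")) {
      generate_synthetic(synthetic_spec(
        n_classes = dc$n_classes, image_side = dc$image_side,
        prototype_density = dc$prototype_density,
        noise_flip_prob = dc$noise_flip_prob,
        intensity_jitter = dc$intensity_jitter,
        n_train_per_class = dc$n_train_per_class,
        n_test_per_class = dc$n_test_per_class,
        seed = nw$seed
      ))
    } else if (identical(dc$type, "idx")) {
      tr <- read_idx(dc$images_path, dc$labels_path)
      te <- read_idx(dc$test_images_path, dc$test_labels_path)
      structure(list(train = tr[c("images", "labels")],
                     test = te[c("images", "labels")]),
                class = "snn_dataset")
    } else {
      stop("data$type must be 'synthetic' or 'idx'")
    }
  }
  list(network_config = ncfg, protocol = protocol, schedule = schedule,
       make_data = make_data)
}

write_manifest <- function(out_dir, config, outputs, started, command) {
  manifest <- list(
    format = "feelnet-manifest-1",
    command = command,
    package_version = as.character(utils::packageVersion("feelnet")),
    seed = config$network$seed,
    config = config,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' Run a configured experiment command
#'
#' Executes one of the pipeline commands and writes its artifacts plus a
#' run manifest (config snapshot, seed, package version, timestamps, output
#' inventory) into `out_dir`. Re-running from the manifest's config snapshot
#' reproduces the run exactly.
#'
#' Commands: `"train"` (learning curve CSV + checkpoint), `"evaluate"`
#' (accuracy of a checkpoint on the configured test set), `"ablate"` (the
#' four connectivity architectures — feed-forward only, output inhibition
#' only, both inhibitions, full recurrent — trained with a shared seed;
#' comparison CSV), `"cluster"` (family tree of a checkpoint as JSON),
#' `"visualize"` (receptive-field product maps as PNG), `"synth-data"`
#' (write the synthetic dataset as CSV).
#'
#' @param config a configuration list, or a path to a YAML file.
#' @param command one of the commands above.
#' @param out_dir output directory (created if needed).
#' @param checkpoint path to a checkpoint JSON, for the commands that
#'   analyze a trained network (default: `out_dir/network.json`).
#' @param verbose print progress.
#' @return a list of the main results, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config, command = c("train", "evaluate", "ablate",
                                               "cluster", "visualize", "synth-data"),
                           out_dir = "feelnet-run", checkpoint = NULL,
                           verbose = FALSE) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  check_config_keys(config)
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(config)
  if (is.null(checkpoint)) checkpoint <- file.path(out_dir, "network.json")
  outputs <- character(0)
  result <- NULL

  if (command == "synth-data") {
    data <- obj$make_data()
    for (split in c("train", "test")) {
      p <- file.path(out_dir, paste0(split, ".csv"))
      utils::write.csv(
        data.frame(label = data[[split]]$labels,
                   round(data[[split]]$images, 3)),
        p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    result <- list(n_train = nrow(data$train$images),
                   n_test = nrow(data$test$images))
  } else if (command == "train") {
    data <- obj$make_data()
    net <- build_network(obj$network_config)
    fit <- train(net, data, obj$schedule, obj$protocol, verbose = verbose)
    curve_path <- file.path(out_dir, "curve.csv")
    write_curve(fit$curve, curve_path)
    save_network(fit$net, checkpoint)
    outputs <- c(outputs, curve_path, checkpoint)
    result <- list(curve = fit$curve,
                   final_accuracy = utils::tail(fit$curve$accuracy, 1))
  } else if (command == "evaluate") {
    data <- obj$make_data()
    net <- load_network(checkpoint)
    acc <- evaluate(net, data$test$images, data$test$labels, obj$protocol)
    p <- file.path(out_dir, "evaluation.csv")
    utils::write.csv(data.frame(n_test = nrow(data$test$images), accuracy = acc),
                     p, row.names = FALSE)
    outputs <- c(outputs, p)
    result <- list(accuracy = acc)
  } else if (command == "ablate") {
    data <- obj$make_data()
    topologies <- list(
      feedforward_only = c(output_inhibition = FALSE, hidden_inhibition = FALSE,
                           reciprocal = FALSE),
      output_inhibition = c(output_inhibition = TRUE, hidden_inhibition = FALSE,
                            reciprocal = FALSE),
      both_inhibitions = c(output_inhibition = TRUE, hidden_inhibition = TRUE,
                           reciprocal = FALSE),
      full_recurrent = c(output_inhibition = TRUE, hidden_inhibition = TRUE,
                         reciprocal = TRUE)
    )
    rows <- lapply(names(topologies), function(nm) {
      cfg_i <- config
      cfg_i$network$enabled <- as.list(topologies[[nm]])
      obj_i <- config_objects(cfg_i)
      net <- build_network(obj_i$network_config)
      fit <- train(net, data, obj_i$schedule, obj_i$protocol, verbose = verbose)
      write_curve(fit$curve, file.path(out_dir, paste0("curve_", nm, ".csv")))
      data.frame(topology = nm,
                 final_accuracy = utils::tail(fit$curve$accuracy, 1))
    })
    cmp <- do.call(rbind, rows)
    p <- file.path(out_dir, "ablation.csv")
    utils::write.csv(cmp, p, row.names = FALSE)
    outputs <- c(outputs, p,
                 file.path(out_dir, paste0("curve_", names(topologies), ".csv")))
    result <- list(comparison = cmp)
  } else if (command == "cluster") {
    net <- load_network(checkpoint)
    tree <- cluster_families(net$groups$lateral_hidden$W)
    p <- file.path(out_dir, "family_tree.json")
    write_family_tree(tree, p)
    outputs <- c(outputs, p)
    result <- list(tree = tree)
  } else if (command == "visualize") {
    net <- load_network(checkpoint)
    maps <- receptive_field_product(net$groups$ff_in_hidden$W,
                                    net$groups$ff_hidden_out$W)
    side <- as.integer(round(sqrt(nrow(maps))))
    p <- file.path(out_dir, "receptive_fields.png")
    grDevices::png(p, width = 160 * ncol(maps), height = 180)
    graphics::par(mfrow = c(1, ncol(maps)), mar = c(0.5, 0.5, 1.5, 0.5))
    for (k in seq_len(ncol(maps))) {
      img <- matrix(maps[, k], side, side)
      graphics::image(t(img[side:1, ]), axes = FALSE, col = grDevices::gray.colors(64),
                      main = paste("class", k - 1))
    }
    grDevices::dev.off()
    outputs <- c(outputs, p)
    result <- list(maps = maps)
  }

  write_manifest(out_dir, config, outputs, started, command)
  invisible(result)
}
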