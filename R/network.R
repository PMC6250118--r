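#' Network configuration
#'
#' All tunables of the recurrent spiking architecture: layer sizes (input,
#' hidden, output), which connection kinds are enabled (ablation switches),
#' the neuron parameters of the hidden and output layers, learning rates of
#' the four rules, current-balancing coefficients, the teacher current, and
#' the seed controlling all randomness.
#'
#' The architecture is the classic three-layer recurrent one: Poisson input
#' units project feed-forward onto a hidden layer, the hidden layer projects
#' feed-forward onto an output (classifying) layer, the output layer projects
#' excitatory reciprocal connections back onto the hidden layer, and both
#' hidden and output layers carry learnable lateral inhibition.
#'
#' @param layer_sizes integer vector `(n_input, n_hidden, n_output)`,
#'   e.g. `c(784, 100, 10)`.
#' @param enabled named logical flags `output_inhibition`,
#'   `hidden_inhibition`, `reciprocal`; disabling a kind removes its current
#'   and its plasticity entirely.
#' @param hidden_params,output_params [layer_params()] for the two LIF
#'   layers; defaults use the standard constants with `N` taken from
#'   `layer_sizes`.
#' @param input_params [layer_params()] governing only the activity-trace
#'   constants of the (membrane-less) Poisson input units; defaults match
#'   the other layers.
#' @param alpha,beta,gamma,eta learning rates of the feed-forward,
#'   reciprocal, output-lateral and hidden-lateral rules.
#' @param tau_decay weight decay constant, ms (default 10 s).
#' @param lateral_decay_target resting value toward which lateral inhibitory
#'   weights decay (default -1: competition is the resting state and
#'   cooperation must be actively maintained by the lateral rules; 0 makes
#'   inhibition decay away like the excitatory weights).
#' @param balancing named non-negative multipliers applied to each current
#'   type: `c_ff_hidden`, `c_ff_output`, `c_lat_hidden`, `c_lat_output`,
#'   `c_rec` (defaults 1).
#' @param I_supervised teacher current amplitude added to the labeled output
#'   neuron during supervised presentations (a.u.).
#' @param learn_in_silence keep plasticity enabled during inter-stimulus
#'   silence (the rules are spike-gated, so silence normally yields only
#'   decay).
#' @param dt simulation step, ms.
#' @param seed integer seed controlling weight initialization (and, through
#'   the training helpers, all other randomness of a run).
#' @return an object of class `network_config`.
#' @export
network_config <- function(layer_sizes = c(784, 100, 10),
                           enabled = c(output_inhibition = TRUE,
                                       hidden_inhibition = TRUE,
                                       reciprocal = TRUE),
                           hidden_params = NULL,
                           output_params = NULL,
                           input_params = NULL,
                           alpha = 0.1, beta = 0.3, gamma = 0.1, eta = 0.15,
                           tau_decay = 10000,
                           lateral_decay_target = -1,
                           balancing = c(c_ff_hidden = 1, c_ff_output = 1,
                                         c_lat_hidden = 1, c_lat_output = 1,
                                         c_rec = 1),
                           I_supervised = 30,
                           learn_in_silence = TRUE,
                           dt = 1,
                           seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) != 3L || any(layer_sizes < 1L)) {
    stop("layer_sizes must be three positive integers (input, hidden, output)")
  }
  flags <- c(output_inhibition = TRUE, hidden_inhibition = TRUE, reciprocal = TRUE)
  if (!all(names(enabled) %in% names(flags))) {
    stop("unknown 'enabled' flag(s): ",
         paste(setdiff(names(enabled), names(flags)), collapse = ", "))
  }
  flags[names(enabled)] <- as.logical(enabled)
  bal <- c(c_ff_hidden = 1, c_ff_output = 1, c_lat_hidden = 1,
           c_lat_output = 1, c_rec = 1)
  if (!all(names(balancing) %in% names(bal))) {
    stop("unknown balancing coefficient(s): ",
         paste(setdiff(names(balancing), names(bal)), collapse = ", "))
  }
  bal[names(balancing)] <- as.numeric(balancing)
  if (any(bal < 0)) stop("balancing coefficients must be >= 0")
  if (is.null(hidden_params)) hidden_params <- layer_params(layer_sizes[2], dt = dt)
  if (is.null(output_params)) output_params <- layer_params(layer_sizes[3], dt = dt)
  if (is.null(input_params)) input_params <- layer_params(layer_sizes[1], dt = dt)
  stopifnot(hidden_params$N == layer_sizes[2], output_params$N == layer_sizes[3],
            input_params$N == layer_sizes[1])
  if (I_supervised < 0) stop("I_supervised must be >= 0")
  if (lateral_decay_target < -1 || lateral_decay_target > 0) {
    stop("lateral_decay_target must lie in [-1, 0]")
  }
  structure(
    list(
      layer_sizes = layer_sizes, enabled = flags,
      input_params = input_params, hidden_params = hidden_params,
      output_params = output_params,
      alpha = alpha, beta = beta, gamma = gamma, eta = eta,
      tau_decay = tau_decay, lateral_decay_target = lateral_decay_target,
      balancing = bal,
      I_supervised = I_supervised, learn_in_silence = learn_in_silence,
      dt = dt, seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

#' Build a network from a configuration
#'
#' Feed-forward weights are initialized Uniform(0, 1); lateral inhibitory
#' weights start at -1 (maximal competition) with a zero diagonal;
#' reciprocal weights start at 0 and can only grow through learning. All
#' neuron states start at zero, except the adaptive thresholds which start
#' at their configured initial value. Deterministic given `config$seed`.
#'
#' The returned network is an environment, so the simulation functions
#' update it in place.
#'
#' @param config a [network_config()].
#' @return an object of class `snn_network` (an environment).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n_in <- config$layer_sizes[1]
  n_hid <- config$layer_sizes[2]
  n_out <- config$layer_sizes[3]
  rng <- local_rng(derive_seed(config$seed, "weight-init"))
  on.exit(rng$restore(), add = TRUE)

  lat <- function(n) {
    W <- matrix(-1, n, n)
    diag(W) <- 0
    W
  }
  net <- new.env(parent = emptyenv())
  net$cfg <- config
  net$t_now <- 0
  net$input <- layer_state(config$input_params)
  net$hidden <- layer_state(config$hidden_params)
  net$output <- layer_state(config$output_params)
  net$groups <- list(
    ff_in_hidden = connection_group(
      matrix(stats::runif(n_in * n_hid), n_in, n_hid),
      "feedforward", config$alpha, config$tau_decay),
    ff_hidden_out = connection_group(
      matrix(stats::runif(n_hid * n_out), n_hid, n_out),
      "feedforward", config$alpha, config$tau_decay),
    reciprocal = connection_group(
      matrix(0, n_out, n_hid),
      "reciprocal", config$beta, config$tau_decay,
      plastic = config$enabled[["reciprocal"]]),
    lateral_output = connection_group(
      lat(n_out), "lateral_output", config$gamma, config$tau_decay,
      plastic = config$enabled[["output_inhibition"]],
      decay_target = config$lateral_decay_target),
    lateral_hidden = connection_group(
      lat(n_hid), "lateral_hidden", config$eta, config$tau_decay,
      plastic = config$enabled[["hidden_inhibition"]],
      decay_target = config$lateral_decay_target)
  )
  class(net) <- c("snn_network", "environment")
  net
}

#' @export
print.snn_network <- function(x, ...) {
  s <- x$cfg$layer_sizes
  cat(sprintf("<snn_network %d-%d-%d  t = %g ms  seed = %d>\n",
              s[1], s[2], s[3], x$t_now, x$cfg$seed))
  cat("  enabled:", paste(names(which(x$cfg$enabled)), collapse = ", "), "\n")
  invisible(x)
}

#' Input currents of the hidden and output layers
#'
#' Each post-synaptic current is the weighted sum of pre-synaptic instant
#' activities, one term per connection type, scaled by its balancing
#' coefficient. Lateral terms are non-positive by weight sign; feed-forward
#' and reciprocal terms non-negative. Disabled connection kinds contribute
#' zero. A supervised target adds the teacher current to that single output
#' neuron.
#'
#' @param net an [build_network()] network.
#' @param supervised_target optional 0-based class index receiving the
#'   teacher current.
#' @return list with numeric vectors `hidden` and `output`.
#' @export
compute_currents <- function(net, supervised_target = NULL) {
  cfg <- net$cfg
  bal <- cfg$balancing
  en <- cfg$enabled
  g <- net$groups
  I_hid <- bal[["c_ff_hidden"]] * drop(crossprod(g$ff_in_hidden$W, net$input$a))
  if (en[["hidden_inhibition"]]) {
    I_hid <- I_hid + bal[["c_lat_hidden"]] * drop(crossprod(g$lateral_hidden$W, net$hidden$a))
  }
  if (en[["reciprocal"]]) {
    I_hid <- I_hid + bal[["c_rec"]] * drop(crossprod(g$reciprocal$W, net$output$a))
  }
  I_out <- bal[["c_ff_output"]] * drop(crossprod(g$ff_hidden_out$W, net$hidden$a))
  if (en[["output_inhibition"]]) {
    I_out <- I_out + bal[["c_lat_output"]] * drop(crossprod(g$lateral_output$W, net$output$a))
  }
  if (!is.null(supervised_target)) {
    k <- as.integer(supervised_target)
    if (k < 0L || k >= cfg$layer_sizes[3]) {
      stop("supervised_target out of range [0, n_output)")
    }
    I_out[k + 1L] <- I_out[k + 1L] + cfg$I_supervised
  }
  list(hidden = I_hid, output = I_out)
}

#' Advance the whole network by one time step
#'
#' Order within a step (making the step a pure function of the previous
#' state): (1) input-layer traces are updated from the presented input
#' spikes; (2) currents are computed from the traces; (3) membrane
#' integration and spike detection in hidden and output layers; (4) adaptive
#' thresholds; (5) activity traces; (6) if learning, the plasticity rules
#' (feed-forward first, then reciprocal — which reads the already-updated
#' forward weights — then the lateral rules); finally the clock advances by
#' `dt`. With `learning = FALSE` both plasticity and weight decay are
#' suspended, so evaluation passes leave all weights bit-identical.
#'
#' @param net an [build_network()] network (modified in place).
#' @param input_spikes binary vector of length `n_input`.
#' @param supervised_target optional 0-based class index for the teacher
#'   current.
#' @param learning apply plasticity rules and decay.
#' @return the network, invisibly.
#' @export
simulate_step <- function(net, input_spikes, supervised_target = NULL,
                          learning = TRUE) {
  cfg <- net$cfg
  if (length(input_spikes) != cfg$layer_sizes[1]) {
    stop("input_spikes length must equal n_input")
  }
  if (any(input_spikes != 0 & input_spikes != 1)) {
    stop("input_spikes must be binary (0/1)")
  }
  net$input$spiked <- as.numeric(input_spikes)
  net$input <- step_activity(net$input, cfg$input_params)

  I <- compute_currents(net, supervised_target)

  net$hidden <- step_membrane(net$hidden, I$hidden, cfg$hidden_params)
  net$output <- step_membrane(net$output, I$output, cfg$output_params)
  net$hidden <- step_threshold(net$hidden, cfg$hidden_params)
  net$output <- step_threshold(net$output, cfg$output_params)
  net$hidden <- step_activity(net$hidden, cfg$hidden_params)
  net$output <- step_activity(net$output, cfg$output_params)

  if (learning) {
    t_now <- net$t_now
    g <- net$groups
    hs <- net$hidden$spiked
    os <- net$output$spiked
    if (any(hs > 0)) {
      g$ff_in_hidden <- update_feedforward(g$ff_in_hidden, net$input, hs, t_now = t_now)
    }
    if (any(os > 0)) {
      g$ff_hidden_out <- update_feedforward(g$ff_hidden_out, net$hidden, os, t_now = t_now)
      if (cfg$enabled[["reciprocal"]]) {
        g$reciprocal <- update_reciprocal(g$reciprocal, g$ff_hidden_out,
                                          net$hidden, os, t_now = t_now)
      }
      if (cfg$enabled[["output_inhibition"]]) {
        g$lateral_output <- update_output_inhibition(g$lateral_output, net$output,
                                                     os, t_now = t_now)
      }
    }
    if (cfg$enabled[["hidden_inhibition"]] && any(hs > 0)) {
      g$lateral_hidden <- update_hidden_lateral(g$lateral_hidden, net$hidden,
                                                hs, t_now = t_now)
    }
    net$groups <- g
  }
  net$t_now <- net$t_now + cfg$dt
  invisible(net)
}

#' Snapshot / restore the dynamic state of a network
#'
#' Captures everything that evolves during simulation (clock, layer states,
#' weights and their decay timestamps) so that an evaluation pass can be run
#' and fully undone. `restore_state` writes a snapshot back in place.
#'
#' @param net an `snn_network`.
#' @return for `snapshot_state`, an opaque list.
#' @export
snapshot_state <- function(net) {
  list(t_now = net$t_now, input = net$input, hidden = net$hidden,
       output = net$output, groups = net$groups)
}

#' @rdname snapshot_state
#' @param snap a snapshot produced by `snapshot_state`.
#' @export
restore_state <- function(net, snap) {
  net$t_now <- snap$t_now
  net$input <- snap$input
  net$hidden <- snap$hidden
  net$output <- snap$output
  net$groups <- snap$groups
  invisible(net)
}

#' Total sum of absolute weights, per connection group
#'
#' A cheap checksum used to assert that evaluation leaves weights untouched.
#'
#' @param net an `snn_network`.
#' @return named numeric vector of `sum(abs(W))` per group.
#' @export
weight_checksum <- function(net) {
  vapply(net$groups, function(g) sum(abs(g$W)), numeric(1))
}

#' Mean absolute current per connection type over a pilot run
#'
#' Runs a short pilot (supervised presentations) and reports the mean
#' absolute unscaled current each connection type delivers, per layer —
#' the measurement behind the manual balancing recipe: match the types'
#' mean magnitudes with the balancing coefficients, then scale each
#' layer's total drive so the homeostatic rate `I/(inc * tau_th)` lands in
#' the intended regime.
#'
#' @param config a [network_config()].
#' @param data an `snn_dataset`.
#' @param protocol a [stimulus_protocol()].
#' @param n_images pilot length in presentations.
#' @return named numeric vector of mean |I| for `ff_hidden`, `lat_hidden`,
#'   `rec`, `ff_output`, `lat_output` (raw, before balancing).
#' @export
pilot_current_summary <- function(config, data, protocol, n_images = 20) {
  net <- build_network(config)
  rng <- local_rng(derive_seed(config$seed, "pilot"))
  on.exit(rng$restore(), add = TRUE)
  acc <- c(ff_hidden = 0, lat_hidden = 0, rec = 0, ff_output = 0, lat_output = 0)
  n_steps <- 0L
  for (i in seq_len(min(n_images, nrow(data$train$images)))) {
    spk <- encode_poisson(data$train$images[i, ], protocol)
    lab <- data$train$labels[i]
    for (t in seq_len(ncol(spk))) {
      g <- net$groups
      acc <- acc + c(
        mean(abs(crossprod(g$ff_in_hidden$W, net$input$a))),
        mean(abs(crossprod(g$lateral_hidden$W, net$hidden$a))),
        mean(abs(crossprod(g$reciprocal$W, net$output$a))),
        mean(abs(crossprod(g$ff_hidden_out$W, net$hidden$a))),
        mean(abs(crossprod(g$lateral_output$W, net$output$a))))
      n_steps <- n_steps + 1L
      simulate_step(net, spk[, t], supervised_target = lab)
    }
    for (t in seq_len(round(protocol$T_silence / protocol$dt))) {
      simulate_step(net, numeric(config$layer_sizes[1]))
    }
  }
  acc / n_steps
}
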