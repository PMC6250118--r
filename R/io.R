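# Checkpoint and result serialization. All artifacts are plain text
# (JSON / CSV) so runs are portable and diffable.

cfg_to_list <- function(cfg) {
  lp <- function(p) p[setdiff(names(p), "N")]
  list(
    layer_sizes = cfg$layer_sizes,
    enabled = as.list(cfg$enabled),
    neuron = lp(cfg$hidden_params),
    input_neuron = lp(cfg$input_params),
    output_neuron = lp(cfg$output_params),
    alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma, eta = cfg$eta,
    tau_decay = cfg$tau_decay,
    lateral_decay_target = cfg$lateral_decay_target,
    balancing = as.list(cfg$balancing),
    I_supervised = cfg$I_supervised,
    learn_in_silence = cfg$learn_in_silence,
    dt = cfg$dt, seed = cfg$seed
  )
}

list_to_cfg <- function(x) {
  mk <- function(p, n) do.call(layer_params, c(list(N = n), p))
  network_config(
    layer_sizes = unlist(x$layer_sizes),
    enabled = unlist(x$enabled),
    hidden_params = mk(x$neuron, x$layer_sizes[[2]]),
    output_params = mk(x$output_neuron, x$layer_sizes[[3]]),
    input_params = mk(x$input_neuron, x$layer_sizes[[1]]),
    alpha = x$alpha, beta = x$beta, gamma = x$gamma, eta = x$eta,
    tau_decay = x$tau_decay,
    lateral_decay_target = x$lateral_decay_target,
    balancing = unlist(x$balancing),
    I_supervised = x$I_supervised, learn_in_silence = x$learn_in_silence,
    dt = x$dt, seed = x$seed
  )
}

#' Save / load a network checkpoint
#'
#' Writes the full network — configuration, clock, every layer state, and
#' every connection group with its weights, decay timestamps and kind — as
#' a JSON file, and reads it back. Pending lazy decay is flushed before
#' saving so the stored weights are current.
#'
#' @param net an `snn_network`.
#' @param path output `.json` path.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   a reconstructed `snn_network`.
#' @export
save_network <- function(net, path) {
  groups <- lapply(net$groups, function(g) {
    g <- flush_decay(g, net$t_now)
    list(W = g$W, kind = g$kind, bounds = g$bounds,
         learning_rate = g$learning_rate, tau_decay = g$tau_decay,
         last_update_time = g$last_update_time, plastic = g$plastic)
  })
  obj <- list(
    format = "feelnet-checkpoint-1",
    config = cfg_to_list(net$cfg),
    t_now = net$t_now,
    states = lapply(list(input = net$input, hidden = net$hidden,
                         output = net$output), unclass),
    groups = groups
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "feelnet-checkpoint-1")) {
    stop("not a feelnet checkpoint: ", path)
  }
  cfg <- list_to_cfg(obj$config)
  net <- build_network(cfg)
  net$t_now <- obj$t_now
  for (nm in c("input", "hidden", "output")) {
    st <- lapply(obj$states[[nm]], as.numeric)
    net[[nm]] <- structure(st, class = "layer_state")
  }
  net$groups <- lapply(names(net$groups), function(nm) {
    g <- net$groups[[nm]]
    s <- obj$groups[[nm]]
    g$W <- matrix(unlist(s$W), nrow(g$W), ncol(g$W))
    g$last_update_time <- matrix(unlist(s$last_update_time), nrow(g$W), ncol(g$W))
    g$plastic <- s$plastic
    g
  })
  names(net$groups) <- c("ff_in_hidden", "ff_hidden_out", "reciprocal",
                         "lateral_output", "lateral_hidden")
  net
}

#' Write a learning curve as CSV
#'
#' @param curve a `learning_curve` data.frame from [train()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a family tree as JSON
#'
#' Levels are stored as lists of components, each component a list of
#' 1-based hidden-neuron indices.
#'
#' @param tree a [cluster_families()] tree.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_family_tree <- function(tree, path) {
  levels <- lapply(seq_along(tree$cutoffs), function(i) {
    memb <- tree$partitions[[i]]
    list(cutoff = tree$cutoffs[i],
         components = lapply(sort(unique(memb)), function(k) which(memb == k)))
  })
  jsonlite::write_json(list(format = "feelnet-family-tree-1",
                            n_neurons = tree$n_neurons, levels = levels),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
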