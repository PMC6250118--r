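# Shared builders and a lazy cache for expensive trained networks.

.fixtures <- new.env(parent = emptyenv())

# A small network used by fast unit tests: 8 input pixels, 4 hidden, 3 output.
tiny_config <- function(seed = 1L, ...) {
  network_config(layer_sizes = c(8L, 4L, 3L), seed = seed, ...)
}

# Layer params with a fixed (non-adaptive) threshold, for LIF oracle tests.
fixed_threshold_params <- function(N, V_thr, dt = 1) {
  layer_params(N = N, tau_th = Inf, delta_V_th = 0, V_th_init = V_thr, dt = dt)
}

# The default desk-scale experiment objects (synthetic task + network),
# per seed. Used by the acceptance tests.
default_objects <- function(seed) {
  cfg <- default_config(seed = seed)
  config_objects(cfg)
}

# Train the default supervised experiment for one seed and cache the result
# (trained network + learning curve + dataset). Several acceptance tests
# reuse these networks.
trained_default <- function(seed, n_train = 1000L, eval_every = 250L,
                            n_eval = 50L) {
  key <- sprintf("trained-%d-%d", seed, n_train)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  obj <- default_objects(seed)
  data <- obj$make_data()
  net <- build_network(obj$network_config)
  sch <- train_schedule("supervised", n_train_total = n_train,
                        eval_every = eval_every, n_eval = n_eval)
  fit <- train(net, data, sch, obj$protocol)
  .fixtures[[key]] <- list(net = fit$net, curve = fit$curve, data = data,
                           protocol = obj$protocol, objects = obj)
  .fixtures[[key]]
}

# Stratified test subset indices, deterministic.
stratified_idx <- function(labels, per_class, seed = 999) {
  set.seed(seed)
  unlist(lapply(sort(unique(labels)), function(k) {
    sample(which(labels == k), per_class)
  }))
}
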