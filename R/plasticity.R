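# The event-driven update rules below apply lazy decay inline with a single
# scalar factor per touched column/row: a rule always decays and stamps a
# whole column (or row), so timestamps stay uniform along the touched slice
# and one exp() per slice equals the per-weight computation of lazy_decay().

#' Connection group: one weight matrix with its kind and plasticity bookkeeping
#'
#' Weights are stored pre-synaptic x post-synaptic. Excitatory kinds
#' (`feedforward`, `reciprocal`) are clamped to `[0, 1]`; lateral inhibitory
#' kinds (`lateral_output`, `lateral_hidden`) to `[-1, 0]` with a
#' structurally zero diagonal. Every weight carries the timestamp of the last
#' time its exponential decay was applied, so decay can be computed lazily at
#' the (event-driven) moments a rule touches the weight.
#'
#' @param W initial weight matrix (pre x post).
#' @param kind one of `"feedforward"`, `"reciprocal"`, `"lateral_output"`,
#'   `"lateral_hidden"`.
#' @param learning_rate rule learning rate (alpha, beta, gamma or eta
#'   depending on kind).
#' @param tau_decay weight decay time constant, ms (default 10 s).
#' @param t_now current simulation time, ms; initializes the decay timestamps.
#' @param plastic when `FALSE`, neither rules nor decay are ever applied.
#' @param decay_target resting value the decay relaxes weights toward.
#'   Excitatory weights decay toward 0 (unused connections are forgotten).
#'   For lateral inhibitory groups the default resting state is the lower
#'   bound -1 — maximal competition — so cooperation (weights near 0) is an
#'   actively-maintained state rather than a fate every regularly-touched
#'   weight drifts into; pass 0 to make inhibition decay away instead.
#' @return an object of class `connection_group`.
#' @export
connection_group <- function(W, kind, learning_rate,
                             tau_decay = 10000, t_now = 0, plastic = TRUE,
                             decay_target = NULL) {
  kind <- match.arg(kind, c("feedforward", "reciprocal", "lateral_output", "lateral_hidden"))
  if (!is.matrix(W)) stop("W must be a matrix (pre x post)")
  bounds <- if (kind %in% c("feedforward", "reciprocal")) c(0, 1) else c(-1, 0)
  lateral <- kind %in% c("lateral_output", "lateral_hidden")
  if (lateral) {
    if (nrow(W) != ncol(W)) stop("lateral groups must be square")
    if (any(diag(W) != 0)) stop("lateral groups must have a zero diagonal (no self-inhibition)")
  }
  if (any(W < bounds[1] - 1e-12) || any(W > bounds[2] + 1e-12)) {
    stop(sprintf("initial weights outside bounds [%g, %g] for kind '%s'",
                 bounds[1], bounds[2], kind))
  }
  if (tau_decay <= 0) stop("tau_decay must be positive")
  if (is.null(decay_target)) decay_target <- if (lateral) -1 else 0
  if (decay_target < bounds[1] || decay_target > bounds[2]) {
    stop("decay_target must lie within the group's bounds")
  }
  structure(
    list(
      W = W, kind = kind, bounds = bounds, learning_rate = learning_rate,
      tau_decay = tau_decay, decay_target = decay_target,
      last_update_time = matrix(t_now, nrow(W), ncol(W)),
      plastic = plastic
    ),
    class = "connection_group"
  )
}

#' Clamp the weights of a group onto the bounds of its kind
#'
#' @param group a [connection_group()].
#' @return the group with every weight projected onto `[low, high]`. Weights
#'   stick at the bounds (hard clamping, no reflection).
#' @export
clamp_weights <- function(group) {
  group$W <- pmin(pmax(group$W, group$bounds[1]), group$bounds[2])
  group
}

#' Event-driven (lazy) exponential weight decay
#'
#' Relaxes each affected weight toward the group's `decay_target` by the
#' factor `exp(-(t_now - last_update)/tau_decay)` — the decay it would have
#' accumulated under a continuous `-(w - target)/tau` term since the last
#' time it was touched — and stamps it with `t_now`. Excitatory weights
#' (target 0) are forgotten when unused; lateral inhibitory weights relax
#' toward their resting competition value (see [connection_group()]).
#' Applying decay only at the moments a plasticity rule touches a weight is
#' exactly equivalent to integrating the decay term densely at every step.
#'
#' @param group a [connection_group()].
#' @param rows,cols index vectors selecting the affected sub-matrix
#'   (default: all rows / all columns).
#' @param t_now current simulation time, ms; must not precede any affected
#'   timestamp.
#' @return the decayed group.
#' @export
lazy_decay <- function(group, t_now, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(group$W))
  if (is.null(cols)) cols <- seq_len(ncol(group$W))
  lu <- group$last_update_time[rows, cols, drop = FALSE]
  if (any(t_now < lu)) stop("t_now precedes a stored decay timestamp (non-monotone clock)")
  tg <- group$decay_target
  group$W[rows, cols] <- tg + (group$W[rows, cols, drop = FALSE] - tg) *
    exp(-(t_now - lu) / group$tau_decay)
  group$last_update_time[rows, cols] <- t_now
  if (group$kind %in% c("lateral_output", "lateral_hidden")) {
    d <- intersect(rows, cols)
    group$W[cbind(d, d)] <- 0   # structural zero diagonal is not a weight
  }
  group
}

#' Apply decay up to the present for every weight of a group
#'
#' Convenience wrapper flushing all pending lazy decay, e.g. before
#' checkpointing or analysing weights.
#'
#' @inheritParams lazy_decay
#' @return the group with all timestamps equal to `t_now`.
#' @export
flush_decay <- function(group, t_now) {
  if (!group$plastic) return(group)
  lazy_decay(group, t_now)
}

#' Feed-forward rule: strengthen inputs that are more active than their average
#'
#' At each spike of a post-synaptic neuron `j`, its incoming column is first
#' lazily decayed and then moved by `alpha * (a_i - theta_i)` for every
#' pre-synaptic neuron `i`: the post neuron strengthens connections with
#' pre neurons whose instant activity exceeds their own running average, and
#' weakens the rest — competitive maximization of the post neuron's input.
#'
#' @param group a feedforward [connection_group()].
#' @param pre_state [layer_state()] of the pre-synaptic layer (supplies
#'   `a` and `theta`).
#' @param post_spikes binary spike vector of the post-synaptic layer.
#' @param alpha learning rate; defaults to the group's.
#' @param t_now current simulation time, ms.
#' @return the updated, clamped group.
#' @export
update_feedforward <- function(group, pre_state, post_spikes,
                               alpha = group$learning_rate, t_now) {
  if (group$kind != "feedforward") stop("group kind must be 'feedforward'")
  if (!group$plastic) return(group)
  js <- which(post_spikes > 0)
  if (length(js) == 0L) return(group)
  drive <- pre_state$a - pre_state$theta
  W <- group$W
  lu <- group$last_update_time
  n_pre <- nrow(W)
  tg <- group$decay_target
  for (j in js) {
    f <- exp(-(t_now - lu[1L, j]) / group$tau_decay)
    w <- tg + (W[, j] - tg) * f + alpha * drive
    W[, j] <- pmin.int(pmax.int(w, 0), 1)
  }
  lu[, js] <- t_now
  group$W <- W
  group$last_update_time <- lu
  group
}

#' Reciprocal rule: the output layer feeds back onto its active suppliers
#'
#' At each spike of an output neuron `k`, the reciprocal weights `w[k, j]`
#' (output -> hidden) move by `beta * (a_j - theta_j) * w_fwd[j, k]`: the
#' output neuron supplies extra current to hidden neurons that are currently
#' highly active *and* strongly connected to it in the forward direction.
#' The forward weight is read at its current (post feed-forward update)
#' value.
#'
#' @param rec_group the reciprocal [connection_group()] (output x hidden).
#' @param fwd_group the matching hidden -> output feedforward group
#'   (hidden x output).
#' @param hidden_state [layer_state()] of the hidden layer.
#' @param output_spikes binary spike vector of the output layer.
#' @param beta learning rate; defaults to the group's.
#' @param t_now current simulation time, ms.
#' @return the updated, clamped reciprocal group.
#' @export
update_reciprocal <- function(rec_group, fwd_group, hidden_state, output_spikes,
                              beta = rec_group$learning_rate, t_now) {
  if (rec_group$kind != "reciprocal") stop("group kind must be 'reciprocal'")
  if (!identical(dim(rec_group$W), rev(dim(fwd_group$W)))) {
    stop("reciprocal group must be the transpose shape of the forward group")
  }
  if (!rec_group$plastic) return(rec_group)
  ks <- which(output_spikes > 0)
  if (length(ks) == 0L) return(rec_group)
  drive <- hidden_state$a - hidden_state$theta
  W <- rec_group$W
  lu <- rec_group$last_update_time
  tg <- rec_group$decay_target
  for (k in ks) {
    f <- exp(-(t_now - lu[k, 1L]) / rec_group$tau_decay)
    w <- tg + (W[k, ] - tg) * f + beta * drive * fwd_group$W[, k]
    W[k, ] <- pmin.int(pmax.int(w, 0), 1)
  }
  lu[ks, ] <- t_now
  rec_group$W <- W
  rec_group$last_update_time <- lu
  rec_group
}

#' Output-layer lateral rule: learnable winner-take-all competition
#'
#' At each spike of an output neuron `k'`, every incoming lateral weight
#' `w[k, k']` moves by `-gamma * (a_k - theta_k)`: a neuron `k` that is more
#' active than its own average (rich in resources) strengthens its inhibition
#' onto the spiker, while under-performing neurons relax theirs.
#'
#' @param group a `lateral_output` [connection_group()] (square, zero
#'   diagonal).
#' @param output_state [layer_state()] of the output layer.
#' @param output_spikes binary spike vector of the output layer.
#' @param gamma learning rate; defaults to the group's.
#' @param t_now current simulation time, ms.
#' @return the updated, clamped group (diagonal kept at 0).
#' @export
update_output_inhibition <- function(group, output_state, output_spikes,
                                     gamma = group$learning_rate, t_now) {
  if (group$kind != "lateral_output") stop("group kind must be 'lateral_output'")
  if (!group$plastic) return(group)
  ks <- which(output_spikes > 0)
  if (length(ks) == 0L) return(group)
  drive <- output_state$a - output_state$theta
  W <- group$W
  lu <- group$last_update_time
  tg <- group$decay_target
  for (k in ks) {
    f <- exp(-(t_now - lu[1L, k]) / group$tau_decay)
    w <- tg + (W[, k] - tg) * f - gamma * drive
    w <- pmin.int(pmax.int(w, -1), 0)
    w[k] <- 0
    W[, k] <- w
  }
  lu[, ks] <- t_now
  group$W <- W
  group$last_update_time <- lu
  group
}

#' Hidden-layer lateral rule: cooperation within, competition between families
#'
#' At each spike of a hidden neuron `j`, its outgoing lateral row moves by
#' `eta * (a_j - theta_j) * (a_j' - theta_j')`: when both neurons are above
#' their running averages the (negative) weight relaxes toward 0
#' (cooperation — absence of competition); discordant pairs drive the weight
#' toward -1 (competition). This is the rule that carves the hidden layer
#' into families of co-active neurons.
#'
#' @param group a `lateral_hidden` [connection_group()] (square, zero
#'   diagonal). The matrix is directed (`w[j, j']` = inhibition from `j`
#'   onto `j'`) and is not forced symmetric.
#' @param hidden_state [layer_state()] of the hidden layer.
#' @param hidden_spikes binary spike vector of the hidden layer.
#' @param eta learning rate; defaults to the group's.
#' @param t_now current simulation time, ms.
#' @return the updated, clamped group (diagonal kept at 0).
#' @export
update_hidden_lateral <- function(group, hidden_state, hidden_spikes,
                                  eta = group$learning_rate, t_now) {
  if (group$kind != "lateral_hidden") stop("group kind must be 'lateral_hidden'")
  if (!group$plastic) return(group)
  js <- which(hidden_spikes > 0)
  if (length(js) == 0L) return(group)
  drive <- hidden_state$a - hidden_state$theta
  W <- group$W
  lu <- group$last_update_time
  tg <- group$decay_target
  for (j in js) {
    f <- exp(-(t_now - lu[j, 1L]) / group$tau_decay)
    w <- tg + (W[j, ] - tg) * f + eta * drive[j] * drive
    w <- pmin.int(pmax.int(w, -1), 0)
    w[j] <- 0
    W[j, ] <- w
  }
  lu[js, ] <- t_now
  group$W <- W
  group$last_update_time <- lu
  group
}

#' BCM-style feed-forward rule (comparison alternative)
#'
#' Rate-based BCM update, event-driven at post-synaptic spikes (the
#' post-rate factor is absorbed by the spike trigger):
#' `w[i, j] <- w[i, j] + rate * a_i * (a_j - theta_j)`. It differs from the
#' feed-forward rule in gating on the *post*-synaptic rate difference and
#' scaling by the pre-synaptic rate. Provided for rule-comparison
#' experiments; not used by default.
#'
#' @param group a feedforward [connection_group()].
#' @param pre_state,post_state [layer_state()] of the two layers.
#' @param post_spikes binary spike vector of the post-synaptic layer.
#' @param rate learning rate; defaults to the group's.
#' @param t_now current simulation time, ms.
#' @return the updated, clamped group.
#' @export
update_bcm <- function(group, pre_state, post_state, post_spikes,
                       rate = group$learning_rate, t_now) {
  if (group$kind != "feedforward") stop("group kind must be 'feedforward'")
  if (!group$plastic) return(group)
  js <- which(post_spikes > 0)
  if (length(js) == 0L) return(group)
  post_drive <- post_state$a - post_state$theta
  W <- group$W
  lu <- group$last_update_time
  tg <- group$decay_target
  for (j in js) {
    f <- exp(-(t_now - lu[1L, j]) / group$tau_decay)
    w <- tg + (W[, j] - tg) * f + rate * pre_state$a * post_drive[j]
    W[, j] <- pmin.int(pmax.int(w, 0), 1)
  }
  lu[, js] <- t_now
  group$W <- W
  group$last_update_time <- lu
  group
}
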