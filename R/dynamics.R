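#' Parameters of a layer of leaky integrate-and-fire neurons
#'
#' Bundles the per-layer constants of the neuron model: the membrane and
#' refractory time constants of the LIF equation, the decay constant and
#' per-spike increment of the adaptive firing threshold, and the fast/slow
#' time constants of the two exponential-moving-average activity traces
#' (the "instant" activity `a` and the "average" activity `theta`) on which
#' all plasticity rules operate.
#'
#' @param N number of neurons in the layer.
#' @param tau_m membrane time constant, ms.
#' @param tau_ref absolute refractory period, ms.
#' @param tau_th decay time constant of the adaptive threshold, ms. `Inf`
#'   freezes the threshold (useful for fixed-threshold experiments).
#' @param delta_V_th threshold increment constant (a.u.). The per-spike
#'   increment applied to a neuron's threshold is `delta_V_th * N` when
#'   `th_increment_mode = "multiply"` (the default: the homeostatic pressure
#'   grows with layer size, keeping firing in a stable, non-saturated
#'   regime) or `delta_V_th / N` when `"divide"`.
#' @param V_th_init initial value of the adaptive threshold (a.u.). The
#'   threshold subsequently decays toward 0 and is bumped at spikes; a fresh
#'   layer therefore starts neither silent nor epileptic.
#' @param tau_a time constant of the instant activity trace, ms.
#' @param tau_theta time constant of the average activity trace, ms.
#'   Must exceed `tau_a`; learning is driven by `a - theta`.
#' @param dt simulation step, ms. Must be smaller than every time constant.
#' @param th_increment_mode `"divide"` or `"multiply"`; see `delta_V_th`.
#' @return an object of class `layer_params` (a named list).
#' @export
layer_params <- function(N,
                         tau_m = 20,
                         tau_ref = 2,
                         tau_th = 50,
                         delta_V_th = 0.1,
                         V_th_init = 0.1,
                         tau_a = 15,
                         tau_theta = 150,
                         dt = 1,
                         th_increment_mode = c("multiply", "divide")) {
  th_increment_mode <- match.arg(th_increment_mode)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be positive and finite")
  if (tau_ref < 0) stop("tau_ref must be >= 0")
  if (tau_th <= 0) stop("tau_th must be positive")
  if (!is.finite(tau_a) || tau_a <= 0) stop("tau_a must be positive and finite")
  if (!is.finite(tau_theta) || tau_theta <= 0) stop("tau_theta must be positive and finite")
  if (tau_a >= tau_theta) stop("tau_a must be smaller than tau_theta (fast vs slow trace)")
  if (dt <= 0) stop("dt must be positive")
  if (dt >= min(tau_a, tau_m, tau_th)) {
    stop("dt must be smaller than min(tau_a, tau_m, tau_th)")
  }
  if (delta_V_th < 0) stop("delta_V_th must be >= 0")
  if (V_th_init < 0) stop("V_th_init must be >= 0")
  structure(
    list(
      N = as.integer(N), tau_m = tau_m, tau_ref = tau_ref, tau_th = tau_th,
      delta_V_th = delta_V_th, V_th_init = V_th_init,
      tau_a = tau_a, tau_theta = tau_theta, dt = dt,
      th_increment_mode = th_increment_mode
    ),
    class = "layer_params"
  )
}

#' Per-spike increment of the adaptive threshold
#'
#' @param params a [layer_params()] object.
#' @return scalar increment, `delta_V_th / N` or `delta_V_th * N`.
#' @export
threshold_increment <- function(params) {
  if (params$th_increment_mode == "divide") {
    params$delta_V_th / params$N
  } else {
    params$delta_V_th * params$N
  }
}

#' Fresh state for a layer of neurons
#'
#' All state variables start at zero except the adaptive threshold, which
#' starts at `V_th_init`.
#'
#' @param params a [layer_params()] object.
#' @return an object of class `layer_state` holding, per neuron: membrane
#'   potential `V`, adaptive threshold `V_th`, remaining refractory time
#'   `refractory_remaining` (ms), instant activity `a` and average activity
#'   `theta` (spikes/ms), and the binary spike indicator `spiked` of the
#'   current step.
#' @export
layer_state <- function(params) {
  z <- numeric(params$N)
  structure(
    list(
      V = z, V_th = rep(params$V_th_init, params$N),
      refractory_remaining = z, a = z, theta = z, spiked = z
    ),
    class = "layer_state"
  )
}

#' Update the instant and average activity traces
#'
#' Applies one step of the exponential-moving-average recurrences
#' `a <- (1 - dt/tau_a) a + s/tau_a` and
#' `theta <- (1 - dt/tau_theta) theta + s/tau_theta`,
#' where `s` is the binary spike vector of the current step (`state$spiked`).
#' The fixed point for a Bernoulli(p)-per-step spike train is `p/dt` for both
#' traces; the plasticity rules act on the difference `a - theta`.
#'
#' @param state a [layer_state()].
#' @param params a [layer_params()].
#' @return the updated state.
#' @export
step_activity <- function(state, params) {
  s <- state$spiked
  state$a <- (1 - params$dt / params$tau_a) * state$a + s / params$tau_a
  state$theta <- (1 - params$dt / params$tau_theta) * state$theta + s / params$tau_theta
  if (anyNA(state$a) || !all(is.finite(state$a)) || !all(is.finite(state$theta))) {
    stop("non-finite activity trace: check tau_a/tau_theta/dt configuration")
  }
  state
}

#' Integrate the membrane potential one step and detect spikes
#'
#' Explicit-Euler step of the LIF equation `tau_m dV/dt = -V + I` for
#' non-refractory neurons. A neuron whose potential reaches its adaptive
#' threshold (`V >= V_th`) emits a spike, resets `V` to 0 and enters the
#' refractory period; refractory neurons clamp `V` at 0, ignore the input
#' current and count their refractory timer down.
#'
#' A spike stores `tau_ref` in `refractory_remaining`; the timer counts down
#' on subsequent steps and integration resumes on the step after it reaches
#' zero, which puts exactly `tau_ref` of dead time between the spike step
#' and the first integration interval. The simulated inter-spike interval
#' therefore matches [lif_isi_closed_form()] to within one `dt`.
#'
#' @param state a [layer_state()].
#' @param I input current per neuron (a.u.), finite.
#' @param params a [layer_params()].
#' @return the updated state, with `spiked` set for this step.
#' @export
step_membrane <- function(state, I, params) {
  if (length(I) != params$N) stop("current vector length must equal N")
  if (!all(is.finite(I))) stop("non-finite input current")
  free <- state$refractory_remaining <= 0
  V <- state$V
  V[free] <- V[free] + (params$dt / params$tau_m) * (-V[free] + I[free])
  spiked <- as.numeric(free & (V >= state$V_th))
  fired <- spiked > 0
  V[fired] <- 0
  V[!free] <- 0
  ref <- state$refractory_remaining
  ref[!free] <- pmax(ref[!free] - params$dt, 0)
  ref[fired] <- params$tau_ref
  state$V <- V
  state$refractory_remaining <- ref
  state$spiked <- spiked
  state
}

#' Update the adaptive firing threshold
#'
#' The threshold decays exponentially with time constant `tau_th` and jumps
#' by [threshold_increment()] at each spike of the neuron, implementing a
#' firing-rate homeostasis that equalizes competition between neurons:
#' `V_th <- V_th (1 - dt/tau_th) + increment * spiked`.
#'
#' @param state a [layer_state()] with `spiked` set for this step.
#' @param params a [layer_params()].
#' @return the updated state. `V_th` is never negative.
#' @export
step_threshold <- function(state, params) {
  decay <- if (is.finite(params$tau_th)) 1 - params$dt / params$tau_th else 1
  state$V_th <- pmax(state$V_th * decay + threshold_increment(params) * state$spiked, 0)
  state
}

#' Closed-form inter-spike interval of a LIF neuron under constant current
#'
#' For a constant supra-threshold current `I` and a fixed threshold `V_thr`,
#' the membrane reaches threshold after `tau_m log(I / (I - V_thr))` and the
#' inter-spike interval is that time plus the refractory period. Used as an
#' independent oracle for the simulated dynamics.
#'
#' @param I constant input current, a.u.; must exceed `V_thr`.
#' @param V_thr fixed firing threshold, a.u.; must be positive.
#' @param params a [layer_params()] supplying `tau_m` and `tau_ref`.
#' @return the inter-spike interval in ms.
#' @export
lif_isi_closed_form <- function(I, V_thr, params) {
  if (V_thr <= 0) stop("V_thr must be positive")
  if (I <= V_thr) stop("I <= V_thr: the neuron never fires")
  params$tau_ref + params$tau_m * log(I / (I - V_thr))
}
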