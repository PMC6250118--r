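test_that("activity traces stay at zero without spikes and track their fixed point", {
  p <- layer_params(N = 3)
  st <- layer_state(p)
  for (i in 1:50) st <- step_activity(st, p)
  expect_identical(st$a, rep(0, 3))
  expect_identical(st$theta, rep(0, 3))

  # Bernoulli(p)-per-step trains: long-run mean of both traces is p/dt
  for (prob in c(0.05, 0.3)) {
    set.seed(10 + round(100 * prob))
    st <- layer_state(p)
    n <- 20000L
    acc_a <- 0; acc_th <- 0
    for (i in seq_len(n)) {
      st$spiked <- as.numeric(runif(3) < prob)
      st <- step_activity(st, p)
      if (i > 1000) { acc_a <- acc_a + mean(st$a); acc_th <- acc_th + mean(st$theta) }
    }
    expect_equal(acc_a / (n - 1000), prob, tolerance = 0.05)
    expect_equal(acc_th / (n - 1000), prob, tolerance = 0.05)
  }
})

test_that("instant and average traces are the same recurrence up to the time constant", {
  # with tau_a = tau_theta the two traces coincide for identical inputs
  p <- layer_params(N = 2, tau_a = 40, tau_theta = 40.000001)
  st <- layer_state(p)
  set.seed(1)
  for (i in 1:500) {
    st$spiked <- as.numeric(runif(2) < 0.2)
    st <- step_activity(st, p)
  }
  expect_equal(st$a, st$theta, tolerance = 1e-5)
})

test_that("trace update rejects degenerate time constants", {
  expect_error(layer_params(N = 1, tau_a = -5), "tau_a")
  expect_error(layer_params(N = 1, tau_a = 200, tau_theta = 150), "tau_a")
  expect_error(layer_params(N = 1, dt = 30), "dt")
})

test_that("a LIF neuron with zero input never fires and holds V = 0", {
  p <- fixed_threshold_params(2, V_thr = 0.1)
  st <- layer_state(p)
  for (i in 1:300) {
    st <- step_membrane(st, c(0, 0), p)
    expect_identical(st$V, c(0, 0))
    expect_identical(st$spiked, c(0, 0))
  }
})

test_that("simulated inter-spike interval matches the closed form within one step", {
  # fine-step simulation against tau_ref + tau_m * log(I / (I - V_thr))
  dt <- 0.01
  cases <- expand.grid(I = c(0.2, 0.35, 0.5, 1, 2), V_thr = c(0.1, 0.15))
  for (r in seq_len(nrow(cases))) {
    I <- cases$I[r]; V_thr <- cases$V_thr[r]
    p <- fixed_threshold_params(1, V_thr = V_thr, dt = dt)
    st <- layer_state(p)
    spike_times <- numeric(0)
    t <- 0
    while (length(spike_times) < 3 && t < 500) {
      st <- step_membrane(st, I, p)
      t <- t + dt
      if (st$spiked[1] > 0) spike_times <- c(spike_times, t)
    }
    expect_gte(length(spike_times), 3)
    isi <- diff(spike_times)
    expected <- lif_isi_closed_form(I, V_thr, p)
    expect_true(all(abs(isi - expected) <= dt + 1e-9),
                info = sprintf("I=%g V_thr=%g isi=%g expected=%g", I, V_thr, isi[1], expected))
  }
})

test_that("closed-form ISI behaves at its limits and rejects sub-threshold drive", {
  p <- layer_params(N = 1)
  expect_equal(lif_isi_closed_form(1e9, 0.1, p), p$tau_ref, tolerance = 1e-6)
  expect_equal(lif_isi_closed_form(0.2, 0.1, p), 2 + 20 * log(2))
  expect_error(lif_isi_closed_form(0.1, 0.1, p), "never fires")
  expect_error(lif_isi_closed_form(0.05, 0.1, p), "never fires")
})

test_that("no two spikes are closer than the refractory period, for any input", {
  p <- fixed_threshold_params(1, V_thr = 0.05)
  st <- layer_state(p)
  set.seed(42)
  times <- numeric(0)
  for (t in 1:2000) {
    I <- runif(1, 0, 3)  # wild supra-threshold input
    st <- step_membrane(st, I, p)
    if (st$spiked[1] > 0) times <- c(times, t * p$dt)
  }
  expect_gt(length(times), 10)
  expect_true(all(diff(times) >= p$tau_ref))
})

test_that("halving the step shrinks the firing-rate discretization error about linearly", {
  currents <- c(0.27, 0.3, 0.34, 0.41, 0.47)
  rate_at <- function(dt) {
    sapply(currents, function(I) {
      p <- fixed_threshold_params(1, V_thr = 0.12, dt = dt)
      st <- layer_state(p)
      n <- round(2000 / dt)
      spikes <- 0
      for (i in seq_len(n)) {
        st <- step_membrane(st, I, p)
        spikes <- spikes + st$spiked[1]
      }
      spikes / (n * dt)
    })
  }
  r_ref <- rate_at(0.0125)
  e1 <- mean(abs(rate_at(0.2) - r_ref))
  e2 <- mean(abs(rate_at(0.1) - r_ref))
  e4 <- mean(abs(rate_at(0.05) - r_ref))
  expect_lt(e2, e1)
  expect_lt(e4, e2)
})

test_that("the adaptive threshold decays exponentially and has the periodic-drive fixed point", {
  # silence: half-life tau_th * log(2)
  p <- layer_params(N = 1, tau_th = 50, dt = 0.01)
  st <- layer_state(p)  # V_th starts at V_th_init
  st$V_th <- 1
  n_half <- round(50 * log(2) / 0.01)
  for (i in seq_len(n_half)) st <- step_threshold(st, p)
  expect_equal(st$V_th, 0.5, tolerance = 0.01)

  # strictly periodic spiking at interval T: V_th at spike moments converges to
  # inc / (1 - exp(-T/tau_th)); oracle = geometric series, checked by iteration
  p1 <- layer_params(N = 4, dt = 1)
  inc <- threshold_increment(p1)
  T_per <- 10
  st <- layer_state(p1)
  st$V_th <- rep(0, 4)
  v_at_spike <- NA
  for (t in 1:3000) {
    st$spiked <- rep(as.numeric(t %% T_per == 0), 4)
    st <- step_threshold(st, p1)
    if (t %% T_per == 0) v_at_spike <- st$V_th[1]
  }
  # discrete-time geometric sum: inc * sum_k ((1-dt/tau)^T)^k
  q <- (1 - 1 / p1$tau_th)^T_per
  expect_equal(v_at_spike, inc / (1 - q), tolerance = 1e-6)
})

test_that("threshold increment honors both layer-size couplings", {
  pm <- layer_params(N = 20, th_increment_mode = "multiply")
  pd <- layer_params(N = 20, th_increment_mode = "divide")
  expect_equal(threshold_increment(pm), 0.1 * 20)
  expect_equal(threshold_increment(pd), 0.1 / 20)
})
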