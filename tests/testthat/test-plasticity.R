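# helpers to build small groups/states with prescribed traces
state_with <- function(a, theta) {
  st <- layer_state(layer_params(N = length(a)))
  st$a <- a; st$theta <- theta
  st
}
spikes <- function(n, on) { s <- numeric(n); s[on] <- 1; s }

test_that("lazy decay is the identity at zero elapsed time and exponential otherwise", {
  g <- connection_group(matrix(0.8, 2, 2), "feedforward", 0.1, tau_decay = 10000)
  expect_equal(lazy_decay(g, t_now = 0)$W, matrix(0.8, 2, 2))
  expect_equal(lazy_decay(g, t_now = 10000)$W, matrix(0.8 / exp(1), 2, 2))
  expect_error(lazy_decay(lazy_decay(g, t_now = 5), t_now = 2), "clock")
})

test_that("event-driven decay equals dense per-step decay on a random spike schedule", {
  # oracle: multiplicative (1 - dt/tau) applied every ms for 5 s
  set.seed(7)
  tau <- 10000
  g <- connection_group(matrix(runif(12), 3, 4), "feedforward", 0, tau_decay = tau)
  dense <- g$W
  spike_steps <- sort(sample(5000, 60))
  pre <- state_with(rep(0, 3), rep(0, 3))  # zero drive: decay is the only effect
  for (t in 1:5000) {
    dense <- dense * (1 - 1 / tau)
    if (t %in% spike_steps) {
      g <- update_feedforward(g, pre, spikes(4, sample(4, 2)), t_now = t)
    }
  }
  g <- flush_decay(g, 5000)
  expect_true(all(abs(g$W - dense) / dense < 0.001))
})

test_that("the four local rules reproduce hand-computed single-step updates", {
  # feed-forward: w + alpha * (a - theta)
  g <- connection_group(matrix(0.20, 1, 1), "feedforward", 0.1)
  pre <- state_with(0.6, 0.1)   # a - theta = 0.5
  g2 <- update_feedforward(g, pre, 1, alpha = 0.1, t_now = 0)
  expect_equal(g2$W[1, 1], 0.25)

  # reciprocal: w + beta * (a_j - theta_j) * w_fwd
  fwd <- connection_group(matrix(0.5, 1, 1), "feedforward", 0.1)
  rec <- connection_group(matrix(0, 1, 1), "reciprocal", 0.3)
  hid <- state_with(0.5, 0.1)   # a - theta = 0.4
  rec2 <- update_reciprocal(rec, fwd, hid, 1, beta = 0.3, t_now = 0)
  expect_equal(rec2$W[1, 1], 0.06)

  # output inhibition: w - gamma * (a_k - theta_k) at a spike of k'
  W <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  g <- connection_group(W, "lateral_output", 0.1)
  out <- state_with(c(0.4, 0), c(0.1, 0))  # neuron 1: a - theta = 0.3
  g2 <- update_output_inhibition(g, out, spikes(2, 2), gamma = 0.1, t_now = 0)
  expect_equal(g2$W[1, 2], -0.53)
  expect_equal(g2$W[2, 1], -0.5)   # column of the non-spiker untouched

  # hidden lateral: w + eta * (a_j - theta_j) * (a_j' - theta_j')
  W <- matrix(c(0, -1, -1, 0), 2, 2)
  g <- connection_group(W, "lateral_hidden", 0.15)
  hid <- state_with(c(0.5, 0.6), c(0.1, 0.1))  # drives 0.4 and 0.5
  g2 <- update_hidden_lateral(g, hid, spikes(2, 1), eta = 0.15, t_now = 0)
  expect_equal(g2$W[1, 2], -0.97)
  expect_equal(g2$W[2, 1], -1)     # row of the non-spiker untouched

  # BCM alternative: w + rate * a_i * (a_j - theta_j)
  g <- connection_group(matrix(0.1, 1, 1), "feedforward", 0.1)
  pre <- state_with(0.2, 0)
  post <- state_with(0.6, 0.1)
  g2 <- update_bcm(g, pre, post, 1, rate = 0.1, t_now = 0)
  expect_equal(g2$W[1, 1], 0.11)
})

test_that("rules are inert when the gating quantity vanishes", {
  pre <- state_with(c(0.3, 0.3), c(0.3, 0.3))   # a == theta
  g <- connection_group(matrix(0.4, 2, 2), "feedforward", 0.1)
  expect_equal(update_feedforward(g, pre, c(1, 1), t_now = 0)$W, g$W)
  # no post spikes at all
  expect_equal(update_feedforward(g, state_with(c(1, 0), c(0, 0)), c(0, 0), t_now = 50)$W, g$W)
  # zero forward weight blocks reciprocal growth
  fwd <- connection_group(matrix(0, 2, 2), "feedforward", 0.1)
  rec <- connection_group(matrix(0, 2, 2), "reciprocal", 0.3)
  expect_equal(update_reciprocal(rec, fwd, state_with(c(1, 1), c(0, 0)), c(1, 1), t_now = 0)$W,
               rec$W)
  # silent pre blocks BCM
  g2 <- update_bcm(g, state_with(c(0, 0), c(0, 0)), state_with(c(1, 1), c(0, 0)),
                   c(1, 1), t_now = 0)
  expect_equal(g2$W, g$W)
})

test_that("clamping projects onto each kind's bounds and cooperation cannot excite", {
  g <- connection_group(matrix(0.9, 1, 1), "feedforward", 1)
  g2 <- update_feedforward(g, state_with(1, 0), 1, alpha = 1, t_now = 0)
  expect_equal(g2$W[1, 1], 1)      # would be 1.9

  W <- matrix(c(0, -0.9, -0.9, 0), 2, 2)
  g <- connection_group(W, "lateral_output", 1)
  g2 <- update_output_inhibition(g, state_with(c(1, 0), c(0, 0)), spikes(2, 2),
                                 gamma = 1, t_now = 0)
  expect_equal(g2$W[1, 2], -1)     # would be -1.9

  # strong cooperation drives a lateral weight to 0, never above
  W <- matrix(c(0, -0.05, -0.05, 0), 2, 2)
  g <- connection_group(W, "lateral_hidden", 1)
  g2 <- update_hidden_lateral(g, state_with(c(1, 1), c(0, 0)), spikes(2, 1),
                              eta = 1, t_now = 0)
  expect_equal(g2$W[1, 2], 0)
  g3 <- clamp_weights(g2)
  expect_equal(g3$W, g2$W)
})

test_that("cooperation with positive drives never deepens a lateral weight", {
  set.seed(3)
  for (i in 1:20) {
    n <- 4
    W <- matrix(-runif(n * n), n, n); diag(W) <- 0
    g <- connection_group(W, "lateral_hidden", 0.15)
    drive <- runif(n, 0.05, 0.5)
    st <- state_with(drive, rep(0, n))
    g2 <- update_hidden_lateral(g, st, spikes(n, 1), t_now = 0)
    expect_true(all(g2$W[1, -1] >= g$W[1, -1]))
  }
})

test_that("weights never leave their kind's bounds under random rule sequences", {
  set.seed(99)
  n <- 5
  ff <- connection_group(matrix(runif(n * n), n, n), "feedforward", 0.3)
  rec <- connection_group(matrix(runif(n * n), n, n), "reciprocal", 0.4)
  lo <- matrix(-runif(n * n), n, n); diag(lo) <- 0
  lat_o <- connection_group(lo, "lateral_output", 0.3)
  lh <- matrix(-runif(n * n), n, n); diag(lh) <- 0
  lat_h <- connection_group(lh, "lateral_hidden", 0.4)
  t_now <- 0
  for (i in 1:2000) {
    t_now <- t_now + rexp(1, 1 / 50)
    st <- state_with(runif(n, 0, 1), runif(n, 0, 1))
    sp <- as.numeric(runif(n) < 0.5)
    ff <- update_feedforward(ff, st, sp, t_now = t_now)
    rec <- update_reciprocal(rec, ff, st, sp, t_now = t_now)
    lat_o <- update_output_inhibition(lat_o, st, sp, t_now = t_now)
    lat_h <- update_hidden_lateral(lat_h, st, sp, t_now = t_now)
  }
  expect_true(all(ff$W >= 0 & ff$W <= 1))
  expect_true(all(rec$W >= 0 & rec$W <= 1))
  expect_true(all(lat_o$W >= -1 & lat_o$W <= 0))
  expect_true(all(lat_h$W >= -1 & lat_h$W <= 0))
  expect_true(all(diag(lat_o$W) == 0) && all(diag(lat_h$W) == 0))
})

test_that("zero learning rates and infinite decay leave weights untouched", {
  set.seed(5)
  g <- connection_group(matrix(runif(9), 3, 3), "feedforward", 0, tau_decay = 1e15)
  W0 <- g$W
  for (t in seq(100, 2000, by = 100)) {
    g <- update_feedforward(g, state_with(runif(3), runif(3)), c(1, 1, 1), t_now = t)
  }
  expect_equal(g$W, W0, tolerance = 1e-9)
})

test_that("lateral groups relax toward their configured resting value", {
  W <- matrix(c(0, -0.2, -0.2, 0), 2, 2)
  g <- connection_group(W, "lateral_hidden", 0.15)        # default rest = -1
  g <- lazy_decay(g, t_now = 10000)
  expect_equal(g$W[1, 2], -1 + (-0.2 + 1) / exp(1))
  g0 <- connection_group(W, "lateral_hidden", 0.15, decay_target = 0)
  g0 <- lazy_decay(g0, t_now = 10000)
  expect_equal(g0$W[1, 2], -0.2 / exp(1))
  expect_error(connection_group(W, "lateral_hidden", 0.15, decay_target = 0.5),
               "decay_target")
})

test_that("group construction enforces kind, shape and diagonal constraints", {
  expect_error(connection_group(matrix(1.5, 2, 2), "feedforward", 0.1), "bounds")
  expect_error(connection_group(matrix(-0.5, 2, 3), "lateral_hidden", 0.1), "square")
  W <- matrix(-0.5, 2, 2)
  expect_error(connection_group(W, "lateral_output", 0.1), "diagonal")
  g <- connection_group(matrix(0.5, 2, 2), "feedforward", 0.1)
  expect_error(update_output_inhibition(g, state_with(c(0, 0), c(0, 0)), c(1, 0), t_now = 0),
               "kind")
  expect_error(update_reciprocal(g, g, state_with(c(0, 0), c(0, 0)), c(1, 0), t_now = 0),
               "kind")
})
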