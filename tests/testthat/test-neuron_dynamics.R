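test_that("resting neuron with zero drive stays at rest and never spikes", {
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 0)
  st <- neuron_state(3, p)
  for (k in 1:200) {
    out <- step_lif(st, p, rep(0, 3), dt = 1)
    st <- out$state
    expect_false(any(out$spikes))
  }
  expect_equal(st$v, rep(p$v_rest, 3))
})

test_that("one-step update without spiking is the exact exponential", {
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 0)
  set.seed(42)
  for (k in 1:20) {
    v0 <- runif(1, -1, 0.5)
    drive <- runif(1, -0.5, 0.9)
    dt <- runif(1, 0.01, 5)
    st <- neuron_state(1, p)
    st$v <- v0
    out <- step_lif(st, p, drive, dt)
    e <- p$gain * drive + p$bias + p$v_rest
    expect_identical(out$state$v, e + (v0 - e) * exp(-dt / p$tau_m))
  }
})

test_that("simulated inter-spike interval matches the closed form", {
  # tau_m = 30, v_th = 1, v_reset = -1: E = 1.5 gives 30*log(2.5/0.5)
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 0)
  expect_equal(closed_form_isi(p, 1.5), 30 * log(2.5 / 0.5))
  p5 <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5)
  expect_equal(closed_form_isi(p5, 1.5), 5 + 30 * log(2.5 / 0.5))
  expect_identical(closed_form_isi(p, 1), Inf)     # E = v_th: never
  expect_lt(closed_form_isi(p5, 1e9) - 5, 1e-6)    # E -> Inf: -> t_ref

  dt <- 0.01
  for (E in c(1.2, 1.5, 4)) {
    st <- neuron_state(1, p)
    spikes <- numeric(0)
    for (k in seq_len(ceiling(4 * closed_form_isi(p, E) / dt))) {
      out <- step_lif(st, p, E, dt)
      st <- out$state
      if (out$spikes[1]) spikes <- c(spikes, k * dt)
    }
    expect_gte(length(spikes), 3)
    expect_lt(abs(diff(spikes)[2] - closed_form_isi(p, E)), 2 * dt)
  }
})

test_that("sub-threshold drive converges to its fixed point with no spikes", {
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 0)
  st <- neuron_state(1, p)
  n_spikes <- 0
  for (k in 1:1000) {  # 1 s at dt = 1 ms
    out <- step_lif(st, p, 0.9, dt = 1)
    st <- out$state
    n_spikes <- n_spikes + sum(out$spikes)
  }
  expect_equal(n_spikes, 0)
  expect_equal(st$v, 0.9, tolerance = 1e-10)
})

test_that("firing rate is non-decreasing in the drive", {
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5)
  rates <- vapply(seq(0.8, 5, by = 0.3), function(E) {
    st <- neuron_state(1, p)
    n <- 0
    for (k in 1:2000) {
      out <- step_lif(st, p, E, dt = 1)
      st <- out$state
      n <- n + sum(out$spikes)
    }
    n
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("no membrane potential exceeds threshold after a completed step", {
  p <- lif_params(tau_m = 10, v_th = 1, v_reset = -1, t_ref = 2)
  st <- neuron_state(50, p)
  set.seed(1)
  for (k in 1:100) {
    out <- step_lif(st, p, runif(50, 0, 5), dt = 1)
    st <- out$state
    expect_true(all(st$v <= p$v_th))
    expect_true(all(st$refrac_remaining >= 0 & st$refrac_remaining <= p$t_ref))
  }
})

test_that("adaptation disabled reproduces the plain LIF exactly", {
  pl <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5)
  pa <- alif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5,
                    inc_n = 0, tau_n = 100)
  sl <- neuron_state(4, pl)
  sa <- neuron_state(4, pa)
  set.seed(3)
  for (k in 1:300) {
    drive <- runif(4, 0, 3)
    ol <- step_lif(sl, pl, drive, dt = 1)
    oa <- step_alif(sa, pa, drive, dt = 1)
    sl <- ol$state
    sa <- oa$state
    expect_identical(sa$v, sl$v)
    expect_identical(oa$spikes, ol$spikes)
  }
})

test_that("adaptation lengthens inter-spike intervals under strong drive", {
  p <- alif_params(tau_m = 30, v_th = 1, v_reset = 0, t_ref = 5,
                   inc_n = 0.15, tau_n = 1000)
  st <- neuron_state(1, p)
  spikes <- numeric(0)
  for (k in 1:4000) {
    out <- step_alif(st, p, 2, dt = 1)
    st <- out$state
    if (out$spikes[1]) spikes <- c(spikes, k)
  }
  isi <- diff(spikes)
  expect_gte(length(isi), 5)
  expect_true(all(diff(isi) >= 0))
})

test_that("adaptation decays exponentially after a single spike", {
  p <- alif_params(tau_m = 30, v_th = 1, v_reset = 0, t_ref = 0,
                   inc_n = 0.01, tau_n = 1000)
  st <- neuron_state(1, p)
  st$v <- 0.999999
  out <- step_alif(st, p, 1.05, dt = 1)  # pushes over threshold
  expect_true(out$spikes[1])
  st <- out$state
  n0 <- st$adapt[1]
  expect_equal(n0, 0.01)
  for (k in 1:500) st <- step_alif(st, p, 0, dt = 1)$state
  expect_equal(st$adapt[1], 0.01 * exp(-500 / 1000), tolerance = 1e-9)
})

test_that("clamped neurons ignore strong drive, then resume from zero", {
  p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 0)
  st <- neuron_state(2, p)
  st <- apply_clamp(st, c(TRUE, FALSE), duration = 10)
  for (k in 1:10) {  # 10 ms at dt = 1, E = 10 on both neurons
    out <- step_lif(st, p, c(10, 10), dt = 1)
    st <- out$state
    expect_false(out$spikes[1])   # clamped: no spike despite E = 10
    expect_identical(st$v[1], 0)
  }
  expect_identical(st$clamp_remaining[1], 0)
  out <- step_lif(st, p, c(10, 10), dt = 1)  # clamp expired: integrates again
  expect_gt(out$state$v[1], 0)
  # duration 0: v forced to 0 for this instant only
  st2 <- apply_clamp(neuron_state(1, p), TRUE, duration = 0)
  expect_identical(st2$v[1], 0)
  expect_identical(st2$clamp_remaining[1], 0)
})

test_that("step functions validate their arguments", {
  p <- lif_params()
  st <- neuron_state(3, p)
  expect_error(step_lif(st, p, rep(0, 2), dt = 1), "one entry per neuron")
  expect_error(step_lif(st, p, rep(0, 3), dt = 0), "positive")
  expect_error(lif_params(v_reset = 2, v_th = 1), "v_reset")
  expect_error(lif_params(tau_m = -1), "tau_m")
})
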