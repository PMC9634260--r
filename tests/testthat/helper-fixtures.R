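# Small fixtures shared across tests; everything is generated in code.

# A reduced synthetic task: 3 classes on an 8x8 grid — large enough that a
# typical foreground volley (13-26 pixels) drives the output layer, small
# enough to train in a few hundred presentations.
small_spec <- function(seed = 1, n_train = 300, n_test = 120) {
  synthetic_spec(n_classes = 3, height = 8, width = 8, flip_prob = 0.1,
                 n_train = n_train, n_test = n_test, seed = seed)
}

# A tiny network for step-level and equivalence tests.
tiny_config <- function(rule = "vdsp", n_in = 9, n_out = 3, seed = 7, ...) {
  network_config(n_in = n_in, n_out = n_out, rule = rule, seed = seed,
                 present_ms = 70, ...)
}

# Run a drive through the pure-R reference step, mirroring run_pass().
run_reference <- function(net, input, steps_per_sample, learn,
                          mode = c("constant", "poisson")) {
  mode <- match.arg(mode)
  n_samples <- ncol(input)
  counts <- matrix(0L, n_samples, net$config$n_out)
  for (s in seq_len(n_samples)) {
    if (mode == "poisson") {
      sample <- encode_poisson(
        input[, s] / 60 * 255, duration = steps_per_sample * net$config$dt,
        dt = net$config$dt, cfg = encoder_config(poisson_max_rate = 60))
      for (k in seq_len(steps_per_sample)) {
        out <- network_step(net, sample$raster[, k], learn)
        net <- out$net
        counts[s, ] <- counts[s, ] + out$out_spikes
      }
    } else {
      for (k in seq_len(steps_per_sample)) {
        out <- network_step(net, input[, s], learn)
        net <- out$net
        counts[s, ] <- counts[s, ] + out$out_spikes
      }
    }
  }
  list(net = net, counts = counts)
}

expect_network_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$W, b$W, tolerance = tol)
  expect_equal(a$in_state$v, b$in_state$v, tolerance = tol)
  expect_equal(a$in_state$refrac_remaining, b$in_state$refrac_remaining)
  expect_equal(a$out_state$v, b$out_state$v, tolerance = tol)
  expect_equal(a$out_state$refrac_remaining, b$out_state$refrac_remaining)
  expect_equal(a$out_state$adapt, b$out_state$adapt, tolerance = tol)
  expect_equal(a$out_state$clamp_remaining, b$out_state$clamp_remaining)
  expect_equal(a$syn, b$syn, tolerance = tol)
  expect_equal(a$traces$x_pre, b$traces$x_pre, tolerance = tol)
  expect_equal(a$traces$x_post, b$traces$x_post, tolerance = tol)
}
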