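test_that("compiled core reproduces the pure-R reference step exactly (vdsp)", {
  cfg <- tiny_config(rule = "vdsp")
  net <- network_init(cfg)
  set.seed(31)
  input <- matrix(runif(9 * 3, 0, 1.2), nrow = 9)  # 3 samples
  ref <- run_reference(net, input, steps_per_sample = 14, learn = TRUE)
  fast <- run_pass(net, input, 14, learn = TRUE, mode = "constant")
  expect_network_equal(ref$net, fast$net)
  expect_equal(unname(fast$counts), unname(ref$counts))
})

test_that("compiled core reproduces the pure-R reference step exactly (stdp)", {
  cfg <- tiny_config(rule = "stdp", stdp = stdp_params(x_tar = 0.2))
  net <- network_init(cfg)
  set.seed(32)
  input <- matrix(runif(9 * 3, 0, 1.2), nrow = 9)
  ref <- run_reference(net, input, 14, learn = TRUE)
  fast <- run_pass(net, input, 14, learn = TRUE, mode = "constant")
  expect_network_equal(ref$net, fast$net)
  expect_equal(unname(fast$counts), unname(ref$counts))
})

test_that("compiled core reproduces the reference in poisson mode", {
  cfg <- tiny_config(rule = "vdsp")
  net <- network_init(cfg)
  rates <- matrix(rep(c(0, 30, 60), each = 3), nrow = 9)[, 1, drop = FALSE]
  rates <- cbind(rates, rev(rates[, 1]))
  set.seed(55)
  ref <- run_reference(net, rates, 20, learn = TRUE, mode = "poisson")
  set.seed(55)
  fast <- run_pass(net, rates, 20, learn = TRUE, mode = "poisson")
  expect_network_equal(ref$net, fast$net)
  expect_equal(unname(fast$counts), unname(ref$counts))
})

test_that("zero drive produces no spikes and leaves weights unchanged", {
  cfg <- tiny_config()
  net <- network_init(cfg)
  res <- run_pass(net, matrix(0, 9, 2), 14, learn = TRUE, mode = "constant")
  expect_identical(sum(res$counts), 0L)
  expect_identical(res$net$W, net$W)
})

test_that("at most one output spikes per timestep", {
  cfg <- tiny_config(n_in = 16, n_out = 5)
  net <- network_init(cfg)
  set.seed(9)
  drive <- runif(16, 0.8, 1.2)
  for (k in 1:60) {
    out <- network_step(net, drive, learn = TRUE)
    net <- out$net
    expect_lte(sum(out$out_spikes), 1)
  }
})

test_that("inference mode never modifies weights", {
  cfg <- tiny_config(n_in = 16)
  net <- network_init(cfg)
  input <- matrix(1.2, nrow = 16, ncol = 5)  # synchronized strong drive
  res <- run_pass(net, input, 14, learn = FALSE, mode = "constant")
  expect_gt(sum(res$counts), 0)            # the network does fire
  expect_identical(res$net$W, net$W)       # but weights are untouched
})

test_that("weights stay inside [0, 1] through long random training", {
  cfg <- network_config(n_in = 25, n_out = 6, present_ms = 70)
  net <- network_init(cfg)
  set.seed(77)
  input <- matrix(runif(25 * 500, 0, 1.5), nrow = 25)
  res <- run_pass(net, input, 14, learn = TRUE, mode = "constant")
  expect_true(all(res$net$W >= 0 & res$net$W <= 1))
  expect_gt(sum(res$counts), 0)
})

test_that("repeated presentation aligns the winner's weights with the pattern", {
  # 9-pixel pattern, strong foreground; cosine similarity to the pattern
  # increases monotonically over the first presentations
  cfg <- network_config(n_in = 16, n_out = 2, present_ms = 350, seed = 4,
                        syn_gain = 1, plasticity = vdsp_params(lr = 0.05))
  net <- network_init(cfg)
  pattern <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 1)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- numeric(5)
  winner <- NULL
  for (k in 1:5) {
    res <- run_sample(net, encode_constant_current(pattern * 255,
                                                   encoder_config()))
    net <- res$net
    if (is.null(winner)) winner <- which.max(res$counts)
    sims[k] <- cosine(net$W[, winner], pattern)
  }
  expect_true(all(diff(sims) > 0))
  # background synapses onto the winner are depressed below their start
  bg <- pattern == 0
  expect_true(all(net$W[bg, winner] <
                    init_weights(16, 2, seed = 4)[bg, winner]))
})

test_that("spike counts are bit-identical across repeated deterministic runs", {
  cfg <- tiny_config()
  net <- network_init(cfg)
  set.seed(2)
  input <- matrix(runif(9 * 4, 0, 1.2), nrow = 9)
  a <- run_pass(net, input, 14, learn = TRUE, mode = "constant")
  b <- run_pass(net, input, 14, learn = TRUE, mode = "constant")
  expect_identical(a$counts, b$counts)
  expect_identical(a$net$W, b$net$W)
})

test_that("adaptation evens out the distribution of output activity", {
  # homeostasis: over an epoch, total spikes across output neurons have a
  # smaller coefficient of variation with adaptation than without
  spec <- small_spec(n_train = 200, n_test = 10)
  ds <- sample_dataset(spec)
  cv <- function(x) sd(x) / mean(x)
  cvs <- vapply(1:5, function(seed) {
    res_a <- run_experiment(ds, n_out = 9, seed = seed,
                            out_params = alif_params())
    res_0 <- run_experiment(ds, n_out = 9, seed = seed,
                            out_params = alif_params(inc_n = 0))
    c(cv(rowSums(res_a$labels$class_spike_totals)),
      cv(rowSums(res_0$labels$class_spike_totals)))
  }, numeric(2))
  expect_lt(mean(cvs[1, ]), mean(cvs[2, ]))
})

test_that("checkpoints round-trip the full network state", {
  cfg <- tiny_config()
  net <- network_init(cfg)
  set.seed(14)
  input <- matrix(runif(9 * 2, 0, 1.2), nrow = 9)
  net <- run_pass(net, input, 14, learn = TRUE, mode = "constant")$net
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_network_equal(net, net2)
  expect_identical(net2$config, net$config)
  suppressWarnings(expect_error(load_checkpoint(tempfile())))
  saveRDS(list(a = 1), f)
  expect_error(load_checkpoint(f), "checkpoint")
})

test_that("mismatched input dimensions are rejected", {
  net <- network_init(tiny_config())
  expect_error(run_pass(net, matrix(0, 5, 1), 14, TRUE, "constant"), "n_in")
  s <- encode_constant_current(rep(0, 5), encoder_config(), duration = 70)
  expect_error(run_sample(net, s), "n_in")
})
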