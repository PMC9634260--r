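#' Two-layer winner-take-all network configuration
#'
#' A fully connected feed-forward network: an input LIF population (one
#' neuron per pixel) drives an output population of adaptive LIF neurons
#' through plastic synapses. Lateral inhibition is realized as winner-take-
#' all: when any output neuron fires, all other outputs have their membrane
#' clamped to zero for `inhibit_ms`. Input spikes are low-pass filtered into
#' a synaptic current with time constant `syn_tau`; one input spike through
#' weight `w` raises the postsynaptic current by `w` (jump normalization),
#' after which it decays exponentially.
#'
#' @param n_in,n_out Population sizes.
#' @param dt Timestep in ms (default 5, equal to the refractory period).
#' @param present_ms Per-sample presentation duration in ms (default 350);
#'   must be a multiple of `dt`.
#' @param inhibit_ms WTA clamp duration in ms (default 10).
#' @param syn_tau Synaptic filter time constant in ms (default 5).
#' @param syn_gain Scale of the synaptic efficacy: one input spike through
#'   weight `w` raises the postsynaptic current by `syn_gain * w`. The
#'   default (0.5) places the output layer at an operating point where a
#'   typical input volley through *untrained* (mean 0.5) weights already
#'   drives outputs past threshold — the network must fire from the start
#'   for unsupervised learning to bootstrap — while keeping the drive close
#'   enough to threshold for the adaptation current to matter; see the
#'   methods vignette.
#' @param rule Plasticity rule, `"vdsp"` or `"stdp"`.
#' @param seed Integer seed used for weight initialization.
#' @param in_params [lif_params()] of the input layer. Defaults follow the
#'   reference configuration: `tau_m = 30`, `v_th = 1`, `v_reset = -1`,
#'   `v_rest = 0`, `t_ref = 5`, `bias = 0.5`. The positive bias puts
#'   background (zero-pixel) neurons at a positive sub-threshold potential,
#'   so their weights onto active outputs are steadily depressed.
#' @param out_params [alif_params()] of the output layer (defaults:
#'   `v_reset = 0`, `bias = 0`, `inc_n = 0.01`, `tau_n = 1000`).
#' @param plasticity A [vdsp_params()] (used when `rule = "vdsp"`).
#' @param stdp An [stdp_params()] (used when `rule = "stdp"`).
#' @param noise_sigma Per-step Gaussian drive noise on the input layer.
#'
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(n_in, n_out, dt = 5, present_ms = 350,
                           inhibit_ms = 10, syn_tau = 5, syn_gain = 0.5,
                           rule = c("vdsp", "stdp"), seed = 1,
                           in_params = lif_params(bias = 0.5),
                           out_params = alif_params(),
                           plasticity = vdsp_params(lr = 0.05),
                           stdp = stdp_params(),
                           noise_sigma = 0) {
  rule <- match.arg(rule)
  stopifnot(n_in >= 1, n_out >= 1, dt > 0, syn_tau > 0)
  if (abs(present_ms / dt - round(present_ms / dt)) > 1e-9 ||
      abs(inhibit_ms / dt - round(inhibit_ms / dt)) > 1e-9) {
    stop("`present_ms` and `inhibit_ms` must be multiples of `dt`",
         call. = FALSE)
  }
  if (rule == "vdsp") check_safe_bound(plasticity, in_params$v_reset)
  structure(
    list(n_in = n_in, n_out = n_out, dt = dt, present_ms = present_ms,
         inhibit_ms = inhibit_ms, syn_tau = syn_tau, syn_gain = syn_gain,
         rule = rule,
         seed = seed, in_params = in_params, out_params = out_params,
         plasticity = plasticity, stdp = stdp, noise_sigma = noise_sigma),
    class = "network_config"
  )
}

#' Initialize a network from its configuration
#'
#' Weights are drawn i.i.d. uniform on `[0, w_max]` from `config$seed`;
#' neuron states start at rest, synaptic currents and STDP traces at zero.
#'
#' @param config A [network_config()].
#' @return An object of class `"vdsp_network"`.
#' @export
network_init <- function(config) {
  w_max <- if (config$rule == "vdsp") config$plasticity$w_max else config$stdp$w_max
  structure(
    list(config = config,
         W = init_weights(config$n_in, config$n_out, seed = config$seed,
                          w_max = w_max),
         in_state = neuron_state(config$n_in, config$in_params),
         out_state = neuron_state(config$n_out, config$out_params),
         syn = rep(0, config$n_out),
         traces = trace_state(config$n_in, config$n_out),
         clock = 0),
    class = "vdsp_network"
  )
}

# Membrane update shared by the reference step: returns pre-reset end-of-step
# potentials, spike candidates and updated holds, without committing resets.
.membrane_update <- function(state, params, eff, dt) {
  v <- state$v
  clamped <- state$clamp_remaining > 0
  refractory <- !clamped & state$refrac_remaining > 0
  free <- !clamped & !refractory
  equil <- eff + params$v_rest
  decay <- exp(-dt / params$tau_m)
  v[free] <- equil[free] + (v[free] - equil[free]) * decay
  v[refractory] <- params$v_reset
  v[clamped] <- 0
  list(v = v, free = free, refractory = refractory, clamped = clamped)
}

#' Advance the network by one timestep (reference implementation)
#'
#' Pure-R reference for the compiled simulation core, executing the step in
#' a fixed order: (1) input-layer update (or consumption of a Poisson raster
#' row); (2) output ALIF update driven by the synaptic current as of the end
#' of the previous step (synaptic transmission carries a one-step delay, so
#' an input spike can excite the output layer only from the following step
#' onward); (3) winner selection among threshold crossers (largest pre-reset
#' potential, then lowest index) and clamping of all other outputs for
#' `inhibit_ms`; (4) synaptic low-pass update with this step's weighted
#' input spike vector; (5) plasticity. The VDSP update reads the presynaptic
#' potential at the end of the step, before any same-step presynaptic reset:
#' with the transmission delay, an input that fired one step earlier (and
#' caused the post spike) is read at its reset value and potentiated, while
#' an input charging toward threshold — or firing in the same step, i.e.
#' just after the post spike — is read high and depressed.
#'
#' @param net A [network_init()] network.
#' @param input For constant-current mode, the drive vector (length `n_in`);
#'   for Poisson mode, a logical spike row.
#' @param learn Apply plasticity if `TRUE`.
#'
#' @return A list `net`, `in_spikes`, `out_spikes`.
#' @export
network_step <- function(net, input, learn = TRUE) {
  cfg <- net$config
  dt <- cfg$dt
  ip <- cfg$in_params
  op <- cfg$out_params

  # (1) input layer
  ist <- net$in_state
  if (is.logical(input)) {            # Poisson raster row: forced spikes
    eff <- rep(ip$bias, cfg$n_in)
    upd <- .membrane_update(ist, ip, eff, dt)
    in_spikes <- input & upd$free
  } else {
    drive <- input
    if (cfg$noise_sigma > 0) drive <- inject_gaussian_noise(drive, cfg$noise_sigma)
    eff <- ip$gain * drive + ip$bias
    upd <- .membrane_update(ist, ip, eff, dt)
    in_spikes <- upd$free & upd$v >= ip$v_th
  }
  v_pre_read <- upd$v                 # end-of-step, pre-reset
  v <- upd$v
  v[in_spikes] <- ip$v_reset
  ist$refrac_remaining[in_spikes] <- ip$t_ref
  hold <- upd$refractory | upd$clamped
  ist$refrac_remaining[hold] <- pmax(ist$refrac_remaining[hold] - dt, 0)
  ist$clamp_remaining[upd$clamped] <- pmax(ist$clamp_remaining[upd$clamped] - dt, 0)
  ist$v <- v
  net$in_state <- ist

  # (2) output ALIF update, driven by last step's synaptic current
  ost <- net$out_state
  eff_out <- op$gain * net$syn + op$bias - ost$adapt
  updo <- .membrane_update(ost, op, eff_out, dt)
  crossers <- updo$free & updo$v >= op$v_th

  # (3) winner take all
  out_spikes <- rep(FALSE, cfg$n_out)
  if (any(crossers)) {
    idx <- which(crossers)
    winner <- idx[which.max(updo$v[idx])]  # ties: lowest index (which.max)
    out_spikes[winner] <- TRUE
  }
  vo <- updo$v
  vo[out_spikes] <- op$v_reset
  ost$refrac_remaining[out_spikes] <- op$t_ref
  holdo <- updo$refractory | updo$clamped
  ost$refrac_remaining[holdo] <- pmax(ost$refrac_remaining[holdo] - dt, 0)
  ost$clamp_remaining[updo$clamped] <- pmax(ost$clamp_remaining[updo$clamped] - dt, 0)
  ost$adapt <- ost$adapt * exp(-dt / op$tau_n)
  if (any(out_spikes)) {
    ost$adapt[out_spikes] <- ost$adapt[out_spikes] + op$inc_n
    vo[!out_spikes] <- 0
    ost$clamp_remaining[!out_spikes] <- cfg$inhibit_ms
  }
  ost$v <- vo
  net$out_state <- ost

  # (4) synaptic current: first-order low-pass of weighted input spikes
  syn <- net$syn * exp(-dt / cfg$syn_tau)
  if (any(in_spikes)) {
    syn <- syn + cfg$syn_gain * colSums(net$W[in_spikes, , drop = FALSE])
  }
  net$syn <- syn

  # (5) plasticity
  if (cfg$rule == "stdp") {
    decayed <- trace_state(cfg$n_in, cfg$n_out)
    decayed$x_pre <- net$traces$x_pre * exp(-dt / cfg$stdp$tau_plus)
    decayed$x_post <- net$traces$x_post * exp(-dt / cfg$stdp$tau_minus)
    if (learn) {
      net$W <- stdp_apply(net$W, decayed, in_spikes, out_spikes, cfg$stdp)
    }
    decayed$x_pre[in_spikes] <- decayed$x_pre[in_spikes] + cfg$stdp$trace_increment
    decayed$x_post[out_spikes] <- decayed$x_post[out_spikes] + cfg$stdp$trace_increment
    net$traces <- decayed
  } else if (learn && any(out_spikes)) {
    net$W <- apply_on_post_spikes(net$W, v_pre_read, out_spikes,
                                  cfg$plasticity)
  }

  if (anyNA(net$out_state$v) || any(!is.finite(net$out_state$v))) {
    stop("non-finite membrane potential in output layer", call. = FALSE)
  }
  net$clock <- net$clock + dt
  list(net = net, in_spikes = in_spikes, out_spikes = out_spikes)
}

#' Present one encoded sample to the network
#'
#' Advances the network `duration/dt` steps with the sample's drive (or
#' spike raster). Neuron states are deliberately *not* reset between
#' samples: presentation is back-to-back with no wait time. By default the
#' compiled core is used; `use_compiled = FALSE` runs the pure-R reference
#' step, which is exact but much slower.
#'
#' @param net A [network_init()] network.
#' @param sample An [encode_constant_current()] / [encode_poisson()] sample.
#' @param learn Apply plasticity if `TRUE`.
#' @param use_compiled Use the compiled simulation core.
#'
#' @return A list with `net` (advanced network) and `counts` (per-output
#'   spike totals for the presentation).
#' @export
run_sample <- function(net, sample, learn = TRUE, use_compiled = TRUE) {
  cfg <- net$config
  n_steps <- round(sample$duration / cfg$dt)
  if (!is.null(sample$raster)) {
    if (nrow(sample$raster) != cfg$n_in) {
      stop("sample dimension does not match `n_in`", call. = FALSE)
    }
    if (use_compiled) {
      return(run_raster_compiled(net, sample$raster, learn))
    }
    counts <- rep(0L, cfg$n_out)
    for (k in seq_len(ncol(sample$raster))) {
      out <- network_step(net, sample$raster[, k], learn)
      net <- out$net
      counts <- counts + out$out_spikes
    }
    return(list(net = net, counts = counts))
  }
  if (length(sample$drive) != cfg$n_in) {
    stop("sample dimension does not match `n_in`", call. = FALSE)
  }
  if (use_compiled) {
    res <- run_pass(net, matrix(sample$drive, ncol = 1), n_steps, learn,
                    mode = "constant")
    return(list(net = res$net, counts = res$counts[1, ]))
  }
  counts <- rep(0L, cfg$n_out)
  for (k in seq_len(n_steps)) {
    out <- network_step(net, sample$drive, learn)
    net <- out$net
    counts <- counts + out$out_spikes
  }
  list(net = net, counts = counts)
}

# Run a whole pass of samples through the compiled core.
# `input` is an n_in x n_samples matrix of constant currents ("constant")
# or firing rates in Hz ("poisson"); every sample lasts `steps_per_sample`
# steps. Returns list(net, counts) with counts n_samples x n_out.
run_pass <- function(net, input, steps_per_sample, learn,
                     mode = c("constant", "poisson")) {
  mode <- match.arg(mode)
  cfg <- net$config
  if (nrow(input) != cfg$n_in) {
    stop("input dimension does not match `n_in`", call. = FALSE)
  }
  res <- sim_pass_cpp(
    W = net$W, input = input, steps = as.integer(steps_per_sample),
    mode_poisson = (mode == "poisson"), learn = learn,
    rule_stdp = (cfg$rule == "stdp"),
    in_par = unclass(cfg$in_params), out_par = unclass(cfg$out_params),
    vdsp_par = unclass(cfg$plasticity), stdp_par = unclass(cfg$stdp),
    dt = cfg$dt, syn_tau = cfg$syn_tau, syn_gain = cfg$syn_gain,
    inhibit_ms = cfg$inhibit_ms, noise_sigma = cfg$noise_sigma,
    v_in = net$in_state$v, ref_in = net$in_state$refrac_remaining,
    v_out = net$out_state$v, ref_out = net$out_state$refrac_remaining,
    adapt = net$out_state$adapt, clamp_out = net$out_state$clamp_remaining,
    syn = net$syn, x_pre = net$traces$x_pre, x_post = net$traces$x_post)
  net$W <- res$W
  net$in_state$v <- res$v_in
  net$in_state$refrac_remaining <- res$ref_in
  net$out_state$v <- res$v_out
  net$out_state$refrac_remaining <- res$ref_out
  net$out_state$adapt <- res$adapt
  net$out_state$clamp_remaining <- res$clamp_out
  net$syn <- res$syn
  net$traces$x_pre <- res$x_pre
  net$traces$x_post <- res$x_post
  net$clock <- net$clock + ncol(input) * steps_per_sample * cfg$dt
  list(net = net, counts = res$counts)
}

run_raster_compiled <- function(net, raster, learn) {
  cfg <- net$config
  res <- sim_raster_cpp(
    W = net$W, raster = raster, learn = learn,
    rule_stdp = (cfg$rule == "stdp"),
    in_par = unclass(cfg$in_params), out_par = unclass(cfg$out_params),
    vdsp_par = unclass(cfg$plasticity), stdp_par = unclass(cfg$stdp),
    dt = cfg$dt, syn_tau = cfg$syn_tau, syn_gain = cfg$syn_gain,
    inhibit_ms = cfg$inhibit_ms,
    v_in = net$in_state$v, ref_in = net$in_state$refrac_remaining,
    v_out = net$out_state$v, ref_out = net$out_state$refrac_remaining,
    adapt = net$out_state$adapt, clamp_out = net$out_state$clamp_remaining,
    syn = net$syn, x_pre = net$traces$x_pre, x_post = net$traces$x_post)
  net$W <- res$W
  net$in_state$v <- res$v_in
  net$in_state$refrac_remaining <- res$ref_in
  net$out_state$v <- res$v_out
  net$out_state$refrac_remaining <- res$ref_out
  net$out_state$adapt <- res$adapt
  net$out_state$clamp_remaining <- res$clamp_out
  net$syn <- res$syn
  net$traces$x_pre <- res$x_pre
  net$traces$x_post <- res$x_post
  net$clock <- net$clock + ncol(raster) * cfg$dt
  list(net = net, counts = drop(res$counts))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration, weight
#' matrix, neuron states, synaptic currents, traces and the current RNG
#' state, so a run can resume bit-identically.
#'
#' @param net A network.
#' @param path Checkpoint file path.
#' @return `path` invisibly ([save_checkpoint()]); the restored network
#'   ([load_checkpoint()]).
#' @export
save_checkpoint <- function(net, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  saveRDS(list(net = net, rng_state = rng, format = "vdsp-checkpoint-1"),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "vdsp-checkpoint-1")) {
    stop("not a network checkpoint", call. = FALSE)
  }
  if (!is.null(ck$rng_state)) {
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  }
  ck$net
}
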