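#' Pair-based STDP parameters (two-trace formulation)
#'
#' Classic exponential spike-timing-dependent plasticity: for a pre/post
#' spike pair separated by \eqn{\Delta t = t_{post} - t_{pre}},
#' \deqn{\Delta w = \begin{cases}
#'   a_+ (w_{max} - w) e^{-\Delta t/\tau_+}, & \Delta t \ge 0 \\
#'   -a_- w \, e^{\Delta t/\tau_-}, & \Delta t < 0,
#' \end{cases}}
#' with soft-bound multiplicative weight dependence so weights remain in
#' `[0, w_max]`. Online, the rule is computed with one decaying trace per
#' neuron (incremented by `trace_increment` on that neuron's spikes):
#' potentiation reads the presynaptic trace on postsynaptic spikes, and
#' depression reads the postsynaptic trace on presynaptic spikes.
#'
#' @param a_plus Potentiation amplitude (>= 0).
#' @param a_minus Depression amplitude (>= 0).
#' @param tau_plus Potentiation time constant in ms (> 0).
#' @param tau_minus Depression time constant in ms (> 0).
#' @param trace_increment Amount added to a trace per spike.
#' @param x_tar Target presynaptic-trace offset for the postsynaptic-spike
#'   update. With `x_tar > 0` the post-spike update becomes
#'   `a_plus * ((w_max - w) * x_pre - x_tar * w)`: inputs whose trace falls
#'   short of the target are depressed when the postsynaptic neuron fires,
#'   the weight-normalizing ingredient competitive unsupervised STDP
#'   networks rely on. The default 0 gives the pure pair-based rule that
#'   reproduces the exponential window for isolated spike pairs.
#' @param w_max Upper weight bound.
#'
#' @return An object of class `"stdp_params"`.
#' @export
stdp_params <- function(a_plus = 0.05, a_minus = 0.05,
                        tau_plus = 20, tau_minus = 20,
                        trace_increment = 1, x_tar = 0, w_max = 1) {
  if (tau_plus <= 0 || tau_minus <= 0) {
    stop("STDP time constants must be positive", call. = FALSE)
  }
  if (a_plus < 0 || a_minus < 0) {
    stop("STDP amplitudes must be non-negative", call. = FALSE)
  }
  structure(
    list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
         tau_minus = tau_minus, trace_increment = trace_increment,
         x_tar = x_tar, w_max = w_max),
    class = "stdp_params"
  )
}

#' STDP weight change for an isolated spike pair
#'
#' @param delta_t Spike-time difference `t_post - t_pre` in ms (vectorized).
#'   `delta_t >= 0` selects the potentiation branch.
#' @param w Current weight(s) in `[0, w_max]`.
#' @param params An [stdp_params()].
#'
#' @return The weight change(s).
#' @export
#' @examples
#' p <- stdp_params(a_plus = 0.01, tau_plus = 20)
#' stdp_dw(20, 0, p)  # a_plus * w_max * exp(-1)
stdp_dw <- function(delta_t, w, params) {
  n <- max(length(delta_t), length(w))
  delta_t <- rep_len(delta_t, n)
  w <- rep_len(w, n)
  dw <- numeric(n)
  pot <- delta_t >= 0
  dw[pot] <- params$a_plus * (params$w_max - w[pot]) *
    exp(-delta_t[pot] / params$tau_plus)
  dw[!pot] <- -params$a_minus * w[!pot] *
    exp(delta_t[!pot] / params$tau_minus)
  dw
}

#' Create an empty pair of pre/post spike traces
#'
#' @param n_pre,n_post Population sizes.
#' @return An object of class `"trace_state"` with fields `x_pre`, `x_post`.
#' @export
trace_state <- function(n_pre, n_post) {
  structure(list(x_pre = rep(0, n_pre), x_post = rep(0, n_post)),
            class = "trace_state")
}

#' Decay and increment STDP spike traces for one timestep
#'
#' Traces decay by `exp(-dt/tau)` and are then incremented by
#' `trace_increment` on their neuron's spikes. Weight updates themselves are
#' applied by [stdp_apply()] *before* the increments of the same step, so a
#' spike never acts on its own trace within its step.
#'
#' @param traces A [trace_state()].
#' @param pre_spikes,post_spikes Logical spike masks.
#' @param dt Timestep in ms (> 0).
#' @param params An [stdp_params()].
#'
#' @return The updated [trace_state()].
#' @export
step_traces <- function(traces, pre_spikes, post_spikes, dt, params) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  traces$x_pre <- traces$x_pre * exp(-dt / params$tau_plus)
  traces$x_post <- traces$x_post * exp(-dt / params$tau_minus)
  traces$x_pre[pre_spikes] <- traces$x_pre[pre_spikes] + params$trace_increment
  traces$x_post[post_spikes] <- traces$x_post[post_spikes] + params$trace_increment
  traces
}

#' Apply trace-based STDP weight updates for one timestep
#'
#' Given the traces *after* this step's decay but *before* this step's
#' increments (see [step_traces()]), applies depression for every presynaptic
#' spike (proportional to the postsynaptic trace) and then potentiation for
#' every postsynaptic spike (proportional to the presynaptic trace).
#' Depression is applied before potentiation; with increments deferred to
#' [step_traces()], the two phases read the same trace values and the order
#' is immaterial for the result, but it is fixed for reproducibility.
#'
#' @param W Weight matrix (pre x post).
#' @param traces A [trace_state()] holding decayed traces.
#' @param pre_spikes,post_spikes Logical spike masks.
#' @param params An [stdp_params()].
#'
#' @return The updated weight matrix.
#' @export
stdp_apply <- function(W, traces, pre_spikes, post_spikes, params) {
  pre_idx <- which(pre_spikes)
  if (length(pre_idx)) {
    # depression: -a_minus * w * x_post, for rows of spiking pre neurons
    W[pre_idx, ] <- W[pre_idx, , drop = FALSE] *
      (1 - params$a_minus * rep(traces$x_post, each = length(pre_idx)))
  }
  post_idx <- which(post_spikes)
  for (j in post_idx) {
    W[, j] <- W[, j] + params$a_plus *
      ((params$w_max - W[, j]) * traces$x_pre - params$x_tar * W[, j])
  }
  W
}
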