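#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the LIF neuron model
#' \deqn{\tau_m \frac{dv}{dt} = -(v - v_{rest}) + g I + b,}
#' where the membrane potential relaxes exponentially toward the equilibrium
#' \eqn{E = g I + b + v_{rest}} and a spike is emitted (followed by a reset to
#' `v_reset` and a refractory hold of `t_ref` milliseconds) whenever `v`
#' crosses the threshold `v_th`.
#'
#' @param tau_m Membrane leak time constant in ms. Must be positive.
#' @param v_th Threshold potential (V).
#' @param v_reset Reset potential (V); must be below `v_th`.
#' @param v_rest Resting potential (V); must be below `v_th`.
#' @param t_ref Refractory period in ms (>= 0). While refractory the membrane
#'   is held at `v_reset` and all input is ignored.
#' @param bias Constant additive drive, on the same (dimensionless) scale as
#'   the input current.
#' @param gain Multiplicative scale applied to the external current.
#'
#' @return An object of class `"lif_params"`.
#' @seealso [alif_params()], [step_lif()], [closed_form_isi()]
#' @export
#' @examples
#' p <- lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5, bias = 0.5)
#' closed_form_isi(p, drive = 1)
lif_params <- function(tau_m = 30, v_th = 1, v_reset = -1, v_rest = 0,
                       t_ref = 5, bias = 0, gain = 1) {
  if (!is.numeric(tau_m) || tau_m <= 0) {
    stop("`tau_m` must be positive", call. = FALSE)
  }
  if (t_ref < 0) stop("`t_ref` must be non-negative", call. = FALSE)
  if (v_reset >= v_th) stop("`v_reset` must be below `v_th`", call. = FALSE)
  if (v_rest >= v_th) stop("`v_rest` must be below `v_th`", call. = FALSE)
  structure(
    list(tau_m = tau_m, v_th = v_th, v_reset = v_reset, v_rest = v_rest,
         t_ref = t_ref, bias = bias, gain = gain),
    class = "lif_params"
  )
}

#' Adaptive LIF (ALIF) neuron parameters
#'
#' Extends [lif_params()] with a spike-triggered adaptation current `n`:
#' every spike increments `n` by `inc_n`, `n` decays exponentially with time
#' constant `tau_n` (\eqn{\tau_n \, dn/dt = -n}), and the instantaneous value
#' of `n` is subtracted from the input current. Sustained strong input
#' therefore produces progressively longer inter-spike intervals.
#'
#' @inheritParams lif_params
#' @param inc_n Adaptation increment per spike (current units, >= 0).
#' @param tau_n Adaptation decay time constant in ms (> 0).
#'
#' @return An object of class `c("alif_params", "lif_params")`.
#' @export
alif_params <- function(tau_m = 30, v_th = 1, v_reset = 0, v_rest = 0,
                        t_ref = 5, bias = 0, gain = 1,
                        inc_n = 0.01, tau_n = 1000) {
  if (inc_n < 0) stop("`inc_n` must be non-negative", call. = FALSE)
  if (tau_n <= 0) stop("`tau_n` must be positive", call. = FALSE)
  p <- lif_params(tau_m, v_th, v_reset, v_rest, t_ref, bias, gain)
  p$inc_n <- inc_n
  p$tau_n <- tau_n
  class(p) <- c("alif_params", "lif_params")
  p
}

#' Create a neuron population state
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] or [alif_params()] object; used to set the
#'   initial membrane potential to the resting potential.
#'
#' @return An object of class `"neuron_state"` with vectors `v` (membrane
#'   potential), `refrac_remaining` (ms), `adapt` (adaptation current) and
#'   `clamp_remaining` (ms).
#' @export
neuron_state <- function(n, params) {
  stopifnot(n >= 1)
  structure(
    list(v = rep(params$v_rest, n),
         refrac_remaining = rep(0, n),
         adapt = rep(0, n),
         clamp_remaining = rep(0, n)),
    class = "neuron_state"
  )
}

check_step_args <- function(state, drive, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (length(drive) != length(state$v)) {
    stop("`drive` must have one entry per neuron", call. = FALSE)
  }
}

#' Advance a LIF population by one timestep
#'
#' Exact exponential (zero-order-hold) update under piecewise-constant drive:
#' for a non-refractory, non-clamped neuron
#' \deqn{v' = E + (v - E) e^{-dt/\tau_m}, \quad E = g\,\mathrm{drive} + b + v_{rest}.}
#' Threshold crossings are detected at the end of the step; spiking neurons
#' are reset to `v_reset` and enter the refractory period, during which the
#' membrane is held at `v_reset`. Clamped neurons (see [apply_clamp()]) hold
#' `v = 0`, ignore all drive, and override refractoriness; both the clamp and
#' refractory timers decrement concurrently.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()].
#' @param drive Numeric vector of input currents, one per neuron.
#' @param dt Timestep in ms.
#'
#' @return A list with elements `state` (updated [neuron_state()]) and
#'   `spikes` (logical mask of neurons that fired this step).
#' @export
step_lif <- function(state, params, drive, dt) {
  check_step_args(state, drive, dt)
  eff <- params$gain * drive + params$bias
  .step_population(state, params, eff, dt)
}

#' Advance an ALIF population by one timestep
#'
#' As [step_lif()], with the adaptation current subtracted from the drive:
#' the effective input is `gain * drive + bias - n`. On each spike `n`
#' increases by `inc_n`; between spikes it decays exponentially with `tau_n`.
#'
#' @inheritParams step_lif
#' @param params An [alif_params()].
#' @return As [step_lif()].
#' @export
step_alif <- function(state, params, drive, dt) {
  check_step_args(state, drive, dt)
  eff <- params$gain * drive + params$bias - state$adapt
  out <- .step_population(state, params, eff, dt)
  st <- out$state
  st$adapt <- st$adapt * exp(-dt / params$tau_n)
  st$adapt[out$spikes] <- st$adapt[out$spikes] + params$inc_n
  out$state <- st
  out
}

# Shared LIF/ALIF membrane update; `eff` is the effective current
# (already includes gain, bias and any adaptation term).
.step_population <- function(state, params, eff, dt) {
  v <- state$v
  refrac <- state$refrac_remaining
  clamp <- state$clamp_remaining

  clamped <- clamp > 0
  refractory <- !clamped & refrac > 0
  free <- !clamped & !refractory

  equil <- eff + params$v_rest
  decay <- exp(-dt / params$tau_m)
  v[free] <- equil[free] + (v[free] - equil[free]) * decay
  v[refractory] <- params$v_reset
  v[clamped] <- 0

  spikes <- free & v >= params$v_th
  v[spikes] <- params$v_reset
  refrac[spikes] <- params$t_ref
  refrac[refractory | clamped] <- pmax(refrac[refractory | clamped] - dt, 0)
  clamp[clamped] <- pmax(clamp[clamped] - dt, 0)

  state$v <- v
  state$refrac_remaining <- refrac
  state$clamp_remaining <- clamp
  list(state = state, spikes = spikes)
}

#' Closed-form inter-spike interval of a LIF neuron under constant drive
#'
#' For a constant effective equilibrium `E = gain * drive + bias + v_rest`
#' above threshold, integrating the membrane equation from `v_reset` to
#' `v_th` gives the inter-spike interval
#' \deqn{ISI = t_{ref} + \tau_m \ln\frac{E - v_{reset}}{E - v_{th}}.}
#' This serves as the independent oracle against which the clock-driven
#' simulator is validated.
#'
#' @param params A [lif_params()].
#' @param drive Constant input current (scalar or vector).
#'
#' @return Inter-spike interval(s) in ms; `Inf` when the equilibrium never
#'   reaches threshold (the neuron never fires).
#' @export
#' @examples
#' closed_form_isi(lif_params(tau_m = 30, v_th = 1, v_reset = -1, t_ref = 5),
#'                 drive = 1.5)  # 5 + 30 * log(2.5 / 0.5)
closed_form_isi <- function(params, drive) {
  e <- params$gain * drive + params$bias + params$v_rest
  isi <- rep(Inf, length(e))
  ok <- e > params$v_th
  isi[ok] <- params$t_ref +
    params$tau_m * log((e[ok] - params$v_reset) / (e[ok] - params$v_th))
  isi
}

#' Clamp the membrane potential of selected neurons to zero
#'
#' Implements winner-take-all lateral inhibition: targeted neurons have their
#' membrane potential forced to 0 V and ignore all drive for `duration` ms.
#' The clamp overrides refractoriness; both timers run down concurrently.
#'
#' @param state A [neuron_state()].
#' @param mask Logical vector of neurons to clamp.
#' @param duration Clamp duration in ms (>= 0).
#'
#' @return The updated [neuron_state()].
#' @export
apply_clamp <- function(state, mask, duration) {
  if (duration < 0) stop("`duration` must be non-negative", call. = FALSE)
  state$v[mask] <- 0
  state$clamp_remaining[mask] <- duration
  state
}
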