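#' Configuration for the voltage / spike-time equivalence analysis
#'
#' Under constant supra-threshold drive `I`, a LIF membrane follows
#' \eqn{v(t) = I + c\,e^{-t/\tau_m}}, so the membrane potential observed at a
#' postsynaptic spike determines the time distance to the nearest presynaptic
#' spike in closed form. These parameters describe the presynaptic neuron
#' (zero bias, zero rest) and the STDP time constants used to map that
#' distance to a normalized weight change.
#'
#' @param tau_m Membrane time constant in ms.
#' @param v_th Threshold potential (V).
#' @param v_reset Reset potential (V).
#' @param I Constant drive; must exceed `v_th` so the presynaptic neuron
#'   spikes in finite time.
#' @param tau_plus,tau_minus STDP potentiation/depression time constants (ms).
#'
#' @return An object of class `"analytic_config"`.
#' @export
analytic_config <- function(tau_m = 30, v_th = 1, v_reset = -1, I,
                            tau_plus = 20, tau_minus = 20) {
  if (I <= v_th) {
    stop("`I` must exceed `v_th` for the presynaptic neuron to spike",
         call. = FALSE)
  }
  if (v_reset >= v_th) stop("`v_reset` must be below `v_th`", call. = FALSE)
  structure(
    list(tau_m = tau_m, v_th = v_th, v_reset = v_reset, I = I,
         tau_plus = tau_plus, tau_minus = tau_minus),
    class = "analytic_config"
  )
}

check_v_obs <- function(v_post_obs, cfg) {
  if (any(v_post_obs < cfg$v_reset | v_post_obs >= cfg$v_th)) {
    stop("`v_post_obs` must lie in [v_reset, v_th)", call. = FALSE)
  }
}

#' Time distance to the nearest presynaptic spike, from the membrane potential
#'
#' Inverts the constant-current membrane trajectory: given the presynaptic
#' potential `v_post_obs` observed at a postsynaptic spike,
#' \deqn{|\Delta t| = \tau_m \min\left\{
#'   \left|\ln\frac{v_{th}-I}{v-I}\right|,
#'   \left|\ln\frac{v_{reset}-I}{v-I}\right| \right\},}
#' i.e. the smaller of the time until the next presynaptic spike (membrane
#' still charging toward `v_th`) and the time since the last one (membrane
#' just left `v_reset`). Assumes no refractory period.
#'
#' @param v_post_obs Observed presynaptic potential(s), in `[v_reset, v_th)`.
#' @param cfg An [analytic_config()].
#'
#' @return Absolute time distance(s) in ms.
#' @export
#' @examples
#' cfg <- analytic_config(I = 2)
#' delta_t_from_voltage(0, cfg)  # 30 * log(1.5)
delta_t_from_voltage <- function(v_post_obs, cfg) {
  check_v_obs(v_post_obs, cfg)
  t_next <- abs(log((cfg$v_th - cfg$I) / (v_post_obs - cfg$I)))
  t_prev <- abs(log((cfg$v_reset - cfg$I) / (v_post_obs - cfg$I)))
  cfg$tau_m * pmin(t_next, t_prev)
}

#' Normalized STDP window expressed in the presynaptic membrane potential
#'
#' Closed form of the exponential STDP window as a function of the
#' presynaptic potential at the postsynaptic spike, for `v_th = 1` and
#' `v_reset = -1`:
#' \deqn{\Delta w = \begin{cases}
#'  \left(\frac{v-I}{-1-I}\right)^{\tau_m/\tau_+}, & v < I - \sqrt{I^2-1}
#'  \quad \text{(pre fired recently: potentiation)}\\[4pt]
#'  -\left(\frac{1-I}{v-I}\right)^{\tau_m/\tau_-}, & \text{otherwise
#'  (pre about to fire: depression).}
#' \end{cases}}
#' The branch point \eqn{v = I - \sqrt{I^2-1}} is where the distances to the
#' previous and next presynaptic spike coincide. Algebraically this equals
#' \eqn{\pm e^{-|\Delta t|/\tau}} with \eqn{|\Delta t|} from
#' [delta_t_from_voltage()].
#'
#' @inheritParams delta_t_from_voltage
#' @return Normalized weight change(s) in `[-1, 1]`.
#' @export
stdp_window_from_voltage <- function(v_post_obs, cfg) {
  if (cfg$v_th != 1 || cfg$v_reset != -1) {
    stop("closed form requires v_th = 1 and v_reset = -1", call. = FALSE)
  }
  check_v_obs(v_post_obs, cfg)
  branch <- cfg$I - sqrt(cfg$I^2 - 1)
  pot <- branch > v_post_obs
  out <- numeric(length(v_post_obs))
  out[pot] <- ((v_post_obs[pot] - cfg$I) / (-1 - cfg$I))^(cfg$tau_m / cfg$tau_plus)
  out[!pot] <- -((1 - cfg$I) / (v_post_obs[!pot] - cfg$I))^(cfg$tau_m / cfg$tau_minus)
  out
}

#' Empirical VDSP plasticity window from a two-neuron protocol
#'
#' Simulates a presynaptic LIF neuron under constant drive `I` (clock-driven,
#' fine `dt`), lets it reach steady periodic firing, and then forces a
#' postsynaptic spike at each offset `delta_t` relative to a reference
#' presynaptic spike. The VDSP update is evaluated at a fixed initial weight
#' `w0` from the presynaptic potential sampled at the forced spike time.
#' The postsynaptic neuron's own dynamics are bypassed (direct spike
#' injection), matching the standard window-characterization protocol.
#'
#' @param cfg An [analytic_config()].
#' @param lr Learning rate used for the probe update.
#' @param w0 Fixed initial weight in `(0, w_max)`.
#' @param delta_t_grid Offsets `t_post - t_pre` in ms at which to probe.
#' @param dt Simulation timestep in ms; should be much smaller than `tau_m`
#'   and the grid spacing.
#' @param t_ref Presynaptic refractory period in ms (default 0; a positive
#'   value produces the characteristic plateau over `[0, t_ref]` where the
#'   membrane is pinned at `v_reset`).
#' @param w_max Upper weight bound.
#'
#' @return A `data.frame` with columns `delta_t_ms`, `v_pre` and `delta_w`.
#' @export
vdsp_window_scan <- function(cfg, lr = 0.001, w0 = 0.5, delta_t_grid,
                             dt = 0.05, t_ref = 0, w_max = 1) {
  if (w0 <= 0 || w0 >= w_max) stop("`w0` must be in (0, w_max)", call. = FALSE)
  params <- lif_params(tau_m = cfg$tau_m, v_th = cfg$v_th,
                       v_reset = cfg$v_reset, v_rest = 0,
                       t_ref = t_ref, bias = 0, gain = 1)
  isi <- closed_form_isi(params, cfg$I)
  # simulate long enough for several periods on both sides of the reference
  horizon <- 6 * isi + 2 * max(abs(delta_t_grid))
  n_steps <- ceiling(horizon / dt)
  st <- neuron_state(1L, params)
  v_trace <- numeric(n_steps)
  spike_steps <- integer(0)
  for (k in seq_len(n_steps)) {
    out <- step_lif(st, params, cfg$I, dt)
    st <- out$state
    if (out$spikes[1L]) {
      spike_steps <- c(spike_steps, k)
      v_trace[k] <- cfg$v_th  # pre-reset potential: at threshold when firing
    } else {
      v_trace[k] <- st$v[1L]
    }
  }
  if (length(spike_steps) < 4L) {
    stop("presynaptic neuron did not reach steady firing; increase drive",
         call. = FALSE)
  }
  # reference spike in steady state, away from both ends of the trace
  ref <- spike_steps[length(spike_steps) %/% 2L]
  probe <- ref + round(delta_t_grid / dt)
  if (any(probe < 1L | probe > n_steps)) {
    stop("`delta_t_grid` extends beyond the simulated trace", call. = FALSE)
  }
  v_pre <- v_trace[probe]
  vp <- vdsp_params(lr = lr, w_max = w_max, v_bound = cfg$v_reset)
  data.frame(delta_t_ms = delta_t_grid, v_pre = v_pre,
             delta_w = vdsp_dw(v_pre, w0, vp))
}

#' Half-width of a plasticity window on the potentiation side
#'
#' Returns the absolute time offset at which the potentiation branch of a
#' window table first falls to half of its maximum, using linear
#' interpolation between grid points. Scale-invariant: multiplying the whole
#' window by a constant leaves the half-width unchanged. A pure exponential
#' `exp(-dt/tau)` has half-width `tau * log(2)`.
#'
#' @param table A `data.frame` with columns `delta_t_ms` and `delta_w`, as
#'   produced by [vdsp_window_scan()].
#'
#' @return Half-width in ms.
#' @export
window_halfwidth <- function(table) {
  pos <- table[table$delta_w > 0, , drop = FALSE]
  if (nrow(pos) < 2L) stop("window has no potentiation side", call. = FALSE)
  x <- abs(pos$delta_t_ms)
  o <- order(x)
  x <- x[o]
  y <- pos$delta_w[o]
  peak <- max(y)
  half <- peak / 2
  below <- which(y < half)
  if (!length(below)) {
    stop("window is flat: |delta_w| never falls below half maximum",
         call. = FALSE)
  }
  i <- below[1L]
  if (i == 1L) return(x[1L])
  # linear interpolation between the last point above half and the first below
  x[i - 1L] + (x[i] - x[i - 1L]) * (y[i - 1L] - half) / (y[i - 1L] - y[i])
}

#' Empirical validation of the voltage-to-spike-time inversion
#'
#' Simulates a presynaptic LIF neuron under constant drive with the
#' clock-driven integrator (no refractory period), samples the membrane
#' potential at random observation times, and compares
#' [delta_t_from_voltage()] against the measured time distance to the
#' nearest recorded presynaptic spike. On an exact integrator the two agree
#' to within the timestep discretization.
#'
#' @param cfg An [analytic_config()].
#' @param dt Simulation timestep in ms.
#' @param n_obs Number of random observation times.
#' @param n_isi Number of inter-spike intervals to simulate.
#' @param seed Seed for drawing observation times.
#'
#' @return A list with `max_deviation_ms` (worst absolute disagreement),
#'   `deviations` and `n_spikes`.
#' @export
delta_t_oracle_check <- function(cfg, dt = 0.01, n_obs = 1000, n_isi = 12,
                                 seed = 1) {
  params <- lif_params(tau_m = cfg$tau_m, v_th = cfg$v_th,
                       v_reset = cfg$v_reset, v_rest = 0, t_ref = 0,
                       bias = 0, gain = 1)
  horizon <- n_isi * closed_form_isi(params, cfg$I)
  n_steps <- ceiling(horizon / dt)
  st <- neuron_state(1L, params)
  v_trace <- numeric(n_steps)
  spike_t <- numeric(0)
  for (k in seq_len(n_steps)) {
    out <- step_lif(st, params, cfg$I, dt)
    st <- out$state
    v_trace[k] <- st$v[1L]
    if (out$spikes[1L]) spike_t <- c(spike_t, k * dt)
  }
  if (length(spike_t) < 3L) stop("too few presynaptic spikes", call. = FALSE)
  # observe strictly between the first and last spike so a nearest
  # neighbour exists on both sides
  lo <- ceiling(spike_t[1L] / dt) + 1L
  hi <- floor(spike_t[length(spike_t)] / dt) - 1L
  set.seed(seed)
  obs <- sample(lo:hi, n_obs, replace = TRUE)
  dev <- vapply(obs, function(k) {
    v <- max(min(v_trace[k], cfg$v_th - 1e-12), cfg$v_reset)
    measured <- min(abs(k * dt - spike_t))
    abs(delta_t_from_voltage(v, cfg) - measured)
  }, numeric(1))
  list(max_deviation_ms = max(dev), deviations = dev,
       n_spikes = length(spike_t))
}
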