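#' Parameters of the voltage-dependent synaptic plasticity (VDSP) rule
#'
#' VDSP updates a synapse only when the postsynaptic neuron spikes, using the
#' presynaptic membrane potential \eqn{V_{pre}} at that moment in place of
#' stored spike times or traces:
#' \deqn{dW = \begin{cases}
#'   (W_{max} - W)(e^{-V_{pre}} - 1)\,lr, & V_{pre} < 0 \\
#'   -W (e^{V_{pre}} - 1)\,lr, & V_{pre} > 0
#' \end{cases}}
#' A negative presynaptic potential (the neuron fired recently and sits near
#' its reset value) potentiates; a positive potential (the neuron is charging
#' toward threshold, about to fire) depresses. The multiplicative factors
#' `(w_max - w)` and `w` soft-bound the weight in `[0, w_max]` with no
#' clipping.
#'
#' Containment without clipping holds provided
#' `lr * (exp(|v_bound|) - 1) <= 1`, where `v_bound` is the most negative
#' reachable presynaptic potential (normally `v_reset`). The constructor
#' warns when the default bound of -1 V violates this condition; use
#' [check_safe_bound()] for other neuron configurations.
#'
#' @param lr Learning rate (> 0, dimensionless).
#' @param w_max Maximum conductance (> 0; default 1).
#' @param v_bound Most negative reachable presynaptic potential used for the
#'   containment check (default -1).
#'
#' @return An object of class `"vdsp_params"`.
#' @seealso [vdsp_dw()], [apply_on_post_spikes()]
#' @export
vdsp_params <- function(lr = 0.05, w_max = 1, v_bound = -1) {
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  if (w_max <= 0) stop("`w_max` must be positive", call. = FALSE)
  p <- structure(list(lr = lr, w_max = w_max), class = "vdsp_params")
  check_safe_bound(p, v_bound)
  p
}

#' Check the no-clipping containment condition of VDSP
#'
#' Iterated VDSP updates stay inside `[0, w_max]` without clipping whenever
#' `lr * (exp(|v_bound|) - 1) <= 1`: a single potentiation step then never
#' moves a weight past `w_max`, and symmetrically for depression.
#'
#' @param params A [vdsp_params()].
#' @param v_bound The largest-magnitude presynaptic potential the rule can
#'   observe (typically `v_reset`).
#'
#' @return `TRUE` (invisibly) if the condition holds, otherwise `FALSE` with
#'   a warning.
#' @export
check_safe_bound <- function(params, v_bound) {
  ok <- params$lr * (exp(abs(v_bound)) - 1) <= 1
  if (!ok) {
    warning(sprintf(
      "lr = %g violates the containment condition lr*(exp(|%g|)-1) <= 1; iterated updates may overshoot [0, w_max]",
      params$lr, v_bound), call. = FALSE)
  }
  invisible(ok)
}

#' VDSP weight change for a single postsynaptic spike
#'
#' Evaluates the voltage-dependent update for presynaptic potential(s)
#' `v_pre` and current weight(s) `w`. Vectorized over both arguments
#' (recycled to a common length). `v_pre = 0` returns exactly 0: both
#' one-sided limits of the rule vanish there.
#'
#' @param v_pre Presynaptic membrane potential(s) (V) at the postsynaptic
#'   spike time.
#' @param w Current weight(s); must lie in `[0, w_max]`.
#' @param params A [vdsp_params()].
#'
#' @return The weight change(s) `dw`; same sign as `-v_pre` (or zero).
#' @export
#' @examples
#' p <- vdsp_params(lr = 0.001)
#' vdsp_dw(-1, 0.5, p)   # potentiation: 0.5 * (e - 1) * 0.001
#' vdsp_dw(0.5, 1, p)    # depression
vdsp_dw <- function(v_pre, w, params) {
  if (any(w < 0 | w > params$w_max)) {
    stop("`w` outside [0, w_max]", call. = FALSE)
  }
  n <- max(length(v_pre), length(w))
  v_pre <- rep_len(v_pre, n)
  w <- rep_len(w, n)
  dw <- numeric(n)
  pot <- v_pre < 0
  dep <- v_pre > 0
  dw[pot] <- (params$w_max - w[pot]) * (exp(-v_pre[pot]) - 1) * params$lr
  dw[dep] <- -w[dep] * (exp(v_pre[dep]) - 1) * params$lr
  dw
}

#' Apply VDSP to the columns of spiking postsynaptic neurons
#'
#' Every column of `W` whose postsynaptic neuron appears in `post_spikes` is
#' updated elementwise with [vdsp_dw()] using the current presynaptic
#' potentials; all other columns are untouched. Under the containment
#' condition the result stays in `[0, w_max]` with no clipping applied.
#'
#' @param W Weight matrix, presynaptic index x postsynaptic index.
#' @param v_pre Presynaptic membrane potential vector (length `nrow(W)`).
#' @param post_spikes Logical mask over postsynaptic neurons (length
#'   `ncol(W)`).
#' @param params A [vdsp_params()].
#'
#' @return The updated weight matrix.
#' @export
apply_on_post_spikes <- function(W, v_pre, post_spikes, params) {
  if (length(v_pre) != nrow(W)) {
    stop("`v_pre` must have one entry per presynaptic neuron", call. = FALSE)
  }
  if (length(post_spikes) != ncol(W)) {
    stop("`post_spikes` must have one entry per postsynaptic neuron",
         call. = FALSE)
  }
  for (j in which(post_spikes)) {
    W[, j] <- W[, j] + vdsp_dw(v_pre, W[, j], params)
  }
  W
}

#' Initialize a uniform random weight matrix
#'
#' Entries are drawn i.i.d. uniform on `[0, w_max]`, matching the random
#' initial conditions of the classification network.
#'
#' @param n_pre,n_post Positive matrix dimensions (presynaptic x
#'   postsynaptic).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param w_max Upper weight bound (default 1).
#'
#' @return A `n_pre` x `n_post` numeric matrix.
#' @export
init_weights <- function(n_pre, n_post, seed, w_max = 1) {
  stopifnot(n_pre >= 1, n_post >= 1)
  rng <- local({
    set.seed(seed)
    stats::runif(n_pre * n_post, min = 0, max = w_max)
  })
  matrix(rng, nrow = n_pre, ncol = n_post)
}

#' Write a weight matrix to CSV
#'
#' Rows are presynaptic indices, columns postsynaptic indices.
#'
#' @param W Weight matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(W, path) {
  utils::write.table(W, path, sep = ",", row.names = FALSE,
                     col.names = paste0("post", seq_len(ncol(W))))
  invisible(path)
}

#' Read a weight matrix written by [write_weights_csv()]
#'
#' @param path CSV file path.
#' @return A numeric matrix.
#' @export
read_weights_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
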