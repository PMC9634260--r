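#include <Rcpp.h>
using namespace Rcpp;

// Clock-driven core of the two-layer winner-take-all network.
//
// Mirrors the pure-R reference step (network_step) exactly, in the same
// fixed order: input-layer membrane update -> output ALIF update driven by
// the previous step's synaptic current (one-step transmission delay) ->
// winner selection and clamp -> synaptic low-pass update with this step's
// weighted input spikes -> plasticity.  The R reference is the contract;
// this function is only a fast path and is cross-checked against it in the
// test suite.
//
// RNG: uses the R RNG (RNGScope) so runs are reproducible via set.seed().
// Draw order per step: for each input neuron, first the optional Gaussian
// drive-noise deviate, then (in Poisson mode without an explicit raster)
// the Bernoulli uniform.  One uniform is consumed per neuron per step
// regardless of refractoriness, matching rasters pre-generated in R.

struct LifPar {
  double tau_m, v_th, v_reset, v_rest, t_ref, bias, gain;
  double inc_n = 0.0, tau_n = 1.0;
};

static LifPar read_par(const List& p, bool adaptive) {
  LifPar q;
  q.tau_m = as<double>(p["tau_m"]);
  q.v_th = as<double>(p["v_th"]);
  q.v_reset = as<double>(p["v_reset"]);
  q.v_rest = as<double>(p["v_rest"]);
  q.t_ref = as<double>(p["t_ref"]);
  q.bias = as<double>(p["bias"]);
  q.gain = as<double>(p["gain"]);
  if (adaptive) {
    q.inc_n = as<double>(p["inc_n"]);
    q.tau_n = as<double>(p["tau_n"]);
  }
  return q;
}

static List sim_core(NumericMatrix W_in, const NumericMatrix& input,
                     const LogicalMatrix& raster, bool have_raster,
                     int steps, bool mode_poisson, bool learn, bool rule_stdp,
                     const List& in_par, const List& out_par,
                     const List& vdsp_par, const List& stdp_par,
                     double dt, double syn_tau, double syn_gain,
                     double inhibit_ms, double noise_sigma,
                     NumericVector v_in0, NumericVector ref_in0,
                     NumericVector v_out0, NumericVector ref_out0,
                     NumericVector adapt0, NumericVector clamp_out0,
                     NumericVector syn0, NumericVector x_pre0,
                     NumericVector x_post0) {
  const LifPar ip = read_par(in_par, false);
  const LifPar op = read_par(out_par, true);
  const double lr = as<double>(vdsp_par["lr"]);
  const double w_max_v = as<double>(vdsp_par["w_max"]);
  const double a_plus = as<double>(stdp_par["a_plus"]);
  const double a_minus = as<double>(stdp_par["a_minus"]);
  const double tau_plus = as<double>(stdp_par["tau_plus"]);
  const double tau_minus = as<double>(stdp_par["tau_minus"]);
  const double tr_inc = as<double>(stdp_par["trace_increment"]);
  const double x_tar = as<double>(stdp_par["x_tar"]);
  const double w_max_s = as<double>(stdp_par["w_max"]);

  const int n_in = W_in.nrow(), n_out = W_in.ncol();
  const int n_samples = have_raster ? 1 : input.ncol();
  const int raster_steps = have_raster ? raster.ncol() : steps;

  NumericMatrix W = clone(W_in);
  NumericVector v_in = clone(v_in0), ref_in = clone(ref_in0);
  NumericVector v_out = clone(v_out0), ref_out = clone(ref_out0);
  NumericVector adapt = clone(adapt0), clamp_out = clone(clamp_out0);
  NumericVector syn = clone(syn0);
  NumericVector x_pre = clone(x_pre0), x_post = clone(x_post0);

  const double dec_in = std::exp(-dt / ip.tau_m);
  const double dec_out = std::exp(-dt / op.tau_m);
  const double dec_syn = std::exp(-dt / syn_tau);
  const double dec_n = std::exp(-dt / op.tau_n);
  const double dec_xp = std::exp(-dt / tau_plus);
  const double dec_xm = std::exp(-dt / tau_minus);

  IntegerMatrix counts(n_samples, n_out);
  std::vector<char> in_spike(n_in);
  std::vector<double> v_read(n_in);

  RNGScope rng;

  for (int s = 0; s < n_samples; ++s) {
    const int n_steps = have_raster ? raster_steps : steps;
    for (int t = 0; t < n_steps; ++t) {
      // (1) input layer
      int n_sp = 0;
      for (int i = 0; i < n_in; ++i) {
        double eps = (noise_sigma > 0) ? norm_rand() * noise_sigma : 0.0;
        bool forced = false;
        if (mode_poisson) {
          if (have_raster) {
            forced = raster(i, t);
          } else {
            double p = input(i, s) * dt / 1000.0;  // rate in Hz
            forced = (unif_rand() < p);
          }
        }
        bool spike = false;
        if (ref_in[i] > 0) {                     // refractory hold
          v_in[i] = ip.v_reset;
          v_read[i] = ip.v_reset;
          ref_in[i] = std::max(ref_in[i] - dt, 0.0);
        } else {
          double drv = mode_poisson ? 0.0 : input(i, s);
          double E = ip.gain * (drv + eps) + ip.bias + ip.v_rest;
          double v = E + (v_in[i] - E) * dec_in;
          v_read[i] = v;                         // end-of-step, pre-reset
          spike = mode_poisson ? forced : (v >= ip.v_th);
          if (spike) {
            v = ip.v_reset;
            ref_in[i] = ip.t_ref;
          }
          v_in[i] = v;
        }
        in_spike[i] = spike;
        if (spike) ++n_sp;
      }

      // (2) output ALIF update, driven by last step's synaptic current
      int winner = -1;
      double v_best = R_NegInf;
      for (int j = 0; j < n_out; ++j) {
        if (clamp_out[j] > 0) {
          v_out[j] = 0.0;
          clamp_out[j] = std::max(clamp_out[j] - dt, 0.0);
          if (ref_out[j] > 0) ref_out[j] = std::max(ref_out[j] - dt, 0.0);
        } else if (ref_out[j] > 0) {
          v_out[j] = op.v_reset;
          ref_out[j] = std::max(ref_out[j] - dt, 0.0);
        } else {
          double E = op.gain * syn[j] + op.bias + op.v_rest - adapt[j];
          double v = E + (v_out[j] - E) * dec_out;
          v_out[j] = v;
          if (v >= op.v_th && v > v_best) {  // ties: first (lowest index)
            v_best = v;
            winner = j;
          }
        }
        adapt[j] *= dec_n;
      }

      // (3) winner take all
      if (winner >= 0) {
        counts(s, winner) += 1;
        for (int j = 0; j < n_out; ++j) {
          if (j == winner) {
            v_out[j] = op.v_reset;
            ref_out[j] = op.t_ref;
            adapt[j] += op.inc_n;
          } else {
            v_out[j] = 0.0;
            clamp_out[j] = inhibit_ms;
          }
        }
      }

      // (4) synaptic current update with this step's input spikes
      for (int j = 0; j < n_out; ++j) syn[j] *= dec_syn;
      if (n_sp > 0) {
        for (int i = 0; i < n_in; ++i) {
          if (!in_spike[i]) continue;
          for (int j = 0; j < n_out; ++j) syn[j] += syn_gain * W(i, j);
        }
      }

      // (5) plasticity
      if (rule_stdp) {
        for (int i = 0; i < n_in; ++i) x_pre[i] *= dec_xp;
        for (int j = 0; j < n_out; ++j) x_post[j] *= dec_xm;
        if (learn) {
          if (n_sp > 0) {                        // depression on pre spikes
            for (int i = 0; i < n_in; ++i) {
              if (!in_spike[i]) continue;
              for (int j = 0; j < n_out; ++j) {
                W(i, j) *= 1.0 - a_minus * x_post[j];
              }
            }
          }
          if (winner >= 0) {                     // post-spike update
            for (int i = 0; i < n_in; ++i) {
              W(i, winner) += a_plus * ((w_max_s - W(i, winner)) * x_pre[i] -
                                        x_tar * W(i, winner));
            }
          }
        }
        for (int i = 0; i < n_in; ++i) {
          if (in_spike[i]) x_pre[i] += tr_inc;
        }
        if (winner >= 0) x_post[winner] += tr_inc;
      } else if (learn && winner >= 0) {
        for (int i = 0; i < n_in; ++i) {
          double v = v_read[i];
          double w = W(i, winner);
          if (v < 0) {
            w += (w_max_v - w) * (std::exp(-v) - 1.0) * lr;
          } else if (v > 0) {
            w -= w * (std::exp(v) - 1.0) * lr;
          }
          W(i, winner) = w;
        }
      }
    }
    for (int j = 0; j < n_out; ++j) {
      if (!R_finite(v_out[j])) {
        stop("non-finite membrane potential in output layer (sample %d)",
             s + 1);
      }
    }
  }

  return List::create(
      _["counts"] = counts, _["W"] = W,
      _["v_in"] = v_in, _["ref_in"] = ref_in,
      _["v_out"] = v_out, _["ref_out"] = ref_out,
      _["adapt"] = adapt, _["clamp_out"] = clamp_out,
      _["syn"] = syn, _["x_pre"] = x_pre, _["x_post"] = x_post);
}

// [[Rcpp::export]]
List sim_pass_cpp(NumericMatrix W, NumericMatrix input, int steps,
                  bool mode_poisson, bool learn, bool rule_stdp,
                  List in_par, List out_par, List vdsp_par, List stdp_par,
                  double dt, double syn_tau, double syn_gain,
                  double inhibit_ms, double noise_sigma,
                  NumericVector v_in, NumericVector ref_in,
                  NumericVector v_out, NumericVector ref_out,
                  NumericVector adapt, NumericVector clamp_out,
                  NumericVector syn, NumericVector x_pre,
                  NumericVector x_post) {
  LogicalMatrix empty(0, 0);
  return sim_core(W, input, empty, false, steps, mode_poisson, learn,
                  rule_stdp, in_par, out_par, vdsp_par, stdp_par, dt,
                  syn_tau, syn_gain, inhibit_ms, noise_sigma, v_in, ref_in,
                  v_out, ref_out, adapt, clamp_out, syn, x_pre, x_post);
}

// [[Rcpp::export]]
List sim_raster_cpp(NumericMatrix W, LogicalMatrix raster, bool learn,
                    bool rule_stdp, List in_par, List out_par,
                    List vdsp_par, List stdp_par, double dt, double syn_tau,
                    double syn_gain, double inhibit_ms,
                    NumericVector v_in, NumericVector ref_in,
                    NumericVector v_out, NumericVector ref_out,
                    NumericVector adapt, NumericVector clamp_out,
                    NumericVector syn, NumericVector x_pre,
                    NumericVector x_post) {
  NumericMatrix empty(raster.nrow(), 1);
  return sim_core(W, empty, raster, true, raster.ncol(), true, learn,
                  rule_stdp, in_par, out_par, vdsp_par, stdp_par, dt,
                  syn_tau, syn_gain, inhibit_ms, 0.0, v_in, ref_in, v_out,
                  ref_out, adapt, clamp_out, syn, x_pre, x_post);
}
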