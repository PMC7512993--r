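#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Event loop of the Approach Sensitivity Cell, mirroring the hardware
// state machine per incoming event: Decay (timestamp-driven) ->
// OnEvent/OffEvent subunit update -> ComputeInputtoAC (center-surround
// over all subunits) -> ComputenetSynapticInput -> ComputeMembranState ->
// ComparetoIFThreshold.
//
// Semantics must stay in lock-step with the pure-R engine built from the
// exported per-operation functions (R/ac-model.R); the test suite asserts
// the two agree event-for-event. Grid storage is column-major (idx =
// row + n_side * col) to match R matrices. Poisson draws use R's RNG so
// both engines consume the identical stream of uniforms.

// [[Rcpp::export]]
List ac_run_cpp(NumericVector t, IntegerVector x, IntegerVector y,
                IntegerVector pol_on,
                int n_side, int rf_side,
                double g_on, double g_off, double w,
                double if_threshold, bool poisson, double refractory_us,
                double decay_period_us, double decay_factor,
                bool surround, bool polarity_swap,
                double time_unit_us, double dt_max_us,
                bool trace) {
  const int n = t.size();
  const int ns = n_side, ncell = ns * ns;
  std::vector<double> von(ncell, 0.0), voff(ncell, 0.0);

  double v_mem = 0.0, t_last_decay = NA_REAL, t_last_event = NA_REAL;
  double t_last_spike = -INFINITY;

  LogicalVector fired(n);
  NumericVector tr_inet(trace ? n : 0), tr_vmem(trace ? n : 0);

  for (int i = 0; i < n; ++i) {
    const double tn = t[i];
    if (i > 0 && tn < t[i - 1])
      stop("out-of-order timestamp at event %d", i + 1);

    // Decay branch: k full periods elapsed since the last decay tick
    if (ISNAN(t_last_decay)) {
      t_last_decay = tn;
    } else {
      double k = std::floor((tn - t_last_decay) / decay_period_us);
      if (k > 0) {
        double f = std::pow(decay_factor, k);
        for (int c = 0; c < ncell; ++c) { von[c] *= f; voff[c] *= f; }
        t_last_decay += k * decay_period_us;
      }
    }

    // OnEvent / OffEvent: deposit into the owning subunit
    int r = y[i] / rf_side, c = x[i] / rf_side;
    int p = pol_on[i];
    if (polarity_swap) p = 1 - p;
    if (p == 1) von[r + ns * c] += w; else voff[r + ns * c] += w;

    // ComputeInputtoAC + ComputenetSynapticInput
    double sum_eff = 0.0, sum_on = 0.0;
    for (int cc = 0; cc < ns; ++cc) {
      for (int rr = 0; rr < ns; ++rr) {
        double center = voff[rr + ns * cc];
        if (center < 0) center = 0;
        double eff = center;
        if (surround && ns > 1) {
          double acc = 0.0; int cnt = 0;
          if (rr > 0)      { double v = voff[rr - 1 + ns * cc]; acc += (v > 0 ? v : 0); ++cnt; }
          if (rr < ns - 1) { double v = voff[rr + 1 + ns * cc]; acc += (v > 0 ? v : 0); ++cnt; }
          if (cc > 0)      { double v = voff[rr + ns * (cc - 1)]; acc += (v > 0 ? v : 0); ++cnt; }
          if (cc < ns - 1) { double v = voff[rr + ns * (cc + 1)]; acc += (v > 0 ? v : 0); ++cnt; }
          eff = center - acc / cnt;
          if (eff < 0) eff = 0;
        }
        sum_eff += eff;
        double vo = von[rr + ns * cc];
        sum_on += (vo > 0 ? vo : 0);
      }
    }
    double i_net = g_off * sum_eff - g_on * sum_on;

    // ComputeMembranState: dT since previous input event, saturated.
    // Membrane is held at reset during the absolute refractory interval.
    double dt_us = ISNAN(t_last_event) ? 0.0 : tn - t_last_event;
    if (dt_us > dt_max_us) dt_us = dt_max_us;
    if (tn - t_last_spike < refractory_us) {
      v_mem = 0;
    } else {
      v_mem += i_net * (dt_us / time_unit_us);
      if (v_mem < 0) v_mem = 0;
    }
    t_last_event = tn;

    // ComparetoIFThreshold (with absolute refractory interval)
    bool f = false;
    if (tn - t_last_spike >= refractory_us) {
      double thr = poisson ? R::runif(0.0, if_threshold) : if_threshold;
      if (v_mem > thr) {
        f = true;
        v_mem = 0;
        t_last_spike = tn;
      }
    }
    fired[i] = f;
    if (trace) { tr_inet[i] = i_net; tr_vmem[i] = v_mem; }
  }

  NumericMatrix von_m(ns, ns), voff_m(ns, ns);
  for (int c = 0; c < ns; ++c)
    for (int r = 0; r < ns; ++r) {
      von_m(r, c) = von[r + ns * c];
      voff_m(r, c) = voff[r + ns * c];
    }

  List out = List::create(_["fired"] = fired,
                          _["v_on"] = von_m, _["v_off"] = voff_m,
                          _["v_mem"] = trace ? (SEXP)tr_vmem : R_NilValue,
                          _["i_net"] = trace ? (SEXP)tr_inet : R_NilValue);
  return out;
}
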