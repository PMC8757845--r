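#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step PSV controller + single-compartment patient, integrated at the
// acquisition rate. The ventilator triggers on the effort-driven flow
// component (pmus/R), i.e. it is leak-compensated by construction; measured
// leak and noise are added downstream in R.
//
// Causes: 0 = patient-triggered, 1 = backup timer, 2 = scheduled auto-trigger.
// [[Rcpp::export]]
List psv_simulate_core(NumericVector pmus, double dt,
                       double epap, double ipap, double f_bck,
                       NumericVector effort_onset, NumericVector effort_end,
                       NumericVector at_times,
                       double sens_lps, double tau_rise, double tau_fall,
                       double cycle_off_frac, double min_insp, double max_insp,
                       double min_exp, double resistance, double compliance) {
  const int n = pmus.size();
  NumericVector paw(n), qpat(n), vol(n);

  double p = epap;
  double v = compliance * epap;       // passive equilibrium volume at EPAP
  bool insp = false;
  double t_onset = -1e9, t_insp_end = -1e9, q_peak = 0.0;
  double next_backup = 0.0;   // the ventilator opens with a machine cycle
  int at_idx = 0, n_at = at_times.size();
  int cur_effort = -1;

  std::vector<double> onsets, insp_ends;
  std::vector<int> causes, effort_ids;

  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    // ventilator pressure dynamics
    double tau = insp ? tau_rise : tau_fall;
    double target = insp ? ipap : epap;
    p += dt * (target - p) / tau;

    // patient flow (L/s) and volume
    double q = (p + pmus[i] - v / compliance) / resistance;
    v += dt * q;
    paw[i] = p; qpat[i] = q; vol[i] = v;

    if (insp) {
      if (q > q_peak) q_peak = q;
      bool off = (t - t_onset >= min_insp && q < cycle_off_frac * q_peak) ||
                 (t - t_onset >= max_insp);
      if (off) { insp = false; t_insp_end = t; }
    } else {
      bool can_trigger = (t - t_insp_end) >= min_exp;
      int cause = -1;
      if (can_trigger && pmus[i] / resistance > sens_lps) cause = 0;
      if (cause < 0 && t >= next_backup) cause = 1;
      if (cause < 0 && at_idx < n_at && t >= at_times[at_idx]) {
        if (can_trigger) { cause = 2; ++at_idx; }
      }
      if (cause >= 0) {
        insp = true; t_onset = t; q_peak = 0.0;
        next_backup = t + 60.0 / f_bck;
        // which effort (if any) is active at the trigger instant
        cur_effort = -1;
        for (int k = 0; k < effort_onset.size(); ++k)
          if (effort_onset[k] <= t && t < effort_end[k]) { cur_effort = k; break; }
        onsets.push_back(t);
        causes.push_back(cause);
        effort_ids.push_back(cur_effort);
        insp_ends.push_back(NA_REAL);  // filled on cycling-off
      }
    }
    if (!insp && !insp_ends.empty() && NumericVector::is_na(insp_ends.back())
        && t_insp_end > t_onset)
      insp_ends.back() = t_insp_end;
  }
  if (!insp_ends.empty() && NumericVector::is_na(insp_ends.back()))
    insp_ends.back() = (n - 1) * dt;

  return List::create(_["paw"] = paw, _["qpat"] = qpat, _["vol"] = vol,
                      _["onset"] = wrap(onsets),
                      _["insp_end"] = wrap(insp_ends),
                      _["cause"] = wrap(causes),
                      _["effort_id"] = wrap(effort_ids));
}
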