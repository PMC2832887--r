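// Direct-method stochastic simulation of the coupled promoter / RNA /
// protein system. Reactions: promoter transitions taken from the
// generator M (column = source state), RNA birth at rate rho[s], RNA
// death at gamma*R, protein birth at beta*R, protein death at gamma_p*P.
// Uses R's RNG so set.seed() gives bitwise-reproducible trajectories.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".ssa_cpp")]]
List ssa_cpp(NumericMatrix M, NumericVector rho,
             double gamma, double beta, double gamma_p,
             double duration, double burn_in, double dt,
             bool record_events, bool promoter_only,
             int init_state, double init_R, double init_P,
             double max_events) {
  const int ns = M.nrow();

  // per-state promoter transition tables
  std::vector< std::vector<int> > targets(ns);
  std::vector< std::vector<double> > rates(ns);
  std::vector<double> prom_total(ns, 0.0);
  for (int s = 0; s < ns; ++s) {
    for (int sp = 0; sp < ns; ++sp) {
      if (sp == s) continue;
      double r = M(sp, s);
      if (r > 0) {
        targets[s].push_back(sp);
        rates[s].push_back(r);
        prom_total[s] += r;
      }
    }
  }

  int state = init_state;          // 0-based
  double R = init_R, P = init_P;
  double t = 0.0;

  std::vector<double> ev_t;
  std::vector<int> ev_state;
  std::vector<double> ev_R, ev_P;

  long n_samples = 0;
  if (dt > 0) n_samples = (long)std::floor((duration - burn_in) / dt) + 1;
  IntegerVector smp_state(dt > 0 ? n_samples : 0);
  NumericVector smp_R(dt > 0 ? n_samples : 0), smp_P(dt > 0 ? n_samples : 0);
  long next_sample = 0;

  double n_events = 0.0;
  RNGScope scope;

  while (t < duration) {
    double a_prom = prom_total[state];
    double a_rb = promoter_only ? 0.0 : rho[state];
    double a_rd = promoter_only ? 0.0 : gamma * R;
    double a_pb = promoter_only ? 0.0 : beta * R;
    double a_pd = promoter_only ? 0.0 : gamma_p * P;
    double a0 = a_prom + a_rb + a_rd + a_pb + a_pd;
    if (a0 > 1e12) stop("total propensity exceeds 1e12 /s");

    double tau = (a0 > 0) ? ::Rf_rexp(1.0 / a0) : R_PosInf;
    double t_new = t + tau;

    // emit samples strictly before the event (left-continuous values)
    if (dt > 0) {
      while (next_sample < n_samples &&
             burn_in + next_sample * dt < std::min(t_new, duration) + 1e-12) {
        smp_state[next_sample] = state;
        smp_R[next_sample] = R;
        smp_P[next_sample] = P;
        ++next_sample;
        if (next_sample % 1048576 == 0) Rcpp::checkUserInterrupt();
      }
    }
    if (!R_FINITE(t_new) || t_new >= duration) break;
    t = t_new;

    double u = ::unif_rand() * a0;
    if (u < a_prom) {
      double acc = 0.0;
      const std::vector<double>& rs = rates[state];
      const std::vector<int>& tg = targets[state];
      int chosen = tg.empty() ? state : tg.back();
      for (size_t k = 0; k < rs.size(); ++k) {
        acc += rs[k];
        if (u <= acc) { chosen = tg[k]; break; }
      }
      state = chosen;
    } else if (u < a_prom + a_rb) {
      R += 1;
    } else if (u < a_prom + a_rb + a_rd) {
      R -= 1;
    } else if (u < a_prom + a_rb + a_rd + a_pb) {
      P += 1;
    } else {
      P -= 1;
    }

    if (record_events && t >= burn_in) {
      ev_t.push_back(t);
      ev_state.push_back(state);
      ev_R.push_back(R);
      ev_P.push_back(P);
    }
    n_events += 1.0;
    if (n_events > max_events)
      stop("event budget exceeded (%.3g events); shorten the run or sample", max_events);
    if (((long)n_events) % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  // fill trailing samples (no further events up to duration)
  if (dt > 0) {
    while (next_sample < n_samples) {
      smp_state[next_sample] = state;
      smp_R[next_sample] = R;
      smp_P[next_sample] = P;
      ++next_sample;
    }
  }

  List out = List::create(
    _["n_events"] = n_events,
    _["final_state"] = state,
    _["final_R"] = R,
    _["final_P"] = P);
  if (dt > 0) {
    out["sample_state"] = smp_state;
    out["sample_R"] = smp_R;
    out["sample_P"] = smp_P;
  }
  if (record_events) {
    out["event_t"] = wrap(ev_t);
    out["event_state"] = wrap(ev_state);
    out["event_R"] = wrap(ev_R);
    out["event_P"] = wrap(ev_P);
  }
  return out;
}
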