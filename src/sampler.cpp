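// Metropolis-within-Gibbs sampler for uniform phase models of calendar ages.
//
// Parameter state: boundary ages b[0..B-1] (cal BP; ordered oldest -> youngest
// along the model's sequence chain), event ages t[0..n-1] (phase members are
// confined to their phase's boundary pair, bare sequence events to their chain
// neighbours), outlier indicators z, raw outlier shifts eps (t_5 for the
// General preset acting on the calendar scale, N(0,1) for SSimple acting on
// the measurement scale in units of sigma), a shared log10 outlier scale
// u ~ U(0,4), and per-event hemispheric curve-mixing fractions m ~ U(0,1).
//
// Joint log density:
//   sum_events loglik(x_i | t_i, z_i, eps_i, u, m_i)
//   + sum_phases span_exp_j * log(a_j - b_j)        [uniform-phase span prior]
//   + order indicators (window and chain ordering, a_j >= t_i >= b_j)
//   + outlier priors: z ~ Bern(q), eps ~ t_5 or N(0,1), u ~ U(0,4), m ~ U(0,1)
//
// All randomness comes from R's RNG (RNGScope), so set.seed() makes runs
// bit-identical on one platform.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct CurveTab {
  double theta0, step;
  NumericVector mu, sig;
  inline bool lookup(double tt, double &muv, double &sgv) const {
    double pos = (tt - theta0) / step;
    int i = (int)std::floor(pos);
    if (i < 0 || i >= mu.size() - 1) return false;
    double w = pos - i;
    muv = mu[i] * (1 - w) + mu[i + 1] * w;
    sgv = sig[i] * (1 - w) + sig[i + 1] * w;
    return true;
  }
};

struct PdfTab {
  bool present = false;
  double grid0, step;
  NumericVector dens;  // density = mass / step
  inline double logdens(double tt) const {
    double pos = (tt - grid0) / step;
    int i = (int)std::floor(pos);
    if (i < 0 || i >= dens.size() - 1) return NEG_INF;
    double w = pos - i;
    double d = dens[i] * (1 - w) + dens[i + 1] * w;
    return d > 0 ? std::log(d) : NEG_INF;
  }
};

class PhaseSampler {
public:
  // model
  int B, n, P, L;                               // L = chain length
  double win_lo, win_hi;
  std::vector<int> phase_start, phase_end;      // boundary index per phase
  std::vector<double> span_exp;
  std::vector<int> chain_type, chain_id;        // 0 = boundary, 1 = event
  std::vector<int> b_chain_pos, ev_chain_pos;   // -1 if not on the chain
  std::vector<int> ev_phase;                    // -1 for bare sequence events
  std::vector<int> lik_type, curve1, curve2, out_type;
  std::vector<double> x, sig, out_q;
  std::vector<CurveTab> curves;
  std::vector<PdfTab> pdfs;
  bool any_general = false;

  // state
  std::vector<double> b, t, eps, mfrac;
  std::vector<int> z;
  double u;

  // proposal scales and adaptation counters
  std::vector<double> sc_b, sc_t, sc_eps, sc_m;
  double sc_u;
  std::vector<int> acc_b, try_b, acc_t, try_t, acc_eps, try_eps, acc_m, try_m;
  int acc_u = 0, try_u = 0;

  inline double chain_age(int pos) const {
    return chain_type[pos] == 0 ? b[chain_id[pos]] : t[chain_id[pos]];
  }
  // [lo, hi] allowed by chain neighbours of the item at chain position pos
  inline void chain_window(int pos, double &lo, double &hi) const {
    lo = (pos + 1 < L) ? chain_age(pos + 1) : win_lo;
    hi = (pos > 0) ? chain_age(pos - 1) : win_hi;
  }

  double ev_loglik(int i, double ti, int zi, double epsi, double ui,
                   double mi) const {
    if (lik_type[i] == 0) return 0.0;
    if (lik_type[i] == 2) return pdfs[i].logdens(ti);
    double tt = ti, xe = x[i];
    if (zi) {
      if (out_type[i] == 1) tt += epsi * std::pow(10.0, ui);
      else if (out_type[i] == 2) xe -= epsi * sig[i];
    }
    double muv, sgv;
    if (curve2[i] > 0) {
      double mu1, sg1, mu2, sg2;
      if (!curves[curve1[i] - 1].lookup(tt, mu1, sg1)) return NEG_INF;
      if (!curves[curve2[i] - 1].lookup(tt, mu2, sg2)) return NEG_INF;
      muv = mi * mu1 + (1 - mi) * mu2;
      sgv = mi * sg1 + (1 - mi) * sg2;
    } else {
      if (!curves[curve1[i] - 1].lookup(tt, muv, sgv)) return NEG_INF;
    }
    double v = sig[i] * sig[i] + sgv * sgv;
    return -0.5 * (xe - muv) * (xe - muv) / v - 0.5 * std::log(v);
  }

  inline double cur_loglik(int i) const {
    return ev_loglik(i, t[i], z[i], eps[i], u, mfrac[i]);
  }

  void update_events() {
    for (int i = 0; i < n; ++i) {
      double lo, hi;
      if (ev_phase[i] >= 0) {
        lo = b[phase_end[ev_phase[i]]];
        hi = b[phase_start[ev_phase[i]]];
      } else {
        chain_window(ev_chain_pos[i], lo, hi);
      }
      lo = std::max(lo, win_lo); hi = std::min(hi, win_hi);
      double prop = t[i] + norm_rand() * sc_t[i];
      ++try_t[i];
      if (prop < lo || prop > hi) continue;
      double d = ev_loglik(i, prop, z[i], eps[i], u, mfrac[i]) - cur_loglik(i);
      if (d >= 0 || unif_rand() < std::exp(d)) { t[i] = prop; ++acc_t[i]; }
    }
  }

  double span_terms(int j, const std::vector<double> &bb) const {
    double s = 0;
    for (int p = 0; p < P; ++p) {
      if (phase_start[p] == j || phase_end[p] == j) {
        double span = bb[phase_start[p]] - bb[phase_end[p]];
        if (span <= 0) return NEG_INF;
        s += span_exp[p] * std::log(span);
      }
    }
    return s;
  }

  void update_bounds() {
    for (int j = 0; j < B; ++j) {
      double lo, hi;
      chain_window(b_chain_pos[j], lo, hi);
      lo = std::max(lo, win_lo); hi = std::min(hi, win_hi);
      for (int p = 0; p < P; ++p) {
        if (phase_start[p] == j)     // older boundary: must stay >= its events
          for (int i = 0; i < n; ++i)
            if (ev_phase[i] == p) lo = std::max(lo, t[i]);
        if (phase_end[p] == j)       // younger boundary: must stay <= its events
          for (int i = 0; i < n; ++i)
            if (ev_phase[i] == p) hi = std::min(hi, t[i]);
      }
      double prop = b[j] + norm_rand() * sc_b[j];
      ++try_b[j];
      if (prop < lo || prop > hi) continue;
      std::vector<double> bb = b; bb[j] = prop;
      double d = span_terms(j, bb) - span_terms(j, b);
      if (d >= 0 || unif_rand() < std::exp(d)) { b[j] = prop; ++acc_b[j]; }
    }
  }

  // SSimple: the measurement-scale shift is conjugate. Collapsed Gibbs on z
  // (the shift integrated out analytically), then an exact normal draw of
  // eps given z.
  void update_ssimple(int i) {
    double muv, sgv;
    bool ok;
    if (curve2[i] > 0) {
      double mu1, sg1, mu2, sg2;
      ok = curves[curve1[i] - 1].lookup(t[i], mu1, sg1) &&
           curves[curve2[i] - 1].lookup(t[i], mu2, sg2);
      muv = mfrac[i] * mu1 + (1 - mfrac[i]) * mu2;
      sgv = mfrac[i] * sg1 + (1 - mfrac[i]) * sg2;
    } else {
      ok = curves[curve1[i] - 1].lookup(t[i], muv, sgv);
    }
    if (!ok) { z[i] = 0; eps[i] = norm_rand(); return; }
    double v = sig[i] * sig[i] + sgv * sgv;
    double resid = x[i] - muv;
    // marginal likelihoods: z=0 -> N(resid; 0, sqrt(v));
    // z=1 -> shift integrated out: N(resid; 0, sqrt(v + sigma^2))
    double l0 = -0.5 * resid * resid / v - 0.5 * std::log(v);
    double v1 = v + sig[i] * sig[i];
    double l1 = -0.5 * resid * resid / v1 - 0.5 * std::log(v1);
    double lp1 = std::log(out_q[i]) + l1, lp0 = std::log(1 - out_q[i]) + l0;
    z[i] = (unif_rand() < 1.0 / (1.0 + std::exp(lp0 - lp1))) ? 1 : 0;
    if (z[i] == 0) { eps[i] = norm_rand(); return; }
    double tau = 1.0 + sig[i] * sig[i] / v;        // posterior precision
    double mean = (resid * sig[i] / v) / tau;
    eps[i] = mean + norm_rand() / std::sqrt(tau);
  }

  // General: Metropolized joint flip of (z, eps). A proposed activation
  // draws the calendar shift from a griddy data-informed density (prior x
  // likelihood on a grid spanning the window), so a grossly offset date can
  // activate in one move; deactivation draws eps from its prior.
  void flip_general(int i) {
    const int K = 48;
    double scale = std::pow(10.0, u);
    double lo = (win_lo - t[i]) / scale, hi = (win_hi - t[i]) / scale;
    if (hi <= lo) return;
    double step = (hi - lo) / K;
    double l0 = ev_loglik(i, t[i], 0, eps[i], u, mfrac[i]);
    if (z[i] == 0) {
      // build proposal q1 on the grid
      std::vector<double> lw(K);
      double lmax = NEG_INF;
      for (int k = 0; k < K; ++k) {
        double e = lo + (k + 0.5) * step;
        lw[k] = R::dt(e, 5.0, 1) + ev_loglik(i, t[i], 1, e, u, mfrac[i]);
        if (lw[k] > lmax) lmax = lw[k];
      }
      if (!std::isfinite(lmax)) return;
      double tot = 0;
      for (int k = 0; k < K; ++k) { lw[k] = std::exp(lw[k] - lmax); tot += lw[k]; }
      double pick = unif_rand() * tot, cum = 0; int kk = K - 1;
      for (int k = 0; k < K; ++k) { cum += lw[k]; if (pick <= cum) { kk = k; break; } }
      double eprop = lo + (kk + unif_rand()) * step;
      double lq1 = std::log(lw[kk] / tot / step);   // proposal log-density
      double l1 = ev_loglik(i, t[i], 1, eprop, u, mfrac[i]);
      // target ratio x proposal ratio (reverse move redraws eps from prior)
      double d = std::log(out_q[i]) + l1 + R::dt(eprop, 5.0, 1)
               - std::log(1 - out_q[i]) - l0 - lq1;
      if (d >= 0 || unif_rand() < std::exp(d)) { z[i] = 1; eps[i] = eprop; }
    } else {
      double lq1 = NEG_INF;
      {
        std::vector<double> lw(K);
        double lmax = NEG_INF;
        for (int k = 0; k < K; ++k) {
          double e = lo + (k + 0.5) * step;
          lw[k] = R::dt(e, 5.0, 1) + ev_loglik(i, t[i], 1, e, u, mfrac[i]);
          if (lw[k] > lmax) lmax = lw[k];
        }
        if (std::isfinite(lmax)) {
          double tot = 0;
          for (int k = 0; k < K; ++k) tot += std::exp(lw[k] - lmax);
          int kc = (int)((eps[i] - lo) / step);
          if (kc >= 0 && kc < K)
            lq1 = lw[kc] - lmax - std::log(tot) - std::log(step);
        }
      }
      double l1 = ev_loglik(i, t[i], 1, eps[i], u, mfrac[i]);
      double d = std::log(1 - out_q[i]) + l0 + lq1
               - std::log(out_q[i]) - l1 - R::dt(eps[i], 5.0, 1);
      if (d >= 0 || unif_rand() < std::exp(d)) {
        z[i] = 0; eps[i] = R::rt(5.0);
      }
    }
  }

  long iter_count = 0;

  void update_outliers() {
    for (int i = 0; i < n; ++i) {
      if (out_type[i] == 0) continue;
      if (out_type[i] == 2) { update_ssimple(i); continue; }
      // the griddy joint flip costs K likelihood evaluations, so cycle it;
      // the cheap moves below run every iteration
      if (iter_count % 5 == 0) flip_general(i);
      if (z[i] == 0) {
        // no likelihood term on the shift: refresh from the prior
        eps[i] = R::rt(5.0);
      } else {
        double prop = eps[i] + norm_rand() * sc_eps[i];
        ++try_eps[i];
        double lp_cur = cur_loglik(i);
        double lp_new = ev_loglik(i, t[i], 1, prop, u, mfrac[i]);
        double pr_cur, pr_new;
        if (out_type[i] == 1) {
          pr_cur = R::dt(eps[i], 5.0, 1); pr_new = R::dt(prop, 5.0, 1);
        } else {
          pr_cur = R::dnorm(eps[i], 0.0, 1.0, 1);
          pr_new = R::dnorm(prop, 0.0, 1.0, 1);
        }
        double d = (lp_new + pr_new) - (lp_cur + pr_cur);
        if (d >= 0 || unif_rand() < std::exp(d)) { eps[i] = prop; ++acc_eps[i]; }
        // likelihood-preserving swap between the event age and its shift
        // (General preset): repropose t_i uniform in its bounds and absorb
        // the move into eps so the effective age t + eps*10^u is unchanged.
        // Lets a contaminated date relocate into the phase bulk so the
        // boundaries can contract around the clean events.
        if (out_type[i] == 1 && ev_phase[i] >= 0) {
          double lo = b[phase_end[ev_phase[i]]], hi = b[phase_start[ev_phase[i]]];
          if (hi > lo) {
            double tprop = lo + unif_rand() * (hi - lo);
            double scale = std::pow(10.0, u);
            double eprop = eps[i] + (t[i] - tprop) / scale;
            double dsw = R::dt(eprop, 5.0, 1) - R::dt(eps[i], 5.0, 1);
            if (dsw >= 0 || unif_rand() < std::exp(dsw)) {
              t[i] = tprop; eps[i] = eprop;
            }
          }
        }
      }
    }
    if (any_general) {
      double prop = u + norm_rand() * sc_u;
      ++try_u;
      if (prop >= 0 && prop <= 4) {
        double d = 0;
        for (int i = 0; i < n; ++i)
          if (out_type[i] == 1 && z[i] == 1)
            d += ev_loglik(i, t[i], 1, eps[i], prop, mfrac[i]) - cur_loglik(i);
        if (d >= 0 || unif_rand() < std::exp(d)) { u = prop; ++acc_u; }
      }
    }
  }

  void update_mix() {
    for (int i = 0; i < n; ++i) {
      if (curve2[i] == 0) continue;
      double prop = mfrac[i] + norm_rand() * sc_m[i];
      ++try_m[i];
      if (prop < 0) prop = -prop;           // reflect at 0 and 1
      if (prop > 1) prop = 2 - prop;
      if (prop < 0 || prop > 1) continue;
      double d = ev_loglik(i, t[i], z[i], eps[i], u, prop) - cur_loglik(i);
      if (d >= 0 || unif_rand() < std::exp(d)) { mfrac[i] = prop; ++acc_m[i]; }
    }
  }

  void iterate() {
    update_events();
    update_bounds();
    update_outliers();
    update_mix();
    ++iter_count;
  }

  static void tune(std::vector<double> &sc, std::vector<int> &acc,
                   std::vector<int> &tr) {
    for (size_t k = 0; k < sc.size(); ++k) {
      if (tr[k] >= 20) {
        double r = (double)acc[k] / tr[k];
        if (r > 0.5) sc[k] *= 1.5; else if (r < 0.2) sc[k] /= 1.5;
      }
      acc[k] = 0; tr[k] = 0;
    }
  }

  void adapt_all() {
    tune(sc_t, acc_t, try_t);
    tune(sc_b, acc_b, try_b);
    tune(sc_eps, acc_eps, try_eps);
    tune(sc_m, acc_m, try_m);
    if (try_u >= 20) {
      double r = (double)acc_u / try_u;
      if (r > 0.5) sc_u *= 1.5; else if (r < 0.2) sc_u /= 1.5;
    }
    acc_u = 0; try_u = 0;
  }
};

// [[Rcpp::export]]
List cpp_phase_sampler(List model, List init, List scales,
                       int n_burn, int n_iter, int thin, bool adapt) {
  RNGScope scope;
  PhaseSampler s;

  NumericVector window = model["window"];
  s.win_lo = window[0]; s.win_hi = window[1];
  s.phase_start = as<std::vector<int>>(model["phase_start"]);
  s.phase_end = as<std::vector<int>>(model["phase_end"]);
  s.span_exp = as<std::vector<double>>(model["span_exp"]);
  s.P = s.phase_start.size();
  s.chain_type = as<std::vector<int>>(model["chain_type"]);
  s.chain_id = as<std::vector<int>>(model["chain_id"]);
  s.L = s.chain_type.size();
  s.b_chain_pos = as<std::vector<int>>(model["b_chain_pos"]);
  s.ev_chain_pos = as<std::vector<int>>(model["ev_chain_pos"]);
  s.ev_phase = as<std::vector<int>>(model["ev_phase"]);
  s.lik_type = as<std::vector<int>>(model["lik_type"]);
  s.curve1 = as<std::vector<int>>(model["curve1"]);
  s.curve2 = as<std::vector<int>>(model["curve2"]);
  s.out_type = as<std::vector<int>>(model["out_type"]);
  s.x = as<std::vector<double>>(model["x"]);
  s.sig = as<std::vector<double>>(model["sigma"]);
  s.out_q = as<std::vector<double>>(model["out_q"]);
  s.n = s.ev_phase.size();
  List cv = model["curves"];
  for (int k = 0; k < cv.size(); ++k) {
    List c = cv[k];
    CurveTab tab;
    tab.theta0 = as<double>(c["theta0"]);
    tab.step = as<double>(c["step"]);
    tab.mu = c["mu"]; tab.sig = c["sigma"];
    s.curves.push_back(tab);
  }
  List pd = model["pdfs"];
  for (int k = 0; k < pd.size(); ++k) {
    PdfTab tab;
    if (!Rf_isNull(pd[k])) {
      List p = pd[k];
      tab.present = true;
      tab.grid0 = as<double>(p["grid0"]);
      tab.step = as<double>(p["step"]);
      tab.dens = p["dens"];
    }
    s.pdfs.push_back(tab);
  }
  for (int i = 0; i < s.n; ++i)
    if (s.out_type[i] == 1) s.any_general = true;

  s.b = as<std::vector<double>>(init["bounds"]);
  s.t = as<std::vector<double>>(init["t"]);
  s.z = as<std::vector<int>>(init["z"]);
  s.eps = as<std::vector<double>>(init["eps"]);
  s.u = as<double>(init["u"]);
  s.mfrac = as<std::vector<double>>(init["m"]);
  s.B = s.b.size();

  s.sc_b = as<std::vector<double>>(scales["bounds"]);
  s.sc_t = as<std::vector<double>>(scales["t"]);
  s.sc_eps = as<std::vector<double>>(scales["eps"]);
  s.sc_m = as<std::vector<double>>(scales["m"]);
  s.sc_u = as<double>(scales["u"]);
  s.acc_b.assign(s.B, 0); s.try_b.assign(s.B, 0);
  s.acc_t.assign(s.n, 0); s.try_t.assign(s.n, 0);
  s.acc_eps.assign(s.n, 0); s.try_eps.assign(s.n, 0);
  s.acc_m.assign(s.n, 0); s.try_m.assign(s.n, 0);

  const int adapt_every = 200;
  for (int it = 0; it < n_burn; ++it) {
    s.iterate();
    if (adapt && (it + 1) % adapt_every == 0) s.adapt_all();
  }
  // reset counters so reported acceptance reflects the retained run
  s.acc_b.assign(s.B, 0); s.try_b.assign(s.B, 0);
  s.acc_t.assign(s.n, 0); s.try_t.assign(s.n, 0);
  s.acc_eps.assign(s.n, 0); s.try_eps.assign(s.n, 0);
  s.acc_m.assign(s.n, 0); s.try_m.assign(s.n, 0);
  s.acc_u = 0; s.try_u = 0;

  int n_keep = n_iter / thin;
  NumericMatrix out_b(n_keep, s.B), out_t(n_keep, s.n),
    out_dates(n_keep, s.P), out_m(n_keep, s.n);
  IntegerMatrix out_z(n_keep, s.n);
  NumericVector out_u(n_keep);
  int row = 0;
  for (int it = 0; it < n_iter; ++it) {
    s.iterate();
    if ((it + 1) % thin == 0 && row < n_keep) {
      for (int j = 0; j < s.B; ++j) out_b(row, j) = s.b[j];
      for (int i = 0; i < s.n; ++i) {
        out_t(row, i) = s.t[i];
        out_z(row, i) = s.z[i];
        out_m(row, i) = s.mfrac[i];
      }
      for (int p = 0; p < s.P; ++p) {
        double lo = s.b[s.phase_end[p]], hi = s.b[s.phase_start[p]];
        out_dates(row, p) = lo + unif_rand() * (hi - lo);
      }
      out_u[row] = s.u;
      ++row;
    }
  }

  double acc_t_rate = 0, acc_b_rate = 0;
  int nt = 0, nb = 0;
  for (int i = 0; i < s.n; ++i)
    if (s.try_t[i] > 0) { acc_t_rate += (double)s.acc_t[i] / s.try_t[i]; ++nt; }
  for (int j = 0; j < s.B; ++j)
    if (s.try_b[j] > 0) { acc_b_rate += (double)s.acc_b[j] / s.try_b[j]; ++nb; }

  return List::create(
    _["bounds"] = out_b, _["t"] = out_t, _["z"] = out_z, _["u"] = out_u,
    _["m"] = out_m, _["dates"] = out_dates,
    _["state"] = List::create(
      _["bounds"] = NumericVector(s.b.begin(), s.b.end()),
      _["t"] = NumericVector(s.t.begin(), s.t.end()),
      _["z"] = IntegerVector(s.z.begin(), s.z.end()),
      _["eps"] = NumericVector(s.eps.begin(), s.eps.end()),
      _["u"] = s.u,
      _["m"] = NumericVector(s.mfrac.begin(), s.mfrac.end())),
    _["scales"] = List::create(
      _["bounds"] = NumericVector(s.sc_b.begin(), s.sc_b.end()),
      _["t"] = NumericVector(s.sc_t.begin(), s.sc_t.end()),
      _["eps"] = NumericVector(s.sc_eps.begin(), s.sc_eps.end()),
      _["m"] = NumericVector(s.sc_m.begin(), s.sc_m.end()),
      _["u"] = s.sc_u),
    _["accept"] = List::create(
      _["events"] = nt > 0 ? acc_t_rate / nt : NA_REAL,
      _["bounds"] = nb > 0 ? acc_b_rate / nb : NA_REAL));
}
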