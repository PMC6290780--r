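#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step RK4 integration of time-delayed S-system (TDSS) dynamics.
//
// Two entry points:
//   sim_gene_cpp    - decoupled single-gene integration against observed
//                     regulator trajectories (fitness evaluation path)
//   sim_network_cpp - full-network method-of-steps integration (data
//                     generation path)
//   sse_batch_cpp   - SSE of a batch of decoded equations over replicates
//
// Delays are integer multiples of the sampling interval dt. History lookups
// into the running fine-grid solution use cubic Hermite interpolation (node
// values + node derivatives) so the delayed lookups do not degrade RK4's
// fourth-order accuracy; lookups into *observed* coarse data use linear
// interpolation, matching the package's delayed_value() contract.

// linear interpolation on the uniform coarse grid; constant history before t0
static inline double coarse_lookup(const NumericMatrix& vals, int j, double tq,
                                   double t0, double dt, int T) {
  double s = (tq - t0) / dt;
  if (s <= 0.0) return vals(j, 0);
  if (s >= T - 1) return vals(j, T - 1);
  int k = (int)std::floor(s);
  if (k >= T - 1) k = T - 2;
  double w = s - k;
  return (1.0 - w) * vals(j, k) + w * vals(j, k + 1);
}

// cubic Hermite interpolation on the fine grid using stored derivatives
static inline double fine_lookup(const std::vector<double>& x,
                                 const std::vector<double>& d,
                                 double tq, double t0, double hf, int filled) {
  double s = (tq - t0) / hf;
  if (s <= 0.0) return x[0];
  int k = (int)std::floor(s);
  if (k >= filled) return x[filled];
  double w = s - k;
  if (w == 0.0) return x[k];
  if (k + 1 > filled) return x[filled];
  double h00 = (1 + 2 * w) * (1 - w) * (1 - w);
  double h10 = w * (1 - w) * (1 - w);
  double h01 = w * w * (3 - 2 * w);
  double h11 = w * w * (w - 1);
  return h00 * x[k] + h10 * hf * d[k] + h01 * x[k + 1] + h11 * hf * d[k + 1];
}

struct Term {
  double rate, cst;
  std::vector<int> j;
  std::vector<double> g;
  std::vector<int> tau;
};

static Term unpack_term(double rate, double cst, const NumericMatrix& f) {
  Term t;
  t.rate = rate;
  t.cst = cst;
  int m = f.nrow();
  t.j.resize(m); t.g.resize(m); t.tau.resize(m);
  for (int r = 0; r < m; ++r) {
    t.j[r] = (int)f(r, 0);       // 0-based gene index
    t.g[r] = f(r, 1);
    t.tau[r] = (int)f(r, 2);
  }
  return t;
}

// --- decoupled single-gene integration -------------------------------------

struct GeneSim {
  const NumericMatrix& obs;
  int target, T;
  double t0, dt, hf, eps;
  const Term &prod, &cons;
  std::vector<double> fine, fined;

  GeneSim(const NumericMatrix& obs_, int target_, double t0_, double dt_,
          double hf_, double eps_, const Term& p, const Term& c, int nfine)
    : obs(obs_), target(target_), T(obs_.ncol()), t0(t0_), dt(dt_), hf(hf_),
      eps(eps_), prod(p), cons(c), fine(nfine + 1), fined(nfine + 1, 0.0) {}

  double term_val(const Term& tm, double t, double xi, int filled) const {
    double v = tm.rate * tm.cst;
    for (size_t r = 0; r < tm.j.size(); ++r) {
      double xv;
      if (tm.j[r] == target) {
        xv = (tm.tau[r] == 0) ? xi
             : fine_lookup(fine, fined, t - tm.tau[r] * dt, t0, hf, filled);
      } else {
        xv = coarse_lookup(obs, tm.j[r], t - tm.tau[r] * dt, t0, dt, T);
      }
      if (xv < eps) xv = eps;
      v *= std::pow(xv, tm.g[r]);
    }
    return v;
  }

  double deriv(double t, double xi, int filled) const {
    return term_val(prod, t, xi, filled) - term_val(cons, t, xi, filled);
  }
};

// returns false on numerical blow-up
static bool sim_gene_core(const NumericVector& times, const NumericMatrix& obs,
                          int target, const Term& prod, const Term& cons,
                          int substeps, double eps, NumericVector& pred) {
  int T = times.size();
  double t0 = times[0], dt = times[1] - times[0];
  double hf = dt / substeps;
  int nfine = (T - 1) * substeps;
  GeneSim gs(obs, target, t0, dt, hf, eps, prod, cons, nfine);
  double x = obs(target, 0);
  gs.fine[0] = x;
  gs.fined[0] = gs.deriv(t0, x, 0);
  for (int s = 0; s < nfine; ++s) {
    double t = t0 + s * hf;
    double k1 = gs.fined[s];  // derivative at node, already computed
    double k2 = gs.deriv(t + hf / 2, x + hf / 2 * k1, s);
    double k3 = gs.deriv(t + hf / 2, x + hf / 2 * k2, s);
    double k4 = gs.deriv(t + hf, x + hf * k3, s);
    x += hf / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    if (!std::isfinite(x)) return false;
    if (x < eps) x = eps;
    gs.fine[s + 1] = x;
    gs.fined[s + 1] = gs.deriv(t + hf, x, s + 1);
    if (!std::isfinite(gs.fined[s + 1])) return false;
  }
  for (int k = 0; k < T; ++k) pred[k] = gs.fine[k * substeps];
  return true;
}

// [[Rcpp::export]]
NumericVector sim_gene_cpp(NumericVector times, NumericMatrix obs, int target,
                           double prod_rate, double prod_cst, NumericMatrix prod_f,
                           double cons_rate, double cons_cst, NumericMatrix cons_f,
                           int substeps, double eps) {
  Term p = unpack_term(prod_rate, prod_cst, prod_f);
  Term c = unpack_term(cons_rate, cons_cst, cons_f);
  NumericVector pred(times.size());
  bool ok = sim_gene_core(times, obs, target, p, c, substeps, eps, pred);
  pred.attr("valid") = ok;
  if (!ok) std::fill(pred.begin(), pred.end(), NA_REAL);
  return pred;
}

// Batch SSE evaluation for a whole population against several replicates.
//
// The regulator values entering a decoupled integration are independent of
// the candidate equation: for every replicate we tabulate, once, the
// log-levels of every gene at every RK4 stage time (half-substep grid) for
// every admissible delay. A term evaluation then reduces to one exp() of a
// dot product instead of one pow() per factor, which dominates the cost of
// an evolutionary run.
struct StageTable {
  // logs[j][tau] is a vector over the half-substep grid 0..2*nfine
  std::vector< std::vector< std::vector<double> > > logs;
  int nhalf;
};

static StageTable build_stage_table(const NumericVector& times,
                                    const NumericMatrix& obs,
                                    int substeps, int tau_max, double eps) {
  int N = obs.nrow(), T = times.size();
  double t0 = times[0], dt = times[1] - times[0];
  double hh = dt / substeps / 2.0;                 // half-substep
  int nhalf = (T - 1) * substeps * 2;
  StageTable st;
  st.nhalf = nhalf;
  st.logs.assign(N, std::vector< std::vector<double> >(tau_max + 1));
  for (int j = 0; j < N; ++j)
    for (int tau = 0; tau <= tau_max; ++tau) {
      std::vector<double>& v = st.logs[j][tau];
      v.resize(nhalf + 1);
      for (int s = 0; s <= nhalf; ++s) {
        double x = coarse_lookup(obs, j, t0 + s * hh - tau * dt, t0, dt, T);
        v[s] = std::log(x < eps ? eps : x);
      }
    }
  return st;
}

struct FastGeneSim {
  const StageTable& st;
  int target;
  double t0, dt, hf, eps;
  const Term &prod, &cons;
  std::vector<double> fine, fined;

  FastGeneSim(const StageTable& st_, int target_, double t0_, double dt_,
              double hf_, double eps_, const Term& p, const Term& c, int nfine)
    : st(st_), target(target_), t0(t0_), dt(dt_), hf(hf_), eps(eps_),
      prod(p), cons(c), fine(nfine + 1), fined(nfine + 1, 0.0) {}

  // sidx indexes the half-substep grid; xi is the stage state of the target
  double term_val(const Term& tm, int sidx, double t, double xi,
                  int filled) const {
    double lg = 0.0;
    for (size_t r = 0; r < tm.j.size(); ++r) {
      double lx;
      if (tm.j[r] == target) {
        double xv = (tm.tau[r] == 0) ? xi
          : fine_lookup(fine, fined, t - tm.tau[r] * dt, t0, hf, filled);
        lx = std::log(xv < eps ? eps : xv);
      } else {
        lx = st.logs[tm.j[r]][tm.tau[r]][sidx];
      }
      lg += tm.g[r] * lx;
    }
    return tm.rate * tm.cst * std::exp(lg);
  }

  double deriv(int sidx, double t, double xi, int filled) const {
    return term_val(prod, sidx, t, xi, filled) -
           term_val(cons, sidx, t, xi, filled);
  }
};

// [[Rcpp::export]]
NumericVector sse_batch_cpp(List eqs, List times_list, List vals_list,
                            int target, int substeps, double eps) {
  int n = eqs.size(), R = times_list.size();
  NumericVector out(n);

  // largest delay referenced by any equation
  int tau_max = 0;
  std::vector<Term> prods(n), conss(n);
  for (int i = 0; i < n; ++i) {
    List eq = eqs[i];
    prods[i] = unpack_term(as<double>(eq["prod_rate"]),
                           as<double>(eq["prod_cst"]),
                           as<NumericMatrix>(eq["prod_f"]));
    conss[i] = unpack_term(as<double>(eq["cons_rate"]),
                           as<double>(eq["cons_cst"]),
                           as<NumericMatrix>(eq["cons_f"]));
    for (int v : prods[i].tau) tau_max = std::max(tau_max, v);
    for (int v : conss[i].tau) tau_max = std::max(tau_max, v);
  }

  std::vector<StageTable> tabs;
  tabs.reserve(R);
  for (int r = 0; r < R; ++r)
    tabs.push_back(build_stage_table(times_list[r], vals_list[r],
                                     substeps, tau_max, eps));

  for (int i = 0; i < n; ++i) {
    double sse = 0.0;
    bool ok = true;
    for (int r = 0; r < R && ok; ++r) {
      NumericVector times = times_list[r];
      NumericMatrix obs = vals_list[r];
      int T = times.size();
      double t0 = times[0], dt = times[1] - times[0];
      double hf = dt / substeps;
      int nfine = (T - 1) * substeps;
      FastGeneSim gs(tabs[r], target, t0, dt, hf, eps, prods[i], conss[i],
                     nfine);
      double x = obs(target, 0);
      gs.fine[0] = x;
      gs.fined[0] = gs.deriv(0, t0, x, 0);
      for (int s = 0; s < nfine && ok; ++s) {
        double t = t0 + s * hf;
        double k1 = gs.fined[s];
        double k2 = gs.deriv(2 * s + 1, t + hf / 2, x + hf / 2 * k1, s);
        double k3 = gs.deriv(2 * s + 1, t + hf / 2, x + hf / 2 * k2, s);
        double k4 = gs.deriv(2 * s + 2, t + hf, x + hf * k3, s);
        x += hf / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
        if (!std::isfinite(x)) { ok = false; break; }
        if (x < eps) x = eps;
        gs.fine[s + 1] = x;
        gs.fined[s + 1] = gs.deriv(2 * (s + 1), t + hf, x, s + 1);
        if (!std::isfinite(gs.fined[s + 1])) { ok = false; break; }
      }
      if (!ok) break;
      for (int k = 0; k < T; ++k) {
        double e = gs.fine[k * substeps] - obs(target, k);
        sse += e * e;
      }
      if (!std::isfinite(sse)) { ok = false; break; }
    }
    out[i] = ok ? sse : -1.0;
  }
  return out;
}

// --- full-network method-of-steps integration ------------------------------

// [[Rcpp::export]]
NumericMatrix sim_network_cpp(NumericVector times, NumericVector x0,
                              List prod_terms, List cons_terms,
                              int substeps, double eps) {
  int N = x0.size(), T = times.size();
  double t0 = times[0], dt = times[1] - times[0];
  double hf = dt / substeps;
  int nfine = (T - 1) * substeps;

  std::vector<Term> prod(N), cons(N);
  for (int i = 0; i < N; ++i) {
    List p = prod_terms[i], c = cons_terms[i];
    prod[i] = unpack_term(as<double>(p["rate"]), as<double>(p["cst"]),
                          as<NumericMatrix>(p["factors"]));
    cons[i] = unpack_term(as<double>(c["rate"]), as<double>(c["cst"]),
                          as<NumericMatrix>(c["factors"]));
  }

  // fine history: values and derivatives per gene
  std::vector< std::vector<double> > X(N, std::vector<double>(nfine + 1)),
                                     D(N, std::vector<double>(nfine + 1, 0.0));
  for (int i = 0; i < N; ++i) X[i][0] = x0[i];

  // derivative of gene i given stage state xs at time t; history filled to node `filled`
  auto term_val = [&](const Term& tm, double t, const std::vector<double>& xs,
                      int filled) {
    double v = tm.rate * tm.cst;
    for (size_t r = 0; r < tm.j.size(); ++r) {
      double xv = (tm.tau[r] == 0)
        ? xs[tm.j[r]]
        : fine_lookup(X[tm.j[r]], D[tm.j[r]], t - tm.tau[r] * dt, t0, hf, filled);
      if (xv < eps) xv = eps;
      v *= std::pow(xv, tm.g[r]);
    }
    return v;
  };
  auto deriv = [&](double t, const std::vector<double>& xs, int filled,
                   std::vector<double>& dx) {
    for (int i = 0; i < N; ++i)
      dx[i] = term_val(prod[i], t, xs, filled) - term_val(cons[i], t, xs, filled);
  };

  std::vector<double> x(N), xs(N), k1(N), k2(N), k3(N), k4(N);
  for (int i = 0; i < N; ++i) x[i] = x0[i];
  deriv(t0, x, 0, k1);
  for (int i = 0; i < N; ++i) D[i][0] = k1[i];

  for (int s = 0; s < nfine; ++s) {
    double t = t0 + s * hf;
    for (int i = 0; i < N; ++i) k1[i] = D[i][s];
    for (int i = 0; i < N; ++i) xs[i] = x[i] + hf / 2 * k1[i];
    deriv(t + hf / 2, xs, s, k2);
    for (int i = 0; i < N; ++i) xs[i] = x[i] + hf / 2 * k2[i];
    deriv(t + hf / 2, xs, s, k3);
    for (int i = 0; i < N; ++i) xs[i] = x[i] + hf * k3[i];
    deriv(t + hf, xs, s, k4);
    for (int i = 0; i < N; ++i) {
      x[i] += hf / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      if (!std::isfinite(x[i]))
        stop("simulation blow-up at t = %f (gene %d)", t + hf, i + 1);
      if (x[i] < eps) x[i] = eps;
      X[i][s + 1] = x[i];
    }
    deriv(t + hf, x, s + 1, k1);
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(k1[i]))
        stop("simulation blow-up at t = %f (gene %d)", t + hf, i + 1);
      D[i][s + 1] = k1[i];
    }
  }

  NumericMatrix out(N, T);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < T; ++k) out(i, k) = X[i][k * substeps];
  return out;
}
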