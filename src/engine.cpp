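// Compiled core for signed-circuit dynamics.
//
// State x is the vector of active protein amounts, one per node, constrained
// to the box [0, T] by the structure of the vector field (capacity factors
// (T - x) on activation, -x factors on inhibition/decay), never by clipping.
//
// Rate law per edge: activation  +k * (T_tgt - x_tgt) * phi(a)
//                    inhibition  -k * x_tgt * phi(a)
// with phi(a) = a^n / (a^n + j^n)  (or a^n / (a^n + j) when denom_jn = false).
// An edge with source index 0 reads the constant stimulation level s instead
// of a node activity.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Circuit {
  int n;                        // nodes
  std::vector<double> d, total, basal;
  int ne;                       // edges
  std::vector<int> esrc, etgt, esign, en;
  std::vector<double> ek, ej;
  double s;
  bool denom_jn;
};

static Circuit unpack(const List& enc) {
  Circuit c;
  NumericVector d = enc["d"], total = enc["total"], basal = enc["basal"];
  IntegerVector esrc = enc["esrc"], etgt = enc["etgt"], esign = enc["esign"], en = enc["en"];
  NumericVector ek = enc["ek"], ej = enc["ej"];
  c.n = d.size();
  c.d.assign(d.begin(), d.end());
  c.total.assign(total.begin(), total.end());
  c.basal.assign(basal.begin(), basal.end());
  c.ne = esrc.size();
  c.esrc.assign(esrc.begin(), esrc.end());
  c.etgt.assign(etgt.begin(), etgt.end());
  c.esign.assign(esign.begin(), esign.end());
  c.en.assign(en.begin(), en.end());
  c.ek.assign(ek.begin(), ek.end());
  c.ej.assign(ej.begin(), ej.end());
  c.s = as<double>(enc["s"]);
  c.denom_jn = as<bool>(enc["denom_jn"]);
  return c;
}

static inline double ipow(double a, int n) {
  double r = a;
  for (int i = 1; i < n; ++i) r *= a;
  return r;
}

static inline double phi(double a, double j, int n, bool denom_jn) {
  if (a <= 0.0) return 0.0;
  double an = ipow(a, n);
  double den = an + (denom_jn ? ipow(j, n) : j);
  return an / den;
}

static void rhs(const Circuit& c, const double* x, double* f) {
  for (int i = 0; i < c.n; ++i)
    f[i] = c.basal[i] * (c.total[i] - x[i]) - c.d[i] * x[i];
  for (int e = 0; e < c.ne; ++e) {
    int tgt = c.etgt[e] - 1;
    double a = (c.esrc[e] == 0) ? c.s : x[c.esrc[e] - 1];
    double p = phi(a, c.ej[e], c.en[e], c.denom_jn);
    if (c.esign[e] > 0)
      f[tgt] += c.ek[e] * (c.total[tgt] - x[tgt]) * p;
    else
      f[tgt] -= c.ek[e] * x[tgt] * p;
  }
}

// Cash-Karp 4(5) embedded Runge-Kutta with adaptive step.
// Returns true if steady (max|f| < tol) was reached before tmax.
static bool integrate_ss(const Circuit& c, std::vector<double>& x,
                         double tmax, double tol, double& t_out, double& resid_out,
                         double atol = 1e-9, double rtol = 1e-6) {
  const int n = c.n;
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
                      b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                      c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                      dc6 = c6 - 1.0 / 4.0;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), xt(n), xe(n), xn(n);
  double t = 0.0, h = 0.01;
  const double hmin = 1e-9, hmax = tmax / 2.0;
  bool steady = false;
  double resid = R_PosInf;

  rhs(c, x.data(), k1.data());
  for (long iter = 0; iter < 10000000L; ++iter) {
    resid = 0.0;
    for (int i = 0; i < n; ++i) resid = std::max(resid, std::fabs(k1[i]));
    if (resid < tol) { steady = true; break; }
    if (t >= tmax) break;
    if (h > tmax - t) h = tmax - t;

    // stages
    for (int i = 0; i < n; ++i) xt[i] = x[i] + h * b21 * k1[i];
    rhs(c, xt.data(), k2.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + h * (b31 * k1[i] + b32 * k2[i]);
    rhs(c, xt.data(), k3.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    rhs(c, xt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    rhs(c, xt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] + b64 * k4[i] + b65 * k5[i]);
    rhs(c, xt.data(), k6.data());

    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      xn[i] = x[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      double err = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] + dc6 * k6[i]);
      double scale = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
      errmax = std::max(errmax, std::fabs(err) / scale);
    }
    if (errmax <= 1.0) {
      t += h;
      x = xn;
      rhs(c, x.data(), k1.data());
      double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      if (h < hmin) break;  // cannot make progress
    }
  }
  t_out = t;
  resid_out = resid;
  return steady;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(List enc, NumericVector x) {
  Circuit c = unpack(enc);
  if ((int)x.size() != c.n) stop("state length does not match node count");
  NumericVector f(c.n);
  rhs(c, REAL(x), REAL(f));
  return f;
}

// [[Rcpp::export]]
List cpp_steady_state(List enc, NumericVector x0, double tmax, double tol) {
  Circuit c = unpack(enc);
  if ((int)x0.size() != c.n) stop("x0 length does not match node count");
  std::vector<double> x(x0.begin(), x0.end());
  double t = 0, resid = 0;
  bool ok = integrate_ss(c, x, tmax, tol, t, resid);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["t"] = t, _["converged"] = ok, _["resid"] = resid);
}

// Dose response: scan the dose node's total over `grid`; start each dose from
// the all-inactive state (or carry the previous steady state forward when
// continuation = true).
// [[Rcpp::export]]
List cpp_dose_response(List enc, int dose_idx, NumericVector grid, int readout_idx,
                       double tmax, double tol, bool continuation) {
  Circuit c = unpack(enc);
  int ng = grid.size();
  NumericVector readout(ng);
  LogicalVector conv(ng);
  NumericMatrix states(ng, c.n);
  std::vector<double> x(c.n, 0.0), prev(c.n, 0.0);
  for (int g = 0; g < ng; ++g) {
    c.total[dose_idx - 1] = grid[g];
    if (continuation && g > 0) {
      for (int i = 0; i < c.n; ++i) x[i] = std::min(prev[i], c.total[i]);
    } else {
      std::fill(x.begin(), x.end(), 0.0);
    }
    double t = 0, resid = 0;
    bool ok = integrate_ss(c, x, tmax, tol, t, resid);
    conv[g] = ok;
    readout[g] = x[readout_idx - 1];
    for (int i = 0; i < c.n; ++i) states(g, i) = x[i];
    prev = x;
  }
  return List::create(_["readout"] = readout, _["converged"] = conv,
                      _["states"] = states);
}

// Batch biphasic/emergent screen. `samples` has one row per parameter set,
// columns: k[1..E], j[1..E], n[1..E], d[1..N], s. Totals are `totals` except
// the dose node, scanned over `grid`. Readout is normalized by `readout_total`
// for the emergence slope (window of `wsteps` grid steps).
// Returns columns: peak, end, bd_value, ed_value, n_nonconverged.
// [[Rcpp::export]]
NumericMatrix cpp_screen_be(int n_nodes, IntegerVector esrc, IntegerVector etgt,
                            IntegerVector esign, NumericVector totals,
                            NumericVector basal, NumericMatrix samples,
                            int dose_idx, int readout_idx, NumericVector grid,
                            double readout_total, int wsteps,
                            double tmax, double tol, bool denom_jn) {
  Circuit c;
  c.n = n_nodes;
  c.ne = esrc.size();
  c.esrc.assign(esrc.begin(), esrc.end());
  c.etgt.assign(etgt.begin(), etgt.end());
  c.esign.assign(esign.begin(), esign.end());
  c.total.assign(totals.begin(), totals.end());
  c.basal.assign(basal.begin(), basal.end());
  c.denom_jn = denom_jn;
  c.ek.resize(c.ne); c.ej.resize(c.ne); c.en.resize(c.ne);
  c.d.resize(c.n);

  int ns = samples.nrow(), ng = grid.size();
  int E = c.ne, N = c.n;
  if (samples.ncol() != 3 * E + N + 1) stop("sample matrix has wrong width");
  NumericMatrix out(ns, 5);
  colnames(out) = CharacterVector::create("peak", "end", "bd", "ed", "nonconv");
  std::vector<double> x(N), resp(ng);

  for (int r = 0; r < ns; ++r) {
    for (int e = 0; e < E; ++e) {
      c.ek[e] = samples(r, e);
      c.ej[e] = samples(r, E + e);
      c.en[e] = (int)samples(r, 2 * E + e);
    }
    for (int i = 0; i < N; ++i) c.d[i] = samples(r, 3 * E + i);
    c.s = samples(r, 3 * E + N);
    int nonconv = 0;
    for (int g = 0; g < ng; ++g) {
      c.total[dose_idx - 1] = grid[g];
      std::fill(x.begin(), x.end(), 0.0);
      double t = 0, resid = 0;
      if (!integrate_ss(c, x, tmax, tol, t, resid)) nonconv++;
      resp[g] = x[readout_idx - 1];
    }
    double peak = 0.0;
    for (int g = 0; g < ng; ++g) peak = std::max(peak, resp[g]);
    double endv = resp[ng - 1];
    double bd = (peak > 0) ? (peak - endv) / peak : 0.0;
    double ed = 0.0;
    for (int g = 0; g + wsteps < ng; ++g) {
      double slope = ((resp[g + wsteps] - resp[g]) / readout_total) /
                     (grid[g + wsteps] - grid[g]);
      ed = std::max(ed, slope);
    }
    out(r, 0) = peak; out(r, 1) = endv; out(r, 2) = bd; out(r, 3) = ed;
    out(r, 4) = nonconv;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Euler-Maruyama path with reflecting boundaries at 0 and T.
// Noise increment per component: sqrt(2*sigma*dt) * N(0,1), optionally scaled
// by the current level x (multiplicative mode). Records every `stride` steps
// (including the initial state).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_langevin(List enc, NumericVector x0, double dt,
                                    int nsteps, double sigma, bool multiplicative,
                                    int stride) {
  Circuit c = unpack(enc);
  int n = c.n;
  if ((int)x0.size() != n) stop("x0 length does not match node count");
  int nrec = nsteps / stride + 1;
  NumericMatrix out(nrec, n);
  std::vector<double> x(x0.begin(), x0.end()), f(n);
  double amp = std::sqrt(2.0 * sigma * dt);
  RNGScope scope;
  int rec = 0;
  for (int i = 0; i < n; ++i) out(rec, i) = x[i];
  rec++;
  for (int step = 1; step <= nsteps; ++step) {
    rhs(c, x.data(), f.data());
    for (int i = 0; i < n; ++i) {
      double noise = amp * norm_rand();
      if (multiplicative) noise *= x[i];
      double dx = f[i] * dt + noise;
      if (std::fabs(dx) > 0.5)
        stop("unstable step (|dx| > 0.5); reduce dt or sigma");
      double xi = x[i] + dx;
      double T = c.total[i];
      // reflect into [0, T]
      for (int guard = 0; guard < 100 && (xi < 0.0 || xi > T); ++guard)
        xi = (xi < 0.0) ? -xi : 2.0 * T - xi;
      if (xi < 0.0) xi = 0.0;
      if (xi > T) xi = T;
      x[i] = xi;
    }
    if (step % stride == 0 && rec < nrec) {
      for (int i = 0; i < n; ++i) out(rec, i) = x[i];
      rec++;
    }
    if (step % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Accumulate post-burn-in occupancy of many Langevin runs on a 2-D lattice.
// Axis values are sums of node activities over the given (1-based) index sets.
// [[Rcpp::export]]
List cpp_accumulate_landscape(List enc, int n_init, double dt, double t_max,
                              double burn_in, int stride, double sigma,
                              bool multiplicative, IntegerVector ax1,
                              IntegerVector ax2, int nb1, int nb2,
                              double ax1max, double ax2max) {
  Circuit c = unpack(enc);
  int n = c.n;
  int nsteps = (int)std::ceil(t_max / dt);
  int burn_steps = (int)std::ceil(burn_in / dt);
  NumericMatrix counts(nb1, nb2);
  std::vector<double> x(n), f(n);
  double amp = std::sqrt(2.0 * sigma * dt);
  double total_pts = 0.0;
  RNGScope scope;
  for (int run = 0; run < n_init; ++run) {
    for (int i = 0; i < n; ++i) x[i] = unif_rand() * c.total[i];
    for (int step = 0; step < nsteps; ++step) {
      rhs(c, x.data(), f.data());
      for (int i = 0; i < n; ++i) {
        double noise = amp * norm_rand();
        if (multiplicative) noise *= x[i];
        double xi = x[i] + f[i] * dt + noise;
        double T = c.total[i];
        for (int guard = 0; guard < 100 && (xi < 0.0 || xi > T); ++guard)
          xi = (xi < 0.0) ? -xi : 2.0 * T - xi;
        if (xi < 0.0) xi = 0.0;
        if (xi > T) xi = T;
        x[i] = xi;
      }
      if (step >= burn_steps && (step - burn_steps) % stride == 0) {
        double v1 = 0, v2 = 0;
        for (int k = 0; k < ax1.size(); ++k) v1 += x[ax1[k] - 1];
        for (int k = 0; k < ax2.size(); ++k) v2 += x[ax2[k] - 1];
        int b1 = (int)(v1 / ax1max * nb1); if (b1 >= nb1) b1 = nb1 - 1; if (b1 < 0) b1 = 0;
        int b2 = (int)(v2 / ax2max * nb2); if (b2 >= nb2) b2 = nb2 - 1; if (b2 < 0) b2 = 0;
        counts(b1, b2) += 1.0;
        total_pts += 1.0;
      }
    }
    if (run % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["total"] = total_pts);
}

// Count distinct attractors per dose by multistart steady-state search,
// entirely in compiled code. Starts are uniform in the state box (R RNG);
// converged endpoints are clustered greedily in max-norm. With early_stop,
// scanning ends at the first dose showing >= 2 clusters.
// [[Rcpp::export]]
IntegerVector cpp_attractor_counts(List enc, int dose_idx, NumericVector doses,
                                   int n_starts, double t_max, double tol,
                                   double cluster_tol, bool early_stop) {
  Circuit c = unpack(enc);
  int n = c.n, nd = doses.size();
  IntegerVector counts(nd, NA_INTEGER);
  std::vector<double> x(n);
  std::vector<std::vector<double> > reps;
  RNGScope scope;
  for (int g = 0; g < nd; ++g) {
    c.total[dose_idx - 1] = doses[g];
    reps.clear();
    int conv = 0;
    for (int s = 0; s < n_starts; ++s) {
      for (int i = 0; i < n; ++i) x[i] = unif_rand() * c.total[i];
      double t = 0, resid = 0;
      if (!integrate_ss(c, x, t_max, tol, t, resid)) continue;
      conv++;
      bool hit = false;
      for (size_t r = 0; r < reps.size(); ++r) {
        double dmax = 0;
        for (int i = 0; i < n; ++i)
          dmax = std::max(dmax, std::fabs(x[i] - reps[r][i]));
        if (dmax < cluster_tol) { hit = true; break; }
      }
      if (!hit) reps.push_back(x);
    }
    counts[g] = conv ? (int)reps.size() : NA_INTEGER;
    if (early_stop && conv && reps.size() >= 2) break;
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
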