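#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hazard families.  family codes: 0 = HRM (trait scales the Gompertz slope),
// 1 = HTM (trait scales the initial mortality, curves time-shifted).
//   HRM: mu(x,t) = a * exp(b * x^k * t)
//   HTM: mu(x,t) = a * x^k * exp(b * t)
// Total hazard adds the age-independent extrinsic rate `ext`.
// ---------------------------------------------------------------------------

static inline double intrinsic_hazard(double x, double t, int family,
                                      double a, double b, double k) {
  double xk = std::pow(x, k);
  if (family == 0) return a * std::exp(b * xk * t);
  return a * xk * std::exp(b * t);
}

// Exact inverse-transform draw of the intrinsic death time: solve H(t) = e
// with e ~ Exp(1).  Closed forms; constant-hazard limits when the Gompertz
// slope vanishes.  HTM at x = 0 never dies intrinsically (+Inf sentinel).
static inline double draw_intrinsic_death(int family, double a, double b,
                                          double k, double x) {
  double e = exp_rand();
  double xk = std::pow(x, k);
  if (family == 0) {  // HRM, rate a at t=0, slope b*x^k
    double w = b * xk;
    if (w <= 0.0) return e / a;
    return std::log1p(w * e / a) / w;
  }
  double axk = a * xk;  // HTM, rate a*x^k at t=0, slope b
  if (axk <= 0.0) return R_PosInf;
  if (b <= 0.0) return e / axk;
  return std::log1p(b * e / axk) / b;
}

static inline double draw_death(int family, double a, double b, double k,
                                double ext, double x) {
  double t = draw_intrinsic_death(family, a, b, k, x);
  if (ext > 0.0) {
    double te = exp_rand() / ext;  // competing age-independent hazard
    if (te < t) t = te;
  }
  return t;
}

// [[Rcpp::export(name = ".cpp_draw_death_times")]]
NumericVector cpp_draw_death_times(NumericVector x, int family, double a,
                                   double b, double k, double ext) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_death(family, a, b, k, ext, x[i]);
  return out;
}

// Discrete-time death age: at each integer age the individual survives with
// probability 1 - min(mu(x, age) + ext, 1).  Returns the age of the failed
// survival test; counts hazard > 1 clampings.
static inline double discrete_death_age(int family, double a, double b,
                                        double k, double ext, double x,
                                        long *clamped) {
  double xk = std::pow(x, k);
  if (family == 1 && a * xk <= 0.0 && ext <= 0.0) return R_PosInf;
  const long max_age = 100000000L;
  for (long age = 1; age <= max_age; ++age) {
    double mu = intrinsic_hazard(x, (double)age, family, a, b, k) + ext;
    double p = mu;
    if (p > 1.0) { p = 1.0; ++(*clamped); }
    if (unif_rand() < p) return (double)age;
  }
  return R_PosInf;  // unreachable for any positive hazard
}

// [[Rcpp::export(name = ".cpp_discrete_death_ages")]]
List cpp_discrete_death_ages(NumericVector x, int family, double a, double b,
                             double k, double ext) {
  int n = x.size();
  NumericVector out(n);
  long clamped = 0;
  for (int i = 0; i < n; ++i)
    out[i] = discrete_death_age(family, a, b, k, ext, x[i], &clamped);
  return List::create(_["death_time"] = out, _["n_clamped"] = (double)clamped);
}

// ---------------------------------------------------------------------------
// Fenwick (binary indexed) tree over individuals; supports O(log n) weight
// updates, prefix sums, and sampling proportional to weight.
// ---------------------------------------------------------------------------

struct Fenwick {
  int n;
  std::vector<double> tree;
  explicit Fenwick(int n_) : n(n_), tree(n_ + 1, 0.0) {}
  void add(int i, double v) {  // 0-based index
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += v;
  }
  double total() const {
    double s = 0.0;
    for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  // smallest 0-based index i with cumsum(0..i) >= u
  int find(double u) const {
    int pos = 0, logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      int np = pos + pw;
      if (np <= n && tree[np] < u) { pos = np; u -= tree[np]; }
    }
    return pos;  // 0-based
  }
};

struct Selector {
  Fenwick w;       // reproduction weights (trait values)
  Fenwick cnt;     // alive indicators, for the zero-total-weight fallback
  const std::vector<double> &x;
  std::vector<char> alive;
  int n_alive;
  Selector(const std::vector<double> &x_)
      : w((int)x_.size()), cnt((int)x_.size()), x(x_),
        alive(x_.size(), 1), n_alive((int)x_.size()) {
    for (size_t i = 0; i < x_.size(); ++i) {
      w.add((int)i, x_[i]);
      cnt.add((int)i, 1.0);
    }
  }
  void kill(int i) {
    if (!alive[i]) return;
    w.add(i, -x[i]);
    cnt.add(i, -1.0);
    alive[i] = 0;
    --n_alive;
  }
  // weight-proportional choice; uniform over alive when all weights vanish
  int choose() {
    double tot = w.total();
    if (tot > 0.0) {
      double u = unif_rand() * tot;
      int i = w.find(u);
      if (i < (int)x.size() && alive[i] && x[i] > 0.0) return i;
    }
    // all alive weights are (numerically) zero: uniform over alive
    int m = n_alive;
    double u = std::floor(unif_rand() * m) + 1.0;
    if (u > m) u = m;
    int i = cnt.find(u - 0.5);
    return i;
  }
};

static inline double reflect01(double y) {
  y = std::fabs(y);
  y -= 2.0 * std::floor(y / 2.0);  // fold with period 2
  if (y > 1.0) y = 2.0 - y;
  return y;
}

static inline double mutate(double childx, double pm, int kernel_type,
                            double ksd) {
  if (pm > 0.0 && unif_rand() < pm) {
    if (kernel_type == 0) return unif_rand();            // uniform reset
    return reflect01(childx + norm_rand() * ksd);        // reflected Gaussian
  }
  return childx;
}

static inline double child_trait(Selector &sel,
                                 const std::vector<double> &px, bool sexual) {
  int p1 = sel.choose();
  if (!sexual || sel.n_alive < 2) return px[p1];
  // two weighted draws without replacement; offspring = parental mean
  sel.w.add(p1, -px[p1]);
  sel.cnt.add(p1, -1.0);
  sel.alive[p1] = 0;
  --sel.n_alive;
  int p2 = sel.choose();
  sel.w.add(p1, px[p1]);
  sel.cnt.add(p1, 1.0);
  sel.alive[p1] = 1;
  ++sel.n_alive;
  return 0.5 * (px[p1] + px[p2]);
}

// ---------------------------------------------------------------------------
// Continuous-time (Gillespie) generation construction.  Parents carry
// pre-drawn death times; reproduction events arrive at unit rate (Exp(1)
// inter-event gaps) starting at the maturation delay; each event copies (or
// recombines) a weight-proportionally chosen alive parent, mutates, and draws
// the offspring's own death time.  Stops when n_out offspring exist
// (fill_time = clock) or the alive set empties (extinction).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_generation_continuous")]]
List cpp_generation_continuous(NumericVector parent_x,
                               NumericVector parent_death, int n_out,
                               double pm, int kernel_type, double ksd,
                               bool sexual, double maturation, int family,
                               double a, double b, double k, double ext) {
  int n = parent_x.size();
  std::vector<double> px(parent_x.begin(), parent_x.end());
  std::vector<double> pd(parent_death.begin(), parent_death.end());

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int i, int j) { return pd[i] < pd[j]; });

  Selector sel(px);
  int dptr = 0;
  double clock = maturation > 0.0 ? maturation : 0.0;
  auto purge = [&](double t) {
    while (dptr < n && pd[ord[dptr]] <= t) sel.kill(ord[dptr++]);
  };

  std::vector<double> cx, cd;
  cx.reserve(n_out);
  cd.reserve(n_out);
  bool extinct = false;
  double fill_time = NA_REAL;

  while ((int)cx.size() < n_out) {
    clock += exp_rand();
    purge(clock);
    if (sel.n_alive <= 0) { extinct = true; break; }
    double xc = child_trait(sel, px, sexual);
    xc = mutate(xc, pm, kernel_type, ksd);
    cx.push_back(xc);
    cd.push_back(draw_death(family, a, b, k, ext, xc));
    if ((int)cx.size() == n_out) fill_time = clock;
  }

  LogicalVector oo(n, false);
  if (!extinct)
    for (int i = 0; i < n; ++i) oo[i] = (pd[i] > fill_time);

  return List::create(_["x"] = NumericVector(cx.begin(), cx.end()),
                      _["death_time"] = NumericVector(cd.begin(), cd.end()),
                      _["fill_time"] = fill_time, _["extinct"] = extinct,
                      _["parent_oldest_old"] = oo);
}

// ---------------------------------------------------------------------------
// Discrete-time generation construction.  Parents carry pre-drawn integer
// death ages (individual alive during step s iff death_time > s, matching
// per-step survival tests).  Each step after the maturation delay, a
// Poisson(1) number of reproduction events occurs among survivors
// (repro_per_step >= 0 fixes the count instead).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_generation_discrete")]]
List cpp_generation_discrete(NumericVector parent_x,
                             NumericVector parent_death, int n_out, double pm,
                             int kernel_type, double ksd, bool sexual,
                             double maturation, int repro_per_step, int family,
                             double a, double b, double k, double ext) {
  int n = parent_x.size();
  std::vector<double> px(parent_x.begin(), parent_x.end());
  std::vector<double> pd(parent_death.begin(), parent_death.end());

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int i, int j) { return pd[i] < pd[j]; });

  Selector sel(px);
  int dptr = 0;
  std::vector<double> cx, cd;
  cx.reserve(n_out);
  cd.reserve(n_out);
  bool extinct = false;
  double fill_time = NA_REAL;
  long clamped = 0;

  for (long s = 1;; ++s) {
    // survival tests at age s happen first: reproducers have death_time > s
    while (dptr < n && pd[ord[dptr]] <= (double)s) sel.kill(ord[dptr++]);
    if (sel.n_alive <= 0) { extinct = true; break; }
    if ((double)s <= maturation) continue;
    int events = repro_per_step >= 0 ? repro_per_step
                                     : (int)R::rpois(1.0);
    for (int e = 0; e < events && (int)cx.size() < n_out; ++e) {
      double xc = child_trait(sel, px, sexual);
      xc = mutate(xc, pm, kernel_type, ksd);
      cx.push_back(xc);
      cd.push_back(discrete_death_age(family, a, b, k, ext, xc, &clamped));
    }
    if ((int)cx.size() >= n_out) { fill_time = (double)s; break; }
  }

  LogicalVector oo(n, false);
  if (!extinct)
    for (int i = 0; i < n; ++i) oo[i] = (pd[i] > fill_time);

  return List::create(_["x"] = NumericVector(cx.begin(), cx.end()),
                      _["death_time"] = NumericVector(cd.begin(), cd.end()),
                      _["fill_time"] = fill_time, _["extinct"] = extinct,
                      _["parent_oldest_old"] = oo,
                      _["n_clamped"] = (double)clamped);
}

// ---------------------------------------------------------------------------
// Dip statistic (Hartigan-style departure from unimodality).
//
// Collapse tied values to unique points u with band centres
// Fm_u = (F(x_u^-) + F(x_u))/2 and half-width deficits d_u = c_u/(2n).
// For a candidate mode at point j, the left part of a unimodal
// distribution function is a convex function h passing within
// eps - d_i of every Fm_i (i < j) and within eps of the pre-jump value
// F(x_j^-) at the mode (a jump is allowed only at the mode); the right
// part is the mirrored concave statement against the post-jump values.
// Restricting h to vertical shifts of the greatest convex minorant (exact
// for equal band widths, conservative by at most max(d) otherwise), the
// side is feasible iff
//   eps >= (max_i(gap_i + d_i) + max_i(d_i - gap_i)) / 2,
// with gap_i the deviation of point i above the minorant.  The dip is the
// minimum over modes of the larger one-side requirement.
// ---------------------------------------------------------------------------

// one-side requirement: lower convex hull of (xs, vs), gaps against it,
// eps = (max(gap + d) + max(d - gap)) / 2
static double side_eps(const std::vector<double> &xs,
                       const std::vector<double> &vs,
                       const std::vector<double> &ds) {
  int m = (int)xs.size();
  if (m <= 1) return 0.0;
  std::vector<int> st;
  st.reserve(m);
  for (int j = 0; j < m; ++j) {
    while (st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      double cross = (xs[b] - xs[a]) * (vs[j] - vs[a]) -
                     (vs[b] - vs[a]) * (xs[j] - xs[a]);
      if (cross <= 0.0) st.pop_back(); else break;
    }
    st.push_back(j);
  }
  double A = 0.0, B = 0.0;  // max(gap + d), max(d - gap)
  int seg = 0;
  for (int i = 0; i < m; ++i) {
    while (seg + 1 < (int)st.size() && xs[st[seg + 1]] <= xs[i]) ++seg;
    double h;
    if (seg + 1 >= (int)st.size()) h = vs[st[seg]];
    else {
      int a = st[seg], b = st[seg + 1];
      h = vs[a] + (vs[b] - vs[a]) * (xs[i] - xs[a]) / (xs[b] - xs[a]);
    }
    double gap = vs[i] - h;
    if (gap < 0) gap = 0;
    if (gap + ds[i] > A) A = gap + ds[i];
    if (ds[i] - gap > B) B = ds[i] - gap;
  }
  return 0.5 * (A + B);
}

// [[Rcpp::export(name = ".cpp_dip")]]
double cpp_dip(NumericVector xsorted) {
  int n = xsorted.size();
  if (n < 2) return 0.0;
  std::vector<double> xu, flo, fhi, fm, dd;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && xsorted[j + 1] == xsorted[i]) ++j;
    xu.push_back(xsorted[i]);
    flo.push_back((double)i / n);
    fhi.push_back((double)(j + 1) / n);
    fm.push_back(((double)i + (double)(j + 1)) / (2.0 * n));
    dd.push_back((double)(j + 1 - i) / (2.0 * n));
    i = j + 1;
  }
  int m = (int)xu.size();
  if (m == 1) return 0.0;

  double dip = R_PosInf;
  std::vector<double> xs, vs, ds;
  xs.reserve(m); vs.reserve(m); ds.reserve(m);
  for (int j = 0; j < m; ++j) {
    // left side: points 0..j-1 at band centres, mode at its pre-jump value
    xs.clear(); vs.clear(); ds.clear();
    for (int t = 0; t < j; ++t) {
      xs.push_back(xu[t]); vs.push_back(fm[t]); ds.push_back(dd[t]);
    }
    xs.push_back(xu[j]); vs.push_back(flo[j]); ds.push_back(0.0);
    double epsL = side_eps(xs, vs, ds);
    // right side, mirrored (x -> -x, F -> -F turns the concave-majorant
    // problem into the convex-minorant one)
    xs.clear(); vs.clear(); ds.clear();
    for (int t = m - 1; t > j; --t) {
      xs.push_back(-xu[t]); vs.push_back(-fm[t]); ds.push_back(dd[t]);
    }
    xs.push_back(-xu[j]); vs.push_back(-fhi[j]); ds.push_back(0.0);
    double epsR = side_eps(xs, vs, ds);
    double e = epsL > epsR ? epsL : epsR;
    if (e < dip) dip = e;
  }
  return dip;
}

// [[Rcpp::export(name = ".cpp_dip_boot")]]
NumericVector cpp_dip_boot(int n, int nboot) {
  NumericVector out(nboot);
  std::vector<double> u(n);
  for (int b2 = 0; b2 < nboot; ++b2) {
    for (int i = 0; i < n; ++i) u[i] = unif_rand();
    std::sort(u.begin(), u.end());
    NumericVector v(u.begin(), u.end());
    out[b2] = cpp_dip(v);
  }
  return out;
}
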