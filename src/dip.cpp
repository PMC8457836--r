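// Hartigan's dip statistic: largest vertical distance between the empirical
// CDF and the closest unimodal (convex-then-concave) CDF.
//
// Two routes, selected on tie structure:
//
//  * distinct values: iterative modal-interval shrinking. Fit the greatest
//    convex minorant (GCM) of the ECDF left limits and the least concave
//    majorant (LCM) of its right limits over the current interval, find the
//    largest vertical gap between the two hull curves at their knots; if it
//    no longer exceeds the accumulated one-sided fit error, stop; otherwise
//    add the max ECDF deviation from the GCM left of the gap and from the
//    LCM right of it, and recurse into the gap interval.
//
//  * tied values: bisection on the sup-error T with an exact feasibility
//    test: a unimodal CDF within +/-T of the ECDF exists iff for some data
//    point there are a convex nondecreasing path through the lower-band /
//    upper-band corridor left of it and a concave one right of it that can
//    hand over monotonically (shared value, or a jump for an atom at the
//    mode). Convex band feasibility reduces to "GCM of upper bounds stays
//    above lower bounds"; the hand-over needs the extreme attainable
//    endpoint values, found by inner bisection.
//
// Both routes agree with each other and with an exhaustive small-n oracle
// (see the package tests); units: counts, result divided by 2n.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// ---------- distinct-value fast path ----------------------------------------
// u: sorted unique values, cnt: multiplicities, cum: cumulative counts
double dip_distinct_counts(const std::vector<double>& u,
                           const std::vector<double>& c0,
                           const std::vector<double>& cc) {
  const int K = (int) u.size();
  const double n = cc[K - 1];
  if (K == 1) return 0.0;

  int lo = 0, hi = K - 1;
  double D2 = 0.0;

  std::vector<int> gcm, lcm;
  gcm.reserve(K); lcm.reserve(K);

  auto curve_at = [&u](const std::vector<int>& hull, const std::vector<double>& y,
                       int m) -> double {
    if (m <= hull.front()) return y[hull.front()];
    if (m >= hull.back())  return y[hull.back()];
    // binary search for segment
    int a = 0, b = (int) hull.size() - 1;
    while (b - a > 1) {
      int mid = (a + b) / 2;
      if (hull[mid] <= m) a = mid; else b = mid;
    }
    int ia = hull[a], ib = hull[b];
    if (ia == ib) return y[ia];
    return y[ia] + (y[ib] - y[ia]) * (u[m] - u[ia]) / (u[ib] - u[ia]);
  };

  for (;;) {
    gcm.clear(); lcm.clear();
    for (int i = lo; i <= hi; ++i) {          // lower hull of (u, c0)
      while ((int) gcm.size() >= 2) {
        int a = gcm[gcm.size() - 2], b = gcm[gcm.size() - 1];
        if ((c0[b] - c0[a]) * (u[i] - u[a]) >= (c0[i] - c0[a]) * (u[b] - u[a]))
          gcm.pop_back();
        else break;
      }
      gcm.push_back(i);
    }
    for (int i = lo; i <= hi; ++i) {          // upper hull of (u, cc)
      while ((int) lcm.size() >= 2) {
        int a = lcm[lcm.size() - 2], b = lcm[lcm.size() - 1];
        if ((cc[b] - cc[a]) * (u[i] - u[a]) <= (cc[i] - cc[a]) * (u[b] - u[a]))
          lcm.pop_back();
        else break;
      }
      lcm.push_back(i);
    }

    // largest index t with hull[t] <= m (hull nonempty, hull.front() <= m)
    auto floor_knot = [](const std::vector<int>& hull, int m) -> size_t {
      size_t a = 0, b = hull.size() - 1;
      if (hull[b] <= m) return b;
      while (b - a > 1) { size_t mid = (a + b) / 2; if (hull[mid] <= m) a = mid; else b = mid; }
      return a;
    };

    double dgap = -1.0;
    int ix = lo, iv = hi;
    for (size_t t = 0; t < gcm.size(); ++t) {
      int m = gcm[t];
      double gap = curve_at(lcm, cc, m) - c0[m];
      if (gap > dgap) {
        dgap = gap; ix = m;
        size_t a = floor_knot(lcm, m);                 // lcm knot right of m
        iv = lcm[std::min(a + 1, lcm.size() - 1)];
      }
    }
    for (size_t t = 0; t < lcm.size(); ++t) {
      int m = lcm[t];
      double gap = cc[m] - curve_at(gcm, c0, m);
      if (gap > dgap) {
        dgap = gap; iv = m;
        ix = gcm[floor_knot(gcm, m)];                  // gcm knot left of m
      }
    }

    if (dgap <= D2 + 1e-12) break;

    double dl = 0.0, du = 0.0;
    for (int m = lo; m <= ix; ++m) {
      double dev = cc[m] - curve_at(gcm, c0, m);
      if (dev > dl) dl = dev;
    }
    for (int m = iv; m <= hi; ++m) {
      double dev = curve_at(lcm, cc, m) - c0[m];
      if (dev > du) du = dev;
    }
    if (dl > D2) D2 = dl;
    if (du > D2) D2 = du;

    if (ix == lo && iv == hi) { if (dgap > D2) D2 = dgap; break; }
    lo = ix; hi = iv;
  }
  return D2 / (2.0 * n);
}

// ---------- tied-value exact path -------------------------------------------

// feasibility of a convex nondecreasing path with lo[i] <= v_i <= hi[i]
// (points x[0..k-1]); equivalent to GCM(hi) >= lo at every point
bool conv_feasible_band(const std::vector<double>& x,
                        const std::vector<double>& lo,
                        const std::vector<double>& hi,
                        int k, double eps = 1e-9) {
  if (k <= 0) return true;
  static thread_local std::vector<int> hull;
  hull.clear();
  for (int i = 0; i < k; ++i) {
    while ((int) hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      if ((hi[b] - hi[a]) * (x[i] - x[a]) >= (hi[i] - hi[a]) * (x[b] - x[a]))
        hull.pop_back();
      else break;
    }
    hull.push_back(i);
  }
  size_t seg = 0;
  for (int m = 0; m < k; ++m) {
    while (seg + 1 < hull.size() && hull[seg + 1] < m) ++seg;
    double val;
    int a = hull[seg];
    if (m == a) val = hi[m];
    else {
      int b = hull[std::min(seg + 1, hull.size() - 1)];
      if (b == a) val = hi[a];
      else if (m == b) val = hi[b];
      else val = hi[a] + (hi[b] - hi[a]) * (x[m] - x[a]) / (x[b] - x[a]);
    }
    if (val < lo[m] - eps) return false;
  }
  return true;
}

// minimal feasible value at the last point (index k-1); +Inf if infeasible
double conv_min_end(std::vector<double> x, std::vector<double> lo,
                    std::vector<double> hi, int k) {
  if (k <= 0) return R_NegInf;
  if (!conv_feasible_band(x, lo, hi, k)) return R_PosInf;
  double a = lo[k - 1], b = hi[k - 1];
  double lo_save = lo[k - 1], hi_save = hi[k - 1];
  for (int it = 0; it < 50; ++it) {
    double v = 0.5 * (a + b);
    lo[k - 1] = v; hi[k - 1] = v;
    if (conv_feasible_band(x, lo, hi, k)) b = v; else a = v;
  }
  lo[k - 1] = lo_save; hi[k - 1] = hi_save;
  return b;
}

struct Mirror {
  // concave problem on x[j..K-1] mapped to a convex one on flipped axes
  std::vector<double> x, lo, hi;
  void build(const std::vector<double>& u, const std::vector<double>& lov,
             const std::vector<double>& hiv, int j, int K) {
    x.clear(); lo.clear(); hi.clear();
    for (int m = K - 1; m >= j; --m) {
      x.push_back(-u[m]);
      lo.push_back(-hiv[m]);
      hi.push_back(-lov[m]);
    }
  }
};

double dip_tied_counts(const std::vector<double>& u,
                       const std::vector<double>& c0,
                       const std::vector<double>& cc) {
  const int K = (int) u.size();
  const double n = cc[K - 1];
  if (K == 1) return 0.0;

  std::vector<double> lo(K), hi(K);
  Mirror mir;
  std::vector<double> xl, lol, hil;

  auto feasible = [&](double T) -> bool {
    for (int m = 0; m < K; ++m) {
      lo[m] = std::max(0.0, cc[m] - T);
      hi[m] = std::min(n, c0[m] + T);
    }
    // mode shared at point k (no jump)
    for (int k = 0; k < K; ++k) {
      if (!conv_feasible_band(u, lo, hi, k + 1)) continue;
      mir.build(u, lo, hi, k, K);
      if (!conv_feasible_band(mir.x, mir.lo, mir.hi, (int) mir.x.size())) continue;
      double A = conv_min_end(u, lo, hi, k + 1);
      double D = -conv_min_end(mir.x, mir.lo, mir.hi, (int) mir.x.size());
      if (A <= D + 1e-7) return true;
    }
    // atom (jump) at point k
    for (int k = 0; k < K; ++k) {
      xl.assign(u.begin(), u.begin() + k); lol.assign(lo.begin(), lo.begin() + k);
      hil.assign(hi.begin(), hi.begin() + k);
      xl.push_back(u[k]);
      lol.push_back(std::max(0.0, c0[k] - T));
      hil.push_back(std::min(n, c0[k] + T));
      if (!conv_feasible_band(xl, lol, hil, k + 1)) continue;
      double A = conv_min_end(xl, lol, hil, k + 1);
      // right side: atom point with right-limit band, then the suffix
      std::vector<double> xr, lor, hir;
      xr.push_back(u[k]);
      lor.push_back(std::max(0.0, cc[k] - T));
      hir.push_back(std::min(n, cc[k] + T));
      for (int m = k + 1; m < K; ++m) { xr.push_back(u[m]); lor.push_back(lo[m]); hir.push_back(hi[m]); }
      Mirror mr; mr.build(xr, lor, hir, 0, (int) xr.size());
      if (!conv_feasible_band(mr.x, mr.lo, mr.hi, (int) mr.x.size())) continue;
      double D = -conv_min_end(mr.x, mr.lo, mr.hi, (int) mr.x.size());
      if (A <= D + 1e-7) return true;
    }
    return false;
  };

  double a = 0.0, b = 0.5 * n;
  for (int it = 0; it < 52; ++it) {
    double mid = 0.5 * (a + b);
    if (feasible(mid)) b = mid; else a = mid;
  }
  return b / n;
}

void unique_counts(const std::vector<double>& xs, std::vector<double>& u,
                   std::vector<double>& c0, std::vector<double>& cc) {
  u.clear(); c0.clear(); cc.clear();
  double run = 0;
  size_t i = 0, n = xs.size();
  while (i < n) {
    size_t j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    u.push_back(xs[i]);
    c0.push_back(run);
    run += (double)(j - i);
    cc.push_back(run);
    i = j;
  }
}

double dip_sorted(const std::vector<double>& xs) {
  std::vector<double> u, c0, cc;
  unique_counts(xs, u, c0, cc);
  bool tied = u.size() != xs.size();
  double d = tied ? dip_tied_counts(u, c0, cc) : dip_distinct_counts(u, c0, cc);
  // conventional floor: the dip of a sample of size n is reported as at
  // least 1/(2n), the value attained by perfectly unimodal configurations
  double floor_ = 0.5 / (double) xs.size();
  return std::max(d, floor_);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// B dip statistics of uniform(0,1) samples of size n (shares R's RNG state)
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int B) {
  NumericVector out(B);
  std::vector<double> xs(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dip_sorted(xs);
  }
  return out;
}
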