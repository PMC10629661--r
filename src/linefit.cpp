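#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive straight-line trajectory search over a (V, c) grid.
//
// All geometry is expressed in integer units of 5 mm, of which every grid
// involved (2 cm position bins, 0.01 m intercept step, V*T offsets for V on
// the 0.5 m/s grid with T = 10 ms, d = 0.30 m) is an exact multiple, so the
// corridor-inclusion predicate |bin_center - (V*t*T + c)| <= d never suffers
// a floating-point boundary tie and the fast and naive evaluations agree
// exactly.
//
// post:    nb x nt posterior (columns sum to 1)
// voff:    per-V offset per time step, units (= V*T / 0.005, integer)
// cmin_u:  first intercept, units
// cstep_u: intercept step, units
// nc:      number of intercepts
// d_u:     corridor half-width, units
// w_u:     bin width, units (bin k center at w_u*k + w_u/2)
//
// Strategy: for each V the per-c corridor mass summed over time bins is
// assembled from a sparse difference array (each bin contributes a
// contiguous run of intercepts), cumulated, and near-maximal cells are
// re-evaluated by direct summation; ties resolve to the first cell in scan
// order (ascending V, then ascending c), matching the naive double loop.

static inline int floordiv(int a, int b) {
  int q = a / b, r = a % b;
  return (r != 0 && ((r < 0) != (b < 0))) ? q - 1 : q;
}
static inline int ceildiv(int a, int b) { return -floordiv(-a, b); }

// direct evaluation of the summed corridor mass at one (voff, c) cell
static double exact_mass(const NumericMatrix& post, int a, int c_u,
                         int d_u, int w_u) {
  int nb = post.nrow(), nt = post.ncol();
  long double tot = 0.0L;
  for (int t = 0; t < nt; ++t) {
    int x = a * t + c_u;
    // bins k with |w_u*k + w_u/2 - x| <= d_u
    int klo = ceildiv(2 * (x - d_u) - w_u, 2 * w_u);
    int khi = floordiv(2 * (x + d_u) - w_u, 2 * w_u);
    if (klo < 0) klo = 0;
    if (khi > nb - 1) khi = nb - 1;
    long double acc = 0.0L;
    for (int k = klo; k <= khi; ++k) acc += post(k, t);
    tot += (double)acc;
  }
  return (double)tot;
}

// [[Rcpp::export]]
List cpp_line_fit(NumericMatrix post, IntegerVector voff, int cmin_u,
                  int cstep_u, int nc, int d_u, int w_u) {
  int nb = post.nrow(), nt = post.ncol(), nv = voff.size();
  std::vector<double> D((size_t)nc + 1);
  std::vector<double> row((size_t)nc);
  double best = -1.0;       // exact summed mass at current best
  int best_v = -1, best_c = -1;
  // approx (cumulated) and exact sums differ only by accumulation round-off
  const double guard = 1e-12;

  for (int v = 0; v < nv; ++v) {
    int a = voff[v];
    int lo_touch = nc, hi_touch = -1;
    for (int t = 0; t < nt; ++t) {
      int base = a * t + cmin_u;
      for (int k = 0; k < nb; ++k) {
        int ctr = w_u * k + w_u / 2;
        // i range with |ctr - (base + cstep_u*i)| <= d_u
        int ilo = ceildiv(ctr - d_u - base, cstep_u);
        int ihi = floordiv(ctr + d_u - base, cstep_u);
        if (ilo < 0) ilo = 0;
        if (ihi > nc - 1) ihi = nc - 1;
        if (ilo > ihi) continue;
        double p = post(k, t);
        if (p == 0.0) continue;
        D[ilo] += p;
        D[ihi + 1] -= p;
        if (ilo < lo_touch) lo_touch = ilo;
        if (ihi + 1 > hi_touch) hi_touch = ihi + 1;
      }
    }
    if (hi_touch < 0) continue;  // line never intersects the track
    // outside [lo_touch, hi_touch) the summed mass is exactly zero
    double acc = 0.0, rmax = 0.0;
    for (int i = lo_touch; i <= hi_touch && i < nc; ++i) {
      acc += D[i];
      row[i] = acc;
      if (acc > rmax) rmax = acc;
    }
    if (rmax > best - guard) {
      for (int i = lo_touch; i <= hi_touch && i < nc; ++i) {
        if (row[i] > best - guard) {
          double ex = exact_mass(post, a, cmin_u + cstep_u * i, d_u, w_u);
          if (ex > best) { best = ex; best_v = v; best_c = i; }
        }
      }
    }
    // reset only the touched range
    for (int i = lo_touch; i <= hi_touch; ++i) D[i] = 0.0;
  }
  return List::create(_["mass"] = best, _["v_index"] = best_v + 1,
                      _["c_index"] = best_c + 1,
                      _["R"] = best / (double)nt);
}

// Corridor mass of a posterior along a fixed line, per time bin
// (used for coherence scoring; same integer-unit predicate as the fit).
// [[Rcpp::export]]
NumericVector cpp_corridor_mass(NumericMatrix post, int a, int c_u,
                                int d_u, int w_u) {
  int nb = post.nrow(), nt = post.ncol();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    int x = a * t + c_u;
    int klo = ceildiv(2 * (x - d_u) - w_u, 2 * w_u);
    int khi = floordiv(2 * (x + d_u) - w_u, 2 * w_u);
    if (klo < 0) klo = 0;
    if (khi > nb - 1) khi = nb - 1;
    long double acc = 0.0L;
    for (int k = klo; k <= khi; ++k) acc += post(k, t);
    out[t] = (double)acc;
  }
  return out;
}
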