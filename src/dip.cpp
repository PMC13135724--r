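#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Hartigan & Hartigan's dip statistic: the smallest sup-norm distance between
// the empirical CDF and any unimodal CDF.  Computed by the classical
// modal-interval narrowing scheme: maintain a candidate modal interval
// [low, high]; fit the greatest convex minorant (GCM) of the ECDF below it
// and the least concave majorant (LCM) above it; the dip is driven by the
// largest of (i) the GCM-LCM separation inside the modal interval and
// (ii) the ECDF's deviations from the GCM/LCM fits outside it.  The interval
// is narrowed to the separation argmax until no improvement is possible.
// Deviations are accumulated in count units and divided by 2n at the end.

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
  const int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  if (x[0] == x[n - 1]) return 0.0;

  // 1-based arrays as in the classical formulation
  std::vector<double> X(n + 1);
  for (int i = 1; i <= n; ++i) X[i] = x[i - 1];

  std::vector<int> mn(n + 1), mj(n + 1), gcm(n + 2), lcm(n + 2);

  // hull "previous vertex" pointers for the convex minorant over the full range
  mn[1] = 1;
  for (int j = 2; j <= n; ++j) {
    mn[j] = j - 1;
    while (true) {
      int mnj = mn[j], mnmnj = mn[mnj];
      if (mnj == 1 ||
          (X[j] - X[mnj]) * (mnj - mnmnj) < (X[mnj] - X[mnmnj]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  // and for the concave majorant
  mj[n] = n;
  for (int k = n - 1; k >= 1; --k) {
    mj[k] = k + 1;
    while (true) {
      int mjk = mj[k], mjmjk = mj[mjk];
      if (mjk == n ||
          (X[k] - X[mjk]) * (mjk - mjmjk) < (X[mjk] - X[mjmjk]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  int low = 1, high = n;
  double dip = 1.0;  // in count units; final statistic is dip / (2n)

  for (int iter = 0; iter < 10000; ++iter) {
    // GCM change points from high to low, LCM from low to high
    int l_gcm, l_lcm;
    gcm[1] = high;
    { int i = 1; while (gcm[i] > low) { gcm[i + 1] = mn[gcm[i]]; ++i; } l_gcm = i; }
    lcm[1] = low;
    { int i = 1; while (lcm[i] < high) { lcm[i + 1] = mj[lcm[i]]; ++i; } l_lcm = i; }

    int ig = l_gcm, ih = l_lcm;
    int ix = l_gcm - 1, iv = 2;
    double d = 0.0;

    if (l_gcm != 2 || l_lcm != 2) {
      // walk both hulls, measuring the vertical separation at each vertex
      do {
        int gcmix = gcm[ix], lcmiv = lcm[iv];
        if (gcmix > lcmiv) {
          // LCM vertex inside a GCM segment
          int gcmi1 = gcm[ix + 1];
          double dx = (lcmiv - gcmi1 + 1) -
            (X[lcmiv] - X[gcmi1]) * (gcmix - gcmi1) / (X[gcmix] - X[gcmi1]);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // GCM vertex inside an LCM segment
          int lcmiv1 = lcm[iv - 1];
          double dx = (X[gcmix] - X[lcmiv1]) * (lcmiv - lcmiv1) /
            (X[lcmiv] - X[lcmiv1]) - (gcmix - lcmiv1 - 1);
          --ix;
          if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 1) ix = 1;
        if (iv > l_lcm) iv = l_lcm;
      } while (gcm[ix] != lcm[iv]);
    } else {
      d = 1.0;
    }

    if (d < dip) break;

    // deviations of the ECDF above the GCM fit, from the separation argmax
    // down to low
    double dip_l = 0.0;
    for (int j = ig; j < l_gcm; ++j) {
      double max_t = 1.0;
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1 && X[je] != X[jb]) {
        double C = (je - jb) / (X[je] - X[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (jj - jb + 1) - (X[jj] - X[jb]) * C;
          if (max_t < t) max_t = t;
        }
      }
      if (dip_l < max_t) dip_l = max_t;
    }
    // deviations of the ECDF below the LCM fit, from the argmax up to high
    double dip_u = 0.0;
    for (int j = ih; j < l_lcm; ++j) {
      double max_t = 1.0;
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1 && X[je] != X[jb]) {
        double C = (je - jb) / (X[je] - X[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (X[jj] - X[jb]) * C - (jj - jb - 1);
          if (max_t < t) max_t = t;
        }
      }
      if (dip_u < max_t) dip_u = max_t;
    }

    double dipnew = std::max(dip_l, dip_u);
    if (dip < dipnew) dip = dipnew;

    if (low == gcm[ig] && high == lcm[ih]) break;
    low = gcm[ig];
    high = lcm[ih];
  }

  return dip / (2.0 * n);
}
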