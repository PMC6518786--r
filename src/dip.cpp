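#include <Rcpp.h>
using namespace Rcpp;

// Hartigan-Hartigan dip statistic for a sorted sample.
//
// The dip is the maximum distance between the empirical CDF and the
// nearest unimodal CDF.  It is found by iteratively shrinking a candidate
// modal interval [low, high]: on each pass the greatest convex minorant
// (GCM) of F_n is fitted on [low, high] together with the least concave
// majorant (LCM), the largest GCM-LCM gap is located, and the deviations of
// F_n from the two fitted curves outside the new modal interval are folded
// into the running dip.  All distances are kept in count units (multiples
// of 1/n) and divided by 2n only on exit, so the arithmetic below is exact
// for the comparisons that drive the control flow.
//
// Index arrays are 1-based to keep the convex-minorant recursions readable;
// slot 0 of each working vector is unused.

// [[Rcpp::export]]
double dip_stat_sorted(NumericVector x) {
  const int n = x.size();
  if (n < 1) stop("empty sample");
  if (n == 1) return 0.0;
  for (int k = 1; k < n; k++)
    if (x[k] < x[k - 1]) stop("sample must be sorted");
  if (x[n - 1] == x[0]) return 0.0;  // degenerate: all values equal

  // 1-based views of the data and work arrays
  std::vector<double> xx(n + 1);
  for (int i = 1; i <= n; i++) xx[i] = x[i - 1];
  std::vector<int> mn(n + 1), mj(n + 1), gcm(n + 1), lcm(n + 1);

  int low = 1, high = n;
  double dip = 1.0;  // count units; the floor 1/(2n) after rescaling

  // mn[j]: the previous GCM touch point if the minorant were fitted on
  // [1, j]; mj[k]: the next LCM touch point fitted on [k, n].  These are
  // global and reused on every pass (the fits on [low, high] are suffixes /
  // prefixes of the chains).
  mn[1] = 1;
  for (int j = 2; j <= n; j++) {
    mn[j] = j - 1;
    for (;;) {
      int mnj = mn[j], mnmnj = mn[mnj];
      if (mnj == 1 ||
          (xx[j] - xx[mnj]) * (mnj - mnmnj) <
              (xx[mnj] - xx[mnmnj]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  mj[n] = n;
  for (int k = n - 1; k >= 1; k--) {
    mj[k] = k + 1;
    for (;;) {
      int mjk = mj[k], mjmjk = mj[mjk];
      if (mjk == n ||
          (xx[k] - xx[mjk]) * (mjk - mjmjk) <
              (xx[mjk] - xx[mjmjk]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  for (int iter = 0; iter < 2 * n + 10; iter++) {
    // GCM touch points on [low, high], stored high -> low
    gcm[1] = high;
    int l_gcm = 1;
    while (gcm[l_gcm] > low) {
      gcm[l_gcm + 1] = mn[gcm[l_gcm]];
      l_gcm++;
    }
    // LCM touch points on [low, high], stored low -> high
    lcm[1] = low;
    int l_lcm = 1;
    while (lcm[l_lcm] < high) {
      lcm[l_lcm + 1] = mj[lcm[l_lcm]];
      l_lcm++;
    }

    // Walk the two chains to find d = max gap between LCM and GCM,
    // recording where it occurs (ig indexes gcm, ih indexes lcm).
    int ig = l_gcm, ih = l_lcm;
    double d = 0.0;
    if (l_gcm != 2 || l_lcm != 2) {
      int ix = l_gcm - 1, iv = 2;
      do {
        int gcmix = gcm[ix], lcmiv = lcm[iv];
        if (gcmix > lcmiv) {
          // next corner along the x axis comes from the LCM: gap between
          // the LCM value at lcmiv and the GCM chord through it
          int gcmi1 = gcm[ix + 1];
          double dx = (lcmiv - gcmi1 + 1) -
                      (xx[lcmiv] - xx[gcmi1]) * (gcmix - gcmi1) /
                          (xx[gcmix] - xx[gcmi1]);
          ++iv;
          if (dx >= d) {
            d = dx;
            ig = ix + 1;
            ih = iv - 1;
          }
        } else {
          // next corner comes from the GCM: gap between the LCM chord and
          // the GCM value at gcmix
          int lcmiv1 = lcm[iv - 1];
          double dx = (xx[gcmix] - xx[lcmiv1]) * (lcmiv - lcmiv1) /
                          (xx[lcmiv] - xx[lcmiv1]) -
                      (gcmix - lcmiv1 - 1);
          --ix;
          if (dx >= d) {
            d = dx;
            ig = ix + 1;
            ih = iv;
          }
        }
        if (ix < 1) ix = 1;
        if (iv > l_lcm) iv = l_lcm;
      } while (gcm[ix] != lcm[iv]);
    } else {
      d = 1.0;  // both curves are single chords: minimal configuration
    }

    if (d <= dip) break;

    // Deviation of F_n from the GCM left of the new modal interval
    double dip_l = 0.0;
    for (int j = ig; j < l_gcm; j++) {
      double max_t = 1.0;
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1 && xx[je] != xx[jb]) {
        double C = (je - jb) / (xx[je] - xx[jb]);
        for (int jj = jb; jj <= je; jj++) {
          double t = (jj - jb + 1) - (xx[jj] - xx[jb]) * C;
          if (max_t < t) max_t = t;
        }
      }
      if (dip_l < max_t) dip_l = max_t;
    }

    // Deviation of F_n from the LCM right of the new modal interval
    double dip_u = 0.0;
    for (int j = ih; j < l_lcm; j++) {
      double max_t = 1.0;
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1 && xx[je] != xx[jb]) {
        double C = (je - jb) / (xx[je] - xx[jb]);
        for (int jj = jb; jj <= je; jj++) {
          double t = (xx[jj] - xx[jb]) * C - (jj - jb - 1);
          if (max_t < t) max_t = t;
        }
      }
      if (dip_u < max_t) dip_u = max_t;
    }

    double dipnew = (dip_u > dip_l) ? dip_u : dip_l;
    if (dip < dipnew) dip = dipnew;

    if (low == gcm[ig] && high == lcm[ih]) break;  // no further shrinkage
    low = gcm[ig];
    high = lcm[ih];
  }

  return dip / (2.0 * n);
}
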