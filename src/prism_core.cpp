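#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All routines below assume observations sorted by (y ascending, events
// before censorings at tied y) unless stated otherwise.  The R layer sorts
// once per node and passes the sorted arrays down.

struct Fit {
  bool ok;
  double th[3];     // theta0, theta1, theta2 (theta2 = 0 when unused)
  bool used_w;
  double wrss;      // Stute-weighted residual sum of squares (the WLS objective)
  double irss;      // sum of squared imputed residuals (split criterion)
  double mean_y;    // Stute-weighted mean of y
  int n, nev;
};

// Kaplan-Meier jump weights over the sorted sample:
// d_(1) = delta_(1)/n, d_(i) = delta_(i)/(n-i+1) * prod_{j<i} ((n-j)/(n-j+1))^delta_(j)
static void stute_weights_sorted(const std::vector<double>& del, std::vector<double>& d) {
  int n = (int)del.size();
  d.assign(n, 0.0);
  double prod = 1.0;
  for (int i = 0; i < n; ++i) {
    if (del[i] > 0.5) d[i] = prod / (double)(n - i);
    if (del[i] > 0.5) prod *= (double)(n - i - 1) / (double)(n - i);
  }
}

// Solve the p x p symmetric system A theta = b in place; false if singular.
static bool solve_sym(double A[3][3], double b[3], int p, double* out) {
  double a[3][4];
  double scale = 0.0;
  for (int i = 0; i < p; ++i) scale = std::max(scale, std::fabs(A[i][i]));
  if (scale <= 0.0) return false;
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) a[i][j] = A[i][j];
    a[i][p] = b[i];
  }
  for (int k = 0; k < p; ++k) {
    int piv = k;
    for (int i = k + 1; i < p; ++i)
      if (std::fabs(a[i][k]) > std::fabs(a[piv][k])) piv = i;
    if (std::fabs(a[piv][k]) < 1e-12 * scale) return false;
    if (piv != k) for (int j = 0; j <= p; ++j) std::swap(a[k][j], a[piv][j]);
    for (int i = k + 1; i < p; ++i) {
      double f = a[i][k] / a[k][k];
      for (int j = k; j <= p; ++j) a[i][j] -= f * a[k][j];
    }
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = a[i][p];
    for (int j = i + 1; j < p; ++j) s -= a[i][j] * out[j];
    out[i] = s / a[i][i];
  }
  return true;
}

// Fit the node model (or evaluate residuals under supplied parent
// coefficients), then impute censored residuals by the conditional-mean rule
// r_hat = mean of uncensored residuals strictly greater than r (fallback r).
static Fit fit_sorted(const std::vector<double>& y, const std::vector<double>& del,
                      const std::vector<double>& x, const std::vector<double>& w,
                      bool use_w,
                      const double* parent_th, bool parent_used_w) {
  Fit f;
  f.ok = false; f.used_w = false;
  f.th[0] = f.th[1] = f.th[2] = 0.0;
  f.wrss = f.irss = f.mean_y = 0.0;
  int n = (int)y.size();
  f.n = n; f.nev = 0;
  for (int i = 0; i < n; ++i) if (del[i] > 0.5) f.nev++;
  if (n == 0 || f.nev == 0) return f;

  std::vector<double> d;
  stute_weights_sorted(del, d);

  double th0, th1, th2; bool used;
  if (parent_th != 0) {
    th0 = parent_th[0]; th1 = parent_th[1]; th2 = parent_th[2];
    used = parent_used_w;
  } else {
    // Drop the x*w column when w does not vary among positively weighted
    // x = 1 rows (the interaction is then collinear with x).
    bool uw = use_w;
    if (uw) {
      bool first = true; double wmin = 0.0, wmax = 0.0;
      for (int i = 0; i < n; ++i) {
        if (d[i] > 0.0 && x[i] > 0.5) {
          if (first) { wmin = wmax = w[i]; first = false; }
          else { wmin = std::min(wmin, w[i]); wmax = std::max(wmax, w[i]); }
        }
      }
      double sc = 1.0 + std::max(std::fabs(wmin), std::fabs(wmax));
      if (first || (wmax - wmin) <= 1e-10 * sc) uw = false;
    }
    for (;;) {
      int p = uw ? 3 : 2;
      double A[3][3] = {{0}}, b[3] = {0}, th[3] = {0};
      for (int i = 0; i < n; ++i) {
        if (d[i] <= 0.0) continue;
        double c[3] = {1.0, x[i], uw ? x[i] * w[i] : 0.0};
        for (int a1 = 0; a1 < p; ++a1) {
          for (int a2 = a1; a2 < p; ++a2) A[a1][a2] += d[i] * c[a1] * c[a2];
          b[a1] += d[i] * c[a1] * y[i];
        }
      }
      for (int a1 = 0; a1 < 3; ++a1)
        for (int a2 = 0; a2 < a1; ++a2) A[a1][a2] = A[a2][a1];
      if (solve_sym(A, b, p, th)) {
        th0 = th[0]; th1 = th[1]; th2 = uw ? th[2] : 0.0; used = uw;
        break;
      }
      if (!uw) return f;  // rank deficient even without the interaction
      uw = false;
    }
  }

  f.th[0] = th0; f.th[1] = th1; f.th[2] = th2; f.used_w = used;

  double sumd = 0.0, sumdy = 0.0;
  std::vector<double> r(n);
  std::vector<double> u; u.reserve(f.nev);
  for (int i = 0; i < n; ++i) {
    double fitv = th0 + th1 * x[i] + (used ? th2 * x[i] * w[i] : 0.0);
    r[i] = y[i] - fitv;
    f.wrss += d[i] * r[i] * r[i];
    sumd += d[i]; sumdy += d[i] * y[i];
    if (del[i] > 0.5) u.push_back(r[i]);
  }
  f.mean_y = sumdy / sumd;

  std::sort(u.begin(), u.end());
  int m = (int)u.size();
  std::vector<double> suff(m + 1, 0.0);
  for (int k = m - 1; k >= 0; --k) suff[k] = suff[k + 1] + u[k];
  for (int i = 0; i < n; ++i) {
    double rh;
    if (del[i] > 0.5) rh = r[i];
    else {
      int k = (int)(std::upper_bound(u.begin(), u.end(), r[i]) - u.begin());
      rh = (k < m) ? suff[k] / (double)(m - k) : r[i];
    }
    f.irss += rh * rh;
  }
  f.ok = true;
  return f;
}

// Exclusion criteria for a daughter node: minimum size, minimum uncensored
// count per focus group, and (HPRISM) uncensored records of each focus group
// spanning at least two distinct tracts.
static bool side_admissible(const std::vector<double>& del, const std::vector<double>& x,
                            const std::vector<int>& tract,
                            int min_node, int min_epg, bool req2tr) {
  int n = (int)del.size();
  if (n < min_node) return false;
  int ev0 = 0, ev1 = 0, tr0 = -1, tr1 = -1;
  bool multi0 = false, multi1 = false;
  for (int i = 0; i < n; ++i) {
    if (del[i] > 0.5) {
      if (x[i] > 0.5) {
        ev1++;
        if (tr1 < 0) tr1 = tract[i]; else if (tract[i] != tr1) multi1 = true;
      } else {
        ev0++;
        if (tr0 < 0) tr0 = tract[i]; else if (tract[i] != tr0) multi0 = true;
      }
    }
  }
  if (ev0 < min_epg || ev1 < min_epg) return false;
  if (req2tr && (!multi0 || !multi1)) return false;
  return true;
}

static double eval_partition_sorted(const std::vector<double>& y, const std::vector<double>& del,
                                    const std::vector<double>& x, const std::vector<double>& w,
                                    const std::vector<int>& tract,
                                    const std::vector<char>& left,
                                    bool use_w, int min_node, int min_epg, bool req2tr,
                                    const double* parent_th, bool parent_used_w) {
  int n = (int)y.size();
  std::vector<double> yl, dl, xl, wl, yr, dr, xr, wr;
  std::vector<int> tl, tr;
  for (int i = 0; i < n; ++i) {
    if (left[i]) {
      yl.push_back(y[i]); dl.push_back(del[i]); xl.push_back(x[i]);
      wl.push_back(w[i]); tl.push_back(tract[i]);
    } else {
      yr.push_back(y[i]); dr.push_back(del[i]); xr.push_back(x[i]);
      wr.push_back(w[i]); tr.push_back(tract[i]);
    }
  }
  if (!side_admissible(dl, xl, tl, min_node, min_epg, req2tr)) return NA_REAL;
  if (!side_admissible(dr, xr, tr, min_node, min_epg, req2tr)) return NA_REAL;
  Fit fl = fit_sorted(yl, dl, xl, wl, use_w, parent_th, parent_used_w);
  if (!fl.ok) return NA_REAL;
  Fit fr = fit_sorted(yr, dr, xr, wr, use_w, parent_th, parent_used_w);
  if (!fr.ok) return NA_REAL;
  return fl.irss + fr.irss;
}

static std::vector<double> to_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_node_fit(NumericVector y, NumericVector delta, NumericVector x,
                  NumericVector w, bool use_w,
                  Nullable<NumericVector> parent_theta = R_NilValue,
                  bool parent_used_w = false) {
  int n = y.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (y[a] != y[b]) return y[a] < y[b];
    return delta[a] > delta[b];
  });
  std::vector<double> ys(n), ds(n), xs(n), ws(n);
  for (int i = 0; i < n; ++i) {
    ys[i] = y[ord[i]]; ds[i] = delta[ord[i]]; xs[i] = x[ord[i]];
    ws[i] = (w.size() == n) ? w[ord[i]] : 0.0;
  }
  const double* pth = 0;
  double pbuf[3];
  if (parent_theta.isNotNull()) {
    NumericVector p(parent_theta);
    pbuf[0] = p[0]; pbuf[1] = p[1]; pbuf[2] = p[2];
    pth = pbuf;
  }
  Fit f = fit_sorted(ys, ds, xs, ws, use_w, pth, parent_used_w);
  return List::create(
    _["ok"] = f.ok,
    _["theta"] = NumericVector::create(f.th[0], f.th[1], f.th[2]),
    _["used_w"] = f.used_w,
    _["rss"] = f.wrss,
    _["irss"] = f.irss,
    _["n"] = f.n,
    _["n_events"] = f.nev,
    _["mean_log_surv"] = f.mean_y);
}

// Inputs pre-sorted by (y asc, events first).  Returns, for each cut, the sum
// of the two daughters' imputed residual sums of squares under the rule
// z < cut -> left, or NA when the cut is inadmissible.
// [[Rcpp::export]]
NumericVector cpp_scan_threshold(NumericVector y, NumericVector delta, NumericVector x,
                                 NumericVector w, IntegerVector tract, NumericVector z,
                                 NumericVector cuts, bool use_w,
                                 int min_node, int min_epg, bool req2tr,
                                 Nullable<NumericVector> parent_theta = R_NilValue,
                                 bool parent_used_w = false) {
  int n = y.size();
  std::vector<double> ys = to_vec(y), ds = to_vec(delta), xs = to_vec(x);
  std::vector<double> ws = (w.size() == n) ? to_vec(w) : std::vector<double>(n, 0.0);
  std::vector<int> ts(tract.begin(), tract.end());
  const double* pth = 0;
  double pbuf[3];
  if (parent_theta.isNotNull()) {
    NumericVector p(parent_theta);
    pbuf[0] = p[0]; pbuf[1] = p[1]; pbuf[2] = p[2];
    pth = pbuf;
  }
  int nc = cuts.size();
  NumericVector out(nc);
  std::vector<char> left(n);
  for (int c = 0; c < nc; ++c) {
    double s = cuts[c];
    for (int i = 0; i < n; ++i) left[i] = (z[i] < s) ? 1 : 0;
    out[c] = eval_partition_sorted(ys, ds, xs, ws, ts, left, use_w,
                                   min_node, min_epg, req2tr, pth, parent_used_w);
  }
  return out;
}

// Same contract for an arbitrary binary partition given as a left indicator.
// [[Rcpp::export]]
double cpp_eval_partition(NumericVector y, NumericVector delta, NumericVector x,
                          NumericVector w, IntegerVector tract, LogicalVector left,
                          bool use_w, int min_node, int min_epg, bool req2tr,
                          Nullable<NumericVector> parent_theta = R_NilValue,
                          bool parent_used_w = false) {
  int n = y.size();
  std::vector<double> ys = to_vec(y), ds = to_vec(delta), xs = to_vec(x);
  std::vector<double> ws = (w.size() == n) ? to_vec(w) : std::vector<double>(n, 0.0);
  std::vector<int> ts(tract.begin(), tract.end());
  std::vector<char> lf(n);
  for (int i = 0; i < n; ++i) lf[i] = left[i] ? 1 : 0;
  const double* pth = 0;
  double pbuf[3];
  if (parent_theta.isNotNull()) {
    NumericVector p(parent_theta);
    pbuf[0] = p[0]; pbuf[1] = p[1]; pbuf[2] = p[2];
    pth = pbuf;
  }
  return eval_partition_sorted(ys, ds, xs, ws, ts, lf, use_w,
                               min_node, min_epg, req2tr, pth, parent_used_w);
}
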