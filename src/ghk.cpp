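#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard-normal CDF via erfc: full double accuracy in both tails.
static inline double ncdf(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

// Acklam's rational approximation to the standard-normal quantile,
// ~1.2e-9 relative accuracy on (0,1) -- ample for simulated draws.
static double nicdf(double p) {
  if (p <= 0.0) return R_NegInf;
  if (p >= 1.0) return R_PosInf;
  static const double a[6] = {
    -3.969683028665376e+01,  2.209460984245205e+02, -2.759285104469687e+02,
     1.383577518672690e+02, -3.066479806614716e+01,  2.506628277459239e+00 };
  static const double b[5] = {
    -5.447609879822406e+01,  1.615858368580409e+02, -1.556989798598866e+02,
     6.680131188771972e+01, -1.328068155288572e+01 };
  static const double c[6] = {
    -7.784894002430293e-03, -3.223964580411365e-01, -2.400758277161838e+00,
    -2.549732539343734e+00,  4.374664141464968e+00,  2.938163982698783e+00 };
  static const double d[4] = {
     7.784695709041462e-03,  3.224671290700398e-01,  2.445134137142996e+00,
     3.754408661907416e+00 };
  const double plow = 0.02425;
  double q, r, x;
  if (p < plow) {
    q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
        ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  } else if (p <= 1.0 - plow) {
    q = p - 0.5; r = q * q;
    x = (((((a[0]*r + a[1])*r + a[2])*r + a[3])*r + a[4])*r + a[5])*q /
        (((((b[0]*r + b[1])*r + b[2])*r + b[3])*r + b[4])*r + 1.0);
  } else {
    q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
         ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  }
  return x;
}

// GHK recursion for P(w > a) (all upper bounds +Inf), w ~ N(0, L L').
// L lower-triangular (d x d); U: npairs x (d-1) raw Halton uniforms shared by
// all observations; sh: per-observation random shift (mod 1) decorrelating
// the simulation error across observations; antithetic pairing.  The last
// dimension needs no draw: only its Phi factor enters the product.
static double ghk_lower(const double* a, const double* L, int d,
                        const double* U, int npairs, int ldu,
                        const double* sh) {
  std::vector<double> z(d);
  double acc = 0.0;
  for (int r = 0; r < npairs; ++r) {
    for (int anti = 0; anti < 2; ++anti) {
      double prod = 1.0;
      for (int k = 0; k < d; ++k) {
        double m = 0.0;
        for (int j = 0; j < k; ++j) m += L[k + j * d] * z[j];
        double t = (a[k] - m) / L[k + k * d];
        double pk = ncdf(-t);        // P(std normal > t)
        prod *= pk;
        if (prod <= 0.0) { prod = 0.0; break; }
        if (k < d - 1) {
          double u = U[r + k * ldu] + sh[k];
          if (u >= 1.0) u -= 1.0;
          if (anti == 1) u = 1.0 - u;
          // truncated-above-t draw: z = Phi^{-1}(1 - pk*(1-u)) = -Phi^{-1}(pk*(1-u))
          double tail = pk * (1.0 - u);
          if (tail < 1e-310) tail = 1e-310;
          z[k] = -nicdf(tail);
        }
      }
      acc += prod;
    }
  }
  return acc / (2.0 * npairs);
}

// Build the lower-bound vector of the choice region for alternative j
// (1-based), in differenced-utility space w = M_j u, from eta = (eta2,eta3,eta4).
// Row convention must match region_matrix() on the R side:
//   j == 1 : w = -u,  rows (u2,u3,u4),  lower bounds eta_k
//   j >= 2 : row 1 = e_{j}, then e_{j} - e_{k} for the other alternatives in
//            ascending order; bounds -eta_j, then eta_k - eta_j.
static void region_lower(int j, const double* eta, double* a) {
  if (j == 1) {
    a[0] = eta[0]; a[1] = eta[1]; a[2] = eta[2];
  } else {
    int jj = j - 2;
    a[0] = -eta[jj];
    int pos = 1;
    for (int kk = 0; kk < 3; ++kk) {
      if (kk == jj) continue;
      a[pos++] = eta[kk] - eta[jj];
    }
  }
}

// Per-observation log-probabilities of the selection system.
// s1: n vector of x1'beta1; eta: n x 3; y1 in {0,1}; y2 in {1..4} (ignored
// when y1 == 0); chols: list of 4 lower Cholesky factors, d x d with
// d = 4 when selection (dims: 3 region rows then the selection error) else 3.
// unif: npairs x (d-1).
// shift: n x (d-1) per-observation shift matrix, or a single row shared by
// all observations.
// [[Rcpp::export]]
NumericVector selmnp_logprobs_cpp(NumericVector s1, NumericMatrix eta,
                                  IntegerVector y1, IntegerVector y2,
                                  List chols, NumericMatrix unif,
                                  NumericMatrix shift, bool selection) {
  int n = s1.size();
  int npairs = unif.nrow();
  NumericVector out(n);
  std::vector<NumericMatrix> Ls;
  for (int j = 0; j < 4; ++j) Ls.push_back(as<NumericMatrix>(chols[j]));
  int d = Ls[0].nrow();
  bool per_obs = shift.nrow() > 1;
  int lds = shift.nrow();
  const double* shp = REAL(shift);
  double a[4];
  double etarow[3];
  double sh[3];
  for (int i = 0; i < n; ++i) {
    if (selection && y1[i] == 0) {
      out[i] = R::pnorm(-s1[i], 0.0, 1.0, 1, 1); // log Phi(-s1)
      continue;
    }
    int j = y2[i];
    etarow[0] = eta(i, 0); etarow[1] = eta(i, 1); etarow[2] = eta(i, 2);
    region_lower(j, etarow, a);
    if (selection) a[3] = -s1[i];
    int si = per_obs ? i : 0;
    for (int k = 0; k < 3; ++k) sh[k] = shp[si + k * lds];
    double p = ghk_lower(a, REAL(Ls[j - 1]), d, REAL(unif), npairs, npairs, sh);
    if (p < 1e-300) p = 1e-300;
    out[i] = std::log(p);
  }
  return out;
}

// All joint probabilities P(y1 = 1, y2 = j), j = 1..4 (selection = TRUE), or
// region probabilities P(y2 = j) (selection = FALSE), for every observation.
// [[Rcpp::export]]
NumericMatrix selmnp_probs_cpp(NumericVector s1, NumericMatrix eta,
                               List chols, NumericMatrix unif,
                               NumericMatrix shift, bool selection) {
  int n = s1.size();
  int npairs = unif.nrow();
  NumericMatrix out(n, 4);
  std::vector<NumericMatrix> Ls;
  for (int j = 0; j < 4; ++j) Ls.push_back(as<NumericMatrix>(chols[j]));
  int d = Ls[0].nrow();
  bool per_obs = shift.nrow() > 1;
  int lds = shift.nrow();
  const double* shp = REAL(shift);
  double a[4];
  double etarow[3];
  double sh[3];
  for (int i = 0; i < n; ++i) {
    etarow[0] = eta(i, 0); etarow[1] = eta(i, 1); etarow[2] = eta(i, 2);
    int si = per_obs ? i : 0;
    for (int k = 0; k < 3; ++k) sh[k] = shp[si + k * lds];
    for (int j = 1; j <= 4; ++j) {
      region_lower(j, etarow, a);
      if (selection) a[3] = -s1[i];
      out(i, j - 1) = ghk_lower(a, REAL(Ls[j - 1]), d, REAL(unif), npairs,
                                npairs, sh);
    }
  }
  return out;
}

// General two-sided GHK rectangle probability P(lower < w < upper),
// w ~ N(0, L L'); bounds may be +/-Inf.  Reflection keeps the truncated draw
// numerically stable when an interval sits deep in the upper tail.
// [[Rcpp::export]]
double ghk_rect_cpp(NumericVector lower, NumericVector upper,
                    NumericMatrix L, NumericMatrix unif) {
  int d = L.nrow();
  int npairs = unif.nrow();
  std::vector<double> z(d);
  double acc = 0.0;
  for (int r = 0; r < npairs; ++r) {
    for (int anti = 0; anti < 2; ++anti) {
      double prod = 1.0;
      for (int k = 0; k < d; ++k) {
        double m = 0.0;
        for (int j = 0; j < k; ++j) m += L(k, j) * z[j];
        double lo = (lower[k] == R_NegInf) ? R_NegInf : (lower[k] - m) / L(k, k);
        double hi = (upper[k] == R_PosInf) ? R_PosInf : (upper[k] - m) / L(k, k);
        double u = (k < d - 1) ? unif(r, k) : 0.5;
        if (anti == 1) u = 1.0 - u;
        bool reflect = false;
        double flo = lo, fhi = hi;
        if ((lo == R_NegInf ? -1.0 : lo) + (hi == R_PosInf ? 1.0 : hi) > 0.0) {
          reflect = true;
          flo = (hi == R_PosInf) ? R_NegInf : -hi;
          fhi = (lo == R_NegInf) ? R_PosInf : -lo;
          u = 1.0 - u;
        }
        double plo = (flo == R_NegInf) ? 0.0 : ncdf(flo);
        double phi = (fhi == R_PosInf) ? 1.0 : ncdf(fhi);
        double pk = phi - plo;
        prod *= pk;
        if (prod <= 0.0) { prod = 0.0; break; }
        if (k < d - 1) {
          double q = plo + u * pk;
          if (q < 1e-310) q = 1e-310;
          if (q > 1.0 - 1e-16) q = 1.0 - 1e-16;
          double zz = nicdf(q);
          z[k] = reflect ? -zz : zz;
        }
      }
      acc += prod;
    }
  }
  return acc / (2.0 * npairs);
}
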