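#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Two-layer hierarchical verdict for the ordered pair (i, j).
// Returns the pairwise score S_ij = I(Y_i < Y_j) + 0.5 * I(Y_i ~ Y_j),
// i.e. 1 if j wins, 0 if i wins, 0.5 on a tie.
// Layer 1 compares deaths: a death is decisive only when the other subject
// is known to be at risk strictly beyond it. Layer 2 compares first
// nonfatal events inside the shared follow-up window min(t1_i, t1_j).
static inline double hier_score(double t1i, int d1i, double t2i, int d2i,
                                double t1j, int d1j, double t2j, int d2j) {
  if (d1i == 1 && t1i < t1j) return 1.0;  // i dies first -> j wins
  if (d1j == 1 && t1j < t1i) return 0.0;  // j dies first -> i wins
  double tau = (t1i < t1j) ? t1i : t1j;   // shared follow-up window
  bool jw = (d2i == 1) && (t2i < tau) && !((d2j == 1) && (t2j <= t2i));
  if (jw) return 1.0;
  bool iw = (d2j == 1) && (t2j < tau) && !((d2i == 1) && (t2i <= t2j));
  if (iw) return 0.0;
  return 0.5;
}

// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(NumericVector t1, IntegerVector d1,
                               NumericVector t2, IntegerVector d2) {
  int n = t1.size();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; i++) {
    S(i, i) = 0.5;  // diagonal is excluded from every estimator sum
    for (int j = i + 1; j < n; j++) {
      double s = hier_score(t1[i], d1[i], t2[i], d2[i],
                            t1[j], d1[j], t2[j], d2[j]);
      S(i, j) = s;
      S(j, i) = 1.0 - s;
    }
  }
  return S;
}

static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Solve the q x q system A x = b in place (Gaussian elimination with
// partial pivoting). Returns false if A is numerically singular.
static bool solve_sym(std::vector<double>& A, std::vector<double>& b, int q) {
  for (int k = 0; k < q; k++) {
    int piv = k;
    double amax = std::fabs(A[k * q + k]);
    for (int r = k + 1; r < q; r++) {
      double v = std::fabs(A[r * q + k]);
      if (v > amax) { amax = v; piv = r; }
    }
    if (amax < 1e-300) return false;
    if (piv != k) {
      for (int c = 0; c < q; c++) std::swap(A[k * q + c], A[piv * q + c]);
      std::swap(b[k], b[piv]);
    }
    double d = A[k * q + k];
    for (int r = k + 1; r < q; r++) {
      double f = A[r * q + k] / d;
      if (f == 0.0) continue;
      for (int c = k; c < q; c++) A[r * q + c] -= f * A[k * q + c];
      b[r] -= f * b[k];
    }
  }
  for (int k = q - 1; k >= 0; k--) {
    double s = b[k];
    for (int c = k + 1; c < q; c++) s -= A[k * q + c] * b[c];
    b[k] = s / A[k * q + k];
  }
  return true;
}

// Fisher scoring for the probabilistic index model with logit link and no
// intercept, on pairwise differences d_ij = z_j - z_i over all n(n-1)
// ordered pairs with fractional responses S_ij in {0, 1/2, 1}.
//
// Score and information never materialize the pair-level design. With
// s = Z beta, lp_ij = s_j - s_i, r_ij = S_ij - expit(lp_ij) (antisymmetric)
// and w_ij = expit'(lp_ij) (symmetric):
//   score   = -2 Z^T rowsum(r)
//   info    =  2 Z^T diag(rowsum(w)) Z - 2 Z^T W Z
// accumulated in one pass over unordered pairs.
template <typename ScoreFun>
List pim_fisher(ScoreFun Sij, int n, const NumericMatrix& Z,
                double tol, int max_iter, double guard,
                const NumericVector& init) {
  int q = Z.ncol();
  std::vector<double> beta(init.begin(), init.end()),
      s(n), rowr(n), wr(n), wv((size_t)n * q);
  bool converged = false, separated = false, singular = false;
  double max_score = R_PosInf;
  int iter = 0;
  while (iter < max_iter) {
    iter++;
    for (int i = 0; i < n; i++) {
      double acc = 0.0;
      for (int k = 0; k < q; k++) acc += Z(i, k) * beta[k];
      s[i] = acc;
      rowr[i] = 0.0; wr[i] = 0.0;
      for (int k = 0; k < q; k++) wv[(size_t)i * q + k] = 0.0;
    }
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double mu = expit(s[j] - s[i]);
        double r = Sij(i, j) - mu;
        double w = mu * (1.0 - mu);
        rowr[i] += r; rowr[j] -= r;
        wr[i] += w; wr[j] += w;
        for (int k = 0; k < q; k++) {
          wv[(size_t)i * q + k] += w * Z(j, k);
          wv[(size_t)j * q + k] += w * Z(i, k);
        }
      }
    }
    std::vector<double> score(q, 0.0), info((size_t)q * q, 0.0);
    for (int i = 0; i < n; i++) {
      for (int k = 0; k < q; k++) {
        score[k] -= 2.0 * Z(i, k) * rowr[i];
        for (int l = 0; l < q; l++) {
          info[k * q + l] += 2.0 * wr[i] * Z(i, k) * Z(i, l)
                           - 2.0 * Z(i, k) * wv[(size_t)i * q + l];
        }
      }
    }
    max_score = 0.0;
    for (int k = 0; k < q; k++)
      max_score = std::max(max_score, std::fabs(score[k]));
    if (max_score <= tol) { converged = true; break; }
    std::vector<double> step(score);
    if (!solve_sym(info, step, q)) { singular = true; break; }
    double step_norm = 0.0, bmax = 0.0;
    for (int k = 0; k < q; k++) {
      beta[k] += step[k];
      step_norm += step[k] * step[k];
      bmax = std::max(bmax, std::fabs(beta[k]));
    }
    if (bmax > guard) { separated = true; break; }
    if (std::sqrt(step_norm) <= 1e-10) { converged = true; break; }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["n_iter"] = iter, _["converged"] = converged,
                      _["max_score"] = max_score,
                      _["separated"] = separated,
                      _["singular"] = singular);
}

// [[Rcpp::export]]
List cpp_pim_fit(NumericMatrix S, NumericMatrix Z, double tol,
                 int max_iter, double guard, NumericVector init) {
  int n = S.nrow();
  auto f = [&S](int i, int j) { return S(i, j); };
  return pim_fisher(f, n, Z, tol, max_iter, guard, init);
}

// [[Rcpp::export]]
List cpp_pim_fit_stream(NumericVector t1, IntegerVector d1, NumericVector t2,
                        IntegerVector d2, NumericMatrix Z, double tol,
                        int max_iter, double guard, NumericVector init) {
  int n = t1.size();
  auto f = [&](int i, int j) {
    return hier_score(t1[i], d1[i], t2[i], d2[i], t1[j], d1[j], t2[j], d2[j]);
  };
  return pim_fisher(f, n, Z, tol, max_iter, guard, init);
}

// One pass over the ordered pairs computing, for the fitted linear score
// v + tauA (v = X tau_X), H_ij = expit(tauA + v_j - v_i) and:
//   nu_direct, nu_stand, nu_aug, and the projection (Hajek) variance of
//   the augmented estimator built from the kernel
//   h_ij = (1-A_i) A_j (S_ij - H_ij) / (p0 p1) + H_ij.
template <typename ScoreFun>
List adjusted_core(ScoreFun Sij, int n, const IntegerVector& arm,
                   double tauA, const NumericVector& v) {
  double n0 = 0.0, n1 = 0.0;
  for (int i = 0; i < n; i++) (arm[i] == 1) ? n1++ : n0++;
  double p0 = n0 / n, p1 = n1 / n, ip = 1.0 / (p0 * p1);
  std::vector<double> rowh(n, 0.0), colh(n, 0.0);
  double sumH = 0.0, sumH01 = 0.0, sumS01 = 0.0;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double s = Sij(i, j);
      // H plugs the (control, treated) arm contrast into both
      // orientations of the pair: H_ji keeps +tauA with the covariate
      // difference reversed.
      double dv = v[j] - v[i];
      double Hij = expit(tauA + dv);
      double Hji = expit(tauA - dv);
      sumH += Hij + Hji;
      double hij = Hij, hji = Hji;
      if (arm[i] == 0 && arm[j] == 1) {
        sumS01 += s; sumH01 += Hij;
        hij += (s - Hij) * ip;
      } else if (arm[i] == 1 && arm[j] == 0) {
        sumS01 += 1.0 - s; sumH01 += Hji;
        hji += ((1.0 - s) - Hji) * ip;
      }
      rowh[i] += hij; colh[j] += hij;
      rowh[j] += hji; colh[i] += hji;
    }
  }
  double np = (double)n * (n - 1);
  double nu_direct = sumS01 / (n0 * n1);
  double nu_stand = sumH / np;
  double nu_aug = nu_direct + sumH / np - sumH01 / (n0 * n1);
  double gm = 0.0;
  std::vector<double> g(n);
  for (int k = 0; k < n; k++) {
    g[k] = (rowh[k] + colh[k]) / (2.0 * (n - 1));
    gm += g[k];
  }
  gm /= n;
  double ss = 0.0;
  for (int k = 0; k < n; k++) ss += (g[k] - gm) * (g[k] - gm);
  double var_nu = 4.0 / n * ss / (n - 1);
  return List::create(_["nu_direct"] = nu_direct, _["nu_stand"] = nu_stand,
                      _["nu_aug"] = nu_aug, _["var_nu"] = var_nu,
                      _["n0"] = n0, _["n1"] = n1);
}

// [[Rcpp::export]]
List cpp_adjusted_core(NumericMatrix S, IntegerVector arm, double tauA,
                       NumericVector v) {
  int n = S.nrow();
  auto f = [&S](int i, int j) { return S(i, j); };
  return adjusted_core(f, n, arm, tauA, v);
}

// [[Rcpp::export]]
List cpp_adjusted_core_stream(NumericVector t1, IntegerVector d1,
                              NumericVector t2, IntegerVector d2,
                              IntegerVector arm, double tauA,
                              NumericVector v) {
  int n = t1.size();
  auto f = [&](int i, int j) {
    return hier_score(t1[i], d1[i], t2[i], d2[i], t1[j], d1[j], t2[j], d2[j]);
  };
  return adjusted_core(f, n, arm, tauA, v);
}

// Win/loss/tie counts over control-vs-treated comparisons plus the
// per-subject means of the kernel K = +1/0/-1 (treated win/tie/loss)
// needed for the two-sample U-statistic variance, without holding S.
template <typename ScoreFun>
List direct_core(ScoreFun Sij, int n, const IntegerVector& arm) {
  std::vector<double> ksum(n, 0.0);
  double wins = 0.0, ties = 0.0, losses = 0.0, n0 = 0.0, n1 = 0.0;
  for (int i = 0; i < n; i++) (arm[i] == 1) ? n1++ : n0++;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      if (arm[i] == arm[j]) continue;
      // orient so (c, t) = (control, treated); s = score of treated
      double s = (arm[i] == 0) ? Sij(i, j) : 1.0 - Sij(i, j);
      int c = (arm[i] == 0) ? i : j, t = (arm[i] == 0) ? j : i;
      double K = 2.0 * s - 1.0;
      if (s == 1.0) wins++; else if (s == 0.0) losses++; else ties++;
      ksum[c] += K;
      ksum[t] += K;
    }
  }
  NumericVector kmean(n);
  for (int i = 0; i < n; i++)
    kmean[i] = ksum[i] / ((arm[i] == 0) ? n1 : n0);
  return List::create(_["n_wins"] = wins, _["n_ties"] = ties,
                      _["n_losses"] = losses, _["n0"] = n0, _["n1"] = n1,
                      _["kmean"] = kmean);
}

// [[Rcpp::export]]
List cpp_direct_core(NumericMatrix S, IntegerVector arm) {
  int n = S.nrow();
  auto f = [&S](int i, int j) { return S(i, j); };
  return direct_core(f, n, arm);
}

// [[Rcpp::export]]
List cpp_direct_core_stream(NumericVector t1, IntegerVector d1,
                            NumericVector t2, IntegerVector d2,
                            IntegerVector arm) {
  int n = t1.size();
  auto f = [&](int i, int j) {
    return hier_score(t1[i], d1[i], t2[i], d2[i], t1[j], d1[j], t2[j], d2[j]);
  };
  return direct_core(f, n, arm);
}
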