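// Compiled cores: tabular relationship matrix and the single-site scan
// kernels of the Gibbs samplers for the bivariate repeatability-maternal
// animal model and the censored log-normal AFT animal model.  The kernels
// advance the chain a fixed number of scans and return the full state, so
// the R wrappers can interleave blocked (joint) location updates that fix
// the slow mixing of single-site scans along weakly identified ridges.
// All randomness goes through R's RNG: set.seed() fully determines chains.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tabular (recursive) additive relationship matrix.
// sire/dam are 1-based positions into the sorted pedigree, 0 = unknown.
// [[Rcpp::export]]
NumericMatrix tabular_A_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int j = 0; j < n; ++j) {
    const int s = sire[j] - 1, d = dam[j] - 1;
    for (int i = 0; i < j; ++i) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(i, s);
      if (d >= 0) v += 0.5 * A(i, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    double diag = 1.0;
    if (s >= 0 && d >= 0) diag += 0.5 * A(s, d);
    A(j, j) = diag;
  }
  return A;
}

// ---- small symmetric-2x2 helpers (storage: v11, v12, v22) -----------------

static inline void inv2(const double* v, double* out) {
  const double det = v[0] * v[2] - v[1] * v[1];
  if (det <= 0.0 || !R_finite(det))
    stop("singular or non-PD 2x2 matrix in sampler (det = %g)", det);
  out[0] = v[2] / det;
  out[1] = -v[1] / det;
  out[2] = v[0] / det;
}

static inline void mul2(const double* m, const double x1, const double x2,
                        double* y1, double* y2) {
  *y1 = m[0] * x1 + m[1] * x2;
  *y2 = m[1] * x1 + m[2] * x2;
}

// theta ~ N(C^{-1} rhs, C^{-1}) for PD 2x2 precision C
static inline void draw_mvn2(const double* C, const double r1, const double r2,
                             double* t1, double* t2) {
  double Ci[3];
  inv2(C, Ci);
  const double m1 = Ci[0] * r1 + Ci[1] * r2;
  const double m2 = Ci[1] * r1 + Ci[2] * r2;
  const double l11 = std::sqrt(Ci[0]);
  const double l21 = Ci[1] / l11;
  const double l22 = std::sqrt(std::max(Ci[2] - l21 * l21, 1e-300));
  const double z1 = norm_rand(), z2 = norm_rand();
  *t1 = m1 + l11 * z1;
  *t2 = m2 + l21 * z1 + l22 * z2;
}

// theta (4-vector) ~ N(C^{-1} rhs, C^{-1}), C symmetric PD 4x4 (row-major)
static inline void draw_mvn4(double* C, double* rhs, double* out) {
  const int p = 4;
  double L[16];
  for (int i = 0; i < 16; ++i) L[i] = C[i];
  // in-place Cholesky (lower)
  for (int k = 0; k < p; ++k) {
    for (int l = 0; l < k; ++l) {
      double s = L[k * p + l];
      for (int u = 0; u < l; ++u) s -= L[k * p + u] * L[l * p + u];
      L[k * p + l] = s / L[l * p + l];
    }
    double s = L[k * p + k];
    for (int u = 0; u < k; ++u) s -= L[k * p + u] * L[k * p + u];
    if (s <= 0) stop("non-PD 4x4 full-conditional in sampler");
    L[k * p + k] = std::sqrt(s);
  }
  double z[4], w[4];
  // mean: solve L w = rhs, L' mu = w
  for (int k = 0; k < p; ++k) {
    double s = rhs[k];
    for (int u = 0; u < k; ++u) s -= L[k * p + u] * w[u];
    w[k] = s / L[k * p + k];
  }
  for (int k = p - 1; k >= 0; --k) {
    double s = w[k];
    for (int u = k + 1; u < p; ++u) s -= L[u * p + k] * out[u];
    out[k] = s / L[k * p + k];
  }
  // noise: solve L' v = z
  for (int k = 0; k < p; ++k) z[k] = norm_rand();
  for (int k = p - 1; k >= 0; --k) {
    double s = z[k];
    for (int u = k + 1; u < p; ++u) s -= L[u * p + k] * w[u];
    w[k] = s / L[k * p + k];
  }
  for (int k = 0; k < p; ++k) out[k] += w[k];
}

// inverse-Wishart_2(df, S) via Bartlett on Wishart(df, S^{-1})
static inline void riwish2(const double df, const double* S, double* out) {
  double Sinv[3];
  inv2(S, Sinv);
  const double l11 = std::sqrt(Sinv[0]);
  const double l21 = Sinv[1] / l11;
  const double l22 = std::sqrt(std::max(Sinv[2] - l21 * l21, 1e-300));
  const double a11 = std::sqrt(R::rchisq(df));
  const double a22 = std::sqrt(R::rchisq(df - 1.0));
  const double a21 = norm_rand();
  const double t11 = l11 * a11;
  const double t21 = l21 * a11 + l22 * a21;
  const double t22 = l22 * a22;
  double W[3];
  W[0] = t11 * t11;
  W[1] = t11 * t21;
  W[2] = t21 * t21 + t22 * t22;
  inv2(W, out);
}

// standard normal truncated to (l, Inf)
static inline double rtnorm_lower(const double l) {
  if (l < 0.5) {
    double z;
    do { z = norm_rand(); } while (z <= l);
    return z;
  }
  const double alpha = 0.5 * (l + std::sqrt(l * l + 4.0));
  for (;;) {
    const double z = l - std::log(unif_rand()) / alpha;
    const double u = unif_rand();
    const double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (u <= rho) return z;
  }
}

// ---------------------------------------------------------------------------
// Bivariate growth-model scan kernel.
//
// State list: b1,b2 (cells), a1,a2 (pedigree), m1,m2 (dams), p1,p2 (kids),
// c1,c2 (herds), cov (15: G,M,P,C,R as v11,v12,v22 each), e1,e2 (records).
// Animals with records have their additive and permanent-environment
// effects drawn as one 4-dimensional block (they compete for the same
// kid-level variance); other levels are 2x2 blocks.  Records with missing
// trait 2 are re-imputed each scan.
// pe2anim maps each permanent-env level to its pedigree position (1-based).
// [[Rcpp::export]]
List gibbs_bivar_scan_cpp(NumericVector y1, LogicalVector obs2,
                          IntegerVector cell, IntegerVector anim,
                          IntegerVector dam, IntegerVector pe,
                          IntegerVector herd, IntegerVector pe2anim,
                          int n_cell, int n_ped, int n_dam, int n_pe,
                          int n_herd,
                          IntegerVector ai_ptr, IntegerVector ai_idx,
                          NumericVector ai_val,
                          double prior_nu, double prior_s1, double prior_s2,
                          List state, int n_scan) {
  const int n = y1.size();

  NumericVector b1 = clone(as<NumericVector>(state["b1"]));
  NumericVector b2 = clone(as<NumericVector>(state["b2"]));
  NumericVector a1 = clone(as<NumericVector>(state["a1"]));
  NumericVector a2 = clone(as<NumericVector>(state["a2"]));
  NumericVector m1 = clone(as<NumericVector>(state["m1"]));
  NumericVector m2 = clone(as<NumericVector>(state["m2"]));
  NumericVector p1 = clone(as<NumericVector>(state["p1"]));
  NumericVector p2 = clone(as<NumericVector>(state["p2"]));
  NumericVector c1 = clone(as<NumericVector>(state["c1"]));
  NumericVector c2 = clone(as<NumericVector>(state["c2"]));
  NumericVector cov = clone(as<NumericVector>(state["cov"]));
  NumericVector e1 = clone(as<NumericVector>(state["e1"]));
  NumericVector e2 = clone(as<NumericVector>(state["e2"]));

  double *G = &cov[0], *M = &cov[3], *P = &cov[6], *C = &cov[9], *R = &cov[12];
  double Gi[3], Mi[3], Pi[3], Ci_[3], Ri[3];
  inv2(G, Gi); inv2(M, Mi); inv2(P, Pi); inv2(C, Ci_); inv2(R, Ri);

  // per-level record counts (constant across scans)
  std::vector<int> ncell(n_cell, 0), nanim(n_ped, 0), ndam(n_dam, 0),
      npe(n_pe, 0), nherd(n_herd, 0);
  for (int j = 0; j < n; ++j) {
    ncell[cell[j] - 1]++;
    nanim[anim[j] - 1]++;
    ndam[dam[j] - 1]++;
    npe[pe[j] - 1]++;
    nherd[herd[j] - 1]++;
  }
  // which pe level (if any) sits on each pedigree animal (0 = none)
  std::vector<int> anim2pe(n_ped, 0);
  for (int k = 0; k < n_pe; ++k) anim2pe[pe2anim[k] - 1] = k + 1;

  NumericMatrix out(n_scan, 15);

  std::vector<double> s1buf, s2buf, d1buf, d2buf, dp1buf, dp2buf;

  for (int it = 0; it < n_scan; ++it) {
    // -- 1. impute missing trait-2 residuals ------------------------------
    const double condb = R[1] / R[0];
    const double condsd = std::sqrt(std::max(R[2] - R[1] * R[1] / R[0], 1e-300));
    for (int j = 0; j < n; ++j)
      if (!obs2[j]) e2[j] = condb * e1[j] + condsd * norm_rand();

    // -- 2. fixed-effect cells (flat prior) -------------------------------
    s1buf.assign(n_cell, 0.0); s2buf.assign(n_cell, 0.0);
    for (int j = 0; j < n; ++j) {
      const int k = cell[j] - 1;
      s1buf[k] += e1[j];
      s2buf[k] += e2[j];
    }
    d1buf.assign(n_cell, 0.0); d2buf.assign(n_cell, 0.0);
    for (int k = 0; k < n_cell; ++k) {
      if (ncell[k] == 0) continue;
      const double nk = (double)ncell[k];
      const double s1 = s1buf[k] + nk * b1[k];
      const double s2 = s2buf[k] + nk * b2[k];
      double r1, r2;
      mul2(Ri, s1, s2, &r1, &r2);
      double Cm[3] = {nk * Ri[0], nk * Ri[1], nk * Ri[2]};
      double t1, t2;
      draw_mvn2(Cm, r1, r2, &t1, &t2);
      d1buf[k] = t1 - b1[k];
      d2buf[k] = t2 - b2[k];
      b1[k] = t1; b2[k] = t2;
    }
    for (int j = 0; j < n; ++j) {
      const int k = cell[j] - 1;
      e1[j] -= d1buf[k];
      e2[j] -= d2buf[k];
    }

    // -- 3. additive (+ permanent env, jointly for recorded animals) ------
    s1buf.assign(n_ped, 0.0); s2buf.assign(n_ped, 0.0);
    for (int j = 0; j < n; ++j) {
      const int k = anim[j] - 1;
      s1buf[k] += e1[j];
      s2buf[k] += e2[j];
    }
    d1buf.assign(n_ped, 0.0); d2buf.assign(n_ped, 0.0);
    dp1buf.assign(n_pe, 0.0); dp2buf.assign(n_pe, 0.0);
    for (int i = 0; i < n_ped; ++i) {
      double adiag = 0.0, q1 = 0.0, q2 = 0.0;
      for (int u = ai_ptr[i]; u < ai_ptr[i + 1]; ++u) {
        const int l = ai_idx[u];
        if (l == i) {
          adiag = ai_val[u];
        } else {
          q1 += ai_val[u] * a1[l];
          q2 += ai_val[u] * a2[l];
        }
      }
      const double ni = (double)nanim[i];
      double g1, g2;
      mul2(Gi, q1, q2, &g1, &g2);
      const int pk = anim2pe[i];  // 1-based pe level or 0
      if (pk == 0) {
        // no records through pe for this animal: plain 2x2 additive block
        const double s1 = s1buf[i] + ni * a1[i];
        const double s2 = s2buf[i] + ni * a2[i];
        double r1, r2;
        mul2(Ri, s1, s2, &r1, &r2);
        r1 -= g1; r2 -= g2;
        double Cm[3] = {ni * Ri[0] + adiag * Gi[0], ni * Ri[1] + adiag * Gi[1],
                        ni * Ri[2] + adiag * Gi[2]};
        double t1, t2;
        draw_mvn2(Cm, r1, r2, &t1, &t2);
        d1buf[i] = t1 - a1[i];
        d2buf[i] = t2 - a2[i];
        a1[i] = t1; a2[i] = t2;
      } else {
        // joint (a_i, p_k) 4-block: both load on the same records
        const int kp = pk - 1;
        const double s1 = s1buf[i] + ni * (a1[i] + p1[kp]);
        const double s2 = s2buf[i] + ni * (a2[i] + p2[kp]);
        double r1, r2;
        mul2(Ri, s1, s2, &r1, &r2);
        double C4[16], rhs[4], th[4];
        C4[0] = ni * Ri[0] + adiag * Gi[0];
        C4[1] = ni * Ri[1] + adiag * Gi[1];
        C4[5] = ni * Ri[2] + adiag * Gi[2];
        C4[4] = C4[1];
        C4[2] = ni * Ri[0]; C4[3] = ni * Ri[1];
        C4[6] = ni * Ri[1]; C4[7] = ni * Ri[2];
        C4[8] = C4[2]; C4[12] = C4[3]; C4[9] = C4[6]; C4[13] = C4[7];
        C4[10] = ni * Ri[0] + Pi[0];
        C4[11] = ni * Ri[1] + Pi[1];
        C4[14] = C4[11];
        C4[15] = ni * Ri[2] + Pi[2];
        rhs[0] = r1 - g1;
        rhs[1] = r2 - g2;
        rhs[2] = r1;
        rhs[3] = r2;
        draw_mvn4(C4, rhs, th);
        d1buf[i] = th[0] - a1[i];
        d2buf[i] = th[1] - a2[i];
        dp1buf[kp] = th[2] - p1[kp];
        dp2buf[kp] = th[3] - p2[kp];
        a1[i] = th[0]; a2[i] = th[1];
        p1[kp] = th[2]; p2[kp] = th[3];
      }
    }
    for (int j = 0; j < n; ++j) {
      const int k = anim[j] - 1;
      const int kp = pe[j] - 1;
      e1[j] -= d1buf[k] + dp1buf[kp];
      e2[j] -= d2buf[k] + dp2buf[kp];
    }

    // -- 4. iid 2x2 terms: maternal, common env ---------------------------
    for (int t = 0; t < 2; ++t) {
      NumericVector& t1v = t == 0 ? m1 : c1;
      NumericVector& t2v = t == 0 ? m2 : c2;
      std::vector<int>& cnt = t == 0 ? ndam : nherd;
      const IntegerVector& lev = t == 0 ? dam : herd;
      double* prec = t == 0 ? Mi : Ci_;
      const int q = t == 0 ? n_dam : n_herd;
      s1buf.assign(q, 0.0); s2buf.assign(q, 0.0);
      for (int j = 0; j < n; ++j) {
        const int k = lev[j] - 1;
        s1buf[k] += e1[j];
        s2buf[k] += e2[j];
      }
      d1buf.assign(q, 0.0); d2buf.assign(q, 0.0);
      for (int k = 0; k < q; ++k) {
        const double nk = (double)cnt[k];
        const double s1 = s1buf[k] + nk * t1v[k];
        const double s2 = s2buf[k] + nk * t2v[k];
        double r1, r2;
        mul2(Ri, s1, s2, &r1, &r2);
        double Cm[3] = {nk * Ri[0] + prec[0], nk * Ri[1] + prec[1],
                        nk * Ri[2] + prec[2]};
        double w1, w2;
        draw_mvn2(Cm, r1, r2, &w1, &w2);
        d1buf[k] = w1 - t1v[k];
        d2buf[k] = w2 - t2v[k];
        t1v[k] = w1; t2v[k] = w2;
      }
      for (int j = 0; j < n; ++j) {
        const int k = lev[j] - 1;
        e1[j] -= d1buf[k];
        e2[j] -= d2buf[k];
      }
    }

    // -- 5. covariance matrices (inverse-Wishart full conditionals) -------
    {
      double S11 = 0.0, S12 = 0.0, S22 = 0.0;
      for (int i = 0; i < n_ped; ++i) {
        double w1 = 0.0, w2 = 0.0;
        for (int u = ai_ptr[i]; u < ai_ptr[i + 1]; ++u) {
          const int l = ai_idx[u];
          w1 += ai_val[u] * a1[l];
          w2 += ai_val[u] * a2[l];
        }
        S11 += a1[i] * w1;
        S12 += a1[i] * w2;
        S22 += a2[i] * w2;
      }
      double S[3] = {S11 + prior_s1, S12, S22 + prior_s2};
      riwish2(prior_nu + n_ped, S, G);
      inv2(G, Gi);
    }
    {
      double S11 = 0, S12 = 0, S22 = 0;
      for (int k = 0; k < n_dam; ++k) {
        S11 += m1[k] * m1[k]; S12 += m1[k] * m2[k]; S22 += m2[k] * m2[k];
      }
      double S[3] = {S11 + prior_s1, S12, S22 + prior_s2};
      riwish2(prior_nu + n_dam, S, M);
      inv2(M, Mi);
    }
    {
      double S11 = 0, S12 = 0, S22 = 0;
      for (int k = 0; k < n_pe; ++k) {
        S11 += p1[k] * p1[k]; S12 += p1[k] * p2[k]; S22 += p2[k] * p2[k];
      }
      double S[3] = {S11 + prior_s1, S12, S22 + prior_s2};
      riwish2(prior_nu + n_pe, S, P);
      inv2(P, Pi);
    }
    {
      double S11 = 0, S12 = 0, S22 = 0;
      for (int k = 0; k < n_herd; ++k) {
        S11 += c1[k] * c1[k]; S12 += c1[k] * c2[k]; S22 += c2[k] * c2[k];
      }
      double S[3] = {S11 + prior_s1, S12, S22 + prior_s2};
      riwish2(prior_nu + n_herd, S, C);
      inv2(C, Ci_);
    }
    {
      double S11 = 0, S12 = 0, S22 = 0;
      for (int j = 0; j < n; ++j) {
        S11 += e1[j] * e1[j]; S12 += e1[j] * e2[j]; S22 += e2[j] * e2[j];
      }
      double S[3] = {S11 + prior_s1, S12, S22 + prior_s2};
      riwish2(prior_nu + n, S, R);
      inv2(R, Ri);
    }

    for (int u = 0; u < 15; ++u) out(it, u) = cov[u];
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  List st = List::create(
      _["b1"] = b1, _["b2"] = b2, _["a1"] = a1, _["a2"] = a2,
      _["m1"] = m1, _["m2"] = m2, _["p1"] = p1, _["p2"] = p2,
      _["c1"] = c1, _["c2"] = c2, _["cov"] = cov, _["e1"] = e1,
      _["e2"] = e2);
  return List::create(_["samples"] = out, _["state"] = st);
}

// ---------------------------------------------------------------------------
// Censored log-normal AFT scan kernel (scalar variances).
// State list: b (p), a (pedigree), m (dams), c (groups),
// var (s2a, s2m, s2c, s2e), y (augmented log-times), e (residuals).
// [[Rcpp::export]]
List gibbs_aft_scan_cpp(LogicalVector cens, double log_h, NumericMatrix X,
                        IntegerVector anim, IntegerVector dam,
                        IntegerVector grp, int n_ped, int n_dam, int n_grp,
                        IntegerVector ai_ptr, IntegerVector ai_idx,
                        NumericVector ai_val,
                        double prior_shape, double prior_rate,
                        List state, int n_scan) {
  const int n = cens.size();
  const int p = X.ncol();

  NumericVector b = clone(as<NumericVector>(state["b"]));
  NumericVector a = clone(as<NumericVector>(state["a"]));
  NumericVector m = clone(as<NumericVector>(state["m"]));
  NumericVector c = clone(as<NumericVector>(state["c"]));
  NumericVector vr = clone(as<NumericVector>(state["var"]));
  NumericVector y = clone(as<NumericVector>(state["y"]));
  NumericVector e = clone(as<NumericVector>(state["e"]));
  double &s2a = vr[0], &s2m = vr[1], &s2c = vr[2], &s2e = vr[3];

  std::vector<int> nanim(n_ped, 0), ndam(n_dam, 0), ngrp(n_grp, 0);
  for (int j = 0; j < n; ++j) {
    nanim[anim[j] - 1]++;
    ndam[dam[j] - 1]++;
    ngrp[grp[j] - 1]++;
  }
  std::vector<double> XtX(p * p, 0.0);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < p; ++k)
      for (int l = 0; l <= k; ++l) XtX[k * p + l] += X(j, k) * X(j, l);
  for (int k = 0; k < p; ++k)
    for (int l = k + 1; l < p; ++l) XtX[k * p + l] = XtX[l * p + k];

  NumericMatrix out(n_scan, p + 4);
  std::vector<double> sums, dbuf, r(p), L(p * p), z(p), bn(p), delta(p);

  for (int it = 0; it < n_scan; ++it) {
    // 1. censored-data augmentation
    const double se = std::sqrt(s2e);
    for (int j = 0; j < n; ++j) {
      if (!cens[j]) continue;
      const double mu = y[j] - e[j];
      const double l = (log_h - mu) / se;
      const double znew = rtnorm_lower(l);
      y[j] = mu + se * znew;
      e[j] = se * znew;
    }

    // 2. fixed regression block
    {
      for (int k = 0; k < p; ++k) r[k] = 0.0;
      for (int j = 0; j < n; ++j) {
        double xb = 0.0;
        for (int k = 0; k < p; ++k) xb += X(j, k) * b[k];
        const double pr = e[j] + xb;
        for (int k = 0; k < p; ++k) r[k] += X(j, k) * pr;
      }
      for (int k = 0; k < p * p; ++k) L[k] = XtX[k] / s2e;
      for (int k = 0; k < p; ++k) {
        for (int l = 0; l < k; ++l) {
          double s = L[k * p + l];
          for (int u = 0; u < l; ++u) s -= L[k * p + u] * L[l * p + u];
          L[k * p + l] = s / L[l * p + l];
        }
        double s = L[k * p + k];
        for (int u = 0; u < k; ++u) s -= L[k * p + u] * L[k * p + u];
        if (s <= 0) stop("singular fixed-effect system in AFT sampler");
        L[k * p + k] = std::sqrt(s);
      }
      for (int k = 0; k < p; ++k) {
        double s = r[k] / s2e;
        for (int u = 0; u < k; ++u) s -= L[k * p + u] * z[u];
        z[k] = s / L[k * p + k];
      }
      for (int k = p - 1; k >= 0; --k) {
        double s = z[k];
        for (int u = k + 1; u < p; ++u) s -= L[u * p + k] * bn[u];
        bn[k] = s / L[k * p + k];
      }
      for (int k = 0; k < p; ++k) z[k] = norm_rand();
      for (int k = p - 1; k >= 0; --k) {
        double s = z[k];
        for (int u = k + 1; u < p; ++u) s -= L[u * p + k] * r[u];
        r[k] = s / L[k * p + k];
      }
      for (int k = 0; k < p; ++k) {
        const double newb = bn[k] + r[k];
        delta[k] = newb - b[k];
        b[k] = newb;
      }
      for (int j = 0; j < n; ++j) {
        double d = 0.0;
        for (int k = 0; k < p; ++k) d += X(j, k) * delta[k];
        e[j] -= d;
      }
    }

    // 3. additive effects (single-site, pedigree-coupled)
    sums.assign(n_ped, 0.0);
    for (int j = 0; j < n; ++j) sums[anim[j] - 1] += e[j];
    dbuf.assign(n_ped, 0.0);
    for (int i = 0; i < n_ped; ++i) {
      double adiag = 0.0, q = 0.0;
      for (int u = ai_ptr[i]; u < ai_ptr[i + 1]; ++u) {
        const int l = ai_idx[u];
        if (l == i) adiag = ai_val[u];
        else q += ai_val[u] * a[l];
      }
      const double ni = (double)nanim[i];
      const double s = sums[i] + ni * a[i];
      const double prec = ni / s2e + adiag / s2a;
      const double rhs = s / s2e - q / s2a;
      const double newa = rhs / prec + norm_rand() / std::sqrt(prec);
      dbuf[i] = newa - a[i];
      a[i] = newa;
    }
    for (int j = 0; j < n; ++j) e[j] -= dbuf[anim[j] - 1];

    // 4. iid scalar terms
    for (int t = 0; t < 2; ++t) {
      NumericVector& th = t == 0 ? m : c;
      std::vector<int>& cnt = t == 0 ? ndam : ngrp;
      const IntegerVector& lev = t == 0 ? dam : grp;
      const double s2 = t == 0 ? s2m : s2c;
      const int q = t == 0 ? n_dam : n_grp;
      sums.assign(q, 0.0);
      for (int j = 0; j < n; ++j) sums[lev[j] - 1] += e[j];
      dbuf.assign(q, 0.0);
      for (int k = 0; k < q; ++k) {
        const double nk = (double)cnt[k];
        const double s = sums[k] + nk * th[k];
        const double prec = nk / s2e + 1.0 / s2;
        const double newt = (s / s2e) / prec + norm_rand() / std::sqrt(prec);
        dbuf[k] = newt - th[k];
        th[k] = newt;
      }
      for (int j = 0; j < n; ++j) e[j] -= dbuf[lev[j] - 1];
    }

    // 5. variances
    {
      double ss = 0.0;
      for (int i = 0; i < n_ped; ++i) {
        double w = 0.0;
        for (int u = ai_ptr[i]; u < ai_ptr[i + 1]; ++u)
          w += ai_val[u] * a[ai_idx[u]];
        ss += a[i] * w;
      }
      s2a = (prior_rate + 0.5 * ss) / R::rgamma(prior_shape + 0.5 * n_ped, 1.0);
    }
    {
      double ss = 0.0;
      for (int k = 0; k < n_dam; ++k) ss += m[k] * m[k];
      s2m = (prior_rate + 0.5 * ss) / R::rgamma(prior_shape + 0.5 * n_dam, 1.0);
    }
    {
      double ss = 0.0;
      for (int k = 0; k < n_grp; ++k) ss += c[k] * c[k];
      s2c = (prior_rate + 0.5 * ss) / R::rgamma(prior_shape + 0.5 * n_grp, 1.0);
    }
    {
      double ss = 0.0;
      for (int j = 0; j < n; ++j) ss += e[j] * e[j];
      s2e = (prior_rate + 0.5 * ss) / R::rgamma(prior_shape + 0.5 * n, 1.0);
    }

    for (int k = 0; k < p; ++k) out(it, k) = b[k];
    out(it, p) = s2a;
    out(it, p + 1) = s2m;
    out(it, p + 2) = s2c;
    out(it, p + 3) = s2e;
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  List st = List::create(_["b"] = b, _["a"] = a, _["m"] = m, _["c"] = c,
                         _["var"] = vr, _["y"] = y, _["e"] = e);
  return List::create(_["samples"] = out, _["state"] = st);
}
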