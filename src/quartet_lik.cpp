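// Exact GTR+Gamma+I site-pattern probabilities and negative log-likelihood
// for a 4-taxon tree, evaluated over the full 256-pattern space.  This is
// the optimizer's inner loop; the R-level implementation in model.R is the
// readable reference and must agree to numerical precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// mean-of-category discrete gamma rates (mean 1), matching
// phangorn::discrete.gamma
static arma::vec discrete_gamma_rates(double shape, int k) {
  arma::vec r(k);
  double scale = 1.0 / shape;
  arma::vec b(k + 1);
  b[0] = 0.0;
  for (int i = 1; i < k; ++i)
    b[i] = R::qgamma((double)i / k, shape, scale, 1, 0);
  b[k] = R_PosInf;
  for (int i = 0; i < k; ++i) {
    double hi = (i == k - 1) ? 1.0 : R::pgamma(b[i + 1], shape + 1.0, scale, 1, 0);
    double lo = (i == 0) ? 0.0 : R::pgamma(b[i], shape + 1.0, scale, 1, 0);
    r[i] = k * (hi - lo);
  }
  return r;
}

struct GtrEigen {
  arma::vec lambda;
  arma::mat B;     // rows scaled by 1/sqrt(bf)
  arma::mat Binv;  // columns scaled by sqrt(bf)
};

static GtrEigen gtr_eigen(const arma::vec& rates, const arma::vec& bf) {
  arma::mat Q(4, 4, arma::fill::zeros);
  // lower triangle column-major: AC, AG, AT, CG, CT, GT
  Q(1, 0) = rates[0]; Q(2, 0) = rates[1]; Q(3, 0) = rates[2];
  Q(2, 1) = rates[3]; Q(3, 1) = rates[4]; Q(3, 2) = rates[5];
  Q = Q + Q.t();
  for (int j = 0; j < 4; ++j) Q.col(j) *= bf[j];
  Q.diag() = -arma::sum(Q, 1);
  double scale = -arma::dot(Q.diag(), bf);
  Q /= scale;
  arma::vec s = arma::sqrt(bf);
  arma::mat S = Q % (s * (1.0 / s).t());
  S = (S + S.t()) / 2.0;
  GtrEigen e;
  arma::mat evec;
  arma::eig_sym(e.lambda, evec, S);
  e.B = evec.each_col() / s;
  e.Binv = evec.t();
  e.Binv.each_row() %= s.t();
  return e;
}

// P(t) into a flat 4x4 row-major array, clamped and row-normalized
static void pmat(const GtrEigen& e, double t, double* P) {
  double ex[4];
  for (int k = 0; k < 4; ++k) ex[k] = std::exp(e.lambda[k] * t);
  for (int i = 0; i < 4; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < 4; ++j) {
      double v = 0.0;
      for (int k = 0; k < 4; ++k) v += e.B(i, k) * ex[k] * e.Binv(k, j);
      if (v < 0.0) v = 0.0;
      P[4 * i + j] = v;
      rowsum += v;
    }
    for (int j = 0; j < 4; ++j) P[4 * i + j] /= rowsum;
  }
}

// topology: 1 = (a,b) sisters, 2 = (a,c), 3 = (b,c); pattern index encodes
// states base 4: idx = a + 4 b + 16 c + 64 o (0-based)
// [[Rcpp::export(name = ".quartet_pattern_probs_cpp")]]
arma::vec quartet_pattern_probs_cpp(const arma::vec& rates,
                                    const arma::vec& bf, double shape,
                                    double pinv, int k,
                                    const arma::vec& blen, int topology) {
  GtrEigen e = gtr_eigen(rates, bf);
  arma::vec g = discrete_gamma_rates(shape, k);
  double wg = (1.0 - pinv) / k;
  if (pinv > 0.0) g /= (1.0 - pinv);
  // branch order in blen: a, b, c, o, int
  int i1, i2, i3;
  if (topology == 1)      { i1 = 0; i2 = 1; i3 = 2; }
  else if (topology == 2) { i1 = 0; i2 = 2; i3 = 1; }
  else                    { i1 = 1; i2 = 2; i3 = 0; }
  arma::vec probs(256, arma::fill::zeros);
  if (pinv > 0.0)
    for (int s = 0; s < 4; ++s)
      probs[s + 4 * s + 16 * s + 64 * s] += pinv * bf[s];
  double P1[16], P2[16], P3[16], Po[16], Pi[16];
  for (int m = 0; m < k; ++m) {
    double r = g[m];
    pmat(e, r * blen[i1], P1);
    pmat(e, r * blen[i2], P2);
    pmat(e, r * blen[i3], P3);
    pmat(e, r * blen[3], Po);
    pmat(e, r * blen[4], Pi);
    // U[x][s1 + 4 s2] = bf[x] P1(x,s1) P2(x,s2); V[y][s3 + 4 so] =
    // P3(y,s3) Po(y,so); W = Pi V folds the internal branch
    double U[4][16], V[4][16], W[4][16];
    for (int x = 0; x < 4; ++x)
      for (int s2 = 0; s2 < 4; ++s2)
        for (int s1 = 0; s1 < 4; ++s1)
          U[x][s1 + 4 * s2] = bf[x] * P1[4 * x + s1] * P2[4 * x + s2];
    for (int y = 0; y < 4; ++y)
      for (int so = 0; so < 4; ++so)
        for (int s3 = 0; s3 < 4; ++s3)
          V[y][s3 + 4 * so] = P3[4 * y + s3] * Po[4 * y + so];
    for (int x = 0; x < 4; ++x)
      for (int c = 0; c < 16; ++c) {
        double acc = 0.0;
        for (int y = 0; y < 4; ++y) acc += Pi[4 * x + y] * V[y][c];
        W[x][c] = acc;
      }
    for (int p = 0; p < 256; ++p) {
      int st[4] = { p & 3, (p >> 2) & 3, (p >> 4) & 3, (p >> 6) & 3 };
      int c12 = st[i1] + 4 * st[i2];
      int c3o = st[i3] + 4 * st[3];
      double tot = U[0][c12] * W[0][c3o] + U[1][c12] * W[1][c3o] +
                   U[2][c12] * W[2][c3o] + U[3][c12] * W[3][c3o];
      probs[p] += wg * tot;
    }
  }
  return probs;
}

// negative log-likelihood on the transformed parameter scale used by
// fit_gtr_gamma_i: par = (log blen[5], log rates[5] vs GT, log bf[3] vs T,
// log shape, logit pinv)
// [[Rcpp::export(name = ".quartet_nll_cpp")]]
double quartet_nll_cpp(const arma::vec& par, const arma::vec& counts,
                       int topology, int k) {
  arma::vec blen = arma::exp(par.subvec(0, 4));
  arma::vec rates(6);
  for (int i = 0; i < 5; ++i) rates[i] = std::exp(par[5 + i]);
  rates[5] = 1.0;
  arma::vec bf(4);
  for (int i = 0; i < 3; ++i) bf[i] = std::exp(par[10 + i]);
  bf[3] = 1.0;
  bf /= arma::sum(bf);
  double shape = std::exp(par[13]);
  double pinv = 1.0 / (1.0 + std::exp(-par[14]));
  arma::vec probs = quartet_pattern_probs_cpp(rates, bf, shape, pinv, k,
                                              blen, topology);
  double ll = 0.0;
  for (int p = 0; p < 256; ++p) {
    if (counts[p] > 0.0) {
      double pr = probs[p] < 1e-300 ? 1e-300 : probs[p];
      ll += counts[p] * std::log(pr);
    }
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
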