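#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout for one variant (all on the log scale):
//   theta[0..B-1]  log mu_DNA per barcode
//   theta[B]       log mu_allele (ref)
//   theta[B+1]     log mu_allele (alt)
//   theta[B+2]     log phi_DNA
//   theta[B+3]     log phi_RNA (ref)
//   theta[B+4]     log phi_RNA (alt)
// Prior families (shape/rate, length 5): mu_dna, mu_rna_ref, mu_rna_alt,
// phi_dna, phi_rna (shared by both RNA dispersions).

static const double THETA_MAX = 30.0;   // exp(30) ~ 1e13; hard support bound

static inline double nb_lpmf(double k, double mu, double phi) {
  // mean-dispersion NB: Var = mu + mu^2/phi  (size = phi)
  return R::dnbinom_mu(k, phi, mu, 1);
}

// [[Rcpp::export]]
double ll_variant_cpp(NumericVector theta,
                      NumericMatrix dna, NumericMatrix rna,
                      NumericVector dDna, NumericVector dRna,
                      IntegerVector allele) {
  const int B = dna.nrow();
  const int Sd = dna.ncol(), Sr = rna.ncol();
  const double phiD = std::exp(theta[B + 2]);
  const double phiR[2] = { std::exp(theta[B + 3]), std::exp(theta[B + 4]) };
  const double muA[2]  = { std::exp(theta[B]),     std::exp(theta[B + 1]) };
  double ll = 0.0;
  for (int b = 0; b < B; ++b) {
    const double muD = std::exp(theta[b]);
    const int a = allele[b];
    for (int s = 0; s < Sd; ++s)
      ll += nb_lpmf(dna(b, s), dDna[s] * muD, phiD);
    for (int s = 0; s < Sr; ++s)
      ll += nb_lpmf(rna(b, s), dRna[s] * muD * muA[a], phiR[a]);
  }
  return ll;
}

// gradient of ll_variant_cpp w.r.t. theta (log-scale parameters)
// [[Rcpp::export]]
NumericVector grad_ll_variant_cpp(NumericVector theta,
                                  NumericMatrix dna, NumericMatrix rna,
                                  NumericVector dDna, NumericVector dRna,
                                  IntegerVector allele) {
  const int B = dna.nrow();
  const int Sd = dna.ncol(), Sr = rna.ncol();
  const double phiD = std::exp(theta[B + 2]);
  const double phiR[2] = { std::exp(theta[B + 3]), std::exp(theta[B + 4]) };
  const double muA[2]  = { std::exp(theta[B]),     std::exp(theta[B + 1]) };
  NumericVector g(theta.size());
  for (int b = 0; b < B; ++b) {
    const double muD = std::exp(theta[b]);
    const int a = allele[b];
    for (int s = 0; s < Sd; ++s) {
      const double mu = dDna[s] * muD, k = dna(b, s);
      const double dmu = k - (k + phiD) * mu / (mu + phiD); // dl/dlog(mu)
      g[b] += dmu;
      g[B + 2] += phiD * (R::digamma(k + phiD) - R::digamma(phiD)
                          + std::log(phiD) + 1.0 - std::log(phiD + mu)
                          - (k + phiD) / (phiD + mu));
    }
    for (int s = 0; s < Sr; ++s) {
      const double mu = dRna[s] * muD * muA[a], k = rna(b, s);
      const double phi = phiR[a];
      const double dmu = k - (k + phi) * mu / (mu + phi);
      g[b] += dmu;
      g[B + a] += dmu;
      g[B + 3 + a] += phi * (R::digamma(k + phi) - R::digamma(phi)
                             + std::log(phi) + 1.0 - std::log(phi + mu)
                             - (k + phi) / (phi + mu));
    }
  }
  return g;
}

static inline double gamma_lpdf_log(double theta, double a, double b,
                                    bool jacobian) {
  // log gamma density of x = exp(theta); with jacobian: density of theta
  const double x = std::exp(theta);
  double v = (a - 1.0) * theta - b * x + a * std::log(b) - std::lgamma(a);
  if (jacobian) v += theta;
  return v;
}

// [[Rcpp::export]]
double lp_variant_cpp(NumericVector theta,
                      NumericMatrix dna, NumericMatrix rna,
                      NumericVector dDna, NumericVector dRna,
                      IntegerVector allele,
                      NumericVector pshape, NumericVector prate,
                      bool jacobian) {
  const int B = dna.nrow();
  double lp = ll_variant_cpp(theta, dna, rna, dDna, dRna, allele);
  for (int b = 0; b < B; ++b)
    lp += gamma_lpdf_log(theta[b], pshape[0], prate[0], jacobian);
  lp += gamma_lpdf_log(theta[B],     pshape[1], prate[1], jacobian);
  lp += gamma_lpdf_log(theta[B + 1], pshape[2], prate[2], jacobian);
  lp += gamma_lpdf_log(theta[B + 2], pshape[3], prate[3], jacobian);
  lp += gamma_lpdf_log(theta[B + 3], pshape[4], prate[4], jacobian);
  lp += gamma_lpdf_log(theta[B + 4], pshape[4], prate[4], jacobian);
  return lp;
}

// [[Rcpp::export]]
NumericVector grad_lp_variant_cpp(NumericVector theta,
                                  NumericMatrix dna, NumericMatrix rna,
                                  NumericVector dDna, NumericVector dRna,
                                  IntegerVector allele,
                                  NumericVector pshape, NumericVector prate,
                                  bool jacobian) {
  const int B = dna.nrow();
  NumericVector g = grad_ll_variant_cpp(theta, dna, rna, dDna, dRna, allele);
  const double off = jacobian ? 0.0 : 1.0;
  for (int b = 0; b < B; ++b)
    g[b] += (pshape[0] - off) - prate[0] * std::exp(theta[b]);
  g[B]     += (pshape[1] - off) - prate[1] * std::exp(theta[B]);
  g[B + 1] += (pshape[2] - off) - prate[2] * std::exp(theta[B + 1]);
  g[B + 2] += (pshape[3] - off) - prate[3] * std::exp(theta[B + 2]);
  g[B + 3] += (pshape[4] - off) - prate[4] * std::exp(theta[B + 3]);
  g[B + 4] += (pshape[4] - off) - prate[4] * std::exp(theta[B + 4]);
  return g;
}

// --- componentwise slice sampler ------------------------------------------

struct VarModel {
  const NumericMatrix &dna, &rna;
  const NumericVector &dDna, &dRna;
  const IntegerVector &allele;
  const NumericVector &pshape, &prate;
  int B;

  // Conditional (unnormalized) log posterior in theta[j] (log scale, with
  // jacobian), restricted to terms depending on theta[j]. Because only
  // within-update differences matter for slice sampling, mu-updates drop
  // the count-and-dispersion-only lgamma terms of the NB pmf (the costly
  // part); phi-updates keep them.
  static inline double nb_mu_part(double k, double mu, double phi) {
    return k * std::log(mu) - (k + phi) * std::log(phi + mu);
  }
  static inline double nb_phi_part(double k, double mu, double phi) {
    return std::lgamma(k + phi) - std::lgamma(phi) + phi * std::log(phi)
      - (k + phi) * std::log(phi + mu);
  }
  double cond(int j, const NumericVector &theta) const {
    if (std::fabs(theta[j]) > THETA_MAX) return R_NegInf;
    const int Sd = dna.ncol(), Sr = rna.ncol();
    const double phiD = std::exp(theta[B + 2]);
    const double phiR[2] = { std::exp(theta[B + 3]), std::exp(theta[B + 4]) };
    const double muA[2]  = { std::exp(theta[B]),     std::exp(theta[B + 1]) };
    double lp = 0.0;
    if (j < B) {                       // one barcode's mu_DNA
      const double muD = std::exp(theta[j]);
      const int a = allele[j];
      for (int s = 0; s < Sd; ++s)
        lp += nb_mu_part(dna(j, s), dDna[s] * muD, phiD);
      for (int s = 0; s < Sr; ++s)
        lp += nb_mu_part(rna(j, s), dRna[s] * muD * muA[a], phiR[a]);
      lp += gamma_lpdf_log(theta[j], pshape[0], prate[0], true);
    } else if (j == B || j == B + 1) { // mu_allele
      const int a = j - B;
      for (int b = 0; b < B; ++b) {
        if (allele[b] != a) continue;
        const double muD = std::exp(theta[b]);
        for (int s = 0; s < Sr; ++s)
          lp += nb_mu_part(rna(b, s), dRna[s] * muD * muA[a], phiR[a]);
      }
      lp += gamma_lpdf_log(theta[j], pshape[1 + a], prate[1 + a], true);
    } else if (j == B + 2) {           // phi_DNA
      for (int b = 0; b < B; ++b) {
        const double muD = std::exp(theta[b]);
        for (int s = 0; s < Sd; ++s)
          lp += nb_phi_part(dna(b, s), dDna[s] * muD, phiD);
      }
      lp += gamma_lpdf_log(theta[j], pshape[3], prate[3], true);
    } else {                           // phi_RNA per allele
      const int a = j - (B + 3);
      for (int b = 0; b < B; ++b) {
        if (allele[b] != a) continue;
        const double muD = std::exp(theta[b]);
        for (int s = 0; s < Sr; ++s)
          lp += nb_phi_part(rna(b, s), dRna[s] * muD * muA[a], phiR[a]);
      }
      lp += gamma_lpdf_log(theta[j], pshape[4], prate[4], true);
    }
    return lp;
  }
};

// one univariate slice update (Neal 2003, stepping out + shrinkage);
// returns the absolute accepted move (for width tuning)
static double slice_update(int j, NumericVector &theta, const VarModel &m,
                           double w, int maxSteps) {
  const double x0 = theta[j];
  const double f0 = m.cond(j, theta);
  if (!R_finite(f0)) return 0.0;
  const double y = f0 - R::exp_rand();
  const double u = R::unif_rand();
  double L = x0 - w * u, R_ = x0 + w * (1.0 - u);
  int jL = (int)std::floor(maxSteps * R::unif_rand());
  int jR = maxSteps - 1 - jL;
  theta[j] = L;
  while (jL-- > 0 && m.cond(j, theta) > y) { L -= w; theta[j] = L; }
  theta[j] = R_;
  while (jR-- > 0 && m.cond(j, theta) > y) { R_ += w; theta[j] = R_; }
  for (int it = 0; it < 1000; ++it) {
    const double x1 = L + R::unif_rand() * (R_ - L);
    theta[j] = x1;
    if (m.cond(j, theta) >= y) return std::fabs(x1 - x0);
    if (x1 < x0) L = x1; else R_ = x1;
  }
  theta[j] = x0; // shrinkage exhausted (numerically degenerate slice)
  return 0.0;
}

// Run one chain; returns (iter x p) matrix of post-warmup draws.
// Uses R's RNG stream, so set.seed() in R makes chains reproducible.
// Per-coordinate stepping-out widths are tuned from the accepted slice
// sizes over the first half of warmup.
// [[Rcpp::export]]
NumericMatrix slice_sample_variant_cpp(NumericVector theta0,
                                       NumericMatrix dna, NumericMatrix rna,
                                       NumericVector dDna, NumericVector dRna,
                                       IntegerVector allele,
                                       NumericVector pshape, NumericVector prate,
                                       int warmup, int iter,
                                       double w, int maxSteps) {
  const int p = theta0.size();
  VarModel m{dna, rna, dDna, dRna, allele, pshape, prate, dna.nrow()};
  NumericVector theta = clone(theta0);
  NumericMatrix out(iter, p);
  std::vector<double> wj(p, w), moveSum(p, 0.0);
  const int tuneEnd = std::max(warmup / 2, 1);
  for (int t = 0; t < warmup + iter; ++t) {
    for (int j = 0; j < p; ++j) {
      const double sz = slice_update(j, theta, m, wj[j], maxSteps);
      if (t < tuneEnd) moveSum[j] += sz;
    }
    if (t == tuneEnd - 1)
      for (int j = 0; j < p; ++j)
        wj[j] = std::min(std::max(4.0 * moveSum[j] / tuneEnd, 0.05), w * 5);
    if (t >= warmup)
      for (int j = 0; j < p; ++j) out(t - warmup, j) = theta[j];
  }
  return out;
}

// Grid scan for the pseudo-significance score: smallest grid mass whose
// shortest-window HDI (lowest start on ties) contains zero.
// x must be sorted ascending. Returns that mass, or the largest grid mass
// when no HDI contains zero.
// [[Rcpp::export]]
double min_hdi_mass_zero_cpp(NumericVector x, double gridStep) {
  const int n = x.size();
  const int nGrid = (int)std::floor((1.0 - gridStep) / gridStep + 1e-9);
  double q = nGrid * gridStep;
  for (int g = 1; g <= nGrid; ++g) {
    const double qq = g * gridStep;
    // the 1e-9 guard pins ceil() against floating-point jitter in qq * n
    const int m = (int)std::ceil(qq * n - 1e-9);
    int jbest = 0;
    double wbest = R_PosInf;
    for (int j = 0; j + m - 1 < n; ++j) {
      const double wd = x[j + m - 1] - x[j];
      if (wd < wbest) { wbest = wd; jbest = j; }
    }
    if (x[jbest] <= 0.0 && x[jbest + m - 1] >= 0.0) { q = qq; break; }
  }
  return q;
}

// Fused value + gradient, for optimizer use (halves the C++ work per
// optimizer iteration relative to separate calls).
// [[Rcpp::export]]
List lp_value_grad_cpp(NumericVector theta,
                       NumericMatrix dna, NumericMatrix rna,
                       NumericVector dDna, NumericVector dRna,
                       IntegerVector allele,
                       NumericVector pshape, NumericVector prate,
                       bool usePrior, bool jacobian) {
  double v;
  NumericVector g;
  if (usePrior) {
    v = lp_variant_cpp(theta, dna, rna, dDna, dRna, allele, pshape, prate,
                       jacobian);
    g = grad_lp_variant_cpp(theta, dna, rna, dDna, dRna, allele, pshape,
                            prate, jacobian);
  } else {
    v = ll_variant_cpp(theta, dna, rna, dDna, dRna, allele);
    g = grad_ll_variant_cpp(theta, dna, rna, dDna, dRna, allele);
  }
  return List::create(_["value"] = v, _["grad"] = g);
}
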