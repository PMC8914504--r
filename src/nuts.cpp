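// No-U-Turn Sampler for the sex-hierarchical Bayesian logistic regression.
//
// Model (all on the standardized design scale):
//   y_i ~ Bernoulli(logit^-1(eta_i))
//   eta_i = alpha + sum_j W_ij * beta_{j, sex(i)} + C_i . gamma
//   beta_{j,s} = mu_j + tau_j * z_{j,s}        (non-centred)
//   alpha ~ N(0, sAlpha), gamma ~ N(0, sGamma), mu_j ~ N(0, sMu),
//   tau_j ~ HalfNormal(sTau) (sampled as log tau with Jacobian), z ~ N(0,1)
//
// Sampler: NUTS with slice-sampled trees (Hoffman & Gelman 2014, Alg. 6),
// dual-averaging step-size adaptation and a single diagonal mass-matrix
// update mid-warmup. All randomness comes from R's RNG, so set.seed() in R
// makes a chain fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  std::vector<double> Wr;  // n x k standardized expressions, row-major
  std::vector<double> Cr;  // n x q covariates, row-major
  std::vector<int> y;      // 0/1 outcome
  std::vector<int> female; // 0/1
  int n, k, q, dim;
  double sAlpha, sGamma, sMu, sTau;
  // parameter layout
  int iA, iG, iMu, iLt, iZm, iZf;

  Model(NumericMatrix W_, NumericMatrix C_, IntegerVector y_,
        IntegerVector female_, double sAlpha_, double sGamma_, double sMu_,
        double sTau_)
      : n(W_.nrow()), k(W_.ncol()), q(C_.ncol()), sAlpha(sAlpha_),
        sGamma(sGamma_), sMu(sMu_), sTau(sTau_) {
    Wr.resize((size_t)n * k);
    Cr.resize((size_t)n * q);
    y.resize(n);
    female.resize(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) Wr[(size_t)i * k + j] = W_(i, j);
      for (int c = 0; c < q; ++c) Cr[(size_t)i * q + c] = C_(i, c);
      y[i] = y_[i];
      female[i] = female_[i];
    }
    iA = 0;
    iG = 1;
    iMu = 1 + q;
    iLt = 1 + q + k;
    iZm = 1 + q + 2 * k;
    iZf = 1 + q + 3 * k;
    dim = 1 + q + 4 * k;
  }

  static double softplus(double x) {
    return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
  }

  // log posterior density (unnormalized) and gradient
  double logpGrad(const std::vector<double>& th, std::vector<double>& g) const {
    std::fill(g.begin(), g.end(), 0.0);
    const double alpha = th[iA];
    std::vector<double> tau(k), bm(k), bf(k);
    for (int j = 0; j < k; ++j) {
      tau[j] = std::exp(th[iLt + j]);
      bm[j] = th[iMu + j] + tau[j] * th[iZm + j];
      bf[j] = th[iMu + j] + tau[j] * th[iZf + j];
    }
    double lp = 0.0;
    std::vector<double> dbm(k, 0.0), dbf(k, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* wi = &Wr[(size_t)i * k];
      const double* ci = &Cr[(size_t)i * q];
      const bool fem = female[i] == 1;
      const double* b = fem ? bf.data() : bm.data();
      double* db = fem ? dbf.data() : dbm.data();
      double eta = alpha;
      for (int j = 0; j < k; ++j) eta += wi[j] * b[j];
      for (int c = 0; c < q; ++c) eta += ci[c] * th[iG + c];
      // one exp per observation serves both log-lik and gradient
      double r, llik;
      if (eta > 0) {
        const double e = std::exp(-eta);
        llik = y[i] * eta - eta - std::log1p(e);
        r = y[i] - 1.0 / (1.0 + e);
      } else {
        const double e = std::exp(eta);
        llik = y[i] * eta - std::log1p(e);
        r = y[i] - e / (1.0 + e);
      }
      lp += llik;
      g[iA] += r;
      for (int c = 0; c < q; ++c) g[iG + c] += ci[c] * r;
      for (int j = 0; j < k; ++j) db[j] += wi[j] * r;
    }
    // priors
    lp += -0.5 * alpha * alpha / (sAlpha * sAlpha);
    g[iA] += -alpha / (sAlpha * sAlpha);
    for (int c = 0; c < q; ++c) {
      lp += -0.5 * th[iG + c] * th[iG + c] / (sGamma * sGamma);
      g[iG + c] += -th[iG + c] / (sGamma * sGamma);
    }
    for (int j = 0; j < k; ++j) {
      const double mu = th[iMu + j], zm = th[iZm + j], zf = th[iZf + j];
      lp += -0.5 * mu * mu / (sMu * sMu) - 0.5 * zm * zm - 0.5 * zf * zf;
      // HalfNormal(sTau) on tau with log-scale Jacobian (+ log tau)
      lp += -0.5 * tau[j] * tau[j] / (sTau * sTau) + th[iLt + j];
      g[iMu + j] += dbm[j] + dbf[j] - mu / (sMu * sMu);
      g[iZm + j] += dbm[j] * tau[j] - zm;
      g[iZf + j] += dbf[j] * tau[j] - zf;
      g[iLt + j] += (dbm[j] * zm + dbf[j] * zf) * tau[j] -
                    tau[j] * tau[j] / (sTau * sTau) + 1.0;
    }
    if (!std::isfinite(lp)) lp = -std::numeric_limits<double>::infinity();
    return lp;
  }
};

struct Sampler {
  const Model& m;
  std::vector<double> invMass;  // diagonal inverse mass = posterior var est
  double maxDeltaH = 1000.0;
  int divergences = 0;

  explicit Sampler(const Model& m_) : m(m_), invMass(m_.dim, 1.0) {}

  double kinetic(const std::vector<double>& p) const {
    double s = 0.0;
    for (int d = 0; d < m.dim; ++d) s += p[d] * p[d] * invMass[d];
    return 0.5 * s;
  }

  void samplePmomentum(std::vector<double>& p) const {
    for (int d = 0; d < m.dim; ++d) p[d] = norm_rand() / std::sqrt(invMass[d]);
  }

  // one leapfrog step; returns log posterior at the new point
  double leapfrog(std::vector<double>& th, std::vector<double>& p,
                  std::vector<double>& grad, double eps) const {
    for (int d = 0; d < m.dim; ++d) p[d] += 0.5 * eps * grad[d];
    for (int d = 0; d < m.dim; ++d) th[d] += eps * invMass[d] * p[d];
    double lp = m.logpGrad(th, grad);
    for (int d = 0; d < m.dim; ++d) p[d] += 0.5 * eps * grad[d];
    return lp;
  }

  struct Tree {
    std::vector<double> thMinus, pMinus, gMinus;
    std::vector<double> thPlus, pPlus, gPlus;
    std::vector<double> thProp;
    double nProp = 0.0;
    bool ok = true;
    double sumAccept = 0.0;
    int nAccept = 0;
  };

  void buildTree(const std::vector<double>& th, const std::vector<double>& p,
                 const std::vector<double>& g, double logu, int dir, int depth,
                 double eps, double joint0, Tree& out) {
    if (depth == 0) {
      out.thMinus = th;
      out.pMinus = p;
      out.gMinus = g;
      double lp = leapfrog(out.thMinus, out.pMinus, out.gMinus, dir * eps);
      double joint = lp - kinetic(out.pMinus);
      out.thPlus = out.thMinus;
      out.pPlus = out.pMinus;
      out.gPlus = out.gMinus;
      out.thProp = out.thMinus;
      out.nProp = (logu <= joint) ? 1.0 : 0.0;
      out.ok = (logu < joint + maxDeltaH);
      if (!out.ok) ++divergences;
      double a = std::exp(std::min(0.0, joint - joint0));
      out.sumAccept = std::isfinite(a) ? a : 0.0;
      out.nAccept = 1;
      return;
    }
    buildTree(th, p, g, logu, dir, depth - 1, eps, joint0, out);
    if (!out.ok) return;
    Tree sub;
    if (dir == -1) {
      buildTree(out.thMinus, out.pMinus, out.gMinus, logu, dir, depth - 1, eps,
                joint0, sub);
      out.thMinus = sub.thMinus;
      out.pMinus = sub.pMinus;
      out.gMinus = sub.gMinus;
    } else {
      buildTree(out.thPlus, out.pPlus, out.gPlus, logu, dir, depth - 1, eps,
                joint0, sub);
      out.thPlus = sub.thPlus;
      out.pPlus = sub.pPlus;
      out.gPlus = sub.gPlus;
    }
    if (sub.ok && sub.nProp > 0 &&
        unif_rand() < sub.nProp / (out.nProp + sub.nProp)) {
      out.thProp = sub.thProp;
    }
    out.nProp += sub.nProp;
    out.sumAccept += sub.sumAccept;
    out.nAccept += sub.nAccept;
    out.ok = out.ok && sub.ok && noUTurn(out.thMinus, out.thPlus, out.pMinus,
                                         out.pPlus);
  }

  bool noUTurn(const std::vector<double>& thm, const std::vector<double>& thp,
               const std::vector<double>& pm,
               const std::vector<double>& pp) const {
    double a = 0.0, b = 0.0;
    for (int d = 0; d < m.dim; ++d) {
      double dth = thp[d] - thm[d];
      a += dth * invMass[d] * pm[d];
      b += dth * invMass[d] * pp[d];
    }
    return a >= 0.0 && b >= 0.0;
  }

  // one NUTS transition; returns average acceptance statistic
  double transition(std::vector<double>& th, double eps, int maxDepth) {
    std::vector<double> p(m.dim), g(m.dim);
    double lp = m.logpGrad(th, g);
    samplePmomentum(p);
    double joint0 = lp - kinetic(p);
    double logu = joint0 + std::log(unif_rand());
    Tree t;
    t.thMinus = th;
    t.pMinus = p;
    t.gMinus = g;
    t.thPlus = th;
    t.pPlus = p;
    t.gPlus = g;
    t.thProp = th;
    t.nProp = 1.0;
    double sumAccept = 0.0;
    int nAccept = 0;
    for (int depth = 0; depth < maxDepth; ++depth) {
      int dir = unif_rand() < 0.5 ? -1 : 1;
      Tree sub;
      if (dir == -1) {
        buildTree(t.thMinus, t.pMinus, t.gMinus, logu, dir, depth, eps, joint0,
                  sub);
        if (sub.ok || sub.nProp > 0) {
          t.thMinus = sub.thMinus;
          t.pMinus = sub.pMinus;
          t.gMinus = sub.gMinus;
        }
      } else {
        buildTree(t.thPlus, t.pPlus, t.gPlus, logu, dir, depth, eps, joint0,
                  sub);
        if (sub.ok || sub.nProp > 0) {
          t.thPlus = sub.thPlus;
          t.pPlus = sub.pPlus;
          t.gPlus = sub.gPlus;
        }
      }
      sumAccept += sub.sumAccept;
      nAccept += sub.nAccept;
      if (sub.ok && sub.nProp > 0 &&
          unif_rand() < std::min(1.0, sub.nProp / t.nProp)) {
        t.thProp = sub.thProp;
      }
      t.nProp += sub.nProp;
      if (!sub.ok ||
          !noUTurn(t.thMinus, t.thPlus, t.pMinus, t.pPlus))
        break;
    }
    th = t.thProp;
    return nAccept > 0 ? sumAccept / nAccept : 0.0;
  }

  double findInitialStepsize(std::vector<double>& th) {
    double eps = 0.1;
    std::vector<double> p(m.dim), g(m.dim);
    double lp = m.logpGrad(th, g);
    samplePmomentum(p);
    double joint0 = lp - kinetic(p);
    std::vector<double> th1 = th, p1 = p, g1 = g;
    double lp1 = leapfrog(th1, p1, g1, eps);
    double dj = (lp1 - kinetic(p1)) - joint0;
    double a = dj > std::log(0.5) ? 1.0 : -1.0;
    for (int iter = 0; iter < 50; ++iter) {
      th1 = th;
      p1 = p;
      g1 = g;
      lp1 = leapfrog(th1, p1, g1, eps);
      dj = (lp1 - kinetic(p1)) - joint0;
      if (!std::isfinite(dj)) dj = -std::numeric_limits<double>::infinity();
      if (a * dj <= a * std::log(0.5)) break;
      eps *= std::pow(2.0, a);
    }
    return eps;
  }
};

}  // namespace

// [[Rcpp::export(name = ".nutsChain")]]
List nutsChain(NumericMatrix W, NumericMatrix C, IntegerVector y,
               IntegerVector female, int warmup, int iter, double targetAccept,
               int maxDepth, double sAlpha, double sGamma, double sMu,
               double sTau) {
  Model model(W, C, y, female, sAlpha, sGamma, sMu, sTau);
  Sampler sampler(model);
  GetRNGstate();

  std::vector<double> th(model.dim, 0.0);
  for (int d = 0; d < model.dim; ++d) th[d] = 0.1 * norm_rand();
  // keep log tau from starting too far into the funnel
  for (int j = 0; j < model.k; ++j) th[model.iLt + j] = -1.0 + 0.1 * norm_rand();

  // dual averaging (Hoffman & Gelman 2014)
  double eps = sampler.findInitialStepsize(th);
  double mu = std::log(10.0 * eps), logEpsBar = 0.0, hBar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int daIter = 0;

  // Welford accumulator for the diagonal mass update
  std::vector<double> wMean(model.dim, 0.0), wM2(model.dim, 0.0);
  int wN = 0;
  const int collectFrom = std::max(25, warmup / 10);
  const int massUpdateAt = std::max(collectFrom + 25, warmup / 2);

  NumericMatrix draws(iter, model.dim);
  int divergencesPost = 0;

  for (int it = 1; it <= warmup + iter; ++it) {
    bool inWarmup = it <= warmup;
    int divBefore = sampler.divergences;
    double accept = sampler.transition(th, eps, maxDepth);
    if (!inWarmup && sampler.divergences > divBefore)
      divergencesPost += sampler.divergences - divBefore;

    if (inWarmup) {
      ++daIter;
      hBar = (1.0 - 1.0 / (daIter + t0)) * hBar +
             (targetAccept - accept) / (daIter + t0);
      double logEps = mu - std::sqrt((double)daIter) / gamma * hBar;
      eps = std::exp(logEps);
      double w = std::pow((double)daIter, -kappa);
      logEpsBar = w * logEps + (1.0 - w) * logEpsBar;

      if (it > collectFrom && it <= massUpdateAt) {
        ++wN;
        for (int d = 0; d < model.dim; ++d) {
          double delta = th[d] - wMean[d];
          wMean[d] += delta / wN;
          wM2[d] += delta * (th[d] - wMean[d]);
        }
      }
      if (it == massUpdateAt && wN > 10) {
        for (int d = 0; d < model.dim; ++d) {
          double v = wM2[d] / (wN - 1);
          sampler.invMass[d] =
              (wN / (wN + 5.0)) * v + 1e-3 * (5.0 / (wN + 5.0));
        }
        // restart step-size adaptation around the current step size
        eps = std::exp(logEpsBar);
        eps = sampler.findInitialStepsize(th);
        mu = std::log(10.0 * eps);
        hBar = 0.0;
        logEpsBar = std::log(eps);
        daIter = 0;
      }
      if (it == warmup) eps = std::exp(logEpsBar);
    } else {
      draws(it - warmup - 1, _) = NumericVector(th.begin(), th.end());
    }
  }
  PutRNGstate();

  return List::create(
      _["draws"] = draws, _["stepsize"] = eps,
      _["divergences"] = divergencesPost,
      _["divergences_total"] = sampler.divergences);
}
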