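// Joint log density, analytic gradient, and No-U-Turn sampler for the
// horseshoe-process regression model.
//
// Unconstrained parameter vector q (dimension D), with M = m - 1 increments:
//   q[0]            alpha_raw            ~ N(0,1),  alpha = a + b * alpha_raw
//   q[1]            tau1                 ~ N(0,1)
//   q[2]            log(tau2),  tau2     ~ InvGamma(1/2, 1/2)
//   q[3 .. 3+M-1]   lambda1_k            ~ N(0,1)
//   q[3+M .. ]      log(lambda2_k)       ~ InvGamma(1/2, 1/2)
//   q[3+2M .. ]     gamma_k              ~ N(0,1)
//   (Gaussian only) sigma1 ~ N(0,1), log(sigma2) with sigma2 ~ InvGamma(1/2,1/2)
//   (p > 0)         beta_raw_l           ~ N(0,1),  beta_l = d_l * beta_raw_l
//
// Model-space transforms (half-Cauchy via normal / sqrt-inverse-gamma):
//   tau    = c * |tau1| * sqrt(tau2)            ~ C+(0, c)
//   lam_k  = |lambda1_k| * sqrt(lambda2_k)      ~ C+(0, 1)
//   sigma  = s * |sigma1| * sqrt(sigma2)        ~ C+(0, s)
//   h_k    = gamma_k * tau * lam_k * sqrt(t_k - t_{k-1})
//   f_j    = alpha + sum_{k<=j} h_k   (or +|h_k| / -|h_k| under monotonicity)
//
// The density includes the log-Jacobian of the log transforms, so it is the
// correct target over q.  All normalizing constants are kept so the value can
// be checked term-by-term against an R-side evaluation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

const double HALF_LOG_2PI = 0.91893853320467274178;
// InvGamma(1/2, 1/2) normalizing constant: a*log(b) - lgamma(a)
const double IG_CONST = 0.5 * std::log(0.5) - std::lgamma(0.5);
const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Model {
  int n, m, p;
  int family;      // 0 gaussian, 1 bernoulli, 2 poisson
  int constraint;  // 0 none, 1 increasing, -1 decreasing
  std::vector<double> y;
  std::vector<int> obs0;       // 0-based grid index per observation
  std::vector<double> sqd;     // sqrt(t_k - t_{k-1}), length m - 1
  std::vector<double> Z;       // n x p, column-major
  double a, b, c, s;
  std::vector<double> d;

  int M() const { return m - 1; }
  int dim() const { return 3 + 3 * (m - 1) + (family == 0 ? 2 : 0) + p; }
  int off_sigma() const { return 3 + 3 * (m - 1); }
  int off_beta() const { return off_sigma() + (family == 0 ? 2 : 0); }
};

Model make_model(const List& spec) {
  Model mod;
  NumericVector y = spec["y"];
  IntegerVector oi = spec["obs_index"];   // 1-based from R
  NumericVector delta = spec["delta"];
  NumericMatrix Z = spec["Z"];
  mod.n = y.size();
  mod.m = delta.size() + 1;
  mod.p = Z.ncol();
  mod.family = as<int>(spec["family"]);
  mod.constraint = as<int>(spec["constraint"]);
  mod.y.assign(y.begin(), y.end());
  mod.obs0.resize(mod.n);
  for (int i = 0; i < mod.n; ++i) mod.obs0[i] = oi[i] - 1;
  mod.sqd.resize(mod.M());
  for (int k = 0; k < mod.M(); ++k) mod.sqd[k] = std::sqrt(delta[k]);
  mod.Z.assign(Z.begin(), Z.end());
  mod.a = as<double>(spec["a"]);
  mod.b = as<double>(spec["b"]);
  mod.c = as<double>(spec["c"]);
  mod.s = as<double>(spec["s"]);
  NumericVector d = spec["d"];
  mod.d.assign(d.begin(), d.end());
  return mod;
}

inline double sgn(double x) { return (x > 0) - (x < 0); }

// log target and gradient; returns -Inf on numerical failure
double lp_grad(const Model& mod, const std::vector<double>& q,
               std::vector<double>& grad) {
  const int m = mod.m, M = mod.M(), p = mod.p, n = mod.n;
  std::fill(grad.begin(), grad.end(), 0.0);
  double lp = 0.0;

  // standard-normal prior on an unconstrained coordinate
  auto npr = [&](int idx) {
    lp += -0.5 * q[idx] * q[idx] - HALF_LOG_2PI;
    grad[idx] += -q[idx];
  };
  // InvGamma(1/2,1/2) on v = exp(u), including the Jacobian term +u:
  // log p(u) = IG_CONST - 1.5*u - 0.5*exp(-u) + u
  auto igpr = [&](int idx) {
    double e = std::exp(-q[idx]);
    lp += IG_CONST - 0.5 * q[idx] - 0.5 * e;
    grad[idx] += -0.5 + 0.5 * e;
  };

  npr(0); npr(1); igpr(2);
  for (int k = 0; k < M; ++k) { npr(3 + k); igpr(3 + M + k); npr(3 + 2 * M + k); }
  const int isig = mod.off_sigma();
  if (mod.family == 0) { npr(isig); igpr(isig + 1); }
  const int ibeta = mod.off_beta();
  for (int l = 0; l < p; ++l) npr(ibeta + l);

  // transforms
  const double alpha = mod.a + mod.b * q[0];
  const double st2 = std::exp(0.5 * q[2]);
  const double tau = mod.c * std::fabs(q[1]) * st2;
  std::vector<double> lam(M), h(M), fs(m);
  for (int k = 0; k < M; ++k) {
    lam[k] = std::fabs(q[3 + k]) * std::exp(0.5 * q[3 + M + k]);
    h[k] = q[3 + 2 * M + k] * tau * lam[k] * mod.sqd[k];
  }
  fs[0] = alpha;
  for (int k = 0; k < M; ++k) {
    double sk = (mod.constraint == 0) ? h[k]
              : (mod.constraint == 1 ? std::fabs(h[k]) : -std::fabs(h[k]));
    fs[k + 1] = fs[k] + sk;
  }
  double sigma = 1.0;
  if (mod.family == 0) {
    sigma = mod.s * std::fabs(q[isig]) * std::exp(0.5 * q[isig + 1]);
    if (!(sigma > 0.0)) return NEG_INF;
  }
  std::vector<double> beta(p);
  for (int l = 0; l < p; ++l) beta[l] = mod.d[l] * q[ibeta + l];

  // likelihood and dL/deta
  std::vector<double> deta(n);
  double dLdsigma = 0.0;
  const double inv_s2 = (mod.family == 0) ? 1.0 / (sigma * sigma) : 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = fs[mod.obs0[i]];
    for (int l = 0; l < p; ++l) eta += beta[l] * mod.Z[(size_t)l * n + i];
    const double yi = mod.y[i];
    if (mod.family == 0) {
      double r = yi - eta;
      lp += -std::log(sigma) - HALF_LOG_2PI - 0.5 * r * r * inv_s2;
      deta[i] = r * inv_s2;
      dLdsigma += -1.0 / sigma + r * r * inv_s2 / sigma;
    } else if (mod.family == 1) {
      double lse = (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                               : std::log1p(std::exp(eta));
      lp += yi * eta - lse;
      deta[i] = yi - 1.0 / (1.0 + std::exp(-eta));
    } else {
      double mu = std::exp(eta);
      lp += yi * eta - mu - std::lgamma(yi + 1.0);
      deta[i] = yi - mu;
    }
  }
  if (!std::isfinite(lp)) return NEG_INF;

  // backpropagate dL/deta through f
  std::vector<double> G(m, 0.0);
  for (int i = 0; i < n; ++i) G[mod.obs0[i]] += deta[i];
  double sumG = 0.0;
  for (int j = 0; j < m; ++j) sumG += G[j];
  grad[0] += mod.b * sumG;

  // increment k enters f_j for all j >= k+1: reverse cumulative sum of G
  double run = 0.0, dLdtau = 0.0;
  for (int k = M - 1; k >= 0; --k) {
    run += G[k + 1];
    double dLdh = run;
    if (mod.constraint != 0)
      dLdh = (mod.constraint == 1 ? 1.0 : -1.0) * run * sgn(h[k]);
    const double gk = q[3 + 2 * M + k];
    grad[3 + 2 * M + k] += dLdh * tau * lam[k] * mod.sqd[k];
    dLdtau += dLdh * gk * lam[k] * mod.sqd[k];
    const double dLdlam = dLdh * gk * tau * mod.sqd[k];
    grad[3 + k] += dLdlam * sgn(q[3 + k]) * std::exp(0.5 * q[3 + M + k]);
    grad[3 + M + k] += dLdlam * 0.5 * lam[k];
  }
  grad[1] += dLdtau * mod.c * sgn(q[1]) * st2;
  grad[2] += dLdtau * 0.5 * tau;
  if (mod.family == 0) {
    grad[isig] += dLdsigma * mod.s * sgn(q[isig]) * std::exp(0.5 * q[isig + 1]);
    grad[isig + 1] += dLdsigma * 0.5 * sigma;
  }
  for (int l = 0; l < p; ++l) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += deta[i] * mod.Z[(size_t)l * n + i];
    grad[ibeta + l] += mod.d[l] * acc;
  }
  return lp;
}

// ---------------------------------------------------------------- NUTS ----

struct PS {  // phase-space point
  std::vector<double> q, p, g;
  double lp;
};

double kinetic(const std::vector<double>& p, const std::vector<double>& invm) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += p[i] * p[i] * invm[i];
  return 0.5 * k;
}

bool leapfrog(const Model& mod, PS& z, double eps,
              const std::vector<double>& invm) {
  const int D = (int)z.q.size();
  for (int i = 0; i < D; ++i) z.p[i] += 0.5 * eps * z.g[i];
  for (int i = 0; i < D; ++i) z.q[i] += eps * invm[i] * z.p[i];
  z.lp = lp_grad(mod, z.q, z.g);
  if (!std::isfinite(z.lp)) return false;
  for (int i = 0; i < D; ++i) z.p[i] += 0.5 * eps * z.g[i];
  return true;
}

struct Tree {
  PS zminus, zplus;            // trajectory endpoints (backward / forward)
  std::vector<double> qprop;
  double lpprop;
  double nvalid;               // number of slice-valid leaves
  bool ok;                     // no divergence, no sub-u-turn
  bool divergent;
  double asum;                 // accumulated acceptance statistic
  int acount;
};

bool uturn(const PS& zminus, const PS& zplus, const std::vector<double>& invm) {
  double dmin = 0.0, dplus = 0.0;
  for (size_t i = 0; i < zminus.q.size(); ++i) {
    double dq = zplus.q[i] - zminus.q[i];
    dmin += dq * invm[i] * zminus.p[i];
    dplus += dq * invm[i] * zplus.p[i];
  }
  return (dmin < 0.0) || (dplus < 0.0);
}

void build_tree(const Model& mod, const PS& z0, double logu, int dir, int depth,
                double eps, const std::vector<double>& invm, double joint0,
                Tree& tree) {
  if (depth == 0) {
    PS z = z0;
    bool okstep = leapfrog(mod, z, dir * eps, invm);
    double joint = okstep ? (z.lp - kinetic(z.p, invm)) : NEG_INF;
    tree.zminus = z;
    tree.zplus = z;
    tree.qprop = z.q;
    tree.lpprop = z.lp;
    tree.nvalid = (logu <= joint) ? 1.0 : 0.0;
    tree.divergent = !(logu - joint <= 1000.0);   // catches NaN / -Inf too
    tree.ok = !tree.divergent;
    double da = joint - joint0;
    tree.asum = std::isfinite(da) ? std::min(1.0, std::exp(da)) : 0.0;
    tree.acount = 1;
    return;
  }
  Tree t1;
  build_tree(mod, z0, logu, dir, depth - 1, eps, invm, joint0, t1);
  if (!t1.ok) { tree = t1; return; }
  Tree t2;
  build_tree(mod, (dir == 1) ? t1.zplus : t1.zminus, logu, dir, depth - 1, eps,
             invm, joint0, t2);
  tree.zminus = (dir == 1) ? t1.zminus : t2.zminus;
  tree.zplus = (dir == 1) ? t2.zplus : t1.zplus;
  double ntot = t1.nvalid + t2.nvalid;
  if (t2.nvalid > 0.0 && unif_rand() * ntot < t2.nvalid) {
    tree.qprop = t2.qprop;
    tree.lpprop = t2.lpprop;
  } else {
    tree.qprop = t1.qprop;
    tree.lpprop = t1.lpprop;
  }
  tree.nvalid = ntot;
  tree.divergent = t1.divergent || t2.divergent;
  tree.ok = t2.ok && !uturn(tree.zminus, tree.zplus, invm);
  tree.asum = t1.asum + t2.asum;
  tree.acount = t1.acount + t2.acount;
}

// One NUTS transition; returns updated state in z, fills stats
void nuts_transition(const Model& mod, PS& z, double eps,
                     const std::vector<double>& invm, int max_treedepth,
                     bool& divergent, bool& hit_max, double& accept_stat,
                     int& n_leapfrog) {
  const int D = (int)z.q.size();
  PS cur = z;
  for (int i = 0; i < D; ++i) cur.p[i] = norm_rand() / std::sqrt(invm[i]);
  const double joint0 = cur.lp - kinetic(cur.p, invm);
  const double logu = joint0 - exp_rand();

  PS zminus = cur, zplus = cur;
  std::vector<double> qsel = cur.q, gsel = cur.g;
  double lpsel = cur.lp;
  double nvalid = 1.0;
  bool s = true;
  divergent = false;
  hit_max = false;
  double asum = 0.0;
  int acount = 0;
  n_leapfrog = 0;

  int depth = 0;
  while (s && depth < max_treedepth) {
    int dir = (unif_rand() < 0.5) ? -1 : 1;
    Tree tree;
    build_tree(mod, (dir == 1) ? zplus : zminus, logu, dir, depth, eps, invm,
               joint0, tree);
    n_leapfrog += tree.acount;
    asum += tree.asum;
    acount += tree.acount;
    if (tree.divergent) divergent = true;
    if (tree.ok) {
      if (tree.nvalid > 0.0 && unif_rand() * nvalid < tree.nvalid) {
        qsel = tree.qprop;
        lpsel = tree.lpprop;
      }
    }
    nvalid += tree.nvalid;
    if (dir == 1) zplus = tree.zplus; else zminus = tree.zminus;
    s = tree.ok && !uturn(zminus, zplus, invm);
    ++depth;
  }
  if (depth == max_treedepth && s) hit_max = true;
  accept_stat = (acount > 0) ? asum / acount : 0.0;

  z.q = qsel;
  z.lp = lp_grad(mod, z.q, z.g);
}

double find_reasonable_eps(const Model& mod, const PS& z0,
                           const std::vector<double>& invm) {
  double eps = 1.0;
  const int D = (int)z0.q.size();
  PS z = z0;
  for (int i = 0; i < D; ++i) z.p[i] = norm_rand() / std::sqrt(invm[i]);
  const double joint0 = z.lp - kinetic(z.p, invm);
  PS zt = z;
  bool okstep = leapfrog(mod, zt, eps, invm);
  double joint = okstep ? (zt.lp - kinetic(zt.p, invm)) : NEG_INF;
  double diff = joint - joint0;
  if (!std::isfinite(diff)) diff = NEG_INF;
  const double dir = (diff > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 100; ++it) {
    zt = z;
    okstep = leapfrog(mod, zt, eps, invm);
    joint = okstep ? (zt.lp - kinetic(zt.p, invm)) : NEG_INF;
    diff = joint - joint0;
    if (!std::isfinite(diff)) diff = NEG_INF;
    if (dir == 1.0 && !(diff > std::log(0.5))) break;
    if (dir == -1.0 && !(diff < std::log(0.5))) break;
    eps *= (dir == 1.0) ? 2.0 : 0.5;
    if (eps > 1e7 || eps < 1e-10) break;
  }
  return eps;
}

struct DualAverage {
  double mu, log_eps, log_eps_bar, hbar;
  int counter;
  double delta;
  static constexpr double gamma_ = 0.05, t0_ = 10.0, kappa_ = 0.75;

  void restart(double eps, double target) {
    mu = std::log(10.0 * eps);
    log_eps = std::log(eps);
    log_eps_bar = 0.0;
    hbar = 0.0;
    counter = 0;
    delta = target;
  }
  double update(double accept) {
    ++counter;
    double eta = 1.0 / (counter + t0_);
    hbar = (1.0 - eta) * hbar + eta * (delta - accept);
    log_eps = mu - std::sqrt((double)counter) / gamma_ * hbar;
    double w = std::pow((double)counter, -kappa_);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
    return std::exp(log_eps);
  }
  double final_eps() const { return std::exp(log_eps_bar); }
};

struct Welford {
  std::vector<double> mean, m2;
  int n;
  void init(int D) { mean.assign(D, 0.0); m2.assign(D, 0.0); n = 0; }
  void add(const std::vector<double>& x) {
    ++n;
    for (size_t i = 0; i < x.size(); ++i) {
      double d = x[i] - mean[i];
      mean[i] += d / n;
      m2[i] += d * (x[i] - mean[i]);
    }
  }
  // regularized variance estimate (shrunk toward unit scale)
  void variance(std::vector<double>& v) const {
    for (size_t i = 0; i < mean.size(); ++i) {
      double var = (n > 1) ? m2[i] / (n - 1) : 1.0;
      v[i] = (n / (n + 5.0)) * var + 1e-3 * (5.0 / (n + 5.0));
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".hpr_lp_grad")]]
List hpr_lp_grad(List model_spec, NumericVector q) {
  Model mod = make_model(model_spec);
  if ((int)q.size() != mod.dim())
    stop("parameter vector has length %d, expected %d", q.size(), mod.dim());
  std::vector<double> qv(q.begin(), q.end()), grad(mod.dim());
  double lp = lp_grad(mod, qv, grad);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export(name = ".hpr_nuts")]]
List hpr_nuts(List model_spec, NumericVector q_init, int warmup, int iter,
              double adapt_target, int max_treedepth) {
  Model mod = make_model(model_spec);
  const int D = mod.dim();
  if ((int)q_init.size() != D)
    stop("init vector has length %d, expected %d", q_init.size(), D);

  PS z;
  z.q.assign(q_init.begin(), q_init.end());
  z.p.assign(D, 0.0);
  z.g.assign(D, 0.0);
  z.lp = lp_grad(mod, z.q, z.g);
  if (!std::isfinite(z.lp)) stop("initial point has non-finite log density");

  std::vector<double> invm(D, 1.0);

  // adaptation window schedule (step size always; metric when warmup allows)
  bool adapt_metric = warmup >= 40;
  int init_buffer = std::min(75, (int)(0.15 * warmup));
  int term_buffer = std::min(50, (int)(0.10 * warmup));
  std::vector<int> window_ends;
  if (adapt_metric) {
    int wstart = init_buffer, wsize = 25;
    while (wstart + wsize < warmup - term_buffer) {
      int wend = wstart + wsize;
      if (wend + 2 * wsize >= warmup - term_buffer) wend = warmup - term_buffer;
      window_ends.push_back(wend);
      wstart = wend;
      wsize *= 2;
    }
    if (window_ends.empty() && warmup - term_buffer > init_buffer)
      window_ends.push_back(warmup - term_buffer);
  }

  double eps = find_reasonable_eps(mod, z, invm);
  DualAverage da;
  da.restart(eps, adapt_target);

  Welford wf;
  wf.init(D);
  size_t next_window = 0;

  NumericMatrix draws(iter, D);
  NumericVector lp_out(iter), accept_out(iter), nleap_out(iter);
  LogicalVector div_out(iter), td_out(iter);
  int div_warm = 0;

  for (int it = 0; it < warmup + iter; ++it) {
    bool divergent = false, hit_max = false;
    double accept = 0.0;
    int nleap = 0;
    nuts_transition(mod, z, eps, invm, max_treedepth, divergent, hit_max,
                    accept, nleap);
    if (it < warmup) {
      if (divergent) ++div_warm;
      eps = da.update(accept);
      bool in_window = adapt_metric && it >= init_buffer &&
                       next_window < window_ends.size();
      if (in_window) {
        wf.add(z.q);
        if (it + 1 == window_ends[next_window]) {
          wf.variance(invm);   // metric M^{-1} = posterior variance estimate
          wf.init(D);
          ++next_window;
          da.restart(eps, adapt_target);
        }
      }
      if (it + 1 == warmup) eps = da.final_eps();
    } else {
      int row = it - warmup;
      for (int i = 0; i < D; ++i) draws(row, i) = z.q[i];
      lp_out[row] = z.lp;
      accept_out[row] = accept;
      nleap_out[row] = nleap;
      div_out[row] = divergent;
      td_out[row] = hit_max;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lp_out, _["divergent"] = div_out,
      _["treedepth_hit"] = td_out, _["accept_stat"] = accept_out,
      _["n_leapfrog"] = nleap_out, _["stepsize"] = eps,
      _["inv_metric"] = NumericVector(invm.begin(), invm.end()),
      _["divergent_warmup"] = div_warm);
}
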