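// Hamiltonian Monte Carlo sampler for hierarchical D6SR models.
//
// Two mean structures share one parameter layout convention:
//   form 0 (gMM):    mu_k = a_k * D_k / (bb_k + D_k)
//     a_k  = a0 + X_k beta + site/tree/sample deviations (non-centered)
//     bb_k = smooth floor of b0 + site/tree/sample deviations at 0.05*b0
//   form 1 (linear): mu_k = c0 + bd * D_k + X_k beta + deviations
// Observation model: y_n ~ Normal(mu_{samp(n)}, sigma), replicates within
// sample share mu. All positive parameters are sampled on the log scale with
// Jacobian corrections; random-effect deviations are standard-normal z scores
// scaled by their level SD (non-centered parameterization).
//
// Warmup follows the standard windowed scheme: dual-averaged step size
// targeting a given acceptance statistic, with doubling memoryless windows in
// which the diagonal (inverse) mass matrix is re-estimated from warmup draws.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct ModelData {
  int form;                 // 0 gmm, 1 linear
  NumericVector y;          // N observations
  IntegerVector samp;       // N, 1-based sample index
  NumericVector D;          // K transformed diameters
  NumericMatrix X;          // K x P asymptote covariates
  IntegerVector site;       // K, 1-based
  IntegerVector tree;       // K, 1-based
  int N, K, S, T, P;
  int lev_site, lev_tree, lev_samp;   // active random-effect levels
  // prior hyperparameters
  double a0_mean, a0_sd;    // intercept / asymptote
  double b0_sd;             // half-normal scale for half-saturation (gmm)
  double bd_sd;             // diameter slope prior sd (linear)
  double slope_sd;          // covariate slope prior sd
  double re_sd_scale;       // half-normal scale for random-effect SDs
  double sigma_scale;       // half-normal scale for residual SD
  double floor_frac;        // bb floored at floor_frac * b0
  double floor_smooth;      // softplus smoothing width
  // cached sufficient stats per sample
  NumericVector nrep, sumy, sumy2;
  // parameter layout offsets
  int n_lev_a, n_lev_b, np;
  int o_beta, o_lsd_a, o_lsd_b, o_lsig;
  int o_zs_a, o_zt_a, o_zk_a, o_zs_b, o_zt_b, o_zk_b;
};

static ModelData build_data(const List& dat) {
  ModelData d;
  d.form = as<int>(dat["form"]);
  d.y = dat["y"]; d.samp = dat["samp"]; d.D = dat["D"];
  d.X = as<NumericMatrix>(dat["X"]);
  d.site = dat["site"]; d.tree = dat["tree"];
  d.N = d.y.size(); d.K = d.D.size();
  d.S = as<int>(dat["S"]); d.T = as<int>(dat["T"]); d.P = d.X.ncol();
  d.lev_site = as<int>(dat["lev_site"]);
  d.lev_tree = as<int>(dat["lev_tree"]);
  d.lev_samp = as<int>(dat["lev_samp"]);
  List pr = dat["priors"];
  d.a0_mean = as<double>(pr["intercept_mean"]);
  d.a0_sd = as<double>(pr["intercept_sd"]);
  d.b0_sd = as<double>(pr["b0_sd"]);
  d.bd_sd = as<double>(pr["diameter_slope_sd"]);
  d.slope_sd = as<double>(pr["slope_sd"]);
  d.re_sd_scale = as<double>(pr["re_sd_scale"]);
  d.sigma_scale = as<double>(pr["sigma_sd"]);
  d.floor_frac = as<double>(pr["floor_frac"]);
  d.floor_smooth = as<double>(pr["floor_smooth"]);
  d.nrep = NumericVector(d.K); d.sumy = NumericVector(d.K); d.sumy2 = NumericVector(d.K);
  for (int n = 0; n < d.N; ++n) {
    int k = d.samp[n] - 1;
    d.nrep[k] += 1; d.sumy[k] += d.y[n]; d.sumy2[k] += d.y[n] * d.y[n];
  }
  d.n_lev_a = d.lev_site * d.S + d.lev_tree * d.T + d.lev_samp * d.K;
  d.n_lev_b = (d.form == 0) ? d.n_lev_a : 0;
  int nsd_a = d.lev_site + d.lev_tree + d.lev_samp;
  int nsd_b = (d.form == 0) ? nsd_a : 0;
  // layout: intercept | lb0 (gmm) or bd (linear) | beta(P) | lsd_a | lsd_b | lsig | z blocks
  int pos = 2;                          // slot 0 intercept, slot 1 lb0/bd
  d.o_beta = pos; pos += d.P;
  d.o_lsd_a = pos; pos += nsd_a;
  d.o_lsd_b = pos; pos += nsd_b;
  d.o_lsig = pos; pos += 1;
  d.o_zs_a = pos; pos += d.lev_site * d.S;
  d.o_zt_a = pos; pos += d.lev_tree * d.T;
  d.o_zk_a = pos; pos += d.lev_samp * d.K;
  d.o_zs_b = pos; pos += (d.form == 0) ? d.lev_site * d.S : 0;
  d.o_zt_b = pos; pos += (d.form == 0) ? d.lev_tree * d.T : 0;
  d.o_zk_b = pos; pos += (d.form == 0) ? d.lev_samp * d.K : 0;
  d.np = pos;
  return d;
}

static inline double half_normal_lp(double x, double scale) {
  return -0.5 * x * x / (scale * scale);
}

// log posterior and gradient; returns lp, fills grad
static double lp_grad(const ModelData& d, const std::vector<double>& th,
                      std::vector<double>& gr) {
  const int K = d.K;
  std::fill(gr.begin(), gr.end(), 0.0);
  double lp = 0.0;

  double intercept, b0 = 0, bd = 0;
  double a0j = 1.0;  // d(intercept)/d(theta0)
  if (d.form == 0) { intercept = std::exp(th[0]); a0j = intercept; b0 = std::exp(th[1]); }
  else             { intercept = th[0]; bd = th[1]; }

  int nsd_a = d.lev_site + d.lev_tree + d.lev_samp;
  std::vector<double> sd_a(3, 0.0), sd_b(3, 0.0);
  {
    int j = 0;
    if (d.lev_site) sd_a[0] = std::exp(th[d.o_lsd_a + j++]);
    if (d.lev_tree) sd_a[1] = std::exp(th[d.o_lsd_a + (j++)]);
    if (d.lev_samp) sd_a[2] = std::exp(th[d.o_lsd_a + (j++)]);
    if (d.form == 0) {
      j = 0;
      if (d.lev_site) sd_b[0] = std::exp(th[d.o_lsd_b + j++]);
      if (d.lev_tree) sd_b[1] = std::exp(th[d.o_lsd_b + (j++)]);
      if (d.lev_samp) sd_b[2] = std::exp(th[d.o_lsd_b + (j++)]);
    }
  }
  double sigma = std::exp(th[d.o_lsig]);
  double sig2 = sigma * sigma;

  // per-sample linear predictors
  std::vector<double> a(K), mu(K), g(K), bb(K), sgm(K);
  for (int k = 0; k < K; ++k) {
    double ak = intercept;
    if (d.form == 1) ak += bd * d.D[k];
    for (int p = 0; p < d.P; ++p) ak += th[d.o_beta + p] * d.X(k, p);
    if (d.lev_site) ak += sd_a[0] * th[d.o_zs_a + d.site[k] - 1];
    if (d.lev_tree) ak += sd_a[1] * th[d.o_zt_a + d.tree[k] - 1];
    if (d.lev_samp) ak += sd_a[2] * th[d.o_zk_a + k];
    a[k] = ak;
    if (d.form == 0) {
      double braw = b0;
      if (d.lev_site) braw += sd_b[0] * th[d.o_zs_b + d.site[k] - 1];
      if (d.lev_tree) braw += sd_b[1] * th[d.o_zt_b + d.tree[k] - 1];
      if (d.lev_samp) braw += sd_b[2] * th[d.o_zk_b + k];
      double lo = d.floor_frac * b0, t = d.floor_smooth;
      double u = (braw - lo) / t;
      double sp = (u > 30) ? u : std::log1p(std::exp(u));
      sgm[k] = 1.0 / (1.0 + std::exp(-u));
      bb[k] = lo + t * sp;
      g[k] = d.D[k] / (bb[k] + d.D[k]);
      mu[k] = ak * g[k];
    } else {
      mu[k] = ak;
    }
  }

  // likelihood via per-sample sufficient statistics
  double SSR = 0.0;
  for (int k = 0; k < K; ++k)
    SSR += d.sumy2[k] - 2.0 * mu[k] * d.sumy[k] + d.nrep[k] * mu[k] * mu[k];
  lp += -d.N * std::log(sigma) - 0.5 * SSR / sig2 - 0.5 * d.N * std::log(2.0 * M_PI);

  // priors (+ log Jacobians for log-scale parameters)
  if (d.form == 0) {
    lp += -0.5 * std::pow((intercept - d.a0_mean) / d.a0_sd, 2) + th[0];
    lp += half_normal_lp(b0, d.b0_sd) + th[1];
  } else {
    lp += -0.5 * std::pow((intercept - d.a0_mean) / d.a0_sd, 2);
    lp += -0.5 * bd * bd / (d.bd_sd * d.bd_sd);
  }
  for (int p = 0; p < d.P; ++p)
    lp += -0.5 * std::pow(th[d.o_beta + p] / d.slope_sd, 2);
  for (int j = 0; j < nsd_a; ++j) {
    double s = std::exp(th[d.o_lsd_a + j]);
    lp += half_normal_lp(s, d.re_sd_scale) + th[d.o_lsd_a + j];
  }
  if (d.form == 0) for (int j = 0; j < nsd_a; ++j) {
    double s = std::exp(th[d.o_lsd_b + j]);
    lp += half_normal_lp(s, d.re_sd_scale) + th[d.o_lsd_b + j];
  }
  lp += half_normal_lp(sigma, d.sigma_scale) + th[d.o_lsig];
  for (int i = d.o_zs_a; i < d.np; ++i) lp += -0.5 * th[i] * th[i];

  // gradients
  std::vector<double> s_k(K), da(K), dbraw(K);
  double sum_da = 0, db0 = 0;
  for (int k = 0; k < K; ++k) {
    s_k[k] = (d.sumy[k] - d.nrep[k] * mu[k]) / sig2;
    if (d.form == 0) {
      da[k] = s_k[k] * g[k];
      double dbb = -s_k[k] * a[k] * g[k] / (bb[k] + d.D[k]);
      dbraw[k] = dbb * sgm[k];
      db0 += dbb * (sgm[k] + d.floor_frac * (1.0 - sgm[k]));
    } else {
      da[k] = s_k[k];
    }
    sum_da += da[k];
  }
  if (d.form == 0) {
    gr[0] = (sum_da - (intercept - d.a0_mean) / (d.a0_sd * d.a0_sd)) * a0j + 1.0;
    gr[1] = (db0 - b0 / (d.b0_sd * d.b0_sd)) * b0 + 1.0;
  } else {
    gr[0] = sum_da - (intercept - d.a0_mean) / (d.a0_sd * d.a0_sd);
    double gbd = 0; for (int k = 0; k < K; ++k) gbd += da[k] * d.D[k];
    gr[1] = gbd - bd / (d.bd_sd * d.bd_sd);
  }
  for (int p = 0; p < d.P; ++p) {
    double gp = 0; for (int k = 0; k < K; ++k) gp += da[k] * d.X(k, p);
    gr[d.o_beta + p] = gp - th[d.o_beta + p] / (d.slope_sd * d.slope_sd);
  }
  // level SD and z gradients
  double re_var = d.re_sd_scale * d.re_sd_scale;
  int j = 0;
  if (d.lev_site) {
    double gsd = 0;
    for (int k = 0; k < K; ++k) {
      double z = th[d.o_zs_a + d.site[k] - 1];
      gsd += da[k] * z;
      gr[d.o_zs_a + d.site[k] - 1] += da[k] * sd_a[0];
    }
    gr[d.o_lsd_a + j] = (gsd - sd_a[0] / re_var) * sd_a[0] + 1.0;
    ++j;
  }
  if (d.lev_tree) {
    double gsd = 0;
    for (int k = 0; k < K; ++k) {
      double z = th[d.o_zt_a + d.tree[k] - 1];
      gsd += da[k] * z;
      gr[d.o_zt_a + d.tree[k] - 1] += da[k] * sd_a[1];
    }
    gr[d.o_lsd_a + j] = (gsd - sd_a[1] / re_var) * sd_a[1] + 1.0;
    ++j;
  }
  if (d.lev_samp) {
    double gsd = 0;
    for (int k = 0; k < K; ++k) {
      double z = th[d.o_zk_a + k];
      gsd += da[k] * z;
      gr[d.o_zk_a + k] += da[k] * sd_a[2];
    }
    gr[d.o_lsd_a + j] = (gsd - sd_a[2] / re_var) * sd_a[2] + 1.0;
  }
  if (d.form == 0) {
    j = 0;
    if (d.lev_site) {
      double gsd = 0;
      for (int k = 0; k < K; ++k) {
        double z = th[d.o_zs_b + d.site[k] - 1];
        gsd += dbraw[k] * z;
        gr[d.o_zs_b + d.site[k] - 1] += dbraw[k] * sd_b[0];
      }
      gr[d.o_lsd_b + j] = (gsd - sd_b[0] / re_var) * sd_b[0] + 1.0;
      ++j;
    }
    if (d.lev_tree) {
      double gsd = 0;
      for (int k = 0; k < K; ++k) {
        double z = th[d.o_zt_b + d.tree[k] - 1];
        gsd += dbraw[k] * z;
        gr[d.o_zt_b + d.tree[k] - 1] += dbraw[k] * sd_b[1];
      }
      gr[d.o_lsd_b + j] = (gsd - sd_b[1] / re_var) * sd_b[1] + 1.0;
      ++j;
    }
    if (d.lev_samp) {
      double gsd = 0;
      for (int k = 0; k < K; ++k) {
        double z = th[d.o_zk_b + k];
        gsd += dbraw[k] * z;
        gr[d.o_zk_b + k] += dbraw[k] * sd_b[2];
      }
      gr[d.o_lsd_b + j] = (gsd - sd_b[2] / re_var) * sd_b[2] + 1.0;
    }
  }
  gr[d.o_lsig] += (-d.N + SSR / sig2) - sig2 / (d.sigma_scale * d.sigma_scale) + 1.0;
  // z prior gradients
  for (int i = d.o_zs_a; i < d.np; ++i) gr[i] += -th[i];
  return lp;
}

// [[Rcpp::export(name = ".hmc_lp_grad")]]
List hmc_lp_grad(NumericVector theta, List dat) {
  ModelData d = build_data(dat);
  if ((int)theta.size() != d.np)
    stop("theta has length %d, model expects %d", theta.size(), d.np);
  std::vector<double> th(theta.begin(), theta.end()), gr(d.np);
  double lp = lp_grad(d, th, gr);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(gr.begin(), gr.end()),
                      _["np"] = d.np);
}

// [[Rcpp::export(name = ".hmc_layout")]]
List hmc_layout(List dat) {
  ModelData d = build_data(dat);
  return List::create(
    _["np"] = d.np, _["o_beta"] = d.o_beta, _["o_lsd_a"] = d.o_lsd_a,
    _["o_lsd_b"] = d.o_lsd_b, _["o_lsig"] = d.o_lsig,
    _["o_zs_a"] = d.o_zs_a, _["o_zt_a"] = d.o_zt_a, _["o_zk_a"] = d.o_zk_a,
    _["o_zs_b"] = d.o_zs_b, _["o_zt_b"] = d.o_zt_b, _["o_zk_b"] = d.o_zk_b);
}

// One HMC chain. Uses R's RNG stream (seed with set.seed before calling).
// [[Rcpp::export(name = ".hmc_chain")]]
List hmc_chain(List dat, NumericVector init, int n_warmup, int n_sample,
               double target_accept, double sim_length, int max_leapfrog,
               double init_step) {
  ModelData d = build_data(dat);
  const int np = d.np;
  if ((int)init.size() != np) stop("init has wrong length");
  RNGScope scope;

  std::vector<double> th(init.begin(), init.end());
  std::vector<double> minv(np, 1.0);   // inverse mass = posterior variances
  std::vector<double> gr(np), thp(np), grp(np), p(np), pp(np);
  double lp = lp_grad(d, th, gr);
  if (!std::isfinite(lp)) stop("initial point has non-finite log posterior");

  double eps = init_step;
  // dual averaging state
  double da_mu = std::log(10 * eps), da_lebar = 0, da_Hbar = 0;
  int da_m = 0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  // mass adaptation windows: 75 init | doubling 25,50,... | 50 final
  std::vector<int> w_end;
  {
    int base = 25, pos = 75;
    while (pos + base < n_warmup - 50) { pos += base; w_end.push_back(pos); base *= 2; }
    if (!w_end.empty()) w_end.back() = n_warmup - 50;
  }
  std::vector<double> wsum(np, 0.0), wsum2(np, 0.0);
  int wn = 0;

  NumericMatrix draws(n_sample, np);
  NumericVector lp_out(n_sample);
  double acc_sum = 0; int n_div = 0;

  for (int it = 1; it <= n_warmup + n_sample; ++it) {
    for (int i = 0; i < np; ++i) p[i] = norm_rand() / std::sqrt(minv[i]);
    double H0 = -lp;
    for (int i = 0; i < np; ++i) H0 += 0.5 * p[i] * p[i] * minv[i];
    int L = (int)std::lround(sim_length / eps * (0.7 + 0.3 * unif_rand()));
    if (L < 1) L = 1; if (L > max_leapfrog) L = max_leapfrog;

    thp = th; grp = gr; pp = p;
    double lpp = lp;
    bool div = false;
    for (int i = 0; i < np; ++i) pp[i] += 0.5 * eps * grp[i];
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < np; ++i) thp[i] += eps * minv[i] * pp[i];
      lpp = lp_grad(d, thp, grp);
      if (!std::isfinite(lpp)) { div = true; break; }
      double half = (l < L - 1) ? eps : 0.5 * eps;
      for (int i = 0; i < np; ++i) pp[i] += half * grp[i];
    }
    double aprob = 0.0;
    if (!div) {
      double H1 = -lpp;
      for (int i = 0; i < np; ++i) H1 += 0.5 * pp[i] * pp[i] * minv[i];
      double dH = H0 - H1;
      if (std::isfinite(dH)) aprob = dH > 0 ? 1.0 : std::exp(dH);
      else div = true;
    }
    if (unif_rand() < aprob) { th = thp; gr = grp; lp = lpp; }

    if (it <= n_warmup) {
      // dual averaging on step size
      da_m += 1;
      da_Hbar = (1.0 - 1.0 / (da_m + t0)) * da_Hbar +
                (target_accept - aprob) / (da_m + t0);
      double leps = da_mu - std::sqrt((double)da_m) / gamma * da_Hbar;
      double w = std::pow((double)da_m, -kappa);
      da_lebar = w * leps + (1.0 - w) * da_lebar;
      eps = std::exp(leps);
      if (it > 75 && it <= n_warmup - 50) {
        for (int i = 0; i < np; ++i) { wsum[i] += th[i]; wsum2[i] += th[i] * th[i]; }
        ++wn;
      }
      for (size_t wi = 0; wi < w_end.size(); ++wi) {
        if (it == w_end[wi] && wn > 4) {
          for (int i = 0; i < np; ++i) {
            double m = wsum[i] / wn;
            double v = (wsum2[i] - wn * m * m) / (wn - 1);
            minv[i] = (wn / (wn + 5.0)) * v + (5.0 / (wn + 5.0)) * 1e-3;
          }
          std::fill(wsum.begin(), wsum.end(), 0.0);
          std::fill(wsum2.begin(), wsum2.end(), 0.0);
          wn = 0;
          eps = std::exp(da_lebar);
          da_mu = std::log(10 * eps); da_lebar = 0; da_Hbar = 0; da_m = 0;
        }
      }
      if (it == n_warmup) eps = std::exp(da_lebar);
    } else {
      int r = it - n_warmup - 1;
      for (int i = 0; i < np; ++i) draws(r, i) = th[i];
      lp_out[r] = lp;
      acc_sum += aprob;
      if (div) ++n_div;
    }
  }
  return List::create(
    _["draws"] = draws, _["lp"] = lp_out,
    _["accept_rate"] = acc_sum / n_sample,
    _["step_size"] = eps, _["divergences"] = n_div,
    _["inv_mass"] = NumericVector(minv.begin(), minv.end()));
}
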