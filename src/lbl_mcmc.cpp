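#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the retrospective-likelihood logistic
// Bayesian LASSO. Haplotype index 0 is the baseline (most frequent); the
// design for a diplotype (k,l) is the copy count of each non-baseline
// haplotype, optionally extended with a binary covariate and
// haplotype-by-covariate products under haplotype-environment independence.
//
// Coefficient layout in beta:
//   [0 .. K-2]        haplotype main effects (haplotype j -> beta[j-1])
//   [K-1]             covariate main effect            (gxe only)
//   [K .. 2K-2]       haplotype x covariate interactions (gxe only)

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct LblState {
  int n, K, M, P;
  bool gxe;
  std::vector<int> y, e;           // per individual
  std::vector<int> pk, pl, off;    // compatible pairs (codes are hap indices)
  std::vector<int> allk, alll;     // all K(K+1)/2 unordered pairs
  std::vector<int> zi;             // index of current pair within off[i]..off[i+1)
  std::vector<double> beta, f;
  double a, lam, d, pE, dmin;
  int n1, n0, ne1;
  double a_lam, b_lam;

  double bmain(int j) const { return j == 0 ? 0.0 : beta[j - 1]; }
  double bint(int j) const { return j == 0 ? 0.0 : beta[K + j - 1]; }

  double lp(int k, int l, int ei) const {
    double v = a + bmain(k) + bmain(l);
    if (gxe && ei)
      v += beta[K - 1] + bint(k) + bint(l);
    return v;
  }
  double llyz(int yi, int k, int l, int ei) const {
    double v = lp(k, l, ei);
    return yi ? -softplus(-v) : -softplus(v);
  }
  double pz(int k, int l) const {
    if (k == l) return d * f[k] + (1.0 - d) * f[k] * f[k];
    return 2.0 * (1.0 - d) * f[k] * f[l];
  }

  // log of theta(y) = sum over all diplotypes (and covariate states) of
  // P(y | z, e) P(z | f, d) P(e); the retrospective normalizer.
  double log_theta(int yv) const {
    double s = 0.0;
    for (int m = 0; m < M; ++m) {
      double pzm = pz(allk[m], alll[m]);
      if (pzm <= 0.0) continue;
      double py;
      if (gxe) {
        py = (1.0 - pE) * std::exp(llyz(yv, allk[m], alll[m], 0)) +
             pE * std::exp(llyz(yv, allk[m], alll[m], 1));
      } else {
        py = std::exp(llyz(yv, allk[m], alll[m], 0));
      }
      s += pzm * py;
    }
    return std::log(s);
  }
  double theta_sum() const {
    return n1 * log_theta(1) + n0 * log_theta(0);
  }
  double sum_ll_y() const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = off[i] + zi[i];
      s += llyz(y[i], pk[j], pl[j], gxe ? e[i] : 0);
    }
    return s;
  }
  double sum_ll_pz() const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = off[i] + zi[i];
      s += std::log(pz(pk[j], pl[j]));
    }
    return s;
  }
};

static inline double dmin_of(const std::vector<double>& f) {
  double fm = f[0];
  for (double v : f) if (v < fm) fm = v;
  return -fm / (1.0 - fm);
}

static double ldirich(const std::vector<double>& x,
                      const std::vector<double>& alpha) {
  double s = 0.0, sa = 0.0;
  for (size_t k = 0; k < x.size(); ++k) {
    s += (alpha[k] - 1.0) * std::log(x[k]) - R::lgammafn(alpha[k]);
    sa += alpha[k];
  }
  return s + R::lgammafn(sa);
}

// [[Rcpp::export]]
List lbl_mcmc_cpp(IntegerVector y, IntegerVector pair_k, IntegerVector pair_l,
                  IntegerVector offsets, int K, NumericVector f0,
                  IntegerVector evec, bool gxe,
                  int n_iter, int burn_in,
                  double a_lam, double b_lam,
                  double sd_beta, double sd_a, double dir_c, double sd_pe,
                  double a_prior_sd, bool adapt) {
  LblState st;
  st.n = y.size();
  st.K = K;
  st.gxe = gxe;
  st.P = gxe ? 2 * K - 1 : K - 1;
  st.y.assign(y.begin(), y.end());
  st.pk.assign(pair_k.begin(), pair_k.end());
  st.pl.assign(pair_l.begin(), pair_l.end());
  st.off.assign(offsets.begin(), offsets.end());
  if (gxe) st.e.assign(evec.begin(), evec.end());
  else st.e.assign(st.n, 0);
  st.a_lam = a_lam; st.b_lam = b_lam;

  st.n1 = 0; st.ne1 = 0;
  for (int i = 0; i < st.n; ++i) { st.n1 += st.y[i]; st.ne1 += st.e[i]; }
  st.n0 = st.n - st.n1;

  // all unordered haplotype pairs
  for (int k = 0; k < K; ++k)
    for (int l = k; l < K; ++l) { st.allk.push_back(k); st.alll.push_back(l); }
  st.M = (int) st.allk.size();

  // initial state
  st.f.assign(f0.begin(), f0.end());
  double fs = 0.0;
  for (double& v : st.f) { if (v < 1e-6) v = 1e-6; fs += v; }
  for (double& v : st.f) v /= fs;
  st.dmin = dmin_of(st.f);
  st.d = 0.0;
  st.beta.assign(st.P, 0.0);
  st.a = std::log((st.n1 + 0.5) / (st.n0 + 0.5));
  st.lam = a_lam / b_lam;
  st.pE = std::min(0.99, std::max(0.01, (st.ne1 + 0.5) / (st.n + 1.0)));

  // start each individual at its most probable pair under f0
  st.zi.assign(st.n, 0);
  for (int i = 0; i < st.n; ++i) {
    double best = -1.0; int bj = 0;
    for (int j = st.off[i]; j < st.off[i + 1]; ++j) {
      double p = st.pz(st.pk[j], st.pl[j]);
      if (p > best) { best = p; bj = j - st.off[i]; }
    }
    st.zi[i] = bj;
  }

  double cur_ll_y = st.sum_ll_y();
  double cur_ll_pz = st.sum_ll_pz();
  double cur_theta = st.theta_sum();

  int n_keep = n_iter - burn_in;
  NumericMatrix beta_out(n_keep, st.P);
  NumericVector a_out(n_keep), lam_out(n_keep), d_out(n_keep);
  std::vector<double> f_sum(K, 0.0);

  std::vector<double> sds(st.P, sd_beta);
  double sda = sd_a, c_dir = dir_c, sdpe = sd_pe;
  std::vector<int> acc(st.P, 0);
  int acc_a = 0, acc_f = 0, acc_d = 0, acc_pe = 0;
  std::vector<int> bacc(st.P, 0);
  int bacc_a = 0, bacc_f = 0, bacc_pe = 0;
  const int batch = 50;

  std::vector<double> wbuf(64), lbuf(64);

  for (int it = 0; it < n_iter; ++it) {
    // --- latent diplotypes Z_i ---------------------------------------
    cur_ll_y = 0.0; cur_ll_pz = 0.0;
    for (int i = 0; i < st.n; ++i) {
      int lo = st.off[i], hi = st.off[i + 1], np = hi - lo;
      if ((int) wbuf.size() < np) { wbuf.resize(np); lbuf.resize(np); }
      double mx = -INFINITY;
      for (int j = 0; j < np; ++j) {
        double p = st.pz(st.pk[lo + j], st.pl[lo + j]);
        double lw = (p > 0 ? std::log(p) : -INFINITY) +
          st.llyz(st.y[i], st.pk[lo + j], st.pl[lo + j], st.e[i]);
        lbuf[j] = lw;
        if (lw > mx) mx = lw;
      }
      double tot = 0.0;
      for (int j = 0; j < np; ++j) {
        wbuf[j] = std::exp(lbuf[j] - mx);
        tot += wbuf[j];
      }
      double u = R::unif_rand() * tot, cum = 0.0;
      int pick = np - 1;
      for (int j = 0; j < np; ++j) {
        cum += wbuf[j];
        if (u <= cum) { pick = j; break; }
      }
      st.zi[i] = pick;
      cur_ll_y += st.llyz(st.y[i], st.pk[lo + pick], st.pl[lo + pick], st.e[i]);
      cur_ll_pz += std::log(st.pz(st.pk[lo + pick], st.pl[lo + pick]));
    }

    // --- intercept a --------------------------------------------------
    {
      double a_old = st.a;
      st.a = a_old + sda * R::norm_rand();
      double new_ll_y = st.sum_ll_y();
      double new_theta = st.theta_sum();
      double lr = (new_ll_y - new_theta) - (cur_ll_y - cur_theta) +
        (a_old * a_old - st.a * st.a) / (2.0 * a_prior_sd * a_prior_sd);
      if (std::log(R::unif_rand()) < lr) {
        cur_ll_y = new_ll_y; cur_theta = new_theta;
        if (it >= burn_in) acc_a++; else bacc_a++;
      } else {
        st.a = a_old;
      }
    }

    // --- regression coefficients (Laplace prior) ----------------------
    for (int p = 0; p < st.P; ++p) {
      double b_old = st.beta[p];
      st.beta[p] = b_old + sds[p] * R::norm_rand();
      double new_ll_y = st.sum_ll_y();
      double new_theta = st.theta_sum();
      double lr = (new_ll_y - new_theta) - (cur_ll_y - cur_theta) +
        st.lam * (std::fabs(b_old) - std::fabs(st.beta[p]));
      if (std::log(R::unif_rand()) < lr) {
        cur_ll_y = new_ll_y; cur_theta = new_theta;
        if (it >= burn_in) acc[p]++; else bacc[p]++;
      } else {
        st.beta[p] = b_old;
      }
    }

    // --- lambda: conjugate Gamma update given |beta| ------------------
    {
      double sb = 0.0;
      for (int p = 0; p < st.P; ++p) sb += std::fabs(st.beta[p]);
      st.lam = R::rgamma(st.a_lam + st.P, 1.0 / (st.b_lam + sb));
    }

    // --- haplotype frequencies f (Dirichlet proposal) -----------------
    {
      std::vector<double> alpha(K), fprop(K), alpha_rev(K);
      double s = 0.0;
      bool ok = true;
      for (int k = 0; k < K; ++k) {
        alpha[k] = c_dir * st.f[k];
        fprop[k] = R::rgamma(alpha[k], 1.0);
        s += fprop[k];
      }
      if (s <= 0) ok = false;
      if (ok) {
        for (int k = 0; k < K; ++k) {
          fprop[k] /= s;
          if (fprop[k] < 1e-7) ok = false;
        }
      }
      double dmin_new = ok ? dmin_of(fprop) : 0.0;
      if (ok && st.d <= dmin_new) ok = false;  // current d outside new support
      if (ok) {
        for (int k = 0; k < K; ++k) alpha_rev[k] = c_dir * fprop[k];
        std::vector<double> f_old = st.f;
        double dmin_old = st.dmin;
        st.f = fprop; st.dmin = dmin_new;
        double new_ll_pz = st.sum_ll_pz();
        double new_theta = st.theta_sum();
        double lr = (new_ll_pz - new_theta) - (cur_ll_pz - cur_theta) +
          ldirich(f_old, alpha_rev) - ldirich(fprop, alpha) +
          std::log1p(-dmin_old) - std::log1p(-dmin_new);  // U(d | dmin, 1]
        if (std::log(R::unif_rand()) < lr) {
          cur_ll_pz = new_ll_pz; cur_theta = new_theta;
          if (it >= burn_in) acc_f++; else bacc_f++;
        } else {
          st.f = f_old; st.dmin = dmin_old;
        }
      }
    }

    // --- HWD parameter d (independent uniform proposal) ---------------
    {
      double d_old = st.d;
      st.d = R::runif(st.dmin, 1.0);
      double new_ll_pz = st.sum_ll_pz();
      double new_theta = st.theta_sum();
      double lr = (new_ll_pz - new_theta) - (cur_ll_pz - cur_theta);
      if (std::log(R::unif_rand()) < lr) {
        cur_ll_pz = new_ll_pz; cur_theta = new_theta;
        if (it >= burn_in) acc_d++;
      } else {
        st.d = d_old;
      }
    }

    // --- covariate frequency pE (gxe only) ----------------------------
    if (gxe) {
      double p_old = st.pE;
      double t = std::log(p_old / (1.0 - p_old)) + sdpe * R::norm_rand();
      st.pE = 1.0 / (1.0 + std::exp(-t));
      double new_theta = st.theta_sum();
      double lr = st.ne1 * (std::log(st.pE) - std::log(p_old)) +
        (st.n - st.ne1) * (std::log(1.0 - st.pE) - std::log(1.0 - p_old)) -
        new_theta + cur_theta +
        std::log(st.pE * (1.0 - st.pE)) - std::log(p_old * (1.0 - p_old));
      if (std::log(R::unif_rand()) < lr) {
        cur_theta = new_theta;
        if (it >= burn_in) acc_pe++; else bacc_pe++;
      } else {
        st.pE = p_old;
      }
    }

    // --- proposal adaptation during burn-in ---------------------------
    if (adapt && it < burn_in && (it + 1) % batch == 0) {
      for (int p = 0; p < st.P; ++p) {
        double r = (double) bacc[p] / batch;
        if (r > 0.5) sds[p] *= 1.25; else if (r < 0.3) sds[p] /= 1.25;
        bacc[p] = 0;
      }
      double ra = (double) bacc_a / batch;
      if (ra > 0.5) sda *= 1.25; else if (ra < 0.3) sda /= 1.25;
      bacc_a = 0;
      double rf = (double) bacc_f / batch;
      if (rf < 0.2) c_dir = std::min(1e7, c_dir * 1.5);
      else if (rf > 0.45) c_dir = std::max(50.0, c_dir / 1.5);
      bacc_f = 0;
      if (gxe) {
        double rp = (double) bacc_pe / batch;
        if (rp > 0.5) sdpe *= 1.25; else if (rp < 0.3) sdpe /= 1.25;
        bacc_pe = 0;
      }
    }

    // --- record --------------------------------------------------------
    if (it >= burn_in) {
      int r = it - burn_in;
      for (int p = 0; p < st.P; ++p) beta_out(r, p) = st.beta[p];
      a_out[r] = st.a;
      lam_out[r] = st.lam;
      d_out[r] = st.d;
      for (int k = 0; k < K; ++k) f_sum[k] += st.f[k];
    }
  }

  NumericVector f_mean(K), acc_rate(st.P);
  for (int k = 0; k < K; ++k) f_mean[k] = f_sum[k] / n_keep;
  for (int p = 0; p < st.P; ++p) acc_rate[p] = (double) acc[p] / n_keep;

  return List::create(
    _["beta"] = beta_out, _["a"] = a_out, _["lambda"] = lam_out,
    _["d"] = d_out, _["f_mean"] = f_mean,
    _["accept_beta"] = acc_rate,
    _["accept_a"] = (double) acc_a / n_keep,
    _["accept_f"] = (double) acc_f / n_keep,
    _["accept_d"] = (double) acc_d / n_keep,
    _["accept_pE"] = gxe ? (double) acc_pe / n_keep : NA_REAL);
}
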