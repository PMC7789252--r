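// Gibbs samplers for the longitudinal varying-coefficient kernel machine
// model (continuous blood pressure) and the probit kernel machine model
// with hierarchical spike-and-slab selection (elevated blood pressure).
//
// Surface hyperparameters (component weights r, GP scale tau2) are
// updated by Metropolis-within-Gibbs against the MARGINAL likelihood of
// per-subject pseudo-observations with the surface integrated out
// (u_i ~ N(0, tau2 K + diag(v)); the random intercept is folded into
// the noise v), after which the surface values are redrawn from their
// Gaussian full conditional. This partially-collapsed scan is what
// lets the selection indicators move at realistic chain lengths.
//
// All randomness goes through R's RNG so set.seed() in R gives
// bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::vec rnorm_vec(const arma::uword n) {
  arma::vec v(n);
  for (arma::uword i = 0; i < n; ++i) v[i] = R::norm_rand();
  return v;
}

// Draw from N(mu, 1) truncated to X > 0 (positive = true) or X < 0.
// Inverse-CDF in the relevant tail keeps accuracy for extreme means.
double rtnorm_mean(const double mu, const bool positive) {
  const double u = R::unif_rand();
  const double a = -mu;  // X > 0  <=>  W = X - mu > a, W standard normal
  double w;
  if (positive) {
    const double s = R::pnorm(a, 0.0, 1.0, 0, 0);  // P(W > a)
    w = R::qnorm(u * s, 0.0, 1.0, 0, 0);
  } else {
    const double s = R::pnorm(a, 0.0, 1.0, 1, 0);  // P(W < a)
    w = R::qnorm(u * s, 0.0, 1.0, 1, 0);
  }
  return mu + w;
}

double rinvgamma(const double shape, const double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Cholesky of K + jitter*I with jitter escalation: start at
// 1e-8 * trace(K)/n and multiply by 10 at most 3 times.
bool chol_jitter(const arma::mat& K, arma::mat& R) {
  const arma::uword n = K.n_rows;
  double j = 1e-8 * arma::trace(K) / n;
  for (int t = 0; t < 4; ++t) {
    if (arma::chol(R, K + j * arma::eye(n, n))) return true;
    j *= 10.0;
  }
  return false;
}

// Per-metal squared-distance matrices, precomputed once.
arma::cube sqdist_cube(const arma::mat& Z) {
  const arma::uword n = Z.n_rows, M = Z.n_cols;
  arma::cube C(n, n, M);
  for (arma::uword m = 0; m < M; ++m) {
    for (arma::uword i = 0; i < n; ++i) {
      C(i, i, m) = 0.0;
      for (arma::uword jj = 0; jj < i; ++jj) {
        const double d = Z(i, m) - Z(jj, m);
        C(i, jj, m) = d * d;
        C(jj, i, m) = d * d;
      }
    }
  }
  return C;
}

// log N(u; 0, tau2*K + diag(v) + lev*J) up to the shared -n/2 log(2*pi),
// J the all-ones matrix. The lev*J term integrates out the flat-prior
// level coefficient (intercept for h1, age slope for h2) so that kernel
// moves are never credited for soaking up a free level.
// Returns false on factorisation failure.
bool marg_ll(const arma::mat& K, const double tau2, const arma::vec& v,
             const arma::vec& u, const double lev, double& out) {
  arma::mat S = tau2 * K + lev;
  S.diag() += v;
  arma::mat R;
  if (!arma::chol(R, S)) return false;
  const arma::vec w = arma::solve(arma::trimatl(R.t()), u);
  out = -arma::sum(arma::log(R.diag())) - 0.5 * arma::dot(w, w);
  return true;
}

// Kernel state for one GP surface. D = accumulated weighted squared
// distances (single-metal proposals are rank-one updates of D);
// K = exp(-D); Kinv refreshed lazily, only when r changed.
struct Surface {
  arma::vec r;
  arma::mat D, K, Kinv;
  bool kinv_fresh = false;
};

void surface_set(Surface& s, const arma::cube& C, const arma::vec& r) {
  s.r = r;
  s.D.zeros(C.n_rows, C.n_cols);
  for (arma::uword m = 0; m < r.n_elem; ++m)
    if (r[m] > 0) s.D += r[m] * C.slice(m);
  s.K = arma::exp(-s.D);
  s.kinv_fresh = false;
}

bool surface_kinv(Surface& s) {
  if (s.kinv_fresh) return true;
  arma::mat R;
  if (!chol_jitter(s.K, R)) return false;
  const arma::mat Rinv = arma::inv(arma::trimatu(R));
  s.Kinv = Rinv * Rinv.t();
  s.kinv_fresh = true;
  return true;
}

// The empty model (no active components) is h == 0 exactly: no GP and
// no tau2. Moves between the empty and non-empty model are
// reversible-jump births/deaths that propose (r, tau2) jointly, with
// the tau2 proposal a log-normal pilot-scaled to the data.
struct MhSettings {
  double r_max, p_incl, prop_rate, rw_sd, tau_rw_sd, ig_a, ig_b;
  bool sample_tau;
};

// log N(u; 0, diag(v) + lev*J) up to -n/2 log(2*pi): the empty-model
// likelihood, with the level coefficient integrated out
// (Sherman-Morrison in closed form).
double null_ll(const arma::vec& u, const arma::vec& v, const double lev) {
  const double s1 = arma::sum(1.0 / v);
  const double su = arma::sum(u / v);
  const double denom = 1.0 + lev * s1;
  return -0.5 * (arma::sum(arma::log(v)) + std::log(denom)) -
         0.5 * (arma::sum(u % u / v) - lev * su * su / denom);
}

double ig_logpdf(const double x, const double a, const double b) {
  return a * std::log(b) - std::lgamma(a) - (a + 1.0) * std::log(x) - b / x;
}

double lnorm_logpdf(const double x, const double mu, const double s) {
  const double z = (std::log(x) - mu) / s;
  return -std::log(x) - std::log(s) - 0.5 * std::log(2.0 * M_PI) -
         0.5 * z * z;
}

// One Metropolis sweep over the component weights of a surface
// (spike-and-slab birth / death / log random walk), then one
// log-random-walk move on tau2, all against the marginal likelihood
// with the surface integrated out. Returns the (possibly new) tau2.
double mh_sweep(Surface& s, const arma::cube& C, const arma::vec& u,
                const arma::vec& v, double tau2, const double lev,
                const MhSettings& st, int& acc_rw, int& att_rw) {
  const arma::uword M = s.r.n_elem;
  arma::uword n_active = arma::accu(s.r > 0);
  double ll_cur;
  if (n_active == 0) ll_cur = null_ll(u, v, lev);
  else if (!marg_ll(s.K, tau2, v, u, lev, ll_cur)) return tau2;
  // pilot scale for the tau2 birth proposal (level-insensitive)
  const arma::vec uc = u - arma::mean(u);
  const double tau_pilot =
      std::max(0.05, arma::dot(uc, uc) / u.n_elem - arma::mean(v));
  const double tau_prop_sd = 1.5;

  for (arma::uword m = 0; m < M; ++m) {
    const double rcur = s.r[m];
    double rnew, lqdiff, tau_cand = tau2;
    if (rcur == 0.0) {
      rnew = R::exp_rand() / st.prop_rate;
      if (rnew >= st.r_max) continue;
      lqdiff = std::log(st.p_incl / (1.0 - st.p_incl)) - std::log(st.r_max) -
               std::log(st.prop_rate) + st.prop_rate * rnew + std::log(0.5);
      if (n_active == 0 && st.sample_tau) {
        // entering the non-empty model: propose tau2 as well
        tau_cand = std::exp(std::log(tau_pilot) +
                            tau_prop_sd * R::norm_rand());
        lqdiff += ig_logpdf(tau_cand, st.ig_a, st.ig_b) -
                  lnorm_logpdf(tau_cand, std::log(tau_pilot), tau_prop_sd);
      }
    } else if (R::unif_rand() < 0.5) {
      rnew = 0.0;
      lqdiff = std::log((1.0 - st.p_incl) / st.p_incl) + std::log(st.r_max) +
               std::log(st.prop_rate) - st.prop_rate * rcur - std::log(0.5);
      if (n_active == 1 && st.sample_tau) {
        // leaving to the empty model: tau2 is dropped
        lqdiff += lnorm_logpdf(tau2, std::log(tau_pilot), tau_prop_sd) -
                  ig_logpdf(tau2, st.ig_a, st.ig_b);
      }
    } else {
      ++att_rw;
      rnew = rcur * std::exp(st.rw_sd * R::norm_rand());
      if (rnew >= st.r_max) continue;
      lqdiff = std::log(rnew / rcur);  // Jacobian; flat slab cancels
    }
    const arma::uword n_active_new = n_active - (rcur > 0) + (rnew > 0);
    double ll_new;
    arma::mat Kc;
    if (n_active_new == 0) {
      ll_new = null_ll(u, v, lev);
    } else {
      Kc = arma::exp(-(s.D + (rnew - rcur) * C.slice(m)));
      if (!marg_ll(Kc, tau_cand, v, u, lev, ll_new)) continue;
    }
    if (std::log(R::unif_rand()) < ll_new - ll_cur + lqdiff) {
      s.D += (rnew - rcur) * C.slice(m);
      if (n_active_new > 0) s.K = std::move(Kc);
      else s.K = arma::exp(-s.D);
      s.r[m] = rnew;
      s.kinv_fresh = false;
      ll_cur = ll_new;
      tau2 = tau_cand;
      n_active = n_active_new;
      if (rcur > 0.0 && rnew > 0.0) ++acc_rw;
    }
  }
  if (st.sample_tau && n_active > 0) {
    const double tnew = tau2 * std::exp(st.tau_rw_sd * R::norm_rand());
    double ll_new;
    if (marg_ll(s.K, tnew, v, u, lev, ll_new)) {
      const double lprior = ig_logpdf(tnew, st.ig_a, st.ig_b) -
                            ig_logpdf(tau2, st.ig_a, st.ig_b);
      if (std::log(R::unif_rand()) <
          ll_new - ll_cur + lprior + std::log(tnew / tau2))
        tau2 = tnew;
    }
  }
  return tau2;
}

// Draw the flat-prior level coefficient with the surface integrated
// out: u = c*1 + f + eps, f ~ N(0, tau2 K), eps ~ N(0, diag(v)),
// c ~ N(0, Vc). K = nullptr encodes the empty model (no surface).
double draw_level(const arma::mat* K, const double tau2,
                  const arma::vec& v, const arma::vec& u, const double Vc) {
  double oneSinv1, oneSinvu;
  if (K == nullptr) {
    oneSinv1 = arma::sum(1.0 / v);
    oneSinvu = arma::sum(u / v);
  } else {
    arma::mat S = tau2 * (*K);
    S.diag() += v;
    arma::mat R;
    if (!arma::chol(R, S)) {
      S.diag() += 1e-6 * arma::trace(S) / S.n_rows;
      if (!arma::chol(R, S)) Rcpp::stop("level draw: factorisation failed");
    }
    const arma::vec w1 = arma::solve(
        arma::trimatl(R.t()), arma::vec(v.n_elem, arma::fill::ones));
    const arma::vec wu = arma::solve(arma::trimatl(R.t()), u);
    oneSinv1 = arma::dot(w1, w1);
    oneSinvu = arma::dot(w1, wu);
  }
  const double prec = oneSinv1 + 1.0 / Vc;
  return oneSinvu / prec + R::norm_rand() / std::sqrt(prec);
}

// Draw from N(A^{-1} rhs, A^{-1}) given precision A.
arma::vec sample_gauss_prec(arma::mat A, const arma::vec& rhs) {
  arma::mat R;
  if (!arma::chol(R, A)) {
    A.diag() += 1e-8 * arma::trace(A) / A.n_rows;
    if (!arma::chol(R, A)) Rcpp::stop("posterior precision not positive definite");
  }
  const arma::vec mu =
      arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), rhs));
  return mu + arma::solve(arma::trimatu(R), rnorm_vec(A.n_rows));
}

double num_or(const List& lst, const char* name, const double fallback,
              bool& fixed) {
  fixed = false;
  if (!lst.containsElementNamed(name)) return fallback;
  RObject o = lst[name];
  if (o.isNULL()) return fallback;
  fixed = true;
  return as<double>(o);
}

void adapt_step(double& rw, int& acc, int& att) {
  if (att < 20) return;
  const double rate = (double)acc / att;
  if (rate < 0.2) rw *= 0.8; else if (rate > 0.4) rw *= 1.25;
  acc = att = 0;
}

}  // namespace

// [[Rcpp::export(name = ".bvckmr_mcmc")]]
List bvckmr_mcmc(const arma::vec& y, const arma::ivec& subj,
                 const arma::vec& agec, const arma::mat& F,
                 const arma::mat& Z, const int niter, const int nburn,
                 const int thin, const List prior, const List control,
                 const List fix) {
  const arma::uword N = y.n_elem;
  const arma::uword n = Z.n_rows;
  const arma::uword M = Z.n_cols;
  const arma::uword p = F.n_cols;

  MhSettings st;
  st.r_max = as<double>(prior["r_max"]);
  st.p_incl = as<double>(prior["p_incl"]);
  st.prop_rate = as<double>(prior["prop_rate"]);
  st.rw_sd = as<double>(prior["rw_sd"]);
  st.tau_rw_sd = 0.8;
  st.ig_a = as<double>(prior["ig_a"]);
  st.ig_b = as<double>(prior["ig_b"]);
  const double theta_var = as<double>(prior["theta_var"]);
  const double ig_a = st.ig_a, ig_b = st.ig_b;

  const bool include_h2 = as<bool>(control["include_h2"]);
  const bool include_ranef = as<bool>(control["include_ranef"]);
  const bool adapt = as<bool>(control["adapt"]);

  bool fix_se, fix_sb, fix_t1, fix_t2;
  double sig_e2 = num_or(fix, "sigma_e2", arma::var(y) / 2.0 + 1e-8, fix_se);
  double sig_b2 = num_or(fix, "sigma_b2", arma::var(y) / 4.0 + 1e-8, fix_sb);
  double tau1 = num_or(fix, "tau1_2", 1.0, fix_t1);
  double tau2 = num_or(fix, "tau2_2", 1.0, fix_t2);
  if (!include_ranef) { sig_b2 = 0.0; fix_sb = true; }

  bool fix_r1 = false, fix_r2 = false, fix_theta = false;
  arma::vec r1_fix, r2_fix, theta_fix;
  if (fix.containsElementNamed("r1") && !Rf_isNull(fix["r1"])) {
    fix_r1 = true; r1_fix = as<arma::vec>(fix["r1"]);
  }
  if (fix.containsElementNamed("r2") && !Rf_isNull(fix["r2"])) {
    fix_r2 = true; r2_fix = as<arma::vec>(fix["r2"]);
  }
  if (fix.containsElementNamed("theta") && !Rf_isNull(fix["theta"])) {
    fix_theta = true; theta_fix = as<arma::vec>(fix["theta"]);
  }

  arma::vec ni(n, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) ni[subj[i]] += 1.0;

  const arma::cube C = sqdist_cube(Z);
  const arma::mat FtF = F.t() * F;

  Surface s1, s2;
  surface_set(s1, C, fix_r1 ? r1_fix : arma::vec(M, arma::fill::zeros));
  surface_set(s2, C, fix_r2 ? r2_fix : arma::vec(M, arma::fill::zeros));

  arma::vec theta = fix_theta ? theta_fix : arma::vec(p, arma::fill::zeros);
  arma::vec h1(n, arma::fill::zeros), h2v(n, arma::fill::zeros),
      b(n, arma::fill::zeros);
  arma::vec Fth = F * theta;

  const int ndraw = (niter - nburn) / thin;
  arma::mat d_theta(ndraw, p), d_h1(ndraw, n), d_h2(ndraw, n),
      d_r1(ndraw, M), d_r2(ndraw, M);
  arma::vec d_se(ndraw), d_sb(ndraw), d_t1(ndraw), d_t2(ndraw);

  MhSettings st1 = st, st2 = st;
  st1.sample_tau = !fix_t1;
  st2.sample_tau = !fix_t2;
  int acc1 = 0, att1 = 0, acc2 = 0, att2 = 0;

  for (int it = 1; it <= niter; ++it) {
    // --- surface 1: pseudo-observations with b, h1 and (unless fixed)
    // the intercept integrated out ---
    {
      const bool collapse0 = !fix_theta;
      const double lev1 = collapse0 ? theta_var : 0.0;
      const double th0 = collapse0 ? theta[0] : 0.0;
      arma::vec se(n, arma::fill::zeros);
      for (arma::uword i = 0; i < N; ++i)
        se[subj[i]] += y[i] - (Fth[i] - th0) - h2v[subj[i]] * agec[i];
      arma::vec u1(n), v1(n);
      for (arma::uword i = 0; i < n; ++i) {
        v1[i] = sig_e2 / ni[i] + (include_ranef ? sig_b2 : 0.0);
        u1[i] = se[i] / ni[i];
      }
      if (!fix_r1 || !fix_t1) {
        st1.rw_sd = st.rw_sd;
        if (!fix_r1) {
          tau1 = mh_sweep(s1, C, u1, v1, tau1, lev1, st1, acc1, att1);
        } else if (!fix_t1) {
          // r fixed: tau-only marginal move
          double ll_cur;
          if (marg_ll(s1.K, tau1, v1, u1, lev1, ll_cur)) {
            const double tnew = tau1 * std::exp(st1.tau_rw_sd * R::norm_rand());
            double ll_new;
            if (marg_ll(s1.K, tnew, v1, u1, lev1, ll_new)) {
              const double lprior = ig_logpdf(tnew, ig_a, ig_b) -
                                    ig_logpdf(tau1, ig_a, ig_b);
              if (std::log(R::unif_rand()) <
                  ll_new - ll_cur + lprior + std::log(tnew / tau1))
                tau1 = tnew;
            }
          }
        }
        if (adapt && it <= nburn && it % 100 == 0) adapt_step(st.rw_sd, acc1, att1);
      }
      const bool empty1 = arma::accu(s1.r > 0) == 0;
      if (collapse0) {
        // redraw the intercept from its surface-marginal conditional
        const double th0_new =
            draw_level(empty1 ? nullptr : &s1.K, tau1, v1, u1, theta_var);
        theta[0] = th0_new;
        Fth += th0_new - th0;
        u1 -= th0_new;
      }
      if (empty1) {
        h1.zeros();  // empty model: no surface
      } else {
        if (!surface_kinv(s1))
          stop("kernel factorisation failed for h1 after jitter escalation (iteration %d)", it);
        arma::mat A = s1.Kinv / tau1;
        arma::vec rhs(n);
        for (arma::uword i = 0; i < n; ++i) {
          A(i, i) += 1.0 / v1[i];
          rhs[i] = u1[i] / v1[i];
        }
        h1 = sample_gauss_prec(A, rhs);
      }
    }

    // --- surface 2 (per-year change): same treatment, with the
    // age-slope coefficient playing the level role ---
    if (include_h2) {
      const bool collapse1 = !fix_theta && p >= 2;
      const double lev2 = collapse1 ? theta_var : 0.0;
      const double th1 = collapse1 ? theta[1] : 0.0;
      arma::vec da(n, arma::fill::zeros), ra(n, arma::fill::zeros),
          sa(n, arma::fill::zeros), se(n, arma::fill::zeros);
      for (arma::uword i = 0; i < N; ++i) {
        const int si = subj[i];
        const double e = y[i] - (Fth[i] - th1 * agec[i]) - h1[si];
        da[si] += agec[i] * agec[i];
        ra[si] += agec[i] * e;
        sa[si] += agec[i];
        se[si] += e;
      }
      arma::vec D2(n), u2(n), v2(n);
      for (arma::uword i = 0; i < n; ++i) {
        const double kap = include_ranef
            ? sig_b2 / (sig_e2 + ni[i] * sig_b2) : 0.0;
        D2[i] = (da[i] - kap * sa[i] * sa[i]) / sig_e2;
        const double rhs_i = (ra[i] - kap * sa[i] * se[i]) / sig_e2;
        if (D2[i] > 1e-12) {
          u2[i] = rhs_i / D2[i];
          v2[i] = 1.0 / D2[i];
        } else {           // subject carries no information about h2
          u2[i] = 0.0;
          v2[i] = 1e12;
          D2[i] = 1e-12;
        }
      }
      if (!fix_r2) {
        st2.rw_sd = st.rw_sd;
        tau2 = mh_sweep(s2, C, u2, v2, tau2, lev2, st2, acc2, att2);
        if (adapt && it <= nburn && it % 100 == 0) adapt_step(st.rw_sd, acc2, att2);
      }
      const bool empty2 = arma::accu(s2.r > 0) == 0;
      if (collapse1) {
        const double th1_new =
            draw_level(empty2 ? nullptr : &s2.K, tau2, v2, u2, theta_var);
        theta[1] = th1_new;
        Fth += (th1_new - th1) * agec;
        u2 -= th1_new;
      }
      if (empty2) {
        h2v.zeros();
      } else {
        if (!surface_kinv(s2))
          stop("kernel factorisation failed for h2 after jitter escalation (iteration %d)", it);
        arma::mat A = s2.Kinv / tau2;
        arma::vec rhs(n);
        for (arma::uword i = 0; i < n; ++i) {
          A(i, i) += D2[i];
          rhs[i] = u2[i] * D2[i];
        }
        h2v = sample_gauss_prec(A, rhs);
      }
    }

    // --- random intercepts ---
    if (include_ranef) {
      arma::vec se(n, arma::fill::zeros);
      for (arma::uword i = 0; i < N; ++i) {
        const int si = subj[i];
        se[si] += y[i] - Fth[i] - h1[si] - h2v[si] * agec[i];
      }
      for (arma::uword i = 0; i < n; ++i) {
        const double prec = 1.0 / sig_b2 + ni[i] / sig_e2;
        b[i] = (se[i] / sig_e2) / prec + R::norm_rand() / std::sqrt(prec);
      }
    }

    // --- fixed effects ---
    if (!fix_theta) {
      arma::vec e(N);
      for (arma::uword i = 0; i < N; ++i) {
        const int si = subj[i];
        e[i] = y[i] - h1[si] - h2v[si] * agec[i] - b[si];
      }
      arma::mat A = FtF / sig_e2;
      A.diag() += 1.0 / theta_var;
      theta = sample_gauss_prec(A, F.t() * e / sig_e2);
      Fth = F * theta;
    }

    // --- variance components ---
    if (!fix_se) {
      double ssr = 0.0;
      for (arma::uword i = 0; i < N; ++i) {
        const int si = subj[i];
        const double e = y[i] - Fth[i] - h1[si] - h2v[si] * agec[i] - b[si];
        ssr += e * e;
      }
      sig_e2 = rinvgamma(ig_a + N / 2.0, ig_b + ssr / 2.0);
    }
    if (!fix_sb && include_ranef)
      sig_b2 = rinvgamma(ig_a + n / 2.0, ig_b + arma::dot(b, b) / 2.0);
    if (!std::isfinite(sig_e2) || !std::isfinite(sig_b2) ||
        !std::isfinite(tau1) || !std::isfinite(tau2))
      stop("divergent chain: non-finite variance draw at iteration %d", it);

    // --- record ---
    if (it > nburn && (it - nburn) % thin == 0) {
      const int k = (it - nburn) / thin - 1;
      d_theta.row(k) = theta.t();
      d_h1.row(k) = h1.t();
      d_h2.row(k) = h2v.t();
      d_r1.row(k) = s1.r.t();
      d_r2.row(k) = s2.r.t();
      d_se[k] = sig_e2;
      d_sb[k] = sig_b2;
      d_t1[k] = tau1;
      d_t2[k] = tau2;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["theta"] = d_theta, _["h1"] = d_h1, _["h2"] = d_h2,
      _["r1"] = d_r1, _["r2"] = d_r2, _["sigma_e2"] = d_se,
      _["sigma_b2"] = d_sb, _["tau1_2"] = d_t1, _["tau2_2"] = d_t2,
      _["rw_sd"] = st.rw_sd,
      _["rw_accept"] = NumericVector::create(
          att1 > 0 ? (double)acc1 / att1 : NA_REAL,
          att2 > 0 ? (double)acc2 / att2 : NA_REAL));
}

// [[Rcpp::export(name = ".bkmr_probit_mcmc")]]
List bkmr_probit_mcmc(const arma::ivec& y, const arma::mat& F,
                      const arma::mat& Z, const arma::ivec& group,
                      const int ngroup, const int niter, const int nburn,
                      const int thin, const List prior, const List control) {
  const arma::uword n = y.n_elem;
  const arma::uword M = Z.n_cols;
  const arma::uword p = F.n_cols;

  const double theta_var = as<double>(prior["theta_var"]);
  const double ig_a = as<double>(prior["ig_a"]);
  const double ig_b = as<double>(prior["ig_b"]);
  const double r_max = as<double>(prior["r_max"]);
  const double p_group = as<double>(prior["p_incl"]);
  const double prop_rate = as<double>(prior["prop_rate"]);
  const double tau_rw_sd = 0.8;
  double rw = as<double>(prior["rw_sd"]);
  const bool adapt = as<bool>(control["adapt"]);
  const bool include_h = as<bool>(control["include_h"]);

  std::vector<std::vector<int>> members(ngroup);
  for (arma::uword m = 0; m < M; ++m) members[group[m]].push_back((int)m);

  const arma::cube C = sqdist_cube(Z);
  const arma::mat FtF = F.t() * F;

  Surface s;
  surface_set(s, C, arma::vec(M, arma::fill::zeros));

  std::vector<int> active(ngroup, 0), sel(ngroup, -1);
  std::vector<double> rval(ngroup, 0.0);

  arma::vec theta(p, arma::fill::zeros), h(n, arma::fill::zeros), ystar(n);
  double tau2 = 1.0;
  arma::vec Fth = F * theta;
  const arma::vec vone(n, arma::fill::ones);

  const int ndraw = (niter - nburn) / thin;
  arma::mat d_theta(ndraw, p), d_h(ndraw, n), d_r(ndraw, M);
  arma::imat d_active(ndraw, ngroup), d_sel(ndraw, ngroup);
  arma::vec d_tau(ndraw);

  int acc_rw = 0, att_rw = 0;

  for (int it = 1; it <= niter; ++it) {
    // --- latent probit variables ---
    for (arma::uword i = 0; i < n; ++i)
      ystar[i] = rtnorm_mean(h[i] + Fth[i], y[i] == 1);

    if (include_h) {
      // intercept collapsed into the marginal alongside h
      arma::vec u = ystar - Fth + theta[0];
      const double lev = theta_var;
      int n_groups_on = 0;
      for (int g = 0; g < ngroup; ++g) n_groups_on += active[g];

      // --- hierarchical selection sweep, h marginalised; the empty
      // model (no active group) is h == 0 with no tau2 ---
      double ll_cur;
      bool ok_cur = true;
      if (n_groups_on == 0) ll_cur = null_ll(u, vone, lev);
      else ok_cur = marg_ll(s.K, tau2, vone, u, lev, ll_cur);
      const arma::vec uc0 = u - arma::mean(u);
      const double tau_pilot =
          std::max(0.05, arma::dot(uc0, uc0) / u.n_elem - 1.0);
      const double tau_prop_sd = 1.5;
      if (ok_cur) {
        for (int g = 0; g < ngroup; ++g) {
          const int gs = (int)members[g].size();
          const double d_choice = gs > 1 ? 1.0 / 3.0 : 0.5;
          std::vector<std::pair<int, double>> deltas;
          double lqdiff = 0.0, tau_cand = tau2;
          int new_sel = sel[g];
          double new_rval = rval[g];
          int new_active = active[g];
          bool is_rw = false;
          if (!active[g]) {
            const int m = members[g][(int)(R::unif_rand() * gs) % gs];
            const double rnew = R::exp_rand() / prop_rate;
            if (rnew >= r_max) continue;
            deltas = {{m, rnew}};
            lqdiff = std::log(p_group / (1.0 - p_group)) - std::log(r_max) -
                     std::log(prop_rate) + prop_rate * rnew +
                     std::log(d_choice);
            if (n_groups_on == 0) {
              tau_cand = std::exp(std::log(tau_pilot) +
                                  tau_prop_sd * R::norm_rand());
              lqdiff += ig_logpdf(tau_cand, ig_a, ig_b) -
                        lnorm_logpdf(tau_cand, std::log(tau_pilot),
                                     tau_prop_sd);
            }
            new_active = 1; new_sel = m; new_rval = rnew;
          } else {
            const double uu = R::unif_rand();
            if (uu < d_choice) {
              deltas = {{sel[g], -rval[g]}};
              lqdiff = std::log((1.0 - p_group) / p_group) +
                       std::log(r_max) + std::log(prop_rate) -
                       prop_rate * rval[g] - std::log(d_choice);
              if (n_groups_on == 1) {
                lqdiff += lnorm_logpdf(tau2, std::log(tau_pilot),
                                       tau_prop_sd) -
                          ig_logpdf(tau2, ig_a, ig_b);
              }
              new_active = 0; new_sel = -1; new_rval = 0.0;
            } else if (gs > 1 && uu < 2.0 * d_choice) {
              int m2 = members[g][(int)(R::unif_rand() * gs) % gs];
              while (m2 == sel[g])
                m2 = members[g][(int)(R::unif_rand() * gs) % gs];
              deltas = {{sel[g], -rval[g]}, {m2, rval[g]}};
              new_sel = m2;
            } else {
              ++att_rw;
              is_rw = true;
              const double rnew = rval[g] * std::exp(rw * R::norm_rand());
              if (rnew >= r_max) continue;
              deltas = {{sel[g], rnew - rval[g]}};
              lqdiff = std::log(rnew / rval[g]);
              new_rval = rnew;
            }
          }
          const int n_on_new = n_groups_on - active[g] + new_active;
          arma::mat Dc = s.D;
          for (const auto& pr : deltas) Dc += pr.second * C.slice(pr.first);
          double ll_new;
          arma::mat Kc;
          if (n_on_new == 0) {
            ll_new = null_ll(u, vone, lev);
          } else {
            Kc = arma::exp(-Dc);
            if (!marg_ll(Kc, tau_cand, vone, u, lev, ll_new)) continue;
          }
          if (std::log(R::unif_rand()) < ll_new - ll_cur + lqdiff) {
            s.D = std::move(Dc);
            s.K = n_on_new == 0 ? arma::exp(-s.D) : std::move(Kc);
            for (const auto& pr : deltas) s.r[pr.first] += pr.second;
            active[g] = new_active; sel[g] = new_sel; rval[g] = new_rval;
            s.kinv_fresh = false;
            ll_cur = ll_new;
            tau2 = tau_cand;
            n_groups_on = n_on_new;
            if (is_rw) ++acc_rw;
          }
        }
        // --- tau2 move (non-empty model only) ---
        if (n_groups_on > 0) {
          const double tnew = tau2 * std::exp(tau_rw_sd * R::norm_rand());
          double ll_new;
          if (marg_ll(s.K, tnew, vone, u, lev, ll_new)) {
            const double lprior = ig_logpdf(tnew, ig_a, ig_b) -
                                  ig_logpdf(tau2, ig_a, ig_b);
            if (std::log(R::unif_rand()) <
                ll_new - ll_cur + lprior + std::log(tnew / tau2))
              tau2 = tnew;
          }
        }
        if (!std::isfinite(tau2))
          stop("divergent chain: non-finite variance draw at iteration %d", it);
      }
      if (adapt && it <= nburn && it % 100 == 0) adapt_step(rw, acc_rw, att_rw);

      // redraw the intercept from its surface-marginal conditional,
      // then condition the h draw on it
      {
        const double th0_new = draw_level(
            n_groups_on == 0 ? nullptr : &s.K, tau2, vone, u, theta_var);
        Fth += th0_new - theta[0];
        theta[0] = th0_new;
        u -= th0_new;
      }

      // --- h | r, tau2, ystar ---
      if (n_groups_on == 0) {
        h.zeros();
      } else {
        if (!surface_kinv(s))
          stop("kernel factorisation failed after jitter escalation (iteration %d)", it);
        arma::mat A = s.Kinv / tau2;
        A.diag() += 1.0;
        h = sample_gauss_prec(A, u);
      }
    }

    // --- fixed effects (unit residual variance) ---
    {
      arma::mat A = FtF;
      A.diag() += 1.0 / theta_var;
      theta = sample_gauss_prec(A, F.t() * (ystar - h));
      Fth = F * theta;
    }

    // --- record ---
    if (it > nburn && (it - nburn) % thin == 0) {
      const int k = (it - nburn) / thin - 1;
      d_theta.row(k) = theta.t();
      d_h.row(k) = h.t();
      d_r.row(k) = s.r.t();
      d_tau[k] = tau2;
      for (int g = 0; g < ngroup; ++g) {
        d_active(k, g) = active[g];
        d_sel(k, g) = sel[g];  // 0-based metal index, -1 when inactive
      }
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["theta"] = d_theta, _["h"] = d_h, _["r"] = d_r,
      _["tau2"] = d_tau, _["active"] = d_active, _["sel"] = d_sel,
      _["rw_sd"] = rw,
      _["rw_accept"] = att_rw > 0 ? (double)acc_rw / att_rw : NA_REAL);
}
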