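// Gibbs-within-Metropolis sampler for the two-level dynamic location-scale
// model of trial series:
//   y_t = mu_i + phi_i * y_{t-1} + bt_i * t + e_t,  e_t ~ N(0, psi_i)
//   (mu, phi, bt, log psi)_i ~ MVN(G x_i, tau)  over the active components
//   x_i (covariates) ~ MVN(nu, Sigma), estimated jointly; missing covariate
//   entries and missing trials are carried as draws.
//
// Centered (hierarchical) parameterization: person effects eta_i are sampled
// directly against their covariate-implied prior, which keeps every update
// conjugate except the log-variance (1-d adaptive random-walk MH per person)
// and the log-variance fixed-effect row when psi carries no random effect.
// All randomness flows through R's RNG so seeds set in R govern the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_PSI_FLOOR = -27.631021; // log(1e-12)

static double rnorm1() { return R::norm_rand(); }

struct Person {
  arma::vec y;     // working series (missing entries hold current imputation)
  arma::vec tr;    // trial numbers
  arma::uvec miss; // 0-based indices of missing y
  arma::mat M;     // sum over t>=2 of z z', z = (1, y_{t-1}, t)
  arma::vec q;     // sum z * y_t
  double s;        // sum y_t^2 over t>=2
  double n_eff;    // number of t>=2 terms

  void update_crossprods() {
    const int T = y.n_elem;
    M.zeros(3, 3);
    q.zeros(3);
    s = 0.0;
    arma::vec z(3);
    for (int t = 1; t < T; ++t) {
      z[0] = 1.0; z[1] = y[t - 1]; z[2] = tr[t];
      M += z * z.t();
      q += z * y[t];
      s += y[t] * y[t];
    }
    n_eff = T - 1;
  }
};

// Inverse-Wishart draw with scale S and degrees of freedom df (Bartlett).
static arma::mat riwish(const arma::mat& S, double df) {
  const int d = S.n_rows;
  arma::mat Sreg = arma::symmatu(S) + 1e-12 * arma::trace(S) / d * arma::eye(d, d);
  arma::mat A = arma::chol(arma::inv_sympd(Sreg), "lower");
  arma::mat T(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    T(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) T(i, j) = rnorm1();
  }
  arma::mat L = A * T;
  return arma::inv_sympd(arma::symmatu(L * L.t()));
}

// MVN draw parameterized by precision P and linear term rhs (mean = P^-1 rhs).
static arma::vec mvn_from_precision(const arma::mat& P, const arma::vec& rhs) {
  arma::mat L = arma::chol(arma::symmatu(P), "lower");
  arma::vec mu = arma::solve(arma::trimatl(L), rhs);
  mu = arma::solve(arma::trimatu(L.t()), mu);
  arma::vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = rnorm1();
  return mu + arma::solve(arma::trimatu(L.t()), z);
}

// [[Rcpp::export]]
List dsem_mcmc_chain(List y_list, List tr_list,
                     arma::mat X, arma::imat x_mis,
                     LogicalVector include_random,
                     int n_iter, int n_burn, int thin,
                     arma::mat prior_mean, arma::mat prior_prec,
                     arma::mat G0, arma::mat tau0, arma::mat eta0,
                     arma::vec nu0, arma::mat Sig0) {
  const int n = y_list.size();
  const int p = X.n_cols;
  const int ncov = p - 1;

  // component bookkeeping
  arma::uvec idx_a;               // active (random) components, ascending
  arma::uvec am;                  // active mean components (subset of 0..2)
  arma::uvec fm;                  // fixed mean components
  const bool av = include_random[3];
  for (int j = 0; j < 4; ++j)
    if (include_random[j]) idx_a.insert_rows(idx_a.n_elem, arma::uvec{(arma::uword)j});
  for (arma::uword j = 0; j < 3; ++j) {
    if (include_random[j]) am.insert_rows(am.n_elem, arma::uvec{j});
    else fm.insert_rows(fm.n_elem, arma::uvec{j});
  }
  const int da = idx_a.n_elem, dm = am.n_elem, dfm = fm.n_elem;

  std::vector<Person> per(n);
  bool any_y_miss = false;
  for (int i = 0; i < n; ++i) {
    per[i].y = as<arma::vec>(y_list[i]);
    per[i].tr = as<arma::vec>(tr_list[i]);
    arma::uvec m = arma::find_nonfinite(per[i].y);
    per[i].miss = m;
    if (m.n_elem > 0) {
      any_y_miss = true;
      // start missing values at the mean of the observed part
      arma::uvec obs = arma::find_finite(per[i].y);
      double m0 = arma::mean(per[i].y.elem(obs));
      per[i].y.elem(m).fill(m0);
    }
    per[i].update_crossprods();
  }
  bool any_x_miss = arma::accu(x_mis) > 0;

  arma::mat G = G0;
  arma::mat eta = eta0;
  arma::mat tau_a;
  if (da > 0) tau_a = tau0.submat(idx_a, idx_a);
  arma::vec nu = nu0;
  arma::mat Sig = Sig0;

  arma::vec vstep(n, arma::fill::value(0.3));
  arma::vec scstep(std::max(da, 1), arma::fill::value(0.3));
  double vacc = 0.0, vtry = 0.0;
  double wstep = 0.02, wacc = 0.0, wtry = 0.0;

  arma::mat Sxx = X.t() * X;

  const int kept = (n_iter - n_burn) / thin;
  arma::cube G_store(4, p, kept);
  arma::cube tau_store(4, 4, kept, arma::fill::zeros);
  arma::cube eta_store(n, 4, kept);
  arma::mat numean_store(kept, std::max(ncov, 1), arma::fill::zeros);
  arma::cube sig_store(std::max(ncov, 1), std::max(ncov, 1), kept,
                       arma::fill::zeros);
  arma::vec ll_store(kept, arma::fill::zeros);
  int k = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // ---- missing trial outcomes: conditional normal given neighbors ----
    if (any_y_miss) {
      for (int i = 0; i < n; ++i) {
        if (per[i].miss.n_elem == 0) continue;
        const double mu = eta(i, 0), phi = eta(i, 1), bt = eta(i, 2);
        const double psi = std::exp(std::max(eta(i, 3), LOG_PSI_FLOOR));
        const int T = per[i].y.n_elem;
        for (arma::uword mI = 0; mI < per[i].miss.n_elem; ++mI) {
          const int t = per[i].miss[mI];
          double prec = 0.0, rhs = 0.0;
          if (t >= 1) {
            prec += 1.0 / psi;
            rhs += (mu + phi * per[i].y[t - 1] + bt * per[i].tr[t]) / psi;
          } else {
            double m1, v1;
            if (std::fabs(phi) < 0.999) {
              m1 = (mu + bt * per[i].tr[0]) / (1.0 - phi);
              v1 = psi / (1.0 - phi * phi);
            } else { m1 = mu; v1 = psi; }
            prec += 1.0 / v1;
            rhs += m1 / v1;
          }
          if (t + 1 < T) {
            prec += phi * phi / psi;
            rhs += phi * (per[i].y[t + 1] - mu - bt * per[i].tr[t + 1]) / psi;
          }
          per[i].y[t] = rhs / prec + rnorm1() / std::sqrt(prec);
        }
        per[i].update_crossprods();
      }
    }

    // ---- tau partitions for the person-level conditionals ----
    arma::mat Sb_inv;        // prior precision of active mean block | u3
    arma::vec kbv;           // regression of mean block on u3
    arma::vec kvb;           // regression of u3 on mean block
    double s2v = 0.0, tau_vv = 0.0;
    if (da > 0) {
      if (dm > 0) {
        arma::mat Tmm = arma::symmatu(tau_a.submat(0, 0, dm - 1, dm - 1));
        // absolute floor keeps conditional precisions bounded when a
        // component's variance (or its Schur complement) collapses toward
        // zero on data truly lacking that random effect
        arma::mat ridge = 1e-12 * arma::eye(dm, dm);
        if (av) {
          arma::vec Tmv = tau_a.submat(0, dm, dm - 1, dm).col(0);
          tau_vv = tau_a(dm, dm);
          kbv = Tmv / tau_vv;
          arma::mat Sb = Tmm - Tmv * Tmv.t() / tau_vv;
          Sb_inv = arma::inv_sympd(arma::symmatu(Sb) + ridge);
          kvb = arma::inv_sympd(Tmm + ridge) * Tmv;
          s2v = std::max(tau_vv - arma::dot(Tmv, kvb), 1e-12);
        } else {
          Sb_inv = arma::inv_sympd(Tmm + ridge);
        }
      } else if (av) {
        tau_vv = tau_a(0, 0);
        s2v = tau_vv;
      }
    }

    // ---- person-level effects ----
    for (int i = 0; i < n; ++i) {
      arma::vec x_i = X.row(i).t();
      arma::vec p_i = G * x_i;
      // keep fixed mean components pinned to their covariate prediction
      for (int j = 0; j < dfm; ++j) eta(i, fm[j]) = p_i(fm[j]);
      double v = av ? eta(i, 3) : p_i(3);
      double psi = std::exp(std::max(v, LOG_PSI_FLOOR));

      if (dm > 0) {
        arma::vec bm = p_i.elem(am);
        if (av) bm += kbv * (v - p_i(3));
        arma::mat A = per[i].M.submat(am, am) / psi + Sb_inv;
        arma::vec rhs = per[i].q.elem(am);
        if (dfm > 0) rhs -= per[i].M.submat(am, fm) * p_i.elem(fm);
        rhs = rhs / psi + Sb_inv * bm;
        arma::vec b = mvn_from_precision(A, rhs);
        for (int j = 0; j < dm; ++j) eta(i, am[j]) = b[j];
      }

      // residual sum of squares at the current mean components
      arma::vec b3 = eta.row(i).cols(0, 2).t();
      double SSR = per[i].s - 2.0 * arma::dot(b3, per[i].q) +
                   arma::as_scalar(b3.t() * per[i].M * b3);
      if (SSR < 0) SSR = 0;

      if (av) {
        double mprior = p_i(3);
        if (dm > 0) {
          arma::vec dev = eta.row(i).t();
          arma::vec devm = dev.elem(am) - p_i.elem(am);
          mprior += arma::dot(kvb, devm);
        }
        const double vcur = eta(i, 3);
        const double lp_cur = -0.5 * per[i].n_eff * vcur -
                              0.5 * SSR * std::exp(-vcur) -
                              0.5 * (vcur - mprior) * (vcur - mprior) / s2v;
        const double vprop = vcur + vstep[i] * rnorm1();
        double alpha = 0.0;
        if (vprop > LOG_PSI_FLOOR) {
          const double lp_prop = -0.5 * per[i].n_eff * vprop -
                                 0.5 * SSR * std::exp(-vprop) -
                                 0.5 * (vprop - mprior) * (vprop - mprior) / s2v;
          alpha = std::min(1.0, std::exp(lp_prop - lp_cur));
          if (R::unif_rand() < alpha) eta(i, 3) = vprop;
        }
        vtry += 1.0; vacc += alpha;
        if (it <= n_burn)
          vstep[i] = std::clamp(
              vstep[i] * std::exp((alpha - 0.44) / std::sqrt((double)it)),
              1e-3, 5.0);
      } else {
        eta(i, 3) = p_i(3);
      }
    }

    // ---- fixed effects G ----
    if (any_x_miss) Sxx = X.t() * X;
    if (da > 0) {
      arma::mat tauinv = arma::inv_sympd(arma::symmatu(tau_a));
      arma::mat Ea = eta.cols(idx_a);
      arma::mat Prec = arma::kron(Sxx, tauinv);
      arma::vec rhs = arma::vectorise(tauinv * Ea.t() * X);
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j < da; ++j) {
          const int pos = kk * da + j;
          const double pp = prior_prec(idx_a[j], kk);
          Prec(pos, pos) += pp;
          rhs(pos) += pp * prior_mean(idx_a[j], kk);
        }
      arma::vec g = mvn_from_precision(Prec, rhs);
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j < da; ++j) G(idx_a[j], kk) = g[kk * da + j];
    }
    if (dfm > 0) {
      const int qf = dfm * p;
      arma::mat A(qf, qf, arma::fill::zeros);
      arma::vec rhs(qf, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::vec x_i = X.row(i).t();
        const double psi = std::exp(std::max(eta(i, 3), LOG_PSI_FLOOR));
        arma::mat Mff = per[i].M.submat(fm, fm);
        arma::vec rv = per[i].q.elem(fm);
        if (dm > 0) {
          arma::vec ba(dm);
          for (int j = 0; j < dm; ++j) ba[j] = eta(i, am[j]);
          rv -= per[i].M.submat(fm, am) * ba;
        }
        A += arma::kron(x_i * x_i.t(), Mff) / psi;
        for (int kk = 0; kk < p; ++kk)
          rhs.subvec(kk * dfm, (kk + 1) * dfm - 1) += x_i[kk] * rv / psi;
      }
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j < dfm; ++j) {
          const int pos = kk * dfm + j;
          const double pp = prior_prec(fm[j], kk);
          A(pos, pos) += pp;
          rhs(pos) += pp * prior_mean(fm[j], kk);
        }
      arma::vec g = mvn_from_precision(A, rhs);
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j < dfm; ++j) G(fm[j], kk) = g[kk * dfm + j];
      for (int i = 0; i < n; ++i) {
        arma::vec x_i = X.row(i).t();
        for (int j = 0; j < dfm; ++j)
          eta(i, fm[j]) = arma::dot(G.row(fm[j]), x_i);
      }
    }
    if (!av) {
      // log-variance fixed-effect row by adaptive random-walk MH
      arma::vec SSRv(n), neffv(n);
      for (int i = 0; i < n; ++i) {
        arma::vec b3 = eta.row(i).cols(0, 2).t();
        double SSR = per[i].s - 2.0 * arma::dot(b3, per[i].q) +
                     arma::as_scalar(b3.t() * per[i].M * b3);
        SSRv[i] = std::max(SSR, 0.0);
        neffv[i] = per[i].n_eff;
      }
      arma::vec w = G.row(3).t();
      auto logpost = [&](const arma::vec& ww) {
        double lp = 0.0;
        for (int i = 0; i < n; ++i) {
          const double v = arma::dot(ww, X.row(i).t());
          if (v < LOG_PSI_FLOOR) return -arma::datum::inf;
          lp += -0.5 * neffv[i] * v - 0.5 * SSRv[i] * std::exp(-v);
        }
        for (int kk = 0; kk < p; ++kk)
          lp += -0.5 * prior_prec(3, kk) *
                (ww[kk] - prior_mean(3, kk)) * (ww[kk] - prior_mean(3, kk));
        return lp;
      };
      double lp_cur = logpost(w);
      for (int rep = 0; rep < 2; ++rep) {
        arma::vec wprop = w;
        for (int kk = 0; kk < p; ++kk) wprop[kk] += wstep * rnorm1();
        const double lp_prop = logpost(wprop);
        const double alpha = std::min(1.0, std::exp(lp_prop - lp_cur));
        if (R::unif_rand() < alpha) { w = wprop; lp_cur = lp_prop; }
        wtry += 1.0; wacc += alpha;
        if (it <= n_burn)
          wstep = std::clamp(
              wstep * std::exp((alpha - 0.23) / std::sqrt((double)it)),
              1e-4, 2.0);
      }
      G.row(3) = w.t();
      eta.col(3) = X * w;
    }

    // ---- random-effect covariance ----
    if (da > 0) {
      arma::mat E = eta.cols(idx_a) - X * G.rows(idx_a).t();
      arma::mat S = E.t() * E;
      // numerical floor: keeps tau invertible when a component's deviations
      // collapse toward zero (data truly without that random effect)
      S.diag() += 1e-10;
      // flat (uniform over PD matrices) prior on tau: posterior
      // IW(S, n - d - 1). The scale-free |tau|^-(d+1)/2 alternative puts a
      // density spike at singular tau that traps chains in a spurious
      // zero-variance mode for weakly identified components.
      tau_a = riwish(S, (double)(n - da - 1));
      tau_a.diag() += 1e-12;
    }

    // ---- group scale moves along each component's funnel direction ----
    // Jointly rescales one component's person deviations and the matching
    // row/column of tau — the move that lets chains traverse the
    // small-variance funnel that plain centered Gibbs crosses only
    // geometrically slowly.
    for (int aj = 0; aj < da; ++aj) {
      const int j = idx_a[aj];
      arma::vec gx = X * G.row(j).t();
      arma::vec u = eta.col(j) - gx;
      const double s = std::exp(scstep[aj] * rnorm1());
      double dll = 0.0;
      if (j < 3) {
        for (int i = 0; i < n; ++i) {
          const double psi = std::exp(std::max(eta(i, 3), LOG_PSI_FLOOR));
          arma::vec b3 = eta.row(i).cols(0, 2).t();
          const double grad = arma::dot(per[i].M.row(j), b3) - per[i].q[j];
          const double del = (s - 1.0) * u[i];
          dll += -0.5 * (2.0 * del * grad + del * del * per[i].M(j, j)) / psi;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          const double v0 = eta(i, 3);
          const double v1 = gx[i] + s * u[i];
          if (v1 < LOG_PSI_FLOOR) { dll = -arma::datum::inf; break; }
          arma::vec b3 = eta.row(i).cols(0, 2).t();
          double SSR = per[i].s - 2.0 * arma::dot(b3, per[i].q) +
                       arma::as_scalar(b3.t() * per[i].M * b3);
          SSR = std::max(SSR, 0.0);
          dll += -0.5 * per[i].n_eff * (v1 - v0) -
                 0.5 * SSR * (std::exp(-v1) - std::exp(-v0));
        }
      }
      // under the flat tau prior the Jacobian and deviation-density terms
      // leave a residual (d+1) log s; the likelihood supplies the rest
      const double alpha =
          std::min(1.0, std::exp(dll + (da + 1) * std::log(s)));
      if (R::unif_rand() < alpha) {
        eta.col(j) = gx + s * u;
        tau_a.row(aj) *= s;
        tau_a.col(aj) *= s;
      }
      if (it <= n_burn)
        scstep[aj] = std::clamp(
            scstep[aj] * std::exp((alpha - 0.44) / std::sqrt((double)it)),
            1e-3, 2.0);
    }

    // ---- exogenous covariate model (joint likelihood for missingness) ----
    if (ncov > 0) {
      arma::mat xc = X.cols(1, p - 1);
      arma::rowvec xbar = arma::mean(xc, 0);
      arma::mat xd = xc.each_row() - xbar;
      arma::mat S0 = xd.t() * xd;
      Sig = riwish(S0, (double)(n - 1));
      arma::mat Ln = arma::chol(arma::symmatu(Sig / (double)n), "lower");
      arma::vec z(ncov);
      for (int kk = 0; kk < ncov; ++kk) z[kk] = rnorm1();
      nu = xbar.t() + Ln * z;

      if (any_x_miss && da == 4) {
        arma::mat tauinv = arma::inv_sympd(arma::symmatu(tau_a));
        for (int i = 0; i < n; ++i) {
          arma::uvec mis, obs;
          for (int c = 0; c < ncov; ++c) {
            if (x_mis(i, c)) mis.insert_rows(mis.n_elem, arma::uvec{(arma::uword)c});
            else obs.insert_rows(obs.n_elem, arma::uvec{(arma::uword)c});
          }
          if (mis.n_elem == 0) continue;
          arma::vec mc; arma::mat C;
          if (obs.n_elem == 0) { mc = nu; C = Sig; }
          else {
            arma::mat Soo = Sig.submat(obs, obs);
            arma::mat Smo = Sig.submat(mis, obs);
            arma::vec xo(obs.n_elem);
            for (arma::uword j = 0; j < obs.n_elem; ++j) xo[j] = X(i, 1 + obs[j]);
            arma::mat K = Smo * arma::inv_sympd(arma::symmatu(Soo));
            mc = nu.elem(mis) + K * (xo - nu.elem(obs));
            C = Sig.submat(mis, mis) - K * Smo.t();
          }
          arma::uvec gcols_mis = mis + 1;
          arma::mat B = G.cols(gcols_mis);
          arma::vec r = eta.row(i).t() - G.col(0);
          for (arma::uword j = 0; j < obs.n_elem; ++j)
            r -= G.col(1 + obs[j]) * X(i, 1 + obs[j]);
          arma::mat Cinv = arma::inv_sympd(arma::symmatu(C));
          arma::mat P = Cinv + B.t() * tauinv * B;
          arma::vec rhs = Cinv * mc + B.t() * tauinv * r;
          arma::vec xm = mvn_from_precision(P, rhs);
          for (arma::uword j = 0; j < mis.n_elem; ++j) X(i, 1 + mis[j]) = xm[j];
        }
      }
    }

    // ---- storage ----
    if (it > n_burn && ((it - n_burn) % thin == 0) && k < kept) {
      G_store.slice(k) = G;
      if (da > 0) {
        arma::mat tf(4, 4, arma::fill::zeros);
        tf.submat(idx_a, idx_a) = tau_a;
        tau_store.slice(k) = tf;
      }
      eta_store.slice(k) = eta;
      if (ncov > 0) {
        numean_store.row(k) = nu.t();
        sig_store.slice(k) = Sig;
      }
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        arma::vec b3 = eta.row(i).cols(0, 2).t();
        double SSR = per[i].s - 2.0 * arma::dot(b3, per[i].q) +
                     arma::as_scalar(b3.t() * per[i].M * b3);
        SSR = std::max(SSR, 0.0);
        const double v = std::max(eta(i, 3), LOG_PSI_FLOOR);
        ll += -0.5 * per[i].n_eff * (std::log(2.0 * M_PI) + v) -
              0.5 * SSR * std::exp(-v);
      }
      ll_store[k] = ll;
      ++k;
    }
  }

  return List::create(
    _["G"] = G_store, _["tau"] = tau_store, _["eta"] = eta_store,
    _["exo_mean"] = numean_store, _["exo_cov"] = sig_store,
    _["loglik"] = ll_store,
    _["accept_v"] = (vtry > 0 ? vacc / vtry : NA_REAL),
    _["accept_w"] = (wtry > 0 ? wacc / wtry : NA_REAL));
}
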