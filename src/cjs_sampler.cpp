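// Marginalized multispecies CJS likelihood and adaptive MCMC.
//
// The likelihood uses the sufficient-statistic form of the chi-recursion
// CJS model: for each species-by-stream group g and interval t,
//   A[g,t]  multiplies log(phi_t)      (forced-alive transitions),
//   D[g,t]  multiplies log(p_{t+1})    (detections after first capture),
//   N[g,t]  multiplies log(1-p_{t+1})  (non-detections inside the history),
//   C[g,o]  multiplies log(chi_o)      (individuals last seen at occasion o),
// with chi_T = 1, chi_o = (1-phi_o) + phi_o (1-p_{o+1}) chi_{o+1}.
// These counts are precomputed once from the capture histories, so one
// likelihood evaluation costs O(T) per group regardless of sample size.
//
// The sampler is adaptive random-walk Metropolis within Gibbs over the
// marginalized posterior. Confounded additive random-effect blocks mix
// through likelihood-invariant "sweep" moves that shift mass between a
// shared effect and the finer effects it overlaps (accepted on the prior
// ratio alone, since the linear predictor is unchanged).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PEPS = 1e-12;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double clampp(double p) {
  return std::min(std::max(p, PEPS), 1.0 - PEPS);
}

// log-likelihood of one group from sufficient statistics.
// phi, p: length T1 arrays (interval scale); chi scratch: length T1 + 1.
static double loglik_group_stats(int g, int T1,
                                 const NumericMatrix& A,
                                 const NumericMatrix& D,
                                 const NumericMatrix& N,
                                 const NumericMatrix& C,
                                 const double* phi, const double* p,
                                 double* chi) {
  chi[T1] = 1.0;  // chi at final occasion
  for (int t = T1 - 1; t >= 0; --t)
    chi[t] = (1.0 - phi[t]) + phi[t] * (1.0 - p[t]) * chi[t + 1];
  double out = 0.0;
  for (int t = 0; t < T1; ++t) {
    if (A(g, t) > 0) out += A(g, t) * std::log(phi[t]);
    if (D(g, t) > 0) out += D(g, t) * std::log(p[t]);
    if (N(g, t) > 0) out += N(g, t) * std::log(1.0 - p[t]);
  }
  for (int o = 0; o <= T1; ++o)            // occasions 1..T, 0-based
    if (C(g, o) > 0) out += C(g, o) * std::log(chi[o]);
  return out;
}

// [[Rcpp::export]]
double cjs_loglik_stats_cpp(NumericMatrix A, NumericMatrix D, NumericMatrix N,
                            NumericMatrix C, NumericMatrix phi,
                            NumericMatrix p) {
  int G = A.nrow(), T1 = A.ncol();
  std::vector<double> ph(T1), pp(T1), chi(T1 + 1);
  double out = 0.0;
  for (int g = 0; g < G; ++g) {
    for (int t = 0; t < T1; ++t) {
      ph[t] = clampp(phi(g, t));
      pp[t] = clampp(p(g, t));
    }
    out += loglik_group_stats(g, T1, A, D, N, C, ph.data(), pp.data(),
                              chi.data());
  }
  return out;
}

struct Sampler {
  // dimensions and design
  int T1, G, J, S;
  int variant_beta;        // 0 none, 1 per-species, 2 shared
  bool use_re, baseline60;
  std::vector<int> gj, gs; // 0-based species/stream of each group
  std::vector<double> frac, x;
  NumericMatrix A, D, N, C;
  double mu_sd, beta_sd, sigma_upper;

  // state
  std::vector<double> mu, beta, lp;          // lp: logit detection, g + t*G
  std::vector<double> e1, e2, e3, e4;        // e2: j + t*J, e3: s + t*S, e4: g + t*G
  double sig_t;
  std::vector<double> sig_j, sig_s, sig_js;

  std::vector<double> ll;                    // per-group loglik cache
  double total_ll;

  // adaptation
  std::vector<double> lstep;
  std::vector<int> acc, att;
  bool adapting;

  // scratch
  std::vector<double> phbuf, ppbuf, chibuf;
  std::vector<std::vector<int> > grp_of_species, grp_of_stream;
  std::vector<int> all_groups;

  double eta(int g, int t) const {
    double v = mu[g];
    if (variant_beta == 1) v += beta[gj[g]] * x[t];
    else if (variant_beta == 2) v += beta[0] * x[t];
    if (use_re)
      v += e1[t] + e2[gj[g] + t * J] + e3[gs[g] + t * S] + e4[g + t * G];
    return v;
  }

  double group_ll(int g) {
    for (int t = 0; t < T1; ++t) {
      double b = invlogit(eta(g, t));
      phbuf[t] = clampp(baseline60 ? std::pow(b, frac[t]) : b);
      ppbuf[t] = clampp(invlogit(lp[g + t * G]));
    }
    return loglik_group_stats(g, T1, A, D, N, C, phbuf.data(), ppbuf.data(),
                              chibuf.data());
  }

  void refresh_all_ll() {
    total_ll = 0.0;
    for (int g = 0; g < G; ++g) { ll[g] = group_ll(g); total_ll += ll[g]; }
  }

  // Generic MH step. `mutate(delta)` applies the move and returns the log
  // prior ratio; rejection applies mutate(-delta). `groups` lists groups
  // whose likelihood the move touches (empty = likelihood-invariant).
  template <class F>
  void mh(int pid, const std::vector<int>& groups, F mutate) {
    double delta = norm_rand() * std::exp(lstep[pid]);
    double logr = mutate(delta);
    double ll_new_sum = 0.0, ll_old_sum = 0.0;
    std::vector<double> ll_new(groups.size());
    for (size_t k = 0; k < groups.size(); ++k) {
      ll_new[k] = group_ll(groups[k]);
      ll_new_sum += ll_new[k];
      ll_old_sum += ll[groups[k]];
    }
    logr += ll_new_sum - ll_old_sum;
    ++att[pid];
    if (std::log(unif_rand()) < logr) {
      ++acc[pid];
      for (size_t k = 0; k < groups.size(); ++k) {
        ll[groups[k]] = ll_new[k];
      }
      total_ll += ll_new_sum - ll_old_sum;
    } else {
      mutate(-delta);
    }
  }

  static inline double dnorm_lratio(double xnew, double xold, double sd) {
    return (xold * xold - xnew * xnew) / (2.0 * sd * sd);
  }

  void update_sigma(int pid, double& sig, const double* eps, int n) {
    // random walk on log sigma; uniform(0, sigma_upper) prior on sigma
    double u = std::log(sig);
    double unew = u + norm_rand() * std::exp(lstep[pid]);
    double snew = std::exp(unew);
    ++att[pid];
    if (snew >= sigma_upper) return;
    double sse = 0.0;
    for (int k = 0; k < n; ++k) sse += eps[k] * eps[k];
    double logr = (unew - u)                                  // Jacobian
      + n * (u - unew)                                        // normal norm.
      + sse * (1.0 / (2.0 * sig * sig) - 1.0 / (2.0 * snew * snew));
    if (std::log(unif_rand()) < logr) { ++acc[pid]; sig = snew; }
  }

  void adapt(int batch) {
    double d = std::min(0.25, 1.0 / std::sqrt((double)batch));
    for (size_t k = 0; k < lstep.size(); ++k) {
      if (att[k] == 0) continue;
      double rate = (double)acc[k] / att[k];
      lstep[k] += (rate > 0.44 ? d : -d);
      acc[k] = 0; att[k] = 0;
    }
  }

  void one_iteration() {
    int pid = 0;
    // intercepts
    for (int g = 0; g < G; ++g, ++pid) {
      std::vector<int> grp(1, g);
      double* m = &mu[g];
      mh(pid, grp, [this, m](double d) {
        double old = *m; *m += d;
        return dnorm_lratio(*m, old, mu_sd);
      });
    }
    // effect sizes
    if (variant_beta == 1) {
      for (int j = 0; j < J; ++j, ++pid) {
        double* b = &beta[j];
        mh(pid, grp_of_species[j], [this, b](double d) {
          double old = *b; *b += d;
          return dnorm_lratio(*b, old, beta_sd);
        });
      }
    } else if (variant_beta == 2) {
      double* b = &beta[0];
      mh(pid, all_groups, [this, b](double d) {
        double old = *b; *b += d;
        return dnorm_lratio(*b, old, beta_sd);
      });
      ++pid;
    }
    // detection (logit scale, uniform(0,1) prior => Jacobian term)
    for (int g = 0; g < G; ++g)
      for (int t = 0; t < T1; ++t, ++pid) {
        std::vector<int> grp(1, g);
        double* v = &lp[g + t * G];
        mh(pid, grp, [v](double d) {
          double old = *v; *v += d;
          double lpr = *v - 2.0 * std::log1p(std::exp(*v));
          double lpo = old - 2.0 * std::log1p(std::exp(old));
          return lpr - lpo;
        });
      }
    if (use_re) {
      // e1
      for (int t = 0; t < T1; ++t, ++pid) {
        double* v = &e1[t];
        mh(pid, all_groups, [this, v](double d) {
          double old = *v; *v += d;
          return dnorm_lratio(*v, old, sig_t);
        });
      }
      // e2
      for (int j = 0; j < J; ++j)
        for (int t = 0; t < T1; ++t, ++pid) {
          double* v = &e2[j + t * J];
          double sd = sig_j[j];
          mh(pid, grp_of_species[j], [v, sd](double d) {
            double old = *v; *v += d;
            return dnorm_lratio(*v, old, sd);
          });
        }
      // e3
      for (int s = 0; s < S; ++s)
        for (int t = 0; t < T1; ++t, ++pid) {
          double* v = &e3[s + t * S];
          double sd = sig_s[s];
          mh(pid, grp_of_stream[s], [v, sd](double d) {
            double old = *v; *v += d;
            return dnorm_lratio(*v, old, sd);
          });
        }
      // e4
      for (int g = 0; g < G; ++g)
        for (int t = 0; t < T1; ++t, ++pid) {
          std::vector<int> grp(1, g);
          double* v = &e4[g + t * G];
          double sd = sig_js[g];
          mh(pid, grp, [v, sd](double d) {
            double old = *v; *v += d;
            return dnorm_lratio(*v, old, sd);
          });
        }
      // standard deviations (no likelihood term)
      {
        update_sigma(pid++, sig_t, e1.data(), T1);
        for (int j = 0; j < J; ++j, ++pid) {
          std::vector<double> row(T1);
          for (int t = 0; t < T1; ++t) row[t] = e2[j + t * J];
          update_sigma(pid, sig_j[j], row.data(), T1);
        }
        for (int s = 0; s < S; ++s, ++pid) {
          std::vector<double> row(T1);
          for (int t = 0; t < T1; ++t) row[t] = e3[s + t * S];
          update_sigma(pid, sig_s[s], row.data(), T1);
        }
        for (int g = 0; g < G; ++g, ++pid) {
          std::vector<double> row(T1);
          for (int t = 0; t < T1; ++t) row[t] = e4[g + t * G];
          update_sigma(pid, sig_js[g], row.data(), T1);
        }
      }
      // likelihood-invariant sweep moves
      std::vector<int> none;
      for (int t = 0; t < T1; ++t, ++pid) {   // e1 <-> e4
        mh(pid, none, [this, t](double d) {
          double lr = dnorm_lratio(e1[t] + d, e1[t], sig_t);
          e1[t] += d;
          for (int g = 0; g < G; ++g) {
            double* v = &e4[g + t * G];
            lr += dnorm_lratio(*v - d, *v, sig_js[g]);
            *v -= d;
          }
          return lr;
        });
      }
      for (int j = 0; j < J; ++j)             // e2 <-> e4
        for (int t = 0; t < T1; ++t, ++pid) {
          mh(pid, none, [this, j, t](double d) {
            double* w = &e2[j + t * J];
            double lr = dnorm_lratio(*w + d, *w, sig_j[j]);
            *w += d;
            for (size_t k = 0; k < grp_of_species[j].size(); ++k) {
              int g = grp_of_species[j][k];
              double* v = &e4[g + t * G];
              lr += dnorm_lratio(*v - d, *v, sig_js[g]);
              *v -= d;
            }
            return lr;
          });
        }
      for (int s = 0; s < S; ++s)             // e3 <-> e4
        for (int t = 0; t < T1; ++t, ++pid) {
          mh(pid, none, [this, s, t](double d) {
            double* w = &e3[s + t * S];
            double lr = dnorm_lratio(*w + d, *w, sig_s[s]);
            *w += d;
            for (size_t k = 0; k < grp_of_stream[s].size(); ++k) {
              int g = grp_of_stream[s][k];
              double* v = &e4[g + t * G];
              lr += dnorm_lratio(*v - d, *v, sig_js[g]);
              *v -= d;
            }
            return lr;
          });
        }
      // mu <-> e1 (shift overall level between intercepts and e1)
      mh(pid++, none, [this](double d) {
        double lr = 0.0;
        for (int g = 0; g < G; ++g) {
          lr += dnorm_lratio(mu[g] + d, mu[g], mu_sd);
          mu[g] += d;
        }
        for (int t = 0; t < T1; ++t) {
          lr += dnorm_lratio(e1[t] - d, e1[t], sig_t);
          e1[t] -= d;
        }
        return lr;
      });
      // mu[g] <-> e4 row g
      for (int g = 0; g < G; ++g, ++pid) {
        mh(pid, none, [this, g](double d) {
          double lr = dnorm_lratio(mu[g] + d, mu[g], mu_sd);
          mu[g] += d;
          for (int t = 0; t < T1; ++t) {
            double* v = &e4[g + t * G];
            lr += dnorm_lratio(*v - d, *v, sig_js[g]);
            *v -= d;
          }
          return lr;
        });
      }
      // mu(species j) <-> e2 row j
      for (int j = 0; j < J; ++j, ++pid) {
        mh(pid, none, [this, j](double d) {
          double lr = 0.0;
          for (size_t k = 0; k < grp_of_species[j].size(); ++k) {
            int g = grp_of_species[j][k];
            lr += dnorm_lratio(mu[g] + d, mu[g], mu_sd);
            mu[g] += d;
          }
          for (int t = 0; t < T1; ++t) {
            double* v = &e2[j + t * J];
            lr += dnorm_lratio(*v - d, *v, sig_j[j]);
            *v -= d;
          }
          return lr;
        });
      }
      // mu(stream s) <-> e3 row s
      for (int s = 0; s < S; ++s, ++pid) {
        mh(pid, none, [this, s](double d) {
          double lr = 0.0;
          for (size_t k = 0; k < grp_of_stream[s].size(); ++k) {
            int g = grp_of_stream[s][k];
            lr += dnorm_lratio(mu[g] + d, mu[g], mu_sd);
            mu[g] += d;
          }
          for (int t = 0; t < T1; ++t) {
            double* v = &e3[s + t * S];
            lr += dnorm_lratio(*v - d, *v, sig_s[s]);
            *v -= d;
          }
          return lr;
        });
      }
      // beta <-> e1 (shift the covariate signal between the shared effect
      // size and the shared temporal effects; likelihood-invariant)
      if (variant_beta == 2) {
        mh(pid++, none, [this](double d) {
          double lr = dnorm_lratio(beta[0] + d, beta[0], beta_sd);
          beta[0] += d;
          for (int t = 0; t < T1; ++t) {
            double step = d * x[t];
            lr += dnorm_lratio(e1[t] - step, e1[t], sig_t);
            e1[t] -= step;
          }
          return lr;
        });
      }
      // non-centered scale moves: multiply a sigma and its effects by
      // exp(delta); standardized residuals are unchanged, so the prior and
      // transform Jacobian reduce to +delta, leaving delta + the
      // likelihood ratio as the acceptance term.
      scale_move(pid++, all_groups, sig_t, e1.data(), T1, 1);
      for (int j = 0; j < J; ++j, ++pid)
        scale_move(pid, grp_of_species[j], sig_j[j], &e2[j], T1, J);
      for (int s = 0; s < S; ++s, ++pid)
        scale_move(pid, grp_of_stream[s], sig_s[s], &e3[s], T1, S);
      for (int g = 0; g < G; ++g, ++pid) {
        std::vector<int> grp(1, g);
        scale_move(pid, grp, sig_js[g], &e4[g], T1, G);
      }
    }
  }

  // eps points at the first element of a strided row (stride elements apart)
  void scale_move(int pid, const std::vector<int>& groups, double& sig,
                  double* eps, int n, int stride) {
    double delta = norm_rand() * std::exp(lstep[pid]);
    double c = std::exp(delta);
    ++att[pid];
    if (sig * c >= sigma_upper) return;
    double sig_old = sig;
    std::vector<double> old_eps(n);
    for (int k = 0; k < n; ++k) { old_eps[k] = eps[k * stride];
                                  eps[k * stride] *= c; }
    sig *= c;
    double ll_new_sum = 0.0, ll_old_sum = 0.0;
    std::vector<double> ll_new(groups.size());
    for (size_t k = 0; k < groups.size(); ++k) {
      ll_new[k] = group_ll(groups[k]);
      ll_new_sum += ll_new[k];
      ll_old_sum += ll[groups[k]];
    }
    double logr = delta + ll_new_sum - ll_old_sum;
    if (std::log(unif_rand()) < logr) {
      ++acc[pid];
      for (size_t k = 0; k < groups.size(); ++k) ll[groups[k]] = ll_new[k];
      total_ll += ll_new_sum - ll_old_sum;
    } else {
      sig = sig_old;
      for (int k = 0; k < n; ++k) eps[k * stride] = old_eps[k];
    }
  }

  int n_params() const {
    int n = G;                                   // mu
    if (variant_beta == 1) n += J;
    if (variant_beta == 2) n += 1;
    n += G * T1;                                 // detection
    if (use_re) n += T1 + J * T1 + S * T1 + G * T1   // effects
                   + 1 + J + S + G;              // variances
    return n;
  }

  void write_row(double* row) const {
    int k = 0;
    for (int g = 0; g < G; ++g) row[k++] = mu[g];
    for (size_t j = 0; j < beta.size(); ++j) row[k++] = beta[j];
    for (int t = 0; t < T1; ++t)
      for (int g = 0; g < G; ++g) row[k++] = invlogit(lp[g + t * G]);
    if (use_re) {
      for (int t = 0; t < T1; ++t) row[k++] = e1[t];
      for (int t = 0; t < T1; ++t)
        for (int j = 0; j < J; ++j) row[k++] = e2[j + t * J];
      for (int t = 0; t < T1; ++t)
        for (int s = 0; s < S; ++s) row[k++] = e3[s + t * S];
      for (int t = 0; t < T1; ++t)
        for (int g = 0; g < G; ++g) row[k++] = e4[g + t * G];
      row[k++] = sig_t * sig_t;
      for (int j = 0; j < J; ++j) row[k++] = sig_j[j] * sig_j[j];
      for (int s = 0; s < S; ++s) row[k++] = sig_s[s] * sig_s[s];
      for (int g = 0; g < G; ++g) row[k++] = sig_js[g] * sig_js[g];
    }
  }
};

// [[Rcpp::export]]
List cjs_mcmc_chain_cpp(NumericMatrix A, NumericMatrix D, NumericMatrix N,
                        NumericMatrix C,
                        IntegerVector gj, IntegerVector gs, int J, int S,
                        NumericVector frac, NumericVector x,
                        int variant_beta, bool use_re, bool baseline60,
                        double mu_sd, double beta_sd, double sigma_upper,
                        int n_iter, int n_burn, int thin,
                        NumericVector mu0, NumericVector beta0,
                        NumericMatrix lp0, NumericVector e1_0,
                        NumericMatrix e2_0, NumericMatrix e3_0,
                        NumericMatrix e4_0, NumericVector sig0) {
  Sampler sm;
  sm.G = A.nrow(); sm.T1 = A.ncol(); sm.J = J; sm.S = S;
  sm.variant_beta = variant_beta; sm.use_re = use_re;
  sm.baseline60 = baseline60;
  sm.A = A; sm.D = D; sm.N = N; sm.C = C;
  sm.mu_sd = mu_sd; sm.beta_sd = beta_sd; sm.sigma_upper = sigma_upper;
  sm.gj.assign(gj.begin(), gj.end());
  sm.gs.assign(gs.begin(), gs.end());
  for (int g = 0; g < sm.G; ++g) { sm.gj[g] -= 1; sm.gs[g] -= 1; }
  sm.frac.assign(frac.begin(), frac.end());
  sm.x.assign(x.begin(), x.end());

  int G = sm.G, T1 = sm.T1;
  sm.mu.assign(mu0.begin(), mu0.end());
  sm.beta.assign(beta0.begin(), beta0.end());
  sm.lp.resize(G * T1);
  for (int g = 0; g < G; ++g)
    for (int t = 0; t < T1; ++t) sm.lp[g + t * G] = lp0(g, t);
  sm.e1.assign(T1, 0.0); sm.e2.assign(J * T1, 0.0);
  sm.e3.assign(S * T1, 0.0); sm.e4.assign(G * T1, 0.0);
  sm.sig_t = 0.5;
  sm.sig_j.assign(J, 0.5); sm.sig_s.assign(S, 0.5); sm.sig_js.assign(G, 0.5);
  if (use_re) {
    for (int t = 0; t < T1; ++t) sm.e1[t] = e1_0[t];
    for (int j = 0; j < J; ++j)
      for (int t = 0; t < T1; ++t) sm.e2[j + t * J] = e2_0(j, t);
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T1; ++t) sm.e3[s + t * S] = e3_0(s, t);
    for (int g = 0; g < G; ++g)
      for (int t = 0; t < T1; ++t) sm.e4[g + t * G] = e4_0(g, t);
    sm.sig_t = sig0[0];
    for (int j = 0; j < J; ++j) sm.sig_j[j] = sig0[1 + j];
    for (int s = 0; s < S; ++s) sm.sig_s[s] = sig0[1 + J + s];
    for (int g = 0; g < G; ++g) sm.sig_js[g] = sig0[1 + J + S + g];
  }

  sm.ll.assign(G, 0.0);
  sm.phbuf.resize(T1); sm.ppbuf.resize(T1); sm.chibuf.resize(T1 + 1);
  sm.grp_of_species.assign(J, std::vector<int>());
  sm.grp_of_stream.assign(S, std::vector<int>());
  for (int g = 0; g < G; ++g) {
    sm.grp_of_species[sm.gj[g]].push_back(g);
    sm.grp_of_stream[sm.gs[g]].push_back(g);
    sm.all_groups.push_back(g);
  }

  // proposal bookkeeping: count scalar proposals per iteration
  int n_props = G + (variant_beta == 1 ? J : (variant_beta == 2 ? 1 : 0)) +
                G * T1;
  if (use_re)
    n_props += T1 + J * T1 + S * T1 + G * T1     // effects
             + 1 + J + S + G                     // sigmas
             + T1 + J * T1 + S * T1 + 1          // sweeps vs e4 / mu-e1
             + G + J + S                         // mu sweeps vs e4/e2/e3
             + (variant_beta == 2 ? 1 : 0)       // beta <-> e1 sweep
             + 1 + J + S + G;                    // scale moves
  sm.lstep.assign(n_props, std::log(0.2));
  sm.acc.assign(n_props, 0);
  sm.att.assign(n_props, 0);
  sm.adapting = true;
  sm.refresh_all_ll();
  if (!std::isfinite(sm.total_ll))
    stop("non-finite log-likelihood at initial values");

  int n_save = (n_iter - n_burn) / thin;
  int npar = sm.n_params();
  NumericMatrix draws(n_save, npar);
  NumericVector deviance(n_save);
  std::vector<double> row(npar);
  int isave = 0, batch = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    sm.one_iteration();
    if (iter % 1000 == 0) sm.refresh_all_ll();  // guard against FP drift
    if (iter <= n_burn && iter % 50 == 0) sm.adapt(++batch);
    if (iter == n_burn) sm.adapting = false;
    if (iter > n_burn && (iter - n_burn) % thin == 0 && isave < n_save) {
      sm.write_row(row.data());
      for (int k = 0; k < npar; ++k) draws(isave, k) = row[k];
      deviance[isave] = -2.0 * sm.total_ll;
      ++isave;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["deviance"] = deviance,
                      _["n_proposals"] = n_props);
}
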