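#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical spatiotemporal
// Poisson model
//
//   y_it ~ Poisson(E_it * exp(eta_it)),
//   eta_it = b0 + u_i + v_i + gamma_t + phi_t + delta_it,
//
// with an intrinsic CAR prior on u (graph Laplacian structure), iid normal
// v and phi, an RW2 prior on gamma, and a space-time interaction field
// delta whose structure is one of: none, I (iid), II (RW2 in time within
// each area), III (ICAR in space within each time slice).  Precisions get
// conjugate Gamma updates using generalized ranks; latent fields use
// adaptive single-site random-walk Metropolis; intrinsic fields are
// re-centred to their constraint spaces after every sweep (centering on
// the fly), with means absorbed into b0 / v / phi where eta-invariant.
//
// All randomness comes from R's RNG, so set.seed() at the R level makes
// runs bit-reproducible.

// index helper: fields stored with area index fastest (column-major n x T)
static inline int IX(int i, int t, int n) { return i + n * t; }

// adaptive step tuning toward 30-50% acceptance, burn-in only
static inline void tune(double &step, int accepts, int proposals) {
  if (proposals == 0) return;
  double rate = (double)accepts / (double)proposals;
  if (rate < 0.30) step *= 0.8;
  else if (rate > 0.50) step *= 1.25;
  if (step < 1e-6) step = 1e-6;
  if (step > 10.0) step = 10.0;
}

// [[Rcpp::export]]
List st_mcmc_chain(NumericMatrix y, NumericMatrix E,
                   IntegerVector adj, IntegerVector adj_ptr,
                   IntegerVector comp, int n_comp,
                   NumericMatrix Qg,
                   int inter_type,
                   NumericVector prior_shape, NumericVector prior_rate,
                   NumericVector gen_rank,
                   int n_iter, int n_burn, int thin, int adapt_window,
                   double b0_init, NumericVector tau_init) {
  const int n = y.nrow(), T = y.ncol();
  const bool has_delta = inter_type > 0;

  // state
  double b0 = b0_init;
  std::vector<double> u(n, 0.0), v(n, 0.0), gam(T, 0.0), phi(T, 0.0);
  std::vector<double> del((size_t)n * T, 0.0);
  // precisions: u, v, gamma, phi, delta
  std::vector<double> tau(5);
  for (int k = 0; k < 5; ++k) tau[k] = tau_init[k];

  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = adj_ptr[i + 1] - adj_ptr[i];
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < n; ++i) comp_size[comp[i]]++;

  // eta surface
  NumericMatrix eta(n, T);
  auto recompute_eta = [&]() {
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i)
        eta(i, t) = b0 + u[i] + v[i] + gam[t] + phi[t] + del[IX(i, t, n)];
  };
  recompute_eta();

  // quadratic forms
  auto quad_icar = [&](const std::vector<double> &x) {
    double q = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
        double d = x[i] - x[adj[k]];
        q += 0.5 * d * d;
      }
    return q;
  };
  auto quad_iid = [&](const std::vector<double> &x) {
    double q = 0.0;
    for (size_t i = 0; i < x.size(); ++i) q += x[i] * x[i];
    return q;
  };
  auto quad_rw2 = [&](const std::vector<double> &g) {
    double q = 0.0;
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int s2 = 0; s2 < T; ++s2) s += Qg(t, s2) * g[s2];
      q += g[t] * s;
    }
    return q;
  };
  auto quad_delta = [&]() {
    if (inter_type == 1) return quad_iid(del);
    double q = 0.0;
    if (inter_type == 2) {              // RW2 within each area
      for (int i = 0; i < n; ++i)
        for (int t = 0; t < T; ++t) {
          double s = 0.0;
          for (int s2 = 0; s2 < T; ++s2) s += Qg(t, s2) * del[IX(i, s2, n)];
          q += del[IX(i, t, n)] * s;
        }
    } else {                            // ICAR within each time slice
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < n; ++i)
          for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
            double d = del[IX(i, t, n)] - del[IX(adj[k], t, n)];
            q += 0.5 * d * d;
          }
    }
    return q;
  };

  // steps + acceptance bookkeeping: b0, u, v, gamma, phi, delta
  double step[6] = {0.1, 0.1, 0.1, 0.1, 0.1, 0.1};
  long acc[6] = {0, 0, 0, 0, 0, 0}, prop[6] = {0, 0, 0, 0, 0, 0};
  long acc_w[6] = {0, 0, 0, 0, 0, 0}, prop_w[6] = {0, 0, 0, 0, 0, 0};

  const int S = (n_iter - n_burn) / thin;
  NumericVector d_b0(S), d_dev(S), d_cres(S);
  NumericMatrix d_tau(S, 5), d_u(S, n), d_v(S, n), d_gam(S, T), d_phi(S, T);
  NumericMatrix d_del(S, has_delta ? n * T : 1);
  NumericMatrix eta_sum(n, T);

  RNGScope scope;
  int stored = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool burn = iter < n_burn;

    // ---- b0: random-walk Metropolis, flat prior
    {
      double d = step[0] * R::norm_rand();
      double dll = 0.0;
      double ed = std::exp(d);
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < n; ++i) {
          double mu0 = E(i, t) * std::exp(eta(i, t));
          dll += y(i, t) * d - mu0 * (ed - 1.0);
        }
      prop[0]++; prop_w[0]++;
      if (std::log(R::unif_rand()) < dll) {
        b0 += d; acc[0]++; acc_w[0]++;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < n; ++i) eta(i, t) += d;
      }
    }

    // ---- u: single-site RW Metropolis, ICAR prior
    for (int i = 0; i < n; ++i) {
      double d = step[1] * R::norm_rand();
      double un = u[i] + d;
      double nbr = 0.0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nbr += u[adj[k]];
      double dlp = -0.5 * tau[0] * (deg[i] * (un * un - u[i] * u[i]) -
                                    2.0 * d * nbr);
      double dll = 0.0, ed = std::exp(d);
      for (int t = 0; t < T; ++t) {
        double mu0 = E(i, t) * std::exp(eta(i, t));
        dll += y(i, t) * d - mu0 * (ed - 1.0);
      }
      prop[1]++; prop_w[1]++;
      if (std::log(R::unif_rand()) < dll + dlp) {
        u[i] = un; acc[1]++; acc_w[1]++;
        for (int t = 0; t < T; ++t) eta(i, t) += d;
      }
    }

    // ---- v: single-site RW Metropolis, iid prior
    for (int i = 0; i < n; ++i) {
      double d = step[2] * R::norm_rand();
      double vn = v[i] + d;
      double dlp = -0.5 * tau[1] * (vn * vn - v[i] * v[i]);
      double dll = 0.0, ed = std::exp(d);
      for (int t = 0; t < T; ++t) {
        double mu0 = E(i, t) * std::exp(eta(i, t));
        dll += y(i, t) * d - mu0 * (ed - 1.0);
      }
      prop[2]++; prop_w[2]++;
      if (std::log(R::unif_rand()) < dll + dlp) {
        v[i] = vn; acc[2]++; acc_w[2]++;
        for (int t = 0; t < T; ++t) eta(i, t) += d;
      }
    }

    // ---- gamma: single-site RW Metropolis, RW2 prior
    for (int t = 0; t < T; ++t) {
      double d = step[3] * R::norm_rand();
      double gn = gam[t] + d;
      double off = 0.0;
      for (int s = 0; s < T; ++s) if (s != t) off += Qg(t, s) * gam[s];
      double dlp = -0.5 * tau[2] * (Qg(t, t) * (gn * gn - gam[t] * gam[t]) +
                                    2.0 * d * off);
      double dll = 0.0, ed = std::exp(d);
      for (int i = 0; i < n; ++i) {
        double mu0 = E(i, t) * std::exp(eta(i, t));
        dll += y(i, t) * d - mu0 * (ed - 1.0);
      }
      prop[3]++; prop_w[3]++;
      if (std::log(R::unif_rand()) < dll + dlp) {
        gam[t] = gn; acc[3]++; acc_w[3]++;
        for (int i = 0; i < n; ++i) eta(i, t) += d;
      }
    }

    // ---- phi: single-site RW Metropolis, iid prior
    for (int t = 0; t < T; ++t) {
      double d = step[4] * R::norm_rand();
      double pn = phi[t] + d;
      double dlp = -0.5 * tau[3] * (pn * pn - phi[t] * phi[t]);
      double dll = 0.0, ed = std::exp(d);
      for (int i = 0; i < n; ++i) {
        double mu0 = E(i, t) * std::exp(eta(i, t));
        dll += y(i, t) * d - mu0 * (ed - 1.0);
      }
      prop[4]++; prop_w[4]++;
      if (std::log(R::unif_rand()) < dll + dlp) {
        phi[t] = pn; acc[4]++; acc_w[4]++;
        for (int i = 0; i < n; ++i) eta(i, t) += d;
      }
    }

    // ---- delta: single-site RW Metropolis, structure per interaction type
    if (has_delta) {
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < n; ++i) {
          double d0 = del[IX(i, t, n)];
          double d = step[5] * R::norm_rand();
          double dn = d0 + d;
          double dlp;
          if (inter_type == 1) {
            dlp = -0.5 * tau[4] * (dn * dn - d0 * d0);
          } else if (inter_type == 2) {
            double off = 0.0;
            for (int s = 0; s < T; ++s)
              if (s != t) off += Qg(t, s) * del[IX(i, s, n)];
            dlp = -0.5 * tau[4] * (Qg(t, t) * (dn * dn - d0 * d0) +
                                   2.0 * d * off);
          } else {
            double nbr = 0.0;
            for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k)
              nbr += del[IX(adj[k], t, n)];
            dlp = -0.5 * tau[4] * (deg[i] * (dn * dn - d0 * d0) -
                                   2.0 * d * nbr);
          }
          double mu0 = E(i, t) * std::exp(eta(i, t));
          double dll = y(i, t) * d - mu0 * (std::exp(d) - 1.0);
          prop[5]++; prop_w[5]++;
          if (std::log(R::unif_rand()) < dll + dlp) {
            del[IX(i, t, n)] = dn; acc[5]++; acc_w[5]++;
            eta(i, t) += d;
          }
        }
    }

    // ---- precisions: conjugate Gamma updates with generalized ranks
    // R::rgamma takes (shape, scale)
    tau[0] = R::rgamma(prior_shape[0] + 0.5 * gen_rank[0],
                       1.0 / (prior_rate[0] + 0.5 * quad_icar(u)));
    tau[1] = R::rgamma(prior_shape[1] + 0.5 * gen_rank[1],
                       1.0 / (prior_rate[1] + 0.5 * quad_iid(v)));
    tau[2] = R::rgamma(prior_shape[2] + 0.5 * gen_rank[2],
                       1.0 / (prior_rate[2] + 0.5 * quad_rw2(gam)));
    tau[3] = R::rgamma(prior_shape[3] + 0.5 * gen_rank[3],
                       1.0 / (prior_rate[3] + 0.5 * quad_iid(phi)));
    if (has_delta)
      tau[4] = R::rgamma(prior_shape[4] + 0.5 * gen_rank[4],
                         1.0 / (prior_rate[4] + 0.5 * quad_delta()));

    // ---- re-centre intrinsic fields (centering on the fly)
    {
      // u: per-component sum-to-zero; overall mean absorbed into b0
      std::vector<double> m(n_comp, 0.0);
      for (int i = 0; i < n; ++i) m[comp[i]] += u[i];
      double mall = 0.0;
      for (int c = 0; c < n_comp; ++c) { mall += m[c]; m[c] /= comp_size[c]; }
      mall /= n;
      for (int i = 0; i < n; ++i) u[i] -= m[comp[i]];
      b0 += mall;

      // gamma: mean into b0, linear null-space component projected out
      double gm = 0.0;
      for (int t = 0; t < T; ++t) gm += gam[t];
      gm /= T;
      for (int t = 0; t < T; ++t) gam[t] -= gm;
      b0 += gm;
      double tc_ss = 0.0, dot = 0.0, tbar = 0.5 * (T - 1);
      for (int t = 0; t < T; ++t) {
        double tc = t - tbar;
        tc_ss += tc * tc; dot += tc * gam[t];
      }
      double slope = dot / tc_ss;
      for (int t = 0; t < T; ++t) gam[t] -= slope * (t - tbar);

      if (inter_type == 2) {
        // per-area constant into v, per-area linear projected out
        for (int i = 0; i < n; ++i) {
          double mi = 0.0;
          for (int t = 0; t < T; ++t) mi += del[IX(i, t, n)];
          mi /= T;
          for (int t = 0; t < T; ++t) del[IX(i, t, n)] -= mi;
          v[i] += mi;
          double dot_i = 0.0;
          for (int t = 0; t < T; ++t) dot_i += (t - tbar) * del[IX(i, t, n)];
          double sl = dot_i / tc_ss;
          for (int t = 0; t < T; ++t) del[IX(i, t, n)] -= sl * (t - tbar);
        }
      } else if (inter_type == 3) {
        // per-time per-component sum-to-zero; overall slice mean into phi_t
        for (int t = 0; t < T; ++t) {
          std::vector<double> mc(n_comp, 0.0);
          for (int i = 0; i < n; ++i) mc[comp[i]] += del[IX(i, t, n)];
          double mt = 0.0;
          for (int c = 0; c < n_comp; ++c) {
            mt += mc[c]; mc[c] /= comp_size[c];
          }
          mt /= n;
          for (int i = 0; i < n; ++i) del[IX(i, t, n)] -= mc[comp[i]];
          phi[t] += mt;
        }
      }
      recompute_eta();
    }

    // divergence guard
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i)
        if (std::abs(eta(i, t)) > 50.0 || !R_finite(eta(i, t)))
          stop("divergent linear predictor (|eta| > 50) at area %d, time %d, "
               "iteration %d", i + 1, t + 1, iter + 1);

    // ---- adapt steps during burn-in
    if (burn && ((iter + 1) % adapt_window == 0)) {
      for (int k = 0; k < 6; ++k) {
        tune(step[k], acc_w[k], prop_w[k]);
        acc_w[k] = 0; prop_w[k] = 0;
      }
    }
    if (iter + 1 == n_burn)
      for (int k = 0; k < 6; ++k) { acc[k] = 0; prop[k] = 0; }

    // ---- store
    if (!burn && ((iter - n_burn) % thin == 0) && stored < S) {
      d_b0[stored] = b0;
      for (int k = 0; k < 5; ++k) d_tau(stored, k) = tau[k];
      for (int i = 0; i < n; ++i) { d_u(stored, i) = u[i]; d_v(stored, i) = v[i]; }
      for (int t = 0; t < T; ++t) { d_gam(stored, t) = gam[t]; d_phi(stored, t) = phi[t]; }
      if (has_delta)
        for (int j = 0; j < n * T; ++j) d_del(stored, j) = del[j];

      double dev = 0.0;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < n; ++i) {
          double mu = E(i, t) * std::exp(eta(i, t));
          double ll = -mu - R::lgammafn(y(i, t) + 1.0);
          if (y(i, t) > 0) ll += y(i, t) * std::log(mu);
          dev += ll;
          eta_sum(i, t) += eta(i, t);
        }
      d_dev[stored] = -2.0 * dev;

      // constraint residuals (should be ~ machine precision)
      double cres = 0.0;
      {
        std::vector<double> cs(n_comp, 0.0);
        for (int i = 0; i < n; ++i) cs[comp[i]] += u[i];
        for (int c = 0; c < n_comp; ++c) cres = std::max(cres, std::abs(cs[c]));
        double gs = 0.0, gl = 0.0, tbar = 0.5 * (T - 1);
        for (int t = 0; t < T; ++t) { gs += gam[t]; gl += (t - tbar) * gam[t]; }
        cres = std::max(cres, std::abs(gs));
        cres = std::max(cres, std::abs(gl));
      }
      d_cres[stored] = cres;
      stored++;
    }
  }

  NumericMatrix eta_mean(n, T);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i) eta_mean(i, t) = eta_sum(i, t) / stored;

  NumericVector acc_rate(6), steps(6);
  CharacterVector nm = CharacterVector::create("b0", "u", "v", "gamma",
                                               "phi", "delta");
  for (int k = 0; k < 6; ++k) {
    acc_rate[k] = prop[k] > 0 ? (double)acc[k] / prop[k] : NA_REAL;
    steps[k] = step[k];
  }
  acc_rate.names() = nm; steps.names() = nm;

  return List::create(
      _["b0"] = d_b0, _["tau"] = d_tau, _["u"] = d_u, _["v"] = d_v,
      _["gamma"] = d_gam, _["phi"] = d_phi,
      _["delta"] = has_delta ? d_del : NumericMatrix(0, 0),
      _["deviance"] = d_dev, _["eta_mean"] = eta_mean,
      _["acceptance"] = acc_rate, _["steps"] = steps,
      _["constraint_resid"] = d_cres, _["n_stored"] = stored);
}
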