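// Evolutionary Monte Carlo sampler for the multi-tissue hierarchical
// sparse-regression model. Chains carry (Gamma, omega, rho); the shrinkage
// factor g is shared and updated against the cold chain. All randomness
// comes from R's RNG so runs are reproducible via set.seed().

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <sstream>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Data {
  arma::mat Xc;                 // n x p, column-centered
  std::vector<arma::mat> Yc;    // q matrices n x r, column-centered
  std::vector<arma::mat> YtY;   // q matrices r x r
  int n = 0, p = 0, q = 0, r = 0;
};

struct Hyper {
  double d;
  arma::vec h;                  // length q
  double a_g, b_g;
  arma::vec a_om, b_om;         // length q
  double c_rho, d_rho;
  int max_size;
};

// log marginal likelihood up to a (gamma, g)-free constant
// returns NA when the selected design is rank deficient
double log_ml(const Data& D, const Hyper& H, int k,
              const arma::uvec& sel, double g) {
  const arma::mat& YtY = D.YtY[k];
  int r = D.r;
  arma::mat R;
  if (sel.n_elem == 0) {
    R = YtY;
  } else {
    arma::mat Xg = D.Xc.cols(sel);
    arma::mat xtx = Xg.t() * Xg;
    arma::mat ch;
    if (!arma::chol(ch, xtx)) return NA_REAL;
    double mx = ch.diag().max();
    if (ch.diag().min() < 1e-7 * mx) return NA_REAL;
    arma::mat xty = Xg.t() * D.Yc[k];
    arma::mat Z = arma::solve(arma::trimatl(ch.t()), xty);
    R = YtY - Z.t() * Z;
  }
  arma::mat M = H.h(k) * arma::eye(r, r) + YtY / (1.0 + g) +
                (g / (1.0 + g)) * R;
  arma::mat chM;
  if (!arma::chol(chM, arma::symmatu(M))) return NA_REAL;
  double logdet = 2.0 * arma::sum(arma::log(chM.diag()));
  return -(r * (double)sel.n_elem / 2.0) * std::log1p(g) -
         ((H.d + D.n + r - 2.0) / 2.0) * logdet;
}

struct Chain {
  arma::umat gamma;             // q x p
  arma::vec omega;              // q
  arma::vec rho;                // p
  arma::vec logml;              // q, cached at current g
  double temp = 1.0;
};

double row_log_prior_g(const arma::umat& G, int k, double omega_k,
                       const arma::vec& rho) {
  double s = 0.0;
  for (arma::uword j = 0; j < G.n_cols; ++j) {
    double w = omega_k * rho(j);
    if (w > 1.0) w = 1.0;
    if (G(k, j)) s += std::log(std::max(w, 1e-300));
    else s += std::log1p(-std::min(w, 1.0 - 1e-300));
  }
  return s;
}

double row_log_prior(const Chain& C, const Hyper& H, int k) {
  return row_log_prior_g(C.gamma, k, C.omega(k), C.rho);
}

double chain_log_posterior(const Chain& C, const Hyper& H) {
  double s = arma::sum(C.logml);
  int q = C.gamma.n_rows, p = C.gamma.n_cols;
  for (int k = 0; k < q; ++k) {
    s += row_log_prior(C, H, k);
    s += R::dbeta(C.omega(k), H.a_om(k), H.b_om(k), 1);
  }
  for (int j = 0; j < p; ++j)
    s += R::dgamma(C.rho(j), H.c_rho, 1.0 / H.d_rho, 1);
  return s;
}

int runif_int(int m) {               // uniform on 0..m-1
  int v = (int)std::floor(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

arma::uvec row_indices(const arma::umat& G, int k, bool ones) {
  std::vector<arma::uword> v;
  for (arma::uword j = 0; j < G.n_cols; ++j)
    if ((G(k, j) != 0) == ones) v.push_back(j);
  return arma::uvec(v);
}

std::string model_key(const arma::umat& G, int k) {
  std::ostringstream os;
  bool first = true;
  for (arma::uword j = 0; j < G.n_cols; ++j)
    if (G(k, j)) { if (!first) os << ","; os << (j + 1); first = false; }
  return os.str();
}

}  // namespace

// Cross-check surface: the same closed form as the R implementation.
// sel1 holds 1-based column indices.
// [[Rcpp::export]]
double mthess_logml_cpp(const arma::mat& Xc, const arma::mat& Yck,
                        const arma::uvec& sel1, double g, double h,
                        double d) {
  Data D;
  D.Xc = Xc; D.Yc = {Yck}; D.YtY = {Yck.t() * Yck};
  D.n = Xc.n_rows; D.p = Xc.n_cols; D.q = 1; D.r = Yck.n_cols;
  Hyper H; H.d = d; H.h = arma::vec{h};
  arma::uvec sel = sel1;
  if (sel.n_elem) sel -= 1;
  return log_ml(D, H, 0, sel, g);
}

// [[Rcpp::export]]
List mthess_emc_cpp(const arma::mat& Xc, const List& Yc_list,
                    const List& hyper, const List& cfg) {
  Data D;
  D.Xc = Xc;
  D.n = Xc.n_rows; D.p = Xc.n_cols;
  D.q = Yc_list.size();
  for (int k = 0; k < D.q; ++k) {
    arma::mat Y = as<arma::mat>(Yc_list[k]);
    D.Yc.push_back(Y);
    D.YtY.push_back(Y.t() * Y);
  }
  D.r = D.Yc[0].n_cols;

  Hyper H;
  H.d = as<double>(hyper["d"]);
  H.h = as<arma::vec>(hyper["h"]);
  H.a_g = as<double>(hyper["a_g"]);
  H.b_g = as<double>(hyper["b_g"]);
  H.a_om = as<arma::vec>(hyper["a_omega"]);
  H.b_om = as<arma::vec>(hyper["b_omega"]);
  H.c_rho = as<double>(hyper["c_rho"]);
  H.d_rho = as<double>(hyper["d_rho"]);
  H.max_size = std::min(as<int>(hyper["max_model_size"]), D.n - 2);

  const int T = as<int>(cfg["n_sweeps"]);
  const int burn = as<int>(cfg["burn_in"]);
  const int nC = as<int>(cfg["n_chains"]);
  arma::vec temps = as<arma::vec>(cfg["temperatures"]);
  const double frac = as<double>(cfg["response_update_fraction"]);
  arma::vec mp = as<arma::vec>(cfg["move_probabilities"]); // add, del, swap
  const int adapt_every = as<int>(cfg["adapt_interval"]);
  const double target_swap = as<double>(cfg["target_swap_rate"]);
  const int thin = as<int>(cfg["trace_thin"]);
  const int n_local = as<int>(cfg["n_local"]);
  const bool fix_hyper = as<bool>(cfg["fix_hyper"]);
  const bool do_global = as<bool>(cfg["global_moves"]) && nC >= 2;
  double g = as<double>(cfg["g_init"]);
  const bool fix_g = as<bool>(cfg["fix_g"]);

  std::vector<Chain> chains(nC);
  arma::vec omega0 = as<arma::vec>(cfg["omega_init"]);
  arma::vec rho0 = as<arma::vec>(cfg["rho_init"]);
  for (int c = 0; c < nC; ++c) {
    chains[c].gamma = arma::umat(D.q, D.p, arma::fill::zeros);
    chains[c].omega = omega0;
    chains[c].rho = rho0;
    chains[c].temp = temps(c);
    chains[c].logml = arma::vec(D.q);
    for (int k = 0; k < D.q; ++k)
      chains[c].logml(k) = log_ml(D, H, k, arma::uvec(), g);
  }

  // adaptive proposal scales
  double s_om = 0.5, s_rho = 0.5, s_g = 0.5;
  double ladder_ratio = nC >= 2 ? temps(1) / temps(0) : 2.0;

  // accumulators (cold chain, post burn-in)
  arma::mat incl_counts(D.q, D.p, arma::fill::zeros);
  std::vector<double> g_samples;
  arma::vec omega_sum(D.q, arma::fill::zeros);
  arma::vec rho_sum(D.p, arma::fill::zeros);
  double g_sum = 0.0;
  int recorded = 0;
  std::vector<std::map<std::string, int>> visited(D.q);
  arma::mat omega_trace, rho_trace;
  int n_thinned = (T - burn + thin - 1) / thin;
  omega_trace.set_size(n_thinned, D.q);
  rho_trace.set_size(n_thinned, D.p);
  int thinned_rows = 0;

  // acceptance bookkeeping: proposed/accepted per move type
  std::map<std::string, double> prop_ct, acc_ct;
  for (auto s : {"add", "delete", "swap", "crossover", "exchange",
                 "omega", "rho", "g"}) { prop_ct[s] = 0; acc_ct[s] = 0; }
  double win_ex_prop = 0, win_ex_acc = 0;       // exchange window for tuning
  double win_om_p = 0, win_om_a = 0, win_rho_p = 0, win_rho_a = 0,
         win_g_p = 0, win_g_a = 0;

  const int n_upd = std::max(1, (int)std::ceil(frac * D.q));

  // top correlated partners per marker (for LD-informed swap proposals):
  // up to 5 columns with |r| >= 0.5, padded with -1
  const int ld_K = 5;
  arma::imat ld_top(D.p, ld_K);
  ld_top.fill(-1);
  {
    arma::mat Z = D.Xc;
    for (int j = 0; j < D.p; ++j) {
      double nrm = arma::norm(Z.col(j));
      if (nrm > 0) Z.col(j) /= nrm;
    }
    arma::mat Ccor = arma::abs(Z.t() * Z);
    Ccor.diag().zeros();
    for (int j = 0; j < D.p; ++j) {
      arma::uvec ord = arma::sort_index(Ccor.row(j).t(), "descend");
      int filled = 0;
      for (arma::uword t2 = 0; t2 < ord.n_elem && filled < ld_K; ++t2) {
        if (Ccor(j, ord(t2)) < 0.5) break;
        ld_top(j, filled++) = ord(t2);
      }
    }
  }

  for (int t = 0; t < T; ++t) {
    // choose responses to update (uniform subset without replacement)
    arma::uvec perm(D.q);
    for (int k = 0; k < D.q; ++k) perm(k) = k;
    for (int k = D.q - 1; k > 0; --k)
      std::swap(perm(k), perm(runif_int(k + 1)));

    for (int u = 0; u < n_upd; ++u) {
      int k = perm(u);

      // ---- 2.1 local moves on each chain ----
      for (int c = 0; c < nC * n_local; ++c) {
        Chain& C = chains[c % nC];
        int size = arma::accu(C.gamma.row(k));
        double uu = unif_rand();
        const char* mtype; int jj = -1, jdel = -1;
        double log_prop_ratio = 0.0;
        bool feasible = true;
        if (uu < mp(0)) {
          mtype = "add";
          if (size >= H.max_size || size >= D.p) feasible = false;
          else {
            arma::uvec zeros = row_indices(C.gamma, k, false);
            jj = zeros(runif_int(zeros.n_elem));
            log_prop_ratio = std::log(mp(1) / (size + 1.0)) -
                             std::log(mp(0) / (double)zeros.n_elem);
          }
        } else if (uu < mp(0) + mp(1)) {
          mtype = "delete";
          if (size == 0) feasible = false;
          else {
            arma::uvec ones = row_indices(C.gamma, k, true);
            jdel = ones(runif_int(ones.n_elem));
            log_prop_ratio = std::log(mp(0) / (D.p - size + 1.0)) -
                             std::log(mp(1) / (double)size);
          }
        } else {
          mtype = "swap";
          if (size == 0 || size >= D.p) feasible = false;
          else {
            arma::uvec ones = row_indices(C.gamma, k, true);
            arma::uvec zeros = row_indices(C.gamma, k, false);
            jdel = ones(runif_int(ones.n_elem));
            // half the swaps draw the incoming marker from the outgoing
            // marker's most-correlated partners (LD-informed proposal);
            // detailed balance is restored by the exact proposal ratio
            auto ld_cand = [&](int j) {
              std::vector<arma::uword> v;
              for (arma::uword t2 = 0; t2 < ld_top.n_cols; ++t2) {
                int cnd = ld_top(j, t2);
                if (cnd >= 0 && C.gamma(k, cnd) == 0 && cnd != jdel)
                  v.push_back(cnd);
              }
              return arma::uvec(v);
            };
            arma::uvec fw = ld_cand(jdel);
            double p_unif = 1.0 / zeros.n_elem;
            if (unif_rand() < 0.5 && fw.n_elem > 0)
              jj = fw(runif_int(fw.n_elem));
            else
              jj = zeros(runif_int(zeros.n_elem));
            auto prop_dens = [&](const arma::uvec& ld, int target) {
              double d2 = 0.5 * p_unif;       // uniform branch
              if (ld.n_elem > 0) {
                bool in_ld = arma::any(ld == (arma::uword)target);
                d2 += 0.5 * (in_ld ? 1.0 / ld.n_elem : 0.0);
              } else d2 += 0.5 * p_unif;      // empty LD set falls back
              return d2;
            };
            double q_f = prop_dens(fw, jj);
            // reverse: jj is included, jdel excluded; excluded-set size equal
            arma::uvec bw;
            {
              std::vector<arma::uword> v;
              for (arma::uword t2 = 0; t2 < ld_top.n_cols; ++t2) {
                int cnd = ld_top(jj, t2);
                if (cnd >= 0 && (C.gamma(k, cnd) == 0 || cnd == jdel) &&
                    cnd != jj)
                  v.push_back(cnd);
              }
              bw = arma::uvec(v);
            }
            double q_r = prop_dens(bw, jdel);
            log_prop_ratio = std::log(q_r) - std::log(q_f);
          }
        }
        prop_ct[mtype] += 1;
        if (!feasible) continue;
        arma::urowvec rk = C.gamma.row(k);
        double dprior = 0.0;
        if (jj >= 0) {
          rk(jj) = 1;
          double w = std::min(C.omega(k) * C.rho(jj), 1.0 - 1e-300);
          dprior += std::log(std::max(w, 1e-300)) - std::log1p(-w);
        }
        if (jdel >= 0) {
          rk(jdel) = 0;
          double w = std::min(C.omega(k) * C.rho(jdel), 1.0 - 1e-300);
          dprior -= std::log(std::max(w, 1e-300)) - std::log1p(-w);
        }
        arma::uvec sel = arma::find(rk);
        double ml_new = log_ml(D, H, k, sel, g);
        if (!R_finite(ml_new)) continue;   // rank-deficient: auto-reject
        double la = (ml_new - C.logml(k) + dprior) / C.temp + log_prop_ratio;
        if (std::log(unif_rand()) < la) {
          C.gamma.row(k) = rk;
          C.logml(k) = ml_new;
          acc_ct[mtype] += 1;
        }
      }

      // ---- 2.2 global (crossover) move on row k ----
      if (do_global) {
        prop_ct["crossover"] += 1;
        int c1 = runif_int(nC), c2 = runif_int(nC - 1);
        if (c2 >= c1) ++c2;
        Chain& A = chains[c1];
        Chain& B = chains[c2];
        arma::urowvec ra = A.gamma.row(k), rb = B.gamma.row(k);
        arma::urowvec na = ra, nb = rb;
        if (unif_rand() < 0.5 && D.p >= 2) {
          int cut = 1 + runif_int(D.p - 1);     // one-point
          for (int j = cut; j < D.p; ++j) std::swap(na(j), nb(j));
        } else {
          for (int j = 0; j < D.p; ++j)          // uniform mask
            if (unif_rand() < 0.5) std::swap(na(j), nb(j));
        }
        int sa = arma::accu(na), sb = arma::accu(nb);
        if (sa <= H.max_size && sb <= H.max_size &&
            !(arma::all(na == ra) && arma::all(nb == rb))) {
          arma::uvec sela = arma::find(na);
          arma::uvec selb = arma::find(nb);
          double mla = log_ml(D, H, k, sela, g);
          double mlb = log_ml(D, H, k, selb, g);
          if (R_finite(mla) && R_finite(mlb)) {
            double lpa_old = row_log_prior(A, H, k);
            double lpb_old = row_log_prior(B, H, k);
            double lpa_new, lpb_new;
            {
              arma::urowvec keep_a = A.gamma.row(k), keep_b = B.gamma.row(k);
              A.gamma.row(k) = na; B.gamma.row(k) = nb;
              lpa_new = row_log_prior(A, H, k);
              lpb_new = row_log_prior(B, H, k);
              A.gamma.row(k) = keep_a; B.gamma.row(k) = keep_b;
            }
            double la = (mla - A.logml(k) + lpa_new - lpa_old) / A.temp +
                        (mlb - B.logml(k) + lpb_new - lpb_old) / B.temp;
            if (std::log(unif_rand()) < la) {
              A.gamma.row(k) = na; A.logml(k) = mla;
              B.gamma.row(k) = nb; B.logml(k) = mlb;
              acc_ct["crossover"] += 1;
            }
          }
        }
      }

      // ---- 2.3 update omega_k on each chain ----
      if (!fix_hyper) {
        for (int c = 0; c < nC; ++c) {
          Chain& C = chains[c];
          prop_ct["omega"] += 1; win_om_p += 1;
          double w = C.omega(k);
          double lo = std::log(w / (1.0 - w)) + s_om * norm_rand();
          double w2 = 1.0 / (1.0 + std::exp(-lo));
          if (w2 <= 0 || w2 >= 1) continue;
          if (w2 * C.rho.max() > 1.0) continue;   // constraint
          double la = (row_log_prior_g(C.gamma, k, w2, C.rho) -
                       row_log_prior(C, H, k) +
                       R::dbeta(w2, H.a_om(k), H.b_om(k), 1) -
                       R::dbeta(w, H.a_om(k), H.b_om(k), 1)) / C.temp +
                      std::log(w2 * (1 - w2)) - std::log(w * (1 - w));
          if (std::log(unif_rand()) < la) {
            C.omega(k) = w2;
            acc_ct["omega"] += 1; win_om_a += 1;
          }
        }
      }
    }

    // ---- 3. update rho on each chain ----
    if (!fix_hyper) {
      for (int c = 0; c < nC; ++c) {
        Chain& C = chains[c];
        double om_max = C.omega.max();
        for (int j = 0; j < D.p; ++j) {
          prop_ct["rho"] += 1; win_rho_p += 1;
          double rj = C.rho(j);
          double r2 = rj * std::exp(s_rho * norm_rand());
          if (r2 * om_max > 1.0) continue;
          double dlp = 0.0;
          for (int k = 0; k < D.q; ++k) {
            double w1 = std::min(C.omega(k) * rj, 1.0 - 1e-300);
            double w2 = std::min(C.omega(k) * r2, 1.0 - 1e-300);
            if (C.gamma(k, j)) dlp += std::log(w2) - std::log(w1);
            else dlp += std::log1p(-w2) - std::log1p(-w1);
          }
          double la = (dlp + R::dgamma(r2, H.c_rho, 1.0 / H.d_rho, 1) -
                       R::dgamma(rj, H.c_rho, 1.0 / H.d_rho, 1)) / C.temp +
                      std::log(r2) - std::log(rj);
          if (std::log(unif_rand()) < la) {
            C.rho(j) = r2;
            acc_ct["rho"] += 1; win_rho_a += 1;
          }
        }
      }
    }

    // ---- exchange move between adjacent temperatures ----
    if (do_global) {
      prop_ct["exchange"] += 1; win_ex_prop += 1;
      int c = runif_int(nC - 1);
      double lp1 = chain_log_posterior(chains[c], H);
      double lp2 = chain_log_posterior(chains[c + 1], H);
      double la = (1.0 / chains[c].temp - 1.0 / chains[c + 1].temp) *
                  (lp2 - lp1);
      if (std::log(unif_rand()) < la) {
        std::swap(chains[c], chains[c + 1]);
        std::swap(chains[c].temp, chains[c + 1].temp);
        acc_ct["exchange"] += 1; win_ex_acc += 1;
      }
    }

    // ---- 4. global shrinkage g (single shared value, cold chain) ----
    if (!fix_g) {
      prop_ct["g"] += 1; win_g_p += 1;
      double g2 = g * std::exp(s_g * norm_rand());
      double num = 0.0, den = arma::sum(chains[0].logml);
      arma::vec ml_new(D.q);
      bool ok = true;
      for (int k = 0; k < D.q; ++k) {
        arma::uvec sel = row_indices(chains[0].gamma, k, true);
        ml_new(k) = log_ml(D, H, k, sel, g2);
        if (!R_finite(ml_new(k))) { ok = false; break; }
        num += ml_new(k);
      }
      if (ok) {
        double lprior_new = -(H.a_g + 1) * std::log(g2) - H.b_g / g2;
        double lprior_old = -(H.a_g + 1) * std::log(g) - H.b_g / g;
        double la = num - den + lprior_new - lprior_old +
                    std::log(g2) - std::log(g);
        if (std::log(unif_rand()) < la) {
          g = g2;
          acc_ct["g"] += 1; win_g_a += 1;
          for (int c = 0; c < nC; ++c) {
            Chain& C = chains[c];
            if (c == 0) C.logml = ml_new;
            else for (int k = 0; k < D.q; ++k)
              C.logml(k) = log_ml(D, H, k, row_indices(C.gamma, k, true), g);
          }
        }
      }
    }

    // ---- burn-in adaptation ----
    if (t < burn && adapt_every > 0 && (t + 1) % adapt_every == 0) {
      auto rm = [](double& s, double p, double a, double lo, double hi,
                   double target) {
        if (p >= 5) {
          double rate = a / p;
          s *= std::exp(0.6 * (rate - target));
          s = std::min(std::max(s, lo), hi);
        }
      };
      rm(s_om, win_om_p, win_om_a, 0.02, 5.0, 0.4);
      rm(s_rho, win_rho_p, win_rho_a, 0.02, 5.0, 0.4);
      rm(s_g, win_g_p, win_g_a, 0.02, 5.0, 0.4);
      win_om_p = win_om_a = win_rho_p = win_rho_a = win_g_p = win_g_a = 0;
      if (do_global && win_ex_prop >= 5) {
        double rate = win_ex_acc / win_ex_prop;
        // geometric ladder: shrink ratio when swaps rarely accepted
        ladder_ratio = std::pow(ladder_ratio,
                                std::exp(0.5 * (rate - target_swap)));
        ladder_ratio = std::min(std::max(ladder_ratio, 1.3), 16.0);
        for (int c = 0; c < nC; ++c)
          chains[c].temp = std::pow(ladder_ratio, c);
        win_ex_prop = win_ex_acc = 0;
      }
    }

    // ---- record cold chain ----
    if (t >= burn) {
      const Chain& C0 = chains[0];
      incl_counts += arma::conv_to<arma::mat>::from(C0.gamma);
      g_samples.push_back(g);
      g_sum += g;
      omega_sum += C0.omega;
      rho_sum += C0.rho;
      for (int k = 0; k < D.q; ++k)
        visited[k][model_key(C0.gamma, k)] += 1;
      if ((t - burn) % thin == 0 && thinned_rows < n_thinned) {
        omega_trace.row(thinned_rows) = C0.omega.t();
        rho_trace.row(thinned_rows) = C0.rho.t();
        ++thinned_rows;
      }
      ++recorded;
    }
  }

  List vis(D.q);
  for (int k = 0; k < D.q; ++k) {
    std::vector<std::string> keys;
    std::vector<int> cts;
    for (auto& kv : visited[k]) { keys.push_back(kv.first); cts.push_back(kv.second); }
    vis[k] = List::create(_["model"] = keys, _["count"] = cts);
  }
  std::vector<std::string> mnames;
  std::vector<double> mprop, macc;
  for (auto& kv : prop_ct) {
    mnames.push_back(kv.first);
    mprop.push_back(kv.second);
    macc.push_back(acc_ct[kv.first]);
  }
  arma::vec final_temps(nC);
  for (int c = 0; c < nC; ++c) final_temps(c) = chains[c].temp;

  return List::create(
      _["inclusion_counts"] = incl_counts,
      _["recorded_sweeps"] = recorded,
      _["g_samples"] = g_samples,
      _["g_mean"] = recorded ? g_sum / recorded : NA_REAL,
      _["omega_mean"] = recorded ? arma::vec(omega_sum / recorded) : omega_sum,
      _["rho_mean"] = recorded ? arma::vec(rho_sum / recorded) : rho_sum,
      _["omega_trace"] = omega_trace.rows(0, std::max(thinned_rows - 1, 0)),
      _["rho_trace"] = rho_trace.rows(0, std::max(thinned_rows - 1, 0)),
      _["visited_models"] = vis,
      _["acceptance"] = DataFrame::create(_["move"] = mnames,
                                          _["proposed"] = mprop,
                                          _["accepted"] = macc),
      _["final_temperatures"] = final_temps,
      _["g_final"] = g);
}
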