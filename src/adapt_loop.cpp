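#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Core trial loop for reward-gated adaptation.
//
// RNG comes from R's generator (seed with set.seed() upstream). Draw order per
// trial is fixed: [schedule draw if random] -> xi_x -> xi_y -> [bernoulli draw
// if the reward is stochastic], so runs are bit-reproducible.
//
// schedule_mode: 0 cyclic, 1 random uniform
// reward_family: 0 binary, 1 smooth deterministic, 2 stochastic bernoulli
// shaping_kind : 0 none, 1 target size (adaptive on reward EMA),
//                2 rotation angle (fixed blocks), 3 rotation angle (adaptive)
//
// [[Rcpp::export(name = ".adapt_loop")]]
List adapt_loop(const NumericMatrix& W0, const NumericMatrix& U,
                const NumericMatrix& V,
                double gamma_final, double sigma, double eta,
                int schedule_mode, int reward_family, double T_smooth,
                double n0_final,
                int shaping_kind, double n0_init, double n0_step,
                double gamma_init, double gamma_step, int block_len,
                int ema_timescale, double steady_tol, double ema_floor,
                int n_trials, double diverge_guard,
                bool early_stop, int early_window)
{
  const int N = U.nrow();
  const int m = U.ncol();
  NumericMatrix W = clone(W0);

  double n0  = (shaping_kind == 1) ? n0_init : n0_final;
  double gam = (shaping_kind == 2 || shaping_kind == 3) ? gamma_init : gamma_final;
  double cg = std::cos(gam), sg = std::sin(gam);

  IntegerVector rec_target(n_trials);
  NumericVector rec_E(n_trials), rec_Et(n_trials), rec_R(n_trials),
                rec_n0(n_trials), rec_gamma(n_trials);

  // cached noiseless errors per target; change only when W or gamma change
  std::vector<double> etil(m);
  auto recompute_etil = [&]() {
    for (int j = 0; j < m; ++j) {
      double y0 = 0.0, y1 = 0.0;
      for (int i = 0; i < N; ++i) {
        y0 += W(0, i) * U(i, j);
        y1 += W(1, i) * U(i, j);
      }
      const double c0 = cg * y0 - sg * y1;
      const double c1 = sg * y0 + cg * y1;
      const double d0 = c0 - V(0, j), d1 = c1 - V(1, j);
      etil[j] = d0 * d0 + d1 * d1;
    }
  };
  recompute_etil();

  // per-target running average of the reward, with a ring buffer holding the
  // EMA values one timescale back so steady state can be detected
  const double alpha = (ema_timescale > 0) ? 1.0 / ema_timescale : 0.0;
  std::vector<double> ema(m, 0.0);
  std::vector<double> ring((size_t)std::max(ema_timescale, 1) * m, 0.0);
  int since_reset = 0;

  bool divergent = false;
  int within_count = 0;
  int t_done = n_trials;

  for (int t = 0; t < n_trials; ++t) {
    int j;
    if (schedule_mode == 0) {
      j = t % m;
    } else {
      j = (int)(unif_rand() * m);
      if (j >= m) j = m - 1;
    }
    const double xi0 = sigma * norm_rand();
    const double xi1 = sigma * norm_rand();

    double y0 = xi0, y1 = xi1;
    for (int i = 0; i < N; ++i) {
      y0 += W(0, i) * U(i, j);
      y1 += W(1, i) * U(i, j);
    }
    const double c0 = cg * y0 - sg * y1;
    const double c1 = sg * y0 + cg * y1;
    const double d0 = c0 - V(0, j), d1 = c1 - V(1, j);
    const double E  = d0 * d0 + d1 * d1;
    const double Et = etil[j];

    double R;
    const double n0sq = n0 * n0;
    if (reward_family == 0) {
      R = (E <= n0sq) ? 1.0 : 0.0;
    } else {
      const double p = 1.0 / (1.0 + std::exp((E - n0sq) / T_smooth));
      R = (reward_family == 1) ? p : ((unif_rand() < p) ? 1.0 : 0.0);
    }

    rec_target[t] = j;
    rec_E[t] = E; rec_Et[t] = Et; rec_R[t] = R;
    rec_n0[t] = n0; rec_gamma[t] = gam;

    if (R != 0.0) {
      const double a0 = eta * R * xi0, a1 = eta * R * xi1;
      for (int i = 0; i < N; ++i) {
        W(0, i) += a0 * U(i, j);
        W(1, i) += a1 * U(i, j);
      }
      recompute_etil();
    }

    bool bad = false;
    for (int jj = 0; jj < m; ++jj)
      if (!std::isfinite(etil[jj]) || etil[jj] > diverge_guard) bad = true;
    if (bad) { divergent = true; t_done = t + 1; break; }

    if (shaping_kind == 1 || shaping_kind == 3) {
      ema[j] = (1.0 - alpha) * ema[j] + alpha * R;
      const bool active = (shaping_kind == 1) ? (n0 > n0_final)
                                              : (gam < gamma_final);
      if (active && ema_timescale > 0) {
        const int slot = (since_reset % ema_timescale) * m;
        bool steady = since_reset >= ema_timescale;
        if (steady) {
          for (int jj = 0; jj < m; ++jj) {
            if (std::fabs(ema[jj] - ring[slot + jj]) >= steady_tol ||
                ema[jj] < ema_floor) { steady = false; break; }
          }
        }
        for (int jj = 0; jj < m; ++jj) ring[slot + jj] = ema[jj];
        ++since_reset;
        if (steady) {
          if (shaping_kind == 1) {
            n0 = std::max(n0 - n0_step, n0_final);
          } else {
            gam = std::min(gam + gamma_step, gamma_final);
            cg = std::cos(gam); sg = std::sin(gam);
            recompute_etil();
          }
          std::fill(ema.begin(), ema.end(), 0.0);
          since_reset = 0;
        }
      }
    } else if (shaping_kind == 2) {
      if (((t + 1) % block_len) == 0 && gam < gamma_final) {
        gam = std::min(gam + gamma_step, gamma_final);
        cg = std::cos(gam); sg = std::sin(gam);
        recompute_etil();
      }
    }

    if (early_stop) {
      const bool shaping_done =
        (shaping_kind == 0) ||
        (shaping_kind == 1 && n0 <= n0_final) ||
        ((shaping_kind == 2 || shaping_kind == 3) && gam >= gamma_final);
      bool all_within = shaping_done;
      if (all_within) {
        const double lim = n0_final * n0_final;
        for (int jj = 0; jj < m; ++jj)
          if (etil[jj] > lim) { all_within = false; break; }
      }
      within_count = all_within ? within_count + 1 : 0;
      if (within_count >= early_window) { t_done = t + 1; break; }
    }
  }

  if (t_done < n_trials) {
    rec_target = IntegerVector(rec_target.begin(), rec_target.begin() + t_done);
    rec_E     = NumericVector(rec_E.begin(),     rec_E.begin()     + t_done);
    rec_Et    = NumericVector(rec_Et.begin(),    rec_Et.begin()    + t_done);
    rec_R     = NumericVector(rec_R.begin(),     rec_R.begin()     + t_done);
    rec_n0    = NumericVector(rec_n0.begin(),    rec_n0.begin()    + t_done);
    rec_gamma = NumericVector(rec_gamma.begin(), rec_gamma.begin() + t_done);
  }

  return List::create(
    _["target"] = rec_target, _["E"] = rec_E, _["E_noiseless"] = rec_Et,
    _["R"] = rec_R, _["n0_t"] = rec_n0, _["gamma_t"] = rec_gamma,
    _["W"] = W, _["divergent"] = divergent, _["n_done"] = t_done);
}
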