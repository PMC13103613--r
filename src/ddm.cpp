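// Compiled core of the multi-alternative Wiener race model: first-passage
// log-terms, the adaptive random-walk Metropolis sampler with block-coupled
// log-scale priors, and a Brownian-path (Euler-Maruyama with bridge crossing
// correction) simulator used as a brute-force oracle in the tests.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727417803297;

// log density of the first passage time of a unit-diffusion Wiener process
// with drift mu through barrier b (inverse-Gaussian with mean b/mu, shape b^2)
static inline double lfpt_density(double t, double mu, double b) {
  double z = b - mu * t;
  return std::log(b) - LOG_SQRT_2PI - 1.5 * std::log(t) - z * z / (2.0 * t);
}

// log survival P(T > t), computed in log space for stability:
// S(t) = Phi((b - mu t)/sqrt(t)) - exp(2 mu b) Phi(-(b + mu t)/sqrt(t))
static inline double lfpt_survival(double t, double mu, double b) {
  double st = std::sqrt(t);
  double la = R::pnorm((b - mu * t) / st, 0.0, 1.0, 1, 1);
  double lb = 2.0 * mu * b + R::pnorm(-(b + mu * t) / st, 0.0, 1.0, 1, 1);
  if (lb >= la) return R_NegInf;
  return la + std::log1p(-std::exp(lb - la));
}

static inline double ldnorm(double x, double sd) {
  return -0.5 * x * x / (sd * sd) - std::log(sd) - LOG_SQRT_2PI;
}

// [[Rcpp::export]]
NumericVector cpp_lfpt_density(NumericVector t, NumericVector mu, NumericVector b) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lfpt_density(t[i], mu[i % mu.size()], b[i % b.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lfpt_survival(NumericVector t, NumericVector mu, NumericVector b) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lfpt_survival(t[i], mu[i % mu.size()], b[i % b.size()]);
  return out;
}

// Adaptive random-walk Metropolis for the race model.
//
// Data (0-based): resp, stim in 0..K-1; blk in 0..B-1; rt in seconds.
// Parameters: log mu[d,s,blk], log b[d,s,blk], and per-stimulus offsets
// delta_s = delta_upper[s] * plogis(z_s) (uniform prior on delta, with the
// logistic Jacobian). Priors on log mu / log b: either iid N(0, prior_sd)
// per block, or a Gaussian random walk across blocks (sd tau_rw) anchored
// by N(0, prior_sd) at block 1.
//
// Returns thinned post-burn-in draws of mu, b (nsave x K*K*B) and delta
// (nsave x K), plus acceptance rates. Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List cpp_ddm_mcmc(IntegerVector resp, IntegerVector stim, IntegerVector blk,
                  NumericVector rt, int K, int B, NumericVector delta_upper,
                  int iters, int burnin, int thin, double tau_rw,
                  bool independent_blocks, double prior_sd) {
  const int n = resp.size();
  const int P = K * K * B;
  auto idx = [K](int d, int s, int j) { return d + K * (s + K * j); };

  std::vector<double> lmu(P, 0.0), lth(P, 0.0);
  std::vector<double> zdel(K, 0.0), delta(K), tau(n);

  // trials per (s, blk) cell and per stimulus
  std::vector<std::vector<int>> cell((size_t)K * B), bystim(K);
  for (int i = 0; i < n; ++i) {
    cell[(size_t)stim[i] * B + blk[i]].push_back(i);
    bystim[stim[i]].push_back(i);
  }

  // crude initialization: delta at half its bound, mu from mean decision time
  for (int s = 0; s < K; ++s) delta[s] = delta_upper[s] * 0.5;
  for (int i = 0; i < n; ++i) tau[i] = rt[i] - delta[stim[i]];
  for (int s = 0; s < K; ++s) {
    for (int j = 0; j < B; ++j) {
      const std::vector<int>& tr = cell[(size_t)s * B + j];
      double m = 0.5;
      if (!tr.empty()) {
        m = 0.0;
        for (int i : tr) m += tau[i];
        m /= tr.size();
      }
      double init = std::log(std::max(0.2, std::min(8.0, 1.0 / m)));
      for (int d = 0; d < K; ++d) lmu[idx(d, s, j)] = init;
    }
  }

  // per-trial caches of tau-derived quantities (updated on offset accepts)
  std::vector<double> st(n), lt15(n);
  auto refresh_tau = [&](int i) {
    st[i] = std::sqrt(tau[i]);
    lt15[i] = 1.5 * std::log(tau[i]);
  };
  for (int i = 0; i < n; ++i) refresh_tau(i);

  // fast log density / survival using the cached sqrt(tau), 1.5*log(tau)
  auto ldens = [&](int i, double mu, double b) {
    double z = b - mu * tau[i];
    return std::log(b) - LOG_SQRT_2PI - lt15[i] - z * z / (2.0 * tau[i]);
  };
  auto lsurv = [&](int i, double mu, double b) {
    double mt = mu * tau[i];
    double la = R::pnorm((b - mt) / st[i], 0.0, 1.0, 1, 1);
    double lb = 2.0 * mu * b + R::pnorm(-(b + mt) / st[i], 0.0, 1.0, 1, 1);
    if (lb >= la) return R_NegInf;
    return la + std::log1p(-std::exp(lb - la));
  };

  // cached per-trial, per-accumulator log terms
  std::vector<double> L((size_t)n * K);
  auto term = [&](int i, int d) {
    int s = stim[i], j = blk[i];
    double mu = std::exp(lmu[idx(d, s, j)]), b = std::exp(lth[idx(d, s, j)]);
    return (resp[i] == d) ? ldens(i, mu, b) : lsurv(i, mu, b);
  };
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < K; ++d) L[(size_t)d * n + i] = term(i, d);

  // prior terms that involve the value at block j of one (d,s) chain
  auto chain_prior = [&](std::vector<double>& th, int d, int s, int j, double val) {
    if (independent_blocks) return ldnorm(val, prior_sd);
    double lp = 0.0;
    if (j == 0) {
      lp += ldnorm(val, prior_sd);
      if (B > 1) lp += ldnorm(th[idx(d, s, 1)] - val, tau_rw);
    } else {
      lp += ldnorm(val - th[idx(d, s, j - 1)], tau_rw);
      if (j + 1 < B) lp += ldnorm(th[idx(d, s, j + 1)] - val, tau_rw);
    }
    return lp;
  };

  std::vector<double> ls_mu(P, std::log(0.25)), ls_th(P, std::log(0.25));
  std::vector<double> ls_z(K, std::log(0.3));
  std::vector<double> acc_mu(P, 0.0), acc_th(P, 0.0), acc_z(K, 0.0);
  std::vector<double> scratch(n);

  int nsave = 0;
  for (int it = burnin; it < iters; ++it)
    if ((it - burnin) % thin == 0) ++nsave;
  NumericMatrix mu_draws(nsave, P), th_draws(nsave, P), del_draws(nsave, K);
  int isave = 0;
  int npost = iters - burnin;

  GetRNGstate();
  for (int it = 0; it < iters; ++it) {
    double gamma = std::pow((double)it + 1.0, -0.6);
    bool adapting = it < burnin;

    // drift and threshold updates, one (d, s, blk) site at a time
    for (int which = 0; which < 2; ++which) {
      std::vector<double>& th = (which == 0) ? lmu : lth;
      std::vector<double>& ls = (which == 0) ? ls_mu : ls_th;
      std::vector<double>& acc = (which == 0) ? acc_mu : acc_th;
      for (int j = 0; j < B; ++j) {
        for (int s = 0; s < K; ++s) {
          const std::vector<int>& tr = cell[(size_t)s * B + j];
          for (int d = 0; d < K; ++d) {
            int p = idx(d, s, j);
            double cur = th[p];
            double prop = cur + std::exp(ls[p]) * norm_rand();
            double dlp = chain_prior(th, d, s, j, prop) -
                         chain_prior(th, d, s, j, cur);
            double mu_d, b_d;
            if (which == 0) { mu_d = std::exp(prop); b_d = std::exp(lth[p]); }
            else           { mu_d = std::exp(lmu[p]); b_d = std::exp(prop); }
            double dll = 0.0;
            for (size_t q = 0; q < tr.size(); ++q) {
              int i = tr[q];
              double nt = (resp[i] == d) ? ldens(i, mu_d, b_d)
                                         : lsurv(i, mu_d, b_d);
              scratch[q] = nt;
              dll += nt - L[(size_t)d * n + i];
            }
            double lalpha = dll + dlp;
            double alpha = (lalpha >= 0.0) ? 1.0 : std::exp(lalpha);
            if (unif_rand() < alpha) {
              th[p] = prop;
              for (size_t q = 0; q < tr.size(); ++q)
                L[(size_t)d * n + tr[q]] = scratch[q];
              if (!adapting) acc[p] += 1.0;
            }
            if (adapting) ls[p] += gamma * (alpha - 0.44);
          }
        }
      }
    }

    // offset updates, one stimulus at a time (touch every block of s)
    for (int s = 0; s < K; ++s) {
      double cur = zdel[s];
      double prop = cur + std::exp(ls_z[s]) * norm_rand();
      double pc = 1.0 / (1.0 + std::exp(-cur));
      double pp = 1.0 / (1.0 + std::exp(-prop));
      double dnew = delta_upper[s] * pp;
      // uniform prior on delta => logistic Jacobian in z
      double dlp = std::log(pp * (1.0 - pp)) - std::log(pc * (1.0 - pc));
      const std::vector<int>& tr = bystim[s];
      double dll = 0.0;
      std::vector<double> newL((size_t)tr.size() * K);
      bool ok = true;
      for (size_t q = 0; q < tr.size() && ok; ++q) {
        int i = tr[q];
        double ti = rt[i] - dnew;
        if (ti <= 0.0) { ok = false; break; }
        int j = blk[i];
        for (int d = 0; d < K; ++d) {
          double mu = std::exp(lmu[idx(d, s, j)]), b = std::exp(lth[idx(d, s, j)]);
          double nt = (resp[i] == d) ? lfpt_density(ti, mu, b)
                                     : lfpt_survival(ti, mu, b);
          newL[q * K + d] = nt;
          dll += nt - L[(size_t)d * n + i];
        }
      }
      double alpha = 0.0;
      if (ok) {
        double lalpha = dll + dlp;
        alpha = (lalpha >= 0.0) ? 1.0 : std::exp(lalpha);
        if (unif_rand() < alpha) {
          zdel[s] = prop;
          delta[s] = dnew;
          for (size_t q = 0; q < tr.size(); ++q) {
            int i = tr[q];
            tau[i] = rt[i] - dnew;
            refresh_tau(i);
            for (int d = 0; d < K; ++d)
              L[(size_t)d * n + i] = newL[q * K + d];
          }
          if (!adapting) acc_z[s] += 1.0;
        }
      }
      if (adapting) ls_z[s] += gamma * (alpha - 0.44);
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int p = 0; p < P; ++p) {
        mu_draws(isave, p) = std::exp(lmu[p]);
        th_draws(isave, p) = std::exp(lth[p]);
      }
      for (int s = 0; s < K; ++s) del_draws(isave, s) = delta[s];
      ++isave;
    }
  }
  PutRNGstate();

  NumericVector acc_rate_mu(P), acc_rate_th(P), acc_rate_z(K);
  for (int p = 0; p < P; ++p) {
    acc_rate_mu[p] = acc_mu[p] / npost;
    acc_rate_th[p] = acc_th[p] / npost;
  }
  for (int s = 0; s < K; ++s) acc_rate_z[s] = acc_z[s] / npost;

  return List::create(_["mu"] = mu_draws, _["b"] = th_draws,
                      _["delta"] = del_draws,
                      _["accept_mu"] = acc_rate_mu,
                      _["accept_b"] = acc_rate_th,
                      _["accept_delta"] = acc_rate_z);
}

// ---- brute-force diffusion oracle ------------------------------------------

// xoshiro256++ with splitmix64 seeding; own RNG because the oracle draws
// billions of normals and must not disturb R's stream. Normals come from a
// 128-layer Marsaglia-Tsang ziggurat (tables built at construction).
struct Xoshiro {
  uint64_t s[4];
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double nfix(int32_t hz, int iz) {
    const double r = 3.442619855899;
    for (;;) {
      double x = hz * wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      hz = (int32_t)(next() >> 32);
      iz = hz & 127;
      uint32_t a = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (a < kn[iz]) return hz * wn[iz];
    }
  }
  inline double norm() {
    int32_t hz = (int32_t)(next() >> 32);
    int iz = hz & 127;
    uint32_t a = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    return (a < kn[iz]) ? hz * wn[iz] : nfix(hz, iz);
  }
};

// Euler-Maruyama simulation of the K-accumulator race with a Brownian-bridge
// crossing correction (without it, first-passage times at step dt carry an
// O(sqrt(dt)) positive bias that exceeds Monte-Carlo error at large n).
// Returns 1-based winning accumulator (0 = no crossing before horizon) and
// the decision time in seconds (excluding any non-decision offset).
// [[Rcpp::export]]
List cpp_race_em(NumericVector mu, NumericVector b, int n, double dt,
                 double horizon, double seed) {
  const int K = mu.size();
  Xoshiro rng((uint64_t)seed);
  IntegerVector choice(n);
  NumericVector time(n);
  const double sdt = std::sqrt(dt);
  std::vector<double> x(K);

  for (int p = 0; p < n; ++p) {
    for (int k = 0; k < K; ++k) x[k] = 0.0;
    double t = 0.0;
    int win = 0;
    double twin = NA_REAL;
    while (t < horizon) {
      double best = R_PosInf;
      int bestk = 0;
      for (int k = 0; k < K; ++k) {
        double xo = x[k];
        double xn = xo + mu[k] * dt + sdt * rng.norm();
        double tc = -1.0;
        if (xn >= b[k]) {
          tc = t + dt * (b[k] - xo) / std::max(xn - xo, 1e-300);
        } else {
          double q = 2.0 * (b[k] - xo) * (b[k] - xn) / dt;
          if (q < 40.0 && rng.unif() < std::exp(-q)) tc = t + 0.5 * dt;
        }
        x[k] = xn;
        if (tc >= 0.0 && tc < best) { best = tc; bestk = k + 1; }
      }
      if (bestk > 0) { win = bestk; twin = best; break; }
      t += dt;
    }
    choice[p] = win;
    time[p] = twin;
  }
  return List::create(_["choice"] = choice, _["time"] = time);
}
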