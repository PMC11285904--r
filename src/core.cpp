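#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Self-contained counter-based RNG (splitmix64 seeding + xoroshiro128+).
// Simulators take an integer seed so trajectories are bitwise reproducible
// independently of R's RNG state.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  bool have_cached;
  double cached;
  explicit Rng(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  // uniform in (0,1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(th);
    have_cached = true;
    return r * std::cos(th);
  }
};

// Deterministic child-seed derivation: one keyed counter stream per
// (master seed, stream code); returns a value in [1, 2^31 - 2].
// [[Rcpp::export]]
double child_seed_cpp(double master, double stream, double index) {
  uint64_t x = (uint64_t)master;
  x = splitmix64(x) ^ (uint64_t)stream;
  x = splitmix64(x) ^ (uint64_t)index;
  uint64_t z = splitmix64(x);
  return (double)(1 + (z % 2147483645ULL));
}

// ---------------------------------------------------------------------------
// Four-gene stem cell network: Nanog (N), Oct4-Sox2 (O), Fgf4 (F), Gata6 (G).
// Parameter order (fixed, shared with R side):
//  0 a0, 1 a1, 2 b0, 3 b1, 4 b2, 5 b3, 6 c0, 7 c1, 8 c2, 9 c3, 10 c4,
// 11 e0, 12 e1, 13 e2, 14 k0, 15 gamma, 16 LIF, 17 I3, 18 alpha
// Reactions 1-4: production of N, O, F, G; reactions 5-8: linear degradation.
// ---------------------------------------------------------------------------

static inline void production_rates(const double *x, const double *p, double *a) {
  const double N = x[0], O = x[1], F = x[2], G = x[3];
  const double kO = p[14] * O;
  const double num = kO * (p[6] + p[7] * N * N + kO + p[8] * p[16]);
  const double den = 1.0 + kO * (p[7] * N * N + kO + p[8] * p[16] + p[9] * F * F);
  a[0] = num / den + p[10] * O * G * G;
  a[1] = p[18] + (p[11] + p[12] * O) / (1.0 + p[12] * O + p[13] * G * G);
  a[2] = (p[0] + p[1] * O) / (1.0 + p[1] * O);
  a[3] = (p[2] + p[3] * G * G + p[5] * O) / (1.0 + p[3] * G * G + p[4] * N * N + p[5] * O);
}

// [[Rcpp::export]]
NumericVector propensities_cpp(NumericVector state, NumericVector params) {
  NumericVector a(8);
  production_rates(state.begin(), params.begin(), a.begin());
  for (int j = 0; j < 4; ++j) a[4 + j] = params[15] * state[j];
  return a;
}

// Gillespie direct method, recording every event (plus the initial state and
// a final hold at t_end).
// [[Rcpp::export]]
List gillespie_path_cpp(NumericVector params, NumericVector x0, double t_end,
                        double seed, double max_events) {
  Rng rng((uint64_t)seed);
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double a[8];
  std::vector<double> times;
  std::vector<double> states;
  times.reserve(1024); states.reserve(4096);
  double t = 0.0;
  times.push_back(t);
  for (int j = 0; j < 4; ++j) states.push_back(x[j]);
  long nev = 0;
  while (t < t_end) {
    production_rates(x, params.begin(), a);
    double tot = a[0] + a[1] + a[2] + a[3];
    for (int j = 0; j < 4; ++j) { a[4 + j] = params[15] * x[j]; tot += a[4 + j]; }
    if (!(tot > 0.0)) break;  // frozen state: no reaction can fire
    double dt = -std::log(rng.unif()) / tot;
    if (t + dt > t_end) break;
    t += dt;
    double r = rng.unif() * tot, acc = 0.0;
    int k = 7;
    for (int i = 0; i < 8; ++i) { acc += a[i]; if (r <= acc) { k = i; break; } }
    if (k < 4) x[k] += 1.0; else x[k - 4] -= 1.0;
    times.push_back(t);
    for (int j = 0; j < 4; ++j) states.push_back(x[j]);
    if (++nev >= (long)max_events)
      stop("gillespie: exceeded max_events (%g) before t_end", max_events);
  }
  times.push_back(t_end);
  for (int j = 0; j < 4; ++j) states.push_back(x[j]);
  int K = (int)times.size();
  NumericMatrix S(4, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < 4; ++j) S(j, i) = states[4 * i + j];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = S);
}

// Gillespie sampled directly on a time grid (left-continuous hold), avoiding
// event storage; used for snapshot dataset generation.
// [[Rcpp::export]]
NumericMatrix gillespie_grid_cpp(NumericVector params, NumericVector x0,
                                 NumericVector grid, double seed) {
  Rng rng((uint64_t)seed);
  int T = grid.size();
  NumericMatrix out(4, T);
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double a[8];
  double t = 0.0;
  int k = 0;
  double t_end = grid[T - 1];
  while (k < T) {
    production_rates(x, params.begin(), a);
    double tot = a[0] + a[1] + a[2] + a[3];
    for (int j = 0; j < 4; ++j) { a[4 + j] = params[15] * x[j]; tot += a[4 + j]; }
    double t_next;
    if (tot > 0.0) t_next = t - std::log(rng.unif()) / tot;
    else t_next = t_end + 1.0;  // frozen: hold state forever
    while (k < T && grid[k] < t_next) {
      for (int j = 0; j < 4; ++j) out(j, k) = x[j];
      ++k;
    }
    if (k >= T) break;
    t = t_next;
    double r = rng.unif() * tot, acc = 0.0;
    int idx = 7;
    for (int i = 0; i < 8; ++i) { acc += a[i]; if (r <= acc) { idx = i; break; } }
    if (idx < 4) x[idx] += 1.0; else x[idx - 4] -= 1.0;
  }
  return out;
}

// Chemical Langevin equation, Euler-Maruyama with per-reaction noise
// nu_i sqrt(a_i(x)) dW_i; states clipped at 0 after every step.
// [[Rcpp::export]]
List cle_path_cpp(NumericVector params, NumericVector x0, double t_end,
                  double dt, double seed, double noise_scale) {
  Rng rng((uint64_t)seed);
  int n_steps = (int)std::ceil(t_end / dt - 1e-12);
  NumericVector times(n_steps + 1);
  NumericMatrix S(4, n_steps + 1);
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double a[8];
  for (int j = 0; j < 4; ++j) S(j, 0) = x[j];
  double t = 0.0;
  for (int s = 1; s <= n_steps; ++s) {
    double h = std::min(dt, t_end - t);
    production_rates(x, params.begin(), a);
    for (int j = 0; j < 4; ++j) a[4 + j] = params[15] * x[j];
    double sh = std::sqrt(h);
    for (int j = 0; j < 4; ++j) {
      double prod = std::max(a[j], 0.0), deg = std::max(a[4 + j], 0.0);
      double drift = (a[j] - a[4 + j]) * h;
      double noise = noise_scale * sh *
        (std::sqrt(prod) * rng.norm() - std::sqrt(deg) * rng.norm());
      x[j] = std::max(0.0, x[j] + drift + noise);
    }
    t += h;
    times[s] = t;
    for (int j = 0; j < 4; ++j) S(j, s) = x[j];
  }
  return List::create(_["times"] = times, _["states"] = S);
}

// ---------------------------------------------------------------------------
// Distance kernels
// ---------------------------------------------------------------------------

static inline double sqdist_rows(const NumericMatrix &A, int i,
                                 const NumericMatrix &B, int j) {
  double s = 0.0;
  for (int k = 0; k < A.ncol(); ++k) {
    double d = A(i, k) - B(j, k);
    s += d * d;
  }
  return s;
}

// Unbiased MMD^2 estimator with Gaussian kernel of bandwidth sigma.
// [[Rcpp::export]]
double mmd2_unbiased_cpp(NumericMatrix X, NumericMatrix Y, double sigma) {
  int m = X.nrow(), n = Y.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      sxx += std::exp(-sqdist_rows(X, i, X, j) * inv2s2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      syy += std::exp(-sqdist_rows(Y, i, Y, j) * inv2s2);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      sxy += std::exp(-sqdist_rows(X, i, Y, j) * inv2s2);
  return 2.0 * sxx / ((double)m * (m - 1)) + 2.0 * syy / ((double)n * (n - 1)) -
         2.0 * sxy / ((double)m * n);
}

// Median of pairwise Euclidean distances of the rows of Z (i < j pairs).
// [[Rcpp::export]]
double median_pairwise_cpp(NumericMatrix Z) {
  int n = Z.nrow();
  if (n < 2) stop("need at least 2 points for pairwise distances");
  std::vector<double> d;
  d.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      d.push_back(std::sqrt(sqdist_rows(Z, i, Z, j)));
  size_t mid = d.size() / 2;
  std::nth_element(d.begin(), d.begin() + mid, d.end());
  double hi = d[mid];
  if (d.size() % 2 == 1) return hi;
  std::nth_element(d.begin(), d.begin() + mid - 1, d.begin() + mid);
  return 0.5 * (hi + d[mid - 1]);
}

// Entropic OT cost <P, C> between weighted empirical measures (atoms in the
// rows of X and Y with probability weights wa, wb), squared Euclidean ground
// cost. Epsilon-annealed Sinkhorn: the regularization starts near the cost
// scale and is divided by 5 each stage down to the target, warm-starting the
// dual potentials. Within a stage the iteration runs in fast scaling form
// (precomputed kernel, multiplication-only updates) whenever the exponent
// range is safely representable, and in log-domain otherwise.
// [[Rcpp::export]]
List sinkhorn_cost_cpp(NumericMatrix X, NumericVector wa,
                       NumericMatrix Y, NumericVector wb, double eps,
                       int max_iter, double tol) {
  int n = X.nrow(), m = Y.nrow();
  std::vector<double> C((size_t)n * m);
  double maxC = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double c = sqdist_rows(X, i, Y, j);
      C[(size_t)i * m + j] = c;
      if (c > maxC) maxC = c;
    }
  std::vector<double> f(n, 0.0), g(m, 0.0), la(n), lb(m);
  for (int i = 0; i < n; ++i) la[i] = std::log(wa[i]);
  for (int j = 0; j < m; ++j) lb[j] = std::log(wb[j]);
  // log-domain half updates (always safe)
  auto update_f_log = [&](double e) {
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *Ci = &C[(size_t)i * m];
      double mx = -R_PosInf;
      for (int j = 0; j < m; ++j) {
        double t = lb[j] + (g[j] - Ci[j]) / e;
        if (t > mx) mx = t;
      }
      double s = 0.0;
      for (int j = 0; j < m; ++j)
        s += std::exp(lb[j] + (g[j] - Ci[j]) / e - mx);
      double fi = -e * (mx + std::log(s));
      delta = std::max(delta, std::fabs(fi - f[i]));
      f[i] = fi;
    }
    return delta;
  };
  auto update_g_log = [&](double e) {
    for (int j = 0; j < m; ++j) {
      double mx = -R_PosInf;
      for (int i = 0; i < n; ++i) {
        double t = la[i] + (f[i] - C[(size_t)i * m + j]) / e;
        if (t > mx) mx = t;
      }
      double s = 0.0;
      for (int i = 0; i < n; ++i)
        s += std::exp(la[i] + (f[i] - C[(size_t)i * m + j]) / e - mx);
      g[j] = -e * (mx + std::log(s));
    }
  };
  auto plan_cost = [&]() {
    double cost = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j)
        cost += wa[i] * wb[j] *
                std::exp((f[i] + g[j] - C[(size_t)i * m + j]) / eps) *
                C[(size_t)i * m + j];
    return cost;
  };
  std::vector<double> K((size_t)n * m), u(n), v(m);
  std::vector<double> stages;
  double e = std::max(eps, maxC / 8.0);
  while (e > eps * 5.0) { stages.push_back(e); e /= 5.0; }
  stages.push_back(eps);
  double res = R_PosInf;
  int it = 0;
  bool converged = false;
  for (size_t s = 0; s < stages.size() && it < max_iter; ++s) {
    double es = stages[s];
    bool final_stage = (s + 1 == stages.size());
    double tol_s = final_stage ? tol : std::max(tol, 1e-3);
    // scaling form is safe when kernel entries stay far above underflow
    bool use_scaling = (maxC / es) < 600.0;
    int burn = 0;
    double last_cost = R_PosInf;
    if (use_scaling) {
      // K absorbs current potentials and weights: K_ij = wb_j exp((f+g-C)/es)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j)
          K[(size_t)i * m + j] =
            wb[j] * std::exp((f[i] + g[j] - C[(size_t)i * m + j]) / es);
      std::fill(u.begin(), u.end(), 1.0);
      std::fill(v.begin(), v.end(), 1.0);
      while (it < max_iter) {
        ++it; ++burn;
        bool bad = false;
        double delta = 0.0;
        for (int i = 0; i < n; ++i) {
          double sum = 0.0;
          const double *Ki = &K[(size_t)i * m];
          for (int j = 0; j < m; ++j) sum += Ki[j] * v[j];
          if (!(sum > 0.0) || !R_finite(sum)) { bad = true; break; }
          double un = 1.0 / sum;
          delta = std::max(delta, std::fabs(std::log(un / u[i])));
          u[i] = un;
        }
        if (!bad) {
          for (int j = 0; j < m; ++j) {
            double sum = 0.0;
            for (int i = 0; i < n; ++i)
              sum += wa[i] * K[(size_t)i * m + j] * u[i] / wb[j];
            if (!(sum > 0.0) || !R_finite(sum)) { bad = true; break; }
            v[j] = 1.0 / sum;
          }
        }
        if (bad) {  // fold what we have and fall back to log-domain
          for (int i = 0; i < n; ++i)
            if (u[i] > 0.0 && R_finite(u[i])) f[i] += es * std::log(u[i]);
          for (int j = 0; j < m; ++j)
            if (v[j] > 0.0 && R_finite(v[j])) g[j] += es * std::log(v[j]);
          use_scaling = false;
          break;
        }
        res = delta;  // log-scale potential movement per iteration
        if (res < tol_s && burn >= 2) { if (final_stage) converged = true; break; }
        if (!final_stage && burn >= 25) break;
        if (final_stage && burn % 25 == 0) {
          for (int i = 0; i < n; ++i) f[i] += es * std::log(u[i]);
          for (int j = 0; j < m; ++j) g[j] += es * std::log(v[j]);
          for (int i = 0; i < n; ++i)
            for (int j = 0; j < m; ++j)
              K[(size_t)i * m + j] =
                wb[j] * std::exp((f[i] + g[j] - C[(size_t)i * m + j]) / es);
          std::fill(u.begin(), u.end(), 1.0);
          std::fill(v.begin(), v.end(), 1.0);
          double cost_now = plan_cost();
          if (std::fabs(cost_now - last_cost) <=
              tol * std::max(1.0, std::fabs(cost_now))) {
            converged = true;
            break;
          }
          last_cost = cost_now;
        }
      }
      if (use_scaling) {  // fold scalings into the potentials
        for (int i = 0; i < n; ++i) f[i] += es * std::log(u[i]);
        for (int j = 0; j < m; ++j) g[j] += es * std::log(v[j]);
        continue;
      }
      // else: fall through into log-domain for this stage
    }
    burn = 0;
    last_cost = R_PosInf;
    while (it < max_iter) {
      ++it; ++burn;
      update_g_log(es);
      double delta = update_f_log(es);
      res = delta / es;
      if (res < tol_s && burn >= 2) { if (final_stage) converged = true; break; }
      if (!final_stage && burn >= 25) break;
      if (final_stage && burn % 25 == 0) {
        double cost_now = plan_cost();
        if (std::fabs(cost_now - last_cost) <=
            tol * std::max(1.0, std::fabs(cost_now))) {
          converged = true;
          break;
        }
        last_cost = cost_now;
      }
    }
  }
  return List::create(_["cost"] = plan_cost(), _["iterations"] = it,
                      _["converged"] = converged, _["residual"] = res);
}

// Mixture-form Monte Carlo estimator of the Bhattacharyya coefficient
// rho = integral sqrt(p q) = E_{z ~ m}[ sqrt(p(z) q(z)) / m(z) ],
// m = (n p + m q)/(n + m), estimated over the pooled sample under Gaussian
// product KDEs with per-dimension bandwidths hx, hy. Each term is bounded
// by 1 (AM-GM), so the estimator is stable even when supports barely
// overlap, and equals 1 when the two KDEs coincide.
// [[Rcpp::export]]
double bhatt_rho_cpp(NumericMatrix X, NumericMatrix Y,
                     NumericVector hx, NumericVector hy) {
  int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  const double log2pi = 1.8378770664093454835606594728112;
  double lognormx = 0.0, lognormy = 0.0;
  for (int k = 0; k < d; ++k) {
    lognormx += -0.5 * log2pi - std::log(hx[k]);
    lognormy += -0.5 * log2pi - std::log(hy[k]);
  }
  // log density of product KDE built on A (bandwidth h) evaluated at row i of B
  auto logkde = [&](const NumericMatrix &A, const NumericVector &h,
                    double lognorm, const NumericMatrix &B, int i) {
    int N = A.nrow();
    double mx = -R_PosInf;
    std::vector<double> e(N);
    for (int r = 0; r < N; ++r) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double z = (B(i, k) - A(r, k)) / h[k];
        s -= 0.5 * z * z;
      }
      e[r] = s;
      if (s > mx) mx = s;
    }
    double acc = 0.0;
    for (int r = 0; r < N; ++r) acc += std::exp(e[r] - mx);
    return mx + std::log(acc) - std::log((double)N) + lognorm;
  };
  const double wp = (double)n / (n + m), wq = (double)m / (n + m);
  double acc = 0.0;
  for (int src = 0; src < 2; ++src) {
    const NumericMatrix &B = (src == 0) ? X : Y;
    for (int i = 0; i < B.nrow(); ++i) {
      double lp = logkde(X, hx, lognormx, B, i);
      double lq = logkde(Y, hy, lognormy, B, i);
      // log m(z) via stable log-sum-exp of the two mixture components
      double hi = std::max(lp + std::log(wp), lq + std::log(wq));
      double lm = hi + std::log(std::exp(lp + std::log(wp) - hi) +
                                std::exp(lq + std::log(wq) - hi));
      acc += std::exp(0.5 * (lp + lq) - lm);
    }
  }
  return acc / (n + m);
}

// Symmetric entropic OT cost OT_eps(X, X) for a weighted empirical measure,
// by the geometric-mean damped fixed-point iteration on the single
// potential (fast for Sinkhorn-divergence debias terms). Runs in scaling
// form with a precomputed kernel when the exponent range allows, log-domain
// otherwise.
// [[Rcpp::export]]
List sinkhorn_sym_cost_cpp(NumericMatrix X, NumericVector wa, double eps,
                           int max_iter, double tol) {
  int n = X.nrow();
  std::vector<double> C((size_t)n * n);
  double maxC = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double c = sqdist_rows(X, i, X, j);
      C[(size_t)i * n + j] = c;
      if (c > maxC) maxC = c;
    }
  std::vector<double> f(n, 0.0), la(n);
  for (int i = 0; i < n; ++i) la[i] = std::log(wa[i]);
  double res = R_PosInf;
  int it = 0;
  bool done = false;
  if (maxC / eps < 600.0) {
    // scaling form: b_i = exp(f_i/eps); fixed point b * (K (w b)) = 1
    std::vector<double> K((size_t)n * n), b(n, 1.0), wb(n);
    for (size_t q = 0; q < K.size(); ++q) K[q] = std::exp(-C[q] / eps);
    for (it = 1; it <= max_iter; ++it) {
      res = 0.0;
      bool bad = false;
      for (int i = 0; i < n; ++i) wb[i] = wa[i] * b[i];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        const double *Ki = &K[(size_t)i * n];
        for (int j = 0; j < n; ++j) s += Ki[j] * wb[j];
        if (!(s > 0.0) || !R_finite(s)) { bad = true; break; }
        double bn = std::sqrt(b[i] / s);  // geometric-mean damping
        res = std::max(res, std::fabs(std::log(bn / b[i])));
        b[i] = bn;
      }
      if (bad) break;  // fall back to log-domain below
      if (res < tol) {
        for (int i = 0; i < n; ++i) f[i] = eps * std::log(b[i]);
        done = true;
        break;
      }
    }
    if (!done && res < R_PosInf && it > max_iter) {
      for (int i = 0; i < n; ++i) f[i] = eps * std::log(b[i]);
    }
  }
  if (!done) {
    std::vector<double> fn(n, 0.0);
    for (it = 1; it <= max_iter; ++it) {
      res = 0.0;
      for (int i = 0; i < n; ++i) {
        double mx = -R_PosInf;
        for (int j = 0; j < n; ++j) {
          double e = la[j] + (f[j] - C[(size_t)i * n + j]) / eps;
          if (e > mx) mx = e;
        }
        double s = 0.0;
        for (int j = 0; j < n; ++j)
          s += std::exp(la[j] + (f[j] - C[(size_t)i * n + j]) / eps - mx);
        double target = -eps * (mx + std::log(s));
        fn[i] = 0.5 * (f[i] + target);
        res = std::max(res, std::fabs(fn[i] - f[i]) / eps);
      }
      f = fn;
      if (res < tol) { done = true; break; }
    }
  }
  double cost = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      cost += wa[i] * wa[j] *
              std::exp((f[i] + f[j] - C[(size_t)i * n + j]) / eps) *
              C[(size_t)i * n + j];
  return List::create(_["cost"] = cost, _["iterations"] = it,
                      _["converged"] = done, _["residual"] = res);
}

// Summed unbiased MMD^2 between two snapshot tensors (4 x T x n, column-major
// as stored by R arrays), Gaussian kernel with per-slice median-heuristic
// bandwidth (pooled sample subsampled by stride to <= 128 points), each
// slice floored at 0. One call per candidate avoids per-slice R overhead.
// [[Rcpp::export]]
NumericVector snapshot_mmd_cpp(NumericVector ref, NumericVector cand,
                               int T, int n1, int n2) {
  const double *A = ref.begin(), *B = cand.begin();
  NumericVector per_t(T);
  std::vector<double> d;
  auto row = [](const double *base, int t, int i, int T_, int k) {
    return base[(size_t)4 * (t + (size_t)T_ * i) + k];
  };
  for (int t = 0; t < T; ++t) {
    // median heuristic over the pooled slice (strided subsample)
    int ntot = n1 + n2;
    int stride = ntot > 128 ? (ntot + 127) / 128 : 1;
    std::vector<const double *> pool;
    for (int i = 0; i < n1; i += stride) pool.push_back(&A[(size_t)4 * (t + (size_t)T * i)]);
    for (int i = 0; i < n2; i += stride) pool.push_back(&B[(size_t)4 * (t + (size_t)T * i)]);
    d.clear();
    for (size_t a = 0; a < pool.size(); ++a)
      for (size_t b = a + 1; b < pool.size(); ++b) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) {
          double diff = pool[a][k] - pool[b][k];
          s += diff * diff;
        }
        d.push_back(std::sqrt(s));
      }
    size_t mid = d.size() / 2;
    std::nth_element(d.begin(), d.begin() + mid, d.end());
    double med = d[mid];
    if (d.size() % 2 == 0) {
      std::nth_element(d.begin(), d.begin() + mid - 1, d.begin() + mid);
      med = 0.5 * (med + d[mid - 1]);
    }
    double sigma = med / 2.0;
    if (!(sigma > 0.0)) {
      // degenerate pool: fall back to smallest positive pairwise distance
      double mn = R_PosInf;
      for (size_t q = 0; q < d.size(); ++q)
        if (d[q] > 0.0 && d[q] < mn) mn = d[q];
      if (!R_finite(mn)) { per_t[t] = 0.0; continue; }
      sigma = mn / 2.0;
    }
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    double sxx = 0.0, syy = 0.0, sxy = 0.0;
    for (int i = 0; i < n1; ++i) {
      const double *xi = &A[(size_t)4 * (t + (size_t)T * i)];
      for (int j = i + 1; j < n1; ++j) {
        const double *xj = &A[(size_t)4 * (t + (size_t)T * j)];
        double s = 0.0;
        for (int k = 0; k < 4; ++k) { double df = xi[k] - xj[k]; s += df * df; }
        sxx += std::exp(-s * inv2s2);
      }
    }
    for (int i = 0; i < n2; ++i) {
      const double *yi = &B[(size_t)4 * (t + (size_t)T * i)];
      for (int j = i + 1; j < n2; ++j) {
        const double *yj = &B[(size_t)4 * (t + (size_t)T * j)];
        double s = 0.0;
        for (int k = 0; k < 4; ++k) { double df = yi[k] - yj[k]; s += df * df; }
        syy += std::exp(-s * inv2s2);
      }
    }
    for (int i = 0; i < n1; ++i) {
      const double *xi = &A[(size_t)4 * (t + (size_t)T * i)];
      for (int j = 0; j < n2; ++j) {
        const double *yj = &B[(size_t)4 * (t + (size_t)T * j)];
        double s = 0.0;
        for (int k = 0; k < 4; ++k) { double df = xi[k] - yj[k]; s += df * df; }
        sxy += std::exp(-s * inv2s2);
      }
    }
    double v = 2.0 * sxx / ((double)n1 * (n1 - 1)) +
               2.0 * syy / ((double)n2 * (n2 - 1)) -
               2.0 * sxy / ((double)n1 * n2);
    per_t[t] = std::max(v, 0.0);
  }
  return per_t;
}
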