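// Shared reaction-network evaluator for both engines, plus the stochastic
// simulation loop. The network is compiled once on the R side into flat
// arrays (compile_for_engine) and held here behind an external pointer, so
// the ODE right-hand side and the SSA propensities are computed from the
// same structures.
//
// Stochastic engine notes:
//  * Species scaling: species flagged scalable are counted in units of
//    Omega copies; a reaction moving any scaled species has its propensity
//    divided by Omega and advances those species by one unit per firing.
//    Low-copy species (lesions, mRNAs, promoter states) stay exact.
//  * The inhibitor depot/blood pair is macroscopic and linear; it is
//    advanced between jumps by its exact solution (Bateman propagator).
//    Propensities involving the blood level are refreshed every step; jump
//    waiting times are capped at tau_max seconds so the quasi-static
//    approximation of the slowly varying blood level stays accurate.
//  * RNG: xoshiro256++ seeded from (root seed, stream index) through
//    splitmix64, giving per-cell streams independent of cell count.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

struct Reaction {
  double k;                       // rate constant times fixed factor
  std::vector<int> rate_idx;      // species multiplying the rate
  std::vector<double> rate_pow;
  std::vector<int> hill_idx;      // saturating/Hill factors (may be empty)
  std::vector<double> hill_K, hill_h;
  std::vector<int> re_idx;        // consumed species
  std::vector<int> re_st;
  std::vector<int> pr_idx;        // produced species
  std::vector<int> pr_st;
  bool pk;                        // analytic PK reaction: skipped in SSA
  bool touches_scaled;
};

struct Net {
  int nsp;
  std::vector<Reaction> rx;
  std::vector<char> scaled;
  std::vector<char> discrete;     // false for drug pools
  int i_dam, i_depot, i_blood, i_casp;
  double d_r1, d_r2, k_dsb, casp_thresh;
  // reaction dependency graph: for each species, reactions to refresh
  std::vector<std::vector<int>> dep;
};

// ---------------------------------------------------------------- RNG ----
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97f4A7C15ULL + stream;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int poisson(double lambda) {
    int total = 0;
    while (lambda > 30.0) {       // chunk to avoid exp underflow
      total += poisson_knuth(30.0);
      lambda -= 30.0;
    }
    return total + poisson_knuth(lambda);
  }
  int poisson_knuth(double lambda) {
    if (lambda <= 0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { k++; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// ------------------------------------------------------------- compile ---
static std::vector<char> to_char_vec(SEXP x) {
  LogicalVector v(x);
  std::vector<char> out(v.size());
  for (int i = 0; i < v.size(); i++) out[i] = v[i] ? 1 : 0;
  return out;
}

static Net *as_net(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP compile_network_cpp(List spec) {
  Net *net = new Net();
  net->nsp = as<int>(spec["nsp"]);
  net->scaled = to_char_vec(spec["scaled"]);
  net->discrete = to_char_vec(spec["discrete"]);
  net->i_dam = as<int>(spec["i_dam"]);
  net->i_depot = as<int>(spec["i_depot"]);
  net->i_blood = as<int>(spec["i_blood"]);
  net->i_casp = as<int>(spec["i_casp"]);
  net->d_r1 = as<double>(spec["d_r1"]);
  net->d_r2 = as<double>(spec["d_r2"]);
  net->k_dsb = as<double>(spec["k_dsb"]);
  net->casp_thresh = as<double>(spec["casp_thresh"]);

  List rxs = spec["reactions"];
  int nrx = rxs.size();
  net->rx.resize(nrx);
  for (int i = 0; i < nrx; i++) {
    List r = rxs[i];
    Reaction &R = net->rx[i];
    R.k = as<double>(r["k"]);
    R.rate_idx = as<std::vector<int>>(r["rate_idx"]);
    R.rate_pow = as<std::vector<double>>(r["rate_pow"]);
    R.hill_idx = as<std::vector<int>>(r["hill_idx"]);
    R.hill_K = as<std::vector<double>>(r["hill_K"]);
    R.hill_h = as<std::vector<double>>(r["hill_h"]);
    R.re_idx = as<std::vector<int>>(r["re_idx"]);
    R.re_st = as<std::vector<int>>(r["re_st"]);
    R.pr_idx = as<std::vector<int>>(r["pr_idx"]);
    R.pr_st = as<std::vector<int>>(r["pr_st"]);
    R.pk = as<bool>(r["pk"]);
    R.touches_scaled = false;
    for (int j : R.re_idx) if (net->scaled[j]) R.touches_scaled = true;
    for (int j : R.pr_idx) if (net->scaled[j]) R.touches_scaled = true;
  }

  // dependency graph: species -> reactions whose propensity reads it
  net->dep.assign(net->nsp, {});
  for (int i = 0; i < nrx; i++) {
    std::vector<char> uses(net->nsp, 0);
    for (int j : net->rx[i].rate_idx) uses[j] = 1;
    for (int j : net->rx[i].hill_idx) uses[j] = 1;
    for (int j : net->rx[i].re_idx) uses[j] = 1;  // guard depends on count
    for (int s = 0; s < net->nsp; s++) if (uses[s]) net->dep[s].push_back(i);
  }

  Rcpp::XPtr<Net> p(net, true);
  return p;
}

// deterministic flux of reaction R at real-valued amounts x
static inline double flux_one(const Reaction &R, const double *x) {
  double f = R.k;
  for (size_t j = 0; j < R.hill_idx.size(); j++) {
    double m = x[R.hill_idx[j]];
    if (m <= 0) return 0.0;
    double mh = std::pow(m, R.hill_h[j]);
    f *= mh / (std::pow(R.hill_K[j], R.hill_h[j]) + mh);
  }
  for (size_t j = 0; j < R.rate_idx.size(); j++) {
    double v = x[R.rate_idx[j]];
    if (v <= 0) return 0.0;
    f *= (R.rate_pow[j] == 1.0) ? v : std::pow(v, R.rate_pow[j]);
  }
  return f;
}

// [[Rcpp::export]]
NumericVector net_fluxes_cpp(SEXP ptr, NumericVector y) {
  Net *net = as_net(ptr);
  int nrx = net->rx.size();
  NumericVector out(nrx);
  for (int i = 0; i < nrx; i++) out[i] = flux_one(net->rx[i], y.begin());
  return out;
}

// ODE right-hand side: S %*% flux (PK reactions included)
// [[Rcpp::export]]
NumericVector net_deriv_cpp(SEXP ptr, NumericVector y) {
  Net *net = as_net(ptr);
  NumericVector dy(net->nsp);
  std::vector<double> x(y.begin(), y.end());
  for (double &v : x) if (v < 0) v = 0;   // integrator may undershoot
  for (size_t i = 0; i < net->rx.size(); i++) {
    const Reaction &R = net->rx[i];
    double f = flux_one(R, x.data());
    if (f == 0) continue;
    for (size_t j = 0; j < R.re_idx.size(); j++) dy[R.re_idx[j]] -= f * R.re_st[j];
    for (size_t j = 0; j < R.pr_idx.size(); j++) dy[R.pr_idx[j]] += f * R.pr_st[j];
  }
  return dy;
}

// ----------------------------------------------------------------- SSA ---
// propensity of reaction R with mixed scaled/exact species.
// `u` holds the internal state: scaled species in units of omega, exact
// species in copies. Real amounts: u * (scaled ? omega : 1).
static inline double propensity(const Net *net, const Reaction &R,
                                const std::vector<double> &u, double omega) {
  // sufficiency guard (in each species' own unit)
  for (size_t j = 0; j < R.re_idx.size(); j++)
    if (u[R.re_idx[j]] < R.re_st[j]) return 0.0;
  double a = R.k;
  for (size_t j = 0; j < R.hill_idx.size(); j++) {
    double m = u[R.hill_idx[j]] * (net->scaled[R.hill_idx[j]] ? omega : 1.0);
    if (m <= 0) return 0.0;
    double mh = std::pow(m, R.hill_h[j]);
    a *= mh / (std::pow(R.hill_K[j], R.hill_h[j]) + mh);
  }
  for (size_t j = 0; j < R.rate_idx.size(); j++) {
    int si = R.rate_idx[j];
    double n = R.rate_pow[j];
    double xr = u[si] * (net->scaled[si] ? omega : 1.0);
    if (xr <= 0) return 0.0;
    if (n == 1.0) { a *= xr; continue; }
    // exact mass-action combinatorics for unscaled species consumed with
    // matching multiplicity (e.g. dimerization on a discrete species)
    int consumed = -1;
    for (size_t q = 0; q < R.re_idx.size(); q++)
      if (R.re_idx[q] == si) { consumed = (int)q; break; }
    if (!net->scaled[si] && consumed >= 0 && R.re_st[consumed] == (int)n) {
      double prod = 1.0;
      for (int m2 = 0; m2 < (int)n; m2++) prod *= (xr - m2);
      a *= prod;
    } else {
      a *= std::pow(xr, n);
    }
  }
  if (R.touches_scaled) a /= omega;
  return a;
}

// exact update of the linear depot->blood->elimination subsystem
static inline void pk_advance(const Net *net, std::vector<double> &u,
                              double dt, double q_drip) {
  if (net->i_blood < 0) return;
  double d1 = net->d_r1, d2 = net->d_r2;
  double e2 = std::exp(-d2 * dt);
  double blood = u[net->i_blood] * e2;
  if (net->i_depot >= 0 && u[net->i_depot] > 0) {
    double e1 = std::exp(-d1 * dt);
    double f = (std::abs(d1 - d2) > 1e-14)
      ? d1 / (d1 - d2) * (e2 - e1)
      : d1 * dt * e1;
    blood += u[net->i_depot] * f;
    u[net->i_depot] *= e1;
  }
  if (q_drip > 0) blood += q_drip / d2 * (1.0 - e2);
  u[net->i_blood] = blood;
}

// [[Rcpp::export]]
List ssa_run_cpp(SEXP ptr, NumericVector init, double omega,
                 NumericVector ev_time, IntegerVector ev_type,
                 NumericVector ev_mag, double horizon_s, double seed,
                 double stream, double tau_max, NumericVector sample_times,
                 bool stop_on_commit, bool deterministic_lesions) {
  Net *net = as_net(ptr);
  int nsp = net->nsp, nrx = net->rx.size();
  Rng rng((uint64_t)seed, (uint64_t)stream);

  // internal state: scaled species in units of omega
  std::vector<double> u(nsp);
  for (int i = 0; i < nsp; i++)
    u[i] = net->scaled[i] ? std::floor(init[i] / omega + 0.5) : init[i];

  std::vector<double> a(nrx, 0.0);
  double a0 = 0.0;
  auto recompute_all = [&]() {
    a0 = 0.0;
    for (int i = 0; i < nrx; i++) {
      a[i] = net->rx[i].pk ? 0.0 : propensity(net, net->rx[i], u, omega);
      a0 += a[i];
    }
  };
  auto refresh_species = [&](int s) {
    for (int i : net->dep[s]) {
      if (net->rx[i].pk) continue;
      double old = a[i];
      a[i] = propensity(net, net->rx[i], u, omega);
      a0 += a[i] - old;
    }
  };

  double t = 0.0, q_drip = 0.0;
  int ev = 0, nev = ev_time.size();
  int ns = sample_times.size(), si = 0;
  NumericMatrix samples(ns, nsp);
  bool committed = false;
  double commit_time = NA_REAL;
  long steps_since_full = 0;

  auto real_amount = [&](int i) {
    return u[i] * (net->scaled[i] ? omega : 1.0);
  };
  auto take_samples_until = [&](double tt) {
    while (si < ns && sample_times[si] <= tt + 1e-9) {
      for (int i = 0; i < nsp; i++) samples(si, i) = real_amount(i);
      si++;
    }
  };
  auto check_commit = [&]() {
    if (!committed && net->i_casp >= 0 &&
        real_amount(net->i_casp) >= net->casp_thresh) {
      committed = true;
      commit_time = t;
    }
  };

  recompute_all();
  check_commit();

  while (t < horizon_s) {
    if (committed && stop_on_commit) break;
    double t_next = horizon_s;
    if (ev < nev && ev_time[ev] < t_next) t_next = ev_time[ev];
    double cap = std::min(tau_max, t_next - t);
    if (cap < 0) cap = 0;

    double dt;
    bool fire = false;
    if (a0 > 1e-300) {
      dt = -std::log(rng.unif()) / a0;
      if (dt <= cap) fire = true; else dt = cap;
    } else {
      dt = cap;
    }
    if (!std::isfinite(a0) || a0 > 1e12)
      stop("propensity overflow (a0 = %g) at t = %g s", a0, t);

    // advance clock and the analytic PK pair
    pk_advance(net, u, dt, q_drip);
    t += dt;
    take_samples_until(t);
    if (net->i_blood >= 0) refresh_species(net->i_blood);

    if (fire) {
      double r = rng.unif() * a0, acc = 0.0;
      int chosen = nrx - 1;
      for (int i = 0; i < nrx; i++) {
        acc += a[i];
        if (r <= acc) { chosen = i; break; }
      }
      const Reaction &R = net->rx[chosen];
      for (size_t j = 0; j < R.re_idx.size(); j++) u[R.re_idx[j]] -= R.re_st[j];
      for (size_t j = 0; j < R.pr_idx.size(); j++) u[R.pr_idx[j]] += R.pr_st[j];
      for (size_t j = 0; j < R.re_idx.size(); j++) refresh_species(R.re_idx[j]);
      for (size_t j = 0; j < R.pr_idx.size(); j++) refresh_species(R.pr_idx[j]);
      check_commit();
      if (++steps_since_full >= 20000) {  // curb float drift in a0
        recompute_all();
        steps_since_full = 0;
      }
    } else if (ev < nev && t >= ev_time[ev] - 1e-9) {
      while (ev < nev && ev_time[ev] <= t + 1e-9) {
        int type = ev_type[ev];
        double mag = ev_mag[ev];
        if (type == 0 && net->i_dam >= 0) {           // irradiate
          double lam = mag * net->k_dsb;
          int add = deterministic_lesions ? (int)std::floor(lam + 0.5)
                                          : rng.poisson(lam);
          u[net->i_dam] += add;
          refresh_species(net->i_dam);
        } else if (type == 1 && net->i_depot >= 0) {  // oral dose to depot
          u[net->i_depot] += mag;
        } else if (type == 2) {                       // drip infusion on
          q_drip = mag / 24.0 / 3600.0;               // per-day -> per-second
        }
        ev++;
      }
      if (net->i_blood >= 0) refresh_species(net->i_blood);
    }
  }
  take_samples_until(horizon_s + 1);

  NumericVector final_state(nsp);
  for (int i = 0; i < nsp; i++) final_state[i] = real_amount(i);
  return List::create(
    _["committed"] = committed,
    _["commit_time_s"] = commit_time,
    _["final_state"] = final_state,
    _["samples"] = samples,
    _["end_time_s"] = t);
}
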