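// Passive branched-cable integrator with stochastic ribbon synapses and
// voltage-gated GABA event trains.  Backward Euler; the per-step linear
// tree system is solved in O(n) by Hines elimination (children eliminated
// into parents, compartments ordered parent-before-child).
//
// Units: mV, ms, nS, pA, pF.  I = g * (V - E) gives pA with g in nS.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: small, fast, deterministic across platforms; one independent
// stream per cell so that sub-circuits replay bit-exactly.
struct SmallRng {
  uint64_t state;
  explicit SmallRng(uint64_t seed) : state(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// binomial draw by CDF inversion; cheap because n <= pool_max (70) and the
// long-run mean released per step is bounded by the refill per step.
int rbinom_small(int n, double p, SmallRng &rng) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  bool flip = p > 0.5;
  double pp = flip ? 1.0 - p : p;
  double odds = pp / (1.0 - pp);
  double f = std::pow(1.0 - pp, n);
  double c = f;
  double u = rng.unif();
  int k = 0;
  while (u > c && k < n) {
    ++k;
    f *= odds * (double)(n - k + 1) / (double)k;
    c += f;
  }
  return flip ? n - k : k;
}

// as above, but with a per-synapse cache of (1 - p')^k: release probabilities
// only change when the driving intensity does, so the powers are reused
// across many consecutive steps.
int rbinom_cached(int n, double p, SmallRng &rng, double *qrow, int qmax,
                  double &cached_p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  bool flip = p > 0.5;
  double pp = flip ? 1.0 - p : p;
  if (p != cached_p) {
    qrow[0] = 1.0;
    for (int k = 1; k <= qmax; ++k) qrow[k] = qrow[k - 1] * (1.0 - pp);
    cached_p = p;
  }
  double odds = pp / (1.0 - pp);
  double f = qrow[n];
  double c = f;
  double u = rng.unif();
  int k = 0;
  while (u > c && k < n) {
    ++k;
    f *= odds * (double)(n - k + 1) / (double)k;
    c += f;
  }
  return flip ? n - k : k;
}

// peak-normalization constant for the double-exponential kernel
double kernel_norm(double tau_r, double tau_d) {
  double tp = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
  return 1.0 / (std::exp(-tp / tau_d) - std::exp(-tp / tau_r));
}

} // namespace

// Simulate a stochastic ribbon synapse alone and return its averaged
// peristimulus time histogram (vesicles per bin, averaged over reps).
// [[Rcpp::export]]
NumericVector ribbon_psth_cpp(double p, double r, double dt, double duration,
                              int reps, double bin_ms, double pool_max,
                              int seed, bool deterministic) {
  int n_steps = (int)std::lround(duration / dt);
  int n_bins = (int)std::ceil(duration / bin_ms);
  NumericVector psth(n_bins);
  SmallRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  int qmax = (int)pool_max;
  std::vector<double> qrow(qmax + 1, 0.0);
  double cached_p = -1.0;
  for (int rep = 0; rep < reps; ++rep) {
    double pool = pool_max;
    for (int s = 0; s < n_steps; ++s) {
      double released;
      if (deterministic) {
        released = pool * p;
      } else {
        released = rbinom_cached((int)std::floor(pool), p, rng, qrow.data(),
                                 qmax, cached_p);
      }
      pool -= released;
      pool += r * dt;
      if (pool > pool_max) pool = pool_max;
      int bin = (int)(s * dt / bin_ms);
      if (bin >= n_bins) bin = n_bins - 1;
      psth[bin] += released;
    }
  }
  for (int b = 0; b < n_bins; ++b) psth[b] /= reps;
  return psth;
}

// [[Rcpp::export]]
List simulate_circuit_cpp(List comp, List exc, List inh, List clampL,
                          List injL, IntegerVector rec, NumericMatrix stim,
                          double stim_dt, double dt, int n_steps,
                          bool deterministic) {
  // --- compartments -------------------------------------------------------
  IntegerVector parent = comp["parent"]; // 0-based, -1 for roots
  NumericVector c_pf = comp["c_pf"];
  NumericVector g_leak = comp["g_leak_ns"];
  NumericVector e_rest = comp["e_rest_mv"];
  NumericVector g_ax = comp["g_ax_ns"]; // to parent; 0 for roots
  int n = parent.size();
  for (int i = 0; i < n; ++i)
    if (parent[i] >= i) stop("compartments must be ordered parent-first");

  std::vector<std::vector<int>> children(n);
  std::vector<double> static_diag(n);
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0) children[parent[i]].push_back(i);
  for (int i = 0; i < n; ++i) {
    double d = c_pf[i] / dt + g_leak[i] + (parent[i] >= 0 ? g_ax[i] : 0.0);
    for (int ch : children[i]) d += g_ax[ch];
    static_diag[i] = d;
  }

  // --- excitatory (ribbon) synapses --------------------------------------
  IntegerVector es_comp = exc["comp"], es_row = exc["stim_row"],
                es_stream = exc["stream"];
  NumericVector es_pfac = exc["pfac"], es_refill = exc["refill"],
                es_w = exc["weight"], es_mult = exc["mult"];
  double es_tau_r = exc["tau_r"], es_tau_d = exc["tau_d"],
         es_erev = exc["e_rev"], pool_max = exc["pool_max"];
  IntegerVector stream_seed = exc["stream_seed"];
  int n_es = es_comp.size();
  double es_N = n_es ? kernel_norm(es_tau_r, es_tau_d) : 1.0;
  double es_da = std::exp(-dt / es_tau_r), es_db = std::exp(-dt / es_tau_d);
  std::vector<double> pool(n_es, pool_max), prevI(n_es, 0.0), eA(n_es, 0.0),
      eB(n_es, 0.0);
  int qmax = (int)pool_max;
  std::vector<double> qtab((size_t)n_es * (qmax + 1), 0.0);
  std::vector<double> qcache_p(n_es, -1.0);
  std::vector<SmallRng> streams;
  for (int s = 0; s < stream_seed.size(); ++s)
    streams.emplace_back((uint64_t)(uint32_t)stream_seed[s] * 2654435761ULL +
                         0xDA3E39CB94B95BDBULL);

  // --- inhibitory (GABA) synapses ----------------------------------------
  IntegerVector is_pre = inh["pre"], is_post = inh["post"];
  NumericVector is_w = inh["weight"], is_erev = inh["e_rev"];
  double is_tau_r = inh["tau_r"], is_tau_d = inh["tau_d"],
         is_thresh = inh["thresh"], is_period = inh["period_ms"];
  int n_is = is_pre.size();
  double is_N = n_is ? kernel_norm(is_tau_r, is_tau_d) : 1.0;
  double is_da = std::exp(-dt / is_tau_r), is_db = std::exp(-dt / is_tau_d);
  std::vector<double> iA(n_is, 0.0), iB(n_is, 0.0), timer(n_is, 0.0);
  std::vector<char> active(n_is, 0);

  // --- clamps / injections / recording ------------------------------------
  IntegerVector cl_comp = clampL["comp"];
  NumericVector cl_level = clampL["level"];
  int n_cl = cl_comp.size();
  std::vector<char> clamped(n, 0);
  std::vector<double> clamp_level(n, 0.0);
  for (int c = 0; c < n_cl; ++c) {
    clamped[cl_comp[c]] = 1;
    clamp_level[cl_comp[c]] = cl_level[c];
  }
  IntegerVector in_comp = injL["comp"];
  NumericVector in_amp = injL["amp_pa"], in_t0 = injL["t0"], in_t1 = injL["t1"];
  int n_in = in_comp.size();

  int n_rec = rec.size();
  NumericMatrix vout(n_rec, n_steps + 1);
  NumericMatrix iout(n_cl, n_steps + 1);
  NumericVector es_total(n_es);

  std::vector<double> V(n), gsum(n), gesum(n), diag(n), rhs(n), iinj(n);
  for (int i = 0; i < n; ++i)
    V[i] = clamped[i] ? clamp_level[i] : e_rest[i];
  for (int k = 0; k < n_rec; ++k) vout(k, 0) = V[rec[k]];

  int stim_cols = stim.ncol();

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    std::fill(iinj.begin(), iinj.end(), 0.0);

    // ribbon synapses: decay kernels, draw release, accumulate conductance
    if (n_es) {
      int sidx = (int)(t / stim_dt);
      if (sidx >= stim_cols) sidx = stim_cols - 1;
      const double *stim_col = &stim[0] + (size_t)sidx * stim.nrow();
      for (int sy = 0; sy < n_es; ++sy) {
        double I = stim_col[es_row[sy]];
        // idle dark synapse: pool is pinned at capacity (reset at the
        // light->dark transition, then refilled) and the kernel has decayed
        if (I <= 0.0 && prevI[sy] <= 0.0 && eB[sy] < 1e-14 &&
            pool[sy] >= pool_max)
          continue;
        eA[sy] *= es_da;
        eB[sy] *= es_db;
        if (prevI[sy] > 0.0 && I <= 0.0) pool[sy] = pool_max; // light -> dark
        prevI[sy] = I;
        if (I > 0.0) {
          double p = es_pfac[sy] * I;
          double released;
          if (deterministic)
            released = pool[sy] * (p > 1.0 ? 1.0 : p);
          else
            released = rbinom_cached((int)std::floor(pool[sy]),
                                     p > 1.0 ? 1.0 : p, streams[es_stream[sy]],
                                     &qtab[(size_t)sy * (qmax + 1)], qmax,
                                     qcache_p[sy]);
          if (released > 0.0) {
            pool[sy] -= released;
            double ev = released * es_mult[sy];
            eA[sy] += ev;
            eB[sy] += ev;
            es_total[sy] += released;
          }
        }
        pool[sy] += es_refill[sy] * dt;
        if (pool[sy] > pool_max) pool[sy] = pool_max;
        double g = es_w[sy] * es_N * (eB[sy] - eA[sy]);
        if (g != 0.0) {
          gsum[es_comp[sy]] += g;
          gesum[es_comp[sy]] += g * es_erev;
        }
      }
    }

    // GABA synapses: event train while presynaptic voltage is above
    // threshold; phase restarts at each suprathreshold crossing
    for (int sy = 0; sy < n_is; ++sy) {
      iA[sy] *= is_da;
      iB[sy] *= is_db;
      if (V[is_pre[sy]] > is_thresh) {
        if (!active[sy]) {
          active[sy] = 1;
          timer[sy] = 0.0;
          iA[sy] += 1.0;
          iB[sy] += 1.0;
        } else {
          timer[sy] += dt;
          while (timer[sy] >= is_period - 1e-9) {
            timer[sy] -= is_period;
            iA[sy] += 1.0;
            iB[sy] += 1.0;
          }
        }
      } else {
        active[sy] = 0;
      }
      double g = is_w[sy] * is_N * (iB[sy] - iA[sy]);
      if (g != 0.0) {
        gsum[is_post[sy]] += g;
        gesum[is_post[sy]] += g * is_erev[sy];
      }
    }

    for (int c = 0; c < n_in; ++c)
      if (t >= in_t0[c] && t < in_t1[c]) iinj[in_comp[c]] += in_amp[c];

    // assemble and solve the backward-Euler system
    for (int i = 0; i < n; ++i) {
      diag[i] = static_diag[i] + gsum[i];
      rhs[i] = c_pf[i] / dt * V[i] + g_leak[i] * e_rest[i] + gesum[i] +
               iinj[i];
    }
    for (int i = n - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      if (clamped[i]) {
        rhs[p] += g_ax[i] * clamp_level[i];
      } else {
        double f = g_ax[i] / diag[i];
        diag[p] -= f * g_ax[i];
        rhs[p] += f * rhs[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) {
        V[i] = clamp_level[i];
      } else if (parent[i] < 0) {
        V[i] = rhs[i] / diag[i];
      } else {
        V[i] = (rhs[i] + g_ax[i] * V[parent[i]]) / diag[i];
      }
      if (!std::isfinite(V[i]))
        stop("non-finite voltage at compartment %d, t = %.3f ms", i + 1, t);
    }

    for (int k = 0; k < n_rec; ++k) vout(k, step + 1) = V[rec[k]];
    for (int c = 0; c < n_cl; ++c) {
      int i = cl_comp[c];
      double I = g_leak[i] * (V[i] - e_rest[i]) + gsum[i] * V[i] - gesum[i] -
                 iinj[i];
      if (parent[i] >= 0) I += g_ax[i] * (V[i] - V[parent[i]]);
      for (int ch : children[i]) I += g_ax[ch] * (V[i] - V[ch]);
      iout(c, step + 1) = I;
    }
  }

  return List::create(_["v"] = vout, _["clamp_i"] = iout,
                      _["release_total"] = es_total);
}
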