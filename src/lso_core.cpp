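// Core simulation engine: counter-based RNG substreams, presynaptic spike
// generation (homogeneous and von Mises phase-locked Poisson), and
// exponential-Euler integration of the active/passive IF membrane with
// event-driven alpha-conductance synapses.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 keyed by (seed, a, b, c). Each (trial, fiber)
// gets its own substream so that generation is reproducible independent of
// execution order.
// ---------------------------------------------------------------------------

static inline uint64_t sm64_mix(uint64_t x) {
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

struct Substream {
  uint64_t state;
  Substream(uint64_t seed, uint64_t a, uint64_t b, uint64_t c) {
    uint64_t x = 0x9E3779B97F4A7C15ULL * (seed + 0x632BE59BD9B4E019ULL);
    x = sm64_mix(x + 0xA24BAED4963EE407ULL * (a + 1));
    x = sm64_mix(x + 0x9FB21C651E98DF25ULL * (b + 1));
    x = sm64_mix(x + 0xD6E8FEB86659FD93ULL * (c + 1));
    state = x;
  }
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    return sm64_mix(z);
  }
  // uniform on (0, 1]
  double unif_pos() {
    double u = (next_u64() >> 11) * (1.0 / 9007199254740992.0); // [0,1)
    return 1.0 - u;
  }
  // uniform on [0, 1)
  double unif() {
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
  double rexp(double rate_per_ms) {
    return -std::log(unif_pos()) / rate_per_ms;
  }
};

// ---------------------------------------------------------------------------
// Presynaptic spike generation
// ---------------------------------------------------------------------------

// Homogeneous Poisson train on [0, dur_ms), rate in spikes/s.
static std::vector<double> gen_hom(double rate_hz, double dur_ms, Substream& rng) {
  std::vector<double> out;
  if (rate_hz <= 0.0) return out;
  double r = rate_hz / 1000.0; // spikes per ms
  double t = rng.rexp(r);
  while (t < dur_ms) {
    out.push_back(t);
    t += rng.rexp(r);
  }
  return out;
}

// Phase-locked inhomogeneous Poisson by thinning. Intensity
//   lambda(t) = rate_hz * exp(kappa * cos(theta(t))) / I0(kappa),
// theta(t) = 2 pi f_m t / 1000 - phi (phi in radians). The envelope rate is
// lambda_max = rate_hz / (I0(kappa) exp(-kappa)) = rate_hz / i0_scaled.
static std::vector<double> gen_vm(double rate_hz, double kappa, double i0_scaled,
                                  double fm_hz, double phi_rad, double dur_ms,
                                  Substream& rng) {
  std::vector<double> out;
  if (rate_hz <= 0.0) return out;
  double lam_max = rate_hz / i0_scaled;
  double r = lam_max / 1000.0;
  double w = 2.0 * M_PI * fm_hz / 1000.0; // rad per ms
  double t = rng.rexp(r);
  while (t < dur_ms) {
    double u = rng.unif();
    if (u < std::exp(kappa * (std::cos(w * t - phi_rad) - 1.0)))
      out.push_back(t);
    t += rng.rexp(r);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hom_poisson(double rate_hz, double dur_ms,
                              double seed, double a, double b, double c) {
  Substream rng((uint64_t)seed, (uint64_t)a, (uint64_t)b, (uint64_t)c);
  std::vector<double> v = gen_hom(rate_hz, dur_ms, rng);
  return wrap(v);
}

// [[Rcpp::export]]
NumericVector cpp_vm_poisson(double rate_hz, double kappa, double i0_scaled,
                             double fm_hz, double phi_rad, double dur_ms,
                             double seed, double a, double b, double c) {
  Substream rng((uint64_t)seed, (uint64_t)a, (uint64_t)b, (uint64_t)c);
  std::vector<double> v = gen_vm(rate_hz, kappa, i0_scaled, fm_hz, phi_rad,
                                 dur_ms, rng);
  return wrap(v);
}

// ---------------------------------------------------------------------------
// Membrane integration
//
// Units: V [mV], t [ms], conductances [nS], C [pF], currents [pA]
// (nS * mV = pA; pA / pF = mV/ms). The spike-associated current of the
// active model is specified in nA and converted to pA by a factor 1000.
//
// Synaptic alpha kernels alpha(s) = A (s/tau) exp(1 - s/tau) are evaluated
// exactly at grid times via a two-state exponential update: with
//   u(t) = sum_i A e exp(-(t - t_i)/tau)
//   g(t) = sum_i A e ((t - t_i)/tau) exp(-(t - t_i)/tau)
// the no-event propagation over a step dt is
//   g <- (g + u dt / tau) exp(-dt/tau);  u <- u exp(-dt/tau)
// and a spike at time ts <= t adds its exactly-decayed contribution. This is
// algebraically identical to direct kernel summation at the grid times.
// ---------------------------------------------------------------------------

struct SynState {
  double u = 0.0, g = 0.0;
  double tau, amp_e; // amp_e = A * e
  double dec, dtau;  // dec = exp(-dt/tau), dtau = dt/tau
  void init(double A, double tau_, double dt) {
    tau = tau_;
    amp_e = A * M_E;
    dec = std::exp(-dt / tau);
    dtau = dt / tau;
  }
  void step() {
    g = (g + u * dtau) * dec;
    u = u * dec;
  }
  // incorporate spike at lag l (>= 0) before the current grid time
  void add_spike(double l) {
    double e = std::exp(-l / tau);
    u += amp_e * e;
    g += amp_e * (l / tau) * e;
  }
};

// Pool per-fiber spike lists into one sorted vector (all fibers of a pathway
// share A and tau, so superposition commutes with pooling).
static std::vector<double> pool_trains(const List& trains) {
  std::vector<double> all;
  for (int m = 0; m < trains.size(); ++m) {
    NumericVector tr = trains[m];
    for (int i = 0; i < tr.size(); ++i) all.push_back(tr[i]);
  }
  std::sort(all.begin(), all.end());
  return all;
}

struct SimResult {
  std::vector<double> spikes;
  std::vector<double> tr_t, tr_v, tr_gex, tr_ginh;
};

// Core integrator. model: 0 = active (KLVA + spike current, no reset),
// 1 = passive (reset/clamp at V0 during refractory period).
static SimResult integrate_if(int model,
                              const NumericVector& prm, // named neuron params
                              double A_ex, double tau_ex, double E_ex,
                              double A_inh, double tau_inh, double E_inh,
                              const std::vector<double>& ex_spk,
                              const std::vector<double>& inh_spk,
                              double dur_ms, double dt,
                              double g_const_ex, double g_const_inh,
                              int trace_every) {
  const double C = prm["C"], gL = prm["gL"], EL = prm["EL"];
  const double Vth = prm["Vth"], Tref = prm["Tref"];
  const double gKL = (model == 0) ? (double)prm["gKL"] : 0.0;
  const double EK = (model == 0) ? (double)prm["EK"] : 0.0;
  const double V0 = (model == 1) ? (double)prm["V0"] : 0.0;

  SynState ex, inh;
  ex.init(A_ex, tau_ex, dt);
  inh.init(A_inh, tau_inh, dt);

  // spike-associated current I_spike(s) = 24 exp(-s/0.15) - 12 exp(-s/0.30) [nA]
  const double spkA = 24.0, spkB = 12.0;
  const double decA = std::exp(-dt / 0.15), decB = std::exp(-dt / 0.30);
  double ia = 0.0, ib = 0.0;

  // KLVA steady state at rest determines initial d
  double V = (model == 0) ? EL : EL;
  double d = 0.0;
  if (model == 0) {
    double w = std::exp((V + 50.0) / 16.0);
    d = w * w / (w * w + 1.0); // alpha/(alpha+beta) = w^2/(w^2+1)
  }

  const long nstep = (long)std::llround(dur_ms / dt);
  SimResult res;
  double refr_until = -1e300;
  bool clamped = false;
  size_t iex = 0, iinh = 0;
  const double eps = 1e-9;

  for (long k = 0; k < nstep; ++k) {
    const double t0 = k * dt, t1 = (k + 1) * dt;

    // currents/conductances at start of step
    const double gex = ex.g + g_const_ex;
    const double ginh = inh.g + g_const_inh;

    if (trace_every > 0 && k % trace_every == 0) {
      res.tr_t.push_back(t0);
      res.tr_v.push_back(V);
      res.tr_gex.push_back(gex);
      res.tr_ginh.push_back(ginh);
    }

    if (model == 1 && clamped) {
      if (t1 >= refr_until - eps) clamped = false;
      V = V0;
    } else {
      double G, B;
      if (model == 0) {
        G = gL + gKL * d + gex + ginh;
        B = gL * EL + gKL * d * EK + gex * E_ex + ginh * E_inh +
            1000.0 * (ia - ib);
      } else {
        G = gL + gex + ginh;
        B = gL * EL + gex * E_ex + ginh * E_inh;
      }
      const double Vinf = B / G;
      const double Vold = V;
      V = Vinf + (V - Vinf) * std::exp(-G * dt / C);
      if (model == 0) {
        // KLVA activation: exponential Euler with rates at the step-start V
        const double w = std::exp((Vold + 50.0) / 16.0);
        const double ad = 0.5 * w, bd = 0.5 / w;
        const double dinf = ad / (ad + bd);
        d = dinf + (d - dinf) * std::exp(-dt * (ad + bd));
      }
    }

    if (!std::isfinite(V))
      stop("membrane potential diverged (non-finite V); reduce dt");

    // decay spike current, advance synapses, absorb spikes in (t0, t1]
    ia *= decA; ib *= decB;
    ex.step(); inh.step();
    while (iex < ex_spk.size() && ex_spk[iex] <= t1) {
      ex.add_spike(t1 - ex_spk[iex]); ++iex;
    }
    while (iinh < inh_spk.size() && inh_spk[iinh] <= t1) {
      inh.add_spike(t1 - inh_spk[iinh]); ++iinh;
    }

    // threshold test at end of step (suspended while refractory)
    if (t1 >= refr_until - eps && V >= Vth) {
      res.spikes.push_back(t1);
      refr_until = t1 + Tref;
      if (model == 0) { ia += spkA; ib += spkB; }
      else { V = V0; clamped = true; }
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_simulate(int model, NumericVector prm,
                  double A_ex, double tau_ex, double E_ex,
                  double A_inh, double tau_inh, double E_inh,
                  List ex_trains, List inh_trains,
                  double dur_ms, double dt,
                  double g_const_ex, double g_const_inh,
                  int trace_every) {
  std::vector<double> ex_spk = pool_trains(ex_trains);
  std::vector<double> inh_spk = pool_trains(inh_trains);
  SimResult r = integrate_if(model, prm, A_ex, tau_ex, E_ex,
                             A_inh, tau_inh, E_inh, ex_spk, inh_spk,
                             dur_ms, dt, g_const_ex, g_const_inh, trace_every);
  List out = List::create(_["spikeTimes"] = wrap(r.spikes));
  if (trace_every > 0) {
    out["trace"] = DataFrame::create(_["t"] = wrap(r.tr_t),
                                     _["V"] = wrap(r.tr_v),
                                     _["gEx"] = wrap(r.tr_gex),
                                     _["gInh"] = wrap(r.tr_ginh));
  }
  return out;
}

// Batch trial runner for one stimulus point: generates fiber trains from
// substreams keyed (seed, point, trial, fiber) and returns per-trial output
// spike counts. Excitatory fibers use fiber ids 1..M_ex, inhibitory fibers
// 1001..1000+M_inh, so pathways never share a stream.
//
// task 0: unmodulated (homogeneous at ex_rate / inh_rate)
// task 1: AM (von Mises at shared rate/kappa; phases phi_ex / phi_inh, rad)
// [[Rcpp::export]]
IntegerVector cpp_run_trials(int model, NumericVector prm,
                             double A_ex, double tau_ex, double E_ex,
                             double A_inh, double tau_inh, double E_inh,
                             int M_ex, int M_inh,
                             int task,
                             double ex_rate, double inh_rate,
                             double kappa, double i0_scaled, double fm_hz,
                             double phi_ex, double phi_inh,
                             int n_trials, double dur_ms, double dt,
                             double seed, double point_id) {
  IntegerVector counts(n_trials);
  for (int tr = 0; tr < n_trials; ++tr) {
    std::vector<double> ex_all, inh_all;
    for (int m = 1; m <= M_ex; ++m) {
      Substream rng((uint64_t)seed, (uint64_t)point_id, (uint64_t)(tr + 1),
                    (uint64_t)m);
      std::vector<double> v = (task == 0)
        ? gen_hom(ex_rate, dur_ms, rng)
        : gen_vm(ex_rate, kappa, i0_scaled, fm_hz, phi_ex, dur_ms, rng);
      ex_all.insert(ex_all.end(), v.begin(), v.end());
    }
    for (int m = 1; m <= M_inh; ++m) {
      Substream rng((uint64_t)seed, (uint64_t)point_id, (uint64_t)(tr + 1),
                    (uint64_t)(1000 + m));
      std::vector<double> v = (task == 0)
        ? gen_hom(inh_rate, dur_ms, rng)
        : gen_vm(inh_rate, kappa, i0_scaled, fm_hz, phi_inh, dur_ms, rng);
      inh_all.insert(inh_all.end(), v.begin(), v.end());
    }
    std::sort(ex_all.begin(), ex_all.end());
    std::sort(inh_all.begin(), inh_all.end());
    SimResult r = integrate_if(model, prm, A_ex, tau_ex, E_ex,
                               A_inh, tau_inh, E_inh, ex_all, inh_all,
                               dur_ms, dt, 0.0, 0.0, 0);
    counts[tr] = (int)r.spikes.size();
    if (tr % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
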