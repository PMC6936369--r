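#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- counter-based per-region noise streams ------------------------------
// Each region owns an independent splitmix64 stream seeded from the master
// seed and its own index, so adding or removing regions never reshuffles
// the noise of the others, and runs are bit-reproducible for a given seed.

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double stream_unif(uint64_t &state) {
  // uniform on (0, 1), 53-bit mantissa, never exactly 0
  return (static_cast<double>(splitmix64_next(state) >> 11) + 0.5) *
         (1.0 / 9007199254740992.0);
}

static inline double stream_normal(uint64_t &state) {
  // Box-Muller, cosine branch only (deterministic, branch-free)
  double u1 = stream_unif(state);
  double u2 = stream_unif(state);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static inline uint64_t mix64(uint64_t z) {
  // splitmix64 finalizer: full avalanche
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31; return z;
}

static inline uint64_t stream_seed(int master, int region) {
  // Scramble master and region through the finalizer so that related
  // master seeds (or region indices) never yield streams that are mere
  // time shifts of one another.
  uint64_t s = mix64(static_cast<uint64_t>(static_cast<uint32_t>(master)) +
                     0xD1B54A32D192ED03ULL);
  return mix64(s ^ ((static_cast<uint64_t>(region) + 1ULL) *
                    0x94D049BB133111EBULL));
}

// ---- reduced Wong-Wang pieces --------------------------------------------

// H(x) = (a x - b) / (1 - exp(-d (a x - b))), continuous at a x = b.
static inline double transfer_H(double x, double a, double b, double d) {
  double h = a * x - b;
  double dh = d * h;
  if (std::fabs(dh) < 1e-8)  // removable singularity: series expansion
    return 1.0 / d + h / 2.0 + d * h * h / 12.0;
  return h / (1.0 - std::exp(-dh));
}

// [[Rcpp::export(name = ".dmf_transfer_cpp")]]
NumericVector dmf_transfer_cpp(NumericVector x, double a, double b, double d) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = transfer_H(x[i], a, b, d);
  return out;
}

// Simulate the coupled reduced Wong-Wang network with Euler-Maruyama and
// (optionally) the Balloon-Windkessel transform in the same pass.
//
// Units: dt and noise_dt in ms, duration/transient/TR in s.  Noise is a
// Wiener kick of sd sigma*sqrt(noise_dt in s), applied at the start of each
// noise bucket, so refining dt leaves the driving noise path unchanged.
//
// The hemodynamic cascade is much slower (time constants ~1 s) than the
// neural step, so it is integrated on a coarser subgrid of `bw_every`
// neural steps (1 ms by default from R) with piecewise-constant neural
// input; this keeps the expensive pow() calls off the hot path.
//
// [[Rcpp::export(name = ".dmf_core_cpp")]]
List dmf_core_cpp(NumericMatrix W, List pars, List hpars,
                  double duration_s, double dt_ms, double transient_s,
                  double TR_s, int seed, NumericVector S0,
                  double noise_dt_ms, double store_neural_dt_ms,
                  bool compute_bold, int bw_every, NumericVector bias) {
  const int N = W.nrow();
  const double a = pars["a"], b = pars["b"], d = pars["d"];
  const double gamma_k = pars["gamma"];  // kinetic factor, 1/s scale
  const double tau_s = as<double>(pars["tau_s"]) / 1000.0;  // ms -> s
  const double J = pars["J_N"], w_loc = pars["w"], I0 = pars["I_0"];
  const double G = pars["G"], sigma = pars["sigma"];

  const double dt = dt_ms / 1000.0;  // s
  const long n_steps = static_cast<long>(std::llround(duration_s / dt));
  const int bucket = std::max(1, static_cast<int>(std::llround(noise_dt_ms / dt_ms)));
  const double kick_sd = sigma * std::sqrt(bucket * dt);

  // hemodynamics
  const double kappa = hpars["kappa"], gamma_h = hpars["gamma_h"];
  const double tau_h = hpars["tau"], alpha = hpars["alpha"];
  const double rho = hpars["rho"], V0 = hpars["V0"];
  const double k1 = hpars["k1"], k2 = hpars["k2"], k3 = hpars["k3"];
  const double ialpha = 1.0 / alpha;

  std::vector<uint64_t> rng(N);
  for (int i = 0; i < N; ++i) rng[i] = stream_seed(seed, i);

  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> hs(N, 0.0), hf(N, 1.0), hv(N, 1.0), hq(N, 1.0);
  std::vector<double> x(N), dS(N);
  const std::vector<double> Wv(W.begin(), W.end());  // column-major copy
  const double dt_bw = bw_every * dt;
  const double log1mrho = std::log(1.0 - rho);

  // output schedules
  int n_bold = 0;
  if (compute_bold)
    n_bold = static_cast<int>(std::floor((duration_s - transient_s) / TR_s + 1e-9));
  NumericMatrix bold(std::max(n_bold, 0), compute_bold ? N : 0);
  int next_bold = 0;

  long store_every = 0;
  long n_neural = 0, transient_steps = 0;
  if (store_neural_dt_ms > 0) {
    store_every = std::max(1L, static_cast<long>(std::llround(store_neural_dt_ms / dt_ms)));
    transient_steps = static_cast<long>(std::llround(transient_s / dt));
    n_neural = (n_steps - transient_steps) / store_every;
  }
  NumericMatrix neural(std::max(n_neural, 0L), store_neural_dt_ms > 0 ? N : 0);
  long next_neural = 0;

  for (long t = 0; t < n_steps; ++t) {
    if (t % bucket == 0) {
      for (int i = 0; i < N; ++i) {
        S[i] += kick_sd * stream_normal(rng[i]);
        if (S[i] < 0.0) S[i] = 0.0; else if (S[i] > 1.0) S[i] = 1.0;
      }
    }
    // network input: region i receives from sources j via W(j, i)
    const double *w_col = Wv.data();
    for (int i = 0; i < N; ++i, w_col += N) {
      double coup = 0.0;
      for (int j = 0; j < N; ++j) coup += w_col[j] * S[j];
      x[i] = w_loc * J * S[i] + G * J * coup + I0 + bias[i];
    }
    for (int i = 0; i < N; ++i) {
      double H = transfer_H(x[i], a, b, d);
      dS[i] = -S[i] / tau_s + (1.0 - S[i]) * gamma_k * H;
    }
    for (int i = 0; i < N; ++i) {
      S[i] += dS[i] * dt;
      if (S[i] < 0.0) S[i] = 0.0; else if (S[i] > 1.0) S[i] = 1.0;
    }
    if (compute_bold && (t + 1) % bw_every == 0) {
      for (int i = 0; i < N; ++i) {
        double f = hf[i], v = hv[i], q = hq[i], s = hs[i];
        double via = std::exp(ialpha * std::log(v));
        double E = 1.0 - std::exp(log1mrho / f);
        double ds_ = S[i] - kappa * s - gamma_h * (f - 1.0);
        double df_ = s;
        double dv_ = (f - via) / tau_h;
        double dq_ = (f * E / rho - q * via / v) / tau_h;
        hs[i] = s + dt_bw * ds_;
        hf[i] = f + dt_bw * df_;
        hv[i] = v + dt_bw * dv_;
        hq[i] = q + dt_bw * dq_;
        if (hf[i] < 1e-6) hf[i] = 1e-6;
        if (hv[i] < 1e-6) hv[i] = 1e-6;
        if (hq[i] < 1e-9) hq[i] = 1e-9;
      }
      double t_now = (t + 1) * dt;
      if (next_bold < n_bold &&
          t_now >= transient_s + (next_bold + 1) * TR_s - 1e-9) {
        for (int i = 0; i < N; ++i)
          bold(next_bold, i) = 100.0 * V0 *
            (k1 * (1.0 - hq[i]) + k2 * (1.0 - hq[i] / hv[i]) +
             k3 * (1.0 - hv[i]));
        ++next_bold;
      }
    }
    if (store_every > 0 && t >= transient_steps &&
        (t - transient_steps) % store_every == store_every - 1 &&
        next_neural < n_neural) {
      for (int i = 0; i < N; ++i) neural(next_neural, i) = S[i];
      ++next_neural;
    }
  }

  return List::create(_["bold"] = bold, _["neural"] = neural,
                      _["S_end"] = NumericVector(S.begin(), S.end()));
}

// Balloon-Windkessel transform of an existing neural trace, integrated at
// the neural sampling step with piecewise-constant input, sampled at TR.
// State (s, f, v, q) starts at the resting point (0, 1, 1, 1).
//
// [[Rcpp::export(name = ".bw_core_cpp")]]
NumericMatrix bw_core_cpp(NumericMatrix neural, double dt_ms, double TR_s,
                          List hpars) {
  const int N = neural.ncol();
  const long T = neural.nrow();
  const double dt = dt_ms / 1000.0;
  const double kappa = hpars["kappa"], gamma_h = hpars["gamma_h"];
  const double tau_h = hpars["tau"], alpha = hpars["alpha"];
  const double rho = hpars["rho"], V0 = hpars["V0"];
  const double k1 = hpars["k1"], k2 = hpars["k2"], k3 = hpars["k3"];
  const double ialpha = 1.0 / alpha;

  const int n_out = static_cast<int>(std::floor(T * dt / TR_s + 1e-9));
  NumericMatrix bold(n_out, N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int next_out = 0;
    // Heun (explicit trapezoid) steps with piecewise-constant input
    auto deriv = [&](double u, double s_, double f_, double v_, double q_,
                     double *out) {
      double via = std::pow(v_, ialpha);
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f_);
      out[0] = u - kappa * s_ - gamma_h * (f_ - 1.0);
      out[1] = s_;
      out[2] = (f_ - via) / tau_h;
      out[3] = (f_ * E / rho - q_ * via / v_) / tau_h;
    };
    for (long t = 0; t < T; ++t) {
      double u = neural(t, i);
      double d1[4], d2[4];
      deriv(u, s, f, v, q, d1);
      deriv(u, s + dt * d1[0], std::max(f + dt * d1[1], 1e-6),
            std::max(v + dt * d1[2], 1e-6), std::max(q + dt * d1[3], 1e-9),
            d2);
      s += dt * 0.5 * (d1[0] + d2[0]);
      f += dt * 0.5 * (d1[1] + d2[1]);
      v += dt * 0.5 * (d1[2] + d2[2]);
      q += dt * 0.5 * (d1[3] + d2[3]);
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (q < 1e-9) q = 1e-9;
      double t_now = (t + 1) * dt;
      if (next_out < n_out && t_now >= (next_out + 1) * TR_s - 1e-9) {
        bold(next_out, i) = 100.0 * V0 *
          (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        ++next_out;
      }
    }
  }
  return bold;
}
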