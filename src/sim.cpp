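#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <xmmintrin.h>
using namespace Rcpp;

// Flush denormal floats to zero while integrating. Synaptic state variables
// decay exponentially and underflow into the denormal range during quiet
// periods; denormal multiplies are microcoded and dominate the run time,
// while their physical contribution (< 1e-300 mV/ms) is zero.
struct FlushDenormals {
  unsigned int csr;
  FlushDenormals() : csr(_mm_getcsr()) { _mm_setcsr(csr | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(csr); }
};

// Wrapped (periodic, period 1) Gaussian density, truncated at +/- k_max shifts.
static inline double wgauss(double u, double sigma, int k_max) {
  const double a = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  const double s2 = 2.0 * sigma * sigma;
  double acc = 0.0;
  for (int k = -k_max; k <= k_max; ++k) {
    const double d = u + k;
    acc += std::exp(-d * d / s2);
  }
  return a * acc;
}

// [[Rcpp::export]]
NumericVector cpp_wrapped_gaussian(NumericVector u, double sigma, int k_max) {
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = wgauss(u[i], sigma, k_max);
  return out;
}

// Inlined exp with ~1e-12 relative accuracy on [-40, 25]: argument reduction
// by ln 2 plus a degree-9 Taylor polynomial. Much cheaper than the libm call
// inside the per-neuron hot loop, and deterministic across runs.
static inline double fast_exp(double x) {
  const double LOG2E = 1.4426950408889634074;
  const double LN2HI = 6.93147180369123816490e-01;
  const double LN2LO = 1.90821492927058770002e-10;
  double t = x * LOG2E;
  int ki = (int)(t + (t >= 0 ? 0.5 : -0.5));
  double k = (double)ki;
  double r = (x - k * LN2HI) - k * LN2LO;
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320 + r * (1.0 / 362880)))))))));
  uint64_t bits = (uint64_t)(ki + 1023) << 52; // 2^k without a libm call
  double scale; std::memcpy(&scale, &bits, 8);
  return p * scale;
}

// Sample one spatial projection between layers on the periodic unit square.
// pre positions are explicit; the postsynaptic layer is a cell-centered
// s_post x s_post lattice. Two schemes:
//   scheme = 0 ("outdegree"): each presynaptic neuron makes exactly
//     K = round(p_bar * n_post) contacts; target displacements are drawn from
//     an isotropic Gaussian of width sigma (wrapped), mapped to the enclosing
//     lattice cell. Repeated draws of the same target are kept as multiple
//     contacts (multi-synapses); self-contacts are redrawn.
//   scheme = 1 ("bernoulli"): every ordered pair is connected independently
//     with probability min(1, p_bar * g(dx) * g(dy)); no duplicates.
// self_idx[i] is the 0-based post index identified with pre neuron i
// (-1 if none). Returns CSR over presynaptic neurons.
// [[Rcpp::export]]
List cpp_sample_synapses(NumericVector pre_x, NumericVector pre_y, int s_post,
                         double sigma, double p_bar, double seed,
                         IntegerVector self_idx, int scheme, int k_max = 5) {
  const int n_pre = pre_x.size(), n_post = s_post * s_post;
  std::mt19937_64 gen((uint64_t)seed);
  const double inv53 = 1.0 / 9007199254740992.0; // 2^-53
  std::vector<int> idx;
  IntegerVector ptr(n_pre + 1);

  if (scheme == 0) {
    const int K = (int)std::lround(p_bar * n_post);
    idx.reserve((size_t)n_pre * K);
    std::normal_distribution<double> gauss(0.0, sigma);
    for (int i = 0; i < n_pre; ++i) {
      const int self = self_idx[i];
      for (int c = 0; c < K; ++c) {
        int tgt, tries = 0;
        do {
          double x = pre_x[i] + gauss(gen);
          double y = pre_y[i] + gauss(gen);
          x -= std::floor(x); y -= std::floor(y);
          int ix = (int)(x * s_post); if (ix >= s_post) ix = s_post - 1;
          int iy = (int)(y * s_post); if (iy >= s_post) iy = s_post - 1;
          tgt = iy * s_post + ix;
        } while (tgt == self && ++tries < 1000);
        idx.push_back(tgt);
      }
      ptr[i + 1] = (int)idx.size();
    }
  } else {
    idx.reserve((size_t)std::min<double>(
        1e8, p_bar * (double)n_pre * n_post * 1.3 + 1024));
    std::vector<double> gx(s_post), gy(s_post);
    for (int i = 0; i < n_pre; ++i) {
      for (int b = 0; b < s_post; ++b) {
        const double pb = (b + 0.5) / s_post;
        gx[b] = wgauss(pre_x[i] - pb, sigma, k_max);
        gy[b] = wgauss(pre_y[i] - pb, sigma, k_max);
      }
      const int self = self_idx[i];
      for (int j = 0; j < n_post; ++j) {
        if (j == self) continue;
        double p = p_bar * gx[j % s_post] * gy[j / s_post];
        if (p > 1.0) p = 1.0;
        const double u = (double)(gen() >> 11) * inv53;
        if (u < p) idx.push_back(j);
      }
      ptr[i + 1] = (int)idx.size();
    }
  }
  return List::create(_["ptr"] = ptr,
                      _["idx"] = IntegerVector(idx.begin(), idx.end()));
}

// One external (feedforward, excitatory-kernel) projection into the layer.
struct ExtProj {
  const int *ptr, *idx;
  const int *sp_step, *sp_pre; // spikes sorted by step
  R_xlen_t n_spk;
  double w_e, w_i;   // synaptic weight (already j / sqrt(N)) by target class
  R_xlen_t cursor;
};

// Forward-Euler integration of one recurrently coupled E/I layer of
// exponential integrate-and-fire neurons. Neurons 0..n_e-1 are excitatory,
// n_e..n_e+n_i-1 inhibitory. Synaptic drive uses the difference-of-
// exponentials kernel realized by two decaying state variables per
// (neuron, presynaptic class); a spike arriving at step s contributes
// eta(k * dt) to the drive at step s + k.
// [[Rcpp::export]]
List cpp_simulate_layer(int n_e, int n_i,
                        double dt, int n_steps,
                        NumericVector gl,       // (E, I)
                        NumericVector delta_t,  // (E, I)
                        IntegerVector tref_steps, // (E, I)
                        double v_l, double v_th, double v_reset, double v_t,
                        double tau_er, double tau_ed,
                        double tau_ir, double tau_id,
                        IntegerVector rec_ptr, IntegerVector rec_idx,
                        NumericVector rec_w,    // (E->E, E->I, I->E, I->I)
                        List ext_projs,
                        NumericVector v_init,
                        NumericVector i_ext,
                        IntegerVector record_idx,
                        double exp_cap = 20.0) {
  const int n = n_e + n_i;
  if (v_init.size() != n) stop("v_init length must equal layer size");
  if (tau_ed <= tau_er || tau_id <= tau_ir)
    stop("synaptic kernel degenerate: tau_decay must exceed tau_rise");
  FlushDenormals ftz_guard;

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> xed(n, 0.0), xer(n, 0.0), xid(n, 0.0), xir(n, 0.0);
  std::vector<double> drive(n, 0.0);
  std::vector<int> ref(n, 0);

  const double der = std::exp(-dt / tau_er), ded = std::exp(-dt / tau_ed);
  const double dir_ = std::exp(-dt / tau_ir), did = std::exp(-dt / tau_id);
  const double inv_e = 1.0 / (tau_ed - tau_er), inv_i = 1.0 / (tau_id - tau_ir);

  std::vector<double> iext(n);
  if (i_ext.size() == 1) std::fill(iext.begin(), iext.end(), i_ext[0]);
  else for (int j = 0; j < n; ++j) iext[j] = i_ext[j];

  std::vector<ExtProj> ext;
  for (R_xlen_t k = 0; k < ext_projs.size(); ++k) {
    List pr = ext_projs[k];
    IntegerVector ptr = pr["ptr"], idx = pr["idx"], st = pr["step"], pre = pr["pre"];
    ExtProj e;
    e.ptr = ptr.begin(); e.idx = idx.begin();
    e.sp_step = st.begin(); e.sp_pre = pre.begin(); e.n_spk = st.size();
    e.w_e = as<double>(pr["w_e"]); e.w_i = as<double>(pr["w_i"]);
    e.cursor = 0;
    ext.push_back(e);
  }

  const int *rp = rec_ptr.begin();
  const int *ri = rec_idx.begin();
  const double wEE = rec_w[0], wEI = rec_w[1], wIE = rec_w[2], wII = rec_w[3];

  std::vector<int> spike_step, spike_id, buf;
  spike_step.reserve(1 << 20); spike_id.reserve(1 << 20);

  const int n_rec = record_idx.size();
  NumericMatrix v_trace(n_rec > 0 ? n_steps : 0, n_rec);
  NumericMatrix i_trace(n_rec > 0 ? n_steps : 0, n_rec);

  bool bad = false;
  for (int t = 0; t < n_steps && !bad; ++t) {
    // deliver last step's recurrent spikes
    for (int s : buf) {
      const bool pre_e = (s < n_e);
      const double we = pre_e ? wEE : wIE, wi = pre_e ? wEI : wII;
      double *xd = pre_e ? xed.data() : xid.data();
      double *xr = pre_e ? xer.data() : xir.data();
      for (int q = rp[s]; q < rp[s + 1]; ++q) {
        const int tgt = ri[q];
        const double w = (tgt < n_e) ? we : wi;
        xd[tgt] += w; xr[tgt] += w;
      }
    }
    buf.clear();

    // deliver external spikes stamped at step t-1
    for (auto &e : ext) {
      while (e.cursor < e.n_spk && e.sp_step[e.cursor] < t - 1) ++e.cursor;
      while (e.cursor < e.n_spk && e.sp_step[e.cursor] == t - 1) {
        const int s = e.sp_pre[e.cursor++];
        for (int q = e.ptr[s]; q < e.ptr[s + 1]; ++q) {
          const int tgt = e.idx[q];
          const double w = (tgt < n_e) ? e.w_e : e.w_i;
          xed[tgt] += w; xer[tgt] += w;
        }
      }
    }

    // decay synaptic states and form the total drive (vectorizable loops)
    for (int j = 0; j < n; ++j) { xed[j] *= ded; xer[j] *= der; }
    for (int j = 0; j < n; ++j) { xid[j] *= did; xir[j] *= dir_; }
    for (int j = 0; j < n; ++j)
      drive[j] = (xed[j] - xer[j]) * inv_e + (xid[j] - xir[j]) * inv_i + iext[j];

    // voltage update per class
    for (int cls = 0; cls < 2; ++cls) {
      const int j0 = cls ? n_e : 0, j1 = cls ? n : n_e;
      const double g = gl[cls], dT = delta_t[cls];
      const int trf = tref_steps[cls];
      for (int j = j0; j < j1; ++j) {
        if (ref[j] > 0) { --ref[j]; v[j] = v_reset; continue; }
        double arg = (v[j] - v_t) / dT;
        if (arg > exp_cap) arg = exp_cap;
        const double ex = (arg < -12.0) ? 0.0 : fast_exp(arg);
        double vj = v[j] + dt * (-g * (v[j] - v_l) + g * dT * ex + drive[j]);
        if (vj >= v_th) {
          spike_step.push_back(t); spike_id.push_back(j);
          buf.push_back(j);
          vj = v_reset;
          ref[j] = trf;
        } else if (!(vj > -1e6 && vj < 1e6)) {
          bad = true;
        }
        v[j] = vj;
      }
    }
    if (bad)
      stop("voltage diverged or became non-finite at step %d", t);

    for (int r = 0; r < n_rec; ++r) {
      const int j = record_idx[r];
      v_trace(t, r) = v[j];
      i_trace(t, r) = drive[j] - iext[j];
    }
  }

  return List::create(
    _["step"] = IntegerVector(spike_step.begin(), spike_step.end()),
    _["id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["v_trace"] = v_trace, _["i_trace"] = i_trace,
    _["v_final"] = NumericVector(v.begin(), v.end()));
}
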