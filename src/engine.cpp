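// Exponential-Euler integrator for the excitatory/inhibitory cortical sheet.
//
// Internal unit system: mV, ms, mS/cm2, uF/cm2 (so g/C has units 1/ms).
// Hodgkin-Huxley gating rates use the classic squid-axon forms written in
// the "resting potential near -65 mV" convention; a configurable voltage
// shift `gate_shift` moves the operating point (rates are evaluated at
// V - gate_shift) so that the network's leak reversal of -70 mV is a true
// fixed point of the full membrane equation.
//
// Synaptic channels are difference-of-exponential kernels represented by two
// exponentially decaying state variables per (neuron, channel); a presynaptic
// spike increments both states by the peak-normalized weight, which is exact
// for this kernel family. Three channels per neuron: recurrent E, recurrent I,
// and feedforward (thalamocortical) E.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

// Classic squid-axon rate functions (1/ms) at membrane potential u (mV,
// -65 mV resting convention). Singularities handled by the analytic limit.
inline HHRates hh_rates_at(double u) {
  HHRates r;
  double x;

  x = u + 40.0;
  r.am = (std::fabs(x) < 1e-7) ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
  r.bm = 4.0 * std::exp(-(u + 65.0) / 18.0);

  r.ah = 0.07 * std::exp(-(u + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(u + 35.0) / 10.0));

  x = u + 55.0;
  r.an = (std::fabs(x) < 1e-7) ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
  r.bn = 0.125 * std::exp(-(u + 65.0) / 80.0);
  return r;
}

// Tabulated exponential-Euler gate update: x <- xinf + (x - xinf) * bfac.
// Tables are rebuilt per run (they depend on dt); linear interpolation in V.
struct GateTables {
  double vmin, dv_inv;
  int n;
  std::vector<double> minf, mfac, hinf, hfac, ninf, nfac;

  void build(double dt, double gate_shift) {
    vmin = -130.0;
    const double vmax = 80.0, dv = 0.02;
    dv_inv = 1.0 / dv;
    n = static_cast<int>((vmax - vmin) / dv) + 1;
    minf.resize(n); mfac.resize(n); hinf.resize(n); hfac.resize(n);
    ninf.resize(n); nfac.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * dv;
      HHRates r = hh_rates_at(v - gate_shift);
      double sm = r.am + r.bm, sh = r.ah + r.bh, sn = r.an + r.bn;
      minf[i] = r.am / sm; mfac[i] = std::exp(-dt * sm);
      hinf[i] = r.ah / sh; hfac[i] = std::exp(-dt * sh);
      ninf[i] = r.an / sn; nfac[i] = std::exp(-dt * sn);
    }
  }

  inline void lookup(double v, double &mi, double &mf, double &hi, double &hf,
                     double &ni, double &nf) const {
    double p = (v - vmin) * dv_inv;
    if (p < 0.0) p = 0.0;
    if (p > n - 1.001) p = n - 1.001;
    int i = static_cast<int>(p);
    double w = p - i;
    mi = minf[i] + w * (minf[i + 1] - minf[i]);
    mf = mfac[i] + w * (mfac[i + 1] - mfac[i]);
    hi = hinf[i] + w * (hinf[i + 1] - hinf[i]);
    hf = hfac[i] + w * (hfac[i + 1] - hfac[i]);
    ni = ninf[i] + w * (ninf[i + 1] - ninf[i]);
    nf = nfac[i] + w * (nfac[i + 1] - nfac[i]);
  }
};

// Peak value of exp(-t/td) - exp(-t/tr) (td > tr > 0), for peak-1 scaling.
inline double kernel_peak(double td, double tr) {
  double tstar = td * tr / (td - tr) * std::log(td / tr);
  return std::exp(-tstar / td) - std::exp(-tstar / tr);
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix hh_rates_cpp(NumericVector V, double gate_shift) {
  int n = V.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("am", "bm", "ah", "bh", "an", "bn");
  for (int i = 0; i < n; ++i) {
    HHRates r = hh_rates_at(V[i] - gate_shift);
    out(i, 0) = r.am; out(i, 1) = r.bm; out(i, 2) = r.ah;
    out(i, 3) = r.bh; out(i, 4) = r.an; out(i, 5) = r.bn;
  }
  return out;
}

// neuron parameter packing (R side keeps the user-facing units):
//  0 C (uF/cm2)  1 gL  2 VL  3 VNa  4 VK  5 VE  6 VI
//  7 GNa  8 GK (mS/cm2)  9 gate_shift (mV)  10 Vth (mV)  11 lockout (ms)

//' @noRd
// [[Rcpp::export]]
List sim_network_cpp(NumericMatrix W, IntegerVector is_inh,
                     NumericVector neuron, NumericVector tau_e,
                     NumericVector tau_i, NumericVector tau_f,
                     IntegerVector in_id, NumericVector in_t, double gmax_f,
                     double dt, double duration, IntegerVector record,
                     int record_every) {
  const int N = is_inh.size();
  if (W.nrow() != N || W.ncol() != N)
    stop("weight matrix dimensions do not match the population size");
  const double C = neuron[0], gL = neuron[1], VL = neuron[2], VNa = neuron[3],
               VK = neuron[4], VE = neuron[5], VI = neuron[6], GNa = neuron[7],
               GK = neuron[8], shift = neuron[9], Vth = neuron[10];
  const int lockout_steps = std::max(1, (int)std::ceil(neuron[11] / dt));
  const long nsteps = (long)std::ceil(duration / dt);

  GateTables tab;
  tab.build(dt, shift);

  // channel decay factors and peak normalizations
  const double fEd = std::exp(-dt / tau_e[0]), fEr = std::exp(-dt / tau_e[1]);
  const double fId = std::exp(-dt / tau_i[0]), fIr = std::exp(-dt / tau_i[1]);
  const double fFd = std::exp(-dt / tau_f[0]), fFr = std::exp(-dt / tau_f[1]);
  const double invPkE = 1.0 / kernel_peak(tau_e[0], tau_e[1]);
  const double invPkI = 1.0 / kernel_peak(tau_i[0], tau_i[1]);
  const double invPkF = 1.0 / kernel_peak(tau_f[0], tau_f[1]);

  // state, initialized at the leak-reversal steady state
  std::vector<double> V(N, VL), m(N), h(N), nn(N);
  {
    HHRates r = hh_rates_at(VL - shift);
    double m0 = r.am / (r.am + r.bm), h0 = r.ah / (r.ah + r.bh),
           n0 = r.an / (r.an + r.bn);
    std::fill(m.begin(), m.end(), m0);
    std::fill(h.begin(), h.end(), h0);
    std::fill(nn.begin(), nn.end(), n0);
  }
  std::vector<double> xEd(N, 0.0), xEr(N, 0.0), xId(N, 0.0), xIr(N, 0.0),
      xFd(N, 0.0), xFr(N, 0.0);
  std::vector<int> lock(N, 0);
  std::vector<int> fired;
  fired.reserve(256);

  std::vector<int> out_id;
  std::vector<double> out_t;
  out_id.reserve(1 << 16);
  out_t.reserve(1 << 16);

  const int nrec = record.size();
  long rec_rows = (nrec > 0) ? (nsteps / record_every + 1) : 0;
  NumericMatrix vtrace(rec_rows, nrec);
  NumericVector rec_time(rec_rows);
  long rec_row = 0;

  const double *Wp = REAL(W);
  double *pV = V.data(), *pm = m.data(), *ph = h.data(), *pn = nn.data();
  double *pEd = xEd.data(), *pEr = xEr.data(), *pId = xId.data(),
         *pIr = xIr.data(), *pFd = xFd.data(), *pFr = xFr.data();
  int *plock = lock.data();
  const int n_in = in_id.size();
  int ip = 0; // pointer into the time-sorted input spike list
  const double incF = gmax_f * invPkF;

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;

    // feedforward spikes arriving in [t, t+dt)
    while (ip < n_in && in_t[ip] < t + dt) {
      int tgt = in_id[ip];
      xFd[tgt] += incF;
      xFr[tgt] += incF;
      ++ip;
    }

    fired.clear();
    for (int i = 0; i < N; ++i) {
      // synaptic state decay (analytic)
      pEd[i] *= fEd; pEr[i] *= fEr;
      pId[i] *= fId; pIr[i] *= fIr;
      pFd[i] *= fFd; pFr[i] *= fFr;
      double gE = (pEd[i] - pEr[i]) + (pFd[i] - pFr[i]);
      double gI = pId[i] - pIr[i];

      double v = pV[i];
      double mi, mf, hi, hf, ni, nf;
      tab.lookup(v, mi, mf, hi, hf, ni, nf);
      double mv = pm[i] = mi + (pm[i] - mi) * mf;
      double hv = ph[i] = hi + (ph[i] - hi) * hf;
      double nv = pn[i] = ni + (pn[i] - ni) * nf;

      double m3h = mv * mv * mv * hv;
      double n4 = nv * nv;
      n4 *= n4;
      double gNa = GNa * m3h, gK = GK * n4;
      double gtot = gL + gNa + gK + gE + gI;
      double vinf =
          (gL * VL + gNa * VNa + gK * VK + gE * VE + gI * VI) / gtot;
      double vnew = vinf + (v - vinf) * std::exp(-dt * gtot / C);
      if (!std::isfinite(vnew))
        stop("non-finite membrane potential at t = %f ms, neuron %d", t,
             i + 1);
      pV[i] = vnew;

      if (plock[i] > 0) {
        --plock[i];
      } else if (v < Vth && vnew >= Vth) {
        fired.push_back(i);
        plock[i] = lockout_steps;
        out_id.push_back(i + 1);
        out_t.push_back(t + dt);
      }
    }

    // recurrent propagation: contiguous column access into W
    for (size_t s = 0; s < fired.size(); ++s) {
      int j = fired[s];
      const double *col = Wp + (size_t)j * N;
      if (is_inh[j]) {
        for (int i = 0; i < N; ++i) {
          double a = col[i];
          if (a != 0.0) {
            a *= invPkI;
            pId[i] += a;
            pIr[i] += a;
          }
        }
      } else {
        for (int i = 0; i < N; ++i) {
          double a = col[i];
          if (a != 0.0) {
            a *= invPkE;
            pEd[i] += a;
            pEr[i] += a;
          }
        }
      }
    }

    if (nrec > 0 && (k % record_every == 0)) {
      for (int r = 0; r < nrec; ++r) vtrace(rec_row, r) = V[record[r] - 1];
      rec_time[rec_row] = t + dt;
      ++rec_row;
    }
  }

  List out = List::create(
      _["id"] = wrap(out_id), _["time"] = wrap(out_t),
      _["voltage"] = vtrace, _["voltage_time"] = rec_time,
      _["n_recorded_rows"] = (double)rec_row);
  return out;
}

//' @noRd
// [[Rcpp::export]]
List sim_single_cpp(NumericVector neuron, NumericVector g_exc,
                    NumericVector g_inh, double dt) {
  const double C = neuron[0], gL = neuron[1], VL = neuron[2], VNa = neuron[3],
               VK = neuron[4], VE = neuron[5], VI = neuron[6], GNa = neuron[7],
               GK = neuron[8], shift = neuron[9], Vth = neuron[10];
  const int lockout_steps = std::max(1, (int)std::ceil(neuron[11] / dt));
  const long nsteps = g_exc.size();
  if (g_inh.size() != nsteps)
    stop("excitatory and inhibitory waveforms must have equal length");

  HHRates r0 = hh_rates_at(VL - shift);
  double m = r0.am / (r0.am + r0.bm), h = r0.ah / (r0.ah + r0.bh),
         n = r0.an / (r0.an + r0.bn);
  double V = VL;
  int lock = 0;

  NumericVector vtrace(nsteps);
  std::vector<double> spikes;

  for (long k = 0; k < nsteps; ++k) {
    HHRates r = hh_rates_at(V - shift);
    double sm = r.am + r.bm, sh = r.ah + r.bh, sn = r.an + r.bn;
    m = r.am / sm + (m - r.am / sm) * std::exp(-dt * sm);
    h = r.ah / sh + (h - r.ah / sh) * std::exp(-dt * sh);
    n = r.an / sn + (n - r.an / sn) * std::exp(-dt * sn);

    double gNa = GNa * m * m * m * h;
    double n2 = n * n;
    double gK = GK * n2 * n2;
    double gE = g_exc[k], gI = g_inh[k];
    double gtot = gL + gNa + gK + gE + gI;
    double vinf = (gL * VL + gNa * VNa + gK * VK + gE * VE + gI * VI) / gtot;
    double vnew = vinf + (V - vinf) * std::exp(-dt * gtot / C);
    if (!std::isfinite(vnew))
      stop("non-finite membrane potential at t = %f ms", k * dt);

    if (lock > 0) {
      --lock;
    } else if (V < Vth && vnew >= Vth) {
      spikes.push_back((k + 1) * dt);
      lock = lockout_steps;
    }
    V = vnew;
    vtrace[k] = V;
  }

  return List::create(_["voltage"] = vtrace, _["spike_times"] = wrap(spikes));
}
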