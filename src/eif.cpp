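#include <Rcpp.h>
using namespace Rcpp;

// Resonate exponential-integrate-and-fire integrator.
//
// State: membrane voltage v, K slow H-like feedback variables w_k (mV units,
// relaxing toward v - EL), and one spike-triggered adaptation current z (pA).
//
//   C dv/dt = -g (v-EL) - sum_k gs_k w_k - z + g dT exp((v-VT)/dT) + I(t)
//   tau_k(v) dw_k/dt = (v - EL) - w_k
//   tau_z dz/dt = -z
//
// tau_k(v) interpolates between tw_hyp (deep hyperpolarization) and tw_rest
// (near rest) through a sigmoid, mirroring the voltage dependence of H-current
// kinetics. When v crosses vcut a stereotyped spike waveform (absolute mV,
// sampled at dt) is written into the trace, after which integration resumes
// from vreset with z incremented by b_z.
//
// Forward Euler at dt; dt <= 0.05 ms is enforced on the R side.
// [[Rcpp::export]]
List eif_integrate_cpp(NumericVector I, double dt,
                       double EL, double g,
                       NumericVector gs, NumericVector tw_hyp,
                       NumericVector tw_rest,
                       double vhalf_tau, double k_tau,
                       double C, double deltaT, double VT,
                       double vcut, double vreset,
                       double tau_z, double b_z,
                       NumericVector spike_wave,
                       bool spiking, double ar2 = 0.0,
                       double w_cap = 1.0e300) {
  const int n = I.size();
  const int K = gs.size();
  const int wlen = spike_wave.size();
  NumericVector V(n);
  std::vector<double> w(K, 0.0);
  std::vector<int> spikes;
  double v = EL, z = 0.0;
  // cap the exponential drive so a missed cut cannot overflow
  const double exp_cap = (vcut - VT) / deltaT + 5.0;
  int i = 0;
  while (i < n) {
    double x = v - EL;
    double Ih = 0.0;
    for (int k = 0; k < K; ++k) Ih += gs[k] * w[k];
    double Isp = 0.0;
    if (spiking) {
      double a = (v - VT) / deltaT;
      if (a > exp_cap) a = exp_cap;
      Isp = g * deltaT * std::exp(a);
    }
    // optional quadratic (anomalous-rectification) conductance term
    double Iar = -ar2 * x * std::fabs(x);
    double dv = (-g * x - Ih - z + Isp + Iar + I[i]) / C * dt;
    double vn = v + dv;
    // H-like activation deactivates above rest: the drive saturates at w_cap
    double xw = (x > w_cap) ? w_cap : x;
    for (int k = 0; k < K; ++k) {
      double tau = tw_hyp[k];
      if (tw_rest[k] != tw_hyp[k])
        tau += (tw_rest[k] - tw_hyp[k]) / (1.0 + std::exp(-(v - vhalf_tau) / k_tau));
      w[k] += dt * (xw - w[k]) / tau;
    }
    if (tau_z > 0.0) z -= dt * z / tau_z;
    v = vn;
    if (spiking && v >= vcut && wlen > 0) {
      spikes.push_back(i);
      for (int j = 0; j < wlen && i < n; ++j, ++i) V[i] = spike_wave[j];
      v = vreset;
      z += b_z;
      // slow variables keep their values through the stereotyped spike
      continue;
    }
    V[i] = v;
    ++i;
  }
  return List::create(_["voltage"] = V,
                      _["spike_onsets"] = wrap(spikes));
}
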