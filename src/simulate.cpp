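#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment (soma + axon initial segment) conductance-based model.
//
// Units throughout: mV, ms, pA, nS, pF (nS * mV = pA; pF * mV/ms = pA).
//
// Soma:  C_s dV/dt = gL (EL - V) + gNa_s m^3 h (ENa - V) + gK n^4 (EK - V)
//                    + gSK s(c) (EK - V) + gH r (EH - V) + gax (Va - V) + I
// AIS:   C_a dV/dt = gNa_a m^3 h (ENa - Va) + gK_a n^4 (EK - Va) + gax (V - Va)
//
// All leak lives in the soma so the passive input resistance is exactly
// 1/gL (the AIS contributes no DC path to ground).  The AIS Na activation
// midpoint sits below the somatic one (na_halfact_shift < 0), so the AIS
// fires first and its axial current produces the initial (AIS) component of
// the somatic upstroke; somatic Na then generates the somatodendritic (SD)
// component.  SK gating uses a phenomenological calcium pool c incremented
// at each somatic spike and decaying exponentially; the SK conductance is
// gSK * c / (c + 1).  Integration is exponential Euler for voltages and
// gates at a fixed internal step (the sampling interval divided into
// `substeps`).

static inline double sigm(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

struct Kinetics {
  // activation midpoints (mV), slopes (mV), time constants (ms)
  double vm_na, km_na, tau_m;
  double vh_na, kh_na, tau_h;
  double vn_k, kn_k, tau_n;
  double vr_h, kr_h;            // HCN; tau supplied per cell
  double e_na, e_k, e_h;
};

static Kinetics default_kinetics() {
  Kinetics k;
  k.vm_na = -22.0; k.km_na = 6.0; k.tau_m = 0.05;
  k.vh_na = -30.0; k.kh_na = 6.0; k.tau_h = 1.0;
  k.vn_k  = -25.0; k.kn_k  = 7.0; k.tau_n = 1.0;
  k.vr_h  = -82.0; k.kr_h  = 9.0;
  k.e_na  = 55.0;  k.e_k   = -90.0; k.e_h = -30.0;
  return k;
}

// optional per-cell kinetic overrides under params$kinetics
static Kinetics kinetics_from(const List& params) {
  Kinetics k = default_kinetics();
  if (!params.containsElementNamed("kinetics")) return k;
  RObject ko = params["kinetics"];
  if (ko.isNULL()) return k;
  List kin(ko);
  auto get = [&](const char* nm, double& slot) {
    if (kin.containsElementNamed(nm)) slot = as<double>(kin[nm]);
  };
  get("vm_na", k.vm_na); get("km_na", k.km_na); get("tau_m", k.tau_m);
  get("vh_na", k.vh_na); get("kh_na", k.kh_na); get("tau_h", k.tau_h);
  get("vn_k", k.vn_k);   get("kn_k", k.kn_k);   get("tau_n", k.tau_n);
  get("vr_h", k.vr_h);   get("kr_h", k.kr_h);
  get("e_na", k.e_na);   get("e_k", k.e_k);     get("e_h", k.e_h);
  return k;
}

// Resting state: damped fixed-point iteration of the steady-state somatic
// voltage with all gates at their steady-state values (AIS rides at V).
static double resting_voltage(const List& p, const Kinetics& kin) {
  double gl  = p["leak_conductance"], el = p["leak_reversal"];
  double gna_s = p["gNa_soma"], gk = p["gK_dr"], gh = p["gH"];
  double v = el;
  for (int it = 0; it < 400; ++it) {
    double m = sigm(v, kin.vm_na, kin.km_na);
    double h = 1.0 - sigm(v, kin.vh_na, kin.kh_na);
    double n = sigm(v, kin.vn_k, kin.kn_k);
    double r = 1.0 - sigm(v, kin.vr_h, kin.kr_h);
    double gna = gna_s * m * m * m * h;
    double gkn = gk * n * n * n * n;
    double ghr = gh * r;
    double gt  = gl + gna + gkn + ghr;
    double vinf = (gl * el + gna * kin.e_na + gkn * kin.e_k + ghr * kin.e_h) / gt;
    v = 0.7 * v + 0.3 * vinf;
  }
  return v;
}

// [[Rcpp::export(name = ".sim_sweeps_cpp")]]
List sim_sweeps_cpp(List params, NumericVector amplitudes,
                    double onset_ms, double duration_ms,
                    double sampling_rate_hz, int n_samples,
                    int substeps, double spike_criterion_mv) {
  Kinetics kin = kinetics_from(params);
  double gl    = params["leak_conductance"];
  double el    = params["leak_reversal"];
  double cs    = params["capacitance_soma"];
  double ca    = params["capacitance_ais"];
  double gax   = params["axial_conductance"];
  double gna_a = params["gNa_ais"];
  double gna_s = params["gNa_soma"];
  double shift = params["na_halfact_shift"];
  double gk    = params["gK_dr"];
  double gsk   = params["gSK"];
  double cainc = params["ca_increment"];
  double catau = params["ca_tau"];
  double gh    = params["gH"];
  double htau  = params["h_tau"];
  double noise = params["noise_sd"];

  const double ais_k_frac = 0.15;   // AIS delayed-rectifier as fraction of gK_dr
  double gk_a = gk * ais_k_frac;

  double sample_dt = 1000.0 / sampling_rate_hz;       // ms
  double dt = sample_dt / substeps;
  int n_sweeps = amplitudes.size();

  NumericMatrix vout(n_samples, n_sweeps);
  List spike_times(n_sweeps);

  double v0 = resting_voltage(params, kin);

  // OU current noise: sd scaled so the passive voltage sd is ~noise (mV)
  double noise_tau = 5.0;                             // ms
  double sd_i = noise * gl;                           // pA
  double ou_a = std::exp(-dt / noise_tau);
  double ou_b = sd_i * std::sqrt(1.0 - ou_a * ou_a);

  double vm_ais = kin.vm_na + shift;

  for (int s = 0; s < n_sweeps; ++s) {
    double amp = amplitudes[s];
    double vs = v0, va = v0;
    double m_s = sigm(vs, kin.vm_na, kin.km_na);
    double h_s = 1.0 - sigm(vs, kin.vh_na, kin.kh_na);
    double m_a = sigm(va, vm_ais, kin.km_na);
    double h_a = 1.0 - sigm(va, kin.vh_na, kin.kh_na);
    double n_s = sigm(vs, kin.vn_k, kin.kn_k);
    double n_a = n_s;
    double r   = 1.0 - sigm(vs, kin.vr_h, kin.kr_h);
    double cpool = 0.0, iou = 0.0;
    bool above = vs >= spike_criterion_mv;
    std::vector<double> st;

    for (int i = 0; i < n_samples; ++i) {
      double t = i * sample_dt;
      for (int k = 0; k < substeps; ++k) {
        double tk = t + k * dt;
        double inj = (tk >= onset_ms && tk < onset_ms + duration_ms) ? amp : 0.0;
        if (noise > 0.0) iou = ou_a * iou + ou_b * R::norm_rand();

        // gate updates (exponential Euler, unconditionally stable)
        double em = std::exp(-dt / kin.tau_m);
        double eh = std::exp(-dt / kin.tau_h);
        // K deactivates quickly at hyperpolarized voltages (Kv3-like), so
        // the spike is narrow without a deep fast afterhyperpolarization
        double tn_s = kin.tau_n * (0.25 + 0.75 * sigm(vs, -30.0, 8.0));
        double tn_a = kin.tau_n * (0.25 + 0.75 * sigm(va, -30.0, 8.0));
        double en   = std::exp(-dt / tn_s);
        double en_a = std::exp(-dt / tn_a);
        double er = std::exp(-dt / htau);
        double minf_s = sigm(vs, kin.vm_na, kin.km_na);
        double hinf_s = 1.0 - sigm(vs, kin.vh_na, kin.kh_na);
        double minf_a = sigm(va, vm_ais, kin.km_na);
        double hinf_a = 1.0 - sigm(va, kin.vh_na, kin.kh_na);
        double ninf_s = sigm(vs, kin.vn_k, kin.kn_k);
        double ninf_a = sigm(va, kin.vn_k, kin.kn_k);
        double rinf   = 1.0 - sigm(vs, kin.vr_h, kin.kr_h);
        m_s = minf_s + (m_s - minf_s) * em;
        h_s = hinf_s + (h_s - hinf_s) * eh;
        m_a = minf_a + (m_a - minf_a) * em;
        h_a = hinf_a + (h_a - hinf_a) * eh;
        n_s = ninf_s + (n_s - ninf_s) * en;
        n_a = ninf_a + (n_a - ninf_a) * en_a;
        r   = rinf   + (r   - rinf)   * er;
        cpool *= std::exp(-dt / catau);

        // somatic compartment
        double gna = gna_s * m_s * m_s * m_s * h_s;
        double n4s = n_s * n_s * n_s * n_s;
        double gkn = gk * n4s;
        double gsk_eff = gsk * cpool / (cpool + 1.0);
        double ghr = gh * r;
        double gt_s = gl + gna + gkn + gsk_eff + ghr + gax;
        double vinf_s = (gl * el + gna * kin.e_na + gkn * kin.e_k +
                         gsk_eff * kin.e_k + ghr * kin.e_h + gax * va +
                         inj + iou) / gt_s;
        double vs_new = vinf_s + (vs - vinf_s) * std::exp(-dt * gt_s / cs);

        // AIS compartment
        double gna2 = gna_a * m_a * m_a * m_a * h_a;
        double n4a = n_a * n_a * n_a * n_a;
        double gkn2 = gk_a * n4a;
        double gt_a = gna2 + gkn2 + gax;
        double vinf_a = (gna2 * kin.e_na + gkn2 * kin.e_k + gax * vs) / gt_a;
        double va_new = vinf_a + (va - vinf_a) * std::exp(-dt * gt_a / ca);

        vs = vs_new; va = va_new;

        // somatic spike detector drives the SK calcium pool and the
        // ground-truth spike times (upward crossing of the criterion)
        if (!above && vs >= spike_criterion_mv) {
          above = true;
          cpool += cainc;
          st.push_back(tk + dt);
        } else if (above && vs < spike_criterion_mv) {
          above = false;
        }
      }
      if (!std::isfinite(vs) || !std::isfinite(va))
        stop("numerical instability: non-finite voltage in sweep %d (amplitude %.1f pA)",
             s + 1, amp);
      vout(i, s) = vs;
    }
    spike_times[s] = wrap(st);
  }

  return List::create(_["voltage"] = vout,
                      _["spike_times"] = spike_times,
                      _["resting_voltage"] = v0);
}
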