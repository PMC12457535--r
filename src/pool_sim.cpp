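// Reduced four-compartment motoneuron pool integrator.
//
// Chain: dendrite -- soma -- axon hillock -- initial segment.
// Hodgkin-Huxley-style channels; activation of fast Na is instantaneous,
// all other gates use exact exponential relaxation, and the voltage update
// is exponential Euler (conductances frozen over the step), which is
// unconditionally stable at the high Na densities of the spike initiation
// zone. A Strang-split gate update plus a predictor-corrector pass on the
// compartment coupling gives second-order accuracy, and steps are refined
// 16-fold while any excitable compartment is depolarized past -55 mV so
// the spike shape and the per-spike Ca influx (which sets the AHP charge
// and hence the firing phase) are integrated on a fine grid.
// Voltage-dependent gate factors come from lookup tables with linear
// interpolation; tables depend only on dt, not on channel parameters.
// Spikes are detected as upward 0-mV crossings of the initial segment with
// a 1-ms lockout; crossing times are linearly interpolated inside the step.
//
// Units: mV, ms, mS, uA, uF, uM, cm2. Injected currents arrive in nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double TAU_P = 4.0;      // persistent Na activation (ms)
const double TAU_MCAN = 4.0;   // N-type Ca activation (ms)
const double TAU_HCAN = 40.0;  // N-type Ca inactivation (ms)
const double TAU_ML = 40.0;    // L-type Ca activation (ms)
const int NSUB = 16;           // refinement factor inside spikes
const double V_REFINE = -55.0; // refinement trigger (mV)

struct Kin {
  static double minf(double v)   { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 7.8)); }
  static double hinf(double v)   { return 1.0 / (1.0 + std::exp((v + 55.0) / 7.0)); }
  static double tauh(double v)   { return 30.0 / (std::exp((v + 50.0) / 15.0) + std::exp(-(v + 50.0) / 16.0)); }
  static double ninf(double v, double half, double slope) {
    return 1.0 / (1.0 + std::exp(-(v - half) / slope));
  }
  static double taun(double v, double scale) {
    return scale * 7.0 / (std::exp((v + 40.0) / 40.0) + std::exp(-(v + 40.0) / 50.0));
  }
  static double pinf(double v)   { return 1.0 / (1.0 + std::exp(-(v + 48.0) / 4.0)); }
  static double mcaninf(double v, double half, double slope) {
    return 1.0 / (1.0 + std::exp(-(v - half) / slope));
  }
  static double hcaninf(double v){ return 1.0 / (1.0 + std::exp((v + 45.0) / 5.0)); }
  static double mlinf(double v)  { return 1.0 / (1.0 + std::exp(-(v + 40.0) / 7.0)); }
};

// Voltage-indexed tables for gate steady states and per-level decay factors.
struct Tables {
  static const int NV = 4601;
  static const int NX = 4001;
  double v0, dv, xmax, dx;
  std::vector<double> minf, hinf, ninf, pinf, mcaninf, hcaninf, mlinf;
  std::vector<double> eh[2], en[2];        // exp(-hdt/tau(V)) for h and n gates
  double ep[2], emcan[2], ehcan[2], eml[2]; // fixed-tau gate decay factors
  std::vector<double> expneg;               // exp(-x), x in [0, xmax]

  void build(double dt_macro, const struct Params& P);

  inline double lut(const std::vector<double>& T, double v) const {
    double x = (v - v0) / dv;
    if (x < 0.0) x = 0.0;
    if (x > NV - 2) x = NV - 2;
    int i = (int)x; double f = x - i;
    return T[i] * (1.0 - f) + T[i + 1] * f;
  }
  inline double ex(double x) const {  // exp(-x) for x >= 0
    if (x >= xmax) return 0.0;
    double y = x / dx; int i = (int)y; double f = y - i;
    return expneg[i] * (1.0 - f) + expneg[i + 1] * f;
  }
};

inline double getd(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing channel parameter '%s'", nm);
  return as<double>(p[nm]);
}

struct Params {
  double cm_d, gl_d, el_d, gcal_d, eca_d, gkca_d;
  double cm_s, gl_s, el_s, ek_s, ena_s, eca_s, gnaf_s, gkdr_s, gcan_s, gkca_s;
  double cm_h, gl_h, el_h, ek_h, ena_h, gkdr_h, gnap_h, gnaf_h;
  double cm_i, gl_i, el_i, ek_i, ena_i, gkdr_i, gnaf_i, gnap_i;
  double ad_ratio, ah_ratio, ai_ratio;   // areas relative to soma
  double gc_ds, gc_sh, gc_hi;            // coupling, mS per cm2 of soma area
  double alpha_ca;                       // uM cm2 / (uA ms)
  double tau_ca;                         // ms
  double kd_kca;                         // uM
  double ninf_half, ninf_slope, taun_scale;   // delayed-rectifier kinetics
  double mcan_half, mcan_slope;               // N-type Ca activation
  double soma_na_shift;                       // depolarizing shift of somatic Na (mV)
  void load(const List& p, const List& fx) {
    cm_d = getd(p, "dend.cm");  gl_d = getd(p, "dend.g_leak"); el_d = getd(p, "dend.e_leak");
    gcal_d = getd(p, "dend.g_cal"); eca_d = getd(p, "dend.e_ca"); gkca_d = getd(p, "dend.g_kca");
    cm_s = getd(p, "soma.cm");  gl_s = getd(p, "soma.g_leak"); el_s = getd(p, "soma.e_leak");
    ek_s = getd(p, "soma.e_k"); ena_s = getd(p, "soma.e_na");  eca_s = getd(p, "soma.e_ca");
    gnaf_s = getd(p, "soma.g_naf"); gkdr_s = getd(p, "soma.g_kdr");
    gcan_s = getd(p, "soma.g_can"); gkca_s = getd(p, "soma.g_kca");
    cm_h = getd(p, "hillock.cm"); gl_h = getd(p, "hillock.g_leak"); el_h = getd(p, "hillock.e_leak");
    ek_h = getd(p, "hillock.e_k"); ena_h = getd(p, "hillock.e_na");
    gkdr_h = getd(p, "hillock.g_kdr"); gnap_h = getd(p, "hillock.g_nap"); gnaf_h = getd(p, "hillock.g_naf");
    cm_i = getd(p, "initseg.cm"); gl_i = getd(p, "initseg.g_leak"); el_i = getd(p, "initseg.e_leak");
    ek_i = getd(p, "initseg.e_k"); ena_i = getd(p, "initseg.e_na");
    gkdr_i = getd(p, "initseg.g_kdr"); gnaf_i = getd(p, "initseg.g_naf"); gnap_i = getd(p, "initseg.g_nap");
    ad_ratio = getd(fx, "ad_ratio"); ah_ratio = getd(fx, "ah_ratio"); ai_ratio = getd(fx, "ai_ratio");
    gc_ds = getd(fx, "gc_ds"); gc_sh = getd(fx, "gc_sh"); gc_hi = getd(fx, "gc_hi");
    alpha_ca = getd(fx, "alpha_ca"); tau_ca = getd(fx, "tau_ca"); kd_kca = getd(fx, "kd_kca");
    ninf_half = getd(fx, "ninf_half"); ninf_slope = getd(fx, "ninf_slope");
    taun_scale = getd(fx, "taun_scale");
    mcan_half = getd(fx, "mcan_half"); mcan_slope = getd(fx, "mcan_slope");
    soma_na_shift = getd(fx, "soma_na_shift");
  }
};

void Tables::build(double dt_macro, const Params& P) {
  v0 = -150.0; dv = 0.05; xmax = 20.0; dx = xmax / (NX - 1);
  minf.resize(NV); hinf.resize(NV); ninf.resize(NV); pinf.resize(NV);
  mcaninf.resize(NV); hcaninf.resize(NV); mlinf.resize(NV);
  for (int l = 0; l < 2; ++l) { eh[l].resize(NV); en[l].resize(NV); }
  double hdt[2] = {0.5 * dt_macro, 0.5 * dt_macro / NSUB};
  for (int i = 0; i < NV; ++i) {
    double v = v0 + i * dv;
    minf[i] = Kin::minf(v); hinf[i] = Kin::hinf(v);
    ninf[i] = Kin::ninf(v, P.ninf_half, P.ninf_slope);
    pinf[i] = Kin::pinf(v);
    mcaninf[i] = Kin::mcaninf(v, P.mcan_half, P.mcan_slope);
    hcaninf[i] = Kin::hcaninf(v); mlinf[i] = Kin::mlinf(v);
    for (int l = 0; l < 2; ++l) {
      eh[l][i] = std::exp(-hdt[l] / Kin::tauh(v));
      en[l][i] = std::exp(-hdt[l] / Kin::taun(v, P.taun_scale));
    }
  }
  for (int l = 0; l < 2; ++l) {
    ep[l] = std::exp(-hdt[l] / TAU_P);
    emcan[l] = std::exp(-hdt[l] / TAU_MCAN);
    ehcan[l] = std::exp(-hdt[l] / TAU_HCAN);
    eml[l] = std::exp(-hdt[l] / TAU_ML);
  }
  expneg.resize(NX);
  for (int i = 0; i < NX; ++i) expneg[i] = std::exp(-i * dx);
}

struct Neuron {
  double a_s, a_d, a_h, a_i;
  double Gl_d, Gcal, Gkca_d, Cd;
  double Gl_s, Gnaf_s, Gkdr_s, Gcan, Gkca_s, Cs;
  double Gl_h, Gkdr_h, Gnap_h, Gnaf_h, Ch;
  double Gl_i, Gkdr_i, Gnaf_i, Gnap_i, Ci;
  double Gds, Gsh, Ghi;
  double vd, vs, vh, vi;
  double h_s, n_s, mcan, hcan, ca_s;
  double ml, ca_d;
  double h_h, n_h, p_h;
  double h_i, n_i, p_i;
  double last_spike;

  // exc scales every conductance density (specific excitability gradient:
  // larger cells have lower specific membrane resistance), not capacitance.
  void build(const Params& P, double diam_um, double exc) {
    a_s = M_PI * diam_um * diam_um * 1e-8;   // sphere surface, cm2
    a_d = P.ad_ratio * a_s; a_h = P.ah_ratio * a_s; a_i = P.ai_ratio * a_s;
    double fd = exc * a_d, fs = exc * a_s, fh = exc * a_h, fi = exc * a_i;
    Gl_d = P.gl_d * fd; Gcal = P.gcal_d * fd; Gkca_d = P.gkca_d * fd; Cd = P.cm_d * a_d;
    Gl_s = P.gl_s * fs; Gnaf_s = P.gnaf_s * fs; Gkdr_s = P.gkdr_s * fs;
    Gcan = P.gcan_s * fs; Gkca_s = P.gkca_s * fs; Cs = P.cm_s * a_s;
    Gl_h = P.gl_h * fh; Gkdr_h = P.gkdr_h * fh; Gnap_h = P.gnap_h * fh;
    Gnaf_h = P.gnaf_h * fh; Ch = P.cm_h * a_h;
    Gl_i = P.gl_i * fi; Gkdr_i = P.gkdr_i * fi; Gnaf_i = P.gnaf_i * fi;
    Gnap_i = P.gnap_i * fi; Ci = P.cm_i * a_i;
    Gds = P.gc_ds * fs; Gsh = P.gc_sh * fs; Ghi = P.gc_hi * fs;
  }

  void init(const Params& P) {
    vd = P.el_d; vs = P.el_s; vh = P.el_h; vi = P.el_i;
    h_s = Kin::hinf(vs - P.soma_na_shift);
    n_s = Kin::ninf(vs, P.ninf_half, P.ninf_slope);
    mcan = Kin::mcaninf(vs, P.mcan_half, P.mcan_slope);
    hcan = Kin::hcaninf(vs); ca_s = 0.0;
    ml = Kin::mlinf(vd); ca_d = 0.0;
    h_h = Kin::hinf(vh); n_h = Kin::ninf(vh, P.ninf_half, P.ninf_slope); p_h = Kin::pinf(vh);
    h_i = Kin::hinf(vi); n_i = Kin::ninf(vi, P.ninf_half, P.ninf_slope); p_i = Kin::pinf(vi);
    last_spike = -1e9;
  }

  // Exact exponential relaxation of all gates over a half step of level l.
  void relax_gates(const Params& P, const Tables& T, int l) {
    double e;
    double vss = vs - P.soma_na_shift;
    e = T.lut(T.eh[l], vss); h_s = T.lut(T.hinf, vss) + (h_s - T.lut(T.hinf, vss)) * e;
    e = T.lut(T.en[l], vs); n_s = T.lut(T.ninf, vs) + (n_s - T.lut(T.ninf, vs)) * e;
    mcan = T.lut(T.mcaninf, vs) + (mcan - T.lut(T.mcaninf, vs)) * T.emcan[l];
    hcan = T.lut(T.hcaninf, vs) + (hcan - T.lut(T.hcaninf, vs)) * T.ehcan[l];
    ml = T.lut(T.mlinf, vd) + (ml - T.lut(T.mlinf, vd)) * T.eml[l];
    e = T.lut(T.eh[l], vh); h_h = T.lut(T.hinf, vh) + (h_h - T.lut(T.hinf, vh)) * e;
    e = T.lut(T.en[l], vh); n_h = T.lut(T.ninf, vh) + (n_h - T.lut(T.ninf, vh)) * e;
    p_h = T.lut(T.pinf, vh) + (p_h - T.lut(T.pinf, vh)) * T.ep[l];
    e = T.lut(T.eh[l], vi); h_i = T.lut(T.hinf, vi) + (h_i - T.lut(T.hinf, vi)) * e;
    e = T.lut(T.en[l], vi); n_i = T.lut(T.ninf, vi) + (n_i - T.lut(T.ninf, vi)) * e;
    p_i = T.lut(T.pinf, vi) + (p_i - T.lut(T.pinf, vi)) * T.ep[l];
  }

  // Calcium influx source (uM/ms) at given voltages with current gates.
  void ca_sources(const Params& P, double wvs, double wvd,
                  double& src_s, double& src_d) const {
    double i_can = Gcan * mcan * mcan * hcan * (wvs - P.eca_s);
    double i_cal = Gcal * ml * (wvd - P.eca_d);
    src_s = -P.alpha_ca * i_can / a_s;
    src_d = -P.alpha_ca * i_cal / a_d;
    if (src_s < 0.0) src_s = 0.0;
    if (src_d < 0.0) src_d = 0.0;
  }

  // Exponential-Euler voltage update over dt, integrating from the stored
  // voltages. Instantaneous activations and the compartment coupling are
  // evaluated at the supplied voltages (old voltages on the predictor pass,
  // midpoint voltages on the corrector pass).
  void volt_update(const Params& P, const Tables& T, double dt, double i_inj,
                   double wd, double ws, double wh, double wi,
                   double& vd_new, double& vs_new, double& vh_new, double& vi_new) const {
    double fkca_d = ca_d / (ca_d + P.kd_kca);
    double g_d = Gl_d + Gcal * ml + Gkca_d * fkca_d + Gds;
    double e_d = Gl_d * P.el_d + Gcal * ml * P.eca_d + Gkca_d * fkca_d * P.ek_s + Gds * ws;

    double ms = T.lut(T.minf, ws - P.soma_na_shift); double ms3 = ms * ms * ms;
    double mc2 = mcan * mcan;
    double fkca_s = ca_s / (ca_s + P.kd_kca);
    double n4s = n_s * n_s * n_s * n_s;
    double g_s = Gl_s + Gnaf_s * ms3 * h_s + Gkdr_s * n4s +
                 Gcan * mc2 * hcan + Gkca_s * fkca_s + Gds + Gsh;
    double e_s = Gl_s * P.el_s + Gnaf_s * ms3 * h_s * P.ena_s + Gkdr_s * n4s * P.ek_s +
                 Gcan * mc2 * hcan * P.eca_s + Gkca_s * fkca_s * P.ek_s +
                 Gds * wd + Gsh * wh + i_inj;

    double mh = T.lut(T.minf, wh); double mh3 = mh * mh * mh;
    double n4h = n_h * n_h * n_h * n_h;
    double g_h = Gl_h + Gnaf_h * mh3 * h_h + Gkdr_h * n4h + Gnap_h * p_h + Gsh + Ghi;
    double e_h = Gl_h * P.el_h + Gnaf_h * mh3 * h_h * P.ena_h + Gkdr_h * n4h * P.ek_h +
                 Gnap_h * p_h * P.ena_h + Gsh * ws + Ghi * wi;

    double mi = T.lut(T.minf, wi); double mi3 = mi * mi * mi;
    double n4i = n_i * n_i * n_i * n_i;
    double g_i = Gl_i + Gnaf_i * mi3 * h_i + Gkdr_i * n4i + Gnap_i * p_i + Ghi;
    double e_i = Gl_i * P.el_i + Gnaf_i * mi3 * h_i * P.ena_i + Gkdr_i * n4i * P.ek_i +
                 Gnap_i * p_i * P.ena_i + Ghi * wh;

    vd_new = e_d / g_d + (vd - e_d / g_d) * T.ex(dt * g_d / Cd);
    vs_new = e_s / g_s + (vs - e_s / g_s) * T.ex(dt * g_s / Cs);
    vh_new = e_h / g_h + (vh - e_h / g_h) * T.ex(dt * g_h / Ch);
    vi_new = e_i / g_i + (vi - e_i / g_i) * T.ex(dt * g_i / Ci);
  }

  // One macro step with spike-resolving refinement.
  double step(const Params& P, const Tables& T, double dt, double t, double i_inj) {
    if (vs > V_REFINE || vh > V_REFINE || vi > V_REFINE) {
      double sub = dt / NSUB, spike = -1.0;
      for (int j = 0; j < NSUB; ++j) {
        double s = step_plain(P, T, 1, sub, t + j * sub, i_inj);
        if (s >= 0.0 && spike < 0.0) spike = j * sub + s;
      }
      return spike;
    }
    return step_plain(P, T, 0, dt, t, i_inj);
  }

  // Strang-split step at refinement level l: half gate relaxation,
  // predictor-corrector voltage update, trapezoidal calcium update, half
  // gate relaxation. i_inj in uA (into soma). Returns interpolated
  // spike-time offset in [0, dt) on an upward 0-mV crossing of the initial
  // segment outside the 1-ms lockout, else a negative value.
  double step_plain(const Params& P, const Tables& T, int l,
                    double dt, double t, double i_inj) {
    relax_gates(P, T, l);
    double pd, ps, ph, pi;
    volt_update(P, T, dt, i_inj, vd, vs, vh, vi, pd, ps, ph, pi);
    double vd_new, vs_new, vh_new, vi_new;
    volt_update(P, T, dt, i_inj, 0.5 * (vd + pd), 0.5 * (vs + ps),
                0.5 * (vh + ph), 0.5 * (vi + pi),
                vd_new, vs_new, vh_new, vi_new);
    double s0s, s0d, s1s, s1d;
    ca_sources(P, vs, vd, s0s, s0d);
    ca_sources(P, vs_new, vd_new, s1s, s1d);
    double ef = T.ex(dt / P.tau_ca);
    double ss = 0.5 * (s0s + s1s), sd = 0.5 * (s0d + s1d);
    ca_s = ss * P.tau_ca + (ca_s - ss * P.tau_ca) * ef;
    ca_d = sd * P.tau_ca + (ca_d - sd * P.tau_ca) * ef;
    double spike = -1.0;
    if (vi < 0.0 && vi_new >= 0.0 && (t - last_spike) > 1.0) {
      double frac = (0.0 - vi) / (vi_new - vi);
      spike = frac * dt;
      last_spike = t + spike;
    }
    vd = vd_new; vs = vs_new; vh = vh_new; vi = vi_new;
    relax_gates(P, T, l);
    return spike;
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_pool_cpp(List par, List fixed, NumericVector diam_um,
                  NumericVector exc_scale,
                  NumericVector drive, double drive_dt_ms, double gain_nA,
                  NumericMatrix noise_nA, double noise_dt_ms,
                  double dt_ms, double t_end_ms,
                  int record_neuron = 0, int record_thin = 40) {
  Params P; P.load(par, fixed);
  Tables T; T.build(dt_ms, P);
  int n = diam_um.size();
  if (exc_scale.size() != n)
    stop("exc_scale must have one entry per neuron");
  if (noise_nA.ncol() != 0 && noise_nA.ncol() != n)
    stop("noise matrix must have one column per neuron");
  std::vector<Neuron> pool(n);
  for (int i = 0; i < n; ++i) {
    pool[i].build(P, diam_um[i], exc_scale[i]);
    pool[i].init(P);
  }

  long n_steps = (long)std::ceil(t_end_ms / dt_ms);
  std::vector< std::vector<double> > spikes(n);
  bool rec = record_neuron >= 1 && record_neuron <= n;
  std::vector<double> rec_t, rec_vd, rec_vs, rec_vh, rec_vi, rec_ca;

  int nd = drive.size();
  bool has_noise = noise_nA.ncol() > 0;
  int nn = has_noise ? noise_nA.nrow() : 0;

  for (long k = 0; k < n_steps; ++k) {
    double t = k * dt_ms;
    double dr;
    if (nd == 1) dr = drive[0];
    else {
      double x = t / drive_dt_ms;
      int j = (int)x;
      if (j >= nd - 1) dr = drive[nd - 1];
      else { double f = x - j; dr = drive[j] * (1.0 - f) + drive[j + 1] * f; }
    }
    int jn = 0;
    if (has_noise) { jn = (int)(t / noise_dt_ms); if (jn >= nn) jn = nn - 1; }
    double base = gain_nA * dr;
    for (int i = 0; i < n; ++i) {
      double inj = base + (has_noise ? noise_nA(jn, i) : 0.0);
      double s = pool[i].step(P, T, dt_ms, t, inj * 1e-3);  // nA -> uA
      if (s >= 0.0) spikes[i].push_back((t + s) * 1e-3);    // ms -> s
      if (!std::isfinite(pool[i].vs) || std::fabs(pool[i].vs) > 200.0)
        stop("membrane potential diverged (neuron %d, t = %.3f ms)", i + 1, t);
    }
    if (rec && (k % record_thin == 0)) {
      Neuron& N = pool[record_neuron - 1];
      rec_t.push_back(t * 1e-3);
      rec_vd.push_back(N.vd); rec_vs.push_back(N.vs);
      rec_vh.push_back(N.vh); rec_vi.push_back(N.vi);
      rec_ca.push_back(N.ca_s);
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = wrap(spikes[i]);
  List out = List::create(_["spikes"] = sp, _["dt_ms"] = dt_ms);
  if (rec) {
    out["trace"] = DataFrame::create(_["t"] = rec_t, _["v_dend"] = rec_vd,
                                     _["v_soma"] = rec_vs, _["v_hillock"] = rec_vh,
                                     _["v_initseg"] = rec_vi, _["ca_soma"] = rec_ca);
  }
  return out;
}
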