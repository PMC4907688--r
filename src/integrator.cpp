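#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integrator for the single-compartment spiking-HEK model.
// All currents are capacitance-normalised (pA/pF == mV/ms), time in ms,
// voltage in mV, light in mW/cm^2.  Gating variables and the drug-blocked
// fraction are advanced with exponential-Euler updates; in free-running
// mode the voltage is advanced with an explicit Euler step.

namespace {

// parameter vector layout (see .pack_params() on the R side)
enum Par {
  P_G_NAV = 0, P_ACT_VH, P_ACT_SL, P_INACT_VH, P_INACT_SL,
  P_TAUM_BASE, P_TAUM_AMP, P_TAUM_VP, P_TAUM_W,
  P_TAUH_BASE, P_TAUH_AMP, P_TAUH_VP, P_TAUH_WL, P_TAUH_WR,
  P_E_NA,
  P_G_KIR, P_E_K, P_KIR_VH, P_KIR_SL,
  P_G_CHR, P_E_CHR, P_EPD50, P_TAU_ON, P_TAU_OFF, P_CHR_VH, P_CHR_SL,
  P_G_KV, P_KV_ACT_VH, P_KV_ACT_SL, P_KV_TAU_ACT,
  P_KV_INACT_VH, P_KV_INACT_SL, P_KV_TAU_F, P_KV_TAU_S, P_KV_FF,
  P_KV_TAU_DEACT,
  P_G_LEAK, P_E_LEAK,
  P_SCHEME, P_CONC, P_KON, P_KOFF, P_KD_REST, P_STATE_PREF,
  P_TONIC_TAU, P_TONIC_FAC,
  P_N
};

inline double boltz_up(double v, double vh, double sl) {
  return 1.0 / (1.0 + std::exp((vh - v) / sl));
}
inline double boltz_down(double v, double vh, double sl) {
  return 1.0 / (1.0 + std::exp((v - vh) / sl));
}
inline double bell(double v, double base, double amp, double vp, double w) {
  double z = (v - vp) / w;
  return base + amp * std::exp(-z * z);
}
// two-sided bell: different widths below/above the peak voltage
inline double bell2(double v, double base, double amp, double vp,
                    double wl, double wr) {
  double z = (v - vp) / (v < vp ? wl : wr);
  return base + amp * std::exp(-z * z);
}

struct Piecewise {
  const double *dur; const double *val; int n;
  double t_end; int idx;
  Piecewise(const NumericVector &d, const NumericVector &v)
      : dur(d.begin()), val(v.begin()), n(d.size()), idx(0) {
    t_end = (n > 0) ? dur[0] : 0.0;
  }
  // value at time t, assuming t is queried in nondecreasing order
  double at(double t) {
    while (idx < n - 1 && t >= t_end) { idx++; t_end += dur[idx]; }
    return (n > 0) ? val[idx] : 0.0;
  }
  double total() const {
    double s = 0.0; for (int i = 0; i < n; i++) s += dur[i]; return s;
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector light_dur, NumericVector light_val,
              NumericVector cmd_dur, NumericVector cmd_val,
              NumericVector par, bool vclamp,
              double dt, int record_every, double duration,
              NumericVector init) {
  if (par.size() != P_N) stop("parameter vector has wrong length");
  const double *p = par.begin();

  Piecewise light(light_dur, light_val);
  Piecewise cmd(cmd_dur, cmd_val);

  long nsteps = (long)std::ceil(duration / dt - 1e-9);
  long nrec = nsteps / record_every + 1;

  NumericVector t_out(nrec), v_out(nrec), jnav(nrec), jkir(nrec),
      jchr(nrec), jkv(nrec), jleak(nrec), b_out(nrec), l_out(nrec),
      m_out(nrec), h_out(nrec);

  // state
  double V = init[0], m = init[1], h = init[2], pc = init[3];
  double a = init[4], i_f = init[5], i_s = init[6], B = init[7];

  const int scheme = (int)p[P_SCHEME];
  const double kon_ms = p[P_KON] * p[P_CONC] / 1000.0;  // (uM s)^-1 * uM -> ms^-1
  const double koff_ms = p[P_KOFF] / 1000.0;
  const double ek = p[P_E_K];

  long irec = 0;
  double t = 0.0;
  for (long step = 0; step <= nsteps; step++) {
    double L = light.at(t);
    if (vclamp) V = cmd.at(t);

    // instantaneous gating targets
    double minf = boltz_up(V, p[P_ACT_VH], p[P_ACT_SL]);
    double hinf = boltz_down(V, p[P_INACT_VH], p[P_INACT_SL]);
    double f_inact = 1.0 - hinf;

    // currents at current state
    double chr_rect = boltz_down(V, p[P_CHR_VH], p[P_CHR_SL]);
    double kir_f = boltz_down(V - ek, p[P_KIR_VH], p[P_KIR_SL]);
    double J_nav = p[P_G_NAV] * m * m * m * h * (1.0 - B) * (V - p[P_E_NA]);
    double J_kir = p[P_G_KIR] * kir_f * (V - ek);
    double J_chr = p[P_G_CHR] * pc * chr_rect * (V - p[P_E_CHR]);
    double J_kv = p[P_G_KV] * a * a * a * a *
        (p[P_KV_FF] * i_f + (1.0 - p[P_KV_FF]) * i_s) * (V - ek);
    double J_leak = p[P_G_LEAK] * (V - p[P_E_LEAK]);

    if (step % record_every == 0 && irec < nrec) {
      t_out[irec] = t; v_out[irec] = V;
      jnav[irec] = J_nav; jkir[irec] = J_kir; jchr[irec] = J_chr;
      jkv[irec] = J_kv; jleak[irec] = J_leak;
      b_out[irec] = B; l_out[irec] = L;
      m_out[irec] = m; h_out[irec] = h;
      irec++;
    }
    if (step == nsteps) break;

    // gating updates (exponential Euler)
    double tau_m = bell(V, p[P_TAUM_BASE], p[P_TAUM_AMP], p[P_TAUM_VP], p[P_TAUM_W]);
    double tau_h = bell2(V, p[P_TAUH_BASE], p[P_TAUH_AMP], p[P_TAUH_VP], p[P_TAUH_WL], p[P_TAUH_WR]);
    m += (minf - m) * (1.0 - std::exp(-dt / tau_m));
    h += (hinf - h) * (1.0 - std::exp(-dt / tau_h));

    // two-state photocycle: opening rate scales with light, closing fixed,
    // so tau(L) = tau_off * EPD50 / (L + EPD50) and p_inf = L/(L + EPD50)
    double pinf = L / (L + p[P_EPD50]);
    double tau_p = p[P_TAU_OFF] * p[P_EPD50] / (L + p[P_EPD50]);
    pc += (pinf - pc) * (1.0 - std::exp(-dt / tau_p));

    if (p[P_G_KV] > 0.0) {
      double ainf = boltz_up(V, p[P_KV_ACT_VH], p[P_KV_ACT_SL]);
      double iinf = boltz_down(V, p[P_KV_INACT_VH], p[P_KV_INACT_SL]);
      double tau_a = (ainf > a) ? p[P_KV_TAU_ACT] : p[P_KV_TAU_DEACT];
      a += (ainf - a) * (1.0 - std::exp(-dt / tau_a));
      i_f += (iinf - i_f) * (1.0 - std::exp(-dt / p[P_KV_TAU_F]));
      i_s += (iinf - i_s) * (1.0 - std::exp(-dt / p[P_KV_TAU_S]));
    }

    // drug block
    if (scheme == 2) {            // state-dependent (guarded receptor)
      double f_bind = p[P_STATE_PREF] * f_inact + (1.0 - p[P_STATE_PREF]);
      double alpha = kon_ms * f_bind, beta = koff_ms;
      double rate = alpha + beta;
      if (rate > 0.0) {
        double binf = alpha / rate;
        B += (binf - B) * (1.0 - std::exp(-dt * rate));
      }
    } else if (scheme == 1) {     // tonic: slow relaxation to equilibrium
      double kd_eff = p[P_KD_REST] /
          (1.0 + (p[P_TONIC_FAC] - 1.0) * f_inact);
      double binf = p[P_CONC] / (p[P_CONC] + kd_eff);
      B += (binf - B) * (1.0 - std::exp(-dt / p[P_TONIC_TAU]));
    }
    if (B < 0.0) B = 0.0; if (B > 1.0) B = 1.0;

    // membrane equation: explicit midpoint (RK2) step at frozen gates
    if (!vclamp) {
      double k1 = -(J_nav + J_kir + J_chr + J_kv + J_leak);
      double Vm = V + 0.5 * dt * k1;
      double k2 = -(p[P_G_NAV] * m * m * m * h * (1.0 - B) * (Vm - p[P_E_NA]) +
                    p[P_G_KIR] * boltz_down(Vm - ek, p[P_KIR_VH], p[P_KIR_SL]) * (Vm - ek) +
                    p[P_G_CHR] * pc * boltz_down(Vm, p[P_CHR_VH], p[P_CHR_SL]) * (Vm - p[P_E_CHR]) +
                    p[P_G_KV] * a * a * a * a *
                      (p[P_KV_FF] * i_f + (1.0 - p[P_KV_FF]) * i_s) * (Vm - ek) +
                    p[P_G_LEAK] * (Vm - p[P_E_LEAK]));
      V += dt * k2;
      if (!R_finite(V))
        stop("integration diverged at t = %f ms", t);
    }
    t += dt;
  }

  return List::create(
      _["t"] = t_out, _["V"] = v_out,
      _["J_nav"] = jnav, _["J_kir"] = jkir, _["J_chr"] = jchr,
      _["J_kv43"] = jkv, _["J_leak"] = jleak,
      _["B"] = b_out, _["light"] = l_out,
      _["m"] = m_out, _["h"] = h_out);
}
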