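#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rate-based microcircuit integrators.  All schedule randomness lives in R;
// these loops are deterministic given their inputs.  Rates use a saturating
// rectified-linear transfer (cap xmax) for SST/UPE/R and a saturating
// rectified-quadratic transfer (cap xmax^2) for PV.

static inline double phi_lin(double x, double xmax) {
  if (x <= 0.0) return 0.0;
  if (x >= xmax) return xmax;
  return x;
}

static inline double phi_quad(double x, double xmax) {
  if (x <= 0.0) return 0.0;
  if (x >= xmax) return xmax * xmax;
  return x * x;
}

// |_x_|+ ^ k
static inline double pospow(double x, double k) {
  if (x <= 0.0) return 0.0;
  return std::pow(x, k);
}

static inline void check_finite(double x, const char *pop, int t) {
  if (!std::isfinite(x)) {
    stop("non-finite rate in population '%s' at timestep %d", pop, t + 1);
  }
}

// Feedforward prediction-error circuit (positive or negative variant).
//
// Positive (SST+ learns the mean, PV+ the variance, UPE+ the error):
//   tauI dSST/dt = -SST + phi((1-b) wSST,a a + b s)
//   tauI dPV/dt  = -PV  + phiPV((1-b) wPV,a a + b (ws s - ws SST))
//   tauE dUPE/dt = -UPE + phi( |_s - SST_|+^k / (I0 + wdiv PV) )
// Negative (SST- carries the stimulus, the mean prediction r_pred is a
// clamped input):
//   tauI dSST/dt = -SST + phi(wSST,s s)
//   tauI dPV/dt  = -PV  + phiPV((1-b) wPV,a a + b (ws r_pred - ws SST))
//   tauE dUPE/dt = -UPE + phi( |_r_pred - SST_|+^k / (I0 + wdiv PV) )
//
// The beta-nudged teaching drives are part of the learning machinery:
// they are applied only on learning timesteps.  On probe timesteps
// (stimulus on, learn off) the interneurons fire from the cue alone, so
// the PV rate reads out the learned variance; on cue-only timesteps
// (stimulus off) the dendritic comparison is silenced as well.
// Plasticity (when learn true):
//   d wSST,a = eta_sst (rSST - phi(wSST,a a)) a        (positive only)
//   d wPV,a  = eta_pv  (rPV  - phiPV(wPV,a a)) a
// [[Rcpp::export]]
List cpp_sim_ff(IntegerVector ctx, NumericVector a, NumericVector s,
                LogicalVector stim_on, LogicalVector learn,
                bool negative, NumericVector r_pred, List par,
                NumericVector w_sst_a, NumericVector w_pv_a,
                NumericVector r0, int thin) {
  const int n = ctx.size();
  const double dt = par["dt"], tau_e = par["tau_e"], tau_i = par["tau_i"];
  const double beta = par["beta"], ws = par["ws"], k = par["k"];
  const double I0 = par["I0"], xmax = par["xmax"], w_div = par["w_div"];
  const double eta_sst = par["eta_sst"], eta_pv = par["eta_pv"];
  const bool clip_w = par["clip_w"];
  const double rmax_q = xmax * xmax;

  NumericVector wsa = clone(w_sst_a), wpa = clone(w_pv_a);
  double rSST = r0[0], rPV = r0[1], rUPE = r0[2];

  const int nrec = (thin > 0) ? n / thin : 0;
  NumericMatrix rates(nrec, 3);
  NumericMatrix wts(nrec, 2);
  IntegerVector tout(nrec);

  int irec = 0;
  for (int t = 0; t < n; ++t) {
    const int c = ctx[t] - 1;  // -1 when no context active
    const double at = a[t];
    const bool on = stim_on[t];
    const double wsa_c = (c >= 0) ? wsa[c] : 0.0;
    const double wpa_c = (c >= 0) ? wpa[c] : 0.0;

    const bool nud = on && learn[t];  // teaching drives only while learning
    double sst_in, pv_in, dend;
    if (negative) {
      sst_in = on ? s[t] : 0.0;  // wSST-,s = 1
      pv_in = nud ? (1.0 - beta) * wpa_c * at +
                        beta * (ws * r_pred[t] - ws * rSST)
                  : wpa_c * at;
      dend = on ? pospow(r_pred[t] - rSST, k) : 0.0;
    } else {
      sst_in = nud ? (1.0 - beta) * wsa_c * at + beta * s[t] : wsa_c * at;
      pv_in = nud ? (1.0 - beta) * wpa_c * at + beta * (ws * s[t] - ws * rSST)
                  : wpa_c * at;
      dend = on ? pospow(s[t] - rSST, k) : 0.0;
    }
    const double upe_in = dend / (I0 + w_div * rPV);

    rSST += dt / tau_i * (-rSST + phi_lin(sst_in, xmax));
    rPV += dt / tau_i * (-rPV + phi_quad(pv_in, xmax));
    rUPE += dt / tau_e * (-rUPE + phi_lin(upe_in, xmax));
    if (rSST < 0) rSST = 0; if (rSST > xmax) rSST = xmax;
    if (rPV < 0) rPV = 0; if (rPV > rmax_q) rPV = rmax_q;
    if (rUPE < 0) rUPE = 0; if (rUPE > xmax) rUPE = xmax;
    check_finite(rSST, negative ? "SST-" : "SST+", t);
    check_finite(rPV, negative ? "PV-" : "PV+", t);
    check_finite(rUPE, negative ? "UPE-" : "UPE+", t);

    if (learn[t] && c >= 0) {
      if (!negative)
        wsa[c] += eta_sst * (rSST - phi_lin(wsa[c] * at, xmax)) * at;
      wpa[c] += eta_pv * (rPV - phi_quad(wpa[c] * at, xmax)) * at;
      if (clip_w) {
        if (wsa[c] < 0) wsa[c] = 0;
        if (wpa[c] < 0) wpa[c] = 0;
      }
    }

    if (thin > 0 && (t + 1) % thin == 0) {
      rates(irec, 0) = rSST; rates(irec, 1) = rPV; rates(irec, 2) = rUPE;
      wts(irec, 0) = (c >= 0) ? wsa[c] : NA_REAL;
      wts(irec, 1) = (c >= 0) ? wpa[c] : NA_REAL;
      tout[irec] = t + 1;
      ++irec;
    }
  }

  return List::create(_["t"] = tout, _["rates"] = rates, _["weights"] = wts,
                      _["r_final"] = NumericVector::create(rSST, rPV, rUPE),
                      _["w_sst_a"] = wsa, _["w_pv_a"] = wpa);
}

// Recurrent circuit with representation neuron R (both PE subcircuits):
//   tauI dSST+/dt = -SST+ + phi(wSST+,R R)
//   tauI dPV+/dt  = -PV+  + phiPV((1-b) wPV+,a a + b (ws s - ws SST+))
//   tauE dUPE+/dt = -UPE+ + phi( |_s - SST+_|+^k / (I0 + wdiv PV+) )
//   tauI dSST-/dt = -SST- + phi(wSST-,s s)
//   tauI dPV-/dt  = -PV-  + phiPV((1-b) wPV-,a a + b (ws R - ws SST-))
//   tauE dUPE-/dt = -UPE- + phi( |_R - SST-_|+^k / (I0 + wdiv PV-) )
//   tauE dR/dt    = -R    + phi(wR,a a + wR,UPE (UPE+ - UPE-))
// With fixed_gain, the divisive denominators are replaced by the constant
// 1/gain (the unmodulated control of the learning-rate comparison).
// [[Rcpp::export]]
List cpp_sim_recurrent(IntegerVector ctx, NumericVector a, NumericVector s,
                       LogicalVector stim_on, LogicalVector learn, List par,
                       NumericVector w_r_a, NumericVector w_pv_p_a,
                       NumericVector w_pv_m_a, NumericVector r0, int thin,
                       bool fixed_gain, double gain, bool clamp_r,
                       double r_clamp) {
  const int n = ctx.size();
  const double dt = par["dt"], tau_e = par["tau_e"], tau_i = par["tau_i"];
  const double beta = par["beta"], ws = par["ws"], k = par["k"];
  const double I0 = par["I0"], xmax = par["xmax"], w_div = par["w_div"];
  const double eta_pv = par["eta_pv"], eta_r = par["eta_r"];
  const double w_r_upe = par["w_r_upe"];
  const bool clip_w = par["clip_w"];
  const double rmax_q = xmax * xmax;

  NumericVector wra = clone(w_r_a), wpp = clone(w_pv_p_a),
                wpm = clone(w_pv_m_a);
  double rSSTp = r0[0], rPVp = r0[1], rUPEp = r0[2], rSSTm = r0[3],
         rPVm = r0[4], rUPEm = r0[5], rR = clamp_r ? r_clamp : r0[6];

  const int nrec = (thin > 0) ? n / thin : 0;
  NumericMatrix rates(nrec, 7);
  NumericMatrix wts(nrec, 3);
  IntegerVector tout(nrec);

  int irec = 0;
  for (int t = 0; t < n; ++t) {
    const int c = ctx[t] - 1;
    const double at = a[t];
    const bool on = stim_on[t];
    const double wra_c = (c >= 0) ? wra[c] : 0.0;
    const double wpp_c = (c >= 0) ? wpp[c] : 0.0;
    const double wpm_c = (c >= 0) ? wpm[c] : 0.0;

    const bool nud = on && learn[t];  // teaching drives only while learning
    const double sstp_in = rR;  // wSST+,R = 1
    const double pvp_in =
        nud ? (1.0 - beta) * wpp_c * at + beta * (ws * s[t] - ws * rSSTp)
            : wpp_c * at;
    const double dend_p = on ? pospow(s[t] - rSSTp, k) : 0.0;
    const double sstm_in = on ? s[t] : 0.0;  // wSST-,s = 1
    const double pvm_in =
        nud ? (1.0 - beta) * wpm_c * at + beta * (ws * rR - ws * rSSTm)
            : wpm_c * at;
    const double dend_m = on ? pospow(rR - rSSTm, k) : 0.0;
    const double div_p = fixed_gain ? 1.0 / gain : I0 + w_div * rPVp;
    const double div_m = fixed_gain ? 1.0 / gain : I0 + w_div * rPVm;
    const double r_in = wra_c * at + w_r_upe * (rUPEp - rUPEm);

    rSSTp += dt / tau_i * (-rSSTp + phi_lin(sstp_in, xmax));
    rPVp += dt / tau_i * (-rPVp + phi_quad(pvp_in, xmax));
    rUPEp += dt / tau_e * (-rUPEp + phi_lin(dend_p / div_p, xmax));
    rSSTm += dt / tau_i * (-rSSTm + phi_lin(sstm_in, xmax));
    rPVm += dt / tau_i * (-rPVm + phi_quad(pvm_in, xmax));
    rUPEm += dt / tau_e * (-rUPEm + phi_lin(dend_m / div_m, xmax));
    if (!clamp_r) rR += dt / tau_e * (-rR + phi_lin(r_in, xmax));

    if (rSSTp < 0) rSSTp = 0; if (rSSTp > xmax) rSSTp = xmax;
    if (rPVp < 0) rPVp = 0; if (rPVp > rmax_q) rPVp = rmax_q;
    if (rUPEp < 0) rUPEp = 0; if (rUPEp > xmax) rUPEp = xmax;
    if (rSSTm < 0) rSSTm = 0; if (rSSTm > xmax) rSSTm = xmax;
    if (rPVm < 0) rPVm = 0; if (rPVm > rmax_q) rPVm = rmax_q;
    if (rUPEm < 0) rUPEm = 0; if (rUPEm > xmax) rUPEm = xmax;
    if (rR < 0) rR = 0; if (rR > xmax) rR = xmax;
    check_finite(rR, "R", t);
    check_finite(rUPEp, "UPE+", t);
    check_finite(rUPEm, "UPE-", t);

    if (learn[t] && c >= 0) {
      wra[c] += eta_r * (rR - phi_lin(wra[c] * at, xmax)) * at;
      wpp[c] += eta_pv * (rPVp - phi_quad(wpp[c] * at, xmax)) * at;
      wpm[c] += eta_pv * (rPVm - phi_quad(wpm[c] * at, xmax)) * at;
      if (clip_w) {
        if (wra[c] < 0) wra[c] = 0;
        if (wpp[c] < 0) wpp[c] = 0;
        if (wpm[c] < 0) wpm[c] = 0;
      }
    }

    if (thin > 0 && (t + 1) % thin == 0) {
      rates(irec, 0) = rSSTp; rates(irec, 1) = rPVp; rates(irec, 2) = rUPEp;
      rates(irec, 3) = rSSTm; rates(irec, 4) = rPVm; rates(irec, 5) = rUPEm;
      rates(irec, 6) = rR;
      wts(irec, 0) = (c >= 0) ? wra[c] : NA_REAL;
      wts(irec, 1) = (c >= 0) ? wpp[c] : NA_REAL;
      wts(irec, 2) = (c >= 0) ? wpm[c] : NA_REAL;
      tout[irec] = t + 1;
      ++irec;
    }
  }

  NumericVector rf = NumericVector::create(rSSTp, rPVp, rUPEp, rSSTm, rPVm,
                                           rUPEm, rR);
  return List::create(_["t"] = tout, _["rates"] = rates, _["weights"] = wts,
                      _["r_final"] = rf, _["w_r_a"] = wra,
                      _["w_pv_p_a"] = wpp, _["w_pv_m_a"] = wpm);
}

// Two-area hierarchical circuit in clamp mode: PV activity (and hence the
// divisive denominators) is fixed to the sensory and prior variances, the
// SST populations relay the compared signals, and the representation
// neuron integrates the difference between bottom-up and local UPEs
// (gradient dynamics; its fixed point is the variance-weighted average of
// stimulus and prior).
//   tauE dUPEs+/dt = -UPEs+ + phi(|_ s - SSTs+ _|+^k / div_s), SSTs+ <- R
//   tauE dUPEs-/dt = -UPEs- + phi(|_ R - SSTs- _|+^k / div_s), SSTs- <- s
//   tauE dUPEl+/dt = -UPEl+ + phi(|_ R - SSTl+ _|+^k / div_p), SSTl+ <- p
//   tauE dUPEl-/dt = -UPEl- + phi(|_ p - SSTl- _|+^k / div_p), SSTl- <- R
//   tauE dR/dt     = (UPEs+ - UPEs-) - (UPEl+ - UPEl-),  R >= 0
// [[Rcpp::export]]
List cpp_sim_hier(NumericVector s, double p, double div_s, double div_p,
                  List par, double r_init, int thin) {
  const int n = s.size();
  const double dt = par["dt"], tau_e = par["tau_e"], tau_i = par["tau_i"];
  const double k = par["k"], xmax = par["xmax"];
  const double r_gain = par["r_gain"];  // slow integration of R vs errors

  double sst_bp = 0, sst_bm = 0, sst_lp = 0, sst_lm = 0;
  double ubp = 0, ubm = 0, ulp = 0, ulm = 0;
  double rR = r_init;

  const int nrec = (thin > 0) ? n / thin : 0;
  NumericMatrix rates(nrec, 5);
  IntegerVector tout(nrec);

  int irec = 0;
  for (int t = 0; t < n; ++t) {
    // bottom area compares stimulus against the representation,
    // local area compares the representation against the prior
    const double d_bp = pospow(s[t] - sst_bp, k);  // SSTs+ relays R
    const double d_bm = pospow(rR - sst_bm, k);    // SSTs- relays s
    const double d_lp = pospow(rR - sst_lp, k);    // SSTl+ relays prior
    const double d_lm = pospow(p - sst_lm, k);     // SSTl- relays R

    const double dR = (ubp - ubm) - (ulp - ulm);

    sst_bp += dt / tau_i * (-sst_bp + phi_lin(rR, xmax));
    sst_bm += dt / tau_i * (-sst_bm + phi_lin(s[t], xmax));
    sst_lp += dt / tau_i * (-sst_lp + phi_lin(p, xmax));
    sst_lm += dt / tau_i * (-sst_lm + phi_lin(rR, xmax));
    ubp += dt / tau_e * (-ubp + phi_lin(d_bp / div_s, xmax));
    ubm += dt / tau_e * (-ubm + phi_lin(d_bm / div_s, xmax));
    ulp += dt / tau_e * (-ulp + phi_lin(d_lp / div_p, xmax));
    ulm += dt / tau_e * (-ulm + phi_lin(d_lm / div_p, xmax));
    rR += dt / tau_e * r_gain * dR;
    if (rR < 0) rR = 0; if (rR > xmax) rR = xmax;
    check_finite(rR, "R", t);

    if (thin > 0 && (t + 1) % thin == 0) {
      rates(irec, 0) = ubp; rates(irec, 1) = ubm; rates(irec, 2) = ulp;
      rates(irec, 3) = ulm; rates(irec, 4) = rR;
      tout[irec] = t + 1;
      ++irec;
    }
  }

  return List::create(
      _["t"] = tout, _["rates"] = rates,
      _["r_final"] = NumericVector::create(ubp, ubm, ulp, ulm, rR));
}
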