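#include <Rcpp.h>
#include <cmath>

// Reduced-order pulsatile coronary circulation.
//
// State layout (12 doubles):
//   y[0]  V_lv     left-ventricular volume (ml)
//   y[1]  P_ao     aortic root pressure (Pa)
//   y[2]  P_wk     systemic Windkessel distal pressure (Pa)
//   y[3+3b..5+3b]  per coronary branch b in {LAD, LCx, RCA}:
//                  P_art (Pa), P_myo transmural (Pa), P_ven (Pa)
//
// The left ventricle is a time-varying elastance with a diode mitral inlet
// fed from the pulmonary venous pressure and a diode aortic valve. Each
// coronary branch is an algebraic epicardial path (linear resistance plus a
// quadratic stenosis loss) feeding an R-C-R-C-R-C microvascular chain whose
// myocardial compartment is loaded by the intramyocardial pressure
// P_im = pim_frac * P_lv(t). Contractility is rescaled between cycles until
// the cycle-mean aortic pressure matches its target.

struct Engine {
  // timing
  double T;            // cardiac period (s)
  int    steps;        // integration steps per cycle (1000)
  int    min_adapt, max_adapt, n_record;
  double conv_tol, damping;
  // heart
  double Emax0, Emin, V0, frac_sys, kappa, R_mit, R_av, Ppv;
  // systemic
  double Z, Rp, C_ao, C_wk, Pvo, Ptarget;
  double pim_frac;
  // branches
  double Rlin[3], Kt[3], Rm1[3], Rm2[3], Rven[3], Cart[3], Cmyo[3], Cven[3];

  double scale; // contractility scale (controller state)

  double activation(double t) const {
    double c = t / T;
    double ph = c - std::floor(c);   // cycle phase in [0, 1)
    double ts = frac_sys;
    if (ph >= ts) return 0.0;
    double s = std::sin(M_PI * ph / ts);
    return std::pow(s * s, kappa);
  }

  static double branch_flow(double dp, double rlin, double kt) {
    if (kt <= 0.0) return dp / rlin;
    double s = (dp >= 0.0) ? 1.0 : -1.0;
    double ad = std::fabs(dp);
    return s * (-rlin + std::sqrt(rlin * rlin + 4.0 * kt * ad)) / (2.0 * kt);
  }

  void rhs(double t, const double* y, double* dy, double* aux) const {
    double V = y[0], Pao = y[1], Pwk = y[2];
    double a = activation(t);
    double Plv = (Emin + scale * Emax0 * a) * (V - V0);
    double Pim = pim_frac * Plv;

    double qmit = (Ppv > Plv) ? (Ppv - Plv) / R_mit : 0.0;
    double qav  = (Plv > Pao) ? (Plv - Pao) / R_av : 0.0;
    double qsys = (Pao - Pwk) / Z;

    double qcor_sum = 0.0;
    for (int b = 0; b < 3; ++b) {
      const double Part = y[3 + 3 * b], Pmyo = y[4 + 3 * b], Pven = y[5 + 3 * b];
      double qb = branch_flow(Pao - Part, Rlin[b], Kt[b]);
      double q1 = (Part - (Pmyo + Pim)) / Rm1[b];
      double q2 = ((Pmyo + Pim) - Pven) / Rm2[b];
      double qv = (Pven - Pvo) / Rven[b];
      dy[3 + 3 * b] = (qb - q1) / Cart[b];
      dy[4 + 3 * b] = (q1 - q2) / Cmyo[b];
      dy[5 + 3 * b] = (q2 - qv) / Cven[b];
      qcor_sum += qb;
      if (aux) aux[1 + b] = qb;
    }

    dy[0] = qmit - qav;
    dy[1] = (qav - qsys - qcor_sum) / C_ao;
    dy[2] = (qsys - (Pwk - Pvo) / Rp) / C_wk;
    if (aux) { aux[0] = qav; aux[4] = Plv; }
  }
};

static bool finite_state(const double* y, int n) {
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(y[i]) || std::fabs(y[i]) > 1e9) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".engine_run")]]
Rcpp::List engine_run(Rcpp::List cfg) {
  Engine e;
  e.T = Rcpp::as<double>(cfg["T"]);
  e.steps = Rcpp::as<int>(cfg["steps_per_cycle"]);
  e.min_adapt = Rcpp::as<int>(cfg["min_adapt"]);
  e.max_adapt = Rcpp::as<int>(cfg["max_adapt"]);
  e.n_record = Rcpp::as<int>(cfg["n_record"]);
  e.conv_tol = Rcpp::as<double>(cfg["conv_tol"]);
  e.damping = Rcpp::as<double>(cfg["damping"]);
  e.Emax0 = Rcpp::as<double>(cfg["Emax0"]);
  e.Emin = Rcpp::as<double>(cfg["Emin"]);
  e.V0 = Rcpp::as<double>(cfg["V0"]);
  e.frac_sys = Rcpp::as<double>(cfg["frac_sys"]);
  e.kappa = Rcpp::as<double>(cfg["kappa"]);
  e.R_mit = Rcpp::as<double>(cfg["R_mit"]);
  e.R_av = Rcpp::as<double>(cfg["R_av"]);
  e.Ppv = Rcpp::as<double>(cfg["Ppv"]);
  e.Z = Rcpp::as<double>(cfg["Z"]);
  e.Rp = Rcpp::as<double>(cfg["Rp"]);
  e.C_ao = Rcpp::as<double>(cfg["C_ao"]);
  e.C_wk = Rcpp::as<double>(cfg["C_wk"]);
  e.Pvo = Rcpp::as<double>(cfg["Pvo"]);
  e.Ptarget = Rcpp::as<double>(cfg["Ptarget"]);
  e.pim_frac = Rcpp::as<double>(cfg["pim_frac"]);
  {
    Rcpp::NumericVector rlin = cfg["Rlin"], kt = cfg["Kt"], rm1 = cfg["Rm1"],
      rm2 = cfg["Rm2"], rv = cfg["Rven"], ca = cfg["Cart"], cm = cfg["Cmyo"],
      cv = cfg["Cven"];
    for (int b = 0; b < 3; ++b) {
      e.Rlin[b] = rlin[b]; e.Kt[b] = kt[b]; e.Rm1[b] = rm1[b];
      e.Rm2[b] = rm2[b]; e.Rven[b] = rv[b]; e.Cart[b] = ca[b];
      e.Cmyo[b] = cm[b]; e.Cven[b] = cv[b];
    }
  }
  e.scale = 1.0;

  const int ns = 12;
  double y[ns];
  // deterministic initial state near a plausible operating point
  y[0] = e.V0 + std::fmin(120.0, std::fmax(20.0, e.Ppv / e.Emin));
  y[1] = e.Ptarget;
  y[2] = 0.95 * e.Ptarget;
  for (int b = 0; b < 3; ++b) {
    y[3 + 3 * b] = 0.9 * e.Ptarget;
    y[4 + 3 * b] = 0.4 * e.Ptarget;
    y[5 + 3 * b] = e.Pvo + 400.0;
  }

  const double dt = e.T / e.steps;
  const int nrec = e.n_record * e.steps;
  Rcpp::NumericVector t_out(nrec), pao_out(nrec), plv_out(nrec), qav_out(nrec),
    vlv_out(nrec);
  Rcpp::NumericMatrix qb_out(nrec, 3), part_out(nrec, 3);

  int status = 0;              // 0 ok, 1 non-finite/diverged
  bool converged = false;
  int prev_ok = 0;             // consecutive cycles within conv_tol
  bool frozen = false;
  int cycles_run = 0, rec_i = 0;
  double mean_rec = 0.0;       // mean P_ao over recorded cycles
  double k1[ns], k2[ns], k3[ns], k4[ns], yt[ns], aux[5];

  int recorded = 0;
  double t = 0.0;
  int max_cycles = e.max_adapt + e.n_record;
  for (int c = 0; c < max_cycles && recorded < e.n_record; ++c) {
    double pao_acc = 0.0;
    for (int i = 0; i < e.steps; ++i) {
      e.rhs(t, y, k1, aux);
      if (frozen) {
        t_out[rec_i] = t; pao_out[rec_i] = y[1]; plv_out[rec_i] = aux[4];
        qav_out[rec_i] = aux[0]; vlv_out[rec_i] = y[0];
        for (int b = 0; b < 3; ++b) {
          qb_out(rec_i, b) = aux[1 + b];
          part_out(rec_i, b) = y[3 + 3 * b];
        }
        mean_rec += y[1];
        ++rec_i;
      }
      for (int j = 0; j < ns; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
      e.rhs(t + 0.5 * dt, yt, k2, NULL);
      for (int j = 0; j < ns; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
      e.rhs(t + 0.5 * dt, yt, k3, NULL);
      for (int j = 0; j < ns; ++j) yt[j] = y[j] + dt * k3[j];
      e.rhs(t + dt, yt, k4, NULL);
      for (int j = 0; j < ns; ++j)
        y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      pao_acc += y[1];
      t += dt;
      if (!finite_state(y, ns)) { status = 1; break; }
    }
    if (status != 0) break;
    ++cycles_run;
    if (frozen) { ++recorded; continue; }

    double pmean = pao_acc / e.steps;
    double rel = std::fabs(pmean - e.Ptarget) / e.Ptarget;
    if (rel < e.conv_tol) ++prev_ok; else prev_ok = 0;
    if ((prev_ok >= 2 && cycles_run >= e.min_adapt) || cycles_run >= e.max_adapt) {
      converged = (prev_ok >= 2);
      frozen = true;
    } else {
      double upd = std::pow(e.Ptarget / pmean, e.damping);
      upd = std::fmin(5.0, std::fmax(0.2, upd));
      e.scale *= upd;
      e.scale = std::fmin(200.0, std::fmax(0.01, e.scale));
    }
  }
  if (status == 0 && recorded < e.n_record) status = 1;
  mean_rec = (rec_i > 0) ? mean_rec / rec_i : NA_REAL;

  return Rcpp::List::create(
    Rcpp::Named("status") = status,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("scale") = e.scale,
    Rcpp::Named("cycles_run") = cycles_run,
    Rcpp::Named("mean_pao") = mean_rec,
    Rcpp::Named("time") = t_out,
    Rcpp::Named("p_ao") = pao_out,
    Rcpp::Named("p_lv") = plv_out,
    Rcpp::Named("q_av") = qav_out,
    Rcpp::Named("v_lv") = vlv_out,
    Rcpp::Named("q_branch") = qb_out,
    Rcpp::Named("p_art") = part_out);
}
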