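#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integrator for a chain of n >= 1 cylindrical compartments.
//
// State matrix columns (canonical units: mol/L for concentrations, dm for
// lengths): 0 Na, 1 K, 2 Cl, 3 X (total impermeant), 4 XZ (= z * X, the
// impermeant charge concentration), 5 radius.
//
// One segment has piecewise-constant event context: an optional linear
// g_KCC2 ramp, an optional pump-rate ramp (linear or exponential approach),
// per-compartment impermeant injection, and an optional linear mean-charge
// ramp at fixed impermeant moles. Electrodiffusion (n > 1) runs every
// substep dt; membrane/volume physics run every `membrane_every` substeps
// (two-rate scheme; membrane_every = 1 recovers the single-rate update).

static inline double clamp01(double u) {
  return u < 0.0 ? 0.0 : (u > 1.0 ? 1.0 : u);
}

// [[Rcpp::export]]
List run_segment_cpp(NumericMatrix state0,
                     double length,
                     double fconst, double rgas, double temp,
                     NumericVector g_na, NumericVector g_k, NumericVector g_cl,
                     NumericVector g_kcc2_0, NumericVector g_kcc2_1,
                     double c_m, double v_w, double p_w,
                     double k_m, double r_a,
                     double p0, double p1, int pump_exp, double pump_tau,
                     int pump_fixed, double fixed_jp,
                     int volume_mode,
                     NumericVector bath,
                     NumericVector inj_rate, NumericVector inj_val,
                     IntegerVector inj_molar,
                     IntegerVector zramp, NumericVector z_target,
                     double d_na, double d_k, double d_cl,
                     int ed_mode, int membrane_every,
                     double dt, double duration, double record_every,
                     int check_steady, double tol_c, double tol_w,
                     int hold_steps) {
  const int n = state0.nrow();
  const double rtf = rgas * temp / fconst;
  const double pi = M_PI;
  const double bna = bath[0], bk = bath[1], bcl = bath[2], bx = bath[3];
  const double osm_o = bna + bk + bcl + bx;

  std::vector<double> na(n), k(n), cl(n), x(n), xz(n), r(n), z0(n), vm(n);
  for (int i = 0; i < n; ++i) {
    na[i] = state0(i, 0); k[i] = state0(i, 1); cl[i] = state0(i, 2);
    x[i] = state0(i, 3); xz[i] = state0(i, 4); r[i] = state0(i, 5);
    z0[i] = x[i] > 0 ? xz[i] / x[i] : 0.0;
  }

  const long long nsteps = (long long)std::llround(duration / dt);
  const long long rec_stride =
      std::max((long long)1, (long long)std::llround(record_every / dt));
  const double dtm = dt * membrane_every;

  // recording: t=0 row plus every rec_stride substeps, plus a possible
  // early-exit row
  const long long nrec_max = nsteps / rec_stride + 3;
  const int nvar = 14;  // per-compartment recorded quantities
  NumericMatrix rec(nrec_max, 1 + n * nvar);
  long long irec = 0;

  // membrane-step cache for recording (fluxes as of the last membrane update)
  std::vector<double> jp_c(n, 0.0), jkcc2_c(n, 0.0);

  double t = 0.0;

  auto voltage = [&](int i) {
    // Vm = F*(Na+K-Cl+zX)/(Cm*Am), Am = 2/r
    return fconst * (na[i] + k[i] - cl[i] + xz[i]) / (c_m * (2.0 / r[i]));
  };

  auto record_row = [&](double tt) {
    if (irec >= nrec_max) return;
    rec(irec, 0) = tt;
    for (int i = 0; i < n; ++i) {
      double w = pi * r[i] * r[i] * length;
      double ena = rtf * std::log(bna / na[i]);
      double ek = rtf * std::log(bk / k[i]);
      double ecl = -rtf * std::log(bcl / cl[i]);
      double v = voltage(i);
      int o = 1 + i * nvar;
      rec(irec, o + 0) = na[i];
      rec(irec, o + 1) = k[i];
      rec(irec, o + 2) = cl[i];
      rec(irec, o + 3) = x[i];
      rec(irec, o + 4) = x[i] > 0 ? xz[i] / x[i] : NA_REAL;
      rec(irec, o + 5) = r[i];
      rec(irec, o + 6) = w;
      rec(irec, o + 7) = v;
      rec(irec, o + 8) = ena;
      rec(irec, o + 9) = ek;
      rec(irec, o + 10) = ecl;
      rec(irec, o + 11) = v - ecl;
      rec(irec, o + 12) = jp_c[i];
      rec(irec, o + 13) = jkcc2_c[i];
    }
    ++irec;
  };

  // initialise flux cache so the t=0 row carries sensible values
  for (int i = 0; i < n; ++i) {
    double ek = rtf * std::log(bk / k[i]);
    double ecl = -rtf * std::log(bcl / cl[i]);
    jp_c[i] = pump_fixed ? fixed_jp : p0 * std::pow(na[i] / bna, 3);
    jkcc2_c[i] = g_kcc2_0[i] * (ek - ecl);
  }
  record_row(0.0);

  // steady-state detection: windowed finite-difference rate over
  // `hold_steps` membrane steps, two consecutive passing windows required
  std::vector<double> snap_c(3 * n), snap_w(n);
  auto take_snapshot = [&]() {
    for (int i = 0; i < n; ++i) {
      snap_c[3 * i] = na[i]; snap_c[3 * i + 1] = k[i];
      snap_c[3 * i + 2] = cl[i];
      snap_w[i] = pi * r[i] * r[i] * length;
    }
  };
  take_snapshot();
  long long mem_count = 0;
  int windows_ok = 0;
  bool steady = false;

  long long s = 0;
  for (; s < nsteps; ++s) {
    t = s * dt;

    if (s % membrane_every == 0) {
      double frac = duration > 0 ? clamp01(t / duration) : 1.0;
      double pcur;
      if (pump_exp)
        pcur = p1 + (p0 - p1) * std::exp(-t / pump_tau);
      else
        pcur = p0 + (p1 - p0) * frac;

      for (int i = 0; i < n; ++i) {
        double w = pi * r[i] * r[i] * length;
        double sa = 2.0 * pi * r[i] * length;
        double am = 2.0 / r[i];
        double v = voltage(i);
        double ena = rtf * std::log(bna / na[i]);
        double ek = rtf * std::log(bk / k[i]);
        double ecl = -rtf * std::log(bcl / cl[i]);
        double jp = pump_fixed ? fixed_jp : pcur * std::pow(na[i] / bna, 3);
        double gk2 = g_kcc2_0[i] + (g_kcc2_1[i] - g_kcc2_0[i]) * frac;
        double jkcc2 = gk2 * (ek - ecl);
        jp_c[i] = jp; jkcc2_c[i] = jkcc2;

        double osm_i = na[i] + k[i] + cl[i] + x[i];
        double dwdt;
        if (volume_mode == 1) {
          double hp = r[i] > r_a ? 4.0 * pi * k_m * (1.0 - r_a / r[i]) : 0.0;
          dwdt = v_w * p_w * sa * (osm_i - osm_o - hp / (rgas * temp));
        } else {
          dwdt = v_w * p_w * sa * (osm_i - osm_o);
        }
        double dil = dwdt / w;

        double dna = -(am / fconst) * (g_na[i] * (v - ena) + 3.0 * jp)
                     - dil * na[i];
        double dk = -(am / fconst) * (g_k[i] * (v - ek) - 2.0 * jp - jkcc2)
                    - dil * k[i];
        double dcl = (am / fconst) * (g_cl[i] * (v - ecl) + jkcc2)
                     - dil * cl[i];

        na[i] += dtm * dna;
        k[i] += dtm * dk;
        cl[i] += dtm * dcl;
        if (na[i] < 0.0 || k[i] < 0.0 || cl[i] < 0.0) {
          const char *ion = na[i] < 0.0 ? "Na" : (k[i] < 0.0 ? "K" : "Cl");
          stop("integration failure: [%s]i went negative in compartment %d "
               "at t = %g s", ion, i + 1, t);
        }

        // impermeant injection (source term after transmembrane updates);
        // molar mode adds a fixed mol/s regardless of the growing volume;
        // negative rates model removal and must not exhaust the pool
        if (inj_rate[i] != 0.0) {
          double dc = inj_molar[i] ? inj_rate[i] / w * dtm
                                   : inj_rate[i] * dtm;
          x[i] += dc;
          xz[i] += dc * inj_val[i];
          if (x[i] < 0.0)
            stop("integration failure: impermeant pool exhausted in "
                 "compartment %d at t = %g s", i + 1, t);
        }

        // volume update (length fixed); impermeant moles conserved exactly
        double wn = w + dwdt * dtm;
        if (wn <= 0.0)
          stop("integration failure: volume collapsed in compartment %d "
               "at t = %g s", i + 1, t);
        double scale = w / wn;
        x[i] *= scale;
        xz[i] *= scale;
        r[i] = std::sqrt(wn / (pi * length));

        // mean-charge ramp: impermeant moles fixed, valence prescribed
        if (zramp[i]) {
          double zt = z0[i] + (z_target[i] - z0[i]) * frac;
          xz[i] = zt * x[i];
        }
      }

      ++mem_count;
      if (check_steady && mem_count % hold_steps == 0) {
        double win = hold_steps * dtm;
        double rate_c = 0.0, rate_w = 0.0;
        for (int i = 0; i < n; ++i) {
          rate_c = std::max(rate_c, std::fabs(na[i] - snap_c[3 * i]) / win);
          rate_c = std::max(rate_c, std::fabs(k[i] - snap_c[3 * i + 1]) / win);
          rate_c = std::max(rate_c, std::fabs(cl[i] - snap_c[3 * i + 2]) / win);
          double w = pi * r[i] * r[i] * length;
          rate_w = std::max(rate_w, std::fabs(w - snap_w[i]) / (win * w));
        }
        if (rate_c < tol_c && rate_w < tol_w) ++windows_ok; else windows_ok = 0;
        take_snapshot();
        if (windows_ok >= 2) { steady = true; ++s; t = s * dt; break; }
      }
    }

    // electrodiffusion between neighbouring compartments (sealed ends)
    if (n > 1) {
      for (int i = 0; i < n; ++i) vm[i] = voltage(i);
      const double dx = length;  // midpoint distance for equal-length comps
      const double ions_d[3] = { d_na, d_k, d_cl };
      const double ions_z[3] = { 1.0, 1.0, -1.0 };
      std::vector<double> *ions_c[3] = { &na, &k, &cl };
      std::vector<double> dc(n);
      for (int q = 0; q < 3; ++q) {
        double D = ions_d[q];
        if (D <= 0.0) continue;
        double zq = ions_z[q];
        std::vector<double> &c = *ions_c[q];
        std::fill(dc.begin(), dc.end(), 0.0);
        // all interface fluxes are evaluated on the pre-step state
        for (int i = 0; i < n - 1; ++i) {
          double cav = 0.5 * (c[i] + c[i + 1]);
          double term = D * (zq * fconst / (rgas * temp) * cav *
                                 (vm[i] - vm[i + 1]) / dx +
                             (c[i] - c[i + 1]) / dx);
          if (ed_mode == 0) {
            // per-length update: each compartment normalises by its own
            // length (exactly mole-conserving only for equal geometries)
            dc[i] -= dt * term / length;
            dc[i + 1] += dt * term / length;
          } else {
            // conservative update through the shared interface area
            double rmin = std::min(r[i], r[i + 1]);
            double a = pi * rmin * rmin;
            double wi = pi * r[i] * r[i] * length;
            double wj = pi * r[i + 1] * r[i + 1] * length;
            dc[i] -= term * a * dt / wi;
            dc[i + 1] += term * a * dt / wj;
          }
        }
        for (int i = 0; i < n; ++i) c[i] += dc[i];
      }
      for (int i = 0; i < n; ++i)
        if (na[i] < 0.0 || k[i] < 0.0 || cl[i] < 0.0)
          stop("integration failure: electrodiffusion drove a concentration "
               "negative in compartment %d at t = %g s", i + 1, t);
    }

    if ((s + 1) % rec_stride == 0) record_row((s + 1) * dt);
  }

  if (steady || (s % rec_stride != 0)) record_row(s * dt);

  NumericMatrix final_state(n, 6);
  for (int i = 0; i < n; ++i) {
    final_state(i, 0) = na[i]; final_state(i, 1) = k[i];
    final_state(i, 2) = cl[i]; final_state(i, 3) = x[i];
    final_state(i, 4) = xz[i]; final_state(i, 5) = r[i];
  }

  int last = (int)(irec > 0 ? irec - 1 : 0);
  return List::create(_["records"] = rec(Range(0, last), Range(0, n * nvar)),
                      _["final_state"] = final_state,
                      _["steady"] = steady,
                      _["t_end"] = s * dt,
                      _["steps"] = (double)s);
}
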