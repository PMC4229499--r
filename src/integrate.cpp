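#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Three-population convolution neural mass over a weighted directed network.
//
// Per source, four second-order synaptic states:
//   v1: excitatory interneurons (spiny-stellate-like input population)
//   v2: principal cells, excitatory PSP component
//   v3: principal cells, inhibitory PSP component
//   v7: inhibitory interneurons
// Observed principal depolarisation vP = v2 - v3.
// Forward extrinsic afferents drive v1; backward afferents drive v2 and v7.
// Extrinsic delays are handled by a ring buffer over past principal firing,
// sampled (linearly interpolated) at the step midpoint and held constant
// within each RK4 step.

struct NMConst {
  double He_te, Hi_ti;          // H/tau
  double i2te, i2ti;            // 2/tau
  double ite2, iti2;            // 1/tau^2
  double g1, g2, g3, g4, r1, r2, s0;
};

static inline double sig(double v, const NMConst &c) {
  return 1.0 / (1.0 + std::exp(-c.r1 * (v - c.r2))) - c.s0;
}

// [[Rcpp::export]]
NumericVector integrate_nm_cpp(NumericMatrix AF, NumericMatrix AB,
                               NumericVector input_gain,
                               NumericVector self_inhib,
                               NumericVector nm,
                               double onset, double width, double amp,
                               double delay_ms, double dt, int n_steps,
                               int keep_every) {
  const int n = AF.nrow();
  NMConst c;
  const double He = nm[0], Hi = nm[1], te = nm[2], ti = nm[3];
  c.He_te = He / te; c.Hi_ti = Hi / ti;
  c.i2te = 2.0 / te; c.i2ti = 2.0 / ti;
  c.ite2 = 1.0 / (te * te); c.iti2 = 1.0 / (ti * ti);
  c.g1 = nm[4]; c.g2 = nm[5]; c.g3 = nm[6]; c.g4 = nm[7];
  c.r1 = nm[8]; c.r2 = nm[9];
  c.s0 = 1.0 / (1.0 + std::exp(c.r1 * c.r2));

  // dense coupling copied out of the R matrices once
  std::vector<double> af(n * n), ab(n * n), gin(n), si(n);
  for (int j = 0; j < n; ++j) {
    gin[j] = input_gain[j];
    si[j] = self_inhib[j];
    for (int i = 0; i < n; ++i) {
      af[i * n + j] = AF(i, j);   // af[from*n + to]
      ab[i * n + j] = AB(i, j);
    }
  }

  const int ns = 8 * n;
  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), xt(ns);
  const double dsteps = delay_ms / dt;
  std::vector<double> hist((size_t)(n_steps + 2) * n, 0.0);
  std::vector<double> dfire(n), extF(n), extB(n);

  const int n_keep = n_steps / keep_every + 1;
  NumericVector out((R_xlen_t)n_keep * n * 3);
  out.attr("dim") = IntegerVector::create(n_keep, n, 3);

  // state layout per source i: [v1 d1 v2 d2 v3 d3 v7 d7]
  auto deriv = [&](const double *s, double t, double *ds) {
    double tt = (t - onset) / width;
    double u = (t < 0) ? 0.0 : amp * std::exp(-0.5 * tt * tt);
    for (int i = 0; i < n; ++i) {
      const double *p = s + 8 * i;
      double *d = ds + 8 * i;
      const double vP = p[2] - p[4];
      const double sP = sig(vP, c);
      const double s1 = sig(p[0], c);
      const double s7 = sig(p[6], c);
      d[0] = p[1];
      d[1] = c.He_te * (c.g1 * sP + extF[i] + gin[i] * u) -
             c.i2te * p[1] - c.ite2 * p[0];
      d[2] = p[3];
      d[3] = c.He_te * (c.g2 * s1 + extB[i]) - c.i2te * p[3] - c.ite2 * p[2];
      d[4] = p[5];
      d[5] = c.Hi_ti * (c.g4 * s7 + si[i] * sP) - c.i2ti * p[5] -
             c.iti2 * p[4];
      d[6] = p[7];
      d[7] = c.He_te * (c.g3 * sP + extB[i]) - c.i2te * p[7] - c.ite2 * p[6];
    }
  };

  int kept = 0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    for (int i = 0; i < n; ++i) {
      const double vP = x[8 * i + 2] - x[8 * i + 4];
      hist[(size_t)step * n + i] = sig(vP, c);
    }
    if (step % keep_every == 0) {
      for (int i = 0; i < n; ++i) {
        const double vP = x[8 * i + 2] - x[8 * i + 4];
        if (!std::isfinite(vP))
          stop("neural-mass integration diverged at t = %f (source %d)",
               t, i + 1);
        out[kept + n_keep * i] = vP;
        out[kept + n_keep * (n + i)] = x[8 * i + 0];
        out[kept + n_keep * (2 * n + i)] = x[8 * i + 6];
      }
      ++kept;
    }
    if (step == n_steps) break;

    // delayed firing at the step midpoint (linear interpolation)
    const double pos = step + 0.5 - dsteps;
    if (pos <= 0) {
      std::fill(dfire.begin(), dfire.end(), 0.0);
    } else {
      const int lo = (int)pos;
      const double w = pos - lo;
      const double *h0 = &hist[(size_t)lo * n];
      const double *h1 = (lo + 1 <= step) ? h0 + n : h0;
      for (int i = 0; i < n; ++i)
        dfire[i] = (1.0 - w) * h0[i] + w * h1[i];
    }
    std::fill(extF.begin(), extF.end(), 0.0);
    std::fill(extB.begin(), extB.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double f = dfire[i];
      if (f == 0.0) continue;
      const double *afr = &af[(size_t)i * n];
      const double *abr = &ab[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        extF[j] += afr[j] * f;
        extB[j] += abr[j] * f;
      }
    }

    deriv(x.data(), t, k1.data());
    for (int q = 0; q < ns; ++q) xt[q] = x[q] + 0.5 * dt * k1[q];
    deriv(xt.data(), t + 0.5 * dt, k2.data());
    for (int q = 0; q < ns; ++q) xt[q] = x[q] + 0.5 * dt * k2[q];
    deriv(xt.data(), t + 0.5 * dt, k3.data());
    for (int q = 0; q < ns; ++q) xt[q] = x[q] + dt * k3[q];
    deriv(xt.data(), t + dt, k4.data());
    const double d6 = dt / 6.0;
    for (int q = 0; q < ns; ++q)
      x[q] += d6 * (k1[q] + 2.0 * (k2[q] + k3[q]) + k4[q]);
  }
  return out;
}
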