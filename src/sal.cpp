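#include <Rcpp.h>
using namespace Rcpp;

// Stochastic simulation of a mass-action reaction network.
//
// Two modes:
//  * exact = true : Gillespie direct method (exponential waiting times,
//    channel chosen proportionally to propensity).
//  * exact = false: step-anticipation tau-leaping (SAL). Each channel's
//    Poisson mean over a leap tau is r_j*tau + 0.5*(dr_j/dt)*tau^2, with the
//    time derivative of the propensity anticipated through the reaction rate
//    equation (chain rule over the mean drift). Channels that consume a
//    species whose count is below ssa_threshold are "critical" and fire one
//    at a time from an exponential clock, so extinction behaviour stays
//    exact; all channels critical reduces the scheme to exact SSA.
//
// Counts are kept as doubles (they can exceed 2^31 in tumor-growth runs) but
// always hold integer values. Uses R's RNG so set.seed() gives
// bit-reproducible trajectories.

static inline double chan_propensity(const double a, const int i1, const int i2,
                                     const std::vector<double> &x) {
  if (i1 < 0) return a;                 // zero-order source
  if (i2 < 0) return a * x[i1];         // unimolecular
  if (i1 == i2) return a * x[i1] * (x[i1] - 1.0) / 2.0; // homodimerization
  return a * x[i1] * x[i2];             // bimolecular, distinct
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(const NumericMatrix nu, const NumericVector a,
                           const IntegerMatrix ridx, const NumericVector x0,
                           const double t0, const double t_final,
                           const NumericVector rec_times, const double epsilon,
                           const double ssa_threshold, const double max_tau,
                           const bool exact) {
  const int d = nu.nrow(), c = nu.ncol(), R_ = rec_times.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(R_, d);
  int ri = 0;

  // per-channel reactant slots (0-based; -1 = empty) and consumed species
  std::vector<int> i1(c), i2(c);
  std::vector<std::vector<int> > consumed(c);
  std::vector<std::vector<int> > touched(c); // species with nu != 0
  for (int j = 0; j < c; ++j) {
    i1[j] = ridx(0, j);
    i2[j] = ridx(1, j);
    for (int k = 0; k < d; ++k) {
      if (nu(k, j) < 0) consumed[j].push_back(k);
      if (nu(k, j) != 0) touched[j].push_back(k);
    }
  }

  std::vector<double> r(c), drdt(c), dxdt(d), xn(d);
  double t = t0;
  const double eps_t = 1e-12 * std::max(1.0, std::fabs(t_final));
  long long iter = 0;

  while (t < t_final) {
    if (++iter > 200000000LL) stop("step budget exceeded");
    // propensities
    double rtot = 0.0;
    for (int j = 0; j < c; ++j) {
      double rj = chan_propensity(a[j], i1[j], i2[j], x);
      if (rj < 0) rj = 0;
      r[j] = rj;
      rtot += rj;
    }
    if (rtot <= 0.0) break; // absorbing state

    double tnew;
    bool did_jump = true;

    if (exact) {
      double tau = R::exp_rand() / rtot;
      tnew = t + tau;
      if (tnew > t_final) { tnew = t_final; did_jump = false; }
      if (did_jump) {
        double u = unif_rand() * rtot, cum = 0.0;
        int jc = c - 1;
        for (int j = 0; j < c; ++j) { cum += r[j]; if (u <= cum) { jc = j; break; } }
        for (int k = 0; k < d; ++k) xn[k] = x[k] + nu(k, jc);
      } else {
        xn = x;
      }
    } else {
      // mean drift dx/dt = sum_j r_j nu^j  (reaction rate equation)
      std::fill(dxdt.begin(), dxdt.end(), 0.0);
      for (int j = 0; j < c; ++j) {
        if (r[j] == 0.0) continue;
        for (size_t q = 0; q < touched[j].size(); ++q) {
          const int k = touched[j][q];
          dxdt[k] += r[j] * nu(k, j);
        }
      }
      // anticipated propensity drift dr_j/dt by the chain rule
      for (int j = 0; j < c; ++j) {
        double g = 0.0;
        if (i1[j] >= 0) {
          if (i2[j] < 0) {
            g = a[j] * dxdt[i1[j]];
          } else if (i1[j] == i2[j]) {
            g = a[j] * (x[i1[j]] - 0.5) * dxdt[i1[j]];
          } else {
            g = a[j] * (x[i1[j]] * dxdt[i2[j]] + x[i2[j]] * dxdt[i1[j]]);
          }
        }
        drdt[j] = g;
      }
      // critical channels: consume a species below the threshold
      double rc = 0.0;
      std::vector<bool> crit(c, false);
      for (int j = 0; j < c; ++j) {
        if (r[j] == 0.0) continue;
        for (size_t q = 0; q < consumed[j].size(); ++q) {
          if (x[consumed[j][q]] < ssa_threshold) { crit[j] = true; break; }
        }
        if (crit[j]) rc += r[j];
      }
      // leap size: bounded relative propensity change for non-critical
      // channels, |dr_j/dt| * tau <= epsilon * max(r_j, a_j), plus
      // non-negative leap means (tau <= 2 r_j / |dr_j/dt| when shrinking)
      double tau1 = std::min(max_tau, t_final - t);
      // never leap across a recording time: recorded states are then exact
      // leap endpoints
      if (ri < R_ && rec_times[ri] > t && rec_times[ri] - t < tau1) {
        tau1 = rec_times[ri] - t;
      }
      for (int j = 0; j < c; ++j) {
        if (crit[j] || r[j] == 0.0) continue;
        const double ad = std::fabs(drdt[j]);
        if (ad > 0.0) {
          const double b1 = epsilon * std::max(r[j], a[j]) / ad;
          if (b1 < tau1) tau1 = b1;
          if (drdt[j] < 0.0) {
            const double b2 = 2.0 * r[j] / ad;
            if (b2 < tau1) tau1 = b2;
          }
        }
      }
      // fluctuation bound per species (non-critical channels): keep the
      // leap's mean shift and standard deviation below epsilon * count,
      // so near-equilibrium fluctuations cannot outrun the anticipation
      {
        std::vector<double> mu(d, 0.0), s2(d, 0.0);
        for (int j = 0; j < c; ++j) {
          if (crit[j] || r[j] == 0.0) continue;
          for (size_t q = 0; q < touched[j].size(); ++q) {
            const int k = touched[j][q];
            const double nv = nu(k, j);
            mu[k] += nv * r[j];
            s2[k] += nv * nv * r[j];
          }
        }
        for (int k = 0; k < d; ++k) {
          if (s2[k] == 0.0 && mu[k] == 0.0) continue;
          const double lim = std::max(epsilon * x[k], 1.0);
          if (mu[k] != 0.0) {
            const double b = lim / std::fabs(mu[k]);
            if (b < tau1) tau1 = b;
          }
          if (s2[k] > 0.0) {
            const double b = lim * lim / s2[k];
            if (b < tau1) tau1 = b;
          }
        }
      }
      // critical clock
      double tcrit = R_PosInf;
      if (rc > 0.0) tcrit = R::exp_rand() / rc;

      int tries = 0;
      for (;;) {
        const bool fire_crit = (tcrit <= tau1);
        const double tau = fire_crit ? tcrit : tau1;
        xn = x;
        for (int j = 0; j < c; ++j) {
          if (crit[j] || r[j] == 0.0) continue;
          double w = r[j] * tau + 0.5 * drdt[j] * tau * tau;
          if (w <= 0.0) continue;
          const double kdraw = R::rpois(w);
          if (kdraw == 0.0) continue;
          for (size_t q = 0; q < touched[j].size(); ++q) {
            const int k = touched[j][q];
            xn[k] += kdraw * nu(k, j);
          }
        }
        if (fire_crit) {
          double u = unif_rand() * rc, cum = 0.0;
          int jc = -1;
          for (int j = 0; j < c; ++j) {
            if (!crit[j]) continue;
            cum += r[j];
            if (u <= cum) { jc = j; break; }
            jc = j;
          }
          for (int k = 0; k < d; ++k) xn[k] += nu(k, jc);
        }
        bool neg = false;
        for (int k = 0; k < d; ++k) if (xn[k] < 0.0) { neg = true; break; }
        if (!neg) { tnew = t + tau; break; }
        // reject: halve the leap and retry; fall back to one exact event
        if (++tries > 40) {
          double tau_ssa = R::exp_rand() / rtot;
          tnew = t + tau_ssa;
          if (tnew > t_final) { tnew = t_final; xn = x; }
          else {
            double u = unif_rand() * rtot, cum = 0.0;
            int jc = c - 1;
            for (int j = 0; j < c; ++j) { cum += r[j]; if (u <= cum) { jc = j; break; } }
            xn = x;
            for (int k = 0; k < d; ++k) xn[k] += nu(k, jc);
          }
          break;
        }
        tau1 /= 2.0;
        if (tau1 < eps_t) tau1 = eps_t;
      }
    }

    // record grid points passed strictly before the jump with the old state
    while (ri < R_ && rec_times[ri] < tnew - eps_t) {
      for (int k = 0; k < d; ++k) out(ri, k) = x[k];
      ++ri;
    }
    x = xn;
    t = tnew;
  }
  while (ri < R_) {
    for (int k = 0; k < d; ++k) out(ri, k) = x[k];
    ++ri;
  }
  return out;
}
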