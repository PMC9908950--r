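// Stokes-vector Monte Carlo photon transport in a non-absorbing
// microsphere suspension.  Polarization is tracked in a local orthonormal
// frame (direction d, parallel vector m, perpendicular vector n); rotating
// the frame about d by the azimuthal scattering angle and applying the
// sphere Mueller matrix in the scattering plane is algebraically identical
// to the classical meridian-plane bookkeeping.
//
// Geometry: box z in [0, depth], x,y in [-half, half]; photons enter at
// z = 0 travelling +z and are detected when they re-exit the z = 0 face
// (index-matched boundary, no Fresnel step).  Side/bottom exits and
// event-cap truncations are tallied, so launched weight is conserved
// exactly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// splitmix64: one independent, order-invariant substream per photon.
static inline uint64_t sm64(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double runif01(uint64_t &s) {
  return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

struct ThetaSampler {
  // piecewise-linear inverse CDF of m11(theta) * sin(theta) on a uniform grid
  const double *theta, *cdf;
  int n;
  double draw(double u) const {
    // binary search for u in cdf
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] <= u) lo = mid; else hi = mid;
    }
    double c0 = cdf[lo], c1 = cdf[hi];
    double f = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
    return theta[lo] + f * (theta[hi] - theta[lo]);
  }
};

static inline double lininterp(const double *x, const double *y, int n,
                               double xi) {
  double step = x[1] - x[0];
  int i = (int)((xi - x[0]) / step);
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  double f = (xi - x[i]) / step;
  return y[i] + f * (y[i + 1] - y[i]);
}

// [[Rcpp::export(name = ".polmc_run")]]
List polmc_run(NumericVector theta_grid,  // radians, uniform, [0, pi]
               NumericVector a12,         // M12/M11 on grid
               NumericVector a33,         // M33/M11 on grid
               NumericVector a34,         // M34/M11 on grid
               NumericVector theta_cdf,   // CDF of M11 sin(theta) on grid
               double mu_s,               // mm^-1
               double depth,              // mm
               double half,               // mm (lateral half-width)
               double beam_sigma,         // mm (Gaussian sigma)
               double inc_V,              // incident V/I (+1 or -1)
               int n_pixels, double pitch, // detector, mm
               double n_photons, int max_events,
               double seed,
               bool polarized_sampling,
               int highn_threshold,
               double cone_cos) {   // min |cos(exit angle)|; 0 = accept all
  const int ng = theta_grid.size();
  const double *thp = REAL(theta_grid);
  ThetaSampler samp{thp, REAL(theta_cdf), ng};
  const double *p12 = REAL(a12), *p33 = REAL(a33), *p34 = REAL(a34);

  const int np = n_pixels;
  NumericMatrix If(np, np), Ip(np, np);   // channel intensities
  NumericMatrix Nf(np, np), Np(np, np);   // intensity-weighted event sums
  NumericMatrix Tf(np, np), Tp(np, np);   // intensity-weighted per-photon mean angle
  NumericMatrix Gf(np, np), Gp(np, np);   // intensity-weighted per-photon mean cos(theta)
  NumericMatrix Cf(np, np), Cp(np, np);   // contributing photon counts
  // binary-classification tallies: each photon assigned wholly to the
  // channel matching the sign of its exit V ("flipped photons" as a
  // sub-population rather than an intensity component)
  NumericMatrix Bf(np, np), Bp(np, np);
  NumericMatrix BNf(np, np), BNp(np, np);
  NumericMatrix BTf(np, np), BTp(np, np);
  NumericMatrix BGf(np, np), BGp(np, np);
  const int nab = 360;                    // exit-direction histogram, [90,180] deg
  NumericVector angf(nab), angp(nab);

  double w_detected = 0.0, w_overflow = 0.0, w_side = 0.0, w_trunc = 0.0;
  double w_cone = 0.0;
  double hn_dsum = 0.0, hn_d2sum = 0.0, hn_wf = 0.0, hn_wp = 0.0;
  double hn_count = 0.0;
  double field_half = 0.5 * np * pitch;
  const uint64_t base = (uint64_t)seed;
  const long ntot = (long)n_photons;

  for (long iph = 0; iph < ntot; ++iph) {
    uint64_t st = base ^ (0xD1B54A32D192ED03ULL * (uint64_t)(iph + 1));
    sm64(st); // decorrelate the cheap key mix

    // launch: Box-Muller Gaussian entry, +z direction, unit weight
    double u1 = runif01(st), u2 = runif01(st);
    if (u1 <= 0) u1 = 1e-300;
    double rr = beam_sigma * std::sqrt(-2.0 * std::log(u1));
    double x = rr * std::cos(2 * M_PI * u2), y = rr * std::sin(2 * M_PI * u2);
    double z = 0.0;
    double dx = 0, dy = 0, dz = 1;       // direction
    double mx = 1, my = 0, mz = 0;       // parallel reference vector
    double nx = 0, ny = 1, nz = 0;       // perpendicular reference vector
    double SQ = 0, SU = 0, SV = inc_V;   // Stokes (I normalized to 1)
    double w = 1.0;
    int nev = 0;
    double thsum = 0.0, cossum = 0.0;
    int fate = 0; // 0 = in flight, 1 = detected, 2 = side/bottom, 3 = truncated
    double ex = 0, ey = 0, edz = 0;

    while (fate == 0) {
      double l = -std::log(1.0 - runif01(st)) / mu_s;
      // distance to each boundary plane along d
      double tmin = l; int face = -1;
      if (dz < 0) { double t = -z / dz;          if (t < tmin) { tmin = t; face = 0; } }
      else if (dz > 0) { double t = (depth - z) / dz; if (t < tmin) { tmin = t; face = 1; } }
      if (dx > 0) { double t = (half - x) / dx;  if (t < tmin) { tmin = t; face = 2; } }
      else if (dx < 0) { double t = (-half - x) / dx; if (t < tmin) { tmin = t; face = 2; } }
      if (dy > 0) { double t = (half - y) / dy;  if (t < tmin) { tmin = t; face = 2; } }
      else if (dy < 0) { double t = (-half - y) / dy; if (t < tmin) { tmin = t; face = 2; } }

      if (face == 0) { fate = 1; ex = x + tmin * dx; ey = y + tmin * dy; edz = dz; break; }
      if (face > 0)  { fate = 2; break; }
      x += l * dx; y += l * dy; z += l * dz;

      if (nev >= max_events) { fate = 3; break; }

      // sample (theta, phi) from the polarization-dependent phase function
      double A = std::sqrt(SQ * SQ + SU * SU);
      double th, ph, c2p, s2p, r12 = 0.0;
      if (!polarized_sampling || A < 1e-12) {
        th = samp.draw(runif01(st));
        ph = 2 * M_PI * runif01(st);
        c2p = std::cos(2 * ph); s2p = std::sin(2 * ph);
        r12 = lininterp(thp, p12, ng, th);
        if (polarized_sampling) {
          // unpolarized state: acceptance probability is 1
        } else {
          // cross-validation mode: unpolarized proposal, intensity weight
          w *= 1.0 + r12 * (SQ * c2p + SU * s2p);
        }
      } else {
        int it = 0;
        for (;;) {
          th = samp.draw(runif01(st));
          ph = 2 * M_PI * runif01(st);
          c2p = std::cos(2 * ph); s2p = std::sin(2 * ph);
          r12 = lininterp(thp, p12, ng, th);
          double pacc = (1.0 + r12 * (SQ * c2p + SU * s2p)) / (1.0 + A);
          if (runif01(st) < pacc) break;
          if (++it > 100000) stop("rejection sampler failed to accept (broken envelope)");
        }
      }

      // rotate Stokes reference frame about d by phi
      double Qr = SQ * c2p + SU * s2p;
      double Ur = -SQ * s2p + SU * c2p;
      // sphere Mueller matrix at theta (M11-normalized), then renormalize I
      double r33 = lininterp(thp, p33, ng, th);
      double r34 = lininterp(thp, p34, ng, th);
      double I2 = 1.0 + r12 * Qr;
      double Q2 = r12 + Qr;
      double U2 = r33 * Ur + r34 * SV;
      double V2 = -r34 * Ur + r33 * SV;
      if (I2 < 1e-15) I2 = 1e-15;
      SQ = Q2 / I2; SU = U2 / I2; SV = V2 / I2;

      // update local frame: rotate (m,n) about d by phi, then tilt by theta
      double cp = std::cos(ph), sp = std::sin(ph);
      double mpx = cp * mx + sp * nx, mpy = cp * my + sp * ny, mpz = cp * mz + sp * nz;
      double npx = -sp * mx + cp * nx, npy = -sp * my + cp * ny, npz = -sp * mz + cp * nz;
      double ct = std::cos(th), stn = std::sin(th);
      double ndx = ct * dx + stn * mpx, ndy = ct * dy + stn * mpy, ndz = ct * dz + stn * mpz;
      mx = ct * mpx - stn * dx; my = ct * mpy - stn * dy; mz = ct * mpz - stn * dz;
      dx = ndx; dy = ndy; dz = ndz;
      // re-orthonormalize to suppress drift
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= dn; dy /= dn; dz /= dn;
      double md = mx * dx + my * dy + mz * dz;
      mx -= md * dx; my -= md * dy; mz -= md * dz;
      double mn = std::sqrt(mx * mx + my * my + mz * mz);
      mx /= mn; my /= mn; mz /= mn;
      nx = dy * mz - dz * my; ny = dz * mx - dx * mz; nz = dx * my - dy * mx;

      ++nev; thsum += th; cossum += ct;
    }

    if (fate == 2) { w_side += w; continue; }
    if (fate == 3) { w_trunc += w; continue; }

    // detected at the entry face: split into helicity channels.
    // V = I_R - I_L; for left-circular incidence (inc_V = -1) the preserved
    // channel is the one matching the incident sign.
    double wf, wp;
    if (inc_V < 0) { wf = 0.5 * w * (1.0 + SV); wp = 0.5 * w * (1.0 - SV); }
    else           { wf = 0.5 * w * (1.0 - SV); wp = 0.5 * w * (1.0 + SV); }

    // exit-direction histogram over polar angle in [90, 180] deg
    // (always unconditional, so the single-scatter oracle is cone-free)
    double psi = std::acos(-edz) * 180.0 / M_PI;   // 0 = exact backscatter
    int ib = (int)std::floor((90.0 - psi) / (90.0 / nab));
    if (ib >= 0 && ib < nab) { angf[ib] += wf; angp[ib] += wp; }

    if (-edz < cone_cos) { w_cone += w; continue; }

    int ix = (int)std::floor((ex + field_half) / pitch);
    int iy = (int)std::floor((ey + field_half) / pitch);
    if (ix < 0 || ix >= np || iy < 0 || iy >= np) {
      w_overflow += w;
    } else {
      If(iy, ix) += wf; Ip(iy, ix) += wp;
      Nf(iy, ix) += wf * nev; Np(iy, ix) += wp * nev;
      double amean = (nev > 0) ? thsum / nev : 0.0;
      double cmean = (nev > 0) ? cossum / nev : 1.0;
      Tf(iy, ix) += wf * amean; Tp(iy, ix) += wp * amean;
      Gf(iy, ix) += wf * cmean; Gp(iy, ix) += wp * cmean;
      if (wf > 0) Cf(iy, ix) += 1;
      if (wp > 0) Cp(iy, ix) += 1;
      bool cls_flip = (inc_V < 0) ? (SV > 0) : (SV < 0);
      if (cls_flip) { Bf(iy, ix) += w; BNf(iy, ix) += w * nev;
                      BTf(iy, ix) += w * amean; BGf(iy, ix) += w * cmean; }
      else          { Bp(iy, ix) += w; BNp(iy, ix) += w * nev;
                      BTp(iy, ix) += w * amean; BGp(iy, ix) += w * cmean; }
      w_detected += w;
    }
    if (nev > highn_threshold) {
      hn_dsum += (wf - wp); hn_d2sum += (wf - wp) * (wf - wp);
      hn_wf += wf; hn_wp += wp; hn_count += 1;
    }
  }

  return List::create(
      _["flipped"] = If, _["preserved"] = Ip,
      _["nsum_flipped"] = Nf, _["nsum_preserved"] = Np,
      _["anglesum_flipped"] = Tf, _["anglesum_preserved"] = Tp,
      _["cossum_flipped"] = Gf, _["cossum_preserved"] = Gp,
      _["count_flipped"] = Cf, _["count_preserved"] = Cp,
      _["class_flipped"] = Bf, _["class_preserved"] = Bp,
      _["class_nsum_flipped"] = BNf, _["class_nsum_preserved"] = BNp,
      _["class_anglesum_flipped"] = BTf, _["class_anglesum_preserved"] = BTp,
      _["class_cossum_flipped"] = BGf, _["class_cossum_preserved"] = BGp,
      _["exit_hist_flipped"] = angf, _["exit_hist_preserved"] = angp,
      _["w_detected"] = w_detected, _["w_overflow"] = w_overflow,
      _["w_side"] = w_side, _["w_truncated"] = w_trunc,
      _["w_outside_cone"] = w_cone,
      _["highn"] = NumericVector::create(
          _["dsum"] = hn_dsum, _["d2sum"] = hn_d2sum,
          _["w_flipped"] = hn_wf, _["w_preserved"] = hn_wp,
          _["count"] = hn_count));
}
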