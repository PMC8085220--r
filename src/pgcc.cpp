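// Compiled hot loops: axis-aligned grid ray traversal (Siddon/Amanatides
// style), per-candidate-energy Compton-cone backprojection, and the 4D
// median filter used between MLEM iterations.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Clip the half-line origin + t*dir (t >= 0) against the box [lo, hi].
// Returns false when there is no intersection of positive length.
static bool clip_ray(const double* o, const double* d,
                     const double* lo, const double* hi,
                     double& tmin, double& tmax) {
  tmin = 0.0;
  tmax = INF;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-300) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double t1 = (lo[a] - o[a]) / d[a];
      double t2 = (hi[a] - o[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  return tmax > tmin + 1e-12;
}

// Walk the grid along a unit-direction ray, reporting (voxel, chord) pairs.
// Chord lengths are exact for the axis-aligned grid because |dir| = 1 makes
// the ray parameter an arc length in mm.
template <typename F>
static void traverse(const double* o, const double* d,
                     const int* dims, double voxel, const double* corner,
                     F&& emit) {
  double lo[3] = {corner[0], corner[1], corner[2]};
  double hi[3] = {corner[0] + dims[0] * voxel,
                  corner[1] + dims[1] * voxel,
                  corner[2] + dims[2] * voxel};
  double tmin, tmax;
  if (!clip_ray(o, d, lo, hi, tmin, tmax)) return;

  double p[3] = {o[0] + d[0] * tmin, o[1] + d[1] * tmin, o[2] + d[2] * tmin};
  int idx[3], step[3];
  double tDelta[3], tNext[3];
  for (int a = 0; a < 3; ++a) {
    idx[a] = (int)std::floor((p[a] - lo[a]) / voxel);
    if (idx[a] < 0) idx[a] = 0;
    if (idx[a] >= dims[a]) idx[a] = dims[a] - 1;
    if (d[a] > 1e-300) {
      step[a] = 1;
      tDelta[a] = voxel / d[a];
      tNext[a] = tmin + ((lo[a] + (idx[a] + 1) * voxel) - p[a]) / d[a];
    } else if (d[a] < -1e-300) {
      step[a] = -1;
      tDelta[a] = -voxel / d[a];
      tNext[a] = tmin + ((lo[a] + idx[a] * voxel) - p[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = INF;
      tNext[a] = INF;
    }
  }

  double t = tmin;
  while (t < tmax - 1e-12) {
    int a = 0;
    if (tNext[1] < tNext[a]) a = 1;
    if (tNext[2] < tNext[a]) a = 2;
    double tn = tNext[a] < tmax ? tNext[a] : tmax;
    double chord = tn - t;
    if (chord > 0)
      emit(idx[0] + dims[0] * (idx[1] + dims[1] * idx[2]), chord,
           0.5 * (t + tn));
    t = tn;
    if (tNext[a] >= tmax) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dims[a]) break;
    tNext[a] += tDelta[a];
  }
}

// [[Rcpp::export]]
List cpp_ray_trace(NumericVector origin, NumericVector direction,
                   IntegerVector dims, double voxel, NumericVector corner) {
  std::vector<int> vox;
  std::vector<double> len;
  int dm[3] = {dims[0], dims[1], dims[2]};
  traverse(&origin[0], &direction[0], dm, voxel, &corner[0],
           [&](int v, double c, double) {
             vox.push_back(v + 1);  // 1-based for R
             len.push_back(c);
           });
  return List::create(_["voxel"] = wrap(vox), _["length"] = wrap(len));
}

// Backproject a set of coincidence events. For each event and each candidate
// energy-bin center E0 with E0 >= E1 + e_margin and a kinematically valid
// Compton cone, n_rays rays are spawned on the cone surface (apex at the
// scatterer interaction, axis from absorber hit towards scatterer hit) and
// their chord lengths through the spatial grid are accumulated in that
// bin's slice, each chord weighted by 1 / r^r_power with r the distance
// from the cone apex (r_power 2 restores the inverse-square emission
// solid angle that the diverging ray bundle does not carry by itself).
// Returns sparse triplets (event, voxel*bin column, weight) with columns
// sorted within each event for reproducible accumulation.
// [[Rcpp::export]]
List cpp_backproject(NumericMatrix pos1, NumericMatrix pos2,
                     NumericVector E1, NumericVector E2,
                     NumericVector bin_centers,
                     IntegerVector dims, double voxel, NumericVector corner,
                     int n_rays, double mec2, double e_margin,
                     double r_power, int n_sub, double bin_width,
                     bool sin_weight, bool kn_weight, double p_peak,
                     double chord_cap, double e_res) {
  const int n = pos1.nrow();
  const int nb = bin_centers.size();
  const int dm[3] = {dims[0], dims[1], dims[2]};
  const int nvox = dm[0] * dm[1] * dm[2];
  const double two_pi = 2.0 * M_PI;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  std::vector<std::pair<int, double> > row;

  for (int i = 0; i < n; ++i) {
    double apex[3] = {pos1(i, 0), pos1(i, 1), pos1(i, 2)};
    double u[3] = {apex[0] - pos2(i, 0), apex[1] - pos2(i, 1),
                   apex[2] - pos2(i, 2)};
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (nu < 1e-9) stop("degenerate event: coincident interaction positions");
    for (int a = 0; a < 3; ++a) u[a] /= nu;

    // orthonormal basis (u, av, bv)
    double e[3] = {0, 0, 0};
    if (std::fabs(u[0]) < 0.9) e[0] = 1; else e[1] = 1;
    double av[3] = {u[1] * e[2] - u[2] * e[1],
                    u[2] * e[0] - u[0] * e[2],
                    u[0] * e[1] - u[1] * e[0]};
    double na = std::sqrt(av[0] * av[0] + av[1] * av[1] + av[2] * av[2]);
    for (int a = 0; a < 3; ++a) av[a] /= na;
    double bv[3] = {u[1] * av[2] - u[2] * av[1],
                    u[2] * av[0] - u[0] * av[2],
                    u[0] * av[1] - u[1] * av[0]};

    std::unordered_map<int, double> acc;
    const double e1 = E1[i];
    const double esum = e1 + E2[i];
    // 1-sigma uncertainty of the summed deposit under the resolution
    // model (fractional FWHM e_res at 0.511 MeV scaling as 1/sqrt(E))
    const double ssum = e_res > 0.0
      ? e_res * std::sqrt(0.511 * esum) / 2.3548200450309493
      : 0.0;

    for (int k = 0; k < nb; ++k) {
      int off = nvox * k;
      const double ck = bin_centers[k];
      // Absorber + resolution response. Full absorption (probability
      // p_peak) makes E0 = E1 + E2 up to the energy blur: that
      // component's weight in bin k is the Gaussian mass of esum over
      // the bin, and it is represented by a single cone at esum clamped
      // into the bin. The partial-deposit tail (E2 < E', probability
      // 1 - p_peak) spreads over all higher bins with the uniform
      // deposit density, represented by n_sub bin-integrated cones.
      double w_peak = 0.0, w_tail = 0.0;
      if (p_peak > 0.0) {
        if (ssum > 0.0) {
          double zhi = (ck + 0.5 * bin_width - esum) / ssum;
          double zlo = (ck - 0.5 * bin_width - esum) / ssum;
          w_peak = p_peak * 0.5 * (std::erf(zhi / M_SQRT2) -
                                   std::erf(zlo / M_SQRT2));
        } else if (std::fabs(esum - ck) <= 0.5 * bin_width + 1e-9) {
          w_peak = p_peak;
        }
        if (ck > esum - 2.0 * ssum - 1e-9) {
          double eprime = std::max(ck - e1, 0.1);
          w_tail = (1.0 - p_peak) * bin_width / (0.8 * eprime);
        }
      } else {
        w_tail = 1.0;
      }

      // peak component: one cone at esum clamped into the bin
      if (w_peak > 1e-6) {
        double E0 = std::min(std::max(esum, ck - 0.5 * bin_width),
                             ck + 0.5 * bin_width);
        if (E0 >= e1 + e_margin) {
          double ct = 1.0 - mec2 * (1.0 / (E0 - e1) - 1.0 / E0);
          if (ct >= -1.0) {
            if (ct > 1.0) ct = 1.0;
            double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
            double fac = w_peak;
            if (sin_weight) fac *= st;
            if (kn_weight) {
              double eps = 1.0 / (1.0 + (E0 / mec2) * (1.0 - ct));
              fac *= eps * eps * (eps + 1.0 / eps - (1.0 - ct * ct));
            }
            for (int r = 0; r < n_rays; ++r) {
              double phi = two_pi * (r + 0.5) / n_rays;
              double cp = std::cos(phi), sp = std::sin(phi);
              double dir[3];
              for (int a = 0; a < 3; ++a)
                dir[a] = ct * u[a] + st * (cp * av[a] + sp * bv[a]);
              traverse(apex, dir, dm, voxel, &corner[0],
                       [&](int v, double c, double tmid) {
                         if (chord_cap > 0.0 && c > chord_cap) c = chord_cap;
                         double w = c * fac;
                         if (r_power != 0.0 && tmid > 1e-6)
                           w /= std::pow(tmid, r_power);
                         acc[off + v] += w;
                       });
            }
          }
        }
      }

      if (w_tail <= 1e-9) continue;
      int nsub_k = n_sub;
      double resp = w_tail;
      // tail component: n_sub candidate energies spread across
      // [center - width/2, center + width/2]
      for (int sb = 0; sb < nsub_k; ++sb) {
        double E0 = ck;
        if (n_sub > 1)
          E0 += bin_width * ((sb + 0.5) / n_sub - 0.5);
        if (E0 < e1 + e_margin) continue;
        double ct = 1.0 - mec2 * (1.0 / (E0 - e1) - 1.0 / E0);
        if (ct < -1.0) continue;  // kinematically invalid candidate
        if (ct > 1.0) ct = 1.0;
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        // per-cone physics factors: sin(theta) converts ray chords to the
        // cone surface measure; the Klein-Nishina density scores how
        // plausible the scattering angle is at this candidate energy
        double fac = resp;
        if (sin_weight) fac *= st;
        if (kn_weight) {
          double eps = 1.0 / (1.0 + (E0 / mec2) * (1.0 - ct));
          fac *= eps * eps * (eps + 1.0 / eps - (1.0 - ct * ct));
        }
        for (int r = 0; r < n_rays; ++r) {
          double phi = two_pi * (r + 0.5) / n_rays;
          double cp = std::cos(phi), sp = std::sin(phi);
          double dir[3];
          for (int a = 0; a < 3; ++a)
            dir[a] = ct * u[a] + st * (cp * av[a] + sp * bv[a]);
          traverse(apex, dir, dm, voxel, &corner[0],
                   [&](int v, double c, double tmid) {
                     if (chord_cap > 0.0 && c > chord_cap) c = chord_cap;
                     double w = c * fac;
                     if (r_power != 0.0 && tmid > 1e-6)
                       w /= std::pow(tmid, r_power);
                     acc[off + v] += w / nsub_k;
                   });
        }
      }
    }

    row.assign(acc.begin(), acc.end());
    std::sort(row.begin(), row.end());
    for (size_t q = 0; q < row.size(); ++q) {
      ti.push_back(i + 1);
      tj.push_back(row[q].first + 1);
      tx.push_back(row[q].second);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// Median filter on a 4D array (x, y, z, energy) with odd window sizes and
// truncated (shrinking) windows at the borders. Median of an even-sized
// truncated window is the mean of the two central order statistics.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector values, IntegerVector dims,
                                IntegerVector window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], ne = dims[3];
  const int hx = window[0] / 2, hy = window[1] / 2, hz = window[2] / 2,
            he = window[3] / 2;
  NumericVector out(values.size());
  std::vector<double> buf;
  buf.reserve((size_t)window[0] * window[1] * window[2] * window[3]);

  for (int l = 0; l < ne; ++l) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          buf.clear();
          for (int dl = std::max(0, l - he); dl <= std::min(ne - 1, l + he); ++dl)
            for (int dk = std::max(0, k - hz); dk <= std::min(nz - 1, k + hz); ++dk)
              for (int dj = std::max(0, j - hy); dj <= std::min(ny - 1, j + hy); ++dj)
                for (int di = std::max(0, i - hx); di <= std::min(nx - 1, i + hx); ++di)
                  buf.push_back(values[di + nx * (dj + ny * (dk + nz * dl))]);
          size_t m = buf.size() / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.end());
          double med = buf[m];
          if (buf.size() % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + m);
            med = 0.5 * (med + lo);
          }
          out[i + nx * (j + ny * (k + nz * l))] = med;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
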