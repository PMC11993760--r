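// Geometric-optics kernel: ray / periodic-height-field intersection and
// deterministic-splitting Monte Carlo tracing. The height field is a
// polyline h[i] sampled at x = i*dcell, periodic with period L = m*dcell.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

struct Hit {
  int status;      // 0 = hit, 1 = escape (no further intersection), 2 = lost
  double t, x, z;  // hit point, x wrapped into [0, L)
  double nx, nz;   // unit normal of the segment, oriented upward (to air)
};

struct Field {
  const double* h;
  int m;
  double dcell, L, zmin, zmax, eps;
  long max_cells;

  // First intersection of (x0,z0) + t*(dx,dz), t >= eps, with the polyline.
  Hit shoot(double x0, double z0, double dx, double dz) const {
    Hit out;
    out.status = 1;
    out.t = out.x = out.z = out.nx = out.nz = 0.0;
    double xw = x0 - L * std::floor(x0 / L);
    if (xw >= L) xw = 0.0;
    int ic = (int)std::floor(xw / dcell);
    if (ic >= m) ic = m - 1;
    double xoff = xw - ic * dcell;
    bool neg = dx < 0;
    if (neg && xoff <= 0.0) { ic = (ic - 1 + m) % m; xoff = dcell; }

    if (dx == 0.0) {  // vertical ray: single cell
      if (dz == 0.0) { out.status = 2; return out; }
      double h0 = h[ic];
      double s = (h[(ic + 1) % m] - h0) / dcell;
      double zs = h0 + xoff * s;
      double t = (zs - z0) / dz;
      if (t >= eps) {
        double nn = std::sqrt(1.0 + s * s);
        out.status = 0; out.t = t; out.x = xw; out.z = zs;
        out.nx = -s / nn; out.nz = 1.0 / nn;
      }
      return out;
    }

    double t_entry = 0.0;
    for (long it = 0; it < max_cells; ++it) {
      double z_entry = z0 + t_entry * dz;
      if (dz > 0 && z_entry > zmax) return out;  // escapes upward
      if (dz < 0 && z_entry < zmin) return out;  // escapes downward
      double h0 = h[ic];
      double s = (h[(ic + 1) % m] - h0) / dcell;
      double t_exit = neg ? t_entry + xoff / (-dx)
                          : t_entry + (dcell - xoff) / dx;
      double a = dz - dx * s;  // d/dt of (ray z - surface z)
      if (a != 0.0) {
        double f_entry = z_entry - h0 - xoff * s;
        double t_star = t_entry - f_entry / a;
        double lo = t_entry > eps ? t_entry : eps;
        if (t_star >= lo - 1e-12 && t_star <= t_exit + 1e-12) {
          double xi = xoff + (t_star - t_entry) * dx;
          if (xi < 0) xi = 0;
          if (xi > dcell) xi = dcell;
          double nn = std::sqrt(1.0 + s * s);
          out.status = 0; out.t = t_star;
          out.x = ic * dcell + xi; out.z = h0 + xi * s;
          out.nx = -s / nn; out.nz = 1.0 / nn;
          return out;
        }
      }
      t_entry = t_exit;
      if (neg) { ic = (ic - 1 + m) % m; xoff = dcell; }
      else     { ic = (ic + 1) % m;     xoff = 0.0;   }
    }
    out.status = 2;  // traversal cap hit (near-horizontal trapped ray)
    return out;
  }
};

struct Ray {
  double x, z, dx, dz, p;
  int depth;
  bool inside;  // true: travelling in the lower medium (index n_in)
};

}  // namespace

// [[Rcpp::export]]
List trace_rays_cpp(NumericVector heights, double dcell, double zmin,
                    double zmax, NumericVector launch_x, double theta_deg,
                    bool from_above, double n_out, double n_in, int max_depth,
                    double power_cutoff, double eps, double max_cells) {
  int m = heights.size();
  Field fld{REAL(heights), m, dcell, m * dcell, zmin, zmax, eps,
            (long)max_cells};
  double th = theta_deg * PI / 180.0;
  int nray = launch_x.size();
  double p0 = 1.0 / nray;
  double cut = power_cutoff * p0;  // cutoff is relative to launch power
  std::vector<double> upA, upP, dnA, dnP;
  upA.reserve(2 * nray); upP.reserve(2 * nray);
  dnA.reserve(2 * nray); dnP.reserve(2 * nray);
  double residual = 0.0, lost = 0.0;
  double nhits = 0.0, ntraced = 0.0;
  int deepest = 0;
  double z_start = from_above ? zmax + 1.0 : zmin - 1.0;
  double d0x = std::sin(th);
  double d0z = from_above ? -std::cos(th) : std::cos(th);
  std::vector<Ray> stack;
  stack.reserve(64);

  for (int i = 0; i < nray; ++i) {
    stack.push_back(Ray{launch_x[i], z_start, d0x, d0z, p0, 0, !from_above});
    while (!stack.empty()) {
      Ray r = stack.back();
      stack.pop_back();
      ++ntraced;
      if (r.depth > deepest) deepest = r.depth;
      Hit ht = fld.shoot(r.x, r.z, r.dx, r.dz);
      if (ht.status == 2) { residual += r.p; lost += r.p; continue; }
      if (ht.status == 1) {
        // escaped: signed exit angle from the global normal; forward side
        // positive so the specular/Snell peak sits at +theta_i
        if (r.dz > 0) {
          upA.push_back(std::atan2(r.dx, r.dz) * 180.0 / PI);
          upP.push_back(r.p);
        } else {
          dnA.push_back(std::atan2(r.dx, -r.dz) * 180.0 / PI);
          dnP.push_back(r.p);
        }
        continue;
      }
      ++nhits;
      double nox = ht.nx, noz = ht.nz;
      if (r.dx * nox + r.dz * noz > 0) { nox = -nox; noz = -noz; }
      double cosi = -(r.dx * nox + r.dz * noz);
      if (cosi < 0) cosi = 0;
      if (cosi > 1) cosi = 1;
      double n1 = r.inside ? n_in : n_out;
      double n2 = r.inside ? n_out : n_in;
      double sini = std::sqrt(1.0 - cosi * cosi);
      double sint = n1 / n2 * sini;
      double rdx = r.dx + 2.0 * cosi * nox;
      double rdz = r.dz + 2.0 * cosi * noz;
      double rn = std::sqrt(rdx * rdx + rdz * rdz);
      rdx /= rn; rdz /= rn;
      double Rfr, Tfr, tdx = 0.0, tdz = 0.0;
      if (sint >= 1.0) {  // total internal reflection
        Rfr = 1.0; Tfr = 0.0;
      } else {
        double cost = std::sqrt(1.0 - sint * sint);
        double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
        double rp = (n2 * cosi - n1 * cost) / (n2 * cosi + n1 * cost);
        Rfr = 0.5 * (rs * rs + rp * rp);
        Tfr = 1.0 - Rfr;
        double eta = n1 / n2;
        tdx = eta * r.dx + (eta * cosi - cost) * nox;
        tdz = eta * r.dz + (eta * cosi - cost) * noz;
        double tn = std::sqrt(tdx * tdx + tdz * tdz);
        tdx /= tn; tdz /= tn;
      }
      int dn = r.depth + 1;
      double pr = r.p * Rfr, pt = r.p * Tfr;
      if (pr > 0) {
        if (dn > max_depth || pr < cut) residual += pr;
        else stack.push_back(Ray{ht.x + eps * rdx, ht.z + eps * rdz,
                                 rdx, rdz, pr, dn, r.inside});
      }
      if (pt > 0) {
        if (dn > max_depth || pt < cut) residual += pt;
        else stack.push_back(Ray{ht.x + eps * tdx, ht.z + eps * tdz,
                                 tdx, tdz, pt, dn, !r.inside});
      }
    }
  }
  return List::create(
      _["up_angle"] = wrap(upA), _["up_power"] = wrap(upP),
      _["down_angle"] = wrap(dnA), _["down_power"] = wrap(dnP),
      _["residual"] = residual, _["lost"] = lost, _["n_hits"] = nhits,
      _["n_traced"] = ntraced, _["deepest"] = deepest);
}

// [[Rcpp::export]]
List intersect_polyline_cpp(NumericVector heights, double dcell, double zmin,
                            double zmax, double x0, double z0, double dx,
                            double dz, double eps, double max_cells) {
  int m = heights.size();
  Field fld{REAL(heights), m, dcell, m * dcell, zmin, zmax, eps,
            (long)max_cells};
  Hit ht = fld.shoot(x0, z0, dx, dz);
  if (ht.status != 0) {
    return List::create(_["hit"] = false, _["lost"] = (ht.status == 2));
  }
  double nox = ht.nx, noz = ht.nz;
  if (dx * nox + dz * noz > 0) { nox = -nox; noz = -noz; }
  double cosi = -(dx * nox + dz * noz);
  if (cosi > 1) cosi = 1;
  if (cosi < -1) cosi = -1;
  return List::create(
      _["hit"] = true, _["lost"] = false, _["t"] = ht.t, _["x"] = ht.x,
      _["z"] = ht.z, _["normal"] = NumericVector::create(ht.nx, ht.nz),
      _["incidence_deg"] = std::acos(cosi) * 180.0 / PI);
}

// Exact two-sided permutation p-value for Spearman's rho on (possibly tied)
// rank vectors; enumerates distinct arrangements of ry.
// [[Rcpp::export]]
double spearman_perm_pvalue_cpp(NumericVector rx, NumericVector ry,
                                double rho_obs) {
  int n = rx.size();
  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());
  std::sort(y.begin(), y.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (x[i] - mx) * (x[i] - mx);
    sy += (y[i] - my) * (y[i] - my);
  }
  double denom = std::sqrt(sx * sy);
  if (denom <= 0) return NA_REAL;
  double thr = std::fabs(rho_obs) - 1e-9;
  double total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += (x[i] - mx) * (y[i] - my);
    double rho = s / denom;
    total += 1;
    if (std::fabs(rho) >= thr) extreme += 1;
  } while (std::next_permutation(y.begin(), y.end()));
  return extreme / total;
}
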