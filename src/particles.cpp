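#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation of a velocity pair (t and t+dt) linear in time,
// restricted to fluid cells with weight renormalisation.  Returns false if
// the point has no fluid support.
struct VelField {
  const double *u0, *v0, *w0, *u1, *v1, *w1;
  const int *tags;
  int nx, ny, nz;
  double x0, y0, z0, h;
  bool twod;
  bool use_ghost;   // ghost values are wall-consistent: include them so
                    // near-wall particles follow the moving wall
};

static bool sample(const VelField &F, double theta, const double *p,
                   double *vel) {
  double gx = (p[0] - F.x0) / F.h - 0.5;
  double gy = (p[1] - F.y0) / F.h - 0.5;
  double gz = F.twod ? 0 : (p[2] - F.z0) / F.h - 0.5;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = F.twod ? 0 : (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = F.twod ? 0 : gz - k0;
  double wsum = 0, acc[3] = {0, 0, 0};
  int kmax = F.twod ? 1 : 2;
  for (int dk = 0; dk < kmax; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || i >= F.nx || j < 0 || j >= F.ny || k < 0 || k >= F.nz)
          continue;
        int c = i + F.nx * (j + F.ny * k);
        if (F.tags[c] != 1 && !(F.use_ghost && F.tags[c] == 2)) continue;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                   (F.twod ? 1.0 : (dk ? fz : 1 - fz));
        if (w <= 0) continue;
        wsum += w;
        acc[0] += w * ((1 - theta) * F.u0[c] + theta * F.u1[c]);
        acc[1] += w * ((1 - theta) * F.v0[c] + theta * F.v1[c]);
        acc[2] += w * ((1 - theta) * F.w0[c] + theta * F.w1[c]);
      }
  if (wsum < 1e-12) return false;
  for (int d = 0; d < 3; ++d) vel[d] = acc[d] / wsum;
  return true;
}

// Classical RK4 advance of active particles over [t, t+dt] with the velocity
// linear in time between the two supplied field levels.  status: 0 = active,
// advanced; 3 = frozen (a stage point lost fluid support).
// [[Rcpp::export]]
List advect_rk4_cpp(NumericMatrix pos, LogicalVector active,
                    NumericVector u0, NumericVector v0, NumericVector w0,
                    NumericVector u1, NumericVector v1, NumericVector w1,
                    IntegerVector tags, int nx, int ny, int nz,
                    double x0, double y0, double z0, double h, double dt,
                    bool use_ghost = true) {
  VelField F{u0.begin(), v0.begin(), w0.begin(),
             u1.begin(), v1.begin(), w1.begin(),
             tags.begin(), nx, ny, nz, x0, y0, z0, h, nz == 1, use_ghost};
  int np = pos.nrow();
  NumericMatrix out = clone(pos);
  IntegerVector st(np);
  for (int q = 0; q < np; ++q) {
    if (!active[q]) { st[q] = 0; continue; }
    double p0[3] = {pos(q, 0), pos(q, 1), pos(q, 2)};
    double k1[3], k2[3], k3[3], k4[3], tmp[3];
    bool ok = sample(F, 0.0, p0, k1);
    if (ok) {
      for (int d = 0; d < 3; ++d) tmp[d] = p0[d] + 0.5 * dt * k1[d];
      ok = sample(F, 0.5, tmp, k2);
    }
    if (ok) {
      for (int d = 0; d < 3; ++d) tmp[d] = p0[d] + 0.5 * dt * k2[d];
      ok = sample(F, 0.5, tmp, k3);
    }
    if (ok) {
      for (int d = 0; d < 3; ++d) tmp[d] = p0[d] + dt * k3[d];
      ok = sample(F, 1.0, tmp, k4);
    }
    if (!ok) { st[q] = 3; continue; }
    for (int d = 0; d < 3; ++d)
      out(q, d) = p0[d] + dt / 6.0 * (k1[d] + 2 * k2[d] + 2 * k3[d] + k4[d]);
    st[q] = 0;
  }
  return List::create(_["positions"] = out, _["status"] = st);
}

// Cell tag under each particle (0 if outside the grid).
// [[Rcpp::export]]
IntegerVector particle_cell_tag(NumericMatrix pos, IntegerVector tags,
                                int nx, int ny, int nz, double x0, double y0,
                                double z0, double h) {
  int np = pos.nrow();
  IntegerVector out(np);
  bool twod = (nz == 1);
  for (int q = 0; q < np; ++q) {
    int i = (int)std::floor((pos(q, 0) - x0) / h);
    int j = (int)std::floor((pos(q, 1) - y0) / h);
    int k = twod ? 0 : (int)std::floor((pos(q, 2) - z0) / h);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) out[q] = 0;
    else out[q] = tags[i + nx * (j + ny * k)];
  }
  return out;
}
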