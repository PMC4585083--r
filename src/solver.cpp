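#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Cell-centered collocated solver kernels on a uniform Cartesian grid.
// Index layout: id = i + nx*(j + ny*k), 0-based.  nz == 1 selects 2-D mode.
//
// Domain-face boundary codes (per face, order xlo,xhi,ylo,yhi,zlo,zhi):
//   0 = no-slip wall   (velocity mirror with sign flip, scalar Neumann)
//   1 = periodic       (must be set on both opposing faces)
//   2 = open           (velocity zero-gradient, pressure Dirichlet 0)
//
// Cell tags: 1 = fluid, 0 = solid interior, 2 = ghost (solid with a fluid
// neighbour; holds a wall-consistent extrapolated value).  Stencils of fluid
// cells may read ghost/solid values directly.

struct Grid {
  int nx, ny, nz;
  double h;
  int bc[6];
  bool twod;
  inline int id(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline int n() const { return nx * ny * nz; }
};

static Grid make_grid(int nx, int ny, int nz, double h, IntegerVector bc) {
  Grid g; g.nx = nx; g.ny = ny; g.nz = nz; g.h = h; g.twod = (nz == 1);
  for (int f = 0; f < 6; ++f) g.bc[f] = bc[f];
  return g;
}

// neighbour fetch with boundary handling; mode: 0 = scalar (Neumann at wall,
// mirror-negative at open face so the face value is 0), 1 = velocity
// (mirror-negative at wall for no-slip, zero-gradient at open)
static inline double fetch(const double *f, const Grid &g, int i, int j,
                           int k, int mode) {
  double sgn = 1.0;
  for (int d = 0; d < 3; ++d) {
    int v = (d == 0) ? i : (d == 1) ? j : k;
    int nmax = (d == 0) ? g.nx : (d == 1) ? g.ny : g.nz;
    if (v >= 0 && v < nmax) continue;
    int face = 2 * d + (v < 0 ? 0 : 1);
    int code = g.bc[face];
    if (code == 1) {                       // periodic
      v = (v + nmax) % nmax;
    } else if (code == 0) {                // wall
      v = (v < 0) ? 0 : nmax - 1;          // mirror first interior cell
      if (mode == 1) sgn = -sgn;           // no-slip: face value = 0
    } else {                               // open
      v = (v < 0) ? 0 : nmax - 1;
      if (mode == 0) sgn = -sgn;           // pressure face value = 0
    }
    if (d == 0) i = v; else if (d == 1) j = v; else k = v;
  }
  return sgn * f[g.id(i, j, k)];
}

// [[Rcpp::export]]
List op_advection(NumericVector u, NumericVector v, NumericVector w,
                  int nx, int ny, int nz, double h, IntegerVector bc,
                  IntegerVector tags, double blend) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector Au(g.n()), Av(g.n()), Aw(g.n());
  const double *uu = u.begin(), *vv = v.begin(), *ww = w.begin();
  const int *tg = tags.begin();
  const double inv2h = 1.0 / (2 * h), invh = 1.0 / h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.id(i, j, k);
        if (tg[c] != 1) { Au[c] = Av[c] = Aw[c] = 0; continue; }
        double uc = uu[c], vc = vv[c], wc = ww[c];
        // full upwinding in a 3-cell buffer against open faces and in the
        // first ring of cells against the immersed wall: the zero-gradient
        // and ghost-extrapolation closures there need dissipative transport
        double bl = blend;
        if ((g.bc[0] == 2 && i < 3) || (g.bc[1] == 2 && i >= nx - 3) ||
            (g.bc[2] == 2 && j < 3) || (g.bc[3] == 2 && j >= ny - 3) ||
            (g.bc[4] == 2 && k < 3) || (g.bc[5] == 2 && k >= nz - 3))
          bl = 1.0;
        else {
          if ((i > 0 && tg[g.id(i-1,j,k)] != 1) ||
              (i + 1 < nx && tg[g.id(i+1,j,k)] != 1) ||
              (j > 0 && tg[g.id(i,j-1,k)] != 1) ||
              (j + 1 < ny && tg[g.id(i,j+1,k)] != 1) ||
              (!g.twod && k > 0 && tg[g.id(i,j,k-1)] != 1) ||
              (!g.twod && k + 1 < nz && tg[g.id(i,j,k+1)] != 1))
            bl = 1.0;
        }
        const double *flds[3] = {uu, vv, ww};
        double adv[3];
        for (int m = 0; m < 3; ++m) {
          const double *f = flds[m];
          double fc = f[c];
          double fxm = fetch(f, g, i - 1, j, k, 1), fxp = fetch(f, g, i + 1, j, k, 1);
          double fym = fetch(f, g, i, j - 1, k, 1), fyp = fetch(f, g, i, j + 1, k, 1);
          double dcx = (fxp - fxm) * inv2h, dcy = (fyp - fym) * inv2h, dcz = 0;
          double dux = (uc > 0 ? (fc - fxm) : (fxp - fc)) * invh;
          double duy = (vc > 0 ? (fc - fym) : (fyp - fc)) * invh;
          double duz = 0;
          if (!g.twod) {
            double fzm = fetch(f, g, i, j, k - 1, 1), fzp = fetch(f, g, i, j, k + 1, 1);
            dcz = (fzp - fzm) * inv2h;
            duz = (wc > 0 ? (fc - fzm) : (fzp - fc)) * invh;
          }
          double dx = (1 - bl) * dcx + bl * dux;
          double dy = (1 - bl) * dcy + bl * duy;
          double dz = (1 - bl) * dcz + bl * duz;
          adv[m] = uc * dx + vc * dy + wc * dz;
        }
        Au[c] = adv[0]; Av[c] = adv[1]; Aw[c] = adv[2];
      }
  return List::create(_["au"] = Au, _["av"] = Av, _["aw"] = Aw);
}

// [[Rcpp::export]]
NumericVector op_laplacian(NumericVector f, int nx, int ny, int nz, double h,
                           IntegerVector bc, IntegerVector tags, int mode) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector L(g.n());
  const double *ff = f.begin();
  const int *tg = tags.begin();
  const double ih2 = 1.0 / (h * h);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.id(i, j, k);
        if (tg[c] != 1) { L[c] = 0; continue; }
        double fc = ff[c];
        double s = fetch(ff, g, i - 1, j, k, mode) + fetch(ff, g, i + 1, j, k, mode) +
                   fetch(ff, g, i, j - 1, k, mode) + fetch(ff, g, i, j + 1, k, mode) -
                   4 * fc;
        if (!g.twod)
          s += fetch(ff, g, i, j, k - 1, mode) + fetch(ff, g, i, j, k + 1, mode) -
               2 * fc;
        L[c] = s * ih2;
      }
  return L;
}

// Jacobi solve of (I - alpha Lap) x = rhs on fluid cells; non-fluid cells are
// untouched (they hold ghost closures).  Returns the solution; iteration
// count and final residual as attributes.
// [[Rcpp::export]]
NumericVector cn_helmholtz(NumericVector x0, NumericVector rhs, double alpha,
                           int nx, int ny, int nz, double h, IntegerVector bc,
                           IntegerVector tags, double tol, int maxit) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  std::vector<double> x(x0.begin(), x0.end()), xn(x);
  const int *tg = tags.begin();
  const double ih2 = alpha / (h * h);
  int ndim = g.twod ? 4 : 6;
  double diag = 1.0 + ndim * ih2;
  double res = 0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    res = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c = g.id(i, j, k);
          if (tg[c] != 1) { xn[c] = x[c]; continue; }
          double s = fetch(x.data(), g, i - 1, j, k, 1) +
                     fetch(x.data(), g, i + 1, j, k, 1) +
                     fetch(x.data(), g, i, j - 1, k, 1) +
                     fetch(x.data(), g, i, j + 1, k, 1);
          if (!g.twod)
            s += fetch(x.data(), g, i, j, k - 1, 1) +
                 fetch(x.data(), g, i, j, k + 1, 1);
          double xnew = (rhs[c] + ih2 * s) / diag;
          res = std::max(res, std::fabs(xnew - x[c]));
          xn[c] = xnew;
        }
    std::swap(x, xn);
    if (res < tol) break;
  }
  NumericVector out(x.begin(), x.end());
  out.attr("iterations") = it + 1;
  out.attr("residual") = res;
  return out;
}

// ---------------------------------------------------------------------------
// Face fluxes and divergence
// ---------------------------------------------------------------------------

// Face-normal fluxes by linear interpolation of cell velocities.  Fluxes on
// faces: Ux has (nx+1)*ny*nz entries, etc.  Wall faces carry 0 flux, open
// faces carry the adjacent cell value (zero gradient), periodic wraps, and
// fluid-solid faces average the fluid and ghost value (the ghost encodes the
// wall velocity so the average approximates the wall-normal motion).
// [[Rcpp::export]]
List face_fluxes(NumericVector u, NumericVector v, NumericVector w,
                 int nx, int ny, int nz, double h, IntegerVector bc,
                 IntegerVector tags) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector Ux((nx + 1) * ny * nz), Uy(nx * (ny + 1) * nz),
      Uz(nx * ny * (nz + 1));
  const double *uu = u.begin(), *vv = v.begin(), *ww = w.begin();
  auto idx = [&](int i, int j, int k) { return g.id(i, j, k); };
  // x faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int f = i + (nx + 1) * (j + ny * k);
        double val;
        if (i == 0 || i == nx) {
          int code = g.bc[i == 0 ? 0 : 1];
          if (code == 0) val = 0;
          else if (code == 1) val = 0.5 * (uu[idx(nx - 1, j, k)] + uu[idx(0, j, k)]);
          else val = uu[idx(i == 0 ? 0 : nx - 1, j, k)];
        } else val = 0.5 * (uu[idx(i - 1, j, k)] + uu[idx(i, j, k)]);
        Ux[f] = val;
      }
  // y faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int f = i + nx * (j + (ny + 1) * k);
        double val;
        if (j == 0 || j == ny) {
          int code = g.bc[j == 0 ? 2 : 3];
          if (code == 0) val = 0;
          else if (code == 1) val = 0.5 * (vv[idx(i, ny - 1, k)] + vv[idx(i, 0, k)]);
          else val = vv[idx(i, j == 0 ? 0 : ny - 1, k)];
        } else val = 0.5 * (vv[idx(i, j - 1, k)] + vv[idx(i, j, k)]);
        Uy[f] = val;
      }
  // z faces
  if (!g.twod)
    for (int k = 0; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int f = i + nx * (j + ny * k);
          double val;
          if (k == 0 || k == nz) {
            int code = g.bc[k == 0 ? 4 : 5];
            if (code == 0) val = 0;
            else if (code == 1) val = 0.5 * (ww[idx(i, j, nz - 1)] + ww[idx(i, j, 0)]);
            else val = ww[idx(i, j, k == 0 ? 0 : nz - 1)];
          } else val = 0.5 * (ww[idx(i, j, k - 1)] + ww[idx(i, j, k)]);
          Uz[f] = val;
        }
  return List::create(_["ux"] = Ux, _["uy"] = Uy, _["uz"] = Uz);
}

// [[Rcpp::export]]
NumericVector face_divergence(NumericVector Ux, NumericVector Uy,
                              NumericVector Uz, int nx, int ny, int nz,
                              double h, IntegerVector tags) {
  NumericVector div((R_xlen_t)nx * ny * nz);
  const int *tg = tags.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + nx * (j + ny * k);
        if (tg[c] != 1) { div[c] = 0; continue; }
        double d = (Ux[i + 1 + (nx + 1) * (j + ny * k)] -
                    Ux[i + (nx + 1) * (j + ny * k)]) +
                   (Uy[i + nx * (j + 1 + (ny + 1) * k)] -
                    Uy[i + nx * (j + (ny + 1) * k)]);
        if (nz > 1)
          d += Uz[i + nx * (j + ny * (k + 1))] - Uz[i + nx * (j + ny * k)];
        div[c] = d / h;
      }
  return div;
}

// ---------------------------------------------------------------------------
// Geometric multigrid Poisson:  Lap p = rhs on fluid cells.
// Neumann at walls and at immersed solid faces, Dirichlet 0 at open faces,
// periodic where requested.  V-cycles with red-black Gauss-Seidel smoothing,
// full-weighting restriction, mask-aware trilinear prolongation.
// ---------------------------------------------------------------------------

struct MGLevel {
  int nx, ny, nz;
  double h;
  std::vector<int> fluid;            // 1 fluid / 0 not
  std::vector<double> p, rhs, res;
  std::vector<double> diag;          // stencil diagonal (sum of face coeffs)
  // precomputed stencil: per cell, up to 6 neighbour indices and coeffs
  std::vector<int> nb;               // 6 entries per cell, -1 = none
  std::vector<double> cf;            // matching coefficients
  std::vector<int> cells;            // list of fluid cell ids
};

struct MGContext {
  std::vector<MGLevel> levels;
  int bc[6];
  bool twod;
  bool pure_neumann;
};

static inline int lid(const MGLevel &L, int i, int j, int k) {
  return i + L.nx * (j + L.ny * k);
}

// neighbour lookup for Poisson stencil; returns coeff and neighbour index
// (-1 if the face contributes no off-diagonal term)
static inline void poisson_nb(const MGContext &C, const MGLevel &L, int i,
                              int j, int k, int d, int dir, double ih2,
                              double &coef, int &nb) {
  int v[3] = {i, j, k};
  int nmax = (d == 0) ? L.nx : (d == 1) ? L.ny : L.nz;
  v[d] += dir;
  if (v[d] < 0 || v[d] >= nmax) {
    int face = 2 * d + (dir < 0 ? 0 : 1);
    int code = C.bc[face];
    if (code == 1) {
      v[d] = (v[d] + nmax) % nmax;
      int q = lid(L, v[0], v[1], v[2]);
      if (L.fluid[q]) { coef = ih2; nb = q; } else { coef = 0; nb = -1; }
      return;
    } else if (code == 0) { coef = 0; nb = -1; return; }        // wall Neumann
    else { coef = 2 * ih2; nb = -1; return; }                   // open Dirichlet
  }
  int q = lid(L, v[0], v[1], v[2]);
  if (L.fluid[q]) { coef = ih2; nb = q; } else { coef = 0; nb = -1; }
}

static void mg_build_diag(MGContext &C, MGLevel &L) {
  double ih2 = 1.0 / (L.h * L.h);
  size_t N = L.fluid.size();
  L.diag.assign(N, 1.0);
  L.nb.assign(6 * N, -1);
  L.cf.assign(6 * N, 0.0);
  L.cells.clear();
  int kmax = C.twod ? 1 : L.nz;
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < L.ny; ++j)
      for (int i = 0; i < L.nx; ++i) {
        int c = lid(L, i, j, k);
        if (!L.fluid[c]) continue;
        L.cells.push_back(c);
        double dsum = 0; double coef; int nb;
        int ndirs = C.twod ? 2 : 3;
        int slot = 0;
        for (int d = 0; d < ndirs; ++d)
          for (int dir = -1; dir <= 1; dir += 2) {
            poisson_nb(C, L, i, j, k, d, dir, ih2, coef, nb);
            dsum += coef;
            L.nb[6 * c + slot] = nb;
            L.cf[6 * c + slot] = coef;
            ++slot;
          }
        L.diag[c] = (dsum > 0) ? dsum : 1.0;   // isolated cell: fixed to rhs/1
      }
}

static void mg_smooth(MGContext &C, MGLevel &L, int sweeps) {
  // red-black over the precomputed fluid-cell stencils
  int nxy = L.nx * L.ny;
  for (int s = 0; s < sweeps; ++s)
    for (int color = 0; color < 2; ++color)
      for (int c : L.cells) {
        int k = c / nxy, r = c % nxy;
        int parity = (r % L.nx + r / L.nx + k) & 1;
        if (parity != color) continue;
        const int *nb = &L.nb[6 * c];
        const double *cf = &L.cf[6 * c];
        double sum = 0;
        for (int q = 0; q < 6; ++q)
          if (nb[q] >= 0) sum += cf[q] * L.p[nb[q]];
        L.p[c] = (sum - L.rhs[c]) / L.diag[c];
      }
}

static double mg_residual(MGContext &C, MGLevel &L, bool compute_vec) {
  double rmax = 0;
  if (compute_vec) L.res.assign(L.fluid.size(), 0.0);
  for (int c : L.cells) {
    const int *nb = &L.nb[6 * c];
    const double *cf = &L.cf[6 * c];
    double sum = -L.diag[c] * L.p[c];
    for (int q = 0; q < 6; ++q)
      if (nb[q] >= 0) sum += cf[q] * L.p[nb[q]];
    double r = L.rhs[c] - sum;
    if (compute_vec) L.res[c] = r;
    rmax = std::max(rmax, std::fabs(r));
  }
  return rmax;
}

static void mg_restrict(MGContext &C, const MGLevel &F, MGLevel &Cr) {
  int kfac = C.twod ? 1 : 2;
  int kmax = C.twod ? 1 : Cr.nz;
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < Cr.ny; ++j)
      for (int i = 0; i < Cr.nx; ++i) {
        int c = lid(Cr, i, j, k);
        if (!Cr.fluid[c]) { Cr.rhs[c] = 0; continue; }
        double sum = 0; int cnt = 0;
        for (int dk = 0; dk < kfac; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int fi = 2 * i + di, fj = 2 * j + dj, fk = kfac * k + dk;
              int fc = lid(F, fi, fj, fk);
              if (F.fluid[fc]) { sum += F.res[fc]; ++cnt; }
            }
        Cr.rhs[c] = (cnt > 0) ? sum / cnt : 0.0;
        Cr.p[c] = 0;
      }
}

static void mg_prolong_add(MGContext &C, const MGLevel &Cr, MGLevel &F) {
  int kmax = C.twod ? 1 : F.nz;
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < F.ny; ++j)
      for (int i = 0; i < F.nx; ++i) {
        int fc = lid(F, i, j, k);
        if (!F.fluid[fc]) continue;
        // trilinear cell-centered weights: nearest coarse cell 3/4, next 1/4
        int ci[2], cj[2], ck[2];
        double wi[2], wj[2], wk[2];
        auto axis = [&](int fine, int ncoarse, int face_lo, int face_hi,
                        int idx[2], double wt[2]) {
          int c0 = fine / 2;
          int off = (fine % 2 == 0) ? -1 : 1;
          int c1 = c0 + off;
          if (c1 < 0 || c1 >= ncoarse) {
            if (C.bc[face_lo] == 1 && C.bc[face_hi] == 1)
              c1 = (c1 + ncoarse) % ncoarse;
            else c1 = c0;
          }
          idx[0] = c0; idx[1] = c1; wt[0] = 0.75; wt[1] = 0.25;
        };
        axis(i, Cr.nx, 0, 1, ci, wi);
        axis(j, Cr.ny, 2, 3, cj, wj);
        if (C.twod) { ck[0] = ck[1] = 0; wk[0] = 1; wk[1] = 0; }
        else axis(k, Cr.nz, 4, 5, ck, wk);
        double sum = 0, wsum = 0;
        int kk_max = C.twod ? 1 : 2;
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int c2 = 0; c2 < kk_max; ++c2) {
              double wgt = wi[a] * wj[b] * wk[c2];
              if (wgt <= 0) continue;
              int cc = lid(Cr, ci[a], cj[b], ck[c2]);
              if (Cr.fluid[cc]) { sum += wgt * Cr.p[cc]; wsum += wgt; }
            }
        if (wsum > 0) F.p[fc] += sum / wsum;
      }
}

static void mg_vcycle(MGContext &C, int lev, int nsmooth) {
  MGLevel &L = C.levels[lev];
  if (lev == (int)C.levels.size() - 1) {
    mg_smooth(C, L, 60);
    return;
  }
  mg_smooth(C, L, nsmooth);
  mg_residual(C, L, true);
  mg_restrict(C, L, C.levels[lev + 1]);
  mg_vcycle(C, lev + 1, nsmooth);
  mg_prolong_add(C, C.levels[lev + 1], L);
  mg_smooth(C, L, nsmooth);
}

// [[Rcpp::export]]
List mg_poisson(NumericVector rhs, IntegerVector tags, int nx, int ny, int nz,
                double h, IntegerVector bc, double tol, int max_cycles,
                int nsmooth, double rtol = 0.0,
                Nullable<NumericVector> p_init = R_NilValue) {
  MGContext C;
  C.twod = (nz == 1);
  C.pure_neumann = true;
  for (int f = 0; f < 6; ++f) {
    C.bc[f] = bc[f];
    if (bc[f] == 2) C.pure_neumann = false;
  }
  // build hierarchy
  MGLevel fine;
  fine.nx = nx; fine.ny = ny; fine.nz = nz; fine.h = h;
  fine.fluid.resize((size_t)nx * ny * nz);
  for (int c = 0; c < nx * ny * nz; ++c) fine.fluid[c] = (tags[c] == 1);
  fine.rhs.assign(rhs.begin(), rhs.end());
  if (p_init.isNotNull()) {
    NumericVector p0(p_init);
    fine.p.assign(p0.begin(), p0.end());
  } else fine.p.assign(fine.fluid.size(), 0.0);
  C.levels.push_back(std::move(fine));
  while (true) {
    MGLevel &F = C.levels.back();
    bool can = (F.nx % 2 == 0) && (F.ny % 2 == 0) && F.nx > 4 && F.ny > 4;
    if (!C.twod) can = can && (F.nz % 2 == 0) && F.nz > 4;
    if (!can || C.levels.size() >= 10) break;
    MGLevel Cr;
    Cr.nx = F.nx / 2; Cr.ny = F.ny / 2; Cr.nz = C.twod ? 1 : F.nz / 2;
    Cr.h = F.h * 2;
    Cr.fluid.assign((size_t)Cr.nx * Cr.ny * Cr.nz, 0);
    int kfac = C.twod ? 1 : 2;
    int kmax = C.twod ? 1 : Cr.nz;
    for (int k = 0; k < kmax; ++k)
      for (int j = 0; j < Cr.ny; ++j)
        for (int i = 0; i < Cr.nx; ++i) {
          int any = 0;
          for (int dk = 0; dk < kfac; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                if (F.fluid[lid(F, 2 * i + di, 2 * j + dj, kfac * k + dk)])
                  any = 1;
          Cr.fluid[lid(Cr, i, j, k)] = any;
        }
    Cr.rhs.assign(Cr.fluid.size(), 0.0);
    Cr.p.assign(Cr.fluid.size(), 0.0);
    C.levels.push_back(std::move(Cr));
  }
  for (auto &L : C.levels) mg_build_diag(C, L);

  MGLevel &L0 = C.levels[0];
  // compatibility for the pure-Neumann/periodic problem
  long nf = 0; double mean = 0;
  for (size_t c = 0; c < L0.fluid.size(); ++c)
    if (L0.fluid[c]) { mean += L0.rhs[c]; ++nf; }
  if (nf == 0) stop("no fluid cells");
  mean /= nf;
  if (C.pure_neumann)
    for (size_t c = 0; c < L0.fluid.size(); ++c)
      if (L0.fluid[c]) L0.rhs[c] -= mean;

  double r0 = mg_residual(C, L0, false);
  double rhs_max = 0;
  for (size_t c = 0; c < L0.fluid.size(); ++c)
    if (L0.fluid[c]) rhs_max = std::max(rhs_max, std::fabs(L0.rhs[c]));
  double tol_eff = std::max(tol, rtol * rhs_max);
  std::vector<double> trace;
  double r = r0;
  int cyc = 0;
  for (cyc = 0; cyc < max_cycles && r > tol_eff; ++cyc) {
    mg_vcycle(C, 0, nsmooth);
    if (C.pure_neumann) {
      double pm = 0;
      for (size_t c = 0; c < L0.fluid.size(); ++c)
        if (L0.fluid[c]) pm += L0.p[c];
      pm /= nf;
      for (size_t c = 0; c < L0.fluid.size(); ++c)
        if (L0.fluid[c]) L0.p[c] -= pm;
    }
    r = mg_residual(C, L0, false);
    trace.push_back(r);
  }
  NumericVector p(L0.p.begin(), L0.p.end());
  p.attr("cycles") = cyc;
  p.attr("residual") = r;
  p.attr("residual0") = r0;
  p.attr("trace") = NumericVector(trace.begin(), trace.end());
  p.attr("rhs_mean_removed") = C.pure_neumann ? mean : 0.0;
  return List::create(_["p"] = p);
}

// Correct cell velocities and face fluxes with the pressure gradient.
// [[Rcpp::export]]
List project_correct(NumericVector u, NumericVector v, NumericVector w,
                     NumericVector Ux, NumericVector Uy, NumericVector Uz,
                     NumericVector p, int nx, int ny, int nz, double h,
                     IntegerVector bc, IntegerVector tags, double dt_rho) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector un = clone(u), vn = clone(v), wn = clone(w);
  NumericVector Uxn = clone(Ux), Uyn = clone(Uy), Uzn = clone(Uz);
  const double *pp = p.begin();
  const int *tg = tags.begin();
  const double inv2h = 1.0 / (2 * h), invh = 1.0 / h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.id(i, j, k);
        if (tg[c] != 1) continue;
        // cell-centred gradient with one-sided differences against solid
        auto grad1 = [&](int d) {
          int im[3] = {i, j, k}, ip[3] = {i, j, k};
          im[d] -= 1; ip[d] += 1;
          int nmax = (d == 0) ? nx : (d == 1) ? ny : nz;
          bool m_in = (im[d] >= 0), p_in = (ip[d] < nmax);
          bool m_fluid = m_in && tg[g.id(im[0], im[1], im[2])] == 1;
          bool p_fluid = p_in && tg[g.id(ip[0], ip[1], ip[2])] == 1;
          double pm = m_in ? pp[g.id(im[0], im[1], im[2])]
                           : fetch(pp, g, im[0], im[1], im[2], 0);
          double pv = p_in ? pp[g.id(ip[0], ip[1], ip[2])]
                           : fetch(pp, g, ip[0], ip[1], ip[2], 0);
          bool m_ok = !m_in || m_fluid, p_ok = !p_in || p_fluid;
          if (m_ok && p_ok) return (pv - pm) * inv2h;
          if (p_ok) return (pv - pp[c]) * invh;   // solid on minus side
          if (m_ok) return (pp[c] - pm) * invh;   // solid on plus side
          return 0.0;
        };
        un[c] -= dt_rho * grad1(0);
        vn[c] -= dt_rho * grad1(1);
        if (!g.twod) wn[c] -= dt_rho * grad1(2);
      }
  // face fluxes: compact gradient; only faces between two fluid cells or at
  // open domain faces are corrected (wall and solid faces keep their flux)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int f = i + (nx + 1) * (j + ny * k);
        if (i == 0 || i == nx) {
          int code = g.bc[i == 0 ? 0 : 1];
          int c = g.id(i == 0 ? 0 : nx - 1, j, k);
          if (code == 2 && tg[c] == 1) {
            // p = 0 on the face, cell centre half a cell inside
            double gdir = (i == 0) ? (pp[c] - 0) * 2 * invh
                                   : (0 - pp[c]) * 2 * invh;
            Uxn[f] -= dt_rho * gdir;
          } else if (code == 1) {
            int cl = g.id(nx - 1, j, k), cr = g.id(0, j, k);
            if (tg[cl] == 1 && tg[cr] == 1)
              Uxn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
          }
          continue;
        }
        int cl = g.id(i - 1, j, k), cr = g.id(i, j, k);
        if (tg[cl] == 1 && tg[cr] == 1)
          Uxn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int f = i + nx * (j + (ny + 1) * k);
        if (j == 0 || j == ny) {
          int code = g.bc[j == 0 ? 2 : 3];
          int c = g.id(i, j == 0 ? 0 : ny - 1, k);
          if (code == 2 && tg[c] == 1) {
            double gdir = (j == 0) ? (pp[c] - 0) * 2 * invh
                                   : (0 - pp[c]) * 2 * invh;
            Uyn[f] -= dt_rho * gdir;
          } else if (code == 1) {
            int cl = g.id(i, ny - 1, k), cr = g.id(i, 0, k);
            if (tg[cl] == 1 && tg[cr] == 1)
              Uyn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
          }
          continue;
        }
        int cl = g.id(i, j - 1, k), cr = g.id(i, j, k);
        if (tg[cl] == 1 && tg[cr] == 1)
          Uyn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
      }
  if (!g.twod)
    for (int k = 0; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int f = i + nx * (j + ny * k);
          if (k == 0 || k == nz) {
            int code = g.bc[k == 0 ? 4 : 5];
            int c = g.id(i, j, k == 0 ? 0 : nz - 1);
            if (code == 2 && tg[c] == 1) {
              // Dirichlet 0 at the face, half-cell gradient
              double gdir = (k == 0) ? (pp[c] - 0) * 2 * invh
                                     : (0 - pp[c]) * 2 * invh;
              Uzn[f] -= dt_rho * gdir;
            } else if (code == 1) {
              int cl = g.id(i, j, nz - 1), cr = g.id(i, j, 0);
              if (tg[cl] == 1 && tg[cr] == 1)
                Uzn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
            }
            continue;
          }
          int cl = g.id(i, j, k - 1), cr = g.id(i, j, k);
          if (tg[cl] == 1 && tg[cr] == 1)
            Uzn[f] -= dt_rho * (pp[cr] - pp[cl]) * invh;
        }
  return List::create(_["u"] = un, _["v"] = vn, _["w"] = wn,
                      _["ux"] = Uxn, _["uy"] = Uyn, _["uz"] = Uzn);
}

// Cell-centred pressure gradient, one-sided against solid cells, boundary
// handling as for scalars (Neumann at walls, Dirichlet 0 at open faces).
// [[Rcpp::export]]
List cell_gradient(NumericVector p, int nx, int ny, int nz, double h,
                   IntegerVector bc, IntegerVector tags) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector gx(g.n()), gy(g.n()), gz(g.n());
  const double *pp = p.begin();
  const int *tg = tags.begin();
  const double inv2h = 1.0 / (2 * h), invh = 1.0 / h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.id(i, j, k);
        if (tg[c] != 1) { gx[c] = gy[c] = gz[c] = 0; continue; }
        auto grad1 = [&](int d) {
          int im[3] = {i, j, k}, ip[3] = {i, j, k};
          im[d] -= 1; ip[d] += 1;
          int nmax = (d == 0) ? nx : (d == 1) ? ny : nz;
          bool m_in = (im[d] >= 0), p_in = (ip[d] < nmax);
          bool m_fluid = m_in && tg[g.id(im[0], im[1], im[2])] == 1;
          bool p_fluid = p_in && tg[g.id(ip[0], ip[1], ip[2])] == 1;
          double pm = m_in ? pp[g.id(im[0], im[1], im[2])]
                           : fetch(pp, g, im[0], im[1], im[2], 0);
          double pv = p_in ? pp[g.id(ip[0], ip[1], ip[2])]
                           : fetch(pp, g, ip[0], ip[1], ip[2], 0);
          bool m_ok = !m_in || m_fluid, p_ok = !p_in || p_fluid;
          if (m_ok && p_ok) return (pv - pm) * inv2h;
          if (p_ok) return (pv - pp[c]) * invh;
          if (m_ok) return (pp[c] - pm) * invh;
          return 0.0;
        };
        gx[c] = grad1(0);
        gy[c] = grad1(1);
        if (!g.twod) gz[c] = grad1(2);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Rhie-Chow correction of interior fluid-fluid face fluxes: replace the
// averaged cell pressure-gradient contribution with the compact face
// gradient of the same pressure, suppressing collocated checkerboarding in
// the incremental projection.
// [[Rcpp::export]]
List rhie_chow_correct(NumericVector Ux, NumericVector Uy, NumericVector Uz,
                       NumericVector p, NumericVector gx, NumericVector gy,
                       NumericVector gz, int nx, int ny, int nz, double h,
                       IntegerVector bc, IntegerVector tags, double dt_rho) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector Uxn = clone(Ux), Uyn = clone(Uy), Uzn = clone(Uz);
  const int *tg = tags.begin();
  const double invh = 1.0 / h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        int cl = g.id(i - 1, j, k), cr = g.id(i, j, k);
        if (tg[cl] != 1 || tg[cr] != 1) continue;
        int f = i + (nx + 1) * (j + ny * k);
        Uxn[f] += dt_rho * (0.5 * (gx[cl] + gx[cr]) - (p[cr] - p[cl]) * invh);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int cl = g.id(i, j - 1, k), cr = g.id(i, j, k);
        if (tg[cl] != 1 || tg[cr] != 1) continue;
        int f = i + nx * (j + (ny + 1) * k);
        Uyn[f] += dt_rho * (0.5 * (gy[cl] + gy[cr]) - (p[cr] - p[cl]) * invh);
      }
  if (!g.twod)
    for (int k = 1; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int cl = g.id(i, j, k - 1), cr = g.id(i, j, k);
          if (tg[cl] != 1 || tg[cr] != 1) continue;
          int f = i + nx * (j + ny * k);
          Uzn[f] += dt_rho * (0.5 * (gz[cl] + gz[cr]) - (p[cr] - p[cl]) * invh);
        }
  // periodic wrap faces
  if (g.bc[0] == 1)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        int cl = g.id(nx - 1, j, k), cr = g.id(0, j, k);
        if (tg[cl] != 1 || tg[cr] != 1) continue;
        double corr = dt_rho * (0.5 * (gx[cl] + gx[cr]) -
                                (p[cr] - p[cl]) * invh);
        Uxn[0 + (nx + 1) * (j + ny * k)] += corr;
        Uxn[nx + (nx + 1) * (j + ny * k)] += corr;
      }
  if (g.bc[2] == 1)
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        int cl = g.id(i, ny - 1, k), cr = g.id(i, 0, k);
        if (tg[cl] != 1 || tg[cr] != 1) continue;
        double corr = dt_rho * (0.5 * (gy[cl] + gy[cr]) -
                                (p[cr] - p[cl]) * invh);
        Uyn[i + nx * (0 + (ny + 1) * k)] += corr;
        Uyn[i + nx * (ny + (ny + 1) * k)] += corr;
      }
  if (!g.twod && g.bc[4] == 1)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int cl = g.id(i, j, nz - 1), cr = g.id(i, j, 0);
        if (tg[cl] != 1 || tg[cr] != 1) continue;
        double corr = dt_rho * (0.5 * (gz[cl] + gz[cr]) -
                                (p[cr] - p[cl]) * invh);
        Uzn[i + nx * (j + ny * 0)] += corr;
        Uzn[i + nx * (j + ny * nz)] += corr;
      }
  return List::create(_["ux"] = Uxn, _["uy"] = Uyn, _["uz"] = Uzn);
}

// ---------------------------------------------------------------------------
// Velocity-gradient invariants: Q and swirl strength lambda_ci.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List vg_invariants(NumericVector u, NumericVector v, NumericVector w,
                   int nx, int ny, int nz, double h, IntegerVector bc,
                   IntegerVector tags) {
  Grid g = make_grid(nx, ny, nz, h, bc);
  NumericVector Q(g.n()), lci(g.n());
  LogicalVector onesided(g.n());
  const double *flds[3] = {u.begin(), v.begin(), w.begin()};
  const int *tg = tags.begin();
  const double inv2h = 1.0 / (2 * h), invh = 1.0 / h;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.id(i, j, k);
        if (tg[c] != 1) { Q[c] = 0; lci[c] = 0; continue; }
        double J[3][3] = {{0}};
        bool flag = false;
        for (int m = 0; m < 3; ++m) {
          const double *f = flds[m];
          for (int d = 0; d < (g.twod ? 2 : 3); ++d) {
            int im[3] = {i, j, k}, ip[3] = {i, j, k};
            im[d] -= 1; ip[d] += 1;
            int nmax = (d == 0) ? nx : (d == 1) ? ny : nz;
            bool m_solid = (im[d] >= 0) && tg[g.id(im[0], im[1], im[2])] != 1;
            bool p_solid = (ip[d] < nmax) && tg[g.id(ip[0], ip[1], ip[2])] != 1;
            double fm = fetch(f, g, im[0], im[1], im[2], 1);
            double fp = fetch(f, g, ip[0], ip[1], ip[2], 1);
            if (m_solid && !p_solid) { J[m][d] = (fp - f[c]) * invh; flag = true; }
            else if (p_solid && !m_solid) { J[m][d] = (f[c] - fm) * invh; flag = true; }
            else J[m][d] = (fp - fm) * inv2h;
          }
        }
        onesided[c] = flag;
        double trJ = J[0][0] + J[1][1] + J[2][2];
        double tr2 = 0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) tr2 += J[a][b] * J[b][a];
        double q = 0.5 * (trJ * trJ - tr2);
        Q[c] = q;
        // characteristic polynomial lambda^3 - P l^2 + Q l - R = 0
        double P = trJ;
        double Rdet = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                      J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                      J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        // substitute l = t + P/3: t^3 + (q - P^2/3) t + (qP/3 - 2P^3/27 - R)
        double p3 = q - P * P / 3.0;
        double qc = -Rdet + q * P / 3.0 - 2.0 * P * P * P / 27.0;
        double disc = qc * qc / 4.0 + p3 * p3 * p3 / 27.0;
        if (disc > 0) {
          // one real root, complex pair: lci = imaginary part
          double sq = std::sqrt(disc);
          double A = std::cbrt(-qc / 2.0 + sq);
          double B = std::cbrt(-qc / 2.0 - sq);
          lci[c] = std::fabs(std::sqrt(3.0) / 2.0 * (A - B));
        } else lci[c] = 0.0;
      }
  return List::create(_["q"] = Q, _["lambda_ci"] = lci,
                      _["onesided"] = onesided);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation restricted to fluid cells (weights renormalised).
// Returns values and a validity weight (0 = no fluid support).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List interp_fluid(NumericMatrix pts, List fields, int nx, int ny, int nz,
                  double x0, double y0, double z0, double h,
                  IntegerVector tags) {
  int np = pts.nrow(), nf = fields.size();
  std::vector<const double *> fp(nf);
  for (int f = 0; f < nf; ++f)
    fp[f] = NumericVector(fields[f]).begin();
  NumericMatrix out(np, nf);
  NumericVector wt(np);
  const int *tg = tags.begin();
  bool twod = (nz == 1);
  for (int q = 0; q < np; ++q) {
    double gx = (pts(q, 0) - x0) / h - 0.5;
    double gy = (pts(q, 1) - y0) / h - 0.5;
    double gz = twod ? 0 : (pts(q, 2) - z0) / h - 0.5;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
        k0 = twod ? 0 : (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = twod ? 0 : gz - k0;
    double wsum = 0;
    std::vector<double> acc(nf, 0.0);
    int kk_max = twod ? 1 : 2;
    for (int dk = 0; dk < kk_max; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
            continue;
          int c = i + nx * (j + ny * k);
          if (tg[c] != 1) continue;
          double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                       (twod ? 1.0 : (dk ? fz : 1 - fz));
          wsum += wgt;
          for (int f = 0; f < nf; ++f) acc[f] += wgt * fp[f][c];
        }
    wt[q] = wsum;
    for (int f = 0; f < nf; ++f)
      out(q, f) = (wsum > 1e-12) ? acc[f] / wsum : NA_REAL;
  }
  return List::create(_["values"] = out, _["weight"] = wt);
}
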