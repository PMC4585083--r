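#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra over a node lattice.
//
// Each lattice cube is split into six tetrahedra sharing the main diagonal
// (0,0,0)-(1,1,1); the decomposition is translation-invariant so shared cube
// faces carry the same diagonal and the extracted surface is watertight.
// Inside is f < iso.  Triangle winding is fixed per-triangle so normals point
// towards increasing f (outward).
// ---------------------------------------------------------------------------

static inline uint64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint32_t>(b);
}

// [[Rcpp::export]]
List mt_isosurface(NumericVector f, NumericVector xs, NumericVector ys,
                   NumericVector zs, double iso) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  if (static_cast<R_xlen_t>(nx) * ny * nz != f.size())
    stop("field size does not match lattice");
  auto nid = [&](int i, int j, int k) { return i + nx * (j + ny * k); };

  // cube corner offsets, vertex numbering v0..v7
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tets sharing diagonal v0-v6
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double px[8], py[8], pz[8], fv[8];
  int gid[8];

  auto edge_vertex = [&](int a, int b) {
    uint64_t key = edge_key(gid[a], gid[b]);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - fv[a]) / (fv[b] - fv[a]);
    t = std::min(1.0, std::max(0.0, t));
    int id = static_cast<int>(vx.size());
    vx.push_back(px[a] + t * (px[b] - px[a]));
    vy.push_back(py[a] + t * (py[b] - py[a]));
    vz.push_back(pz[a] + t * (pz[b] - pz[a]));
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int e1, int e2, int e3, double ox, double oy, double oz,
                  double ix, double iy, double iz) {
    // orient so normal points from inside centroid towards outside centroid
    double ax = vx[e2] - vx[e1], ay = vy[e2] - vy[e1], az = vz[e2] - vz[e1];
    double bx = vx[e3] - vx[e1], by = vy[e3] - vy[e1], bz = vz[e3] - vz[e1];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double dot = nxv * (ox - ix) + nyv * (oy - iy) + nzv * (oz - iz);
    if (dot >= 0) { tri.push_back(e1); tri.push_back(e2); tri.push_back(e3); }
    else          { tri.push_back(e1); tri.push_back(e3); tri.push_back(e2); }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          gid[c] = nid(ii, jj, kk);
          px[c] = xs[ii]; py[c] = ys[jj]; pz[c] = zs[kk];
          fv[c] = f[gid[c]];
          (fv[c] < iso ? anyin : anyout) = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c)
            if (fv[tv[c]] < iso) in[nin++] = tv[c]; else out[nout++] = tv[c];
          if (nin == 0 || nin == 4) continue;
          // centroids of inside / outside corners for orientation reference
          double icx = 0, icy = 0, icz = 0, ocx = 0, ocy = 0, ocz = 0;
          for (int c = 0; c < nin; ++c) { icx += px[in[c]]; icy += py[in[c]]; icz += pz[in[c]]; }
          for (int c = 0; c < nout; ++c) { ocx += px[out[c]]; ocy += py[out[c]]; ocz += pz[out[c]]; }
          icx /= nin; icy /= nin; icz /= nin;
          ocx /= nout; ocy /= nout; ocz /= nout;
          if (nin == 1) {
            int e1 = edge_vertex(in[0], out[0]);
            int e2 = edge_vertex(in[0], out[1]);
            int e3 = edge_vertex(in[0], out[2]);
            emit(e1, e2, e3, ocx, ocy, ocz, icx, icy, icz);
          } else if (nin == 3) {
            int e1 = edge_vertex(in[0], out[0]);
            int e2 = edge_vertex(in[1], out[0]);
            int e3 = edge_vertex(in[2], out[0]);
            emit(e1, e2, e3, ocx, ocy, ocz, icx, icy, icz);
          } else { // nin == 2: quad a-b-c-d
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[0], out[1]);
            int c = edge_vertex(in[1], out[1]);
            int d = edge_vertex(in[1], out[0]);
            emit(a, b, c, ocx, ocy, ocz, icx, icy, icz);
            emit(a, c, d, ocx, ocy, ocz, icx, icy, icz);
          }
        }
      }

  const int nv = static_cast<int>(vx.size());
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  const int nt = static_cast<int>(tri.size()) / 3;
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tri[3 * t] + 1; T(t, 1) = tri[3 * t + 1] + 1; T(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Uniform triangle binning for nearest-triangle queries.
// ---------------------------------------------------------------------------

struct TriBins {
  double x0, y0, z0, cell;
  int bx, by, bz;
  std::vector<std::vector<int>> bins;
  int idx(int i, int j, int k) const { return i + bx * (j + by * k); }
};

static TriBins build_bins(const NumericMatrix &V, const IntegerMatrix &T,
                          double target_cell) {
  TriBins B;
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int v = 0; v < V.nrow(); ++v) {
    xmin = std::min(xmin, V(v,0)); xmax = std::max(xmax, V(v,0));
    ymin = std::min(ymin, V(v,1)); ymax = std::max(ymax, V(v,1));
    zmin = std::min(zmin, V(v,2)); zmax = std::max(zmax, V(v,2));
  }
  double pad = 1e-9 + 1e-6 * (xmax - xmin + ymax - ymin + zmax - zmin);
  B.x0 = xmin - pad; B.y0 = ymin - pad; B.z0 = zmin - pad;
  B.cell = target_cell;
  B.bx = std::max(1, (int)std::ceil((xmax - B.x0 + pad) / B.cell));
  B.by = std::max(1, (int)std::ceil((ymax - B.y0 + pad) / B.cell));
  B.bz = std::max(1, (int)std::ceil((zmax - B.z0 + pad) / B.cell));
  // cap the bin lattice so tiny target cells cannot blow up memory
  while ((double)B.bx * B.by * B.bz > 2e7) {
    B.cell *= 2.0;
    B.bx = std::max(1, (B.bx + 1) / 2);
    B.by = std::max(1, (B.by + 1) / 2);
    B.bz = std::max(1, (B.bz + 1) / 2);
  }
  B.bins.assign((size_t)B.bx * B.by * B.bz, {});
  for (int t = 0; t < T.nrow(); ++t) {
    double txmin = R_PosInf, txmax = R_NegInf, tymin = R_PosInf,
           tymax = R_NegInf, tzmin = R_PosInf, tzmax = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      int v = T(t, c) - 1;
      txmin = std::min(txmin, V(v,0)); txmax = std::max(txmax, V(v,0));
      tymin = std::min(tymin, V(v,1)); tymax = std::max(tymax, V(v,1));
      tzmin = std::min(tzmin, V(v,2)); tzmax = std::max(tzmax, V(v,2));
    }
    int i0 = std::max(0, (int)((txmin - B.x0) / B.cell));
    int i1 = std::min(B.bx - 1, (int)((txmax - B.x0) / B.cell));
    int j0 = std::max(0, (int)((tymin - B.y0) / B.cell));
    int j1 = std::min(B.by - 1, (int)((tymax - B.y0) / B.cell));
    int k0 = std::max(0, (int)((tzmin - B.z0) / B.cell));
    int k1 = std::min(B.bz - 1, (int)((tzmax - B.z0) / B.cell));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          B.bins[B.idx(i, j, k)].push_back(t);
  }
  return B;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; bary[0]=1;bary[1]=0;bary[2]=0; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; bary[0]=0;bary[1]=1;bary[2]=0; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    bary[0]=1-v;bary[1]=v;bary[2]=0; return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; bary[0]=0;bary[1]=0;bary[2]=1; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    bary[0]=1-w;bary[1]=0;bary[2]=w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    bary[0]=0;bary[1]=1-w;bary[2]=w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
  bary[0]=1-v-w;bary[1]=v;bary[2]=w;
}

// Nearest triangle, closest point, barycentric coords and signed distance via
// angle-weighted pseudo-normal; sign > 0 means outside (along normal).
// [[Rcpp::export]]
List point_mesh_query(NumericMatrix P, NumericMatrix V, IntegerMatrix T) {
  // face normals (area weighted) and angle-weighted vertex pseudo-normals
  const int nt = T.nrow(), nv = V.nrow(), np = P.nrow();
  std::vector<double> fn(3 * nt, 0.0), vn(3 * nv, 0.0);
  double mean_edge = 0;
  for (int t = 0; t < nt; ++t) {
    int a = T(t,0)-1, b = T(t,1)-1, c = T(t,2)-1;
    double e1[3], e2[3];
    for (int i=0;i<3;++i) { e1[i]=V(b,i)-V(a,i); e2[i]=V(c,i)-V(a,i); }
    fn[3*t]   = e1[1]*e2[2]-e1[2]*e2[1];
    fn[3*t+1] = e1[2]*e2[0]-e1[0]*e2[2];
    fn[3*t+2] = e1[0]*e2[1]-e1[1]*e2[0];
    double vv[3][3];
    for (int i=0;i<3;++i) { vv[0][i]=V(a,i); vv[1][i]=V(b,i); vv[2][i]=V(c,i); }
    int ids[3] = {a, b, c};
    double nrm = std::sqrt(fn[3*t]*fn[3*t]+fn[3*t+1]*fn[3*t+1]+fn[3*t+2]*fn[3*t+2]);
    mean_edge += std::sqrt(e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2]);
    if (nrm <= 0) continue;
    for (int c2 = 0; c2 < 3; ++c2) {
      double u[3], w[3];
      int p0 = ids[c2], pm = (c2+2)%3, pp = (c2+1)%3;
      for (int i=0;i<3;++i) { u[i]=vv[pp][i]-vv[c2][i]; w[i]=vv[pm][i]-vv[c2][i]; }
      double du = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
      double dw = std::sqrt(w[0]*w[0]+w[1]*w[1]+w[2]*w[2]);
      if (du <= 0 || dw <= 0) continue;
      double cosang = (u[0]*w[0]+u[1]*w[1]+u[2]*w[2]) / (du*dw);
      cosang = std::min(1.0, std::max(-1.0, cosang));
      double ang = std::acos(cosang);
      for (int i=0;i<3;++i) vn[3*p0+i] += ang * fn[3*t+i] / nrm;
    }
  }
  mean_edge /= std::max(1, nt);
  TriBins B = build_bins(V, T, std::max(mean_edge * 2.0, 1e-12));

  NumericVector dist(np), sdist(np);
  IntegerVector tri_id(np);
  NumericMatrix closest(np, 3), bcoord(np, 3);

  for (int q = 0; q < np; ++q) {
    double p[3] = {P(q,0), P(q,1), P(q,2)};
    // spiral outward over bins until a hit, then one extra ring for safety
    int ci = std::min(B.bx-1, std::max(0, (int)((p[0]-B.x0)/B.cell)));
    int cj = std::min(B.by-1, std::max(0, (int)((p[1]-B.y0)/B.cell)));
    int ck = std::min(B.bz-1, std::max(0, (int)((p[2]-B.z0)/B.cell)));
    double best = R_PosInf, bbary[3] = {0,0,0}, bpt[3] = {0,0,0};
    int btri = -1;
    int maxr = std::max(std::max(B.bx, B.by), B.bz);
    for (int r = 0; r <= maxr; ++r) {
      bool found_before = std::isfinite(best);
      // once found, only search one extra ring
      int i0 = std::max(0, ci - r), i1 = std::min(B.bx - 1, ci + r);
      int j0 = std::max(0, cj - r), j1 = std::min(B.by - 1, cj + r);
      int k0 = std::max(0, ck - r), k1 = std::min(B.bz - 1, ck + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            if (r > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1) continue; // shell only
            for (int t : B.bins[B.idx(i, j, k)]) {
              int a = T(t,0)-1, b = T(t,1)-1, c = T(t,2)-1;
              double A[3]={V(a,0),V(a,1),V(a,2)}, Bv[3]={V(b,0),V(b,1),V(b,2)},
                     C[3]={V(c,0),V(c,1),V(c,2)};
              double cp[3], bc[3];
              closest_on_tri(p, A, Bv, C, cp, bc);
              double d2 = 0; for (int ii=0;ii<3;++ii) { double d=p[ii]-cp[ii]; d2+=d*d; }
              if (d2 < best) {
                best = d2; btri = t;
                for (int ii=0;ii<3;++ii) { bpt[ii]=cp[ii]; bbary[ii]=bc[ii]; }
              }
            }
          }
      if (found_before) break; // searched one ring beyond first hit
      if (std::isfinite(best) && (double)r * B.cell > std::sqrt(best) + B.cell)
        break;
    }
    double d = std::sqrt(best);
    dist[q] = d; tri_id[q] = btri + 1;
    for (int ii=0;ii<3;++ii) { closest(q,ii)=bpt[ii]; bcoord(q,ii)=bbary[ii]; }
    // pseudo-normal at the closest point: barycentric blend of vertex normals
    double pn[3] = {0,0,0};
    if (btri >= 0) {
      int a = T(btri,0)-1, b = T(btri,1)-1, c = T(btri,2)-1;
      for (int ii=0;ii<3;++ii)
        pn[ii] = bbary[0]*vn[3*a+ii] + bbary[1]*vn[3*b+ii] + bbary[2]*vn[3*c+ii];
    }
    double dot = pn[0]*(p[0]-bpt[0]) + pn[1]*(p[1]-bpt[1]) + pn[2]*(p[2]-bpt[2]);
    sdist[q] = (dot >= 0) ? d : -d;
  }
  return List::create(_["distance"] = dist, _["signed_distance"] = sdist,
                      _["triangle"] = tri_id, _["closest"] = closest,
                      _["barycentric"] = bcoord);
}

// Ray-parity inside test for all cell centres of a uniform grid: rays are the
// +x grid lines.  Returns logical array (length nx*ny*nz), TRUE = inside.
// [[Rcpp::export]]
LogicalVector grid_inside_parity(NumericMatrix V, IntegerMatrix T,
                                 double x0, double y0, double z0, double h,
                                 int nx, int ny, int nz) {
  // jitter ray origins slightly off symmetric positions
  const double jy = 0.5 + 1.2345e-4, jz = 0.5 + 2.3456e-4;
  std::vector<std::vector<double>> cross((size_t)ny * nz);
  for (int t = 0; t < T.nrow(); ++t) {
    int a = T(t,0)-1, b = T(t,1)-1, c = T(t,2)-1;
    double ay = V(a,1), az = V(a,2), by = V(b,1), bz = V(b,2),
           cy = V(c,1), cz = V(c,2);
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    double zmin = std::min(az, std::min(bz, cz)), zmax = std::max(az, std::max(bz, cz));
    int j0 = std::max(0, (int)std::ceil((ymin - y0) / h - jy));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / h - jy));
    int k0 = std::max(0, (int)std::ceil((zmin - z0) / h - jz));
    int k1 = std::min(nz - 1, (int)std::floor((zmax - z0) / h - jz));
    for (int k = k0; k <= k1; ++k) {
      double rz = z0 + (k + jz) * h;
      for (int j = j0; j <= j1; ++j) {
        double ry = y0 + (j + jy) * h;
        // 2-D point-in-triangle in (y,z); if inside, solve for x on the plane
        double d1 = (by-ay)*(rz-az) - (bz-az)*(ry-ay);
        double d2 = (cy-by)*(rz-bz) - (cz-bz)*(ry-by);
        double d3 = (ay-cy)*(rz-cz) - (az-cz)*(ry-cy);
        bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (neg && pos) continue;
        // barycentric in (y,z)
        double det = (by-ay)*(cz-az) - (cy-ay)*(bz-az);
        if (det == 0) continue;
        double l2 = ((ry-ay)*(cz-az) - (cy-ay)*(rz-az)) / det;
        double l3 = ((by-ay)*(rz-az) - (ry-ay)*(bz-az)) / det;
        double l1 = 1.0 - l2 - l3;
        double xi = l1 * V(a,0) + l2 * V(b,0) + l3 * V(c,0);
        cross[(size_t)j + (size_t)ny * k].push_back(xi);
      }
    }
  }
  LogicalVector inside((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      auto &cr = cross[(size_t)j + (size_t)ny * k];
      std::sort(cr.begin(), cr.end());
      size_t m = 0;
      for (int i = 0; i < nx; ++i) {
        double xc = x0 + (i + 0.5) * h;
        while (m < cr.size() && cr[m] < xc) ++m;
        inside[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = (m % 2) == 1;
      }
    }
  return inside;
}

// Signed volume and area of a triangulated surface (divergence theorem).
// [[Rcpp::export]]
NumericVector mesh_volume_area(NumericMatrix V, IntegerMatrix T) {
  double vol = 0, area = 0;
  for (int t = 0; t < T.nrow(); ++t) {
    int a = T(t,0)-1, b = T(t,1)-1, c = T(t,2)-1;
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    vol += (ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx)) / 6.0;
    double ux = bx-ax, uy = by-ay, uz = bz-az, wx = cx-ax, wy = cy-ay, wz = cz-az;
    double nx_ = uy*wz-uz*wy, ny_ = uz*wx-ux*wz, nz_ = ux*wy-uy*wx;
    area += 0.5 * std::sqrt(nx_*nx_ + ny_*ny_ + nz_*nz_);
  }
  return NumericVector::create(_["volume"] = vol, _["area"] = area);
}
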