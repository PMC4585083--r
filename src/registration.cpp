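#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Currents representation of an oriented triangulated surface: area-weighted
// face normals N_f at centroids c_f with a Gaussian kernel
// K(x,y) = exp(-|x-y|^2 / sigma^2).  The squared currents distance
//   E(S,T) = <S,S> - 2<S,T> + <T,T>,
//   <A,B>  = sum_{f in A, g in B} (N_f . N_g) K(c_f, c_g)
// is the matching term; its gradient with respect to the vertices of S
// drives the greedy diffeomorphic flow.

struct FaceData {
  std::vector<double> cx, cy, cz, nx, ny, nz;
  int n;
};

static FaceData face_data(const NumericMatrix &V, const IntegerMatrix &T) {
  FaceData F;
  F.n = T.nrow();
  F.cx.resize(F.n); F.cy.resize(F.n); F.cz.resize(F.n);
  F.nx.resize(F.n); F.ny.resize(F.n); F.nz.resize(F.n);
  for (int t = 0; t < F.n; ++t) {
    int a = T(t,0)-1, b = T(t,1)-1, c = T(t,2)-1;
    F.cx[t] = (V(a,0)+V(b,0)+V(c,0))/3.0;
    F.cy[t] = (V(a,1)+V(b,1)+V(c,1))/3.0;
    F.cz[t] = (V(a,2)+V(b,2)+V(c,2))/3.0;
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double wx = V(c,0)-V(a,0), wy = V(c,1)-V(a,1), wz = V(c,2)-V(a,2);
    F.nx[t] = 0.5*(uy*wz - uz*wy);
    F.ny[t] = 0.5*(uz*wx - ux*wz);
    F.nz[t] = 0.5*(ux*wy - uy*wx);
  }
  return F;
}

static double inner(const FaceData &A, const FaceData &B, double s2) {
  double e = 0;
  for (int f = 0; f < A.n; ++f)
    for (int g = 0; g < B.n; ++g) {
      double dx = A.cx[f]-B.cx[g], dy = A.cy[f]-B.cy[g], dz = A.cz[f]-B.cz[g];
      double k = std::exp(-(dx*dx+dy*dy+dz*dz)/s2);
      e += (A.nx[f]*B.nx[g] + A.ny[f]*B.ny[g] + A.nz[f]*B.nz[g]) * k;
    }
  return e;
}

// [[Rcpp::export]]
double currents_energy_cpp(NumericMatrix VS, IntegerMatrix TS,
                           NumericMatrix VT, IntegerMatrix TT, double sigma) {
  double s2 = sigma * sigma;
  FaceData S = face_data(VS, TS), T = face_data(VT, TT);
  return inner(S, S, s2) - 2.0 * inner(S, T, s2) + inner(T, T, s2);
}

// Gradient of E(S,T) with respect to the vertices of S.
// [[Rcpp::export]]
NumericMatrix currents_gradient_cpp(NumericMatrix VS, IntegerMatrix TS,
                                    NumericMatrix VT, IntegerMatrix TT,
                                    double sigma) {
  double s2 = sigma * sigma;
  FaceData S = face_data(VS, TS), T = face_data(VT, TT);
  int nv = VS.nrow(), nf = S.n;
  NumericMatrix G(nv, 3);
  // per-face accumulators: dE/dN_f (vector) and dE/dc_f (vector)
  std::vector<double> dNx(nf,0), dNy(nf,0), dNz(nf,0),
      dCx(nf,0), dCy(nf,0), dCz(nf,0);
  for (int f = 0; f < nf; ++f) {
    // S-S part (d/df of sum_{f,g} N_f.N_g K: both orders -> factor 2)
    for (int g = 0; g < nf; ++g) {
      double dx = S.cx[f]-S.cx[g], dy = S.cy[f]-S.cy[g], dz = S.cz[f]-S.cz[g];
      double k = std::exp(-(dx*dx+dy*dy+dz*dz)/s2);
      double ndot = S.nx[f]*S.nx[g] + S.ny[f]*S.ny[g] + S.nz[f]*S.nz[g];
      dNx[f] += 2*k*S.nx[g]; dNy[f] += 2*k*S.ny[g]; dNz[f] += 2*k*S.nz[g];
      double cf = -2.0/s2 * 2*ndot*k;
      dCx[f] += cf*dx; dCy[f] += cf*dy; dCz[f] += cf*dz;
    }
    // cross part, factor -2
    for (int g = 0; g < T.n; ++g) {
      double dx = S.cx[f]-T.cx[g], dy = S.cy[f]-T.cy[g], dz = S.cz[f]-T.cz[g];
      double k = std::exp(-(dx*dx+dy*dy+dz*dz)/s2);
      double ndot = S.nx[f]*T.nx[g] + S.ny[f]*T.ny[g] + S.nz[f]*T.nz[g];
      dNx[f] += -2*k*T.nx[g]; dNy[f] += -2*k*T.ny[g]; dNz[f] += -2*k*T.nz[g];
      double cf = -2.0/s2 * (-2.0)*ndot*k;
      dCx[f] += cf*dx; dCy[f] += cf*dy; dCz[f] += cf*dz;
    }
  }
  // chain rule to vertices: N = 0.5 (b-a)x(c-a), c = (a+b+c)/3
  for (int f = 0; f < nf; ++f) {
    int a = TS(f,0)-1, b = TS(f,1)-1, c = TS(f,2)-1;
    double M[3] = {dNx[f], dNy[f], dNz[f]};
    double A[3] = {VS(a,0), VS(a,1), VS(a,2)};
    double B[3] = {VS(b,0), VS(b,1), VS(b,2)};
    double C[3] = {VS(c,0), VS(c,1), VS(c,2)};
    auto crossadd = [&](int v, const double *p, const double *q) {
      // grad_v (N.M) = 0.5 (p - q) x M
      double ex = p[0]-q[0], ey = p[1]-q[1], ez = p[2]-q[2];
      G(v,0) += 0.5*(ey*M[2]-ez*M[1]);
      G(v,1) += 0.5*(ez*M[0]-ex*M[2]);
      G(v,2) += 0.5*(ex*M[1]-ey*M[0]);
    };
    crossadd(a, B, C);
    crossadd(b, C, A);
    crossadd(c, A, B);
    for (int d = 0; d < 3; ++d) {
      G(a,d) += (d==0?dCx[f]:d==1?dCy[f]:dCz[f]) / 3.0;
      G(b,d) += (d==0?dCx[f]:d==1?dCy[f]:dCz[f]) / 3.0;
      G(c,d) += (d==0?dCx[f]:d==1?dCy[f]:dCz[f]) / 3.0;
    }
  }
  return G;
}

// Gaussian-kernel smoothing of a vertex vector field:
// out_i = sum_j exp(-|q_i - q_j|^2/sigma^2) m_j
// [[Rcpp::export]]
NumericMatrix kernel_smooth_cpp(NumericMatrix Q, NumericMatrix M,
                                double sigma) {
  double s2 = sigma * sigma;
  int n = Q.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double ax = 0, ay = 0, az = 0;
    for (int j = 0; j < n; ++j) {
      double dx = Q(i,0)-Q(j,0), dy = Q(i,1)-Q(j,1), dz = Q(i,2)-Q(j,2);
      double k = std::exp(-(dx*dx+dy*dy+dz*dz)/s2);
      ax += k*M(j,0); ay += k*M(j,1); az += k*M(j,2);
    }
    out(i,0) = ax; out(i,1) = ay; out(i,2) = az;
  }
  return out;
}
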