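#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 26-connectivity component labeling on a 3-D logical grid.
// Labels are assigned in order of first encounter (column-major scan),
// background voxels get 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(start);
    labels[start] = next_label;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Isotropic linear-elastic stiffness for tet4 / tet10 meshes.
// Engineering-strain B matrices, constitutive matrix D(E, nu).
// tet10 uses the 4-point Gauss rule (exact for the affine geometry used here).
// Node ordering: corners 1-4, then (for tet10) edge midpoints in the order
// (1,2),(2,3),(3,1),(1,4),(2,4),(3,4).
// ---------------------------------------------------------------------------

static void dmatrix(double E, double nu, double D[6][6]) {
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) D[a][b] = 0.0;
  const double c = E / ((1.0 + nu) * (1.0 - 2.0 * nu));
  D[0][0] = D[1][1] = D[2][2] = c * (1.0 - nu);
  D[0][1] = D[0][2] = D[1][0] = D[1][2] = D[2][0] = D[2][1] = c * nu;
  D[3][3] = D[4][4] = D[5][5] = c * (1.0 - 2.0 * nu) / 2.0;
}

// gradients of barycentric coordinates for the corner tet; returns 6*volume
static double bary_grads(const double x[4][3], double gL[4][3]) {
  double a[3], b[3], c[3];
  for (int d = 0; d < 3; ++d) {
    a[d] = x[1][d] - x[0][d];
    b[d] = x[2][d] - x[0][d];
    c[d] = x[3][d] - x[0][d];
  }
  double det =
    a[0] * (b[1] * c[2] - b[2] * c[1]) -
    a[1] * (b[0] * c[2] - b[2] * c[0]) +
    a[2] * (b[0] * c[1] - b[1] * c[0]);
  // inverse transpose rows give grad L2, L3, L4
  double inv[3][3];
  inv[0][0] = (b[1] * c[2] - b[2] * c[1]) / det;
  inv[0][1] = (b[2] * c[0] - b[0] * c[2]) / det;
  inv[0][2] = (b[0] * c[1] - b[1] * c[0]) / det;
  inv[1][0] = (a[2] * c[1] - a[1] * c[2]) / det;
  inv[1][1] = (a[0] * c[2] - a[2] * c[0]) / det;
  inv[1][2] = (a[1] * c[0] - a[0] * c[1]) / det;
  inv[2][0] = (a[1] * b[2] - a[2] * b[1]) / det;
  inv[2][1] = (a[2] * b[0] - a[0] * b[2]) / det;
  inv[2][2] = (a[0] * b[1] - a[1] * b[0]) / det;
  for (int d = 0; d < 3; ++d) {
    gL[1][d] = inv[0][d];
    gL[2][d] = inv[1][d];
    gL[3][d] = inv[2][d];
    gL[0][d] = -(inv[0][d] + inv[1][d] + inv[2][d]);
  }
  return det; // 6 * signed volume
}

// shape-function gradients at barycentric point L for tet4 or tet10
static void shape_grads(int nen, const double L[4], const double gL[4][3],
                        double dN[10][3]) {
  static const int ea[6] = {0, 1, 2, 0, 1, 2};
  static const int eb[6] = {1, 2, 0, 3, 3, 3};
  if (nen == 4) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) dN[i][d] = gL[i][d];
    return;
  }
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d) dN[i][d] = (4.0 * L[i] - 1.0) * gL[i][d];
  for (int e = 0; e < 6; ++e) {
    int a = ea[e], b = eb[e];
    for (int d = 0; d < 3; ++d)
      dN[4 + e][d] = 4.0 * (L[b] * gL[a][d] + L[a] * gL[b][d]);
  }
}

// [[Rcpp::export(name = ".tet_stiffness_triplets")]]
List tet_stiffness_triplets(NumericMatrix nodes, IntegerMatrix elems,
                            NumericVector E, double nu) {
  const int m = elems.nrow();
  const int nen = elems.ncol();
  if (nen != 4 && nen != 10) stop("elements must have 4 or 10 nodes");
  if (E.size() != m) stop("one modulus per element required");
  const int ndof = 3 * nen;
  const R_xlen_t nt = (R_xlen_t)m * ndof * ndof;
  IntegerVector I(nt), J(nt);
  NumericVector X(nt);

  // Gauss points: tet4 -> centroid (exact, constant strain);
  // tet10 -> 4-point rule, weight V/4 each.
  const double ga = 0.5854101966249685, gb = 0.1381966011250105;
  double D[6][6];
  double gL[4][3], dN[10][3];
  double x[4][3];
  std::vector<double> Ke(ndof * ndof);

  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) x[i][d] = nodes(elems(e, i) - 1, d);
    double det = bary_grads(x, gL);
    double vol = det / 6.0;
    if (!(vol > 0.0))
      stop("element %d has non-positive volume", e + 1);
    dmatrix(E[e], nu, D);
    std::fill(Ke.begin(), Ke.end(), 0.0);

    int ngp = (nen == 4) ? 1 : 4;
    for (int g = 0; g < ngp; ++g) {
      double L[4];
      if (nen == 4) {
        L[0] = L[1] = L[2] = L[3] = 0.25;
      } else {
        L[0] = L[1] = L[2] = L[3] = gb;
        L[g] = ga;
      }
      double w = vol / ngp;
      shape_grads(nen, L, gL, dN);
      // B is 6 x ndof; accumulate Ke += w * B^T D B
      // B columns for node i: [dNx 0 0; 0 dNy 0; 0 0 dNz; dNy dNx 0; 0 dNz dNy; dNz 0 dNx]
      for (int i = 0; i < nen; ++i) {
        double Bi[6][3] = {
          {dN[i][0], 0, 0}, {0, dN[i][1], 0}, {0, 0, dN[i][2]},
          {dN[i][1], dN[i][0], 0}, {0, dN[i][2], dN[i][1]}, {dN[i][2], 0, dN[i][0]}
        };
        double DBi[6][3];
        for (int r = 0; r < 6; ++r)
          for (int cdof = 0; cdof < 3; ++cdof) {
            double s = 0.0;
            for (int k = 0; k < 6; ++k) s += D[r][k] * Bi[k][cdof];
            DBi[r][cdof] = s;
          }
        for (int j = 0; j < nen; ++j) {
          double Bj[6][3] = {
            {dN[j][0], 0, 0}, {0, dN[j][1], 0}, {0, 0, dN[j][2]},
            {dN[j][1], dN[j][0], 0}, {0, dN[j][2], dN[j][1]}, {dN[j][2], 0, dN[j][0]}
          };
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) {
              double s = 0.0;
              for (int r = 0; r < 6; ++r) s += Bj[r][a] * DBi[r][b];
              Ke[(3 * i + b) * ndof + (3 * j + a)] += w * s;
            }
        }
      }
    }
    for (int i = 0; i < nen; ++i)
      for (int a = 0; a < 3; ++a)
        for (int j = 0; j < nen; ++j)
          for (int b = 0; b < 3; ++b) {
            I[pos] = 3 * (elems(e, i) - 1) + a + 1;
            J[pos] = 3 * (elems(e, j) - 1) + b + 1;
            X[pos] = Ke[(3 * i + a) * ndof + (3 * j + b)];
            ++pos;
          }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}

// [[Rcpp::export(name = ".tet_element_strains")]]
NumericMatrix tet_element_strains(NumericMatrix nodes, IntegerMatrix elems,
                                  NumericMatrix U) {
  const int m = elems.nrow();
  const int nen = elems.ncol();
  if (nen != 4 && nen != 10) stop("elements must have 4 or 10 nodes");
  NumericMatrix S(m, 6); // exx eyy ezz exy eyz exz (tensor shear)
  double gL[4][3], dN[10][3], x[4][3];
  const double Lc[4] = {0.25, 0.25, 0.25, 0.25};
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) x[i][d] = nodes(elems(e, i) - 1, d);
    bary_grads(x, gL);
    shape_grads(nen, Lc, gL, dN);
    double g[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}}; // grad u
    for (int i = 0; i < nen; ++i) {
      int nd = elems(e, i) - 1;
      for (int a = 0; a < 3; ++a)
        for (int d = 0; d < 3; ++d)
          g[a][d] += U(nd, a) * dN[i][d];
    }
    S(e, 0) = g[0][0];
    S(e, 1) = g[1][1];
    S(e, 2) = g[2][2];
    S(e, 3) = 0.5 * (g[0][1] + g[1][0]);
    S(e, 4) = 0.5 * (g[1][2] + g[2][1]);
    S(e, 5) = 0.5 * (g[0][2] + g[2][0]);
  }
  return S;
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle distances (Ericson closest-point construction),
// brute force or accelerated with a uniform grid over triangle bounding boxes.
// ---------------------------------------------------------------------------

static double tri_dist2(const double p[3], const double a[3],
                        const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int d=0;d<3;++d) q[d]=a[d]; goto done; }
  {
    double bp[3];
    for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { for (int d=0;d<3;++d) q[d]=b[d]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = d1 / (d1 - d3);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + v * ab[d];
      goto done;
    }
    double cp[3];
    for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { for (int d=0;d<3;++d) q[d]=c[d]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = d2 / (d2 - d6);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + w * ac[d];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int d = 0; d < 3; ++d) q[d] = b[d] + w * (c[d] - b[d]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int d = 0; d < 3; ++d) q[d] = a[d] + ab[d] * v + ac[d] * w;
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export(name = ".point_tri_min_dist")]]
NumericVector point_tri_min_dist(NumericMatrix pts, NumericMatrix ta,
                                 NumericMatrix tb, NumericMatrix tc,
                                 bool use_index, double cell) {
  const int np = pts.nrow(), nt = ta.nrow();
  if (nt == 0) stop("empty triangle set");
  NumericVector out(np);
  double p[3], a[3], b[3], c[3];

  if (!use_index) {
    for (int i = 0; i < np; ++i) {
      for (int d = 0; d < 3; ++d) p[d] = pts(i, d);
      double best = R_PosInf;
      for (int t = 0; t < nt; ++t) {
        for (int d = 0; d < 3; ++d) {
          a[d] = ta(t, d); b[d] = tb(t, d); c[d] = tc(t, d);
        }
        double d2 = tri_dist2(p, a, b, c);
        if (d2 < best) best = d2;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }

  // uniform grid over triangle bounding boxes
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int t = 0; t < nt; ++t)
    for (int d = 0; d < 3; ++d) {
      double mn = std::min(ta(t, d), std::min(tb(t, d), tc(t, d)));
      double mx = std::max(ta(t, d), std::max(tb(t, d), tc(t, d)));
      lo[d] = std::min(lo[d], mn); hi[d] = std::max(hi[d], mx);
    }
  int gx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / cell));
  int gy = std::max(1, (int)std::ceil((hi[1] - lo[1]) / cell));
  int gz = std::max(1, (int)std::ceil((hi[2] - lo[2]) / cell));
  std::vector< std::vector<int> > buckets((size_t)gx * gy * gz);
  for (int t = 0; t < nt; ++t) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double mn = std::min(ta(t, d), std::min(tb(t, d), tc(t, d)));
      double mx = std::max(ta(t, d), std::max(tb(t, d), tc(t, d)));
      int i0 = (int)std::floor((mn - lo[d]) / cell);
      int i1 = (int)std::floor((mx - lo[d]) / cell);
      int gmax = (d == 0 ? gx : (d == 1 ? gy : gz)) - 1;
      c0[d] = std::max(0, std::min(i0, gmax));
      c1[d] = std::max(0, std::min(i1, gmax));
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          buckets[i + (size_t)gx * (j + (size_t)gy * k)].push_back(t);
  }
  int max_ring = std::max(gx, std::max(gy, gz));
  for (int ip = 0; ip < np; ++ip) {
    for (int d = 0; d < 3; ++d) p[d] = pts(ip, d);
    int ci = std::max(0, std::min(gx - 1, (int)std::floor((p[0] - lo[0]) / cell)));
    int cj = std::max(0, std::min(gy - 1, (int)std::floor((p[1] - lo[1]) / cell)));
    int ck = std::max(0, std::min(gz - 1, (int)std::floor((p[2] - lo[2]) / cell)));
    double best = R_PosInf;
    for (int r = 0; r <= max_ring; ++r) {
      // once every triangle within ring r-1 cells has been checked, any
      // remaining triangle is at least (r-1)*cell away
      if (best < R_PosInf && (double)(r - 1) * cell > std::sqrt(best)) break;
      bool any_cell = false;
      for (int k = std::max(0, ck - r); k <= std::min(gz - 1, ck + r); ++k)
        for (int j = std::max(0, cj - r); j <= std::min(gy - 1, cj + r); ++j)
          for (int i = std::max(0, ci - r); i <= std::min(gx - 1, ci + r); ++i) {
            int ring = std::max(std::abs(i - ci),
                        std::max(std::abs(j - cj), std::abs(k - ck)));
            if (ring != r) continue;
            any_cell = true;
            const std::vector<int> &bk = buckets[i + (size_t)gx * (j + (size_t)gy * k)];
            for (size_t s = 0; s < bk.size(); ++s) {
              int t = bk[s];
              for (int d = 0; d < 3; ++d) {
                a[d] = ta(t, d); b[d] = tb(t, d); c[d] = tc(t, d);
              }
              double d2 = tri_dist2(p, a, b, c);
              if (d2 < best) best = d2;
            }
          }
      if (!any_cell && best < R_PosInf) break;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}
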