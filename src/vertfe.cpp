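#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected (face-connected) component labelling of a 3D mask.
// `mask` is a logical/integer vector in R array order [z, y, x]
// (z fastest); returns integer labels, 0 = background, components
// numbered from 1 in order of first (lowest linear index) encounter.
// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed]) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && !labels[w]) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Matrix-free product K * u for a voxel mesh with one shared 24x24 element
// stiffness. elem_nodes: nelem x 8 (1-based node ids); u: length 3*nnodes,
// dof order node-major with components (x, y, z).
// [[Rcpp::export(name = ".fe_matvec")]]
NumericVector fe_matvec(IntegerMatrix elem_nodes, NumericMatrix Ke,
                        NumericVector u) {
  const int nelem = elem_nodes.nrow();
  NumericVector out(u.size());
  double K[24][24];
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) K[i][j] = Ke(i, j);
  const int *en = elem_nodes.begin();
  const double *up = u.begin();
  double *op = out.begin();
  double ue[24], fe[24];
  for (int e = 0; e < nelem; ++e) {
    int base[8];
    for (int a = 0; a < 8; ++a) {
      base[a] = 3 * (en[e + (R_xlen_t)a * nelem] - 1);
      ue[3 * a]     = up[base[a]];
      ue[3 * a + 1] = up[base[a] + 1];
      ue[3 * a + 2] = up[base[a] + 2];
    }
    for (int i = 0; i < 24; ++i) {
      double s = 0.0;
      for (int j = 0; j < 24; ++j) s += K[i][j] * ue[j];
      fe[i] = s;
    }
    for (int a = 0; a < 8; ++a) {
      op[base[a]]     += fe[3 * a];
      op[base[a] + 1] += fe[3 * a + 1];
      op[base[a] + 2] += fe[3 * a + 2];
    }
  }
  return out;
}

// Diagonal of the assembled stiffness (for Jacobi preconditioning).
// [[Rcpp::export(name = ".fe_diag")]]
NumericVector fe_diag(IntegerMatrix elem_nodes, NumericMatrix Ke, int nnodes) {
  const int nelem = elem_nodes.nrow();
  NumericVector out(3 * (R_xlen_t)nnodes);
  for (int e = 0; e < nelem; ++e) {
    for (int a = 0; a < 8; ++a) {
      int b = 3 * (elem_nodes(e, a) - 1);
      out[b]     += Ke(3 * a, 3 * a);
      out[b + 1] += Ke(3 * a + 1, 3 * a + 1);
      out[b + 2] += Ke(3 * a + 2, 3 * a + 2);
    }
  }
  return out;
}

// Assembled stiffness triplets restricted to element list; used for the
// sparse (small-mesh) solver path. Returns i, j (1-based dof ids) and x.
// [[Rcpp::export(name = ".fe_triplets")]]
List fe_triplets(IntegerMatrix elem_nodes, NumericMatrix Ke) {
  const int nelem = elem_nodes.nrow();
  const R_xlen_t nnz = (R_xlen_t)nelem * 576;
  IntegerVector ti(nnz), tj(nnz);
  NumericVector tx(nnz);
  R_xlen_t k = 0;
  for (int e = 0; e < nelem; ++e) {
    int dofs[24];
    for (int a = 0; a < 8; ++a) {
      int b = 3 * (elem_nodes(e, a) - 1);
      dofs[3 * a] = b + 1;
      dofs[3 * a + 1] = b + 2;
      dofs[3 * a + 2] = b + 3;
    }
    for (int i = 0; i < 24; ++i)
      for (int j = 0; j < 24; ++j) {
        ti[k] = dofs[i];
        tj[k] = dofs[j];
        tx[k] = Ke(i, j);
        ++k;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}
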