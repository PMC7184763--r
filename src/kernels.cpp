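#include <Rcpp.h>
#include <map>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Gauss-Seidel sweeps on a CSR matrix. Iterates
//   x_i <- (b_i - sum_{j != i} a_ij x_j) / a_ii
// in natural order until the relative residual ||b - Ax|| / ||b|| drops
// below tol or max_iter sweeps have run. Diagonal entries must be nonzero.
// [[Rcpp::export(name = ".gs_csr")]]
List gs_csr(IntegerVector row_ptr, IntegerVector col_idx, NumericVector vals,
            NumericVector b, NumericVector x0, double tol, int max_iter) {
  const int n = b.size();
  NumericVector x = clone(x0);
  std::vector<double> diag(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
      if (col_idx[k] == i) diag[i] = vals[k];
    if (diag[i] == 0.0) stop("singular diagonal");
  }
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rel = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double s = b[i];
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) {
        int j = col_idx[k];
        if (j != i) s -= vals[k] * x[j];
      }
      x[i] = s / diag[i];
    }
    double rn = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = b[i];
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        r -= vals[k] * x[col_idx[k]];
      rn += r * r;
    }
    rel = std::sqrt(rn) / bnorm;
    if (rel <= tol) { ++it; break; }
  }
  return List::create(_["x"] = x, _["residual"] = rel, _["iterations"] = it,
                      _["converged"] = rel <= tol);
}

// Marching tetrahedra over a corner-value grid.
// values: (nx+1)*(ny+1)*(nz+1) corner scalars, x fastest;
// each cell is split into 6 tetrahedra sharing the main diagonal
// (corner 0 to corner 7); surface vertices are interpolated linearly on
// tet edges and welded by (cornerA, cornerB) edge key.
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector values, int nx, int ny, int nz,
                double iso, NumericVector origin, double h) {
  const int sx = 1, sy = nx + 1, sz = (nx + 1) * (ny + 1);
  // 6-tet decomposition of the cube using local corner ids 0..7
  // (corner id bit0 = x, bit1 = y, bit2 = z)
  static const int tets[6][4] = {
    {0, 5, 1, 3}, {0, 5, 3, 7}, {0, 5, 7, 4},
    {0, 3, 2, 7}, {0, 2, 6, 7}, {0, 4, 7, 6}};
  std::map<std::pair<int, int>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto corner_pos = [&](int gid, double *p) {
    int iz = gid / sz, rem = gid % sz;
    int iy = rem / sy, ix = rem % sy;
    p[0] = origin[0] + ix * h;
    p[1] = origin[1] + iy * h;
    p[2] = origin[2] + iz * h;
  };
  auto edge_vert = [&](int ga, int gb) {
    if (ga > gb) std::swap(ga, gb);
    auto key = std::make_pair(ga, gb);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = values[ga], fb = values[gb];
    double t = (iso - fa) / (fb - fa);
    if (!std::isfinite(t)) t = 0.5;
    t = std::min(1.0, std::max(0.0, t));
    double pa[3], pb[3];
    corner_pos(ga, pa); corner_pos(gb, pb);
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int base = ix * sx + iy * sy + iz * sz;
        int g[8];
        for (int c = 0; c < 8; ++c)
          g[c] = base + (c & 1) * sx + ((c >> 1) & 1) * sy + ((c >> 2) & 1) * sz;
        for (int t = 0; t < 6; ++t) {
          int a = g[tets[t][0]], b = g[tets[t][1]],
              c = g[tets[t][2]], d = g[tets[t][3]];
          bool ia = values[a] < iso, ib = values[b] < iso,
               ic = values[c] < iso, id_ = values[d] < iso;
          int ninside = ia + ib + ic + id_;
          if (ninside == 0 || ninside == 4) continue;
          // orient so the "inside" set is first
          int vs[4] = {a, b, c, d};
          bool in[4] = {ia, ib, ic, id_};
          if (ninside == 1 || ninside == 3) {
            bool want = (ninside == 1);
            int k = 0;
            for (int q = 0; q < 4; ++q) if (in[q] == want) k = q;
            int lone = vs[k];
            int others[3]; int m = 0;
            for (int q = 0; q < 4; ++q) if (q != k) others[m++] = vs[q];
            int e0 = edge_vert(lone, others[0]);
            int e1 = edge_vert(lone, others[1]);
            int e2 = edge_vert(lone, others[2]);
            tri.push_back(e0); tri.push_back(e1); tri.push_back(e2);
          } else { // 2 inside, 2 outside: quad -> two triangles
            int ins[2], outs[2]; int mi = 0, mo = 0;
            for (int q = 0; q < 4; ++q) {
              if (in[q]) ins[mi++] = vs[q]; else outs[mo++] = vs[q];
            }
            int e00 = edge_vert(ins[0], outs[0]);
            int e01 = edge_vert(ins[0], outs[1]);
            int e10 = edge_vert(ins[1], outs[0]);
            int e11 = edge_vert(ins[1], outs[1]);
            tri.push_back(e00); tri.push_back(e01); tri.push_back(e11);
            tri.push_back(e00); tri.push_back(e11); tri.push_back(e10);
          }
        }
      }

  int nv = vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  int nt = tri.size() / 3;
  IntegerMatrix Fm(nt, 3);
  for (int i = 0; i < nt; ++i) {
    Fm(i, 0) = tri[3 * i] + 1; Fm(i, 1) = tri[3 * i + 1] + 1;
    Fm(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Gradient descent for the 3-parameter logistic curve
//   N(t) = K / (1 + (K/N0 - 1) exp(-r t))
// minimizing the residual sum of squares over theta = (log N0, log K, log r)
// (log transform keeps all parameters positive). Fixed learning rate with
// halving on any RSS increase. Values are expected pre-scaled by the caller.
// [[Rcpp::export(name = ".logistic_gd")]]
List logistic_gd(NumericVector t, NumericVector y,
                 double n0_init, double k_init, double r_init,
                 double lr, int max_iter, double ftol) {
  const int n = t.size();
  double th[3] = {std::log(n0_init), std::log(k_init), std::log(r_init)};
  auto rss = [&](const double *p) {
    double N0 = std::exp(p[0]), K = std::exp(p[1]), r = std::exp(p[2]);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double pred = K / (1.0 + (K / N0 - 1.0) * std::exp(-r * t[i]));
      double e = pred - y[i];
      s += e * e;
    }
    return s;
  };
  double f = rss(th);
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    double N0 = std::exp(th[0]), K = std::exp(th[1]), r = std::exp(th[2]);
    double g[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < n; ++i) {
      double E = std::exp(-r * t[i]);
      double A = K / N0 - 1.0;
      double den = 1.0 + A * E;
      double pred = K / den;
      double e = pred - y[i];
      // dpred/dK = 1/den - K * (E/N0) / den^2
      double dK = 1.0 / den - K * (E / N0) / (den * den);
      // dpred/dN0 = K * (K/N0^2) * E / den^2
      double dN0 = K * (K / (N0 * N0)) * E / (den * den);
      // dpred/dr = K * A * t * E / den^2
      double dr = K * A * t[i] * E / (den * den);
      g[0] += 2.0 * e * dN0 * N0;  // chain rule through log
      g[1] += 2.0 * e * dK * K;
      g[2] += 2.0 * e * dr * r;
    }
    double step = lr;
    double trial[3], ftrial = R_PosInf;
    int halvings = 0;
    while (halvings < 40) {
      for (int j = 0; j < 3; ++j) trial[j] = th[j] - step * g[j];
      ftrial = rss(trial);
      if (ftrial <= f) break;
      step *= 0.5; ++halvings;
    }
    if (ftrial > f) { converged = true; break; }  // cannot descend further
    double df = f - ftrial;
    for (int j = 0; j < 3; ++j) th[j] = trial[j];
    f = ftrial;
    if (df < ftol * (1.0 + f)) { converged = true; ++it; break; }
  }
  return List::create(_["n0"] = std::exp(th[0]), _["k"] = std::exp(th[1]),
                      _["r"] = std::exp(th[2]), _["rss"] = f,
                      _["iterations"] = it, _["converged"] = converged);
}
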