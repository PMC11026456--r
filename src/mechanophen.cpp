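#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first search.
// connectivity must be 4 or 8; labels are assigned in raster-scan order so
// they are contiguous positive integers.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> qi, qj;
  qi.reserve(nr * nc / 4 + 1);
  qj.reserve(nr * nc / 4 + 1);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      size_t head = 0;
      while (head < qi.size()) {
        const int ci = qi[head], cj = qj[head];
        ++head;
        for (int n = 0; n < nnb; ++n) {
          const int ni = ci + di8[n], nj = cj + dj8[n];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation (dilate = true) or erosion with a disk structuring element
// of the given pixel radius. Outside the image counts as background.
// [[Rcpp::export]]
LogicalMatrix morph_disk_cpp(const LogicalMatrix& mask, double radius, bool dilate) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> oi, oj;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if ((double)(di * di + dj * dj) <= radius * radius + 1e-9) {
        oi.push_back(di); oj.push_back(dj);
      }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool hit = dilate ? false : true;
      for (size_t n = 0; n < oi.size(); ++n) {
        const int ni = i + oi[n], nj = j + oj[n];
        const bool v = (ni >= 0 && ni < nr && nj >= 0 && nj < nc) ? (bool)mask(ni, nj) : false;
        if (dilate) { if (v) { hit = true; break; } }
        else        { if (!v) { hit = false; break; } }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// Direct real-space summation of the Boussinesq half-space surface solution:
// u(x) = sum_src G(x - x_src) T(x_src) h^2, with
// G(r) = (1+nu)/(pi E r^3) [ (1-nu) r^2 + nu x^2,  nu x y ;
//                            nu x y,  (1-nu) r^2 + nu y^2 ].
// The singular self-cell contribution is integrated numerically on a
// self_sub x self_sub subgrid of the grid cell. Sources with |T| below
// rel_tol * max|T| are skipped (compact-support shortcut).
// Matrices are indexed [row i -> y, col j -> x]; h is the grid spacing.
// [[Rcpp::export]]
List boussinesq_direct_cpp(const NumericMatrix& tx, const NumericMatrix& ty,
                           double h, double E, double nu,
                           double rel_tol, int self_sub) {
  const int nr = tx.nrow(), nc = tx.ncol();
  NumericMatrix ux(nr, nc), uy(nr, nc);
  const double pref = (1.0 + nu) / (M_PI * E);
  double tmax = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double m = std::sqrt(tx(i, j) * tx(i, j) + ty(i, j) * ty(i, j));
      if (m > tmax) tmax = m;
    }
  const double thr = rel_tol * tmax;
  // subgrid offsets for the self cell (never lands on r = 0 for even self_sub)
  std::vector<double> sox, soy;
  const double sub_h = h / self_sub;
  for (int u = 0; u < self_sub; ++u)
    for (int v = 0; v < self_sub; ++v) {
      sox.push_back((u + 0.5) * sub_h - 0.5 * h);
      soy.push_back((v + 0.5) * sub_h - 0.5 * h);
    }
  const double sub_dA = sub_h * sub_h;
  const double dA = h * h;
  for (int js = 0; js < nc; ++js) {
    for (int is = 0; is < nr; ++is) {
      const double fx = tx(is, js), fy = ty(is, js);
      if (std::sqrt(fx * fx + fy * fy) <= thr) continue;
      for (int jt = 0; jt < nc; ++jt) {
        const double dx = (jt - js) * h;
        for (int it = 0; it < nr; ++it) {
          const double dy = (it - is) * h;
          if (it == is && jt == js) {
            double gxx = 0.0, gyy = 0.0, gxy = 0.0;
            for (size_t n = 0; n < sox.size(); ++n) {
              const double x = sox[n], y = soy[n];
              const double r2 = x * x + y * y;
              const double r = std::sqrt(r2);
              const double inv_r3 = 1.0 / (r2 * r);
              gxx += ((1.0 - nu) * r2 + nu * x * x) * inv_r3;
              gyy += ((1.0 - nu) * r2 + nu * y * y) * inv_r3;
              gxy += nu * x * y * inv_r3;
            }
            ux(it, jt) += pref * sub_dA * (gxx * fx + gxy * fy);
            uy(it, jt) += pref * sub_dA * (gxy * fx + gyy * fy);
          } else {
            const double r2 = dx * dx + dy * dy;
            const double r = std::sqrt(r2);
            const double c = pref * dA / (r2 * r);
            ux(it, jt) += c * (((1.0 - nu) * r2 + nu * dx * dx) * fx + nu * dx * dy * fy);
            uy(it, jt) += c * (nu * dx * dy * fx + ((1.0 - nu) * r2 + nu * dy * dy) * fy);
          }
        }
      }
    }
  }
  return List::create(_["ux"] = ux, _["uy"] = uy);
}
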