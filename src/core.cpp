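#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential hard-core (RSA) placement of disks on a rectangle.
// Candidate diameters are pre-drawn in R (so the diameter law stays an R-side
// concern); centers are drawn here from R's RNG, keeping the whole draw
// reproducible under set.seed(). A uniform cell grid sized to the maximal
// interaction radius makes each acceptance test O(1) amortized.
// [[Rcpp::export]]
List rsa_place(int n_target, NumericVector diam_pool_nm,
               double field_w_nm, double field_h_nm, double min_gap_nm) {
  int max_attempts = diam_pool_nm.size();
  std::vector<double> xs, ys, ds;
  xs.reserve(n_target); ys.reserve(n_target); ds.reserve(n_target);

  double dmax = 0.0;
  for (int i = 0; i < max_attempts; ++i)
    if (diam_pool_nm[i] > dmax) dmax = diam_pool_nm[i];
  double cell = std::max(dmax + min_gap_nm, 1e-9);
  int ncx = std::max(1, (int)std::floor(field_w_nm / cell));
  int ncy = std::max(1, (int)std::floor(field_h_nm / cell));
  double cw = field_w_nm / ncx, ch = field_h_nm / ncy;
  std::vector< std::vector<int> > grid((size_t)ncx * ncy);

  int attempts = 0;
  RNGScope scope;
  while ((int)xs.size() < n_target && attempts < max_attempts) {
    double d = diam_pool_nm[attempts];
    double x = unif_rand() * field_w_nm;
    double y = unif_rand() * field_h_nm;
    ++attempts;
    int cx = std::min(ncx - 1, (int)(x / cw));
    int cy = std::min(ncy - 1, (int)(y / ch));
    bool ok = true;
    for (int ix = std::max(0, cx - 1); ix <= std::min(ncx - 1, cx + 1) && ok; ++ix)
      for (int iy = std::max(0, cy - 1); iy <= std::min(ncy - 1, cy + 1) && ok; ++iy) {
        const std::vector<int>& bucket = grid[(size_t)ix * ncy + iy];
        for (size_t k = 0; k < bucket.size(); ++k) {
          int j = bucket[k];
          double need = 0.5 * (d + ds[j]) + min_gap_nm;
          double dx = x - xs[j], dy = y - ys[j];
          if (dx * dx + dy * dy < need * need) { ok = false; break; }
        }
      }
    if (ok) {
      grid[(size_t)cx * ncy + cy].push_back((int)xs.size());
      xs.push_back(x); ys.push_back(y); ds.push_back(d);
    }
  }
  return List::create(_["x_nm"] = wrap(xs), _["y_nm"] = wrap(ys),
                      _["d_nm"] = wrap(ds), _["attempts"] = attempts);
}

static double disk_coverage(double pr, double pc, double cr, double cc,
                            double rad, int ss) {
  // Fraction of the unit pixel [pr,pr+1)x[pc,pc+1) covered by the disk,
  // estimated by ss x ss midpoint supersampling (boundary pixels only;
  // callers short-circuit clearly-inside / clearly-outside pixels).
  int inside = 0;
  double step = 1.0 / ss, half = step / 2.0;
  for (int a = 0; a < ss; ++a)
    for (int b = 0; b < ss; ++b) {
      double dr = pr + half + a * step - cr;
      double dc = pc + half + b * step - cc;
      if (dr * dr + dc * dc <= rad * rad) ++inside;
    }
  return (double)inside / (ss * ss);
}

// Render anti-aliased dark disks on a bright background. Centers/radii are in
// pixel units; pixel (r,c) spans [r,r+1)x[c,c+1). Coverage from overlapping
// anti-aliasing fringes accumulates and is clamped to 1.
// [[Rcpp::export]]
NumericMatrix render_disks(int nrow, int ncol,
                           NumericVector ctr_row_px, NumericVector ctr_col_px,
                           NumericVector radius_px,
                           double fibril_intensity, double background_intensity,
                           int supersample) {
  NumericMatrix cov(nrow, ncol);
  double hd = std::sqrt(0.5); // half-diagonal of a pixel
  for (int i = 0; i < ctr_row_px.size(); ++i) {
    double cr = ctr_row_px[i], cc = ctr_col_px[i], rad = radius_px[i];
    int r0 = std::max(0, (int)std::floor(cr - rad - 1.0));
    int r1 = std::min(nrow - 1, (int)std::ceil(cr + rad + 1.0));
    int c0 = std::max(0, (int)std::floor(cc - rad - 1.0));
    int c1 = std::min(ncol - 1, (int)std::ceil(cc + rad + 1.0));
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c) {
        double dr = r + 0.5 - cr, dc = c + 0.5 - cc;
        double dist = std::sqrt(dr * dr + dc * dc);
        double add;
        if (dist <= rad - hd) add = 1.0;
        else if (dist >= rad + hd) add = 0.0;
        else add = disk_coverage((double)r, (double)c, cr, cc, rad, supersample);
        if (add > 0.0) {
          double v = cov(r, c) + add;
          cov(r, c) = v > 1.0 ? 1.0 : v;
        }
      }
  }
  NumericMatrix img(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c)
      img(r, c) = background_intensity +
        cov(r, c) * (fibril_intensity - background_intensity);
  return img;
}

// Connected-component labeling by flood fill, 4- or 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int *dr = connectivity == 8 ? dr8 : dr4;
  int *dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  return lab;
}

// Per-component area, centroid sums (0-based pixel indices) and count of
// exposed 4-neighbor edges (image border counts as exposure).
// [[Rcpp::export]]
DataFrame component_features(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  int nlab = 0;
  for (int i = 0; i < nr * nc; ++i) if (lab[i] > nlab) nlab = lab[i];
  std::vector<double> area(nlab, 0.0), sr(nlab, 0.0), sc(nlab, 0.0);
  std::vector<double> edges(nlab, 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int k = l - 1;
      area[k] += 1.0; sr[k] += r; sc[k] += c;
      if (r == 0      || lab(r - 1, c) != l) edges[k] += 1.0;
      if (r == nr - 1 || lab(r + 1, c) != l) edges[k] += 1.0;
      if (c == 0      || lab(r, c - 1) != l) edges[k] += 1.0;
      if (c == nc - 1 || lab(r, c + 1) != l) edges[k] += 1.0;
    }
  NumericVector a(nlab), crow(nlab), ccol(nlab), ed(nlab);
  for (int k = 0; k < nlab; ++k) {
    a[k] = area[k];
    crow[k] = sr[k] / area[k];
    ccol[k] = sc[k] / area[k];
    ed[k] = edges[k];
  }
  return DataFrame::create(_["label"] = seq(1, nlab), _["area_px"] = a,
                           _["centroid_row"] = crow, _["centroid_col"] = ccol,
                           _["boundary_edges"] = ed);
}

// Per-window centroid counts for the density estimator: window i counts
// centroids with row in [r0[i], r0[i]+w) and col in [c0[i], c0[i]+w).
// [[Rcpp::export]]
IntegerVector window_counts(NumericVector rows, NumericVector cols,
                            IntegerVector r0, IntegerVector c0, int w) {
  int nw = r0.size(), nd = rows.size();
  IntegerVector out(nw);
  for (int i = 0; i < nw; ++i) {
    int cnt = 0;
    double rlo = r0[i], rhi = r0[i] + (double)w;
    double clo = c0[i], chi = c0[i] + (double)w;
    for (int j = 0; j < nd; ++j)
      if (rows[j] >= rlo && rows[j] < rhi && cols[j] >= clo && cols[j] < chi)
        ++cnt;
    out[i] = cnt;
  }
  return out;
}
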