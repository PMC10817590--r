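#include <Rcpp.h>
using namespace Rcpp;

static inline double clip8(double v) {
  v = std::round(v);
  if (v < 0) return 0;
  if (v > 255) return 255;
  return v;
}

// Assemble an OCT-like intensity volume from integer layer-top indices and
// per-layer en-face texture fields.
//
// tops: npix x (L+1) matrix of 0-based integer surface depths (ceil of the
//       fractional interfaces); voxel with 0-based depth dd lies in layer k
//       iff tops(p,k) <= dd < tops(p,k+1).
// fields: npix x L matrix, additive en-face texture per layer (constant in
//       depth within a layer).
// base: length-L mean reflectivity per layer; voxels outside the retina take
//       the constant `background` (no noise there: those voxels never enter
//       a layer projection).
// Gaussian depth-independent noise with sd `noise_sd` is added per retinal
// voxel, values are rounded and clipped to [0, 255]. Pixel index p
// corresponds to (bscan b, ascan a) with p = b + a * n_bscan, matching an R
// array of dim (n_bscan, n_depth, n_ascan) filled column-major.
// [[Rcpp::export]]
NumericVector assemble_volume_cpp(IntegerMatrix tops, NumericMatrix fields,
                                  NumericVector base, double background,
                                  double noise_sd, int n_bscan, int n_depth,
                                  int n_ascan) {
  const int nsurf = tops.ncol();
  const int nlay = nsurf - 1;
  const double bg = clip8(background);
  NumericVector out((R_xlen_t)n_bscan * n_depth * n_ascan, bg);
  for (int a = 0; a < n_ascan; ++a) {
    for (int b = 0; b < n_bscan; ++b) {
      const int p = b + a * n_bscan;
      const R_xlen_t off = (R_xlen_t)b + (R_xlen_t)a * n_bscan * n_depth;
      for (int k = 0; k < nlay; ++k) {
        const int d0 = tops(p, k), d1 = tops(p, k + 1);
        const double mu = base[k] + fields(p, k);
        for (int d = d0; d < d1 && d < n_depth; ++d) {
          double v = mu;
          if (noise_sd > 0) v += R::rnorm(0.0, noise_sd);
          out[off + (R_xlen_t)d * n_bscan] = clip8(v);
        }
      }
    }
  }
  return out;
}

// Depth-average a volume between integer depth spans [top, bot) per en-face
// pixel. Returns c(values, mask) stacked: first npix entries are the means
// (NA where the span is empty), next npix entries are 1/0 validity flags.
// [[Rcpp::export]]
NumericVector mvf_project_cpp(NumericVector vol, IntegerVector top,
                              IntegerVector bot, int n_bscan, int n_depth,
                              int n_ascan) {
  const int npix = n_bscan * n_ascan;
  NumericVector out(2 * (R_xlen_t)npix);
  for (int a = 0; a < n_ascan; ++a) {
    for (int b = 0; b < n_bscan; ++b) {
      const int p = b + a * n_bscan;
      const int t = top[p], s = bot[p];
      if (s <= t) {
        out[p] = NA_REAL;
        out[npix + p] = 0.0;
        continue;
      }
      double acc = 0.0;
      for (int d = t; d < s; ++d) {
        acc += vol[(R_xlen_t)b + (R_xlen_t)d * n_bscan +
                   (R_xlen_t)a * n_bscan * n_depth];
      }
      out[p] = acc / (s - t);
      out[npix + p] = 1.0;
    }
  }
  return out;
}

// Mean-pool runs of `f` consecutive columns; NA marks invalid pixels. A
// pooled pixel is the mean of its valid sources, NA only if none is valid.
// Returns c(values, validity) stacked, each nr x (nc / f).
// [[Rcpp::export]]
NumericVector pool_columns_cpp(NumericMatrix v, int f) {
  const int nr = v.nrow(), nc = v.ncol(), no = nc / f;
  NumericVector out(2 * (R_xlen_t)nr * no);
  for (int g = 0; g < no; ++g) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0; int cnt = 0;
      for (int s = 0; s < f; ++s) {
        const double x = v(r, g * f + s);
        if (!ISNAN(x)) { acc += x; ++cnt; }
      }
      const R_xlen_t o = (R_xlen_t)r + (R_xlen_t)g * nr;
      out[o] = cnt > 0 ? acc / cnt : NA_REAL;
      out[(R_xlen_t)nr * no + o] = cnt > 0 ? 1.0 : 0.0;
    }
  }
  return out;
}

static inline double xlog2(double p) { return p > 0 ? p * std::log2(p) : 0.0; }

// The 21 GLCM texture features of a normalized symmetric co-occurrence
// matrix, grey levels indexed 1..n. Order matches glcm_feature_names().
// sv_about: 0 = Sum Variance about Sum Average (standard erratum fix),
//           1 = about Sum Entropy (the misprinted original).
// dv_variant: 0 = Difference Variance as the variance of p_{x-y},
//             1 = its raw second moment.
// [[Rcpp::export]]
NumericVector glcm_features_cpp(NumericMatrix P, int sv_about, int dv_variant) {
  const int n = P.nrow();
  std::vector<double> px(n, 0.0), py(n, 0.0);
  std::vector<double> p_sum(2 * n - 1, 0.0);  // k = 2..2n at index k-2
  std::vector<double> p_diff(n, 0.0);         // k = 0..n-1
  double autoc = 0, contrast = 0, dissim = 0, homog = 0, invdiff = 0;
  double idmn = 0, idn = 0, energy = 0, entropy = 0, maxp = 0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double p = P(i, j);
      const int I = i + 1, J = j + 1, ad = std::abs(i - j);
      px[i] += p; py[j] += p;
      p_sum[I + J - 2] += p;
      p_diff[ad] += p;
      autoc += p * I * J;
      contrast += p * ad * ad;
      dissim += p * ad;
      homog += p / (1.0 + ad * ad);
      invdiff += p / (1.0 + ad);
      idmn += p / (1.0 + (double)(ad * ad) / (n * n));
      idn += p / (1.0 + (double)ad / n);
      energy += p * p;
      entropy -= xlog2(p);
      if (p > maxp) maxp = p;
    }
  }
  double mu_x = 0, mu_y = 0;
  for (int i = 0; i < n; ++i) { mu_x += (i + 1) * px[i]; mu_y += (i + 1) * py[i]; }
  double var_x = 0, var_y = 0, hx = 0, hy = 0;
  for (int i = 0; i < n; ++i) {
    var_x += (i + 1 - mu_x) * (i + 1 - mu_x) * px[i];
    var_y += (i + 1 - mu_y) * (i + 1 - mu_y) * py[i];
    hx -= xlog2(px[i]); hy -= xlog2(py[i]);
  }
  double shade = 0, prom = 0;
  double sum_avg = 0, sum_ent = 0;
  for (int k = 2; k <= 2 * n; ++k) {
    const double p = p_sum[k - 2];
    const double c = k - mu_x - mu_y;
    shade += c * c * c * p;
    prom += c * c * c * c * p;
    sum_avg += k * p;
    sum_ent -= xlog2(p);
  }
  const double sv_centre = sv_about == 0 ? sum_avg : sum_ent;
  double sum_var = 0;
  for (int k = 2; k <= 2 * n; ++k) {
    sum_var += (k - sv_centre) * (k - sv_centre) * p_sum[k - 2];
  }
  double diff_ent = 0, mu_d = 0;
  for (int k = 0; k < n; ++k) { diff_ent -= xlog2(p_diff[k]); mu_d += k * p_diff[k]; }
  double diff_var = 0;
  for (int k = 0; k < n; ++k) {
    const double c = dv_variant == 0 ? (k - mu_d) : (double)k;
    diff_var += c * c * p_diff[k];
  }
  double corr = (var_x > 0 && var_y > 0)
                    ? (autoc - mu_x * mu_y) / std::sqrt(var_x * var_y)
                    : 0.0;
  double hxy1 = 0, hxy2 = 0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double q = px[i] * py[j];
      if (q > 0) hxy1 -= P(i, j) * std::log2(q);
      hxy2 -= xlog2(q);
    }
  }
  const double hmax = std::max(hx, hy);
  const double imc1 = hmax > 0 ? (entropy - hxy1) / hmax : 0.0;
  double imc2_arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  const double imc2 = imc2_arg > 0 ? std::sqrt(imc2_arg) : 0.0;

  return NumericVector::create(
      autoc, prom, shade, contrast, corr, diff_ent, diff_var, dissim, energy,
      entropy, homog, imc1, imc2, invdiff, idmn, idn, maxp, sum_avg, sum_ent,
      var_x, sum_var);
}

// Fast path for one quantized tile: symmetric normalized GLCMs at the four
// orientations (0, 45, 90, 135 degrees at distance d) and their 21 features.
// Returns a 21 x 4 matrix; a column is NaN-filled when that orientation has
// no valid pixel pair.
// [[Rcpp::export]]
NumericMatrix tile_features_cpp(IntegerMatrix lv, int n_levels, int d,
                                int sv_about, int dv_variant) {
  static const int DR[4] = {0, -1, -1, -1};
  static const int DC[4] = {1, 1, 0, -1};
  const int nr = lv.nrow(), nc = lv.ncol();
  NumericMatrix out(21, 4);
  NumericMatrix P(n_levels, n_levels);
  for (int ang = 0; ang < 4; ++ang) {
    std::fill(P.begin(), P.end(), 0.0);
    const int dr = DR[ang] * d, dc = DC[ang] * d;
    double tot = 0;
    for (int c = 0; c < nc; ++c) {
      const int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      for (int r = 0; r < nr; ++r) {
        const int r2 = r + dr;
        if (r2 < 0 || r2 >= nr) continue;
        const int i = lv(r, c), j = lv(r2, c2);
        if (i == NA_INTEGER || j == NA_INTEGER) continue;
        P(i, j) += 1.0;
        P(j, i) += 1.0;
        tot += 2.0;
      }
    }
    if (tot == 0) {
      for (int f = 0; f < 21; ++f) out(f, ang) = NA_REAL;
      continue;
    }
    for (int k = 0; k < n_levels * n_levels; ++k) P[k] /= tot;
    NumericVector feats = glcm_features_cpp(P, sv_about, dv_variant);
    for (int f = 0; f < 21; ++f) out(f, ang) = feats[f];
  }
  return out;
}

// Symmetric GLCM counts for one displacement (dr, dc) on a quantized tile.
// lv: integer matrix with levels in 0..n_levels-1, NA_INTEGER = invalid.
// Each valid ordered pair contributes to (i,j) and (j,i) (the opposite
// direction, 180 deg apart, pooled into the same matrix).
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerMatrix lv, int dr, int dc, int n_levels) {
  const int nr = lv.nrow(), nc = lv.ncol();
  NumericMatrix counts(n_levels, n_levels);
  for (int c = 0; c < nc; ++c) {
    const int c2 = c + dc;
    if (c2 < 0 || c2 >= nc) continue;
    for (int r = 0; r < nr; ++r) {
      const int r2 = r + dr;
      if (r2 < 0 || r2 >= nr) continue;
      const int i = lv(r, c), j = lv(r2, c2);
      if (i == NA_INTEGER || j == NA_INTEGER) continue;
      counts(i, j) += 1.0;
      counts(j, i) += 1.0;
    }
  }
  return counts;
}
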