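#include <Rcpp.h>
using namespace Rcpp;

// Rounding rule used for vote placement: half away from zero (std::lround).
// The R-side brute-force oracle mirrors this rule; keep them in sync.

// Cast GHT votes into a 5-D accumulator indexed [Sx, Sy, theta, y, x].
//
// ex, ey, ephi: edge point coordinates and gradient orientations (mod pi).
// rho, alpha:   R-table entries in polar form, sorted by orientation bin;
//               bin_start is the 0-based offset vector (length nbins + 1)
//               delimiting each bin's entries.
// sx, sy, th:   pose grid axes.  x0, y0, nx, ny: position window.
//
// A displacement r is scaled per axis first, then rotated:
//   r' = Rot(th) diag(Sx, Sy) r,   vote at (ex, ey) + r'.
// The R-table lookup bin is shifted by the candidate rotation:
//   bin( (ephi - th) mod pi ).
// [[Rcpp::export]]
IntegerVector ght_vote_cpp(NumericVector ex, NumericVector ey, NumericVector ephi,
                           NumericVector rho, NumericVector alpha,
                           IntegerVector bin_start, int nbins,
                           NumericVector sx, NumericVector sy, NumericVector th,
                           int x0, int y0, int nx, int ny) {
  const int nsx = sx.size(), nsy = sy.size(), nth = th.size();
  const int ne = ex.size(), nent = rho.size();
  IntegerVector votes(static_cast<R_xlen_t>(nsx) * nsy * nth * ny * nx);
  votes.attr("dim") = IntegerVector::create(nsx, nsy, nth, ny, nx);
  const double dt = M_PI / nbins;

  std::vector<double> rx(nent), ry(nent);
  for (int j = 0; j < nent; ++j) {
    rx[j] = rho[j] * std::cos(alpha[j]);
    ry[j] = rho[j] * std::sin(alpha[j]);
  }

  for (int it = 0; it < nth; ++it) {
    const double ct = std::cos(th[it]), st = std::sin(th[it]);
    for (int e = 0; e < ne; ++e) {
      double a = ephi[e] - th[it];
      a -= M_PI * std::floor(a / M_PI);  // reduce to [0, pi)
      int b = static_cast<int>(std::floor(a / dt));
      if (b >= nbins) b = nbins - 1;  // guard a == pi after fp roundoff
      for (int j = bin_start[b]; j < bin_start[b + 1]; ++j) {
        for (int is = 0; is < nsx; ++is) {
          const double sxr = sx[is] * rx[j];
          for (int js = 0; js < nsy; ++js) {
            const double syr = sy[js] * ry[j];
            const int ix = static_cast<int>(std::lround(ex[e] + ct * sxr - st * syr)) - x0;
            const int iy = static_cast<int>(std::lround(ey[e] + st * sxr + ct * syr)) - y0;
            if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) continue;
            votes[is + static_cast<R_xlen_t>(nsx) *
                      (js + static_cast<R_xlen_t>(nsy) *
                      (it + static_cast<R_xlen_t>(nth) *
                      (iy + static_cast<R_xlen_t>(ny) * ix)))] += 1;
          }
        }
      }
    }
  }
  return votes;
}

// Positional box support: for every cell, the sum of votes in the
// (2r+1)^2 (x, y) neighborhood at the same (Sx, Sy, theta).  Peaks of this
// support consolidate votes smeared over adjacent positions by edge-pixel
// quantization; the reported detection rate stays the raw cell count.
// [[Rcpp::export]]
IntegerVector box_support_cpp(IntegerVector votes, int r) {
  IntegerVector dims = votes.attr("dim");
  const int npose = dims[0] * dims[1] * dims[2], ny = dims[3], nx = dims[4];
  IntegerVector out(votes.size());
  out.attr("dim") = dims;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = static_cast<R_xlen_t>(npose) * (y + static_cast<R_xlen_t>(ny) * x);
      for (int dx = -r; dx <= r; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -r; dy <= r; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          const R_xlen_t src = static_cast<R_xlen_t>(npose) * (yy + static_cast<R_xlen_t>(ny) * xx);
          for (int p = 0; p < npose; ++p) out[base + p] += votes[src + p];
        }
      }
    }
  }
  return out;
}

// Per-pixel distance to a polyline given as a point set, plus the index of
// the nearest polyline point (1-based).  Used by the phantom painter to
// build the myocardial band and label its septal/lateral sides.
// [[Rcpp::export]]
List polyline_dist_cpp(NumericVector px, NumericVector py, int width, int height) {
  NumericMatrix d(height, width);
  IntegerMatrix idx(height, width);
  const int np = px.size();
  for (int x = 0; x < width; ++x) {
    for (int y = 0; y < height; ++y) {
      double best = R_PosInf;
      int bi = 0;
      for (int j = 0; j < np; ++j) {
        const double dx = x - px[j], dy = y - py[j];
        const double dd = dx * dx + dy * dy;
        if (dd < best) { best = dd; bi = j; }
      }
      d(y, x) = std::sqrt(best);
      idx(y, x) = bi + 1;
    }
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}
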