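#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exhaustive block matching between two frames.
//
// For each block on a regular grid in `prev`, finds the integer displacement
// within +/- search that minimizes the chosen dissimilarity (SSD or SAD)
// against `next`, then refines to subpixel precision by fitting a 1D
// parabola through the cost minimum along each axis. Blocks whose intensity
// s.d. falls below `var_floor`, whose cost minimum is not unique, or whose
// minimum sits on the search border are flagged non-confident (their integer
// estimate is still reported).
//
// Returns a list of matrices (rows = block rows, cols = block cols):
// dx, dy (pixels; dx along columns/x, dy along rows/y), confident (logical),
// bx, by (block-centre pixel coordinates, 1-based).
// [[Rcpp::export(name = ".block_match_pair")]]
List block_match_pair(NumericMatrix prev, NumericMatrix nxt,
                      int block_size, int search_radius, int step,
                      double var_floor, bool use_sad) {
  const int nr = prev.nrow(), nc = prev.ncol();
  const int b = block_size, s = search_radius;
  if (nxt.nrow() != nr || nxt.ncol() != nc)
    stop("frames must have identical dimensions");
  if (b < 4) stop("block_size must be >= 4");
  if (s < 1) stop("search_radius must be >= 1");
  if (step < 1) stop("step must be >= 1");

  // block top-left positions (0-based) so block + search window fit
  std::vector<int> rows0, cols0;
  for (int r = s; r + b + s <= nr; r += step) rows0.push_back(r);
  for (int c = s; c + b + s <= nc; c += step) cols0.push_back(c);
  const int nbr = rows0.size(), nbc = cols0.size();
  if (nbr == 0 || nbc == 0)
    stop("frame too small for the requested block and search sizes");

  NumericMatrix dx(nbr, nbc), dy(nbr, nbc), bx(nbr, nbc), by(nbr, nbc);
  LogicalMatrix conf(nbr, nbc);
  const int w = 2 * s + 1;
  std::vector<double> cost(w * w);

  for (int bi = 0; bi < nbr; ++bi) {
    for (int bj = 0; bj < nbc; ++bj) {
      const int r0 = rows0[bi], c0 = cols0[bj];

      // block intensity s.d. (texture check)
      double sum = 0.0, sum2 = 0.0;
      for (int c = 0; c < b; ++c)
        for (int r = 0; r < b; ++r) {
          double v = prev(r0 + r, c0 + c);
          sum += v; sum2 += v * v;
        }
      const double npx = (double)b * b;
      double sd = std::sqrt(std::max(0.0, sum2 / npx - (sum / npx) * (sum / npx)));
      bool textured = sd > var_floor;

      // exhaustive integer search
      double best = std::numeric_limits<double>::infinity();
      int bdr = 0, bdc = 0, nbest = 0;
      for (int drow = -s; drow <= s; ++drow) {
        for (int dcol = -s; dcol <= s; ++dcol) {
          double cst = 0.0;
          for (int c = 0; c < b; ++c) {
            for (int r = 0; r < b; ++r) {
              double d = prev(r0 + r, c0 + c) - nxt(r0 + r + drow, c0 + c + dcol);
              cst += use_sad ? std::fabs(d) : d * d;
            }
          }
          cost[(drow + s) * w + (dcol + s)] = cst;
          if (cst < best - 1e-12) { best = cst; bdr = drow; bdc = dcol; nbest = 1; }
          else if (cst <= best + 1e-12) ++nbest;
        }
      }
      bool unique_min = (nbest == 1);
      bool interior = (bdr > -s && bdr < s && bdc > -s && bdc < s);

      double sub_r = (double)bdr, sub_c = (double)bdc;
      // a numerically-zero minimum is an exact match; refinement would only
      // move it off the true integer displacement
      bool exact = best <= 1e-9 * npx;
      if (interior && !exact) {
        // parabola refinement along each axis through the cost minimum
        double c0r = cost[(bdr - 1 + s) * w + (bdc + s)];
        double c1r = cost[(bdr + s) * w + (bdc + s)];
        double c2r = cost[(bdr + 1 + s) * w + (bdc + s)];
        double den = c0r - 2.0 * c1r + c2r;
        if (den > 1e-12) {
          double off = 0.5 * (c0r - c2r) / den;
          off = std::min(0.5, std::max(-0.5, off));
          sub_r += off;
        }
        double c0c = cost[(bdr + s) * w + (bdc - 1 + s)];
        double c2c = cost[(bdr + s) * w + (bdc + 1 + s)];
        den = c0c - 2.0 * c1r + c2c;
        if (den > 1e-12) {
          double off = 0.5 * (c0c - c2c) / den;
          off = std::min(0.5, std::max(-0.5, off));
          sub_c += off;
        }
      }

      dy(bi, bj) = sub_r;
      dx(bi, bj) = sub_c;
      conf(bi, bj) = textured && unique_min && interior;
      by(bi, bj) = r0 + (b + 1) / 2.0;   // 1-based centre
      bx(bi, bj) = c0 + (b + 1) / 2.0;
    }
  }

  return List::create(_["dx"] = dx, _["dy"] = dy, _["confident"] = conf,
                      _["bx"] = bx, _["by"] = by);
}
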