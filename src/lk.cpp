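#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pyramidal Lucas-Kanade sparse optical flow.
//
// Per frame pair and point, the displacement is the iterated least-squares
// solution of the brightness-constancy equations over a fixed window,
// refined coarse-to-fine over an image pyramid (3-tap 1/4,1/2,1/4
// smoothing + 2x decimation). Two candidate solves are run when a warm
// start from the previous step is available: a pyramidal solve from zero
// (captures large unknown motion of large structures) and a base-level
// solve from the warm start (follows thin structures whose coarse-level
// appearance vanishes); the candidate with the lower window residual wins.
// Points whose window leaves the image or whose gradient matrix is
// degenerate at the base level are flagged invalid.

struct Pyramid {
  std::vector<std::vector<double>> img;
  std::vector<int> nr, nc;
};

static void downsample(const std::vector<double>& src, int nr, int nc,
                       std::vector<double>& dst, int& dnr, int& dnc) {
  std::vector<double> tmp(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = src.data() + static_cast<size_t>(j) * nr;
    double* out = tmp.data() + static_cast<size_t>(j) * nr;
    for (int i = 0; i < nr; ++i) {
      int up = i > 0 ? i - 1 : 0, dn = i < nr - 1 ? i + 1 : nr - 1;
      out[i] = 0.25 * col[up] + 0.5 * col[i] + 0.25 * col[dn];
    }
  }
  std::vector<double> tmp2(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; ++j) {
    int lf = j > 0 ? j - 1 : 0, rt = j < nc - 1 ? j + 1 : nc - 1;
    const double* cl = tmp.data() + static_cast<size_t>(lf) * nr;
    const double* cc = tmp.data() + static_cast<size_t>(j) * nr;
    const double* cr = tmp.data() + static_cast<size_t>(rt) * nr;
    double* out = tmp2.data() + static_cast<size_t>(j) * nr;
    for (int i = 0; i < nr; ++i)
      out[i] = 0.25 * cl[i] + 0.5 * cc[i] + 0.25 * cr[i];
  }
  dnr = (nr + 1) / 2;
  dnc = (nc + 1) / 2;
  dst.resize(static_cast<size_t>(dnr) * dnc);
  for (int j = 0; j < dnc; ++j)
    for (int i = 0; i < dnr; ++i)
      dst[i + static_cast<size_t>(j) * dnr] =
        tmp2[2 * i + static_cast<size_t>(2 * j) * nr];
}

static void build_pyramid(const NumericMatrix& m, int max_level, int win,
                          Pyramid& p) {
  p.img.clear(); p.nr.clear(); p.nc.clear();
  p.img.emplace_back(m.begin(), m.end());
  p.nr.push_back(m.nrow());
  p.nc.push_back(m.ncol());
  for (int l = 0; l < max_level; ++l) {
    if (std::min(p.nr.back(), p.nc.back()) < 2 * win) break;
    std::vector<double> d;
    int dnr, dnc;
    downsample(p.img.back(), p.nr.back(), p.nc.back(), d, dnr, dnc);
    p.img.push_back(std::move(d));
    p.nr.push_back(dnr);
    p.nc.push_back(dnc);
  }
}

static inline double bilin(const std::vector<double>& m, int nr,
                           double y, double x) {
  int y0 = static_cast<int>(std::floor(y));
  int x0 = static_cast<int>(std::floor(x));
  double fy = y - y0, fx = x - x0;
  const double* c0 = m.data() + static_cast<size_t>(x0) * nr;
  const double* c1 = c0 + nr;
  double a = c0[y0] + fy * (c0[y0 + 1] - c0[y0]);
  double b = c1[y0] + fy * (c1[y0 + 1] - c1[y0]);
  return a + fx * (b - a);
}

struct LKParams {
  int win, max_iter;
  double eps, min_eig;
};

struct LKResult {
  bool ok;
  double dx, dy, resid;
};

// coarse-to-fine solve starting at start_level with displacement init
// (given at base-level scale); levels above start_level are ignored
static LKResult lk_solve(const Pyramid& p0, const Pyramid& p1,
                         double ptx, double pty, double init_dx,
                         double init_dy, int start_level,
                         const LKParams& par,
                         std::vector<double>& T, std::vector<double>& Ix,
                         std::vector<double>& Iy) {
  const int hw = (par.win - 1) / 2;
  const int wpx = par.win * par.win;
  double dx = init_dx / std::pow(2.0, start_level);
  double dy = init_dy / std::pow(2.0, start_level);
  LKResult res{false, 0.0, 0.0, 1e300};
  bool ok = true, solved_any = false;
  for (int l = start_level; l >= 0; --l) {
    const std::vector<double>& A0 = p0.img[l];
    const std::vector<double>& A1 = p1.img[l];
    const int nr = p0.nr[l], nc = p0.nc[l];
    const double scale = std::pow(2.0, l);
    const double px = ptx / scale, py = pty / scale;
    if (l < start_level) { dx *= 2.0; dy *= 2.0; }
    if (px < hw + 2 || py < hw + 2 || px > nc - hw - 3 || py > nr - hw - 3) {
      if (l == 0) ok = false;
      continue;
    }
    double Gxx = 0, Gxy = 0, Gyy = 0;
    int idx = 0;
    for (int ox = -hw; ox <= hw; ++ox) {
      for (int oy = -hw; oy <= hw; ++oy, ++idx) {
        double yy = py + oy, xx = px + ox;
        T[idx] = bilin(A0, nr, yy, xx);
        double gx = 0.5 * (bilin(A0, nr, yy, xx + 1) - bilin(A0, nr, yy, xx - 1));
        double gy = 0.5 * (bilin(A0, nr, yy + 1, xx) - bilin(A0, nr, yy - 1, xx));
        Ix[idx] = gx;
        Iy[idx] = gy;
        Gxx += gx * gx;
        Gxy += gx * gy;
        Gyy += gy * gy;
      }
    }
    double det = Gxx * Gyy - Gxy * Gxy;
    double tr = Gxx + Gyy;
    double disc = tr * tr - 4.0 * det;
    double emin = (tr - std::sqrt(disc > 0 ? disc : 0)) / 2.0 / wpx;
    if (!(det > 0) || emin < par.min_eig) {
      if (l == 0) ok = false;  // flat at full resolution: no reliable flow
      continue;
    }
    for (int it = 0; it < par.max_iter; ++it) {
      double qx = px + dx, qy = py + dy;
      if (qx < hw + 1 || qy < hw + 1 || qx > nc - hw - 2 || qy > nr - hw - 2) {
        ok = false;
        break;
      }
      double bx = 0, by = 0;
      idx = 0;
      for (int ox = -hw; ox <= hw; ++ox) {
        for (int oy = -hw; oy <= hw; ++oy, ++idx) {
          double diff = bilin(A1, nr, qy + oy, qx + ox) - T[idx];
          bx += Ix[idx] * diff;
          by += Iy[idx] * diff;
        }
      }
      double ddx = -(Gyy * bx - Gxy * by) / det;
      double ddy = -(-Gxy * bx + Gxx * by) / det;
      dx += ddx;
      dy += ddy;
      if (ddx * ddx + ddy * ddy < par.eps * par.eps) break;
    }
    if (!ok) break;
    solved_any = true;
    if (l == 0) {
      // window residual at the converged base-level displacement
      double qx = px + dx, qy = py + dy;
      if (qx < hw + 1 || qy < hw + 1 || qx > nc - hw - 2 || qy > nr - hw - 2) {
        ok = false;
        break;
      }
      double s = 0;
      idx = 0;
      for (int ox = -hw; ox <= hw; ++ox)
        for (int oy = -hw; oy <= hw; ++oy, ++idx)
          s += std::fabs(bilin(A1, nr, qy + oy, qx + ox) - T[idx]);
      res.resid = s / wpx;
    }
  }
  if (ok && solved_any) {
    res.ok = true;
    res.dx = dx;
    res.dy = dy;
  }
  return res;
}

static void track_pair(const Pyramid& p0, const Pyramid& p1,
                       const std::vector<double>& px,
                       const std::vector<double>& py,
                       const std::vector<double>& warm_dx,
                       const std::vector<double>& warm_dy,
                       const std::vector<bool>& live, const LKParams& par,
                       std::vector<double>& out_dx,
                       std::vector<double>& out_dy,
                       std::vector<bool>& out_ok) {
  const int nlev = static_cast<int>(p0.img.size());
  const int wpx = par.win * par.win;
  std::vector<double> T(wpx), Ix(wpx), Iy(wpx);
  const int n = static_cast<int>(px.size());
  const int nr0 = p0.nr[0], nc0 = p0.nc[0];
  for (int k = 0; k < n; ++k) {
    out_ok[k] = false;
    out_dx[k] = NA_REAL;
    out_dy[k] = NA_REAL;
    if (!live[k]) continue;
    LKResult best = lk_solve(p0, p1, px[k], py[k], 0.0, 0.0, nlev - 1, par,
                             T, Ix, Iy);
    bool have_warm = std::fabs(warm_dx[k]) > 1e-9 || std::fabs(warm_dy[k]) > 1e-9;
    if (have_warm) {
      LKResult warm = lk_solve(p0, p1, px[k], py[k], warm_dx[k], warm_dy[k],
                               0, par, T, Ix, Iy);
      // hysteresis in favour of track continuity: keep following the
      // motion-consistent solution unless it is clearly worse than the
      // from-scratch solve (e.g. when a tracked structure crosses in
      // front of differently-moving texture, both windows are partly
      // mismatched and the residuals are close)
      if (warm.ok && (!best.ok || warm.resid <= 1.5 * best.resid)) best = warm;
    }
    if (!best.ok) continue;
    double fx = px[k] + best.dx, fy = py[k] + best.dy;
    if (fx < 0 || fy < 0 || fx > nc0 - 1 || fy > nr0 - 1) continue;
    out_ok[k] = true;
    out_dx[k] = best.dx;
    out_dy[k] = best.dy;
  }
}

// [[Rcpp::export(name = ".lk_pair")]]
List lk_pair(NumericMatrix I0, NumericMatrix I1, NumericMatrix pts,
             NumericMatrix init, int win = 21, int max_level = 3,
             int max_iter = 30, double eps = 0.01, double min_eig = 1e-4) {
  if (win % 2 == 0) stop("window size must be odd");
  const int n = pts.nrow();
  LKParams par{win, max_iter, eps, min_eig};
  Pyramid p0, p1;
  build_pyramid(I0, max_level, win, p0);
  build_pyramid(I1, max_level, win, p1);
  std::vector<double> px(n), py(n), wdx(n), wdy(n), odx(n), ody(n);
  std::vector<bool> live(n, true), ook(n);
  for (int k = 0; k < n; ++k) {
    px[k] = pts(k, 0); py[k] = pts(k, 1);
    wdx[k] = init(k, 0); wdy[k] = init(k, 1);
  }
  track_pair(p0, p1, px, py, wdx, wdy, live, par, odx, ody, ook);
  NumericMatrix d(n, 2);
  LogicalVector status(n);
  for (int k = 0; k < n; ++k) {
    d(k, 0) = odx[k];
    d(k, 1) = ody[k];
    status[k] = ook[k];
  }
  return List::create(_["d"] = d, _["status"] = status);
}

// [[Rcpp::export(name = ".lk_track")]]
List lk_track(List frames, NumericMatrix pts, int win = 21, int max_level = 3,
              int max_iter = 30, double eps = 0.01, double min_eig = 1e-4) {
  if (win % 2 == 0) stop("window size must be odd");
  const int nf = frames.size();
  if (nf < 2) stop("need at least 2 frames");
  const int n = pts.nrow();
  LKParams par{win, max_iter, eps, min_eig};
  NumericMatrix tx(nf, n), ty(nf, n);
  LogicalMatrix status(nf, n);
  std::fill(tx.begin(), tx.end(), NA_REAL);
  std::fill(ty.begin(), ty.end(), NA_REAL);
  std::vector<double> px(n), py(n), wdx(n, 0.0), wdy(n, 0.0), odx(n), ody(n);
  std::vector<bool> live(n, true), ook(n);
  for (int k = 0; k < n; ++k) {
    px[k] = pts(k, 0);
    py[k] = pts(k, 1);
    tx(0, k) = px[k];
    ty(0, k) = py[k];
    status(0, k) = true;
  }
  Pyramid pa, pb;
  {
    NumericMatrix f0 = as<NumericMatrix>(frames[0]);
    build_pyramid(f0, max_level, win, pa);
  }
  Pyramid* prev = &pa;
  Pyramid* cur = &pb;
  for (int f = 1; f < nf; ++f) {
    NumericMatrix ff = as<NumericMatrix>(frames[f]);
    if (ff.nrow() != prev->nr[0] || ff.ncol() != prev->nc[0])
      stop("frame %d shape mismatch", f + 1);
    build_pyramid(ff, max_level, win, *cur);
    track_pair(*prev, *cur, px, py, wdx, wdy, live, par, odx, ody, ook);
    for (int k = 0; k < n; ++k) {
      if (!live[k]) continue;
      if (!ook[k]) {
        live[k] = false;  // invalid from this step onward
        wdx[k] = wdy[k] = 0.0;
        continue;
      }
      px[k] += odx[k];
      py[k] += ody[k];
      wdx[k] = odx[k];
      wdy[k] = ody[k];
      tx(f, k) = px[k];
      ty(f, k) = py[k];
      status(f, k) = true;
    }
    std::swap(prev, cur);
  }
  return List::create(_["x"] = tx, _["y"] = ty, _["status"] = status);
}
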