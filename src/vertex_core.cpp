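#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State layout for an N-cell spheroid (6N doubles):
//   [ax_0..ax_{N-1}, ay, bx, by, kappa_a, kappa_b]
// Apical/basal loops are counterclockwise; cell i is bounded by the basal arc
// (b_i -> b_{i+1}), laterals, and the apical arc (a_i -> a_{i+1}). Positive arc
// curvature bulges to the right of the traversal direction, i.e. away from the
// enclosed (lumen / tissue) interior.

static const double AMAX = 0.999; // optimizer clamp on |kappa| d / 2 (1 = semicircle)
static const double PEN = 1e6;

// arc length for chord d, curvature kappa; infeasible arcs clamped with penalty
static double arc_len_pen(double d, double kappa, double *pen) {
  double ak = std::fabs(kappa);
  double a = ak * d / 2.0;
  if (a < 1e-9) return d;
  if (a > AMAX) {
    *pen += PEN * (a - AMAX) * (a - AMAX);
    a = AMAX;
    d = 2.0 * a / ak;
  }
  return 2.0 / ak * std::asin(a);
}

// signed circular-segment area (positive kappa adds area on the bulge side)
static double seg_area_pen(double d, double kappa, double *pen) {
  double ak = std::fabs(kappa);
  double a = ak * d / 2.0;
  if (a < 1e-9) return 0.0;
  if (a > AMAX) {
    *pen += PEN * (a - AMAX) * (a - AMAX);
    a = AMAX;
  }
  double R = 1.0 / ak;
  double th = 2.0 * std::asin(a);
  double A = 0.5 * R * R * (th - std::sin(th));
  return kappa > 0 ? A : -A;
}

struct EnergyOut {
  double total;   // penalized energy used by the optimizer
  double lumen;   // lumen area A_L
  double pen;     // infeasibility penalty (0 when all arcs are feasible)
  std::vector<double> cell; // per-cell summand (area + three length terms)
};

static void geom_energy(const double *x, int N, double p, double k,
                        double la, double lb, EnergyOut &out) {
  const double *ax = x, *ay = x + N, *bx = x + 2 * N, *by = x + 3 * N;
  const double *ka = x + 4 * N, *kb = x + 5 * N;
  double pen = 0.0;
  double AL = 0.0;
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    AL += 0.5 * (ax[i] * ay[j] - ax[j] * ay[i]);
    double da = std::hypot(ax[j] - ax[i], ay[j] - ay[i]);
    AL += seg_area_pen(da, ka[i], &pen);
  }
  out.lumen = AL;
  out.cell.assign(N, 0.0);
  double tot = -p * AL;
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    double da = std::hypot(ax[j] - ax[i], ay[j] - ay[i]);
    double db = std::hypot(bx[j] - bx[i], by[j] - by[i]);
    double ll = std::hypot(ax[i] - bx[i], ay[i] - by[i]);
    double qx[4] = {bx[i], bx[j], ax[j], ax[i]};
    double qy[4] = {by[i], by[j], ay[j], ay[i]};
    double A = 0.0;
    for (int q = 0; q < 4; ++q) {
      int r = (q + 1) % 4;
      A += 0.5 * (qx[q] * qy[r] - qx[r] * qy[q]);
    }
    A += seg_area_pen(db, kb[i], &pen);
    A -= seg_area_pen(da, ka[i], &pen);
    double lai = arc_len_pen(da, ka[i], &pen);
    double lbi = arc_len_pen(db, kb[i], &pen);
    double e = (A - 1.0) * (A - 1.0) +
               k * ((lai - la) * (lai - la) + (lbi - lb) * (lbi - lb) + ll * ll);
    out.cell[i] = e;
    tot += e;
  }
  out.pen = pen;
  out.total = tot + pen;
}

// exact (unclamped) geometry; arcs with |kappa| d / 2 > 1 flagged infeasible
// [[Rcpp::export]]
List vm_geometry_cpp(NumericVector state, int N) {
  const double *x = state.begin();
  const double *ax = x, *ay = x + N, *bx = x + 2 * N, *by = x + 3 * N;
  const double *ka = x + 4 * N, *kb = x + 5 * N;
  NumericVector area(N), lai(N), lbi(N), lli(N);
  bool feasible = true;
  double AL = 0.0;
  auto arc_exact = [&](double d, double kap) {
    double akd = std::fabs(kap) * d / 2.0;
    if (akd < 1e-9) return d;
    if (akd > 1.0 + 1e-12) { feasible = false; return NA_REAL; }
    return 2.0 / std::fabs(kap) * std::asin(std::min(akd, 1.0));
  };
  auto seg_exact = [&](double d, double kap) {
    double akd = std::fabs(kap) * d / 2.0;
    if (akd < 1e-9) return 0.0;
    if (akd > 1.0 + 1e-12) { feasible = false; return NA_REAL; }
    double R = 1.0 / std::fabs(kap);
    double th = 2.0 * std::asin(std::min(akd, 1.0));
    double A = 0.5 * R * R * (th - std::sin(th));
    return kap > 0 ? A : -A;
  };
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    double da = std::hypot(ax[j] - ax[i], ay[j] - ay[i]);
    double db = std::hypot(bx[j] - bx[i], by[j] - by[i]);
    lli[i] = std::hypot(ax[i] - bx[i], ay[i] - by[i]);
    lai[i] = arc_exact(da, ka[i]);
    lbi[i] = arc_exact(db, kb[i]);
    AL += 0.5 * (ax[i] * ay[j] - ax[j] * ay[i]) + seg_exact(da, ka[i]);
    double qx[4] = {bx[i], bx[j], ax[j], ax[i]};
    double qy[4] = {by[i], by[j], ay[j], ay[i]};
    double A = 0.0;
    for (int q = 0; q < 4; ++q) {
      int r = (q + 1) % 4;
      A += 0.5 * (qx[q] * qy[r] - qx[r] * qy[q]);
    }
    area[i] = A + seg_exact(db, kb[i]) - seg_exact(da, ka[i]);
  }
  return List::create(_["area"] = area, _["l_a"] = lai, _["l_b"] = lbi,
                      _["l_l"] = lli, _["lumen_area"] = AL,
                      _["feasible"] = feasible);
}

// [[Rcpp::export]]
List vm_energy_cpp(NumericVector state, int N, double p, double k,
                   double la, double lb) {
  EnergyOut o;
  geom_energy(state.begin(), N, p, k, la, lb, o);
  return List::create(_["energy"] = o.total, _["penalty"] = o.pen,
                      _["lumen_area"] = o.lumen,
                      _["per_cell"] = NumericVector(o.cell.begin(), o.cell.end()));
}

static double pen_energy(const double *x, int N, double p, double k,
                         double la, double lb) {
  EnergyOut o;
  geom_energy(x, N, p, k, la, lb, o);
  return o.total;
}

// [[Rcpp::export]]
NumericVector vm_grad_cpp(NumericVector state, int N, double p, double k,
                          double la, double lb, double h = 1e-6) {
  int n = 6 * N;
  std::vector<double> x(state.begin(), state.end());
  NumericVector g(n);
  for (int i = 0; i < n; ++i) {
    double x0 = x[i];
    x[i] = x0 + h;
    double ep = pen_energy(x.data(), N, p, k, la, lb);
    x[i] = x0 - h;
    double em = pen_energy(x.data(), N, p, k, la, lb);
    x[i] = x0;
    g[i] = (ep - em) / (2.0 * h);
  }
  return g;
}

static int orient_sgn(double ax, double ay, double bx, double by, double cx,
                      double cy) {
  double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  if (v > 1e-14) return 1;
  if (v < -1e-14) return -1;
  return 0;
}

static bool seg_cross(double ax, double ay, double bx, double by, double cx,
                      double cy, double dx, double dy) {
  int o1 = orient_sgn(ax, ay, bx, by, cx, cy);
  int o2 = orient_sgn(ax, ay, bx, by, dx, dy);
  int o3 = orient_sgn(cx, cy, dx, dy, ax, ay);
  int o4 = orient_sgn(cx, cy, dx, dy, bx, by);
  return (o1 * o2 < 0) && (o3 * o4 < 0);
}

// Sampled loop with a per-arc, length-proportional power-of-two point count.
// Power-of-two counts make the sample positions refinement-stable: when a
// division splits an arc into two half-arcs, the daughters are sampled at
// exactly the parent's positions, so the physicality verdict cannot flip at
// the division step.
struct LoopSamples {
  std::vector<double> x, y;
  std::vector<int> off; // off[i]..off[i+1]-1 are arc i's samples; off[N] = total
  std::vector<double> cbb; // bbox per 8-segment chunk (x0, x1, y0, y1)
};

static const int CHUNK = 8;

static void chunk_bboxes(LoopSamples &L) {
  int n = (int)L.x.size();
  int nc = (n + CHUNK - 1) / CHUNK;
  L.cbb.assign(4 * nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    double x0 = 1e300, x1 = -1e300, y0 = 1e300, y1 = -1e300;
    int hi = std::min((c + 1) * CHUNK, n);
    for (int q = c * CHUNK; q <= hi; ++q) {
      int idx = q % n;
      x0 = std::min(x0, L.x[idx]); x1 = std::max(x1, L.x[idx]);
      y0 = std::min(y0, L.y[idx]); y1 = std::max(y1, L.y[idx]);
    }
    L.cbb[4 * c] = x0; L.cbb[4 * c + 1] = x1;
    L.cbb[4 * c + 2] = y0; L.cbb[4 * c + 3] = y1;
  }
}

static int arc_sample_count(double l) {
  double target = std::max(l, 1e-3) * 32.0; // ~32 samples for a unit-length arc
  int p = (int)std::ceil(std::log2(target));
  if (p < 2) p = 2;
  if (p > 7) p = 7;
  return 1 << p;
}

static void sample_loop(const double *px, const double *py, const double *kk,
                        int N, LoopSamples &L) {
  L.x.clear(); L.y.clear();
  L.off.assign(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    double dx = px[j] - px[i], dy = py[j] - py[i];
    double d = std::hypot(dx, dy);
    double a = std::fabs(kk[i]) * d / 2.0;
    double pen = 0.0;
    int m = arc_sample_count(arc_len_pen(d, kk[i], &pen));
    if (a < 1e-9 || d < 1e-12) {
      for (int q = 0; q < m; ++q) {
        double t = (double)q / m;
        L.x.push_back(px[i] + t * dx);
        L.y.push_back(py[i] + t * dy);
      }
    } else {
      if (a > 1.0) a = 1.0;
      double R = 1.0 / std::fabs(kk[i]);
      double ux = dx / d, uy = dy / d;
      double nx = uy, ny = -ux; // right of travel
      double sgn = kk[i] > 0 ? 1.0 : -1.0;
      double h = std::sqrt(std::max(R * R - d * d / 4.0, 0.0));
      double cxd = (px[i] + px[j]) / 2.0 - sgn * h * nx;
      double cyd = (py[i] + py[j]) / 2.0 - sgn * h * ny;
      double th = 2.0 * std::asin(a);
      // incremental rotation about the center (no per-sample trig)
      double dphi = sgn * th / m;
      double cd = std::cos(dphi), sd = std::sin(dphi);
      double vx = px[i] - cxd, vy = py[i] - cyd;
      for (int q = 0; q < m; ++q) {
        L.x.push_back(cxd + vx);
        L.y.push_back(cyd + vy);
        double t = vx * cd - vy * sd;
        vy = vx * sd + vy * cd;
        vx = t;
      }
    }
    L.off[i + 1] = (int)L.x.size();
  }
}

static void arc_bboxes(const LoopSamples &L, int N, std::vector<double> &bb) {
  bb.assign(4 * N, 0.0);
  int n = (int)L.x.size();
  for (int i = 0; i < N; ++i) {
    double x0 = 1e300, x1 = -1e300, y0 = 1e300, y1 = -1e300;
    for (int q = L.off[i]; q <= L.off[i + 1]; ++q) {
      int idx = q % n; // include the arc-closing point
      x0 = std::min(x0, L.x[idx]); x1 = std::max(x1, L.x[idx]);
      y0 = std::min(y0, L.y[idx]); y1 = std::max(y1, L.y[idx]);
    }
    bb[4 * i] = x0; bb[4 * i + 1] = x1; bb[4 * i + 2] = y0; bb[4 * i + 3] = y1;
  }
}

static bool bbox_overlap(const std::vector<double> &a, int i,
                         const std::vector<double> &b, int j) {
  return !(a[4 * i + 1] < b[4 * j] || b[4 * j + 1] < a[4 * i] ||
           a[4 * i + 3] < b[4 * j + 2] || b[4 * j + 3] < a[4 * i + 2]);
}

// proper crossing between segment ranges of two sampled loops (possibly the
// same loop; segments sharing an endpoint cannot "properly" cross)
static bool range_cross(const LoopSamples &A, int i0, int i1,
                        const LoopSamples &B, int j0, int j1, bool same) {
  int n = (int)A.x.size(), m = (int)B.x.size();
  for (int ca = i0 / CHUNK; ca * CHUNK < i1; ++ca) {
    int sa0 = std::max(i0, ca * CHUNK), sa1 = std::min(i1, (ca + 1) * CHUNK);
    for (int cb = j0 / CHUNK; cb * CHUNK < j1; ++cb) {
      int sb0 = std::max(j0, cb * CHUNK), sb1 = std::min(j1, (cb + 1) * CHUNK);
      if (same && sb1 <= sa0 + 1) continue; // handled by the (j > i) clip
      if (A.cbb[4 * ca + 1] < B.cbb[4 * cb] ||
          B.cbb[4 * cb + 1] < A.cbb[4 * ca] ||
          A.cbb[4 * ca + 3] < B.cbb[4 * cb + 2] ||
          B.cbb[4 * cb + 3] < A.cbb[4 * ca + 2])
        continue;
      for (int i = sa0; i < sa1; ++i) {
        int i2 = (i + 1) % n;
        int jstart = same ? std::max(sb0, i + 1) : sb0;
        for (int j = jstart; j < sb1; ++j) {
          int j2 = (j + 1) % m;
          if (seg_cross(A.x[i % n], A.y[i % n], A.x[i2], A.y[i2],
                        B.x[j % m], B.y[j % m], B.x[j2], B.y[j2]))
            return true;
        }
      }
    }
  }
  return false;
}

// physicality check on the sampled arc boundaries: the apical and basal
// loops are simple, do not cross each other, and laterals do not cross
// (arc pairs pruned by bounding boxes; chords of bulging arcs may cross
// legitimately, so the check runs on the arcs themselves)
static bool simple_ok(const double *x, int N) {
  const double *ax = x, *ay = x + N, *bx = x + 2 * N, *by = x + 3 * N;
  const double *ka = x + 4 * N, *kb = x + 5 * N;
  static thread_local LoopSamples LA, LB;
  static thread_local std::vector<double> bba, bbb;
  sample_loop(ax, ay, ka, N, LA);
  sample_loop(bx, by, kb, N, LB);
  arc_bboxes(LA, N, bba);
  arc_bboxes(LB, N, bbb);
  chunk_bboxes(LA);
  chunk_bboxes(LB);
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      if (bbox_overlap(bba, i, bba, j) &&
          range_cross(LA, LA.off[i], LA.off[i + 1], LA, LA.off[j],
                      LA.off[j + 1], true))
        return false;
      if (bbox_overlap(bbb, i, bbb, j) &&
          range_cross(LB, LB.off[i], LB.off[i + 1], LB, LB.off[j],
                      LB.off[j + 1], true))
        return false;
    }
    for (int j = 0; j < N; ++j) {
      if (bbox_overlap(bba, i, bbb, j) &&
          range_cross(LA, LA.off[i], LA.off[i + 1], LB, LB.off[j],
                      LB.off[j + 1], false))
        return false;
    }
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (seg_cross(ax[i], ay[i], bx[i], by[i], ax[j], ay[j], bx[j], by[j]))
        return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
bool vm_simple_cpp(NumericVector state, int N) {
  return simple_ok(state.begin(), N);
}

// simplicity of a single arc loop (e.g. the apical lumen boundary alone)
// [[Rcpp::export]]
bool vm_loop_simple_cpp(NumericVector px, NumericVector py, NumericVector kk) {
  int N = px.size();
  LoopSamples L;
  std::vector<double> bb;
  sample_loop(px.begin(), py.begin(), kk.begin(), N, L);
  arc_bboxes(L, N, bb);
  chunk_bboxes(L);
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      if (bbox_overlap(bb, i, bb, j) &&
          range_cross(L, L.off[i], L.off[i + 1], L, L.off[j], L.off[j + 1],
                      true))
        return false;
    }
  }
  return true;
}

// Stochastic gradient descent with backtracking acceptance (energy never
// increases), seeded Gaussian direction noise decaying as 1/sqrt(iter), and a
// two-part convergence certificate: max-norm displacement of a full pass below
// tol_disp AND no single-coordinate move of size `probe` lowering the energy.
// Uses R's RNG, so behaviour is reproducible under set.seed().
// [[Rcpp::export]]
List vm_minimize_cpp(NumericVector state0, int N, double p, double k,
                     double la, double lb, double step0 = 1e-3,
                     double noise0 = 0.05, double tol_disp = 1e-3,
                     double probe = 0.01, int maxit = 5000,
                     double fd_h = 1e-6) {
  RNGScope scope;
  int n = 6 * N;
  std::vector<double> x(state0.begin(), state0.end());
  EnergyOut o;
  geom_energy(x.data(), N, p, k, la, lb, o);
  double E = o.total;
  double E0 = E;
  bool simple_req = simple_ok(x.data(), N);
  bool converged = false;
  int it = 1;
  std::vector<double> g(n), dir(n), xp(n);
  for (; it <= maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      double x0 = x[i];
      x[i] = x0 + fd_h;
      double ep = pen_energy(x.data(), N, p, k, la, lb);
      x[i] = x0 - fd_h;
      double em = pen_energy(x.data(), N, p, k, la, lb);
      x[i] = x0;
      g[i] = (ep - em) / (2.0 * fd_h);
    }
    double ns = noise0 / std::sqrt((double)it);
    for (int i = 0; i < n; ++i) dir[i] = -g[i] + ns * norm_rand();
    double step = step0;
    bool accepted = false;
    double disp = 0.0;
    for (int tries = 0; tries < 16; ++tries) {
      disp = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = step * dir[i];
        xp[i] = x[i] + d;
        if (std::fabs(d) > disp) disp = std::fabs(d);
      }
      EnergyOut op;
      geom_energy(xp.data(), N, p, k, la, lb, op);
      bool ok = op.total <= E + 1e-12;
      if (ok && simple_req) ok = simple_ok(xp.data(), N);
      if (ok) {
        x.swap(xp);
        E = op.total;
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!simple_req && simple_ok(x.data(), N)) simple_req = true;
    if (!accepted) disp = 0.0;
    if (disp < tol_disp) {
      bool improved = false;
      for (int i = 0; i < n && !improved; ++i) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          std::copy(x.begin(), x.end(), xp.begin());
          xp[i] += sgn * probe;
          EnergyOut op;
          geom_energy(xp.data(), N, p, k, la, lb, op);
          if (op.total < E - 1e-10 &&
              (!simple_req || simple_ok(xp.data(), N))) {
            x.swap(xp);
            E = op.total;
            improved = true;
            break;
          }
        }
      }
      if (!improved) {
        converged = true;
        break;
      }
    }
  }
  geom_energy(x.data(), N, p, k, la, lb, o);
  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["energy"] = o.total, _["energy0"] = E0,
                      _["penalty"] = o.pen, _["converged"] = converged,
                      _["iterations"] = std::min(it, maxit));
}

// Fasano-Franceschini two-sample statistic: max quadrant-fraction difference
// over data-point origins of each sample, averaged over the two samples.
// Points lying on an origin's axes are excluded from all four quadrants.
// [[Rcpp::export]]
double ks2d_stat_cpp(NumericVector x1, NumericVector y1, NumericVector x2,
                     NumericVector y2) {
  auto quad = [](const NumericVector &x, const NumericVector &y, double xo,
                 double yo, double f[4]) {
    int n = x.size();
    int c[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (x[i] > xo && y[i] > yo) c[0]++;
      else if (x[i] < xo && y[i] > yo) c[1]++;
      else if (x[i] < xo && y[i] < yo) c[2]++;
      else if (x[i] > xo && y[i] < yo) c[3]++;
    }
    for (int q = 0; q < 4; ++q) f[q] = (double)c[q] / n;
  };
  double f1[4], f2[4];
  double d1 = 0.0, d2 = 0.0;
  for (int i = 0; i < x1.size(); ++i) {
    quad(x1, y1, x1[i], y1[i], f1);
    quad(x2, y2, x1[i], y1[i], f2);
    for (int q = 0; q < 4; ++q) d1 = std::max(d1, std::fabs(f1[q] - f2[q]));
  }
  for (int i = 0; i < x2.size(); ++i) {
    quad(x1, y1, x2[i], y2[i], f1);
    quad(x2, y2, x2[i], y2[i], f2);
    for (int q = 0; q < 4; ++q) d2 = std::max(d2, std::fabs(f1[q] - f2[q]));
  }
  return 0.5 * (d1 + d2);
}

// 6-connected 3D component labelling (EBImage::bwlabel is 2D only)
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz, 0);
  int cur = 0;
  std::vector<int> stack;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k0 = 0; k0 < nz; ++k0)
    for (int j0 = 0; j0 < ny; ++j0)
      for (int i0 = 0; i0 < nx; ++i0) {
        int id0 = i0 + nx * (j0 + ny * k0);
        if (!mask[id0] || lab[id0] != 0) continue;
        ++cur;
        lab[id0] = cur;
        stack.push_back(id0);
        while (!stack.empty()) {
          int id = stack.back();
          stack.pop_back();
          int ii = id % nx, jj = (id / nx) % ny, kk = id / (nx * ny);
          for (int q = 0; q < 6; ++q) {
            int i2 = ii + di[q], j2 = jj + dj[q], k2 = kk + dk[q];
            if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
              continue;
            int id2 = i2 + nx * (j2 + ny * k2);
            if (mask[id2] && lab[id2] == 0) {
              lab[id2] = cur;
              stack.push_back(id2);
            }
          }
        }
      }
  return lab;
}
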