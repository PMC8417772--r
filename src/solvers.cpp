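// Voxel-grid PDE solvers and morphological primitives.
// All arrays are flattened 3-D lattices in R's column-major order:
// linear index t = i + nx*(j + ny*k), 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline bool finite_d(double x) { return R_finite(x); }

// ---------------------------------------------------------------------------
// Jacobi solver for the Laplace equation with Dirichlet conditions.
//
// domain:   voxels where the potential is unknown
// bc:       Dirichlet value at boundary voxels (NA elsewhere); boundary voxels
//           lie OUTSIDE the domain
// bc_dist:  per-boundary-voxel distance factor (multiple of the axis spacing)
//           at which the condition is taken to hold: 0.5 places the boundary
//           on the shared voxel face (Shortley-Weller), 1.0 at the voxel
//           centre (used for in-cortex sheets such as the Purkinje lamina)
// Sides with neither domain nor boundary neighbours are treated as zero-flux
// (mirror) sides.
// [[Rcpp::export]]
List cpp_jacobi_laplace(LogicalVector domain, NumericVector bc,
                        NumericVector bc_dist, IntegerVector dim,
                        NumericVector spacing, double tol, int max_iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> psi(n, NA_REAL), nxt(n, NA_REAL);
  std::vector<R_xlen_t> dom;
  dom.reserve(1024);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (domain[t]) { psi[t] = 0.5; dom.push_back(t); }
    else if (!NumericVector::is_na(bc[t])) psi[t] = bc[t];
  }
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const R_xlen_t off[3] = {1, nx, (R_xlen_t)nx * ny};
  std::vector<double> deltas;
  deltas.reserve(max_iter > 0 ? std::min(max_iter, 100000) : 1);
  int iter = 0;
  double maxdel = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    maxdel = 0.0;
    for (size_t q = 0; q < dom.size(); ++q) {
      const R_xlen_t t = dom[q];
      const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
      const int ci[3] = {i, j, k}, nd[3] = {nx, ny, nz};
      double num = 0.0, den = 0.0;
      for (int a = 0; a < 3; ++a) {
        double vl, dl, vr, dr;
        if (ci[a] > 0) {
          const R_xlen_t u = t - off[a];
          if (domain[u]) { vl = psi[u]; dl = h[a]; }
          else if (!NumericVector::is_na(bc[u])) { vl = bc[u]; dl = h[a] * bc_dist[u]; }
          else { vl = psi[t]; dl = h[a]; }
        } else { vl = psi[t]; dl = h[a]; }
        if (ci[a] < nd[a] - 1) {
          const R_xlen_t u = t + off[a];
          if (domain[u]) { vr = psi[u]; dr = h[a]; }
          else if (!NumericVector::is_na(bc[u])) { vr = bc[u]; dr = h[a] * bc_dist[u]; }
          else { vr = psi[t]; dr = h[a]; }
        } else { vr = psi[t]; dr = h[a]; }
        const double cl = 2.0 / (dl * (dl + dr));
        const double cr = 2.0 / (dr * (dl + dr));
        num += cl * vl + cr * vr;
        den += cl + cr;
      }
      const double v = num / den;
      const double d = std::fabs(v - psi[t]);
      if (d > maxdel) maxdel = d;
      nxt[t] = v;
    }
    for (size_t q = 0; q < dom.size(); ++q) psi[dom[q]] = nxt[dom[q]];
    deltas.push_back(maxdel);
    if (maxdel < tol) { ++iter; break; }
  }
  NumericVector out(n, NA_REAL);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = psi[t];
  return List::create(_["psi"] = out, _["iterations"] = iter,
                      _["max_update"] = maxdel,
                      _["update_history"] = NumericVector(deltas.begin(), deltas.end()));
}

// ---------------------------------------------------------------------------
// First-order fast marching for F|grad D| = 1. Seeds carry D = 0. Voxels of
// the domain never reached keep +Inf.
// [[Rcpp::export]]
NumericVector cpp_fast_marching(NumericVector speed, LogicalVector seed,
                                LogicalVector domain, IntegerVector dim,
                                NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const R_xlen_t off[3] = {1, nx, (R_xlen_t)nx * ny};
  std::vector<double> D(n, R_PosInf);
  std::vector<unsigned char> state(n, 0); // 0 far, 1 trial, 2 known
  typedef std::pair<double, R_xlen_t> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > heap;

  // local solve of the upwind quadratic at voxel t
  auto solve_at = [&](R_xlen_t t) -> double {
    const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
    const int ci[3] = {i, j, k}, nd[3] = {nx, ny, nz};
    double u[3], hv[3];
    int m = 0;
    for (int a = 0; a < 3; ++a) {
      double best = R_PosInf;
      if (ci[a] > 0) {
        const R_xlen_t q = t - off[a];
        if (state[q] == 2 && D[q] < best) best = D[q];
      }
      if (ci[a] < nd[a] - 1) {
        const R_xlen_t q = t + off[a];
        if (state[q] == 2 && D[q] < best) best = D[q];
      }
      if (finite_d(best)) { u[m] = best; hv[m] = h[a]; ++m; }
    }
    if (m == 0) return R_PosInf;
    const double f = speed[t];
    if (!(f > 0)) return R_PosInf;
    const double rhs = 1.0 / f;
    // sort the (u, h) pairs by u ascending
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b)
        if (u[b] < u[a]) { std::swap(u[a], u[b]); std::swap(hv[a], hv[b]); }
    double sol = u[0] + rhs * hv[0];
    for (int mm = 2; mm <= m; ++mm) {
      if (sol <= u[mm - 1]) break;
      double A = 0, B = 0, C = -rhs * rhs;
      for (int a = 0; a < mm; ++a) {
        const double w = 1.0 / (hv[a] * hv[a]);
        A += w; B -= 2.0 * u[a] * w; C += u[a] * u[a] * w;
      }
      const double disc = B * B - 4.0 * A * C;
      if (disc < 0) break;
      const double cand = (-B + std::sqrt(disc)) / (2.0 * A);
      if (cand >= u[mm - 1]) sol = cand;
    }
    return sol;
  };

  for (R_xlen_t t = 0; t < n; ++t) {
    if (seed[t] && domain[t]) { D[t] = 0.0; state[t] = 2; }
  }
  for (R_xlen_t t = 0; t < n; ++t) {
    if (state[t] != 2) continue;
    const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
    const int ci[3] = {i, j, k}, nd[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      for (int s = -1; s <= 1; s += 2) {
        const int c = ci[a] + s;
        if (c < 0 || c >= nd[a]) continue;
        const R_xlen_t q = t + s * off[a];
        if (!domain[q] || state[q] == 2) continue;
        const double v = solve_at(q);
        if (v < D[q]) { D[q] = v; state[q] = 1; heap.push(P(v, q)); }
      }
    }
  }
  while (!heap.empty()) {
    const P top = heap.top(); heap.pop();
    const R_xlen_t t = top.second;
    if (state[t] == 2 || top.first > D[t]) continue;
    state[t] = 2;
    const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
    const int ci[3] = {i, j, k}, nd[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      for (int s = -1; s <= 1; s += 2) {
        const int c = ci[a] + s;
        if (c < 0 || c >= nd[a]) continue;
        const R_xlen_t q = t + s * off[a];
        if (!domain[q] || state[q] == 2) continue;
        const double v = solve_at(q);
        if (v < D[q]) { D[q] = v; state[q] = 1; heap.push(P(v, q)); }
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = domain[t] ? D[t] : NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// Upwind Gauss-Seidel solver for grad(L) . G = 1 on the domain, with L = 0 on
// boundary voxels (outside the domain) at distance bc_dist * spacing along the
// connecting axis. (gx, gy, gz) is the unit direction of increasing L.
// [[Rcpp::export]]
List cpp_upwind_arclength(NumericVector gx, NumericVector gy, NumericVector gz,
                          LogicalVector domain, LogicalVector bc,
                          NumericVector bc_dist, IntegerVector dim,
                          NumericVector spacing, double tol, int max_iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const R_xlen_t off[3] = {1, nx, (R_xlen_t)nx * ny};
  // Yezzi-Prince style iteration: start at 0 everywhere and relax
  // L = (1 + sum_a w_a L_upwind,a) / sum_a w_a,  w_a = |G_a| / d_a,
  // with alternating sweep order, until the largest update falls below tol.
  std::vector<double> L(n, 0.0);
  std::vector<unsigned char> fed(n, 1); // has at least one upwind source
  std::vector<R_xlen_t> dom;
  for (R_xlen_t t = 0; t < n; ++t) if (domain[t]) dom.push_back(t);
  double maxdel = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter && maxdel >= tol; ++iter) {
    maxdel = 0.0;
    const bool rev = (iter % 2) == 1;
    for (size_t qq = 0; qq < dom.size(); ++qq) {
      const R_xlen_t t = dom[rev ? dom.size() - 1 - qq : qq];
      const double g[3] = {gx[t], gy[t], gz[t]};
      const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
      const int ci[3] = {i, j, k}, nd[3] = {nx, ny, nz};
      double num = 1.0, den = 0.0;
      for (int a = 0; a < 3; ++a) {
        const double ga = g[a];
        if (!finite_d(ga) || std::fabs(ga) < 1e-12) continue;
        const int s = ga > 0 ? -1 : 1; // upwind neighbour (smaller L)
        const int c = ci[a] + s;
        if (c < 0 || c >= nd[a]) continue;
        const R_xlen_t q = t + s * off[a];
        double lv, d;
        if (domain[q]) { lv = L[q]; d = h[a]; }
        else if (bc[q]) { lv = 0.0; d = h[a] * bc_dist[q]; }
        else continue;
        const double w = std::fabs(ga) / d;
        num += w * lv; den += w;
      }
      if (den <= 0) { fed[t] = 0; continue; }
      fed[t] = 1;
      const double v = num / den;
      const double d = std::fabs(v - L[t]);
      if (d > maxdel) maxdel = d;
      L[t] = v;
    }
  }
  NumericVector out(n, NA_REAL);
  int unfed = 0;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!domain[t]) continue;
    if (!fed[t]) { ++unfed; continue; }
    out[t] = L[t];
  }
  return List::create(_["L"] = out, _["iterations"] = iter,
                      _["max_update"] = maxdel, _["unreached"] = unfed);
}

// ---------------------------------------------------------------------------
// Masked trilinear sampling helpers.
static inline double sample_masked(const double *arr, const int *valid,
                                   int nx, int ny, int nz,
                                   double x, double y, double z,
                                   double *wsum_out) {
  const int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  double wsum = 0.0, vsum = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    const int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    const double wz = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      const int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      const double wy = dj ? fy : 1.0 - fy;
      for (int di = 0; di < 2; ++di) {
        const int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        const double wx = di ? fx : 1.0 - fx;
        const R_xlen_t t = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!valid[t]) continue;
        const double w = wx * wy * wz;
        const double v = arr[t];
        if (!finite_d(v)) continue;
        wsum += w; vsum += w * v;
      }
    }
  }
  *wsum_out = wsum;
  return wsum > 0 ? vsum / wsum : NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, LogicalVector valid,
                            IntegerVector dim, NumericVector px,
                            NumericVector py, NumericVector pz,
                            double min_weight) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t m = px.size();
  NumericVector out(m, NA_REAL);
  std::vector<int> vmask(valid.size());
  for (R_xlen_t t = 0; t < valid.size(); ++t) vmask[t] = valid[t] ? 1 : 0;
  for (R_xlen_t q = 0; q < m; ++q) {
    double w = 0.0;
    const double v = sample_masked(REAL(arr), vmask.data(), nx, ny, nz,
                                   px[q], py[q], pz[q], &w);
    if (w >= min_weight) out[q] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Streamline tracing with multiplicative surface-element evolution:
// ds_{n+1} = ds_n * (1 + dir * dl * div F). The field (fx,fy,fz) is the unit
// normalised Laplace gradient pointing toward the inner (WM) boundary; the
// WM-ward trace follows +F, the pial-ward trace follows -F. Positions are
// continuous 0-based voxel coordinates; dl is a world-unit step.
// [[Rcpp::export]]
List cpp_trace_ratio(NumericVector fx, NumericVector fy, NumericVector fz,
                     NumericVector dv, LogicalVector domain, IntegerVector dim,
                     NumericVector spacing, double dl, int max_steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  NumericVector v_wm(n, NA_REAL), v_pial(n, NA_REAL);
  LogicalVector ok(n, false);
  std::vector<int> vmask(n);
  for (R_xlen_t t = 0; t < n; ++t) vmask[t] = domain[t] ? 1 : 0;
  const double *FX = REAL(fx), *FY = REAL(fy), *FZ = REAL(fz), *DV = REAL(dv);

  for (R_xlen_t t = 0; t < n; ++t) {
    if (!domain[t]) continue;
    const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
    bool both_ok = true;
    for (int dir = 1; dir >= -1; dir -= 2) {
      double x = i, y = j, z = k;
      double s = 1.0, V = 0.0, s_last = 1.0;
      double xp = x, yp = y, zp = z;
      bool reached = false;
      for (int st = 0; st < max_steps; ++st) {
        double w;
        const double ux = sample_masked(FX, vmask.data(), nx, ny, nz, x, y, z, &w);
        if (w < 0.5) {
          // crossed out of the domain: clip the last (already accumulated)
          // segment at the boundary by bisecting for the 0.5-weight crossing
          reached = true;
          if (st > 0) {
            double lo = 0.0, hi = 1.0;
            for (int b = 0; b < 8; ++b) {
              const double mid = 0.5 * (lo + hi);
              double wm;
              sample_masked(FX, vmask.data(), nx, ny, nz,
                            xp + mid * (x - xp), yp + mid * (y - yp),
                            zp + mid * (z - zp), &wm);
              if (wm < 0.5) hi = mid; else lo = mid;
            }
            V -= (1.0 - 0.5 * (lo + hi)) * s_last * dl;
          }
          break;
        }
        const double uy = sample_masked(FY, vmask.data(), nx, ny, nz, x, y, z, &w);
        const double uz = sample_masked(FZ, vmask.data(), nx, ny, nz, x, y, z, &w);
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (!finite_d(nrm) || nrm < 1e-6) { reached = false; break; }
        const double dvv = sample_masked(DV, vmask.data(), nx, ny, nz, x, y, z, &w);
        V += s * dl;
        s_last = s;
        double growth = 1.0 + dir * dl * (finite_d(dvv) ? dvv : 0.0);
        if (growth < 0.05) growth = 0.05;
        s *= growth;
        xp = x; yp = y; zp = z;
        x += dir * dl * ux / (nrm * h[0]);
        y += dir * dl * uy / (nrm * h[1]);
        z += dir * dl * uz / (nrm * h[2]);
      }
      if (dir > 0) v_wm[t] = V; else v_pial[t] = V;
      if (!reached) both_ok = false;
    }
    ok[t] = both_ok;
  }
  return List::create(_["v_wm"] = v_wm, _["v_pial"] = v_pial, _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6 or 26 connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t t0 = 0; t0 < n; ++t0) {
    if (!mask[t0] || lab[t0] != 0) continue;
    ++next;
    lab[t0] = next;
    stack.clear();
    stack.push_back(t0);
    while (!stack.empty()) {
      const R_xlen_t t = stack.back(); stack.pop_back();
      const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && ad > 1) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            const R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test on the 3x3x3 neighbourhood (Malandain-style topological
// numbers): the voxel is simple iff the foreground 26-components in N26 equal
// 1 and the background 6-components in N18 touching a face neighbour equal 1.
static bool simple_point(const std::vector<unsigned char> &fg,
                         int nx, int ny, int nz, int i, int j, int k) {
  unsigned char nb[27];
  int idx = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++idx) {
        const int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
          nb[idx] = 0;
          continue;
        }
        nb[idx] = fg[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
      }
  nb[13] = 0; // centre removed
  // T26: 26-components of foreground among the 26 neighbours
  int comp26 = 0;
  bool seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp26;
    int stack[27], sp = 0;
    stack[sp++] = s; seen[s] = true;
    while (sp) {
      const int c = stack[--sp];
      const int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || seen[q] || !nb[q]) continue;
        const int qi = q % 3, qj = (q / 3) % 3, qk = q / 9;
        if (std::abs(qi - ci) <= 1 && std::abs(qj - cj) <= 1 && std::abs(qk - ck) <= 1) {
          seen[q] = true; stack[sp++] = q;
        }
      }
    }
  }
  if (comp26 != 1) return false;
  // T6: 6-components of background within N18 containing a face neighbour
  const int face[6] = {4, 10, 12, 14, 16, 22};
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    const int si = s % 3 - 1, sj = (s / 3) % 3 - 1, sk = s / 9 - 1;
    const int ad = std::abs(si) + std::abs(sj) + std::abs(sk);
    in18[s] = (ad >= 1 && ad <= 2);
  }
  bool seenb[27] = {false};
  int comp6 = 0;
  for (int f = 0; f < 6; ++f) {
    const int s = face[f];
    if (nb[s] || seenb[s]) continue;
    ++comp6;
    int stack[27], sp = 0;
    stack[sp++] = s; seenb[s] = true;
    while (sp) {
      const int c = stack[--sp];
      const int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int q = 0; q < 27; ++q) {
        if (seenb[q] || nb[q] || !in18[q]) continue;
        const int qi = q % 3, qj = (q / 3) % 3, qk = q / 9;
        const int ad = std::abs(qi - ci) + std::abs(qj - cj) + std::abs(qk - ck);
        if (ad == 1) { seenb[q] = true; stack[sp++] = q; }
      }
    }
  }
  return comp6 == 1;
}

// Recursive geodesic erosion: remove simple points in increasing `ord` order
// until stable, leaving a thin connectivity-preserving sheet. Only locally
// thick voxels (>= min_fg foreground 26-neighbours; a one-voxel sheet
// interior has at most 8) are candidates for removal, so open sheets are
// thinned across but never peeled away from their free edges.
// [[Rcpp::export]]
LogicalVector cpp_thin_sheet(LogicalVector cand, NumericVector ord,
                             IntegerVector dim, int min_fg = 9) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> fg(n, 0);
  std::vector<R_xlen_t> vox;
  for (R_xlen_t t = 0; t < n; ++t)
    if (cand[t]) { fg[t] = 1; vox.push_back(t); }
  std::sort(vox.begin(), vox.end(), [&](R_xlen_t a, R_xlen_t b) {
    return ord[a] < ord[b];
  });
  bool changed = true;
  int pass = 0;
  while (changed && pass < 100) {
    changed = false;
    ++pass;
    for (size_t q = 0; q < vox.size(); ++q) {
      const R_xlen_t t = vox[q];
      if (!fg[t]) continue;
      const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
      int nfg = 0;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            if (fg[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) ++nfg;
          }
      if (nfg < min_fg) continue;
      if (simple_point(fg, nx, ny, nz, i, j, k)) {
        fg[t] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n, false);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = fg[t] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Unit eigenvector of the algebraically smallest eigenvalue of symmetric 3x3
// matrices (the across-ridge direction when applied to the Hessian of a
// distance map at a collision shock).
// [[Rcpp::export]]
NumericMatrix cpp_sym3_minvec(NumericVector xx, NumericVector xy, NumericVector xz,
                              NumericVector yy, NumericVector yz, NumericVector zz) {
  const R_xlen_t n = xx.size();
  NumericMatrix out(n, 4); // vx, vy, vz, lambda_min
  for (R_xlen_t t = 0; t < n; ++t) {
    double a[3][3] = {{xx[t], xy[t], xz[t]},
                      {xy[t], yy[t], yz[t]},
                      {xz[t], yz[t], zz[t]}};
    double V[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    bool bad = false;
    for (int r2 = 0; r2 < 3 && !bad; ++r2)
      for (int c2 = 0; c2 < 3; ++c2)
        if (!finite_d(a[r2][c2])) { bad = true; break; }
    if (bad) {
      out(t, 0) = NA_REAL; out(t, 1) = NA_REAL; out(t, 2) = NA_REAL;
      out(t, 3) = NA_REAL;
      continue;
    }
    for (int sweep = 0; sweep < 30; ++sweep) {
      double offd = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
      if (offd < 1e-14) break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::fabs(a[p][q]) < 1e-300) continue;
          const double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
          const double tsign = theta >= 0 ? 1.0 : -1.0;
          const double tt = tsign / (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
          const double c = 1.0 / std::sqrt(tt * tt + 1.0), sv = tt * c;
          double ap[3], aq[3];
          for (int r2 = 0; r2 < 3; ++r2) { ap[r2] = a[p][r2]; aq[r2] = a[q][r2]; }
          for (int r2 = 0; r2 < 3; ++r2) {
            a[p][r2] = c * ap[r2] - sv * aq[r2];
            a[q][r2] = sv * ap[r2] + c * aq[r2];
          }
          for (int r2 = 0; r2 < 3; ++r2) { ap[r2] = a[r2][p]; aq[r2] = a[r2][q]; }
          for (int r2 = 0; r2 < 3; ++r2) {
            a[r2][p] = c * ap[r2] - sv * aq[r2];
            a[r2][q] = sv * ap[r2] + c * aq[r2];
          }
          for (int r2 = 0; r2 < 3; ++r2) { ap[r2] = V[r2][p]; aq[r2] = V[r2][q]; }
          for (int r2 = 0; r2 < 3; ++r2) {
            V[r2][p] = c * ap[r2] - sv * aq[r2];
            V[r2][q] = sv * ap[r2] + c * aq[r2];
          }
        }
    }
    int imin = 0;
    if (a[1][1] < a[imin][imin]) imin = 1;
    if (a[2][2] < a[imin][imin]) imin = 2;
    out(t, 0) = V[0][imin]; out(t, 1) = V[1][imin]; out(t, 2) = V[2][imin];
    out(t, 3) = a[imin][imin];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (zero padding; kernels truncated at 3 sigma).
// sigma is in voxels, per axis; non-positive sigma skips the axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dim,
                         NumericVector sigma) {
  const int nd[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = (R_xlen_t)nd[0] * nd[1] * nd[2];
  std::vector<double> cur(REAL(arr), REAL(arr) + n), nxt(n);
  const R_xlen_t off[3] = {1, nd[0], (R_xlen_t)nd[0] * nd[1]};
  for (int a = 0; a < 3; ++a) {
    const double s = sigma[a];
    if (!(s > 0)) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double ks = 0;
    for (int q = -r; q <= r; ++q) {
      ker[q + r] = std::exp(-0.5 * q * q / (s * s));
      ks += ker[q + r];
    }
    for (int q = 0; q <= 2 * r; ++q) ker[q] /= ks;
    for (R_xlen_t t = 0; t < n; ++t) {
      const int i = (int)(t % nd[0]), j = (int)((t / nd[0]) % nd[1]),
                k = (int)(t / ((R_xlen_t)nd[0] * nd[1]));
      const int ci[3] = {i, j, k};
      double acc = 0;
      for (int q = -r; q <= r; ++q) {
        const int c = ci[a] + q;
        if (c < 0 || c >= nd[a]) continue;
        acc += ker[q + r] * cur[t + (R_xlen_t)q * off[a]];
      }
      nxt[t] = acc;
    }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// ---------------------------------------------------------------------------
// Eigenvalues of symmetric 3x3 matrices by cyclic Jacobi rotations, returned
// sorted by absolute value (|l1| <= |l2| <= |l3|).
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigs(NumericVector xx, NumericVector xy, NumericVector xz,
                            NumericVector yy, NumericVector yz, NumericVector zz) {
  const R_xlen_t n = xx.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t t = 0; t < n; ++t) {
    double a[3][3] = {{xx[t], xy[t], xz[t]},
                      {xy[t], yy[t], yz[t]},
                      {xz[t], yz[t], zz[t]}};
    for (int sweep = 0; sweep < 30; ++sweep) {
      double offd = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
      if (offd < 1e-14) break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::fabs(a[p][q]) < 1e-300) continue;
          const double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
          const double tsign = theta >= 0 ? 1.0 : -1.0;
          const double tt = tsign / (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
          const double c = 1.0 / std::sqrt(tt * tt + 1.0), sv = tt * c;
          double ap[3], aq[3];
          for (int r2 = 0; r2 < 3; ++r2) { ap[r2] = a[p][r2]; aq[r2] = a[q][r2]; }
          for (int r2 = 0; r2 < 3; ++r2) {
            a[p][r2] = c * ap[r2] - sv * aq[r2];
            a[q][r2] = sv * ap[r2] + c * aq[r2];
          }
          for (int r2 = 0; r2 < 3; ++r2) { ap[r2] = a[r2][p]; aq[r2] = a[r2][q]; }
          for (int r2 = 0; r2 < 3; ++r2) {
            a[r2][p] = c * ap[r2] - sv * aq[r2];
            a[r2][q] = sv * ap[r2] + c * aq[r2];
          }
        }
    }
    double ev[3] = {a[0][0], a[1][1], a[2][2]};
    // sort by absolute value
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q)
        if (std::fabs(ev[q]) < std::fabs(ev[p])) std::swap(ev[p], ev[q]);
    out(t, 0) = ev[0]; out(t, 1) = ev[1]; out(t, 2) = ev[2];
  }
  return out;
}
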