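#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Masks arrive as integer matrices in R layout (row = y, column = x).
// All exported coordinates are 0-based with x = column, y = row.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      lab(r0, c0) = ++next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Zhang-Suen thinning with an active-front queue so long bands thin in
// time proportional to their area, not area x thickness.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m(clone(mask));
  for (int i = 0; i < nr * nc; ++i) m[i] = m[i] != 0 ? 1 : 0;

  std::vector<int> cand;
  std::vector<char> inCand((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (m(r, c)) {
        bool edge = false;
        for (int dr = -1; dr <= 1 && !edge; ++dr)
          for (int dc = -1; dc <= 1 && !edge; ++dc)
            if (!at(m, r + dr, c + dc)) edge = true;
        if (edge) {
          cand.push_back(r + nr * c);
          inCand[(size_t)r + (size_t)nr * c] = 1;
        }
      }

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        int idx = cand[k];
        int r = idx % nr, c = idx / nr;
        if (!m(r, c)) continue;
        // neighbours clockwise from north: p2..p9
        int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1);
        int p4 = at(m, r, c + 1),     p5 = at(m, r + 1, c + 1);
        int p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1);
        int p8 = at(m, r, c - 1),     p9 = at(m, r - 1, c - 1);
        int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (b < 2 || b > 6) continue;
        int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (a != 1) continue;
        if (pass == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        kill.push_back(idx);
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) {
        int idx = kill[k];
        int r = idx % nr, c = idx / nr;
        m(r, c) = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            size_t j = (size_t)rr + (size_t)nr * cc;
            if (m(rr, cc) && !inCand[j]) {
              inCand[j] = 1;
              cand.push_back(rr + nr * cc);
            }
          }
      }
    }
  }
  return m;
}

// Even-odd rule: a point on the ray-crossing boundary follows the
// half-open convention (edges [y_i, y_j) counted once).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(const NumericVector& px,
                                    const NumericVector& py,
                                    const NumericMatrix& poly) {
  const int n = px.size(), nv = poly.nrow();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    bool in = false;
    double x = px[i], y = py[i];
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      double xa = poly(a, 0), ya = poly(a, 1);
      double xb = poly(b, 0), yb = poly(b, 1);
      if ((ya > y) != (yb > y)) {
        double xint = xa + (y - ya) * (xb - xa) / (yb - ya);
        if (x < xint) in = !in;
      }
    }
    inside[i] = in;
  }
  return inside;
}

// Moore-neighbour boundary tracing of the component carrying `label`,
// with backtracking and Jacob's stopping criterion (stop when the start
// pixel is re-entered from the original backtrack position). Returns an
// ordered closed contour as (x, y) 0-based coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_trace_boundary(const IntegerMatrix& lab, int label) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  for (int c = 0; c < nc && sr < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return NumericMatrix(0, 2);

  // neighbour offsets in consistent rotational order starting west
  const int dr[8] = { 0, -1, -1, -1, 0, 1, 1, 1 };
  const int dc[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  // start was found scanning columns left-to-right, so its west neighbour
  // is background: that is the initial backtrack position
  int r = sr, c = sc;
  int btr = sr, btc = sc - 1;
  const int btr0 = btr, btc0 = btc;

  std::vector<int> xs, ys;
  const size_t maxsteps = 4 * ((size_t)nr * nc + 4);
  size_t steps = 0;
  int start_visits = 0;
  bool first = true;
  while (steps++ < maxsteps) {
    if (!first && r == sr && c == sc) {
      // Jacob's criterion, plus a visit cap: a legitimate trace passes the
      // start at most twice (once per side of a one-pixel spur)
      if ((btr == btr0 && btc == btc0) || ++start_visits >= 3) break;
    }
    xs.push_back(c);
    ys.push_back(r);
    first = false;
    // locate the backtrack position among the neighbours
    int i0 = 0;
    for (int d = 0; d < 8; ++d)
      if (r + dr[d] == btr && c + dc[d] == btc) { i0 = d; break; }
    int found = -1;
    int pr = btr, pc = btc;  // last background position examined
    for (int k = 1; k <= 8; ++k) {
      int d = (i0 + k) % 8;
      int rr = r + dr[d], cc = c + dc[d];
      bool fg = rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) == label;
      if (fg) { found = d; break; }
      pr = rr; pc = cc;
    }
    if (found < 0) break;  // isolated pixel
    btr = pr; btc = pc;
    r += dr[found];
    c += dc[found];
  }

  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}
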