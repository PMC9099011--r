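#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxel (r,c,s) is 1-based; its continuous extent is [r-1, r) x ... with
// center (r-0.5, c-0.5, s-0.5). Flat index follows R array layout.
static inline int flat3(int r, int c, int s, int X, int Y) {
  return (r - 1) + (c - 1) * X + (s - 1) * X * Y;
}

// Parametric boundary-crossing traversal of the segment joining two voxel
// centers. At an exact corner/edge hit (tied boundary crossings) all tied
// axes advance together: the corner-touched side voxels have zero chord
// inside the segment and are not part of the voxelization.
static std::vector<std::array<int,3> > trace_line(const int start[3],
                                                  const int goal[3]) {
  std::vector<std::array<int,3> > out;
  int cur[3] = {start[0], start[1], start[2]};
  out.push_back({cur[0], cur[1], cur[2]});
  if (cur[0] == goal[0] && cur[1] == goal[1] && cur[2] == goal[2]) return out;

  double p[3], d[3], tMax[3], tDelta[3];
  int step[3];
  for (int i = 0; i < 3; ++i) {
    p[i] = cur[i] - 0.5;              // 0-based center
    d[i] = (double)(goal[i] - start[i]);
    if (d[i] > 0) {
      step[i] = 1;
      tMax[i] = ((double)cur[i] - p[i]) / d[i];   // upper boundary at cur (0-based cur = cur-1, upper = cur)
      tDelta[i] = 1.0 / d[i];
    } else if (d[i] < 0) {
      step[i] = -1;
      tMax[i] = (((double)cur[i] - 1.0) - p[i]) / d[i]; // lower boundary
      tDelta[i] = -1.0 / d[i];
    } else {
      step[i] = 0;
      tMax[i] = R_PosInf;
      tDelta[i] = R_PosInf;
    }
  }

  const double tol = 1e-12;
  int guard = 4 * (std::abs(goal[0] - start[0]) + std::abs(goal[1] - start[1]) +
                   std::abs(goal[2] - start[2])) + 8;
  while (guard-- > 0) {
    double m = std::min(tMax[0], std::min(tMax[1], tMax[2]));
    if (m > 1.0 + tol) break;  // past the goal center
    for (int i = 0; i < 3; ++i)
      if (tMax[i] <= m + tol) { cur[i] += step[i]; tMax[i] += tDelta[i]; }
    out.push_back({cur[0], cur[1], cur[2]});
    if (cur[0] == goal[0] && cur[1] == goal[1] && cur[2] == goal[2]) break;
  }
  // ensure the goal terminates the list even under numerical slack
  const std::array<int,3> &last = out.back();
  if (last[0] != goal[0] || last[1] != goal[1] || last[2] != goal[2])
    out.push_back({goal[0], goal[1], goal[2]});
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_trace_line(IntegerVector start, IntegerVector goal) {
  int s[3] = {start[0], start[1], start[2]};
  int g[3] = {goal[0], goal[1], goal[2]};
  std::vector<std::array<int,3> > v = trace_line(s, g);
  IntegerMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i)
    for (int j = 0; j < 3; ++j) m(i, j) = v[i][j];
  return m;
}

// Score many center lines at a sampling stride. lut is indexed by label
// value (lut[0] = 0 for background); voxels outside the head mask score 0.
// [[Rcpp::export]]
List cpp_score_lines(IntegerMatrix starts, IntegerMatrix goals,
                     int stride, IntegerVector labels, NumericVector lut,
                     LogicalVector mask, IntegerVector dims) {
  int X = dims[0], Y = dims[1];
  int k = starts.nrow();
  NumericVector penalty(k);
  IntegerVector len(k);
  for (int w = 0; w < k; ++w) {
    int s[3] = {starts(w, 0), starts(w, 1), starts(w, 2)};
    int g[3] = {goals(w, 0), goals(w, 1), goals(w, 2)};
    std::vector<std::array<int,3> > line = trace_line(s, g);
    double pen = 0.0;
    int L = (int)line.size();
    for (int i = 0; i < L; i += stride) {
      int f = flat3(line[i][0], line[i][1], line[i][2], X, Y);
      if (mask[f]) {
        int lab = labels[f];
        if (lab > 0) pen += lut[lab];
      }
    }
    penalty[w] = pen;
    len[w] = L;
  }
  return List::create(_["penalty"] = penalty, _["length"] = len);
}

// Nearest candidate (Euclidean on voxel indices) per query point;
// candidates must be pre-sorted lexicographically so that strict "<"
// keeps the lexicographically smallest among ties.
// [[Rcpp::export]]
IntegerVector cpp_nearest_voxel(IntegerMatrix points, IntegerMatrix cand) {
  int k = points.nrow(), m = cand.nrow();
  IntegerVector idx(k);
  for (int i = 0; i < k; ++i) {
    double best = R_PosInf;
    int bestj = 0;
    double p0 = points(i, 0), p1 = points(i, 1), p2 = points(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = cand(j, 0) - p0, d1 = cand(j, 1) - p1, d2 = cand(j, 2) - p2;
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
  }
  return idx;
}

// 26-connected components of a 3D logical mask; labels assigned in
// flat scan order. Returns integer vector (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_connected_components(LogicalVector mask, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int n = X * Y * Z;
  IntegerVector comp(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int f0 = 0; f0 < n; ++f0) {
    if (!mask[f0] || comp[f0] != 0) continue;
    ++next;
    comp[f0] = next;
    stack.clear();
    stack.push_back(f0);
    while (!stack.empty()) {
      int f = stack.back();
      stack.pop_back();
      int s = f / (X * Y), rem = f % (X * Y), c = rem / X, r = rem % X;
      for (int ds = -1; ds <= 1; ++ds)
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc && !ds) continue;
            int nr = r + dr, nc = c + dc, ns = s + ds;
            if (nr < 0 || nr >= X || nc < 0 || nc >= Y || ns < 0 || ns >= Z)
              continue;
            int nf = nr + nc * X + ns * X * Y;
            if (mask[nf] && comp[nf] == 0) {
              comp[nf] = next;
              stack.push_back(nf);
            }
          }
    }
  }
  return comp;
}
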