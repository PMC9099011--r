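#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int flat3(int r, int c, int s, int X, int Y) {
  return (r - 1) + (c - 1) * X + (s - 1) * X * Y;
}

// Fixed enumeration of the 26 unit offsets: lexicographic over
// (dr, dc, ds) in {-1,0,1}^3 minus the origin. Must match actionOffsets().
static void action_table(int off[26][3]) {
  int k = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc)
      for (int ds = -1; ds <= 1; ++ds) {
        if (!dr && !dc && !ds) continue;
        off[k][0] = dr; off[k][1] = dc; off[k][2] = ds;
        ++k;
      }
}

// Tabular Q-learning over an admissible voxel-node set. Transition reward
// is the reward of the destination node; terminal destinations end the
// episode. Uses R's RNG, so results are reproducible under set.seed().
// Q (nodes x 26) is updated in place.
// [[Rcpp::export]]
List cpp_train(IntegerVector nodeIndex, IntegerVector dims,
               NumericVector reward, IntegerVector terminal,
               IntegerMatrix starts, IntegerMatrix nodeVoxels,
               NumericMatrix Q,
               int episodes, double alpha, double gamma,
               double eps0, double eps1, int maxSteps,
               bool uniformStart) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int off[26][3];
  action_table(off);
  int nStarts = starts.nrow(), nNodes = nodeVoxels.nrow();
  NumericVector epReturn(episodes);
  IntegerVector epSteps(episodes), epCause(episodes);

  int adm[26], nAdm;
  for (int ep = 0; ep < episodes; ++ep) {
    double eps = (episodes > 1)
      ? eps0 + (eps1 - eps0) * ((double)ep / (double)(episodes - 1))
      : eps0;
    int cur[3];
    if (uniformStart) {
      int j = (int)(unif_rand() * nNodes);
      if (j >= nNodes) j = nNodes - 1;
      cur[0] = nodeVoxels(j, 0); cur[1] = nodeVoxels(j, 1); cur[2] = nodeVoxels(j, 2);
    } else {
      int j = (int)(unif_rand() * nStarts);
      if (j >= nStarts) j = nStarts - 1;
      cur[0] = starts(j, 0); cur[1] = starts(j, 1); cur[2] = starts(j, 2);
    }
    double ret = 0.0, gpow = 1.0;
    int steps = 0, cause = 0;
    while (steps < maxSteps) {
      int fcur = flat3(cur[0], cur[1], cur[2], X, Y);
      int ni = nodeIndex[fcur];
      // admissible actions at cur
      nAdm = 0;
      for (int a = 0; a < 26; ++a) {
        int nr = cur[0] + off[a][0], nc = cur[1] + off[a][1], ns = cur[2] + off[a][2];
        if (nr < 1 || nr > X || nc < 1 || nc > Y || ns < 1 || ns > Z) continue;
        if (nodeIndex[flat3(nr, nc, ns, X, Y)] > 0) adm[nAdm++] = a;
      }
      if (nAdm == 0) { cause = 3; break; }
      int a;
      if (unif_rand() < eps) {
        int j = (int)(unif_rand() * nAdm);
        if (j >= nAdm) j = nAdm - 1;
        a = adm[j];
      } else {
        a = adm[0];
        double best = Q(ni - 1, adm[0]);
        for (int j = 1; j < nAdm; ++j)
          if (Q(ni - 1, adm[j]) > best) { best = Q(ni - 1, adm[j]); a = adm[j]; }
      }
      int nr = cur[0] + off[a][0], nc = cur[1] + off[a][1], ns = cur[2] + off[a][2];
      int fdst = flat3(nr, nc, ns, X, Y);
      int nj = nodeIndex[fdst];
      double r = reward[fdst];
      ret += gpow * r;
      gpow *= gamma;
      ++steps;
      double maxFuture = 0.0;
      if (!terminal[fdst]) {
        bool any = false;
        for (int b = 0; b < 26; ++b) {
          int mr = nr + off[b][0], mc = nc + off[b][1], ms = ns + off[b][2];
          if (mr < 1 || mr > X || mc < 1 || mc > Y || ms < 1 || ms > Z) continue;
          if (nodeIndex[flat3(mr, mc, ms, X, Y)] > 0) {
            double qv = Q(nj - 1, b);
            if (!any || qv > maxFuture) { maxFuture = qv; any = true; }
          }
        }
        if (!any) maxFuture = 0.0;
      }
      Q(ni - 1, a) += alpha * (r + gamma * maxFuture - Q(ni - 1, a));
      if (terminal[fdst]) { cause = (r > 0) ? 1 : 2; break; }
      cur[0] = nr; cur[1] = nc; cur[2] = ns;
    }
    epReturn[ep] = ret;
    epSteps[ep] = steps;
    epCause[ep] = cause;
  }
  return List::create(_["returns"] = epReturn, _["steps"] = epSteps,
                      _["cause"] = epCause);
}

// Bellman-optimal state values under the same reward-on-entry semantics
// (terminal and action-less states have value 0); synchronous sweeps
// until the max change drops below tol.
// [[Rcpp::export]]
NumericVector cpp_value_iteration(IntegerVector nodeIndex, IntegerVector dims,
                                  NumericVector reward, IntegerVector terminal,
                                  IntegerMatrix nodeVoxels, double gamma,
                                  double tol, int maxIter) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int off[26][3];
  action_table(off);
  int N = nodeVoxels.nrow();
  NumericVector V(N, 0.0), Vn(N, 0.0);
  std::vector<int> flatOf(N), termOf(N);
  for (int i = 0; i < N; ++i) {
    flatOf[i] = flat3(nodeVoxels(i, 0), nodeVoxels(i, 1), nodeVoxels(i, 2), X, Y);
    termOf[i] = terminal[flatOf[i]];
  }
  for (int it = 0; it < maxIter; ++it) {
    double delta = 0.0;
    for (int i = 0; i < N; ++i) {
      if (termOf[i]) { Vn[i] = 0.0; continue; }
      int r = nodeVoxels(i, 0), c = nodeVoxels(i, 1), s = nodeVoxels(i, 2);
      double best = 0.0;
      bool any = false;
      for (int a = 0; a < 26; ++a) {
        int nr = r + off[a][0], nc = c + off[a][1], ns = s + off[a][2];
        if (nr < 1 || nr > X || nc < 1 || nc > Y || ns < 1 || ns > Z) continue;
        int fdst = flat3(nr, nc, ns, X, Y);
        int nj = nodeIndex[fdst];
        if (nj <= 0) continue;
        double q = reward[fdst] + (terminal[fdst] ? 0.0 : gamma * V[nj - 1]);
        if (!any || q > best) { best = q; any = true; }
      }
      Vn[i] = any ? best : 0.0;
      double d = std::fabs(Vn[i] - V[i]);
      if (d > delta) delta = d;
    }
    std::copy(Vn.begin(), Vn.end(), V.begin());
    if (delta < tol) break;
  }
  return V;
}
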