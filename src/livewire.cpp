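// Dijkstra shortest path on the 8-connected pixel graph with
// intelligent-scissors local edge costs
//   l(p,q) = [ w_Z * f_Z(q) + w_D * f_D(p,q) + w_G * f_G(q) ] * len(p,q)
// len = 1 for axial moves, sqrt(2) for diagonal. Ties are broken by the fixed
// neighbor order N, NE, E, SE, S, SW, W, NW and FIFO among equal keys, so the
// returned path is identical across runs and platforms.

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <cmath>
using namespace Rcpp;

static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1}; // N NE E SE S SW W NW
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// direction feature, scaled to [0,1]; dgr/dgc are unit gradient components
static inline double f_dir(double pr_g, double pc_g, double qr_g, double qc_g,
                           int dr, int dc, double len) {
  bool pzero = (pr_g == 0.0 && pc_g == 0.0);
  bool qzero = (qr_g == 0.0 && qc_g == 0.0);
  if (pzero && qzero) return 0.0;
  // D(p): unit vector perpendicular to the gradient
  double dpr = -pc_g, dpc = pr_g;
  double dqr = -qc_g, dqc = qr_g;
  double lr = dr / len, lc = dc / len;
  if (dpr * lr + dpc * lc < 0) { lr = -lr; lc = -lc; }
  double d_p = dpr * lr + dpc * lc;       // in [0,1]
  double d_q = lr * dqr + lc * dqc;       // in [-1,1]
  if (d_p > 1.0) d_p = 1.0; if (d_p < -1.0) d_p = -1.0;
  if (d_q > 1.0) d_q = 1.0; if (d_q < -1.0) d_q = -1.0;
  return (std::acos(d_p) + std::acos(d_q)) * (2.0 / (3.0 * M_PI));
}

// [[Rcpp::export(name = ".dijkstra_cpp")]]
List dijkstra_cpp(NumericMatrix fZ, NumericMatrix fG,
                  NumericMatrix dgr, NumericMatrix dgc,
                  NumericVector weights, IntegerVector start,
                  IntegerVector end) {
  const int nr = fZ.nrow(), nc = fZ.ncol();
  const double wz = weights[0], wg = weights[1], wd = weights[2];
  const int s = (start[0] - 1) + (start[1] - 1) * nr;
  const int t = (end[0] - 1) + (end[1] - 1) * nr;
  const double SQRT2 = std::sqrt(2.0);

  std::vector<double> dist(nr * nc, R_PosInf);
  std::vector<int> pred(nr * nc, -1);
  std::vector<char> done(nr * nc, 0);

  typedef std::tuple<double, long long, int> QN; // cost, fifo counter, node
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  long long counter = 0;
  dist[s] = 0.0;
  pq.push(QN(0.0, counter++, s));

  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int u = std::get<2>(top);
    if (done[u]) continue;
    done[u] = 1;
    if (u == t) break;
    int ur = u % nr, uc = u / nr;
    double du = dist[u];
    for (int k = 0; k < 8; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      if (done[v]) continue;
      double len = (DR[k] != 0 && DC[k] != 0) ? SQRT2 : 1.0;
      double fd = f_dir(dgr(ur, uc), dgc(ur, uc), dgr(vr, vc), dgc(vr, vc),
                        DR[k], DC[k], len);
      double w = (wz * fZ(vr, vc) + wd * fd + wg * fG(vr, vc)) * len;
      double alt = du + w;
      if (alt < dist[v]) {
        dist[v] = alt;
        pred[v] = u;
        pq.push(QN(alt, counter++, v));
      }
    }
  }

  if (!R_FINITE(dist[t])) stop("no path found (disconnected graph?)");

  std::vector<int> nodes;
  for (int v = t; v != -1; v = pred[v]) nodes.push_back(v);
  const int m = nodes.size();
  IntegerMatrix path(m, 2);
  for (int i = 0; i < m; ++i) {
    int v = nodes[m - 1 - i];
    path(i, 0) = v % nr + 1;
    path(i, 1) = v / nr + 1;
  }
  return List::create(_["path"] = path, _["cost"] = dist[t]);
}
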