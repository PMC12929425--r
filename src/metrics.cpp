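#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Weighted NODF (nested overlap and decreasing fill).
// For every unordered pair of rows, the member with the strictly larger
// binary fill (number of positive cells) is the "richer"; the pair scores
// 100 * #{k : 0 < w_poor,k < w_rich,k} / #{k : w_poor,k > 0}.
// Pairs with tied fills score 0 (the decreasing-fill condition is strict).
// Same over column pairs; the index is the mean over all row pairs and
// column pairs. Order-independent by construction.
// [[Rcpp::export]]
double wnodf_cpp(NumericMatrix w) {
  int nr = w.nrow(), nc = w.ncol();
  if (nr < 2 || nc < 2) stop("weighted NODF needs at least 2 rows and 2 columns");
  std::vector<int> rf(nr, 0), cf(nc, 0);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (w(i, j) > 0) { ++rf[i]; ++cf[j]; }

  double sum = 0.0;
  long npairs = 0;
  for (int a = 0; a < nr - 1; ++a) {
    for (int b = a + 1; b < nr; ++b) {
      ++npairs;
      if (rf[a] == rf[b] || rf[a] == 0 || rf[b] == 0) continue;
      int rich = rf[a] > rf[b] ? a : b;
      int poor = rich == a ? b : a;
      int nless = 0;
      for (int k = 0; k < nc; ++k) {
        double wp = w(poor, k);
        if (wp > 0 && wp < w(rich, k)) ++nless;
      }
      sum += 100.0 * nless / rf[poor];
    }
  }
  for (int a = 0; a < nc - 1; ++a) {
    for (int b = a + 1; b < nc; ++b) {
      ++npairs;
      if (cf[a] == cf[b] || cf[a] == 0 || cf[b] == 0) continue;
      int rich = cf[a] > cf[b] ? a : b;
      int poor = rich == a ? b : a;
      int nless = 0;
      for (int k = 0; k < nr; ++k) {
        double wp = w(k, poor);
        if (wp > 0 && wp < w(k, rich)) ++nless;
      }
      sum += 100.0 * nless / cf[poor];
    }
  }
  return sum / npairs;
}

static double q_from_labels(const NumericMatrix& w,
                            const std::vector<int>& rlab,
                            const std::vector<int>& clab,
                            const std::vector<double>& rt,
                            const std::vector<double>& ct,
                            double m) {
  double q = 0.0;
  int nr = w.nrow(), nc = w.ncol();
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (rlab[i] == clab[j]) q += w(i, j) - rt[i] * ct[j] / m;
  return q / m;
}

// Barber bipartite modularity of a given partition:
// Q = (1/m) sum_ij (w_ij - r_i c_j / m) [plant i and pollinator j share a module]
// [[Rcpp::export]]
double barber_q_cpp(NumericMatrix w, IntegerVector row_labels, IntegerVector col_labels) {
  int nr = w.nrow(), nc = w.ncol();
  if (row_labels.size() != nr || col_labels.size() != nc)
    stop("partition does not cover all vertices");
  std::vector<double> rt(nr, 0.0), ct(nc, 0.0);
  double m = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) { rt[i] += w(i, j); ct[j] += w(i, j); m += w(i, j); }
  if (m <= 0) stop("network has no positive weight");
  std::vector<int> rl(row_labels.begin(), row_labels.end());
  std::vector<int> cl(col_labels.begin(), col_labels.end());
  return q_from_labels(w, rl, cl, rt, ct, m);
}

// one label-propagation sweep phase + agglomerative merging, seeded by the
// R RNG (RNGScope supplied by Rcpp attributes). Labels start unique per row.
static void compactify(std::vector<int>& rlab, std::vector<int>& clab, int& nlab) {
  std::map<int, int> remap;
  int next = 0;
  for (int& l : rlab) {
    auto it = remap.find(l);
    if (it == remap.end()) { remap[l] = next; l = next; ++next; }
    else l = it->second;
  }
  for (int& l : clab) {
    auto it = remap.find(l);
    if (it == remap.end()) { remap[l] = next; l = next; ++next; }
    else l = it->second;
  }
  nlab = next;
}

// [[Rcpp::export]]
List lpa_modularity_cpp(NumericMatrix w, bool random_init = false) {
  int nr = w.nrow(), nc = w.ncol();
  std::vector<double> rt(nr, 0.0), ct(nc, 0.0);
  double m = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) { rt[i] += w(i, j); ct[j] += w(i, j); m += w(i, j); }
  if (m <= 0) stop("network has no positive weight");

  const double eps = 1e-12;
  // canonical start: every row in its own module; random starts (used for
  // later restarts) draw labels from a random number of modules so that
  // restarts explore genuinely different partitions
  std::vector<int> rlab(nr), clab(nc, -1);
  if (random_init) {
    int k0 = 1 + (int)(unif_rand() * nr);
    if (k0 > nr) k0 = nr;
    for (int i = 0; i < nr; ++i) {
      int l = (int)(unif_rand() * k0);
      if (l >= k0) l = k0 - 1;
      rlab[i] = l;
    }
  } else {
    for (int i = 0; i < nr; ++i) rlab[i] = i;
  }
  int nlab = nr;
  // fresh labels for columns preferring nothing yet: assign each column its
  // best row label immediately (ties -> smallest label)
  std::vector<double> score;
  auto update_cols = [&]() {
    bool changed = false;
    // random sweep order from R RNG
    std::vector<int> ord(nc);
    for (int j = 0; j < nc; ++j) ord[j] = j;
    for (int j = nc - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(ord[j], ord[k]);
    }
    score.assign(nlab, 0.0);
    for (int jj = 0; jj < nc; ++jj) {
      int j = ord[jj];
      std::fill(score.begin(), score.end(), 0.0);
      for (int i = 0; i < nr; ++i)
        score[rlab[i]] += w(i, j) - rt[i] * ct[j] / m;
      int best = -1;
      double bestv = 0.0; // singleton (no shared module) scores 0
      for (int l = 0; l < nlab; ++l)
        if (score[l] > bestv + eps) { bestv = score[l]; best = l; }
      if (best == -1) { // stay/become singleton: fresh label
        if (clab[j] >= 0) {
          // keep current only if it scores ~0 too; otherwise detach
          double cur = score[clab[j]];
          if (cur < -eps) { clab[j] = -1; changed = true; }
        }
      } else if (clab[j] != best) {
        clab[j] = best;
        changed = true;
      }
    }
    return changed;
  };
  auto update_rows = [&]() {
    bool changed = false;
    std::vector<int> ord(nr);
    for (int i = 0; i < nr; ++i) ord[i] = i;
    for (int i = nr - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(ord[i], ord[k]);
    }
    for (int ii = 0; ii < nr; ++ii) {
      int i = ord[ii];
      score.assign(nlab, 0.0);
      for (int j = 0; j < nc; ++j)
        if (clab[j] >= 0) score[clab[j]] += w(i, j) - rt[i] * ct[j] / m;
      int best = -1;
      double bestv = 0.0;
      for (int l = 0; l < nlab; ++l)
        if (score[l] > bestv + eps) { bestv = score[l]; best = l; }
      if (best == -1) {
        // isolate: fresh unique label
        if (score[rlab[i]] < -eps) { rlab[i] = nlab++; score.push_back(0.0); changed = true; }
      } else if (rlab[i] != best) {
        rlab[i] = best;
        changed = true;
      }
    }
    return changed;
  };

  update_cols();
  std::vector<int> cl0(nc);
  for (int j = 0; j < nc; ++j) cl0[j] = clab[j] < 0 ? nlab + j : clab[j];
  double q = q_from_labels(w, rlab, cl0, rt, ct, m);

  for (int outer = 0; outer < 200; ++outer) {
    bool any = false;
    // local phase
    for (int it = 0; it < 200; ++it) {
      bool c1 = update_rows();
      bool c2 = update_cols();
      std::vector<int> rtmp = rlab, ctmp(nc);
      for (int j = 0; j < nc; ++j) ctmp[j] = clab[j] < 0 ? nlab + nc + j : clab[j];
      compactify(rtmp, ctmp, nlab);
      rlab = rtmp;
      clab = ctmp;
      double qn = q_from_labels(w, rlab, clab, rt, ct, m);
      if (qn > q + eps) any = true;
      q = qn;
      if (!(c1 || c2)) break;
    }
    // agglomeration phase: merge the module pair with the best positive gain
    bool merged = true;
    while (merged) {
      merged = false;
      compactify(rlab, clab, nlab);
      if (nlab < 2) break;
      // precompute per-(module-pair) cross sums
      std::vector<std::vector<double>> gain(nlab, std::vector<double>(nlab, 0.0));
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) {
          int a = rlab[i], b = clab[j];
          if (a != b) gain[a][b] += w(i, j) - rt[i] * ct[j] / m;
        }
      int ba = -1, bb = -1;
      double bestg = eps;
      for (int a = 0; a < nlab - 1; ++a)
        for (int b = a + 1; b < nlab; ++b) {
          double g = gain[a][b] + gain[b][a];
          if (g > bestg) { bestg = g; ba = a; bb = b; }
        }
      if (ba >= 0) {
        for (int& l : rlab) if (l == bb) l = ba;
        for (int& l : clab) if (l == bb) l = ba;
        q += bestg / m;
        merged = true;
        any = true;
      }
    }
    if (!any) break;
  }
  compactify(rlab, clab, nlab);
  q = q_from_labels(w, rlab, clab, rt, ct, m);
  return List::create(_["q"] = q,
                      _["row_labels"] = IntegerVector(rlab.begin(), rlab.end()),
                      _["col_labels"] = IntegerVector(clab.begin(), clab.end()));
}

// Exhaustive maximization of Barber Q. Partitions of the smaller side are
// enumerated as restricted growth strings; each vertex on the larger side
// then joins its best-scoring module independently (or stays a singleton,
// contributing 0), which attains the global optimum for that partition.
// [[Rcpp::export]]
List exhaustive_modularity_cpp(NumericMatrix w0) {
  bool transposed = w0.nrow() > w0.ncol();
  NumericMatrix w;
  if (transposed) {
    w = NumericMatrix(w0.ncol(), w0.nrow());
    for (int i = 0; i < w0.nrow(); ++i)
      for (int j = 0; j < w0.ncol(); ++j) w(j, i) = w0(i, j);
  } else w = w0;

  int nr = w.nrow(), nc = w.ncol();
  std::vector<double> rt(nr, 0.0), ct(nc, 0.0);
  double m = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) { rt[i] += w(i, j); ct[j] += w(i, j); m += w(i, j); }
  if (m <= 0) stop("network has no positive weight");

  std::vector<int> a(nr, 0);
  std::vector<int> bestr(nr, 0), bestc(nc, 0);
  double bestq = R_NegInf;
  bool done = false;
  while (!done) {
    int k = *std::max_element(a.begin(), a.end()) + 1;
    // columns choose their best module under partition a
    double q = 0.0;
    std::vector<int> cassign(nc);
    for (int j = 0; j < nc; ++j) {
      double bv = 0.0;
      int bl = -1;
      for (int l = 0; l < k; ++l) {
        double s = 0.0;
        for (int i = 0; i < nr; ++i)
          if (a[i] == l) s += w(i, j) - rt[i] * ct[j] / m;
        if (s > bv) { bv = s; bl = l; }
      }
      cassign[j] = bl < 0 ? k + j : bl; // singleton otherwise
      q += bv;
    }
    q /= m;
    if (q > bestq + 1e-15) {
      bestq = q;
      bestr = a;
      bestc = cassign;
    }
    // next restricted growth string
    int i = nr - 1;
    while (i > 0) {
      int maxprev = 0;
      for (int t = 0; t < i; ++t) maxprev = std::max(maxprev, a[t]);
      if (a[i] <= maxprev) { ++a[i]; break; }
      a[i] = 0;
      --i;
    }
    if (i == 0) done = true;
  }
  IntegerVector rl, cl;
  if (transposed) {
    rl = IntegerVector(bestc.begin(), bestc.end());
    cl = IntegerVector(bestr.begin(), bestr.end());
  } else {
    rl = IntegerVector(bestr.begin(), bestr.end());
    cl = IntegerVector(bestc.begin(), bestc.end());
  }
  return List::create(_["q"] = bestq, _["row_labels"] = rl, _["col_labels"] = cl);
}
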