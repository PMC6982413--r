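#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Multiresolution region-merging segmentation.
//
// Objects start as single pixels and are merged bottom-up under a mutual
// best-fit rule: a merge of adjacent objects A,B executes only when its
// heterogeneity increase
//   dh = sum_b w_b * ( n_AB*sd_b(AB) - n_A*sd_b(A) - n_B*sd_b(B) )
// (population sd) is below scale^2 AND each object is the other's
// minimum-cost neighbour. Deterministic scheduling: objects visited in
// ascending id, cost ties broken towards the lower neighbour id, the merged
// object keeps the smaller id. Passes repeat until a full pass makes no merge.
//
// Two routes are provided: an incremental one carrying per-object sufficient
// statistics (n, sum, sum of squares per band), and a naive reference that
// recomputes every statistic from the pixel label array at each cost
// evaluation. For 8-bit inputs both accumulate exact integers in doubles, so
// their partitions must agree bitwise.

static inline double band_sd(double n, double s, double ss) {
  double v = ss / n - (s / n) * (s / n);
  return v > 0.0 ? std::sqrt(v) : 0.0;
}

struct ObjStats {
  double n;
  double sum[3];
  double ssq[3];
};

static inline double merge_cost(const ObjStats& a, const ObjStats& b,
                                const double* w) {
  double dh = 0.0;
  for (int k = 0; k < 3; ++k) {
    double n = a.n + b.n;
    double s = a.sum[k] + b.sum[k];
    double ss = a.ssq[k] + b.ssq[k];
    dh += w[k] * (n * band_sd(n, s, ss)
                  - a.n * band_sd(a.n, a.sum[k], a.ssq[k])
                  - b.n * band_sd(b.n, b.sum[k], b.ssq[k]));
  }
  return dh;
}

static void neighbours_of(int idx, int nrow, int ncol, int connectivity,
                          int* out, int* n_out) {
  int r = idx % nrow, c = idx / nrow, m = 0;
  if (r > 0)        out[m++] = idx - 1;
  if (r < nrow - 1) out[m++] = idx + 1;
  if (c > 0)        out[m++] = idx - nrow;
  if (c < ncol - 1) out[m++] = idx + nrow;
  if (connectivity == 8) {
    if (r > 0 && c > 0)               out[m++] = idx - 1 - nrow;
    if (r > 0 && c < ncol - 1)        out[m++] = idx - 1 + nrow;
    if (r < nrow - 1 && c > 0)        out[m++] = idx + 1 - nrow;
    if (r < nrow - 1 && c < ncol - 1) out[m++] = idx + 1 + nrow;
  }
  *n_out = m;
}

static void sorted_insert(std::vector<int>& v, int x) {
  std::vector<int>::iterator it = std::lower_bound(v.begin(), v.end(), x);
  if (it == v.end() || *it != x) v.insert(it, x);
}

static void sorted_erase(std::vector<int>& v, int x) {
  std::vector<int>::iterator it = std::lower_bound(v.begin(), v.end(), x);
  if (it != v.end() && *it == x) v.erase(it);
}

// [[Rcpp::export]]
IntegerVector cpp_mrs_segment(NumericVector red, NumericVector green,
                              NumericVector blue, LogicalVector nodata,
                              int nrow, int ncol, double scale,
                              NumericVector weights, int connectivity) {
  const int npix = nrow * ncol;
  const double s2 = scale * scale;
  double w[3] = { weights[0], weights[1], weights[2] };

  // initial ids in R column-major order over valid pixels
  std::vector<int> id_of(npix, 0);
  int nobj = 0;
  for (int i = 0; i < npix; ++i) if (!nodata[i]) id_of[i] = ++nobj;
  if (nobj == 0) return IntegerVector(npix, 0);

  std::vector<ObjStats> st(nobj + 1);
  std::vector<char> alive(nobj + 1, 1);
  std::vector<int> parent(nobj + 1);
  std::vector< std::vector<int> > adj(nobj + 1);
  for (int i = 0; i <= nobj; ++i) parent[i] = i;

  const double* band[3] = { &red[0], &green[0], &blue[0] };
  int nb_idx[8], nb_n;
  for (int i = 0; i < npix; ++i) {
    int id = id_of[i];
    if (!id) continue;
    st[id].n = 1.0;
    for (int k = 0; k < 3; ++k) {
      double v = band[k][i];
      st[id].sum[k] = v;
      st[id].ssq[k] = v * v;
    }
    neighbours_of(i, nrow, ncol, connectivity, nb_idx, &nb_n);
    for (int m = 0; m < nb_n; ++m) {
      int oid = id_of[nb_idx[m]];
      if (oid && oid != id) sorted_insert(adj[id], oid);
    }
  }

  // best (min-cost) alive neighbour, ties to the lower id; -1 if none
  // (adjacency is kept sorted so iteration order realises the tie rule)
  struct Best {
    static int find(int id, const std::vector< std::vector<int> >& adj,
                    const std::vector<ObjStats>& st,
                    const std::vector<char>& alive, const double* w,
                    double* cost_out) {
      int best = -1;
      double best_cost = 0.0;
      const std::vector<int>& nbs = adj[id];
      for (size_t m = 0; m < nbs.size(); ++m) {
        int nb = nbs[m];
        if (!alive[nb]) continue;
        double c = merge_cost(st[id], st[nb], w);
        if (best < 0 || c < best_cost) { best = nb; best_cost = c; }
      }
      *cost_out = best_cost;
      return best;
    }
  };

  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (int id = 1; id <= nobj; ++id) {
      if (!alive[id]) continue;
      double c1, c2;
      int nb = Best::find(id, adj, st, alive, w, &c1);
      if (nb < 0 || c1 >= s2) continue;
      int back = Best::find(nb, adj, st, alive, w, &c2);
      if (back != id) continue;  // not mutual best fit
      int keep = std::min(id, nb), gone = std::max(id, nb);
      st[keep].n += st[gone].n;
      for (int k = 0; k < 3; ++k) {
        st[keep].sum[k] += st[gone].sum[k];
        st[keep].ssq[k] += st[gone].ssq[k];
      }
      for (size_t m = 0; m < adj[gone].size(); ++m) {
        int x = adj[gone][m];
        if (x == keep) continue;
        sorted_erase(adj[x], gone);
        sorted_insert(adj[x], keep);
        sorted_insert(adj[keep], x);
      }
      sorted_erase(adj[keep], gone);
      std::vector<int>().swap(adj[gone]);
      alive[gone] = 0;
      parent[gone] = keep;
      merged_any = true;
    }
  }

  // path-compressed resolve, then contiguous relabel in ascending kept id
  std::vector<int> newid(nobj + 1, 0);
  int k = 0;
  for (int i = 1; i <= nobj; ++i) if (alive[i]) newid[i] = ++k;
  IntegerVector out(npix);
  for (int i = 0; i < npix; ++i) {
    int id = id_of[i];
    if (!id) { out[i] = 0; continue; }
    while (parent[id] != id) id = parent[id];
    out[i] = newid[id];
  }
  return out;
}

// Naive reference: identical scheduling, but every object statistic is
// recomputed from the pixel/label arrays at each evaluation, and merges are
// executed by relabelling pixels. Quadratic; intended for tiny images.
// [[Rcpp::export]]
IntegerVector cpp_mrs_segment_naive(NumericVector red, NumericVector green,
                                    NumericVector blue, LogicalVector nodata,
                                    int nrow, int ncol, double scale,
                                    NumericVector weights, int connectivity) {
  const int npix = nrow * ncol;
  const double s2 = scale * scale;
  double w[3] = { weights[0], weights[1], weights[2] };
  const double* band[3] = { &red[0], &green[0], &blue[0] };

  std::vector<int> lab(npix, 0);
  int nobj = 0;
  for (int i = 0; i < npix; ++i) if (!nodata[i]) lab[i] = ++nobj;
  if (nobj == 0) return IntegerVector(npix, 0);

  struct Naive {
    const std::vector<int>* lab;
    const double** band;
    int npix, nrow, ncol, conn;
    ObjStats stats(int id) const {
      ObjStats s; s.n = 0;
      for (int k = 0; k < 3; ++k) { s.sum[k] = 0; s.ssq[k] = 0; }
      for (int i = 0; i < npix; ++i) {
        if ((*lab)[i] != id) continue;
        s.n += 1.0;
        for (int k = 0; k < 3; ++k) {
          double v = band[k][i];
          s.sum[k] += v; s.ssq[k] += v * v;
        }
      }
      return s;
    }
    std::vector<int> neighbours(int id) const {
      std::vector<int> out;
      int nb[8], m;
      for (int i = 0; i < npix; ++i) {
        if ((*lab)[i] != id) continue;
        neighbours_of(i, nrow, ncol, conn, nb, &m);
        for (int j = 0; j < m; ++j) {
          int o = (*lab)[nb[j]];
          if (o && o != id) sorted_insert(out, o);
        }
      }
      return out;
    }
    int best(int id, const double* w, double* cost_out) const {
      std::vector<int> nbs = neighbours(id);
      ObjStats sa = stats(id);
      int bestid = -1; double bestc = 0.0;
      for (size_t m = 0; m < nbs.size(); ++m) {
        double c = merge_cost(sa, stats(nbs[m]), w);
        if (bestid < 0 || c < bestc) { bestid = nbs[m]; bestc = c; }
      }
      *cost_out = bestc;
      return bestid;
    }
  };
  const double* bands_[3] = { band[0], band[1], band[2] };
  Naive nv; nv.lab = &lab; nv.band = bands_; nv.npix = npix;
  nv.nrow = nrow; nv.ncol = ncol; nv.conn = connectivity;

  std::vector<char> alive(nobj + 1, 1);
  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (int id = 1; id <= nobj; ++id) {
      if (!alive[id]) continue;
      double c1, c2;
      int nb = nv.best(id, w, &c1);
      if (nb < 0 || c1 >= s2) continue;
      if (nv.best(nb, w, &c2) != id) continue;
      int keep = std::min(id, nb), gone = std::max(id, nb);
      for (int i = 0; i < npix; ++i) if (lab[i] == gone) lab[i] = keep;
      alive[gone] = 0;
      merged_any = true;
    }
  }

  std::vector<int> newid(nobj + 1, 0);
  int k = 0;
  for (int i = 1; i <= nobj; ++i) if (alive[i]) newid[i] = ++k;
  IntegerVector out(npix);
  for (int i = 0; i < npix; ++i) out[i] = lab[i] ? newid[lab[i]] : 0;
  return out;
}

// Connected-component labelling of an integer mask: components are maximal
// connected sets of equal nonzero mask values. Zero cells get label 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int nrow, int ncol,
                                   int connectivity) {
  const int npix = nrow * ncol;
  IntegerVector out(npix, 0);
  int lab = 0, nb[8], m;
  std::vector<int> stack;
  for (int i = 0; i < npix; ++i) {
    if (mask[i] == 0 || out[i] != 0) continue;
    ++lab;
    stack.push_back(i);
    out[i] = lab;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      neighbours_of(p, nrow, ncol, connectivity, nb, &m);
      for (int j = 0; j < m; ++j) {
        int q = nb[j];
        if (out[q] == 0 && mask[q] == mask[p]) { out[q] = lab; stack.push_back(q); }
      }
    }
  }
  return out;
}
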