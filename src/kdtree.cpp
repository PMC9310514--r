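#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Exact k-d tree over unit-norm row vectors. On the unit sphere squared
// Euclidean distance is 2 - 2*cosine, so Euclidean nearest-neighbour
// order equals cosine order. Ties in distance are broken by a caller-
// supplied lexicographic rank so that rankings are fully deterministic.

struct KdNode {
  int lo, hi;          // range in idx[]
  int split_dim;
  double split_val;
  int left, right;     // node indices, -1 for leaf
};

struct KdTree {
  int dim;
  std::vector<double> pts;   // row-major n x dim
  std::vector<int> idx;      // permutation of 0..n-1
  std::vector<int> lexrank;  // tie-break rank per point
  std::vector<KdNode> nodes;
  int n;
};

static int kd_build(KdTree& t, int lo, int hi) {
  KdNode nd; nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
  nd.split_dim = 0; nd.split_val = 0.0;
  int me = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (hi - lo <= 16) return me;

  // split on the dimension with the largest spread
  int best_d = 0; double best_spread = -1.0;
  for (int d = 0; d < t.dim; ++d) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double v = t.pts[(size_t)t.idx[i] * t.dim + d];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (mx - mn > best_spread) { best_spread = mx - mn; best_d = d; }
  }
  if (best_spread <= 0.0) return me; // all points identical: leaf

  int mid = (lo + hi) / 2;
  const int dd = best_d; const int dimension = t.dim;
  const std::vector<double>& P = t.pts;
  std::nth_element(t.idx.begin() + lo, t.idx.begin() + mid, t.idx.begin() + hi,
                   [&](int a, int b) {
                     return P[(size_t)a * dimension + dd] < P[(size_t)b * dimension + dd];
                   });
  double sv = P[(size_t)t.idx[mid] * dimension + dd];
  t.nodes[me].split_dim = dd;
  t.nodes[me].split_val = sv;
  int l = kd_build(t, lo, mid);
  int r = kd_build(t, mid, hi);
  t.nodes[me].left = l;
  t.nodes[me].right = r;
  return me;
}

// [[Rcpp::export(name = ".kd_build")]]
SEXP kd_build_r(NumericMatrix x, IntegerVector lexrank) {
  KdTree* t = new KdTree();
  t->n = x.nrow(); t->dim = x.ncol();
  t->pts.resize((size_t)t->n * t->dim);
  for (int i = 0; i < t->n; ++i)
    for (int d = 0; d < t->dim; ++d)
      t->pts[(size_t)i * t->dim + d] = x(i, d);
  t->idx.resize(t->n);
  for (int i = 0; i < t->n; ++i) t->idx[i] = i;
  t->lexrank.assign(lexrank.begin(), lexrank.end());
  t->nodes.reserve(2 * t->n / 16 + 4);
  kd_build(*t, 0, t->n);
  XPtr<KdTree> p(t, true);
  return p;
}

struct HeapItem {
  double d2; int lex; int id;
  bool operator<(const HeapItem& o) const { // max-heap: worst on top
    if (d2 != o.d2) return d2 < o.d2;
    return lex < o.lex;
  }
};

static void kd_search(const KdTree& t, int node, const double* q, int k,
                      std::priority_queue<HeapItem>& heap) {
  const KdNode& nd = t.nodes[node];
  if (nd.left < 0) { // leaf: scan
    for (int i = nd.lo; i < nd.hi; ++i) {
      int id = t.idx[i];
      const double* p = &t.pts[(size_t)id * t.dim];
      double d2 = 0.0;
      for (int d = 0; d < t.dim; ++d) {
        double diff = q[d] - p[d];
        d2 += diff * diff;
      }
      HeapItem it{d2, t.lexrank[id], id};
      if ((int)heap.size() < k) heap.push(it);
      else if (it < heap.top()) { heap.pop(); heap.push(it); }
    }
    return;
  }
  double diff = q[nd.split_dim] - nd.split_val;
  int near = diff < 0 ? nd.left : nd.right;
  int far  = diff < 0 ? nd.right : nd.left;
  kd_search(t, near, q, k, heap);
  // visit the far side unless every point there is provably worse than
  // the current k-th best (non-strict to keep exact ties reachable)
  if ((int)heap.size() < k || diff * diff <= heap.top().d2)
    kd_search(t, far, q, k, heap);
}

// [[Rcpp::export(name = ".kd_query")]]
List kd_query_r(SEXP ptr, NumericVector q, int k) {
  XPtr<KdTree> t(ptr);
  if ((int)q.size() != t->dim) stop("query dimension mismatch");
  if (k > t->n) k = t->n;
  std::priority_queue<HeapItem> heap;
  kd_search(*t, 0, q.begin(), k, heap);
  int m = (int)heap.size();
  IntegerVector ids(m);
  NumericVector d2(m);
  for (int i = m - 1; i >= 0; --i) {
    ids[i] = heap.top().id + 1;
    d2[i] = heap.top().d2;
    heap.pop();
  }
  return List::create(_["id"] = ids, _["dist2"] = d2);
}

// [[Rcpp::export(name = ".kd_size")]]
int kd_size_r(SEXP ptr) {
  XPtr<KdTree> t(ptr);
  return t->n;
}
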