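// Exact closest-point queries on triangle meshes.
//
// A median-split AABB tree accelerates queries; results are identical to an
// exhaustive scan because both paths share the same point-triangle routine
// and the same tie-break (lowest face id wins on exact distance ties).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 add(const Vec3& a, const Vec3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 scale(const Vec3& a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// Ericson-style closest point on triangle (a, b, c) to point p.
static Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }

  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;    // children (node indices), -1 for leaf
  int begin, end;     // face range (into order[]) for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;           // permutation of face indices
  std::vector<Vec3> va, vb, vc;     // per-face vertices (original face order)
};

static void node_bounds(BVHNode& nd, const BVH& t, const std::vector<Vec3>& cent) {
  for (int k = 0; k < 3; ++k) { nd.lo[k] = R_PosInf; nd.hi[k] = R_NegInf; }
  for (int i = nd.begin; i < nd.end; ++i) {
    int f = t.order[i];
    const Vec3* vs[3] = {&t.va[f], &t.vb[f], &t.vc[f]};
    for (const Vec3* v : vs) {
      nd.lo[0] = std::min(nd.lo[0], v->x); nd.hi[0] = std::max(nd.hi[0], v->x);
      nd.lo[1] = std::min(nd.lo[1], v->y); nd.hi[1] = std::max(nd.hi[1], v->y);
      nd.lo[2] = std::min(nd.lo[2], v->z); nd.hi[2] = std::max(nd.hi[2], v->z);
    }
  }
  (void)cent;
}

static int build_node(BVH& t, std::vector<Vec3>& cent, int begin, int end, int leaf_size) {
  BVHNode nd;
  nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
  node_bounds(nd, t, cent);
  int idx = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (end - begin > leaf_size) {
    // split along widest centroid extent at the median
    double clo[3] = {R_PosInf, R_PosInf, R_PosInf}, chi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = begin; i < end; ++i) {
      const Vec3& c = cent[t.order[i]];
      double cc[3] = {c.x, c.y, c.z};
      for (int k = 0; k < 3; ++k) { clo[k] = std::min(clo[k], cc[k]); chi[k] = std::max(chi[k], cc[k]); }
    }
    int axis = 0;
    double w = chi[0] - clo[0];
    if (chi[1] - clo[1] > w) { axis = 1; w = chi[1] - clo[1]; }
    if (chi[2] - clo[2] > w) { axis = 2; }
    int mid = (begin + end) / 2;
    std::nth_element(t.order.begin() + begin, t.order.begin() + mid, t.order.begin() + end,
                     [&](int a, int b) {
                       const Vec3& ca = cent[a];
                       const Vec3& cb = cent[b];
                       double xa = (axis == 0 ? ca.x : axis == 1 ? ca.y : ca.z);
                       double xb = (axis == 0 ? cb.x : axis == 1 ? cb.y : cb.z);
                       if (xa != xb) return xa < xb;
                       return a < b;
                     });
    if (mid > begin && mid < end) {
      int li = build_node(t, cent, begin, mid, leaf_size);
      int ri = build_node(t, cent, mid, end, leaf_size);
      t.nodes[idx].left = li;
      t.nodes[idx].right = ri;
    }
  }
  return idx;
}

static double box_dist2(const BVHNode& nd, const Vec3& p) {
  double d2 = 0.0, pc[3] = {p.x, p.y, p.z};
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (pc[k] < nd.lo[k]) d = nd.lo[k] - pc[k];
    else if (pc[k] > nd.hi[k]) d = pc[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

static void query_bvh(const BVH& t, const Vec3& p, double& best_d2, int& best_f, Vec3& best_q) {
  // manual stack, near child first
  std::vector<int> stack;
  stack.reserve(64);
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode& nd = t.nodes[ni];
    if (box_dist2(nd, p) > best_d2) continue;
    if (nd.left < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int f = t.order[i];
        Vec3 q = closest_on_triangle(p, t.va[f], t.vb[f], t.vc[f]);
        Vec3 dq = sub(p, q);
        double d2 = dot(dq, dq);
        if (d2 < best_d2 || (d2 == best_d2 && f < best_f)) {
          best_d2 = d2; best_f = f; best_q = q;
        }
      }
    } else {
      double dl = box_dist2(t.nodes[nd.left], p);
      double dr = box_dist2(t.nodes[nd.right], p);
      if (dl < dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
      else { stack.push_back(nd.left); stack.push_back(nd.right); }
    }
  }
}

static BVH make_bvh(const NumericMatrix& V, const IntegerMatrix& F) {
  BVH t;
  int nf = F.nrow();
  t.va.resize(nf); t.vb.resize(nf); t.vc.resize(nf);
  std::vector<Vec3> cent(nf);
  t.order.resize(nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    t.va[f] = {V(i, 0), V(i, 1), V(i, 2)};
    t.vb[f] = {V(j, 0), V(j, 1), V(j, 2)};
    t.vc[f] = {V(k, 0), V(k, 1), V(k, 2)};
    cent[f] = scale(add(t.va[f], add(t.vb[f], t.vc[f])), 1.0 / 3.0);
    t.order[f] = f;
  }
  build_node(t, cent, 0, nf, 8);
  return t;
}

static List query_all(const BVH& t, const NumericMatrix& Q) {
  int nq = Q.nrow();
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  for (int qi = 0; qi < nq; ++qi) {
    Vec3 p = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    double best_d2 = R_PosInf;
    int best_f = INT32_MAX;
    Vec3 best_q = p;
    query_bvh(t, p, best_d2, best_f, best_q);
    P(qi, 0) = best_q.x; P(qi, 1) = best_q.y; P(qi, 2) = best_q.z;
    face[qi] = best_f + 1;
    dist[qi] = std::sqrt(best_d2);
  }
  return List::create(_["point"] = P, _["face"] = face, _["distance"] = dist);
}

// [[Rcpp::export(name = ".cpp_bvh_build")]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<BVH> ptr(new BVH(make_bvh(V, F)), true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_bvh_query")]]
List cpp_bvh_query(SEXP tree, NumericMatrix Q) {
  XPtr<BVH> ptr(tree);
  return query_all(*ptr, Q);
}

// [[Rcpp::export(name = ".cpp_closest_point")]]
List cpp_closest_point(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  BVH t = make_bvh(V, F);
  int nq = Q.nrow();
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  for (int qi = 0; qi < nq; ++qi) {
    Vec3 p = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    double best_d2 = R_PosInf;
    int best_f = INT32_MAX;
    Vec3 best_q = p;
    query_bvh(t, p, best_d2, best_f, best_q);
    P(qi, 0) = best_q.x; P(qi, 1) = best_q.y; P(qi, 2) = best_q.z;
    face[qi] = best_f + 1;
    dist[qi] = std::sqrt(best_d2);
  }
  return List::create(_["point"] = P, _["face"] = face, _["distance"] = dist);
}

// [[Rcpp::export(name = ".cpp_closest_point_exhaustive")]]
List cpp_closest_point_exhaustive(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  for (int qi = 0; qi < nq; ++qi) {
    Vec3 p = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    double best_d2 = R_PosInf;
    int best_f = -1;
    Vec3 best_q = p;
    for (int f = 0; f < nf; ++f) {
      int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
      Vec3 a = {V(i, 0), V(i, 1), V(i, 2)};
      Vec3 b = {V(j, 0), V(j, 1), V(j, 2)};
      Vec3 c = {V(k, 0), V(k, 1), V(k, 2)};
      Vec3 q = closest_on_triangle(p, a, b, c);
      Vec3 dq = sub(p, q);
      double d2 = dot(dq, dq);
      if (d2 < best_d2) { best_d2 = d2; best_f = f; best_q = q; }
    }
    P(qi, 0) = best_q.x; P(qi, 1) = best_q.y; P(qi, 2) = best_q.z;
    face[qi] = best_f + 1;
    dist[qi] = std::sqrt(best_d2);
  }
  return List::create(_["point"] = P, _["face"] = face, _["distance"] = dist);
}
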