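// Core amino-acid likelihood machinery: Felsenstein pruning over site
// patterns with per-class (mixture component x gamma category) partials,
// column scaling to avoid underflow, and branch-length optimisation by
// one-dimensional Brent sweeps using outside/inside directional partials.
//
// Trees arrive as ape-style postorder edge lists (1-based node numbers,
// tips 1..n_tips, root = n_tips + 1). Tip data arrive as 0-based residue
// codes, -1 meaning total ambiguity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ClassSys {
  mat V;      // diag(1/sqrt(pi)) U
  mat Vinv;   // U' diag(sqrt(pi))
  vec lam;    // eigenvalues of the symmetrised rate matrix
  vec pi;     // stationary frequencies of the component
  double w;   // class weight (component weight x category weight)
  double rate; // gamma-category rate multiplier
};

std::vector<ClassSys> unpack_classes(const Rcpp::List& classes) {
  std::vector<ClassSys> out;
  for (int i = 0; i < classes.size(); ++i) {
    Rcpp::List cl = classes[i];
    ClassSys cs;
    cs.V = Rcpp::as<mat>(cl["V"]);
    cs.Vinv = Rcpp::as<mat>(cl["Vinv"]);
    cs.lam = Rcpp::as<vec>(cl["lambda"]);
    cs.pi = Rcpp::as<vec>(cl["pi"]);
    cs.w = Rcpp::as<double>(cl["weight"]);
    cs.rate = Rcpp::as<double>(cl["rate"]);
    out.push_back(cs);
  }
  return out;
}

mat pmat(const ClassSys& cs, double t) {
  mat P = cs.V * diagmat(exp(cs.lam * (t * cs.rate))) * cs.Vinv;
  P.clamp(0.0, datum::inf);
  return P;
}

// contribution matrix of a child across one edge: column j is
// sum_b P(.,b) partial_child(b,j); tips are handled via their codes
mat edge_contribution(const mat& P, int child, int n_tips,
                      const imat& tipcodes,
                      const std::vector<mat>& partial, uword npat) {
  if (child <= n_tips) {
    mat C(20, npat);
    for (uword j = 0; j < npat; ++j) {
      int code = tipcodes(child - 1, j);
      if (code < 0) C.col(j).ones();
      else C.col(j) = P.col(code);
    }
    return C;
  }
  return P * partial[child - 1];
}

// full postorder pruning for one class; fills partial (per node) and a
// per-node column log-scale; returns per-pattern log-likelihood
rowvec prune_class(const ClassSys& cs, const imat& edges, const vec& lengths,
                   const imat& tipcodes, int n_tips, int n_nodes, int root,
                   std::vector<mat>* keep_partial = nullptr,
                   std::vector<rowvec>* keep_scale = nullptr) {
  uword npat = tipcodes.n_cols;
  std::vector<mat> partial(n_nodes);
  std::vector<rowvec> scale(n_nodes);
  for (int v = 0; v < n_nodes; ++v) scale[v] = rowvec(npat, fill::zeros);

  int E = edges.n_rows;
  for (int e = 0; e < E; ++e) {
    int p = edges(e, 0), u = edges(e, 1);
    mat P = pmat(cs, lengths(e));
    mat C = edge_contribution(P, u, n_tips, tipcodes, partial, npat);
    rowvec m = max(C, 0);
    m.transform([](double x) { return x > 1e-300 ? x : 1e-300; });
    C.each_row() /= m;
    if (partial[p - 1].n_elem == 0) partial[p - 1] = C;
    else partial[p - 1] %= C;
    scale[p - 1] += log(m);
    if (u > n_tips) scale[p - 1] += scale[u - 1];
  }
  rowvec loglik = log(cs.pi.t() * partial[root - 1]) + scale[root - 1];
  if (keep_partial) *keep_partial = std::move(partial);
  if (keep_scale) *keep_scale = std::move(scale);
  return loglik;
}

// log-sum-exp combine of per-class site log-likelihoods with class weights
rowvec combine_classes(const std::vector<rowvec>& cls_loglik,
                       const std::vector<ClassSys>& classes) {
  uword npat = cls_loglik[0].n_elem;
  size_t C = cls_loglik.size();
  rowvec mx(npat, fill::value(-datum::inf));
  for (size_t c = 0; c < C; ++c) mx = max(mx, cls_loglik[c]);
  rowvec acc(npat, fill::zeros);
  for (size_t c = 0; c < C; ++c)
    acc += classes[c].w * exp(cls_loglik[c] - mx);
  return log(acc) + mx;
}

} // namespace

// Per-pattern log-likelihoods, overall and per class.
// [[Rcpp::export]]
Rcpp::List cpp_site_loglik(const arma::imat& tipcodes,
                           const Rcpp::List& classes,
                           const arma::imat& edges,
                           const arma::vec& lengths,
                           int n_tips, int n_nodes, int root) {
  std::vector<ClassSys> cls = unpack_classes(classes);
  uword npat = tipcodes.n_cols;
  std::vector<rowvec> per_class;
  for (auto& cs : cls)
    per_class.push_back(prune_class(cs, edges, lengths, tipcodes,
                                    n_tips, n_nodes, root));
  rowvec total = combine_classes(per_class, cls);
  mat cls_mat(npat, cls.size());
  for (size_t c = 0; c < cls.size(); ++c) cls_mat.col(c) = per_class[c].t();
  return Rcpp::List::create(
      Rcpp::Named("site_loglik") = Rcpp::NumericVector(total.begin(), total.end()),
      Rcpp::Named("class_site_loglik") = cls_mat);
}

namespace {

// state shared by the branch-length optimiser for one tree
struct EdgeWork {
  // per class: inside partial D and its log-scale for every node, plus the
  // outside vector F (pi-weighted) for the currently optimised edge
  std::vector<std::vector<mat>> D;
  std::vector<std::vector<rowvec>> Dscale;
  std::vector<mat> F;          // per class, 20 x npat
  std::vector<rowvec> Fscale;  // per class
};

// children edges of each node, and parent edge of each node
void index_edges(const imat& edges, int n_nodes,
                 std::vector<std::vector<int>>& children,
                 std::vector<int>& parent_edge) {
  children.assign(n_nodes, {});
  parent_edge.assign(n_nodes, -1);
  for (uword e = 0; e < edges.n_rows; ++e) {
    children[edges(e, 0) - 1].push_back(e);
    parent_edge[edges(e, 1) - 1] = e;
  }
}

// outside partial for edge e = (p, u): walk the path root -> p, folding in
// sibling subtrees; D must be current
void outside_for_edge(int e, const std::vector<ClassSys>& cls,
                      const imat& edges, const vec& lengths,
                      const imat& tipcodes, int n_tips, int root,
                      const std::vector<std::vector<int>>& children,
                      const std::vector<int>& parent_edge,
                      EdgeWork& wk) {
  uword npat = tipcodes.n_cols;
  // path of edges from root down to p
  std::vector<int> path;
  int node = edges(e, 0);
  while (node != root) {
    path.push_back(parent_edge[node - 1]);
    node = edges(parent_edge[node - 1], 0);
  }
  std::reverse(path.begin(), path.end());

  for (size_t c = 0; c < cls.size(); ++c) {
    mat F(20, npat);
    F.each_col() = cls[c].pi;
    rowvec sc(npat, fill::zeros);
    int at = root;
    auto fold_siblings = [&](int except_edge) {
      for (int f : children[at - 1]) {
        if (f == except_edge) continue;
        int s = edges(f, 1);
        mat P = pmat(cls[c], lengths(f));
        mat C = edge_contribution(P, s, n_tips, tipcodes, wk.D[c], npat);
        rowvec m = max(C, 0);
        m.transform([](double x) { return x > 1e-300 ? x : 1e-300; });
        C.each_row() /= m;
        F %= C;
        sc += log(m);
        if (s > n_tips) sc += wk.Dscale[c][s - 1];
      }
    };
    for (int g : path) {
      fold_siblings(g);
      // cross edge g downwards: O_child = P_g^T F
      mat P = pmat(cls[c], lengths(g));
      F = P.t() * F;
      rowvec m = max(F, 0);
      m.transform([](double x) { return x > 1e-300 ? x : 1e-300; });
      F.each_row() /= m;
      sc += log(m);
      at = edges(g, 1);
    }
    fold_siblings(e);
    wk.F[c] = std::move(F);
    wk.Fscale[c] = std::move(sc);
  }
}

// total log-likelihood of the tree as a function of the length of edge e,
// with D and F current for that edge
double edge_loglik(double t, int e, const std::vector<ClassSys>& cls,
                   const imat& edges, const imat& tipcodes, int n_tips,
                   const vec& patw, const EdgeWork& wk) {
  uword npat = tipcodes.n_cols;
  int u = edges(e, 1);
  std::vector<rowvec> per_class(cls.size());
  for (size_t c = 0; c < cls.size(); ++c) {
    mat P = pmat(cls[c], t);
    mat C = edge_contribution(P, u, n_tips, tipcodes, wk.D[c], npat);
    rowvec lik = sum(wk.F[c] % C, 0);
    lik.transform([](double x) { return x > 1e-300 ? x : 1e-300; });
    rowvec sc = wk.Fscale[c];
    if (u > n_tips) sc += wk.Dscale[c][u - 1];
    per_class[c] = log(lik) + sc;
  }
  rowvec total = combine_classes(per_class, cls);
  return dot(total, patw.t());
}

// Brent's localmin on [lo, hi]
template <typename F>
double brent_max(F f, double lo, double hi, double x0, double tol,
                 int max_iter, double* fmax_out) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = std::min(std::max(x0, lo), hi);
  double w = x, v = x;
  double fx = -f(x), fw = fx, fv = fx;
  double d = 0.0, ee = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool parab = false;
    if (std::fabs(ee) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = ee;
      ee = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        parab = true;
        d = p / q;
        double uu = x + d;
        if (uu - a < tol2 || b - uu < tol2) d = (xm >= x) ? tol1 : -tol1;
      }
    }
    if (!parab) {
      ee = (x >= xm) ? a - x : b - x;
      d = gold * ee;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = -f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  if (fmax_out) *fmax_out = -fx;
  return x;
}

} // namespace

// Branch-length optimisation by repeated per-edge Brent sweeps.
// Returns optimised lengths, the total log-likelihood, per-pattern and
// per-class log-likelihoods, and the number of sweeps used.
// [[Rcpp::export]]
Rcpp::List cpp_optimize_bl(const arma::imat& tipcodes,
                           const Rcpp::List& classes,
                           const arma::imat& edges,
                           arma::vec lengths,
                           int n_tips, int n_nodes, int root,
                           const arma::vec& patw,
                           double tol, int max_rounds,
                           double min_bl, double max_bl) {
  std::vector<ClassSys> cls = unpack_classes(classes);
  int E = edges.n_rows;
  std::vector<std::vector<int>> children;
  std::vector<int> parent_edge;
  index_edges(edges, n_nodes, children, parent_edge);

  EdgeWork wk;
  wk.D.resize(cls.size());
  wk.Dscale.resize(cls.size());
  wk.F.resize(cls.size());
  wk.Fscale.resize(cls.size());

  auto total_loglik = [&]() {
    std::vector<rowvec> per_class;
    for (auto& cs : cls)
      per_class.push_back(prune_class(cs, edges, lengths, tipcodes,
                                      n_tips, n_nodes, root));
    rowvec total = combine_classes(per_class, cls);
    return dot(total, patw.t());
  };

  double prev = total_loglik();
  int rounds = 0;
  for (int round = 0; round < max_rounds; ++round) {
    ++rounds;
    for (int e = 0; e < E; ++e) {
      // refresh inside partials with the current lengths, then build the
      // outside partial for this edge
      for (size_t c = 0; c < cls.size(); ++c)
        prune_class(cls[c], edges, lengths, tipcodes, n_tips, n_nodes, root,
                    &wk.D[c], &wk.Dscale[c]);
      outside_for_edge(e, cls, edges, lengths, tipcodes, n_tips, root,
                       children, parent_edge, wk);
      auto f = [&](double t) {
        return edge_loglik(t, e, cls, edges, tipcodes, n_tips, patw, wk);
      };
      double fbest;
      lengths(e) = brent_max(f, min_bl, max_bl, lengths(e), 1e-4, 40, &fbest);
    }
    double cur = total_loglik();
    if (cur - prev < tol) { prev = std::max(cur, prev); break; }
    prev = cur;
  }

  std::vector<rowvec> per_class;
  for (auto& cs : cls)
    per_class.push_back(prune_class(cs, edges, lengths, tipcodes,
                                    n_tips, n_nodes, root));
  rowvec total = combine_classes(per_class, cls);
  mat cls_mat(tipcodes.n_cols, cls.size());
  for (size_t c = 0; c < cls.size(); ++c) cls_mat.col(c) = per_class[c].t();

  return Rcpp::List::create(
      Rcpp::Named("lengths") = Rcpp::NumericVector(lengths.begin(), lengths.end()),
      Rcpp::Named("loglik") = dot(total, patw.t()),
      Rcpp::Named("site_loglik") = Rcpp::NumericVector(total.begin(), total.end()),
      Rcpp::Named("class_site_loglik") = cls_mat,
      Rcpp::Named("rounds") = rounds);
}
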