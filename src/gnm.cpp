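#include <Rcpp.h>
using namespace Rcpp;

// Generative wiring simulation core.
//
// State kept incrementally:
//   A    binary adjacency
//   deg  nodal degree
//   N    shared-neighbour counts, N(i,j) = #{k : A(i,k) & A(k,j)} = (A^2)_ij
//   W    candidate weights D^eta * (K + eps)^gamma (0 on connected pairs)
// Adding edge (u,v) changes K only for pairs with an endpoint in {u, v}
// (plus, for the clustering rule, pairs touching a common neighbour of u
// and v), so each iteration costs O(n^2) additions for the sampling sweep
// but only O(n) pow() evaluations.  Rule codes: 0 spatial, 1 matching,
// 2 neighbours, 3 clustering_average, 4 degree_average.

struct GnmState {
  int n;
  IntegerMatrix A;
  IntegerVector deg;
  IntegerMatrix N;
  NumericVector clust;
  NumericMatrix Dp; // D^eta, 0 on diagonal
  NumericMatrix W;
  double eps, gamma;
  int rule;

  double rule_value(int i, int j) const {
    switch (rule) {
    case 0: return 1.0;
    case 1: { // matching: shared / union, neighbourhoods excluding the pair
      double shared = N(i, j);
      double uni = deg[i] - A(i, j) + deg[j] - A(i, j) - shared;
      return uni > 0 ? shared / uni : 0.0;
    }
    case 2: return N(i, j);
    case 3: return 0.5 * (clust[i] + clust[j]);
    case 4: return 0.5 * (deg[i] + deg[j]);
    }
    return NA_REAL;
  }

  void set_clustering(int i) {
    if (deg[i] < 2) { clust[i] = 0.0; return; }
    double tri2 = 0.0;
    for (int j = 0; j < n; ++j) if (A(i, j)) tri2 += N(i, j);
    clust[i] = tri2 / ((double)deg[i] * (deg[i] - 1));
  }

  void set_weight(int i, int j) {
    if (i == j || A(i, j)) { W(i, j) = W(j, i) = 0.0; return; }
    double wij = Dp(i, j) * std::pow(rule_value(i, j) + eps, gamma);
    if (!R_finite(wij) || wij < 0)
      stop("non-finite wiring weight at pair (%d, %d)", i + 1, j + 1);
    W(i, j) = W(j, i) = wij;
  }
};

// [[Rcpp::export]]
List gnm_simulate_cpp(IntegerMatrix A0, NumericMatrix D,
                      double eta, double gamma, double eps,
                      int rule, int n_add, bool record) {
  int n = A0.nrow();
  GnmState st{n, clone(A0), IntegerVector(n), IntegerMatrix(n, n),
              NumericVector(n), NumericMatrix(n, n), NumericMatrix(n, n),
              eps, gamma, rule};

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) if (st.A(i, j)) st.deg[i]++;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int s = 0;
      for (int k = 0; k < n; ++k) s += st.A(i, k) * st.A(k, j);
      st.N(i, j) = st.N(j, i) = s;
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      st.Dp(i, j) = (i == j) ? 0.0 : std::pow(D(i, j), eta);
  if (rule == 3) for (int i = 0; i < n; ++i) st.set_clustering(i);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) st.set_weight(i, j);

  IntegerMatrix edges(n_add, 2);
  NumericVector prob_node_mean(n);
  int n_iter_rec = record ? std::max(n_add, 1) : 0;
  NumericMatrix value_iter(record ? n : 0, n_iter_rec);
  NumericMatrix prob_iter(record ? n : 0, n_iter_rec);

  int n_steps = std::max(n_add, record ? 1 : 0);
  std::vector<int> touched; touched.reserve(n);

  for (int step = 0; step < n_steps; ++step) {
    if (record) { // nodal value term: sum_j (K_ij + eps)^gamma over all j != i
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j)
          if (j != i) acc += std::pow(st.rule_value(i, j) + eps, gamma);
        value_iter(i, step) = acc;
      }
    }
    if (step >= n_add) break; // record-only pass on a no-op trace

    double tot = 0.0;
    int m = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (!st.A(i, j)) { tot += st.W(i, j); ++m; }
    if (m == 0) stop("no unconnected pairs left: graph saturated");
    if (tot <= 0) stop("all wiring weights are zero; cannot normalise");

    // per-node candidate probability mass (for stochasticity summaries)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) if (!st.A(i, j) && j != i) acc += st.W(i, j);
      double p = acc / tot;
      prob_node_mean[i] += p;
      if (record) prob_iter(i, step) = p;
    }

    // inverse-CDF sample over the lexicographically ordered candidates
    double u = unif_rand() * tot, cum = 0.0;
    int pu = -1, pv = -1;
    for (int i = 0; i < n && pu < 0; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (st.A(i, j)) continue;
        cum += st.W(i, j);
        if (u <= cum) { pu = i; pv = j; break; }
      }
    if (pu < 0) { // numerical slack: take the last candidate
      for (int i = n - 1; i >= 0 && pu < 0; --i)
        for (int j = n - 1; j > i; --j)
          if (!st.A(i, j)) { pu = i; pv = j; break; }
    }

    edges(step, 0) = pu + 1; edges(step, 1) = pv + 1;
    st.A(pu, pv) = st.A(pv, pu) = 1;
    st.deg[pu]++; st.deg[pv]++;
    touched.clear();
    for (int a = 0; a < n; ++a) {
      if (a != pv && st.A(a, pu)) { st.N(a, pv)++; st.N(pv, a)++; }
      if (a != pu && st.A(a, pv)) { st.N(a, pu)++; st.N(pu, a)++; }
      if (rule == 3 && a != pu && a != pv && st.A(a, pu) && st.A(a, pv))
        touched.push_back(a); // common neighbour: clustering changes
    }
    touched.push_back(pu); touched.push_back(pv);
    if (rule == 3) for (int a : touched) st.set_clustering(a);
    st.W(pu, pv) = st.W(pv, pu) = 0.0;
    if (rule != 0)
      for (int a : touched)
        for (int b = 0; b < n; ++b) if (b != a) st.set_weight(a, b);
  }

  if (n_add > 0) prob_node_mean = prob_node_mean / (double)n_add;

  List out = List::create(_["edges"] = edges,
                          _["final"] = st.A,
                          _["prob_node_mean"] = prob_node_mean);
  if (record) {
    NumericVector nodal_value(n);
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int s = 0; s < n_iter_rec; ++s) acc += value_iter(i, s);
      nodal_value[i] = acc / n_iter_rec;
    }
    out["nodal_value"] = nodal_value;
    out["value_iter"] = value_iter;
    out["prob_iter"] = prob_iter;
  }
  return out;
}

// Topological value matrix for a static graph (shares the rule definitions
// with the simulator so the R-level oracle tests cover both paths).
// [[Rcpp::export]]
NumericMatrix topological_value_cpp(IntegerMatrix A, int rule) {
  int n = A.nrow();
  GnmState st{n, A, IntegerVector(n), IntegerMatrix(n, n),
              NumericVector(n), NumericMatrix(0, 0), NumericMatrix(0, 0),
              0.0, 1.0, rule};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) if (A(i, j)) st.deg[i]++;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int s = 0;
      for (int k = 0; k < n; ++k) s += A(i, k) * A(k, j);
      st.N(i, j) = st.N(j, i) = s;
    }
  if (rule == 3) for (int i = 0; i < n; ++i) st.set_clustering(i);
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K(i, j) = (i == j) ? 0.0 : st.rule_value(i, j);
  return K;
}
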