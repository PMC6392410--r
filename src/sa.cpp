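#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Simulated-annealing maximisation of Newman-Girvan modularity
//   Q = sum_s [ l_s/L - (d_s/(2L))^2 ]
// with single-node moves at every temperature step plus one merge and one
// split proposal per temperature. Uses R's RNG so results are reproducible
// under set.seed().

namespace {

struct State {
  int n;
  long L;
  std::vector<std::vector<int>> adj;
  std::vector<int> memb;      // module id per node, ids in [0, n)
  std::vector<long> lmod;     // within-module edge count per module id
  std::vector<long> dmod;     // degree sum per module id
  std::vector<int> sizes;     // node count per module id

  double q() const {
    double L2 = 2.0 * L, acc = 0.0;
    for (int s = 0; s < n; ++s) {
      if (sizes[s] == 0) continue;
      double df = dmod[s] / L2;
      acc += (double)lmod[s] / L - df * df;
    }
    return acc;
  }

  int links_to(int i, int mod) const {
    int k = 0;
    for (int v : adj[i]) if (memb[v] == mod) ++k;
    return k;
  }

  // dQ for moving node i from its module to module t (t may be empty)
  double move_dq(int i, int t, int &kis, int &kit) const {
    int s = memb[i];
    kis = links_to(i, s);
    kit = links_to(i, t);
    double ki = adj[i].size();
    return (kit - kis) / (double)L +
           ki * (dmod[s] - dmod[t] - ki) / (2.0 * L * (double)L);
  }

  void apply_move(int i, int t, int kis, int kit) {
    int s = memb[i];
    long ki = adj[i].size();
    lmod[s] -= kis; lmod[t] += kit;
    dmod[s] -= ki;  dmod[t] += ki;
    sizes[s]--;     sizes[t]++;
    memb[i] = t;
  }
};

int runif_int(int k) {  // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

}  // namespace

// [[Rcpp::export]]
List sa_anneal_cpp(int n, IntegerMatrix edges, double t0, double cooling,
                   int steps_per_temp, double tmin) {
  State st;
  st.n = n;
  st.L = edges.nrow();
  st.adj.assign(n, {});
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);  // 0-based
    st.adj[a].push_back(b);
    st.adj[b].push_back(a);
  }
  st.memb.resize(n);
  st.lmod.assign(n, 0);
  st.dmod.assign(n, 0);
  st.sizes.assign(n, 0);
  for (int i = 0; i < n; ++i) {  // every node starts in its own module
    st.memb[i] = i;
    st.dmod[i] = st.adj[i].size();
    st.sizes[i] = 1;
  }

  double q = st.q();
  double best_q = q;
  std::vector<int> best_memb = st.memb;

  auto record = [&]() {
    if (q > best_q + 1e-12) { best_q = q; best_memb = st.memb; }
  };

  for (double T = t0; T > tmin; T *= cooling) {
    // single-node moves
    for (int step = 0; step < steps_per_temp; ++step) {
      int i = runif_int(n);
      int t;
      if (!st.adj[i].empty() && unif_rand() < 0.5) {
        t = st.memb[st.adj[i][runif_int((int)st.adj[i].size())]];
      } else {
        t = runif_int(n);
      }
      if (t == st.memb[i]) continue;
      int kis, kit;
      double dq = st.move_dq(i, t, kis, kit);
      if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
        st.apply_move(i, t, kis, kit);
        q += dq;
        record();
      }
    }
    // one merge proposal
    {
      int i = runif_int(n), j = runif_int(n);
      int s = st.memb[i], t = st.memb[j];
      if (s != t) {
        long lst = 0;
        for (int u = 0; u < n; ++u) {
          if (st.memb[u] != s) continue;
          for (int v : st.adj[u]) if (st.memb[v] == t) ++lst;
        }
        double dq = lst / (double)st.L -
                    st.dmod[s] * (double)st.dmod[t] / (2.0 * st.L * (double)st.L);
        if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
          for (int u = 0; u < n; ++u) if (st.memb[u] == s) st.memb[u] = t;
          st.lmod[t] += st.lmod[s] + lst;
          st.dmod[t] += st.dmod[s];
          st.sizes[t] += st.sizes[s];
          st.lmod[s] = st.dmod[s] = 0;
          st.sizes[s] = 0;
          q += dq;
          record();
        }
      }
    }
    // one split proposal: random bipartition of one module
    {
      int s = st.memb[runif_int(n)];
      if (st.sizes[s] >= 2) {
        std::vector<int> members;
        for (int u = 0; u < n; ++u) if (st.memb[u] == s) members.push_back(u);
        std::vector<char> half(n, 0);
        int nb = 0;
        for (int u : members) if (unif_rand() < 0.5) { half[u] = 1; ++nb; }
        if (nb > 0 && nb < (int)members.size()) {
          int free_id = -1;
          for (int m = 0; m < n; ++m) if (st.sizes[m] == 0) { free_id = m; break; }
          if (free_id >= 0) {
            long lab = 0, lb = 0, db = 0;
            for (int u : members) {
              if (half[u]) db += st.adj[u].size();
              for (int v : st.adj[u]) {
                if (st.memb[v] != s) continue;
                if (half[u] != half[v]) ++lab;           // counted twice
                else if (half[u] && half[v] && u < v) ++lb;
              }
            }
            lab /= 2;
            long da = st.dmod[s] - db;
            double dq = -lab / (double)st.L +
                        da * (double)db / (2.0 * st.L * (double)st.L);
            if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
              for (int u : members) if (half[u]) st.memb[u] = free_id;
              st.lmod[free_id] = lb;
              st.lmod[s] -= lb + lab;
              st.dmod[free_id] = db;
              st.dmod[s] = da;
              st.sizes[free_id] = nb;
              st.sizes[s] -= nb;
              q += dq;
              record();
            }
          }
        }
      }
    }
  }

  // greedy refinement of the best state: single-node moves to the best of
  // the neighbouring modules (or a singleton) until no move improves Q
  st.memb = best_memb;
  std::fill(st.lmod.begin(), st.lmod.end(), 0);
  std::fill(st.dmod.begin(), st.dmod.end(), 0);
  std::fill(st.sizes.begin(), st.sizes.end(), 0);
  for (int i = 0; i < n; ++i) {
    st.dmod[st.memb[i]] += st.adj[i].size();
    st.sizes[st.memb[i]]++;
  }
  for (int i = 0; i < n; ++i)
    for (int v : st.adj[i])
      if (st.memb[v] == st.memb[i] && i < v) st.lmod[st.memb[i]]++;
  q = st.q();
  bool improved = true;
  for (int pass = 0; pass < 100 && improved; ++pass) {
    improved = false;
    for (int i = 0; i < n; ++i) {
      int s = st.memb[i];
      std::vector<int> cand;
      for (int v : st.adj[i]) if (st.memb[v] != s) cand.push_back(st.memb[v]);
      for (int m = 0; m < n; ++m) if (st.sizes[m] == 0) { cand.push_back(m); break; }
      double best_dq = 1e-12;
      int best_t = -1, bkis = 0, bkit = 0;
      for (int t : cand) {
        if (t == s) continue;
        int kis, kit;
        double dq = st.move_dq(i, t, kis, kit);
        if (dq > best_dq) { best_dq = dq; best_t = t; bkis = kis; bkit = kit; }
      }
      if (best_t >= 0) {
        st.apply_move(i, best_t, bkis, bkit);
        q += best_dq;
        improved = true;
      }
    }
  }
  if (q > best_q) { best_q = q; best_memb = st.memb; }

  // relabel modules contiguously in order of first appearance
  std::vector<int> relab(n, -1);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (relab[best_memb[i]] < 0) relab[best_memb[i]] = next++;
    out[i] = relab[best_memb[i]] + 1;  // 1-based for R
  }
  return List::create(_["membership"] = out, _["q"] = best_q,
                      _["n_modules"] = next);
}
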