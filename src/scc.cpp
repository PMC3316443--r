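// Iterative Tarjan strongly-connected components on an explicit edge list.
// Used by the optimizer plan for the cycle-membership pattern; returns, for
// each state, whether it lies in an SCC with two or more states.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector scc_nontrivial(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  std::vector<int> head(n, -1), nxt(m), dest(m);
  for (int e = 0; e < m; ++e) {
    dest[e] = to[e];
    nxt[e] = head[from[e]];
    head[from[e]] = e;
  }
  std::vector<int> index(n, -1), low(n, 0), comp(n, -1);
  std::vector<char> onstack(n, 0);
  std::vector<int> stk;
  std::vector<int> comp_size;
  int counter = 0;

  // explicit DFS stack of (node, current edge cursor)
  std::vector<std::pair<int, int>> dfs;
  for (int root = 0; root < n; ++root) {
    if (index[root] != -1) continue;
    dfs.push_back({root, head[root]});
    index[root] = low[root] = counter++;
    stk.push_back(root);
    onstack[root] = 1;
    while (!dfs.empty()) {
      int v = dfs.back().first;
      int e = dfs.back().second;
      if (e != -1) {
        dfs.back().second = nxt[e];
        int w = dest[e];
        if (index[w] == -1) {
          index[w] = low[w] = counter++;
          stk.push_back(w);
          onstack[w] = 1;
          dfs.push_back({w, head[w]});
        } else if (onstack[w] && index[w] < low[v]) {
          low[v] = index[w];
        }
      } else {
        dfs.pop_back();
        if (!dfs.empty()) {
          int p = dfs.back().first;
          if (low[v] < low[p]) low[p] = low[v];
        }
        if (low[v] == index[v]) {
          int cid = static_cast<int>(comp_size.size());
          int size = 0, w;
          do {
            w = stk.back();
            stk.pop_back();
            onstack[w] = 0;
            comp[w] = cid;
            ++size;
          } while (w != v);
          comp_size.push_back(size);
        }
      }
    }
  }
  LogicalVector res(n);
  for (int v = 0; v < n; ++v) res[v] = comp_size[comp[v]] >= 2;
  return res;
}
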