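#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG stream (single-threaded, reproducible
// under set.seed()).
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Grow a random diffusion subgraph (a tree) from `start`, then emit its Euler
// circuit (every tree edge traversed twice), giving one token sequence.
//
// Growth rule: repeatedly pick a uniformly random already-included node that
// still has at least one neighbour outside the subgraph, then a uniformly
// random such neighbour, until `size` nodes are included or the reachable
// neighbourhood is exhausted.  Nodes that run out of free neighbours can never
// regain them, so they are dropped from the candidate pool permanently.
static void one_walk(int start, int size,
                     const std::vector<int> &off, const std::vector<int> &nbr,
                     std::vector<int> &stamp, int cur_stamp,
                     std::vector<int> &out) {
  std::vector<int> nodes;             // tree nodes in insertion order
  std::vector<std::vector<int> > kids; // children (tree indices)
  std::vector<int> tidx_of;           // tree index of active nodes
  std::vector<int> active;            // nodes possibly having free neighbours

  nodes.push_back(start);
  kids.push_back(std::vector<int>());
  stamp[start] = cur_stamp;
  active.push_back(start);
  tidx_of.push_back(0);

  std::vector<int> free_nbrs;
  while ((int)nodes.size() < size && !active.empty()) {
    int ai = runif_int((int)active.size());
    int u = active[ai];
    free_nbrs.clear();
    for (int e = off[u]; e < off[u + 1]; ++e)
      if (stamp[nbr[e]] != cur_stamp) free_nbrs.push_back(nbr[e]);
    if (free_nbrs.empty()) {
      active[ai] = active.back(); active.pop_back();
      tidx_of[ai] = tidx_of.back(); tidx_of.pop_back();
      continue;
    }
    int w = free_nbrs[runif_int((int)free_nbrs.size())];
    int w_tidx = (int)nodes.size();
    nodes.push_back(w);
    kids.push_back(std::vector<int>());
    kids[tidx_of[ai]].push_back(w_tidx);
    stamp[w] = cur_stamp;
    active.push_back(w);
    tidx_of.push_back(w_tidx);
  }

  // Euler circuit of the doubled tree edges: DFS emitting a node on entry and
  // again after returning from each child.  Depth bounded by subgraph size.
  std::vector<std::pair<int, size_t> > st; // (tree index, next child slot)
  out.push_back(nodes[0]);
  st.push_back(std::make_pair(0, (size_t)0));
  while (!st.empty()) {
    int t = st.back().first;
    size_t &ci = st.back().second;
    if (ci < kids[t].size()) {
      int c = kids[t][ci++];
      out.push_back(nodes[c]);
      st.push_back(std::make_pair(c, (size_t)0));
    } else {
      st.pop_back();
      if (!st.empty()) out.push_back(nodes[st.back().first]);
    }
  }
}

// [[Rcpp::export]]
List diffusion_walks_cpp(IntegerVector offsets, IntegerVector neighbors,
                         int walks_per_node, int subgraph_size) {
  int n = offsets.size() - 1;
  std::vector<int> off(offsets.begin(), offsets.end());
  std::vector<int> nbr(neighbors.begin(), neighbors.end());
  std::vector<int> stamp(n, -1);
  int cur_stamp = 0;

  List walks(n * walks_per_node);
  std::vector<int> seq;
  int k = 0;
  for (int v = 0; v < n; ++v) {
    for (int r = 0; r < walks_per_node; ++r) {
      seq.clear();
      if (off[v + 1] == off[v]) {
        seq.push_back(v); // isolated node: singleton sequence
      } else {
        one_walk(v, subgraph_size, off, nbr, stamp, cur_stamp++, seq);
      }
      IntegerVector s(seq.size());
      for (size_t i = 0; i < seq.size(); ++i) s[i] = seq[i] + 1; // 1-based
      walks[k++] = s;
    }
  }
  return walks;
}
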