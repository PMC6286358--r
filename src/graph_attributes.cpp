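// Core kernel: the four word-graph attributes (N, RE, LSC, ASP) on a token
// sequence, plus the word-shuffle null used for normalization.  The shuffle
// null evaluates ~1e5 tiny graphs per cohort, which is why this lives in
// compiled code.  Token ids must be positive integers; 1..N compact coding
// is produced by the R callers.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

struct Attrs {
  int n_nodes;
  double re;
  int lsc;
  double asp;
  long long finite_pairs; // ordered u!=v pairs with a finite directed distance
};

// Tarjan strongly connected components, iterative (transcript-level graphs
// can have thousands of nodes; no recursion).
static int largest_scc(int n, const std::vector<std::vector<int>> &out) {
  std::vector<int> index(n, -1), low(n, 0), comp(n, -1);
  std::vector<bool> on_stack(n, false);
  std::vector<int> stack_scc;
  int next_index = 0, best = 0;
  // explicit DFS stack of (node, child-pointer)
  std::vector<std::pair<int, size_t>> dfs;
  for (int s = 0; s < n; ++s) {
    if (index[s] != -1) continue;
    dfs.push_back(std::make_pair(s, (size_t)0));
    index[s] = low[s] = next_index++;
    stack_scc.push_back(s);
    on_stack[s] = true;
    while (!dfs.empty()) {
      int v = dfs.back().first;
      size_t &ci = dfs.back().second;
      if (ci < out[v].size()) {
        int w = out[v][ci++];
        if (index[w] == -1) {
          index[w] = low[w] = next_index++;
          stack_scc.push_back(w);
          on_stack[w] = true;
          dfs.push_back(std::make_pair(w, (size_t)0));
        } else if (on_stack[w] && index[w] < low[v]) {
          low[v] = index[w];
        }
      } else {
        if (low[v] == index[v]) {
          int size = 0, w;
          do {
            w = stack_scc.back();
            stack_scc.pop_back();
            on_stack[w] = false;
            ++size;
          } while (w != v);
          if (size > best) best = size;
        }
        dfs.pop_back();
        if (!dfs.empty()) {
          int parent = dfs.back().first;
          if (low[v] < low[parent]) low[parent] = low[v];
        }
      }
    }
  }
  return n > 0 ? (best > 0 ? best : 1) : 0;
}

static Attrs compute_attrs(const std::vector<int> &seq, bool asp_directed,
                           bool re_excess) {
  Attrs a;
  int n = 0;
  for (size_t i = 0; i < seq.size(); ++i)
    if (seq[i] + 1 > n) n = seq[i] + 1;
  a.n_nodes = n;
  // multiplicity per ordered pair; adjacency of distinct pairs
  std::unordered_map<long long, int> mult;
  std::vector<std::vector<int>> out(n);
  for (size_t i = 0; i + 1 < seq.size(); ++i) {
    int u = seq[i], v = seq[i + 1];
    long long key = (long long)u * n + v;
    std::unordered_map<long long, int>::iterator it = mult.find(key);
    if (it == mult.end()) {
      mult[key] = 1;
      out[u].push_back(v);
    } else {
      it->second += 1;
    }
  }
  // RE: sum of multiplicities over ordered pairs linked more than once
  // (excess mode: total instances minus distinct pairs)
  double re = 0.0;
  for (std::unordered_map<long long, int>::iterator it = mult.begin();
       it != mult.end(); ++it) {
    int m = it->second;
    if (re_excess) re += m - 1;
    else if (m >= 2) re += m;
  }
  a.re = re;

  a.lsc = largest_scc(n, out);

  // ASP: mean BFS distance over reachable ordered pairs u != v
  std::vector<std::vector<int>> adj;
  if (asp_directed) {
    adj = out;
  } else {
    adj.assign(n, std::vector<int>());
    for (std::unordered_map<long long, int>::iterator it = mult.begin();
         it != mult.end(); ++it) {
      int u = (int)(it->first / n), v = (int)(it->first % n);
      adj[u].push_back(v);
      if (u != v) adj[v].push_back(u);
    }
  }
  long long pairs = 0;
  double total = 0.0;
  std::vector<int> dist(n), queue_(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    queue_[tail++] = s;
    while (head < tail) {
      int u = queue_[head++];
      const std::vector<int> &nb = adj[u];
      for (size_t k = 0; k < nb.size(); ++k) {
        int w = nb[k];
        if (dist[w] == -1) {
          dist[w] = dist[u] + 1;
          queue_[tail++] = w;
        }
      }
    }
    for (int v = 0; v < n; ++v) {
      if (v != s && dist[v] > 0) {
        total += dist[v];
        ++pairs;
      }
    }
  }
  a.finite_pairs = pairs;
  a.asp = pairs > 0 ? total / pairs : 0.0;
  return a;
}

static std::vector<int> as_zero_based(const IntegerVector &ids) {
  std::vector<int> seq(ids.size());
  for (int i = 0; i < ids.size(); ++i) {
    if (ids[i] == NA_INTEGER || ids[i] < 1)
      stop("token ids must be positive integers");
    seq[i] = ids[i] - 1;
  }
  return seq;
}

// [[Rcpp::export]]
NumericVector graph_attrs_cpp(IntegerVector ids, bool asp_directed = true,
                              bool re_excess = false) {
  if (ids.size() == 0) stop("empty token sequence");
  std::vector<int> seq = as_zero_based(ids);
  Attrs a = compute_attrs(seq, asp_directed, re_excess);
  NumericVector res = NumericVector::create(
      _["N"] = (double)a.n_nodes, _["RE"] = a.re, _["LSC"] = (double)a.lsc,
      _["ASP"] = a.asp, _["finite_pairs"] = (double)a.finite_pairs);
  return res;
}

// Attributes of n_shuffles uniform permutations of the window.  Uses R's RNG
// (Fisher-Yates with unif_rand) so results are reproducible under set.seed.
// [[Rcpp::export]]
NumericMatrix shuffle_attrs_cpp(IntegerVector ids, int n_shuffles,
                                bool asp_directed = true,
                                bool re_excess = false) {
  if (ids.size() == 0) stop("empty token sequence");
  if (n_shuffles < 1) stop("n_shuffles must be >= 1");
  std::vector<int> seq = as_zero_based(ids);
  int len = (int)seq.size();
  NumericMatrix res(n_shuffles, 4);
  colnames(res) = CharacterVector::create("N", "RE", "LSC", "ASP");
  RNGScope scope;
  std::vector<int> work(seq);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = len - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i; // guard against unif_rand() == 1.0
      std::swap(work[i], work[j]);
    }
    Attrs a = compute_attrs(work, asp_directed, re_excess);
    res(s, 0) = (double)a.n_nodes;
    res(s, 1) = a.re;
    res(s, 2) = (double)a.lsc;
    res(s, 3) = a.asp;
  }
  return res;
}
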