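#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Families whose parent-configuration count exceeds this are given -Inf so the
// search can never walk into parameter blow-up (no cap on parents otherwise).
static const long long MAX_Q = 4000000LL;

// BIC family score: maximised multinomial log-likelihood of `node` given the
// observed parent configurations, minus log(n)/2 * (r-1)*q free parameters.
// Zero cells contribute 0 (0*log 0 == 0 convention). `node`/`parents` 0-based;
// data entries are 1-based level indices.
static double family_bic(const IntegerMatrix& X, const IntegerVector& nlev,
                         int node, const std::vector<int>& parents) {
  const int n = X.nrow();
  const int r = nlev[node];
  long long q = 1;
  for (size_t j = 0; j < parents.size(); ++j) {
    q *= nlev[parents[j]];
    if (q > MAX_Q) return -std::numeric_limits<double>::infinity();
  }
  std::vector<int> counts((size_t)(q * r), 0);
  const int* xnode = &X[0] + (size_t)node * n;
  const size_t np = parents.size();
  std::vector<const int*> pcol(np);
  std::vector<long long> stride(np);
  long long s = 1;
  for (size_t j = 0; j < np; ++j) {
    pcol[j] = &X[0] + (size_t)parents[j] * n;
    stride[j] = s;
    s *= nlev[parents[j]];
  }
  if (np == 0) {
    for (int i = 0; i < n; ++i) counts[xnode[i] - 1]++;
  } else if (np == 1) {
    const int* p0 = pcol[0];
    for (int i = 0; i < n; ++i)
      counts[(size_t)(p0[i] - 1) * r + (xnode[i] - 1)]++;
  } else {
    for (int i = 0; i < n; ++i) {
      long long pc = 0;
      for (size_t j = 0; j < np; ++j)
        pc += stride[j] * (long long)(pcol[j][i] - 1);
      counts[(size_t)(pc * r + (xnode[i] - 1))]++;
    }
  }
  double ll = 0.0;
  for (long long c = 0; c < q; ++c) {
    int tot = 0;
    for (int k = 0; k < r; ++k) tot += counts[(size_t)(c * r + k)];
    if (tot == 0) continue;
    const double ltot = std::log((double)tot);
    for (int k = 0; k < r; ++k) {
      int cnt = counts[(size_t)(c * r + k)];
      if (cnt > 0) ll += cnt * (std::log((double)cnt) - ltot);
    }
  }
  double penalty = 0.5 * std::log((double)n) * (double)(r - 1) * (double)q;
  return ll - penalty;
}

// [[Rcpp::export]]
double family_score_cpp(IntegerMatrix X, IntegerVector nlev, int node,
                        IntegerVector parents) {
  std::vector<int> ps(parents.begin(), parents.end());
  return family_bic(X, nlev, node, ps);
}

// ---- tabu search over DAG space ------------------------------------------

// Is there a directed path from `from` to `to` in amat (excluding arcs removed
// via the mask)? Iterative DFS; p is small (<= ~30 nodes).
static bool has_path(const std::vector<char>& amat, int p, int from, int to) {
  if (from == to) return true;
  std::vector<char> seen(p, 0);
  std::vector<int> stack;
  stack.push_back(from);
  seen[from] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int v = 0; v < p; ++v) {
      if (amat[(size_t)u * p + v] && !seen[v]) {
        if (v == to) return true;
        seen[v] = 1;
        stack.push_back(v);
      }
    }
  }
  return false;
}

struct TabuState {
  int p;
  std::vector<char> amat;           // amat[u*p+v] == arc u -> v
  std::vector<unsigned long long> pmask;  // parent bitmask per node
  std::unordered_map<unsigned long long, double> cache;
  const IntegerMatrix* X;
  const IntegerVector* nlev;

  double fscore(int node, unsigned long long mask) {
    unsigned long long key = (mask << 6) | (unsigned long long)node;
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    std::vector<int> ps;
    for (int j = 0; j < p; ++j)
      if ((mask >> j) & 1ULL) ps.push_back(j);
    double v = family_bic(*X, *nlev, node, ps);
    cache[key] = v;
    return v;
  }
};

// Moves are encoded op * p * p + u * p + v, op: 0 add, 1 delete, 2 reverse.
// The inverse of the applied move goes on the tabu list; a listed move is
// forbidden unless it beats the best score seen (aspiration).
// Deterministic: candidate moves are scanned in lexicographic
// (op, from, to) order and only a strictly better delta displaces the choice.
// [[Rcpp::export]]
List tabu_search_cpp(IntegerMatrix X, IntegerVector nlev, LogicalMatrix start,
                     LogicalMatrix wl, LogicalMatrix bl, int tabu_len,
                     int max_iter, int max_stall) {
  const int p = nlev.size();
  if (p > 57) stop("tabu_search_cpp supports at most 57 nodes");
  TabuState st;
  st.p = p;
  st.X = &X;
  st.nlev = &nlev;
  st.amat.assign((size_t)p * p, 0);
  st.pmask.assign(p, 0ULL);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v)
      if (start(u, v)) {
        st.amat[(size_t)u * p + v] = 1;
        st.pmask[v] |= (1ULL << u);
      }

  double current = 0.0;
  for (int v = 0; v < p; ++v) current += st.fscore(v, st.pmask[v]);
  double best = current;
  std::vector<char> best_amat = st.amat;

  std::deque<long long> tabu;
  auto is_tabu = [&](long long code) {
    for (long long t : tabu)
      if (t == code) return true;
    return false;
  };

  const double eps = 1e-12;
  int stall = 0;
  int iter = 0;
  for (; iter < max_iter && stall < max_stall; ++iter) {
    double best_delta = -std::numeric_limits<double>::infinity();
    int b_op = -1, b_u = -1, b_v = -1;
    double b_new1 = 0, b_new2 = 0;  // family scores after the move

    for (int op = 0; op < 3; ++op) {
      for (int u = 0; u < p; ++u) {
        for (int v = 0; v < p; ++v) {
          if (u == v) continue;
          double delta, new1 = 0, new2 = 0;
          if (op == 0) {  // add u -> v
            if (st.amat[(size_t)u * p + v] || st.amat[(size_t)v * p + u])
              continue;
            if (bl(u, v)) continue;
            if (has_path(st.amat, p, v, u)) continue;  // would create a cycle
            new1 = st.fscore(v, st.pmask[v] | (1ULL << u));
            delta = new1 - st.fscore(v, st.pmask[v]);
          } else if (op == 1) {  // delete u -> v
            if (!st.amat[(size_t)u * p + v]) continue;
            if (wl(u, v)) continue;
            new1 = st.fscore(v, st.pmask[v] & ~(1ULL << u));
            delta = new1 - st.fscore(v, st.pmask[v]);
          } else {  // reverse u -> v
            if (!st.amat[(size_t)u * p + v]) continue;
            if (wl(u, v) || bl(v, u)) continue;
            st.amat[(size_t)u * p + v] = 0;  // test cycle without the arc
            bool cyc = has_path(st.amat, p, u, v);
            st.amat[(size_t)u * p + v] = 1;
            if (cyc) continue;
            new1 = st.fscore(v, st.pmask[v] & ~(1ULL << u));
            new2 = st.fscore(u, st.pmask[u] | (1ULL << v));
            delta = (new1 - st.fscore(v, st.pmask[v])) +
                    (new2 - st.fscore(u, st.pmask[u]));
          }
          if (!std::isfinite(delta)) continue;
          long long code = (long long)op * p * p + (long long)u * p + v;
          if (is_tabu(code) && !(current + delta > best + eps)) continue;
          if (delta > best_delta + eps) {
            best_delta = delta;
            b_op = op;
            b_u = u;
            b_v = v;
            b_new1 = new1;
            b_new2 = new2;
          }
        }
      }
    }

    if (b_op < 0) break;  // no admissible move

    // apply and record the inverse move
    long long inv;
    if (b_op == 0) {
      st.amat[(size_t)b_u * p + b_v] = 1;
      st.pmask[b_v] |= (1ULL << b_u);
      inv = (long long)1 * p * p + (long long)b_u * p + b_v;
    } else if (b_op == 1) {
      st.amat[(size_t)b_u * p + b_v] = 0;
      st.pmask[b_v] &= ~(1ULL << b_u);
      inv = (long long)0 * p * p + (long long)b_u * p + b_v;
    } else {
      st.amat[(size_t)b_u * p + b_v] = 0;
      st.amat[(size_t)b_v * p + b_u] = 1;
      st.pmask[b_v] &= ~(1ULL << b_u);
      st.pmask[b_u] |= (1ULL << b_v);
      inv = (long long)2 * p * p + (long long)b_v * p + b_u;
    }
    (void)b_new1;
    (void)b_new2;
    tabu.push_back(inv);
    while ((int)tabu.size() > tabu_len) tabu.pop_front();

    current += best_delta;
    if (current > best + 1e-9) {
      best = current;
      best_amat = st.amat;
      stall = 0;
    } else {
      stall++;
    }
  }

  LogicalMatrix out(p, p);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v) out(u, v) = best_amat[(size_t)u * p + v] != 0;
  return List::create(_["amat"] = out, _["score"] = best,
                      _["iterations"] = iter);
}
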