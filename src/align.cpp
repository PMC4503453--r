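#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <queue>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -1e18;

// ---------------------------------------------------------------------------
// Infix (semi-global) edit distance: best occurrence of `pattern` as an
// approximate substring of `text`.  Unit costs.  Ties broken toward the
// leftmost end position, then the leftmost start.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".lf_edit_find")]]
IntegerVector lf_edit_find(std::string text, std::string pattern) {
  int n = (int) text.size(), m = (int) pattern.size();
  if (m == 0 || n == 0)
    return IntegerVector::create(_["dist"] = m, _["start"] = NA_INTEGER,
                                 _["end"] = NA_INTEGER);
  // column-wise DP over text positions; rows 0..m over pattern
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> sprev(m + 1), scur(m + 1); // start index (0-based) of path
  for (int i = 0; i <= m; ++i) { prev[i] = i; sprev[i] = 0; }
  int best = prev[m], bestEnd = 0, bestStart = 0;
  for (int j = 1; j <= n; ++j) {
    cur[0] = 0; scur[0] = j; // free leading gap in text
    for (int i = 1; i <= m; ++i) {
      int sub = prev[i - 1] + (text[j - 1] == pattern[i - 1] ? 0 : 1);
      int del = prev[i] + 1;   // consume text char
      int ins = cur[i - 1] + 1; // consume pattern char
      int v = sub, s = sprev[i - 1];
      if (del < v || (del == v && sprev[i] < s)) { v = del; s = sprev[i]; }
      if (ins < v || (ins == v && scur[i - 1] < s)) { v = ins; s = scur[i - 1]; }
      cur[i] = v; scur[i] = s;
    }
    if (cur[m] < best) { best = cur[m]; bestEnd = j; bestStart = scur[m]; }
    std::swap(prev, cur); std::swap(sprev, scur);
  }
  if (bestEnd == 0) { // pattern never placed (n too short): align at left edge
    bestStart = 0; bestEnd = std::min(n, m);
  }
  return IntegerVector::create(_["dist"] = best, _["start"] = bestStart + 1,
                               _["end"] = bestEnd);
}

// ---------------------------------------------------------------------------
// Banded affine-gap pairwise alignment (Gotoh) with configurable free end
// gaps.  Band: cells with |j - i - offset| <= band (i over `a`, j over `b`).
// Returns the aligned region and the per-column operation string:
//   0 = match, 1 = mismatch, 2 = gap in b (consumes a), 3 = gap in a.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".lf_align")]]
List lf_align(std::string a, std::string b,
              double match, double mismatch, double gap_open, double gap_ext,
              bool free_a_start, bool free_b_start,
              bool free_a_end, bool free_b_end,
              int band, int offset) {
  int n = (int) a.size(), m = (int) b.size();
  if (band <= 0) band = std::max(n, m) + 1; // full DP
  int W = 2 * band + 1;
  size_t sz = (size_t)(n + 1) * W;
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  std::vector<int8_t> tM(sz, -1), tX(sz, -1), tY(sz, -1);
  // band column for (i, j): c = j - (i + offset - band); valid 0..W-1
  auto idx = [&](int i, int c) { return (size_t) i * W + c; };
  auto colOf = [&](int i, int j) { return j - (i + offset - band); };
  const int8_t START = 9;

  for (int i = 0; i <= n; ++i) {
    int lo = std::max(0, i + offset - band), hi = std::min(m, i + offset + band);
    for (int j = lo; j <= hi; ++j) {
      int c = colOf(i, j);
      size_t id = idx(i, c);
      if (i == 0 && j == 0) { M[id] = 0; tM[id] = START; }
      if (i == 0 && j > 0) {
        if (free_b_start) { M[id] = 0; tM[id] = START; }
        // gap path along first row
        double fromM = (j - 1 >= lo) ? M[idx(0, colOf(0, j - 1))] : NEG_INF;
        double fromY = (j - 1 >= lo) ? Y[idx(0, colOf(0, j - 1))] : NEG_INF;
        double og = fromM + gap_open + gap_ext, eg = fromY + gap_ext;
        if (og >= eg) { if (og > Y[id]) { Y[id] = og; tY[id] = 0; } }
        else { if (eg > Y[id]) { Y[id] = eg; tY[id] = 2; } }
      }
      if (j == 0 && i > 0) {
        if (free_a_start) { M[id] = 0; tM[id] = START; }
        int cp = colOf(i - 1, 0);
        if (cp >= 0 && cp < W) {
          double fromM = M[idx(i - 1, cp)] + gap_open + gap_ext;
          double fromX = X[idx(i - 1, cp)] + gap_ext;
          if (fromM >= fromX) { if (fromM > X[id]) { X[id] = fromM; tX[id] = 0; } }
          else { if (fromX > X[id]) { X[id] = fromX; tX[id] = 1; } }
        }
      }
      if (i > 0 && j > 0) {
        // M: diagonal
        int cd = colOf(i - 1, j - 1);
        if (cd >= 0 && cd < W) {
          size_t pd = idx(i - 1, cd);
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          double vm = M[pd], vx = X[pd], vy = Y[pd];
          double bestv = vm; int8_t bt = 0;
          if (vx > bestv) { bestv = vx; bt = 1; }
          if (vy > bestv) { bestv = vy; bt = 2; }
          if (bestv > NEG_INF / 2) { M[id] = bestv + s; tM[id] = bt; }
        }
        // X: gap in b, from (i-1, j)
        int cu = colOf(i - 1, j);
        if (cu >= 0 && cu < W) {
          size_t pu = idx(i - 1, cu);
          double og = M[pu] + gap_open + gap_ext, eg = X[pu] + gap_ext;
          if (og >= eg) { if (og > NEG_INF / 2) { X[id] = og; tX[id] = 0; } }
          else { X[id] = eg; tX[id] = 1; }
        }
        // Y: gap in a, from (i, j-1)
        int cl = colOf(i, j - 1);
        if (cl >= 0 && cl < W) {
          size_t pl = idx(i, cl);
          double og = M[pl] + gap_open + gap_ext, eg = Y[pl] + gap_ext;
          if (og >= eg) { if (og > NEG_INF / 2) { Y[id] = og; tY[id] = 0; } }
          else { Y[id] = eg; tY[id] = 2; }
        }
      }
    }
  }

  // endpoint selection
  double best = NEG_INF; int bi = -1, bj = -1; int8_t bs = 0;
  auto consider = [&](int i, int j) {
    int c = colOf(i, j);
    if (c < 0 || c >= W) return;
    size_t id = idx(i, c);
    double vals[3] = { M[id], X[id], Y[id] };
    for (int s = 0; s < 3; ++s) {
      double v = vals[s];
      if (v <= NEG_INF / 2) continue;
      if (v > best || (v == best && (i + j > bi + bj))) {
        best = v; bi = i; bj = j; bs = (int8_t) s;
      }
    }
  };
  consider(n, m);
  if (free_b_end) for (int j = 0; j <= m; ++j) consider(n, j);
  if (free_a_end) for (int i = 0; i <= n; ++i) consider(i, m);
  if (bi < 0)
    return List::create(_["score"] = NA_REAL);

  // traceback
  std::vector<int> ops;
  int i = bi, j = bj; int8_t s = bs;
  while (true) {
    int c = colOf(i, j);
    size_t id = idx(i, c);
    if (s == 0) {
      int8_t t = tM[id];
      if (t == START) break;
      if (i == 0 && j == 0) break;
      ops.push_back(a[i - 1] == b[j - 1] ? 0 : 1);
      --i; --j; s = t;
    } else if (s == 1) {
      int8_t t = tX[id];
      ops.push_back(2);
      --i; s = (t == 0) ? 0 : 1;
    } else {
      int8_t t = tY[id];
      ops.push_back(3);
      --j; s = (t == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,   // 0-based half-open on a
    _["b_start"] = j, _["b_end"] = bj,
    _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// ---------------------------------------------------------------------------
// 2-bit k-mer encoding helpers
// ---------------------------------------------------------------------------
static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Modal diagonal offset (pos_b - pos_a) over shared k-mers.
// [[Rcpp::export(name = ".lf_kmer_offset")]]
IntegerVector lf_kmer_offset(std::string a, std::string b, int k) {
  int n = (int) a.size(), m = (int) b.size();
  if (n < k || m < k)
    return IntegerVector::create(_["offset"] = NA_INTEGER, _["votes"] = 0,
                                 _["offset2"] = NA_INTEGER, _["votes2"] = 0);
  std::unordered_map<uint64_t, int> amap; // kmer -> first pos in a
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = baseCode(a[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run >= k) amap.emplace(key, i - k + 1);
  }
  std::unordered_map<int, int> votes;
  key = 0; run = 0;
  for (int j = 0; j < m; ++j) {
    int c = baseCode(b[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run >= k) {
      auto it = amap.find(key);
      if (it != amap.end()) ++votes[(j - k + 1) - it->second];
    }
  }
  if (votes.empty())
    return IntegerVector::create(_["offset"] = NA_INTEGER, _["votes"] = 0,
                                 _["offset2"] = NA_INTEGER, _["votes2"] = 0);
  // modal diagonal, plus the strongest diagonal further than 8 from it
  int bestOff = 0, bestVotes = -1;
  for (auto &kv : votes)
    if (kv.second > bestVotes ||
        (kv.second == bestVotes && kv.first < bestOff)) {
      bestVotes = kv.second; bestOff = kv.first;
    }
  int off2 = NA_INTEGER, votes2 = 0;
  for (auto &kv : votes) {
    if (std::abs(kv.first - bestOff) <= 8) continue;
    if (kv.second > votes2 || (kv.second == votes2 && kv.first < off2)) {
      votes2 = kv.second; off2 = kv.first;
    }
  }
  return IntegerVector::create(_["offset"] = bestOff, _["votes"] = bestVotes,
                               _["offset2"] = off2, _["votes2"] = votes2);
}

// ---------------------------------------------------------------------------
// Shared-k-mer candidate pairs: for each pair of sequences sharing >=
// min_shared seeded k-mers, report the pair.  Seeding is by k-mer content
// (hash mod stride), so it is invariant to 5' truncation of a sequence.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".lf_kmer_pairs")]]
IntegerMatrix lf_kmer_pairs(CharacterVector seqs, int k, int stride,
                            int min_shared, int max_bucket) {
  int N = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < N; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int n = (int) s.size();
    uint64_t key = 0; int run = 0;
    std::vector<uint64_t> mine;
    for (int i = 0; i < n; ++i) {
      int c = baseCode(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (run + 1 >= k) {
        uint64_t h = key * 0x9E3779B97F4A7C15ULL;
        if (stride <= 1 || (h >> 33) % (uint64_t) stride == 0)
          mine.push_back(key);
      }
      ++run;
    }
    std::sort(mine.begin(), mine.end());
    mine.erase(std::unique(mine.begin(), mine.end()), mine.end());
    for (uint64_t km : mine) buckets[km].push_back(r);
  }
  std::unordered_map<uint64_t, int> counts;
  for (auto &kv : buckets) {
    std::vector<int> &v = kv.second;
    if ((int) v.size() < 2 || (int) v.size() > max_bucket) continue;
    for (size_t x = 0; x + 1 < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        counts[((uint64_t) v[x] << 32) | (uint64_t) v[y]]++;
  }
  std::vector<std::array<int, 3>> out;
  for (auto &kv : counts)
    if (kv.second >= min_shared)
      out.push_back({(int)(kv.first >> 32), (int)(kv.first & 0xffffffffULL),
                     kv.second});
  std::sort(out.begin(), out.end());
  IntegerMatrix res(out.size(), 3);
  for (size_t r = 0; r < out.size(); ++r) {
    res(r, 0) = out[r][0] + 1; // 1-based ids for R
    res(r, 1) = out[r][1] + 1;
    res(r, 2) = out[r][2];
  }
  colnames(res) = CharacterVector::create("i", "j", "shared");
  return res;
}

// ---------------------------------------------------------------------------
// Partial-order alignment consensus.
// Sequences are threaded into a DAG in the given order (caller sorts by
// decreasing length); each read is aligned to the graph semi-globally (read
// fully consumed, graph ends free), matching nodes accumulate the read's
// weight, mismatch/insertion columns create new nodes.  The consensus is the
// heaviest path (node-weight sum) through the final DAG.
// ---------------------------------------------------------------------------
struct PoaGraph {
  std::vector<char> base;
  std::vector<double> weight;
  std::vector<std::vector<int>> preds;
  std::vector<std::vector<double>> predw; // edge weight, parallel to preds
  std::vector<std::vector<int>> succs;
  int addNode(char b, double w) {
    base.push_back(b); weight.push_back(w);
    preds.push_back({}); predw.push_back({}); succs.push_back({});
    return (int) base.size() - 1;
  }
  void addEdge(int u, int v, double w) {
    if (u < 0 || v < 0) return;
    for (size_t x = 0; x < preds[v].size(); ++x)
      if (preds[v][x] == u) { predw[v][x] += w; return; }
    preds[v].push_back(u); predw[v].push_back(w); succs[u].push_back(v);
  }
  std::vector<int> topo() const {
    int V = (int) base.size();
    std::vector<int> indeg(V, 0), order;
    for (int v = 0; v < V; ++v) indeg[v] = (int) preds[v].size();
    std::priority_queue<int, std::vector<int>, std::greater<int>> q;
    for (int v = 0; v < V; ++v) if (indeg[v] == 0) q.push(v);
    while (!q.empty()) {
      int v = q.top(); q.pop();
      order.push_back(v);
      for (int s : succs[v]) if (--indeg[s] == 0) q.push(s);
    }
    return order;
  }
};

// [[Rcpp::export(name = ".lf_poa_consensus")]]
List lf_poa_consensus(CharacterVector seqs, NumericVector weights,
                      double match, double mismatch, double gap) {
  PoaGraph g;
  int nseq = seqs.size();
  for (int r = 0; r < nseq; ++r) {
    std::string s = as<std::string>(seqs[r]);
    double w = weights[r];
    int L = (int) s.size();
    if (L == 0) continue;
    if (g.base.empty()) {
      int prev = -1;
      for (int j = 0; j < L; ++j) {
        int v = g.addNode(s[j], w);
        g.addEdge(prev, v, w);
        prev = v;
      }
      continue;
    }
    std::vector<int> order = g.topo();
    int V = (int) order.size();
    std::vector<int> tpos(g.base.size());
    for (int t = 0; t < V; ++t) tpos[order[t]] = t;
    // dp[(t+1)][j]: best score, read[0..j) consumed, node order[t] last used.
    // row 0 = virtual start (no node consumed): dp = j * gap.
    size_t rows = (size_t) V + 1, cols = (size_t) L + 1;
    std::vector<double> dp(rows * cols, NEG_INF);
    std::vector<int32_t> bt(rows * cols, -1);   // packed: pred_row * 4 + op
    // op: 0 align, 1 read-del (consume node only), 2 read-ins (consume char)
    auto id = [&](size_t t, size_t j) { return t * cols + j; };
    for (int j = 0; j <= L; ++j) dp[id(0, j)] = (double) j * gap;
    for (int t = 1; t <= V; ++t) {
      int v = order[t - 1];
      std::vector<int> prows; // pred rows (0 = virtual)
      prows.push_back(0);
      for (int p : g.preds[v]) prows.push_back(tpos[p] + 1);
      for (int j = 0; j <= L; ++j) {
        double bestv = NEG_INF; int32_t bb = -1;
        if (j > 0) {
          double sc = (g.base[v] == s[j - 1]) ? match : mismatch;
          for (int pr : prows) {
            double cand = dp[id(pr, j - 1)] + sc;
            if (cand > bestv) { bestv = cand; bb = pr * 4 + 0; }
          }
        }
        for (int pr : prows) {
          double cand = dp[id(pr, j)] + gap;
          if (cand > bestv) { bestv = cand; bb = pr * 4 + 1; }
        }
        if (j > 0) {
          double cand = dp[id(t, j - 1)] + gap;
          if (cand > bestv) { bestv = cand; bb = (int32_t) t * 4 + 2; }
        }
        dp[id(t, j)] = bestv; bt[id(t, j)] = bb;
      }
    }
    // endpoint: read fully consumed, any node (free graph suffix)
    double best = NEG_INF; int bt_row = 0;
    for (int t = 0; t <= V; ++t)
      if (dp[id(t, L)] > best) { best = dp[id(t, L)]; bt_row = t; }
    // traceback: collect (op, node, readpos)
    struct Step { int op; int node; int readpos; };
    std::vector<Step> path;
    int t = bt_row, j = L;
    while (!(t == 0 && j == 0)) {
      if (t == 0) { path.push_back({2, -1, j - 1}); --j; continue; }
      int32_t b = bt[id(t, j)];
      if (b < 0) break;
      int pr = b / 4, op = b % 4;
      int v = order[t - 1];
      if (op == 0) { path.push_back({0, v, j - 1}); t = pr; --j; }
      else if (op == 1) { path.push_back({1, v, -1}); t = pr; }
      else { path.push_back({2, -1, j - 1}); --j; }
    }
    std::reverse(path.begin(), path.end());
    int prev = -1;
    for (Step &st : path) {
      if (st.op == 1) continue; // node skipped by this read
      int node;
      if (st.op == 0 && g.base[st.node] == s[st.readpos]) {
        node = st.node;
        g.weight[node] += w;
      } else {
        node = g.addNode(s[st.readpos], w);
      }
      g.addEdge(prev, node, w);
      prev = node;
    }
  }
  // consensus: heaviest path by summed EDGE weights (read bundles), so a
  // detour through a low-support insertion node never beats the direct
  // well-travelled edge; low-support dangling ends are trimmed afterwards.
  std::vector<int> order = g.topo();
  int V = (int) order.size();
  if (V == 0) return List::create(_["consensus"] = "", _["support"] = NumericVector());
  std::vector<double> best(g.base.size(), 0);
  std::vector<int> from(g.base.size(), -1);
  double gbest = NEG_INF; int gend = -1;
  for (int t = 0; t < V; ++t) {
    int v = order[t];
    double b = 0; int f = -1;
    for (size_t x = 0; x < g.preds[v].size(); ++x) {
      int p = g.preds[v][x];
      double cand = best[p] + g.predw[v][x];
      if (cand > b || (cand == b && f >= 0 && p < f)) { b = cand; f = p; }
    }
    best[v] = b; from[v] = f;
    if (best[v] > gbest || (best[v] == gbest && v < gend)) { gbest = best[v]; gend = v; }
  }
  std::vector<int> nodes;
  for (int v = gend; v >= 0; v = from[v]) nodes.push_back(v);
  std::reverse(nodes.begin(), nodes.end());
  // trim weakly supported terminal nodes (below a quarter of the median
  // node support along the path)
  {
    std::vector<double> ws;
    for (int v : nodes) ws.push_back(g.weight[v]);
    std::vector<double> sorted = ws;
    std::sort(sorted.begin(), sorted.end());
    double med = sorted.empty() ? 0 : sorted[sorted.size() / 2];
    size_t lo = 0, hi = nodes.size();
    while (lo < hi && g.weight[nodes[lo]] < 0.25 * med) ++lo;
    while (hi > lo && g.weight[nodes[hi - 1]] < 0.25 * med) --hi;
    nodes = std::vector<int>(nodes.begin() + lo, nodes.begin() + hi);
  }
  std::string cons;
  NumericVector supp(nodes.size());
  for (size_t x = 0; x < nodes.size(); ++x) {
    cons.push_back(g.base[nodes[x]]);
    supp[x] = g.weight[nodes[x]];
  }
  return List::create(_["consensus"] = cons, _["support"] = supp);
}
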