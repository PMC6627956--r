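// Partial-order alignment (POA) multiple aligner.  Reads are added one at a
// time by optimal global alignment to the growing sequence graph (linear gap
// scoring); aligned matches fuse into existing nodes, mismatches fuse into an
// "aligned ring" alternative, insertions create fresh nodes.  The graph is
// finally linearised: each ring of mutually aligned nodes becomes one MSA
// column, so deleting the gaps of row i reproduces read i exactly.
//
// The sequence-to-graph DP can be banded around each node's approximate
// template position; with amplicon reads the band only needs to absorb the
// cumulative indel drift, so a generous band leaves alignments unchanged
// while cutting the runtime by roughly the band/length ratio.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

const float NEG = -1e30f;
enum { MV_NONE = 0, MV_DIAG, MV_VERT, MV_HORIZ, MV_SDIAG, MV_SVERT };

struct PoaGraph {
  std::vector<char> base;
  std::vector<std::vector<int>> pred, succ;
  std::vector<int> ring;
  std::vector<std::vector<int>> ringMembers;
  std::vector<int> apos;  // approximate template position, band centre
  std::vector<std::vector<int>> paths;

  int addNode(char b, int pos) {
    base.push_back(b);
    pred.emplace_back();
    succ.emplace_back();
    ring.push_back((int)ringMembers.size());
    ringMembers.push_back({(int)base.size() - 1});
    apos.push_back(pos);
    return (int)base.size() - 1;
  }
  void joinRing(int node, int anchor) {
    ringMembers[ring[node]].clear();
    ring[node] = ring[anchor];
    ringMembers[ring[anchor]].push_back(node);
  }
  void addEdge(int u, int v) {
    if (u < 0 || v < 0 || u == v) return;
    for (int s : succ[u])
      if (s == v) return;
    succ[u].push_back(v);
    pred[v].push_back(u);
  }
};

std::vector<int> topoOrder(const PoaGraph &g) {
  const int N = (int)g.base.size();
  std::vector<int> indeg(N), order;
  order.reserve(N);
  std::vector<int> q;
  for (int v = 0; v < N; ++v) {
    indeg[v] = (int)g.pred[v].size();
    if (!indeg[v]) q.push_back(v);
  }
  while (!q.empty()) {
    int v = q.back();
    q.pop_back();
    order.push_back(v);
    for (int s : g.succ[v])
      if (--indeg[s] == 0) q.push_back(s);
  }
  if ((int)order.size() != N) stop("poa: graph is not acyclic");
  return order;
}

struct Buffers {
  std::vector<float> H;
  std::vector<int32_t> Pn;
  std::vector<uint8_t> Mv;
};

// Returns false when the banded DP could not reach a sink (band too narrow).
bool alignAndFuse(PoaGraph &g, const std::string &seq, float match,
                  float mismatch, float gap, int band, Buffers &buf) {
  const int N = (int)g.base.size(), L = (int)seq.size();
  std::vector<int> order = topoOrder(g);
  std::vector<int> rankOf(N);
  for (int k = 0; k < N; ++k) rankOf[order[k]] = k;

  const size_t W = (size_t)L + 1, sz = (size_t)N * W;
  if (buf.H.size() < sz) {
    buf.H.resize(sz);
    buf.Pn.resize(sz);
    buf.Mv.resize(sz);
  }
  float *H = buf.H.data();
  int32_t *Pn = buf.Pn.data();
  uint8_t *Mv = buf.Mv.data();

  for (int v : order) {
    float *row = H + (size_t)v * W;
    int32_t *prn = Pn + (size_t)v * W;
    uint8_t *pmv = Mv + (size_t)v * W;
    int jl = 0, jh = L;
    if (band > 0) {
      jl = std::max(0, g.apos[v] - band);
      jh = std::min(L, g.apos[v] + band);
      std::fill(row, row + W, NEG);  // cells outside the band stay -inf
    }
    const bool src = g.pred[v].empty();
    for (int j = jl; j <= jh; ++j) {
      float best = NEG;
      uint8_t bmv = MV_NONE;
      int32_t bpn = -1;
      if (src) {
        if (j >= 1) {
          const float sc = (float)(j - 1) * gap +
                           (g.base[v] == seq[j - 1] ? match : mismatch);
          if (sc > best) { best = sc; bmv = MV_SDIAG; }
        }
        const float sc = (float)j * gap + gap;
        if (sc > best) { best = sc; bmv = MV_SVERT; }
      }
      for (int p : g.pred[v]) {
        const float *prow = H + (size_t)p * W;
        if (j >= 1 && prow[j - 1] > NEG / 2) {
          const float sc =
              prow[j - 1] + (g.base[v] == seq[j - 1] ? match : mismatch);
          if (sc > best) { best = sc; bmv = MV_DIAG; bpn = p; }
        }
        if (prow[j] > NEG / 2) {
          const float sc = prow[j] + gap;
          if (sc > best) { best = sc; bmv = MV_VERT; bpn = p; }
        }
      }
      if (j >= 1 && row[j - 1] > NEG / 2) {
        const float sc = row[j - 1] + gap;
        if (sc > best) { best = sc; bmv = MV_HORIZ; }
      }
      row[j] = best;
      pmv[j] = bmv;
      prn[j] = bpn;
    }
  }

  int endv = -1;
  float bestScore = NEG;
  for (int v = 0; v < N; ++v)
    if (g.succ[v].empty() && H[(size_t)v * W + L] > bestScore) {
      bestScore = H[(size_t)v * W + L];
      endv = v;
    }
  if (endv < 0 || bestScore < NEG / 2) return false;

  std::vector<std::pair<int, int>> ops;
  ops.reserve(L + 16);
  int v = endv, j = L;
  for (;;) {
    const uint8_t mv = Mv[(size_t)v * W + j];
    const int32_t pn = Pn[(size_t)v * W + j];
    if (mv == MV_DIAG) {
      ops.push_back({v, j}); v = pn; --j;
    } else if (mv == MV_VERT) {
      ops.push_back({v, -1}); v = pn;
    } else if (mv == MV_HORIZ) {
      ops.push_back({-1, j}); --j;
    } else if (mv == MV_SDIAG) {
      ops.push_back({v, j}); --j;
      while (j >= 1) { ops.push_back({-1, j}); --j; }
      break;
    } else if (mv == MV_SVERT) {
      ops.push_back({v, -1});
      while (j >= 1) { ops.push_back({-1, j}); --j; }
      break;
    } else {
      stop("poa: corrupt traceback");
    }
  }
  std::reverse(ops.begin(), ops.end());

  // fuse into the graph; the rank guard keeps the node graph acyclic
  std::vector<int> path;
  path.reserve(L);
  int lastNode = -1, lastOldRank = -1;
  for (auto &op : ops) {
    const int nodeHit = op.first, sp = op.second;
    if (sp < 0) continue;  // deletion: read skips this graph node
    const char c = seq[sp - 1];
    int node = -1;
    if (nodeHit >= 0) {
      int cand = -1;
      if (g.base[nodeHit] == c) {
        cand = nodeHit;
      } else {
        for (int w : g.ringMembers[g.ring[nodeHit]])
          if (w < N && g.base[w] == c) { cand = w; break; }
      }
      // only pre-existing nodes downstream of the last fused old node may be
      // reused; anything else would risk a cycle or a double visit
      if (cand >= N || (cand >= 0 && rankOf[cand] <= lastOldRank)) cand = -1;
      if (cand >= 0) {
        node = cand;
        lastOldRank = rankOf[node];
      } else {
        node = g.addNode(c, g.apos[nodeHit]);
        g.joinRing(node, nodeHit);
      }
    } else {
      node = g.addNode(c, lastNode >= 0 ? g.apos[lastNode] + 1 : sp);
    }
    if (lastNode >= 0) g.addEdge(lastNode, node);
    path.push_back(node);
    lastNode = node;
  }
  g.paths.push_back(path);
  return true;
}

}  // namespace

// [[Rcpp::export]]
CharacterVector poa_msa_cpp(CharacterVector seqs, double match = 2.0,
                            double mismatch = -2.0, double gap = -2.0,
                            int band = 0) {
  const int nseq = seqs.size();
  if (nseq == 0) stop("poa: no sequences");
  PoaGraph g;
  {
    const std::string s0 = as<std::string>(seqs[0]);
    if (s0.empty()) stop("poa: empty sequence");
    std::vector<int> path;
    path.reserve(s0.size());
    int prev = -1;
    for (int i = 0; i < (int)s0.size(); ++i) {
      int v = g.addNode(s0[i], i);
      g.addEdge(prev, v);
      path.push_back(v);
      prev = v;
    }
    g.paths.push_back(path);
  }
  Buffers buf;
  for (int k = 1; k < nseq; ++k) {
    const std::string s = as<std::string>(seqs[k]);
    if (s.empty()) stop("poa: empty sequence");
    bool ok = alignAndFuse(g, s, (float)match, (float)mismatch, (float)gap,
                           band, buf);
    if (!ok)  // band too narrow for this read: realign unbanded
      ok = alignAndFuse(g, s, (float)match, (float)mismatch, (float)gap, 0,
                        buf);
    if (!ok) stop("poa: alignment failed");
  }

  const int N = (int)g.base.size();
  std::vector<int> colOf(N, -1);
  int ncol = 0;
  bool ok = true;

  // ring-level topological sort: one column per ring
  {
    const int R = (int)g.ringMembers.size();
    std::vector<std::vector<int>> rsucc(R);
    std::vector<int> indeg(R, 0), alive(R, 0);
    for (int v = 0; v < N; ++v) alive[g.ring[v]] = 1;
    for (int u = 0; u < N; ++u)
      for (int v : g.succ[u]) {
        const int ru = g.ring[u], rv = g.ring[v];
        if (ru == rv) { ok = false; continue; }
        bool seen = false;
        for (int s : rsucc[ru])
          if (s == rv) { seen = true; break; }
        if (!seen) { rsucc[ru].push_back(rv); ++indeg[rv]; }
      }
    if (ok) {
      std::vector<int> q, order;
      for (int r = 0; r < R; ++r)
        if (alive[r] && indeg[r] == 0) q.push_back(r);
      std::vector<int> ringCol(R, -1);
      while (!q.empty()) {
        int r = q.back();
        q.pop_back();
        order.push_back(r);
        for (int s : rsucc[r])
          if (--indeg[s] == 0) q.push_back(s);
      }
      int nAlive = 0;
      for (int r = 0; r < R; ++r) nAlive += alive[r];
      if ((int)order.size() != nAlive) {
        ok = false;
      } else {
        for (int k = 0; k < (int)order.size(); ++k) ringCol[order[k]] = k;
        for (int v = 0; v < N; ++v) colOf[v] = ringCol[g.ring[v]];
        ncol = (int)order.size();
      }
    }
    if (ok) {
      for (auto &path : g.paths) {
        int prev = -1;
        for (int v : path) {
          if (colOf[v] <= prev) { ok = false; break; }
          prev = colOf[v];
        }
        if (!ok) break;
      }
    }
  }
  if (!ok) {
    // degenerate fallback: one column per node (always consistent)
    std::vector<int> order = topoOrder(g);
    for (int k = 0; k < N; ++k) colOf[order[k]] = k;
    ncol = N;
  }

  CharacterVector out(nseq);
  for (int k = 0; k < nseq; ++k) {
    std::string row(ncol, '-');
    for (int v : g.paths[k]) row[colOf[v]] = g.base[v];
    out[k] = row;
  }
  return out;
}
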