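// Pairwise alignment kernels: affine-gap global alignment (Gotoh, optionally
// banded) with full traceback, and a semi-global locator used for tag/primer
// search (pattern aligned end-to-end, free gaps at both ends of the text).
// Banded calls only initialise and compute the cells around the
// length-proportional diagonal, so the cost is O(length * band).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {
const float NEG = -1e30f;
enum { SM = 0, SX = 1, SY = 2 };

std::string rle_cigar(const std::string &ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

struct SgHit {
  double identity, score;
  int start, end, matches, columns;
};

// Semi-global core with caller-provided buffers (reused across calls).
SgHit sg_core(const std::string &pattern, const std::string &text,
              float match, float mismatch, float gap_open, float gap_extend,
              std::vector<float> &M, std::vector<float> &X,
              std::vector<float> &Y, std::vector<uint8_t> &tM,
              std::vector<uint8_t> &tX, std::vector<uint8_t> &tY) {
  const int m = (int)pattern.size(), n = (int)text.size();
  const size_t W = (size_t)n + 1, sz = (size_t)(m + 1) * W;
  if (M.size() < sz) {
    M.resize(sz); X.resize(sz); Y.resize(sz);
    tM.resize(sz); tX.resize(sz); tY.resize(sz);
  }
  for (int j = 0; j <= n; ++j) { M[j] = 0.0f; X[j] = NEG; Y[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    const size_t r0 = (size_t)i * W;
    M[r0] = NEG;
    X[r0] = gap_open + (float)(i - 1) * gap_extend;
    tX[r0] = (i == 1) ? SM : SX;
    Y[r0] = NEG;
    for (int j = 1; j <= n; ++j) {
      const size_t c = r0 + j, d = r0 - W + (j - 1), u = r0 - W + j,
                   l = r0 + (j - 1);
      const float s = (pattern[i - 1] == text[j - 1]) ? match : mismatch;
      float best = M[d]; uint8_t st = SM;
      if (X[d] > best) { best = X[d]; st = SX; }
      if (Y[d] > best) { best = Y[d]; st = SY; }
      M[c] = (best > NEG / 2) ? best + s : NEG;
      tM[c] = st;

      best = M[u] + gap_open; st = SM;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; st = SX; }
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; st = SY; }
      X[c] = (best > NEG / 2) ? best : NEG;
      tX[c] = st;

      best = M[l] + gap_open; st = SM;
      if (X[l] + gap_open > best) { best = X[l] + gap_open; st = SX; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; st = SY; }
      Y[c] = (best > NEG / 2) ? best : NEG;
      tY[c] = st;
    }
  }
  float score = NEG;
  int jend = -1; uint8_t state = SM;
  const size_t rm = (size_t)m * W;
  for (int j = 1; j <= n; ++j) {
    if (M[rm + j] > score) { score = M[rm + j]; jend = j; state = SM; }
    if (X[rm + j] > score) { score = X[rm + j]; jend = j; state = SX; }
  }
  SgHit hit{0, (double)score, 0, jend, 0, 0};
  int i = m, j = jend;
  while (i > 0) {
    const size_t c = (size_t)i * W + j;
    ++hit.columns;
    if (state == SM) {
      if (pattern[i - 1] == text[j - 1]) ++hit.matches;
      state = tM[c]; --i; --j;
    } else if (state == SX) {
      state = tX[c]; --i;
    } else {
      state = tY[c]; --j;
    }
  }
  hit.start = j + 1;
  hit.identity = (double)hit.matches / (double)hit.columns;
  return hit;
}
}  // namespace

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = -2.0, double gap_extend = -1.0,
                  int band = 0) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("nw_align: empty sequence");
  if (band <= 0 && (double)(m + 1) * (double)(n + 1) > 6.4e7)
    stop("nw_align: sequences too long for full dynamic programming");
  const size_t W = (size_t)n + 1, sz = (size_t)(m + 1) * W;
  static std::vector<float> M, X, Y;
  static std::vector<uint8_t> tM, tX, tY;
  if (M.size() < sz) {
    M.resize(sz); X.resize(sz); Y.resize(sz);
    tM.resize(sz); tX.resize(sz); tY.resize(sz);
  }
  std::vector<int> lo(m + 1, 0), hi(m + 1, n);
  if (band > 0) {
    for (int i = 0; i <= m; ++i) {
      const int ci = (int)std::llround((double)i * n / (double)m);
      lo[i] = std::max(0, ci - band);
      hi[i] = std::min(n, ci + band);
    }
  }
  // initialise each row over its band plus a margin wide enough to cover
  // every cell the next row reads
  for (int i = 0; i <= m; ++i) {
    const int nx = std::min(i + 1, m);
    const int fl = std::max(0, std::min(lo[i], lo[nx]) - 1);
    const int fh = std::min(n, std::max(hi[i], hi[nx]) + 1);
    const size_t r0 = (size_t)i * W;
    for (int j = fl; j <= fh; ++j) { M[r0 + j] = NEG; X[r0 + j] = NEG; Y[r0 + j] = NEG; }
  }
  M[0] = 0.0f;
  for (int j = 1; j <= hi[0]; ++j) {
    Y[j] = (float)(gap_open + (double)(j - 1) * gap_extend);
    tY[j] = (j == 1) ? SM : SY;
  }
  for (int i = 1; i <= m; ++i) {
    const size_t r0 = (size_t)i * W;
    if (lo[i] == 0) {
      X[r0] = (float)(gap_open + (double)(i - 1) * gap_extend);
      tX[r0] = (i == 1) ? SM : SX;
    }
    const int jl = std::max(1, lo[i]), jh = hi[i];
    for (int j = jl; j <= jh; ++j) {
      const size_t c = r0 + j, d = r0 - W + (j - 1), u = r0 - W + j,
                   l = r0 + (j - 1);
      const float s = (a[i - 1] == b[j - 1]) ? (float)match : (float)mismatch;
      float best = M[d];
      uint8_t st = SM;
      if (X[d] > best) { best = X[d]; st = SX; }
      if (Y[d] > best) { best = Y[d]; st = SY; }
      M[c] = (best > NEG / 2) ? best + s : NEG;
      tM[c] = st;

      best = M[u] + (float)gap_open; st = SM;
      if (X[u] + (float)gap_extend > best) { best = X[u] + (float)gap_extend; st = SX; }
      if (Y[u] + (float)gap_open > best) { best = Y[u] + (float)gap_open; st = SY; }
      X[c] = (best > NEG / 2) ? best : NEG;
      tX[c] = st;

      best = M[l] + (float)gap_open; st = SM;
      if (X[l] + (float)gap_open > best) { best = X[l] + (float)gap_open; st = SX; }
      if (Y[l] + (float)gap_extend > best) { best = Y[l] + (float)gap_extend; st = SY; }
      Y[c] = (best > NEG / 2) ? best : NEG;
      tY[c] = st;
    }
  }

  const size_t corner = (size_t)m * W + n;
  float score = M[corner];
  uint8_t state = SM;
  if (X[corner] > score) { score = X[corner]; state = SX; }
  if (Y[corner] > score) { score = Y[corner]; state = SY; }
  if (score < NEG / 2) stop("nw_align: band too narrow to reach the corner");

  std::string ra, rb, ops;
  ra.reserve(m + n); rb.reserve(m + n); ops.reserve(m + n);
  int i = m, j = n;
  int matches = 0;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == SM) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); ops.push_back('M');
      if (a[i - 1] == b[j - 1]) ++matches;
      state = tM[c]; --i; --j;
    } else if (state == SX) {
      ra.push_back(a[i - 1]); rb.push_back('-'); ops.push_back('I');
      state = tX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); ops.push_back('D');
      state = tY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  std::reverse(ops.begin(), ops.end());
  const int columns = (int)ops.size();
  return List::create(
      _["score"] = (double)score, _["aligned_a"] = ra, _["aligned_b"] = rb,
      _["cigar"] = rle_cigar(ops), _["matches"] = matches,
      _["columns"] = columns,
      _["identity"] = (double)matches / (double)columns);
}

// Semi-global: pattern aligned end-to-end, text end gaps free.
// [[Rcpp::export]]
List sg_locate_cpp(std::string pattern, std::string text,
                   double match = 1.0, double mismatch = -1.0,
                   double gap_open = -2.0, double gap_extend = -1.0) {
  if (pattern.empty() || text.empty()) stop("sg_locate: empty sequence");
  static std::vector<float> M, X, Y;
  static std::vector<uint8_t> tM, tX, tY;
  SgHit hit = sg_core(pattern, text, (float)match, (float)mismatch,
                      (float)gap_open, (float)gap_extend, M, X, Y, tM, tX, tY);
  return List::create(
      _["identity"] = hit.identity, _["score"] = hit.score,
      _["start"] = hit.start, _["end"] = hit.end, _["matches"] = hit.matches,
      _["columns"] = hit.columns);
}

// Scan every read's first/last `window` bases against a panel of front/back
// tag patterns; returns, per read, the best front and back hit.
// [[Rcpp::export]]
NumericMatrix tag_scan_cpp(CharacterVector reads, CharacterVector front_pats,
                           CharacterVector back_pats, int window = 150,
                           double match = 1.0, double mismatch = -1.0,
                           double gap_open = -2.0, double gap_extend = -1.0) {
  const int nr = reads.size(), nf = front_pats.size(), nb = back_pats.size();
  NumericMatrix out(nr, 6);
  colnames(out) = CharacterVector::create("front_idx", "front_id", "front_end",
                                          "back_idx", "back_id", "back_start");
  std::vector<std::string> fp(nf), bp(nb);
  for (int k = 0; k < nf; ++k) fp[k] = as<std::string>(front_pats[k]);
  for (int k = 0; k < nb; ++k) bp[k] = as<std::string>(back_pats[k]);
  std::vector<float> M, X, Y;
  std::vector<uint8_t> tM, tX, tY;
  for (int r = 0; r < nr; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int len = (int)rd.size();
    const int w = std::min(window, len);
    const std::string fw = rd.substr(0, w);
    const std::string bw = rd.substr(len - w);
    double bid = -1, bend = NA_REAL;
    int bidx = -1;
    for (int k = 0; k < nf; ++k) {
      if ((int)fp[k].size() > w) continue;
      SgHit hit = sg_core(fp[k], fw, (float)match, (float)mismatch,
                          (float)gap_open, (float)gap_extend, M, X, Y, tM, tX,
                          tY);
      if (hit.identity > bid) { bid = hit.identity; bidx = k + 1; bend = hit.end; }
    }
    out(r, 0) = bidx; out(r, 1) = bid; out(r, 2) = bend;
    bid = -1; bidx = -1;
    double bstart = NA_REAL;
    for (int k = 0; k < nb; ++k) {
      if ((int)bp[k].size() > w) continue;
      SgHit hit = sg_core(bp[k], bw, (float)match, (float)mismatch,
                          (float)gap_open, (float)gap_extend, M, X, Y, tM, tX,
                          tY);
      if (hit.identity > bid) {
        bid = hit.identity; bidx = k + 1;
        bstart = (double)(len - w + hit.start);
      }
    }
    out(r, 3) = bidx; out(r, 4) = bid; out(r, 5) = bstart;
  }
  return out;
}
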