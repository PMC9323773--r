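#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded sequences.
//
// Gap convention follows BLAST: a gap of length L costs gap_open + L * gap_extend,
// so the first gapped column already pays gap_open + gap_extend.
//
// With banded = true, computation is restricted to cells with
// diag_lo <= (j - i) <= diag_hi (i = query row, j = subject column, 1-based
// in the DP). Cells outside the band are unreachable. Traceback bytes are
// stored band-compressed: row i holds columns i+diag_lo .. i+diag_hi.
//
// Traceback distinguishes the three affine states so gap openings and
// extensions are recovered exactly. One byte per cell packs:
//   bits 0-1: H source (0 = stop/local start, 1 = diagonal, 2 = E, 3 = F)
//   bit  2:   E source (0 = opened from H, 1 = extended from E)
//   bit  3:   F source (0 = opened from H, 1 = extended from F)

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(IntegerVector q_, IntegerVector s_, NumericMatrix submat_,
                  double gap_open, double gap_extend,
                  bool banded, int diag_lo, int diag_hi, int wildcard) {
  const int m = q_.size(), n = s_.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0);
  const double go = gap_open + gap_extend; // opening a gap of length 1
  const double ge = gap_extend;
  const int *q = INTEGER(q_);
  const int *s = INTEGER(s_);
  const double *sub = REAL(submat_);
  const int nsub = submat_.nrow();

  if (!banded) { diag_lo = -m; diag_hi = n; }
  const int bw = diag_hi - diag_lo + 1;        // traceback band width
  std::vector<uint8_t> tb((size_t)(m + 1) * bw, 0);

  // E: gap in query (within-row, consumes subject) -- scalar along j.
  // F: gap in subject (across rows, consumes query) -- per-column array.
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fcol(n + 1, NEG_INF);
  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + diag_lo);
    int jhi = std::min(n, i + diag_hi);
    if (jlo > jhi) {
      std::fill(Hcur.begin(), Hcur.end(), 0.0);
      std::swap(Hprev, Hcur);
      continue;
    }
    Hcur[jlo - 1] = 0.0;
    double E = NEG_INF;
    const double *subrow = sub + (size_t)q[i - 1];
    uint8_t *tbrow = tb.data() + (size_t)i * bw;  // indexed by j - (i + diag_lo)
    const int joff = i + diag_lo;
    double *Hc = Hcur.data(), *Hp = Hprev.data(), *Fc = Fcol.data();
    for (int j = jlo; j <= jhi; ++j) {
      double e_open = Hc[j - 1] - go;
      double e_ext = E - ge;
      E = e_open > e_ext ? e_open : e_ext;
      uint8_t flags = (e_ext > e_open) ? 4 : 0;
      double f_open = Hp[j] - go;
      double f_ext = Fc[j] - ge;
      double F = f_open > f_ext ? f_open : f_ext;
      if (f_ext > f_open) flags |= 8;
      Fc[j] = F;
      double diag = Hp[j - 1] + subrow[(size_t)nsub * s[j - 1]];
      double h = 0.0;
      uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      Hc[j] = h;
      tbrow[j - joff] = flags | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (banded) {
      // cells leaving the band are unreachable for the next row
      if (jlo >= 1) { Hc[jlo - 1] = 0.0; Fcol[jlo - 1] = NEG_INF; }
      if (jhi + 1 <= n) { Hc[jhi + 1] = 0.0; Fcol[jhi + 1] = NEG_INF; }
    }
    std::swap(Hprev, Hcur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback from (bi, bj) in state H
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int cols = 0, ids = 0, gaps = 0;
  while (i > 0 && j > 0) {
    if (j < i + diag_lo || j > i + diag_hi) break;  // left the band
    uint8_t cell = tb[(size_t)i * bw + (j - (i + diag_lo))];
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == 0) break;
      if (src == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1] && q[i - 1] != wildcard) ++ids;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E consumes subject
      ++cols; ++gaps;
      state = (cell & 4) ? 1 : 0;
      --j;
    } else {                 // F consumes query
      ++cols; ++gaps;
      state = (cell & 8) ? 2 : 0;
      --i;
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,     // 0-based half-open
    _["s_start"] = j, _["s_end"] = bj,
    _["cols"] = cols, _["ids"] = ids, _["gaps"] = gaps);
}

// Score-only variant (no traceback); same banding semantics.
// [[Rcpp::export(name = ".cpp_sw_score")]]
double cpp_sw_score(IntegerVector q_, IntegerVector s_, NumericMatrix submat_,
                    double gap_open, double gap_extend,
                    bool banded, int diag_lo, int diag_hi) {
  const int m = q_.size(), n = s_.size();
  if (m == 0 || n == 0) return 0.0;
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int *q = INTEGER(q_);
  const int *s = INTEGER(s_);
  const double *sub = REAL(submat_);
  const int nsub = submat_.nrow();
  if (!banded) { diag_lo = -m; diag_hi = n; }
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fcol(n + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + diag_lo);
    int jhi = std::min(n, i + diag_hi);
    if (jlo > jhi) {
      std::fill(Hcur.begin(), Hcur.end(), 0.0);
      std::swap(Hprev, Hcur);
      continue;
    }
    Hcur[jlo - 1] = 0.0;
    double E = NEG_INF;
    const double *subrow = sub + (size_t)q[i - 1];
    double *Hc = Hcur.data(), *Hp = Hprev.data(), *Fc = Fcol.data();
    for (int j = jlo; j <= jhi; ++j) {
      double e_open = Hc[j - 1] - go, e_ext = E - ge;
      E = e_open > e_ext ? e_open : e_ext;
      double f_open = Hp[j] - go, f_ext = Fc[j] - ge;
      double F = f_open > f_ext ? f_open : f_ext;
      Fc[j] = F;
      double h = Hp[j - 1] + subrow[(size_t)nsub * s[j - 1]];
      if (E > h) h = E;
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      Hc[j] = h;
      if (h > best) best = h;
    }
    if (banded) {
      if (jlo >= 1) { Hc[jlo - 1] = 0.0; Fcol[jlo - 1] = NEG_INF; }
      if (jhi + 1 <= n) { Hc[jhi + 1] = 0.0; Fcol[jhi + 1] = NEG_INF; }
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Exact k-mer seed matches between q and s. Codes >= alphabet (ambiguity
// codes) invalidate any k-mer containing them. Returns a 2-column matrix of
// 0-based (q_pos, s_pos) start positions.
// [[Rcpp::export(name = ".cpp_find_seeds")]]
IntegerMatrix cpp_find_seeds(IntegerVector q_, IntegerVector s_, int k, int alphabet) {
  const int m = q_.size(), n = s_.size();
  std::vector<std::pair<int,int>> out;
  if (m < k || n < k) return IntegerMatrix(0, 2);
  const int *q = INTEGER(q_);
  const int *s = INTEGER(s_);
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)m * 2);
  const uint64_t A = (uint64_t)alphabet;
  uint64_t mask = 1;
  for (int t = 0; t < k; ++t) mask *= A;
  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < m; ++i) {
    int c = q[i];
    if (c < 0 || c >= alphabet) { valid = 0; key = 0; continue; }
    key = (key * A + (uint64_t)c) % mask;
    ++valid;
    if (valid >= k) index[key].push_back(i - k + 1);
  }
  key = 0; valid = 0;
  for (int j = 0; j < n; ++j) {
    int c = s[j];
    if (c < 0 || c >= alphabet) { valid = 0; key = 0; continue; }
    key = (key * A + (uint64_t)c) % mask;
    ++valid;
    if (valid >= k) {
      auto it = index.find(key);
      if (it != index.end())
        for (int qp : it->second)
          out.emplace_back(qp, j - k + 1);
    }
  }
  IntegerMatrix res((int)out.size(), 2);
  for (size_t t = 0; t < out.size(); ++t) {
    res((int)t, 0) = out[t].first;
    res((int)t, 1) = out[t].second;
  }
  return res;
}
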