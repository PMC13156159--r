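#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Pairwise alignment kernels shared by the circular-alignment and
// read-mapping layers. Scoring is a flat scheme (match, mismatch, linear
// gap). To make identities well defined when several alignments share the
// optimal score, the DP objective is lexicographic:
//   maximize score, then matches, then minimize gap columns.
// Traceback prefers diagonal, then gap-in-b (up), then gap-in-a (left),
// which together with the objective makes results fully deterministic.

struct Cell {
  int score;
  int matches;
  int gaps; // gap columns on the optimal path (minimized)
};

static inline bool better(const Cell& x, const Cell& y) {
  if (x.score != y.score) return x.score > y.score;
  if (x.matches != y.matches) return x.matches > y.matches;
  return x.gaps < y.gaps;
}

// traceback codes
enum Move : uint8_t { STOP = 0, DIAG = 1, UP = 2, LEFT = 3 };

static void nw_fill(const std::string& a, const std::string& b,
                    int match, int mismatch, int gap,
                    std::vector<Cell>& prev, std::vector<Cell>& cur,
                    std::vector<uint8_t>& tb, Cell& out) {
  const int n = (int)a.size(), m = (int)b.size();
  // tb has (n+1)*(m+1) entries, row-major
  prev.assign(m + 1, Cell{0, 0, 0});
  cur.assign(m + 1, Cell{0, 0, 0});
  tb.assign((size_t)(n + 1) * (m + 1), STOP);
  for (int j = 1; j <= m; ++j) {
    prev[j] = Cell{gap * j, 0, j};
    tb[j] = LEFT;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = Cell{gap * i, 0, i};
    tb[(size_t)i * (m + 1)] = UP;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      // N (or any non-ACGT) never counts as a match
      const bool eq = (ai == bj) && (ai == 'A' || ai == 'C' || ai == 'G' || ai == 'T');
      Cell d{prev[j - 1].score + (eq ? match : mismatch),
             prev[j - 1].matches + (eq ? 1 : 0), prev[j - 1].gaps};
      Cell u{prev[j].score + gap, prev[j].matches, prev[j].gaps + 1};
      Cell l{cur[j - 1].score + gap, cur[j - 1].matches, cur[j - 1].gaps + 1};
      uint8_t mv = DIAG; Cell best = d;
      if (better(u, best)) { best = u; mv = UP; }
      if (better(l, best)) { best = l; mv = LEFT; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  out = prev[m];
}

static void nw_traceback(const std::string& a, const std::string& b,
                         const std::vector<uint8_t>& tb,
                         std::string& a_aln, std::string& b_aln) {
  const int m = (int)b.size();
  int i = (int)a.size(), j = m;
  a_aln.clear(); b_aln.clear();
  while (i > 0 || j > 0) {
    uint8_t mv = tb[(size_t)i * (m + 1) + j];
    if (mv == DIAG) { a_aln.push_back(a[i - 1]); b_aln.push_back(b[j - 1]); --i; --j; }
    else if (mv == UP) { a_aln.push_back(a[i - 1]); b_aln.push_back('-'); --i; }
    else { a_aln.push_back('-'); b_aln.push_back(b[j - 1]); --j; }
  }
  std::reverse(a_aln.begin(), a_aln.end());
  std::reverse(b_aln.begin(), b_aln.end());
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  if ((double)(a.size() + 1) * (double)(b.size() + 1) > 6e7)
    stop("sequences too long for global alignment");
  std::vector<Cell> prev, cur;
  std::vector<uint8_t> tb;
  Cell res;
  nw_fill(a, b, match, mismatch, gap, prev, cur, tb, res);
  std::string aa, bb;
  nw_traceback(a, b, tb, aa, bb);
  int columns = (int)aa.size();
  return List::create(_["score"] = res.score, _["matches"] = res.matches,
                      _["gap_columns"] = res.gaps, _["columns"] = columns,
                      _["a_aln"] = aa, _["b_aln"] = bb);
}

// All rotations of b (and no strand handling: the caller supplies the
// reverse complement itself). Returns the rotation with the highest
// identity = matches / columns; ties broken by the smallest reported
// rotation offset r = (m - k) mod m, where k is the left-rotation of b.
// [[Rcpp::export]]
List circular_nw_cpp(std::string a, std::string b,
                     int match = 1, int mismatch = -1, int gap = -2) {
  const int m = (int)b.size();
  if ((double)(a.size() + 1) * (double)(m + 1) * (double)m > 2e9)
    stop("sequences too long for exhaustive circular alignment");
  std::vector<Cell> prev, cur;
  std::vector<uint8_t> tb;
  std::string bb = b + b;
  long best_num = -1, best_den = 1; // identity = matches / columns, exact
  int best_r = 0, best_k = 0;
  std::string best_rot;
  for (int k = 0; k < std::max(1, m); ++k) {
    std::string rot = m > 0 ? bb.substr(k, m) : b;
    Cell res;
    nw_fill(a, rot, match, mismatch, gap, prev, cur, tb, res);
    // every column is a gap column or consumes one char of each sequence:
    // columns = gaps + (n + m - gaps) / 2
    int n = (int)a.size();
    long columns = res.gaps + (n + m - res.gaps) / 2;
    long num = res.matches, den = std::max(1L, columns);
    int r = m > 0 ? (m - k) % m : 0;
    bool take;
    long cmp = num * best_den - best_num * den; // ident - best_ident, sign
    if (best_num < 0) take = true;
    else if (cmp > 0) take = true;
    else if (cmp == 0 && r < best_r) take = true;
    else take = false;
    if (take) {
      best_num = num; best_den = den; best_r = r; best_k = k; best_rot = rot;
    }
  }
  // redo fill + traceback for the winning rotation
  Cell res;
  nw_fill(a, best_rot, match, mismatch, gap, prev, cur, tb, res);
  std::string aa, ba;
  nw_traceback(a, best_rot, tb, aa, ba);
  return List::create(_["score"] = res.score, _["matches"] = res.matches,
                      _["gap_columns"] = res.gaps, _["columns"] = (int)aa.size(),
                      _["rotation_offset"] = best_r, _["rotation_k"] = best_k,
                      _["a_aln"] = aa, _["b_aln"] = ba);
}

// Smith-Waterman local alignment with the same lexicographic objective.
// Returns 1-based coordinates of the best local alignment, or score 0 when
// nothing aligns with positive score.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int)a.size(), m = (int)b.size();
  if ((double)(n + 1) * (double)(m + 1) > 6e7)
    stop("sequences too long for local alignment");
  std::vector<Cell> prev(m + 1, Cell{0, 0, 0}), cur(m + 1, Cell{0, 0, 0});
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), STOP);
  Cell best{0, 0, 0};
  int bi = 0, bj = 0;
  const Cell zero{0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    cur[0] = zero;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj_ = b[j - 1];
      const bool eq = (ai == bj_) && (ai == 'A' || ai == 'C' || ai == 'G' || ai == 'T');
      Cell d{prev[j - 1].score + (eq ? match : mismatch),
             prev[j - 1].matches + (eq ? 1 : 0), prev[j - 1].gaps};
      Cell u{prev[j].score + gap, prev[j].matches, prev[j].gaps + 1};
      Cell l{cur[j - 1].score + gap, cur[j - 1].matches, cur[j - 1].gaps + 1};
      uint8_t mv = DIAG; Cell bc = d;
      if (better(u, bc)) { bc = u; mv = UP; }
      if (better(l, bc)) { bc = l; mv = LEFT; }
      if (better(zero, bc)) { bc = zero; mv = STOP; }
      cur[j] = bc;
      tb[(size_t)i * (m + 1) + j] = mv;
      if (better(bc, best)) { best = bc; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  std::string aa, ba;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t mv = tb[(size_t)i * (m + 1) + j];
    if (mv == STOP) break;
    if (mv == DIAG) { aa.push_back(a[i - 1]); ba.push_back(b[j - 1]); --i; --j; }
    else if (mv == UP) { aa.push_back(a[i - 1]); ba.push_back('-'); --i; }
    else { aa.push_back('-'); ba.push_back(b[j - 1]); --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ba.begin(), ba.end());
  return List::create(_["score"] = best.score, _["matches"] = best.matches,
                      _["gap_columns"] = best.gaps, _["columns"] = (int)aa.size(),
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["a_aln"] = aa, _["b_aln"] = ba);
}

// Gapless circular comparison: best rotation x (caller-supplied strand) by
// match count; ties by smallest reported offset r = (m - k) mod m.
// Requires equal lengths. Returns match count, rotation and the rotated b.
// [[Rcpp::export]]
List circular_gapless_cpp(std::string a, std::string b) {
  const int n = (int)a.size();
  if ((int)b.size() != n) stop("gapless circular comparison needs equal lengths");
  int best_m = -1, best_r = 0, best_k = 0;
  for (int k = 0; k < n; ++k) {
    int mm = 0;
    for (int i = 0; i < n; ++i) {
      const char ai = a[i];
      const char bi = b[(i + k) % n];
      if (ai == bi && (ai == 'A' || ai == 'C' || ai == 'G' || ai == 'T')) ++mm;
    }
    int r = (n - k) % n;
    if (mm > best_m || (mm == best_m && r < best_r)) {
      best_m = mm; best_r = r; best_k = k;
    }
  }
  std::string rot = b.substr(best_k) + b.substr(0, best_k);
  return List::create(_["matches"] = best_m, _["rotation_offset"] = best_r,
                      _["b_rot"] = rot);
}
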