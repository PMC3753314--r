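#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Deterministic overlap-style global alignment: match +1, mismatch 0,
// gap -1, terminal gaps free. Score-maximizing with a neutral mismatch,
// so full overlap of two same-locus amplicons is always preferred over
// staggered terminal gaps, even for highly divergent pairs. Used for all
// pairwise comparisons and as the backbone of the three-way alignment.
// Tie-breaking: match > mismatch > gap-in-shorter-sequence; homopolymer
// gaps are left-shifted afterwards so indel placement is canonical.

static const int MATCH = 1, MISMATCH = 0, GAP = -1;

static inline int sc(char a, char b) { return a == b ? MATCH : MISMATCH; }

// shift gaps leftward through homopolymer runs of the opposite row; score
// preserving because the opposite characters are identical
static void left_shift_gaps(std::string &g, const std::string &other) {
  bool moved = true;
  while (moved) {
    moved = false;
    for (size_t k = 1; k < g.size(); ++k) {
      if (g[k] == '-' && g[k - 1] != '-' && other[k] != '-' &&
          other[k - 1] == other[k] && g[k - 1] == other[k]) {
        std::swap(g[k - 1], g[k]);
        moved = true;
      }
    }
  }
}

// best end cell on the last row/column (free trailing gaps): highest
// score, ties resolved towards covering more of both sequences, then
// towards the bottom-right corner
static void best_end(const std::vector<std::vector<int> > &S, int n, int m,
                     int &ei, int &ej) {
  ei = n; ej = m;
  int best = S[n][m];
  for (int j = m - 1; j >= 0; --j)
    if (S[n][j] > best) { best = S[n][j]; ei = n; ej = j; }
  for (int i = n - 1; i >= 0; --i)
    if (S[i][m] > best) { best = S[i][m]; ei = i; ej = m; }
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1, 0));
  // free leading gaps: first row/col zero
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = S[i - 1][j - 1] + sc(a[i - 1], b[j - 1]);
      int u = S[i - 1][j] + GAP;
      int l = S[i][j - 1] + GAP;
      S[i][j] = std::max(d, std::max(u, l));
    }
  }
  int ei, ej;
  best_end(S, n, m, ei, ej);

  std::string ra, rb;
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

  bool prefer_up = n >= m;  // the gap goes into the shorter sequence's row
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    int here = S[i][j];
    int d = S[i - 1][j - 1] + sc(a[i - 1], b[j - 1]);
    int u = S[i - 1][j] + GAP;
    int l = S[i][j - 1] + GAP;
    if (d == here) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (u == here && (prefer_up || l != here)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  left_shift_gaps(ra, rb);
  left_shift_gaps(rb, ra);
  return List::create(_["a"] = ra, _["b"] = rb);
}

// Column statistics of an aligned pair, excluding terminal-gap columns:
// first/last columns where both rows carry a base bound the scored region.
// [[Rcpp::export(name = ".pair_stats_cpp")]]
List pair_stats_cpp(std::string ra, std::string rb) {
  const int L = ra.size();
  int first = -1, last = -1;
  for (int k = 0; k < L; ++k)
    if (ra[k] != '-' && rb[k] != '-') { if (first < 0) first = k; last = k; }
  int nsub = 0, nindel = 0, ncols = 0;
  if (first >= 0) {
    ncols = last - first + 1;
    for (int k = first; k <= last; ++k) {
      if (ra[k] == '-' || rb[k] == '-') ++nindel;
      else if (ra[k] != rb[k]) ++nsub;
    }
  }
  double dist = ncols > 0 ? (double)(nsub + nindel) / ncols : 1.0;
  return List::create(_["n_sub"] = nsub, _["n_indel"] = nindel,
                      _["n_cols"] = ncols, _["dist"] = dist);
}

// Align a daughter sequence to the two-row profile of an aligned parent
// pair, same scoring. Consuming a profile column with a daughter base
// scores +1 when the base matches either parent's character, else -1; a
// daughter gap over a column where a parent also has a gap scores +1
// (the daughter mirrors that parent's indel), over a both-base column -1;
// inserting a daughter base opens an all-gap parent column at -1.
// Terminal gaps free on both ends.
// [[Rcpp::export(name = ".align_daughter_cpp")]]
List align_daughter_cpp(std::string p1, std::string p2, std::string d) {
  const int n = d.size(), m = p1.size();  // p1, p2 same length
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cs = (d[i - 1] == p1[j - 1] || d[i - 1] == p2[j - 1]) ? MATCH
                                                                : MISMATCH;
      int cg = (p1[j - 1] == '-' || p2[j - 1] == '-') ? MATCH : GAP;
      int diag = S[i - 1][j - 1] + cs;
      int left = S[i][j - 1] + cg;   // daughter gap over column j-1
      int up = S[i - 1][j] + GAP;    // insertion: new all-gap parent column
      S[i][j] = std::max(diag, std::max(left, up));
    }
  }
  int ei, ej;
  best_end(S, n, m, ei, ej);

  std::string r1, r2, rd;
  for (int j = m; j > ej; --j) {
    r1.push_back(p1[j - 1]); r2.push_back(p2[j - 1]); rd.push_back('-');
  }
  for (int i = n; i > ei; --i) {
    r1.push_back('-'); r2.push_back('-'); rd.push_back(d[i - 1]);
  }
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    int here = S[i][j];
    int cs = (d[i - 1] == p1[j - 1] || d[i - 1] == p2[j - 1]) ? MATCH
                                                              : MISMATCH;
    int cg = (p1[j - 1] == '-' || p2[j - 1] == '-') ? MATCH : GAP;
    if (S[i - 1][j - 1] + cs == here) {
      r1.push_back(p1[j - 1]); r2.push_back(p2[j - 1]); rd.push_back(d[i - 1]);
      --i; --j;
    } else if (S[i][j - 1] + cg == here) {
      r1.push_back(p1[j - 1]); r2.push_back(p2[j - 1]); rd.push_back('-');
      --j;
    } else {
      r1.push_back('-'); r2.push_back('-'); rd.push_back(d[i - 1]);
      --i;
    }
  }
  while (i > 0) { r1.push_back('-'); r2.push_back('-'); rd.push_back(d[i - 1]); --i; }
  while (j > 0) { r1.push_back(p1[j - 1]); r2.push_back(p2[j - 1]); rd.push_back('-'); --j; }
  std::reverse(r1.begin(), r1.end());
  std::reverse(r2.begin(), r2.end());
  std::reverse(rd.begin(), rd.end());
  return List::create(_["p1"] = r1, _["p2"] = r2, _["d"] = rd);
}
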