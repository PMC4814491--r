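#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Gotoh local alignment (affine gaps). A gap of length L costs
// gap_open + L * gap_extend, both stored as non-positive numbers.
// Tie-breaking among equal-scoring maximal alignments: smallest query
// start, then smallest subject start; within a traceback the move
// preference is diagonal > gap-in-subject (up) > gap-in-query (left).

namespace {

const double NEG_INF = -1e18;

struct Cell {
  int i, j;
};

struct Traceback {
  double score;
  int q_start, q_end, s_start, s_end;
  std::string a_aln, b_aln;
};

// state: 0 = H (match/mismatch), 1 = E (gap in a, consumes b), 2 = F (gap in b, consumes a)
Traceback trace_from(int ei, int ej,
                     const std::vector<double>& H,
                     const std::vector<double>& E,
                     const std::vector<double>& F,
                     const std::string& a, const std::string& b,
                     const std::vector<double>& scr,
                     const std::vector<int>& idx,
                     int nlet, double go, double ge) {
  int n = (int)b.size();
  int W = n + 1;
  std::string aa, bb;
  int i = ei, j = ej, state = 0;
  Traceback tb;
  tb.score = H[(size_t)ei * W + ej];
  tb.q_end = ei;
  tb.s_end = ej;
  while (true) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (H[c] == 0.0) break;
      double diag = H[c - W - 1] + scr[(size_t)idx[(unsigned char)a[i - 1]] * nlet +
                                       idx[(unsigned char)b[j - 1]]];
      if (i > 0 && j > 0 && H[c] == diag) {
        aa.push_back(a[i - 1]);
        bb.push_back(b[j - 1]);
        --i; --j;
      } else if (H[c] == F[c]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) {  // gap in b, consumes a[i]
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      double open_from = H[c - W] + go + ge;
      --i;
      if (F[c] == open_from) state = 0; else state = 2;
    } else {  // state == 1: gap in a, consumes b[j]
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      double open_from = H[c - 1] + go + ge;
      --j;
      if (E[c] == open_from) state = 0; else state = 1;
    }
  }
  tb.q_start = i + 1;
  tb.s_start = j + 1;
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  tb.a_aln = aa;
  tb.b_aln = bb;
  return tb;
}

}  // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  NumericMatrix submat, CharacterVector letters,
                  double gap_open, double gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  int nlet = letters.size();
  if (submat.nrow() != nlet || submat.ncol() != nlet)
    stop("substitution matrix dimensions do not match the alphabet");

  std::vector<int> idx(256, -1);
  for (int k = 0; k < nlet; ++k) {
    std::string l = as<std::string>(letters[k]);
    if (l.size() != 1) stop("alphabet letters must be single characters");
    idx[(unsigned char)l[0]] = k;
  }
  for (int i = 0; i < m; ++i)
    if (idx[(unsigned char)a[i]] < 0)
      stop("query contains letter '%s' not covered by the scoring scheme",
           std::string(1, a[i]).c_str());
  for (int j = 0; j < n; ++j)
    if (idx[(unsigned char)b[j]] < 0)
      stop("subject contains letter '%s' not covered by the scoring scheme",
           std::string(1, b[j]).c_str());

  // flattened row-major score lookup
  std::vector<double> scr((size_t)nlet * nlet);
  for (int r = 0; r < nlet; ++r)
    for (int c = 0; c < nlet; ++c)
      scr[(size_t)r * nlet + c] = submat(r, c);

  int W = n + 1;
  std::vector<double> H((size_t)(m + 1) * W, 0.0);
  std::vector<double> E((size_t)(m + 1) * W, NEG_INF);
  std::vector<double> F((size_t)(m + 1) * W, NEG_INF);

  double best = 0.0;
  std::vector<Cell> best_cells;
  for (int i = 1; i <= m; ++i) {
    int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t)i * W + j;
      double e = std::max(H[c - 1] + gap_open + gap_extend, E[c - 1] + gap_extend);
      double f = std::max(H[c - W] + gap_open + gap_extend, F[c - W] + gap_extend);
      double h = H[c - W - 1] + scr[(size_t)ai * nlet + idx[(unsigned char)b[j - 1]]];
      h = std::max(std::max(h, std::max(e, f)), 0.0);
      E[c] = e; F[c] = f; H[c] = h;
      if (h > best) {
        best = h;
        best_cells.clear();
        best_cells.push_back({i, j});
      } else if (h == best && best > 0.0) {
        best_cells.push_back({i, j});
      }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aligned_query"] = "",
                        _["aligned_subject"] = "");
  }

  bool have = false;
  Traceback chosen;
  for (size_t k = 0; k < best_cells.size(); ++k) {
    Traceback tb = trace_from(best_cells[k].i, best_cells[k].j, H, E, F, a, b,
                              scr, idx, nlet, gap_open, gap_extend);
    if (!have || tb.q_start < chosen.q_start ||
        (tb.q_start == chosen.q_start && tb.s_start < chosen.s_start)) {
      chosen = tb;
      have = true;
    }
  }

  return List::create(_["score"] = chosen.score, _["q_start"] = chosen.q_start,
                      _["q_end"] = chosen.q_end, _["s_start"] = chosen.s_start,
                      _["s_end"] = chosen.s_end,
                      _["aligned_query"] = chosen.a_aln,
                      _["aligned_subject"] = chosen.b_aln);
}

// score-only batched variant: best local score for each (a[i], b[i]) pair,
// two rolling rows, no traceback. Used to pre-screen seeded windows.
// [[Rcpp::export]]
NumericVector sw_score_batch(CharacterVector a, CharacterVector b,
                             NumericMatrix submat, CharacterVector letters,
                             double gap_open, double gap_extend) {
  int np = a.size();
  if (b.size() != np) stop("mismatched batch lengths");
  int nlet = letters.size();
  std::vector<int> idx(256, -1);
  for (int k = 0; k < nlet; ++k) {
    std::string l = as<std::string>(letters[k]);
    idx[(unsigned char)l[0]] = k;
  }
  std::vector<double> scr((size_t)nlet * nlet);
  for (int r = 0; r < nlet; ++r)
    for (int c = 0; c < nlet; ++c)
      scr[(size_t)r * nlet + c] = submat(r, c);

  NumericVector out(np);
  std::vector<double> Hprev, Hcur, Eprev, Ecur, Fprev, Fcur;
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]);
    std::string sb = as<std::string>(b[p]);
    int m = (int)sa.size(), n = (int)sb.size();
    for (int i = 0; i < m; ++i)
      if (idx[(unsigned char)sa[i]] < 0)
        stop("query contains letter '%s' not covered by the scoring scheme",
             std::string(1, sa[i]).c_str());
    for (int j = 0; j < n; ++j)
      if (idx[(unsigned char)sb[j]] < 0)
        stop("subject contains letter '%s' not covered by the scoring scheme",
             std::string(1, sb[j]).c_str());
    Hprev.assign(n + 1, 0.0);
    Hcur.assign(n + 1, 0.0);
    Eprev.assign(n + 1, NEG_INF);
    Ecur.assign(n + 1, NEG_INF);
    Fprev.assign(n + 1, NEG_INF);
    Fcur.assign(n + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      int ai = idx[(unsigned char)sa[i - 1]];
      Hcur[0] = 0.0;
      Ecur[0] = NEG_INF;
      Fcur[0] = NEG_INF;
      for (int j = 1; j <= n; ++j) {
        double e = std::max(Hcur[j - 1] + gap_open + gap_extend,
                            Ecur[j - 1] + gap_extend);
        double f = std::max(Hprev[j] + gap_open + gap_extend,
                            Fprev[j] + gap_extend);
        double h = Hprev[j - 1] + scr[(size_t)ai * nlet +
                                      idx[(unsigned char)sb[j - 1]]];
        h = std::max(std::max(h, std::max(e, f)), 0.0);
        Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Eprev, Ecur);
      std::swap(Fprev, Fcur);
    }
    out[p] = best;
  }
  return out;
}
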