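// Exact Smith-Waterman local alignment with affine gaps.
//
// Scoring: a gap of length g costs gap_open + (g-1) * gap_extend, both
// penalties negative (gap_open is the cost of the first gap residue).
// Sequences arrive as 1-based indices into the substitution matrix rows.
//
// Tie-breaking: among all maximal-score end cells, each is traced back
// (within a traceback: diagonal preferred, then subject-gap, then
// query-gap; gap closure preferred over extension) and the alignment with
// the lexicographically smallest (q_start, s_start, n_columns, q_end,
// s_end) is returned, so equal-scoring results are deterministic.

#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct Aln {
  int score = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  int n_id = 0, n_cols = 0;
  std::vector<int> q_aln, s_aln;  // matrix indices (1-based), 0 = gap
};

struct DP {
  int n, m;
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
  std::vector<int> sidx;
  int best;
  std::vector<std::pair<int, int> > best_cells;

  inline int idx(int i, int j) const { return i * (m + 1) + j; }

  void fill(const int* q, int n_, const int* s, int m_, const IntegerMatrix& mat,
            int open, int ext) {
    n = n_; m = m_;
    size_t sz = (size_t)(n + 1) * (m + 1);
    if (H.size() < sz) {
      H.resize(sz); E.resize(sz); F.resize(sz);
      tbH.resize(sz); tbE.resize(sz); tbF.resize(sz);
    }
    // interior cells are written before they are read, so only the borders
    // (row 0 and column 0) need initialising between fills
    for (int j = 0; j <= m; ++j) {
      H[j] = 0; E[j] = NEG; F[j] = NEG; tbH[j] = 0;
    }
    for (int i = 1; i <= n; ++i) {
      int k = idx(i, 0);
      H[k] = 0; E[k] = NEG; F[k] = NEG; tbH[k] = 0;
    }
    best = 0;
    best_cells.clear();
    const int* matp = &mat(0, 0);
    int nrow = mat.nrow();
    if ((int)sidx.size() < m) sidx.resize(m);
    for (int j = 0; j < m; ++j) sidx[j] = (s[j] - 1) * nrow;
    for (int i = 1; i <= n; ++i) {
      const int* mrow = matp + (size_t)(q[i - 1] - 1);
      int* Hc = &H[idx(i, 0)];       const int* Hp = &H[idx(i - 1, 0)];
      int* Ec = &E[idx(i, 0)];
      int* Fc = &F[idx(i, 0)];       const int* Fp = &F[idx(i - 1, 0)];
      unsigned char* tHc = &tbH[idx(i, 0)];
      unsigned char* tEc = &tbE[idx(i, 0)];
      unsigned char* tFc = &tbF[idx(i, 0)];
      int hdiag = 0;                 // H[i-1][0]
      int hleft = 0, eleft = NEG;    // H[i][j-1], E[i][j-1]
      for (int j = 1; j <= m; ++j) {
        // E: gap in query (consumes subject); F: gap in subject
        int e_open = hleft + open, e_ext = eleft + ext;
        bool eo = e_open >= e_ext;
        int e = eo ? e_open : e_ext;
        int f_open = Hp[j] + open, f_ext = Fp[j] + ext;
        bool fo = f_open >= f_ext;
        int f = fo ? f_open : f_ext;
        int diag = hdiag + mrow[sidx[j - 1]];
        // preference on ties: diagonal > E > F > zero-stop
        int h = diag; unsigned char tb = 1;
        if (e > h) { h = e; tb = 2; }
        if (f > h) { h = f; tb = 3; }
        if (h <= 0) { h = 0; tb = 0; }
        Ec[j] = e; tEc[j] = eo;
        Fc[j] = f; tFc[j] = fo;
        Hc[j] = h; tHc[j] = tb;
        hdiag = Hp[j]; hleft = h; eleft = e;
        if (h >= best && h > 0) {
          if (h > best) { best = h; best_cells.clear(); }
          best_cells.push_back(std::make_pair(i, j));
        }
      }
    }
  }

  Aln traceback(int i, int j, const int* q, const int* s, int x_code) const {
    Aln a;
    a.score = H[idx(i, j)];
    a.q_end = i; a.s_end = j;
    std::vector<int> qa, sa;
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (true) {
      int k = idx(i, j);
      if (state == 0) {
        unsigned char tb = tbH[k];
        if (tb == 0) break;
        if (tb == 1) {
          qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
          --i; --j;
        } else if (tb == 2) state = 1;
        else state = 2;
      } else if (state == 1) {   // gap in query, consume subject
        qa.push_back(0); sa.push_back(s[j - 1]);
        unsigned char open = tbE[k];
        --j;
        if (open) state = 0;
      } else {                   // gap in subject, consume query
        qa.push_back(q[i - 1]); sa.push_back(0);
        unsigned char open = tbF[k];
        --i;
        if (open) state = 0;
      }
    }
    a.q_start = i + 1; a.s_start = j + 1;
    a.n_cols = (int)qa.size();
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    for (int c = 0; c < a.n_cols; ++c)
      if (qa[c] != 0 && qa[c] == sa[c] && qa[c] != x_code) ++a.n_id;
    a.q_aln = qa; a.s_aln = sa;
    return a;
  }

  Aln best_alignment(const int* q, const int* s, int x_code) const {
    Aln chosen;
    if (best <= 0) return chosen;  // empty alignment, score 0
    bool have = false;
    for (size_t c = 0; c < best_cells.size(); ++c) {
      Aln a = traceback(best_cells[c].first, best_cells[c].second, q, s, x_code);
      if (!have) { chosen = a; have = true; continue; }
      long ka[5] = { a.q_start, a.s_start, a.n_cols, a.q_end, a.s_end };
      long kc[5] = { chosen.q_start, chosen.s_start, chosen.n_cols,
                     chosen.q_end, chosen.s_end };
      for (int t = 0; t < 5; ++t) {
        if (ka[t] < kc[t]) { chosen = a; break; }
        if (ka[t] > kc[t]) break;
      }
    }
    return chosen;
  }
};

List aln_to_list(const Aln& a) {
  return List::create(
    _["score"] = a.score,
    _["q_start"] = a.q_start, _["q_end"] = a.q_end,
    _["s_start"] = a.s_start, _["s_end"] = a.s_end,
    _["n_identities"] = a.n_id, _["n_columns"] = a.n_cols,
    _["q_aln"] = IntegerVector(a.q_aln.begin(), a.q_aln.end()),
    _["s_aln"] = IntegerVector(a.s_aln.begin(), a.s_aln.end()));
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  int gap_open, int gap_extend, int x_code) {
  DP dp;
  dp.fill(q.begin(), q.size(), s.begin(), s.size(), mat, gap_open, gap_extend);
  return aln_to_list(dp.best_alignment(q.begin(), s.begin(), x_code));
}

// Batched sliding-window scan: aligns every (window, subject) pair and
// returns per-pair score/identity plus full alignment detail for pairs
// meeting the hit rule (identity_fraction > min_ident, n_columns >=
// window length).
// [[Rcpp::export(name = ".sw_window_scan_cpp")]]
List sw_window_scan_cpp(IntegerVector q, List subjects, int width,
                        IntegerMatrix mat, int gap_open, int gap_extend,
                        int x_code, double min_ident) {
  int L = q.size();
  int n_win = L >= width ? L - width + 1 : 1;
  int n_sub = subjects.size();
  IntegerVector win_start(n_win), win_len(n_win);
  NumericMatrix ident(n_win, n_sub);
  IntegerMatrix cols(n_win, n_sub), score(n_win, n_sub);
  List hits;
  DP dp;
  std::vector<std::vector<int> > subj(n_sub);
  for (int b = 0; b < n_sub; ++b) {
    IntegerVector sv = subjects[b];
    subj[b].assign(sv.begin(), sv.end());
  }
  for (int w = 0; w < n_win; ++w) {
    int start = (L >= width) ? w : 0;
    int len = (L >= width) ? width : L;
    win_start[w] = start + 1;
    win_len[w] = len;
    const int* wq = q.begin() + start;
    for (int b = 0; b < n_sub; ++b) {
      dp.fill(wq, len, subj[b].data(), (int)subj[b].size(), mat,
              gap_open, gap_extend);
      Aln a = dp.best_alignment(wq, subj[b].data(), x_code);
      double fr = a.n_cols > 0 ? (double)a.n_id / a.n_cols : 0.0;
      ident(w, b) = fr;
      cols(w, b) = a.n_cols;
      score(w, b) = a.score;
      if (a.n_cols >= len && fr > min_ident) {
        List h = aln_to_list(a);
        h["window_index"] = w + 1;
        h["subject_index"] = b + 1;
        hits.push_back(h);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["window_start"] = win_start, _["window_len"] = win_len,
    _["identity"] = ident, _["n_columns"] = cols, _["score"] = score,
    _["hits"] = hits);
}
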