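#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman over amino-acid strings.
//
// Gap of length L costs gap_open + L * gap_extend (BLAST convention).
// '*' (stop codon) scores a large negative value against everything so a
// local alignment can never cross a stop. Characters absent from the
// substitution matrix fall back to the matrix's 'X' row.
//
// Traceback tie-break: diagonal > up (gap in subject) > left (gap in query),
// applied both when choosing the best cell state and during traceback, so
// coordinates are deterministic. The best cell itself is the first maximum
// in row-major order.

static const int NEG = -100000000;
static const int STOP_PEN = -1000000;

struct AlnResult {
  int score;
  int q_start, q_end, s_start, s_end; // 1-based inclusive; 0 if empty
  int n_ident, aln_len;
};

// Flattened scoring table over K+1 codes; code K is '*'.
struct ScoreTable {
  int K;                  // number of matrix letters
  std::vector<int> tab;   // (K+1) x (K+1)
  int code[256];          // char -> code (unknown -> X)
  std::vector<char> letter; // code -> char (for identity checks)
};

static ScoreTable make_table(const IntegerMatrix &mat,
                             const CharacterVector &letters) {
  ScoreTable st;
  st.K = letters.size();
  int x_idx = -1;
  st.letter.resize(st.K + 1);
  for (int i = 0; i < st.K; i++) {
    const char *s = CHAR(STRING_ELT(letters, i));
    st.letter[i] = s[0];
    if (s[0] == 'X') x_idx = i;
  }
  st.letter[st.K] = '*';
  if (x_idx < 0) x_idx = 0;
  for (int c = 0; c < 256; c++) st.code[c] = x_idx;
  for (int i = 0; i < st.K; i++)
    st.code[(unsigned char)st.letter[i]] = i;
  st.code[(unsigned char)'*'] = st.K;
  st.tab.assign((st.K + 1) * (st.K + 1), STOP_PEN);
  for (int i = 0; i < st.K; i++)
    for (int j = 0; j < st.K; j++)
      st.tab[i * (st.K + 1) + j] = mat(i, j);
  return st;
}

static std::vector<int> encode(const char *s, int n, const ScoreTable &st) {
  std::vector<int> v(n);
  for (int i = 0; i < n; i++) v[i] = st.code[(unsigned char)s[i]];
  return v;
}

static AlnResult sw_core(const std::vector<int> &q, const std::vector<int> &s,
                         const ScoreTable &st, int gap_open, int gap_extend,
                         bool traceback,
                         std::vector<int> &H, std::vector<int> &E,
                         std::vector<int> &F) {
  AlnResult res = {0, 0, 0, 0, 0, 0, 0};
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return res;
  const int W = m + 1;
  H.assign((n + 1) * W, 0);
  E.assign((n + 1) * W, NEG);
  F.assign((n + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  const int go = gap_open + gap_extend;
  const int K1 = st.K + 1;
  const int *tab = st.tab.data();
  for (int i = 1; i <= n; i++) {
    const int *row = tab + (size_t)q[i - 1] * K1;
    int *Hi = H.data() + (size_t)i * W, *Hp = H.data() + (size_t)(i - 1) * W;
    int *Ei = E.data() + (size_t)i * W, *Ep = E.data() + (size_t)(i - 1) * W;
    int *Fi = F.data() + (size_t)i * W;
    for (int j = 1; j <= m; j++) {
      int e = Hp[j] - go;
      if (Ep[j] - gap_extend > e) e = Ep[j] - gap_extend;
      int f = Hi[j - 1] - go;
      if (Fi[j - 1] - gap_extend > f) f = Fi[j - 1] - gap_extend;
      int h = Hp[j - 1] + row[s[j - 1]]; // diagonal preferred on ties
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hi[j] = h; Ei[j] = e; Fi[j] = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best == 0 || !traceback) return res;

  int i = bi, j = bj, state = 1;
  res.q_end = bi; res.s_end = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * W + j;
    if (state == 1) {
      int h = H[idx];
      if (h == 0) break;
      int d = H[idx - W - 1] + st.tab[(size_t)q[i - 1] * K1 + s[j - 1]];
      if (h == d) {
        res.aln_len++;
        if (q[i - 1] == s[j - 1] && st.letter[q[i - 1]] != 'X')
          res.n_ident++;
        res.q_start = i; res.s_start = j;
        i--; j--;
        if (H[(size_t)i * W + j] == 0) break;
      } else if (h == E[idx]) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) { // vertical gap run (consumes query)
      res.aln_len++;
      int from_h = H[idx - W] - gap_open - gap_extend;
      res.q_start = i;
      i--;
      if (E[idx] == from_h) state = 1;
    } else { // horizontal gap run (consumes subject)
      res.aln_len++;
      int from_h = H[idx - 1] - gap_open - gap_extend;
      res.s_start = j;
      j--;
      if (F[idx] == from_h) state = 1;
    }
  }
  return res;
}

// [[Rcpp::export]]
List sw_align(std::string query, std::string subject, IntegerMatrix mat,
              CharacterVector letters, int gap_open, int gap_extend) {
  ScoreTable st = make_table(mat, letters);
  std::vector<int> q = encode(query.c_str(), query.size(), st);
  std::vector<int> s = encode(subject.c_str(), subject.size(), st);
  std::vector<int> H, E, F;
  AlnResult r = sw_core(q, s, st, gap_open, gap_extend, true, H, E, F);
  return List::create(
      _["score"] = r.score, _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["s_start"] = r.s_start, _["s_end"] = r.s_end,
      _["n_ident"] = r.n_ident, _["aln_len"] = r.aln_len);
}

// Cross-product search: every query against every subject, keeping pairs
// whose raw score reaches min_raw. Queries are typically six-frame
// translations; index bookkeeping stays in R.
// [[Rcpp::export]]
List sw_search(CharacterVector queries, CharacterVector subjects,
               IntegerMatrix mat, CharacterVector letters, int gap_open,
               int gap_extend, int min_raw) {
  ScoreTable st = make_table(mat, letters);
  int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int> > subs(ns);
  for (int j = 0; j < ns; j++) {
    const char *p = CHAR(STRING_ELT(subjects, j));
    subs[j] = encode(p, std::strlen(p), st);
  }
  std::vector<int> qi, si, score, qs, qe, ss, se, nid, alen;
  std::vector<int> H, E, F;
  for (int i = 0; i < nq; i++) {
    const char *p = CHAR(STRING_ELT(queries, i));
    std::vector<int> q = encode(p, std::strlen(p), st);
    for (int j = 0; j < ns; j++) {
      AlnResult r = sw_core(q, subs[j], st, gap_open, gap_extend, false,
                            H, E, F);
      if (r.score >= min_raw) {
        r = sw_core(q, subs[j], st, gap_open, gap_extend, true, H, E, F);
        qi.push_back(i + 1); si.push_back(j + 1); score.push_back(r.score);
        qs.push_back(r.q_start); qe.push_back(r.q_end);
        ss.push_back(r.s_start); se.push_back(r.s_end);
        nid.push_back(r.n_ident); alen.push_back(r.aln_len);
      }
    }
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["query_idx"] = wrap(qi), _["subject_idx"] = wrap(si),
      _["raw_score"] = wrap(score), _["q_start"] = wrap(qs),
      _["q_end"] = wrap(qe), _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
      _["n_ident"] = wrap(nid), _["aln_len"] = wrap(alen));
}
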