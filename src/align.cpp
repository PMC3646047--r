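#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Sequences arrive as 0-based integer
// codes into the scoring matrix alphabet. Gap of length k costs open + k*ext.
// Traceback tie-break is fixed: diagonal, then up (consume a), then left.

static const int NEG = -1000000000 / 4; // safe -inf (no overflow on + scores)

// [[Rcpp::export]]
List cpp_align(IntegerVector a, IntegerVector b, IntegerMatrix submat,
               int gap_open, int gap_ext, bool local) {
  const int m = a.size(), n = b.size();
  const int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  // H(i,j) = max of three states
  auto H = [&](int i, int j) {
    int h = std::max(M[i * W + j], std::max(X[i * W + j], Y[i * W + j]));
    return h;
  };

  M[0] = 0;
  if (!local) {
    for (int i = 1; i <= m; ++i) X[i * W] = -(gap_open + i * gap_ext);
    for (int j = 1; j <= n; ++j) Y[j] = -(gap_open + j * gap_ext);
  } else {
    for (int i = 1; i <= m; ++i) M[i * W] = 0;
    for (int j = 1; j <= n; ++j) M[j] = 0;
  }

  int best = NEG, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int s = submat(ai, b[j - 1]);
      int diag = H(i - 1, j - 1);
      int mm = (diag <= NEG / 2) ? NEG : diag + s;
      if (local && mm < 0) mm = 0;
      M[i * W + j] = mm;
      int hup = H(i - 1, j);
      int x = std::max(X[(i - 1) * W + j] - gap_ext,
                       (hup <= NEG / 2) ? NEG : hup - gap_open - gap_ext);
      X[i * W + j] = x;
      int hle = H(i, j - 1);
      int y = std::max(Y[i * W + j - 1] - gap_ext,
                       (hle <= NEG / 2) ? NEG : hle - gap_open - gap_ext);
      Y[i * W + j] = y;
      if (local) {
        int h = std::max(mm, std::max(x, y));
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
  }

  int score, ei, ej;
  if (local) {
    if (best <= 0) { // empty local alignment
      return List::create(_["score"] = 0,
                          _["a_aln"] = IntegerVector(0), _["b_aln"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = -1,
                          _["b_start"] = 0, _["b_end"] = -1);
    }
    score = best; ei = bi; ej = bj;
  } else {
    score = H(m, n); ei = m; ej = n;
  }

  // traceback: prefer diagonal (M), then up (X), then left (Y)
  std::vector<int> ra, rb; // residue codes, -1 for gap
  int i = ei, j = ej;
  // state: 0=M,1=X,2=Y; pick state achieving H at end
  int st;
  {
    int h = H(i, j);
    if (M[i * W + j] == h) st = 0; else if (X[i * W + j] == h) st = 1; else st = 2;
  }
  while (true) {
    if (local) {
      if (H(i, j) <= 0 || (i == 0 && j == 0)) break;
      if (st == 0 && M[i * W + j] == 0) break;
    } else {
      if (i == 0 && j == 0) break;
    }
    if (st == 0) { // came via diagonal
      if (i == 0 || j == 0) { // global boundary: must be gap states
        if (i > 0) st = 1; else st = 2;
        continue;
      }
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      int h = H(i, j);
      if (local && h <= 0) break;
      if (M[i * W + j] == h) st = 0; else if (X[i * W + j] == h) st = 1; else st = 2;
    } else if (st == 1) { // gap in b, consume a
      ra.push_back(a[i - 1]); rb.push_back(-1);
      // did X extend or open?
      int opened = (i >= 1) ? H(i - 1, j) - gap_open - gap_ext : NEG;
      int extended = (i >= 1) ? X[(i - 1) * W + j] - gap_ext : NEG;
      --i;
      if (X[(i + 1) * W + j] == extended && extended >= opened) st = 1;
      else {
        int h = H(i, j);
        if (M[i * W + j] == h) st = 0; else if (X[i * W + j] == h) st = 1; else st = 2;
      }
    } else { // gap in a, consume b
      ra.push_back(-1); rb.push_back(b[j - 1]);
      int opened = (j >= 1) ? H(i, j - 1) - gap_open - gap_ext : NEG;
      int extended = (j >= 1) ? Y[i * W + j - 1] - gap_ext : NEG;
      --j;
      if (Y[i * W + j + 1] == extended && extended >= opened) st = 2;
      else {
        int h = H(i, j);
        if (M[i * W + j] == h) st = 0; else if (X[i * W + j] == h) st = 1; else st = 2;
      }
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = IntegerVector(ra.begin(), ra.end()),
                      _["b_aln"] = IntegerVector(rb.begin(), rb.end()),
                      _["a_start"] = i + 1, _["a_end"] = ei,
                      _["b_start"] = j + 1, _["b_end"] = ej);
}

// Batch Smith-Waterman, score only: many short queries against one subject.
// Lane-parallel int16 layout (16 queries simultaneously) so the inner loop
// vectorizes; used by the metagenome screen where ~10^6 translated frames
// are scored against a reference panel. Queries and subject arrive as
// strings and are byte-mapped to alphabet indices here; characters outside
// the alphabet map to `default_idx` (e.g. X) or raise an error if that is
// negative. Scores must stay below 32767 (true for protein scores at these
// lengths; the caller guards).

// [[Rcpp::export]]
IntegerVector cpp_sw_scoremax_batch(CharacterVector queries, std::string db,
                                    IntegerMatrix submat,
                                    std::string alphabet,
                                    int gap_open, int gap_ext,
                                    int default_idx) {
  typedef int16_t T;
  const int L = 16;
  const int nq = queries.size();
  const int asize = submat.nrow();
  if ((int)alphabet.size() != asize) stop("alphabet/matrix size mismatch");
  int16_t cmap[256];
  for (int c = 0; c < 256; ++c) cmap[c] = -1;
  for (int c = 0; c < asize; ++c) {
    cmap[(unsigned char)alphabet[c]] = c;
    cmap[(unsigned char)std::tolower(alphabet[c])] = c;
  }
  auto enc = [&](const char *s, int len, std::vector<int16_t> &out_codes) {
    out_codes.resize(len);
    for (int i = 0; i < len; ++i) {
      int v = cmap[(unsigned char)s[i]];
      if (v < 0) {
        if (default_idx < 0) stop("character '%c' outside alphabet", s[i]);
        v = default_idx;
      }
      out_codes[i] = (int16_t)v;
    }
  };
  std::vector<int16_t> dbe;
  enc(db.c_str(), db.size(), dbe);
  const int n = dbe.size();

  IntegerVector out(nq);
  const T PAD = -10000; // pad residue score: kills padded rows

  // order queries by length (desc) so batches are homogeneous
  std::vector<int> ord(nq), qlen(nq);
  for (int i = 0; i < nq; ++i) {
    ord[i] = i;
    qlen[i] = LENGTH(STRING_ELT(queries, i));
  }
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return qlen[x] > qlen[y]; });

  std::vector<T> prof, Hprev, Hcur, E, Fv, bestv;
  std::vector<int16_t> qcodes;
  for (int b0 = 0; b0 < nq; b0 += L) {
    const int nb = std::min(L, nq - b0);
    int m = 0;
    for (int l = 0; l < nb; ++l) m = std::max(m, qlen[ord[b0 + l]]);
    if (m == 0) continue;
    // query profile: prof[c][i][lane]
    prof.assign((size_t)asize * m * L, PAD);
    for (int l = 0; l < nb; ++l) {
      SEXP qs = STRING_ELT(queries, ord[b0 + l]);
      enc(CHAR(qs), LENGTH(qs), qcodes);
      for (size_t i = 0; i < qcodes.size(); ++i) {
        const int qi = qcodes[i];
        for (int c = 0; c < asize; ++c)
          prof[((size_t)c * m + i) * L + l] = (T)submat(qi, c);
      }
    }
    Hprev.assign((size_t)(m + 1) * L, 0);
    Hcur.assign((size_t)(m + 1) * L, 0);
    E.assign((size_t)(m + 1) * L, PAD);
    bestv.assign(L, 0);
    Fv.assign(L, PAD);
    T *H0 = Hprev.data(), *H1 = Hcur.data(), *Ep = E.data();
    T *__restrict__ bp = bestv.data();
    const T oe = gap_open + gap_ext, ex = gap_ext;
    for (int j = 0; j < n; ++j) {
      const T *pc = &prof[(size_t)dbe[j] * m * L];
      T *__restrict__ fp = Fv.data();
      for (int l = 0; l < L; ++l) fp[l] = PAD;
      for (int i = 1; i <= m; ++i) {
        const T *__restrict__ pd = pc + (size_t)(i - 1) * L;
        const T *__restrict__ hprow = H0 + (size_t)(i - 1) * L;
        const T *__restrict__ hprow1 = H0 + (size_t)i * L;
        const T *__restrict__ hcup = H1 + (size_t)(i - 1) * L;
        T *__restrict__ erow = Ep + (size_t)i * L;
        T *__restrict__ hrow = H1 + (size_t)i * L;
#pragma GCC ivdep
        for (int l = 0; l < L; ++l) {
          T e = (T)(erow[l] - ex);
          T eo = (T)(hprow1[l] - oe);
          if (eo > e) e = eo;
          if (e < PAD) e = PAD; // floor: no int16 underflow on long subjects
          erow[l] = e;
          T f = (T)(fp[l] - ex);
          T fo = (T)(hcup[l] - oe);
          if (fo > f) f = fo;
          fp[l] = f;
          T h = (T)(hprow[l] + pd[l]);
          if (e > h) h = e;
          if (f > h) h = f;
          if (h < 0) h = 0;
          hrow[l] = h;
          bp[l] = h > bp[l] ? h : bp[l];
        }
      }
      std::swap(H0, H1);
    }
    for (int l = 0; l < nb; ++l) out[ord[b0 + l]] = bestv[l];
  }
  return out;
}
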