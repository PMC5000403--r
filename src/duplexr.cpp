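#include <Rcpp.h>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Shared alignment machinery for the within-family MSA (global, Gotoh affine)
// and the SSCS reconciliation step (local, Smith-Waterman affine).
// Tie-breaking is fixed: diagonal > up (gap in b) > left (gap in a), so that
// traceback is deterministic for identical inputs.

static const double NEG_INF = -1e30;

static inline double subscore(char a, char b, double match, double mismatch) {
  // N never matches anything, including another N.
  if (a == b && a != 'N') return match;
  return mismatch;
}

struct PW {
  std::string ga, gb;
  double score;
  int a_start, a_end, b_start, b_end;  // 1-based; 0 when alignment is empty
};

// state codes used in traceback matrices
enum { TB_NONE = 0, TB_M = 1, TB_X = 2, TB_Y = 3, TB_STOP = 4 };

// Banded global alignment: only cells with j in [i - h, i + (m - n) + h]
// are evaluated. Family reads are near-identical copies of one template, so
// a generous band around the (shifted) main diagonal always contains the
// optimal path in practice; band <= 0 disables banding. Reused thread-local
// buffers hold stale values outside the band, which are never read because
// sentinel cells (-inf) are written just outside each row's band.
static PW align_global(const std::string &a, const std::string &b,
                       double match, double mismatch, double go, double ge,
                       int band = 0) {
  const int n = a.size(), m = b.size();
  const int w = m + 1;
  const int diff = m - n;
  const int h = band <= 0 ? (n > m ? n : m) : band + (diff < 0 ? -diff : diff);
  static thread_local std::vector<double> M, X, Y;
  static thread_local std::vector<unsigned char> tM, tX, tY;
  const size_t need = (size_t)(n + 1) * w;
  if (M.size() < need) {
    M.resize(need); X.resize(need); Y.resize(need);
    tM.resize(need); tX.resize(need); tY.resize(need);
  }
  auto lo_of = [&](int i) { int lo = i - h; return lo < 1 ? 1 : lo; };
  auto hi_of = [&](int i) { int hi = i + diff + h; return hi > m ? m : hi; };
  // row 0 borders + sentinel
  M[0] = 0.0; X[0] = Y[0] = NEG_INF;
  {
    int hi0 = hi_of(0);
    for (int j = 1; j <= hi0; ++j) {
      Y[j] = go + (j - 1) * ge;
      tY[j] = (j == 1) ? TB_M : TB_Y;
      M[j] = X[j] = NEG_INF;
    }
    if (hi0 + 1 <= m) M[hi0 + 1] = X[hi0 + 1] = Y[hi0 + 1] = NEG_INF;
  }
  for (int i = 1; i <= n; ++i) {
    const int lo = lo_of(i), hi = hi_of(i);
    if (lo == 1) {
      M[i * w] = Y[i * w] = NEG_INF;
      X[i * w] = go + (i - 1) * ge;
      tX[i * w] = (i == 1) ? TB_M : TB_X;
    } else {
      M[i * w + lo - 1] = X[i * w + lo - 1] = Y[i * w + lo - 1] = NEG_INF;
    }
    if (hi + 1 <= m) {
      M[i * w + hi + 1] = X[i * w + hi + 1] = Y[i * w + hi + 1] = NEG_INF;
    }
    for (int j = lo; j <= hi; ++j) {
      const int ij = i * w + j, dg = (i - 1) * w + (j - 1), up = (i - 1) * w + j,
                lf = i * w + (j - 1);
      // M: a[i] aligned to b[j]
      double best = M[dg];
      unsigned char src = TB_M;
      if (X[dg] > best) { best = X[dg]; src = TB_X; }
      if (Y[dg] > best) { best = Y[dg]; src = TB_Y; }
      M[ij] = best + subscore(a[i - 1], b[j - 1], match, mismatch);
      tM[ij] = src;
      // X: gap in b (consume a[i])
      best = M[up] + go; src = TB_M;
      if (X[up] + ge > best) { best = X[up] + ge; src = TB_X; }
      if (Y[up] + go > best) { best = Y[up] + go; src = TB_Y; }
      X[ij] = best; tX[ij] = src;
      // Y: gap in a (consume b[j])
      best = M[lf] + go; src = TB_M;
      if (X[lf] + go > best) { best = X[lf] + go; src = TB_X; }
      if (Y[lf] + ge > best) { best = Y[lf] + ge; src = TB_Y; }
      Y[ij] = best; tY[ij] = src;
    }
  }
  PW out;
  const int end = n * w + m;
  double best = M[end];
  unsigned char st = TB_M;
  if (X[end] > best) { best = X[end]; st = TB_X; }
  if (Y[end] > best) { best = Y[end]; st = TB_Y; }
  out.score = best;
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == TB_M) {
      unsigned char nx = tM[i * w + j];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; st = nx;
    } else if (st == TB_X) {
      unsigned char nx = tX[i * w + j];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; st = nx;
    } else {
      unsigned char nx = tY[i * w + j];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; st = nx;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  out.ga = ga; out.gb = gb;
  out.a_start = n > 0 ? 1 : 0; out.a_end = n;
  out.b_start = m > 0 ? 1 : 0; out.b_end = m;
  return out;
}

static PW align_local(const std::string &a, const std::string &b,
                      double match, double mismatch, double go, double ge) {
  const int n = a.size(), m = b.size();
  const int w = m + 1;
  std::vector<double> H((n + 1) * w, 0.0), E((n + 1) * w, NEG_INF),
      F((n + 1) * w, NEG_INF);
  std::vector<unsigned char> tH((n + 1) * w, TB_STOP), tE((n + 1) * w, TB_NONE),
      tF((n + 1) * w, TB_NONE);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * w + j, dg = (i - 1) * w + (j - 1), up = (i - 1) * w + j,
                lf = i * w + (j - 1);
      // F: gap in b ("up"), E: gap in a ("left")
      if (F[up] + ge > H[up] + go) { F[ij] = F[up] + ge; tF[ij] = TB_X; }
      else { F[ij] = H[up] + go; tF[ij] = TB_M; }
      if (E[lf] + ge > H[lf] + go) { E[ij] = E[lf] + ge; tE[ij] = TB_Y; }
      else { E[ij] = H[lf] + go; tE[ij] = TB_M; }
      double h = H[dg] + subscore(a[i - 1], b[j - 1], match, mismatch);
      unsigned char src = TB_M;
      if (F[ij] > h) { h = F[ij]; src = TB_X; }
      if (E[ij] > h) { h = E[ij]; src = TB_Y; }
      if (h <= 0.0) { h = 0.0; src = TB_STOP; }
      H[ij] = h; tH[ij] = src;
      // prefer later cells on ties so reconciliation keeps full-length overlaps
      if (h >= best && h > 0.0) { best = h; bi = i; bj = j; }
    }
  }
  PW out;
  out.score = best;
  if (best <= 0.0) {
    out.ga = ""; out.gb = "";
    out.a_start = out.a_end = out.b_start = out.b_end = 0;
    return out;
  }
  std::string ga, gb;
  int i = bi, j = bj;
  unsigned char st = TB_M;
  while (i > 0 && j > 0) {
    if (st == TB_M) {
      unsigned char src = tH[i * w + j];
      if (src == TB_STOP) break;
      if (src == TB_M) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        --i; --j;
      } else {
        st = src;  // enter a gap state, consume nothing yet
      }
    } else if (st == TB_X) {
      unsigned char src = tF[i * w + j];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i;
      st = (src == TB_X) ? TB_X : TB_M;
    } else {
      unsigned char src = tE[i * w + j];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j;
      st = (src == TB_Y) ? TB_Y : TB_M;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  out.ga = ga; out.gb = gb;
  out.a_start = i + 1; out.a_end = bi;
  out.b_start = j + 1; out.b_end = bj;
  return out;
}

// [[Rcpp::export]]
List cpp_pairwise_align(std::string a, std::string b, double match,
                        double mismatch, double gap_open, double gap_extend,
                        bool local) {
  PW r = local ? align_local(a, b, match, mismatch, gap_open, gap_extend)
               : align_global(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["aligned_a"] = r.ga, _["aligned_b"] = r.gb,
                      _["score"] = r.score, _["a_start"] = r.a_start,
                      _["a_end"] = r.a_end, _["b_start"] = r.b_start,
                      _["b_end"] = r.b_end);
}

// Center-star multiple alignment: every read is globally aligned to the
// center (longest read, first on ties) and the pairwise gap patterns are
// merged into one master coordinate system. Adequate for duplex families,
// whose members are near-identical copies of one template.
// [[Rcpp::export]]
List cpp_center_star(CharacterVector seqs, CharacterVector quals, double match,
                     double mismatch, double gap_open, double gap_extend,
                     int band = 16) {
  const int n = seqs.size();
  std::vector<std::string> s(n), q(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    q[i] = as<std::string>(quals[i]);
  }
  int center = 0;
  for (int i = 1; i < n; ++i)
    if (s[i].size() > s[center].size()) center = i;
  const std::string &cs = s[center];
  const int m = cs.size();

  // per-read parse of its alignment to the center:
  //   ins[k]  = inserted read chars falling between center positions k and k+1
  //   at[k]   = read char (or '-') aligned to center position k+1
  std::vector<std::vector<std::string>> ins(n), insq(n);
  std::vector<std::string> at(n), atq(n);
  std::vector<int> master(m + 1, 0);
  for (int r = 0; r < n; ++r) {
    ins[r].assign(m + 1, "");
    insq[r].assign(m + 1, "");
    at[r].assign(m, '-');
    atq[r].assign(m, ' ');
    if (r == center) {
      at[r] = cs;
      atq[r] = q[r];
      continue;
    }
    if (s[r] == cs) {  // identical reads need no alignment
      at[r] = cs;
      atq[r] = q[r];
      continue;
    }
    PW pw = align_global(cs, s[r], match, mismatch, gap_open, gap_extend, band);
    int k = 0;        // center positions consumed
    int rpos = 0;     // read positions consumed
    for (size_t c = 0; c < pw.ga.size(); ++c) {
      if (pw.ga[c] == '-') {
        ins[r][k].push_back(pw.gb[c]);
        insq[r][k].push_back(q[r][rpos]);
        ++rpos;
      } else if (pw.gb[c] == '-') {
        at[r][k] = '-';
        atq[r][k] = ' ';
        ++k;
      } else {
        at[r][k] = pw.gb[c];
        atq[r][k] = q[r][rpos];
        ++rpos;
        ++k;
      }
    }
    for (int k2 = 0; k2 <= m; ++k2)
      if ((int)ins[r][k2].size() > master[k2]) master[k2] = ins[r][k2].size();
  }
  CharacterVector out_s(n), out_q(n);
  for (int r = 0; r < n; ++r) {
    std::string row, rowq;
    for (int k = 0; k <= m; ++k) {
      row += ins[r][k];
      rowq += insq[r][k];
      for (int p = ins[r][k].size(); p < master[k]; ++p) {
        row.push_back('-');
        rowq.push_back(' ');
      }
      if (k < m) {
        row.push_back(at[r][k]);
        rowq.push_back(atq[r][k]);
      }
    }
    out_s[r] = row;
    out_q[r] = rowq;
  }
  return List::create(_["seqs"] = out_s, _["quals"] = out_q,
                      _["center"] = center + 1);
}

// Phred score standing in for a gap when it competes in the per-column vote:
// weighted mean of the up-to-8 nearest real bases of that row (up to 4 per
// side), weight 5 - d where d is the rank distance on that side, renormalised
// near sequence ends. Returns 0 when the row has no real base.
static double gap_phred(const std::string &qrow, const std::vector<int> &pos,
                        int col, int offset) {
  if (pos.empty()) return 0.0;
  // first real base at column >= col
  int lo = 0, hi = pos.size();
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (pos[mid] < col) lo = mid + 1; else hi = mid;
  }
  double num = 0.0, den = 0.0;
  for (int d = 1; d <= 4; ++d) {
    int ir = lo + d - 1;               // right side, rank d
    if (ir < (int)pos.size()) {
      num += (5 - d) * (qrow[pos[ir]] - offset);
      den += 5 - d;
    }
    int il = lo - d;                   // left side, rank d
    if (il >= 0) {
      num += (5 - d) * (qrow[pos[il]] - offset);
      den += 5 - d;
    }
  }
  if (den == 0.0) return 0.0;
  return num / den;
}

// [[Rcpp::export]]
double cpp_gap_quality(std::string qrow_gapped, std::string row_gapped,
                       int position, int phred_offset) {
  std::vector<int> pos;
  for (size_t c = 0; c < row_gapped.size(); ++c)
    if (row_gapped[c] != '-') pos.push_back(c);
  return gap_phred(qrow_gapped, pos, position - 1, phred_offset);
}

// Column-wise consensus over a gapped family alignment. Gaps vote like bases
// and carry their neighbourhood-derived quality; characters below the Phred
// threshold are not counted; a character needs a strict majority of counted
// votes, otherwise the column is 'N'. Gap columns are retained here ('-') and
// removed by the R wrapper.
// [[Rcpp::export]]
std::string cpp_consensus(CharacterVector rows, CharacterVector qrows,
                          double qual_thresh, int phred_offset) {
  const int n = rows.size();
  std::vector<std::string> s(n), q(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(rows[i]);
    q[i] = as<std::string>(qrows[i]);
  }
  const int L = n > 0 ? s[0].size() : 0;
  std::vector<std::vector<int>> pos(n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < L; ++c)
      if (s[i][c] != '-') pos[i].push_back(c);
  std::string cons(L, 'N');
  for (int c = 0; c < L; ++c) {
    int counts[256];
    std::memset(counts, 0, sizeof(counts));
    int counted = 0;
    for (int i = 0; i < n; ++i) {
      char ch = s[i][c];
      double ph = (ch == '-') ? gap_phred(q[i], pos[i], c, phred_offset)
                              : (double)(q[i][c] - phred_offset);
      if (ph >= qual_thresh) {
        ++counts[(unsigned char)ch];
        ++counted;
      }
    }
    char call = 'N';
    if (counted > 0) {
      static const char alphabet[] = "ACGTN-";
      for (const char *p = alphabet; *p; ++p) {
        if (2 * counts[(unsigned char)*p] > counted) { call = *p; break; }
      }
    }
    cons[c] = call;
  }
  return cons;
}

// Bytewise (C-locale) lexicographic a <= b, immune to collation settings.
// [[Rcpp::export]]
LogicalVector cpp_str_leq(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *pa = CHAR(STRING_ELT(a, i)), *pb = CHAR(STRING_ELT(b, i));
    out[i] = std::strcmp(pa, pb) <= 0;
  }
  return out;
}
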