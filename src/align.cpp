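#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise protein alignment with free (unpenalised) end gaps:
// the "overlap" flavour of Needleman-Wunsch. A gap run of length k costs
// gap_open + k * gap_ext. Terminal overhangs are left unaligned, so the
// identity denominator is the aligned core only (internal gap columns count,
// terminal ones never appear).
//
// States: M (q_i ~ s_j), X (gap in subject, consumes q), Y (gap in query).
// Boundary entry (score 0) is allowed along i==0 or j==0; exit is the best
// state anywhere in the last row or last column.

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int matches;
  int cols;       // aligned columns, terminal gaps excluded
  int q_start, q_end, s_start, s_end; // 1-based inclusive aligned spans
  std::string aq, as;                 // aligned strings (optional)
};

static void align_one(const int* q, int n, const int* s, int m,
                      const double* sub, int K,
                      double go, double ge,
                      bool want_strings, const std::string& qs,
                      const std::string& ss, AlnResult& out) {
  const int W = m + 1;
  static thread_local std::vector<double> Mv, Xv, Yv;
  static thread_local std::vector<unsigned char> tM, tX, tY;
  size_t need = (size_t)(n + 1) * W;
  if (Mv.size() < need) {
    Mv.resize(need); Xv.resize(need); Yv.resize(need);
    tM.resize(need); tX.resize(need); tY.resize(need);
  }
  double gop = go + ge; // cost of opening (first gap char)

  // row 0
  for (int j = 0; j <= m; ++j) { Mv[j] = NEG_INF; Xv[j] = NEG_INF; Yv[j] = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    Mv[r] = NEG_INF; Xv[r] = NEG_INF; Yv[r] = NEG_INF;
    const double* srow = sub + (size_t)q[i - 1] * K;
    for (int j = 1; j <= m; ++j) {
      // M: diagonal predecessor (boundary => 0, trace 0)
      double dM = Mv[p + j - 1], dX = Xv[p + j - 1], dY = Yv[p + j - 1];
      double best; unsigned char tb;
      if (i == 1 || j == 1) { best = 0.0; tb = 0; }
      else { best = NEG_INF; tb = 0; }
      if (dM > best) { best = dM; tb = 1; }
      if (dX > best) { best = dX; tb = 2; }
      if (dY > best) { best = dY; tb = 3; }
      Mv[r + j] = best + srow[s[j - 1]];
      tM[r + j] = tb;
      // X: gap in subject (move down)
      double a = Mv[p + j] - gop, b = Xv[p + j] - ge, c = Yv[p + j] - gop;
      if (a >= b && a >= c)      { Xv[r + j] = a; tX[r + j] = 1; }
      else if (b >= c)           { Xv[r + j] = b; tX[r + j] = 2; }
      else                       { Xv[r + j] = c; tX[r + j] = 3; }
      // Y: gap in query (move right)
      a = Mv[r + j - 1] - gop; b = Yv[r + j - 1] - ge; c = Xv[r + j - 1] - gop;
      if (a >= b && a >= c)      { Yv[r + j] = a; tY[r + j] = 1; }
      else if (b >= c)           { Yv[r + j] = b; tY[r + j] = 3; }
      else                       { Yv[r + j] = c; tY[r + j] = 2; }
    }
  }

  // best exit over last row and last column; fixed scan order for determinism
  double best = NEG_INF; int bi = n, bj = m, bs = 1;
  for (int j = 1; j <= m; ++j) {
    size_t c = (size_t)n * W + j;
    if (Mv[c] > best) { best = Mv[c]; bi = n; bj = j; bs = 1; }
    if (Xv[c] > best) { best = Xv[c]; bi = n; bj = j; bs = 2; }
    if (Yv[c] > best) { best = Yv[c]; bi = n; bj = j; bs = 3; }
  }
  for (int i = 1; i <= n; ++i) {
    size_t c = (size_t)i * W + m;
    if (Mv[c] > best) { best = Mv[c]; bi = i; bj = m; bs = 1; }
    if (Xv[c] > best) { best = Xv[c]; bi = i; bj = m; bs = 2; }
    if (Yv[c] > best) { best = Yv[c]; bi = i; bj = m; bs = 3; }
  }
  if (n == 0 || m == 0) { best = 0.0; bi = 0; bj = 0; }

  out.score = best;
  out.q_end = bi; out.s_end = bj;
  out.matches = 0; out.cols = 0;
  std::string aq, as;

  // traceback
  int i = bi, j = bj, st = bs;
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    if (st == 1) {
      ++out.cols;
      if (q[i - 1] == s[j - 1]) ++out.matches;
      if (want_strings) { aq.push_back(qs[i - 1]); as.push_back(ss[j - 1]); }
      unsigned char tb = tM[c];
      --i; --j;
      if (tb == 0) break;   // entered at boundary
      st = tb;
    } else if (st == 2) {
      ++out.cols;
      if (want_strings) { aq.push_back(qs[i - 1]); as.push_back('-'); }
      st = tX[c]; --i;
    } else {
      ++out.cols;
      if (want_strings) { aq.push_back('-'); as.push_back(ss[j - 1]); }
      st = tY[c]; --j;
    }
  }
  out.q_start = i + 1; out.s_start = j + 1;
  if (bi == 0 || bj == 0) { out.q_start = 1; out.q_end = 0; out.s_start = 1; out.s_end = 0; }
  if (want_strings) {
    out.aq.assign(aq.rbegin(), aq.rend());
    out.as.assign(as.rbegin(), as.rend());
  }
}

static void encode_seq(const std::string& s, const int* lut, std::vector<int>& enc) {
  enc.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lut[(unsigned char)s[i]];
    enc[i] = v;
  }
}

// [[Rcpp::export(name = ".aln_batch_cpp")]]
DataFrame aln_batch_cpp(CharacterVector q, CharacterVector s,
                        NumericMatrix sub, double gap_open, double gap_ext,
                        bool strings) {
  int np = q.size();
  if (s.size() != np) stop("query and subject vectors must have equal length");
  int K = sub.nrow();
  List dn = sub.attr("dimnames");
  CharacterVector rn = dn[0];
  int lut[256];
  int xcode = -1;
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < K; ++i) {
    std::string a = as<std::string>(rn[i]);
    lut[(unsigned char)a[0]] = i;
    if (a[0] == 'X') xcode = i;
  }
  if (xcode >= 0)
    for (int i = 0; i < 256; ++i) if (lut[i] < 0) lut[i] = xcode;
  std::vector<double> subv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) subv[(size_t)i * K + j] = sub(i, j);

  NumericVector score(np);
  IntegerVector matches(np), cols(np), qs_(np), qe_(np), ss_(np), se_(np);
  CharacterVector aq(strings ? np : 0), as_(strings ? np : 0);
  std::vector<int> eq, es;
  AlnResult res;
  for (int p = 0; p < np; ++p) {
    std::string qstr = as<std::string>(q[p]);
    std::string sstr = as<std::string>(s[p]);
    if (qstr.empty() || sstr.empty()) stop("empty sequence in alignment batch");
    encode_seq(qstr, lut, eq);
    encode_seq(sstr, lut, es);
    align_one(eq.data(), (int)eq.size(), es.data(), (int)es.size(),
              subv.data(), K, gap_open, gap_ext, strings, qstr, sstr, res);
    score[p] = res.score; matches[p] = res.matches; cols[p] = res.cols;
    qs_[p] = res.q_start; qe_[p] = res.q_end; ss_[p] = res.s_start; se_[p] = res.s_end;
    if (strings) { aq[p] = res.aq; as_[p] = res.as; }
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  if (strings)
    return DataFrame::create(_["score"] = score, _["matches"] = matches,
                             _["columns"] = cols, _["q_start"] = qs_, _["q_end"] = qe_,
                             _["s_start"] = ss_, _["s_end"] = se_,
                             _["aln_q"] = aq, _["aln_s"] = as_,
                             _["stringsAsFactors"] = false);
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["columns"] = cols, _["q_start"] = qs_, _["q_end"] = qe_,
                           _["s_start"] = ss_, _["s_end"] = se_);
}

// Hamming mismatch counts between pairs of equal-length strings, gaps ('-')
// skipped; used for fast distance matrices on stacked alignments.
// [[Rcpp::export(name = ".mismatch_pairs_cpp")]]
List mismatch_pairs_cpp(CharacterVector seqs, IntegerVector ia, IntegerVector ib) {
  int np = ia.size();
  std::vector<std::string> sv(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) sv[i] = as<std::string>(seqs[i]);
  IntegerVector mm(np), shared(np);
  for (int p = 0; p < np; ++p) {
    const std::string& a = sv[ia[p] - 1];
    const std::string& b = sv[ib[p] - 1];
    if (a.size() != b.size()) stop("sequences must have equal length");
    int m = 0, sh = 0;
    for (size_t k = 0; k < a.size(); ++k) {
      char ca = a[k], cb = b[k];
      if (ca == '-' || cb == '-') continue;
      ++sh;
      if (ca != cb) ++m;
    }
    mm[p] = m; shared[p] = sh;
  }
  return List::create(_["mismatch"] = mm, _["shared"] = shared);
}
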