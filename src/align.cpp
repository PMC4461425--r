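#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch with affine gap costs (Gotoh three-state recursion),
// optionally end-gap free. States: 0 = M (diagonal), 1 = X (gap in b,
// consumes a base of a), 2 = Y (gap in a, consumes a base of b).
// Tie-breaking is fixed: at every choice point prefer M, then X, then Y,
// which realises the "diagonal > gap-in-b > gap-in-a" traceback rule.

static const double NEG_INF = -1e30;

static inline bool base_match(char x, char y, bool n_wild) {
  if (x == y) return true;
  if (n_wild && (x == 'N' || y == 'N')) return true;
  return false;
}

// Column-wise stats of a gapped pair that contains no all-gap column.
// A gap run is a maximal block of '-' in one sequence; a run touching the
// first or last alignment column is terminal.
static NumericVector gapped_stats(const std::string &ga, const std::string &gb,
                                  bool n_wild) {
  int L = (int) ga.size();
  int M = 0, X = 0, C_int = 0, R_int = 0, C_term = 0, R_term = 0;
  int run_start = -1;   // current gap run (in either sequence; runs in a and
  int run_in = 0;       // b cannot overlap because no column is gap in both)
  for (int k = 0; k <= L; ++k) {
    int in = 0;
    if (k < L) {
      char ca = ga[k], cb = gb[k];
      if (ca == '-') in = 1;          // gap in a
      else if (cb == '-') in = 2;     // gap in b
      else if (base_match(ca, cb, n_wild)) { M++; }
      else { X++; }
    }
    if (run_start >= 0 && in != run_in) {
      int len = k - run_start;
      bool term = (run_start == 0) || (k == L);
      if (term) { C_term += len; R_term += 1; }
      else      { C_int  += len; R_int  += 1; }
      run_start = -1; run_in = 0;
    }
    if (in != 0 && run_start < 0) { run_start = k; run_in = in; }
  }
  NumericVector out = NumericVector::create(
    _["M"] = M, _["X"] = X, _["C_int"] = C_int, _["R_int"] = R_int,
    _["C_term"] = C_term, _["R_term"] = R_term,
    _["overlap"] = M + X + C_int, _["length"] = L);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gapped_stats(std::string ga, std::string gb, bool n_wild) {
  if (ga.size() != gb.size())
    stop("gapped sequences have unequal lengths");
  return gapped_stats(ga, gb, n_wild);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, double match, double mismatch,
               double gap_open, double gap_extend, bool free_end_gaps,
               bool n_wild) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("cannot align an empty sequence");
  int W = m + 1;
  // rolling double rows for scores; full byte matrices for traceback
  static std::vector<double> Mp_v, Xp_v, Yp_v, Mc_v, Xc_v, Yc_v;
  static std::vector<unsigned char> pM, pX, pY;
  static std::vector<double> lcM, lcX, lcY;  // last-column scores per row
  Mp_v.assign(W, NEG_INF); Xp_v.assign(W, NEG_INF); Yp_v.assign(W, NEG_INF);
  Mc_v.assign(W, NEG_INF); Xc_v.assign(W, NEG_INF); Yc_v.assign(W, NEG_INF);
  pM.assign((size_t)(n + 1) * W, 0); pX.assign((size_t)(n + 1) * W, 0);
  pY.assign((size_t)(n + 1) * W, 0);
  lcM.assign(n + 1, NEG_INF); lcX.assign(n + 1, NEG_INF);
  lcY.assign(n + 1, NEG_INF);
  Mp_v[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Yp_v[j] = free_end_gaps ? 0.0 : gap_open + gap_extend * j;
    pY[j] = (j == 1) ? 0 : 2;
  }
  lcM[0] = Mp_v[m]; lcX[0] = Xp_v[m]; lcY[0] = Yp_v[m];
  const double goe = gap_open + gap_extend, ge = gap_extend;
  for (int i = 1; i <= n; ++i) {
    char ai = a[i - 1];
    bool aN = n_wild && ai == 'N';
    double *Mp = Mp_v.data(), *Xp = Xp_v.data(), *Yp = Yp_v.data();
    double *Mc = Mc_v.data(), *Xc = Xc_v.data(), *Yc = Yc_v.data();
    unsigned char *pMc = &pM[(size_t) i * W], *pXc = &pX[(size_t) i * W],
                  *pYc = &pY[(size_t) i * W];
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = free_end_gaps ? 0.0 : gap_open + gap_extend * i;
    pXc[0] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      char bj = b[j - 1];
      double s = (ai == bj || aN || (n_wild && bj == 'N')) ? match : mismatch;
      // M state: predecessors at (i-1, j-1), preference M > X > Y
      double best = Mp[j - 1]; unsigned char arg = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; arg = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; arg = 2; }
      Mc[j] = best + s; pMc[j] = arg;
      // X state: gap in b, predecessors at (i-1, j)
      best = Mp[j] + goe; arg = 0;
      double v = Xp[j] + ge;
      if (v > best) { best = v; arg = 1; }
      v = Yp[j] + goe;
      if (v > best) { best = v; arg = 2; }
      Xc[j] = best; pXc[j] = arg;
      // Y state: gap in a, predecessors at (i, j-1)
      best = Mc[j - 1] + goe; arg = 0;
      v = Xc[j - 1] + goe;
      if (v > best) { best = v; arg = 1; }
      v = Yc[j - 1] + ge;
      if (v > best) { best = v; arg = 2; }
      Yc[j] = best; pYc[j] = arg;
    }
    lcM[i] = Mc[m]; lcX[i] = Xc[m]; lcY[i] = Yc[m];
    std::swap(Mp_v, Mc_v); std::swap(Xp_v, Xc_v); std::swap(Yp_v, Yc_v);
  }
  // after the swaps, *_p rows hold row n (the last row)
  const double *lrM = Mp_v.data(), *lrX = Xp_v.data(), *lrY = Yp_v.data();
  // End point selection. With free end gaps the alignment may end anywhere
  // on the last row or column; trailing gaps are appended unpenalised.
  int ei = n, ej = m, estate = 0;
  double score;
  if (!free_end_gaps) {
    score = lrM[m]; estate = 0;
    if (lrX[m] > score) { score = lrX[m]; estate = 1; }
    if (lrY[m] > score) { score = lrY[m]; estate = 2; }
  } else {
    score = NEG_INF;
    ei = ej = -1;
    // candidates on the last column (trailing gap in b), then last row
    // (trailing gap in a); prefer higher score, then fewer terminal gap
    // columns (larger i + j), then last column over last row, then M > X > Y.
    for (int pass = 0; pass < 2; ++pass) {
      for (int t = (pass == 0 ? n : m); t >= 0; --t) {
        int i = (pass == 0) ? t : n;
        int j = (pass == 0) ? m : t;
        double cand[3];
        if (pass == 0) { cand[0] = lcM[i]; cand[1] = lcX[i]; cand[2] = lcY[i]; }
        else { cand[0] = lrM[j]; cand[1] = lrX[j]; cand[2] = lrY[j]; }
        for (int s = 0; s < 3; ++s) {
          double v = cand[s];
          bool better = v > score;
          if (!better && v == score && ei >= 0) {
            if (i + j > ei + ej) better = true;
          }
          if (better) { score = v; ei = i; ej = j; estate = s; }
        }
      }
    }
  }
  std::string ra, rb;  // reversed
  ra.reserve(n + m); rb.reserve(n + m);
  // trailing free gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 || j == 0) stop("traceback corrupted");  // cannot happen
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      st = pM[i * W + j]; --i; --j;
    } else if (st == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      st = pX[i * W + j]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      st = pY[i * W + j]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["gapped_a"] = ra, _["gapped_b"] = rb,
                      _["score"] = score,
                      _["stats"] = gapped_stats(ra, rb, n_wild));
}

// Stats for one pair of rows taken from an MSA: columns gapped in both rows
// are deleted first, then the usual pair stats apply.
static bool msa_pair(const std::string &x, const std::string &y, bool n_wild,
                     int out[6]) {
  int L = (int) x.size();
  int M = 0, Xc = 0, C_int = 0, R_int = 0, C_term = 0, R_term = 0;
  int run_start = -1, run_in = 0, col = 0;  // col indexes retained columns
  for (int k = 0; k <= L; ++k) {
    int in = 0;
    if (k < L) {
      char cx = x[k], cy = y[k];
      if (cx == '-' && cy == '-') continue;  // column dropped
      if (cx == '-') in = 1;
      else if (cy == '-') in = 2;
      else if (base_match(cx, cy, n_wild)) M++;
      else Xc++;
    }
    if (run_start >= 0 && in != run_in) {
      int len = col - run_start;
      // terminal: touches the first or the last retained column
      bool term = (run_start == 0) || (k == L);
      if (term) { C_term += len; R_term += 1; }
      else      { C_int  += len; R_int  += 1; }
      run_start = -1; run_in = 0;
    }
    if (k < L && in != 0 && run_start < 0) { run_start = col; run_in = in; }
    if (k < L) col++;
  }
  out[0] = M; out[1] = Xc; out[2] = C_int; out[3] = R_int;
  out[4] = C_term; out[5] = R_term;
  return (M + Xc) > 0;
}

// [[Rcpp::export]]
NumericVector cpp_msa_pair_stats(std::string x, std::string y, bool n_wild) {
  if (x.size() != y.size()) stop("MSA rows have unequal widths");
  int s[6];
  msa_pair(x, y, n_wild, s);
  return NumericVector::create(
    _["M"] = s[0], _["X"] = s[1], _["C_int"] = s[2], _["R_int"] = s[3],
    _["C_term"] = s[4], _["R_term"] = s[5],
    _["overlap"] = s[0] + s[1] + s[2],
    _["length"] = s[0] + s[1] + s[2] + s[4]);
}

// All-pairs divergence matrices under the three identity definitions from
// one MSA, sharing a single stats pass per pair. count_terminal selects the
// terminal-gap policy (true = COUNT, false = EXCLUDE).
// [[Rcpp::export]]
List cpp_msa_distances(CharacterVector aligned, bool count_terminal,
                       bool n_wild, bool undefined_max) {
  int n = aligned.size();
  std::vector<std::string> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = as<std::string>(aligned[i]);
  for (int i = 1; i < n; ++i)
    if (rows[i].size() != rows[0].size())
      stop("MSA rows have unequal widths");
  NumericMatrix dng(n, n), dog(n, n), deg(n, n);
  int s[6];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!msa_pair(rows[i], rows[j], n_wild, s)) {
        if (!undefined_max)
          stop("identity undefined (no comparable columns) for pair %d, %d",
               i + 1, j + 1);
        dng(i, j) = dng(j, i) = 1.0;
        dog(i, j) = dog(j, i) = 1.0;
        deg(i, j) = deg(j, i) = 1.0;
        continue;
      }
      double M = s[0], X = s[1];
      double R = s[3] + (count_terminal ? s[5] : 0);
      double C = s[2] + (count_terminal ? s[4] : 0);
      double v1 = 1.0 - M / (M + X);
      double v2 = 1.0 - M / (M + X + R);
      double v3 = 1.0 - M / (M + X + C);
      dng(i, j) = dng(j, i) = v1;
      dog(i, j) = dog(j, i) = v2;
      deg(i, j) = deg(j, i) = v3;
    }
  }
  return List::create(_["no_gaps"] = dng, _["one_gap"] = dog,
                      _["each_gap"] = deg);
}
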