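#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Dynamic-programming kernels for local profile-HMM scoring and affine-gap
// local alignment.  All profile scores are log2-odds against an i.i.d.
// background null.
//
// Model layout passed from R:
//   mlodds : L x 21 matrix, log2( e_j(a) / q(a) ); 0-based column 20 is the
//            'X' residue and is ignored ('X' emits background, odds 0).
//   tr     : L x 7 matrix of log2 transition probabilities, columns
//            MM MI MD IM II DM DD; row j holds transitions leaving model
//            position j (row L is unused).
//   seq    : integer vector, residues coded 0..19, 20 = 'X'.
//
// Local alignment semantics: uniform entry into any match state (cost
// log2(1/L)), free exit from any match state.  Insert states emit the
// background, so they contribute transition costs only.

static const double NEG_INF = -1e30;

static inline double lse2(double a, double b) {
  // log2( 2^a + 2^b )
  if (a < b) std::swap(a, b);
  if (b <= NEG_INF / 2) return a;
  return a + std::log2(1.0 + std::exp2(b - a));
}

// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix mlodds, NumericMatrix tr, IntegerVector seq) {
  const int L = mlodds.nrow();
  const int n = seq.size();
  const double entry = -std::log2((double)L);

  std::vector<std::vector<double> > VM(n + 1, std::vector<double>(L + 1, NEG_INF));
  std::vector<std::vector<double> > VI(n + 1, std::vector<double>(L + 1, NEG_INF));
  std::vector<std::vector<double> > VD(n + 1, std::vector<double>(L + 1, NEG_INF));
  // traceback codes: 0 entry, 1 from M, 2 from D, 3 from I
  std::vector<std::vector<signed char> > PM(n + 1, std::vector<signed char>(L + 1, -1));
  std::vector<std::vector<signed char> > PI(n + 1, std::vector<signed char>(L + 1, -1));
  std::vector<std::vector<signed char> > PD(n + 1, std::vector<signed char>(L + 1, -1));

  double best = NEG_INF;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; i++) {
    const int a = seq[i - 1];
    for (int j = 1; j <= L; j++) {
      const double em = (a >= 20) ? 0.0 : mlodds(j - 1, a);
      // preference on exact ties: M > D > I > entry
      double sc = NEG_INF;
      signed char from = -1;
      if (j >= 2) {
        double cand = VM[i - 1][j - 1] + tr(j - 2, 0); // MM
        if (cand > sc) { sc = cand; from = 1; }
        cand = VD[i - 1][j - 1] + tr(j - 2, 5);        // DM
        if (cand > sc) { sc = cand; from = 2; }
        cand = VI[i - 1][j - 1] + tr(j - 2, 3);        // IM
        if (cand > sc) { sc = cand; from = 3; }
      }
      if (entry > sc) { sc = entry; from = 0; }
      VM[i][j] = em + sc;
      PM[i][j] = from;

      if (j <= L - 1) {
        const double ci  = VM[i - 1][j] + tr(j - 1, 1); // MI
        const double cii = VI[i - 1][j] + tr(j - 1, 4); // II
        if (ci >= cii) { VI[i][j] = ci;  PI[i][j] = 1; }
        else           { VI[i][j] = cii; PI[i][j] = 3; }
      }
      if (j >= 2) {
        const double cd  = VM[i][j - 1] + tr(j - 2, 2); // MD
        const double cdd = VD[i][j - 1] + tr(j - 2, 6); // DD
        if (cd >= cdd) { VD[i][j] = cd;  PD[i][j] = 1; }
        else           { VD[i][j] = cdd; PD[i][j] = 2; }
      }
      if (VM[i][j] > best) { best = VM[i][j]; best_i = i; best_j = j; }
    }
  }

  if (best_i < 0) {
    return List::create(Named("score") = NEG_INF,
                        Named("span") = IntegerVector::create(0, 0),
                        Named("model_span") = IntegerVector::create(0, 0),
                        Named("path") = "");
  }

  std::string path;
  int i = best_i, j = best_j;
  int state = 1; // 1 = M, 2 = D, 3 = I
  int first_i = best_i, first_j = best_j;
  while (true) {
    if (state == 1) {
      path.push_back('M');
      first_i = i; first_j = j;
      const signed char from = PM[i][j];
      if (from == 0) break;
      state = from;
      i -= 1; j -= 1;
    } else if (state == 2) {
      path.push_back('D');
      first_j = j;
      state = PD[i][j];
      j -= 1;
    } else {
      path.push_back('I');
      first_i = i;
      state = PI[i][j];
      i -= 1;
    }
  }
  std::reverse(path.begin(), path.end());

  return List::create(
    Named("score") = best,
    Named("span") = IntegerVector::create(first_i - 1, best_i),   // 0-based half-open on query
    Named("model_span") = IntegerVector::create(first_j, best_j), // 1-based inclusive on model
    Named("path") = path);
}

// rolling-row Viterbi, score only; raw-pointer hot loop
static double viterbi_score_only(const NumericMatrix& mlodds, const NumericMatrix& tr,
                                 const IntegerVector& seq) {
  const int L = mlodds.nrow();
  const int n = seq.size();
  const double entry = -std::log2((double)L);
  const double* M  = REAL(mlodds); // column-major, L rows
  const double* T  = REAL(tr);     // column-major, L rows, 7 columns
  const double* tMM = T;           // T[j-1 + col*L]
  const double* tMI = T + 1L * L;
  const double* tMD = T + 2L * L;
  const double* tIM = T + 3L * L;
  const double* tII = T + 4L * L;
  const double* tDM = T + 5L * L;
  const double* tDD = T + 6L * L;
  std::vector<double> VMp(L + 1, NEG_INF), VIp(L + 1, NEG_INF), VDp(L + 1, NEG_INF);
  std::vector<double> VM(L + 1, NEG_INF), VI(L + 1, NEG_INF), VD(L + 1, NEG_INF);
  double best = NEG_INF;
  for (int i = 1; i <= n; i++) {
    const int a = seq[i - 1];
    const double* mcol = (a >= 20) ? 0 : (M + (long)a * L);
    double vd_prev = NEG_INF; // VD[j-1] in current row
    for (int j = 1; j <= L; j++) {
      const double em = mcol ? mcol[j - 1] : 0.0;
      double sc = entry;
      if (j >= 2) {
        const int k = j - 2;
        double c = VMp[j - 1] + tMM[k];
        if (c > sc) sc = c;
        c = VDp[j - 1] + tDM[k];
        if (c > sc) sc = c;
        c = VIp[j - 1] + tIM[k];
        if (c > sc) sc = c;
      }
      const double vm = em + sc;
      VM[j] = vm;
      if (j <= L - 1) {
        const double ci  = VMp[j] + tMI[j - 1];
        const double cii = VIp[j] + tII[j - 1];
        VI[j] = (ci >= cii) ? ci : cii;
      } else {
        VI[j] = NEG_INF;
      }
      if (j >= 2) {
        const double cd  = VM[j - 1] + tMD[j - 2];
        const double cdd = vd_prev + tDD[j - 2];
        vd_prev = (cd >= cdd) ? cd : cdd;
      } else {
        vd_prev = NEG_INF;
      }
      VD[j] = vd_prev;
      if (vm > best) best = vm;
    }
    VMp.swap(VM); VIp.swap(VI); VDp.swap(VD);
  }
  return best;
}

// [[Rcpp::export]]
double cpp_viterbi_score(NumericMatrix mlodds, NumericMatrix tr, IntegerVector seq) {
  return viterbi_score_only(mlodds, tr, seq);
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_batch(NumericMatrix mlodds, NumericMatrix tr, List seqs) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int k = 0; k < m; k++) {
    IntegerVector s = seqs[k];
    out[k] = viterbi_score_only(mlodds, tr, s);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_forward(NumericMatrix mlodds, NumericMatrix tr, IntegerVector seq) {
  const int L = mlodds.nrow();
  const int n = seq.size();
  const double entry = -std::log2((double)L);
  std::vector<double> FMp(L + 1, NEG_INF), FIp(L + 1, NEG_INF), FDp(L + 1, NEG_INF);
  std::vector<double> FM(L + 1, NEG_INF), FI(L + 1, NEG_INF), FD(L + 1, NEG_INF);
  double total = NEG_INF;
  for (int i = 1; i <= n; i++) {
    const int a = seq[i - 1];
    for (int j = 1; j <= L; j++) {
      const double em = (a >= 20) ? 0.0 : mlodds(j - 1, a);
      double sc = entry;
      if (j >= 2) {
        sc = lse2(sc, FMp[j - 1] + tr(j - 2, 0));
        sc = lse2(sc, FDp[j - 1] + tr(j - 2, 5));
        sc = lse2(sc, FIp[j - 1] + tr(j - 2, 3));
      }
      FM[j] = em + sc;
      if (j <= L - 1) {
        FI[j] = lse2(FMp[j] + tr(j - 1, 1), FIp[j] + tr(j - 1, 4));
      } else {
        FI[j] = NEG_INF;
      }
      if (j >= 2) {
        FD[j] = lse2(FM[j - 1] + tr(j - 2, 2), FD[j - 1] + tr(j - 2, 6));
      } else {
        FD[j] = NEG_INF;
      }
      total = lse2(total, FM[j]); // free exit from every match state
    }
    FMp.swap(FM); FIp.swap(FI); FDp.swap(FD);
  }
  return total;
}

// Smith-Waterman local alignment with affine gaps, score only.
// s1, s2: residues coded 0..(nrow(submat)-1); penalties positive.
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector s1, IntegerVector s2, NumericMatrix submat,
                    double gap_open, double gap_ext) {
  const int n = s1.size(), m = s2.size();
  std::vector<double> Hp(m + 1, 0.0), H(m + 1, 0.0);
  std::vector<double> Ep(m + 1, NEG_INF), E(m + 1, NEG_INF); // gap in s2 (vertical)
  std::vector<double> F(m + 1, NEG_INF);                     // gap in s1 (horizontal)
  double best = 0.0;
  for (int i = 1; i <= n; i++) {
    H[0] = 0.0; F[0] = NEG_INF;
    double Fcur = NEG_INF;
    for (int j = 1; j <= m; j++) {
      E[j] = std::max(Hp[j] - gap_open - gap_ext, Ep[j] - gap_ext);
      Fcur = std::max(H[j - 1] - gap_open - gap_ext, Fcur - gap_ext);
      double diag = Hp[j - 1] + submat(s1[i - 1], s2[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(E[j], Fcur)));
      H[j] = h;
      if (h > best) best = h;
    }
    Hp.swap(H); Ep.swap(E);
  }
  return best;
}
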