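#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment.
// Gap of length L costs gap_open + L * gap_ext (both supplied as positive
// costs), matching the convention of Biostrings::pairwiseAlignment.
// Three-state DP (match state M, gap-in-a state E, gap-in-b state F) with a
// deterministic traceback preference (M, then F, then E) so repeated runs on
// identical input return identical alignments.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char x, char y, double match, double mismatch) {
  bool xa = (x=='A'||x=='C'||x=='G'||x=='T');
  bool ya = (y=='A'||y=='C'||y=='G'||y=='T');
  if (xa && ya && x == y) return match;
  return mismatch;  // ambiguity codes and N are scored as mismatches
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double go = -(gap_open + gap_ext);  // cost of opening (first gap pos)
  const double ge = -gap_ext;               // cost of each further gap pos

  std::vector<double> M((n+1)*(m+1), NEG_INF), E((n+1)*(m+1), NEG_INF),
                      F((n+1)*(m+1), NEG_INF);
  // traceback: which state each cell's max came from (0=M,1=E,2=F)
  std::vector<unsigned char> tM((n+1)*(m+1)), tE((n+1)*(m+1)), tF((n+1)*(m+1));
  auto ix = [m](int i, int j){ return i*(m+1)+j; };

  M[ix(0,0)] = 0.0;
  for (int j = 1; j <= m; ++j) { E[ix(0,j)] = -(gap_open + gap_ext*j); tE[ix(0,j)] = 1; }
  for (int i = 1; i <= n; ++i) { F[ix(i,0)] = -(gap_open + gap_ext*i); tF[ix(i,0)] = 2; }
  tE[ix(0,1)] = 0; tF[ix(1,0)] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i-1], b[j-1], match, mismatch);
      // M: from any state at (i-1, j-1)
      double m0 = M[ix(i-1,j-1)], m1 = E[ix(i-1,j-1)], m2 = F[ix(i-1,j-1)];
      double best = m0; unsigned char tb = 0;
      if (m2 > best) { best = m2; tb = 2; }
      if (m1 > best) { best = m1; tb = 1; }
      M[ix(i,j)] = best + s; tM[ix(i,j)] = tb;
      // E: gap in a (consume b[j-1])
      double e0 = M[ix(i,j-1)] + go, e1 = E[ix(i,j-1)] + ge, e2 = F[ix(i,j-1)] + go;
      best = e0; tb = 0;
      if (e2 > best) { best = e2; tb = 2; }
      if (e1 > best) { best = e1; tb = 1; }
      E[ix(i,j)] = best; tE[ix(i,j)] = tb;
      // F: gap in b (consume a[i-1])
      double f0 = M[ix(i-1,j)] + go, f1 = F[ix(i-1,j)] + ge, f2 = E[ix(i-1,j)] + go;
      best = f0; tb = 0;
      if (f2 > best) { best = f2; tb = 1; }
      if (f1 > best) { best = f1; tb = 2; }
      F[ix(i,j)] = best; tF[ix(i,j)] = tb;
    }
  }

  double sM = M[ix(n,m)], sE = E[ix(n,m)], sF = F[ix(n,m)];
  double score = sM; int state = 0;
  if (sF > score) { score = sF; state = 2; }
  if (sE > score) { score = sE; state = 1; }

  std::string oa, ob;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1; else if (j == 0) state = 2;
    if (state == 0) {
      unsigned char tb = tM[ix(i,j)];
      oa.push_back(a[i-1]); ob.push_back(b[j-1]);
      --i; --j; state = tb;
    } else if (state == 1) {       // gap in a
      unsigned char tb = tE[ix(i,j)];
      oa.push_back('-'); ob.push_back(b[j-1]);
      --j; state = tb;
    } else {                        // gap in b
      unsigned char tb = tF[ix(i,j)];
      oa.push_back(a[i-1]); ob.push_back('-');
      --i; state = tb;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["aligned_a"] = oa, _["aligned_b"] = ob,
                      _["score"] = score);
}

// Align one sequence to a gapped profile (counts matrix with rows
// A, C, G, T, gap; one column per alignment column). Column-vs-base score is
// the count-weighted mean substitution score; profile gap counts contribute
// zero (a residue aligned over an existing gap is neither rewarded nor
// penalised). Returns the edit path as a string of operations:
//   'M' consume one profile column and one sequence base
//   'D' consume one profile column, gap in the sequence
//   'I' consume one sequence base, new all-gap column in the profile
// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix profile, std::string s,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int n = profile.ncol(), m = s.size();
  const double go = -(gap_open + gap_ext), ge = -gap_ext;
  const char bases[4] = {'A','C','G','T'};

  // precompute column score against each of A,C,G,T and non-ACGT
  std::vector<double> colscore(n*5);
  for (int j = 0; j < n; ++j) {
    int tot = 0;
    for (int r = 0; r < 5; ++r) tot += profile(r, j);
    for (int x = 0; x < 5; ++x) {
      double sc = 0.0;
      char cx = (x < 4) ? bases[x] : 'N';
      for (int r = 0; r < 4; ++r)
        sc += profile(r, j) * subst(bases[r], cx, match, mismatch);
      colscore[j*5 + x] = (tot > 0) ? sc / tot : 0.0;
    }
  }
  auto baseidx = [&](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return 4; }
  };

  std::vector<double> M((n+1)*(m+1), NEG_INF), E((n+1)*(m+1), NEG_INF),
                      F((n+1)*(m+1), NEG_INF);
  std::vector<unsigned char> tM((n+1)*(m+1)), tE((n+1)*(m+1)), tF((n+1)*(m+1));
  auto ix = [m](int i, int j){ return i*(m+1)+j; };
  M[ix(0,0)] = 0.0;
  for (int j = 1; j <= m; ++j) E[ix(0,j)] = -(gap_open + gap_ext*j);
  for (int i = 1; i <= n; ++i) F[ix(i,0)] = -(gap_open + gap_ext*i);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = colscore[(i-1)*5 + baseidx(s[j-1])];
      double m0 = M[ix(i-1,j-1)], m1 = E[ix(i-1,j-1)], m2 = F[ix(i-1,j-1)];
      double best = m0; unsigned char tb = 0;
      if (m2 > best) { best = m2; tb = 2; }
      if (m1 > best) { best = m1; tb = 1; }
      M[ix(i,j)] = best + sc; tM[ix(i,j)] = tb;
      double e0 = M[ix(i,j-1)] + go, e1 = E[ix(i,j-1)] + ge, e2 = F[ix(i,j-1)] + go;
      best = e0; tb = 0;
      if (e2 > best) { best = e2; tb = 2; }
      if (e1 > best) { best = e1; tb = 1; }
      E[ix(i,j)] = best; tE[ix(i,j)] = tb;
      double f0 = M[ix(i-1,j)] + go, f1 = F[ix(i-1,j)] + ge, f2 = E[ix(i-1,j)] + go;
      best = f0; tb = 0;
      if (f2 > best) { best = f2; tb = 1; }
      if (f1 > best) { best = f1; tb = 2; }
      F[ix(i,j)] = best; tF[ix(i,j)] = tb;
    }
  }

  double sM = M[ix(n,m)], sE = E[ix(n,m)], sF = F[ix(n,m)];
  double score = sM; int state = 0;
  if (sF > score) { score = sF; state = 2; }
  if (sE > score) { score = sE; state = 1; }

  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1; else if (j == 0) state = 2;
    if (state == 0) { ops.push_back('M'); state = tM[ix(i,j)]; --i; --j; }
    else if (state == 1) { ops.push_back('I'); state = tE[ix(i,j)]; --j; }
    else { ops.push_back('D'); state = tF[ix(i,j)]; --i; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = ops, _["score"] = score);
}
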