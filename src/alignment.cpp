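#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with full traceback.
// Gap of length g costs gap_open + g * gap_ext, matching the convention of
// Biostrings::pairwiseAlignment(gapOpening, gapExtension).
// Coordinates in the result are 0-based half-open.
// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string a, std::string b,
              double match = 1.0, double mismatch = -2.0,
              double gap_open = -5.0, double gap_ext = -2.0) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // H, E (gap in a: move along b), F (gap in b: move along a)
  std::vector<double> Hp(m + 1, 0.0), Hc(m + 1, 0.0);
  std::vector<double> Ep(m + 1, NEG), Ec(m + 1, NEG);
  std::vector<double> Fc(m + 1, NEG), Fp(m + 1, NEG);
  // traceback: tbH 0=stop 1=diag 2=fromE 3=fromF; tbE 1=open 0=extend; tbF same
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hc[0] = 0.0; Ec[0] = NEG; Fc[0] = NEG;
    size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (consume b[j-1])
      double e_open = Hc[j - 1] + gap_open + gap_ext;
      double e_ext  = Ec[j - 1] + gap_ext;
      if (e_open >= e_ext) { Ec[j] = e_open; tbE[row + j] = 1; }
      else                 { Ec[j] = e_ext;  tbE[row + j] = 0; }
      // F: gap in b (consume a[i-1])
      double f_open = Hp[j] + gap_open + gap_ext;
      double f_ext  = Fp[j] + gap_ext;
      if (f_open >= f_ext) { Fc[j] = f_open; tbF[row + j] = 1; }
      else                 { Fc[j] = f_ext;  tbF[row + j] = 0; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = Hp[j - 1] + s;
      double h = 0.0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (Ec[j] > h) { h = Ec[j]; t = 2; }
      if (Fc[j] > h) { h = Fc[j]; t = 3; }
      Hc[j] = h; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj, state = 0; // 0=H 1=E 2=F
  int n_ident = 0, n_mism = 0, n_gapopen = 0, aln_len = 0;
  int ae = bi, be = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        if (a[i - 1] == b[j - 1]) ++n_ident; else ++n_mism;
        ++aln_len; --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // in E: gap in a, consume b
      unsigned char t = tbE[idx];
      ++aln_len; --j;
      if (t == 1) { ++n_gapopen; state = 0; }
    } else { // in F: gap in b, consume a
      unsigned char t = tbF[idx];
      ++aln_len; --i;
      if (t == 1) { ++n_gapopen; state = 0; }
    }
  }
  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = ae,
    _["b_start"] = j, _["b_end"] = be,
    _["n_ident"] = n_ident, _["n_mismatch"] = n_mism,
    _["n_gapopen"] = n_gapopen, _["aln_len"] = aln_len);
}

// Global affine-gap alignment of two nucleotide profiles (Gotoh).
// Profiles are 4 x L matrices of A/C/G/T frequencies (columns may sum to < 1
// when rows carry gaps; the residual mass scores 0 against everything).
// Returns an integer vector of ops: 1 = consume a column of both profiles,
// 2 = column from A only (gap inserted in B), 3 = column from B only.
// [[Rcpp::export(name = ".nw_profile")]]
IntegerVector nw_profile(NumericMatrix pa, NumericMatrix pb,
                         double match = 1.0, double mismatch = -1.0,
                         double gap_open = -4.0, double gap_ext = -1.0) {
  const int n = pa.ncol(), m = pb.ncol();
  const double NEG = -1e18;
  // precompute column substitution scores
  std::vector<double> sub((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          s += pa(x, i) * pb(y, j) * (x == y ? match : mismatch);
      sub[(size_t)i * m + j] = s;
    }
  std::vector<double> Hp(m + 1), Hc(m + 1), Ep(m + 1), Ec(m + 1), Fp(m + 1), Fc(m + 1);
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  Hp[0] = 0.0; Ep[0] = NEG; Fp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Ep[j] = gap_open + gap_ext * j;
    Hp[j] = Ep[j]; Fp[j] = NEG;
    tbH[j] = 2; tbE[j] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1);
    Fc[0] = gap_open + gap_ext * i;
    Hc[0] = Fc[0]; Ec[0] = NEG;
    tbH[row] = 3; tbF[row] = (i == 1) ? 1 : 0;
    for (int j = 1; j <= m; ++j) {
      double e_open = Hc[j - 1] + gap_open + gap_ext;
      double e_ext  = Ec[j - 1] + gap_ext;
      if (e_open >= e_ext) { Ec[j] = e_open; tbE[row + j] = 1; }
      else                 { Ec[j] = e_ext;  tbE[row + j] = 0; }
      double f_open = Hp[j] + gap_open + gap_ext;
      double f_ext  = Fp[j] + gap_ext;
      if (f_open >= f_ext) { Fc[j] = f_open; tbF[row + j] = 1; }
      else                 { Fc[j] = f_ext;  tbF[row + j] = 0; }
      double diag = Hp[j - 1] + sub[(size_t)(i - 1) * m + (j - 1)];
      double h = diag; unsigned char t = 1;
      if (Ec[j] > h) { h = Ec[j]; t = 2; }
      if (Fc[j] > h) { h = Fc[j]; t = 3; }
      Hc[j] = h; tbH[row + j] = t;
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  // traceback
  std::vector<int> ops;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 1) { ops.push_back(1); --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tbE[idx];
      ops.push_back(3); --j;
      if (t == 1) state = 0;
    } else {
      unsigned char t = tbF[idx];
      ops.push_back(2); --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
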