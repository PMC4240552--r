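#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming kernels for the builtin profile backend.
// Sequences are passed as 1-based integer residue codes; substitution
// matrices and profile score tables are indexed with those codes.

// Affine-gap global alignment (Needleman-Wunsch / Gotoh). Scores in the
// units of `sub`; gap penalties positive. Traceback preference:
// diagonal, then gap in seq2 (consume seq1), then gap in seq1.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector s1, IntegerVector s2, NumericMatrix sub,
              double gap_open, double gap_extend) {
  const int n = s1.size(), m = s2.size();
  const double NEG = -1e30;
  // M: end in match; X: gap in s2 (s1 consumed); Y: gap in s1 (s2 consumed)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_extend * (i - 1);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_extend * (j - 1);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(s1[i - 1] - 1, s2[j - 1] - 1);
      double best = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + s;
      X(i, j) = std::max(M(i - 1, j) - gap_open, X(i - 1, j) - gap_extend);
      Y(i, j) = std::max(M(i, j - 1) - gap_open, Y(i, j - 1) - gap_extend);
    }
  }
  double score = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback
  std::vector<int> a1, a2; // 0 = gap, else residue code
  int i = n, j = m;
  int state; // 0 = M, 1 = X, 2 = Y; preference order M, X, Y
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      double prev = M(i, j) - sub(s1[i - 1] - 1, s2[j - 1] - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - prev) < 1e-6 && M(i, j) > NEG / 2) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-6 && X(i, j) > NEG / 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      a1.push_back(s1[i - 1]); a2.push_back(0);
      bool from_m = std::abs(X(i, j) - (M(i - 1, j) - gap_open)) < 1e-6;
      --i;
      state = from_m ? 0 : 1;
    } else {
      a1.push_back(0); a2.push_back(s2[j - 1]);
      bool from_m = std::abs(Y(i, j) - (M(i, j - 1) - gap_open)) < 1e-6;
      --j;
      state = from_m ? 0 : 2;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["score"] = score,
                      _["aligned1"] = IntegerVector(a1.begin(), a1.end()),
                      _["aligned2"] = IntegerVector(a2.begin(), a2.end()));
}

// Batch of global alignment scores of one sequence against many (center
// selection for the star alignment).
// [[Rcpp::export(name = ".nw_score_matrix")]]
NumericMatrix nw_score_matrix(List seqs, NumericMatrix sub,
                              double gap_open, double gap_extend) {
  const int k = seqs.size();
  NumericMatrix out(k, k);
  const double NEG = -1e30;
  for (int a = 0; a < k; ++a) {
    IntegerVector s1 = seqs[a];
    for (int b = a + 1; b < k; ++b) {
      IntegerVector s2 = seqs[b];
      const int n = s1.size(), m = s2.size();
      std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1), Mc(m + 1), Xc(m + 1), Yc(m + 1);
      Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
      for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG; Xp[j] = NEG; Yp[j] = -gap_open - gap_extend * (j - 1);
      }
      for (int i = 1; i <= n; ++i) {
        Mc[0] = NEG; Yc[0] = NEG; Xc[0] = -gap_open - gap_extend * (i - 1);
        for (int j = 1; j <= m; ++j) {
          double s = sub(s1[i - 1] - 1, s2[j - 1] - 1);
          Mc[j] = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) + s;
          Xc[j] = std::max(Mp[j] - gap_open, Xp[j] - gap_extend);
          Yc[j] = std::max(Mc[j - 1] - gap_open, Yc[j - 1] - gap_extend);
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
      }
      double sc = std::max(Mp[m], std::max(Xp[m], Yp[m]));
      out(a, b) = sc; out(b, a) = sc;
    }
  }
  return out;
}

// Local (Smith-Waterman-style) alignment of a sequence against the match
// columns of a position-specific score table (L x K, bits). Affine gaps.
// Traceback preference: diagonal, then gap in the sequence (consume a
// profile column), then gap in the profile (consume a residue).
// Returns the optimal score (floored at 0) and the aligned spans.
// [[Rcpp::export(name = ".sw_profile")]]
List sw_profile(NumericMatrix scores, IntegerVector seq,
                double gap_open, double gap_extend) {
  const int L = scores.nrow(), m = seq.size();
  const double NEG = -1e30;
  NumericMatrix M(L + 1, m + 1), X(L + 1, m + 1), Y(L + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; X(0, j) = NEG; Y(0, j) = NEG; }
  for (int i = 0; i <= L; ++i) { M(i, 0) = 0; X(i, 0) = NEG; Y(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = scores(i - 1, seq[j - 1] - 1);
      double d = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                          Y(i - 1, j - 1));
      M(i, j) = std::max(0.0, d + s);
      // X: gap in sequence (profile column i consumed, no residue)
      X(i, j) = std::max(M(i - 1, j) - gap_open, X(i - 1, j) - gap_extend);
      // Y: gap in profile (residue j consumed, no column)
      Y(i, j) = std::max(M(i, j - 1) - gap_open, Y(i, j - 1) - gap_extend);
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  int pi_end = bi, pj_end = bj;
  int i = bi, j = bj, state = 0;
  // traceback from the best M cell until a zero M cell
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M(i, j) <= 0.0) break;
      double s = scores(i - 1, seq[j - 1] - 1);
      double prev = M(i, j) - s;
      --i; --j;
      if (std::abs(M(i, j) - prev) < 1e-6) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-6) state = 1;
      else state = 2;
      if (state == 0 && M(i, j) <= 0.0) break;
    } else if (state == 1) {
      bool from_m = std::abs(X(i, j) - (M(i - 1, j) - gap_open)) < 1e-6;
      --i;
      state = from_m ? 0 : 1;
    } else {
      bool from_m = std::abs(Y(i, j) - (M(i, j - 1) - gap_open)) < 1e-6;
      --j;
      state = from_m ? 0 : 2;
    }
  }
  int pi_start = i + 1, pj_start = j + 1;
  if (best <= 0.0) { pi_start = pj_start = 1; pi_end = pj_end = 0; }
  return List::create(_["score"] = best,
                      _["prof_start"] = pi_start, _["prof_end"] = pi_end,
                      _["seq_start"] = pj_start, _["seq_end"] = pj_end);
}

// Score many integer-coded sequences against one profile table; scores only
// (used for Gumbel calibration of the null distribution).
// [[Rcpp::export(name = ".sw_profile_scores")]]
NumericVector sw_profile_scores(NumericMatrix scores, List seqs,
                                double gap_open, double gap_extend) {
  const int n = seqs.size();
  const int L = scores.nrow();
  NumericVector out(n);
  const double NEG = -1e30;
  for (int q = 0; q < n; ++q) {
    IntegerVector seq = seqs[q];
    const int m = seq.size();
    std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
    std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
      for (int j = 1; j <= m; ++j) {
        double s = scores(i - 1, seq[j - 1] - 1);
        double d = std::max(std::max(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
        Mc[j] = std::max(0.0, d + s);
        Xc[j] = std::max(Mp[j] - gap_open, Xp[j] - gap_extend);
        Yc[j] = std::max(Mc[j - 1] - gap_open, Yc[j - 1] - gap_extend);
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[q] = best;
  }
  return out;
}
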