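#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of a residue-indexed sequence against a
// position-specific scoring model with affine gap penalties (Gotoh).
//
// score:  L_model x 20 matrix of per-column residue scores (bits).
// seq:    0-based residue indices; negative = unknown residue (scores 0).
// gap_open / gap_extend: positive penalties, subtracted.
//
// Returns the single best local alignment: its score, the matched
// (model column, sequence position) pairs (1-based), and the aligned
// sequence span.  Ties are resolved to the first cell in row-major
// (model-column major) order, which makes the scan deterministic.
// [[Rcpp::export(name = ".sw_scan_one")]]
List sw_scan_one(NumericMatrix score, IntegerVector seq,
                 double gap_open, double gap_extend) {
  const int M = score.nrow();   // model columns
  const int N = seq.size();     // sequence length
  const double NEG = -1e30;

  // DP matrices, (M+1) x (N+1), flattened.
  std::vector<double> H((M + 1) * (N + 1), 0.0);
  std::vector<double> E((M + 1) * (N + 1), NEG);  // gap in model (insertion)
  std::vector<double> F((M + 1) * (N + 1), NEG);  // gap in sequence (deletion)
  // traceback for H: 0 stop, 1 diagonal, 2 from E, 3 from F
  std::vector<unsigned char> TH((M + 1) * (N + 1), 0);
  // traceback for E/F: 1 = opened from H, 0 = extension
  std::vector<unsigned char> TE((M + 1) * (N + 1), 0);
  std::vector<unsigned char> TF((M + 1) * (N + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= M; ++i) {
    for (int j = 1; j <= N; ++j) {
      const int idx = i * (N + 1) + j;
      const int up = (i - 1) * (N + 1) + j;
      const int left = i * (N + 1) + (j - 1);
      const int diag = (i - 1) * (N + 1) + (j - 1);

      double e_open = H[left] - gap_open;
      double e_ext  = E[left] - gap_extend;
      E[idx] = (e_open >= e_ext) ? (TE[idx] = 1, e_open) : (TE[idx] = 0, e_ext);

      double f_open = H[up] - gap_open;
      double f_ext  = F[up] - gap_extend;
      F[idx] = (f_open >= f_ext) ? (TF[idx] = 1, f_open) : (TF[idx] = 0, f_ext);

      const int r = seq[j - 1];
      const double s = (r >= 0) ? score(i - 1, r) : 0.0;
      double h = H[diag] + s;
      unsigned char t = 1;
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      if (h <= 0.0) { h = 0.0; t = 0; }
      H[idx] = h;
      TH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> mcols, spos;
  int i = bi, j = bj;
  int state = 0;  // 0 = in H
  while (i > 0 && j > 0) {
    const int idx = i * (N + 1) + j;
    if (state == 0) {
      unsigned char t = TH[idx];
      if (t == 0) break;
      if (t == 1) {
        mcols.push_back(i);
        spos.push_back(j);
        --i; --j;
      } else if (t == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {     // in E: consumes sequence position
      unsigned char t = TE[idx];
      --j;
      if (t == 1) state = 0;
    } else {                     // in F: consumes model column
      unsigned char t = TF[idx];
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(mcols.begin(), mcols.end());
  std::reverse(spos.begin(), spos.end());

  int seq_start = spos.empty() ? 0 : spos.front();
  int seq_end = spos.empty() ? 0 : spos.back();

  return List::create(
    _["score"] = best,
    _["model_cols"] = wrap(mcols),
    _["seq_pos"] = wrap(spos),
    _["seq_start"] = seq_start,
    _["seq_end"] = seq_end);
}
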