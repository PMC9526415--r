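#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// Exhaustive terminal-inverted-repeat search.
//
// seq: uppercase DNA. Candidate left repeats lie entirely in
// [l0, center_start); right repeats entirely in [r0, r1) with
// r0 >= center_end (all 0-based half-open). A pair (i, j, L) qualifies when
// seq[i, i+L) equals the reverse complement of seq[j, j+L) up to
// allowed[L - min_len] mismatches and (j + L) - i <= max_span.
// Objective: maximize L, then minimize mismatches, then smallest i, then
// smallest j. Returns (i, j, L, mismatches) or an empty vector.

// [[Rcpp::export]]
IntegerVector tir_scan_cpp(std::string seq, int center_start, int center_end,
                           int l0, int r0, int r1, int min_len, int max_len,
                           int max_span, IntegerVector allowed) {
  const int n = (int)seq.size();
  if (l0 < 0) l0 = 0;
  if (r0 < center_end) r0 = center_end;
  if (r1 > n) r1 = n;
  int best_L = -1, best_mm = 0, best_i = -1, best_j = -1;

  for (int L = max_len; L >= min_len; --L) {
    const int max_mm = allowed[L - min_len];
    const int l_last = center_start - L;
    for (int i = l0; i <= l_last; ++i) {
      const int j_hi = std::min(r1 - L, i + max_span - L);
      for (int j = r0; j <= j_hi; ++j) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (seq[i + k] != comp(seq[j + L - 1 - k])) {
            if (++mm > max_mm) break;
          }
        }
        if (mm <= max_mm && (best_i < 0 || mm < best_mm)) {
          best_L = L; best_mm = mm; best_i = i; best_j = j;
        }
      }
      if (best_i >= 0 && best_mm == 0) break;  // earliest i with perfect pair
    }
    if (best_i >= 0) break;  // longest length wins
  }

  if (best_i < 0) return IntegerVector(0);
  return IntegerVector::create(best_i, best_j, best_L, best_mm);
}
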