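#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// q, s: 1-based integer codes indexing rows/cols of the substitution matrix.
// A gap of length k costs gap_open + k * gap_extend (BLAST convention: with
// open 11 / extend 1 a length-1 gap costs 12).
//
// The optimum ends in the match state; ties are broken by the smallest
// (query row, subject col). Traceback reports 1-based aligned spans.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  const int gop = gap_open + gap_extend;  // cost of opening a length-1 gap

  // full matrices for traceback; (n+1) x (m+1)
  std::vector<int> M((n + 1) * (m + 1), 0);
  std::vector<int> Ix((n + 1) * (m + 1), NEG);  // gap in subject (consume query)
  std::vector<int> Iy((n + 1) * (m + 1), NEG);  // gap in query (consume subject)
  const int W = m + 1;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, left = i * W + j - 1,
                diag = (i - 1) * W + j - 1;
      int ix = std::max(M[up] - gop, Ix[up] - gap_extend);
      int iy = std::max(M[left] - gop, Iy[left] - gap_extend);
      int prev = std::max(0, std::max(M[diag], std::max(Ix[diag], Iy[diag])));
      int sc = prev + sub(qi, s[j - 1] - 1);
      if (sc < 0) sc = 0;
      M[idx] = sc;
      Ix[idx] = ix;
      Iy[idx] = iy;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }

  if (best == 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);

  // traceback from (bi, bj) in state M until the local alignment starts
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    int idx = i * W + j;
    if (state == 0) {
      int diag = (i - 1) * W + j - 1;
      int here = M[idx] - sub(q[i - 1] - 1, s[j - 1] - 1);
      qs = i; ss = j;
      if (here == 0) break;  // alignment starts here
      if (here == M[diag]) state = 0;
      else if (here == Ix[diag]) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      int up = (i - 1) * W + j;
      if (Ix[idx] == M[up] - gop) state = 0; else state = 1;
      --i;
    } else {
      int left = i * W + j - 1;
      if (Iy[idx] == M[left] - gop) state = 0; else state = 2;
      --j;
    }
  }

  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = bi,
                      _["s_start"] = ss, _["s_end"] = bj);
}
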