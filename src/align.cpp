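#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Global (Needleman-Wunsch) protein alignment with affine gap penalties,
// three-state Gotoh recursion.  A gap of length L costs gapOpen + L * gapExt.
//
// States: 0 = M  (a[i] aligned to b[j], "diagonal")
//         1 = Ix (a[i] aligned to a gap in b, "up")
//         2 = Iy (b[j] aligned to a gap in a, "left")
//
// Determinism: every argmax is taken in state order M, Ix, Iy with strict
// improvement, so ties resolve diagonal > up > left both in the recursion
// and in the traceback.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector ai, IntegerVector bi, IntegerMatrix smat,
                 int gapOpen, int gapExt) {
  const int na = ai.size(), nb = bi.size();
  const int ncol = nb + 1;
  const int nalpha = smat.nrow();
  // flat copies for fast inner-loop access
  std::vector<int> S(nalpha * nalpha);
  for (int c = 0; c < nalpha; ++c)
    for (int r = 0; r < nalpha; ++r) S[r * nalpha + c] = smat(r, c);
  std::vector<int> av(na), bv(nb);
  for (int i = 0; i < na; ++i) av[i] = ai[i] - 1;
  for (int j = 0; j < nb; ++j) bv[j] = bi[j] - 1;
  // score + traceback (previous state) per state
  std::vector<int> M((na + 1) * ncol, NEG_INF), Ix((na + 1) * ncol, NEG_INF),
      Iy((na + 1) * ncol, NEG_INF);
  std::vector<signed char> pM((na + 1) * ncol, -1), pIx((na + 1) * ncol, -1),
      pIy((na + 1) * ncol, -1);

  M[0] = 0;
  for (int i = 1; i <= na; ++i) {
    Ix[i * ncol] = -(gapOpen + i * gapExt);
    pIx[i * ncol] = 1;
  }
  pIx[ncol] = 0;  // first gap column opens from M
  for (int j = 1; j <= nb; ++j) {
    Iy[j] = -(gapOpen + j * gapExt);
    pIy[j] = 2;
  }
  pIy[1] = 0;

  const int openExt = gapOpen + gapExt;
  for (int i = 1; i <= na; ++i) {
    const int *srow = &S[av[i - 1] * nalpha];
    int *Mr = &M[i * ncol], *Ixr = &Ix[i * ncol], *Iyr = &Iy[i * ncol];
    const int *Mp = &M[(i - 1) * ncol], *Ixp = &Ix[(i - 1) * ncol],
        *Iyp = &Iy[(i - 1) * ncol];
    signed char *pMr = &pM[i * ncol], *pIxr = &pIx[i * ncol],
        *pIyr = &pIy[i * ncol];
    for (int j = 1; j <= nb; ++j) {
      const int s = srow[bv[j - 1]];

      // M: from any state at (i-1, j-1); ties prefer M > Ix > Iy
      int best = Mp[j - 1];
      signed char from = 0;
      if (Ixp[j - 1] > best) { best = Ixp[j - 1]; from = 1; }
      if (Iyp[j - 1] > best) { best = Iyp[j - 1]; from = 2; }
      Mr[j] = best + s;
      pMr[j] = from;

      // Ix: consume a[i], gap in b; opening from M/Iy costs gapOpen+gapExt
      best = Mp[j] - openExt; from = 0;
      if (Ixp[j] - gapExt > best) { best = Ixp[j] - gapExt; from = 1; }
      if (Iyp[j] - openExt > best) { best = Iyp[j] - openExt; from = 2; }
      Ixr[j] = best; pIxr[j] = from;

      // Iy: consume b[j], gap in a
      best = Mr[j - 1] - openExt; from = 0;
      if (Ixr[j - 1] - openExt > best) { best = Ixr[j - 1] - openExt;
                                         from = 1; }
      if (Iyr[j - 1] - gapExt > best) { best = Iyr[j - 1] - gapExt;
                                        from = 2; }
      Iyr[j] = best; pIyr[j] = from;
    }
  }

  const int end = na * ncol + nb;
  int state = 0, score = M[end];
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }

  // traceback: collect moves from the end
  std::vector<int> outA, outB;  // 0 = gap, else 1-based input position
  outA.reserve(na + nb); outB.reserve(na + nb);
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pM[i * ncol + j];
      outA.push_back(i); outB.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = pIx[i * ncol + j];
      outA.push_back(i); outB.push_back(0);
      --i;
    } else {
      prev = pIy[i * ncol + j];
      outA.push_back(0); outB.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(outA.begin(), outA.end());
  std::reverse(outB.begin(), outB.end());

  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(outA.begin(), outA.end()),
                      _["b_pos"] = IntegerVector(outB.begin(), outB.end()));
}
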