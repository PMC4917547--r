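#include <Rcpp.h>
using namespace Rcpp;

// Sequential fibroblast movement in the given (already randomized) order:
// each mover relocates to a uniformly random empty Moore neighbour, or stays
// when fully surrounded. Uses R's RNG so runs stay seed-reproducible.
// [[Rcpp::export]]
List move_cells_cpp(IntegerMatrix occupancy, IntegerVector ci, IntegerVector cj,
                    IntegerVector movers, int nx, int ny) {
  IntegerMatrix occ = clone(occupancy);
  IntegerVector i2 = clone(ci), j2 = clone(cj);
  static const int DI[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int DJ[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int cand[8];
  for (int m = 0; m < movers.size(); ++m) {
    int id = movers[m];            // 1-based cell id
    int i = i2[id - 1], j = j2[id - 1];
    int nfree = 0;
    for (int q = 0; q < 8; ++q) {
      int ii = i + DI[q], jj = j + DJ[q];
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) continue;
      int lin = (ii - 1) + nx * (jj - 1);
      if (occ[lin] == 0) cand[nfree++] = lin;
    }
    if (nfree == 0) continue;
    int pick = cand[nfree == 1 ? 0 : (int)(unif_rand() * nfree)];
    occ[(i - 1) + nx * (j - 1)] = 0;
    occ[pick] = id;
    i2[id - 1] = pick % nx + 1;
    j2[id - 1] = pick / nx + 1;
  }
  return List::create(_["occupancy"] = occ, _["ci"] = i2, _["cj"] = j2);
}
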