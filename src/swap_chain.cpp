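#include <Rcpp.h>
using namespace Rcpp;

// Margin-preserving swap randomization of a binary matrix.
//
// The chain proposes a random pair of rows and a random pair of columns;
// when the 2x2 submatrix is a checkerboard (10/01 or 01/10) the two
// configurations are exchanged, preserving every row and column sum.
// Counting every proposal as a step gives a symmetric chain whose
// stationary distribution is uniform over all 0/1 matrices with the
// observed margins.
//
// Returns an n_draws x n_pairs integer matrix of co-occurrence counts
// (number of columns where both paired rows are 1), sampled every
// `thin` accepted-or-rejected proposals after `burn` initial proposals.
// Uses R's RNG so results are reproducible under set.seed().
// One realization of the swap chain: n_steps proposals from `mat`.
// [[Rcpp::export]]
IntegerMatrix swap_chain_step(IntegerMatrix mat, double n_steps) {
  int nr = mat.nrow(), nc = mat.ncol();
  IntegerMatrix m = clone(mat);
  if (nr < 2 || nc < 2) stop("matrix must be at least 2x2");
  RNGScope scope;
  for (double i = 0; i < n_steps; i++) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a + d == 2 && b + c == 0) {
      m(r1, c1) = 0; m(r2, c2) = 0; m(r1, c2) = 1; m(r2, c1) = 1;
    } else if (a + d == 0 && b + c == 2) {
      m(r1, c1) = 1; m(r2, c2) = 1; m(r1, c2) = 0; m(r2, c1) = 0;
    }
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix swap_null_cooc(IntegerMatrix mat, IntegerVector pair_a,
                             IntegerVector pair_b, int n_draws,
                             double burn, double thin) {
  int nr = mat.nrow(), nc = mat.ncol();
  int np = pair_a.size();
  IntegerMatrix m = clone(mat);
  IntegerMatrix out(n_draws, np);
  if (nr < 2 || nc < 2) stop("matrix must be at least 2x2");

  RNGScope scope;
  auto step = [&]() {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a + d == 2 && b + c == 0) {         // 1 0 / 0 1  ->  0 1 / 1 0
      m(r1, c1) = 0; m(r2, c2) = 0; m(r1, c2) = 1; m(r2, c1) = 1;
    } else if (a + d == 0 && b + c == 2) {  // 0 1 / 1 0  ->  1 0 / 0 1
      m(r1, c1) = 1; m(r2, c2) = 1; m(r1, c2) = 0; m(r2, c1) = 0;
    }
  };

  for (double i = 0; i < burn; i++) step();
  for (int d = 0; d < n_draws; d++) {
    for (double i = 0; i < thin; i++) step();
    for (int p = 0; p < np; p++) {
      int ra = pair_a[p], rb = pair_b[p], cnt = 0;
      for (int j = 0; j < nc; j++) cnt += m(ra, j) & m(rb, j);
      out(d, p) = cnt;
    }
    if (d % 256 == 0) checkUserInterrupt();
  }
  return out;
}
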