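#include <Rcpp.h>
using namespace Rcpp;

// Kawasaki exchange Monte Carlo on a fixed site lattice.
//
// Sites are sorted by leaflet: [0, n_inner) inner, [n_inner, n) outer.
// Moves swap the species labels of two random sites of the same leaflet
// and are accepted with the Metropolis rule at kT = 1 (energies are
// pre-scaled by the caller). Site energies are an S x N matrix E(s, i).
// Uses R's RNG so runs are reproducible under set.seed().
//
// [[Rcpp::export]]
List mc_sort_kernel(IntegerVector labels0, NumericMatrix energy,
                    int n_inner, int n_sweeps, int record_every) {
  const int n = labels0.size();
  const int n_outer = n - n_inner;
  std::vector<int> lab(labels0.begin(), labels0.end()); // 0-based species
  const double p_inner = (double)n_inner / n;

  int n_frames = n_sweeps / record_every + 1;
  IntegerMatrix frames(n_frames, n);
  IntegerVector frame_sweep(n_frames);
  for (int i = 0; i < n; ++i) frames(0, i) = lab[i] + 1;
  frame_sweep[0] = 0;
  int fi = 1;

  double accepted = 0.0, attempted = 0.0;
  RNGScope scope;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i, j;
      if (unif_rand() < p_inner) {
        i = (int)(unif_rand() * n_inner); if (i >= n_inner) i = n_inner - 1;
        j = (int)(unif_rand() * n_inner); if (j >= n_inner) j = n_inner - 1;
      } else {
        i = n_inner + (int)(unif_rand() * n_outer);
        j = n_inner + (int)(unif_rand() * n_outer);
        if (i >= n) i = n - 1;
        if (j >= n) j = n - 1;
      }
      attempted += 1.0;
      int si = lab[i], sj = lab[j];
      if (si == sj) continue;
      double dE = energy(sj, i) + energy(si, j)
                - energy(si, i) - energy(sj, j);
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        lab[i] = sj; lab[j] = si;
        accepted += 1.0;
      }
    }
    if (sweep % record_every == 0 && fi < n_frames) {
      for (int i = 0; i < n; ++i) frames(fi, i) = lab[i] + 1;
      frame_sweep[fi] = sweep;
      ++fi;
    }
  }
  return List::create(_["frames"] = frames,
                      _["frame_sweep"] = frame_sweep,
                      _["acceptance"] = accepted / attempted);
}
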