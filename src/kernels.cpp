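#include <Rcpp.h>
using namespace Rcpp;

// Per-frame Gaussian structural-similarity sums.
//
// coords: n_atoms x 3 x n_frames array (Calpha coordinates per frame)
// ai, aj: 0-based atom indices of the scored residue pairs
// ref_d : reference distance per pair (native or all-pair reference), Angstrom
// denom : per-pair exponent denominator, i.e. 2*sigma_ij^2 (Q(NC)) or
//         sigma_ij^2 (q(similarity)) with sigma_ij = |i-j|^0.15
//
// Returns the raw per-frame sum; normalization is applied by the R caller.
// [[Rcpp::export]]
NumericVector cpp_gauss_score_series(NumericVector coords,
                                     IntegerVector ai, IntegerVector aj,
                                     NumericVector ref_d, NumericVector denom) {
  IntegerVector dims = coords.attr("dim");
  const int n_atoms = dims[0], n_frames = dims[2];
  const int n_pairs = ai.size();
  const double *c = coords.begin();
  NumericVector out(n_frames);
  const long frame_stride = (long)n_atoms * 3L;
  for (int f = 0; f < n_frames; ++f) {
    const double *cf = c + (long)f * frame_stride;
    double s = 0.0;
    for (int p = 0; p < n_pairs; ++p) {
      const int a = ai[p], b = aj[p];
      const double dx = cf[a] - cf[b];
      const double dy = cf[a + n_atoms] - cf[b + n_atoms];
      const double dz = cf[a + 2 * n_atoms] - cf[b + 2 * n_atoms];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double diff = ref_d[p] - r;
      s += std::exp(-(diff * diff) / denom[p]);
    }
    out[f] = s;
  }
  return out;
}

// Pairwise distances for an explicit pair list on a single n x 3 coordinate set.
// [[Rcpp::export]]
NumericVector cpp_pair_dists(NumericMatrix xyz, IntegerVector ai, IntegerVector aj) {
  const int n_pairs = ai.size();
  NumericVector out(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    const double dx = xyz(ai[p], 0) - xyz(aj[p], 0);
    const double dy = xyz(ai[p], 1) - xyz(aj[p], 1);
    const double dz = xyz(ai[p], 2) - xyz(aj[p], 2);
    out[p] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area.
//
// xyz    : n x 3 heavy-atom coordinates, Angstrom
// radii  : per-atom van der Waals radius
// probe  : probe radius (water: 1.4)
// sphere : m x 3 unit sphere point set (deterministic golden spiral from R)
//
// Per-atom accessible area = (exposed points / m) * 4*pi*(r_i + probe)^2.
// Returns the per-atom area vector; sum gives the total SASA.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii, double probe,
                       NumericMatrix sphere) {
  const int n = xyz.nrow(), m = sphere.nrow();
  NumericVector area(n);
  std::vector<double> rext(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    rext[i] = radii[i] + probe;
    if (rext[i] > rmax) rmax = rext[i];
  }
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double ri = rext[i];
    const double reach = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double cut = ri + rext[j];
      if (d2 < cut * cut && d2 < reach * reach) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xyz(i, 0) + ri * sphere(k, 0);
      const double py = xyz(i, 1) + ri * sphere(k, 1);
      const double pz = xyz(i, 2) + ri * sphere(k, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rext[j] * rext[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)exposed / (double)m;
  }
  return area;
}
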