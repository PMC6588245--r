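#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Delayed-embedding coordinate k of point i for series x, lag tau.
static inline double emb(const NumericVector& x, int i, int k, int tau) {
  return x[i + k * tau];
}

// Squared Euclidean distance between embedded points i and j in dimension d.
static inline double dist2(const NumericVector& x, int i, int j, int d, int tau) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = emb(x, i, k, tau) - emb(x, j, k, tau);
    s += diff * diff;
  }
  return s;
}

// Pair counts for delayed sample entropy: B = template pairs matching at
// length m, A = matching at length m+1, Chebyshev distance, tolerance r,
// self-matches excluded. Both counts use the index set for which the
// (m+1)-length template exists, so A/B is a proper conditional probability.
// A sort on the first coordinate restricts the quadratic scan to pairs
// already within r there; the counts are exact.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, int tau, double r) {
  const int n = x.size();
  const int nt = n - m * tau;          // templates extendable to m+1
  if (nt < 2) return NumericVector::create(0.0, 0.0);

  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (x[j] - x[i] > r) break;      // sorted: no later j can match

      bool match_m = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(emb(x, i, k, tau) - emb(x, j, k, tau)) > r) {
          match_m = false;
          break;
        }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(emb(x, i, m, tau) - emb(x, j, m, tau)) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Fraction of false nearest neighbours at embedding dimension d (lag tau).
// Neighbours are searched among all points whose (d+1)-dimensional
// extension exists, excluding |i - j| <= theiler; ref_idx (0-based)
// selects the reference points scored. sigma is the series SD used by the
// loneliness (atol) criterion. Returns NA when no reference point has an
// admissible neighbour.
// [[Rcpp::export]]
double cpp_fnn_fraction(NumericVector x, int tau, int d, double rtol,
                        double atol, int theiler, IntegerVector ref_idx,
                        double sigma) {
  const int n = x.size();
  const int npts = n - d * tau;        // valid for the (d+1)-th coordinate
  if (npts < 2) return NA_REAL;

  int scored = 0, false_nn = 0;
  for (int ri = 0; ri < ref_idx.size(); ++ri) {
    const int i = ref_idx[ri];
    if (i >= npts) continue;
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j < npts; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double s = 0.0;                  // early-abandoned partial distance
      int k = 0;
      for (; k < d; ++k) {
        double diff = emb(x, i, k, tau) - emb(x, j, k, tau);
        s += diff * diff;
        if (s >= best) break;
      }
      if (k == d && s < best) { best = s; jbest = j; }
    }
    if (jbest < 0) continue;
    const double Rd = std::sqrt(best);
    const double e = std::fabs(emb(x, i, d, tau) - emb(x, jbest, d, tau));
    // guard the ratio test against numerically-degenerate duplicates
    // (e.g. exactly periodic signals): distances at double rounding level
    // carry no geometric information
    const double floor_d = 1e-8 * sigma;
    const bool isfalse = (e / std::max(Rd, floor_d) > rtol) ||
                         (std::sqrt(Rd * Rd + e * e) / sigma > atol);
    ++scored;
    if (isfalse) ++false_nn;
  }
  if (scored == 0) return NA_REAL;
  return (double)false_nn / (double)scored;
}

// Wolf fiducial-trajectory largest Lyapunov exponent, in nats per sample.
// From the start of the embedded series, a neighbour with separation in
// [min_sep, max_sep] (temporal exclusion `theiler`) is tracked for
// `evolve` samples; ln(d'/d) is accumulated (separations clamped below at
// the min_sep noise floor). When the separation exceeds max_sep the
// neighbour is replaced by the candidate inside the probe annulus that
// minimises the change in orientation of the separation vector; if the
// annulus is empty, the closest admissible point above the noise floor is
// taken, and failing that the current neighbour is kept.
// [[Rcpp::export]]
double cpp_wolf_lye(NumericVector x, int tau, int dim, int evolve,
                    double min_sep, double max_sep, int theiler) {
  const int n = x.size();
  const int npts = n - (dim - 1) * tau;
  if (npts < evolve + 2) stop("series too short for Wolf estimation");

  // Replacement search for fiducial point i. Among candidates inside the
  // probe annulus [min_sep, max_sep] (temporal exclusion applied), prefer
  // the closest point whose separation vector deviates < 30 degrees from
  // the current one (dir); failing that, the smallest angular deviation
  // in the annulus; failing that, the nearest point above the noise
  // floor. dir may be null (initial search): then simply the nearest
  // point in the annulus.
  const double cone = 30.0 * M_PI / 180.0;
  std::vector<double> dirv(dim);
  auto search = [&](int i, const double* dir, int exclude) -> int {
    double best_cone = R_PosInf, best_ang = R_PosInf, best_any = R_PosInf;
    int jb_cone = -1, jb_ang = -1, jb_any = -1;
    double dirnorm = 0.0;
    if (dir) {
      for (int k = 0; k < dim; ++k) dirnorm += dir[k] * dir[k];
      dirnorm = std::sqrt(dirnorm);
      if (dirnorm == 0.0) dir = nullptr;
    }
    const double max2 = max_sep * max_sep;
    for (int j = 0; j < npts - evolve; ++j) {
      if (std::abs(i - j) <= theiler || j == exclude) continue;
      // abandon once the partial distance is useless both as an annulus
      // member and as the nearest fallback
      double s = 0.0;
      double bound = std::max(max2, best_any * best_any);
      int k = 0;
      for (; k < dim; ++k) {
        double diff = emb(x, j, k, tau) - emb(x, i, k, tau);
        s += diff * diff;
        if (s > bound) break;
      }
      if (k < dim) continue;
      double dd = std::sqrt(s);
      if (dd < min_sep) continue;
      if (dd < best_any) { best_any = dd; jb_any = j; }
      if (dd > max_sep) continue;
      if (dir) {
        double dot = 0.0;
        for (int k = 0; k < dim; ++k)
          dot += dir[k] * (emb(x, j, k, tau) - emb(x, i, k, tau));
        double c = dot / (dd * dirnorm);
        double ang = std::acos(std::max(-1.0, std::min(1.0, c)));
        if (ang < cone && dd < best_cone) { best_cone = dd; jb_cone = j; }
        if (ang < best_ang) { best_ang = ang; jb_ang = j; }
      } else if (dd < best_cone) { // no orientation yet: nearest in annulus
        best_cone = dd; jb_cone = j;
      }
    }
    if (jb_cone >= 0) return jb_cone;
    if (jb_ang >= 0) return jb_ang;
    return jb_any;
  };

  int i = 0;
  int j = search(0, nullptr, 0);
  if (j < 0) stop("no admissible neighbour found (degenerate series?)");
  double sum_log = 0.0;
  long steps = 0;

  while (i + evolve < npts) {
    if (j + evolve >= npts) {
      // neighbour ran off the data: replace it and keep the fiducial going
      for (int k = 0; k < dim; ++k)
        dirv[k] = emb(x, j, k, tau) - emb(x, i, k, tau);
      int jn = search(i, dirv.data(), j);
      if (jn < 0) break;
      j = jn;
    }
    double d0 = std::max(std::sqrt(dist2(x, i, j, dim, tau)), min_sep);
    double d1 = std::max(std::sqrt(dist2(x, i + evolve, j + evolve, dim, tau)),
                         min_sep);
    sum_log += std::log(d1 / d0);
    steps += evolve;
    i += evolve;
    j += evolve;
    if (d1 > max_sep && i + evolve < npts && j + evolve < npts) {
      for (int k = 0; k < dim; ++k)
        dirv[k] = emb(x, j, k, tau) - emb(x, i, k, tau);
      int jn = search(i, dirv.data(), j);
      if (jn >= 0) j = jn;
    }
  }
  if (steps == 0) stop("no divergence steps accumulated");
  return sum_log / (double)steps;
}

// Mutual-information profile over lags 1..max_lag from pre-binned symbol
// sequences (values 1..bins). Returns nats.
// [[Rcpp::export]]
NumericVector cpp_ami_profile(IntegerVector ix, int bins, int max_lag) {
  const int n = ix.size();
  NumericVector out(max_lag);
  std::vector<double> joint(bins * bins), p1(bins), p2(bins);
  for (int lag = 1; lag <= max_lag; ++lag) {
    const int np = n - lag;
    std::fill(joint.begin(), joint.end(), 0.0);
    std::fill(p1.begin(), p1.end(), 0.0);
    std::fill(p2.begin(), p2.end(), 0.0);
    const double inv = 1.0 / np;
    for (int t = 0; t < np; ++t) {
      const int a = ix[t] - 1, b = ix[t + lag] - 1;
      joint[a + bins * b] += inv;
      p1[a] += inv;
      p2[b] += inv;
    }
    double mi = 0.0;
    for (int a = 0; a < bins; ++a) {
      for (int b = 0; b < bins; ++b) {
        const double j = joint[a + bins * b];
        if (j > 0.0) mi += j * std::log(j / (p1[a] * p2[b]));
      }
    }
    out[lag - 1] = mi;
  }
  return out;
}
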