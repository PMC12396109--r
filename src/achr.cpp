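#include <Rcpp.h>
using namespace Rcpp;

// Artificial-centering hit-and-run core.
//
// The direction pool is the warmup vertex set plus every sample recorded
// so far; the centering point is the running mean over all chain
// iterates. Each step draws a pool point, walks from the current point
// along (point - center) to a uniform position on the feasible segment
// (bounds only: both endpoints of the direction lie in the steady-state
// affine subspace, so S v = 0 is preserved), and records every
// `thinning`-th iterate. Uses R's RNG, so runs are reproducible from the
// R-side seed.
//
// Rounding error orthogonal to the steady-state subspace is amplified
// geometrically by the centering feedback, so the point and the center
// are re-projected onto the null space of S (projector P) every
// `proj_every` steps and before every record.
//
// [[Rcpp::export]]
List achr_core(NumericMatrix warmup, NumericMatrix recorded_prev,
               NumericVector current, NumericVector center,
               double center_count, int n_record, int thinning,
               NumericVector lb, NumericVector ub, NumericMatrix P,
               int proj_every = 50) {
  const int n = current.size();
  const int n_warm = warmup.nrow();
  const int n_prev = recorded_prev.nrow();
  NumericMatrix out(n_record, n);
  std::vector<double> v(current.begin(), current.end());
  std::vector<double> cen(center.begin(), center.end());
  std::vector<double> dir(n);
  const double dir_tol = 1e-12;

  std::vector<double> tmp(n);
  auto project = [&](std::vector<double>& x) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += P(i, j) * x[j];
      tmp[i] = s;
    }
    x.swap(tmp);
  };

  int recorded = 0;
  int step_in_thin = 0;
  int step_since_proj = 0;
  int consecutive_fail = 0;
  double cnt = center_count;

  while (recorded < n_record) {
    // pick a stored point: warmup, previously recorded, or this batch
    int pool = n_warm + n_prev + recorded;
    int idx = (int)std::floor(unif_rand() * pool);
    if (idx >= pool) idx = pool - 1;
    double nrm2 = 0.0;
    for (int j = 0; j < n; ++j) {
      double pj;
      if (idx < n_warm) pj = warmup(idx, j);
      else if (idx < n_warm + n_prev) pj = recorded_prev(idx - n_warm, j);
      else pj = out(idx - n_warm - n_prev, j);
      dir[j] = pj - cen[j];
      nrm2 += dir[j] * dir[j];
    }
    double nrm = std::sqrt(nrm2);
    if (nrm < dir_tol) {
      if (++consecutive_fail >= 1000)
        stop("hit-and-run: 1000 consecutive degenerate directions");
      continue;
    }
    for (int j = 0; j < n; ++j) dir[j] /= nrm;

    double tmin = -std::numeric_limits<double>::infinity();
    double tmax = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      if (dir[j] > dir_tol) {
        double hi = (ub[j] - v[j]) / dir[j];
        double lo = (lb[j] - v[j]) / dir[j];
        if (hi < tmax) tmax = hi;
        if (lo > tmin) tmin = lo;
      } else if (dir[j] < -dir_tol) {
        double hi = (lb[j] - v[j]) / dir[j];
        double lo = (ub[j] - v[j]) / dir[j];
        if (hi < tmax) tmax = hi;
        if (lo > tmin) tmin = lo;
      }
    }
    if (!(tmax - tmin > dir_tol)) {
      if (++consecutive_fail >= 1000)
        stop("hit-and-run: 1000 consecutive degenerate segments");
      continue;
    }
    consecutive_fail = 0;
    // t in [tmin, tmax] keeps v within bounds up to rounding; no
    // clamping: snapping to a bound would leave the steady-state subspace
    double t = tmin + unif_rand() * (tmax - tmin);
    for (int j = 0; j < n; ++j) {
      v[j] += t * dir[j];
      cen[j] = (cen[j] * cnt + v[j]) / (cnt + 1.0);
    }
    cnt += 1.0;

    if (++step_since_proj >= proj_every) {
      step_since_proj = 0;
      project(v);
      project(cen);
    }
    if (++step_in_thin == thinning) {
      step_in_thin = 0;
      project(v);
      for (int j = 0; j < n; ++j) out(recorded, j) = v[j];
      ++recorded;
    }
  }

  return List::create(_["samples"] = out,
                      _["current"] = NumericVector(v.begin(), v.end()),
                      _["center"] = NumericVector(cen.begin(), cen.end()),
                      _["center_count"] = cnt);
}
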