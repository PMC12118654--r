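// Low-level kernels for image segmentation and Monte-Carlo survival screening.
// All RNG goes through R's generator (unif_rand) so set.seed() governs results.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------- components

// Label connected components of a logical mask (true pixels). Labels are
// assigned in column-major scan order starting at 1; false pixels get 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const bool diag = (connectivity == 8);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (!diag && dr != 0 && dc != 0) continue;
            int qr = pr + dr, qc = pc + dc;
            if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
            if (mask(qr, qc) && !lab(qr, qc)) {
              lab(qr, qc) = next;
              stack.push_back(qc * nr + qr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// --------------------------------------------------------- distance transform

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance from each true pixel to the nearest false pixel.
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix sq(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      sq(r, c) = mask(r, c) ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {           // along rows (vertical pass)
    for (int r = 0; r < nr; ++r) f[r] = sq(r, c);
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) sq(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {           // horizontal pass
    for (int c = 0; c < nc; ++c) f[c] = sq(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) sq(r, c) = std::sqrt(d[c]);
  }
  return sq;
}

// Square-window maximum filter (radius r), used for local-maximum detection
// on distance transforms.
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(const NumericMatrix& x, int r) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int rw = 0; rw < nr; ++rw) {
      double m = -std::numeric_limits<double>::infinity();
      for (int dc = std::max(0, c - r); dc <= std::min(nc - 1, c + r); ++dc)
        for (int dr = std::max(0, rw - r); dr <= std::min(nr - 1, rw + r); ++dr)
          if (x(dr, dc) > m) m = x(dr, dc);
      out(rw, c) = m;
    }
  }
  return out;
}

// ------------------------------------------------------------------- voronoi

// Assign each foreground pixel to its nearest seed (Euclidean, pixel centers
// at integer 0-based coordinates). Ties resolved to the lowest seed index.
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_labels(const NumericVector& seed_r,
                                 const NumericVector& seed_c,
                                 const LogicalMatrix& fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  const int ns = seed_r.size();
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!fg(r, c)) continue;
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int s = 0; s < ns; ++s) {
        double dr = r - seed_r[s], dc = c - seed_c[s];
        double d = dr * dr + dc * dc;
        if (d < best) { best = d; bi = s + 1; }
      }
      lab(r, c) = bi;
    }
  }
  return lab;
}

// ------------------------------------------------------- nearest-neighbor NN

static double nn_mean_impl(const double* sr, const double* sc, int ns,
                           const double* tr, const double* tc, int nt) {
  // Mean over source points of the minimal non-zero distance to a target
  // point (coincident centroids excluded); sources with no valid target are
  // dropped; NA when none remain.
  const double eps2 = 1e-18;
  double acc = 0.0;
  int nvalid = 0;
  for (int i = 0; i < ns; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nt; ++j) {
      double dr = sr[i] - tr[j], dc = sc[i] - tc[j];
      double d = dr * dr + dc * dc;
      if (d > eps2 && d < best) best = d;
    }
    if (best < std::numeric_limits<double>::infinity()) {
      acc += std::sqrt(best);
      ++nvalid;
    }
  }
  if (nvalid == 0) return NA_REAL;
  return acc / nvalid;
}

// [[Rcpp::export]]
double cpp_nn_mean(const NumericMatrix& src, const NumericMatrix& tgt) {
  if (src.nrow() == 0 || tgt.nrow() == 0) return NA_REAL;
  return nn_mean_impl(&src(0, 0), &src(0, 1), src.nrow(),
                      &tgt(0, 0), &tgt(0, 1), tgt.nrow());
}

static void sample_idx(int n, int k, std::vector<int>& pool, std::vector<int>& out) {
  // Partial Fisher-Yates without replacement using R's RNG.
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// Permutation null for the mean nearest-neighbor distance: each repetition
// draws n_a source cells (and, unless self, independently n_b target cells)
// uniformly without replacement from all cell positions in scope.
// [[Rcpp::export]]
NumericVector cpp_perm_null(const NumericMatrix& pts, int n_a, int n_b,
                            bool self, int reps) {
  const int n = pts.nrow();
  NumericVector out(reps);
  std::vector<int> pool(n), ia(n_a), ib(n_b);
  std::vector<double> ar(n_a), ac(n_a), br(n_b), bc(n_b);
  for (int rep = 0; rep < reps; ++rep) {
    sample_idx(n, n_a, pool, ia);
    for (int i = 0; i < n_a; ++i) { ar[i] = pts(ia[i], 0); ac[i] = pts(ia[i], 1); }
    if (self) {
      out[rep] = nn_mean_impl(ar.data(), ac.data(), n_a, ar.data(), ac.data(), n_a);
    } else {
      sample_idx(n, n_b, pool, ib);
      for (int i = 0; i < n_b; ++i) { br[i] = pts(ib[i], 0); bc[i] = pts(ib[i], 1); }
      out[rep] = nn_mean_impl(ar.data(), ac.data(), n_a, br.data(), bc.data(), n_b);
    }
  }
  return out;
}

// ------------------------------------------------------------------ log-rank

struct Subject { double time; int event; int group; };

static void logrank_stat(std::vector<Subject>& s, double& chi2, double& var) {
  // Two-group log-rank: chi2 = (O1-E1)^2 / V with hypergeometric variance.
  std::sort(s.begin(), s.end(),
            [](const Subject& a, const Subject& b) { return a.time < b.time; });
  const int n = (int)s.size();
  double OmE = 0.0, V = 0.0;
  int i = 0;
  int at_risk = n;
  int at_risk1 = 0;
  for (int k = 0; k < n; ++k) at_risk1 += s[k].group;
  while (i < n) {
    double t = s[i].time;
    int d = 0, d1 = 0, m = 0, m1 = 0;   // events and removals at t
    while (i < n && s[i].time == t) {
      if (s[i].event) { ++d; d1 += s[i].group; }
      ++m; m1 += s[i].group;
      ++i;
    }
    if (d > 0 && at_risk > 1) {
      double n1 = at_risk1, ntot = at_risk;
      OmE += d1 - d * n1 / ntot;
      V += d * (n1 / ntot) * (1.0 - n1 / ntot) * (at_risk - d) / (at_risk - 1.0);
    }
    at_risk -= m;
    at_risk1 -= m1;
  }
  var = V;
  chi2 = (V > 0) ? OmE * OmE / V : 0.0;
}

// Returns c(chi2, variance). variance == 0 flags a degenerate comparison.
// [[Rcpp::export]]
NumericVector cpp_logrank(const NumericVector& time, const IntegerVector& event,
                          const IntegerVector& group) {
  const int n = time.size();
  std::vector<Subject> s(n);
  for (int i = 0; i < n; ++i) s[i] = {time[i], event[i], group[i]};
  double chi2, var;
  logrank_stat(s, chi2, var);
  return NumericVector::create(chi2, var);
}

// Restricted mean survival time: area under the Kaplan-Meier curve up to tau.
// [[Rcpp::export]]
double cpp_rmst(const NumericVector& time, const IntegerVector& event, double tau) {
  const int n = time.size();
  std::vector<Subject> s(n);
  for (int i = 0; i < n; ++i) s[i] = {time[i], event[i], 0};
  std::sort(s.begin(), s.end(),
            [](const Subject& a, const Subject& b) { return a.time < b.time; });
  double S = 1.0, area = 0.0, prev = 0.0;
  int at_risk = n, i = 0;
  while (i < n && s[i].time <= tau) {
    double t = s[i].time;
    int d = 0, m = 0;
    while (i < n && s[i].time == t) { d += s[i].event; ++m; ++i; }
    area += S * (t - prev);
    prev = t;
    if (d > 0) S *= 1.0 - (double)d / at_risk;
    at_risk -= m;
  }
  if (tau > prev) area += S * (tau - prev);
  return area;
}

// ----------------------------------------------------------- inner Monte-Carlo

// One inner resampling pass over a patient x parameter matrix: per repetition
// draw n_select patients, median-split each parameter, log-rank the two
// halves; upon significance record the per-group parameter means, attributing
// "short" to the half with the smaller restricted mean survival.
// [[Rcpp::export]]
List cpp_inner_loop(const NumericMatrix& X, const NumericVector& time,
                    const IntegerVector& event, int n_select, int reps,
                    double alpha) {
  const int n = X.nrow(), p = X.ncol();
  IntegerVector nsig(p);
  NumericVector sum_short(p), sum_long(p);
  IntegerVector skipped(p);    // repetitions lost to ties/missing values
  std::vector<int> pool(n), idx(n_select);
  const int nlow = n_select / 2;
  std::vector<std::pair<double, int> > ord(n_select);
  std::vector<Subject> subj(n_select);
  NumericVector tlow(nlow), thigh(n_select - nlow);
  IntegerVector elow(nlow), ehigh(n_select - nlow);

  for (int rep = 0; rep < reps; ++rep) {
    sample_idx(n, n_select, pool, idx);
    double tau = 0.0;
    for (int i = 0; i < n_select; ++i) tau = std::max(tau, time[idx[i]]);
    for (int j = 0; j < p; ++j) {
      bool bad = false;
      for (int i = 0; i < n_select; ++i) {
        double v = X(idx[i], j);
        if (NumericVector::is_na(v)) { bad = true; break; }
        ord[i] = std::make_pair(v, idx[i]);
      }
      if (bad) { ++skipped[j]; continue; }
      std::stable_sort(ord.begin(), ord.end());
      if (ord.front().first == ord.back().first) { ++skipped[j]; continue; }
      double mlow = 0.0, mhigh = 0.0;
      for (int i = 0; i < n_select; ++i) {
        subj[i].time = time[ord[i].second];
        subj[i].event = event[ord[i].second];
        subj[i].group = (i >= nlow) ? 1 : 0;
        if (i < nlow) mlow += ord[i].first; else mhigh += ord[i].first;
      }
      mlow /= nlow; mhigh /= (n_select - nlow);
      std::vector<Subject> scopy(subj);
      double chi2, var;
      logrank_stat(scopy, chi2, var);
      if (var <= 0) continue;
      double pval = R::pchisq(chi2, 1.0, 0, 0);
      if (pval < alpha) {
        int il = 0, ih = 0;
        for (int i = 0; i < n_select; ++i) {
          if (i < nlow) { tlow[il] = subj[i].time; elow[il] = subj[i].event; ++il; }
          else { thigh[ih] = subj[i].time; ehigh[ih] = subj[i].event; ++ih; }
        }
        double rm_low = cpp_rmst(tlow, elow, tau);
        double rm_high = cpp_rmst(thigh, ehigh, tau);
        // smaller KM area = worse survival = the "short" group
        double ms = (rm_low <= rm_high) ? mlow : mhigh;
        double ml = (rm_low <= rm_high) ? mhigh : mlow;
        sum_short[j] += ms;
        sum_long[j] += ml;
        ++nsig[j];
      }
    }
  }
  return List::create(_["n_significant"] = nsig,
                      _["sum_short"] = sum_short,
                      _["sum_long"] = sum_long,
                      _["skipped"] = skipped);
}
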