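#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Event segmentation by a sliding two-window mean-shift statistic.
// A boundary is placed at sample i (event starts at i) when the absolute
// difference between the means of the w samples before and after i exceeds
// `threshold` and is a strict local maximum within +/- (w-1) samples.
// [[Rcpp::export(name = ".segment_events_cpp")]]
DataFrame segment_events_cpp(NumericVector signal, int w, double threshold,
                             double jump_threshold) {
  const int n = signal.size();
  if (n < 2) stop("signal must have at least 2 samples");
  std::vector<double> prefix(n + 1, 0.0);
  for (int i = 0; i < n; ++i) prefix[i + 1] = prefix[i] + signal[i];
  std::vector<double> stat(n, 0.0);
  for (int i = w; i + w <= n; ++i) {
    double left = (prefix[i] - prefix[i - w]) / w;
    double right = (prefix[i + w] - prefix[i]) / w;
    stat[i] = std::fabs(right - left);
  }
  std::vector<bool> is_bound(n + 1, false);
  for (int i = w; i + w <= n; ++i) {
    if (stat[i] < threshold) continue;
    bool is_max = true;
    for (int j = std::max(w, i - w + 1); j <= std::min(n - w, i + w - 1); ++j) {
      if (j == i) continue;
      if (stat[j] > stat[i] || (stat[j] == stat[i] && j < i)) { is_max = false; break; }
    }
    if (is_max) is_bound[i] = true;
  }
  // fine scale: single-sample jumps catch one-sample dwells that the
  // two-window statistic smears over
  if (jump_threshold > 0) {
    for (int i = 1; i < n; ++i) {
      double d = std::fabs(signal[i] - signal[i - 1]);
      if (d < jump_threshold) continue;
      double dl = i >= 2 ? std::fabs(signal[i - 1] - signal[i - 2]) : 0.0;
      double dr = i + 1 < n ? std::fabs(signal[i + 1] - signal[i]) : 0.0;
      if (d >= dl && d > dr) is_bound[i] = true;
    }
  }
  std::vector<int> bounds;
  bounds.push_back(0);
  for (int i = 1; i < n; ++i) if (is_bound[i]) bounds.push_back(i);
  bounds.push_back(n);
  const int ne = bounds.size() - 1;
  IntegerVector start(ne), end(ne), dur(ne);
  NumericVector mean(ne), sdv(ne);
  for (int e = 0; e < ne; ++e) {
    int a = bounds[e], b = bounds[e + 1];
    double s = 0.0, s2 = 0.0;
    for (int i = a; i < b; ++i) { s += signal[i]; s2 += signal[i] * signal[i]; }
    int d = b - a;
    double m = s / d;
    double var = s2 / d - m * m;
    start[e] = a; end[e] = b; dur[e] = d;
    mean[e] = m; sdv[e] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["duration"] = dur, _["mean"] = mean,
                           _["sd"] = sdv);
}

// Banded Viterbi alignment of event means to reference k-mer levels.
// States: event i emitted by k-mer j. Transitions: match (advance one k-mer),
// insert (extra event on the same k-mer), and geometric runs of skipped
// k-mers folded into the match step. The emission of k-mer j is the best of
// its candidate levels (canonical plus analogue variants, CSR layout via
// cand_start), so alignment stays sharp at any substitution rate without
// committing to a substitution call. Returns the 1-based k-mer assignment
// of every event.
// [[Rcpp::export(name = ".viterbi_align_cpp")]]
List viterbi_align_cpp(NumericVector ev_mean, NumericVector cand_mean,
                       IntegerVector cand_start, NumericVector km_sd,
                       int band, double lp_match, double lp_insert,
                       double lp_skip, IntegerVector centres) {
  const int E = ev_mean.size(), K = km_sd.size();
  if (E < 1) stop("need at least one event");
  if (K < 1) stop("need at least one k-mer");
  if (cand_start.size() != K + 1) stop("cand_start must have length K + 1");
  const bool anchored = centres.size() == E;
  if (centres.size() != 0 && !anchored) stop("centres must be empty or one per event");
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = 2 * band + 1;

  std::vector<double> lconst(K), lprec(K);
  for (int j = 0; j < K; ++j) {
    lconst[j] = -0.5 * std::log(2.0 * M_PI) - std::log(km_sd[j]);
    lprec[j] = 0.5 / (km_sd[j] * km_sd[j]);
  }
  auto centre = [&](int i) {
    if (anchored) return (int) centres[i] - 1;
    if (E == 1) return 0;
    return (int) std::lround((double) i * (K - 1) / (double) (E - 1));
  };
  // V stored band-relative: V[i][j - lo(i)]
  std::vector<double> V((size_t) E * W, NEG);
  std::vector<int> lo(E), hi(E);
  for (int i = 0; i < E; ++i) {
    int c = centre(i);
    lo[i] = std::max(0, c - band);
    hi[i] = std::min(K - 1, c + band);
  }
  auto emis = [&](int i, int j) {
    double best = NEG;
    for (int q = cand_start[j]; q < cand_start[j + 1]; ++q) {
      double d = ev_mean[i] - cand_mean[q];
      double v = -d * d;
      if (v > best) best = v;
    }
    return lconst[j] + best * lprec[j];
  };
  for (int j = lo[0]; j <= hi[0]; ++j) {
    V[j - lo[0]] = emis(0, j) + j * lp_skip;
  }
  std::vector<double> Mprev(W);
  for (int i = 1; i < E; ++i) {
    // running-max over previous row with skip penalties:
    // M[j] = max_{j' <= j} V[i-1][j'] + (j - j') * lp_skip
    double run = NEG;
    int pl = lo[i - 1], ph = hi[i - 1];
    for (int j = pl; j <= ph; ++j) {
      run = std::max(V[(size_t) (i - 1) * W + (j - pl)], run + lp_skip);
      Mprev[j - pl] = run;
    }
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double best = NEG;
      if (j >= pl && j <= ph) {                 // insert: extra event, same k-mer
        double v = V[(size_t) (i - 1) * W + (j - pl)];
        if (v > NEG) best = v + lp_insert;
      }
      if (j - 1 >= pl) {                        // match, possibly after skips
        int jj = std::min(j - 1, ph);
        double m = Mprev[jj - pl] + (double) (j - 1 - jj) * lp_skip + lp_match;
        if (m > best) best = m;
      }
      if (best > NEG) V[(size_t) i * W + (j - lo[i])] = emis(i, j) + best;
    }
  }
  // terminal: remaining k-mers skipped
  double best_end = NEG; int best_j = -1;
  for (int j = lo[E - 1]; j <= hi[E - 1]; ++j) {
    double v = V[(size_t) (E - 1) * W + (j - lo[E - 1])];
    if (v == NEG) continue;
    double s = v + (double) (K - 1 - j) * lp_skip;
    if (s > best_end) { best_end = s; best_j = j; }
  }
  if (best_j < 0) {
    return List::create(_["ok"] = false, _["score"] = NA_REAL,
                        _["assignment"] = IntegerVector(0));
  }
  // traceback, recomputing the skip running-max per visited row
  IntegerVector assign(E);
  int j = best_j;
  const double tol = 1e-9;
  for (int i = E - 1; i >= 1; --i) {
    assign[i] = j + 1;
    double target = V[(size_t) i * W + (j - lo[i])] - emis(i, j);
    int pl = lo[i - 1], ph = hi[i - 1];
    // insert?
    bool done = false;
    if (j >= pl && j <= ph) {
      double v = V[(size_t) (i - 1) * W + (j - pl)];
      if (v > NEG && std::fabs(v + lp_insert - target) < tol) { done = true; }
    }
    if (!done) {
      // match after s >= 0 skips: find source j' <= j-1
      int jmax = std::min(j - 1, ph);
      for (int jp = jmax; jp >= pl; --jp) {
        double v = V[(size_t) (i - 1) * W + (jp - pl)];
        if (v == NEG) continue;
        double cand = v + (double) (j - 1 - jp) * lp_skip + lp_match;
        if (std::fabs(cand - target) < tol) { j = jp; done = true; break; }
      }
      if (!done) stop("viterbi traceback failed");
    }
  }
  assign[0] = j + 1;
  return List::create(_["ok"] = true, _["score"] = best_end,
                      _["assignment"] = assign);
}

// Sample-level Viterbi refinement ("resquiggle"): re-aligns every raw
// sample to a reference k-mer inside a narrow k-mer band around an anchor
// path (from the event-level alignment). Each k-mer consumes a geometric
// run of samples; skipped k-mers are allowed with a penalty. Emissions take
// the best candidate level of the k-mer (canonical or analogue variant).
// Returns the 1-based k-mer occupying each sample.
// [[Rcpp::export(name = ".sample_viterbi_cpp")]]
IntegerVector sample_viterbi_cpp(NumericVector signal, NumericVector cand_mean,
                                 IntegerVector cand_start, NumericVector km_sd,
                                 IntegerVector anchor, int band,
                                 double lp_stay, double lp_advance,
                                 double lp_skip) {
  const int n = signal.size(), K = km_sd.size();
  if (anchor.size() != n) stop("anchor must have one k-mer per sample");
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = 2 * band + 1;
  std::vector<double> lconst(K), lprec(K);
  for (int j = 0; j < K; ++j) {
    lconst[j] = -0.5 * std::log(2.0 * M_PI) - std::log(km_sd[j]);
    lprec[j] = 0.5 / (km_sd[j] * km_sd[j]);
  }
  auto emis = [&](int s, int j) {
    double best = NEG;
    for (int q = cand_start[j]; q < cand_start[j + 1]; ++q) {
      double d = signal[s] - cand_mean[q];
      double v = -d * d;
      if (v > best) best = v;
    }
    return lconst[j] + best * lprec[j];
  };
  // the anchor is monotone non-decreasing, so fixed-width bands around it
  // are monotone too and always overlap between consecutive samples
  std::vector<int> lo(n), hi(n);
  for (int s = 0; s < n; ++s) {
    int c = anchor[s] - 1;
    lo[s] = std::max(0, c - band);
    hi[s] = std::min(K - 1, c + band);
  }
  std::vector<double> V((size_t) n * W, NEG);
  std::vector<double> Mprev(W);
  for (int j = lo[0]; j <= hi[0]; ++j) {
    V[j - lo[0]] = emis(0, j) + (double) (j - lo[0]) * lp_skip;
  }
  for (int s = 1; s < n; ++s) {
    int pl = lo[s - 1], ph = hi[s - 1];
    double run = NEG;
    for (int j = pl; j <= ph; ++j) {
      run = std::max(V[(size_t) (s - 1) * W + (j - pl)], run + lp_skip);
      Mprev[j - pl] = run;
    }
    for (int j = lo[s]; j <= hi[s]; ++j) {
      double best = NEG;
      if (j >= pl && j <= ph) {
        double v = V[(size_t) (s - 1) * W + (j - pl)];
        if (v > NEG) best = v + lp_stay;
      }
      if (j - 1 >= pl) {
        int jj = std::min(j - 1, ph);
        double m = Mprev[jj - pl] + (double) (j - 1 - jj) * lp_skip + lp_advance;
        if (m > best) best = m;
      }
      if (best > NEG) V[(size_t) s * W + (j - lo[s])] = emis(s, j) + best;
    }
  }
  double best_end = NEG; int bj = -1;
  for (int j = lo[n - 1]; j <= hi[n - 1]; ++j) {
    double v = V[(size_t) (n - 1) * W + (j - lo[n - 1])];
    if (v == NEG) continue;
    double sc = v + (double) (K - 1 - j) * lp_skip;
    if (sc > best_end) { best_end = sc; bj = j; }
  }
  if (bj < 0) stop("sample-level refinement found no valid path");
  IntegerVector occ(n);
  int j = bj;
  const double tol = 1e-9;
  for (int s = n - 1; s >= 1; --s) {
    occ[s] = j + 1;
    double target = V[(size_t) s * W + (j - lo[s])] - emis(s, j);
    int pl = lo[s - 1], ph = hi[s - 1];
    bool done = false;
    if (j >= pl && j <= ph) {
      double v = V[(size_t) (s - 1) * W + (j - pl)];
      if (v > NEG && std::fabs(v + lp_stay - target) < tol) done = true;
    }
    if (!done) {
      int jmax = std::min(j - 1, ph);
      for (int jp = jmax; jp >= pl; --jp) {
        double v = V[(size_t) (s - 1) * W + (jp - pl)];
        if (v == NEG) continue;
        double cand = v + (double) (j - 1 - jp) * lp_skip + lp_advance;
        if (std::fabs(cand - target) < tol) { j = jp; done = true; break; }
      }
      if (!done) stop("sample-level traceback failed");
    }
  }
  occ[0] = j + 1;
  return occ;
}
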