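#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <algorithm>
#include <vector>
#include <set>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Event segmentation: Welch t-statistic over rolling windows.
// ---------------------------------------------------------------------------

// Welch t between samples[i-w, i) and samples[i, i+w), computed from prefix
// sums.  Sample variance (n-1 denominator); a zero-variance pair with equal
// means scores 0, with distinct means scores a large sentinel so that clean
// steps always qualify.
static void welch_track(const NumericVector& x, int w, double thr,
                        std::set<int>& out) {
  const int n = x.size();
  if (n <= 2 * w) return;
  std::vector<double> s(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  const int lo = w, hi = n - w; // candidate boundary offsets i in [lo, hi]
  std::vector<double> t(n, 0.0);
  for (int i = lo; i <= hi; ++i) {
    const double sumL = s[i] - s[i - w], sumR = s[i + w] - s[i];
    const double mL = sumL / w, mR = sumR / w;
    const double vL = std::max(0.0, (s2[i] - s2[i - w] - w * mL * mL) / (w - 1));
    const double vR = std::max(0.0, (s2[i + w] - s2[i] - w * mR * mR) / (w - 1));
    const double den = std::sqrt(vL / w + vR / w);
    const double num = std::fabs(mL - mR);
    // degeneracy guard scaled to the signal magnitude: prefix-sum rounding
    // leaves O(eps * |signal|) residue in means/variances of constant runs
    const double tol = 1e-9 * (1.0 + std::fabs(mL) + std::fabs(mR));
    if (den <= tol) {
      t[i] = (num <= tol) ? 0.0 : 1e12;
    } else {
      t[i] = num / den;
    }
  }
  // candidate peaks: above threshold and local maxima
  std::vector<int> cand;
  for (int i = lo; i <= hi; ++i) {
    const double left = (i > lo) ? t[i - 1] : -1.0;
    const double right = (i < hi) ? t[i + 1] : -1.0;
    if (t[i] > thr && t[i] >= left && t[i] > right) cand.push_back(i);
  }
  // non-maximum suppression: a peak within w samples of a stronger peak is
  // a side lobe of the same level transition
  std::stable_sort(cand.begin(), cand.end(),
                   [&](int a, int b) { return t[a] > t[b]; });
  std::vector<int> kept;
  for (int c : cand) {
    bool shadowed = false;
    for (int kpt : kept) {
      if (std::abs(kpt - c) < w) { shadowed = true; break; }
    }
    if (!shadowed) kept.push_back(c);
  }
  out.insert(kept.begin(), kept.end());
}

// [[Rcpp::export]]
IntegerVector cpp_detect_boundaries(NumericVector samples,
                                    IntegerVector windows,
                                    NumericVector thresholds) {
  if (windows.size() != thresholds.size())
    stop("windows and thresholds must have equal length");
  std::set<int> bset;
  for (int j = 0; j < windows.size(); ++j) {
    if (windows[j] < 2) stop("segmentation window lengths must be >= 2");
    if (!(thresholds[j] > 0)) stop("t thresholds must be positive");
    welch_track(samples, windows[j], thresholds[j], bset);
  }
  return IntegerVector(bset.begin(), bset.end());
}

// Segment [0, n) at the given sorted boundary offsets; drop segments shorter
// than min_len.  Returns start (0-based), length, mean per retained segment.
// [[Rcpp::export]]
List cpp_segments_to_events(NumericVector samples, IntegerVector boundaries,
                            int min_len) {
  const int n = samples.size();
  std::vector<int> cuts;
  cuts.push_back(0);
  for (int i = 0; i < boundaries.size(); ++i) {
    int b = boundaries[i];
    if (b <= 0 || b >= n) stop("boundary offset out of range");
    if (b <= cuts.back()) stop("boundaries must be strictly increasing");
    cuts.push_back(b);
  }
  cuts.push_back(n);
  std::vector<int> st, len;
  std::vector<double> mu;
  for (size_t i = 0; i + 1 < cuts.size(); ++i) {
    const int a = cuts[i], b = cuts[i + 1];
    const int L = b - a;
    if (L < min_len || L <= 0) continue;
    double sum = 0.0;
    for (int j = a; j < b; ++j) sum += samples[j];
    st.push_back(a);
    len.push_back(L);
    mu.push_back(sum / L);
  }
  return List::create(_["start"] = wrap(st), _["length"] = wrap(len),
                      _["mean"] = wrap(mu));
}

// ---------------------------------------------------------------------------
// Quantization: top Q bits of the IEEE-754 single-precision pattern, with p
// bits pruned after the two most significant bits; code = E[1,2]E[3+p,Q].
// ---------------------------------------------------------------------------

static inline uint32_t quantize_one(double value, int Q, int p) {
  float f = static_cast<float>(value);
  if (f == 0.0f) f = 0.0f; // canonicalize -0 to +0
  uint32_t bits;
  std::memcpy(&bits, &f, sizeof(bits));
  const uint32_t top = (Q == 32) ? bits : (bits >> (32 - Q));
  const int keep_low = Q - 2 - p;           // bits (3+p)..Q
  const uint32_t hi = top >> (Q - 2);       // bits 1..2 (sign + exponent MSB)
  const uint32_t lo = top & ((1u << keep_low) - 1u);
  return (hi << keep_low) | lo;
}

static void check_qp(int Q, int p) {
  if (p < 0) stop("p must be >= 0");
  if (Q > 32) stop("Q must be <= 32");
  if (!(2 + p < Q)) stop("quantization requires 2 + p < Q");
  if (Q - p > 31) stop("code width Q - p must fit a signed 32-bit integer");
}

// [[Rcpp::export]]
IntegerVector cpp_quantize(NumericVector values, int Q, int p) {
  check_qp(Q, p);
  const int n = values.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = values[i];
    if (ISNA(x)) { // a true NA gap propagates; NaN/Inf signal corruption
      out[i] = NA_INTEGER;
    } else if (!std::isfinite(x)) {
      stop("non-finite event value at position %d", i + 1);
    } else {
      out[i] = static_cast<int>(quantize_one(x, Q, p));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed packing and the 32-bit mix.
// ---------------------------------------------------------------------------

static inline uint32_t fmix32(uint32_t h) {
  h ^= h >> 16;
  h *= 0x85ebca6bu;
  h ^= h >> 13;
  h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

static inline uint64_t fmix64(uint64_t z) {
  z ^= z >> 30;
  z *= 0xbf58476d1ce4e5b9ull;
  z ^= z >> 27;
  z *= 0x94d049bb133111ebull;
  z ^= z >> 31;
  return z;
}

static inline uint32_t hash_packed(uint64_t packed, int width) {
  if (width <= 32) return fmix32(static_cast<uint32_t>(packed));
  const uint64_t h = fmix64(packed);
  return static_cast<uint32_t>(h ^ (h >> 32));
}

// [[Rcpp::export]]
NumericVector cpp_hash_packed(NumericVector packed, int width) {
  if (width < 1 || width > 64) stop("width must be in [1, 64]");
  NumericVector out(packed.size());
  for (int i = 0; i < packed.size(); ++i) {
    if (packed[i] < 0 || packed[i] != std::floor(packed[i]))
      stop("packed values must be non-negative integers");
    if (width < 53 && packed[i] >= std::ldexp(1.0, width))
      stop("packed value exceeds 2^width");
    out[i] = static_cast<double>(hash_packed(static_cast<uint64_t>(packed[i]), width));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pack_seed(IntegerVector codes, int width_per_code) {
  const int n = codes.size();
  if (n < 1) stop("need at least one code");
  if (n * width_per_code > 53)
    stop("packed width exceeds exact double precision; use cpp_seed_hashes");
  double packed = 0.0;
  const double base = std::ldexp(1.0, width_per_code);
  for (int i = 0; i < n; ++i) {
    if (IntegerVector::is_na(codes[i])) stop("NA code in seed");
    if (codes[i] < 0 || codes[i] >= base) stop("code exceeds its bit width");
    packed = packed * base + codes[i];
  }
  return NumericVector::create(packed);
}

// Hash every window of n consecutive codes; NA where the window contains an
// NA code (events interrupted by ambiguous reference bases).
// [[Rcpp::export]]
NumericVector cpp_seed_hashes(IntegerVector codes, int n, int width_per_code) {
  const int m = codes.size();
  const int total = n * width_per_code;
  if (n < 1) stop("n must be >= 1");
  if (total > 64) stop("n * (Q - p) must be <= 64");
  if (m < n) return NumericVector(0);
  NumericVector out(m - n + 1);
  for (int j = 0; j + n <= m; ++j) {
    bool ok = true;
    uint64_t packed = 0;
    for (int i = 0; i < n; ++i) {
      const int c = codes[j + i];
      if (c == NA_INTEGER) { ok = false; break; }
      packed = (packed << width_per_code) | static_cast<uint64_t>(c);
    }
    out[j] = ok ? static_cast<double>(hash_packed(packed, total)) : NA_REAL;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Colinear chaining.  Anchors must arrive sorted by (tid, strand, cpos, qidx);
// cpos is the chain coordinate (forward position for '+', mirrored for '-').
// f(j) = match + max(0, max_i f(i) - gap_scale * |dcpos - dq|) over admissible
// predecessors: same tid/strand, cpos and qidx strictly increasing, both
// deltas <= max_gap.  No distance coefficient.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_chain_anchors(IntegerVector tid, IntegerVector strand,
                       IntegerVector cpos, IntegerVector qidx,
                       double match_score, double gap_scale,
                       int max_gap, int max_skip, int max_chains) {
  const int n = tid.size();
  std::vector<double> f(n, match_score);
  std::vector<int> pred(n, -1);
  for (int j = 0; j < n; ++j) {
    double best = 0.0;
    int bi = -1, checked = 0;
    for (int i = j - 1; i >= 0; --i) {
      if (tid[i] != tid[j] || strand[i] != strand[j]) break;
      const int dt = cpos[j] - cpos[i];
      if (dt > max_gap) break;
      if (++checked > max_skip) break;
      if (dt <= 0) continue;
      const int dq = qidx[j] - qidx[i];
      if (dq <= 0 || dq > max_gap) continue;
      const double cand = f[i] - gap_scale * std::fabs((double)dt - (double)dq);
      if (cand > best) { best = cand; bi = i; }
    }
    if (best > 0.0) { f[j] = match_score + best; pred[j] = bi; }
  }
  // extract chains greedily from the highest-scoring endpoints
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return f[a] > f[b]; });
  std::vector<bool> used(n, false);
  std::vector<double> c_score;
  std::vector<int> c_tid, c_strand, c_cstart, c_cend, c_qstart, c_qend, c_n;
  for (int oi = 0; oi < n && (int)c_score.size() < max_chains; ++oi) {
    int j = ord[oi];
    if (used[j]) continue;
    int qmin = qidx[j], qmax = qidx[j], cmin = cpos[j], cmax = cpos[j], cnt = 0;
    int i = j;
    while (i >= 0 && !used[i]) {
      used[i] = true;
      ++cnt;
      qmin = std::min(qmin, qidx[i]);
      qmax = std::max(qmax, qidx[i]);
      cmin = std::min(cmin, cpos[i]);
      cmax = std::max(cmax, cpos[i]);
      i = pred[i];
    }
    c_score.push_back(f[j]);
    c_tid.push_back(tid[j]);
    c_strand.push_back(strand[j]);
    c_cstart.push_back(cmin);
    c_cend.push_back(cmax);
    c_qstart.push_back(qmin);
    c_qend.push_back(qmax);
    c_n.push_back(cnt);
  }
  return List::create(_["score"] = wrap(c_score), _["tid"] = wrap(c_tid),
                      _["strand"] = wrap(c_strand),
                      _["cstart"] = wrap(c_cstart), _["cend"] = wrap(c_cend),
                      _["qstart"] = wrap(c_qstart), _["qend"] = wrap(c_qend),
                      _["n_anchors"] = wrap(c_n));
}

// Raw DP scores only (for the oracle-equivalence tests).
// [[Rcpp::export]]
NumericVector cpp_chain_scores(IntegerVector tid, IntegerVector strand,
                               IntegerVector cpos, IntegerVector qidx,
                               double match_score, double gap_scale,
                               int max_gap, int max_skip) {
  const int n = tid.size();
  std::vector<double> f(n, match_score);
  for (int j = 0; j < n; ++j) {
    double best = 0.0;
    int checked = 0;
    for (int i = j - 1; i >= 0; --i) {
      if (tid[i] != tid[j] || strand[i] != strand[j]) break;
      const int dt = cpos[j] - cpos[i];
      if (dt > max_gap) break;
      if (++checked > max_skip) break;
      if (dt <= 0) continue;
      const int dq = qidx[j] - qidx[i];
      if (dq <= 0 || dq > max_gap) continue;
      const double cand = f[i] - gap_scale * std::fabs((double)dt - (double)dq);
      if (cand > best) best = cand;
    }
    f[j] = match_score + std::max(0.0, best);
  }
  return wrap(f);
}
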