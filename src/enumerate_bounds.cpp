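#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of homozygosity over the discrete frequency simplex.
//
// Frequencies live on a 1/step grid (default step = 100, i.e. 0.01
// increments). A vector is admissible when it has length K with entries
// >= 0 (at most K alleles, matching the bound theorem's premise) summing to
// `step` with maximum entry exactly `m`. Enumeration is over non-increasing
// representatives (H is permutation-symmetric). For each admissible vector
// H = sum((p_k/step)^2) is accumulated; the function returns the observed
// min/max of H, the vector count, and how many H values fall outside
// [lo - slack, hi + slack].
//
// The recursion assigns parts 2..K in non-increasing order with a
// feasibility prune: remaining sum must be achievable with the remaining
// parts each in [0, cap].

struct EnumState {
  int K;
  int step;
  double lo, hi, slack;
  double h_min, h_max;
  double n;
  double n_violations;
};

static void recurse(EnumState &st, int part_idx, int remaining, int cap,
                    long long sumsq) {
  int parts_left = st.K - part_idx + 1;
  if (parts_left == 1) {
    // last part is forced
    if (remaining >= 0 && remaining <= cap) {
      long long total = sumsq + (long long)remaining * remaining;
      double H = (double)total / ((double)st.step * (double)st.step);
      if (H < st.h_min) st.h_min = H;
      if (H > st.h_max) st.h_max = H;
      if (H < st.lo - st.slack || H > st.hi + st.slack) st.n_violations += 1;
      st.n += 1;
    }
    return;
  }
  // part value v must satisfy: 0 <= v <= cap, and remaining - v must be
  // achievable by parts_left - 1 parts each in [0, v].
  int v_hi = std::min(cap, remaining);
  for (int v = v_hi; v >= 0; --v) {
    int rem2 = remaining - v;
    if (rem2 > (long long)(parts_left - 1) * v) break; // v too small; all smaller fail too
    recurse(st, part_idx + 1, rem2, v, sumsq + (long long)v * v);
  }
}

// [[Rcpp::export(name = ".enumerate_h_range_cpp")]]
NumericVector enumerate_h_range_cpp(int K, int m, int step, double lo,
                                    double hi, double slack) {
  if (K < 1 || m < 1 || m > step) stop("invalid K or m");
  EnumState st;
  st.K = K;
  st.step = step;
  st.lo = lo;
  st.hi = hi;
  st.slack = slack;
  st.h_min = R_PosInf;
  st.h_max = R_NegInf;
  st.n = 0;
  st.n_violations = 0;

  if (K == 1) {
    if (m == step) {
      st.h_min = st.h_max = 1.0;
      st.n = 1;
      if (1.0 < lo - slack || 1.0 > hi + slack) st.n_violations = 1;
    }
  } else {
    int remaining = step - m;
    // first part fixed at m; remaining K-1 parts each in [0, m]
    if (remaining >= 0 && remaining <= (long long)(K - 1) * m) {
      recurse(st, 2, remaining, m, (long long)m * m);
    }
  }

  return NumericVector::create(_["h_min"] = st.h_min, _["h_max"] = st.h_max,
                               _["n"] = st.n,
                               _["n_violations"] = st.n_violations);
}
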