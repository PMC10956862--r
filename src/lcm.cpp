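#include <Rcpp.h>
using namespace Rcpp;

// Local center of mass from a monotone cumulative edge-energy sequence D.
//
// C_n = (sum_{m<=n} m e^{D_m - D_n} + sum_{m>n} m e^{D_n - D_m}) /
//       (sum_{m<=n}   e^{D_m - D_n} + sum_{m>n}   e^{D_n - D_m})
//
// evaluated by forward/backward recurrences in which every exponent is
// <= 0 (D is nondecreasing), so no overflow occurs for any alpha.
// Indices are 1-based in the returned profile.
// [[Rcpp::export]]
NumericVector lcm_from_energy(NumericVector D) {
  const int N = D.size();
  NumericVector C(N);
  if (N == 0) return C;
  std::vector<double> S(N), T(N), B(N), Bp(N);
  S[0] = 1.0;  // m = 1 term
  T[0] = 1.0;
  for (int n = 1; n < N; ++n) {
    double e = std::exp(D[n - 1] - D[n]);
    S[n] = S[n - 1] * e + (n + 1);
    T[n] = T[n - 1] * e + 1.0;
  }
  B[N - 1] = 0.0;
  Bp[N - 1] = 0.0;
  for (int n = N - 2; n >= 0; --n) {
    double e = std::exp(D[n] - D[n + 1]);
    B[n]  = e * (B[n + 1] + (n + 2));
    Bp[n] = e * (Bp[n + 1] + 1.0);
  }
  for (int n = 0; n < N; ++n)
    C[n] = (S[n] + B[n]) / (T[n] + Bp[n]);
  return C;
}
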