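#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference march of 1-D semi-infinite diffusion with a
// Nernstian (equilibrium) surface boundary condition.
//
// u        initial concentration profile of the tracked species (length N);
//          u[0] is the electrode surface node, u[N-1] the bulk boundary.
// surf     surface concentration imposed during each waveform interval
//          (Nernst partition of the total couple concentration).
// m        number of sub-steps in each interval.
// lam      diffusion number D*dt/dx^2 for each interval (must be <= 0.5).
// bulk     fixed concentration at the outer boundary.
//
// Returns the one-sided surface gradient (u[1]-u[0])/1 (per node spacing) at
// the END of each interval; multiply by n F A D / dx for the current.
// [[Rcpp::export]]
NumericVector diffuse_fd(NumericVector u, NumericVector surf,
                         IntegerVector m, NumericVector lam, double bulk) {
  const int K = surf.size();
  const int N = u.size();
  if (m.size() != K || lam.size() != K)
    stop("surf, m and lam must have equal length");
  if (N < 3) stop("spatial grid must have at least 3 nodes");
  NumericVector grad(K);
  std::vector<double> c(u.begin(), u.end());
  for (int k = 0; k < K; ++k) {
    const double s = surf[k];
    const double l = lam[k];
    if (l > 0.5) stop("stability violated: lambda > 0.5");
    for (int t = 0; t < m[k]; ++t) {
      c[0] = s;
      double left = c[0];
      for (int j = 1; j < N - 1; ++j) {
        const double cur = c[j];
        c[j] = cur + l * (c[j + 1] - 2.0 * cur + left);
        left = cur;
      }
      c[N - 1] = bulk;
    }
    c[0] = s;
    // second-order one-sided surface gradient (per node spacing)
    grad[k] = (-3.0 * c[0] + 4.0 * c[1] - c[2]) / 2.0;
  }
  return grad;
}
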