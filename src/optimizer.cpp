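#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Restraint energy and gradient at coords x (n x 3).
// Pair kinds: lower[p] == 1 marks a one-sided lower bound (excluded volume,
// active only when d < target); otherwise a two-sided harmonic.
static double energyGrad(const std::vector<double> &x, int n,
                         const IntegerVector &pi, const IntegerVector &pj,
                         const NumericVector &pd, const NumericVector &pk,
                         const IntegerVector &lower,
                         std::vector<double> &grad) {
  std::fill(grad.begin(), grad.end(), 0.0);
  double e = 0.0;
  const int np = pi.size();
  for (int p = 0; p < np; ++p) {
    const int a = pi[p], b = pj[p];
    const double dx = x[a] - x[b];
    const double dy = x[a + n] - x[b + n];
    const double dz = x[a + 2 * n] - x[b + 2 * n];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (lower[p] && d >= pd[p]) continue;
    if (d < 1e-9) d = 1e-9;
    const double diff = d - pd[p];
    e += pk[p] * diff * diff;
    const double g = 2.0 * pk[p] * diff / d;
    grad[a] += g * dx;          grad[b] -= g * dx;
    grad[a + n] += g * dy;      grad[b + n] -= g * dy;
    grad[a + 2 * n] += g * dz;  grad[b + 2 * n] -= g * dz;
  }
  return e;
}

// Gradient descent with bold-driver step adaptation and annealing
// perturbation cycles.  All randomness (init, noise) is pregenerated by the
// caller, so the result is a deterministic function of the inputs.
// [[Rcpp::export]]
List optimizeModelCpp(NumericMatrix init, IntegerVector pi, IntegerVector pj,
                      NumericVector pd, NumericVector pk, IntegerVector lower,
                      NumericMatrix noise, IntegerVector cycleIters,
                      NumericVector noiseAmp, double lr0) {
  const int n = init.nrow();
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> grad(3 * n), best(x), trial(3 * n);
  const int nCycles = cycleIters.size();

  double bestE = energyGrad(x, n, pi, pj, pd, pk, lower, grad);
  double lastCycleImprovement = 0.0;

  for (int c = 0; c < nCycles; ++c) {
    if (c > 0) {
      // perturb the best-seen state and continue from there
      x = best;
      const double amp = noiseAmp[c - 1];
      for (int r = 0; r < n; ++r)
        for (int col = 0; col < 3; ++col)
          x[r + col * n] += amp * noise((c - 1) * n + r, col);
    }
    double lr = lr0;
    double prevE = energyGrad(x, n, pi, pj, pd, pk, lower, grad);
    const double cycleStartBest = bestE;
    for (int it = 0; it < cycleIters[c]; ++it) {
      for (int t = 0; t < 3 * n; ++t) trial[t] = x[t] - lr * grad[t];
      const double e = energyGrad(trial, n, pi, pj, pd, pk, lower, grad);
      if (e <= prevE) {
        x.swap(trial);
        prevE = e;
        lr *= 1.05;
        if (e < bestE) { bestE = e; best = x; }
      } else {
        lr *= 0.5;
        // recompute gradient at the retained state
        prevE = energyGrad(x, n, pi, pj, pd, pk, lower, grad);
        if (lr < 1e-12) break;
      }
    }
    lastCycleImprovement = cycleStartBest - bestE;
  }
  NumericMatrix out(n, 3);
  std::copy(best.begin(), best.end(), out.begin());
  const bool converged =
      lastCycleImprovement <= 1e-6 * (1.0 + std::abs(bestE));
  return List::create(_["coords"] = out, _["score"] = bestE,
                      _["converged"] = converged);
}
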