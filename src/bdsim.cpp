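#include <Rcpp.h>
using namespace Rcpp;

// Forward Gillespie simulation of the number of extant descendants of a
// single lineage alive at age t under a birth-death-skyline model.
// Tracks only the population count, so it stays fast at large replicate
// counts; used as a simulation oracle for the closed-form descendant
// distributions. Rates are indexed youngest-first; an age equal to a
// shift time belongs to the younger interval, matching the R side.
//
// [[Rcpp::export]]
IntegerVector rbd_descendants(int reps, double t, NumericVector lambdas,
                              NumericVector mus, NumericVector shift_times,
                              int cap = 1000000) {
  int m = shift_times.size();
  if (lambdas.size() != mus.size() || lambdas.size() != m + 1)
    stop("need length(lambdas) == length(mus) == length(shift_times) + 1");
  IntegerVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    double age = t;
    long k = 1;
    while (k > 0 && age > 0) {
      // interval index = number of shift times strictly below age
      int iv = 0;
      while (iv < m && shift_times[iv] < age) ++iv;
      double lo = (iv > 0) ? shift_times[iv - 1] : 0.0;
      double lam = lambdas[iv], mu = mus[iv];
      double rate = k * (lam + mu);
      if (rate <= 0) { age = lo; if (iv == 0) age = 0; continue; }
      double dt = R::rexp(1.0 / rate);
      if (age - dt <= lo) {
        age = lo; // memoryless: re-draw in the next interval
        continue;
      }
      age -= dt;
      if (R::unif_rand() < lam / (lam + mu)) {
        if (++k > cap) stop("population exceeded `cap`; reduce lambda * t");
      } else {
        --k;
      }
    }
    out[rep] = (int) k;
  }
  return out;
}
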