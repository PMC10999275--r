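#include <Rcpp.h>
using namespace Rcpp;

// Event loop of the neutral zero-sum Moran chain with immigration.
// One event = one uniformly chosen death followed by replacement from the
// metacommunity (prob m) or by a uniformly chosen local parent (prob 1-m).
// Uses R's RNG so set.seed() in R makes runs bit-reproducible.
//
// counts:   initial per-species counts (sums to J)
// meta_cum: cumulative metacommunity relative abundances
// sample_at: 1-based event indices (strictly increasing) at which to
//            record a snapshot
// record_events: if true, also return the full per-event count log
// [[Rcpp::export(name = ".moran_chain")]]
List moran_chain(NumericVector counts0, double J, double m,
                 NumericVector meta_cum, IntegerVector sample_at,
                 bool record_events) {
  int S = counts0.size();
  std::vector<double> counts(counts0.begin(), counts0.end());
  int n_samples = sample_at.size();
  int n_events = n_samples > 0 ? sample_at[n_samples - 1] : 0;
  NumericMatrix samples(n_samples, S);
  NumericMatrix events(record_events ? n_events : 0,
                       record_events ? S : 0);
  int si = 0;
  RNGScope scope;
  for (int e = 1; e <= n_events; ++e) {
    // death: uniform over the J individuals
    double v = unif_rand() * J;
    double acc = 0.0;
    int die = S - 1;
    for (int i = 0; i < S; ++i) {
      acc += counts[i];
      if (v < acc) { die = i; break; }
    }
    counts[die] -= 1.0;
    // replacement: immigrant or local birth
    int born;
    if (unif_rand() < m) {
      double u = unif_rand();
      born = S - 1;
      for (int i = 0; i < S; ++i) {
        if (u < meta_cum[i]) { born = i; break; }
      }
    } else {
      double w = unif_rand() * (J - 1.0);
      acc = 0.0;
      born = S - 1;
      for (int i = 0; i < S; ++i) {
        acc += counts[i];
        if (w < acc) { born = i; break; }
      }
    }
    counts[born] += 1.0;
    if (record_events)
      for (int i = 0; i < S; ++i) events(e - 1, i) = counts[i];
    if (si < n_samples && e == sample_at[si]) {
      for (int i = 0; i < S; ++i) samples(si, i) = counts[i];
      ++si;
    }
  }
  return List::create(_["samples"] = samples,
                      _["final"] = NumericVector(counts.begin(), counts.end()),
                      _["events"] = events);
}
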