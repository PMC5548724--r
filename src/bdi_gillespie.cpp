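#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact event-level simulation of the Birth-Death-cis-Innovation process.
// State: the multiset of family sizes. Hazards: lambda*N (birth), delta*N
// (death), mu*N (cis-innovation: one element leaves its family and founds a
// new size-1 family, N conserved), nu (de novo: a brand-new size-1 family,
// one new element). Uses R's RNG so trajectories are reproducible via
// set.seed() on the R side.

// pick the family containing a uniformly chosen element (linear walk over
// the size vector; family counts stay small enough that this is cheap)
static int pick_family(const std::vector<int>& sizes, int N) {
  double r = unif_rand() * N;
  double acc = 0.0;
  for (size_t j = 0; j < sizes.size(); ++j) {
    acc += sizes[j];
    if (r < acc) return (int)j;
  }
  return (int)sizes.size() - 1; // guard against round-off
}

// [[Rcpp::export]]
List cpp_bdi_simulate(IntegerVector init_sizes, double lambda, double delta,
                      double mu, double nu, double t_max, double max_events) {
  std::vector<int> sizes(init_sizes.begin(), init_sizes.end());
  long long N = 0;
  for (int s : sizes) {
    if (s < 1) stop("initial family sizes must be >= 1");
    N += s;
  }
  double t = 0.0;
  long long events = 0, births = 0, deaths = 0;
  long long cis_splits = 0, cis_relabels = 0, denovo = 0, fam_deaths = 0;
  bool extinct = false;

  RNGScope scope;
  while (events < (long long)max_events) {
    double a_tot = (lambda + delta + mu) * (double)N + nu;
    if (a_tot <= 0.0) { extinct = (N == 0); break; }
    t += exp_rand() / a_tot;
    if (t > t_max) { t = t_max; break; }
    ++events;
    double u = unif_rand() * a_tot;
    if (u < lambda * N) { // birth
      int j = pick_family(sizes, (int)N);
      ++sizes[j]; ++N; ++births;
    } else if (u < (lambda + delta) * N) { // death
      int j = pick_family(sizes, (int)N);
      if (--sizes[j] == 0) {
        sizes[j] = sizes.back();
        sizes.pop_back();
        ++fam_deaths;
      }
      --N; ++deaths;
      if (N == 0) {
        if (nu <= 0.0) { extinct = true; break; }
      }
    } else if (u < (lambda + delta + mu) * N) { // cis-innovation
      int j = pick_family(sizes, (int)N);
      if (sizes[j] >= 2) {
        --sizes[j];
        sizes.push_back(1);
        ++cis_splits; // F increases by 1
      } else {
        ++cis_relabels; // size-1 family relabelled: structurally a no-op
      }
    } else { // de novo innovation: new element in a new family
      sizes.push_back(1);
      ++N; ++denovo;
    }
  }

  return List::create(
    _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
    _["t"] = t,
    _["n_events"] = (double)events,
    _["births"] = (double)births,
    _["deaths"] = (double)deaths,
    _["cis_splits"] = (double)cis_splits,
    _["cis_relabels"] = (double)cis_relabels,
    _["denovo"] = (double)denovo,
    _["fam_deaths"] = (double)fam_deaths,
    _["extinct"] = extinct);
}
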