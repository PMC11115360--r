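#include <Rcpp.h>
using namespace Rcpp;

// Within-trial sampling kernels.  All randomness goes through R's RNG
// (norm_rand / unif_rand), so set.seed() on the R side gives bit-identical
// sample streams and the stream is shared with R-level code in call order.
//
// Target families: 0 = gaussian(mean, sd); 1 = discrete grid.  For the grid
// family chain positions are 0-based grid indices and the local proposal is a
// +/-1 index step (symmetric; off-grid proposals are rejected in place).
// Algorithms: 0 = mc3, 1 = rwm, 2 = direct (i.i.d.).

namespace {

struct Target {
  int family;
  double mean, sd;
  NumericVector grid_values, grid_logmass;
  NumericVector grid_cum; // normalised CDF, built lazily for direct draws

  double logp(double pos) const {
    if (family == 0) {
      double z = (pos - mean) / sd;
      return -0.5 * z * z;
    }
    return grid_logmass[(int)pos];
  }
  double value(double pos) const {
    return family == 0 ? pos : grid_values[(int)pos];
  }
};

Target make_target(int family, double mean, double sd,
                   NumericVector gv, NumericVector glm) {
  Target t;
  t.family = family; t.mean = mean; t.sd = sd;
  t.grid_values = gv; t.grid_logmass = glm;
  if (family == 1) {
    int n = glm.size();
    NumericVector cum(n);
    double mx = *std::max_element(glm.begin(), glm.end());
    double acc = 0.0;
    for (int i = 0; i < n; ++i) { acc += std::exp(glm[i] - mx); cum[i] = acc; }
    for (int i = 0; i < n; ++i) cum[i] /= acc;
    t.grid_cum = cum;
  }
  return t;
}

double direct_draw(const Target& t) {
  if (t.family == 0) return t.mean + t.sd * norm_rand();
  double u = unif_rand();
  int n = t.grid_cum.size();
  for (int i = 0; i < n; ++i) if (u <= t.grid_cum[i]) return (double)i;
  return (double)(n - 1);
}

// one Metropolis step on chain c at temperature temps[c]; updates pos in place
void mh_step_one(std::vector<double>& pos, int c, const Target& t,
                 double temp, double proposal_sd) {
  double cur = pos[c], prop;
  if (t.family == 0) {
    prop = cur + proposal_sd * norm_rand();
  } else {
    prop = cur + (unif_rand() < 0.5 ? -1.0 : 1.0);
    if (prop < 0 || prop >= t.grid_logmass.size()) { unif_rand(); return; }
  }
  double logr = (t.logp(prop) - t.logp(cur)) / temp;
  if (std::log(unif_rand()) < logr) pos[c] = prop;
}

// adjacent-pair swap proposal; consumes RNG in a fixed order
void swap_step_one(std::vector<double>& pos, const Target& t,
                   const NumericVector& temps, double swap_prob) {
  int nc = pos.size();
  if (nc < 2 || unif_rand() >= swap_prob) return;
  int k = (int)std::floor(unif_rand() * (nc - 1));
  if (k > nc - 2) k = nc - 2;
  double la = (t.logp(pos[k + 1]) - t.logp(pos[k])) *
              (1.0 / temps[k] - 1.0 / temps[k + 1]);
  if (std::log(unif_rand()) < la) std::swap(pos[k], pos[k + 1]);
}

// advance the sampler by one reported sample; returns cold-chain position
double advance(std::vector<double>& pos, const Target& t, int algorithm,
               const NumericVector& temps, double proposal_sd,
               double swap_prob) {
  if (algorithm == 2) { pos[0] = direct_draw(t); return pos[0]; }
  int nc = (algorithm == 1) ? 1 : pos.size();
  for (int c = 0; c < nc; ++c) mh_step_one(pos, c, t, temps[c], proposal_sd);
  if (algorithm == 0) swap_step_one(pos, t, temps, swap_prob);
  return pos[0];
}

int classify_value(double h, const NumericVector& boundaries) {
  // half-open intervals [b_k, b_{k+1}): a value on a boundary goes up
  int k = 0;
  for (int i = 0; i < boundaries.size(); ++i) if (h >= boundaries[i]) ++k;
  return k; // 0-based alternative index
}

int argmax_random_tie(const std::vector<double>& tot) {
  double mx = *std::max_element(tot.begin(), tot.end());
  std::vector<int> tied;
  for (size_t i = 0; i < tot.size(); ++i)
    if (tot[i] == mx) tied.push_back((int)i);
  if (tied.size() == 1) return tied[0];
  int j = (int)std::floor(unif_rand() * tied.size());
  if (j >= (int)tied.size()) j = tied.size() - 1;
  return tied[j];
}

} // namespace

// [[Rcpp::export]]
List cpp_draw_samples(NumericVector positions, int family, double mean,
                      double sd, NumericVector grid_values,
                      NumericVector grid_logmass, int algorithm,
                      NumericVector temps, double proposal_sd,
                      double swap_prob, int n) {
  Target t = make_target(family, mean, sd, grid_values, grid_logmass);
  std::vector<double> pos(positions.begin(), positions.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = advance(pos, t, algorithm, temps, proposal_sd, swap_prob);
  return List::create(_["samples"] = out,
                      _["positions"] = NumericVector(pos.begin(), pos.end()));
}

// [[Rcpp::export]]
NumericVector cpp_mh_step(NumericVector positions, int chain, int family,
                          double mean, double sd, NumericVector grid_values,
                          NumericVector grid_logmass, NumericVector temps,
                          double proposal_sd) {
  Target t = make_target(family, mean, sd, grid_values, grid_logmass);
  std::vector<double> pos(positions.begin(), positions.end());
  mh_step_one(pos, chain, t, temps[chain], proposal_sd);
  return NumericVector(pos.begin(), pos.end());
}

// [[Rcpp::export]]
NumericVector cpp_swap_step(NumericVector positions, int family, double mean,
                            double sd, NumericVector grid_values,
                            NumericVector grid_logmass, NumericVector temps,
                            double swap_prob) {
  Target t = make_target(family, mean, sd, grid_values, grid_logmass);
  std::vector<double> pos(positions.begin(), positions.end());
  swap_step_one(pos, t, temps, swap_prob);
  return NumericVector(pos.begin(), pos.end());
}

// Run one trial's sampling loop: draw samples, tally evidence against the
// partition, stop per the rule (0 = fixed_n, 1 = max-minus-next with cap).
// Pseudocounts seed the accumulator, so a biased prior can stop at N = 0.
// [[Rcpp::export]]
List cpp_collect_samples(NumericVector positions, int family, double mean,
                         double sd, NumericVector grid_values,
                         NumericVector grid_logmass, int algorithm,
                         NumericVector temps, double proposal_sd,
                         double swap_prob, NumericVector boundaries,
                         NumericVector alphas, int rule_kind, int n_fixed,
                         int delta, int n_max) {
  Target t = make_target(family, mean, sd, grid_values, grid_logmass);
  std::vector<double> pos(positions.begin(), positions.end());
  int m = alphas.size();
  std::vector<int> counts(m, 0);
  std::vector<double> samples;
  samples.reserve(rule_kind == 0 ? n_fixed : 64);

  auto totals = [&](int j) { return alphas[j] + counts[j]; };
  auto mmn_met = [&]() {
    double top = -1e300, next = -1e300;
    for (int j = 0; j < m; ++j) {
      double v = totals(j);
      if (v > top) { next = top; top = v; } else if (v > next) next = v;
    }
    return top - next >= (double)delta;
  };

  int n = 0;
  bool stopped = (rule_kind == 1 && mmn_met()) || (rule_kind == 0 && n_fixed == 0);
  while (!stopped) {
    double p = advance(pos, t, algorithm, temps, proposal_sd, swap_prob);
    samples.push_back(t.value(p));
    counts[classify_value(t.value(p), boundaries)]++;
    ++n;
    if (rule_kind == 0) stopped = (n >= n_fixed);
    else stopped = mmn_met() || (n >= n_max);
  }

  std::vector<double> tot(m);
  for (int j = 0; j < m; ++j) tot[j] = totals(j);
  int chosen = argmax_random_tie(tot);

  return List::create(
      _["samples"] = NumericVector(samples.begin(), samples.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["chosen"] = chosen + 1,
      _["positions"] = NumericVector(pos.begin(), pos.end()));
}
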