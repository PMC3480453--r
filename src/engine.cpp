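#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Trail-choice preference computation shared by the engine.
// Mirrors the R-level preference() functions; the R implementations are the
// reference and the test suite checks both routes agree.

// Discrimination preprocessing: trails whose sorted strengths chain together
// with gaps < d form one group (single linkage); group members share the
// group mean as effective strength. Returns group id per trail via `group`
// and writes effective strengths into `eff`.
static void discriminate(const std::vector<double> &c, double d,
                         std::vector<double> &eff, std::vector<int> &group) {
  int s = c.size();
  std::vector<int> ord(s);
  for (int i = 0; i < s; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return c[a] < c[b]; });
  int g = 0;
  group[ord[0]] = 0;
  for (int j = 1; j < s; ++j) {
    if (!(c[ord[j]] - c[ord[j - 1]] < d)) ++g; // strict: gap < d merges
    group[ord[j]] = g;
  }
  int ngroup = g + 1;
  std::vector<double> sum(ngroup, 0.0);
  std::vector<int> cnt(ngroup, 0);
  for (int i = 0; i < s; ++i) {
    sum[group[i]] += c[i];
    cnt[group[i]] += 1;
  }
  for (int i = 0; i < s; ++i) eff[i] = sum[group[i]] / cnt[group[i]];
}

// rule codes: 0 random, 1 linear, 2 sigmoidal, 3 ranked
static void preference_cpp(const std::vector<double> &pher, int rule,
                           double k, double x, double p_top, int err_uniform,
                           double d, std::vector<double> &prob) {
  int s = pher.size();
  if (rule == 0) {
    for (int i = 0; i < s; ++i) prob[i] = 1.0 / s;
    return;
  }
  std::vector<double> eff(s);
  std::vector<int> group(s);
  if (d > 0) {
    discriminate(pher, d, eff, group);
  } else {
    for (int i = 0; i < s; ++i) { eff[i] = pher[i]; group[i] = i; }
  }
  if (rule == 1 || rule == 2) {
    double kk = (rule == 1) ? 0.0 : k;
    double xx = (rule == 1) ? 1.0 : x;
    double tot = 0.0;
    for (int i = 0; i < s; ++i) {
      prob[i] = std::pow(kk + eff[i], xx);
      tot += prob[i];
    }
    if (tot <= 0.0) {
      for (int i = 0; i < s; ++i) prob[i] = 1.0 / s;
    } else {
      for (int i = 0; i < s; ++i) prob[i] /= tot;
    }
    return;
  }
  // ranked: positional masses for a strict ranking, averaged over tied blocks
  std::vector<double> q(s);
  double rem = 1.0;
  for (int r = 0; r < s - 1; ++r) {
    q[r] = rem * p_top;
    rem *= (1.0 - p_top);
  }
  q[s - 1] = rem;
  if (err_uniform) {
    q[0] = p_top;
    for (int r = 1; r < s; ++r) q[r] = (1.0 - p_top) / (s - 1);
  }
  std::vector<int> ord(s);
  for (int i = 0; i < s; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (eff[a] != eff[b]) return eff[a] > eff[b];
    return a < b;
  });
  // tied trails (equal effective strength) share the mean positional mass
  int j = 0;
  while (j < s) {
    int j2 = j;
    double qs = q[j];
    while (j2 + 1 < s && eff[ord[j2 + 1]] == eff[ord[j]]) {
      ++j2;
      qs += q[j2];
    }
    double qa = qs / (j2 - j + 1);
    for (int r = j; r <= j2; ++r) prob[ord[r]] = qa;
    j = j2 + 1;
  }
}

// [[Rcpp::export]]
NumericVector preference_engine(NumericVector pheromone, int rule, double k,
                                double x, double p_top, int err_uniform,
                                double d) {
  int s = pheromone.size();
  std::vector<double> pher(pheromone.begin(), pheromone.end());
  std::vector<double> prob(s);
  preference_cpp(pher, rule, k, x, p_top, err_uniform, d, prob);
  return NumericVector(prob.begin(), prob.end());
}

// Multinomial draw by sequential conditional binomials; consumes one
// R::rbinom per trail except the last, matching the R reference step.
static void multinom_draw(int n, const std::vector<double> &p,
                          std::vector<int> &out) {
  int s = p.size();
  double rem = 1.0;
  int left = n;
  for (int i = 0; i < s - 1; ++i) {
    double pi = p[i] / rem;
    if (pi > 1.0) pi = 1.0;
    if (pi < 0.0) pi = 0.0;
    // always draw, so the stream matches the R reference step exactly
    int ni = (int)R::rbinom((double)left, pi);
    out[i] = ni;
    left -= ni;
    rem -= p[i];
    if (rem < 1e-14) rem = 1e-14;
  }
  out[s - 1] = left;
}

// One simulation run. Per-step bookkeeping uses counts only (ants are
// interchangeable), so cost is O(n_trails * cycle length) per step.
// deposit_walk = 1: `deposit` units laid per time step of the homeward walk
// by each successful forager; 0: a single `deposit` at nest arrival.
// [[Rcpp::export]]
List sim_run_engine(int colony, int n_steps, int s, double p_leave,
                    int travel_steps, int feed_steps, int return_steps,
                    double deposit, int deposit_walk, double decay,
                    double capacity, int rule, double k, double x,
                    double p_top, int err_uniform, double d,
                    NumericVector pheromone0) {
  RNGScope scope;
  IntegerMatrix choices(n_steps, s);
  IntegerMatrix returns(n_steps, s);
  NumericMatrix pher_rec(n_steps, s);
  IntegerVector outside(n_steps);

  std::vector<double> pher(pheromone0.begin(), pheromone0.end());
  std::vector<double> prob(s);
  std::vector<int> ch(s);
  int nest = colony;
  // queues: [trail][slot], slot 0 = just entered
  std::vector<std::vector<int>> outb(s, std::vector<int>(travel_steps, 0));
  std::vector<std::vector<int>> feed(s, std::vector<int>(feed_steps, 0));
  std::vector<std::vector<int>> inb_s(s, std::vector<int>(return_steps, 0));
  std::vector<std::vector<int>> inb_f(s, std::vector<int>(return_steps, 0));

  for (int t = 0; t < n_steps; ++t) {
    // 1. departures choose a trail from start-of-step pheromone
    int nl = (nest > 0 && p_leave > 0)
                 ? (int)R::rbinom((double)nest, p_leave)
                 : 0;
    if (nl > 0) {
      preference_cpp(pher, rule, k, x, p_top, err_uniform, d, prob);
      multinom_draw(nl, prob, ch);
    } else {
      std::fill(ch.begin(), ch.end(), 0);
    }
    nest -= nl;

    for (int i = 0; i < s; ++i) {
      // 2. queues advance one slot
      int arrive = outb[i][travel_steps - 1];
      for (int j = travel_steps - 1; j > 0; --j) outb[i][j] = outb[i][j - 1];
      outb[i][0] = ch[i];
      int done = feed[i][feed_steps - 1];
      for (int j = feed_steps - 1; j > 0; --j) feed[i][j] = feed[i][j - 1];
      feed[i][0] = 0;
      int ret_s = inb_s[i][return_steps - 1];
      int ret_f = inb_f[i][return_steps - 1];
      for (int j = return_steps - 1; j > 0; --j) {
        inb_s[i][j] = inb_s[i][j - 1];
        inb_f[i][j] = inb_f[i][j - 1];
      }
      // 3. patch admission up to free capacity; overflow turns back
      int occ = 0;
      for (int j = 0; j < feed_steps; ++j) occ += feed[i][j];
      int room = (capacity == R_PosInf)
                     ? arrive
                     : std::max(0, (int)capacity - occ);
      int adm = std::min(arrive, room);
      feed[i][0] = adm;
      inb_f[i][0] = arrive - adm;
      // 4. feeding completions start the homeward walk
      inb_s[i][0] = done;
      // 5. nest arrivals rejoin the pool
      nest += ret_s + ret_f;
      returns(t, i) = ret_s;
      // pheromone deposition
      if (deposit_walk) {
        int walkers = 0;
        for (int j = 0; j < return_steps; ++j) walkers += inb_s[i][j];
        pher[i] += deposit * walkers;
      } else {
        pher[i] += deposit * ret_s;
      }
      // 6. evaporation after all behaviours of the step
      pher[i] *= (1.0 - decay);
      choices(t, i) = ch[i];
      pher_rec(t, i) = pher[i];
    }
    outside[t] = colony - nest;

    // conservation invariant (internal bug guard)
    int tot = nest;
    for (int i = 0; i < s; ++i) {
      for (int j = 0; j < travel_steps; ++j) tot += outb[i][j];
      for (int j = 0; j < feed_steps; ++j) tot += feed[i][j];
      for (int j = 0; j < return_steps; ++j) tot += inb_s[i][j] + inb_f[i][j];
    }
    if (tot != colony) stop("ant conservation violated at step %d", t + 1);
  }

  return List::create(_["choices"] = choices, _["outside"] = outside,
                      _["pheromone"] = pher_rec, _["returns"] = returns);
}
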