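// Structured-coalescent engine.
//
// Time is measured in units of 2*N_ref generations, population sizes are
// relative to N_ref (diffusion scaling).  A model is a set of present-day
// populations plus a time-ordered event list applied backward in time:
//   type 0: set_size(pop, size, growth)   -- size at the event time; going
//           further back the size is  size * exp(-growth * (t - t_event))
//   type 1: join(from, to)                -- lineages in `from` move to `to`
//                                            and `from` is retired
//   type 2: set_migration(rate)           -- per-lineage scaled rate to each
//                                            other active population
// All randomness comes from R's RNG, so set.seed() on the R side makes every
// entry point deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Event {
  double time;
  int type;
  int a;       // pop / from (0-based)
  int b;       // to (0-based)
  double size;
  double growth;
};

struct Model {
  int npop;
  std::vector<double> sizes, growth;
  double mig;
  std::vector<Event> events;
};

Model parse_model(const List& m) {
  Model mod;
  mod.npop = as<int>(m["npop"]);
  mod.sizes = as<std::vector<double> >(m["sizes"]);
  mod.growth = as<std::vector<double> >(m["growth"]);
  mod.mig = as<double>(m["migration"]);
  NumericVector t = m["ev_time"];
  IntegerVector ty = m["ev_type"], ea = m["ev_a"], eb = m["ev_b"];
  NumericVector es = m["ev_size"], eg = m["ev_growth"];
  for (int i = 0; i < t.size(); ++i) {
    Event e;
    e.time = t[i]; e.type = ty[i];
    e.a = ea[i] - 1; e.b = eb[i] - 1;  // R is 1-based
    e.size = es[i]; e.growth = eg[i];
    mod.events.push_back(e);
  }
  return mod;
}

struct PopState {
  bool active;
  double nu;     // size at tref
  double alpha;  // backward growth rate
  double tref;
};

// Genealogy of one non-recombining locus.
struct Genealogy {
  int nleaf;
  int k;                        // number of present-day populations
  std::vector<double> birth, death;
  std::vector<int> child1, child2;   // -1 for leaves
  std::vector<int> cfg;              // flat nleaf-config per lineage, stride k
  int root;
};

double coal_wait(double t, const PopState& p, int kk) {
  if (kk < 2) return INF;
  double C = 0.5 * kk * (kk - 1);
  double nu_t = p.nu * std::exp(-p.alpha * (t - p.tref));
  double E = R::exp_rand();
  if (p.alpha == 0.0) return E * nu_t / C;
  double arg = 1.0 + p.alpha * E * nu_t / C;
  if (arg <= 0.0) return INF;
  return std::log(arg) / p.alpha;
}

// Simulate one genealogy for sample_sizes (per present-day pop).
// The Genealogy and per-population buffers are reused across replicates
// (single-threaded R), which matters in the optimizer's hot loop.
Genealogy& simulate_genealogy(const Model& mod, const std::vector<int>& ss) {
  int k = mod.npop;
  int n = 0;
  for (int i = 0; i < k; ++i) n += ss[i];
  if (n < 2) stop("need at least 2 sampled chromosomes in total");

  static Genealogy g;
  g.nleaf = n; g.k = k;
  int maxlin = 2 * n - 1;
  g.birth.assign(maxlin, 0.0);
  g.death.assign(maxlin, 0.0);
  g.child1.assign(maxlin, -1);
  g.child2.assign(maxlin, -1);
  g.cfg.assign((size_t)maxlin * k, 0);

  static std::vector<PopState> pops;
  pops.assign(k, PopState());
  for (int i = 0; i < k; ++i) {
    pops[i].active = true;
    pops[i].nu = mod.sizes[i];
    pops[i].alpha = mod.growth[i];
    pops[i].tref = 0.0;
  }
  double mig = mod.mig;

  static std::vector<std::vector<int> > byPop;
  if ((int)byPop.size() < k) byPop.resize(k);
  for (int i = 0; i < k; ++i) byPop[i].clear();
  int id = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < ss[i]; ++j) {
      byPop[i].push_back(id);
      g.cfg[(size_t)id * k + i] = 1;
      ++id;
    }

  double t = 0.0;
  size_t evptr = 0;
  int nlive = n;
  int nextid = n;

  while (nlive > 1) {
    int nactive = 0;
    for (int i = 0; i < k; ++i) if (pops[i].active) ++nactive;

    double best = INF;
    int bpop = -1;
    bool bmig = false;
    for (int i = 0; i < k; ++i) {
      if (!pops[i].active) continue;
      double w = coal_wait(t, pops[i], (int)byPop[i].size());
      if (w < best) { best = w; bpop = i; bmig = false; }
    }
    if (mig > 0.0 && nactive > 1) {
      double rate = mig * (nactive - 1) * nlive;
      double w = R::exp_rand() / rate;
      if (w < best) { best = w; bmig = true; }
    }

    double tev = (evptr < mod.events.size()) ? mod.events[evptr].time : INF;
    if (tev <= t + best) {
      if (tev == INF)
        stop("lineages cannot fully coalesce under this model (no further events, no coalescence possible)");
      const Event& e = mod.events[evptr];
      t = e.time;
      if (e.type == 0) {
        pops[e.a].active = true;
        pops[e.a].nu = e.size;
        pops[e.a].alpha = e.growth;
        pops[e.a].tref = t;
      } else if (e.type == 1) {
        for (size_t j = 0; j < byPop[e.a].size(); ++j)
          byPop[e.b].push_back(byPop[e.a][j]);
        byPop[e.a].clear();
        pops[e.a].active = false;
        // freeze receiving pop's reference time (size unchanged at t)
        PopState& pr = pops[e.b];
        pr.nu = pr.nu * std::exp(-pr.alpha * (t - pr.tref));
        pr.tref = t;
      } else if (e.type == 2) {
        mig = e.size;
      }
      ++evptr;
      continue;
    }

    if (best == INF)
      stop("lineages cannot fully coalesce under this model (no further events, no coalescence possible)");
    t += best;

    if (bmig) {
      // uniform lineage, move to a uniform other active pop
      int r = (int)std::floor(R::unif_rand() * nlive);
      if (r >= nlive) r = nlive - 1;
      int src = -1, idx = -1;
      for (int i = 0; i < k; ++i) {
        int sz = (int)byPop[i].size();
        if (r < sz) { src = i; idx = r; break; }
        r -= sz;
      }
      int nopts = nactive - 1;
      int pick = (int)std::floor(R::unif_rand() * nopts);
      if (pick >= nopts) pick = nopts - 1;
      int dst = -1;
      for (int i = 0; i < k; ++i) {
        if (!pops[i].active || i == src) continue;
        if (pick == 0) { dst = i; break; }
        --pick;
      }
      int lin = byPop[src][idx];
      byPop[src][idx] = byPop[src].back();
      byPop[src].pop_back();
      byPop[dst].push_back(lin);
    } else {
      std::vector<int>& v = byPop[bpop];
      int kk = (int)v.size();
      int i1 = (int)std::floor(R::unif_rand() * kk);
      if (i1 >= kk) i1 = kk - 1;
      int i2 = (int)std::floor(R::unif_rand() * (kk - 1));
      if (i2 >= kk - 1) i2 = kk - 2;
      if (i2 >= i1) ++i2;
      int a = v[i1], b = v[i2];
      // remove both (remove larger index first)
      int hi = std::max(i1, i2), lo = std::min(i1, i2);
      v[hi] = v.back(); v.pop_back();
      v[lo] = v.back(); v.pop_back();
      int nw = nextid++;
      g.birth[nw] = t;
      g.death[a] = t; g.death[b] = t;
      g.child1[nw] = a; g.child2[nw] = b;
      for (int j = 0; j < k; ++j)
        g.cfg[(size_t)nw * k + j] =
          g.cfg[(size_t)a * k + j] + g.cfg[(size_t)b * k + j];
      v.push_back(nw);
      --nlive;
    }
  }

  int root = -1;
  for (int i = 0; i < k; ++i)
    if (!byPop[i].empty()) root = byPop[i][0];
  g.death[root] = t;
  g.root = root;
  return g;
}

// linear (column-major, R array layout) index of a config
inline size_t cfg_index(const int* cfg, const std::vector<int>& dims, int k) {
  size_t idx = 0, mult = 1;
  for (int j = 0; j < k; ++j) {
    idx += (size_t)cfg[j] * mult;
    mult *= dims[j];
  }
  return idx;
}

void collect_leaves(const Genealogy& g, int node, std::vector<int>& out) {
  if (g.child1[node] < 0) { out.push_back(node); return; }
  std::vector<int> stack;
  stack.push_back(node);
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    if (g.child1[nd] < 0) out.push_back(nd);
    else { stack.push_back(g.child1[nd]); stack.push_back(g.child2[nd]); }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_branch_sfs")]]
List cpp_branch_sfs(List model, IntegerVector sample_sizes, int nreps) {
  Model mod = parse_model(model);
  std::vector<int> ss = as<std::vector<int> >(sample_sizes);
  int k = mod.npop;
  if ((int)ss.size() != k) stop("sample_sizes length must equal number of populations");
  std::vector<int> dims(k);
  size_t size = 1;
  for (int j = 0; j < k; ++j) { dims[j] = ss[j] + 1; size *= dims[j]; }

  std::vector<double> sum(size, 0.0), sumsq(size, 0.0), rep(size, 0.0);
  std::vector<size_t> touched;
  for (int r = 0; r < nreps; ++r) {
    Genealogy& g = simulate_genealogy(mod, ss);
    int nlin = 2 * g.nleaf - 1;
    touched.clear();
    for (int i = 0; i < nlin; ++i) {
      if (i == g.root) continue;
      double len = g.death[i] - g.birth[i];
      size_t idx = cfg_index(&g.cfg[(size_t)i * k], dims, k);
      if (rep[idx] == 0.0) touched.push_back(idx);
      rep[idx] += len;
    }
    for (size_t j = 0; j < touched.size(); ++j) {
      size_t idx = touched[j];
      sum[idx] += rep[idx];
      sumsq[idx] += rep[idx] * rep[idx];
      rep[idx] = 0.0;
    }
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector mean(size), se(size);
  for (size_t i = 0; i < size; ++i) {
    double m = sum[i] / nreps;
    mean[i] = m;
    double var = (sumsq[i] / nreps - m * m) / std::max(1, nreps - 1) * nreps;
    se[i] = std::sqrt(std::max(0.0, var) / nreps);
  }
  return List::create(_["mean"] = mean, _["se"] = se, _["dims"] = wrap(dims));
}

//' @noRd
// [[Rcpp::export(name = "cpp_sim_loci")]]
List cpp_sim_loci(List model, IntegerVector sample_sizes, double theta_locus,
                  int nloci) {
  Model mod = parse_model(model);
  std::vector<int> ss = as<std::vector<int> >(sample_sizes);
  if ((int)ss.size() != mod.npop) stop("sample_sizes length must equal number of populations");
  int n = 0;
  for (size_t i = 0; i < ss.size(); ++i) n += ss[i];

  List out(nloci);
  for (int l = 0; l < nloci; ++l) {
    Genealogy& g = simulate_genealogy(mod, ss);
    int nlin = 2 * n - 1;
    std::vector<double> cum(nlin, 0.0);
    double tot = 0.0;
    for (int i = 0; i < nlin; ++i) {
      if (i != g.root) tot += g.death[i] - g.birth[i];
      cum[i] = tot;
    }
    int nmut = (int)R::rpois(0.5 * theta_locus * tot);
    IntegerMatrix m(nmut, n);  // sites x chromosomes, 0/1 derived
    for (int s = 0; s < nmut; ++s) {
      double u = R::unif_rand() * tot;
      int lo = 0, hi = nlin - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      std::vector<int> leaves;
      collect_leaves(g, lo, leaves);
      for (size_t j = 0; j < leaves.size(); ++j) m(s, leaves[j]) = 1;
    }
    out[l] = m;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_sim_pair_times")]]
List cpp_sim_pair_times(List model, IntegerVector sample_sizes, int nreps) {
  Model mod = parse_model(model);
  std::vector<int> ss = as<std::vector<int> >(sample_sizes);
  NumericVector tmrca(nreps), totlen(nreps);
  for (int r = 0; r < nreps; ++r) {
    Genealogy& g = simulate_genealogy(mod, ss);
    int nlin = 2 * g.nleaf - 1;
    double tot = 0.0;
    for (int i = 0; i < nlin; ++i)
      if (i != g.root) tot += g.death[i] - g.birth[i];
    tmrca[r] = g.death[g.root];
    totlen[r] = tot;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tmrca"] = tmrca, _["total_length"] = totlen);
}

//' @noRd
// [[Rcpp::export(name = "cpp_sim_tajima_null")]]
NumericVector cpp_sim_tajima_null(int n, int S, int nreps) {
  if (n < 4) stop("need at least 4 chromosomes");
  if (S < 1) stop("need S >= 1");
  // Tajima (1989) constants
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double denom = std::sqrt(e1 * S + e2 * S * (S - 1.0));
  double nc2 = 0.5 * n * (n - 1.0);

  Model mod;
  mod.npop = 1;
  mod.sizes.assign(1, 1.0);
  mod.growth.assign(1, 0.0);
  mod.mig = 0.0;
  std::vector<int> ss(1, n);

  NumericVector out(nreps);
  for (int r = 0; r < nreps; ++r) {
    Genealogy& g = simulate_genealogy(mod, ss);
    int nlin = 2 * n - 1;
    std::vector<double> cum(nlin, 0.0);
    double tot = 0.0;
    for (int i = 0; i < nlin; ++i) {
      if (i != g.root) tot += g.death[i] - g.birth[i];
      cum[i] = tot;
    }
    double pi_sum = 0.0;
    for (int s = 0; s < S; ++s) {
      double u = R::unif_rand() * tot;
      int lo = 0, hi = nlin - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      int c = g.cfg[lo];  // k = 1
      pi_sum += (double)c * (n - c);
    }
    double pi = pi_sum / nc2;
    out[r] = (pi - S / a1) / denom;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
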