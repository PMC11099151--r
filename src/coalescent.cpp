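// Coalescent engine for structured populations with population-specific
// effective recombination (rho_eff = rho * sigma).
//
// Design: each population p carries an independent Poisson breakpoint process
// along the chromosome with intensity 4*N_p*rho_p*sigma_p per bp.  Between
// two consecutive pop-p breakpoints the within-population part of p's
// genealogy (from the present back to the first demographic event involving
// p) is held fixed; at a breakpoint it is redrawn.  The post-event
// ("ancestral") part of the genealogy is redrawn for every local block
// (union of all populations' breakpoints) -- an SMC-flavoured approximation.
// Mutations are dropped on each local tree under the infinite-sites model.
//
// Uses R's RNG throughout so that set.seed() in R gives full determinism.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Forest {
  // Internal nodes only; tips are encoded by their global id (< ntot),
  // internal nodes by ntot + local index.
  std::vector<double> time;
  std::vector<int> childA, childB;
  std::vector<int> roots;  // encoded surviving lineages at phase end
};

// Kingman coalescent among `tips` in a diploid population of size N,
// run from time 0 to t_end (generations).
Forest sim_forest(const std::vector<int>& tips, double N, double t_end,
                  int ntot) {
  Forest f;
  std::vector<int> act(tips);
  double t = 0.0;
  while (act.size() > 1) {
    const double k = static_cast<double>(act.size());
    const double rate = k * (k - 1.0) / (4.0 * N);
    t += exp_rand() / rate;
    if (t > t_end) break;
    int i = static_cast<int>(unif_rand() * act.size());
    int j = static_cast<int>(unif_rand() * (act.size() - 1));
    if (j >= i) ++j;
    const int code = ntot + static_cast<int>(f.time.size());
    f.time.push_back(t);
    f.childA.push_back(act[i]);
    f.childB.push_back(act[j]);
    act[std::min(i, j)] = code;
    act.erase(act.begin() + std::max(i, j));
  }
  f.roots = act;
  return f;
}

struct DemEvent {
  double time;
  int type;  // 0 = activation of sampled pop's surviving lineages, 1 = merge
  int pop_a; // activation: pop; merge: child
  int pop_b; // merge: parent
};

}  // namespace

// [[Rcpp::export(name = ".sim_chromosome_cpp")]]
List sim_chromosome_cpp(int npop,
                        IntegerVector nhap,
                        NumericVector Ndip,
                        NumericVector breaks_per_bp,
                        double mu_bp,
                        double L,
                        NumericVector phase_end,
                        NumericVector merge_time,
                        IntegerVector merge_child,
                        IntegerVector merge_parent) {
  const int ntot = std::accumulate(nhap.begin(), nhap.end(), 0);
  if (ntot < 2) stop("need at least two haplotypes");

  // global tip ids per population
  std::vector<std::vector<int>> tip_ids(npop);
  {
    int next = 0;
    for (int p = 0; p < npop; ++p)
      for (int i = 0; i < nhap[p]; ++i) tip_ids[p].push_back(next++);
  }

  // population-specific breakpoints
  std::vector<std::vector<double>> bp(npop);
  IntegerVector n_recomb(npop);
  std::vector<double> all_bp;
  for (int p = 0; p < npop; ++p) {
    const double lambda = breaks_per_bp[p] * L;
    const int nb = lambda > 0 ? static_cast<int>(R::rpois(lambda)) : 0;
    n_recomb[p] = nb;
    for (int i = 0; i < nb; ++i) bp[p].push_back(unif_rand() * L);
    std::sort(bp[p].begin(), bp[p].end());
    all_bp.insert(all_bp.end(), bp[p].begin(), bp[p].end());
  }
  std::sort(all_bp.begin(), all_bp.end());
  all_bp.erase(std::unique(all_bp.begin(), all_bp.end()), all_bp.end());

  // within-population forests per pop segment
  std::vector<std::vector<Forest>> forests(npop);
  for (int p = 0; p < npop; ++p) {
    if (nhap[p] == 0) continue;
    const int nseg = static_cast<int>(bp[p].size()) + 1;
    forests[p].reserve(nseg);
    for (int s = 0; s < nseg; ++s)
      forests[p].push_back(sim_forest(tip_ids[p], Ndip[p], phase_end[p], ntot));
  }

  // demographic event schedule (activations before merges at equal times)
  std::vector<DemEvent> events;
  for (int p = 0; p < npop; ++p)
    if (nhap[p] > 0 && R_finite(phase_end[p]))
      events.push_back({phase_end[p], 0, p, -1});
  for (int m = 0; m < merge_time.size(); ++m)
    events.push_back({merge_time[m], 1, merge_child[m], merge_parent[m]});
  std::stable_sort(events.begin(), events.end(),
                   [](const DemEvent& a, const DemEvent& b) {
                     if (a.time != b.time) return a.time < b.time;
                     return a.type < b.type;
                   });

  // per-block simulation and mutation dropping
  std::vector<double> block_edges;
  block_edges.push_back(0.0);
  block_edges.insert(block_edges.end(), all_bp.begin(), all_bp.end());
  block_edges.push_back(L);
  const int nblocks = static_cast<int>(block_edges.size()) - 1;

  std::vector<double> mut_pos;
  std::vector<std::vector<int>> mut_carriers;

  std::vector<double> times;
  std::vector<int> cA, cB;
  std::vector<double> cum;

  for (int g = 0; g < nblocks; ++g) {
    const double lo = block_edges[g], hi = block_edges[g + 1];
    const double mid = 0.5 * (lo + hi);

    // assemble block tree: tips then forest copies then ancestral nodes
    times.assign(ntot, 0.0);
    cA.assign(ntot, -1);
    cB.assign(ntot, -1);
    std::vector<std::vector<int>> act(npop);
    std::vector<std::vector<int>> pending_roots(npop);

    for (int p = 0; p < npop; ++p) {
      if (nhap[p] == 0) continue;
      const int seg = static_cast<int>(
          std::upper_bound(bp[p].begin(), bp[p].end(), mid) - bp[p].begin());
      const Forest& f = forests[p][seg];
      const int base = static_cast<int>(times.size());
      for (size_t i = 0; i < f.time.size(); ++i) {
        int a = f.childA[i], b = f.childB[i];
        if (a >= ntot) a = base + (a - ntot);
        if (b >= ntot) b = base + (b - ntot);
        times.push_back(f.time[i]);
        cA.push_back(a);
        cB.push_back(b);
      }
      std::vector<int>& dst =
          R_finite(phase_end[p]) ? pending_roots[p] : act[p];
      for (int r : f.roots) dst.push_back(r >= ntot ? base + (r - ntot) : r);
      if (!R_finite(phase_end[p]) && npop == 1) {
        // single population, full coalescence already achieved in the forest
      }
    }

    // ancestral (event-driven structured) phase
    int total = 0;
    for (int p = 0; p < npop; ++p)
      total += static_cast<int>(act[p].size() + pending_roots[p].size());
    double t = 0.0;
    size_t ev = 0;
    while (total > 1) {
      double rate = 0.0;
      for (int p = 0; p < npop; ++p) {
        const double k = static_cast<double>(act[p].size());
        if (k >= 2) rate += k * (k - 1.0) / (4.0 * Ndip[p]);
      }
      double tc = R_PosInf;
      if (rate > 0) tc = t + exp_rand() / rate;
      if (ev < events.size() && events[ev].time <= tc) {
        t = events[ev].time;
        const DemEvent& e = events[ev];
        if (e.type == 0) {
          for (int r : pending_roots[e.pop_a]) act[e.pop_a].push_back(r);
          pending_roots[e.pop_a].clear();
        } else {
          for (int r : act[e.pop_a]) act[e.pop_b].push_back(r);
          act[e.pop_a].clear();
        }
        ++ev;
        continue;
      }
      if (!R_finite(tc)) stop("disconnected demography: lineages cannot coalesce");
      t = tc;
      double u = unif_rand() * rate;
      int p = -1;
      for (int q = 0; q < npop; ++q) {
        const double k = static_cast<double>(act[q].size());
        if (k >= 2) {
          u -= k * (k - 1.0) / (4.0 * Ndip[q]);
          if (u <= 0) { p = q; break; }
        }
      }
      if (p < 0) continue;
      int i = static_cast<int>(unif_rand() * act[p].size());
      int j = static_cast<int>(unif_rand() * (act[p].size() - 1));
      if (j >= i) ++j;
      const int node = static_cast<int>(times.size());
      times.push_back(t);
      cA.push_back(act[p][i]);
      cB.push_back(act[p][j]);
      act[p][std::min(i, j)] = node;
      act[p].erase(act[p].begin() + std::max(i, j));
      --total;
    }

    // branch lengths (all nodes except the root have a parent)
    const int nn = static_cast<int>(times.size());
    std::vector<double> blen(nn, 0.0);
    for (int v = ntot; v < nn; ++v) {
      blen[cA[v]] = times[v] - times[cA[v]];
      blen[cB[v]] = times[v] - times[cB[v]];
    }
    double tot_len = 0.0;
    for (int v = 0; v < nn - 1; ++v) tot_len += blen[v];
    if (tot_len <= 0) continue;

    const double lambda_mut = mu_bp * (hi - lo) * tot_len;
    const int M = static_cast<int>(R::rpois(lambda_mut));
    if (M == 0) continue;

    // descendant tip sets (index order is topological)
    std::vector<std::vector<int>> desc(nn);
    for (int v = 0; v < ntot; ++v) desc[v].push_back(v);
    for (int v = ntot; v < nn; ++v) {
      desc[v] = desc[cA[v]];
      desc[v].insert(desc[v].end(), desc[cB[v]].begin(), desc[cB[v]].end());
    }
    cum.assign(nn - 1, 0.0);
    double acc = 0.0;
    for (int v = 0; v < nn - 1; ++v) { acc += blen[v]; cum[v] = acc; }
    for (int m = 0; m < M; ++m) {
      const double u = unif_rand() * acc;
      const int v = static_cast<int>(
          std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      mut_pos.push_back(lo + unif_rand() * (hi - lo));
      mut_carriers.push_back(desc[v]);
    }
  }

  // order sites by position
  const int S = static_cast<int>(mut_pos.size());
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });

  NumericVector pos(S);
  IntegerMatrix hap(ntot, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = mut_pos[ord[s]];
    for (int tip : mut_carriers[ord[s]]) hap(tip, s) = 1;
  }

  return List::create(_["positions"] = pos,
                      _["haplotypes"] = hap,
                      _["n_recomb"] = n_recomb,
                      _["n_blocks"] = nblocks);
}
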