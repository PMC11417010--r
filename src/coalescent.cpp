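#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent core for one or two demes with epochs of size change
// and (possibly asymmetric) migration.
//
// Epoch matrix `ep` (rows oldest -> newest), columns:
//   0: T        epoch duration, units of 2*Ne_anc generations
//   1: ndemes   1 or 2
//   2: nu1_start  3: nu1_end  4: dyn1 (0 sudden, 1 linear, 2 exponential)
//   5: nu2_start  6: nu2_end  7: dyn2
//   8: M_1to2   forward-time scaled migration 2*Ne_anc*m (deme1 -> deme2)
//   9: M_2to1
// Older than the first row sits a single ancestral deme at nu = 1.
// Backward-time convention: a lineage now in deme d jumps to deme e at the
// rate of forward flow e -> d (migrants present in d trace back to e).

struct Lineage {
  int node;   // tree node id (1-based), tree mode only
  int i, j;   // descendant leaf counts per deme, SFS mode only
  int deme;   // 1 or 2
};

struct EpochView {
  double T, s0, s1; // backward global times: s0 (recent) .. s1 (old)
  int ndemes;
  double nu1s, nu1e, nu2s, nu2e;
  int dyn1, dyn2;
  double m12, m21;
};

static double nu_at(double u, double T, double nus, double nue, int dyn) {
  // u: backward-local time in [0, T]; u = 0 is the recent edge of the epoch
  if (dyn == 0 || T <= 0.0) return nue;
  double f = (T - u) / T; // forward fraction through the epoch
  if (dyn == 1) return nus + (nue - nus) * f;
  return nus * std::pow(nue / nus, f); // exponential
}

static std::vector<EpochView> build_views(const NumericMatrix& ep) {
  std::vector<EpochView> v;
  int ne = ep.nrow();
  double s = 0.0;
  for (int r = ne - 1; r >= 0; --r) { // newest first, stacking backward times
    EpochView e;
    e.T = ep(r, 0); e.ndemes = (int)ep(r, 1);
    e.nu1s = ep(r, 2); e.nu1e = ep(r, 3); e.dyn1 = (int)ep(r, 4);
    e.nu2s = ep(r, 5); e.nu2e = ep(r, 6); e.dyn2 = (int)ep(r, 7);
    e.m12 = ep(r, 8); e.m21 = ep(r, 9);
    e.s0 = s; e.s1 = s + e.T; s = e.s1;
    v.push_back(e);
  }
  return v;
}

// One realization of the genealogy; fills tree arrays if `tree_mode`,
// otherwise accumulates per-lineage (i,j) occupancy time into `grid`.
// Returns total branch length (units of 2*Ne_anc generations).
static double simulate_once(int k1, int k2,
                            const std::vector<EpochView>& eps,
                            double time_cap, bool tree_mode,
                            std::vector<int>* parent, std::vector<double>* ntime,
                            std::vector<int>* chA, std::vector<int>* chB,
                            double* grid, int g1, int g2) {
  int n = k1 + k2;
  std::vector<Lineage> act;
  act.reserve(n);
  for (int a = 0; a < k1; ++a) act.push_back({a + 1, 1, 0, 1});
  for (int a = 0; a < k2; ++a) act.push_back({k1 + a + 1, 0, 1, 2});
  int next_node = n + 1;
  double s = 0.0, total_len = 0.0;
  size_t ei = 0;
  bool ancestral = eps.empty();

  auto flush = [&](double ds) {
    total_len += ds * act.size();
    if (!tree_mode && grid) {
      for (const Lineage& L : act) grid[L.i + (g1 + 1) * L.j] += ds;
    }
  };

  while (act.size() > 1) {
    // current epoch window [s0, s1) and parameters
    double s1, numin1, numin2, m_bw1, m_bw2; // m_bw1: rate deme1 lineage -> deme2
    int ndem;
    const EpochView* E = nullptr;
    if (!ancestral && ei < eps.size()) {
      E = &eps[ei];
      s1 = E->s1; ndem = E->ndemes;
      numin1 = (E->dyn1 == 0) ? E->nu1e : std::min(E->nu1s, E->nu1e);
      numin2 = (E->dyn2 == 0) ? E->nu2e : std::min(E->nu2s, E->nu2e);
      m_bw1 = (ndem == 2) ? E->m21 : 0.0; // deme1 lineage traces back to source of 2->1 flow
      m_bw2 = (ndem == 2) ? E->m12 : 0.0;
    } else {
      ancestral = true;
      s1 = R_PosInf; ndem = 1; numin1 = 1.0; numin2 = 1.0; m_bw1 = m_bw2 = 0.0;
      E = nullptr;
    }
    if (ndem == 1) {
      // collapse: any deme-2 lineages belong to the single (ancestral) deme
      for (Lineage& L : act) L.deme = 1;
    }

    bool epoch_done = false;
    while (!epoch_done && act.size() > 1) {
      int c1 = 0, c2 = 0;
      for (const Lineage& L : act) (L.deme == 1 ? c1 : c2)++;
      double cr1max = 0.5 * c1 * (c1 - 1) / numin1;
      double cr2max = (ndem == 2 && numin2 > 0) ? 0.5 * c2 * (c2 - 1) / numin2 : 0.0;
      double mg1 = c1 * m_bw1, mg2 = c2 * m_bw2;
      double lmax = cr1max + cr2max + mg1 + mg2;
      if (lmax <= 0.0) { // nothing can happen here; advance to boundary
        if (!R_FINITE(s1)) stop("non-coalescing configuration: no events possible in unbounded ancestral epoch");
        flush(s1 - s); s = s1; break;
      }
      double dt = R::exp_rand() / lmax;
      if (s + dt >= s1) { flush(s1 - s); s = s1; break; }
      flush(dt); s += dt;
      if (s > time_cap)
        stop("genealogy did not coalesce before the time cap (%.1f); check migration/join structure", time_cap);
      // actual rates at time s (thinning for time-varying sizes)
      double nu1 = E ? nu_at(s - E->s0, E->T, E->nu1s, E->nu1e, E->dyn1) : 1.0;
      double nu2 = (E && ndem == 2) ? nu_at(s - E->s0, E->T, E->nu2s, E->nu2e, E->dyn2) : 1.0;
      double cr1 = 0.5 * c1 * (c1 - 1) / nu1;
      double cr2 = (ndem == 2) ? 0.5 * c2 * (c2 - 1) / nu2 : 0.0;
      double ltot = cr1 + cr2 + mg1 + mg2;
      double u = unif_rand() * lmax;
      if (u >= ltot) continue; // thinning rejection
      if (u < cr1 + cr2) {
        int deme = (u < cr1) ? 1 : 2;
        // pick an unordered pair within `deme`
        std::vector<int> idx;
        for (size_t a = 0; a < act.size(); ++a) if (act[a].deme == deme) idx.push_back((int)a);
        int kk = (int)idx.size();
        int a1 = (int)(unif_rand() * kk); if (a1 >= kk) a1 = kk - 1;
        int a2 = (int)(unif_rand() * (kk - 1)); if (a2 >= kk - 1) a2 = kk - 2;
        if (a2 >= a1) a2++;
        int ia = idx[a1], ib = idx[a2];
        if (tree_mode) {
          int nd = next_node++;
          (*parent)[act[ia].node - 1] = nd;
          (*parent)[act[ib].node - 1] = nd;
          (*ntime)[nd - 1] = s;
          (*chA)[nd - 1] = act[ia].node;
          (*chB)[nd - 1] = act[ib].node;
          act[ia].node = nd;
        }
        act[ia].i += act[ib].i; act[ia].j += act[ib].j;
        act.erase(act.begin() + ib);
      } else {
        double um = u - cr1 - cr2;
        int from = (um < mg1) ? 1 : 2;
        std::vector<int> idx;
        for (size_t a = 0; a < act.size(); ++a) if (act[a].deme == from) idx.push_back((int)a);
        int pick = (int)(unif_rand() * idx.size()); if (pick >= (int)idx.size()) pick = (int)idx.size() - 1;
        act[idx[pick]].deme = (from == 1) ? 2 : 1;
      }
      epoch_done = false;
    }
    if (act.size() > 1 && s >= s1 && !ancestral) ++ei;
    if (s > time_cap)
      stop("genealogy did not coalesce before the time cap (%.1f)", time_cap);
  }
  if (tree_mode && n > 1) {
    // root node time recorded at its creation; nothing further
  }
  return total_len;
}

// [[Rcpp::export(name = ".sim_tree_cpp")]]
List sim_tree_cpp(int k1, int k2, NumericMatrix ep, double time_cap) {
  int n = k1 + k2;
  if (n < 1) stop("need at least one lineage");
  std::vector<EpochView> eps = build_views(ep);
  if (n == 1) {
    return List::create(_["n_leaves"] = 1,
                        _["edge"] = IntegerMatrix(0, 2),
                        _["length"] = NumericVector(0),
                        _["node_time"] = NumericVector::create(0.0),
                        _["leaf_deme"] = IntegerVector::create(k1 == 1 ? 1 : 2),
                        _["total_length"] = 0.0);
  }
  int nn = 2 * n - 1;
  std::vector<int> parent(nn, 0), chA(nn, 0), chB(nn, 0);
  std::vector<double> ntime(nn, 0.0);
  double tot = simulate_once(k1, k2, eps, time_cap, true,
                             &parent, &ntime, &chA, &chB, nullptr, 0, 0);
  IntegerMatrix edge(nn - 1, 2);
  NumericVector elen(nn - 1);
  int r = 0;
  for (int v = 1; v <= nn; ++v) {
    if (parent[v - 1] > 0) {
      edge(r, 0) = v; edge(r, 1) = parent[v - 1];
      elen[r] = ntime[parent[v - 1] - 1] - ntime[v - 1];
      ++r;
    }
  }
  IntegerVector ld(n);
  for (int a = 0; a < n; ++a) ld[a] = (a < k1) ? 1 : 2;
  return List::create(_["n_leaves"] = n, _["edge"] = edge, _["length"] = elen,
                      _["node_time"] = NumericVector(ntime.begin(), ntime.end()),
                      _["leaf_deme"] = ld, _["total_length"] = tot);
}

// Monte-Carlo estimate of expected branch length subtending (i, j) leaf
// configurations: E[xi_ij] = (theta / 2) * mean_grid[i, j].
// [[Rcpp::export(name = ".mc_branch_sfs_cpp")]]
List mc_branch_sfs_cpp(int k1, int k2, NumericMatrix ep, int nreps, double time_cap) {
  std::vector<EpochView> eps = build_views(ep);
  int g1 = k1, g2 = k2;
  int ncell = (g1 + 1) * (g2 + 1);
  std::vector<double> grid(ncell), sum(ncell, 0.0), sumsq(ncell, 0.0);
  for (int r = 0; r < nreps; ++r) {
    std::fill(grid.begin(), grid.end(), 0.0);
    simulate_once(k1, k2, eps, time_cap, false,
                  nullptr, nullptr, nullptr, nullptr, grid.data(), g1, g2);
    for (int c = 0; c < ncell; ++c) { sum[c] += grid[c]; sumsq[c] += grid[c] * grid[c]; }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(g1 + 1, g2 + 1), se(g1 + 1, g2 + 1);
  for (int j = 0; j <= g2; ++j) for (int i = 0; i <= g1; ++i) {
    int c = i + (g1 + 1) * j;
    double m = sum[c] / nreps;
    double var = (sumsq[c] - nreps * m * m) / std::max(1, nreps - 1);
    mean(i, j) = m;
    se(i, j) = std::sqrt(std::max(0.0, var) / nreps);
  }
  return List::create(_["mean"] = mean, _["se"] = se, _["nreps"] = nreps);
}

// Batch simulation of contigs: genealogy + infinite-sites mutations, returning
// a 0/1 haplotype matrix per segregating site. `mut_per_unit` is the expected
// number of mutations per unit of branch length (= mu * L_contig * 2 * Ne_anc).
// [[Rcpp::export(name = ".sim_contig_sites_cpp")]]
List sim_contig_sites_cpp(int k1, int k2, NumericMatrix ep, int n_contigs,
                          double mut_per_unit, double time_cap) {
  int n = k1 + k2;
  std::vector<EpochView> eps = build_views(ep);
  std::vector<std::vector<int> > carriers; // per site: leaf ids (1-based)
  std::vector<int> site_contig;
  int nn = 2 * n - 1;
  std::vector<int> parent(nn), chA(nn), chB(nn);
  std::vector<double> ntime(nn);
  std::vector<int> stack; stack.reserve(n);
  for (int cg = 1; cg <= n_contigs; ++cg) {
    if (n == 1) continue;
    std::fill(parent.begin(), parent.end(), 0);
    std::fill(chA.begin(), chA.end(), 0);
    std::fill(chB.begin(), chB.end(), 0);
    std::fill(ntime.begin(), ntime.end(), 0.0);
    double tot = simulate_once(k1, k2, eps, time_cap, true,
                               &parent, &ntime, &chA, &chB, nullptr, 0, 0);
    int nmut = (int)R::rpois(mut_per_unit * tot);
    if (nmut <= 0) { if ((cg & 255) == 0) Rcpp::checkUserInterrupt(); continue; }
    // cumulative branch lengths over non-root nodes
    std::vector<double> cum(nn, 0.0);
    double acc = 0.0;
    for (int v = 1; v <= nn; ++v) {
      if (parent[v - 1] > 0) acc += ntime[parent[v - 1] - 1] - ntime[v - 1];
      cum[v - 1] = acc;
    }
    for (int mu_i = 0; mu_i < nmut; ++mu_i) {
      double u = unif_rand() * acc;
      int v = 1;
      while (v <= nn && cum[v - 1] < u) ++v;
      if (v > nn) v = nn;
      // descendants of v
      std::vector<int> car;
      stack.clear(); stack.push_back(v);
      while (!stack.empty()) {
        int w = stack.back(); stack.pop_back();
        if (w <= n) car.push_back(w);
        else { stack.push_back(chA[w - 1]); stack.push_back(chB[w - 1]); }
      }
      carriers.push_back(car);
      site_contig.push_back(cg);
    }
    if ((cg & 255) == 0) Rcpp::checkUserInterrupt();
  }
  int ns = (int)carriers.size();
  IntegerMatrix hap(ns, n);
  for (int sidx = 0; sidx < ns; ++sidx)
    for (int leaf : carriers[sidx]) hap(sidx, leaf - 1) = 1;
  return List::create(_["haplotypes"] = hap,
                      _["contig"] = IntegerVector(site_contig.begin(), site_contig.end()));
}
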