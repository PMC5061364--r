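// Structured-coalescent core for the two-deme isolation-with-migration
// model. Time runs backwards in generations; each deme of N diploids holds
// 2N gene copies, so a pair of lineages within a deme coalesces at rate
// 1/(2N) per generation and each lineage migrates (backwards) at its
// per-generation rate. At T_div both demes merge into one ancestral deme.
//
// Three entry points share one event loop:
//  - branch-length accumulation into the joint SFS (expected-SFS service),
//  - Poisson mutation counts into the joint SFS (pseudo-observed data),
//  - full genotype matrices (0/1 derived alleles per sampled copy).
//
// Uses R's RNG so set.seed() in R makes every run reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Lineage {
  int d1, d2;    // sampled descendants in deme 1 / deme 2
  int deme;      // current deme (0 or 1; 0 also = ancestral pool)
  int id;        // node id (genotype mode only)
};

struct SimState {
  int n1, n2;
  double N, Nanc, Tdiv, m12, m21;
  bool panmictic_phase1;
};

// When both backward migration rates are large relative to the
// coalescence rate the two demes mix much faster than they coalesce and
// the genealogy is that of a single pool of 4N copies; simulating every
// migration event would cost O(N*m) events per coalescence for no
// distributional gain.
inline bool strong_migration(double N, double m12, double m21) {
  return (2.0 * N * m12 > 50.0) && (2.0 * N * m21 > 50.0);
}

typedef void (*IntervalFn)(const std::vector<Lineage>&, double, void*);

// Shared event loop. Calls `fn(lineages, dt, payload)` for every interval
// of constant lineage configuration; `merge_cb` (genotype mode) records
// coalescences.
void run_coalescent(const SimState& st, IntervalFn fn, void* payload,
                    std::vector<std::pair<int, std::pair<int,int> > >* merges,
                    int* next_id) {
  std::vector<Lineage> lin;
  lin.reserve(st.n1 + st.n2);
  for (int i = 0; i < st.n1; ++i) lin.push_back(Lineage{1, 0, 0, i});
  for (int i = 0; i < st.n2; ++i)
    lin.push_back(Lineage{0, 1, 1, st.n1 + i});

  double t = 0.0;
  bool merged = false;
  const bool pan1 = st.panmictic_phase1;

  while (lin.size() > 1) {
    int k0 = 0, k1 = 0;
    for (size_t i = 0; i < lin.size(); ++i) (lin[i].deme == 0 ? k0 : k1)++;

    double rate_c0, rate_c1, rate_m0, rate_m1;
    if (merged) {
      rate_c0 = k0 * (k0 - 1) / 2.0 / (2.0 * st.Nanc);
      rate_c1 = rate_m0 = rate_m1 = 0.0;
    } else if (pan1) {
      // strong-migration limit: one pool of 2 demes x 2N copies
      int k = k0 + k1;
      rate_c0 = k * (k - 1) / 2.0 / (4.0 * st.N);
      rate_c1 = rate_m0 = rate_m1 = 0.0;
    } else {
      rate_c0 = k0 * (k0 - 1) / 2.0 / (2.0 * st.N);
      rate_c1 = k1 * (k1 - 1) / 2.0 / (2.0 * st.N);
      rate_m0 = k0 * st.m12;
      rate_m1 = k1 * st.m21;
    }
    double total = rate_c0 + rate_c1 + rate_m0 + rate_m1;

    double dt;
    if (total <= 0.0) {
      dt = R_PosInf;
    } else {
      dt = R::exp_rand() / total;
    }

    if (!merged && t + dt >= st.Tdiv) {
      double span = st.Tdiv - t;
      if (span > 0.0) fn(lin, span, payload);
      t = st.Tdiv;
      merged = true;
      for (size_t i = 0; i < lin.size(); ++i) lin[i].deme = 0;
      continue;
    }

    fn(lin, dt, payload);
    t += dt;

    double u = R::unif_rand() * total;
    if (u < rate_c0 + rate_c1) {
      int deme = (u < rate_c0) ? 0 : 1;
      if (merged || pan1) deme = -1; // any deme = single pool
      // pick two distinct lineages in `deme` (or anywhere if deme == -1)
      std::vector<int> idx;
      for (size_t i = 0; i < lin.size(); ++i)
        if (deme < 0 || lin[i].deme == deme) idx.push_back((int)i);
      int a = (int)(R::unif_rand() * idx.size());
      int b = (int)(R::unif_rand() * (idx.size() - 1));
      if (b >= a) b++;
      int ia = idx[a], ib = idx[b];
      if (ia > ib) std::swap(ia, ib);
      Lineage parent;
      parent.d1 = lin[ia].d1 + lin[ib].d1;
      parent.d2 = lin[ia].d2 + lin[ib].d2;
      parent.deme = (deme < 0) ? 0 : deme;
      parent.id = next_id ? (*next_id)++ : -1;
      if (merges)
        merges->push_back(std::make_pair(parent.id,
                          std::make_pair(lin[ia].id, lin[ib].id)));
      lin.erase(lin.begin() + ib);
      lin.erase(lin.begin() + ia);
      lin.push_back(parent);
    } else {
      int deme = (u - rate_c0 - rate_c1 < rate_m0) ? 0 : 1;
      std::vector<int> idx;
      for (size_t i = 0; i < lin.size(); ++i)
        if (lin[i].deme == deme) idx.push_back((int)i);
      int a = (int)(R::unif_rand() * idx.size());
      lin[idx[a]].deme = 1 - deme;
    }
  }
}

struct BranchPayload {
  NumericMatrix* sfs; // (n1+1) x (n2+1)
};

void branch_fn(const std::vector<Lineage>& lin, double dt, void* p) {
  BranchPayload* bp = static_cast<BranchPayload*>(p);
  for (size_t i = 0; i < lin.size(); ++i)
    (*bp->sfs)(lin[i].d1, lin[i].d2) += dt;
}

struct MutPayload {
  IntegerMatrix* sfs;
  double muL;
};

void mut_fn(const std::vector<Lineage>& lin, double dt, void* p) {
  MutPayload* mp = static_cast<MutPayload*>(p);
  for (size_t i = 0; i < lin.size(); ++i) {
    int nm = (int)R::rpois(mp->muL * dt);
    if (nm > 0) (*mp->sfs)(lin[i].d1, lin[i].d2) += nm;
  }
}

struct GenoPayload {
  std::vector<int>* mut_node;     // node id per mutation
  std::vector<double>* node_len;  // accumulated length per node id
  double muL;
};

void geno_fn(const std::vector<Lineage>& lin, double dt, void* p) {
  GenoPayload* gp = static_cast<GenoPayload*>(p);
  for (size_t i = 0; i < lin.size(); ++i) {
    if ((size_t)lin[i].id >= gp->node_len->size())
      gp->node_len->resize(lin[i].id + 1, 0.0);
    (*gp->node_len)[lin[i].id] += dt;
    int nm = (int)R::rpois(gp->muL * dt);
    for (int m = 0; m < nm; ++m) gp->mut_node->push_back(lin[i].id);
  }
}

} // namespace

// Accumulated branch lengths per (d1, d2) configuration, summed over
// `n_frag` independent fragments. Divide by n_frag and multiply by mu*L
// to get the expected unfolded joint SFS per fragment.
// [[Rcpp::export]]
NumericMatrix im_branch_sfs_cpp(int n1, int n2, double N, double Nanc,
                                double Tdiv, double m12, double m21,
                                int n_frag) {
  NumericMatrix sfs(n1 + 1, n2 + 1);
  SimState st{n1, n2, N, Nanc, Tdiv, m12, m21,
              strong_migration(N, m12, m21)};
  BranchPayload bp{&sfs};
  for (int f = 0; f < n_frag; ++f)
    run_coalescent(st, branch_fn, &bp, nullptr, nullptr);
  return sfs;
}

// Pseudo-observed unfolded joint SFS: Poisson(mu*L*branch) mutations per
// lineage interval, summed over fragments.
// [[Rcpp::export]]
IntegerMatrix im_mutation_sfs_cpp(int n1, int n2, double N, double Nanc,
                                  double Tdiv, double m12, double m21,
                                  double muL, int n_frag) {
  IntegerMatrix sfs(n1 + 1, n2 + 1);
  SimState st{n1, n2, N, Nanc, Tdiv, m12, m21,
              strong_migration(N, m12, m21)};
  MutPayload mp{&sfs, muL};
  for (int f = 0; f < n_frag; ++f)
    run_coalescent(st, mut_fn, &mp, nullptr, nullptr);
  return sfs;
}

// Full genotype matrices: one 0/1 matrix (mutations x samples) per
// fragment; columns 1..n1 are deme-1 copies, n1+1..n1+n2 deme-2 copies.
// [[Rcpp::export]]
List im_genotypes_cpp(int n1, int n2, double N, double Nanc, double Tdiv,
                      double m12, double m21, double muL, int n_frag) {
  List out(n_frag);
  SimState st{n1, n2, N, Nanc, Tdiv, m12, m21,
              strong_migration(N, m12, m21)};
  int n = n1 + n2;
  for (int f = 0; f < n_frag; ++f) {
    std::vector<int> mut_node;
    std::vector<double> node_len;
    std::vector<std::pair<int, std::pair<int,int> > > merges;
    int next_id = n;
    GenoPayload gp{&mut_node, &node_len, muL};
    run_coalescent(st, geno_fn, &gp, &merges, &next_id);
    // descendant tip lists per node
    int n_nodes = next_id;
    std::vector<std::vector<int> > desc(n_nodes);
    for (int i = 0; i < n; ++i) desc[i].push_back(i);
    for (size_t mgi = 0; mgi < merges.size(); ++mgi) {
      int pid = merges[mgi].first;
      const std::vector<int>& a = desc[merges[mgi].second.first];
      const std::vector<int>& b = desc[merges[mgi].second.second];
      desc[pid].reserve(a.size() + b.size());
      desc[pid].insert(desc[pid].end(), a.begin(), a.end());
      desc[pid].insert(desc[pid].end(), b.begin(), b.end());
    }
    int M = (int)mut_node.size();
    IntegerMatrix G(M, n);
    for (int m = 0; m < M; ++m) {
      const std::vector<int>& d = desc[mut_node[m]];
      for (size_t q = 0; q < d.size(); ++q) G(m, d[q]) = 1;
    }
    out[f] = G;
  }
  return out;
}
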