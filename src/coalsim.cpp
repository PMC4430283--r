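// Multi-deme coalescent simulator with divergence (deme merge), instantaneous
// size change, admixture pulses and exponential growth, plus infinite-sites
// mutation overlay and weighted summary statistics for ABC.
//
// Time runs backwards from the present in years (= generations here).
// Effective sizes are haploid: in a deme of size N the coalescence rate for k
// lineages is k(k-1)/2 / N per generation.
//
// Event encoding (rows of a numeric matrix, sorted by time ascending):
//   col 0: time (years before present)
//   col 1: type  1 = split  (lineages in deme d1 move to d2; d1 closes)
//               2 = size   (deme d1 size set to x)
//               3 = admix  (lineages in d1 move to d2 with prob x, else d3;
//                           d1 closes)
//               4 = growth (deme d1 exponential growth rate set to x per year,
//                           backward size N(t) = N_ref * exp(-x * (t - t_ref)))
//   col 2-4: d1, d2, d3 (1-based deme ids; 0 when unused)
//   col 5: x
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Demography {
  int D;
  std::vector<double> N, g, tref;
  std::vector<bool> open;
};

struct Tree {
  // nodes 0..n-1 are leaves at time 0; internal nodes appended
  std::vector<int> parent;
  std::vector<double> time;
  int n;
  double tmrca;
  double tlen() const {
    double s = 0.0;
    for (int v = 0; v < (int)parent.size() - 1; ++v) s += time[parent[v]] - time[v];
    return s;
  }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Simulate one genealogy for samples placed in demes (0-based ids).
Tree simulate_tree(const NumericMatrix& events, const NumericVector& N0,
                   const IntegerVector& sample_deme) {
  int n = sample_deme.size();
  int D = N0.size();
  Demography dem;
  dem.D = D;
  // internal sizes are on the coalescent timescale: pair rate 1/(2Ne),
  // so theta = 4 Ne mu (the convention the analytic checks use)
  dem.N.assign(N0.begin(), N0.end());
  for (int d = 0; d < D; ++d) dem.N[d] *= 2.0;
  dem.g.assign(D, 0.0);
  dem.tref.assign(D, 0.0);
  dem.open.assign(D, true);
  for (int d = 0; d < D; ++d)
    if (dem.N[d] <= 0) stop("effective sizes must be positive");

  Tree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  std::vector<int> node(n), deme(n);
  for (int i = 0; i < n; ++i) {
    node[i] = i;
    deme[i] = sample_deme[i];
    if (deme[i] < 0 || deme[i] >= D) stop("sample deme out of range");
  }
  int n_active = n, next_node = n, ev = 0, n_ev = events.nrow();
  double t = 0.0;

  while (n_active > 1) {
    // per-deme lineage counts
    std::vector<int> k(D, 0);
    for (int i = 0; i < n_active; ++i) k[deme[i]]++;

    // candidate coalescence waiting time per deme (competing exponentials)
    double w_min = R_PosInf;
    int d_min = -1;
    for (int d = 0; d < D; ++d) {
      if (k[d] < 2) continue;
      double pairs = 0.5 * k[d] * (k[d] - 1);
      double w;
      if (dem.g[d] == 0.0) {
        w = R::exp_rand() * dem.N[d] / pairs;
      } else {
        double Nt = dem.N[d] * std::exp(-dem.g[d] * (t - dem.tref[d]));
        double base = pairs / Nt;  // instantaneous rate at time t
        double E = R::exp_rand();
        double arg = 1.0 + dem.g[d] * E / base;
        w = (arg <= 0.0) ? R_PosInf : std::log(arg) / dem.g[d];
      }
      if (w < w_min) { w_min = w; d_min = d; }
    }
    double t_coal = (d_min >= 0) ? t + w_min : R_PosInf;
    double t_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;

    if (t_ev <= t_coal) {
      if (!R_finite(t_ev)) stop("lineages stranded: no coalescent route to a common ancestor");
      t = t_ev;
      int type = (int)events(ev, 1);
      int d1 = (int)events(ev, 2) - 1;
      int d2 = (int)events(ev, 3) - 1;
      int d3 = (int)events(ev, 4) - 1;
      double x = events(ev, 5);
      if (d1 < 0 || d1 >= D) stop("event deme out of range");
      if (type == 1) {
        for (int i = 0; i < n_active; ++i) if (deme[i] == d1) deme[i] = d2;
        dem.open[d1] = false;
      } else if (type == 2) {
        dem.N[d1] = 2.0 * x;
        dem.tref[d1] = t;
      } else if (type == 3) {
        for (int i = 0; i < n_active; ++i)
          if (deme[i] == d1) deme[i] = (unif_rand() < x) ? d2 : d3;
        dem.open[d1] = false;
      } else if (type == 4) {
        double Nt = dem.N[d1] * std::exp(-dem.g[d1] * (t - dem.tref[d1]));
        dem.N[d1] = Nt;
        dem.g[d1] = x;
        dem.tref[d1] = t;
      } else stop("unknown event type");
      ++ev;
    } else {
      if (!R_finite(t_coal)) stop("lineages stranded: no coalescent route to a common ancestor");
      t = t_coal;
      // choose two distinct lineages in deme d_min
      std::vector<int> idx;
      idx.reserve(n_active);
      for (int i = 0; i < n_active; ++i) if (deme[i] == d_min) idx.push_back(i);
      int a = (int)(unif_rand() * idx.size());
      int b = (int)(unif_rand() * (idx.size() - 1));
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      int anc = next_node++;
      tr.time[anc] = t;
      tr.parent[node[ia]] = anc;
      tr.parent[node[ib]] = anc;
      node[ia] = anc;
      deme[ia] = d_min;
      node[ib] = node[n_active - 1];
      deme[ib] = deme[n_active - 1];
      --n_active;
    }
  }
  tr.tmrca = t;
  return tr;
}

// weighted leaf counts per group under every node (post-order via parent array)
void group_counts(const Tree& tr, const IntegerVector& group,
                  const NumericVector& w, int G,
                  std::vector<std::vector<double>>& cnt) {
  int m = tr.parent.size();
  cnt.assign(m, std::vector<double>(G, 0.0));
  for (int v = 0; v < tr.n; ++v) cnt[v][group[v]] = w[v];
  // nodes are created in increasing time order, so a simple upward sweep works
  for (int v = 0; v < m - 1; ++v) {
    int p = tr.parent[v];
    for (int gg = 0; gg < G; ++gg) cnt[p][gg] += cnt[v][gg];
  }
}

// sample a branch index proportional to branch length
int sample_branch(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

std::vector<double> branch_cum(const Tree& tr) {
  int m = tr.parent.size();
  std::vector<double> cum(m - 1);
  double s = 0.0;
  for (int v = 0; v < m - 1; ++v) {
    s += tr.time[tr.parent[v]] - tr.time[v];
    cum[v] = s;
  }
  return cum;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix coalsim_trees_cpp(NumericMatrix events, NumericVector N0,
                                IntegerVector sample_deme, int n_reps) {
  NumericMatrix out(n_reps, 2);
  for (int r = 0; r < n_reps; ++r) {
    Tree tr = simulate_tree(events, N0, sample_deme);
    out(r, 0) = tr.tmrca;
    out(r, 1) = tr.tlen();
  }
  colnames(out) = CharacterVector::create("tmrca", "tlen");
  return out;
}

// Simulate independent genealogies and return their parent/time arrays
// (nodes 0..n-1 are the sampled leaves; internal nodes follow in coalescence
// order; the root has parent 0 in the returned 1-based encoding).
//' @noRd
// [[Rcpp::export]]
List coalsim_genealogies_cpp(NumericMatrix events, NumericVector N0,
                             IntegerVector sample_deme, int n_loci) {
  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = simulate_tree(events, N0, sample_deme);
    int m = tr.parent.size();
    IntegerVector par(m);
    NumericVector tm(m);
    for (int v = 0; v < m; ++v) {
      par[v] = tr.parent[v] + 1;  // root keeps 0
      tm[v] = tr.time[v];
    }
    out[l] = List::create(_["parent"] = par, _["time"] = tm,
                          _["n_leaves"] = tr.n, _["tmrca"] = tr.tmrca,
                          _["tlen"] = tr.tlen());
  }
  return out;
}

// Batch simulation of weighted summary statistics for ABC.
// scen_list: list of list(events = matrix, N0 = numeric) parameter draws.
// For each draw, n_loci independent genealogies are simulated; mutations are
// Poisson with per-site rate mu_site and locus lengths locus_len.
// Summaries (groups 0..G-1, weighted sample sizes n_g = sum of weights):
//   per group: Nh, S, mean pairwise differences
//   per pair (g<h): W (mean within-sample pairwise diff) and
//                   B (mean between-sample pairwise diff)
//' @noRd
// [[Rcpp::export]]
NumericMatrix abc_sim_batch_cpp(List scen_list, IntegerVector sample_deme,
                                IntegerVector group, NumericVector weights,
                                NumericVector locus_len, double mu_site) {
  int n_draws = scen_list.size();
  int n = sample_deme.size();
  int n_loci = locus_len.size();
  int G = 0;
  for (int i = 0; i < n; ++i) G = std::max(G, group[i] + 1);
  int n_pairs = G * (G - 1) / 2;
  int n_sum = 3 * G + 2 * n_pairs;
  NumericMatrix out(n_draws, n_sum);

  std::vector<double> ng(G, 0.0);
  for (int i = 0; i < n; ++i) ng[group[i]] += weights[i];
  std::vector<double> pair_within(G);
  for (int gg = 0; gg < G; ++gg) pair_within[gg] = 0.5 * ng[gg] * (ng[gg] - 1.0);

  for (int r = 0; r < n_draws; ++r) {
    List sc = scen_list[r];
    NumericMatrix events = sc["events"];
    NumericVector N0 = sc["N0"];
    std::vector<double> S(G, 0.0), within(G, 0.0);
    std::vector<double> between(n_pairs, 0.0);
    std::vector<uint64_t> hap(n, 0ULL);
    int mut_id = 0;

    for (int l = 0; l < n_loci; ++l) {
      Tree tr = simulate_tree(events, N0, sample_deme);
      std::vector<double> cum = branch_cum(tr);
      int M = (int)R::rpois(mu_site * locus_len[l] * cum.back());
      if (M == 0) continue;
      std::vector<std::vector<double>> cnt;
      group_counts(tr, group, weights, G, cnt);
      int mnod = tr.parent.size();
      std::vector<std::vector<int>> ch(mnod);
      for (int v = 0; v < mnod - 1; ++v) ch[tr.parent[v]].push_back(v);
      for (int mu = 0; mu < M; ++mu) {
        int b = sample_branch(cum);
        uint64_t h = splitmix64((uint64_t)(mut_id++) * 2654435761ULL + 17ULL * (l + 1));
        // update leaf haplotype hashes (XOR of carried mutation hashes)
        std::vector<int> stack{b};
        while (!stack.empty()) {
          int v = stack.back();
          stack.pop_back();
          if (v < n) hap[v] ^= h;
          else for (int c : ch[v]) stack.push_back(c);
        }
        const std::vector<double>& c = cnt[b];
        int pi = 0;
        for (int gg = 0; gg < G; ++gg) {
          if (c[gg] > 0.0 && c[gg] < ng[gg]) S[gg] += 1.0;
          within[gg] += c[gg] * (ng[gg] - c[gg]);
        }
        for (int gg = 0; gg < G; ++gg)
          for (int hh = gg + 1; hh < G; ++hh, ++pi)
            between[pi] += c[gg] * (ng[hh] - c[hh]) + c[hh] * (ng[gg] - c[gg]);
      }
    }

    // distinct haplotypes per group (lineage-level; copies share a lineage)
    std::vector<double> Nh(G, 0.0);
    for (int gg = 0; gg < G; ++gg) {
      std::vector<uint64_t> hs;
      for (int i = 0; i < n; ++i) if (group[i] == gg) hs.push_back(hap[i]);
      std::sort(hs.begin(), hs.end());
      Nh[gg] = std::unique(hs.begin(), hs.end()) - hs.begin();
    }

    int col = 0;
    for (int gg = 0; gg < G; ++gg) {
      out(r, col++) = Nh[gg];
      out(r, col++) = S[gg];
      out(r, col++) = pair_within[gg] > 0 ? within[gg] / pair_within[gg] : 0.0;
    }
    int pi = 0;
    for (int gg = 0; gg < G; ++gg)
      for (int hh = gg + 1; hh < G; ++hh, ++pi) {
        double pw = pair_within[gg] + pair_within[hh];
        out(r, col++) = pw > 0 ? (within[gg] + within[hh]) / pw : 0.0;
        out(r, col++) = between[pi] / (ng[gg] * ng[hh]);
      }
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Constant-size coalescent conditioned on a fixed number of segregating
// sites: returns derived-allele counts per site and the haplotype count.
//' @noRd
// [[Rcpp::export]]
List fixed_s_batch_cpp(int n, int S, int n_reps) {
  NumericMatrix ev(0, 6);
  NumericVector N0 = NumericVector::create(1.0);
  IntegerVector deme(n, 0);
  IntegerMatrix counts(n_reps, S);
  IntegerVector K(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    Tree tr = simulate_tree(ev, N0, deme);
    std::vector<double> cum = branch_cum(tr);
    int mnod = tr.parent.size();
    std::vector<std::vector<int>> ch(mnod);
    for (int v = 0; v < mnod - 1; ++v) ch[tr.parent[v]].push_back(v);
    std::vector<uint64_t> hap(n, 0ULL);
    for (int s = 0; s < S; ++s) {
      int b = sample_branch(cum);
      uint64_t h = splitmix64((uint64_t)s * 1099511628211ULL + 3ULL);
      int cnt = 0;
      std::vector<int> stack{b};
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < n) { hap[v] ^= h; ++cnt; }
        else for (int c : ch[v]) stack.push_back(c);
      }
      counts(r, s) = cnt;
    }
    std::sort(hap.begin(), hap.end());
    K[r] = std::unique(hap.begin(), hap.end()) - hap.begin();
    if (r % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["K"] = K);
}
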