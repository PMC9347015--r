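// Structured coalescent simulator for multiple populations with timed
// divergence (lineage-merging) and admixture-pulse events, under the
// infinite-sites mutation model with free recombination between loci.
//
// Two entry points share the same event machinery:
//   cpp_expected_sfs  - accumulates expected branch length per SFS cell
//                       (the mu -> 0 conditional SFS; no mutation noise),
//                       either per population pair or as a sparse joint
//                       spectrum, plus mean total tree length and TMRCA.
//   cpp_sim_snps      - drops Poisson(mu * branch length) mutations and
//                       returns the haplotype matrix of segregating sites.
//
// Time is measured in generations; population sizes are diploid N, so a
// pair of lineages in a population of size N coalesces at rate 1/(2N).
// All randomness comes from R's RNG (deterministic under set.seed()).

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

struct Event {
  double t;
  int source;      // population whose lineages all move at time t
  int dest1;
  int dest2;       // -1 for a plain divergence
  double p1;       // probability a lineage moves to dest1
  double new_size; // resize dest1 after the event; <=0 keeps current size
};

static std::vector<Event> parse_events(const NumericMatrix& ev) {
  std::vector<Event> events;
  for (int i = 0; i < ev.nrow(); ++i) {
    Event e;
    e.t = ev(i, 0);
    e.source = (int)ev(i, 1);
    e.dest1 = (int)ev(i, 2);
    e.dest2 = ISNAN(ev(i, 3)) ? -1 : (int)ev(i, 3);
    e.p1 = ISNAN(ev(i, 4)) ? 1.0 : ev(i, 4);
    e.new_size = ISNAN(ev(i, 5)) ? -1.0 : ev(i, 5);
    events.push_back(e);
  }
  return events;
}

// Draw two distinct indices in [0, k)
static inline void draw_pair(int k, int& i, int& j) {
  i = (int)(unif_rand() * k); if (i == k) i = k - 1;
  j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
  if (j >= i) ++j;
}

// -------------------------------------------------------------------------
// Expected SFS by branch-length accumulation
// -------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_expected_sfs(NumericVector sizes, IntegerVector samp,
                      NumericMatrix event_mat, int n_sims, bool joint) {
  const int P = sizes.size();
  if (samp.size() != P) stop("sizes/samp length mismatch");
  std::vector<Event> events = parse_events(event_mat);
  int n_tot = 0;
  for (int p = 0; p < P; ++p) n_tot += samp[p];
  if (n_tot < 2) stop("need at least two sampled lineages");

  // pairwise accumulators (a < b), row-major (samp[a]+1) x (samp[b]+1)
  std::vector<std::pair<int, int> > pairs;
  for (int a = 0; a < P; ++a)
    for (int b = a + 1; b < P; ++b) pairs.push_back(std::make_pair(a, b));
  std::vector<std::vector<double> > pw(pairs.size());
  for (size_t q = 0; q < pairs.size(); ++q)
    pw[q].assign((samp[pairs[q].first] + 1) * (samp[pairs[q].second] + 1), 0.0);
  // marginal accumulators
  std::vector<std::vector<double> > marg(P);
  for (int p = 0; p < P; ++p) marg[p].assign(samp[p] + 1, 0.0);
  // sparse joint accumulator, key = sum_p c_p * stride_p
  std::map<long long, double> jmap;
  std::vector<long long> stride(P, 1);
  for (int p = 1; p < P; ++p) stride[p] = stride[p - 1] * (samp[p - 1] + 1);

  const int max_lin = 2 * n_tot;
  std::vector<double> birth(max_lin);
  std::vector<int> cnt(max_lin * P);
  std::vector<std::vector<int> > members(P);

  double sum_ttot = 0.0, sum_tmrca = 0.0;

  for (int s = 0; s < n_sims; ++s) {
    std::vector<double> N(sizes.begin(), sizes.end());
    int next_id = 0;
    for (int p = 0; p < P; ++p) {
      members[p].clear();
      for (int k = 0; k < samp[p]; ++k) {
        birth[next_id] = 0.0;
        for (int q = 0; q < P; ++q) cnt[next_id * P + q] = 0;
        cnt[next_id * P + p] = 1;
        members[p].push_back(next_id++);
      }
    }
    double t = 0.0, ttot = 0.0;
    size_t ev_i = 0;
    int alive = n_tot;
    while (alive > 1) {
      double rate = 0.0;
      for (int p = 0; p < P; ++p) {
        double k = (double)members[p].size();
        if (k > 1.5) rate += k * (k - 1.0) / (4.0 * N[p]);
      }
      double t_next = R_PosInf;
      if (rate > 0.0) t_next = t + exp_rand() / rate;
      if (ev_i < events.size() && events[ev_i].t <= t_next) {
        const Event& e = events[ev_i];
        t = e.t;
        if (!members[e.source].empty() && e.source != e.dest1) {
          for (size_t m = 0; m < members[e.source].size(); ++m) {
            int lid = members[e.source][m];
            int d = (e.dest2 < 0 || unif_rand() < e.p1) ? e.dest1 : e.dest2;
            members[d].push_back(lid);
          }
          members[e.source].clear();
        }
        if (e.new_size > 0.0) N[e.dest1] = e.new_size;
        ++ev_i;
        continue;
      }
      if (!R_FINITE(t_next))
        stop("no coalescence possible and no further events (no single root)");
      t = t_next;
      // choose population proportional to its coalescence rate
      double u = unif_rand() * rate, acc = 0.0;
      int cp = -1;
      for (int p = 0; p < P; ++p) {
        double k = (double)members[p].size();
        if (k > 1.5) {
          acc += k * (k - 1.0) / (4.0 * N[p]);
          if (u <= acc) { cp = p; break; }
        }
      }
      if (cp < 0) cp = P - 1;
      int k = (int)members[cp].size();
      int i, j;
      draw_pair(k, i, j);
      int li = members[cp][i], lj = members[cp][j];
      // record the two child branches
      for (int child = 0; child < 2; ++child) {
        int lid = child == 0 ? li : lj;
        double len = t - birth[lid];
        ttot += len;
        int tot = 0;
        for (int p = 0; p < P; ++p) tot += cnt[lid * P + p];
        if (tot < n_tot) { // branches subtending everything are invisible
          for (size_t q = 0; q < pairs.size(); ++q) {
            int a = pairs[q].first, b = pairs[q].second;
            int ca = cnt[lid * P + a], cb = cnt[lid * P + b];
            if ((ca > 0 || cb > 0) && !(ca == samp[a] && cb == samp[b]))
              pw[q][ca * (samp[b] + 1) + cb] += len;
          }
          for (int p = 0; p < P; ++p) {
            int c = cnt[lid * P + p];
            if (c > 0 && c < samp[p]) marg[p][c] += len;
            else if (c > 0 && c == samp[p] && samp[p] < n_tot) marg[p][c] += len;
          }
          if (joint) {
            long long key = 0;
            for (int p = 0; p < P; ++p) key += (long long)cnt[lid * P + p] * stride[p];
            jmap[key] += len;
          }
        }
      }
      // merged lineage
      int nid = next_id++;
      birth[nid] = t;
      for (int p = 0; p < P; ++p)
        cnt[nid * P + p] = cnt[li * P + p] + cnt[lj * P + p];
      // remove li, lj from members[cp]; add nid
      if (i < j) std::swap(i, j); // erase larger index first
      members[cp].erase(members[cp].begin() + i);
      members[cp].erase(members[cp].begin() + j);
      members[cp].push_back(nid);
      --alive;
    }
    sum_ttot += ttot;
    sum_tmrca += t;
  }

  List pw_out(pairs.size());
  CharacterVector pw_names(pairs.size());
  for (size_t q = 0; q < pairs.size(); ++q) {
    int a = pairs[q].first, b = pairs[q].second;
    NumericMatrix m(samp[a] + 1, samp[b] + 1);
    for (int ca = 0; ca <= samp[a]; ++ca)
      for (int cb = 0; cb <= samp[b]; ++cb)
        m(ca, cb) = pw[q][ca * (samp[b] + 1) + cb];
    pw_out[q] = m;
    pw_names[q] = std::to_string(a) + "_" + std::to_string(b);
  }
  pw_out.names() = pw_names;
  List marg_out(P);
  for (int p = 0; p < P; ++p) marg_out[p] = NumericVector(marg[p].begin(), marg[p].end());
  List joint_out = R_NilValue;
  if (joint) {
    int nc = jmap.size();
    NumericVector keys(nc), mass(nc);
    int idx = 0;
    for (std::map<long long, double>::iterator it = jmap.begin(); it != jmap.end(); ++it) {
      keys[idx] = (double)it->first;
      mass[idx] = it->second;
      ++idx;
    }
    joint_out = List::create(_["key"] = keys, _["mass"] = mass);
  }
  return List::create(
    _["pairwise"] = pw_out,
    _["marginal"] = marg_out,
    _["joint"] = joint_out,
    _["mean_ttot"] = sum_ttot / n_sims,
    _["mean_tmrca"] = sum_tmrca / n_sims);
}

// -------------------------------------------------------------------------
// SNP simulation (infinite sites, one tree per unlinked locus)
// -------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim_snps(NumericVector sizes, IntegerVector samp,
                  NumericMatrix event_mat, int n_loci, double mu) {
  const int P = sizes.size();
  std::vector<Event> events = parse_events(event_mat);
  int n_tot = 0;
  for (int p = 0; p < P; ++p) n_tot += samp[p];
  if (n_tot < 2) stop("need at least two sampled lineages");

  std::vector<std::vector<int> > members(P);
  std::vector<double> birth(2 * n_tot);
  std::vector<std::vector<int> > leaves(2 * n_tot);

  std::vector<int> snp_carriers;   // flattened carrier lists
  std::vector<int> snp_offset;     // start index of each SNP
  std::vector<int> snp_locus;      // locus index of each SNP
  NumericVector tmrca(n_loci);
  double sum_ttot = 0.0;

  for (int s = 0; s < n_loci; ++s) {
    std::vector<double> N(sizes.begin(), sizes.end());
    int next_id = 0;
    for (int p = 0; p < P; ++p) {
      members[p].clear();
      for (int k = 0; k < samp[p]; ++k) {
        birth[next_id] = 0.0;
        leaves[next_id].assign(1, next_id);
        members[p].push_back(next_id++);
      }
    }
    double t = 0.0;
    size_t ev_i = 0;
    int alive = n_tot;
    while (alive > 1) {
      double rate = 0.0;
      for (int p = 0; p < P; ++p) {
        double k = (double)members[p].size();
        if (k > 1.5) rate += k * (k - 1.0) / (4.0 * N[p]);
      }
      double t_next = R_PosInf;
      if (rate > 0.0) t_next = t + exp_rand() / rate;
      if (ev_i < events.size() && events[ev_i].t <= t_next) {
        const Event& e = events[ev_i];
        t = e.t;
        if (!members[e.source].empty() && e.source != e.dest1) {
          for (size_t m = 0; m < members[e.source].size(); ++m) {
            int lid = members[e.source][m];
            int d = (e.dest2 < 0 || unif_rand() < e.p1) ? e.dest1 : e.dest2;
            members[d].push_back(lid);
          }
          members[e.source].clear();
        }
        if (e.new_size > 0.0) N[e.dest1] = e.new_size;
        ++ev_i;
        continue;
      }
      if (!R_FINITE(t_next))
        stop("no coalescence possible and no further events (no single root)");
      t = t_next;
      double u = unif_rand() * rate, acc = 0.0;
      int cp = -1;
      for (int p = 0; p < P; ++p) {
        double k = (double)members[p].size();
        if (k > 1.5) {
          acc += k * (k - 1.0) / (4.0 * N[p]);
          if (u <= acc) { cp = p; break; }
        }
      }
      if (cp < 0) cp = P - 1;
      int k = (int)members[cp].size();
      int i, j;
      draw_pair(k, i, j);
      int li = members[cp][i], lj = members[cp][j];
      for (int child = 0; child < 2; ++child) {
        int lid = child == 0 ? li : lj;
        double len = t - birth[lid];
        sum_ttot += len;
        if ((int)leaves[lid].size() < n_tot && mu > 0.0) {
          int nmut = (int)R::rpois(len * mu);
          for (int m = 0; m < nmut; ++m) {
            snp_offset.push_back((int)snp_carriers.size());
            snp_locus.push_back(s);
            snp_carriers.insert(snp_carriers.end(),
                                leaves[lid].begin(), leaves[lid].end());
          }
        }
      }
      int nid = next_id++;
      birth[nid] = t;
      leaves[nid].clear();
      leaves[nid].insert(leaves[nid].end(), leaves[li].begin(), leaves[li].end());
      leaves[nid].insert(leaves[nid].end(), leaves[lj].begin(), leaves[lj].end());
      if (i < j) std::swap(i, j);
      members[cp].erase(members[cp].begin() + i);
      members[cp].erase(members[cp].begin() + j);
      members[cp].push_back(nid);
      --alive;
    }
    tmrca[s] = t;
  }

  int n_snps = snp_offset.size();
  snp_offset.push_back((int)snp_carriers.size());
  IntegerMatrix H(n_tot, n_snps);
  for (int m = 0; m < n_snps; ++m)
    for (int c = snp_offset[m]; c < snp_offset[m + 1]; ++c)
      H(snp_carriers[c], m) = 1;
  return List::create(
    _["haplotypes"] = H,
    _["locus"] = IntegerVector(snp_locus.begin(), snp_locus.end()),
    _["tmrca"] = tmrca,
    _["mean_ttot"] = sum_ttot / n_loci);
}
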