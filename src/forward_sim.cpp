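// Forward Wright-Fisher simulator for two partially isolated populations:
// infinite-sites mutation, Poisson crossovers, unidirectional migration
// B -> A, and viability selection on a single focal site in population A.
// Haplotypes are sorted vectors of derived-allele positions (0-based bp).
// Uses R's RNG throughout so set.seed() gives bit-identical runs.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;
typedef std::vector<Hap> Pop; // 2N haplotypes; individual i owns 2i, 2i+1

static Hap make_gamete(const Hap& h1, const Hap& h2, double rec_total,
                       double mu_total, int seq_len) {
  int k = (int)R::rpois(rec_total);
  const Hap* cur = (unif_rand() < 0.5) ? &h1 : &h2;
  const Hap* oth = (cur == &h1) ? &h2 : &h1;
  Hap g;
  if (k == 0) {
    g = *cur;
  } else {
    std::vector<int> bp(k);
    for (int i = 0; i < k; ++i) bp[i] = (int)(unif_rand() * seq_len);
    std::sort(bp.begin(), bp.end());
    bp.push_back(seq_len);
    int lo = 0;
    g.reserve(h1.size() + h2.size());
    for (size_t i = 0; i < bp.size(); ++i) {
      int hi = bp[i];
      Hap::const_iterator a = std::lower_bound(cur->begin(), cur->end(), lo);
      Hap::const_iterator b = std::lower_bound(cur->begin(), cur->end(), hi);
      g.insert(g.end(), a, b);
      std::swap(cur, oth);
      lo = hi;
    }
  }
  int nm = (int)R::rpois(mu_total);
  for (int i = 0; i < nm; ++i) {
    int pos = (int)(unif_rand() * seq_len);
    Hap::iterator it = std::lower_bound(g.begin(), g.end(), pos);
    if (it == g.end() || *it != pos) g.insert(it, pos); // recurrent hits dropped
  }
  return g;
}

static inline bool carries(const Hap& h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

static int focal_count(const Pop& p, int pos) {
  int c = 0;
  for (size_t i = 0; i < p.size(); ++i)
    if (carries(p[i], pos)) ++c;
  return c;
}

// One offspring generation. src_mig: source population for migrant
// offspring (NULL = no migration). Viability selection: offspring accepted
// with probability w/(1+s) where w depends on the focal-site genotype.
static Pop next_generation(const Pop& pop, const Pop* src_mig, double mig,
                           double s, double h, int focal_pos,
                           double rec_total, double mu_total, int seq_len) {
  int n_dip = (int)pop.size() / 2;
  Pop next;
  next.reserve(pop.size());
  double wmax = 1.0 + (s > 0 ? s : 0.0);
  for (int i = 0; i < n_dip; ++i) {
    for (;;) {
      const Pop& src = (src_mig && unif_rand() < mig) ? *src_mig : pop;
      int np = (int)src.size() / 2;
      int p1 = (int)(unif_rand() * np);
      int p2 = (int)(unif_rand() * np);
      Hap g1 = make_gamete(src[2 * p1], src[2 * p1 + 1], rec_total, mu_total,
                           seq_len);
      Hap g2 = make_gamete(src[2 * p2], src[2 * p2 + 1], rec_total, mu_total,
                           seq_len);
      if (s > 0) {
        int cnt = (carries(g1, focal_pos) ? 1 : 0) +
                  (carries(g2, focal_pos) ? 1 : 0);
        double w = (cnt == 2) ? (1.0 + s) : (cnt == 1 ? 1.0 + h * s : 1.0);
        if (unif_rand() >= w / wmax) continue; // offspring dies
      }
      next.push_back(g1);
      next.push_back(g2);
      break;
    }
  }
  return next;
}

// Remove mutations fixed in every haplotype of every listed population;
// they contribute nothing to within- or between-population statistics.
static void drop_fixed(std::vector<Pop*>& pops) {
  size_t total = 0;
  std::unordered_map<int, size_t> cnt;
  for (size_t p = 0; p < pops.size(); ++p) {
    total += pops[p]->size();
    for (size_t i = 0; i < pops[p]->size(); ++i)
      for (size_t j = 0; j < (*pops[p])[i].size(); ++j)
        ++cnt[(*pops[p])[i][j]];
  }
  std::vector<int> fixed;
  for (std::unordered_map<int, size_t>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == total) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (size_t p = 0; p < pops.size(); ++p)
    for (size_t i = 0; i < pops[p]->size(); ++i) {
      Hap& hh = (*pops[p])[i];
      Hap out;
      out.reserve(hh.size());
      std::set_difference(hh.begin(), hh.end(), fixed.begin(), fixed.end(),
                          std::back_inserter(out));
      hh.swap(out);
    }
}

static List sample_pop(const Pop& pop, int n_sample) {
  int n_dip = (int)pop.size() / 2;
  int want = n_sample / 2;
  std::vector<int> idx(n_dip);
  for (int i = 0; i < n_dip; ++i) idx[i] = i;
  // partial Fisher-Yates without replacement
  for (int i = 0; i < want; ++i) {
    int j = i + (int)(unif_rand() * (n_dip - i));
    std::swap(idx[i], idx[j]);
  }
  List out(2 * want);
  for (int i = 0; i < want; ++i) {
    out[2 * i] = wrap(pop[2 * idx[i]]);
    out[2 * i + 1] = wrap(pop[2 * idx[i] + 1]);
  }
  return out;
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_diploid, double mu_total, double rec_total, double mig,
                double s, double h, int seq_len, int focal_pos,
                int burnin_gens, int split_gens, int n_sample) {
  Pop anc(2 * n_diploid);
  std::vector<Pop*> one;
  for (int g = 0; g < burnin_gens; ++g) {
    anc = next_generation(anc, NULL, 0.0, 0.0, h, focal_pos, rec_total,
                          mu_total, seq_len);
    if (g % 50 == 49) {
      one.clear();
      one.push_back(&anc);
      drop_fixed(one);
    }
  }
  // split: both daughter populations are Wright-Fisher draws from the
  // ancestral pool
  Pop A = next_generation(anc, NULL, 0.0, 0.0, h, focal_pos, rec_total,
                          mu_total, seq_len);
  Pop B = next_generation(anc, NULL, 0.0, 0.0, h, focal_pos, rec_total,
                          mu_total, seq_len);
  anc.clear();

  int reseeds = 0;
  if (s > 0) {
    int i = (int)(unif_rand() * A.size());
    Hap::iterator it = std::lower_bound(A[i].begin(), A[i].end(), focal_pos);
    if (it == A[i].end() || *it != focal_pos) A[i].insert(it, focal_pos);
  }
  std::vector<Pop*> both;
  for (int g = 0; g < split_gens; ++g) {
    Pop newA = next_generation(A, &B, mig, s, h, focal_pos, rec_total,
                               mu_total, seq_len);
    Pop newB = next_generation(B, NULL, 0.0, 0.0, h, focal_pos, rec_total,
                               mu_total, seq_len);
    A.swap(newA);
    B.swap(newB);
    if (s > 0 && focal_count(A, focal_pos) == 0) {
      int i = (int)(unif_rand() * A.size());
      Hap::iterator it = std::lower_bound(A[i].begin(), A[i].end(), focal_pos);
      A[i].insert(it, focal_pos);
      ++reseeds;
    }
    if (g % 50 == 49) {
      both.clear();
      both.push_back(&A);
      both.push_back(&B);
      drop_fixed(both);
    }
  }
  return List::create(_["hapA"] = sample_pop(A, n_sample),
                      _["hapB"] = sample_pop(B, n_sample),
                      _["reseeds"] = reseeds);
}
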