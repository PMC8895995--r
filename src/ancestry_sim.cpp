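// Forward Wright-Fisher simulator of a BSA experiment with explicit
// ancestry-junction tracking. Each haplotype is stored as its ordered list
// of ancestry breakpoints plus the ancestry label of the leftmost segment
// (0 = blue / A strain, 1 = red / a strain). Coordinates are 0-based
// integers in [0, L); a breakpoint at p means ancestry switches between
// p - 1 and p. All randomness comes from R's RNG so that set.seed() in R
// makes every run bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Hap {
  std::vector<double> bp;  // sorted, unique, in (0, L)
  int left;                // ancestry of segment starting at 0
};

// ancestry at integer position p: parity of breakpoints <= p
static inline int ancestry_at(const Hap &h, double p) {
  size_t k = std::upper_bound(h.bp.begin(), h.bp.end(), p) - h.bp.begin();
  return h.left ^ (int)(k & 1);
}

// k distinct crossover positions, uniform integers in [1, L-1]
static void draw_crossovers(double r, double L, std::vector<double> &xo) {
  xo.clear();
  int k = (int)R::rpois(r * L);
  while ((int)xo.size() < k) {
    double p = std::floor(unif_rand() * (L - 1.0)) + 1.0;
    if (std::find(xo.begin(), xo.end(), p) == xo.end()) xo.push_back(p);
  }
  std::sort(xo.begin(), xo.end());
}

// Gamete from one meiosis of parent (h1, h2). The gamete alternates
// between the two parental haplotypes at the crossover positions (starting
// haplotype chosen uniformly); stored breakpoints are true ancestry
// switches only (same-ancestry junctions coalesce away).
static Hap meiosis(const Hap &h1, const Hap &h2, double r, double L) {
  std::vector<double> xo;
  draw_crossovers(r, L, xo);
  int start = (unif_rand() < 0.5) ? 0 : 1;

  if (xo.empty() && h1.bp.empty() && h2.bp.empty()) {
    Hap g;
    g.left = start == 0 ? h1.left : h2.left;
    return g;
  }

  // candidate change points: both parents' breakpoints plus crossovers
  std::vector<double> cand;
  cand.reserve(h1.bp.size() + h2.bp.size() + xo.size());
  cand.insert(cand.end(), h1.bp.begin(), h1.bp.end());
  cand.insert(cand.end(), h2.bp.begin(), h2.bp.end());
  cand.insert(cand.end(), xo.begin(), xo.end());
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  Hap g;
  auto value_at = [&](double p) -> int {
    size_t nx = std::upper_bound(xo.begin(), xo.end(), p) - xo.begin();
    int src = start ^ (int)(nx & 1);
    return src == 0 ? ancestry_at(h1, p) : ancestry_at(h2, p);
  };
  int prev = value_at(0.0);
  g.left = prev;
  for (double p : cand) {
    int v = value_at(p);
    if (v != prev) {
      g.bp.push_back(p);
      prev = v;
    }
  }
  return g;
}

typedef std::vector<Hap> Pop;  // 2 * n haplotypes; individual i owns 2i, 2i+1

// sample k distinct indices from 0..n-1 (partial Fisher-Yates)
static std::vector<int> sample_without_replacement(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

static int qtl_geno(const Pop &pop, int ind, double qtl) {
  // 0 = AA (blue/blue), 1 = Aa, 2 = aa (red/red)
  return ancestry_at(pop[2 * ind], qtl) + ancestry_at(pop[2 * ind + 1], qtl);
}

// [[Rcpp::export]]
List sim_population_cpp(double L, double qtl_pos, double r, int t,
                        int n_census, int ne_breeders, std::string scheme) {
  if (t < 2) stop("t must be >= 2");
  if (ne_breeders < 2 || ne_breeders > n_census)
    stop("ne_breeders must be in [2, n_census]");

  // F1: every individual carries one all-blue and one all-red haplotype
  // (gametes of the inbred parental strains carry no junctions).
  Pop cur(2 * n_census);
  for (int i = 0; i < n_census; ++i) {
    cur[2 * i].left = 0;
    cur[2 * i + 1].left = 1;
  }

  std::vector<int> breeders;
  for (int gen = 2; gen <= t; ++gen) {
    // generation `gen` is formed from gametes of generation `gen - 1`
    breeders = sample_without_replacement(n_census, ne_breeders);

    bool backcross = false;
    if (scheme == "hs") {
      std::vector<int> keep;
      for (int b : breeders)
        if (qtl_geno(cur, b, qtl_pos) == 1) keep.push_back(b);
      if ((int)keep.size() < 2)
        stop("heterozygote-selection scheme: fewer than 2 Aa breeders in "
             "generation %d", gen - 1);
      breeders = keep;
    } else if (scheme == "im" && gen >= 3 && (gen - 1) % 2 == 0) {
      // AA homozygotes selected in even generations, backcrossed to the
      // red parental strain (an externally maintained inbred stock)
      std::vector<int> keep;
      for (int b : breeders)
        if (qtl_geno(cur, b, qtl_pos) == 0) keep.push_back(b);
      if (keep.empty())
        stop("introgression scheme: no AA individuals among the breeders "
             "of generation %d", gen - 1);
      breeders = keep;
      backcross = true;
    } else if (scheme != "standard" && scheme != "im" && scheme != "hs") {
      stop("unknown scheme '%s'", scheme.c_str());
    }

    int nb = (int)breeders.size();
    Pop nxt(2 * n_census);
    for (int j = 0; j < n_census; ++j) {
      if (backcross) {
        int p1 = breeders[(int)std::floor(unif_rand() * nb)];
        nxt[2 * j] = meiosis(cur[2 * p1], cur[2 * p1 + 1], r, L);
        nxt[2 * j + 1].left = 1;  // pure-red gamete from the parental strain
      } else {
        int a = (int)std::floor(unif_rand() * nb);
        int b = (int)std::floor(unif_rand() * (nb - 1));
        if (b >= a) ++b;  // two distinct parents
        int p1 = breeders[a], p2 = breeders[b];
        nxt[2 * j] = meiosis(cur[2 * p1], cur[2 * p1 + 1], r, L);
        nxt[2 * j + 1] = meiosis(cur[2 * p2], cur[2 * p2 + 1], r, L);
      }
    }
    cur.swap(nxt);
  }

  // flatten to compact vectors
  int nh = 2 * n_census;
  IntegerVector left(nh), nbp(nh);
  size_t total = 0;
  for (int i = 0; i < nh; ++i) total += cur[i].bp.size();
  NumericVector bp(total);
  size_t off = 0;
  for (int i = 0; i < nh; ++i) {
    left[i] = cur[i].left;
    nbp[i] = (int)cur[i].bp.size();
    for (double p : cur[i].bp) bp[off++] = p;
  }
  return List::create(_["left"] = left, _["nbp"] = nbp, _["bp"] = bp);
}

// [[Rcpp::export]]
List meiosis_cpp(NumericVector bp1, int left1, NumericVector bp2, int left2,
                 double r, double L) {
  Hap h1, h2;
  h1.bp.assign(bp1.begin(), bp1.end());
  h1.left = left1;
  h2.bp.assign(bp2.begin(), bp2.end());
  h2.left = left2;
  Hap g = meiosis(h1, h2, r, L);
  return List::create(_["breakpoints"] = NumericVector(g.bp.begin(), g.bp.end()),
                      _["left"] = g.left);
}

// Ancestry label of each listed haplotype at one position.
// [[Rcpp::export]]
IntegerVector ancestry_at_cpp(IntegerVector nbp, NumericVector bp,
                              IntegerVector left, double pos) {
  int nh = nbp.size();
  IntegerVector out(nh);
  size_t off = 0;
  for (int i = 0; i < nh; ++i) {
    const double *beg = bp.begin() + off, *end = beg + nbp[i];
    size_t k = std::upper_bound(beg, end, pos) - beg;
    out[i] = left[i] ^ (int)(k & 1);
    off += nbp[i];
  }
  return out;
}

// Count of blue (ancestry 0) chromosomes among `hap_idx` (1-based into the
// flattened population) at each sorted marker position. One linear sweep
// per haplotype.
// [[Rcpp::export]]
IntegerVector pool_blue_counts_cpp(IntegerVector nbp, NumericVector bp,
                                   IntegerVector left, IntegerVector hap_idx,
                                   NumericVector positions) {
  int nm = positions.size();
  IntegerVector out(nm);
  // offsets of each haplotype into bp
  std::vector<size_t> off(nbp.size() + 1, 0);
  for (int i = 0; i < nbp.size(); ++i) off[i + 1] = off[i] + nbp[i];
  for (int hi = 0; hi < hap_idx.size(); ++hi) {
    int h = hap_idx[hi] - 1;
    const double *beg = bp.begin() + off[h], *end = beg + nbp[h];
    const double *cursor = beg;
    int anc = left[h];
    for (int m = 0; m < nm; ++m) {
      while (cursor != end && *cursor <= positions[m]) {
        anc ^= 1;
        ++cursor;
      }
      if (anc == 0) ++out[m];
    }
  }
  return out;
}
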