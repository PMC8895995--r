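---
title: "Predicting and simulating the mapping resolution of bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and simulating the mapping resolution of bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsares)
```

## The question the package answers

A bulk segregant analysis (BSA) experiment crosses two inbred strains
("blue", carrying the A allele of a single QTL, and "red", carrying a),
interbreeds the offspring for `t` generations, and finally sequences two
pools of `s` chromosomes each: one from AA individuals, one from aa. Every
sampled chromosome is a mosaic of blue and red ancestry segments, but
around the QTL all chromosomes of the AA pool are still blue and all of
the aa pool still red. The length of that shared-ancestry region is what
the experiment can resolve. Writing `D` for the distance from the QTL to
the closest ancestry breakpoint downstream of it across all `2s` pooled
chromosomes, the expected mapped-region length is `2 E[D]` by symmetry.

`bsares` computes `E[D]` analytically, measures it by forward simulation,
and reproduces the marker-statistic layer (G′ peaks) through which real
experiments observe it.

## The analytic model

Ancestry breakpoints are created only by crossovers in individuals that
carry blue ancestry on one chromosome and red on the other at the
crossover position. In the F1 every individual is heterozygous everywhere,
so all crossovers count; from the F2 on, a random individual is
ancestry-heterozygous at a given position with probability 1/2 (as long as
both ancestries still segregate near 50%). The per-lineage, per-bp
breakpoint rates are therefore ρ(2) = r and ρ(i > 2) = r/2 for the
standard design.

In an infinite population the `2s` sampled lineages never coalesce during
the experiment, giving a total rate `R = r s t` and `E[D] = 1/(r s t)`. In
a finite population, lineages coalesce and share breakpoints; the expected
number of distinct lineages `x(i)` in generation `i` follows a
balls-in-boxes occupancy step per generation,

$$E[x(i-1)] = 2N_e\left[1 - \left(1 - \frac{1}{2N_e}\right)^{x(i)}\right],
\qquad x(t) = 2s,$$

and the total breakpoint rate along the genealogy is
$R = \sum_{i=2}^{t} \rho(i)\,E[x(i)]$ with $E[D] = 1/R$. Modelling
breakpoint positions as a Poisson process along the chromosome (valid
while `R` per bp is small — the code warns if `R > 0.1`), `D` is
approximately exponential, which also explains why its distribution is
strongly right-skewed and its mean sits well above its median.

`expected_resolution()` exposes four methods:

* `recursion` — the reference: exact occupancy recursion, any scheme, any
  user-supplied ρ schedule. Lineage counts are kept real-valued
  throughout; they are expectations, and rounding them would bias `R`.
* `integration` — closed form
  $E[D] = 1/\left(2N_e r \ln(2s[e^{t/4N_e}-1]+1)\right)$ obtained by a
  deterministic approximation of the lineage counts and a continuous-time
  integral of the rate. Standard scheme only (it hard-codes the uniform
  r/2 rate); it underestimates `E[D]` when `s` approaches `Ne` or when `t`
  is very small, where the continuous integral misrepresents the few
  discrete generations.
* `taylor` — further approximation for `t ≪ 4 Ne`:
  $E[D] = 1/\left(2 r N_e \ln(st/2N_e + 1)\right)$; depends on `s` and `t`
  only through `s·t`, which is the practically useful design insight
  (doubling the sample buys as much as doubling the duration).
* `infinite` — `1/(r s t)`, a lower bound on `E[D]` for any finite `Ne`.

All four agree within 2% when `st/(2 Ne) ≤ 0.01`; the test suite checks
this, the bound, and the exact `1/r` scaling.

### Crossing schemes

`scheme_parameters()` encodes two published modifications:

* **Introgression mapping (`im`)**: AA homozygotes are selected in even
  generations and backcrossed to the red strain. Near the QTL breakpoints
  arise at rate r in interbreeding generations and 0 in backcross
  generations — averaged over the experiment, the same r/2 as standard
  BSA — but selection keeps only ~1/4 of individuals, so the coalescence
  size drops to `Ne = 0.4 N′` (harmonic mean of interbreeding and
  selection generations). We use the whole-experiment average schedule
  rather than the exact alternating one because the scheme's headline
  numbers are averages; the alternating schedule can still be supplied as
  a custom `rho` vector to `bsa_design()`.
* **Heterozygote selection (`hs`)**: only Aa individuals breed, so
  ρ(i) = r for every generation at the cost of `Ne = 0.5 N′`.

## The forward simulator

`run_experiment()` replaces tree-sequence machinery with direct
ancestry-junction tracking: a chromosome is stored as its ordered list of
breakpoints plus the leftmost ancestry label, and a meiosis draws
`Poisson(rL)` crossover positions, alternates between the parent's
haplotypes, and keeps only true ancestry switches. Design choices that the
underlying model leaves open, and how we resolved them:

* **Coordinates** are 0-based integers in `[0, L)`; a breakpoint at `p`
  switches ancestry between `p − 1` and `p`. Crossover positions are drawn
  continuously, floored, and redrawn on collision — unambiguous integer
  bookkeeping at `L = 1e8`.
* **Demography**: the F1 is seeded from the two inbred strains (1,000 +
  1,000 parents; every F1 individual is one blue plus one red chromosome),
  then discrete non-overlapping generations at a census of `n_census`
  (default 2,000), of which `ne_breeders` randomly chosen individuals
  breed. Each offspring draws two *distinct* parents uniformly from the
  breeders; sexes are only enforced in forming the F1. This plain diploid
  Wright–Fisher scheme makes `ne_breeders` the coalescence effective size
  the theory needs.
* **Scheme selection order**: for `hs`/`im`, the genotype filter is
  applied *after* the random choice of `ne_breeders` individuals, so the
  realized breeder counts (~Ne/2 for HS; ~Ne/4 in IM selection
  generations) are exactly what the `0.5 N′` / `0.4 N′` effective sizes
  describe. Applying the filter first would silently double the effective
  size and break the theory agreement — the agreement test is the arbiter
  here. IM backcross gametes come from an infinite, drift-free red
  parental stock, as parental strains are maintained outside the
  experiment; sample IM experiments at an even `t`, when AA homozygotes
  exist.
* **Censoring**: if no breakpoint exists on one side of the QTL, `D` is
  censored at the chromosome end, included in means at its censoring value
  and flagged — this quantifies when the theory's "neglect edge effects"
  assumption fails, rather than hiding it.
* **Infeasible replicates**: under strong drift the QTL allele can
  approach fixation, leaving too few homozygotes of one class to fill the
  pools (at `Ne = 10, t = 10` roughly a fifth of runs). Such runs are not
  observations of `D`; `replicate_D()` flags them as `failed` and excludes
  them from summaries. The mean over feasible runs still matches the
  recursion, which itself assumes frequencies stay near 50%.
* **Reproducibility**: all randomness (R and C++ sides) flows through R's
  RNG; replicate `i` of `replicate_D()` seeds with `seed + i`, so every
  stochastic result in the package is bit-reproducible from its recorded
  seed.

## The marker layer

Real experiments infer breakpoints from marker SNPs that differentiate the
founder strains. `marker_panel()` places markers equidistantly (10 kb by
default, 1 kb for Pool-seq analyses); `genotype_pools()` counts blue/red
ancestry per pool at each marker; `poolseq_resample()` emulates short-read
pooled sequencing by observing, independently at each marker, `C`
chromosomes drawn with replacement from the pool — implemented as the
distributionally identical Binomial(`C`, pool frequency) draw.

`g_statistic()` is the 2×2 likelihood-ratio statistic on the two pools'
allele counts with the `0·ln 0 = 0` convention and no pseudocounts (a
fixed table `(10,0,0,10)` gives exactly `40 ln 2`). `smooth_gprime()`
computes G′ by Nadaraya–Watson regression with tricube weights over a
window of half-width `W` bracketing each marker; each G′ value is a convex
combination of the raw G values in its window. Equidistant panels use a
convolution fast path, verified in the tests against the brute-force
double loop.

### Tunables that matter

* **Kernel half-width `W`** (default 50 kb). The sources describing this
  analysis style do not print the bandwidth they used; we fix the default
  by a visible constraint instead: with 10-kb markers, the shortest
  callable peaks come out at ≈100 kb — the kernel support — matching the
  floor reported for this kind of simulation. Larger `W` trades resolution
  floor for smoothness; it is a plain argument everywhere.
* **Significance percentile** (default 99.9). Computed over all G′ values
  of the chromosome by linear interpolation (`quantile()` type 7); markers
  tied with the threshold count as above it.
* **Peak extent rule**. By default `call_peaks()` reports the span from
  the leftmost to the rightmost above-threshold marker on the chromosome
  (`max_gap = Inf`). We also provide an optional gap rule (split peaks at
  gaps `> max_gap`, flag the one containing the global maximum as main)
  for multi-QTL or noisy settings — but it is *not* the default because it
  systematically shortens noisy tracks: isolated above-threshold noise
  markers contribute to the whole-span length of a Pool-seq track but are
  discarded by the gap rule. In paired 200-replicate comparisons the gap
  rule was enough to reverse the (small, ~1–2%) expected ordering between
  Pool-seq at 40× of 400 chromosomes and full genotyping of 400
  chromosomes; the whole-span rule preserves it.

## What the simulations do and do not emulate

The generator reproduces the study conditions the theory was validated
under: a single QTL on a 100-Mb chromosome, uniform recombination at
1 cM/Mb modelled as a Poisson crossover process with obligate crossover
(no gene conversion, no interference), neutral interbreeding, perfect
marker information, and pool contamination only by heterozygotes. It does
not model sequencing errors, read lengths or mapping artifacts,
non-uniform recombination maps, multi-QTL architectures, selection at the
QTL, or overlapping generations. Passing tests therefore show that the
implementation matches the theory under the theory's own assumptions —
not that a real experiment with messy data will achieve these numbers;
real resolution will generally be somewhat worse.

## Validation scale

The test suite validates at sizes chosen to keep Monte-Carlo error a few
percent of the quantities compared: simulator-vs-recursion at five
parameter sets (`Ne ∈ {10, 100, 1000}`, `s ∈ {8, 32, 128}`, `t = 10`) with
500–700 replicates each on the 100-Mb chromosome; the F2 closed form
`1/(2rs)` with 1,000 replicates; the occupancy oracle with 1e5 draws; the
Pool-seq comparison with 600 paired replicates (its two close arms differ
by under 2%, which 200 replicates cannot resolve); and contamination
robustness with 200 paired replicates.

## Known limitations

* For `t ≳ 4 Ne`, drift erodes ancestry heterozygosity and all analytic
  methods overestimate `R` (predict too-small `E[D]`); the package warns
  rather than correcting for it.
* `Ne` is the coalescence effective size of the interbreeding population —
  in real experiments it is usually well below the census size and hard to
  estimate; the census is only an upper bound.
* The theory treats a single QTL; with several linked QTL the predictions
  are at best lower bounds on mapped-region lengths.
* Peak lengths are measured on the marker grid, so they are quantized at
  the marker spacing; comparisons across different spacings carry an
  edge bias of up to about one spacing per peak side.
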