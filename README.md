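# bsares — genomic resolution of bulk segregant analysis

Bulk segregant analysis (BSA) maps quantitative trait loci by crossing two
inbred strains, interbreeding the offspring for `t` generations, and then
sequencing two pools of individuals taken from the opposite tails of the
phenotypic distribution. The mapped region around a QTL is the stretch of
chromosome over which every pooled chromosome still carries the ancestry of
its founder strain; its length — and therefore the mapping resolution of
the experiment — is set by the ancestry breakpoints closest to the QTL
among all pooled chromosomes.

`bsares` is for experimentalists planning such crosses and for
methodologists studying them. It provides:

* **Analytic predictions** of the expected one-sided distance `E[D]` from
  the QTL to the nearest informative ancestry breakpoint, so that the
  expected mapped-region length is `2 E[D]`.
* **A forward Wright–Fisher simulator** with explicit ancestry-junction
  tracking (Rcpp core) that measures `D` directly, for validating the
  theory and exploring designs it does not cover.
* **The marker layer used in practice**: pool genotyping on a marker grid,
  Pool-seq coverage resampling, the G statistic with tricube-smoothed G′,
  and significance-peak calling.

## The model

Breakpoints captured by a sample of `2s` chromosomes accumulate along the
sample's genealogy. In a diploid Wright–Fisher population with coalescence
effective size `Ne`, the expected number of distinct ancestral lineages
`x(i)` in generation `i` follows the occupancy recursion

    E[x(i-1)] = 2 Ne [ 1 - (1 - 1/(2 Ne))^x(i) ],   x(t) = 2s,

evaluated back to generation 2. Crossovers create new ancestry breakpoints
only in individuals carrying both ancestries at the crossover point, at a
per-lineage, per-bp rate ρ(i) (for the standard design ρ(2) = r and
ρ(i > 2) = r/2). The total breakpoint rate along the genealogy is

    R = Σ_{i=2..t} ρ(i) E[x(i)],     E[D] = 1 / R,

with closed-form `integration` and `taylor` approximations and the
infinite-population limit `E[D] = 1/(r s t)` also available. Alternative
crossing schemes are handled by their own ρ schedules and effective sizes:
introgression mapping (`im`, Ne = 0.4 N′) and heterozygote selection
(`hs`, ρ(i) = r, Ne = 0.5 N′).

## Worked example

A Wagyu cattle cross (r = 1.23e-8 per bp, s = 13 sampled individuals,
t = 3 generations, Ne ≈ 4 because a single bull sired every generation):

```r
library(bsares)
design <- bsa_design(r = 1.23e-8, s = 13, t = 3, ne = 4)
expected_resolution(design)
#> Expected BSA mapping resolution (recursion method)
#>   breakpoint rate R = 2.552e-07 per bp
#>   E[D]   = 3.918e+06 bp (3.92 Mb)
#>   2 E[D] = 7.836e+06 bp (7.84 Mb)  [expected mapped-region length]
```

The experiment is expected to localize the QTL only to within ~8 Mb — close
to the ~5 Mb candidate region that this cross actually produced.

Validating the theory by simulation (insect-scale design, 100-Mb
chromosome, census 2,000, 100 breeders):

```r
cfg <- sim_config(t = 10, ne_breeders = 100, s = 20)
summary(replicate_D(cfg, n_reps = 200, seed = 1))
#> D over 200 replicates (down + up pooled):
#>   mean 7.638e+05 bp | quartiles 2.158e+05 / 5.265e+05 / 1.033e+06 bp
expected_resolution(bsa_design(1e-8, 20, 10, ne = 100))$E_D
#> [1] 692346.6
```

The simulated mean (7.6e5 bp; note the strong right skew — the mean sits
well above the median) agrees with the recursion prediction (6.9e5 bp)
within Monte-Carlo error. The marker pipeline on one simulated experiment
with 400-chromosome pools and 10-kb markers:

```r
set.seed(1)
ex <- run_experiment(sim_config(t = 10, ne_breeders = 100, s = 200))
track <- smooth_gprime(genotype_pools(ex$pools, marker_panel(1e8, 1e4)))
main_peak(track)
#> # A tibble: 1 × 7
#>      start      end length n_markers max_gprime  max_pos is_main
#> 1 49885000 50455000 570000        58       555. 49885000 TRUE
```

The called G′ peak (570 kb) brackets the true QTL at 50 Mb.

A command-line wrapper covering the three workflows is installed at
`system.file("cli", "bsares", package = "bsares")`, e.g.

```sh
bsares predict --scheme standard --r 0.74e-8 --s 200 --t 6 --ne 1000
bsares simulate --t 10 --ne 100 --s 20 --reps 100 --seed 1 --out run1
bsares gprime --counts counts.tsv --window-halfwidth 50000 --out run1
```

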