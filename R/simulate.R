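#' Ancestry haplotype
#'
#' A chromosome represented as an ordered mosaic of founder-strain ancestry
#' segments: a strictly increasing vector of breakpoint positions plus the
#' ancestry label of the leftmost segment. Ancestry alternates at each
#' breakpoint. Coordinates are 0-based integers in `[0, L)`; a breakpoint at
#' `p` means ancestry switches between `p - 1` and `p`.
#'
#' @param breakpoints Strictly increasing numeric vector of breakpoint
#'   positions in `(0, L)`; empty for a single-ancestry chromosome.
#' @param left_ancestry Ancestry of the segment starting at position 0:
#'   `"blue"` (A-strain) or `"red"` (a-strain), or the integer codes 0/1.
#' @return Object of class `"ancestry_haplotype"`: list with `breakpoints`
#'   and `left` (0 = blue, 1 = red).
#' @examples
#' h <- ancestry_haplotype(c(2e6, 5e6), "blue")
#' ancestry_at(h, c(0, 3e6, 7e6))
#' @export
ancestry_haplotype <- function(breakpoints = numeric(), left_ancestry = "blue") {
  left <- decode_ancestry(left_ancestry)
  breakpoints <- as.numeric(breakpoints)
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (length(breakpoints) && any(breakpoints <= 0)) {
    stop("breakpoints must be positive", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, left = left),
            class = "ancestry_haplotype")
}

decode_ancestry <- function(x) {
  if (is.character(x)) match(match.arg(x, c("blue", "red")),
                             c("blue", "red")) - 1L
  else as.integer(x)
}

#' @rdname ancestry_haplotype
#' @param hap An `ancestry_haplotype`.
#' @param pos Positions (bp) at which to evaluate ancestry.
#' @return `ancestry_at()`: integer vector, 0 = blue, 1 = red.
#' @export
ancestry_at <- function(hap, pos) {
  stopifnot(inherits(hap, "ancestry_haplotype"))
  (hap$left + findInterval(pos, hap$breakpoints)) %% 2L
}

#' @export
print.ancestry_haplotype <- function(x, ...) {
  cat("ancestry haplotype: left =", c("blue", "red")[x$left + 1L],
      "|", length(x$breakpoints), "breakpoint(s)\n")
  if (length(x$breakpoints)) {
    cat(" ", paste(format(x$breakpoints, big.mark = ",", trim = TRUE),
                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Configure a simulated BSA experiment
#'
#' Parameters of one forward Wright-Fisher simulation with ancestry-junction
#' tracking. Defaults mirror a typical insect-scale BSA experiment: a 100-Mb
#' chromosome with the QTL at its centre, uniform recombination at 1 cM/Mb,
#' a census of 2,000 individuals per generation of which `ne_breeders`
#' randomly chosen ones reproduce.
#'
#' @param t Generations of interbreeding; the population is sampled in
#'   generation t (the F1 is generation 1).
#' @param ne_breeders Number of randomly chosen individuals allowed to breed
#'   each generation; this is the simulator's effective population size.
#' @param s Chromosomes per selected pool (must be even: pools are built
#'   from whole diploid individuals).
#' @param L Chromosome length in bp.
#' @param qtl_pos Position of the QTL (bp), default mid-chromosome.
#' @param r Recombination rate per bp per generation.
#' @param n_census Census size per generation.
#' @param scheme Crossing scheme: `"standard"`, `"im"`, or `"hs"`.
#' @param contamination Fraction of each pool's individuals that are QTL
#'   heterozygotes (phenotyping inaccuracy), in `[0, 1)`.
#' @param seed Integer RNG seed recorded with the configuration; used by
#'   [replicate_D()] and the command-line interface.
#' @return Object of class `"sim_config"`.
#' @examples
#' sim_config(t = 10, ne_breeders = 100, s = 20)
#' @export
sim_config <- function(t, ne_breeders, s, L = 1e8, qtl_pos = floor(L / 2),
                       r = 1e-8, n_census = 2000,
                       scheme = c("standard", "im", "hs"),
                       contamination = 0, seed = NULL) {
  scheme <- match.arg(scheme)
  check_count(t, "t", min = 2)
  check_count(ne_breeders, "ne_breeders", min = 2)
  check_count(s, "s", min = 2)
  check_count(n_census, "n_census", min = 2)
  stopifnot(r > 0, L > 1, qtl_pos > 0, qtl_pos < L,
            contamination >= 0, contamination < 1)
  if (ne_breeders > n_census) {
    stop("ne_breeders must not exceed n_census", call. = FALSE)
  }
  if (s %% 2L != 0L) {
    stop("`s` must be even: pools are built from whole diploid individuals",
         call. = FALSE)
  }
  structure(list(L = L, qtl_pos = qtl_pos, r = r, t = as.integer(t),
                 n_census = as.integer(n_census),
                 ne_breeders = as.integer(ne_breeders), scheme = scheme,
                 s = as.integer(s), contamination = contamination,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("BSA simulation config:", x$scheme, "scheme\n")
  cat(sprintf("  L = %.3g bp, QTL at %.3g, r = %.3g\n", x$L, x$qtl_pos, x$r))
  cat(sprintf("  t = %d generations, census %d, Ne (breeders) %d\n",
              x$t, x$n_census, x$ne_breeders))
  cat(sprintf("  pools: s = %d chromosomes, contamination %.0f%%\n",
              x$s, 100 * x$contamination))
  invisible(x)
}

#' One meiosis of a diploid parent
#'
#' Draws `Poisson(r * L)` crossover positions uniformly along the chromosome
#' and returns the gamete obtained by alternating between the parent's two
#' haplotypes at those positions (the starting haplotype is chosen
#' uniformly). All recombination events are crossovers; stored breakpoints
#' are true ancestry switches, so crossovers in regions where the parent
#' carries the same ancestry on both haplotypes leave no junction.
#'
#' Uses R's global RNG stream (`set.seed()` makes it reproducible).
#'
#' @param parent List with elements `hap1`, `hap2`, both
#'   [ancestry_haplotype()] objects.
#' @param r Crossover rate per bp.
#' @param L Chromosome length (bp).
#' @return An [ancestry_haplotype()].
#' @examples
#' f1 <- list(hap1 = ancestry_haplotype(left_ancestry = "blue"),
#'            hap2 = ancestry_haplotype(left_ancestry = "red"))
#' set.seed(1)
#' meiosis(f1, r = 1e-8, L = 1e8)
#' @export
meiosis <- function(parent, r, L) {
  stopifnot(inherits(parent$hap1, "ancestry_haplotype"),
            inherits(parent$hap2, "ancestry_haplotype"), r >= 0, L > 1)
  g <- meiosis_cpp(parent$hap1$breakpoints, parent$hap1$left,
                   parent$hap2$breakpoints, parent$hap2$left, r, L)
  ancestry_haplotype(g$breakpoints, g$left)
}

#' Run one simulated BSA experiment
#'
#' Simulates the full crossing design forward in time and selects the two
#' segregant pools. The F1 is formed from the two inbred parental strains,
#' so every F1 individual carries one all-blue and one all-red chromosome.
#' Each subsequent generation holds `n_census` offspring produced by
#' `ne_breeders` randomly chosen parents (Wright-Fisher, discrete
#' non-overlapping generations, no selection on the trait except as imposed
#' by the crossing scheme):
#'
#' * `standard`: random interbreeding throughout.
#' * `hs`: only QTL heterozygotes among the chosen breeders reproduce.
#' * `im`: in even generations the AA homozygotes among the chosen breeders
#'   are backcrossed to the (externally maintained, drift-free) red parental
#'   strain; odd generations interbreed freely. Sample at an even `t` so
#'   that AA homozygotes exist.
#'
#' @param config A [sim_config()].
#' @return List of class `"bsa_experiment"` with elements `population`
#'   (class `"bsa_population"`, the final generation) and `pools`
#'   (class `"pool_pair"`, see [select_pools()]).
#' @examples
#' set.seed(42)
#' ex <- run_experiment(sim_config(t = 3, ne_breeders = 50, s = 8,
#'                                 L = 1e7, n_census = 200))
#' ex$pools
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  raw <- sim_population_cpp(config$L, config$qtl_pos, config$r, config$t,
                            config$n_census, config$ne_breeders,
                            config$scheme)
  pop <- structure(list(left = raw$left, nbp = raw$nbp, bp = raw$bp,
                        offset = c(0L, cumsum(raw$nbp)),
                        n = config$n_census, L = config$L,
                        qtl_pos = config$qtl_pos, t = config$t,
                        scheme = config$scheme),
                   class = "bsa_population")
  pools <- select_pools(pop, config$s, config$contamination)
  structure(list(population = pop, pools = pools), class = "bsa_experiment")
}

#' @export
print.bsa_population <- function(x, ...) {
  cat("simulated BSA population:", x$n, "diploid individuals, generation",
      x$t, paste0("(", x$scheme, " scheme)\n"))
  cat(sprintf("  chromosome L = %.3g bp, QTL at %.3g\n", x$L, x$qtl_pos))
  cat(sprintf("  mean junctions per chromosome: %.2f\n", mean(x$nbp)))
  invisible(x)
}

#' Extract one chromosome from a simulated population
#'
#' @param pop A `"bsa_population"`.
#' @param k Haplotype index in `1..2n`; individual `i` owns haplotypes
#'   `2i - 1` and `2i`.
#' @return An [ancestry_haplotype()].
#' @export
haplotype <- function(pop, k) {
  stopifnot(inherits(pop, "bsa_population"), k >= 1, k <= 2 * pop$n)
  idx <- seq_len(pop$nbp[k]) + pop$offset[k]
  ancestry_haplotype(pop$bp[idx], pop$left[k])
}

#' QTL genotypes of all individuals
#'
#' @param pop A `"bsa_population"`.
#' @param pos Position at which to genotype (default the QTL).
#' @return Factor of length `n` with levels `AA`, `Aa`, `aa` (blue ancestry
#'   carries the A allele).
#' @export
qtl_genotypes <- function(pop, pos = pop$qtl_pos) {
  stopifnot(inherits(pop, "bsa_population"))
  anc <- ancestry_at_cpp(pop$nbp, pop$bp, pop$left, pos)
  g <- anc[seq(1, length(anc), by = 2)] + anc[seq(2, length(anc), by = 2)]
  factor(c("AA", "Aa", "aa")[g + 1L], levels = c("AA", "Aa", "aa"))
}

#' Select the two segregant pools
#'
#' Forms the high (AA) and low (aa) pools from the final generation, each
#' holding `s` chromosomes from `s / 2` whole diploid individuals. A
#' fraction `contamination` of each pool's individuals are QTL heterozygotes
#' (drawn uniformly, mimicking phenotyping errors); the remainder are
#' correct homozygotes drawn uniformly without replacement. Under the
#' introgression (`im`) scheme only AA individuals are sequenced: the
#' combined sample is `s` AA individuals (`2s` chromosomes), stored in the
#' high pool, and the low pool is empty.
#'
#' @param population A `"bsa_population"` from [run_experiment()].
#' @param s Chromosomes per pool (even).
#' @param contamination Heterozygote fraction per pool, in `[0, 1)`.
#' @return Object of class `"pool_pair"`: list with the `population`,
#'   haplotype indices `high_chrom` / `low_chrom`, individual indices
#'   `high_ind` / `low_ind`, `s`, and `contamination`.
#' @export
select_pools <- function(population, s, contamination = 0) {
  stopifnot(inherits(population, "bsa_population"))
  check_count(s, "s", min = 2)
  if (s %% 2L != 0L) {
    stop("`s` must be even: pools are built from whole diploid individuals",
         call. = FALSE)
  }
  stopifnot(contamination >= 0, contamination < 1)
  geno <- qtl_genotypes(population)

  if (population$scheme == "im") {
    if (contamination > 0) {
      stop("contamination is not defined for the introgression scheme ",
           "(a single AA bulk is sequenced)", call. = FALSE)
    }
    aa_ind <- which(geno == "AA")
    if (length(aa_ind) < s) {
      stop(sprintf(
        "introgression scheme needs s = %d AA individuals but the final generation has %d (AA/Aa/aa = %d/%d/%d); sample at an even generation t",
        s, length(aa_ind), sum(geno == "AA"), sum(geno == "Aa"),
        sum(geno == "aa")), call. = FALSE)
    }
    pick <- sample(aa_ind, s)
    return(structure(list(population = population,
                          high_chrom = ind_to_chrom(pick),
                          low_chrom = integer(),
                          high_ind = pick, low_ind = integer(),
                          s = as.integer(s), contamination = 0),
                     class = "pool_pair"))
  }

  n_ind <- s %/% 2L
  n_het <- round(contamination * n_ind)
  n_hom <- n_ind - n_het
  counts <- table(geno)
  if (counts[["AA"]] < n_hom || counts[["aa"]] < n_hom ||
      counts[["Aa"]] < 2 * n_het) {
    stop(sprintf(
      "cannot fill pools: need %d AA, %d aa and %d Aa individuals but the final generation has AA/Aa/aa = %d/%d/%d",
      n_hom, n_hom, 2 * n_het, counts[["AA"]], counts[["Aa"]],
      counts[["aa"]]), call. = FALSE)
  }
  high_ind <- sample(which(geno == "AA"), n_hom)
  low_ind <- sample(which(geno == "aa"), n_hom)
  if (n_het > 0) {
    het <- sample(which(geno == "Aa"), 2 * n_het)
    high_ind <- c(high_ind, het[seq_len(n_het)])
    low_ind <- c(low_ind, het[n_het + seq_len(n_het)])
  }
  structure(list(population = population,
                 high_chrom = ind_to_chrom(high_ind),
                 low_chrom = ind_to_chrom(low_ind),
                 high_ind = high_ind, low_ind = low_ind,
                 s = as.integer(s), contamination = contamination),
            class = "pool_pair")
}

ind_to_chrom <- function(ind) as.integer(rbind(2L * ind - 1L, 2L * ind))

#' @export
print.pool_pair <- function(x, ...) {
  cat("segregant pool pair:", length(x$high_chrom), "chromosomes (high/AA),",
      length(x$low_chrom), "chromosomes (low/aa)\n")
  if (x$contamination > 0) {
    cat(sprintf("  heterozygote contamination: %.0f%% of individuals per pool\n",
                100 * x$contamination))
  }
  invisible(x)
}

#' Assemble a pool pair from explicit haplotypes
#'
#' Builds a `"pool_pair"` directly from lists of [ancestry_haplotype()]
#' objects, without running a simulation. Intended for constructing small
#' synthetic examples and for genotyping externally defined chromosomes.
#' Each consecutive pair of haplotypes within a pool is treated as one
#' diploid individual.
#'
#' @param high,low Lists of [ancestry_haplotype()] objects (the low pool may
#'   be empty).
#' @param L Chromosome length (bp).
#' @param qtl_pos QTL position (bp).
#' @param contamination Recorded heterozygote contamination fraction.
#' @return A `"pool_pair"`.
#' @export
pool_pair <- function(high, low = list(), L, qtl_pos, contamination = 0) {
  haps <- c(high, low)
  stopifnot(length(haps) > 0,
            all(vapply(haps, inherits, logical(1), "ancestry_haplotype")))
  nbp <- vapply(haps, function(h) length(h$breakpoints), integer(1))
  pop <- structure(list(left = vapply(haps, `[[`, integer(1), "left"),
                        nbp = nbp,
                        bp = unlist(lapply(haps, `[[`, "breakpoints")),
                        offset = c(0L, cumsum(nbp)),
                        n = ceiling(length(haps) / 2), L = L,
                        qtl_pos = qtl_pos, t = NA_integer_,
                        scheme = "standard"),
                   class = "bsa_population")
  structure(list(population = pop,
                 high_chrom = seq_along(high),
                 low_chrom = length(high) + seq_along(low),
                 high_ind = NULL, low_ind = NULL,
                 s = length(high), contamination = contamination),
            class = "pool_pair")
}

#' Distance from the QTL to the nearest pooled ancestry breakpoint
#'
#' The mapped region of an idealized (uncontaminated) BSA experiment is
#' delimited by the closest ancestry breakpoints upstream and downstream of
#' the QTL over all pooled chromosomes. This measures both one-sided
#' distances directly from the junction lists. When no chromosome carries a
#' breakpoint on one side, the distance is censored at the chromosome end.
#'
#' @param pools A `"pool_pair"` with `contamination == 0` (for contaminated
#'   pools the mapped region is only defined through the marker statistics;
#'   see [smooth_gprime()]).
#' @param qtl_pos,L Override the QTL position / chromosome length recorded
#'   in the pools.
#' @return Object of class `"d_sample"`: list with `d_down`, `d_up` (bp) and
#'   logical `censored_down`, `censored_up`.
#' @export
nearest_breakpoint_distance <- function(pools, qtl_pos = NULL, L = NULL) {
  stopifnot(inherits(pools, "pool_pair"))
  if (pools$contamination > 0) {
    stop("the breakpoint distance D is defined for uncontaminated pools; ",
         "analyse contaminated pools with the G' pipeline instead",
         call. = FALSE)
  }
  pop <- pools$population
  qtl <- if (is.null(qtl_pos)) pop$qtl_pos else qtl_pos
  L <- if (is.null(L)) pop$L else L
  chrom <- c(pools$high_chrom, pools$low_chrom)

  d_down <- Inf
  d_up <- Inf
  for (k in chrom) {
    if (pop$nbp[k] > 0) {
      b <- pop$bp[seq_len(pop$nbp[k]) + pop$offset[k]]
      dn <- b[b > qtl]
      if (length(dn)) d_down <- min(d_down, dn[1] - qtl)
      up <- b[b <= qtl]
      if (length(up)) d_up <- min(d_up, qtl - up[length(up)])
    }
  }
  censored_down <- !is.finite(d_down)
  censored_up <- !is.finite(d_up)
  if (censored_down) d_down <- L - qtl
  if (censored_up) d_up <- qtl
  structure(list(d_down = d_down, d_up = d_up,
                 censored_down = censored_down, censored_up = censored_up),
            class = "d_sample")
}

#' @export
print.d_sample <- function(x, ...) {
  cat(sprintf("D downstream: %.4g bp%s | D upstream: %.4g bp%s\n",
              x$d_down, if (x$censored_down) " (censored)" else "",
              x$d_up, if (x$censored_up) " (censored)" else ""))
  invisible(x)
}

#' Replicate the breakpoint distance D over independent experiments
#'
#' Runs `n_reps` independent simulated experiments and records the
#' downstream and upstream distances from the QTL to the nearest pooled
#' ancestry breakpoint. Replicate `i` seeds R's RNG with `seed + i`, so the
#' whole run is exactly reproducible. The distribution of D is strongly
#' right-skewed, so its mean (the quantity predicted by
#' [expected_resolution()]) is typically well above its median; the summary
#' reports both.
#'
#' Under strong drift (small `ne_breeders`, many generations) the QTL allele
#' can approach fixation, leaving too few homozygotes of one class to fill
#' the pools. Such replicates are experimentally infeasible rather than
#' observations of D: they are flagged in the `failed` column (distances
#' `NA`) and excluded from the summary, which reports how many there were.
#'
#' @param config A [sim_config()] with `contamination = 0`.
#' @param n_reps Number of replicate experiments.
#' @param seed Base seed; defaults to `config$seed` (or 1).
#' @return A tibble of class `"d_replicates"` with columns `replicate`,
#'   `d_down`, `d_up`, `censored_down`, `censored_up`, `failed`; censored
#'   distances enter the means at their censoring value (distance to the
#'   chromosome end) and are flagged. `summary()` reports means and
#'   quartiles over the non-failed replicates.
#' @examples
#' cfg <- sim_config(t = 2, ne_breeders = 100, s = 8, L = 1e7,
#'                   n_census = 100)
#' summary(replicate_D(cfg, n_reps = 5, seed = 1))
#' @export
replicate_D <- function(config, n_reps, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  if (config$contamination > 0) {
    stop("D replication requires uncontaminated pools", call. = FALSE)
  }
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    ex <- tryCatch(run_experiment(config), error = function(e) {
      if (grepl("cannot fill pools|fewer than|no AA individuals",
                conditionMessage(e))) NULL else stop(e)
    })
    out[[i]] <- if (is.null(ex)) {
      c(NA_real_, NA_real_, NA, NA, TRUE)
    } else {
      d <- nearest_breakpoint_distance(ex$pools)
      c(d$d_down, d$d_up, d$censored_down, d$censored_up, FALSE)
    }
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(replicate = seq_len(n_reps),
                        d_down = m[, 1], d_up = m[, 2],
                        censored_down = as.logical(m[, 3]),
                        censored_up = as.logical(m[, 4]),
                        failed = as.logical(m[, 5]))
  class(res) <- c("d_replicates", class(res))
  attr(res, "config") <- config
  attr(res, "seed") <- seed
  res
}

#' @export
summary.d_replicates <- function(object, ...) {
  ok <- object[!object$failed, ]
  d <- c(ok$d_down, ok$d_up)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(n_reps = nrow(object), n_failed = sum(object$failed),
              mean = mean(d),
              q1 = q[1], median = q[2], q3 = q[3],
              mean_down = mean(ok$d_down), mean_up = mean(ok$d_up),
              censored_frac = mean(c(ok$censored_down, ok$censored_up)))
  class(out) <- "summary.d_replicates"
  out
}

#' @export
print.summary.d_replicates <- function(x, ...) {
  cat(sprintf("D over %d replicates (down + up pooled):\n",
              x$n_reps - x$n_failed))
  if (x$n_failed > 0) {
    cat(sprintf("  %d replicate(s) infeasible (pools could not be filled)\n",
                x$n_failed))
  }
  cat(sprintf("  mean %.4g bp | quartiles %.4g / %.4g / %.4g bp\n",
              x$mean, x$q1, x$median, x$q3))
  if (x$censored_frac > 0) {
    cat(sprintf("  %.1f%% of distances censored at the chromosome end\n",
                100 * x$censored_frac))
  }
  invisible(x)
}
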