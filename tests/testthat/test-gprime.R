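make_tiny_pools <- function() {
  # 4 chromosomes per pool on a 1-Mb chromosome, QTL at 5e5;
  # high pool blue at the QTL, low pool red, with known junctions
  high <- list(ancestry_haplotype(c(7e5), "blue"),
               ancestry_haplotype(c(2e5), "red"),
               ancestry_haplotype(numeric(), "blue"),
               ancestry_haplotype(c(6e5, 8e5), "blue"))
  low <- list(ancestry_haplotype(c(3e5, 9e5), "blue"),
              ancestry_haplotype(numeric(), "red"),
              ancestry_haplotype(c(5.5e5), "red"),
              ancestry_haplotype(c(1e5), "blue"))
  pool_pair(high, low, L = 1e6, qtl_pos = 5e5)
}

test_that("marker panels are sorted, in range, with the requested spacing", {
  p <- marker_panel(1e6, 1e5)
  expect_true(all(p >= 0 & p < 1e6))
  expect_equal(unique(diff(p)), 1e5)
  expect_error(marker_panel(1e4, 1e5))
})

test_that("full genotyping counts ancestry exactly", {
  pools <- make_tiny_pools()
  counts <- genotype_pools(pools, marker_panel(1e6, 1e5))
  expect_equal(counts$n_blue_high + counts$n_red_high, rep(4L, 10))
  expect_equal(counts$n_blue_low + counts$n_red_low, rep(4L, 10))
  at_qtl <- counts[counts$pos == 5.5e5, ]  # first marker past the QTL
  # haplotype 3 of the low pool switches to blue exactly at 5.5e5
  expect_equal(at_qtl$n_blue_high, 4L)
  expect_equal(at_qtl$n_blue_low, 1L)
  # hand-checked column at 0.5e5: high = blue,red,blue,blue; low = b,r,r,b
  at0 <- counts[counts$pos == 0.5e5, ]
  expect_equal(at0$n_blue_high, 3L)
  expect_equal(at0$n_blue_low, 2L)
})

test_that("heterozygote contamination shifts pool frequencies to 80:20 at the QTL", {
  set.seed(21)
  ex <- run_experiment(sim_config(t = 4, ne_breeders = 200, s = 40,
                                  L = 1e7, n_census = 500,
                                  contamination = 0.4))
  qtl_marker <- ex$population$qtl_pos
  counts <- genotype_pools(ex$pools, qtl_marker)
  # 8 of 20 individuals per pool are Aa: blue fraction 0.8 / 0.2 exactly
  expect_equal(counts$n_blue_high / 40, 0.8)
  expect_equal(counts$n_blue_low / 40, 0.2)
})

test_that("Pool-seq resampling is binomial around the true pool frequency", {
  pools <- make_tiny_pools()
  panel <- marker_panel(1e6, 1e5)
  truth <- genotype_pools(pools, panel)
  set.seed(22)
  ps <- poolseq_resample(pools, panel, coverage = 40)
  expect_equal(ps$n_blue_high + ps$n_red_high, rep(40L, 10))
  # C = 1 reports a single chromosome per pool per marker
  one <- poolseq_resample(pools, panel, coverage = 1)
  expect_true(all(one$n_blue_high %in% 0:1))
  # binomial oracle at one marker: mean C*f, variance C*f*(1-f)
  f <- truth$n_blue_high[1] / 4  # 3/4 at the first marker
  draws <- replicate(4000, poolseq_resample(pools, panel[1],
                                            coverage = 40)$n_blue_high)
  expect_lt(abs(mean(draws) - 40 * f), 3 * stats::sd(draws) / sqrt(4000))
  expect_equal(stats::var(draws), 40 * f * (1 - f), tolerance = 0.1)
  # high coverage converges to the true frequency
  big <- poolseq_resample(pools, panel, coverage = 20000)
  expect_equal(big$n_blue_high / 20000, truth$n_blue_high / 4,
               tolerance = 0.05)
})

test_that("G statistic matches the 2x2 likelihood-ratio oracle", {
  expect_equal(g_statistic(10, 0, 0, 10), 40 * log(2))
  expect_equal(g_statistic(7, 3, 7, 3), 0)
  # linear in counts at fixed proportions
  expect_equal(g_statistic(20, 0, 0, 20), 2 * g_statistic(10, 0, 0, 10))
  # empty row or column is defined as 0
  expect_equal(g_statistic(0, 0, 5, 5), 0)
  expect_equal(g_statistic(0, 10, 0, 10), 0)
  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(g_statistic(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 lr_from_chisq(tab), tolerance = 1e-10)
  }
})

test_that("tricube smoothing is a windowed convex combination", {
  counts <- tibble::tibble(pos = seq(0, 99) * 1e3,
                           n_blue_high = 5L, n_red_high = 5L,
                           n_blue_low = 5L, n_red_low = 5L)
  # constant G stays constant
  counts$n_blue_high <- 10L; counts$n_red_high <- 0L
  counts$n_blue_low <- 0L; counts$n_red_low <- 10L
  tr <- smooth_gprime(counts, window_halfwidth = 5e3)
  expect_equal(tr$Gprime, rep(40 * log(2), 100))

  # single spike: support confined to +/- W, zero weight at exactly W
  counts2 <- tibble::tibble(pos = seq(0, 99) * 1e3,
                            n_blue_high = c(rep(5L, 50), 10L, rep(5L, 49)),
                            n_red_high = c(rep(5L, 50), 0L, rep(5L, 49)),
                            n_blue_low = 5L, n_red_low = 5L)
  tr2 <- smooth_gprime(counts2, window_halfwidth = 4e3)
  nz <- which(tr2$Gprime > 0)
  expect_equal(tr2$pos[nz], seq(47, 53) * 1e3)

  # equidistant fast path equals the brute-force double loop
  set.seed(24)
  counts3 <- tibble::tibble(pos = seq(0, 199) * 5e2,
                            n_blue_high = rbinom(200, 10, 0.7),
                            n_blue_low = rbinom(200, 10, 0.3))
  counts3$n_red_high <- 10L - counts3$n_blue_high
  counts3$n_red_low <- 10L - counts3$n_blue_low
  tr3 <- smooth_gprime(counts3, window_halfwidth = 7e3)
  expect_equal(tr3$Gprime, naive_tricube(tr3$G, tr3$pos, 7e3),
               tolerance = 1e-12)
  # convex combination: bounded by the window's raw G range
  expect_true(all(tr3$Gprime <= max(tr3$G) + 1e-9))
  expect_true(all(tr3$Gprime >= min(tr3$G) - 1e-9))

  # irregular spacing falls back to the same definition
  irr <- counts3[sort(sample.int(200, 80)), ]
  tri <- smooth_gprime(irr, window_halfwidth = 7e3)
  expect_equal(tri$Gprime, naive_tricube(tri$G, tri$pos, 7e3),
               tolerance = 1e-12)
})

test_that("peak calling applies the percentile threshold and span rules", {
  pos <- seq(0, 999) * 1e4
  g <- rep(0, 1000); g[501] <- 10
  tr <- structure(tibble::tibble(pos = pos, G = g, Gprime = g),
                  window_halfwidth = 5e4,
                  class = c("gprime_track", class(tibble::tibble())))
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$length, 0)       # single above-threshold marker
  expect_equal(pk$max_pos, 5e6)

  # two separated clusters: whole-span by default, split with a gap rule
  g2 <- rep(0, 1000); g2[300:310] <- 5; g2[700:705] <- 8
  tr2 <- structure(tibble::tibble(pos = pos, G = g2, Gprime = g2),
                   window_halfwidth = 5e4,
                   class = c("gprime_track", class(tibble::tibble())))
  whole <- call_peaks(tr2, percentile = 99)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$length, (704 - 299) * 1e4)
  split <- call_peaks(tr2, percentile = 99, max_gap = 2e5)
  expect_equal(nrow(split), 2)
  expect_equal(split$is_main, c(TRUE, FALSE))
  expect_equal(split$max_pos[split$is_main], 6.99e6)

  # threshold is the linearly interpolated percentile; ties count as above
  thr <- attr(whole, "threshold")
  expect_equal(thr, unname(stats::quantile(g2, 0.99)))
  expect_equal(sum(tr2$Gprime >= thr), whole$n_markers)
})

test_that("the QTL lies inside the called peak of a simulated experiment", {
  set.seed(25)
  ex <- run_experiment(sim_config(t = 10, ne_breeders = 100, s = 100))
  tr <- smooth_gprime(genotype_pools(ex$pools, marker_panel(1e8, 1e4)))
  pk <- main_peak(tr)
  expect_lte(pk$start, 5e7)
  expect_gte(pk$end, 5e7)
  expect_equal(pk$max_pos, 5e7, tolerance = 0.02)
})
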