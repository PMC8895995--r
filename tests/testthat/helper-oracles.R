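# Independent oracles used across the test files.

# Monte-Carlo occupancy: number of distinct boxes hit when n_balls are
# thrown uniformly into n_boxes, replicated `reps` times. This is one
# backward generation of lineage coalescence (balls = lineages, boxes =
# parental chromosomes), used as the independent check of the lineage-count
# recursion.
mc_occupancy <- function(n_balls, n_boxes, reps) {
  draws <- sample.int(n_boxes, reps * n_balls, replace = TRUE)
  idx <- draws + (rep(seq_len(reps), each = n_balls) - 1L) * n_boxes
  hit <- tabulate(idx, nbins = reps * n_boxes) > 0L
  colSums(matrix(hit, nrow = n_boxes))
}

# Likelihood-ratio statistic of a 2x2 table computed through the expected
# counts of stats::chisq.test (independent of the package's formula).
lr_from_chisq <- function(tab) {
  e <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected
  2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
}

# Brute-force Nadaraya-Watson tricube smoother (double loop).
naive_tricube <- function(G, pos, W) {
  vapply(seq_along(G), function(k) {
    d <- abs(pos - pos[k])
    j <- d <= W
    w <- (1 - (d[j] / W)^3)^3
    sum(w * G[j]) / sum(w)
  }, numeric(1))
}

# An F1-style parent: one all-blue and one all-red chromosome.
f1_parent <- function() {
  list(hap1 = ancestry_haplotype(left_ancestry = "blue"),
       hap2 = ancestry_haplotype(left_ancestry = "red"))
}
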