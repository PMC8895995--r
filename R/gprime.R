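#' Equidistant marker panel
#'
#' Marker SNPs placed at equidistant intervals along the chromosome, used to
#' distinguish founder-strain ancestry in the pools. The default spacing is
#' 10 kb; Pool-seq analyses typically use a denser 1-kb grid.
#'
#' @param L Chromosome length (bp).
#' @param spacing Distance between adjacent markers (bp).
#' @return Numeric vector of marker positions (class `"marker_panel"`,
#'   attributes `L` and `spacing`), sorted, within `[0, L)`.
#' @examples
#' marker_panel(1e6, spacing = 1e5)
#' @export
marker_panel <- function(L, spacing = 1e4) {
  stopifnot(L > 1, spacing >= 1, spacing < L)
  pos <- seq(floor(spacing / 2), L - 1, by = spacing)
  structure(pos, L = L, spacing = spacing, class = "marker_panel")
}

#' Genotype the pools at a marker panel
#'
#' Counts, at every marker, how many chromosomes in each pool carry blue
#' (A-strain) versus red (a-strain) ancestry. This is the full-information
#' limit in which every pooled chromosome is genotyped at every marker.
#'
#' @param pools A `"pool_pair"` (from [select_pools()] or [pool_pair()]).
#' @param panel A [marker_panel()] (or sorted numeric positions).
#' @return A tibble with columns `pos`, `n_blue_high`, `n_red_high`,
#'   `n_blue_low`, `n_red_low`; per-pool totals equal the pool size at every
#'   marker.
#' @export
genotype_pools <- function(pools, panel) {
  stopifnot(inherits(pools, "pool_pair"))
  pos <- as.numeric(panel)
  stopifnot(!is.unsorted(pos))
  pop <- pools$population
  if (any(pos < 0 | pos >= pop$L)) {
    stop("marker positions must lie within [0, L)", call. = FALSE)
  }
  blue_high <- pool_blue_counts_cpp(pop$nbp, pop$bp, pop$left,
                                    pools$high_chrom, pos)
  n_high <- length(pools$high_chrom)
  if (length(pools$low_chrom)) {
    blue_low <- pool_blue_counts_cpp(pop$nbp, pop$bp, pop$left,
                                     pools$low_chrom, pos)
  } else {
    blue_low <- integer(length(pos))
  }
  n_low <- length(pools$low_chrom)
  tibble::tibble(pos = pos,
                 n_blue_high = as.integer(blue_high),
                 n_red_high = n_high - as.integer(blue_high),
                 n_blue_low = as.integer(blue_low),
                 n_red_low = n_low - as.integer(blue_low))
}

#' Pool-seq resampling of marker counts
#'
#' Emulates short-read pooled sequencing at coverage `coverage`: at each
#' marker, independently of all other markers, `coverage` chromosomes are
#' drawn uniformly with replacement from the pool and their ancestry is
#' counted. Because each of the `coverage` draws is blue with probability
#' equal to the pool's true blue frequency at that marker, the blue count is
#' an exact Binomial(`coverage`, frequency) draw, which is how it is
#' generated. Uses R's global RNG stream.
#'
#' @inheritParams genotype_pools
#' @param coverage Number of chromosomes observed per marker per pool
#'   (sequencing coverage C).
#' @return A tibble in the same shape as [genotype_pools()], with per-pool
#'   totals equal to `coverage` at every marker.
#' @export
poolseq_resample <- function(pools, panel, coverage) {
  check_count(coverage, "coverage", min = 1)
  full <- genotype_pools(pools, panel)
  n_high <- full$n_blue_high + full$n_red_high
  n_low <- full$n_blue_low + full$n_red_low
  nm <- nrow(full)
  blue_high <- stats::rbinom(nm, coverage, full$n_blue_high / n_high)
  blue_low <- stats::rbinom(nm, coverage, full$n_blue_low / n_low)
  tibble::tibble(pos = full$pos,
                 n_blue_high = blue_high,
                 n_red_high = as.integer(coverage) - blue_high,
                 n_blue_low = blue_low,
                 n_red_low = as.integer(coverage) - blue_low)
}

#' G statistic for pool allele counts
#'
#' The 2x2 log-likelihood-ratio statistic comparing the blue/red allele
#' counts of the two pools at one marker:
#' \deqn{G = 2 \sum_{cells} n \ln(n / \hat n)}
#' with expected counts \eqn{\hat n} from the row/column totals under
#' independence, and the convention `0 * ln(0) = 0`. `G` is 0 when the two
#' pools have identical allele frequencies, and 0 by definition when a row
#' or column total is 0. All arguments are vectorised over markers.
#'
#' @param n_blue_high,n_red_high Blue/red counts in the high (AA) pool.
#' @param n_blue_low,n_red_low Blue/red counts in the low (aa) pool.
#' @return Numeric vector of G values (non-negative).
#' @examples
#' g_statistic(10, 0, 0, 10)  # = 40 * log(2)
#' @export
g_statistic <- function(n_blue_high, n_red_high, n_blue_low, n_red_low) {
  a <- n_blue_high; b <- n_red_high; c <- n_blue_low; d <- n_red_low
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  N <- a + b + c + d
  row1 <- a + b; row2 <- c + d
  col1 <- a + c; col2 <- b + d
  xlx <- function(n, e) ifelse(n > 0, n * log(n / e), 0)
  g <- 2 * (xlx(a, row1 * col1 / N) + xlx(b, row1 * col2 / N) +
            xlx(c, row2 * col1 / N) + xlx(d, row2 * col2 / N))
  g[row1 == 0 | row2 == 0 | col1 == 0 | col2 == 0 | N == 0] <- 0
  pmax(g, 0)  # clamp tiny negative rounding error
}

#' Tricube-smoothed G' track
#'
#' Computes the raw G statistic at every marker and smooths it by a
#' Nadaraya-Watson kernel regression with tricube weights over a window of
#' half-width `window_halfwidth` bracketing each focal marker:
#' \deqn{G'_k = \sum_j w_{jk} G_j / \sum_j w_{jk}, \quad
#'       w_{jk} = (1 - (|p_j - p_k| / W)^3)^3}
#' for markers `j` with `|p_j - p_k| <= W`. Each `G'` value is therefore a
#' convex combination of the raw G values within its window (the focal
#' marker has weight 1; a marker exactly at distance `W` has weight 0).
#'
#' @param counts An allele-count table as returned by [genotype_pools()] or
#'   [poolseq_resample()] (columns `pos`, `n_blue_high`, `n_red_high`,
#'   `n_blue_low`, `n_red_low`), positions sorted.
#' @param window_halfwidth Kernel half-width `W` in bp. Default 50 kb.
#' @return A tibble of class `"gprime_track"` with columns `pos`, `G`,
#'   `Gprime`; attribute `window_halfwidth`.
#' @export
smooth_gprime <- function(counts, window_halfwidth = 5e4) {
  stopifnot(is.data.frame(counts), window_halfwidth > 0,
            all(c("pos", "n_blue_high", "n_red_high", "n_blue_low",
                  "n_red_low") %in% names(counts)))
  pos <- counts$pos
  stopifnot(!is.unsorted(pos))
  G <- g_statistic(counts$n_blue_high, counts$n_red_high,
                   counts$n_blue_low, counts$n_red_low)
  gp <- tricube_smooth(G, pos, window_halfwidth)
  res <- tibble::tibble(pos = pos, G = G, Gprime = gp)
  attr(res, "window_halfwidth") <- window_halfwidth
  class(res) <- c("gprime_track", class(res))
  res
}

tricube <- function(d, W) (1 - (abs(d) / W)^3)^3

# Nadaraya-Watson smoothing with a tricube kernel. Equidistant panels take
# a fast convolution path (stats::filter); irregular spacing falls back to
# an explicit sliding window.
tricube_smooth <- function(G, pos, W) {
  n <- length(G)
  if (n == 1L) return(G)
  d <- diff(pos)
  if (max(d) - min(d) < 1e-9 * max(d, 1)) {
    spacing <- d[1]
    m <- floor(W / spacing)
    if (m == 0L) return(G)
    w <- tricube(seq(-m, m) * spacing, W)
    pad <- numeric(m)
    num <- stats::filter(c(pad, G, pad), w, sides = 2)[(m + 1):(m + n)]
    den <- stats::filter(c(pad, rep(1, n), pad), w, sides = 2)[(m + 1):(m + n)]
    return(as.numeric(num / den))
  }
  vapply(seq_len(n), function(k) {
    j <- which(abs(pos - pos[k]) <= W)
    w <- tricube(pos[j] - pos[k], W)
    sum(w * G[j]) / sum(w)
  }, numeric(1))
}

#' Call significance peaks on a G' track
#'
#' The significance threshold is the 99.9th percentile (by default) of all
#' G' values along the chromosome, computed with linear interpolation; all
#' markers with `G' >= threshold` (ties count as above) are considered part
#' of the peak, which extends from the leftmost to the rightmost
#' above-threshold marker. By default (`max_gap = Inf`) this is a single
#' chromosome-wide span — occasional isolated noise markers above the
#' threshold count towards the peak length, exactly as in the
#' leftmost-to-rightmost definition. Setting a finite `max_gap` instead
#' splits above-threshold markers separated by more than `max_gap` into
#' separate peaks (e.g. `max_gap = 2 * W` to confine peaks to contiguous
#' kernel support); the peak containing the global G' maximum is then
#' flagged as the main peak. Note that a finite gap rule systematically
#' shortens noisy (e.g. Pool-seq) tracks relative to the whole-span
#' definition.
#'
#' @param track A `"gprime_track"` from [smooth_gprime()].
#' @param percentile Significance percentile of the G' distribution
#'   (default 99.9).
#' @param max_gap Largest distance between consecutive above-threshold
#'   markers kept in one peak; default `Inf` (one leftmost-to-rightmost
#'   span).
#' @return A tibble with one row per peak: `start`, `end`, `length`
#'   (`end - start`, bp), `n_markers`, `max_gprime`, `max_pos`, `is_main`;
#'   attribute `threshold`.
#' @export
call_peaks <- function(track, percentile = 99.9, max_gap = Inf) {
  stopifnot(inherits(track, "gprime_track"), nrow(track) > 0,
            percentile > 0, percentile < 100, max_gap > 0)
  thr <- stats::quantile(track$Gprime, percentile / 100, names = FALSE)
  above <- which(track$Gprime >= thr)
  if (!length(above)) {
    out <- tibble::tibble(start = numeric(), end = numeric(),
                          length = numeric(), n_markers = integer(),
                          max_gprime = numeric(), max_pos = numeric(),
                          is_main = logical())
    attr(out, "threshold") <- thr
    return(out)
  }
  pos <- track$pos[above]
  grp <- cumsum(c(1, diff(pos) > max_gap))
  peaks <- lapply(split(seq_along(above), grp), function(ii) {
    idx <- above[ii]
    k <- idx[which.max(track$Gprime[idx])]
    tibble::tibble(start = track$pos[idx[1]],
                   end = track$pos[idx[length(idx)]],
                   length = track$pos[idx[length(idx)]] - track$pos[idx[1]],
                   n_markers = length(idx),
                   max_gprime = track$Gprime[k],
                   max_pos = track$pos[k])
  })
  out <- do.call(rbind, peaks)
  out$is_main <- out$max_gprime == max(out$max_gprime)
  out <- out[order(-out$is_main, out$start), ]
  attr(out, "threshold") <- thr
  out
}

#' Main peak of a G' track
#'
#' Convenience wrapper around [call_peaks()] returning only the peak that
#' contains the global G' maximum (the mapped QTL region in a single-QTL
#' experiment).
#'
#' @inheritParams call_peaks
#' @return One-row tibble (see [call_peaks()]).
#' @export
main_peak <- function(track, percentile = 99.9, max_gap = Inf) {
  p <- call_peaks(track, percentile, max_gap)
  p[p$is_main, ][1, ]
}
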