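#' Describe a bulk segregant analysis experiment
#'
#' Collects the scalar parameters of one BSA experiment into a design object
#' used by [expected_resolution()]. The design covers the standard BSA
#' crossing scheme as well as two common modifications: introgression mapping
#' (`"im"`, alternating homozygote selection and backcrossing) and
#' heterozygote selection (`"hs"`, only QTL heterozygotes reproduce).
#'
#' For the non-standard schemes the coalescence effective size of the
#' interbreeding population is derived from `n_prime`, the effective size the
#' population would have without the selection step: `Ne = 0.4 * n_prime`
#' under introgression mapping (harmonic mean of interbreeding and selection
#' generations, where only ~1/4 of individuals survive selection) and
#' `Ne = 0.5 * n_prime` under heterozygote selection (~1/2 of individuals are
#' heterozygous at the QTL at any time). See [scheme_parameters()].
#'
#' @param r Recombination rate per bp per generation (crossovers are modelled
#'   as a Poisson process along the chromosome). 1 cM/Mb corresponds to
#'   `r = 1e-8`.
#' @param s Number of chromosomes per selected pool; the combined sample
#'   holds `2 * s` chromosomes.
#' @param t Number of generations of interbreeding; the population is
#'   sampled in generation t (counting the parental cross as generation 0,
#'   the F1 as generation 1). Must be at least 2.
#' @param ne Coalescence effective population size (diploid individuals) of
#'   the interbreeding population. Required for the standard scheme; for
#'   `"im"`/`"hs"` it is normally derived from `n_prime`, but may be given
#'   directly if already adjusted for the selection step.
#' @param scheme Crossing scheme, one of `"standard"`, `"im"`, `"hs"`.
#' @param n_prime For `"im"`/`"hs"`: effective size the interbreeding
#'   population would have without the selection step.
#' @param rho Optional breakpoint-rate schedule overriding the scheme
#'   default: numeric vector of length `t - 1` giving the per-bp, per-lineage
#'   rate at which new ancestry breakpoints arise in the gametes forming
#'   generations `2, ..., t`. Must lie in `[0, r]`.
#'
#' @return An object of class `"bsa_design"`: a list with elements `r`, `s`,
#'   `t`, `ne`, `scheme`, `n_prime`, and `rho` (named vector, names
#'   `"2", ..., "t"`).
#' @examples
#' bsa_design(r = 1e-8, s = 20, t = 10, ne = 100)
#' bsa_design(r = 1e-8, s = 20, t = 10, scheme = "hs", n_prime = 200)
#' @export
bsa_design <- function(r, s, t, ne = NULL, scheme = c("standard", "im", "hs"),
                       n_prime = NULL, rho = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (r <= 0) stop("recombination rate `r` must be positive", call. = FALSE)
  check_count(s, "s", min = 1)
  check_count(t, "t", min = 2)

  if (is.null(ne) && is.null(n_prime)) {
    stop("supply `ne` (standard scheme) or `n_prime` (im/hs schemes)",
         call. = FALSE)
  }
  if (scheme == "standard" && is.null(ne)) ne <- n_prime
  if (is.null(ne)) {
    sp <- scheme_parameters(scheme, r, n_prime, t)
    ne <- sp$ne
  }
  stopifnot(is.numeric(ne), length(ne) == 1L, is.finite(ne))
  if (ne < 1) stop("`ne` must be at least 1", call. = FALSE)

  if (is.null(rho)) {
    rho <- scheme_parameters(scheme, r, if (is.null(n_prime)) ne else n_prime,
                             t)$rho
  } else {
    if (length(rho) != t - 1L) {
      stop("`rho` must have length t - 1 (one rate per generation 2..t)",
           call. = FALSE)
    }
    if (any(rho < 0 | rho > r)) {
      stop("breakpoint rates must lie in [0, r]", call. = FALSE)
    }
    names(rho) <- as.character(2:t)
  }

  structure(list(r = r, s = as.integer(s), t = as.integer(t), ne = ne,
                 scheme = scheme, n_prime = n_prime, rho = rho),
            class = "bsa_design")
}

#' @export
print.bsa_design <- function(x, ...) {
  cat("BSA experiment design (", x$scheme, " scheme)\n", sep = "")
  cat(sprintf("  r  = %.3g per bp, s = %d chromosomes/pool, t = %d generations\n",
              x$r, x$s, x$t))
  cat(sprintf("  Ne = %.6g diploid individuals", x$ne))
  if (!is.null(x$n_prime)) cat(sprintf(" (from N' = %.6g)", x$n_prime))
  cat("\n")
  invisible(x)
}

#' Effective size and breakpoint-rate schedule for a crossing scheme
#'
#' Ancestry breakpoints (junctions between the two founder-strain ancestries)
#' are created only by crossovers in individuals that carry both ancestries at
#' the crossover position. The per-lineage, per-bp rate `rho(i)` at which the
#' gametes forming generation `i` acquire new breakpoints therefore depends on
#' the crossing scheme:
#'
#' * `standard`: every F1 individual is ancestry-heterozygous everywhere, so
#'   `rho(2) = r`; from the F2 on, a random individual is heterozygous at a
#'   given position with probability 1/2, so `rho(i > 2) = r / 2`. The
#'   effective size is `n_prime` itself.
#' * `im` (introgression mapping): near the QTL, breakpoints arise at rate
#'   `2 * (r/2) = r` in interbreeding generations and 0 in backcross
#'   generations; averaged over the experiment this is the same `r/2`
#'   schedule as standard BSA, but selection of homozygotes raises the
#'   coalescence rate, giving `Ne = 0.4 * n_prime`.
#' * `hs` (heterozygote selection): all parents are QTL heterozygotes, so
#'   near the QTL `rho(i) = r` for every generation, at the cost of
#'   `Ne = 0.5 * n_prime`.
#'
#' @inheritParams bsa_design
#' @param n_prime Effective size of the interbreeding population without the
#'   selection step (equal to `ne` for the standard scheme).
#' @return List with `ne` (scheme-adjusted effective size) and `rho`
#'   (named numeric vector over generations `2..t`).
#' @examples
#' scheme_parameters("hs", r = 1e-8, n_prime = 200, t = 5)
#' @export
scheme_parameters <- function(scheme = c("standard", "im", "hs"), r, n_prime, t) {
  scheme <- match.arg(scheme)
  stopifnot(r > 0, n_prime >= 1)
  check_count(t, "t", min = 2)
  rho <- switch(scheme,
    standard = c(r, rep(r / 2, t - 2L)),
    im       = c(r, rep(r / 2, t - 2L)),
    hs       = rep(r, t - 1L)
  )
  ne <- switch(scheme, standard = n_prime, im = 0.4 * n_prime,
               hs = 0.5 * n_prime)
  names(rho) <- as.character(2:t)
  list(ne = ne, rho = rho)
}

#' Expected number of ancestral lineages per generation
#'
#' Traces the genealogy of `2 * s` sampled chromosomes backwards through a
#' diploid Wright-Fisher population of effective size `ne`. Writing `x(i)`
#' for the expected number of distinct ancestral lineages (at one genomic
#' position) present in generation `i`, one occupancy step gives
#'
#' \deqn{E[x(i-1)] = 2 Ne \left[1 - \left(1 - \frac{1}{2 Ne}\right)^{x(i)}\right]}
#'
#' i.e. `x(i)` lineages each pick one of the `2 * Ne` parental chromosomes
#' uniformly, and `x(i-1)` is the expected number of distinct chromosomes
#' picked. The recursion starts from `x(t) = 2 * s` and is evaluated back to
#' generation 2. Values are expectations and deliberately kept real-valued.
#'
#' @inheritParams bsa_design
#' @param ne Diploid coalescence effective population size.
#' @return Named numeric vector `x` over generations `2, ..., t`
#'   (names are the generation indices), non-decreasing in the generation
#'   index, with `x[as.character(t)] == 2 * s`.
#' @examples
#' lineage_recursion(ne = 4, s = 13, t = 3)
#' @export
lineage_recursion <- function(ne, s, t) {
  stopifnot(is.numeric(ne), ne >= 1)
  check_count(s, "s", min = 1)
  check_count(t, "t", min = 2)
  x <- numeric(t - 1L)
  names(x) <- as.character(2:t)
  x[t - 1L] <- 2 * s
  if (t > 2L) {
    for (i in seq(t - 1L, 2L)) {
      x[i - 1L] <- 2 * ne * (1 - (1 - 1 / (2 * ne))^x[i])
    }
  }
  x
}

#' Deterministic approximation to the lineage count
#'
#' Closed-form approximation for the expected number of ancestral lineages
#' `x(i)` obtained by mapping the occupancy recursion (see
#' [lineage_recursion()]) to a differential equation:
#'
#' \deqn{x(i) \approx \frac{2s}{2s - (2s - 1) e^{-(t - i)/(4 Ne)}}}
#'
#' It equals `2 * s` at `i = t` and decays towards 1 as `t - i` grows.
#'
#' @inheritParams lineage_recursion
#' @param i Generation index (vectorised), `0 <= i <= t`.
#' @return Approximate lineage count(s), same length as `i`.
#' @export
lineage_approx <- function(ne, s, t, i) {
  stopifnot(ne >= 1, s >= 1, t >= 2, all(i >= 0), all(i <= t))
  2 * s / (2 * s - (2 * s - 1) * exp(-(t - i) / (4 * ne)))
}

#' Expected mapping resolution of a BSA experiment
#'
#' Computes the expected distance `E[D]` from the QTL to the nearest
#' informative ancestry breakpoint on one side, over all `2 * s` pooled
#' chromosomes. Breakpoints captured by the sample accumulate along the
#' sample's genealogy at a total per-bp rate
#'
#' \deqn{R = \sum_{i=2}^{t} \rho(i)\, E[x(i)]}
#'
#' and, modelling their positions as a Poisson process, `E[D] = 1 / R`. The
#' expected length of the mapped region is `2 * E[D]` by upstream/downstream
#' symmetry.
#'
#' Four evaluation methods are available:
#' \describe{
#'   \item{`recursion`}{The reference method: `x(i)` from the exact occupancy
#'     recursion ([lineage_recursion()]), combined with the scheme's
#'     breakpoint-rate schedule. Works for all schemes, including custom
#'     `rho` schedules.}
#'   \item{`integration`}{Closed form for the standard scheme obtained by
#'     replacing the sum with an integral over the deterministic lineage
#'     approximation: `E[D] = 1 / (2 Ne r ln(2s [e^{t/(4Ne)} - 1] + 1))`.}
#'   \item{`taylor`}{Further Taylor approximation valid when `t << 4 Ne`:
#'     `E[D] = 1 / (2 r Ne ln(s t / (2 Ne) + 1))`; depends on `s` and `t`
#'     only through their product.}
#'   \item{`infinite`}{Infinite-population limit `E[D] = 1 / (r s t)`; a
#'     lower bound on `E[D]` (upper bound on resolution) for any finite
#'     population.}
#' }
#'
#' A warning is emitted when `t >= 4 * ne`, where drift erodes ancestry
#' heterozygosity noticeably over the experiment and all methods tend to
#' overestimate the breakpoint rate; and when the total rate `R` approaches 1
#' per bp, where the Poisson thinness assumption breaks down.
#'
#' @param design A [bsa_design()] object.
#' @param method One of `"recursion"` (default), `"integration"`, `"taylor"`,
#'   `"infinite"`.
#' @return An object of class `"bsa_prediction"`: list with `R` (total per-bp
#'   breakpoint rate), `E_D` (bp), `resolution` (`2 * E_D`, bp), `method`,
#'   and the `design`.
#' @examples
#' # Wagyu cattle intramuscular-fat mapping design
#' d <- bsa_design(r = 1.23e-8, s = 13, t = 3, ne = 4)
#' expected_resolution(d)
#' @export
expected_resolution <- function(design,
                                method = c("recursion", "integration",
                                           "taylor", "infinite")) {
  stopifnot(inherits(design, "bsa_design"))
  method <- match.arg(method)
  r <- design$r; s <- design$s; t <- design$t; ne <- design$ne

  if (method != "infinite" && t >= 4 * ne) {
    warning("t >= 4*Ne: drift erodes ancestry heterozygosity over the ",
            "experiment and the predicted breakpoint rate is an overestimate",
            call. = FALSE)
  }

  R <- switch(method,
    infinite = r * s * t,
    recursion = {
      x <- lineage_recursion(ne, s, t)
      sum(design$rho * x)
    },
    integration = {
      if (design$scheme != "standard" ||
          !isTRUE(all.equal(unname(design$rho),
                            c(r, rep(r / 2, t - 2L))))) {
        stop("the integration closed form is derived for the standard ",
             "scheme's uniform r/2 breakpoint rate; use method = \"recursion\"",
             call. = FALSE)
      }
      2 * ne * r * log(2 * s * (exp(t / (4 * ne)) - 1) + 1)
    },
    taylor = 2 * r * ne * log(s * t / (2 * ne) + 1)
  )

  if (R > 0.1) {
    warning("total breakpoint rate R = ", signif(R, 3),
            " per bp is not small; the Poisson approximation (R << 1) is ",
            "unreliable", call. = FALSE)
  }

  structure(list(R = R, E_D = 1 / R, resolution = 2 / R, method = method,
                 design = design),
            class = "bsa_prediction")
}

#' @export
print.bsa_prediction <- function(x, ...) {
  cat("Expected BSA mapping resolution (", x$method, " method)\n", sep = "")
  cat(sprintf("  breakpoint rate R = %.4g per bp\n", x$R))
  cat(sprintf("  E[D]   = %.4g bp (%.3g Mb)\n", x$E_D, x$E_D / 1e6))
  cat(sprintf("  2 E[D] = %.4g bp (%.3g Mb)  [expected mapped-region length]\n",
              x$resolution, x$resolution / 1e6))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(TRUE)
}
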