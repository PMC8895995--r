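test_that("infinite-population prediction is 1/(r s t) with the expected scaling", {
  p <- expected_resolution(bsa_design(1e-8, 20, 10, ne = 1e9), "infinite")
  expect_equal(p$E_D, 5e5)
  expect_equal(p$resolution, 1e6)

  p2 <- expected_resolution(bsa_design(1e-8, 200, 6, ne = 1e9), "infinite")
  expect_equal(p2$E_D, 1 / (1e-8 * 1200))

  # doubling s halves E[D]; E[D] exactly inversely proportional to r
  for (m in c("infinite", "recursion", "integration", "taylor")) {
    a <- expected_resolution(bsa_design(1e-8, 16, 8, ne = 500), m)$E_D
    b <- expected_resolution(bsa_design(2e-8, 16, 8, ne = 500), m)$E_D
    expect_equal(a / b, 2)
  }
  a <- expected_resolution(bsa_design(1e-8, 16, 8, ne = 1e9), "infinite")$E_D
  b <- expected_resolution(bsa_design(1e-8, 32, 8, ne = 1e9), "infinite")$E_D
  expect_equal(a / b, 2)
})

test_that("lineage recursion starts at 2s, stays in [1, 2s], non-decreasing in i", {
  for (prm in list(c(5, 4, 6), c(100, 20, 10), c(1000, 200, 6),
                   c(2, 8, 12))) {
    x <- lineage_recursion(prm[1], prm[2], prm[3])
    expect_equal(unname(x[length(x)]), 2 * prm[2])
    expect_true(all(x >= 1 & x <= 2 * prm[2]))
    expect_true(all(diff(x) >= 0))  # fewer lineages further in the past
  }
  # effectively infinite population: no coalescence, x(i) ~ 2s throughout
  x <- lineage_recursion(1e9, 20, 10)
  expect_equal(unname(x), rep(40, 9), tolerance = 1e-6)
})

test_that("one recursion step matches the Monte-Carlo occupancy oracle", {
  set.seed(11)
  for (prm in list(c(4, 26), c(20, 40), c(50, 64))) {
    ne <- prm[1]; balls <- prm[2]
    occ <- mc_occupancy(balls, 2 * ne, reps = 3e4)
    predicted <- 2 * ne * (1 - (1 - 1 / (2 * ne))^balls)
    se <- stats::sd(occ) / sqrt(length(occ))
    expect_lt(abs(mean(occ) - predicted), 3 * se)
  }
  # t = 3 means a single occupancy step from x(3) = 2s
  x <- lineage_recursion(4, 13, 3)
  expect_equal(unname(x["2"]), 8 * (1 - (7 / 8)^26))
})

test_that("deterministic lineage approximation has the right endpoints", {
  expect_equal(lineage_approx(100, 20, 10, i = 10), 40)
  expect_equal(lineage_approx(3, 32, 5000, i = 0), 1, tolerance = 1e-6)
  # close to the recursion in a moderate-coalescence regime
  x2 <- unname(lineage_recursion(100, 20, 10)["2"])
  expect_equal(lineage_approx(100, 20, 10, i = 2), x2, tolerance = 0.05)
})

test_that("scheme parameters follow the crossing designs", {
  sp <- scheme_parameters("standard", r = 1e-8, n_prime = 100, t = 10)
  expect_equal(sp$ne, 100)
  expect_equal(unname(sp$rho), c(1e-8, rep(0.5e-8, 8)))

  sp <- scheme_parameters("hs", r = 1e-8, n_prime = 200, t = 10)
  expect_equal(sp$ne, 100)
  expect_equal(unname(sp$rho), rep(1e-8, 9))

  sp <- scheme_parameters("im", r = 1e-8, n_prime = 100, t = 10)
  expect_equal(sp$ne, 40)
  expect_equal(unname(sp$rho), c(1e-8, rep(0.5e-8, 8)))

  d <- bsa_design(1e-8, 20, 10, scheme = "hs", n_prime = 200)
  expect_equal(d$ne, 100)
})

test_that("recursion converges to the infinite model and bounds it", {
  # with no coalescence, R = r*2s + (r/2)*2s*(t-2) = r*s*t
  p <- expected_resolution(bsa_design(1e-8, 20, 10, ne = 1e9), "recursion")
  expect_equal(p$E_D, 5e5, tolerance = 1e-6)
  # finite populations never improve resolution
  for (ne in c(5, 50, 500)) {
    for (s in c(4, 64)) {
      rec <- expected_resolution(bsa_design(1e-8, s, 10, ne), "recursion")$E_D
      expect_gte(rec, 5e5 * 20 / s * (1 - 1e-9))
      expect_gte(rec, expected_resolution(bsa_design(1e-8, s, 10, ne),
                                          "infinite")$E_D * (1 - 1e-12))
    }
  }
})

test_that("integration closed form agrees with numerical quadrature of the lineage ODE", {
  for (prm in list(c(100, 20, 10), c(1000, 200, 6), c(50, 8, 15))) {
    ne <- prm[1]; s <- prm[2]; t <- prm[3]
    r <- 1e-8
    quad <- stats::integrate(function(y) lineage_approx(ne, s, t, y),
                             0, t, rel.tol = 1e-10)$value
    oracle_E_D <- 1 / (r / 2 * quad)
    p <- expected_resolution(bsa_design(r, s, t, ne), "integration")
    expect_equal(p$E_D, oracle_E_D, tolerance = 1e-6)
  }
  # frozen spot value from the quadrature oracle
  p <- expected_resolution(bsa_design(1e-8, 20, 10, 100), "integration")
  expect_equal(p$E_D, 714868, tolerance = 1e-4)
  # the closed form assumes the standard scheme's uniform r/2 rate
  expect_error(expected_resolution(
    bsa_design(1e-8, 20, 10, scheme = "hs", n_prime = 200), "integration"),
    "standard")
})

test_that("Taylor form depends on s and t only through their product", {
  a <- expected_resolution(bsa_design(1e-8, 40, 5, ne = 1000), "taylor")$E_D
  b <- expected_resolution(bsa_design(1e-8, 20, 10, ne = 1000), "taylor")$E_D
  expect_equal(a, b)
  # st << 2Ne collapses to the infinite model
  c1 <- expected_resolution(bsa_design(1e-8, 2, 2, ne = 1e6), "taylor")$E_D
  expect_equal(c1, 1 / (1e-8 * 4), tolerance = 1e-3)
})

test_that("all four methods agree when st << 2Ne", {
  for (prm in list(c(2, 2, 1000), c(10, 5, 5000), c(20, 10, 2e4))) {
    s <- prm[1]; t <- prm[2]; ne <- prm[3]
    stopifnot(s * t / (2 * ne) <= 0.01)
    d <- bsa_design(1e-8, s, t, ne)
    vals <- vapply(c("infinite", "recursion", "integration", "taylor"),
                   function(m) expected_resolution(d, m)$E_D, numeric(1))
    expect_lt(diff(range(vals)) / min(vals), 0.02)
  }
})

test_that("invalid designs and regimes are rejected or flagged", {
  expect_error(bsa_design(-1e-8, 20, 10, 100), "positive")
  expect_error(bsa_design(1e-8, 0, 10, 100), "integer")
  expect_error(bsa_design(1e-8, 20, 1, 100), "integer")
  expect_error(bsa_design(1e-8, 20, 10), "supply")
  expect_error(bsa_design(1e-8, 20, 10, 100, rho = rep(1e-8, 3)), "length")
  expect_error(bsa_design(1e-8, 20, 10, 100, rho = rep(2e-8, 9)), "\\[0, r\\]")
  # strong drift: heterozygosity decays, prediction flagged
  expect_warning(expected_resolution(bsa_design(1e-8, 10, 20, ne = 4)),
                 "drift")
  # custom schedule is accepted and used
  d <- bsa_design(1e-8, 20, 10, ne = 1e9, rho = rep(1e-8, 9))
  p <- expected_resolution(d, "recursion")
  expect_equal(p$E_D, 1 / (1e-8 * 40 * 9), tolerance = 1e-6)
})
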