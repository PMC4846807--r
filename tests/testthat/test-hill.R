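test_that("observed Hill numbers match closed forms", {
  expect_equal(unname(hill_number(c(10, 10, 10, 10))), c(4, 4, 4))
  expect_equal(unname(hill_number(c(9, 1), q = 2)), 1 / 0.82, tolerance = 1e-9)
  expect_error(hill_number(c(0, 0)))
  expect_error(hill_number(c(2, 1), q = 3))
})

test_that("Hill numbers are nonincreasing in q at any standardized size", {
  set.seed(11)
  for (i in 1:5) {
    x <- as.numeric(rmultinom(1, 300, exp(rnorm(20))))
    x <- x[x > 0]
    n <- sum(x)
    for (m in c(5, 50, round(n / 2), n, round(1.5 * n), 2 * n)) {
      est <- if (m <= n) rarefy_hill(x, m = m)$estimate
             else extrapolate_hill(x, m = m)$estimate
      expect_true(all(diff(est) <= 1e-8),
                  label = paste("monotone in q at m =", m))
    }
  }
})

test_that("rarefied richness equals exhaustive subsample enumeration", {
  # toy community [4, 2, 1]: all C(7, 3) subsamples
  x <- c(4, 2, 1)
  expect_equal(rarefy_hill(x, q = 0, m = 3)$estimate, oracle_rarefy_q0(x, 3),
               tolerance = 1e-12)
  x2 <- c(5, 3, 2, 1)
  for (m in c(2, 4, 6)) {
    expect_equal(rarefy_hill(x2, q = 0, m = m)$estimate,
                 oracle_rarefy_q0(x2, m), tolerance = 1e-12)
  }
})

test_that("curves hit the trivial endpoints", {
  x <- c(12, 6, 3, 1)
  n <- sum(x)
  expect_equal(rarefy_hill(x, m = 1)$estimate, rep(1, 3))
  expect_equal(rarefy_hill(x, m = n)$estimate, unname(hill_number(x)),
               tolerance = 1e-9)
  expect_error(rarefy_hill(x, m = n + 1))
  expect_error(extrapolate_hill(x, m = n))
})

test_that("rarefaction and coverage are nondecreasing in sample size", {
  set.seed(12)
  x <- as.numeric(rmultinom(1, 400, exp(1.2 * rnorm(25))))
  x <- x[x > 0]
  n <- sum(x)
  grid <- sort(unique(c(1:10, seq(20, 2 * n, by = 37), n, 2 * n)))
  for (qq in 0:2) {
    est <- c(rarefy_hill(x, qq, grid[grid <= n])$estimate,
             extrapolate_hill(x, qq, grid[grid > n])$estimate)
    expect_true(all(diff(est) >= -1e-8), label = paste("q =", qq))
  }
  cov <- coverage_estimate(x, grid)
  expect_true(all(diff(cov) >= -1e-8))
  expect_true(all(cov >= 0 & cov <= 1))
})

test_that("interpolated and extrapolated segments agree at the reference", {
  set.seed(13)
  x <- as.numeric(rmultinom(1, 500, exp(rnorm(30))))
  x <- x[x > 0]
  n <- sum(x)
  obs <- unname(hill_number(x))
  inner <- rarefy_hill(x, m = n)$estimate
  expect_equal(inner, obs, tolerance = 1e-9)
  # stepping one individual beyond the reference moves the estimate by less
  # than one part in 1e4 of the local curve increment scale
  outer1 <- extrapolate_hill(x, m = n + 1)$estimate
  expect_equal(outer1, obs, tolerance = 1e-3)
  expect_true(all(outer1 >= obs - 1e-8))
})

test_that("communities without singletons show complete coverage", {
  x <- c(10, 8, 5, 3, 2)  # f1 = 0
  n <- sum(x)
  expect_equal(coverage_estimate(x, n), 1)
  # no unseen-species signal: extrapolated richness stays at S_obs
  ext <- extrapolate_hill(x, q = 0, m = c(n + 5, 2 * n))
  expect_equal(ext$estimate, c(5, 5))
})

test_that("an all-singleton sample has zero estimated coverage", {
  x <- rep(1, 10)
  expect_equal(coverage_estimate(x, 10), 0)
})

test_that("interpolated coverage matches the exhaustive Good-Turing oracle", {
  x <- c(5, 4, 2, 1)  # 12 individuals
  for (m in c(4, 6)) {
    expect_equal(coverage_estimate(x, m), oracle_coverage(x, m),
                 tolerance = 1e-10)
  }
  expect_error(coverage_estimate(x, 30), "twice")
})

test_that("incidence-based estimators honour their endpoints", {
  sv <- small_survey(seed = 21)
  stems_b <- dplyr::filter(sv$stems, belt == "birch")
  inc <- incidence_table(stems_b, "plot")
  Tn <- attr(inc, "T")
  obs <- unname(hill_number(inc$Y_i))
  est_ref <- rarefy_hill(inc$Y_i, m = Tn, basis = "incidence", n_units = Tn)
  expect_equal(est_ref$estimate, obs, tolerance = 1e-9)
  est1 <- rarefy_hill(inc$Y_i, m = 1, basis = "incidence", n_units = Tn)
  # one sampling unit: expected species per unit, identical across q = 0 and
  # within a whisker for q = 1, 2
  expect_true(all(est1$estimate > 1))
  ext <- extrapolate_hill(inc$Y_i, m = 2 * Tn, basis = "incidence",
                          n_units = Tn)
  expect_true(all(ext$estimate >= obs - 1e-8))
  # monotone in t for all q
  grid <- c(2, 5, 10, 20, 25, 30, 40, 50)
  for (qq in 0:2) {
    est <- c(rarefy_hill(inc$Y_i, qq, grid[grid <= Tn], "incidence", Tn)$estimate,
             extrapolate_hill(inc$Y_i, qq, grid[grid > Tn], "incidence", Tn)$estimate)
    expect_true(all(diff(est) >= -1e-6), label = paste("incidence q =", qq))
  }
})

test_that("the doubling rule sets the comparison endpoint", {
  expect_equal(extrapolation_limit(120, 100), 200)
  expect_equal(extrapolation_limit(100), 200)
  expect_error(extrapolation_limit())
})

test_that("bootstrap bands are reproducible under a fixed seed", {
  x <- c(40, 25, 12, 6, 3, 2, 1, 1)
  a <- hill_curve(x, reps = 2, knots = 8, seed = 99)
  b <- hill_curve(x, reps = 2, knots = 8, seed = 99)
  expect_equal(a, b)
  expect_true(all(a$ci_low <= a$estimate + 1e-9))
  expect_true(all(a$ci_high >= a$estimate - 1e-9))

  # a one-species community cannot vary in richness
  mono <- hill_curve(30, q = 0, reps = 10, knots = 5, seed = 1)
  expect_equal(mono$ci_high - mono$ci_low, rep(0, nrow(mono)))
})

test_that("curve output is tidy and flags interpolation vs extrapolation", {
  x <- c(20, 10, 5, 1)
  hc <- hill_curve(x, reps = 0, knots = 10)
  expect_s3_class(hc, "hill_curve")
  expect_named(hc, c("basis", "q", "m", "coverage", "estimate",
                     "ci_low", "ci_high", "kind"))
  n <- sum(x)
  expect_equal(unique(hc$kind[hc$m < n]), "interpolated")
  expect_equal(unique(hc$kind[hc$m == n]), "observed")
  expect_equal(unique(hc$kind[hc$m > n]), "extrapolated")
  expect_s3_class(autoplot(hc), "ggplot")
})
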