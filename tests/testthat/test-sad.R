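test_that("broken-stick expectations telescope to N", {
  expect_equal(expected_broken_stick(30, 3),
               c(10 * (1 + 1/2 + 1/3), 10 * (1/2 + 1/3), 10 / 3),
               tolerance = 1e-12)
  expect_equal(expected_broken_stick(7, 1), 7)
  for (S in c(2, 17, 40)) {
    N <- S * 11
    expect_equal(sum(expected_broken_stick(N, S)), N, tolerance = 1e-9)
  }
})

test_that("niche-preemption expectations decay geometrically", {
  expect_equal(expected_preemption(100, 3, 0.5), c(50, 25, 12.5))
  a <- expected_preemption(1000, 20, 0.23)
  expect_true(all(diff(a) < 0))
  # closed-form partial sum
  for (alpha in c(0.1, 0.5, 0.9)) {
    S <- 12; N <- 500
    expect_equal(sum(expected_preemption(N, S, alpha)),
                 N * (1 - (1 - alpha)^S), tolerance = 1e-9)
  }
  expect_error(expected_preemption(10, 3, 1.2))
})

test_that("log-normal expectations follow the quantile construction", {
  # sigma -> 1: degenerate at mu
  expect_equal(expected_lognormal(5, 10, 1 + 1e-12), rep(10, 5),
               tolerance = 1e-6)
  # odd S: median rank sits exactly at mu
  expect_equal(expected_lognormal(5, 10, exp(1))[3], 10)
  # hand-computed quantile evaluation, S = 5, mu = 10, log sigma = 1
  pos <- (5 - 1:5 + 0.5) / 5
  expect_equal(expected_lognormal(5, 10, exp(1)), exp(log(10) + qnorm(pos)))
})

test_that("Zipf and Zipf-Mandelbrot obey the reduction identity", {
  expect_equal(expected_zipf(100, 3, 0.5, -1), c(50, 25, 50 / 3))
  expect_equal(expected_zm(100, 8, 0.5, 0, -1.3),
               expected_zipf(100, 8, 0.5, -1.3))
  expect_error(expected_zipf(100, 3, 0.5, 0.2))
  expect_error(expected_zm(100, 3, 0.5, -1.5, -1))
})

test_that("the neutral spectrum is nonnegative and conserves individuals", {
  phi <- neutral_phi(c(1, 2, 5, 10, 100, 500, 1000), 50, 0.1, 1000)
  expect_true(all(phi >= 0))
  # sum_n n phi_n = J
  J <- 200
  phi_all <- neutral_phi(1:J, 20, 0.3, J)
  expect_equal(sum((1:J) * phi_all) / J, 1, tolerance = 0.01)
})

test_that("the neutral spectrum approaches the Ewens expectation as m -> 1", {
  J <- 100; theta <- 10
  n <- c(1, 2, 5, 10, 30)
  phi <- neutral_phi(n, theta, 0.999, J)
  expect_equal(phi, oracle_ewens_phi(n, theta, J), tolerance = 0.06)
})

test_that("adaptive quadrature agrees with fine-grid trapezoid integration", {
  for (nn in c(1, 3, 10, 25)) {
    expect_equal(neutral_phi(nn, 8, 0.25, 50),
                 oracle_neutral_phi_trapz(nn, 8, 0.25, 50),
                 tolerance = 1e-4) # 4 significant digits
  }
})

test_that("the K-S statistic vanishes only for identical distributions", {
  expect_equal(forestdiv:::.ks_sad(c(5, 3, 1), c(5, 3, 1))$stat, 0)
  expect_gt(forestdiv:::.ks_sad(c(5, 3, 1), c(6, 2, 1))$stat, 0)
})

test_that("every fit satisfies the AIC identity exactly", {
  set.seed(31)
  x <- as.numeric(rmultinom(1, 800, expected_broken_stick(800, 15) / 800))
  cmp <- compare_sad_models(x)
  ok <- dplyr::filter(cmp, converged)
  expect_equal(ok$AIC, -2 * ok$logL + 2 * ok$k, tolerance = 1e-12)
  expect_true(all(ok$ks_stat >= 0 & ok$ks_stat <= 1))
  # -2 * (-10) + 2 * 2 = 24 shape of the identity
  expect_equal(-2 * (-10) + 2 * 2, 24)
})

test_that("model comparison always reports all six models", {
  set.seed(32)
  x <- as.numeric(rmultinom(1, 600, exp(1.4 * rnorm(25))))
  x <- x[x > 0]
  cmp <- compare_sad_models(x)
  expect_equal(nrow(cmp), 6)
  expect_setequal(cmp$model, c("broken-stick", "preemption", "lognormal",
                               "zipf", "zipf-mandelbrot", "neutral"))
  fin <- is.finite(cmp$AIC) & cmp$converged
  expect_true(all(diff(cmp$AIC[fin]) >= 0)) # sorted ascending
  # failures, if any, are last and carry a reason
  if (any(!fin)) {
    expect_true(all(which(!fin) > max(which(fin))))
  }
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("parametric fits agree with an independent rank-abundance fitter", {
  set.seed(36)
  x <- as.numeric(rmultinom(1, 900, exp(1.3 * rnorm(30))))
  x <- sort(x[x > 0], decreasing = TRUE)

  f_ln <- fit_sad(x, "lognormal")
  v_ln <- vegan::rad.lognormal(x)
  expect_equal(f_ln$expected, unname(fitted(v_ln)), tolerance = 1e-6)
  expect_equal(f_ln$AIC, unname(AIC(v_ln)), tolerance = 1e-6)

  f_pre <- fit_sad(x, "preemption")
  v_pre <- vegan::rad.preempt(x)
  expect_equal(f_pre$params$alpha, unname(coef(v_pre)), tolerance = 1e-4)
  expect_equal(f_pre$AIC, unname(AIC(v_pre)), tolerance = 1e-4)

  f_z <- fit_sad(x, "zipf", free_p1 = TRUE)  # vegan's parameterisation
  v_z <- vegan::rad.zipf(x)
  expect_equal(f_z$params$gamma, unname(coef(v_z)[2]), tolerance = 1e-5)
  expect_equal(f_z$AIC, unname(AIC(v_z)), tolerance = 1e-5)

  # the 3-parameter Zipf-Mandelbrot profile is nonconvex, so the two
  # optimisers may land on different local optima; ours must do at least
  # as well as the reference fitter
  f_zm <- fit_sad(x, "zipf-mandelbrot")
  v_zm <- vegan::rad.zipfbrot(x)
  expect_lte(f_zm$AIC, unname(AIC(v_zm)) + 1e-3)
})

test_that("the Zipf exponent is recovered from Zipf-generated data", {
  set.seed(33)
  gammas <- replicate(5, {
    x <- gen_community(50, 20000, "zipf", list(gamma = -1.2))
    f <- fit_sad(x[x > 0], "zipf")
    f$params$gamma
  })
  expect_equal(mean(gammas), -1.2, tolerance = 0.1)
})

test_that("a dominant-plus-singletons community favours geometric decay over broken-stick", {
  x <- c(400, rep(1, 12))
  cmp <- compare_sad_models(x, models = c("broken-stick", "preemption", "zipf"))
  expect_true(cmp$model[1] != "broken-stick")
  aic <- setNames(cmp$AIC, cmp$model)
  expect_lt(min(aic[c("preemption", "zipf")]), aic[["broken-stick"]])
})

test_that("fitted objects expose tidy and glance methods", {
  set.seed(34)
  x <- as.numeric(rmultinom(1, 500, expected_preemption(1, 12, 0.4)
                            / sum(expected_preemption(1, 12, 0.4))))
  f <- fit_sad(x[x > 0], "preemption")
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "alpha")
  expect_equal(td$estimate, f$params$alpha)
  gl <- glance(f)
  expect_named(gl, c("model", "k", "logL", "AIC", "ks_stat", "ks_p",
                     "converged"))
  expect_equal(gl$k, 1)
  expect_output(print(f), "preemption")
})
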