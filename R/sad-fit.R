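# Maximum-likelihood fitting of the six SAD models to ranked abundances.
# All models share one objective -- the Poisson likelihood of the observed
# abundance of each rank given the model's expected abundance -- so their
# log-likelihoods and AICs are directly comparable.

.sad_models <- c("broken-stick", "preemption", "lognormal", "zipf",
                 "zipf-mandelbrot", "neutral")

.ranked <- function(x) {
  if (is.data.frame(x)) x <- x$n_i
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0) abort("Need positive abundances")
  a <- sort(as.numeric(x), decreasing = TRUE)
  list(a = a, N = sum(a), S = length(a), r = seq_along(a))
}

.pois_ll <- function(a, lambda) {
  lambda <- pmax(lambda, 1e-12)
  sum(dpois(round(a), lambda, log = TRUE))
}

.ks_sad <- function(a_obs, a_exp) {
  ks <- suppressWarnings(ks.test(a_obs, a_exp, exact = FALSE))
  list(stat = unname(ks$statistic), p = unname(ks$p.value))
}

.fit_result <- function(model, params, k, a_obs, a_exp, converged = TRUE,
                        message = NA_character_) {
  ll <- .pois_ll(a_obs, a_exp)
  ks <- .ks_sad(a_obs, a_exp)
  structure(
    list(
      model = model, params = params, k = k,
      logL = ll, AIC = -2 * ll + 2 * k,
      ks_stat = ks$stat, ks_p = ks$p,
      observed = a_obs, expected = a_exp,
      converged = converged, message = message
    ),
    class = "sad_fit"
  )
}

.fit_failure <- function(model, k, a_obs, message) {
  structure(
    list(
      model = model, params = list(), k = k,
      logL = NA_real_, AIC = NA_real_,
      ks_stat = NA_real_, ks_p = NA_real_,
      observed = a_obs, expected = rep(NA_real_, length(a_obs)),
      converged = FALSE, message = message
    ),
    class = "sad_fit"
  )
}

.fit_preemption <- function(rk) {
  nll <- function(alpha) -.pois_ll(rk$a, expected_preemption(rk$N, rk$S, alpha))
  opt <- optimize(nll, interval = c(1e-6, 1 - 1e-6), tol = 1e-8)
  .fit_result("preemption", list(alpha = opt$minimum), 1,
              rk$a, expected_preemption(rk$N, rk$S, opt$minimum))
}

.fit_lognormal <- function(rk) {
  phi <- qnorm((rk$S - rk$r + 0.5) / rk$S)
  fit <- suppressWarnings(glm(rk$a ~ phi, family = poisson(link = "log")))
  b <- coef(fit)
  params <- list(mu = exp(b[[1]]), sigma = exp(b[[2]]))
  .fit_result("lognormal", params, 2, rk$a,
              exp(b[[1]] + b[[2]] * phi), converged = fit$converged)
}

.fit_zipf <- function(rk, free_p1 = FALSE) {
  lr <- log(rk$r)
  if (free_p1) {
    fit <- suppressWarnings(glm(rk$a ~ lr, family = poisson(link = "log")))
    b <- coef(fit)
    p1 <- exp(b[[1]]) / rk$N; gam <- b[[2]]
    lam <- exp(b[[1]] + gam * lr)
    k <- 2
  } else {
    p1 <- rk$a[1] / rk$N
    off <- rep(log(rk$N * p1), rk$S)
    fit <- suppressWarnings(glm(rk$a ~ 0 + lr, family = poisson(link = "log"),
                                offset = off))
    gam <- coef(fit)[[1]]
    lam <- exp(off + gam * lr)
    k <- 1
  }
  .fit_result("zipf", list(p1 = p1, gamma = gam), k, rk$a, lam,
              converged = fit$converged && gam < 0)
}

.fit_zm <- function(rk) {
  profile_dev <- function(beta) {
    lrb <- log(rk$r + beta)
    fit <- tryCatch(
      suppressWarnings(glm(rk$a ~ lrb, family = poisson(link = "log"))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(list(dev = Inf, fit = NULL))
    list(dev = fit$deviance, fit = fit)
  }
  grid <- c(seq(-0.9, -0.1, by = 0.2), 0, 10^seq(-2, 2.5, length.out = 12))
  devs <- vapply(grid, function(b) profile_dev(b)$dev, numeric(1))
  if (all(!is.finite(devs))) {
    return(.fit_failure("zipf-mandelbrot", 3, rk$a, "profile fit failed at all offsets"))
  }
  i <- which.min(devs)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- tryCatch(
    optimize(function(b) profile_dev(b)$dev, interval = c(lo, hi), tol = 1e-6),
    error = function(e) NULL
  )
  beta <- if (is.null(opt) || !is.finite(opt$objective)) grid[i] else opt$minimum
  pf <- profile_dev(beta)
  if (is.null(pf$fit)) {
    return(.fit_failure("zipf-mandelbrot", 3, rk$a, "profile refit failed"))
  }
  b <- coef(pf$fit)
  c_par <- exp(b[[1]]) / rk$N; gam <- b[[2]]
  lam <- exp(b[[1]] + gam * log(rk$r + beta))
  if (!is.finite(.pois_ll(rk$a, lam)) || gam >= 0) {
    return(.fit_failure("zipf-mandelbrot", 3, rk$a,
                        "no admissible decreasing fit (gamma >= 0)"))
  }
  .fit_result("zipf-mandelbrot", list(c = c_par, beta = beta, gamma = gam), 3,
              rk$a, lam)
}

.fit_neutral <- function(rk) {
  J <- rk$N
  nll <- function(theta, m) {
    a_exp <- tryCatch(.neutral_expected_ranks(rk$S, theta, m, J),
                      error = function(e) NULL)
    if (is.null(a_exp)) return(Inf)
    -.pois_ll(rk$a, a_exp)
  }
  theta_grid <- exp(seq(log(max(rk$S / 8, 1)), log(rk$S * 3), length.out = 5))
  best <- list(val = Inf, theta = NA, m = NA)
  for (th in theta_grid) {
    opt <- tryCatch(
      optimize(function(m) nll(th, m), interval = c(0.02, 0.98), tol = 1e-3),
      error = function(e) NULL
    )
    if (!is.null(opt) && opt$objective < best$val) {
      best <- list(val = opt$objective, theta = th, m = opt$minimum)
    }
  }
  if (!is.finite(best$val)) {
    return(.fit_failure("neutral", 2, rk$a, "grid search failed"))
  }
  refine <- tryCatch(
    optim(
      c(log(best$theta), qlogis_safe(best$m)),
      function(par) nll(exp(par[1]), plogis_safe(par[2])),
      method = "Nelder-Mead",
      control = list(maxit = 120, reltol = 1e-8)
    ),
    error = function(e) NULL
  )
  if (!is.null(refine) && is.finite(refine$value) && refine$value <= best$val) {
    theta <- exp(refine$par[1]); m <- plogis_safe(refine$par[2])
  } else {
    theta <- best$theta; m <- best$m
  }
  a_exp <- .neutral_expected_ranks(rk$S, theta, m, J)
  .fit_result("neutral", list(theta = theta, m = m, J = J), 2, rk$a, a_exp)
}

qlogis_safe <- function(p) log(p / (1 - p))
plogis_safe <- function(x) {
  p <- 1 / (1 + exp(-x))
  pmin(pmax(p, 1e-4), 1 - 1e-4)
}

#' Fit one species-abundance-distribution model
#'
#' Fits a rank-abundance model by maximising the Poisson likelihood of the
#' observed abundance at each rank given the model's expected abundance, and
#' evaluates the agreement with a two-sample Kolmogorov-Smirnov statistic on
#' the observed vs expected abundance values (asymptotic p-value; abundances
#' are discrete and tied, so treat the p-value as approximate).
#' `AIC = -2 logL + 2k` with `k` free parameters: broken-stick 0, preemption
#' 1, Zipf 1 (`p1` tied to the observed rank-1 proportion; 2 with
#' `free_p1 = TRUE`), log-normal 2, neutral 2, Zipf-Mandelbrot 3.  The
#' neutral model is fitted over `(theta, m)` by a nested 1-D search on a log
#' grid followed by Nelder-Mead refinement, with `J` fixed at the total count.
#'
#' @param x Abundance vector or a tibble with a `n_i` column
#'   (e.g. [pooled_abundance()]).
#' @param model One of `"broken-stick"`, `"preemption"`, `"lognormal"`,
#'   `"zipf"`, `"zipf-mandelbrot"`, `"neutral"`.
#' @param free_p1 For the Zipf model, estimate `p1` freely (`k = 2`).
#' @return An object of class `"sad_fit"`; see [tidy()] and [glance()]
#'   methods.  Non-convergence yields a flagged result (`converged = FALSE`,
#'   `AIC = NA`), not an error.
#' @export
fit_sad <- function(x, model = .sad_models, free_p1 = FALSE) {
  model <- arg_match(model, .sad_models)
  rk <- .ranked(x)
  if (model != "broken-stick" && rk$S < 3) {
    abort("Parametric SAD models need at least 3 species")
  }
  switch(model,
    "broken-stick" = .fit_result("broken-stick", list(), 0, rk$a,
                                 expected_broken_stick(rk$N, rk$S)),
    "preemption" = .fit_preemption(rk),
    "lognormal" = .fit_lognormal(rk),
    "zipf" = .fit_zipf(rk, free_p1),
    "zipf-mandelbrot" = .fit_zm(rk),
    "neutral" = .fit_neutral(rk)
  )
}

#' @export
print.sad_fit <- function(x, ...) {
  cat("SAD fit:", x$model, "\n")
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params),
                           signif(unlist(x$params), 4),
                           sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  logL = %.3f  AIC = %.3f  K-S = %.4f (p = %.3g)%s\n",
              x$logL, x$AIC, x$ks_stat, x$ks_p,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @export
tidy.sad_fit <- function(x, ...) {
  if (length(x$params) == 0) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$params), estimate = unname(unlist(x$params)))
}

#' @export
glance.sad_fit <- function(x, ...) {
  tibble(
    model = x$model, k = x$k, logL = x$logL, AIC = x$AIC,
    ks_stat = x$ks_stat, ks_p = x$ks_p, converged = x$converged
  )
}

#' Fit and rank all six SAD models
#'
#' Attempts all six models on the same ranked abundances and returns their
#' fit summaries sorted by increasing AIC; fits that failed (flagged
#' non-convergent with `NA` AIC) are listed last with their reason.
#'
#' @inheritParams fit_sad
#' @param models Models to attempt (default all six).
#' @return A tibble of class `"sad_comparison"` (one row per model, columns
#'   as [glance.sad_fit()] plus `message`); the full `sad_fit` objects are in
#'   `attr(, "fits")`.
#' @export
compare_sad_models <- function(x, models = .sad_models, free_p1 = FALSE) {
  fits <- lapply(models, function(mod) {
    tryCatch(fit_sad(x, mod, free_p1 = free_p1),
             error = function(e) .fit_failure(mod, NA_integer_, .ranked(x)$a,
                                              conditionMessage(e)))
  })
  names(fits) <- models
  out <- purrr::map_dfr(fits, glance) %>%
    mutate(message = purrr::map_chr(fits, "message")) %>%
    arrange(!is.finite(AIC) | !converged, AIC)
  attr(out, "fits") <- fits
  class(out) <- c("sad_comparison", class(out))
  out
}

#' @export
autoplot.sad_comparison <- function(object, ...) {
  fits <- attr(object, "fits")
  obs <- tibble(rank = seq_along(fits[[1]]$observed),
                abundance = fits[[1]]$observed)
  exp_df <- purrr::map_dfr(fits, function(f) {
    if (!f$converged && all(is.na(f$expected))) return(NULL)
    tibble(model = f$model, rank = seq_along(f$expected),
           expected = f$expected)
  })
  ggplot2::ggplot(obs, ggplot2::aes(rank, abundance)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::geom_line(data = exp_df,
                       ggplot2::aes(rank, expected, colour = model)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Species rank", y = "Abundance",
                  colour = "SAD model") +
    ggplot2::theme_minimal()
}
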