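# Hill-number rarefaction / extrapolation for abundance and incidence data.
#
# Interpolation uses exact hypergeometric expectations (q = 0, 1) and the
# minimum-variance unbiased Simpson form (q = 2, valid at any size).
# Extrapolation anchors q = 0 on the Chao1/Chao2 asymptotic richness
# estimator and q = 1 on a sample-size-weighted blend of the observed and
# asymptotic entropy, continuous at the reference sample.

.check_counts <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0 || all(x == 0)) abort("Need at least one positive count")
  if (any(x < 0)) abort("Counts must be nonnegative")
  x[x > 0]
}

#' Observed Hill numbers of a pooled abundance vector
#'
#' Effective numbers of species: `q = 0` species richness, `q = 1` the
#' exponential of Shannon entropy, `q = 2` inverse Simpson concentration,
#' computed on relative abundances `p_i = n_i / N`.
#'
#' @param x Vector of species abundances (or incidence frequencies).
#' @param q Diversity orders, any subset of `c(0, 1, 2)`.
#' @return Named numeric vector, one effective species number per order.
#' @export
#' @examples
#' hill_number(c(10, 10, 10, 10))     # 4 4 4
#' hill_number(c(9, 1), q = 2)        # 1.2195
hill_number <- function(x, q = c(0, 1, 2)) {
  x <- .check_counts(x)
  if (!all(q %in% c(0, 1, 2))) abort("q must be in {0, 1, 2}")
  p <- x / sum(x)
  vapply(q, function(qq) {
    switch(as.character(qq),
      "0" = as.numeric(length(p)),
      "1" = exp(-sum(p * log(p))),
      "2" = 1 / sum(p^2)
    )
  }, numeric(1)) |> setNames(paste0("q", q))
}

# ---- internal estimator core: abundance basis -------------------------------

.f_counts <- function(x) c(f1 = sum(x == 1), f2 = sum(x == 2))

.chao_f0 <- function(x) {
  n <- sum(x); f <- .f_counts(x)
  if (f["f1"] == 0) return(0)
  if (f["f2"] > 0) (n - 1) / n * f[["f1"]]^2 / (2 * f[["f2"]])
  else             (n - 1) / n * f[["f1"]] * (f[["f1"]] - 1) / 2
}

# Asymptotic Shannon entropy (Chao-type low-abundance correction).
.entropy_asy <- function(x) {
  x <- x[x > 0]; n <- sum(x)
  if (n <= 1) return(0)
  h1 <- sum(x / n * (digamma(n) - digamma(x)))
  f <- .f_counts(x)
  A <- if (f[["f2"]] > 0) 2 * f[["f2"]] / ((n - 1) * f[["f1"]] + 2 * f[["f2"]])
       else if (f[["f1"]] > 0) 2 / ((n - 1) * (f[["f1"]] - 1) + 2)
       else 1
  h2 <- 0
  if (A < 1 && f[["f1"]] > 0) {
    r <- seq_len(n - 1)
    tail_sum <- -log(A) - sum((1 - A)^r / r)
    if (is.finite(tail_sum) && tail_sum > 0) {
      log_h2 <- log(f[["f1"]] / n) + (1 - n) * log1p(-A) + log(tail_sum)
      h2 <- exp(log_h2)
      if (!is.finite(h2)) h2 <- 0
    }
  }
  h1 + h2
}

.d0_abund <- function(x, m) {
  n <- sum(x); S <- length(x)
  vapply(m, function(mm) {
    if (mm <= n) {
      S - sum(exp(lchoose(n - x, mm) - lchoose(n, mm)))
    } else {
      f0 <- .chao_f0(x); f1 <- .f_counts(x)[["f1"]]
      if (f1 == 0 || f0 == 0) return(S)
      B <- 1 - f1 / (n * f0 + f1)
      S + f0 * (1 - B^(mm - n))
    }
  }, numeric(1))
}

.d1_abund <- function(x, m) {
  n <- sum(x)
  p <- x / n
  h_obs <- -sum(p * log(p))
  vapply(m, function(mm) {
    if (mm == 1) return(1)
    if (mm < n) {
      K <- seq_len(min(mm, max(x)))
      l1 <- outer(x, K, lchoose)
      l2 <- outer(n - x, K, function(a, k) lchoose(a, mm - k))
      efk <- colSums(exp(l1 + l2 - lchoose(n, mm)))
      exp(sum(-(K / mm) * log(K / mm) * efk))
    } else if (mm == n) {
      exp(h_obs)
    } else {
      w <- n / mm
      exp(w * h_obs + (1 - w) * max(h_obs, .entropy_asy(x)))
    }
  }, numeric(1))
}

.d2_abund <- function(x, m) {
  n <- sum(x)
  if (n == 1) return(rep(1, length(m)))
  s2 <- sum(x * (x - 1)) / (n * (n - 1))
  vapply(m, function(mm) {
    if (mm == 1) return(1)
    1 / (1 / mm + (1 - 1 / mm) * s2)
  }, numeric(1))
}

.d_abund <- function(x, q, m) {
  switch(as.character(q),
    "0" = .d0_abund(x, m),
    "1" = .d1_abund(x, m),
    "2" = .d2_abund(x, m)
  )
}

.cov_abund <- function(x, m) {
  n <- sum(x)
  f <- .f_counts(x)
  vapply(m, function(mm) {
    if (mm < n) {
      1 - sum((x / n) * exp(lchoose(n - x, mm) - lchoose(n - 1, mm)))
    } else {
      if (f[["f1"]] == 0) return(1)
      A <- (n - 1) * f[["f1"]] / ((n - 1) * f[["f1"]] + 2 * f[["f2"]])
      1 - f[["f1"]] / n * A^(mm - n + 1)
    }
  }, numeric(1))
}

# ---- internal estimator core: incidence basis -------------------------------

.q_counts <- function(y) c(q1 = sum(y == 1), q2 = sum(y == 2))

.chao_q0 <- function(y, Tn) {
  qc <- .q_counts(y)
  if (qc[["q1"]] == 0) return(0)
  if (qc[["q2"]] > 0) (Tn - 1) / Tn * qc[["q1"]]^2 / (2 * qc[["q2"]])
  else                (Tn - 1) / Tn * qc[["q1"]] * (qc[["q1"]] - 1) / 2
}

.d0_incid <- function(y, Tn, t) {
  S <- length(y)
  vapply(t, function(tt) {
    if (tt <= Tn) {
      S - sum(exp(lchoose(Tn - y, tt) - lchoose(Tn, tt)))
    } else {
      q0 <- .chao_q0(y, Tn); q1 <- .q_counts(y)[["q1"]]
      if (q1 == 0 || q0 == 0) return(S)
      B <- 1 - q1 / (Tn * q0 + q1)
      S + q0 * (1 - B^(tt - Tn))
    }
  }, numeric(1))
}

.d1_incid <- function(y, Tn, t) {
  U <- sum(y)
  p <- y / U
  h_obs <- -sum(p * log(p))
  vapply(t, function(tt) {
    if (tt < Tn) {
      Ut <- tt * U / Tn
      K <- seq_len(min(tt, max(y)))
      l1 <- outer(y, K, lchoose)
      l2 <- outer(Tn - y, K, function(a, k) lchoose(a, tt - k))
      eqk <- colSums(exp(l1 + l2 - lchoose(Tn, tt)))
      exp(sum(-(K / Ut) * log(K / Ut) * eqk))
    } else if (tt == Tn) {
      exp(h_obs)
    } else {
      w <- Tn / tt
      boot <- .bootstrap_incid_pi(y, Tn)
      pa <- boot$pi / sum(boot$pi)
      h_asy <- -sum(pa * log(pa))
      exp(w * h_obs + (1 - w) * max(h_obs, h_asy))
    }
  }, numeric(1))
}

.d2_incid <- function(y, Tn, t) {
  U <- sum(y)
  if (Tn == 1) return(rep(hill_number(y, 2), length(t)))
  s2 <- sum(y * (y - 1)) / (Tn * (Tn - 1))
  vapply(t, function(tt) {
    denom <- Tn / (tt * U) + (tt - 1) / tt * Tn^2 * s2 / U^2
    if (denom <= 0) return(1)
    1 / denom
  }, numeric(1))
}

.d_incid <- function(y, Tn, q, t) {
  switch(as.character(q),
    "0" = .d0_incid(y, Tn, t),
    "1" = .d1_incid(y, Tn, t),
    "2" = .d2_incid(y, Tn, t)
  )
}

.cov_incid <- function(y, Tn, t) {
  U <- sum(y)
  qc <- .q_counts(y)
  vapply(t, function(tt) {
    if (tt < Tn) {
      1 - sum((y / U) * exp(lchoose(Tn - y, tt) - lchoose(Tn - 1, tt)))
    } else {
      if (qc[["q1"]] == 0) return(1)
      A <- (Tn - 1) * qc[["q1"]] / ((Tn - 1) * qc[["q1"]] + 2 * qc[["q2"]])
      1 - qc[["q1"]] / U * A^(tt - Tn + 1)
    }
  }, numeric(1))
}

# ---- bootstrap assemblages --------------------------------------------------

.bootstrap_abund_p <- function(x) {
  n <- sum(x)
  chat <- .cov_abund(x, n)
  f0 <- ceiling(.chao_f0(x))
  lam_denom <- sum((x / n) * (1 - x / n)^n)
  lam <- if (lam_denom > 0) (1 - chat) / lam_denom else 0
  p_seen <- (x / n) * (1 - lam * (1 - x / n)^n)
  p_unseen <- if (f0 > 0 && chat < 1) rep((1 - chat) / f0, f0) else numeric(0)
  c(p_seen, p_unseen)
}

.bootstrap_incid_pi <- function(y, Tn) {
  U <- sum(y)
  chat <- .cov_incid(y, Tn, Tn)
  q0 <- ceiling(.chao_q0(y, Tn))
  lam_denom <- sum((y / Tn) * (1 - y / Tn)^Tn)
  lam <- if (lam_denom > 0) (U / Tn) * (1 - chat) / lam_denom else 0
  pi_seen <- (y / Tn) * (1 - lam * (1 - y / Tn)^Tn)
  pi_unseen <- if (q0 > 0 && chat < 1) {
    rep(min(1, (U / Tn) * (1 - chat) / q0), q0)
  } else numeric(0)
  list(pi = c(pi_seen, pi_unseen), n_unseen = q0)
}

# ---- public interface -------------------------------------------------------

#' Estimated sample coverage at a given sample size
#'
#' Good-Turing-based estimate of the fraction of the assemblage's individual
#' (or incidence) probability accounted for by the species detected in a
#' hypothetical sample of size `m`.  At the reference size `n` this is
#' `1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))` with `f1`, `f2` the singleton
#' and doubleton counts; smaller sizes use the exact hypergeometric
#' expectation and larger sizes the geometric extension, up to `m = 2n`.
#'
#' @param x Abundance vector (or incidence frequencies for
#'   `basis = "incidence"`).
#' @param m Sample size(s): individuals (abundance) or sampling units
#'   (incidence).
#' @param basis `"abundance"` or `"incidence"`.
#' @param n_units Number of sampling units `T` (incidence basis only).
#' @return Coverage value(s) in `[0, 1]`.
#' @export
coverage_estimate <- function(x, m, basis = c("abundance", "incidence"),
                              n_units = NULL) {
  basis <- arg_match(basis)
  x <- .check_counts(x)
  if (any(m < 1)) abort("m must be >= 1")
  ref <- if (basis == "abundance") sum(x) else n_units
  if (basis == "incidence" && is.null(n_units)) {
    abort("n_units (number of sampling units) is required for incidence data")
  }
  if (any(m > 2 * ref)) {
    abort("m beyond twice the reference sample size is outside the supported extrapolation range")
  }
  if (basis == "abundance") .cov_abund(x, m) else .cov_incid(x, n_units, m)
}

.estimate_tbl <- function(x, q, m, basis, n_units) {
  ref <- if (basis == "abundance") sum(x) else n_units
  purrr::map_dfr(q, function(qq) {
    est <- if (basis == "abundance") .d_abund(x, qq, m)
           else .d_incid(x, n_units, qq, m)
    cov <- if (basis == "abundance") .cov_abund(x, m) else .cov_incid(x, n_units, m)
    tibble(
      basis = basis, q = qq, m = m, coverage = cov, estimate = est,
      kind = dplyr::case_when(m < ref ~ "interpolated",
                              m == ref ~ "observed",
                              TRUE ~ "extrapolated")
    )
  })
}

#' Rarefy Hill diversity to a smaller sample size
#'
#' Expected Hill number of order `q` for samples of size `m` at or below the
#' reference sample, via exact hypergeometric rarefaction (`q = 0, 1`) or the
#' unbiased Simpson form (`q = 2`).
#'
#' @inheritParams coverage_estimate
#' @param q Diversity orders (subset of 0, 1, 2).
#' @return Tibble with columns `basis`, `q`, `m`, `coverage`, `estimate`,
#'   `kind`.
#' @export
rarefy_hill <- function(x, q = c(0, 1, 2), m,
                        basis = c("abundance", "incidence"), n_units = NULL) {
  basis <- arg_match(basis)
  x <- .check_counts(x)
  ref <- if (basis == "abundance") sum(x) else n_units
  if (basis == "incidence" && is.null(n_units)) abort("n_units required")
  if (any(m < 1) || any(m > ref)) abort("Rarefaction needs 1 <= m <= reference size")
  .estimate_tbl(x, q, m, basis, n_units)
}

#' Extrapolate Hill diversity beyond the reference sample
#'
#' Short-range extrapolation anchored on the Chao1 (abundance) or Chao2
#' (incidence) asymptotic richness estimator for `q = 0`; prediction is
#' reliable up to about double the reference size.
#'
#' @inheritParams rarefy_hill
#' @export
extrapolate_hill <- function(x, q = c(0, 1, 2), m,
                             basis = c("abundance", "incidence"),
                             n_units = NULL) {
  basis <- arg_match(basis)
  x <- .check_counts(x)
  ref <- if (basis == "abundance") sum(x) else n_units
  if (basis == "incidence" && is.null(n_units)) abort("n_units required")
  if (any(m <= ref)) abort("Extrapolation needs m > reference size")
  .estimate_tbl(x, q, m, basis, n_units)
}

#' Doubling-rule extrapolation limit for comparing assemblages
#'
#' When two or more assemblages are compared, curves are extended to twice
#' the smallest reference sample size.
#'
#' @param ... Reference sample sizes (individuals or sampling units).
#' @return `2 * min(...)`.
#' @export
#' @examples
#' extrapolation_limit(2934, 2752) # 5504
extrapolation_limit <- function(...) {
  sizes <- c(...)
  if (length(sizes) == 0 || any(sizes < 1)) abort("Need positive reference sizes")
  2 * min(sizes)
}

#' Rarefaction/extrapolation curve with bootstrap confidence band
#'
#' Computes analytic point estimates of Hill diversity on a grid of sample
#' sizes from 1 to `endpoint` (default twice the reference sample), together
#' with estimated sample coverage, and a normal-approximation confidence band
#' `estimate +/- z * SD` where the SD is taken over bootstrap replicates
#' drawn from an estimated assemblage that includes an unseen-species
#' component.
#'
#' @inheritParams rarefy_hill
#' @param knots Number of grid sizes (endpoint and reference always added).
#' @param endpoint Largest size; default `2 *` reference.
#' @param reps Bootstrap replications (default 200; `0` skips the band).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed making the bootstrap deterministic.
#' @return A tibble of class `"hill_curve"` with columns `basis`, `q`, `m`,
#'   `coverage`, `estimate`, `ci_low`, `ci_high`, `kind`.
#' @export
hill_curve <- function(x, q = c(0, 1, 2),
                       basis = c("abundance", "incidence"), n_units = NULL,
                       knots = 40, endpoint = NULL, reps = 200, conf = 0.95,
                       seed = NULL) {
  basis <- arg_match(basis)
  x <- .check_counts(x)
  if (reps == 1) abort("reps must be 0 (no band) or >= 2")
  ref <- if (basis == "abundance") sum(x) else n_units
  if (basis == "incidence" && is.null(n_units)) abort("n_units required")
  if (is.null(endpoint)) endpoint <- 2 * ref
  grid <- sort(unique(c(round(seq(1, endpoint, length.out = knots)), ref, endpoint)))
  grid <- grid[grid >= 1]
  out <- .estimate_tbl(x, q, grid, basis, n_units)

  if (reps >= 2) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    boot_est <- if (basis == "abundance") {
      p <- .bootstrap_abund_p(x)
      n <- sum(x)
      replicate(reps, {
        xb <- as.numeric(rmultinom(1, n, p))
        xb <- xb[xb > 0]
        unlist(lapply(q, function(qq) .d_abund(xb, qq, grid)))
      })
    } else {
      boot <- .bootstrap_incid_pi(x, n_units)
      replicate(reps, {
        yb <- rbinom(length(boot$pi), n_units, boot$pi)
        yb <- yb[yb > 0]
        if (length(yb) == 0) yb <- 1L
        unlist(lapply(q, function(qq) .d_incid(yb, n_units, qq, grid)))
      })
    }
    sds <- apply(boot_est, 1, sd)
    z <- qnorm(1 - (1 - conf) / 2)
    out$ci_low <- pmax(out$estimate - z * sds, 1)
    out$ci_high <- out$estimate + z * sds
  } else {
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
  }
  out <- out %>% select(basis, q, m, coverage, estimate, ci_low, ci_high, kind)
  class(out) <- c("hill_curve", class(out))
  out
}

#' @export
autoplot.hill_curve <- function(object, x_axis = c("size", "coverage"), ...) {
  x_axis <- arg_match(x_axis)
  xvar <- if (x_axis == "size") "m" else "coverage"
  has_ci <- !all(is.na(object$ci_low))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xvar]], y = estimate))
  if (has_ci) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = ci_low, ymax = ci_high), alpha = 0.25, fill = "grey40"
    )
  }
  p +
    ggplot2::geom_line(data = function(d) dplyr::filter(d, kind != "extrapolated"),
                       linewidth = 0.6) +
    ggplot2::geom_line(data = function(d) dplyr::filter(d, kind != "interpolated"),
                       linetype = "dashed", linewidth = 0.6) +
    ggplot2::geom_point(data = function(d) dplyr::filter(d, kind == "observed"),
                        size = 2) +
    ggplot2::facet_wrap(~q, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = if (x_axis == "size") "Sample size" else "Sample coverage",
      y = "Effective number of species"
    ) +
    ggplot2::theme_minimal()
}
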