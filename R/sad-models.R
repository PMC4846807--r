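# Expected rank-abundance curves of the six classical SAD models, plus the
# neutral-theory abundance spectrum (sampling-formula integral).

#' Broken-stick expected abundances
#'
#' \deqn{\hat a_r = (N/S) \sum_{k=r}^{S} 1/k}
#' Resource apportioning by simultaneous random division; no free parameters.
#' The expectations telescope so that their sum is exactly `N`.
#'
#' @param N Total individuals.
#' @param S Number of species.
#' @return Expected abundance per rank `1..S` (descending).
#' @export
#' @examples
#' expected_broken_stick(30, 3)
expected_broken_stick <- function(N, S) {
  if (S < 1 || N < S) abort("Need S >= 1 and N >= S")
  inv <- 1 / seq_len(S)
  (N / S) * rev(cumsum(rev(inv)))
}

#' Niche-preemption (geometric series) expected abundances
#'
#' \deqn{\hat a_r = N \alpha (1-\alpha)^{r-1}}
#'
#' @param N Total individuals.
#' @param S Number of ranks.
#' @param alpha Preemption fraction, in (0, 1).
#' @export
expected_preemption <- function(N, S, alpha) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1)")
  N * alpha * (1 - alpha)^(seq_len(S) - 1)
}

#' Log-normal expected abundances
#'
#' \deqn{\hat a_r = \exp[\log\mu + \log\sigma \cdot \Phi_r]}
#' where \eqn{\Phi_r} is the standard normal quantile at the mid-rank
#' plotting position `(S - r + 0.5)/S`, so the median rank sits at
#' abundance ~ `mu`.
#'
#' @param S Number of species.
#' @param mu Median abundance scale (> 0).
#' @param sigma Shape; `log(sigma) > 0` spreads abundances, `sigma -> 1`
#'   degenerates to all species at `mu`.
#' @export
expected_lognormal <- function(S, mu, sigma) {
  if (mu <= 0 || sigma <= 0) abort("mu and sigma must be positive")
  r <- seq_len(S)
  pos <- (S - r + 0.5) / S
  exp(log(mu) + log(sigma) * qnorm(pos))
}

#' Zipf expected abundances
#'
#' \deqn{\hat a_r = N \hat p_1 r^{\gamma}}, \eqn{\gamma < 0}.
#'
#' @param N Total individuals.
#' @param S Number of ranks.
#' @param p1 Estimated proportion of the most abundant species.
#' @param gamma Decay exponent (negative).
#' @export
expected_zipf <- function(N, S, p1, gamma) {
  if (gamma >= 0) abort("gamma must be negative")
  if (p1 <= 0 || p1 > 1) abort("p1 must lie in (0, 1]")
  N * p1 * seq_len(S)^gamma
}

#' Zipf-Mandelbrot expected abundances
#'
#' \deqn{\hat a_r = N c (r+\beta)^{\gamma}}; reduces to Zipf at `beta = 0`
#' with `c = p1`.
#'
#' @param N Total individuals.
#' @param S Number of ranks.
#' @param c_par Scale parameter (> 0).
#' @param beta Rank offset (> -1).
#' @param gamma Decay exponent (negative).
#' @export
expected_zm <- function(N, S, c_par, beta, gamma) {
  if (gamma >= 0) abort("gamma must be negative")
  if (beta <= -1) abort("beta must exceed -1")
  if (c_par <= 0) abort("c_par must be positive")
  N * c_par * (seq_len(S) + beta)^gamma
}

#' Neutral-theory expected abundance spectrum
#'
#' Expected number of species with exactly `n` individuals in a local
#' community of size `J` under the dispersal-limited neutral model with
#' fundamental biodiversity number `theta` and migration rate `m`:
#' \deqn{\phi_n = \theta \binom{J}{n} \frac{\Gamma(\gamma)}{\Gamma(J+\gamma)}
#'   \int_0^{\gamma} \frac{\Gamma(n+y)}{\Gamma(1+y)}
#'   \frac{\Gamma(J-n+\gamma-y)}{\Gamma(\gamma-y)} e^{-y\theta/\gamma}\,dy}
#' with \eqn{\gamma = m(J-1)/(1-m)}.  The integrand is evaluated in the
#' log-Gamma domain and integrated by adaptive quadrature.
#'
#' @param n Abundance class(es), integers in `1..J`.
#' @param theta Fundamental biodiversity number (> 0).
#' @param m Migration (immigration) probability in (0, 1).
#' @param J Local community size.
#' @return `phi_n >= 0`, one value per element of `n`.
#' @export
neutral_phi <- function(n, theta, m, J) {
  if (theta <= 0) abort("theta must be positive")
  if (m <= 0 || m >= 1) abort("m must lie strictly in (0, 1)")
  if (any(n < 1) || any(n > J)) abort("n must lie in 1..J")
  gam <- m * (J - 1) / (1 - m)
  log_pref <- log(theta) + lgamma(J + 1) + lgamma(gam) - lgamma(J + gam)
  vapply(n, function(nn) {
    log_binom_part <- -lgamma(nn + 1) - lgamma(J - nn + 1)
    integrand <- function(y) {
      # guard the y -> gam endpoint where Gamma(gam - y) diverges
      y <- pmin(y, gam * (1 - 1e-12))
      lg <- lgamma(nn + y) - lgamma(1 + y) +
        lgamma(J - nn + gam - y) - lgamma(gam - y) -
        y * theta / gam
      exp(lg + log_pref + log_binom_part)
    }
    val <- tryCatch(
      integrate(integrand, lower = 0, upper = gam,
                rel.tol = 1e-8, subdivisions = 400L)$value,
      error = function(e) {
        abort(paste0("Quadrature failed for phi_", nn, ": ", conditionMessage(e)))
      }
    )
    max(val, 0)
  }, numeric(1))
}

# Expected rank abundances implied by the neutral spectrum: invert the
# cumulative expected species count G(a) = sum_{n >= a} phi_n at r - 1/2.
# phi is evaluated exactly for small n and on a geometric grid above,
# log-interpolated in between.
.neutral_expected_ranks <- function(S, theta, m, J) {
  n_exact <- seq_len(min(J, 30L))
  n_grid <- unique(c(n_exact, round(exp(seq(log(30), log(J), length.out = 30)))))
  n_grid <- sort(unique(pmin(pmax(n_grid, 1L), J)))
  phi_grid <- neutral_phi(n_grid, theta, m, J)
  phi_grid <- pmax(phi_grid, 1e-300)
  # per-integer phi via log-linear interpolation on the grid
  all_n <- seq_len(J)
  log_phi <- approx(log(n_grid), log(phi_grid), xout = log(all_n),
                    rule = 2)$y
  phi_all <- exp(log_phi)
  # cumulative expected species count from the most abundant class downwards
  G <- rev(cumsum(rev(phi_all)))          # G[a] = sum_{n >= a} phi_n
  targets <- seq_len(S) - 0.5
  a_hat <- vapply(targets, function(tg) {
    if (tg >= G[1]) return(0.5)           # more ranks than expected species
    idx <- which(G <= tg)[1]              # G is nonincreasing in a
    if (is.na(idx)) return(as.numeric(J))
    if (idx == 1) return(1)
    # interpolate between abundance classes idx-1 and idx
    g_hi <- G[idx - 1]; g_lo <- G[idx]
    frac <- if (g_hi > g_lo) (g_hi - tg) / (g_hi - g_lo) else 0
    (idx - 1) + frac
  }, numeric(1))
  sort(pmax(a_hat, 1e-3), decreasing = TRUE)
}
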