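#' Circular summary statistics of spike phases
#'
#' Mean resultant vector length `R = |sum(exp(i theta))|/n`, circular mean
#' phase, and the Rayleigh test of uniformity with the standard finite-n
#' approximation `p = exp(-Z) (1 + (2Z - Z^2)/(4n))`, `Z = n R^2`.
#'
#' @param phases Degrees (any real values; reduced mod 360).
#' @return One-row tibble: `n`, `mean_phase` (deg in \[0,360)),
#'   `vector_length`, `rayleigh_p`.
#' @export
circ_stats <- function(phases) {
  n <- length(phases)
  if (n == 0) abort("need at least one phase")
  th <- phases * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2) / n
  mu <- (atan2(S, C) * 180 / pi) %% 360
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
  tibble(n = n, mean_phase = mu, vector_length = R,
         rayleigh_p = min(max(p, 0), 1))
}

#' Watson's two-sample U^2 test for circular homogeneity
#'
#' Rank-based Watson U^2 statistic comparing two samples of circular data,
#' with the asymptotic tail probability and the tabulated critical values at
#' 0.05 (0.187) and 0.01 (0.268).
#'
#' @param a,b Phases in degrees, each with at least 8 observations.
#' @return One-row tibble: `u2`, `p`, `n_a`, `n_b`, `sig_05`, `sig_01`.
#' @export
watson_two_sample <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n < 8 || m < 8) abort("need at least 8 observations per sample")
  x <- (a %% 360) / 360
  y <- (b %% 360) / 360
  N <- n + m
  all_v <- c(x, y)
  o <- order(all_v)
  grp <- c(rep(1L, n), rep(2L, m))[o]
  cum_a <- cumsum(grp == 1L) / n
  cum_b <- cumsum(grp == 2L) / m
  d <- cum_a - cum_b
  u2 <- (n * m) / N^2 * (sum(d^2) - sum(d)^2 / N)
  # asymptotic null distribution shared with the one-sample statistic
  k <- 1:25
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  p <- min(max(p, 0), 1)
  tibble(u2 = u2, p = p, n_a = n, n_b = m,
         sig_05 = u2 > 0.187, sig_01 = u2 > 0.268)
}

#' Draw von Mises variates
#'
#' Best-Fisher rejection sampler; used by the synthetic generators for
#' theta- and ripple-coupled spike phases.
#'
#' @param n Count.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0); 0 is uniform.
#' @return Radians in \[0, 2 pi).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

#' Ratio of modified Bessel functions I1/I0
#'
#' The population mean resultant length of a von Mises distribution with
#' concentration `kappa`; the analytic target for coupling-recovery tests.
#'
#' @param kappa Concentration.
#' @return `I1(kappa)/I0(kappa)`.
#' @export
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

circ_mean_deg <- function(phases) {
  th <- phases * pi / 180
  (atan2(sum(sin(th)), sum(cos(th))) * 180 / pi) %% 360
}
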