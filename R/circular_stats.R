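#' Circular mean vector
#'
#' First trigonometric moment of a sample of angles: the mean direction
#' `mu` (degrees) indicates the preferred phase, the vector length `r`
#' (0-1) the strength of phase coupling.
#'
#' @param angles_deg Angles in degrees.
#' @return List of class `mean_vector`: `mu_deg`, `r`, `n`.
#' @export
mean_vector <- function(angles_deg) {
  if (!length(angles_deg)) stop("empty angle vector")
  th <- angles_deg * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) * 180 / pi
  structure(list(mu_deg = (mu + 360) %% 360, r = r, n = length(angles_deg)),
            class = "mean_vector")
}

#' @export
print.mean_vector <- function(x, ...) {
  cat(sprintf("mu = %.1f deg, r = %.3f (n = %d)\n", x$mu_deg, x$r, x$n))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of a uniform phase distribution with
#' `Z = n r^2` and the standard series approximation of the p-value.
#'
#' @param angles_deg Angles in degrees (n >= 3).
#' @return An object of class `htest`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 3) stop("need at least 3 angles")
  mv <- mean_vector(angles_deg)
  Z <- n * mv$r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(statistic = c(Z = Z), p.value = p,
                 estimate = c(mu_deg = mv$mu_deg, r = mv$r),
                 parameter = c(n = n),
                 method = "Rayleigh test of circular uniformity",
                 data.name = deparse(substitute(angles_deg))),
            class = "htest")
}

moore_rstar <- function(mu_deg, r) {
  n <- length(mu_deg)
  rk <- rank(r, ties.method = "average")
  th <- mu_deg * pi / 180
  X <- sum(rk * cos(th)) / n^1.5
  Y <- sum(rk * sin(th)) / n^1.5
  sqrt(X^2 + Y^2)
}

#' Moore's Modified Rayleigh test for second-order vectors
#'
#' Tests whether per-animal mean vectors share a preferred direction,
#' weighting each direction by the rank of its vector length (Moore's
#' `R*` statistic).  The p-value is obtained by seeded Monte Carlo
#' simulation of the uniform-direction null, holding the observed vector
#' lengths fixed.
#'
#' @param mu_deg Per-animal mean directions (degrees), >= 3.
#' @param r Per-animal vector lengths, same length as `mu_deg`.
#' @param n_sim Monte Carlo draws for the null distribution.
#' @param seed Seed for the simulation.
#' @return An object of class `htest` with statistic `R*`.
#' @export
moore_modified_rayleigh <- function(mu_deg, r, n_sim = 2000, seed = 1) {
  if (length(mu_deg) < 3) stop("need at least 3 second-order vectors")
  if (length(mu_deg) != length(r)) stop("mu_deg and r lengths differ")
  obs <- moore_rstar(mu_deg, r)
  set.seed(seed)
  n <- length(mu_deg)
  sims <- replicate(n_sim, moore_rstar(runif(n, 0, 360), r))
  p <- (1 + sum(sims >= obs)) / (n_sim + 1)
  structure(list(statistic = c("R*" = obs), p.value = p,
                 parameter = c(n = n, n_sim = n_sim),
                 method = "Moore's Modified Rayleigh test (Monte Carlo p)",
                 data.name = "second-order mean vectors"),
            class = "htest")
}

#' Hotelling two-sample test on mean vectors
#'
#' Compares the phase relations of two groups of per-animal mean vectors
#' by a two-sample Hotelling T-squared test on their Cartesian components.
#'
#' @param mu_a_deg,r_a Directions (deg) and lengths of group A (>= 3).
#' @param mu_b_deg,r_b Directions (deg) and lengths of group B (>= 3).
#' @return An object of class `htest` with an F statistic.
#' @export
hotelling_two_sample <- function(mu_a_deg, r_a, mu_b_deg, r_b) {
  if (length(mu_a_deg) < 3 || length(mu_b_deg) < 3)
    stop("each group needs at least 3 vectors")
  xy <- function(mu, r) cbind(r * cos(mu * pi / 180), r * sin(mu * pi / 180))
  A <- xy(mu_a_deg, r_a); B <- xy(mu_b_deg, r_b)
  n1 <- nrow(A); n2 <- nrow(B)
  d <- colMeans(A) - colMeans(B)
  S <- ((n1 - 1) * stats::cov(A) + (n2 - 1) * stats::cov(B)) / (n1 + n2 - 2)
  if (!all(is.finite(S)) || abs(det(S)) < 1e-12)
    stop("degenerate covariance: test inconclusive for these samples")
  T2 <- (n1 * n2) / (n1 + n2) * drop(t(d) %*% solve(S, d))
  Fstat <- (n1 + n2 - 3) / (2 * (n1 + n2 - 2)) * T2
  p <- pf(Fstat, 2, n1 + n2 - 3, lower.tail = FALSE)
  structure(list(statistic = c(F = Fstat), p.value = p,
                 parameter = c(df1 = 2, df2 = n1 + n2 - 3),
                 method = "Hotelling two-sample test on circular mean vectors",
                 data.name = "two groups of mean vectors"),
            class = "htest")
}
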