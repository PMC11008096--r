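# Independent oracles used across the suite.  These deliberately do not
# reuse the package's tensor machinery: the dense SCF oracle builds the
# damped dipole interaction matrix from the textbook Thole expressions and
# the reciprocal oracle is an explicit structure-factor loop.

K_E <- 332.063713

`%||%` <- function(a, b) if (is.null(a)) b else a

# Thole-damped dipole field tensor between two sites (vacuum), textbook form
oracle_dipole_tensor <- function(xi, xj, alpha_i, alpha_j, a = 0.39) {
  r <- xi - xj
  rr <- sqrt(sum(r^2))
  lam3 <- 1; lam5 <- 1
  if (alpha_i > 0 && alpha_j > 0) {
    u <- rr / (alpha_i * alpha_j)^(1 / 6)
    au3 <- a * u^3
    lam3 <- 1 - exp(-au3)
    lam5 <- 1 - (1 + au3) * exp(-au3)
  }
  (3 * lam5 * outer(r, r) / rr^5 - lam3 * diag(3) / rr^3)
}

# dense solve of (alpha^-1 - T) mu = E for a vacuum cluster
oracle_dense_scf <- function(xyz, alpha, E, a = 0.39) {
  n <- nrow(xyz)
  act <- which(alpha > 0)
  m <- length(act)
  A <- matrix(0, 3 * m, 3 * m)
  for (p in seq_len(m)) {
    i <- act[p]
    A[(3 * p - 2):(3 * p), (3 * p - 2):(3 * p)] <- diag(3) * K_E / alpha[i]
    for (q in seq_len(m)) {
      if (p == q) next
      j <- act[q]
      A[(3 * p - 2):(3 * p), (3 * q - 2):(3 * q)] <-
        -K_E * oracle_dipole_tensor(xyz[i, ], xyz[j, ], alpha[i], alpha[j], a)
    }
  }
  b <- as.vector(t(E[act, , drop = FALSE]))
  mu <- matrix(0, n, 3)
  mu[act, ] <- matrix(solve(A, b), ncol = 3, byrow = TRUE)
  mu
}

# explicit Ewald k-space structure-factor sum for multipole sources
oracle_ksum <- function(xyz, M, cell, beta, kmax = 10) {
  V <- cell$volume
  Astar <- t(cell$inv)
  U <- 0
  n <- nrow(M)
  for (m1 in -kmax:kmax) for (m2 in -kmax:kmax) for (m3 in -kmax:kmax) {
    if (m1 == 0 && m2 == 0 && m3 == 0) next
    mv <- as.vector(Astar %*% c(m1, m2, m3))
    m2n <- sum(mv^2)
    S <- 0 + 0i
    for (i in seq_len(n)) {
      ph <- 2i * pi * sum(mv * xyz[i, ])
      Lf <- M[i, 1] + sum(M[i, 2:4] * (2i * pi * mv)) +
        sum((matrix(M[i, 5:13], 3, 3) / 3) *
              outer(2i * pi * mv, 2i * pi * mv))
      S <- S + Lf * exp(ph)
    }
    U <- U + exp(-pi^2 * m2n / beta^2) / (2 * pi * V * m2n) * Mod(S)^2
  }
  U * K_E
}

# vacuum variant of a periodic fixture (for closed-form polarization tests)
vacuum_fixture <- function(fx) {
  fx$system$cell <- NULL
  fx$config$beta <- NULL
  fx$config$cutoff <- Inf
  fx$config$grid <- NULL
  fx
}

# total permanent Ewald energy through the package
perm_total_energy <- function(fx, lz = numeric(0)) {
  e <- cph_energy(fx$system, lz, fx$config, gradient = FALSE,
                  terms = c("real", "recip", "selfneut"))
  e$energy
}

expect_rel <- function(actual, expected, tol, scale = NULL) {
  s <- if (is.null(scale)) max(abs(expected), 1e-10) else scale
  expect_lt(abs(actual - expected) / s, tol)
}
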