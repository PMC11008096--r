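# Smooth particle-mesh Ewald for point multipoles (charge + dipole +
# quadrupole sources), B-spline interpolation, arbitrary triclinic cells.
#
# Conventions: reciprocal vectors without the 2*pi factor (a* . a = 1),
# influence kernel exp(-pi^2 m^2 / beta^2) / (2 pi V m^2) with the Euler
# spline factors |b1 b2 b3|^2.  Modes where the odd-order spline factor is
# singular (m = K/2 for odd orders) are dropped from the sum.

# Cardinal B-spline values M_n(u - k) and derivatives for the n support
# points of one fractional coordinate u; returns a list of vectors of
# length n for derivative orders 0..dmax.
#' @noRd
bspline_weights <- function(u, n, dmax = 2L) {
  k0 <- floor(u)
  t <- u - k0                     # in [0,1)
  # M_j evaluated at t + s for s = 0..j-1 via the stable recursion
  spl <- function(ord) {
    v <- numeric(ord)
    v[1] <- 1
    if (ord > 1) for (j in 2:ord) {
      w <- numeric(j)
      for (s in 1:j) {
        x1 <- t + (s - 1)
        a <- if (s > 1) v[s - 1] else 0
        b <- if (s <= j - 1) v[s] else 0
        w[s] <- ((x1) * b + (j - x1) * a) / (j - 1)
      }
      v <- w
    }
    v
  }
  base <- lapply(n:(n - dmax), spl)
  out <- vector("list", dmax + 1)
  out[[1]] <- base[[1]]
  if (dmax >= 1) {
    m1 <- c(0, base[[2]], 0)      # padded M_{n-1}
    out[[2]] <- m1[2:(n + 1)] - m1[1:n]
  }
  if (dmax >= 2) {
    m2 <- c(0, 0, base[[3]], 0, 0)
    out[[3]] <- m2[3:(n + 2)] - 2 * m2[2:(n + 1)] + m2[1:n]
  }
  if (dmax >= 3) {
    m3 <- c(0, 0, 0, base[[4]], 0, 0, 0)
    out[[4]] <- m3[4:(n + 3)] - 3 * m3[3:(n + 2)] + 3 * m3[2:(n + 1)] - m3[1:n]
  }
  # weights listed for grid offsets k = k0 - n + 1 .. k0, i.e. M_n(u - k)
  # with argument decreasing; spl() returns M_n at t, t+1, ..., t+n-1 which
  # corresponds to k = k0, k0-1, ..., k0-n+1 -- reverse to ascending k.
  list(k0 = k0, w = lapply(out, rev))
}

# Euler exponential spline |b(m)|^2 factors for one dimension.
#' @noRd
bspline_modulus <- function(K, n) {
  m <- 0:(K - 1)
  kk <- 0:(n - 2)
  Mn <- .bspline_at_integers(n)   # M_n(1), ..., M_n(n-1)
  denom <- vapply(m, function(mm) {
    s <- sum(Mn * exp(2i * pi * mm * kk / K))
    Mod(s)^2
  }, numeric(1))
  denom
}

#' @noRd
.bspline_at_integers <- function(n) {
  # M_n(j) for j = 1..n-1, from the generic evaluator at u = 0
  v <- rev(bspline_weights(0, n, 0L)$w[[1]])   # M_n(0), ..., M_n(n-1)
  v[2:n]
}

# Precompute the reciprocal influence array c(m1,m2,m3) (real, with spline
# modulus folded in) for a cell/grid/beta combination.
#' @noRd
pme_influence <- function(cell, grid, order, beta) {
  K <- grid
  Astar <- t(cell$inv)            # columns are reciprocal vectors
  ms <- lapply(1:3, function(d) {
    m <- 0:(K[d] - 1)
    ifelse(m > K[d] / 2, m - K[d], m)
  })
  B1 <- bspline_modulus(K[1], order)
  B2 <- bspline_modulus(K[2], order)
  B3 <- bspline_modulus(K[3], order)
  out <- array(0, K)
  # vectorized m^2 over the grid
  mx <- array(0, K); my <- array(0, K); mz <- array(0, K)
  for (d in 1:3) {
    shape <- c(1, 1, 1); shape[d] <- K[d]
    mv <- array(rep(ms[[d]], times = prod(K) / K[d]), K[c(d, setdiff(1:3, d))])
    mv <- aperm(mv, order(c(d, setdiff(1:3, d))))
    mx <- mx + Astar[1, d] * mv
    my <- my + Astar[2, d] * mv
    mz <- mz + Astar[3, d] * mv
  }
  msq <- mx^2 + my^2 + mz^2
  Bm <- outer(outer(B1, B2), B3)
  ok <- msq > 1e-12 & Bm > 1e-10
  out[ok] <- exp(-pi^2 * msq[ok] / beta^2) / (2 * pi * cell$volume * msq[ok]) /
    Bm[ok]
  out
}

# Per-atom spline data: weights, derivative products and target grid indices.
# D is the chain matrix d u_d / d x_gamma = K_d * inv(A)[d, gamma].
#' @noRd
pme_atom_splines <- function(xyz_row, cell, K, order, dmax) {
  s <- as.vector(cell$inv %*% xyz_row)
  s <- s - floor(s)
  u <- s * K
  ws <- lapply(1:3, function(d) bspline_weights(u[d], order, dmax))
  idx <- lapply(1:3, function(d) ((ws[[d]]$k0 - order + 1):ws[[d]]$k0) %% K[d] + 1)
  # derivative chain: du_d/dx_gamma
  D <- K * cell$inv               # row d scaled by K_d
  list(w = lapply(ws, `[[`, "w"), idx = idx, D = D)
}

# product array of per-dimension spline vectors with derivative orders
# (o1, o2, o3)
#' @noRd
.spl_prod <- function(w, o) {
  outer(outer(w[[1]][[o[1] + 1]], w[[2]][[o[2] + 1]]), w[[3]][[o[3] + 1]])
}

# Spread multipole sources onto the grid.  M: n x 13 global moments (any
# rows of all-zeros are skipped).  Returns the real source grid.
#' @noRd
pme_spread <- function(M, spl, K) {
  Q <- array(0, K)
  n <- nrow(M)
  for (i in seq_len(n)) {
    mi <- M[i, ]
    if (all(mi == 0)) next
    sp <- spl[[i]]
    D <- sp$D
    c0 <- mi[1]
    d_frac <- as.vector(D %*% mi[2:4])
    Qc <- matrix(mi[5:13], 3, 3) / 3
    Q_frac <- D %*% Qc %*% t(D)
    arr <- c0 * .spl_prod(sp$w, c(0, 0, 0))
    if (any(mi[2:4] != 0) || any(mi[5:13] != 0)) {
      for (d in 1:3) {
        if (d_frac[d] != 0) {
          o <- c(0, 0, 0); o[d] <- 1
          arr <- arr + d_frac[d] * .spl_prod(sp$w, o)
        }
      }
      for (d in 1:3) for (e in d:3) {
        coef <- if (d == e) Q_frac[d, d] else 2 * Q_frac[d, e]
        if (coef != 0) {
          o <- c(0, 0, 0); o[d] <- o[d] + 1; o[e] <- o[e] + 1
          arr <- arr + coef * .spl_prod(sp$w, o)
        }
      }
    }
    Q[sp$idx[[1]], sp$idx[[2]], sp$idx[[3]]] <-
      Q[sp$idx[[1]], sp$idx[[2]], sp$idx[[3]]] + arr
  }
  Q
}

# Gather dU/dM (13 components) at each atom from a potential grid.
#' @noRd
pme_gather_phi <- function(phi, spl, n) {
  out <- matrix(0, n, 13)
  for (i in seq_len(n)) {
    sp <- spl[[i]]
    sub <- phi[sp$idx[[1]], sp$idx[[2]], sp$idx[[3]]]
    D <- sp$D
    out[i, 1] <- sum(sub * .spl_prod(sp$w, c(0, 0, 0)))
    g_frac <- numeric(3)
    for (d in 1:3) {
      o <- c(0, 0, 0); o[d] <- 1
      g_frac[d] <- sum(sub * .spl_prod(sp$w, o))
    }
    out[i, 2:4] <- as.vector(t(D) %*% g_frac)
    H <- matrix(0, 3, 3)
    for (d in 1:3) for (e in d:3) {
      o <- c(0, 0, 0); o[d] <- o[d] + 1; o[e] <- o[e] + 1
      H[d, e] <- H[e, d] <- sum(sub * .spl_prod(sp$w, o))
    }
    Hc <- t(D) %*% H %*% D
    out[i, 5:13] <- as.vector(Hc) / 3
  }
  out
}

# Cartesian gradient of the cross energy sum_g phi(g) * Q_i(g; x_i) for each
# atom's own spreading coefficients.
#' @noRd
pme_gather_force <- function(phi, spl, M) {
  n <- nrow(M)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    mi <- M[i, ]
    if (all(mi == 0)) next
    sp <- spl[[i]]
    sub <- phi[sp$idx[[1]], sp$idx[[2]], sp$idx[[3]]]
    D <- sp$D
    c0 <- mi[1]
    d_frac <- as.vector(D %*% mi[2:4])
    Q_frac <- D %*% (matrix(mi[5:13], 3, 3) / 3) %*% t(D)
    hasd <- any(mi[2:4] != 0); hasQ <- any(mi[5:13] != 0)
    # derivative w.r.t. fractional coordinate u_f of the spread coefficients
    g_frac <- numeric(3)
    for (f in 1:3) {
      o <- c(0, 0, 0); o[f] <- 1
      acc <- c0 * sum(sub * .spl_prod(sp$w, o))
      if (hasd || hasQ) {
        for (d in 1:3) {
          if (d_frac[d] != 0) {
            o2 <- o; o2[d] <- o2[d] + 1
            acc <- acc + d_frac[d] * sum(sub * .spl_prod(sp$w, o2))
          }
        }
        for (d in 1:3) for (e in d:3) {
          coef <- if (d == e) Q_frac[d, d] else 2 * Q_frac[d, e]
          if (coef != 0) {
            o2 <- o; o2[d] <- o2[d] + 1; o2[e] <- o2[e] + 1
            acc <- acc + coef * sum(sub * .spl_prod(sp$w, o2))
          }
        }
      }
      g_frac[f] <- acc
    }
    out[i, ] <- as.vector(t(D) %*% g_frac)
  }
  out
}

#' Reciprocal-space PME energy of permanent multipoles
#'
#' B-spline spreading of charge, dipole and quadrupole sources, convolution
#' with the Ewald influence function via forward/inverse FFT, and per-site
#' reciprocal potential/field/field-gradient (as dU/dM components) for reuse
#' by the state-derivative contraction.
#'
#' @param system a [cph_system()] with a periodic cell.
#' @param M n x 13 matrix of global-frame moments.
#' @param config list with `beta`, `grid` (length-3 integer), `order`.
#' @param gradient compute Cartesian forces.
#' @return list with `energy` (kcal/mol, k_e included), `phi_m` (n x 13,
#'   dU/dM at each site), `forces`, and the raw potential grid + spline data
#'   for cross-term reuse.
#' @export
pme_reciprocal <- function(system, M, config, gradient = TRUE) {
  cell <- system$cell
  if (is.null(cell)) stop("PME requires a periodic cell")
  K <- as.integer(config$grid)
  if (length(K) == 1) K <- rep(K, 3)
  if (any(K <= 0)) stop("PME grid dimensions must be positive")
  order <- config$order %||% 5L
  if (any(K < 2 * order)) stop("PME grid must be at least twice the spline order")
  beta <- config$beta
  dmax <- if (gradient) 3L else 2L
  spl <- lapply(seq_len(system$n), function(i)
    pme_atom_splines(system$xyz[i, ], cell, K, order, dmax))
  Qg <- pme_spread(M, spl, K)
  cinf <- config$influence %||% pme_influence(cell, K, order, beta)
  Fq <- stats::fft(Qg)
  phi <- 2 * Re(stats::fft(cinf * Fq, inverse = TRUE))
  U <- 0.5 * sum(Qg * phi) * KCOUL
  phi_m <- pme_gather_phi(phi, spl, system$n) * KCOUL
  forces <- NULL
  if (gradient) forces <- -pme_gather_force(phi, spl, M) * KCOUL
  list(energy = U, phi_m = phi_m, forces = forces, grid = phi, spl = spl,
       Qgrid = Qg, influence = cinf, K = K, order = order)
}

#' Contract reciprocal potentials with state derivatives of the moments
#'
#' Given the per-site reciprocal `dU/dM` from [pme_reciprocal()] and the
#' state derivatives of the global moments, returns dU_rec/d(lambda or zeta)
#' for every extended variable without a second FFT pass.
#'
#' @param phi_m n x 13 matrix of dU/dM.
#' @param dM sparse state-derivative structure from the interpolated system.
#' @return numeric vector over extended variables.
#' @export
recip_lambda_derivative <- function(phi_m, dM) {
  vapply(dM, function(dk) {
    if (!length(dk$atoms)) return(0)
    sum(dk$m * phi_m[dk$atoms, , drop = FALSE])
  }, numeric(1))
}
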