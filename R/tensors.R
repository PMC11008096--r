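# Cartesian interaction tensors for point multipoles.
#
# All pair interactions (permanent multipole energies, polarization fields,
# and their Cartesian derivatives) are generated from a single radial kernel
# F_n, n = 0..5, obeying the gradient recursion  grad F_n(r) = -x F_{n+1},
# where x = x_i - x_j.  Three kernels share this recursion and can therefore
# be combined linearly with constant coefficients:
#   - Coulomb:        C_n = (2n-1)!! / r^(2n+1)
#   - Ewald real:     B_n = recursion on erfc(beta r)/r
#   - Thole-damped:   lam_{2n+1}(u) * C_n  (exponential smeared-charge form)
# Masked/damped real-space kernels are built as B_n - (1-s) C_n (permanent)
# or B_n - C_n + s lam_n C_n (induction channels).

DOUBLE_FACT <- c(1, 1, 3, 15, 105, 945)  # (2n-1)!! for n = 0..5

#' @noRd
bn_coulomb <- function(r, nmax = 5L) {
  n <- 0:nmax
  DOUBLE_FACT[n + 1] / r^(2 * n + 1)
}

#' @noRd
bn_ewald <- function(r, beta, nmax = 5L) {
  out <- numeric(nmax + 1)
  br <- beta * r
  expterm <- exp(-br * br)
  out[1] <- erfc(br) / r
  r2 <- r * r
  tb2 <- 2 * beta * beta
  fac <- 1 / (beta * sqrt(pi))
  for (n in 0:(nmax - 1)) {
    out[n + 2] <- ((2 * n + 1) * out[n + 1] + tb2^(n + 1) * expterm * fac) / r2
  }
  out
}

#' @noRd
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Thole damping factors lam_{2n+1} for the exponential charge density
# rho ~ exp(-a u^3), u = r / (alpha_i alpha_j)^(1/6).  Order n multiplies C_n.
#' @noRd
thole_factors <- function(r, gamma, a = 0.39, nmax = 5L) {
  if (!is.finite(gamma) || gamma <= 0) return(rep(1, nmax + 1))
  u3 <- (r / gamma)^3
  au3 <- a * u3
  e <- exp(-au3)
  lam <- numeric(nmax + 1)
  # order 0 (potential-potential) has no elementary damped form; it is never
  # used by any induction channel (fields start at order 1), so keep it at 1
  lam[1] <- 1
  if (nmax >= 1) lam[2] <- 1 - e                          # lam3
  if (nmax >= 2) lam[3] <- 1 - (1 + au3) * e              # lam5
  if (nmax >= 3) lam[4] <- 1 - (1 + au3 + 0.6 * au3^2) * e            # lam7
  if (nmax >= 4) lam[5] <- 1 - (1 + au3 + (18 / 35) * au3^2 +
                                  (9 / 35) * au3^3) * e               # lam9
  if (nmax >= 5) lam[6] <- .lam11(au3, e)
  lam
}

# lam11 from Bd_5 = -(1/r) d/dr Bd_4 with Bd_4 = 105 lam9 / r^9:
# lam11 = (9 lam9 - r lam9')/9 where lam9 = 1 - bracket9 e, so that
# r lam9' = -r d(bracket9 e)/dr.
#' @noRd
.lam11 <- function(au3, e) {
  t <- au3
  rdb <- e * ((3 / 35) * t^2 + (27 / 35) * t^3 - (27 / 35) * t^4)
  lam9 <- 1 - (1 + t + (18 / 35) * t^2 + (9 / 35) * t^3) * e
  (9 * lam9 + rdb) / 9
}

# Effective radial kernel for one pair and one interaction channel.
#   scale : mask scale factor s in [0,1]
#   gamma : Thole damping width (alpha_i alpha_j)^(1/6), NULL to disable
#   beta  : Ewald splitting parameter, NULL for vacuum (plain Coulomb)
# For the permanent channel Thole damping is off (gamma = NULL).
#' @noRd
kernel_radial <- function(r, beta = NULL, scale = 1, gamma = NULL,
                          thole_a = 0.39, nmax = 5L) {
  Cn <- bn_coulomb(r, nmax)
  lam <- if (is.null(gamma)) rep(1, nmax + 1) else
    thole_factors(r, gamma, thole_a, nmax)
  if (is.null(beta)) {
    scale * lam * Cn
  } else {
    Bn <- bn_ewald(r, beta, nmax)
    Bn - Cn + scale * lam * Cn
  }
}

# ---------------------------------------------------------------------------
# Symmetric tensor assembly.  Permutation tables are computed once.

.tensor_env <- new.env(parent = emptyenv())

.delta_perms <- function() {
  if (!is.null(.tensor_env$ready)) return(invisible(NULL))
  # rank 3: delta at (p,q), x at remaining position
  .tensor_env$p3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  # rank 4: delta pair positions among 4 (6 of them), xx at rest
  prs4 <- utils::combn(4, 2, simplify = FALSE)
  .tensor_env$p4dxx <- lapply(prs4, function(p) c(p, setdiff(1:4, p)))
  # rank 4: delta-delta pairings (3)
  .tensor_env$p4dd <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  # rank 5: delta pair + xxx (10)
  prs5 <- utils::combn(5, 2, simplify = FALSE)
  .tensor_env$p5dxxx <- lapply(prs5, function(p) c(p, setdiff(1:5, p)))
  # rank 5: delta-delta + x (15 pairings)
  dd <- list()
  for (p in prs5) {
    rest <- setdiff(1:5, p)
    sub <- utils::combn(rest, 2, simplify = FALSE)
    for (q in sub) {
      if (p[1] < q[1]) dd[[length(dd) + 1]] <- c(p, q, setdiff(rest, q))
    }
  }
  .tensor_env$p5ddx <- dd
  .tensor_env$ready <- TRUE
  invisible(NULL)
}

.sum_perms <- function(base, perms) {
  out <- aperm(base, order(perms[[1]]))
  if (length(perms) > 1) {
    for (k in 2:length(perms)) out <- out + aperm(base, order(perms[[k]]))
  }
  out
}

# Interaction tensors T^(0..maxord) for separation x (= x_i - x_j) and radial
# kernel F (orders 0..maxord).  T^(n) = grad^n applied to F_0 viewed through
# the recursion above.
#' @noRd
build_tensors <- function(x, F, maxord = 4L) {
  .delta_perms()
  I3 <- diag(3)
  out <- vector("list", maxord + 1)
  out[[1]] <- F[1]
  if (maxord >= 1) out[[2]] <- -x * F[2]
  xx <- outer(x, x)
  if (maxord >= 2) out[[3]] <- xx * F[3] - I3 * F[2]
  if (maxord >= 3) {
    x3 <- outer(xx, x)
    dx <- .sum_perms(outer(I3, x), .tensor_env$p3)
    out[[4]] <- -x3 * F[4] + dx * F[3]
  }
  if (maxord >= 4) {
    x3 <- outer(xx, x)
    x4 <- outer(x3, x)
    dxx <- .sum_perms(outer(I3, xx), .tensor_env$p4dxx)
    dd <- .sum_perms(outer(I3, I3), .tensor_env$p4dd)
    out[[5]] <- x4 * F[5] - dxx * F[4] + dd * F[3]
  }
  if (maxord >= 5) {
    x3 <- outer(xx, x)
    x5 <- outer(outer(x3, x), x)
    dxxx <- .sum_perms(outer(I3, x3), .tensor_env$p5dxxx)
    ddx <- .sum_perms(outer(outer(I3, I3), x), .tensor_env$p5ddx)
    out[[6]] <- -x5 * F[6] + dxxx * F[5] - ddx * F[4]
  }
  out
}

# contract the last index of tensor T with vector v
#' @noRd
ctr1 <- function(T, v) {
  d <- dim(T)
  if (is.null(d)) stop("ctr1 needs an array")
  res <- matrix(T, nrow = prod(d) / 3, ncol = 3) %*% v
  if (length(d) == 2) as.vector(res) else array(res, d[-length(d)])
}

# contract the last two indices of tensor T with 3x3 matrix M
#' @noRd
ctr2 <- function(T, M) {
  d <- dim(T)
  res <- matrix(T, nrow = prod(d) / 9, ncol = 9) %*% as.vector(M)
  if (length(d) == 3) as.vector(res) else
    if (length(d) == 2) drop(res) else array(res, d[1:(length(d) - 2)])
}

# 13-vector layout for a permanent multipole: q, dx, dy, dz, then the full
# 3x3 quadrupole in column-major order.  The energy convention contracts the
# stored quadrupole with a factor 1/3 (traceless Cartesian convention).
#' @noRd
m13 <- function(q = 0, d = c(0, 0, 0), Q = matrix(0, 3, 3)) {
  c(q, d, as.vector(Q))
}

#' @noRd
m13_q <- function(m) m[1]
#' @noRd
m13_d <- function(m) m[2:4]
#' @noRd
m13_Q <- function(m) matrix(m[5:13], 3, 3)

# "Potential vector" at site i due to multipole m_j a distance x away:
# phi[k] = dU_pair/d m_i[k] (for unit k_e), using tensors T (orders 0..4).
# Signs: source operator picks up (-1)^{order of b}.
#' @noRd
phi13 <- function(T, mj, with_quad_rows = TRUE) {
  q <- mj[1]; d <- mj[2:4]
  hasd <- any(d != 0); hasQ <- any(mj[5:13] != 0)
  out <- numeric(13)
  out[1] <- q * T[[1]]
  out[2:4] <- q * T[[2]]
  if (with_quad_rows) out[5:13] <- as.vector(q * T[[3]]) / 3
  if (hasd) {
    out[1] <- out[1] - sum(d * T[[2]])
    out[2:4] <- out[2:4] - ctr1(T[[3]], d)
    if (with_quad_rows) out[5:13] <- out[5:13] - as.vector(ctr1(T[[4]], d)) / 3
  }
  if (hasQ) {
    Q <- matrix(mj[5:13], 3, 3) / 3
    out[1] <- out[1] + ctr2(T[[3]], Q)
    out[2:4] <- out[2:4] + ctr2(T[[4]], Q)
    if (with_quad_rows) out[5:13] <- out[5:13] + as.vector(ctr2(T[[5]], Q)) / 3
  }
  out
}

# Derivative of phi13 with respect to x (= x_i - x_j): a 13 x 3 matrix,
# needing tensors up to order 5.  dU_pair/dx = m_i %*% dphi13.
#' @noRd
dphi13 <- function(T, mj, with_quad_rows = TRUE) {
  q <- mj[1]; d <- mj[2:4]
  hasd <- any(d != 0); hasQ <- any(mj[5:13] != 0)
  out <- matrix(0, 13, 3)
  out[1, ] <- q * T[[2]]
  out[2:4, ] <- q * T[[3]]
  if (with_quad_rows) out[5:13, ] <- matrix(q * T[[4]], 9, 3) / 3
  if (hasd) {
    out[1, ] <- out[1, ] - ctr1(T[[3]], d)
    out[2:4, ] <- out[2:4, ] - ctr1(T[[4]], d)
    if (with_quad_rows) out[5:13, ] <- out[5:13, ] - matrix(ctr1(T[[5]], d), 9, 3) / 3
  }
  if (hasQ) {
    Q <- matrix(mj[5:13], 3, 3) / 3
    out[1, ] <- out[1, ] + ctr2(T[[4]], Q)
    out[2:4, ] <- out[2:4, ] + ctr2(T[[5]], Q)
    if (with_quad_rows) out[5:13, ] <- out[5:13, ] + matrix(ctr2(T[[6]], Q), 9, 3) / 3
  }
  out
}
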