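# Induced-dipole self-consistent field with Thole damping and group-based
# masking; polarization energy, Cartesian gradient, and the single-SCF
# extended-variable derivative.
#
# Two permanent field sets are maintained: the direct field E_d (polarization
# group masking; sources within a group do not induce each other) drives the
# dipoles mu, and the energy field E_p (bonded p-mask) defines the energy
# U = -1/2 mu . E_p.  The exact gradient additionally needs the auxiliary
# dipoles nu solved against E_p; in vacuum with equal masks nu = mu.
# Under PBC all field pieces decompose into real (erfc + mask/Thole
# corrections), reciprocal (PME) and self contributions.

# channel mask scale for a pair: "d" (group), "p" (bonded), "u" (mutual)
#' @noRd
pol_scale <- function(channel, system, i, j, paths, pscales) {
  if (channel == "d") {
    if (system$polar$group[i] == system$polar$group[j]) 0 else 1
  } else if (channel == "p") {
    p <- paths[i, j]
    if (p <= 1L) 1.0 else pscales[p - 1L]
  } else 1.0
}

#' @noRd
pol_gamma <- function(gm, i, j) {
  ai <- gm$damp_alpha[i]; aj <- gm$damp_alpha[j]
  if (ai <= 0 || aj <= 0) return(NULL)
  (ai * aj)^(1 / 6)
}

#' Permanent multipole fields at every atom
#'
#' Computes the group-masked direct field `E_d` and the bonded-masked energy
#' field `E_p` (kcal/mol/e/Angstrom), including reciprocal and self
#' contributions under PBC.
#'
#' @param system a [cph_system()].
#' @param gm global moments structure.
#' @param config electrostatics config (`beta` NULL for vacuum, `cutoff`,
#'   `thole_a`, optional `recip` = result of [pme_reciprocal()] for reuse).
#' @return list with matrices `E_d`, `E_p` (n x 3).
#' @export
compute_fields <- function(system, gm, config) {
  n <- system$n
  beta <- config$beta
  paths <- config$paths %||% bond_paths(system)
  prs <- config$pairs %||% elec_pairs(system, config$cutoff %||% Inf, paths)
  pscales <- system$params$scales$`polar-p` %||% c(0, 0, 1, 1)
  a_thole <- config$thole_a %||% 0.39
  E_d <- matrix(0, n, 3); E_p <- matrix(0, n, 3)
  M <- gm$M
  for (p in prs) {
    i <- p$i; j <- p$j; r <- p$r
    gam <- pol_gamma(gm, i, j)
    at <- min(system$polar$thole[i], system$polar$thole[j], a_thole)
    for (ch in c("d", "p")) {
      s <- pol_scale(ch, system, i, j, paths, pscales)
      Fk <- .pol_kernel(r, beta, s, gam, at, p$in_cut, 3L)
      if (all(Fk == 0)) next
      if (!all(M[j, ] == 0)) {
        T <- build_tensors(p$dx, Fk, 3L)
        ph <- phi13(T, M[j, ], with_quad_rows = FALSE)
        fld <- -KCOUL * ph[2:4]
        if (ch == "d") E_d[i, ] <- E_d[i, ] + fld else E_p[i, ] <- E_p[i, ] + fld
      }
      if (!all(M[i, ] == 0)) {
        T <- build_tensors(-p$dx, Fk, 3L)
        ph <- phi13(T, M[i, ], with_quad_rows = FALSE)
        fld <- -KCOUL * ph[2:4]
        if (ch == "d") E_d[j, ] <- E_d[j, ] + fld else E_p[j, ] <- E_p[j, ] + fld
      }
    }
  }
  if (!is.null(beta)) {
    rc <- config$recip
    if (is.null(rc)) rc <- pme_reciprocal(system, M, config, gradient = FALSE)
    Erec <- -rc$phi_m[, 2:4, drop = FALSE]
    Eself <- KCOUL * (4 * beta^3 / (3 * sqrt(pi))) * M[, 2:4, drop = FALSE]
    E_d <- E_d + Erec + Eself
    E_p <- E_p + Erec + Eself
  }
  list(E_d = E_d, E_p = E_p)
}

# effective kernel for induction channels (orders 0..maxord)
#' @noRd
.pol_kernel <- function(r, beta, s, gam, at, in_cut, maxord) {
  Cn <- bn_coulomb(r, maxord)
  lam <- if (is.null(gam)) rep(1, maxord + 1) else
    thole_factors(r, gam, at, maxord)
  if (is.null(beta)) {
    s * lam * Cn
  } else {
    Bn <- if (in_cut) bn_ewald(r, beta, maxord) else numeric(maxord + 1)
    Bn - Cn + s * lam * Cn
  }
}

# field at all atoms due to a set of point dipoles (n x 3), u-channel
# (Thole damped, unmasked), including PME recip + self under PBC.
# Returns list(field, phi_grid) so converged grids can be reused.
#' @noRd
dipole_field <- function(system, gm, mu, config, want_grid = FALSE) {
  n <- system$n
  beta <- config$beta
  prs <- config$pairs %||% elec_pairs(system, config$cutoff %||% Inf,
                                      config$paths %||% bond_paths(system))
  a_thole <- config$thole_a %||% 0.39
  E <- matrix(0, n, 3)
  for (p in prs) {
    i <- p$i; j <- p$j
    gam <- pol_gamma(gm, i, j)
    at <- min(system$polar$thole[i], system$polar$thole[j], a_thole)
    Fk <- .pol_kernel(p$r, beta, 1, gam, at, p$in_cut, 2L)
    if (all(Fk == 0)) next
    T2 <- build_tensors(p$dx, Fk, 2L)[[3]]
    if (any(mu[j, ] != 0)) E[i, ] <- E[i, ] + KCOUL * as.vector(T2 %*% mu[j, ])
    if (any(mu[i, ] != 0)) E[j, ] <- E[j, ] + KCOUL * as.vector(T2 %*% mu[i, ])
  }
  grid <- NULL
  if (!is.null(beta)) {
    Mmu <- cbind(0, mu, matrix(0, n, 9))
    rc <- pme_reciprocal(system, Mmu, config, gradient = FALSE)
    E <- E - rc$phi_m[, 2:4, drop = FALSE] +
      KCOUL * (4 * beta^3 / (3 * sqrt(pi))) * mu
    if (want_grid) grid <- rc
  }
  list(field = E, recip = grid)
}

#' Solve the induced-dipole self-consistent field
#'
#' Preconditioned conjugate gradient on the symmetric system
#' `(alpha^-1 - T11) mu = E` over sites with positive polarizability,
#' initialized from the direct dipoles `mu0 = alpha E`.  Zero-polarizability
#' sites carry exactly zero dipole.
#'
#' @param system,gm,config as in [compute_fields()].
#' @param E right-hand-side field (n x 3), e.g. `E_d`.
#' @param tol convergence tolerance on the max induced-dipole component
#'   change (e*Angstrom), default `config$scf_tol` or 1e-6.
#' @param max_iter iteration cap (default 100).
#' @return list with `mu` (n x 3), `iterations`, `residual`, `converged`.
#' @export
scf_solve <- function(system, gm, E, config, tol = NULL, max_iter = NULL) {
  tol <- tol %||% config$scf_tol %||% 1e-6
  max_iter <- max_iter %||% config$scf_max_iter %||% 100L
  alpha <- gm$alpha
  act <- which(alpha > 0)
  n <- system$n
  mu <- matrix(0, n, 3)
  if (!length(act)) {
    return(list(mu = mu, iterations = 0L, converged = TRUE, residual = 0))
  }
  # fields are in kcal/mol/e/Angstrom, dipoles in e*Angstrom: the effective
  # polarizability in these units is alpha / k_e
  amat <- matrix(alpha / KCOUL, n, 3)
  Aop <- function(m) {
    # (alpha^-1 - T) m over active sites
    f <- dipole_field(system, gm, m, config)$field
    out <- m / amat - f
    out[-act, ] <- 0
    out[alpha == 0, ] <- 0
    out
  }
  b <- E
  b[-act, ] <- 0
  x <- amat * b; x[-act, ] <- 0
  r <- b - Aop(x); r[-act, ] <- 0
  z <- amat * r
  if (max(abs(z)) < tol) {
    # direct-field initialization already solves the system (no mutual
    # coupling): report the single evaluation
    return(list(mu = x, iterations = 1L, converged = TRUE,
                residual = max(abs(z))))
  }
  p <- z
  rz <- sum(r * z)
  it <- 0L
  res_hist <- numeric(0)
  repeat {
    it <- it + 1L
    Ap <- Aop(p)
    a_step <- rz / sum(p * Ap)
    dx <- a_step * p
    x <- x + dx
    r <- r - a_step * Ap; r[-act, ] <- 0
    res <- max(abs(dx))
    res_hist <- c(res_hist, res)
    if (res < tol || it >= max_iter) break
    z <- amat * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  conv <- max(abs(dx)) < tol
  if (!conv)
    stop("SCF failed to converge after ", it, " iterations; residual history: ",
         paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
  list(mu = x, iterations = it, converged = conv, residual = res)
}

#' Full polarization state (mu and nu dipole sets)
#'
#' Runs one SCF for the direct-field dipoles `mu` and one for the
#' energy-field auxiliaries `nu`, stores the total fields at every site
#' needed by the single-SCF state derivative, and (under PBC) the converged
#' reciprocal grids.
#'
#' @inheritParams compute_fields
#' @param tol,max_iter forwarded to [scf_solve()].
#' @return object of class `cph_scf`.
#' @export
polarization_scf <- function(system, gm, config, tol = NULL, max_iter = NULL) {
  flds <- compute_fields(system, gm, config)
  s_mu <- scf_solve(system, gm, flds$E_d, config, tol, max_iter)
  s_nu <- scf_solve(system, gm, flds$E_p, config, tol, max_iter)
  fm <- dipole_field(system, gm, s_mu$mu, config, want_grid = TRUE)
  fn <- dipole_field(system, gm, s_nu$mu, config, want_grid = TRUE)
  structure(list(
    mu = s_mu$mu, nu = s_nu$mu,
    E_d = flds$E_d, E_p = flds$E_p,
    F_d = flds$E_d + fm$field,    # total field sustaining mu
    F_p = flds$E_p + fn$field,
    recip_mu = fm$recip, recip_nu = fn$recip,
    iterations = s_mu$iterations + s_nu$iterations,
    residual = max(s_mu$residual, s_nu$residual),
    converged = s_mu$converged && s_nu$converged
  ), class = "cph_scf")
}

#' Polarization energy
#'
#' `U_pol = -1/2 mu . E_p` from a converged SCF state.
#'
#' @param scf a `cph_scf` from [polarization_scf()].
#' @return energy in kcal/mol.
#' @export
polarization_energy <- function(scf) {
  if (!isTRUE(scf$converged)) stop("polarization energy requires a converged SCF")
  -0.5 * sum(scf$mu * scf$E_p)
}

#' Polarization Cartesian gradient and dU/dM accumulation
#'
#' Analytic gradient `-1/2 [Edot_p.mu + Edot_d.nu + nu^T Tdot11 mu]`
#' including Thole-damped tensor derivatives, PME reciprocal cross terms and
#' the self/surface pieces; also returns dU_pol/dM for the frame (torque)
#' chain and the state-derivative contraction.
#'
#' @param system,gm,config as in [compute_fields()].
#' @param scf converged `cph_scf`.
#' @return list with `forces` (n x 3, without frame chain) and `phi_m`
#'   (n x 13).
#' @export
polarization_gradient <- function(system, gm, scf, config) {
  n <- system$n
  beta <- config$beta
  paths <- config$paths %||% bond_paths(system)
  prs <- config$pairs %||% elec_pairs(system, config$cutoff %||% Inf, paths)
  pscales <- system$params$scales$`polar-p` %||% c(0, 0, 1, 1)
  a_thole <- config$thole_a %||% 0.39
  M <- gm$M
  mu <- scf$mu; nu <- scf$nu
  forces <- matrix(0, n, 3)
  phi_m <- matrix(0, n, 13)
  m13d <- function(v) c(0, v, rep(0, 9))
  for (p in prs) {
    i <- p$i; j <- p$j; r <- p$r
    gam <- pol_gamma(gm, i, j)
    at <- min(system$polar$thole[i], system$polar$thole[j], a_thole)
    # (a) permanent-field terms, channels p (with mu) and d (with nu)
    for (ch in c("p", "d")) {
      s <- pol_scale(ch, system, i, j, paths, pscales)
      Fk <- .pol_kernel(r, beta, s, gam, at, p$in_cut, 5L)
      if (all(Fk == 0)) next
      w <- if (ch == "p") mu else nu
      Tij <- build_tensors(p$dx, Fk, 5L)
      Tji <- build_tensors(-p$dx, Fk, 5L)
      # U_pair = 1/2 m_w(i) . phi(T_ij, M_j) + 1/2 m_w(j) . phi(T_ji, M_i)
      if (any(w[i, ] != 0)) {
        mwi <- m13d(w[i, ] / 2)
        g <- KCOUL * as.vector(mwi %*% dphi13(Tij, M[j, ], with_quad_rows = FALSE))
        forces[i, ] <- forces[i, ] - g
        forces[j, ] <- forces[j, ] + g
        phi_m[j, ] <- phi_m[j, ] + KCOUL * phi13(Tji, mwi)
      }
      if (any(w[j, ] != 0)) {
        mwj <- m13d(w[j, ] / 2)
        g <- KCOUL * as.vector(mwj %*% dphi13(Tji, M[i, ], with_quad_rows = FALSE))
        forces[j, ] <- forces[j, ] - g
        forces[i, ] <- forces[i, ] + g
        phi_m[i, ] <- phi_m[i, ] + KCOUL * phi13(Tij, mwj)
      }
    }
    # (b) mutual term -1/2 nu^T Tdot mu: pair orderings (nu_i, mu_j), (nu_j, mu_i)
    Fk <- .pol_kernel(r, beta, 1, gam, at, p$in_cut, 3L)
    if (!all(Fk == 0)) {
      Tij <- build_tensors(p$dx, Fk, 3L)
      Tji <- build_tensors(-p$dx, Fk, 3L)
      if (any(nu[i, ] != 0) && any(mu[j, ] != 0)) {
        g <- KCOUL * as.vector(m13d(nu[i, ] / 2) %*%
                                 dphi13(Tij, m13d(mu[j, ]), with_quad_rows = FALSE))
        forces[i, ] <- forces[i, ] - g
        forces[j, ] <- forces[j, ] + g
      }
      if (any(nu[j, ] != 0) && any(mu[i, ] != 0)) {
        g <- KCOUL * as.vector(m13d(nu[j, ] / 2) %*%
                                 dphi13(Tji, m13d(mu[i, ]), with_quad_rows = FALSE))
        forces[j, ] <- forces[j, ] - g
        forces[i, ] <- forces[i, ] + g
      }
    }
  }
  if (!is.null(beta)) {
    # reciprocal cross terms via the converged dipole grids
    rcM <- config$recip
    if (is.null(rcM)) rcM <- pme_reciprocal(system, M, config, gradient = FALSE)
    phi_S <- (scf$recip_mu$grid + scf$recip_nu$grid) / 2
    Smat <- cbind(0, (mu + nu) / 2, matrix(0, n, 9))
    spl <- rcM$spl
    # term (a) recip: X(S, M)
    forces <- forces - KCOUL * (pme_gather_force(rcM$grid, spl, Smat) +
                                  pme_gather_force(phi_S, spl, M))
    phi_m <- phi_m + KCOUL * pme_gather_phi(phi_S, spl, n)
    # term (b) recip: value +1/2 X(nu, mu)
    Mnu <- cbind(0, nu, matrix(0, n, 9))
    Mmu <- cbind(0, mu, matrix(0, n, 9))
    forces <- forces -
      KCOUL * 0.5 * (pme_gather_force(scf$recip_mu$grid, spl, Mnu) +
                       pme_gather_force(scf$recip_nu$grid, spl, Mmu))
    # self pieces: (a) -k (2 beta^3/(3 sqrt(pi))) sum (mu+nu) . d_perm
    cs <- KCOUL * 2 * beta^3 / (3 * sqrt(pi))
    phi_m[, 2:4] <- phi_m[, 2:4] - cs * (mu + nu)
  }
  list(forces = forces, phi_m = phi_m)
}

#' Single-SCF extended-variable derivative of the polarization energy
#'
#' From one converged SCF state: the permanent-derivative field terms are
#' the contraction of `dM` with `dU_pol/dM`; the diagonal polarizability
#' term is `-1/2 sum_i dalpha_i F_p(i) . F_d(i)` over the atoms of the
#' titrating site, written with the total fields so it remains finite when
#' `alpha -> 0`.  No SCF re-solve is performed here.
#'
#' @param gm global moments structure.
#' @param scf converged `cph_scf`.
#' @param phi_m_pol dU_pol/dM from [polarization_gradient()].
#' @return vector of dU_pol/d(lambda or zeta) over extended variables.
#' @export
polarization_lambda_derivative <- function(gm, scf, phi_m_pol) {
  nth <- length(gm$dM)
  out <- numeric(nth)
  for (k in seq_len(nth)) {
    dk <- gm$dM[[k]]
    if (length(dk$atoms))
      out[k] <- sum(dk$m * phi_m_pol[dk$atoms, , drop = FALSE])
    da <- gm$dAlpha[[k]]
    if (length(da$atoms)) {
      Fd <- scf$F_d[da$atoms, , drop = FALSE]
      Fp <- scf$F_p[da$atoms, , drop = FALSE]
      out[k] <- out[k] - 0.5 * sum(da$a * rowSums(Fp * Fd)) / KCOUL
    }
  }
  out
}
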