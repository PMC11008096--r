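# Permanent multipole electrostatics under periodic boundary conditions:
# real-space Ewald (with optional charge-charge soft core), reciprocal-space
# PME, self and uniform-background (neutrality) corrections.  Energies,
# Cartesian forces including frame (torque) chain terms, and analytic
# lambda/zeta derivatives via contraction of dU/dM with the rotated state
# derivatives of the moments.

# pair list within a cutoff under minimum image, always including bonded
# masked pairs (path <= 5) so mask corrections are applied beyond cutoff
#' @noRd
elec_pairs <- function(system, cutoff, paths) {
  n <- system$n
  out <- list()
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- min_image(system$xyz[i, ] - system$xyz[j, ], system$cell)
      r <- sqrt(sum(dx^2))
      masked <- paths[i, j] > 1L
      if (r < cutoff || masked)
        out[[length(out) + 1]] <- list(i = i, j = j, dx = dx, r = r,
                                       path = paths[i, j],
                                       in_cut = r < cutoff)
    }
  }
  out
}

#' Real-space permanent multipole energy
#'
#' Pairwise screened multipole interactions `erfc(beta f)/f` within the
#' cutoff under minimum image, with AMOEBA m-scale bonded masking applied as
#' complementary Coulomb corrections.  With soft core enabled for a pair,
#' `f = r + alpha_sc (1 - lambda_k lambda_l)^2` augments the charge-charge
#' component only (titrating-hydrogen moments vanish at the decoupled end
#' state); by default soft core is off and `f = r`, eliminating the
#' `df/dlambda` term from the state derivative.
#'
#' @param system a [cph_system()].
#' @param gm global moments structure (internal; from the interpolated state).
#' @param config list with `beta` (Ewald parameter, 1/Angstrom; NULL for a
#'   vacuum/direct Coulomb evaluation), `cutoff`, optional `softcore`
#'   (list `enabled`, `alpha_sc`).
#' @param gradient compute forces.
#' @return list with `energy`, `forces` (without frame chain), `phi_m`
#'   (n x 13 dU/dM), and `dlz_extra` (soft-core df/dlambda contributions).
#' @export
real_space_permanent <- function(system, gm, config, gradient = TRUE) {
  n <- system$n
  beta <- config$beta
  cutoff <- config$cutoff %||% Inf
  mscales <- system$params$scales$mpole %||% c(0, 0, 0.4, 0.8)
  paths <- config$paths %||% bond_paths(system)
  prs <- config$pairs %||% elec_pairs(system, cutoff, paths)
  M <- gm$M
  sc_cfg <- config$softcore %||% list(enabled = FALSE)
  nth <- if (is.null(system$n_theta)) 0L else system$n_theta
  # per-atom lambda coupling for soft core (titrating hydrogens)
  hlam <- rep(1, n); hsite <- rep(NA_integer_, n)
  if (isTRUE(sc_cfg$enabled)) {
    for (site in system$sites) {
      if (!is.null(site$tit_h) && nrow(site$tit_h)) {
        hlam[site$tit_h$atom] <- NA  # filled from lz by caller config
      }
    }
    hlam <- sc_cfg$hlam %||% hlam
    hsite <- sc_cfg$hsite %||% hsite
  }
  U <- 0
  forces <- matrix(0, n, 3)
  phi_m <- matrix(0, n, 13)
  dlz_extra <- numeric(max(nth, 1))
  maxord <- if (gradient) 5L else 4L
  for (p in prs) {
    i <- p$i; j <- p$j; r <- p$r
    mi <- M[i, ]; mj <- M[j, ]
    if (all(mi == 0) && all(mj == 0)) next
    s <- if (p$path > 1L) mscales[p$path - 1L] else 1.0
    if (r < 1e-6) stop("overlapping atoms ", i, " and ", j,
                       " without soft-core electrostatics")
    Bn <- if (is.null(beta)) {
      s * bn_coulomb(r, maxord)
    } else {
      ew <- if (p$in_cut) bn_ewald(r, beta, maxord) else numeric(maxord + 1)
      ew - (1 - s) * bn_coulomb(r, maxord)
    }
    if (all(Bn == 0)) next
    T <- build_tensors(p$dx, Bn, maxord)
    ph_i <- KCOUL * phi13(T, mj)
    U <- U + sum(mi * ph_i)
    phi_m[i, ] <- phi_m[i, ] + ph_i
    Tji <- build_tensors(-p$dx, Bn, maxord)
    phi_m[j, ] <- phi_m[j, ] + KCOUL * phi13(Tji, mi)
    if (gradient) {
      g <- KCOUL * as.vector(mi %*% dphi13(T, mj))
      forces[i, ] <- forces[i, ] - g
      forces[j, ] <- forces[j, ] + g
    }
    # soft-core charge-charge replacement
    if (isTRUE(sc_cfg$enabled) && (hlam[i] < 1 || hlam[j] < 1) && p$in_cut &&
        !is.null(beta)) {
      qq <- KCOUL * s * mi[1] * mj[1]
      if (qq != 0) {
        asc <- sc_cfg$alpha_sc %||% 0.7
        lp <- hlam[i] * hlam[j]
        f <- r + asc * (1 - lp)^2
        g0r <- erfc(beta * r) / r
        g0f <- erfc(beta * f) / f
        dgf <- -erfc(beta * f) / f^2 - 2 * beta * exp(-(beta * f)^2) /
          (sqrt(pi) * f)
        dU <- qq * (g0f - g0r)
        U <- U + dU
        phi_m[i, 1] <- phi_m[i, 1] + KCOUL * s * mj[1] * (g0f - g0r)
        phi_m[j, 1] <- phi_m[j, 1] + KCOUL * s * mi[1] * (g0f - g0r)
        if (gradient) {
          dgr <- -erfc(beta * r) / r^2 - 2 * beta * exp(-(beta * r)^2) /
            (sqrt(pi) * r)
          gg <- qq * (dgf - dgr) * p$dx / r
          forces[i, ] <- forces[i, ] - gg
          forces[j, ] <- forces[j, ] + gg
        }
        # df/dlambda = -2 alpha_sc (1 - lp) * d(lp)/dlambda
        for (a in c(i, j)) {
          if (!is.na(hsite[a]) && hlam[a] < 1) {
            other <- if (a == i) hlam[j] else hlam[i]
            dlz_extra[hsite[a]] <- dlz_extra[hsite[a]] +
              qq * dgf * (-2 * asc * (1 - lp)) * other
          }
        }
      }
    }
  }
  list(energy = U, forces = forces, phi_m = phi_m,
       dlz_extra = if (nth > 0) dlz_extra[seq_len(nth)] else numeric(0))
}

#' Ewald self-energy and neutrality (uniform background) correction
#'
#' The multipole self-energy removes the central-cell self-interaction
#' introduced by the reciprocal sum; the background term corrects for a net
#' charged cell, and its state derivative follows from dq_tot/dlambda.
#'
#' @param M n x 13 global moments.
#' @param config list with `beta`, `neutralize` (logical), and `boundary`
#'   (`"tinfoil"`, the default conducting boundary, or `"vacuum"` to add the
#'   spherical surface-dipole term `2 pi |P|^2 / (3 V)` used when comparing
#'   against isolated-cluster limits).
#' @param cell a [crystal_cell()].
#' @param xyz coordinates (needed only for the vacuum boundary term).
#' @return list with `energy`, `phi_m` (n x 13 dU/dM) and `forces`.
#' @export
self_and_neutrality <- function(M, config, cell, xyz = NULL) {
  beta <- config$beta
  n <- nrow(M)
  phi_m <- matrix(0, n, 13)
  q <- M[, 1]
  d2 <- rowSums(M[, 2:4, drop = FALSE]^2)
  Q2 <- rowSums(M[, 5:13, drop = FALSE]^2)
  c0 <- beta / sqrt(pi)
  U <- -KCOUL * sum(c0 * q^2 + (2 * beta^2 / 3) * c0 * d2 +
                      (8 * beta^4 / 45) * c0 * Q2)
  phi_m[, 1] <- -2 * KCOUL * c0 * q
  phi_m[, 2:4] <- -KCOUL * (4 * beta^3 / (3 * sqrt(pi))) * M[, 2:4]
  phi_m[, 5:13] <- -KCOUL * (16 * beta^5 / (45 * sqrt(pi))) * M[, 5:13]
  if (isTRUE(config$neutralize %||% TRUE)) {
    qt <- sum(q)
    Un <- -KCOUL * pi * qt^2 / (2 * beta^2 * cell$volume)
    U <- U + Un
    phi_m[, 1] <- phi_m[, 1] - KCOUL * pi * qt / (beta^2 * cell$volume)
  }
  forces <- matrix(0, n, 3)
  if (identical(config$boundary %||% "tinfoil", "vacuum")) {
    if (is.null(xyz)) stop("vacuum boundary term needs coordinates")
    P <- colSums(q * xyz) + colSums(M[, 2:4, drop = FALSE])
    pref <- 2 * pi * KCOUL / (3 * cell$volume)
    U <- U + pref * sum(P^2)
    phi_m[, 1] <- phi_m[, 1] + 2 * pref * as.vector(xyz %*% P)
    phi_m[, 2:4] <- phi_m[, 2:4] + matrix(2 * pref * P, n, 3, byrow = TRUE)
    forces <- -2 * pref * outer(q, P)
  }
  list(energy = U, phi_m = phi_m, forces = forces)
}

# ---------------------------------------------------------------------------
# Frame (torque) chain: forces arising because the global moments rotate
# with the frame-defining atoms.

# Given dU/dM (n x 13) and the frames/local moments of the current state,
# accumulate forces on frame-defining atoms.
#' @noRd
frame_chain_forces <- function(system, gm, phi_m) {
  forces <- matrix(0, system$n, 3)
  for (i in seq_len(system$n)) {
    fr <- gm$frames[[i]]
    if (fr$type == "none" || !length(fr$deps)) next
    dMl <- frame_dM(fr, gm$M_local[i, ])
    for (k in seq_along(fr$deps)) {
      a <- fr$deps[k]
      forces[a, ] <- forces[a, ] - as.vector(phi_m[i, ] %*% dMl[[k]])
    }
  }
  forces
}

#' Torque on each multipole from the accumulated dU/dM
#'
#' @param M n x 13 global moments.
#' @param phi_m n x 13 accumulated dU/dM.
#' @return n x 3 matrix of torques (kcal/mol/rad).
#' @export
multipole_torques <- function(M, phi_m) {
  n <- nrow(M)
  out <- matrix(0, n, 3)
  skew <- function(A) c(A[2, 3] - A[3, 2], A[3, 1] - A[1, 3],
                        A[1, 2] - A[2, 1])
  for (i in seq_len(n)) {
    d <- M[i, 2:4]; g <- phi_m[i, 2:4]
    Q <- matrix(M[i, 5:13], 3, 3); G <- matrix(phi_m[i, 5:13], 3, 3)
    out[i, ] <- -pracma_cross(d, g) + skew(G %*% t(Q)) - skew(t(Q) %*% G)
  }
  out
}

#' Distribute multipole torques onto frame-defining atoms
#'
#' Converts the torque on each atom's multipole into force increments on its
#' frame-defining atoms via the analytic Jacobian of the frame orientation,
#' conserving the total force (the frame axes depend only on interatomic
#' differences).
#'
#' @param torques n x 3 torque matrix.
#' @param system a [cph_system()].
#' @param frames per-atom frame structures (internal; built from positions).
#' @return n x 3 matrix of force increments.
#' @export
distribute_torques <- function(torques, system, frames = NULL) {
  if (is.null(frames))
    frames <- lapply(seq_len(system$n), function(i) {
      ms <- .atom_frame(system, i)
      build_frame(ms$frame, i, ms$frame_atoms, system$xyz)
    })
  forces <- matrix(0, system$n, 3)
  for (i in seq_len(system$n)) {
    tau <- torques[i, ]
    if (all(tau == 0)) next
    fr <- frames[[i]]
    if (fr$type == "none" || !length(fr$deps)) next
    # dw/dp = 1/2 sum_k [e_k]_x de_k/dp ; f_a = t(dw/dp_a) %*% tau
    for (k in seq_along(fr$deps)) {
      a <- fr$deps[k]
      dw <- matrix(0, 3, 3)   # column l: d(omega)/d p_l
      if (fr$type == "zonly") {
        # only rotations moving ez are defined; the spin about ez is free
        # (axial multipoles carry no torque component along ez)
        ez <- fr$R[, 3]
        dez <- fr$dez[[k]]
        dw <- vapply(1:3, function(l) pracma_cross(ez, dez[, l]), numeric(3))
      } else {
        for (ek in 1:3) {
          e <- fr$R[, ek]
          de <- fr$dR[[k]][, ek, ]
          dw <- dw + 0.5 * vapply(1:3, function(l)
            pracma_cross(e, de[, l]), numeric(3))
        }
      }
      forces[a, ] <- forces[a, ] + as.vector(t(dw) %*% tau)
    }
  }
  forces
}
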