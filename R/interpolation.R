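# State interpolation of permanent multipoles and polarizabilities, and
# rotation from local chemical frames into the global frame.
#
# Mixing conventions (tautomer direction: zeta = 1 selects the P1/epsilon
# side):
#   LYS, CYS : M(l)      = (1-l) M_U + l M_P
#   ASP, GLU : M(l, z)   = (1-l) M_U + l [z M_P1 + (1-z) M_P2]
#   HIS      : M(l, z)   = l M_P + (1-l) [z M_U1 + (1-z) M_U2]
# The same forms apply to isotropic polarizabilities.  Derivatives are the
# exact analytic linears; both the moments and their derivatives are rotated
# by the one shared frame rotation per atom.

#' Interpolate the permanent multipole of one site atom
#'
#' @param site a titratable site (see [build_titratable_sites()]).
#' @param atom atom index (must be a member of the site).
#' @param lambda titration state in `[0, 1]`; 1 = protonated.
#' @param zeta tautomer state in `[0, 1]`, or NULL for LYS/CYS.
#' @return list with 13-vectors `M`, `dM_dlambda`, `dM_dzeta` in the local
#'   frame (layout: charge, dipole, 3x3 quadrupole).
#' @export
interpolate_multipole <- function(site, atom, lambda, zeta = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  a <- as.character(atom)
  kind <- site$residue_kind
  es <- function(s) mset_to_m13(site$endstates[[s]][[a]]$multipole)
  if (kind %in% c("LYS", "CYS")) {
    if (!is.null(zeta) && !is.na(zeta))
      stop(kind, " sites have no tautomer variable; zeta must not be supplied")
    U <- es("U"); P <- es("P")
    list(M = (1 - lambda) * U + lambda * P,
         dM_dlambda = P - U,
         dM_dzeta = numeric(13))
  } else if (kind %in% c("ASP", "GLU")) {
    stopifnot(zeta >= 0, zeta <= 1)
    U <- es("U"); P1 <- es("P1"); P2 <- es("P2")
    P <- zeta * P1 + (1 - zeta) * P2
    list(M = (1 - lambda) * U + lambda * P,
         dM_dlambda = P - U,
         dM_dzeta = lambda * (P1 - P2))
  } else { # HIS
    stopifnot(zeta >= 0, zeta <= 1)
    P <- es("P"); U1 <- es("U1"); U2 <- es("U2")
    U <- zeta * U1 + (1 - zeta) * U2
    list(M = lambda * P + (1 - lambda) * U,
         dM_dlambda = P - U,
         dM_dzeta = (1 - lambda) * (U1 - U2))
  }
}

#' Interpolate the polarizability of one site atom
#'
#' Titrating hydrogens reduce to linearly switching the polarizability on or
#' off; sulfur and carboxylate oxygens interpolate between two nonzero
#' end-state values.
#'
#' @inheritParams interpolate_multipole
#' @return list with scalars `alpha`, `dalpha_dlambda`, `dalpha_dzeta`.
#' @export
interpolate_polarizability <- function(site, atom, lambda, zeta = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  a <- as.character(atom)
  kind <- site$residue_kind
  es <- function(s) site$endstates[[s]][[a]]$alpha
  out <- if (kind %in% c("LYS", "CYS")) {
    if (!is.null(zeta) && !is.na(zeta))
      stop(kind, " sites have no tautomer variable; zeta must not be supplied")
    U <- es("U"); P <- es("P")
    list(alpha = (1 - lambda) * U + lambda * P,
         dalpha_dlambda = P - U, dalpha_dzeta = 0)
  } else if (kind %in% c("ASP", "GLU")) {
    U <- es("U"); P1 <- es("P1"); P2 <- es("P2")
    P <- zeta * P1 + (1 - zeta) * P2
    list(alpha = (1 - lambda) * U + lambda * P,
         dalpha_dlambda = P - U,
         dalpha_dzeta = lambda * (P1 - P2))
  } else {
    P <- es("P"); U1 <- es("U1"); U2 <- es("U2")
    U <- zeta * U1 + (1 - zeta) * U2
    list(alpha = lambda * P + (1 - lambda) * U,
         dalpha_dlambda = P - U,
         dalpha_dzeta = (1 - lambda) * (U1 - U2))
  }
  if (out$alpha < -1e-12)
    stop("interpolated polarizability is negative; end states must be >= 0")
  out$alpha <- max(out$alpha, 0)
  out
}

#' Fixed Thole damping width for a titrating atom
#'
#' The Thole charge density entering `u = R_ij/(alpha_i alpha_j)^(1/6)` is
#' frozen so that it carries no derivative with respect to titration or
#' tautomer variables: for atoms interpolating between two nonzero
#' end-state polarizabilities (titrating sulfur, carboxylate oxygen) the
#' damping width uses the mean of the end-state values; for titrating
#' hydrogens (zero at one end) it uses the nonzero end-state value.
#'
#' @param site a titratable site.
#' @param atom member atom index.
#' @return the state-independent polarizability (Angstrom^3) entering the
#'   damping width.
#' @export
thole_effective_density <- function(site, atom) {
  a <- as.character(atom)
  vals <- vapply(site$endstates, function(es) es[[a]]$alpha, numeric(1))
  nz <- vals[vals > 0]
  if (length(nz) == 0) return(0)
  if (any(vals == 0)) mean(nz[1]) else mean(range(vals))
}

# ---------------------------------------------------------------------------
# Local frames: rotation matrices and their position Jacobians.

#' @noRd
.hat <- function(u) u / sqrt(sum(u^2))
#' @noRd
.dhat <- function(u) {
  nrm <- sqrt(sum(u^2))
  (diag(3) - outer(u, u) / nrm^2) / nrm
}
# Jacobian columns of a x b where A = da/dp (3x3), b fixed
#' @noRd
.crossjac_a <- function(A, b) {
  cbind(pracma_cross(A[, 1], b), pracma_cross(A[, 2], b),
        pracma_cross(A[, 3], b))
}
#' @noRd
.crossjac_b <- function(a, B) {
  cbind(pracma_cross(a, B[, 1]), pracma_cross(a, B[, 2]),
        pracma_cross(a, B[, 3]))
}

# Build frame rotation and Jacobians.  positions: full n x 3 matrix.
# Returns list(type, owner, fatoms, deps, R, dR) where dR[[k]] is a 3x3x3
# array, dR[[k]][i, j, l] = d R[i,j] / d p_l of dependency atom deps[k].
# For "zonly" R carries an arbitrary (smooth in ez) transverse choice; the
# multipole it rotates must be axially symmetric, and the Jacobian path uses
# the axial formulas via dez only.
#' @noRd
build_frame <- function(frame, owner, fatoms, positions, jacobian = TRUE) {
  p0 <- positions[owner, ]
  if (frame == "none") {
    return(list(type = frame, owner = owner, fatoms = integer(0),
                deps = integer(0), R = diag(3), dR = list()))
  }
  get <- function(k) positions[fatoms[k], ]
  if (frame == "zonly") {
    u <- get(1) - p0
    ez <- .hat(u)
    a <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ex <- .hat(pracma_cross(a, ez))
    ey <- pracma_cross(ez, ex)
    out <- list(type = frame, owner = owner, fatoms = fatoms,
                deps = c(fatoms[1], owner), R = cbind(ex, ey, ez))
    if (jacobian) {
      dh <- .dhat(u)
      out$dez <- list(dh, -dh)   # per dep
    }
    return(out)
  }
  if (frame == "zthenx") {
    u <- get(1) - p0; v <- get(2) - p0
    du <- list(p1 = .dhat(u), p0 = -.dhat(u))
    ez <- .hat(u)
    deps <- c(fatoms[1], fatoms[2], owner)
    # dez per dep: p1, p2, p0
    dez <- list(du$p1, matrix(0, 3, 3), du$p0)
    dv <- list(matrix(0, 3, 3), diag(3), -diag(3))
  } else if (frame == "bisector") {
    u1 <- get(1) - p0; u2 <- get(2) - p0
    b <- .hat(u1) + .hat(u2)
    if (sqrt(sum(b^2)) < 1e-8)
      stop("degenerate bisector frame at atoms ",
           paste(c(owner, fatoms), collapse = ", "))
    ez <- .hat(b)
    deps <- c(fatoms[1], fatoms[2], owner)
    dhb <- .dhat(b)
    d1 <- .dhat(u1); d2 <- .dhat(u2)
    dez <- list(dhb %*% d1, dhb %*% d2, -dhb %*% (d1 + d2))
    v <- u1
    dv <- list(diag(3), matrix(0, 3, 3), -diag(3))
  } else if (frame == "zbisect") {
    u <- get(1) - p0
    ez <- .hat(u)
    u2 <- get(2) - p0; u3 <- get(3) - p0
    b <- .hat(u2) + .hat(u3)
    deps <- c(fatoms[1], fatoms[2], fatoms[3], owner)
    dhu <- .dhat(u)
    dez <- list(dhu, matrix(0, 3, 3), matrix(0, 3, 3), -dhu)
    d2 <- .dhat(u2); d3 <- .dhat(u3)
    v <- b
    dv <- list(matrix(0, 3, 3), d2, d3, -(d2 + d3))
  } else stop("unknown frame type: ", frame)

  # Gram-Schmidt x axis: w = v - (v.ez) ez
  w <- v - sum(v * ez) * ez
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8)
    stop("degenerate frame geometry (collinear axes) at atoms ",
         paste(c(owner, fatoms), collapse = ", "))
  ex <- w / nw
  ey <- pracma_cross(ez, ex)
  R <- cbind(ex, ey, ez)
  out <- list(type = frame, owner = owner, fatoms = fatoms, deps = deps, R = R)
  if (jacobian) {
    dhw <- .dhat(w)
    dR <- vector("list", length(deps))
    for (k in seq_along(deps)) {
      dez_k <- dez[[k]]
      # dw = dv - ez (v . dez + ez . dv) - (v.ez) dez
      dw_k <- dv[[k]] - outer(ez, as.vector(t(dez_k) %*% v)) -
        outer(ez, as.vector(t(dv[[k]]) %*% ez)) - sum(v * ez) * dez_k
      dex_k <- dhw %*% dw_k
      dey_k <- .crossjac_a(dez_k, ex) + .crossjac_b(ez, dex_k)
      arr <- array(0, c(3, 3, 3))
      arr[, 1, ] <- dex_k; arr[, 2, ] <- dey_k; arr[, 3, ] <- dez_k
      dR[[k]] <- arr
    }
    out$dR <- dR
  }
  out
}

# Rotate a local 13-vector into the global frame given a rotation matrix.
#' @noRd
rotate_m13 <- function(m, R) {
  out <- numeric(13)
  out[1] <- m[1]
  out[2:4] <- R %*% m[2:4]
  out[5:13] <- as.vector(R %*% matrix(m[5:13], 3, 3) %*% t(R))
  out
}

#' Rotate a multipole (or its state derivative) into the global frame
#'
#' The charge is unchanged, the dipole transforms by R, the quadrupole by
#' R Q R^T.  The identical rotation applies to state derivatives of the
#' moments, which is what makes a single torque accumulation valid.
#'
#' @param m a 13-vector (charge, dipole, 3x3 quadrupole) in the local frame.
#' @param frame frame convention string.
#' @param owner_pos position of the owning atom.
#' @param frame_pos matrix (rows) of frame-atom positions, in frame order.
#' @return the rotated 13-vector.
#' @export
rotate_to_global <- function(m, frame, owner_pos, frame_pos) {
  if (frame == "none") return(m)
  frame_pos <- matrix(frame_pos, ncol = 3)
  positions <- rbind(owner_pos, frame_pos)
  fr <- build_frame(frame, 1L, seq_len(nrow(frame_pos)) + 1L, positions,
                    jacobian = FALSE)
  if (frame == "zonly") .check_axial(m)
  rotate_m13(m, fr$R)
}

#' @noRd
.check_axial <- function(m) {
  Q <- matrix(m[5:13], 3, 3)
  if (any(abs(m[2:3]) > 1e-9) || abs(Q[1, 1] - Q[2, 2]) > 1e-9 ||
      any(abs(Q[upper.tri(Q)]) > 1e-9))
    stop("z-only frames require axially symmetric multipoles")
  invisible(TRUE)
}

# dM_global/dp for each dependency atom: list of 13 x 3 matrices.
#' @noRd
frame_dM <- function(fr, m_local) {
  if (fr$type == "none" || length(fr$deps) == 0) return(list())
  d <- m_local[2:4]; Q <- matrix(m_local[5:13], 3, 3)
  out <- vector("list", length(fr$deps))
  if (fr$type == "zonly") {
    # axial multipole: d_g = dz ez ; Q_g = Qzz (3 ez ez^T - I)/2
    dz <- d[3]; Qzz <- Q[3, 3]
    ez <- fr$R[, 3]
    for (k in seq_along(fr$deps)) {
      dez <- fr$dez[[k]]
      dm <- matrix(0, 13, 3)
      dm[2:4, ] <- dz * dez
      for (l in 1:3) {
        dQ <- (3 / 2) * Qzz * (outer(dez[, l], ez) + outer(ez, dez[, l]))
        dm[5:13, l] <- as.vector(dQ)
      }
      out[[k]] <- dm
    }
    return(out)
  }
  R <- fr$R
  for (k in seq_along(fr$deps)) {
    arr <- fr$dR[[k]]
    dm <- matrix(0, 13, 3)
    for (l in 1:3) {
      dRl <- arr[, , l]
      dm[2:4, l] <- dRl %*% d
      dm[5:13, l] <- as.vector(dRl %*% Q %*% t(R) + R %*% Q %*% t(dRl))
    }
    out[[k]] <- dm
  }
  out
}

# ---------------------------------------------------------------------------
# System-level state interpolation.

#' Interpolate every atom's moments and polarizability at a state
#'
#' Applies the residue mixing rules across all titratable sites and returns
#' the local-frame moments (n x 13), polarizabilities, frozen damping
#' widths, and the sparse state derivatives per extended variable.
#'
#' @param system a [cph_system()].
#' @param lz lambda/zeta vector (length `system$n_theta`), indexed by the
#'   sites' `lambda_index` / `zeta_index`.
#' @return list with `M_local`, `alpha`, `damp_alpha`, `dM_local`, `dAlpha`.
#' @export
interpolate_system <- function(system, lz) {
  n <- system$n
  M <- matrix(0, n, 13)
  for (i in seq_len(n)) M[i, ] <- mset_to_m13(system$multipoles[[i]])
  alpha <- system$polar$alpha
  damp_alpha <- alpha
  nth <- if (is.null(system$n_theta)) 0L else system$n_theta
  dM <- vector("list", nth)
  dAlpha <- vector("list", nth)
  for (k in seq_len(nth)) {
    dM[[k]] <- list(atoms = integer(0), m = NULL)
    dAlpha[[k]] <- list(atoms = integer(0), a = numeric(0))
  }
  for (site in system$sites) {
    li <- site$lambda_index; zi <- site$zeta_index
    lam <- lz[li]
    zet <- if (!is.na(zi)) lz[zi] else NULL
    dm_l <- matrix(0, length(site$atoms), 13)
    dm_z <- matrix(0, length(site$atoms), 13)
    da_l <- numeric(length(site$atoms)); da_z <- numeric(length(site$atoms))
    for (ai in seq_along(site$atoms)) {
      a <- site$atoms[ai]
      mi <- interpolate_multipole(site, a, lam, zet)
      pi_ <- interpolate_polarizability(site, a, lam, zet)
      M[a, ] <- mi$M
      alpha[a] <- pi_$alpha
      damp_alpha[a] <- thole_effective_density(site, a)
      dm_l[ai, ] <- mi$dM_dlambda
      dm_z[ai, ] <- mi$dM_dzeta
      da_l[ai] <- pi_$dalpha_dlambda
      da_z[ai] <- pi_$dalpha_dzeta
    }
    dM[[li]] <- list(atoms = site$atoms, m = dm_l)
    dAlpha[[li]] <- list(atoms = site$atoms, a = da_l)
    if (!is.na(zi)) {
      dM[[zi]] <- list(atoms = site$atoms, m = dm_z)
      dAlpha[[zi]] <- list(atoms = site$atoms, a = da_z)
    }
  }
  list(M_local = M, alpha = alpha, damp_alpha = damp_alpha,
       dM_local = dM, dAlpha = dAlpha)
}

#' Rotate interpolated moments (and their state derivatives) to the global frame
#'
#' One shared rotation per atom is applied to the moments and to their
#' lambda/zeta derivatives (valid because all end states share frames).
#'
#' @param system a [cph_system()].
#' @param interp result of [interpolate_system()].
#' @param jacobian also build the frame Jacobians needed by force routines.
#' @return list with `M` (n x 13 global), `dM`, `frames`, `alpha`,
#'   `damp_alpha`, `dAlpha`, `M_local`.
#' @export
global_moments <- function(system, interp, jacobian = TRUE) {
  n <- system$n
  frames <- vector("list", n)
  M <- interp$M_local
  for (i in seq_len(n)) {
    ms <- .atom_frame(system, i)
    frames[[i]] <- build_frame(ms$frame, i, ms$frame_atoms, system$xyz,
                               jacobian = jacobian)
    if (ms$frame == "zonly") .check_axial(interp$M_local[i, ])
    M[i, ] <- rotate_m13(interp$M_local[i, ], frames[[i]]$R)
  }
  dM <- interp$dM_local
  for (k in seq_along(dM)) {
    if (length(dM[[k]]$atoms)) {
      mm <- dM[[k]]$m
      for (ai in seq_along(dM[[k]]$atoms)) {
        a <- dM[[k]]$atoms[ai]
        mm[ai, ] <- rotate_m13(mm[ai, ], frames[[a]]$R)
      }
      dM[[k]]$m <- mm
    }
  }
  list(M = M, dM = dM, frames = frames,
       alpha = interp$alpha, damp_alpha = interp$damp_alpha,
       dAlpha = interp$dAlpha, M_local = interp$M_local)
}

# Frame spec for atom i: site end states share frames, so take any end state
# if the atom belongs to a site, else the static multipole.
#' @noRd
.atom_frame <- function(system, i) {
  for (site in system$sites) {
    if (i %in% site$atoms) {
      ms <- site$endstates[[1]][[as.character(i)]]$multipole
      return(list(frame = ms$frame, frame_atoms = ms$frame_atoms))
    }
  }
  ms <- system$multipoles[[i]]
  list(frame = ms$frame, frame_atoms = ms$frame_atoms)
}
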