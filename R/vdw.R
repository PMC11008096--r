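# Buffered 14-7 van der Waals with per-atom titration/tautomer scaling.
#
# Pair energies are scaled by f_i(lambda, zeta) * f_j(lambda, zeta) where the
# per-proton scale factors follow the residue table:
#   non-titrating atom : 1
#   LYS, CYS proton    : lambda
#   ASP, GLU proton    : lambda * fm(zeta)
#   HIS protons        : (1 - lambda) * fm(zeta) + lambda
# with fm(zeta) = zeta for a +1 tautomer direction tag (the epsilon/HE2
# proton) and 1 - zeta for -1 (HD1).  The alchemical path needs no soft core
# because each proton stays protected by its heavy atom's repulsion; a
# soft-core form is provided as a standalone function.

# buffering constants of the buffered 14-7 potential
VDW_DELTA <- 0.07
VDW_GAMMA <- 0.12

#' Buffered 14-7 pair potential
#'
#' @param r separation, Angstrom (> 0).
#' @param r_min minimum-energy separation, Angstrom.
#' @param eps well depth, kcal/mol.
#' @return list with `energy` (kcal/mol) and `dE_dr` (kcal/mol/Angstrom).
#'   The minimum value is `-eps` at `r = r_min`.
#' @export
buffered_14_7 <- function(r, r_min, eps) {
  if (any(r <= 0)) stop("buffered 14-7 requires r > 0")
  rho <- r / r_min
  t1 <- ((1 + VDW_DELTA) / (rho + VDW_DELTA))^7
  t2 <- (1 + VDW_GAMMA) / (rho^7 + VDW_GAMMA)
  e <- eps * t1 * (t2 - 2)
  dt1 <- -7 * t1 / (rho + VDW_DELTA)
  dt2 <- -7 * rho^6 * t2^2 / (1 + VDW_GAMMA)
  list(energy = e, dE_dr = eps * (dt1 * (t2 - 2) + t1 * dt2) / r_min)
}

#' Soft-core buffered 14-7 potential
#'
#' Replaces the buffered distances by `alpha_sc (1 - lambda)^2`-augmented
#' forms so the potential stays finite at zero separation when the pair is
#' partially decoupled, and reduces exactly to [buffered_14_7()] at
#' `lambda = 1`.
#'
#' @param rho normalized separation `r / r_min`.
#' @param eps well depth, kcal/mol.
#' @param lambda pair coupling in `[0, 1]`.
#' @param alpha_sc soft-core radius constant (default 0.7).
#' @param n_sc coupling exponent (default 2).
#' @return energy in kcal/mol.
#' @export
softcore_14_7 <- function(rho, eps, lambda, alpha_sc = 0.7, n_sc = 2) {
  stopifnot(lambda >= 0, lambda <= 1)
  sc <- alpha_sc * (1 - lambda)^2
  t1 <- (1 + VDW_DELTA)^7 / (sc + (rho + VDW_DELTA)^7)
  t2 <- (1 + VDW_GAMMA) / (sc + rho^7 + VDW_GAMMA)
  lambda^n_sc * eps * t1 * (t2 - 2)
}

# AMOEBA combining rules: cubic-mean r_min, HHG epsilon
#' @noRd
vdw_combine <- function(r1, e1, r2, e2) {
  rmin <- (r1^3 + r2^3) / (r1^2 + r2^2)
  se <- sqrt(e1) + sqrt(e2)
  eps <- if (se > 0) 4 * e1 * e2 / se^2 else 0
  c(rmin, eps)
}

# C2 quintic taper from 1 at r <= on to 0 at r >= off, with derivative
#' @noRd
vdw_taper <- function(r, on, off) {
  if (r <= on) return(c(1, 0))
  if (r >= off) return(c(0, 0))
  x <- (r - on) / (off - on)
  s <- 1 - (10 * x^3 - 15 * x^4 + 6 * x^5)
  ds <- -(30 * x^2 - 60 * x^3 + 30 * x^4) / (off - on)
  c(s, ds)
}

# Per-atom scale factors f_i and sparse derivatives w.r.t. the lambda/zeta
# vector.  Returns list(f = n-vector, df = n x n_theta matrix).
#' @noRd
vdw_scale_factors <- function(system, lz) {
  n <- system$n
  nth <- if (is.null(system$n_theta)) 0L else system$n_theta
  f <- rep(1, n)
  df <- matrix(0, n, max(nth, 1))
  for (site in system$sites) {
    li <- site$lambda_index; zi <- site$zeta_index
    lam <- lz[li]
    zet <- if (!is.na(zi)) lz[zi] else NA
    th <- site$tit_h
    if (is.null(th) || nrow(th) == 0) next
    for (r in seq_len(nrow(th))) {
      a <- th$atom[r]; dir <- th$dir[r]
      fm <- if (is.na(dir) || dir == 0) 1 else if (dir > 0) zet else 1 - zet
      dfm <- if (is.na(dir) || dir == 0) 0 else dir
      kind <- site$residue_kind
      if (kind %in% c("LYS", "CYS")) {
        f[a] <- lam
        df[a, li] <- 1
      } else if (kind %in% c("ASP", "GLU")) {
        f[a] <- lam * fm
        df[a, li] <- fm
        df[a, zi] <- lam * dfm
      } else { # HIS
        f[a] <- (1 - lam) * fm + lam
        df[a, li] <- 1 - fm
        df[a, zi] <- (1 - lam) * dfm
      }
    }
  }
  list(f = f, df = df)
}

# Bond-path distance classes (2 = 1-2, 3 = 1-3, 4 = 1-4, 5 = 1-5, 0 = far).
#' @noRd
bond_paths <- function(system) {
  n <- system$n
  P <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    dist <- rep(0L, n); dist[i] <- 1L
    frontier <- i
    for (depth in 2:5) {
      nxt <- unique(unlist(system$bonds[frontier]))
      nxt <- nxt[dist[nxt] == 0L]
      if (!length(nxt)) break
      dist[nxt] <- depth
      frontier <- nxt
    }
    P[i, ] <- dist
  }
  diag(P) <- 1L
  P
}

#' @noRd
mask_scale <- function(paths, i, j, scales) {
  p <- paths[i, j]
  if (p <= 1L) 1.0 else scales[p - 1L]
}

#' Extended-system van der Waals energy
#'
#' Buffered 14-7 energy over all pairs within the cutoff (minimum image),
#' with AMOEBA combining rules, hydrogen reduction-factor site placement,
#' bonded mask scales, a quintic taper window, and the residue-table
#' lambda/zeta scale factors with their analytic derivatives.
#'
#' @param system a [cph_system()] with parameters applied.
#' @param lz lambda/zeta state vector (may be empty for a static system).
#' @param config list with `cutoff` (Angstrom), `taper` (taper onset),
#'   optionally `paths` (precomputed bond-path matrix).
#' @param gradient if FALSE skip force computation.
#' @return list with `energy`, `forces` (n x 3), `dlz` (derivative per
#'   lambda/zeta variable).
#' @export
vdw_energy <- function(system, lz = numeric(0), config = list(),
                       gradient = TRUE) {
  n <- system$n
  cutoff <- config$cutoff %||% 12
  taper_on <- config$taper %||% (cutoff - 2)
  cell <- system$cell
  if (!is.null(cell)) {
    if (cutoff > min(cell_widths(cell)) / 2 + 1e-9)
      stop("vdw cutoff exceeds half the minimum cell width")
  }
  paths <- config$paths %||% bond_paths(system)
  vs <- system$params$scales$vdw %||% c(0, 0, 1, 1)
  sc <- vdw_scale_factors(system, lz)
  nth <- if (is.null(system$n_theta)) 0L else system$n_theta
  # reduced interaction sites for hydrogens
  red <- system$vdw$reduction
  heavy <- vapply(seq_len(n), function(i) {
    if (red[i] < 1 && length(system$bonds[[i]]))
      as.integer(system$bonds[[i]][1]) else i
  }, integer(1))
  site_xyz <- system$xyz
  for (i in seq_len(n)) {
    if (heavy[i] != i)
      site_xyz[i, ] <- system$xyz[heavy[i], ] +
        red[i] * (system$xyz[i, ] - system$xyz[heavy[i], ])
  }
  U <- 0
  forces <- matrix(0, n, 3)
  dlz <- numeric(max(nth, 1))
  if (n < 2) return(list(energy = 0, forces = forces,
                         dlz = if (nth > 0) dlz[seq_len(nth)] else numeric(0)))
  for (i in seq_len(n - 1)) {
    if (system$vdw$eps[i] == 0) next
    for (j in (i + 1):n) {
      if (system$vdw$eps[j] == 0) next
      ms <- mask_scale(paths, i, j, vs)
      if (ms == 0) next
      dx <- min_image(site_xyz[i, ] - site_xyz[j, ], cell)
      r <- sqrt(sum(dx^2))
      if (r >= cutoff) next
      cmb <- vdw_combine(system$vdw$rmin[i], system$vdw$eps[i],
                         system$vdw$rmin[j], system$vdw$eps[j])
      bv <- buffered_14_7(r, cmb[1], cmb[2])
      tp <- vdw_taper(r, taper_on, cutoff)
      fij <- sc$f[i] * sc$f[j]
      e_geom <- bv$energy * tp[1]
      U <- U + ms * fij * e_geom
      if (gradient) {
        dEdr <- ms * fij * (bv$dE_dr * tp[1] + bv$energy * tp[2])
        g <- dEdr * dx / r        # dU/dx_i at the reduced site
        # distribute across reduction sites
        for (pr in list(c(i, 1), c(j, -1))) {
          a <- pr[1]; sgn <- pr[2]
          if (heavy[a] == a) forces[a, ] <- forces[a, ] - sgn * g
          else {
            forces[a, ] <- forces[a, ] - sgn * red[a] * g
            forces[heavy[a], ] <- forces[heavy[a], ] - sgn * (1 - red[a]) * g
          }
        }
        if (nth > 0) {
          dfij <- sc$df[i, ] * sc$f[j] + sc$f[i] * sc$df[j, ]
          dlz <- dlz + ms * e_geom * dfij
        }
      }
    }
  }
  list(energy = U, forces = forces,
       dlz = if (nth > 0) dlz[seq_len(nth)] else numeric(0))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
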