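# Assembly of the extended-system potential at a fixed (lambda, zeta) state:
# bonded terms (always those of the protonated topology), scaled buffered
# 14-7 vdW, permanent-multipole Ewald/PME electrostatics, induced-dipole
# polarization.  Every term reports its energy, Cartesian forces (with the
# frame/torque chain applied) and analytic d/dlambda, d/dzeta.

#' Default configuration for energy evaluations
#'
#' @param cell optional [crystal_cell()]; vacuum defaults are used without.
#' @param ... overrides.
#' @return config list.
#' @export
cph_config <- function(cell = NULL, ...) {
  cfg <- list(
    beta = if (is.null(cell)) NULL else 0.545,
    cutoff = 7.0,
    grid = NULL, order = 5L,
    neutralize = TRUE, boundary = "tinfoil",
    vdw_cutoff = 12.0, vdw_taper = 10.0,
    scf_tol = 1e-6, scf_max_iter = 100L,
    thole_a = 0.39,
    softcore = list(enabled = FALSE, alpha_sc = 0.7),
    polarization = "mutual"
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  if (!is.null(cell) && is.null(cfg$grid)) {
    # grid spacing <= 1 A, even dimensions
    w <- sqrt(colSums(cell$lattice^2))
    cfg$grid <- pmax(2 * ceiling(w / 2), 2L * cfg$order)
  }
  cfg
}

# bonded energy: harmonic bonds/angles, parameters fixed to the protonated
# topology; contributes nothing to d/dtheta
#' @noRd
bonded_energy <- function(system, gradient = TRUE) {
  U <- 0
  forces <- matrix(0, system$n, 3)
  bd <- system$bonded
  if (!is.null(bd$bonds) && nrow(bd$bonds)) {
    for (r in seq_len(nrow(bd$bonds))) {
      i <- bd$bonds$i[r]; j <- bd$bonds$j[r]
      dx <- system$xyz[i, ] - system$xyz[j, ]   # bonds never wrap in fixtures
      rr <- sqrt(sum(dx^2))
      U <- U + bd$bonds$k[r] * (rr - bd$bonds$r0[r])^2
      if (gradient) {
        g <- 2 * bd$bonds$k[r] * (rr - bd$bonds$r0[r]) * dx / rr
        forces[i, ] <- forces[i, ] - g
        forces[j, ] <- forces[j, ] + g
      }
    }
  }
  if (!is.null(bd$angles) && nrow(bd$angles)) {
    for (r in seq_len(nrow(bd$angles))) {
      i <- bd$angles$i[r]; j <- bd$angles$j[r]; k <- bd$angles$k[r]
      u <- system$xyz[i, ] - system$xyz[j, ]
      v <- system$xyz[k, ] - system$xyz[j, ]
      nu_ <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      cth <- max(-1, min(1, sum(u * v) / (nu_ * nv)))
      th <- acos(cth)
      dth <- th - bd$angles$th0[r]
      U <- U + bd$angles$k[r] * dth^2
      if (gradient) {
        sth <- sqrt(max(1 - cth^2, 1e-12))
        dcth_du <- v / (nu_ * nv) - cth * u / nu_^2
        dcth_dv <- u / (nu_ * nv) - cth * v / nv^2
        pref <- 2 * bd$angles$k[r] * dth * (-1 / sth)
        gi <- pref * dcth_du
        gk <- pref * dcth_dv
        forces[i, ] <- forces[i, ] - gi
        forces[k, ] <- forces[k, ] - gk
        forces[j, ] <- forces[j, ] + gi + gk
      }
    }
  }
  list(energy = U, forces = forces,
       dlz = numeric(system$n_theta %||% 0))
}

#' Nonbonded + bonded energy of the extended system at a fixed state
#'
#' Evaluates every potential term at the given lambda/zeta values with
#' analytic Cartesian forces (including frame rotation chain terms) and
#' analytic state derivatives.  The polarization state derivative uses the
#' single converged SCF of this call; no term re-solves the field.
#'
#' @param system a [cph_system()] (with `sites` for titration).
#' @param lz lambda/zeta vector (length `system$n_theta`), values in `[0,1]`.
#' @param config from [cph_config()].
#' @param gradient compute forces and state derivatives.
#' @param terms character subset of
#'   `c("bonded", "vdw", "real", "recip", "selfneut", "pol")` to evaluate.
#' @return list with `energy`, `forces`, `dlz`, and per-term breakdown in
#'   `$terms`.
#' @export
cph_energy <- function(system, lz = numeric(0), config = NULL,
                       gradient = TRUE,
                       terms = c("bonded", "vdw", "real", "recip",
                                 "selfneut", "pol")) {
  if (is.null(config)) config <- cph_config(system$cell)
  n <- system$n
  nth <- system$n_theta %||% 0L
  vacuum <- is.null(system$cell)
  config$paths <- config$paths %||% bond_paths(system)
  out <- list()
  zero <- list(energy = 0, forces = matrix(0, n, 3), dlz = numeric(nth))

  if ("bonded" %in% terms) out$bonded <- bonded_energy(system, gradient)

  if ("vdw" %in% terms && any(system$vdw$eps > 0)) {
    out$vdw <- vdw_energy(system, lz,
                          list(cutoff = config$vdw_cutoff,
                               taper = config$vdw_taper,
                               paths = config$paths),
                          gradient)
  }

  needs_elec <- any(c("real", "recip", "selfneut", "pol") %in% terms)
  if (needs_elec) {
    interp <- interpolate_system(system, lz)
    gm <- global_moments(system, interp, jacobian = gradient)
    ecfg <- config
    if (vacuum) ecfg$beta <- NULL
    ecfg$pairs <- elec_pairs(system, ecfg$cutoff, config$paths)
    if (isTRUE(config$softcore$enabled)) {
      hlam <- rep(1, n); hsite <- rep(NA_integer_, n)
      for (site in system$sites) {
        if (!is.null(site$tit_h) && nrow(site$tit_h)) {
          hlam[site$tit_h$atom] <- lz[site$lambda_index]
          hsite[site$tit_h$atom] <- site$lambda_index
        }
      }
      ecfg$softcore$hlam <- hlam
      ecfg$softcore$hsite <- hsite
    }
    finish <- function(tm, phi_m, extra_dlz = NULL) {
      if (gradient) {
        tm$forces <- tm$forces + frame_chain_forces(system, gm, phi_m)
        tm$dlz <- vapply(seq_len(nth), function(k) {
          dk <- gm$dM[[k]]
          if (!length(dk$atoms)) return(0)
          sum(dk$m * phi_m[dk$atoms, , drop = FALSE])
        }, numeric(1))
        if (!is.null(extra_dlz)) tm$dlz <- tm$dlz + extra_dlz
      } else tm$dlz <- numeric(nth)
      tm
    }
    if ("real" %in% terms) {
      re <- real_space_permanent(system, gm, ecfg, gradient)
      out$real <- finish(list(energy = re$energy, forces = re$forces),
                         re$phi_m,
                         if (length(re$dlz_extra)) re$dlz_extra else NULL)
    }
    rc <- NULL
    if (!vacuum && any(c("recip", "pol") %in% terms)) {
      rc <- pme_reciprocal(system, gm$M, ecfg, gradient)
      ecfg$recip <- rc
      ecfg$influence <- rc$influence
    }
    if ("recip" %in% terms && !vacuum) {
      out$recip <- finish(list(energy = rc$energy, forces = rc$forces),
                          rc$phi_m)
    }
    if ("selfneut" %in% terms && !vacuum) {
      sn <- self_and_neutrality(gm$M, ecfg, system$cell, system$xyz)
      out$selfneut <- finish(list(energy = sn$energy, forces = sn$forces),
                             sn$phi_m)
    }
    if ("pol" %in% terms && any(gm$alpha > 0)) {
      scf <- polarization_scf(system, gm, ecfg)
      Upol <- polarization_energy(scf)
      tm <- list(energy = Upol, forces = matrix(0, n, 3), dlz = numeric(nth))
      if (gradient) {
        pg <- polarization_gradient(system, gm, scf, ecfg)
        tm$forces <- pg$forces + frame_chain_forces(system, gm, pg$phi_m)
        tm$dlz <- polarization_lambda_derivative(gm, scf, pg$phi_m)
      }
      tm$scf_iterations <- scf$iterations
      out$pol <- tm
    }
  }

  total <- zero
  for (tm in out) {
    total$energy <- total$energy + tm$energy
    if (gradient) {
      total$forces <- total$forces + tm$forces
      total$dlz <- total$dlz + tm$dlz
    }
  }
  list(energy = total$energy, forces = total$forces, dlz = total$dlz,
       terms = out)
}
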