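# Extended-Hamiltonian assembly and Langevin propagation: Cartesian
# coordinates and the titration/tautomer angles theta evolve jointly, with
# lambda = sin^2(theta) keeping every state variable in [0, 1] without
# reflection logic.  The bias has three parts per site: a barrier 4 b_t
# l (1 - l) suppressing intermediate states, the model-compound potential
# U_mod (polynomial, fit by the sampling module so that the model titrates
# according to its reference pKa), and the pH term
# ln(10) kB T (pKa_ref - pH) (1 - lambda), with lambda = 1 protonated.

#' @noRd
polyval0 <- function(coef, x) {
  # polynomial with zero constant term: sum coef[j] x^j
  if (!length(coef)) return(c(v = 0, d = 0))
  j <- seq_along(coef)
  c(v = sum(coef * x^j), d = sum(coef * j * x^(j - 1)))
}

#' Bias energy of the extended variables
#'
#' @param system a [cph_system()] with titratable sites.
#' @param lz lambda/zeta vector.
#' @param params list with `pH`, `temperature` (K), `barrier` (kcal/mol,
#'   default 2).
#' @return list with `energy` and `dlz`, plus a per-component breakdown.
#' @export
bias_energy <- function(system, lz, params) {
  nth <- system$n_theta %||% 0L
  U <- 0; dlz <- numeric(nth)
  bt <- params$barrier %||% 2.0
  kT <- KBOLTZ * (params$temperature %||% 298)
  comp <- c(barrier = 0, mod = 0, pH = 0)
  for (site in system$sites) {
    li <- site$lambda_index; zi <- site$zeta_index
    lam <- lz[li]
    # barrier terms
    U <- U + 4 * bt * lam * (1 - lam)
    comp["barrier"] <- comp["barrier"] + 4 * bt * lam * (1 - lam)
    dlz[li] <- dlz[li] + 4 * bt * (1 - 2 * lam)
    if (!is.na(zi)) {
      zet <- lz[zi]
      U <- U + 4 * bt * zet * (1 - zet)
      comp["barrier"] <- comp["barrier"] + 4 * bt * zet * (1 - zet)
      dlz[zi] <- dlz[zi] + 4 * bt * (1 - 2 * zet)
    }
    # model potential
    mb <- site$model_bias
    if (site$residue_kind == "HIS") {
      zet <- lz[zi]
      p1 <- polyval0(mb$tit1, lam)   # titration PMF bias on the HIE side
      p2 <- polyval0(mb$tit2, lam)   # HID side
      pt <- polyval0(mb$taut, zet)
      um <- zet * p1["v"] + (1 - zet) * p2["v"] + (1 - lam) * pt["v"]
      U <- U + um
      comp["mod"] <- comp["mod"] + um
      dlz[li] <- dlz[li] + zet * p1["d"] + (1 - zet) * p2["d"] - pt["v"]
      dlz[zi] <- dlz[zi] + p1["v"] - p2["v"] + (1 - lam) * pt["d"]
    } else {
      pm <- polyval0(mb$tit, lam)
      U <- U + pm["v"]
      comp["mod"] <- comp["mod"] + pm["v"]
      dlz[li] <- dlz[li] + pm["d"]
    }
    # pH bias
    dpk <- site$pKa_ref - params$pH
    uph <- log(10) * kT * dpk * (1 - lam)
    U <- U + uph
    comp["pH"] <- comp["pH"] + uph
    dlz[li] <- dlz[li] - log(10) * kT * dpk
  }
  list(energy = unname(U), dlz = dlz, components = comp)
}

# synthetic environment surface in lambda carried by toy sites (a stand-in
# for nonbonded interactions in zero-atom analytic fixtures)
#' @noRd
env_energy <- function(system, lz) {
  nth <- system$n_theta %||% 0L
  U <- 0; dlz <- numeric(nth)
  for (site in system$sites) {
    if (!is.null(site$env_poly)) {
      pv <- polyval0(site$env_poly, lz[site$lambda_index])
      U <- U + pv["v"]
      dlz[site$lambda_index] <- dlz[site$lambda_index] + pv["d"]
    }
  }
  list(energy = unname(U), dlz = dlz)
}

#' Construct an extended state
#'
#' @param system a [cph_system()].
#' @param theta initial extended angles; by default every lambda and zeta
#'   starts at 0.5 (`theta = asin(sqrt(0.5))`).
#' @param theta_mass fictitious inertia per theta variable, amu*Angstrom^2.
#' @return object of class `cph_state`.
#' @export
extended_state <- function(system, theta = NULL, theta_mass = 5.0) {
  nth <- system$n_theta %||% 0L
  if (is.null(theta)) theta <- rep(asin(sqrt(0.5)), nth)
  structure(list(
    xyz = system$xyz,
    vel = matrix(0, system$n, 3),
    theta = theta,
    theta_vel = numeric(nth),
    theta_mass = rep(theta_mass, length.out = nth)
  ), class = "cph_state")
}

#' @noRd
state_lz <- function(state) sin(state$theta)^2

#' Total extended-system energy and generalized forces
#'
#' `U = U_bonded(X) + U_nonbonded(X, lambda, zeta) + U_bias(lambda, zeta)`
#' with `dU/dtheta_k = dU/dlambda_k * sin(2 theta_k)` through the sin^2
#' mapping.  Bonded terms always use the protonated-state parameters and
#' contribute nothing to the theta forces.
#'
#' @param system a [cph_system()].
#' @param state a `cph_state` from [extended_state()].
#' @param config a [cph_config()].
#' @param params bias parameters (see [bias_energy()]).
#' @param gradient compute forces.
#' @return list with `energy`, `forces` (n x 3), `dtheta`, `components`.
#' @export
total_extended_energy <- function(system, state, config, params,
                                  gradient = TRUE) {
  lz <- state_lz(state)
  sys <- system
  sys$xyz <- state$xyz
  if (system$n > 0) {
    nb <- cph_energy(sys, lz, config, gradient = gradient)
  } else {
    nb <- list(energy = 0, forces = matrix(0, 0, 3),
               dlz = numeric(system$n_theta %||% 0L), terms = list())
  }
  ev <- env_energy(system, lz)
  bi <- bias_energy(system, lz, params)
  U <- nb$energy + ev$energy + bi$energy
  dlz <- nb$dlz + ev$dlz + bi$dlz
  dtheta <- dlz * sin(2 * state$theta)
  list(energy = U, forces = nb$forces, dtheta = dtheta,
       components = c(list(nonbonded = nb$terms, env = ev$energy),
                      bias = list(bi$components)))
}

#' One BAOAB Langevin step of the joint (X, theta) system
#'
#' Deterministic given the RNG state; lambda stays in `[0, 1]` by
#' construction of the sin^2 mapping.  Pass `friction = 0` and
#' `temperature = NA` for a velocity-Verlet (NVE) limit.
#'
#' @param system,config,params as in [total_extended_energy()].
#' @param state current `cph_state`.
#' @param deriv current energy/forces (from [total_extended_energy()]); if
#'   NULL it is computed.
#' @param spec list with `timestep` (fs), `friction` (1/ps),
#'   `temperature` (K).
#' @return list `state`, `deriv` (forces at the new state), `energy`.
#' @export
langevin_step <- function(system, state, spec, config, params, deriv = NULL) {
  if (is.null(deriv)) deriv <- total_extended_energy(system, state, config,
                                                     params)
  if (system$n > 0 && any(!is.finite(deriv$forces)))
    stop("non-finite force encountered")
  dt <- spec$timestep
  gam <- (spec$friction %||% 1.0) * 1e-3      # 1/ps -> 1/fs
  Tbath <- spec$temperature %||% params$temperature %||% 298
  nvt <- is.finite(Tbath) && gam > 0
  m <- system$masses
  mth <- state$theta_mass
  # B
  if (system$n > 0) state$vel <- state$vel + 0.5 * dt * MDACC * deriv$forces / m
  state$theta_vel <- state$theta_vel - 0.5 * dt * MDACC * deriv$dtheta / mth
  # A
  if (system$n > 0) state$xyz <- state$xyz + 0.5 * dt * state$vel
  state$theta <- state$theta + 0.5 * dt * state$theta_vel
  # O
  if (nvt) {
    c1 <- exp(-gam * dt)
    if (system$n > 0) {
      sig <- sqrt(KBOLTZ * Tbath * MDACC / m) * sqrt(1 - c1^2)
      state$vel <- c1 * state$vel +
        sig * matrix(stats::rnorm(3 * system$n), system$n, 3)
    }
    if (length(mth)) {
      sigt <- sqrt(KBOLTZ * Tbath * MDACC / mth) * sqrt(1 - c1^2)
      state$theta_vel <- c1 * state$theta_vel +
        sigt * stats::rnorm(length(mth))
    }
  }
  # A
  if (system$n > 0) state$xyz <- state$xyz + 0.5 * dt * state$vel
  state$theta <- state$theta + 0.5 * dt * state$theta_vel
  # B with new forces
  deriv <- total_extended_energy(system, state, config, params)
  if (system$n > 0) state$vel <- state$vel + 0.5 * dt * MDACC * deriv$forces / m
  state$theta_vel <- state$theta_vel - 0.5 * dt * MDACC * deriv$dtheta / mth
  list(state = state, deriv = deriv, energy = deriv$energy)
}

#' Run a constant-pH lambda-dynamics simulation
#'
#' Titratable sites start at the intermediate state (lambda = zeta = 0.5)
#' unless `theta0` is given; lambda/zeta values are recorded every
#' `save_interval` steps.
#'
#' @param system a [cph_system()] with sites.
#' @param config a [cph_config()].
#' @param params list with `pH`, `temperature`, `barrier`, `timestep`
#'   (fs), `friction` (1/ps), `theta_mass`, `steps`, `save_interval`,
#'   `seed`, optional `theta0`, optional `fixed_lambda` (freeze theta).
#' @return a list with `record` (data.frame: step, site, lambda, zeta, pH),
#'   `state`, `energies` (sampled total energies).
#' @export
run_cphmd <- function(system, config, params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  steps <- params$steps %||% 1000L
  sv <- params$save_interval %||% 10L
  spec <- list(timestep = params$timestep %||% 1.0,
               friction = params$friction %||% 5.0,
               temperature = params$temperature %||% 298)
  state <- extended_state(system, theta = params$theta0,
                          theta_mass = params$theta_mass %||% 5.0)
  fixed <- isTRUE(params$fixed_lambda)
  deriv <- total_extended_energy(system, state, config, params)
  keep_traj <- isTRUE(params$store_traj)
  traj <- list()
  ns <- length(system$sites)
  li <- vapply(system$sites, `[[`, integer(1), "lambda_index")
  zi <- vapply(system$sites, `[[`, integer(1), "zeta_index")
  nsnap <- 1L + (if (steps > 0) steps %/% sv else 0L)
  step_v <- integer(nsnap * ns)
  lam_m <- matrix(NA_real_, nsnap, ns)
  zet_m <- matrix(NA_real_, nsnap, ns)
  energies <- numeric(0)
  snap_row <- 0L
  snap <- function(step, st) {
    snap_row <<- snap_row + 1L
    if (ns == 0L) return(invisible(NULL))
    lzv <- sin(st$theta)^2
    step_v[seq_len(ns) + (snap_row - 1L) * ns] <<- step
    lam_m[snap_row, ] <<- lzv[li]
    zet_m[snap_row, ] <<- ifelse(is.na(zi), NA_real_, lzv[pmax(zi, 1L)])
  }
  snap(0L, state)
  if (steps > 0) {
    for (s in seq_len(steps)) {
      out <- langevin_step(system, state, spec, config, params, deriv)
      state <- out$state; deriv <- out$deriv
      if (fixed) {
        state$theta <- extended_state(system, params$theta0)$theta
        state$theta_vel[] <- 0
      }
      if (s %% sv == 0) {
        snap(s, state)
        energies <- c(energies, out$energy)
        if (keep_traj) traj[[length(traj) + 1]] <- state$xyz
      }
    }
  }
  used <- seq_len(snap_row)
  record <- data.frame(
    step = step_v[seq_len(snap_row * ns)],
    site = rep(seq_len(ns), times = snap_row),
    lambda = as.vector(t(lam_m[used, , drop = FALSE])),
    zeta = as.vector(t(zet_m[used, , drop = FALSE])),
    pH = params$pH %||% NA_real_)
  list(record = record, state = state, energies = energies,
       traj = if (keep_traj) traj else NULL)
}

#' Write / read a titration record as CSV
#'
#' Columns: step, site, lambda, zeta, pH.
#' @param record data.frame from [run_cphmd()].
#' @param path file path.
#' @export
write_titration_record <- function(record, path) {
  utils::write.csv(record, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_record
#' @export
read_titration_record <- function(path) {
  utils::read.csv(path)
}

#' Read a YAML run configuration
#'
#' Recognized keys (hyphenated or underscored): ph, temperature,
#' timestep-fs, steps, save-interval, barrier, theta-mass, friction, seed,
#' ph-ladder, exchange-interval.
#' @param path YAML file.
#' @return params list for [run_cphmd()] / [run_phrex()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  names(y) <- gsub("-", "_", names(y))
  map <- c(ph = "pH", timestep_fs = "timestep")
  for (k in names(map)) {
    if (!is.null(y[[k]])) { y[[map[k]]] <- y[[k]]; y[[k]] <- NULL }
  }
  y
}
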