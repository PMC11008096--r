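# pH replica exchange, BAR-based model-PMF construction, end-state fraction
# counting, and Hill-equation pKa fitting.

#' Metropolis criterion for a pH replica exchange
#'
#' Only the pH bias depends on pH, so the exchange energy is
#' `dE = [U_pH(lz_A; pH_B) + U_pH(lz_B; pH_A)] - [U_pH(lz_A; pH_A) +
#' U_pH(lz_B; pH_B)]` and the acceptance probability `min(1, exp(-dE/kT))`.
#'
#' @param lz_A,lz_B lambda/zeta vectors of the two replicas.
#' @param pH_A,pH_B their current pH values.
#' @param sites titratable sites (for reference pKas and lambda indices).
#' @param temperature K.
#' @return list with `dE` (kcal/mol) and `p` (acceptance probability).
#' @export
exchange_criterion <- function(lz_A, lz_B, pH_A, pH_B, sites, temperature) {
  kT <- KBOLTZ * temperature
  uph <- function(lz, pH) {
    s <- 0
    for (site in sites)
      s <- s + log(10) * kT * (site$pKa_ref - pH) *
        (1 - lz[site$lambda_index])
    s
  }
  dE <- (uph(lz_A, pH_B) + uph(lz_B, pH_A)) -
    (uph(lz_A, pH_A) + uph(lz_B, pH_B))
  list(dE = dE, p = min(1, exp(-dE / kT)))
}

#' Run pH replica exchange
#'
#' Replicas advance in blocks of `interval` steps; neighbour swaps are
#' attempted on alternating even/odd pairs, exchanging the pH values between
#' simulations.  Records are tagged by pH (the thermodynamic ensemble), not
#' by walker.
#'
#' @param system,config as in [run_cphmd()].
#' @param params base dynamics parameters (temperature, timestep, ...).
#' @param ph_ladder ascending pH values (>= 2).
#' @param steps total MD steps per replica.
#' @param interval steps between exchange attempts (default 500).
#' @param seed RNG seed.
#' @return list with `records` (one data.frame per pH, named by pH),
#'   `acceptance` (per neighbour pair), `attempts`.
#' @export
run_phrex <- function(system, config, params, ph_ladder, steps,
                      interval = 500L, seed = 1) {
  stopifnot(length(ph_ladder) >= 2, !is.unsorted(ph_ladder))
  set.seed(seed)
  R <- length(ph_ladder)
  walker_ph <- ph_ladder          # pH currently assigned to each walker
  states <- lapply(seq_len(R), function(r)
    extended_state(system, theta = params$theta0,
                   theta_mass = params$theta_mass %||% 5.0))
  derivs <- vector("list", R)
  spec <- list(timestep = params$timestep %||% 1.0,
               friction = params$friction %||% 5.0,
               temperature = params$temperature %||% 298)
  ns <- length(system$sites)
  li <- vapply(system$sites, `[[`, integer(1), "lambda_index")
  zi <- vapply(system$sites, `[[`, integer(1), "zeta_index")
  acc <- integer(R - 1); att <- integer(R - 1)
  n_blocks <- max(1L, floor(steps / interval))
  sv <- params$save_interval %||% 10L
  # walkers sharing a pH (a degenerate ladder) pool into one ensemble record
  cap <- R * n_blocks * (interval %/% sv) + 8L
  mk_buf <- function() list(row = 0L, step = integer(cap),
                            lam = matrix(NA_real_, cap, ns),
                            zet = matrix(NA_real_, cap, ns))
  bufs <- stats::setNames(lapply(unique(ph_ladder), function(p) mk_buf()),
                          as.character(unique(ph_ladder)))
  for (blk in seq_len(n_blocks)) {
    for (r in seq_len(R)) {
      pr <- params; pr$pH <- walker_ph[r]
      if (is.null(derivs[[r]]))
        derivs[[r]] <- total_extended_energy(system, states[[r]], config, pr)
      key <- as.character(walker_ph[r])
      for (s in seq_len(interval)) {
        out <- langevin_step(system, states[[r]], spec, config, pr,
                             derivs[[r]])
        states[[r]] <- out$state; derivs[[r]] <- out$deriv
        if (s %% sv == 0) {
          lzv <- sin(states[[r]]$theta)^2
          b <- bufs[[key]]
          b$row <- b$row + 1L
          b$step[b$row] <- (blk - 1L) * interval + s
          b$lam[b$row, ] <- lzv[li]
          b$zet[b$row, ] <- ifelse(is.na(zi), NA_real_, lzv[pmax(zi, 1L)])
          bufs[[key]] <- b
        }
      }
    }
    # neighbour exchanges on the pH ladder, alternating parity
    ord <- order(walker_ph)
    start <- if (blk %% 2 == 1) 1L else 2L
    ks <- if (start <= R - 1L) seq(start, R - 1L, by = 2L) else integer(0)
    for (k in ks) {
      a <- ord[k]; b <- ord[k + 1]
      ex <- exchange_criterion(state_lz(states[[a]]), state_lz(states[[b]]),
                               walker_ph[a], walker_ph[b], system$sites,
                               spec$temperature)
      att[k] <- att[k] + 1L
      if (stats::runif(1) < ex$p) {
        acc[k] <- acc[k] + 1L
        tmp <- walker_ph[a]; walker_ph[a] <- walker_ph[b]; walker_ph[b] <- tmp
        derivs[a] <- list(NULL); derivs[b] <- list(NULL)  # pH bias changed
      }
    }
  }
  records <- lapply(bufs, function(b) {
    if (b$row == 0L) return(NULL)
    used <- seq_len(b$row)
    data.frame(step = rep(b$step[used], each = ns),
               site = rep(seq_len(ns), times = b$row),
               lambda = as.vector(t(b$lam[used, , drop = FALSE])),
               zeta = as.vector(t(b$zet[used, , drop = FALSE])),
               pH = NA_real_)
  })
  names(records) <- names(bufs)
  for (k in names(records)) if (!is.null(records[[k]]))
    records[[k]]$pH <- as.numeric(k)
  list(records = records, acceptance = ifelse(att > 0, acc / att, NA),
       attempts = att)
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Self-consistent BAR solved by bisection to 1e-10 kcal/mol, with the
#' asymptotic variance estimate.  Forward work is for the A to B
#' perturbation, reverse for B to A; the estimate is antisymmetric under
#' swapping the two arrays.
#'
#' @param forward_work,reverse_work numeric vectors (kcal/mol), non-empty.
#' @param temperature K.
#' @return list with `dG` (kcal/mol) and `se` (standard error).
#' @export
bar_estimate <- function(forward_work, reverse_work, temperature = 298) {
  if (!length(forward_work) || !length(reverse_work))
    stop("BAR requires non-empty forward and reverse work arrays")
  beta <- 1 / (KBOLTZ * temperature)
  nf <- length(forward_work); nr <- length(reverse_work)
  M <- log(nf / nr) / beta
  f <- function(dG) {
    sum(1 / (1 + exp(beta * (M + forward_work - dG)))) -
      sum(1 / (1 + exp(-beta * (M - reverse_work - dG))))
  }
  lo <- min(-reverse_work, forward_work) - 50
  hi <- max(forward_work, -reverse_work) + 50
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  dG <- root$root
  # Bennett asymptotic variance
  ff <- 1 / (1 + exp(beta * (M + forward_work - dG)))
  fr <- 1 / (1 + exp(-beta * (M - reverse_work - dG)))
  ovl <- (mean(c(ff * (1 - ff), fr * (1 - fr))))
  if (ovl < 1e-12) {
    warning("negligible forward/reverse overlap; BAR uncertainty is large")
    se <- Inf
  } else {
    var_f <- (mean(ff^2) / mean(ff)^2 - 1) / nf
    var_r <- (mean(fr^2) / mean(fr)^2 - 1) / nr
    se <- sqrt(max(var_f + var_r, 0)) / beta
  }
  list(dG = dG, se = se)
}

#' Fit the model-compound bias polynomial from window free energies
#'
#' Accumulates the neighbour-window `dG` values into a PMF `G(lambda)` with
#' `G(0) = 0`, least-squares fits a polynomial with zero constant term, and
#' returns the coefficients of `U_mod = -G_fit`, the bias that flattens the
#' measured surface.  For ASP/GLU the tautomer-symmetric constraint
#' `G(1) = 0` is imposed (the two carboxylate oxygens are equivalent, so
#' the end states are degenerate).
#'
#' @param lambdas ascending window lambda values (first must be 0).
#' @param dG neighbour free-energy differences, `length(lambdas) - 1`.
#' @param degree polynomial degree (default 4).
#' @param symmetric impose the ASP/GLU end-state constraint.
#' @return coefficient vector for powers `1..degree` of U_mod.
#' @export
fit_model_pmf <- function(lambdas, dG, degree = 4, symmetric = FALSE) {
  stopifnot(length(lambdas) >= 3, length(dG) == length(lambdas) - 1)
  if (degree >= length(lambdas))
    stop("polynomial degree must be below the number of windows")
  G <- c(0, cumsum(dG))
  X <- outer(lambdas, seq_len(degree), `^`)
  if (symmetric) {
    # constrain sum(c_j) = 0 (G(1) = 0): substitute the last coefficient
    Xc <- X[, -degree, drop = FALSE] -
      outer(X[, degree], rep(1, degree - 1))
    fit <- stats::lm.fit(Xc, G)
    cc <- fit$coefficients
    coefs <- c(cc, -sum(cc))
  } else {
    coefs <- stats::lm.fit(X, G)$coefficients
  }
  -unname(coefs)
}

#' Collect titration windows and estimate the model PMF
#'
#' Runs fixed-lambda dynamics in each window, records the potential-energy
#' differences to the neighbouring windows as forward/reverse work, and
#' combines them with [bar_estimate()].
#'
#' @param system,config,params as in [run_cphmd()].
#' @param lambdas window values (default 11 evenly spaced on `[0, 1]`).
#' @param steps MD steps per window.
#' @param site_index which site titrates (others stay at their start).
#' @param zeta fixed tautomer value during titration windows.
#' @return list with `lambdas`, `dG`, `se` per neighbour pair.
#' @export
collect_pmf_windows <- function(system, config, params,
                                lambdas = seq(0, 1, length.out = 11),
                                steps = 200L, site_index = 1L, zeta = 0.5) {
  site <- system$sites[[site_index]]
  nth <- system$n_theta
  theta_of <- function(lam) {
    th <- rep(asin(sqrt(0.5)), nth)
    th[site$lambda_index] <- asin(sqrt(lam))
    if (!is.na(site$zeta_index)) th[site$zeta_index] <- asin(sqrt(zeta))
    th
  }
  lz_of <- function(lam) sin(theta_of(lam))^2
  u_at <- function(state_xyz, lam) {
    sys <- system; sys$xyz <- state_xyz
    lzv <- lz_of(lam)
    u <- if (system$n > 0)
      cph_energy(sys, lzv, config, gradient = FALSE)$energy else 0
    u + env_energy(system, lzv)$energy
  }
  nw <- length(lambdas)
  wf <- vector("list", nw); wr <- vector("list", nw)
  for (w in seq_len(nw)) {
    pr <- params
    pr$fixed_lambda <- TRUE
    pr$theta0 <- theta_of(lambdas[w])
    pr$barrier <- 0
    pr$store_traj <- system$n > 0
    pr$steps <- if (system$n > 0) steps else 0L
    out <- run_cphmd(system, config, pr)
    frames <- if (system$n > 0 && length(out$traj)) out$traj else
      list(system$xyz)
    wf[[w]] <- numeric(0); wr[[w]] <- numeric(0)
    for (xyz in frames) {
      u0 <- u_at(xyz, lambdas[w])
      if (w < nw) wf[[w]] <- c(wf[[w]], u_at(xyz, lambdas[w + 1]) - u0)
      if (w > 1) wr[[w]] <- c(wr[[w]], u_at(xyz, lambdas[w - 1]) - u0)
    }
  }
  dG <- numeric(nw - 1); se <- numeric(nw - 1)
  for (w in seq_len(nw - 1)) {
    est <- bar_estimate(wf[[w]], wr[[w + 1]],
                        params$temperature %||% 298)
    dG[w] <- est$dG; se[w] <- est$se
  }
  list(lambdas = lambdas, dG = dG, se = se)
}

#' Count protonation-state fractions from a lambda series
#'
#' Samples with `lambda <= 0.10` count as deprotonated, `lambda >= 0.90` as
#' protonated; anything between is discarded.
#'
#' @param lambda numeric vector of lambda samples (after any burn-in).
#' @return list with `S_deprot`, `n_deprot`, `n_prot`, `n_discarded`.
#' @export
count_fractions <- function(lambda) {
  stopifnot(length(lambda) > 0)
  nd <- sum(lambda <= 0.10)
  np <- sum(lambda >= 0.90)
  if (nd + np == 0)
    stop("no samples at either end state; deprotonated fraction undefined")
  list(S_deprot = nd / (nd + np), n_deprot = nd, n_prot = np,
       n_discarded = length(lambda) - nd - np)
}

#' Fit a titration curve to the Hill equation
#'
#' `S_deprot = 1 / (1 + 10^(n (pKa - pH)))` by nonlinear least squares;
#' the initial guess takes pKa at the pH whose fraction is closest to 0.5
#' and `n = 1`.
#'
#' @param pH pH values (>= 3, spanning the transition).
#' @param S deprotonated fractions in `[0, 1]`.
#' @return list with `pKa`, `n`, `residuals`, `cov` (parameter covariance).
#' @export
fit_hill <- function(pH, S) {
  stopifnot(length(pH) == length(S), length(pH) >= 3)
  if (max(S) < 0.05 || min(S) > 0.95)
    stop("no titration transition in the data; Hill fit is degenerate")
  df <- data.frame(pH = pH, S = S)
  start <- list(pKa = pH[which.min(abs(S - 0.5))], n = 1)
  fit <- minpack.lm::nlsLM(S ~ 1 / (1 + 10^(n * (pKa - pH))), data = df,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["n"]] <= 0) stop("Hill fit produced a non-positive coefficient")
  list(pKa = unname(cf[["pKa"]]), n = unname(cf[["n"]]),
       residuals = stats::residuals(fit),
       cov = tryCatch(stats::vcov(fit), error = function(e) NULL))
}

#' Titration curve and pKa from replica-exchange records
#'
#' Applies burn-in, counts end-state fractions per pH, and fits the Hill
#' equation.
#'
#' @param records list of per-pH records from [run_phrex()].
#' @param site site index to analyse.
#' @param burn_in fraction of initial samples discarded (default 0.1).
#' @return list with `pH`, `S`, `counts`, and the [fit_hill()] result.
#' @export
titration_curve <- function(records, site = 1L, burn_in = 0.1) {
  phs <- as.numeric(names(records))
  S <- numeric(0); keep_ph <- numeric(0); counts <- list()
  for (k in seq_along(records)) {
    r <- records[[k]]
    if (is.null(r)) next
    r <- r[r$site == site, ]
    r <- r[r$step > burn_in * max(r$step), ]
    fr <- count_fractions(r$lambda)
    S <- c(S, fr$S_deprot); keep_ph <- c(keep_ph, phs[k])
    counts[[as.character(phs[k])]] <- fr
  }
  fit <- fit_hill(keep_ph, S)
  list(pH = keep_ph, S = S, counts = counts, pKa = fit$pKa, n = fit$n,
       fit = fit)
}
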