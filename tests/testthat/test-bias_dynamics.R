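# Bias terms, extended-Hamiltonian assembly, Langevin propagation.

test_that("pH bias closed forms and barrier construction", {
  fx <- make_fixture("analytic-site", pKa_ref = 8.0)
  sys <- fx$system
  # pH = pKa: U_pH identically zero for any lambda
  for (lam in c(0, 0.3, 1)) {
    b <- bias_energy(sys, lam, list(pH = 8.0, temperature = 298, barrier = 0))
    expect_equal(unname(b$components["pH"]), 0)
  }
  # lambda = 1: U_pH = 0 ; lambda = 0 with pKa - pH = 1 at 298 K
  b1 <- bias_energy(sys, 1, list(pH = 7.0, temperature = 298, barrier = 0))
  expect_equal(unname(b1$components["pH"]), 0, tolerance = 1e-12)
  b0 <- bias_energy(sys, 0, list(pH = 7.0, temperature = 298, barrier = 0))
  expect_equal(unname(b0$components["pH"]),
               log(10) * 0.0019872041 * 298, tolerance = 1e-10)
  # barrier: U(0.5) - U(0) = beta_t exactly
  prm <- list(pH = 8.0, temperature = 298, barrier = 2.3)
  expect_equal(bias_energy(sys, 0.5, prm)$components[["barrier"]] -
                 bias_energy(sys, 0, prm)$components[["barrier"]], 2.3)
})

test_that("HIS three-surface model bias and analytic state derivatives", {
  sys <- make_fixture("model-compound", residue = "HIS")$system
  sys$sites[[1]]$model_bias <- list(tit1 = c(0.5, -1.2, 0.3),
                                    tit2 = c(-0.2, 0.8),
                                    taut = c(0.4, -0.4))
  prm <- list(pH = 6.6, temperature = 298, barrier = 1.7)
  h <- 1e-6
  set.seed(12)
  for (rep in 1:3) {
    lz <- runif(2, 0.05, 0.95)
    b <- bias_energy(sys, lz, prm)
    for (k in 1:2) {
      lp <- lm_ <- lz; lp[k] <- lp[k] + h; lm_[k] <- lm_[k] - h
      fd <- (bias_energy(sys, lp, prm)$energy -
               bias_energy(sys, lm_, prm)$energy) / (2 * h)
      expect_rel(b$dlz[k], fd, 1e-7, scale = max(abs(fd), 1e-3))
    }
  }
})

test_that("theta chain rule: dU/dtheta vanishes at theta = 0 and matches FD", {
  fx <- make_fixture("model-compound", residue = "CYS")
  sys <- fx$system; cfg <- fx$config
  cfg$scf_tol <- 1e-11
  prm <- list(pH = 8.3, temperature = 298, barrier = 2.0)
  st <- extended_state(sys, theta = 0)
  d0 <- total_extended_energy(sys, st, cfg, prm)
  expect_equal(d0$dtheta[1], 0)    # sin-chain factor kills the derivative
  st2 <- extended_state(sys, theta = 0.6)
  d2 <- total_extended_energy(sys, st2, cfg, prm)
  h <- 1e-5
  stp <- extended_state(sys, theta = 0.6 + h)
  stm <- extended_state(sys, theta = 0.6 - h)
  fd <- (total_extended_energy(sys, stp, cfg, prm, gradient = FALSE)$energy -
           total_extended_energy(sys, stm, cfg, prm,
                                 gradient = FALSE)$energy) / (2 * h)
  expect_rel(d2$dtheta[1], fd, 1e-5, scale = max(abs(fd), 1e-3))
})

test_that("sin^2 mapping keeps lambda in [0,1] over arbitrary theta walks", {
  set.seed(13)
  th <- cumsum(rnorm(2000, 0, 0.4))
  lam <- sin(th)^2
  expect_true(all(lam >= 0 & lam <= 1))
})

test_that("velocity-Verlet limit conserves extended energy", {
  fx <- make_fixture("model-compound", residue = "CYS")
  sys <- fx$system; cfg <- fx$config
  cfg$scf_tol <- 1e-9
  prm <- list(pH = 8.3, temperature = 30, barrier = 2.0)
  st <- extended_state(sys)
  set.seed(14)
  # relax at low temperature first so the conservation measurement is not
  # dominated by the initial geometry releasing potential energy
  spec_eq <- list(timestep = 0.5, friction = 25, temperature = 30)
  dv <- total_extended_energy(sys, st, cfg, prm)
  for (s in 1:120) {
    out <- langevin_step(sys, st, spec_eq, cfg, prm, dv)
    st <- out$state; dv <- out$deriv
  }
  spec <- list(timestep = 0.5, friction = 0, temperature = NA)
  ke <- function(s) (0.5 * sum(sys$masses * s$vel^2) +
                       0.5 * sum(s$theta_mass * s$theta_vel^2)) /
    cph_constants$acc
  e0 <- dv$energy + ke(st)
  nst <- 50
  for (s in seq_len(nst)) {
    out <- langevin_step(sys, st, spec, cfg, prm, dv)
    st <- out$state; dv <- out$deriv
  }
  expect_lt(abs(dv$energy + ke(st) - e0) / nst, 1e-4)
})

test_that("same seed gives bit-identical trajectories; free flight is linear", {
  fxa <- make_fixture("analytic-site")
  prm <- list(pH = 7, temperature = 298, barrier = 2, timestep = 1,
              friction = 5, steps = 200, save_interval = 10, seed = 42)
  r1 <- run_cphmd(fxa$system, fxa$config, prm)
  r2 <- run_cphmd(fxa$system, fxa$config, prm)
  expect_identical(r1$record, r2$record)
  # zero forces, zero friction: theta advances linearly
  sys0 <- fxa$system
  sys0$sites[[1]]$env_poly <- NULL
  sys0$sites[[1]]$pKa_ref <- 7
  st <- extended_state(sys0, theta = 0.3)
  st$theta_vel <- 0.01
  spec <- list(timestep = 1, friction = 0, temperature = NA)
  prm0 <- list(pH = 7, temperature = 298, barrier = 0)
  for (s in 1:5) {
    out <- langevin_step(sys0, st, spec, fxa$config, prm0)
    st <- out$state
  }
  expect_equal(st$theta, 0.3 + 5 * 0.01, tolerance = 1e-12)
})

test_that("thermostat equilibrates theta kinetic energy to the bath", {
  fxa <- make_fixture("analytic-site")
  sys <- fxa$system
  sys$sites[[1]]$env_poly <- NULL
  prm <- list(pH = 7, temperature = 298, barrier = 0.5, timestep = 2,
              friction = 10, theta_mass = 2)
  st <- extended_state(sys)
  spec <- list(timestep = 2, friction = 10, temperature = 298)
  set.seed(15)
  ke <- numeric(0)
  dv <- total_extended_energy(sys, st, fxa$config, prm)
  for (s in 1:20000) {
    out <- langevin_step(sys, st, spec, fxa$config, prm, dv)
    st <- out$state; dv <- out$deriv
    if (s > 2000 && s %% 10 == 0)
      ke <- c(ke, 0.5 * st$theta_mass * st$theta_vel^2 / cph_constants$acc)
  }
  target <- 0.5 * 0.0019872041 * 298
  # within 3 standard errors of the equipartition value (chi-square spread)
  se <- stats::sd(ke) / sqrt(length(ke) / 10)   # ~10-sample correlation
  expect_lt(abs(mean(ke) - target), 3 * se + 0.02 * target)
})

test_that("strong acid/base toys land on the expected end states", {
  run_toy <- function(dpk, seed) {
    fxa <- make_fixture("analytic-site", pKa_ref = 7 + dpk)
    sys <- fxa$system
    sys$sites[[1]]$env_poly <- NULL
    prm <- list(pH = 7, temperature = 298, barrier = 1.0, timestep = 2,
                friction = 10, theta_mass = 2, steps = 30000,
                save_interval = 20, seed = seed)
    out <- run_cphmd(sys, fxa$config, prm)
    lam <- out$record$lambda
    lam <- lam[seq_along(lam) > length(lam) * 0.2]
    mean(lam < 0.1)
  }
  expect_gt(run_toy(-6, 21), 0.95)   # strong acid: deprotonates and stays
  expect_lt(run_toy(+6, 22), 0.05)   # strong base: mirror
})

test_that("zero-step run records only the intermediate initial state", {
  fxa <- make_fixture("analytic-site")
  prm <- list(pH = 7, temperature = 298, barrier = 2, steps = 0, seed = 1)
  out <- run_cphmd(fxa$system, fxa$config, prm)
  expect_equal(nrow(out$record), 1L)
  expect_equal(out$record$lambda, 0.5, tolerance = 1e-12)
})
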