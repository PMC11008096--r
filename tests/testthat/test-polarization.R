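# Induced-dipole SCF, polarization energy/gradient, single-SCF derivative.

test_that("permanent fields: Coulomb closed form and group masking", {
  # unit charge probing a polarizable site 3 A away, vacuum
  sys <- cph_system(c("Q", "P"), c(1L, 2L), rbind(c(0, 0, 0), c(3, 0, 0)))
  sys$params <- list(scales = list(mpole = c(0, 0, 0.4, 0.8),
                                   `polar-p` = c(0, 0, 1, 1)))
  sys$multipoles[[1]] <- multipole_set(q = 1)
  sys$polar$alpha <- c(0, 1.0)
  sys$polar$group <- c(1L, 2L)
  cfg <- cph_config(NULL, cutoff = Inf)
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  fl <- compute_fields(sys, gm, cfg)
  expect_rel(sqrt(sum(fl$E_d[2, ]^2)), 332.063713 / 9, 1e-10)
  # same polarization group: no mutual direct-field contribution
  sys$polar$group <- c(1L, 1L)
  fl2 <- compute_fields(sys, gm, cfg)
  expect_equal(max(abs(fl2$E_d[2, ])), 0)
  expect_gt(max(abs(fl2$E_p[2, ])), 0)   # bonded p-mask unaffected (1-x pair)
})

test_that("field of a pure quadrupole matches numerical potential gradient", {
  Q <- diag(c(0.2, -0.05, -0.15))
  sys <- cph_system(c("A", "B"), c(1L, 2L), rbind(c(0, 0, 0), c(2.5, 1.1, -0.7)))
  sys$params <- list(scales = list(mpole = c(0, 0, 0.4, 0.8)))
  sys$multipoles[[1]] <- multipole_set(Q = Q)
  sys$polar$alpha <- c(0, 0.8)
  cfg <- cph_config(NULL, cutoff = Inf)
  # potential at x via the package's real-space dU/dM (charge row of atom B)
  pot <- function(x) {
    s2 <- sys; s2$xyz[2, ] <- x
    gm <- global_moments(s2, interpolate_system(s2, numeric(0)),
                         jacobian = FALSE)
    re <- real_space_permanent(s2, gm, c(cfg,
                                         list(paths = cphmdr:::bond_paths(s2))),
                               gradient = FALSE)
    re$phi_m[2, 1]
  }
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  fl <- compute_fields(sys, gm, cfg)
  h <- 1e-5
  x0 <- sys$xyz[2, ]
  for (g in 1:3) {
    xp <- x0; xp[g] <- xp[g] + h; xm <- x0; xm[g] <- xm[g] - h
    E_fd <- -(pot(xp) - pot(xm)) / (2 * h)
    expect_rel(fl$E_d[2, g], E_fd, 1e-7, scale = max(abs(E_fd), 1e-6))
  }
})

test_that("SCF: single site closed form, zero alpha, dense-matrix oracle", {
  # one polarizable site in the field of two fixed charges (vacuum)
  sys <- cph_system(c("Q1", "Q2", "P"), 1:3,
                    rbind(c(-3, 0, 0), c(3.5, 0.5, 0), c(0, 0.2, 0.1)))
  sys$params <- list(scales = list(mpole = c(0, 0, 0.4, 0.8)))
  sys$multipoles[[1]] <- multipole_set(q = 0.7)
  sys$multipoles[[2]] <- multipole_set(q = -0.4)
  sys$polar$alpha <- c(0, 0, 1.2)
  cfg <- cph_config(NULL, cutoff = Inf)
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  fl <- compute_fields(sys, gm, cfg)
  s <- scf_solve(sys, gm, fl$E_d, cfg, tol = 1e-12)
  expect_equal(s$iterations, 1L)             # no mutual coupling
  expect_equal(s$mu[3, ], 1.2 * fl$E_d[3, ] / 332.063713, tolerance = 1e-10)
  expect_equal(max(abs(s$mu[1:2, ])), 0)     # zero-alpha sites stay zero
  scf <- polarization_scf(sys, gm, cfg, tol = 1e-12)
  E2 <- sum(fl$E_p[3, ] * fl$E_d[3, ])
  expect_rel(polarization_energy(scf), -0.5 * 1.2 * E2 / 332.063713, 1e-9)

  # multi-site vacuum cluster against the independent dense solve
  fx <- vacuum_fixture(make_fixture("water-box", n = 2, seed = 5))
  sysv <- fx$system
  gmv <- global_moments(sysv, interpolate_system(sysv, numeric(0)),
                        jacobian = FALSE)
  cfgv <- fx$config
  flv <- compute_fields(sysv, gmv, cfgv)
  sv <- scf_solve(sysv, gmv, flv$E_d, cfgv, tol = 1e-13)
  # oracle: all pairs undamped/unmasked except intra-group direct masking is
  # already inside E_d; mutual induction has u-scale 1 with Thole damping
  mu_o <- oracle_dense_scf(sysv$xyz, gmv$alpha, flv$E_d)
  expect_lt(max(abs(sv$mu - mu_o)), 1e-9)
})

test_that("alpha = 0 everywhere gives exactly zero polarization", {
  fx <- vacuum_fixture(make_fixture("water-box", n = 2, seed = 6))
  sys <- fx$system
  sys$polar$alpha[] <- 0
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  fl <- compute_fields(sys, gm, fx$config)
  s <- scf_solve(sys, gm, fl$E_d, fx$config)
  expect_equal(max(abs(s$mu)), 0)
})

test_that("polarization energy is non-positive and finite under Thole at r -> 0", {
  fx <- vacuum_fixture(make_fixture("water-box", n = 2, seed = 7))
  sys <- fx$system
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  scf <- polarization_scf(sys, gm, fx$config)
  expect_lte(polarization_energy(scf), 0)
  # two polarizable sites approaching contact stay finite
  s2 <- cph_system(c("A", "B"), c(1L, 2L), rbind(c(0, 0, 0), c(0.05, 0, 0)))
  s2$params <- list(scales = list(mpole = c(0, 0, 0.4, 0.8)))
  s2$multipoles[[1]] <- multipole_set(q = 0.3)
  s2$multipoles[[2]] <- multipole_set(q = -0.3)
  s2$polar$alpha <- c(1.0, 1.0)
  cfg <- cph_config(NULL, cutoff = Inf)
  gm2 <- global_moments(s2, interpolate_system(s2, numeric(0)),
                        jacobian = FALSE)
  scf2 <- polarization_scf(s2, gm2, cfg)
  expect_true(is.finite(polarization_energy(scf2)))
})

test_that("unconverged SCF state is rejected", {
  fx <- vacuum_fixture(make_fixture("water-box", n = 2, seed = 8))
  sys <- fx$system
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  expect_error(scf_solve(sys, gm, compute_fields(sys, gm, fx$config)$E_d,
                         fx$config, tol = 1e-14, max_iter = 2L),
               "converge")
  scf <- polarization_scf(sys, gm, fx$config)
  scf$converged <- FALSE
  expect_error(polarization_energy(scf), "converged")
})

test_that("polarization gradient matches finite differences, forces sum to zero", {
  fx <- vacuum_fixture(make_fixture("water-box", n = 2, seed = 9))
  sys <- fx$system
  cfg <- fx$config
  cfg$scf_tol <- 1e-11
  e <- cph_energy(sys, numeric(0), cfg, terms = "pol")
  expect_lt(max(abs(colSums(e$terms$pol$forces))), 1e-8)
  h <- 1e-4
  set.seed(10)
  for (rep in 1:4) {
    i <- sample(sys$n, 1); g <- sample(3, 1)
    ep <- em <- sys
    ep$xyz[i, g] <- ep$xyz[i, g] + h
    em$xyz[i, g] <- em$xyz[i, g] - h
    fd <- (cph_energy(ep, numeric(0), cfg, gradient = FALSE,
                      terms = "pol")$energy -
             cph_energy(em, numeric(0), cfg, gradient = FALSE,
                        terms = "pol")$energy) / (2 * h)
    expect_rel(-e$terms$pol$forces[i, g], fd, 1e-5,
               scale = max(abs(fd), 1e-3))
  }
})

test_that("single-SCF state derivative equals re-solved finite difference", {
  for (res in c("CYS", "HIS")) {
    fx <- make_fixture("model-compound", residue = res)
    sys <- fx$system
    cfg <- fx$config
    cfg$scf_tol <- 1e-11
    set.seed(11)
    lz <- runif(sys$n_theta, 0.2, 0.8)
    e <- cph_energy(sys, lz, cfg, terms = "pol")
    h <- 1e-4
    for (k in seq_len(sys$n_theta)) {
      lp <- lm_ <- lz; lp[k] <- lp[k] + h; lm_[k] <- lm_[k] - h
      fd <- (cph_energy(sys, lp, cfg, gradient = FALSE,
                        terms = "pol")$energy -
               cph_energy(sys, lm_, cfg, gradient = FALSE,
                          terms = "pol")$energy) / (2 * h)
      expect_rel(e$terms$pol$dlz[k], fd, 1e-5, scale = max(abs(fd), 1e-3))
    }
  }
})
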