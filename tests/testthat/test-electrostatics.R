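# Permanent multipole electrostatics: Ewald real space, PME, corrections.

test_that("neutral charge pair reproduces Coulomb's law in the cluster limit", {
  fx <- make_fixture("two-charges")     # +1/-1 at 3 A, vacuum boundary
  U <- perm_total_energy(fx)
  expect_rel(U, -332.063713 / 3, 1e-4)
})

test_that("8-ion rock-salt lattice reproduces the Madelung constant", {
  fx <- make_fixture("ionic-lattice", n = 8)
  U <- perm_total_energy(fx)
  # energy per ion pair over nearest-neighbour distance 2.5 A, 4 pairs
  madelung <- -U / 4 * 2.5 / 332.063713
  expect_rel(madelung, 1.747565, 5e-4)
})

test_that("PME equals the direct k-space structure-factor sum", {
  fx <- make_fixture("water-box", n = 2, seed = 3)
  sys <- fx$system
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  cfg <- fx$config
  cfg$beta <- 0.7; cfg$grid <- rep(32, 3); cfg$order <- 8L
  rc <- pme_reciprocal(sys, gm$M, cfg, gradient = FALSE)
  Uk <- oracle_ksum(sys$xyz, gm$M, sys$cell, cfg$beta, kmax = 12)
  expect_rel(rc$energy, Uk, 1e-6)
  # doubling the grid density leaves the reciprocal energy unchanged
  cfg$grid <- rep(64, 3)
  r2 <- pme_reciprocal(sys, gm$M, cfg, gradient = FALSE)
  expect_rel(r2$energy, rc$energy, 1e-6)
})

test_that("total energy is invariant to the Ewald split (beta +- 20%)", {
  # charge pair in a large cell
  fx <- make_fixture("two-charges")
  U1 <- perm_total_energy(fx)
  fx2 <- fx
  fx2$config$beta <- fx$config$beta * 1.2
  fx2$config$grid <- rep(48, 3)
  expect_rel(perm_total_energy(fx2), U1, 1e-5)
  # ionic lattice (large |U|, dense packing)
  fxi <- make_fixture("ionic-lattice", n = 8)
  fxi$config$beta <- 1.45; fxi$config$order <- 8L
  Ua <- perm_total_energy(fxi)
  fxi$config$beta <- 1.74; fxi$config$grid <- rep(36, 3)
  expect_rel(perm_total_energy(fxi), Ua, 1e-5)
})

test_that("reciprocal energy is invariant under uniform translation", {
  fx <- make_fixture("diatomic-multipole")
  fx$config$order <- 10L
  fx$config$grid <- rep(32, 3)
  fx$config$beta <- 0.6
  U1 <- perm_total_energy(fx)
  fx$system$xyz <- fx$system$xyz + matrix(c(0.271, -0.38, 0.1492), 2, 3,
                                          byrow = TRUE)
  U2 <- perm_total_energy(fx)
  expect_lt(abs(U2 - U1), 1e-7)
})

test_that("self-energy closed form and neutrality behaviour", {
  cell <- crystal_cell(c(20, 20, 20, 90, 90, 90))
  M <- matrix(c(1, rep(0, 12)), 1)
  sn <- self_and_neutrality(M, list(beta = 0.5, neutralize = FALSE), cell)
  expect_equal(sn$energy, -0.5 / sqrt(pi) * 332.063713, tolerance = 1e-10)
  # neutral system: background term contributes nothing
  M2 <- rbind(c(1, rep(0, 12)), c(-1, rep(0, 12)))
  a <- self_and_neutrality(M2, list(beta = 0.5, neutralize = TRUE), cell)
  b <- self_and_neutrality(M2, list(beta = 0.5, neutralize = FALSE), cell)
  expect_equal(a$energy, b$energy)
  # charged system: the lambda derivative of the background term follows
  # dq_tot/dlambda through the charge row of dU/dM
  M3 <- matrix(c(0.4, rep(0, 12)), 1)
  qdot <- 1.0
  h <- 1e-6
  up <- self_and_neutrality(matrix(c(0.4 + h, rep(0, 12)), 1),
                            list(beta = 0.5), cell)$energy
  dn <- self_and_neutrality(matrix(c(0.4 - h, rep(0, 12)), 1),
                            list(beta = 0.5), cell)$energy
  sn3 <- self_and_neutrality(M3, list(beta = 0.5), cell)
  expect_rel(sn3$phi_m[1, 1] * qdot, (up - dn) / (2 * h), 1e-6)
})

test_that("zero moments give zero energy and forces", {
  fx <- make_fixture("diatomic-multipole")
  sys <- fx$system
  gm <- list(M = matrix(0, 2, 13), M_local = matrix(0, 2, 13),
             frames = lapply(1:2, function(i) list(type = "none",
                                                   deps = integer(0))))
  re <- real_space_permanent(sys, gm, c(fx$config,
                                        list(paths = cphmdr:::bond_paths(sys))))
  expect_equal(re$energy, 0)
  expect_equal(max(abs(re$forces)), 0)
})

test_that("state derivative of a titrating charge equals potential x q", {
  # two atoms: a fixed unit charge and a site whose charge is lambda * qP
  fx <- make_fixture("model-compound", residue = "LYS")
  sys <- fx$system; cfg <- fx$config
  cfg$scf_tol <- 1e-11
  lz <- 0.37
  e <- cph_energy(sys, lz, cfg, terms = c("real", "recip", "selfneut"))
  h <- 1e-5
  ep <- cph_energy(sys, lz + h, cfg, gradient = FALSE,
                   terms = c("real", "recip", "selfneut"))
  em <- cph_energy(sys, lz - h, cfg, gradient = FALSE,
                   terms = c("real", "recip", "selfneut"))
  dlz <- sum(vapply(e$terms, function(tm) tm$dlz[1], numeric(1)))
  expect_rel(dlz, (ep$energy - em$energy) / (2 * h), 1e-6,
             scale = max(abs(dlz), 1e-3))
})

test_that("reciprocal state-derivative contraction: nullity and linearity", {
  fx <- make_fixture("model-compound", residue = "CYS")
  sys <- fx$system
  lz <- 0.42
  gm <- global_moments(sys, interpolate_system(sys, lz), jacobian = FALSE)
  rc <- pme_reciprocal(sys, gm$M, fx$config, gradient = FALSE)
  # zero dM -> zero derivative
  dM0 <- lapply(gm$dM, function(d) list(atoms = d$atoms,
                                        m = if (length(d$atoms)) d$m * 0))
  expect_equal(recip_lambda_derivative(rc$phi_m, dM0), 0)
  # linear: doubling dM doubles the derivative
  d1 <- recip_lambda_derivative(rc$phi_m, gm$dM)
  dM2 <- lapply(gm$dM, function(d) list(atoms = d$atoms,
                                        m = if (length(d$atoms)) d$m * 2))
  expect_equal(recip_lambda_derivative(rc$phi_m, dM2), 2 * d1)
})

test_that("torque distribution conserves force and matches the frame chain", {
  fx <- make_fixture("water-box", n = 2, seed = 9)
  sys <- fx$system
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)))
  cfg <- c(fx$config, list(paths = cphmdr:::bond_paths(sys)))
  cfg$pairs <- cphmdr:::elec_pairs(sys, cfg$cutoff, cfg$paths)
  re <- real_space_permanent(sys, gm, cfg)
  # zero torque -> zero increments
  z <- distribute_torques(matrix(0, sys$n, 3), sys)
  expect_equal(max(abs(z)), 0)
  # torque route equals the dM/dp chain route for the same dU/dM
  tau <- multipole_torques(gm$M, re$phi_m)
  f_tau <- distribute_torques(tau, sys, gm$frames)
  f_chain <- cphmdr:::frame_chain_forces(sys, gm, re$phi_m)
  expect_lt(max(abs(f_tau - f_chain)), 1e-8)
  # net force conservation of the full real-space term
  total <- re$forces + f_chain
  expect_lt(max(abs(colSums(total))), 1e-8)
})

test_that("overlapping atoms without soft core raise a domain error", {
  fx <- make_fixture("diatomic-multipole")
  sys <- fx$system
  sys$xyz[2, ] <- sys$xyz[1, ] + 1e-8
  gm <- global_moments(sys, interpolate_system(sys, numeric(0)),
                       jacobian = FALSE)
  cfg <- c(fx$config, list(paths = cphmdr:::bond_paths(sys)))
  expect_error(real_space_permanent(sys, gm, cfg, gradient = FALSE),
               "overlapping")
})
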