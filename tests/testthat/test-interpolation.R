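# State interpolation of moments and polarizabilities, frame rotations.

mk_traceless <- function(seed, s = 0.2) {
  set.seed(seed)
  Q <- matrix(rnorm(9), 3, 3); Q <- Q + t(Q)
  (Q - diag(3) * sum(diag(Q)) / 3) * s
}

test_that("multipole interpolation endpoints and linear midpoints", {
  lys <- make_fixture("model-compound", residue = "LYS")$system
  site <- lys$sites[[1]]
  iN <- site$atoms[5]
  U <- cphmdr:::mset_to_m13(site$endstates$U[[as.character(iN)]]$multipole)
  P <- cphmdr:::mset_to_m13(site$endstates$P[[as.character(iN)]]$multipole)
  at0 <- interpolate_multipole(site, iN, 0)
  expect_equal(at0$M, U)
  expect_equal(at0$dM_dlambda, P - U)
  at1 <- interpolate_multipole(site, iN, 1)
  expect_equal(at1$M, P)
  # linear midpoint of the charge: q(U) = -0.7, q(P) = -0.2 -> -0.45
  mid <- interpolate_multipole(site, iN, 0.5)
  expect_equal(mid$M[1], (U[1] + P[1]) / 2)
  expect_error(interpolate_multipole(site, iN, 0.5, zeta = 0.3), "tautomer")
})

test_that("bilinear mixing matches finite differences for HIS", {
  his <- make_fixture("model-compound", residue = "HIS")$system
  site <- his$sites[[1]]
  a <- site$atoms[2]          # ND1, carries a dipole
  h <- 1e-5
  for (st in list(c(0.3, 0.7), c(0.85, 0.15))) {
    lam <- st[1]; zet <- st[2]
    v <- interpolate_multipole(site, a, lam, zet)
    fd_l <- (interpolate_multipole(site, a, lam + h, zet)$M -
               interpolate_multipole(site, a, lam - h, zet)$M) / (2 * h)
    fd_z <- (interpolate_multipole(site, a, lam, zet + h)$M -
               interpolate_multipole(site, a, lam, zet - h)$M) / (2 * h)
    expect_lt(max(abs(fd_l - v$dM_dlambda)), 1e-8)
    expect_lt(max(abs(fd_z - v$dM_dzeta)), 1e-8)
  }
})

test_that("cysteine sulfur polarizability interpolates 4.0 -> 2.8", {
  cys <- make_fixture("model-compound", residue = "CYS")$system
  site <- cys$sites[[1]]
  iS <- site$atoms[5]
  expect_equal(interpolate_polarizability(site, iS, 1)$alpha, 2.8)
  expect_equal(interpolate_polarizability(site, iS, 0)$alpha, 4.0)
  # brute-force linear form at lambda = 0.25
  expect_equal(interpolate_polarizability(site, iS, 0.25)$alpha,
               0.75 * 4.0 + 0.25 * 2.8)
  # titrating hydrogen switches off at the deprotonated end
  iHS <- site$tit_h$atom[1]
  expect_equal(interpolate_polarizability(site, iHS, 0)$alpha, 0)
  expect_equal(interpolate_polarizability(site, iHS, 1)$alpha, 0.496)
})

test_that("Thole damping width is frozen at the end-state mean", {
  cys <- make_fixture("model-compound", residue = "CYS")$system
  site <- cys$sites[[1]]
  iS <- site$atoms[5]
  expect_equal(thole_effective_density(site, iS), (4.0 + 2.8) / 2)
  # titrating hydrogen: the nonzero end state
  expect_equal(thole_effective_density(site, site$tit_h$atom[1]), 0.496)
  # state-independence: the same value at any lambda by construction, and
  # interpolate_system must carry zero damping derivative (value identical
  # at different states)
  i1 <- interpolate_system(cys, c(0.2))
  i2 <- interpolate_system(cys, c(0.9))
  expect_identical(i1$damp_alpha, i2$damp_alpha)
})

test_that("rotation to global frame: closed forms and invariants", {
  m <- m13_set <- c(0.3, 0.1, -0.2, 0.05, as.vector(mk_traceless(1)))
  # identity geometry: frame axes = lab axes
  owner <- c(0, 0, 0)
  fp <- rbind(c(0, 0, 1), c(1, 0, 0))   # z along z, x along x
  expect_equal(rotate_to_global(m, "zthenx", owner, fp), m)
  # 90 degree rotation about z maps an x-dipole to y
  dx <- c(0, 1, 0, 0, rep(0, 9))
  fp2 <- rbind(c(0, 0, 1), c(0, 1, 0))  # local x axis points along lab y
  r <- rotate_to_global(dx, "zthenx", owner, fp2)
  expect_equal(r[2:4], c(0, 1, 0), tolerance = 1e-12)
  # random rotation preserves |d| and quadrupole eigenvalues
  set.seed(4)
  fp3 <- matrix(rnorm(6), 2, 3)
  r3 <- rotate_to_global(m, "zthenx", owner, fp3)
  expect_equal(sqrt(sum(r3[2:4]^2)), sqrt(sum(m[2:4]^2)), tolerance = 1e-10)
  expect_equal(sort(eigen(matrix(r3[5:13], 3, 3))$values),
               sort(eigen(matrix(m[5:13], 3, 3))$values), tolerance = 1e-10)
  # degenerate frame errors
  expect_error(rotate_to_global(m, "zthenx", owner,
                                rbind(c(0, 0, 1), c(0, 0, 2))), "degenerate")
})

test_that("endpoint exactness after identical rotation", {
  cys <- make_fixture("model-compound", residue = "CYS")$system
  gm0 <- global_moments(cys, interpolate_system(cys, 0), jacobian = FALSE)
  gm1 <- global_moments(cys, interpolate_system(cys, 1), jacobian = FALSE)
  site <- cys$sites[[1]]
  for (a in site$atoms) {
    fr <- gm0$frames[[a]]
    U <- cphmdr:::rotate_m13(cphmdr:::mset_to_m13(site$endstates$U[[as.character(a)]]$multipole),
                    fr$R)
    P <- cphmdr:::rotate_m13(cphmdr:::mset_to_m13(site$endstates$P[[as.character(a)]]$multipole),
                    fr$R)
    expect_identical(gm0$M[a, ], U)
    expect_identical(gm1$M[a, ], P)
  }
})

test_that("total charge is affine in lambda with slope +-1 e", {
  for (res in c("LYS", "CYS", "ASP", "HIS")) {
    sys <- make_fixture("model-compound", residue = res)$system
    nth <- sys$n_theta
    lz <- rep(0.5, nth)
    qtot <- function(lam) {
      l <- lz; l[sys$sites[[1]]$lambda_index] <- lam
      sum(interpolate_system(sys, l)$M_local[, 1])
    }
    q0 <- qtot(0); q5 <- qtot(0.5); q1 <- qtot(1)
    expect_equal(q1 - q0, 1, tolerance = 1e-9)       # one proton charge
    expect_equal(q5, (q0 + q1) / 2, tolerance = 1e-9) # affine
  }
})
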