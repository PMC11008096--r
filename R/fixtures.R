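# Deterministic generators for all test systems: toy diatomics, small water
# boxes, titratable model compounds (reduced capped-residue analogs), a tiny
# P1 ionic lattice, and a dipeptide-crystal toy pairing an imidazole with a
# carboxylate in one periodic cell.
#
# The force-field numbers shipped here are fixture parameters: plausible
# subsets in the style of a polarizable multipole protein force field,
# documented as such (they are not a published parameter distribution).
# The cysteine sulfur polarizability end states (4.0 deprotonated, 2.8
# protonated, Angstrom^3) are the literature values for the titrating thiol.

AMOEBA_SCALES <- list(mpole = c(0, 0, 0.4, 0.8),
                      `polar-p` = c(0, 0, 1.0, 1.0),
                      vdw = c(0, 0, 1.0, 1.0))

#' @noRd
.msd <- function(q = 0, d = c(0, 0, 0), Q = matrix(0, 3, 3),
                 frame = "none", fa = integer(0))
  multipole_set(q, d, Q, frame, fa)

# harmonic bonded terms from the current geometry (taken as equilibrium)
#' @noRd
auto_bonded <- function(sys, k_bond = 400, k_angle = 50) {
  bonds <- list(); angles <- list()
  for (i in seq_len(sys$n)) for (j in sys$bonds[[i]]) if (j > i) {
    r0 <- sqrt(sum((sys$xyz[i, ] - sys$xyz[j, ])^2))
    kk <- if (sys$masses[i] < 2 || sys$masses[j] < 2) 450 else k_bond
    bonds[[length(bonds) + 1]] <- data.frame(i = i, j = j, k = kk, r0 = r0)
  }
  for (j in seq_len(sys$n)) {
    nb <- sys$bonds[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (c_ in seq_len(ncol(cmb))) {
        i <- cmb[1, c_]; k <- cmb[2, c_]
        u <- sys$xyz[i, ] - sys$xyz[j, ]; v <- sys$xyz[k, ] - sys$xyz[j, ]
        th0 <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
        angles[[length(angles) + 1]] <-
          data.frame(i = i, j = j, k = k, k_ = k_angle, th0 = th0)
      }
    }
  }
  sys$bonded <- list(
    bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
    angles = if (length(angles)) {
      a <- do.call(rbind, angles); names(a)[4] <- "k"; a
    } else NULL)
  sys
}

# one AMOEBA-style water (types: O = 101, H = 102), local geometry
#' @noRd
.water_block <- function(origin, rot = diag(3)) {
  r_oh <- 0.9572; ang <- 104.52 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(r_oh * sin(ang / 2), 0, r_oh * cos(ang / 2)),
               c(-r_oh * sin(ang / 2), 0, r_oh * cos(ang / 2)))
  xyz <- t(rot %*% t(xyz)) + matrix(origin, 3, 3, byrow = TRUE)
  list(names = c("O", "H1", "H2"), types = c(101L, 102L, 102L), xyz = xyz,
       bonds = list(c(2L, 3L), 1L, 1L))
}

#' @noRd
.water_params <- function(sys, idx, group) {
  O <- idx[1]; H1 <- idx[2]; H2 <- idx[3]
  qO <- -0.51966; qH <- 0.25983
  sys$multipoles[[O]] <- .msd(qO, c(0, 0, 0.14279 * BOHR),
                              diag(c(0.37928, -0.41809, 0.03881)) * BOHR^2,
                              "bisector", c(H1, H2))
  for (h in c(H1, H2)) {
    oth <- if (h == H1) H2 else H1
    sys$multipoles[[h]] <- .msd(qH, c(-0.03859, 0, -0.05818) * BOHR,
                                diag(c(-0.03673, -0.10739, 0.14412)) * BOHR^2,
                                "zthenx", c(O, oth))
  }
  sys$polar$alpha[idx] <- c(0.837, 0.496, 0.496)
  sys$polar$thole[idx] <- 0.39
  sys$polar$group[idx] <- group
  sys$vdw$rmin[idx] <- c(3.405, 2.655, 2.655)
  sys$vdw$eps[idx] <- c(0.110, 0.0135, 0.0135)
  sys$vdw$reduction[idx] <- c(1, 0.91, 0.91)
  sys$masses[idx] <- c(15.999, 1.008, 1.008)
  sys
}

# random rotation matrix from a seed-controlled RNG stream
#' @noRd
.rand_rot <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Titratable model-compound definitions (reduced Ace-X-Nme analogs).

#' Shipped cysteine model compound (methanethiol fragment)
#'
#' Builds atoms, geometry and end-state parameters for a titrating thiol:
#' sulfur polarizability 4.0 Angstrom^3 deprotonated, 2.8 protonated; the
#' titrating hydrogen switches off linearly.  Reference model pKa 8.3.
#'
#' @param offset index of the first atom of the fragment minus one.
#' @param origin position of the methyl carbon.
#' @return list with `block` (names/types/xyz/bonds) and `def` (residue
#'   definition for [build_titratable_sites()]).
#' @export
cys_model_def <- function(offset = 0L, origin = c(0, 0, 0)) {
  # C, HC x3, S, HS
  xyz <- rbind(c(0, 0, 0),
               c(-0.52, 0.95, 0), c(-0.52, -0.47, 0.82), c(-0.52, -0.47, -0.82),
               c(1.82, 0, 0),
               c(2.25, 1.27, 0))
  xyz <- xyz + matrix(origin, 6, 3, byrow = TRUE)
  names <- c("C", "HC1", "HC2", "HC3", "S", "HS")
  types <- c(201L, 202L, 202L, 202L, 203L, 204L)
  bonds <- list(c(2L, 3L, 4L, 5L), 1L, 1L, 1L, c(1L, 6L), 5L)
  bonds <- lapply(bonds, function(b) b + offset)
  iC <- 1L + offset; iS <- 5L + offset; iHS <- 6L + offset
  iHC <- 2:4 + offset
  mk <- function(qS, dS, qHS, qC, qHC, aS, aHS) {
    es <- list()
    es[[as.character(iC)]] <- list(multipole = .msd(qC), alpha = 1.334)
    for (h in iHC) es[[as.character(h)]] <- list(multipole = .msd(qHC),
                                                 alpha = 0.496)
    es[[as.character(iS)]] <- list(
      multipole = .msd(qS, c(0, 0, dS * BOHR), frame = "zthenx",
                       fa = c(iC, iHS)), alpha = aS)
    es[[as.character(iHS)]] <- list(multipole = .msd(qHS), alpha = aHS)
    es
  }
  def <- list(
    kind = "CYS",
    atoms = (1:6) + offset,
    tit_h = data.frame(atom = iHS, dir = 0),
    endstates = list(
      P = mk(qS = -0.22, dS = 0.25, qHS = 0.14, qC = 0.02, qHC = 0.02,
             aS = 2.8, aHS = 0.496),
      U = mk(qS = -0.90, dS = 0.40, qHS = 0.00, qC = -0.16, qHC = 0.02,
             aS = 4.0, aHS = 0.0)),
    pKa_ref = 8.3,
    model_bias = list(tit = numeric(0)))
  list(block = list(names = names, types = types, xyz = xyz, bonds = bonds),
       def = def,
       vdw = data.frame(idx = (1:6) + offset,
                        rmin = c(3.82, 2.96, 2.96, 2.96, 4.005, 2.77),
                        eps = c(0.101, 0.024, 0.024, 0.024, 0.355, 0.012),
                        reduction = c(1, 0.92, 0.92, 0.92, 1, 0.98)),
       masses = c(12.011, 1.008, 1.008, 1.008, 32.06, 1.008))
}

#' Shipped lysine model compound (methylammonium fragment)
#'
#' Titrating amine proton; no tautomer variable.  Reference model pKa 10.4.
#' @inheritParams cys_model_def
#' @export
lys_model_def <- function(offset = 0L, origin = c(0, 0, 0)) {
  # C, HC x3, N, HN1 (titrating), HN2, HN3
  xyz <- rbind(c(0, 0, 0),
               c(-0.52, 0.95, 0), c(-0.52, -0.47, 0.82), c(-0.52, -0.47, -0.82),
               c(1.49, 0, 0),
               c(1.90, 0.96, 0), c(1.90, -0.48, 0.83), c(1.90, -0.48, -0.83))
  xyz <- xyz + matrix(origin, 8, 3, byrow = TRUE)
  names <- c("C", "HC1", "HC2", "HC3", "N", "HZ1", "HZ2", "HZ3")
  types <- c(211L, 212L, 212L, 212L, 213L, 214L, 215L, 215L)
  bonds <- list(c(2L, 3L, 4L, 5L), 1L, 1L, 1L, c(1L, 6L, 7L, 8L), 5L, 5L, 5L)
  bonds <- lapply(bonds, function(b) b + offset)
  iC <- 1L + offset; iN <- 5L + offset; iHZ <- 6L + offset
  mk <- function(qN, dN, qHZ1, qHZ, qC, aHZ1) {
    es <- list()
    es[[as.character(iC)]] <- list(multipole = .msd(qC), alpha = 1.334)
    for (h in 2:4 + offset)
      es[[as.character(h)]] <- list(multipole = .msd(0.06), alpha = 0.496)
    es[[as.character(iN)]] <- list(
      multipole = .msd(qN, c(0, 0, dN * BOHR), frame = "zthenx",
                       fa = c(iC, iHZ)), alpha = 1.073)
    es[[as.character(iHZ)]] <- list(multipole = .msd(qHZ1), alpha = aHZ1)
    for (h in 7:8 + offset)
      es[[as.character(h)]] <- list(multipole = .msd(qHZ), alpha = 0.496)
    es
  }
  def <- list(
    kind = "LYS",
    atoms = (1:8) + offset,
    tit_h = data.frame(atom = iHZ, dir = 0),
    endstates = list(
      P = mk(qN = -0.20, dN = 0.12, qHZ1 = 0.31, qHZ = 0.31, qC = 0.09,
             aHZ1 = 0.496),
      U = mk(qN = -0.70, dN = 0.30, qHZ1 = 0.00, qHZ = 0.26, qC = 0.0,
             aHZ1 = 0.0)),
    pKa_ref = 10.4,
    model_bias = list(tit = numeric(0)))
  list(block = list(names = names, types = types, xyz = xyz, bonds = bonds),
       def = def,
       vdw = data.frame(idx = (1:8) + offset,
                        rmin = c(3.82, 2.96, 2.96, 2.96, 3.71, 2.70, 2.70, 2.70),
                        eps = c(0.101, 0.024, 0.024, 0.024, 0.105, 0.011,
                                0.011, 0.011),
                        reduction = c(1, 0.92, 0.92, 0.92, 1, 0.97, 0.97, 0.97)),
       masses = c(12.011, 1.008, 1.008, 1.008, 14.007, 1.008, 1.008, 1.008))
}

#' Shipped aspartate/glutamate model compound (acetate-like fragment)
#'
#' Carboxylate with two titrating "dummy" protons, one per oxygen, tagged
#' with opposite tautomer directions; the symmetric parameter sets make the
#' two protonated tautomers equivalent.  Reference model pKa 4.0 (ASP) or
#' 4.4 (GLU).
#' @param kind `"ASP"` or `"GLU"`.
#' @inheritParams cys_model_def
#' @export
asp_model_def <- function(offset = 0L, origin = c(0, 0, 0), kind = "ASP") {
  # Cme, HCx3, Ccarb, O1, O2, H1, H2
  xyz <- rbind(c(0, 0, 0),
               c(-0.52, 0.95, 0), c(-0.52, -0.47, 0.82), c(-0.52, -0.47, -0.82),
               c(1.52, 0, 0),
               c(2.17, 1.07, 0), c(2.17, -1.07, 0),
               c(3.14, 1.02, 0), c(3.14, -1.02, 0))
  xyz <- xyz + matrix(origin, 9, 3, byrow = TRUE)
  names <- c("CB", "HB1", "HB2", "HB3", "CG", "OD1", "OD2", "HD1", "HD2")
  types <- c(221L, 222L, 222L, 222L, 223L, 224L, 224L, 225L, 225L)
  bonds <- list(c(2L, 3L, 4L, 5L), 1L, 1L, 1L, c(1L, 6L, 7L),
                c(5L, 8L), c(5L, 9L), 6L, 7L)
  bonds <- lapply(bonds, function(b) b + offset)
  iCG <- 5L + offset; iO1 <- 6L + offset; iO2 <- 7L + offset
  iH1 <- 8L + offset; iH2 <- 9L + offset
  mk <- function(qO1, qO2, dO1, dO2, qH1, qH2, qCG, qCB, aO1, aO2, aH1, aH2) {
    es <- list()
    es[[as.character(1L + offset)]] <- list(multipole = .msd(qCB),
                                            alpha = 1.334)
    for (h in 2:4 + offset)
      es[[as.character(h)]] <- list(multipole = .msd(0.0), alpha = 0.496)
    es[[as.character(iCG)]] <- list(multipole = .msd(qCG), alpha = 1.334)
    es[[as.character(iO1)]] <- list(
      multipole = .msd(qO1, c(0, 0, dO1 * BOHR), frame = "zthenx",
                       fa = c(iCG, iO2)), alpha = aO1)
    es[[as.character(iO2)]] <- list(
      multipole = .msd(qO2, c(0, 0, dO2 * BOHR), frame = "zthenx",
                       fa = c(iCG, iO1)), alpha = aO2)
    es[[as.character(iH1)]] <- list(multipole = .msd(qH1), alpha = aH1)
    es[[as.character(iH2)]] <- list(multipole = .msd(qH2), alpha = aH2)
    es
  }
  def <- list(
    kind = kind,
    atoms = (1:9) + offset,
    tit_h = data.frame(atom = c(iH1, iH2), dir = c(1, -1)),
    endstates = list(
      U = mk(-0.80, -0.80, 0.30, 0.30, 0, 0, 0.90, -0.30,
             aO1 = 0.92, aO2 = 0.92, aH1 = 0, aH2 = 0),
      P1 = mk(-0.60, -0.55, 0.22, 0.25, 0.45, 0, 0.75, -0.05,
              aO1 = 0.83, aO2 = 0.92, aH1 = 0.496, aH2 = 0),
      P2 = mk(-0.55, -0.60, 0.25, 0.22, 0, 0.45, 0.75, -0.05,
              aO1 = 0.92, aO2 = 0.83, aH1 = 0, aH2 = 0.496)),
    pKa_ref = if (kind == "ASP") 4.0 else 4.4,
    model_bias = list(tit = numeric(0)))
  list(block = list(names = names, types = types, xyz = xyz, bonds = bonds),
       def = def,
       vdw = data.frame(idx = (1:9) + offset,
                        rmin = c(3.82, 2.96, 2.96, 2.96, 3.82, 3.30, 3.30,
                                 2.66, 2.66),
                        eps = c(0.101, 0.024, 0.024, 0.024, 0.106, 0.112,
                                0.112, 0.015, 0.015),
                        reduction = c(1, 0.92, 0.92, 0.92, 1, 1, 1, 0.94, 0.94)),
       masses = c(12.011, 1.008, 1.008, 1.008, 12.011, 15.999, 15.999,
                  1.008, 1.008))
}

#' Shipped histidine model compound (imidazole fragment)
#'
#' Two titrating ring protons: HE2 (tautomer direction +1) and HD1 (-1).
#' Charged end state P; neutral tautomers U1 (epsilon-protonated, HIE) and
#' U2 (delta-protonated, HID).  Reference model pKa 6.6.
#' @inheritParams cys_model_def
#' @export
his_model_def <- function(offset = 0L, origin = c(0, 0, 0)) {
  # ring: CG, ND1, CE1, NE2, CD2 ; protons: HD1, HE1, HE2, HD2
  R <- 1.37 / (2 * sin(pi / 5))
  ang <- (0:4) * 2 * pi / 5 + pi / 2
  ring <- cbind(R * cos(ang), R * sin(ang), 0)
  hpos <- function(k) ring[k, ] * (1 + 1.02 / R)
  xyz <- rbind(ring, hpos(2), hpos(3), hpos(4), hpos(5))
  xyz <- xyz + matrix(origin, 9, 3, byrow = TRUE)
  names <- c("CG", "ND1", "CE1", "NE2", "CD2", "HD1", "HE1", "HE2", "HD2")
  types <- c(231L, 232L, 233L, 234L, 235L, 236L, 237L, 238L, 239L)
  bonds <- list(c(2L, 5L), c(1L, 3L, 6L), c(2L, 4L, 7L), c(3L, 5L, 8L),
                c(4L, 1L, 9L), 2L, 3L, 4L, 5L)
  bonds <- lapply(bonds, function(b) b + offset)
  iCG <- 1L + offset; iND1 <- 2L + offset; iCE1 <- 3L + offset
  iNE2 <- 4L + offset; iCD2 <- 5L + offset
  iHD1 <- 6L + offset; iHE1 <- 7L + offset; iHE2 <- 8L + offset
  iHD2 <- 9L + offset
  mk <- function(qCG, qND1, qCE1, qNE2, qCD2, qHD1, qHE2, dND1, dNE2,
                 aHD1, aHE2) {
    es <- list()
    put <- function(i, ms, a) es[[as.character(i)]] <<- list(multipole = ms,
                                                             alpha = a)
    put(iCG, .msd(qCG), 1.75)
    put(iND1, .msd(qND1, c(0, 0, dND1 * BOHR), frame = "zthenx",
                   fa = c(iCE1, iCG)), 1.073)
    put(iCE1, .msd(qCE1), 1.75)
    put(iNE2, .msd(qNE2, c(0, 0, dNE2 * BOHR), frame = "zthenx",
                   fa = c(iCE1, iCD2)), 1.073)
    put(iCD2, .msd(qCD2), 1.75)
    put(iHD1, .msd(qHD1), aHD1)
    put(iHE1, .msd(0.08), 0.496)
    put(iHE2, .msd(qHE2), aHE2)
    put(iHD2, .msd(0.08), 0.496)
    es
  }
  def <- list(
    kind = "HIS",
    atoms = (1:9) + offset,
    tit_h = data.frame(atom = c(iHE2, iHD1), dir = c(1, -1)),
    endstates = list(
      P  = mk(0.10, -0.15, 0.22, -0.15, 0.18, 0.32, 0.32, 0.10, 0.10,
              aHD1 = 0.496, aHE2 = 0.496),
      U1 = mk(0.00, -0.56, 0.09, -0.10, 0.11, 0.00, 0.30, 0.35, 0.12,
              aHD1 = 0.0, aHE2 = 0.496),                       # HIE
      U2 = mk(0.11, -0.10, 0.09, -0.56, 0.00, 0.30, 0.00, 0.12, 0.35,
              aHD1 = 0.496, aHE2 = 0.0)),                      # HID
    pKa_ref = 6.6,
    model_bias = list(tit1 = numeric(0), tit2 = numeric(0),
                      taut = numeric(0)))
  list(block = list(names = names, types = types, xyz = xyz, bonds = bonds),
       def = def,
       vdw = data.frame(idx = (1:9) + offset,
                        rmin = c(3.80, 3.71, 3.80, 3.71, 3.80, 2.59, 2.98,
                                 2.59, 2.98),
                        eps = c(0.101, 0.105, 0.101, 0.105, 0.101, 0.022,
                                0.026, 0.022, 0.026),
                        reduction = c(1, 1, 1, 1, 1, 0.96, 0.92, 0.96, 0.92)),
       masses = c(12.011, 14.007, 12.011, 14.007, 12.011, 1.008, 1.008,
                  1.008, 1.008))
}

# assemble blocks into one system
#' @noRd
.assemble <- function(blocks, cell = NULL) {
  names <- unlist(lapply(blocks, `[[`, "names"))
  types <- unlist(lapply(blocks, `[[`, "types"))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  bonds <- do.call(c, lapply(blocks, `[[`, "bonds"))
  sys <- cph_system(names, types, xyz, bonds, cell = cell)
  sys$params <- list(scales = AMOEBA_SCALES)
  sys
}

#' @noRd
.apply_model <- function(sys, model, group) {
  sys$vdw[model$vdw$idx, ] <- model$vdw[, c("rmin", "eps", "reduction")]
  sys$masses[model$def$atoms] <- model$masses
  sys$polar$group[model$def$atoms] <- group
  # static multipoles/alphas are irrelevant for site atoms (interpolation
  # overrides), but polarize/thole defaults matter for damping widths
  sys$polar$thole[model$def$atoms] <- 0.39
  sys
}

#' Generate a deterministic test fixture
#'
#' @param kind one of `"diatomic-multipole"`, `"two-charges"`,
#'   `"water-box"`, `"ionic-lattice"`, `"model-compound"`,
#'   `"dipeptide-crystal-toy"`, `"analytic-site"`.
#' @param n size parameter (waters in the box; ions in the lattice).
#' @param residue for `"model-compound"`: ASP, GLU, HIS, LYS or CYS.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param pKa_ref reference pKa for `"analytic-site"`.
#' @return list with `system` (a [cph_system()]) and `config` (a matched
#'   [cph_config()] with fixture-scaled Ewald settings).
#' @export
make_fixture <- function(kind, n = 8, residue = "CYS", seed = 1,
                         pKa_ref = 7.0) {
  set.seed(seed)
  kind <- match.arg(kind, c("diatomic-multipole", "two-charges", "water-box",
                            "ionic-lattice", "model-compound",
                            "dipeptide-crystal-toy", "analytic-site"))
  if (kind == "diatomic-multipole") {
    L <- 10
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    sys <- cph_system(c("A", "B"), c(1L, 2L),
                      rbind(c(3.0, 5.0, 5.0), c(6.1, 5.2, 4.9)),
                      list(2L, 1L), cell = cell)
    sys$params <- list(scales = AMOEBA_SCALES)
    sys$multipoles[[1]] <- .msd(0.4, c(0, 0, 0.12), diag(c(-0.1, -0.1, 0.2)),
                                "zonly", 2L)
    sys$multipoles[[2]] <- .msd(-0.4, c(0, 0, -0.08),
                                diag(c(0.05, 0.05, -0.1)), "zonly", 1L)
    sys$polar$alpha <- c(1.1, 0.9)
    sys$polar$group <- c(1L, 2L)
    sys <- auto_bonded(sys)
    cfg <- cph_config(cell, beta = 0.8, cutoff = 4.9, grid = rep(24, 3),
                      order = 6L, vdw_cutoff = 4.9, vdw_taper = 4.0)
    return(list(system = sys, config = cfg))
  }
  if (kind == "two-charges") {
    L <- 40
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    sys <- cph_system(c("P", "M"), c(1L, 2L),
                      rbind(c(0, 0, 0), c(3, 0, 0)), cell = cell)
    sys$params <- list(scales = AMOEBA_SCALES)
    sys$multipoles[[1]] <- .msd(1)
    sys$multipoles[[2]] <- .msd(-1)
    cfg <- cph_config(cell, beta = 0.35, cutoff = 14, grid = rep(40, 3),
                      order = 6L, boundary = "vacuum")
    return(list(system = sys, config = cfg))
  }
  if (kind == "ionic-lattice") {
    a <- 5.0
    m <- round(n^(1 / 3))
    stopifnot(m^3 == n)
    L <- a / 2 * m
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    g <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1))) * a / 2
    q <- (-1)^rowSums(g / (a / 2))
    sys <- cph_system(paste0("I", seq_len(n)), seq_len(n), g, cell = cell)
    sys$params <- list(scales = AMOEBA_SCALES)
    for (i in seq_len(n)) sys$multipoles[[i]] <- .msd(q[i])
    cfg <- cph_config(cell, beta = 1.3, cutoff = L / 2 - 0.01,
                      grid = rep(24, 3), order = 6L)
    return(list(system = sys, config = cfg))
  }
  if (kind == "water-box") {
    m <- ceiling(n^(1 / 3))
    sp <- 3.1
    L <- max(m * sp, 8.6)
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    blocks <- list()
    cnt <- 0
    for (ix in 0:(m - 1)) for (iy in 0:(m - 1)) for (iz in 0:(m - 1)) {
      if (cnt >= n) next
      cnt <- cnt + 1
      origin <- (c(ix, iy, iz) + 0.5) * L / m +
        stats::runif(3, -0.25, 0.25)
      blocks[[cnt]] <- .water_block(origin, .rand_rot())
    }
    # reindex bonds per block
    off <- 0
    for (b in seq_along(blocks)) {
      blocks[[b]]$bonds <- lapply(blocks[[b]]$bonds, function(x) x + off)
      off <- off + 3
    }
    sys <- .assemble(blocks, cell)
    for (b in seq_along(blocks))
      sys <- .water_params(sys, (b - 1) * 3 + 1:3, group = b)
    sys <- auto_bonded(sys)
    cfg <- cph_config(cell, beta = max(0.9, 3.8 / (L / 2 - 0.4)),
                      cutoff = L / 2 - 0.3,
                      grid = rep(2 * ceiling(L * 1.2), 3), order = 6L,
                      vdw_cutoff = L / 2 - 0.3, vdw_taper = L / 2 - 1.3)
    return(list(system = sys, config = cfg))
  }
  if (kind == "model-compound") {
    residue <- toupper(residue)
    L <- 14
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    origin <- c(L / 2 - 1, L / 2, L / 2)
    model <- switch(residue,
                    CYS = cys_model_def(0L, origin),
                    LYS = lys_model_def(0L, origin),
                    ASP = asp_model_def(0L, origin, "ASP"),
                    GLU = asp_model_def(0L, origin, "GLU"),
                    HIS = his_model_def(0L, origin))
    wb <- .water_block(origin + c(4.4, 0.6, 0.2), .rand_rot())
    nmod <- length(model$block$names)
    wb$bonds <- lapply(wb$bonds, function(x) x + nmod)
    sys <- .assemble(list(model$block, wb), cell)
    sys <- .apply_model(sys, model, group = 1L)
    sys <- .water_params(sys, nmod + 1:3, group = 2L)
    sys <- build_titratable_sites(sys, list(model$def))
    sys <- auto_bonded(sys)
    cfg <- cph_config(cell, beta = 0.65, cutoff = 6.4, grid = rep(28, 3),
                      order = 6L, vdw_cutoff = 6.4, vdw_taper = 5.2)
    return(list(system = sys, config = cfg))
  }
  if (kind == "dipeptide-crystal-toy") {
    L <- 13.5
    cell <- crystal_cell(c(L, L, L, 90, 90, 90))
    his <- his_model_def(0L, c(4.0, 6.8, 6.8))
    nh <- length(his$block$names)
    asp <- asp_model_def(nh, c(8.2, 6.3, 6.8), "ASP")
    sys <- .assemble(list(his$block, asp$block), cell)
    sys <- .apply_model(sys, his, group = 1L)
    sys <- .apply_model(sys, asp, group = 2L)
    sys <- build_titratable_sites(sys, list(his$def, asp$def))
    sys <- auto_bonded(sys)
    cfg <- cph_config(cell, beta = 0.68, cutoff = 6.2, grid = rep(28, 3),
                      order = 6L, vdw_cutoff = 6.2, vdw_taper = 5.0)
    return(list(system = sys, config = cfg))
  }
  # analytic-site: a zero-atom toy with one two-state titration site whose
  # synthetic environment potential stands in for the nonbonded PMF
  sys <- cph_system(character(0), integer(0), matrix(0, 0, 3))
  sys$params <- list(scales = AMOEBA_SCALES)
  def <- list(kind = "LYS", atoms = integer(0),
              tit_h = data.frame(atom = integer(0), dir = numeric(0)),
              endstates = list(U = list(), P = list()),
              pKa_ref = pKa_ref,
              model_bias = list(tit = numeric(0)))
  sys <- build_titratable_sites(sys, list(def))
  # smooth synthetic environment surface in lambda (kcal/mol)
  sys$sites[[1]]$env_poly <- c(0.8, -2.1, 1.5)   # c1 l + c2 l^2 + c3 l^3
  cfg <- cph_config(NULL)
  list(system = sys, config = cfg)
}
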