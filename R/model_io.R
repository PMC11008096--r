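# Domain model: molecular systems, force-field parameters, titratable sites.

#' Construct a permanent atomic multipole set
#'
#' A multipole set holds the charge, dipole and traceless quadrupole of one
#' atom, expressed in a local chemical frame.  Dipoles are in e*Angstrom and
#' quadrupoles in e*Angstrom^2 (see [cph_constants] for unit conventions).
#'
#' @param q monopole, elementary charge units.
#' @param d dipole 3-vector.
#' @param Q symmetric 3x3 quadrupole; any trace is removed (shifted equally
#'   off the diagonal) with a warning if it exceeds 1e-10.
#' @param frame local frame convention: one of `"none"`, `"zonly"`,
#'   `"zthenx"`, `"bisector"`, `"zbisect"`.
#' @param frame_atoms integer indices of the frame-defining atoms (up to 3).
#' @return an object of class `cph_multipole`.
#' @export
multipole_set <- function(q = 0, d = c(0, 0, 0), Q = matrix(0, 3, 3),
                          frame = "none", frame_atoms = integer(0)) {
  frame <- match.arg(frame, c("none", "zonly", "zthenx", "bisector", "zbisect"))
  Q <- (Q + t(Q)) / 2
  tr <- sum(diag(Q))
  if (abs(tr) > 1e-10) Q <- Q - diag(3) * tr / 3
  structure(list(q = q, d = as.numeric(d), Q = Q, frame = frame,
                 frame_atoms = as.integer(frame_atoms)),
            class = "cph_multipole")
}

#' @noRd
mset_to_m13 <- function(ms) m13(ms$q, ms$d, ms$Q)

#' Construct a triclinic crystal cell
#'
#' @param lattice either a 3x3 matrix whose columns are the cell vectors
#'   a, b, c (Angstrom) or a length-6 vector `c(a, b, c, alpha, beta, gamma)`
#'   with angles in degrees.
#' @return object of class `cph_cell` with the lattice matrix, its inverse
#'   and the cell volume.
#' @export
crystal_cell <- function(lattice) {
  if (is.numeric(lattice) && length(lattice) == 6) {
    lattice <- lattice_from_abc(lattice[1], lattice[2], lattice[3],
                                lattice[4], lattice[5], lattice[6])
  }
  stopifnot(is.matrix(lattice), all(dim(lattice) == c(3, 3)))
  det <- det(lattice)
  if (abs(det) < 1e-8) stop("cell lattice is singular")
  structure(list(lattice = lattice, inv = solve(lattice), volume = abs(det),
                 abc = unname(sqrt(colSums(lattice^2)))),
            class = "cph_cell")
}

#' @noRd
lattice_from_abc <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  av <- c(a, 0, 0)
  bv <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  cbind(av, bv, c(cx, cy, cz))
}

# width of the cell slab along each lattice direction (for min-image safety)
#' @noRd
cell_widths <- function(cell) {
  L <- cell$lattice
  w <- numeric(3)
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    nrm <- pracma_cross(L[, others[1]], L[, others[2]])
    w[k] <- abs(sum(L[, k] * nrm)) / sqrt(sum(nrm^2))
  }
  w
}

#' @noRd
pracma_cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                                 u[3] * v[1] - u[1] * v[3],
                                 u[1] * v[2] - u[2] * v[1])

# minimum-image displacement x_i - x_j (3-vector) under a cell (NULL = vacuum)
#' @noRd
min_image <- function(dx, cell) {
  if (is.null(cell)) return(dx)
  s <- cell$inv %*% dx
  as.vector(cell$lattice %*% (s - round(s)))
}

#' Assemble a molecular system
#'
#' The container used throughout the package.  Atom indices are 1-based.
#'
#' @param names character atom labels.
#' @param types integer force-field atom types.
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param bonds list of integer vectors; `bonds[[i]]` are the neighbours of
#'   atom i.  Must be symmetric.
#' @param cell optional [crystal_cell()].
#' @param params optional force-field table from [read_parameters()].
#' @param masses optional atomic masses (amu); guessed from names if missing.
#' @return object of class `cph_system`.
#' @export
cph_system <- function(names, types, xyz, bonds = NULL, cell = NULL,
                       params = NULL, masses = NULL) {
  n <- length(names)
  xyz <- matrix(as.numeric(xyz), n, 3)
  if (is.null(bonds)) bonds <- rep(list(integer(0)), n)
  check_bond_symmetry(bonds)
  if (is.null(masses)) masses <- guess_mass(names)
  sys <- structure(list(
    n = n, names = names, types = as.integer(types), xyz = xyz,
    bonds = bonds, cell = cell, params = params, masses = masses,
    sites = list(),
    multipoles = rep(list(multipole_set()), n),
    polar = data.frame(alpha = numeric(n), thole = rep(0.39, n),
                       group = seq_len(n)),
    vdw = data.frame(rmin = rep(0, n), eps = rep(0, n),
                     reduction = rep(1, n))
  ), class = "cph_system")
  if (!is.null(params)) sys <- apply_parameters(sys)
  sys
}

#' @noRd
check_bond_symmetry <- function(bonds) {
  for (i in seq_along(bonds)) {
    for (j in bonds[[i]]) {
      if (j < 1 || j > length(bonds) || !(i %in% bonds[[j]]))
        stop(sprintf("bond list is not symmetric: %d-%d", i, j))
    }
  }
  invisible(TRUE)
}

#' Read a Tinker-style XYZ file
#'
#' First line: atom count (and optional title).  An optional second line with
#' exactly six numbers is interpreted as the periodic box
#' `a b c alpha beta gamma`.  Atom records are
#' `index name x y z type [bonded indices...]`.
#'
#' @param path file path.
#' @return a list with elements `system` (a [cph_system()] without parameters)
#'   and `cell` (a [crystal_cell()] or NULL).
#' @export
read_tinker_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n)) stop("line 1: expected an atom count")
  cur <- 2
  cell <- NULL
  tok2 <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  nums <- suppressWarnings(as.numeric(tok2))
  if (length(tok2) == 6 && !anyNA(nums)) {
    cell <- crystal_cell(nums)
    cur <- 3
  }
  if (length(lines) < cur + n - 1) stop("fewer atom records than the header count")
  nm <- character(n); ty <- integer(n); xyz <- matrix(0, n, 3)
  bonds <- rep(list(integer(0)), n)
  for (k in seq_len(n)) {
    ln <- cur + k - 1
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 6) stop(sprintf("line %d: malformed atom record", ln))
    vals <- suppressWarnings(as.numeric(tok[c(1, 3, 4, 5, 6)]))
    if (anyNA(vals)) stop(sprintf("line %d: malformed atom record", ln))
    idx <- as.integer(vals[1])
    if (idx != k) stop(sprintf("line %d: atom indices must be contiguous", ln))
    nm[k] <- tok[2]
    xyz[k, ] <- vals[2:4]
    ty[k] <- as.integer(vals[5])
    if (length(tok) > 6) bonds[[k]] <- as.integer(tok[7:length(tok)])
  }
  sys <- cph_system(nm, ty, xyz, bonds, cell = cell)
  list(system = sys, cell = cell)
}

#' Write a Tinker-style XYZ file
#'
#' @param system a [cph_system()].
#' @param path output path.
#' @param title optional title appended to the header line.
#' @export
write_tinker_xyz <- function(system, path, title = "cphmdr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%6d  %s", system$n, title), con)
  if (!is.null(system$cell)) {
    L <- system$cell$lattice
    abc <- sqrt(colSums(L^2))
    ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    writeLines(sprintf("  %12.8f %12.8f %12.8f %12.6f %12.6f %12.6f",
                       abc[1], abc[2], abc[3],
                       ang(L[, 2], L[, 3]), ang(L[, 1], L[, 3]),
                       ang(L[, 1], L[, 2])), con)
  }
  for (k in seq_len(system$n)) {
    writeLines(sprintf("%6d  %-4s %13.8f %13.8f %13.8f %6d %s",
                       k, system$names[k], system$xyz[k, 1], system$xyz[k, 2],
                       system$xyz[k, 3], system$types[k],
                       paste(sprintf("%6d", system$bonds[[k]]), collapse = "")),
               con)
  }
  invisible(path)
}

#' Read a force-field parameter file
#'
#' A simplified Tinker-PRM-like dialect.  Records:
#' \preformatted{
#' scale mpole  0.0 0.0 0.4 0.8      # 1-2 1-3 1-4 1-5 permanent mask
#' scale polar-p 0.0 0.0 1.0 1.0     # bonded mask for the energy field
#' scale vdw    0.0 0.0 1.0 1.0
#' atom      <type> <name> <mass>
#' vdw       <type> <rmin> <eps> [reduction]
#' polarize  <type> <alpha> <thole> <group-id>
#' multipole <type> <frame> [frame type args]
#'           <q>
#'           <dx> <dy> <dz>                   (e*Bohr)
#'           <Qxx> <Qyy> <Qzz> <Qxy> <Qxz> <Qyz>  (e*Bohr^2)
#' }
#' Frame keywords: `none`, `zonly`, `zthenx`, `bisector`, `zbisect`.  Dipoles
#' and quadrupoles are converted from the Tinker e*Bohr convention on load and
#' quadrupoles are made traceless.
#'
#' @param path file path.
#' @return a list with data frames `atoms`, `vdw`, `polarize`, a list
#'   `multipoles` keyed by atom type, and `scales`.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  strip <- function(s) trimws(sub("#.*$", "", s))
  out <- list(atoms = NULL, vdw = NULL, polarize = NULL,
              multipoles = list(),
              scales = list(mpole = c(0, 0, 0.4, 0.8),
                            `polar-p` = c(0, 0, 1, 1),
                            vdw = c(0, 0, 1, 1)))
  at <- list(); vd <- list(); pl <- list()
  i <- 1
  while (i <= length(lines)) {
    s <- strip(lines[i])
    if (!nzchar(s)) { i <- i + 1; next }
    tok <- strsplit(s, "\\s+")[[1]]
    key <- tolower(tok[1])
    if (key == "scale") {
      out$scales[[tolower(tok[2])]] <- as.numeric(tok[3:6])
    } else if (key == "atom") {
      at[[length(at) + 1]] <- data.frame(type = as.integer(tok[2]),
                                         name = tok[3],
                                         mass = as.numeric(tok[4]))
    } else if (key == "vdw") {
      vd[[length(vd) + 1]] <- data.frame(
        type = as.integer(tok[2]), rmin = as.numeric(tok[3]),
        eps = as.numeric(tok[4]),
        reduction = if (length(tok) >= 5) as.numeric(tok[5]) else 1.0)
    } else if (key == "polarize") {
      pl[[length(pl) + 1]] <- data.frame(
        type = as.integer(tok[2]), alpha = as.numeric(tok[3]),
        thole = as.numeric(tok[4]), group = as.integer(tok[5]))
    } else if (key == "multipole") {
      frame <- tolower(tok[3])
      if (!frame %in% c("none", "zonly", "zthenx", "bisector", "zbisect"))
        stop(sprintf("line %d: unknown multipole frame keyword '%s'", i, tok[3]))
      nargs <- c(none = 0, zonly = 1, zthenx = 2, bisector = 2, zbisect = 3)[frame]
      ftypes <- if (nargs > 0) as.integer(tok[4:(3 + nargs)]) else integer(0)
      qv <- as.numeric(strsplit(strip(lines[i + 1]), "\\s+")[[1]])
      dv <- as.numeric(strsplit(strip(lines[i + 2]), "\\s+")[[1]])
      qq <- as.numeric(strsplit(strip(lines[i + 3]), "\\s+")[[1]])
      if (length(qv) != 1 || length(dv) != 3 || length(qq) != 6)
        stop(sprintf("line %d: malformed multipole block", i))
      Q <- matrix(0, 3, 3)
      diag(Q) <- qq[1:3]
      Q[1, 2] <- Q[2, 1] <- qq[4]; Q[1, 3] <- Q[3, 1] <- qq[5]
      Q[2, 3] <- Q[3, 2] <- qq[6]
      ms <- multipole_set(q = qv, d = dv * BOHR, Q = Q * BOHR^2, frame = frame)
      ms$frame_types <- ftypes
      out$multipoles[[as.character(as.integer(tok[2]))]] <- ms
      i <- i + 3
    } else {
      stop(sprintf("line %d: unknown record '%s'", i, tok[1]))
    }
    i <- i + 1
  }
  out$atoms <- if (length(at)) do.call(rbind, at) else
    data.frame(type = integer(0), name = character(0), mass = numeric(0))
  out$vdw <- if (length(vd)) do.call(rbind, vd) else
    data.frame(type = integer(0), rmin = numeric(0), eps = numeric(0),
               reduction = numeric(0))
  out$polarize <- if (length(pl)) do.call(rbind, pl) else
    data.frame(type = integer(0), alpha = numeric(0), thole = numeric(0),
               group = integer(0))
  # every atom type referenced by a multipole frame must exist
  reftypes <- unique(unlist(lapply(out$multipoles, `[[`, "frame_types")))
  known <- unique(c(out$atoms$type,
                    as.integer(names(out$multipoles))))
  missing <- setdiff(reftypes, known)
  if (length(missing))
    stop("multipole frames reference unknown atom types: ",
         paste(missing, collapse = ", "))
  out
}

# Attach per-atom parameters (vdw, polarize, multipole + resolved frame
# atoms) from system$params to the system.
#' @noRd
apply_parameters <- function(sys) {
  p <- sys$params
  for (i in seq_len(sys$n)) {
    ty <- sys$types[i]
    r <- p$vdw[p$vdw$type == ty, ]
    if (nrow(r)) sys$vdw[i, ] <- list(r$rmin[1], r$eps[1], r$reduction[1])
    r <- p$polarize[p$polarize$type == ty, ]
    if (nrow(r)) sys$polar[i, ] <- list(r$alpha[1], r$thole[1], r$group[1])
    r <- p$atoms[p$atoms$type == ty, ]
    if (nrow(r)) sys$masses[i] <- r$mass[1]
    ms <- p$multipoles[[as.character(ty)]]
    if (!is.null(ms)) {
      ms$frame_atoms <- resolve_frame_atoms(sys, i, ms$frame, ms$frame_types)
      sys$multipoles[[i]] <- ms
    }
  }
  sys
}

# Resolve frame-defining atom types to indices: z among bonded neighbours,
# x among remaining neighbours or neighbours-of-z, y among the rest.
#' @noRd
resolve_frame_atoms <- function(sys, i, frame, ftypes) {
  if (frame == "none" || length(ftypes) == 0) return(integer(0))
  nb <- sys$bonds[[i]]
  pick <- function(cands, ty, used) {
    hit <- cands[sys$types[cands] == ty & !(cands %in% c(i, used))]
    if (!length(hit)) NA_integer_ else hit[1]
  }
  z <- pick(nb, ftypes[1], integer(0))
  if (is.na(z)) stop(sprintf("atom %d: no bonded neighbour of type %d for the z axis",
                             i, ftypes[1]))
  out <- z
  if (length(ftypes) >= 2) {
    cands <- unique(c(nb, sys$bonds[[z]]))
    x <- pick(cands, ftypes[2], out)
    if (is.na(x)) stop(sprintf("atom %d: cannot resolve x-axis atom of type %d",
                               i, ftypes[2]))
    out <- c(out, x)
  }
  if (length(ftypes) >= 3) {
    cands <- unique(c(nb, sys$bonds[[z]]))
    y <- pick(cands, ftypes[3], out)
    if (is.na(y)) stop(sprintf("atom %d: cannot resolve third frame atom of type %d",
                               i, ftypes[3]))
    out <- c(out, y)
  }
  out
}

#' Define titratable sites on a system
#'
#' Builds validated titratable-site records from residue definitions.  Each
#' definition lists the member atoms, the titrating hydrogens with their
#' tautomer direction tags, the per-atom end-state multipoles and
#' polarizabilities, the reference model pKa and the model-bias polynomial.
#'
#' End states must share the local frame convention and frame atoms for every
#' member atom: the state-interpolated moments are rotated once into the
#' global frame, which is only valid when the frames concur.
#'
#' HIS sites carry a tautomer variable (zeta) and three end states (`P`,
#' `U1` = epsilon-protonated, `U2` = delta-protonated); ASP/GLU carry zeta
#' with end states `U`, `P1`, `P2`; LYS/CYS have no tautomer and end states
#' `U`, `P`.
#'
#' @param system a [cph_system()].
#' @param definitions list of residue definitions (see [cys_model_def()] and
#'   friends for the shipped model-compound set).
#' @return the system with `sites` populated; lambda/zeta indices into the
#'   theta vector are assigned in order.
#' @export
build_titratable_sites <- function(system, definitions) {
  theta_i <- 0L
  sites <- list()
  for (def in definitions) {
    kind <- toupper(def$kind)
    if (!kind %in% c("ASP", "GLU", "HIS", "LYS", "CYS"))
      stop("unsupported residue kind: ", kind)
    has_zeta <- kind %in% c("ASP", "GLU", "HIS")
    needed <- if (kind == "HIS") c("P", "U1", "U2") else
      if (has_zeta) c("U", "P1", "P2") else c("U", "P")
    if (!all(needed %in% names(def$endstates)))
      stop(kind, " definition must provide end states: ",
           paste(needed, collapse = ", "))
    # frame consistency across end states, per atom
    for (a in as.character(def$atoms)) {
      fr <- lapply(def$endstates[needed], function(es) es[[a]]$multipole)
      f0 <- fr[[1]]
      for (f in fr[-1]) {
        if (!identical(f$frame, f0$frame) ||
            !identical(f$frame_atoms, f0$frame_atoms))
          stop("atom ", a, ": local frame and frame atoms must be identical ",
               "for all titration end states (single shared rotation)")
      }
    }
    theta_i <- theta_i + 1L
    lam_idx <- as.integer(theta_i)
    zeta_idx <- NA_integer_
    if (has_zeta) { theta_i <- theta_i + 1L; zeta_idx <- as.integer(theta_i) }
    nb <- def$model_bias
    if (is.null(nb)) {
      nb <- if (kind == "HIS")
        list(tit1 = numeric(0), tit2 = numeric(0), taut = numeric(0))
      else list(tit = numeric(0))
    }
    sites[[length(sites) + 1]] <- structure(list(
      residue_kind = kind,
      lambda_index = lam_idx,
      zeta_index = zeta_idx,
      atoms = as.integer(def$atoms),
      tit_h = def$tit_h,              # data.frame(atom, dir in {+1,-1,0})
      endstates = def$endstates,
      pKa_ref = def$pKa_ref,
      model_bias = nb
    ), class = "cph_site")
  }
  system$sites <- sites
  system$n_theta <- theta_i
  system
}
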