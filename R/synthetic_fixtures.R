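# Synthetic binder-phosphopeptide fixtures ----------------------------------
#
# Deterministic generator of idealized complexes so every pipeline stage is
# testable without structure downloads.  Backbones are built by internal-
# coordinate (NeRF) chaining with ideal bond lengths and angles; side
# chains beyond C-beta are omitted except the phosphotyrosine (full ring +
# phosphate at ideal geometry) and explicit pseudo-donor atoms, because all
# in-scope metrics are backbone/C-beta/phosphate based.  Not a physical
# model: no rotamers, no minimization, only a hard-sphere sanity check.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
            y = "PTR")

HELIX_PHI <- -57; HELIX_PSI <- -47
STRAND_PHI <- -120; STRAND_PSI <- 120
EXTENDED_PHI <- -140; EXTENDED_PSI <- 140

rot_about_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s,  a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s,  a[2] * a[2] * C + c_,        a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s,  a[3] * a[2] * C + a[1] * s,  a[3] * a[3] * C + c_
  ), 3, 3, byrow = TRUE)
}

rot_align <- function(a, b) {
  # rotation taking unit vector a onto unit vector b
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b)
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) pracma_cross(a, c(1, 0, 0)) else pracma_cross(a, c(0, 1, 0))
    return(rot_about_axis(perp, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
}

# Build a backbone chain from per-residue (phi, psi) by NeRF chaining.
# Returns an atom data.frame (N, CA, C, O, CB except GLY; PTR side chains
# when requested).
build_chain_atoms <- function(resnames, phi, psi, omega = 180,
                              chain = "A", start_resno = 1L) {
  n <- length(resnames)
  stopifnot(length(phi) == n, length(psi) == n)
  rows <- list()
  add <- function(resno, resname, elety, xyz, sc = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, elety = elety,
      element = guess_element(elety), x = xyz[1], y = xyz[2], z = xyz[3],
      occ = 1.0, stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C <- CA + c(1.525 * cos(pi - ang), 1.525 * sin(pi - ang), 0)
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    if (i > 1) {
      N <- place_atom_nerf(prevN, prevCA, prevC, 1.329, 116.2, psi[i - 1])
      CA <- place_atom_nerf(prevCA, prevC, N, 1.458, 121.7, omega)
      C <- place_atom_nerf(prevC, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom_nerf(N, CA, C, 1.231, 120.5, psi[i] + 180)
    add(resno, resnames[i], "N", N)
    add(resno, resnames[i], "CA", CA)
    add(resno, resnames[i], "C", C)
    add(resno, resnames[i], "O", O)
    if (resnames[i] != "GLY") {
      CB <- ideal_cbeta(N, CA, C)
      add(resno, resnames[i], "CB", CB, sc = TRUE)
      if (resnames[i] == "PTR") {
        CG  <- place_atom_nerf(N, CA, CB, 1.51, 113.9, -60)
        CD1 <- place_atom_nerf(CA, CB, CG, 1.39, 120.9, 90)
        CD2 <- place_atom_nerf(CA, CB, CG, 1.39, 120.9, -90)
        CE1 <- place_atom_nerf(CB, CG, CD1, 1.39, 121.0, 180)
        CE2 <- place_atom_nerf(CB, CG, CD2, 1.39, 121.0, 180)
        CZ  <- place_atom_nerf(CG, CD1, CE1, 1.39, 119.8, 0)
        OH  <- place_atom_nerf(CD1, CE1, CZ, 1.38, 120.0, 180)
        P   <- place_atom_nerf(CE1, CZ, OH, 1.61, 119.0, 90)
        O1P <- place_atom_nerf(CZ, OH, P, 1.48, 108.0, 60)
        O2P <- place_atom_nerf(CZ, OH, P, 1.48, 108.0, 180)
        O3P <- place_atom_nerf(CZ, OH, P, 1.48, 108.0, -60)
        for (nm in c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH",
                     "P", "O1P", "O2P", "O3P")) {
          add(resno, resnames[i], nm, get(nm), sc = TRUE)
        }
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, rows)
}

#' Build an ideal poly-alanine alpha helix
#'
#' Ideal helical dihedrals (phi = -57, psi = -47, omega = 180 degrees) with
#' ideal bond geometry; the helix axis is aligned to +z and the first
#' C-alpha starts near `start`.
#'
#' @param length number of residues (>= 2).
#' @param start 3-vector for the helix start.
#' @param chain chain id.
#' @param start_resno first residue number.
#' @return atom data.frame suitable for [complex_structure()].
#' @export
build_ideal_helix <- function(length, start = c(0, 0, 0), chain = "A",
                              start_resno = 1L) {
  if (length < 2) stop("helix length must be >= 2")
  at <- build_chain_atoms(rep("ALA", length), rep(HELIX_PHI, length),
                          rep(HELIX_PSI, length), chain = chain,
                          start_resno = start_resno)
  align_chain_axis(at, target = c(0, 0, 1), origin = start)
}

# Align a chain's CA principal axis to `target` (pointing from first to
# last residue), then translate so the CA centroid sits at `origin`.
align_chain_axis <- function(at, target = c(0, 0, 1), origin = c(0, 0, 0)) {
  ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  axis <- sv$v[, 1]
  if (sum(axis * (ca[nrow(ca), ] - ca[1, ])) < 0) axis <- -axis
  R <- rot_align(axis, target)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, cen) %*% t(R)
  xyz <- sweep(xyz, 2, origin, `+`)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

#' Build a phosphopeptide chain
#'
#' One-letter sequence over the 20 standard amino acids plus `'y'` for
#' phosphotyrosine; PTR positions get the full ring and phosphate group at
#' ideal geometry, all other residues are backbone + C-beta.
#'
#' @param sequence one-letter sequence string.
#' @param conformation `"extended"`, `"strand"`, or `"helix"`.
#' @param chain chain id.
#' @param start_resno first residue number.
#' @return atom data.frame.
#' @export
build_phosphopeptide <- function(sequence,
                                 conformation = c("extended", "strand", "helix"),
                                 chain = "B", start_resno = 1L) {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- which(!(letters1 %in% names(AA1TO3)))
  if (length(bad) > 0) {
    stop("invalid sequence character '", letters1[bad[1]], "' at position ", bad[1])
  }
  resnames <- unname(AA1TO3[letters1])
  n <- length(resnames)
  if (n < 3) stop("peptide length must be >= 3")
  dih <- switch(conformation,
                helix = c(HELIX_PHI, HELIX_PSI),
                strand = c(STRAND_PHI, STRAND_PSI),
                extended = c(EXTENDED_PHI, EXTENDED_PSI))
  at <- build_chain_atoms(resnames, rep(dih[1], n), rep(dih[2], n),
                          chain = chain, start_resno = start_resno)
  align_chain_axis(at)
}

#' Fixture specification for a toy binder-phosphopeptide complex
#'
#' @param binder_topology `"single_helix"`, `"helix_bundle"` (three packed
#'   antiparallel helices), or `"sheet"` (three antiparallel strands).
#' @param binder_length core binder residue count (>= 10; tails extra).
#' @param peptide_sequence one-letter sequence, `'y'` = PTR.
#' @param peptide_conformation backbone conformation of the peptide.
#' @param separation minimum C-beta gap between peptide contact residues
#'   and the binder, Angstrom (must be <= 7 for contacts to be possible).
#' @param n_contact_residues how many peptide residues (counted from the
#'   N-terminus) must be in C-beta contact (<= 7 A) with the binder.
#' @param phosphate_donor_distances distances (A) at which pseudo-donor
#'   nitrogens are planted from a terminal phosphate oxygen (max 3).
#' @param disorder_tail_len unfolded extended residues appended at each
#'   binder terminus.
#' @param seed integer seed (recorded; the construction is deterministic).
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(binder_topology = c("helix_bundle", "single_helix", "sheet"),
                         binder_length = 48L,
                         peptide_sequence = "AAEyIAA",
                         peptide_conformation = "extended",
                         separation = 5.5,
                         n_contact_residues = 4L,
                         phosphate_donor_distances = c(2.9, 3.0),
                         disorder_tail_len = 0L,
                         seed = 1L) {
  binder_topology <- match.arg(binder_topology)
  if (binder_length < 10) stop("binder_length must be >= 10")
  if (nchar(peptide_sequence) < 3) stop("peptide length must be >= 3")
  if (separation <= 0) stop("separation must be > 0")
  if (length(phosphate_donor_distances) > 3) {
    stop("at most 3 phosphate donor distances supported")
  }
  structure(list(binder_topology = binder_topology,
                 binder_length = as.integer(binder_length),
                 peptide_sequence = peptide_sequence,
                 peptide_conformation = peptide_conformation,
                 separation = separation,
                 n_contact_residues = as.integer(n_contact_residues),
                 phosphate_donor_distances = phosphate_donor_distances,
                 disorder_tail_len = as.integer(disorder_tail_len),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

build_binder_atoms <- function(spec) {
  n <- spec$binder_length
  tail_n <- spec$disorder_tail_len
  ext <- c(EXTENDED_PHI, EXTENDED_PSI)
  hel <- c(HELIX_PHI, HELIX_PSI)
  if (spec$binder_topology == "single_helix") {
    total <- n + 2 * tail_n
    phi <- c(rep(ext[1], tail_n), rep(hel[1], n), rep(ext[1], tail_n))
    psi <- c(rep(ext[2], tail_n), rep(hel[2], n), rep(ext[2], tail_n))
    at <- build_chain_atoms(rep("ALA", total), phi, psi, chain = "A")
    at <- align_core_axis(at, core = tail_n + seq_len(n))
    if (tail_n > 0) {
      at <- hinge_tail(at, seq_len(tail_n), tail_n + 1L, c(-1, 0, -0.7))
      at <- hinge_tail(at, n + tail_n + seq_len(tail_n), n + tail_n, c(-1, 0, 0.7))
    }
    return(at)
  }
  if (spec$binder_topology == "sheet") {
    len <- floor(n / 3)
    segs <- list()
    resno0 <- 1L
    for (k in 1:3) {
      sl <- if (k == 3) n - 2 * len else len
      phi <- rep(STRAND_PHI, sl); psi <- rep(STRAND_PSI, sl)
      if (k == 1 && tail_n > 0) {
        sl <- sl + tail_n; phi <- c(rep(ext[1], tail_n), phi); psi <- c(rep(ext[2], tail_n), psi)
      }
      if (k == 3 && tail_n > 0) {
        sl <- sl + tail_n; phi <- c(phi, rep(ext[1], tail_n)); psi <- c(psi, rep(ext[2], tail_n))
      }
      at <- build_chain_atoms(rep("ALA", sl), phi, psi, chain = "A",
                              start_resno = resno0)
      core <- seq_len(sl)
      if (k == 1 && tail_n > 0) core <- core[-seq_len(tail_n)]
      if (k == 3 && tail_n > 0) core <- core[seq_len(length(core) - tail_n)]
      at <- align_core_axis(at, core = core)
      if (k %% 2 == 0) at <- flip_chain(at)
      at <- translate_atoms(at, c(4.8 * (k - 1), 0, 0))
      resnos <- sort(unique(at$resno))
      if (k == 1 && tail_n > 0) {
        at <- hinge_tail(at, resnos[seq_len(tail_n)], resnos[tail_n + 1],
                         c(0, -1, -0.7))
      }
      if (k == 3 && tail_n > 0) {
        nr <- length(resnos)
        at <- hinge_tail(at, resnos[(nr - tail_n + 1):nr], resnos[nr - tail_n],
                         c(0, 1, 0.7))
      }
      segs[[k]] <- at
      resno0 <- resno0 + sl
    }
    return(do.call(rbind, segs))
  }
  # helix_bundle: three antiparallel helices on a triangle, axis spacing
  # 10 A; azimuths chosen so the groove between the first two helices faces
  # +x, where the peptide is later docked
  len <- floor(n / 3)
  r <- 10 / sqrt(3)
  az <- c(-60, 60, 180) * pi / 180
  centers <- cbind(r * cos(az), r * sin(az), 0)
  segs <- list()
  resno0 <- 1L
  for (k in 1:3) {
    sl <- if (k == 3) n - 2 * len else len
    phi <- rep(hel[1], sl); psi <- rep(hel[2], sl)
    if (k == 1 && tail_n > 0) {
      sl <- sl + tail_n; phi <- c(rep(ext[1], tail_n), phi); psi <- c(rep(ext[2], tail_n), psi)
    }
    if (k == 3 && tail_n > 0) {
      sl <- sl + tail_n; phi <- c(phi, rep(ext[1], tail_n)); psi <- c(psi, rep(ext[2], tail_n))
    }
    at <- build_chain_atoms(rep("ALA", sl), phi, psi, chain = "A",
                            start_resno = resno0)
    core <- seq_len(sl)
    if (k == 1 && tail_n > 0) core <- core[-seq_len(tail_n)]
    if (k == 3 && tail_n > 0) core <- core[seq_len(length(core) - tail_n)]
    at <- align_core_axis(at, core = core)
    if (k %% 2 == 0) at <- flip_chain(at)
    at <- translate_atoms(at, centers[k, ])
    resnos <- sort(unique(at$resno))
    if (k == 1 && tail_n > 0) {
      out1 <- c(cos(az[1]), sin(az[1]), 0) + c(0, 0, -0.7)
      at <- hinge_tail(at, resnos[seq_len(tail_n)], resnos[tail_n + 1], out1)
    }
    if (k == 3 && tail_n > 0) {
      nr <- length(resnos)
      out3 <- c(cos(az[3]), sin(az[3]), 0) + c(0, 0, 0.7)
      at <- hinge_tail(at, resnos[(nr - tail_n + 1):nr], resnos[nr - tail_n], out3)
    }
    segs[[k]] <- at
    resno0 <- resno0 + sl
  }
  do.call(rbind, segs)
}

# Swing a terminal tail outward: rigid rotation of the tail atoms about the
# junction CA so the tail points along `out_dir`, clear of the folded core,
# plus a small outward push so even the innermost tail residue packs below
# the folded threshold (the junction geometry is idealized, not physical).
hinge_tail <- function(at, tail_resnos, pivot_resno, out_dir, push = 1.5) {
  pivot <- as.numeric(at[at$elety == "CA" & at$resno == pivot_resno,
                         c("x", "y", "z")][1, ])
  sel <- at$resno %in% tail_resnos
  tail_ca <- as.matrix(at[sel & at$elety == "CA", c("x", "y", "z"), drop = FALSE])
  v <- colMeans(tail_ca) - pivot
  R <- rot_align(v, out_dir)
  u <- out_dir / sqrt(sum(out_dir^2))
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot + push * u, `+`)
  at$x[sel] <- xyz[, 1]; at$y[sel] <- xyz[, 2]; at$z[sel] <- xyz[, 3]
  at
}

align_core_axis <- function(at, core) {
  resnos <- sort(unique(at$resno))
  core_resno <- resnos[core]
  ca <- as.matrix(at[at$elety == "CA" & at$resno %in% core_resno, c("x", "y", "z")])
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  axis <- sv$v[, 1]
  if (sum(axis * (ca[nrow(ca), ] - ca[1, ])) < 0) axis <- -axis
  R <- rot_align(axis, c(0, 0, 1))
  xyz <- sweep(as.matrix(at[, c("x", "y", "z")]), 2, cen) %*% t(R)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

flip_chain <- function(at) {
  at$x <- -at$x   # 180 deg about z: (x,y) -> (-x,-y)
  at$y <- -at$y
  at
}

translate_atoms <- function(at, v) {
  at$x <- at$x + v[1]; at$y <- at$y + v[2]; at$z <- at$z + v[3]
  at
}

min_cb_dist_per_residue <- function(pep_cb, binder_cb) {
  vapply(seq_len(nrow(pep_cb)), function(i) {
    min(sqrt(rowSums((binder_cb -
                        matrix(pep_cb[i, ], nrow(binder_cb), 3, byrow = TRUE))^2)))
  }, numeric(1))
}

#' Assemble a toy binder-phosphopeptide complex
#'
#' Builds the binder per topology, places the peptide so that exactly the
#' requested number of N-terminal peptide residues are in C-beta contact
#' (<= 7 A) with the binder at the requested gap (the remaining residues
#' are hinged away), plants pseudo-donor nitrogens at the requested
#' distances from a terminal phosphate oxygen on the nearest binder
#' residue (renamed ARG), and appends unfolded extended tails.  Fully
#' deterministic given the fixture specification.
#'
#' @param spec a [fixture_spec()].
#' @return a `ComplexStructure` with chain A = binder, chain B = target.
#' @export
assemble_complex <- function(spec) {
  if (spec$n_contact_residues > 0 && spec$separation > 7) {
    stop("infeasible: contacts requested at separation > 7 A")
  }
  n_pep <- nchar(spec$peptide_sequence)
  if (spec$n_contact_residues > n_pep) {
    stop("infeasible: more contact residues than peptide residues")
  }
  binder <- build_binder_atoms(spec)
  binder_cb_at <- binder[binder$elety == "CB", , drop = FALSE]
  binder_cb <- as.matrix(binder_cb_at[, c("x", "y", "z")])
  pep0 <- build_phosphopeptide(spec$peptide_sequence,
                               spec$peptide_conformation, chain = "B")
  # orient the C-beta pleat perpendicular to the approach direction (+x)
  # so contact residues see near-uniform C-beta gaps; contact block
  # centered on the binder's z-extent
  ca <- as.matrix(pep0[pep0$elety == "CA", c("x", "y", "z")])
  cb <- as.matrix(pep0[pep0$elety %in% c("CB"), c("x", "y", "z")])
  cb_dir <- colMeans(cb) - colMeans(ca[seq_len(nrow(cb)), , drop = FALSE])
  cb_dir[3] <- 0
  if (sqrt(sum(cb_dir^2)) > 1e-6) {
    R <- rot_align(cb_dir, c(0, 1, 0))
    xyz <- as.matrix(pep0[, c("x", "y", "z")]) %*% t(R)
    pep0$x <- xyz[, 1]; pep0$y <- xyz[, 2]; pep0$z <- xyz[, 3]
  }
  nc <- spec$n_contact_residues
  contact_resno <- sort(unique(pep0$resno))[seq_len(max(nc, 1))]
  # center the contact block on z = 0 (binder core center)
  blk_ca <- pep0[pep0$elety == "CA" & pep0$resno %in% contact_resno, c("x", "y", "z")]
  pep0 <- translate_atoms(pep0, -c(mean(blk_ca$x), mean(blk_ca$y), mean(blk_ca$z)))
  # calibrate the x-offset so the farthest contact residue sits at the
  # requested C-beta gap
  measure <- function(D) {
    pep <- translate_atoms(pep0, c(D, 0, 0))
    pcb <- as.matrix(pep[pep$elety == "CB" & pep$resno %in% contact_resno,
                         c("x", "y", "z"), drop = FALSE])
    max(min_cb_dist_per_residue(pcb, binder_cb))
  }
  lo <- 0; hi <- 80
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (measure(mid) < spec$separation) lo <- mid else hi <- mid
  }
  pep <- translate_atoms(pep0, c((lo + hi) / 2, 0, 0))
  # hinge the non-contact tail away from the binder
  if (nc > 0 && nc < n_pep) {
    resnos <- sort(unique(pep$resno))
    tail_resno <- resnos[(nc + 1):n_pep]
    pivot <- as.numeric(pep[pep$elety == "CA" & pep$resno == resnos[nc],
                            c("x", "y", "z")])
    ok <- FALSE
    for (ang_deg in seq(60, 150, by = 10)) {
      cand <- pep
      sel <- cand$resno %in% tail_resno
      R <- rot_about_axis(c(0, 1, 0), ang_deg * pi / 180)
      xyz <- as.matrix(cand[sel, c("x", "y", "z")])
      # rotate about the hinge, then push the tail a little further out
      # along +x so it clears wide binder topologies
      xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot + c(1.5, 0, 0), `+`)
      cand$x[sel] <- xyz[, 1]; cand$y[sel] <- xyz[, 2]; cand$z[sel] <- xyz[, 3]
      pcb <- cand[cand$elety == "CB", , drop = FALSE]
      d <- min_cb_dist_per_residue(as.matrix(pcb[, c("x", "y", "z")]), binder_cb)
      in_contact <- pcb$resno[d <= 7]
      if (setequal(in_contact, intersect(contact_resno, pcb$resno))) {
        pep <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible geometry: could not hinge tail out of contact")
  }
  atoms <- rbind(binder, pep)
  # plant pseudo-donors near a terminal phosphate oxygen
  if (length(spec$phosphate_donor_distances) > 0 &&
      any(pep$resname == "PTR")) {
    pp <- pep[pep$resname == "PTR", , drop = FALSE]
    ptr_resno <- pp$resno[1]
    Pxyz <- as.numeric(pp[pp$elety == "P", c("x", "y", "z")][1, ])
    o_names <- intersect(TERMINAL_PHOSPHATE_O, pp$elety)
    Oxyz <- as.numeric(pp[pp$elety == o_names[1], c("x", "y", "z")][1, ])
    u0 <- (Oxyz - Pxyz); u0 <- u0 / sqrt(sum(u0^2))
    e1 <- pracma_cross(u0, c(0, 0, 1)); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- pracma_cross(u0, e1)
    tilts <- list(c(0, 0), c(0.35, 0), c(0, 0.35))
    # nearest binder residue hosts the donors and becomes a pseudo-ARG
    dmin <- sqrt(rowSums((binder_cb - matrix(Oxyz, nrow(binder_cb), 3, byrow = TRUE))^2))
    host <- binder_cb_at$resno[which.min(dmin)]
    atoms$resname[atoms$chain == "A" & atoms$resno == host] <- "ARG"
    donor_names <- c("NE", "NH1", "NH2")
    for (k in seq_along(spec$phosphate_donor_distances)) {
      dir_k <- u0 + tilts[[k]][1] * e1 + tilts[[k]][2] * e2
      dir_k <- dir_k / sqrt(sum(dir_k^2))
      pos <- Oxyz + spec$phosphate_donor_distances[k] * dir_k
      atoms <- rbind(atoms, data.frame(
        chain = "A", resno = host, resname = "ARG", elety = donor_names[k],
        element = "N", x = pos[1], y = pos[2], z = pos[3], occ = 1.0,
        stringsAsFactors = FALSE))
    }
    atoms <- atoms[order(match(atoms$chain, c("A", "B")),
                         atoms$resno,
                         seq_len(nrow(atoms))), , drop = FALSE]
  }
  cs <- complex_structure(atoms, source = "synthetic")
  assign_roles(cs, binder_chains = "A")
}

#' Write a fixture plus its JSON manifest
#'
#' @param spec a [fixture_spec()].
#' @param pdb_path output PDB path; the manifest goes to `<pdb_path>.json`.
#' @return the assembled `ComplexStructure`, invisibly.
#' @export
write_fixture <- function(spec, pdb_path) {
  cs <- assemble_complex(spec)
  write_structure(cs, pdb_path)
  jsonlite::write_json(unclass(spec), paste0(pdb_path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cs)
}
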