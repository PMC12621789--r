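# Structure model and I/O --------------------------------------------------
#
# A ComplexStructure is the central container every annotation attaches to:
# a flat atom table plus a chain -> role map.  Atom records are kept in file
# order; residues are identified by (chain, resno) with resno being the
# author numbering as read, while all per-residue results are returned in
# 0-based positional order so numbering gaps in deposited files never leak
# into geometry.

#' Van der Waals radii (heavy-atom set), in Angstrom
#'
#' Fixed published element radii used for surface calculations.  Elements
#' outside the table fall back to carbon (1.70 A).
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, SE = 1.90)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a ComplexStructure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `element`, `x`, `y`, `z`, and optionally `occ`.
#' @param chain_roles named character vector mapping chain id to `"binder"`
#'   or `"target"`; may be empty and assigned later with [assign_roles()].
#' @param source provenance string (file path or `"synthetic"`).
#' @return An object of class `ComplexStructure`.
#' @export
complex_structure <- function(atoms, chain_roles = character(), source = "synthetic") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  if (is.null(atoms$occ)) atoms$occ <- 1.0
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  atoms$is_sidechain <- !(atoms$elety %in% BACKBONE_ATOMS) &
    !grepl("^H[A]?$", atoms$elety)
  rad <- vdw_radii()
  atoms$vdw <- unname(rad[atoms$element])
  atoms$vdw[is.na(atoms$vdw)] <- rad[["C"]]
  # monotone residue order within each chain
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn, strictly = FALSE)) {
      stop("residue numbering not monotone within chain ", ch)
    }
  }
  structure(
    list(atoms = atoms, chain_roles = chain_roles, source = source),
    class = "ComplexStructure"
  )
}

#' @export
print.ComplexStructure <- function(x, ...) {
  rt <- residue_table(x)
  cat("ComplexStructure:", nrow(rt), "residues,", nrow(x$atoms), "atoms\n")
  for (ch in unique(rt$chain)) {
    role <- if (ch %in% names(x$chain_roles)) x$chain_roles[[ch]] else "unassigned"
    cat(sprintf("  chain %s (%s): %d residues\n", ch, role, sum(rt$chain == ch)))
  }
  invisible(x)
}

guess_element <- function(elety) {
  nm <- toupper(gsub("[0-9']", "", elety))
  nm <- sub("^H.*", "H", nm)
  two <- substr(nm, 1, 2)
  out <- ifelse(two == "SE", "SE", substr(nm, 1, 1))
  out[out == ""] <- "C"
  out
}

#' Residue table of a structure
#'
#' One row per residue in file order, with a positional 0-based `index`, the
#' residue key `"chain:resno"`, and the chain role.
#'
#' @param cs a `ComplexStructure`.
#' @return data.frame with columns `index`, `chain`, `resno`, `resname`,
#'   `key`, `role`.
#' @export
residue_table <- function(cs) {
  a <- cs$atoms
  key <- paste(a$chain, a$resno, sep = ":")
  first <- !duplicated(key)
  rt <- data.frame(
    chain = a$chain[first], resno = a$resno[first], resname = a$resname[first],
    key = key[first], stringsAsFactors = FALSE
  )
  rt$index <- seq_len(nrow(rt)) - 1L
  rt$role <- chain_role(cs, rt$chain)
  rt[, c("index", "chain", "resno", "resname", "key", "role")]
}

chain_role <- function(cs, chains) {
  out <- rep(NA_character_, length(chains))
  hit <- chains %in% names(cs$chain_roles)
  out[hit] <- unname(cs$chain_roles[chains[hit]])
  out
}

#' Extract a single residue
#'
#' @param cs a `ComplexStructure`.
#' @param chain chain id.
#' @param resno author residue number.
#' @return list with `chain`, `resno`, `resname` and an `atoms` data.frame.
#' @export
get_residue <- function(cs, chain, resno) {
  sel <- cs$atoms$chain == chain & cs$atoms$resno == resno
  if (!any(sel)) stop("no residue ", chain, ":", resno)
  at <- cs$atoms[sel, , drop = FALSE]
  list(chain = chain, resno = resno, resname = at$resname[1], atoms = at)
}

#' Read a complex structure from PDB or mmCIF
#'
#' Heavy atoms are always retained; hydrogens are kept when present.
#' Alternate locations are resolved to the highest-occupancy copy (ties
#' broken by altloc letter order).  Waters and non-PTR heteroatoms are
#' excluded by default; phosphotyrosine (PTR) is always kept.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return A `ComplexStructure` with no chain roles assigned.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    withCallingHandlers(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
      warning = function(w) {
        # bio3d's mmCIF reader warns about its own beta status and absent
        # helix/sheet records; neither concerns the atom records we use
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  a <- pdb$atom
  if (nrow(a) == 0) stop("empty structure: no atoms in ", path)
  # drop waters and non-PTR heteroatoms
  keep <- a$type == "ATOM" | a$resid == "PTR"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure after heteroatom filtering: ", path)
  a$chain[is.na(a$chain)] <- "A"
  # altloc resolution: highest occupancy wins, ties by altloc letter order
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    a$.file_order <- seq_len(nrow(a))
    akey <- paste(a$chain, a$resno, a$elety, sep = "|")
    occ <- ifelse(is.na(a$o), 1, a$o)
    a <- a[order(akey, -occ, alt), , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$elety, sep = "|")), , drop = FALSE]
    a <- a[order(a$.file_order), , drop = FALSE]
  }
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, resname = a$resid, elety = a$elety,
    element = ifelse(!is.null(a$elesy) & !is.na(a$elesy) & a$elesy != "",
                     toupper(a$elesy), guess_element(a$elety)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE
  )
  complex_structure(atoms, source = path)
}

#' Write a complex structure as PDB
#'
#' @param cs a `ComplexStructure`.
#' @param path output file path.
#' @param ori optional 3-vector; written as a pseudoatom remark plus a
#'   HETATM `ORI` record on chain `X`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(cs, path, ori = NULL) {
  a <- cs$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = a$resno, resid = a$resname,
    chain = a$chain, elety = a$elety, o = a$occ, b = rep(0, nrow(a)),
    elesy = a$element
  )
  if (!is.null(ori)) {
    lines <- readLines(path)
    remark <- sprintf("REMARK 999 ORI PSEUDOATOM %8.3f %8.3f %8.3f",
                      ori[1], ori[2], ori[3])
    het <- sprintf("HETATM%5d  ORI ORI X%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   nrow(a) + 1L, 1L, ori[1], ori[2], ori[3])
    end <- grepl("^END", lines)
    writeLines(c(remark, lines[!end], het, lines[end]), path)
  }
  invisible(path)
}

#' Assign binder/target roles to chains
#'
#' Chains named in `binder_chains` become binders; every other chain becomes
#' a target.  Interface operations require at least one of each.
#'
#' @param cs a `ComplexStructure`.
#' @param binder_chains character vector of chain ids.
#' @return The structure with `chain_roles` filled for every chain.
#' @export
assign_roles <- function(cs, binder_chains) {
  chains <- unique(cs$atoms$chain)
  unknown <- setdiff(binder_chains, chains)
  if (length(unknown) > 0) {
    stop("unknown chain id(s) ", paste(unknown, collapse = ","),
         "; available: ", paste(chains, collapse = ","))
  }
  roles <- ifelse(chains %in% binder_chains, "binder", "target")
  names(roles) <- chains
  cs$chain_roles <- roles
  cs
}

check_interface_roles <- function(cs) {
  if (!any(cs$chain_roles == "binder")) stop("no binder chain assigned")
  if (!any(cs$chain_roles == "target")) stop("no target chain assigned")
  invisible(cs)
}

atom_coord <- function(res, elety) {
  i <- match(elety, res$atoms$elety)
  if (is.na(i)) return(NULL)
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

#' Actual-or-virtual C-beta coordinate of a residue
#'
#' Returns the deposited CB when present (non-glycine); otherwise an ideal
#' CB is constructed from N/CA/C at 1.522 A bond length with tetrahedral
#' geometry, so glycine and CB-less models are first-class in all C-beta
#' based interface definitions.
#'
#' @param res a residue from [get_residue()].
#' @return Numeric 3-vector (Angstrom).
#' @export
virtual_cbeta <- function(res) {
  cb <- atom_coord(res, "CB")
  if (!is.null(cb) && res$resname != "GLY") return(cb)
  n <- atom_coord(res, "N"); ca <- atom_coord(res, "CA"); cc <- atom_coord(res, "C")
  for (nm in c("N", "CA", "C")) {
    if (is.null(atom_coord(res, nm))) {
      stop("cannot build virtual CB for ", res$chain, ":", res$resno,
           ": missing backbone atom ", nm)
    }
  }
  ideal_cbeta(n, ca, cc)
}

# Ideal CB from backbone frame: bond 1.522 A, angle N-CA-CB 110.4 deg,
# dihedral C-N-CA-CB -122.6 deg (standard L-amino-acid construction).
ideal_cbeta <- function(n, ca, cc) {
  place_atom_nerf(cc, n, ca, bond = 1.522, angle = 110.4, dihedral = -122.6)
}

# NeRF placement: new atom D bonded to C, with angle B-C-D and dihedral
# A-B-C-D given in degrees.
place_atom_nerf <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), -bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# C-beta matrix for a set of residues (virtual where needed), rows aligned
# with residue_table order.
cbeta_matrix <- function(cs, rt = residue_table(cs)) {
  out <- matrix(NA_real_, nrow(rt), 3)
  for (i in seq_len(nrow(rt))) {
    res <- get_residue(cs, rt$chain[i], rt$resno[i])
    out[i, ] <- tryCatch(virtual_cbeta(res), error = function(e) rep(NA_real_, 3))
  }
  rownames(out) <- rt$key
  out
}

atom_coord_matrix <- function(cs, elety) {
  a <- cs$atoms[cs$atoms$elety == elety, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, sep = ":")
  m
}

#' Phosphate atom group of a phosphotyrosine residue
#'
#' Returns the phosphorus and its bonded oxygens: the three terminal
#' phosphate oxygens (O1P/O2P/O3P, also accepted in OP1-style naming) and
#' the bridging ester oxygen OH, which is flagged distinctly.
#'
#' @param res a residue from [get_residue()]; must be PTR.
#' @return data.frame of atom records with a logical `bridging` column.
#' @export
phosphate_atoms <- function(res) {
  if (res$resname != "PTR") {
    stop("phosphate_atoms: residue ", res$chain, ":", res$resno,
         " is ", res$resname, ", not PTR")
  }
  at <- res$atoms
  if (!("P" %in% at$elety)) {
    stop("incomplete PTR ", res$chain, ":", res$resno, ": missing P")
  }
  terminal <- c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3")
  sel <- at$elety == "P" | at$elety %in% terminal | at$elety == "OH"
  grp <- at[sel, , drop = FALSE]
  grp$bridging <- grp$elety == "OH"
  nterm <- sum(grp$elety %in% terminal)
  if (nterm < 3) {
    warning("PTR ", res$chain, ":", res$resno, " has only ", nterm,
            " terminal phosphate oxygens")
  }
  grp
}

#' All phosphotyrosine residues on chains with a given role
#' @param cs a `ComplexStructure`.
#' @param role `"target"`, `"binder"`, or `"any"`.
#' @return data.frame subset of [residue_table()].
#' @export
ptr_residues <- function(cs, role = "any") {
  rt <- residue_table(cs)
  sel <- rt$resname == "PTR"
  if (role != "any") sel <- sel & !is.na(rt$role) & rt$role == role
  rt[sel, , drop = FALSE]
}

# Apply a rigid transform (rotation matrix R, translation t) to a structure.
transform_structure <- function(cs, R, t = c(0, 0, 0)) {
  m <- as.matrix(cs$atoms[, c("x", "y", "z")])
  m2 <- m %*% t(R)
  cs$atoms$x <- m2[, 1] + t[1]
  cs$atoms$y <- m2[, 2] + t[2]
  cs$atoms$z <- m2[, 3] + t[3]
  cs
}

# Subset a structure to a set of residue keys ("chain:resno"), keeping order.
subset_structure <- function(cs, keys) {
  akey <- paste(cs$atoms$chain, cs$atoms$resno, sep = ":")
  cs$atoms <- cs$atoms[akey %in% keys, , drop = FALSE]
  if (nrow(cs$atoms) == 0) stop("subset leaves no atoms")
  cs
}
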