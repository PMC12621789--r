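# Design filtering -----------------------------------------------------------
#
# Geometric accept/reject gates for designed phosphopeptide binders:
# at least two hydrogen bonds from the binder to the phosphotyrosine's
# phosphate group (phospho-specificity), at most twelve total hydrogen
# bonds to the peptide (penalizes promiscuous polar contact), and a
# phosphotyrosine RMSD below 5 A between the designed and the predicted
# complex after superposition on the binder (motif fidelity).  Confidence
# gates (pLDDT / iPAE / iPTM / PTM) are mandatory-explicit configuration:
# no silent numeric defaults.

# Donor/acceptor typing.  Heavy-atom based: donors are N/O bearing an
# (implicit) hydrogen; acceptors carry a lone pair.  The antecedent atom
# defines the acceptor-side angle.  PRO backbone N has no H.
DONOR_TABLE <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", PTR = character()
)
ACCEPTOR_TABLE <- list(
  backbone = c(O = "C", OXT = "C"),
  ASP = c(OD1 = "CG", OD2 = "CG"), GLU = c(OE1 = "CD", OE2 = "CD"),
  ASN = c(OD1 = "CG"), GLN = c(OE1 = "CD"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  PTR = c(O1P = "P", O2P = "P", O3P = "P", OP1 = "P", OP2 = "P", OP3 = "P",
          OH = "P")
)
TERMINAL_PHOSPHATE_O <- c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3")

vec_angle <- function(a, vertex, b) {
  u <- a - vertex; v <- b - vertex
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

hbond_roles <- function(atoms) {
  is_donor <- logical(nrow(atoms))
  is_acceptor <- logical(nrow(atoms))
  antecedent <- rep(NA_character_, nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    rn <- atoms$resname[i]; an <- atoms$elety[i]
    if (an == "N" && rn != "PRO") is_donor[i] <- TRUE
    if (!is.null(DONOR_TABLE[[rn]]) && an %in% DONOR_TABLE[[rn]]) is_donor[i] <- TRUE
    bb <- ACCEPTOR_TABLE$backbone
    if (an %in% names(bb)) { is_acceptor[i] <- TRUE; antecedent[i] <- bb[[an]] }
    side <- ACCEPTOR_TABLE[[rn]]
    if (!is.null(side) && an %in% names(side)) {
      is_acceptor[i] <- TRUE; antecedent[i] <- side[[an]]
    }
  }
  data.frame(is_donor = is_donor, is_acceptor = is_acceptor,
             antecedent = antecedent, stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds (heavy-atom geometric criterion)
#'
#' A donor heavy atom D and acceptor A form a hydrogen bond iff
#' `|D - A| <= d_cutoff` and the acceptor-side angle
#' `angle(antecedent, A, D) >= angle_min`.  When explicit hydrogens are
#' present on the donor, additionally requires a D-H...A angle of at least
#' 120 degrees for some attached H.  Intra-residue pairs are excluded and
#' each D-A pair is counted once.
#'
#' @param cs a `ComplexStructure`.
#' @param d_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_min minimum antecedent-acceptor-donor angle, degrees.
#' @return data.frame of class `HBondList`: one row per bond with donor and
#'   acceptor residue keys, atom names, distance, `is_sidechain_sidechain`
#'   and `acceptor_is_phosphate_oxygen`.
#' @export
detect_hbonds <- function(cs, d_cutoff = 3.5, angle_min = 90) {
  a <- cs$atoms
  roles <- hbond_roles(a)
  heavy <- a$element != "H"
  don <- which(roles$is_donor & heavy)
  acc <- which(roles$is_acceptor & heavy)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  akey <- paste(a$chain, a$resno, sep = ":")
  rows <- list()
  for (d in don) {
    dd <- sqrt(rowSums((xyz[acc, , drop = FALSE] -
                          matrix(xyz[d, ], length(acc), 3, byrow = TRUE))^2))
    cand <- acc[dd <= d_cutoff & akey[acc] != akey[d]]
    for (ac in cand) {
      dist <- sqrt(sum((xyz[d, ] - xyz[ac, ])^2))
      ante <- roles$antecedent[ac]
      if (!is.na(ante)) {
        ai <- which(akey == akey[ac] & a$elety == ante)
        if (length(ai) == 1 &&
            vec_angle(xyz[ai, ], xyz[ac, ], xyz[d, ]) < angle_min) next
      }
      # explicit-hydrogen check: any H within 1.3 A of the donor
      hi <- which(akey == akey[d] & a$element == "H")
      if (length(hi) > 0) {
        hd <- sqrt(rowSums((xyz[hi, , drop = FALSE] -
                              matrix(xyz[d, ], length(hi), 3, byrow = TRUE))^2))
        hi <- hi[hd <= 1.3]
        if (length(hi) > 0) {
          angs <- vapply(hi, function(h) vec_angle(xyz[d, ], xyz[h, ], xyz[ac, ]),
                         numeric(1))
          if (max(angs) < 120) next
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor_residue = akey[d], donor_atom = a$elety[d],
        acceptor_residue = akey[ac], acceptor_atom = a$elety[ac],
        distance = dist,
        is_sidechain_sidechain = a$is_sidechain[d] && a$is_sidechain[ac],
        acceptor_is_phosphate_oxygen = a$resname[ac] == "PTR" &&
          a$elety[ac] %in% TERMINAL_PHOSPHATE_O,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(donor_residue = character(), donor_atom = character(),
               acceptor_residue = character(), acceptor_atom = character(),
               distance = numeric(), is_sidechain_sidechain = logical(),
               acceptor_is_phosphate_oxygen = logical())
  } else do.call(rbind, rows)
  class(out) <- c("HBondList", "data.frame")
  out
}

residue_role_of_key <- function(cs, keys) {
  chain_role(cs, sub(":.*", "", keys))
}

#' Count binder-to-phosphate hydrogen bonds
#'
#' Bonds whose acceptor is a terminal phosphate oxygen of a target-chain
#' PTR and whose donor sits on a binder chain (backbone or side chain).
#'
#' @param bonds an `HBondList` from [detect_hbonds()].
#' @param cs the `ComplexStructure` the bonds were computed on.
#' @return integer count.
#' @export
count_phosphate_hbonds <- function(bonds, cs) {
  ptr <- ptr_residues(cs, role = "target")
  if (nrow(ptr) == 0) stop("no phosphotyrosine in target")
  sel <- bonds$acceptor_is_phosphate_oxygen &
    bonds$acceptor_residue %in% ptr$key &
    residue_role_of_key(cs, bonds$donor_residue) == "binder"
  sum(sel, na.rm = TRUE)
}

#' Count binder-peptide hydrogen bonds
#'
#' @param bonds an `HBondList`.
#' @param cs the `ComplexStructure`.
#' @return list with `total` (all binder-target bonds in either
#'   donor/acceptor direction, phosphate bonds included) and
#'   `sidechain_sidechain` (subset where both atoms are side-chain atoms).
#' @export
count_peptide_hbonds <- function(bonds, cs) {
  drole <- residue_role_of_key(cs, bonds$donor_residue)
  arole <- residue_role_of_key(cs, bonds$acceptor_residue)
  cross <- (drole == "binder" & arole == "target") |
    (drole == "target" & arole == "binder")
  list(total = sum(cross, na.rm = TRUE),
       sidechain_sidechain = sum(cross & bonds$is_sidechain_sidechain, na.rm = TRUE))
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile %*% t(R) + t` onto `reference`.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point lists differ in length")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m0 <- sweep(mobile, 2, mc); r0 <- sweep(reference, 2, rc)
  h <- t(m0) %*% r0
  s <- svd(h)
  if (s$d[2] < 1e-8) stop("degenerate (rank-deficient) point set")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- rc - as.numeric(R %*% mc)
  fitted <- m0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# Matched binder CA coordinate pairs (chain id + sequential position;
# mismatched lengths use the common prefix with a warning).
matched_binder_ca <- function(designed, predicted) {
  d_rt <- residue_table(designed); p_rt <- residue_table(predicted)
  d_chains <- unique(d_rt$chain[d_rt$role == "binder"])
  des <- list(); pre <- list()
  for (ch in d_chains) {
    dk <- d_rt$key[d_rt$chain == ch & d_rt$role == "binder"]
    pk <- p_rt$key[p_rt$chain == ch & p_rt$role == "binder"]
    n <- min(length(dk), length(pk))
    if (length(dk) != length(pk)) {
      warning("binder chain ", ch, " length mismatch (", length(dk), " vs ",
              length(pk), "); using common prefix of ", n)
    }
    dca <- atom_coord_matrix(designed, "CA")
    pca <- atom_coord_matrix(predicted, "CA")
    des[[ch]] <- dca[match(dk[seq_len(n)], rownames(dca)), , drop = FALSE]
    pre[[ch]] <- pca[match(pk[seq_len(n)], rownames(pca)), , drop = FALSE]
  }
  list(designed = do.call(rbind, des), predicted = do.call(rbind, pre))
}

#' Phosphotyrosine RMSD between designed and predicted complexes
#'
#' Superposes the predicted structure onto the designed one using matched
#' binder C-alpha pairs, then computes the RMSD over the phosphotyrosine's
#' shared heavy atoms without further fitting.
#'
#' @param designed the design-model `ComplexStructure` (roles assigned).
#' @param predicted the predicted `ComplexStructure` (roles assigned).
#' @param phosphate_only restrict the RMSD to the phosphate atom group.
#' @return RMSD in Angstrom, with the compared atom names in attribute
#'   `"atoms"`.
#' @export
ptyr_rmsd <- function(designed, predicted, phosphate_only = FALSE) {
  d_ptr <- ptr_residues(designed); p_ptr <- ptr_residues(predicted)
  if (nrow(d_ptr) == 0) stop("no PTR in designed structure")
  if (nrow(p_ptr) == 0) stop("no PTR in predicted structure")
  ca <- matched_binder_ca(designed, predicted)
  if (is.null(ca$designed) || nrow(ca$designed) < 3) {
    stop("fewer than 3 matched binder C-alpha pairs")
  }
  fit <- kabsch_superpose(ca$predicted, ca$designed)
  d_res <- get_residue(designed, d_ptr$chain[1], d_ptr$resno[1])
  p_res <- get_residue(predicted, p_ptr$chain[1], p_ptr$resno[1])
  d_at <- d_res$atoms[d_res$atoms$element != "H", , drop = FALSE]
  p_at <- p_res$atoms[p_res$atoms$element != "H", , drop = FALSE]
  if (phosphate_only) {
    keep <- c("P", TERMINAL_PHOSPHATE_O, "OH")
    d_at <- d_at[d_at$elety %in% keep, , drop = FALSE]
    p_at <- p_at[p_at$elety %in% keep, , drop = FALSE]
  }
  shared <- intersect(d_at$elety, p_at$elety)
  if (length(shared) == 0) stop("no shared PTR heavy atoms")
  dm <- as.matrix(d_at[match(shared, d_at$elety), c("x", "y", "z")])
  pm <- as.matrix(p_at[match(shared, p_at$elety), c("x", "y", "z")])
  pm_fit <- pm %*% t(fit$rotation) +
    matrix(fit$translation, nrow(pm), 3, byrow = TRUE)
  out <- sqrt(mean(rowSums((pm_fit - dm)^2)))
  attr(out, "atoms") <- shared
  out
}

#' Design filter thresholds
#'
#' Geometric gates default to the published criteria; confidence gates have
#' no defaults and are applied only when explicitly supplied.
#'
#' @param min_phosphate_hbonds minimum binder-phosphate hydrogen bonds.
#' @param max_peptide_hbonds maximum total binder-peptide hydrogen bonds.
#' @param max_ptyr_rmsd maximum phosphotyrosine RMSD, Angstrom (exclusive:
#'   the RMSD must be strictly below this).
#' @param max_design_binder_len binder length must be strictly below this.
#' @param min_plddt,max_ipae,min_iptm,min_ptm optional confidence gates.
#' @return list of class `FilterThresholds`.
#' @export
filter_thresholds <- function(min_phosphate_hbonds = 2L,
                              max_peptide_hbonds = 12L,
                              max_ptyr_rmsd = 5.0,
                              max_design_binder_len = 160L,
                              min_plddt = NULL, max_ipae = NULL,
                              min_iptm = NULL, min_ptm = NULL) {
  th <- list(min_phosphate_hbonds = min_phosphate_hbonds,
             max_peptide_hbonds = max_peptide_hbonds,
             max_ptyr_rmsd = max_ptyr_rmsd,
             max_design_binder_len = max_design_binder_len,
             min_plddt = min_plddt, max_ipae = max_ipae,
             min_iptm = min_iptm, min_ptm = min_ptm)
  num <- unlist(th[!vapply(th, is.null, logical(1))])
  if (any(!is.finite(num))) stop("thresholds must be finite")
  structure(th, class = "FilterThresholds")
}

#' Apply the design accept/reject gates
#'
#' Collects one failure reason per violated gate; a degenerate input yields
#' a fail verdict with reasons, never an exception.  Gates whose metric is
#' missing are skipped with a warning.
#'
#' @param n_phosphate_hbonds integer.
#' @param n_peptide_hbonds_total integer.
#' @param ptyr_rmsd RMSD in Angstrom, or `NA`.
#' @param binder_length integer residue count.
#' @param confidence optional named list/vector with any of `plddt`,
#'   `ipae`, `iptm`, `ptm`.
#' @param n_sidechain_sidechain_hbonds optional integer, carried into the
#'   report for ranking.
#' @param thresholds a [filter_thresholds()].
#' @return list of class `FilterReport` with all metrics, `verdict`
#'   (`"pass"`/`"fail"`) and `fail_reasons`.
#' @export
apply_filters <- function(n_phosphate_hbonds, n_peptide_hbonds_total,
                          ptyr_rmsd = NA_real_, binder_length = NA_integer_,
                          confidence = list(),
                          n_sidechain_sidechain_hbonds = NA_integer_,
                          thresholds = filter_thresholds()) {
  reasons <- character()
  if (is.na(n_phosphate_hbonds) || n_phosphate_hbonds < thresholds$min_phosphate_hbonds) {
    reasons <- c(reasons, "insufficient_phosphate_hbonds")
  }
  if (!is.na(n_peptide_hbonds_total) &&
      n_peptide_hbonds_total > thresholds$max_peptide_hbonds) {
    reasons <- c(reasons, "excess_peptide_hbonds")
  }
  if (is.na(ptyr_rmsd)) {
    warning("ptyr_rmsd missing; RMSD gate skipped")
  } else if (ptyr_rmsd >= thresholds$max_ptyr_rmsd) {
    reasons <- c(reasons, "ptyr_rmsd")
  }
  if (!is.na(binder_length) && binder_length >= thresholds$max_design_binder_len) {
    reasons <- c(reasons, "binder_too_long")
  }
  conf_gate <- function(metric, thr, cmp, reason) {
    if (is.null(thr)) return(invisible())
    v <- confidence[[metric]]
    if (is.null(v) || is.na(v)) {
      warning("confidence metric ", metric, " missing; gate skipped")
    } else if (!cmp(v, thr)) {
      reasons <<- c(reasons, reason)
    }
  }
  conf_gate("plddt", thresholds$min_plddt, `>=`, "low_plddt")
  conf_gate("ipae", thresholds$max_ipae, `<=`, "high_ipae")
  conf_gate("iptm", thresholds$min_iptm, `>=`, "low_iptm")
  conf_gate("ptm", thresholds$min_ptm, `>=`, "low_ptm")
  structure(list(
    n_phosphate_hbonds = n_phosphate_hbonds,
    n_peptide_hbonds_total = n_peptide_hbonds_total,
    n_sidechain_sidechain_hbonds = n_sidechain_sidechain_hbonds,
    ptyr_rmsd = ptyr_rmsd, binder_length = binder_length,
    confidence = confidence,
    verdict = if (length(reasons) == 0) "pass" else "fail",
    fail_reasons = reasons
  ), class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %s (phosphate H-bonds %s, peptide H-bonds %s, pTyr RMSD %s)\n",
              x$verdict, x$n_phosphate_hbonds, x$n_peptide_hbonds_total,
              if (is.na(x$ptyr_rmsd)) "NA" else sprintf("%.2f A", x$ptyr_rmsd)))
  if (length(x$fail_reasons) > 0) {
    cat("  reasons:", paste(x$fail_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a confidence sidecar (JSON keyed plddt/ipae/iptm/ptm)
#' @param path JSON file path.
#' @return named list of confidence metrics.
#' @export
read_confidence_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
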