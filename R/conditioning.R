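# 1D conditioning features ---------------------------------------------------
#
# Per-token (residue) feature matrix with fixed, versioned channel blocks:
# amino-acid one-hot (20 standard + unknown), secondary-structure token
# (helix/strand/coil; all-zero allowed when unassigned), motif flag,
# hotspot/anti-hotspot masks, continuous hotspot value, and RASA.  Total
# width 29.  Residue rows can be broadcast to atom slots so atom-level
# models receive the same conditioning at every atom of a residue.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

CHANNEL_VERSION <- "1"

conditioning_channels <- function() {
  c(paste0("aa_", c(AA3, "UNK")), paste0("ss_", c("H", "E", "C")),
    "motif_flag", "hotspot_mask", "antihotspot_mask", "hotspot_value", "rasa")
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# phi/psi per residue; NA at chain termini / missing atoms.
backbone_dihedrals <- function(cs) {
  rt <- residue_table(cs)
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  coords <- lapply(seq_len(n), function(i) {
    res <- get_residue(cs, rt$chain[i], rt$resno[i])
    list(N = atom_coord(res, "N"), CA = atom_coord(res, "CA"), C = atom_coord(res, "C"))
  })
  for (i in seq_len(n)) {
    prev_ok <- i > 1 && rt$chain[i - 1] == rt$chain[i] &&
      rt$resno[i - 1] == rt$resno[i] - 1
    next_ok <- i < n && rt$chain[i + 1] == rt$chain[i] &&
      rt$resno[i + 1] == rt$resno[i] + 1
    ci <- coords[[i]]
    if (prev_ok && !is.null(coords[[i - 1]]$C) && !any(vapply(ci, is.null, logical(1)))) {
      phi[i] <- dihedral_angle(coords[[i - 1]]$C, ci$N, ci$CA, ci$C)
    }
    if (next_ok && !is.null(coords[[i + 1]]$N) && !any(vapply(ci, is.null, logical(1)))) {
      psi[i] <- dihedral_angle(ci$N, ci$CA, ci$C, coords[[i + 1]]$N)
    }
  }
  data.frame(key = rt$key, phi = phi, psi = psi)
}

in_helix_window <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
}
in_strand_window <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi >= -180 & phi <= -80 &
    ((psi >= 80 & psi <= 180) | (psi >= -180 & psi <= -170))
}

#' Assign coarse secondary-structure tokens
#'
#' Self-contained dihedral-window rule (no external assigner): a residue is
#' `H` if its (phi, psi) and both neighbors' fall in the helical window
#' `[-100, -30] x [-80, -5]` degrees; `E` if its own and at least one
#' neighbor's fall in the extended window
#' `[-180, -80] x ([80, 180] or [-180, -170])`; else `C`.  Chain termini
#' (undefined dihedrals) default to `C`.
#'
#' @param cs a `ComplexStructure`.
#' @return named character vector (`"H"`, `"E"`, `"C"`) over residue keys.
#' @export
assign_secondary_structure <- function(cs) {
  dh <- backbone_dihedrals(cs)
  rt <- residue_table(cs)
  n <- nrow(rt)
  helix <- in_helix_window(dh$phi, dh$psi)
  strand <- in_strand_window(dh$phi, dh$psi)
  same_chain <- function(i, j) {
    j >= 1 && j <= n && rt$chain[j] == rt$chain[i]
  }
  out <- rep("C", n)
  names(out) <- rt$key
  for (i in seq_len(n)) {
    prev_h <- same_chain(i, i - 1) && helix[i - 1]
    next_h <- same_chain(i, i + 1) && helix[i + 1]
    prev_e <- same_chain(i, i - 1) && strand[i - 1]
    next_e <- same_chain(i, i + 1) && strand[i + 1]
    if (helix[i] && prev_h && next_h) {
      out[i] <- "H"
    } else if (strand[i] && (prev_e || next_e)) {
      out[i] <- "E"
    }
  }
  out
}

#' Build the per-token conditioning tensor
#'
#' One row per residue in structure order.  Unknown amino acids (including
#' PTR) use the unknown one-hot slot, with their identity recorded in the
#' tensor metadata.  Channels absent from `channel_mask` are zero-filled and
#' the mask is recorded, so downstream consumers can tell "off" from
#' "zero-valued".
#'
#' @param cs a `ComplexStructure`.
#' @param annotation list with `hotspot`, `antihotspot`, `hotspot_value`
#'   over target residue keys (as from the interface annotators); may be
#'   `NULL` for target-free featurization.
#' @param rasa named RASA vector from [rasa_per_residue()], or `NULL`.
#' @param ss named secondary-structure tokens from
#'   [assign_secondary_structure()], or `NULL` (all-zero ss block).
#' @param motif_residues character vector of residue keys flagged as motif.
#' @param channel_mask character vector of active channel names (default:
#'   all).
#' @return list of class `ConditioningTensor` with `tokens`, `values`
#'   (token x 29 matrix), `channel_mask`, `metadata`.
#' @export
build_conditioning_tensor <- function(cs, annotation = NULL, rasa = NULL,
                                      ss = NULL, motif_residues = character(),
                                      channel_mask = conditioning_channels()) {
  rt <- residue_table(cs)
  channels <- conditioning_channels()
  bad <- setdiff(channel_mask, channels)
  if (length(bad) > 0) stop("unknown channels in mask: ", paste(bad, collapse = ", "))
  check_index <- function(x, what) {
    if (is.null(x)) return(invisible())
    extra <- setdiff(names(x), rt$key)
    if (length(extra) > 0) {
      stop(what, " indexed over unknown residue ", extra[1])
    }
  }
  check_index(annotation$hotspot, "annotation$hotspot")
  check_index(rasa, "rasa")
  check_index(ss, "ss")
  m <- matrix(0, nrow(rt), length(channels),
              dimnames = list(rt$key, channels))
  unknown_ids <- character()
  for (i in seq_len(nrow(rt))) {
    rn <- rt$resname[i]
    if (rn %in% AA3) {
      m[i, paste0("aa_", rn)] <- 1
    } else {
      m[i, "aa_UNK"] <- 1
      unknown_ids <- c(unknown_ids, paste0(rt$key[i], "=", rn))
    }
  }
  if (!is.null(ss)) {
    for (tok in c("H", "E", "C")) {
      hit <- names(ss)[ss == tok]
      m[match(hit, rt$key), paste0("ss_", tok)] <- 1
    }
  }
  fill <- function(col, x) {
    if (is.null(x)) return(invisible())
    idx <- match(names(x), rt$key)
    m[idx, col] <<- as.numeric(x)
  }
  fill("hotspot_mask", annotation$hotspot)
  fill("antihotspot_mask", annotation$antihotspot)
  fill("hotspot_value", annotation$hotspot_value)
  fill("rasa", rasa)
  m[is.na(m)] <- 0
  if (length(motif_residues) > 0) {
    m[match(motif_residues, rt$key), "motif_flag"] <- 1
  }
  off <- setdiff(channels, channel_mask)
  m[, off] <- 0
  if (any(m[, "hotspot_mask"] > 0 & m[, "antihotspot_mask"] > 0)) {
    stop("hotspot and antihotspot masks overlap")
  }
  structure(list(
    tokens = rt$key, values = m, channel_mask = channel_mask,
    metadata = list(channel_version = CHANNEL_VERSION,
                    unknown_residues = unknown_ids)
  ), class = "ConditioningTensor")
}

#' Broadcast residue conditioning rows to atom slots
#'
#' Every atom of residue i receives a copy of tensor row i, so the output
#' has one row per atom (`sum` of per-residue atom counts).
#'
#' @param tensor a `ConditioningTensor`.
#' @param cs the `ComplexStructure` the tensor was built from.
#' @return numeric matrix, one row per atom, same 29 channels.
#' @export
broadcast_to_atoms <- function(tensor, cs) {
  akey <- paste(cs$atoms$chain, cs$atoms$resno, sep = ":")
  if (!setequal(unique(akey), tensor$tokens)) {
    stop("tensor tokens do not match structure residues")
  }
  counts <- table(akey)[tensor$tokens]
  if (any(counts == 0 | is.na(counts))) stop("residue with zero atoms")
  idx <- match(akey, tensor$tokens)
  out <- tensor$values[idx, , drop = FALSE]
  rownames(out) <- paste(akey, cs$atoms$elety, sep = ":")
  out
}

#' Write / read a conditioning tensor (TSV + JSON sidecar)
#'
#' The TSV carries one token per row with named channel columns at 6
#' significant digits; the sidecar records channel order, channel mask,
#' version and metadata (including the ORI coordinate when given), so a
#' tensor is fully reconstructable from the pair.
#'
#' @param tensor a `ConditioningTensor`.
#' @param path TSV path; the sidecar goes to `<path>.json`.
#' @param ori optional ORI 3-vector recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_tensor_tsv <- function(tensor, path, ori = NULL) {
  df <- data.frame(token = tensor$tokens,
                   signif(tensor$values, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(channel_version = tensor$metadata$channel_version,
                  channels = conditioning_channels(),
                  channel_mask = tensor$channel_mask,
                  tokens = tensor$tokens,
                  unknown_residues = tensor$metadata$unknown_residues)
  if (!is.null(ori)) sidecar$ori <- as.numeric(ori)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tensor_tsv
#' @export
read_tensor_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$token
  structure(list(tokens = df$token, values = m,
                 channel_mask = sidecar$channel_mask,
                 metadata = list(channel_version = sidecar$channel_version,
                                 unknown_residues = sidecar$unknown_residues,
                                 ori = sidecar$ori)),
            class = "ConditioningTensor")
}
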