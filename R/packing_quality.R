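# Packing quality, trimming and cropping -----------------------------------
#
# The side-chain-neighbor (SCN) count is a cone-weighted count of C-alpha
# neighbors in the direction of a residue's (virtual) C-beta — a cheap,
# rotamer-free proxy for packing density.  Two derived fractions gate
# training examples: binder_FBSCN (fraction of binder residues with
# SCN > 4.0, reject < 0.12) and interface_FBSCN (same fraction over binder
# interface residues, reject < 0.13).  The target side is deliberately
# never assessed or trimmed so peptide targets stay intact.

#' Side-chain-neighbor (SCN) packing count per residue
#'
#' For residue i with C-alpha at `a` and unit C-beta direction
#' `u = (CB - CA)/|CB - CA|`, SCN_i sums over all other residues j:
#' `w_dist(d) * w_ang(theta)` with `d = |CA_j - CA_i|`,
#' `w_dist = 1 / (1 + exp(d - 9))`, `cos(theta) = u . (CA_j - CA_i) / d`,
#' and `w_ang = ((cos(theta) + 0.5) / 1.5)^2` for `cos(theta) > -0.5`,
#' else 0.  Residues missing backbone atoms are skipped with a warning and
#' reported `NA`.
#'
#' @param cs a `ComplexStructure`.
#' @return named numeric vector over all residue keys, in structure order.
#' @export
scn_per_residue <- function(cs) {
  rt <- residue_table(cs)
  ca_all <- atom_coord_matrix(cs, "CA")
  ca <- ca_all[match(rt$key, rownames(ca_all)), , drop = FALSE]
  cb <- cbeta_matrix(cs, rt)
  out <- rep(NA_real_, nrow(rt))
  names(out) <- rt$key
  ok <- !apply(is.na(ca), 1, any) & !apply(is.na(cb), 1, any)
  if (any(!ok)) {
    warning("SCN skipped for residues with missing backbone: ",
            paste(rt$key[!ok], collapse = ", "))
  }
  for (i in which(ok)) {
    u <- cb[i, ] - ca[i, ]
    u <- u / sqrt(sum(u^2))
    rel <- ca[ok, , drop = FALSE] - matrix(ca[i, ], sum(ok), 3, byrow = TRUE)
    d <- sqrt(rowSums(rel^2))
    sel <- d > 1e-9   # exclude self
    d <- d[sel]; rel <- rel[sel, , drop = FALSE]
    w_dist <- 1 / (1 + exp(d - 9))
    cos_t <- as.numeric(rel %*% u) / d
    w_ang <- ifelse(cos_t > -0.5, ((cos_t + 0.5) / 1.5)^2, 0)
    out[i] <- sum(w_dist * w_ang)
  }
  out
}

#' Binder interface residues
#'
#' A binder residue is an interface residue iff its (virtual) C-beta is
#' within `cb_cutoff` of any target (virtual) C-beta — the mirror image of
#' the hotspot contact rule, without the solvent-exposure gate.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param cb_cutoff contact cutoff, Angstrom (inclusive).
#' @return named logical vector over binder residue keys.
#' @export
interface_residues <- function(cs, cb_cutoff = 7.0) {
  check_interface_roles(cs)
  rt <- residue_table(cs)
  cb <- cbeta_matrix(cs, rt)
  bnd <- which(rt$role == "binder")
  tgt <- which(rt$role == "target")
  tcb <- cb[tgt, , drop = FALSE]
  out <- logical(length(bnd))
  names(out) <- rt$key[bnd]
  for (k in seq_along(bnd)) {
    bcb <- cb[bnd[k], ]
    if (any(is.na(bcb))) next
    d <- sqrt(rowSums((tcb - matrix(bcb, nrow(tcb), 3, byrow = TRUE))^2))
    out[k] <- any(d <= cb_cutoff, na.rm = TRUE)
  }
  out
}

#' Folding-quality curation verdict
#'
#' Applies the four training-curation gates: binder_FBSCN >= `fbscn_min`,
#' interface_FBSCN >= `iface_fbscn_min`, at least one hotspot, and binder
#' length at most `max_binder_len`.  Degenerate inputs (no interface
#' residues) define interface_FBSCN as 0 and reject rather than error.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param scn per-residue SCN from [scn_per_residue()].
#' @param hotspots hotspot mask from [detect_hotspots()].
#' @param max_binder_len maximum binder residue count.
#' @param fbscn_min minimum binder_FBSCN.
#' @param iface_fbscn_min minimum interface_FBSCN.
#' @param scn_folded_cut SCN threshold defining a packed residue.
#' @return list of class `PackingReport` with `scn`, `binder_fbscn`,
#'   `interface_fbscn`, `n_binder`, `verdict` and `reject_reasons`.
#' @export
curation_verdict <- function(cs, scn, hotspots, max_binder_len = 170L,
                             fbscn_min = 0.12, iface_fbscn_min = 0.13,
                             scn_folded_cut = 4.0) {
  rt <- residue_table(cs)
  bnd_keys <- rt$key[rt$role == "binder"]
  bscn <- scn[bnd_keys]
  binder_fbscn <- mean(bscn > scn_folded_cut, na.rm = TRUE)
  iface <- interface_residues(cs)
  iface_keys <- names(iface)[iface]
  interface_fbscn <- if (length(iface_keys) == 0) 0 else
    mean(scn[iface_keys] > scn_folded_cut, na.rm = TRUE)
  reasons <- character()
  if (binder_fbscn < fbscn_min) reasons <- c(reasons, "low_binder_fbscn")
  if (interface_fbscn < iface_fbscn_min) reasons <- c(reasons, "low_interface_fbscn")
  if (!any(hotspots)) reasons <- c(reasons, "no_hotspots")
  if (length(bnd_keys) > max_binder_len) reasons <- c(reasons, "binder_too_long")
  structure(list(
    scn = scn, binder_fbscn = binder_fbscn, interface_fbscn = interface_fbscn,
    n_binder = length(bnd_keys),
    verdict = if (length(reasons) == 0) "accept" else "reject",
    reject_reasons = reasons
  ), class = "PackingReport")
}

#' @export
print.PackingReport <- function(x, ...) {
  cat(sprintf("PackingReport: %s (binder_FBSCN %.3f, interface_FBSCN %.3f, %d binder residues)\n",
              x$verdict, x$binder_fbscn, x$interface_fbscn, x$n_binder))
  if (length(x$reject_reasons) > 0) {
    cat("  reasons:", paste(x$reject_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

trim_tolerance <- function(w) if (w <= 4) 0L else if (w <= 8) 1L else 2L

# Trim one terminus of a vector of folded flags; returns the number of
# residues removed plus whether the single-residue floor stopped it early.
trim_one_end <- function(folded, bound_dist = Inf, max_past_bound = 9L) {
  n_removed <- 0L
  past_bound <- 0L
  hit_floor <- FALSE
  repeat {
    w <- min(9L, length(folded))
    win <- folded[seq_len(w)]
    if (sum(win) > trim_tolerance(w)) break
    if (length(folded) <= 1) { hit_floor <- TRUE; break }
    if (n_removed >= bound_dist) {
      # inside the protected hotspot bounds: only unfolded residues may go,
      # and at most max_past_bound of them
      if (folded[1] || past_bound >= max_past_bound) break
      past_bound <- past_bound + 1L
    }
    folded <- folded[-1]
    n_removed <- n_removed + 1L
  }
  list(n_removed = n_removed, hit_floor = hit_floor)
}

#' Trim disordered binder termini
#'
#' A binder residue is "folded" iff its SCN exceeds `sc_neigh_threshold`
#' (1.0).  From each terminus, iteratively: take the terminal window of
#' `min(9, remaining)` residues; if its folded count is at or below the
#' tolerance (0 for windows of length <= 4, 1 for <= 8, 2 for > 8), remove
#' the terminal residue and repeat; stop at the first window that exceeds
#' tolerance.  When `hotspot_bounds` is given (range of binder residue
#' numbers to protect), trimming may extend at most 9 residues past a bound
#' and only while the intervening residues are all unfolded.  Target chains
#' are never trimmed.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param scn per-residue SCN from [scn_per_residue()].
#' @param sc_neigh_threshold SCN cutoff defining a folded residue.
#' @param hotspot_bounds optional integer `c(lo, hi)` of protected binder
#'   residue numbers.
#' @return list of class `CropResult` with `retained` residue keys,
#'   `trimmed_n_terminal`, `trimmed_c_terminal` and an event `log`.
#' @export
trim_termini <- function(cs, scn, sc_neigh_threshold = 1.0,
                         hotspot_bounds = NULL) {
  rt <- residue_table(cs)
  log <- character()
  trimmed_n <- 0L; trimmed_c <- 0L
  retained <- rt$key
  for (ch in unique(rt$chain[rt$role == "binder"])) {
    keys <- rt$key[rt$chain == ch]
    folded <- scn[keys] > sc_neigh_threshold
    folded[is.na(folded)] <- FALSE
    nb_dist <- cb_dist <- Inf
    if (!is.null(hotspot_bounds)) {
      resnos <- rt$resno[rt$chain == ch]
      nb_dist <- max(0L, sum(resnos < hotspot_bounds[1]))
      cb_dist <- max(0L, sum(resnos > hotspot_bounds[2]))
    }
    n_end <- trim_one_end(folded, bound_dist = nb_dist)
    n_rm <- n_end$n_removed
    c_end <- trim_one_end(rev(folded[seq.int(n_rm + 1L, length(folded))]),
                          bound_dist = cb_dist)
    c_rm <- c_end$n_removed
    if (n_end$hit_floor || c_end$hit_floor) {
      warning("trim_termini would leave chain ", ch,
              " empty; keeping one residue")
    }
    keep <- keys[seq.int(n_rm + 1L, length(keys) - c_rm)]
    retained <- setdiff(retained, setdiff(keys, keep))
    trimmed_n <- trimmed_n + n_rm
    trimmed_c <- trimmed_c + c_rm
    if (n_rm + c_rm > 0) {
      log <- c(log, sprintf("chain %s: trimmed %d N-terminal, %d C-terminal", ch, n_rm, c_rm))
    }
  }
  structure(list(retained = retained, trimmed_n_terminal = trimmed_n,
                 trimmed_c_terminal = trimmed_c, crop_center = NA_character_,
                 log = log),
            class = "CropResult")
}

#' Radial crop of the target around a hotspot
#'
#' Picks a center hotspot (uniformly under the seed, or as given) and
#' retains a target residue iff any of its heavy atoms lies within `radius`
#' of the center residue's (virtual) C-beta.  Binder residues are always
#' retained.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param hotspots hotspot mask over target residue keys.
#' @param center residue key to center on, or `NULL` for a random hotspot.
#' @param radius crop radius, Angstrom.
#' @param seed integer seed for the random-center draw.
#' @return list of class `CropResult`.
#' @export
radial_crop <- function(cs, hotspots, center = NULL, radius = 25.0, seed = 0L) {
  check_interface_roles(cs)
  if (is.null(center)) {
    hot_keys <- names(hotspots)[hotspots]
    if (length(hot_keys) == 0) stop("radial_crop: no hotspots")
    rng <- make_rng(seed)
    center <- hot_keys[rng$int_in(1L, length(hot_keys))]
  }
  rt <- residue_table(cs)
  if (!(center %in% rt$key)) stop("radial_crop: unknown center residue ", center)
  ci <- match(center, rt$key)
  ccb <- virtual_cbeta(get_residue(cs, rt$chain[ci], rt$resno[ci]))
  a <- cs$atoms[cs$atoms$element != "H", , drop = FALSE]
  akey <- paste(a$chain, a$resno, sep = ":")
  d <- sqrt((a$x - ccb[1])^2 + (a$y - ccb[2])^2 + (a$z - ccb[3])^2)
  retained <- rt$key[vapply(seq_len(nrow(rt)), function(i) {
    if (rt$role[i] == "binder") return(TRUE)
    any(d[akey == rt$key[i]] <= radius)
  }, logical(1))]
  structure(list(retained = retained, trimmed_n_terminal = 0L,
                 trimmed_c_terminal = 0L, crop_center = center,
                 log = sprintf("radial crop at %s, radius %.1f A: kept %d/%d residues",
                               center, radius, length(retained), nrow(rt))),
            class = "CropResult")
}

#' @export
print.CropResult <- function(x, ...) {
  cat("CropResult:", length(x$retained), "residues retained")
  if (x$trimmed_n_terminal + x$trimmed_c_terminal > 0) {
    cat(sprintf(" (trimmed %d N / %d C)", x$trimmed_n_terminal, x$trimmed_c_terminal))
  }
  if (!is.na(x$crop_center)) cat(", crop center", x$crop_center)
  cat("\n")
  invisible(x)
}

#' Apply a CropResult to a structure
#' @param cs a `ComplexStructure`.
#' @param crop a `CropResult`.
#' @return The structure restricted to the retained residues.
#' @export
apply_crop <- function(cs, crop) subset_structure(cs, crop$retained)
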