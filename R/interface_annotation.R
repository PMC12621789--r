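# Interface annotation ------------------------------------------------------
#
# Hotspots: target residues in C-beta contact with the binder (<= 7 A) that
# are also solvent exposed (SASA >= 30 A^2 at the 2.8 A probe).  Anti-
# hotspots: target residues whose closest heavy atom is more than 10 A from
# every binder atom.  Super-hotspot values grade hotspots by cross-chain
# C-alpha neighbor density.  The 7 <= 10 relation makes the two masks
# disjoint by construction.

#' Detect interface hotspot residues on the target
#'
#' A target residue is a hotspot iff its (virtual) C-beta lies within
#' `cb_cutoff` of any binder (virtual) C-beta and its SASA is at least
#' `sasa_min`.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param sasa result of [sasa_per_residue()] at the gate probe (2.8 A).
#' @param cb_cutoff C-beta contact cutoff, Angstrom (inclusive).
#' @param sasa_min minimum solvent exposure, A^2 (inclusive).
#' @return named logical vector over target residue keys, in structure order.
#' @export
detect_hotspots <- function(cs, sasa = NULL, cb_cutoff = 7.0, sasa_min = 30.0) {
  check_interface_roles(cs)
  if (is.null(sasa)) sasa <- sasa_per_residue(cs, probe_radius = 2.8)
  rt <- residue_table(cs)
  cb <- cbeta_matrix(cs, rt)
  tgt <- which(rt$role == "target")
  bnd <- which(rt$role == "binder")
  out <- logical(length(tgt))
  names(out) <- rt$key[tgt]
  bcb <- cb[bnd, , drop = FALSE]
  for (k in seq_along(tgt)) {
    tcb <- cb[tgt[k], ]
    if (any(is.na(tcb))) next
    d <- sqrt(rowSums((bcb - matrix(tcb, nrow(bcb), 3, byrow = TRUE))^2))
    s <- sasa$per_residue_sasa[[rt$key[tgt[k]]]]
    out[k] <- any(d <= cb_cutoff, na.rm = TRUE) && !is.null(s) && s >= sasa_min
  }
  out
}

#' Detect anti-hotspot residues on the target
#'
#' A target residue is an anti-hotspot iff the minimum heavy-atom distance
#' from any of its atoms to any binder atom exceeds `dist_cutoff`
#' (strictly).
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param dist_cutoff distance cutoff, Angstrom (exclusive).
#' @return named logical vector over target residue keys.
#' @export
detect_antihotspots <- function(cs, dist_cutoff = 10.0) {
  check_interface_roles(cs)
  rt <- residue_table(cs)
  a <- cs$atoms[cs$atoms$element != "H", , drop = FALSE]
  role <- chain_role(cs, a$chain)
  bxyz <- as.matrix(a[role == "binder", c("x", "y", "z"), drop = FALSE])
  tgt <- rt[rt$role == "target", , drop = FALSE]
  out <- logical(nrow(tgt))
  names(out) <- tgt$key
  akey <- paste(a$chain, a$resno, sep = ":")
  for (k in seq_len(nrow(tgt))) {
    txyz <- as.matrix(a[akey == tgt$key[k], c("x", "y", "z"), drop = FALSE])
    dmin <- min(vapply(seq_len(nrow(txyz)), function(i) {
      min(sqrt(rowSums((bxyz - matrix(txyz[i, ], nrow(bxyz), 3, byrow = TRUE))^2)))
    }, numeric(1)))
    out[k] <- dmin > dist_cutoff
  }
  out
}

#' Continuous super-hotspot values
#'
#' For each hotspot residue, counts binder C-alpha atoms within `radius` of
#' its own C-alpha, optionally adds an integer jitter drawn uniformly from
#' \{-1, 0, +1\} under the seed, caps at `cap` and normalizes to `[0, 1]`.
#' Non-hotspot residues get 0.
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param hotspots logical hotspot mask from [detect_hotspots()].
#' @param radius neighbor radius, Angstrom.
#' @param cap neighbor-count cap (normalization denominator).
#' @param jitter logical; add the +/-1 jitter.
#' @param seed integer seed for the jitter draw.
#' @return named numeric vector over target residue keys, values in `[0,1]`.
#' @export
superhotspot_values <- function(cs, hotspots, radius = 10.0, cap = 12L,
                                jitter = FALSE, seed = 0L) {
  check_interface_roles(cs)
  rt <- residue_table(cs)
  ca <- atom_coord_matrix(cs, "CA")
  role_ca <- chain_role(cs, sub(":.*", "", rownames(ca)))
  bca <- ca[role_ca == "binder", , drop = FALSE]
  out <- numeric(length(hotspots))
  names(out) <- names(hotspots)
  hot_idx <- which(hotspots)
  jit <- integer(length(hot_idx))
  if (jitter && length(hot_idx) > 0) {
    rng <- make_rng(seed)
    jit <- vapply(seq_along(hot_idx), function(i) rng$int_in(-1L, 1L), integer(1))
  }
  for (i in seq_along(hot_idx)) {
    key <- names(hotspots)[hot_idx[i]]
    tca <- ca[match(key, rownames(ca)), ]
    if (any(is.na(tca))) next
    d <- sqrt(rowSums((bca - matrix(tca, nrow(bca), 3, byrow = TRUE))^2))
    n <- sum(d <= radius) + jit[i]
    out[hot_idx[i]] <- min(max(n, 0L), cap) / cap
  }
  out
}

#' Hotspot mask sampling configuration
#'
#' Defaults mirror the training-time conditioning schedule: hotspot masks
#' present in 75% of examples, anti-hotspots in 10%, and hotspot coverage
#' downsampled to at most 20% of target residues by a speckle-or-region
#' strategy.
#'
#' @param hotspot_inclusion_prob probability a training example carries the
#'   hotspot mask at all.
#' @param antihotspot_inclusion_prob same for the anti-hotspot mask.
#' @param max_coverage maximum fraction of target residues kept as hotspots.
#' @param strategy `"speckle"` (scattered singletons) or `"region"` (one
#'   contiguous spatial patch).
#' @param seed integer seed.
#' @return list of class `MaskSamplingConfig`.
#' @export
mask_sampling_config <- function(hotspot_inclusion_prob = 0.75,
                                 antihotspot_inclusion_prob = 0.10,
                                 max_coverage = 0.20,
                                 strategy = c("speckle", "region"),
                                 seed = 0L) {
  strategy <- match.arg(strategy)
  probs <- c(hotspot_inclusion_prob, antihotspot_inclusion_prob, max_coverage)
  if (any(probs < 0 | probs > 1)) stop("probabilities and coverage must be in [0,1]")
  structure(list(hotspot_inclusion_prob = hotspot_inclusion_prob,
                 antihotspot_inclusion_prob = antihotspot_inclusion_prob,
                 max_coverage = max_coverage, strategy = strategy,
                 seed = as.integer(seed)),
            class = "MaskSamplingConfig")
}

#' Downsample a hotspot mask to a coverage budget
#'
#' Keeps a subset of the input mask with at most
#' `ceil(max_coverage * n_target_residues)` residues.  The speckle strategy
#' samples uniformly without replacement; the region strategy picks one
#' seeded hotspot and grows by 3D nearest-neighbor order among hotspots
#' until the budget is filled.  Fully deterministic given the config seed.
#'
#' @param cs a `ComplexStructure` (used for C-beta geometry under the
#'   region strategy).
#' @param hotspots logical mask over target residues.
#' @param config a [mask_sampling_config()].
#' @return logical mask, a subset of the input.
#' @export
downsample_hotspots <- function(cs, hotspots, config = mask_sampling_config()) {
  n_target <- length(hotspots)
  budget <- ceiling(config$max_coverage * n_target)
  out <- hotspots & FALSE
  idx <- which(hotspots)
  if (length(idx) == 0) {
    warning("downsample_hotspots: empty input mask")
    return(out)
  }
  if (length(idx) <= budget) return(hotspots)
  rng <- make_rng(config$seed)
  if (config$strategy == "speckle") {
    keep <- rng$sample_without_replacement(idx, budget)
  } else {
    rt <- residue_table(cs)
    cb <- cbeta_matrix(cs, rt)
    pos <- cb[match(names(hotspots)[idx], rownames(cb)), , drop = FALSE]
    seed_i <- rng$int_in(1L, length(idx))
    d <- sqrt(rowSums((pos - matrix(pos[seed_i, ], nrow(pos), 3, byrow = TRUE))^2))
    keep <- idx[order(d)][seq_len(budget)]
  }
  out[keep] <- TRUE
  out
}

#' ORI pseudoatom placement
#'
#' The ORI is the center of the starting residue noise cloud used to steer
#' binder placement; the most consistent placement is the geometric center
#' of the hotspot mask (mean of hotspot C-beta positions).
#'
#' @param cs a `ComplexStructure`.
#' @param hotspots logical hotspot mask (required for `hotspot_center`).
#' @param mode `"hotspot_center"` or `"user_point"`.
#' @param point user-supplied 3-vector for `user_point` mode.
#' @return numeric 3-vector (Angstrom).
#' @export
compute_ori <- function(cs, hotspots = NULL,
                        mode = c("hotspot_center", "user_point"), point = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_point") {
    if (is.null(point) || length(point) != 3) stop("user_point mode needs a 3-vector")
    return(as.numeric(point))
  }
  if (is.null(hotspots) || !any(hotspots)) {
    stop("compute_ori: no hotspots to center on")
  }
  rt <- residue_table(cs)
  cb <- cbeta_matrix(cs, rt)
  pos <- cb[match(names(hotspots)[hotspots], rownames(cb)), , drop = FALSE]
  colMeans(pos)
}

#' Export interface annotations as TSV
#'
#' @param cs a `ComplexStructure` with roles assigned.
#' @param annotation list with `hotspot`, `antihotspot`, `hotspot_value`
#'   vectors over target residue keys.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(cs, annotation, path) {
  rt <- residue_table(cs)
  tgt <- rt[rt$role == "target", , drop = FALSE]
  df <- data.frame(
    chain = tgt$chain, seq_index = tgt$resno, resname = tgt$resname,
    hotspot = as.integer(annotation$hotspot[tgt$key]),
    antihotspot = as.integer(annotation$antihotspot[tgt$key]),
    hotspot_value = signif(annotation$hotspot_value[tgt$key], 6)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
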