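# Solvent-accessible surface area ------------------------------------------
#
# Shrake-Rupley point sampling on a deterministic golden-spiral sphere, so
# results are bit-for-bit reproducible at fixed n_points.  Two probes are in
# play in this package: the hotspot gate uses 2.8 A (paired with interface
# detection in complex context), the RASA conditioning channel uses the
# conventional water probe of 1.4 A.

# Deterministic, near-uniform unit-sphere point set (Fibonacci lattice).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Maximum accessible surface area per residue type (theoretical values of
# the Tien et al. scale), A^2; PTR normalized with the tyrosine value.
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174,
    PTR = 263)
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA with a deterministic golden-spiral point set.  Each
#' atom's sphere (vdW radius + probe) is sampled at `n_points` points; a
#' point is accessible if no other occluding atom's expanded sphere covers
#' it.  Residue SASA is the sum over the residue's heavy atoms.
#'
#' @param cs a `ComplexStructure`.
#' @param probe_radius probe radius in Angstrom (> 0).
#' @param context `"complex"` (all atoms occlude) or `"chain_alone"` (only
#'   atoms of the residue's own chain occlude).
#' @param n_points sphere sampling density per atom (default 960).
#' @return list with `per_residue_sasa` (named numeric, names are residue
#'   keys in structure order), `probe_radius`, `n_points`.
#' @export
sasa_per_residue <- function(cs, probe_radius = 2.8,
                             context = c("complex", "chain_alone"),
                             n_points = 960) {
  context <- match.arg(context)
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  a <- cs$atoms[cs$atoms$element != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms")
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- a$vdw + probe_radius
  sphere <- golden_spiral_points(n_points)
  atom_sasa <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    occl <- if (context == "complex") seq_len(nrow(a)) else which(a$chain == a$chain[i])
    occl <- setdiff(occl, i)
    # only neighbors whose expanded sphere can reach atom i's surface
    if (length(occl) > 0) {
      d2 <- rowSums((coords[occl, , drop = FALSE] -
                       matrix(coords[i, ], length(occl), 3, byrow = TRUE))^2)
      occl <- occl[d2 < (radii[occl] + radii[i])^2]
    }
    pts <- sphere * radii[i] +
      matrix(coords[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in occl) {
      if (!any(acc)) break
      dj2 <- rowSums((pts[acc, , drop = FALSE] -
                        matrix(coords[j, ], sum(acc), 3, byrow = TRUE))^2)
      acc[acc] <- dj2 >= radii[j]^2
    }
    atom_sasa[i] <- 4 * pi * radii[i]^2 * sum(acc) / n_points
  }
  key <- paste(a$chain, a$resno, sep = ":")
  rt <- residue_table(cs)
  per_res <- vapply(rt$key, function(k) sum(atom_sasa[key == k]), numeric(1))
  list(per_residue_sasa = per_res, probe_radius = probe_radius, n_points = n_points)
}

#' Per-residue relative solvent accessibility (RASA)
#'
#' SASA at the 1.4 A water probe in complex context, divided by the
#' residue type's theoretical maximum ASA, clipped to `[0, 1]`.  PTR uses
#' the tyrosine maximum; residue types outside the table are reported as
#' `NA` (missing), never as zero.
#'
#' @param cs a `ComplexStructure`.
#' @param n_points sphere sampling density.
#' @return named numeric vector over residue keys, values in `[0, 1]` or `NA`.
#' @export
rasa_per_residue <- function(cs, n_points = 960) {
  sasa <- sasa_per_residue(cs, probe_radius = 1.4, context = "complex",
                           n_points = n_points)
  rt <- residue_table(cs)
  maxasa <- max_asa_table()
  out <- rep(NA_real_, nrow(rt))
  names(out) <- rt$key
  known <- rt$resname %in% names(maxasa)
  out[known] <- pmin(1, pmax(0, sasa$per_residue_sasa[known] /
                                  maxasa[rt$resname[known]]))
  out
}

#' Export per-residue SASA and RASA as TSV
#'
#' @param cs a `ComplexStructure`.
#' @param path output TSV path.
#' @param probe_radius probe for the `sasa` column (gate probe by default).
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(cs, path, probe_radius = 2.8) {
  rt <- residue_table(cs)
  sasa <- sasa_per_residue(cs, probe_radius = probe_radius)
  rasa <- rasa_per_residue(cs)
  df <- data.frame(
    chain = rt$chain, seq_index = rt$resno, resname = rt$resname,
    sasa = signif(sasa$per_residue_sasa, 6), rasa = signif(rasa, 6)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
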