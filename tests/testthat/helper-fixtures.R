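# Programmatic fixtures and independent oracles shared across test files.

# rbind atom tables that may disagree on the optional `element` column
# (it is re-derived from atom names by complex_structure anyway).
bind_atoms <- function(...) {
  dfs <- lapply(list(...), function(d) { d$element <- NULL; d })
  do.call(rbind, dfs)
}

# A residue with full backbone (+CB unless GLY) at an arbitrary location,
# built from a translated ideal geometry template.
residue_atoms <- function(chain, resno, resname = "ALA", at = c(0, 0, 0)) {
  tmpl <- rbind(
    c(-1.458, 0.000, 0.000),   # N
    c( 0.000, 0.000, 0.000),   # CA
    c( 0.547, 1.423, 0.000),   # C
    c(-0.200, 2.400, 0.000),   # O
    c( 0.500, -0.760, 1.200))  # CB
  names_ <- c("N", "CA", "C", "O", "CB")
  if (resname == "GLY") { tmpl <- tmpl[1:4, ]; names_ <- names_[1:4] }
  data.frame(chain = chain, resno = resno, resname = resname, elety = names_,
             x = tmpl[, 1] + at[1], y = tmpl[, 2] + at[2], z = tmpl[, 3] + at[3],
             occ = 1, stringsAsFactors = FALSE)
}

# Binder residue i at `binder_at`, target residue at `target_at`.
two_residue_complex <- function(binder_at = c(0, 0, 0), target_at = c(6, 0, 0),
                                target_resname = "ALA") {
  at <- rbind(residue_atoms("A", 1, "ALA", binder_at),
              residue_atoms("B", 1, target_resname, target_at))
  assign_roles(complex_structure(at), "A")
}

# Independent Monte-Carlo rejection SASA oracle (random sphere points, own
# RNG), for tiny systems only.
mc_sasa_oracle <- function(coords, radii, probe, n_mc = 20000, seed = 42) {
  set.seed(seed)
  total <- 0
  exp_r <- radii + probe
  for (i in seq_len(nrow(coords))) {
    p <- matrix(stats::rnorm(3 * n_mc), n_mc, 3)
    p <- p / sqrt(rowSums(p^2)) * exp_r[i]
    p <- sweep(p, 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_mc)
    for (j in setdiff(seq_len(nrow(coords)), i)) {
      d2 <- rowSums(sweep(p, 2, coords[j, ])^2)
      acc <- acc & d2 >= exp_r[j]^2
    }
    total <- total + 4 * pi * exp_r[i]^2 * mean(acc)
  }
  total
}

# Independent brute-force rigid-superposition oracle: nested grid search
# over ZYZ Euler angles, translations from centroids.
grid_search_rmsd <- function(mobile, reference) {
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m0 <- sweep(mobile, 2, mc); r0 <- sweep(reference, 2, rc)
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                             3, 3, byrow = TRUE)
  roty <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                             3, 3, byrow = TRUE)
  rmsd_of <- function(ang) {
    R <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
    sqrt(mean(rowSums((m0 %*% t(R) - r0)^2)))
  }
  best <- c(0, 0, 0); best_val <- rmsd_of(best); step <- pi / 8
  grid0 <- as.matrix(expand.grid(a = seq(0, 2 * pi, by = step),
                                 b = seq(0, pi, by = step),
                                 c = seq(0, 2 * pi, by = step)))
  vals <- apply(grid0, 1, rmsd_of)
  best <- grid0[which.min(vals), ]; best_val <- min(vals)
  for (lvl in 1:14) {
    step <- step / 2
    loc <- as.matrix(expand.grid(a = best[1] + step * (-4:4),
                                 b = best[2] + step * (-4:4),
                                 c = best[3] + step * (-4:4)))
    vals <- apply(loc, 1, rmsd_of)
    if (min(vals) < best_val) { best <- loc[which.min(vals), ]; best_val <- min(vals) }
  }
  best_val
}

# Direct (loop-based) evaluation of the SCN cone formula, independent of
# the vectorized implementation.
scn_direct <- function(ca, cb, i) {
  u <- (cb[i, ] - ca[i, ]); u <- u / sqrt(sum(u^2))
  s <- 0
  for (j in seq_len(nrow(ca))) {
    if (j == i) next
    rel <- ca[j, ] - ca[i, ]
    d <- sqrt(sum(rel^2))
    ct <- sum(u * rel) / d
    if (ct <= -0.5) next
    s <- s + 1 / (1 + exp(d - 9)) * ((ct + 0.5) / 1.5)^2
  }
  s
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

minimal_pdb_text <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  GLY A   2       3.988   2.839   0.000  1.00  0.00           C",
  "END")

minimal_cif_text <- function() c(
  "data_mini",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
  "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
  "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 0.00 ? 1 ALA A C 1",
  "ATOM 4 O O . ALA A 1 1 ? 1.251 2.390 0.000 1.00 0.00 ? 1 ALA A O 1",
  "ATOM 5 N N . GLY A 1 2 ? 3.332 1.536 0.000 1.00 0.00 ? 2 GLY A N 1",
  "ATOM 6 C CA . GLY A 1 2 ? 3.988 2.839 0.000 1.00 0.00 ? 2 GLY A CA 1")

# Dense occluding shell of pseudo-atoms (distinct names, one extra residue)
# at `radius` around `center`.
burial_shell_atoms <- function(chain, resno, center, radius = 5.5, n = 170) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  data.frame(chain = chain, resno = resno, resname = "UNK",
             elety = sprintf("C%03d", seq_len(n)),
             x = center[1] + radius * sin(phi) * cos(theta),
             y = center[2] + radius * sin(phi) * sin(theta),
             z = center[3] + radius * cos(phi),
             occ = 1, stringsAsFactors = FALSE)
}

# Two concentric shells: fully buries a residue's heavy atoms even at the
# 2.8 A gate probe.
double_burial_shell <- function(chain, resno_base, center) {
  rbind(burial_shell_atoms(chain, resno_base, center, radius = 4.5, n = 150),
        burial_shell_atoms(chain, resno_base + 1L, center, radius = 6.5, n = 300))
}
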