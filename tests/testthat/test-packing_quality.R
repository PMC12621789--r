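# SCN packing metric, FBSCN gates, terminal trimming, radial cropping

# Residue with CA at `ca` and CB such that the cone axis is +z.
cone_residue <- function(chain, resno, ca) {
  data.frame(chain = chain, resno = resno, resname = "ALA",
             elety = c("N", "CA", "C", "O", "CB"),
             x = ca[1] + c(-1.458, 0, 0.55, -0.2, 0),
             y = ca[2] + c(0, 0, 1.42, 2.4, 0),
             z = ca[3] + c(0, 0, 0, 0, 1.522),
             occ = 1, stringsAsFactors = FALSE)
}

test_that("SCN matches direct evaluation of the cone formula", {
  # isolated residue: zero
  cs0 <- complex_structure(cone_residue("A", 1, c(0, 0, 0)))
  expect_equal(unname(scn_per_residue(cs0)[["A:1"]]), 0)
  # one neighbor straight along the cone axis at d = 5
  cs1 <- complex_structure(rbind(cone_residue("A", 1, c(0, 0, 0)),
                                 cone_residue("A", 2, c(0, 0, 5))))
  expect_equal(unname(scn_per_residue(cs1)[["A:1"]]), 1 / (1 + exp(-4)),
               tolerance = 1e-9)
  # irregular cluster: agrees with the independent loop oracle
  set.seed(7)
  rows <- list(cone_residue("A", 1, c(0, 0, 0)))
  for (i in 2:15) {
    rows[[i]] <- cone_residue("A", i, stats::runif(3, -7, 7))
  }
  cs <- complex_structure(do.call(rbind, rows))
  scn <- scn_per_residue(cs)
  ca <- binderprep:::atom_coord_matrix(cs, "CA")
  cb <- binderprep:::cbeta_matrix(cs)
  for (i in c(1, 5, 12)) {
    expect_equal(unname(scn[i]), scn_direct(ca, cb, i), tolerance = 1e-9)
  }
})

test_that("a dense in-cone cluster drives SCN above the folded threshold", {
  rows <- list(cone_residue("A", 1, c(0, 0, 0)))
  k <- 2
  for (dx in c(-2, 0, 2)) for (dy in c(-2, 0, 2)) {
    for (dz in c(3, 5.5)) {
      rows[[k]] <- cone_residue("A", k, c(dx, dy, dz)); k <- k + 1
    }
  }
  cs <- complex_structure(do.call(rbind, rows))
  expect_gt(scn_per_residue(cs)[["A:1"]], 4.0)
})

test_that("SCN is rigid-motion invariant and grows when the cone fills", {
  base <- rbind(cone_residue("A", 1, c(0, 0, 0)),
                cone_residue("A", 2, c(1, 1, 4)))
  cs <- complex_structure(base)
  s0 <- scn_per_residue(cs)[["A:1"]]
  R <- random_rotation(4)
  cs_r <- binderprep:::transform_structure(cs, R, c(-3, 8, 2))
  expect_equal(scn_per_residue(cs_r)[["A:1"]], s0, tolerance = 1e-9)
  # adding an in-cone neighbor within 9 A never decreases SCN
  for (p in list(c(0, 2, 3), c(2, 0, 6), c(-1, -1, 5))) {
    cs_plus <- complex_structure(rbind(base, cone_residue("A", 3, p)))
    expect_gte(scn_per_residue(cs_plus)[["A:1"]], s0)
  }
})

test_that("interface residues mirror the hotspot contact rule", {
  cs <- two_residue_complex(target_at = c(5, 0, 0))
  expect_true(interface_residues(cs)[["A:1"]])
  cs_far <- two_residue_complex(target_at = c(20, 0, 0))
  expect_false(interface_residues(cs_far)[["A:1"]])
  # mirror symmetry with hotspot detection, exposure gate aside
  cs_fix <- assemble_complex(fixture_spec())
  hs_nogate <- detect_hotspots(cs_fix, sasa_min = 0)
  swapped <- assign_roles(cs_fix, "B")
  expect_equal(sum(interface_residues(swapped)), sum(hs_nogate))
})

test_that("curation gates fire on either side of the FBSCN thresholds", {
  cs <- assemble_complex(fixture_spec())
  rt <- residue_table(cs)
  bk <- rt$key[rt$role == "binder"]
  iface <- interface_residues(cs)
  ik <- names(iface)[iface]
  hs <- detect_hotspots(cs)
  n_b <- length(bk)
  mk_scn <- function(frac_binder, frac_iface) {
    scn <- stats::setNames(rep(0.5, nrow(rt)), rt$key)
    non_iface <- setdiff(bk, ik)
    n_if <- round(frac_iface * length(ik))
    scn[ik[seq_len(n_if)]] <- 5
    extra <- round(frac_binder * n_b) - n_if
    if (extra > 0) scn[non_iface[seq_len(extra)]] <- 5
    scn
  }
  # both fractions comfortably above the gates: accept
  v <- curation_verdict(cs, mk_scn(0.5, 0.5), hs)
  expect_equal(v$verdict, "accept")
  expect_equal(v$binder_fbscn, 0.5)
  # binder_FBSCN below 0.12
  scn_low <- stats::setNames(rep(0.5, nrow(rt)), rt$key)
  scn_low[ik] <- 5   # interface fine, whole-binder fraction too low? no:
  # with all interface folded, binder fraction = |iface|/n_b; force below 0.12
  scn_lowb <- stats::setNames(rep(0.5, nrow(rt)), rt$key)
  scn_lowb[bk[seq_len(floor(0.10 * n_b))]] <- 5
  v2 <- curation_verdict(cs, scn_lowb, hs)
  expect_true("low_binder_fbscn" %in% v2$reject_reasons)
  expect_equal(v2$verdict, "reject")
  expect_lt(v2$binder_fbscn, 0.12)
  # interface_FBSCN below 0.13 while binder_FBSCN passes
  scn_lowi <- stats::setNames(rep(0.5, nrow(rt)), rt$key)
  scn_lowi[setdiff(bk, ik)[seq_len(ceiling(0.2 * n_b))]] <- 5
  v3 <- curation_verdict(cs, scn_lowi, hs)
  expect_gte(v3$binder_fbscn, 0.12)
  expect_lt(v3$interface_fbscn, 0.13)
  expect_identical(v3$reject_reasons, "low_interface_fbscn")
  # empty hotspot mask
  v4 <- curation_verdict(cs, mk_scn(0.5, 0.5), hs & FALSE)
  expect_true("no_hotspots" %in% v4$reject_reasons)
  # binder length cap
  v5 <- curation_verdict(cs, mk_scn(0.5, 0.5), hs, max_binder_len = 40L)
  expect_true("binder_too_long" %in% v5$reject_reasons)
  # FBSCN fractions match brute-force recomputation exactly
  scn_real <- scn_per_residue(cs)
  v6 <- curation_verdict(cs, scn_real, hs)
  expect_identical(v6$binder_fbscn, mean(scn_real[bk] > 4.0))
  expect_identical(v6$interface_fbscn, mean(scn_real[ik] > 4.0))
})

# Build a single binder chain whose folded pattern is exactly `folded`
# (logical, N-terminus first), by passing a crafted SCN vector.
trim_fixture <- function(folded) {
  n <- length(folded)
  rows <- lapply(seq_len(n), function(i) cone_residue("A", i, c(3.8 * i, 0, 0)))
  rows[[n + 1]] <- cone_residue("B", 1, c(200, 0, 0))
  cs <- assign_roles(complex_structure(do.call(rbind, rows)), "A")
  scn <- stats::setNames(c(ifelse(folded, 2, 0.2), 2), residue_table(cs)$key)
  list(cs = cs, scn = scn)
}

test_that("terminal trimming follows the 9-window tolerance scheme", {
  # window <= 4 (chain of 4): tolerance 0; fully trimmable, so the
  # single-residue floor stops it with a warning
  f <- trim_fixture(c(FALSE, FALSE, FALSE, FALSE))
  expect_warning(tr <- trim_termini(f$cs, f$scn), "keeping one residue")
  expect_equal(tr$trimmed_n_terminal, 3)   # stops at the last residue
  f <- trim_fixture(c(TRUE, FALSE, FALSE, FALSE))
  tr <- trim_termini(f$cs, f$scn)
  expect_equal(tr$trimmed_n_terminal, 0)   # 1 folded > tolerance 0
  # window <= 8 (chain of 7): tolerance 1
  f <- trim_fixture(c(FALSE, rep(c(FALSE, TRUE), 3)))
  tr <- trim_termini(f$cs, f$scn)
  expect_equal(tr$trimmed_n_terminal, 0)   # 3 folded > 1
  f <- trim_fixture(c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  tr <- trim_termini(f$cs, f$scn)          # 1 folded <= 1: trims until the
  expect_gt(tr$trimmed_n_terminal, 0)      # window exceeds tolerance
  # window 9 (long chain): tolerance 2
  f <- trim_fixture(c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      FALSE, rep(TRUE, 12)))
  tr <- trim_termini(f$cs, f$scn)
  expect_equal(tr$trimmed_n_terminal, 0)   # 3 folded in first 9 > 2
  f <- trim_fixture(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      FALSE, rep(TRUE, 12)))
  tr <- trim_termini(f$cs, f$scn)
  # 2 folded <= tolerance 2: one residue goes, then the folded block enters
  # the window (3 folded > 2) and trimming stops
  expect_equal(tr$trimmed_n_terminal, 1)
  # a well-folded terminal window is never trimmed
  f <- trim_fixture(c(TRUE, TRUE, TRUE, rep(TRUE, 10)))
  tr <- trim_termini(f$cs, f$scn)
  expect_equal(tr$trimmed_n_terminal + tr$trimmed_c_terminal, 0)
})

test_that("trimming is idempotent and keeps a contiguous subsequence", {
  f <- trim_fixture(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      FALSE, rep(TRUE, 12), FALSE, FALSE, FALSE))
  tr <- trim_termini(f$cs, f$scn)
  rt <- residue_table(f$cs)
  kept_idx <- match(setdiff(tr$retained, "B:1"), rt$key)
  expect_identical(kept_idx, seq(min(kept_idx), max(kept_idx)))
  cs2 <- apply_crop(f$cs, tr)
  scn2 <- f$scn[tr$retained]
  tr2 <- trim_termini(cs2, scn2)
  expect_equal(tr2$trimmed_n_terminal + tr2$trimmed_c_terminal, 0)
  # target chain is never trimmed
  expect_true("B:1" %in% tr$retained)
})

test_that("trimming may extend only a bounded distance into hotspot bounds", {
  folded <- c(rep(FALSE, 20), rep(TRUE, 5))
  f <- trim_fixture(folded)
  # unbounded: the window rule eats unfolded residues until three folded
  # residues enter the 9-window (after 14 removals)
  tr_free <- trim_termini(f$cs, f$scn)
  expect_equal(tr_free$trimmed_n_terminal, 14)
  # bounds protecting residues >= 2 allow 1 residue plus at most 9 more
  # unfolded residues inside the protected region
  tr <- trim_termini(f$cs, f$scn, hotspot_bounds = c(2, 25))
  expect_equal(tr$trimmed_n_terminal, 1 + 9)
})

test_that("radial crop keeps near-target residues and all binder residues", {
  rows <- list(cone_residue("A", 1, c(0, 0, 0)),       # binder (center host)
               cone_residue("A", 2, c(0, 0, 40)),      # binder, far: kept anyway
               cone_residue("B", 1, c(5, 0, 0)),       # target near
               cone_residue("B", 2, c(20, 0, 0)),      # target at 20: kept
               cone_residue("B", 3, c(33, 0, 0)))      # all atoms beyond 25: dropped
  cs <- assign_roles(complex_structure(do.call(rbind, rows)), "A")
  hs <- c("B:1" = TRUE, "B:2" = FALSE, "B:3" = FALSE)
  cr <- radial_crop(cs, hs, center = "B:1", radius = 25)
  expect_true(all(c("A:1", "A:2", "B:1", "B:2") %in% cr$retained))
  expect_false("B:3" %in% cr$retained)
  expect_error(radial_crop(cs, hs & FALSE), "no hotspots")
})

test_that("radial crop retained set is monotone in radius", {
  cs <- assemble_complex(fixture_spec(peptide_sequence = "AAyAAAAAAAAAA",
                                      n_contact_residues = 3, separation = 6))
  hs <- detect_hotspots(cs)
  prev <- character()
  for (r in c(5, 10, 15, 25, 40)) {
    cur <- radial_crop(cs, hs, center = names(hs)[which(hs)[1]], radius = r)$retained
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("random crop centers are seed-deterministic hotspots", {
  cs <- assemble_complex(fixture_spec())
  hs <- detect_hotspots(cs)
  c1 <- radial_crop(cs, hs, seed = 9)
  c2 <- radial_crop(cs, hs, seed = 9)
  expect_identical(c1$crop_center, c2$crop_center)
  expect_true(c1$crop_center %in% names(hs)[hs])
})
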