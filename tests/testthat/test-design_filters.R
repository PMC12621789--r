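# Hydrogen-bond detection and counting, Kabsch/pTyr RMSD, accept-reject gates

# Binder residue with its backbone N placed exactly `d` Angstrom from the
# first terminal phosphate oxygen of a target PTR peptide, approaching from
# the side opposite the phosphorus so the acceptor angle is valid.
phosphate_probe_complex <- function(d) {
  pep <- build_phosphopeptide("AAyAA")
  p <- as.numeric(pep[pep$elety == "P", c("x", "y", "z")])
  o1 <- as.numeric(pep[pep$elety == "O1P", c("x", "y", "z")])
  u <- (o1 - p) / sqrt(sum((o1 - p)^2))
  at <- bind_atoms(residue_atoms("A", 1, "ALA", o1 + u * d + c(1.458, 0, 0)), pep)
  # residue_atoms places N at offset (-1.458, 0, 0) from its anchor
  assign_roles(complex_structure(at), "A")
}

test_that("hydrogen-bond geometry: distance cutoff and acceptor angle", {
  cs <- phosphate_probe_complex(3.2)
  bonds <- detect_hbonds(cs)
  ph <- bonds[bonds$acceptor_is_phosphate_oxygen, ]
  expect_gte(nrow(ph), 1)
  expect_true(any(abs(ph$distance - 3.2) < 1e-6))
  expect_equal(count_phosphate_hbonds(bonds, cs), 1)
  # same geometry beyond the 3.5 A cutoff: nothing
  cs_far <- phosphate_probe_complex(3.8)
  expect_equal(count_phosphate_hbonds(detect_hbonds(cs_far), cs_far), 0)
  # intra-residue donor/acceptor pairs are never reported
  expect_false(any(bonds$donor_residue == bonds$acceptor_residue))
})

test_that("acceptor-side angle rejects donors tucked behind the antecedent", {
  pep <- build_phosphopeptide("AAyAA")
  p <- as.numeric(pep[pep$elety == "P", c("x", "y", "z")])
  o1 <- as.numeric(pep[pep$elety == "O1P", c("x", "y", "z")])
  u <- (o1 - p) / sqrt(sum((o1 - p)^2))
  # donor placed 3.0 A from O1P but on the phosphorus side (angle < 90 deg)
  bad <- o1 - u * 3.0
  donor <- data.frame(chain = "A", resno = 1, resname = "ALA", elety = "N",
                      x = bad[1], y = bad[2], z = bad[3], occ = 1,
                      stringsAsFactors = FALSE)
  at <- bind_atoms(donor, pep)
  cs <- assign_roles(complex_structure(at), "A")
  bonds <- detect_hbonds(cs)
  expect_equal(count_phosphate_hbonds(bonds, cs), 0)
})

test_that("phosphate bonds require a binder donor and a target PTR acceptor", {
  # donors on the target chain itself are not counted
  pep <- build_phosphopeptide("AAyKA")
  cs <- assign_roles(
    complex_structure(bind_atoms(residue_atoms("A", 1, "ALA", c(50, 0, 0)), pep)), "A")
  bonds <- detect_hbonds(cs)
  expect_equal(count_phosphate_hbonds(bonds, cs), 0)
  # no PTR anywhere: hard error
  cs2 <- two_residue_complex()
  expect_error(count_phosphate_hbonds(detect_hbonds(cs2), cs2),
               "no phosphotyrosine")
})

test_that("donor pseudo-atoms at the fixture's requested distances are counted", {
  cs3 <- assemble_complex(fixture_spec(phosphate_donor_distances = c(2.9, 3.0, 3.1)))
  bonds <- detect_hbonds(cs3)
  expect_equal(count_phosphate_hbonds(bonds, cs3), 3)
  cs1 <- assemble_complex(fixture_spec(phosphate_donor_distances = 2.9))
  expect_equal(count_phosphate_hbonds(detect_hbonds(cs1), cs1), 1)
  # phosphate bonds are a subset of the total peptide bonds
  pep <- count_peptide_hbonds(bonds, cs3)
  expect_gte(pep$total, count_phosphate_hbonds(bonds, cs3))
})

test_that("peptide bond counting separates side-chain-side-chain bonds", {
  # hand-built: 2 backbone-backbone bonds + 1 sidechain(N)-phosphate bond
  pep <- build_phosphopeptide("AAyAA")
  o_res1 <- as.numeric(pep[pep$resno == 1 & pep$elety == "O", c("x", "y", "z")])
  n_res5 <- as.numeric(pep[pep$resno == 5 & pep$elety == "N", c("x", "y", "z")])
  p <- as.numeric(pep[pep$elety == "P", c("x", "y", "z")])
  o1 <- as.numeric(pep[pep$elety == "O1P", c("x", "y", "z")])
  u <- (o1 - p) / sqrt(sum((o1 - p)^2))
  binder <- rbind(
    # backbone N donor to peptide residue 1 backbone O (acceptor antecedent C)
    data.frame(chain = "A", resno = 1, resname = "GLY", elety = c("N", "CA"),
               x = c(o_res1[1], o_res1[1] + 4), y = c(o_res1[2] + 2.9, o_res1[2] + 4),
               z = c(o_res1[3], o_res1[3]), occ = 1, stringsAsFactors = FALSE),
    # backbone O acceptor near peptide residue 5 backbone N donor
    data.frame(chain = "A", resno = 2, resname = "GLY",
               elety = c("O", "C", "CA"),
               x = n_res5[1] + c(0, 1.23, 2.4), y = n_res5[2] + c(2.9, 3.4, 3.4),
               z = n_res5[3], occ = 1, stringsAsFactors = FALSE),
    # arginine side-chain donor to a phosphate oxygen (sidechain-sidechain)
    data.frame(chain = "A", resno = 3, resname = "ARG", elety = "NH1",
               x = o1[1] + 2.9 * u[1], y = o1[2] + 2.9 * u[2],
               z = o1[3] + 2.9 * u[3], occ = 1, stringsAsFactors = FALSE))
  cs <- assign_roles(complex_structure(bind_atoms(binder, pep)), "A")
  bonds <- detect_hbonds(cs)
  counts <- count_peptide_hbonds(bonds, cs)
  expect_equal(counts$total, 3)
  expect_equal(counts$sidechain_sidechain, 1)
  expect_equal(count_phosphate_hbonds(bonds, cs), 1)
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  cs <- assemble_complex(fixture_spec())
  b0 <- detect_hbonds(cs)
  cs2 <- binderprep:::transform_structure(cs, random_rotation(8), c(4, 4, -9))
  b1 <- detect_hbonds(cs2)
  expect_equal(nrow(b1), nrow(b0))
  expect_equal(b1$donor_residue, b0$donor_residue)
  expect_equal(b1$distance, b0$distance, tolerance = 1e-9)
})

test_that("Kabsch superposition: exact on rigid motions, oracle on deformations", {
  set.seed(11)
  pts <- matrix(stats::rnorm(24), 8, 3)
  self <- kabsch_superpose(pts, pts)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- pts %*% t(R90) + matrix(c(5, -2, 7), 8, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(pts, moved)$rmsd, 0, tolerance = 1e-6)
  # non-rigid deformation: least-squares optimum matches a brute-force
  # Euler-grid search
  stretched <- pts %*% diag(c(2, 1, 0.5))
  mine <- kabsch_superpose(pts, stretched)$rmsd
  oracle <- grid_search_rmsd(pts, stretched)
  expect_equal(mine, oracle, tolerance = 1e-3)
  expect_lte(mine, oracle + 1e-9)   # never worse than the search
  # symmetry in the argument order
  expect_equal(kabsch_superpose(stretched, pts)$rmsd, mine, tolerance = 1e-9)
  expect_error(kabsch_superpose(pts[1:2, ], stretched[1:2, ]), "3 points")
})

test_that("pTyr RMSD: self-zero, rigid invariance, constructed displacement", {
  cs <- assemble_complex(fixture_spec())
  expect_equal(as.numeric(ptyr_rmsd(cs, cs)), 0, tolerance = 1e-9)
  # global rigid motion of the prediction leaves the RMSD at zero
  pred_rigid <- binderprep:::transform_structure(cs, random_rotation(5), c(3, 3, 3))
  expect_equal(as.numeric(ptyr_rmsd(cs, pred_rigid)), 0, tolerance = 1e-6)
  # rigid 6 A displacement of the PTR alone reads back as 6.00
  pred <- cs
  sel <- pred$atoms$resname == "PTR"
  pred$atoms$x[sel] <- pred$atoms$x[sel] + 6
  pred <- binderprep:::transform_structure(pred, random_rotation(6), c(-4, 2, 8))
  expect_equal(as.numeric(ptyr_rmsd(cs, pred)), 6, tolerance = 0.01)
  # missing PTR side-chain atoms: RMSD over the shared subset only
  pred2 <- cs
  pred2$atoms <- pred2$atoms[!(pred2$atoms$resname == "PTR" &
                                 pred2$atoms$elety %in% c("O2P", "O3P")), ]
  r <- ptyr_rmsd(cs, pred2)
  expect_equal(as.numeric(r), 0, tolerance = 1e-9)
  expect_false(any(c("O2P", "O3P") %in% attr(r, "atoms")))
})

test_that("pTyr RMSD refuses structures without a PTR or matched binder", {
  no_ptr <- assign_roles(
    complex_structure(rbind(residue_atoms("A", 1), residue_atoms("B", 1, at = c(9, 0, 0)))),
    "A")
  cs <- assemble_complex(fixture_spec())
  expect_error(ptyr_rmsd(no_ptr, cs), "no PTR in designed")
  expect_error(ptyr_rmsd(cs, no_ptr), "no PTR in predicted")
})

test_that("design gates produce the full pass/fail truth table", {
  for (nph in c(1, 2)) for (ntot in c(12, 13)) for (rmsd in c(4.9, 5.2)) {
    rep <- apply_filters(n_phosphate_hbonds = nph, n_peptide_hbonds_total = ntot,
                         ptyr_rmsd = rmsd, binder_length = 100)
    should_pass <- nph >= 2 && ntot <= 12 && rmsd < 5
    expect_equal(rep$verdict == "pass", should_pass,
                 label = sprintf("nph=%d ntot=%d rmsd=%.1f", nph, ntot, rmsd))
    if (nph < 2) expect_true("insufficient_phosphate_hbonds" %in% rep$fail_reasons)
    if (ntot > 12) expect_true("excess_peptide_hbonds" %in% rep$fail_reasons)
    if (rmsd >= 5) expect_true("ptyr_rmsd" %in% rep$fail_reasons)
  }
})

test_that("length and confidence gates fire only when configured", {
  long <- apply_filters(3, 5, 1.0, binder_length = 160)
  expect_true("binder_too_long" %in% long$fail_reasons)
  ok <- apply_filters(3, 5, 1.0, binder_length = 159)
  expect_equal(ok$verdict, "pass")
  th <- filter_thresholds(min_plddt = 80, max_ipae = 10)
  conf_bad <- apply_filters(3, 5, 1.0, 100, confidence = list(plddt = 70, ipae = 5),
                            thresholds = th)
  expect_identical(conf_bad$fail_reasons, "low_plddt")
  conf_ok <- apply_filters(3, 5, 1.0, 100, confidence = list(plddt = 90, ipae = 5),
                           thresholds = th)
  expect_equal(conf_ok$verdict, "pass")
  # unsupplied confidence metric: gate skipped with a warning, not a failure
  th1 <- filter_thresholds(min_plddt = 80)
  expect_warning(skipped <- apply_filters(3, 5, 1.0, 100, confidence = list(),
                                          thresholds = th1), "skipped")
  expect_equal(skipped$verdict, "pass")
})

test_that("relaxing any threshold never turns a pass into a fail", {
  base <- filter_thresholds()
  relaxed <- list(
    filter_thresholds(min_phosphate_hbonds = 1L),
    filter_thresholds(max_peptide_hbonds = 20L),
    filter_thresholds(max_ptyr_rmsd = 10),
    filter_thresholds(max_design_binder_len = 300L))
  set.seed(3)
  for (i in 1:20) {
    nph <- sample(0:4, 1); ntot <- sample(0:20, 1)
    rmsd <- stats::runif(1, 0, 8); len <- sample(50:250, 1)
    v0 <- apply_filters(nph, ntot, rmsd, len, thresholds = base)$verdict
    for (th in relaxed) {
      v1 <- apply_filters(nph, ntot, rmsd, len, thresholds = th)$verdict
      if (v0 == "pass") expect_equal(v1, "pass")
    }
  }
})
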