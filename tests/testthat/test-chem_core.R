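# Structure I/O, PEOE charges, template alignment and congener selection.

test_that("SMILES parsing reproduces known topologies with 3D coordinates", {
  mols <- parse_smiles(c("c1ccccc1\tbz", "NC(=S)N/N=C/c1ccccc1\ttsc"))
  bz <- mols[[1]]; tsc <- mols[[2]]
  expect_length(heavy_atoms(bz), 6)
  ring_bonds <- bz$bonds[bz$atoms$element[bz$bonds$i] == "C" &
                           bz$atoms$element[bz$bonds$j] == "C", ]
  expect_equal(nrow(ring_bonds), 6)
  # thiosemicarbazone: 12 heavy atoms, one C=S and one C=N double bond
  expect_length(heavy_atoms(tsc), 12)
  el <- tsc$atoms$element
  dbl <- tsc$bonds[tsc$bonds$order == 2, ]
  pairs <- paste0(pmin(el[dbl$i], el[dbl$j]), pmax(el[dbl$i], el[dbl$j]))
  expect_true("CS" %in% pairs)
  expect_true("CN" %in% pairs)
  # coordinates are real 3D, not a flat placeholder
  expect_gt(max(apply(coords(tsc), 2, function(v) diff(range(v)))), 1)
})

test_that("SMILES embedding is deterministic for a fixed seed", {
  a <- parse_smiles("NC(=S)N/N=C/c1ccc(F)cc1\tx", seed = 7)[[1]]
  b <- parse_smiles("NC(=S)N/N=C/c1ccc(F)cc1\tx", seed = 7)[[1]]
  expect_identical(coords(a), coords(b))
})

test_that("SDF round trip preserves record count, elements and charges", {
  mols <- parse_smiles(c("CCO\te", "c1ccncc1\tpy"))
  tf <- tempfile(fileext = ".sdf")
  write_sdf(mols, tf)
  back <- read_molecules(tf, "sdf")
  expect_length(back, 2)
  expect_identical(back[[1]]$atoms$element, mols[[1]]$atoms$element)
  expect_equal(coords(back[[2]]), coords(mols[[2]]), tolerance = 1e-3)
  # formal charges survive via M CHG lines
  ion <- parse_smiles("[NH4+]\tion")[[1]]
  write_sdf(ion, tf)
  expect_equal(sum(read_molecules(tf, "sdf")[[1]]$atoms$formal_charge), 1)
})

test_that("reading rejects empty and malformed input", {
  tf <- tempfile(fileext = ".smi")
  writeLines(character(0), tf)
  expect_error(read_molecules(tf, "smiles"), "empty")
  writeLines("not_a_smiles(((", tf)
  expect_error(read_molecules(tf, "smiles"), "record")
})

test_that("activity tables convert IC50 to pIC50 and check consistency", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,ic50_nM", "a,1000", "b,10"), tf)
  d <- read_activities(tf)
  expect_equal(d$pic50, c(6, 8))
  writeLines(c("compound_id,ic50_nM,pic50", "a,1000,6.5"), tf)
  expect_error(read_activities(tf), "disagree")
})

test_that("PEOE charges match the reference implementation on methane", {
  ch4 <- assign_peoe_charges(fixture_smiles_mol("C", "methane"))
  # reference values from RDKit's Gasteiger implementation (6 iterations)
  expect_equal(ch4$charges[ch4$atoms$element == "C"], -0.0776, tolerance = 2e-3)
  expect_equal(unname(ch4$charges[ch4$atoms$element == "H"]),
               rep(0.0194, 4), tolerance = 2e-3)
})

test_that("PEOE charges are symmetric, conservative and motion-invariant", {
  h2 <- assign_peoe_charges(fixture_smiles_mol("[H][H]", "h2"))
  expect_equal(h2$charges, c(0, 0))
  tsc <- assign_peoe_charges(fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "t"))
  expect_lt(abs(sum(tsc$charges)), 1e-3)
  moved <- assign_peoe_charges(rigid_move(fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "t"),
                                          theta = 1.1, shift = c(3, -2, 7)))
  expect_equal(moved$charges, tsc$charges)
  expect_error(assign_peoe_charges(make_mol("he", "He", matrix(0, 1, 3))),
               "He")
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  tsc <- fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "t")
  self <- align_to_template(tsc, "NC(=S)NN=C", tsc)
  expect_true(self$matched)
  expect_lt(self$rmsd, 1e-10)
  moved <- rigid_move(tsc, theta = 0.7, shift = c(1, 2, 3))
  back <- align_to_template(moved, "NC(=S)NN=C", tsc)
  expect_lt(back$rmsd, 1e-8)
  expect_lt(max(abs(coords(back$molecule) - coords(tsc))), 1e-6)
  # rigid alignment preserves intramolecular distances
  expect_equal(as.matrix(dist(coords(back$molecule))),
               as.matrix(dist(coords(moved))), tolerance = 1e-6)
})

test_that("molecules without the template core report no match, not an error", {
  res <- align_to_template(fixture_smiles_mol("CCO", "eth"), "NC(=S)NN=C",
                           fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "t"))
  expect_false(res$matched)
  expect_true(is.na(res$rmsd))
})

test_that("congener selection keeps low-RMSD matches and drops the rest", {
  ref <- fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "ref")
  distort <- function(m, eps, id) {
    set.seed(99)
    m$atoms[, c("x", "y", "z")] <- coords(m) + matrix(stats::rnorm(3 * n_atoms(m), 0, eps),
                                                      ncol = 3)
    m$id <- id
    m
  }
  mols <- list(ref,
               rigid_move(ref, 0.5, c(1, 0, 0)),
               distort(ref, 2.0, "bad1"),
               distort(ref, 2.5, "bad2"),
               fixture_smiles_mol("CCO", "nomatch"))
  kept <- select_congeners(mols, "NC(=S)NN=C", ref, rmsd_cutoff = 1.0)
  ids <- vapply(kept, function(a) a$molecule$id, character(1))
  expect_setequal(ids, c("ref", "ref"))
  expect_true(all(diff(vapply(kept, `[[`, numeric(1), "rmsd")) >= 0))
  expect_setequal(attr(kept, "excluded"), c("bad1", "bad2", "nomatch"))
  expect_error(select_congeners(list(fixture_smiles_mol("CCO", "x")),
                                "NC(=S)NN=C", ref, 1.0), "cutoff")
})

test_that("molecule invariants are enforced", {
  expect_error(make_mol("m", "C", matrix(c(0, 0, NA), 1, 3)), "finite")
  expect_error(molecule("m", data.frame(element = "C", x = 0, y = 0, z = 0,
                                        formal_charge = 0),
                        data.frame(i = 1, j = 2, order = 1)), "out of range")
  expect_error(make_mol("m", c("C", "H"), matrix(0, 2, 3),
                        charges = c(0.5, 0.4)), "formal charge")
})
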