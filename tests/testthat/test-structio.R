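test_that("read_structure parses the hand-written two-chain fixture", {
  path <- write_tiny_pdb()
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residue), 3)
  expect_equal(unique(m$atom$chain), c("A", "B"))
  ca <- m$atom[m$atom$name == "CA", ]
  expect_equal(ca$x, c(1.458, 3.800, 0.000))
  expect_equal(ca$y, c(0.000, 1.250, 5.000))
  expect_equal(ca$z, c(0.000, 0.000, 2.500))
  # author numbering preserved; ordinals contiguous
  expect_equal(m$residue$resid, c(590L, 591L, 10L))
  expect_equal(m$residue$ordinal, 1:3)
})

test_that("a C-alpha-only PDB is a valid model with one atom per residue", {
  path <- tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines[-2], path)  # drop the N atom
  m <- read_structure(path)
  expect_equal(nrow(m$atom), nrow(m$residue))
})

test_that("a PDB without atoms raises an empty-input error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "REMARK  2"), path)
  expect_error(read_structure(path), "empty|unparsable")
})

test_that("insertion codes are rejected and altlocs resolved by occupancy", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_structure(path), "insertion")

  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), path2)
  m <- read_structure(path2)
  expect_equal(nrow(m$atom), 2)
  expect_equal(m$atom$x[m$atom$resid == 1], 9.0)  # higher occupancy wins
})

test_that("write/read round-trips names, numbering, chains and coordinates", {
  spec <- ensemble_spec(n_residues_per_chain = 8, loop_bounds = c(562, 565),
                        n_frames = 2, seed = 3)
  m <- build_toy_reference(spec)
  path <- tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_equal(m2$atom$name, m$atom$name)
  expect_equal(m2$atom$resid, m$atom$resid)
  expect_equal(m2$atom$chain, m$atom$chain)
  expect_equal(coords(m2), coords(m), tolerance = 1e-3)
  expect_equal(m2$atom$het, m$atom$het)  # HETATM ligand survives
})

test_that("read_ensemble concatenates replicas with per-file labels", {
  spec <- ensemble_spec(n_residues_per_chain = 6, loop_bounds = c(561, 563),
                        n_frames = 10, seed = 5)
  topo <- build_toy_reference(spec)
  paths <- vapply(1:3, function(k) {
    e <- generate_ensemble(ensemble_spec(n_residues_per_chain = 6,
                                         loop_bounds = c(561, 563),
                                         n_frames = 10, seed = k))
    write_ensemble(e, tempfile(fileext = ".pdb"))
  }, "")
  ens <- read_ensemble(topo, paths, format = "pdb", system_name = "sys")
  expect_equal(n_frames(ens), 30)
  expect_equal(unique(ens$frames$replica), 1:3)
  expect_equal(ens$frames$frame[11], 1)  # frame numbering restarts per replica
  expect_equal(unique(ens$frames$system), "sys")

  # single-frame file
  one <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", distfluct:::.model_lines(topo), "ENDMDL", "END"), one)
  e1 <- read_ensemble(topo, one, format = "pdb")
  expect_equal(n_frames(e1), 1)

  # atom-count mismatch names the file
  small <- build_toy_reference(ensemble_spec(n_residues_per_chain = 5,
                                             loop_bounds = c(561, 563),
                                             n_frames = 2, seed = 1))
  bad <- tempfile(fileext = ".pdb")
  write_structure(small, bad)
  expect_error(read_ensemble(topo, c(paths[1], bad), format = "pdb"),
               "topology mismatch.*\\.pdb")
  expect_error(read_ensemble(topo, paths[1], format = "xtc"), "XTC")
})

test_that("concat_meta counts frames, keeps labels and is associative", {
  spec <- ensemble_spec(n_residues_per_chain = 6, loop_bounds = c(561, 563),
                        n_frames = 100, seed = 7)
  reps <- lapply(1:3, function(k)
    generate_ensemble(ensemble_spec(n_residues_per_chain = 6,
                                    loop_bounds = c(561, 563),
                                    n_frames = 100, seed = k)))
  meta <- concat_meta(reps)
  expect_equal(n_frames(meta), 300)
  ab_c <- concat_meta(list(concat_meta(reps[1:2]), reps[[3]]))
  a_bc <- concat_meta(list(reps[[1]], concat_meta(reps[2:3])))
  expect_identical(ab_c$xyz, a_bc$xyz)
  # identity
  expect_identical(concat_meta(list(reps[[1]]))$xyz, reps[[1]]$xyz)
  # topology mismatch
  other <- generate_ensemble(ensemble_spec(n_residues_per_chain = 7,
                                           loop_bounds = c(561, 563),
                                           n_frames = 10, seed = 1))
  expect_error(concat_meta(list(reps[[1]], other)), "topology mismatch")
})

test_that("selection grammar honors author numbering, and/or and edge cases", {
  spec <- ensemble_spec(n_residues_per_chain = 31, first_resid = 585,
                        loop_bounds = c(590, 610), n_frames = 2, seed = 1)
  m <- build_toy_reference(spec)  # chains A,B residues 585-615 + ligand
  s <- select_atoms(m, "chain A and resid 590-610 and name CA")
  expect_equal(length(s$atom_idx), 21)  # inclusive on both ends
  expect_equal(length(select_atoms(m, "name CA")$atom_idx), 62)
  s_or <- select_atoms(m, "chain A and resid 590 or chain B and resid 590")
  expect_equal(length(s_or$atom_idx), 2)
  expect_warning(s0 <- select_atoms(m, "resid 9999"), "matches no atoms")
  expect_equal(length(s0$atom_idx), 0)
  expect_error(select_atoms(m, "chian A"), "parse error")
  expect_error(select_atoms(m, "chain"), "needs an argument")
  # idempotent
  expect_identical(select_atoms(m, "name CA")$atom_idx,
                   select_atoms(m, "name CA")$atom_idx)
})

test_that("unknown elements fall back to a 1.5 A radius with a warning", {
  at <- data.frame(serial = 1:2, name = c("CA", "XX"), element = c("C", "XQ"),
                   resname = "ALA", resid = 1:2, chain = "A",
                   x = c(0, 5), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_warning(m <- structure_model(at), "unknown element")
  expect_equal(m$atom$vdw_radius, c(1.70, 1.5))
})
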