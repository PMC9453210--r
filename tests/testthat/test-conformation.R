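test_that("superposition recovers exact rigid transforms", {
  set.seed(31)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  sp0 <- superpose(ref, ref)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sp0$fit_rmsd, 0, tolerance = 1e-10)

  rot <- rotation_about_z(pi / 2)
  shift <- c(10, -3, 7)
  mob <- rigid_transform(ref, rot, shift)
  sp <- superpose(mob, ref)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
  # recovered transform inverts the applied one
  expect_equal(sp$rotation, t(rot), tolerance = 1e-9)
  expect_equal(apply_superposition(sp, mob), ref, tolerance = 1e-9)
})

test_that("superposition matches the numerical-minimization oracle", {
  # 4-point toy with one point displaced off the rigid fit
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mob <- base
  mob[4, ] <- mob[4, ] + c(1, 0, 0)
  mob <- rigid_transform(mob, rotation_about_z(0.7), c(5, 5, 5))
  sp <- superpose(mob, base)
  expect_equal(sp$fit_rmsd, numeric_fit_rmsd(mob, base), tolerance = 1e-6)
})

test_that("fitted RMSD is symmetric in its arguments", {
  set.seed(32)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(a, b)$fit_rmsd, superpose(b, a)$fit_rmsd,
               tolerance = 1e-9)
})

test_that("superposition rejects degenerate geometry", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(0:4, 0, 0)
  expect_error(superpose(line + rnorm(15, sd = 1e-12), line), "collinear")
})

test_that("rmsd_series isolates loop displacement from the fitted frame", {
  spec <- ensemble_spec(n_residues_per_chain = 20, first_resid = 1,
                        loop_bounds = c(8, 12), n_frames = 2, seed = 1)
  ref <- build_toy_reference(spec)
  base <- coords(ref)
  loop_idx <- which(ref$atom$chain == "A" & ref$atom$resid %in% 8:12)
  fit_idx <- setdiff(which(ref$atom$chain == "A"), loop_idx)
  # frames: reference itself, then loop rigidly displaced by 5 A
  disp <- base
  disp[loop_idx, 1] <- disp[loop_idx, 1] + 5
  e <- ensemble_from_coords(ref, list(base, rigid_transform(disp,
                                                            rotation_about_z(1),
                                                            c(3, -2, 8))))
  fit_sel <- selection_from_indices(ref, fit_idx)
  loop_sel <- selection_from_indices(ref, loop_idx)
  rs <- rmsd_series(e, ref, fit_sel, loop_sel)
  expect_equal(rs$values[1], 0, tolerance = 1e-9)
  expect_equal(rs$values[2], 5, tolerance = 1e-6)
  # measure == fit reproduces the per-frame fit RMSD (zero for rigid copies)
  rs_fit <- rmsd_series(e, ref, fit_sel, fit_sel)
  expect_equal(rs_fit$values, c(0, 0), tolerance = 1e-9)
})

test_that("state classification applies the 3 A threshold with <= closed", {
  st <- classify_states(c(1.0, 4.0, 2.9, 3.1), threshold = 3.0)
  expect_equal(as.character(st$labels), c("closed", "open", "closed", "open"))
  expect_equal(st$occupancy_open, 0.5)
  expect_equal(as.character(classify_states(3.0)$labels), "closed")  # boundary
  expect_equal(classify_states(rep(0, 10))$occupancy_closed, 1.0)
  expect_error(classify_states(numeric(0)), "empty")
  expect_error(classify_states(c(1, 2), threshold = -1), "threshold")
})

test_that("site selection honors the distance cutoff and is monotone", {
  at <- data.frame(
    serial = 1:3, name = c("O1", "CA", "CA"), element = c("O", "C", "C"),
    resname = c("LIG", "ALA", "ALA"), resid = c(901L, 1L, 2L),
    chain = c("L", "A", "A"),
    x = c(0, 5.9, 6.01), y = 0, z = 0,
    het = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  m <- structure_model(at)
  lig <- select_atoms(m, "chain L")
  s6 <- site_selection(m, lig, 6.0)
  res6 <- m$atom$resid[s6$atom_idx]
  expect_true(1 %in% res6)
  expect_false(2 %in% res6)
  expect_warning(s0 <- site_selection(m, lig, 0), "empty")
  expect_equal(length(s0$atom_idx), 0)
  s7 <- site_selection(m, lig, 7.0)
  expect_true(all(s6$atom_idx %in% s7$atom_idx))  # enlarging never removes
  expect_error(site_selection(m, s0, 6.0), "empty ligand")
})

test_that("single-sphere SASA matches the closed form within quadrature error", {
  at <- data.frame(serial = 1L, name = "CA", element = "C", resname = "ALA",
                   resid = 1L, chain = "A", x = 0, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  m <- structure_model(at)  # carbon: r = 1.7 A
  s <- sasa_atoms(m, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(s, 4 * pi * 3.1^2, tolerance = 0.02)
  # spiral quadrature with no occluders is exact for the full sphere
  expect_equal(s, 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("SASA is additive at infinite separation and zero when buried", {
  at2 <- data.frame(serial = 1:2, name = "CA", element = "C", resname = "ALA",
                    resid = 1:2, chain = "A", x = c(0, 100), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  s2 <- sasa_atoms(structure_model(at2))
  expect_equal(sum(s2), 2 * 4 * pi * 3.1^2, tolerance = 1e-9)

  # central atom enclosed by a dense shell of neighbors
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  shell <- sweep(dirs / sqrt(rowSums(dirs^2)), 1, rep(2.0, nrow(dirs)), `*`)
  at_shell <- data.frame(
    serial = seq_len(nrow(shell) + 1), name = "S",
    element = "S", resname = "ALA", resid = seq_len(nrow(shell) + 1),
    chain = "A",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    stringsAsFactors = FALSE)
  s_shell <- sasa_atoms(structure_model(at_shell))
  expect_equal(s_shell[1], 0)
})

test_that("SASA decreases monotonically as a second atom approaches", {
  seps <- seq(20, 2, length.out = 10)
  vals <- vapply(seps, function(d) {
    at <- data.frame(serial = 1:2, name = "CA", element = "C", resname = "ALA",
                     resid = 1:2, chain = "A", x = c(0, d), y = 0, z = 0,
                     stringsAsFactors = FALSE)
    sasa_atoms(structure_model(at))[1]
  }, 0)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("per-frame site SASA separates open from closed loop states", {
  spec <- ensemble_spec(n_residues_per_chain = 20, n_frames = 60, seed = 41,
                        first_resid = 560, loop_bounds = c(566, 572),
                        p_open = 0.5, background_sigma = 0.05,
                        loop_sigma_closed = 0.05, loop_sigma_open = 0.05)
  e <- generate_ensemble(spec)
  ref <- build_toy_reference(spec)
  site <- site_selection(ref, select_atoms(ref, "chain L"), 6.0)
  ss <- sasa_series(e, site)
  st <- true_states(e)$state_A
  expect_setequal(unique(st), c("open", "closed"))
  expect_gt(median(ss$values[st == "open"]), median(ss$values[st == "closed"]))
})
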