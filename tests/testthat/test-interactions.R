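# two-residue toys at controlled separations, plus a hand-built all-atom
# arginine-like donor + carboxylate-like acceptor for the hydrogen-bond tests

two_residue_model <- function(d, chains = c("A", "B")) {
  structure_model(data.frame(
    serial = 1:2, name = "CA", element = "C", resname = "ALA",
    resid = c(10L, 50L), chain = chains, x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

# donor residue: N-H pointing at the acceptor oxygen along +x
hbond_model <- function(n_o_dist = 2.9, resid_a = 599L) {
  structure_model(data.frame(
    serial = 1:5,
    name = c("CA", "NH1", "HH11", "C1", "O1"),
    element = c("C", "N", "H", "C", "O"),
    resname = c("ARG", "ARG", "ARG", "LIG", "LIG"),
    resid = c(resid_a, resid_a, resid_a, 901L, 901L),
    chain = c("A", "A", "A", "L", "L"),
    x = c(-1.5, 0, 1.0, n_o_dist + 1.3, n_o_dist),
    y = 0, z = 0,
    het = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

test_that("native contacts follow the heavy-atom cutoff and sequence rule", {
  m_in <- two_residue_model(4.4)
  m_out <- two_residue_model(4.6)
  region <- function(m) select_atoms(m, "resid 10")
  expect_equal(nrow(native_contacts(m_in, region(m_in), cutoff = 4.5)), 1)
  expect_equal(nrow(native_contacts(m_out, region(m_out), cutoff = 4.5)), 0)

  # same-chain neighbors i, i+2 at 3 A excluded by min_seq_sep = 3
  m_seq <- structure_model(data.frame(
    serial = 1:3, name = "CA", element = "C", resname = "ALA",
    resid = 10:12, chain = "A", x = c(0, 1.5, 3), y = 0, z = 0,
    stringsAsFactors = FALSE))
  expect_equal(nrow(native_contacts(m_seq, select_atoms(m_seq, "resid 10"),
                                    cutoff = 4.5, min_seq_sep = 3)), 0)
  # inter-chain pair at 4.0 A included regardless of ordinals
  m_ic <- two_residue_model(4.0)
  expect_equal(nrow(native_contacts(m_ic, region(m_ic), cutoff = 4.5,
                                    min_seq_sep = 3)), 1)
  expect_error(native_contacts(m_ic, select_atoms(m_ic, "name CA and chain Q")),
               "empty region") |> suppressWarnings()
})

test_that("contact persistence counts formed frames and classifies tiers", {
  m <- two_residue_model(4.0)
  frames <- lapply(c(rep(4.0, 7), rep(6.0, 3)), function(d)
    rbind(c(0, 0, 0), c(d, 0, 0)))
  e <- ensemble_from_coords(m, frames)
  ct <- native_contacts(m, select_atoms(m, "resid 10"))
  pr <- contact_persistence(e, ct, cutoff = 4.5)
  expect_equal(pr$persistence, 0.7)
  expect_equal(pr$classification, "maintained")

  e_never <- ensemble_from_coords(m, lapply(rep(9, 5), function(d)
    rbind(c(0, 0, 0), c(d, 0, 0))))
  pr0 <- contact_persistence(e_never, ct)
  expect_equal(pr0$persistence, 0)
  expect_equal(pr0$classification, "lost")
})

test_that("native contacts of a 1-frame reference trajectory persist exactly", {
  spec <- ensemble_spec(n_residues_per_chain = 15, n_frames = 2, seed = 5,
                        first_resid = 560, loop_bounds = c(563, 568))
  ref <- build_toy_reference(spec)
  nat <- native_contacts(ref, select_atoms(ref, "chain A and resid 563-568"))
  expect_gt(nrow(nat), 0)
  e1 <- ensemble_from_coords(ref, list(coords(ref)))
  pr <- contact_persistence(e1, nat)
  expect_true(all(pr$persistence == 1.0))
})

test_that("persistence is monotone in the distance cutoff", {
  spec <- ensemble_spec(n_residues_per_chain = 15, n_frames = 100, seed = 6,
                        first_resid = 560, loop_bounds = c(563, 568),
                        p_open = 0.3)
  ref <- build_toy_reference(spec)
  e <- generate_ensemble(spec)
  nat <- native_contacts(ref, select_atoms(ref, "chain A and resid 563-568"),
                         cutoff = 5.0)
  p40 <- contact_persistence(e, nat, cutoff = 4.0)$persistence
  p45 <- contact_persistence(e, nat, cutoff = 4.5)$persistence
  p50 <- contact_persistence(e, nat, cutoff = 5.0)$persistence
  expect_true(all(p40 <= p45 + 1e-12))
  expect_true(all(p45 <= p50 + 1e-12))
})

test_that("new stable contacts are disjoint from native ones and thresholded", {
  # reference: residues 8 A apart (no native contact); trajectory mostly close
  m <- two_residue_model(8.0)
  region <- select_atoms(m, "resid 10")
  mk <- function(fracs) ensemble_from_coords(m, lapply(fracs, function(d)
    rbind(c(0, 0, 0), c(d, 0, 0))))
  e80 <- mk(c(rep(4.0, 8), rep(8.0, 2)))
  ns <- new_stable_contacts(e80, m, region, steady_threshold = 0.5)
  expect_equal(nrow(ns), 1)
  expect_equal(ns$persistence, 0.8)
  expect_equal(nrow(native_contacts(m, region)), 0)  # disjoint by construction

  e30 <- mk(c(rep(4.0, 3), rep(8.0, 7)))
  expect_equal(nrow(new_stable_contacts(e30, m, region,
                                        steady_threshold = 0.5)), 0)
  expect_equal(nrow(new_stable_contacts(e30, m, region,
                                        steady_threshold = 0.25)), 1)
})

test_that("the locked synthetic loop gains inter-chain contacts the reference lacks", {
  spec <- ensemble_spec(n_residues_per_chain = 20, n_frames = 150, seed = 7,
                        first_resid = 560, loop_bounds = c(566, 572),
                        p_open = 0.02,
                        closed_displacement = c(7.2, 0, 0))  # hug chain B
  ref <- build_toy_reference(spec)  # neutral loop: far from chain B
  e <- generate_ensemble(spec)
  region <- select_atoms(ref, "chain A and resid 566-572")
  ns <- new_stable_contacts(e, ref, region)
  expect_gt(nrow(ns), 0)
  expect_true(any(ns$chain_a == "A" & ns$chain_b == "B"))
})

test_that("hydrogen bonds use distance + angle when hydrogens exist", {
  m <- hbond_model(n_o_dist = 2.9)  # collinear N-H...O at 180 degrees
  e <- ensemble_from_coords(m, list(coords(m)))
  don <- select_atoms(m, "resid 599")
  acc <- select_atoms(m, "chain L")
  hb <- hbond_series(e, don, acc)
  expect_false(hb$fallback)
  expect_equal(hb$fraction_formed, 1.0)

  m_far <- hbond_model(n_o_dist = 3.6)  # beyond the 3.5 A cutoff
  e_far <- ensemble_from_coords(m_far, list(coords(m_far)))
  expect_equal(hbond_series(e_far, select_atoms(m_far, "resid 599"),
                            select_atoms(m_far, "chain L"))$fraction_formed, 0)

  # 10-frame toy, bond present in 9
  frames <- c(lapply(rep(2.9, 9), function(d) coords(hbond_model(d))),
              lapply(5.5, function(d) coords(hbond_model(d))))
  e10 <- ensemble_from_coords(m, frames)
  expect_equal(hbond_series(e10, don, acc)$fraction_formed, 0.9)
})

test_that("angle criterion vetoes bent donor-H-acceptor geometries", {
  # acceptor placed behind the hydrogen: short N-O but angle near 0
  m <- structure_model(data.frame(
    serial = 1:4,
    name = c("NH1", "HH11", "C1", "O1"),
    element = c("N", "H", "C", "O"),
    resname = c("ARG", "ARG", "LIG", "LIG"),
    resid = c(599L, 599L, 901L, 901L),
    chain = c("A", "A", "L", "L"),
    x = c(0, 1.0, -1.6, -2.6), y = c(0, 0, 1.5, 1.5), z = 0,
    het = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE))
  e <- ensemble_from_coords(m, list(coords(m)))
  hb <- hbond_series(e, select_atoms(m, "resid 599"),
                     select_atoms(m, "chain L"), dist_cutoff = 3.5)
  expect_false(hb$fallback)
  expect_equal(hb$fraction_formed, 0)
})

test_that("hydrogen-free topologies fall back to the N-O salt-bridge rule", {
  m <- structure_model(data.frame(
    serial = 1:3,
    name = c("NH1", "C1", "O1"),
    element = c("N", "C", "O"),
    resname = c("ARG", "LIG", "LIG"),
    resid = c(599L, 901L, 901L),
    chain = c("A", "L", "L"),
    x = c(0, 5.1, 3.8), y = 0, z = 0,
    het = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE))
  e <- ensemble_from_coords(m, list(coords(m)))
  hb <- hbond_series(e, select_atoms(m, "resid 599"), select_atoms(m, "chain L"))
  expect_true(hb$fallback)
  expect_equal(hb$fraction_formed, 1.0)  # N-O 3.8 <= 4.0
  expect_equal(hb$criteria$dist_cutoff, 4.0)
})

test_that("C-alpha-only topologies raise a chemistry error", {
  spec <- ensemble_spec(n_residues_per_chain = 10, n_frames = 5, seed = 1,
                        loop_bounds = c(562, 565))
  e <- generate_ensemble(spec)
  don <- select_atoms(e$topology, "chain A and resid 561")
  acc <- select_atoms(e$topology, "chain L")
  expect_error(hbond_series(e, don, acc), "chemistry error")
})
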