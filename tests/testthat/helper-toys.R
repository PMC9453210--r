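# Fixtures are built in code: small structure models, ensembles assembled
# from explicit coordinate lists, rigid transforms, and a numerical
# superposition oracle independent of the Kabsch implementation.

# hand-written 3-residue, 2-chain PDB fixture (known coordinates)
tiny_pdb_lines <- c(
  "HEADER    TOY FIXTURE",
  "ATOM      1  N   ALA A 590       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A 590       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  GLY A 591       3.800   1.250   0.000  1.00  0.00           C",
  "ATOM      4  CA  SER B  10       0.000   5.000   2.500  1.00  0.00           C",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines, path)
  path
}

# straight-line C-alpha chain: n residues spaced `spacing` A along x
linear_model <- function(n, spacing = 10, chain = "A", first_resid = 1L) {
  structure_model(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resid = seq(first_resid, length.out = n), chain = chain,
    x = spacing * (seq_len(n) - 1), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

# ensemble from an explicit list of n_atoms x 3 coordinate matrices
ensemble_from_coords <- function(topology, coord_list, system = "toy",
                                 replica = 1L) {
  xyz <- do.call(rbind, lapply(coord_list, function(m) as.vector(t(m))))
  distfluct:::.new_ensemble(
    topology, xyz,
    data.frame(system = system, replica = replica,
               frame = seq_along(coord_list), stringsAsFactors = FALSE))
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(coords, rot = diag(3), shift = c(0, 0, 0)) {
  sweep(coords %*% t(rot), 2, shift, `+`)
}

# apply an independent random rigid transform to every frame
transform_ensemble_frames <- function(ensemble) {
  n_at <- nrow(ensemble$topology$atom)
  xyz <- ensemble$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m <- rigid_transform(m, random_rotation(), rnorm(3, sd = 20))
    xyz[f, ] <- as.vector(t(m))
  }
  distfluct:::.new_ensemble(ensemble$topology, xyz, ensemble$frames)
}

# brute-force pooled population variance of each pair's distance series
pooled_df_oracle <- function(ensemble, selection) {
  ds <- pairwise_distance_series(ensemble, selection)
  v <- apply(ds$values, 2, function(x) mean((x - mean(x))^2))
  n <- nrow(ds$residues)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

# independent numerical superposition oracle: optimal translation aligns the
# centroids; the rotation is found by multi-start quasi-Newton minimization
# over Euler angles
numeric_fit_rmsd <- function(mobile, reference) {
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(reference, 2, colMeans(reference))
  msd <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cc <- cos(par[3]); sc <- sin(par[3])
    rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cc, -sc, 0, sc, cc), 3, byrow = TRUE)
    mean(rowSums((pm %*% t(rz %*% ry %*% rx) - pr)^2))
  }
  starts <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
                 c(pi, 0, 0), c(0, pi, 0), c(pi / 4, pi / 4, pi / 4),
                 c(-pi / 2, pi / 3, 0.3), c(2, 1, -1), c(-2.5, 0.7, 1.9))
  best <- Inf
  for (s in starts) {
    r <- optim(s, msd, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
    best <- min(best, r$value)
  }
  sqrt(best)
}
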