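## conformation: rigid-body superposition (Kabsch), loop RMSD series,
## closed/open state classification, catalytic-site shell selection and
## per-frame Shrake-Rupley SASA.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over proper rotations and
#' translations, via SVD of the weighted covariance matrix with the usual
#' determinant sign correction, so the returned rotation is always proper
#' (det = +1, no reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3, not collinear)
#' @param weights optional per-atom weights (non-negative, not all zero)
#' @return a `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length-3, A) and `fit_rmsd` (A). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (see [apply_superposition()]).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("geometry error: coordinate sets differ in size")
  if (n < 3) stop("geometry error: need at least 3 atoms to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("geometry error: bad weights")
  w <- weights / sum(weights)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(reference * w)
  pm <- sweep(mobile, 2, cm_m)
  pr <- sweep(reference, 2, cm_r)
  if (svd(pr * sqrt(w))$d[2] < 1e-8)
    stop("geometry error: reference atoms are (near-)collinear")
  h <- t(pm * w) %*% pr
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot_row <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)  # applied as x %*% rot_row
  rotation <- t(rot_row)
  translation <- as.vector(cm_r - rotation %*% cm_m)
  fitted <- pm %*% rot_row
  fit_rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  structure(list(rotation = rotation, translation = translation,
                 fit_rmsd = fit_rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `superposition`
#' @param x n x 3 coordinate matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sp, x) {
  sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: fit_rmsd", signif(x$fit_rmsd, 6), "A\n")
  invisible(x)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is rigid-body superposed onto the reference over
#' `fit_selection` (typically backbone atoms outside the mobile segment, so
#' segment motion does not bias the frame of reference), then the RMSD over
#' `measure_selection` is taken in that fitted frame without refitting.
#'
#' @param ensemble an `ensemble`
#' @param reference a `structure_model`; its atoms are matched to the
#'   ensemble topology by (chain, resid, name)
#' @param fit_selection,measure_selection `atom_selection`s on the ensemble
#'   topology
#' @return an `rmsd_series`: list with `values` (A, one per frame), `frames`,
#'   `fit_expression`, `measure_expression`
#' @export
rmsd_series <- function(ensemble, reference, fit_selection, measure_selection) {
  topo <- ensemble$topology
  fit_ref_idx <- .match_selection(fit_selection, topo, reference)
  mea_ref_idx <- .match_selection(measure_selection, topo, reference)
  ref_xyz <- coords(reference)
  ref_fit <- ref_xyz[fit_ref_idx, , drop = FALSE]
  ref_mea <- ref_xyz[mea_ref_idx, , drop = FALSE]
  nf <- n_frames(ensemble)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    mob_fit <- .frame_coords(ensemble, fit_selection$atom_idx, f)
    mob_mea <- .frame_coords(ensemble, measure_selection$atom_idx, f)
    sp <- superpose(mob_fit, ref_fit)
    vals[f] <- .rmsd(apply_superposition(sp, mob_mea), ref_mea)
  }
  structure(list(values = vals, frames = ensemble$frames,
                 fit_expression = fit_selection$expression,
                 measure_expression = measure_selection$expression),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("rmsd_series:", length(x$values), "frames; mean",
      signif(mean(x$values), 4), "A, max", signif(max(x$values), 4), "A\n")
  invisible(x)
}

#' Classify frames into closed/open states by an RMSD threshold
#'
#' Frames with RMSD at or below the threshold are labeled `closed`, above it
#' `open` (the boundary value itself counts as closed). The 3 A default
#' separates the closed from the open gate-loop conformation.
#'
#' @param series an `rmsd_series` (or bare numeric vector of RMSDs, A)
#' @param threshold RMSD threshold in A (> 0), default 3.0
#' @return a `state_series`: list with `labels` (factor closed/open),
#'   `threshold`, `occupancy_closed`, `occupancy_open`, `frames`
#' @export
classify_states <- function(series, threshold = 3.0) {
  if (threshold <= 0) stop("parameter error: threshold must be > 0")
  vals <- if (inherits(series, "rmsd_series")) series$values else as.numeric(series)
  if (length(vals) == 0) stop("empty input: no RMSD values to classify")
  labels <- factor(ifelse(vals <= threshold, "closed", "open"),
                   levels = c("closed", "open"))
  occ <- as.vector(table(labels)) / length(labels)
  structure(list(labels = labels, threshold = threshold,
                 occupancy_closed = occ[1], occupancy_open = occ[2],
                 frames = if (inherits(series, "rmsd_series")) series$frames else NULL),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("state_series: threshold", x$threshold, "A;",
      "closed", signif(x$occupancy_closed, 4), "/ open",
      signif(x$occupancy_open, 4), "\n")
  invisible(x)
}

#' Catalytic-site shell selection around a ligand
#'
#' All residues with at least one heavy atom within `cutoff` of any ligand
#' heavy atom, computed once on the given (reference) structure and then held
#' fixed for the whole ensemble, so the residue set is identical across
#' systems. The ligand's own residues are excluded; the returned selection
#' covers all atoms of the qualifying residues.
#'
#' @param structure a `structure_model`
#' @param ligand_selection non-empty `atom_selection` of ligand atoms
#' @param cutoff shell radius in A, default 6.0
#' @return an `atom_selection`; empty with a warning when nothing qualifies
#' @export
site_selection <- function(structure, ligand_selection, cutoff = 6.0) {
  if (length(ligand_selection$atom_idx) == 0)
    stop("parameter error: empty ligand selection")
  at <- structure$atom
  heavy <- toupper(at$element) != "H"
  lig_idx <- intersect(ligand_selection$atom_idx, which(heavy))
  lig_ord <- unique(at$ordinal[ligand_selection$atom_idx])
  prot_idx <- which(heavy & !(at$ordinal %in% lig_ord))
  xyz <- coords(structure)
  keep_ord <- integer()
  if (cutoff > 0 && length(prot_idx) > 0) {
    d2 <- outer(rowSums(xyz[prot_idx, , drop = FALSE]^2),
                rowSums(xyz[lig_idx, , drop = FALSE]^2), `+`) -
      2 * xyz[prot_idx, , drop = FALSE] %*% t(xyz[lig_idx, , drop = FALSE])
    near <- apply(d2, 1, min) <= cutoff^2 + 1e-12
    keep_ord <- unique(at$ordinal[prot_idx[near]])
  }
  idx <- which(at$ordinal %in% keep_ord)
  if (length(idx) == 0)
    warning("site selection is empty at cutoff ", cutoff, " A", call. = FALSE)
  selection_from_indices(structure, idx,
                         sprintf("<residues within %g A of %s>", cutoff,
                                 ligand_selection$expression))
}

#' Per-frame solvent-accessible surface area of a site selection
#'
#' Shrake-Rupley SASA computed per frame over ALL atoms of the topology
#' (protein plus ligand context), then summed over the atoms of `site`.
#' Sphere quadrature uses a deterministic golden-section spiral.
#'
#' @param ensemble an `ensemble`
#' @param site an `atom_selection` whose per-atom SASA is summed
#' @param probe_radius solvent probe radius in A, default 1.4
#' @param n_sphere_points quadrature points per atom, default 960
#' @return a `sasa_series`: list with `values` (A^2 per frame),
#'   `probe_radius`, `n_sphere_points`, `site_residues`, `frames`
#' @export
sasa_series <- function(ensemble, site, probe_radius = 1.4,
                        n_sphere_points = 960L) {
  at <- ensemble$topology$atom
  radii <- at$vdw_radius
  if (anyNA(radii) || any(radii <= 0)) {
    bad <- which(is.na(radii) | radii <= 0)[1]
    stop("radius error: atom ", at$serial[bad], " (", at$name[bad],
         ") has no usable vdW radius")
  }
  if (length(site$atom_idx) == 0) stop("parameter error: empty site selection")
  vals <- sasa_site_series_cpp(ensemble$xyz, radii, probe_radius,
                               as.integer(n_sphere_points),
                               site$atom_idx - 1L)
  site_res <- .residue_info(ensemble$topology, site$residue_ord)
  structure(list(values = vals, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 site_residues = site_res, frames = ensemble$frames),
            class = "sasa_series")
}

#' Per-atom Shrake-Rupley SASA of a single structure
#'
#' @param model a `structure_model`
#' @param probe_radius probe radius in A
#' @param n_sphere_points quadrature points per atom
#' @return numeric vector, one SASA value (A^2) per atom
#' @export
sasa_atoms <- function(model, probe_radius = 1.4, n_sphere_points = 960L) {
  sasa_atoms_cpp(coords(model), model$atom$vdw_radius, probe_radius,
                 as.integer(n_sphere_points))
}

#' @export
print.sasa_series <- function(x, ...) {
  cat("sasa_series:", length(x$values), "frames over",
      nrow(x$site_residues), "site residues; median",
      signif(median(x$values), 5), "A^2\n")
  invisible(x)
}

#' Write a per-frame series (RMSD, state or SASA) as a tab-delimited table
#' @param x an `rmsd_series`, `state_series` or `sasa_series`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# distfluct %s %s", packageVersion("distfluct"), class(x)[1])
  if (inherits(x, "rmsd_series")) {
    writeLines(c(hdr, sprintf("# fit=%s measure=%s (A)", x$fit_expression,
                              x$measure_expression)), con)
    tab <- cbind(x$frames, rmsd = x$values)
  } else if (inherits(x, "state_series")) {
    writeLines(c(hdr, sprintf("# threshold=%g A occupancy_closed=%g occupancy_open=%g",
                              x$threshold, x$occupancy_closed, x$occupancy_open)), con)
    tab <- data.frame(state = as.character(x$labels))
    if (!is.null(x$frames)) tab <- cbind(x$frames, tab)
  } else if (inherits(x, "sasa_series")) {
    writeLines(c(hdr, sprintf("# probe=%g A points=%d site_residues=%s (A^2)",
                              x$probe_radius, x$n_sphere_points,
                              paste(x$site_residues$resid, collapse = ","))), con)
    tab <- cbind(x$frames, sasa = x$values)
  } else stop("unsupported series class")
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
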