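## interactions: native-contact persistence, detection of new steady contacts,
## and hydrogen-bond/salt-bridge tracking between a loop residue and a ligand.
##
## A contact is a residue pair whose minimum heavy-atom distance is at or
## below a cutoff (default 4.5 A, the common MD convention); same-chain pairs
## closer than `min_seq_sep` in sequence are excluded as trivially bonded.

.heavy_atoms_by_residue <- function(model) {
  at <- model$atom
  heavy <- which(toupper(at$element) != "H")
  split(heavy, at$ordinal[heavy])
}

## min distance between two atom-index sets in an n x 3 coordinate matrix
.min_dist <- function(xyz, ia, ib) {
  a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

#' Native contacts of a region in a reference structure
#'
#' Residue pairs with one member inside `region` and the partner anywhere in
#' the structure whose minimum heavy-atom distance in the reference is at or
#' below `cutoff`. Same-chain pairs with sequence separation below
#' `min_seq_sep` are excluded; inter-chain pairs are always eligible.
#'
#' @param reference a `structure_model`
#' @param region non-empty `atom_selection` (e.g. the gate loop)
#' @param cutoff heavy-atom distance cutoff in A, default 4.5
#' @param min_seq_sep minimum same-chain ordinal separation, default 3
#' @return a `contact_set` data frame: `chain_a`, `resid_a`, `chain_b`,
#'   `resid_b`, `ord_a`, `ord_b`, `ref_distance` (A), with `ord_a < ord_b`
#' @export
native_contacts <- function(reference, region, cutoff = 4.5, min_seq_sep = 3) {
  if (length(region$atom_idx) == 0) stop("parameter error: empty region selection")
  res <- reference$residue
  by_res <- .heavy_atoms_by_residue(reference)
  xyz <- coords(reference)
  region_ord <- region$residue_ord
  all_ord <- res$ordinal
  out <- list()
  for (a in region_ord) {
    ia <- by_res[[as.character(a)]]
    if (is.null(ia)) next
    for (b in all_ord) {
      if (b <= a && b %in% region_ord) next  # each unordered pair once
      if (b == a) next
      same_chain <- res$chain[match(a, all_ord)] == res$chain[match(b, all_ord)]
      if (same_chain && abs(a - b) < min_seq_sep) next
      ib <- by_res[[as.character(b)]]
      if (is.null(ib)) next
      d <- .min_dist(xyz, ia, ib)
      if (d <= cutoff) {
        lo <- min(a, b); hi <- max(a, b)
        out[[length(out) + 1]] <- data.frame(
          chain_a = res$chain[match(lo, all_ord)], resid_a = res$resid[match(lo, all_ord)],
          chain_b = res$chain[match(hi, all_ord)], resid_b = res$resid[match(hi, all_ord)],
          ord_a = lo, ord_b = hi, ref_distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(out) == 0) {
    data.frame(chain_a = character(), resid_a = integer(), chain_b = character(),
               resid_b = integer(), ord_a = integer(), ord_b = integer(),
               ref_distance = numeric(), stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, out))
  }
  rownames(tab) <- NULL
  class(tab) <- c("contact_set", "data.frame")
  tab
}

## per-contact fraction of frames with min heavy-atom distance <= cutoff
.contact_fractions <- function(ensemble, contacts, cutoff) {
  topo <- ensemble$topology
  by_res <- .heavy_atoms_by_residue(topo)
  nf <- n_frames(ensemble)
  sapply(seq_len(nrow(contacts)), function(k) {
    ia <- by_res[[as.character(contacts$ord_a[k])]]
    ib <- by_res[[as.character(contacts$ord_b[k])]]
    ## distance series over all frames, vectorized over atom pairs
    md2 <- rep(Inf, nf)
    for (i in ia) for (j in ib) {
      dx <- ensemble$xyz[, 3 * i - 2] - ensemble$xyz[, 3 * j - 2]
      dy <- ensemble$xyz[, 3 * i - 1] - ensemble$xyz[, 3 * j - 1]
      dz <- ensemble$xyz[, 3 * i] - ensemble$xyz[, 3 * j]
      md2 <- pmin(md2, dx * dx + dy * dy + dz * dz)
    }
    mean(md2 <= cutoff^2)
  })
}

#' Persistence of contacts over an ensemble
#'
#' For each contact, the fraction of frames in which the pair's minimum
#' heavy-atom distance is at or below `cutoff`. Contacts are classified as
#' `maintained` (persistence >= `maintained_threshold`), `weakened`
#' (in [0.1, threshold)) or `lost` (< 0.1).
#'
#' @param ensemble an `ensemble`
#' @param contacts a `contact_set` from [native_contacts()]
#' @param cutoff heavy-atom distance cutoff in A, default 4.5
#' @param maintained_threshold persistence threshold for `maintained`,
#'   default 0.5
#' @return a `persistence_report` data frame: the contacts plus `persistence`
#'   and `classification`
#' @export
contact_persistence <- function(ensemble, contacts, cutoff = 4.5,
                                maintained_threshold = 0.5) {
  if (nrow(contacts) == 0) stop("parameter error: empty contact set")
  pers <- .contact_fractions(ensemble, contacts, cutoff)
  cls <- ifelse(pers >= maintained_threshold, "maintained",
                ifelse(pers >= 0.1, "weakened", "lost"))
  out <- cbind(as.data.frame(contacts), persistence = pers, classification = cls)
  class(out) <- c("persistence_report", "data.frame")
  out
}

#' New steady contacts formed during an ensemble
#'
#' Residue pairs (one member in `region`, partner anywhere) that are NOT
#' contacts in the reference structure but are formed in at least
#' `steady_threshold` of frames. Disjoint from [native_contacts()] by
#' construction.
#'
#' @param ensemble an `ensemble`
#' @param reference a `structure_model` (defines the native contact set)
#' @param region non-empty `atom_selection`
#' @param cutoff heavy-atom distance cutoff in A, default 4.5
#' @param steady_threshold minimum formed-frame fraction, default 0.5
#' @param min_seq_sep minimum same-chain ordinal separation, default 3
#' @return data frame of new contacts with their `persistence`
#' @export
new_stable_contacts <- function(ensemble, reference, region, cutoff = 4.5,
                                steady_threshold = 0.5, min_seq_sep = 3) {
  if (length(region$atom_idx) == 0) stop("parameter error: empty region selection")
  topo <- ensemble$topology
  res <- topo$residue
  native <- native_contacts(reference, region, cutoff = cutoff,
                            min_seq_sep = min_seq_sep)
  native_key <- paste(native$ord_a, native$ord_b)
  region_ord <- region$residue_ord
  cand <- list()
  for (a in region_ord) {
    for (b in res$ordinal) {
      if (b == a) next
      if (b <= a && b %in% region_ord) next
      same_chain <- res$chain[match(a, res$ordinal)] == res$chain[match(b, res$ordinal)]
      if (same_chain && abs(a - b) < min_seq_sep) next
      lo <- min(a, b); hi <- max(a, b)
      if (paste(lo, hi) %in% native_key) next
      cand[[length(cand) + 1]] <- c(lo, hi)
    }
  }
  if (length(cand) == 0) return(native[0, ])
  cand <- unique(do.call(rbind, cand))
  tab <- data.frame(
    chain_a = res$chain[match(cand[, 1], res$ordinal)],
    resid_a = res$resid[match(cand[, 1], res$ordinal)],
    chain_b = res$chain[match(cand[, 2], res$ordinal)],
    resid_b = res$resid[match(cand[, 2], res$ordinal)],
    ord_a = cand[, 1], ord_b = cand[, 2],
    ref_distance = NA_real_, stringsAsFactors = FALSE)
  pers <- .contact_fractions(ensemble, tab, cutoff)
  keep <- pers >= steady_threshold
  out <- cbind(tab[keep, ], persistence = pers[keep])
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond / salt-bridge series between a donor and an acceptor residue
#'
#' When the topology carries hydrogens, a frame counts as formed if any donor
#' nitrogen--acceptor oxygen distance is at or below `dist_cutoff` AND the
#' corresponding donor-H...acceptor angle is at least `angle_cutoff` (hydrogens
#' are assigned to the nearest donor nitrogen within 1.25 A in the first
#' frame). Hydrogen-free topologies fall back to a distance-only salt-bridge
#' criterion (N--O <= 4.0 A), flagged in the result. Topologies without donor
#' nitrogens or acceptor oxygens (e.g. C-alpha-only traces) are refused: no
#' chemistry can be faked from them.
#'
#' @param ensemble an `ensemble`
#' @param donor_residue `atom_selection` containing the donor residue's atoms
#'   (e.g. the arginine guanidinium nitrogens)
#' @param acceptor_residue `atom_selection` containing the acceptor atoms
#'   (e.g. carboxylate oxygens of 2-oxoglutarate)
#' @param dist_cutoff donor-N to acceptor-O distance cutoff in A, default 3.5
#' @param angle_cutoff N-H...O angle cutoff in degrees, default 120
#' @return an `hbond_series`: list with `formed` (logical per frame),
#'   `fraction_formed`, `criteria`, `fallback` (TRUE when the distance-only
#'   salt-bridge criterion was used), `frames`
#' @export
hbond_series <- function(ensemble, donor_residue, acceptor_residue,
                         dist_cutoff = 3.5, angle_cutoff = 120) {
  at <- ensemble$topology$atom
  don_n <- donor_residue$atom_idx[toupper(at$element[donor_residue$atom_idx]) == "N"]
  acc_o <- acceptor_residue$atom_idx[toupper(at$element[acceptor_residue$atom_idx]) == "O"]
  if (length(don_n) == 0 || length(acc_o) == 0)
    stop("chemistry error: donor selection must contain N atoms and acceptor ",
         "selection O atoms (C-alpha-only topologies cannot run this analysis)")
  don_res_atoms <- which(at$ordinal %in% unique(at$ordinal[donor_residue$atom_idx]))
  hyd <- don_res_atoms[toupper(at$element[don_res_atoms]) == "H"]
  nf <- n_frames(ensemble)
  xyz1 <- .frame_coords(ensemble, seq_len(nrow(at)), 1)
  ## map hydrogens to their donor nitrogen from first-frame geometry
  hn <- list()
  if (length(hyd) > 0) {
    for (h in hyd) {
      d <- sqrt(colSums((t(xyz1[don_n, , drop = FALSE]) - xyz1[h, ])^2))
      if (min(d) <= 1.25) {
        n_of_h <- don_n[which.min(d)]
        hn[[length(hn) + 1]] <- c(h = h, n = n_of_h)
      }
    }
  }
  fallback <- length(hn) == 0
  formed <- logical(nf)
  cosmin <- cos(angle_cutoff * pi / 180)
  eff_cut <- if (fallback) 4.0 else dist_cutoff
  for (f in seq_len(nf)) {
    x <- .frame_coords(ensemble, seq_len(nrow(at)), f)
    ok <- FALSE
    for (ni in don_n) {
      dvec <- t(x[acc_o, , drop = FALSE]) - x[ni, ]
      dno <- sqrt(colSums(dvec^2))
      close_o <- which(dno <= eff_cut)
      if (length(close_o) == 0) next
      if (fallback) { ok <- TRUE; break }
      for (pair in hn) {
        if (pair["n"] != ni) next
        hx <- x[pair["h"], ]
        v1 <- x[ni, ] - hx
        for (oi in close_o) {
          v2 <- x[acc_o[oi], ] - hx
          ## angle N-H...O >= cutoff  <=>  cos(angle) <= cos(cutoff)
          ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          if (ca <= cosmin) { ok <- TRUE; break }
        }
        if (ok) break
      }
      if (ok) break
    }
    formed[f] <- ok
  }
  structure(list(formed = formed, fraction_formed = mean(formed),
                 criteria = list(dist_cutoff = eff_cut, angle_cutoff = angle_cutoff),
                 fallback = fallback, frames = ensemble$frames),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat("hbond_series:", length(x$formed), "frames; fraction_formed",
      signif(x$fraction_formed, 4),
      if (x$fallback) "(distance-only salt-bridge criterion)" else "", "\n")
  invisible(x)
}

#' Write a persistence report or contact set as a tab-delimited table
#' @param x a `contact_set` or `persistence_report`
#' @param path output path
#' @param settings optional named list echoed into the comment header
#' @return `path`, invisibly
#' @export
write_contacts <- function(x, path, settings = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# distfluct %s %s (distances in A)",
                 packageVersion("distfluct"), class(x)[1])
  if (length(settings) > 0)
    hdr <- c(hdr, paste0("# ", paste(names(settings), unlist(settings),
                                     sep = "=", collapse = " ")))
  writeLines(hdr, con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
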