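## structio: structures, ensembles, selections, meta-trajectories.
##
## A structure_model holds one conformation bound to a topology; an ensemble
## binds a frames x (3 * n_atoms) coordinate matrix (bio3d xyz layout, Angstrom)
## to that topology together with per-frame (system, replica, frame) labels.
## Author residue numbers (PDB numbering) are the user-facing coordinate
## system; internal math uses contiguous 1-based residue ordinals.

## van der Waals radii (Angstrom) by element, Bondi-type values as used by
## common SASA codes. Unknown elements fall back to 1.5 A with a warning.
.VDW_RADII <- c(
  "H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
  "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98, "FE" = 1.40, "ZN" = 1.39,
  "MG" = 1.73, "CA" = 2.31, "NA" = 2.27, "K" = 2.75, "MN" = 1.61, "CU" = 1.40
)

.vdw_radius <- function(element) {
  el <- toupper(element)
  r <- unname(.VDW_RADII[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using vdW radius 1.5 A", call. = FALSE)
    r[is.na(r)] <- 1.5
  }
  r
}

## Guess element from a PDB atom name when the element column is absent.
.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(.VDW_RADII) & !(one %in% c("C", "N", "O", "H", "S", "P")),
         two, one)
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by the readers and by the synthetic-ensemble
#' generator. Residue ordinals are assigned contiguously (1-based) in atom
#' order, per (chain, resid) group.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid` (author residue number, integer), `chain`
#'   (single-character label), `x`, `y`, `z` (Angstrom) and optionally
#'   `het` (logical, HETATM flag) and `vdw_radius`.
#' @return An object of class `structure_model`: list with elements `atom`
#'   (the completed atom table, plus `ordinal`) and `residue` (one row per
#'   residue: `chain`, `resid`, `resname`, `ordinal`).
#' @export
structure_model <- function(atoms) {
  req <- c("serial", "name", "element", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty input: structure has zero atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- .vdw_radius(atoms$element)
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom key: ", key[duplicated(key)][1])
  rkey <- paste(atoms$chain, atoms$resid)
  atoms$ordinal <- match(rkey, unique(rkey))
  residue <- atoms[!duplicated(rkey), c("chain", "resid", "resname", "ordinal")]
  rownames(atoms) <- rownames(residue) <- NULL
  structure(list(atom = atoms, residue = residue), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atom), "atoms,", nrow(x$residue), "residues,",
      "chains", paste(unique(x$atom$chain), collapse = ","), "\n")
  invisible(x)
}

#' Coordinates of a structure model
#' @param model a `structure_model`
#' @return n_atoms x 3 numeric matrix (Angstrom)
#' @export
coords <- function(model) {
  as.matrix(model$atom[, c("x", "y", "z")])
}

## Convert one model of a bio3d pdb object into a structure_model.
.from_bio3d <- function(pdb, path) {
  at <- pdb$atom
  if (any(!is.na(at$insert)))
    stop("insertion codes are not supported (found in ", path, ")")
  ## altloc: keep highest occupancy, first on tie
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, ][!duplicated(sort(key)), ]
    at <- at[order(at$eleno), ]
  }
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z))) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))[1]
    stop("unparsable coordinates at ATOM serial ", at$eleno[bad], " in ", path)
  }
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el[is.na(el) | el == ""] <- .element_from_name(at$elety[is.na(el) | el == ""])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  structure_model(data.frame(
    serial = at$eleno, name = at$elety, element = el, resname = at$resid,
    resid = at$resno, chain = chain,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  ))
}

#' Read a structure from a PDB file
#'
#' Reads ATOM/HETATM records of the first MODEL (or the whole file when no
#' MODEL records are present). Author residue numbering is preserved;
#' insertion codes are rejected; for alternate locations the highest-occupancy
#' copy is kept (first on ties). Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path path to a PDB file
#' @param format only `"pdb"` is supported
#' @return a [structure_model()]
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("empty or unparsable PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("empty input: no ATOM/HETATM records in ", path)
  .from_bio3d(pdb, path)
}

.pdb_atom_line <- function(type, serial, name, resname, chain, resid, x, y, z, element) {
  ## PDB fixed columns; atom names shorter than 4 characters start in col 14
  nm <- ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", name))
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000, nm, resname, chain, resid %% 10000,
          x, y, z, 1.00, 0.00, toupper(element))
}

.model_lines <- function(model, xyz = NULL) {
  at <- model$atom
  if (is.null(xyz)) xyz <- coords(model)
  .pdb_atom_line(ifelse(at$het, "HETATM", "ATOM"), at$serial, at$name,
                 at$resname, at$chain, at$resid,
                 xyz[, 1], xyz[, 2], xyz[, 3], at$element)
}

#' Write a structure model as a PDB file
#' @param model a `structure_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  writeLines(c(.model_lines(model), "END"), path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#' @param ensemble an `ensemble`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ensemble <- function(ensemble, path) {
  n <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    xyz <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
    writeLines(c(sprintf("MODEL     %4d", f),
                 .model_lines(ensemble$topology, xyz),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

.new_ensemble <- function(topology, xyz, frames) {
  stopifnot(ncol(xyz) == 3 * nrow(topology$atom), nrow(xyz) == nrow(frames))
  structure(list(topology = topology, xyz = xyz, frames = frames),
            class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble an `ensemble`
#' @return integer frame count
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_frames(x), "frames x", nrow(x$topology$atom), "atoms;",
      "systems:", paste(unique(x$frames$system), collapse = ","),
      "; replicas:", length(unique(paste(x$frames$system, x$frames$replica))), "\n")
  invisible(x)
}

#' Read a conformational ensemble bound to a topology
#'
#' Each input file becomes one replica; frames are concatenated in path order
#' and `frame` numbering restarts per replica. Multi-model PDB and DCD are
#' read through bio3d. XTC is not readable with the installed R stack: convert
#' to DCD or multi-model PDB first (e.g. `mdconvert` or `catdcd`).
#'
#' @param topology a `structure_model` giving the atom order of every frame
#' @param paths character vector of trajectory files (one per replica)
#' @param format `"pdb"` (multi-model PDB) or `"dcd"`
#' @param system_name label stored in the per-frame labels
#' @return an `ensemble`
#' @export
read_ensemble <- function(topology, paths, format = c("pdb", "dcd", "xtc"),
                          system_name = "system") {
  format <- match.arg(format)
  if (format == "xtc")
    stop("XTC trajectories are not supported by the installed R readers; ",
         "convert to DCD or multi-model PDB first")
  n_at <- nrow(topology$atom)
  xyz_list <- vector("list", length(paths))
  frames_list <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[k]
    if (!file.exists(p)) stop("file not found: ", p)
    m <- if (format == "pdb") {
      pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE))
      pdb$xyz
    } else {
      bio3d::read.dcd(p, verbose = FALSE)
    }
    m <- rbind(m)  # ensure matrix for 1-frame inputs
    if (ncol(m) != 3 * n_at)
      stop("topology mismatch for ", p, ": file has ", ncol(m) / 3,
           " atoms, topology has ", n_at)
    if (nrow(m) == 0) stop("empty input: no frames in ", p)
    xyz_list[[k]] <- m
    frames_list[[k]] <- data.frame(system = system_name, replica = k,
                                   frame = seq_len(nrow(m)),
                                   stringsAsFactors = FALSE)
  }
  .new_ensemble(topology, do.call(rbind, xyz_list), do.call(rbind, frames_list))
}

.same_topology <- function(a, b) {
  isTRUE(all.equal(a$atom[, c("chain", "resid", "name", "element")],
                   b$atom[, c("chain", "resid", "name", "element")],
                   check.attributes = FALSE))
}

#' Concatenate replica ensembles into a meta-trajectory
#'
#' Pools independent replica ensembles of one (or more) systems into a single
#' meta-ensemble prior to computing ensemble statistics. All inputs must share
#' the topology atom-for-atom; frame labels are preserved in input order.
#'
#' @param ensembles list of `ensemble` objects (or several `ensemble`
#'   arguments via `...`)
#' @return an `ensemble` whose frame count is the sum of the inputs'
#' @export
concat_meta <- function(ensembles) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1)
  topo <- ensembles[[1]]$topology
  for (e in ensembles[-1])
    if (!.same_topology(topo, e$topology))
      stop("topology mismatch between ensembles in concat_meta")
  .new_ensemble(topo,
                do.call(rbind, lapply(ensembles, function(e) e$xyz)),
                do.call(rbind, lapply(ensembles, function(e) e$frames)))
}

## ---- selections -------------------------------------------------------------

#' Select atoms by a small expression grammar
#'
#' Grammar: terms `chain <id>`, `resid <a>-<b>` (author numbering, inclusive)
#' or `resid <a>`, `name <atom-name>`, combined with `and` (higher precedence)
#' and `or`. Example: `"chain A and resid 590-610 and name CA"`.
#'
#' @param model a `structure_model`
#' @param expression selection string
#' @return an `atom_selection`: list with `atom_idx` (1-based, strictly
#'   increasing), `residue_ord` (residue ordinals covered) and `expression`.
#'   An expression matching nothing yields an empty selection with a warning.
#' @export
select_atoms <- function(model, expression) {
  at <- model$atom
  tokens <- strsplit(trimws(expression), "\\s+")[[1]]
  if (length(tokens) == 0) stop("selection parse error: empty expression")
  pos <- 0
  peek <- function() if (pos < length(tokens)) tokens[pos + 1] else NA_character_
  advance <- function() { pos <<- pos + 1; tokens[pos] }
  parse_term <- function() {
    kw <- advance()
    if (is.na(kw)) stop("selection parse error at token ", pos, ": expected term")
    arg <- advance()
    if (is.na(arg))
      stop("selection parse error at token ", pos, ": '", kw, "' needs an argument")
    switch(kw,
      chain = at$chain == arg,
      name = at$name == arg,
      resid = {
        if (grepl("^-?[0-9]+--?[0-9]+$", arg)) {
          ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", arg), " ")[[1]])
          at$resid >= ab[1] & at$resid <= ab[2]
        } else if (grepl("^-?[0-9]+$", arg)) {
          at$resid == as.integer(arg)
        } else stop("selection parse error at token ", pos,
                    ": bad resid range '", arg, "'")
      },
      stop("selection parse error at token ", pos, ": unknown keyword '", kw, "'")
    )
  }
  parse_and <- function() {
    m <- parse_term()
    while (!is.na(peek()) && peek() == "and") { advance(); m <- m & parse_term() }
    m
  }
  parse_or <- function() {
    m <- parse_and()
    while (!is.na(peek()) && peek() == "or") { advance(); m <- m | parse_and() }
    m
  }
  mask <- parse_or()
  if (pos != length(tokens))
    stop("selection parse error at token ", pos + 1, ": unexpected '", peek(), "'")
  idx <- which(mask)
  if (length(idx) == 0)
    warning("selection '", expression, "' matches no atoms", call. = FALSE)
  structure(list(atom_idx = idx,
                 residue_ord = sort(unique(at$ordinal[idx])),
                 expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection '", x$expression, "': ", length(x$atom_idx), " atoms, ",
      length(x$residue_ord), " residues\n", sep = "")
  invisible(x)
}

#' Build a selection from explicit atom indices
#' @param model a `structure_model`
#' @param atom_idx 1-based atom indices
#' @param expression label stored with the selection
#' @return an `atom_selection`
#' @export
selection_from_indices <- function(model, atom_idx, expression = "<indices>") {
  atom_idx <- sort(unique(as.integer(atom_idx)))
  stopifnot(all(atom_idx >= 1), all(atom_idx <= nrow(model$atom)))
  structure(list(atom_idx = atom_idx,
                 residue_ord = sort(unique(model$atom$ordinal[atom_idx])),
                 expression = expression),
            class = "atom_selection")
}

## Resolve a selection's atoms on another model by (chain, resid, name);
## errors if any atom is missing (alignment error between topologies).
.match_selection <- function(sel, from, to) {
  a <- from$atom[sel$atom_idx, ]
  key_to <- paste(to$atom$chain, to$atom$resid, to$atom$name)
  idx <- match(paste(a$chain, a$resid, a$name), key_to)
  if (anyNA(idx))
    stop("alignment error: ", sum(is.na(idx)),
         " selected atom(s) absent from the other structure")
  idx
}

## Column indices into an xyz matrix for a set of atom indices.
.xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

## Per-frame coordinates of selected atoms: n_sel x 3 matrix.
.frame_coords <- function(ensemble, atom_idx, frame) {
  matrix(ensemble$xyz[frame, .xyz_cols(atom_idx)], ncol = 3, byrow = TRUE)
}

## Check a selection is one C-alpha (or at least one atom) per residue.
.check_one_per_residue <- function(model, sel) {
  ords <- model$atom$ordinal[sel$atom_idx]
  if (anyDuplicated(ords))
    stop("selection error: more than one selected atom for residue ordinal ",
         ords[duplicated(ords)][1])
  ords
}
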