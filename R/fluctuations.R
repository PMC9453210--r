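## fluctuations: distance-fluctuation (DF) matrices and local-fluctuation (LF)
## profiles over C-alpha atoms.
##
## DF(i,j) is the variance over frames of the instantaneous C-alpha distance
## d_ij. The time-average convention is a population variance (divide by N).
## Being built from internal distances, DF is invariant under rigid-body
## motion of each frame and needs no reference structure or superposition.

## dist() vector ordering: unordered pairs (1,2),(1,3),...,(1,n),(2,3),...
.pair_table <- function(sel_res) {
  n <- length(sel_res)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  data.frame(i = i, j = j, ord_i = sel_res[i], ord_j = sel_res[j])
}

.residue_info <- function(model, residue_ord) {
  model$residue[match(residue_ord, model$residue$ordinal), ]
}

#' Per-frame pairwise C-alpha distance series
#'
#' Euclidean distances between every unordered pair of selected atoms, per
#' frame. Distances are frame-internal: no superposition is performed, so the
#' series is invariant under per-frame rigid transforms.
#'
#' @param ensemble an `ensemble`
#' @param selection an `atom_selection` with exactly one C-alpha per residue
#' @return a `distance_series`: list with `values` (frames x pairs matrix, A),
#'   `pairs` (pair table with residue ordinals) and `residues`
#' @export
pairwise_distance_series <- function(ensemble, selection) {
  ords <- .check_one_per_residue(ensemble$topology, selection)
  if (length(ords) < 2) stop("size error: need at least 2 residues")
  nf <- n_frames(ensemble)
  cols <- .xyz_cols(selection$atom_idx)
  np <- length(ords) * (length(ords) - 1) / 2
  values <- matrix(NA_real_, nf, np)
  for (f in seq_len(nf)) {
    x <- matrix(ensemble$xyz[f, cols], ncol = 3, byrow = TRUE)
    values[f, ] <- as.vector(dist(x))
  }
  structure(list(values = values, pairs = .pair_table(ords),
                 residues = .residue_info(ensemble$topology, ords)),
            class = "distance_series")
}

.df_from_pair_variances <- function(v, residues, n_frames, system_name) {
  n <- nrow(residues)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v  # column-major fill matches dist() ordering
  m <- m + t(m)
  dimnames(m) <- list(residues$resid, residues$resid)
  structure(list(values = m, n_frames = n_frames, residues = residues,
                 system = system_name),
            class = "df_matrix")
}

#' Distance-fluctuation matrix
#'
#' For each unordered residue pair (i, j), the population variance (divide by
#' N) of the C-alpha distance d_ij over all frames of the (meta-)ensemble.
#' Small DF marks pairs moving in a coordinated, quasi-rigid fashion. Computed
#' with a single streaming pass (Welford update), which matches the two-pass
#' definition to well below 1e-9 A^2.
#'
#' @param ensemble an `ensemble` with at least 2 frames
#' @param selection one C-alpha per residue
#' @return a `df_matrix`: list with `values` (n_res x n_res, A^2, symmetric,
#'   zero diagonal), `n_frames`, `residues`, `system`
#' @export
df_matrix <- function(ensemble, selection) {
  ords <- .check_one_per_residue(ensemble$topology, selection)
  if (length(ords) < 2) stop("size error: need at least 2 residues")
  nf <- n_frames(ensemble)
  if (nf < 2) stop("insufficient data: need at least 2 frames for a variance")
  cols <- .xyz_cols(selection$atom_idx)
  np <- length(ords) * (length(ords) - 1) / 2
  mu <- numeric(np); m2 <- numeric(np)
  for (f in seq_len(nf)) {
    x <- matrix(ensemble$xyz[f, cols], ncol = 3, byrow = TRUE)
    d <- as.vector(dist(x))
    delta <- d - mu
    mu <- mu + delta / f
    m2 <- m2 + delta * (d - mu)
  }
  .df_from_pair_variances(m2 / nf, .residue_info(ensemble$topology, ords),
                          nf, paste(unique(ensemble$frames$system), collapse = "+"))
}

#' @export
print.df_matrix <- function(x, ...) {
  cat("df_matrix:", nrow(x$values), "residues,", x$n_frames, "frames,",
      "system", x$system, "; max DF", signif(max(x$values), 4), "A^2\n")
  invisible(x)
}

#' Plot a DF matrix as a grayscale image
#'
#' Low DF (coordinated pairs) renders white, high DF dark/blue. An optional
#' significance mask overlays flagged pairs in red.
#'
#' @param x a `df_matrix`
#' @param mask optional `significance_mask` to overlay
#' @param ... passed to [graphics::image()]
#' @export
plot.df_matrix <- function(x, mask = NULL, ...) {
  n <- nrow(x$values)
  pal <- grDevices::colorRampPalette(c("white", "steelblue4"))(64)
  graphics::image(seq_len(n), seq_len(n), x$values, col = pal,
                  xlab = "residue index", ylab = "residue index",
                  main = paste("DF matrix:", x$system), useRaster = TRUE, ...)
  if (!is.null(mask)) {
    w <- which(mask$mask, arr.ind = TRUE)
    graphics::points(w[, 1], w[, 2], pch = ".", col = "red")
  }
  invisible(x)
}

## LF from an existing DF matrix: mean of DF(i, i+w) over in-chain neighbors.
.lf_from_df <- function(df, window) {
  res <- df$residues
  n <- nrow(res)
  vals <- numeric(n)
  for (k in seq_len(n)) {
    nb <- k + window
    nb <- nb[nb >= 1 & nb <= n & res$chain[pmin(pmax(nb, 1), n)] == res$chain[k]]
    if (length(nb) == 0) { vals[k] <- NA_real_; next }
    vals[k] <- mean(df$values[k, nb])
  }
  vals
}

#' Local-fluctuation profile
#'
#' LF(i) is the mean of the distance variances DF(i, j) to the sequence
#' neighbors j = i + w for offsets `window` (default -2, -1, +1, +2).
#' Neighbors never cross chain boundaries; terminal residues average over the
#' neighbors that exist. With `mode = "replica"` (default) the profile is
#' computed per replica and averaged; `mode = "meta"` computes it once on the
#' pooled meta-ensemble.
#'
#' @param ensemble an `ensemble`
#' @param selection one C-alpha per residue (at least 3 residues per chain)
#' @param window integer offsets, non-empty, excluding 0
#' @param mode `"replica"` or `"meta"`
#' @return an `lf_profile`: list with `values` (A^2), `residues`, `window`,
#'   `mode`
#' @export
lf_profile <- function(ensemble, selection, window = c(-2L, -1L, 1L, 2L),
                       mode = c("replica", "meta")) {
  mode <- match.arg(mode)
  if (length(window) == 0) stop("parameter error: empty LF window")
  window <- as.integer(window)
  if (any(window == 0)) stop("parameter error: LF window must exclude 0")
  ords <- .check_one_per_residue(ensemble$topology, selection)
  res <- .residue_info(ensemble$topology, ords)
  if (any(table(res$chain) < 3))
    stop("size error: need at least 3 residues per chain for an LF profile")
  if (mode == "meta") {
    vals <- .lf_from_df(df_matrix(ensemble, selection), window)
  } else {
    key <- paste(ensemble$frames$system, ensemble$frames$replica)
    profs <- lapply(unique(key), function(k) {
      sub <- .new_ensemble(ensemble$topology,
                           ensemble$xyz[key == k, , drop = FALSE],
                           ensemble$frames[key == k, , drop = FALSE])
      .lf_from_df(df_matrix(sub, selection), window)
    })
    vals <- Reduce(`+`, profs) / length(profs)
  }
  structure(list(values = vals, residues = res, window = window, mode = mode),
            class = "lf_profile")
}

#' @export
print.lf_profile <- function(x, ...) {
  cat("lf_profile:", length(x$values), "residues, window {",
      paste(x$window, collapse = ","), "}, mode", x$mode,
      "; max LF", signif(max(x$values, na.rm = TRUE), 4), "A^2\n")
  invisible(x)
}

#' @export
plot.lf_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "residue index", ylab = "LF (A^2)", ...)
  invisible(x)
}

#' Write a DF matrix as a tab-delimited square table
#' @param df a `df_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_df_matrix <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# distfluct %s DF matrix (A^2)", packageVersion("distfluct")),
               sprintf("# system=%s n_frames=%d n_residues=%d",
                       df$system, df$n_frames, nrow(df$values))), con)
  write.table(df$values, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write an LF profile as a two-column table
#' @param lf an `lf_profile`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lf_profile <- function(lf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# distfluct %s LF profile (A^2)", packageVersion("distfluct")),
               sprintf("# window={%s} mode=%s", paste(lf$window, collapse = ","), lf$mode)),
             con)
  write.table(data.frame(chain = lf$residues$chain, resid = lf$residues$resid,
                         lf = lf$values),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
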