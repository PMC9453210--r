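## synth: synthetic two-chain conformational ensembles with known ground
## truth. A stiff helical C-alpha background plus a "gate loop" segment that
## toggles between a closed and an open conformation via a two-state Markov
## chain, and a pseudo-ligand marking the catalytic site. Emulates a
## metal-locked system (loop pinned closed, persistent loop-ligand contact)
## versus a free system (loop toggling, larger site accessibility), so every
## analysis stage can be validated without running MD.

#' Parameterization of a synthetic ensemble
#'
#' The toy is a two-chain C-alpha trace on a helix with consecutive-residue
#' spacing 3.8 A, author numbering starting at `first_resid` per chain, and a
#' single-atom pseudo-ligand (chain L). Chain A's loop moves toward the
#' ligand/partner side; chain B's loop is mirrored (x-component negated) so it
#' opens away from chain A.
#'
#' Per frame, each chain's hidden loop state follows a two-state Markov chain
#' with stationary open probability `p_open` and persistence `switching`
#' (probability scale of remaining in the current state; transition
#' probabilities are (1 - switching) * stationary weights). Coordinates are
#' reference + state-dependent rigid loop offset + independent per-atom
#' isotropic Gaussian displacement: s.d. `background_sigma` outside the loop,
#' `loop_sigma_closed` / `loop_sigma_open` inside it.
#'
#' @param n_residues_per_chain residues per chain (chain count is fixed at 2)
#' @param first_resid author number of the first residue of each chain,
#'   default 560 (so the default loop carries ids 590-610)
#' @param loop_bounds inclusive author-id bounds of the gate loop
#' @param background_sigma per-axis displacement s.d. of the stiff core, A
#' @param loop_sigma_closed,loop_sigma_open per-axis loop displacement s.d., A
#' @param open_displacement rigid offset of the open loop (3-vector, A)
#' @param closed_displacement rigid offset of the closed loop, default zero;
#'   nonzero values build systems whose closed loop hugs the partner chain
#' @param p_open stationary open probability in [0, 1]
#' @param switching Markov persistence probability in [0, 1)
#' @param ligand_position 3-vector, default 3.5 A from the loop-center
#'   C-alpha of chain A toward chain B
#' @param n_frames frames per generated replica
#' @param seed integer seed; fixes the full output
#' @return an `ensemble_spec`
#' @export
ensemble_spec <- function(n_residues_per_chain = 60L,
                          first_resid = 560L,
                          loop_bounds = c(590L, 610L),
                          background_sigma = 0.3,
                          loop_sigma_closed = 0.3,
                          loop_sigma_open = 0.9,
                          open_displacement = c(-5, 2, 0),
                          closed_displacement = c(0, 0, 0),
                          p_open = 0.5,
                          switching = 0.9,
                          ligand_position = NULL,
                          n_frames = 2000L,
                          seed = 1L) {
  spec <- list(n_residues_per_chain = as.integer(n_residues_per_chain),
               first_resid = as.integer(first_resid),
               loop_bounds = as.integer(loop_bounds),
               background_sigma = background_sigma,
               loop_sigma_closed = loop_sigma_closed,
               loop_sigma_open = loop_sigma_open,
               open_displacement = as.numeric(open_displacement),
               closed_displacement = as.numeric(closed_displacement),
               p_open = p_open, switching = switching,
               ligand_position = ligand_position,
               n_frames = as.integer(n_frames), seed = as.integer(seed))
  .validate_spec(spec)
  structure(spec, class = "ensemble_spec")
}

.validate_spec <- function(spec) {
  last <- spec$first_resid + spec$n_residues_per_chain - 1L
  if (spec$loop_bounds[1] > spec$loop_bounds[2] ||
      spec$loop_bounds[1] < spec$first_resid || spec$loop_bounds[2] > last)
    stop("parameter error: loop bounds outside chain (",
         spec$first_resid, "-", last, ")")
  if (spec$p_open < 0 || spec$p_open > 1)
    stop("parameter error: p_open must be in [0, 1]")
  if (spec$switching < 0 || spec$switching >= 1)
    stop("parameter error: switching must be in [0, 1)")
  if (any(c(spec$background_sigma, spec$loop_sigma_closed, spec$loop_sigma_open) < 0))
    stop("parameter error: sigmas must be >= 0")
  if (length(spec$open_displacement) != 3 || length(spec$closed_displacement) != 3)
    stop("parameter error: displacements must be 3-vectors")
  invisible(spec)
}

## Helix geometry: radius and turn angle chosen so that consecutive C-alphas
## are 3.8 A apart and i/i+3 pairs sit inside a 4.5 A contact cutoff, giving
## the toy some tertiary contacts to track.
.HELIX_RADIUS <- 2.2
.HELIX_TURN <- 110 * pi / 180
.CA_SPACING <- 3.8
.CHAIN_B_OFFSET <- c(11, 0, 1.9)

.helix_rise <- function() {
  chord <- 2 * .HELIX_RADIUS * sin(.HELIX_TURN / 2)
  sqrt(.CA_SPACING^2 - chord^2)
}

.chain_coords <- function(n) {
  k <- seq_len(n) - 1
  cbind(.HELIX_RADIUS * cos(k * .HELIX_TURN),
        .HELIX_RADIUS * sin(k * .HELIX_TURN),
        k * .helix_rise())
}

#' Deterministic two-chain toy reference structure
#'
#' C-alpha-only trace of two identical helical chains (A and B) with author
#' numbering `first_resid` onward per chain and a single-atom pseudo-ligand
#' (chain L, resid 901, HETATM). The same spec always yields the identical
#' structure.
#'
#' @param spec an `ensemble_spec`
#' @return a `structure_model`
#' @export
build_toy_reference <- function(spec) {
  .validate_spec(spec)
  n <- spec$n_residues_per_chain
  xa <- .chain_coords(n)
  xb <- sweep(.chain_coords(n), 2, .CHAIN_B_OFFSET, `+`)
  resids <- seq(spec$first_resid, length.out = n)
  lig <- spec$ligand_position
  if (is.null(lig)) {
    mid <- round(mean(spec$loop_bounds)) - spec$first_resid + 1
    lig <- xa[mid, ] + c(3.5, 0, 0)  # toward chain B
  }
  atoms <- data.frame(
    serial = seq_len(2 * n + 1),
    name = c(rep("CA", 2 * n), "O1"),
    element = c(rep("C", 2 * n), "O"),
    resname = c(rep("ALA", 2 * n), "LIG"),
    resid = c(resids, resids, 901L),
    chain = c(rep("A", n), rep("B", n), "L"),
    x = c(xa[, 1], xb[, 1], lig[1]),
    y = c(xa[, 2], xb[, 2], lig[2]),
    z = c(xa[, 3], xb[, 3], lig[3]),
    het = c(rep(FALSE, 2 * n), TRUE),
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

.loop_atom_idx <- function(spec, model) {
  at <- model$atom
  lapply(c(A = "A", B = "B"), function(ch)
    which(at$chain == ch & at$resid >= spec$loop_bounds[1] &
            at$resid <= spec$loop_bounds[2]))
}

## Markov chain over {closed=0, open=1}; stationary open fraction p_open.
.simulate_states <- function(n, p_open, switching) {
  s <- integer(n)
  s[1] <- rbinom(1, 1, p_open)
  if (n > 1) {
    u <- runif(n - 1)
    p_co <- (1 - switching) * p_open        # closed -> open
    p_oc <- (1 - switching) * (1 - p_open)  # open -> closed
    for (t in 2:n)
      s[t] <- if (s[t - 1] == 1) as.integer(u[t - 1] >= p_oc)
              else as.integer(u[t - 1] < p_co)
  }
  s
}

## Simulate n_frames from the current RNG state (no reseeding here, so
## replicas drawn sequentially share one stream per spec).
.simulate_frames <- function(spec, ref, n_frames_sim) {
  n_at <- nrow(ref$atom)
  ref_vec <- as.vector(t(coords(ref)))
  loops <- .loop_atom_idx(spec, ref)
  st_a <- .simulate_states(n_frames_sim, spec$p_open, spec$switching)
  st_b <- .simulate_states(n_frames_sim, spec$p_open, spec$switching)
  sd_mat <- matrix(spec$background_sigma, n_frames_sim, 3 * n_at)
  off <- matrix(0, n_frames_sim, 3 * n_at)
  disp <- rbind(closed = spec$closed_displacement, open = spec$open_displacement)
  for (ch in c("A", "B")) {
    idx <- loops[[ch]]
    st <- if (ch == "A") st_a else st_b
    mirror <- if (ch == "B") c(-1, 1, 1) else c(1, 1, 1)
    sd_loop <- ifelse(st == 1, spec$loop_sigma_open, spec$loop_sigma_closed)
    cols <- .xyz_cols(idx)
    sd_mat[, cols] <- matrix(rep(sd_loop, length(cols)), n_frames_sim)
    d <- disp[st + 1, , drop = FALSE] * rep(mirror, each = n_frames_sim)
    off[, cols[seq(1, length(cols), 3)]] <- d[, 1]
    off[, cols[seq(2, length(cols), 3)]] <- d[, 2]
    off[, cols[seq(3, length(cols), 3)]] <- d[, 3]
  }
  noise <- matrix(rnorm(n_frames_sim * 3 * n_at, sd = as.vector(sd_mat)),
                  n_frames_sim, 3 * n_at)
  xyz <- matrix(ref_vec, n_frames_sim, 3 * n_at, byrow = TRUE) + off + noise
  list(xyz = xyz, states = data.frame(state_A = ifelse(st_a == 1, "open", "closed"),
                                      state_B = ifelse(st_b == 1, "open", "closed"),
                                      stringsAsFactors = FALSE))
}

#' Generate a synthetic conformational ensemble
#'
#' One replica of `spec$n_frames` frames; seed-reproducible. The hidden loop
#' state of each chain is stored in the `states` attribute (per-frame
#' closed/open labels) as ground truth for classification tests.
#'
#' @param spec an `ensemble_spec` with `n_frames >= 2`
#' @param system_name label for the frame table
#' @return an `ensemble` with a `states` attribute
#' @export
generate_ensemble <- function(spec, system_name = "synthetic") {
  .validate_spec(spec)
  if (spec$n_frames < 2) stop("parameter error: n_frames must be >= 2")
  ref <- build_toy_reference(spec)
  set.seed(spec$seed)
  sim <- .simulate_frames(spec, ref, spec$n_frames)
  e <- .new_ensemble(ref, sim$xyz,
                     data.frame(system = system_name, replica = 1L,
                                frame = seq_len(spec$n_frames),
                                stringsAsFactors = FALSE))
  attr(e, "states") <- cbind(e$frames, sim$states)
  e
}

#' Generate several replicas and pool them into a meta-ensemble
#'
#' Replicas are drawn sequentially from the spec's single pseudorandom stream
#' (seeded once), mimicking independent MD replicas of one system.
#'
#' @param spec an `ensemble_spec`
#' @param n_replicas number of replicas, default 3
#' @param system_name label for the frame table
#' @return an `ensemble` with `n_replicas * spec$n_frames` frames and a
#'   `states` attribute
#' @export
generate_replicas <- function(spec, n_replicas = 3L, system_name = "synthetic") {
  .validate_spec(spec)
  if (spec$n_frames < 2) stop("parameter error: n_frames must be >= 2")
  ref <- build_toy_reference(spec)
  set.seed(spec$seed)
  parts <- vector("list", n_replicas)
  states <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    sim <- .simulate_frames(spec, ref, spec$n_frames)
    frames <- data.frame(system = system_name, replica = r,
                         frame = seq_len(spec$n_frames), stringsAsFactors = FALSE)
    parts[[r]] <- .new_ensemble(ref, sim$xyz, frames)
    states[[r]] <- cbind(frames, sim$states)
  }
  e <- concat_meta(parts)
  attr(e, "states") <- do.call(rbind, states)
  e
}

#' Ground-truth DF matrix of a synthetic spec
#'
#' Closed-form branch (`method = "limit"`): the large-separation approximation
#' DF(i, j) ~ sigma_i^2 + sigma_j^2 (per-axis variances of two independent
#' isotropic displacements), valid only in the single-state regime
#' (`p_open` 0 or 1) and refused when any pair separation R is below 10x the
#' largest sigma. Monte-Carlo branch (`method = "mc"`): direct i.i.d. sampling
#' of the generative model (stationary state draws, no Markov dynamics —
#' the stationary variance is identical), returning sampled ground truth with
#' standard errors in the `se` attribute. `method = "auto"` picks the limit
#' branch when valid.
#'
#' @param spec an `ensemble_spec`
#' @param selection optional `atom_selection` on [build_toy_reference()]
#'   restricting the residue set (default: all C-alphas)
#' @param method `"auto"`, `"limit"` or `"mc"`
#' @param n_samples Monte-Carlo sample count (>= 1e5 recommended)
#' @return a `df_matrix`; MC results carry an `se` attribute (same shape)
#' @export
expected_df <- function(spec, selection = NULL,
                        method = c("auto", "limit", "mc"), n_samples = 1e5) {
  method <- match.arg(method)
  ref <- build_toy_reference(spec)
  if (is.null(selection)) selection <- select_atoms(ref, "name CA")
  ords <- .check_one_per_residue(ref, selection)
  res <- .residue_info(ref, ords)
  xyz <- coords(ref)[selection$atom_idx, , drop = FALSE]
  at <- ref$atom[selection$atom_idx, ]
  in_loop <- at$chain %in% c("A", "B") &
    at$resid >= spec$loop_bounds[1] & at$resid <= spec$loop_bounds[2]
  single_state <- spec$p_open %in% c(0, 1) || !any(in_loop)
  sig <- ifelse(in_loop,
                if (spec$p_open >= 1) spec$loop_sigma_open else spec$loop_sigma_closed,
                spec$background_sigma)
  n <- length(ords)
  pt <- .pair_table(ords)
  rsep <- sqrt(rowSums((xyz[pt$i, , drop = FALSE] - xyz[pt$j, , drop = FALSE])^2))
  if (method == "auto")
    method <- if (single_state && min(rsep) >= 10 * max(sig, 1e-12)) "limit" else "mc"
  if (method == "limit") {
    if (!single_state)
      stop("limit branch requires a single-state regime (p_open 0 or 1); ",
           "use method = 'mc'")
    if (min(rsep) < 10 * max(sig, 1e-12))
      stop("limit approximation invalid: min pair separation ", signif(min(rsep), 3),
           " A is below 10 x sigma; use method = 'mc'")
    v <- sig[pt$i]^2 + sig[pt$j]^2
    out <- .df_from_pair_variances(v, res, NA_integer_, "expected(limit)")
    attr(out, "method") <- "limit"
    return(out)
  }
  ## Monte-Carlo branch: independent code path from the trajectory generator.
  disp <- rbind(spec$closed_displacement, spec$open_displacement)
  v <- se <- numeric(nrow(pt))
  memo <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(pt))) {
    i <- pt$i[k]; j <- pt$j[k]
    plain <- !in_loop[i] && !in_loop[j]
    key <- if (plain) sprintf("%.6f_%.8f_%.8f", rsep[k], sig[i], sig[j]) else NA
    if (plain && !is.null(memo[[key]])) {
      v[k] <- memo[[key]][1]; se[k] <- memo[[key]][2]
      next
    }
    off_i <- off_j <- matrix(0, n_samples, 3)
    if (in_loop[i] || in_loop[j]) {
      same_chain <- at$chain[i] == at$chain[j]
      st_i <- rbinom(n_samples, 1, spec$p_open)
      st_j <- if (same_chain) st_i else rbinom(n_samples, 1, spec$p_open)
      mir_i <- if (at$chain[i] == "B") c(-1, 1, 1) else c(1, 1, 1)
      mir_j <- if (at$chain[j] == "B") c(-1, 1, 1) else c(1, 1, 1)
      if (in_loop[i]) off_i <- disp[st_i + 1, , drop = FALSE] %*% diag(mir_i)
      if (in_loop[j]) off_j <- disp[st_j + 1, , drop = FALSE] %*% diag(mir_j)
      sig_i <- ifelse(in_loop[i] & st_i == 1, spec$loop_sigma_open,
                      ifelse(in_loop[i], spec$loop_sigma_closed, spec$background_sigma))
      sig_j <- ifelse(in_loop[j] & st_j == 1, spec$loop_sigma_open,
                      ifelse(in_loop[j], spec$loop_sigma_closed, spec$background_sigma))
    } else {
      sig_i <- rep(sig[i], n_samples); sig_j <- rep(sig[j], n_samples)
    }
    pi_ <- matrix(rep(xyz[i, ], each = n_samples), ncol = 3) + off_i +
      matrix(rnorm(3 * n_samples, sd = rep(sig_i, 3)), ncol = 3)
    pj_ <- matrix(rep(xyz[j, ], each = n_samples), ncol = 3) + off_j +
      matrix(rnorm(3 * n_samples, sd = rep(sig_j, 3)), ncol = 3)
    d <- sqrt(rowSums((pi_ - pj_)^2))
    dv <- d - mean(d)
    m2 <- mean(dv^2); m4 <- mean(dv^4)
    v[k] <- m2
    se[k] <- sqrt(max(m4 - m2^2, 0) / n_samples)
    if (plain) memo[[key]] <- c(v[k], se[k])
  }
  out <- .df_from_pair_variances(v, res, NA_integer_, "expected(mc)")
  se_m <- .df_from_pair_variances(se, res, NA_integer_, "se")$values
  attr(out, "se") <- se_m
  attr(out, "method") <- "mc"
  out
}

#' Hidden-state ground truth of a generated ensemble
#' @param ensemble an ensemble from [generate_ensemble()] or
#'   [generate_replicas()]
#' @return data frame of per-frame hidden loop states (chains A and B)
#' @export
true_states <- function(ensemble) {
  st <- attr(ensemble, "states")
  if (is.null(st)) stop("ensemble carries no hidden-state ground truth")
  st
}

#' Write the hidden-state ground truth as a sidecar table
#' @param ensemble a generated ensemble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_states <- function(ensemble, path) {
  st <- true_states(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# distfluct %s hidden loop states", packageVersion("distfluct")), con)
  write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
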