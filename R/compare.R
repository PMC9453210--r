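## compare_stats: pair-by-pair F-test comparison of two systems' DF matrices,
## multiple-testing control, and summarization of significant residue pairs
## into contiguous sequence regions.

#' F-test comparison of two DF matrices
#'
#' For every off-diagonal residue pair, the variance ratio
#' F = DF_test / DF_ref with a two-sided p-value
#' 2 * min(P(F <= f), P(F >= f)) from the F distribution with
#' (dof_test, dof_ref) degrees of freedom. MD frames are autocorrelated, so
#' the naive default dof = n_frames - 1 (used with a warning when `dof_*` is
#' NULL) overstates the evidence; callers holding an effective-sample-size
#' estimate should pass it explicitly.
#'
#' Degenerate pairs: both variances zero -> undefined (NA, masked);
#' DF_ref = 0 with DF_test > 0 -> F = Inf, p = 0.
#'
#' @param df_test,df_ref `df_matrix` objects over the identical residue set
#' @param dof_test,dof_ref degrees of freedom (>= 2); default n_frames - 1
#' @return a `df_comparison`: list with `f_ratio`, `p_value` (n x n, symmetric,
#'   NA diagonal), `df_test_values`, `df_ref_values`, `dof_test`, `dof_ref`,
#'   `residues`, `test_name`, `reference_name`
#' @export
f_test_matrix <- function(df_test, df_ref, dof_test = NULL, dof_ref = NULL) {
  if (!isTRUE(all.equal(df_test$residues[, c("chain", "resid")],
                        df_ref$residues[, c("chain", "resid")],
                        check.attributes = FALSE)))
    stop("alignment error: DF matrices cover different residue sets")
  if (is.null(dof_test) || is.null(dof_ref)) {
    if (is.null(dof_test)) dof_test <- df_test$n_frames - 1
    if (is.null(dof_ref)) dof_ref <- df_ref$n_frames - 1
    warning("using naive dof = n_frames - 1; MD frames are autocorrelated, ",
            "consider an effective sample size", call. = FALSE)
  }
  if (dof_test < 2 || dof_ref < 2) stop("parameter error: dof must be >= 2")
  vt <- df_test$values
  vr <- df_ref$values
  f <- vt / vr
  p <- 2 * pmin(pf(f, dof_test, dof_ref), pf(f, dof_test, dof_ref, lower.tail = FALSE))
  p <- pmin(p, 1)
  both_zero <- vt == 0 & vr == 0
  f[both_zero] <- NA_real_
  p[both_zero] <- NA_real_
  p[vr == 0 & vt > 0] <- 0  # infinitely significant flag
  p[vt == 0 & vr > 0] <- 0
  diag(f) <- NA_real_
  diag(p) <- NA_real_
  structure(list(f_ratio = f, p_value = p,
                 df_test_values = vt, df_ref_values = vr,
                 dof_test = dof_test, dof_ref = dof_ref,
                 residues = df_test$residues,
                 test_name = df_test$system, reference_name = df_ref$system),
            class = "df_comparison")
}

#' @export
print.df_comparison <- function(x, ...) {
  cat("df_comparison:", x$test_name, "vs reference", x$reference_name,
      "; dof", x$dof_test, "/", x$dof_ref,
      "; min p", signif(min(x$p_value, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Significant residue pairs of a DF comparison
#'
#' Adjusts the p-values of all defined off-diagonal pairs (each unordered pair
#' counted once) and flags those with adjusted p below `alpha`.
#'
#' @param cmp a `df_comparison`
#' @param alpha significance level in (0, 1)
#' @param correction `"none"` (default; matching an uncorrected per-pair
#'   test), `"bonferroni"` or `"benjamini-hochberg"`
#' @return a `significance_mask`: list with `mask` (n x n logical, symmetric,
#'   FALSE where p undefined), `p_adj`, `alpha`, `correction`, `n_tests`,
#'   `residues`, plus the comparison it derives from
#' @export
significant_pairs <- function(cmp, alpha = 0.05,
                              correction = c("none", "bonferroni", "benjamini-hochberg")) {
  if (!(alpha > 0 && alpha < 1)) stop("parameter error: alpha must be in (0,1)")
  correction <- match.arg(correction)
  meth <- c(none = "none", bonferroni = "bonferroni", `benjamini-hochberg` = "BH")[correction]
  p <- cmp$p_value
  ut <- upper.tri(p)
  defined <- ut & !is.na(p)
  n_tests <- sum(defined)
  p_adj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  p_adj[defined] <- p.adjust(p[defined], method = meth)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  mask <- !is.na(p_adj) & p_adj < alpha
  structure(list(mask = mask, p_adj = p_adj, alpha = alpha,
                 correction = correction, n_tests = n_tests,
                 residues = cmp$residues, comparison = cmp),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat("significance_mask: alpha", x$alpha, "correction", x$correction, ";",
      sum(x$mask[upper.tri(x$mask)]), "of", x$n_tests, "pairs flagged\n")
  invisible(x)
}

#' Summarize significant pairs into contiguous residue regions
#'
#' A residue is flagged when it has at least one significant pair and at least
#' `min_pair_frac` of its defined pairs are significant; maximal runs of at
#' least `min_run` consecutive flagged residues (author numbering, same chain)
#' become segments. `min_pair_frac = 0` reduces to the permissive
#' "any significant pair" rule, which saturates whenever one segment's
#' fluctuation amplitude differs (every distant residue then has significant
#' pairs *with* that segment); the default 0.5 keeps the summary selective for
#' the residues that themselves moved differently.
#'
#' @param mask a `significance_mask`
#' @param min_run minimum run length (>= 1)
#' @param min_pair_frac minimum fraction of a residue's defined pairs that
#'   must be significant for the residue to be flagged
#' @return data frame with one row per segment: `chain`, `start_resid`,
#'   `end_resid`, `n_residues`, `n_flagged_pairs`, `direction` (`"higher"` or
#'   `"lower"`: majority sign of DF_test - DF_ref over the segment's
#'   significant pairs)
#' @export
summarize_regions <- function(mask, min_run = 3, min_pair_frac = 0.5) {
  stopifnot(min_run >= 1, min_pair_frac >= 0, min_pair_frac <= 1)
  res <- mask$residues
  m <- mask$mask
  defined <- !is.na(mask$p_adj)
  n_sig <- rowSums(m)
  n_def <- rowSums(defined)
  flagged <- n_sig >= 1 & (n_sig / pmax(n_def, 1)) >= min_pair_frac
  cmp <- mask$comparison
  ddiff <- cmp$df_test_values - cmp$df_ref_values
  out <- list()
  for (ch in unique(res$chain)) {
    in_ch <- which(res$chain == ch)
    ## break runs at author-numbering gaps
    brk <- cumsum(c(1, diff(res$resid[in_ch]) != 1))
    for (g in unique(brk)) {
      idx <- in_ch[brk == g]
      r <- rle(flagged[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (s in which(r$values & r$lengths >= min_run)) {
        seg <- idx[starts[s]:ends[s]]
        seg_mask <- m[seg, , drop = FALSE]
        n_pairs <- sum(seg_mask)  # residue-pair participations of the segment
        sgn <- sum(sign(ddiff[seg, , drop = FALSE][seg_mask]))
        out[[length(out) + 1]] <- data.frame(
          chain = ch,
          start_resid = res$resid[seg[1]],
          end_resid = res$resid[seg[length(seg)]],
          n_residues = length(seg),
          n_flagged_pairs = n_pairs,
          direction = if (sgn >= 0) "higher" else "lower",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(), start_resid = integer(),
                      end_resid = integer(), n_residues = integer(),
                      n_flagged_pairs = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write a DF comparison as a long-format table
#'
#' One row per defined unordered pair: residue ids, both DF values, F, p,
#' adjusted p and the significance flag.
#'
#' @param mask a `significance_mask`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_comparison <- function(mask, path) {
  cmp <- mask$comparison
  res <- cmp$residues
  ut <- which(upper.tri(cmp$p_value) & !is.na(cmp$p_value), arr.ind = TRUE)
  tab <- data.frame(
    chain_i = res$chain[ut[, 1]], res_i = res$resid[ut[, 1]],
    chain_j = res$chain[ut[, 2]], res_j = res$resid[ut[, 2]],
    df_test = cmp$df_test_values[ut], df_ref = cmp$df_ref_values[ut],
    f = cmp$f_ratio[ut], p = cmp$p_value[ut], p_adj = mask$p_adj[ut],
    significant = mask$mask[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# distfluct %s DF comparison: %s vs reference %s",
                       packageVersion("distfluct"), cmp$test_name, cmp$reference_name),
               sprintf("# dof_test=%g dof_ref=%g alpha=%g correction=%s n_tests=%d",
                       cmp$dof_test, cmp$dof_ref, mask$alpha, mask$correction,
                       mask$n_tests)), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
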