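#' @title Differential pull-down proteomics
#' @description Helpers implementing the TMT pull-down comparison pipeline:
#'   flag-based cleaning, per-channel log2 + median normalization, the
#'   completeness filter, an S0-moderated two-sample statistic with
#'   permutation-based FDR control, preferential-binder classification, and
#'   the iBAQ abundance screen.
#' @name proteomics
NULL

# Channel metadata travels as an attribute; dplyr verbs drop it, so the
# pipeline reattaches it explicitly after each step.
channel_design <- function(t) {
  d <- attr(t, "channel_design")
  if (is.null(d)) abort("Table has no channel design attribute.")
  d
}

with_design <- function(t, design) {
  attr(t, "channel_design") <- design
  if (!inherits(t, "cap_proteingroups")) {
    class(t) <- c("cap_proteingroups", class(t))
  }
  t
}

#' Remove decoy, site-only and contaminant protein groups
#'
#' Drops rows flagged as reverse (decoy-database match), only-identified-by-
#' site, or potential contaminant; removal counts are reported.
#'
#' @param t A protein-group tibble with logical columns `flag_reverse`,
#'   `flag_site_only`, `flag_contaminant`.
#' @return The cleaned tibble (channel design preserved).
#' @export
clean_protein_groups <- function(t) {
  design <- channel_design(t)
  flags <- c("flag_reverse", "flag_site_only", "flag_contaminant")
  if (!all(flags %in% names(t))) {
    abort("Flag columns are missing from the table.")
  }
  counts <- vapply(flags, function(f) sum(t[[f]], na.rm = TRUE), numeric(1))
  inform(sprintf(
    "Removed %d reverse, %d site-only, %d contaminant group(s).",
    counts[1], counts[2], counts[3]
  ))
  keep <- !(t$flag_reverse | t$flag_site_only | t$flag_contaminant)
  out <- t[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("All protein groups were flagged; table is empty.")
  with_design(out, design)
}

#' Log2 transform and median-center reporter intensities per channel
#'
#' Each reporter channel is log2 transformed (zeros and non-positive values
#' become missing) and the channel's median — computed over non-missing
#' values — is subtracted, so every channel has median 0 afterwards.
#'
#' @param t A protein-group tibble with one column per reporter channel.
#' @return The normalized tibble; intensities are now on the centred log2
#'   scale.
#' @export
log2_median_normalize <- function(t) {
  design <- channel_design(t)
  for (ch in design$channel) {
    v <- t[[ch]]
    v[!is.na(v) & v <= 0] <- NA_real_
    v <- log2(v)
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) abort(sprintf("Channel '%s' is entirely missing.", ch))
    t[[ch]] <- v - m
  }
  with_design(t, design)
}

#' Completeness and identification-quality filter
#'
#' Keeps protein groups identified by at least `min_razor` razor + unique
#' peptides and quantified in every reporter channel (a complete set of 9
#' values). Missing intensities are never imputed; this filter removes the
#' need.
#'
#' @param t A (normalized) protein-group tibble.
#' @param min_razor Minimum razor + unique peptide count.
#' @return The filtered tibble.
#' @export
completeness_filter <- function(t, min_razor = 2) {
  design <- channel_design(t)
  complete <- rowSums(is.na(as.matrix(t[design$channel]))) == 0
  keep <- t$razor_unique_peptides >= min_razor & complete
  with_design(t[keep, , drop = FALSE], design)
}

# All balanced 3-vs-3 relabelings of six channels: columns of combn(6, 3).
# The observed labeling (1,2,3) and its sign-flip complement (4,5,6) are
# excluded from the null set: |d| is invariant under the complement, so
# keeping them would plant the observed statistics inside their own null.
balanced_relabelings <- function() {
  combs <- utils::combn(6, 3)
  keep <- !apply(combs, 2, function(ix) {
    identical(ix, c(1L, 2L, 3L)) || identical(ix, c(4L, 5L, 6L))
  })
  combs[, keep, drop = FALSE]
}

s0_d_stat <- function(a_mat, b_mat, s0) {
  nA <- ncol(a_mat)
  nB <- ncol(b_mat)
  mA <- rowMeans(a_mat)
  mB <- rowMeans(b_mat)
  vA <- rowSums((a_mat - mA)^2) / (nA - 1)
  vB <- rowSums((b_mat - mB)^2) / (nB - 1)
  se <- sqrt(vA / nA + vB / nB)
  (mA - mB) / (se + s0)
}

#' S0-moderated two-sided test with permutation-based FDR
#'
#' For each protein group the moderated statistic is
#' `d = (mean_A - mean_B) / (s + s0)` with `s` the Welch standard-error
#' denominator `sqrt(var_A/n_A + var_B/n_B)`; `s0` damps low-variance false
#' positives. The null distribution is built from the balanced 3-vs-3
#' relabelings of the six channels (18 after excluding the observed labeling
#' and its sign-flip complement, which leave `|d|` unchanged). The two-sided
#' significance cutoff is the smallest `|d|` threshold `c` whose estimated
#' FDR
#' `((1 + mean permutation count >= c)) / (observed count >= c)` — with a
#' +1 numerator correction so an empty null never certifies a call — does
#' not exceed `fdr`.
#'
#' @param t A cleaned, normalized, completeness-filtered protein-group
#'   tibble (log2 scale).
#' @param comparison A string `"<condition A> vs <condition B>"`, e.g.
#'   `"AR-2 vs AR-1"`; positive `log2fc` means enrichment in condition A.
#' @param s0 Variance-regularization constant (default 1).
#' @param fdr Target permutation-based false discovery rate (default 0.02).
#' @return A tibble of class `cap_comparison`: `group_id`, `log2fc`,
#'   `d_stat`, `significant`, `comparison`; the threshold, settings and
#'   number of permutations are attached as attributes.
#' @export
s0_test <- function(t, comparison, s0 = 1, fdr = 0.02) {
  design <- channel_design(t)
  parts <- strsplit(comparison, " vs ", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% design$condition)) {
    abort("`comparison` must be '<condition A> vs <condition B>' over known conditions.")
  }
  cols_a <- design$channel[design$condition == parts[1]]
  cols_b <- design$channel[design$condition == parts[2]]
  if (length(cols_a) != 3 || length(cols_b) != 3) {
    abort("Each condition must have exactly 3 channels.")
  }
  mat <- as.matrix(t[c(cols_a, cols_b)])
  if (anyNA(mat)) abort("Complete 3 vs 3 values required; run completeness_filter() first.")
  if (nrow(mat) == 0) abort("No protein groups to test.")

  d_obs <- s0_d_stat(mat[, 1:3, drop = FALSE], mat[, 4:6, drop = FALSE], s0)
  relabel <- balanced_relabelings()
  n_perm <- ncol(relabel)
  d_perm <- vapply(seq_len(n_perm), function(j) {
    ia <- relabel[, j]
    s0_d_stat(mat[, ia, drop = FALSE], mat[, setdiff(1:6, ia), drop = FALSE], s0)
  }, numeric(nrow(mat)))

  abs_obs <- abs(d_obs)
  abs_perm_sorted <- sort(abs(as.numeric(d_perm)))
  candidates <- sort(unique(abs_obs))
  n_obs_ge <- length(abs_obs) - findInterval(candidates - 1e-12, sort(abs_obs))
  perm_ge <- length(abs_perm_sorted) -
    findInterval(candidates - 1e-12, abs_perm_sorted)
  fdr_hat <- ((1 + perm_ge) / n_perm) / n_obs_ge
  ok <- which(fdr_hat <= fdr)
  threshold <- if (length(ok)) candidates[min(ok)] else Inf

  out <- tibble::tibble(
    group_id = t$group_id,
    log2fc = rowMeans(mat[, 1:3, drop = FALSE]) -
      rowMeans(mat[, 4:6, drop = FALSE]),
    d_stat = d_obs,
    significant = abs_obs >= threshold,
    comparison = comparison
  )
  attr(out, "threshold") <- threshold
  attr(out, "s0") <- s0
  attr(out, "fdr") <- fdr
  attr(out, "n_perm") <- n_perm
  class(out) <- c("cap_comparison", class(out))
  out
}

#' Classify preferential binders across pull-down comparisons
#'
#' A protein group is a preferential binder in a comparison when it is
#' significant and (by default) enriched — positive `log2fc` — in the first
#' condition. Returns the per-comparison binder sets, their intersection
#' over the requested comparisons, and a fold-change-versus-fold-change
#' table for plotting.
#'
#' @param results A named list of `cap_comparison` tibbles sharing a protein
#'   universe (names default to each result's comparison label).
#' @param intersect_of Comparisons whose binder sets are intersected
#'   (default: the first two).
#' @param require_positive Require positive `log2fc` in addition to
#'   significance.
#' @return A list of class `cap_binders`: `sets` (named list of group-id
#'   vectors), `intersection`, `fc_fc` (tibble of `log2fc` per comparison
#'   with significance flags).
#' @export
preferential_binders <- function(results,
                                 intersect_of = NULL,
                                 require_positive = TRUE) {
  if (inherits(results, "cap_comparison")) results <- list(results)
  labels <- names(results) %||%
    vapply(results, function(r) r$comparison[1], character(1))
  if (is.null(names(results))) names(results) <- labels
  sets <- lapply(results, function(r) {
    sel <- r$significant
    if (require_positive) sel <- sel & r$log2fc > 0
    r$group_id[sel]
  })
  intersect_of <- intersect_of %||% head(names(results), 2)
  inter <- Reduce(intersect, sets[intersect_of])

  fc_fc <- NULL
  if (length(results) >= 1) {
    fc_fc <- purrr::imap(results, function(r, nm) {
      out <- r[c("group_id", "log2fc", "significant")]
      names(out)[2:3] <- paste0(c("log2fc.", "significant."), nm)
      out
    }) |>
      purrr::reduce(dplyr::inner_join, by = "group_id")
  }
  structure(
    list(sets = sets, intersection = inter, fc_fc = fc_fc),
    class = "cap_binders"
  )
}

#' @export
print.cap_binders <- function(x, ...) {
  cat("<cap_binders>\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %s: %d preferential binder(s)\n", nm, length(x$sets[[nm]])))
  }
  cat(sprintf("  intersection: %d\n", length(x$intersection)))
  invisible(x)
}

#' Flag protein groups in the top iBAQ quartile
#'
#' `TRUE` for rows whose iBAQ value is at or above the 75th percentile of
#' the table (ties at the threshold are kept — inclusive screening). Missing
#' iBAQ values are excluded from the percentile computation and flagged
#' `FALSE`.
#'
#' @param t A protein-group tibble with an `ibaq` column.
#' @return A logical vector along the rows of `t`.
#' @export
ibaq_top_quartile <- function(t) {
  if (!"ibaq" %in% names(t)) abort("No `ibaq` column present.")
  q <- quantile(t$ibaq, 0.75, na.rm = TRUE, names = FALSE)
  !is.na(t$ibaq) & t$ibaq >= q
}

#' Fold-change versus fold-change scatter of two comparisons
#'
#' @param binders A `cap_binders` result whose `fc_fc` table contains the
#'   two comparisons.
#' @param x,y Comparison labels to plot (default: first two columns found).
#' @return A ggplot; points significant in both comparisons are highlighted.
#' @export
plot_fc_fc <- function(binders, x = NULL, y = NULL) {
  stopifnot(inherits(binders, "cap_binders"))
  fc <- binders$fc_fc
  fc_cols <- grep("^log2fc\\.", names(fc), value = TRUE)
  x <- x %||% fc_cols[1]
  y <- y %||% fc_cols[2]
  sig_cols <- sub("^log2fc\\.", "significant.", c(x, y))
  fc$both <- fc[[sig_cols[1]]] & fc[[sig_cols[2]]]
  ggplot2::ggplot(fc, ggplot2::aes(.data[[x]], .data[[y]], colour = both)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "significant in both") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2)
}
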