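#' Cumulative reporter expression per replicate
#'
#' Sums luminescence over the collection schedule for each sample x
#' replicate (x cell line / batch when present). Because the culture medium
#' is replaced at every collection, each reading measures the protein
#' secreted since the previous timepoint, and the cumulative total is the
#' plain sum of the readings. Replicates missing any scheduled timepoint are
#' excluded with a warning.
#'
#' @param data Long-format expression table with columns `sample_id`,
#'   `replicate`, `timepoint`, `luminescence`, and optionally `cell_line`.
#' @param schedule The declared collection timepoints, hours.
#' @return A tibble with one row per sample x replicate (x cell line):
#'   `total` is the cumulative luminescence.
#' @export
cumulative_expression <- function(data, schedule = c(16, 40, 64, 88)) {
  data <- tibble::as_tibble(data)
  need <- c("sample_id", "replicate", "timepoint", "luminescence")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(data$timepoint %in% schedule)) {
    abort("Timepoints outside the declared schedule.")
  }
  if (any(data$luminescence < 0, na.rm = TRUE)) {
    abort("Luminescence must be >= 0.")
  }
  keys <- intersect(c("cell_line", "sample_id", "replicate"), names(data))
  totals <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_timepoints = dplyr::n_distinct(timepoint),
      total = sum(luminescence),
      .groups = "drop"
    )
  incomplete <- totals$n_timepoints < length(schedule)
  if (any(incomplete)) {
    warn(sprintf("%d replicate(s) missing scheduled timepoints were excluded.",
                 sum(incomplete)))
    totals <- totals[!incomplete, ]
  }
  totals$n_timepoints <- NULL
  totals
}

#' Normalize cumulative expression to a reference cap
#'
#' Divides each replicate total by the mean of the reference sample's totals
#' (within the same cell line / batch when that column is present), then
#' summarizes each sample as mean +- sample SD of its normalized replicates.
#' The reference sample's normalized mean is exactly 1 by construction, and
#' its SD equals its coefficient of variation.
#'
#' @param totals Per-replicate totals from [cumulative_expression()].
#' @param reference Label of the reference sample (the unmodified cap-1
#'   trinucleotide by default).
#' @param summarize Return per-sample summaries (default) or per-replicate
#'   normalized totals.
#' @return A tibble: per sample (`sample_id`, optional `cell_line`, `n`,
#'   `normalized_mean`, `normalized_sd`), or per replicate with a
#'   `normalized` column when `summarize = FALSE`.
#' @export
normalize_expression <- function(totals,
                                 reference = "m7GpppAmpG",
                                 summarize = TRUE) {
  totals <- tibble::as_tibble(totals)
  stopifnot(all(c("sample_id", "replicate", "total") %in% names(totals)))
  if (!reference %in% totals$sample_id) {
    abort(sprintf("Reference sample '%s' not present.", reference))
  }
  batch <- intersect("cell_line", names(totals))
  grouped <- if (length(batch)) dplyr::group_by(totals, dplyr::across(dplyr::all_of(batch))) else totals
  normed <- grouped |>
    dplyr::mutate(
      .ref_mean = mean(total[sample_id == reference]),
      normalized = total / .ref_mean
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(normed$normalized))) {
    abort("Reference mean is zero; cannot normalize.")
  }
  normed$.ref_mean <- NULL
  if (!summarize) {
    return(normed)
  }
  normed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(batch, "sample_id")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      normalized_mean = mean(normalized),
      normalized_sd = if (dplyr::n() > 1) sd(normalized) else NA_real_,
      .groups = "drop"
    )
}
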