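#' Nucleotide amount from optical density
#'
#' Converts an optical-density measure (`mOD` = absorbance of the pooled
#' solution x its volume in ml) into a molar amount via the Beer-Lambert
#' law: `amount [umol] = mOD / (epsilon * path)`, with the extinction
#' coefficient in L mmol^-1 cm^-1 and a 1 cm default path. Conventional
#' coefficients at 260 nm: 32.0 for trinucleotide cap analogs, 27.1 for
#' A/G-containing dinucleotides, 11.4 for 7-methylguanosine mononucleotides.
#'
#' @param mOD Optical density measure(s), ml x OD units (>= 0). Vectorized.
#' @param epsilon Extinction coefficient(s), L mmol^-1 cm^-1 (> 0).
#' @param path Optical path length, cm.
#' @return Amount(s) in umol.
#' @examples
#' amount_from_mOD(12060, 11.4) # ~1058 umol = 1.06 mmol
#' @export
amount_from_mOD <- function(mOD, epsilon, path = 1) {
  if (any(mOD < 0)) abort("`mOD` must be >= 0.")
  if (any(epsilon <= 0)) abort("`epsilon` must be > 0.")
  if (any(path <= 0)) abort("`path` must be > 0.")
  mOD / (epsilon * path)
}

#' Percent synthesis yield
#'
#' `100 * product / start`. Yields above 100% (possible when amounts are
#' quantitated with different extinction coefficients or carry-over) are
#' reported as-is but flagged in the `capped` attribute.
#'
#' @param product_umol Product amount, umol.
#' @param start_umol Starting amount, umol (> 0).
#' @return Percent yield(s); attribute `capped` is `TRUE` where the yield
#'   exceeds 100%.
#' @export
percent_yield <- function(product_umol, start_umol) {
  if (any(start_umol <= 0)) abort("`start_umol` must be > 0.")
  if (any(product_umol < 0)) abort("`product_umol` must be >= 0.")
  y <- 100 * product_umol / start_umol
  if (any(y > 100)) warn("Yield above 100% - check quantitation inputs.")
  structure(y, capped = y > 100)
}

#' Quantitate a table of optical-density measurements
#'
#' Tidy wrapper over [amount_from_mOD()] and [percent_yield()]: takes a
#' table with one row per compound and returns it with amounts (and yields,
#' when starting amounts are present) appended.
#'
#' @param data A data frame with columns `compound`, `mOD`, `epsilon`,
#'   optionally `path` (cm) and `start_umol`.
#' @return The input tibble with `amount_umol` (and `yield_percent` if
#'   `start_umol` was supplied) added.
#' @export
quantitate_nucleotides <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("compound", "mOD", "epsilon")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", ")))
  }
  path <- if ("path" %in% names(data)) data$path else 1
  out <- dplyr::mutate(data, amount_umol = amount_from_mOD(mOD, epsilon, path))
  if ("start_umol" %in% names(out)) {
    out$yield_percent <- as.numeric(percent_yield(out$amount_umol, out$start_umol))
  }
  out
}
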