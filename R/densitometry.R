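#' Asymmetric least-squares baseline estimation
#'
#' Estimates a slowly varying baseline under a lane trace by iteratively
#' reweighted penalized least squares (Eilers-style asymmetric smoothing):
#' points above the current baseline get a small weight `p`, points below get
#' `1 - p`, so peaks are ignored while the smooth drift is followed. The
#' smoother solves `(W + lambda * D'D) z = W y` with `D` the second
#' difference operator, on sparse matrices.
#'
#' @param intensity Numeric trace.
#' @param lambda Smoothness penalty (larger = stiffer baseline).
#' @param p Asymmetry weight for points above the baseline, in (0, 0.5).
#' @param maxit Maximum reweighting iterations.
#' @return The estimated baseline, same length as `intensity`.
#' @export
estimate_baseline <- function(intensity, lambda = 1e6, p = 0.01, maxit = 20) {
  n <- length(intensity)
  if (n < 10) abort("Trace too short for baseline estimation.")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2),
                                           rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- intensity
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * intensity))
    w_new <- ifelse(intensity > z_new, p, 1 - p)
    done <- all(w_new == w)
    w <- w_new
    z <- z_new
    if (done) break
  }
  z
}

#' Detect and integrate bands in a lane profile
#'
#' Subtracts an asymmetric least-squares baseline, finds peaks as local
#' maxima exceeding a prominence threshold (a fraction of the tallest
#' baseline-corrected signal), and integrates each peak by the trapezoidal
#' rule between its flanking valley minima. Flat-topped (saturated) peaks
#' are flagged.
#'
#' @param profile A data frame with strictly monotone `position` and
#'   non-negative `intensity` columns (e.g. from [sim_lane_profile()] or
#'   [read_lane_profile()]).
#' @param min_prominence Peak acceptance threshold as a fraction of the
#'   maximum baseline-corrected intensity.
#' @param baseline Logical: estimate and subtract a baseline first?
#' @param lambda,p Baseline-smoother settings (see [estimate_baseline()]).
#' @param smooth_window Width (points) of the Savitzky-Golay filter applied
#'   before peak *detection* (the integration itself uses the unsmoothed
#'   signal); `NULL` picks an odd window of about 2% of the trace length.
#'   Set to 1 to disable smoothing.
#' @return A tibble of class `cap_bands`, one row per detected band:
#'   `band_id` (ordered by position), `position` (peak apex), `area`
#'   (integrated intensity above baseline), `height`, `saturated`. Empty
#'   (zero-row) when no peaks are found.
#' @export
integrate_bands <- function(profile,
                            min_prominence = 0.05,
                            baseline = TRUE,
                            lambda = 1e6,
                            p = 0.01,
                            smooth_window = NULL) {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("position", "intensity") %in% names(profile)))
  x <- profile$position
  y <- profile$intensity
  if (is.unsorted(x, strictly = TRUE)) {
    abort("`position` must be strictly increasing.")
  }
  base <- if (baseline) estimate_baseline(y, lambda = lambda, p = p) else rep(0, length(y))
  ys <- y - base
  n <- length(ys)

  # peak detection runs on a lightly smoothed copy so instrument noise does
  # not fragment a band into several local maxima
  if (is.null(smooth_window)) {
    smooth_window <- max(5L, 2L * floor(n * 0.01) + 1L)
  }
  yd <- if (smooth_window > 1 && n > smooth_window) {
    pracma::savgol(ys, smooth_window, forder = 3)
  } else {
    ys
  }

  empty <- tibble::tibble(band_id = character(), position = numeric(),
                          area = numeric(), height = numeric(),
                          saturated = logical())
  class(empty) <- c("cap_bands", class(empty))

  # acceptance threshold: a fraction of the tallest signal, floored at a
  # robust multiple of the point-to-point noise so a featureless noisy
  # trace yields no bands
  noise_floor <- 6 * stats::mad(ys - yd)
  thresh <- max(min_prominence * max(yd), noise_floor)
  if (!is.finite(thresh) || max(yd) <= 0 || max(yd) < thresh) return(empty)

  is_peak <- which(yd[-c(1, n)] >= yd[-c(n - 1, n)] &
                     yd[-c(1, n)] >= yd[-c(1, 2)] &
                     yd[-c(1, n)] >= thresh) + 1L
  if (length(is_peak) == 0) return(empty)
  # collapse plateaus to a single apex
  keep <- c(TRUE, diff(is_peak) > 1)
  groups <- cumsum(keep)
  apex <- vapply(split(is_peak, groups), function(ix) ix[ceiling(length(ix) / 2)],
                 numeric(1))
  apex <- as.integer(apex)
  # merge residual noise maxima closer than the detection smoothing scale,
  # keeping the taller apex of each pair
  min_sep <- max(smooth_window, 3L)
  while (length(apex) > 1 && any(diff(apex) < min_sep)) {
    i <- which(diff(apex) < min_sep)[1]
    drop <- if (yd[apex[i]] >= yd[apex[i + 1]]) i + 1 else i
    apex <- apex[-drop]
  }

  # integration limits: valley minima between neighbouring peaks, trace ends
  # outside the outermost peaks, shrunk to each band's support (where the
  # detection trace exceeds 0.5% of the apex)
  k <- length(apex)
  left <- integer(k)
  right <- integer(k)
  for (i in seq_len(k)) {
    lo <- if (i == 1) 1L else {
      seg <- apex[i - 1]:apex[i]
      seg[which.min(yd[seg])]
    }
    hi <- if (i == k) n else {
      seg <- apex[i]:apex[i + 1]
      seg[which.min(yd[seg])]
    }
    edge <- 0.005 * yd[apex[i]]
    while (lo < apex[i] && yd[lo] < edge) lo <- lo + 1L
    while (hi > apex[i] && yd[hi] < edge) hi <- hi - 1L
    left[i] <- lo
    right[i] <- hi
  }

  # second-pass baseline: re-smooth the raw trace with the detected band
  # regions (padded) given zero weight, so off-band points are fitted
  # unbiasedly (not at a low quantile) and the baseline interpolates
  # smoothly underneath each band
  if (baseline) {
    pad <- max(smooth_window, 3L)
    w2 <- rep(1, n)
    for (i in seq_len(k)) {
      w2[max(1, left[i] - pad):min(n, right[i] + pad)] <- 0
    }
    if (any(w2 > 0)) {
      base <- whittaker_baseline(y, w2, lambda = lambda)
      ys <- y - base
    }
  }
  area <- vapply(seq_len(k), function(i) {
    ix <- left[i]:right[i]
    max(pracma::trapz(x[ix], ys[ix]), 0)
  }, numeric(1))
  saturated <- vapply(seq_len(k), function(i) {
    ix <- left[i]:right[i]
    sum(y[ix] == max(y[ix])) >= 3 # flat-topped raw signal
  }, logical(1))

  out <- tibble::tibble(
    band_id = paste0("band_", seq_len(k)),
    position = x[apex],
    area = area,
    height = yd[apex],
    saturated = saturated
  )
  if (any(saturated)) warn("Flat-topped (possibly saturated) peak detected.")
  attr(out, "baseline") <- base
  class(out) <- c("cap_bands", class(out))
  out
}

# Weighted Whittaker smoother: penalized least squares with fixed weights
# (zero inside band supports), used for the second-pass baseline.
whittaker_baseline <- function(y, w, lambda = 1e6) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2),
                                           rep(-2, n - 2),
                                           rep(1, n - 2)))
  as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + lambda * Matrix::crossprod(D),
                           w * y))
}

band_area <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1) abort("Band area must be a single number.")
    return(x)
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !"area" %in% names(x)) {
      abort("Expected a one-row band table with an `area` column.")
    }
    return(x$area)
  }
  abort("Band must be a number or a one-row band table.")
}

#' Capping efficiency from capped and uncapped band areas
#'
#' The fraction of in vitro transcripts carrying a cap, estimated as the
#' ratio of the capped-RNA band to the sum of the capped and uncapped RNA
#' bands on a denaturing gel: `CE = A_capped / (A_capped + A_uncapped)`.
#'
#' @param capped,uncapped Integrated band areas (numbers or one-row band
#'   tables from [integrate_bands()]).
#' @return Capping efficiency as a fraction in `[0, 1]`.
#' @examples
#' capping_efficiency(90, 10)
#' @export
capping_efficiency <- function(capped, uncapped) {
  a <- band_area(capped)
  b <- band_area(uncapped)
  if (a < 0 || b < 0) abort("Band areas must be >= 0.")
  if (a + b == 0) abort("Both band areas are zero.")
  a / (a + b)
}

#' Identify the capped and uncapped bands in a lane
#'
#' Assigns band identities either by proximity to caller-supplied expected
#' positions, or — by default — by migration order, labelling the band at the
#' larger migration coordinate `capped` (capped RNA is longer and runs more
#' slowly).
#'
#' @param bands A `cap_bands` table with exactly two usable bands (the two
#'   largest by area are used when more are present).
#' @param expected Optional named vector
#'   `c(capped = <position>, uncapped = <position>)`.
#' @return The two-row band table with `band_id` set to `capped`/`uncapped`.
#' @export
assign_cap_bands <- function(bands, expected = NULL) {
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) < 2) abort("Need at least two bands to assign capped/uncapped.")
  top2 <- dplyr::slice_max(bands, area, n = 2, with_ties = FALSE)
  if (!is.null(expected)) {
    stopifnot(all(c("capped", "uncapped") %in% names(expected)))
    d_cap <- abs(top2$position - expected[["capped"]])
    d_unc <- abs(top2$position - expected[["uncapped"]])
    cap_ix <- if (which.min(d_cap) != which.min(d_unc)) which.min(d_cap) else which.max(d_unc)
  } else {
    cap_ix <- which.max(top2$position)
  }
  top2$band_id <- ifelse(seq_len(2) == cap_ix, "capped", "uncapped")
  dplyr::arrange(top2, dplyr::desc(band_id == "capped"))
}

#' Decapping time course and susceptibility statistic
#'
#' Computes the capped fraction at each timepoint from capped/uncapped band
#' areas, the fraction of initially capped RNA remaining
#' (`remaining(t) = cf(t) / cf(0)` when `normalize = TRUE`), and the
#' decapping susceptibility `decapped_at = 1 - remaining(query_time)`,
#' clipped to `[0, 1]`.
#'
#' @param band_table A tibble (`timepoint`, `band_id` in
#'   `c("capped", "uncapped")`, `area`), e.g. from [sim_decapping_series()].
#' @param query_time Timepoint (minutes) at which susceptibility is reported;
#'   must be present in the table (no interpolation).
#' @param normalize Normalize to the t = 0 capped fraction (default), so
#'   incomplete initial capping does not inflate apparent decapping.
#' @return A list of class `cap_decapping`: `series` (tibble with
#'   `timepoint`, `capped_fraction`, `remaining`, `decapped`), `decapped_at`,
#'   `query_time`.
#' @export
decapping_course <- function(band_table, query_time = 30, normalize = TRUE) {
  band_table <- tibble::as_tibble(band_table)
  stopifnot(all(c("timepoint", "band_id", "area") %in% names(band_table)))
  wide <- tidyr::pivot_wider(band_table, id_cols = "timepoint",
                             names_from = "band_id", values_from = "area")
  if (!all(c("capped", "uncapped") %in% names(wide))) {
    abort("`band_table` must contain capped and uncapped bands.")
  }
  wide <- dplyr::arrange(wide, timepoint)
  if (!0 %in% wide$timepoint) abort("Timepoint 0 is required.")
  if (!query_time %in% wide$timepoint) {
    abort(sprintf("Query time %s min is not in the series (no interpolation).",
                  query_time))
  }
  wide$capped_fraction <- wide$capped / (wide$capped + wide$uncapped)
  cf0 <- wide$capped_fraction[wide$timepoint == 0]
  if (cf0 == 0) abort("Capped fraction at t = 0 is zero.")
  wide$remaining <- if (normalize) wide$capped_fraction / cf0 else wide$capped_fraction
  if (any(wide$remaining > 1 + 1e-12)) {
    warn("Capped fraction above its t = 0 value (noise); decapped values clipped to 0.")
  }
  wide$decapped <- pmin(pmax(1 - wide$remaining, 0), 1)
  structure(
    list(
      series = wide[c("timepoint", "capped_fraction", "remaining", "decapped")],
      decapped_at = wide$decapped[wide$timepoint == query_time],
      query_time = query_time
    ),
    class = "cap_decapping"
  )
}

#' @export
print.cap_decapping <- function(x, ...) {
  cat("<cap_decapping>\n")
  print(x$series)
  cat(sprintf("  decapped at %g min: %.3f\n", x$query_time, x$decapped_at))
  invisible(x)
}

#' Mean and sample standard deviation of replicate fractions
#'
#' @param values Numeric replicate values (fractions or any measurement).
#' @return A one-row tibble: `mean`, `sd` (n-1 denominator; `NA` with a
#'   warning when only one value is supplied), `n`.
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) abort("No values supplied.")
  if (length(values) == 1) warn("Single value: SD is undefined.")
  tibble::tibble(
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else NA_real_,
    n = length(values)
  )
}

#' Plot a lane profile with its estimated baseline and detected bands
#'
#' @param object A `cap_lane` tibble.
#' @param bands Optional `cap_bands` result to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cap_lane
#' @export
autoplot.cap_lane <- function(object, bands = NULL, ...) {
  pl <- ggplot2::ggplot(object, ggplot2::aes(position, intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "migration coordinate", y = "intensity (a.u.)")
  if (!is.null(bands)) {
    base <- attr(bands, "baseline")
    if (!is.null(base)) {
      pl <- pl + ggplot2::geom_line(
        data = tibble::tibble(position = object$position, intensity = base),
        colour = "steelblue", linetype = 2
      )
    }
    pl <- pl + ggplot2::geom_vline(xintercept = bands$position,
                                   colour = "firebrick", alpha = 0.5)
  }
  pl
}
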