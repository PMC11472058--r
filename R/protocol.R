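#' Describe a fluorescence titration protocol
#'
#' Captures everything needed to turn raw aliquot/fluorescence readings into
#' a corrected binding curve: the starting cuvette volume and protein
#' concentration, the sequence of titrant aliquots with their stock
#' concentrations, and the optical constants that drive the inner-filter
#' correction. Defaults reflect a standard quenching titration of eIF4E:
#' 1 ul aliquots added to 1.4 ml of 0.1 uM protein in a semi-micro cuvette
#' with 4 mm absorption and 10 mm emission paths.
#'
#' @param aliquot_ul Volumes of the successive titrant aliquots, ul.
#' @param stock_uM Stock concentration of each aliquot, uM (same length).
#' @param start_volume_ul Starting volume in the cuvette, ul.
#' @param protein_uM Nominal starting protein concentration, uM.
#' @param eps_ex,eps_em Molar extinction coefficients of the titrant at the
#'   excitation and emission wavelengths, L mmol^-1 cm^-1. The default keeps
#'   the excitation-side value typical of a trinucleotide cap (32.0) and
#'   assumes negligible absorbance at the emission wavelength.
#' @param path_ex_cm,path_em_cm Optical path lengths for absorption and
#'   emission, cm.
#' @return An object of class `cap_protocol` (a list).
#' @examples
#' titration_protocol(rep(1, 5), c(5, 10, 20, 40, 80))
#' @export
titration_protocol <- function(aliquot_ul,
                               stock_uM,
                               start_volume_ul = 1400,
                               protein_uM = 0.1,
                               eps_ex = 32.0,
                               eps_em = 0,
                               path_ex_cm = 0.4,
                               path_em_cm = 1.0) {
  if (length(aliquot_ul) != length(stock_uM)) {
    abort("`aliquot_ul` and `stock_uM` must have the same length.")
  }
  vals <- c(aliquot_ul, stock_uM, start_volume_ul, protein_uM,
            eps_ex, eps_em, path_ex_cm, path_em_cm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("Protocol volumes, concentrations and optical constants must be finite and >= 0.")
  }
  structure(
    list(
      aliquot_ul = as.numeric(aliquot_ul),
      stock_uM = as.numeric(stock_uM),
      start_volume_ul = start_volume_ul,
      protein_uM = protein_uM,
      eps_ex = eps_ex,
      eps_em = eps_em,
      path_ex_cm = path_ex_cm,
      path_em_cm = path_em_cm
    ),
    class = "cap_protocol"
  )
}

#' @export
print.cap_protocol <- function(x, ...) {
  cat("<cap_protocol>\n")
  cat(sprintf("  %d aliquots into %.0f ul of %.3g uM protein\n",
              length(x$aliquot_ul), x$start_volume_ul, x$protein_uM))
  cat(sprintf("  stocks %.3g-%.3g uM; eps_ex/em %.3g/%.3g L/mmol/cm; paths %.2g/%.2g cm\n",
              min(x$stock_uM), max(x$stock_uM), x$eps_ex, x$eps_em,
              x$path_ex_cm, x$path_em_cm))
  invisible(x)
}

#' Design a titration protocol that reaches prescribed ligand concentrations
#'
#' Computes the escalating stock concentrations such that after aliquot `i`
#' the cumulative total ligand concentration in the cuvette equals
#' `target_L_uM[i]`, for fixed-size aliquots. By default the targets are
#' log-spaced between `span[1]` and `span[2]` times the expected dissociation
#' constant — a design that samples the ligand-depletion curve from its
#' sub-stoichiometric foot to well past saturation.
#'
#' @details With `spacing = "response"` (the default) the targets are placed
#' where the information about the association constant lives: most points
#' are spaced uniformly in the *expected bound fraction* (computed from
#' `kd_nM` and the protein concentration via the ligand-depletion
#' equilibrium), with a few logarithmic anchor points below and above the
#' transition to pin down the initial fluorescence and the free-ligand
#' slope. `spacing = "geometric"` gives plain log-spaced targets. In either
#' case the highest target is raised, if necessary, to
#' `saturation_factor` times the protein concentration so the protein can
#' be driven to saturation even when `K_D` is far below the protein
#' concentration.
#'
#' @param kd_nM Expected dissociation constant, nM (sets the span).
#' @param n_points Number of titration points (aliquots).
#' @param span Multiples of the expected K_D covered by the cumulative ligand
#'   concentration, low and high.
#' @param spacing Target placement: `"response"` (transition-weighted,
#'   default) or `"geometric"`.
#' @param saturation_factor Minimum top concentration as a multiple of the
#'   protein concentration.
#' @param target_L_uM Optional explicit cumulative ligand targets, uM;
#'   overrides `kd_nM`/`span`/`spacing`.
#' @param aliquot_ul Aliquot volume, ul (all aliquots equal).
#' @inheritParams titration_protocol
#' @param ... Passed on to [titration_protocol()] (optical constants etc.).
#' @return A `cap_protocol`.
#' @export
design_titration_protocol <- function(kd_nM = 42.1,
                                      n_points = 40,
                                      span = c(0.1, 20),
                                      spacing = c("response", "geometric"),
                                      saturation_factor = 8,
                                      target_L_uM = NULL,
                                      aliquot_ul = 1,
                                      start_volume_ul = 1400,
                                      protein_uM = 0.1,
                                      ...) {
  spacing <- match.arg(spacing)
  if (is.null(target_L_uM)) {
    kd_uM <- kd_nM / 1000
    lo <- span[1] * kd_uM
    hi <- max(span[2] * kd_uM, saturation_factor * protein_uM)
    if (spacing == "geometric") {
      target_L_uM <- exp(seq(log(lo), log(hi), length.out = n_points))
    } else {
      K <- 1 / kd_uM
      P <- protein_uM
      f <- seq(0.05, 0.97, length.out = max(n_points - 10, 5))
      cx <- f * P
      L_mid <- cx + cx / (K * (P - cx))
      L_mid <- L_mid[L_mid < hi]
      L_lo <- exp(seq(log(lo), log(L_mid[1]), length.out = 6))[-6]
      n_hi <- max(n_points - length(L_mid) - 5, 2)
      L_hi <- exp(seq(log(max(L_mid)), log(hi), length.out = n_hi))[-1]
      target_L_uM <- sort(unique(c(L_lo, L_mid, L_hi)))
    }
  }
  if (is.unsorted(target_L_uM, strictly = TRUE)) {
    abort("`target_L_uM` must be strictly increasing.")
  }
  n <- length(target_L_uM)
  v <- rep(aliquot_ul, n)
  stock <- numeric(n)
  carried <- 0 # cumulative nmol of ligand already in the cuvette (uM * ul)
  for (i in seq_len(n)) {
    V_i <- start_volume_ul + i * aliquot_ul
    need <- target_L_uM[i] * V_i - carried
    if (need < 0) {
      abort("Dilution outpaces the requested targets; space them more widely.")
    }
    stock[i] <- need / aliquot_ul
    carried <- carried + stock[i] * aliquot_ul
  }
  titration_protocol(v, stock,
                     start_volume_ul = start_volume_ul,
                     protein_uM = protein_uM, ...)
}
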