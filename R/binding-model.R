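#' Equilibrium concentration of the cap-eIF4E complex
#'
#' Solves the single-site binding equilibrium under ligand depletion: for
#' total ligand `L`, total active protein `P_act` and association constant
#' `K_as`, the complex concentration `cx` is the physically admissible root of
#' `K_as * (L - cx) * (P_act - cx) = cx`. Because titrations of eIF4E run at
#' protein concentrations comparable to the dissociation constant, the
#' free-ligand approximation does not hold and this quadratic ("tight
#' binding") form is required.
#'
#' The closed form is evaluated through the numerically stable rationalized
#' root `cx = 2 K L P / (b + sqrt(b^2 - 4 K^2 L P))` with
#' `b = K (L + P) + 1`, which avoids catastrophic cancellation when binding
#' is weak; it is algebraically identical to the textbook expression
#' `((L + P + 1/K) - sqrt((L + P + 1/K)^2 - 4 L P)) / 2`.
#'
#' @param L Total ligand (cap analog) concentration, uM. Vectorized.
#' @param P_act Total active protein concentration, uM. Scalar or same length
#'   as `L`.
#' @param K_as Association constant, 1/uM. Scalar.
#' @return Complex concentration in uM, same length as `L`; always within
#'   `[0, min(L, P_act)]`. `K_as = 0` returns 0 (no binding limit).
#' @examples
#' complex_concentration(0.1, 0.1, 23.753)
#' @export
complex_concentration <- function(L, P_act, K_as) {
  if (any(L < 0) || any(P_act < 0)) {
    abort("`L` and `P_act` must be non-negative concentrations.")
  }
  if (length(K_as) != 1L || is.na(K_as) || K_as < 0) {
    abort("`K_as` must be a single non-negative association constant.")
  }
  if (K_as == 0) {
    return(rep(0, length(L)))
  }
  b <- K_as * (L + P_act) + 1
  disc <- b^2 - 4 * K_as^2 * L * P_act
  disc[disc < 0] <- 0 # guard tiny negative round-off
  cx <- 2 * K_as * L * P_act / (b + sqrt(disc))
  pmin(pmax(cx, 0), pmin(L, P_act))
}

#' Model fluorescence of a titration point
#'
#' Predicted (corrected) fluorescence of an eIF4E solution titrated with a
#' cap analog: `F = F0 - cx * (delta_phi + phi_lig_free) + L * phi_lig_free`,
#' where `cx` is the ligand-depletion complex concentration. `delta_phi` is
#' the difference between the fluorescence efficiencies of the apo and
#' cap-bound protein (quench amplitude per uM of complex) and `phi_lig_free`
#' the fluorescence efficiency of the free cap analog.
#'
#' @param L Total ligand concentration, uM (vectorized).
#' @param params Named list or vector with elements `K_as` (1/uM), `P_act`
#'   (uM), `F0`, `delta_phi`, `phi_lig_free`.
#' @param P_at_point Optional per-point total protein concentration (uM),
#'   overriding `params$P_act` to account for dilution along the titration.
#' @return Predicted fluorescence, arbitrary units.
#' @export
model_fluorescence <- function(L, params, P_at_point = NULL) {
  p <- as.list(params)
  needed <- c("K_as", "P_act", "F0", "delta_phi", "phi_lig_free")
  if (!all(needed %in% names(p))) {
    abort(paste0(
      "`params` must contain: ", paste(needed, collapse = ", ")
    ))
  }
  P <- P_at_point %||% p$P_act
  cx <- complex_concentration(L, P, p$K_as)
  p$F0 - cx * (p$delta_phi + p$phi_lig_free) + L * p$phi_lig_free
}

#' Convert between association constants and dissociation constants
#'
#' `K_as` is carried in 1/uM internally; dissociation constants are reported
#' in nM, so `K_D [nM] = 1000 / K_as [1/uM]`. Standard errors propagate by
#' the delta method: `SE(K_D) = 1000 * SE(K_as) / K_as^2`.
#'
#' @param K_as Association constant(s), 1/uM.
#' @param se Optional standard error(s) of `K_as`.
#' @return If `se` is `NULL`, a numeric vector of `K_D` in nM; otherwise a
#'   tibble with columns `kd_nM` and `kd_se_nM`.
#' @export
kas_to_kd <- function(K_as, se = NULL) {
  kd <- 1000 / K_as
  if (is.null(se)) {
    return(kd)
  }
  tibble::tibble(kd_nM = kd, kd_se_nM = 1000 * se / K_as^2)
}
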