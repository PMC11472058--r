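#' Build a corrected binding curve from raw titration readings
#'
#' Converts a raw titration table (one row per reading, including the
#' ligand-free point) into the corrected curve the binding model is fitted
#' to. Per point `i` with cumulative volume `V_i`:
#' * total ligand `L_i = sum(c_j v_j) / V_i` (uM),
#' * total protein `P_i = P0 V0 / V_i` (dilution of the protein),
#' * `F_corrected = F_obs * (V_i / V0) * 10^((A_ex + A_em) / 2)`, the
#'   multiplicative dilution correction times the geometric-mean inner-filter
#'   correction, with `A_ex = eps_ex * L_i[mM] * path_ex` and likewise for
#'   emission. Only the titrant contributes to the changing absorbance.
#'
#' @param raw A data frame with columns `aliquot_ul`, `stock_uM`, `F_obs`.
#'   The first row must be the ligand-free reading (`aliquot_ul = 0`).
#' @param protocol A [titration_protocol()] supplying the start volume,
#'   protein concentration and optical constants. Its aliquot list must match
#'   the non-zero aliquots of `raw`.
#' @return A tibble of class `cap_titration` with columns `L_total`,
#'   `P_at_point`, `F_obs`, `dilution_factor`, `inner_filter_factor`,
#'   `F_corrected`; the protocol is attached as an attribute.
#' @export
build_titration_curve <- function(raw, protocol) {
  stopifnot(inherits(protocol, "cap_protocol"))
  raw <- tibble::as_tibble(raw)
  need <- c("aliquot_ul", "stock_uM", "F_obs")
  if (!all(need %in% names(raw))) {
    abort(paste0("`raw` must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(raw) < 1 || raw$aliquot_ul[1] != 0) {
    abort("The first row of `raw` must be the ligand-free reading (aliquot_ul = 0).")
  }
  if (any(is.na(raw$stock_uM[-1]))) {
    abort("Missing stock concentration in `raw`.")
  }
  added <- raw$aliquot_ul[-1]
  if (length(added) != length(protocol$aliquot_ul) ||
      any(abs(added - protocol$aliquot_ul) > 1e-9)) {
    abort("Aliquot volumes in `raw` do not match the protocol.")
  }
  V0 <- protocol$start_volume_ul
  V <- V0 + cumsum(raw$aliquot_ul)
  if (is.unsorted(V)) abort("Cumulative volumes must be non-decreasing.")
  L <- cumsum(raw$stock_uM * raw$aliquot_ul) / V
  P <- protocol$protein_uM * V0 / V
  A_ex <- protocol$eps_ex * (L / 1000) * protocol$path_ex_cm
  A_em <- protocol$eps_em * (L / 1000) * protocol$path_em_cm
  dil <- V / V0
  iff <- 10^((A_ex + A_em) / 2)
  out <- tibble::tibble(
    point = seq_len(nrow(raw)) - 1L,
    L_total = L,
    P_at_point = P,
    F_obs = raw$F_obs,
    dilution_factor = dil,
    inner_filter_factor = iff,
    F_corrected = raw$F_obs * dil * iff
  )
  attr(out, "protocol") <- protocol
  class(out) <- c("cap_titration", class(out))
  out
}

free_param_names <- c("K_as", "P_act", "F0", "delta_phi", "phi_lig_free")

# Residual vector for the binding model on a corrected curve.
# `r_dil` is the per-point protein dilution profile (P_at_point / nominal P).
binding_residuals <- function(free, fixed, curve, r_dil) {
  p <- c(as.list(free), fixed)
  P <- p$P_act * r_dil
  pred <- p$F0 -
    complex_concentration(curve$L_total, P, p$K_as) *
      (p$delta_phi + p$phi_lig_free) +
    curve$L_total * p$phi_lig_free
  pred - curve$F_corrected
}

#' Fit the ligand-depletion binding model to a titration curve
#'
#' Least-squares fit of the quenching model
#' `F = F0 - cx * (delta_phi + phi_lig_free) + L * phi_lig_free` with the
#' quadratic ligand-depletion complex concentration `cx`. All five parameters
#' (`K_as`, `P_act`, `F0`, `delta_phi`, `phi_lig_free`) are free by default;
#' any subset can be fixed. Fitting is a bounded Levenberg-Marquardt search
#' multi-started over a log-spaced grid of `K_as` values; the best
#' sum-of-squares wins, ties resolved toward the smaller `K_as`. Standard
#' errors come from the residual-variance-scaled inverse curvature at the
#' optimum.
#'
#' `P_act` is bounded within `[0.2, 1.5]` times the protocol's nominal
#' protein concentration to prevent exchange with the quench amplitude.
#'
#' @param curve A `cap_titration` from [build_titration_curve()].
#' @param fix Named list of parameters to hold fixed (e.g.
#'   `list(phi_lig_free = 0)`).
#' @param p_mode `"per_point"` (default) scales the fitted `P_act` by the
#'   per-point dilution profile; `"fixed"` ignores protein dilution.
#' @param n_starts Number of log-spaced `K_as` starting values.
#' @param kas_range Range (1/uM) covered by the multi-start grid.
#' @param ftol,ptol Relative convergence tolerances passed to the optimizer.
#' @return An object of class `cap_binding_fit`; see [tidy.cap_binding_fit()]
#'   and [glance.cap_binding_fit()].
#' @export
fit_titration <- function(curve,
                          fix = list(),
                          p_mode = c("per_point", "fixed"),
                          n_starts = 12,
                          kas_range = c(1e-3, 1e3),
                          ftol = 1e-10,
                          ptol = 1e-10) {
  p_mode <- match.arg(p_mode)
  stopifnot(is.data.frame(curve))
  if (!all(c("L_total", "F_corrected", "P_at_point") %in% names(curve))) {
    abort("`curve` must have columns L_total, F_corrected, P_at_point (see build_titration_curve()).")
  }
  if (nrow(curve) < 6) abort("At least 6 titration points are required.")
  if (length(fix) && !all(names(fix) %in% free_param_names)) {
    abort("Unknown parameter name in `fix`.")
  }

  protocol <- attr(curve, "protocol")
  P_nom <- if (!is.null(protocol)) protocol$protein_uM else max(curve$P_at_point)
  r_dil <- if (p_mode == "per_point") curve$P_at_point / P_nom else rep(1, nrow(curve))

  # Heuristic starts: F0 from the ligand-free reading, quench amplitude from
  # the observed drop, free-ligand slope from the saturated tail.
  F0_start <- curve$F_corrected[which.min(curve$L_total)]
  depth <- max(F0_start - min(curve$F_corrected), 0.05 * abs(F0_start), 1e-6)
  tail_n <- min(4L, nrow(curve) - 1L)
  tail_idx <- order(curve$L_total, decreasing = TRUE)[seq_len(tail_n)]
  tail_slope <- tryCatch(
    unname(coef(stats::lm(F_corrected ~ L_total, data = curve[tail_idx, ]))[2]),
    error = function(e) 0
  )
  start_base <- c(
    P_act = P_nom,
    F0 = F0_start,
    delta_phi = depth / max(P_nom, 1e-9),
    phi_lig_free = max(tail_slope, 0)
  )
  lower <- c(K_as = kas_range[1], P_act = 0.2 * P_nom, F0 = 0,
             delta_phi = 0, phi_lig_free = 0)
  upper <- c(K_as = kas_range[2], P_act = 1.5 * P_nom,
             F0 = 10 * max(abs(curve$F_corrected)),
             delta_phi = Inf, phi_lig_free = Inf)

  fixed <- as.list(fix)
  free_names <- setdiff(free_param_names, names(fixed))
  if (!"K_as" %in% free_names) {
    kas_starts <- fixed$K_as
  } else {
    kas_starts <- 10^seq(log10(kas_range[1]), log10(kas_range[2]),
                         length.out = n_starts)
  }

  best <- NULL
  for (k0 in kas_starts) {
    start <- c(K_as = unname(k0), start_base)[free_names]
    start <- pmin(pmax(start, lower[free_names]), upper[free_names])
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower[free_names], upper = upper[free_names],
        fn = binding_residuals, fixed = fixed, curve = curve, r_dil = r_dil,
        control = minpack.lm::nls.lm.control(
          ftol = ftol, ptol = ptol, maxiter = 500
        )
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ssr <- res$deviance
    better <- is.null(best) || ssr < best$deviance * (1 - 1e-12) ||
      (abs(ssr - best$deviance) <= best$deviance * 1e-12 &&
         "K_as" %in% free_names && res$par[["K_as"]] < best$par[["K_as"]])
    if (better) best <- res
  }
  if (is.null(best)) {
    abort("Titration fit failed to converge from every start.")
  }

  est <- best$par
  params <- c(as.list(est), fixed)[free_param_names]
  n <- nrow(curve)
  df_resid <- n - length(est)
  sigma2 <- best$deviance / max(df_resid, 1)

  # Curvature-based SEs: J'J from a numerical jacobian at the optimum.
  se <- setNames(rep(NA_real_, length(free_param_names)), free_param_names)
  J <- tryCatch(
    pracma::jacobian(
      function(th) binding_residuals(setNames(th, names(est)),
                                     fixed, curve, r_dil),
      unname(est)
    ),
    error = function(e) NULL
  )
  if (!is.null(J)) {
    covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covm)) {
      se[names(est)] <- sqrt(pmax(diag(covm), 0))
    }
  }

  at_bound <- vapply(names(est), function(nm) {
    span <- max(abs(est[nm]), 1)
    isTRUE(abs(est[nm] - lower[nm]) < 1e-8 * span) ||
      (is.finite(upper[nm]) && isTRUE(abs(est[nm] - upper[nm]) < 1e-8 * span))
  }, logical(1))
  if (any(at_bound)) {
    warn(paste0("Parameter(s) at bound: ",
                paste(names(est)[at_bound], collapse = ", ")))
  }

  kd <- kas_to_kd(params$K_as, se[["K_as"]])
  structure(
    list(
      params = params,
      se = se,
      fixed = names(fixed),
      ssr = best$deviance,
      sigma = sqrt(sigma2),
      n_points = n,
      df_residual = df_resid,
      converged = best$info %in% 1:4,
      at_bound = at_bound,
      kd_nM = kd$kd_nM,
      kd_se_nM = kd$kd_se_nM,
      p_mode = p_mode,
      curve = curve
    ),
    class = "cap_binding_fit"
  )
}

#' @export
print.cap_binding_fit <- function(x, ...) {
  cat("<cap_binding_fit>\n")
  cat(sprintf("  K_as = %.4g 1/uM (SE %.3g)  =>  K_D = %.3g nM (SE %.3g)\n",
              x$params$K_as, x$se[["K_as"]], x$kd_nM, x$kd_se_nM))
  cat(sprintf("  %d points, SSR %.4g, converged: %s\n",
              x$n_points, x$ssr, x$converged))
  if (length(x$fixed)) {
    cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a binding fit into a parameter table
#'
#' @param x A `cap_binding_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`, `fixed`.
#' @method tidy cap_binding_fit
#' @export
tidy.cap_binding_fit <- function(x, ...) {
  tibble::tibble(
    term = free_param_names,
    estimate = unlist(x$params[free_param_names]),
    std.error = unname(x$se[free_param_names]),
    fixed = free_param_names %in% x$fixed
  )
}

#' One-row summary of a binding fit
#'
#' @param x A `cap_binding_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `kas_per_uM`, `kas_se`, `kd_nM`, `kd_se_nM`,
#'   `ssr`, `sigma`, `n_points`, `converged`.
#' @method glance cap_binding_fit
#' @export
glance.cap_binding_fit <- function(x, ...) {
  tibble::tibble(
    kas_per_uM = x$params$K_as,
    kas_se = unname(x$se[["K_as"]]),
    kd_nM = x$kd_nM,
    kd_se_nM = x$kd_se_nM,
    ssr = x$ssr,
    sigma = x$sigma,
    n_points = x$n_points,
    converged = x$converged
  )
}

#' Pool replicate binding fits by inverse-variance weighting
#'
#' Combines replicate association constants into a final value using the
#' standard meta-analytic fixed-effect rule: weights `w_i = 1 / SE_i^2`,
#' pooled `K = sum(w K) / sum(w)`, `SE = sqrt(1 / sum(w))`. The pooled
#' constant is reported as a dissociation constant in nM. Fits with missing
#' or zero standard errors trigger a fall-back to the unweighted mean (with
#' `method = "unweighted"`).
#'
#' @param fits A list of `cap_binding_fit` objects (a single fit is passed
#'   through), or a data frame with columns `kas_per_uM` and `kas_se`.
#' @return A one-row tibble of class `cap_binding_pool`: `kas_per_uM`,
#'   `kas_se`, `kd_nM`, `kd_se_nM`, `n_replicates`, `method`.
#' @export
pool_binding_fits <- function(fits) {
  if (inherits(fits, "cap_binding_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    k <- fits$kas_per_uM
    s <- fits$kas_se
  } else {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(conv)) abort("No converged fit to pool.")
    fits <- fits[conv]
    k <- vapply(fits, function(f) f$params$K_as, numeric(1))
    s <- vapply(fits, function(f) unname(f$se[["K_as"]]), numeric(1))
  }
  n <- length(k)
  if (n == 0) abort("No fits supplied.")
  ok <- is.finite(s) & s > 0
  if (all(ok)) {
    w <- 1 / s^2
    pooled <- sum(w * k) / sum(w)
    pooled_se <- sqrt(1 / sum(w))
    method <- "inverse_variance"
  } else {
    warn("Missing or zero standard errors; falling back to the unweighted mean.")
    pooled <- mean(k)
    pooled_se <- if (n > 1) sd(k) / sqrt(n) else NA_real_
    method <- "unweighted"
  }
  kd <- kas_to_kd(pooled, pooled_se)
  out <- tibble::tibble(
    kas_per_uM = pooled,
    kas_se = pooled_se,
    kd_nM = kd$kd_nM,
    kd_se_nM = kd$kd_se_nM,
    n_replicates = n,
    method = method
  )
  class(out) <- c("cap_binding_pool", class(out))
  out
}

#' Plot a titration curve, optionally with its fitted model
#'
#' @param object A `cap_titration` or `cap_binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cap_titration
#' @export
autoplot.cap_titration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(L_total, F_corrected)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total cap analog (uM)",
                  y = "corrected fluorescence (a.u.)")
}

#' @rdname autoplot.cap_titration
#' @method autoplot cap_binding_fit
#' @export
autoplot.cap_binding_fit <- function(object, ...) {
  curve <- object$curve
  grid <- tibble::tibble(
    L_total = exp(seq(log(max(min(curve$L_total[curve$L_total > 0]), 1e-6)),
                      log(max(curve$L_total)), length.out = 200))
  )
  P <- approx(curve$L_total, curve$P_at_point, xout = grid$L_total,
              rule = 2)$y
  if (object$p_mode == "per_point") {
    protocol <- attr(curve, "protocol")
    P_nom <- if (!is.null(protocol)) protocol$protein_uM else max(curve$P_at_point)
    P <- object$params$P_act * P / P_nom
  } else {
    P <- object$params$P_act
  }
  grid$F_fit <- model_fluorescence(grid$L_total, object$params, P_at_point = P)
  autoplot.cap_titration(curve) +
    ggplot2::geom_line(data = grid, ggplot2::aes(L_total, F_fit),
                       colour = "firebrick")
}
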