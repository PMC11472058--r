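# Shared fixtures for the test suite; everything is generated in code.

# Brute-force oracle for the ligand-depletion complex concentration:
# real root of K*cx^2 - (K*(L+P)+1)*cx + K*L*P = 0 inside [0, min(L, P)],
# located by polynomial root finding (independent of the closed form).
oracle_cx <- function(L, P, K) {
  if (L == 0 || P == 0 || K == 0) return(0)
  roots <- polyroot(c(K * L * P, -(K * (L + P) + 1), K))
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * Mod(roots) + 1e-300]
  re <- re[re >= -1e-12 & re <= min(L, P) * (1 + 1e-9)]
  if (length(re) == 0) stop("oracle found no admissible root")
  min(max(re[1], 0), min(L, P))
}

# One corrected synthetic curve + its generating truth, shared across tests.
make_curve <- function(kd_nM = 42.1, seed = 1, noise = 0.02, n_points = 40) {
  protocol <- design_titration_protocol(kd_nM = kd_nM, n_points = n_points)
  truth <- sim_binding_params(kd_nM)
  raw <- sim_titration(truth, protocol, sim_config(seed = seed, noise_scale = noise))
  list(curve = build_titration_curve(raw, protocol),
       truth = truth, protocol = protocol)
}

# Analysis-protocol fit: protein concentration and free-cap fluorescence
# are known from independent measurements, so they are held fixed.
fit_fixed <- function(curve, truth) {
  suppressWarnings(fit_titration(
    curve,
    fix = list(P_act = truth$P_act, phi_lig_free = truth$phi_lig_free)
  ))
}

# Two-band lane with a linear baseline drift (5% of the tallest peak).
make_ce_lane <- function(ce = 0.9, total_area = 10, seed = 7, noise = 0.01,
                         width = 2) {
  bands <- data.frame(
    position = c(40, 60),
    area = c(total_area * (1 - ce), total_area * ce),
    width = width
  )
  peak_h <- max(bands$area) / (width * sqrt(2 * pi))
  sim_lane_profile(bands, baseline = c(0.01, 0.05 * peak_h / 100),
                   sim = sim_config(seed = seed, noise_scale = noise))
}

# Full cleaning + normalization + completeness cascade, quietly.
proteomics_cascade <- function(t, min_razor = 2) {
  suppressMessages(clean_protein_groups(t)) |>
    log2_median_normalize() |>
    completeness_filter(min_razor = min_razor)
}
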