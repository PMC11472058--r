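test_that("identical simulation configs give bitwise-identical outputs", {
  pro <- design_titration_protocol(kd_nM = 42.1, n_points = 12)
  tp <- sim_binding_params(42.1)
  s <- sim_config(seed = 11, noise_scale = 0.02)
  expect_identical(sim_titration(tp, pro, s), sim_titration(tp, pro, s))

  bands <- data.frame(position = 50, area = 3, width = 2)
  expect_identical(sim_lane_profile(bands, sim = sim_config(seed = 2)),
                   sim_lane_profile(bands, sim = sim_config(seed = 2)))
  expect_identical(sim_decapping_series(0.9, 0.05, sim = sim_config(seed = 3)),
                   sim_decapping_series(0.9, 0.05, sim = sim_config(seed = 3)))
  lv <- c(m7GpppAmpG = 1, test = 1.3)
  expect_identical(sim_expression_plate(lv, sim = sim_config(seed = 4)),
                   sim_expression_plate(lv, sim = sim_config(seed = 4)))
  expect_identical(sim_protein_groups(50, sim = sim_config(seed = 5)),
                   sim_protein_groups(50, sim = sim_config(seed = 5)))
})

test_that("noiseless titration equals the model prediction after corrections", {
  pro <- design_titration_protocol(kd_nM = 42.1, n_points = 15,
                                   eps_ex = 0, eps_em = 0)
  tp <- sim_binding_params(42.1)
  raw <- sim_titration(tp, pro, sim_config(seed = 1, noise_scale = 0))
  curve <- build_titration_curve(raw, pro)
  pred <- model_fluorescence(curve$L_total, tp, P_at_point = curve$P_at_point)
  expect_equal(curve$F_corrected, pred, tolerance = 1e-12)
  # with eps = 0 the only distortion of the raw table is dilution scaling
  expect_equal(raw$F_obs, pred / curve$dilution_factor, tolerance = 1e-12)
})

test_that("simulated inner filter and correction are exact inverses", {
  pro <- design_titration_protocol(kd_nM = 42.1, n_points = 15,
                                   eps_ex = 32, eps_em = 10)
  tp <- sim_binding_params(42.1)
  raw <- sim_titration(tp, pro, sim_config(seed = 1, noise_scale = 0))
  curve <- build_titration_curve(raw, pro)
  pred <- model_fluorescence(curve$L_total, tp, P_at_point = curve$P_at_point)
  expect_equal(curve$F_corrected, pred, tolerance = 1e-12)
})

test_that("lane generator produces normalized Gaussian bands on a baseline", {
  lane <- sim_lane_profile(data.frame(position = 50, area = 5, width = 2),
                           sim = sim_config(seed = 1, noise_scale = 0))
  expect_equal(pracma::trapz(lane$position, lane$intensity), 5,
               tolerance = 1e-3)
  flat <- sim_lane_profile(data.frame(position = 50, area = 0, width = 2),
                           baseline = c(0.3, 0.01),
                           sim = sim_config(seed = 1, noise_scale = 0))
  expect_equal(flat$intensity, 0.3 + 0.01 * flat$position, tolerance = 1e-12)
  expect_error(sim_lane_profile(data.frame(position = 50, area = 1, width = 2),
                                n_points = 5), "n_points")
  expect_error(sim_lane_profile(data.frame(position = 50, area = -1, width = 2)),
               "areas")
  expect_error(sim_lane_profile(data.frame(position = 500, area = 1, width = 2)),
               "inside")
})

test_that("decapping generator follows first-order decay with conserved totals", {
  s <- sim_decapping_series(0.9, 0, sim = sim_config(seed = 1, noise_scale = 0))
  cf <- attr(s, "ground_truth")$capped_fraction
  expect_true(all(cf == 0.9))
  rate <- -log(0.10) / 30
  s2 <- sim_decapping_series(0.9, rate, sim = sim_config(seed = 1, noise_scale = 0))
  dc <- decapping_course(s2)
  expect_equal(dc$decapped_at, 0.90, tolerance = 1e-12)
  totals <- tapply(s2$area, s2$timepoint, sum)
  expect_true(all(abs(totals - 100) < 1e-9))
  expect_error(sim_decapping_series(1.2, 0.1), "capped_fraction")
  expect_error(sim_decapping_series(0.9, 0.1, timepoints = c(-5, 0)), "Timepoints")
})

test_that("expression generator reproduces its relative levels at zero noise", {
  lv <- c(m7GpppAmpG = 1, analog8 = 1.32, tetra = 0.02)
  plate <- sim_expression_plate(lv, sim = sim_config(seed = 1, noise_scale = 0))
  res <- cumulative_expression(plate) |> normalize_expression()
  expect_equal(setNames(res$normalized_mean, res$sample_id)[names(lv)], lv)
  expect_equal(res$normalized_sd, rep(0, 3))
  expect_error(sim_expression_plate(c(a = 2)), "reference")
  expect_error(sim_expression_plate(numeric(0)), "Empty")
})

test_that("protein-group generator honours flags, missingness and spikes", {
  t0 <- sim_protein_groups(100, sim = sim_config(seed = 1, noise_scale = 0.5))
  filtered <- proteomics_cascade(t0)
  expect_equal(nrow(filtered), 100)

  t_decoy <- sim_protein_groups(
    100, flags_rate = c(reverse = 1, contaminant = 0, site_only = 0),
    sim = sim_config(seed = 1, noise_scale = 0.5))
  expect_warning(cleaned <- suppressMessages(clean_protein_groups(t_decoy)),
                 "flagged")
  expect_equal(nrow(cleaned), 0)

  t_sp <- sim_protein_groups(
    50, spikes = data.frame(group = "AR-2", log2fc = 2, n = 10),
    sim = sim_config(seed = 2, noise_scale = 0.5))
  gt <- attr(t_sp, "ground_truth")
  expect_equal(sum(!is.na(gt$spiked_group)), 10)
  expect_equal(nrow(t_sp), 60)
  expect_error(
    sim_protein_groups(10, spikes = data.frame(group = "XX", log2fc = 2)),
    "conditions"
  )

  t_miss <- sim_protein_groups(200, missing_rate = 0.2,
                               sim = sim_config(seed = 3, noise_scale = 0.5))
  design <- attr(t_miss, "channel_design")
  expect_gt(sum(is.na(as.matrix(t_miss[design$channel]))), 0)
  expect_lt(nrow(proteomics_cascade(t_miss)), 200)
})

test_that("generated fractions and intensities respect their ranges", {
  s <- sim_decapping_series(0.8, 0.03, sim = sim_config(seed = 9, noise_scale = 0.05))
  expect_true(all(s$area >= 0))
  plate <- sim_expression_plate(c(m7GpppAmpG = 1, x = 0.01),
                                sim = sim_config(seed = 9, noise_scale = 0.3))
  expect_true(all(plate$luminescence >= 0))
  pg <- sim_protein_groups(50, sim = sim_config(seed = 9, noise_scale = 1))
  design <- attr(pg, "channel_design")
  expect_true(all(as.matrix(pg[design$channel]) >= 0, na.rm = TRUE))
  expect_true(all(pg$razor_unique_peptides >= 1))
})
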