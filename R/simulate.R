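#' Configure a seeded noise model for the synthetic-data generators
#'
#' Every generator takes one of these; identical configurations produce
#' bitwise-identical output. `noise_scale` is interpreted by model:
#' `gaussian_relative` adds `N(0, (scale * signal)^2)` per point,
#' `gaussian_absolute` adds `N(0, scale^2)`, and `lognormal` multiplies by
#' `exp(N(0, scale^2))` centred so the expected value is preserved.
#'
#' @param seed Integer RNG seed.
#' @param noise_model One of `"gaussian_relative"`, `"gaussian_absolute"`,
#'   `"lognormal"`.
#' @param noise_scale Non-negative noise magnitude (dimensionless for the
#'   relative and lognormal models, signal units for the absolute model).
#'   The default, 2% relative Gaussian noise, is typical of spectrofluorometer
#'   repeatability.
#' @return An object of class `cap_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       noise_model = c("gaussian_relative",
                                       "gaussian_absolute",
                                       "lognormal"),
                       noise_scale = 0.02) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(noise_scale) || noise_scale < 0) {
    abort("`noise_scale` must be a finite non-negative number.")
  }
  structure(
    list(seed = as.integer(seed), noise_model = noise_model,
         noise_scale = noise_scale),
    class = "cap_sim_config"
  )
}

apply_noise <- function(signal, sim) {
  n <- length(signal)
  if (sim$noise_scale == 0) {
    return(signal)
  }
  switch(sim$noise_model,
    gaussian_relative = signal * (1 + rnorm(n, 0, sim$noise_scale)),
    gaussian_absolute = signal + rnorm(n, 0, sim$noise_scale),
    lognormal = signal * exp(rnorm(n, -sim$noise_scale^2 / 2, sim$noise_scale))
  )
}

#' Generating parameters for a simulated titration
#'
#' Convenience constructor for the ground-truth parameter set of
#' [sim_titration()]: an association constant derived from the requested
#' dissociation constant, plus spectroscopic defaults chosen to resemble a
#' quenching titration of 0.1 uM eIF4E (initial fluorescence 1000 a.u.,
#' ~80% quench at saturation, a weakly fluorescent free cap).
#'
#' @param kd_nM Ground-truth dissociation constant, nM.
#' @param protein_uM Active protein concentration, uM.
#' @param F0 Initial (ligand-free) fluorescence, a.u.
#' @param delta_phi Quench amplitude per uM of complex.
#' @param phi_lig_free Fluorescence efficiency of the free cap, per uM.
#' @return A named list usable as `true_params` in [sim_titration()].
#' @export
sim_binding_params <- function(kd_nM,
                               protein_uM = 0.1,
                               F0 = 1000,
                               delta_phi = 8000,
                               phi_lig_free = 25) {
  list(K_as = 1000 / kd_nM, P_act = protein_uM, F0 = F0,
       delta_phi = delta_phi, phi_lig_free = phi_lig_free)
}

#' Simulate a raw fluorescence quenching titration
#'
#' Forward model of the titration assay: for each point the generator
#' computes the diluted total ligand and protein concentrations, evaluates
#' the ligand-depletion fluorescence model at those concentrations, and then
#' *un-corrects* the value — dividing by the dilution factor and the
#' inner-filter factor — so that [build_titration_curve()] applied to the
#' output recovers the model prediction exactly at zero noise. Noise is added
#' to the observed (instrument-scale) reading.
#'
#' @param true_params Named list of generating parameters (`K_as`, `P_act`,
#'   `F0`, `delta_phi`, `phi_lig_free`); see [model_fluorescence()].
#' @param protocol A [titration_protocol()].
#' @param sim A [sim_config()].
#' @return A raw titration tibble (`aliquot_ul`, `stock_uM`, `F_obs`) whose
#'   first row is the ligand-free reading; the generating parameters are
#'   attached as the `ground_truth` attribute.
#' @export
sim_titration <- function(true_params, protocol, sim = sim_config()) {
  stopifnot(inherits(protocol, "cap_protocol"), inherits(sim, "cap_sim_config"))
  set.seed(sim$seed)
  v <- c(0, protocol$aliquot_ul)
  s <- c(0, protocol$stock_uM)
  V0 <- protocol$start_volume_ul
  V <- V0 + cumsum(v)
  L <- cumsum(s * v) / V
  P <- true_params$P_act * V0 / V
  F_model <- model_fluorescence(L, true_params, P_at_point = P)
  A_ex <- protocol$eps_ex * (L / 1000) * protocol$path_ex_cm
  A_em <- protocol$eps_em * (L / 1000) * protocol$path_em_cm
  F_obs <- F_model / ((V / V0) * 10^((A_ex + A_em) / 2))
  out <- tibble::tibble(
    aliquot_ul = v,
    stock_uM = s,
    F_obs = apply_noise(F_obs, sim)
  )
  attr(out, "ground_truth") <- list(
    params = true_params,
    kd_nM = 1000 / true_params$K_as,
    protocol = protocol,
    sim = sim
  )
  out
}

#' Simulate a 1-D gel lane densitometric trace
#'
#' Lanes are modelled as a sum of Gaussian bands on a polynomial baseline:
#' `trace(x) = sum(area_k * dnorm(x, position_k, width_k)) + baseline(x)`,
#' plus noise. Band areas are therefore exact integrals of the noiseless,
#' baseline-free trace.
#'
#' @param bands A data frame with columns `position`, `area`, `width`
#'   (migration units; `area` >= 0, `width` > 0).
#' @param baseline Polynomial coefficients of the baseline, lowest order
#'   first (default: flat zero baseline).
#' @param sim A [sim_config()].
#' @param n_points Number of points in the trace (>= 10).
#' @param x_range Migration-coordinate range of the trace.
#' @return A tibble (`position`, `intensity`) of class `cap_lane`, with the
#'   generating bands in the `ground_truth` attribute.
#' @export
sim_lane_profile <- function(bands,
                             baseline = 0,
                             sim = sim_config(noise_scale = 0.01),
                             n_points = 1000,
                             x_range = c(0, 100)) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("position", "area", "width") %in% names(bands)))
  if (n_points < 10) abort("`n_points` must be at least 10.")
  if (any(bands$area < 0)) abort("Band areas must be >= 0.")
  if (any(bands$width <= 0)) abort("Band widths must be > 0.")
  if (any(bands$position < x_range[1] | bands$position > x_range[2])) {
    abort("Band positions must lie inside the trace range.")
  }
  set.seed(sim$seed)
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  signal <- rep(0, n_points)
  for (k in seq_len(nrow(bands))) {
    signal <- signal + bands$area[k] * dnorm(x, bands$position[k], bands$width[k])
  }
  base <- rep(0, n_points)
  for (j in seq_along(baseline)) base <- base + baseline[j] * x^(j - 1)
  out <- tibble::tibble(
    position = x,
    intensity = apply_noise(signal + base, sim)
  )
  attr(out, "ground_truth") <- list(bands = bands, baseline = baseline, sim = sim)
  class(out) <- c("cap_lane", class(out))
  out
}

#' Simulate a first-order decapping time course as band intensities
#'
#' The capped fraction decays as
#' `cf(t) = initial_capped_fraction * exp(-rate * t)`; at each timepoint the
#' lane's total intensity is constant before noise, split between a capped
#' and an uncapped band.
#'
#' @param initial_capped_fraction Capped fraction at t = 0, in `[0, 1]`.
#' @param rate First-order decapping rate, 1/min (>= 0).
#' @param timepoints Sampling times in minutes (default the assay schedule
#'   0, 5, 15, 30, 60).
#' @param total_intensity Total lane intensity before noise.
#' @param sim A [sim_config()].
#' @return A band-intensity tibble (`timepoint`, `band_id`, `area`) with the
#'   generating parameters in the `ground_truth` attribute.
#' @export
sim_decapping_series <- function(initial_capped_fraction,
                                 rate,
                                 timepoints = c(0, 5, 15, 30, 60),
                                 total_intensity = 100,
                                 sim = sim_config()) {
  if (initial_capped_fraction < 0 || initial_capped_fraction > 1) {
    abort("`initial_capped_fraction` must be in [0, 1].")
  }
  if (rate < 0) abort("`rate` must be >= 0.")
  if (any(timepoints < 0)) abort("Timepoints must be >= 0 minutes.")
  set.seed(sim$seed)
  cf <- initial_capped_fraction * exp(-rate * timepoints)
  out <- tibble::tibble(
    timepoint = rep(timepoints, each = 2),
    band_id = rep(c("capped", "uncapped"), length(timepoints)),
    area = apply_noise(
      as.numeric(rbind(cf, 1 - cf)) * total_intensity, sim
    )
  )
  out$area <- pmax(out$area, 0)
  attr(out, "ground_truth") <- list(
    initial_capped_fraction = initial_capped_fraction,
    rate = rate,
    capped_fraction = setNames(cf, timepoints),
    sim = sim
  )
  out
}

#' Simulate a reporter-luminescence plate
#'
#' Each sample expresses at a known level relative to a reference (level 1);
#' per-replicate luminescence at each timepoint is
#' `level * shape_weight * base_luminescence * noise`. The time-course shape
#' mimics the declining per-interval output of a transfected secreted
#' reporter under medium replacement.
#'
#' @param true_relative_levels Named numeric vector of relative expression
#'   levels; must contain `reference` with level 1.
#' @param reference Name of the reference sample.
#' @param timecourse_shape Weights for the collection timepoints (summing to
#'   anything; only ratios matter downstream).
#' @param timepoints Collection times, hours.
#' @param n_replicates Replicates per sample.
#' @param base_luminescence Scale of the raw readings (RLU).
#' @param sim A [sim_config()].
#' @return An expression tibble (`sample_id`, `replicate`, `timepoint`,
#'   `luminescence`) with ground truth attached.
#' @export
sim_expression_plate <- function(true_relative_levels,
                                 reference = "m7GpppAmpG",
                                 timecourse_shape = c(0.40, 0.30, 0.20, 0.10),
                                 timepoints = c(16, 40, 64, 88),
                                 n_replicates = 3,
                                 base_luminescence = 1e6,
                                 sim = sim_config(noise_scale = 0.05)) {
  if (length(true_relative_levels) == 0) abort("Empty sample map.")
  if (!reference %in% names(true_relative_levels) ||
      abs(true_relative_levels[[reference]] - 1) > 1e-12) {
    abort("`true_relative_levels` must contain the reference sample at level 1.")
  }
  if (length(timecourse_shape) != length(timepoints)) {
    abort("`timecourse_shape` and `timepoints` must have the same length.")
  }
  set.seed(sim$seed)
  grid <- tidyr::expand_grid(
    sample_id = names(true_relative_levels),
    replicate = seq_len(n_replicates),
    tp_index = seq_along(timepoints)
  )
  grid$timepoint <- timepoints[grid$tp_index]
  signal <- true_relative_levels[grid$sample_id] *
    timecourse_shape[grid$tp_index] * base_luminescence
  out <- tibble::tibble(
    sample_id = grid$sample_id,
    replicate = grid$replicate,
    timepoint = grid$timepoint,
    luminescence = pmax(apply_noise(unname(signal), sim), 0)
  )
  attr(out, "ground_truth") <- list(
    levels = true_relative_levels, reference = reference, sim = sim
  )
  out
}

#' Simulate a TMT-like protein-group quantification table
#'
#' Generates a 9-channel (3 pull-down conditions x 3 replicates) reporter
#' intensity matrix with log-normal per-protein baselines, optional spiked
#' group effects, missing-at-random values, and decoy / contaminant /
#' site-only flag rows, mirroring the structure of a MaxQuant proteinGroups
#' export after reporter quantification.
#'
#' @param n_background Number of unperturbed background proteins.
#' @param spikes Optional data frame with columns `group` (condition whose
#'   channels are shifted), `log2fc` (shift on the log2 scale) and optionally
#'   `n` (rows per spike specification, default 1).
#' @param conditions Condition labels (3 channels each).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-protein
#'   log2 intensity baselines.
#' @param flags_rate Named fractions for `reverse`, `contaminant`,
#'   `site_only` flags (applied independently per row).
#' @param missing_rate Fraction of intensities set missing (MCAR).
#' @param razor_min Minimum razor+unique peptide count (counts are
#'   `razor_min + Poisson(5)`).
#' @param sim A [sim_config()]; its `noise_scale` is the per-measurement SD
#'   on the log2 scale (default 0.5).
#' @return A wide tibble of class `cap_proteingroups` with one intensity
#'   column per channel, peptide counts, iBAQ values and QC flags; the
#'   channel design and spike ground truth are attached as attributes.
#' @export
sim_protein_groups <- function(n_background = 1000,
                               spikes = NULL,
                               conditions = c("AR-1", "AR-2", "AR-3"),
                               baseline_log2_mean = 20,
                               baseline_log2_sd = 2,
                               flags_rate = c(reverse = 0, contaminant = 0,
                                              site_only = 0),
                               missing_rate = 0,
                               razor_min = 2,
                               sim = sim_config(noise_scale = 0.5)) {
  stopifnot(length(conditions) == 3)
  set.seed(sim$seed)
  flags_rate <- c(flags_rate)[c("reverse", "contaminant", "site_only")]
  flags_rate[is.na(flags_rate)] <- 0

  spike_tbl <- NULL
  if (!is.null(spikes) && nrow(spikes) > 0) {
    spikes <- tibble::as_tibble(spikes)
    if (!all(c("group", "log2fc") %in% names(spikes))) {
      abort("`spikes` needs columns `group` and `log2fc`.")
    }
    if (!all(spikes$group %in% conditions)) {
      abort("Spike groups must be one of the channel conditions.")
    }
    n_rep <- spikes$n %||% rep(1L, nrow(spikes))
    if (is.null(spikes$n)) spikes$n <- n_rep
    spike_tbl <- tidyr::uncount(spikes[c("group", "log2fc", "n")], n)
  }
  n_spike <- if (is.null(spike_tbl)) 0L else nrow(spike_tbl)
  n <- n_background + n_spike

  design <- tidyr::expand_grid(condition = conditions, replicate = 1:3)
  design$channel <- paste0(design$condition, "_R", design$replicate)

  group_id <- c(
    sprintf("BG%04d", seq_len(n_background)),
    if (n_spike) sprintf("SPIKE%04d", seq_len(n_spike))
  )
  spiked_group <- c(rep(NA_character_, n_background),
                    if (n_spike) spike_tbl$group)
  spiked_log2fc <- c(rep(0, n_background), if (n_spike) spike_tbl$log2fc)

  base <- rnorm(n, baseline_log2_mean, baseline_log2_sd)
  logmat <- matrix(rnorm(n * 9, 0, sim$noise_scale), n, 9) + base
  colnames(logmat) <- design$channel
  if (n_spike) {
    for (i in which(!is.na(spiked_group))) {
      cols <- design$channel[design$condition == spiked_group[i]]
      logmat[i, cols] <- logmat[i, cols] + spiked_log2fc[i]
    }
  }
  intens <- 2^logmat
  if (missing_rate > 0) {
    intens[runif(length(intens)) < missing_rate] <- NA_real_
  }

  razor <- razor_min + rpois(n, 5)
  ibaq <- rowMeans(2^logmat) / razor * exp(rnorm(n, 0, 0.3))

  out <- tibble::tibble(
    group_id = group_id,
    razor_unique_peptides = razor,
    ibaq = ibaq,
    flag_reverse = runif(n) < flags_rate[["reverse"]],
    flag_contaminant = runif(n) < flags_rate[["contaminant"]],
    flag_site_only = runif(n) < flags_rate[["site_only"]]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(intens))
  attr(out, "channel_design") <- design
  attr(out, "ground_truth") <- tibble::tibble(
    group_id = group_id,
    spiked_group = spiked_group,
    log2fc = spiked_log2fc
  )
  class(out) <- c("cap_proteingroups", class(out))
  out
}
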