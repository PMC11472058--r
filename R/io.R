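#' Read a delimited analysis table
#'
#' Thin, validating wrapper over readr for the dialects the pipeline
#' consumes. `generic_csv` / `generic_tsv` return the typed tibble as-is
#' (after checking any `required` columns); `maxquant_proteingroups`
#' delegates to [read_proteingroups()].
#'
#' @param path File path.
#' @param dialect One of `"generic_csv"`, `"generic_tsv"`,
#'   `"maxquant_proteingroups"`.
#' @param required Column names that must be present.
#' @param ... Passed to the dialect reader.
#' @return A tibble.
#' @export
read_cap_table <- function(path,
                           dialect = c("generic_csv", "generic_tsv",
                                       "maxquant_proteingroups"),
                           required = NULL,
                           ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("Empty input file: %s", path))
  if (dialect == "maxquant_proteingroups") {
    return(read_proteingroups(path, ...))
  }
  reader <- if (dialect == "generic_csv") readr::read_csv else readr::read_tsv
  out <- reader(path, show_col_types = FALSE, progress = FALSE, ...)
  if (nrow(out) == 0) abort(sprintf("No data rows in: %s", path))
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort(sprintf("Missing mandatory column(s) in %s: %s",
                  path, paste(missing, collapse = ", ")))
  }
  inform(sprintf("Read %d x %d table from %s", nrow(out), ncol(out), path))
  out
}

#' Read a lane profile from two-column delimited text
#'
#' @param path CSV with columns `position`, `intensity`.
#' @return A `cap_lane` tibble.
#' @export
read_lane_profile <- function(path) {
  out <- read_cap_table(path, "generic_csv",
                        required = c("position", "intensity"))
  class(out) <- c("cap_lane", class(out))
  out
}

mq_reporter_cols <- function(n = 9) paste("Reporter intensity corrected", seq_len(n))

default_channel_design <- function(conditions = c("AR-1", "AR-2", "AR-3")) {
  design <- tidyr::expand_grid(condition = conditions, replicate = 1:3)
  design$channel <- paste0(design$condition, "_R", design$replicate)
  design
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated proteinGroups dialect: reporter channels from
#' `Reporter intensity corrected 1..9`, peptide counts from
#' `Razor + unique peptides`, abundance from `iBAQ`, and the `Reverse`,
#' `Only identified by site` and `Potential contaminant` marker columns
#' (`+` means flagged). Channels 1-9 are assigned to the pull-down design
#' (3 conditions x 3 replicates) in order.
#'
#' @param path Tab-separated proteinGroups file.
#' @param conditions Condition labels, one per block of 3 channels.
#' @param id_col Column used as the protein-group identifier.
#' @return A `cap_proteingroups` tibble (see [sim_protein_groups()] for the
#'   layout).
#' @export
read_proteingroups <- function(path,
                               conditions = c("AR-1", "AR-2", "AR-3"),
                               id_col = "Protein IDs") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("No data rows in: %s", path))
  design <- default_channel_design(conditions)
  need <- c(id_col, mq_reporter_cols(), "Razor + unique peptides", "iBAQ")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("Missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  flag <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    !is.na(raw[[col]]) & raw[[col]] == "+"
  }
  out <- tibble::tibble(
    group_id = raw[[id_col]],
    razor_unique_peptides = raw[["Razor + unique peptides"]],
    ibaq = suppressWarnings(as.numeric(raw[["iBAQ"]])),
    flag_reverse = flag("Reverse"),
    flag_contaminant = flag("Potential contaminant"),
    flag_site_only = flag("Only identified by site")
  )
  intens <- raw[mq_reporter_cols()]
  names(intens) <- design$channel
  out <- dplyr::bind_cols(out, intens)
  inform(sprintf("Read %d protein group(s) with 9 reporter channels from %s",
                 nrow(out), path))
  with_design(out, design)
}

#' Write a protein-group table in the MaxQuant proteinGroups dialect
#'
#' Inverse of [read_proteingroups()]; round-trips the standard layout.
#'
#' @param t A `cap_proteingroups` tibble.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_proteingroups <- function(t, path) {
  design <- channel_design(t)
  out <- tibble::tibble(
    `Protein IDs` = t$group_id,
    `Razor + unique peptides` = t$razor_unique_peptides,
    iBAQ = t$ibaq,
    Reverse = ifelse(t$flag_reverse, "+", ""),
    `Potential contaminant` = ifelse(t$flag_contaminant, "+", ""),
    `Only identified by site` = ifelse(t$flag_site_only, "+", "")
  )
  intens <- t[design$channel]
  names(intens) <- mq_reporter_cols(length(design$channel))
  readr::write_tsv(dplyr::bind_cols(out, intens), path, progress = FALSE)
  invisible(path)
}

#' Write a generated table with its ground-truth sidecar
#'
#' Writes the data as CSV and, when the object carries a `ground_truth`
#' attribute, a `<path>.truth` sidecar in `key = value` text form so
#' recovery tests can reload the generating parameters.
#'
#' @param x A tibble from one of the `sim_*()` generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    lines <- flatten_truth(gt)
    writeLines(lines, paste0(path, ".truth"))
  }
  invisible(path)
}

flatten_truth <- function(x, prefix = "") {
  out <- character()
  nms <- names(x) %||% seq_along(x)
  for (i in seq_along(x)) {
    key <- paste0(prefix, nms[i])
    v <- x[[i]]
    if (inherits(v, "cap_protocol") || inherits(v, "cap_sim_config")) {
      v <- unclass(v)
    }
    if (is.list(v) || is.data.frame(v)) {
      out <- c(out, flatten_truth(as.list(v), paste0(key, ".")))
    } else {
      out <- c(out, paste0(key, " = ", paste(format(v, digits = 17), collapse = ",")))
    }
  }
  out
}

#' Read a ground-truth sidecar file
#'
#' @param path Path to a `.truth` sidecar written by [write_sim_table()].
#' @return A named list of character values (numeric where parseable).
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  setNames(vals, vapply(kv, `[[`, character(1), 1))
}

pipeline_stages <- c("quantitation", "binding", "densitometry", "decapping",
                     "expression", "proteomics")

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML with a global `seed`, an `output_dir`, and one
#' block per stage to run (`quantitation`, `binding`, `densitometry`,
#' `decapping`, `expression`, `proteomics`). Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return The validated configuration list, class `cap_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("seed", "output_dir", pipeline_stages))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "cap_run_config")
}

#' Derive a stage- or replicate-level seed from a global seed
#'
#' Deterministic fan-out so every stage and replicate is independently
#' reproducible from one global seed; results stay within 32-bit integer
#' range.
#'
#' @param seed Global integer seed.
#' @param index Stage/replicate index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483629)
}

#' Run the configured analysis stages and write a result bundle
#'
#' Executes each configured stage in the fixed order quantitation, binding,
#' densitometry, decapping, expression, proteomics; writes per-stage CSV
#' outputs plus a machine-readable `summary.yaml` carrying the headline
#' quantity of every stage together with the configuration hash and seed.
#' A stage failure halts the run with a stage-tagged error; outputs of
#' completed stages are preserved.
#'
#' @param config A `cap_run_config` (or path to one).
#' @param out_dir Output directory (defaults to the config's `output_dir`).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config))
  )

  run_stage <- function(name, fun) {
    if (is.null(config[[name]])) return(NULL)
    tryCatch(fun(config[[name]]),
             error = function(e) {
               abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
             })
  }

  summary$quantitation <- run_stage("quantitation", function(blk) {
    tab <- read_cap_table(blk$table, "generic_csv",
                          required = c("compound", "mOD", "epsilon"))
    res <- quantitate_nucleotides(tab)
    readr::write_csv(res, file.path(out_dir, "quantitation.csv"), progress = FALSE)
    list(n_compounds = nrow(res),
         amounts_umol = setNames(as.list(round(res$amount_umol, 6)),
                                 res$compound))
  })

  summary$binding <- run_stage("binding", function(blk) {
    protocol <- do.call(titration_protocol, blk$protocol)
    fits <- lapply(blk$titrations, function(f) {
      raw <- read_cap_table(f, "generic_csv",
                            required = c("aliquot_ul", "stock_uM", "F_obs"))
      fit_titration(build_titration_curve(raw, protocol))
    })
    pooled <- pool_binding_fits(fits)
    per_fit <- dplyr::bind_rows(lapply(fits, glance))
    readr::write_csv(per_fit, file.path(out_dir, "binding_fits.csv"), progress = FALSE)
    readr::write_csv(pooled, file.path(out_dir, "binding_pooled.csv"), progress = FALSE)
    list(compound = blk$compound %||% "unknown",
         kd_nM = round(pooled$kd_nM, 4), kd_se_nM = round(pooled$kd_se_nM, 4),
         n_replicates = pooled$n_replicates)
  })

  summary$densitometry <- run_stage("densitometry", function(blk) {
    ces <- vapply(blk$lanes, function(f) {
      lane <- read_lane_profile(f)
      bands <- assign_cap_bands(integrate_bands(lane))
      capping_efficiency(bands[bands$band_id == "capped", ],
                         bands[bands$band_id == "uncapped", ])
    }, numeric(1))
    res <- tibble::tibble(lane = unlist(blk$lanes), capping_efficiency = ces)
    readr::write_csv(res, file.path(out_dir, "capping_efficiency.csv"), progress = FALSE)
    summ <- replicate_summary(ces)
    list(capping_efficiency_mean = round(summ$mean, 6),
         capping_efficiency_sd = round(summ$sd, 6), n_lanes = summ$n)
  })

  summary$decapping <- run_stage("decapping", function(blk) {
    tab <- read_cap_table(blk$table, "generic_csv",
                          required = c("timepoint", "band_id", "area"))
    dc <- decapping_course(tab, query_time = blk$query_time %||% 30)
    readr::write_csv(dc$series, file.path(out_dir, "decapping.csv"), progress = FALSE)
    list(decapped_at = round(dc$decapped_at, 6), query_time = dc$query_time)
  })

  summary$expression <- run_stage("expression", function(blk) {
    tab <- read_cap_table(blk$table, "generic_csv",
                          required = c("sample_id", "replicate", "timepoint",
                                       "luminescence"))
    res <- cumulative_expression(tab) |>
      normalize_expression(reference = blk$reference %||% "m7GpppAmpG")
    readr::write_csv(res, file.path(out_dir, "expression.csv"), progress = FALSE)
    list(samples = setNames(as.list(round(res$normalized_mean, 6)),
                            res$sample_id))
  })

  summary$proteomics <- run_stage("proteomics", function(blk) {
    t <- read_proteingroups(blk$table,
                            conditions = unlist(blk$conditions %||%
                                                  c("AR-1", "AR-2", "AR-3")))
    filtered <- t |>
      clean_protein_groups() |>
      log2_median_normalize() |>
      completeness_filter(min_razor = blk$min_razor %||% 2)
    comparisons <- unlist(blk$comparisons %||%
                            list("AR-3 vs AR-1", "AR-2 vs AR-1", "AR-3 vs AR-2"))
    results <- lapply(comparisons, function(cmp) {
      res <- s0_test(filtered, cmp, s0 = blk$s0 %||% 1, fdr = blk$fdr %||% 0.02)
      fn <- file.path(out_dir, paste0("proteomics_", gsub("[^A-Za-z0-9]+", "_", cmp), ".csv"))
      readr::write_csv(res, fn, progress = FALSE)
      res
    })
    names(results) <- comparisons
    binders <- preferential_binders(results)
    readr::write_csv(binders$fc_fc, file.path(out_dir, "proteomics_fc_fc.csv"),
                     progress = FALSE)
    list(n_filtered = nrow(filtered),
         binders = lapply(binders$sets, length),
         intersection = length(binders$intersection))
  })

  summary <- summary[!vapply(summary, is.null, logical(1))]
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(summary)
}
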