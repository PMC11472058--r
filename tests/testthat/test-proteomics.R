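make_pg <- function(values, razor = 5, ibaq = 1) {
  # `values` is a 9-column matrix; channels follow the default design
  design <- capquant:::default_channel_design()
  t <- tibble::tibble(
    group_id = sprintf("P%03d", seq_len(nrow(values))),
    razor_unique_peptides = rep_len(razor, nrow(values)),
    ibaq = rep_len(ibaq, nrow(values)),
    flag_reverse = FALSE, flag_contaminant = FALSE, flag_site_only = FALSE
  )
  v <- tibble::as_tibble(as.data.frame(values))
  names(v) <- design$channel
  t <- dplyr::bind_cols(t, v)
  attr(t, "channel_design") <- design
  class(t) <- c("cap_proteingroups", class(t))
  t
}

test_that("cleaning removes exactly the flagged protein groups", {
  t <- make_pg(matrix(1, 100, 9))
  t$flag_reverse[1:5] <- TRUE
  expect_message(cleaned <- clean_protein_groups(t), "5 reverse")
  expect_equal(nrow(cleaned), 95)
  t2 <- make_pg(matrix(1, 10, 9))
  expect_equal(nrow(suppressMessages(clean_protein_groups(t2))), 10)
})

test_that("log2 median normalization centres every channel at zero", {
  t <- make_pg(matrix(rep(c(2, 4, 8), 9), nrow = 3))
  norm <- log2_median_normalize(t)
  design <- attr(norm, "channel_design")
  for (ch in design$channel) {
    expect_equal(norm[[ch]], c(-1, 0, 1))
  }
  const <- log2_median_normalize(make_pg(matrix(7, 5, 9)))
  expect_true(all(as.matrix(const[design$channel]) == 0))
  rnd <- log2_median_normalize(
    sim_protein_groups(200, sim = sim_config(seed = 8, noise_scale = 0.7)))
  meds <- apply(as.matrix(rnd[design$channel]), 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, 9), tolerance = 1e-12)
})

test_that("the completeness filter enforces razor count and complete channels", {
  vals <- matrix(2, 4, 9)
  vals[2, 5] <- NA # incomplete row
  t <- make_pg(vals, razor = c(5, 5, 1, 2))
  kept <- completeness_filter(log2_median_normalize(t))
  expect_equal(kept$group_id, c("P001", "P004"))
  # generator ground truth: only unflagged, complete, well-identified rows pass
  t3 <- sim_protein_groups(300, missing_rate = 0.1,
                           flags_rate = c(reverse = 0.05, contaminant = 0.05,
                                          site_only = 0.05),
                           sim = sim_config(seed = 4, noise_scale = 0.5))
  design <- attr(t3, "channel_design")
  flagged <- t3$flag_reverse | t3$flag_contaminant | t3$flag_site_only
  complete <- rowSums(is.na(as.matrix(t3[design$channel]))) == 0
  expected_n <- sum(!flagged & complete & t3$razor_unique_peptides >= 2)
  expect_equal(nrow(proteomics_cascade(t3)), expected_n)
})

test_that("cleaning and normalization commute when nothing is flagged", {
  t <- sim_protein_groups(150, sim = sim_config(seed = 6, noise_scale = 0.5))
  a <- suppressMessages(clean_protein_groups(log2_median_normalize(t)))
  b <- log2_median_normalize(suppressMessages(clean_protein_groups(t)))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("the moderated statistic matches hand arithmetic and is antisymmetric", {
  # group A spread sqrt(1.5) around 5, group B around 3: Welch SE = 1
  set.seed(1)
  d0 <- sqrt(1.5)
  row1 <- c(5 - d0, 5, 5 + d0, 3 - d0, 3, 3 + d0)
  vals <- rbind(
    matrix(c(row1, 0, 0, 0), nrow = 1),
    matrix(rnorm(45, 0, 0.1), 5, 9)
  )
  vals[1, ] <- c(row1, 0, 0, 0)
  t <- make_pg(vals)
  res <- s0_test(t, "AR-1 vs AR-2", s0 = 1)
  expect_equal(res$d_stat[1], (5 - 3) / (1 + 1), tolerance = 1e-10)
  rev <- s0_test(t, "AR-2 vs AR-1", s0 = 1)
  expect_equal(rev$d_stat, -res$d_stat, tolerance = 1e-12)
  expect_equal(rev$log2fc, -res$log2fc, tolerance = 1e-12)
})

test_that("identical groups give zero statistics and no calls", {
  set.seed(2)
  vals <- cbind(matrix(1:10, 10, 3), matrix(1:10, 10, 3),
                matrix(rnorm(30), 10, 3))
  t <- make_pg(vals)
  res <- s0_test(t, "AR-1 vs AR-2")
  expect_true(all(res$d_stat == 0))
  expect_false(any(res$significant))
})

test_that("zero-variance rows are regularized by s0 rather than dividing by zero", {
  set.seed(3)
  vals <- matrix(rnorm(90, 0, 0.3), 10, 9)
  vals[1, 1:3] <- 2 # exactly constant in group A
  vals[1, 4:6] <- 0 # and in group B
  res <- s0_test(make_pg(vals), "AR-1 vs AR-2", s0 = 1)
  expect_equal(res$d_stat[1], 2) # (2 - 0) / (0 + 1)
  expect_true(is.finite(res$d_stat[1]))
})

test_that("null tables produce no significant calls", {
  counts <- vapply(1:10, function(s) {
    t <- sim_protein_groups(800, sim = sim_config(seed = s, noise_scale = 0.5))
    sum(s0_test(proteomics_cascade(t), "AR-2 vs AR-1")$significant)
  }, numeric(1))
  expect_true(mean(counts == 0) >= 0.95)
})

test_that("strong spikes are detected with high power and correct direction", {
  t <- sim_protein_groups(
    1000, spikes = data.frame(group = "AR-2", log2fc = 2, n = 50),
    sim = sim_config(seed = 11, noise_scale = 0.5))
  gt <- attr(t, "ground_truth")
  spiked <- gt$group_id[!is.na(gt$spiked_group)]
  res <- s0_test(proteomics_cascade(t), "AR-2 vs AR-1")
  hits <- res$group_id[res$significant & res$log2fc > 0]
  expect_gte(mean(spiked %in% hits), 0.9)
  false_calls <- setdiff(hits, spiked)
  expect_lte(length(false_calls), 0.1 * length(hits))
})

test_that("preferential binders intersect correctly across comparisons", {
  t <- sim_protein_groups(
    500,
    spikes = data.frame(group = c("AR-2", "AR-3"), log2fc = 4, n = c(20, 20)),
    sim = sim_config(seed = 21, noise_scale = 0.4))
  gt <- attr(t, "ground_truth")
  filtered <- proteomics_cascade(t)
  res <- list(
    "AR-2 vs AR-1" = s0_test(filtered, "AR-2 vs AR-1"),
    "AR-3 vs AR-1" = s0_test(filtered, "AR-3 vs AR-1")
  )
  binders <- preferential_binders(res)
  sp2 <- gt$group_id[!is.na(gt$spiked_group) & gt$spiked_group == "AR-2"]
  sp3 <- gt$group_id[!is.na(gt$spiked_group) & gt$spiked_group == "AR-3"]
  # disjoint spikes: no protein is enriched in both tetraphosphate resins
  expect_length(binders$intersection, 0)
  expect_setequal(binders$sets[["AR-2 vs AR-1"]], sp2)
  expect_setequal(binders$sets[["AR-3 vs AR-1"]], sp3)
  expect_s3_class(plot_fc_fc(binders), "ggplot")

  # the same protein spiked in both conditions lands in the intersection
  t2 <- sim_protein_groups(
    300, spikes = data.frame(group = "AR-2", log2fc = 4, n = 15),
    sim = sim_config(seed = 22, noise_scale = 0.4))
  design <- attr(t2, "channel_design")
  ar3 <- design$channel[design$condition == "AR-3"]
  gt2 <- attr(t2, "ground_truth")
  sp <- !is.na(gt2$spiked_group)
  t2[sp, ar3] <- t2[sp, ar3] * 2^4
  filtered2 <- proteomics_cascade(t2)
  res2 <- list(
    "AR-2 vs AR-1" = s0_test(filtered2, "AR-2 vs AR-1"),
    "AR-3 vs AR-1" = s0_test(filtered2, "AR-3 vs AR-1")
  )
  binders2 <- preferential_binders(res2)
  expect_setequal(binders2$intersection, gt2$group_id[sp])
})

test_that("no significant rows yields empty binder sets", {
  t <- sim_protein_groups(300, sim = sim_config(seed = 31, noise_scale = 0.5))
  filtered <- proteomics_cascade(t)
  res <- list("AR-2 vs AR-1" = s0_test(filtered, "AR-2 vs AR-1"),
              "AR-3 vs AR-1" = s0_test(filtered, "AR-3 vs AR-1"))
  binders <- preferential_binders(res)
  expect_true(all(lengths(binders$sets) == 0))
  expect_length(binders$intersection, 0)
})

test_that("the iBAQ screen flags the top quartile with inclusive ties", {
  t <- make_pg(matrix(1, 100, 9), ibaq = 1:100)
  mask <- ibaq_top_quartile(t)
  expect_equal(sum(mask), 25)
  expect_true(all(which(mask) == 76:100))
  t_eq <- make_pg(matrix(1, 10, 9), ibaq = 7)
  expect_true(all(ibaq_top_quartile(t_eq)))
  t_na <- make_pg(matrix(1, 4, 9), ibaq = c(1, 2, 3, NA))
  mask_na <- ibaq_top_quartile(t_na)
  expect_false(mask_na[4])
})
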