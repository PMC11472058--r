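test_that("baseline estimation tracks a drifting baseline under peaks", {
  x <- seq(0, 100, length.out = 800)
  truth <- 2 + 0.05 * x
  y <- truth + 8 * dnorm(x, 50, 2)
  base <- estimate_baseline(y)
  # compare away from the peak, where the baseline is directly visible
  away <- abs(x - 50) > 10
  expect_lt(max(abs(base[away] - truth[away])), 0.15)
})

test_that("a single Gaussian band is integrated to within 1% of its area", {
  lane <- sim_lane_profile(data.frame(position = 50, area = 5, width = 2),
                           sim = sim_config(seed = 1, noise_scale = 0))
  bands <- integrate_bands(lane)
  expect_equal(nrow(bands), 1)
  expect_equal(bands$area, 5, tolerance = 0.01)
  expect_equal(bands$position, 50, tolerance = 0.2)
})

test_that("featureless traces yield an empty band list", {
  flat <- tibble::tibble(position = seq(0, 100, length.out = 200),
                         intensity = rep(1, 200))
  expect_equal(nrow(integrate_bands(flat)), 0)
  noisy_flat <- sim_lane_profile(
    data.frame(position = 50, area = 0, width = 2), baseline = 1,
    sim = sim_config(seed = 1, noise_scale = 0.01))
  expect_equal(nrow(integrate_bands(noisy_flat)), 0)
})

test_that("two bands at a 9:1 area ratio are recovered", {
  lane <- make_ce_lane(ce = 0.9, seed = 3)
  bands <- integrate_bands(lane)
  expect_equal(nrow(bands), 2)
  ratio <- max(bands$area) / min(bands$area)
  expect_equal(ratio, 9, tolerance = 0.2 / 9 * 3) # 9.0 +- 0.2 allowance
})

test_that("capping efficiency is the capped share of total band area", {
  expect_equal(capping_efficiency(90, 10), 0.90)
  expect_equal(capping_efficiency(0, 7), 0)
  expect_equal(capping_efficiency(7, 0), 1)
  expect_error(capping_efficiency(0, 0), "zero")
  expect_error(capping_efficiency(-1, 5), ">= 0")
})

test_that("capping efficiency recovery holds across the reported range", {
  for (ce in c(0.6, 0.75, 0.9)) {
    lane <- make_ce_lane(ce = ce, seed = 11)
    bands <- assign_cap_bands(integrate_bands(lane))
    got <- capping_efficiency(bands[bands$band_id == "capped", ],
                              bands[bands$band_id == "uncapped", ])
    expect_lt(abs(got - ce), 0.03)
  }
})

test_that("densitometry statistics are invariant to lane-wide intensity scaling", {
  lane <- make_ce_lane(ce = 0.75, seed = 13)
  scaled <- lane
  scaled$intensity <- scaled$intensity * 37.5
  ce1 <- {
    b <- assign_cap_bands(integrate_bands(lane))
    capping_efficiency(b[b$band_id == "capped", ], b[b$band_id == "uncapped", ])
  }
  ce2 <- {
    b <- assign_cap_bands(integrate_bands(scaled))
    capping_efficiency(b[b$band_id == "capped", ], b[b$band_id == "uncapped", ])
  }
  expect_equal(ce1, ce2, tolerance = 1e-12)

  s <- sim_decapping_series(0.9, 0.05, sim = sim_config(seed = 2, noise_scale = 0.02))
  s2 <- s
  s2$area <- s2$area * 12
  expect_equal(decapping_course(s)$decapped_at, decapping_course(s2)$decapped_at,
               tolerance = 1e-12)
})

test_that("band identity assignment uses position order with caller override", {
  bands <- tibble::tibble(band_id = c("band_1", "band_2"),
                          position = c(40, 60), area = c(1, 9),
                          height = c(0.2, 1.8), saturated = FALSE)
  auto <- assign_cap_bands(bands)
  expect_equal(auto$band_id[auto$position == 60], "capped")
  manual <- assign_cap_bands(bands, expected = c(capped = 40, uncapped = 60))
  expect_equal(manual$band_id[manual$position == 40], "capped")
})

test_that("decapping course normalizes, clips and validates", {
  tab <- tibble::tibble(
    timepoint = rep(c(0, 30), each = 2),
    band_id = rep(c("capped", "uncapped"), 2),
    area = c(0.90, 0.10, 0.090, 0.910)
  )
  dc <- decapping_course(tab)
  expect_equal(dc$decapped_at, 0.90, tolerance = 1e-12)

  const <- tibble::tibble(timepoint = rep(c(0, 15, 30), each = 2),
                          band_id = rep(c("capped", "uncapped"), 3),
                          area = rep(c(0.8, 0.2), 3))
  expect_equal(decapping_course(const)$series$decapped, rep(0, 3))

  upward <- tibble::tibble(timepoint = rep(c(0, 30), each = 2),
                           band_id = rep(c("capped", "uncapped"), 2),
                           area = c(0.8, 0.2, 0.85, 0.15))
  expect_warning(dc_up <- decapping_course(upward), "clipped")
  expect_equal(dc_up$decapped_at, 0)

  expect_error(decapping_course(tab, query_time = 45), "interpolation")
  zero0 <- tibble::tibble(timepoint = rep(c(0, 30), each = 2),
                          band_id = rep(c("capped", "uncapped"), 2),
                          area = c(0, 1, 0, 1))
  expect_error(decapping_course(zero0), "zero")
})

test_that("decapping susceptibility grows monotonically for decaying inputs", {
  s <- sim_decapping_series(0.85, 0.04, sim = sim_config(seed = 5, noise_scale = 0))
  dec <- decapping_course(s)$series$decapped
  expect_true(all(diff(dec) >= 0))
})

test_that("replicate summaries use the sample standard deviation", {
  expect_equal(replicate_summary(c(0.9, 0.9, 0.9)),
               tibble::tibble(mean = 0.9, sd = 0, n = 3L))
  r <- replicate_summary(c(0.8, 0.9, 1.0))
  expect_equal(r$mean, 0.9)
  expect_equal(r$sd, 0.1, tolerance = 1e-12)
  expect_warning(single <- replicate_summary(0.9), "undefined")
  expect_true(is.na(single$sd))
})

test_that("triplicate decapping series recover the generating susceptibility", {
  rate <- -log(1 - 0.65) / 30 # 65% decapped at 30 min
  vals <- vapply(1:3, function(s) {
    tab <- sim_decapping_series(0.86, rate,
                                sim = sim_config(seed = s, noise_scale = 0.02))
    decapping_course(tab)$decapped_at
  }, numeric(1))
  summ <- replicate_summary(vals)
  expect_lt(abs(summ$mean - 0.65), 0.05)
})
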