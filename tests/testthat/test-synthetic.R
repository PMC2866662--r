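test_that("library simulation matches the effect model marginally", {
  # all-inactive limit
  lib0 <- simulate_library(50, effect_model(p_inactive = 1), seed = 1)
  expect_true(all(lib0$activity_factor == 0))

  # binomial oracle on the inactive fraction
  lib <- simulate_library(10000, effect_model(p_inactive = 0.5), seed = 2)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(mean(lib$activity_factor == 0) - 0.5), 3 * se)

  # mutation counts stay in the configured range
  expect_true(all(lib$n_mutations >= 2 & lib$n_mutations <= 10))

  # campaign-scale library
  big <- simulate_library(30000, seed = 3)
  expect_equal(nrow(big), 30000)
  expect_error(simulate_library(10, effect_model(p_inactive = 2)))
})

test_that("simulation is deterministic under a fixed seed", {
  lib <- simulate_library(500, seed = 7)
  s1 <- simulate_screen(lib, 2, seed = 11)
  s2 <- simulate_screen(lib, 2, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_screen(lib, 2, seed = 12)
  expect_false(identical(s1$wells$pre_activity, s3$wells$pre_activity))
})

test_that("noise-free wild-type-only screen collapses to the control value", {
  lib <- simulate_library(100, effect_model(p_inactive = 0,
                                            activity_sdlog = 0,
                                            tolerance_sdlog = 0,
                                            tolerance_meanlog = 0), seed = 1)
  cfg <- screen_config(cv = 0, background_slope_fraction = 0,
                       read_noise_au = 0)
  s <- simulate_screen(lib, 1, cfg, seed = 1)
  w <- s$wells
  occupied <- w$n_genes > 0
  expect_true(all(abs(w$pre_activity[occupied] -
                        cfg$wt_activity_per_ul) < 1e-9))
  expect_true(all(w$pre_activity[!occupied] == 0))
  r <- w$post_activity[occupied] / cfg$volume_factor /
    w$pre_activity[occupied]
  expect_equal(unname(r),
               rep(exp(-cfg$decay_rate_per_ul * cfg$exposure_volume_ul),
                   sum(occupied)), tolerance = 1e-9)
})

test_that("empty-well fraction matches the Poisson design point", {
  lib <- simulate_library(30000, seed = 4)
  s <- simulate_screen(lib, 20, seed = 5)
  samp <- s$wells[s$wells$role == "sample", ]
  p_empty <- mean(samp$n_genes == 0)
  se <- sqrt(0.1 * 0.9 / nrow(samp))
  expect_lt(abs(p_empty - exp(-2.3)), 3 * se)
})

test_that("replicate wild-type ratio CV reproduces the configured CV", {
  # 88 wild-type replicate wells at configured CV 0.17
  lib <- simulate_library(100, seed = 6)
  cfg <- screen_config(cv = 0.17, background_slope_fraction = 0)
  s <- simulate_screen(lib, 11, cfg, seed = 8)
  wt <- s$wells[s$wells$role == "wildtype_control", ][1:88, ]
  ratio <- (wt$post_activity / cfg$volume_factor) / wt$pre_activity
  # SE of a CV estimate: approx cv / sqrt(2 n)
  se <- 0.17 / sqrt(2 * 88)
  expect_lt(abs(cv(ratio) - 0.17), 3 * se)
})

test_that("truth table traces every well back to its members", {
  lib <- simulate_library(2000, seed = 9)
  s <- simulate_screen(lib, 3, seed = 10)
  expect_identical(s$truth$well, s$wells$well)
  expect_identical(s$truth$mutant_ids, s$wells$mutant_ids)
  samp <- s$truth[s$truth$role == "sample" & s$truth$n_genes > 0, ]
  ids <- unlist(strsplit(samp$mutant_ids, ","))
  expect_true(all(ids %in% lib$mutant_id))
  # member count agrees with the recorded gene count
  expect_equal(lengths(strsplit(samp$mutant_ids, ",")), samp$n_genes)
})

test_that("co-occupancy averages member signals", {
  # a 3x mutant sharing a well with an inactive mutant gives the mean of
  # the two signals (half the solo signal)
  lib <- data.frame(mutant_id = c("A", "B"), n_mutations = c(2L, 2L),
                    activity_factor = c(3, 0), tolerance_factor = c(1, 1))
  cfg <- screen_config(cv = 0, background_slope_fraction = 0)
  layout <- plate_layout()
  # force one well to hold both mutants by lambda so high both always land
  s <- simulate_screen(lib, 1, cfg, seed = 2, layout = layout)
  tr <- s$truth[s$truth$role == "sample" & s$truth$n_genes == 2 &
                  s$truth$mutant_ids %in% c("A,B", "B,A"), ]
  expect_gt(nrow(tr), 0)
  expect_equal(tr$true_pre_per_ul,
               rep(cfg$wt_activity_per_ul * 1.5, nrow(tr)))
})

test_that("planted wells override occupancy with the requested mutant", {
  lib <- simulate_library(1000, seed = 11)
  lib$activity_factor[1] <- 4
  planted <- data.frame(plate = 1, well = "C5", mutant_id = "M00001")
  s <- simulate_screen(lib, 1, seed = 12, planted = planted)
  row <- s$truth[s$truth$plate == 1 & s$truth$well == "C5", ]
  expect_identical(row$mutant_ids, "M00001")
  expect_equal(row$true_pre_per_ul, 4 * screen_config()$wt_activity_per_ul)
  expect_error(
    simulate_screen(lib, 1, seed = 12,
                    planted = data.frame(plate = 1, well = "A1",
                                         mutant_id = "M00001")),
    "not a sample well")
})

test_that("generated traces invert the assay conversions", {
  cfg <- screen_config()
  # flat when nothing is present
  flat <- generate_trace(0, 1, cfg, background = FALSE, noise = FALSE)
  expect_true(all(flat$a578 == flat$a578[1]))
  # round trip across an activity grid
  for (a in c(10, 150, 1500, 4000)) {
    tr <- generate_trace(a, 1, cfg, background = FALSE, noise = FALSE)
    expect_equal(measure_trace(tr, 1)$activity_per_ul, a, tolerance = 1e-9)
  }
})

test_that("traces are clipped at methyl viologen depletion", {
  cfg <- screen_config()
  # activity implying > 2 mM MV reduced over the 2-minute read
  huge <- 2.5e5
  tr <- generate_trace(huge, 1, cfg, background = FALSE, noise = FALSE)
  expect_true(attr(tr, "saturated"))
  slope <- fit_slope(tr)$slope_au_per_min
  max_slope <- cfg$mv_concentration_mM / 2 * cfg$conversion_coefficient
  expect_equal(slope, max_slope, tolerance = 1e-9)
  expect_false(attr(generate_trace(1500, 1, cfg, noise = FALSE),
                    "saturated"))
})

test_that("background-only traces stay below the screening QC cutoff", {
  cfg <- screen_config()
  cutoff <- cfg$min_pre_activity_fraction * cfg$wt_activity_per_ul
  set.seed(707)
  acts <- vapply(1:300, function(i) {
    tr <- generate_trace(0, 1, cfg, background = TRUE, noise = TRUE)
    measure_trace(tr, 1)$activity_per_ul
  }, 0)
  expect_gte(mean(acts < cutoff), 0.99)
})
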