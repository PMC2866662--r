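test_that("residual ratio puts both assays on a per-volume basis", {
  # design point: pre 10 from 1 uL, post 10 raw from 5 uL -> 20% residual
  expect_equal(residual_ratio(10, 10, 5), 0.2)
  expect_equal(residual_ratio(10, 50, 5), 1)   # no deactivation
  expect_equal(residual_ratio(10, 0, 5), 0)
  expect_error(residual_ratio(0, 10, 5), "positive")
})

test_that("coefficient of variance is SD over mean", {
  expect_equal(cv(c(8, 10, 12)), 0.2)
  expect_equal(cv(rep(5, 10)), 0)
  expect_error(cv(5), "2 values")
  expect_error(cv(c(-2, 2)), "mean")
})

test_that("CV estimate at replicate-plate scale matches the configured value", {
  set.seed(808)
  sdl <- sqrt(log1p(0.17^2))
  est <- vapply(1:200, function(i) cv(rlnorm(88, 0, sdl)), 0)
  se <- 0.17 / sqrt(2 * 88)
  expect_lt(abs(mean(est) - 0.17), 3 * se / sqrt(200) + 0.003)
})

test_that("QC disqualifies low-signal wells, threshold inclusive", {
  rec <- data.frame(pre_activity = c(0, 4.9, 5, 10))
  out <- qc_filter(rec, 5)
  expect_identical(out$qc_pass, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(qc_filter(rec, 0)$qc_pass))
})

test_that("QC removes truth-inactive wells in a simulated screen", {
  set.seed(909)
  hits <- vapply(1:20, function(i) {
    lib <- simulate_library(500, effect_model(p_inactive = 0.3), seed = i)
    s <- simulate_screen(lib, 1, seed = 1000 + i)
    res <- screen_analyze(s$wells, s$config)
    truth_inactive <- s$truth$n_genes > 0 & s$truth$true_pre_per_ul == 0 &
      s$truth$role == "sample"
    mean(!res$records$qc_pass[truth_inactive])
  }, 0)
  expect_gte(mean(hits), 0.95)
})

test_that("plate normalization centres wild-type scores at 1 and is scale invariant", {
  set.seed(111)
  wt_pre <- rlnorm(8, log(100), 0.1)
  wt_post <- 5 * 0.17 * wt_pre * rlnorm(8, 0, 0.1)
  s_pre <- rlnorm(20, log(100), 0.2)
  s_post <- 5 * 0.17 * s_pre * rlnorm(20, 0, 0.2)
  w <- well_table(wt_pre, wt_post, s_pre, s_post)
  res <- screen_analyze(w, screen_config())
  wt_rows <- res$records$role == "wildtype_control"
  expect_equal(mean(res$records$normalized_tolerance[wt_rows]), 1,
               tolerance = 1e-12)
  expect_equal(mean(res$records$normalized_activity[wt_rows]), 1,
               tolerance = 1e-12)

  # rescaling every raw activity leaves scores, QC and hit calls unchanged
  w2 <- w
  w2$pre_activity <- w$pre_activity * 37.5
  w2$post_activity <- w$post_activity * 37.5
  res2 <- screen_analyze(w2, screen_config())
  expect_equal(res2$records$normalized_tolerance,
               res$records$normalized_tolerance)
  expect_equal(res2$records$normalized_activity,
               res$records$normalized_activity)
  expect_identical(res2$records$qc_pass, res$records$qc_pass)
  expect_identical(res2$records$tolerance_hit, res$records$tolerance_hit)
  expect_identical(res2$records$activity_hit, res$records$activity_hit)
})

test_that("plates without two usable wild-type controls are rejected", {
  w <- well_table(wt_pre = 100, wt_post = 85, sample_pre = c(90, 110),
                  sample_post = c(80, 90))
  expect_error(screen_analyze(w, screen_config()), "fewer than 2")
})

test_that("identical deactivation severity differences normalize away", {
  # two plates, the second with 2x harsher deactivation: identical
  # libraries give the same normalized tolerance distribution
  set.seed(222)
  make_plate <- function(plate, severity) {
    pre <- rlnorm(28, log(100), 0.12)
    ratio_true <- c(rep(0.17, 8), rep(0.17, 20)) * severity
    post <- 5 * ratio_true * pre * rlnorm(28, 0, 0.12)
    well_table(pre[1:8] , post[1:8], pre[9:28], post[9:28], plate = plate)
  }
  w <- rbind(make_plate(1, 1), make_plate(2, 0.5))
  res <- screen_analyze(w, screen_config())
  by_plate <- split(res$records$normalized_tolerance[
    res$records$role == "sample"], res$records$plate[
      res$records$role == "sample"])
  expect_equal(mean(by_plate[[1]]), mean(by_plate[[2]]), tolerance = 0.15)
  expect_gt(stats::ks.test(by_plate[[1]], by_plate[[2]])$p.value, 0.01)
})

test_that("hit calling flags nothing when all wells are identical", {
  w <- well_table(rep(100, 8), rep(85, 8), rep(100, 20), rep(85, 20))
  res <- screen_analyze(w, screen_config())
  expect_false(any(res$records$tolerance_hit))
  expect_false(any(res$records$activity_hit))
  expect_true(res$summary[["1"]]$degenerate)
})

test_that("null false-positive rate reflects the 2-SD triage design", {
  # normal-approximation oracle: a well exactly at the wild-type
  # distribution crosses an exact 2-SD threshold with P(Z > 2) = 2.3% per
  # tail; power_curve at zero improvement measures exactly this
  p0 <- power_curve(0, cv = 0.2, n_sims = 20000, seed = 12)
  expect_lt(abs(p0$detection_probability - pnorm(2, lower.tail = FALSE)),
            0.005)
  # in a full null screen the rate widens (lognormal skew, threshold
  # estimated from 8 controls per plate) but stays a small triage rate
  set.seed(333)
  fp <- vapply(1:40, function(i) {
    lib <- simulate_library(200, effect_model(p_inactive = 0,
                                              activity_sdlog = 0,
                                              tolerance_sdlog = 0,
                                              tolerance_meanlog = 0),
                            seed = 500 + i)
    s <- simulate_screen(lib, 1, screen_config(cv = 0.2), seed = 600 + i)
    res <- screen_analyze(s$wells, s$config)
    samp <- res$records$role == "sample" & res$records$qc_pass
    mean(res$records$tolerance_hit[samp])
  }, 0)
  expect_gt(mean(fp), 0.01)
  expect_lt(mean(fp), 0.12)
})

test_that("a planted 4x activity mutant is always called an activity hit", {
  set.seed(444)
  found <- vapply(1:60, function(i) {
    lib <- simulate_library(500, seed = i)
    lib$activity_factor[1] <- 4
    s <- simulate_screen(lib, 1, screen_config(cv = 0.20), seed = 2000 + i,
                         planted = data.frame(plate = 1, well = "C5",
                                              mutant_id = "M00001"))
    res <- screen_analyze(s$wells, s$config)
    res$records$activity_hit[res$records$well == "C5"]
  }, TRUE)
  expect_gte(mean(found), 0.99)
})

test_that("a planted cohort of >= 2x tolerance-improved mutants is recovered", {
  # 40 planted solo wells per plate carry tolerance mutants whose
  # residual-activity scores are improved by factors drawn in [2, 3];
  # recall and precision of the tolerance-hit list against the truth
  # table, aggregated over seeds
  set.seed(555)
  cfg <- screen_config()
  kv <- cfg$decay_rate_per_ul * cfg$exposure_volume_ul
  layout <- plate_layout()
  plant_wells <- layout$well[layout$role == "sample"][1:40]
  tp <- fn <- fp <- 0
  for (i in 1:25) {
    lib <- simulate_library(500, seed = 100 + i)
    factors <- runif(40, 2, 3)            # >= 2x improved ratio
    tf <- 1 - log(factors) / kv           # implied deactivation-rate factor
    lib$tolerance_factor[1:40] <- tf
    lib$activity_factor[1:40] <- 1
    s <- simulate_screen(lib, 1, cfg, seed = 3000 + i,
                         planted = data.frame(plate = 1, well = plant_wells,
                                              mutant_id = lib$mutant_id[1:40]))
    rec <- screen_analyze(s$wells, s$config)$records
    planted <- rec$well %in% plant_wells
    tp <- tp + sum(rec$tolerance_hit[planted])
    fn <- fn + sum(!rec$tolerance_hit[planted])
    fp <- fp + sum(rec$tolerance_hit[!planted])
  }
  expect_gte(tp / (tp + fn), 0.95)  # recall
  expect_gte(tp / (tp + fp), 0.90)  # precision
})

test_that("co-occupancy with an inactive mutant halves the expected signal", {
  cfg <- screen_config(cv = 0, background_slope_fraction = 0)
  lib <- data.frame(mutant_id = c("IMP", "DEAD"), n_mutations = c(3L, 3L),
                    activity_factor = c(4, 0), tolerance_factor = c(1, 1))
  s <- simulate_screen(lib, 1, cfg, seed = 3)
  tr <- s$truth[s$truth$n_genes == 2 &
                  s$truth$mutant_ids %in% c("IMP,DEAD", "DEAD,IMP"), ]
  solo <- s$truth[s$truth$n_genes == 1 & s$truth$mutant_ids == "IMP", ]
  expect_gt(nrow(tr), 0); expect_gt(nrow(solo), 0)
  expect_equal(unique(tr$true_pre_per_ul),
               unique(solo$true_pre_per_ul) / 2)
})

test_that("detectable improvement is the threshold crossing of the mean score", {
  expect_equal(detectable_improvement(0.15), 0.30)
  expect_equal(detectable_improvement(0.25), 0.50)
  expect_equal(detectable_improvement(0), 0)
  # threshold consistency: the noise-free expected normalized score at
  # this improvement equals the hit threshold exactly
  for (cvv in c(0.1, 0.15, 0.2, 0.25)) {
    imp <- detectable_improvement(cvv)
    expect_equal(1 + imp, 1 + 2 * cvv)
  }
})

test_that("power curve behaves at the null, threshold and separation limits", {
  cvv <- 0.2
  pc <- power_curve(c(0, 2 * cvv, 10 * cvv), cv = cvv, n_sims = 10000,
                    seed = 99)
  # null: detection probability = per-tail false-positive rate (2.3%)
  expect_lt(abs(pc$detection_probability[1] -
                  pnorm(2, lower.tail = FALSE)), 0.01)
  # threshold symmetry: 50% detection at improvement = 2 x CV
  expect_lt(abs(pc$detection_probability[2] - 0.5), 0.03)
  # separation limit (noise scales with the score, so convergence to 1
  # is asymptotic)
  expect_gt(pc$detection_probability[3], 0.99)
  # monotone non-decreasing over a grid (within MC error)
  grid <- power_curve(seq(0, 1, 0.1), cv = cvv, n_sims = 4000, seed = 100)
  expect_true(all(diff(grid$detection_probability) > -0.03))
})

test_that("replicate averaging sharpens the power curve", {
  cvv <- 0.2
  p1 <- power_curve(0.6, cvv, n_replicates = 1, n_sims = 8000, seed = 5)
  p4 <- power_curve(0.6, cvv, n_replicates = 4, n_sims = 8000, seed = 5)
  expect_gt(p4$detection_probability, p1$detection_probability)
})
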