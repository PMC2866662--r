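test_that("occupancy pmf matches the Poisson law and accounts for tail mass", {
  m <- occupancy_model(2.3)
  p <- occupancy_pmf(m, k_max = 6)
  expect_equal(unname(p["0"]), exp(-2.3), tolerance = 1e-12)
  expect_equal(unname(p), dpois(0:6, 2.3), ignore_attr = TRUE)
  expect_equal(sum(p) + attr(p, "tail_mass"), 1, tolerance = 1e-12)

  # the 10%-empty design point and its inverse from the 10 uL dilution row
  expect_equal(unname(occupancy_pmf(m, 0)["0"]), 0.100, tolerance = 0.005)
  expect_equal(unname(occupancy_pmf(occupancy_model(0.69), 0)["0"]), 0.50,
               tolerance = 0.005)

  # trivial no-template case
  p0 <- occupancy_pmf(occupancy_model(0), 3)
  expect_equal(unname(p0), c(1, 0, 0, 0), ignore_attr = TRUE)

  expect_error(occupancy_model(-1), "non-negative")
  expect_error(occupancy_pmf(m, -1), "k_max")
})

test_that("multi-gene fraction agrees with brute-force and sampling oracles", {
  # brute-force pmf summation to k = 200 gives 0.7437092446 at lambda = 2.3
  expect_equal(multi_gene_fraction(occupancy_model(2.3)), 0.7437092446,
               tolerance = 1e-9)
  # Monte-Carlo oracle at lambda = 1: 10^6 Poisson draws gave 0.418325
  expect_equal(multi_gene_fraction(occupancy_model(1)), 0.418325,
               tolerance = 0.003)
  # limit behaviour
  expect_equal(multi_gene_fraction(occupancy_model(0)), 0)
  expect_lt(multi_gene_fraction(occupancy_model(1e-8)), 1e-7)
})

test_that("zero-class estimator reproduces printed dilution-series values", {
  # 5 uL row: 26.4% amplified -> 0.31 molecules/reaction
  e5 <- estimate_lambda(fraction = 0.264, n_wells = 31, reaction_volume = 5)
  expect_lt(abs(e5$lambda_hat - 0.31), 0.005)
  expect_true(e5$ci_low <= e5$lambda_hat && e5$lambda_hat <= e5$ci_high)

  # 15 uL row: 62.3% -> 0.98; per-5 uL -> 0.33
  e15 <- estimate_lambda(fraction = 0.623, n_wells = 31, reaction_volume = 15)
  expect_lt(abs(e15$lambda_hat - 0.98), 0.005)
  expect_lt(abs(scale_to_reference(e15, 5)$lambda_hat - 0.33), 0.005)

  # 10 uL row: 50% -> 0.69; per-5 uL -> 0.35 (printed rounding)
  e10 <- estimate_lambda(fraction = 0.5, n_wells = 31, reaction_volume = 10)
  expect_lt(abs(e10$lambda_hat - 0.69), 0.005)
  expect_equal(round(scale_to_reference(e10, 5)$lambda_hat, 2), 0.35)

  expect_equal(estimate_lambda(n_amplified = 0, n_wells = 31)$lambda_hat, 0)
})

test_that("saturated outcomes yield a lower bound, not a point estimate", {
  e <- estimate_lambda(n_amplified = 31, n_wells = 31)
  expect_true(e$saturated)
  expect_identical(e$lambda_hat, Inf)
  expect_true(is.finite(e$ci_low) && e$ci_low > 0)
})

test_that("estimator round-trips the exact zero-class probability", {
  for (lam in c(0.1, 0.5, 1, 2.3, 5)) {
    f <- 1 - exp(-lam)
    expect_equal(estimate_lambda(fraction = f)$lambda_hat, lam,
                 tolerance = 1e-12)
  }
})

test_that("zero-class estimate maximizes the binomial likelihood", {
  # brute-force oracle: dense lambda grid, binomial log-likelihood in the
  # fraction of occupied wells
  grid <- seq(0.001, 8, by = 0.001)
  for (f in c(0.05, 0.264, 0.5, 0.623, 0.9, 0.99)) {
    ll <- f * log1p(-exp(-grid)) - (1 - f) * grid
    expect_lt(abs(estimate_lambda(fraction = f)$lambda_hat -
                    grid[which.max(ll)]), 0.001)
  }
})

test_that("reference-volume rescaling is linear and composes", {
  e <- estimate_lambda(fraction = 0.5, n_wells = 40, reaction_volume = 10)
  via5 <- scale_to_reference(scale_to_reference(e, 5), 1)
  direct <- scale_to_reference(e, 1)
  expect_equal(via5$lambda_hat, direct$lambda_hat)
  expect_equal(via5$ci_low, direct$ci_low)
  expect_equal(via5$ci_high, direct$ci_high)
  # identity
  expect_equal(scale_to_reference(e, 10)$lambda_hat, e$lambda_hat)
})

test_that("graded-volume consistency holds for the dilution-series table", {
  tab <- data.frame(reaction_volume_ul = c(5, 10, 15), n_wells = 31,
                    fraction_amplified = c(0.264, 0.50, 0.623))
  est <- estimate_lambda_table(tab, reference_volume = 5)
  expect_equal(round(est$lambda_per_reference, 2), c(0.31, 0.35, 0.33))
  chk <- consistency_check(tab)
  expect_gt(chk$p_value, 0.05)
  expect_equal(chk$df, 2)
  expect_error(consistency_check(tab[1, , drop = FALSE]), "two rows")
  expect_error(consistency_check(
    data.frame(reaction_volume_ul = c(5, 10), n_wells = 31,
               fraction_amplified = c(0, 0))), "degenerate")
})

test_that("consistency test is calibrated under the null and detects 3x shifts", {
  set.seed(101)
  n_sims <- 1000
  vols <- c(5, 10, 15)
  c_true <- 0.065
  rej_null <- rej_alt <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    f0 <- rbinom(3, 31, 1 - exp(-c_true * vols)) / 31
    ok0 <- !all(f0 == 0) && !all(f0 == 1)
    rej_null[i] <- ok0 && consistency_check(
      data.frame(reaction_volume_ul = vols, n_wells = 31,
                 fraction_amplified = f0))$p_value < 0.05
    # alternative: middle row from a 3x concentration
    fa <- rbinom(3, 31, 1 - exp(-c_true * c(1, 3, 1) * vols)) / 31
    oka <- !all(fa == 0) && !all(fa == 1)
    rej_alt[i] <- oka && consistency_check(
      data.frame(reaction_volume_ul = vols, n_wells = 31,
                 fraction_amplified = fa))$p_value < 0.05
  }
  # type-I error within 3 binomial SEs of nominal 0.05
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lt(abs(mean(rej_null) - 0.05), 3 * se)
  # power well above the null rejection rate at this effect size
  expect_gt(mean(rej_alt), 0.5)
})

test_that("consistency-test power grows with wells per row", {
  set.seed(202)
  vols <- c(5, 10, 15)
  c_true <- 0.065
  pow <- vapply(c(31, 300), function(n) {
    mean(vapply(1:200, function(i) {
      f <- rbinom(3, n, 1 - exp(-c_true * c(1, 3, 1) * vols)) / n
      consistency_check(
        data.frame(reaction_volume_ul = vols, n_wells = n,
                   fraction_amplified = f))$p_value < 0.05
    }, TRUE))
  }, 0)
  expect_gt(pow[2], pow[1])
  expect_gt(pow[2], 0.99)
})

test_that("dilution planning reaches the working concentration exactly", {
  # 10^11 /uL stock to the 100 /uL working stock in 1-uL-into-1-mL steps
  plan <- plan_dilution(1e11, 100, step_ratio = 1001)
  expect_equal(nrow(plan), 3)
  expect_equal(plan$concentration[3], 100, tolerance = 1e-6)
  expect_equal(prod(plan$ratio), 1e9, tolerance = 1e-3)
  expect_true(all(plan$ratio[-nrow(plan)] == 1001))

  # nothing to do
  expect_equal(nrow(plan_dilution(100, 100)), 0)

  # per-step loss means more transfers and a compensating plan
  lossy <- plan_dilution(1e11, 100, step_ratio = 1001, recovery = 0.8)
  expect_equal(lossy$concentration[nrow(lossy)], 100, tolerance = 1e-6)
})
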