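#' Poisson occupancy model for a limiting-dilution design
#'
#' In a limiting-dilution screen, template molecules are distributed into
#' the wells of a PCR plate so that gene counts per well follow a Poisson
#' distribution with mean `mean_molecules_per_well` (lambda). The model
#' object carries lambda together with the reference volume used when
#' concentrations from different reaction volumes are compared.
#'
#' @param mean_molecules_per_well Poisson mean number of template molecules
#'   per well. Must be a single non-negative number; 0 is allowed only as
#'   the trivial no-template case.
#' @param reference_volume Reference reaction volume in microlitres used
#'   when rescaling concentration estimates (default 5).
#' @return An object of class `occupancy_model`.
#' @examples
#' m <- occupancy_model(2.3)
#' occupancy_pmf(m, k_max = 4)
#' multi_gene_fraction(m)
#' @export
occupancy_model <- function(mean_molecules_per_well, reference_volume = 5) {
  if (!is.numeric(mean_molecules_per_well) ||
      length(mean_molecules_per_well) != 1L ||
      is.na(mean_molecules_per_well) || mean_molecules_per_well < 0) {
    stop("`mean_molecules_per_well` must be a single non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(reference_volume) || length(reference_volume) != 1L ||
      is.na(reference_volume) || reference_volume <= 0) {
    stop("`reference_volume` must be a single positive number", call. = FALSE)
  }
  structure(
    list(mean_molecules_per_well = as.numeric(mean_molecules_per_well),
         reference_volume = as.numeric(reference_volume)),
    class = "occupancy_model"
  )
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("Poisson occupancy model\n")
  cat(sprintf("  lambda (molecules/well): %g\n", x$mean_molecules_per_well))
  cat(sprintf("  P(empty well):           %.4f\n",
              exp(-x$mean_molecules_per_well)))
  cat(sprintf("  P(>1 gene | occupied):   %.4f\n", multi_gene_fraction(x)))
  invisible(x)
}

#' Occupancy probability mass function
#'
#' Probability that a well receives exactly k template molecules,
#' P(k) = exp(-lambda) lambda^k / k!, evaluated for k = 0..`k_max`. The
#' probability mass beyond `k_max` is attached as attribute `tail_mass`.
#'
#' @param model An [occupancy_model()].
#' @param k_max Largest occupancy count to report (non-negative integer).
#' @return Named numeric vector of probabilities for k = 0..`k_max`, with
#'   attribute `tail_mass` giving P(k > k_max).
#' @export
occupancy_pmf <- function(model, k_max = 10L) {
  stopifnot(inherits(model, "occupancy_model"))
  if (!is.numeric(k_max) || length(k_max) != 1L || is.na(k_max) || k_max < 0) {
    stop("`k_max` must be a non-negative integer", call. = FALSE)
  }
  k <- 0:as.integer(k_max)
  p <- stats::dpois(k, lambda = model$mean_molecules_per_well)
  names(p) <- as.character(k)
  attr(p, "tail_mass") <-
    stats::ppois(k_max, lambda = model$mean_molecules_per_well,
                 lower.tail = FALSE)
  p
}

#' Fraction of occupied wells holding two or more genes
#'
#' The screen's resolution penalty of raising lambda: when several genes
#' land in one well their signals are averaged, so the quantity of interest
#' is P(k >= 2 | k >= 1) = (1 - exp(-lambda) - lambda exp(-lambda)) /
#' (1 - exp(-lambda)). Returns 0 by convention for lambda = 0.
#'
#' @param model An [occupancy_model()].
#' @return Probability that an occupied well contains more than one gene.
#' @export
multi_gene_fraction <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  lam <- model$mean_molecules_per_well
  if (lam == 0) return(0)
  p0 <- exp(-lam)
  p1 <- lam * exp(-lam)
  (1 - p0 - p1) / (1 - p0)
}

#' Zero-class (most probable number) estimate of the Poisson mean
#'
#' Estimates the mean number of template molecules per reaction from the
#' fraction of reactions in which amplification occurred, using the
#' zero-class estimator lambda = -log(1 - f). Amplification is treated as
#' a deterministic indicator of at least one template molecule.
#'
#' The confidence interval is a Clopper-Pearson binomial interval on f,
#' transformed through -log(1 - f); it behaves sensibly for f near 0 and 1.
#' When only a fraction is supplied (e.g. a printed percentage), counts for
#' the interval are obtained by rounding `fraction * n_wells`; when
#' `n_wells` is unknown the interval is `NA`. A saturated outcome (f = 1)
#' admits no point estimate: `lambda_hat` is `Inf` with `saturated = TRUE`
#' and only the one-sided lower confidence bound is reported.
#'
#' @param n_amplified Number of wells in which amplification occurred.
#' @param n_wells Number of scored wells.
#' @param fraction Alternatively, the observed amplified fraction directly
#'   (overrides `n_amplified`); useful for reproducing printed tables.
#' @param reaction_volume Volume of template-containing mix per reaction
#'   (microlitres); the estimate is molecules per this volume.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `lambda_estimate`: a list with `lambda_hat`,
#'   `ci_low`, `ci_high`, `fraction`, `n_wells`, `reaction_volume`,
#'   `saturated`, `conf_level`.
#' @examples
#' estimate_lambda(fraction = 0.264, n_wells = 31, reaction_volume = 5)
#' @export
estimate_lambda <- function(n_amplified = NULL, n_wells = NULL,
                            fraction = NULL, reaction_volume = 1,
                            conf_level = 0.95) {
  if (is.null(fraction)) {
    if (is.null(n_amplified) || is.null(n_wells)) {
      stop("supply either `fraction` or both `n_amplified` and `n_wells`",
           call. = FALSE)
    }
    if (n_wells <= 0 || n_amplified < 0 || n_amplified > n_wells) {
      stop("need 0 <= n_amplified <= n_wells with n_wells > 0", call. = FALSE)
    }
    fraction <- n_amplified / n_wells
  }
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (reaction_volume <= 0) {
    stop("`reaction_volume` must be positive", call. = FALSE)
  }

  saturated <- fraction >= 1
  lambda_hat <- if (saturated) Inf else -log1p(-fraction)

  ci_low <- ci_high <- NA_real_
  if (!is.null(n_wells) && n_wells > 0) {
    x <- if (is.null(n_amplified)) round(fraction * n_wells) else n_amplified
    ci_f <- stats::binom.test(x, n_wells, conf.level = conf_level)$conf.int
    ci_low <- -log1p(-ci_f[1])
    ci_high <- if (ci_f[2] >= 1) Inf else -log1p(-ci_f[2])
  }

  structure(
    list(lambda_hat = lambda_hat, ci_low = ci_low, ci_high = ci_high,
         fraction = fraction,
         n_wells = if (is.null(n_wells)) NA_integer_ else as.integer(n_wells),
         reaction_volume = reaction_volume, saturated = saturated,
         conf_level = conf_level),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat("Zero-class (MPN) Poisson estimate\n")
  cat(sprintf("  amplified fraction: %.3f (n = %s wells)\n", x$fraction,
              ifelse(is.na(x$n_wells), "?", x$n_wells)))
  if (x$saturated) {
    cat(sprintf("  saturated (f = 1): lambda > %.3f (one-sided %g%% bound)\n",
                x$ci_low, 100 * x$conf_level))
  } else {
    cat(sprintf("  lambda: %.3f molecules / %g uL reaction", x$lambda_hat,
                x$reaction_volume))
    if (!is.na(x$ci_low)) {
      cat(sprintf("  [%.3f, %.3f]", x$ci_low, x$ci_high))
    }
    cat("\n")
  }
  invisible(x)
}

#' Rescale a concentration estimate to a reference reaction volume
#'
#' Expresses a per-reaction estimate as molecules per `reference_volume`
#' (e.g. per 5 uL), multiplying the point estimate and interval by
#' `reference_volume / reaction_volume`. The rescaling is linear and
#' composes: rescaling to 5 uL and then to 1 uL equals rescaling to 1 uL.
#'
#' @param est A `lambda_estimate`.
#' @param reference_volume Target volume in microlitres.
#' @return A `lambda_estimate` expressed per `reference_volume`.
#' @export
scale_to_reference <- function(est, reference_volume) {
  stopifnot(inherits(est, "lambda_estimate"))
  if (reference_volume <= 0) {
    stop("`reference_volume` must be positive", call. = FALSE)
  }
  fac <- reference_volume / est$reaction_volume
  est$lambda_hat <- est$lambda_hat * fac
  est$ci_low <- est$ci_low * fac
  est$ci_high <- est$ci_high * fac
  est$reaction_volume <- reference_volume
  est
}

#' Per-row MPN estimates for an amplification table
#'
#' Applies [estimate_lambda()] to each row of an amplification table and
#' reports estimates both per reaction and per `reference_volume`.
#'
#' @param table Data frame with columns `reaction_volume_ul`, `n_wells`,
#'   and either `n_amplified` or `fraction_amplified`.
#' @param reference_volume Reference volume (uL) for the rescaled column.
#' @return Data frame with one row per input row: the amplified fraction,
#'   lambda per reaction with confidence bounds, and lambda per
#'   `reference_volume`.
#' @export
estimate_lambda_table <- function(table, reference_volume = 5) {
  table <- validate_amplification_table(table, require_distinct = FALSE)
  out <- lapply(seq_len(nrow(table)), function(i) {
    est <- estimate_lambda(
      n_amplified = if ("n_amplified" %in% names(table)) table$n_amplified[i],
      n_wells = table$n_wells[i],
      fraction = if (!"n_amplified" %in% names(table))
        table$fraction_amplified[i],
      reaction_volume = table$reaction_volume_ul[i]
    )
    ref <- scale_to_reference(est, reference_volume)
    data.frame(
      reaction_volume_ul = table$reaction_volume_ul[i],
      fraction_amplified = est$fraction,
      lambda_per_reaction = est$lambda_hat,
      ci_low = est$ci_low, ci_high = est$ci_high,
      lambda_per_reference = ref$lambda_hat,
      saturated = est$saturated
    )
  })
  res <- do.call(rbind, out)
  attr(res, "reference_volume") <- reference_volume
  res
}

validate_amplification_table <- function(table, require_distinct = TRUE) {
  table <- as.data.frame(table)
  if (!"reaction_volume_ul" %in% names(table) || !"n_wells" %in% names(table)) {
    stop("amplification table needs `reaction_volume_ul` and `n_wells`",
         call. = FALSE)
  }
  if (!("n_amplified" %in% names(table)) &&
      !("fraction_amplified" %in% names(table))) {
    stop("amplification table needs `n_amplified` or `fraction_amplified`",
         call. = FALSE)
  }
  if (any(table$reaction_volume_ul <= 0)) {
    stop("reaction volumes must be positive", call. = FALSE)
  }
  if ("n_amplified" %in% names(table) &&
      any(table$n_amplified > table$n_wells | table$n_amplified < 0)) {
    stop("need 0 <= n_amplified <= n_wells in every row", call. = FALSE)
  }
  if (require_distinct &&
      anyDuplicated(table$reaction_volume_ul) > 0) {
    stop("reaction volumes must be distinct across rows", call. = FALSE)
  }
  table
}

#' Consistency of amplification outcomes across reaction volumes
#'
#' A graded-volume plate (e.g. thirds receiving 5, 10 and 15 uL of the
#' same template mix) tests whether amplified products arise from single
#' template molecules: under that model the amplified fractions share a
#' single template concentration c (molecules per uL), with
#' f_i = 1 - exp(-c V_i). The common c is fitted by maximum likelihood and
#' compared with the saturated per-row model by a likelihood-ratio test
#' against chi-square with (rows - 1) degrees of freedom.
#'
#' Amplified counts may be fractional (e.g. reconstructed from printed
#' percentages); the binomial log-likelihood is then a quasi-likelihood
#' weighted by `n_wells`.
#'
#' @param table Amplification table as in [estimate_lambda_table()]; at
#'   least two rows with distinct volumes.
#' @return List with `concentration` (common molecules/uL), `lambda_per_row`
#'   (fitted means per reaction), `statistic`, `df`, `p_value`.
#' @export
consistency_check <- function(table) {
  table <- validate_amplification_table(table)
  if (nrow(table) < 2) {
    stop("need at least two rows with distinct volumes", call. = FALSE)
  }
  f <- if ("n_amplified" %in% names(table)) {
    table$n_amplified / table$n_wells
  } else {
    table$fraction_amplified
  }
  n <- table$n_wells
  v <- table$reaction_volume_ul
  if (all(f == 0) || all(f >= 1)) {
    stop("degenerate fit: all rows empty or all saturated", call. = FALSE)
  }

  loglik_terms <- function(fobs, p) {
    # binomial (quasi-)log-likelihood, safe at fobs in {0, 1}
    t1 <- ifelse(fobs > 0, fobs * log(p), 0)
    t2 <- ifelse(fobs < 1, (1 - fobs) * log1p(-p), 0)
    t1 + t2
  }
  nll <- function(log_c) {
    p <- -expm1(-exp(log_c) * v)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n * loglik_terms(f, p))
  }
  # start from the average per-uL zero-class estimate over non-saturated rows
  ok <- f < 1 & f > 0
  c0 <- mean(-log1p(-f[ok]) / v[ok])
  opt <- stats::optim(log(c0), nll, method = "BFGS")
  c_hat <- exp(opt$par)

  p_hat <- -expm1(-c_hat * v)
  ll_common <- sum(n * loglik_terms(f, pmin(pmax(p_hat, 1e-12), 1 - 1e-12)))
  ll_sat <- sum(n * loglik_terms(f, pmin(pmax(f, 1e-12), 1 - 1e-12)))
  stat <- max(0, 2 * (ll_sat - ll_common))
  df <- nrow(table) - 1L

  list(concentration = c_hat,
       lambda_per_row = c_hat * v,
       statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Plan a serial dilution down to a target concentration
#'
#' Computes the smallest sequence of equal-ratio serial-dilution steps
#' (e.g. 1 uL into 1 mL, a 1001-fold step) whose cumulative factor reaches
#' `stock_concentration / target_concentration`, adjusting the final
#' step's ratio so the plan lands exactly on the target. An optional
#' per-step recovery factor (< 1) models template loss per transfer;
#' adsorptive losses are otherwise assumed to be controlled chemically.
#'
#' @param stock_concentration Stock concentration, molecules/uL.
#' @param target_concentration Desired working concentration, molecules/uL.
#' @param step_ratio Dilution factor of a full step (default 1001,
#'   i.e. 1 uL into 1 mL); must exceed 1.
#' @param recovery Fraction of template surviving each transfer (default 1).
#' @return Data frame with one row per step: `step`, `ratio`,
#'   `cumulative_factor`, `concentration` after the step. Zero rows when
#'   the stock is already at (or below) the target.
#' @export
plan_dilution <- function(stock_concentration, target_concentration,
                          step_ratio = 1001, recovery = 1) {
  if (stock_concentration <= 0 || target_concentration <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (step_ratio <= 1) stop("`step_ratio` must exceed 1", call. = FALSE)
  if (recovery <= 0 || recovery > 1) {
    stop("`recovery` must lie in (0, 1]", call. = FALSE)
  }
  total <- stock_concentration / target_concentration
  if (total <= 1) {
    return(data.frame(step = integer(), ratio = numeric(),
                      cumulative_factor = numeric(),
                      concentration = numeric()))
  }
  eff <- step_ratio / recovery  # effective per-step concentration divisor
  n_steps <- ceiling(log(total) / log(eff))
  ratios <- rep(step_ratio, n_steps)
  # adjust the last step so recovery^n / prod(ratios) lands on target
  ratios[n_steps] <- total * recovery^n_steps / step_ratio^(n_steps - 1)
  cum <- cumprod(ratios)
  conc <- stock_concentration * recovery^seq_len(n_steps) / cum
  data.frame(step = seq_len(n_steps), ratio = ratios,
             cumulative_factor = cum, concentration = conc)
}
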