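#' Volume-normalized residual-activity ratio
#'
#' The screen's oxygen-tolerance score: post-exposure activity divided by
#' pre-exposure activity, with both on a per-uL-of-CFPS-product basis.
#' The protocol assays `volume_factor` times as much CFPS product after
#' exposure as before (5x for a 20% residual target), so the raw post
#' rate is divided by `volume_factor` before the ratio is taken.
#'
#' @param pre Pre-exposure rate measured from 1 volume unit of product.
#' @param post Raw post-exposure rate measured from `volume_factor`
#'   volume units.
#' @param volume_factor Post/pre assayed-volume ratio (default 5).
#' @return Dimensionless residual-activity ratio.
#' @examples
#' residual_ratio(10, 10, 5)  # 0.2, the design point
#' @export
residual_ratio <- function(pre, post, volume_factor = 5) {
  if (any(pre <= 0)) {
    stop("`pre` must be positive; low-signal wells must fail QC instead",
         call. = FALSE)
  }
  (post / volume_factor) / pre
}

#' Coefficient of variance
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' The screen's precision metric, computed over replicate wild-type
#' wells; it sets the minimal detectable improvement (about 2 x CV at a
#' 2-SD threshold).
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return SD/mean.
#' @examples
#' cv(c(8, 10, 12))  # 0.2
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV undefined for non-positive mean", call. = FALSE)
  stats::sd(values) / m
}

#' Apply the minimum pre-exposure activity cutoff
#'
#' Wells with pre-exposure activity below the cutoff are disqualified:
#' their low signal-to-noise inflates the residual-activity ratio, so
#' they get no ratio and no hit flags. A well exactly at the threshold
#' passes.
#'
#' @param records Well table with a `pre_activity` column.
#' @param min_pre_activity Absolute activity cutoff (same units as
#'   `pre_activity`).
#' @return `records` with a logical `qc_pass` column.
#' @export
qc_filter <- function(records, min_pre_activity) {
  if (min_pre_activity < 0) {
    stop("`min_pre_activity` must be non-negative", call. = FALSE)
  }
  records$qc_pass <- records$pre_activity >= min_pre_activity
  records
}

#' Normalize well scores to the plate's wild-type controls
#'
#' Wild-type control reactions on every plate absorb plate-to-plate and
#' day-to-day variation in CFPS performance and exposure effectiveness:
#' each well's residual-activity ratio and pre-exposure activity are
#' divided by the mean over the plate's QC-passing wild-type controls. A
#' plate with fewer than two usable controls is rejected.
#'
#' @param records Well table for ONE plate with columns `role`,
#'   `pre_activity`, `residual_ratio`, `qc_pass`.
#' @return `records` with `normalized_tolerance` and
#'   `normalized_activity` columns (NA for QC failures).
#' @export
plate_normalize <- function(records) {
  wt <- records$role == "wildtype_control" & records$qc_pass
  if (sum(wt) < 2) {
    stop("plate rejected: fewer than 2 usable wild-type control wells",
         call. = FALSE)
  }
  wt_ratio <- mean(records$residual_ratio[wt])
  wt_pre <- mean(records$pre_activity[wt])
  records$normalized_tolerance <-
    ifelse(records$qc_pass, records$residual_ratio / wt_ratio, NA_real_)
  records$normalized_activity <-
    ifelse(records$qc_pass, records$pre_activity / wt_pre, NA_real_)
  records
}

#' Call tolerance and activity hits at an SD threshold
#'
#' One-tailed hit calling on the normalized scale, per plate: a sample
#' well is a tolerance hit when its normalized residual-activity ratio
#' strictly exceeds the wild-type controls' mean plus `sd_multiplier`
#' standard deviations, and an activity hit analogously on normalized
#' pre-exposure activity. The 2-SD rule is a triage threshold with
#' downstream re-testing, so no multiple-testing correction is applied
#' by default; `bonferroni = TRUE` divides the implied tail probability
#' by the number of sample wells (normal quantile).
#'
#' @param records One plate's normalized well table (after
#'   [plate_normalize()]).
#' @param sd_multiplier Threshold in wild-type SDs (default 2).
#' @param bonferroni Apply a Bonferroni-adjusted multiplier instead
#'   (default FALSE).
#' @return List: `records` with logical `tolerance_hit`/`activity_hit`
#'   columns, and `summary` (wild-type means, SDs, CVs, thresholds,
#'   `degenerate` flag when the WT variance is zero).
#' @export
call_hits <- function(records, sd_multiplier = 2, bonferroni = FALSE) {
  if (!all(c("normalized_tolerance", "normalized_activity") %in%
           names(records))) {
    stop("run plate_normalize() first", call. = FALSE)
  }
  wt <- records$role == "wildtype_control" & records$qc_pass
  mult <- sd_multiplier
  if (bonferroni) {
    n_tests <- sum(records$role == "sample" & records$qc_pass)
    alpha <- stats::pnorm(sd_multiplier, lower.tail = FALSE)
    mult <- stats::qnorm(alpha / max(n_tests, 1), lower.tail = FALSE)
  }

  stats_for <- function(x) {
    m <- mean(x[wt]); s <- stats::sd(x[wt])
    list(mean = m, sd = s, cv = s / m, threshold = m + mult * s)
  }
  tol <- stats_for(records$normalized_tolerance)
  act <- stats_for(records$normalized_activity)
  degenerate <- tol$sd == 0 || act$sd == 0

  eligible <- records$role == "sample" & records$qc_pass
  records$tolerance_hit <- eligible &
    !is.na(records$normalized_tolerance) &
    records$normalized_tolerance > tol$threshold
  records$activity_hit <- eligible &
    !is.na(records$normalized_activity) &
    records$normalized_activity > act$threshold

  list(records = records,
       summary = list(
         wt_n = sum(wt),
         tolerance = tol, activity = act,
         sd_multiplier = mult, degenerate = degenerate))
}

#' Score and call hits across a whole screen
#'
#' The full decision layer over a well table: per plate, compute
#' residual ratios, derive the minimum pre-exposure cutoff as
#' `min_pre_activity_fraction` of the plate's wild-type mean
#' pre-exposure activity, QC-filter, normalize to the plate's wild-type
#' controls, and call hits at the configured SD multiplier. Wild-type
#' statistics are per plate (replicate drift between experiments is why
#' controls sit on every plate); pooling is not offered here.
#'
#' @param wells Well table with columns `plate`, `well`, `role`,
#'   `pre_activity` (per uL, from 1 volume unit) and `post_activity`
#'   (raw, from `volume_factor` volume units).
#' @param config A [screen_config()].
#' @return List of class `screen_result`: `records` (scored well table),
#'   `summary` (per-plate wild-type stats and thresholds), `hits`
#'   (subset of records flagged on either score).
#' @export
screen_analyze <- function(wells, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  needed <- c("plate", "well", "role", "pre_activity", "post_activity")
  if (!all(needed %in% names(wells))) {
    stop("well table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(wells, wells$plate), function(pw) {
    wt_pre <- mean(pw$pre_activity[pw$role == "wildtype_control"])
    cutoff <- config$min_pre_activity_fraction * wt_pre
    pw <- qc_filter(pw, cutoff)
    pw$residual_ratio <- NA_real_
    ok <- pw$qc_pass & pw$pre_activity > 0
    pw$residual_ratio[ok] <- residual_ratio(
      pw$pre_activity[ok], pw$post_activity[ok], config$volume_factor)
    pw$qc_pass <- ok
    pw <- plate_normalize(pw)
    res <- call_hits(pw, config$sd_multiplier)
    res$summary$min_pre_activity <- cutoff
    res
  })
  records <- do.call(rbind, lapply(out, `[[`, "records"))
  rownames(records) <- NULL
  summaries <- lapply(out, `[[`, "summary")
  hits <- records[records$tolerance_hit | records$activity_hit, ,
                  drop = FALSE]
  structure(list(records = records, summary = summaries, hits = hits,
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cvs <- vapply(x$summary, function(s) s$tolerance$cv, 0)
  cat(sprintf("Screen result: %d wells on %d plates\n", nrow(x$records),
              length(x$summary)))
  cat(sprintf("  wild-type tolerance-score CV per plate: %s\n",
              paste(sprintf("%.3f", cvs), collapse = ", ")))
  cat(sprintf("  hits: %d tolerance, %d activity\n",
              sum(x$records$tolerance_hit), sum(x$records$activity_hit)))
  invisible(x)
}

#' Minimal detectable improvement at an SD threshold
#'
#' With a hit threshold `sd_multiplier` SDs above the wild-type mean, a
#' mutant whose expected normalized score is exactly at the threshold is
#' improved by `sd_multiplier x cv` — the improvement detected with
#' probability about one half under symmetric noise. At the protocol's
#' 2-SD threshold and 15-25% CV this is a 30-50% improvement.
#'
#' @param cv Wild-type coefficient of variance (fraction).
#' @param sd_multiplier Threshold multiplier (default 2).
#' @return Fractional improvement sitting exactly at the threshold.
#' @examples
#' detectable_improvement(0.15)  # 0.30
#' detectable_improvement(0.25)  # 0.50
#' @export
detectable_improvement <- function(cv, sd_multiplier = 2) {
  if (any(cv < 0)) stop("`cv` must be non-negative", call. = FALSE)
  sd_multiplier * cv
}

#' Monte-Carlo power curve for a single-read screen
#'
#' Detection probability of an improved mutant as a function of its true
#' fractional improvement: each draw gives the mutant a measured
#' normalized score of (1 + improvement) times a mean-1 multiplicative
#' noise factor with the wild-type CV (averaged over `n_replicates`
#' reads; the protocol reads each mutant once), and detection means
#' strictly exceeding the threshold 1 + `sd_multiplier` x cv. With
#' symmetric (`"normal"`) noise the probability at improvement =
#' `sd_multiplier` x cv is exactly one half; `"lognormal"` matches the
#' simulator's noise model and is slightly asymmetric.
#'
#' @param improvements Grid of fractional improvements (>= 0).
#' @param cv Wild-type coefficient of variance.
#' @param n_replicates Reads averaged per mutant (default 1).
#' @param sd_multiplier Threshold multiplier (default 2).
#' @param n_sims Monte-Carlo draws per grid point (default 10000).
#' @param noise `"normal"` (symmetric, default) or `"lognormal"`.
#' @param seed Integer seed.
#' @return Data frame `improvement`, `detection_probability`.
#' @export
power_curve <- function(improvements, cv, n_replicates = 1,
                        sd_multiplier = 2, n_sims = 10000,
                        noise = c("normal", "lognormal"), seed = 1L) {
  noise <- match.arg(noise)
  if (any(improvements < 0)) {
    stop("`improvements` must be non-negative", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  set.seed(seed)
  threshold <- 1 + sd_multiplier * cv
  detect <- vapply(improvements, function(imp) {
    draws <- matrix(
      if (noise == "normal") {
        1 + cv * stats::rnorm(n_sims * n_replicates)
      } else {
        sdl <- sqrt(log1p(cv^2))
        stats::rlnorm(n_sims * n_replicates, -sdl^2 / 2, sdl)
      },
      nrow = n_sims
    )
    score <- (1 + imp) * rowMeans(draws)
    mean(score > threshold)
  }, 0)
  data.frame(improvement = improvements, detection_probability = detect)
}
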