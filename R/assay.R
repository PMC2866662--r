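#' Construct an absorbance trace
#'
#' One well's methyl viologen (MV) A578 time series. In the
#' H2-consumption direction the enzyme reduces MV (clear to blue), so
#' absorbance rises and active wells have positive slopes. Traces are
#' read for about two minutes; times are seconds and strictly increasing.
#'
#' @param well_id Plate coordinate, e.g. `"A1"`.
#' @param times Time points in seconds, strictly increasing, length >= 3.
#' @param a578 Absorbance readings (AU), same length as `times`.
#' @param assay_volume_ul Assay volume in the well, uL (default 200).
#' @param mv_concentration_mM MV concentration, mM (default 2).
#' @return Object of class `absorbance_trace`.
#' @export
absorbance_trace <- function(well_id, times, a578, assay_volume_ul = 200,
                             mv_concentration_mM = 2) {
  if (length(times) != length(a578)) {
    stop("`times` and `a578` must have equal length", call. = FALSE)
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), times = as.numeric(times),
         a578 = as.numeric(a578), assay_volume_ul = assay_volume_ul,
         mv_concentration_mM = mv_concentration_mM),
    class = "absorbance_trace"
  )
}

#' Fit the kinetic slope of an absorbance trace
#'
#' Ordinary least-squares slope of A578 against time over the full trace
#' (the protocol reads two minutes and fits the whole window), reported
#' per minute. Nonlinearity (R-squared < 0.9) is flagged, as saturating
#' traces bias the rate downward. An optional initial-linear-window
#' selector maximizes R-squared over prefixes of at least 5 points; it is
#' off by default.
#'
#' @param trace An [absorbance_trace()] (or list with `times` seconds and
#'   `a578`).
#' @param window `"full"` (default) or `"initial"` (best linear prefix).
#' @return List with `slope_au_per_min`, `intercept`, `r_squared`
#'   (`NA` for flat traces, where total variance is zero), `nonlinear`
#'   flag, and `n_points` used.
#' @examples
#' tr <- absorbance_trace("A1", seq(0, 120, 10), 0.2 + 0.05 * seq(0, 2, 1/6))
#' fit_slope(tr)$slope_au_per_min
#' @export
fit_slope <- function(trace, window = c("full", "initial")) {
  window <- match.arg(window)
  if (length(trace$times) < 3) {
    stop("need at least 3 points to fit a slope", call. = FALSE)
  }
  t_min <- trace$times / 60
  y <- trace$a578

  ols <- function(idx) {
    fit <- stats::lm(y[idx] ~ t_min[idx])
    ss_tot <- sum((y[idx] - mean(y[idx]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), r2 = r2, n = length(idx))
  }

  res <- ols(seq_along(y))
  if (window == "initial" && length(y) > 5) {
    cands <- lapply(5:length(y), function(m) ols(seq_len(m)))
    r2s <- vapply(cands, function(z) ifelse(is.na(z$r2), -Inf, z$r2), 0)
    if (any(is.finite(r2s))) res <- cands[[which.max(r2s)]]
  }

  list(slope_au_per_min = res$slope, intercept = res$intercept,
       r_squared = res$r2,
       nonlinear = !is.na(res$r2) && res$r2 < 0.9,
       n_points = res$n)
}

#' Convert an absorbance slope into an MV turnover rate
#'
#' Beer's-law conversion with a lumped, path-length-inclusive coefficient:
#' rate (mM reduced MV per minute) = slope (AU/min) / coefficient
#' (AU per mM). The protocol's plate-reader coefficient is 9.78; whether
#' it assumes a 1 cm path or folds in the plate geometry is not
#' distinguished here — it is a single configurable constant.
#'
#' @param slope_au_per_min Absorbance slope, AU/min.
#' @param conversion_coefficient AU per mM of reduced MV (default 9.78).
#' @return MV reduction rate, mM/min.
#' @export
slope_to_mv_rate <- function(slope_au_per_min, conversion_coefficient = 9.78) {
  if (any(conversion_coefficient <= 0)) {
    stop("`conversion_coefficient` must be positive", call. = FALSE)
  }
  slope_au_per_min / conversion_coefficient
}

#' Convert an MV turnover rate into a hydrogen rate
#'
#' Hydrogenases interconvert H2 with protons and electrons; each H2
#' oxidized delivers two single-electron MV reductions, so
#' h2_rate (pmol/min) = mv_rate (mM/min) x assay volume (uL) x 1000 / 2
#' (mM x uL = nmol; x1000 converts to pmol). The electron stoichiometry
#' is exposed for transparency.
#'
#' @param mv_rate_mM_per_min MV reduction rate, mM/min.
#' @param assay_volume_ul Assay volume, uL (default 200).
#' @param electrons_per_h2 Single-electron MV reductions per H2
#'   (default 2).
#' @return H2 rate, pmol/min.
#' @examples
#' mv_rate_to_h2_rate(0.01, 200)  # 1000 pmol H2/min
#' @export
mv_rate_to_h2_rate <- function(mv_rate_mM_per_min, assay_volume_ul = 200,
                               electrons_per_h2 = 2) {
  if (any(assay_volume_ul <= 0)) {
    stop("`assay_volume_ul` must be positive", call. = FALSE)
  }
  mv_rate_mM_per_min * assay_volume_ul * 1000 / electrons_per_h2
}

#' Full activity measurement for one trace
#'
#' Chains slope fitting, Beer's-law conversion and stoichiometry, and
#' normalizes by the volume of CFPS product assayed to give activity per
#' uL of CFPS reaction — the screen's working unit. Negative slopes are
#' permitted (background drift can dominate inactive wells) and flagged.
#'
#' @param trace An [absorbance_trace()].
#' @param cfps_volume_ul Volume of CFPS product added to the assay, uL.
#' @param conversion_coefficient AU per mM (default 9.78).
#' @param electrons_per_h2 Electron stoichiometry (default 2).
#' @return One-row data frame: `well`, `slope_au_min`, `mv_rate_mm_min`,
#'   `h2_rate_pmol_min`, `activity_per_ul`, `r_squared`, `nonlinear`,
#'   `background_dominated`.
#' @export
measure_trace <- function(trace, cfps_volume_ul,
                          conversion_coefficient = 9.78,
                          electrons_per_h2 = 2) {
  if (cfps_volume_ul <= 0) {
    stop("`cfps_volume_ul` must be positive", call. = FALSE)
  }
  sl <- fit_slope(trace)
  mv <- slope_to_mv_rate(sl$slope_au_per_min, conversion_coefficient)
  h2 <- mv_rate_to_h2_rate(mv, trace$assay_volume_ul, electrons_per_h2)
  data.frame(
    well = trace$well_id,
    slope_au_min = sl$slope_au_per_min,
    mv_rate_mm_min = mv,
    h2_rate_pmol_min = h2,
    activity_per_ul = h2 / cfps_volume_ul,
    r_squared = sl$r_squared,
    nonlinear = sl$nonlinear,
    background_dominated = sl$slope_au_per_min < 0
  )
}

#' Activity measurements for a set of traces
#'
#' @param traces List of [absorbance_trace()] objects.
#' @param cfps_volume_ul Volume of CFPS product per assay (recycled).
#' @param conversion_coefficient AU per mM (default 9.78).
#' @param electrons_per_h2 Electron stoichiometry (default 2).
#' @return Data frame with one row per trace (columns as
#'   [measure_trace()]).
#' @export
measure_traces <- function(traces, cfps_volume_ul,
                           conversion_coefficient = 9.78,
                           electrons_per_h2 = 2) {
  cf <- rep_len(cfps_volume_ul, length(traces))
  do.call(rbind, Map(function(tr, v) {
    measure_trace(tr, v, conversion_coefficient, electrons_per_h2)
  }, traces, cf))
}

#' Specific activity of an enzyme sample
#'
#' Rate divided by soluble protein mass, in pmol H2/min/ng. The direction
#' label records whether the rate was measured as H2 consumption (MV
#' reduction) or H2 production. Specific activities are only comparable
#' when expression levels are similar; [fold_improvement()] enforces a
#' similarity band.
#'
#' @param rate_pmol_min Measured rate, pmol H2/min.
#' @param protein_mass_ng Soluble protein yield, ng (> 0).
#' @param direction `"consumption"` or `"production"`.
#' @return Object of class `specific_activity`: `rate`, `protein_mass`,
#'   `value` (pmol H2/min/ng), `direction`.
#' @examples
#' specific_activity(1500, 10)$value  # 150, wild-type magnitude
#' @export
specific_activity <- function(rate_pmol_min, protein_mass_ng,
                              direction = c("consumption", "production")) {
  direction <- match.arg(direction)
  if (!is.numeric(protein_mass_ng) || protein_mass_ng <= 0) {
    stop("`protein_mass_ng` must be positive", call. = FALSE)
  }
  structure(
    list(rate = rate_pmol_min, protein_mass = protein_mass_ng,
         value = rate_pmol_min / protein_mass_ng, direction = direction),
    class = "specific_activity"
  )
}

#' @export
print.specific_activity <- function(x, ...) {
  cat(sprintf("Specific activity (%s): %.3g pmol H2/min/ng (%g pmol/min over %g ng)\n",
              x$direction, x$value, x$rate, x$protein_mass))
  invisible(x)
}

#' Fold improvement of a mutant over the wild type
#'
#' Ratio of specific activities measured in the same direction. By
#' default the comparison is refused when the two samples' protein yields
#' differ by more than `expression_band` (25%), since specific activities
#' are only compared when expression levels are similar.
#'
#' @param mutant,wildtype `specific_activity` objects with matching
#'   direction.
#' @param expression_band Maximum relative difference in protein mass
#'   allowed for a comparison (default 0.25; `Inf` disables the check).
#' @return Dimensionless fold improvement.
#' @export
fold_improvement <- function(mutant, wildtype, expression_band = 0.25) {
  stopifnot(inherits(mutant, "specific_activity"),
            inherits(wildtype, "specific_activity"))
  if (mutant$direction != wildtype$direction) {
    stop("cannot compare specific activities measured in different directions",
         call. = FALSE)
  }
  if (wildtype$value <= 0) {
    stop("wild-type specific activity must be positive", call. = FALSE)
  }
  rel <- abs(mutant$protein_mass - wildtype$protein_mass) /
    wildtype$protein_mass
  if (rel > expression_band) {
    stop(sprintf(paste0("expression levels differ by %.0f%% (> %.0f%% band); ",
                        "specific activities are not comparable"),
                 100 * rel, 100 * expression_band), call. = FALSE)
  }
  mutant$value / wildtype$value
}

#' Protein mass from radiolabel counting parameters
#'
#' Pure arithmetic converting scintillation counts of 14C-leucine
#' incorporation into protein mass: disintegrations = counts /
#' counting_efficiency; mol leucine = disintegrations / specific
#' radioactivity; mol protein = mol leucine / leucines per protein;
#' mass = mol protein x molar mass. All parameters are user-supplied;
#' the counting chemistry itself is out of scope.
#'
#' @param counts Measured counts per minute.
#' @param counting_efficiency Fraction of disintegrations counted.
#' @param specific_radioactivity_dpm_per_mol Label activity, dpm/mol
#'   leucine.
#' @param leucines_per_protein Leucine residues per protein molecule.
#' @param protein_molar_mass_g_per_mol Protein molar mass, g/mol.
#' @return Protein mass in ng.
#' @export
protein_mass_from_counts <- function(counts, counting_efficiency,
                                     specific_radioactivity_dpm_per_mol,
                                     leucines_per_protein,
                                     protein_molar_mass_g_per_mol) {
  if (counting_efficiency <= 0 || counting_efficiency > 1) {
    stop("`counting_efficiency` must lie in (0, 1]", call. = FALSE)
  }
  dpm <- counts / counting_efficiency
  mol_leu <- dpm / specific_radioactivity_dpm_per_mol
  mol_protein <- mol_leu / leucines_per_protein
  mol_protein * protein_molar_mass_g_per_mol * 1e9
}
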