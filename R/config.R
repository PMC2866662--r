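#' Screen configuration: every protocol constant in one object
#'
#' Collects the constants of the screening protocol with their
#' provenance. Defaults marked "protocol" are the published operating
#' points; defaults marked "choice" are package decisions where the
#' protocol states none.
#'
#' @param lambda Mean template molecules per well (protocol: 2.3, leaving
#'   about 10% of wells empty).
#' @param cv Target coefficient of variance of replicate wild-type
#'   residual-activity ratios (protocol range 0.15-0.25; default 0.20).
#' @param decay_rate_per_ul Oxygen-deactivation rate k, per uL of
#'   air-equilibrated buffer (choice: 0.12, which puts the protocol's
#'   15 uL exposure at exp(-1.8) = 16.5% residual, inside the 15-20%
#'   operating band).
#' @param exposure_volume_ul Exposure volume, uL (protocol: 15).
#' @param volume_factor Post/pre assayed-volume ratio (protocol: 5; 1 uL
#'   pre vs 5 uL post).
#' @param sd_multiplier Hit threshold in wild-type SDs above the mean
#'   (protocol: 2).
#' @param min_pre_activity_fraction Minimum pre-exposure activity, as a
#'   fraction of the plate wild-type mean, below which a well is
#'   disqualified (choice: 0.25, above the control background band).
#' @param conversion_coefficient Beer's-law conversion, AU per mM of
#'   reduced MV (protocol: 9.78).
#' @param mv_concentration_mM Methyl viologen concentration, mM
#'   (protocol: 2).
#' @param o2_concentration_mM Dissolved O2 of air-equilibrated buffer, mM
#'   (protocol: ~0.25).
#' @param assay_volume_ul Assay volume, uL (protocol: 200).
#' @param electrons_per_h2 MV reductions per H2 (stoichiometry: 2).
#' @param target_residual Residual-activity operating band (protocol:
#'   0.15-0.20).
#' @param wt_activity_per_ul Wild-type activity per uL of CFPS product,
#'   pmol H2/min/uL (choice: 1500, i.e. the 150 pmol/min/ng wild-type
#'   specific activity at a 10 ng/uL soluble CFPS yield; the implied
#'   pre-exposure slope, about 0.15 AU/min, keeps plate-reader noise
#'   negligible next to biological variation, as in the protocol).
#' @param wt_specific_activity Wild-type specific activity, pmol
#'   H2/min/ng (protocol: 150).
#' @param background_slope_fraction No-enzyme background slope as a
#'   fraction of the wild-type slope (choice: 0.05 — control slopes are
#'   small compared to hydrogenase wells).
#' @param read_noise_au Gaussian per-point absorbance read noise, AU
#'   (choice: 0.002).
#' @param pre_cfps_volume_ul CFPS product volume assayed pre-exposure, uL
#'   (protocol: 1).
#' @return Object of class `screen_config` (a validated named list with a
#'   `provenance` attribute).
#' @examples
#' cfg <- screen_config()
#' cfg$lambda
#' @export
screen_config <- function(lambda = 2.3,
                          cv = 0.20,
                          decay_rate_per_ul = 0.12,
                          exposure_volume_ul = 15,
                          volume_factor = 5,
                          sd_multiplier = 2,
                          min_pre_activity_fraction = 0.25,
                          conversion_coefficient = 9.78,
                          mv_concentration_mM = 2,
                          o2_concentration_mM = 0.25,
                          assay_volume_ul = 200,
                          electrons_per_h2 = 2,
                          target_residual = c(0.15, 0.20),
                          wt_activity_per_ul = 1500,
                          wt_specific_activity = 150,
                          background_slope_fraction = 0.05,
                          read_noise_au = 0.002,
                          pre_cfps_volume_ul = 1) {
  cfg <- list(
    lambda = lambda, cv = cv, decay_rate_per_ul = decay_rate_per_ul,
    exposure_volume_ul = exposure_volume_ul, volume_factor = volume_factor,
    sd_multiplier = sd_multiplier,
    min_pre_activity_fraction = min_pre_activity_fraction,
    conversion_coefficient = conversion_coefficient,
    mv_concentration_mM = mv_concentration_mM,
    o2_concentration_mM = o2_concentration_mM,
    assay_volume_ul = assay_volume_ul,
    electrons_per_h2 = electrons_per_h2,
    target_residual = target_residual,
    wt_activity_per_ul = wt_activity_per_ul,
    wt_specific_activity = wt_specific_activity,
    background_slope_fraction = background_slope_fraction,
    read_noise_au = read_noise_au,
    pre_cfps_volume_ul = pre_cfps_volume_ul
  )
  scalars <- setdiff(names(cfg), "target_residual")
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  positive <- c("lambda", "decay_rate_per_ul", "volume_factor",
                "conversion_coefficient", "assay_volume_ul",
                "electrons_per_h2", "wt_activity_per_ul",
                "pre_cfps_volume_ul")
  for (nm in positive) {
    if (cfg[[nm]] <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  if (length(cfg$target_residual) != 2L ||
      any(cfg$target_residual <= 0) || any(cfg$target_residual >= 1) ||
      diff(cfg$target_residual) < 0) {
    stop("`target_residual` must be an increasing pair inside (0, 1)",
         call. = FALSE)
  }
  provenance <- c(
    lambda = "protocol", cv = "protocol range 0.15-0.25",
    decay_rate_per_ul = "choice", exposure_volume_ul = "protocol",
    volume_factor = "protocol", sd_multiplier = "protocol",
    min_pre_activity_fraction = "choice",
    conversion_coefficient = "protocol", mv_concentration_mM = "protocol",
    o2_concentration_mM = "protocol", assay_volume_ul = "protocol",
    electrons_per_h2 = "stoichiometry", target_residual = "protocol",
    wt_activity_per_ul = "choice", wt_specific_activity = "protocol",
    background_slope_fraction = "choice", read_noise_au = "choice",
    pre_cfps_volume_ul = "protocol"
  )
  structure(cfg, provenance = provenance, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Screen configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %-12s [%s]\n", nm,
                paste(format(x[[nm]]), collapse = "-"), prov[[nm]]))
  }
  invisible(x)
}

# wild-type slope implied by the config, AU/min, for 1 uL CFPS assayed
wt_slope_au_per_min <- function(config, cfps_volume_ul = 1) {
  h2 <- config$wt_activity_per_ul * cfps_volume_ul
  mv <- h2 * config$electrons_per_h2 / (config$assay_volume_ul * 1000)
  mv * config$conversion_coefficient
}
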