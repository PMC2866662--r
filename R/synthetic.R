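#' Mutant effect model for library simulation
#'
#' The genotype-to-phenotype map of the simulator: a mutant is inactive
#' with probability `p_inactive`; otherwise its specific activity and its
#' oxygen-deactivation rate are the wild-type values times lognormal
#' multiplicative factors. Tolerance factors below 1 mean slower
#' deactivation (more tolerant). The real library's effect-size spectrum
#' is unknown; these distributions are declared stand-ins. Defaults make
#' substantially tolerance-improved mutants vanishingly rare, mirroring
#' the screening campaign's outcome, while leaving a thin upper tail of
#' activity-improved mutants.
#'
#' @param p_inactive Probability a mutant is inactive (default 0.3, a
#'   typical knockout fraction at 2-10 nucleotide changes per gene).
#' @param activity_meanlog,activity_sdlog Lognormal parameters of the
#'   activity factor for active mutants (default median 1, sdlog 0.2).
#' @param tolerance_meanlog,tolerance_sdlog Lognormal parameters of the
#'   deactivation-rate factor (default meanlog 0.05, sdlog 0.05: factors
#'   concentrate just above 1).
#' @param mutations_range Integer range of nucleotide mutations per gene
#'   (default 2 to 10).
#' @return Object of class `effect_model`.
#' @export
effect_model <- function(p_inactive = 0.3,
                         activity_meanlog = 0, activity_sdlog = 0.2,
                         tolerance_meanlog = 0.05, tolerance_sdlog = 0.05,
                         mutations_range = c(2L, 10L)) {
  if (p_inactive < 0 || p_inactive > 1) {
    stop("`p_inactive` must lie in [0, 1]", call. = FALSE)
  }
  if (activity_sdlog < 0 || tolerance_sdlog < 0) {
    stop("sdlog parameters must be non-negative", call. = FALSE)
  }
  if (length(mutations_range) != 2L || mutations_range[1] < 0 ||
      diff(mutations_range) < 0) {
    stop("`mutations_range` must be a non-decreasing pair of non-negative integers",
         call. = FALSE)
  }
  structure(
    list(p_inactive = p_inactive,
         activity_meanlog = activity_meanlog,
         activity_sdlog = activity_sdlog,
         tolerance_meanlog = tolerance_meanlog,
         tolerance_sdlog = tolerance_sdlog,
         mutations_range = as.integer(mutations_range)),
    class = "effect_model"
  )
}

#' Simulate a mutant library
#'
#' Draws `n_mutants` mutants from an [effect_model()]. Inactive mutants
#' have `activity_factor = 0`. Output is reproducible for a fixed seed.
#'
#' @param n_mutants Library size (>= 1). The published campaign screened
#'   about 30,000 mutants.
#' @param model An [effect_model()].
#' @param seed Integer seed.
#' @return Data frame: `mutant_id`, `n_mutations`, `activity_factor`,
#'   `tolerance_factor`.
#' @export
simulate_library <- function(n_mutants, model = effect_model(), seed = 1L) {
  stopifnot(inherits(model, "effect_model"))
  if (n_mutants < 1) stop("`n_mutants` must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_mutants)
  inactive <- stats::runif(n) < model$p_inactive
  act <- stats::rlnorm(n, model$activity_meanlog, model$activity_sdlog)
  act[inactive] <- 0
  tol <- stats::rlnorm(n, model$tolerance_meanlog, model$tolerance_sdlog)
  data.frame(
    mutant_id = sprintf("M%05d", seq_len(n)),
    n_mutations = sample(model$mutations_range[1]:model$mutations_range[2],
                         n, replace = TRUE),
    activity_factor = act,
    tolerance_factor = tol,
    stringsAsFactors = FALSE
  )
}

#' Plate layout specification
#'
#' Default 96-well layout: 8 wild-type control wells (column 1, rows
#' A-H... truncated to the requested count), 2 no-template and 2 CAT
#' (chloramphenicol acetyltransferase, an unrelated-enzyme background)
#' controls in the last column, remaining wells are samples. Wild-type
#' controls on every plate are required by the per-plate normalization.
#'
#' @param plate_size 96 or 384.
#' @param n_wildtype,n_no_template,n_cat Control well counts per plate.
#' @return Data frame `well`, `role` covering the whole plate.
#' @export
plate_layout <- function(plate_size = 96, n_wildtype = 8,
                         n_no_template = 2, n_cat = 2) {
  wells <- plate_wells(plate_size)
  n <- length(wells)
  if (n_wildtype < 1) {
    stop("at least one wild-type control well is required", call. = FALSE)
  }
  if (n_wildtype + n_no_template + n_cat >= n) {
    stop("controls exceed plate capacity", call. = FALSE)
  }
  role <- rep("sample", n)
  role[seq_len(n_wildtype)] <- "wildtype_control"           # column 1
  tail_idx <- n - seq_len(n_no_template + n_cat) + 1        # last column
  role[tail_idx[seq_len(n_cat)]] <- "CAT_control"
  role[tail_idx[n_cat + seq_len(n_no_template)]] <- "no_template_control"
  data.frame(well = wells, role = role, stringsAsFactors = FALSE)
}

# canonical well ids, column-major within rows A.. (A1, B1, ... then A2 ...)
plate_wells <- function(plate_size = 96) {
  if (plate_size == 96) {
    rows <- LETTERS[1:8]; cols <- 1:12
  } else if (plate_size == 384) {
    rows <- LETTERS[1:16]; cols <- 1:24
  } else {
    stop("`plate_size` must be 96 or 384", call. = FALSE)
  }
  as.vector(outer(rows, cols, function(r, cc) paste0(r, cc)))
}

#' Simulate a full screening campaign
#'
#' Generates the well-level truth and measured activities of a
#' limiting-dilution screen. Per sample well, the gene count is
#' Poisson(`lambda`); wells drawing 0 are empty. Members are taken
#' sequentially from the library (wrapping around if the campaign
#' exceeds the library). A well's true pre-exposure activity is the MEAN
#' of its members' activities times the wild-type level — co-occupancy
#' averages an improved mutant's signal with its well-mates' — times a
#' lognormal CFPS-yield factor. The true post-exposure activity applies
#' each member's own deactivation rate over the configured exposure.
#'
#' Measured activities multiply independent lognormal read-noise factors
#' onto the pre and post assays, calibrated so the residual-activity
#' ratio of replicate wild-type wells has the configured CV (yield
#' variation cancels in the ratio, so the two read noises carry it:
#' each has sdlog = sqrt(log(1 + cv^2) / 2); the yield factor reuses the
#' same sdlog, splitting a single read's variance evenly between yield
#' and measurement). A small background activity (lognormal around
#' `background_slope_fraction` of wild type) adds to every assay,
#' dominating empty and control wells. The post assay uses
#' `volume_factor` times the pre volume of CFPS product, so raw post
#' rates are comparable to pre rates near the residual-activity target.
#'
#' @param library Data frame from [simulate_library()].
#' @param n_plates Number of plates.
#' @param config A [screen_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param layout A [plate_layout()] (default 96-well with 8 WT controls).
#' @param planted Optional data frame `plate`, `well`, `mutant_id`
#'   forcing those sample wells to contain exactly that library mutant
#'   (used to plant known hits for power evaluation).
#' @return List of class `simulated_screen`: `wells` (plate, well, role,
#'   mutant_ids, pre/post measured activities), `truth` (member ids and
#'   true activities per well), `config`, `seed`.
#' @export
simulate_screen <- function(library, n_plates, config = screen_config(),
                            seed = 1L, layout = plate_layout(),
                            planted = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (config$lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  if (config$cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  set.seed(seed)

  sdlog_read <- sqrt(log1p(config$cv^2) / 2)
  sdlog_yield <- sdlog_read
  k <- config$decay_rate_per_ul
  v_exp <- config$exposure_volume_ul
  wt <- config$wt_activity_per_ul
  bg_level <- config$background_slope_fraction * wt

  grid <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    cbind(plate = p, layout)
  }))
  n_wells_total <- nrow(grid)
  is_sample <- grid$role == "sample"
  is_wt <- grid$role == "wildtype_control"

  # Poisson occupancy for sample wells; members drawn sequentially
  counts <- integer(n_wells_total)
  counts[is_sample] <- stats::rpois(sum(is_sample), config$lambda)
  counts[is_wt] <- 1L
  lib_n <- nrow(library)
  total_needed <- sum(counts[is_sample])
  lib_idx <- if (total_needed > 0) {
    ((seq_len(total_needed) - 1L) %% lib_n) + 1L
  } else integer(0)

  member_ids <- vector("list", n_wells_total)
  act <- tol <- vector("list", n_wells_total)
  pos <- 0L
  for (i in which(is_sample)) {
    ki <- counts[i]
    if (ki > 0) {
      idx <- lib_idx[pos + seq_len(ki)]
      pos <- pos + ki
      member_ids[[i]] <- library$mutant_id[idx]
      act[[i]] <- library$activity_factor[idx]
      tol[[i]] <- library$tolerance_factor[idx]
    } else {
      member_ids[[i]] <- character(0)
      act[[i]] <- numeric(0)
      tol[[i]] <- numeric(0)
    }
  }
  for (i in which(is_wt)) {
    member_ids[[i]] <- "WT"
    act[[i]] <- 1
    tol[[i]] <- 1
  }

  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    for (j in seq_len(nrow(planted))) {
      sel <- which(grid$plate == planted$plate[j] &
                     grid$well == planted$well[j])
      if (length(sel) != 1L || grid$role[sel] != "sample") {
        stop(sprintf("planted well %s on plate %s is not a sample well",
                     planted$well[j], planted$plate[j]), call. = FALSE)
      }
      li <- match(planted$mutant_id[j], library$mutant_id)
      if (is.na(li)) {
        stop(sprintf("planted mutant %s not in library",
                     planted$mutant_id[j]), call. = FALSE)
      }
      member_ids[[sel]] <- library$mutant_id[li]
      act[[sel]] <- library$activity_factor[li]
      tol[[sel]] <- library$tolerance_factor[li]
      counts[sel] <- 1L
    }
  }

  # true activities: mean over members (signal averaging in shared wells)
  true_pre <- vapply(act, function(a) if (length(a)) wt * mean(a) else 0, 0)
  true_post <- mapply(function(a, tf) {
    if (length(a)) wt * mean(a * exp(-tf * k * v_exp)) else 0
  }, act, tol)

  yield <- stats::rlnorm(n_wells_total, -sdlog_yield^2 / 2, sdlog_yield)
  noise_pre <- stats::rlnorm(n_wells_total, -sdlog_read^2 / 2, sdlog_read)
  # post-read meanlog offset makes the post/pre RATIO mean-unbiased
  # (E[noise_post/noise_pre] = 1), so replicate wild-type wells average to
  # exp(-k V) with the configured CV
  noise_post <- stats::rlnorm(n_wells_total, -3 * sdlog_read^2 / 2,
                              sdlog_read)
  bg_pre <- bg_level * stats::rlnorm(n_wells_total, 0, 0.5)
  bg_post <- bg_level * stats::rlnorm(n_wells_total, 0, 0.5)

  pre_per_ul <- true_pre * yield * noise_pre + bg_pre
  # raw post rate: volume_factor x the per-uL post activity, same yield
  post_raw <- config$volume_factor * true_post * yield * noise_post + bg_post

  wells <- data.frame(
    plate = grid$plate, well = grid$well, role = grid$role,
    mutant_ids = vapply(member_ids, paste, "", collapse = ","),
    n_genes = counts,
    pre_activity = pre_per_ul,
    post_activity = post_raw,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    plate = grid$plate, well = grid$well, role = grid$role,
    mutant_ids = wells$mutant_ids, n_genes = counts,
    true_pre_per_ul = true_pre, true_post_per_ul = true_post,
    cfps_yield_factor = yield,
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells, truth = truth, config = config, seed = seed),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("Simulated screen: %d plates, %d wells (%d sample, %d WT control), seed %d\n",
              length(unique(x$wells$plate)), nrow(x$wells),
              sum(x$wells$role == "sample"),
              sum(x$wells$role == "wildtype_control"), x$seed))
  invisible(x)
}

#' Generate a synthetic absorbance trace for a known activity
#'
#' Inverse of the assay module: pushes a true activity (pmol H2/min/uL of
#' CFPS product) backward through stoichiometry and Beer's law to an
#' absorbance slope, then emits a linear A578 ramp with Gaussian read
#' noise plus a background slope (no-enzyme wells drift slowly). Slopes
#' implying depletion of the MV pool within the 2-minute read (more than
#' `mv_concentration_mM` reduced) are clipped and flagged `saturated`.
#'
#' @param true_activity_per_ul True activity, pmol H2/min/uL (>= 0).
#' @param cfps_volume_ul CFPS product volume in the assay, uL.
#' @param config A [screen_config()].
#' @param well_id Well label for the trace.
#' @param times Read times, seconds (default 0-120 s every 10 s).
#' @param background Include the background slope (default TRUE).
#' @param noise Include Gaussian read noise (default TRUE).
#' @return An [absorbance_trace()] with attribute `saturated`.
#' @export
generate_trace <- function(true_activity_per_ul, cfps_volume_ul,
                           config = screen_config(), well_id = "A1",
                           times = seq(0, 120, by = 10),
                           background = TRUE, noise = TRUE) {
  if (true_activity_per_ul < 0) {
    stop("`true_activity_per_ul` must be non-negative", call. = FALSE)
  }
  h2_rate <- true_activity_per_ul * cfps_volume_ul
  mv_rate <- h2_rate * config$electrons_per_h2 /
    (config$assay_volume_ul * 1000)
  slope <- mv_rate * config$conversion_coefficient
  if (background) {
    slope <- slope + config$background_slope_fraction *
      wt_slope_au_per_min(config, config$pre_cfps_volume_ul)
  }

  # mass balance: reads last 2 minutes; cannot reduce more MV than the pool
  duration_min <- (max(times) - min(times)) / 60
  max_mv_rate <- config$mv_concentration_mM / max(duration_min, 1e-9)
  max_slope <- max_mv_rate * config$conversion_coefficient
  saturated <- slope > max_slope
  if (saturated) slope <- max_slope

  a0 <- 0.2
  a <- a0 + slope * times / 60
  if (noise) a <- a + stats::rnorm(length(times), 0, config$read_noise_au)
  tr <- absorbance_trace(well_id, times, a,
                         assay_volume_ul = config$assay_volume_ul,
                         mv_concentration_mM = config$mv_concentration_mM)
  attr(tr, "saturated") <- saturated
  tr
}

#' Absorbance traces for a simulated screen
#'
#' Emits pre- and post-exposure traces for every well of a
#' [simulate_screen()] result, consistent with its measured activities
#' (the trace slope encodes the well's noisy measured rate; trace read
#' noise comes on top). Intended for exercising the assay module
#' end-to-end on plate-sized data.
#'
#' @param screen A `simulated_screen`.
#' @param plates Which plates to emit (default: all).
#' @return List with `pre` and `post`: lists of [absorbance_trace()],
#'   named `plate:well`.
#' @export
screen_traces <- function(screen, plates = NULL) {
  stopifnot(inherits(screen, "simulated_screen"))
  w <- screen$wells
  if (!is.null(plates)) w <- w[w$plate %in% plates, , drop = FALSE]
  cfg <- screen$config
  mk <- function(activity, cfps_vol, id) {
    generate_trace(max(activity, 0) / cfps_vol, cfps_vol, cfg,
                   well_id = id, background = FALSE, noise = TRUE)
  }
  ids <- paste(w$plate, w$well, sep = ":")
  pre <- Map(function(a, id) mk(a * cfg$pre_cfps_volume_ul,
                                cfg$pre_cfps_volume_ul, id),
             w$pre_activity, ids)
  post_vol <- cfg$pre_cfps_volume_ul * cfg$volume_factor
  post <- Map(function(a, id) mk(a, post_vol, id), w$post_activity, ids)
  list(pre = stats::setNames(pre, ids), post = stats::setNames(post, ids))
}
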