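#' Read a plate map
#'
#' CSV contract: header `well,role[,mutant_ids]`. Well coordinates are
#' letter-row/number-column (A1..H12 for 96-well, A1..P24 for 384-well),
#' case-insensitive on input and canonical uppercase on output. Roles
#' come from the fixed vocabulary `sample`, `wildtype_control`,
#' `no_template_control`, `CAT_control`. Duplicate wells are rejected by
#' name.
#'
#' @param path CSV file path.
#' @return Data frame `well`, `role` (and `mutant_ids` if present) with
#'   attribute `plate_size`.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "role") %in% names(df))) {
    stop("plate map needs columns `well` and `role`", call. = FALSE)
  }
  df$well <- toupper(trimws(df$well))
  bad <- !grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", df$well)
  if (any(bad)) {
    stop("malformed well coordinates: ",
         paste(unique(df$well[bad]), collapse = ", "), call. = FALSE)
  }
  dup <- df$well[duplicated(df$well)]
  if (length(dup)) {
    stop("duplicate wells: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  roles <- c("sample", "wildtype_control", "no_template_control",
             "CAT_control")
  if (!all(df$role %in% roles)) {
    stop("unknown roles: ",
         paste(unique(setdiff(df$role, roles)), collapse = ", "),
         call. = FALSE)
  }
  rows <- substr(df$well, 1, 1)
  cols <- as.integer(substring(df$well, 2))
  plate_size <- if (all(rows %in% LETTERS[1:8]) && all(cols <= 12)) 96 else 384
  attr(df, "plate_size") <- plate_size
  df
}

#' Write a plate map
#'
#' @param map Data frame `well`, `role` (optionally `mutant_ids`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Read absorbance traces from long-format CSV
#'
#' CSV contract: header `well,time_s,a578`, one row per read. Rows are
#' grouped by well and sorted by time; duplicated timestamps within a
#' well are rejected (the sorting contract makes row order irrelevant).
#' Non-numeric values are reported with their row numbers. An empty file
#' yields an empty list with a warning.
#'
#' @param path CSV file path.
#' @param assay_volume_ul Assay volume recorded on each trace (default
#'   200).
#' @param mv_concentration_mM MV concentration recorded on each trace
#'   (default 2).
#' @return Named list of [absorbance_trace()] objects.
#' @export
read_traces <- function(path, assay_volume_ul = 200,
                        mv_concentration_mM = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) {
    warning("no trace rows in ", path)
    return(list())
  }
  if (!all(c("well", "time_s", "a578") %in% names(df))) {
    stop("trace file needs columns `well`, `time_s`, `a578`", call. = FALSE)
  }
  t_num <- suppressWarnings(as.numeric(df$time_s))
  a_num <- suppressWarnings(as.numeric(df$a578))
  bad <- which(is.na(t_num) | is.na(a_num))
  if (length(bad)) {
    stop("non-numeric time_s/a578 at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$time_s <- t_num
  df$a578 <- a_num
  traces <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    if (anyDuplicated(d$time_s)) {
      stop("duplicate timestamps in well ", d$well[1], call. = FALSE)
    }
    absorbance_trace(d$well[1], d$time_s, d$a578, assay_volume_ul,
                     mv_concentration_mM)
  })
  traces[order(names(traces))]
}

#' Write absorbance traces to long-format CSV
#'
#' @param traces List of [absorbance_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(well = tr$well_id, time_s = tr$times, a578 = tr$a578)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an amplification-outcome table
#'
#' CSV contract: header `reaction_volume_ul,n_wells,n_amplified` (or
#' `fraction_amplified` in place of the count).
#'
#' @param path CSV file path.
#' @return Validated amplification table.
#' @export
read_amplification_table <- function(path) {
  validate_amplification_table(
    utils::read.csv(path, stringsAsFactors = FALSE),
    require_distinct = FALSE)
}

#' Write an amplification-outcome table
#'
#' @param table Amplification table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_amplification_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# keys a run configuration may contain, beyond the screen constants
run_config_extra_keys <- c("n_mutants", "n_plates", "seed", "out_dir",
                           "use_traces", "plate_size", "n_wildtype",
                           "n_no_template", "n_cat")

#' Read and validate a run configuration
#'
#' YAML with two groups of keys: campaign keys (`n_mutants`, `n_plates`,
#' `seed`, `out_dir`, `use_traces`, `plate_size`, `n_wildtype`,
#' `n_no_template`, `n_cat`) and any [screen_config()] constant.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return List with `screen` (a `screen_config`) and the campaign keys.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  screen_keys <- names(formals(screen_config))
  unknown <- setdiff(names(raw), c(screen_keys, run_config_extra_keys))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  screen_args <- raw[intersect(names(raw), screen_keys)]
  cfg <- do.call(screen_config, screen_args)
  extras <- raw[intersect(names(raw), run_config_extra_keys)]
  defaults <- list(n_mutants = 1000, n_plates = 2, seed = 1L,
                   out_dir = "screen_run", use_traces = TRUE,
                   plate_size = 96, n_wildtype = 8, n_no_template = 2,
                   n_cat = 2)
  extras <- utils::modifyList(defaults, extras)
  c(list(screen = cfg), extras)
}

#' Run the full synthetic screening pipeline
#'
#' simulate -> assay -> analyze -> summarize. Simulates a campaign from
#' the run configuration, optionally regenerates absorbance traces and
#' re-derives every activity through the assay module (slope fit, Beer's
#' law, stoichiometry), scores and calls hits, and writes: per-plate
#' plate maps, trace CSVs (when `use_traces`), the scored well table and
#' hit list as TSV, a JSON screen summary, and a manifest recording the
#' seed, configuration, and md5 of every output so a run can be
#' reproduced exactly. All randomness flows from the single configured
#' seed; outputs are byte-identical across reruns.
#'
#' @param config A list from [read_run_config()] (or of the same shape).
#' @return The output directory path, invisibly; the `screen_result` as
#'   attribute `result`.
#' @export
run_pipeline <- function(config) {
  cfg <- config$screen
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lib <- simulate_library(config$n_mutants, seed = config$seed)
  layout <- plate_layout(config$plate_size, config$n_wildtype,
                         config$n_no_template, config$n_cat)
  screen <- simulate_screen(lib, config$n_plates, cfg,
                            seed = config$seed + 1L, layout = layout)
  wells <- screen$wells

  files <- character(0)
  for (p in unique(wells$plate)) {
    pm <- wells[wells$plate == p, c("well", "role", "mutant_ids")]
    f <- file.path(out_dir, sprintf("plate_%03d_map.csv", p))
    write_plate_map(pm, f)
    files <- c(files, f)
  }

  if (isTRUE(config$use_traces)) {
    # push activities through traces and back through the assay module
    traces <- screen_traces(screen)
    for (p in unique(wells$plate)) {
      sel <- startsWith(names(traces$pre), paste0(p, ":"))
      f1 <- file.path(out_dir, sprintf("plate_%03d_pre_traces.csv", p))
      f2 <- file.path(out_dir, sprintf("plate_%03d_post_traces.csv", p))
      write_traces(traces$pre[sel], f1)
      write_traces(traces$post[sel], f2)
      files <- c(files, f1, f2)
    }
    pre_meas <- measure_traces(traces$pre, cfg$pre_cfps_volume_ul,
                               cfg$conversion_coefficient,
                               cfg$electrons_per_h2)
    post_vol <- cfg$pre_cfps_volume_ul * cfg$volume_factor
    post_meas <- measure_traces(traces$post, post_vol,
                                cfg$conversion_coefficient,
                                cfg$electrons_per_h2)
    ids <- paste(wells$plate, wells$well, sep = ":")
    wells$pre_activity <-
      pre_meas$activity_per_ul[match(ids, pre_meas$well)] *
      cfg$pre_cfps_volume_ul
    wells$post_activity <-
      post_meas$h2_rate_pmol_min[match(ids, post_meas$well)]
  }

  result <- screen_analyze(wells, cfg)

  scored <- file.path(out_dir, "wells_scored.tsv")
  utils::write.table(result$records, scored, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  hitfile <- file.path(out_dir, "hits.tsv")
  utils::write.table(result$hits, hitfile, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, scored, hitfile)

  summary_file <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(seed = config$seed,
         n_plates = config$n_plates,
         n_wells = nrow(result$records),
         n_tolerance_hits = sum(result$records$tolerance_hit),
         n_activity_hits = sum(result$records$activity_hit),
         per_plate = result$summary),
    summary_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, summary_file)

  cfg_echo <- file.path(out_dir, "config_echo.json")
  jsonlite::write_json(unclass(cfg), cfg_echo, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, cfg_echo)

  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_echo)),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- invisible(out_dir)
  attr(out, "result") <- result
  out
}
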