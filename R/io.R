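csv_dialect <- c("subject_id", "sex", "route", "label", "dose_mg_per_kg",
                 "time_h", "conc_ug_per_ml")

#' Read a concentration-time CSV into series objects
#'
#' Reads the package CSV dialect (one row per observation; header with
#' columns `subject_id`, `sex`, `route`, `label`, `dose_mg_per_kg`,
#' `time_h`, `conc_ug_per_ml`, optional `censored`; period decimal
#' separator, UTF-8) and validates it row by row: unknown routes or
#' sexes, negative concentrations, non-increasing times within a subject
#' and inconsistent per-subject dose are rejected with the offending line
#' number (header = line 1).
#'
#' @param path Path to the CSV file.
#' @return List of [concentration_series()], one per subject, in order of
#'   first appearance. An empty file with a valid header yields an empty
#'   list with a warning.
#' @export
read_concentration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(csv_dialect, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("no observations in ", path)
    return(list())
  }
  line <- seq_len(nrow(df)) + 1L
  bad <- !df$route %in% c("oral", "iv")
  if (any(bad))
    stop(sprintf("line %d: unknown route '%s' (column route)",
                 line[bad][1], df$route[bad][1]), call. = FALSE)
  bad <- !df$sex %in% c("male", "female")
  if (any(bad))
    stop(sprintf("line %d: unknown sex '%s' (column sex)",
                 line[bad][1], df$sex[bad][1]), call. = FALSE)
  for (col in c("dose_mg_per_kg", "time_h", "conc_ug_per_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.finite(v)
    if (any(bad))
      stop(sprintf("line %d: non-numeric value '%s' (column %s)",
                   line[bad][1], df[[col]][bad][1], col), call. = FALSE)
    df[[col]] <- v
  }
  bad <- df$conc_ug_per_ml < 0
  if (any(bad))
    stop(sprintf("line %d: negative concentration (column conc_ug_per_ml)",
                 line[bad][1]), call. = FALSE)
  if (!"censored" %in% names(df)) df$censored <- df$conc_ug_per_ml == 0
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    sub <- df[df$subject_id == id, ]
    if (length(unique(sub$dose_mg_per_kg)) != 1L ||
        length(unique(sub$route)) != 1L)
      stop(sprintf("line %d: subject %s has inconsistent dose or route",
                   line[df$subject_id == id][1], id), call. = FALSE)
    noninc <- which(diff(sub$time_h) <= 0)
    if (length(noninc) > 0L)
      stop(sprintf("line %d: time not strictly increasing for subject %s (column time_h)",
                   line[df$subject_id == id][noninc[1] + 1L], id),
           call. = FALSE)
    concentration_series(id, sub$sex[1], sub$route[1],
                         sub$dose_mg_per_kg[1], sub$time_h,
                         sub$conc_ug_per_ml, label = sub$label[1],
                         censored = as.logical(sub$censored))
  })
}

#' Write concentration data to CSV
#'
#' Accepts either the flat data frame produced by [generate_study()] or a
#' list of [concentration_series()], and writes the package CSV dialect
#' (period decimal separator, UTF-8, header row).
#'
#' @param x Data frame or list of `conc_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(x, path) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "conc_series")))
    df <- do.call(rbind, lapply(x, function(s) {
      data.frame(subject_id = s$subject_id, sex = s$sex, route = s$route,
                 label = s$label, dose_mg_per_kg = s$dose$amount,
                 time_h = s$observations$time_h,
                 conc_ug_per_ml = s$observations$conc_ug_per_ml,
                 censored = s$observations$censored)
    }))
  }
  missing_cols <- setdiff(csv_dialect, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialise fit results to a machine-readable report
#'
#' One record per fit with estimates, standard errors, 95% confidence
#' intervals, significance flags, WRSS, AIC and convergence diagnostics.
#'
#' @param fits List of `"tk_fit"` objects.
#' @return A list (JSON-ready); use [write_fit_report()] to write it.
#' @export
fit_report <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "tk_fit")))
  lapply(fits, function(f) {
    list(subject_id = f$series$subject_id, sex = f$series$sex,
         route = f$series$route, label = f$series$label,
         dose_mg_per_kg = f$series$dose$amount, model = f$model,
         estimates = as.list(f$estimates), se = as.list(f$se),
         ci95_low = as.list(f$ci95[, "low"]),
         ci95_high = as.list(f$ci95[, "high"]),
         significant = as.list(f$significant),
         wrss = f$wrss, aic = f$aic, n_obs = f$n_obs,
         n_excluded = f$n_excluded, converged = f$converged,
         n_iter = f$n_iter, weighting = f$weighting)
  })
}

#' @rdname fit_report
#' @param path Output path for the JSON report.
#' @export
write_fit_report <- function(fits, path) {
  jsonlite::write_json(fit_report(fits), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feeding-scenario configuration file
#'
#' JSON or YAML (by file extension) with keys `total_dose_mg_per_kg`,
#' `k_a_per_h`, `k_e_per_h`, optional `f`, `dt_min`, `horizon_min` and
#' `bouts`, a list of `{start_min, end_min, rate_mg_per_kg_min}` records.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [feeding_scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)",
         call. = FALSE))
  need <- c("total_dose_mg_per_kg", "k_a_per_h", "k_e_per_h", "bouts")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys) > 0L)
    stop("scenario config missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  bouts <- as.data.frame(cfg$bouts)
  feeding_scenario(cfg$total_dose_mg_per_kg, bouts,
                   k_a = cfg$k_a_per_h, k_e = cfg$k_e_per_h,
                   f = if (is.null(cfg$f)) 1 else cfg$f,
                   dt = if (is.null(cfg$dt_min)) 1 else cfg$dt_min,
                   horizon_min = cfg$horizon_min)
}

#' Write a burden trace and its summary to disk
#'
#' The per-step trace goes to CSV (`t_min`, `d_gut`, `d_int`,
#' `cum_ingested`, `cum_eliminated`); the summary (`max_d_int`,
#' `t_of_max_min`, `auc_int`) to JSON.
#'
#' @param trace A `"burden_trace"`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_trace <- function(trace, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(trace, "burden_trace"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(trace), csv_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  s <- trace_summary(trace)
  if (!is.null(json_path))
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: the logical command, the
#' configuration (echoed with every default resolved, plus an MD5 digest
#' of its JSON serialisation), seeds, package version and timestamp.
#'
#' @param path Manifest path (JSON).
#' @param command Short name of the operation performed.
#' @param config List of the fully resolved configuration.
#' @param seed Integer seed(s) used, or `NULL` for deterministic runs.
#' @param outputs Character vector of files written.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NULL,
                               outputs = character()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    command = command, config = config, config_md5 = digest,
    seed = seed,
    package = "tkburden",
    version = as.character(utils::packageVersion("tkburden")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the reference bolus-versus-dietary comparison
#'
#' Simulates the four reference feeding scenarios ([preset_scenario()])
#' under worst-case kinetics and tabulates the maximum internal dose of
#' each, as absolute values and as a percentage of the bolus peak,
#' together with the half-life table implied by the published group rate
#' constants. Optionally writes the tables, traces and a run manifest to
#' a directory.
#'
#' @param total_dose Total dose, mg a.i. kg^-1 bw; default the rat oral
#'   LD50 of thiamethoxam, 1563.
#' @param k_a,k_e Worst-case rate constants, h^-1 (defaults 2.2, 0.25).
#' @param f Bioavailability; default 1.
#' @param dt Euler step, minutes; default 1.
#' @param literal_rates Use the published rounded ingestion rates.
#' @param out_dir Optional output directory.
#' @return List with `scenarios` (data frame: scenario, max_d_int,
#'   t_of_max_min, pct_of_bolus) and `half_lives` (data frame of
#'   absorption/elimination half-lives in minutes per study group).
#' @export
run_feeding_comparison <- function(total_dose = 1563, k_a = 2.2,
                                   k_e = 0.25, f = 1, dt = 1,
                                   literal_rates = FALSE, out_dir = NULL) {
  names <- c("bolus", "2h", "4h", "split")
  traces <- lapply(names, function(nm)
    simulate_body_burden(preset_scenario(nm, total_dose = total_dose,
                                         k_a = k_a, k_e = k_e, f = f,
                                         dt = dt,
                                         literal_rates = literal_rates)))
  sums <- lapply(traces, trace_summary)
  scen <- data.frame(
    scenario = names,
    max_d_int = vapply(sums, `[[`, 0, "max_d_int"),
    t_of_max_min = vapply(sums, `[[`, 0, "t_of_max_min"))
  scen$pct_of_bolus <- 100 * scen$max_d_int / scen$max_d_int[1]
  ref <- reference_group_means()
  th_a <- rep(NA_real_, nrow(ref))
  th_a[!is.na(ref$ka_mean)] <- round(half_life(ref$ka_mean[!is.na(ref$ka_mean)]), 1)
  half <- data.frame(
    route = ref$route, dose = ref$dose, label = ref$label, sex = ref$sex,
    t_half_a_min = th_a,
    t_half_e_min = round(half_life(ref$ke_mean), 1))
  out <- list(scenarios = scen, half_lives = half)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    p <- file.path(out_dir, "scenario_summary.csv")
    utils::write.csv(scen, p, row.names = FALSE); files <- c(files, p)
    p <- file.path(out_dir, "half_lives.csv")
    utils::write.csv(half, p, row.names = FALSE); files <- c(files, p)
    for (i in seq_along(names)) {
      p <- file.path(out_dir, paste0("trace_", names[i], ".csv"))
      write_trace(traces[[i]], csv_path = p)
      files <- c(files, p)
    }
    write_run_manifest(file.path(out_dir, "manifest.json"),
                       command = "feeding_comparison",
                       config = list(total_dose = total_dose, k_a = k_a,
                                     k_e = k_e, f = f, dt = dt,
                                     literal_rates = literal_rates),
                       outputs = files)
  }
  out
}
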