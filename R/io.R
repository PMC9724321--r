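# All numeric emissions use 6 significant digits so golden-file comparisons
# are stable across platforms.
.fmt6 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

.read_csv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in required) {
    if (!col %in% names(df)) {
      stop(sprintf("%s: required column '%s' is missing", path, col),
           call. = FALSE)
    }
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(sprintf("%s: non-numeric value '%s' at row %d, column '%s'",
                     path, v[bad[1]], bad[1], col), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  df
}

#' Read a broth concentration time course
#'
#' Reads the comma-separated HPLC-export dialect (`time_h` plus
#' `<species>_g_L` columns), converts g/L to the internal g/mL, sorts by
#' time, and zero-fills missing species columns with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `broth_samples` data.frame; see [as_broth_samples()].
#' @export
read_timecourse <- function(path) {
  df <- .read_csv_checked(path, required = "time_h",
                          numeric_cols = .TIMECOURSE_COLS)
  as_broth_samples(df)
}

#' Write a broth concentration time course
#'
#' Inverse of [read_timecourse()]: writes a `broth_samples` object (or a
#' simulator output's `$samples` table, already in g/L) as the external CSV
#' dialect, numeric values at 6 significant digits.
#'
#' @param samples A `broth_samples` object or a g/L data.frame with the
#'   dialect's columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(samples, path) {
  if (inherits(samples, "broth_samples")) {
    out <- data.frame(time_h = samples$time_h)
    for (sp in .SPECIES) out[[paste0(sp, "_g_L")]] <- samples[[sp]] * 1000
  } else {
    if (!all(.TIMECOURSE_COLS %in% names(samples))) {
      stop("'samples' must be broth_samples or carry the g/L dialect columns",
           call. = FALSE)
    }
    out <- samples[.TIMECOURSE_COLS]
  }
  out[] <- lapply(out, .fmt6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SSF loading configuration file
#'
#' Parses a plain-text key-value file (`key = value`, one per line, `#`
#' comments allowed) with keys `total_mass_g`, `glucan_mass_g`,
#' `initial_insoluble_solids_frac`, and optionally `glucan_frac`,
#' `xylan_frac`, `lignin_frac`, `enzyme_mg_per_g_glucan`, `temperature_C`.
#'
#' @param path Path to the config file.
#' @return An [ssf_config()].
#' @export
read_ssf_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.+)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad)) {
    stop(sprintf("%s: cannot parse line: '%s'", path, lines[bad[1]]),
         call. = FALSE)
  }
  vals <- stats::setNames(
    as.numeric(vapply(kv, `[[`, character(1), 3)),
    vapply(kv, `[[`, character(1), 2)
  )
  need <- c("total_mass_g", "glucan_mass_g", "initial_insoluble_solids_frac")
  miss <- setdiff(need, names(vals))
  if (length(miss)) {
    stop(sprintf("%s: missing required key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  get_or <- function(k, d) if (k %in% names(vals)) unname(vals[[k]]) else d
  ssf_config(
    total_mass_g = unname(vals[["total_mass_g"]]),
    glucan_mass_g = unname(vals[["glucan_mass_g"]]),
    insoluble_solids_frac = unname(vals[["initial_insoluble_solids_frac"]]),
    glucan_frac = get_or("glucan_frac", 0.885),
    xylan_frac = get_or("xylan_frac", 0.030),
    lignin_frac = get_or("lignin_frac", 0.023),
    enzyme_mg_per_g_glucan = get_or("enzyme_mg_per_g_glucan", 15),
    temperature_C = get_or("temperature_C", 37)
  )
}

#' Read an OD600 time series
#'
#' Columns `time_h`, `od600` and optional `dilution_factor` (default 1); the
#' dilution factor is applied on read so downstream fitting sees corrected
#' optical densities.
#'
#' @param path Path to the CSV file.
#' @return Data.frame with columns `time_h`, `od600` (dilution-corrected).
#' @export
read_od_series <- function(path) {
  df <- .read_csv_checked(path, required = c("time_h", "od600"),
                          numeric_cols = c("time_h", "od600", "dilution_factor"))
  dil <- if ("dilution_factor" %in% names(df)) df$dilution_factor else 1
  out <- data.frame(time_h = df$time_h, od600 = df$od600 * dil)
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a cell axis-measurement export
#'
#' Columns `cell_id`, `condition`, `major_axis_um`, `minor_axis_um` (full
#' axis lengths as measured with a line tool).
#'
#' @param path Path to the CSV file.
#' @return Data.frame suitable for [cell_shape_metrics()].
#' @export
read_cell_measurements <- function(path) {
  .read_csv_checked(path,
                    required = c("cell_id", "condition",
                                 "major_axis_um", "minor_axis_um"),
                    numeric_cols = c("major_axis_um", "minor_axis_um"))
}

#' Write a yield report, summary and run manifest to a directory
#'
#' Emits three files: `timecourse_report.csv` (per-timepoint mass-balance
#' states), `summary.json` (peak ethanol and time, final yields, arrest
#' flag), and `run_manifest.json` (input paths, config echo, package version,
#' seed, warnings). All emissions are deterministic given identical inputs:
#' stable column order and 6-significant-digit formatting.
#'
#' @param report A `yield_report` from [analyze_timecourse()].
#' @param out_dir Output directory (created if absent).
#' @param inputs Named character vector of input paths to echo (optional).
#' @param seed Seed to record, if any.
#' @param warnings Character vector of warnings to record.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir, inputs = character(0),
                         seed = NULL, warnings = character(0)) {
  if (!inherits(report, "yield_report")) {
    stop("'report' must be a yield_report", call. = FALSE)
  }
  if (nrow(report$states) == 0) stop("refusing to write an empty report",
                                     call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  paths <- c(
    table = file.path(out_dir, "timecourse_report.csv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  tab <- report$states
  tab[] <- lapply(tab, .fmt6)
  utils::write.csv(tab, paths[["table"]], row.names = FALSE, quote = FALSE)

  summary <- lapply(report$summary, function(v) {
    if (is.numeric(v)) signif(v, 6) else v
  })
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  manifest <- list(
    package = "ssfyield",
    version = as.character(utils::packageVersion("ssfyield")),
    inputs = as.list(inputs),
    config = unclass(report$config),
    seed = seed,
    warnings = as.list(warnings)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

#' Read back a written yield-report table
#'
#' @param path Path to a `timecourse_report.csv` written by [write_report()].
#' @return Data.frame of per-timepoint states.
#' @export
read_report_table <- function(path) {
  .read_csv_checked(path, required = c("time_h", "v_liquid_mL"),
                    numeric_cols = c("time_h", "rho_l_g_cc", "s_i", "s_i_raw",
                                     "v_liquid_mL", "glucose_yield_pct",
                                     "glucan_conversion_pct",
                                     "ethanol_yield_pct",
                                     "productivity_g_g_day"))
}
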