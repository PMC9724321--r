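# Column names of the external (g/L) time-course dialect, in canonical order.
.TIMECOURSE_COLS <- c("time_h", paste0(.SPECIES, "_g_L"))

#' Coerce a g/L concentration table to internal broth samples
#'
#' Takes a data.frame in the external HPLC-export dialect (columns `time_h`,
#' `glucose_g_L`, `cellobiose_g_L`, `xylose_g_L`, `glycerol_g_L`,
#' `acetic_acid_g_L`, `ethanol_g_L`) and returns the internal representation
#' with concentrations in g/mL, sorted by time. Missing species columns are
#' zero-filled with a warning; a missing `time_h` column is an error.
#'
#' @param df A data.frame of broth concentrations in g/L.
#' @return A `broth_samples` data.frame with columns `time_h` and one g/mL
#'   column per species.
#' @export
as_broth_samples <- function(df) {
  if (!is.data.frame(df)) stop("'df' must be a data.frame", call. = FALSE)
  if (!"time_h" %in% names(df)) {
    stop("required column 'time_h' is missing", call. = FALSE)
  }
  out <- data.frame(time_h = as.numeric(df$time_h))
  missing <- character(0)
  for (sp in .SPECIES) {
    col <- paste0(sp, "_g_L")
    if (col %in% names(df)) {
      v <- df[[col]]
      if (!is.numeric(v)) {
        stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
      }
      out[[sp]] <- v / 1000  # g/L -> g/mL
    } else {
      missing <- c(missing, col)
      out[[sp]] <- 0
    }
  }
  if (length(missing)) {
    warning("missing species column(s) zero-filled: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(out$time_h)) || any(out$time_h < 0)) {
    stop("'time_h' must be finite and non-negative", call. = FALSE)
  }
  for (sp in .SPECIES) {
    if (any(!is.finite(out[[sp]])) || any(out[[sp]] < 0)) {
      stop(sprintf("'%s' concentrations must be finite and non-negative", sp),
           call. = FALSE)
    }
    if (any(out[[sp]] > 0.3)) {
      stop(sprintf("'%s' concentration exceeds 0.3 g/mL; input is likely not in g/L",
                   sp), call. = FALSE)
    }
  }
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("broth_samples", "data.frame")
  out
}

#' Mass-balance analysis of an SSF broth time course
#'
#' Composes the mass-balance chain per timepoint: liquid density from the
#' sugar concentrations, insoluble solids fraction from the concentration
#' changes since the baseline, liquid volume from the shrinking solids, and
#' from those the glucose yield, glucan conversion, theoretical ethanol yield
#' and ethanol productivity. The first sample is the baseline for all deltas.
#'
#' Fermentation arrest is flagged when, between consecutive samples, ethanol
#' rises by less than `arrest_ethanol_g_L` while glucose rises by more than
#' `arrest_glucose_g_L` (ethanol production stops while sugar keeps
#' accumulating).
#'
#' @param samples A `broth_samples` object (see [as_broth_samples()]) or a
#'   data.frame in the external g/L dialect.
#' @param config An [ssf_config()] describing the loading.
#' @param water_density If `TRUE`, use the zero-solute solvent density
#'   (0.97 g/cc) everywhere instead of the sugar-dependent correlation — the
#'   low-solids (< 5 wt%) simplification. Default `FALSE`.
#' @param arrest_ethanol_g_L,arrest_glucose_g_L Arrest-flag tolerances, g/L.
#' @return A `yield_report`: list with `states` (per-timepoint data.frame),
#'   `summary` (peak ethanol and time, final yields, arrest flag) and the
#'   echoed `config`.
#' @export
analyze_timecourse <- function(samples, config,
                               water_density = FALSE,
                               arrest_ethanol_g_L = 0.5,
                               arrest_glucose_g_L = 1.0) {
  if (!inherits(config, "ssf_config")) {
    stop("'config' must be an ssf_config object", call. = FALSE)
  }
  if (!inherits(samples, "broth_samples")) samples <- as_broth_samples(samples)
  n <- nrow(samples)
  if (n < 1) stop("'samples' is empty", call. = FALSE)
  if (any(duplicated(samples$time_h))) {
    stop("duplicate timepoints in 'samples'", call. = FALSE)
  }
  if (is.unsorted(samples$time_h, strictly = TRUE)) {
    stop("'samples' times must be strictly increasing", call. = FALSE)
  }

  rho_l <- if (water_density) {
    rep(0.97, n)
  } else {
    liquid_density(samples$glucose, samples$cellobiose, samples$xylose)
  }

  base <- samples[1, .SPECIES, drop = FALSE]
  deltas <- as.data.frame(lapply(.SPECIES, function(sp) {
    samples[[sp]] - base[[sp]]
  }))
  names(deltas) <- .SPECIES
  if (any(as.matrix(deltas) < -0.002)) {
    warning("concentration drop below baseline exceeds 0.002 g/mL; ",
            "possible assay problem", call. = FALSE)
  }

  s_i_raw <- insoluble_solids_fraction(
    config$insoluble_solids_frac,
    d_glucose = deltas$glucose, d_cellobiose = deltas$cellobiose,
    d_xylose = deltas$xylose, d_glycerol = deltas$glycerol,
    d_acetic_acid = deltas$acetic_acid, d_ethanol = deltas$ethanol,
    rho_l = rho_l
  )
  s_i <- s_i_raw
  if (any(s_i < 0)) {
    warning("computed insoluble solids fraction fell below 0 and was ",
            "clamped; raw values kept in 's_i_raw'", call. = FALSE)
    s_i <- pmax(s_i, 0)
  }

  v_l <- liquid_volume(config$total_mass_g, s_i, rho_l)
  ethanol_g <- samples$ethanol * v_l
  elapsed_d <- (samples$time_h - samples$time_h[1]) / 24
  productivity <- rep(NA_real_, n)
  pos <- elapsed_d > 0
  if (any(pos)) {
    productivity[pos] <- ssf_productivity(ethanol_g[pos], config$glucan_mass_g,
                                          elapsed_d[pos])
  }

  states <- data.frame(
    time_h = samples$time_h,
    rho_l_g_cc = rho_l,
    s_i = s_i,
    s_i_raw = s_i_raw,
    v_liquid_mL = v_l,
    glucose_yield_pct = glucose_yield(samples$glucose, v_l, config$glucan_mass_g),
    glucan_conversion_pct = glucan_conversion(
      c_glucose = samples$glucose, c_cellobiose = samples$cellobiose,
      c_glycerol = samples$glycerol, c_acetic_acid = samples$acetic_acid,
      c_ethanol = samples$ethanol,
      v_liquid = v_l, m_glucan = config$glucan_mass_g
    ),
    ethanol_yield_pct = theoretical_ethanol_yield(samples$ethanol, v_l,
                                                  config$glucan_mass_g),
    productivity_g_g_day = productivity
  )

  # Arrest: ethanol stalls while glucose builds up, between consecutive samples.
  eth_gL <- samples$ethanol * 1000
  glc_gL <- samples$glucose * 1000
  arrest_idx <- NA_integer_
  if (n >= 2) {
    d_eth <- diff(eth_gL)
    d_glc <- diff(glc_gL)
    hits <- which(d_eth < arrest_ethanol_g_L & d_glc > arrest_glucose_g_L)
    if (length(hits)) arrest_idx <- hits[1] + 1L
  }

  peak_i <- which.max(eth_gL)
  summary <- list(
    peak_ethanol_g_L = eth_gL[peak_i],
    peak_ethanol_time_h = samples$time_h[peak_i],
    final_time_h = samples$time_h[n],
    final_glucose_yield_pct = states$glucose_yield_pct[n],
    final_glucan_conversion_pct = states$glucan_conversion_pct[n],
    final_ethanol_yield_pct = states$ethanol_yield_pct[n],
    arrest_detected = !is.na(arrest_idx),
    arrest_time_h = if (is.na(arrest_idx)) NA_real_ else samples$time_h[arrest_idx]
  )

  structure(
    list(states = states, summary = summary, config = config,
         samples = samples),
    class = "yield_report"
  )
}

#' @export
print.yield_report <- function(x, ...) {
  s <- x$summary
  n <- nrow(x$states)
  cat(sprintf("SSF yield report: %d timepoints over %.3g h\n", n, s$final_time_h))
  cat(sprintf("  peak ethanol:      %.4g g/L at %.3g h\n",
              s$peak_ethanol_g_L, s$peak_ethanol_time_h))
  cat(sprintf("  final yields:      glucose %.4g%%, glucan conversion %.4g%%, ethanol %.4g%% of theoretical\n",
              s$final_glucose_yield_pct, s$final_glucan_conversion_pct,
              s$final_ethanol_yield_pct))
  if (s$arrest_detected) {
    cat(sprintf("  fermentation arrest flagged at %.3g h (ethanol stalled while glucose rose)\n",
                s$arrest_time_h))
  } else {
    cat("  no fermentation arrest flagged\n")
  }
  invisible(x)
}
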