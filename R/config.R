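#' SSF loading configuration
#'
#' Describes the initial state of a simultaneous saccharification and
#' fermentation run: the total charged mass, the glucan it contains, the
#' insoluble solids fraction, and the composition of the pretreated substrate.
#' Enzyme dose and temperature are carried as metadata.
#'
#' @param total_mass_g Initial total system mass (solids + liquids), g.
#' @param glucan_mass_g Initial glucan mass, g. Must not exceed `total_mass_g`.
#' @param insoluble_solids_frac Initial insoluble solids mass fraction,
#'   in `[0, 1)`.
#' @param glucan_frac,xylan_frac,lignin_frac Mass fractions of the pretreated
#'   substrate, each in `[0, 1]`.
#' @param enzyme_mg_per_g_glucan Enzyme dose, mg protein per g glucan
#'   (metadata).
#' @param temperature_C Fermentation temperature, degrees C (metadata).
#' @return An object of class `ssf_config`.
#' @examples
#' ssf_config(total_mass_g = 25, glucan_mass_g = 4.425,
#'            insoluble_solids_frac = 0.20)
#' @export
ssf_config <- function(total_mass_g, glucan_mass_g, insoluble_solids_frac,
                       glucan_frac = 0.885, xylan_frac = 0.030,
                       lignin_frac = 0.023,
                       enzyme_mg_per_g_glucan = 15, temperature_C = 37) {
  if (total_mass_g <= 0) stop("'total_mass_g' must be positive", call. = FALSE)
  if (glucan_mass_g <= 0) stop("'glucan_mass_g' must be positive", call. = FALSE)
  if (glucan_mass_g > total_mass_g) {
    stop("'glucan_mass_g' cannot exceed 'total_mass_g'", call. = FALSE)
  }
  if (insoluble_solids_frac < 0 || insoluble_solids_frac >= 1) {
    stop("'insoluble_solids_frac' must lie in [0, 1)", call. = FALSE)
  }
  for (nm in c("glucan_frac", "xylan_frac", "lignin_frac")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  if (glucan_mass_g > insoluble_solids_frac * total_mass_g + 1e-9) {
    stop("'glucan_mass_g' exceeds the insoluble solids mass implied by ",
         "'insoluble_solids_frac'", call. = FALSE)
  }
  structure(
    list(
      total_mass_g = total_mass_g,
      glucan_mass_g = glucan_mass_g,
      insoluble_solids_frac = insoluble_solids_frac,
      glucan_frac = glucan_frac,
      xylan_frac = xylan_frac,
      lignin_frac = lignin_frac,
      enzyme_mg_per_g_glucan = enzyme_mg_per_g_glucan,
      temperature_C = temperature_C
    ),
    class = "ssf_config"
  )
}

#' @export
print.ssf_config <- function(x, ...) {
  cat("SSF configuration\n")
  cat(sprintf("  total mass:        %.3g g\n", x$total_mass_g))
  cat(sprintf("  glucan mass:       %.4g g\n", x$glucan_mass_g))
  cat(sprintf("  insoluble solids:  %.1f wt%%\n", 100 * x$insoluble_solids_frac))
  cat(sprintf("  substrate:         %.1f%% glucan / %.1f%% xylan / %.1f%% lignin\n",
              100 * x$glucan_frac, 100 * x$xylan_frac, 100 * x$lignin_frac))
  cat(sprintf("  enzyme dose:       %g mg protein / g glucan\n",
              x$enzyme_mg_per_g_glucan))
  cat(sprintf("  temperature:       %g C\n", x$temperature_C))
  invisible(x)
}
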