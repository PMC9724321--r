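#' @keywords internal
"_PACKAGE"

# Anhydro correction factors: grams of dissolved species per gram of glucan
# (or xylan, for xylose) consumed. Used as printed in the source correlations;
# note acetic acid carries 1.11 in the solids balance but 1.111 in the
# conversion sum, and both are kept verbatim.
.ANHYDRO_SOLIDS <- c(
  glucose = 1.11, cellobiose = 1.056, xylose = 1.36,
  glycerol = 1.135, acetic_acid = 1.11, ethanol = 0.567
)
.ANHYDRO_CONVERSION <- c(
  glucose = 1.11, cellobiose = 1.056,
  glycerol = 1.135, acetic_acid = 1.111, ethanol = 0.567
)

.SPECIES <- c("glucose", "cellobiose", "xylose", "glycerol", "acetic_acid", "ethanol")

.check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

#' Liquid-phase density from dissolved sugar concentrations
#'
#' Density of the fermentation broth liquid phase as a linear function of the
#' total dissolved sugar (glucose + cellobiose + xylose) concentration,
#' \eqn{\rho_l = 0.456\,(C_g + C_{cb} + C_x) + 0.97} with concentrations in
#' g/mL and density in g/cc. At zero sugars the correlation returns the
#' solvent-phase value 0.97 g/cc.
#'
#' @param c_glucose,c_cellobiose,c_xylose Concentrations in g/mL.
#' @return Density in g/cc (vectorized over the inputs).
#' @examples
#' liquid_density(0, 0, 0)        # 0.97
#' liquid_density(0.10, 0, 0)     # 1.0156
#' @export
liquid_density <- function(c_glucose, c_cellobiose = 0, c_xylose = 0) {
  .check_nonneg(c_glucose, "c_glucose")
  .check_nonneg(c_cellobiose, "c_cellobiose")
  .check_nonneg(c_xylose, "c_xylose")
  0.456 * (c_glucose + c_cellobiose + c_xylose) + 0.97
}

#' Insoluble solids fraction from solubilized-mass changes
#'
#' Estimates the insoluble solids mass fraction at time t from the change in
#' liquid-phase concentrations since the start of the run. Each concentration
#' change is converted to the mass of insoluble polymer it represents via its
#' anhydro correction factor (glucose 1.11, cellobiose 1.056, xylose 1.36,
#' glycerol 1.135, acetic acid 1.11, ethanol 0.567), summed, scaled by the
#' liquid density, and used in
#' \eqn{S_i = (S_{i0} - D)/(1 - D)} where D is the solubilized mass fraction.
#'
#' Negative deltas (assay noise) are passed through unchanged. A computed
#' solubilized fraction D >= 1 is a degenerate state (more mass dissolved than
#' the system holds) and raises an error.
#'
#' @param s_i0 Initial insoluble solids mass fraction, in `[0, 1)`.
#' @param d_glucose,d_cellobiose,d_xylose,d_glycerol,d_acetic_acid,d_ethanol
#'   Concentration changes since t = 0, g/mL.
#' @param rho_l Liquid-phase density at time t, g/cc.
#' @return Insoluble solids fraction (vectorized).
#' @export
insoluble_solids_fraction <- function(s_i0,
                                      d_glucose = 0, d_cellobiose = 0,
                                      d_xylose = 0, d_glycerol = 0,
                                      d_acetic_acid = 0, d_ethanol = 0,
                                      rho_l) {
  if (any(s_i0 < 0) || any(s_i0 >= 1)) {
    stop("'s_i0' must lie in [0, 1)", call. = FALSE)
  }
  if (any(rho_l <= 0)) stop("'rho_l' must be positive", call. = FALSE)
  d <- (d_glucose / 1.11 + d_cellobiose / 1.056 + d_xylose / 1.36 +
          d_glycerol / 1.135 + d_acetic_acid / 1.11 + d_ethanol / 0.567) / rho_l
  if (any(d >= 1)) {
    stop("degenerate state: solubilized mass fraction >= 1", call. = FALSE)
  }
  (s_i0 - d) / (1 - d)
}

#' Liquid-phase volume from system mass and solids fraction
#'
#' \eqn{V_l = M (1 - S_i) / \rho_l}: the mass of the system not held in
#' insoluble solids, divided by the liquid density.
#'
#' @param m_total Initial total system mass (solids + liquids), g.
#' @param s_i Insoluble solids fraction at time t.
#' @param rho_l Liquid density, g/cc.
#' @return Liquid volume in mL.
#' @export
liquid_volume <- function(m_total, s_i, rho_l) {
  if (any(m_total <= 0)) stop("'m_total' must be positive", call. = FALSE)
  if (any(s_i < 0) || any(s_i > 1)) stop("'s_i' must lie in [0, 1]", call. = FALSE)
  if (any(rho_l <= 0)) stop("'rho_l' must be positive", call. = FALSE)
  m_total * (1 - s_i) / rho_l
}

#' Glucose yield as percent of initial glucan
#'
#' Glucose in the broth expressed as the percentage of the initial glucan it
#' represents: \eqn{(C_g V_l / 1.11) / M_g \times 100}. The 1.11 factor is the
#' water gained when a glucan unit is hydrolyzed to glucose.
#'
#' @param c_glucose Glucose concentration, g/mL.
#' @param v_liquid Liquid volume, mL.
#' @param m_glucan Initial glucan mass, g.
#' @return Yield in percent.
#' @export
glucose_yield <- function(c_glucose, v_liquid, m_glucan) {
  if (any(m_glucan <= 0)) stop("'m_glucan' must be positive", call. = FALSE)
  .check_nonneg(c_glucose, "c_glucose")
  (c_glucose * v_liquid / 1.11) / m_glucan * 100
}

#' Glucan conversion as percent of initial glucan
#'
#' Sums all glucan-derived liquid products (glucose, cellobiose, glycerol,
#' acetic acid, ethanol), each divided by its anhydro correction factor to put
#' it back on a glucan-mass basis, and reports the total as a percentage of
#' the initial glucan:
#' \deqn{\%conv = \frac{(C_g/1.11 + C_{cb}/1.056 + C_{Gly}/1.135 +
#'   C_{Ac}/1.111 + C_{Eth}/0.567)\, V_l}{M_g} \times 100.}
#'
#' @param c_glucose,c_cellobiose,c_glycerol,c_acetic_acid,c_ethanol
#'   Concentrations, g/mL.
#' @param v_liquid Liquid volume, mL.
#' @param m_glucan Initial glucan mass, g.
#' @return Conversion in percent.
#' @export
glucan_conversion <- function(c_glucose = 0, c_cellobiose = 0, c_glycerol = 0,
                              c_acetic_acid = 0, c_ethanol = 0,
                              v_liquid, m_glucan) {
  if (any(m_glucan <= 0)) stop("'m_glucan' must be positive", call. = FALSE)
  gl_eq <- c_glucose / 1.11 + c_cellobiose / 1.056 + c_glycerol / 1.135 +
    c_acetic_acid / 1.111 + c_ethanol / 0.567
  gl_eq * v_liquid / m_glucan * 100
}

#' Theoretical ethanol yield
#'
#' Ethanol produced as a percentage of the stoichiometric maximum from the
#' initial glucan: \eqn{(C_{Eth} V_l \times 0.9) / (0.51\, M_g) \times 100}.
#' The 0.9 factor converts glucan to its glucose equivalent (1/1.11 rounded as
#' printed) and 0.51 is the mass yield of ethanol from glucose.
#'
#' @param c_ethanol Ethanol concentration, g/mL.
#' @param v_liquid Liquid volume, mL.
#' @param m_glucan Initial glucan mass, g.
#' @return Percent of theoretical ethanol yield.
#' @export
theoretical_ethanol_yield <- function(c_ethanol, v_liquid, m_glucan) {
  if (any(m_glucan <= 0)) stop("'m_glucan' must be positive", call. = FALSE)
  .check_nonneg(c_ethanol, "c_ethanol")
  (c_ethanol * v_liquid * 0.9) / (0.51 * m_glucan) * 100
}

#' Glucan-equivalent loading of an insoluble-solids charge
#'
#' Maps an insoluble-solids loading (wt%) and the glucan mass fraction of the
#' substrate to the glucan-equivalent loading. Reported rounded to the nearest
#' integer percent (the conventional reporting style) with the exact value
#' alongside.
#'
#' @param solids_wt_pct Insoluble solids loading, wt% of total charge.
#' @param glucan_fraction Glucan mass fraction of the substrate, in `[0, 1]`.
#' @return A data.frame with columns `solids_wt_pct`, `glucan_fraction`,
#'   `glucan_wt_pct` (exact) and `glucan_wt_pct_rounded`.
#' @examples
#' glucan_equivalent_loading(c(13, 17, 20), 0.885)
#' @export
glucan_equivalent_loading <- function(solids_wt_pct, glucan_fraction) {
  if (any(solids_wt_pct < 0) || any(solids_wt_pct > 100)) {
    stop("'solids_wt_pct' must lie in [0, 100]", call. = FALSE)
  }
  if (any(glucan_fraction < 0) || any(glucan_fraction > 1)) {
    stop("'glucan_fraction' must lie in [0, 1]", call. = FALSE)
  }
  exact <- solids_wt_pct * glucan_fraction
  data.frame(
    solids_wt_pct = solids_wt_pct,
    glucan_fraction = glucan_fraction,
    glucan_wt_pct = exact,
    glucan_wt_pct_rounded = round(exact)
  )
}

#' Ethanol productivity per glucose equivalent of initial glucan
#'
#' Ethanol mass produced per gram of glucose equivalent of the initial glucan
#' per day. The glucose equivalent of glucan is 1.11 times its mass (the
#' hydration gained on hydrolysis).
#'
#' @param ethanol_g Ethanol mass produced, g.
#' @param m_glucan Initial glucan mass, g.
#' @param elapsed_days Elapsed time, days.
#' @return Productivity in g ethanol / g glucose equivalent / day.
#' @export
ssf_productivity <- function(ethanol_g, m_glucan, elapsed_days) {
  if (any(m_glucan <= 0)) stop("'m_glucan' must be positive", call. = FALSE)
  if (any(elapsed_days <= 0)) stop("'elapsed_days' must be positive", call. = FALSE)
  .check_nonneg(ethanol_g, "ethanol_g")
  ethanol_g / (1.11 * m_glucan) / elapsed_days
}

#' Ethanol productivity per glucose fed
#'
#' For pure-sugar fermentations: grams of ethanol produced per gram of glucose
#' fed per hour.
#'
#' @param ethanol_g Ethanol mass produced, g.
#' @param glucose_fed_g Glucose fed, g.
#' @param elapsed_h Elapsed time, hours.
#' @return Productivity in g ethanol / g glucose fed / h.
#' @export
sugar_productivity <- function(ethanol_g, glucose_fed_g, elapsed_h) {
  if (any(glucose_fed_g <= 0)) stop("'glucose_fed_g' must be positive", call. = FALSE)
  if (any(elapsed_h <= 0)) stop("'elapsed_h' must be positive", call. = FALSE)
  .check_nonneg(ethanol_g, "ethanol_g")
  ethanol_g / glucose_fed_g / elapsed_h
}
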