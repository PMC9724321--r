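#' Parameters for the SSF time-course simulator
#'
#' Bundles the kinetic and bookkeeping parameters of the synthetic SSF
#' generator with a loading configuration. The generator keeps its internal
#' ledger in glucan-equivalent mass units using the same anhydro factors as
#' the analyzer (1.11 g glucose, 0.567 g ethanol, 1.135 g glycerol per g
#' glucan), so its emitted concentrations close the analyzer's mass balance
#' exactly when noise is off.
#'
#' @param config An [ssf_config()]; default is a 25 g charge at 20 wt%
#'   insoluble solids of an 88.5% glucan substrate (glucan 4.425 g).
#' @param duration_days Length of the simulated course, days.
#' @param interval_h Sampling interval, hours.
#' @param hydrolysis_rate First-order hydrolysis rate constant, 1/day,
#'   applied to the remaining hydrolyzable glucan.
#' @param max_hydrolyzable Fraction of the initial glucan that enzymes can
#'   ever reach, in `[0, 1]`.
#' @param ethanol_fraction,glycerol_fraction Glucan-equivalent fractions of
#'   consumed sugar routed to ethanol and glycerol. Their sum must not exceed
#'   1; any remainder is carbon diverted to biomass/CO2 beyond the anhydro
#'   factors and is tracked in the truth ledger. The defaults (0.95, 0.05)
#'   sum to 1, i.e. all consumed carbon is visible in the broth; the ethanol
#'   mass yield is then about 0.49 g per g glucose consumed, below the 0.511
#'   stoichiometric maximum.
#' @param arrest_ethanol_g_L Broth ethanol concentration at which sugar
#'   uptake stops permanently (ethanol/temperature stress arrest), g/L.
#' @param uptake_g_L_day Glucose uptake capacity of the culture, g glucose
#'   per L of broth per day.
#' @param noise_cv Multiplicative log-normal noise CV applied to emitted
#'   concentrations only (never to the internal ledger).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(config = ssf_config(total_mass_g = 25,
                                           glucan_mass_g = 25 * 0.20 * 0.885,
                                           insoluble_solids_frac = 0.20),
                       duration_days = 7, interval_h = 6,
                       hydrolysis_rate = 0.8, max_hydrolyzable = 0.9,
                       ethanol_fraction = 0.95, glycerol_fraction = 0.05,
                       arrest_ethanol_g_L = 75, uptake_g_L_day = 50,
                       noise_cv = 0, seed = 1L) {
  if (!inherits(config, "ssf_config")) {
    stop("'config' must be an ssf_config", call. = FALSE)
  }
  if (duration_days <= 0 || interval_h <= 0) {
    stop("'duration_days' and 'interval_h' must be positive", call. = FALSE)
  }
  if (hydrolysis_rate < 0 || uptake_g_L_day < 0 || arrest_ethanol_g_L < 0 ||
      noise_cv < 0) {
    stop("rates, capacities and noise must be non-negative", call. = FALSE)
  }
  if (max_hydrolyzable < 0 || max_hydrolyzable > 1) {
    stop("'max_hydrolyzable' must lie in [0, 1]", call. = FALSE)
  }
  if (ethanol_fraction < 0 || glycerol_fraction < 0) {
    stop("yield fractions must be non-negative", call. = FALSE)
  }
  if (ethanol_fraction + glycerol_fraction > 1 + 1e-12) {
    stop("invalid params: ethanol_fraction + glycerol_fraction > 1",
         call. = FALSE)
  }
  structure(
    list(config = config, duration_days = duration_days,
         interval_h = interval_h, hydrolysis_rate = hydrolysis_rate,
         max_hydrolyzable = max_hydrolyzable,
         ethanol_fraction = ethanol_fraction,
         glycerol_fraction = glycerol_fraction,
         arrest_ethanol_g_L = arrest_ethanol_g_L,
         uptake_g_L_day = uptake_g_L_day,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate a high-solids SSF broth time course with known ground truth
#'
#' Fixed-step generator of an SSF fermentation: first-order hydrolysis
#' releases glucose from the remaining hydrolyzable glucan; the culture takes
#' up glucose at a capped rate and converts it to ethanol and glycerol (in
#' glucan-equivalent fractions) until the broth ethanol concentration reaches
#' the arrest threshold, after which uptake stops and glucose accumulates —
#' the fermentation-arrest phenotype. Concentrations are mass over the liquid
#' volume obtained from the same solids-fraction/density/volume chain the
#' analyzer uses, so on noise-free output [analyze_timecourse()] recovers the
#' generator's true conversion exactly. Optional multiplicative noise is
#' applied last, to emitted concentrations only.
#'
#' @param params A [sim_params()] object.
#' @return An `ssf_simulation`: list with `samples` (external g/L dialect,
#'   suitable for [as_broth_samples()] or writing to CSV), `truth`
#'   (per-timepoint ledger: glucan consumed, glucan equivalents accounted in
#'   the liquid, true conversion and ethanol yield, solids fraction, liquid
#'   volume), `arrest_time_h` (NA if never triggered), and the `params`.
#' @export
simulate_ssf_timecourse <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) {
    stop("'params' must come from sim_params()", call. = FALSE)
  }
  cfg <- params$config
  M <- cfg$total_mass_g
  Mg <- cfg$glucan_mass_g
  Ms0 <- cfg$insoluble_solids_frac * M

  times_h <- seq(0, params$duration_days * 24, by = params$interval_h)
  dt_d <- params$interval_h / 24
  n <- length(times_h)

  # Glucan-equivalent ledger (g of glucan). Products in the liquid:
  H <- params$max_hydrolyzable * Mg  # hydrolyzable glucan left in solids
  p_glc <- 0    # dissolved, unfermented (as glucose)
  p_eth <- 0    # fermented to ethanol
  p_gly <- 0    # fermented to glycerol
  diverted <- 0 # consumed but invisible to the broth assay
  X <- 0        # cumulative glucan removed from solids

  state_row <- function(t) {
    s_i <- (Ms0 - X) / M
    L <- M * (1 - s_i)           # liquid mass, g
    m_glc <- 1.11 * p_glc
    m_eth <- 0.567 * p_eth
    m_gly <- 1.135 * p_gly
    # Self-consistent solution of the linear density correlation:
    # rho = 0.456 * (m_glc / V_l) + 0.97 with V_l = L / rho.
    rho <- 0.97 / (1 - 0.456 * m_glc / L)
    v_l <- L / rho
    list(time_h = t, s_i = s_i, rho = rho, v_l = v_l,
         c_glc = m_glc / v_l, c_eth = m_eth / v_l, c_gly = m_gly / v_l,
         m_eth = m_eth)
  }

  rows <- vector("list", n)
  rows[[1]] <- state_row(times_h[1])
  arrested <- FALSE
  arrest_time <- NA_real_

  for (i in seq(2, length.out = n - 1)) {
    prev <- rows[[i - 1]]
    # hydrolysis over the step, exact first-order decay
    dX <- H * (1 - exp(-params$hydrolysis_rate * dt_d))
    H <- H - dX
    p_glc <- p_glc + dX
    X <- X + dX
    # uptake, unless arrested
    if (!arrested) {
      cap_glc_g <- params$uptake_g_L_day * (prev$v_l / 1000) * dt_d
      q <- min(p_glc, cap_glc_g / 1.11)
      p_glc <- p_glc - q
      p_eth <- p_eth + q * params$ethanol_fraction
      p_gly <- p_gly + q * params$glycerol_fraction
      diverted <- diverted + q * (1 - params$ethanol_fraction - params$glycerol_fraction)
    }
    rows[[i]] <- state_row(times_h[i])
    if (!arrested && rows[[i]]$c_eth * 1000 >= params$arrest_ethanol_g_L) {
      arrested <- TRUE
      arrest_time <- times_h[i]
    }
  }

  s_i <- vapply(rows, `[[`, numeric(1), "s_i")
  v_l <- vapply(rows, `[[`, numeric(1), "v_l")
  c_glc <- vapply(rows, `[[`, numeric(1), "c_glc")
  c_eth <- vapply(rows, `[[`, numeric(1), "c_eth")
  c_gly <- vapply(rows, `[[`, numeric(1), "c_gly")
  m_eth <- vapply(rows, `[[`, numeric(1), "m_eth")

  # Truth ledger: glucan equivalents in the liquid, recovered exactly from
  # the noise-free masses via the same anhydro factors the ledger uses.
  accounted <- (c_glc * v_l) / 1.11 + (c_eth * v_l) / 0.567 + (c_gly * v_l) / 1.135
  glucan_consumed <- (Ms0 - s_i * M)

  truth <- data.frame(
    time_h = times_h,
    glucan_consumed_g = glucan_consumed,
    accounted_glucan_eq_g = accounted,
    true_conversion_pct = accounted / Mg * 100,
    true_ethanol_yield_pct = m_eth * 0.9 / (0.51 * Mg) * 100,
    s_i = s_i,
    v_liquid_mL = v_l
  )

  conc <- cbind(glucose = c_glc, cellobiose = 0, xylose = 0,
                glycerol = c_gly, acetic_acid = 0, ethanol = c_eth)
  if (params$noise_cv > 0) {
    set.seed(params$seed)
    sdlog <- sqrt(log(1 + params$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog),
                    nrow = nrow(conc))
    conc <- conc * noise
  }

  samples <- data.frame(time_h = times_h)
  for (j in seq_along(.SPECIES)) {
    samples[[paste0(.SPECIES[j], "_g_L")]] <- conc[, j] * 1000
  }

  structure(
    list(samples = samples, truth = truth, arrest_time_h = arrest_time,
         params = params),
    class = "ssf_simulation"
  )
}

#' @export
print.ssf_simulation <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Simulated SSF course: %d timepoints over %g h\n",
              n, max(x$samples$time_h)))
  cat(sprintf("  final ethanol %.4g g/L, final true conversion %.4g%%\n",
              x$samples$ethanol_g_L[n], x$truth$true_conversion_pct[n]))
  if (!is.na(x$arrest_time_h)) {
    cat(sprintf("  uptake arrested at %g h (ethanol threshold %g g/L)\n",
                x$arrest_time_h, x$params$arrest_ethanol_g_L))
  }
  invisible(x)
}

#' Simulate an OD600 growth curve
#'
#' Flat at `od0` during the lag phase, exponential at `alpha` afterwards,
#' capped at `od_max` (stationary). Optional multiplicative log-normal noise
#' with coefficient of variation `noise_cv`.
#'
#' @param alpha True exponential growth rate, h^-1.
#' @param od0 Inoculation OD600.
#' @param lag_h Lag-phase duration, hours.
#' @param od_max Stationary-phase ceiling (use `Inf` for unbounded growth).
#' @param duration_h,interval_h Sampling schedule, hours.
#' @param noise_cv Multiplicative noise CV (0 for noiseless).
#' @param seed Integer seed.
#' @return Data.frame with columns `time_h`, `od600`.
#' @export
simulate_growth_curve <- function(alpha, od0 = 0.05, lag_h = 2, od_max = 10,
                                  duration_h = 24, interval_h = 1,
                                  noise_cv = 0, seed = 1L) {
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (od0 <= 0) stop("'od0' must be positive", call. = FALSE)
  if (lag_h < 0 || od_max <= 0 || duration_h <= 0 || interval_h <= 0 ||
      noise_cv < 0) {
    stop("invalid growth-curve parameters", call. = FALSE)
  }
  t <- seq(0, duration_h, by = interval_h)
  od <- ifelse(t <= lag_h, od0, pmin(od0 * exp(alpha * (t - lag_h)), od_max))
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    od <- od * stats::rlnorm(length(od), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(time_h = t, od600 = od)
}

#' Simulate cell axis measurements
#'
#' Draws `n` cells with log-normally distributed horizontal and vertical
#' semi-axes around the given means and emits the measurement-export dialect
#' (full axis lengths, i.e. twice the semi-axes).
#'
#' @param mean_a,mean_b Mean horizontal and vertical semi-axes, um, with
#'   `mean_b >= mean_a > 0`.
#' @param cv Coefficient of variation of each axis (log-normal).
#' @param n Number of cells.
#' @param condition Condition label attached to every row.
#' @param seed Integer seed.
#' @return Data.frame with columns `cell_id`, `condition`, `major_axis_um`,
#'   `minor_axis_um`.
#' @export
simulate_cell_dimensions <- function(mean_a = 2.0, mean_b = 2.6, cv = 0.1,
                                     n = 100, condition = "reference",
                                     seed = 1L) {
  if (mean_a <= 0 || mean_b < mean_a) {
    stop("need mean_b >= mean_a > 0", call. = FALSE)
  }
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  if (cv == 0) {
    a <- rep(mean_a, n)
    b <- rep(mean_b, n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    a <- stats::rlnorm(n, meanlog = log(mean_a) - sdlog^2 / 2, sdlog = sdlog)
    b <- stats::rlnorm(n, meanlog = log(mean_b) - sdlog^2 / 2, sdlog = sdlog)
  }
  # Emitted as drawn: the vertical axis is reported as the major axis. A
  # noisy draw can put the horizontal axis larger (as a real line-tool export
  # can); readers canonicalize per cell.
  data.frame(
    cell_id = sprintf("cell_%04d", seq_len(n)),
    condition = condition,
    major_axis_um = 2 * b,
    minor_axis_um = 2 * a
  )
}
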