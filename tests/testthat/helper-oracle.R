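# Independent straight-line oracle for the mass-balance chain.
# Deliberately shares no code with the package: every formula is written out
# inline, row by row, from the printed correlations.
oracle_mass_balance <- function(gL, M, Mg, Si0) {
  stopifnot(nrow(gL) >= 1)
  out <- data.frame(time_h = gL$time_h, rho = NA_real_, s_i = NA_real_,
                    v_l = NA_real_, glc_yield = NA_real_, conv = NA_real_,
                    eth_yield = NA_real_)
  for (i in seq_len(nrow(gL))) {
    cg  <- gL$glucose_g_L[i] / 1000
    ccb <- gL$cellobiose_g_L[i] / 1000
    cx  <- gL$xylose_g_L[i] / 1000
    cgl <- gL$glycerol_g_L[i] / 1000
    cac <- gL$acetic_acid_g_L[i] / 1000
    cet <- gL$ethanol_g_L[i] / 1000
    rho <- 0.456 * (cg + ccb + cx) + 0.97
    dg  <- cg  - gL$glucose_g_L[1] / 1000
    dcb <- ccb - gL$cellobiose_g_L[1] / 1000
    dx  <- cx  - gL$xylose_g_L[1] / 1000
    dgl <- cgl - gL$glycerol_g_L[1] / 1000
    dac <- cac - gL$acetic_acid_g_L[1] / 1000
    det <- cet - gL$ethanol_g_L[1] / 1000
    D <- (dg / 1.11 + dcb / 1.056 + dx / 1.36 + dgl / 1.135 +
            dac / 1.11 + det / 0.567) / rho
    s_i <- (Si0 - D) / (1 - D)
    v_l <- M * (1 - s_i) / rho
    out$rho[i] <- rho
    out$s_i[i] <- s_i
    out$v_l[i] <- v_l
    out$glc_yield[i] <- (cg * v_l / 1.11) / Mg * 100
    out$conv[i] <- (cg / 1.11 + ccb / 1.056 + cgl / 1.135 + cac / 1.111 +
                      cet / 0.567) * v_l / Mg * 100
    out$eth_yield[i] <- (cet * v_l * 0.9) / (0.51 * Mg) * 100
  }
  out
}

# Random, physically plausible broth time courses in the external g/L dialect,
# with a zero baseline and slowly accumulating products.
random_timecourse <- function(n_times = 10) {
  t <- sort(c(0, runif(n_times - 1, 1, 168)))
  grow <- function(top) c(0, sort(runif(n_times - 1, 0, top)))
  data.frame(
    time_h = t,
    glucose_g_L = grow(30),
    cellobiose_g_L = grow(3),
    xylose_g_L = grow(4),
    glycerol_g_L = grow(3),
    acetic_acid_g_L = grow(1.5),
    ethanol_g_L = grow(30)
  )
}

random_config <- function() {
  M <- runif(1, 20, 200)
  Si0 <- runif(1, 0.12, 0.25)
  ssf_config(
    total_mass_g = M,
    glucan_mass_g = Si0 * M * runif(1, 0.6, 0.885),
    insoluble_solids_frac = Si0
  )
}
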