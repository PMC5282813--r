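# Independent oracles used to cross-check the implementation.

# Combustion-balance ThOD oracle: solves the product coefficients of
# CxHyOzNn + a O2 -> x CO2 + b H2O + n NH3 from element conservation
# (C fixes CO2, N fixes NH3, H fixes H2O, then the O balance fixes O2).
thod_oracle <- function(formula, charge = 0) {
  f <- parse_formula(formula)
  el <- function(e) if (e %in% names(f)) f[[e]] else 0
  h <- el("H") + max(-charge, 0) # conjugate acid for anions
  n_co2 <- el("C")
  n_nh3 <- el("N")
  n_h2o <- (h - 3 * n_nh3) / 2
  n_o2 <- (2 * n_co2 + n_h2o - el("O")) / 2
  mass <- sum(f * atomic_masses[names(f)]) + max(-charge, 0) * atomic_masses[["H"]]
  max(n_o2, 0) * 32 / mass
}

# Row-by-row brute-force recomputation of a period summary
# (mean-of-daily-ratios), written with scalar arithmetic and its own
# interpolation calls.
oracle_period_summary <- function(influent, effluent, gas, hrt, window) {
  sel <- effluent$time_d >= window[1] & effluent$time_d <= window[2]
  eff <- effluent[sel, , drop = FALSE]
  interp <- function(df, col, t) {
    if (nrow(df) == 1) return(df[[col]][1])
    stats::approx(df$time_d, df[[col]], xout = t, rule = 2)$y
  }
  vfa_cols_in <- grep("^vfa_.*_gCOD_L$", names(influent), value = TRUE)
  vfa_cols_out <- grep("^vfa_.*_gCOD_L$", names(effluent), value = TRUE)
  rows <- NULL
  for (i in seq_len(nrow(eff))) {
    t <- eff$time_d[i]
    cod_in <- interp(influent, "cod_gCOD_L", t)
    vfa_in <- 0
    for (cl in vfa_cols_in) vfa_in <- vfa_in + interp(influent, cl, t)
    cod_out <- eff$cod_gCOD_L[i]
    vfa_out <- 0
    for (cl in vfa_cols_out) vfa_out <- vfa_out + eff[[cl]][i]
    ch4 <- interp(gas, "ch4_mL_L_d", t)
    co2 <- interp(gas, "co2_mL_L_d", t)
    h2 <- interp(gas, "h2_mL_L_d", t)
    vss_cod <- if ("vss_cod_gCOD_L_d" %in% names(eff)) {
      eff$vss_cod_gCOD_L_d[i]
    } else {
      eff$vss_g_L[i] / hrt * 1.2
    }
    fed <- cod_in / hrt
    removed <- (cod_in - cod_out) / hrt
    net_vfa <- (vfa_out - vfa_in) / hrt
    ch4_cod <- ch4 / 1000 / 22.4 * 64
    tracked <- net_vfa + ch4_cod + vss_cod
    rows <- rbind(rows, c(
      da = 100 * (vfa_out - vfa_in) / (cod_in - vfa_in),
      yvfa = 100 * (vfa_out - vfa_in) /
        ((cod_in - vfa_in) - (cod_out - vfa_out)),
      ych4 = if (removed > 0) (ch4 / 1000) / removed else
        if (ch4 == 0) 0 else NA_real_,
      vfa_prod = net_vfa, ch4_cod = ch4_cod, vss_cod = vss_cod,
      fed = fed, removed = removed, tracked = tracked,
      tracked_pct = 100 * tracked / fed,
      biogas_ch4 = if (ch4 + co2 + h2 > 0) 100 * ch4 / (ch4 + co2 + h2)
        else NA_real_,
      fed_as_ch4 = 100 * ch4_cod / fed
    ))
  }
  list(mean = colMeans(rows), sd = apply(rows, 2, stats::sd))
}

# Random steady-ish reactor fixture with valid constraints.
random_period_fixture <- function(seed) {
  set.seed(seed)
  times <- 0:14
  n <- length(times)
  cod_in <- runif(1, 30, 80)
  vfa_in <- runif(1, 0, 0.2) * cod_in
  influent <- data.frame(
    time_d = times, cod_gCOD_L = cod_in * (1 + runif(n, -0.05, 0.05)),
    vfa_acetate_gCOD_L = vfa_in * (1 + runif(n, -0.1, 0.1))
  )
  conv <- runif(1, 0.2, 0.7)
  eff_cod <- cod_in * (1 - runif(1, 0.01, 0.2)) * (1 + runif(n, -0.05, 0.05))
  vfa_out <- conv * eff_cod * runif(n, 0.8, 1)
  effluent <- data.frame(
    time_d = times, cod_gCOD_L = eff_cod,
    vfa_acetate_gCOD_L = 0.4 * vfa_out, vfa_butyrate_gCOD_L = 0.6 * vfa_out,
    vss_g_L = runif(n, 2, 15)
  )
  gas <- data.frame(
    time_d = times, h2_mL_L_d = runif(n, 0, 50),
    co2_mL_L_d = runif(n, 50, 400), ch4_mL_L_d = runif(n, 10, 400)
  )
  list(influent = influent, effluent = effluent, gas = gas,
       hrt = runif(1, 5, 15), window = c(5, 14))
}

# Simplex draw for random pathway weights.
random_weights <- function(total = 1) {
  x <- stats::runif(4)
  w <- total * x / sum(x)
  names(w) <- c("ethanol", "acetate_h2", "butyrate", "homoacetate")
  w
}
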