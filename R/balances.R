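# Reactor performance equations and period summaries: degree of
# acidification, VFA bioconversion yield, methanogenesis yield, COD
# mass balance (COD tracked) and biogas composition, plus the
# period-summary machinery that turns influent/effluent/gas time
# series into a report.
#
# Undefined yields (zero denominators) are reported as NA and rendered
# "n.d."; they are a data condition, not an error.

#' Degree of acidification (COD to VFAs)
#'
#' `100 * (VFA_out - VFA_in) / (COD_in - VFA_in)`: the fraction of
#' non-VFA influent COD converted to VFAs.
#'
#' @param vfa_in,vfa_out Influent/effluent VFA concentration
#'   (g_COD L^-1).
#' @param cod_in Influent total COD (g_COD L^-1); must exceed `vfa_in`.
#' @return Percent. Vectorised.
#' @export
degree_of_acidification <- function(vfa_in, vfa_out, cod_in) {
  if (any(cod_in <= vfa_in)) {
    stop("cod_in must exceed vfa_in (non-positive denominator)")
  }
  100 * (vfa_out - vfa_in) / (cod_in - vfa_in)
}

#' VFA bioconversion yield
#'
#' `100 * (VFA_out - VFA_in) / ((COD_in - VFA_in) - (COD_out -
#' VFA_out))`: VFA production on the COD actually transformed. Unlike
#' the degree of acidification this excludes untouched effluent COD, so
#' it is typically higher and can exceed 100%. A zero denominator
#' yields `NA` (undefined), not an error.
#'
#' @param vfa_in,vfa_out,cod_in,cod_out Concentrations in g_COD L^-1.
#' @return Percent (possibly > 100), `NA` where undefined. Vectorised.
#' @export
y_vfa <- function(vfa_in, vfa_out, cod_in, cod_out) {
  denom <- (cod_in - vfa_in) - (cod_out - vfa_out)
  out <- ifelse(abs(denom) < .Machine$double.eps^0.5, NA_real_,
                100 * (vfa_out - vfa_in) / denom)
  out
}

#' Methanogenesis yield
#'
#' Litres of CH4 produced per gram of COD removed:
#' `(CH4 mL rate / 1000) / COD removal rate`. Zero production with
#' positive removal gives 0; production with zero removal is undefined
#' (`NA`).
#'
#' @param ch4_volume_rate mL CH4 L^-1 d^-1.
#' @param cod_removed_rate g_COD L^-1 d^-1.
#' @return L CH4 per g_COD removed; `NA` where undefined. Vectorised.
#' @export
y_ch4 <- function(ch4_volume_rate, cod_removed_rate) {
  ifelse(cod_removed_rate > 0,
         (ch4_volume_rate / 1000) / cod_removed_rate,
         ifelse(ch4_volume_rate == 0, 0, NA_real_))
}

#' COD mass balance (COD tracked)
#'
#' Sum of the three accounted daily production terms -- net VFAs, CH4
#' as COD, biomass VSS as COD -- and that sum as a percent of fed COD.
#'
#' @param net_vfa,ch4_as_cod,vss_as_cod,cod_fed Rates in
#'   g_COD L^-1 d^-1; `cod_fed > 0`.
#' @return List with `rate` (g_COD L^-1 d^-1) and `percent`.
#' @examples
#' cod_tracked(2.47, 0.60, 2.94, 4.70) # 6.01 g_COD/L/d, 127.9%
#' @export
cod_tracked <- function(net_vfa, ch4_as_cod, vss_as_cod, cod_fed) {
  if (any(cod_fed <= 0)) stop("cod_fed must be positive")
  rate <- net_vfa + ch4_as_cod + vss_as_cod
  list(rate = rate, percent = 100 * rate / cod_fed)
}

#' Biogas composition
#'
#' Per-species volume percent of the produced biogas.
#'
#' @param ch4,co2,h2 Volumes or volume rates (same units).
#' @return Named vector of percents (`NA`s if the total is zero).
#' @export
biogas_composition <- function(ch4, co2, h2 = 0) {
  total <- ch4 + co2 + h2
  if (any(c(ch4, co2, h2) < 0)) stop("gas volumes must be non-negative")
  if (total == 0) {
    return(c(ch4 = NA_real_, co2 = NA_real_, h2 = NA_real_))
  }
  c(ch4 = 100 * ch4 / total, co2 = 100 * co2 / total, h2 = 100 * h2 / total)
}

#' H2:CO2 volume ratio
#'
#' @param h2,co2 Volumes (same units); `NA` where CO2 is zero.
#' @return Dimensionless ratio. Vectorised.
#' @export
h2_co2_ratio <- function(h2, co2) {
  ifelse(co2 > 0, h2 / co2, NA_real_)
}

.vfa_columns <- function(df) grep("^vfa_.*_gCOD_L$", names(df), value = TRUE)

.total_vfa <- function(df) {
  cols <- .vfa_columns(df)
  if (length(cols) == 0) stop("no vfa_<species>_gCOD_L columns found")
  rowSums(df[, cols, drop = FALSE])
}

#' Assemble a reactor period
#'
#' Bundles influent/effluent stream series, a gas series, the hydraulic
#' retention time and an evaluation window into the object
#' [summarize_period()] consumes.
#'
#' @param influent,effluent data.frames with columns `time_d`,
#'   `cod_gCOD_L`, one or more `vfa_<species>_gCOD_L`, and optionally
#'   `vss_g_L`, `vss_cod_gCOD_L_d`, `ph`, `cond_mS_cm`.
#' @param gas data.frame with columns `time_d`, `h2_mL_L_d`,
#'   `co2_mL_L_d`, `ch4_mL_L_d`.
#' @param hrt Hydraulic retention time in days (> 0).
#' @param olr_nominal Nominal organic loading rate (g_COD L^-1 d^-1),
#'   metadata only.
#' @param window `c(start, end)` in days; defaults to the last 10 days
#'   of the effluent series.
#' @return Object of class `reactor_period`.
#' @export
reactor_period <- function(influent, effluent, gas, hrt,
                           olr_nominal = NA_real_, window = NULL) {
  stopifnot(hrt > 0)
  .check_stream_schema(influent, "influent")
  .check_stream_schema(effluent, "effluent")
  .check_gas_schema(gas)
  if (is.null(window)) {
    tmax <- max(effluent$time_d)
    window <- c(max(min(effluent$time_d), tmax - 10), tmax)
  }
  stopifnot(length(window) == 2, window[2] >= window[1])
  structure(
    list(influent = influent, effluent = effluent, gas = gas,
         hrt = hrt, olr_nominal = olr_nominal, window = window),
    class = "reactor_period"
  )
}

.schema_error <- function(msg) {
  stop(structure(
    class = c("vfaferm_schema_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.check_stream_schema <- function(df, what = "stream") {
  need <- c("time_d", "cod_gCOD_L")
  missing <- setdiff(need, names(df))
  if (length(.vfa_columns(df)) == 0) {
    missing <- c(missing, "vfa_<species>_gCOD_L")
  }
  if (length(missing) > 0) {
    .schema_error(paste0(what, " series lacks column(s): ",
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}

.check_gas_schema <- function(df) {
  need <- c("time_d", "h2_mL_L_d", "co2_mL_L_d", "ch4_mL_L_d")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    .schema_error(paste0("gas series lacks column(s): ",
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}

.series_at <- function(times, values, at) {
  if (length(times) == 1) return(rep(values, length(at)))
  stats::approx(times, values, xout = at, rule = 2)$y
}

#' Summarise a reactor period into a balance report
#'
#' Computes the daily performance metrics at each effluent sampling
#' time inside the window (influent and gas series are linearly
#' interpolated to those times) and then averages. The default
#' averaging order is mean-of-daily-ratios; `averaging = "period"`
#' instead applies the formulas once to window means.
#'
#' The biomass COD flux uses a direct `vss_cod_gCOD_L_d` effluent
#' column when present, otherwise effluent `vss_g_L / HRT * 1.2`.
#'
#' @param period A [reactor_period()].
#' @param factors A [conversion_factors()].
#' @param averaging `"ratio"` (mean of daily ratios, default) or
#'   `"period"` (ratio of window means).
#' @param molar_volume Gas molar volume (L mol^-1) for COD conversion.
#' @return Object of class `balance_report`: a list with `summary`
#'   (mean and sd per metric), the `daily` metric table and metadata.
#' @export
summarize_period <- function(period, factors = conversion_factors(),
                             averaging = c("ratio", "period"),
                             molar_volume = 22.4) {
  stopifnot(inherits(period, "reactor_period"))
  averaging <- match.arg(averaging)
  eff <- period$effluent
  sel <- eff$time_d >= period$window[1] & eff$time_d <= period$window[2]
  if (!any(sel)) .schema_error("empty evaluation window")
  eff <- eff[sel, , drop = FALSE]
  at <- eff$time_d
  inf <- period$influent
  gas <- period$gas
  hrt <- period$hrt

  cod_in <- .series_at(inf$time_d, inf$cod_gCOD_L, at)
  vfa_in <- .series_at(inf$time_d, .total_vfa(inf), at)
  cod_out <- eff$cod_gCOD_L
  vfa_out <- .total_vfa(eff)
  ch4 <- .series_at(gas$time_d, gas$ch4_mL_L_d, at)
  co2 <- .series_at(gas$time_d, gas$co2_mL_L_d, at)
  h2 <- .series_at(gas$time_d, gas$h2_mL_L_d, at)

  vss_cod <- if ("vss_cod_gCOD_L_d" %in% names(eff)) {
    eff$vss_cod_gCOD_L_d
  } else if ("vss_g_L" %in% names(eff)) {
    vss_to_cod(eff$vss_g_L / hrt, factors)
  } else {
    .schema_error("effluent series lacks column(s): vss_g_L or vss_cod_gCOD_L_d")
  }

  daily_metrics <- function(cod_in, vfa_in, cod_out, vfa_out,
                            ch4, co2, h2, vss_cod) {
    cod_fed <- cod_in / hrt
    cod_removed <- (cod_in - cod_out) / hrt
    net_vfa <- (vfa_out - vfa_in) / hrt
    ch4_cod <- gas_to_cod(ch4, "CH4", molar_volume)
    tracked <- cod_tracked(net_vfa, ch4_cod, vss_cod, cod_fed)
    total_gas <- ch4 + co2 + h2
    data.frame(
      time_d = if (length(cod_in) == length(at)) at else NA_real_,
      da_percent = degree_of_acidification(vfa_in, vfa_out, cod_in),
      y_vfa_percent = y_vfa(vfa_in, vfa_out, cod_in, cod_out),
      vfa_productivity = net_vfa,
      ch4_mL_L_d = ch4,
      ch4_as_cod = ch4_cod,
      y_ch4_L_per_gCOD = y_ch4(ch4, cod_removed),
      vss_as_cod = vss_cod,
      cod_fed = cod_fed,
      cod_removed = cod_removed,
      cod_tracked = tracked$rate,
      cod_tracked_percent = tracked$percent,
      biogas_ch4_percent = ifelse(total_gas > 0, 100 * ch4 / total_gas, NA_real_),
      fed_cod_as_ch4_percent = 100 * ch4_cod / cod_fed,
      h2_co2 = h2_co2_ratio(h2, co2)
    )
  }

  daily <- daily_metrics(cod_in, vfa_in, cod_out, vfa_out, ch4, co2, h2, vss_cod)

  if (averaging == "ratio") {
    metrics <- setdiff(names(daily), "time_d")
    summary <- data.frame(
      metric = metrics,
      mean = vapply(metrics, function(m) mean(daily[[m]]), numeric(1)),
      sd = vapply(metrics, function(m) stats::sd(daily[[m]]), numeric(1)),
      row.names = NULL
    )
  } else {
    one <- daily_metrics(
      mean(cod_in), mean(vfa_in), mean(cod_out), mean(vfa_out),
      mean(ch4), mean(co2), mean(h2), mean(vss_cod)
    )
    metrics <- setdiff(names(one), "time_d")
    summary <- data.frame(
      metric = metrics,
      mean = as.numeric(one[1, metrics]),
      sd = NA_real_,
      row.names = NULL
    )
  }

  structure(
    list(summary = summary, daily = daily, window = period$window,
         hrt = hrt, olr_nominal = period$olr_nominal,
         averaging = averaging, n_days = nrow(daily)),
    class = "balance_report"
  )
}

#' Extract a metric from a balance report
#'
#' @param report A `balance_report`.
#' @param metric Metric name as in `report$summary$metric`.
#' @return Named numeric `c(mean, sd)`.
#' @export
report_metric <- function(report, metric) {
  i <- match(metric, report$summary$metric)
  if (is.na(i)) stop("unknown metric: ", metric)
  c(mean = report$summary$mean[i], sd = report$summary$sd[i])
}

.fmt_nd <- function(x, digits = 1) {
  ifelse(is.na(x), "n.d.", formatC(round(x, digits), format = "f", digits = digits))
}

#' @export
print.balance_report <- function(x, ...) {
  g <- function(m) report_metric(x, m)
  cat(sprintf("Reactor period summary (window %.1f-%.1f d, HRT %.1f d, %s averaging, n = %d)\n",
              x$window[1], x$window[2], x$hrt, x$averaging, x$n_days))
  rows <- rbind(
    c("COD to VFAs (DA)        [%]", .fmt_nd(g("da_percent")[1]), .fmt_nd(g("da_percent")[2])),
    c("Y_VFA                   [%]", .fmt_nd(g("y_vfa_percent")[1]), .fmt_nd(g("y_vfa_percent")[2])),
    c("VFA productivity  [gCOD/L/d]", .fmt_nd(g("vfa_productivity")[1], 2), .fmt_nd(g("vfa_productivity")[2], 2)),
    c("CH4 production     [mL/L/d]", .fmt_nd(g("ch4_mL_L_d")[1]), .fmt_nd(g("ch4_mL_L_d")[2])),
    c("CH4 as COD       [gCOD/L/d]", .fmt_nd(g("ch4_as_cod")[1], 2), .fmt_nd(g("ch4_as_cod")[2], 2)),
    c("Y_CH4          [L/gCOD rem]", .fmt_nd(g("y_ch4_L_per_gCOD")[1], 3), .fmt_nd(g("y_ch4_L_per_gCOD")[2], 3)),
    c("VSS as COD       [gCOD/L/d]", .fmt_nd(g("vss_as_cod")[1], 2), .fmt_nd(g("vss_as_cod")[2], 2)),
    c("COD fed          [gCOD/L/d]", .fmt_nd(g("cod_fed")[1], 2), .fmt_nd(g("cod_fed")[2], 2)),
    c("COD removed      [gCOD/L/d]", .fmt_nd(g("cod_removed")[1], 2), .fmt_nd(g("cod_removed")[2], 2)),
    c("COD tracked      [gCOD/L/d]", .fmt_nd(g("cod_tracked")[1], 2), .fmt_nd(g("cod_tracked")[2], 2)),
    c("COD tracked           [% fed]", .fmt_nd(g("cod_tracked_percent")[1]), .fmt_nd(g("cod_tracked_percent")[2])),
    c("Biogas CH4 content      [%]", .fmt_nd(g("biogas_ch4_percent")[1]), .fmt_nd(g("biogas_ch4_percent")[2])),
    c("Fed COD as CH4          [%]", .fmt_nd(g("fed_cod_as_ch4_percent")[1]), .fmt_nd(g("fed_cod_as_ch4_percent")[2]))
  )
  cat(sprintf("  %-30s %10s %10s\n", "metric", "mean", "sd"))
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("  %-30s %10s %10s\n", rows[i, 1], rows[i, 2], rows[i, 3]))
  }
  invisible(x)
}

#' Read a tidy stream CSV
#'
#' Expected columns: `time_d`, `stream` (`in`/`out`), `cod_gCOD_L`, one
#' or more `vfa_<species>_gCOD_L`, optionally `vss_g_L`,
#' `vss_cod_gCOD_L_d`, `ph`, `cond_mS_cm`.
#'
#' @param path CSV path.
#' @return List with `influent` and `effluent` data.frames.
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stream" %in% names(df)) .schema_error("stream CSV lacks column: stream")
  .check_stream_schema(df, basename(path))
  list(
    influent = df[df$stream == "in", , drop = FALSE],
    effluent = df[df$stream == "out", , drop = FALSE]
  )
}

#' Read a gas-series CSV
#'
#' Expected columns: `time_d`, `h2_mL_L_d`, `co2_mL_L_d`, `ch4_mL_L_d`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_gas_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_gas_schema(df)
  df
}

#' Write a balance report to JSON (and optionally text)
#'
#' @param report A `balance_report`.
#' @param json_path Output JSON path.
#' @param txt_path Optional rendered-text output path.
#' @return Invisibly, the JSON path.
#' @export
write_balance_report <- function(report, json_path, txt_path = NULL) {
  payload <- list(
    window = report$window, hrt = report$hrt,
    olr_nominal = report$olr_nominal, averaging = report$averaging,
    n_days = report$n_days,
    metrics = stats::setNames(
      lapply(seq_len(nrow(report$summary)), function(i) {
        list(mean = report$summary$mean[i], sd = report$summary$sd[i])
      }),
      report$summary$metric
    )
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(txt_path)) {
    txt <- utils::capture.output(print(report))
    writeLines(txt, txt_path)
  }
  invisible(json_path)
}
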