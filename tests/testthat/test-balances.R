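# Performance equations and period summaries.

test_that("degree of acidification matches its definition and guards its domain", {
  expect_equal(round(degree_of_acidification(0, 2.47, 4.70), 1), 52.6)
  expect_equal(degree_of_acidification(1.3, 1.3, 5), 0)
  expect_equal(round(degree_of_acidification(0.14, 6.77 + 0.14, 9.82), 1), 69.9)
  expect_error(degree_of_acidification(5, 6, 5), "exceed")
})

test_that("y_vfa can exceed 100% and signals undefined denominators", {
  # net VFA 2.47 against 3.09 transformed: 79.9%
  expect_equal(round(y_vfa(0, 2.47, 4.70, 4.70 - 0.62), 1), 79.9)
  # net VFA equal to the full transformed COD: exactly 100%
  expect_equal(y_vfa(0, 3, 10, 10), 100)
  # effluent non-VFA COD grew: yield above 100%
  expect_gt(y_vfa(0, 2, 5, 6), 100)
  expect_true(is.na(y_vfa(0, 2, 5, 7)))
})

test_that("y_ch4 reproduces the worked methanogenesis yields", {
  expect_equal(round(y_ch4(211.3, 0.62), 3), 0.341)
  expect_equal(round(y_ch4(114.9, 0.41), 3), 0.280)
  expect_equal(y_ch4(0, 0.5), 0)
  expect_true(is.na(y_ch4(100, 0)))
})

test_that("cod_tracked sums the accounted pools and scales correctly", {
  ct <- cod_tracked(2.47, 0.60, 2.94, 4.70)
  expect_equal(ct$rate, 6.01)
  expect_equal(round(ct$percent, 1), 127.9)
  ct2 <- cod_tracked(6.77, 1.04, 3.40, 9.82)
  expect_equal(ct2$rate, 11.21)
  expect_equal(round(ct2$percent, 1), 114.2)
  expect_equal(cod_tracked(0, 0, 0, 1)$percent, 0)
  # percent is scale invariant
  k <- 3.7
  expect_equal(cod_tracked(k * 2.47, k * 0.60, k * 2.94, k * 4.70)$percent,
               ct$percent)
  expect_error(cod_tracked(1, 1, 1, 0), "positive")
})

test_that("biogas composition and H2:CO2 ratio behave", {
  expect_equal(round(biogas_composition(211.3, 359)[["ch4"]]), 37)
  expect_equal(round(biogas_composition(114.9, 137)[["ch4"]], 1), 45.6)
  expect_equal(biogas_composition(50, 0, 0)[["ch4"]], 100)
  expect_true(all(is.na(biogas_composition(0, 0, 0))))
  expect_equal(round(h2_co2_ratio(480, 961), 1), 0.5)
  expect_equal(h2_co2_ratio(0, 10), 0)
  expect_equal(h2_co2_ratio(7, 7), 1)
  expect_true(is.na(h2_co2_ratio(5, 0)))
})

test_that("DA never exceeds Y_VFA when effluent non-VFA COD is non-negative", {
  set.seed(11)
  for (i in 1:200) {
    cod_in <- runif(1, 5, 100)
    vfa_in <- runif(1, 0, 0.3) * cod_in
    cod_out <- runif(1, 0.3, 0.999) * cod_in
    vfa_out <- runif(1, vfa_in / cod_out, 1) * cod_out
    da <- degree_of_acidification(vfa_in, vfa_out, cod_in)
    yv <- y_vfa(vfa_in, vfa_out, cod_in, cod_out)
    if (!is.na(yv) && yv > 0) expect_lte(da, yv + 1e-9)
  }
})

.steady_fixture <- function(cod_in, vfa_out, cod_out, vss_cod, ch4, co2,
                            times = 0:10) {
  n <- length(times)
  list(
    influent = data.frame(time_d = times, cod_gCOD_L = cod_in,
                          vfa_acetate_gCOD_L = 0),
    effluent = data.frame(time_d = times, cod_gCOD_L = cod_out,
                          vfa_acetate_gCOD_L = 0.4 * vfa_out,
                          vfa_butyrate_gCOD_L = 0.6 * vfa_out,
                          vss_g_L = 0, vss_cod_gCOD_L_d = vss_cod),
    gas = data.frame(time_d = times, h2_mL_L_d = 0, co2_mL_L_d = co2,
                     ch4_mL_L_d = ch4)
  )
}

test_that("a constant steady-state series gives zero SD and the single-day formulas", {
  fx <- .steady_fixture(47.0, 24.7, 40.8, 2.94, 211.3, 359)
  period <- reactor_period(fx$influent, fx$effluent, fx$gas, hrt = 10,
                           window = c(0, 10))
  rep <- summarize_period(period)
  expect_equal(unname(report_metric(rep, "da_percent")), c(52.55319, 0),
               tolerance = 1e-6)
  expect_equal(report_metric(rep, "y_ch4_L_per_gCOD")[["mean"]],
               y_ch4(211.3, 0.62), tolerance = 1e-9)
  expect_equal(report_metric(rep, "cod_tracked")[["sd"]], 0)
  # both averaging orders coincide on a constant series
  rep2 <- summarize_period(period, averaging = "period")
  expect_equal(report_metric(rep2, "y_vfa_percent")[["mean"]],
               report_metric(rep, "y_vfa_percent")[["mean"]], tolerance = 1e-9)
})

test_that("period summaries reproduce the published-style derived columns", {
  # OLR 5 operating point (fed 4.70, net VFA 2.47, CH4 211.3, VSS 2.94)
  fx <- .steady_fixture(47.0, 24.7, 40.8, 2.94, 211.3, 359)
  rep <- summarize_period(reactor_period(fx$influent, fx$effluent, fx$gas,
                                         hrt = 10, window = c(0, 10)))
  expect_equal(round(report_metric(rep, "y_ch4_L_per_gCOD")[["mean"]], 3), 0.341)
  expect_equal(round(report_metric(rep, "cod_tracked")[["mean"]], 2), 6.01)
  expect_equal(report_metric(rep, "cod_tracked_percent")[["mean"]], 127.8,
               tolerance = 0.002)
  expect_equal(round(report_metric(rep, "biogas_ch4_percent")[["mean"]]), 37)
  expect_equal(round(report_metric(rep, "fed_cod_as_ch4_percent")[["mean"]]), 13)
})

test_that("summarize_period equals the brute-force oracle on random fixtures", {
  for (seed in 1:10) {
    fx <- random_period_fixture(seed)
    period <- reactor_period(fx$influent, fx$effluent, fx$gas, hrt = fx$hrt,
                             window = fx$window)
    rep <- summarize_period(period)
    oracle <- oracle_period_summary(fx$influent, fx$effluent, fx$gas,
                                    fx$hrt, fx$window)
    pairs <- c(da_percent = "da", y_vfa_percent = "yvfa",
               y_ch4_L_per_gCOD = "ych4", vfa_productivity = "vfa_prod",
               ch4_as_cod = "ch4_cod", vss_as_cod = "vss_cod",
               cod_fed = "fed", cod_removed = "removed",
               cod_tracked = "tracked", cod_tracked_percent = "tracked_pct",
               biogas_ch4_percent = "biogas_ch4",
               fed_cod_as_ch4_percent = "fed_as_ch4")
    for (m in names(pairs)) {
      expect_equal(report_metric(rep, m)[["mean"]],
                   oracle$mean[[pairs[[m]]]], tolerance = 1e-9,
                   info = paste(m, "seed", seed))
      expect_equal(report_metric(rep, m)[["sd"]],
                   oracle$sd[[pairs[[m]]]], tolerance = 1e-9)
    }
  }
})

test_that("window defaulting, schema validation and undefined rendering work", {
  fx <- .steady_fixture(47.0, 24.7, 40.8, 2.94, 211.3, 359, times = 0:30)
  p <- reactor_period(fx$influent, fx$effluent, fx$gas, hrt = 10)
  expect_equal(p$window, c(20, 30))
  bad_eff <- fx$effluent[, setdiff(names(fx$effluent), c("vfa_acetate_gCOD_L",
                                                         "vfa_butyrate_gCOD_L"))]
  expect_error(
    reactor_period(fx$influent, bad_eff, fx$gas, hrt = 10),
    "vfa_<species>_gCOD_L", class = "vfaferm_schema_error"
  )
  expect_error(
    reactor_period(fx$influent, fx$effluent, fx$gas[, 1:2], hrt = 10),
    "gas series lacks", class = "vfaferm_schema_error"
  )
  expect_error(
    summarize_period(reactor_period(fx$influent, fx$effluent, fx$gas,
                                    hrt = 10, window = c(100, 101))),
    "empty", class = "vfaferm_schema_error"
  )
  # a zero-removal fixture renders its undefined yield as n.d.
  fx2 <- .steady_fixture(40, 10, 40, 1, 100, 50)
  rep2 <- summarize_period(reactor_period(fx2$influent, fx2$effluent, fx2$gas,
                                          hrt = 10, window = c(0, 10)))
  expect_true(is.na(report_metric(rep2, "y_ch4_L_per_gCOD")[["mean"]]))
  out <- capture.output(print(rep2))
  expect_true(any(grepl("n.d.", out, fixed = TRUE)))
})

test_that("stream and gas CSVs round-trip through the readers", {
  fx <- .steady_fixture(47.0, 24.7, 40.8, 2.94, 211.3, 359)
  dir <- withr::local_tempdir()
  stream <- rbind(
    cbind(fx$influent, stream = "in", vfa_butyrate_gCOD_L = 0,
          vss_g_L = 0, vss_cod_gCOD_L_d = 0),
    cbind(fx$effluent, stream = "out")
  )
  write.csv(stream, file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(fx$gas, file.path(dir, "g.csv"), row.names = FALSE)
  got <- read_stream_csv(file.path(dir, "s.csv"))
  expect_equal(nrow(got$influent), nrow(fx$influent))
  expect_equal(nrow(got$effluent), nrow(fx$effluent))
  gg <- read_gas_csv(file.path(dir, "g.csv"))
  expect_equal(gg$ch4_mL_L_d, fx$gas$ch4_mL_L_d)
  writeLines("time_d,foo\n1,2", file.path(dir, "bad.csv"))
  expect_error(read_gas_csv(file.path(dir, "bad.csv")),
               class = "vfaferm_schema_error")
})
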