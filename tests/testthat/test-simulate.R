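# The synthetic-data generator: stoichiometric closure, design
# fidelity and reproducibility.

test_that("config validation enforces the stated invariants", {
  expect_error(batch_config(pathway_weights = c(ethanol = 0.5, acetate_h2 = 0.6,
                                                butyrate = 0, homoacetate = 0)),
               "sum to at most 1")
  expect_error(batch_config(pathway_weights = c(ethanol = -0.1, acetate_h2 = 0.5,
                                                butyrate = 0.3, homoacetate = 0.3)),
               "non-negative")
  expect_error(batch_config(biomass_yield = 0.7))
  expect_error(pbbr_config(olr_schedule = cbind(day = c(0, 5, 3),
                                                olr = c(5, 10, 12))))
  expect_error(pbbr_config(methanogenesis_fraction = 1.5))
})

test_that("per-interval COD closure is exact for batch and continuous runs", {
  sim_b <- simulate_batch(batch_preset("terrestrial", seed = 5))
  expect_lt(max(abs(sim_b$truth$intervals$closure_residual)), 1e-9)
  sim_p <- simulate_pbbr(pbbr_preset("marine", seed = 5))
  expect_lt(max(abs(sim_p$truth$intervals$closure_residual)), 1e-9)
  # closure also holds when part of the converted COD is untracked
  w <- c(ethanol = 0.1, acetate_h2 = 0.2, butyrate = 0.3, homoacetate = 0.2)
  sim_u <- simulate_batch(batch_config(pathway_weights = w, seed = 5))
  expect_lt(max(abs(sim_u$truth$intervals$closure_residual)), 1e-9)
  expect_true(all(sim_u$truth$intervals$produced_other > 0))
})

test_that("pure homoacetogenesis yields acetate only with zero gas", {
  w <- c(ethanol = 0, acetate_h2 = 0, butyrate = 0, homoacetate = 1)
  sim <- simulate_batch(batch_config(pathway_weights = w, noise_cv = 0, seed = 2))
  st <- sim$truth$state
  expect_true(all(st$vfa_butyrate_gCOD_L == 0))
  expect_true(all(st$ethanol_gCOD_L == 0))
  expect_true(all(st$h2_mL_L == 0))
  expect_true(all(st$co2_mL_L == 0))
  expect_gt(max(st$vfa_acetate_gCOD_L), 0)
})

test_that("the butyrate route fixes the H2:CO2 volume ratio at 1", {
  w <- c(ethanol = 0, acetate_h2 = 0, butyrate = 1, homoacetate = 0)
  sim <- simulate_batch(batch_config(pathway_weights = w, noise_cv = 0, seed = 2))
  st <- sim$truth$state
  nz <- st$co2_mL_L > 0
  expect_true(any(nz))
  expect_equal(st$h2_mL_L[nz] / st$co2_mL_L[nz], rep(1, sum(nz)),
               tolerance = 1e-9)
})

test_that("the enrichment preset lands in the observed day-7 VFA window", {
  sim <- simulate_batch(batch_preset("terrestrial", olr = 5, ph_i = 7, seed = 42))
  st <- sim$truth$state
  last <- st[st$batch == max(st$batch) &
               st$time_d == max(st$time_d), , drop = FALSE]
  vfa <- last$vfa_acetate_gCOD_L + last$vfa_butyrate_gCOD_L
  expect_gte(vfa, 25)
  expect_lte(vfa, 35)
})

test_that("identical seeds give byte-identical emitted CSVs; different seeds differ", {
  cfg <- batch_preset("marine", seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim_csv(simulate_batch(cfg), d1)
  p2 <- write_sim_csv(simulate_batch(cfg), d2)
  for (f in c("stream", "gas", "truth")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  p3 <- write_sim_csv(simulate_batch(batch_preset("marine", seed = 100)),
                      withr::local_tempdir())
  expect_false(identical(readLines(p1[["stream"]]), readLines(p3[["stream"]])))
})

test_that("conductivity strictly increases with added NaCl at every sample", {
  base <- simulate_batch(batch_config(nacl_added = 0, noise_cv = 0, seed = 3))
  prev <- base$truth$state$cond_mS_cm
  for (nacl in c(5, 22.8, 40)) {
    cur <- simulate_batch(batch_config(nacl_added = nacl, noise_cv = 0,
                                       seed = 3))$truth$state$cond_mS_cm
    expect_true(all(cur > prev))
    prev <- cur
  }
})

test_that("pH drifts down with acid production and is reset at correction days", {
  sim <- simulate_batch(batch_config(noise_cv = 0, buffer_capacity = 0.3,
                                     seed = 4))
  st <- sim$truth$state
  b1 <- st[st$batch == 1, ]
  expect_lt(b1$ph[b1$time_d == 7], 7)       # free drift after day 4
  expect_true(all(st$ph >= 4))
  expect_lt(b1$ph[b1$time_d == 1], 7)       # sampled before correction
})

test_that("serial batches emit the designed sampling pattern", {
  sim <- simulate_batch(batch_preset("terrestrial", seed = 1))
  out <- sim$stream[sim$stream$stream == "out", ]
  expect_equal(nrow(out), 3 * 5) # five sampling days per batch, three batches
  expect_equal(sort(unique(out$time_d[out$batch == 2])), 7 + c(0, 1, 2, 4, 7))
  # transfers dilute: VFA at the start of batch 2 is the transfer
  # fraction of the end of batch 1
  st <- sim$truth$state
  end1 <- st[st$batch == 1 & st$time_d == 7, ]
  start2 <- st[st$batch == 2 & st$time_d == 7, ]
  expect_equal(start2$vfa_butyrate_gCOD_L,
               (15 / 80) * end1$vfa_butyrate_gCOD_L, tolerance = 1e-9)
})

test_that("a no-reaction PBBR follows the CSTR washout closed form", {
  cfg <- pbbr_config(uptake_rate = 0, methanogenesis_fraction = 0,
                     startup_batch_days = 0,
                     olr_schedule = cbind(day = 0, olr = 5),
                     duration = 40, noise_cv = 0)
  eff <- simulate_pbbr(cfg)$truth$effluent
  closed_form <- 50 * (1 - exp(-eff$time_d / 10))
  expect_lt(max(abs(eff$cod_gCOD_L - closed_form)), 1e-6)
  # 63.2% of the inlet after one HRT
  expect_equal(eff$cod_gCOD_L[eff$time_d == 10] / 50, 1 - exp(-1),
               tolerance = 1e-9)
})

test_that("a converting PBBR reaches the algebraic steady-state balance", {
  cfg <- pbbr_config(olr_schedule = cbind(day = 0, olr = 5), duration = 120,
                     noise_cv = 0, seed = 8)
  sim <- simulate_pbbr(cfg)
  eff <- sim$truth$effluent
  ints <- sim$truth$intervals
  n <- nrow(eff)
  # C_in - C = r * HRT with r the daily consumption rate
  expect_equal(50 - (eff$cod_gCOD_L[n] - eff$vss_g_L[n] * 1.2 -
                       eff$vfa_acetate_gCOD_L[n] - eff$vfa_butyrate_gCOD_L[n] -
                       eff$ethanol_gCOD_L[n]),
               ints$consumed_gCOD[n] * 10, tolerance = 1e-3)
})

test_that("effluent stabilises within one to three retention times", {
  cfg <- pbbr_config(olr_schedule = cbind(day = 0, olr = 5), duration = 77,
                     noise_cv = 0, seed = 8)
  eff <- simulate_pbbr(cfg)$truth$effluent
  ss <- eff$cod_gCOD_L[nrow(eff)]
  within5 <- abs(eff$cod_gCOD_L - ss) / ss < 0.05
  t_star <- min(eff$time_d[within5])
  expect_gte(t_star, 10)
  expect_lte(t_star, 30)
})

test_that("doubling the OLR roughly doubles VFA productivity at steady state", {
  sim <- simulate_pbbr(pbbr_config(seed = 3, noise_cv = 0))
  r1 <- summarize_period(as_reactor_period(sim, window = c(37, 47), truth = TRUE))
  r2 <- summarize_period(as_reactor_period(sim, window = c(67, 77), truth = TRUE))
  ratio <- report_metric(r2, "vfa_productivity")[["mean"]] /
    report_metric(r1, "vfa_productivity")[["mean"]]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.1)
})

test_that("balances on noisy observations still track COD within ten percent", {
  sim <- simulate_pbbr(pbbr_config(olr_schedule = cbind(day = 0, olr = 5),
                                   duration = 77, seed = 21))
  rep <- summarize_period(as_reactor_period(sim))
  expect_equal(report_metric(rep, "cod_tracked_percent")[["mean"]], 100,
               tolerance = 0.1)
})
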