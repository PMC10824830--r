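test_that("base speed is a stationary AR(1) with the configured moments", {
  cfg0 <- dyad_sim_config(duration_s = 30, climax_time_s = 15, base_sd = 0,
                          noise_sd = 1, seed = 1)
  expect_equal(as.numeric(simulate_base_speed(cfg0)), rep(0, 30 * 120 - 1))
  # white-noise case: sample sd within 3 standard errors at n = 36,000
  cfg <- dyad_sim_config(duration_s = 300, climax_time_s = 150,
                         base_sd = 2, base_phi = 0, seed = 7)
  s <- as.numeric(simulate_base_speed(cfg))
  n <- length(s)
  expect_equal(n, 35999)
  se_sd <- 2 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(s) - 2), 3 * se_sd)
  expect_lt(abs(mean(s)), 3 * 2 / sqrt(n))
  # smooth case: lag-1 autocorrelation near phi
  cfg2 <- dyad_sim_config(duration_s = 300, climax_time_s = 150,
                          base_phi = 0.9, seed = 8)
  s2 <- as.numeric(simulate_base_speed(cfg2))
  expect_lt(abs(cor(s2[-1], s2[-length(s2)]) - 0.9), 0.02)
  # determinism: the same seed reproduces the signal exactly
  expect_identical(as.numeric(simulate_base_speed(cfg)), s)
})

test_that("coupled signals echo the storyteller at the configured delay", {
  # noiseless single coupling: exact echo at the coupling lag
  cfg <- dyad_sim_config(duration_s = 30, climax_time_s = 15,
                         base_phi = 0.9, noise_sd = 0,
                         coupling_pre = coupling(500, 2),
                         coupling_post = coupling(500, 2), seed = 3)
  sig <- simulate_dyad_signals(cfg)
  L <- round(0.5 * 120)
  got <- xcorr_at_lag(sig$storyteller, sig$child, L)
  expect_equal(got$r, 1, tolerance = 1e-12)
  # negative gain gives a perfect anticorrelation
  cfgn <- dyad_sim_config(duration_s = 30, climax_time_s = 15,
                          base_phi = 0.9, noise_sd = 0,
                          coupling_pre = coupling(500, -2),
                          coupling_post = coupling(500, -2), seed = 3)
  expect_equal(xcorr_at_lag(simulate_dyad_signals(cfgn)$storyteller,
                            simulate_dyad_signals(cfgn)$child, L)$r,
               -1, tolerance = 1e-12)
  # regime switch: no coupling before the climax, coupling after
  cfg2 <- dyad_sim_config(duration_s = 60, climax_time_s = 30,
                          base_phi = 0, noise_sd = 1,
                          coupling_pre = coupling(),
                          coupling_post = coupling(500, 1), seed = 4)
  sig2 <- simulate_dyad_signals(cfg2)
  cf <- sig2$climax_frame
  pre <- xcorr_at_lag(sig2$storyteller[1:cf], sig2$child[1:cf], L)
  n <- length(sig2$storyteller)
  post <- xcorr_at_lag(sig2$storyteller[(cf + 1):n], sig2$child[(cf + 1):n], L)
  expect_lt(abs(pre$r), 0.1)
  expect_gt(post$r, 0.6)
})

test_that("the closed-form expected correlation matches its variance algebra", {
  base <- dyad_sim_config(duration_s = 300, climax_time_s = 150, base_phi = 0,
                          base_sd = 1, noise_sd = 1,
                          coupling_post = coupling(500, 1))
  expect_equal(theoretical_rho(base, 500), 1 / sqrt(2), tolerance = 1e-15)
  g0 <- base; g0$coupling_post <- coupling(500, 0)
  expect_equal(theoretical_rho(g0, 500), 0)
  noiseless <- dyad_sim_config(duration_s = 300, climax_time_s = 150,
                               base_phi = 0, noise_sd = 0,
                               coupling_post = coupling(500, -3))
  expect_equal(theoretical_rho(noiseless, 500), -1)
  expect_equal(theoretical_rho(base, 300), 0)  # off-lag, white-noise base
  multi <- base; multi$coupling_post <- coupling(c(300, 500), c(1, 1))
  expect_error(theoretical_rho(multi, 500), "unsupported")
  # Monte-Carlo recovery at n ~ 36,000: observed r within 3 MC standard errors
  cfg <- dyad_sim_config(duration_s = 300, climax_time_s = 150, base_phi = 0,
                         base_sd = 1, noise_sd = 1,
                         coupling_pre = coupling(500, 1),
                         coupling_post = coupling(500, 1), seed = 11)
  sig <- simulate_dyad_signals(cfg)
  r <- xcorr_at_lag(sig$storyteller, sig$child, 60)$r
  m <- length(sig$storyteller) - 60
  se_r <- (1 - 0.5) / sqrt(m)   # delta-method sd of r at rho = 1/sqrt(2)
  expect_lt(abs(r - 1 / sqrt(2)), 3 * se_r)
})

test_that("marker embedding reproduces the generating signals downstream", {
  cfg <- dyad_sim_config(duration_s = 30, climax_time_s = 15, base_phi = 0.9,
                         noise_sd = 1, marker_jitter_sd = 0,
                         coupling_pre = coupling(500, 1),
                         coupling_post = coupling(500, 1), seed = 5)
  sim <- simulate_dyad(cfg, "dX", "6y", "PAI")
  expect_s3_class(sim$table, "marker_table")
  expect_equal(length(unique(sim$table$marker)), 14)  # 7 markers per interactant
  expect_equal(nrow(sim$table), 14 * 30 * 120)
  expect_equal(sim$meta$dyad_id, "dX")
  rec <- apply_labels(sim$table, sim$labels)
  # only the 8 back markers survive labeling
  expect_equal(length(unique(rec$data$marker)), 8)
  sig <- preprocess_dyad(rec, cutoff_hz = NULL)
  # recovered approach-axis speeds track the generating truth
  # (the 0.999 mean-reversion drift used to keep posture bounded perturbs the
  # recovered speed slightly, so agreement is near- but not exactly perfect)
  expect_gt(xcorr_coef(sig$storyteller, sim$truth$storyteller), 0.99)
  expect_gt(xcorr_coef(sig$child, sim$truth$child), 0.99)
})

test_that("group simulation writes a reproducible, readable dataset", {
  tpl <- dyad_sim_config(duration_s = 5, climax_time_s = 2.5, seed = 1)
  gcfg <- group_sim_config(n_per_cell = 1, template = tpl, base_seed = 99)
  d1 <- withr::local_tempdir()
  man <- simulate_group(gcfg, d1)
  expect_length(man$marker_paths, 4)       # one dyad per 2 x 2 cell
  expect_equal(nrow(man$metadata), 4)
  expect_true(all(file.exists(man$marker_paths)))
  tab <- read_marker_table(man$marker_paths[1], fps = 120)
  expect_equal(length(unique(tab$marker)), 14)
  # byte-identical regeneration from the same base seed
  d2 <- withr::local_tempdir()
  simulate_group(gcfg, d2)
  for (f in basename(c(man$marker_paths, man$metadata_path, man$labels_path))) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
  # cell overrides reach the per-dyad configs
  gcfg2 <- group_sim_config(n_per_cell = 1, template = tpl,
                            cell_overrides = list("3y.PII" = list(noise_sd = 0)),
                            base_seed = 99)
  d3 <- withr::local_tempdir()
  man3 <- simulate_group(gcfg2, d3)
  expect_false(identical(readLines(man3$marker_paths[["3y_PII_01"]]),
                         readLines(man$marker_paths[["3y_PII_01"]])))
  expect_identical(readLines(man3$marker_paths[["3y_PAI_01"]]),
                   readLines(man$marker_paths[["3y_PAI_01"]]))
})
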