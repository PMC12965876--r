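test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_sites = 0), "positive integer")
  expect_error(sim_config(detect_prob = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(group_r2 = c(pesticides = 0.7, soil = 0.4)), "sum to < 1")
  expect_error(sim_config(group_r2 = c(weather = 0.2)), "unknown driver group")
  expect_error(sim_config(ecosystem_props = c(0.5, 0.5)), "match ecosystem_levels")
  expect_error(generate_environment(sim_config(env_correlation = -0.99)),
               "positive definite")
})

test_that("concentration censoring behaves at both degenerate limits", {
  all_zero <- generate_concentrations(sim_config(n_sites = 50, detect_prob = 0,
                                                 plant_rare_column = FALSE))
  expect_true(all(all_zero == 0))
  all_pos <- generate_concentrations(sim_config(n_sites = 50, detect_prob = 1,
                                                loq = 0, round_digits = 9,
                                                plant_rare_column = FALSE))
  expect_true(all(all_pos > 0))
})

test_that("no generated concentration lies strictly inside (0, LOQ)", {
  cfg <- sim_config(n_sites = 200, loq = 0.005, seed = 23)
  conc <- generate_concentrations(cfg)
  expect_true(all(conc == 0 | conc >= cfg$loq))
})

test_that("column detection frequencies agree with the binomial 99% CI", {
  # loq far below the 0.1% lognormal quantile so censoring does not bite
  q001 <- qlnorm(0.001, log(0.02), 1)
  cfg <- sim_config(n_sites = 1000, n_pesticides = 20, detect_prob = 0.3,
                    loq = q001 / 10, round_digits = 9,
                    plant_rare_column = FALSE, seed = 24)
  conc <- generate_concentrations(cfg)
  freq <- colMeans(conc > 0)
  half <- qnorm(0.995) * sqrt(0.3 * 0.7 / 1000)
  # 99% CI per column; allow the rare straggler over 20 columns
  expect_gte(mean(abs(freq - 0.3) <= half), 0.9)
  expect_lt(abs(mean(freq) - 0.3), 0.01)
})

test_that("environment reproduces requested correlations and ecosystem proportions", {
  cfg <- sim_config(n_sites = 5000, env_correlation = 0.5, seed = 25)
  env <- generate_environment(cfg)
  # two untransformed soil variables carry the raw latent correlation
  expect_equal(cor(env$sand, env$clay), 0.5, tolerance = 0.05)

  cfg0 <- sim_config(n_sites = 5000, env_correlation = 0, seed = 26)
  env0 <- generate_environment(cfg0)
  expect_lt(abs(cor(env0$sand, env0$clay)), 0.05)

  cfg373 <- sim_config(seed = 27)  # default 373 sites, survey proportions
  env373 <- generate_environment(cfg373)
  obs <- table(env373$ecosystem)
  gof <- chisq.test(obs, p = cfg373$ecosystem_props)
  expect_gt(gof$p.value, 0.01)
  expect_true(all(env373$conductivity > 0))
})

test_that("counts have the requested library-size floor and Dirichlet limits", {
  cfg <- sim_config(n_sites = 40, n_taxa = 100, seed = 28)
  cg <- generate_counts(cfg)
  for (g in names(cg$counts)) {
    tot <- rowSums(cg$counts[[g]])
    expect_true(all(tot >= 5000 & tot <= 50000))
    expect_true(all(cg$counts[[g]] >= 0))
  }
  expect_true(all(cg$gene_summaries$functional_reads > 0))

  # near-uniform taxon probabilities: per-site Shannon approaches ln(S)
  cfg_unif <- sim_config(n_sites = 10, n_taxa = 50, dirichlet_conc = 1e6,
                         lib_size_range = c(50000L, 50000L), seed = 29)
  sh <- richness_shannon(generate_counts(cfg_unif)$counts$bacteria)$shannon
  expect_equal(mean(sh), log(50), tolerance = 0.01)

  # rarefaction monotonicity: observed richness falls as depth falls
  cfg_r <- sim_config(n_sites = 30, n_taxa = 100, dirichlet_conc = 0.5,
                      lib_size_range = c(10000L, 10000L), seed = 30)
  tab <- generate_counts(cfg_r)$counts$fungi
  rich_full <- mean(richness_shannon(tab)$richness)
  expect_lt(rich_full, 100)
  rich_sub <- mean(richness_shannon(srs_normalize(tab, 500, seed = 1))$richness)
  rich_sub2 <- mean(richness_shannon(srs_normalize(tab, 100, seed = 1))$richness)
  expect_lt(rich_sub, rich_full)
  expect_lt(rich_sub2, rich_sub)
})

test_that("responses hit the planted variance structure at its limits", {
  # no drivers: fitted full-model r2 stays near zero
  cfg0 <- sim_config(n_sites = 400, group_r2 = c(pesticides = 0, soil = 0, climate = 0),
                     seed = 31, response_metrics = "m")
  sim0 <- suppressWarnings(simulate_soildriver(cfg0))
  d0 <- cbind(sim0$environment, as.data.frame(sim0$concentrations), sim0$responses["m"])
  f0 <- fit_driver_glm("m", c("water_content", "sand", "mat", "pest_01"), d0)
  expect_lt(f0$diagnostics$r2, 0.05)

  # noiseless single predictor: r2 = 1 to numerical precision
  cfg1 <- sim_config(n_sites = 120, noise_sd = 0, orthogonalize = FALSE,
                     group_r2 = c(soil = 0.9), n_true = c(soil = 1L),
                     response_metrics = "m", seed = 32)
  sim1 <- suppressWarnings(simulate_soildriver(cfg1))
  d1 <- cbind(sim1$environment, sim1$responses["m"])
  f1 <- fit_driver_glm("m", sim1$truth$m$true_terms$soil, d1)
  expect_equal(f1$diagnostics$r2, 1, tolerance = 1e-9)

  # unattainable targets raise a calibration failure
  expect_error(
    suppressWarnings(simulate_soildriver(
      sim_config(n_sites = 60, noise_sd = 1e6,
                 group_r2 = c(soil = 0.9), response_metrics = "m", seed = 33))),
    "calibration failure")
})

test_that("realized unique fractions match the planted group_r2", {
  cfg <- sim_config(n_sites = 300, seed = 34)
  sim <- suppressWarnings(simulate_soildriver(cfg))
  for (mt in cfg$response_metrics) {
    tr <- sim$truth[[mt]]
    expect_equal(unname(tr$realized_unique),
                 unname(cfg$group_r2[names(tr$realized_unique)]),
                 tolerance = 0.05)
    # and independently recomputed through the attribution module
    d <- cbind(sim$environment, as.data.frame(sim$concentrations),
               sim$responses[mt])
    vp <- variation_partition(mt, tr$true_terms, d)
    expect_equal(unname(vp$unique[names(cfg$group_r2)]),
                 unname(cfg$group_r2), tolerance = 0.05)
  }
})

test_that("identical configuration reproduces a bit-identical dataset", {
  cfg <- sim_config(n_sites = 60, n_pesticides = 6, n_taxa = 30, seed = 35)
  s1 <- suppressWarnings(simulate_soildriver(cfg))
  s2 <- suppressWarnings(simulate_soildriver(cfg))
  expect_identical(s1$concentrations, s2$concentrations)
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$responses, s2$responses)
})

test_that("all generated tables share one ordered site-identifier set", {
  sim <- quiet_sim(n_sites = 40, n_pesticides = 5, n_taxa = 20, seed = 36,
                   group_r2 = c(soil = 0.25), n_true = c(soil = 2L))
  ids <- rownames(sim$concentrations)
  expect_identical(sim$environment$site_id, ids)
  expect_identical(sim$responses$site_id, ids)
  for (g in names(sim$counts)) expect_identical(rownames(sim$counts[[g]]), ids)
  expect_setequal(unique(sim$gene_summaries$site_id), ids)
})

test_that("simulated datasets round-trip to plain-text tables", {
  sim <- quiet_sim(n_sites = 20, n_pesticides = 4, n_taxa = 10, seed = 37,
                   group_r2 = c(soil = 0.25), n_true = c(soil = 2L))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  files <- list.files(dir)
  expect_true(all(c("concentrations.tsv", "environment.tsv", "responses.tsv",
                    "catalog.tsv", "truth.json") %in% files))
  back <- read.delim(file.path(dir, "concentrations.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[-1]), sim$concentrations, ignore_attr = TRUE)
})
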