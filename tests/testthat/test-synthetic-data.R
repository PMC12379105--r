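test_that("noiseless series satisfy the model exactly, including C(tz) = Cz", {
  sc <- flux_scenario(true_cm = 450, true_a = 0.02, true_b = 0.05,
    true_tz = 10, true_cz = 400, noise_sd = 0)
  s <- generate_flux_series(sc)
  expect_equal(length(s$t), 180)
  # value at t = tz is exactly Cz
  expect_identical(s$conc[s$t == 10], 400)
  # every timestamp satisfies the model
  expected <- 450 + 0.02 * (s$t - 10) + (400 - 450) * exp(-0.05 * (s$t - 10))
  expect_identical(s$conc, expected)
})

test_that("generators are pure functions of (scenario, seed)", {
  sc <- flux_scenario(noise_sd = 2, seed = 7)
  expect_identical(generate_flux_series(sc)$conc,
    generate_flux_series(sc)$conc)
  sc2 <- flux_scenario(noise_sd = 2, seed = 8)
  expect_false(identical(generate_flux_series(sc)$conc,
    generate_flux_series(sc2)$conc))
  # the global RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_flux_series(sc)); after <- runif(3)
  expect_identical(before, after)

  t1 <- generate_trait_table(trait_scenario(n_samples = 20, seed = 3))
  t2 <- generate_trait_table(trait_scenario(n_samples = 20, seed = 3))
  expect_identical(t1$samples, t2$samples)

  c1 <- generate_at_curve(at_scenario(noise_sd = 0.5, seed = 4))
  c2 <- generate_at_curve(at_scenario(noise_sd = 0.5, seed = 4))
  expect_identical(c1$assim, c2$assim)

  m1 <- generate_microclimate(seed = 5)
  m2 <- generate_microclimate(seed = 5)
  expect_identical(m1$value, m2$value)
})

test_that("scenario validation names the offending field", {
  expect_error(flux_scenario(duration = -1), "duration")
  expect_error(flux_scenario(noise_sd = -1), "noise_sd")
  expect_error(flux_scenario(sampling_rate = 0), "sampling_rate")
  expect_error(generate_diurnal_campaign(n_rounds = 30), "n_rounds")
  expect_error(generate_diurnal_campaign(missing_rounds = c(2L, 2L)),
    "duplicate")
  expect_error(at_scenario(n_points = 5), "n_points")
  expect_error(trait_scenario(violation_rates = c(ldmc = 2)),
    "violation_rates")
})

test_that("start-error modes move the first retained reading out of band", {
  s <- generate_flux_series(flux_scenario(failure_mode = "high_start",
    start_conc = 560, noise_sd = 0))
  tr <- trim_series(s)
  expect_gt(tr$start_conc, 521)
  f <- fit_exponential(tr)
  expect_identical(classify_flux(f, tr)$flag, "start_error")

  s2 <- generate_flux_series(flux_scenario(failure_mode = "low_start",
    noise_sd = 0))
  tr2 <- trim_series(s2)
  expect_lt(tr2$start_conc, 321)
})

test_that("a full campaign emits one NEE and one ER per plot and round", {
  camp <- generate_diurnal_campaign(n_sites = 1, plots_per_site = 2,
    n_rounds = 24, noise_sd = 0.5, seed = 2)
  expect_equal(nrow(camp), 2 * 24 * 2)
  counts <- table(camp$turfID, camp$round, camp$type)
  expect_true(all(counts == 1))
  # paired measurements share covariates
  by_slot <- split(camp, paste(camp$turfID, camp$round))
  for (sl in by_slot[1:5]) {
    expect_equal(sl$temp_airavg[1], sl$temp_airavg[2])
    expect_equal(sl$temp_soil[1], sl$temp_soil[2])
  }
})

test_that("trait generator inverts the processing rules it expects", {
  out <- generate_trait_table(trait_scenario(n_samples = 80, seed = 6))
  # zero violation rates: nothing is flagged
  expect_true(all(out$truth$intended_flag == "none"))
  derived <- derive_traits(out$samples)
  v <- validate_traits(derived)
  expect_equal(sum(v$raw$removed), 0)

  # folded species carry half their true area in the scanned column
  m <- merge(out$samples, out$truth, by = "ID")
  folded <- m[m$folded, ]
  expect_gt(nrow(folded), 0)
  expect_equal(folded$scanned_area_cm2, folded$true_area_cm2 / 2)
  unfolded <- m[!m$folded, ]
  expect_equal(unfolded$scanned_area_cm2, unfolded$true_area_cm2)

  # derivation recovers the true per-leaf SLA and LDMC
  sla <- derived[derived$trait == "SLA_cm2_g", c("ID", "value")]
  ms <- merge(sla, out$truth, by = "ID")
  expect_equal(ms$value, ms$true_sla, tolerance = 1e-10)
  ldmc <- derived[derived$trait == "LDMC_g_g", c("ID", "value")]
  ml <- merge(ldmc, out$truth, by = "ID")
  expect_equal(ml$value, ml$true_ldmc, tolerance = 1e-10)
})

test_that("injected violation rates land inside the binomial 99% interval", {
  n <- 1000
  p <- 0.05
  out <- generate_trait_table(trait_scenario(n_samples = n,
    violation_rates = c(ldmc = p), seed = 12))
  hits <- sum(grepl("LDMC", out$truth$intended_flag))
  band <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
  # and validation flags exactly the injected samples
  v <- validate_traits(derive_traits(out$samples))
  flagged_ids <- unique(v$raw$ID[v$raw$removed])
  intended_ids <- out$truth$ID[out$truth$intended_flag != "none"]
  expect_setequal(flagged_ids, intended_ids)
})

test_that("synthetic AT curves have the labelled shape at zero noise", {
  uni <- generate_at_curve(at_scenario("unimodal", true_topt = 22,
    noise_sd = 0))
  # exactly one interior maximum
  expect_equal(spline_modality(uni), 1L)
  expect_equal(uni$leaf_temp_c[which.max(uni$assim)], 22, tolerance = 0.5)

  bi <- generate_at_curve(at_scenario("bimodal", noise_sd = 0))
  expect_gte(spline_modality(bi), 2L)

  mono <- generate_at_curve(at_scenario("monotone", noise_sd = 0))
  # still rising at the top of the range: boundary maximum only
  expect_equal(spline_modality(mono), 1L)
  expect_equal(which.max(mono$assim), length(mono$assim))
})

test_that("microclimate generator injects exactly the labelled violations", {
  mc <- generate_microclimate(n_loggers = 2,
    violation_rates = c(air_high = 0.05, soil_low = 0.05,
      moisture_low = 0.05), seed = 13)
  th <- apply_microclimate_thresholds(mc)
  expect_identical(is.na(th$raw$flag), is.na(mc$intended_flag))
  hit <- !is.na(mc$intended_flag)
  expect_identical(th$raw$flag[hit], mc$intended_flag[hit])
  # zero-rate generator is clean
  mc0 <- generate_microclimate(seed = 13)
  th0 <- apply_microclimate_thresholds(mc0)
  expect_true(all(is.na(th0$raw$flag)))
})
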