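test_that("the decision tree classifies each documented case", {
  ch <- chamber_spec()
  cases <- list(
    # start gate first: outside 421 +/- 100 ppm
    list(series = make_series_for_qc(start_conc = 560),
      fit = make_fit(), flag = "start_error"),
    list(series = make_series_for_qc(start_conc = 280),
      fit = make_fit(), flag = "start_error"),
    # b artefact with trend -> discard; without trend -> zero
    list(series = make_series_for_qc(), fit = make_fit(b = 1.2, r = 0.8),
      flag = "discard"),
    list(series = make_series_for_qc(), fit = make_fit(b = 1.2, r = 0.3),
      flag = "zero"),
    list(series = make_series_for_qc(), fit = make_fit(b = -0.01, r = 0.2),
      flag = "zero"),
    # ER uptake is a bad fit
    list(series = make_series_for_qc(kind = "ER"),
      fit = make_fit(slope = -0.4, r = 0.7), flag = "discard"),
    # NEE uptake is fine
    list(series = make_series_for_qc(kind = "NEE"),
      fit = make_fit(slope = -0.4, r = 0.7), flag = "okflux"),
    # non-convergence is a bad fit
    list(series = make_series_for_qc(),
      fit = make_fit(converged = FALSE, r = 0.1), flag = "zero"),
    # passes all gates
    list(series = make_series_for_qc(start_conc = 430),
      fit = make_fit(b = 0.4, r = 0.9), flag = "okflux")
  )
  for (cs in cases) {
    got <- classify_flux(cs$fit, cs$series, ch)
    expect_identical(got$flag, cs$flag)
    if (cs$flag %in% c("start_error", "discard")) {
      expect_true(is.na(got$flux_value))
    } else if (cs$flag == "zero") {
      expect_identical(got$flux_value, 0)
    } else {
      expect_false(is.na(got$flux_value))
    }
  }
})

test_that("boundary conventions: b = 1 is bad, |r| = 0.5 is the zero branch", {
  ch <- chamber_spec()
  got <- classify_flux(make_fit(b = 1, r = 0.5), make_series_for_qc(), ch)
  expect_identical(got$flag, "zero")
  got2 <- classify_flux(make_fit(b = 1, r = 0.51), make_series_for_qc(), ch)
  expect_identical(got2$flag, "discard")
  # start exactly on the band edge is retained (centre 421, halfwidth 100)
  got3 <- classify_flux(make_fit(), make_series_for_qc(start_conc = 521), ch)
  expect_identical(got3$flag, "okflux")
})

test_that("okflux values match the slope conversion at the window mean temperature", {
  ch <- chamber_spec()
  s <- make_series_for_qc(start_conc = 430)
  f <- make_fit(b = 0.4, slope = 1.5, r = 0.9)
  got <- classify_flux(f, s, ch)
  expect_equal(got$flux_value,
    flux_from_slope(1.5, ch, mean(s$airtemp_c) + 273.15))
})

test_that("manual weird-flux overrides change exactly the named records", {
  rec <- tibble::tibble(
    fluxID = c("F1", "F2", "F3"),
    flag = c("okflux", "zero", "missing_round"),
    flux_value = c(10, 0, NA)
  )
  expect_identical(mark_weird(rec, character()), rec)
  out <- mark_weird(rec, "F1")
  expect_identical(out$flag, c("weird_flux", "zero", "missing_round"))
  expect_true(is.na(out$flux_value[1]))
  # missing_round cannot be overridden
  out2 <- mark_weird(rec, "F3")
  expect_identical(out2$flag[3], "missing_round")
  expect_warning(mark_weird(rec, "nope"), "unknown fluxID")
})

test_that("GPP arithmetic and flag propagation follow the pairing rules", {
  mk <- function(value, flag) list(flux_value = value, flag = flag,
    turfID = "T1", round = 1)
  # plain arithmetic: GPP = NEE - ER
  got <- compute_gpp(mk(-10, "okflux"), mk(4, "okflux"))
  expect_equal(got$flux_value, -14)
  expect_identical(got$flag, "okflux")
  # zeroed ER contributes 0 and marks the GPP
  got <- compute_gpp(mk(-10, "okflux"), mk(0, "zero"))
  expect_equal(got$flux_value, -10)
  expect_identical(got$flag, "zeroER")
  got <- compute_gpp(mk(0, "zero"), mk(4, "okflux"))
  expect_equal(got$flux_value, -4)
  expect_identical(got$flag, "zeroNEE")
  # a blocked member blocks the GPP with its own flag
  for (f in c("discard", "start_error", "weird_flux")) {
    got <- compute_gpp(mk(NA, f), mk(4, "okflux"))
    expect_true(is.na(got$flux_value))
    expect_identical(got$flag, f)
  }
  # mismatched pairing keys
  bad <- mk(4, "okflux"); bad$round <- 2
  expect_error(compute_gpp(mk(-10, "okflux"), bad), "not paired")
})

test_that("night correction zeroes the most positive GPP per site cycle", {
  rec <- tibble::tibble(
    datetime = as.POSIXct("2022-07-24 12:00:00", tz = "UTC") +
      c(0, 3600, 7200, 0, 3600),
    destSiteID = c("s1", "s1", "s1", "s2", "s2"),
    type = "GPP",
    flux_value = c(-12, -4.5, 1.5, -5, -2),
    flag = "okflux"
  )
  out <- night_correct_gpp(rec)
  expect_equal(out$flux_value[1:3], c(-13.5, -6, 0))
  expect_equal(out$flux_value[4:5], c(-3, 0))
  expect_equal(out$gpp_offset, c(1.5, 1.5, 1.5, -2, -2))
  # per-group maximum is exactly zero
  expect_equal(max(out$flux_value[1:3]), 0, tolerance = 1e-12)
  # single-record group collapses to zero
  one <- rec[3, ]
  expect_equal(night_correct_gpp(one)$flux_value, 0)
})

test_that("missing rounds become placeholders that complete the slot grid", {
  camp <- generate_diurnal_campaign(
    n_sites = 1, plots_per_site = 2, n_rounds = 6,
    missing_rounds = c(3L), noise_sd = 0, seed = 5
  )
  # one absent round x 2 plots x 2 types of raw series
  expect_equal(nrow(camp), 2 * 5 * 2)
  rec <- process_campaign(camp)
  miss <- rec[rec$flag == "missing_round", ]
  # NEE, ER and the derived GPP slot are all placeheld
  expect_equal(nrow(miss), 2 * 3)
  expect_setequal(unique(miss$round), 3L)
  # every (turf, round, type) slot appears exactly once
  slots <- paste(rec$turfID, rec$round, rec$type)
  expect_equal(anyDuplicated(slots), 0L)
  expect_equal(length(slots), 2 * 6 * 3)
  # flag counts partition the slots
  expect_equal(sum(flag_report(rec)$n), nrow(rec))
})

test_that("disabling night correction leaves GPP = NEE - ER bit-exact", {
  camp <- generate_diurnal_campaign(n_sites = 1, plots_per_site = 2,
    n_rounds = 5, noise_sd = 1, seed = 9)
  rec <- process_campaign(camp, night_correction = FALSE)
  gpp <- rec[rec$type == "GPP", ]
  for (i in seq_len(nrow(gpp))) {
    nee <- rec[rec$type == "NEE" & rec$turfID == gpp$turfID[i] &
      rec$round == gpp$round[i], ]
    er <- rec[rec$type == "ER" & rec$turfID == gpp$turfID[i] &
      rec$round == gpp$round[i], ]
    if (gpp$flag[i] %in% c("okflux", "zeroER", "zeroNEE", "zero")) {
      expect_identical(gpp$flux_value[i], nee$flux_value - er$flux_value)
    }
  }
  # no correction, no provenance offset column
  expect_false("gpp_offset" %in% names(rec))
})

test_that("campaign processing is deterministic for a fixed seed", {
  camp1 <- generate_diurnal_campaign(n_sites = 1, plots_per_site = 1,
    n_rounds = 3, noise_sd = 1.5, seed = 21)
  camp2 <- generate_diurnal_campaign(n_sites = 1, plots_per_site = 1,
    n_rounds = 3, noise_sd = 1.5, seed = 21)
  expect_identical(camp1$series[[1]]$conc, camp2$series[[1]]$conc)
  r1 <- process_campaign(camp1)
  r2 <- process_campaign(camp2)
  expect_identical(r1$flux_value, r2$flux_value)
  expect_identical(r1$flag, r2$flag)
})
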