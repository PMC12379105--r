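test_that("trait derivation reproduces the worked example", {
  s <- tibble::tibble(
    ID = "AAB0001", species = "Achillea millefolium", n_leaves = 2,
    n_leaves_at_dry = 2, wet_mass_g = 0.2, dry_mass_g = 0.05,
    scanned_area_cm2 = 10, thickness_1_mm = 0.20, thickness_2_mm = 0.25,
    thickness_3_mm = 0.21, plant_height_cm = 12
  )
  tr <- derive_traits(s)
  val <- function(trait) tr$value[tr$trait == trait]
  expect_equal(val("wet_mass_g"), 0.1)
  expect_equal(val("dry_mass_g"), 0.025)
  expect_equal(val("leaf_area_cm2"), 5)
  expect_equal(val("SLA_cm2_g"), 200)
  expect_equal(val("LDMC_g_g"), 0.25)
  expect_equal(val("leaf_thickness_mm"), 0.22)
  expect_equal(val("plant_height"), 12)
})

test_that("folded graminoids get their scanned area doubled", {
  s <- tibble::tibble(
    ID = c("A", "B"), species = c("Festuca rubra", "Agrostis capillaris"),
    n_leaves = 1, n_leaves_at_dry = 1, wet_mass_g = 0.1, dry_mass_g = 0.03,
    scanned_area_cm2 = 3.10, thickness_1_mm = 0.2, thickness_2_mm = NA,
    thickness_3_mm = NA, plant_height_cm = 10
  )
  tr <- derive_traits(s)
  area <- tr[tr$trait == "leaf_area_cm2", ]
  expect_equal(area$value[area$ID == "A"], 6.20)
  expect_equal(area$value[area$ID == "B"], 3.10)
})

test_that("leaves lost before drying use the drying-station leaf count", {
  s <- tibble::tibble(
    ID = "A", species = "Viola biflora", n_leaves = 4, n_leaves_at_dry = 3,
    wet_mass_g = 0.4, dry_mass_g = 0.09, scanned_area_cm2 = 20,
    thickness_1_mm = 0.2, thickness_2_mm = NA, thickness_3_mm = NA,
    plant_height_cm = 5
  )
  tr <- derive_traits(s)
  val <- function(trait) tr$value[tr$trait == trait]
  expect_equal(val("wet_mass_g"), 0.1)       # /4
  expect_equal(val("dry_mass_g"), 0.03)      # /3
  expect_equal(val("leaf_area_cm2"), 5)      # /4
  expect_equal(val("SLA_cm2_g"), 5 / 0.03)
  expect_equal(val("LDMC_g_g"), 0.03 / 0.1)
})

test_that("missing inputs yield flagged absent values, not errors", {
  s <- tibble::tibble(
    ID = "A", species = "Viola biflora", n_leaves = 1, n_leaves_at_dry = 1,
    wet_mass_g = NA_real_, dry_mass_g = 0.03, scanned_area_cm2 = 6,
    thickness_1_mm = NA_real_, thickness_2_mm = NA_real_,
    thickness_3_mm = NA_real_, plant_height_cm = NA_real_
  )
  tr <- derive_traits(s)
  expect_true(is.na(tr$value[tr$trait == "LDMC_g_g"]))
  expect_match(tr$flag[tr$trait == "LDMC_g_g"], "missing")
  expect_true(is.na(tr$value[tr$trait == "wet_mass_g"]))
  expect_true(is.na(tr$value[tr$trait == "leaf_thickness_mm"]))
  expect_false(is.na(tr$value[tr$trait == "SLA_cm2_g"]))
})

test_that("SLA x LDMC equals area per wet mass (algebraic identity)", {
  out <- generate_trait_table(trait_scenario(n_samples = 400, seed = 31))
  tr <- derive_traits(out$samples)
  wide <- tidyr::pivot_wider(tr[, c("ID", "trait", "value")],
    names_from = "trait", values_from = "value")
  lhs <- wide$SLA_cm2_g * wide$LDMC_g_g
  rhs <- wide$leaf_area_cm2 / wide$wet_mass_g
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("per-leaf division is scale-invariant for SLA and LDMC", {
  base <- tibble::tibble(
    ID = "A", species = "Viola biflora", n_leaves = 1, n_leaves_at_dry = 1,
    wet_mass_g = 0.12, dry_mass_g = 0.04, scanned_area_cm2 = 7,
    thickness_1_mm = 0.2, thickness_2_mm = NA, thickness_3_mm = NA,
    plant_height_cm = 5
  )
  multi <- base
  multi$n_leaves <- 5
  multi$n_leaves_at_dry <- 5
  multi$wet_mass_g <- base$wet_mass_g * 5
  multi$dry_mass_g <- base$dry_mass_g * 5
  multi$scanned_area_cm2 <- base$scanned_area_cm2 * 5
  t1 <- derive_traits(base)
  t5 <- derive_traits(multi)
  for (trait in c("SLA_cm2_g", "LDMC_g_g")) {
    expect_equal(t5$value[t5$trait == trait], t1$value[t1$trait == trait])
  }
})

test_that("chemical ratios and pooled expansion behave as documented", {
  r <- derive_chemical_ratios(45, 2.25, 0.2)
  expect_equal(r$cn_ratio, 20)
  expect_equal(r$np_ratio, 2.25 / 0.2)
  r2 <- derive_chemical_ratios(c(45, NA), c(2, 2), c(0.2, 0.2))
  expect_equal(r2$cn_ratio, c(22.5, NA))
  expect_equal(r2$np_ratio, c(10, 10))
  r3 <- derive_chemical_ratios(45, NA, 0.2)
  expect_true(is.na(r3$cn_ratio) && is.na(r3$np_ratio))

  pooled <- tibble::tibble(
    pool_id = c("P1", "P1", "P2"),
    trait = c("N_percent", "C_percent", "N_percent"),
    value = c(2.1, 44, 3.2)
  )
  members <- list(P1 = c("A", "B", "C"), P2 = "D")
  out <- expand_pooled_chemistry(pooled, members)
  expect_equal(nrow(out), 3 + 3 + 1)
  p1n <- out[out$trait == "N_percent" & out$ID %in% c("A", "B", "C"), ]
  expect_true(all(p1n$merged))
  expect_true(all(p1n$ID_merged == "A_B_C"))
  expect_false(out$merged[out$ID == "D"])
  # de-duplication drops n - 1 rows per pool and trait
  dedup <- out[!duplicated(out[, c("ID_merged", "trait")]) | !out$merged, ]
  expect_equal(nrow(dedup), 3)
  expect_error(expand_pooled_chemistry(pooled, list(P1 = "A")), "P2")
})

test_that("validation thresholds are strict and value-level", {
  rec <- tibble::tibble(
    ID = c("A", "A", "B", "B", "C", "D", "E"),
    species = "x",
    trait = c("LDMC_g_g", "SLA_cm2_g", "SLA_cm2_g", "N_percent",
      "SLA_cm2_g", "SLA_cm2_g", "N_percent"),
    value = c(1.05, 200, 500, 7.0, 4.9, 500.1, 6.4),
    flag = "", problem = "", comment = ""
  )
  v <- validate_traits(rec)
  expect_true(v$raw$removed[1])                  # LDMC 1.05 > 1
  expect_false(v$raw$removed[2])                 # SLA 200 retained
  expect_false(v$raw$removed[3])                 # SLA exactly 500 retained
  expect_true(v$raw$removed[4])                  # N 7.0 > 6.4
  expect_true(v$raw$removed[5])                  # SLA 4.9 < 5
  expect_true(v$raw$removed[6])                  # SLA 500.1 > 500
  expect_false(v$raw$removed[7])                 # N exactly 6.4 retained
  # value-level: sample A keeps its SLA row in the clean view
  expect_true(any(v$clean$ID == "A" & v$clean$trait == "SLA_cm2_g"))
  expect_false(any(v$clean$ID == "A" & v$clean$trait == "LDMC_g_g"))
  expect_match(v$raw$flag[1], "unreliable LDMC")
})

test_that("validation is monotone in the thresholds and books balance", {
  out <- generate_trait_table(trait_scenario(n_samples = 300,
    violation_rates = c(ldmc = 0.05, sla_low = 0.03, sla_high = 0.03,
      nitrogen = 0.05), seed = 17))
  rec <- derive_traits(out$samples)
  v1 <- validate_traits(rec)
  # widening every interval can only flag fewer records
  v2 <- validate_traits(rec, trait_thresholds(ldmc_max = 2, sla_min = 1,
    sla_max = 1000, n_max = 10))
  expect_lte(sum(v2$raw$removed), sum(v1$raw$removed))
  # exact bookkeeping
  expect_equal(nrow(v1$clean),
    nrow(rec) - sum(v1$raw$removed & !v1$raw$duplicate) -
      sum(v1$raw$duplicate))
  # duplicates are dropped keeping the first
  dup <- dplyr::bind_rows(rec, rec[1, ])
  vd <- validate_traits(dup)
  expect_equal(sum(vd$raw$duplicate), 1)
})
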