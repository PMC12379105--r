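#' Scenario for a synthetic leaf-trait envelope table
#'
#' Ground truth is drawn per sample: per-leaf dry mass, SLA and LDMC in
#' realistic grassland ranges; the raw envelope measurements (bulk wet and
#' dry mass, scanned area, thickness readings) are then back-computed so
#' that trait derivation must invert every processing rule (per-leaf
#' averaging, folded-graminoid area doubling) to recover the truth.
#' Threshold violations are injected independently per rule at the
#' requested rates, each constructed to trip exactly its own rule: an LDMC
#' violation rescales wet mass only, SLA violations rescale area only, and
#' a nitrogen violation raises leaf N only.
#'
#' @param n_samples Number of leaf samples.
#' @param species_pool Species names to draw from; defaults to the five
#'   folded-leaf graminoids plus five broadleaf herbs and dwarf shrubs.
#' @param leaf_count_range Inclusive range of leaves per composite sample.
#' @param violation_rates Named probabilities for `ldmc` (LDMC > 1),
#'   `sla_low` (SLA < 5), `sla_high` (SLA > 500) and `nitrogen`
#'   (N > 6.4 percent).
#' @param seed Integer RNG seed.
#' @return An object of class `trait_scenario`.
#' @export
trait_scenario <- function(n_samples = 200,
                           species_pool = c(folded_graminoids(),
                             "Achillea millefolium", "Alchemilla alpina",
                             "Vaccinium vitis-idaea", "Viola biflora",
                             "Bistorta vivipara"),
                           leaf_count_range = c(1, 5),
                           violation_rates = c(ldmc = 0, sla_low = 0,
                             sla_high = 0, nitrogen = 0),
                           seed = 1L) {
  check_field(is.numeric(n_samples) && n_samples >= 1, "n_samples",
    "must be >= 1")
  rates <- c(ldmc = 0, sla_low = 0, sla_high = 0, nitrogen = 0)
  rates[names(violation_rates)] <- violation_rates
  check_field(all(rates >= 0 & rates <= 1), "violation_rates",
    "must be probabilities")
  structure(
    list(
      n_samples = as.integer(n_samples),
      species_pool = species_pool,
      leaf_count_range = leaf_count_range,
      violation_rates = rates,
      seed = as.integer(seed)
    ),
    class = "trait_scenario"
  )
}

#' Generate a raw leaf-sample table with known ground truth
#'
#' @param scenario A [trait_scenario()].
#' @return A list with `samples` (the envelope-style raw table consumed by
#'   [derive_traits()]) and `truth` (per-sample true per-leaf SLA, LDMC and
#'   total leaf area, plus the intended validation flags, `"none"` when no
#'   violation was injected).
#' @export
generate_trait_table <- function(scenario) {
  stopifnot(inherits(scenario, "trait_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    n <- sc$n_samples
    species <- sample(sc$species_pool, n, replace = TRUE)
    folded <- species %in% folded_graminoids()
    n_leaves <- sample(
      seq(sc$leaf_count_range[1], sc$leaf_count_range[2]), n, replace = TRUE
    )

    dry_leaf <- exp(runif(n, log(0.005), log(0.1)))
    sla <- runif(n, 80, 350)
    ldmc <- runif(n, 0.15, 0.5)
    n_pct <- runif(n, 1, 4)
    c_pct <- runif(n, 42, 48)
    p_pct <- runif(n, 0.1, 0.3)

    viol <- sc$violation_rates
    v_ldmc <- runif(n) < viol[["ldmc"]]
    v_sla_low <- runif(n) < viol[["sla_low"]]
    v_sla_high <- runif(n) < viol[["sla_high"]] & !v_sla_low
    v_n <- runif(n) < viol[["nitrogen"]]

    ldmc[v_ldmc] <- runif(sum(v_ldmc), 1.01, 1.3)
    sla[v_sla_low] <- runif(sum(v_sla_low), 0.5, 4.9)
    sla[v_sla_high] <- runif(sum(v_sla_high), 505, 600)
    n_pct[v_n] <- runif(sum(v_n), 6.5, 8)

    area_leaf <- sla * dry_leaf
    wet_leaf <- dry_leaf / ldmc
    area_total <- area_leaf * n_leaves
    scanned <- ifelse(folded, area_total / 2, area_total)

    thick <- runif(n, 0.1, 0.4)
    samples <- tibble::tibble(
      ID = sprintf("LF%05d", seq_len(n)),
      species = species,
      n_leaves = n_leaves,
      n_leaves_at_dry = n_leaves,
      wet_mass_g = wet_leaf * n_leaves,
      dry_mass_g = dry_leaf * n_leaves,
      scanned_area_cm2 = scanned,
      thickness_1_mm = thick + rnorm(n, 0, 0.01),
      thickness_2_mm = thick + rnorm(n, 0, 0.01),
      thickness_3_mm = thick + rnorm(n, 0, 0.01),
      plant_height_cm = runif(n, 2, 40),
      c_percent = c_pct,
      n_percent = n_pct,
      p_percent = p_pct
    )

    flags <- purrr::pmap_chr(
      list(v_ldmc, v_sla_low | v_sla_high, v_n),
      function(l, s, nn) {
        f <- c(
          if (l) "unreliable LDMC",
          if (s) "unreliable SLA",
          if (nn) "unreliable N"
        )
        if (length(f) == 0) "none" else paste(f, collapse = "; ")
      }
    )
    truth <- tibble::tibble(
      ID = samples$ID,
      species = species,
      folded = folded,
      true_sla = sla,
      true_ldmc = ldmc,
      true_area_cm2 = area_total,
      intended_flag = flags
    )
    list(samples = samples, truth = truth)
  })
}
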