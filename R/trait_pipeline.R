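#' Graminoid species scanned with folded leaves
#'
#' These five graminoids have naturally tightly folded leaves that are
#' scanned folded; their scanned area is doubled during trait derivation to
#' recover the true one-sided leaf area.
#'
#' @return Character vector of species names.
#' @export
folded_graminoids <- function() {
  c("Festuca rubra", "Festuca ovina", "Festuca vivipara",
    "Avenella flexuosa", "Nardus stricta")
}

#' Derive per-leaf functional traits from raw envelope measurements
#'
#' Computes the standard leaf economics traits from an envelope-style table
#' (one row per leaf sample, possibly a multi-leaf composite):
#' \itemize{
#'   \item leaf area: scanned area, doubled for folded-graminoid species,
#'     divided by the number of leaves;
#'   \item wet and dry mass per leaf; dry mass uses the leaf count at the
#'     drying station (`n_leaves_at_dry`) when leaves were lost between
#'     weighing and drying, so each trait stays internally consistent;
#'   \item leaf thickness: mean of up to three micrometer readings;
#'   \item SLA = leaf area / dry mass (cm^2 g^-1), per-leaf values;
#'   \item LDMC = dry mass / wet mass (g g^-1), masses over the same leaf
#'     set (per-leaf values when the counts differ);
#'   \item chemical traits (C, N, P percent, d13C, d15N) passed through and
#'     C:N, N:P ratios derived when present.
#' }
#' Missing or zero-denominator inputs yield absent derived values flagged
#' `"missing <field>"` rather than errors.
#'
#' @param samples Data frame with columns `ID`, `species`, `n_leaves`,
#'   `n_leaves_at_dry`, `wet_mass_g`, `dry_mass_g`, `scanned_area_cm2`,
#'   `thickness_1_mm`..`thickness_3_mm`, `plant_height_cm` and optionally
#'   `c_percent`, `n_percent`, `p_percent`, `dc13_permil`, `dn15_permil`.
#' @param folded_species Species whose scanned area is doubled.
#' @return A long tibble with columns `ID`, `species`, `trait`, `value`,
#'   `flag`, `problem`, `comment` (one row per sample and trait).
#' @examples
#' s <- tibble::tibble(
#'   ID = "AAB0001", species = "Achillea millefolium", n_leaves = 2,
#'   n_leaves_at_dry = 2, wet_mass_g = 0.2, dry_mass_g = 0.05,
#'   scanned_area_cm2 = 10, thickness_1_mm = 0.20, thickness_2_mm = 0.25,
#'   thickness_3_mm = 0.21, plant_height_cm = 12
#' )
#' derive_traits(s)
#' @export
derive_traits <- function(samples, folded_species = folded_graminoids()) {
  s <- tibble::as_tibble(samples)
  n_rows <- nrow(s)
  col <- function(nm) {
    if (nm %in% names(s)) as.numeric(s[[nm]]) else rep(NA_real_, n_rows)
  }
  species <- if ("species" %in% names(s)) as.character(s$species) else
    rep(NA_character_, n_rows)

  n <- col("n_leaves")
  n_dry <- col("n_leaves_at_dry")
  n_dry <- ifelse(is.na(n_dry), n, n_dry)
  wet <- col("wet_mass_g")
  dry <- col("dry_mass_g")
  area_scan <- col("scanned_area_cm2")
  folded <- !is.na(species) & species %in% folded_species
  area_total <- ifelse(folded, area_scan * 2, area_scan)

  wet_leaf <- ifelse(is.na(wet) | is.na(n) | n < 1, NA_real_, wet / n)
  dry_leaf <- ifelse(is.na(dry) | is.na(n_dry) | n_dry < 1, NA_real_,
    dry / n_dry)
  area_leaf <- ifelse(is.na(area_total) | is.na(n) | n < 1, NA_real_,
    area_total / n)

  th <- cbind(col("thickness_1_mm"), col("thickness_2_mm"),
    col("thickness_3_mm"))
  thickness <- rowMeans(th, na.rm = TRUE)
  thickness[!is.finite(thickness)] <- NA_real_

  sla <- ifelse(is.na(area_leaf) | is.na(dry_leaf) | dry_leaf <= 0,
    NA_real_, area_leaf / dry_leaf)
  ldmc <- ifelse(is.na(dry_leaf) | is.na(wet_leaf) | wet_leaf <= 0,
    NA_real_, dry_leaf / wet_leaf)

  height <- col("plant_height_cm")
  cp <- col("c_percent"); np <- col("n_percent"); pp <- col("p_percent")
  ratios <- derive_chemical_ratios(cp, np, pp)
  d13 <- col("dc13_permil"); d15 <- col("dn15_permil")

  # one long block per trait; morphological traits always present (flagged
  # when an input was missing), chemistry only where measured
  mk <- function(trait, value, missing_flag = NULL, keep = NULL) {
    if (is.null(keep)) keep <- rep(TRUE, n_rows)
    flag <- rep("", n_rows)
    if (!is.null(missing_flag)) flag[is.na(value)] <- missing_flag
    tibble::tibble(
      .idx = which(keep), ID = s$ID[keep], species = species[keep],
      trait = trait, value = value[keep], flag = flag[keep],
      problem = "", comment = ""
    )
  }
  out <- dplyr::bind_rows(
    mk("plant_height", height, "missing plant_height"),
    mk("wet_mass_g", wet_leaf, "missing wet_mass"),
    mk("dry_mass_g", dry_leaf, "missing dry_mass"),
    mk("leaf_area_cm2", area_leaf, "missing leaf_area"),
    mk("leaf_thickness_mm", thickness, "missing leaf_thickness"),
    mk("SLA_cm2_g", sla, "missing SLA input"),
    mk("LDMC_g_g", ldmc, "missing LDMC input"),
    mk("C_percent", cp, keep = !is.na(cp)),
    mk("N_percent", np, keep = !is.na(np)),
    mk("P_percent", pp, keep = !is.na(pp)),
    mk("CN_ratio", ratios$cn_ratio, keep = !is.na(ratios$cn_ratio)),
    mk("NP_ratio", ratios$np_ratio, keep = !is.na(ratios$np_ratio)),
    mk("dC13", d13, keep = !is.na(d13)),
    mk("dN15", d15, keep = !is.na(d15))
  )
  out <- dplyr::arrange(out, .data$.idx)
  out$.idx <- NULL
  out
}

#' Elemental ratios from leaf chemistry
#'
#' `CN = C / N` and `NP = N / P`; a ratio is absent when an input is absent
#' or its denominator is zero.
#'
#' @param c_percent,n_percent,p_percent Leaf carbon, nitrogen and
#'   phosphorus content, percent of dry mass. Vectorised.
#' @return A list with numeric vectors `cn_ratio` and `np_ratio`.
#' @export
derive_chemical_ratios <- function(c_percent, n_percent, p_percent) {
  cn <- ifelse(
    is.na(c_percent) | is.na(n_percent) | n_percent == 0,
    NA_real_, c_percent / n_percent
  )
  np <- ifelse(
    is.na(n_percent) | is.na(p_percent) | p_percent == 0,
    NA_real_, n_percent / p_percent
  )
  list(cn_ratio = as.numeric(cn), np_ratio = as.numeric(np))
}

#' Expand pooled chemistry results to the contributing leaves
#'
#' Leaves too small for elemental analysis are pooled; the assay result is
#' then reported for every contributing individual, marked `merged` with
#' the pool membership recorded in `ID_merged` (members joined by
#' underscores). Singleton pools stay unmerged.
#'
#' @param pooled Long tibble of assay results with columns `pool_id`,
#'   `trait`, `value`.
#' @param members Named list mapping each `pool_id` to the character vector
#'   of member leaf IDs.
#' @return A long tibble with one row per member and trait, plus `merged`
#'   and `ID_merged` columns.
#' @export
expand_pooled_chemistry <- function(pooled, members) {
  pooled <- tibble::as_tibble(pooled)
  missing_pools <- setdiff(unique(pooled$pool_id), names(members))
  if (length(missing_pools) > 0) {
    stop("no member list for pool(s): ",
      paste(missing_pools, collapse = ", "), call. = FALSE)
  }
  purrr::pmap_dfr(list(seq_len(nrow(pooled))), function(i) {
    row <- pooled[i, ]
    ids <- members[[row$pool_id]]
    tibble::tibble(
      ID = ids,
      trait = row$trait,
      value = row$value,
      merged = length(ids) > 1,
      ID_merged = if (length(ids) > 1) paste(ids, collapse = "_") else
        NA_character_
    )
  })
}

#' Trait validation thresholds
#'
#' Published plausibility limits: leaf dry matter content cannot exceed
#' 1 g g^-1; specific leaf area below 5 or above 500 cm^2 g^-1 is outside
#' the plausible vascular-plant range; leaf nitrogen above 6.4 percent
#' exceeds the highest value reported for these genera in a global trait
#' database (the cutoff is accepted as a configuration value, not
#' recomputed). All comparisons are strict, so boundary-equal values are
#' retained.
#'
#' @param ldmc_max,sla_min,sla_max,n_max The thresholds.
#' @return A list of thresholds.
#' @export
trait_thresholds <- function(ldmc_max = 1, sla_min = 5, sla_max = 500,
                             n_max = 6.4) {
  list(ldmc_max = ldmc_max, sla_min = sla_min, sla_max = sla_max,
    n_max = n_max)
}

#' Validate derived trait records and build the clean view
#'
#' Flags individual trait values outside the plausibility thresholds
#' (value-level removal: only the offending trait row is excluded, not the
#' whole leaf), drops duplicated `(ID, trait)` rows keeping the first, and
#' returns both the fully annotated raw view and the clean view.
#'
#' @param records A long trait tibble from [derive_traits()].
#' @param thresholds A [trait_thresholds()] list.
#' @return A list with elements `raw` (all rows, flags filled, plus logical
#'   columns `removed` and `duplicate`) and `clean` (flagged-removed and
#'   duplicate rows excluded).
#' @export
validate_traits <- function(records, thresholds = trait_thresholds()) {
  records <- tibble::as_tibble(records)
  if (!"flag" %in% names(records)) records$flag <- ""
  records$flag[is.na(records$flag)] <- ""
  th <- thresholds

  bad <- rep(FALSE, nrow(records))
  label <- rep(NA_character_, nrow(records))
  v <- records$value
  sel <- records$trait == "LDMC_g_g" & !is.na(v) & v > th$ldmc_max
  bad[sel] <- TRUE; label[sel] <- "unreliable LDMC"
  sel <- records$trait == "SLA_cm2_g" & !is.na(v) &
    (v < th$sla_min | v > th$sla_max)
  bad[sel] <- TRUE; label[sel] <- "unreliable SLA"
  sel <- records$trait == "N_percent" & !is.na(v) & v > th$n_max
  bad[sel] <- TRUE; label[sel] <- "unreliable N"

  records$flag[bad] <- ifelse(
    records$flag[bad] == "", label[bad],
    paste(records$flag[bad], label[bad], sep = "; ")
  )
  records$removed <- bad
  records$duplicate <- duplicated(records[, c("ID", "trait")])

  clean <- records[!records$removed & !records$duplicate, ]
  clean <- clean[, setdiff(names(clean), c("removed", "duplicate"))]
  list(raw = records, clean = clean)
}
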