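#' Thresholds of the flux quality-control decision tree
#'
#' Defaults are the published values: a closure must start within
#' 421 +/- 100 ppm of ambient; fits with `b >= 1` (or `b < 0`, both exits of
#' the interval are optimiser artefacts) are bad; an ER closure must not
#' show net uptake; `|r| > 0.5` separates a discarded trend from noise that
#' is zeroed.
#'
#' @param start_center Centre of the acceptable start-concentration band,
#'   ppm.
#' @param start_halfwidth Half width of that band, ppm.
#' @param b_max Upper bound on the equilibration parameter `b` (s^-1);
#'   `b >= b_max` marks a bad fit.
#' @param b_min Lower bound; `b < b_min` marks a bad fit.
#' @param r_cut Threshold on `|pearson_r|` separating `discard` from `zero`.
#' @return A list of thresholds.
#' @export
flux_thresholds <- function(start_center = 421, start_halfwidth = 100,
                            b_max = 1, b_min = 0, r_cut = 0.5) {
  list(
    start_center = start_center,
    start_halfwidth = start_halfwidth,
    b_max = b_max,
    b_min = b_min,
    r_cut = r_cut
  )
}

#' Classify one fitted flux with the QC decision tree
#'
#' Applies, in order: (1) a start-concentration gate (`start_error` when the
#' first retained reading lies outside `start_center +/- start_halfwidth`);
#' (2) a fit-quality gate (`b` outside `[b_min, b_max)`, an ER closure with
#' a negative slope, or a non-converged optimiser); a bad fit is discarded
#' when time and concentration are correlated (`|r| > r_cut`) and replaced
#' by zero when the variation is mostly noise (`|r| <= r_cut`); (3)
#' otherwise the flux is `okflux` and the slope is converted to
#' mmol m^-2 h^-1 with [flux_from_slope()] at the mean chamber air
#' temperature of the retained window.
#'
#' @param fit An [fit_exponential()] result for the trimmed series.
#' @param series The trimmed [concentration_series()] the fit was made on.
#' @param chamber A [chamber_spec()].
#' @param thresholds A [flux_thresholds()] list.
#' @return A list with `flag` (one of `okflux`, `start_error`, `discard`,
#'   `zero`) and `flux_value` (mmol m^-2 h^-1; `NA` for `start_error` and
#'   `discard`, exactly 0 for `zero`).
#' @export
classify_flux <- function(fit, series, chamber = chamber_spec(),
                          thresholds = flux_thresholds()) {
  stopifnot(inherits(fit, "exponential_fit"),
    inherits(series, "concentration_series"))
  th <- thresholds

  if (abs(series$start_conc - th$start_center) > th$start_halfwidth) {
    return(list(flag = "start_error", flux_value = NA_real_))
  }

  bad_fit <- fit$b >= th$b_max || fit$b < th$b_min ||
    (series$kind == "ER" && fit$slope_at_tz < 0) ||
    !isTRUE(fit$converged)

  if (bad_fit) {
    if (abs(fit$pearson_r) > th$r_cut) {
      return(list(flag = "discard", flux_value = NA_real_))
    }
    return(list(flag = "zero", flux_value = 0))
  }

  temp_k <- mean_airtemp_k(series)
  list(
    flag = "okflux",
    flux_value = flux_from_slope(fit$slope_at_tz, chamber, temp_k)
  )
}

mean_airtemp_k <- function(series) {
  if (is.null(series$airtemp_c)) {
    stop("series has no air temperature; flux conversion needs one",
      call. = FALSE)
  }
  mean(series$airtemp_c) + 273.15
}

# Flags whose flux value is absent by definition.
ABSENT_FLAGS <- c("start_error", "discard", "weird_flux", "missing_round")

#' Override flags for visually rejected fluxes
#'
#' Marks analyst-identified measurements whose concentration changes have no
#' reasonable natural explanation. The override applies to any flag except
#' `missing_round` and blanks the flux value.
#'
#' @param records A flux record table (see [process_campaign()]).
#' @param flux_ids `fluxID` values to mark.
#' @return The records with the selected rows flagged `weird_flux`.
#' @export
mark_weird <- function(records, flux_ids) {
  if (length(flux_ids) == 0) return(records)
  unknown <- setdiff(flux_ids, records$fluxID)
  if (length(unknown) > 0) {
    warning("unknown fluxID(s), not changed: ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- records$fluxID %in% flux_ids & records$flag != "missing_round"
  records$flag[hit] <- "weird_flux"
  records$flux_value[hit] <- NA_real_
  records
}

#' Gross primary production from a paired NEE and ER measurement
#'
#' `GPP = NEE - ER`; GPP is negative when the ecosystem removes CO2 from
#' the atmosphere. Flag propagation: both members `okflux` gives `okflux`;
#' a zeroed NEE or ER contributes a 0 and flags the GPP `zeroNEE` /
#' `zeroER`; a member with an absent value (start_error, discard,
#' weird_flux, missing_round) makes the GPP absent and carries the blocking
#' member's flag.
#'
#' @param nee,er Single flux records (one-row data frames or lists) with
#'   fields `flux_value`, `flag`, `turfID` and `round`.
#' @return A list with `flux_value` and `flag` for the GPP record.
#' @export
compute_gpp <- function(nee, er) {
  if (!identical(nee$turfID, er$turfID) || !identical(nee$round, er$round)) {
    stop("NEE and ER records are not paired (turfID/round mismatch)",
      call. = FALSE)
  }
  if (nee$flag %in% ABSENT_FLAGS) {
    return(list(flux_value = NA_real_, flag = nee$flag))
  }
  if (er$flag %in% ABSENT_FLAGS) {
    return(list(flux_value = NA_real_, flag = er$flag))
  }
  value <- nee$flux_value - er$flux_value
  flag <- if (nee$flag == "zero" && er$flag == "zero") {
    "zero"
  } else if (nee$flag == "zero") {
    "zeroNEE"
  } else if (er$flag == "zero") {
    "zeroER"
  } else {
    "okflux"
  }
  list(flux_value = value, flag = flag)
}

# Vectorised GPP computation over a record table: pairs NEE and ER rows by
# (turfID, round) and appends one GPP row per pair.
add_gpp_records <- function(records) {
  nee <- dplyr::filter(records, .data$type == "NEE")
  er <- dplyr::filter(records, .data$type == "ER")
  pairs <- dplyr::inner_join(
    nee, er,
    by = c("turfID", "round"),
    suffix = c("_nee", "_er")
  )
  if (nrow(pairs) + nrow(dplyr::anti_join(nee, er, by = c("turfID", "round"))) !=
      nrow(nee)) {
    stop("ambiguous NEE/ER pairing: duplicate (turfID, round) slots",
      call. = FALSE)
  }
  gpp <- purrr::pmap_dfr(
    list(seq_len(nrow(pairs))),
    function(i) {
      p <- pairs[i, ]
      res <- compute_gpp(
        list(flux_value = p$flux_value_nee, flag = p$flag_nee,
          turfID = p$turfID, round = p$round),
        list(flux_value = p$flux_value_er, flag = p$flag_er,
          turfID = p$turfID, round = p$round)
      )
      tibble::tibble(
        datetime = p$datetime_nee,
        origSiteID = p$origSiteID_nee,
        destSiteID = p$destSiteID_nee,
        turfID = p$turfID,
        warming = p$warming_nee,
        type = "GPP",
        round = p$round,
        fluxID = paste0(p$fluxID_nee, "-", p$fluxID_er),
        flux_value = res$flux_value,
        PARavg = p$PARavg_nee,
        temp_soil = p$temp_soil_nee,
        temp_airavg = p$temp_airavg_nee,
        flag = res$flag
      )
    }
  )
  dplyr::bind_rows(records, gpp)
}

#' Diurnal baseline correction of GPP
#'
#' CO2 accumulated in the vegetation layer before a transparent-chamber
#' measurement biases night-time GPP positive. Within each site x 24 h
#' measurement cycle, the correction shifts all valued GPP records so that
#' the most positive GPP equals zero; NEE and ER are untouched. The applied
#' offset is stored in a `gpp_offset` column for provenance. Groups without
#' a valued GPP are skipped with a warning.
#'
#' @param records A flux record table containing GPP rows.
#' @return The records with corrected GPP values and a `gpp_offset` column.
#' @export
night_correct_gpp <- function(records) {
  records$gpp_offset <- NA_real_
  is_gpp <- records$type == "GPP"
  cycles <- gpp_cycle_id(records)
  for (g in unique(cycles[is_gpp])) {
    sel <- is_gpp & cycles == g
    vals <- records$flux_value[sel]
    if (all(is.na(vals))) {
      warning("no valued GPP in group ", g, "; skipped", call. = FALSE)
      next
    }
    offset <- max(vals, na.rm = TRUE)
    records$flux_value[sel] <- records$flux_value[sel] - offset
    records$gpp_offset[sel] <- offset
  }
  records
}

# Site x 24 h cycle grouping, anchored at each site's first measurement
# (campaigns start mid-day, so calendar midnight would split a cycle).
gpp_cycle_id <- function(records) {
  dt <- as.numeric(as.POSIXct(records$datetime, tz = "UTC"))
  site <- records$destSiteID
  start <- tapply(dt, site, min)[site]
  cycle <- floor((dt - start) / 86400)
  paste0(site, "#", cycle)
}

#' Insert placeholders for measurement rounds missed in the field
#'
#' Compares the record table against the campaign schedule (one expected
#' NEE and ER measurement per plot and round, plus the derived GPP slot)
#' and appends one `missing_round` placeholder per absent slot.
#'
#' @param records A flux record table.
#' @param schedule A data frame of expected slots with columns `turfID`,
#'   `round`, `type` and the plot metadata columns.
#' @return The records with placeholder rows appended.
#' @export
detect_missing_rounds <- function(records, schedule) {
  missing <- dplyr::anti_join(schedule, records,
    by = c("turfID", "round", "type"))
  if (nrow(missing) == 0) return(records)
  missing$flux_value <- NA_real_
  missing$flag <- "missing_round"
  missing$fluxID <- NA_character_
  dplyr::bind_rows(records, missing)
}

#' Run the whole flux pipeline on a simulated or assembled campaign
#'
#' For every closure: trim, estimate `Cz`, fit the exponential model,
#' classify with the QC decision tree; then pair NEE with ER into GPP,
#' insert `missing_round` placeholders from the campaign schedule and
#' (optionally) apply the diurnal GPP baseline correction.
#'
#' @param campaign A campaign table from [generate_diurnal_campaign()] (or
#'   the same shape assembled from field files): one row per closure with a
#'   `series` list column.
#' @param chamber A [chamber_spec()].
#' @param thresholds A [flux_thresholds()] list.
#' @param night_correction Apply [night_correct_gpp()]? Disabling it leaves
#'   `GPP = NEE - ER` untouched for users who prefer uncorrected data.
#' @param trim_head_s,trim_tail_s Seconds trimmed from each closure.
#' @return A tibble of flux records with the output schema columns
#'   (`datetime`, `time`, `origSiteID`, `destSiteID`, `turfID`, `warming`,
#'   `type`, `fluxID`, `flux_value`, `PARavg`, `temp_soil`, `temp_airavg`,
#'   `flag`) plus `round` and `gpp_offset`.
#' @export
process_campaign <- function(campaign, chamber = chamber_spec(),
                             thresholds = flux_thresholds(),
                             night_correction = TRUE,
                             trim_head_s = 10, trim_tail_s = 10) {
  records <- purrr::pmap_dfr(
    list(seq_len(nrow(campaign))),
    function(i) {
      row <- campaign[i, ]
      series <- row$series[[1]]
      trimmed <- trim_series(series, trim_head_s, trim_tail_s)
      fit <- fit_exponential(trimmed)
      cls <- classify_flux(fit, trimmed, chamber, thresholds)
      tibble::tibble(
        datetime = row$datetime,
        origSiteID = row$origSiteID,
        destSiteID = row$destSiteID,
        turfID = row$turfID,
        warming = row$warming,
        type = row$type,
        round = row$round,
        fluxID = row$fluxID,
        flux_value = cls$flux_value,
        PARavg = row$PARavg,
        temp_soil = row$temp_soil,
        temp_airavg = row$temp_airavg,
        flag = cls$flag
      )
    }
  )
  records <- add_gpp_records(records)
  schedule <- attr(campaign, "schedule")
  if (!is.null(schedule)) {
    records <- detect_missing_rounds(records, schedule)
  }
  if (night_correction) {
    records <- night_correct_gpp(records)
  }
  records$time <- format(as.POSIXct(records$datetime, tz = "UTC"), "%H:%M:%S")
  dplyr::relocate(
    records,
    "datetime", "time", "origSiteID", "destSiteID", "turfID", "warming",
    "type", "fluxID", "flux_value", "PARavg", "temp_soil", "temp_airavg",
    "flag"
  )
}

#' Count records per QC flag
#'
#' @param records A flux record table.
#' @return A tibble of flag counts; the counts partition the record rows.
#' @export
flag_report <- function(records) {
  dplyr::count(records, .data$flag, name = "n")
}
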