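#' Plausibility ranges for microclimate variables
#'
#' Published limits for near-surface logger data in these grasslands: air
#' temperature (15 cm) within [-40, 30] degrees C, ground temperature
#' (0 cm) within [-40, 35], soil temperature (-8 cm) within [5, 20] during
#' the growing season, and volumetric soil moisture not below 0 percent.
#' Values strictly beyond a limit are flagged; boundary-equal values are
#' retained.
#'
#' @return Named list of `c(min, max)` ranges keyed by climate variable.
#' @export
microclimate_ranges <- function() {
  list(
    air_temperature = c(-40, 30),
    ground_temperature = c(-40, 35),
    soil_temperature = c(5, 20),
    soil_moisture = c(0, Inf)
  )
}

# Short variable tokens used in flag names (cut_Tmax_air, ...).
MC_SHORT <- c(
  air_temperature = "air",
  ground_temperature = "ground",
  soil_temperature = "soil"
)

#' Trim logger series to their deployment window
#'
#' Keeps rows with `datetime_in <= datetime <= datetime_out` (closed
#' interval); readings logged before installation or after removal are
#' dropped.
#'
#' @param records A microclimate tibble with columns `datetime`,
#'   `datetime_in`, `datetime_out`.
#' @return The trimmed records; warns if nothing remains.
#' @export
trim_to_deployment <- function(records) {
  keep <- records$datetime >= records$datetime_in &
    records$datetime <= records$datetime_out
  out <- records[keep, ]
  if (nrow(out) == 0) {
    warning("no readings inside the deployment window", call. = FALSE)
  }
  out
}

#' Apply plausibility thresholds to microclimate readings
#'
#' Flags readings strictly outside their variable's range
#' (`cut_Tmin_<var>` / `cut_Tmax_<var>` for temperatures,
#' `cut_min_moist` for negative soil moisture). Flagged values are nulled
#' in the clean view but kept, with their flag, in the raw view. The
#' filter is idempotent: reapplying it to either view changes nothing.
#'
#' @param records A microclimate tibble with columns `climate_variable`
#'   and `value`.
#' @param ranges A [microclimate_ranges()] list.
#' @return A list with `raw` (values kept, `flag` column filled) and
#'   `clean` (flagged values set to `NA`).
#' @export
apply_microclimate_thresholds <- function(records,
                                          ranges = microclimate_ranges()) {
  records <- tibble::as_tibble(records)
  if (!"flag" %in% names(records)) records$flag <- NA_character_
  v <- records$value
  var <- records$climate_variable

  flag <- records$flag
  for (nm in names(ranges)) {
    sel <- var == nm & !is.na(v)
    lo <- ranges[[nm]][1]
    hi <- ranges[[nm]][2]
    if (nm == "soil_moisture") {
      flag[sel & v < lo] <- "cut_min_moist"
    } else {
      short <- MC_SHORT[[nm]]
      flag[sel & v < lo] <- paste0("cut_Tmin_", short)
      flag[sel & v > hi] <- paste0("cut_Tmax_", short)
    }
  }
  raw <- records
  raw$flag <- flag
  clean <- raw
  clean$value[!is.na(clean$flag)] <- NA_real_
  list(raw = raw, clean = clean)
}

#' Calibrate raw soil-moisture counts to volumetric content
#'
#' Applies a soil-specific polynomial calibration to the logger's raw
#' moisture signal. Coefficients are supplied by the user for the
#' configured soil class (they are derived externally per soil type and
#' accepted here as opaque configuration).
#'
#' @param raw_counts Raw sensor counts.
#' @param coefficients Numeric vector of polynomial coefficients in
#'   increasing power order (`c(intercept, linear, quadratic, ...)`);
#'   `c(0, 1)` is the identity pass-through.
#' @return Volumetric soil moisture, percent
#'   ((m^3 water / m^3 soil) x 100).
#' @export
calibrate_moisture <- function(raw_counts, coefficients) {
  if (missing(coefficients) || is.null(coefficients) ||
      length(coefficients) == 0 || !is.numeric(coefficients)) {
    stop("moisture calibration `coefficients` are required", call. = FALSE)
  }
  out <- rep(0, length(raw_counts))
  for (i in seq_along(coefficients)) {
    out <- out + coefficients[i] * raw_counts^(i - 1)
  }
  out
}

#' Generate a synthetic microclimate logger table
#'
#' Emulates a 15-minute four-sensor logger record (air, ground and soil
#' temperature plus soil moisture) per plot: smooth diurnal cycles with
#' small reading noise, all inside the plausibility ranges, with
#' out-of-range values injected at the requested per-variable rates, each
#' designed to trip exactly one flag.
#'
#' @param n_loggers Number of loggers (one per plot).
#' @param window POSIXct pair: deployment `datetime_in` and
#'   `datetime_out`.
#' @param violation_rates Named probabilities for `air_high`,
#'   `ground_high`, `soil_high`, `soil_low`, `moisture_low`.
#' @param pad_intervals Number of extra 15-min readings emitted before and
#'   after the deployment window (dropped by [trim_to_deployment()]).
#' @param seed Integer RNG seed.
#' @return A tibble with one row per logger, timestamp and climate
#'   variable, including `datetime_in`/`datetime_out` and the ground-truth
#'   `intended_flag` column (`NA` when in range).
#' @export
generate_microclimate <- function(n_loggers = 2,
                                  window = as.POSIXct(
                                    c("2022-07-24 00:00:00",
                                      "2022-07-26 00:00:00"), tz = "UTC"),
                                  violation_rates = c(air_high = 0,
                                    ground_high = 0, soil_high = 0,
                                    soil_low = 0, moisture_low = 0),
                                  pad_intervals = 0, seed = 1L) {
  rates <- c(air_high = 0, ground_high = 0, soil_high = 0, soil_low = 0,
    moisture_low = 0)
  rates[names(violation_rates)] <- violation_rates
  check_field(all(rates >= 0 & rates <= 1), "violation_rates",
    "must be probabilities")

  times <- seq(window[1] - pad_intervals * 900,
    window[2] + pad_intervals * 900, by = 900)
  hours <- as.numeric(format(times, "%H")) +
    as.numeric(format(times, "%M")) / 60

  with_seed(seed, {
    out <- list()
    for (lg in seq_len(n_loggers)) {
      loggerID <- sprintf("9420%04d", lg)
      base <- list(
        air_temperature = 12 + 7 * sin(pi * (hours - 7) / 12) +
          rnorm(length(times), 0, 0.4),
        ground_temperature = 11 + 5 * sin(pi * (hours - 8) / 12) +
          rnorm(length(times), 0, 0.3),
        soil_temperature = 10 + 1.8 * sin(pi * (hours - 10) / 12) +
          rnorm(length(times), 0, 0.2),
        soil_moisture = 28 + 4 * sin(pi * hours / 24) +
          rnorm(length(times), 0, 0.5)
      )
      for (var in names(base)) {
        value <- base[[var]]
        intended <- rep(NA_character_, length(value))
        inject <- function(rate, range, flag) {
          hit <- runif(length(value)) < rate
          value[hit] <<- runif(sum(hit), range[1], range[2])
          intended[hit] <<- flag
        }
        if (var == "air_temperature") {
          inject(rates[["air_high"]], c(30.5, 36), "cut_Tmax_air")
        } else if (var == "ground_temperature") {
          inject(rates[["ground_high"]], c(35.5, 40), "cut_Tmax_ground")
        } else if (var == "soil_temperature") {
          inject(rates[["soil_high"]], c(20.5, 24), "cut_Tmax_soil")
          inject(rates[["soil_low"]], c(0.5, 4.9), "cut_Tmin_soil")
        } else {
          inject(rates[["moisture_low"]], c(-5, -0.1), "cut_min_moist")
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          loggerID = loggerID,
          datetime = times,
          turfID = sprintf("plot-%d", lg),
          origSiteID = "site_1",
          destSiteID = "site_1",
          warming = ifelse(lg %% 2 == 0, "W", "A"),
          climate_variable = var,
          value = value,
          datetime_in = window[1],
          datetime_out = window[2],
          intended_flag = intended
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
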