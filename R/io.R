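#' @name flux_io
#' @title Readers and writers for the campaign CSV schemas
#'
#' @description
#' All interchange is plain UTF-8 CSV with a decimal point and ISO-8601
#' datetimes. `write_flux_table()` / `read_flux_table()` handle the flux
#' record schema (columns `datetime`, `time`, `origSiteID`, `destSiteID`,
#' `turfID`, `warming`, `type`, `fluxID`, `flux_value`, `PARavg`,
#' `temp_soil`, `temp_airavg`, `flag`); the trait, AT-curve and
#' microclimate writers mirror their module's long-format schemas. Readers
#' validate the header and fail naming any missing column.
NULL

FLUX_TABLE_COLUMNS <- c(
  "datetime", "time", "origSiteID", "destSiteID", "turfID", "warming",
  "type", "fluxID", "flux_value", "PARavg", "temp_soil", "temp_airavg",
  "flag"
)

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @rdname flux_io
#' @param records A flux record table (see [process_campaign()]).
#' @param path File path.
#' @export
write_flux_table <- function(records, path) {
  check_columns(records, FLUX_TABLE_COLUMNS, path)
  out <- records[, FLUX_TABLE_COLUMNS]
  out$datetime <- format(as.POSIXct(out$datetime, tz = "UTC"),
    "%Y-%m-%d %H:%M:%S")
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname flux_io
#' @export
read_flux_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, FLUX_TABLE_COLUMNS, path)
  df$datetime <- as.POSIXct(df$datetime, tz = "UTC")
  tibble::as_tibble(df)
}

#' @rdname flux_io
#' @param series_list A list of [concentration_series()] objects.
#' @export
write_flux_series_csv <- function(series_list, path) {
  rows <- purrr::map_dfr(series_list, function(s) {
    tibble::tibble(
      fluxID = s$fluxID,
      seconds = s$t,
      conc_ppm = s$conc,
      temp_air = if (is.null(s$airtemp_c)) NA_real_ else
        rep_len(s$airtemp_c, length(s$t)),
      temp_soil = if (is.null(s$temp_soil_c)) NA_real_ else
        rep_len(s$temp_soil_c, length(s$t)),
      par = if (is.null(s$par)) NA_real_ else rep_len(s$par, length(s$t)),
      kind = s$kind
    )
  })
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname flux_io
#' @export
read_flux_series_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, c("fluxID", "seconds", "conc_ppm"), path)
  split_df <- split(df, df$fluxID)
  purrr::map(split_df, function(d) {
    d <- d[order(d$seconds), ]
    concentration_series(
      t = d$seconds, conc = d$conc_ppm,
      kind = if ("kind" %in% names(d)) d$kind[1] else "NEE",
      fluxID = d$fluxID[1],
      airtemp_c = if ("temp_air" %in% names(d)) d$temp_air else NULL,
      par = if ("par" %in% names(d)) d$par else NULL
    )
  })
}

TRAIT_TABLE_COLUMNS <- c("ID", "species", "trait", "value", "flag",
  "problem", "comment")

#' @rdname flux_io
#' @param traits A long trait table from [derive_traits()] /
#'   [validate_traits()].
#' @export
write_trait_table <- function(traits, path) {
  check_columns(traits, TRAIT_TABLE_COLUMNS, path)
  write.csv(traits, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname flux_io
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, TRAIT_TABLE_COLUMNS, path)
  df$flag[is.na(df$flag)] <- ""
  df$problem[is.na(df$problem)] <- ""
  df$comment[is.na(df$comment)] <- ""
  tibble::as_tibble(df)
}

#' @rdname flux_io
#' @param curves A list of [at_curve()] objects.
#' @export
write_at_curves_csv <- function(curves, path) {
  rows <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(
      curveID = cv$curveID,
      leaf_temp_C = cv$leaf_temp_c,
      assim_umol_m2_s = cv$assim
    )
  })
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname flux_io
#' @export
read_at_curves_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, c("curveID", "leaf_temp_C", "assim_umol_m2_s"), path)
  purrr::map(split(df, df$curveID), function(d) {
    at_curve(d$curveID[1], d$leaf_temp_C, d$assim_umol_m2_s)
  })
}

MICROCLIMATE_COLUMNS <- c("datetime", "loggerID", "turfID", "origSiteID",
  "destSiteID", "warming", "datetime_in", "datetime_out",
  "climate_variable", "value")

#' @rdname flux_io
#' @param microclimate A microclimate record table.
#' @export
write_microclimate_csv <- function(microclimate, path) {
  check_columns(microclimate, MICROCLIMATE_COLUMNS, path)
  out <- microclimate[, c(MICROCLIMATE_COLUMNS,
    intersect("flag", names(microclimate)))]
  for (col in c("datetime", "datetime_in", "datetime_out")) {
    out[[col]] <- format(as.POSIXct(out[[col]], tz = "UTC"),
      "%Y-%m-%d %H:%M:%S")
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname flux_io
#' @export
read_microclimate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, MICROCLIMATE_COLUMNS, path)
  for (col in c("datetime", "datetime_in", "datetime_out")) {
    df[[col]] <- as.POSIXct(df[[col]], tz = "UTC")
  }
  tibble::as_tibble(df)
}

#' File name for a clean exported dataset
#'
#' Follows the campaign's published naming pattern
#' `<nr>_<campaign>_clean_<experiment>_<variable>_<years>.csv`.
#'
#' @param nr Dataset number (roman numeral string).
#' @param experiment Experiment label.
#' @param variable Response variable label.
#' @param years Year or year range string.
#' @param campaign Campaign token.
#' @return The file name.
#' @examples
#' clean_data_filename("v", "global_change", "co2_fluxes", "2022")
#' @export
clean_data_filename <- function(nr, experiment, variable, years,
                                campaign = "campaign") {
  sprintf("%s_%s_clean_%s_%s_%s.csv", nr, campaign, experiment, variable,
    years)
}
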