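#' Default pipeline configuration
#'
#' One auditable list of every constant the pipeline uses: chamber
#' geometry, flux QC thresholds, trait validation thresholds, microclimate
#' plausibility ranges, the folded-graminoid species list, the soil
#' moisture calibration, and processing switches. The defaults are the
#' published values used throughout the documentation of the individual
#' modules.
#'
#' @return A nested named list (class `fluxtraits_config`).
#' @export
default_config <- function() {
  structure(
    list(
      chamber = list(pressure_atm = 1, volume_l = 25, area_m2 = 0.0625),
      flux_qc = list(
        start_center = 421, start_halfwidth = 100,
        b_max = 1, b_min = 0, r_cut = 0.5,
        trim_head_s = 10, trim_tail_s = 10, cz_window_s = 15
      ),
      traits = list(
        ldmc_max = 1, sla_min = 5, sla_max = 500, n_max = 6.4,
        folded_species = folded_graminoids()
      ),
      microclimate = list(
        air_temperature = c(-40, 30),
        ground_temperature = c(-40, 35),
        soil_temperature = c(5, 20),
        soil_moisture_min = 0,
        moisture_soil_class = "silt_loam",
        moisture_coefficients = c(0, 1)
      ),
      processing = list(night_correction = TRUE, seed = 1L)
    ),
    class = "fluxtraits_config"
  )
}

CONFIG_REQUIRED <- c("chamber", "flux_qc", "traits", "microclimate",
  "processing")

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with the structure of
#'   [default_config()].
#' @return The configuration list; missing top-level sections raise an
#'   error naming the key.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(CONFIG_REQUIRED, names(cfg))
  if (length(missing) > 0) {
    stop("config is missing key(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  structure(cfg, class = "fluxtraits_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
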