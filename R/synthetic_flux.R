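#' Scenario for one synthetic chamber closure
#'
#' Describes the ground truth of a simulated closed-chamber measurement:
#' the exponential model parameters, the noise level and an optional
#' injected failure mode. With `failure_mode = "none"` and `noise_sd = 0`
#' the emitted series satisfies the model exactly at every timestamp.
#'
#' Failure modes and the QC flag each is designed to trigger:
#' \describe{
#'   \item{`none`}{well-behaved closure; `okflux`.}
#'   \item{`high_start` / `low_start`}{the first retained reading is moved
#'     to `start_conc`, outside the acceptable band; `start_error`.}
#'   \item{`nonmonotone_noise`}{a fast transient followed by a trendless
#'     signal whose best exponential fit has `b >= 1` and a weak
#'     time-concentration correlation; `zero`.}
#'   \item{`negative_er_slope`}{a steadily declining ER closure (apparent
#'     uptake) with a strong correlation; `discard`.}
#' }
#'
#' @param true_cm Equilibrium concentration `Cm`, ppm.
#' @param true_a Linear drift `a`, ppm s^-1.
#' @param true_b Equilibration rate `b`, s^-1.
#' @param true_tz Crossing time `tz`, s; the model satisfies
#'   `C(tz) = Cz`. The default sits at the start of the retained window
#'   under the standard 10 s head trim.
#' @param true_cz Starting concentration `Cz`, ppm.
#' @param noise_sd Additive i.i.d. Gaussian noise on concentration, ppm.
#' @param duration Closure length, s.
#' @param sampling_rate Readings per second, Hz.
#' @param start_conc Target first retained reading for the start-error
#'   modes, ppm.
#' @param failure_mode One of the modes above.
#' @param kind `"NEE"` or `"ER"`.
#' @param seed Integer RNG seed; generation is a pure function of
#'   (scenario, seed).
#' @return An object of class `flux_scenario`.
#' @export
flux_scenario <- function(true_cm = 450, true_a = 0.02, true_b = 0.05,
                          true_tz = 10, true_cz = 400, noise_sd = 1,
                          duration = 180, sampling_rate = 1,
                          start_conc = NA_real_,
                          failure_mode = c("none", "high_start", "low_start",
                            "nonmonotone_noise", "negative_er_slope"),
                          kind = c("NEE", "ER"), seed = 1L) {
  failure_mode <- match.arg(failure_mode)
  kind <- match.arg(kind)
  check_field(is.numeric(duration) && duration > 0, "duration",
    "must be > 0")
  check_field(is.numeric(sampling_rate) && sampling_rate > 0,
    "sampling_rate", "must be > 0")
  check_field(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd",
    "must be >= 0")
  check_field(is.numeric(true_b) && true_b > 0, "true_b", "must be > 0")
  if (failure_mode %in% c("high_start", "low_start") && is.na(start_conc)) {
    start_conc <- if (failure_mode == "high_start") 560 else 280
  }
  structure(
    list(
      true_cm = true_cm, true_a = true_a, true_b = true_b,
      true_tz = true_tz, true_cz = true_cz, noise_sd = noise_sd,
      duration = duration, sampling_rate = sampling_rate,
      start_conc = start_conc, failure_mode = failure_mode,
      kind = kind, seed = as.integer(seed)
    ),
    class = "flux_scenario"
  )
}

intended_flux_flag <- function(failure_mode) {
  switch(failure_mode,
    none = "okflux",
    high_start = "start_error",
    low_start = "start_error",
    nonmonotone_noise = "zero",
    negative_er_slope = "discard"
  )
}

#' Generate one synthetic chamber closure
#'
#' Evaluates the exponential concentration model on the scenario's time
#' grid, injects the requested failure mode, adds Gaussian noise and
#' attaches the ground truth (generating parameters, true slope at `tz`
#' and the intended QC flag) to the series metadata.
#'
#' @param scenario A [flux_scenario()].
#' @param fluxID Identifier for the emitted series.
#' @param airtemp_c Chamber air temperature recorded with the closure,
#'   degrees C.
#' @param metadata Extra metadata merged into the series.
#' @return A [concentration_series()] whose `metadata$truth` records the
#'   ground truth.
#' @export
generate_flux_series <- function(scenario, fluxID = "sim-1",
                                 airtemp_c = 15, metadata = list()) {
  stopifnot(inherits(scenario, "flux_scenario"))
  sc <- scenario
  n <- round(sc$duration * sc$sampling_rate)
  t <- seq(0, by = 1 / sc$sampling_rate, length.out = n)

  pars <- effective_params(sc)
  conc <- exp_model(t, pars$cm, pars$a, pars$b, pars$tz, pars$cz)
  conc <- conc + pars$offset

  if (sc$noise_sd > 0) {
    conc <- with_seed(sc$seed, conc + rnorm(n, 0, sc$noise_sd))
  }

  truth <- c(pars, list(
    true_slope = pars$a + pars$b * (pars$cm - pars$cz),
    intended_flag = intended_flux_flag(sc$failure_mode),
    failure_mode = sc$failure_mode,
    noise_sd = sc$noise_sd
  ))
  concentration_series(
    t = t, conc = conc, kind = sc$kind, fluxID = fluxID,
    airtemp_c = airtemp_c,
    metadata = c(metadata, list(truth = truth))
  )
}

# Resolve the curve actually drawn for a scenario. Start-error modes shift
# the whole curve so the reading at the start of the standard retained
# window (t = 10 s) equals `start_conc`; the slope is unchanged.
effective_params <- function(sc) {
  cm <- sc$true_cm; a <- sc$true_a; b <- sc$true_b
  tz <- sc$true_tz; cz <- sc$true_cz
  offset <- 0
  if (sc$failure_mode %in% c("high_start", "low_start")) {
    offset <- sc$start_conc - exp_model(10, cm, a, b, tz, cz)
  } else if (sc$failure_mode == "nonmonotone_noise") {
    # Artefact regime: b far above 1, no drift; after the transient the
    # signal carries no trend, so the bad fit resolves to `zero`.
    a <- 0
    b <- 2.5
    cm <- cz - 30
  } else if (sc$failure_mode == "negative_er_slope") {
    # Mirror the nominal slope magnitude downwards (apparent uptake).
    s_nom <- abs(sc$true_a + sc$true_b * (sc$true_cm - sc$true_cz))
    a <- -abs(sc$true_a)
    cm <- cz + (-s_nom - a) / b
  }
  list(cm = cm, a = a, b = b, tz = tz, cz = cz, offset = offset)
}

#' Draw a battery of realistic flux scenarios
#'
#' Samples well-behaved closure scenarios from the same distribution the
#' campaign generator uses: starting concentration U(400, 440) ppm, drift
#' U(-0.02, 0.02) ppm/s, equilibration rate log-uniform on [0.005, 0.1]
#' s^-1 (time constants of 10-200 s for a fan-mixed 25 L chamber), slope
#' magnitude U(0.1, 2) ppm/s with alternating sign. Used for parameter
#' recovery studies.
#'
#' @param n Number of scenarios.
#' @param noise_sd Concentration noise, ppm.
#' @param seed Integer RNG seed.
#' @return A list of [flux_scenario()] objects.
#' @export
sample_flux_scenarios <- function(n, noise_sd = 0, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cz <- runif(1, 400, 440)
      a <- runif(1, -0.02, 0.02)
      b <- exp(runif(1, log(0.005), log(0.1)))
      slope <- sample(c(-1, 1), 1) * runif(1, 0.1, 2)
      cm <- cz + (slope - a) / b
      flux_scenario(
        true_cm = cm, true_a = a, true_b = b, true_tz = 10, true_cz = cz,
        noise_sd = noise_sd, seed = seed + 104729L * i
      )
    })
  })
}

# Draw one realistic scenario for a campaign slot. Slope sign follows the
# measurement type and light level: transparent-chamber (NEE) closures
# show uptake in daylight; darkened-chamber (ER) closures always respire.
draw_scenario <- function(kind, par, noise_sd, failure_mode, seed) {
  cz <- runif(1, 400, 440)
  a <- runif(1, -0.02, 0.02)
  b <- exp(runif(1, log(0.005), log(0.1)))
  mag <- runif(1, 0.1, 2)
  sign <- if (kind == "ER") 1 else if (par > 50) -1 else 1
  slope <- sign * mag
  cm <- cz + (slope - a) / b
  flux_scenario(
    true_cm = cm, true_a = a, true_b = b, true_tz = 10, true_cz = cz,
    noise_sd = noise_sd, failure_mode = failure_mode, kind = kind,
    seed = seed
  )
}

#' Generate a diurnal flux measurement campaign
#'
#' Simulates hourly paired NEE/ER closures over a 24 h cycle for each plot
#' of each site, mirroring a field protocol in which every plot is measured
#' once per round with a transparent and then a darkened chamber. Paired
#' measurements share their covariates (PAR, air and soil temperature).
#' Failure modes are injected at the requested rates and every closure
#' carries its ground truth.
#'
#' @param n_sites Number of sites.
#' @param plots_per_site Plots per site; warming alternates ambient (`A`)
#'   and warmed (`W`) across plots.
#' @param n_rounds Number of hourly rounds (max 24).
#' @param missing_rounds Integer round indices skipped in the field (no
#'   series emitted; the schedule still expects them).
#' @param failure_rates Named numeric vector of injection probabilities for
#'   `high_start`, `low_start`, `nonmonotone_noise`, `negative_er_slope`
#'   (the remainder is well-behaved).
#' @param noise_sd Concentration noise, ppm.
#' @param start_datetime POSIXct of the first round.
#' @param seed Integer RNG seed.
#' @return A tibble with one row per emitted closure: plot metadata,
#'   `round`, `type`, `datetime`, `fluxID`, shared covariates, a `series`
#'   list column, and ground-truth columns `true_slope` and
#'   `intended_flag`. The full expected slot grid (including missing rounds
#'   and GPP slots) is attached as attribute `"schedule"`.
#' @export
generate_diurnal_campaign <- function(n_sites = 1, plots_per_site = 3,
                                      n_rounds = 24,
                                      missing_rounds = integer(),
                                      failure_rates = c(high_start = 0,
                                        low_start = 0,
                                        nonmonotone_noise = 0,
                                        negative_er_slope = 0),
                                      noise_sd = 1,
                                      start_datetime = as.POSIXct(
                                        "2022-07-24 12:00:00", tz = "UTC"),
                                      seed = 1L) {
  check_field(n_rounds <= 24, "n_rounds", "must be <= 24")
  if (anyDuplicated(missing_rounds)) {
    stop("duplicate round indices in `missing_rounds`", call. = FALSE)
  }
  if (length(missing_rounds) > 0 &&
      !all(missing_rounds %in% seq_len(n_rounds))) {
    stop("`missing_rounds` must be a subset of the round schedule",
      call. = FALSE)
  }
  rates <- c(high_start = 0, low_start = 0, nonmonotone_noise = 0,
    negative_er_slope = 0)
  rates[names(failure_rates)] <- failure_rates
  check_field(sum(rates) <= 1, "failure_rates", "must sum to at most 1")

  plots <- tidyr::expand_grid(
    site = sprintf("site_%d", seq_len(n_sites)),
    plot = seq_len(plots_per_site)
  )
  plots$warming <- ifelse(plots$plot %% 2 == 0, "W", "A")
  plots$turfID <- sprintf("%s-p%d-%s", plots$site, plots$plot, plots$warming)

  rows <- with_seed(seed, {
    out <- list()
    flux_nr <- 0L
    for (r in seq_len(n_rounds)) {
      if (r %in% missing_rounds) next
      hour <- (as.numeric(format(start_datetime, "%H")) + r - 1) %% 24
      par <- max(0, 1500 * sin(pi * (hour - 5) / 14)) + runif(1, 0, 30)
      airtemp <- 10 + 7 * sin(pi * (hour - 7) / 12) + rnorm(1, 0, 0.5)
      soiltemp <- 9 + 2 * sin(pi * (hour - 9) / 12) + rnorm(1, 0, 0.3)
      for (p in seq_len(nrow(plots))) {
        dt <- start_datetime + (r - 1) * 3600 + (p - 1) * 450
        mode_draw <- runif(1)
        mode <- "none"
        cum <- 0
        for (m in names(rates)) {
          cum <- cum + rates[[m]]
          if (mode_draw < cum) { mode <- m; break }
        }
        for (type in c("NEE", "ER")) {
          flux_nr <- flux_nr + 1L
          # apparent-uptake artefacts only exist for darkened-chamber
          # closures; the paired NEE member stays well-behaved
          mode_t <- if (mode == "negative_er_slope" && type == "NEE")
            "none" else mode
          sc <- draw_scenario(type, par, noise_sd, mode_t,
            seed = seed + 7919L * flux_nr)
          series <- generate_flux_series(
            sc, fluxID = sprintf("F%04d", flux_nr), airtemp_c = airtemp
          )
          truth <- series$metadata$truth
          out[[length(out) + 1L]] <- tibble::tibble(
            datetime = dt,
            origSiteID = plots$site[p],
            destSiteID = plots$site[p],
            turfID = plots$turfID[p],
            warming = plots$warming[p],
            round = r,
            type = type,
            fluxID = sprintf("F%04d", flux_nr),
            PARavg = if (type == "ER") 0 else par,
            temp_soil = soiltemp,
            temp_airavg = airtemp,
            series = list(series),
            true_slope = truth$true_slope,
            intended_flag = truth$intended_flag
          )
        }
      }
    }
    dplyr::bind_rows(out)
  })

  schedule <- tidyr::expand_grid(
    plots[, c("site", "turfID", "warming")],
    round = seq_len(n_rounds),
    type = c("NEE", "ER", "GPP")
  )
  schedule <- dplyr::rename(schedule, destSiteID = "site")
  schedule$origSiteID <- schedule$destSiteID
  attr(rows, "schedule") <- schedule
  rows
}
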