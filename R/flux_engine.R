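#' Chamber geometry for the flux conversion
#'
#' Bundles the physical constants of the closed chamber that convert a
#' concentration slope (ppm s^-1) into an areal CO2 flux. The defaults match
#' a 25 x 25 x 40 cm plexiglass chamber (25 L including negligible tubing)
#' sealed on a 25 x 25 cm frame base at ambient pressure.
#'
#' @param pressure_atm Air pressure inside the chamber, atm.
#' @param volume_l Volume of chamber plus tubing, L.
#' @param area_m2 Area of the chamber frame base, m^2.
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec()
#' @export
chamber_spec <- function(pressure_atm = 1, volume_l = 25, area_m2 = 0.0625) {
  check_field(is.numeric(pressure_atm) && pressure_atm > 0, "pressure_atm",
    "must be a positive number")
  check_field(is.numeric(volume_l) && volume_l > 0, "volume_l",
    "must be a positive number")
  check_field(is.numeric(area_m2) && area_m2 > 0, "area_m2",
    "must be a positive number")
  structure(
    list(
      pressure_atm = pressure_atm,
      volume_l = volume_l,
      area_m2 = area_m2,
      gas_constant = GAS_CONSTANT_L_ATM
    ),
    class = "chamber_spec"
  )
}

#' One chamber closure as a concentration time series
#'
#' @param t Seconds since chamber closure, strictly increasing.
#' @param conc CO2 concentration, ppm (umol mol^-1); finite, same length as
#'   `t`.
#' @param kind `"NEE"` (transparent chamber) or `"ER"` (darkened chamber).
#' @param fluxID Identifier of the measurement.
#' @param airtemp_c Chamber air temperature, degrees C; a per-reading series
#'   or a single window mean.
#' @param par Photosynthetically active radiation, umol m^-2 s^-1 (optional).
#' @param temp_soil_c Soil temperature, degrees C (optional).
#' @param metadata Named list of plot metadata (turfID, origSiteID,
#'   destSiteID, warming, datetime, ...).
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(t, conc, kind = c("NEE", "ER"),
                                 fluxID = NA_character_,
                                 airtemp_c = NULL, par = NULL,
                                 temp_soil_c = NULL, metadata = list()) {
  kind <- match.arg(kind)
  t <- as.numeric(t)
  conc <- as.numeric(conc)
  check_field(length(t) == length(conc), "conc",
    "must have the same length as t")
  check_field(length(t) >= 2 && all(diff(t) > 0), "t",
    "must be strictly increasing")
  check_field(all(is.finite(conc)), "conc", "must be finite")
  structure(
    list(
      fluxID = fluxID,
      kind = kind,
      t = t,
      conc = conc,
      airtemp_c = airtemp_c,
      par = par,
      temp_soil_c = temp_soil_c,
      start_conc = conc[1],
      metadata = metadata
    ),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf(
    "<concentration_series> %s %s: %d readings, t = [%g, %g] s, conc = [%.1f, %.1f] ppm\n",
    x$kind, x$fluxID, length(x$t), min(x$t), max(x$t),
    min(x$conc), max(x$conc)
  ))
  invisible(x)
}

# Nominal duration of a series: last timestamp plus one sampling interval.
series_duration <- function(series) {
  dt <- median(diff(series$t))
  max(series$t) + dt
}

#' Trim the unstable head and tail of a chamber closure
#'
#' Removes the first `head_s` and last `tail_s` seconds of the measurement
#' (sealing and venting disturb the concentration signal). The retained
#' window is `[head_s, duration - tail_s)`; timestamps stay expressed
#' relative to the original closure, and `start_conc` becomes the first
#' retained reading, which is what the start-concentration QC gate inspects.
#'
#' @param series A [concentration_series()].
#' @param head_s,tail_s Seconds removed at the start and end.
#' @return The trimmed `concentration_series`.
#' @export
trim_series <- function(series, head_s = 10, tail_s = 10) {
  stopifnot(inherits(series, "concentration_series"))
  dur <- series_duration(series)
  if (dur <= head_s + tail_s + 30) {
    stop(sprintf(
      "series too short to fit: duration %.1f s <= head (%g) + tail (%g) + 30 s",
      dur, head_s, tail_s
    ), call. = FALSE)
  }
  keep <- series$t >= head_s & series$t < dur - tail_s
  if (sum(keep) < 30) {
    stop("fewer than 30 readings retained after trimming", call. = FALSE)
  }
  out <- series
  out$t <- series$t[keep]
  out$conc <- series$conc[keep]
  if (!is.null(series$airtemp_c) && length(series$airtemp_c) == length(keep)) {
    out$airtemp_c <- series$airtemp_c[keep]
  }
  if (!is.null(series$par) && length(series$par) == length(keep)) {
    out$par <- series$par[keep]
  }
  out$start_conc <- out$conc[1]
  out
}

#' Estimate the starting concentration Cz by a linear fit
#'
#' Ordinary least squares of concentration on time over the first
#' `window_s` seconds of the (trimmed) series; `Cz` is the intercept at the
#' start of the window and anchors the exponential model, whose `tz`
#' satisfies `C(tz) = Cz`.
#'
#' @param series A trimmed [concentration_series()].
#' @param window_s Length of the fitting window, s.
#' @return A list with elements `cz` (ppm) and `slope` (ppm s^-1).
#' @export
estimate_cz <- function(series, window_s = 15) {
  stopifnot(inherits(series, "concentration_series"))
  tau <- series$t - series$t[1]
  w <- tau < window_s
  if (sum(w) < 2) {
    stop("fewer than 2 readings in the Cz window", call. = FALSE)
  }
  fit <- lm(series$conc[w] ~ tau[w])
  list(cz = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# Model curve: C(t) = Cm + a (t - tz) + (Cz - Cm) exp(-b (t - tz))
exp_model <- function(t, cm, a, b, tz, cz) {
  cm + a * (t - tz) + (cz - cm) * exp(-b * (t - tz))
}

# Starting points for the simplex search. With (b, tz) held fixed the
# model is linear in (Cm, a):
#   C(t) - Cz e^{-b tau} = Cm (1 - e^{-b tau}) + a tau,   tau = t - tz,
# so (Cm, a) can be profiled out by least squares on a log-spaced grid of
# b; the best few grid points seed the full four-parameter search. This
# keeps the search deterministic and reaches the right basin even for
# near-linear closures where b and Cm are almost unidentifiable.
profile_starts <- function(t, conc, cz, n_starts) {
  tz0 <- t[1]
  tau <- t - tz0
  b_grid <- exp(seq(log(1e-4), log(2), length.out = 24))
  cand <- lapply(b_grid, function(b) {
    ebt <- exp(-b * tau)
    x <- cbind(1 - ebt, tau)
    y <- conc - cz * ebt
    fit <- tryCatch(stats::lm.fit(x, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    list(par = c(unname(fit$coefficients), b, tz0),
      rss = sum(fit$residuals^2))
  })
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) {
    return(list(c(mean(tail(conc, 10)),
      unname(coef(lm(conc ~ t))[2]), 0.1, tz0)))
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "rss"))
  lapply(cand[ord[seq_len(min(n_starts, length(cand)))]], `[[`, "par")
}

#' Fit the exponential chamber model to a trimmed closure
#'
#' Estimates `(Cm, a, b, tz)` of the model
#' `C(t) = Cm + a (t - tz) + (Cz - Cm) exp(-b (t - tz))`
#' by minimising the root mean square error of the residuals with a
#' derivative-free simplex search, with `Cz` held fixed at the linear-fit
#' estimate from [estimate_cz()]. `Cm` is the equilibrium concentration,
#' `a` the linear drift, `b` the equilibration rate (s^-1) and `tz` the time
#' at which the model crosses `Cz`. The search is run from several starting
#' values of `b` and restarted until the objective stabilises; the start
#' with the lowest RMSE wins, so the fit is deterministic.
#'
#' The reported flux slope is the model derivative at `tz`,
#' `C'(tz) = a + b (Cm - Cz)`, stored as `slope_at_tz` (the identity is
#' exact on the stored fields). `pearson_r` is the Pearson correlation of
#' time and concentration over the same window, used by the QC decision
#' tree to separate noise from trend when the fit is poor.
#'
#' @param series A trimmed [concentration_series()].
#' @param cz Optional fixed `Cz`; defaults to `estimate_cz(series)$cz`.
#' @param n_starts Number of profiled starting points handed to the
#'   simplex search.
#' @param max_restarts Maximum simplex restarts per start value.
#' @return An object of class `exponential_fit` with fields `cm`, `a`, `b`,
#'   `tz`, `cz`, `rmse`, `slope_at_tz`, `pearson_r`, `converged`, `n`.
#' @export
fit_exponential <- function(series, cz = NULL, n_starts = 3,
                            max_restarts = 25) {
  stopifnot(inherits(series, "concentration_series"))
  t <- series$t
  conc <- series$conc
  if (is.null(cz)) cz <- estimate_cz(series)$cz

  objective <- function(p) {
    pred <- exp_model(t, p[1], p[2], p[3], p[4], cz)
    if (any(!is.finite(pred))) return(1e10)
    sqrt(mean((conc - pred)^2))
  }

  starts <- profile_starts(t, conc, cz, n_starts)

  best <- NULL
  best_conv <- FALSE
  for (s in starts) {
    o <- optim(s, objective)
    converged <- o$convergence == 0
    last <- o$value
    for (i in seq_len(max_restarts)) {
      o <- optim(o$par, objective)
      improved <- last - o$value
      last <- o$value
      if (o$convergence == 0 || improved < 1e-10 * (1 + o$value)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || o$value < best$value) {
      best <- o
      best_conv <- converged
    }
  }

  r <- suppressWarnings(cor(t, conc))
  if (is.na(r)) r <- 0

  cm <- best$par[1]; a <- best$par[2]; b <- best$par[3]; tz <- best$par[4]
  structure(
    list(
      cm = cm, a = a, b = b, tz = tz, cz = cz,
      rmse = best$value,
      slope_at_tz = a + b * (cm - cz),
      pearson_r = r,
      converged = best_conv,
      n = length(t)
    ),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<exponential_fit> Cm = %.2f, a = %.4f, b = %.4f, tz = %.2f, Cz = %.2f\n",
      "  slope at tz = %.4f ppm/s, rmse = %.3f ppm, |r| = %.3f, converged: %s\n"
    ),
    x$cm, x$a, x$b, x$tz, x$cz, x$slope_at_tz, x$rmse,
    abs(x$pearson_r), x$converged
  ))
  invisible(x)
}

#' Convert a concentration slope into an areal CO2 flux
#'
#' Applies the ideal-gas conversion
#' `flux = slope * P V / (R T A)` with the slope in ppm s^-1 read as
#' umol mol^-1 s^-1, giving umol m^-2 s^-1, then rescales to
#' mmol m^-2 h^-1 (x 3600 / 1000).
#'
#' @param slope Concentration slope at `tz`, ppm s^-1.
#' @param chamber A [chamber_spec()].
#' @param temp_k Chamber air temperature, K.
#' @return Flux in mmol m^-2 h^-1.
#' @examples
#' flux_from_slope(1, chamber_spec(), temp_k = 293.15)
#' @export
flux_from_slope <- function(slope, chamber = chamber_spec(), temp_k) {
  stopifnot(inherits(chamber, "chamber_spec"))
  check_field(is.numeric(temp_k) && all(temp_k > 0), "temp_k",
    "must be positive (kelvin)")
  umol_m2_s <- slope * chamber$pressure_atm * chamber$volume_l /
    (chamber$gas_constant * temp_k * chamber$area_m2)
  umol_m2_s * 3600 / 1000
}
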