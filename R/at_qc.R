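#' Sharpe-Schoolfield thermal performance model with high-temperature
#' deactivation
#'
#' The reparameterisation with an explicit optimum temperature:
#' \deqn{r(T) = r_{tref} \exp\!\left[\frac{E}{k}\left(\frac{1}{T_{ref}} -
#'   \frac{1}{T}\right)\right] \Big/ \left[1 + \frac{E}{E_h - E}
#'   \exp\!\left(\frac{E_h}{k}\left(\frac{1}{T_{opt}} -
#'   \frac{1}{T}\right)\right)\right]}
#' with temperatures in kelvin and `k` the Boltzmann constant in eV K^-1.
#' `r_tref` is the rate at the reference temperature (20 degrees C by
#' convention here), `E` the activation energy (eV) governing the rise,
#' `E_h > E` the deactivation energy governing the fall above the optimum,
#' and `T_opt` the temperature of peak performance.
#'
#' @param temp_c Leaf temperature, degrees C. Vectorised.
#' @param r_tref Rate at the reference temperature (assimilation units).
#' @param e Activation energy, eV.
#' @param eh High-temperature deactivation energy, eV; must exceed `e`.
#' @param topt_c Optimum temperature, degrees C.
#' @param tref_c Reference temperature, degrees C.
#' @return Modelled rate at `temp_c`.
#' @export
sharpe_schoolfield <- function(temp_c, r_tref, e, eh, topt_c, tref_c = 20) {
  tk <- temp_c + 273.15
  tref <- tref_c + 273.15
  topt <- topt_c + 273.15
  boltz <- exp(e / BOLTZMANN_EV * (1 / tref - 1 / tk))
  inact <- 1 + e / (eh - e) * exp(eh / BOLTZMANN_EV * (1 / topt - 1 / tk))
  r_tref * boltz / inact
}

#' An assimilation-temperature response curve
#'
#' @param curveID Identifier.
#' @param leaf_temp_c Measured leaf temperature, degrees C.
#' @param assim Net assimilation, umol m^-2 s^-1; same length as
#'   `leaf_temp_c`.
#' @param species,siteID Optional metadata.
#' @param metadata Extra metadata (ground truth for synthetic curves).
#' @return An object of class `at_curve`.
#' @export
at_curve <- function(curveID, leaf_temp_c, assim, species = NA_character_,
                     siteID = NA_character_, metadata = list()) {
  leaf_temp_c <- as.numeric(leaf_temp_c)
  assim <- as.numeric(assim)
  check_field(length(leaf_temp_c) == length(assim), "assim",
    "must have the same length as leaf_temp_c")
  check_field(length(leaf_temp_c) >= 20, "leaf_temp_c",
    "needs at least 20 points")
  check_field(diff(range(leaf_temp_c)) > 0, "leaf_temp_c",
    "temperature span must be positive")
  structure(
    list(curveID = curveID, leaf_temp_c = leaf_temp_c, assim = assim,
      species = species, siteID = siteID, metadata = metadata),
    class = "at_curve"
  )
}

#' @export
print.at_curve <- function(x, ...) {
  cat(sprintf(
    "<at_curve> %s (%s): %d points, leaf temperature %.1f-%.1f C\n",
    x$curveID, x$species, length(x$assim), min(x$leaf_temp_c),
    max(x$leaf_temp_c)
  ))
  invisible(x)
}

#' Count the maxima of a smoothed assimilation-temperature curve
#'
#' Fits a cubic smoothing spline (smoothness by generalised
#' cross-validation, with the equivalent degrees of freedom capped so that
#' measurement noise cannot fragment a single physiological peak),
#' evaluates it on a dense uniform grid over the measured temperature
#' range, and counts its local maxima. Plateaus collapse to a single
#' maximum; a monotone curve counts one boundary maximum; maxima whose
#' prominence (height above the deeper adjacent saddle) is below
#' `prominence` times the fitted range are treated as noise ripples, not
#' modes.
#'
#' @param curve An [at_curve()].
#' @param grid_n Evaluation grid size.
#' @param df_max Cap on the spline's equivalent degrees of freedom.
#' @param prominence Minimum relative prominence of a counted maximum.
#' @return Integer number of maxima (>= 1), or `NA` if the spline fit
#'   fails.
#' @export
spline_modality <- function(curve, grid_n = 512, df_max = 10,
                            prominence = 0.05) {
  stopifnot(inherits(curve, "at_curve"))
  sp <- tryCatch({
    s0 <- smooth.spline(curve$leaf_temp_c, curve$assim)
    if (s0$df > df_max) {
      smooth.spline(curve$leaf_temp_c, curve$assim, df = df_max)
    } else {
      s0
    }
  }, error = function(e) NULL)
  if (is.null(sp)) return(NA_integer_)
  g <- seq(min(curve$leaf_temp_c), max(curve$leaf_temp_c),
    length.out = grid_n)
  yh <- predict(sp, g)$y
  count_maxima(yh, prominence)
}

# Local maxima of a sampled function, plateau-collapsed and filtered by
# relative prominence. Boundary maxima count.
count_maxima <- function(yh, prominence = 0) {
  n <- length(yh)
  d <- diff(yh)
  up <- c(TRUE, d > 0)
  dn <- c(d < 0, TRUE)
  idx <- which(up & dn)
  # a flat plateau produces no index; treat a constant function as unimodal
  if (length(idx) == 0) return(1L)
  if (length(idx) == 1) return(1L)
  rng <- diff(range(yh))
  if (rng == 0) return(1L)
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    left_min <- if (j == 1) min(yh[1:i]) else min(yh[idx[j - 1]:i])
    right_min <- if (j == length(idx)) min(yh[i:n]) else min(yh[i:idx[j + 1]])
    keep[j] <- (yh[i] - max(left_min, right_min)) >= prominence * rng
  }
  max(1L, sum(keep))
}

#' Fit the optimum temperature of an assimilation-temperature curve
#'
#' Nonlinear least squares of the explicit-Topt Sharpe-Schoolfield model
#' ([sharpe_schoolfield()]) via Levenberg-Marquardt, multi-started over a
#' coarse grid of candidate optimum temperatures (the grid extends beyond
#' the measured range so that out-of-range optima can be recovered and
#' rejected by the range criterion). The multi-start is deterministic: the
#' converged start with the lowest residual sum of squares wins.
#'
#' @param curve An [at_curve()].
#' @param topt_grid Candidate starting values for the optimum, degrees C.
#' @param tref_c Reference temperature of the model, degrees C.
#' @param eh_max Upper bound on the deactivation energy, eV. Published
#'   deactivation energies for photosynthesis are a few eV; without a
#'   ceiling the optimiser can fake an arbitrarily sharp deactivation
#'   cliff at the edge of the data and pull an out-of-range optimum just
#'   inside the measured range.
#' @return A list with `topt_c`, `coef` (all model parameters), `rss` and
#'   `converged` (`FALSE` when every start failed).
#' @export
fit_topt <- function(curve, topt_grid = seq(0, 60, by = 5), tref_c = 20,
                     eh_max = 8) {
  stopifnot(inherits(curve, "at_curve"))
  tc <- curve$leaf_temp_c
  y <- curve$assim
  r0 <- max(stats::approx(tc, y, xout = tref_c, rule = 2)$y, max(y) * 0.1)
  best <- NULL
  for (t0 in topt_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ sharpe_schoolfield(tc, r_tref, e, eh, topt, tref_c = tref_c),
        start = list(r_tref = r0, e = 0.5, eh = 3, topt = t0),
        lower = c(1e-8, 0.01, 0.02, -30),
        upper = c(Inf, 15, eh_max, 90),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(topt_c = NA_real_, coef = NULL, rss = NA_real_,
      converged = FALSE))
  }
  cf <- coef(best)
  list(topt_c = unname(cf[["topt"]]), coef = cf, rss = deviance(best),
    converged = TRUE)
}

#' Keep-or-exclude decision for an assimilation-temperature curve
#'
#' A curve is excluded when (in order) the smoothing spline is multimodal
#' (more than one maximum; stomatal oscillations and similar confounders),
#' the thermal model cannot be fitted, or the fitted optimum temperature
#' falls strictly outside the measured leaf temperature range (the data do
#' not cover the optimum, so the curve cannot constrain it). Boundary-equal
#' optima are kept.
#'
#' @param curve An [at_curve()].
#' @param grid_n,df_max,prominence Passed to [spline_modality()].
#' @param topt_grid,tref_c Passed to [fit_topt()].
#' @return An object of class `at_qc_result`: a list with `curveID`,
#'   `decision` (`keep`/`exclude`), `reason` (`none`, `multimodal`,
#'   `topt_out_of_range`, `fit_failed`), `fitted_topt` and
#'   `n_spline_maxima`.
#' @export
at_qc <- function(curve, grid_n = 512, df_max = 10, prominence = 0.05,
                  topt_grid = seq(0, 60, by = 5), tref_c = 20) {
  stopifnot(inherits(curve, "at_curve"))
  n_max <- spline_modality(curve, grid_n, df_max, prominence)
  if (is.na(n_max)) {
    return(at_qc_result(curve$curveID, "exclude", "fit_failed",
      NA_real_, NA_integer_))
  }
  if (n_max > 1) {
    return(at_qc_result(curve$curveID, "exclude", "multimodal",
      NA_real_, n_max))
  }
  fit <- fit_topt(curve, topt_grid, tref_c)
  if (!fit$converged) {
    return(at_qc_result(curve$curveID, "exclude", "fit_failed",
      NA_real_, n_max))
  }
  lo <- min(curve$leaf_temp_c)
  hi <- max(curve$leaf_temp_c)
  if (fit$topt_c < lo || fit$topt_c > hi) {
    return(at_qc_result(curve$curveID, "exclude", "topt_out_of_range",
      fit$topt_c, n_max))
  }
  at_qc_result(curve$curveID, "keep", "none", fit$topt_c, n_max)
}

at_qc_result <- function(curveID, decision, reason, fitted_topt,
                         n_spline_maxima) {
  structure(
    list(curveID = curveID, decision = decision, reason = reason,
      fitted_topt = fitted_topt, n_spline_maxima = n_spline_maxima),
    class = "at_qc_result"
  )
}

#' @export
print.at_qc_result <- function(x, ...) {
  cat(sprintf(
    "<at_qc_result> %s: %s (%s), Topt = %.1f C, %s spline maxima\n",
    x$curveID, x$decision, x$reason,
    if (is.na(x$fitted_topt)) NA else x$fitted_topt,
    x$n_spline_maxima
  ))
  invisible(x)
}

#' QC a batch of assimilation-temperature curves
#'
#' @param curves A list of [at_curve()] objects.
#' @param ... Passed to [at_qc()].
#' @return A tibble with one row per curve (`curveID`, `decision`,
#'   `reason`, `fitted_topt`, `n_spline_maxima`); the exclusion counts by
#'   reason are attached as attribute `"report"`.
#' @export
at_qc_batch <- function(curves, ...) {
  res <- purrr::map_dfr(curves, function(cv) {
    r <- at_qc(cv, ...)
    tibble::tibble(
      curveID = r$curveID, decision = r$decision, reason = r$reason,
      fitted_topt = r$fitted_topt, n_spline_maxima = r$n_spline_maxima
    )
  })
  attr(res, "report") <- dplyr::count(res, .data$decision, .data$reason,
    name = "n")
  res
}
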