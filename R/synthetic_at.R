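#' Scenario for a synthetic assimilation-temperature curve
#'
#' \describe{
#'   \item{`unimodal`}{drawn from the Sharpe-Schoolfield model itself with
#'     the optimum at `true_topt`; with `noise_sd = 0` the series has
#'     exactly one local maximum when the optimum lies inside
#'     `temp_range`.}
#'   \item{`bimodal`}{the same thermal response plus a second bump at a
#'     higher temperature (emulating e.g. stomatal oscillation artefacts);
#'     always excluded as multimodal.}
#'   \item{`monotone`}{a response still rising at the top of the measured
#'     range (optimum far above it); excluded because the fitted optimum
#'     falls outside the data.}
#' }
#'
#' @param modality `"unimodal"`, `"bimodal"` or `"monotone"`.
#' @param true_topt True optimum temperature, degrees C. For `monotone`
#'   curves the effective optimum is placed above `temp_range` regardless.
#' @param temp_range Measured leaf temperature range, degrees C.
#' @param noise_sd Additive Gaussian noise on assimilation (same units as
#'   the rate).
#' @param n_points Number of readings along the ramp.
#' @param r_tref,e,eh Thermal model parameters (rate at 20 degrees C,
#'   activation and deactivation energies in eV).
#' @param seed Integer RNG seed.
#' @return An object of class `at_scenario`.
#' @export
at_scenario <- function(modality = c("unimodal", "bimodal", "monotone"),
                        true_topt = 22, temp_range = c(8, 42),
                        noise_sd = 0.5, n_points = 200,
                        r_tref = 10, e = 0.6, eh = 3.5, seed = 1L) {
  modality <- match.arg(modality)
  check_field(length(temp_range) == 2 && temp_range[2] > temp_range[1],
    "temp_range", "must be an increasing pair")
  check_field(n_points >= 20, "n_points", "needs at least 20 points")
  check_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_field(eh > e && e > 0, "eh", "needs eh > e > 0")
  structure(
    list(modality = modality, true_topt = true_topt,
      temp_range = temp_range, noise_sd = noise_sd,
      n_points = as.integer(n_points), r_tref = r_tref, e = e, eh = eh,
      seed = as.integer(seed)),
    class = "at_scenario"
  )
}

#' Draw a labelled battery of synthetic assimilation-temperature curves
#'
#' Mixes unimodal (optimum uniform in 15-30 degrees C), bimodal and
#' monotone scenarios; the noise level is expressed as a fraction of each
#' curve's peak assimilation so that all shapes are equally hard.
#'
#' @param n Number of curves.
#' @param noise_frac Noise standard deviation as a fraction of peak
#'   assimilation.
#' @param weights Sampling probabilities for unimodal, bimodal, monotone.
#' @param seed Integer RNG seed.
#' @return A list of [at_curve()] objects with ground-truth metadata.
#' @export
sample_at_curves <- function(n = 100, noise_frac = 0.05,
                             weights = c(0.5, 0.25, 0.25), seed = 1L) {
  with_seed(seed, {
    modality <- sample(c("unimodal", "bimodal", "monotone"), n,
      replace = TRUE, prob = weights)
    topt <- runif(n, 15, 30)
    lapply(seq_len(n), function(i) {
      sc0 <- at_scenario(modality[i], true_topt = topt[i], noise_sd = 0,
        seed = seed + 31L * i)
      peak <- max(generate_at_curve(sc0)$assim)
      sc <- at_scenario(modality[i], true_topt = topt[i],
        noise_sd = noise_frac * peak, seed = seed + 31L * i)
      generate_at_curve(sc, curveID = sprintf("AT%03d", i))
    })
  })
}

#' Generate a synthetic assimilation-temperature curve
#'
#' @param scenario An [at_scenario()].
#' @param curveID Identifier for the emitted curve.
#' @return An [at_curve()] whose `metadata` records the ground truth
#'   (`true_topt`, `modality`, and the expected QC `intended_decision` and
#'   `intended_reason`).
#' @export
generate_at_curve <- function(scenario, curveID = "AT-1") {
  stopifnot(inherits(scenario, "at_scenario"))
  sc <- scenario
  tc <- seq(sc$temp_range[1], sc$temp_range[2], length.out = sc$n_points)

  topt_eff <- switch(sc$modality,
    unimodal = sc$true_topt,
    # keep the primary peak in the lower half of the range so the second
    # bump is well separated (>= ~40% of the span away)
    bimodal = min(sc$true_topt,
      sc$temp_range[1] + 0.35 * diff(sc$temp_range)),
    monotone = max(sc$temp_range) + 10
  )
  y <- sharpe_schoolfield(tc, sc$r_tref, sc$e, sc$eh, topt_eff)
  if (sc$modality == "bimodal") {
    span <- diff(sc$temp_range)
    bump_at <- sc$temp_range[1] + 0.8 * span
    y <- y + 0.6 * max(y) * exp(-(tc - bump_at)^2 / (2 * 3^2))
  }
  if (sc$noise_sd > 0) {
    y <- with_seed(sc$seed, y + rnorm(sc$n_points, 0, sc$noise_sd))
  }

  if (sc$modality == "bimodal") {
    decision <- "exclude"; reason <- "multimodal"
  } else if (topt_eff < sc$temp_range[1] || topt_eff > sc$temp_range[2]) {
    decision <- "exclude"; reason <- "topt_out_of_range"
  } else {
    decision <- "keep"; reason <- "none"
  }

  at_curve(
    curveID = curveID, leaf_temp_c = tc, assim = y,
    metadata = list(
      true_topt = topt_eff, modality = sc$modality,
      intended_decision = decision, intended_reason = reason
    )
  )
}
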