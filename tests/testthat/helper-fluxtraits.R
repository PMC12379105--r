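# Shared fixtures, built in code.

# A noiseless, well-behaved closure matching the documented worked example.
make_clean_series <- function(cm = 450, a = 0.02, b = 0.05, tz = 10,
                              cz = 400, noise_sd = 0, seed = 1,
                              kind = "NEE") {
  generate_flux_series(
    flux_scenario(
      true_cm = cm, true_a = a, true_b = b, true_tz = tz, true_cz = cz,
      noise_sd = noise_sd, kind = kind, seed = seed
    )
  )
}

# A hand-built exponential_fit for decision-tree tests (classification
# only looks at stored fields, so fits can be constructed directly).
make_fit <- function(b = 0.1, slope = 1, r = 0.9, converged = TRUE,
                     cm = 450, cz = 400) {
  a <- slope - b * (cm - cz)
  structure(
    list(cm = cm, a = a, b = b, tz = 10, cz = cz, rmse = 0.5,
      slope_at_tz = a + b * (cm - cz), pearson_r = r,
      converged = converged, n = 160),
    class = "exponential_fit"
  )
}

# A trimmed series with a chosen start concentration and kind.
make_series_for_qc <- function(start_conc = 430, kind = "NEE") {
  t <- 10:169
  concentration_series(
    t = t, conc = rep(start_conc, length(t)) + 0.01 * (t - 10),
    kind = kind, airtemp_c = 15
  )
}
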