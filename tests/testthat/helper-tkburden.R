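# Shared fixtures: noiseless series generated from known parameters, and
# lognormal noise with a given CV and unit mean.

study_times <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 48)

noiseless_oral_series <- function(k_a, k_e, v_over_f, dose = 100,
                                  times = study_times, id = "oral1",
                                  sex = "male", label = "thiazol") {
  p <- tk_params(k_e = k_e, v_over_f = v_over_f, k_a = k_a, route = "oral")
  concentration_series(id, sex, "oral", dose, times,
                       oral_concentration(p, dose_spec(dose, "oral"), times),
                       label = label)
}

noiseless_iv_series <- function(k_e, v, dose = 0.5, times = study_times,
                                id = "iv1", sex = "male") {
  p <- tk_params(k_e = k_e, v_over_f = v, route = "iv")
  concentration_series(id, sex, "iv", dose, times,
                       iv_concentration(p, dose_spec(dose, "iv"), times),
                       label = "thiazol")
}

unit_mean_lnorm <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# largest relative deviation of a simulated trace from the closed form,
# normalised by the peak of the closed-form curve
trace_deviation <- function(scenario) {
  tr <- simulate_body_burden(scenario)
  an <- analytic_burden(scenario, tr$t_min)
  max(abs(tr$d_int - an$d_int)) / max(an$d_int)
}
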