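test_that("noiseless oral series are recovered to < 0.1% across a rate-constant grid", {
  for (ka in c(0.5, 1, 2, 4)) for (ke in c(0.1, 0.25, 0.5)) {
    if (ka <= ke) next
    s <- noiseless_oral_series(ka, ke, v_over_f = 1.4)
    f <- fit_one_compartment(s)
    expect_true(f$converged)
    est <- f$estimates
    expect_lt(abs(est[["k_a"]] - ka) / ka, 1e-3)
    expect_lt(abs(est[["k_e"]] - ke) / ke, 1e-3)
    expect_lt(abs(est[["v_over_f"]] - 1.4) / 1.4, 1e-3)
  }
})

test_that("noiseless i.v. fit reproduces the 160.0 min elimination half-life", {
  f <- fit_one_compartment(noiseless_iv_series(k_e = 0.26, v = 0.84))
  expect_true(f$converged)
  expect_equal(round(half_life(f$estimates[["k_e"]]), 1), 160.0)
  expect_lt(abs(f$estimates[["v"]] - 0.84) / 0.84, 1e-3)
})

test_that("fits land on the k_a > k_e branch regardless of the generating branch", {
  # data generated on the slow-absorption branch: same curve as
  # (k_a, k_e, V) = (1.5, 0.3, V * 1.5 / 0.3)
  s <- noiseless_oral_series(k_a = 0.3, k_e = 1.5, v_over_f = 1)
  f <- fit_one_compartment(s)
  expect_true(f$converged)
  expect_gt(f$estimates[["k_a"]], f$estimates[["k_e"]])
  expect_equal(f$estimates[["k_a"]], 1.5, tolerance = 1e-3)
  expect_equal(f$estimates[["k_e"]], 0.3, tolerance = 1e-3)
  expect_equal(f$estimates[["v_over_f"]], 5, tolerance = 1e-3)
})

test_that("the damped iteration never increases the objective", {
  set.seed(11)
  for (r in 1:5) {
    s <- noiseless_oral_series(2, 0.3, 1)
    obs <- s$observations
    obs$conc_ug_per_ml <- obs$conc_ug_per_ml * unit_mean_lnorm(nrow(obs), 0.2)
    s2 <- concentration_series("x", "male", "oral", 100, obs$time_h,
                               obs$conc_ug_per_ml)
    f <- fit_one_compartment(s2)
    expect_lte(f$obj_final, f$obj_init)
  }
})

test_that("estimates depend only on times, concentrations and dose, not metadata", {
  a <- noiseless_oral_series(2, 0.3, 1, id = "a", sex = "male",
                             label = "thiazol")
  b <- noiseless_oral_series(2, 0.3, 1, id = "b", sex = "female",
                             label = "oxadiazin")
  expect_identical(fit_one_compartment(a)$estimates,
                   fit_one_compartment(b)$estimates)
})

test_that("zero observations are excluded under reciprocal weighting and counted", {
  s <- noiseless_oral_series(2, 0.3, 1)
  conc <- s$observations$conc_ug_per_ml
  conc[9] <- 0  # censored 48 h sample
  s2 <- concentration_series("z", "male", "oral", 100,
                             s$observations$time_h, conc)
  f <- fit_one_compartment(s2)
  expect_equal(f$n_excluded, 1L)
  expect_equal(f$n_obs, 8L)
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["k_a"]] - 2) / 2, 1e-3)
})

test_that("too few usable observations is an input error", {
  s <- concentration_series("s", "male", "oral", 100,
                            time_h = c(0.5, 1, 2),
                            conc_ug_per_ml = c(30, 40, 35))
  expect_error(fit_one_compartment(s), "at least 4")
})

test_that("AIC follows n ln(WRSS) + 2p, penalises parameters, flags perfect fits", {
  fake <- function(n, p, wrss)
    structure(list(n_obs = n, estimates = numeric(p), wrss = wrss),
              class = "tk_fit")
  expect_equal(compute_aic(fake(9, 3, 1)), 6.0)
  # one extra parameter at unchanged WRSS costs exactly 2
  expect_equal(compute_aic(fake(9, 4, 2.7)) - compute_aic(fake(9, 3, 2.7)), 2)
  expect_warning(val <- compute_aic(fake(9, 3, 0)), "perfect")
  expect_identical(val, -Inf)
})

test_that("AIC prefers the data-generating compartment count in the majority of replicates", {
  set.seed(7)
  tt <- study_times
  # biexponential data with well-separated phases
  two_wins <- 0
  for (r in 1:40) {
    y <- (3 * exp(-2 * tt) + 1 * exp(-0.1 * tt)) * unit_mean_lnorm(9, 0.05)
    s <- concentration_series("b", "male", "iv", 0.5, tt, y)
    f1 <- fit_one_compartment(s)
    f2 <- fit_two_compartment(s)
    if (compute_aic(f2) < compute_aic(f1)) two_wins <- two_wins + 1
  }
  expect_gt(two_wins / 40, 0.5)
  # one-compartment data: the simpler model wins
  one_wins <- 0
  p <- tk_params(k_e = 0.3, v_over_f = 1, route = "iv")
  mu <- iv_concentration(p, dose_spec(0.5, "iv"), tt)
  for (r in 1:40) {
    y <- mu * unit_mean_lnorm(9, 0.05)
    s <- concentration_series("m", "male", "iv", 0.5, tt, y)
    f1 <- fit_one_compartment(s)
    f2 <- fit_two_compartment(s)
    if (compute_aic(f1) < compute_aic(f2)) one_wins <- one_wins + 1
  }
  expect_gt(one_wins / 40, 0.5)
})

test_that("two-compartment comparator rejects under-determined series", {
  s <- concentration_series("s", "male", "iv", 0.5,
                            time_h = c(0.5, 1, 2, 4),
                            conc_ug_per_ml = c(0.5, 0.4, 0.3, 0.2))
  expect_error(fit_two_compartment(s), "at least 5")
})

test_that("bioavailability is the dose-normalised AUC ratio", {
  expect_equal(relative_bioavailability(2.3, 0.5, 2.3, 0.5)$f, 1)
  # group-mean arithmetic from the published low- and high-dose AUCs
  expect_equal(relative_bioavailability(1.49, 0.5, 2.30, 0.5)$f, 0.648,
               tolerance = 1e-3)
  expect_equal(relative_bioavailability(342, 100, 2.30, 0.5)$f, 0.743,
               tolerance = 1e-3)
  # scale invariance in the AUCs
  b1 <- relative_bioavailability(1.49, 0.5, 2.30, 0.5)
  b2 <- relative_bioavailability(1.49 * 17, 0.5, 2.30 * 17, 0.5)
  expect_equal(b1$f, b2$f)
  expect_true(relative_bioavailability(5, 1, 4, 1)$above_one)
  expect_false(b1$above_one)
  expect_error(relative_bioavailability(1, 1, 0, 1), "positive")
  expect_error(relative_bioavailability(-1, 1, 2, 1), "positive")
})

test_that("group summaries report mean, SD, min, max and handle single fits", {
  fits <- lapply(c(0.24, 0.26, 0.28), function(ke)
    fit_one_compartment(noiseless_iv_series(ke, v = 0.84, id = paste0("s", ke))))
  tab <- summarize_group(fits, by = "route")
  ke_row <- tab[tab$parameter == "k_e", ]
  expect_equal(ke_row$mean, 0.26, tolerance = 1e-6)
  expect_equal(ke_row$min, 0.24, tolerance = 1e-6)
  expect_equal(ke_row$max, 0.28, tolerance = 1e-6)
  expect_equal(ke_row$sd, sd(c(0.24, 0.26, 0.28)), tolerance = 1e-6)
  expect_equal(ke_row$n, 3L)
  single <- summarize_group(fits[1], by = "route")
  expect_true(is.na(single$sd[single$parameter == "k_e"]))
})
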