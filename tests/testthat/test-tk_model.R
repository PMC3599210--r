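test_that("i.v. curve is the monoexponential with the halving property", {
  p <- tk_params(k_e = 0.26, v_over_f = 1, route = "iv")
  d <- dose_spec(1, "iv")
  expect_equal(iv_concentration(p, d, 0), 1)
  expect_equal(iv_concentration(p, d, log(2) / 0.26), 0.5)
  # one half-life halves the concentration at every starting time
  t <- c(0, 0.3, 1, 5, 20)
  expect_equal(iv_concentration(p, d, t + log(2) / 0.26),
               iv_concentration(p, d, t) / 2)
  # strictly decreasing
  tt <- seq(0, 48, by = 0.5)
  expect_true(all(diff(iv_concentration(p, d, tt)) < 0))
  expect_error(iv_concentration(p, d, -1), "non-negative")
})

test_that("i.v. curve matches numerical integration of dC/dt = -k_e C", {
  skip_if_not_installed("deSolve")
  p <- tk_params(k_e = 0.5, v_over_f = 1, route = "iv")
  d <- dose_spec(2, "iv")
  sol <- deSolve::lsoda(c(C = 2), times = c(0, 4),
                        func = function(t, y, parms) list(-0.5 * y),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(iv_concentration(p, d, 4), sol[2, "C"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(iv_concentration(p, d, 4), 2 * exp(-2))
})

test_that("oral Bateman curve starts at zero, stays non-negative, peaks where the ODE says", {
  p <- tk_params(k_e = 0.25, v_over_f = 1, k_a = 2.2, route = "oral")
  d <- dose_spec(1563, "oral")
  expect_equal(oral_concentration(p, d, 0), 0)
  tt <- seq(0, 48, by = 0.05)
  expect_true(all(oral_concentration(p, d, tt) >= 0))
  skip_if_not_installed("deSolve")
  # fine-grid integration of the absorption-elimination system
  ode <- deSolve::lsoda(
    c(G = 1563, C = 0), times = seq(0, 3, by = 0.001),
    func = function(t, y, parms)
      list(c(-2.2 * y["G"], 2.2 * y["G"] - 0.25 * y["C"])),
    rtol = 1e-10, atol = 1e-10)
  tmax <- log(2.2 / 0.25) / (2.2 - 0.25)
  i <- which.min(abs(ode[, "time"] - tmax))
  expect_equal(oral_concentration(p, d, tmax), ode[i, "C"],
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(oral_concentration(p, d, tmax), 1182.8, tolerance = 1e-4)
})

test_that("k_a = k_e degeneracy uses the analytic limit k t exp(-k t)", {
  p <- tk_params(k_e = 1, v_over_f = 1 / exp(1), k_a = 1, route = "oral")
  expect_equal(oral_concentration(p, dose_spec(1, "oral"), 1), 1)
  # continuity across the branch switch
  pe <- tk_params(k_e = 1, v_over_f = 1, k_a = 1 + 1e-9, route = "oral")
  pl <- tk_params(k_e = 1, v_over_f = 1, k_a = 1, route = "oral")
  d <- dose_spec(5, "oral")
  expect_equal(oral_concentration(pe, d, 2), oral_concentration(pl, d, 2),
               tolerance = 1e-7)
})

test_that("flip-flop: swapping k_a and k_e with rescaled V/F leaves the curve unchanged", {
  d <- dose_spec(10, "oral")
  tt <- seq(0, 24, by = 0.25)
  for (pair in list(c(2.2, 0.25), c(0.5, 0.1), c(4, 0.5))) {
    ka <- pair[1]; ke <- pair[2]; v <- 1.4
    a <- tk_params(k_e = ke, v_over_f = v, k_a = ka, route = "oral")
    b <- tk_params(k_e = ka, v_over_f = v * ke / ka, k_a = ke,
                   route = "oral")
    expect_equal(oral_concentration(a, d, tt), oral_concentration(b, d, tt))
  }
})

test_that("half-life arithmetic is exact and reported in minutes", {
  expect_equal(round(half_life(0.26), 1), 160.0)
  expect_equal(round(half_life(0.50), 1), 83.2)
  expect_equal(half_life(60 * log(2)), 1.0)
  # k * t_half == 60 ln 2 identically
  k <- c(0.05, 0.26, 1, 7.3)
  expect_equal(half_life(k) * k, rep(60 * log(2), 4))
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("time of Cmax matches a golden-section argmax and is swap-symmetric", {
  p <- tk_params(k_e = 0.25, v_over_f = 1, k_a = 2.2, route = "oral")
  d <- dose_spec(1, "oral")
  opt <- optimize(function(t) oral_concentration(p, d, t),
                  interval = c(0, 24), maximum = TRUE, tol = 1e-10)
  expect_equal(time_of_cmax(p), opt$maximum, tolerance = 1e-6)
  expect_equal(time_of_cmax(p), 1.1153, tolerance = 1e-4)
  swapped <- tk_params(k_e = 2.2, v_over_f = 1, k_a = 0.25, route = "oral")
  expect_equal(time_of_cmax(swapped), time_of_cmax(p))
  eq <- tk_params(k_e = 2, v_over_f = 1, k_a = 2, route = "oral")
  expect_equal(time_of_cmax(eq), 0.5)
  iv <- tk_params(k_e = 0.26, v_over_f = 1, route = "iv")
  expect_equal(time_of_cmax(iv), 0)
  cm <- cmax(iv, dose_spec(0.5, "iv"))
  expect_equal(cm$t_max_h, 0)
  expect_equal(cm$cmax, 0.5)
})

test_that("compartmental AUC equals the integral of the curve and is linear in dose", {
  # dose/V = 1.3 ug ml^-1, k_e = 0.26 -> AUC = 1.3 / 0.26 = 5
  piv <- tk_params(k_e = 0.26, v_over_f = 0.5 / 1.3, route = "iv")
  expect_equal(model_auc(piv, dose_spec(0.5, "iv")), 5)
  # quadrature oracle across a parameter grid, 0.05 <= k <= 10
  grid <- expand.grid(ka = c(0.05, 0.5, 2.2, 10), ke = c(0.05, 0.25, 2))
  for (i in seq_len(nrow(grid))) {
    ka <- grid$ka[i]; ke <- grid$ke[i]
    if (ka == ke) next
    p <- tk_params(k_e = ke, v_over_f = 2, k_a = ka, route = "oral")
    d <- dose_spec(7, "oral")
    quad <- integrate(function(t) oral_concentration(p, d, t),
                      0, 200 / min(ka, ke), rel.tol = 1e-10)$value
    expect_equal(model_auc(p, d), quad, tolerance = 1e-4)
  }
  p <- tk_params(k_e = 0.25, v_over_f = 1, k_a = 2.2, route = "oral")
  expect_equal(model_auc(p, dose_spec(20, "oral")),
               2 * model_auc(p, dose_spec(10, "oral")))
})

test_that("parameter and dose constructors enforce their invariants", {
  expect_error(tk_params(k_e = -0.1, v_over_f = 1, route = "iv"), "positive")
  expect_error(tk_params(k_e = 0.2, v_over_f = 0, route = "iv"), "positive")
  expect_error(tk_params(k_e = 0.2, v_over_f = 1, route = "oral"), "k_a")
  expect_error(tk_params(k_e = 0.2, v_over_f = 1, k_a = 1, route = "iv"),
               "no meaning")
  expect_error(dose_spec(0, "oral"), "positive")
  p <- tk_params(k_e = 0.2, v_over_f = 1, k_a = 1, route = "oral")
  expect_error(oral_concentration(p, dose_spec(1, "iv"), 1), "oral")
})
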