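#' One-compartment kinetic parameters
#'
#' Container for a subject's first-order rate constants and apparent volume
#' of distribution. Rate constants are stored in h^-1 throughout the
#' package; the body-burden simulator converts to min^-1 internally at a
#' single boundary.
#'
#' For oral administration only the ratio `V/F` (apparent volume of
#' distribution over bioavailability) is identifiable, so `v_over_f` holds
#' that ratio. For intravenous administration `F == 1` by definition and
#' `v_over_f` holds `V` itself. Units are such that
#' `dose [mg kg^-1 bw] / v_over_f` is a blood concentration in ug ml^-1
#' (i.e. litres of blood per kg body weight).
#'
#' @param k_e Elimination rate constant, h^-1. Must be positive.
#' @param v_over_f Apparent volume of distribution over bioavailability
#'   (oral) or volume of distribution (i.v.). Must be positive.
#' @param k_a Absorption rate constant, h^-1. Required (and positive) for
#'   the oral route; must be omitted for i.v.
#' @param route `"oral"` or `"iv"`.
#'
#' @return An object of class `"tk_params"`.
#' @examples
#' tk_params(k_e = 0.25, v_over_f = 1.4, k_a = 2.2, route = "oral")
#' tk_params(k_e = 0.26, v_over_f = 0.84, route = "iv")
#' @export
tk_params <- function(k_e, v_over_f, k_a = NULL, route = c("oral", "iv")) {
  route <- match.arg(route)
  if (!is.numeric(k_e) || length(k_e) != 1L || !is.finite(k_e) || k_e <= 0)
    stop("`k_e` must be a single positive number (h^-1)", call. = FALSE)
  if (!is.numeric(v_over_f) || length(v_over_f) != 1L ||
      !is.finite(v_over_f) || v_over_f <= 0)
    stop("`v_over_f` must be a single positive number", call. = FALSE)
  if (route == "oral") {
    if (is.null(k_a) || !is.numeric(k_a) || length(k_a) != 1L ||
        !is.finite(k_a) || k_a <= 0)
      stop("oral route requires a positive `k_a` (h^-1)", call. = FALSE)
  } else {
    if (!is.null(k_a))
      stop("`k_a` has no meaning for the i.v. route; omit it", call. = FALSE)
    k_a <- NA_real_
  }
  structure(
    list(k_a = as.numeric(k_a), k_e = as.numeric(k_e),
         v_over_f = as.numeric(v_over_f), route = route),
    class = "tk_params"
  )
}

#' @export
print.tk_params <- function(x, ...) {
  cat("One-compartment TK parameters (", x$route, ")\n", sep = "")
  if (x$route == "oral")
    cat(sprintf("  k_a      = %.4g h^-1 (absorption)\n", x$k_a))
  cat(sprintf("  k_e      = %.4g h^-1 (elimination)\n", x$k_e))
  lbl <- if (x$route == "oral") "V/F" else "V"
  cat(sprintf("  %-8s = %.4g l kg^-1 bw\n", lbl, x$v_over_f))
  cat(sprintf("  elimination half-life = %.1f min\n", half_life(x$k_e)))
  invisible(x)
}

#' Dose specification
#'
#' Administered dose of active ingredient per kg body weight and its route.
#'
#' @param amount Dose, mg a.i. per kg body weight; positive.
#' @param route `"oral"` or `"iv"`.
#' @return An object of class `"dose_spec"`.
#' @export
dose_spec <- function(amount, route = c("oral", "iv")) {
  route <- match.arg(route)
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) ||
      amount <= 0)
    stop("`amount` must be a single positive dose (mg kg^-1 bw)",
         call. = FALSE)
  structure(list(amount = as.numeric(amount), route = route),
            class = "dose_spec")
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and non-negative (hours)", call. = FALSE)
  as.numeric(t)
}

#' Blood concentration after an intravenous bolus
#'
#' Monoexponential decay `C(t) = (dose / V) * exp(-k_e * t)` of the
#' one-compartment model.
#'
#' @param params A [tk_params()] object with `route = "iv"`.
#' @param dose A [dose_spec()] with `route = "iv"`.
#' @param t Time(s) after administration, hours; non-negative.
#' @return Concentration(s), ug ml^-1.
#' @export
iv_concentration <- function(params, dose, t) {
  stopifnot(inherits(params, "tk_params"), inherits(dose, "dose_spec"))
  if (params$route != "iv" || dose$route != "iv")
    stop("iv_concentration() requires i.v. parameters and dose",
         call. = FALSE)
  t <- check_time(t)
  (dose$amount / params$v_over_f) * exp(-params$k_e * t)
}

# Relative difference below which k_a and k_e are treated as equal and the
# removable singularity of the Bateman expression is replaced by its limit.
.bateman_eq_tol <- 1e-8

bateman <- function(scale, k_a, k_e, t) {
  if (abs(k_a - k_e) / k_e < .bateman_eq_tol) {
    k <- (k_a + k_e) / 2
    scale * k * t * exp(-k * t)
  } else {
    scale * (k_a / (k_a - k_e)) * (exp(-k_e * t) - exp(-k_a * t))
  }
}

#' Blood concentration after an oral dose
#'
#' First-order absorption with first-order elimination (Bateman curve):
#' `C(t) = dose/(V/F) * k_a/(k_a - k_e) * (exp(-k_e t) - exp(-k_a t))`.
#' When `k_a` and `k_e` coincide (relative difference below 1e-8) the
#' analytic limit `dose/(V/F) * k_a * t * exp(-k_a t)` is used instead of
#' the numerically unstable main branch.
#'
#' @inheritParams iv_concentration
#' @param params A [tk_params()] object with `route = "oral"`.
#' @param dose A [dose_spec()] with `route = "oral"`.
#' @return Concentration(s), ug ml^-1; zero at `t = 0`.
#' @export
oral_concentration <- function(params, dose, t) {
  stopifnot(inherits(params, "tk_params"), inherits(dose, "dose_spec"))
  if (params$route != "oral" || dose$route != "oral")
    stop("oral_concentration() requires oral parameters and dose",
         call. = FALSE)
  t <- check_time(t)
  bateman(dose$amount / params$v_over_f, params$k_a, params$k_e, t)
}

#' Half-life of a first-order rate constant, in minutes
#'
#' `60 * ln(2) / k` for a rate constant `k` in h^-1. Reported in minutes,
#' the convention used for absorption and elimination half-lives in rat
#' ADME summaries (e.g. k_e = 0.26 h^-1 gives 160.0 min).
#'
#' @param k Rate constant(s), h^-1; positive.
#' @return Half-life in minutes.
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("`k` must be positive (h^-1)", call. = FALSE)
  60 * log(2) / k
}

#' Time of maximum concentration for the oral curve
#'
#' `t_max = ln(k_a / k_e) / (k_a - k_e)`, the argmax of the Bateman curve;
#' symmetric under exchanging `k_a` and `k_e`. For `k_a == k_e` the
#' analytic limit `1 / k_a` is returned. For an i.v. bolus the maximum is
#' at `t = 0` (boundary of a monotone curve).
#'
#' @param params A [tk_params()] object.
#' @return Time of maximum concentration, hours.
#' @export
time_of_cmax <- function(params) {
  stopifnot(inherits(params, "tk_params"))
  if (params$route == "iv") return(0)
  ka <- params$k_a; ke <- params$k_e
  if (abs(ka - ke) / ke < .bateman_eq_tol) 1 / ka
  else log(ka / ke) / (ka - ke)
}

#' Maximum concentration and its time
#'
#' For the i.v. route this is `(C(0), 0)`; for the oral route the Bateman
#' maximum at [time_of_cmax()].
#'
#' @inheritParams iv_concentration
#' @return A list with elements `cmax` (ug ml^-1) and `t_max_h`.
#' @export
cmax <- function(params, dose) {
  tm <- time_of_cmax(params)
  cm <- if (params$route == "iv") iv_concentration(params, dose, 0)
        else oral_concentration(params, dose, tm)
  list(cmax = cm, t_max_h = tm)
}

#' Model (compartmental) area under the concentration-time curve
#'
#' The 0-to-infinity integral of the model curve: `dose / (V * k_e)` for
#' i.v., `dose / ((V/F) * k_e)` for oral. The absorption rate constant
#' cancels from the oral integral.
#'
#' @inheritParams iv_concentration
#' @param dose A [dose_spec()] matching the parameter route.
#' @return AUC, h ug ml^-1.
#' @export
model_auc <- function(params, dose) {
  stopifnot(inherits(params, "tk_params"), inherits(dose, "dose_spec"))
  if (params$route != dose$route)
    stop("parameter and dose routes differ", call. = FALSE)
  dose$amount / (params$v_over_f * params$k_e)
}
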