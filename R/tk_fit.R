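#' One subject's concentration-time series
#'
#' Bundles a subject's metadata, administered dose and blood
#' concentration-time observations. Sampling times must be strictly
#' increasing and non-negative; concentrations non-negative (zeros are
#' allowed and represent values censored below the limit of
#' quantification).
#'
#' @param subject_id Subject identifier (character).
#' @param sex `"male"` or `"female"`.
#' @param route `"oral"` or `"iv"`.
#' @param dose_mg_per_kg Administered dose, mg a.i. kg^-1 bw.
#' @param time_h Sampling times, hours.
#' @param conc_ug_per_ml Blood concentrations, ug ml^-1.
#' @param label Radiolabel position or other kinetically inert tag.
#' @param censored Optional logical vector flagging observations reported
#'   as zero because they fell below the limit of quantification.
#'
#' @return An object of class `"conc_series"`: a list with `subject_id`,
#'   `sex`, `route`, `label`, `dose` (a [dose_spec()]) and `observations`
#'   (a data frame with columns `time_h`, `conc_ug_per_ml`, `censored`).
#' @export
concentration_series <- function(subject_id, sex, route, dose_mg_per_kg,
                                 time_h, conc_ug_per_ml, label = "",
                                 censored = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  route <- match.arg(route, c("oral", "iv"))
  time_h <- as.numeric(time_h)
  conc <- as.numeric(conc_ug_per_ml)
  if (length(time_h) != length(conc))
    stop("`time_h` and `conc_ug_per_ml` lengths differ", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("sampling times must be finite and >= 0", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (is.null(censored)) censored <- conc == 0
  structure(
    list(subject_id = as.character(subject_id), sex = sex, route = route,
         label = as.character(label),
         dose = dose_spec(dose_mg_per_kg, route),
         observations = data.frame(time_h = time_h, conc_ug_per_ml = conc,
                                   censored = as.logical(censored))),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("Concentration series: subject %s (%s), %s %g mg kg^-1 bw%s\n",
              x$subject_id, x$sex, x$route, x$dose$amount,
              if (nzchar(x$label)) paste0(", label ", x$label) else ""))
  print(x$observations, row.names = FALSE)
  invisible(x)
}

# Log-linear terminal slope, curve-stripping and trapezoid-AUC starting
# values. Deterministic and derivative-free; used when the caller supplies
# no initial estimate.
init_one_compartment <- function(series) {
  obs <- series$observations
  pos <- obs[obs$conc_ug_per_ml > 0, ]
  if (nrow(pos) < 2L)
    stop("need at least two positive concentrations to initialise a fit",
         call. = FALSE)
  tail_n <- min(3L, nrow(pos))
  tl <- utils::tail(pos, tail_n)
  sl <- stats::coef(stats::lm(log(conc_ug_per_ml) ~ time_h, data = tl))
  ke0 <- max(-sl[[2]], 1e-3)
  auc0 <- auc_trapezoid(pos$time_h, pos$conc_ug_per_ml) +
    utils::tail(pos$conc_ug_per_ml, 1) / ke0  # log-tail extrapolation
  v0 <- max(series$dose$amount / (auc0 * ke0), 1e-6)
  if (series$route == "iv")
    return(tk_params(k_e = ke0, v_over_f = v0, route = "iv"))
  # method of residuals: strip the extrapolated terminal line from the
  # absorption-phase points and take the slope of the log residuals
  pre <- pos[pos$time_h < time_of_cmax_guess(pos), , drop = FALSE]
  resid <- exp(sl[[1]] - ke0 * pre$time_h) - pre$conc_ug_per_ml
  ok <- is.finite(resid) & resid > 0
  ka0 <- if (sum(ok) >= 2L) {
    s2 <- stats::coef(stats::lm(log(resid[ok]) ~ pre$time_h[ok]))[[2]]
    if (is.finite(s2) && s2 < 0) -s2 else 3 * ke0
  } else 3 * ke0
  ka0 <- max(ka0, 1.5 * ke0)  # start on the k_a > k_e branch
  tk_params(k_e = ke0, v_over_f = v0, k_a = ka0, route = "oral")
}

time_of_cmax_guess <- function(pos) {
  pos$time_h[which.max(pos$conc_ug_per_ml)]
}

#' Trapezoidal area under observed concentrations
#'
#' Linear-trapezoid AUC over the observed interval (no extrapolation).
#'
#' @param time_h Times, hours, strictly increasing.
#' @param conc_ug_per_ml Concentrations, ug ml^-1.
#' @return AUC, h ug ml^-1.
#' @export
auc_trapezoid <- function(time_h, conc_ug_per_ml) {
  if (length(time_h) < 2L) return(0)
  sum(diff(time_h) * (utils::head(conc_ug_per_ml, -1) +
                        utils::tail(conc_ug_per_ml, -1)) / 2)
}

predict_curve <- function(route, par, dose_amount, t) {
  if (route == "iv") (dose_amount / par[["v"]]) * exp(-par[["k_e"]] * t)
  else bateman(dose_amount / par[["v_over_f"]], par[["k_a"]], par[["k_e"]], t)
}

num_jacobian <- function(fn, par) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    up <- dn <- par
    up[j] <- par[j] + h; dn[j] <- max(par[j] - h, 1e-12)
    J[, j] <- (fn(up) - fn(dn)) / (up[j] - dn[j])
  }
  J
}

finish_fit <- function(series, model, par, predfun, t, y, w, keep_n_excluded,
                       converged, n_iter, obj_init, weighting) {
  n <- length(y); p <- length(par)
  pred <- predfun(par)
  wrss <- sum(w * (y - pred)^2)
  aic <- aic_score(n, p, wrss)
  J <- num_jacobian(predfun, par) * sqrt(w)
  se <- rep(NA_real_, p)
  cov_ok <- FALSE
  if (wrss == 0) {
    # exact interpolation (minpack reports it as info = 4): zero residual
    # variance, degenerate intervals
    se <- rep(0, p); cov_ok <- TRUE; converged <- TRUE
  } else if (n > p) {
    XtX <- crossprod(J)
    cv <- try(solve(XtX) * wrss / (n - p), silent = TRUE)
    if (!inherits(cv, "try-error") && all(is.finite(diag(cv))) &&
        all(diag(cv) >= 0)) {
      se <- sqrt(diag(cv)); cov_ok <- TRUE
    }
  }
  tq <- if (n > p) stats::qt(0.975, n - p) else NA_real_
  ci <- cbind(low = par - tq * se, high = par + tq * se)
  rownames(ci) <- names(par)
  structure(
    list(model = model, series = series,
         estimates = par, se = stats::setNames(se, names(par)), ci95 = ci,
         significant = stats::setNames(ci[, "low"] > 0, names(par)),
         wrss = wrss, aic = aic, n_obs = n, n_excluded = keep_n_excluded,
         df_residual = n - p, converged = converged && cov_ok,
         n_iter = n_iter, obj_init = obj_init, obj_final = wrss,
         weighting = weighting),
    class = "tk_fit"
  )
}

aic_score <- function(n, p, wrss) {
  if (wrss <= 0) {
    warning("perfect fit: WRSS is zero, AIC reported as -Inf")
    return(-Inf)
  }
  n * log(wrss) + 2 * p
}

#' Fit a one-compartment model to a concentration series
#'
#' Minimises the weighted residual sum of squares
#' `sum_i w_i (C_obs,i - C_pred,i)^2` by the Marquardt (damped
#' Gauss-Newton) method, with `w_i = 1 / C_obs,i` by default — reciprocal
#' weighting of the observed values, which is near-optimal when measurement
#' error is proportional to the concentration. Oral fits estimate
#' `(k_a, k_e, V/F)`; i.v. fits estimate `(k_e, V)`.
#'
#' Standard errors are asymptotic, from the inverse weighted Gauss-Newton
#' Hessian at the optimum, and 95% confidence intervals use the Student-t
#' quantile at `n - p` degrees of freedom. A parameter is flagged
#' non-significant when its interval includes zero.
#'
#' The oral curve is invariant under exchanging `k_a` and `k_e` with a
#' compensating rescaling of `V/F` (flip-flop kinetics), so the returned
#' solution is normalised to the conventional branch `k_a > k_e`.
#'
#' Observations equal to zero (censored below the limit of quantification)
#' are excluded under reciprocal weighting, where their weight is
#' undefined; the count is reported in `n_excluded`.
#'
#' @param series A [concentration_series()].
#' @param init Optional [tk_params()] starting values; by default derived
#'   from the terminal log-linear slope, the method of residuals and the
#'   trapezoidal AUC.
#' @param weighting `"inverse_observed"` (default) or `"uniform"`.
#' @param max_iter Maximum Marquardt iterations.
#'
#' @return An object of class `"tk_fit"` with elements `estimates`, `se`,
#'   `ci95`, `significant`, `wrss`, `aic`, `n_obs`, `n_excluded`,
#'   `converged`, `n_iter` and the fitted [tk_params()] accessible via
#'   [fitted_params()]. Non-convergent fits are returned (with
#'   `converged = FALSE`), never silently dropped.
#' @export
fit_one_compartment <- function(series, init = NULL,
                                weighting = c("inverse_observed", "uniform"),
                                max_iter = 200L) {
  stopifnot(inherits(series, "conc_series"))
  weighting <- match.arg(weighting)
  obs <- series$observations
  keep <- if (weighting == "inverse_observed") obs$conc_ug_per_ml > 0
          else rep(TRUE, nrow(obs))
  t <- obs$time_h[keep]; y <- obs$conc_ug_per_ml[keep]
  w <- if (weighting == "inverse_observed") 1 / y else rep(1, length(y))
  p <- if (series$route == "oral") 3L else 2L
  if (length(y) < p + 1L)
    stop(sprintf("need at least %d usable observations for a %d-parameter fit",
                 p + 1L, p), call. = FALSE)
  if (is.null(init)) init <- init_one_compartment(series)
  stopifnot(inherits(init, "tk_params"), init$route == series$route)
  par0 <- if (series$route == "oral")
    c(k_a = init$k_a, k_e = init$k_e, v_over_f = init$v_over_f)
  else c(k_e = init$k_e, v = init$v_over_f)
  predfun <- function(par) predict_curve(series$route, par,
                                         series$dose$amount, t)
  resfun <- function(par) sqrt(w) * (y - predfun(par))
  obj_init <- sum(resfun(par0)^2)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = rep(1e-8, p), fn = resfun,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  par <- fit$par
  if (series$route == "oral" && par[["k_a"]] < par[["k_e"]]) {
    # flip-flop normalisation: identical curve on the k_a > k_e branch
    par <- c(k_a = par[["k_e"]], k_e = par[["k_a"]],
             v_over_f = par[["v_over_f"]] * par[["k_e"]] / par[["k_a"]])
  }
  finish_fit(series, "one_compartment", par, predfun, t, y, w,
             keep_n_excluded = sum(!keep),
             converged = fit$info %in% 1:3, n_iter = fit$niter,
             obj_init = obj_init, weighting = weighting)
}

#' Kinetic parameters of a converged one-compartment fit
#'
#' @param fit A `"tk_fit"` from [fit_one_compartment()].
#' @return A [tk_params()] object.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "tk_fit"))
  if (fit$model != "one_compartment")
    stop("fitted_params() is defined for one-compartment fits", call. = FALSE)
  est <- fit$estimates
  if (fit$series$route == "oral")
    tk_params(k_e = est[["k_e"]], v_over_f = est[["v_over_f"]],
              k_a = est[["k_a"]], route = "oral")
  else tk_params(k_e = est[["k_e"]], v_over_f = est[["v"]], route = "iv")
}

#' @export
print.tk_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, subject %s): %s after %d iterations\n",
              gsub("_", "-", x$model), x$series$route, x$series$subject_id,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    ci_low = x$ci95[, "low"], ci_high = x$ci95[, "high"],
                    significant = x$significant)
  print(signif(tab[1:4], 4))
  cat(sprintf("WRSS = %.4g, AIC = %.2f, n = %d (%d excluded)\n",
              x$wrss, x$aic, x$n_obs, x$n_excluded))
  invisible(x)
}

#' Akaike information criterion of a fit
#'
#' `AIC = n * ln(WRSS) + 2p`, the convention of compartmental PK software,
#' where WRSS is the weighted residual sum of squares and `p` the number of
#' fitted parameters. Only differences between models fitted to the same
#' data under the same weighting are meaningful; lower is better.
#'
#' @param fit A `"tk_fit"`.
#' @return The AIC score (`-Inf` with a warning for a perfect fit).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "tk_fit"))
  aic_score(fit$n_obs, length(fit$estimates), fit$wrss)
}

#' Fit a two-compartment comparator model
#'
#' The richer model used to confirm by AIC that one compartment suffices:
#' a biexponential disposition `A exp(-l1 t) + B exp(-l2 t)` for i.v.
#' data, or the same disposition with first-order absorption
#' `A exp(-l1 t) + B exp(-l2 t) - (A + B) exp(-k_a t)` for oral data
#' (C(0) = 0). Fitted under the same weighting scheme as
#' [fit_one_compartment()] so that [compute_aic()] can rank the two models.
#'
#' @inheritParams fit_one_compartment
#' @return A `"tk_fit"` with `model = "two_compartment"`.
#' @export
fit_two_compartment <- function(series,
                                weighting = c("inverse_observed", "uniform"),
                                max_iter = 200L) {
  stopifnot(inherits(series, "conc_series"))
  weighting <- match.arg(weighting)
  obs <- series$observations
  keep <- if (weighting == "inverse_observed") obs$conc_ug_per_ml > 0
          else rep(TRUE, nrow(obs))
  t <- obs$time_h[keep]; y <- obs$conc_ug_per_ml[keep]
  w <- if (weighting == "inverse_observed") 1 / y else rep(1, length(y))
  base <- init_one_compartment(series)
  if (series$route == "iv") {
    p <- 4L
    if (length(y) < p + 1L)
      stop("need at least 5 usable observations for a biexponential fit",
           call. = FALSE)
    c0 <- series$dose$amount / base$v_over_f
    par0 <- c(A = 0.7 * c0, B = 0.3 * c0,
              l1 = 3 * base$k_e, l2 = 0.5 * base$k_e)
    predfun <- function(par)
      par[["A"]] * exp(-par[["l1"]] * t) + par[["B"]] * exp(-par[["l2"]] * t)
  } else {
    p <- 5L
    if (length(y) < p + 1L)
      stop("need at least 6 usable observations for an oral two-compartment fit",
           call. = FALSE)
    cm <- bateman(series$dose$amount / base$v_over_f, base$k_a, base$k_e,
                  log(base$k_a / base$k_e) / (base$k_a - base$k_e))
    par0 <- c(k_a = base$k_a, A = cm, B = 0.3 * cm,
              l1 = 1.5 * base$k_e, l2 = 0.5 * base$k_e)
    predfun <- function(par)
      par[["A"]] * exp(-par[["l1"]] * t) + par[["B"]] * exp(-par[["l2"]] * t) -
      (par[["A"]] + par[["B"]]) * exp(-par[["k_a"]] * t)
  }
  resfun <- function(par) sqrt(w) * (y - predfun(par))
  obj_init <- sum(resfun(par0)^2)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = rep(1e-8, p), fn = resfun,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  finish_fit(series, "two_compartment", fit$par, predfun, t, y, w,
             keep_n_excluded = sum(!keep),
             converged = fit$info %in% 1:3, n_iter = fit$niter,
             obj_init = obj_init, weighting = weighting)
}

#' Relative oral bioavailability from dose-normalised AUC ratio
#'
#' `F = (AUC_po / dose_po) / (AUC_iv / dose_iv)`: the fraction of an oral
#' dose reaching systemic circulation, relative to the i.v. reference. The
#' oral AUC is computed per individual; the i.v. reference AUC is
#' conventionally a group mean. `F` may exceed 1 only through estimation
#' noise, in which case it is flagged.
#'
#' @param auc_po Oral AUC, h ug ml^-1 (one individual).
#' @param dose_po Oral dose, mg kg^-1 bw.
#' @param auc_iv Reference i.v. AUC, h ug ml^-1.
#' @param dose_iv i.v. dose, mg kg^-1 bw.
#' @return An object of class `"bioavailability"`: list with `f`,
#'   `above_one` flag and the four inputs.
#' @export
relative_bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  vals <- c(auc_po = auc_po, dose_po = dose_po,
            auc_iv = auc_iv, dose_iv = dose_iv)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("AUCs and doses must be positive; got ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "),
         call. = FALSE)
  f <- (auc_po / dose_po) / (auc_iv / dose_iv)
  structure(list(f = f, above_one = f > 1, auc_po = auc_po,
                 auc_iv_reference = auc_iv, dose_po = dose_po,
                 dose_iv = dose_iv),
            class = "bioavailability")
}

#' @export
print.bioavailability <- function(x, ...) {
  cat(sprintf("Relative bioavailability F = %.3f%s\n", x$f,
              if (x$above_one) " (exceeds 1: estimation noise)" else ""))
  cat(sprintf("  AUC p.o. %.4g at %g mg kg^-1; AUC i.v. %.4g at %g mg kg^-1\n",
              x$auc_po, x$dose_po, x$auc_iv_reference, x$dose_iv))
  invisible(x)
}

#' Summarise fitted parameters by group
#'
#' Mean, SD (n - 1 denominator), minimum and maximum of the kinetic
#' parameters, derived half-lives (minutes) and compartmental AUC per
#' group of subjects, in the layout of a study summary table. Groups with
#' a single converged fit report an absent (NA) SD; empty groups are
#' skipped with a warning. Non-convergent fits are counted and excluded
#' from the statistics, never silently dropped from the report.
#'
#' @param fits List of one-compartment `"tk_fit"` objects.
#' @param by Metadata fields defining the groups, a subset of
#'   `c("route", "dose", "label", "sex")`.
#' @return A data frame, one row per group x parameter, with columns
#'   `n`, `n_converged`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_group <- function(fits, by = c("route", "dose", "label", "sex")) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "tk_fit")))
  by <- match.arg(by, c("route", "dose", "label", "sex"), several.ok = TRUE)
  rows <- lapply(fits, function(f) {
    s <- f$series
    pr <- if (f$converged) fitted_params(f) else NULL
    data.frame(
      route = s$route, dose = s$dose$amount, label = s$label, sex = s$sex,
      converged = f$converged,
      k_a = if (f$converged) pr$k_a else NA_real_,
      k_e = if (f$converged) pr$k_e else NA_real_,
      v_over_f = if (f$converged) pr$v_over_f else NA_real_,
      auc = if (f$converged) model_auc(pr, s$dose) else NA_real_,
      t_half_a_min = if (f$converged && !is.na(pr$k_a)) half_life(pr$k_a)
                     else NA_real_,
      t_half_e_min = if (f$converged) half_life(pr$k_e) else NA_real_)
  })
  df <- do.call(rbind, rows)
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  params <- c("k_a", "k_e", "v_over_f", "auc", "t_half_a_min", "t_half_e_min")
  out <- lapply(levels(key), function(g) {
    sub <- df[key == g, , drop = FALSE]
    conv <- sub[sub$converged, , drop = FALSE]
    if (nrow(conv) == 0L) {
      warning("group ", g, " has no converged fits; skipped")
      return(NULL)
    }
    do.call(rbind, lapply(params, function(pn) {
      v <- conv[[pn]]; v <- v[is.finite(v)]
      if (length(v) == 0L) return(NULL)
      cbind(sub[1L, by, drop = FALSE],
            data.frame(parameter = pn, n = nrow(sub),
                       n_converged = nrow(conv), mean = mean(v),
                       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                       min = min(v), max = max(v)))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
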