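#' Published group-level toxicokinetic summaries for thiamethoxam in rats
#'
#' Group means and standard deviations of the one-compartment parameters
#' (k_a, k_e in h^-1; AUC in h ug ml^-1; bioavailability F) for the ten
#' treatment-group x sex combinations of the rat ADME study design:
#' i.v. 0.5 mg kg^-1 bw and oral 0.5 / 100 mg kg^-1 bw under two
#' radiolabel positions (`thiazol`, `oxadiazin`), three males and three
#' females per group. These published summaries are the package's default
#' population for synthetic-study generation and the source of the pooled
#' worst-case simulation constants.
#'
#' The apparent volume term is not published; `vof_mean` is derived from
#' the compartmental identity `V/F = dose / (AUC * k_e)` applied to the
#' group means, and its between-subject spread defaults to a 30% CV.
#'
#' @return Data frame, one row per group x sex, with columns `route`,
#'   `dose`, `label`, `sex`, `n`, `ka_mean`, `ka_sd`, `ke_mean`, `ke_sd`,
#'   `auc_mean`, `auc_sd`, `f_mean`, `f_sd`, `vof_mean`, `vof_cv`.
#' @export
reference_group_means <- function() {
  df <- data.frame(
    route = c("iv", "iv", rep("oral", 8)),
    dose = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 100, 100, 100, 100),
    label = c("thiazol", "thiazol", "thiazol", "thiazol", "oxadiazin",
              "oxadiazin", "thiazol", "thiazol", "oxadiazin", "oxadiazin"),
    sex = rep(c("male", "female"), 5),
    n = 3L,
    ka_mean = c(NA, NA, 2.1, 2.3, 1.20, 3.2, 0.78, 1.6, 0.71, 2.00),
    ka_sd = c(NA, NA, 1.62, 1.93, 0.93, 0.29, 0.32, 0.71, 0.73, 1.37),
    ke_mean = c(0.26, 0.50, 0.23, 0.23, 0.34, 0.25, 0.28, 0.18, 0.25, 0.19),
    ke_sd = c(0.02, 0.11, 0.09, 0.13, 0.034, 0.06, 0.12, 0.06, 0.11, 0.06),
    auc_mean = c(2.30, 1.63, 1.49, 1.56, 1.30, 1.03, 342, 278, 359, 294),
    auc_sd = c(0.19, 0.38, 0.15, 0.53, 0.015, 0.13, 80, 59, 50, 24),
    f_mean = c(NA, NA, 0.62, 0.94, 0.67, 0.75, 0.84, 0.94, 0.80, 0.96),
    f_sd = c(NA, NA, 0.11, 0.27, 0.01, 0.12, 0.21, 0.22, 0.11, 0.11)
  )
  df$vof_mean <- df$dose / (df$auc_mean * df$ke_mean)
  df$vof_cv <- 0.3
  df
}

#' Pooled rate constants used to parameterise burden simulations
#'
#' Pools the published group means into the four simulation inputs:
#' mean absorption rate constant for low- and high-dose oral groups and
#' mean elimination rate constant for i.v. and orally exposed rats.
#' Pooling averages the group means with equal weight (each group has the
#' same n). Values are returned unrounded; the conventional reporting
#' rounds k_a to one decimal and k_e to one (i.v.) or two (oral) decimals,
#' giving the worst-case pair (high k_a = 2.2, low k_e = 0.25 h^-1) used
#' by [preset_scenario()].
#'
#' @param ref Group summary table, by default [reference_group_means()].
#' @return List with `ka_low_dose`, `ka_high_dose`, `ke_iv`, `ke_oral`
#'   (h^-1).
#' @export
pooled_rate_constants <- function(ref = reference_group_means()) {
  oral <- ref[ref$route == "oral", ]
  list(
    ka_low_dose = mean(oral$ka_mean[oral$dose == 0.5]),
    ka_high_dose = mean(oral$ka_mean[oral$dose == 100]),
    ke_iv = mean(ref$ke_mean[ref$route == "iv"]),
    ke_oral = mean(oral$ke_mean)
  )
}

#' Synthetic ADME study design
#'
#' Describes the structure of a synthetic rat ADME study: treatment
#' groups, blood-sampling schedule, limit of quantification and the
#' proportional measurement noise. The default reproduces the reference
#' design: i.v. 0.5 mg kg^-1 bw (one label) plus oral 0.5 and
#' 100 mg kg^-1 bw under two labels, 3 males + 3 females per group,
#' sampling at 0.25, 0.5, 1, 2, 4, 8, 12, 24 and 48 h.
#'
#' @param groups Data frame with columns `route`, `dose`, `label`,
#'   `n_males`, `n_females`; defaults to the reference design derived
#'   from [reference_group_means()].
#' @param sampling_times_h Strictly increasing sampling times, hours.
#' @param loq Limit of quantification, ug ml^-1; simulated concentrations
#'   below it are reported as zero and flagged censored. The default
#'   0.002 makes late low-dose samples fall below LOQ, as observed.
#' @param noise_cv Coefficient of variation of the proportional
#'   (lognormal) measurement noise; default 0.10.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(groups = NULL,
                         sampling_times_h = c(0.25, 0.5, 1, 2, 4, 8, 12,
                                              24, 48),
                         loq = 0.002, noise_cv = 0.10) {
  if (is.null(groups)) {
    ref <- reference_group_means()
    g <- unique(ref[c("route", "dose", "label")])
    groups <- data.frame(g, n_males = 3L, n_females = 3L)
  }
  stopifnot(is.data.frame(groups),
            all(c("route", "dose", "label", "n_males", "n_females") %in%
                  names(groups)))
  if (any(groups$n_males < 1L) || any(groups$n_females < 1L))
    stop("each group needs at least one animal per sex", call. = FALSE)
  sampling_times_h <- as.numeric(sampling_times_h)
  if (any(diff(sampling_times_h) <= 0) || any(sampling_times_h < 0))
    stop("sampling times must be non-negative and strictly increasing",
         call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  rownames(groups) <- NULL
  structure(list(groups = groups, sampling_times_h = sampling_times_h,
                 loq = loq, noise_cv = noise_cv),
            class = "study_design")
}

#' Population distributions for synthetic individuals
#'
#' Per-group between-subject distributions of the kinetic parameters.
#' Individuals are drawn from lognormal distributions moment-matched to
#' the supplied natural-scale mean and SD (a zero SD collapses to the
#' mean exactly). Defaults come from [reference_group_means()].
#'
#' @param table Data frame with columns `route`, `dose`, `label`, `sex`,
#'   `ka_mean`, `ka_sd`, `ke_mean`, `ke_sd`, `vof_mean` and either
#'   `vof_sd` or `vof_cv`.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(table = reference_group_means()) {
  need <- c("route", "dose", "label", "sex", "ke_mean", "ke_sd", "vof_mean")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  if (!"vof_sd" %in% names(table)) {
    cv <- if ("vof_cv" %in% names(table)) table$vof_cv else 0.3
    table$vof_sd <- cv * table$vof_mean
  }
  bad <- with(table, ke_mean <= 0 | vof_mean <= 0 |
                (route == "oral" & (is.na(ka_mean) | ka_mean <= 0)))
  if (any(bad))
    stop("non-positive distribution moments in rows ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  structure(list(table = table), class = "population_spec")
}

# lognormal draw moment-matched to a natural-scale mean and SD
rlnorm_mm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw synthetic individuals from a population
#'
#' Samples one row per animal of the design from the group's lognormal
#' parameter distributions. Deterministic given `seed`.
#'
#' @param spec A [population_spec()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `sex`, `route`, `dose`,
#'   `label`, `k_a`, `k_e`, `v_over_f` (one row per animal).
#' @export
sample_individuals <- function(spec, design, seed) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(design, "study_design"))
  set.seed(as.integer(seed))
  tab <- spec$table
  out <- list()
  for (g in seq_len(nrow(design$groups))) {
    grp <- design$groups[g, ]
    for (sx in c("male", "female")) {
      n <- if (sx == "male") grp$n_males else grp$n_females
      row <- tab[tab$route == grp$route & tab$dose == grp$dose &
                   tab$label == grp$label & tab$sex == sx, ]
      if (nrow(row) != 1L)
        stop(sprintf("no population row for group %s/%g/%s/%s",
                     grp$route, grp$dose, grp$label, sx), call. = FALSE)
      ka <- if (grp$route == "oral") rlnorm_mm(n, row$ka_mean, row$ka_sd)
            else rep(NA_real_, n)
      ke <- rlnorm_mm(n, row$ke_mean, row$ke_sd)
      vof <- rlnorm_mm(n, row$vof_mean, row$vof_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%g_%s_%s_%d", grp$route, grp$dose,
                             grp$label, substr(sx, 1, 1), seq_len(n)),
        sex = sx, route = grp$route, dose = grp$dose, label = grp$label,
        k_a = ka, k_e = ke, v_over_f = vof)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

individual_params <- function(ind) {
  if (ind$route == "oral")
    tk_params(k_e = ind$k_e, v_over_f = ind$v_over_f, k_a = ind$k_a,
              route = "oral")
  else tk_params(k_e = ind$k_e, v_over_f = ind$v_over_f, route = "iv")
}

#' Simulate one subject's concentration series
#'
#' Evaluates the closed-form one-compartment curve for the individual at
#' the design's sampling times, multiplies by lognormal measurement noise
#' with the design's CV, and censors values below the limit of
#' quantification to zero (flagged in the `censored` column).
#'
#' @param individual One row of [sample_individuals()] output (or any list
#'   with fields `subject_id`, `sex`, `route`, `dose`, `label`, `k_a`,
#'   `k_e`, `v_over_f`).
#' @param design A [study_design()].
#' @param seed Optional integer seed (omit when called inside a larger
#'   generation loop that already seeded the RNG).
#' @return A [concentration_series()].
#' @export
generate_series <- function(individual, design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- individual_params(individual)
  dose <- dose_spec(individual$dose, individual$route)
  t <- design$sampling_times_h
  true <- if (pr$route == "oral") oral_concentration(pr, dose, t)
          else iv_concentration(pr, dose, t)
  noisy <- true * rlnorm_mm(length(t), 1, design$noise_cv)
  cens <- noisy < design$loq
  noisy[cens] <- 0
  concentration_series(individual$subject_id, individual$sex,
                       individual$route, individual$dose,
                       time_h = t, conc_ug_per_ml = noisy,
                       label = individual$label, censored = cens)
}

#' Simulate an equilibrium tissue-residue panel
#'
#' Tissue concentrations as partition coefficient times the blood
#' concentration (instant-equilibrium assumption), with proportional
#' lognormal noise. Without noise every tissue is exactly proportional to
#' blood, so their Pearson correlation is 1 by construction; with
#' realistic noise the correlation stays high, the property that licenses
#' treating blood as representative of whole-body burden.
#'
#' @param individual As in [generate_series()].
#' @param partition_coeffs Named numeric vector of tissue:blood ratios.
#' @param times_h Sampling times, hours.
#' @param noise_cv Proportional noise CV; default 0.
#' @param seed Optional integer seed.
#' @return Data frame with columns `tissue`, `time_h`, `conc`, `blood`.
#' @export
generate_tissue_panel <- function(individual, partition_coeffs, times_h,
                                  noise_cv = 0, seed = NULL) {
  if (any(partition_coeffs <= 0))
    stop("partition coefficients must be positive", call. = FALSE)
  if (is.null(names(partition_coeffs)))
    names(partition_coeffs) <- paste0("tissue", seq_along(partition_coeffs))
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- individual_params(individual)
  dose <- dose_spec(individual$dose, individual$route)
  blood <- if (pr$route == "oral") oral_concentration(pr, dose, times_h)
           else iv_concentration(pr, dose, times_h)
  out <- lapply(names(partition_coeffs), function(ts) {
    conc <- partition_coeffs[[ts]] * blood *
      rlnorm_mm(length(blood), 1, noise_cv)
    data.frame(tissue = ts, time_h = times_h, conc = conc, blood = blood)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a full synthetic ADME study
#'
#' Draws individuals for every design group and simulates each subject's
#' concentration series, returning the study as a flat data frame in the
#' package CSV dialect (one row per observation) that round-trips through
#' [write_concentration_csv()] / [read_concentration_csv()] losslessly.
#' Fully deterministic given `seed`.
#'
#' @param spec A [population_spec()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `sex`, `route`, `label`,
#'   `dose_mg_per_kg`, `time_h`, `conc_ug_per_ml`, `censored`, plus an
#'   attribute `individuals` holding the generating parameters.
#' @export
generate_study <- function(spec = population_spec(),
                           design = study_design(), seed = 1L) {
  inds <- sample_individuals(spec, design, seed)
  rows <- lapply(seq_len(nrow(inds)), function(i) {
    s <- generate_series(inds[i, ], design)
    data.frame(subject_id = s$subject_id, sex = s$sex, route = s$route,
               label = s$label, dose_mg_per_kg = s$dose$amount,
               time_h = s$observations$time_h,
               conc_ug_per_ml = s$observations$conc_ug_per_ml,
               censored = s$observations$censored)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "individuals") <- inds
  out
}
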