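#' Default planted fixed effects per metric
#'
#' One row per tract-averaged metric with the intercept and the group
#' (patient vs control), timepoint (after surgery vs baseline), age
#' (per year, centred at 12) and gender (male vs female) fixed effects used
#' by the cohort simulator. Magnitudes are typical of optic-radiation
#' tract-averaged values in a paediatric cohort; effects reported as
#' non-significant in such cohorts are set to zero, so the implied
#' sign pattern is: group — diffusivities (MD, AD, RD, muMD, Long, Trans)
#' up, muFA down, FA and ODEntropy null; timepoint — AD, FA, Long, muFA,
#' ODEntropy down, RD and Trans up, MD and muMD null.
#'
#' @return a tibble with columns `metric`, `intercept`, `group`,
#'   `timepoint`, `age`, `gender`.
#' @export
cohort_effect_defaults <- function() {
  tibble::tribble(
    ~metric,     ~intercept, ~group,    ~timepoint, ~age,      ~gender,
    "MD",        7.94e-4,    3.01e-5,   0,          -5.29e-6,  1.48e-5,
    "AD",        1.23e-3,    4.13e-5,   -3.95e-5,   -4.18e-6,  2.40e-5,
    "RD",        5.81e-4,    2.74e-5,   1.65e-5,    -5.92e-6,  1.21e-5,
    "FA",        4.32e-1,    0,         -2.80e-2,   3.76e-3,   0,
    "muMD",      1.07e-3,    3.98e-5,   0,          -6.04e-6,  1.62e-5,
    "Long",      2.68e-3,    7.96e-5,   -4.12e-5,   -9.39e-6,  3.38e-5,
    "Trans",     2.61e-4,    1.97e-5,   1.03e-5,    -4.27e-6,  9.82e-6,
    "muFA",      8.86e-1,    -4.86e-3,  -6.58e-3,   1.66e-3,   0,
    "ODEntropy", 4.65e-1,    0,         -4.37e-2,   4.50e-3,   0)
}

#' Specification of a synthetic metric cohort
#'
#' Defines the generative model for a patient/control cohort of
#' tract-averaged metrics: per-metric fixed effects plus Gaussian random
#' effects. The noise scales are *relative*: each is multiplied by the
#' metric's |intercept|, so one set of scales works across metrics whose
#' natural units differ by orders of magnitude (diffusivities in mm^2/s vs
#' unitless anisotropies).
#'
#' @param n_patients,n_controls subject counts (each >= 2). Defaults mirror
#'   a 43-patient / 50-control paediatric cohort.
#' @param effects effect table as in [cohort_effect_defaults()].
#' @param subject_sd,hemisphere_sd,residual_sd relative noise scales
#'   (>= 0): subject-specific intercept, within-subject hemisphere
#'   deviation, and residual.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 43, n_controls = 50,
                            effects = cohort_effect_defaults(),
                            subject_sd = 0.01, hemisphere_sd = 0.005,
                            residual_sd = 0.01, seed = 1L) {
  if (n_patients < 2 || n_controls < 2) stop("counts must be >= 2")
  if (any(c(subject_sd, hemisphere_sd, residual_sd) < 0))
    stop("noise scales must be >= 0")
  need <- c("metric", "intercept", "group", "timepoint", "age", "gender")
  if (!all(need %in% names(effects))) stop("`effects` is missing columns")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 effects = effects, subject_sd = subject_sd,
                 hemisphere_sd = hemisphere_sd, residual_sd = residual_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a long-format cohort metric table
#'
#' One row per subject x timepoint x hemisphere x metric. Patients carry
#' both timepoints and ipsi/contra hemisphere coding; controls carry only
#' the baseline timepoint with left/right coding. Each value is
#' `intercept + group + timepoint + age*(age - 12) + gender + b_subject +
#' b_hemisphere + residual`, where the `b` terms and the residual are
#' independent Gaussians with the spec's (relative) standard deviations.
#' Fixed seed implies an identical table across runs.
#'
#' @param spec a [cohort_sim_spec()].
#' @return a tibble with columns `subject`, `group`, `timepoint`,
#'   `hemisphere`, `age`, `gender`, `metric`, `value`.
#' @export
simulate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    subjects <- tibble::tibble(
      subject = c(sprintf("P%02d", seq_len(spec$n_patients)),
                  sprintf("C%02d", seq_len(spec$n_controls))),
      group = rep(c("patient", "control"),
                  c(spec$n_patients, spec$n_controls)),
      age = round(runif(spec$n_patients + spec$n_controls, 5, 19), 1),
      gender = ifelse(rbinom(spec$n_patients + spec$n_controls, 1, 0.5) == 1,
                      "M", "F"))
    design <- dplyr::bind_rows(
      tidyr::expand_grid(subject = subjects$subject[subjects$group == "patient"],
                         timepoint = c("baseline", "after_surgery"),
                         hemisphere = c("ipsi", "contra")),
      tidyr::expand_grid(subject = subjects$subject[subjects$group == "control"],
                         timepoint = "baseline",
                         hemisphere = c("left", "right")))
    design <- dplyr::left_join(design, subjects, by = "subject")
    eff <- spec$effects
    names(eff)[names(eff) != "metric"] <-
      paste0("e_", names(eff)[names(eff) != "metric"])
    rows <- tidyr::expand_grid(design, metric = eff$metric)
    rows <- dplyr::left_join(rows, eff, by = "metric")
    # random effects, drawn per subject x metric and subject x hemisphere x metric
    bsub <- rows |>
      dplyr::distinct(.data$subject, .data$metric, .data$e_intercept) |>
      dplyr::mutate(b_subject = rnorm(dplyr::n(),
                                      sd = spec$subject_sd * abs(.data$e_intercept)))
    bhem <- rows |>
      dplyr::distinct(.data$subject, .data$hemisphere, .data$metric,
                      .data$e_intercept) |>
      dplyr::mutate(b_hemi = rnorm(dplyr::n(),
                                   sd = spec$hemisphere_sd * abs(.data$e_intercept)))
    rows <- rows |>
      dplyr::left_join(bsub[c("subject", "metric", "b_subject")],
                       by = c("subject", "metric")) |>
      dplyr::left_join(bhem[c("subject", "hemisphere", "metric", "b_hemi")],
                       by = c("subject", "hemisphere", "metric")) |>
      dplyr::mutate(
        value = .data$e_intercept +
          .data$e_group * (.data$group == "patient") +
          .data$e_timepoint * (.data$timepoint == "after_surgery") +
          .data$e_age * (.data$age - 12) +
          .data$e_gender * (.data$gender == "M") +
          .data$b_subject + .data$b_hemi +
          rnorm(dplyr::n(), sd = spec$residual_sd * abs(.data$e_intercept)))
    tibble::as_tibble(rows[c("subject", "group", "timepoint", "hemisphere",
                             "age", "gender", "metric", "value")])
  })
}
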