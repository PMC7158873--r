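or_metrics <- c("MD", "AD", "RD", "FA", "muMD", "Long", "Trans", "muFA",
                "ODEntropy")

#' Assemble the long-format metric observation table
#'
#' Joins per-subject/timepoint/hemisphere tract-averaged metric values with
#' subject covariates and validates the hemisphere encoding: patients use
#' ipsilateral/contralateral (relative to the resection), controls use
#' left/right. Rows whose subject lacks covariates are dropped with a
#' warning.
#'
#' @param averages tibble with columns `subject`, `group`, `timepoint`,
#'   `hemisphere`, `metric`, `value`.
#' @param covariates tibble with columns `subject`, `age`, `gender`.
#' @return a tibble, one row per subject x timepoint x hemisphere x metric.
#' @export
build_long_table <- function(averages, covariates) {
  need <- c("subject", "group", "timepoint", "hemisphere", "metric", "value")
  if (!all(need %in% names(averages)))
    stop("`averages` must have columns ", paste(need, collapse = ", "))
  bad_p <- averages$group == "patient" &
    !averages$hemisphere %in% c("ipsi", "contra")
  bad_c <- averages$group == "control" &
    !averages$hemisphere %in% c("left", "right")
  if (any(bad_p) || any(bad_c))
    stop("hemisphere must be ipsi/contra for patients and left/right for controls")
  out <- dplyr::inner_join(averages, covariates[c("subject", "age", "gender")],
                           by = "subject")
  out <- out[!is.na(out$age) & !is.na(out$gender), , drop = FALSE]
  n_dropped <- nrow(averages) - nrow(out)
  if (n_dropped > 0)
    warning(n_dropped, " rows dropped for missing covariates")
  tibble::as_tibble(out[c("subject", "group", "timepoint", "hemisphere",
                          "age", "gender", "metric", "value")])
}

#' Fit the linear mixed-effects model for one metric
#'
#' REML fit of `value ~ age + gender + group + timepoint` with a random
#' subject intercept and a hemisphere intercept nested in subject,
#' `(1 | subject) + (1 | subject:hemisphere)`. Reference levels: control,
#' baseline, female — so the group coefficient is patient minus control and
#' the timepoint coefficient is after-surgery minus baseline. If the nested
#' hemisphere term makes the fit singular it is dropped and the refit is
#' flagged.
#'
#' @param table a long table from [build_long_table()] or
#'   [simulate_cohort_table()].
#' @param metric which metric to fit (one of the table's `metric` values).
#' @param hemisphere_re include the nested hemisphere random term
#'   (default `TRUE`).
#' @return an object of class `or_lmm` wrapping the \pkg{lmerTest} fit,
#'   with elements `model`, `metric`, `dropped_hemisphere_re`.
#' @export
fit_mixed_model <- function(table, metric, hemisphere_re = TRUE) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(d)) stop("no rows for metric ", metric)
  n_per_group <- tapply(d$subject, d$group, function(s) length(unique(s)))
  if (length(n_per_group) < 2L || any(n_per_group < 2L))
    stop("need >= 2 subjects in each of the patient and control groups")
  tp <- unique(d$timepoint[d$group == "patient"])
  if (!all(c("baseline", "after_surgery") %in% tp))
    stop("patients must contribute both timepoints")
  d$group <- factor(d$group, levels = c("control", "patient"))
  d$timepoint <- factor(d$timepoint, levels = c("baseline", "after_surgery"))
  d$gender <- factor(d$gender, levels = c("F", "M"))
  form <- value ~ age + gender + group + timepoint + (1 | subject) +
    (1 | subject:hemisphere)
  dropped <- FALSE
  if (!hemisphere_re) {
    form <- value ~ age + gender + group + timepoint + (1 | subject)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = d, REML = TRUE)))
  if (hemisphere_re && lme4::isSingular(fit, tol = 1e-5)) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ age + gender + group + timepoint + (1 | subject),
                     data = d, REML = TRUE)))
    dropped <- TRUE
  }
  structure(list(model = fit, metric = metric,
                 dropped_hemisphere_re = dropped),
            class = "or_lmm")
}

#' @export
print.or_lmm <- function(x, ...) {
  cat("<or_lmm> metric ", x$metric,
      if (x$dropped_hemisphere_re) " (hemisphere RE dropped: singular)", "\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' Broom-style accessors for mixed-model fits
#'
#' `tidy()` returns one row per fixed effect with the estimate, standard
#' error, t-value and Satterthwaite degrees of freedom / p-value from
#' \pkg{lmerTest}; `glance()` returns one-row fit summaries.
#'
#' @param x an `or_lmm` from [fit_mixed_model()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.or_lmm <- function(x, ...) {
  cf <- coef(summary(x$model))
  out <- tibble::tibble(metric = x$metric, term = rownames(cf),
                        estimate = cf[, "Estimate"],
                        std.error = cf[, "Std. Error"],
                        statistic = cf[, "t value"])
  if ("df" %in% colnames(cf)) {
    out$df <- cf[, "df"]
    out$p.value <- cf[, "Pr(>|t|)"]
  } else {
    out$df <- NA_real_
    out$p.value <- ifelse(abs(out$statistic) > 2, 0, 1)  # |t| > 2 fallback
  }
  out
}

#' @rdname tidy.or_lmm
#' @export
glance.or_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble::tibble(metric = x$metric,
                 nobs = stats::nobs(x$model),
                 n_subjects = length(unique(x$model@frame$subject)),
                 sigma = stats::sigma(x$model),
                 sd_subject = vc$sdcor[vc$grp == "subject"][1],
                 sd_hemisphere = if (any(vc$grp == "subject:hemisphere"))
                   vc$sdcor[vc$grp == "subject:hemisphere"][1] else NA_real_,
                 REMLcrit = stats::deviance(x$model, REML = TRUE),
                 dropped_hemisphere_re = x$dropped_hemisphere_re)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Significance sign pattern across metrics
#'
#' Classifies the group and timepoint fixed effects of each metric's mixed
#' model as increased (`"up"`), decreased (`"down"`) or null (`"none"`) at
#' significance level `alpha`, reproducing the familiar arrow-table summary
#' of group and surgery effects.
#'
#' @param fits a list of `or_lmm` objects (one per metric), or a tibble as
#'   returned by binding `tidy()` rows.
#' @param alpha significance level (p < alpha calls an arrow).
#' @return a tibble with columns `metric`, `effect` (`group`/`timepoint`),
#'   `estimate`, `p.value`, `call` and `symbol` (up/down arrows, en dash).
#' @export
sign_pattern <- function(fits, alpha = 0.05) {
  td <- if (inherits(fits, "data.frame")) tibble::as_tibble(fits)
        else dplyr::bind_rows(lapply(fits, tidy))
  td <- td[td$term %in% c("grouppatient", "timepointafter_surgery"), ]
  td$effect <- ifelse(td$term == "grouppatient", "group", "timepoint")
  td$call <- ifelse(td$p.value < alpha,
                    ifelse(td$estimate > 0, "up", "down"), "none")
  td$symbol <- c(up = "↑", down = "↓", none = "–")[td$call]
  tibble::as_tibble(td[c("metric", "effect", "estimate", "p.value", "call",
                         "symbol")])
}
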