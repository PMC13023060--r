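# The three study designs. All models use listwise deletion and report
# the number of rows actually analyzed (n_used), since per-analysis
# missingness makes the residual dfs vary between result tables.

model_result <- function(term, estimate, df1, df2, p, partial_eta_sq = NA,
                         r_sq = NA, n_used, beta_std = NA) {
  data.frame(term = term, estimate = estimate, df1 = df1, df2 = df2,
             p = p, partial_eta_sq = partial_eta_sq, r_sq = r_sq,
             n_used = n_used, beta_std = beta_std,
             stringsAsFactors = FALSE)
}

# guard against (near-)collinear designs: error names the offending columns
check_collinearity <- function(mm, kappa_max = 1e8) {
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  sds <- apply(mm, 2, sd)
  if (any(sds == 0))
    stop_connseg("constant predictor column(s): %s",
                 paste(colnames(mm)[sds == 0], collapse = ", "))
  kn <- kappa(scale(mm), exact = TRUE)
  if (kn > kappa_max) {
    cc <- abs(cor(mm))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop_connseg("collinear design (condition number %.3g); worst pair: %s, %s",
                 kn, colnames(mm)[worst[1]], colnames(mm)[worst[2]])
  }
  invisible(kn)
}

#' Cross-sectional regression of a baseline FC measure on symptom severity
#'
#' Ordinary least squares with the connectivity measure as outcome and
#' baseline BDI-II, age, sex and education (ISCED) as predictors. The
#' headline quantity is the standardized coefficient of the BDI-II term.
#'
#' @param feature Numeric vector, one FC value per subject at baseline.
#' @param cohort Cohort data frame with `bdi_t0`, `age`, `sex`, `isced`.
#' @return A one-row model-result data frame for the BDI-II term:
#'   `estimate` and `beta_std` are the standardized coefficient, `r_sq`
#'   the model fit, `n_used` the rows analyzed after listwise deletion.
#' @export
cross_sectional_regression <- function(feature, cohort) {
  d <- data.frame(y = feature, bdi = cohort$bdi_t0, age = cohort$age,
                  sex = factor(cohort$sex), isced = cohort$isced)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0 || sd(d$y) == 0) {
    warning("constant or empty outcome; returning NA result", call. = FALSE)
    return(model_result(term = "bdi_t0", estimate = NA_real_, df1 = 1,
                        df2 = NA, p = NA_real_, n_used = nrow(d)))
  }
  fit <- lm(y ~ bdi + age + sex + isced, data = d)
  check_collinearity(stats::model.matrix(fit))
  sm <- summary(fit)
  co <- sm$coefficients["bdi", ]
  beta_std <- co["Estimate"] * sd(d$bdi) / sd(d$y)
  model_result(term = "bdi_t0", estimate = unname(beta_std), df1 = 1,
               df2 = fit$df.residual, p = unname(co["Pr(>|t|)"]),
               r_sq = sm$r.squared, n_used = nrow(d),
               beta_std = unname(beta_std))
}

#' Two-timepoint repeated-measures ANCOVA interaction test
#'
#' Tests the time-by-moderator interaction in a repeated-measures ANCOVA
#' with a within-subject pair (`y_t0`, `y_t1`), sex as between-subject
#' factor and age, education and inter-scan interval as covariates. With
#' exactly two levels of the within factor this F-test is identical to
#' the squared t of the moderator in a regression of the difference score
#' `y_t1 - y_t0` on the same terms, which is how it is computed here.
#'
#' Serves both longitudinal designs: `y` = FC with moderator
#' `delta_bdi` (symptom change explaining connectivity change), and `y` =
#' BDI-II with moderator FC at baseline (baseline connectivity predicting
#' symptom change); see [rm_time_by_deltabdi()] and [rm_time_by_fc0()].
#'
#' @param y_t0,y_t1 Within-subject measurements at the two visits.
#' @param moderator Covariate whose interaction with time is tested.
#' @param cohort Cohort data frame with `sex`, `age`, `isced`, `interval`.
#' @param term Label for the result row.
#' @return One-row model-result data frame: `estimate` is the interaction
#'   F with `df1 = 1`, `df2 = n_used - 6`; `partial_eta_sq` is
#'   `F / (F + df2)`; `beta_std` the signed standardized moderator
#'   coefficient on the difference score (carries the direction).
#' @export
rm_ancova_interaction <- function(y_t0, y_t1, moderator, cohort,
                                  term = "time:moderator") {
  d <- data.frame(delta = y_t1 - y_t0, sex = factor(cohort$sex),
                  age = cohort$age, isced = cohort$isced,
                  interval = cohort$interval, mod = moderator)
  d <- d[complete.cases(d), , drop = FALSE]
  n_par <- 6L  # intercept, sex, age, isced, interval, moderator
  if (nrow(d) <= n_par)
    stop_connseg("only %d complete rows for %d parameters", nrow(d), n_par)
  if (var(d$delta) == 0)
    return(model_result(term = term, estimate = 0, df1 = 1,
                        df2 = nrow(d) - n_par, p = 1, partial_eta_sq = 0,
                        n_used = nrow(d), beta_std = 0))
  if (var(d$mod) == 0) {
    warning("constant moderator; returning NA result", call. = FALSE)
    return(model_result(term = term, estimate = NA_real_, df1 = 1,
                        df2 = nrow(d) - n_par, p = NA_real_,
                        n_used = nrow(d)))
  }
  fit <- lm(delta ~ sex + age + isced + interval + mod, data = d)
  co <- summary(fit)$coefficients["mod", ]
  f <- unname(co["t value"]^2)
  df2 <- fit$df.residual
  model_result(term = term, estimate = f, df1 = 1, df2 = df2,
               p = unname(co["Pr(>|t|)"]),
               partial_eta_sq = f / (f + df2), n_used = nrow(d),
               beta_std = unname(co["Estimate"]) * sd(d$mod) / sd(d$delta))
}

#' @describeIn rm_ancova_interaction FC at both visits as the
#'   within-subject pair, symptom change as moderator.
#' @param fc_t0,fc_t1 Connectivity measure at the two visits.
#' @export
rm_time_by_deltabdi <- function(fc_t0, fc_t1, cohort) {
  rm_ancova_interaction(fc_t0, fc_t1, cohort$delta_bdi, cohort,
                        term = "time:delta_bdi")
}

#' @describeIn rm_ancova_interaction BDI-II at both visits as the
#'   within-subject pair, baseline FC as moderator.
#' @export
rm_time_by_fc0 <- function(fc_t0, cohort) {
  rm_ancova_interaction(cohort$bdi_t0, cohort$bdi_t1, fc_t0, cohort,
                        term = "time:fc_t0")
}

#' Baseline-severity-adjusted regression of symptom change on baseline FC
#'
#' OLS of `delta_bdi` on the baseline FC measure, age, sex, education,
#' inter-scan interval *and baseline BDI-II*; shows whether baseline
#' connectivity carries predictive information beyond baseline severity
#' (and is immune to pure regression-to-the-mean in the symptom scores).
#'
#' @param fc_t0 Baseline connectivity measure, one value per subject.
#' @param cohort Cohort data frame with `delta_bdi`, `age`, `sex`,
#'   `isced`, `interval`, `bdi_t0`.
#' @return One-row model-result data frame for the FC term: `estimate` is
#'   the t statistic, `beta_std` the standardized coefficient, `r_sq` the
#'   adjusted R-squared.
#' @export
baseline_adjusted_regression <- function(fc_t0, cohort) {
  d <- data.frame(delta = cohort$delta_bdi, fc = fc_t0, age = cohort$age,
                  sex = factor(cohort$sex), isced = cohort$isced,
                  interval = cohort$interval, bdi0 = cohort$bdi_t0)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 8 || sd(d$fc) == 0) {
    warning("constant FC measure or too few rows; returning NA result",
            call. = FALSE)
    return(model_result(term = "fc_t0", estimate = NA_real_, df1 = 1,
                        df2 = NA, p = NA_real_, n_used = nrow(d)))
  }
  fit <- lm(delta ~ fc + age + sex + isced + interval + bdi0, data = d)
  check_collinearity(stats::model.matrix(fit))
  sm <- summary(fit)
  co <- sm$coefficients["fc", ]
  model_result(term = "fc_t0", estimate = unname(co["t value"]), df1 = 1,
               df2 = fit$df.residual, p = unname(co["Pr(>|t|)"]),
               r_sq = sm$adj.r.squared, n_used = nrow(d),
               beta_std = unname(co["Estimate"]) * sd(d$fc) / sd(d$delta))
}
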