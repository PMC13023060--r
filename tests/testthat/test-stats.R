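# Cross-sectional and longitudinal designs, corrections, domain scores,
# robustness and ROI drill-down.

test_that("cross-sectional regression matches a normal-equations oracle", {
  co <- toy_cohort(12, seed = 41)
  set.seed(42)
  y <- rnorm(12)
  co$bdi_t0 <- sample(0:19, 12, TRUE)
  res <- cross_sectional_regression(y, co)
  # independent solve of the normal equations
  x <- cbind(1, co$bdi_t0, co$age, co$sex == "male", co$isced)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  rss <- sum((y - x %*% beta)^2)
  sigma2 <- rss / (12 - 5)
  se <- sqrt(sigma2 * solve(t(x) %*% x)[2, 2])
  tval <- beta[2] / se
  expect_equal(res$beta_std, unname(beta[2] * sd(co$bdi_t0) / sd(y)),
               tolerance = 1e-12)
  expect_equal(res$p, unname(2 * pt(-abs(tval), 12 - 5)), tolerance = 1e-12)
  tss <- sum((y - mean(y))^2)
  expect_equal(res$r_sq, unname(1 - rss / tss), tolerance = 1e-12)
  expect_equal(res$n_used, 12)
  expect_equal(res$df2, 7)
})

test_that("cross-sectional null keeps its nominal rejection rate", {
  co <- toy_cohort(200, seed = 51)
  co$bdi_t0 <- sample(0:19, 200, TRUE)
  set.seed(52)
  ps <- replicate(100, cross_sectional_regression(rnorm(200), co)$p)
  expect_gt(mean(ps < 0.05), 0)   # not degenerate at 0 rejections... loose
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)       # roughly uniform, mean ~ 0.5
  expect_lt(mean(ps), 0.65)
})

test_that("a planted standardized coefficient is recovered at large n", {
  co <- toy_cohort(4000, seed = 61)
  co$bdi_t0 <- sample(0:19, 4000, TRUE)
  set.seed(62)
  zb <- scale(co$bdi_t0)[, 1]
  za <- scale(co$age)[, 1]
  y <- -0.13 * zb + 0.1 * za + rnorm(4000, 0, sqrt(1 - 0.13^2 - 0.1^2))
  res <- cross_sectional_regression(y, co)
  expect_lt(abs(res$beta_std - (-0.13)), 0.05)
  expect_lt(res$p, 0.001)
})

test_that("collinear designs error naming the offending columns", {
  co <- toy_cohort(30, seed = 71)
  co$bdi_t0 <- sample(0:19, 30, TRUE)
  co$isced <- co$bdi_t0        # exact collinearity
  expect_error(cross_sectional_regression(rnorm(30), co),
               "collinear|constant")
})

test_that("interaction F equals the aov repeated-measures oracle", {
  co <- toy_cohort(10, seed = 81)
  set.seed(82)
  y0 <- rnorm(10)
  mod <- rnorm(10)
  y1 <- y0 + 0.8 * mod + rnorm(10, 0, 0.6)
  res <- rm_ancova_interaction(y0, y1, mod, co)
  ora <- aov_interaction_oracle(y0, y1, mod, co)
  expect_equal(res$estimate, ora$f, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_equal(res$df2, res$n_used - 6)
})

test_that("no within-subject change gives a zero interaction F", {
  co <- toy_cohort(15, seed = 91)
  y0 <- rnorm(15)
  res <- rm_ancova_interaction(y0, y0, rnorm(15), co)
  expect_equal(res$estimate, 0)
  expect_equal(res$p, 1)
  expect_equal(res$partial_eta_sq, 0)
})

test_that("partial eta squared from F equals the sums-of-squares route", {
  co <- toy_cohort(40, seed = 101)
  set.seed(102)
  y0 <- rnorm(40); y1 <- rnorm(40); mod <- rnorm(40)
  res <- rm_ancova_interaction(y0, y1, mod, co)
  d <- data.frame(delta = y1 - y0, sex = factor(co$sex), age = co$age,
                  isced = co$isced, interval = co$interval, mod = mod)
  full <- lm(delta ~ sex + age + isced + interval + mod, data = d)
  red <- lm(delta ~ sex + age + isced + interval, data = d)
  ss_err <- sum(residuals(full)^2)
  ss_eff <- sum(residuals(red)^2) - ss_err
  expect_equal(res$partial_eta_sq, ss_eff / (ss_eff + ss_err),
               tolerance = 1e-12)
})

test_that("too-small samples are refused", {
  co <- toy_cohort(6)
  expect_error(rm_ancova_interaction(rnorm(6), rnorm(6), rnorm(6), co),
               "complete rows")
})

test_that("a planted moderator effect is detected at the cohort scale", {
  co <- toy_cohort(243, seed = 111)
  set.seed(112)
  mod <- rnorm(243)
  y0 <- rnorm(243)
  y1 <- y0 - 0.5 * mod + rnorm(243)
  res <- rm_ancova_interaction(y0, y1, mod, co)
  expect_lt(res$beta_std, -0.2)
  expect_lt(res$p, 0.001)
  expect_gt(res$partial_eta_sq, 0.05)
})

test_that("design-B rejection rate under the null stays near alpha", {
  co <- toy_cohort(243, seed = 121)
  co$bdi_t0 <- sample(0:19, 243, TRUE)
  co$bdi_t1 <- pmax(co$bdi_t0 + sample(-3:3, 243, TRUE), 0)
  set.seed(122)
  ps <- replicate(500, rm_time_by_fc0(rnorm(243), co)$p)
  rate <- mean(ps < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rate - 0.05), se3)
})

test_that("baseline-adjusted regression matches a brute-force OLS oracle", {
  co <- toy_cohort(20, seed = 131)
  set.seed(132)
  co$bdi_t0 <- sample(0:19, 20, TRUE)
  co$delta_bdi <- sample(-5:5, 20, TRUE)
  fc <- rnorm(20)
  res <- baseline_adjusted_regression(fc, co)
  x <- cbind(1, fc, co$age, co$sex == "male", co$isced, co$interval,
             co$bdi_t0)
  beta <- solve(t(x) %*% x, t(x) %*% co$delta_bdi)
  rss <- sum((co$delta_bdi - x %*% beta)^2)
  se <- sqrt(rss / (20 - 7) * solve(t(x) %*% x)[2, 2])
  expect_equal(res$estimate, unname(beta[2] / se), tolerance = 1e-10)
  expect_equal(res$beta_std,
               unname(beta[2] * sd(fc) / sd(co$delta_bdi)),
               tolerance = 1e-10)
})

test_that("pure regression-to-the-mean leaves the FC term null", {
  co <- toy_cohort(500, seed = 141)
  set.seed(142)
  co$bdi_t0 <- sample(0:19, 500, TRUE)
  # change depends only on baseline severity, never on connectivity
  co$delta_bdi <- round(-0.5 * scale(co$bdi_t0)[, 1] * 3 + rnorm(500, 0, 3))
  fc <- rnorm(500)
  res <- baseline_adjusted_regression(fc, co)
  expect_lt(abs(res$beta_std), 0.15)
})

test_that("an FC effect survives adjustment for baseline severity", {
  co <- toy_cohort(243, seed = 151)
  set.seed(152)
  co$bdi_t0 <- sample(0:19, 243, TRUE)
  fc <- rnorm(243)
  co$delta_bdi <- round(-0.4 * scale(co$bdi_t0)[, 1] * 3 - 1.2 * fc +
                          rnorm(243, 0, 2.5))
  res <- baseline_adjusted_regression(fc, co)
  expect_lt(res$beta_std, -0.15)
  expect_lt(res$p, 0.01)
})

test_that("the Bonferroni threshold over seven networks is 0.007", {
  expect_equal(round(bonferroni_threshold(0.05, 7), 3), 0.007)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  thr <- bonferroni_threshold(0.05, 7)
  expect_false(flag_bonferroni(thr, 0.05, 7))       # boundary not flagged
  expect_true(flag_bonferroni(thr - 1e-9, 0.05, 7))
  expect_false(flag_bonferroni(NA_real_, 0.05, 7))
})

test_that("BH adjustment matches the hand step-up and ignores input order", {
  expect_equal(bh_fdr(0.03)$q, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  set.seed(161)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)$q[perm], bh_fdr(p[perm])$q)
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("domain scores partition the BDI total", {
  expect_equal(unlist(domain_scores(rep(0L, 21))),
               c(cognitive = 0, affective = 0, somatic = 0))
  toy_map <- list(cognitive = 1:7, affective = 8:14, somatic = 15:21)
  expect_equal(unlist(domain_scores(rep(1L, 21), toy_map)),
               c(cognitive = 7, affective = 7, somatic = 7))
  set.seed(171)
  items <- matrix(sample(0:3, 21 * 25, TRUE), 25, 21)
  ds <- domain_scores(items)
  expect_equal(rowSums(ds), rowSums(items))
  expect_error(domain_scores(rep(0L, 21),
                             list(a = 1:10, b = 10:21)),  # overlap
               "exactly once")
  expect_error(domain_scores(rep(0L, 21), list(a = 1:10, b = 11:20)),
               "exactly once")
})

test_that("domain sub-scores from simulated items enter the designs", {
  scheme <- seven_net_scheme(1)
  sim <- simulate_cohort(scheme, n_subjects = 60, keep_bold = FALSE,
                         seed = 231)
  co <- sim$cohort
  d0 <- domain_scores(as.matrix(co[, sprintf("bdi_item%02d_t0", 1:21)]))
  d1 <- domain_scores(as.matrix(co[, sprintf("bdi_item%02d_t1", 1:21)]))
  expect_equal(rowSums(d0), as.numeric(co$bdi_t0))
  expect_equal(rowSums(d1), as.numeric(co$bdi_t1))
  set.seed(232)
  fc <- rnorm(60)
  for (dom in names(d0)) {
    res <- rm_ancova_interaction(d0[[dom]], d1[[dom]], fc, co,
                                 term = sprintf("time:fc [%s]", dom))
    expect_true(is.finite(res$estimate))
    expect_true(res$p > 0 && res$p <= 1)
  }
})

test_that("robustness with a non-matching rule reproduces the primary fit", {
  co <- toy_cohort(60, seed = 181)
  set.seed(182)
  co$bdi_t0 <- sample(0:10, 60, TRUE)  # nobody in the 14-19 band
  co$bdi_t1 <- co$bdi_t0 + sample(-2:2, 60, TRUE)
  res <- robustness_reanalysis(rnorm(60), co, rule = "exclude_mild")
  expect_equal(res$n_excluded, 0)
  expect_identical(res$primary, res$reanalysis)
})

test_that("robustness bookkeeping drops exactly the banded rows", {
  co <- toy_cohort(80, seed = 191)
  set.seed(192)
  co$bdi_t0 <- sample(0:19, 80, TRUE)
  co$bdi_t1 <- pmin(pmax(co$bdi_t0 + sample(-3:3, 80, TRUE), 0), 19)
  n_mild <- sum(co$bdi_t0 >= 14 & co$bdi_t0 <= 19)
  fc <- rnorm(80)
  res <- robustness_reanalysis(fc, co, rule = "exclude_mild")
  expect_equal(res$n_excluded, n_mild)
  expect_equal(res$reanalysis$n_used, 80 - n_mild)
  res0 <- robustness_reanalysis(fc, co, rule = "exclude_zero")
  expect_equal(res0$n_excluded, sum(co$bdi_t0 == 0))
})

test_that("excluding a planted outlier subgroup nulls a spurious effect", {
  co <- toy_cohort(108, seed = 201)
  set.seed(202)
  co$bdi_t0 <- c(sample(1:10, 100, TRUE), rep(18L, 8))
  # bulk: no FC-change relation; outliers: extreme FC and extreme change
  fc <- c(rnorm(100), rnorm(8, 5, 0.3))
  co$bdi_t1 <- c(pmax(co$bdi_t0[1:100] + sample(-2:2, 100, TRUE), 0),
                 co$bdi_t0[101:108] + 12L)
  co$delta_bdi <- co$bdi_t1 - co$bdi_t0
  res <- robustness_reanalysis(fc, co, rule = "custom",
                               custom = function(x) x$bdi_t0 >= 14)
  expect_lt(res$primary$p, 0.001)
  expect_gt(res$primary$beta_std, 0.4)
  expect_gt(res$reanalysis$p, 0.05)
  expect_lt(abs(res$reanalysis$beta_std), 0.2)
  expect_equal(res$n_excluded, 8)
})

test_that("ROI drill-down recovers a right-lateralized planted effect", {
  scheme <- make_parcel_scheme(c(VN = 2, SMN = 2, DAN = 2, VAN = 6,
                                 LN = 2, CN = 2, DMN = 2))
  co <- toy_cohort(243, seed = 211)
  set.seed(212)
  co$bdi_t0 <- sample(0:15, 243, TRUE)
  van <- which(scheme$network == "VAN")
  right_van <- van[scheme$hemisphere[van] == "R"]
  driver <- rnorm(243)
  node_fc <- matrix(rnorm(243 * nrow(scheme), 0.3, 0.05), 243)
  # only right-hemisphere VAN nodes carry the driver signal
  node_fc[, right_van] <- 0.3 + 0.05 * matrix(
    sqrt(0.5) * driver + sqrt(0.5) * rnorm(243 * length(right_van)),
    243, length(right_van))
  co$bdi_t1 <- pmax(co$bdi_t0 + round(-1.5 * driver + rnorm(243, 0, 2)), 0)
  co$delta_bdi <- co$bdi_t1 - co$bdi_t0
  res <- posthoc_roi(node_fc, scheme, "VAN", co)
  expect_equal(nrow(res$roi), 6)           # ROI count = network size
  hemi <- res$hemisphere
  p_r <- hemi$p[hemi$hemisphere == "R"]
  p_l <- hemi$p[hemi$hemisphere == "L"]
  # the planted signal lives on the right: orders of magnitude separation
  expect_lt(p_r, 1e-4)
  expect_gt(p_l, 100 * p_r)
  expect_true(all(res$roi$significant[res$roi$hemisphere == "R"]))
  expect_false(any(res$roi$significant[res$roi$hemisphere == "L"]))
})

test_that("an all-null ROI family yields an empty BH rejection set", {
  scheme <- make_parcel_scheme(c(VN = 2, SMN = 2, DAN = 2, VAN = 6,
                                 LN = 2, CN = 2, DMN = 2))
  co <- toy_cohort(150, seed = 221)
  set.seed(222)
  co$bdi_t0 <- sample(0:15, 150, TRUE)
  co$bdi_t1 <- pmax(co$bdi_t0 + sample(-2:2, 150, TRUE), 0)
  co$delta_bdi <- co$bdi_t1 - co$bdi_t0
  node_fc <- matrix(rnorm(150 * nrow(scheme), 0.3, 0.05), 150)
  res <- posthoc_roi(node_fc, scheme, "VAN", co)
  expect_false(any(res$roi$significant))
  expect_true(all(res$roi$q >= res$roi$p))
})
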