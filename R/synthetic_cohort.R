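# Synthetic cohort generator. Defaults emulate the study conditions the
# analysis assumes: 243 subjects seen twice about 3.7 years apart, 296
# retained volumes of network-structured, temporally autocorrelated BOLD,
# subthreshold depression scores (mean ~4, SD ~3.6, totals < 20) that are
# stable across visits, and an optional planted linear effect of baseline
# target-network coupling on symptom change.

#' Block-structured spatial covariance aligned to a parcellation
#'
#' Unit-variance covariance matrix with correlation `within` (scalar or
#' named per-network vector) inside each network block and `between`
#' elsewhere.
#'
#' @param scheme A [parcel_scheme()].
#' @param within Within-network correlation level(s).
#' @param between Between-network correlation level.
#' @param variance Common diagonal variance.
#' @return N x N covariance matrix.
#' @export
block_covariance <- function(scheme, within = 0.3, between = 0.05,
                             variance = 1) {
  nets <- as.character(scheme$network)
  n <- nrow(scheme)
  if (length(within) == 1 && is.null(names(within)))
    within <- setNames(rep(within, nlevels(scheme$network)),
                       levels(scheme$network))
  same <- outer(nets, nets, "==")
  sigma <- matrix(between, n, n)
  wvec <- within[nets]
  sigma[same] <- (outer(wvec, wvec, function(a, b) (a + b) / 2))[same]
  diag(sigma) <- 1
  sigma * variance
}

#' Simulate a parcellated BOLD run
#'
#' Draws an N x `n_volumes` matrix from a stationary AR(1) Gaussian
#' process whose spatial (cross-node) covariance is the requested block
#' structure; the first `n_discard` volumes are then dropped, mirroring
#' the usual discarding of pre-equilibrium volumes.
#'
#' @param scheme A [parcel_scheme()].
#' @param n_volumes Number of volumes to simulate (default 300).
#' @param n_discard Leading volumes to drop (default 4, leaving 296).
#' @param within,between Block correlation levels, see [block_covariance()].
#' @param sigma Optional full covariance matrix overriding the block spec;
#'   must be positive semi-definite.
#' @param ar_coef Lag-1 temporal autocorrelation (default 0.3).
#' @param tr_seconds Sampling interval.
#' @param seed Optional integer seed.
#' @return A [bold_matrix()] with `ncol = n_volumes - n_discard`.
#' @export
simulate_bold <- function(scheme, n_volumes = 300, n_discard = 4,
                          within = 0.3, between = 0.05, sigma = NULL,
                          ar_coef = 0.3, tr_seconds = 2.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_discard >= n_volumes)
    stop_connseg("n_discard (%d) must be smaller than n_volumes (%d)",
                 n_discard, n_volumes)
  sigma <- sigma %||% block_covariance(scheme, within, between)
  n <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    # allow exactly singular PSD matrices via eigendecomposition
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stop_connseg("covariance specification is not positive semi-definite")
    ch <- t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n))
  }
  innov <- t(ch) %*% matrix(rnorm(n * n_volumes), n, n_volumes)
  x <- innov
  scale_new <- sqrt(1 - ar_coef^2)
  for (t in seq_len(n_volumes)[-1])
    x[, t] <- ar_coef * x[, t - 1] + scale_new * innov[, t]
  x <- x[, (n_discard + 1):n_volumes, drop = FALSE]
  rownames(x) <- scheme$label
  bold_matrix(x, tr_seconds = tr_seconds)
}

#' Specify a plantable connectivity-to-symptom-change effect
#'
#' @param network Target network whose baseline within-network coupling
#'   drives symptom change.
#' @param magnitude Absolute standardized effect (SDs of symptom change
#'   per SD of baseline coupling); `>= 0`.
#' @param sign Direction; the default `-1` plants *lower* baseline
#'   coupling leading to *increasing* symptoms.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(network = "VAN", magnitude = 0.2, sign = -1) {
  stopifnot(magnitude >= 0, sign %in% c(-1, 1))
  structure(list(network = network, magnitude = magnitude, sign = sign),
            class = "effect_spec")
}

# allocate a BDI total over 21 items scored 0-3, uniformly over capacity
distribute_bdi_items <- function(total) {
  items <- integer(21)
  for (p in seq_len(total)) {
    open <- which(items < 3L)
    pick <- if (length(open) == 1) open else sample(open, 1)
    items[pick] <- items[pick] + 1L
  }
  items
}

#' Simulate a two-visit cohort with BOLD data and a plantable effect
#'
#' Per subject and network, a within-network coupling level is drawn with
#' between-subject variance at the first visit and re-drawn at follow-up
#' with correlation `stability`, emulating stable individual differences.
#' Symptom change (`delta_bdi`) is a linear function of the *target*
#' network's baseline coupling (standardized effect `effect$magnitude`
#' with sign `effect$sign`), a small age effect, and Gaussian noise scaled
#' so that the two visits' totals correlate at about `bdi_retest`.
#' BDI-II totals are drawn from a truncated negative-binomial (mean
#' `bdi_mean`, SD `bdi_sd`, totals < 20) and decomposed into 21 items
#' scored 0-3, so totals always equal the item sums.
#'
#' @param scheme A [parcel_scheme()].
#' @param n_subjects Cohort size (default 243).
#' @param effect An [effect_spec()].
#' @param n_volumes,n_discard,ar_coef,between BOLD settings, see
#'   [simulate_bold()].
#' @param within_mean,within_sd Mean and between-subject SD of the
#'   within-network coupling.
#' @param stability Correlation of a network's coupling across visits.
#' @param bdi_mean,bdi_sd,bdi_retest Symptom-score distribution targets.
#' @param age_beta Standardized age effect on symptom change.
#' @param covariates Named list overriding covariate distribution
#'   parameters (`age_mean`, `age_sd`, `age_range`, `isced_mean`,
#'   `isced_sd`, `interval_mean`, `interval_sd`, `demtect_mean`,
#'   `demtect_sd`, `demtect_range`, `p_female`, `p_flags`).
#' @param keep_bold If `FALSE`, BOLD matrices are not generated (fast path
#'   when only the cohort table is needed).
#' @param bold_visits Visits for which BOLD is generated (default both);
#'   designs that only use baseline connectomes can skip `"t1"`.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   cohorts.
#' @return List with `cohort` (data frame), `bold` (per-subject list of
#'   `t0`/`t1` [bold_matrix()] objects, or `NULL`), `coupling` (n x K x 2
#'   array of latent coupling levels) and `params`.
#' @export
simulate_cohort <- function(scheme, n_subjects = 243,
                            effect = effect_spec(),
                            n_volumes = 300, n_discard = 4, ar_coef = 0.3,
                            within_mean = 0.3, within_sd = 0.08,
                            between = 0.05, stability = 0.7,
                            bdi_mean = 4.05, bdi_sd = 3.58,
                            bdi_retest = 0.568, age_beta = 0.05,
                            covariates = list(), keep_bold = TRUE,
                            bold_visits = c("t0", "t1"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- modifyList(list(age_mean = 67.05, age_sd = 6.55,
                        age_range = c(55, 84), isced_mean = 6.76,
                        isced_sd = 1.93, interval_mean = 3.7,
                        interval_sd = 0.7, demtect_mean = 14.8,
                        demtect_sd = 2.35, demtect_range = c(9, 18),
                        p_female = 0.5,
                        p_flags = c(psychiatric = 0, antidepressant = 0,
                                    neurological = 0)),
                   covariates)
  nets <- levels(scheme$network)
  k <- length(nets)
  if (!effect$network %in% nets)
    stop_connseg("effect network '%s' not in scheme", effect$network)
  n <- n_subjects

  age <- rnorm_trunc(n, cv$age_mean, cv$age_sd, cv$age_range[1],
                     cv$age_range[2])
  sex <- ifelse(rbinom(n, 1, cv$p_female) == 1, "female", "male")
  isced <- clamp(round(rnorm(n, cv$isced_mean, cv$isced_sd)), 1, 9)
  interval <- rnorm_trunc(n, cv$interval_mean, cv$interval_sd, 0.5, Inf)
  demtect <- clamp(round(rnorm(n, cv$demtect_mean, cv$demtect_sd)),
                   cv$demtect_range[1], cv$demtect_range[2])
  flags <- matrix(vapply(cv$p_flags, function(p) rbinom(n, 1, p) == 1,
                         logical(n)), nrow = n,
                  dimnames = list(NULL, names(cv$p_flags)))

  # latent per-network coupling, clamped inside the PSD-safe range
  c_lo <- between + 0.02
  c_hi <- 0.9
  c0 <- matrix(rnorm(n * k, within_mean, within_sd), n, k,
               dimnames = list(NULL, nets))
  c1 <- within_mean + stability * (c0 - within_mean) +
    sqrt(1 - stability^2) * matrix(rnorm(n * k, 0, within_sd), n, k)
  c0 <- clamp(c0, c_lo, c_hi)
  c1 <- clamp(c1, c_lo, c_hi)

  # baseline totals: truncated negative binomial matching mean/SD targets
  nb_size <- bdi_mean^2 / max(bdi_sd^2 - bdi_mean, 0.1)
  bdi_t0 <- stats::rnbinom(n, size = nb_size, mu = bdi_mean)
  over <- which(bdi_t0 > 19)
  while (length(over)) {
    bdi_t0[over] <- stats::rnbinom(length(over), size = nb_size,
                                   mu = bdi_mean)
    over <- over[bdi_t0[over] > 19]
  }

  sd_delta <- bdi_sd * sqrt(2 * (1 - bdi_retest))
  z_coupling <- (c0[, effect$network] - within_mean) / within_sd
  z_age <- (age - cv$age_mean) / cv$age_sd
  noise_sd <- sd_delta *
    sqrt(max(0, 1 - effect$magnitude^2 - age_beta^2))
  delta_raw <- effect$sign * effect$magnitude * sd_delta * z_coupling +
    age_beta * sd_delta * z_age + rnorm(n, 0, noise_sd)
  bdi_t1 <- clamp(bdi_t0 + round(delta_raw), 0, 63)

  items_t0 <- t(vapply(bdi_t0, distribute_bdi_items, integer(21)))
  items_t1 <- t(vapply(bdi_t1, distribute_bdi_items, integer(21)))
  colnames(items_t0) <- sprintf("bdi_item%02d_t0", 1:21)
  colnames(items_t1) <- sprintf("bdi_item%02d_t1", 1:21)

  cohort <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                       age = age, sex = sex, isced = isced,
                       interval = interval, demtect = demtect,
                       flag_psychiatric = flags[, "psychiatric"],
                       flag_antidepressant = flags[, "antidepressant"],
                       flag_neurological = flags[, "neurological"],
                       bdi_t0 = as.integer(bdi_t0),
                       bdi_t1 = as.integer(bdi_t1),
                       delta_bdi = as.integer(bdi_t1 - bdi_t0),
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, items_t0, items_t1)

  bold <- NULL
  if (keep_bold) {
    cc <- list(t0 = c0, t1 = c1)
    bold <- lapply(seq_len(n), function(i) {
      lapply(setNames(nm = bold_visits), function(v)
        simulate_bold(scheme, n_volumes, n_discard,
                      within = setNames(cc[[v]][i, ], nets),
                      between = between, ar_coef = ar_coef))
    })
    names(bold) <- cohort$subject_id
  }

  coupling <- array(c(c0, c1), dim = c(n, k, 2),
                    dimnames = list(cohort$subject_id, nets,
                                    c("t0", "t1")))
  list(cohort = cohort, bold = bold, coupling = coupling,
       params = list(effect = effect, within_mean = within_mean,
                     within_sd = within_sd, between = between,
                     stability = stability, ar_coef = ar_coef,
                     n_volumes = n_volumes, n_discard = n_discard,
                     sd_delta = sd_delta, covariates = cv))
}

#' Apply the cohort inclusion filters
#'
#' Drops rows failing any rule and logs the first failing rule per
#' excluded subject, checked in this order: psychiatric-treatment flag,
#' antidepressant flag, baseline BDI-II above `bdi_max`, neurological-
#' disease flag, DemTect below `demtect_min`.
#'
#' @param cohort A cohort data frame as produced by [simulate_cohort()].
#' @param bdi_max Maximum allowed baseline BDI-II total (default 19;
#'   totals above it indicate at least moderate symptoms).
#' @param demtect_min Minimum allowed DemTect score (default 9).
#' @return List with `cohort` (rows passing all filters) and `log`
#'   (data frame `subject_id`, `reason`; one row per excluded subject).
#' @export
apply_inclusion_filters <- function(cohort, bdi_max = 19,
                                    demtect_min = 9) {
  reason <- rep(NA_character_, nrow(cohort))
  rule <- function(cond, label) {
    hit <- which(is.na(reason) & cond)
    reason[hit] <<- label
  }
  rule(cohort$flag_psychiatric, "psychiatric_treatment")
  rule(cohort$flag_antidepressant, "antidepressant_use")
  rule(cohort$bdi_t0 > bdi_max, sprintf("bdi_t0 > %d", bdi_max))
  rule(cohort$flag_neurological, "neurological_disease")
  rule(cohort$demtect < demtect_min, sprintf("demtect < %d", demtect_min))
  keep <- is.na(reason)
  list(cohort = cohort[keep, , drop = FALSE],
       log = data.frame(subject_id = cohort$subject_id[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Cohort table as TSV, one TSV per subject-visit BOLD matrix, and a JSON
#' manifest tying subjects to files.
#'
#' @param sim Output of [simulate_cohort()] (with `keep_bold = TRUE` if
#'   BOLD files are wanted).
#' @param dir Output directory (created if missing).
#' @param seed Seed to record in the manifest.
#' @return The manifest, invisibly.
#' @export
write_cohort_data <- function(sim, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(seed = seed, n_subjects = nrow(sim$cohort),
                   cohort = "cohort.tsv", bold = list())
  if (!is.null(sim$bold)) {
    dir.create(file.path(dir, "bold"), showWarnings = FALSE)
    for (id in names(sim$bold)) {
      files <- list()
      for (v in names(sim$bold[[id]])) {
        fn <- file.path("bold", sprintf("%s_%s.tsv", id, v))
        write.table(sim$bold[[id]][[v]], file.path(dir, fn), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        files[[v]] <- fn
      }
      manifest$bold[[id]] <- files
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
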