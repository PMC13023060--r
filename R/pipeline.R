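# Config-driven orchestration: simulate (or ingest) -> connectomes ->
# metrics -> stats -> report. Every stage reads its inputs from and
# writes its outputs to the run directory, so stages can be re-run
# individually; all outputs carry the config hash for provenance.

#' Default pipeline configuration
#'
#' Every tunable defaults to the study value where one exists (1000
#' surrogates, edge alpha 0.05, Bonferroni over 7 networks, 300 volumes
#' with 4 discarded, effect target VAN); the bundled simulation profile is
#' deliberately small (20 subjects, 4 nodes per network, 60 surrogates)
#' so an end-to-end run stays fast.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    out_dir = "connseg_run",
    paths = list(parcellation = NULL, cohort = NULL, bold_manifest = NULL),
    surrogate = list(n_surrogates = 1000, alpha = 0.05),
    metrics = list(q_sign = "pos"),
    stats = list(designs = c("cross_sectional", "time_by_deltabdi",
                             "time_by_fc0"),
                 bonferroni_alpha = 0.05, fdr_alpha = 0.05),
    simulation = list(n_subjects = 20, nodes_per_network = 4,
                      n_volumes = 300, n_discard = 4, ar_coef = 0.3,
                      effect = list(network = "VAN", magnitude = 0.2,
                                    sign = -1),
                      n_surrogates = 60),
    seed = 1
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values found in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(modifyList(default_config(), cfg))
}

#' @describeIn load_config Validate a configuration list; errors before
#'   any computation when a field is out of range.
#' @param config Configuration list.
#' @export
validate_config <- function(config) {
  s <- config$surrogate
  if (!is.numeric(s$n_surrogates) || s$n_surrogates < 1)
    stop_connseg("config: surrogate$n_surrogates must be >= 1")
  if (!(s$alpha > 0 && s$alpha <= 1))
    stop_connseg("config: surrogate$alpha must be in (0, 1]")
  if (!config$metrics$q_sign %in% c("pos", "neg"))
    stop_connseg("config: metrics$q_sign must be 'pos' or 'neg'")
  sim <- config$simulation
  if (sim$n_discard >= sim$n_volumes)
    stop_connseg("config: simulation$n_discard must be < n_volumes")
  if (!is.numeric(config$seed))
    stop_connseg("config: seed must be numeric")
  config
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  close(con)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

read_stage_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

pipeline_log <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", sep = "", file = file.path(dir, "log.txt"), append = TRUE)
  invisible(line)
}

#' Read a BOLD TSV written by [write_cohort_data()]
#' @param path TSV file, one row per node.
#' @param tr_seconds Sampling interval to attach.
#' @return A [bold_matrix()].
#' @export
read_bold <- function(path, tr_seconds = 2.2) {
  bold_matrix(as.matrix(read.table(path, sep = "\t")),
              tr_seconds = tr_seconds)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order. `simulate` generates a cohort
#' from the config's simulation block (skipped when `paths$cohort` and
#' `paths$bold_manifest` point at existing data); `connectome` builds a
#' surrogate-thresholded connectome per subject-visit; `metrics` computes
#' the feature table; `stats` runs the configured designs per network
#' measure with Bonferroni flags; `report` writes a plain-text summary.
#' Deterministic given `config$seed`: per-subject surrogate seeds are
#' derived from it.
#'
#' @param config Configuration list, see [default_config()].
#' @param stages Stages to run, in order.
#' @return Invisibly, the run state (cohort, features, stats tables).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "connectome", "metrics",
                                    "stats", "report")) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  state <- list(config = config, hash = hash)
  for (st in stages) {
    t0 <- Sys.time()
    state <- switch(st,
      simulate = stage_simulate(state),
      connectome = stage_connectome(state),
      metrics = stage_metrics(state),
      stats = stage_stats(state),
      report = stage_report(state),
      stop_connseg("unknown stage '%s'", st))
    pipeline_log(config$out_dir,
                 sprintf("stage %s done in %.2f s", st,
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(state)
}

stage_simulate <- function(state) {
  cfg <- state$config
  sim_cfg <- cfg$simulation
  if (!is.null(cfg$paths$cohort) && !is.null(cfg$paths$bold_manifest)) {
    pipeline_log(cfg$out_dir, "simulate: external data supplied, skipping")
    return(state)
  }
  scheme <- if (!is.null(cfg$paths$parcellation))
    load_parcellation(cfg$paths$parcellation)
  else
    make_parcel_scheme(setNames(rep(sim_cfg$nodes_per_network, 7),
                                NETWORKS_7))
  eff <- effect_spec(sim_cfg$effect$network, sim_cfg$effect$magnitude,
                     sim_cfg$effect$sign)
  sim <- simulate_cohort(scheme, n_subjects = sim_cfg$n_subjects,
                         effect = eff, n_volumes = sim_cfg$n_volumes,
                         n_discard = sim_cfg$n_discard,
                         ar_coef = sim_cfg$ar_coef, seed = cfg$seed)
  write_parcellation(scheme, file.path(cfg$out_dir, "parcellation.tsv"))
  write_cohort_data(sim, cfg$out_dir, seed = cfg$seed)
  state$scheme <- scheme
  state$sim <- sim
  state
}

load_run_inputs <- function(state) {
  cfg <- state$config
  if (is.null(state$scheme)) {
    pf <- cfg$paths$parcellation %||%
      file.path(cfg$out_dir, "parcellation.tsv")
    state$scheme <- load_parcellation(pf)
  }
  if (is.null(state$sim)) {
    cf <- cfg$paths$cohort %||% file.path(cfg$out_dir, "cohort.tsv")
    state$sim <- list(cohort = read.table(cf, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE))
  }
  state
}

stage_connectome <- function(state) {
  state <- load_run_inputs(state)
  cfg <- state$config
  mf <- cfg$paths$bold_manifest %||% file.path(cfg$out_dir, "manifest.json")
  manifest <- jsonlite::read_json(mf)
  base <- dirname(mf)
  n_sur <- cfg$simulation$n_surrogates %||% cfg$surrogate$n_surrogates
  out <- file.path(cfg$out_dir, "connectomes")
  dir.create(out, showWarnings = FALSE)
  ids <- names(manifest$bold)
  zs <- list()
  for (i in seq_along(ids)) {
    for (v in names(manifest$bold[[ids[i]]])) {
      bb <- state$sim$bold[[ids[i]]][[v]] %||%
        read_bold(file.path(base, manifest$bold[[ids[i]]][[v]]))
      # per-subject-visit seed derived from the run seed
      z <- build_connectome(bb, n_surrogates = n_sur,
                            alpha = cfg$surrogate$alpha,
                            seed = (cfg$seed + 2L * i + (v == "t1")) %% .Machine$integer.max)
      zs[[sprintf("%s_%s", ids[i], v)]] <- z
      write_connectome(z, file.path(out, sprintf("%s_%s.tsv", ids[i], v)))
    }
  }
  state$connectomes <- zs
  state
}

stage_metrics <- function(state) {
  state <- load_run_inputs(state)
  cfg <- state$config
  if (is.null(state$connectomes)) {
    files <- list.files(file.path(cfg$out_dir, "connectomes"),
                        pattern = "\\.tsv$", full.names = TRUE)
    state$connectomes <- lapply(files, read_connectome,
                                alpha = cfg$surrogate$alpha)
    names(state$connectomes) <- sub("\\.tsv$", "", basename(files))
  }
  keys <- names(state$connectomes)
  mets <- lapply(state$connectomes, network_metrics, scheme = state$scheme,
                 q_sign = cfg$metrics$q_sign)
  ids <- data.frame(
    subject_id = sub("_(t0|t1)$", "", keys),
    visit = sub("^.*_(t0|t1)$", "\\1", keys),
    stringsAsFactors = FALSE)
  feats <- feature_table(unname(mets), ids)
  write_stage_table(feats, file.path(cfg$out_dir, "features.tsv"),
                    state$hash)
  state$features <- feats
  state
}

# network-level measures entered into the designs, per sign variant
measure_columns <- function(features) {
  grep("^(VN|SMN|DAN|VAN|LN|CN|DMN)(_[A-Z]+)?_(intra|inter|between|Q)",
       names(features), value = TRUE)
}

stage_stats <- function(state) {
  cfg <- state$config
  if (is.null(state$features))
    state$features <- read_stage_table(file.path(cfg$out_dir,
                                                 "features.tsv"))
  state <- load_run_inputs(state)
  cohort <- state$sim$cohort
  feats <- state$features
  f0 <- feats[feats$visit == "t0", ]
  f1 <- feats[feats$visit == "t1", ]
  f0 <- f0[match(cohort$subject_id, f0$subject_id), ]
  f1 <- f1[match(cohort$subject_id, f1$subject_id), ]
  cols <- measure_columns(feats)
  rows <- list()
  for (m in cols) {
    if (all(is.na(f0[[m]]))) next
    if ("cross_sectional" %in% cfg$stats$designs)
      rows[[length(rows) + 1]] <- cbind(measure = m,
        design = "cross_sectional",
        cross_sectional_regression(f0[[m]], cohort))
    if ("time_by_deltabdi" %in% cfg$stats$designs)
      rows[[length(rows) + 1]] <- cbind(measure = m,
        design = "time_by_deltabdi",
        rm_time_by_deltabdi(f0[[m]], f1[[m]], cohort))
    if ("time_by_fc0" %in% cfg$stats$designs)
      rows[[length(rows) + 1]] <- cbind(measure = m, design = "time_by_fc0",
        rm_time_by_fc0(f0[[m]], cohort))
  }
  res <- do.call(rbind, rows)
  res$bonferroni_significant <-
    flag_bonferroni(res$p, cfg$stats$bonferroni_alpha, k = 7)
  write_stage_table(res, file.path(cfg$out_dir, "stats.tsv"), state$hash)
  state$stats <- res
  state
}

stage_report <- function(state) {
  cfg <- state$config
  if (is.null(state$stats))
    state$stats <- read_stage_table(file.path(cfg$out_dir, "stats.tsv"))
  res <- state$stats
  lines <- c(sprintf("connseg pipeline report (config %s)", state$hash),
             sprintf("models fitted: %d", nrow(res)),
             sprintf("Bonferroni threshold (7 networks): %.3f",
                     bonferroni_threshold(cfg$stats$bonferroni_alpha, 7)),
             "", "results passing the Bonferroni threshold:")
  sig <- res[res$bonferroni_significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(lines, sprintf(
      "  %s [%s]: F/stat = %.3f, p = %.4g, partial eta^2 = %.3f, n = %d",
      sig$measure, sig$design, sig$estimate, sig$p,
      ifelse(is.na(sig$partial_eta_sq), NA, sig$partial_eta_sq),
      sig$n_used))
  }
  writeLines(lines, file.path(cfg$out_dir, "report.txt"))
  state
}
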