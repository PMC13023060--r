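#' Robustness re-analysis under a cohort exclusion rule
#'
#' Re-runs a longitudinal design after excluding a subgroup, reporting the
#' primary and re-analysis results side by side. Built-in rules:
#' `"exclude_mild"` drops subjects with mild baseline symptoms (BDI-II
#' 14-19, the standard banding), `"exclude_zero"` drops subjects without
#' any baseline symptoms (BDI-II = 0). A custom rule is a predicate over
#' the cohort returning `TRUE` for rows to *exclude*.
#'
#' @param fc_t0 Baseline connectivity measure (moderator of the design).
#' @param cohort Cohort data frame.
#' @param rule `"exclude_mild"`, `"exclude_zero"`, or `"custom"`.
#' @param custom Predicate function `cohort -> logical` when
#'   `rule = "custom"`.
#' @param design Function `(fc_t0, cohort) -> model result`; defaults to
#'   the baseline-FC interaction design [rm_time_by_fc0()].
#' @return List with `primary`, `reanalysis` (model-result rows),
#'   `n_excluded` and `rule`.
#' @export
robustness_reanalysis <- function(fc_t0, cohort,
                                  rule = c("exclude_mild", "exclude_zero",
                                           "custom"),
                                  custom = NULL, design = rm_time_by_fc0) {
  rule <- match.arg(rule)
  drop <- switch(rule,
    exclude_mild = cohort$bdi_t0 >= 14 & cohort$bdi_t0 <= 19,
    exclude_zero = cohort$bdi_t0 == 0,
    custom = {
      if (!is.function(custom)) stop_connseg("rule 'custom' needs a predicate")
      custom(cohort)
    })
  drop <- !is.na(drop) & drop
  keep <- !drop
  primary <- design(fc_t0, cohort)
  reanalysis <- design(fc_t0[keep], cohort[keep, , drop = FALSE])
  list(primary = primary, reanalysis = reanalysis,
       n_excluded = sum(drop), rule = rule)
}

#' Region-of-interest post-hoc drill-down of a network-level effect
#'
#' For every ROI of the target network, enters the node-level baseline
#' intra-network connectivity into the baseline-FC interaction design and
#' corrects the ROI p-values with Benjamini-Hochberg. Left- and
#' right-hemisphere aggregates (mean over the network's nodes per
#' hemisphere) are additionally tested separately.
#'
#' @param node_fc_t0 Subjects x N matrix of node-level baseline
#'   intra-network connectivity (e.g. the `node{ID}_intra_pos` columns of
#'   [feature_table()] at the first visit, in node order).
#' @param scheme The [parcel_scheme()].
#' @param target_network Network whose ROIs are examined; must have nodes
#'   in both hemispheres.
#' @param cohort Cohort data frame.
#' @param alpha FDR level for the ROI rejection set.
#' @param design Design function `(fc, cohort) -> model result`; default
#'   [rm_time_by_fc0()].
#' @return List with `roi` (per-ROI results incl. BH `q`) and
#'   `hemisphere` (two aggregate results).
#' @export
posthoc_roi <- function(node_fc_t0, scheme, target_network, cohort,
                        alpha = 0.05, design = rm_time_by_fc0) {
  sel <- which(as.character(scheme$network) == target_network)
  if (!length(sel))
    stop_connseg("network '%s' has no nodes", target_network)
  hemis <- scheme$hemisphere[sel]
  if (length(unique(hemis)) < 2)
    stop_connseg("network '%s' must have nodes in both hemispheres",
                 target_network)
  if (ncol(node_fc_t0) != nrow(scheme))
    stop_connseg("node_fc_t0 must have one column per scheme node")
  fits <- lapply(sel, function(j) design(node_fc_t0[, j], cohort))
  roi <- do.call(rbind, fits)
  roi <- cbind(data.frame(node_id = scheme$node_id[sel],
                          label = scheme$label[sel], hemisphere = hemis,
                          stringsAsFactors = FALSE), roi)
  bh <- bh_fdr(roi$p, alpha = alpha)
  roi$q <- bh$q
  roi$significant <- bh$reject
  hemi_rows <- lapply(c("L", "R"), function(h) {
    agg <- rowMeans(node_fc_t0[, sel[hemis == h], drop = FALSE])
    cbind(data.frame(hemisphere = h, n_rois = sum(hemis == h)),
          design(agg, cohort))
  })
  list(roi = roi, hemisphere = do.call(rbind, hemi_rows))
}
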