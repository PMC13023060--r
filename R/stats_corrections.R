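#' Bonferroni-adjusted significance threshold over networks
#'
#' Divides the significance level by the number of networks analyzed;
#' with the default seven networks, 0.05 / 7 = 0.007 (3 d.p.).
#'
#' @param alpha Family-wise level (default 0.05).
#' @param k Number of tests, default 7 networks.
#' @return The adjusted threshold `alpha / k`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, k = 7) {
  stopifnot(k >= 1, alpha > 0, alpha <= 1)
  alpha / k
}

#' @describeIn bonferroni_threshold Flag p-values passing the adjusted
#'   threshold; strictly below (a p exactly at the threshold is not
#'   flagged).
#' @param p Vector of p-values.
#' @export
flag_bonferroni <- function(p, alpha = 0.05, k = 7) {
  !is.na(p) & p < bonferroni_threshold(alpha, k)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted q-values via [stats::p.adjust()] plus the rejection
#' set at level `alpha`. Output is invariant to the input order.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @param alpha FDR level for the rejection set (default 0.05).
#' @return List with `q` (adjusted values, same order as input) and
#'   `reject` (logical).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (any(!is.na(pvals) & (pvals <= 0 | pvals > 1)))
    stop_connseg("p-values must lie in (0, 1]")
  q <- p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q < alpha)
}

#' Default BDI-II item-to-domain mapping
#'
#' Reads the editable YAML config shipped with the package assigning each
#' of the 21 items to the cognitive, affective or somatic domain.
#'
#' @param path Optional path to an alternative YAML mapping.
#' @return Named list of integer item vectors, one per domain.
#' @export
default_bdi_domains <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bdi_domains.yaml",
                                package = "connseg")
  lapply(yaml::read_yaml(path), as.integer)
}

#' Decompose BDI-II item scores into symptom-domain sub-scores
#'
#' The mapping must partition items 1..21 (each item in exactly one
#' domain), so the domain sub-scores always sum to the total.
#'
#' @param items Integer matrix (subjects x 21) or vector of 21 item
#'   scores, each in 0..3.
#' @param mapping Named list of item index vectors, see
#'   [default_bdi_domains()].
#' @return Data frame with one column per domain (and rows matching
#'   `items`).
#' @export
domain_scores <- function(items, mapping = default_bdi_domains()) {
  if (is.vector(items)) items <- matrix(items, nrow = 1)
  if (ncol(items) != 21)
    stop_connseg("expected 21 item columns, got %d", ncol(items))
  all_items <- sort(unlist(mapping))
  if (!identical(as.integer(all_items), 1:21))
    stop_connseg("domain mapping must assign each of items 1..21 exactly once")
  out <- lapply(mapping, function(ix)
    rowSums(items[, ix, drop = FALSE]))
  as.data.frame(out)
}
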