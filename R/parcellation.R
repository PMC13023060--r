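#' The seven canonical cortical networks
#'
#' Order used throughout the package for network-level outputs.
#' @export
NETWORKS_7 <- c("VN", "SMN", "DAN", "VAN", "LN", "CN", "DMN")

#' Default mapping from parcellation label tokens to network codes
#'
#' Schaefer-style parcel labels encode the network as the token after the
#' hemisphere field (e.g. `7Networks_RH_SalVentAttn_FrOper_1`). The mapping
#' from those tokens to the short network codes used here is shipped as an
#' editable YAML file so that other label dialects can be supported without
#' code changes.
#'
#' @param path Optional path to a YAML file mapping label tokens to network
#'   codes. Defaults to the file shipped with the package.
#' @return Named character vector, names are label tokens, values network
#'   codes.
#' @export
default_network_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "network_tokens.yaml",
                                package = "connseg")
  m <- yaml::read_yaml(path)
  unlist(m)
}

new_parcel_scheme <- function(df) {
  structure(df, class = c("parcel_scheme", "data.frame"))
}

#' Construct and validate a parcellation scheme
#'
#' A parcellation scheme assigns each of N nodes to exactly one functional
#' network and one hemisphere. Every aggregation in the package (strengths,
#' between-network matrices, segregation) is defined relative to such a
#' scheme.
#'
#' @param node_id Integer node indices, must be exactly `1:N`.
#' @param network Character vector of network codes; all declared networks
#'   must be non-empty.
#' @param hemisphere Character vector, `"L"` or `"R"` per node.
#' @param label Optional node labels (defaults to a generated label).
#' @param networks Character vector giving the expected set and order of
#'   networks; if `NULL` (default) the set is inferred from the data, in
#'   canonical order where the codes are canonical. Pass [NETWORKS_7] to
#'   require the full 7-network scheme.
#' @return A `parcel_scheme` data frame with columns `node_id`, `label`,
#'   `network`, `hemisphere`.
#' @export
parcel_scheme <- function(node_id, network, hemisphere, label = NULL,
                          networks = NULL) {
  n <- length(node_id)
  label <- label %||% sprintf("%s_%s_%d", hemisphere, network, node_id)
  df <- data.frame(node_id = as.integer(node_id), label = label,
                   network = as.character(network),
                   hemisphere = as.character(hemisphere),
                   stringsAsFactors = FALSE)
  validate_parcel_scheme(new_parcel_scheme(df), networks = networks)
}

#' @rdname parcel_scheme
#' @param scheme A `parcel_scheme` object to validate.
#' @export
validate_parcel_scheme <- function(scheme, networks = NULL) {
  ids <- scheme$node_id
  n <- nrow(scheme)
  if (anyDuplicated(ids))
    stop_connseg("duplicate node ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!identical(sort(ids), seq_len(n)))
    stop_connseg("node ids must be contiguous 1..N; got %d rows with range [%d, %d]",
                 n, min(ids), max(ids))
  if (any(is.na(scheme$network)) || any(scheme$network == ""))
    stop_connseg("every node must belong to a network")
  if (!all(scheme$hemisphere %in% c("L", "R")))
    stop_connseg("hemisphere must be 'L' or 'R'")
  present <- unique(scheme$network)
  if (!is.null(networks)) {
    missing <- setdiff(networks, present)
    if (length(missing))
      stop_connseg("declared networks with no nodes: %s",
                   paste(missing, collapse = ", "))
    extra <- setdiff(present, networks)
    if (length(extra))
      stop_connseg("unknown network codes: %s", paste(extra, collapse = ", "))
    scheme$network <- factor(scheme$network, levels = networks)
  } else {
    lev <- if (all(present %in% NETWORKS_7))
      NETWORKS_7[NETWORKS_7 %in% present] else sort(present)
    scheme$network <- factor(scheme$network, levels = lev)
  }
  if (nlevels(scheme$network) < 2)
    stop_connseg("a scheme needs at least 2 networks")
  scheme[order(scheme$node_id), , drop = FALSE]
}

#' Load a parcellation lookup table
#'
#' Reads either a FreeSurfer-style color lookup table (columns: index,
#' label, R, G, B, A; network and hemisphere parsed from the label) or a
#' minimal TSV with columns `node_id`/`id`, `network`, `hemisphere` (and
#' optionally `label`).
#'
#' @param path File to read.
#' @param format `"auto"` (default), `"lut"` or `"tsv"`.
#' @param network_map Named vector mapping label tokens to network codes,
#'   see [default_network_map()].
#' @param networks Expected network set (`NULL` = infer from the file).
#' @return A validated [parcel_scheme()].
#' @export
load_parcellation <- function(path, format = c("auto", "lut", "tsv"),
                              network_map = default_network_map(),
                              networks = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\t", first) && grepl("network", first, ignore.case = TRUE))
      "tsv" else "lut"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    names(df)[names(df) == "id"] <- "node_id"
    return(parcel_scheme(df$node_id, df$network, df$hemisphere,
                         label = df$label, networks = networks))
  }
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2)
    stop_connseg("LUT file needs at least index and label columns")
  parsed <- parse_schaefer_labels(df[[2]], network_map)
  parcel_scheme(df[[1]], parsed$network, parsed$hemisphere,
                label = df[[2]], networks = networks)
}

# split labels like "7Networks_LH_Vis_12" into hemisphere + network code
parse_schaefer_labels <- function(labels, network_map) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  hemi <- character(length(labels))
  net <- character(length(labels))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    h <- p[p %in% c("LH", "RH", "L", "R")]
    if (length(h) != 1)
      stop_connseg("row %d: cannot parse hemisphere from label '%s'",
                   i, labels[i])
    hemi[i] <- substr(h, 1, 1)
    tok <- intersect(p, names(network_map))
    if (length(tok) != 1)
      stop_connseg("row %d: no known network token in label '%s'",
                   i, labels[i])
    net[i] <- network_map[[tok]]
  }
  list(hemisphere = hemi, network = net)
}

#' Write a parcellation scheme as TSV
#'
#' Round-trips through [load_parcellation()] with `format = "tsv"`.
#'
#' @param scheme A `parcel_scheme`.
#' @param path Output file.
#' @export
write_parcellation <- function(scheme, path) {
  df <- as.data.frame(scheme)
  df$network <- as.character(df$network)
  write.table(df[, c("node_id", "network", "hemisphere", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of nodes per network
#'
#' @param scheme A `parcel_scheme`.
#' @return Named integer vector in network order; sums to N.
#' @export
network_sizes <- function(scheme) {
  tab <- table(scheme$network)
  setNames(as.integer(tab), names(tab))
}

#' Build a synthetic parcellation scheme
#'
#' Convenience constructor for simulations and tests: `sizes` nodes per
#' network, nodes split as evenly as possible between hemispheres (left
#' hemisphere first).
#'
#' @param sizes Named integer vector, nodes per network. The default is a
#'   400-node scheme with the standard 7-network parcel counts.
#' @return A [parcel_scheme()].
#' @export
make_parcel_scheme <- function(sizes = c(VN = 61, SMN = 77, DAN = 46,
                                         VAN = 47, LN = 26, CN = 52,
                                         DMN = 91)) {
  stopifnot(!is.null(names(sizes)), all(sizes >= 1))
  network <- rep(names(sizes), times = sizes)
  hemisphere <- unlist(lapply(sizes, function(k) {
    c(rep("L", ceiling(k / 2)), rep("R", floor(k / 2)))
  }), use.names = FALSE)
  parcel_scheme(seq_len(sum(sizes)), network, hemisphere,
                networks = names(sizes))
}

#' @export
print.parcel_scheme <- function(x, ...) {
  cat(sprintf("parcel_scheme: %d nodes, %d networks\n",
              nrow(x), nlevels(x$network)))
  print(network_sizes(x))
  invisible(x)
}
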