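# Strength definitions. For a node i in network k (size n_k, N nodes
# total), with W the sign-restricted z matrix (negative weights as
# magnitudes) and each undirected edge counted once per node end:
#   intra_i      = sum_{j in k, j != i} W_ij / (n_k (n_k - 1) / 2)
#   inter_i      = sum_{j not in k}     W_ij / (n_k (N - n_k))
#   between_i[B] = sum_{j in B}         W_ij / (n_k n_B)
# The denominators are the network-wide possible-edge counts, parallel to
# the intra definition; they differ from per-node counts only by a
# constant factor per network.

#' Node-level intra-, inter- and between-network strengths
#'
#' @param z A `z_connectome` from [threshold_and_ztransform()].
#' @param scheme A [parcel_scheme()] whose N matches the connectome.
#' @param sign `"pos"` to use the positive part, `"neg"` for the negative
#'   part; negative weights enter as magnitudes so that larger values mean
#'   stronger negative connectivity.
#' @return A `node_strengths` list: `intra` and `inter` (length-N
#'   vectors), `between` (N x K matrix, own-network column `NA`),
#'   `between_mean` (row mean of `between` over the other networks, the
#'   single per-node between summary), and bookkeeping fields.
#' @export
node_strengths <- function(z, scheme, sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  n <- nrow(scheme)
  if (z$n != n)
    stop_connseg("connectome has %d nodes but scheme has %d", z$n, n)
  w <- if (sign == "pos") z$z_pos else -z$z_neg
  nets <- levels(scheme$network)
  k <- length(nets)
  memb <- outer(as.character(scheme$network), nets, "==") * 1  # N x K
  sizes <- colSums(memb)
  s <- w %*% memb                                   # N x K edge sums
  own <- match(as.character(scheme$network), nets)
  n_k <- sizes[own]
  own_sum <- s[cbind(seq_len(n), own)]
  intra <- own_sum / (n_k * (n_k - 1) / 2)
  intra[n_k == 1] <- 0        # singleton network: no within edges
  inter <- (rowSums(w) - own_sum) / (n_k * (n - n_k))
  between <- s / (n_k %o% sizes)
  between[cbind(seq_len(n), own)] <- NA_real_
  colnames(between) <- nets
  structure(list(intra = intra, inter = inter, between = between,
                 between_mean = rowMeans(between, na.rm = TRUE),
                 sign = sign, networks = nets, sizes = setNames(sizes, nets),
                 membership = own),
            class = "node_strengths")
}

#' Network-level strengths from node strengths
#'
#' Network intra and inter values are the arithmetic means of the member
#' nodes' values. The between-network matrix entry (A, B) is the mean
#' z weight per possible cross edge, `sum_{i in A, j in B} W_ij / (n_A
#' n_B)`; summing the member nodes' between values reproduces this exactly
#' because the node values already carry the `n_A n_B` denominator.
#'
#' @param nodes A `node_strengths` object.
#' @param scheme The matching [parcel_scheme()].
#' @return A `network_strengths` list: `intra`, `inter` (named vectors),
#'   `between` (K x K symmetric matrix, `NA` diagonal), `sign`.
#' @export
network_level <- function(nodes, scheme) {
  nets <- nodes$networks
  grp <- factor(nets[nodes$membership], levels = nets)
  intra <- tapply(nodes$intra, grp, mean)
  inter <- tapply(nodes$inter, grp, mean)
  between <- rowsum(nodes$between, grp)              # K x K, diag NA
  between <- (as.matrix(between) + t(as.matrix(between))) / 2  # symmetrize fp noise
  diag(between) <- NA_real_
  structure(list(intra = setNames(as.numeric(intra), nets),
                 inter = setNames(as.numeric(inter), nets),
                 between = between, sign = nodes$sign),
            class = "network_strengths")
}

#' Network segregation score
#'
#' `Q = (intra - inter) / (intra + inter)`: 1 means maximal segregation
#' (all weight inside the network), -1 maximal integration (all weight
#' outside), 0 a balanced system. Undefined when `intra + inter = 0`;
#' those entries are returned as `NA` with a warning.
#'
#' @param intra,inter Network-level strength values (vectorized).
#' @return Numeric vector of scores in `[-1, 1]` (or `NA`).
#' @export
segregation_score <- function(intra, inter) {
  denom <- intra + inter
  q <- (intra - inter) / denom
  bad <- which(denom == 0)
  if (length(bad)) {
    q[bad] <- NA_real_
    warning(sprintf("segregation undefined (intra + inter = 0) for: %s",
                    paste(names(denom)[bad] %||% bad, collapse = ", ")),
            call. = FALSE)
  }
  q
}

#' All strength metrics of one connectome
#'
#' Node- and network-level strengths for both signs plus per-network
#' segregation.
#'
#' @param z A `z_connectome`.
#' @param scheme The matching [parcel_scheme()].
#' @param q_sign Sign variant feeding the segregation score; the default
#'   `"pos"` computes Q from positive-weight intra and inter strengths,
#'   `"neg"` is available as a variant.
#' @return A `network_metrics` list with elements `node` (per sign),
#'   `net` (per sign), `Q` (named per-network vector) and `q_sign`.
#' @export
network_metrics <- function(z, scheme, q_sign = c("pos", "neg")) {
  q_sign <- match.arg(q_sign)
  node <- list(pos = node_strengths(z, scheme, "pos"),
               neg = node_strengths(z, scheme, "neg"))
  net <- list(pos = network_level(node$pos, scheme),
              neg = network_level(node$neg, scheme))
  q <- segregation_score(net[[q_sign]]$intra, net[[q_sign]]$inter)
  structure(list(node = node, net = net, Q = q, q_sign = q_sign),
            class = "network_metrics")
}

#' Subject x feature table of connectivity metrics
#'
#' Emits one row per subject-visit. Node-level features follow the grammar
#' `node{ID}_{metric}_{sign}` with metrics `intra`, `inter`, `between`
#' (the per-node between summary: mean over the other networks), giving
#' exactly `N x 6` node-level values per row. Network-level features are
#' `{network}_{intra|inter}_{sign}`, network-pair features
#' `{A}_{B}_between_{sign}` (upper pairs in network order), and `{network}_Q`.
#'
#' @param metrics List of `network_metrics`, one per subject-visit.
#' @param ids Data frame with one row per element of `metrics`, carrying at
#'   least `subject_id` and `visit`.
#' @return Data frame: id columns followed by feature columns.
#' @export
feature_table <- function(metrics, ids) {
  stopifnot(length(metrics) == nrow(ids))
  rows <- lapply(metrics, function(m) {
    nets <- m$node$pos$networks
    n <- length(m$node$pos$intra)
    node_part <- unlist(lapply(c("pos", "neg"), function(s) {
      ns <- m$node[[s]]
      v <- c(ns$intra, ns$inter, ns$between_mean)
      names(v) <- c(sprintf("node%d_intra_%s", seq_len(n), s),
                    sprintf("node%d_inter_%s", seq_len(n), s),
                    sprintf("node%d_between_%s", seq_len(n), s))
      v
    }))
    pairs <- upper_pairs(length(nets))
    net_part <- unlist(lapply(c("pos", "neg"), function(s) {
      nl <- m$net[[s]]
      v <- c(setNames(nl$intra, sprintf("%s_intra_%s", nets, s)),
             setNames(nl$inter, sprintf("%s_inter_%s", nets, s)),
             setNames(nl$between[pairs],
                      sprintf("%s_%s_between_%s", nets[pairs[, 1]],
                              nets[pairs[, 2]], s)))
      v
    }))
    qv <- setNames(m$Q, sprintf("%s_Q", nets))
    c(node_part, net_part, qv)
  })
  feat <- do.call(rbind, rows)
  cbind(ids, as.data.frame(feat, row.names = NULL))
}
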