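#' Construct a BOLD time-series matrix
#'
#' @param values Numeric node x time matrix (one row per parcel).
#' @param tr_seconds Sampling interval of the series, in seconds.
#' @return A `bold_matrix` (numeric matrix with a `tr_seconds` attribute).
#' @export
bold_matrix <- function(values, tr_seconds = 2.2) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop_connseg("BOLD matrix contains non-finite values")
  if (ncol(values) < 3)
    stop_connseg("BOLD matrix needs at least 3 time points, got %d",
                 ncol(values))
  structure(values, tr_seconds = tr_seconds,
            class = c("bold_matrix", class(values)))
}

#' Pearson edge matrix of a parcellated BOLD run
#'
#' Computes the node-by-node matrix of Pearson correlations between row
#' time series. The diagonal is undefined and returned as `NA`. Rows with
#' zero variance cannot carry a correlation: their edges are set to `NA`
#' and the offending node ids are recorded in the `undefined_nodes`
#' attribute (with a warning), never silently zeroed.
#'
#' @param ts A [bold_matrix()] or plain node x time matrix.
#' @return An `edge_matrix`: symmetric N x N matrix, `NA` diagonal.
#' @export
correlation_matrix <- function(ts) {
  x <- unclass(as.matrix(ts))
  if (ncol(x) < 3)
    stop_connseg("need at least 3 time points")
  sds <- apply(x, 1, sd)
  flat <- which(sds == 0)
  r <- suppressWarnings(cor(t(x)))
  if (length(flat)) {
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
    warning(sprintf("zero-variance rows, edges undefined: %s",
                    paste(flat, collapse = ", ")), call. = FALSE)
  }
  diag(r) <- NA_real_
  structure(r, undefined_nodes = flat, class = c("edge_matrix", "matrix",
                                                 "array"))
}

# positive-frequency index block shared by the surrogate routines:
# bins 2..half+1 get free phases; DC (bin 1) and, for even T, the Nyquist
# bin keep theirs, which guarantees a real-valued, mean-preserving output
pos_freq_count <- function(t_len) floor((t_len - 1) / 2)

#' Phase-randomization surrogate of a BOLD matrix
#'
#' Each row is Fourier transformed, its positive-frequency phases replaced
#' by independent uniform draws (conjugate-symmetric assignment, DC and
#' Nyquist fixed), and transformed back. The surrogate row has exactly the
#' original amplitude spectrum — hence the original mean, variance and
#' autocorrelation function — but cross-row dependence is destroyed.
#'
#' @param ts A [bold_matrix()] or node x time matrix.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A matrix of the same dimensions; a `bold_matrix` attribute-
#'   preserving surrogate.
#' @export
phase_randomize <- function(ts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- t(unclass(as.matrix(ts)))            # time x node for mvfft
  t_len <- nrow(x)
  n <- ncol(x)
  f <- mvfft(x)
  half <- pos_freq_count(t_len)
  if (half > 0) {
    idx <- 2:(half + 1)
    cidx <- (t_len - half + 1):t_len
    rot <- exp(1i * matrix(runif(half * n, 0, 2 * pi), half, n))
    f[idx, ] <- f[idx, , drop = FALSE] * rot
    f[cidx, ] <- Conj(f[idx[half:1], , drop = FALSE])
  }
  out <- t(Re(mvfft(f, inverse = TRUE)) / t_len)
  dimnames(out) <- dimnames(ts)
  tr <- attr(ts, "tr_seconds")
  if (!is.null(tr)) out <- bold_matrix(out, tr_seconds = tr)
  out
}

#' Edge-wise surrogate permutation p-values
#'
#' Re-scrambles all rows jointly `n_surrogates` times and recomputes the
#' full correlation matrix once per iteration. The two-sided p-value of
#' edge (i, j) uses the add-one estimator
#' `p = (1 + #\{|r_surr| >= |r_obs|\}) / (1 + n_surrogates)`, so p is never
#' zero and the smallest achievable value is `1 / (1 + n_surrogates)`.
#'
#' The per-surrogate correlations are evaluated in the frequency domain
#' (phase surrogates preserve each row's mean and variance, so the
#' centering and scaling terms are constants); this is exactly equivalent
#' to materializing each surrogate and calling [correlation_matrix()].
#'
#' @param ts A [bold_matrix()] or node x time matrix.
#' @param n_surrogates Number of surrogate draws (>= 1; 1000 by default).
#' @param seed Optional integer seed.
#' @return N x N matrix of p-values in (0, 1]; diagonal and edges touching
#'   zero-variance rows are `NA`.
#' @export
surrogate_edge_pvalues <- function(ts, n_surrogates = 1000, seed = NULL) {
  if (n_surrogates < 1) stop_connseg("n_surrogates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- unclass(as.matrix(ts))
  n <- nrow(x)
  t_len <- ncol(x)
  robs <- suppressWarnings(abs(cor(t(x))))
  xt <- t(x)
  f <- mvfft(xt)
  half <- pos_freq_count(t_len)
  fpos <- f[1 + seq_len(half), , drop = FALSE]
  dc <- Re(f[1, ])
  ny <- if (t_len %% 2 == 0) Re(f[t_len / 2 + 1, ]) else numeric(n)
  base <- outer(dc, dc) + outer(ny, ny)
  cm <- colMeans(xt)
  sds <- sqrt((colSums(xt^2) - t_len * cm^2) / (t_len - 1))
  bad <- which(sds == 0 | !is.finite(sds))
  robs_cmp <- robs
  robs_cmp[is.na(robs_cmp)] <- Inf     # undefined edges never exceeded
  cnt <- surrogate_exceed_counts(fpos, base, robs_cmp, cm,
                                 pmax(sds, .Machine$double.xmin),
                                 t_len, as.integer(n_surrogates))
  p <- (1 + cnt) / (1 + n_surrogates)
  if (length(bad)) {
    p[bad, ] <- NA_real_
    p[, bad] <- NA_real_
  }
  diag(p) <- NA_real_
  dimnames(p) <- list(rownames(x), rownames(x))
  p
}

#' Threshold an edge matrix and Fisher-transform the survivors
#'
#' Edges with `p >= alpha` (boundary excluded) are set to zero; surviving
#' edges are transformed with Fisher's r-to-z (`atanh`) and split by sign
#' into a positive and a negative matrix with disjoint support.
#' Correlations with `|r| = 1` are clipped to `1 - 1e-7` before the
#' transform (with a message), since `atanh(1)` is infinite.
#'
#' @param r An `edge_matrix` from [correlation_matrix()].
#' @param p Matching p-value matrix from [surrogate_edge_pvalues()].
#' @param alpha Edge-wise significance level, default 0.05.
#' @return A `z_connectome`: list with elements `z_pos` (entries >= 0),
#'   `z_neg` (entries <= 0), `sig_mask` (logical survivors), `alpha`, `n`.
#' @export
threshold_and_ztransform <- function(r, p, alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) stop_connseg("alpha must be in (0, 1]")
  r <- unclass(r)
  if (!identical(dim(r), dim(p)))
    stop_connseg("r and p dimensions differ")
  sig <- !is.na(p) & p < alpha & !is.na(r)
  diag(sig) <- FALSE
  clipped <- which(sig & abs(r) >= 1)
  if (length(clipped)) {
    message(sprintf("|r| = 1 on %d edge(s); clipped before atanh",
                    length(clipped) / 2L))
    r[clipped] <- sign(r[clipped]) * (1 - 1e-7)
  }
  z <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  z[sig] <- atanh(r[sig])
  structure(list(z_pos = pmax(z, 0), z_neg = pmin(z, 0), sig_mask = sig,
                 alpha = alpha, n = nrow(r)),
            class = "z_connectome")
}

#' @export
print.z_connectome <- function(x, ...) {
  m <- sum(x$sig_mask[upper.tri(x$sig_mask)])
  tot <- x$n * (x$n - 1) / 2
  cat(sprintf(
    "z_connectome: %d nodes, %d/%d edges significant at alpha = %g (%d pos, %d neg)\n",
    x$n, m, tot, x$alpha,
    sum(x$z_pos[upper.tri(x$z_pos)] > 0), sum(x$z_neg[upper.tri(x$z_neg)] < 0)))
  invisible(x)
}

#' One-call connectome construction
#'
#' Pearson edges, surrogate thresholding and Fisher-z sign split.
#'
#' @inheritParams surrogate_edge_pvalues
#' @inheritParams threshold_and_ztransform
#' @return A `z_connectome`.
#' @export
build_connectome <- function(ts, n_surrogates = 1000, alpha = 0.05,
                             seed = NULL) {
  r <- correlation_matrix(ts)
  p <- surrogate_edge_pvalues(ts, n_surrogates = n_surrogates, seed = seed)
  threshold_and_ztransform(r, p, alpha = alpha)
}

#' Write a connectome as an upper-triangle edge list
#'
#' One row per undirected edge: `node_i`, `node_j`, `z`, `sign`
#' (`pos`/`neg`/`none`), `significant`.
#'
#' @param z A `z_connectome`.
#' @param path Output TSV file.
#' @export
write_connectome <- function(z, path) {
  ut <- upper_pairs(z$n)
  zval <- (z$z_pos + z$z_neg)[ut]
  df <- data.frame(node_i = ut[, 1], node_j = ut[, 2], z = zval,
                   sign = ifelse(zval > 0, "pos",
                                 ifelse(zval < 0, "neg", "none")),
                   significant = z$sig_mask[ut])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectome edge list written by [write_connectome()]
#'
#' @param path Edge-list TSV.
#' @param alpha Edge alpha to record on the object.
#' @return A `z_connectome`.
#' @export
read_connectome <- function(path, alpha = 0.05) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  n <- max(df$node_j)
  z <- matrix(0, n, n)
  sig <- matrix(FALSE, n, n)
  ij <- cbind(df$node_i, df$node_j)
  z[ij] <- df$z
  sig[ij] <- df$significant
  z <- z + t(z)
  sig <- sig | t(sig)
  structure(list(z_pos = pmax(z, 0), z_neg = pmin(z, 0), sig_mask = sig,
                 alpha = alpha, n = n),
            class = "z_connectome")
}
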