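`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# truncated-normal draws by resampling; bounds are inclusive and wide
# relative to sd in every caller, so rejection rates stay tiny
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# indices of the strict upper triangle, as a two-column matrix
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

stop_connseg <- function(...) stop(sprintf(...), call. = FALSE)
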