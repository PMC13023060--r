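# Shared fixtures and independent oracles, built in code.

# small scheme: k nodes in each of the seven canonical networks
seven_net_scheme <- function(per_network = 2) {
  make_parcel_scheme(setNames(rep(per_network, 7), NETWORKS_7))
}

# wrap a symmetric weight matrix (zero diagonal) as a z_connectome with
# every non-zero edge marked significant
z_from_weights <- function(w, alpha = 0.05) {
  stopifnot(isSymmetric(w), all(diag(w) == 0))
  structure(list(z_pos = pmax(w, 0), z_neg = pmin(w, 0),
                 sig_mask = w != 0 & !diag(TRUE, nrow(w)),
                 alpha = alpha, n = nrow(w)),
            class = "z_connectome")
}

# exhaustive edge-enumeration oracle for node strengths: plain loops,
# no shared code with the implementation
oracle_strengths <- function(w, scheme, sign) {
  w <- if (sign == "pos") pmax(w, 0) else -pmin(w, 0)
  nets <- levels(scheme$network)
  n <- nrow(w)
  sizes <- vapply(nets, function(k) sum(scheme$network == k), integer(1))
  intra <- inter <- numeric(n)
  between <- matrix(NA_real_, n, length(nets), dimnames = list(NULL, nets))
  for (i in seq_len(n)) {
    own <- as.character(scheme$network[i])
    n_k <- sizes[[own]]
    s_in <- s_out <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (as.character(scheme$network[j]) == own) s_in <- s_in + w[i, j]
      else s_out <- s_out + w[i, j]
    }
    intra[i] <- if (n_k > 1) s_in / (n_k * (n_k - 1) / 2) else 0
    inter[i] <- s_out / (n_k * (n - n_k))
    for (b in setdiff(nets, own)) {
      s_b <- 0
      for (j in which(as.character(scheme$network) == b))
        s_b <- s_b + w[i, j]
      between[i, b] <- s_b / (n_k * sizes[[b]])
    }
  }
  list(intra = intra, inter = inter, between = between)
}

# exhaustive cross-network edge mean
oracle_between_networks <- function(w, scheme, sign, a, b) {
  w <- if (sign == "pos") pmax(w, 0) else -pmin(w, 0)
  ia <- which(as.character(scheme$network) == a)
  ib <- which(as.character(scheme$network) == b)
  s <- 0
  for (i in ia) for (j in ib) s <- s + w[i, j]
  s / (length(ia) * length(ib))
}

# random symmetric weight matrix with zero diagonal, mixed signs
random_weights <- function(n, density = 1) {
  w <- matrix(rnorm(n * n), n, n)
  w[runif(n * n) > density] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# independent long-format repeated-measures ANCOVA via aov();
# returns the time x moderator interaction F and p
aov_interaction_oracle <- function(y0, y1, moderator, cohort) {
  n <- length(y0)
  long <- data.frame(
    y = c(y0, y1), time = factor(rep(c("t0", "t1"), each = n)),
    subj = factor(rep(seq_len(n), 2)), sex = factor(rep(cohort$sex, 2)),
    age = rep(cohort$age, 2), isced = rep(cohort$isced, 2),
    interval = rep(cohort$interval, 2), mod = rep(moderator, 2))
  fit <- aov(y ~ (sex + age + isced + interval + mod) * time +
               Error(subj / time), data = long)
  tab <- summary(fit)[["Error: subj:time"]][[1]]
  ix <- grep("mod:time", rownames(tab))
  list(f = tab[ix, "F value"], p = tab[ix, "Pr(>F)"])
}

# minimal cohort covariate table for the model tests
toy_cohort <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             age = rnorm(n, 67, 6.5),
             sex = sample(c("male", "female"), n, TRUE),
             isced = sample(1:9, n, TRUE),
             interval = rnorm(n, 3.7, 0.7),
             demtect = sample(9:18, n, TRUE),
             flag_psychiatric = FALSE, flag_antidepressant = FALSE,
             flag_neurological = FALSE,
             stringsAsFactors = FALSE)
}
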