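# Shared fixtures and independent oracles.

# A small deterministic increment pool: n_fish series over the given
# ages with radii = age * slope + per-fish offset (strictly
# increasing), suitable for hand-verifiable detrending.
toy_pool <- function(n_fish = 5, ages = 1:10, slope = 2,
                     offsets = seq_len(n_fish)) {
  do.call(rbind, lapply(seq_len(n_fish), function(i) {
    data.frame(fish_id = sprintf("T%02d", i), age_dph = ages,
               radius_um = ages * slope + offsets[i],
               settlement_index = max(ages), stage = "settler",
               capture_day = 100, stringsAsFactors = FALSE)
  }))
}

# Brute-force Gaussian Bayes oracle: class posteriors from explicit
# multivariate normal densities with the pooled covariance, computed
# via solve() and det() -- an algebraic route independent of the
# package's Cholesky discriminant.
bayes_oracle <- function(X_train, y_train, X_new, prior = NULL) {
  lv <- sort(unique(as.character(y_train)))
  y <- factor(as.character(y_train), levels = lv)
  # replicate the model's preprocessing contract (population moments)
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, function(v) sqrt(mean((v - mean(v))^2)))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X_train, 2, ctr), 2, scl, "/")
  Zn <- sweep(sweep(X_new, 2, ctr), 2, scl, "/")
  p <- ncol(Z); k <- length(lv); n <- nrow(Z)
  mu <- lapply(lv, function(cl) colMeans(Z[y == cl, , drop = FALSE]))
  S <- matrix(0, p, p)
  for (j in seq_len(k)) {
    D <- sweep(Z[y == lv[j], , drop = FALSE], 2, mu[[j]])
    S <- S + t(D) %*% D
  }
  S <- S / n
  Sinv <- solve(S)
  dets <- det(S)
  if (is.null(prior)) prior <- rep(1 / k, k)
  dens <- vapply(seq_len(k), function(j) {
    apply(Zn, 1, function(z) {
      d <- z - mu[[j]]
      (2 * pi)^(-p / 2) * dets^(-0.5) *
        exp(-0.5 * drop(t(d) %*% Sinv %*% d)) * prior[j]
    })
  }, numeric(nrow(Zn)))
  dens <- matrix(dens, nrow = nrow(Zn), dimnames = list(NULL, lv))
  dens / rowSums(dens)
}

# Random small classification instance with well-conditioned classes.
random_lda_instance <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  p <- sample(1:3, 1)
  n_per <- sample(5:9, 1)
  mu <- matrix(rnorm(k * p, sd = 2), k, p)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per * p), n_per, p) +
      matrix(mu[j, ], n_per, p, byrow = TRUE)
  }))
  colnames(X) <- paste0("t", seq_len(p))
  y <- rep(LETTERS[seq_len(k)], each = n_per)
  Xn <- matrix(rnorm(6 * p, sd = 2), 6, p,
               dimnames = list(NULL, colnames(X)))
  list(X = X, y = y, X_new = Xn, k = k)
}

# Cached mid-size cohorts so several test files can share one
# simulation.
cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(tag, params) {
  if (is.null(cohort_cache[[tag]])) {
    cohort_cache[[tag]] <- simulate_cohort(params)
  }
  cohort_cache[[tag]]
}
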