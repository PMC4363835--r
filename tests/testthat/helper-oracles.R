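# Independent oracles: a Monte-Carlo gene-dropping estimator of the additive
# relationship matrix (allele-based, sharing no code with kinship()), and a
# direct dense multivariate-normal profile likelihood (no spectral rotation,
# sharing no code with fit_polygenic()).

# Drops discrete founder alleles down the pedigree `reps` times and counts
# identity by descent. Returns the estimated 2*phi matrix and its entrywise
# Monte-Carlo standard errors.
gene_drop_relmatrix <- function(ped, reps = 20000) {
  n <- nrow(ped)
  fidx <- attr(ped, "fidx")
  midx <- attr(ped, "midx")
  stopifnot(all(is.na(fidx) == is.na(midx)))  # oracle handles full parent pairs
  ord <- order(attr(ped, "depth"))
  A1 <- matrix(0L, reps, n)
  A2 <- matrix(0L, reps, n)
  for (i in ord) {
    if (is.na(fidx[i])) {
      A1[, i] <- 2L * i - 1L
      A2[, i] <- 2L * i
    } else {
      pick <- stats::runif(reps) < 0.5
      A1[, i] <- ifelse(pick, A1[, fidx[i]], A2[, fidx[i]])
      pick <- stats::runif(reps) < 0.5
      A2[, i] <- ifelse(pick, A1[, midx[i]], A2[, midx[i]])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      # per-replicate 2*phi: half the count of IBD-matching allele pairs
      m <- ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
              (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 2
      est[i, j] <- est[j, i] <- mean(m)
      se[i, j] <- se[j, i] <- stats::sd(m) / sqrt(reps)
    }
  }
  list(est = est, se = se, reps = reps)
}

# Dense profile log-likelihood at a given h2: GLS beta and closed-form
# sigma2_p plugged into the unrotated multivariate-normal likelihood.
dense_profile_loglik <- function(h2, y, X, K) {
  n <- length(y)
  S <- h2 * K + (1 - h2) * diag(n)
  ch <- chol(S)
  solve_S <- function(v) backsolve(ch, forwardsolve(t(ch), v))
  Xi <- solve_S(X)
  beta <- solve(crossprod(X, Xi), crossprod(Xi, y))
  r <- drop(y - X %*% beta)
  rss <- sum(r * solve_S(r))
  s2 <- rss / n
  ld <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi) + ld + n * log(s2) + n)
}

# Brute-force grid search over h2 in {0, 0.01, ..., 1}
grid_fit_polygenic <- function(y, X, K, grid = seq(0, 1, by = 0.01)) {
  ll <- vapply(grid, function(h2) dense_profile_loglik(h2, y, X, K),
               numeric(1))
  list(h2 = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}
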