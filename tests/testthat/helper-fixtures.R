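# shared in-code fixtures; everything is generated, nothing is stored

tiny_counts <- function() {
  m <- matrix(c(5L, 3L, 0L,
                2L, 7L, 1L,
                9L, 0L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("ASV_0001", "ASV_0002", "ASV_0003"),
                              c("S1", "S2", "S3")))
  tax <- data.frame(taxon = rownames(m),
                    genus = c("Prevotella", "Prevotella", "Streptococcus"),
                    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes"))
  count_table(m, tax)
}

# a small balanced-age cohort for pipeline tests
quick_cohort <- function(n = 200, p = 40, depth = 5000, seed = 11, ...) {
  generate_cohort(cohort_spec(n_samples = n, n_taxa = p,
                              reads_per_sample = depth,
                              age_bin_weights = c(2, 1, 1, 1, 1, 1),
                              seed = seed, ...))
}

# counts drawn from a latent Gaussian with a given taxon covariance, so
# network tests control the true conditional-dependence structure
counts_from_cov <- function(n, sigma, depth = 2e4, seed = 1, baseline = 4) {
  set.seed(seed)
  p <- nrow(sigma)
  L <- chol(sigma)
  eta <- baseline + matrix(rnorm(n * p), n, p) %*% L
  cnt <- apply(eta, 1, function(e) rmultinom(1, depth, exp(e - max(e))))
  dimnames(cnt) <- list(sprintf("ASV_%04d", 1:p), sprintf("S%04d", 1:n))
  count_table(cnt, data.frame(taxon = rownames(cnt), genus = rownames(cnt),
                              phylum = "Firmicutes"))
}

# covariance whose precision encodes a chain A-B-C (partial correlation rho
# between consecutive chain members) among otherwise independent taxa
chain_precision_cov <- function(p, rho, chain_len = 3) {
  omega <- diag(p)
  for (i in seq_len(chain_len - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -rho
  stopifnot(min(eigen(omega)$values) > 0)
  solve(omega)
}

expect_dist_equal <- function(a, b, tol = 1e-10) {
  expect_equal(as.matrix(a), as.matrix(b), tolerance = tol)
}
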