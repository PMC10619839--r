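# Shared fixtures: small synthetic inputs built in code at test time.

fixture_coords <- function(n = 50, seed = 42, d = 2) {
  withr::with_seed(seed, {
    S <- matrix(runif(n * d), n, d)
    colnames(S) <- c("x", "y", "z")[seq_len(d)]
    rownames(S) <- paste0("loc", seq_len(n))
    S
  })
}

fixture_expression <- function(n_genes = 5, n_loc = 8, seed = 42) {
  withr::with_seed(seed, {
    Y <- matrix(rpois(n_genes * n_loc, lambda = 3), n_genes, n_loc)
    storage.mode(Y) <- "double"
    dimnames(Y) <- list(paste0("gene", seq_len(n_genes)),
                        paste0("loc", seq_len(n_loc)))
    Y
  })
}

# Centered random expression vector (non-degenerate).
fixture_centered_y <- function(n, seed = 1) {
  withr::with_seed(seed, {
    y <- rnorm(n)
    y - mean(y)
  })
}

intercept_design <- function(n) matrix(1, n, 1)

# Exact moments of T = u'Bu/N for u uniform on the unit sphere of the
# centered subspace (dimension m = N - 1), B = PKP: the independent
# closed-form oracle for the Monte-Carlo null.
spherical_null_moments <- function(K, n) {
  P <- diag(n) - 1 / n
  B <- P %*% smashsvg:::kernel_values(K) %*% P
  m <- n - 1
  trB <- sum(diag(B))
  trB2 <- sum(B * B)
  mean_T <- trB / (m * n)
  var_T <- 2 * (m * trB2 - trB^2) / (m^2 * (m + 2) * n^2)
  list(mean = mean_T, var = var_T)
}
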