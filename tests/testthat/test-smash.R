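test_that("the kernel statistic collapses the trace form to a quadratic form", {
  # identity kernel: y'y cancels, T = 1/N
  y <- fixture_centered_y(10)
  expect_equal(smash_statistic(y, diag(10)), 1 / 10)

  # hand arithmetic on N = 2
  y2 <- c(1, -1)
  K2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(smash_statistic(y2, K2), 0.25)

  # scale invariance
  S <- fixture_coords(20)
  K <- gaussian_kernel(S, 0.3)
  y20 <- fixture_centered_y(20)
  expect_equal(smash_statistic(3.7 * y20, K), smash_statistic(y20, K))
  expect_equal(smash_statistic(-0.2 * y20, K), smash_statistic(y20, K))

  # invariance to shifts inside the covariate column space (residualize first)
  X <- cbind(1, S[, 1])
  y_shift <- y20 + 5 - 2.2 * S[, 1]
  expect_equal(smash_statistic(residualize(y_shift, X), K),
               smash_statistic(residualize(y20, X), K))

  expect_error(smash_statistic(rep(0, 20), K), "degenerate")
})

test_that("the expression Gram matrix has unit trace and unit squared trace", {
  withr::with_seed(77, {
    for (i in 1:10) {
      y <- rnorm(15)
      y <- y - mean(y)
      E <- tcrossprod(y) / sum(y^2)
      expect_equal(sum(diag(E)), 1, tolerance = 1e-12)
      expect_equal(sum(diag(E %*% E)), 1, tolerance = 1e-12)
    }
  })
})

test_that("gamma null parameters follow the moment-matching formulas", {
  p <- gamma_null_params(diag(10), 10)
  expect_equal(p$mean, 0.1)
  expect_equal(p$variance, 0.002)
  expect_equal(p$shape, 5)
  expect_equal(p$scale, 0.02)
  # moment identities theta1*theta2 = E, theta1*theta2^2 = V
  expect_equal(p$shape * p$scale, p$mean)
  expect_equal(p$shape * p$scale^2, p$variance)

  # any unit-diagonal kernel gives E = 1/N exactly
  S <- fixture_coords(25)
  for (K in list(gaussian_kernel(S, 0.2), cosine_kernel(S, 0.4))) {
    expect_equal(gamma_null_params(K, 25)$mean, 1 / 25)
  }
})

test_that("gamma p-values agree with an independent tail integral", {
  params <- gamma_null_params(diag(10), 10)  # shape 5, scale 0.02
  expect_equal(gamma_pvalue(0, params), 1)
  expect_lt(gamma_pvalue(1, params), 1e-12)

  # numeric integration of the density as the oracle
  dens <- function(x) dgamma(x, shape = 5, scale = 0.02)
  at_mean <- integrate(dens, lower = 0.1, upper = Inf,
                       rel.tol = 1e-12)$value
  expect_equal(gamma_pvalue(0.1, params), at_mean, tolerance = 1e-8)

  for (q in c(0.05, 0.12, 0.2)) {
    oracle <- integrate(dens, lower = q, upper = Inf, rel.tol = 1e-12)$value
    expect_equal(gamma_pvalue(q, params), oracle, tolerance = 1e-8)
  }
})

test_that("projection-kernel p-values reproduce the regression score test", {
  withr::with_seed(19, {
    n <- 200
    S <- matrix(runif(2 * n), n, 2)
    K <- projection_kernel(S)
    Sc <- sweep(S, 2, colMeans(S))

    # orthogonal y: statistic 0, p = 1
    y_orth <- residualize(fixture_centered_y(n, seed = 4), cbind(1, S))
    expect_equal(sparkx_pvalue(y_orth, K), 1)

    # y equal to a centered coordinate column: N R^2 = N
    y_col <- Sc[, 1]
    expect_equal(sparkx_pvalue(y_col, K),
                 pchisq(n, df = 2, lower.tail = FALSE))

    # random null genes vs the N R^2 ~ chi^2_d oracle from an explicit fit
    for (i in 1:25) {
      y <- rnorm(n); y <- y - mean(y)
      fit <- lm(y ~ Sc)
      r2 <- summary(fit)$r.squared
      oracle <- pchisq(n * r2, df = 2, lower.tail = FALSE)
      expect_equal(sparkx_pvalue(y, K), oracle, tolerance = 1e-10)
      # matrix-input route agrees with the kernel route
      expect_equal(sparkx_pvalue(y, S), sparkx_pvalue(y, K),
                   tolerance = 1e-12)
    }
  })
})

test_that("minimum-p combination is Bonferroni on the smallest p-value", {
  expect_equal(combine_min_p(c(0.01, 0.5, 0.9)), 0.03)
  expect_equal(combine_min_p(c(1, 1)), 1)
  expect_equal(combine_min_p(0.2), 0.2)
  expect_equal(combine_min_p(c(0.3, 0.4), method = "sidak"),
               1 - 0.7^2)
  expect_error(combine_min_p(numeric(0)), "no p-values")
})

test_that("Cauchy combination averages tangent-transformed p-values", {
  expect_equal(combine_cauchy(c(0.5, 0.5, 0.5)), 0.5)
  for (p in c(0.01, 0.2, 0.77)) {
    expect_equal(combine_cauchy(rep(p, 3)), p, tolerance = 1e-12)
  }
  # a single tiny p dominates moderate companions
  combined <- combine_cauchy(c(1e-12, 0.3, 0.6, 0.9))
  oracle <- 0.5 - atan(mean(tan((0.5 - c(1e-12, 0.3, 0.6, 0.9)) * pi))) / pi
  expect_equal(combined, oracle, tolerance = 1e-15)
  expect_lt(combined, 1e-10)
  # boundary values are clipped, not propagated as infinities
  expect_true(is.finite(combine_cauchy(c(0, 1, 0.5))))
})

test_that("FDR adjustment matches hand-computed step-up values", {
  ps <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_fdr(ps, "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(ps, "BY"), c(0.03, 0.03, 0.03) * (11 / 6))
  expect_equal(adjust_fdr(0.2), 0.2)
  # input order restored
  ps2 <- c(0.9, 0.001, 0.5)
  expect_equal(adjust_fdr(ps2, "BH")[2], min(1, 0.001 * 3))
})

test_that("batched pipeline statistics equal a per-gene loop", {
  withr::with_seed(55, {
    n <- 30
    Y <- matrix(rnorm(50 * n, mean = 5), 50, n)
    rownames(Y) <- paste0("g", 1:50)
    S <- matrix(runif(2 * n), n, 2)
    specs <- default_kernel_specs(S, n_lengthscales = 2L, n_periods = 2L)
    res <- run_smash(Y, S, kernels = specs)
    t_mat <- attr(res, "per_kernel_stat")
    p_mat <- attr(res, "per_kernel_p")

    X <- covariate_design(NULL, n)
    Yr <- residualize(Y, X)
    for (r in seq_along(specs)) {
      K <- build_kernel(specs[[r]], S)
      Kc <- residual_kernel(K, X)
      for (g in c(1, 17, 50)) {
        expect_equal(t_mat[g, r], smash_statistic(Yr[g, ], K),
                     tolerance = 1e-12)
        if (specs[[r]]$family == "linear_projection") {
          expect_equal(p_mat[g, r], sparkx_pvalue(Yr[g, ], K),
                       tolerance = 1e-10)
        } else {
          expect_equal(p_mat[g, r],
                       gamma_pvalue(t_mat[g, r],
                                    gamma_null_params(Kc, n)),
                       tolerance = 1e-12)
        }
      }
    }
    # combined columns recompute from the per-kernel matrix
    is_proj <- vapply(specs, function(s) s$family == "linear_projection",
                      logical(1))
    expect_equal(res$p_smash, apply(p_mat, 1, combine_min_p))
    expect_equal(res$p_sparkx,
                 apply(p_mat[, is_proj, drop = FALSE], 1, combine_cauchy))
    expect_equal(res$p_adjust_smash, adjust_fdr(res$p_smash, "BY"))
  })
})

test_that("SPARK-X emerges as the projection-kernel special case", {
  withr::with_seed(66, {
    n <- 80
    S <- matrix(runif(2 * n), n, 2)
    Y <- matrix(rpois(40 * n, 3), 40, n)
    storage.mode(Y) <- "double"
    rownames(Y) <- paste0("g", 1:40)
    proj_specs <- Filter(function(s) s$family == "linear_projection",
                         default_kernel_specs(S))
    res <- run_smash(Y, S, kernels = proj_specs)

    Yr <- residualize(Y, covariate_design(NULL, n))
    standalone <- vapply(seq_len(40), function(g) {
      ps <- vapply(proj_specs, function(sp) {
        sparkx_pvalue(Yr[g, ],
                      transform_coordinates(S, sp$transform, sp$scales))
      }, numeric(1))
      combine_cauchy(ps)
    }, numeric(1))
    expect_equal(res$p_sparkx, standalone, tolerance = 1e-10)
  })
})

test_that("output rows align with input genes and degenerate genes report p = 1", {
  withr::with_seed(91, {
    n <- 40
    S <- matrix(runif(2 * n), n, 2)
    Y <- matrix(rpois(6 * n, 4), 6, n)
    storage.mode(Y) <- "double"
    Y[3, ] <- 7          # constant gene: zero residual variance
    rownames(Y) <- paste0("g", 1:6)
    res <- run_smash(Y, S, n_lengthscales = 2L, n_periods = 2L)
    expect_identical(nrow(res), 6L)
    expect_identical(res$gene_id, rownames(Y))
    expect_equal(res$p_smash[3], 1)
    expect_equal(res$p_sparkx[3], 1)
    expect_true(is.na(res$statistic_best_kernel[3]))
    expect_true(all(res$p_smash >= 0 & res$p_smash <= 1))
  })
})

test_that("pure-noise genes are rejected at no more than a conservative rate", {
  withr::with_seed(101, {
    n <- 300
    S <- matrix(runif(2 * n), n, 2)
    Y <- matrix(rnorm(200 * n), 200, n)
    rownames(Y) <- paste0("g", 1:200)
    res <- run_smash(Y, S)
    expect_lte(rejection_rate(res$p_smash, 0.05), 0.08)
  })
})
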