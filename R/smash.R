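#' Kernel association statistic for one gene
#'
#' Computes `T = y' K y / (N y'y)`, the trace-form dependence statistic
#' `tr(E K) / N` with the rank-one expression Gram matrix
#' `E = y (y'y)^{-1} y'` collapsed to a quadratic form (E is never
#' materialized). `y` must already be residualized/centered; the statistic
#' is invariant to rescaling of `y`.
#'
#' @param y_resid Length-N residualized expression vector.
#' @param K A `kernel_matrix` or N x N symmetric matrix.
#' @return The statistic (a scalar).
#' @export
smash_statistic <- function(y_resid, K) {
  V <- kernel_values(K)
  n <- length(y_resid)
  stopifnot(nrow(V) == n)
  yy <- sum(y_resid^2)
  if (yy <= 0) stop("degenerate expression vector (zero residual variance)",
                    call. = FALSE)
  as.numeric(crossprod(y_resid, V %*% y_resid)) / (n * yy)
}

#' Gamma parameters of the null distribution
#'
#' Moment-matched (Welch-Satterthwaite) gamma approximation to the
#' quadratic-form null of the kernel statistic:
#' `E(T) = tr(K)/N^2`, `V(T) = 2 tr(K^2)/N^4`, shape `= E^2/V`,
#' scale `= V/E`. The traces are taken from the kernel as given; pass the
#' covariate-projected kernel (see [residual_kernel()]) to obtain the null
#' used by the testing pipeline.
#'
#' @param K A `kernel_matrix` or symmetric matrix.
#' @param n Number of locations N.
#' @return List with `shape`, `scale`, `mean`, `variance`.
#' @export
gamma_null_params <- function(K, n) {
  tr <- kernel_traces(K)
  if (tr[["trace_sq"]] <= 0) stop("tr(K^2) must be positive", call. = FALSE)
  if (tr[["trace"]] <= 0) {
    stop("tr(K) must be positive for the gamma null", call. = FALSE)
  }
  Em <- tr[["trace"]] / n^2
  Vm <- 2 * tr[["trace_sq"]] / n^4
  list(shape = Em^2 / Vm, scale = Vm / Em, mean = Em, variance = Vm)
}

#' Upper-tail gamma p-value
#'
#' @param T_stat Observed statistic.
#' @param params Output of [gamma_null_params()].
#' @return `P(Gamma(shape, scale) > T)`, clipped to `[1e-300, 1]`.
#' @export
gamma_pvalue <- function(T_stat, params) {
  p <- stats::pgamma(T_stat, shape = params$shape, scale = params$scale,
                     lower.tail = FALSE)
  clip_pvalue(p)
}

#' Projection-kernel (SPARK-X) p-value
#'
#' For an idempotent rank-r projection kernel the quadratic-form null — a
#' weighted mixture of chi-square(1) variables with weights given by the
#' eigenvalue products of the rank-one expression Gram matrix and the
#' projection — collapses to `N^2 T ~ chi^2_r`. Equivalently `N R^2` for the
#' regression of `y` on the centered transformed coordinates.
#'
#' @param y_resid Length-N residualized expression vector.
#' @param K_proj A projection `kernel_matrix` (from [projection_kernel()]),
#'   or an N x r basis/coordinate matrix to project on.
#' @return Upper-tail chi-square p-value.
#' @export
sparkx_pvalue <- function(y_resid, K_proj) {
  n <- length(y_resid)
  yy <- sum(y_resid^2)
  if (yy <= 0) stop("degenerate expression vector (zero residual variance)",
                    call. = FALSE)
  if (inherits(K_proj, "kernel_matrix")) {
    r <- if (!is.null(K_proj$rank)) K_proj$rank else round(K_proj$trace)
    stat <- n^2 * smash_statistic(y_resid, K_proj)
  } else {
    Q <- projection_basis(K_proj)
    r <- ncol(Q)
    stat <- n * sum(as.vector(crossprod(Q, y_resid))^2) / yy
  }
  clip_pvalue(stats::pchisq(stat, df = r, lower.tail = FALSE))
}

#' Minimum-p combination across kernels
#'
#' Bonferroni-corrected minimum: `min(1, R * min(p))`. Conservative under
#' dependence among the per-kernel tests. The Sidak variant
#' `1 - (1 - min p)^R` is available via `method`.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` (default) or `"sidak"`.
#' @return Combined p-value.
#' @export
combine_min_p <- function(ps, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (length(ps) == 0L) stop("no p-values to combine", call. = FALSE)
  stopifnot(all(ps >= 0 & ps <= 1))
  R <- length(ps)
  if (method == "bonferroni") min(1, R * min(ps))
  else 1 - (1 - min(ps))^R
}

#' Cauchy combination of p-values
#'
#' Transforms each p to `tan((0.5 - p) * pi)`, averages, and maps back:
#' `0.5 - atan(mean)/pi`. Robust to dependence and driven by the smallest
#' p-values. Inputs at exactly 0 or 1 are clipped to `[1e-15, 1 - 1e-15]`.
#'
#' @param ps Numeric vector of p-values.
#' @return Combined p-value.
#' @export
combine_cauchy <- function(ps) {
  if (length(ps) == 0L) stop("no p-values to combine", call. = FALSE)
  stopifnot(all(ps >= 0 & ps <= 1))
  ps <- pmin(pmax(ps, 1e-15), 1 - 1e-15)
  t_bar <- mean(tan((0.5 - ps) * pi))
  clip_pvalue(0.5 - atan(t_bar) / pi)
}

#' FDR adjustment (Benjamini-Yekutieli / Benjamini-Hochberg)
#'
#' Step-up adjusted p-values; BY multiplies the BH values by the harmonic
#' sum `c(m) = sum_{i<=m} 1/i`, making the control valid under arbitrary
#' dependence. Values are monotone-enforced, clipped at 1, and returned in
#' the input order.
#'
#' @param ps Numeric vector of p-values.
#' @param method `"BY"` (default) or `"BH"`.
#' @return Adjusted p-values, same length and order as `ps`.
#' @export
adjust_fdr <- function(ps, method = c("BY", "BH")) {
  method <- match.arg(method)
  stopifnot(all(ps >= 0 & ps <= 1))
  stats::p.adjust(ps, method = method)
}

# Statistics for all genes against one dense kernel, as batched quadratic
# forms: rowSums((Y K) * Y) / (N * rowSums(Y^2)).
batched_statistics <- function(Yr, K_values, row_ss) {
  n <- ncol(Yr)
  num <- rowSums((Yr %*% K_values) * Yr)
  num / (n * row_ss)
}

#' Run the kernel SVG tests over all genes
#'
#' The full testing pipeline: residualizes every gene against the covariate
#' design (intercept-only if none), builds each kernel in the family once,
#' computes all genes' statistics per kernel as batched quadratic forms,
#' converts them to p-values (gamma null for Gaussian/cosine kernels, with
#' moments from the covariate-projected kernel; exact chi-square for
#' projection kernels), combines per-gene p-values across all kernels with
#' the minimum-p rule (the SMASH result), separately combines the
#' projection-kernel p-values with the Cauchy rule (the SPARK-X result), and
#' adjusts both with the requested FDR procedure.
#'
#' Genes whose residual variance is (numerically) zero are kept in the
#' output with p = 1 so rows align with the input.
#'
#' @param Y genes x locations expression matrix.
#' @param S N x d coordinate matrix (rows match columns of `Y`).
#' @param X Optional N x q covariate matrix (an intercept is always
#'   included); `NULL` for intercept-only.
#' @param kernels List of `kernel_spec`s, or `NULL` for
#'   [default_kernel_specs()] on `S`.
#' @param families,n_lengthscales,n_periods,pd_adjust Passed to
#'   [default_kernel_specs()] when `kernels` is `NULL`.
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @param fdr_level Significance level for the `is_svg_*` calls
#'   (default 0.05).
#' @param min_p_method Passed to [combine_min_p()].
#' @return A `data.frame` of class `"smash_result"` with one row per input
#'   gene and columns `gene_id`, `statistic_best_kernel`, `kernel_family`,
#'   `kernel_param`, `p_smash`, `p_adjust_smash`, `p_sparkx`,
#'   `p_adjust_sparkx`, `is_svg_smash`, `is_svg_sparkx`. The per-kernel
#'   p-value matrix and the kernel specs are attached as attributes
#'   `"per_kernel_p"`, `"per_kernel_stat"` and `"kernel_specs"`.
#' @export
run_smash <- function(Y, S, X = NULL, kernels = NULL,
                      families = c("gaussian", "cosine", "linear_projection"),
                      n_lengthscales = 10L, n_periods = 10L,
                      pd_adjust = FALSE,
                      fdr_method = c("BY", "BH"), fdr_level = 0.05,
                      min_p_method = c("bonferroni", "sidak")) {
  fdr_method <- match.arg(fdr_method)
  min_p_method <- match.arg(min_p_method)
  Y <- check_expression(Y)
  S <- check_coords(S)
  if (ncol(Y) != nrow(S)) {
    stop(sprintf("expression has %d locations but coordinates have %d",
                 ncol(Y), nrow(S)), call. = FALSE)
  }
  n <- nrow(S)
  X <- covariate_design(X, n = n)
  if (is.null(kernels)) {
    kernels <- default_kernel_specs(S, families = families,
                                    n_lengthscales = n_lengthscales,
                                    n_periods = n_periods,
                                    pd_adjust = pd_adjust)
  }
  stopifnot(length(kernels) >= 1L)

  Yr <- residualize(Y, X)
  row_ss <- rowSums(Yr^2)
  scale_ref <- rowSums(Y^2)
  degenerate <- row_ss <= pmax(scale_ref, 1) * 1e-12
  if (all(degenerate)) stop("all genes are degenerate after residualization",
                            call. = FALSE)
  row_ss[degenerate] <- 1  # placeholder; overwritten with p = 1 below

  n_genes <- nrow(Y)
  R <- length(kernels)
  p_mat <- matrix(NA_real_, n_genes, R)
  t_mat <- matrix(NA_real_, n_genes, R)
  is_proj <- vapply(kernels, function(s) s$family == "linear_projection",
                    logical(1L))

  for (r in seq_len(R)) {
    spec <- kernels[[r]]
    if (is_proj[r]) {
      Q <- projection_basis(transform_coordinates(S, spec$transform,
                                                  spec$scales))
      B <- Yr %*% Q
      stat <- n * rowSums(B^2) / row_ss        # = N^2 T = N R^2
      t_mat[, r] <- stat / n^2
      p_mat[, r] <- clip_pvalue(stats::pchisq(stat, df = ncol(Q),
                                              lower.tail = FALSE))
    } else {
      K <- build_kernel(spec, S)
      Kc <- residual_kernel(K, X)
      params <- gamma_null_params(Kc, n)
      t_mat[, r] <- batched_statistics(Yr, K$values, row_ss)
      p_mat[, r] <- gamma_pvalue(t_mat[, r], params)
    }
  }

  p_smash <- apply(p_mat, 1L, combine_min_p, method = min_p_method)
  p_sparkx <- if (any(is_proj)) {
    apply(p_mat[, is_proj, drop = FALSE], 1L, combine_cauchy)
  } else rep(NA_real_, n_genes)
  p_smash[degenerate] <- 1
  if (any(is_proj)) p_sparkx[degenerate] <- 1

  p_adj_smash <- adjust_fdr(p_smash, fdr_method)
  p_adj_sparkx <- if (any(is_proj)) adjust_fdr(p_sparkx, fdr_method) else
    rep(NA_real_, n_genes)

  # Best kernel per gene: smallest p, ties broken by larger statistic then
  # kernel order.
  best <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    o <- order(p_mat[g, ], -t_mat[g, ])
    best[g] <- o[1L]
  }
  fam <- vapply(kernels, function(s) s$family, character(1L))
  par <- vapply(kernels, function(s) {
    switch(s$family,
           gaussian = format(s$lengthscale, digits = 6),
           cosine = format(s$period, digits = 6),
           linear_projection = s$transform)
  }, character(1L))

  out <- data.frame(
    gene_id = rownames(Y),
    statistic_best_kernel = t_mat[cbind(seq_len(n_genes), best)],
    kernel_family = fam[best],
    kernel_param = par[best],
    p_smash = p_smash,
    p_adjust_smash = p_adj_smash,
    p_sparkx = p_sparkx,
    p_adjust_sparkx = p_adj_sparkx,
    stringsAsFactors = FALSE
  )
  out$statistic_best_kernel[degenerate] <- NA_real_
  out$kernel_family[degenerate] <- NA_character_
  out$kernel_param[degenerate] <- NA_character_
  out$is_svg_smash <- out$p_adjust_smash < fdr_level
  out$is_svg_sparkx <- out$p_adjust_sparkx < fdr_level
  attr(out, "per_kernel_p") <- p_mat
  attr(out, "per_kernel_stat") <- t_mat
  attr(out, "kernel_specs") <- kernels
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("smash_result", "data.frame")
  out
}

#' @exportS3Method base::print
print.smash_result <- function(x, ...) {
  n_svg <- sum(x$is_svg_smash, na.rm = TRUE)
  n_svg_x <- sum(x$is_svg_sparkx, na.rm = TRUE)
  cat(sprintf(
    "Kernel SVG test results: %d genes, %d kernels; %d SVGs (SMASH), %d SVGs (SPARK-X) at FDR %.2g\n",
    nrow(x), length(attr(x, "kernel_specs")), n_svg, n_svg_x,
    attr(x, "fdr_level")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
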