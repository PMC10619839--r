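#' Kernel specification
#'
#' A lightweight descriptor of a spatial kernel: its family and the single
#' hyperparameter that family uses (`lengthscale` for Gaussian, `period` for
#' cosine, a coordinate `transform` plus per-dimension `scales` for
#' linear-projection kernels).
#'
#' @param family `"gaussian"`, `"cosine"` or `"linear_projection"`.
#' @param lengthscale Gaussian characteristic lengthscale (> 0).
#' @param period Cosine period (> 0).
#' @param transform For projection kernels: `"identity"`,
#'   `"gaussian_transform"` or `"cosine_transform"`.
#' @param scales Per-dimension positive scales for a non-identity transform.
#' @param pd_adjust Whether negative eigenvalues are truncated after
#'   construction (relevant for the cosine family, which is indefinite).
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("gaussian", "cosine", "linear_projection"),
                        lengthscale = NULL, period = NULL,
                        transform = c("identity", "gaussian_transform",
                                      "cosine_transform"),
                        scales = NULL, pd_adjust = FALSE) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (family == "gaussian") {
    assert_scalar_positive(lengthscale, "lengthscale")
    period <- NULL; transform <- NULL; scales <- NULL
  } else if (family == "cosine") {
    assert_scalar_positive(period, "period")
    lengthscale <- NULL; transform <- NULL; scales <- NULL
  } else {
    lengthscale <- NULL; period <- NULL
    if (transform != "identity") {
      stopifnot(is.numeric(scales), all(scales > 0))
    } else scales <- NULL
  }
  structure(list(family = family, lengthscale = lengthscale, period = period,
                 transform = transform, scales = scales,
                 pd_adjust = isTRUE(pd_adjust)),
            class = "kernel_spec")
}

#' @exportS3Method base::format
format.kernel_spec <- function(x, ...) {
  param <- switch(x$family,
    gaussian = sprintf("l=%.4g", x$lengthscale),
    cosine = sprintf("p=%.4g", x$period),
    linear_projection = x$transform)
  paste0(x$family, "(", param, ")")
}

#' @exportS3Method base::print
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", format(x), "\n"); invisible(x)
}

new_kernel_matrix <- function(values, spec) {
  structure(list(values = values,
                 trace = sum(diag(values)),
                 trace_sq = sum(values^2),
                 spec = spec),
            class = "kernel_matrix")
}

#' @exportS3Method base::print
print.kernel_matrix <- function(x, ...) {
  lab <- if (is.null(x$spec)) "custom" else format(x$spec)
  cat(sprintf("<kernel_matrix> %s  N=%d  tr=%.4g  tr(K^2)=%.4g\n",
              lab, nrow(x$values), x$trace, x$trace_sq))
  invisible(x)
}

# Accept either a kernel_matrix or a plain symmetric matrix.
kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

#' Pairwise Euclidean distances between locations
#'
#' @param S N x d coordinate matrix.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(S) {
  S <- check_coords(S)
  as.matrix(stats::dist(S))
}

#' Gaussian (squared-exponential) spatial kernel
#'
#' Entries `exp(-d_ij^2 / (2 l^2))`: unit diagonal, positive semidefinite,
#' correlation decaying with distance at rate set by the lengthscale.
#'
#' @param S N x d coordinate matrix.
#' @param lengthscale Characteristic lengthscale l > 0.
#' @return A `kernel_matrix`.
#' @export
gaussian_kernel <- function(S, lengthscale) {
  assert_scalar_positive(lengthscale, "lengthscale")
  d <- pairwise_distances(S)
  new_kernel_matrix(exp(-d^2 / (2 * lengthscale^2)),
                    kernel_spec("gaussian", lengthscale = lengthscale))
}

#' Cosine (periodic) spatial kernel
#'
#' Entries `cos(2 pi d_ij / p)`: unit diagonal, capturing periodic spatial
#' covariance at wavelength `p`. The matrix is generally indefinite; see
#' [truncate_negative_eigenvalues()] for the positive-semidefinite repair.
#'
#' @param S N x d coordinate matrix.
#' @param period Period p > 0.
#' @param pd_adjust If `TRUE`, truncate negative eigenvalues after
#'   construction.
#' @return A `kernel_matrix`.
#' @export
cosine_kernel <- function(S, period, pd_adjust = FALSE) {
  assert_scalar_positive(period, "period")
  d <- pairwise_distances(S)
  K <- new_kernel_matrix(cos(2 * pi * d / period),
                         kernel_spec("cosine", period = period,
                                     pd_adjust = pd_adjust))
  if (pd_adjust) K <- truncate_negative_eigenvalues(K) else K
}

#' Element-wise non-linear coordinate transforms
#'
#' Applies, per dimension t, either `exp(-s^2 / (2 sigma_t^2))`
#' (`"gaussian_transform"`) or `cos(2 pi s / phi_t)` (`"cosine_transform"`)
#' to the raw coordinates; `"identity"` returns the input. Used to build the
#' transformed-coordinate projection kernels of the linear family.
#'
#' @param S N x d coordinate matrix.
#' @param kind Transform name.
#' @param scales Positive scale per dimension (ignored for identity).
#' @return Transformed N x d matrix.
#' @export
transform_coordinates <- function(S,
                                  kind = c("identity", "gaussian_transform",
                                           "cosine_transform"),
                                  scales = NULL) {
  kind <- match.arg(kind)
  S <- check_coords(S)
  if (kind == "identity") return(S)
  stopifnot(is.numeric(scales), length(scales) == ncol(S))
  if (any(scales <= 0)) stop("transform scales must be positive",
                             call. = FALSE)
  out <- if (kind == "gaussian_transform") {
    exp(-sweep(S^2, 2L, 2 * scales^2, "/"))
  } else {
    cos(sweep(S, 2L, scales, "/") * 2 * pi)
  }
  dimnames(out) <- dimnames(S)
  out
}

#' Projection (linear) kernel from transformed coordinates
#'
#' Column-centers `M` and returns the hat matrix `M (M'M)^{-1} M'` of the
#' linear regression on the centered columns: idempotent, with trace equal
#' to its rank. This is the distance-covariance kernel of the SPARK-X score
#' test.
#'
#' @param M N x r matrix of (transformed) coordinates.
#' @param spec Optional `kernel_spec` to attach.
#' @return A `kernel_matrix` whose spec records the rank in `scales`.
#' @export
projection_kernel <- function(M, spec = NULL) {
  M <- as.matrix(M)
  M <- sweep(M, 2L, colMeans(M), "-")
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    stop("transformed coordinates are collinear after centering",
         call. = FALSE)
  }
  Q <- qr.Q(qm)
  K <- tcrossprod(Q)
  if (is.null(spec)) spec <- kernel_spec("linear_projection")
  out <- new_kernel_matrix(K, spec)
  out$rank <- ncol(M)
  out
}

# Orthonormal basis of the centered (transformed) coordinates; cheaper than
# materializing the N x N projection kernel when only quadratic forms are
# needed.
projection_basis <- function(M) {
  M <- as.matrix(M)
  M <- sweep(M, 2L, colMeans(M), "-")
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    stop("transformed coordinates are collinear after centering",
         call. = FALSE)
  }
  qr.Q(qm)
}

# Distance matrix on a subsample of at most `cap` locations; deterministic
# for a given subsample seed.
subsampled_distances <- function(S, cap = 2000L, seed = 1L) {
  S <- check_coords(S)
  n <- nrow(S)
  if (n > cap) {
    idx <- with_seed_or_not(seed, sample.int(n, cap))
    S <- S[idx, , drop = FALSE]
  }
  D <- as.matrix(stats::dist(S))
  if (all(D == 0)) stop("all pairwise distances are zero", call. = FALSE)
  D
}

# Shared grid rule: n log-spaced values from the median nonzero
# nearest-neighbor distance (the sampling-resolution limit, below which no
# kernel can resolve spatial structure) up to the 97.5th percentile of the
# pairwise distances (the tissue extent). Spanning resolution to extent lets
# the family detect both very short-range and long-range covariance.
distance_quantile_grid <- function(S, n, cap, seed) {
  stopifnot(n >= 1L)
  D <- subsampled_distances(S, cap = cap, seed = seed)
  nn <- apply(D, 1L, function(row) {
    pos <- row[row > 0]
    if (length(pos)) min(pos) else NA_real_
  })
  lo <- stats::median(nn, na.rm = TRUE)
  dv <- D[upper.tri(D)]
  hi <- stats::quantile(dv[dv > 0], 0.975, names = FALSE)
  if (lo >= hi) return(lo)  # degenerate span collapses to one value
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Data-driven lengthscale grid for the Gaussian kernel
#'
#' Returns `n` strictly increasing lengthscales, logarithmically spaced
#' from the median nearest-neighbor distance (the sampling resolution, the
#' shortest scale at which covariance is observable) to the 97.5th
#' percentile of the pairwise distances (the tissue extent). Distances are
#' computed on a random subsample of at most `cap` locations for
#' scalability; `subsample_seed` makes the subsample reproducible.
#'
#' @param S N x d coordinate matrix.
#' @param n Number of grid values (default 10).
#' @param cap Subsample cap for the distance computation.
#' @param subsample_seed Seed for the subsample draw.
#' @return Increasing positive numeric vector (length `n`, or 1 when the
#'   percentile span is degenerate).
#' @export
default_lengthscales <- function(S, n = 10L, cap = 2000L,
                                 subsample_seed = 1L) {
  distance_quantile_grid(S, n, cap, subsample_seed)
}

#' Data-driven period grid for the cosine kernel
#'
#' Same construction as [default_lengthscales()], applied to the period
#' hyperparameter: periods spanning short- to long-wavelength structure
#' relative to the observed inter-location distances.
#'
#' @inheritParams default_lengthscales
#' @return Increasing positive numeric vector.
#' @export
default_periods <- function(S, n = 10L, cap = 2000L, subsample_seed = 1L) {
  distance_quantile_grid(S, n, cap, subsample_seed)
}

# Per-dimension scales for the transformed projection kernels: {25, 50, 75}%
# quantiles of |centered coordinate|, one scale vector per quantile level.
transform_scale_grid <- function(S, probs = c(0.25, 0.5, 0.75)) {
  S <- check_coords(S)
  Sc <- abs(sweep(S, 2L, colMeans(S), "-"))
  lapply(probs, function(p) {
    sc <- apply(Sc, 2L, stats::quantile, probs = p, names = FALSE)
    pmax(sc, .Machine$double.eps)
  })
}

#' Truncate negative eigenvalues of a kernel matrix
#'
#' Eigendecomposes a symmetric kernel and zeroes its negative eigenvalues,
#' returning the nearest positive-semidefinite matrix in Frobenius norm.
#' Used to repair the indefinite cosine kernel when a proper covariance is
#' required (e.g. for Gaussian-process sampling).
#'
#' @param K A `kernel_matrix` or symmetric numeric matrix.
#' @return Object of the same type with non-negative spectrum.
#' @export
truncate_negative_eigenvalues <- function(K) {
  V <- kernel_values(K)
  e <- eigen(V, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(V)
  if (inherits(K, "kernel_matrix")) {
    spec <- K$spec
    spec$pd_adjust <- TRUE
    new_kernel_matrix(out, spec)
  } else out
}

#' Trace quantities of a kernel matrix
#'
#' Returns `tr(K)` and `tr(K^2)`; the latter is computed as the sum of
#' squared entries (valid for symmetric K), avoiding any eigendecomposition
#' so the cost stays quadratic in N.
#'
#' @param K A `kernel_matrix` or symmetric numeric matrix.
#' @return Named numeric vector `c(trace = , trace_sq = )`.
#' @export
kernel_traces <- function(K) {
  if (inherits(K, "kernel_matrix")) {
    return(c(trace = K$trace, trace_sq = K$trace_sq))
  }
  V <- as.matrix(K)
  c(trace = sum(diag(V)), trace_sq = sum(V^2))
}

#' Project a kernel onto the residual space of a design matrix
#'
#' Returns `P K P` with `P = I - X (X'X)^{-1} X'`. After expression vectors
#' are residualized against `X`, the test statistic depends on the kernel
#' only through this projected matrix, so its traces are the ones that
#' parameterize the null distribution. With an intercept-only design this is
#' the doubly centered kernel.
#'
#' @param K A `kernel_matrix` or symmetric matrix.
#' @param X N x q full-rank design matrix.
#' @return A `kernel_matrix` with updated traces.
#' @export
residual_kernel <- function(K, X) {
  V <- kernel_values(K)
  Q <- qr.Q(qr(as.matrix(X)))
  A <- V %*% Q                       # N x q
  QtA <- crossprod(Q, A)             # q x q
  out <- V - tcrossprod(Q, A) - tcrossprod(A, Q) + Q %*% QtA %*% t(Q)
  out <- (out + t(out)) / 2
  spec <- if (inherits(K, "kernel_matrix")) K$spec else NULL
  new_kernel_matrix(out, spec)
}

#' Build the default kernel family for a coordinate set
#'
#' Assembles the kernel list the test aggregates over: Gaussian kernels on a
#' data-driven lengthscale grid, cosine kernels on a period grid, and the
#' linear-projection family (identity plus Gaussian- and cosine-transformed
#' coordinates at three data-driven scale levels).
#'
#' @param S N x d coordinate matrix.
#' @param families Character subset of
#'   `c("gaussian", "cosine", "linear_projection")`.
#' @param n_lengthscales,n_periods Grid sizes (default 10 each).
#' @param pd_adjust Truncate negative eigenvalues of cosine kernels.
#' @param cap,subsample_seed Passed to the grid constructors.
#' @return List of `kernel_spec` objects (projection specs carry their
#'   transform and scales; materialize with [build_kernel()]).
#' @export
default_kernel_specs <- function(S,
                                 families = c("gaussian", "cosine",
                                              "linear_projection"),
                                 n_lengthscales = 10L, n_periods = 10L,
                                 pd_adjust = FALSE, cap = 2000L,
                                 subsample_seed = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  specs <- list()
  if ("gaussian" %in% families) {
    for (l in default_lengthscales(S, n_lengthscales, cap, subsample_seed)) {
      specs <- c(specs, list(kernel_spec("gaussian", lengthscale = l)))
    }
  }
  if ("cosine" %in% families) {
    for (p in default_periods(S, n_periods, cap, subsample_seed)) {
      specs <- c(specs, list(kernel_spec("cosine", period = p,
                                         pd_adjust = pd_adjust)))
    }
  }
  if ("linear_projection" %in% families) {
    specs <- c(specs, list(kernel_spec("linear_projection")))
    for (sc in transform_scale_grid(S)) {
      specs <- c(specs,
                 list(kernel_spec("linear_projection",
                                  transform = "gaussian_transform",
                                  scales = sc)),
                 list(kernel_spec("linear_projection",
                                  transform = "cosine_transform",
                                  scales = sc)))
    }
  }
  specs
}

#' Materialize a kernel matrix from a spec
#'
#' @param spec A `kernel_spec`.
#' @param S N x d coordinate matrix.
#' @return A `kernel_matrix`.
#' @export
build_kernel <- function(spec, S) {
  stopifnot(inherits(spec, "kernel_spec"))
  switch(spec$family,
    gaussian = gaussian_kernel(S, spec$lengthscale),
    cosine = cosine_kernel(S, spec$period, pd_adjust = spec$pd_adjust),
    linear_projection = projection_kernel(
      transform_coordinates(S, spec$transform, spec$scales), spec = spec))
}
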