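#' Simulation configuration
#'
#' Bundles the parameters of the three synthetic-data setups:
#' `"nb_pattern"` (negative binomial counts with a streak/hotspot mean
#' pattern at a given fold change), `"gp_gaussian"` and `"gp_cosine"`
#' (zero-mean Gaussian-process expression with covariance
#' `h * K + (1 - h) * I`, so the spatial and noise variances sum to one:
#' `tau^2 = h`, `sigma^2 = 1 - h`).
#'
#' @param setup `"nb_pattern"`, `"gp_gaussian"` or `"gp_cosine"`.
#' @param n Number of locations N.
#' @param n_genes Number of genes K.
#' @param pattern Setup-1 pattern: `"streak"`, `"reverse_streak"`,
#'   `"hotspot"`, `"reverse_hotspot"`.
#' @param pattern_frac Fraction of locations inside the pattern
#'   (default 0.2).
#' @param fold Setup-1 fold change of patterned vs background mean
#'   (fold = 1 is the null).
#' @param signal_frac Fraction of genes carrying signal (default 0.5).
#' @param base_mean,dispersion Setup-1 negative binomial baseline mean and
#'   size (dispersion) parameters.
#' @param param Setup-2 lengthscale l / setup-3 period p.
#' @param h Setups 2-3 effect size in `[0, 1]`: the spatial share of the
#'   unit total variance (h = 0 is the null).
#' @param window Axis-aligned rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param seed Integer seed; all generation is reproducible given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(setup = c("nb_pattern", "gp_gaussian", "gp_cosine"),
                       n = 1000L, n_genes = 500L,
                       pattern = c("streak", "reverse_streak", "hotspot",
                                   "reverse_hotspot"),
                       pattern_frac = 0.2, fold = 3, signal_frac = 0.5,
                       base_mean = 2, dispersion = 10,
                       param = 0.5, h = 0.4,
                       window = c(0, 5, 0, 5), seed = 1L) {
  setup <- match.arg(setup)
  pattern <- match.arg(pattern)
  stopifnot(n >= 2L, n_genes >= 1L, fold >= 1, h >= 0, h <= 1,
            pattern_frac > 0, pattern_frac < 1, base_mean > 0,
            dispersion > 0, param > 0, signal_frac >= 0, signal_frac <= 1)
  structure(list(setup = setup, n = as.integer(n),
                 n_genes = as.integer(n_genes), pattern = pattern,
                 pattern_frac = pattern_frac, fold = fold,
                 signal_frac = signal_frac, base_mean = base_mean,
                 dispersion = dispersion, param = param, h = h,
                 window = window, seed = as.integer(seed)),
            class = "sim_config")
}

#' Uniform point-pattern locations
#'
#' Draws N i.i.d. uniform locations in a rectangular window — a homogeneous
#' Poisson point process conditioned on its count.
#'
#' @param n Number of locations (>= 2).
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param seed Optional integer seed.
#' @return N x 2 coordinate matrix with rownames `loc1..locN`.
#' @export
poisson_locations <- function(n, window = c(0, 5, 0, 5), seed = NULL) {
  stopifnot(n >= 2L, length(window) == 4L,
            window[2] > window[1], window[4] > window[3])
  S <- with_seed_or_not(seed, cbind(
    x = stats::runif(n, window[1], window[2]),
    y = stats::runif(n, window[3], window[4])))
  rownames(S) <- paste0("loc", seq_len(n))
  S
}

#' Pattern membership mask
#'
#' Marks `round(frac * N)` locations as "patterned": for the streak
#' patterns, the band of locations with the largest first coordinate; for
#' the hotspot patterns, the locations nearest the window center. The
#' reverse variants share the mask — the fold change is applied to the
#' complementary side by [nb_counts()].
#'
#' @param S N x d coordinate matrix.
#' @param pattern Pattern name.
#' @param frac Fraction of patterned locations (default 0.2).
#' @return Logical length-N vector.
#' @export
assign_pattern <- function(S, pattern = c("streak", "reverse_streak",
                                          "hotspot", "reverse_hotspot"),
                           frac = 0.2) {
  pattern <- match.arg(pattern)
  S <- check_coords(S)
  stopifnot(frac > 0, frac < 1)
  n <- nrow(S)
  m <- round(frac * n)
  mask <- rep(FALSE, n)
  if (grepl("streak", pattern)) {
    mask[order(S[, 1L], decreasing = TRUE)[seq_len(m)]] <- TRUE
  } else {
    center <- apply(S, 2L, function(v) mean(range(v)))
    d2 <- rowSums(sweep(S, 2L, center, "-")^2)
    mask[order(d2)[seq_len(m)]] <- TRUE
  }
  mask
}

#' Negative binomial counts with a spatial mean pattern
#'
#' Simulates genes x locations counts. The first `signal_frac * K` genes are
#' signal genes whose mean is `fold * base_mean` on the patterned locations
#' (on the background for `reverse_*` patterns) and `base_mean` elsewhere;
#' the remaining genes are spatially flat. `fold = 1` makes every gene null.
#'
#' @param mask Logical length-N pattern mask from [assign_pattern()].
#' @param config A [sim_config()] with `setup = "nb_pattern"`.
#' @return genes x locations count matrix; attribute `"is_signal"` holds the
#'   truth labels.
#' @export
nb_counts <- function(mask, config) {
  stopifnot(inherits(config, "sim_config"), is.logical(mask))
  n <- length(mask)
  K <- config$n_genes
  n_sig <- round(config$signal_frac * K)
  is_signal <- seq_len(K) <= n_sig
  high_side <- if (grepl("^reverse", config$pattern)) !mask else mask
  mu_base <- rep(config$base_mean, n)
  mu_sig <- mu_base
  mu_sig[high_side] <- config$fold * config$base_mean
  Y <- with_seed_or_not(config$seed, {
    out <- matrix(0, K, n)
    for (k in seq_len(K)) {
      mu <- if (is_signal[k]) mu_sig else mu_base
      out[k, ] <- stats::rnbinom(n, size = config$dispersion, mu = mu)
    }
    out
  })
  dimnames(Y) <- list(paste0("gene", seq_len(K)), paste0("loc", seq_len(n)))
  attr(Y, "is_signal") <- is_signal
  Y
}

#' Gaussian-process expression
#'
#' Draws each gene independently from a zero-mean multivariate normal with
#' covariance `h * K_fam + (1 - h) * I`, where `K_fam` is the unit-diagonal
#' Gaussian or cosine kernel on the locations; the total marginal variance
#' is 1 by construction. The indefinite cosine kernel is repaired by
#' eigenvalue truncation before sampling (the covariance must be a proper
#' covariance; the test itself may still use the unadjusted kernel).
#'
#' @param S N x d coordinate matrix.
#' @param family `"gaussian"` or `"cosine"`.
#' @param param Lengthscale (gaussian) or period (cosine).
#' @param h Effect size in `[0, 1]`.
#' @param n_genes Number of genes.
#' @param seed Optional integer seed.
#' @return genes x locations matrix; attribute `"is_signal"` is all-TRUE
#'   when `h > 0`, all-FALSE when `h = 0`.
#' @export
gp_expression <- function(S, family = c("gaussian", "cosine"), param, h,
                          n_genes, seed = NULL) {
  family <- match.arg(family)
  S <- check_coords(S)
  stopifnot(h >= 0, h <= 1, n_genes >= 1L)
  n <- nrow(S)
  if (h == 0) {
    A <- diag(n)
  } else {
    Kf <- if (family == "gaussian") gaussian_kernel(S, param) else
      cosine_kernel(S, param)
    Sigma <- h * Kf$values + (1 - h) * diag(n)
    e <- eigen(Sigma, symmetric = TRUE)
    lam <- pmax(e$values, 0)  # PSD repair (cosine family is indefinite)
    A <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  }
  Y <- with_seed_or_not(seed,
    matrix(stats::rnorm(n_genes * n), n_genes, n) %*% A)
  dimnames(Y) <- list(paste0("gene", seq_len(n_genes)),
                      paste0("loc", seq_len(n)))
  attr(Y, "is_signal") <- rep(h > 0, n_genes)
  Y
}

#' Permute spatial locations
#'
#' Randomly permutes the coordinate rows while keeping the location IDs in
#' place, breaking the pairing between expression columns and their
#' locations (the permutation null used to check p-value calibration).
#'
#' @param S N x d coordinate matrix.
#' @param seed Optional integer seed.
#' @return Permuted coordinate matrix with the original rownames.
#' @export
permute_locations <- function(S, seed = NULL) {
  S <- check_coords(S)
  ids <- rownames(S)
  perm <- with_seed_or_not(seed, sample.int(nrow(S)))
  out <- S[perm, , drop = FALSE]
  rownames(out) <- ids
  out
}

#' Simulate a full dataset from a configuration
#'
#' Draws locations and expression per the configured setup and returns them
#' together with the ground-truth signal labels.
#'
#' @param config A [sim_config()].
#' @return List with elements `Y` (genes x locations), `S` (N x d),
#'   `is_signal` (logical per gene) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- poisson_locations(config$n, config$window, seed = config$seed)
  if (config$setup == "nb_pattern") {
    mask <- assign_pattern(S, config$pattern, config$pattern_frac)
    cfg_counts <- config
    cfg_counts$seed <- config$seed + 1L  # counts drawn independently of the locations
    Y <- nb_counts(mask, cfg_counts)
  } else {
    fam <- if (config$setup == "gp_gaussian") "gaussian" else "cosine"
    Y <- gp_expression(S, fam, config$param, config$h, config$n_genes,
                       seed = config$seed + 1L)
  }
  list(Y = Y, S = S, is_signal = attr(Y, "is_signal"), config = config)
}
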