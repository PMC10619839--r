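#' Rejection rate at a significance level
#'
#' @param ps Numeric vector of p-values.
#' @param alpha Level in (0, 1).
#' @return Fraction of p-values strictly below `alpha`.
#' @export
rejection_rate <- function(ps, alpha = 0.05) {
  if (length(ps) == 0L) stop("empty p-value list", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  mean(ps < alpha)
}

#' Power and type-I error over a simulation grid
#'
#' For each configuration and method, simulates `replicates` datasets (seeds
#' `base_seed + offset`), runs [run_smash()], and averages the rejection
#' rate at level `alpha` separately over signal genes (power) and null
#' genes (type-I error).
#'
#' @param grid List of [sim_config()] objects.
#' @param methods Character subset of `c("smash", "sparkx")`.
#' @param alpha Significance level (default 0.05).
#' @param replicates Number of replicate datasets per configuration
#'   (default 5).
#' @param base_seed Base seed; replicate r of configuration c uses
#'   `config$seed + 1000 * (r - 1) + base_seed`.
#' @param ... Further arguments passed to [run_smash()] (e.g. `families`).
#' @return A `data.frame` with one row per configuration x method:
#'   setup, n, n_genes, fold, h, param, pattern, method, alpha, power,
#'   type1, n_replicates.
#' @export
power_table <- function(grid, methods = c("smash", "sparkx"), alpha = 0.05,
                        replicates = 5L, base_seed = 0L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1L)
  rows <- list()
  for (config in grid) {
    pow <- stats::setNames(numeric(length(methods)), methods)
    t1 <- pow
    n_pow <- 0L; n_t1 <- 0L
    for (rep_i in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * (rep_i - 1L) + as.integer(base_seed)
      sim <- simulate_dataset(cfg)
      res <- run_smash(sim$Y, sim$S, ...)
      ps <- list(smash = res$p_smash, sparkx = res$p_sparkx)
      for (m in methods) {
        if (any(sim$is_signal)) {
          pow[m] <- pow[m] + rejection_rate(ps[[m]][sim$is_signal], alpha)
        }
        if (any(!sim$is_signal)) {
          t1[m] <- t1[m] + rejection_rate(ps[[m]][!sim$is_signal], alpha)
        }
      }
      n_pow <- n_pow + as.integer(any(sim$is_signal))
      n_t1 <- n_t1 + as.integer(any(!sim$is_signal))
    }
    for (m in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        setup = config$setup, n = config$n, n_genes = config$n_genes,
        fold = config$fold, h = config$h, param = config$param,
        pattern = config$pattern, method = m, alpha = alpha,
        power = if (n_pow > 0L) pow[[m]] / n_pow else NA_real_,
        type1 = if (n_t1 > 0L) t1[[m]] / n_t1 else NA_real_,
        n_replicates = replicates, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Quantile-quantile points for p-value calibration
#'
#' Pairs the sorted observed p-values with the Uniform(0,1) order-statistic
#' expectations `i / (m + 1)`, both on the -log10 scale. Points above the
#' diagonal indicate inflation; below, conservativeness.
#'
#' @param ps Numeric vector of p-values.
#' @return `data.frame` with columns `expected` and `observed`
#'   (-log10 scale), most significant row first.
#' @export
qq_points <- function(ps) {
  if (length(ps) == 0L) stop("empty p-value list", call. = FALSE)
  m <- length(ps)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(clip_pvalue(ps))))
}

#' Marker gene sets from labeled locations
#'
#' For each label, ranks genes by the fold change between mean expression in
#' the label and mean expression elsewhere (with a small pseudocount) and
#' keeps the top `top_n` — the marker sets used for enrichment scoring.
#'
#' @param Y genes x locations expression matrix.
#' @param labels Length-N vector of cell-type/layer labels (>= 2 levels).
#' @param top_n Markers per label (default 50).
#' @param eps Pseudocount guarding zero means (default 1e-9).
#' @return Named list of gene-ID vectors, one per label.
#' @export
build_marker_sets <- function(Y, labels, top_n = 50L, eps = 1e-9) {
  Y <- check_expression(Y)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(Y))
  lev <- unique(labels)
  if (length(lev) < 2L) stop("need at least two labels", call. = FALSE)
  out <- list()
  for (m in lev) {
    inside <- labels == m
    fc <- (rowMeans(Y[, inside, drop = FALSE]) + eps) /
      (rowMeans(Y[, !inside, drop = FALSE]) + eps)
    ord <- order(fc, decreasing = TRUE)
    out[[m]] <- rownames(Y)[ord[seq_len(min(top_n, nrow(Y)))]]
  }
  out
}

#' Unweighted gene-set enrichment score
#'
#' Kolmogorov-Smirnov running-sum statistic: walking down the ranking (most
#' to least significant), add `1/|set|` at each set member and subtract
#' `1/(L - |set|)` otherwise; the score is the running sum's maximum
#' deviation from zero, signed (positive when the set concentrates at the
#' top of the ranking).
#'
#' @param ranked_genes Full ranked gene list, most significant first.
#' @param gene_set Gene IDs to score; must be a nonempty strict subset of
#'   `ranked_genes`.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked_genes, gene_set) {
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  if (anyDuplicated(ranked_genes)) stop("duplicate genes in ranking",
                                        call. = FALSE)
  hit <- ranked_genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit < length(unique(gene_set))) {
    stop("gene_set contains genes absent from the ranking", call. = FALSE)
  }
  L <- length(ranked_genes)
  if (n_hit == L) stop("gene_set must be a strict subset of the ranking",
                       call. = FALSE)
  step <- ifelse(hit, 1 / n_hit, -1 / (L - n_hit))
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Rank genes for enrichment scoring
#'
#' Orders genes from most to least significant by combined p-value, with
#' ties broken by statistic (descending) and then input order, so the
#' ranking — and any enrichment score built on it — is deterministic.
#'
#' @param result A [run_smash()] result.
#' @param method `"smash"` or `"sparkx"` p-values.
#' @return Character vector of gene IDs.
#' @export
rank_genes <- function(result, method = c("smash", "sparkx")) {
  method <- match.arg(method)
  p <- if (method == "smash") result$p_smash else result$p_sparkx
  stat <- result$statistic_best_kernel
  stat[is.na(stat)] <- -Inf
  result$gene_id[order(p, -stat, seq_along(p))]
}

#' Monte-Carlo null draws of the kernel statistic
#'
#' Draws standard-normal expression vectors, centers them, and returns the
#' kernel statistic for each — the empirical null against which the gamma
#' approximation can be validated.
#'
#' @param K A `kernel_matrix` or N x N symmetric matrix.
#' @param n_draws Number of null draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_draws` statistic values.
#' @export
monte_carlo_null <- function(K, n_draws, seed = NULL) {
  V <- kernel_values(K)
  n <- nrow(V)
  stopifnot(n_draws >= 1L)
  Z <- with_seed_or_not(seed, matrix(stats::rnorm(n_draws * n), n_draws, n))
  Z <- Z - rowMeans(Z)
  rowSums((Z %*% V) * Z) / (n * rowSums(Z^2))
}
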