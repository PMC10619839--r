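# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, leaving the
# caller's RNG untouched. NULL seed runs the code as-is.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Clip p-values away from exact 0 to keep -log10(p) finite in reports.
clip_pvalue <- function(p, lower = 1e-300) {
  pmin(pmax(p, lower), 1)
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Validate a genes x locations expression matrix.
check_expression <- function(Y) {
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop("expression must be a numeric matrix (genes x locations)",
         call. = FALSE)
  }
  if (anyNA(Y) || any(!is.finite(Y))) {
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  }
  if (is.null(rownames(Y))) {
    rownames(Y) <- paste0("gene", seq_len(nrow(Y)))
  }
  if (anyDuplicated(rownames(Y))) stop("duplicate gene identifiers",
                                       call. = FALSE)
  Y
}

# Validate an N x d coordinate matrix, d in {2, 3}.
check_coords <- function(S) {
  if (!is.matrix(S) || !is.numeric(S)) {
    stop("coordinates must be a numeric matrix (locations x dimensions)",
         call. = FALSE)
  }
  if (!ncol(S) %in% c(2L, 3L)) {
    stop("coordinates must have 2 or 3 columns", call. = FALSE)
  }
  if (anyNA(S) || any(!is.finite(S))) {
    stop("coordinates contain missing or non-finite values", call. = FALSE)
  }
  if (nrow(S) < 2L) stop("need at least two locations", call. = FALSE)
  if (!is.null(rownames(S)) && anyDuplicated(rownames(S))) {
    stop("duplicate location identifiers", call. = FALSE)
  }
  S
}
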