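#' Read a gene expression matrix
#'
#' Reads expression values either from a Matrix Market coordinate file with
#' companion one-ID-per-line gene and location ID files, or from a delimited
#' table (TSV/CSV) whose first column holds gene identifiers and whose header
#' row holds location identifiers. The returned matrix is always oriented
#' genes x locations; set `transpose = TRUE` when the on-disk matrix is
#' locations x genes (common for spot-by-gene exports).
#'
#' @param path Path to the `.mtx` file or the delimited table.
#' @param format One of `"auto"`, `"mtx"`, `"table"`. `"auto"` picks `"mtx"`
#'   for a `.mtx` extension.
#' @param gene_ids,location_ids For `format = "mtx"`, paths to the plain-text
#'   ID files (one ID per line) for rows and columns of the on-disk matrix.
#' @param transpose If `TRUE`, the on-disk matrix is location x gene and is
#'   transposed after reading.
#' @return A dense numeric matrix, genes in rows (rownames = gene IDs),
#'   locations in columns (colnames = location IDs).
#' @seealso [read_coordinates()], [filter_genes()], [normalize_expression()]
#' @export
read_expression <- function(path, format = c("auto", "mtx", "table"),
                            gene_ids = NULL, location_ids = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "table"
  }
  if (format == "mtx") {
    if (is.null(gene_ids) || is.null(location_ids)) {
      stop("mtx format requires `gene_ids` and `location_ids` files",
           call. = FALSE)
    }
    if (!file.exists(gene_ids)) stop("file not found: ", gene_ids,
                                     call. = FALSE)
    if (!file.exists(location_ids)) stop("file not found: ", location_ids,
                                         call. = FALSE)
    M <- as.matrix(Matrix::readMM(path))
    if (transpose) M <- t(M)
    g <- readLines(gene_ids)
    l <- readLines(location_ids)
    if (length(g) != nrow(M)) {
      stop(sprintf("gene ID count (%d) does not match matrix rows (%d)",
                   length(g), nrow(M)), call. = FALSE)
    }
    if (length(l) != ncol(M)) {
      stop(sprintf("location ID count (%d) does not match matrix columns (%d)",
                   length(l), ncol(M)), call. = FALSE)
    }
    dimnames(M) <- list(g, l)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1L]])
    M <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- ids
    if (transpose) M <- t(M)
  }
  if (anyNA(M)) stop("expression matrix contains missing values",
                     call. = FALSE)
  if (any(M < 0)) stop("expression matrix contains negative entries",
                       call. = FALSE)
  check_expression(M)
}

#' Write an expression matrix as Matrix Market triplets
#'
#' Companion writer for [read_expression()]: writes `<prefix>.mtx`,
#' `<prefix>.genes.txt` and `<prefix>.locations.txt`.
#'
#' @param Y genes x locations numeric matrix.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_expression_mtx <- function(Y, prefix) {
  Y <- check_expression(Y)
  paths <- paste0(prefix, c(".mtx", ".genes.txt", ".locations.txt"))
  Matrix::writeMM(Matrix::Matrix(Y, sparse = TRUE), paths[1L])
  writeLines(rownames(Y), paths[2L])
  if (is.null(colnames(Y))) colnames(Y) <- paste0("loc", seq_len(ncol(Y)))
  writeLines(colnames(Y), paths[3L])
  invisible(paths)
}

#' Read spatial coordinates
#'
#' Reads a delimited table whose first column is the location ID followed by
#' 2 or 3 numeric coordinate columns. Row order defines location order.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @return Numeric matrix N x d (d inferred from the columns), rownames =
#'   location IDs.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L || ncol(dt) > 4L) {
    stop("coordinate table must have an ID column plus 2 or 3 coordinate columns",
         call. = FALSE)
  }
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicate location IDs in coordinate table",
                               call. = FALSE)
  S <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(S)) stop("non-numeric coordinates", call. = FALSE)
  storage.mode(S) <- "double"
  rownames(S) <- ids
  check_coords(S)
}

#' Write spatial coordinates
#'
#' @param S N x d coordinate matrix with location IDs as rownames.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(S, path) {
  S <- check_coords(S)
  if (is.null(rownames(S))) rownames(S) <- paste0("loc", seq_len(nrow(S)))
  df <- data.frame(id = rownames(S), S, row.names = NULL)
  names(df) <- c("id", c("x", "y", "z")[seq_len(ncol(S))])
  data.table::fwrite(df, path)
  invisible(path)
}

#' Filter genes by detection fraction
#'
#' Keeps the genes expressed (value > 0) in strictly more than `min_frac` of
#' the locations. With the conventional 1% threshold a gene detected in
#' exactly 1% of spots is dropped.
#'
#' @param Y genes x locations matrix.
#' @param min_frac Detection fraction threshold in `[0, 1)`.
#' @return The filtered matrix (possibly with zero rows); gene order
#'   preserved.
#' @export
filter_genes <- function(Y, min_frac = 0.01) {
  Y <- check_expression(Y)
  stopifnot(is.numeric(min_frac), length(min_frac) == 1L,
            min_frac >= 0, min_frac < 1)
  keep <- rowMeans(Y > 0) > min_frac
  Y[keep, , drop = FALSE]
}

#' Normalize expression counts
#'
#' `"log1p_scaled"` rescales each location (column) to the median total count
#' and applies `log(1 + x)`; `"none"` returns the input unchanged.
#'
#' @param Y genes x locations matrix of non-negative values.
#' @param method `"none"` or `"log1p_scaled"`.
#' @return Matrix of the same shape.
#' @export
normalize_expression <- function(Y, method = c("log1p_scaled", "none")) {
  method <- match.arg(method)
  Y <- check_expression(Y)
  if (method == "none") return(Y)
  if (any(Y < 0)) stop("log1p_scaled requires non-negative values",
                       call. = FALSE)
  cs <- colSums(Y)
  if (any(cs == 0)) stop("column(s) with zero total count cannot be scaled",
                         call. = FALSE)
  sf <- stats::median(cs) / cs
  log1p(sweep(Y, 2L, sf, "*"))
}

#' Build a covariate design matrix
#'
#' Prepends an intercept column (if absent) and checks full column rank.
#'
#' @param X N x q numeric matrix of covariates, or `NULL` for intercept-only.
#' @param n Number of locations (required when `X` is `NULL`).
#' @return N x q design matrix with a leading column of ones.
#' @export
covariate_design <- function(X = NULL, n = NULL) {
  if (is.null(X)) {
    stopifnot(!is.null(n))
    return(matrix(1, nrow = n, ncol = 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite covariates",
                                           call. = FALSE)
  has_intercept <- any(apply(X, 2L, function(v) all(v == v[1L]) && v[1L] != 0))
  if (!has_intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient",
                                 call. = FALSE)
  X
}

#' Residualize expression against covariates
#'
#' Replaces `y` with `(I - P_X) y` where `P_X = X (X'X)^{-1} X'`, removing
#' the covariate-explained component before kernel testing. With an
#' intercept-only design this is mean-centering. Accepts a vector (one gene)
#' or a genes x locations matrix (rows residualized jointly).
#'
#' @param y Length-N numeric vector or K x N matrix.
#' @param X N x q full-rank design matrix (see [covariate_design()]).
#' @return Residualized object of the same shape, orthogonal to the columns
#'   of `X`.
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient",
                              call. = FALSE)
  if (is.matrix(y)) {
    stopifnot(ncol(y) == nrow(X))
    out <- t(qr.resid(qx, t(y)))
    dimnames(out) <- dimnames(y)
    out
  } else {
    stopifnot(length(y) == nrow(X))
    as.vector(qr.resid(qx, y))
  }
}
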