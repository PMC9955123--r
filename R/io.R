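#' Read a binary adjacency matrix
#'
#' Supports Matrix Market coordinate files (pattern or integer field,
#' 1-based) and tab-separated edge lists `src<TAB>dst`.  Duplicate edges
#' collapse to a single 1 (with a message reporting the count); self-loops
#' are kept, the model permits them.
#'
#' @param path file path.
#' @param format `"mtx"` or `"edgelist"`.
#' @param index_base for edge lists, 1 (default) or 0.
#' @param dims for edge lists, optional `c(nr, nc)`; defaults to the maximum
#'   observed indices.
#' @return a base dense binary matrix.
#' @export
read_adjacency <- function(path, format = c("mtx", "edgelist"),
                           index_base = 1L, dims = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    M <- Matrix::readMM(path)
    A <- as.matrix(M)
    dups <- sum(A > 1)
    if (dups > 0) message(sprintf("collapsed %d duplicate edges", dups))
    return((A > 0) * 1)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("src", "dst"),
                          colClasses = "integer")
  if (nrow(df) == 0) stop("ParseError: empty edge list", call. = FALSE)
  src <- df$src + (1L - as.integer(index_base))
  dst <- df$dst + (1L - as.integer(index_base))
  if (any(src < 1L) || any(dst < 1L)) {
    stop(sprintf("IndexOutOfRange: nonpositive index at line %d",
                 which(src < 1L | dst < 1L)[1]), call. = FALSE)
  }
  if (is.null(dims)) dims <- c(max(src), max(dst))
  if (any(src > dims[1]) || any(dst > dims[2])) {
    stop(sprintf("IndexOutOfRange: index exceeds dims at line %d",
                 which(src > dims[1] | dst > dims[2])[1]), call. = FALSE)
  }
  keys <- paste(src, dst)
  ndup <- sum(duplicated(keys))
  if (ndup > 0) message(sprintf("collapsed %d duplicate edges", ndup))
  A <- matrix(0, dims[1], dims[2])
  A[cbind(src, dst)] <- 1
  A
}

#' Write a binary adjacency matrix
#'
#' @param A binary matrix.
#' @param path output path.
#' @param format `"mtx"` (Matrix Market coordinate, 1-based) or `"edgelist"`
#'   (1-based TSV).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path, format = c("mtx", "edgelist")) {
  format <- match.arg(format)
  stopifnot(is.matrix(A) || inherits(A, "Matrix"))
  A <- as.matrix(A)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(A, sparse = TRUE, doDiag = FALSE), path)
  } else {
    idx <- which(A > 0, arr.ind = TRUE)
    utils::write.table(idx[order(idx[, 1], idx[, 2]), , drop = FALSE], path,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a membership matrix from CSV
#'
#' Expects the header `node, comm_1 .. comm_K`; validates that every row is a
#' probability vector.
#'
#' @param path file path.
#' @param tol row-sum tolerance (CSV round trips at full double precision,
#'   so the default is forgiving only of print formatting).
#' @return an `n x K` matrix, rows ordered by the `node` column.
#' @export
read_membership_csv <- function(path, tol = 1e-8) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"node" %in% names(df)) stop("ParseError: missing `node` column", call. = FALSE)
  comm_cols <- grep("^comm_", names(df), value = TRUE)
  if (!length(comm_cols)) stop("ParseError: no `comm_*` columns", call. = FALSE)
  df <- df[order(df$node), ]
  pi <- as.matrix(df[comm_cols])
  bad <- which(abs(rowSums(pi) - 1) > tol)
  if (length(bad)) {
    stop(sprintf("membership row for node %d does not sum to 1", df$node[bad[1]]),
         call. = FALSE)
  }
  dimnames(pi) <- NULL
  pi
}

#' Write a membership matrix to CSV
#'
#' @param pi `n x K` row-stochastic matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership_csv <- function(pi, path) {
  df <- tibble::as_tibble(pi, .name_repair = ~ paste0("comm_", seq_along(.x)))
  df <- tibble::add_column(df, node = seq_len(nrow(pi)), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}
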