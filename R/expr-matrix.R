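#' Expression matrix container
#'
#' An `expr_matrix` is a probe-by-cell numeric matrix of normalized expression
#' signal together with a `scale_tag` describing the scale the values live on:
#' `"mas5_linear"` (MAS5-summarized microarray signal, linear scale),
#' `"tpm"` (transcripts per million, linear scale), or `"log2_already"`
#' (values already log2-transformed). Linear-scale matrices must be finite and
#' non-negative; probe and cell identifiers must be unique. Every stage of the
#' pipeline consumes this container.
#'
#' @param values Numeric matrix with probe identifiers as rownames and cell
#'   identifiers as colnames.
#' @param scale_tag One of `"mas5_linear"`, `"tpm"`, `"log2_already"`.
#' @return An `expr_matrix` object.
#' @examples
#' m <- expr_matrix(matrix(2^rexp(6, 1 / 4), 3, 2,
#'   dimnames = list(paste0("p", 1:3), c("cellA", "cellB"))
#' ), "mas5_linear")
#' dim(m)
#' @export
expr_matrix <- function(values, scale_tag = c("mas5_linear", "tpm", "log2_already")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  x <- structure(values, scale_tag = scale_tag, class = c("expr_matrix", "matrix"))
  validate_expr_matrix(x)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique probe and cell identifiers,
#' all values finite, and non-negative values on linear scales.
#'
#' @param x An `expr_matrix`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expr_matrix <- function(x) {
  if ((nrow(x) > 0L && is.null(rownames(x))) ||
    (ncol(x) > 0L && is.null(colnames(x)))) {
    stop("expression matrix must carry probe rownames and cell colnames", call. = FALSE)
  }
  dup_p <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_p)) {
    stop("duplicate probe id(s): ", paste(dup_p, collapse = ", "), call. = FALSE)
  }
  dup_c <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_c)) {
    stop("duplicate cell id(s): ", paste(dup_c, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(unclass(x)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite value at probe '%s', cell '%s'",
      rownames(x)[bad[1]], colnames(x)[bad[2]]
    ), call. = FALSE)
  }
  if (scale_tag(x) %in% c("mas5_linear", "tpm") && any(x < 0)) {
    bad <- which(unclass(x) < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative value at probe '%s', cell '%s' not allowed on scale '%s'",
      rownames(x)[bad[1]], colnames(x)[bad[2]], scale_tag(x)
    ), call. = FALSE)
  }
  invisible(x)
}

#' @rdname expr_matrix
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' Scale tag of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character scalar.
#' @export
scale_tag <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) "mas5_linear" else tag
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d probes x %d cells [%s]\n",
    nrow(x), ncol(x), scale_tag(x)
  ))
  n <- min(5L, nrow(x))
  m <- min(5L, ncol(x))
  if (n && m) print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, scale_tag = scale_tag(x), class = c("expr_matrix", "matrix"))
  } else {
    out
  }
}

#' Log2-scale view of an expression matrix
#'
#' Returns the matrix on the log2 scale used by the variance filter, the
#' clustering distance, detection calls and correlate screens. Linear-scale
#' matrices (`mas5_linear`, `tpm`) are transformed as `log2(x + 1)`;
#' `log2_already` matrices are returned as-is.
#'
#' @param x An `expr_matrix`.
#' @return A plain numeric matrix of log2 signal.
#' @export
as_log2 <- function(x) {
  stopifnot(is_expr_matrix(x))
  v <- unclass(x)
  attr(v, "scale_tag") <- NULL
  if (scale_tag(x) == "log2_already") v else log2(v + 1)
}
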