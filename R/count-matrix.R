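#' Construct a validated gene-by-cell count matrix
#'
#' The container every analysis stage consumes: a genes x cells matrix of
#' non-negative integer transcript counts with unique gene and cell
#' identifiers. Validation is strict because the downstream lattice and
#' quantization results are exact statements about integers; fractional
#' counts (e.g. from ambient-RNA correction or prior normalisation) make
#' them meaningless and are rejected rather than rounded.
#'
#' @param counts numeric matrix of non-negative integers, genes in rows,
#'   cells in columns. At least 2 cells (a variance needs two observations).
#' @param gene_ids,cell_ids unique identifier character vectors; default to
#'   the dimnames of `counts` or `gene1..`, `cell1..`.
#' @return A `count_matrix`: an integer matrix with dimnames and class
#'   `c("count_matrix", "matrix", "array")`.
#' @examples
#' m <- count_matrix(rbind(g1 = c(0, 1, 2), g2 = c(0, 0, 0)))
#' n_cells(m)
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- gene_ids %||% rownames(counts) %||%
    paste0("gene", seq_len(nrow(counts)))
  cell_ids <- cell_ids %||% colnames(counts) %||%
    paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(counts) < 2) {
    stop("a count_matrix needs at least 2 cells (n_c >= 2)", call. = FALSE)
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "invalid count at gene '%s', cell '%s': %s (counts must be integers >= 0)",
      gene_ids[i], cell_ids[j], format(counts[i, j])), call. = FALSE)
  }
  if (!is.integer(counts)) storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, cell_ids)
  class(counts) <- c("count_matrix", "matrix", "array")
  counts
}

#' @rdname count_matrix
#' @param x object to convert or query.
#' @param ... passed on to methods.
#' @export
as_count_matrix <- function(x, ...) UseMethod("as_count_matrix")

#' @export
as_count_matrix.count_matrix <- function(x, ...) x

#' @export
as_count_matrix.matrix <- function(x, ...) count_matrix(x, ...)

#' @export
as_count_matrix.data.frame <- function(x, ...) {
  # dense convention: first column = gene id when non-numeric
  if (ncol(x) >= 1 && !is.numeric(x[[1]])) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    count_matrix(m, ...)
  } else {
    count_matrix(as.matrix(x), ...)
  }
}

#' @export
as_count_matrix.default <- function(x, ...) {
  if (inherits(x, "sparseMatrix")) {
    return(count_matrix(as.matrix(x), ...))
  }
  stop("cannot convert object of class ", paste(class(x), collapse = "/"),
       " to count_matrix", call. = FALSE)
}

#' @rdname count_matrix
#' @export
n_cells <- function(x) ncol(as_count_matrix(x))

#' @rdname count_matrix
#' @export
n_genes <- function(x) nrow(as_count_matrix(x))

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, %d non-zero entries\n",
              nrow(x), ncol(x), sum(x > 0)))
  if (nrow(x) <= 10 && ncol(x) <= 10) {
    print(unclass(x))
  } else {
    print(unclass(x[seq_len(min(5, nrow(x))), seq_len(min(8, ncol(x))),
                    drop = FALSE]))
    cat("...\n")
  }
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, drop = FALSE]
  class(out) <- c("count_matrix", "matrix", "array")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
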