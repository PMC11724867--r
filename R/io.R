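#' Read a count matrix from disk
#'
#' Supports the two dominant community layouts for raw single-cell count
#' data: a 10x-style Matrix Market directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, each optionally
#' gzipped) and a dense delimited table whose first column holds gene
#' identifiers and whose header row holds cell identifiers. Orientation
#' is genes x cells; a dense file laid out cells x genes must be
#' declared with `orientation = "cells_by_genes"` -- there is no
#' guessing by shape.
#'
#' Values must be non-negative integer literals. In the default strict
#' mode a dense entry written in float notation (`"2.0"`, `"1e2"`) is
#' rejected even when its value is integral, because exact rational
#' results downstream presuppose genuinely integer data; set
#' `permissive = TRUE` to accept float notation whose value is exactly
#' integral. Fractional values are always an error, never rounded.
#'
#' @param path for `mtx_dir`, the directory; otherwise the file.
#' @param format `"auto"` (directory => `mtx_dir`, else by extension),
#'   `"mtx_dir"`, `"dense_csv"` or `"dense_tsv"`.
#' @param orientation layout of a dense file; ignored for `mtx_dir`
#'   (Matrix Market convention is rows = features, columns = barcodes).
#' @param permissive accept exactly-integral float notation (see above).
#' @return A [count_matrix()].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- count_matrix(rbind(g1 = c(0L, 1L, 2L), g2 = c(0L, 0L, 0L)))
#' write_counts(m, file.path(dir, "counts.csv"))
#' read_counts(file.path(dir, "counts.csv"))
#' @export
read_counts <- function(path,
                        format = c("auto", "mtx_dir", "dense_csv", "dense_tsv"),
                        orientation = c("genes_by_cells", "cells_by_genes"),
                        permissive = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("input path does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "mtx_dir"
    } else if (grepl("\\.tsv(\\.gz)?$", path)) {
      "dense_tsv"
    } else {
      "dense_csv"
    }
  }
  if (format == "mtx_dir") {
    read_counts_mtx_dir(path)
  } else {
    read_counts_dense(path, delim = if (format == "dense_tsv") "\t" else ",",
                      orientation = orientation, permissive = permissive)
  }
}

# locate the first existing candidate (plain or gz) inside an mtx directory
.find_member <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("missing file in mtx directory '%s': expected one of %s",
               dir, paste(candidates, collapse = ", ")), call. = FALSE)
}

read_counts_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) stop("not a directory: ", dir, call. = FALSE)
  mtx <- .find_member(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feats <- .find_member(dir, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"))
  bars <- .find_member(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  if (!methods::is(m, "dMatrix")) m <- methods::as(m, "dMatrix")
  vals <- m@x
  if (length(vals) && any(vals != round(vals) | vals < 0)) {
    bad <- which(vals != round(vals) | vals < 0)[1]
    tm <- methods::as(m, "TsparseMatrix")
    stop(sprintf("invalid value in %s at gene row %d, cell column %d: %s",
                 mtx, tm@i[bad] + 1L, tm@j[bad] + 1L, format(vals[bad])),
         call. = FALSE)
  }
  # features.tsv may carry id [, symbol, type, ...]; column 1 is the id
  feat_tbl <- readr::read_tsv(feats, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  bar_tbl <- readr::read_tsv(bars, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(feat_tbl) != nrow(m)) {
    stop(sprintf("feature table has %d rows but matrix has %d rows",
                 nrow(feat_tbl), nrow(m)), call. = FALSE)
  }
  if (nrow(bar_tbl) != ncol(m)) {
    stop(sprintf("barcode table has %d rows but matrix has %d columns",
                 nrow(bar_tbl), ncol(m)), call. = FALSE)
  }
  count_matrix(as.matrix(m), gene_ids = feat_tbl[[1]], cell_ids = bar_tbl[[1]])
}

read_counts_dense <- function(path, delim, orientation, permissive) {
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(tbl) < 2) stop("dense count table needs id column + data", call. = FALSE)
  ids <- tbl[[1]]
  body <- as.matrix(tbl[, -1, drop = FALSE])
  vals <- .parse_count_strings(body, permissive, ids, colnames(body))
  rownames(vals) <- ids
  if (orientation == "cells_by_genes") vals <- t(vals)
  count_matrix(vals)
}

.parse_count_strings <- function(body, permissive, row_ids, col_ids) {
  chr <- array(trimws(body), dim = dim(body), dimnames = dimnames(body))
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr),
                                dimnames = dimnames(chr)))
  bad <- if (permissive) {
    is.na(num) | num < 0 | num != round(num)
  } else {
    !grepl("^[0-9]+$", chr)
  }
  bad <- array(bad, dim = dim(chr))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid count at row '%s', column '%s': '%s' (%s)",
      row_ids[idx[1]], col_ids[idx[2]], body[idx[1], idx[2]],
      if (permissive) "must be an integral value >= 0"
      else "must be an integer literal; use permissive = TRUE for float notation"),
      call. = FALSE)
  }
  num
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: `mtx_dir` writes Matrix Market coordinate
#' format with integer values and 1-based indices plus `features.tsv`
#' and `barcodes.tsv`; dense formats write gene ids in the first column
#' under a header of cell ids.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param path target directory (`mtx_dir`) or file.
#' @param format as in [read_counts()]; `"auto"` picks `mtx_dir` when
#'   `path` has no `.csv`/`.tsv` extension.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path,
                         format = c("auto", "mtx_dir", "dense_csv", "dense_tsv")) {
  x <- as_count_matrix(x)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv(\\.gz)?$", path)) {
      "dense_tsv"
    } else if (grepl("\\.csv(\\.gz)?$", path)) {
      "dense_csv"
    } else {
      "mtx_dir"
    }
  }
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nz <- which(unclass(x) != 0, arr.ind = TRUE)
    # build a general dgTMatrix explicitly: Matrix() would pick pattern or
    # symmetric representations whose MTX headers readMM round-trips
    # differently
    sp <- Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2],
                               x = as.double(unclass(x)[nz]),
                               dims = dim(x), repr = "T")
    mtx <- file.path(path, "matrix.mtx")
    Matrix::writeMM(sp, mtx)
    # writeMM emits an implicit-value "pattern" file when all entries are 1;
    # keep the explicit integer field the 10x convention expects
    lines <- readLines(mtx)
    if (grepl("pattern", lines[1])) {
      entries <- setdiff(which(!grepl("^%", lines)), which(!grepl("^%", lines))[1])
      lines[entries] <- paste(lines[entries], "1")
      lines[1] <- sub("pattern", "integer", lines[1])
      writeLines(lines, mtx)
    }
    readr::write_tsv(tibble::tibble(id = rownames(x), name = rownames(x)),
                     file.path(path, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble::tibble(barcode = colnames(x)),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
  } else {
    delim <- if (format == "dense_tsv") "\t" else ","
    tbl <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
    tbl <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)), tbl)
    readr::write_delim(tbl, path, delim = delim)
  }
  invisible(path)
}
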