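#' Assign genes to curves by their count signature
#'
#' Curve membership is determined exactly from the counts, never by
#' geometric proximity in the plot: a gene whose counts never exceed 2
#' belongs to Curve `k = ` number of cells with exactly two transcripts;
#' genes with higher counts are mapped into the family through
#' `k_effective = (S - T)/2` and flagged `simple = FALSE`. Unexpressed
#' genes (T = 0) are excluded (their Fano factor is undefined).
#'
#' @param x a [count_matrix()] (or coercible).
#' @param mean_max analysis window: keep genes with mean <= `mean_max`
#'   (default 1, the weakly-expressed region where the patterns live).
#' @return A tibble sorted by (`k`, `mean`): `k`, `gene_id`, `total`,
#'   `mean`, `fano`, `fano_num`, `fano_den`, `max_count`, `simple`, `n_c`.
#' @examples
#' m <- make_fixture("fig2_genes", n_c = 20)
#' assign_curves(m)
#' @export
assign_curves <- function(x, mean_max = 1) {
  x <- as_count_matrix(x)
  gene_moments(x) |>
    dplyr::filter(.data$expressed, .data$mean <= mean_max) |>
    dplyr::mutate(k = .data$k_effective, simple = .data$max_count <= 2) |>
    dplyr::select("k", "gene_id", "total", "mean", "fano", "fano_num",
                  "fano_den", "max_count", "simple", "n_c") |>
    dplyr::arrange(.data$k, .data$mean, .data$gene_id)
}

#' Vertical spacing between successive genes on each curve
#'
#' On Curve k the mean of a gene is i/n_c for an integer i, so the
#' spacing between successive distinct means on the same curve is an
#' integer multiple of 1/n_c; a step of 2 signals one missing lattice
#' point between the two genes. Duplicate (mean, Fano) coordinates are
#' collapsed before differencing (distinct genes can share a point).
#'
#' @param curves output of [assign_curves()] (or a [count_matrix()],
#'   which is passed through `assign_curves(x, mean_max)` first).
#' @param mean_max analysis window when `curves` is a matrix.
#' @return A tibble of class `deltay_report`, one row per curve with at
#'   least 2 distinct means: `k`, `n_c`, `n_points` (distinct means),
#'   `n_steps`, `steps` (list column of integer steps in 1/n_c units),
#'   `fraction_unit` (share of steps equal to exactly 1/n_c). Curves
#'   with fewer than 2 distinct means are dropped with a message.
#' @examples
#' m <- make_fixture("lattice_with_gaps", n_c = 20)
#' delta_y(m)
#' @export
delta_y <- function(curves, mean_max = 1) {
  if (!is.data.frame(curves)) curves <- assign_curves(curves, mean_max)
  groups <- dplyr::group_split(curves, .data$k)
  rows <- purrr::map(groups, function(g) {
    tot <- sort(unique(g$total))  # exact means are total/n_c
    if (length(tot) < 2) {
      return(tibble::tibble(k = g$k[1], n_c = g$n_c[1],
                            n_points = length(tot), n_steps = 0L,
                            steps = list(integer(0)), fraction_unit = NA_real_))
    }
    steps <- as.integer(diff(tot))
    frac1 <- mean(steps == 1L)
    tibble::tibble(k = g$k[1], n_c = g$n_c[1], n_points = length(tot),
                   n_steps = length(steps), steps = list(steps),
                   fraction_unit = frac1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(k = numeric(0), n_c = integer(0),
                          n_points = integer(0), n_steps = integer(0),
                          steps = list(), fraction_unit = numeric(0))
  }
  dropped <- out$n_points < 2
  if (any(dropped)) {
    message(sum(dropped), " curve(s) with < 2 distinct means dropped from the ",
            "spacing report")
    out <- out[!dropped, , drop = FALSE]
  }
  class(out) <- c("deltay_report", class(out))
  out
}

#' Per-gene fractions of cells at 0, 1 and 2 transcripts
#'
#' Genes on different curves are indistinguishable by the fraction of
#' cells with 0 or 1 transcripts; what separates Curve k is having
#' exactly k cells at 2. For a simple gene on Curve k the composition is
#' exact: `frac0 + frac1 + k/n_c = 1`.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param curves optional output of [assign_curves()] restricting which
#'   genes are reported; defaults to all expressed genes with mean <= 1.
#' @return A tibble: `gene_id`, `k`, `frac0`, `frac1` (exact fractions as
#'   doubles; denominators are n_c), `n_two` (number of cells at exactly
#'   2), `n_above2`, `n_c`, `simple`.
#' @examples
#' m <- make_fixture("fig2_genes", n_c = 20)
#' curve_cell_fractions(m)
#' @export
curve_cell_fractions <- function(x, curves = NULL) {
  x <- as_count_matrix(x)
  if (is.null(curves)) curves <- assign_curves(x)
  missing_ids <- setdiff(curves$gene_id, rownames(x))
  if (length(missing_ids)) {
    stop("genes absent from the matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  cm <- unclass(x)[curves$gene_id, , drop = FALSE]
  n_c <- ncol(cm)
  tibble::tibble(
    gene_id = curves$gene_id,
    k = curves$k,
    frac0 = unname(rowSums(cm == 0)) / n_c,
    frac1 = unname(rowSums(cm == 1)) / n_c,
    n_two = unname(rowSums(cm == 2)),
    n_above2 = unname(rowSums(cm > 2)),
    n_c = n_c,
    simple = curves$simple
  )
}

#' Match observed genes to the predicted lattice
#'
#' Every expressed gene with counts <= 2 must sit exactly on a predicted
#' lattice point (mean = i/n_c on Curve k); this match is verified in
#' exact rational arithmetic and a failure is raised as an internal
#' consistency error, since the theory guarantees it for any integer
#' data. Lattice points with no observed gene are reported as missing
#' (the gene either does not exist or went undetected through imperfect
#' transcript capture). Genes with counts above 2 are reported
#' separately under their effective curve index.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param mean_max analysis window on the mean (default 1).
#' @param k_max largest curve index considered (default 2, the highlighted
#'   curves).
#' @return A `lattice_match` object: list with tibbles `matched`
#'   (lattice point + `gene_ids` list column + `n_genes`), `missing`
#'   (unrealized lattice points), `off_lattice` (non-simple genes with
#'   their `k_effective`), and fields `n_c`, `mean_max`, `k_max`,
#'   `n_genes_analysed`. Has [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and print methods.
#' @examples
#' m <- make_fixture("lattice_with_gaps", n_c = 20)
#' match_lattice(m)
#' @export
match_lattice <- function(x, mean_max = 1, k_max = 2) {
  x <- as_count_matrix(x)
  lattice <- predict_lattice(n_cells(x), k_max = k_max, mean_max = mean_max)
  curves <- assign_curves(x, mean_max = mean_max)
  obs <- dplyr::filter(curves, .data$simple, .data$k <= k_max)
  # exact match: a simple gene with total T on curve k sits at lattice
  # point (i = T, k); verify the Fano coordinate agrees exactly too
  key <- paste(obs$total, obs$k)
  lat_key <- paste(lattice$i, lattice$k)
  hit <- match(key, lat_key)
  if (anyNA(hit)) {
    stop("internal consistency error: simple-theory gene off the lattice: ",
         paste(obs$gene_id[is.na(hit)][1]), call. = FALSE)
  }
  same_fano <- obs$fano_num == lattice$fano_num[hit] &
    obs$fano_den == lattice$fano_den[hit]
  if (!all(same_fano)) {
    stop("internal consistency error: exact Fano mismatch for gene ",
         obs$gene_id[!same_fano][1], call. = FALSE)
  }
  occupancy <- obs |>
    dplyr::mutate(.lat = hit) |>
    dplyr::group_by(.data$.lat) |>
    dplyr::summarise(gene_ids = list(.data$gene_id), n_genes = dplyr::n())
  lattice$gene_ids <- rep(list(character(0)), nrow(lattice))
  lattice$n_genes <- 0L
  lattice$gene_ids[occupancy$.lat] <- occupancy$gene_ids
  lattice$n_genes[occupancy$.lat] <- occupancy$n_genes
  off <- dplyr::filter(curves, !.data$simple, .data$k <= k_max) |>
    dplyr::select("gene_id", k_effective = "k", "total", "mean", "fano",
                  "max_count")
  structure(list(
    matched = dplyr::filter(lattice, .data$n_genes > 0),
    missing = dplyr::select(dplyr::filter(lattice, .data$n_genes == 0),
                            -"gene_ids", -"n_genes"),
    off_lattice = off,
    n_c = n_cells(x),
    mean_max = mean_max,
    k_max = k_max,
    n_genes_analysed = nrow(obs)
  ), class = "lattice_match")
}

#' @export
print.lattice_match <- function(x, ...) {
  cat(sprintf(
    "<lattice_match> n_c = %d, k <= %d, mean <= %s\n", x$n_c, x$k_max,
    format(x$mean_max)))
  cat(sprintf("  %d simple genes on %d lattice points; %d predicted points unrealized; %d genes with counts > 2\n",
              x$n_genes_analysed, nrow(x$matched), nrow(x$missing),
              nrow(x$off_lattice)))
  invisible(x)
}

#' Export per-gene statistics and theoretical curves for plotting
#'
#' Writes two CSV files into `dir`: `genes.csv` (gene_id, mean, fano, k,
#' max_count, simple) and `curves.csv` (a dense sampling of each
#' theoretical curve over its feasible mean range). Both start with a
#' comment line recording n_c so a plot can be regenerated without the
#' matrix. Suitable for redrawing the mean-Fano scatter with the curve
#' family overlaid.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param dir output directory (created if needed).
#' @param k_list curve indices to sample (default 0:2).
#' @param mean_max analysis window (default 1).
#' @param n_samples points per curve in `curves.csv`.
#' @return Invisibly, the two file paths.
#' @export
export_plot_data <- function(x, dir, k_list = 0:2, mean_max = 1,
                             n_samples = 400) {
  x <- as_count_matrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- assign_curves(x, mean_max = mean_max) |>
    dplyr::select("gene_id", "mean", "fano", "k", "max_count", "simple")
  curves <- curve_samples(n_cells(x), k_list = k_list, mean_max = mean_max,
                          n_samples = n_samples)
  paths <- c(genes = file.path(dir, "genes.csv"),
             curves = file.path(dir, "curves.csv"))
  .write_csv_nc(genes, paths[["genes"]], n_cells(x))
  .write_csv_nc(curves, paths[["curves"]], n_cells(x))
  invisible(paths)
}

#' Dense samples of the theoretical curves
#'
#' @inheritParams predict_lattice
#' @param k_list curve indices to sample.
#' @param n_samples points per curve.
#' @return tibble `k`, `mean`, `fano`.
#' @export
curve_samples <- function(n_c, k_list = 0:2, mean_max = 1, n_samples = 400) {
  purrr::map_dfr(k_list, function(k) {
    r <- feasible_mean_range(k, n_c)
    hi <- min(r$upper, mean_max)
    if (hi < r$lower) return(tibble::tibble())
    mean <- seq(r$lower, hi, length.out = n_samples)
    tibble::tibble(k = k, mean = mean, fano = curve_ff(mean, k, n_c))
  })
}

# CSV with a leading "# n_c = N" comment line
.write_csv_nc <- function(tbl, path, n_c) {
  readr::write_lines(sprintf("# n_c = %d", n_c), path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
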