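#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lattice match
#'
#' One row per predicted lattice point with its realization status and
#' the genes occupying it.
#'
#' @param x a `lattice_match` from [match_lattice()].
#' @param ... unused.
#' @return A tibble: `i`, `k`, `mean`, `fano`, `status`
#'   (`"observed"`/`"missing"`), `n_genes`, `gene_ids` (list column).
#' @method tidy lattice_match
#' @export
tidy.lattice_match <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$matched, status = "observed"),
    dplyr::mutate(x$missing, status = "missing", n_genes = 0L,
                  gene_ids = list(character(0)))
  ) |>
    dplyr::arrange(.data$k, .data$i) |>
    dplyr::select("i", "k", "mean", "fano", "status", "n_genes", "gene_ids")
}

#' @rdname tidy.lattice_match
#' @return For `glance`: a one-row tibble summarising the match --
#'   `n_c`, `k_max`, `mean_max`, `n_lattice`, `n_observed`, `n_missing`,
#'   `n_off_lattice`, `n_genes_analysed`, `occupancy` (share of
#'   predicted points realized).
#' @method glance lattice_match
#' @export
glance.lattice_match <- function(x, ...) {
  n_lat <- nrow(x$matched) + nrow(x$missing)
  tibble::tibble(
    n_c = x$n_c, k_max = x$k_max, mean_max = x$mean_max,
    n_lattice = n_lat,
    n_observed = nrow(x$matched),
    n_missing = nrow(x$missing),
    n_off_lattice = nrow(x$off_lattice),
    n_genes_analysed = x$n_genes_analysed,
    occupancy = if (n_lat > 0) nrow(x$matched) / n_lat else NA_real_
  )
}

#' Tidy a spacing report
#'
#' @param x a `deltay_report` from [delta_y()].
#' @param ... unused.
#' @return For `tidy`: one row per spacing step -- `k`, `n_c`, `step`
#'   (integer, units of 1/n_c), `delta_y` (= step / n_c). For `glance`:
#'   one row with `n_curves`, `n_steps`, `fraction_unit` (pooled share
#'   of steps equal to 1/n_c) and `all_integer` (always `TRUE` for
#'   integer count data; reported for symmetry with external checks).
#' @method tidy deltay_report
#' @export
tidy.deltay_report <- function(x, ...) {
  tidyr::unnest(tibble::as_tibble(x)[, c("k", "n_c", "steps")], "steps") |>
    dplyr::rename(step = "steps") |>
    dplyr::mutate(delta_y = .data$step / .data$n_c)
}

#' @rdname tidy.deltay_report
#' @method glance deltay_report
#' @export
glance.deltay_report <- function(x, ...) {
  steps <- unlist(x$steps)
  tibble::tibble(
    n_curves = nrow(x),
    n_steps = length(steps),
    fraction_unit = if (length(steps)) mean(steps == 1L) else NA_real_,
    all_integer = length(steps) == 0 || all(steps == round(steps))
  )
}
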