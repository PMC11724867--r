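#' Deterministic archetype and lattice fixtures
#'
#' Hand-constructed matrices realizing the canonical configurations:
#'
#' * `"fig2_genes"` -- the three archetypes distinguishing Curves 0, 1
#'   and 2: gene A has only 0/1 counts, gene B has exactly one cell at
#'   2 transcripts, gene C exactly two (rest 0/1).
#' * `"lattice_complete"` -- one gene for every predicted lattice point
#'   with k in 0..2 and mean <= 1 (i from max(2k, 1) to n_c), so a
#'   lattice match over that window reports nothing missing.
#' * `"lattice_with_gaps"` -- the same with named points omitted
#'   (default: i = 3 on Curve 0), producing a spacing step of 2/n_c
#'   between the genes flanking the gap.
#'
#' @param kind fixture name (see above).
#' @param n_c number of cells, >= 10.
#' @param gaps for `"lattice_with_gaps"`, a data frame with columns `i`
#'   and `k` naming the lattice points to omit.
#' @return A [count_matrix()].
#' @examples
#' assign_curves(make_fixture("fig2_genes", 20))
#' @export
make_fixture <- function(kind = c("lattice_complete", "lattice_with_gaps",
                                  "fig2_genes"),
                         n_c = 20,
                         gaps = data.frame(i = 3, k = 0)) {
  kind <- match.arg(kind)
  if (n_c < 10) stop("fixtures need n_c >= 10", call. = FALSE)
  cells <- paste0("cell", seq_len(n_c))
  if (kind == "fig2_genes") {
    ones <- function(n1, n2) c(rep(2L, n2), rep(1L, n1), rep(0L, n_c - n1 - n2))
    m <- rbind(geneA = ones(4, 0), geneB = ones(3, 1), geneC = ones(2, 2))
    return(count_matrix(m, cell_ids = cells))
  }
  grid <- predict_lattice(n_c, k_max = 2, mean_max = 1)[, c("i", "k")]
  if (kind == "lattice_with_gaps") {
    stopifnot(is.data.frame(gaps), all(c("i", "k") %in% names(gaps)))
    drop <- paste(grid$i, grid$k) %in% paste(gaps$i, gaps$k)
    if (!any(drop)) stop("requested gaps are not in the lattice window",
                         call. = FALSE)
    grid <- grid[!drop, , drop = FALSE]
  }
  rows <- purrr::map2(grid$i, grid$k, function(i, k) {
    n1 <- i - 2 * k  # i = (# ones) + 2k within the feasible window
    c(rep(2L, k), rep(1L, n1), rep(0L, n_c - k - n1))
  })
  m <- do.call(rbind, rows)
  count_matrix(m, gene_ids = sprintf("gene_i%d_k%d", grid$i, grid$k),
               cell_ids = cells)
}
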