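#' Per-gene exact count moments
#'
#' For each gene, computes the integer moment sums `total` (T, the sum of
#' counts over cells) and `sum_sq` (S, the sum of squared counts), and from
#' them the population mean T/n_c and population Fano factor
#' (n_c*S - T^2) / (n_c*T). Population moments (divisor n_c, not n_c - 1)
#' are used throughout the curve logic because the curve and lattice
#' identities are exact only for that convention; a sample-variance column
#' is available separately via `sample_variance = TRUE` and is never used
#' by the theory.
#'
#' The Fano factor is undefined for genes never observed (T = 0); those
#' rows carry `NA` and are flagged in `expressed`.
#'
#' All derived statistics are exact rationals: `mean = total / n_c` (so the
#' numerator column is `total` with denominator `n_c`), and the Fano factor
#' is returned reduced as `fano_num / fano_den` alongside its double
#' approximation `fano`.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param sample_variance also report the n_c - 1 divisor variance
#'   (`var_sample`), for interfacing with conventional QC tooling.
#' @return A tibble with one row per gene: `gene_id`, `total`, `sum_sq`,
#'   `n_c`, `mean`, `fano`, `fano_num`, `fano_den`, `max_count`,
#'   `k_simple` (number of cells with exactly two transcripts, `NA` when
#'   some cell exceeds 2), `k_effective` (= (S - T)/2, the curve index
#'   valid for any counts), `expressed`.
#' @examples
#' m <- count_matrix(rbind(gA = c(0, 1, 2, 2, 1, 0)))
#' gene_moments(m)   # mean 1, Fano 2/3
#' @export
gene_moments <- function(x, sample_variance = FALSE) {
  x <- as_count_matrix(x)
  cm <- unclass(x)
  storage.mode(cm) <- "double"  # exact for counts; avoids integer overflow
  n_c <- ncol(cm)
  total <- unname(rowSums(cm))
  sum_sq <- unname(rowSums(cm^2))
  max_count <- unname(apply(cm, 1, max))
  twos <- unname(rowSums(cm == 2))
  fano_num_raw <- n_c * sum_sq - total^2
  fano_den_raw <- n_c * total
  defined <- total > 0
  fr <- rational(ifelse(defined, fano_num_raw, 0),
                 ifelse(defined, fano_den_raw, 1))
  out <- tibble::tibble(
    gene_id = rownames(cm),
    total = total,
    sum_sq = sum_sq,
    n_c = n_c,
    mean = total / n_c,
    fano = ifelse(defined, fano_num_raw / fano_den_raw, NA_real_),
    fano_num = ifelse(defined, rat_num(fr), NA_real_),
    fano_den = ifelse(defined, rat_den(fr), NA_real_),
    max_count = max_count,
    k_simple = ifelse(max_count <= 2, twos, NA_real_),
    k_effective = (sum_sq - total) / 2,
    expressed = defined
  )
  if (sample_variance) {
    out$var_sample <- (sum_sq - total^2 / n_c) / (n_c - 1)
  }
  out
}

#' Per-gene curve signature
#'
#' The histogram `m_i` of cells with exactly `i >= 2` transcripts, which
#' determines the curve a gene sits on: genes whose counts never exceed 2
#' have the simple index `k = m_2`; in general the effective index is
#' `k_effective = sum over i >= 2 of choose(i, 2) * m_i`, which collapses
#' every gene onto the same curve family (it equals `(S - T) / 2`).
#'
#' @param x a [count_matrix()] (or coercible).
#' @return A tibble: `gene_id`, `max_count`, `m` (list column: named
#'   integer vector, names are the count values `i >= 2`), `k_simple`
#'   (`NA` when `max_count > 2`), `k_effective`, `simple` (logical,
#'   `max_count <= 2`).
#' @examples
#' m <- count_matrix(rbind(gB = c(2, 1, 0, 0), gD = c(3, 1, 0, 0)))
#' curve_signature(m)
#' @export
curve_signature <- function(x) {
  x <- as_count_matrix(x)
  cm <- unclass(x)
  rows <- purrr::map(seq_len(nrow(cm)), function(i) {
    v <- cm[i, ]
    hi <- v[v >= 2]
    m <- table(hi)
    stats::setNames(as.integer(m), names(m))
  })
  max_count <- apply(cm, 1, max)
  k_eff <- purrr::map_dbl(rows, function(m) {
    if (length(m) == 0) return(0)
    i <- as.numeric(names(m))
    sum(choose(i, 2) * m)
  })
  tibble::tibble(
    gene_id = rownames(cm),
    max_count = as.numeric(max_count),
    m = rows,
    k_simple = ifelse(max_count <= 2,
                      purrr::map_dbl(rows, ~ sum(.x[names(.x) == "2"])),
                      NA_real_),
    k_effective = k_eff,
    simple = max_count <= 2
  )
}
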