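#' Fano factor of Curve k
#'
#' Genes whose counts are all 0/1 except for exactly `k` cells at 2
#' transcripts trace out Curve k in the mean-Fano factor plane:
#'
#'   FF = 1 - <n> + 2k / (n_c <n>)
#'
#' Curve 0 (k = 0) is the Bernoulli line FF = 1 - <n>. Via the effective
#' index `k_effective = (S - T)/2` the same formula is an exact identity
#' for *any* integer count vector, which is what the lattice matching
#' relies on.
#'
#' @param mean mean transcript count, > 0. Numeric, or a [rational()]
#'   vector for an exact result.
#' @param k curve index, non-negative integer. Simple-theory genes have
#'   k <= n_c; effective indices of genes with counts above 2 may exceed
#'   n_c and are accepted here (enumeration functions stay capped).
#' @param n_c number of cells, >= 2.
#' @return Fano factor; a [rational()] if `mean` was rational, else double.
#' @examples
#' curve_ff(0.1, k = 1, n_c = 100)          # 1.1
#' curve_ff(rational(1, 101), 0, 101)       # 100/101 exactly
#' @export
curve_ff <- function(mean, k, n_c) {
  .check_k(k, n_c)
  if (is_rational(mean)) {
    if (any(mean <= rational(0))) stop("`mean` must be > 0", call. = FALSE)
    return(1 - mean + rational(2 * k) / (rational(n_c) * mean))
  }
  if (any(mean <= 0)) stop("`mean` must be > 0 (Fano factor undefined at mean 0)",
                           call. = FALSE)
  1 - mean + 2 * k / (n_c * mean)
}

#' Mean transcript count on Curve k at a given Fano factor
#'
#' Inverts [curve_ff()]: the k = 0 branch is the line `mean = 1 - FF`
#' (requiring FF < 1 for a positive mean); for k >= 1 the positive root
#'
#'   mean = (1 - FF + sqrt((8k + n_c (FF - 1)^2) / n_c)) / 2
#'
#' is taken (the negative root never yields a positive mean). The square
#' root is evaluated in double precision; round-tripping through
#' [curve_ff()] is exact to ~1e-15 relative.
#'
#' @inheritParams curve_ff
#' @param fano Fano factor (numeric).
#' @return mean transcript count (double).
#' @examples
#' curve_mean(1.1, k = 1, n_c = 100)   # 0.1
#' curve_mean(1, k = 2, n_c = 100)     # sqrt(2 * 2 / 100)
#' @export
curve_mean <- function(fano, k, n_c) {
  .check_k(k, n_c)
  fano <- as.numeric(fano)
  n <- max(length(fano), length(k), length(n_c))
  fano <- rep_len(fano, n); k <- rep_len(k, n); n_c <- rep_len(n_c, n)
  if (any(k == 0 & fano >= 1)) {
    stop("Curve 0 has no positive mean at fano >= 1 (mean = 1 - fano)",
         call. = FALSE)
  }
  ifelse(k == 0,
         1 - fano,
         0.5 * (1 - fano + sqrt((8 * k + n_c * (fano - 1)^2) / n_c)))
}

#' Fano factor for an arbitrary cells-at-i histogram
#'
#' General form of [curve_ff()] for genes that may have cells above two
#' transcripts: with `m_i` cells at exactly `i >= 2` transcripts,
#'
#'   FF = 1 - <n> + sum_i i (i - 1) m_i / (n_c <n>)
#'
#' which reduces to Curve `k = m_2` when the histogram has support only
#' at i = 2, and equals `curve_ff(mean, k_effective, n_c)` in general
#' since `sum i (i - 1) m_i = 2 k_effective`.
#'
#' @inheritParams curve_ff
#' @param m named vector mapping count value `i >= 2` to the number of
#'   cells `m_i` with exactly that count (e.g. `c("2" = 1, "3" = 2)`);
#'   an empty vector means all counts are 0/1.
#' @return Fano factor; a [rational()] if `mean` was rational, else double.
#' @examples
#' general_ff(4 / 3, c("3" = 1), n_c = 3)            # 7/6
#' general_ff(rational(4, 3), c("3" = 1), n_c = 3)
#' @export
general_ff <- function(mean, m, n_c) {
  if (length(m) == 0) {
    i <- numeric(0); mi <- numeric(0)
  } else {
    if (is.null(names(m)) || any(!grepl("^[0-9]+$", names(m)))) {
      stop("`m` must be named by integer count values i >= 2", call. = FALSE)
    }
    i <- as.numeric(names(m)); mi <- as.numeric(m)
  }
  if (any(i < 2)) stop("histogram support must be at i >= 2", call. = FALSE)
  if (any(mi < 0 | mi != round(mi))) {
    stop("cell counts m_i must be non-negative integers", call. = FALSE)
  }
  if (sum(mi) > n_c) stop("sum of m_i exceeds the number of cells", call. = FALSE)
  # feasibility window of the mean given the histogram: the remaining
  # n_c - sum(m_i) cells contribute between 0 and 1 transcript each
  lo <- rational(sum(i * mi), n_c)
  hi <- rational(n_c - sum(mi) + sum(i * mi), n_c)
  mean_r <- if (is_rational(mean)) mean else NULL
  mean_num <- if (is.null(mean_r)) mean else as.numeric(mean_r)
  infeasible <- if (!is.null(mean_r)) {
    any(mean_r < lo) || any(mean_r > hi)   # exact
  } else {
    any(mean_num < as.numeric(lo) - 1e-12) ||
      any(mean_num > as.numeric(hi) + 1e-12)
  }
  if (infeasible) {
    stop(sprintf("mean %s is inconsistent with the histogram (feasible [%s, %s])",
                 format(mean_num[1]), format(lo), format(hi)), call. = FALSE)
  }
  d2 <- sum(i * (i - 1) * mi)  # = 2 * k_effective
  if (!is.null(mean_r)) {
    if (any(mean_r <= rational(0))) stop("`mean` must be > 0", call. = FALSE)
    return(1 - mean_r + rational(d2) / (rational(n_c) * mean_r))
  }
  if (any(mean_num <= 0)) stop("`mean` must be > 0", call. = FALSE)
  1 - mean_num + d2 / (n_c * mean_num)
}

#' Lower bound on the mean at a given Fano factor
#'
#' Any discrete distribution of transcript numbers satisfies
#' `mean >= 1 - FF`, with equality exactly when every count is 0 or 1
#' (Bernoulli, i.e. Curve 0). In the mean-Fano factor plane this carves
#' out the empty triangle below the Curve-0 line.
#'
#' @param fano Fano factor(s), >= 0; numeric or [rational()].
#' @return `max(0, 1 - fano)`, rational if the input was.
#' @examples
#' min_mean_bound(0.4)   # 0.6
#' min_mean_bound(2)     # 0
#' @export
min_mean_bound <- function(fano) {
  if (is_rational(fano)) {
    if (any(fano < rational(0))) stop("`fano` must be >= 0", call. = FALSE)
    return(rat_pmax(1 - fano, rational(0)))
  }
  if (any(fano < 0)) stop("`fano` must be >= 0", call. = FALSE)
  pmax(0, 1 - fano)
}

#' Range of means realizable on Curve k
#'
#' A gene on Curve k has k cells at 2 transcripts and the remaining
#' n_c - k cells at 0 or 1, so its total count T runs over
#' max(2k, 1), ..., n_c + k (T = 0 is excluded: the Fano factor needs an
#' expressed gene). The attainable means are therefore the rationals
#' i/n_c with i in that integer window.
#'
#' @inheritParams curve_ff
#' @return A tibble: `k`, `n_c`, `i_min`, `i_max` (integer bounds on the
#'   mean numerator) and their double values `lower`, `upper`.
#' @examples
#' feasible_mean_range(0, 100)   # means 1/100 .. 1
#' feasible_mean_range(2, 6)     # means 4/6 .. 8/6
#' @export
feasible_mean_range <- function(k, n_c) {
  .check_k(k, n_c, bound_nc = TRUE)
  tibble::tibble(
    k = k, n_c = n_c,
    i_min = pmax(2 * k, 1),
    i_max = n_c + k,
    lower = pmax(2 * k, 1) / n_c,
    upper = (n_c + k) / n_c
  )
}

#' Predicted (mean, Fano factor) lattice
#'
#' At finite sample size every expressed gene whose counts never exceed 2
#' must land on one of a discrete set of points: mean = i/n_c for an
#' integer i in the feasible window of its curve, Fano factor given by
#' [curve_ff()]. This function enumerates that lattice for curves 0..k_max
#' up to a mean cut-off, with exact rational coordinates.
#'
#' @inheritParams curve_ff
#' @param k_max largest curve index to enumerate (<= n_c).
#' @param mean_max upper limit on the mean (the weakly-expressed window;
#'   default 1).
#' @return A tibble: `i`, `k`, `n_c`, `mean`, `fano` (doubles) and exact
#'   coordinates `mean_num` (= i), `mean_den` (= n_c), `fano_num`,
#'   `fano_den` (reduced).
#' @examples
#' predict_lattice(101, k_max = 0, mean_max = 0.05)   # 5 points
#' @export
predict_lattice <- function(n_c, k_max = 2, mean_max = 1) {
  .check_k(k_max, n_c, bound_nc = TRUE)
  if (mean_max <= 0) stop("`mean_max` must be > 0", call. = FALSE)
  i_cap <- floor(mean_max * n_c + 1e-9)
  purrr::map_dfr(0:k_max, function(k) {
    r <- feasible_mean_range(k, n_c)
    if (r$i_min > min(r$i_max, i_cap)) return(tibble::tibble())
    i <- seq.int(r$i_min, min(r$i_max, i_cap))
    ff <- curve_ff(rational(i, n_c), k, n_c)
    tibble::tibble(
      i = i, k = k, n_c = n_c,
      mean = i / n_c,
      fano = as.numeric(ff),
      mean_num = i, mean_den = n_c,
      fano_num = rat_num(ff), fano_den = rat_den(ff)
    )
  })
}

# bound_nc: simple-theory contexts cap k at n_c (at most n_c cells can hold
# two transcripts); effective indices from counts above 2 may exceed it
.check_k <- function(k, n_c, bound_nc = FALSE) {
  if (any(n_c < 2 | n_c != round(n_c))) {
    stop("`n_c` must be an integer >= 2", call. = FALSE)
  }
  if (any(k < 0 | k != round(k))) {
    stop("`k` must be a non-negative integer", call. = FALSE)
  }
  if (bound_nc && any(k > n_c)) {
    stop("`k` must satisfy k <= n_c here", call. = FALSE)
  }
  invisible(TRUE)
}
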