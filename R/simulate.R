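#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_counts()]. Per-gene
#' parameters are drawn from ranges so a single config describes a
#' heterogeneous transcriptome; all ranges target the weakly expressed
#' regime (mean < 1) where the finite-sample patterns are visible.
#'
#' Families and their `params` entries:
#' \describe{
#'   \item{bernoulli}{`p` (range, default `c(0.005, 0.5)`): per-cell
#'     detection probability; counts are 0/1 so genes sit on Curve 0.}
#'   \item{poisson}{`mean` (range, default `c(0.005, 1)`, log-uniform):
#'     constitutive expression.}
#'   \item{negative_binomial}{`mean` (range, default `c(0.005, 1)`,
#'     log-uniform) and `fano` (range, default `c(1, 4)`, uniform,
#'     must exceed 1): bursty expression with burst size `fano - 1`.}
#'   \item{telegraph}{`burst_freq` (range, default `c(0.05, 0.5)`),
#'     `burst_size` (range, default `c(0.5, 3)`), `koff` (scalar,
#'     default 10): two-state promoter steady state sampled as a
#'     Poisson mixture over Beta(burst_freq, koff) promoter activity
#'     with intensity `burst_size * koff`.}
#'   \item{custom_pmf}{`pmf` (probability vector over `values`,
#'     default values `0:(length(pmf) - 1)`): any finite discrete
#'     distribution -- the patterns do not depend on the law, only on
#'     the counts being integers.}
#' }
#'
#' @param n_genes,n_c numbers of genes and cells (`n_c >= 2`).
#' @param family one of `"bernoulli"`, `"poisson"`, `"negative_binomial"`,
#'   `"telegraph"`, `"custom_pmf"`.
#' @param params named list overriding family defaults (see Details).
#' @param capture_efficiency per-transcript retention probability in
#'   (0, 1]; applied by binomial thinning after sampling. 1 = no loss.
#' @param extrinsic_cv coefficient of variation of a positive unit-mean
#'   log-normal per-cell factor multiplying each cell's mean before
#'   sampling (0 = purely intrinsic noise). Not defined for
#'   `custom_pmf`.
#' @param seed integer seed; expands into per-gene substreams so adding
#'   genes never reshuffles existing ones.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes, n_c,
                       family = c("negative_binomial", "bernoulli", "poisson",
                                  "telegraph", "custom_pmf"),
                       params = list(), capture_efficiency = 1,
                       extrinsic_cv = 0, seed = 1L) {
  family <- match.arg(family)
  if (n_genes < 1 || n_c < 2) stop("need n_genes >= 1 and n_c >= 2", call. = FALSE)
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    stop("`capture_efficiency` must be in (0, 1]", call. = FALSE)
  }
  if (extrinsic_cv < 0) stop("`extrinsic_cv` must be >= 0", call. = FALSE)
  defaults <- switch(family,
    bernoulli = list(p = c(0.005, 0.5)),
    poisson = list(mean = c(0.005, 1)),
    negative_binomial = list(mean = c(0.005, 1), fano = c(1, 4)),
    telegraph = list(burst_freq = c(0.05, 0.5), burst_size = c(0.5, 3),
                     koff = 10),
    custom_pmf = list(pmf = c(0.9, 0.08, 0.02), values = NULL)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown params for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, params)
  if (family == "negative_binomial" && max(params$fano) <= 1) {
    stop("negative binomial requires fano > 1 (burst size = fano - 1 > 0)",
         call. = FALSE)
  }
  if (family == "custom_pmf") {
    if (extrinsic_cv > 0) {
      stop("extrinsic noise is not defined for custom_pmf", call. = FALSE)
    }
    pmf <- params$pmf
    if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-9) {
      stop("`pmf` must be a probability vector summing to 1", call. = FALSE)
    }
    values <- params$values %||% (seq_along(pmf) - 1)
    if (length(values) != length(pmf) || any(values < 0 | values != round(values))) {
      stop("`values` must be non-negative integers matching `pmf`", call. = FALSE)
    }
    params$values <- values
  }
  structure(list(n_genes = as.integer(n_genes), n_c = as.integer(n_c),
                 family = family, params = params,
                 capture_efficiency = capture_efficiency,
                 extrinsic_cv = extrinsic_cv, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic count matrix
#'
#' Draws, for each gene, `n_c` i.i.d. counts from the configured family
#' (optionally modulated by a shared per-cell extrinsic factor and
#' thinned by imperfect capture) and returns a [count_matrix()]. Every
#' family produces genuinely integer counts, so all finite-sample
#' pattern guarantees (lattice exactness, 1/n_c spacing quantization,
#' the Curve-0 lower bound) hold for the output whatever the mechanism
#' -- that mechanism-independence is the point of the generator.
#'
#' @param config a [sim_config()]; alternatively pass its arguments via
#'   `...` for convenience.
#' @param ... arguments forwarded to [sim_config()] when `config` is not
#'   supplied.
#' @return A [count_matrix()] with genes `gene1..` and cells `cell1..`.
#' @examples
#' m <- simulate_counts(sim_config(50, 101, "poisson", seed = 7))
#' identical(m, simulate_counts(sim_config(50, 101, "poisson", seed = 7)))
#' @export
simulate_counts <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  if (!inherits(config, "sim_config")) {
    stop("`config` must come from sim_config()", call. = FALSE)
  }
  ng <- config$n_genes; nc <- config$n_c; p <- config$params
  # shared per-cell extrinsic factor (cell-level property, one draw per cell)
  cell_factor <- rep(1, nc)
  if (config$extrinsic_cv > 0) {
    s2 <- log(1 + config$extrinsic_cv^2)
    withr_seed(.substream_seed(config$seed, 0L), {
      cell_factor <- stats::rlnorm(nc, meanlog = -s2 / 2, sdlog = sqrt(s2))
    })
  }
  counts <- matrix(0L, nrow = ng, ncol = nc)
  for (g in seq_len(ng)) {
    withr_seed(.substream_seed(config$seed, g), {
      counts[g, ] <- .sim_gene(config$family, p, nc, cell_factor)
    })
  }
  m <- count_matrix(counts,
                    gene_ids = paste0("gene", seq_len(ng)),
                    cell_ids = paste0("cell", seq_len(nc)))
  if (config$capture_efficiency < 1) {
    m <- apply_capture(m, config$capture_efficiency,
                       seed = .substream_seed(config$seed, -1L))
  }
  m
}

.sim_gene <- function(family, p, nc, cell_factor) {
  draw_range <- function(r, log = FALSE) {
    if (length(r) == 1) return(r)
    if (log) exp(stats::runif(1, base::log(r[1]), base::log(r[2])))
    else stats::runif(1, r[1], r[2])
  }
  switch(family,
    bernoulli = {
      prob <- pmin(1, draw_range(p$p) * cell_factor)
      stats::rbinom(nc, 1L, prob)
    },
    poisson = {
      stats::rpois(nc, draw_range(p$mean, log = TRUE) * cell_factor)
    },
    negative_binomial = {
      mu <- draw_range(p$mean, log = TRUE)
      ff <- draw_range(p$fano)
      if (ff <= 1) stop("negative binomial requires fano > 1", call. = FALSE)
      size <- mu / (ff - 1)  # variance = mu + mu^2/size = ff * mu
      stats::rnbinom(nc, size = size, mu = mu * cell_factor)
    },
    telegraph = {
      kon <- draw_range(p$burst_freq)
      bs <- draw_range(p$burst_size)
      koff <- p$koff
      activity <- stats::rbeta(nc, kon, koff)
      stats::rpois(nc, bs * koff * activity * cell_factor)
    },
    custom_pmf = {
      sample(p$values, nc, replace = TRUE, prob = p$pmf)
    }
  )
}

#' Binomial capture thinning
#'
#' Models imperfect transcript capture: each transcript of every entry
#' is retained independently with probability `efficiency`, i.e. entry
#' `n` becomes `Binomial(n, efficiency)`. Thinning uses a per-gene
#' random substream keyed by the gene identifier, so thinning a subset
#' of genes gives the same counts as subsetting after thinning.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param efficiency retention probability in (0, 1]; 1 is the identity.
#' @param seed integer seed.
#' @return A [count_matrix()] of the same shape.
#' @examples
#' m <- simulate_counts(sim_config(10, 50, "poisson", seed = 1))
#' identical(apply_capture(m, 1, seed = 5), m)
#' @export
apply_capture <- function(x, efficiency, seed = 1L) {
  x <- as_count_matrix(x)
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  if (efficiency == 1) return(x)
  cm <- unclass(x)
  out <- cm
  for (g in seq_len(nrow(cm))) {
    withr_seed(.id_seed(seed, rownames(cm)[g]), {
      out[g, ] <- stats::rbinom(ncol(cm), cm[g, ], efficiency)
    })
  }
  count_matrix(out, gene_ids = rownames(cm), cell_ids = colnames(cm))
}

# run code under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit substream seeds; index-keyed (simulation) ...
.substream_seed <- function(seed, index) {
  ((as.double(seed) %% 2147483647) * 48271 + (index + 2) * 16807) %% 2147483647
}

# ... or identifier-keyed (thinning), so gene subsetting commutes
.id_seed <- function(seed, id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 131 + c) %% 2147483647
  (h + (as.double(seed) %% 2147483647) * 48271) %% 2147483647
}
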