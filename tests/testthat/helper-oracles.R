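# Brute-force oracles, independent of the package's exact-arithmetic path.
# All values involved are small integers, for which double arithmetic is
# itself exact, so plain mean()/sum() serve as the reference.

# all count vectors of length n_c with entries 0..max_entry (rows)
enum_vectors <- function(n_c, max_entry) {
  g <- do.call(expand.grid, rep(list(0:max_entry), n_c))
  as.matrix(g)
}

# population moments straight from the definition
oracle_mean <- function(v) mean(v)
oracle_fano <- function(v) {
  m <- mean(v)
  (mean(v^2) - m^2) / m
}

# number of cells with exactly two transcripts
oracle_twos <- function(v) sum(v == 2)

# histogram of cells at i >= 2 transcripts, named by i
oracle_m_hist <- function(v) {
  hi <- v[v >= 2]
  if (!length(hi)) return(stats::setNames(integer(0), character(0)))
  tab <- table(hi)
  stats::setNames(as.integer(tab), names(tab))
}

# a count matrix from a list of count vectors
vectors_as_matrix <- function(vs) {
  m <- do.call(rbind, vs)
  count_matrix(m, gene_ids = paste0("g", seq_len(nrow(m))))
}

# exact equality of a double ratio pair against p/q via cross-multiplication
expect_exact_ratio <- function(num, den, p, q) {
  expect_true(all(num * q == p * den))
}
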