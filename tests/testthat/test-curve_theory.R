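test_that("gene_moments reproduces the brute-force moment oracle", {
  m <- count_matrix(rbind(gA = c(0, 1, 2, 2, 1, 0),
                          gB = rep(1, 6),
                          gC = c(rep(0, 5), 1),
                          gZ = rep(0, 6)))
  gs <- gene_moments(m)
  expect_equal(gs$total, c(6, 6, 1, 0))
  expect_equal(gs$sum_sq, c(10, 6, 1, 0))
  expect_equal(gs$mean, c(1, 1, 1 / 6, 0))
  # exact Fano factors: 2/3, 0, 5/6; undefined for the unexpressed gene
  expect_exact_ratio(gs$fano_num[1:3], gs$fano_den[1:3],
                     c(2, 0, 5), c(3, 1, 6))
  expect_true(is.na(gs$fano[4]))
  expect_equal(gs$expressed, c(TRUE, TRUE, TRUE, FALSE))
  # against the definition, on every row
  for (i in 1:3) {
    v <- unclass(m)[i, ]
    expect_equal(gs$mean[i], oracle_mean(v))
    expect_equal(gs$fano[i], oracle_fano(v))
  }
  # the Bernoulli singleton sits on Curve 0: fano = 1 - mean
  expect_equal(gs$fano[3], 1 - gs$mean[3])
})

test_that("sample variance accessor differs from population variance", {
  m <- count_matrix(rbind(g = c(0, 1, 2, 2, 1, 0)))
  gs <- gene_moments(m, sample_variance = TRUE)
  expect_equal(gs$var_sample, var(c(0, 1, 2, 2, 1, 0)))
  expect_equal(gs$fano * gs$mean, var(c(0, 1, 2, 2, 1, 0)) * 5 / 6)
})

test_that("curve_ff matches direct substitution and the k = 0 line", {
  expect_equal(curve_ff(0.1, k = 1, n_c = 100), 1.1)
  means <- c(0.03, 0.2, 0.77, 1)
  expect_equal(curve_ff(means, 0, 101), 1 - means)
  # exact rational evaluation
  ff <- curve_ff(rational(1, 101), 0, 101)
  expect_identical(c(rat_num(ff), rat_den(ff)), c(100, 101))
  # and it agrees with the moments of (0,1,2,2,1,0): mean 1, k = 2, n_c = 6
  expect_equal(curve_ff(1, 2, 6), 2 / 3)
  expect_error(curve_ff(0, 1, 100), "mean")
  expect_error(curve_ff(0.5, -1, 100), "k")
  expect_error(curve_ff(0.5, 1.5, 100), "k")
  # effective indices may exceed n_c (counts above 2); simple-theory
  # enumeration contexts stay capped
  expect_silent(curve_ff(0.5, 101, 100))
  expect_error(feasible_mean_range(101, 100), "n_c")
})

test_that("curve_mean inverts curve_ff on its feasible domain", {
  expect_equal(curve_mean(1.1, k = 1, n_c = 100), 0.1)
  expect_error(curve_mean(1, k = 0, n_c = 100), "Curve 0")
  eps <- 1e-6
  expect_equal(curve_mean(1 - eps, 0, 100), eps)
  expect_equal(curve_mean(1, k = 1:3, n_c = 100), sqrt(2 * (1:3) / 100))
  for (n_c in c(50, 101, 500)) {
    for (k in 0:20) {
      r <- feasible_mean_range(k, n_c)
      i <- seq(r$i_min, r$i_max)
      m <- i / n_c
      back <- curve_mean(curve_ff(m, k, n_c), k, n_c)
      expect_lt(max(abs(back - m) / m), 1e-12)
    }
  }
})

test_that("every 0/1/2 count vector lands exactly on its curve", {
  # full enumeration: n_c in 2..6, entries in {0,1,2}, T > 0
  for (n_c in 2:6) {
    vs <- enum_vectors(n_c, 2)
    vs <- vs[rowSums(vs) > 0, , drop = FALSE]
    gs <- gene_moments(count_matrix(vs, gene_ids = paste0("g", seq_len(nrow(vs)))))
    k <- rowSums(vs == 2)
    # exact: fano == 1 - i/n_c + 2k/i  with i = T, via cross-multiplication
    ff <- curve_ff(rational(gs$total, n_c), k, n_c)
    expect_true(all(gs$fano_num * rat_den(ff) == rat_num(ff) * gs$fano_den))
    # and in double arithmetic against the oracle
    expect_equal(gs$fano, curve_ff(gs$mean, k, n_c))
  }
})

test_that("general_ff extends the curve formula to arbitrary counts", {
  # worked example: counts (0,1,3), n_c = 3 -> mean 4/3, FF 7/6
  ff <- general_ff(rational(4, 3), c("3" = 1), n_c = 3)
  expect_identical(c(rat_num(ff), rat_den(ff)), c(7, 6))
  v <- c(0, 1, 3)
  expect_equal(oracle_fano(v), as.numeric(ff))
  # empty histogram reduces to the Curve-0 line
  expect_equal(general_ff(0.4, stats::setNames(numeric(0), character(0)), 10),
               0.6)
  # support only at i = 2 is exactly curve_ff with k = m_2, all feasible means
  for (n_c in 2:6) {
    vs <- enum_vectors(n_c, 2)
    vs <- vs[rowSums(vs) > 0, , drop = FALSE]
    for (r in seq_len(nrow(vs))) {
      v <- vs[r, ]
      k <- oracle_twos(v)
      mean_r <- rational(sum(v), n_c)
      g <- general_ff(mean_r, oracle_m_hist(v), n_c)
      expect_true(g == curve_ff(mean_r, k, n_c))
    }
  }
  expect_error(general_ff(0.01, c("2" = 5), n_c = 10), "inconsistent")
  expect_error(general_ff(0.5, c("2" = 11), n_c = 10), "exceeds")
})

test_that("random high-count vectors obey the general theory exactly", {
  set.seed(99)
  for (rep in 1:400) {
    n_c <- sample(2:12, 1)
    v <- sample(0:5, n_c, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    gs <- gene_moments(count_matrix(rbind(g = v)))
    mean_r <- rational(sum(v), n_c)
    g <- general_ff(mean_r, oracle_m_hist(v), n_c)
    expect_true(g == rational(gs$fano_num, gs$fano_den))
    # and equals the effective-index curve
    expect_true(g == curve_ff(mean_r, gs$k_effective, n_c))
  }
})

test_that("the mean is bounded below by 1 - FF, tightly on Bernoulli data", {
  expect_equal(min_mean_bound(0.4), 0.6)
  expect_equal(min_mean_bound(2), 0)
  expect_error(min_mean_bound(-0.1), ">= 0")
  # saturation example: (1,1,0,0,0) has mean 0.4 = 1 - fano
  gs <- gene_moments(count_matrix(rbind(g = c(1, 1, 0, 0, 0))))
  expect_equal(gs$mean, 0.4)
  expect_equal(gs$fano, 0.6)
  expect_equal(gs$mean, min_mean_bound(gs$fano))
  # exhaustive: equality iff all entries in {0,1}
  for (n_c in 2:6) {
    vs <- enum_vectors(n_c, 3)
    vs <- vs[rowSums(vs) > 0, , drop = FALSE]
    gs <- gene_moments(count_matrix(vs, gene_ids = paste0("g", seq_len(nrow(vs)))))
    bernoulli <- apply(vs, 1, max) <= 1
    # exact comparison: mean >= 1 - fano  <=>  T * fano_den >= (fano_den - fano_num) * n_c
    lhs <- gs$total * gs$fano_den
    rhs <- (gs$fano_den - gs$fano_num) * n_c
    expect_true(all(lhs >= rhs))
    expect_identical(lhs == rhs, unname(bernoulli))
  }
})

test_that("feasible mean windows match enumeration", {
  r <- feasible_mean_range(0, 100)
  expect_equal(c(r$lower, r$upper), c(1 / 100, 1))
  r <- feasible_mean_range(2, 6)
  expect_equal(c(r$i_min, r$i_max), c(4, 8))
  # oracle: all vectors with exactly two 2s, rest 0/1, n_c = 6
  vs <- enum_vectors(6, 2)
  vs <- vs[rowSums(vs == 2) == 2, , drop = FALSE]
  tots <- rowSums(vs)
  expect_equal(range(tots), c(4, 8))
  expect_setequal(tots, 4:8)
  r <- feasible_mean_range(6, 6)
  expect_equal(c(r$lower, r$upper), c(2, 2))
  expect_error(feasible_mean_range(7, 6), "k")
})

test_that("the predicted lattice has exact i/n_c coordinates", {
  pts <- predict_lattice(101, k_max = 0, mean_max = 1)
  expect_equal(nrow(pts), 101)
  expect_equal(pts$i, 1:101)
  first <- pts[1, ]
  expect_equal(c(first$mean_num, first$mean_den), c(1, 101))
  expect_exact_ratio(first$fano_num, first$fano_den, 100, 101)
  # successive points on a fixed curve differ in mean by exactly 1/n_c
  pts2 <- predict_lattice(101, k_max = 2, mean_max = 1)
  for (k in 0:2) {
    i <- sort(pts2$i[pts2$k == k])
    expect_true(all(diff(i) == 1))
  }
  # window cut: mean_max = 0.05 keeps exactly i = 1..5
  small <- predict_lattice(101, k_max = 0, mean_max = 0.05)
  expect_equal(small$i, 1:5)
  # every lattice fano agrees with curve_ff at the rational mean
  ff <- curve_ff(rational(pts2$i, 101), pts2$k, 101)
  expect_identical(pts2$fano_num, rat_num(ff))
  expect_identical(pts2$fano_den, rat_den(ff))
})

test_that("realizable means always have denominator dividing n_c", {
  set.seed(5)
  for (rep in 1:50) {
    n_c <- sample(2:30, 1)
    v <- rpois(n_c, 0.5)
    if (sum(v) == 0) v[1] <- 1
    mean_r <- rational(sum(v), n_c)
    expect_true(n_c %% rat_den(mean_r) == 0)
  }
})

test_that("curve_signature agrees with its histogram definition", {
  m <- count_matrix(rbind(gB = c(2, 1, 0, 0), gD = c(3, 1, 0, 0),
                          gE = c(3, 2, 2, 0)))
  sig <- curve_signature(m)
  expect_equal(sig$k_simple, c(1, NA, NA))
  expect_equal(sig$k_effective, c(1, 3, 5))  # C(3,2) + 2 C(2,2) = 5
  expect_equal(sig$simple, c(TRUE, FALSE, FALSE))
  expect_equal(sig$m[[2]], c("3" = 1L))
  # property: k_effective == (S - T) / 2 == sum C(i,2) m_i, random matrices
  set.seed(21)
  for (rep in 1:20) {
    v <- rpois(15, 1.2)
    sig <- curve_signature(count_matrix(rbind(g = v)))
    expect_equal(sig$k_effective, (sum(v^2) - sum(v)) / 2)
    h <- oracle_m_hist(v)
    expect_equal(sig$k_effective,
                 sum(choose(as.numeric(names(h)), 2) * h))
    expect_equal(sig$k_effective == 0, max(v) <= 1)
  }
})
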