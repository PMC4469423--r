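test_that("Spearman test matches the classic no-ties formula and cor.test", {
  expect_equal(spearman_dependence(1:5, 1:5)$rho, 1)
  expect_equal(spearman_dependence(1:5, 5:1)$rho, -1)
  r <- spearman_dependence(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)  # 1 - 6*4/(5*24)
  set.seed(9)
  x <- rnorm(25); y <- rnorm(25)
  ours <- spearman_dependence(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  # two-sided t approximation agrees with the t transform of rho
  tv <- ours$rho * sqrt(23 / (1 - ours$rho^2))
  expect_equal(ours$p, 2 * pt(-abs(tv), 23))
})

test_that("degenerate Spearman inputs are flagged, not guessed", {
  expect_warning(r <- spearman_dependence(rep(1, 10), rnorm(10)), "constant")
  expect_equal(r$rho, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  expect_error(spearman_dependence(1:4, 1:5), "equal length")
  expect_error(spearman_dependence(1:3, 1:3), "at least 4")
})

test_that("equal-width discretization follows the documented auto rule", {
  expect_equal(discretize(rnorm(118))$n_bins, 8L)  # Sturges at n = 118
  expect_equal(discretize(rnorm(24))$n_bins, 3L)   # occupancy cap at small n
  b <- discretize(c(0, 10), n_bins = 2)
  expect_identical(b$labels, c(0L, 1L))
  b <- discretize(rep(5, 7))
  expect_equal(b$n_bins, 1L)
  expect_true(all(b$labels == 0L))
  # maximum lands in the last bin, not outside
  b <- discretize(c(1, 2, 3, 4), n_bins = 3)
  expect_equal(b$labels[4], 2L)
  expect_true(all(b$labels >= 0 & b$labels < b$n_bins))
})

test_that("plug-in entropies reproduce hand-computed values", {
  one_bin <- discretize(rep(2, 8))
  expect_equal(marginal_entropy(one_bin), 0)
  coin <- discretize(c(rep(0, 4), rep(1, 4)), n_bins = 2)
  expect_equal(marginal_entropy(coin), 1)
  skewed <- discretize(c(0, 0.4, 1.4, 2.9), n_bins = 3)  # counts 2,1,1
  expect_equal(marginal_entropy(skewed), 1.5)
  expect_equal(joint_entropy(coin, coin), 1)
  quarters <- discretize(c(0, 0, 1, 1), n_bins = 2)
  checker <- discretize(c(0, 1, 0, 1), n_bins = 2)
  expect_equal(joint_entropy(quarters, checker), 2)  # uniform over 4 cells
  expect_equal(joint_entropy(one_bin, one_bin), 0)
})

test_that("mutual information reproduces its defining identities", {
  set.seed(4)
  x <- rnorm(40)
  expect_equal(mutual_information(x, x),
               marginal_entropy(discretize(x)))    # self-information = H(X)
  diag2 <- c(0, 0, 1, 1)
  expect_equal(mutual_information(diag2, diag2, n_bins = 2), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1), n_bins = 2), 0)
})

test_that("MI is symmetric, bounded and equals the direct-sum oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    expect_identical(mutual_information(x, y), mutual_information(y, x))
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, min(marginal_entropy(discretize(x)),
                       marginal_entropy(discretize(y))) + 1e-12)
    expect_equal(mi, mi_direct(x, y), tolerance = 1e-12)
  }
})

test_that("permutation p-values are bounded, deterministic and exact in edge cases", {
  set.seed(5)
  y <- rnorm(20)
  r1 <- mi_permutation_pvalue(rnorm(20), y, 200, seed = 7)
  expect_gte(r1$p, 1 / 201)
  expect_lte(r1$p, 1)
  r2 <- mi_permutation_pvalue(rnorm(20), y, 200, seed = 7)
  expect_false(identical(r1, r2))  # different x
  x <- rnorm(20)
  expect_identical(mi_permutation_pvalue(x, y, 200, seed = 7),
                   mi_permutation_pvalue(x, y, 200, seed = 7))
  # constant x: no information, p = 1
  rc <- mi_permutation_pvalue(rep(3, 20), y, 200, seed = 1)
  expect_equal(rc$mi_obs, 0)
  expect_equal(rc$p, 1)
  # exact copy with distinct values: smallest attainable p
  x <- as.numeric(1:30)
  expect_equal(mi_permutation_pvalue(x, x, 999, seed = 2)$p, 1 / 1000)
  expect_error(mi_permutation_pvalue(x, x, 50, seed = 1), ">= 100")
})

test_that("empirical p-value converges to the exhaustive permutation null", {
  # n = 6: all 720 permutations enumerable with the independent oracle
  set.seed(21)
  x <- c(1.2, 3.4, 0.7, 5.1, 2.2, 4.0)
  y <- c(1.0, 3.0, 1.5, 4.8, 2.6, 4.4)
  q <- exact_mi_tail(x, y, n_bins = 2)
  est <- mi_permutation_pvalue(x, y, 4000, seed = 9, n_bins = 2)$p
  expect_lt(abs(est - q), 3 * sqrt(q * (1 - q) / 4000) + 1e-3)
})

test_that("the z-test mode upper-tails the surrogate distribution", {
  set.seed(13)
  x <- rnorm(60); y <- x + rnorm(60, sd = 0.4)
  rz <- mi_permutation_pvalue(x, y, 500, mode = "ztest", seed = 3)
  expect_identical(rz$mode, "ztest")
  expect_equal(rz$p,
               pnorm(rz$mi_obs, rz$surrogate_mean, rz$surrogate_sd,
                     lower.tail = FALSE))
  # degenerate surrogates (constant x) fall back to the empirical mode
  expect_warning(rf <- mi_permutation_pvalue(rep(1, 20), y[1:20], 200,
                                             mode = "ztest", seed = 3),
                 "falling back")
  expect_identical(rf$mode, "empirical")
  expect_equal(rf$p, 1)
})

test_that("the crossed test declares signed edges and is swap-symmetric", {
  cfg <- analysis_config(n_permutations = 500, master_seed = 5)
  set.seed(31)
  x <- rnorm(118); y <- x + rnorm(118, sd = 0.5)   # strong monotone link
  r <- pair_dependence(x, y, cfg, "A", "B")
  expect_true(r$edge)
  expect_identical(r$sign, "positive")
  rneg <- pair_dependence(x, -x, cfg, "A", "B")
  expect_true(rneg$edge)
  expect_identical(rneg$sign, "negative")
  # swapping the inputs (and names) changes nothing
  rswap <- pair_dependence(y, x, cfg, "B", "A")
  expect_equal(rswap$rho, r$rho)
  expect_equal(rswap$p_spearman, r$p_spearman)
  expect_equal(rswap$mi_bits, r$mi_bits)
  expect_equal(rswap$p_mi, r$p_mi)
  # an independent pair at these defaults stays unlinked
  np <- simulate_null_pair(118, seed = 8)
  expect_false(pair_dependence(np$x, np$y, cfg, "A", "B")$edge)
})
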