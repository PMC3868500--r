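test_that("per-million normalization floors absent miRNAs at 0.01", {
  expect_equal(normalize_expression(1000, 1e6), 1000)
  expect_equal(normalize_expression(0, 123456), 0.01)
  expect_equal(round_half_up(normalize_expression(2, 16001191), 3), 0.125)
  expect_error(normalize_expression(-1, 100), "non-negative")
  expect_error(normalize_expression(1, 0), "positive")
})

test_that("fold change reproduces published normalized-pair values", {
  expect_lt(abs(fold_change(13344.793, 26.5605) - 8.97277891), 1e-8)
  expect_lt(abs(fold_change(9.2717, 0.01) - 9.85669008), 1e-8)
  expect_lt(abs(fold_change(1.1702, 0.125) - 3.22675512), 1e-8)
  expect_equal(fold_change(5, 5), 0)
  expect_error(fold_change(0, 1), "positive")
})

test_that("fold change is antisymmetric", {
  set.seed(9)
  a <- runif(50, 0.01, 1e5)
  b <- runif(50, 0.01, 1e5)
  expect_equal(fold_change(a, b), -fold_change(b, a))
})

test_that("Audic-Claverie point probability matches closed small cases", {
  expect_equal(ac_point_prob(0, 0, 100, 100), 0.5)
  expect_equal(ac_point_prob(1, 1, 100, 100), 0.25)
  expect_equal(ac_point_exact(0, 0, 7, 13), 7 / 20)
})

test_that("point probability obeys its exchange identities", {
  set.seed(12)
  for (i in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    n1 <- sample(1000:1e6, 1); n2 <- sample(1000:1e6, 1)
    # equal totals: fully symmetric in the two counts
    expect_equal(ac_point_prob(x, y, n1, n1), ac_point_prob(y, x, n1, n1),
                 tolerance = 1e-12)
    # unequal totals: the swapped probability differs by exactly n1/n2
    expect_equal(ac_point_prob(x, y, n1, n2) * n2,
                 ac_point_prob(y, x, n2, n1) * n1, tolerance = 1e-12)
  }
})

test_that("log-gamma evaluation agrees with the exact rational oracle", {
  # frozen high-count instance, cross-checked against exact decimal
  # arithmetic: P(13 | 2) with the study's library totals
  target <- 1.983040342156950e-04
  expect_equal(ac_point_prob(2, 13, 16001191, 11109127), target,
               tolerance = 1e-12)
  expect_equal(ac_point_exact(2, 13, 16001191, 11109127), target,
               tolerance = 1e-12)
  # no underflow at large counts
  expect_gt(ac_point_prob(1e6, 1e6, 1.1e7, 1.1e7), 0)
})

test_that("independent negative-binomial route confirms the point formula", {
  set.seed(3)
  for (i in 1:25) {
    x <- sample(0:50, 1); y <- sample(0:50, 1)
    n1 <- sample(100:1e5, 1); n2 <- sample(100:1e5, 1)
    nb <- stats::dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
    expect_equal(ac_point_prob(x, y, n1, n2), nb, tolerance = 1e-12)
  }
})

test_that("tail p-value equals term-by-term summation and dominates the point", {
  # direct summation of every outcome no more probable than the observed
  brute_tail <- function(x, y, n1, n2) {
    ys <- 0:(ceiling(max(y, x * n2 / n1)) + 20000) # remainder negligible
    p <- ac_point_prob(x, ys, n1, n2)
    min(1, sum(p[p <= ac_point_prob(x, y, n1, n2) * (1 + 1e-9)]))
  }
  expect_equal(ac_pvalue(2, 5, 100, 100, mode = "tail"),
               brute_tail(2, 5, 100, 100), tolerance = 1e-10)
  expect_equal(ac_pvalue(10, 2, 100, 100, mode = "tail"),
               brute_tail(10, 2, 100, 100), tolerance = 1e-10)
  expect_equal(ac_pvalue(0, 0, 123, 456, mode = "tail"), 1)
  set.seed(21)
  for (i in 1:20) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    n1 <- sample(50:5000, 1); n2 <- sample(50:5000, 1)
    tail <- ac_pvalue(x, y, n1, n2, mode = "tail")
    expect_equal(tail, brute_tail(x, y, n1, n2), tolerance = 1e-9)
    expect_gte(tail + 1e-12, ac_point_prob(x, y, n1, n2))
  }
})

test_that("differential calls apply the joint P and fold-change rule", {
  fc <- c(-1.5, 0.5, 3.0, 1.03, 0.9, -1.03)
  p <- c(0.001, 1e-6, 0.02, 1e-5, 1e-5, 1e-5)
  calls <- call_differential(fc, p)
  expect_identical(as.character(calls),
                   c("down", "unchanged", "unchanged", "up", "unchanged",
                     "down"))
})

test_that("diff_expression assembles a consistent record table", {
  counts <- tibble::tibble(
    mirna = c("a", "b", "c"),
    count_nc = c(100L, 0L, 10L),
    count_mn = c(10L, 50L, 10L)
  )
  de <- diff_expression(counts, n1 = 1e5, n2 = 1e5)
  expect_s3_class(de, "de_result")
  expect_equal(de$norm_nc, c(1000, 0.01, 100))
  expect_true(de$floored_nc[2])
  expect_equal(de$log2_fc, log2(de$norm_mn / de$norm_nc))
  expect_identical(as.character(de$call), c("down", "up", "unchanged"))
  g <- glance(de)
  expect_identical(g$n_up + g$n_down + g$n_unchanged, g$n_mirnas)
})

test_that("top tables rank by fold change with published ordering", {
  pub <- read_example("mn_top_fold_changes.tsv")
  de <- tibble::tibble(
    mirna = pub$mirna,
    log2_fc = fold_change(pub$norm_mn, pub$norm_nc),
    p_value = pub$p_printed,
    call = call_differential(fold_change(pub$norm_mn, pub$norm_nc),
                             pub$p_printed)
  )
  tt <- top_tables(de, 20)
  expect_identical(tt$down$mirna[1], "hsa-miR-217")
  expect_identical(tt$up$mirna[1], "novel_miR_15")
  expect_true(all(diff(tt$down$log2_fc) >= 0))
  expect_true(all(diff(tt$up$log2_fc) <= 0))
  expect_equal(nrow(top_tables(de, 0)$up), 0)
  expect_lte(nrow(top_tables(de, 1000)$down), nrow(de))
  expect_error(top_tables(de, -1), "non-negative")
})
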