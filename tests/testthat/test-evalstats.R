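test_that("dice coefficient matches hand counts and symmetry", {
  a <- array(0L, c(10, 10, 2)); a[1:100] <- 1L          # 100 voxels
  b <- array(0L, c(10, 10, 2)); b[1:50] <- 1L           # first 50 of A
  expect_equal(dice_coefficient(a, b, 1), 2 * 50 / 150)
  expect_equal(dice_coefficient(b, a, 1), 2 * 50 / 150)
  expect_equal(dice_coefficient(a, a, 1), 1)
  disj <- array(0L, c(10, 10, 2)); disj[101:200] <- 1L
  expect_equal(dice_coefficient(a, disj, 1), 0)
  # both empty -> 1 by convention
  expect_equal(dice_coefficient(a, a, 2), 1)
  expect_error(dice_coefficient(a, array(0L, c(5, 5, 2)), 1), "aligned")
  # complement of dice_loss for one-hot single-class inputs
  onehot <- array(0, c(10, 10, 2, 3))
  onehot[, , , 1][a == 0L] <- 1; onehot[, , , 2][a == 1L] <- 1
  d <- dice_coefficient(a, b, 1)
  l <- dice_loss(onehot, b)
  # loss averages class 1 (dice d) and class 2 (empty-empty, dice 1)
  expect_lt(abs((1 - l) - (d + 1) / 2), 1e-5)
})

test_that("wilcoxon signed-rank: exact small-sample and degenerate cases", {
  expect_warning(w <- wilcoxon_signed_rank(c(3, 4, 5), c(3, 4, 5)))
  expect_equal(w$p_value, 1)

  # n = 6, all differences positive: exact p = 2/2^6
  w6 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 2, 3, 4))
  expect_equal(w6$p_value, 2 / 2^6)
  expect_identical(w6$method, "exact")

  # agreement with the base-R exact distribution on tie-free data
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }

  # agreement with the tie-corrected normal approximation on tied data
  set.seed(43)
  x <- sample(1:5, 40, TRUE); y <- sample(1:5, 40, TRUE)
  keep <- x != y
  ours <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(wilcox.test(x[keep], y[keep], paired = TRUE,
                                      exact = FALSE, correct = FALSE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("mann-whitney: exact enumeration and tie handling", {
  expect_equal(mann_whitney(5, 5)$p_value, 1)
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$p_value, 1 / 3)  # 2 * 1/C(4,2)
  expect_equal(mw$statistic, 0)

  set.seed(44)
  a <- rnorm(10); b <- rnorm(12)
  ours <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$statistic))

  a <- sample(1:5, 30, TRUE); b <- sample(1:5, 35, TRUE)
  ours <- mann_whitney(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # two-sided invariance under group relabelling
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
})

test_that("Yates chi-square matches the direct formula and base R", {
  set.seed(45)
  for (i in 1:20) {
    tab <- matrix(sample(1:80, 4), 2, 2)
    ours <- chi_square_yates(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-12)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-12)
  }
  # equal row proportions -> chi2 = 0, p = 1
  eq <- chi_square_yates(matrix(c(10, 20, 20, 40), 2, 2, byrow = TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(chi_square_yates(c(0, 0, 5, 5)), "marginal")
})

test_that("weighted kappa: identity, independence, and 2-category identity", {
  x <- c(1, 2, 3, 4, 5, 2, 3)
  expect_equal(weighted_kappa(x, x), 1)
  expect_equal(weighted_kappa(x, x, weighting = "quadratic"), 1)

  # independent large-sample ratings: kappa near 0
  set.seed(46)
  a <- sample(1:5, 4000, TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  b <- sample(a)  # identical marginals, independent pairing
  expect_lt(abs(weighted_kappa(a, b)), 0.05)
  expect_lt(abs(weighted_kappa(a, b, weighting = "quadratic")), 0.07)

  # 2 categories: linear and quadratic weights equal unweighted kappa
  set.seed(47)
  r1 <- sample(1:2, 60, TRUE); r2 <- sample(1:2, 60, TRUE)
  kl <- weighted_kappa(r1, r2, categories = 1:2, weighting = "linear")
  kq <- weighted_kappa(r1, r2, categories = 1:2, weighting = "quadratic")
  # unweighted kappa by direct formula
  po <- mean(r1 == r2)
  pe <- sum((table(factor(r1, 1:2)) / 60) * (table(factor(r2, 1:2)) / 60))
  k0 <- (po - pe) / (1 - pe)
  expect_equal(kl, k0, tolerance = 1e-12)
  expect_equal(kq, k0, tolerance = 1e-12)

  expect_error(weighted_kappa(rep(3, 5), rep(3, 5)), "undefined")
  expect_error(weighted_kappa(c(1, 6), c(1, 2)), "category")
})

test_that("score summaries reproduce the reporting format", {
  tab <- score_table(data.frame(
    case = rep(1:5, 2), structure = "C5",
    condition = rep(c("focused", "unmodified"), each = 5),
    reader = 1L, score = c(2, 2, 3, 3, 3, 5, 5, 5, 4, 5)))
  s <- summarize_scores(tab)
  foc <- s[s$condition == "focused", ]
  expect_equal(foc$median, 3)
  expect_equal(foc$min, 2); expect_equal(foc$max, 3)

  # even-sample half-integer median, matching the reporting convention
  t2 <- score_table(data.frame(case = 1:4, structure = "C5",
                               condition = "focused", reader = 1L,
                               score = c(2, 2, 3, 3)))
  s2 <- summarize_scores(t2)
  expect_equal(s2$median, 2.5)

  t3 <- score_table(data.frame(case = 1:4, structure = "x",
                               condition = "focused", reader = 1L,
                               score = c(4, 4, 4, 4)))
  expect_equal(summarize_scores(t3)$summary, "4 (IQR: 4-4, range: 4-4)")

  t4 <- score_table(data.frame(case = 1:5, structure = "y",
                               condition = "focused", reader = 1L,
                               score = 1:5))
  s4 <- summarize_scores(t4)
  expect_equal(s4$median, 3)
  expect_equal(s4$min, 1); expect_equal(s4$max, 5)

  expect_error(score_table(data.frame(case = 1, structure = "a",
                                      condition = "focused", reader = 1,
                                      score = 6)), "1..5")
  expect_error(score_table(data.frame(case = c(1, 1), structure = "a",
                                      condition = "focused", reader = 1,
                                      score = c(3, 4))), "duplicate")
})
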