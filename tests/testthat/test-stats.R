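test_that("one-tailed Fisher p equals hypergeometric enumeration", {
  expect_equal(fisher_exact_one_tailed(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               17 / 70)
  expect_equal(fisher_exact_one_tailed(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 6)
  expect_equal(fisher_exact_one_tailed(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               1 / choose(20, 10))
  expect_error(fisher_exact_one_tailed(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact_one_tailed(matrix(c(-1, 1, 1, 1), 2)), "integer")

  set.seed(501)
  for (i in 1:200) {
    tab <- matrix(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)), 2)
    dir <- sample(c("greater", "less"), 1)
    expect_equal(fisher_exact_one_tailed(tab, dir), oracle_fisher_p(tab, dir))
    # and the established implementation agrees
    expect_equal(fisher_exact_one_tailed(tab, dir),
                 stats::fisher.test(tab, alternative = dir)$p.value)
  }
})

test_that("BH adjustment matches the step-up definition and its laws", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(502)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("Wilcoxon signed-rank exact p equals 2^n sign enumeration", {
  res <- wilcoxon_signed_rank(rep(2.5, 5), rep(0, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 2 / 32)
  expect_identical(res$method, "exact")

  expect_error(wilcoxon_signed_rank(1:4, 1:4), class = "drawmetry_not_testable")

  set.seed(503)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    d <- round(rnorm(n, sample(c(0, 1), 1), 2), sample(0:1, 1))
    d <- d[d != 0]
    if (length(d) < 2) next
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p_value, oracle_wilcoxon_p(d))
    # sign flip leaves the two-sided p unchanged
    expect_equal(wilcoxon_signed_rank(-d)$p_value, res$p_value)
  }
  # no ties: agree with the reference exact implementation
  for (i in 1:10) {
    d <- rnorm(sample(6:20, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("large-sample Wilcoxon uses a continuity-corrected normal z", {
  set.seed(504)
  d <- rnorm(60, 0.4)
  res <- wilcoxon_signed_rank(d)
  expect_identical(res$method, "normal approximation with continuity correction")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(2 * pnorm(-abs(res$z)), res$p_value)
})

test_that("Spearman rho and exact permutation p match enumeration", {
  x <- c(1, 2, 5, 7, 9)
  res <- spearman_corr(x, x^2)
  expect_equal(res$rho, 1)

  res <- spearman_corr(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res$rho, -0.5)
  expect_equal(res$p_value, 1)

  expect_error(spearman_corr(1:5, rep(2, 5)), class = "drawmetry_not_testable")

  set.seed(505)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- round(rnorm(n), 1)  # occasional ties exercise midranks
    if (sd(rank(y)) == 0) next
    res <- spearman_corr(x, y)
    expect_equal(res$rho, cor(x, y, method = "spearman"))
    expect_equal(res$p_value, oracle_spearman_p(x, y))
    expect_equal(spearman_corr(y, x)$rho, res$rho)
  }
  # t approximation path agrees with the reference implementation
  x <- rnorm(30); y <- x + rnorm(30)
  res <- spearman_corr(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))
})

test_that("normality gate routes skewed data to nonparametric tests", {
  set.seed(506)
  skewed <- rexp(50)^2
  g <- normality_gate(skewed)
  expect_true(g$use_nonparametric)
  normal <- rnorm(50)
  g2 <- normality_gate(normal)
  expect_false(g2$use_nonparametric)
  expect_equal(g2$W, unname(shapiro.test(normal)$statistic))
  expect_error(normality_gate(rep(1, 10)), class = "drawmetry_not_testable")
  expect_error(normality_gate(c(1, 2)), class = "drawmetry_not_testable")
})

test_that("Bonferroni threshold is family_alpha / m", {
  expect_identical(bonferroni_threshold(0.05, 2), 0.025)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(1.2, 2), "family_alpha")
})
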