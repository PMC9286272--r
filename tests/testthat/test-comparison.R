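test_that("KS statistic equals the ECDF sweep oracle and stays in [0, 1]", {
  withr::with_seed(10, x <- round(rnorm(10, 5, 2), 2))
  got <- ks_normality(x)
  expect_equal(got$statistic, ks_sweep_stat(x))
  for (seed in 1:10) {
    withr::with_seed(seed, y <- rlnorm(50))
    s <- ks_normality(y)$statistic
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  flat <- ks_normality(rep(3, 10))
  expect_equal(flat$statistic, 1)
  expect_true(flat$significant)
})

test_that("KS on truly normal samples rarely rejects", {
  hits <- 0
  for (seed in 1:50) {
    withr::with_seed(seed, x <- rnorm(1000, 7, 1.5))
    if (ks_normality(x)$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("Mann-Whitney handles separation, identity and degeneracy", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 8)
  expect_equal(same$p_value, 1)

  flat <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(flat$statistic, 5 * 7 / 2)
  expect_equal(flat$p_value, 1)
})

test_that("exact Mann-Whitney agrees with enumeration on small samples", {
  withr::with_seed(77, {
    x <- rnorm(5); y <- rnorm(6) + 0.5
  })
  expect_equal(mann_whitney_u(x, y)$p_value, mw_enum_p(x, y))
  # exact and approximate p-values stay close on tie-free data
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- rnorm(7); b <- rnorm(7)
    })
    pe <- mann_whitney_u(a, b, exact = TRUE)$p_value
    pa <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.015) # small-sample sanity bound
  }
})

test_that("Kruskal-Wallis matches hand rank-sum arithmetic", {
  h <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(h$statistic, kw_hand_h(list(c(1, 2), c(3, 4), c(5, 6))))
  expect_equal(h$statistic, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 21)

  withr::with_seed(8, g <- list(rnorm(9), rnorm(7) + 1, rnorm(11)))
  expect_equal(kruskal_wallis(g)$statistic, kw_hand_h(g))

  same <- kruskal_wallis(list(rep(4, 3), rep(4, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("two-group Kruskal-Wallis is the squared Mann-Whitney z", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      x <- rnorm(30); y <- rnorm(25) + 0.3
    })
    kw <- kruskal_wallis(list(x, y))
    mw <- mann_whitney_u(x, y, exact = FALSE, correct = FALSE)
    z <- qnorm(mw$p_value / 2)
    expect_equal(kw$statistic, z^2, tolerance = 1e-8)
  }
})

test_that("rank tests are invariant under monotone transforms", {
  withr::with_seed(31, {
    x <- rlnorm(40); y <- rlnorm(35) * 1.4; z <- rlnorm(20)
  })
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(log(x), log(y))$p_value)
  expect_equal(kruskal_wallis(list(x, y, z))$statistic,
               kruskal_wallis(list(sqrt(x), sqrt(y), sqrt(z)))$statistic)
  expect_equal(ks_normality(x)$statistic > 0, TRUE)
})

test_that("comparison table shapes results and tolerates empty partitions", {
  vals <- list(T1 = list(WBC = rnorm(30, 8), Hgb = rnorm(30, 12)),
               T2 = list(WBC = rnorm(30, 8.2), Hgb = rnorm(30, 11.6)),
               T3 = list(WBC = rnorm(30, 8.5), Hgb = rnorm(30, 12.4)),
               NP = list(WBC = rnorm(30, 6.5), Hgb = rnorm(30, 13)))
  tab <- comparison_table(vals)
  expect_equal(tab$analyte, c("WBC", "Hgb"))
  expect_true(all(vapply(tab[grep("^p_", names(tab))], function(p)
    all(p >= 0 & p <= 1), logical(1))))

  vals$NP <- list()
  tab2 <- comparison_table(vals)
  expect_true(all(is.na(tab2$p_preg_vs_np)))
  expect_false(anyNA(tab2$p_trimesters))
})

test_that("a large trimester shift is detected nearly always", {
  hits <- 0
  for (seed in 1:60) {
    withr::with_seed(seed, {
      t1 <- rnorm(130, 8, 2)
      t3 <- rnorm(130, 10, 2) # 1 SD location shift
    })
    if (mann_whitney_u(t1, t3)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})
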