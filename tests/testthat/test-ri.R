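test_that("reference limit ranks follow the plotting-position formula", {
  expect_equal(unlist(reference_limit_ranks(119)[c("rank_low", "rank_high")]),
               c(rank_low = 3, rank_high = 117))
  expect_equal(unlist(reference_limit_ranks(39)[c("rank_low", "rank_high")]),
               c(rank_low = 1, rank_high = 39))
  expect_equal(unlist(reference_limit_ranks(395)[c("rank_low", "rank_high")]),
               c(rank_low = 9.9, rank_high = 386.1))
  # clamping keeps ranks inside [1, n]
  expect_equal(reference_limit_ranks(10)$rank_high, 10)
  expect_error(reference_limit_ranks(100, 0.5, 0.2), "probabilities")
})

test_that("value_at_rank interpolates and matches a sort-and-index oracle", {
  expect_equal(value_at_rank(1:10, 2.5), 2.5)
  expect_equal(value_at_rank(1:10, 1), 1)
  expect_equal(value_at_rank(1:10, 10), 10)
  expect_error(value_at_rank(1:10, 0.5), "outside")
  expect_error(value_at_rank(1:10, 10.5), "outside")

  withr::with_seed(2, x <- sort(rlnorm(57)))
  for (r in seq_along(x)) expect_equal(value_at_rank(x, r), x[r])
  withr::with_seed(3, p <- runif(20, 0.01, 0.99))
  for (pp in p) {
    expect_equal(value_at_rank(x, min(max(pp * 58, 1), 57)),
                 sort_interp_percentile(x, pp))
  }
})

test_that("interval of a known sequence and of heavy normal sampling", {
  ri <- nonparametric_ri(1:39)
  expect_equal(c(ri$lower_limit, ri$upper_limit), c(1, 39))
  expect_equal(ri$median, 20)

  withr::with_seed(20190601, x <- rnorm(200000))
  ri <- nonparametric_ri(x)
  expect_lt(abs(ri$lower_limit + 1.959964), 0.03)
  expect_lt(abs(ri$upper_limit - 1.959964), 0.03)
})

test_that("limits are equivariant and bounded by the sample", {
  for (seed in 1:10) {
    withr::with_seed(seed, x <- rgamma(200, 3, 1))
    ri <- nonparametric_ri(x)
    expect_gte(ri$lower_limit, min(x))
    expect_lte(ri$upper_limit, max(x))
    expect_lte(ri$lower_limit, ri$median)
    expect_lte(ri$median, ri$upper_limit)
    tr <- nonparametric_ri(2.5 * x + 3)
    expect_equal(tr$lower_limit, 2.5 * ri$lower_limit + 3)
    expect_equal(tr$upper_limit, 2.5 * ri$upper_limit + 3)
  }
})

test_that("order-statistic CI ranks match the enumeration oracle", {
  pair <- rank_ci_for_percentile(120, 0.025, 0.90)
  expect_true(pair$attainable)
  expect_equal(c(pair$l, pair$u), c(1, 7))

  for (n in c(60, 120, 200, 395)) {
    for (p in c(0.025, 0.1)) {
      got <- rank_ci_for_percentile(n, p, 0.90)
      want <- rank_ci_enum(n, p, 0.90)
      if (is.null(want)) {
        expect_false(got$attainable, label = paste("n =", n, "p =", p))
      } else {
        expect_equal(c(got$l, got$u), c(want$l, want$u),
                     label = paste("n =", n, "p =", p))
      }
    }
  }

  # mirror symmetry between p and 1 - p
  for (n in c(50, 120, 301)) {
    lo <- rank_ci_for_percentile(n, 0.025, 0.90)
    hi <- rank_ci_for_percentile(n, 0.975, 0.90)
    expect_equal(c(hi$l, hi$u), c(n + 1 - lo$u, n + 1 - lo$l))
  }

  expect_false(rank_ci_for_percentile(10, 0.025, 0.90)$attainable)
})

test_that("small samples fall back to the bootstrap or mark CIs unavailable", {
  withr::with_seed(4, x <- rnorm(30, 10, 2))
  auto <- nonparametric_ri(x)
  expect_identical(auto$ci_method, "bootstrap")
  expect_true(all(is.finite(c(auto$lower_ci, auto$upper_ci))))
  expect_lte(auto$lower_ci[1], auto$lower_limit)
  expect_gte(auto$lower_ci[2], auto$lower_limit)

  forced <- nonparametric_ri(x, ci_method = "rank-binomial")
  expect_identical(forced$ci_method, "unavailable")
  expect_true(all(is.na(c(forced$lower_ci, forced$upper_ci))))

  # at reference-cohort sizes the rank CI is attainable and brackets the limit
  withr::with_seed(5, y <- rnorm(150, 10, 2))
  big <- nonparametric_ri(y)
  expect_identical(big$ci_method, "rank-binomial")
  expect_true(big$lower_ci[1] <= big$lower_limit &&
                big$lower_limit <= big$lower_ci[2])
  expect_true(big$upper_ci[1] <= big$upper_limit &&
                big$upper_limit <= big$upper_ci[2])
})
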