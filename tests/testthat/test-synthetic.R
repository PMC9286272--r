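test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- cohort_config(n_per_partition = 40, random_seed = 11)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)
  c <- generate_study(cohort_config(n_per_partition = 40, random_seed = 12))
  expect_false(identical(a$WBC, c$WBC))
})

test_that("cohort has the designed shape and screening structure", {
  cohort <- generate_study(cohort_config(random_seed = 3))
  expect_equal(nrow(cohort), 600)
  expect_setequal(unique(cohort$partition), c("T1", "T2", "T3", "NP"))
  expect_true(all(table(cohort$partition) == 150))
  expect_true(all(cohort$age >= 15 & cohort$age <= 49))
  analytes <- unique(study_analyte_specs()$analyte)
  expect_true(all(analytes %in% names(cohort)))
  expect_true(all(as.matrix(cohort[analytes]) >= 0))

  # zero ineligibility passes everyone; default rate loses ~11.2% of 600
  clean <- generate_study(cohort_config(ineligible_fraction = 0,
                                        random_seed = 3))
  expect_equal(summarize_flow(clean)$eligible, 600)
  flow <- summarize_flow(cohort)
  expect_lt(abs(flow$eligible - 533), 4 * sqrt(600 * 0.112 * 0.888))
})

test_that("unknown partitions and missing calibrations are reported", {
  specs <- study_analyte_specs()
  expect_error(generate_study(cohort_config(partitions = c("T1", "XX"))),
               "XX")
  expect_error(generate_study(cohort_config(),
                              specs = specs[specs$partition != "NP", ]),
               "partition")
})

test_that("outlier injection displaces the requested count reproducibly", {
  withr::with_seed(5, x <- rnorm(100, 50, 5))
  expect_error(inject_outliers(numeric(0), 0.1), "empty")
  none <- inject_outliers(x, 0, seed = 1)
  expect_identical(none$values, x)
  expect_length(none$index, 0)
  one <- inject_outliers(x, 1 / 100, seed = 1)
  expect_length(one$index, 1)
  expect_equal(sum(one$values != x), 1)
  expect_identical(inject_outliers(x, 0.05, seed = 9),
                   inject_outliers(x, 0.05, seed = 9))
})

test_that("injected outliers satisfy the one-third-range rule by construction", {
  for (seed in 1:20) {
    withr::with_seed(seed, x <- rnorm(150, 8, 2))
    inj <- inject_outliers(x, 2 / 150, magnitude = 5, seed = seed + 100)
    for (i in inj$index) {
      v <- inj$values[i]
      clean <- inj$values[-inj$index]
      gap <- min(abs(v - clean))
      rng <- max(c(clean, v)) - min(c(clean, v))
      expect_gt(gap / rng, 1 / 3)
    }
  }
})

test_that("clean cohorts round-trip the calibration targets", {
  # replicate-mean reference limits at n = 5000 per partition, moderate-skew
  # analytes; tolerance 2% of the target span
  specs <- study_analyte_specs()
  keep <- c("WBC", "Hgb", "MCV", "PLT")
  cells <- expand.grid(analyte = keep, partition = c("T1", "NP"),
                       stringsAsFactors = FALSE)
  reps <- 5
  est <- array(NA_real_, c(nrow(cells), 2, reps))
  for (r in seq_len(reps)) {
    cohort <- generate_study(
      cohort_config(n_per_partition = 5000, ineligible_fraction = 0,
                    outlier_rate = 0, random_seed = 20190600 + r),
      specs = specs[specs$analyte %in% keep, ])
    for (i in seq_len(nrow(cells))) {
      v <- cohort[[cells$analyte[i]]][cohort$partition == cells$partition[i]]
      ri <- nonparametric_ri(v, ci_method = "rank-binomial")
      est[i, , r] <- c(ri$lower_limit, ri$upper_limit)
    }
  }
  for (i in seq_len(nrow(cells))) {
    s <- specs[specs$analyte == cells$analyte[i] &
                 specs$partition == cells$partition[i], ]
    span <- s$q_high - s$q_low
    expect_lt(abs(mean(est[i, 1, ]) - s$q_low), 0.02 * span)
    expect_lt(abs(mean(est[i, 2, ]) - s$q_high), 0.02 * span)
  }
})
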