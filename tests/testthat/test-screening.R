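# a single fully eligible record used as the base for rule checks
eligible_record <- function(partition = "T1") {
  df <- data.frame(participant_id = "x-001", partition = partition,
                   age = 28, residence = "urban", altitude_class = "lowland",
                   weight = 60, height = 1.6, systolic_bp = 110,
                   diastolic_bp = 70, stringsAsFactors = FALSE)
  for (f in cohort_schema(character(0))$flags) df[[f]] <- FALSE
  df
}

test_that("BMI arithmetic and the inclusive obesity boundary", {
  expect_equal(compute_bmi(75, 1.5), 33.33, tolerance = 1e-3)
  expect_equal(compute_bmi(60, 1.6), 23.44, tolerance = 1e-3)
  expect_error(compute_bmi(0, 1.6), "positive")
  expect_error(compute_bmi(60, -1), "positive")

  rec <- eligible_record()
  rec$weight <- 76.8 # BMI exactly 30 -> excluded (boundary inclusive)
  out <- evaluate_eligibility(rec)
  expect_false(out$eligible)
  expect_identical(out$reasons, "obesity")
})

test_that("individual exclusion rules fire with the right reasons", {
  rec <- eligible_record()
  expect_true(evaluate_eligibility(rec)$eligible)
  expect_length(evaluate_eligibility(rec)$reasons, 0)

  hb <- rec; hb$hbsag <- TRUE
  out <- evaluate_eligibility(hb)
  expect_false(out$eligible)
  expect_identical(out$reasons, "serology")

  # hypertension: systolic > 140 OR diastolic > 90, both strict
  bp <- rec; bp$systolic_bp <- 145
  expect_identical(evaluate_eligibility(bp)$reasons, "blood_pressure")
  bp <- rec; bp$diastolic_bp <- 95
  expect_identical(evaluate_eligibility(bp)$reasons, "blood_pressure")
  bp <- rec; bp$systolic_bp <- 140; bp$diastolic_bp <- 90
  expect_true(evaluate_eligibility(bp)$eligible)
})

test_that("non-pregnant-only rules apply only to the NP partition", {
  preg <- eligible_record("T2"); preg$menstruating <- TRUE
  expect_true(evaluate_eligibility(preg)$eligible)
  np <- eligible_record("NP"); np$menstruating <- TRUE
  expect_identical(evaluate_eligibility(np)$reasons, "np_specific")

  # iron/folate is routine supplementation in pregnancy, exclusionary for NP
  preg <- eligible_record("T3"); preg$iron_folate <- TRUE
  expect_true(evaluate_eligibility(preg)$eligible)
  np <- eligible_record("NP"); np$iron_folate <- TRUE
  expect_identical(evaluate_eligibility(np)$reasons, "medication_substance")
})

test_that("missing screening fields are named in validation errors", {
  rec <- eligible_record()
  rec$hcv <- NULL
  expect_error(evaluate_eligibility(rec), "hcv")
  rec2 <- eligible_record()
  rec2$weight <- NA
  expect_error(evaluate_eligibility(rec2), "weight")
})

test_that("eligibility is monotone and screening is idempotent", {
  flags <- cohort_schema(character(0))$flags
  base <- eligible_record("NP")
  for (f in flags) {
    rec <- base
    rec[[f]] <- TRUE
    one <- evaluate_eligibility(rec)
    for (g in setdiff(flags, f)) {
      rec2 <- rec
      rec2[[g]] <- TRUE
      two <- evaluate_eligibility(rec2)
      # adding a flag can only keep or lose eligibility
      expect_true(!two$eligible || one$eligible)
      expect_true(all(one$reasons %in% two$reasons))
    }
  }

  cohort <- generate_study(cohort_config(random_seed = 21))
  flow <- summarize_flow(cohort)
  again <- summarize_flow(cohort[flow$is_eligible, , drop = FALSE])
  expect_equal(again$eligible, again$enrolled)
})

test_that("flow report reproduces the study's participant flow", {
  cohort <- make_flow_cohort()
  flow <- summarize_flow(cohort)
  expect_equal(flow$enrolled, 600)
  expect_equal(flow$eligible, 533)
  expect_equal(flow$eligible_percent, 88.8)
  expect_equal(flow$excluded_percent, 11.2)
  expect_equal(as.integer(flow$excluded_by_partition[c("T1", "T2", "T3",
                                                       "NP")]),
               c(14, 20, 19, 14))
  # conservation: reasons, partitions and the total all agree
  expect_equal(sum(flow$excluded_by_reason), flow$excluded)
  expect_equal(sum(flow$excluded_by_partition), flow$excluded)
  expect_equal(flow$eligible + flow$excluded, flow$enrolled)

  clean <- generate_study(cohort_config(ineligible_fraction = 0,
                                        random_seed = 2))
  expect_equal(summarize_flow(clean)$eligible_percent, 100.0)
})

test_that("sample-size planner applies the exclusion-rate correction", {
  plan <- plan_sample_size(120, 4, 0.20)
  expect_equal(plan$base_total, 480)
  expect_equal(plan$corrected_total, 600)
  expect_equal(plan_sample_size(120, 4, 0)$corrected_total, 480)
  expect_equal(plan_sample_size(100, 1, 0.5)$corrected_total, 200)
  expect_error(plan_sample_size(120, 4, 1), "exclusion_rate")
})
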