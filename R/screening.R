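#' Body mass index
#'
#' @param weight weight in kg.
#' @param height height in m.
#' @return `weight / height^2` in kg/m^2 (vectorized). The obesity exclusion
#'   compares this against a cutoff of 30 kg/m^2, boundary inclusive.
#' @examples
#' compute_bmi(75, 1.5)   # 33.3, obese
#' compute_bmi(76.8, 1.6) # exactly 30, still excluded
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive and finite")
  }
  weight / height^2
}

#' Eligibility screening thresholds
#'
#' The hypertension rule is systolic > 140 mmHg OR diastolic > 90 mmHg
#' (the conventional screening thresholds; some published wordings transpose
#' the two labels). Age bounds are inclusive.
#'
#' @param bmi_cutoff obesity cutoff in kg/m^2, inclusive.
#' @param systolic_max,diastolic_max blood-pressure thresholds in mmHg,
#'   exclusive (values strictly above are excluded).
#' @param age_min,age_max inclusive reproductive-age bounds in years.
#' @return An object of class `screening_rules`.
#' @export
screening_rules <- function(bmi_cutoff = 30, systolic_max = 140,
                            diastolic_max = 90, age_min = 15, age_max = 49) {
  stopifnot(bmi_cutoff > 0, systolic_max > 0, diastolic_max > 0,
            age_min < age_max)
  structure(list(bmi_cutoff = bmi_cutoff, systolic_max = systolic_max,
                 diastolic_max = diastolic_max,
                 age_min = age_min, age_max = age_max),
            class = "screening_rules")
}

# documented rule order; first firing reason is the one counted in the flow
# report, though evaluate_eligibility() returns every firing reason
screening_reason_order <- function() {
  c("serology", "parasite", "chronic_history", "medication_substance",
    "obstetric", "obesity", "blood_pressure", "np_specific",
    "specimen_quality")
}

#' Validate a participant table
#'
#' Checks that all screening columns exist and carry no missing values, and
#' that ages lie within the reproductive-age bounds.
#'
#' @param records participant data.frame.
#' @param rules a [screening_rules()].
#' @return `records`, invisibly; errors name the offending field.
#' @export
validate_cohort <- function(records, rules = screening_rules()) {
  schema <- cohort_schema(analytes = character(0))
  required <- c(schema$id, schema$numeric, schema$flags)
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("missing required screening field(s): ",
         paste(missing, collapse = ", "))
  }
  for (f in required) {
    if (anyNA(records[[f]])) {
      stop("missing values in required screening field: ", f,
           " (rows ", paste(utils::head(which(is.na(records[[f]])), 5),
                            collapse = ", "), ")")
    }
  }
  if (any(records$age < rules$age_min | records$age > rules$age_max)) {
    stop("age outside the reproductive-age range [", rules$age_min, ", ",
         rules$age_max, "]")
  }
  invisible(records)
}

# n x reason logical matrix, columns in screening_reason_order()
screening_reason_matrix <- function(records, rules) {
  np <- records$partition == "NP"
  bmi <- compute_bmi(records$weight, records$height)
  m <- cbind(
    serology = records$hiv | records$hbsag | records$hcv |
      records$syphilis | records$crp,
    parasite = records$hemoparasite | records$intestinal_parasite,
    chronic_history = records$chronic_disease | records$transfusion_1y |
      records$donation_3m | records$admission_1y | records$surgery_3y |
      records$malaria_6m | records$tb_2y,
    # prescription drugs exclude everyone; iron/folate supplementation is
    # routine in pregnancy and only exclusionary for the non-pregnant group
    medication_substance = records$medication | records$substance_use |
      records$hazardous_exposure | (records$iron_folate & np),
    obstetric = records$obstetric_complication & !np,
    # tiny tolerance keeps the inclusive cutoff robust to float noise in
    # weight / height^2 (e.g. 76.8 kg at 1.60 m is exactly BMI 30)
    obesity = bmi >= rules$bmi_cutoff - 1e-9,
    blood_pressure = records$systolic_bp > rules$systolic_max |
      records$diastolic_bp > rules$diastolic_max,
    np_specific = np & (records$menstruating | records$breastfeeding |
                          records$oral_contraceptive),
    specimen_quality = records$specimen_quality_fail)
  m[, screening_reason_order(), drop = FALSE]
}

#' Screen one participant record
#'
#' @param record a one-row participant data.frame.
#' @param rules a [screening_rules()].
#' @return List with `eligible` (logical) and `reasons` (every firing
#'   exclusion reason, in the documented rule order; empty when eligible).
#' @export
evaluate_eligibility <- function(record, rules = screening_rules()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  validate_cohort(record, rules)
  fired <- screening_reason_matrix(record, rules)[1L, ]
  list(eligible = !any(fired), reasons = names(fired)[fired])
}

#' Participant-flow report
#'
#' Applies every screening rule to the cohort and reports the enrolled /
#' eligible flow. An excluded subject is counted once, under the first rule
#' that fires in the documented order.
#'
#' @param records participant data.frame.
#' @param rules a [screening_rules()].
#' @return An `eligibility_report`: enrolled, eligible, eligible percentage
#'   (one decimal), exclusion counts by reason and by partition, and the
#'   per-record logical eligibility vector.
#' @export
summarize_flow <- function(records, rules = screening_rules()) {
  if (nrow(records) == 0L) stop("empty participant table")
  validate_cohort(records, rules)
  m <- screening_reason_matrix(records, rules)
  excluded <- rowSums(m) > 0
  first <- apply(m[excluded, , drop = FALSE], 1L,
                 function(r) colnames(m)[which(r)[1L]])
  by_reason <- table(factor(first, levels = screening_reason_order()))
  by_partition <- table(factor(records$partition[excluded],
                               levels = unique(records$partition)))
  structure(list(
    enrolled = nrow(records),
    eligible = sum(!excluded),
    eligible_percent = round(100 * sum(!excluded) / nrow(records), 1),
    excluded = sum(excluded),
    excluded_percent = round(100 * sum(excluded) / nrow(records), 1),
    excluded_by_reason = by_reason,
    excluded_by_partition = by_partition,
    is_eligible = !excluded), class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Participant flow: ", x$enrolled, " enrolled -> ", x$eligible,
      " eligible (", sprintf("%.1f", x$eligible_percent), "%), ",
      x$excluded, " excluded (", sprintf("%.1f", x$excluded_percent),
      "%)\n", sep = "")
  if (x$excluded > 0) {
    nz <- x$excluded_by_reason[x$excluded_by_reason > 0]
    cat("  by reason:   ",
        paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
    cat("  by partition:",
        paste(names(x$excluded_by_partition), x$excluded_by_partition,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plan the study sample size
#'
#' The CLSI/IFCC nonparametric method needs at least 120 reference subjects
#' per partition; the recruitment target is inflated for the anticipated
#' screening exclusion rate via
#' `corrected = ceiling(base / (1 - exclusion_rate))`.
#'
#' @param per_partition_minimum minimum reference subjects per partition.
#' @param n_partitions number of partitions.
#' @param exclusion_rate anticipated proportion of recruits excluded,
#'   in `[0, 1)`.
#' @return A `sample_size_plan` list: `per_partition_minimum`,
#'   `n_partitions`, `exclusion_rate`, `base_total`, `corrected_total`.
#' @examples
#' plan_sample_size(120, 4, 0.20) # base 480, corrected 600
#' @export
plan_sample_size <- function(per_partition_minimum = 120, n_partitions = 4,
                             exclusion_rate = 0.20) {
  stopifnot(per_partition_minimum >= 1, n_partitions >= 1)
  if (exclusion_rate < 0 || exclusion_rate >= 1) {
    stop("exclusion_rate must be in [0, 1)")
  }
  base <- per_partition_minimum * n_partitions
  structure(list(per_partition_minimum = per_partition_minimum,
                 n_partitions = n_partitions,
                 exclusion_rate = exclusion_rate,
                 base_total = base,
                 corrected_total = ceiling(base / (1 - exclusion_rate))),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat("Sample-size plan: ", x$per_partition_minimum, " x ", x$n_partitions,
      " = ", x$base_total, " base; corrected for ",
      100 * x$exclusion_rate, "% exclusions -> ", x$corrected_total,
      " recruits\n", sep = "")
  invisible(x)
}
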