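#' Configuration for the synthetic cohort generator
#'
#' Defines the design of a simulated reference-interval study: four
#' partitions (three pregnancy trimesters and a non-pregnant group) of 150
#' women each, an expected ineligible fraction of 11.2% spread over the
#' screening reasons, and sporadic gross outliers per analyte.
#'
#' @param partitions ordered partition labels.
#' @param n_per_partition subjects recruited per partition.
#' @param ineligible_fraction expected proportion of recruits failing
#'   eligibility screening (Bernoulli per record).
#' @param ineligibility_weights named weights over the reason categories
#'   `serology`, `chronic_history`, `transfusion_donation`, `obesity`,
#'   `high_bp` used to choose which screening field is set on an ineligible
#'   record.
#' @param outlier_rate proportion of values per analyte and partition
#'   displaced into gross outliers.
#' @param outlier_magnitude displacement in multiples of the clean
#'   interquartile range beyond the clean minimum/maximum.
#' @param random_seed integer seed; the same configuration and seed always
#'   reproduce the identical table.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(partitions = c("T1", "T2", "T3", "NP"),
                          n_per_partition = 150L,
                          ineligible_fraction = 0.112,
                          ineligibility_weights = c(serology = 0.35,
                                                    chronic_history = 0.25,
                                                    transfusion_donation = 0.15,
                                                    obesity = 0.15,
                                                    high_bp = 0.10),
                          outlier_rate = 0.005,
                          outlier_magnitude = 5,
                          random_seed = 1L) {
  stopifnot(length(partitions) >= 1, !anyDuplicated(partitions),
            n_per_partition >= 1,
            ineligible_fraction >= 0, ineligible_fraction <= 1,
            outlier_rate >= 0, outlier_rate <= 1, outlier_magnitude >= 0,
            is.numeric(random_seed), length(random_seed) == 1L)
  known <- c("serology", "chronic_history", "transfusion_donation",
             "obesity", "high_bp")
  if (!all(names(ineligibility_weights) %in% known) ||
      any(ineligibility_weights < 0) || sum(ineligibility_weights) <= 0) {
    stop("ineligibility_weights must be non-negative weights over: ",
         paste(known, collapse = ", "))
  }
  structure(list(partitions = partitions,
                 n_per_partition = as.integer(n_per_partition),
                 ineligible_fraction = ineligible_fraction,
                 ineligibility_weights = ineligibility_weights,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 random_seed = as.integer(random_seed)),
            class = "cohort_config")
}

# screening flag columns shared by the generator, validator and screener
cohort_flag_fields <- function() {
  c("hiv", "hbsag", "hcv", "syphilis", "crp",
    "hemoparasite", "intestinal_parasite",
    "chronic_disease", "transfusion_1y", "donation_3m", "admission_1y",
    "surgery_3y", "malaria_6m", "tb_2y",
    "medication", "iron_folate", "substance_use", "hazardous_exposure",
    "obstetric_complication",
    "menstruating", "breastfeeding", "oral_contraceptive",
    "specimen_quality_fail")
}

#' Column schema of a participant table
#'
#' @param analytes character vector of analyte column names (defaults to the
#'   shipped panel).
#' @return Named list with the identifier, numeric-screening, boolean-flag
#'   and analyte column names, in table order.
#' @export
cohort_schema <- function(analytes = unique(study_analyte_specs()$analyte)) {
  list(id = c("participant_id", "partition", "age", "residence",
              "altitude_class"),
       numeric = c("weight", "height", "systolic_bp", "diastolic_bp"),
       flags = cohort_flag_fields(),
       analytes = analytes)
}

#' Displace a fraction of values into gross outliers
#'
#' Supports ground-truth testing of the outlier screen: `round(rate * n)`
#' randomly chosen entries are moved to `max + magnitude * IQR` (upper tail)
#' or `min - magnitude * IQR` (lower tail), alternating tails. A lower-tail
#' placement that would go negative is redirected to the upper tail, since
#' analyte values are non-negative. All outliers sent to a given tail share
#' the same displaced value, so they are flagged (and removed) together by
#' the one-third-range rule's tie handling.
#'
#' @param values numeric vector, no NAs.
#' @param rate proportion of entries to displace, in `[0, 1]`.
#' @param magnitude displacement in multiples of the interquartile range.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return List with `values` (modified vector), `index` (sorted positions of
#'   displaced entries) and `original` (their original values).
#' @export
inject_outliers <- function(values, rate, magnitude = 5, seed = NULL) {
  if (length(values) == 0L) stop("cannot inject outliers into an empty vector")
  stopifnot(is.numeric(values), all(is.finite(values)),
            rate >= 0, rate <= 1, magnitude >= 0)
  run <- function() {
    n <- length(values)
    k <- round(rate * n)
    if (k == 0L) {
      return(list(values = values, index = integer(0), original = numeric(0)))
    }
    idx <- sort(sample.int(n, k))
    iqr <- stats::IQR(values)
    lo <- min(values) - magnitude * iqr
    hi <- max(values) + magnitude * iqr
    tails <- rep_len(c("upper", "lower"), k)
    if (lo < 0) tails[tails == "lower"] <- "upper"
    out <- values
    out[idx] <- ifelse(tails == "upper", hi, lo)
    list(values = out, index = idx, original = values[idx])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# draw screening fields for one partition; flips flags on ineligible records
simulate_screening_fields <- function(partition, n, config) {
  height <- round(stats::rnorm(n, 1.60, 0.06), 2)
  bmi <- pmin(stats::rnorm(n, 23, 2.5), 29.4)
  weight <- round(bmi * height^2, 1)
  sys <- round(pmin(stats::rnorm(n, 112, 9), 138))
  dia <- round(pmin(stats::rnorm(n, 72, 7), 88))
  # right-skewed ages averaging ~26 y within the 15-49 reproductive range
  age <- pmin(49, 15 + round(stats::rgamma(n, shape = 2.5, scale = 4.5)))
  df <- data.frame(
    participant_id = sprintf("%s-%03d", partition, seq_len(n)),
    partition = partition,
    age = age,
    residence = sample(c("urban", "rural"), n, replace = TRUE,
                       prob = c(0.52, 0.48)),
    altitude_class = sample(c("lowland", "highland"), n, replace = TRUE,
                            prob = c(0.547, 0.453)),
    weight = weight, height = height,
    systolic_bp = sys, diastolic_bp = dia,
    stringsAsFactors = FALSE)
  for (f in cohort_flag_fields()) df[[f]] <- FALSE

  inel <- stats::runif(n) < config$ineligible_fraction
  w <- config$ineligibility_weights
  for (i in which(inel)) {
    reason <- sample(names(w), 1L, prob = w)
    switch(reason,
      serology = {
        f <- sample(c("hiv", "hbsag", "hcv", "syphilis", "crp"), 1L)
        df[[f]][i] <- TRUE
      },
      chronic_history = {
        f <- sample(c("chronic_disease", "admission_1y", "surgery_3y",
                      "malaria_6m", "tb_2y"), 1L)
        df[[f]][i] <- TRUE
      },
      transfusion_donation = {
        f <- sample(c("transfusion_1y", "donation_3m"), 1L)
        df[[f]][i] <- TRUE
      },
      obesity = {
        bmi_i <- stats::runif(1, 30, 38)
        df$weight[i] <- round(bmi_i * df$height[i]^2, 1)
      },
      high_bp = {
        if (stats::runif(1) < 0.5) {
          df$systolic_bp[i] <- round(stats::runif(1, 142, 175))
        } else {
          df$diastolic_bp[i] <- round(stats::runif(1, 92, 110))
        }
      })
  }
  df
}

#' Generate a synthetic reference-interval study cohort
#'
#' Draws one participant table with the structure the downstream analysis
#' assumes: `n_per_partition` subjects per partition, an expected
#' `ineligible_fraction` of records carrying the screening field that makes
#' them ineligible, analyte values drawn independently from distributions
#' calibrated to the per-partition quantile targets (truncated at zero and
#' rounded to the analyte's reporting precision), and sporadic gross
#' outliers. Analytes are simulated as independent marginals; physiological
#' couplings (e.g. Hgb with HCT) are not modelled.
#'
#' @param config a [cohort_config()].
#' @param specs calibration table as from [study_analyte_specs()].
#' @return A `data.frame`, one row per participant (see [cohort_schema()]),
#'   with attribute `outlier_log`: a data.frame of the injected outliers
#'   (`row`, `partition`, `analyte`, `original`, `displaced`).
#' @examples
#' cohort <- generate_study(cohort_config(random_seed = 7))
#' nrow(cohort)
#' @export
generate_study <- function(config = cohort_config(),
                           specs = study_analyte_specs()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_analyte_specs(specs)
  if (!all(config$partitions %in% unique(specs$partition))) {
    stop("no analyte calibration for partition(s): ",
         paste(setdiff(config$partitions, unique(specs$partition)),
               collapse = ", "))
  }
  analytes <- unique(specs$analyte)
  with_seed(config$random_seed, {
    parts <- lapply(config$partitions, function(p) {
      df <- simulate_screening_fields(p, config$n_per_partition, config)
      for (a in analytes) {
        s <- specs[specs$analyte == a & specs$partition == p, ]
        if (nrow(s) != 1L) stop("missing analyte calibration: ", a, " / ", p)
        d <- calibrate_distribution(s$q_low, s$q_med, s$q_high)
        df[[a]] <- round(pmax(r_analyte_dist(d, nrow(df)), 0), s$decimals)
      }
      df
    })
    cohort <- do.call(rbind, parts)
    rownames(cohort) <- NULL

    log <- list()
    offset <- 0L
    for (p in config$partitions) {
      rows <- which(cohort$partition == p)
      for (a in analytes) {
        dec <- specs$decimals[specs$analyte == a & specs$partition == p]
        inj <- inject_outliers(cohort[[a]][rows], config$outlier_rate,
                               config$outlier_magnitude)
        if (length(inj$index)) {
          vals <- round(pmax(inj$values[inj$index], 0), dec)
          cohort[[a]][rows[inj$index]] <- vals
          log[[length(log) + 1L]] <- data.frame(
            row = rows[inj$index], partition = p, analyte = a,
            original = inj$original, displaced = vals,
            stringsAsFactors = FALSE)
        }
      }
    }
    attr(cohort, "outlier_log") <- if (length(log)) do.call(rbind, log) else
      data.frame(row = integer(0), partition = character(0),
                 analyte = character(0), original = numeric(0),
                 displaced = numeric(0))
    cohort
  })
}
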