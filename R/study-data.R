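#' Shipped study reference tables
#'
#' The package ships, as plain-text tables under `inst/extdata/`, the
#' published summary statistics that drive the synthetic cohort generator and
#' the out-of-range analysis: per-partition quantile calibration targets
#' (median and 2.5th/97.5th percentiles for each of the 19 CBC analytes in
#' the three trimesters and the non-pregnant group), the pooled
#' pregnant/non-pregnant interval summaries, the manufacturer reference
#' intervals with the published per-limit out-of-range counts, the
#' participant-flow counts, and residence/altitude demographics.
#'
#' One published anomaly is repaired in the calibration table (not in
#' [study_reference_intervals()]): the non-pregnant PDW median is printed
#' below the lower interval bound, so its central calibration target is the
#' printed mean instead. Calibration requires `q_low < q_med < q_high`.
#'
#' @return Each accessor returns a `data.frame`.
#' @name study_tables
NULL

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "hemaRI")
  if (path == "") stop("shipped data file not found: ", file)
  path
}

#' @describeIn study_tables per-analyte, per-partition calibration targets
#'   (`analyte`, `label`, `units`, `decimals`, `partition`, `q_low`, `q_med`,
#'   `q_high`).
#' @export
study_analyte_specs <- function() {
  df <- utils::read.csv(extdata_path("analyte_calibration.csv"),
                        stringsAsFactors = FALSE)
  validate_analyte_specs(df)
  df
}

#' Validate an analyte calibration table
#'
#' Checks the `AnalyteSpec` invariants: strictly monotone quantile triples,
#' non-empty units, and a complete set of partitions per analyte.
#'
#' @param specs a data.frame shaped like [study_analyte_specs()].
#' @return `specs`, invisibly, or an error.
#' @export
validate_analyte_specs <- function(specs) {
  needed <- c("analyte", "units", "decimals", "partition",
              "q_low", "q_med", "q_high")
  missing <- setdiff(needed, names(specs))
  if (length(missing)) {
    stop("analyte spec table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (any(!nzchar(specs$units))) stop("analyte units must be non-empty")
  bad <- !(specs$q_low < specs$q_med & specs$q_med < specs$q_high)
  if (any(bad)) {
    stop("non-monotone quantile triple for ",
         paste(unique(paste(specs$analyte[bad], specs$partition[bad])),
               collapse = ", "))
  }
  counts <- table(specs$analyte)
  if (length(unique(counts)) != 1L) {
    stop("each analyte must have a calibration triple for every partition")
  }
  invisible(specs)
}

#' @describeIn study_tables pooled pregnant / non-pregnant interval summaries
#'   (`analyte`, `group`, `n`, `mean`, `median`, `q_low`, `q_high`), as
#'   published, anomalies included.
#' @export
study_reference_intervals <- function() {
  utils::read.csv(extdata_path("study_reference_intervals.csv"),
                  stringsAsFactors = FALSE)
}

#' @describeIn study_tables manufacturer intervals, established intervals and
#'   published per-limit out-of-range counts (`analyte`, `mfr_low`,
#'   `mfr_high`, `est_low`, `est_high`, `below_n`, `above_n`).
#' @export
manufacturer_intervals <- function() {
  utils::read.csv(extdata_path("manufacturer_ri.csv"),
                  stringsAsFactors = FALSE)
}

#' @describeIn study_tables published participant-flow counts per partition
#'   (`partition`, `enrolled`, `excluded`).
#' @export
study_flow_counts <- function() {
  utils::read.csv(extdata_path("study_flow.csv"), stringsAsFactors = FALSE)
}

#' @describeIn study_tables residence and altitude demographics for the
#'   pregnant and non-pregnant groups.
#' @export
study_demographics <- function() {
  utils::read.csv(extdata_path("study_demographics.csv"),
                  stringsAsFactors = FALSE)
}
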