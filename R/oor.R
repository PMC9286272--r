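#' Count values outside an interval
#'
#' Boundary values are in range: only `v < low` or `v > high` count.
#'
#' @param values numeric vector (NAs dropped).
#' @param low,high interval bounds, `low <= high`.
#' @return Named integer vector `c(below, above)`.
#' @examples
#' count_oor(1:10, 3, 7) # below 2, above 3
#' @export
count_oor <- function(values, low, high) {
  if (!(is.finite(low) && is.finite(high)) || low > high) {
    stop("interval must satisfy low <= high")
  }
  values <- values[!is.na(values)]
  c(below = sum(values < low), above = sum(values > high))
}

#' Out-of-range rows from per-limit counts
#'
#' Recomputes totals and percentages from per-limit out-of-range counts,
#' enforcing `total = below + above` and reporting the percentage to one
#' decimal. Used both for the pipeline's own counts and for re-deriving the
#' arithmetic of published count tables.
#'
#' @param counts data.frame with columns `below_n` and `above_n` (other
#'   columns are carried through).
#' @param denominator count used for the percentage (scalar or per-row).
#' @return `counts` with `total_n`, `denominator` and `percent` columns.
#' @export
oor_from_counts <- function(counts, denominator) {
  stopifnot(all(c("below_n", "above_n") %in% names(counts)),
            all(denominator > 0))
  counts$total_n <- counts$below_n + counts$above_n
  counts$denominator <- denominator
  counts$percent <- round(100 * counts$total_n / denominator, 1)
  counts
}

#' Out-of-range misclassification table
#'
#' Scores how many subjects of a cohort fall outside the manufacturer
#' interval for each analyte, alongside the locally established interval.
#' By default the percentage denominator is the number of subjects enrolled
#' in the group (`denominator_mode = "enrolled"`); `"per_analyte"` uses each
#' analyte's non-missing count instead.
#'
#' @param data cohort data.frame (e.g. the pregnant subjects) with one
#'   column per analyte.
#' @param manufacturer data.frame with `analyte`, `mfr_low`, `mfr_high`.
#' @param established optional data.frame with `analyte`, `est_low`,
#'   `est_high` carried into the output for side-by-side display.
#' @param denominator_mode `"enrolled"` or `"per_analyte"`.
#' @return A data.frame with one row per analyte: intervals, `below_n`,
#'   `above_n`, `total_n`, `denominator`, `percent`.
#' @export
oor_table <- function(data, manufacturer = manufacturer_intervals(),
                      established = NULL,
                      denominator_mode = c("enrolled", "per_analyte")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(all(c("analyte", "mfr_low", "mfr_high") %in%
                  names(manufacturer)))
  missing <- setdiff(manufacturer$analyte, names(data))
  if (length(missing)) {
    stop("cohort has no column for analyte(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manufacturer)), function(i) {
    a <- manufacturer$analyte[i]
    v <- data[[a]]
    cnt <- count_oor(v, manufacturer$mfr_low[i], manufacturer$mfr_high[i])
    denom <- if (denominator_mode == "enrolled") nrow(data) else
      sum(!is.na(v))
    df <- data.frame(analyte = a,
                     mfr_low = manufacturer$mfr_low[i],
                     mfr_high = manufacturer$mfr_high[i],
                     below_n = unname(cnt["below"]),
                     above_n = unname(cnt["above"]),
                     stringsAsFactors = FALSE)
    oor_from_counts(df, denom)
  })
  out <- do.call(rbind, rows)
  if (!is.null(established)) {
    stopifnot(all(c("analyte", "est_low", "est_high") %in%
                    names(established)))
    out <- merge(out, established[, c("analyte", "est_low", "est_high")],
                 by = "analyte", sort = FALSE)
    out <- out[, c("analyte", "mfr_low", "mfr_high", "est_low", "est_high",
                   "below_n", "above_n", "total_n", "denominator",
                   "percent")]
  }
  rownames(out) <- NULL
  out
}
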