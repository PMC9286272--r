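#' Fractional ranks of the reference limits
#'
#' The nonparametric reference limits are the 2.5th and 97.5th percentiles
#' of the ranked reference sample, located at the plotting-position ranks
#' `p * (n + 1)`; the ranks are clamped into `[1, n]`.
#'
#' @param n sample size.
#' @param p_low,p_high limit probabilities (defaults 0.025 and 0.975).
#' @return List with `rank_low`, `rank_high`, `n`, `p_low`, `p_high`.
#' @examples
#' reference_limit_ranks(119) # ranks 3 and 117
#' reference_limit_ranks(395) # fractional ranks 9.9 and 386.1
#' @export
reference_limit_ranks <- function(n, p_low = 0.025, p_high = 0.975) {
  stopifnot(n >= 1)
  if (!(p_low > 0 && p_low < p_high && p_high < 1)) {
    stop("probabilities must satisfy 0 < p_low < p_high < 1")
  }
  clamp <- function(r) min(max(r, 1), n)
  list(rank_low = clamp(p_low * (n + 1)),
       rank_high = clamp(p_high * (n + 1)),
       n = as.integer(n), p_low = p_low, p_high = p_high)
}

#' Value at a fractional rank
#'
#' Linear interpolation between the order statistics bracketing a fractional
#' rank, the standard companion of the `p * (n + 1)` plotting position.
#'
#' @param sorted_values numeric vector sorted ascending.
#' @param rank fractional rank in `[1, length(sorted_values)]`.
#' @return Interpolated value.
#' @export
value_at_rank <- function(sorted_values, rank) {
  n <- length(sorted_values)
  stopifnot(n >= 1, !is.unsorted(sorted_values))
  if (rank < 1 || rank > n) stop("rank ", rank, " outside [1, ", n, "]")
  lo <- floor(rank)
  hi <- ceiling(rank)
  if (lo == hi) return(sorted_values[lo])
  sorted_values[lo] + (rank - lo) * (sorted_values[hi] - sorted_values[lo])
}

#' Distribution-free order-statistic CI ranks for a percentile
#'
#' Finds the narrowest pair of order-statistic ranks `(l, u)`, `l < u`, whose
#' interval `[x_(l), x_(u)]` covers the true `p`-th percentile with at least
#' the requested confidence: with `K ~ Binomial(n, p)` counting observations
#' below the percentile, the coverage is `P(l <= K < u)`. Ties on width are
#' broken toward equal tail probabilities, then toward the smaller `l`. The
#' pair for `1 - p` is by construction the mirror image
#' `(n + 1 - u, n + 1 - l)` of the pair for `p`.
#'
#' @param n sample size.
#' @param p percentile probability.
#' @param confidence required coverage (default 0.90).
#' @return List with `l`, `u`, `coverage`, `attainable`. When no pair
#'   reaches the confidence at this `n`, `attainable` is `FALSE` and the
#'   ranks are `NA` (callers fall back to the bootstrap).
#' @examples
#' rank_ci_for_percentile(120, 0.025, 0.90) # ranks (1, 7)
#' @export
rank_ci_for_percentile <- function(n, p, confidence = 0.90) {
  stopifnot(n >= 1, p > 0, p < 1, confidence > 0, confidence < 1)
  if (p > 0.5) {
    mirror <- rank_ci_for_percentile(n, 1 - p, confidence)
    if (!mirror$attainable) return(mirror)
    return(list(l = n + 1 - mirror$u, u = n + 1 - mirror$l,
                coverage = mirror$coverage, attainable = TRUE))
  }
  if (n < 2) {
    return(list(l = NA_integer_, u = NA_integer_, coverage = NA_real_,
                attainable = FALSE))
  }
  cdf <- stats::pbinom(0:n, n, p)           # cdf[k + 1] = P(K <= k)
  for (w in 1:(n - 1)) {
    l <- seq_len(n - w)
    u <- l + w
    cov <- cdf[u] - cdf[l]                  # P(l <= K <= u - 1)
    ok <- which(cov >= confidence)
    if (length(ok)) {
      # balance the two tail probabilities P(K < l) and P(K >= u)
      bal <- abs(cdf[l[ok]] - (1 - cdf[u[ok]]))
      best <- ok[order(bal, l[ok])][1L]
      return(list(l = l[best], u = u[best], coverage = cov[best],
                  attainable = TRUE))
    }
  }
  list(l = NA_integer_, u = NA_integer_, coverage = NA_real_,
       attainable = FALSE)
}

#' Nonparametric reference interval with 90% confidence limits
#'
#' Estimates the reference interval of an outlier-screened sample: the
#' lower and upper reference limits at the plotting-position ranks from
#' [reference_limit_ranks()] (linearly interpolated, or rounded to the
#' nearest integer rank with `interpolate = FALSE`), together with the mean
#' and median. Each limit carries a confidence interval: the distribution-
#' free order-statistic CI from [rank_ci_for_percentile()] when attainable
#' at this sample size, otherwise a seeded percentile bootstrap of the limit
#' estimator.
#'
#' @param values numeric vector (NAs dropped), `n >= 2`.
#' @param confidence CI confidence level (default 0.90).
#' @param p_low,p_high limit probabilities.
#' @param ci_method `"auto"` (rank-binomial with bootstrap fallback),
#'   `"rank-binomial"`, or `"bootstrap"`.
#' @param boot_n bootstrap resamples.
#' @param interpolate interpolate fractional ranks (default) or round them.
#' @param analyte,partition optional labels carried into the result.
#' @return An object of class `reference_interval` with fields `analyte`,
#'   `partition`, `n`, `mean`, `median`, `lower_limit`, `upper_limit`,
#'   `lower_ci`, `upper_ci`, `ci_method` (`"rank-binomial"`, `"bootstrap"`
#'   or `"unavailable"`), `confidence`.
#' @examples
#' ri <- nonparametric_ri(1:119)
#' c(ri$lower_limit, ri$upper_limit)
#' @export
nonparametric_ri <- function(values, confidence = 0.90,
                             p_low = 0.025, p_high = 0.975,
                             ci_method = c("auto", "rank-binomial",
                                           "bootstrap"),
                             boot_n = 2000, interpolate = TRUE,
                             analyte = NA_character_,
                             partition = NA_character_) {
  ci_method <- match.arg(ci_method)
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values for an interval")
  n <- length(values)
  sorted <- sort(values)

  rk <- reference_limit_ranks(n, p_low, p_high)
  pick <- function(r) {
    if (!interpolate) r <- min(max(round(r), 1), n)
    value_at_rank(sorted, r)
  }
  lower <- pick(rk$rank_low)
  upper <- pick(rk$rank_high)

  boot_ci <- function(p, rank_field) {
    est <- vapply(seq_len(boot_n), function(i) {
      bs <- sort(sample(values, n, replace = TRUE))
      r <- reference_limit_ranks(n, p_low, p_high)[[rank_field]]
      if (!interpolate) r <- min(max(round(r), 1), n)
      value_at_rank(bs, r)
    }, numeric(1))
    unname(stats::quantile(est, c((1 - confidence) / 2,
                                  1 - (1 - confidence) / 2)))
  }

  method <- ci_method
  if (ci_method %in% c("auto", "rank-binomial")) {
    lo_pair <- rank_ci_for_percentile(n, p_low, confidence)
    hi_pair <- rank_ci_for_percentile(n, p_high, confidence)
    if (lo_pair$attainable && hi_pair$attainable) {
      lower_ci <- c(sorted[lo_pair$l], sorted[lo_pair$u])
      upper_ci <- c(sorted[hi_pair$l], sorted[hi_pair$u])
      method <- "rank-binomial"
    } else if (ci_method == "auto") {
      lower_ci <- boot_ci(p_low, "rank_low")
      upper_ci <- boot_ci(p_high, "rank_high")
      method <- "bootstrap"
    } else {
      lower_ci <- c(NA_real_, NA_real_)
      upper_ci <- c(NA_real_, NA_real_)
      method <- "unavailable"
    }
  } else {
    lower_ci <- boot_ci(p_low, "rank_low")
    upper_ci <- boot_ci(p_high, "rank_high")
  }

  structure(list(analyte = analyte, partition = partition, n = n,
                 mean = mean(values), median = stats::median(values),
                 lower_limit = lower, upper_limit = upper,
                 lower_ci = lower_ci, upper_ci = upper_ci,
                 ci_method = method, confidence = confidence,
                 p_low = p_low, p_high = p_high),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$analyte, x$partition)), collapse = " / ")
  if (nzchar(lab)) lab <- paste0(lab, ": ")
  cat("<reference_interval> ", lab, "n = ", x$n, "\n", sep = "")
  cat(sprintf("  limits %.4g - %.4g (mean %.4g, median %.4g)\n",
              x$lower_limit, x$upper_limit, x$mean, x$median))
  cat(sprintf("  %d%% CI lower [%.4g, %.4g], upper [%.4g, %.4g] (%s)\n",
              round(100 * x$confidence), x$lower_ci[1], x$lower_ci[2],
              x$upper_ci[1], x$upper_ci[2], x$ci_method))
  invisible(x)
}

#' Reference-interval table per analyte and partition
#'
#' Builds the standard report table (N, mean, median, limits, CIs) from
#' screened per-partition samples, rounded to each analyte's reporting
#' precision plus one guard digit.
#'
#' @param screened output of [screen_cohort()], or a compatible nested list
#'   `values[[partition]][[analyte]]`.
#' @param specs calibration/precision table as from [study_analyte_specs()].
#' @param partitions partitions to include, in order.
#' @param ... passed to [nonparametric_ri()].
#' @return A data.frame with one row per analyte and partition.
#' @export
ri_table <- function(screened, specs = study_analyte_specs(),
                     partitions = NULL, ...) {
  values <- if (!is.null(screened$values)) screened$values else screened
  if (is.null(partitions)) partitions <- names(values)
  rows <- list()
  for (p in partitions) {
    for (a in names(values[[p]])) {
      v <- values[[p]][[a]]
      dec <- specs$decimals[specs$analyte == a][1] %||% 2
      if (length(v) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = a, partition = p, n = length(v), mean = NA, median = NA,
          lower_limit = NA, upper_limit = NA, lower_ci_lo = NA,
          lower_ci_hi = NA, upper_ci_lo = NA, upper_ci_hi = NA,
          ci_method = "unavailable", stringsAsFactors = FALSE)
        next
      }
      ri <- nonparametric_ri(v, analyte = a, partition = p, ...)
      rnd <- function(x) round(x, dec + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, partition = p, n = ri$n, mean = rnd(ri$mean),
        median = rnd(ri$median), lower_limit = rnd(ri$lower_limit),
        upper_limit = rnd(ri$upper_limit),
        lower_ci_lo = rnd(ri$lower_ci[1]), lower_ci_hi = rnd(ri$lower_ci[2]),
        upper_ci_lo = rnd(ri$upper_ci[1]), upper_ci_hi = rnd(ri$upper_ci[2]),
        ci_method = ri$ci_method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
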