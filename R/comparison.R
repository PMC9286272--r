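comparison_result <- function(label, test, statistic, p_value, alpha,
                              analyte = NA_character_, available = TRUE) {
  structure(list(analyte = analyte, label = label, test = test,
                 statistic = unname(statistic), p_value = unname(p_value),
                 significant = isTRUE(p_value < alpha), alpha = alpha,
                 available = available),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "-", x$label, "\n")
  if (!x$available) {
    cat("  unavailable (degenerate input)\n")
  } else {
    cat(sprintf("  statistic = %.4g, p = %s%s\n", x$statistic,
                format_pvalue(x$p_value),
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' Compares the empirical CDF with a normal CDF whose mean and SD are
#' estimated from the same data. With estimated parameters the asymptotic
#' p-value is conservative (too large); `corrected = TRUE` switches to the
#' Lilliefors small-sample correction. A zero-variance sample is reported as
#' non-normal with the statistic-1 convention.
#'
#' @param values numeric vector, `n >= 5`.
#' @param corrected use the Lilliefors-corrected p-value.
#' @param alpha significance level.
#' @return A `comparison_result` with the KS statistic (in `[0, 1]`) and
#'   p-value.
#' @export
ks_normality <- function(values, corrected = FALSE, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("need at least 5 values for the KS check")
  if (stats::sd(values) == 0) {
    return(comparison_result("normality", "KS-normality", 1, 0, alpha))
  }
  if (corrected) {
    t <- nortest::lillie.test(values)
  } else {
    t <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  }
  comparison_result("normality", "KS-normality", t$statistic, t$p.value,
                    alpha)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups with midranks for ties. The two-sided
#' p-value is exact when the combined sample size is at most 14 and there
#' are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance and (by default) continuity correction. When
#' every value in both groups is identical, `U = n_x * n_y / 2` and `p = 1`.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact force exact/approximate; default chooses as above.
#' @param correct continuity correction for the normal approximation.
#' @param alpha significance level.
#' @param label comparison label carried into the result.
#' @return A `comparison_result` with the U statistic (rank-sum of `x`
#'   above `y`) and two-sided p-value.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL, correct = TRUE, alpha = 0.05,
                           label = "x vs y") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(comparison_result(label, "Mann-Whitney U",
                             length(x) * length(y) / 2, 1, alpha))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 14) && !ties
  t <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = correct))
  comparison_result(label, "Mann-Whitney U", t$statistic, t$p.value, alpha)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and p-value from the chi-square
#' approximation on `k - 1` degrees of freedom. When the pooled sample is
#' constant there is no rank separation: `H = 0`, `p = 1`.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @param alpha significance level.
#' @param label comparison label.
#' @return A `comparison_result` with the H statistic and p-value.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, label = "k groups") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(!lengths(groups))) {
    stop("need at least 2 non-empty groups")
  }
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    return(comparison_result(label, "Kruskal-Wallis", 0, 1, alpha))
  }
  t <- stats::kruskal.test(groups)
  comparison_result(label, "Kruskal-Wallis", t$statistic, t$p.value, alpha)
}

#' Partition comparison table
#'
#' For every analyte: pooled pregnant versus non-pregnant (Mann-Whitney),
#' the three trimester pairs (Mann-Whitney), and the three-way trimester
#' comparison (Kruskal-Wallis). Pairwise p-values are reported without
#' multiplicity adjustment by default, with an optional Bonferroni
#' correction over the trimester pairs. Comparisons whose partitions are
#' empty for an analyte are reported as `NA` rather than failing.
#'
#' @param values nested list `values[[partition]][[analyte]]` of (screened)
#'   samples, e.g. from [screen_cohort()].
#' @param trimesters the pregnant partition labels, in order.
#' @param np_label the non-pregnant partition label.
#' @param alpha significance level.
#' @param bonferroni apply Bonferroni correction to the trimester pairs.
#' @return A data.frame with one row per analyte and the p-value columns
#'   `p_preg_vs_np`, `p_t1_vs_t2`, `p_t1_vs_t3`, `p_t2_vs_t3`,
#'   `p_trimesters`.
#' @export
comparison_table <- function(values, trimesters = c("T1", "T2", "T3"),
                             np_label = "NP", alpha = 0.05,
                             bonferroni = FALSE) {
  if (!is.null(values$values)) values <- values$values
  analytes <- unique(unlist(lapply(values, names)))
  get <- function(p, a) values[[p]][[a]] %||% numeric(0)
  safe_p <- function(x, y, label) {
    if (!length(x) || !length(y)) return(NA_real_)
    mann_whitney_u(x, y, alpha = alpha, label = label)$p_value
  }
  rows <- lapply(analytes, function(a) {
    preg <- unlist(lapply(trimesters, get, a = a))
    np <- get(np_label, a)
    t <- lapply(trimesters, get, a = a)
    pair <- c(safe_p(t[[1]], t[[2]], "1st vs 2nd"),
              safe_p(t[[1]], t[[3]], "1st vs 3rd"),
              safe_p(t[[2]], t[[3]], "2nd vs 3rd"))
    if (bonferroni) pair <- pmin(1, pair * 3)
    kw <- if (all(lengths(t) > 0)) {
      kruskal_wallis(t, alpha = alpha, label = "trimesters")$p_value
    } else NA_real_
    data.frame(analyte = a,
               p_preg_vs_np = safe_p(preg, np, "pregnant vs non-pregnant"),
               p_t1_vs_t2 = pair[1], p_t1_vs_t3 = pair[2],
               p_t2_vs_t3 = pair[3], p_trimesters = kw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
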