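#' Calibrate a continuous distribution to a quantile triple
#'
#' Solves for a distribution whose 2.5th percentile, median and 97.5th
#' percentile (or any other probability triple) match three given targets.
#' When the targets are symmetric about the median a normal distribution is
#' used; otherwise a three-parameter shifted log-normal family is fitted,
#' reflected when the targets are left-skewed. Published reference intervals
#' are often asymmetric about the median (e.g. leukocyte counts), which a
#' two-parameter normal cannot reproduce; the shifted log-normal matches any
#' strictly monotone triple in closed form.
#'
#' For right-skewed targets the model is `X = shift + exp(mu + sigma * Z)`
#' with `Z` standard normal. Writing `a = q_med - q_low`, `b = q_high - q_med`
#' and `z` for the normal quantile of `p_high`, the quantile equations give
#' `sigma = log(b / a) / z`, `exp(mu) = a / (1 - exp(-sigma * z))` and
#' `shift = q_med - exp(mu)`, so the three anchor quantiles are matched
#' exactly (residuals at machine precision).
#'
#' @param q_low target lower quantile (probability `p_low`).
#' @param q_med target median.
#' @param q_high target upper quantile (probability `p_high`).
#' @param p_low,p_high anchor probabilities, defaults 0.025 and 0.975. Must be
#'   symmetric (`p_low = 1 - p_high`).
#' @param symmetric_tol relative tolerance on `|b - a| / (b + a)` below which
#'   the symmetric normal family is used.
#'
#' @return An object of class `analyte_dist`: a list with elements `family`
#'   (`"normal"`, `"shifted_lognormal"` or `"reflected_shifted_lognormal"`),
#'   the family parameters, and the anchor targets. Use [q_analyte_dist()]
#'   and [r_analyte_dist()] to evaluate quantiles and draw samples.
#' @examples
#' d <- calibrate_distribution(4.0, 8.1, 13.2)
#' q_analyte_dist(d, c(0.025, 0.5, 0.975))
#' @export
calibrate_distribution <- function(q_low, q_med, q_high,
                                   p_low = 0.025, p_high = 0.975,
                                   symmetric_tol = 1e-8) {
  stopifnot(is.numeric(q_low), is.numeric(q_med), is.numeric(q_high),
            length(q_low) == 1L, length(q_med) == 1L, length(q_high) == 1L,
            is.finite(q_low), is.finite(q_med), is.finite(q_high))
  if (!(q_low < q_med && q_med < q_high)) {
    stop("calibration targets must satisfy q_low < q_med < q_high (got ",
         q_low, ", ", q_med, ", ", q_high, ")")
  }
  if (abs(p_low - (1 - p_high)) > 1e-12 || p_low <= 0 || p_high >= 1) {
    stop("anchor probabilities must satisfy 0 < p_low = 1 - p_high < 0.5")
  }
  z <- stats::qnorm(p_high)
  a <- q_med - q_low
  b <- q_high - q_med

  if (abs(b - a) / (b + a) < symmetric_tol) {
    out <- list(family = "normal", mean = q_med, sd = a / z)
  } else if (b > a) {
    sigma <- log(b / a) / z
    scale <- a / (1 - exp(-sigma * z))   # exp(mu)
    out <- list(family = "shifted_lognormal",
                shift = q_med - scale, mu = log(scale), sigma = sigma)
  } else {
    # left skew: calibrate the reflection -X to (-q_high, -q_med, -q_low)
    sigma <- log(a / b) / z
    scale <- b / (1 - exp(-sigma * z))
    out <- list(family = "reflected_shifted_lognormal",
                shift = -q_med - scale, mu = log(scale), sigma = sigma)
  }
  out$targets <- c(q_low = q_low, q_med = q_med, q_high = q_high)
  out$p <- c(p_low = p_low, p_high = p_high)
  class(out) <- "analyte_dist"

  resid <- max(abs(q_analyte_dist(out, c(p_low, 0.5, p_high)) -
                     c(q_low, q_med, q_high)))
  if (!is.finite(resid) || resid > 1e-6 * max(1, abs(q_high - q_low))) {
    stop("calibration failed: anchor-quantile residual ", format(resid),
         " for targets (", q_low, ", ", q_med, ", ", q_high, ")")
  }
  out
}

#' Quantile function of a calibrated distribution
#'
#' @param dist an `analyte_dist` from [calibrate_distribution()].
#' @param p vector of probabilities.
#' @return Numeric vector of quantiles.
#' @export
q_analyte_dist <- function(dist, p) {
  stopifnot(inherits(dist, "analyte_dist"), all(p >= 0 & p <= 1))
  switch(dist$family,
    normal = stats::qnorm(p, dist$mean, dist$sd),
    shifted_lognormal = dist$shift + stats::qlnorm(p, dist$mu, dist$sigma),
    reflected_shifted_lognormal =
      -(dist$shift + stats::qlnorm(1 - p, dist$mu, dist$sigma)),
    stop("unknown family: ", dist$family)
  )
}

#' Draw random values from a calibrated distribution
#'
#' @param dist an `analyte_dist` from [calibrate_distribution()].
#' @param n number of draws.
#' @return Numeric vector of length `n`. Uses the session RNG stream.
#' @export
r_analyte_dist <- function(dist, n) {
  stopifnot(inherits(dist, "analyte_dist"), n >= 0)
  switch(dist$family,
    normal = stats::rnorm(n, dist$mean, dist$sd),
    shifted_lognormal = dist$shift + stats::rlnorm(n, dist$mu, dist$sigma),
    reflected_shifted_lognormal =
      -(dist$shift + stats::rlnorm(n, dist$mu, dist$sigma)),
    stop("unknown family: ", dist$family)
  )
}

#' @export
print.analyte_dist <- function(x, ...) {
  cat("<analyte_dist>", x$family, "\n")
  pars <- x[setdiff(names(x), c("family", "targets", "p"))]
  cat(paste(names(pars), signif(unlist(pars), 6), sep = " = ",
            collapse = ", "), "\n")
  cat("anchors:", paste(signif(x$targets, 6), collapse = " / "),
      "at p =", paste(x$p, collapse = ", "), "\n")
  invisible(x)
}
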