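#' Dixon/Reed one-third-range outlier screen
#'
#' Screens a sample for extreme values before reference-limit estimation.
#' At each pass the data are sorted and, for each tail, `D` is the gap
#' between the extreme value and its nearest distinct neighbour and `R` is
#' the full range; the extreme is rejected when `D/R > 1/3`. Values tied
#' with a flagged extreme are removed with it, since the rule cannot
#' distinguish them. By default the rule is re-applied to the reduced sample
#' until no value is removed (capped at `max_passes`); single-pass screening
#' is available via `iterate = FALSE`. Because `D/R` is location- and
#' scale-free, the screen is invariant under affine transforms of the data.
#'
#' Samples smaller than `min_n` are returned unscreened with `skipped = TRUE`:
#' on tiny samples the one-third rule degenerates (it would flag an extreme
#' of almost any 3-point sample), and reference cohorts are far larger.
#' A constant sample has `R = 0`; the ratio is taken as 0 and nothing is
#' removed.
#'
#' @param values numeric vector of finite values.
#' @param iterate re-apply until fixpoint (default) or single pass.
#' @param min_n smallest sample the rule is applied to.
#' @param max_passes iteration cap.
#' @return An object of class `outlier_screen`: `retained` (input order
#'   preserved), `removed` (data.frame with `value`, `pass`, `tail`, `D`,
#'   `R`, `ratio`), `n_input`, `n_passes`, `skipped`.
#' @examples
#' dixon_reed_screen(c(10, 11, 12, 13, 30), min_n = 1)
#' @export
dixon_reed_screen <- function(values, iterate = TRUE, min_n = 20,
                              max_passes = 10) {
  if (length(values) == 0L) stop("cannot screen an empty vector")
  stopifnot(is.numeric(values), all(is.finite(values)), min_n >= 1,
            max_passes >= 1)

  empty_log <- data.frame(value = numeric(0), pass = integer(0),
                          tail = character(0), D = numeric(0),
                          R = numeric(0), ratio = numeric(0),
                          stringsAsFactors = FALSE)
  if (length(values) < min_n) {
    return(structure(list(retained = values, removed = empty_log,
                          n_input = length(values), n_passes = 0L,
                          skipped = TRUE), class = "outlier_screen"))
  }

  keep <- rep(TRUE, length(values))
  log <- empty_log
  pass <- 0L
  repeat {
    pass <- pass + 1L
    x <- values[keep]
    r <- max(x) - min(x)
    removed_this_pass <- FALSE
    if (r > 0 && length(x) >= 3L) {
      for (tail in c("lower", "upper")) {
        extreme <- if (tail == "lower") min(x) else max(x)
        neighbour <- if (tail == "lower") min(x[x > extreme]) else
          max(x[x < extreme])
        d <- abs(extreme - neighbour)
        if (d / r > 1 / 3) {
          hit <- keep & values == extreme
          keep[hit] <- FALSE
          log <- rbind(log, data.frame(
            value = rep(extreme, sum(hit)), pass = pass, tail = tail,
            D = d, R = r, ratio = d / r, stringsAsFactors = FALSE))
          removed_this_pass <- TRUE
        }
      }
    }
    if (!iterate || !removed_this_pass || pass >= max_passes ||
        sum(keep) < 3L) break
  }
  structure(list(retained = values[keep], removed = log,
                 n_input = length(values), n_passes = pass,
                 skipped = FALSE), class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat("<outlier_screen> n =", x$n_input, "retained =", length(x$retained),
      "removed =", nrow(x$removed), "passes =", x$n_passes,
      if (x$skipped) "(skipped: below min_n)" else "", "\n")
  if (nrow(x$removed)) print(x$removed, row.names = FALSE)
  invisible(x)
}

#' Screen every analyte within every partition of a cohort
#'
#' Screening is independent per analyte and partition, so the retained
#' sample size varies across analytes, as it does in practice.
#'
#' @param data participant data.frame (typically the eligible subset).
#' @param analytes analyte column names; defaults to the shipped panel
#'   columns present in `data`.
#' @param partition_col name of the partition column.
#' @param ... passed to [dixon_reed_screen()].
#' @return List with `values` (`values[[partition]][[analyte]]`, retained
#'   numeric vectors) and `log` (removal log with `partition`, `analyte`,
#'   `value`, `pass`, `tail`, `D`, `R`, `ratio`).
#' @export
screen_cohort <- function(data, analytes = NULL, partition_col = "partition",
                          ...) {
  if (is.null(analytes)) {
    analytes <- intersect(unique(study_analyte_specs()$analyte), names(data))
  }
  stopifnot(all(analytes %in% names(data)), partition_col %in% names(data))
  parts <- unique(data[[partition_col]])
  values <- list()
  logs <- list()
  for (p in parts) {
    values[[p]] <- list()
    for (a in analytes) {
      v <- data[[a]][data[[partition_col]] == p]
      v <- v[!is.na(v)]
      scr <- dixon_reed_screen(v, ...)
      values[[p]][[a]] <- scr$retained
      if (nrow(scr$removed)) {
        logs[[length(logs) + 1L]] <- cbind(
          data.frame(partition = p, analyte = a, stringsAsFactors = FALSE),
          scr$removed)
      }
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(partition = character(0), analyte = character(0),
               value = numeric(0), pass = integer(0), tail = character(0),
               D = numeric(0), R = numeric(0), ratio = numeric(0),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(values = values, log = log)
}
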