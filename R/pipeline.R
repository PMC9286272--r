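#' Analysis configuration
#'
#' Collects every tunable of the pipeline with validated defaults. Unknown
#' settings are rejected rather than silently ignored.
#'
#' @param screening a [screening_rules()] object.
#' @param outlier list: `iterate`, `min_n`, `max_passes` (see
#'   [dixon_reed_screen()]).
#' @param ri list: `p_low`, `p_high`, `confidence`, `ci_method`, `boot_n`,
#'   `interpolate` (see [nonparametric_ri()]).
#' @param comparison list: `alpha`, `bonferroni`, `ks_corrected`.
#' @param oor list: `denominator_mode` (see [oor_table()]).
#' @param seed integer seed covering every stochastic step (bootstrap CIs).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(screening = screening_rules(),
                            outlier = list(), ri = list(),
                            comparison = list(), oor = list(), seed = 1L) {
  merge_known <- function(defaults, given, what) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      stop("unknown ", what, " setting(s): ", paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, given)
  }
  if (!inherits(screening, "screening_rules")) {
    screening <- do.call(screening_rules, screening)
  }
  cfg <- list(
    screening = screening,
    outlier = merge_known(list(iterate = TRUE, min_n = 20, max_passes = 10),
                          outlier, "outlier"),
    ri = merge_known(list(p_low = 0.025, p_high = 0.975, confidence = 0.90,
                          ci_method = "auto", boot_n = 2000,
                          interpolate = TRUE), ri, "ri"),
    comparison = merge_known(list(alpha = 0.05, bonferroni = FALSE,
                                  ks_corrected = FALSE),
                             comparison, "comparison"),
    oor = merge_known(list(denominator_mode = "enrolled"), oor, "oor"),
    seed = as.integer(seed))
  stopifnot(cfg$ri$p_low > 0, cfg$ri$p_low < cfg$ri$p_high,
            cfg$ri$p_high < 1, cfg$ri$confidence > 0,
            cfg$ri$confidence < 1, cfg$comparison$alpha > 0,
            cfg$comparison$alpha < 1)
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' @param path file whose extension selects the parser (`.yml`/`.yaml` or
#'   `.json`). Top-level keys mirror the arguments of [analysis_config()].
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path)
  }
  known <- c("screening", "outlier", "ri", "comparison", "oor", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a participant table from CSV
#'
#' Validates the screening schema (errors name any missing column and the
#' rows carrying missing screening values) and checks that every analyte in
#' `specs` has a column. Unknown extra columns are kept with a warning.
#'
#' @param path CSV written by [write_cohort()] or matching its schema.
#' @param specs analyte table defining the expected analyte columns.
#' @return The participant data.frame.
#' @export
read_cohort <- function(path, specs = study_analyte_specs()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- cohort_schema(analytes = unique(specs$analyte))
  missing <- setdiff(schema$analytes, names(df))
  if (length(missing)) {
    stop("cohort is missing analyte column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), unlist(schema))
  if (length(extra)) {
    warning("ignoring unknown cohort column(s): ",
            paste(extra, collapse = ", "))
  }
  validate_cohort(df)
  df
}

#' Write a participant table to CSV
#'
#' @param cohort participant data.frame.
#' @param path output file; `read_cohort()` round-trips it.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reference-interval pipeline
#'
#' Executes the whole analysis on a participant table: eligibility
#' screening with flow report, per-partition and pooled-group Dixon/Reed
#' outlier screening, nonparametric reference intervals with confidence
#' limits, normality checks and partition comparisons, and out-of-range
#' scoring of the pregnant group against the manufacturer intervals. The
#' run is deterministic given `config$seed`.
#'
#' @param cohort participant data.frame or path to a cohort CSV.
#' @param config an [analysis_config()].
#' @param specs analyte calibration/precision table.
#' @param manufacturer manufacturer interval table (see
#'   [manufacturer_intervals()]).
#' @param trimesters,np_label partition labels.
#' @return An object of class `ri_report`: `flow`, `outlier_log`,
#'   `ri_partitions` (per trimester and non-pregnant), `ri_groups` (pooled
#'   pregnant and non-pregnant), `normality`, `comparisons`, `oor`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         specs = study_analyte_specs(),
                         manufacturer = manufacturer_intervals(),
                         trimesters = c("T1", "T2", "T3"),
                         np_label = "NP") {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort, specs)
  analytes <- intersect(unique(specs$analyte), names(cohort))
  manufacturer <- manufacturer[manufacturer$analyte %in% analytes, ,
                               drop = FALSE]

  with_seed(config$seed, {
    flow <- stage("screening", summarize_flow(cohort, config$screening))
    eligible <- cohort[flow$is_eligible, , drop = FALSE]

    screened <- stage("outlier_screen", {
      per_part <- screen_cohort(eligible, analytes,
                                iterate = config$outlier$iterate,
                                min_n = config$outlier$min_n,
                                max_passes = config$outlier$max_passes)
      pooled_df <- eligible
      pooled_df$partition <- ifelse(pooled_df$partition %in% trimesters,
                                    "Pregnant", "NonPregnant")
      pooled <- screen_cohort(pooled_df, analytes,
                              iterate = config$outlier$iterate,
                              min_n = config$outlier$min_n,
                              max_passes = config$outlier$max_passes)
      list(per_part = per_part, pooled = pooled)
    })

    ri_args <- list(p_low = config$ri$p_low, p_high = config$ri$p_high,
                    confidence = config$ri$confidence,
                    ci_method = config$ri$ci_method,
                    boot_n = config$ri$boot_n,
                    interpolate = config$ri$interpolate)
    ri_partitions <- stage("ri_estimation", do.call(ri_table, c(
      list(screened$per_part, specs = specs,
           partitions = c(trimesters, np_label)), ri_args)))
    ri_groups <- stage("ri_estimation", do.call(ri_table, c(
      list(screened$pooled, specs = specs,
           partitions = c("Pregnant", "NonPregnant")), ri_args)))

    normality <- stage("comparisons", {
      rows <- lapply(analytes, function(a) {
        ks <- ks_normality(screened$pooled$values[["Pregnant"]][[a]],
                           corrected = config$comparison$ks_corrected,
                           alpha = config$comparison$alpha)
        data.frame(analyte = a, group = "Pregnant",
                   ks_statistic = ks$statistic, p_value = ks$p_value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    comparisons <- stage("comparisons", {
      values <- screened$per_part$values
      values$Pregnant <- screened$pooled$values$Pregnant
      comparison_table(values, trimesters = trimesters,
                       np_label = np_label,
                       alpha = config$comparison$alpha,
                       bonferroni = config$comparison$bonferroni)
    })

    oor <- stage("oor", {
      pregnant_all <- cohort[cohort$partition %in% trimesters, , drop = FALSE]
      est <- ri_groups[ri_groups$partition == "Pregnant",
                       c("analyte", "lower_limit", "upper_limit")]
      names(est) <- c("analyte", "est_low", "est_high")
      oor_table(pregnant_all, manufacturer = manufacturer,
                established = est,
                denominator_mode = config$oor$denominator_mode)
    })

    manifest <- list(
      package = "hemaRI",
      version = as.character(utils::packageVersion("hemaRI")),
      seed = config$seed,
      config_hash = config_hash(config),
      counts = list(enrolled = flow$enrolled, eligible = flow$eligible,
                    outliers_removed = nrow(screened$per_part$log)))

    structure(list(flow = flow,
                   outlier_log = screened$per_part$log,
                   ri_partitions = ri_partitions,
                   ri_groups = ri_groups,
                   normality = normality,
                   comparisons = comparisons,
                   oor = oor,
                   manifest = manifest), class = "ri_report")
  })
}

#' @export
print.ri_report <- function(x, ...) {
  cat("<ri_report> seed", x$manifest$seed, "\n")
  print(x$flow)
  cat("  reference intervals:", nrow(x$ri_partitions), "partition rows,",
      nrow(x$ri_groups), "group rows;", x$manifest$counts$outliers_removed,
      "outliers removed\n")
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits `flow.csv`, `ri_partitions.csv`, `ri_groups.csv`,
#' `normality.csv`, `comparisons.csv`, `oor.csv`, `outlier_log.csv` and
#' `manifest.json` into `dir`. The files are byte-identical across reruns
#' with the same cohort and seed. On any failure every partial output is
#' removed.
#'
#' @param report an `ri_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_tables <- function(report, dir) {
  stopifnot(inherits(report, "ri_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    flow <- report$flow
    emit(data.frame(partition = names(flow$excluded_by_partition),
                    excluded = as.integer(flow$excluded_by_partition),
                    enrolled = flow$enrolled,
                    eligible = flow$eligible,
                    eligible_percent = flow$eligible_percent),
         "flow.csv")
    emit(report$ri_partitions, "ri_partitions.csv")
    emit(report$ri_groups, "ri_groups.csv")
    emit(report$normality, "normality.csv")
    cmp <- report$comparisons
    for (col in grep("^p_", names(cmp), value = TRUE)) {
      cmp[[paste0(col, "_display")]] <- format_pvalue(cmp[[col]])
    }
    emit(cmp, "comparisons.csv")
    emit(report$oor, "oor.csv")
    emit(report$outlier_log, "outlier_log.csv")
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)
    invisible(written)
  }, error = function(e) {
    unlink(written)
    stop("writing report failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
}
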