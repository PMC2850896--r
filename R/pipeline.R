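# Study-replica pipeline: cohort in (simulated or CSV), 4C composition per
# phase, change scores, cross-sectional and change-tracking agreement,
# covariate scan, report bundle out.

#' Analysis configuration
#'
#' @param records a measurement-record data.frame (takes precedence).
#' @param input path to a cohort CSV (used when `records` is NULL).
#' @param cohort a [cohort_config()]; simulated when neither `records` nor
#'   `input` is given.
#' @param precision_threshold %FM half-width of the DXA precision band;
#'   `NULL` (default) disables the filter, `2.9` reproduces the published
#'   sensitivity reanalysis. Subjects whose DXA %FM change lies strictly
#'   inside `(-threshold, threshold)` are excluded (boundary retained).
#' @param alpha significance level for all tests.
#' @param loa_multiplier limits-of-agreement multiplier (1.96 = 95%).
#' @param normality_alpha Shapiro-Wilk gate level for paired tests.
#' @param reference_fractions named list of reference-population constants
#'   for the one-sample tests (defaults are the classical reference-body
#'   values; they are configurable inputs, not assertions about any
#'   particular study population). Set to `NULL` to skip.
#' @param holm apply a Holm adjustment across the exploratory covariate
#'   scan (default FALSE, matching the unadjusted published analysis).
#' @param densities a [component_densities()] object.
#' @param out_dir if non-NULL, [write_study_report()] is called on the
#'   result.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(records = NULL, input = NULL,
                            cohort = cohort_config(),
                            precision_threshold = NULL,
                            alpha = 0.05, loa_multiplier = 1.96,
                            normality_alpha = 0.05,
                            reference_fractions = list(
                              tbw_ffm = 0.7382, m_ffm = 0.0682,
                              protein_ffm = 0.1936, ffm_d = 1.1),
                            holm = FALSE,
                            densities = component_densities(),
                            out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) .stop("`alpha` must lie in (0, 1)")
  if (!is.null(precision_threshold))
    .check_num(precision_threshold, "precision_threshold", non_negative = TRUE)
  structure(as.list(environment()), class = "analysis_config")
}

#' Per-subject change scores from a composed cohort
#'
#' Pairs each subject's two phases and computes pre-competition minus
#' stability deltas for every variable of interest, for both methods.
#' Subjects missing a phase are dropped with a warning.
#'
#' @param comp output of [compose_cohort()] (DXA columns required).
#' @return data.frame, one row per complete subject, with columns
#'   `d_pfm_4c`, `d_fm_4c`, `d_ffm_4c`, `d_pfm_dxa`, `d_fm_dxa`,
#'   `d_ffm_dxa`, `d_bw`, `d_ffm_d`, `d_tbw_ffm`, `d_m_ffm`,
#'   `d_protein_ffm` and, when regional columns exist, `d_<region>_fm` /
#'   `d_<region>_lst`.
#' @export
change_records <- function(comp) {
  if (!all(.dxa_cols %in% names(comp)))
    .stop("change records need DXA columns (%s)", paste(.dxa_cols, collapse = ", "))
  s <- comp[comp$phase == "stability", ]
  p <- comp[comp$phase == "precompetition", ]
  both <- intersect(s$subject_id, p$subject_id)
  dropped <- setdiff(unique(comp$subject_id), both)
  if (length(dropped))
    warning(sprintf("dropping %d subject(s) missing a phase: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  if (length(both) == 0) .stop("no subject has both phases")
  s <- s[match(both, s$subject_id), ]
  p <- p[match(both, p$subject_id), ]
  delta <- function(col) p[[col]] - s[[col]]
  out <- data.frame(
    subject_id = both,
    d_pfm_4c = delta("pfm_4c"), d_fm_4c = delta("fm_4c_kg"),
    d_ffm_4c = delta("ffm_4c_kg"),
    d_pfm_dxa = delta("pfm_dxa"), d_fm_dxa = delta("dxa_fm_kg"),
    d_ffm_dxa = delta("dxa_ffm_kg"),
    d_bw = delta("bw_kg"), d_ffm_d = delta("ffm_d"),
    d_tbw_ffm = delta("tbw_ffm"), d_m_ffm = delta("m_ffm"),
    d_protein_ffm = delta("protein_ffm"))
  for (col in intersect(.regional_cols, names(comp)))
    out[[paste0("d_", sub("_kg$", "", col))]] <- delta(col)
  out
}

#' Precision-band filter on DXA change scores
#'
#' Retains subjects whose DXA %FM change is at or beyond the instrument's
#' precision band, i.e. `|d_pfm_dxa| >= threshold`; values strictly inside
#' the open interval `(-threshold, threshold)` are excluded, so boundary
#' cases are retained.
#'
#' @param changes a [change_records()] table.
#' @param threshold %FM half-width of the band (>= 0).
#' @return The filtered table, with attributes `n_removed` and `threshold`.
#' @export
apply_precision_filter <- function(changes, threshold) {
  .check_num(threshold, "threshold", non_negative = TRUE)
  keep <- abs(changes$d_pfm_dxa) >= threshold
  out <- changes[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "threshold") <- threshold
  out
}

.change_vars <- c(pfm = "%FM", fm = "FM (kg)", ffm = "FFM (kg)")

.change_agreement_set <- function(changes, cfg) {
  if (nrow(changes) < 3) .stop("fewer than 3 subjects available for change analysis")
  lapply(names(.change_vars), function(v) {
    agreement_report(changes[[paste0("d_", v, "_4c")]],
                     changes[[paste0("d_", v, "_dxa")]],
                     variable = paste("change in", .change_vars[[v]]),
                     multiplier = cfg$loa_multiplier,
                     normality_alpha = cfg$normality_alpha)
  })
}

.flatten_reports <- function(reports, phase) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(phase = phase, variable = r$variable, n = r$n,
               slope = r$slope, intercept = r$intercept, r = r$r, see = r$see,
               slope_p_vs_1 = r$slope_p_vs_1,
               intercept_p_vs_0 = r$intercept_p_vs_0,
               r2_percent = r$r2_percent,
               bias = r$bias, sd_diff = r$sd_diff,
               loa_lower = r$loa_lower, loa_upper = r$loa_upper,
               trend_r = r$trend_r, trend_p = r$trend_p,
               mean_comparison_p = r$mean_comparison_p,
               mean_comparison_test = r$mean_comparison_test)))
}

#' Run the complete validation study
#'
#' Orchestrates the full replica: obtain a cohort (supplied, read from CSV,
#' or simulated), compute the 4C composition of every subject-phase, build
#' change scores, and produce (a) a phase/change summary of all body
#' composition variables with one-sample reference tests, (b) DXA
#' cross-sectional performance per phase, (c) change-tracking agreement per
#' variable, (d) a covariate-correlation scan of the method differences,
#' and (e) a run log. Optionally repeats the change analysis after the
#' precision-band exclusion.
#'
#' @param config an [analysis_config()].
#' @return Object of class `study_report`.
#' @examples
#' rep <- run_study(analysis_config(cohort = cohort_config(n_subjects = 12, seed = 3)))
#' rep$change_table
#' @export
run_study <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }

  if (!is.null(config$records)) {
    records <- validate_records(config$records, bw_tol = Inf)
    note("input: supplied records (%d rows)", nrow(records))
  } else if (!is.null(config$input)) {
    records <- read_cohort(config$input)
    note("input: %s (%d rows)", config$input, nrow(records))
  } else {
    records <- generate_cohort(config$cohort)
    note("input: simulated cohort (n = %d, seed = %d)",
         config$cohort$n_subjects, config$cohort$seed)
  }

  comp <- compose_cohort(records, config$densities)
  if (!all(.dxa_cols %in% names(comp)))
    .stop("run_study needs DXA columns to compare methods")
  changes <- change_records(comp)
  if (nrow(changes) < 3) .stop("fewer than 3 subjects with both phases")
  note("subjects with both phases: %d", nrow(changes))

  # (a) summary of all variables, per phase and as changes -------------
  vars <- c(bw = "bw_kg", pfm_4c = "pfm_4c", fm_4c = "fm_4c_kg",
            ffm_4c = "ffm_4c_kg", pfm_dxa = "pfm_dxa", fm_dxa = "dxa_fm_kg",
            ffm_dxa = "dxa_ffm_kg", ffm_d = "ffm_d", tbw_ffm = "tbw_ffm",
            m_ffm = "m_ffm", protein_ffm = "protein_ffm")
  phase_rows <- function(phase) {
    sub <- comp[comp$phase == phase & comp$subject_id %in% changes$subject_id, ]
    data.frame(variable = names(vars), phase = phase,
               mean = vapply(vars, function(c) mean(sub[[c]]), 0),
               sd = vapply(vars, function(c) sd(sub[[c]]), 0))
  }
  dvars <- c(bw = "d_bw", pfm_4c = "d_pfm_4c", fm_4c = "d_fm_4c",
             ffm_4c = "d_ffm_4c", pfm_dxa = "d_pfm_dxa", fm_dxa = "d_fm_dxa",
             ffm_dxa = "d_ffm_dxa", ffm_d = "d_ffm_d", tbw_ffm = "d_tbw_ffm",
             m_ffm = "d_m_ffm", protein_ffm = "d_protein_ffm")
  summary_tab <- rbind(
    phase_rows("stability"), phase_rows("precompetition"),
    data.frame(variable = names(dvars), phase = "change",
               mean = vapply(dvars, function(c) mean(changes[[c]]), 0),
               sd = vapply(dvars, function(c) sd(changes[[c]]), 0)))
  rownames(summary_tab) <- NULL

  # one-sample tests of the FFM composition against reference constants
  reference_tests <- NULL
  if (!is.null(config$reference_fractions)) {
    rows <- list()
    for (v in names(config$reference_fractions)) {
      for (phase in .phases) {
        sub <- comp[comp$phase == phase & comp$subject_id %in% changes$subject_id, ]
        ht <- one_sample_vs_reference(sub[[vars[[v]]]], config$reference_fractions[[v]])
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, phase = phase, mean = ht$mean, ref = ht$ref,
          t = ht$t, p_value = ht$p_value)
      }
    }
    reference_tests <- do.call(rbind, rows)
    note("one-sample reference tests: %d", nrow(reference_tests))
  }

  # (b) cross-sectional performance per phase --------------------------
  cs_reports <- list()
  for (phase in .phases) {
    sub <- comp[comp$phase == phase & comp$subject_id %in% changes$subject_id, ]
    pair <- list(pfm = c("pfm_4c", "pfm_dxa"),
                 fm = c("fm_4c_kg", "dxa_fm_kg"),
                 ffm = c("ffm_4c_kg", "dxa_ffm_kg"))
    cs_reports[[phase]] <- lapply(names(pair), function(v)
      agreement_report(sub[[pair[[v]][1]]], sub[[pair[[v]][2]]],
                       variable = .change_vars[[v]],
                       multiplier = config$loa_multiplier,
                       normality_alpha = config$normality_alpha))
  }
  cross_sectional <- rbind(.flatten_reports(cs_reports$stability, "stability"),
                           .flatten_reports(cs_reports$precompetition,
                                            "precompetition"))

  # (c) change-tracking agreement --------------------------------------
  change_reports <- .change_agreement_set(changes, config)
  for (r in change_reports)
    note("change agreement [%s]: mean comparison via %s", r$variable,
         r$mean_comparison_test)
  change_table <- .flatten_reports(change_reports, "change")

  # (d) covariate scan of the method differences ------------------------
  covs <- c("d_bw", "d_ffm_d", "d_tbw_ffm", "d_m_ffm", "d_protein_ffm",
            grep("^d_(trunk|arms|legs)_", names(changes), value = TRUE))
  scan <- list()
  for (v in names(.change_vars)) {
    diffs <- changes[[paste0("d_", v, "_dxa")]] - changes[[paste0("d_", v, "_4c")]]
    for (cv in covs) {
      ct <- correlate_differences(diffs, changes[[cv]])
      scan[[length(scan) + 1]] <- data.frame(
        variable = paste0("d_", v), covariate = cv, n = ct$n,
        r = ct$r, p_value = ct$p_value, computable = ct$computable)
    }
  }
  covariate_scan <- do.call(rbind, scan)
  if (config$holm)
    covariate_scan$p_holm <- stats::p.adjust(covariate_scan$p_value, "holm")

  # (e) optional precision-band sensitivity reanalysis ------------------
  precision <- NULL
  if (!is.null(config$precision_threshold)) {
    filt <- apply_precision_filter(changes, config$precision_threshold)
    note("precision filter +/- %.1f %%FM: removed %d of %d subjects",
         config$precision_threshold, attr(filt, "n_removed"), nrow(changes))
    reports <- .change_agreement_set(filt, config)
    precision <- list(threshold = config$precision_threshold,
                      n_removed = attr(filt, "n_removed"),
                      n_retained = nrow(filt),
                      change_table = .flatten_reports(reports, "change"),
                      change_reports = reports)
  }

  meta <- attr(records, "meta")
  report <- structure(list(
    n_subjects = nrow(changes),
    summary = summary_tab,
    reference_tests = reference_tests,
    cross_sectional = cross_sectional,
    change_table = change_table,
    change_reports = change_reports,
    covariate_scan = covariate_scan,
    precision = precision,
    changes = changes,
    composition = comp,
    log = log,
    meta = c(list(package_version = as.character(utils::packageVersion("dxa4c")),
                  alpha = config$alpha,
                  loa_multiplier = config$loa_multiplier,
                  difference_direction = "DXA minus 4C",
                  regression_orientation = "criterion (4C) on predictor (DXA)"),
             meta)), class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Write a study report bundle to disk
#'
#' Emits machine-readable CSVs (summary, cross-sectional, change agreement,
#' covariate scan), a JSON bundle of every statistic, a plain-text
#' rendering of the performance tables, and the run log. Output is a pure
#' function of the report (no timestamps), so identical runs produce
#' byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) if (!is.null(df))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wcsv(report$summary, "summary.csv")
  wcsv(report$reference_tests, "reference_tests.csv")
  wcsv(report$cross_sectional, "cross_sectional.csv")
  wcsv(report$change_table, "change_agreement.csv")
  wcsv(report$covariate_scan, "covariate_scan.csv")
  wcsv(report$changes, "change_records.csv")
  if (!is.null(report$precision))
    wcsv(report$precision$change_table, "precision_change_agreement.csv")
  json <- report[c("n_subjects", "summary", "reference_tests",
                   "cross_sectional", "change_table", "covariate_scan",
                   "meta")]
  if (!is.null(report$precision))
    json$precision <- report$precision[c("threshold", "n_removed",
                                         "n_retained", "change_table")]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("4C / DXA validation study report (n = %d subjects)\n", x$n_subjects))
  cat(sprintf("Conventions: differences are %s; regression is %s.\n\n",
              x$meta$difference_direction, x$meta$regression_orientation))
  fmt_tab <- function(tab, title) {
    cat(title, "\n")
    shown <- tab[c("phase", "variable", "slope", "intercept", "r", "see",
                   "bias", "loa_upper", "loa_lower", "trend_r")]
    for (c in c("slope", "intercept", "r", "see", "bias", "loa_upper",
                "loa_lower", "trend_r"))
      shown[[c]] <- round(shown[[c]], 2)
    print(shown, row.names = FALSE)
    cat("\n")
  }
  fmt_tab(x$cross_sectional, "DXA cross-sectional performance (criterion: 4C)")
  fmt_tab(x$change_table, "DXA change-tracking performance (criterion: 4C)")
  if (!is.null(x$precision))
    cat(sprintf("Precision-band reanalysis (+/- %.1f %%FM): %d removed, %d retained.\n",
                x$precision$threshold, x$precision$n_removed,
                x$precision$n_retained))
  cat("Note: trend is the Pearson r of (DXA - 4C) vs the methods' mean.\n")
  invisible(x)
}
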