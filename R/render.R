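# Report rendering: lossless JSON, human-readable text tables in the
# conventional clinical-table layout, and CSV exports (ROC coordinates,
# per-patient scores).

#' Render an analysis report to files
#'
#' @param report An `analysis_report` from [run_pipeline].
#' @param dir Output directory, created if needed.
#' @param format One or more of `"json"`, `"text"`, `"csv"`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("json", "text", "csv")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!all(format %in% c("json", "text", "csv"))) stop("unknown format")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, path)
  }
  if ("text" %in% format) {
    path <- file.path(dir, "report.txt")
    writeLines(render_text(report), path)
    written <- c(written, path)
  }
  if ("csv" %in% format) {
    if (!is.null(report$models)) {
      for (id in names(report$models$rocs)) {
        roc <- report$models$rocs[[id]]
        path <- file.path(dir, paste0("roc_model_", id, ".csv"))
        utils::write.csv(
          data.frame(threshold = roc$thresholds$threshold,
                     sensitivity = roc$thresholds$sensitivity,
                     one_minus_specificity = 1 - roc$thresholds$specificity),
          path, row.names = FALSE)
        written <- c(written, path)
      }
    }
    path <- file.path(dir, "scores.csv")
    write_scores(report$scores, path)
    written <- c(written, path)
  }
  invisible(written)
}

# plain-list view of a report for lossless JSON round-tripping
#' @keywords internal
report_to_list <- function(report) {
  strip <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      lapply(unclass(x), strip)
    } else if (is.matrix(x)) {
      list(rows = rownames(x), cols = colnames(x),
           values = apply(unname(x), 1L, as.vector, simplify = FALSE))
    } else if (is.factor(x)) {
      as.character(x)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)          # keep names in the JSON object
    } else x
  }
  strip(unclass(report))
}

.fmt_table <- function(df) {
  txt <- utils::capture.output(print(df, row.names = FALSE))
  txt
}

#' Render the human-readable text report
#'
#' Section ordering and row ordering follow the conventional presentation:
#' baseline characteristics, per-parameter univariate tests, the
#' inter-parameter correlation matrix, VIFs, the adjusted logistic model
#' (rows: age, sex, care level, score), and the three-model comparison.
#'
#' @param report An `analysis_report`.
#' @return Character vector of lines.
#' @export
render_text <- function(report) {
  out <- c("CoRAS validation report",
           paste0("config hash: ", report$provenance$config_hash,
                  " | seed: ", report$provenance$seed %||% "NA",
                  " | n: ", report$provenance$n),
           "")
  if (!is.null(report$baseline)) {
    b <- report$baseline
    out <- c(out, "== Baseline ==",
             sprintf("pneumonia: %d / %d (%.1f%%)", b$n_pneumonia, b$n,
                     100 * b$prevalence),
             sprintf("sex: chi2 = %.3f, p = %s", b$sex$statistic,
                     format_pvalue(b$sex$p)),
             sprintf("age: median without %.1f vs with %.1f, U = %.1f, p = %s",
                     b$age_median["without"], b$age_median["with"],
                     b$age$U, format_pvalue(b$age$p)),
             sprintf("care level: chi2 = %.3f, p = %s", b$care$statistic,
                     format_pvalue(b$care$p)),
             sprintf("risk category: chi2 = %.3f, p = %s", b$risk$statistic,
                     format_pvalue(b$risk$p)),
             sprintf("incidence: low %.1f%%, moderate %.1f%%, high %.1f%%",
                     100 * b$risk_incidence[1], 100 * b$risk_incidence[2],
                     100 * b$risk_incidence[3]),
             "")
  }
  if (!is.null(report$screening)) {
    s <- report$screening
    out <- c(out, "== Low-risk screening (printed convention: condition = no pneumonia) ==",
             sprintf("sensitivity = %.2f, specificity = %.2f",
                     s$sensitivity, s$specificity),
             sprintf("conventional orientation (condition = pneumonia, positive = not low risk): sensitivity = %.2f, specificity = %.2f",
                     s$conventional$sensitivity, s$conventional$specificity),
             "")
  }
  if (!is.null(report$univariate)) {
    out <- c(out, "== Univariate parameter tests ==",
             vapply(coras_parameters, function(p) {
               u <- report$univariate[[p]]
               sprintf("%-16s chi2 = %8.3f, df = %d, p = %s",
                       p, u$statistic, u$df, format_pvalue(u$p))
             }, character(1)), "")
  }
  out <- c(out, "== Inter-parameter correlations ==",
           utils::capture.output(print(round(report$correlation, 2))), "",
           "== Variance inflation factors (8 parameters) ==",
           utils::capture.output(print(report$vif)), "")
  if (!is.null(report$logistic)) {
    out <- c(out, "== Adjusted logistic regression (age, sex, care level, CoRAS) ==",
             utils::capture.output(print(report$logistic$fit)),
             sprintf("max VIF among the four factors: %.2f",
                     report$logistic$vif$max_vif), "")
  }
  if (!is.null(report$models)) {
    m <- report$models
    tab <- m$table
    tab$auc <- sprintf("%.3f", tab$auc)
    tab$ci <- sprintf("%.3f-%.3f", m$table$ci_lower, m$table$ci_upper)
    tab$aic <- sprintf("%.1f", m$table$aic)
    out <- c(out, "== Model comparison ==",
             .fmt_table(tab[c("model", "auc", "ci", "aic")]),
             sprintf("a vs c: LRT chi2 = %.2f (df %d), p = %s | DeLong z = %.2f, p = %s",
                     m$a_vs_c$lrt$statistic, m$a_vs_c$lrt$df,
                     format_pvalue(m$a_vs_c$lrt$p),
                     m$a_vs_c$auc_test$z, format_pvalue(m$a_vs_c$auc_test$p)),
             sprintf("b vs c: LRT chi2 = %.2f (df %d), p = %s | DeLong z = %.2f, p = %s",
                     m$b_vs_c$lrt$statistic, m$b_vs_c$lrt$df,
                     format_pvalue(m$b_vs_c$lrt$p),
                     m$b_vs_c$auc_test$z, format_pvalue(m$b_vs_c$auc_test$p)),
             sprintf("a vs b: DeLong z = %.2f, p = %s",
                     m$a_vs_b$auc_test$z, format_pvalue(m$a_vs_b$auc_test$p)),
             "")
  }
  if (length(report$errors)) {
    out <- c(out, "== Skipped sections ==",
             vapply(names(report$errors), function(nm) {
               paste0(nm, ": ", report$errors[[nm]])
             }, character(1)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
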