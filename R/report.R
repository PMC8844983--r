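# End-to-end study report: overall concordance, per-category performance
# block (both "listed first" and "listed in top k"), mean detected
# diagnoses, and optional usability summaries.

#' Run the full concordance and agreement analysis
#'
#' @param records List of [patient_record()]s (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param k Top-k window for the secondary analysis (default 5).
#' @param conf_level Confidence level for all intervals.
#' @param categories Disorder categories for the per-category block
#'   (default: the three most prevalent in the study).
#' @param sus Optional SUS response matrix (n x 10, 1-5 convention).
#' @param feedback Optional feedback response matrix (values 1-4).
#' @return A `study_report` list with elements `overall` (top-1/top-k
#'   `binom_prop`s), `detected` (mean/sd of diagnoses detected),
#'   `per_category` (per category x window: contingency stats + AC1),
#'   `verdicts` (per-patient table), optional `usability`, and
#'   `provenance`.
#' @export
evaluate_study <- function(records, k = 5L, conf_level = 0.95,
                           categories = c("affective", "anxiety",
                                          "somatoform_associated"),
                           sus = NULL, feedback = NULL) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  verdicts <- evaluate_cohort(records, k = k)
  overall <- overall_concordance(verdicts, conf_level)

  per_category <- list()
  for (cat_i in categories) {
    for (kk in c(1L, as.integer(k))) {
      tab <- category_table(records, cat_i, k = kk)
      entry <- contingency_stats(tab, conf_level)
      entry$ac1 <- tryCatch(gwet_ac1(tab, conf_level),
                            error = function(e) NULL)
      key <- paste0(cat_i, if (kk == 1L) "_top1" else paste0("_top", kk))
      per_category[[key]] <- entry
    }
  }

  usability <- NULL
  if (!is.null(sus) || !is.null(feedback)) {
    usability <- list()
    if (!is.null(sus)) {
      comp <- impute_missing(sus, "item_mean")
      scores <- score_sus(comp$data)
      usability$sus <- list(
        mean = mean(scores), sd = stats::sd(scores),
        label = bangor_label(mean(scores)),
        n = length(scores), n_imputed = sum(comp$imputed))
    }
    if (!is.null(feedback)) {
      usability$feedback <- feedback_table(feedback)
    }
  }

  structure(
    list(overall = overall,
         detected = mean_detected(verdicts),
         per_category = per_category,
         verdicts = verdicts,
         usability = usability,
         provenance = list(
           n_patients = length(records), k = as.integer(k),
           conf_level = conf_level, categories = categories,
           package_version = tryCatch(
             as.character(utils::packageVersion("dxconcord")),
             error = function(e) "dev"),
           created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Symptom-checker concordance report (n =",
      x$provenance$n_patients, "patients)\n")
  cat("  top-1 agreement: "); print(x$overall$top1)
  cat(sprintf("  top-%d agreement: ", x$provenance$k)); print(x$overall$topk)
  cat(sprintf("  diagnoses detected per patient: mean %.2f (SD %.2f)\n",
              x$detected[["mean"]], x$detected[["sd"]]))
  for (nm in names(x$per_category)) {
    e <- x$per_category[[nm]]
    cat(sprintf(
      "  %-32s acc %.2f (%.2f-%.2f)  sens %s  spec %s  AC1 %s\n",
      nm, e$accuracy$p_hat, e$accuracy$ci_low, e$accuracy$ci_high,
      fmt_or_na(e$sensitivity), fmt_or_na(e$specificity),
      if (is.null(e$ac1)) "NA"
      else sprintf("%.2f (%s)", e$ac1$ac1, e$ac1$benchmark)))
  }
  if (!is.null(x$usability$sus)) {
    cat(sprintf("  SUS: mean %.2f (SD %.2f), %s\n", x$usability$sus$mean,
                x$usability$sus$sd, x$usability$sus$label))
  }
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "undef" else sprintf("%.2f", v)

binom_prop_list <- function(bp) {
  list(x = bp$x, n = bp$n, proportion = bp$p_hat,
       ci_low = bp$ci_low, ci_high = bp$ci_high,
       conf_level = bp$conf_level)
}

#' Serialize a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  per_cat <- lapply(report$per_category, function(e) {
    list(category = e$category, k = e$k,
         counts = list(tp = e$tp, fp = e$fp, fn = e$fn, tn = e$tn, n = e$n),
         accuracy = binom_prop_list(e$accuracy),
         sensitivity = if (is.na(e$sensitivity)) NULL else e$sensitivity,
         specificity = if (is.na(e$specificity)) NULL else e$specificity,
         ac1 = if (is.null(e$ac1)) NULL else list(
           value = e$ac1$ac1, ci_low = e$ac1$ci_low,
           ci_high = e$ac1$ci_high, benchmark = e$ac1$benchmark))
  })
  obj <- list(
    overall = list(top1 = binom_prop_list(report$overall$top1),
                   topk = binom_prop_list(report$overall$topk)),
    detected = list(mean = report$detected[["mean"]],
                    sd = report$detected[["sd"]]),
    per_category = per_cat,
    usability = report$usability,
    verdicts = report$verdicts,
    provenance = report$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Render a study report as Markdown tables
#'
#' Produces the per-category performance block in the layout of the
#' study's table: one column per category x window, rows for accuracy
#' (with CI), sensitivity, specificity, and AC1 (with CI and benchmark).
#'
#' @param report A `study_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "study_report"))
  p <- function(v) sprintf("%.1f", 100 * v)
  o1 <- report$overall$top1
  ok <- report$overall$topk
  lines <- c(
    "# Symptom-checker concordance report", "",
    sprintf("Patients: %d", report$provenance$n_patients),
    sprintf("- Top-1 agreement: %d/%d = %s%% (%s to %s)",
            o1$x, o1$n, p(o1$p_hat), p(o1$ci_low), p(o1$ci_high)),
    sprintf("- Top-%d agreement: %d/%d = %s%% (%s to %s)",
            report$provenance$k, ok$x, ok$n, p(ok$p_hat), p(ok$ci_low),
            p(ok$ci_high)),
    sprintf("- Diagnoses detected per patient: mean %.2f (SD %.2f)",
            report$detected[["mean"]], report$detected[["sd"]]), "",
    "| Statistic | " %+% paste(names(report$per_category), collapse = " | ")
      %+% " |",
    "|---|" %+% paste(rep("---|", length(report$per_category)), collapse = ""))
  row <- function(label, f) {
    vals <- vapply(report$per_category, f, "")
    "| " %+% label %+% " | " %+% paste(vals, collapse = " | ") %+% " |"
  }
  lines <- c(
    lines,
    row("Accuracy (95% CI)", function(e)
      sprintf("%.2f (%.2f to %.2f)", e$accuracy$p_hat, e$accuracy$ci_low,
              e$accuracy$ci_high)),
    row("Sensitivity", function(e) fmt_or_na(e$sensitivity)),
    row("Specificity", function(e) fmt_or_na(e$specificity)),
    row("AC1 (95% CI)", function(e)
      if (is.null(e$ac1)) "undef"
      else sprintf("%.2f (%.2f to %.2f)", e$ac1$ac1, e$ac1$ci_low,
                   e$ac1$ci_high)),
    row("Benchmark", function(e)
      if (is.null(e$ac1)) "undef" else e$ac1$benchmark))
  if (!is.null(report$usability$sus)) {
    lines <- c(lines, "",
               sprintf("SUS: mean %.2f (SD %.2f), %s (n = %d, %d cells imputed)",
                       report$usability$sus$mean, report$usability$sus$sd,
                       report$usability$sus$label, report$usability$sus$n,
                       report$usability$sus$n_imputed))
  }
  if (!is.null(report$usability$feedback)) {
    fb <- report$usability$feedback
    lines <- c(lines, "", "| Feedback item | Agreement n (%) |", "|---|---|",
               sprintf("| %s | %d (%d) |", fb$item, fb$x, fb$percent))
  }
  lines
}

`%+%` <- function(a, b) paste0(a, b)
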