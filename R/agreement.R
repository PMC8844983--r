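# Agreement statistics: Agresti-Coull binomial intervals, patient-level
# 2x2 contingency statistics per disorder category, and Gwet's
# first-order agreement coefficient (AC1) with a linearized variance.
#
# AC1 corrects observed agreement for chance using pe = 2*pi*(1-pi), with
# pi the mean of the two raters' marginal probabilities. Unlike Cohen's
# kappa it does not collapse when base rates are skewed, which matters
# here: category prevalences run as low as 9%.

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' Adds z^2/2 pseudo-successes and z^2 pseudo-trials, then applies the
#' Wald formula to the adjusted proportion; bounds are clipped to the
#' unit interval.
#' The exact normal quantile is used (1.959964 at 95%), not 1.96.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return A `binom_prop` list: `x`, `n`, `p_hat`, `p_tilde`, `ci_low`,
#'   `ci_high`, `conf_level`.
#' @examples
#' agresti_coull_ci(25, 49)  # 95% CI 0.375 to 0.644
#' @export
agresti_coull_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L)
  if (is.na(x) || is.na(n) || n < 1 || x < 0 || x > n) {
    stop("need 0 <= x <= n with n >= 1 (got x=", x, ", n=", n, ")",
         call. = FALSE)
  }
  if (conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must be strictly between 0 and 1", call. = FALSE)
  }
  z <- stats::qnorm((1 + conf_level) / 2)
  n_t <- n + z^2
  p_t <- (x + z^2 / 2) / n_t
  hw <- z * sqrt(p_t * (1 - p_t) / n_t)
  structure(
    list(x = x, n = n, p_hat = x / n, p_tilde = p_t,
         ci_low = max(0, p_t - hw), ci_high = min(1, p_t + hw),
         conf_level = conf_level),
    class = "binom_prop")
}

#' @export
print.binom_prop <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f)\n",
              x$x, x$n, 100 * x$p_hat, 100 * x$conf_level,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Patient-level 2x2 table for one disorder category
#'
#' Binarizes at the patient level: a patient is therapist-positive when
#' any interview-based diagnosis falls in the category, and
#' checker-positive when any of the top-k condition suggestions carries a
#' code in the category.
#'
#' @param records List of [patient_record()]s.
#' @param category One of `disorder_categories()`.
#' @param k Number of top suggestions considered (default 5; use 1 for
#'   the "listed first" variant).
#' @return A `category_table` list with counts `tp`, `fp`, `fn`, `tn`,
#'   total `n`, plus `category` and `k`.
#' @export
category_table <- function(records, category, k = 5L) {
  stopifnot(length(records) > 0L, k >= 1L)
  category <- match.arg(category, disorder_categories())
  th <- vapply(records, function(r) {
    any(icd10_category(unique(r$diagnoses)) == category)
  }, logical(1))
  ck <- vapply(records, function(r) {
    s <- r$suggestions
    if (nrow(s) == 0L) return(FALSE)
    s <- s[order(s$rank), , drop = FALSE]
    top <- s$codes[seq_len(min(k, nrow(s)))]
    codes <- unique(unlist(top))
    length(codes) > 0L && any(icd10_category(codes) == category)
  }, logical(1))
  structure(
    list(category = category, k = as.integer(k),
         tp = sum(th & ck), fp = sum(!th & ck),
         fn = sum(th & !ck), tn = sum(!th & !ck),
         n = length(records)),
    class = "category_table")
}

#' Construct a 2x2 table from counts
#'
#' @param tp,fp,fn,tn Cell counts (therapist presence x checker presence).
#' @param category,k Optional metadata carried along.
#' @return A `category_table`.
#' @export
as_category_table <- function(tp, fp, fn, tn, category = "custom", k = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn >= 1)
  structure(list(category = category, k = k, tp = tp, fp = fp, fn = fn,
                 tn = tn, n = tp + fp + fn + tn),
            class = "category_table")
}

#' Accuracy, sensitivity and specificity of a 2x2 table
#'
#' Accuracy is (TP+TN)/N with an Agresti-Coull interval on the agreement
#' count; sensitivity TP/(TP+FN); specificity TN/(TN+FP). A zero
#' denominator yields `NA` (explicitly undefined), never a silent 0/0.
#'
#' @param table A `category_table`.
#' @param conf_level Confidence level for the accuracy interval.
#' @return List with `accuracy` (a `binom_prop`), `sensitivity`,
#'   `specificity` and the input counts.
#' @export
contingency_stats <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "category_table"))
  with(table, {
    acc <- agresti_coull_ci(tp + tn, n, conf_level)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    list(category = category, k = k, accuracy = acc,
         sensitivity = sens, specificity = spec,
         tp = tp, fp = fp, fn = fn, tn = tn, n = n)
  })
}

ac1_point <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  pa <- (tp + tn) / n
  pi1 <- ((tp + fn) / n + (tp + fp) / n) / 2
  pe <- 2 * pi1 * (1 - pi1)
  list(pa = pa, pi = pi1, pe = pe, ac1 = (pa - pe) / (1 - pe))
}

# Gwet's (2008) first-order linearized variance for two raters and two
# categories, computed from subject-level components. Subjects fall into
# the four table cells; within a cell the per-subject contribution is
# constant, so the sum collapses to a weighted sum over cells.
ac1_variance_linearized <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  pt <- ac1_point(tp, fp, fn, tn)
  pi2 <- 1 - pt$pi
  cells <- list(c(tp, 1, 1, 1), c(tn, 1, 0, 0),
                c(fp, 0, 0, 1), c(fn, 0, 1, 0))  # count, agree, rater1, rater2
  tot <- 0
  for (cc in cells) {
    cnt <- cc[1]
    if (cnt == 0) next
    pa_i <- cc[2]
    pi1_i <- (cc[3] + cc[4]) / 2           # share of raters choosing cat 1
    pe_i <- pi1_i * (1 - pt$pi) + (1 - pi1_i) * (1 - pi2)
    g_i <- (pa_i - pt$pe) / (1 - pt$pe)
    g_star <- g_i - 2 * (1 - pt$ac1) * (pe_i - pt$pe) / (1 - pt$pe)
    tot <- tot + cnt * (g_star - pt$ac1)^2
  }
  tot / (n * (n - 1))
}

ac1_variance_jackknife <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  vals <- numeric(0)
  for (cell in seq_along(counts)) {
    if (counts[cell] == 0) next
    d <- counts
    d[cell] <- d[cell] - 1
    vals <- c(vals, rep(ac1_point(d["tp"], d["fp"], d["fn"], d["tn"])$ac1,
                        counts[cell]))
  }
  (n - 1) / n * sum((vals - mean(vals))^2)
}

#' Gwet's first-order agreement coefficient (AC1)
#'
#' AC1 = (pa - pe)/(1 - pe) with pa the observed agreement proportion and
#' pe = 2*pi*(1-pi) chance agreement from the mean marginal probability
#' pi. The confidence interval is a normal approximation using either the
#' first-order linearized variance (default, as agreement software does)
#' or a leave-one-subject-out jackknife; bounds are truncated to lie
#' between -1 and 1.
#'
#' @param table A `category_table`.
#' @param conf_level Confidence level; default 0.95.
#' @param variance `"linearized"` (default) or `"jackknife"`.
#' @return An `ac1_estimate` list: `ac1`, `pa`, `pe`, `pi`, `variance`,
#'   `ci_low`, `ci_high`, `benchmark`, `conf_level`.
#' @examples
#' gwet_ac1(as_category_table(tp = 20, fp = 5, fn = 5, tn = 20))
#' @export
gwet_ac1 <- function(table, conf_level = 0.95,
                     variance = c("linearized", "jackknife")) {
  stopifnot(inherits(table, "category_table"), table$n >= 2L)
  variance <- match.arg(variance)
  pt <- with(table, ac1_point(tp, fp, fn, tn))
  if (pt$pe >= 1) {
    stop("degenerate marginals: chance agreement pe = 1, AC1 undefined",
         call. = FALSE)
  }
  v <- with(table, switch(variance,
    linearized = ac1_variance_linearized(tp, fp, fn, tn),
    jackknife = ac1_variance_jackknife(tp, fp, fn, tn)))
  z <- stats::qnorm((1 + conf_level) / 2)
  structure(
    list(ac1 = pt$ac1, pa = pt$pa, pe = pt$pe, pi = pt$pi,
         variance = v, variance_method = variance,
         ci_low = max(-1, pt$ac1 - z * sqrt(v)),
         ci_high = min(1, pt$ac1 + z * sqrt(v)),
         benchmark = benchmark_ac1(pt$ac1),
         conf_level = conf_level),
    class = "ac1_estimate")
}

#' @export
print.ac1_estimate <- function(x, ...) {
  cat(sprintf("AC1 = %.2f (%.0f%% CI %.2f to %.2f), %s agreement\n",
              x$ac1, 100 * x$conf_level, x$ci_low, x$ci_high, x$benchmark))
  invisible(x)
}

#' Benchmark label for an agreement coefficient
#'
#' Bands: poor (<0.20), fair (0.21-0.40), moderate (0.41-0.60), good
#' (0.61-0.80), very good (>0.81). Values falling in the gaps between
#' printed band edges (e.g. 0.205) are assigned to the lower band and a
#' message is emitted.
#'
#' @param value Numeric between -1 and 1.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`,
#'   `"very_good"`.
#' @export
benchmark_ac1 <- function(value) {
  stopifnot(length(value) == 1L, value >= -1, value <= 1)
  in_gap <- (value > 0.20 && value < 0.21) || (value > 0.40 && value < 0.41) ||
    (value > 0.60 && value < 0.61) || (value > 0.80 && value <= 0.81)
  if (in_gap) {
    message("value ", format(value),
            " falls between benchmark bands; assigned to the lower band")
  }
  if (value < 0.21) "poor"
  else if (value < 0.41) "fair"
  else if (value < 0.61) "moderate"
  else if (value <= 0.81) "good"
  else "very_good"
}

#' Overall top-1 / top-k percent agreement with confidence intervals
#'
#' @param verdicts Verdict data frame from [evaluate_cohort()].
#' @param conf_level Confidence level.
#' @return List with `binom_prop` elements `top1` and `topk`.
#' @export
overall_concordance <- function(verdicts, conf_level = 0.95) {
  if (is.null(verdicts) || nrow(verdicts) == 0L) {
    stop("empty verdict table", call. = FALSE)
  }
  n <- nrow(verdicts)
  list(top1 = agresti_coull_ci(sum(verdicts$top1_match), n, conf_level),
       topk = agresti_coull_ci(sum(verdicts$topk_match), n, conf_level))
}
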