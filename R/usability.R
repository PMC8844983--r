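# System Usability Scale scoring and feedback-questionnaire aggregation.
#
# SUS: 10 items, alternating polarity. On the canonical 1-5 response
# convention the adjusted contribution is raw-1 for odd items and 5-raw
# for even items; the sum of adjustments times 2.5 gives a 0-100 score.
# Datasets declared on a 0-4 convention are shifted up by one before
# scoring (the two conventions then score identically).

#' Score the System Usability Scale
#'
#' @param items Numeric vector of 10 responses, or a matrix/data frame
#'   with 10 columns (one row per respondent).
#' @param scale Declared response convention, `"1-5"` (canonical) or
#'   `"0-4"` (shifted up by 1 before scoring, with a message).
#' @return Numeric score(s) on 0-100.
#' @examples
#' score_sus(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
#' score_sus(rep(3, 10))                       # 50
#' @export
score_sus <- function(items, scale = c("1-5", "0-4")) {
  scale <- match.arg(scale)
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1L)
       else as.matrix(items)
  if (ncol(m) != 10L) {
    stop("SUS needs exactly 10 items, got ", ncol(m), call. = FALSE)
  }
  if (anyNA(m)) {
    stop("missing SUS items; impute first (see impute_missing) or drop ",
         "incomplete respondents explicitly", call. = FALSE)
  }
  if (scale == "0-4") {
    message("shifting declared 0-4 responses to the canonical 1-5 convention")
    m <- m + 1
  }
  if (any(m < 1 | m > 5)) {
    stop("SUS responses outside the declared range", call. = FALSE)
  }
  odd <- c(1, 3, 5, 7, 9)
  even <- c(2, 4, 6, 8, 10)
  adj <- rowSums(m[, odd, drop = FALSE] - 1) +
    rowSums(5 - m[, even, drop = FALSE])
  score <- 2.5 * adj
  if (is.null(dim(items))) score[[1L]] else score
}

#' Usability benchmark label for a SUS score
#'
#' Thresholds: > 70 is acceptable, >= 85.5 is excellent.
#'
#' @param score Numeric vector of SUS scores on 0-100.
#' @return Character vector in `"excellent"`, `"acceptable"`,
#'   `"below_acceptable"`.
#' @export
bangor_label <- function(score) {
  stopifnot(all(score >= 0 & score <= 100))
  ifelse(score >= 85.5, "excellent",
         ifelse(score > 70, "acceptable", "below_acceptable"))
}

#' Aggregated agreement frequency for one feedback item
#'
#' Counts responses of 3 ("agree") or 4 ("completely agree") among
#' non-missing answers on the 4-point scale.
#'
#' @param responses Matrix or data frame of feedback responses (rows =
#'   respondents), values in 1-4 or `NA`.
#' @param item Column index or name of the item.
#' @param conf_level Confidence level for the Agresti-Coull interval.
#' @return A `binom_prop` with an extra `percent` field rounded to the
#'   nearest integer (half away from zero), as agreement tables print it.
#' @export
feedback_agreement <- function(responses, item, conf_level = 0.95) {
  m <- as.matrix(responses)
  v <- m[, item]
  ok <- !is.na(v)
  if (!any(ok)) stop("item has no non-missing responses", call. = FALSE)
  if (any(!v[ok] %in% 1:4)) {
    stop("feedback responses must be integers 1-4", call. = FALSE)
  }
  bp <- agresti_coull_ci(sum(v[ok] %in% c(3, 4)), sum(ok), conf_level)
  bp$percent <- round_half_up(100 * bp$p_hat, 0)
  bp
}

#' Agreement table over all feedback items
#'
#' @param responses Matrix or data frame of feedback responses.
#' @param items Columns to aggregate (default: all).
#' @return Data frame with one row per item: `item`, `x`, `n`, `percent`.
#' @export
feedback_table <- function(responses, items = seq_len(ncol(as.matrix(responses)))) {
  rows <- lapply(items, function(i) {
    bp <- feedback_agreement(responses, i)
    data.frame(item = if (is.character(i)) i else as.character(i),
               x = bp$x, n = bp$n, percent = bp$percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# round half away from zero at `digits` decimals (matches the printed style;
# base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Impute missing questionnaire responses
#'
#' Single imputation by item mean or person mean, with an explicit flag
#' matrix marking the imputed cells. Imputation refuses to run when any
#' item is missing more than `max_missing` of its responses.
#'
#' @param responses Matrix or data frame (rows = respondents).
#' @param policy `"item_mean"`, `"person_mean"` or `"none"`.
#' @param max_missing Maximum tolerated missing fraction per item
#'   (default 0.04, the study's observed ceiling).
#' @return List with `data` (completed numeric matrix) and `imputed`
#'   (logical matrix flagging imputed cells).
#' @export
impute_missing <- function(responses, policy = c("item_mean", "person_mean", "none"),
                           max_missing = 0.04) {
  policy <- match.arg(policy)
  m <- as.matrix(responses)
  storage.mode(m) <- "double"
  miss <- is.na(m)
  # count-based ceiling: an item may have at most ceiling(max_missing * n)
  # missing responses (2 of 49 counts as 4%)
  too_many <- colSums(miss) > ceiling(max_missing * nrow(m))
  if (any(too_many)) {
    stop("missingness above threshold (", max_missing, ") for item(s) ",
         paste(which(too_many), collapse = ", "), call. = FALSE)
  }
  if (policy == "none" || !any(miss)) {
    return(list(data = m, imputed = miss & FALSE))
  }
  if (policy == "item_mean") {
    fill <- matrix(rep(colMeans(m, na.rm = TRUE), each = nrow(m)), nrow(m))
  } else {
    fill <- matrix(rep(rowMeans(m, na.rm = TRUE), times = ncol(m)), nrow(m))
  }
  m[miss] <- fill[miss]
  list(data = m, imputed = miss)
}
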