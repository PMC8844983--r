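# Patient-level containers and the long-format cohort CSV dialect.
#
# One row per (patient, source, rank): columns patient_id, source
# ("therapist" or "checker"), rank (empty for therapist rows), code
# (";"-separated canonical ICD-10 codes, may be empty when only a label is
# available), label, probability ("X out of 10" numerator, optional),
# less_probable (TRUE/FALSE).

#' Construct a patient record
#'
#' @param patient_id Identifier (coerced to character).
#' @param diagnoses Character vector of therapist ICD-10 codes (non-empty;
#'   patients without an interview-based diagnosis are excluded from
#'   analysis upstream).
#' @param suggestions Data frame of checker condition suggestions with
#'   columns `rank`, `label`, `codes` (list column of character vectors),
#'   and optionally `probability` and `less_probable`. Ranks must be
#'   unique and all main suggestions must precede "less probable" ones.
#' @param sus Optional numeric vector of 10 System Usability Scale items.
#' @param feedback Optional numeric vector of feedback-questionnaire items.
#' @return A `patient_record` object.
#' @export
patient_record <- function(patient_id, diagnoses, suggestions = NULL,
                           sus = NULL, feedback = NULL) {
  if (length(diagnoses) == 0L) {
    stop("patient '", patient_id, "': therapist diagnosis list is empty",
         call. = FALSE)
  }
  diagnoses <- parse_icd10(diagnoses)
  if (is.null(suggestions)) {
    suggestions <- suggestion_frame(character(0))
  }
  stopifnot(is.data.frame(suggestions),
            all(c("rank", "label", "codes") %in% names(suggestions)))
  if (is.null(suggestions$probability)) suggestions$probability <- NA_integer_
  if (is.null(suggestions$less_probable)) suggestions$less_probable <- FALSE
  if (nrow(suggestions) > 0L) {
    if (anyDuplicated(suggestions$rank) || any(suggestions$rank < 1L)) {
      stop("patient '", patient_id, "': suggestion ranks must be unique ",
           "positive integers", call. = FALSE)
    }
    suggestions <- suggestions[order(suggestions$rank), , drop = FALSE]
    lp <- suggestions$less_probable
    if (any(lp) && any(!lp[seq_len(nrow(suggestions)) > match(TRUE, lp)])) {
      stop("patient '", patient_id, "': main suggestions must precede ",
           "'less probable' ones in rank order", call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         diagnoses = diagnoses,
         suggestions = suggestions,
         sus = sus, feedback = feedback),
    class = "patient_record")
}

#' Build a suggestion data frame from codes and/or labels
#'
#' Convenience constructor for [patient_record()]: each suggestion may carry
#' explicit codes, or a label to be resolved through the term map.
#'
#' @param code Character vector, one entry per suggestion; each entry is a
#'   `";"`-separated code list or `""`/`NA` when only a label is known.
#' @param label Character vector of condition labels (optional).
#' @param probability Optional integer vector ("X out of 10" numerators).
#' @param less_probable Optional logical vector.
#' @param term_map Term map used to resolve label-only suggestions.
#' @return Data frame with columns `rank`, `label`, `codes` (list column),
#'   `probability`, `less_probable`.
#' @export
suggestion_frame <- function(code, label = rep("", length(code)),
                             probability = rep(NA_integer_, length(code)),
                             less_probable = rep(FALSE, length(code)),
                             term_map = default_term_map()) {
  n <- length(code)
  codes <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- code[i]
    if (!is.na(ci) && nzchar(trimws(ci))) {
      codes[[i]] <- parse_icd10(strsplit(ci, ";", fixed = TRUE)[[1L]])
    } else if (nzchar(trimws(label[i]))) {
      codes[[i]] <- map_label(label[i], term_map)
    } else {
      codes[[i]] <- character(0)
    }
  }
  out <- data.frame(rank = seq_len(n), label = as.character(label),
                    probability = as.integer(probability),
                    less_probable = as.logical(less_probable),
                    stringsAsFactors = FALSE)
  out$codes <- codes
  out[, c("rank", "label", "codes", "probability", "less_probable")]
}

#' Read a cohort from long-format CSV
#'
#' @param path Path to the cohort CSV (see the package vignette for the
#'   dialect).
#' @param term_map Term map used to resolve label-only checker suggestions.
#' @return List of [patient_record()]s, ordered by first appearance.
#' @export
read_cohort <- function(path, term_map = default_term_map()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  req <- c("patient_id", "source", "code", "label")
  if (!all(req %in% names(df))) {
    stop("cohort CSV must have columns ",
         paste(req, collapse = ", "), "; missing: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$rank)) df$rank <- NA_integer_
  if (is.null(df$probability)) df$probability <- NA_integer_
  if (is.null(df$less_probable)) df$less_probable <- FALSE
  df$less_probable <- df$less_probable %in% c(TRUE, "TRUE", "true", "1", 1)
  bad <- !df$source %in% c("therapist", "checker")
  if (any(bad)) {
    stop("invalid source value(s) in rows ",
         paste(which(bad), collapse = ", "),
         " (must be 'therapist' or 'checker')", call. = FALSE)
  }
  ids <- unique(df$patient_id)
  lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    th <- rows[rows$source == "therapist", , drop = FALSE]
    ch <- rows[rows$source == "checker", , drop = FALSE]
    ch <- ch[order(ch$rank), , drop = FALSE]
    sug <- suggestion_frame(ch$code, ch$label, ch$probability,
                            ch$less_probable, term_map = term_map)
    sug$rank <- as.integer(ch$rank)
    patient_record(id, diagnoses = th$code, suggestions = sug)
  })
}

#' Write a cohort to long-format CSV
#'
#' @param records List of [patient_record()]s.
#' @param path Output path.
#' @export
write_cohort <- function(records, path) {
  rows <- lapply(records, function(r) {
    th <- data.frame(patient_id = r$patient_id, source = "therapist",
                     rank = NA_integer_, code = r$diagnoses, label = "",
                     probability = NA_integer_, less_probable = FALSE,
                     stringsAsFactors = FALSE)
    s <- r$suggestions
    if (nrow(s) == 0L) return(th)
    ch <- data.frame(
      patient_id = r$patient_id, source = "checker", rank = s$rank,
      code = vapply(s$codes, paste, "", collapse = ";"),
      label = s$label, probability = s$probability,
      less_probable = s$less_probable, stringsAsFactors = FALSE)
    rbind(th, ch)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
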