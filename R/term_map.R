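# Condition-label -> ICD-10 term map.
#
# Symptom checkers emit free-text condition labels, not codes; concordance
# analysis needs every label resolved to one or more ICD-10 codes. The map
# is an editable CSV (label_pattern, icd_codes, note) shipped with the
# package; unknown labels resolve to an empty set with a warning, never a
# silent guess.

norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Read a term map from CSV
#'
#' The file has columns `label_pattern` and `icd_codes` (codes separated by
#' `";"`), an optional `note` column, and `#` comment lines.
#'
#' @param path Path to the CSV file.
#' @return A `term_map` data frame with columns `label_pattern`,
#'   `icd_codes`, `note` and a normalized lookup key.
#' @export
read_term_map <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("label_pattern", "icd_codes")
  if (!all(req %in% names(df))) {
    stop("term map must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$note)) df$note <- ""
  df$key <- norm_label(df$label_pattern)
  if (anyDuplicated(df$key)) {
    stop("duplicate label patterns in term map: ",
         paste(unique(df$key[duplicated(df$key)]), collapse = ", "),
         call. = FALSE)
  }
  # validate every code up front
  lapply(strsplit(df$icd_codes, ";", fixed = TRUE), parse_icd10)
  class(df) <- c("term_map", "data.frame")
  df
}

#' Write a term map to CSV
#'
#' @param term_map A `term_map` data frame.
#' @param path Output path.
#' @export
write_term_map <- function(term_map, path) {
  utils::write.csv(
    term_map[, c("label_pattern", "icd_codes", "note")],
    path, row.names = FALSE, quote = TRUE
  )
  invisible(path)
}

#' The default term map shipped with the package
#'
#' Contains the study's coding conventions (Burnout as depressive disorder,
#' functional somatic syndromes as F45, agoraphobia/panic terms) plus a
#' conventional label table for common mental-disorder terms.
#'
#' @return A `term_map` data frame.
#' @export
default_term_map <- function() {
  read_term_map(system.file("extdata", "term_map.csv", package = "dxconcord",
                            mustWork = TRUE))
}

#' Map a condition label to ICD-10 codes
#'
#' Lookup is case- and whitespace-insensitive. Unknown labels return an
#' empty set and raise a warning so that no suggestion is ever silently
#' guessed into a code.
#'
#' @param label Character vector of condition labels.
#' @param term_map A `term_map`, by default the shipped one.
#' @param quiet If `TRUE`, suppress the unknown-label warning.
#' @return For a single label, a character vector of codes (possibly empty);
#'   for several labels, a list of such vectors named by label.
#' @examples
#' map_label("Burnout")
#' map_label("irritable bowel syndrome")
#' @export
map_label <- function(label, term_map = default_term_map(), quiet = FALSE) {
  keys <- norm_label(label)
  idx <- match(keys, term_map$key)
  res <- lapply(seq_along(keys), function(i) {
    if (is.na(idx[i])) character(0)
    else parse_icd10(strsplit(term_map$icd_codes[idx[i]], ";", fixed = TRUE)[[1L]])
  })
  unknown <- is.na(idx) & nzchar(keys)
  if (any(unknown) && !quiet) {
    warning("unknown condition label(s), mapped to empty code set: ",
            paste(sprintf("'%s'", label[unknown]), collapse = ", "),
            call. = FALSE)
  }
  names(res) <- label
  if (length(res) == 1L) res[[1L]] else res
}
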