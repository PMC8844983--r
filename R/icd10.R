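# ICD-10 code parsing, normalization and disorder-category assignment.
#
# Codes are represented as canonical strings ("F32", "F40.01"): a chapter
# letter, a two-digit stem number, and an optional post-point specifier of
# one or two digits. Accessor helpers extract the structural parts; all
# functions are vectorized over character vectors.

ICD10_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"

#' Parse and normalize ICD-10 codes
#'
#' Converts free-text ICD-10 codes to canonical form: whitespace stripped,
#' chapter letter upper-cased, so that `"f32.2 "` becomes `"F32.2"`.
#' Parsing canonical output again is a no-op.
#'
#' @param x Character vector of codes (e.g. `"F40.01"`, `" f32.2"`).
#' @return Character vector of canonical codes.
#' @examples
#' parse_icd10(c("F40.01", " f32.2 "))
#' @export
parse_icd10 <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) x <- as.character(x)
  out <- toupper(gsub("[[:space:]]+", "", x))
  bad <- is.na(out) | !grepl(ICD10_PATTERN, out)
  if (any(bad)) {
    stop("not a valid ICD-10 code: ",
         paste(sprintf("'%s'", x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname icd10_fields
#' @export
icd10_chapter <- function(code) substr(parse_icd10(code), 1L, 1L)

#' @rdname icd10_fields
#' @export
icd10_stem <- function(code) substr(parse_icd10(code), 1L, 3L)

#' @rdname icd10_fields
#' @export
icd10_detail <- function(code) {
  code <- parse_icd10(code)
  ifelse(nchar(code) > 4L, substring(code, 5L), "")
}

#' Structural fields of ICD-10 codes
#'
#' @param code Character vector of ICD-10 codes (parsed if not canonical).
#' @return For `icd10_fields()`, a data frame with columns `raw`, `chapter`,
#'   `stem`, `detail` and `full`; the other accessors return the single
#'   field as a character vector (`detail` is `""` for 3-digit codes).
#' @examples
#' icd10_fields("f40.01")
#' @export
icd10_fields <- function(code) {
  full <- parse_icd10(code)
  data.frame(
    raw = as.character(code),
    chapter = substr(full, 1L, 1L),
    stem = substr(full, 1L, 3L),
    detail = ifelse(nchar(full) > 4L, substring(full, 5L), ""),
    full = full,
    stringsAsFactors = FALSE
  )
}

#' Disorder category of an ICD-10 code
#'
#' Assigns the patient-level analysis categories: stems F30-F39 are
#' affective disorders, F40-F41 anxiety disorders, F45 somatoform and
#' associated disorders (functional somatic syndromes are mapped to F45 by
#' the term map, so they land here too), and everything else `"other"`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param extra_somatoform Optional character vector of additional 3-digit
#'   stems to count as somatoform-associated (off by default).
#' @return Character vector with values in `"affective"`, `"anxiety"`,
#'   `"somatoform_associated"`, `"other"`.
#' @examples
#' icd10_category(c("F32.1", "F41.0", "F45.1", "F50.0"))
#' @export
icd10_category <- function(code, extra_somatoform = character(0)) {
  stem <- icd10_stem(code)
  chap <- substr(stem, 1L, 1L)
  num <- as.integer(substr(stem, 2L, 3L))
  out <- rep("other", length(stem))
  is_f <- chap == "F"
  out[is_f & num >= 30L & num <= 39L] <- "affective"
  out[is_f & num >= 40L & num <= 41L] <- "anxiety"
  out[stem == "F45" | stem %in% extra_somatoform] <- "somatoform_associated"
  out
}

#' The four disorder categories used in patient-level analyses
#'
#' @return Character vector: affective, anxiety, somatoform_associated,
#'   other.
#' @export
disorder_categories <- function() {
  c("affective", "anxiety", "somatoform_associated", "other")
}
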