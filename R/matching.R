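# Concordance rules between checker condition codes and therapist ICD-10
# diagnoses.
#
# The default comparison is at 4-digit precision. On top of that sit the
# study's enumerated equivalences:
#   (a) exact 4-digit (full-string) equality;
#   (b) 3-digit (stem) equality for a fixed exception set of disorders
#       where the 4th digit only grades severity/course: depressive
#       episode (F32), recurrent depression (F33), bipolar disorder (F31),
#       OCD (F42), conduct disorder (F91), schizophrenia (F20);
#   (c) recurrent depression is equated with the nonrecurrent category
#       (F33.x == F32.x), because checkers do not emit recurrent codes;
#   (d) a therapist diagnosis of agoraphobia with panic disorder (F40.01)
#       is credited to any agoraphobia suggestion (F40.0x) and to panic
#       disorder (F41.0);
#   (e) within one psychoactive-substance stem (F10-F19), harmful
#       use/abuse (.1x) and dependence (.2x) are equated, since checkers
#       do not distinguish abuse from addiction.
# Rules (a), (b), (c), (e) are symmetric; (d) keys on the therapist side.

#' Stems matched at 3-digit precision
#'
#' @return Character vector of stems whose 4th digit is ignored when
#'   comparing codes.
#' @export
stem_exception_set <- function() c("F32", "F33", "F31", "F42", "F91", "F20")

# map F33 -> F32 keeping the detail digits (rule c)
dep_norm <- function(full) {
  ifelse(substr(full, 1L, 3L) == "F33", paste0("F32", substring(full, 4L)), full)
}

substance_stem <- function(stem) {
  num <- suppressWarnings(as.integer(substr(stem, 2L, 3L)))
  substr(stem, 1L, 1L) == "F" & !is.na(num) & num >= 10L & num <= 19L
}

#' Do a checker code and a therapist code agree?
#'
#' Applies the matching rules documented above. Vectorized; the two
#' arguments are recycled to a common length.
#'
#' @param suggestion ICD-10 code(s) of the checker's condition suggestion.
#' @param therapist ICD-10 code(s) of the therapist diagnosis.
#' @return Logical vector.
#' @examples
#' codes_match("F41.0", "F40.01")  # panic credited to agoraphobia w/ panic
#' codes_match("F32.2", "F33.2")   # recurrent == nonrecurrent depression
#' codes_match("F10.1", "F10.2")   # abuse == dependence
#' codes_match("F40.1", "F40.2")   # distinct phobias do not agree
#' @export
codes_match <- function(suggestion, therapist) {
  s <- parse_icd10(suggestion)
  t <- parse_icd10(therapist)
  n <- max(length(s), length(t))
  s <- rep_len(s, n)
  t <- rep_len(t, n)

  sn <- dep_norm(s)
  tn <- dep_norm(t)
  s_stem <- substr(sn, 1L, 3L)
  t_stem <- substr(tn, 1L, 3L)

  # (a) exact 4-digit equality, with (c) folded in via dep_norm
  hit <- sn == tn
  # (b) stem-level match inside the exception set
  hit <- hit | (s_stem == t_stem & s_stem %in% dep_norm(stem_exception_set()))
  # (d) agoraphobia with panic disorder on the therapist side
  s_detail <- ifelse(nchar(s) > 4L, substring(s, 5L), "")
  agora <- substr(s, 1L, 3L) == "F40" & substr(s_detail, 1L, 1L) == "0"
  hit <- hit | (t == "F40.01" & (agora | s == "F41.0"))
  # (e) abuse == dependence within one substance stem
  s_d1 <- substr(ifelse(nchar(s) > 4L, substring(s, 5L), ""), 1L, 1L)
  t_d1 <- substr(ifelse(nchar(t) > 4L, substring(t, 5L), ""), 1L, 1L)
  hit <- hit | (substr(s, 1L, 3L) == substr(t, 1L, 3L) &
                  substance_stem(substr(s, 1L, 3L)) &
                  s_d1 %in% c("1", "2") & t_d1 %in% c("1", "2"))
  hit
}

# any code in `codes` matching any therapist code in `dx`
any_match <- function(codes, dx) {
  if (length(codes) == 0L || length(dx) == 0L) return(FALSE)
  grid <- expand.grid(s = codes, t = dx, stringsAsFactors = FALSE)
  any(codes_match(grid$s, grid$t))
}

#' Evaluate one patient's top-k concordance
#'
#' Takes the first `k` condition suggestions in rank order ("less probable"
#' suggestions fill the remaining slots, so a patient with 3 main and 4
#' less-probable suggestions is judged on the first 5 of the combined
#' list) and records whether the first suggestion, and whether any of the
#' top `k`, matches at least one therapist diagnosis.
#'
#' @param record A [patient_record()].
#' @param k Number of top suggestions considered (default 5).
#' @return A `match_verdict` list: `patient_id`, `top1_match`,
#'   `topk_match`, `k`, `n_detected` (distinct therapist diagnoses matched
#'   within the top `k`), and `matched_pairs` (data frame of suggestion
#'   rank / therapist code, first matching rank per diagnosis).
#' @export
evaluate_patient <- function(record, k = 5L) {
  stopifnot(inherits(record, "patient_record"), k >= 1L)
  dx <- unique(record$diagnoses)
  sug <- record$suggestions
  if (nrow(sug) == 0L) {
    warning("patient '", record$patient_id, "' has no condition suggestions",
            call. = FALSE)
    return(structure(
      list(patient_id = record$patient_id, top1_match = FALSE,
           topk_match = FALSE, k = as.integer(k), n_detected = 0L,
           matched_pairs = data.frame(rank = integer(0),
                                      therapist_code = character(0))),
      class = "match_verdict"))
  }
  sug <- sug[order(sug$rank), , drop = FALSE]
  top <- sug[seq_len(min(k, nrow(sug))), , drop = FALSE]

  first_rank <- rep(NA_integer_, length(dx))
  for (i in seq_len(nrow(top))) {
    codes <- top$codes[[i]]
    if (length(codes) == 0L) next
    for (j in seq_along(dx)) {
      if (is.na(first_rank[j]) && any_match(codes, dx[j])) {
        first_rank[j] <- top$rank[i]
      }
    }
  }
  det <- !is.na(first_rank)
  top1 <- length(top$codes[[1L]]) > 0L &&
    any(first_rank[det] == top$rank[1L])
  structure(
    list(
      patient_id = record$patient_id,
      top1_match = isTRUE(top1),
      topk_match = any(det),
      k = as.integer(k),
      n_detected = sum(det),
      matched_pairs = data.frame(rank = first_rank[det],
                                 therapist_code = dx[det],
                                 stringsAsFactors = FALSE)
    ),
    class = "match_verdict")
}

#' Evaluate a whole cohort
#'
#' @param records List of [patient_record()]s.
#' @param k Number of top suggestions considered.
#' @return Data frame with one row per patient: `patient_id`,
#'   `top1_match`, `topk_match`, `n_detected`, `n_diagnoses`.
#' @export
evaluate_cohort <- function(records, k = 5L) {
  stopifnot(length(records) > 0L)
  rows <- lapply(records, function(r) {
    v <- evaluate_patient(r, k = k)
    data.frame(patient_id = v$patient_id, top1_match = v$top1_match,
               topk_match = v$topk_match, n_detected = v$n_detected,
               n_diagnoses = length(unique(r$diagnoses)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- as.integer(k)
  out
}

#' Mean number of therapist diagnoses detected per patient
#'
#' @param verdicts A verdict data frame from [evaluate_cohort()].
#' @return Named numeric vector `c(mean = , sd = )` of per-patient
#'   `n_detected`.
#' @export
mean_detected <- function(verdicts) {
  if (is.null(verdicts$n_detected) || nrow(verdicts) == 0L) {
    stop("need a non-empty verdict table with an n_detected column",
         call. = FALSE)
  }
  c(mean = mean(verdicts$n_detected), sd = stats::sd(verdicts$n_detected))
}
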