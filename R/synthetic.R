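# Synthetic cohort generator.
#
# Emulates the statistical structure of an outpatient symptom-checker
# evaluation: ~2 comorbid ICD-10 diagnoses per patient, ~3.4 ranked
# condition suggestions, category prevalences of 33.7% affective / 26.7%
# anxiety / 8.9% somatoform-associated / 30.7% other, and a controllable
# true top-1 / top-5 match probability. Matches are constructed through a
# uniformly chosen matching rule (exact code, severity-level variant,
# recurrent/nonrecurrent depression swap, agoraphobia/panic credit,
# abuse/dependence swap, label-only Burnout or functional-somatic
# suggestions), so every equivalence rule is exercised. Distractor
# suggestions are rejection-sampled against the full rule set and are
# guaranteed not to match any therapist diagnosis.
#
# Count distributions are moment-matched shifted binomials:
# 1 + Binomial(14, 1.06/14) gives diagnoses/patient mean 2.06, SD 0.99;
# 1 + Binomial(5, 2.44/5) gives suggestions/patient mean 3.44, SD 1.12.

default_code_pools <- function() {
  list(
    affective = c("F32.0", "F32.1", "F32.2", "F33.0", "F33.1", "F33.2",
                  "F31.1", "F34.1"),
    anxiety = c("F40.00", "F40.01", "F40.1", "F40.2", "F41.0", "F41.1",
                "F41.2"),
    somatoform_associated = c("F45", "F45.0", "F45.1", "F45.2", "F45.30"),
    other = c("F43.1", "F43.2", "F48.0", "F50.0", "F50.2", "F10.1",
              "F10.2", "F12.1", "F90.0", "F42.1", "F51.0", "F60.31")
  )
}

default_distractor_pool <- function() {
  c("F06.4", "F17.2", "F22.0", "F25.1", "F44.4", "F64.0", "F84.5",
    "F95.1", "G43.0", "I10", "E66.0", "J45.9", "M54.5", "K29.7")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 49 patients, top-1 match
#' probability 0.51, top-5 match probability 0.69, diagnosis and
#' suggestion counts moment-matched to means 2.06 (SD 0.99) and 3.44, and
#' the observed category prevalences.
#'
#' @param n_patients Cohort size (>= 1).
#' @param seed Integer RNG seed (mandatory; same seed + config gives a
#'   byte-identical cohort).
#' @param theta_top1 True probability the rank-1 suggestion matches some
#'   therapist diagnosis.
#' @param theta_top5 True probability some top-5 suggestion matches
#'   (>= `theta_top1`).
#' @param category_prevalence Probability vector over the four disorder
#'   categories (must sum to 1).
#' @param dx_count Shifted-binomial parameters `list(size=, prob=)` for
#'   diagnoses per patient (count = 1 + Binomial).
#' @param sug_count Same for the suggestion-list length.
#' @param code_pools Named list of per-category ICD-10 code vectors.
#' @param distractor_pool Extra codes used only as distractors.
#' @param sus_adj_probs Length-5 probabilities of adjusted SUS item
#'   contributions 0..4 (defaults give mean score about 81.5).
#' @param feedback_agree_probs Per-item probability of an agreeing (3/4)
#'   feedback answer; defaults follow the study's item table.
#' @param missing_rate Fraction of usability cells set missing at random.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_patients = 49L,
                         seed,
                         theta_top1 = 0.51,
                         theta_top5 = 0.69,
                         category_prevalence = c(affective = 0.337,
                                                 anxiety = 0.267,
                                                 somatoform_associated = 0.089,
                                                 other = 0.307),
                         dx_count = list(size = 14L, prob = 1.06 / 14),
                         sug_count = list(size = 5L, prob = 2.44 / 5),
                         code_pools = default_code_pools(),
                         distractor_pool = default_distractor_pool(),
                         sus_adj_probs = c(0.02, 0.04, 0.10, 0.34, 0.50),
                         feedback_agree_probs = c(0.22, 0.69, 0.94, 0.61,
                                                  0.02, 0.76, 0.96, 0.88,
                                                  0.04, 0.06, 0.71),
                         missing_rate = 0) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_patients >= 1L,
            theta_top1 >= 0, theta_top5 <= 1, theta_top1 <= theta_top5,
            abs(sum(category_prevalence) - 1) < 1e-8,
            all(names(category_prevalence) == disorder_categories()),
            missing_rate >= 0, missing_rate < 1)
  if (any(lengths(code_pools) == 0L)) {
    stop("empty code pool for category ",
         paste(names(code_pools)[lengths(code_pools) == 0L], collapse = ", "),
         call. = FALSE)
  }
  lapply(code_pools, parse_icd10)
  parse_icd10(distractor_pool)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         theta_top1 = theta_top1, theta_top5 = theta_top5,
         category_prevalence = category_prevalence,
         dx_count = dx_count, sug_count = sug_count,
         code_pools = code_pools, distractor_pool = distractor_pool,
         sus_adj_probs = sus_adj_probs,
         feedback_agree_probs = feedback_agree_probs,
         missing_rate = missing_rate),
    class = "synth_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file; `seed` is mandatory, all other fields default
#'   as in [synth_config()].
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config field 'seed' is mandatory", call. = FALSE)
  args <- y[intersect(names(y), names(formals(synth_config)))]
  if (!is.null(args$category_prevalence)) {
    args$category_prevalence <- unlist(args$category_prevalence)
  }
  do.call(synth_config, args)
}

# all candidate (code(s), label) pairs that match therapist code `t`
# under some rule; used to instantiate a constructed match
match_options <- function(t, term_map) {
  opts <- list(list(codes = t, label = ""))
  stem <- icd10_stem(t)
  detail <- icd10_detail(t)
  norm_stem <- if (stem == "F33") "F32" else stem
  if (norm_stem %in% c("F32", "F31", "F42", "F91", "F20")) {
    # severity/course variant at the same 3-digit stem
    d <- setdiff(as.character(0:3), detail)[1:2]
    for (dd in d) opts <- c(opts, list(list(codes = paste0(stem, ".", dd),
                                            label = "")))
  }
  if (stem %in% c("F32", "F33")) {
    swap <- paste0(if (stem == "F32") "F33" else "F32",
                   if (nzchar(detail)) paste0(".", detail) else "")
    opts <- c(opts, list(list(codes = swap, label = ""),
                         list(codes = "", label = "Burnout")))
  }
  if (t == "F40.01") {
    opts <- c(opts,
              list(list(codes = "F40.00", label = ""),
                   list(codes = "F41.0", label = ""),
                   list(codes = "", label = "panic disorder"),
                   list(codes = "", label = "agoraphobia")))
  }
  if (substance_stem(stem) && substr(detail, 1L, 1L) %in% c("1", "2")) {
    flipped <- paste0(stem, ".", chartr("12", "21", substr(detail, 1L, 1L)),
                      substring(detail, 2L))
    opts <- c(opts, list(list(codes = flipped, label = "")))
  }
  if (t == "F45") {
    opts <- c(opts, list(list(codes = "", label = "irritable bowel syndrome"),
                         list(codes = "", label = "fibromyalgia")))
  }
  opts
}

sample_one <- function(x) x[[sample.int(length(x), 1L)]]

#' Generate a synthetic patient cohort
#'
#' Reproducible given the config seed. Constructed matches instantiate a
#' uniformly chosen matching rule; all other suggestions are distractors
#' rejection-sampled to be non-matching under the complete rule set, and
#' no two therapist diagnoses of one patient are mutually equivalent, so
#' a patient's `n_detected` is exactly the indicator of a constructed
#' match.
#'
#' @param config A [synth_config()].
#' @param term_map Term map used for label-only constructed suggestions.
#' @return List of [patient_record()]s.
#' @export
generate_cohort <- function(config, term_map = default_term_map()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      generate_patient(sprintf("S%04d", i), config, term_map)
    })
  })
}

generate_patient <- function(id, config, term_map) {
  cats <- disorder_categories()
  pools <- config$code_pools

  # therapist diagnoses: mutually non-equivalent under the matching rules
  n_dx <- 1L + stats::rbinom(1L, config$dx_count$size, config$dx_count$prob)
  dx <- character(0)
  guard <- 0L
  while (length(dx) < n_dx && guard < 200L) {
    guard <- guard + 1L
    cat_i <- sample(cats, 1L, prob = config$category_prevalence)
    # keep the drawn category (so marginal prevalences are honored) and
    # look for a code not equivalent to an existing diagnosis; redraw the
    # category only if the pool's equivalence classes are exhausted
    pool <- sample(pools[[cat_i]])
    for (cand in pool) {
      if (length(dx) == 0L ||
          !any(codes_match(cand, dx) | codes_match(dx, cand))) {
        dx <- c(dx, cand)
        break
      }
    }
  }

  # suggestion slots and match placement
  n_sug <- 1L + stats::rbinom(1L, config$sug_count$size, config$sug_count$prob)
  u <- stats::runif(1L)
  if (u < config$theta_top1) {
    match_rank <- 1L
  } else if (u < config$theta_top5) {
    # uniform over ranks 2..5, clipped to the drawn list length so the
    # suggestion-count distribution is not inflated
    if (n_sug < 2L) n_sug <- 2L
    slots <- 2:min(5L, n_sug)
    match_rank <- slots[sample.int(length(slots), 1L)]
  } else {
    match_rank <- NA_integer_
  }

  code_col <- character(n_sug)
  label_col <- character(n_sug)
  used <- character(0)
  if (!is.na(match_rank)) {
    target <- sample(dx, 1L)
    opt <- sample_one(match_options(target, term_map))
    code_col[match_rank] <- opt$codes
    label_col[match_rank] <- opt$label
    oc <- if (nzchar(opt$codes)) opt$codes
          else map_label(opt$label, term_map, quiet = TRUE)
    stopifnot(any_match(oc, target))  # generator self-check
    used <- oc
  }
  for (r in seq_len(n_sug)) {
    if (!is.na(match_rank) && r == match_rank) next
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 500L) stop("distractor sampling failed; pools too small",
                             call. = FALSE)
      cand <- sample(c(unlist(pools, use.names = FALSE),
                       config$distractor_pool), 1L)
      if (!cand %in% used && !any(codes_match(cand, dx))) break
    }
    code_col[r] <- cand
    used <- c(used, cand)
  }

  main_n <- min(n_sug, sample(2:4, 1L))
  prob_num <- pmin(10L, pmax(1L, 9L - 2L * (seq_len(n_sug) - 1L) +
                               sample(-1:1, n_sug, replace = TRUE)))
  sug <- suggestion_frame(code = code_col, label = label_col,
                          probability = prob_num,
                          less_probable = seq_len(n_sug) > main_n,
                          term_map = term_map)
  patient_record(id, diagnoses = dx, suggestions = sug)
}

#' Generate synthetic usability questionnaires
#'
#' SUS items are drawn independently from the configured adjusted-score
#' distribution (odd items raw = adjusted + 1, even items raw = 5 -
#' adjusted, on the 1-5 convention); feedback items are drawn with the
#' configured per-item agreement probabilities. Per item,
#' `round(missing_rate * n)` cells are set missing at random rows, so no
#' item exceeds the configured missingness fraction.
#'
#' @param config A [synth_config()].
#' @return List with matrices `sus` (n x 10, values 1-5) and `feedback`
#'   (n x number of feedback items, values 1-4), `NA` where missing.
#' @export
generate_usability <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_patients
    adj <- matrix(sample(0:4, n * 10L, replace = TRUE,
                         prob = config$sus_adj_probs), n, 10L)
    sus <- adj
    odd <- seq(1L, 9L, 2L)
    even <- seq(2L, 10L, 2L)
    sus[, odd] <- adj[, odd] + 1L
    sus[, even] <- 5L - adj[, even]
    colnames(sus) <- paste0("sus_", 1:10)

    p <- config$feedback_agree_probs
    fb <- sapply(p, function(pi) {
      agree <- stats::runif(n) < pi
      ifelse(agree, sample(3:4, n, replace = TRUE, prob = c(0.6, 0.4)),
             sample(1:2, n, replace = TRUE, prob = c(0.3, 0.7)))
    })
    colnames(fb) <- paste0("fb_", seq_along(p))

    if (config$missing_rate > 0) {
      # per item, round(rate * n) cells at random rows: keeps every item
      # at or below the configured missingness fraction
      k <- round(config$missing_rate * n)
      if (k > 0) {
        for (j in seq_len(ncol(sus))) sus[sample.int(n, k), j] <- NA
        for (j in seq_len(ncol(fb))) fb[sample.int(n, k), j] <- NA
      }
    }
    list(sus = sus, feedback = fb)
  })
}

#' Coverage experiment for the top-1 accuracy interval
#'
#' Repeatedly generates a cohort, runs the full matching pipeline, and
#' checks whether the Agresti-Coull interval for top-1 agreement covers
#' the generating `theta_top1`.
#'
#' @param config A [synth_config()]; replicate r uses seed `seed + r`.
#' @param n_replicates Number of replicates (>= 1).
#' @param conf_level Confidence level of the interval under test.
#' @param term_map Term map passed to the generator.
#' @return List with `n_replicates`, `coverage` (empirical CI coverage of
#'   `theta_top1`), `mae` (mean absolute error of the top-1 estimate),
#'   and the per-replicate `estimates`.
#' @export
run_recovery <- function(config, n_replicates, conf_level = 0.95,
                         term_map = default_term_map()) {
  stopifnot(inherits(config, "synth_config"), n_replicates >= 1L)
  cover <- logical(n_replicates)
  est <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    cohort <- generate_cohort(cfg, term_map)
    oc <- overall_concordance(evaluate_cohort(cohort), conf_level)$top1
    cover[r] <- oc$ci_low <= config$theta_top1 &&
      config$theta_top1 <= oc$ci_high
    est[r] <- oc$p_hat
  }
  list(n_replicates = n_replicates,
       theta_top1 = config$theta_top1,
       coverage = mean(cover),
       mae = mean(abs(est - config$theta_top1)),
       estimates = est)
}
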