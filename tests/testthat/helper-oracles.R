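# Independent reference implementations used only as test oracles.
# Deliberately written as literal rule-by-rule enumeration, not sharing
# code with the package.

# brute-force matching oracle: tries each rule in turn on a single pair
oracle_codes_match <- function(s, t) {
  canon <- function(x) toupper(gsub(" ", "", x))
  s <- canon(s); t <- canon(t)
  stem <- function(x) substr(x, 1, 3)
  detail <- function(x) if (nchar(x) > 4) substring(x, 5) else ""
  dep <- function(x) if (stem(x) %in% c("F32", "F33")) {
    paste0("F32", if (nzchar(detail(x))) paste0(".", detail(x)) else "")
  } else x
  # rule a (with recurrent/nonrecurrent fold)
  if (dep(s) == dep(t)) return(TRUE)
  # rule b: 3-digit exceptions
  exc <- c("F32", "F33", "F31", "F42", "F91", "F20")
  if (stem(s) %in% exc && stem(t) %in% exc &&
      stem(dep(s)) == stem(dep(t))) return(TRUE)
  # rule d: therapist F40.01
  if (t == "F40.01") {
    if (s == "F41.0") return(TRUE)
    if (stem(s) == "F40" && nzchar(detail(s)) &&
        substr(detail(s), 1, 1) == "0") return(TRUE)
  }
  # rule e: abuse vs dependence within one substance stem
  num <- suppressWarnings(as.integer(substr(stem(s), 2, 3)))
  if (!is.na(num) && substr(s, 1, 1) == "F" && num >= 10 && num <= 19 &&
      stem(s) == stem(t)) {
    d1s <- substr(detail(s), 1, 1); d1t <- substr(detail(t), 1, 1)
    if (d1s %in% c("1", "2") && d1t %in% c("1", "2")) return(TRUE)
  }
  FALSE
}

# AC1 recomputed from raw per-subject binary vectors (therapist, checker)
oracle_ac1_from_vectors <- function(rater1, rater2) {
  n <- length(rater1)
  pa <- mean(rater1 == rater2)
  p1 <- mean(rater1)
  p2 <- mean(rater2)
  pi1 <- (p1 + p2) / 2
  pe <- 2 * pi1 * (1 - pi1)
  (pa - pe) / (1 - pe)
}

# leave-one-subject-out jackknife variance of AC1
oracle_ac1_jackknife <- function(rater1, rater2) {
  n <- length(rater1)
  loo <- vapply(seq_len(n), function(i) {
    oracle_ac1_from_vectors(rater1[-i], rater2[-i])
  }, numeric(1))
  (n - 1) / n * sum((loo - mean(loo))^2)
}

# independent Cohen's kappa from binary vectors
oracle_cohen_kappa <- function(rater1, rater2) {
  po <- mean(rater1 == rater2)
  pe <- mean(rater1) * mean(rater2) +
    (1 - mean(rater1)) * (1 - mean(rater2))
  (po - pe) / (1 - pe)
}

# turn a 2x2 count table into raw binary rating vectors
table_to_vectors <- function(tp, fp, fn, tn) {
  list(
    therapist = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn)),
    checker = c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  )
}

# random non-degenerate 2x2 table, n between 10 and 200
random_table <- function() {
  repeat {
    n <- sample(10:200, 1)
    p <- rexp(4)
    tab <- as.vector(stats::rmultinom(1, n, p / sum(p)))
    pi1 <- ((tab[1] + tab[3]) / n + (tab[1] + tab[2]) / n) / 2
    if (2 * pi1 * (1 - pi1) == 1) next
    return(list(tp = tab[1], fp = tab[2], fn = tab[3], tn = tab[4], n = n))
  }
}

fixture_cohort <- function() {
  read_cohort(system.file("extdata", "synthetic_cohort_6.csv",
                          package = "dxconcord", mustWork = TRUE))
}
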