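test_that("the enumerated matching rules hold, positive and negative", {
  # (a) exact 4-digit equality is the default
  expect_true(codes_match("F40.1", "F40.1"))
  expect_false(codes_match("F40.1", "F40.2"))
  expect_false(codes_match("F43.1", "F43.2"))
  # (b) 3-digit precision inside the exception set
  expect_true(codes_match("F32.1", "F32.8"))
  expect_true(codes_match("F31.1", "F31.6"))
  expect_true(codes_match("F42.0", "F42.1"))
  expect_true(codes_match("F91.1", "F91.2"))
  expect_true(codes_match("F20.0", "F20.5"))
  expect_false(codes_match("F45.1", "F45.2"))  # F45 not in the set
  # (c) recurrent depression equals the nonrecurrent category
  expect_true(codes_match("F32.2", "F33.2"))
  expect_true(codes_match("F33.0", "F32.1"))   # via 3-digit rule after fold
  expect_false(codes_match("F34.1", "F32.1"))
  # (d) agoraphobia with panic disorder, therapist side only
  expect_true(codes_match("F41.0", "F40.01"))
  expect_true(codes_match("F40.00", "F40.01"))
  expect_true(codes_match("F40.0", "F40.01"))
  expect_false(codes_match("F40.2", "F40.01"))
  expect_false(codes_match("F40.01", "F41.0"))  # asymmetric by design
  # (e) abuse equals dependence within one substance stem
  expect_true(codes_match("F10.1", "F10.2"))
  expect_true(codes_match("F15.1", "F15.2"))
  expect_true(codes_match("F10.2", "F10.25"))
  expect_false(codes_match("F10.1", "F11.2"))
  expect_false(codes_match("F10.0", "F10.1"))
})

test_that("codes_match is reflexive and symmetric except for the F40.01 rule", {
  pool <- c("F32", "F32.1", "F33.2", "F40.01", "F40.1", "F41.0", "F10.1",
            "F10.2", "F45.1", "F20.3", "G43.0")
  expect_true(all(codes_match(pool, pool)))
  for (a in pool) for (b in pool) {
    if (a != "F40.01" && b != "F40.01") {
      expect_equal(codes_match(a, b), codes_match(b, a),
                   info = paste(a, b))
    }
  }
})

test_that("codes_match agrees with a brute-force rule enumeration", {
  pool <- c("F32", "F32.0", "F32.2", "F33.0", "F33.2", "F31.1", "F31.6",
            "F42.0", "F42.1", "F91.1", "F20.0", "F20.5", "F40.0", "F40.00",
            "F40.01", "F40.1", "F40.2", "F41.0", "F41.1", "F10.1", "F10.2",
            "F10.25", "F11.2", "F15.1", "F45", "F45.1", "F45.2", "F34.1",
            "F43.1", "G43.0", "I10")
  set.seed(11)
  for (i in 1:500) {
    s <- sample(pool, 1)
    t <- sample(pool, 1)
    expect_equal(codes_match(s, t), oracle_codes_match(s, t),
                 info = paste(s, "vs", t))
  }
})

make_record <- function(id, dx, codes, lp = rep(FALSE, length(codes))) {
  patient_record(id, dx,
                 suggestion_frame(codes, less_probable = lp))
}

test_that("top-1 and top-k verdicts follow the rank window", {
  # rank-1 panic disorder suggestion against agoraphobia with panic
  r <- patient_record("A", c("F40.01", "F40.2"),
                      suggestion_frame(c("", "F45.0"),
                                       label = c("panic disorder", "")))
  v <- evaluate_patient(r)
  expect_true(v$top1_match)
  expect_true(v$topk_match)
  expect_equal(v$n_detected, 1L)
  expect_equal(v$matched_pairs$therapist_code, "F40.01")

  # sole match at combined rank 5 via the less-probable fill
  r2 <- make_record("B", "F41.1",
                    c("F43.1", "F50.0", "F45.0", "F40.1", "F41.1"),
                    lp = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  v2 <- evaluate_patient(r2)
  expect_false(v2$top1_match)
  expect_true(v2$topk_match)
  expect_equal(v2$matched_pairs$rank, 5L)

  # a match beyond the top-k window does not count
  r3 <- make_record("C", "F41.1",
                    c("F43.1", "F50.0", "F45.0", "F40.1", "F22.0", "F41.1"),
                    lp = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_false(evaluate_patient(r3, k = 5)$topk_match)
  expect_true(evaluate_patient(r3, k = 6)$topk_match)

  # disjoint codes everywhere
  v4 <- evaluate_patient(make_record("D", "F60.31", c("F32.1", "F41.0")))
  expect_false(v4$top1_match)
  expect_false(v4$topk_match)
  expect_equal(v4$n_detected, 0L)
})

test_that("top-1 is invariant in k and top-k is monotone in k", {
  set.seed(21)
  cfg <- synth_config(n_patients = 40, seed = 77, theta_top1 = 0.4,
                      theta_top5 = 0.7)
  cohort <- generate_cohort(cfg)
  for (rec in cohort[1:15]) {
    prev <- FALSE
    for (k in 1:6) {
      v <- evaluate_patient(rec, k = k)
      expect_equal(v$top1_match, evaluate_patient(rec, k = 1)$top1_match)
      expect_true(v$topk_match >= prev)
      if (v$top1_match) expect_true(v$topk_match)
      expect_true(v$n_detected <= length(unique(rec$diagnoses)))
      prev <- v$topk_match
    }
  }
})

test_that("duplicate therapist codes are deduplicated in n_detected", {
  r <- patient_record("A", c("F32.1", "F32.1"),
                      suggestion_frame("F32.1"))
  v <- evaluate_patient(r)
  expect_equal(v$n_detected, 1L)
})

test_that("an empty suggestion list warns and yields a negative verdict", {
  r <- patient_record("A", "F32.1")
  expect_warning(v <- evaluate_patient(r), "no condition suggestions")
  expect_false(v$top1_match)
  expect_false(v$topk_match)
})

test_that("mean detected diagnoses is the sample mean and SD", {
  verdicts <- data.frame(n_detected = c(0, 1, 2))
  md <- mean_detected(verdicts)
  expect_equal(md[["mean"]], 1)
  expect_equal(md[["sd"]], 1)
  expect_equal(mean_detected(data.frame(n_detected = rep(2, 5)))[["sd"]], 0)
  expect_error(mean_detected(data.frame(n_detected = numeric(0))), "empty")
})

test_that("record invariants are enforced", {
  expect_error(patient_record("A", character(0)), "empty")
  sug <- suggestion_frame(c("F32.1", "F33.0"))
  sug$rank <- c(1L, 1L)
  expect_error(patient_record("A", "F32.1", sug), "unique")
  sug2 <- suggestion_frame(c("F32.1", "F33.0", "F41.0"),
                           less_probable = c(FALSE, TRUE, FALSE))
  expect_error(patient_record("A", "F32.1", sug2), "precede")
})
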