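test_that("the same seed and config give an identical cohort", {
  cfg <- synth_config(n_patients = 25, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synth_config(n_patients = 25, seed = 102))
  expect_false(identical(a, c2))
})

test_that("theta extremes force the corresponding verdicts", {
  all_hit <- generate_cohort(synth_config(n_patients = 30, seed = 7,
                                          theta_top1 = 1, theta_top5 = 1))
  v <- evaluate_cohort(all_hit)
  expect_true(all(v$top1_match))

  none <- generate_cohort(synth_config(n_patients = 30, seed = 7,
                                       theta_top1 = 0, theta_top5 = 0))
  v0 <- evaluate_cohort(none)
  expect_false(any(v0$topk_match))
  expect_true(all(v0$n_detected == 0))
})

test_that("distractors never match any therapist diagnosis", {
  # the generator's hardest guarantee: verified exhaustively per cohort
  cfg <- synth_config(n_patients = 80, seed = 31, theta_top1 = 0,
                      theta_top5 = 0)
  cohort <- generate_cohort(cfg)
  for (rec in cohort) {
    for (codes in rec$suggestions$codes) {
      for (code in codes) {
        expect_false(any(codes_match(code, rec$diagnoses)),
                     info = paste(rec$patient_id, code))
      }
    }
  }
})

test_that("constructed matches satisfy the rules and land at their rank", {
  cfg <- synth_config(n_patients = 120, seed = 13, theta_top1 = 0.5,
                      theta_top5 = 1)
  cohort <- generate_cohort(cfg)
  v <- evaluate_cohort(cohort)
  expect_true(all(v$topk_match))         # theta_top5 = 1 by construction
  expect_true(all(v$n_detected == 1))    # one non-equivalent match each
})

test_that("cohort moments approach the configured study conditions", {
  cfg <- synth_config(n_patients = 4000, seed = 19)
  cohort <- generate_cohort(cfg)
  n_dx <- vapply(cohort, function(r) length(r$diagnoses), numeric(1))
  n_sug <- vapply(cohort, function(r) nrow(r$suggestions), numeric(1))
  # mean 2.06 and 3.44 within 4 sigma / sqrt(n)
  expect_lt(abs(mean(n_dx) - 2.06), 4 * 0.99 / sqrt(4000))
  expect_lt(abs(mean(n_sug) - 3.44), 4 * 1.2 / sqrt(4000) + 0.05)
  expect_lt(abs(sd(n_dx) - 0.99), 0.1)

  cats <- icd10_category(unlist(lapply(cohort, `[[`, "diagnoses")))
  prev <- table(factor(cats, disorder_categories())) / length(cats)
  expect_lt(max(abs(prev - c(0.337, 0.267, 0.089, 0.307))), 0.03)
})

test_that("the measured top-1 rate sits inside the binomial band", {
  n <- 4000
  cfg <- synth_config(n_patients = n, seed = 23, theta_top1 = 0.5,
                      theta_top5 = 0.7)
  v <- evaluate_cohort(generate_cohort(cfg))
  # 99.9% two-sided binomial band around 0.5
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5) / n
  p1 <- mean(v$top1_match)
  expect_true(p1 >= band[1] && p1 <= band[2])
  pk <- mean(v$topk_match)
  bandk <- qbinom(c(5e-4, 1 - 5e-4), n, 0.7) / n
  expect_true(pk >= bandk[1] && pk <= bandk[2])
})

test_that("usability generation respects seed, convention and missingness", {
  cfg <- synth_config(n_patients = 49, seed = 41)
  u1 <- generate_usability(cfg)
  u2 <- generate_usability(cfg)
  expect_identical(u1, u2)
  expect_true(all(u1$sus >= 1 & u1$sus <= 5))
  expect_true(all(u1$feedback %in% 1:4))
  expect_false(anyNA(u1$sus))

  cfg_m <- synth_config(n_patients = 49, seed = 41, missing_rate = 0.04)
  um <- generate_usability(cfg_m)
  expect_gt(sum(is.na(um$sus)) + sum(is.na(um$feedback)), 0)
  expect_identical(um, generate_usability(cfg_m))

  # degenerate all-agree distribution scores 100 for every respondent
  cfg_top <- synth_config(n_patients = 10, seed = 5,
                          sus_adj_probs = c(0, 0, 0, 0, 1))
  expect_equal(score_sus(generate_usability(cfg_top)$sus), rep(100, 10))
})

test_that("config validation rejects bad inputs", {
  expect_error(synth_config(n_patients = 10), "seed")
  expect_error(synth_config(seed = 1, theta_top1 = 0.8, theta_top5 = 0.5))
  expect_error(synth_config(seed = 1,
                            category_prevalence = c(affective = 1, anxiety = 1,
                                                    somatoform_associated = 0,
                                                    other = 0)))
  pools <- default_code_pools()
  pools$anxiety <- character(0)
  expect_error(synth_config(seed = 1, code_pools = pools), "empty code pool")
})

test_that("YAML configs round-trip with mandatory seed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 11", "n_patients: 12", "theta_top1: 0.3",
               "theta_top5: 0.6"), path)
  cfg <- read_synth_config(path)
  expect_equal(cfg$seed, 11L)
  expect_equal(cfg$n_patients, 12L)
  expect_identical(generate_cohort(cfg),
                   generate_cohort(synth_config(n_patients = 12, seed = 11,
                                                theta_top1 = 0.3,
                                                theta_top5 = 0.6)))
  writeLines("n_patients: 5", path)
  expect_error(read_synth_config(path), "seed")
})

test_that("recovery experiments estimate without bias at theta zero", {
  cfg <- synth_config(n_patients = 20, seed = 3, theta_top1 = 0,
                      theta_top5 = 0)
  rec <- run_recovery(cfg, n_replicates = 5)
  expect_equal(rec$estimates, rep(0, 5))
  expect_equal(rec$mae, 0)
})
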