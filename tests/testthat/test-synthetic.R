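rs <- read_rules()

test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(c("A", "B"), 15, producer_prob = 0.5,
                      noise = 0.2, transporter_prob = 0.3, seed = 99)
  c1 <- generate_cohort(spec, rs)
  c2 <- generate_cohort(spec, rs)
  expect_identical(c1, c2)
  # and the generator does not disturb the global RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(spec, rs)); after <- runif(1)
  expect_identical(before, after)
})

test_that("forced producer/non-producer probabilities yield exact truths", {
  all_on <- cohort_spec("P", 6, producer_prob = 1, seed = 2)
  co <- generate_cohort(all_on, rs)
  preds <- predict_cohort(co$matrix, rs)
  expect_true(all(unlist(preds[bvitamins()])))

  all_off <- cohort_spec("P", 6, producer_prob = 0, seed = 3)
  co0 <- generate_cohort(all_off, rs)
  preds0 <- predict_cohort(co0$matrix, rs)
  expect_false(any(unlist(preds0[bvitamins()])))
})

test_that("predictions recover the planted truth, even under tolerated noise", {
  spec <- cohort_spec(c("A", "B", "C"), 20, producer_prob = 0.5,
                      noise = 0.5, seed = 17)
  co <- generate_cohort(spec, rs)
  preds <- predict_cohort(co$matrix, rs)
  for (v in bvitamins())
    expect_equal(preds[[v]], co$truth[[v]], label = v)
})

test_that("planted prevalence is recovered within binomial bounds", {
  spec <- cohort_spec(c("A", "B"), 100, producer_prob = 0.4, seed = 7)
  co <- generate_cohort(spec, rs)
  frac <- mean(co$truth$biotin)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 200))
})

test_that("non-producers can carry the vitamin transporter", {
  spec <- cohort_spec("P", 40, producer_prob = 0,
                      transporter_prob = 1, seed = 23)
  co <- generate_cohort(spec, rs)
  # every non-producer genome carries the transporters at prob 1
  expect_true(all(co$matrix[, "BioY"] == 1L))
  expect_true(all(co$matrix[, "RibU"] == 1L))
  spec0 <- cohort_spec("P", 40, producer_prob = 0,
                       transporter_prob = 0, seed = 23)
  co0 <- generate_cohort(spec0, rs)
  expect_true(all(co0$matrix[, "BioY"] == 0L))
  # transporters never rescue a producer call
  expect_false(any(unlist(predict_cohort(co$matrix, rs)[bvitamins()])))
})

test_that("planted complement pairs are detected exactly", {
  pats <- c("11110000", "10101010", "11011011")
  co <- plant_pattern_pairs(pats, counts_a = c(5, 2, 1),
                            counts_b = c(2, 2, 4), rules = rs, seed = 31)
  preds <- predict_cohort(co$matrix, rs)
  cen <- pattern_census(preds, "planted")
  pairs <- inversed_pairs(cen)
  expect_equal(nrow(pairs), 3L)
  row <- pairs[pairs$pattern_a == "00001111" |
                 pairs$pattern_b == "00001111", ]
  expect_setequal(c(row$count_a, row$count_b), c(5L, 2L))

  # all-distinct, non-complementary patterns -> zero pairs
  co0 <- cohort_from_patterns(c("11111111", "11111110", "11111100"),
                              counts = 2, rules = rs, seed = 5)
  cen0 <- pattern_census(predict_cohort(co0$matrix, rs))
  expect_equal(nrow(inversed_pairs(cen0)), 0L)

  expect_error(plant_pattern_pairs(c("11110000", "00001111"), seed = 1),
               "complement")
  expect_error(plant_pattern_pairs(c("11110000", "11110000"), seed = 1),
               "distinct")
})

test_that("generated evidence flips truth at the requested error rate", {
  spec <- cohort_spec("P", 30, producer_prob = 0.5, seed = 41)
  co <- generate_cohort(spec, rs)
  preds <- predict_cohort(co$matrix, rs)

  ev0 <- generate_evidence(co$truth, n_strains = 16, error_rate = 0,
                           seed = 1)
  expect_equal(score_concordance(preds, ev0)$fraction, 1.0)

  ev1 <- generate_evidence(co$truth, n_strains = 16, error_rate = 1,
                           seed = 1)
  expect_equal(score_concordance(preds, ev1)$fraction, 0.0)

  # mean concordance over seeds ~ 1 - error_rate (the reported 88% scale)
  fracs <- vapply(1:30, function(s) {
    ev <- generate_evidence(co$truth, n_strains = 16, error_rate = 0.12,
                            seed = s)
    score_concordance(preds, ev)$fraction
  }, numeric(1))
  se <- sqrt(0.12 * 0.88 / (30 * 128))
  expect_lt(abs(mean(fracs) - 0.88), 4 * se)

  expect_error(generate_evidence(co$truth, n_strains = 31, seed = 1),
               "exceeds")
})

test_that("cohort_spec validates its probabilities and seed", {
  expect_error(cohort_spec("A", 5, producer_prob = 1.2, seed = 1),
               "\\[0, 1\\]")
  expect_error(cohort_spec("A", 5, producer_prob = 0.5), "seed")
  pp <- matrix(0.5, 2, 8)
  expect_silent(cohort_spec(c("A", "B"), 5, pp, seed = 1))
  expect_error(cohort_spec(c("A", "B"), 5, matrix(0.5, 3, 8), seed = 1),
               "matrix")
})
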