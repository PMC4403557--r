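rs <- read_rules()

test_that("rule evaluation follows the essential-role combinations", {
  # either biotin route suffices
  expect_true(evaluate_rule(c("BioC", "BioFADB"), rs$rules$biotin)$producer)
  expect_true(evaluate_rule(c("BioW", "BioFADB"), rs$rules$biotin)$producer)
  expect_false(evaluate_rule("BioFADB", rs$rules$biotin)$producer)
  expect_false(evaluate_rule(character(), rs$rules$biotin)$producer)

  # pantothenate: one branched-pathway enzyme may be missing...
  pan_all <- c("KPHMT", "KPRED", "ASPDC", "PBAL", "PANK", "PPCS",
               "PPCDC", "DPCK")
  res <- evaluate_rule(setdiff(pan_all, "ASPDC"), rs$rules$pantothenate)
  expect_true(res$producer)
  expect_equal(res$provenance, "tolerance:1")
  # ...but two may not, and PBAL absence always vetoes
  expect_false(evaluate_rule(setdiff(pan_all, c("ASPDC", "KPHMT")),
                             rs$rules$pantothenate)$producer)
  expect_false(evaluate_rule(setdiff(pan_all, "PBAL"),
                             rs$rules$pantothenate)$producer)

  # no rule is satisfied by an empty genome
  for (r in rs$rules)
    expect_false(evaluate_rule(character(), r)$producer)
})

test_that("brute-force oracle matches hand-enumerated truth tables", {
  conj <- rules_from_yaml(c("vitamins:", "  biotin:",
                            "    lines: ['A + B']"))
  tt <- brute_force_oracle(conj$rules$biotin)
  expect_equal(nrow(tt), 4L)
  expect_equal(sum(tt$producer), 1L)

  orr <- rules_from_yaml(c("vitamins:", "  biotin:",
                           "    lines: ['(A or B) + C']"))
  tt2 <- brute_force_oracle(orr$rules$biotin)
  expect_equal(nrow(tt2), 8L)
  expect_equal(sum(tt2$producer), 3L)

  expect_error(brute_force_oracle(conj$rules$biotin,
                                  universe = sprintf("r%d", 1:21)),
               "too large")
})

test_that("rule engine agrees with the oracle on sampled presence vectors", {
  # the exhaustive sweep over every rule's full universe lives in the
  # acceptance suite; here a random sample per rule keeps unit runs fast
  set.seed(101)
  for (v in names(rs$rules)) {
    rule <- rs$rules[[v]]
    universe <- rule_universe(rule, rs$subsets)
    tt <- brute_force_oracle(rule, universe, rs$subsets)
    rows <- sample(nrow(tt), min(nrow(tt), 300))
    engine <- vapply(rows, function(k) {
      present <- expand_presence(universe[tt[k, universe] == 1],
                                 rs$subsets)
      evaluate_rule(present, rule)$producer
    }, logical(1))
    expect_equal(engine, tt$producer[rows],
                 label = paste("engine calls for", v))
  }
})

test_that("adding roles never flips a producer to non-producer", {
  set.seed(7)
  for (v in names(rs$rules)) {
    rule <- rs$rules[[v]]
    universe <- rule_universe(rule, rs$subsets)
    for (k in 1:50) {
      base <- universe[runif(length(universe)) < 0.5]
      extra <- unique(c(base, sample(universe, 1)))
      before <- evaluate_rule(expand_presence(base, rs$subsets),
                              rule)$producer
      after <- evaluate_rule(expand_presence(extra, rs$subsets),
                             rule)$producer
      expect_true(!before || after)
    }
  }
})

test_that("cohort prediction covers every call with provenance", {
  all_roles <- sort(unique(unlist(lapply(rs$rules, rule_universe,
                                         subsets = rs$subsets))))
  m <- role_matrix(matrix(1L, 1, length(all_roles),
                          dimnames = list("gAll", all_roles)))
  preds <- predict_cohort(m, rs)
  expect_true(all(unlist(preds[bvitamins()])))
  prov <- unlist(preds[paste0("provenance_", bvitamins())])
  expect_true(all(grepl("^line:", prov)))
  # cobalamin provenance records the first satisfied line in config order
  expect_equal(preds$provenance_cobalamin, "line:1")
})

test_that("curation overrides take precedence and are flagged", {
  # genome missing BioC entirely, like a strain whose relatives all carry it
  m <- role_matrix(matrix(
    c(1L, 1L, 1L, 1L), 1, 4,
    dimnames = list("gD11", c("BioF", "BioA", "BioD", "BioB"))))
  base <- predict_cohort(m, rs)
  expect_false(base$biotin)
  over <- data.frame(genome_id = "gD11", vitamin = "biotin",
                     verdict = "producer",
                     justification = "all related genomes contain BioC")
  fixed <- predict_cohort(m, rs, overrides = over)
  expect_true(fixed$biotin)
  expect_equal(fixed$provenance_biotin, "override")

  expect_error(predict_cohort(m, rs, overrides = transform(
    over, genome_id = "nope")), "not in the matrix")
  expect_error(predict_cohort(m, rs, overrides = transform(
    over, justification = " ")), "justification")
})

test_that("role and producer prevalence tally fractions by taxon", {
  m <- role_matrix(matrix(
    c(1L, 1L, 1L, 0L,  0L, 0L, 0L, 0L), 4, 2,
    dimnames = list(sprintf("g%d", 1:4), c("BioG", "BioH"))))
  tax <- make_taxonomy(sprintf("g%d", 1:4), phylum = "Bacteroidetes")
  prev <- role_prevalence(m, tax, c("BioG", "BioH"), rank = "phylum")
  expect_equal(prev$fraction[prev$id == "BioG"], 0.75)
  expect_equal(prev$fraction[prev$id == "BioH"], 0)

  # producer fractions: 4 of 10 biotin producers -> 0.40 over the cohort
  calls <- matrix(FALSE, 10, 8,
                  dimnames = list(sprintf("g%02d", 1:10), NULL))
  calls[1:4, 1] <- TRUE      # biotin producers
  calls[, 7] <- TRUE         # everyone makes riboflavin
  preds <- make_predictions(calls)
  tax10 <- make_taxonomy(preds$genome_id)
  prev10 <- producer_prevalence(preds, tax10, rank = "cohort")
  expect_equal(prev10$fraction[prev10$vitamin == "biotin"], 0.40)
  expect_equal(prev10$fraction[prev10$vitamin == "riboflavin"], 1.0)
  expect_equal(prev10$fraction[prev10$vitamin == "thiamin"], 0)

  # genomes without a taxon assignment drop out with a warning
  tax_part <- tax10[1:8, ]
  expect_warning(p <- producer_prevalence(preds, tax_part, rank = "phylum"),
                 "excluded")
  expect_equal(unique(p$n_genomes), 8L)
})

test_that("prevalence of a planted probability lands within binomial error", {
  spec <- cohort_spec("Phylum1", 200, producer_prob = 0.5, seed = 11)
  cohort <- generate_cohort(spec, rs)
  preds <- predict_cohort(cohort$matrix, rs)
  prev <- producer_prevalence(preds, cohort$taxonomy, rank = "phylum")
  se3 <- 3 * sqrt(0.5 * 0.5 / 200)
  expect_true(all(abs(prev$fraction - 0.5) <= se3))
})
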