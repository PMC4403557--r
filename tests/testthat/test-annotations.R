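test_that("role matrix TSV round-trips and validates dimensions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tBioF\tBioB\tBioC\tpabAc",
               "g1\t1\t0\t1\t1",
               "g2\t0\t0\t0\t1",
               "g3\t1\t1\t1\t0"), path)
  m <- read_role_matrix(path)
  expect_s3_class(m, "role_matrix")
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(rownames(m), c("g1", "g2", "g3"))
  expect_equal(unname(m["g1", ]), c(1L, 0L, 1L, 1L))

  # property: write -> read is the identity on random binary matrices
  set.seed(42)
  for (k in 1:5) {
    orig <- random_role_matrix(20, 30)
    out <- withr::local_tempfile(fileext = ".tsv")
    write_role_matrix(orig, out)
    expect_equal(read_role_matrix(out), orig)
  }
})

test_that("degenerate and malformed role matrices are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tBioF\tBioB", path)
  empty <- read_role_matrix(path)
  expect_equal(dim(empty), c(0L, 2L))

  writeLines(c("genome_id\tBioF", "g1\t1", "g1\t0"), path)
  expect_error(read_role_matrix(path), "duplicate genome id: g1")

  writeLines(c("genome_id\tBioF\tBioB", "g1\t1\t2"), path)
  expect_error(read_role_matrix(path), "non-binary cell.*g1.*BioB")

  expect_error(role_matrix(matrix(1, 1, 2, dimnames = list("g1",
    c("A", "A")))), "duplicate role id: A")
})

test_that("taxonomy reader preserves ranks and tolerates blanks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\tname\tphylum\tclass\torder\tfamily\tcohort",
    "g1\tBacteroides sp.\tBacteroidetes\tBacteroidia\t\t\tHGM",
    "g2\tFaecalibacterium sp.\tFirmicutes\tClostridia\tClostridiales\t\tHGM"),
    path)
  tax <- read_taxonomy(path)
  expect_equal(nrow(tax), 2L)
  expect_equal(tax$phylum, c("Bacteroidetes", "Firmicutes"))
  expect_equal(tax$family, c("", ""))   # missing ranks stored empty

  writeLines("genome_id\tname\tphylum\tclass\torder\tfamily\tcohort", path)
  expect_equal(nrow(read_taxonomy(path)), 0L)

  writeLines(c(
    "genome_id\tname\tphylum\tclass\torder\tfamily\tcohort",
    "g1\ta\tX\t\t\t\tHGM", "g1\tb\tY\t\t\t\tHGM"), path)
  expect_error(read_taxonomy(path), "duplicate genome_id")
})

test_that("packaged default rules reproduce the essential-role table", {
  rs <- read_rules()
  expect_named(rs$rules, bvitamins())
  lines_per_vitamin <- vapply(rs$rules, function(r) length(r$lines),
                              integer(1))
  expect_equal(unname(lines_per_vitamin), c(2L, 2L, 1L, 1L, 1L, 2L, 1L, 2L))

  # biotin: two alternative routes sharing the BioFADB core
  expect_equal(rs$rules$biotin$lines,
               list(list("BioW", "BioFADB"), list("BioC", "BioFADB")))
  # thiamin line 1 opens with an OR-term over the two glycine-imine roles
  expect_equal(rs$rules$thiamin$lines[[1]][[1]], c("ThiH", "ThiO"))
  # pantothenate tolerance: one branched-pathway enzyme may be missing,
  # but the CoA steps and PBAL never
  tol <- rs$rules$pantothenate$tolerance
  expect_equal(sort(tol$tolerable), c("ASPDC", "KPHMT", "KPRED"))
  expect_equal(tol$max_missing, 1L)
  expect_equal(sort(rs$rules$pantothenate$mandatory),
               c("DPCK", "PANK", "PBAL", "PPCDC", "PPCS"))
  # compound mnemonics expand to atomic members
  expect_equal(rs$subsets$BioFADB, c("BioF", "BioA", "BioD", "BioB"))
  expect_true(all(vapply(rs$rules, function(r)
    length(rule_universe(r, rs$subsets)) <= 20, logical(1))))
})

test_that("rule config validation catches structural errors", {
  expect_error(rules_from_yaml(c(
    "vitamins:", "  biotin:", "    lines: []")), "no rule lines")
  expect_error(rules_from_yaml(c(
    "vitamins:", "  biotin:", "    lines:", "      - ''")),
    "empty rule line")
  expect_error(rules_from_yaml(c(
    "vitamins:",
    "  pantothenate:",
    "    lines: ['A + B']",
    "    tolerance: {tolerable: [A], max_missing: 1}",
    "    mandatory: [A, B]")),
    "mandatory and tolerable roles overlap")
  expect_error(rules_from_yaml(c(
    "vitamins:",
    "  biotin:",
    "    lines: ['A + B']",
    "    mandatory: [C]")),
    "not used in any rule line")

  one <- rules_from_yaml(c(
    "subsets:", "  AB: [A, B]",
    "vitamins:", "  biotin:", "    lines: ['AB + C']"))
  expect_length(one$rules, 1L)
  expect_equal(rule_universe(one$rules$biotin, one$subsets),
               c("A", "B", "C"))
})

test_that("evidence reader enforces the closed vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("organism\tgenome_id\tvitamin\tevidence\tsource",
               "Org A\tg1\tbiotin\tproducer_equivalent\tref1",
               "Org A\tg1\tfolate\tunknown\tref2"), path)
  ev <- read_evidence(path)
  expect_equal(nrow(ev), 2L)

  writeLines(c("organism\tgenome_id\tvitamin\tevidence\tsource",
               "Org A\tg1\tvitaminC\tproducer_equivalent\tref"), path)
  expect_error(read_evidence(path), "outside the canonical list")

  writeLines(c("organism\tgenome_id\tvitamin\tevidence\tsource",
               "Org A\tg1\tbiotin\tproducer_equivalent\tref",
               "Org A\tg1\tbiotin\tnonproducer_equivalent\tref"), path)
  expect_error(read_evidence(path), "more than one evidence record")
})
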