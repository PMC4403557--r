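#' Specification for a synthetic genome cohort
#'
#' Describes the statistical structure the generator emulates: taxonomic
#' block structure over phyla, per-phylum per-vitamin producer
#' probabilities, optional dropout noise restricted to tolerated roles,
#' and optional transporter roles carried by non-producers (organisms
#' that need a vitamin they cannot make tend to carry its uptake
#' transporter).
#'
#' @param phyla Character vector of phylum names.
#' @param n_genomes Genomes per phylum (recycled to `length(phyla)`).
#' @param producer_prob Producer probability per (phylum, vitamin): a
#'   single number, a named per-vitamin vector, or a
#'   `length(phyla) x 8` matrix (rows = phyla, columns = canonical
#'   vitamin order).
#' @param noise Probability that a producer genome drops a tolerated role
#'   (never more than the rule's `max_missing`), so predictions still
#'   equal the planted truth.
#' @param transporter_prob Probability that a non-producer carries the
#'   vitamin's transporter role (BioY, PANF, RibU, PnuC, PdxK).
#' @param cohort Cohort label for the taxonomy table.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(phyla, n_genomes, producer_prob, noise = 0,
                        transporter_prob = 0, cohort = "HGM", seed) {
  if (missing(seed)) vs_stop("cohort_spec requires an explicit seed")
  vits <- bvitamins()
  n_genomes <- rep_len(as.integer(n_genomes), length(phyla))
  if (any(n_genomes < 0)) vs_stop("n_genomes must be >= 0")
  pp <- producer_prob
  if (is.matrix(pp)) {
    if (nrow(pp) != length(phyla) || ncol(pp) != 8)
      vs_stop("producer_prob matrix must be length(phyla) x 8")
  } else if (length(pp) == 1) {
    pp <- matrix(pp, length(phyla), 8)
  } else if (length(pp) == 8) {
    if (!is.null(names(pp))) {
      if (!identical(sort(names(pp)), vits))
        vs_stop("per-vitamin producer_prob must be named by the 8 vitamins")
      pp <- pp[vits]
    }
    pp <- matrix(pp, length(phyla), 8, byrow = TRUE)
  } else vs_stop("producer_prob must be scalar, length-8, or a matrix")
  dimnames(pp) <- list(phyla, vits)
  if (any(pp < 0 | pp > 1)) vs_stop("probabilities must lie in [0, 1]")
  if (noise < 0 || noise > 1 || transporter_prob < 0 ||
      transporter_prob > 1)
    vs_stop("probabilities must lie in [0, 1]")
  structure(list(phyla = phyla, n_genomes = n_genomes,
                 producer_prob = pp, noise = noise,
                 transporter_prob = transporter_prob, cohort = cohort,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## transporter role emitted for non-producers, per vitamin
transporter_roles <- c(biotin = "BioY", niacin = "PnuC",
                       pantothenate = "PANF", pyridoxine = "PdxK",
                       riboflavin = "RibU")

#' Generate a synthetic cohort with known ground truth
#'
#' For every genome and vitamin the generator plants a producer/
#' non-producer truth value, then emits functional roles accordingly:
#' producers receive the full atomic role set of one randomly chosen rule
#' line (with one alternative picked per OR-term, and optionally up to
#' `max_missing` tolerated roles dropped as noise); non-producers receive
#' that set minus enough roles to verifiably break the rule.  Every
#' emitted genome is re-checked through [evaluate_rule()] rather than
#' trusted by construction, so the returned truth table is guaranteed
#' consistent with the matrix under the given rules.
#'
#' @param spec A [cohort_spec()].
#' @param rules A `rule_set` (default packaged rules).
#' @return List with `matrix` (a [role_matrix()]), `taxonomy` (data
#'   frame), and `truth` (data frame of planted calls with a `pattern`
#'   column).  Deterministic given `spec$seed`.
#' @examples
#' spec <- cohort_spec(c("Bacteroidetes", "Firmicutes"), 5,
#'                     producer_prob = 0.5, seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort$truth$pattern
#' @export
generate_cohort <- function(spec, rules = read_rules()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(rules, "rule_set"))
  vits <- bvitamins()
  if (!identical(sort(names(rules$rules)), vits))
    vs_stop("rule set must cover exactly the 8 canonical vitamins")
  with_local_seed(spec$seed, {
    phylum <- rep(spec$phyla, spec$n_genomes)
    n <- length(phylum)
    ids <- sprintf("SYNG%04d", seq_len(n))
    truth <- matrix(FALSE, n, 8, dimnames = list(ids, vits))
    for (p in spec$phyla) {
      rows <- which(phylum == p)
      for (v in vits)
        truth[rows, v] <- stats::runif(length(rows)) <
          spec$producer_prob[p, v]
    }
    mat <- emit_roles(truth, rules, spec$noise, spec$transporter_prob)
    taxonomy <- data.frame(genome_id = ids, name = ids, phylum = phylum,
                           class = "", order = "", family = "",
                           cohort = spec$cohort)
    truth_df <- data.frame(genome_id = ids, as.data.frame(truth),
                           check.names = FALSE, row.names = NULL)
    truth_df$pattern <- apply(truth, 1, function(b)
      paste(as.integer(b), collapse = ""))
    list(matrix = mat, taxonomy = taxonomy, truth = truth_df)
  })
}

#' Generate a cohort realising fixed pathway patterns
#'
#' Builds a cohort whose genomes display exactly the requested 8-bit
#' patterns (in canonical vitamin order) with the requested
#' multiplicities; used to plant complementary pattern pairs.
#'
#' @param patterns Character vector of 8-bit pattern strings.
#' @param counts Genomes per pattern (recycled).
#' @param rules A `rule_set`.
#' @param seed Integer seed.
#' @param phylum,cohort Labels for the taxonomy table.
#' @return As [generate_cohort()].
#' @export
cohort_from_patterns <- function(patterns, counts = 1,
                                 rules = read_rules(), seed,
                                 phylum = "Synthetica",
                                 cohort = "synthetic") {
  if (!all(grepl("^[01]{8}$", patterns)))
    vs_stop("patterns must be 8-character 0/1 strings")
  counts <- rep_len(as.integer(counts), length(patterns))
  vits <- bvitamins()
  with_local_seed(seed, {
    per_genome <- rep(patterns, counts)
    n <- length(per_genome)
    ids <- sprintf("SYNG%04d", seq_len(n))
    truth <- t(vapply(per_genome, function(p)
      as.integer(strsplit(p, "")[[1]]) == 1L, logical(8)))
    dimnames(truth) <- list(ids, vits)
    mat <- emit_roles(truth, rules, noise = 0, transporter_prob = 0)
    taxonomy <- data.frame(genome_id = ids, name = ids, phylum = phylum,
                           class = "", order = "", family = "",
                           cohort = cohort)
    truth_df <- data.frame(genome_id = ids, as.data.frame(truth),
                           check.names = FALSE, row.names = NULL)
    truth_df$pattern <- per_genome
    list(matrix = mat, taxonomy = taxonomy, truth = truth_df)
  })
}

#' Plant complementary pattern pairs in a synthetic cohort
#'
#' Emits a cohort containing, for each requested pattern, both the
#' pattern and its bitwise complement, with the requested genome counts
#' per side, so that [inversed_pairs()] on the cohort's census returns
#' exactly the planted pairs.
#'
#' @param patterns Character vector of 8-bit patterns, one side per pair;
#'   must be pairwise distinct and no pattern may be another's
#'   complement.
#' @param counts_a,counts_b Genome counts for each pattern and its
#'   complement (recycled).
#' @param rules A `rule_set`.
#' @param seed Integer seed.
#' @return As [generate_cohort()].
#' @export
plant_pattern_pairs <- function(patterns, counts_a = 1, counts_b = 1,
                                rules = read_rules(), seed) {
  if (anyDuplicated(patterns)) vs_stop("planted patterns must be distinct")
  if (any(pattern_complement(patterns) %in% patterns))
    vs_stop("planted patterns must not include each other's complements")
  counts_a <- rep_len(as.integer(counts_a), length(patterns))
  counts_b <- rep_len(as.integer(counts_b), length(patterns))
  cohort_from_patterns(c(patterns, pattern_complement(patterns)),
                       c(counts_a, counts_b), rules, seed)
}

#' Generate an evidence table from planted truth
#'
#' Samples strains from a truth table and emits growth-equivalent
#' evidence that flips the planted producer status with probability
#' `error_rate`, emulating the disagreement level between annotation-based
#' predictions and published growth experiments.
#'
#' @param truth Truth data frame from [generate_cohort()].
#' @param n_strains Number of strains to sample (without replacement).
#' @param error_rate Per-record flip probability.
#' @param seed Integer seed.
#' @return Evidence data frame in the [read_evidence()] layout.
#' @export
generate_evidence <- function(truth, n_strains, error_rate = 0, seed) {
  if (n_strains > nrow(truth))
    vs_stop("n_strains exceeds the number of genomes in the truth table")
  if (error_rate < 0 || error_rate > 1)
    vs_stop("error_rate must lie in [0, 1]")
  vits <- bvitamins()
  with_local_seed(seed, {
    pick <- sort(sample(nrow(truth), n_strains))
    recs <- expand.grid(genome_id = truth$genome_id[pick],
                        vitamin = vits, stringsAsFactors = FALSE)
    planted <- mapply(function(g, v)
      isTRUE(truth[[v]][truth$genome_id == g]),
      recs$genome_id, recs$vitamin)
    flip <- stats::runif(nrow(recs)) < error_rate
    observed <- xor(planted, flip)
    data.frame(organism = recs$genome_id, genome_id = recs$genome_id,
               vitamin = recs$vitamin,
               evidence = ifelse(observed, "producer_equivalent",
                                 "nonproducer_equivalent"),
               source = "synthetic growth evidence")
  })
}

## internal: emit a role matrix realising a truth matrix under the rules.
## Producers get one rule line's full atomic set (noise may drop tolerated
## roles within max_missing); non-producers get that set minus roles until
## the rule verifiably fails.  Every call is re-verified via evaluate_rule.
emit_roles <- function(truth, rules, noise, transporter_prob) {
  vits <- colnames(truth)
  all_roles <- sort(unique(c(
    unlist(lapply(rules$rules, rule_universe, subsets = rules$subsets)),
    unname(transporter_roles))))
  n <- nrow(truth)
  m <- matrix(0L, n, length(all_roles),
              dimnames = list(rownames(truth), all_roles))
  for (g in seq_len(n)) {
    for (v in vits) {
      rule <- rules$rules[[v]]
      line <- rule$lines[[sample.int(length(rule$lines), 1)]]
      ## one alternative per OR-term, subsets expanded to atoms
      chosen <- unlist(lapply(line, function(term)
        term[[sample.int(length(term), 1)]]))
      atoms <- unique(unlist(lapply(chosen, function(id)
        if (id %in% names(rules$subsets)) rules$subsets[[id]] else id)))
      if (truth[g, v]) {
        if (noise > 0 && !is.null(rule$tolerance)) {
          droppable <- intersect(atoms, rule$tolerance$tolerable)
          drop <- droppable[stats::runif(length(droppable)) < noise]
          if (length(drop) > rule$tolerance$max_missing)
            drop <- drop[seq_len(rule$tolerance$max_missing)]
          atoms <- setdiff(atoms, drop)
        }
      } else {
        ## remove roles (never merely-tolerable ones) until the rule fails
        removable <- setdiff(atoms,
                             if (!is.null(rule$tolerance))
                               rule$tolerance$tolerable else character())
        removable <- sample(removable)
        repeat {
          present <- expand_presence(atoms, rules$subsets)
          if (!evaluate_rule(present, rule)$producer) break
          if (!length(removable))
            vs_stop("cannot construct a non-producer for '", v,
                    "': every deletion is tolerated by the rule")
          atoms <- setdiff(atoms, removable[1])
          removable <- removable[-1]
        }
        tr <- transporter_roles[v]
        if (!is.na(tr) && stats::runif(1) < transporter_prob)
          atoms <- c(atoms, unname(tr))
      }
      ## rejection check: the emitted roles must realise the planted call
      verdict <- evaluate_rule(expand_presence(atoms, rules$subsets),
                               rule)$producer
      if (verdict != truth[g, v])
        vs_stop("generator failed to realise the planted call for ",
                rownames(truth)[g], " / ", v)
      m[g, match(atoms, all_roles)] <- 1L
    }
  }
  role_matrix(m)
}
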