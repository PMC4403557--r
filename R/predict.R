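#' Expand subset presence over a set of atomic roles
#'
#' A compound subset id counts as present iff every member role is present.
#' Returns the atomic ids plus every satisfied subset id.
#'
#' @param atomic_ids Character vector of atomic role ids present in a
#'   genome.
#' @param subsets Named list of subset memberships.
#' @return Character vector of present ids (atomic and subset).
#' @export
expand_presence <- function(atomic_ids, subsets = list()) {
  present_subsets <- names(subsets)[vapply(subsets, function(members)
    all(members %in% atomic_ids), logical(1))]
  unique(c(atomic_ids, present_subsets))
}

#' Evaluate a producer rule against a set of present roles
#'
#' A genome is called a producer iff at least one rule line is satisfied
#' outright (every term present; an OR-group counts as present if any
#' alternative is), or, when the rule declares a tolerance, some line
#' fails only by missing at most `max_missing` tolerable single-role
#' terms while every mandatory role is present.
#'
#' @param present_ids Character vector of present role/subset ids, with
#'   subset presence already expanded (see [expand_presence()]).
#' @param rule A `vitamin_rule` (see [read_rules()]).
#' @return List with `producer` (logical) and `provenance` (a string:
#'   `"line:<i>"`, `"tolerance:<i>"` or `"none"`).  When several lines are
#'   satisfied, the first in config order is recorded.
#' @examples
#' rs <- read_rules()
#' evaluate_rule(c("BioC", "BioFADB"), rs$rules$biotin)
#' @export
evaluate_rule <- function(present_ids, rule) {
  for (i in seq_along(rule$lines)) {
    sat <- vapply(rule$lines[[i]], function(term)
      any(term %in% present_ids), logical(1))
    if (all(sat))
      return(list(producer = TRUE, provenance = paste0("line:", i)))
  }
  tol <- rule$tolerance
  if (!is.null(tol)) {
    if (all(rule$mandatory %in% present_ids)) {
      for (i in seq_along(rule$lines)) {
        unsat <- rule$lines[[i]][!vapply(rule$lines[[i]], function(term)
          any(term %in% present_ids), logical(1))]
        singles <- lengths(unsat) == 1L
        if (all(singles) &&
            all(unlist(unsat) %in% tol$tolerable) &&
            length(unsat) <= tol$max_missing)
          return(list(producer = TRUE, provenance = paste0("tolerance:", i)))
      }
    }
  }
  list(producer = FALSE, provenance = "none")
}

#' Exhaustive truth table for a producer rule
#'
#' Independent brute-force oracle: enumerates every one of the `2^n`
#' presence vectors over the rule's atomic universe and derives the
#' producer verdict directly from the rule-line definition, without going
#' through [evaluate_rule()].  Used to cross-check the rule engine.
#'
#' @param rule A `vitamin_rule`.
#' @param universe Character vector of atomic role ids (defaults to
#'   [rule_universe()]); must have at most 20 elements.
#' @param subsets Named list of subset memberships.
#' @return Data frame with one 0/1 column per universe role and a logical
#'   `producer` column, one row per presence vector.
#' @export
brute_force_oracle <- function(rule, universe = NULL, subsets = list()) {
  if (is.null(universe)) universe <- rule_universe(rule, subsets)
  n <- length(universe)
  if (n > 20)
    vs_stop("universe of ", n, " roles is too large to enumerate (max 20)")
  grid <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- universe
  ## direct re-derivation of the semantics, column-wise over all rows:
  ## subset present iff all members present; term present iff any
  ## alternative id present
  have <- function(id) {
    if (id %in% names(subsets)) {
      members <- subsets[[id]]
      if (!all(members %in% universe)) return(rep(FALSE, nrow(grid)))
      rowSums(grid[, members, drop = FALSE]) == length(members)
    } else {
      if (!id %in% universe) return(rep(FALSE, nrow(grid)))
      grid[, id] == 1
    }
  }
  term_ok <- function(term)
    Reduce(`|`, lapply(term, have))
  verdict <- rep(FALSE, nrow(grid))
  for (ln in rule$lines)
    verdict <- verdict | Reduce(`&`, lapply(ln, term_ok))
  tol <- rule$tolerance
  if (!is.null(tol)) {
    mand_ok <- if (length(rule$mandatory))
      Reduce(`&`, lapply(rule$mandatory, have)) else rep(TRUE, nrow(grid))
    for (ln in rule$lines) {
      tol_term <- vapply(ln, function(t)
        length(t) == 1L && t %in% tol$tolerable, logical(1))
      sat <- lapply(ln, term_ok)
      ## every non-tolerable term satisfied, and at most max_missing of
      ## the tolerable single-role terms unsatisfied
      nontol_ok <- if (any(!tol_term))
        Reduce(`&`, sat[!tol_term]) else rep(TRUE, nrow(grid))
      n_missing <- if (any(tol_term))
        Reduce(`+`, lapply(sat[tol_term], function(s) !s))
      else rep(0L, nrow(grid))
      verdict <- verdict |
        (mand_ok & nontol_ok & n_missing <= tol$max_missing)
    }
  }
  out <- as.data.frame(grid)
  out$producer <- verdict
  out
}

#' Predict producer status for every genome and vitamin
#'
#' Evaluates each vitamin's rule over each genome's annotated roles.
#' Manual curation overrides (e.g. a genome missing one role that all its
#' relatives carry) take precedence over rule evaluation and are flagged
#' in the provenance columns.
#'
#' @param matrix A [role_matrix()].
#' @param rules A `rule_set` from [read_rules()].
#' @param overrides Optional data frame with columns `genome_id`,
#'   `vitamin`, `verdict` (`"producer"`/`"non-producer"`) and a mandatory
#'   free-text `justification` (audit trail).
#' @return A `prediction_table`: data frame with `genome_id`, one logical
#'   producer column per vitamin in canonical order, and one
#'   `provenance_<vitamin>` column per vitamin.
#' @examples
#' rs <- read_rules()
#' m <- role_matrix(matrix(1L, 1, 6, dimnames = list("g1",
#'   c("BioC", "BioF", "BioA", "BioD", "BioB", "BioW"))))
#' predict_cohort(m, rs)$biotin
#' @export
predict_cohort <- function(matrix, rules, overrides = NULL) {
  stopifnot(inherits(matrix, "role_matrix"), inherits(rules, "rule_set"))
  vits <- names(rules$rules)
  genomes <- rownames(matrix)
  if (!is.null(overrides)) {
    need <- c("genome_id", "vitamin", "verdict", "justification")
    if (!all(need %in% colnames(overrides)))
      vs_stop("overrides need columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(overrides$genome_id, genomes)
    if (length(unknown))
      vs_stop("override(s) for genome(s) not in the matrix: ",
              paste(unknown, collapse = ", "))
    if (any(!nzchar(trimws(overrides$justification))))
      vs_stop("every override must carry a justification")
    if (!all(overrides$verdict %in% c("producer", "non-producer")))
      vs_stop("override verdict must be 'producer' or 'non-producer'")
    if (!all(overrides$vitamin %in% vits))
      vs_stop("override vitamin(s) outside the rule set: ",
              paste(setdiff(overrides$vitamin, vits), collapse = ", "))
  }
  calls <- matrix(FALSE, length(genomes), length(vits),
                  dimnames = list(genomes, vits))
  prov <- matrix("none", length(genomes), length(vits),
                 dimnames = list(genomes, vits))
  roles <- colnames(matrix)
  for (g in seq_along(genomes)) {
    present <- expand_presence(roles[matrix[g, ] == 1L], rules$subsets)
    for (v in vits) {
      res <- evaluate_rule(present, rules$rules[[v]])
      calls[g, v] <- res$producer
      prov[g, v] <- res$provenance
    }
  }
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      g <- overrides$genome_id[k]
      v <- overrides$vitamin[k]
      calls[g, v] <- overrides$verdict[k] == "producer"
      prov[g, v] <- "override"
    }
  }
  out <- data.frame(genome_id = genomes, as.data.frame(calls),
                    check.names = FALSE, row.names = NULL)
  provdf <- as.data.frame(prov)
  colnames(provdf) <- paste0("provenance_", vits)
  out <- cbind(out, provdf)
  rownames(out) <- NULL
  class(out) <- c("prediction_table", class(out))
  out
}

#' Per-taxon prevalence of functional roles
#'
#' Fraction of genomes in each taxon that carry each queried role or
#' subset (the bar-chart quantity shown alongside pathway diagrams:
#' percentage of organisms in each phylum containing a functional role).
#'
#' @param matrix A [role_matrix()].
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).  Genomes
#'   present in the matrix but absent from the taxonomy are excluded from
#'   the summary with a warning.
#' @param ids Role or subset ids to tally.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, or
#'   `"cohort"` for whole-collection fractions.
#' @param subsets Named list of subset memberships used to resolve
#'   compound ids.
#' @return Data frame with columns `taxon`, `id`, `n_genomes`,
#'   `n_present`, `fraction`.
#' @export
role_prevalence <- function(matrix, taxonomy, ids,
                            rank = c("phylum", "class", "order", "family",
                                     "cohort"),
                            subsets = list()) {
  rank <- match.arg(rank)
  stopifnot(inherits(matrix, "role_matrix"))
  present <- vapply(ids, function(id) {
    members <- if (id %in% names(subsets)) subsets[[id]] else id
    missing_roles <- setdiff(members, colnames(matrix))
    if (length(missing_roles))
      return(rep(0L, nrow(matrix)))
    as.integer(rowSums(matrix[, members, drop = FALSE] == 1L) ==
                 length(members))
  }, integer(nrow(matrix)))
  present <- matrix(present, nrow = nrow(matrix),
                    dimnames = list(rownames(matrix), ids))
  taxa <- taxon_of(rownames(matrix), taxonomy, rank)
  keep <- !is.na(taxa) & nzchar(taxa)
  if (any(!keep))
    warning(sum(!keep), " genome(s) without ", rank,
            " assignment excluded from prevalence summary")
  tally_by_taxon(present[keep, , drop = FALSE], taxa[keep])
}

#' Per-taxon prevalence of predicted producers
#'
#' As [role_prevalence()], but over producer calls: the fraction of
#' genomes in each taxon predicted to synthesise each vitamin.
#'
#' @param predictions A `prediction_table` from [predict_cohort()].
#' @param taxonomy Taxonomy data frame.
#' @param rank Taxonomic rank, or `"cohort"` for whole-collection
#'   producer ratios.
#' @return Data frame with columns `taxon`, `vitamin`, `n_genomes`,
#'   `n_producers`, `fraction`.
#' @export
producer_prevalence <- function(predictions, taxonomy,
                                rank = c("phylum", "class", "order",
                                         "family", "cohort")) {
  rank <- match.arg(rank)
  vits <- bvitamins()
  calls <- sapply(vits, function(v) as.integer(predictions[[v]]))
  calls <- matrix(calls, nrow = nrow(predictions),
                  dimnames = list(predictions$genome_id, vits))
  taxa <- taxon_of(predictions$genome_id, taxonomy, rank)
  keep <- !is.na(taxa) & nzchar(taxa)
  if (any(!keep))
    warning(sum(!keep), " genome(s) without ", rank,
            " assignment excluded from prevalence summary")
  out <- tally_by_taxon(calls[keep, , drop = FALSE], taxa[keep])
  names(out)[names(out) == "id"] <- "vitamin"
  names(out)[names(out) == "n_present"] <- "n_producers"
  out
}

## internal: taxon label per genome at a rank ("cohort" is the cohort col)
taxon_of <- function(genome_ids, taxonomy, rank) {
  idx <- match(genome_ids, taxonomy$genome_id)
  taxonomy[[rank]][idx]
}

## internal: column-wise fractions within taxon groups
tally_by_taxon <- function(m, taxa) {
  out <- do.call(rbind, lapply(split(seq_along(taxa), taxa), function(rows) {
    data.frame(taxon = taxa[rows[1]], id = colnames(m),
               n_genomes = length(rows),
               n_present = colSums(m[rows, , drop = FALSE]),
               row.names = NULL)
  }))
  out$fraction <- out$n_present / out$n_genomes
  rownames(out) <- NULL
  out
}
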