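#' Pathway pattern strings
#'
#' A pathway pattern is the ordered 8-bit vector of producer calls in
#' canonical vitamin order, written as a string such as `"10110101"`
#' (`1` = biosynthesis pathway present).
#'
#' @param predictions A `prediction_table`.
#' @return Character vector of 8-character pattern strings, one per
#'   genome, named by `genome_id`.
#' @export
pathway_patterns <- function(predictions) {
  vits <- bvitamins()
  bits <- sapply(vits, function(v) as.integer(predictions[[v]]))
  bits <- matrix(bits, nrow = nrow(predictions))
  out <- apply(bits, 1, paste, collapse = "")
  names(out) <- predictions$genome_id
  out
}

#' Bitwise complement of pattern strings
#'
#' Swaps present and absent pathways.  An involution:
#' `pattern_complement(pattern_complement(p)) == p`.
#'
#' @param p Character vector of 0/1 pattern strings.
#' @return Complemented pattern strings.
#' @examples
#' pattern_complement("10110101")
#' @export
pattern_complement <- function(p) {
  if (!all(grepl("^[01]+$", p))) vs_stop("patterns must be 0/1 strings")
  chartr("01", "10", p)
}

#' Census of pathway patterns in a cohort
#'
#' Counts how many genomes display each distinct 8-bit pathway pattern.
#' With 8 vitamins there are `2^8 = 256` possible patterns; the census
#' records only the observed ones.
#'
#' @param predictions A `prediction_table` with complete calls for all 8
#'   vitamins.
#' @param cohort Cohort label stored with the census.
#' @return A `pattern_census`: list with `counts` (named integer vector,
#'   pattern string -> genome count), `cohort`, and `total` genomes.
#' @export
pattern_census <- function(predictions, cohort = "cohort") {
  vits <- bvitamins()
  missing_cols <- setdiff(vits, colnames(predictions))
  if (length(missing_cols))
    vs_stop("predictions missing vitamin column(s): ",
            paste(missing_cols, collapse = ", "))
  if (anyNA(predictions[, vits]))
    vs_stop("predictions contain missing producer calls")
  pats <- pathway_patterns(predictions)
  counts <- table(pats)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, cohort = cohort,
                 total = length(pats)),
            class = "pattern_census")
}

#' @export
print.pattern_census <- function(x, ...) {
  cat("pattern_census (", x$cohort, "): ", length(x$counts),
      " distinct patterns over ", x$total, " genomes\n", sep = "")
  top <- sort(x$counts, decreasing = TRUE)
  show <- utils::head(top, 5)
  for (i in seq_along(show))
    cat("  ", names(show)[i], "  ", show[i], " genome(s)\n", sep = "")
  if (length(top) > 5) cat("  ...\n")
  invisible(x)
}

#' Compare the pattern repertoires of two cohorts
#'
#' Partitions the 256-pattern space into four groups: patterns observed
#' only in cohort A, in both cohorts, only in cohort B, and in neither.
#'
#' @param a,b `pattern_census` objects built with the same canonical
#'   vitamin order.
#' @return A `cohort_comparison`: list of character vectors `only_a`,
#'   `shared`, `only_b`, and the integer `n_absent`; group sizes always
#'   sum to 256.
#' @export
compare_cohorts <- function(a, b) {
  stopifnot(inherits(a, "pattern_census"), inherits(b, "pattern_census"))
  pa <- names(a$counts)
  pb <- names(b$counts)
  only_a <- sort(setdiff(pa, pb))
  only_b <- sort(setdiff(pb, pa))
  shared <- sort(intersect(pa, pb))
  structure(list(only_a = only_a, shared = shared, only_b = only_b,
                 n_absent = 256L - length(only_a) - length(shared) -
                   length(only_b),
                 cohort_a = a$cohort, cohort_b = b$cohort),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("cohort_comparison of the 256 possible pathway patterns:\n")
  cat("  only ", x$cohort_a, ": ", length(x$only_a), "\n", sep = "")
  cat("  shared: ", length(x$shared), "\n", sep = "")
  cat("  only ", x$cohort_b, ": ", length(x$only_b), "\n", sep = "")
  cat("  in neither: ", x$n_absent, "\n", sep = "")
  invisible(x)
}

#' Inversed (complementary) pattern pairs in a census
#'
#' Finds pairs of observed patterns that are bitwise complements of one
#' another — pathways present in one genome and absent in the other, and
#' vice versa.  Such pairs are candidates for metabolic complementarity
#' (cross-feeding) between organisms.  Each pair is listed once with the
#' lexicographically smaller pattern first; for even-length binary
#' patterns a pattern can never equal its own complement, which the code
#' asserts rather than handles.
#'
#' @param census A `pattern_census`.
#' @return Data frame with columns `pattern_a`, `pattern_b`, `count_a`,
#'   `count_b`, `genomes` (total genomes across both sides); zero rows
#'   when no complementary pair is observed.
#' @export
inversed_pairs <- function(census) {
  stopifnot(inherits(census, "pattern_census"))
  pats <- names(census$counts)
  comp <- pattern_complement(pats)
  stopifnot(!any(comp == pats))   # impossible at even pattern length
  hit <- comp %in% pats & pats < comp
  out <- data.frame(pattern_a = pats[hit], pattern_b = comp[hit],
                    count_a = unname(census$counts[pats[hit]]),
                    count_b = unname(census$counts[comp[hit]]))
  out$genomes <- out$count_a + out$count_b
  out[order(out$pattern_a), , drop = FALSE]
}

#' Pattern composition of each taxon
#'
#' Tabulates the distinct pathway patterns within each taxon and the
#' fraction of the taxon's genomes carrying each; per-taxon fractions sum
#' to 1.
#'
#' @param predictions A `prediction_table`.
#' @param taxonomy Taxonomy data frame.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`.
#' @return Data frame with columns `taxon`, `pattern`, `count`,
#'   `fraction`.
#' @export
taxon_pattern_summary <- function(predictions, taxonomy,
                                  rank = c("phylum", "class", "order",
                                           "family")) {
  rank <- match.arg(rank)
  pats <- pathway_patterns(predictions)
  taxa <- taxon_of(predictions$genome_id, taxonomy, rank)
  keep <- !is.na(taxa) & nzchar(taxa)
  if (any(!keep))
    warning(sum(!keep), " genome(s) without ", rank,
            " assignment excluded from pattern summary")
  pats <- pats[keep]
  taxa <- taxa[keep]
  out <- do.call(rbind, lapply(split(pats, taxa), function(p) {
    tab <- sort(table(p), decreasing = TRUE)
    data.frame(pattern = names(tab), count = as.integer(tab),
               fraction = as.integer(tab) / length(p), row.names = NULL)
  }))
  out <- data.frame(taxon = rep(names(split(pats, taxa)),
                                vapply(split(pats, taxa),
                                       function(p) length(unique(p)),
                                       integer(1))),
                    out, row.names = NULL)
  out
}
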