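#' Score predictions against experimental evidence
#'
#' Compares predicted producer calls with an experimental evidence table
#' (organism x vitamin records from defined-medium growth or secretion
#' studies).  A record matches when a predicted producer has
#' `producer_equivalent` evidence or a predicted non-producer has
#' `nonproducer_equivalent` evidence; records with `unknown` evidence are
#' excluded from the denominator.
#'
#' @param predictions A `prediction_table`.
#' @param evidence Evidence data frame (see [read_evidence()]).
#' @param mapping Optional data frame with columns `organism`,
#'   `genome_id`, mapping evidence organisms to prediction genomes when
#'   the evidence strain differs from the annotated strain (never matched
#'   fuzzily by name).  When `NULL`, the evidence table's own `genome_id`
#'   column is used.
#' @return A `concordance_result`: list with `details` (per-record data
#'   frame with predicted/evidence/match columns), `compared`, `matched`,
#'   `excluded_unknown`, `skipped` (records whose organism maps to no
#'   genome, dropped with a warning), and `fraction` matched.
#' @examples
#' preds <- read_predictions(system.file("extdata",
#'   "synthetic_predictions16.tsv", package = "vitasynth"))
#' ev <- read_evidence(system.file("extdata",
#'   "synthetic_evidence16.tsv", package = "vitasynth"))
#' score_concordance(preds, ev)
#' @export
score_concordance <- function(predictions, evidence, mapping = NULL) {
  vits <- bvitamins()
  bad <- setdiff(unique(evidence$vitamin), vits)
  if (length(bad))
    vs_stop("evidence vitamin(s) outside the canonical list: ",
            paste(bad, collapse = ", "))
  gid <- if (!is.null(mapping)) {
    if (!all(c("organism", "genome_id") %in% colnames(mapping)))
      vs_stop("mapping needs columns organism, genome_id")
    mapping$genome_id[match(evidence$organism, mapping$organism)]
  } else evidence$genome_id
  gid[is.na(gid)] <- ""
  known <- gid %in% predictions$genome_id
  if (any(!known))
    warning(sum(!known), " evidence record(s) skipped: organism(s) ",
            paste(unique(evidence$organism[!known]), collapse = ", "),
            " map to no predicted genome")
  details <- evidence[known, c("organism", "vitamin", "evidence"),
                      drop = FALSE]
  gid <- gid[known]
  idx <- match(gid, predictions$genome_id)
  details$genome_id <- gid
  details$predicted_producer <- vapply(seq_len(nrow(details)), function(k)
    isTRUE(predictions[[details$vitamin[k]]][idx[k]]), logical(1))
  details$match <- ifelse(
    details$evidence == "unknown", NA,
    (details$predicted_producer &
       details$evidence == "producer_equivalent") |
      (!details$predicted_producer &
         details$evidence == "nonproducer_equivalent"))
  compared <- sum(!is.na(details$match))
  matched <- sum(details$match, na.rm = TRUE)
  structure(list(details = details, compared = compared, matched = matched,
                 excluded_unknown = sum(is.na(details$match)),
                 skipped = sum(!known),
                 fraction = if (compared > 0) matched / compared else NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("concordance: ", x$matched, " of ", x$compared,
      " prediction(s) match the experimental evidence (",
      if (is.na(x$fraction)) "NA" else sprintf("%.0f%%", 100 * x$fraction),
      ")\n", sep = "")
  if (x$excluded_unknown)
    cat("  ", x$excluded_unknown,
        " record(s) with unknown evidence excluded\n", sep = "")
  if (x$skipped)
    cat("  ", x$skipped, " record(s) skipped (no mapped genome)\n",
        sep = "")
  invisible(x)
}
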