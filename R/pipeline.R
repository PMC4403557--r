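#' Run the full annotation-to-supply analysis pipeline
#'
#' Chains the four analysis stages over one set of inputs: producer
#' prediction from the role matrix, pathway-pattern census and cohort
#' comparison with inversed-pair detection, concordance scoring against
#' experimental evidence, and the microbiota vitamin supply table.  Each
#' enabled stage writes its TSV outputs into `out_dir` together with a
#' human-readable `summary.txt`; reruns on identical inputs produce
#' identical outputs.
#'
#' @param config A list (or path to a YAML file encoding one) with
#'   elements:
#'   \describe{
#'     \item{`matrix`}{path to the role matrix TSV (required for the
#'       predict stage).}
#'     \item{`taxonomy`}{path to the taxonomy TSV.}
#'     \item{`rules`}{optional rule config path (default packaged rules).}
#'     \item{`overrides`}{optional overrides TSV (genome_id, vitamin,
#'       verdict, justification).}
#'     \item{`predictions`}{optional pre-computed predictions TSV; when
#'       given, the predict stage is skipped and these calls feed the
#'       downstream stages (e.g. an externally curated per-genome call
#'       table).}
#'     \item{`evidence`, `mapping`}{optional evidence / organism-mapping
#'       TSVs for the concordance stage.}
#'     \item{`measurements`, `constants`}{optional supply-stage inputs
#'       (defaults packaged).}
#'     \item{`stages`}{character subset of `c("predict", "patterns",
#'       "concordance", "supply")`; default all whose inputs are
#'       available.}
#'     \item{`out_dir`}{output directory (required).}
#'   }
#' @return Invisibly, a report list with the stage results (`predictions`,
#'   `producer_prevalence`, `censuses`, `comparison`, `pairs`,
#'   `concordance`, `supply`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) vs_stop("config requires out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("predict", "patterns",
      if (!is.null(config$evidence)) "concordance", "supply")
  report <- list()
  summary_lines <- character()

  rules <- if (is.null(config$rules)) read_rules()
           else read_rules(config$rules)

  preds <- NULL
  taxonomy <- NULL
  if (!is.null(config$taxonomy)) taxonomy <- read_taxonomy(config$taxonomy)

  if ("predict" %in% stages || "patterns" %in% stages ||
      "concordance" %in% stages) {
    if (!is.null(config$predictions)) {
      preds <- read_predictions(config$predictions)
    } else if (!is.null(config$matrix)) {
      mat <- read_role_matrix(config$matrix)
      overrides <- if (!is.null(config$overrides))
        read_tsv(config$overrides)
      preds <- predict_cohort(mat, rules, overrides)
      write_predictions(preds, file.path(config$out_dir,
                                         "predictions.tsv"))
    } else if ("predict" %in% stages) {
      vs_stop("predict stage needs config$matrix or config$predictions")
    }
    report$predictions <- preds
  }

  if ("predict" %in% stages && !is.null(preds) && !is.null(taxonomy)) {
    prev <- producer_prevalence(preds, taxonomy, rank = "cohort")
    report$producer_prevalence <- prev
    utils::write.table(prev,
                       file.path(config$out_dir,
                                 "producer_prevalence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (co in unique(prev$taxon))
      summary_lines <- c(summary_lines,
        paste0("producer fractions (", co, "): ",
               paste(sprintf("%s %.2f", prev$vitamin[prev$taxon == co],
                             prev$fraction[prev$taxon == co]),
                     collapse = ", ")))
  }

  if ("patterns" %in% stages && !is.null(preds)) {
    cohorts <- if (!is.null(taxonomy))
      taxonomy$cohort[match(preds$genome_id, taxonomy$genome_id)]
    else rep("cohort", nrow(preds))
    cohorts[is.na(cohorts) | !nzchar(cohorts)] <- "cohort"
    censuses <- lapply(unique(cohorts), function(co)
      pattern_census(preds[cohorts == co, , drop = FALSE], cohort = co))
    names(censuses) <- unique(cohorts)
    report$censuses <- censuses
    for (co in names(censuses)) {
      cen <- censuses[[co]]
      utils::write.table(
        data.frame(pattern = names(cen$counts), count = cen$counts),
        file.path(config$out_dir, paste0("census_", co, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pairs <- inversed_pairs(cen)
      utils::write.table(pairs,
                         file.path(config$out_dir,
                                   paste0("inversed_pairs_", co, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary_lines <- c(summary_lines,
        paste0("cohort ", co, ": ", length(cen$counts),
               " distinct pathway patterns in ", cen$total, " genomes, ",
               nrow(pairs), " inversed pattern pair(s)"))
      report$pairs[[co]] <- pairs
    }
    if (length(censuses) == 2) {
      cmp <- compare_cohorts(censuses[[1]], censuses[[2]])
      report$comparison <- cmp
      utils::write.table(
        data.frame(group = c(paste0("only_", cmp$cohort_a), "shared",
                             paste0("only_", cmp$cohort_b), "absent"),
                   n_patterns = c(length(cmp$only_a), length(cmp$shared),
                                  length(cmp$only_b), cmp$n_absent)),
        file.path(config$out_dir, "cohort_comparison.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      summary_lines <- c(summary_lines,
        sprintf("pattern groups: %d only %s, %d shared, %d only %s, %d absent",
                length(cmp$only_a), cmp$cohort_a, length(cmp$shared),
                length(cmp$only_b), cmp$cohort_b, cmp$n_absent))
    }
  }

  if ("concordance" %in% stages) {
    if (is.null(config$evidence))
      vs_stop("concordance stage needs config$evidence")
    ev <- read_evidence(config$evidence)
    mapping <- if (!is.null(config$mapping)) read_tsv(config$mapping)
    conc <- score_concordance(preds, ev, mapping)
    report$concordance <- conc
    utils::write.table(conc$details,
                       file.path(config$out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines,
      sprintf("concordance: %d/%d predictions match evidence (%.0f%%)",
              conc$matched, conc$compared, 100 * conc$fraction))
  }

  if ("supply" %in% stages) {
    params <- if (is.null(config$constants)) supply_parameters()
              else supply_parameters(config$constants)
    meas <- if (is.null(config$measurements)) read_measurements()
            else read_measurements(config$measurements)
    supply <- suppressWarnings(build_supply_table(meas, params))
    report$supply <- supply
    utils::write.table(supply,
                       file.path(config$out_dir, "supply_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines,
      paste0("%DRI from microbiota: ",
             paste(sprintf("%s %.2g", supply$vitamin, supply$percent_dri),
                   collapse = ", ")))
  }

  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  invisible(report)
}
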