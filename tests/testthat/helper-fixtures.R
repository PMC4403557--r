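# Small programmatic fixtures shared across test files.

# random binary genome x role matrix with generic ids
random_role_matrix <- function(n_genomes, n_roles, p = 0.5) {
  m <- matrix(rbinom(n_genomes * n_roles, 1, p), n_genomes, n_roles,
              dimnames = list(sprintf("g%02d", seq_len(n_genomes)),
                              sprintf("role%02d", seq_len(n_roles))))
  role_matrix(m)
}

# prediction_table from a logical genome x vitamin matrix
make_predictions <- function(calls) {
  stopifnot(ncol(calls) == 8)
  colnames(calls) <- bvitamins()
  df <- data.frame(genome_id = rownames(calls), as.data.frame(calls),
                   check.names = FALSE, row.names = NULL)
  for (v in bvitamins()) df[[paste0("provenance_", v)]] <- "line:1"
  class(df) <- c("prediction_table", class(df))
  df
}

# prediction_table in which each genome displays a given pattern string
predictions_from_patterns <- function(patterns) {
  calls <- t(vapply(patterns, function(p)
    as.integer(strsplit(p, "")[[1]]) == 1L, logical(8)))
  rownames(calls) <- sprintf("g%03d", seq_along(patterns))
  make_predictions(calls)
}

# minimal taxonomy for a set of genome ids
make_taxonomy <- function(genome_ids, phylum = "Bacteroidetes",
                          cohort = "HGM") {
  data.frame(genome_id = genome_ids, name = genome_ids,
             phylum = rep_len(phylum, length(genome_ids)),
             class = "", order = "", family = "",
             cohort = rep_len(cohort, length(genome_ids)))
}

# ad hoc rule_set written through a temp YAML (exercises the real parser)
rules_from_yaml <- function(text) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  read_rules(path)
}
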