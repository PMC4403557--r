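#' Construct a genome-by-role annotation matrix
#'
#' A `role_matrix` is a binary incidence matrix with genomes as rows and
#' functional roles (named protein functions) as columns, mirroring the
#' spreadsheet orientation of curated subsystem platforms: cell (g, r) is 1
#' iff genome g carries an annotation for role r.
#'
#' @param presence Matrix coercible to integer 0/1, with genome ids as row
#'   names and role ids as column names.  Role and genome ids are opaque,
#'   case-sensitive tokens.
#' @return An object of class `role_matrix` (an integer matrix).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("BioF", "BioB")))
#' role_matrix(m)
#' @export
role_matrix <- function(presence) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) && nrow(presence) > 0)
    vs_stop("role matrix must have genome ids as row names")
  if (is.null(colnames(presence)) && ncol(presence) > 0)
    vs_stop("role matrix must have role ids as column names")
  if (anyDuplicated(rownames(presence)))
    vs_stop("duplicate genome id: ",
            rownames(presence)[duplicated(rownames(presence))][1])
  if (anyDuplicated(colnames(presence)))
    vs_stop("duplicate role id: ",
            colnames(presence)[duplicated(colnames(presence))][1])
  if (length(presence)) {
    bad <- which(!(presence %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(presence))
      vs_stop("non-binary cell at genome '", rownames(presence)[rc[1]],
              "', role '", colnames(presence)[rc[2]], "': ",
              presence[bad[1]])
    }
  }
  storage.mode(presence) <- "integer"
  class(presence) <- c("role_matrix", class(presence))
  presence
}

#' @export
print.role_matrix <- function(x, ...) {
  cat("role_matrix: ", nrow(x), " genomes x ", ncol(x),
      " functional roles\n", sep = "")
  cat("roles annotated per genome: ",
      paste(range(if (nrow(x)) rowSums(x) else 0L), collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Read a genome-by-role annotation matrix from TSV
#'
#' Expects a header row of role ids and a first column of genome ids; all
#' other cells must be binary.  Row and column order is preserved.
#'
#' @param path File path, or `"-"` for standard input.
#' @param truthy,falsy Tokens interpreted as presence/absence (besides
#'   numeric 1/0).
#' @return A [role_matrix()].
#' @export
read_role_matrix <- function(path, truthy = c("1", "TRUE"),
                             falsy = c("0", "FALSE")) {
  df <- read_tsv(path)
  if (ncol(df) < 1) vs_stop("role matrix file has no columns")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  m <- matrix(0L, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- trimws(as.character(vals[[j]]))
    out <- ifelse(v %in% truthy, 1L, ifelse(v %in% falsy, 0L, NA_integer_))
    if (anyNA(out)) {
      i <- which(is.na(out))[1]
      vs_stop("non-binary cell at row ", i, " (genome '", ids[i],
              "'), column '", colnames(vals)[j], "': '", v[i], "'")
    }
    m[, j] <- out
  }
  role_matrix(m)
}

#' Write a role matrix to TSV
#'
#' Inverse of [read_role_matrix()]: the written file reads back to an
#' identical matrix.
#'
#' @param x A [role_matrix()].
#' @param path Output file path.
#' @export
write_role_matrix <- function(x, path) {
  df <- data.frame(genome_id = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome taxonomy table
#'
#' TSV with columns `genome_id`, `name`, `phylum`, `class`, `order`,
#' `family`, `cohort`.  Unknown ranks may be left blank; blank cells are
#' stored as empty strings.  `cohort` labels the genome collection a genome
#' belongs to (e.g. human gut vs other body sites).
#'
#' @param path File path, or `"-"` for standard input.
#' @return A data frame of genome records keyed by `genome_id`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  cols <- c("genome_id", "name", "phylum", "class", "order", "family",
            "cohort")
  missing_cols <- setdiff(cols, colnames(df))
  if (length(missing_cols))
    vs_stop("taxonomy file missing column(s): ",
            paste(missing_cols, collapse = ", "))
  df <- df[, cols]
  for (j in seq_along(df)) {
    df[[j]] <- as.character(df[[j]])
    df[[j]][is.na(df[[j]])] <- ""
  }
  if (any(df$genome_id == ""))
    vs_stop("taxonomy row ", which(df$genome_id == "")[1],
            " has an empty genome_id")
  if (anyDuplicated(df$genome_id))
    vs_stop("duplicate genome_id in taxonomy: ",
            df$genome_id[duplicated(df$genome_id)][1])
  df
}

#' Read an experimental evidence table
#'
#' TSV with columns `organism`, `genome_id` (may be blank), `vitamin`,
#' `evidence` and `source`.  `evidence` must be one of
#' `producer_equivalent` (the organism grows without the vitamin or
#' secretes it), `nonproducer_equivalent` (the vitamin is required in a
#' defined growth medium) or `unknown` (ambiguous reports).
#'
#' @param path File path, or `"-"` for standard input.
#' @return A data frame of evidence records.
#' @export
read_evidence <- function(path) {
  df <- read_tsv(path)
  cols <- c("organism", "genome_id", "vitamin", "evidence", "source")
  missing_cols <- setdiff(cols, colnames(df))
  if (length(missing_cols))
    vs_stop("evidence file missing column(s): ",
            paste(missing_cols, collapse = ", "))
  df <- df[, cols]
  for (j in seq_along(df)) {
    df[[j]] <- as.character(df[[j]])
    df[[j]][is.na(df[[j]])] <- ""
  }
  bad <- setdiff(unique(df$vitamin), bvitamins())
  if (length(bad))
    vs_stop("evidence vitamin(s) outside the canonical list: ",
            paste(bad, collapse = ", "))
  levels_ok <- c("producer_equivalent", "nonproducer_equivalent", "unknown")
  if (!all(df$evidence %in% levels_ok))
    vs_stop("evidence values must be one of: ",
            paste(levels_ok, collapse = ", "))
  key <- paste(df$organism, df$vitamin)
  if (anyDuplicated(key))
    vs_stop("more than one evidence record for (",
            key[duplicated(key)][1], ")")
  df
}

#' Read a table of producer calls
#'
#' Reads a predictions TSV as written by [write_predictions()] (or an
#' externally curated per-genome call table with the same layout): a
#' `genome_id` column followed by one 0/1 column per vitamin in canonical
#' order.  Provenance columns are optional and preserved when present.
#'
#' @param path File path, or `"-"` for standard input.
#' @return A `prediction_table` data frame (see [predict_cohort()]).
#' @export
read_predictions <- function(path) {
  df <- read_tsv(path)
  vits <- bvitamins()
  missing_cols <- setdiff(c("genome_id", vits), colnames(df))
  if (length(missing_cols))
    vs_stop("predictions file missing column(s): ",
            paste(missing_cols, collapse = ", "))
  df$genome_id <- as.character(df$genome_id)
  for (v in vits) {
    x <- df[[v]]
    if (!all(x %in% c(0, 1, TRUE, FALSE)))
      vs_stop("non-binary producer call in column '", v, "'")
    df[[v]] <- as.logical(as.integer(x))
  }
  prov <- paste0("provenance_", vits)
  if (!all(prov %in% colnames(df)))
    for (p in prov) df[[p]] <- NA_character_
  out <- df[, c("genome_id", vits, prov)]
  class(out) <- c("prediction_table", class(out))
  out
}

#' Write a prediction table to TSV
#'
#' Producer calls are written as 0/1 columns in canonical vitamin order,
#' followed by one provenance column per vitamin.
#'
#' @param predictions A `prediction_table` from [predict_cohort()].
#' @param path Output file path.
#' @export
write_predictions <- function(predictions, path) {
  vits <- bvitamins()
  df <- as.data.frame(predictions)
  for (v in vits) df[[v]] <- as.integer(df[[v]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## internal: TSV reader with "-" = stdin, blank cells kept as ""
read_tsv <- function(path) {
  con <- if (identical(path, "-")) file("stdin") else path
  utils::read.delim(con, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    stringsAsFactors = FALSE)
}
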