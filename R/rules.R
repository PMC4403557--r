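#' Read B-vitamin producer rule definitions
#'
#' Parses a YAML rule config into a `rule_set`.  The config declares
#' `subsets:` (compound role mnemonics mapped to their atomic member
#' roles; a subset is present in a genome iff every member is) and
#' `vitamins:`, each with `lines:` (rule lines), and optionally
#' `tolerance:` (`tolerable` ids plus `max_missing`) and `mandatory:`
#' (ids whose absence always vetoes producer status).
#'
#' A rule line is a `+`-separated conjunction of terms; a term is a single
#' role/subset id or an OR-group written `(A or B)`.  A genome is a
#' producer iff some line is fully satisfied, or some line fails only by
#' at most `max_missing` tolerable ids with every mandatory id present.
#'
#' @param path YAML config path; defaults to the packaged rule definitions
#'   covering the eight B-vitamin biosynthesis pathways.
#' @return A `rule_set`: list with elements `subsets` (named list of
#'   character vectors) and `rules` (named list of `vitamin_rule`).
#' @examples
#' rs <- read_rules()
#' names(rs$rules)
#' rs$rules$biotin
#' @export
read_rules <- function(path = default_rules_path()) {
  cfg <- yaml::read_yaml(path)
  subsets <- lapply(cfg$subsets, as.character)
  if (is.null(subsets)) subsets <- list()
  for (s in names(subsets)) {
    if (!length(subsets[[s]]))
      vs_stop("subset '", s, "' has no member roles")
    if (s %in% subsets[[s]])
      vs_stop("subset '", s, "' lists itself as a member")
  }
  if (!length(cfg$vitamins)) vs_stop("rule config declares no vitamins")
  rules <- lapply(names(cfg$vitamins), function(v) {
    spec <- cfg$vitamins[[v]]
    if (!length(spec$lines)) vs_stop("vitamin '", v, "' has no rule lines")
    lines <- lapply(spec$lines, parse_rule_line)
    tol <- NULL
    if (!is.null(spec$tolerance)) {
      tol <- list(tolerable = as.character(spec$tolerance$tolerable),
                  max_missing = as.integer(spec$tolerance$max_missing))
      if (is.na(tol$max_missing) || tol$max_missing < 0)
        vs_stop("vitamin '", v, "': tolerance max_missing must be >= 0")
    }
    mandatory <- as.character(spec$mandatory %||% character())
    if (!is.null(tol) && length(intersect(mandatory, tol$tolerable)))
      vs_stop("vitamin '", v, "': mandatory and tolerable roles overlap: ",
              paste(intersect(mandatory, tol$tolerable), collapse = ", "))
    structure(list(vitamin = v, lines = lines, tolerance = tol,
                   mandatory = mandatory),
              class = "vitamin_rule")
  })
  names(rules) <- names(cfg$vitamins)
  rs <- structure(list(subsets = subsets, rules = rules),
                  class = "rule_set")
  validate_rule_refs(rs)
  rs
}

#' Path to the packaged default rule config
#' @return File path of the YAML shipped with the package.
#' @export
default_rules_path <- function() {
  system.file("extdata", "bvitamin_rules.yaml", package = "vitasynth",
              mustWork = TRUE)
}

## internal: "(A or B) + C + D" -> list(c("A","B"), "C", "D")
parse_rule_line <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) vs_stop("empty rule line")
  ## split on '+' at top level; OR-groups contain no '+'
  parts <- trimws(strsplit(line, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(parts))) vs_stop("empty term in rule line: '", line, "'")
  lapply(parts, function(term) {
    if (grepl("^\\(.*\\)$", term)) {
      inner <- sub("^\\((.*)\\)$", "\\1", term)
      ids <- trimws(strsplit(inner, "\\bor\\b")[[1]])
      ids <- ids[nzchar(ids)]
      if (length(ids) < 2)
        vs_stop("OR-group needs at least two alternatives: '", term, "'")
      ids
    } else {
      if (grepl("[() ]", term))
        vs_stop("malformed term '", term, "' in rule line: '", line, "'")
      term
    }
  })
}

## internal: every id referenced by a rule must be a declared subset or an
## atomic role (anything that is not a subset id is atomic by convention);
## compound-looking ids used in lines but not declared are caught when a
## matrix lacking them is evaluated, so here we only check tolerance and
## mandatory ids against the rule's own universe.
validate_rule_refs <- function(rs) {
  for (rule in rs$rules) {
    ids <- rule_ids(rule)
    extra <- setdiff(c(rule$mandatory,
                       if (!is.null(rule$tolerance)) rule$tolerance$tolerable),
                     ids)
    if (length(extra))
      vs_stop("vitamin '", rule$vitamin,
              "': tolerance/mandatory id(s) not used in any rule line: ",
              paste(extra, collapse = ", "))
  }
  invisible(rs)
}

## internal: all role/subset ids named in a rule's lines
rule_ids <- function(rule) {
  unique(unlist(rule$lines, use.names = FALSE))
}

#' Atomic role universe of a rule
#'
#' All atomic role ids a rule can depend on, with declared subset ids
#' expanded to their member roles.
#'
#' @param rule A `vitamin_rule`.
#' @param subsets Named list of subset memberships (from a `rule_set`).
#' @return Character vector of atomic role ids.
#' @export
rule_universe <- function(rule, subsets = list()) {
  ids <- rule_ids(rule)
  unique(unlist(lapply(ids, function(id)
    if (id %in% names(subsets)) subsets[[id]] else id)))
}

#' @export
print.vitamin_rule <- function(x, ...) {
  fmt_term <- function(t)
    if (length(t) > 1) paste0("(", paste(t, collapse = " or "), ")") else t
  cat("Producer rule for ", x$vitamin, ":\n", sep = "")
  for (ln in x$lines)
    cat("  ", paste(vapply(ln, fmt_term, ""), collapse = " + "), "\n",
        sep = "")
  if (!is.null(x$tolerance))
    cat("  tolerance: up to ", x$tolerance$max_missing, " of {",
        paste(x$tolerance$tolerable, collapse = ", "), "} may be missing\n",
        sep = "")
  if (length(x$mandatory))
    cat("  mandatory: ", paste(x$mandatory, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("rule_set: ", length(x$rules), " vitamins, ",
      length(x$subsets), " role subsets\n", sep = "")
  for (r in x$rules) print(r)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
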