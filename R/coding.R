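#' Construct a binary coding matrix
#'
#' A coding matrix records the binary content analysis of a policy corpus:
#' one row per policy, one column per indicator, each cell 1 if the policy
#' text is consistent with the indicator's criterion and 0 otherwise
#' (the binary-count convention — every indicator carries equal weight).
#' The indicator set must match the schema's exactly, including the
#' implicit indicator of any direct-scored primary.
#'
#' @param values numeric/integer matrix of 0s and 1s, policies x indicators.
#' @param policy_ids unique policy identifiers (defaults to rownames).
#' @param indicator_ids indicator codes (defaults to colnames).
#' @param schema optional `pmc_schema` to validate the indicator set against.
#' @return An object of class `pmc_coding`.
#' @export
pmc_coding <- function(values, policy_ids = rownames(values),
                       indicator_ids = colnames(values), schema = NULL) {
  values <- as.matrix(values)
  if (is.null(policy_ids) || is.null(indicator_ids)) {
    stop("policy and indicator identifiers are required")
  }
  if (anyDuplicated(policy_ids)) {
    stop("duplicate policy id(s): ",
         paste(unique(policy_ids[duplicated(policy_ids)]), collapse = ", "))
  }
  ok <- matrix(values %in% c(0, 1), nrow = nrow(values))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary cell at policy '", policy_ids[bad[1, 1]],
         "', indicator '", indicator_ids[bad[1, 2]], "': value ",
         values[bad[1, 1], bad[1, 2]])
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(policy_ids, indicator_ids)
  obj <- structure(list(policy_ids = as.character(policy_ids),
                        indicator_ids = as.character(indicator_ids),
                        values = values),
                   class = "pmc_coding")
  if (!is.null(schema)) check_coding_schema(obj, schema)
  obj
}

check_coding_schema <- function(coding, schema) {
  want <- indicator_ids(schema)
  have <- coding$indicator_ids
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing)) {
    stop("coding matrix is missing indicator(s): ",
         paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("coding matrix has unknown indicator(s): ",
         paste(extra, collapse = ", "))
  }
  invisible(coding)
}

#' @export
print.pmc_coding <- function(x, ...) {
  cat("<pmc_coding> ", length(x$policy_ids), " policies x ",
      length(x$indicator_ids), " indicators; ",
      sum(x$values), " of ", length(x$values), " cells coded 1\n", sep = "")
  invisible(x)
}

#' Read a binary coding matrix from CSV
#'
#' The CSV has one header row naming the indicator ids, a first column of
#' policy ids, and 0/1 cells. Cells other than 0/1 are rejected; with
#' `blank_as_zero = TRUE` empty cells are coerced to 0 (the binary-count
#' convention of scoring absence as non-consistency).
#'
#' @param file path to the CSV.
#' @param schema `pmc_schema` the matrix must conform to.
#' @param blank_as_zero treat empty cells as 0 instead of erroring.
#' @return A validated `pmc_coding`.
#' @export
read_coding_matrix <- function(file, schema, blank_as_zero = FALSE) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        comment.char = "#")
  if (ncol(df) < 2) stop("coding CSV needs a policy-id column plus indicators")
  policies <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (blank_as_zero) cells[!nzchar(trimws(cells))] <- "0"
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  nb <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(nb) > 0) {
    stop("non-binary cell at policy '", policies[nb[1, 1]], "', indicator '",
         colnames(cells)[nb[1, 2]], "': '", cells[nb[1, 1], nb[1, 2]], "'")
  }
  pmc_coding(num, policy_ids = policies, indicator_ids = colnames(cells),
             schema = schema)
}

#' Write a coding matrix to CSV
#'
#' Inverse of [read_coding_matrix()]; read-write-read round-trips
#' bit-exactly.
#'
#' @param coding a `pmc_coding`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_coding_matrix <- function(coding, file) {
  df <- data.frame(policy_id = coding$policy_ids, coding$values,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Load the packaged pilot-programme fixture
#'
#' Returns the published evaluation of 37 county/district health promotion
#' policies from the Sichuan pilot programme: the per-policy
#' primary-variable score table (the indicator-level assignments were never
#' published, so the fixture enters the pipeline at the primary-score
#' stage) and the expert field-evaluation totals on a 0-100 percentage
#' scale. Policy `Pk` and pilot area `k` refer to the same region, so the
#' two tables pair positionally.
#'
#' @return A list with `primary_scores` (tibble: `policy_id`, `X1`..`X10`)
#'   and `expert_scores` (tibble: `area_id`, `total`).
#' @examples
#' fx <- load_paper_fixture()
#' nrow(fx$primary_scores)
#' @export
load_paper_fixture <- function() {
  ps <- utils::read.csv(
    system.file("extdata", "hpp_primary_scores.csv", package = "pmcindex"),
    check.names = FALSE, comment.char = "#")
  es <- utils::read.csv(
    system.file("extdata", "hpp_expert_scores.csv", package = "pmcindex"),
    comment.char = "#")
  stopifnot(nrow(ps) == nrow(es))
  list(primary_scores = tibble::as_tibble(ps),
       expert_scores = tibble::as_tibble(es))
}
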