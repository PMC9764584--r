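#' Score one primary variable from its binary indicators
#'
#' The primary-variable score is the equal-weight mean of the binary
#' assignments in its indicator block: the number of criteria the policy
#' satisfies divided by the number of criteria in the dimension. It lies
#' in `[0, 1]` by construction.
#'
#' @param assignments binary vector (0/1), one entry per indicator of the
#'   primary; must be nonempty.
#' @return The score, a number in `[0, 1]`.
#' @examples
#' primary_score(c(1, 1, 1, 1, 1, 1, 0))  # 6/7
#' @export
primary_score <- function(assignments) {
  if (length(assignments) == 0) stop("empty assignment vector")
  if (!all(assignments %in% c(0, 1))) {
    stop("non-binary assignment: ",
         paste(assignments[!(assignments %in% c(0, 1))][1]))
  }
  sum(assignments) / length(assignments)
}

#' Aggregate primary scores into the PMC index
#'
#' The PMC (Policy Modeling Consistency) index of a policy is the plain sum
#' of its primary-variable scores, so it ranges from 0 to the number of
#' primaries (10 for the default schema). Higher values mean the policy
#' text is more consistent with the full evaluation system.
#'
#' @param primary_scores numeric vector of per-primary scores in `[0, 1]`.
#' @return The index, in `[0, length(primary_scores)]`.
#' @export
pmc_index <- function(primary_scores) {
  if (any(primary_scores < 0 | primary_scores > 1)) {
    stop("primary scores must lie in [0, 1]")
  }
  sum(primary_scores)
}

#' Grade a PMC index value
#'
#' Maps an index value to its consistency letter using left-closed,
#' right-open bands (the top band is closed at the maximum), evaluated on
#' the unrounded value so display rounding can never flip a grade.
#'
#' @param pmc index value(s).
#' @param scale a `pmc_grade_scale`, e.g. `default_schema()$grade_scale`.
#' @return Character vector of grade letters.
#' @examples
#' sc <- default_schema()$grade_scale
#' pmc_grade(c(9, 7, 6.99, 4.99), sc)
#' @export
pmc_grade <- function(pmc, scale) {
  lo <- min(scale$min); hi <- max(scale$max)
  if (any(pmc < lo | pmc > hi)) {
    stop("index value outside the graded range [", lo, ", ", hi, "]")
  }
  top <- which.max(scale$max)
  vapply(pmc, function(v) {
    in_band <- (v >= scale$min & v < scale$max) |
      (seq_len(nrow(scale)) == top & v == scale$max[top])
    scale$grade[which(in_band)[1]]
  }, "")
}

#' Score a policy corpus
#'
#' Runs the full scoring chain for every policy: primary-variable scores
#' by equal-weight means over each indicator block (when starting from a
#' binary coding matrix), the PMC index as their sum, and the consistency
#' grade from the schema's scale. A primary-score table (e.g. the packaged
#' fixture, where indicator-level data were never published) enters the
#' chain directly at the aggregation step.
#'
#' @param input either a `pmc_coding`, or a data frame of primary scores
#'   with a `policy_id` column and one column per primary id.
#' @param schema a `pmc_schema`; defaults to [default_schema()].
#' @return A tibble of class `pmc_scores`: `policy_id`, one column per
#'   primary, `pmc`, `grade`. Row order follows the input.
#' @examples
#' fx <- load_paper_fixture()
#' scores <- score_policies(fx$primary_scores)
#' scores[scores$policy_id == "P7", c("policy_id", "pmc", "grade")]
#' @export
score_policies <- function(input, schema = default_schema()) {
  pids <- primary_ids(schema)
  if (inherits(input, "pmc_coding")) {
    check_coding_schema(input, schema)
    blocks <- indicator_blocks(schema)
    prim <- vapply(blocks, function(cols) {
      apply(input$values[, cols, drop = FALSE], 1, primary_score)
    }, numeric(length(input$policy_ids)))
    prim <- matrix(prim, ncol = length(pids),
                   dimnames = list(NULL, pids))
    out <- tibble::tibble(policy_id = input$policy_ids)
    out <- cbind(out, as.data.frame(prim))
  } else if (is.data.frame(input)) {
    if (!"policy_id" %in% names(input)) {
      stop("primary-score input needs a 'policy_id' column")
    }
    missing <- setdiff(pids, names(input))
    if (length(missing)) {
      stop("primary-score input is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    vals <- as.matrix(input[, pids, drop = FALSE])
    if (any(vals < 0 | vals > 1)) stop("primary scores must lie in [0, 1]")
    out <- data.frame(policy_id = as.character(input$policy_id),
                      vals, check.names = FALSE)
  } else {
    stop("input must be a pmc_coding or a primary-score data frame")
  }
  out$pmc <- rowSums(out[, pids, drop = FALSE])
  out$grade <- pmc_grade(out$pmc, schema$grade_scale)
  out <- tibble::as_tibble(out)
  class(out) <- c("pmc_scores", class(out))
  out
}

#' @export
print.pmc_scores <- function(x, ...) {
  cat("<pmc_scores> ", nrow(x), " policies; mean PMC ",
      format(round(mean(x$pmc), 3), nsmall = 3), "; grades: ",
      paste(names(table(x$grade)), table(x$grade), sep = ":", collapse = " "),
      "\n", sep = "")
  NextMethod()
}
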