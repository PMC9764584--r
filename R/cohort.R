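#' Per-variable corpus means
#'
#' Unweighted arithmetic mean of each primary-variable score and of the
#' PMC index across a policy corpus — the "average of all" row of a score
#' table. Low-mean dimensions are the corpus-wide weaknesses.
#'
#' @param scores a `pmc_scores` tibble from [score_policies()].
#' @return Named numeric vector: one mean per primary, plus `pmc`.
#' @examples
#' fx <- load_paper_fixture()
#' round(variable_means(score_policies(fx$primary_scores)), 3)
#' @export
variable_means <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stop("scores must be a nonempty pmc_scores table")
  }
  cols <- c(grep("^X[0-9]+$", names(scores), value = TRUE), "pmc")
  colMeans(scores[, cols])
}

#' Grade distribution of a corpus
#'
#' Counts policies per consistency grade, in the scale's order (best
#' first). Grades are taken from the score table, i.e. recomputed from the
#' index values, never read from an external column.
#'
#' @param scores a nonempty `pmc_scores` tibble.
#' @param scale grade scale defining the letter order; defaults to the
#'   default schema's.
#' @return Named integer vector of counts, one entry per grade letter;
#'   sums to `nrow(scores)`.
#' @export
grade_distribution <- function(scores, scale = default_schema()$grade_scale) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stop("scores must be a nonempty pmc_scores table")
  }
  counts <- table(factor(scores$grade, levels = scale$grade))
  out <- as.integer(counts)
  names(out) <- scale$grade
  out
}

#' Compare two grade groups variable by variable
#'
#' Splits the corpus by recomputed grade and contrasts the per-variable
#' means of two groups, reporting `group1 - group2` differences — the
#' standard rank-comparison table exposing which evaluation dimensions
#' separate, say, good-consistency from acceptable-consistency policies.
#'
#' @param scores a `pmc_scores` tibble.
#' @param g1,g2 grade letters of the two groups; both must be nonempty.
#' @return A tibble: `variable` (`X1`.., `pmc`), `mean_g1`, `mean_g2`,
#'   `difference`.
#' @examples
#' fx <- load_paper_fixture()
#' rank_comparison(score_policies(fx$primary_scores), "B", "C")
#' @export
rank_comparison <- function(scores, g1, g2) {
  s1 <- scores[scores$grade == g1, , drop = FALSE]
  s2 <- scores[scores$grade == g2, , drop = FALSE]
  if (nrow(s1) == 0) stop("no policies with grade '", g1, "'")
  if (nrow(s2) == 0) stop("no policies with grade '", g2, "'")
  m1 <- variable_means(s1)
  m2 <- variable_means(s2)
  tibble::tibble(variable = names(m1),
                 mean_g1 = unname(m1), mean_g2 = unname(m2),
                 difference = unname(m1 - m2))
}
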