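#' Pearson concordance between index and expert scores
#'
#' Quantifies the formulation-implementation relationship: the
#' product-moment correlation between per-policy PMC index values
#' (formulation side) and expert field-evaluation totals (implementation
#' side), with a two-tailed test from the exact t reference distribution,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' The coefficient is invariant under positive affine rescaling of either
#' vector, so percentage vs raw expert totals give identical results.
#'
#' @param pmc numeric vector of index values.
#' @param expert numeric vector of expert totals, same length.
#' @param alpha two-tailed significance level.
#' @return An object of class `pmc_concordance`: list with `n`, `r`,
#'   `p_two_tailed`, `alpha`, `significant`.
#' @examples
#' fx <- load_paper_fixture()
#' s <- score_policies(fx$primary_scores)
#' pearson_concordance(s$pmc, fx$expert_scores$total)
#' @export
pearson_concordance <- function(pmc, expert, alpha = 0.05) {
  if (length(pmc) != length(expert)) {
    stop("vectors differ in length (", length(pmc), " vs ", length(expert), ")")
  }
  n <- length(pmc)
  if (n < 3) stop("need at least 3 pairs, got ", n)
  dx <- pmc - mean(pmc)
  dy <- expert - mean(expert)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- sum(dx * dy) / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(n = n, r = r, p_two_tailed = p, alpha = alpha,
                 significant = p < alpha),
            class = "pmc_concordance")
}

#' @export
print.pmc_concordance <- function(x, ...) {
  cat("<pmc_concordance> n = ", x$n,
      ", r = ", format(round(x$r, 3), nsmall = 3),
      ", two-tailed p = ", signif(x$p_two_tailed, 3),
      " (alpha = ", x$alpha, "): ",
      if (x$significant) "significant" else "not significant", "\n", sep = "")
  invisible(x)
}

#' Scatter plot of index versus expert scores
#'
#' Deterministic scatter of expert totals against PMC index values with a
#' least-squares trend line. With fewer than 3 points, or a constant
#' x-vector, the trend line (and any inference annotation) is omitted and
#' only the points are drawn.
#'
#' @param pmc,expert paired numeric vectors.
#' @param out output image path (`.png`).
#' @param width,height,dpi image geometry passed to [ggplot2::ggsave()].
#' @return `out`, invisibly; the ggplot object is attached as attribute
#'   `"plot"`.
#' @export
scatter_plot <- function(pmc, expert, out, width = 6, height = 4.5,
                         dpi = 150) {
  if (length(pmc) != length(expert)) stop("vectors differ in length")
  df <- data.frame(pmc = pmc, expert = expert)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = pmc, y = expert)) +
    ggplot2::geom_point(colour = "steelblue4", size = 2) +
    ggplot2::labs(x = "PMC index", y = "Expert field-evaluation total") +
    ggplot2::theme_bw()
  if (length(pmc) >= 3 && stats::sd(pmc) > 0) {
    fit <- stats::lm(expert ~ pmc, data = df)
    p <- p + ggplot2::geom_abline(intercept = stats::coef(fit)[1],
                                  slope = stats::coef(fit)[2],
                                  colour = "firebrick", linewidth = 0.6)
  }
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  attr(out, "plot") <- p
  invisible(out)
}
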