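#' Build the 3x3 PMC-surface matrix of a policy
#'
#' The PMC surface arranges the first nine primary scores as the square
#' matrix `[[X1, X4, X7], [X2, X5, X8], [X3, X6, X9]]` — a symmetric,
#' balanced layout whose rendered 3-D surface localises a policy's
#' weaknesses as depressions. X10 is excluded from the surface (a 10th
#' score cannot enter a square arrangement), so the cell sum plus the X10
#' score recovers the policy's PMC index. Defined only for the canonical
#' 10-primary layout.
#'
#' @param score one policy's scores: a one-row `pmc_scores` subset, or a
#'   named numeric vector with elements `X1`..`X9` (plus optionally `X10`).
#' @param policy_id identifier attached to the matrix (taken from the
#'   `policy_id` column when `score` is a data frame).
#' @return A 3x3 numeric matrix of class `pmc_surface` with attributes
#'   `policy_id` and (when available) `grade`.
#' @examples
#' fx <- load_paper_fixture()
#' s <- score_policies(fx$primary_scores)
#' surface_matrix(s[s$policy_id == "P7", ])
#' @export
surface_matrix <- function(score, policy_id = NULL) {
  grade <- NULL
  if (is.data.frame(score)) {
    if (nrow(score) != 1) stop("supply exactly one policy row")
    policy_id <- policy_id %||% as.character(score$policy_id)
    grade <- if ("grade" %in% names(score)) score$grade else NULL
    score <- unlist(score[, grep("^X[0-9]+$", names(score), value = TRUE)])
  }
  need <- paste0("X", 1:9)
  if (!all(need %in% names(score))) {
    stop("surface requires the 10-primary layout with scores X1..X9; ",
         "missing: ", paste(setdiff(need, names(score)), collapse = ", "))
  }
  cells <- matrix(score[c("X1", "X4", "X7",
                          "X2", "X5", "X8",
                          "X3", "X6", "X9")],
                  nrow = 3, byrow = TRUE)
  structure(cells, class = c("pmc_surface", class(cells)),
            policy_id = policy_id, grade = grade)
}

#' @export
print.pmc_surface <- function(x, ...) {
  cat("<pmc_surface>", attr(x, "policy_id") %||% "", "\n")
  print(matrix(as.numeric(x), 3, 3))
  invisible(x)
}

# bilinear refinement of the 3x3 grid onto an n x n grid over [1, 3]^2
refine_surface <- function(cells, n) {
  xs <- seq(1, 3, length.out = n)
  z <- pracma::interp2(x = 1:3, y = 1:3, Z = cells,
                       xp = rep(xs, each = n), yp = rep(xs, times = n),
                       method = "linear")
  matrix(z, nrow = n)  # [y, x] layout, rows = matrix rows
}

#' Render a PMC surface to an image file
#'
#' Draws the 3-D surface over grid coordinates (1..3) x (1..3) with
#' `z = cell value` and the z-axis fixed to `[0, 1]` so depressions are
#' comparable across policies. By default the 9 raw cells are bilinearly
#' interpolated onto a finer grid for visual smoothness; the raw values
#' remain the data and are annotated below the title. Rendering is
#' deterministic given the options. Matrix row r maps to plot axis y = r
#' and column c to x = c.
#'
#' @param surface a `pmc_surface`.
#' @param out output image path (`.png`).
#' @param interpolate bilinearly refine the grid (`TRUE`) or plot the raw
#'   3x3 grid (`FALSE`).
#' @param n_grid refined grid resolution per axis.
#' @param theta,phi viewpoint angles passed to [graphics::persp()].
#' @param width,height image size in pixels.
#' @return `out`, invisibly.
#' @export
render_surface <- function(surface, out, interpolate = TRUE, n_grid = 41,
                           theta = -40, phi = 25, width = 720, height = 600) {
  stopifnot(inherits(surface, "pmc_surface"))
  cells <- matrix(as.numeric(surface), 3, 3)
  z <- if (interpolate) refine_surface(cells, n_grid) else cells
  ax <- seq(1, 3, length.out = nrow(z))
  pid <- attr(surface, "policy_id") %||% "policy"
  grd <- attr(surface, "grade")
  main <- paste0("PMC surface: ", pid,
                 if (!is.null(grd)) paste0(" (grade ", grd, ")") else "")
  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  # persp takes z[x, y]; our rows are y, so transpose
  # pad zlim by an epsilon: persp() warns when z touches the bound exactly
  graphics::persp(x = ax, y = ax, z = t(z), zlim = c(-1e-6, 1 + 1e-6),
                  theta = theta, phi = phi, expand = 0.7,
                  col = "lightsteelblue", shade = 0.35, ticktype = "detailed",
                  xlab = "column", ylab = "row", zlab = "score",
                  main = main)
  graphics::mtext(paste("cells:", paste(sprintf("%.3f", t(cells)),
                                        collapse = " ")),
                  side = 1, line = 3, cex = 0.8)
  invisible(out)
}
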