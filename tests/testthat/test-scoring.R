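test_that("primary_score is the equal-weight mean of a binary block", {
  expect_equal(round(primary_score(c(1, 1, 1, 1, 1, 1, 0)), 3), 0.857)
  expect_equal(primary_score(c(0, 0, 0, 0)), 0)
  expect_equal(primary_score(rep(1, 5)), 1)
  expect_error(primary_score(numeric(0)), "empty")
  expect_error(primary_score(c(1, 2)), "non-binary")
})

test_that("pmc_index sums primary scores and checks their range", {
  p7 <- c(1, 1, 1, 0.75, 1, 1, 1, 0.25, 1, 1)
  expect_equal(pmc_index(p7), 9.000)
  p1 <- c(0.857, 0.5, 0.5, 0.25, 0.8, 1, 1, 0.25, 1, 1)
  expect_equal(pmc_index(p1), 7.157)
  expect_equal(pmc_index(rep(0, 10)), 0)
  expect_error(pmc_index(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("grading uses left-closed bands on the unrounded index", {
  sc <- default_schema()$grade_scale
  expect_equal(pmc_grade(9.000, sc), "A")
  expect_equal(pmc_grade(6.198, sc), "C")
  expect_equal(pmc_grade(4.021, sc), "D")
  expect_equal(pmc_grade(7.000, sc), "B")   # boundary: left-closed
  expect_equal(pmc_grade(10, sc), "A")      # top band closed above
  expect_equal(pmc_grade(c(0, 4.999999, 5), sc), c("D", "D", "C"))
  expect_error(pmc_grade(10.5, sc), "outside")
  expect_error(pmc_grade(-0.1, sc), "outside")
})

test_that("score_policies scores coding matrices and score tables alike", {
  sch <- default_schema()
  ids <- indicator_ids(sch)
  ones <- pmc_coding(matrix(1, 3, length(ids)),
                     policy_ids = paste0("P", 1:3), indicator_ids = ids)
  s <- score_policies(ones, sch)
  expect_equal(s$pmc, rep(10, 3))
  expect_equal(s$grade, rep("A", 3))

  # exactly one satisfied indicator per block: pmc is the sum of the
  # blocks' unit fractions (computed here as the independent oracle)
  blocks <- indicator_blocks(sch)
  vals <- matrix(0, 1, length(ids), dimnames = list("P1", ids))
  for (blk in blocks) vals[1, blk[1]] <- 1
  s1 <- score_policies(pmc_coding(vals), sch)
  expect_equal(s1$pmc, sum(1 / lengths(blocks)), tolerance = 1e-12)
  expect_equal(round(s1$pmc, 4), 2.9095)

  # a primary-score table enters at the aggregation step
  tab <- data.frame(policy_id = "Q1",
                    t(stats::setNames(c(1, 1, 1, 0.75, 1, 1, 1, 0.25, 1, 1),
                                      paste0("X", 1:10))),
                    check.names = FALSE)
  sq <- score_policies(tab, sch)
  expect_equal(sq$pmc, 9)
  expect_equal(sq$grade, "A")
  expect_error(score_policies(tab[, -1], sch), "policy_id")
  bad <- tab; bad$X3 <- 1.4
  expect_error(score_policies(bad, sch), "\\[0, 1\\]")
})

test_that("vectorised scoring agrees with the brute-force oracle", {
  schemas <- list(tiny_schema(), default_schema())
  set.seed(101)
  for (sch in schemas) {
    for (rep in 1:25) {
      cm <- random_coding(sch, sample(1:6, 1), prob = runif(1))
      expect_equal(score_policies(cm, sch)$pmc, brute_pmc(cm, sch),
                   tolerance = 1e-12)
    }
  }
})

test_that("flipping one 0 to 1 raises the index by exactly 1/T", {
  sch <- default_schema()
  blocks <- indicator_blocks(sch)
  set.seed(202)
  for (rep in 1:20) {
    cm <- random_coding(sch, 1, prob = 0.4)
    zeros <- which(cm$values[1, ] == 0)
    if (length(zeros) == 0) next
    j <- sample(zeros, 1)
    flipped <- cm
    flipped$values[1, j] <- 1L
    t_j <- lengths(blocks)[vapply(blocks, function(b)
      cm$indicator_ids[j] %in% b, TRUE)]
    d <- score_policies(flipped, sch)$pmc - score_policies(cm, sch)$pmc
    expect_equal(d, unname(1 / t_j), tolerance = 1e-12)
    expect_gt(d, 0)
  }
})

test_that("the index is always within [0, n_primaries]", {
  set.seed(303)
  for (rep in 1:20) {
    cm <- random_coding(tiny_schema(), 5, prob = runif(1))
    pmc <- score_policies(cm, tiny_schema())$pmc
    expect_true(all(pmc >= 0 & pmc <= 2))
  }
})
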