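test_that("default schema has the canonical variable system", {
  sch <- default_schema()
  expect_length(sch$primaries, 10)
  counts <- vapply(sch$primaries, function(p) length(p$secondaries), 1L)
  expect_equal(counts, c(7L, 4L, 4L, 4L, 5L, 6L, 5L, 4L, 5L, 0L))
  expect_equal(sum(counts), 44L)
  expect_equal(primary_ids(sch), paste0("X", 1:10))
  # X10 is direct-scored: its implicit indicator is the primary id itself
  expect_identical(indicator_blocks(sch)$X10, "X10")
  expect_length(indicator_ids(sch), 45)
  expect_length(validate_schema(sch), 0)
})

test_that("schema YAML round-trips to an equal schema", {
  sch <- default_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  back <- load_schema(path)
  expect_identical(back$primaries, sch$primaries)
  expect_equal(back$grade_scale, sch$grade_scale)
  # also from a string
  back2 <- load_schema(write_schema(sch))
  expect_identical(back2$primaries, sch$primaries)
})

test_that("load_schema builds small schemas and rejects malformed ones", {
  cfg <- "
name: mini
primaries:
  - id: X1
    label: one
    secondaries:
      - {id: 'X1:1', label: a, criterion: q1}
      - {id: 'X1:2', label: b, criterion: q2}
  - id: X2
    label: two
    secondaries:
      - {id: 'X2:1', label: c, criterion: q3}
      - {id: 'X2:2', label: d, criterion: q4}
grade_bands:
  - {min: 1, max: 2, grade: A}
  - {min: 0, max: 1, grade: B}
"
  sch <- load_schema(cfg)
  expect_length(indicator_ids(sch), 4)
  expect_length(validate_schema(sch), 0)

  dup <- sub("id: 'X1:2'", "id: 'X1:1'", cfg)
  expect_error(load_schema(dup), "duplicate secondary")
  orphan <- sub("id: 'X2:1'", "id: 'X9:1'", cfg)
  expect_error(load_schema(orphan), "parent primary")
  expect_error(load_schema("name: x"), "primaries")
})

test_that("validate_schema reports band violations", {
  sch <- default_schema()
  sch$grade_scale <- grade_scale(min = c(8, 0), max = c(10, 9),
                                 grade = c("A", "B"))
  expect_match(paste(validate_schema(sch), collapse = "; "), "overlap")

  sch2 <- default_schema()
  sch2$grade_scale <- grade_scale(min = c(5, 0), max = c(8, 5),
                                  grade = c("A", "B"))
  expect_match(paste(validate_schema(sch2), collapse = "; "),
               "attainable index range")

  sch3 <- default_schema()
  sch3$grade_scale <- grade_scale(min = c(7, 0), max = c(10, 5),
                                  grade = c("A", "B"))
  expect_match(paste(validate_schema(sch3), collapse = "; "), "gap")
})

test_that("every attainable index value maps to exactly one grade band", {
  for (sch in list(default_schema(), tiny_schema())) {
    scale <- sch$grade_scale
    grid <- seq(0, n_primaries(sch), by = 0.01)
    for (v in grid) {
      hits <- sum((v >= scale$min & v < scale$max) |
                    (v == max(scale$max) & scale$max == max(scale$max)))
      expect_equal(hits, 1)
    }
    expect_length(pmc_grade(grid, scale), length(grid))
  }
})

test_that("multi-input-output table lays out one column per primary", {
  tab <- multi_input_output_table(default_schema())
  expect_equal(names(tab), paste0("X", 1:10))
  expect_equal(tab$X1, paste0("X1:", 1:7))
  expect_equal(tab$X10, c("-", rep("", 6)))
  expect_equal(nrow(tab), 7)

  one <- pmc_schema(
    list(list(id = "Z1", label = "z", secondaries = list(
      list(id = "Z1:1", label = "a", criterion = "?"),
      list(id = "Z1:2", label = "b", criterion = "?"),
      list(id = "Z1:3", label = "c", criterion = "?")))),
    grade_scale(min = 0, max = 1, grade = "A"))
  t1 <- multi_input_output_table(one)
  expect_equal(dim(t1), c(3L, 1L))

  empty <- structure(list(name = "none", primaries = list(),
                          grade_scale = NULL), class = "pmc_schema")
  expect_equal(nrow(multi_input_output_table(empty)), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  multi_input_output_table(default_schema(), path)
  expect_true(file.exists(path))
})
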