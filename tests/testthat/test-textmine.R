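test_that("tokenize lowercases, matches alphanumeric runs, drops stopwords", {
  expect_equal(tokenize("Health education; health SERVICE."),
               c("health", "education", "health", "service"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("THE and OF", stopwords = c("the", "and", "of")),
               character(0))
  expect_equal(tokenize("Case KEEPS", lowercase = FALSE),
               c("Case", "KEEPS"))
  # stopwords are removed after matching, not before
  expect_equal(tokenize("health-care care", stopwords = "care"), "health")
})

test_that("term frequencies rank by count then lexicographically", {
  corp <- list(d1 = c("health", "education", "health"),
               d2 = c("health", "service"),
               d3 = "education")
  tf <- term_frequencies(corp, 10)
  expect_equal(tf$term, c("health", "education", "service"))
  expect_equal(tf$frequency, c(3L, 2L, 1L))
  expect_equal(term_frequencies(list(d = c("a", "a", "a")), 1),
               data.frame(term = "a", frequency = 3L))
  # ties break lexicographically
  tie <- term_frequencies(list(d = c("b", "a")), 5)
  expect_equal(tie$term, c("a", "b"))
  # frequency total equals token count
  expect_equal(sum(term_frequencies(corp, 100)$frequency),
               sum(lengths(corp)))
  expect_error(term_frequencies(list(), 3), "empty corpus")
  expect_error(term_frequencies(corp, 0), "top_k")
  expect_error(term_frequencies(list(c("a"), c("b")), 1), "unique nonempty")
})

test_that("document-scope co-word matrix counts co-presence once per doc", {
  corp <- list(d1 = c("health", "education", "health"),
               d2 = c("health", "service"),
               d3 = "education")
  m <- coword_matrix(corp, c("health", "education"))
  expect_equal(m["health", "education"], 1L)
  expect_equal(m["health", "health"], 2L)      # document frequency
  expect_equal(m["education", "education"], 2L)
  expect_identical(m, t(m))

  one <- coword_matrix(list(d = c("x", "x")), "x")
  expect_equal(as.integer(one), 1L)

  disjoint <- coword_matrix(list(a = "p", b = "q"), c("p", "q"))
  expect_equal(disjoint["p", "q"], 0L)
  # absent term gives a zero row, empty vocabulary errors
  z <- coword_matrix(corp, c("health", "ghost"))
  expect_equal(sum(z["ghost", ]), 0L)
  expect_error(coword_matrix(corp, character(0)), "nonempty")
})

test_that("window-scope counting slides over token positions", {
  corp <- list(d = c("a", "b", "c", "a"))
  # windows of size 2: (a b), (b c), (c a)
  m <- coword_matrix(corp, c("a", "b", "c"), scope = "window",
                     window_size = 2)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["a", "c"], 1L)
  expect_equal(m["b", "c"], 1L)
  expect_equal(m["a", "a"], 2L)   # windows containing "a"
  # a document shorter than the window is one window
  short <- coword_matrix(list(d = c("a", "b")), c("a", "b"),
                         scope = "window", window_size = 10)
  expect_equal(short["a", "b"], 1L)
})

test_that("co-word invariants hold on random corpora", {
  set.seed(5)
  vocab <- letters[1:6]
  for (rep in 1:10) {
    corp <- lapply(1:5, function(i) sample(vocab, sample(0:8, 1), replace = TRUE))
    names(corp) <- paste0("d", 1:5)
    m <- coword_matrix(corp, vocab)
    expect_identical(m, t(m))
    df <- diag(m)
    for (a in vocab) for (b in vocab) {
      expect_lte(m[a, b], min(df[a], df[b]))
    }
    # document order does not matter
    m2 <- coword_matrix(rev(corp), vocab)
    expect_identical(matrix(m2, nrow(m2), dimnames = dimnames(m2)),
                     matrix(m, nrow(m), dimnames = dimnames(m)))
  }
})

test_that("edge-list export keeps nonzero upper-triangle pairs", {
  corp <- list(d1 = c("health", "education"), d2 = c("health", "service"))
  m <- coword_matrix(corp, c("health", "education", "service"))
  e <- coword_edges(m)
  expect_equal(nrow(e), 2)
  expect_true(all(e$count == 1L))
  expect_setequal(paste(e$term_a, e$term_b),
                  c("health education", "health service"))
})
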