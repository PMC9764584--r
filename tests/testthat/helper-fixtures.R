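# Shared fixtures: a miniature schema, random coding matrices, and an
# independent brute-force scoring oracle the vectorised path is checked
# against.

tiny_schema <- function() {
  pmc_schema(
    primaries = list(
      list(id = "A1", label = "dimension one", secondaries = list(
        list(id = "A1:1", label = "a", criterion = "first?"),
        list(id = "A1:2", label = "b", criterion = "second?"))),
      list(id = "A2", label = "dimension two", secondaries = list(
        list(id = "A2:1", label = "c", criterion = "third?"),
        list(id = "A2:2", label = "d", criterion = "fourth?")))),
    grade_scale = grade_scale(min = c(1.5, 0), max = c(2, 1.5),
                              grade = c("A", "B"),
                              connotation = c("high", "low")),
    name = "tiny")
}

random_coding <- function(schema, n_policies, prob = 0.5) {
  ids <- indicator_ids(schema)
  vals <- matrix(rbinom(n_policies * length(ids), 1, prob),
                 nrow = n_policies)
  pmc_coding(vals, policy_ids = paste0("P", seq_len(n_policies)),
             indicator_ids = ids, schema = schema)
}

# brute-force oracle: explicit loops, no shared code with score_policies()
brute_pmc <- function(coding, schema) {
  blocks <- indicator_blocks(schema)
  sapply(seq_along(coding$policy_ids), function(i) {
    total <- 0
    for (blk in blocks) {
      ones <- 0
      for (id in blk) ones <- ones + coding$values[i, id]
      total <- total + ones / length(blk)
    }
    total
  })
}
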