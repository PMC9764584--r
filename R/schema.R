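#' Construct an evaluation schema
#'
#' An evaluation schema is the variable system that drives binary coding and
#' PMC-Index scoring: an ordered set of primary variables (evaluation
#' dimensions), each owning zero or more secondary variables (binary yes/no
#' indicators), plus a grade scale that maps index values to consistency
#' letters. A primary with no secondaries is *direct-scored*: it is coded
#' 0/1 itself and treated as owning one implicit indicator, so the
#' equal-weight mean applies uniformly to every dimension.
#'
#' @param primaries list of primary variables, each a list with elements
#'   `id` (e.g. `"X1"`), `label`, and `secondaries` — a (possibly empty)
#'   list of lists with `id` (e.g. `"X1:1"`), `label`, `criterion`.
#' @param grade_scale a grade scale, see [grade_scale()].
#' @param name schema identifier.
#' @return An object of class `pmc_schema`.
#' @seealso [default_schema()], [load_schema()], [validate_schema()]
#' @export
pmc_schema <- function(primaries, grade_scale, name = "custom") {
  stopifnot(is.list(primaries), is.character(name), length(name) == 1)
  primaries <- lapply(primaries, function(p) {
    p$secondaries <- lapply(p$secondaries %||% list(), function(s) {
      list(id = as.character(s$id), label = as.character(s$label %||% s$id),
           criterion = as.character(s$criterion %||% ""))
    })
    list(id = as.character(p$id), label = as.character(p$label %||% p$id),
         secondaries = p$secondaries)
  })
  structure(list(name = name, primaries = primaries,
                 grade_scale = grade_scale),
            class = "pmc_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a grade scale
#'
#' Bands are left-closed, right-open intervals `[min, max)`, with the top
#' band closed at the maximum attainable index, so that every real index
#' value in `[0, max]` belongs to exactly one band. Published band labels
#' such as "7~8.99" are a 2-decimal display convention for the half-open
#' interval `[7, 9)`.
#'
#' @param min,max numeric lower/upper bounds, in index units.
#' @param grade letter for each band (e.g. `"A"`), ordered best first.
#' @param connotation free-text meaning of each band.
#' @return A `data.frame` with class `pmc_grade_scale`.
#' @export
grade_scale <- function(min, max, grade, connotation = grade) {
  stopifnot(length(min) == length(max), length(grade) == length(min))
  out <- data.frame(min = as.numeric(min), max = as.numeric(max),
                    grade = as.character(grade),
                    connotation = as.character(connotation),
                    stringsAsFactors = FALSE)
  class(out) <- c("pmc_grade_scale", "data.frame")
  out
}

#' The default health-promotion-policy evaluation schema
#'
#' The packaged variable system used throughout the worked example: 10
#' primary variables (policy nature, timeliness, relevance, incentives and
#' constraints, subjects, content, evaluation, issuing agency, objects,
#' disclosure) with 44 secondary indicators distributed as
#' (7, 4, 4, 4, 5, 6, 5, 4, 5, 0); X10 (policy disclosure) is
#' direct-scored. The attached grade scale is A `[9, 10]` excellent,
#' B `[7, 9)` good, C `[5, 7)` acceptable, D `[0, 5)` poor consistency.
#'
#' @return A `pmc_schema`.
#' @examples
#' sch <- default_schema()
#' length(sch$primaries)
#' @export
default_schema <- function() {
  sec <- function(id, label, q) list(id = id, label = label, criterion = q)
  primaries <- list(
    list(id = "X1", label = "Policy nature", secondaries = list(
      sec("X1:1", "prediction",     "Does the policy reflect prediction?"),
      sec("X1:2", "supervision",    "Does the policy reflect supervision?"),
      sec("X1:3", "recommendation", "Does the policy reflect suggestion?"),
      sec("X1:4", "support",        "Does the policy reflect support?"),
      sec("X1:5", "guidance",       "Does the policy reflect guidance?"),
      sec("X1:6", "diagnosis",      "Does the policy reflect diagnosis?"),
      sec("X1:7", "description",    "Does the policy reflect description?"))),
    list(id = "X2", label = "Policy timeliness", secondaries = list(
      sec("X2:1", "long term",   "Does it involve content longer than 5 years?"),
      sec("X2:2", "medium-term", "Does it involve a 3-5 year horizon?"),
      sec("X2:3", "short term",  "Does it involve a 1-3 year horizon?"),
      sec("X2:4", "temporary",   "Does it involve content under 1 year?"))),
    list(id = "X3", label = "Policy relevance", secondaries = list(
      sec("X3:1", "national policy",   "Is it related to national policies?"),
      sec("X3:2", "provincial policy", "Is it related to provincial policies?"),
      sec("X3:3", "municipal policy",  "Is it related to municipal policies?"),
      sec("X3:4", "other policies",    "Is it related to other (county-level etc.) policies?"))),
    list(id = "X4", label = "Incentives and constraints", secondaries = list(
      sec("X4:1", "talent incentives", "Is there talent incentive content?"),
      sec("X4:2", "fiscal incentives", "Are there fiscal and tax incentives?"),
      sec("X4:3", "administrative approval incentives", "Is there administrative approval support?"),
      sec("X4:4", "laws and regulations", "Do laws and regulations support it?"))),
    list(id = "X5", label = "Policy subjects", secondaries = list(
      sec("X5:1", "politics",    "Does the policy involve the political field?"),
      sec("X5:2", "economy",     "Does the policy involve the economic field?"),
      sec("X5:3", "technology",  "Does the policy involve the technical field?"),
      sec("X5:4", "society",     "Does the policy involve social and livelihood fields?"),
      sec("X5:5", "environmental protection", "Does the policy involve environmental protection?"))),
    list(id = "X6", label = "Policy content", secondaries = list(
      sec("X6:1", "improve the policy system",  "Does the content improve the policy system?"),
      sec("X6:2", "strengthen organizational management", "Does the content strengthen organizational management?"),
      sec("X6:3", "building a healthy place",   "Does the content establish a healthy place?"),
      sec("X6:4", "spreading health culture",   "Does the content spread healthy culture?"),
      sec("X6:5", "creating a healthy environment", "Does the content create a healthy environment?"),
      sec("X6:6", "foster healthy people",      "Does the content cultivate healthy people?"))),
    list(id = "X7", label = "Policy evaluation", secondaries = list(
      sec("X7:1", "specific goals",    "Does the policy have specific goals?"),
      sec("X7:2", "detailed planning", "Is the policy planning detailed?"),
      sec("X7:3", "scientific programme", "Is the policy programme scientific?"),
      sec("X7:4", "sufficient basis",  "Is the policy basis sufficient?"),
      sec("X7:5", "clear rights and responsibilities", "Does the policy have clear rights and responsibilities?"))),
    list(id = "X8", label = "Issuing agency", secondaries = list(
      sec("X8:1", "people's congress", "Is the issuing agency the people's congress?"),
      sec("X8:2", "party commission",  "Is the issuing agency the party commission?"),
      sec("X8:3", "government offices", "Is the issuing agency the local government office?"),
      sec("X8:4", "other government departments", "Is the issuing agency another functional department?"))),
    list(id = "X9", label = "Policy objects", secondaries = list(
      sec("X9:1", "public institution", "Does it affect institutions (schools, hospitals, ...)?"),
      sec("X9:2", "enterprise units",   "Does it affect enterprise units?"),
      sec("X9:3", "public environment", "Does it affect the public environment (parks, trails, ...)?"),
      sec("X9:4", "communities",        "Does it affect communities?"),
      sec("X9:5", "families and individuals", "Does it affect families and individuals?"))),
    list(id = "X10", label = "Policy disclosure", secondaries = list())
  )
  scale <- grade_scale(
    min = c(9, 7, 5, 0), max = c(10, 9, 7, 5),
    grade = c("A", "B", "C", "D"),
    connotation = c("Excellent consistency", "Good consistency",
                    "Acceptable consistency", "Poor consistency"))
  pmc_schema(primaries, scale, name = "hpp-default")
}

#' @export
print.pmc_schema <- function(x, ...) {
  cat("<pmc_schema> ", x$name, "\n", sep = "")
  cat(" ", length(x$primaries), " primary variables, ",
      sum(vapply(x$primaries, function(p) length(p$secondaries), 1L)),
      " secondary indicators\n", sep = "")
  for (p in x$primaries) {
    n <- length(p$secondaries)
    cat("  ", p$id, " ", p$label, " (",
        if (n == 0) "direct-scored" else paste0(n, " indicators"), ")\n",
        sep = "")
  }
  cat("  grades:", paste(x$grade_scale$grade, collapse = " > "), "\n")
  invisible(x)
}

# ---- accessors ------------------------------------------------------------

#' Schema accessors
#'
#' `primary_ids()` returns the ordered primary codes; `indicator_ids()` the
#' full ordered indicator set a coding matrix must supply — the secondary
#' ids, with a direct-scored primary contributing its own id as the implicit
#' indicator; `indicator_blocks()` the indicator ids grouped by primary;
#' `n_primaries()` the number of primaries, which is also the maximum
#' attainable PMC index.
#'
#' @param schema a `pmc_schema`.
#' @return Character vector(s) of ids; a named list for
#'   `indicator_blocks()`; an integer for `n_primaries()`.
#' @export
primary_ids <- function(schema) {
  vapply(schema$primaries, `[[`, "", "id")
}

#' @rdname primary_ids
#' @export
indicator_blocks <- function(schema) {
  out <- lapply(schema$primaries, function(p) {
    if (length(p$secondaries) == 0) p$id
    else vapply(p$secondaries, `[[`, "", "id")
  })
  names(out) <- primary_ids(schema)
  out
}

#' @rdname primary_ids
#' @export
indicator_ids <- function(schema) {
  unlist(indicator_blocks(schema), use.names = FALSE)
}

#' @rdname primary_ids
#' @export
n_primaries <- function(schema) length(schema$primaries)

# ---- validation -----------------------------------------------------------

#' Validate an evaluation schema
#'
#' Checks well-formedness and returns a character vector of violated
#' invariants (zero-length when the schema is valid): unique primary ids,
#' unique secondary ids, secondary ids prefixed by their parent primary
#' code, and a grade scale whose bands are ordered, non-overlapping, and
#' jointly cover `[0, n_primaries]` without gaps.
#'
#' @param schema a `pmc_schema`.
#' @return Character vector of human-readable violations; `character(0)`
#'   iff the schema is well-formed.
#' @export
validate_schema <- function(schema) {
  bad <- character(0)
  if (!inherits(schema, "pmc_schema")) {
    return("not a pmc_schema object")
  }
  pids <- primary_ids(schema)
  if (anyDuplicated(pids)) {
    bad <- c(bad, paste0("duplicate primary id(s): ",
                         paste(unique(pids[duplicated(pids)]), collapse = ", ")))
  }
  sids <- unlist(lapply(schema$primaries, function(p)
    vapply(p$secondaries, `[[`, "", "id")), use.names = FALSE)
  if (anyDuplicated(sids)) {
    bad <- c(bad, paste0("duplicate secondary id(s): ",
                         paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  }
  for (p in schema$primaries) {
    for (s in p$secondaries) {
      if (!startsWith(s$id, paste0(p$id, ":"))) {
        bad <- c(bad, paste0("secondary '", s$id,
                             "' does not encode its parent primary '", p$id, "'"))
      }
    }
  }
  gs <- schema$grade_scale
  if (is.null(gs) || nrow(gs) == 0) {
    bad <- c(bad, "grade scale is empty")
    return(bad)
  }
  if (anyDuplicated(gs$grade)) bad <- c(bad, "duplicate grade letters")
  if (any(gs$max <= gs$min)) bad <- c(bad, "grade band with max <= min")
  o <- order(gs$min)
  lo <- gs$min[o]; hi <- gs$max[o]
  if (any(utils::head(hi, -1) > lo[-1] + 1e-12)) {
    bad <- c(bad, "overlapping grade bands")
  }
  if (any(abs(utils::head(hi, -1) - lo[-1]) > 1e-9)) {
    bad <- c(bad, "gap between grade bands")
  }
  mx <- n_primaries(schema)
  if (abs(lo[1] - 0) > 1e-9 || abs(hi[length(hi)] - mx) > 1e-9) {
    bad <- c(bad, paste0("grade bands cover [", lo[1], ", ", hi[length(hi)],
                         "] but the attainable index range is [0, ", mx, "]"))
  }
  bad
}

# ---- config I/O -----------------------------------------------------------

#' Load an evaluation schema from a YAML config
#'
#' The config is a hierarchical document with keys `name`,
#' `primaries: [{id, label, secondaries: [{id, label, criterion}]}]` and
#' `grade_bands: [{min, max, grade, connotation}]`. Ordering is preserved
#' from the config. The loaded schema must pass [validate_schema()].
#'
#' @param source path to a YAML file, or a single YAML string.
#' @return A `pmc_schema`.
#' @export
load_schema <- function(source) {
  cfg <- if (length(source) == 1 && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(cfg$primaries) || is.null(cfg$grade_bands)) {
    stop("schema config must provide 'primaries' and 'grade_bands'")
  }
  gb <- cfg$grade_bands
  scale <- grade_scale(
    min = vapply(gb, function(b) as.numeric(b$min), 1),
    max = vapply(gb, function(b) as.numeric(b$max), 1),
    grade = vapply(gb, function(b) as.character(b$grade), ""),
    connotation = vapply(gb, function(b) as.character(b$connotation %||% b$grade), ""))
  schema <- pmc_schema(cfg$primaries, scale, name = cfg$name %||% "unnamed")
  bad <- validate_schema(schema)
  if (length(bad)) {
    stop("invalid schema config:\n  - ", paste(bad, collapse = "\n  - "))
  }
  schema
}

#' Serialise a schema to YAML
#'
#' Inverse of [load_schema()]: `load_schema(write_schema(s))` reproduces
#' `s` up to attribute class.
#'
#' @param schema a `pmc_schema`.
#' @param path optional file path; when `NULL` the YAML text is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
write_schema <- function(schema, path = NULL) {
  cfg <- list(
    name = schema$name,
    primaries = lapply(schema$primaries, function(p) {
      list(id = p$id, label = p$label,
           secondaries = lapply(p$secondaries, function(s)
             list(id = s$id, label = s$label, criterion = s$criterion)))
    }),
    grade_bands = lapply(seq_len(nrow(schema$grade_scale)), function(i) {
      b <- schema$grade_scale[i, ]
      list(min = b$min, max = b$max, grade = b$grade,
           connotation = b$connotation)
    }))
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Lay out the multi-input-output table
#'
#' The multi-input-output table is the columnar presentation of the
#' variable system: one column per primary variable listing its secondary
#' indicator ids in order; a direct-scored primary renders a single `"-"`
#' cell. Shorter columns are padded with empty strings.
#'
#' @param schema a valid `pmc_schema`.
#' @param path optional CSV path to write the layout to.
#' @return A character `data.frame`, one column per primary.
#' @export
multi_input_output_table <- function(schema, path = NULL) {
  if (length(schema$primaries) == 0) {
    return(data.frame())
  }
  bad <- validate_schema(schema)
  if (length(bad)) stop("invalid schema: ", paste(bad, collapse = "; "))
  cols <- lapply(schema$primaries, function(p) {
    if (length(p$secondaries) == 0) "-"
    else vapply(p$secondaries, `[[`, "", "id")
  })
  depth <- if (length(cols)) max(lengths(cols)) else 0L
  out <- as.data.frame(lapply(cols, function(x) c(x, rep("", depth - length(x)))),
                       col.names = primary_ids(schema), check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
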