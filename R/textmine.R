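#' Tokenize a document
#'
#' Splits raw text into an ordered token stream: maximal alphanumeric runs
#' matched by `pattern`, lowercased when `lowercase = TRUE`, with stopwords
#' removed after matching (so stopword comparison sees the normalised
#' form). Languages without whitespace word boundaries should be segmented
#' upstream and supplied pre-tokenized.
#'
#' @param text a character scalar (or vector, concatenated with spaces).
#' @param lowercase lowercase before matching.
#' @param pattern regular expression for one token.
#' @param stopwords tokens to drop after matching.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Health education; health SERVICE.")
#' @export
tokenize <- function(text, lowercase = TRUE, pattern = "[[:alnum:]]+",
                     stopwords = character(0)) {
  text <- paste(text, collapse = " ")
  if (lowercase) {
    text <- tolower(text)
    stopwords <- tolower(stopwords)
  }
  toks <- regmatches(text, gregexpr(pattern, text))[[1]]
  toks[!toks %in% stopwords]
}

as_corpus <- function(corpus) {
  if (!is.list(corpus)) stop("corpus must be a named list of token vectors")
  if (length(corpus) == 0) return(corpus)
  if (is.null(names(corpus)) || anyDuplicated(names(corpus)) ||
      any(!nzchar(names(corpus)))) {
    stop("corpus documents must have unique nonempty names (doc ids)")
  }
  lapply(corpus, as.character)
}

#' Ranked term frequencies of a corpus
#'
#' Total occurrence counts across all documents, ranked by descending
#' frequency with ties broken lexicographically — the "high-frequency
#' word" selection step of co-word analysis.
#'
#' @param corpus named list of token vectors (doc id -> tokens), e.g. from
#'   [tokenize()].
#' @param top_k maximum number of terms returned (at least 1); a `top_k`
#'   beyond the vocabulary size returns the full vocabulary.
#' @return A data.frame with columns `term`, `frequency`.
#' @export
term_frequencies <- function(corpus, top_k = 20L) {
  corpus <- as_corpus(corpus)
  if (length(corpus) == 0) stop("empty corpus")
  if (top_k < 1) stop("top_k must be at least 1")
  tab <- table(unlist(corpus, use.names = FALSE))
  if (length(tab) == 0) {
    return(data.frame(term = character(0), frequency = integer(0)))
  }
  df <- data.frame(term = names(tab), frequency = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$term), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Co-word co-occurrence matrix
#'
#' Builds the symmetric term-by-term co-occurrence matrix over a selected
#' vocabulary. Under document scope, cell (a, b) counts the documents
#' containing both terms (presence, not multiplicity — the standard
#' co-word convention) and the diagonal holds each term's document
#' frequency. Under window scope the counting unit is every sliding window
#' of `window_size` consecutive tokens (a document shorter than the window
#' contributes one window). Terms absent from the corpus get zero rows.
#'
#' @param corpus named list of token vectors.
#' @param terms nonempty character vector of vocabulary terms.
#' @param scope `"document"` or `"window"`.
#' @param window_size window length in tokens (window scope only).
#' @return A symmetric integer matrix with `terms` as dimnames, plus
#'   attributes `scope` and (for window scope) `window_size`.
#' @export
coword_matrix <- function(corpus, terms, scope = c("document", "window"),
                          window_size = 10L) {
  corpus <- as_corpus(corpus)
  scope <- match.arg(scope)
  if (length(terms) == 0) stop("terms must be nonempty")
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("terms must be unique")
  units <- if (scope == "document") {
    corpus
  } else {
    if (window_size < 1) stop("window_size must be at least 1")
    unlist(lapply(corpus, function(toks) {
      n <- length(toks)
      if (n <= window_size) return(list(toks))
      lapply(seq_len(n - window_size + 1L),
             function(i) toks[i:(i + window_size - 1L)])
    }), recursive = FALSE)
  }
  counts <- matrix(0L, length(terms), length(terms),
                   dimnames = list(terms, terms))
  for (u in units) {
    present <- terms %in% u
    counts <- counts + outer(present, present)
  }
  storage.mode(counts) <- "integer"
  structure(counts, scope = scope,
            window_size = if (scope == "window") window_size else NULL)
}

#' Export a co-word matrix as an edge list
#'
#' Upper-triangle nonzero co-occurrences as a three-column table, the
#' format network tools ingest.
#'
#' @param counts a matrix from [coword_matrix()].
#' @return A data.frame with columns `term_a`, `term_b`, `count`.
#' @export
coword_edges <- function(counts) {
  idx <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
  data.frame(term_a = rownames(counts)[idx[, 1]],
             term_b = colnames(counts)[idx[, 2]],
             count = counts[idx],
             stringsAsFactors = FALSE)
}
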