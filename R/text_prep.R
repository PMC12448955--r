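# Tokenisation, stop-word removal and document-term matrix construction,
# shared by the exploration (correlations, topics) and examination (TF-IDF,
# KWIC) stages.
#
# No stemming is performed anywhere: clinical and pathologic vocabulary stems
# badly (stems are often unrecognisable partial words), so variant discovery
# is handled downstream by substring search over the intact vocabulary.

#' Tokenise free text
#'
#' Splits text into word tokens and punctuation tokens. Word tokens are runs
#' of letters/digits; internal hyphens are kept inside the token (so
#' `plasmodium-like` is a single searchable term) while any other punctuation
#' character — including `/`, so `freeze/thaw` yields two word tokens — is
#' emitted as its own punctuation token. Newlines count as punctuation:
#' merged findings sections are newline-separated, so a phrase can never
#' bridge two sections. Punctuation tokens are retained because the
#' keyword-in-context phrase rule needs them as phrase boundaries.
#'
#' @param text A single character string (may be empty).
#' @param accession_id Optional id recorded on every token row.
#' @return A tibble (`token_stream`) with columns `accession_id`, `surface`,
#'   `normalized` (lowercased surface), `is_punct`, `start` (1-based
#'   character offset).
#' @examples
#' tokenize("No evidence of pneumonia.")
#' @export
tokenize <- function(text, accession_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(accession_id = character(), surface = character(),
                          normalized = character(), is_punct = logical(),
                          start = integer()))
  }
  pattern <- "[[:alnum:]]+(?:-[[:alnum:]]+)*|\n|[^[:alnum:][:space:]]"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(accession_id = character(), surface = character(),
                          normalized = character(), is_punct = logical(),
                          start = integer()))
  }
  surface <- regmatches(text, list(m))[[1]]
  is_punct <- !grepl("^[[:alnum:]]", surface)
  tibble::tibble(
    accession_id = rep(accession_id, length(surface)),
    surface = surface,
    normalized = tolower(surface),
    is_punct = is_punct,
    start = as.integer(m)
  )
}

#' Tokenise every document of a corpus
#'
#' @param corpus A `necropsy_corpus`.
#' @return A named list of token streams, one per accession id, in corpus
#'   order.
#' @export
tokenize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  streams <- Map(tokenize, corpus$documents$text, corpus$documents$accession_id)
  stats::setNames(streams, corpus$documents$accession_id)
}

#' Default English stop-word list
#'
#' The standard snowball English list shipped with the package
#' (`inst/extdata/stopwords_en.txt`), lowercased, one term per line.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "necrotext")
  load_stopwords(path)
}

#' Load a stop-word list from file
#'
#' @param path UTF-8 text file, one term per line; blank lines and `#`
#'   comments ignored.
#' @return Character vector of lowercase stop words.
#' @export
load_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Remove stop words from a token stream
#'
#' Drops word tokens whose normalised form is in `stoplist`. Punctuation
#' tokens are untouched: they remain available as phrase boundaries.
#'
#' @param stream A token stream from [tokenize()].
#' @param stoplist Character vector of lowercase stop words.
#' @return The filtered token stream.
#' @export
remove_stopwords <- function(stream, stoplist = default_stopwords()) {
  stream[stream$is_punct | !(stream$normalized %in% stoplist), , drop = FALSE]
}

#' Build a document-term matrix
#'
#' Counts normalised word tokens per document over a stop-word-filtered
#' vocabulary. Pure-numeral tokens are excluded by default (they clutter
#' TF-IDF tables without carrying findings) but remain in token streams for
#' keyword-in-context windows. Vocabulary order is lexicographic, so the
#' matrix is fully deterministic.
#'
#' @param corpus A non-empty `necropsy_corpus`.
#' @param stoplist Stop words to exclude (default [default_stopwords()]).
#' @param keep_numerals Keep pure-numeral tokens in the vocabulary?
#' @return A `necropsy_dtm`: list with `counts` (sparse docs x terms
#'   [Matrix::dgCMatrix-class] with dimnames), `doc_ids`, `vocabulary`,
#'   `n_docs`, and `doc_freq` (documents containing each term).
#' @export
build_dtm <- function(corpus, stoplist = default_stopwords(), keep_numerals = FALSE) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  if (n_docs(corpus) == 0L) stop("empty corpus", call. = FALSE)
  streams <- tokenize_corpus(corpus)
  term_lists <- lapply(streams, function(s) {
    s <- remove_stopwords(s, stoplist)
    terms <- s$normalized[!s$is_punct]
    if (!keep_numerals) terms <- terms[!grepl("^[0-9]+$", terms)]
    terms
  })
  vocab <- sort(unique(unlist(term_lists, use.names = FALSE)))
  doc_ids <- corpus$documents$accession_id
  if (length(vocab) == 0L) {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = integer(),
                                   dims = c(length(doc_ids), 0L),
                                   dimnames = list(doc_ids, character()))
  } else {
    ijx <- lapply(seq_along(term_lists), function(d) {
      tl <- term_lists[[d]]
      if (!length(tl)) return(NULL)
      tab <- table(tl)
      data.frame(i = d, j = match(names(tab), vocab), x = as.integer(tab))
    })
    ijx <- do.call(rbind, ijx)
    counts <- Matrix::sparseMatrix(i = ijx$i, j = ijx$j, x = ijx$x,
                                   dims = c(length(doc_ids), length(vocab)),
                                   dimnames = list(doc_ids, vocab))
  }
  new_dtm(counts)
}

new_dtm <- function(counts) {
  structure(
    list(counts = counts,
         doc_ids = rownames(counts),
         vocabulary = colnames(counts),
         n_docs = nrow(counts),
         doc_freq = Matrix::colSums(counts > 0)),
    class = "necropsy_dtm"
  )
}

#' Construct a document-term matrix from a count matrix
#'
#' Mainly for tests and simulations; `build_dtm()` is the corpus-facing
#' constructor.
#'
#' @param counts Non-negative integer matrix (docs x terms) with dimnames.
#' @return A `necropsy_dtm`.
#' @export
as_dtm <- function(counts) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  new_dtm(Matrix::Matrix(counts, sparse = TRUE))
}

#' @export
print.necropsy_dtm <- function(x, ...) {
  cat("<necropsy_dtm> ", x$n_docs, " documents x ", length(x$vocabulary),
      " terms, ", sum(x$counts), " tokens\n", sep = "")
  invisible(x)
}
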