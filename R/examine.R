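# Examine stage: TF-IDF keyword retrieval, partial-word search,
# keyword-in-context (KWIC) retrieval with a punctuation-bounded phrase
# rule, negation-aware counting of positive records, and export of matched
# records.

#' Collated table of top TF-IDF words per document
#'
#' For each document, ranks terms by term frequency x inverse document
#' frequency and keeps the top `words_per_document` (default forty); the
#' per-document lists are collated into one table sorted by TF-IDF
#' descending. With
#' \eqn{tf = n_{dt} / n_d} (term count over filtered document length) and
#' \eqn{idf = \ln(N / n_t)} (log of corpus size over documents containing
#' the term), a high \eqn{tf \cdot idf} flags a word used heavily in one
#' document but rarely elsewhere — the words most likely to differentiate
#' that record. A term present in every document has idf 0 and can never
#' outrank a document-specific term. Ties in a document's ranking are broken
#' by term lexicographic order.
#'
#' @param dtm A `necropsy_dtm` with at least one document and term.
#' @param words_per_document Words kept per document (default 40). Smaller
#'   values give a more concise overview; larger values surface rarer
#'   variants at the cost of noise.
#' @return Tibble `accession_id`, `term`, `tf`, `idf`, `tfidf`.
#' @export
top_tfidf_table <- function(dtm, words_per_document = 40) {
  stopifnot(inherits(dtm, "necropsy_dtm"), words_per_document >= 1)
  if (dtm$n_docs == 0L) stop("empty corpus", call. = FALSE)
  if (length(dtm$vocabulary) == 0L) stop("empty vocabulary", call. = FALSE)
  counts <- dtm$counts
  doc_len <- Matrix::rowSums(counts)
  idf <- log(dtm$n_docs / dtm$doc_freq)
  summ <- Matrix::summary(counts)   # i, j, x triplets of nonzero counts
  tf_v <- unname(summ$x / doc_len[summ$i])
  idf_v <- unname(idf[summ$j])
  entries <- tibble::tibble(
    accession_id = dtm$doc_ids[summ$i],
    term = dtm$vocabulary[summ$j],
    tf = tf_v,
    idf = idf_v,
    tfidf = tf_v * idf_v
  )
  kept <- dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(entries, .data$accession_id),
                   dplyr::desc(.data$tfidf), .data$term),
    n = words_per_document
  )
  dplyr::arrange(dplyr::ungroup(kept),
                 dplyr::desc(.data$tfidf), .data$accession_id, .data$term)
}

#' Partial-word search over a term table
#'
#' Case-insensitive substring match at any position within the term — the
#' replacement for stemming: searching `"plas"` surfaces `plasmodium`,
#' `plasmodial` and `plasmodium-like` together so the user can select every
#' variant, and searching `"an"` matches not only `anaerobic` and `animal`
#' but also `organism` and `avian`.
#'
#' @param table Any tibble with a `term` column (typically from
#'   [top_tfidf_table()]).
#' @param query Non-empty search string (matched literally, not as a regex).
#' @return The matching rows, original order preserved.
#' @export
search_table <- function(table, query) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  table[grepl(tolower(query), tolower(table$term), fixed = TRUE), , drop = FALSE]
}

#' Keyword-in-context hits for a term
#'
#' Finds every exact-token occurrence of `term` (normalised-form equality —
#' variants like `plasmodial` are separate terms, selected individually) and
#' returns, per hit, a window of up to `window` word tokens on each side and
#' the *phrase*: the sub-span delimited by the nearest punctuation token
#' before and after the hit within the window, falling back to the window
#' edge when there is none. A hit is flagged negated when any word token of
#' its phrase is a negation cue, so "no evidence of pneumonia" negates
#' `pneumonia` while "severe pneumonia. No nephritis." does not — the full
#' stop bounds the phrase before the cue.
#'
#' @param stream A token stream from [tokenize()] (un-stopworded: negation
#'   cues must still be present).
#' @param term Normalised (lowercase) term to locate.
#' @param window Word tokens on each side of the hit (default 10; `Inf`
#'   extends to the whole document).
#' @param lexicon Negation cues, a [negation_lexicon()].
#' @return Tibble `accession_id`, `term`, `token_position` (row index of the
#'   hit in the stream), `window_text`, `phrase_text`, `negated`.
#' @export
kwic <- function(stream, term, window = 10, lexicon = negation_lexicon()) {
  stopifnot(window >= 1)
  empty <- tibble::tibble(accession_id = character(), term = character(),
                          token_position = integer(), window_text = character(),
                          phrase_text = character(), negated = logical())
  if (nrow(stream) == 0L) return(empty)
  word_pos <- which(!stream$is_punct)        # stream rows of word tokens
  hits <- which(!stream$is_punct & stream$normalized == term)
  if (!length(hits)) return(empty)
  word_rank <- match(hits, word_pos)         # hit's index among word tokens
  rows <- lapply(seq_along(hits), function(h) {
    p <- hits[h]
    r <- word_rank[h]
    lo_rank <- if (is.finite(window)) max(1L, r - window) else 1L
    hi_rank <- if (is.finite(window)) min(length(word_pos), r + window) else length(word_pos)
    span <- word_pos[lo_rank]:word_pos[hi_rank]
    punct_in_span <- span[stream$is_punct[span]]
    before <- punct_in_span[punct_in_span < p]
    after <- punct_in_span[punct_in_span > p]
    lo <- if (length(before)) max(before) + 1L else span[1]
    hi <- if (length(after)) min(after) - 1L else span[length(span)]
    phrase <- lo:hi
    phrase_words <- stream$normalized[phrase][!stream$is_punct[phrase]]
    tibble::tibble(
      accession_id = stream$accession_id[p],
      term = term,
      token_position = p,
      window_text = paste(stream$surface[span], collapse = " "),
      phrase_text = paste(stream$surface[phrase][!stream$is_punct[phrase]],
                          collapse = " "),
      negated = any(phrase_words %in% lexicon$terms)
    )
  })
  dplyr::bind_rows(rows)
}

#' Negation cue lexicon
#'
#' Lowercase cue words whose presence anywhere within a hit's phrase negates
#' it. The default covers the negation constructions common in necropsy
#' prose ("no evidence of X", "without X", "X absent", "free of X",
#' "negative for X", "unremarkable"). Phrase-level scoping means
#' pseudo-negations such as "not only" also negate — an accepted
#' imperfection of rule-based negation detection over natural language.
#'
#' @param terms Character vector of cues (lowercased).
#' @return A `negation_lexicon`.
#' @export
negation_lexicon <- function(terms = c("no", "not", "without", "absent",
                                       "absence", "free", "negative", "non",
                                       "neither", "nor", "unremarkable")) {
  terms <- tolower(as.character(terms))
  if (!length(terms)) stop("negation lexicon must be non-empty", call. = FALSE)
  structure(list(terms = unique(terms)), class = "negation_lexicon")
}

#' Load a negation lexicon from file
#'
#' @param path UTF-8 text file, one cue per line.
#' @return A `negation_lexicon`.
#' @export
load_negation_lexicon <- function(path) {
  negation_lexicon(load_stopwords(path))
}

#' Count records positive for selected finding terms
#'
#' A record is positive for a term when at least one keyword-in-context hit
#' of that term is not negated — so a record whose only mention is "no
#' evidence of pneumonia" is not counted, while one non-negated mention
#' anywhere suffices. Reports per-term positive-record counts and the set of
#' unique records positive for at least one term (a record matching several
#' terms is counted once in the unique total).
#'
#' The report is incremental: pass a previous report as `report` and only
#' the new terms are computed; earlier terms' results are reused.
#'
#' @param corpus A `necropsy_corpus`.
#' @param terms Character vector of (lowercase) finding terms.
#' @param lexicon A [negation_lexicon()].
#' @param window KWIC window size (word tokens each side; default 10).
#' @param report Optional `findings_report` from a previous call to extend.
#' @return A `findings_report`: list with `counts` (tibble `term`,
#'   `n_positive`), `positive_ids` (named list of accession-id vectors),
#'   `unique_records` (character vector), `window`, `lexicon`.
#' @export
positive_records <- function(corpus, terms, lexicon = negation_lexicon(),
                             window = 10, report = NULL) {
  stopifnot(inherits(corpus, "necropsy_corpus"), length(terms) >= 1)
  terms <- tolower(as.character(terms))
  positive_ids <- list()
  if (!is.null(report)) {
    stopifnot(inherits(report, "findings_report"))
    if (!identical(report$window, window) ||
        !setequal(report$lexicon$terms, lexicon$terms)) {
      stop("cannot extend a report computed with different window or lexicon",
           call. = FALSE)
    }
    positive_ids <- report$positive_ids
  }
  todo <- setdiff(terms, names(positive_ids))
  if (length(todo)) {
    streams <- tokenize_corpus(corpus)
    for (term in todo) {
      pos <- vapply(streams, function(s) {
        hits <- kwic(s, term, window = window, lexicon = lexicon)
        nrow(hits) > 0L && any(!hits$negated)
      }, logical(1))
      positive_ids[[term]] <- corpus$documents$accession_id[pos]
    }
  }
  all_terms <- union(names(positive_ids), terms)
  counts <- tibble::tibble(
    term = all_terms,
    n_positive = unname(vapply(positive_ids[all_terms], length, integer(1)))
  )
  structure(
    list(counts = counts,
         positive_ids = positive_ids,
         unique_records = unique(unlist(positive_ids, use.names = FALSE)) %||% character(),
         window = window, lexicon = lexicon),
    class = "findings_report"
  )
}

#' @export
print.findings_report <- function(x, ...) {
  cat("<findings_report> ", nrow(x$counts), " term(s), ",
      length(x$unique_records), " unique positive record(s)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Export records positive for at least one selected term
#'
#' Writes the unique positive records of a [positive_records()] report to
#' CSV via [write_records()], for manual review under a stricter case
#' definition.
#'
#' @param corpus The corpus the report was computed on.
#' @param report A `findings_report`.
#' @param path Output CSV path.
#' @return Invisibly, rows written (= number of unique positive records).
#' @export
export_positive <- function(corpus, report, path) {
  stopifnot(inherits(report, "findings_report"))
  write_records(corpus, report$unique_records, path)
}
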