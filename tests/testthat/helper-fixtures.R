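# Shared fixtures: in-code corpora, random document-term matrices, and the
# independent brute-force oracles the implementation is checked against.

# Build a corpus by writing a register-shaped CSV to a temp file and reading
# it back through the package's own loader.
make_corpus <- function(df, text_columns, id_column = "accession",
                        metadata_columns = NULL, date_format = "%Y-%m-%d") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  meta <- metadata_columns %||%
    setdiff(names(df), c(id_column, text_columns))
  if (length(meta) && is.null(names(meta))) names(meta) <- meta
  read_export(path, column_mapping(id_column, text_columns, meta, date_format))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny corpus whose documents are given directly as text strings.
text_corpus <- function(texts, ids = sprintf("D%02d", seq_along(texts))) {
  make_corpus(tibble::tibble(accession = ids, body = texts, group = "g"),
              text_columns = "body")
}

# Random DTM: every document has >= 1 token and every term occurs in >= 1
# document (columns failing that are resampled into a guaranteed row).
random_dtm <- function(n_docs, n_terms, lambda = 0.3) {
  counts <- matrix(stats::rpois(n_docs * n_terms, lambda),
                   nrow = n_docs,
                   dimnames = list(sprintf("doc%03d", seq_len(n_docs)),
                                   sprintf("t%03d", seq_len(n_terms))))
  for (j in which(colSums(counts) == 0)) counts[sample.int(n_docs, 1L), j] <- 1L
  for (i in which(rowSums(counts) == 0)) counts[i, sample.int(n_terms, 1L)] <- 1L
  as_dtm(counts)
}

random_binary_dtm <- function(n_docs, n_terms, p = 0.35) {
  counts <- matrix(as.integer(stats::runif(n_docs * n_terms) < p),
                   nrow = n_docs,
                   dimnames = list(sprintf("doc%03d", seq_len(n_docs)),
                                   sprintf("t%03d", seq_len(n_terms))))
  for (j in which(colSums(counts) == 0)) counts[sample.int(n_docs, 1L), j] <- 1L
  for (i in which(rowSums(counts) == 0)) counts[i, sample.int(n_terms, 1L)] <- 1L
  as_dtm(counts)
}

# Brute-force TF-IDF oracle: explicit loops over the dense count matrix,
# independent of the package's sparse-matrix implementation.
oracle_tfidf <- function(dtm, words_per_document) {
  counts <- as.matrix(dtm$counts)
  N <- nrow(counts)
  rows <- list()
  for (d in seq_len(N)) {
    len <- sum(counts[d, ])
    entries <- list()
    for (t in seq_len(ncol(counts))) {
      if (counts[d, t] > 0) {
        n_t <- sum(counts[, t] > 0)
        tf <- counts[d, t] / len
        idf <- log(N / n_t)
        entries[[length(entries) + 1L]] <- data.frame(
          accession_id = rownames(counts)[d], term = colnames(counts)[t],
          tf = tf, idf = idf, tfidf = tf * idf, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, entries)
    df <- df[order(-df$tfidf, df$term), , drop = FALSE]
    rows[[d]] <- utils::head(df, words_per_document)
  }
  out <- do.call(rbind, rows)
  out[order(-out$tfidf, out$accession_id, out$term), , drop = FALSE]
}

# Pearson correlation of the two binary document-indicator vectors — the
# definition phi must reproduce.
oracle_phi <- function(dtm, term_a, term_b) {
  a <- as.numeric(dtm$counts[, term_a] > 0)
  b <- as.numeric(dtm$counts[, term_b] > 0)
  suppressWarnings(stats::cor(a, b))
}

# Best-permutation mean cosine similarity between estimated topic-word rows
# and planted distributions (k <= 4: permutations enumerated).
best_permutation_cosine <- function(phi_est, phi_true) {
  k <- nrow(phi_true)
  common <- intersect(colnames(phi_est), colnames(phi_true))
  A <- phi_est[, common, drop = FALSE]
  B <- phi_true[, common, drop = FALSE]
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  perms <- perms_of(k)
  best <- -Inf
  for (p in perms) {
    m <- mean(vapply(seq_len(k), function(i) cosine(A[p[i], ], B[i, ]), 0))
    best <- max(best, m)
  }
  best
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in perms_of(k - 1)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}
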