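test_that("top_tfidf_table matches the hand-computed two-document example", {
  corpus <- text_corpus(c("plasmodium liver liver", "liver firm"),
                        ids = c("doc1", "doc2"))
  tab <- top_tfidf_table(build_dtm(corpus, stoplist = character()))
  plas <- tab[tab$term == "plasmodium", ]
  expect_equal(plas$tfidf, (1 / 3) * log(2), tolerance = 1e-12)
  # a term in every document has idf 0 and never outranks a specific term
  liver <- tab[tab$term == "liver", ]
  expect_equal(liver$tfidf, c(0, 0))
  expect_true(all(tab$tfidf[1:2] > 0))   # plasmodium and firm rank first
})

test_that("top_tfidf_table agrees with the explicit-loop oracle", {
  set.seed(13)
  for (i in 1:5) {
    dtm <- random_dtm(sample(5:15, 1), sample(20:60, 1), lambda = 0.4)
    got <- top_tfidf_table(dtm, words_per_document = 10)
    want <- oracle_tfidf(dtm, words_per_document = 10)
    expect_equal(got$accession_id, want$accession_id)
    expect_equal(got$term, want$term)
    expect_equal(got$tfidf, want$tfidf, tolerance = 1e-12)
  }
})

test_that("shrinking words_per_document preserves the ranking prefix", {
  set.seed(14)
  dtm <- random_dtm(8, 80, lambda = 0.5)
  t40 <- top_tfidf_table(dtm, 40)
  t10 <- top_tfidf_table(dtm, 10)
  for (d in unique(t10$accession_id)) {
    expect_lte(sum(t10$accession_id == d), 10L)
    expect_equal(t10$term[t10$accession_id == d],
                 t40$term[t40$accession_id == d][seq_len(sum(t10$accession_id == d))])
  }
  expect_equal(formals(top_tfidf_table)$words_per_document, 40)
})

test_that("search_table does case-insensitive substring matching anywhere", {
  tab <- tibble::tibble(term = c("plasmodium", "plasmodial", "plasmodium-like",
                                 "anaerobic", "animal", "organism", "avian",
                                 "Liver"))
  expect_setequal(search_table(tab, "plas")$term,
                  c("plasmodium", "plasmodial", "plasmodium-like"))
  expect_setequal(search_table(tab, "an")$term,
                  c("anaerobic", "animal", "organism", "avian"))
  expect_equal(search_table(tab, "liver")$term, "Liver")
  expect_equal(nrow(search_table(tab, "zzz")), 0L)
  expect_true("plasmodium" %in% search_table(tab, "plasmodium")$term)
})

test_that("kwic applies the punctuation-bounded phrase rule", {
  s <- tokenize("No evidence of pneumonia.", "A1")
  hit <- kwic(s, "pneumonia")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$phrase_text, "No evidence of pneumonia")
  expect_true(hit$negated)

  s <- tokenize("Severe pneumonia. No nephritis.", "A2")
  hit <- kwic(s, "pneumonia")
  expect_equal(hit$phrase_text, "Severe pneumonia")
  expect_false(hit$negated)
  # the nephritis hit, by contrast, is negated
  expect_true(kwic(s, "nephritis")$negated)

  expect_equal(nrow(kwic(s, "hepatitis")), 0L)
})

test_that("kwic matching is exact-token, not substring", {
  s <- tokenize("plasmodium-like organisms seen", "A1")
  expect_equal(nrow(kwic(s, "plasmodium")), 0L)
  expect_equal(nrow(kwic(s, "plasmodium-like")), 1L)
})

test_that("kwic window limits the phrase and Inf degrades to the whole text", {
  # cue 12 words before the hit: outside a 10-word window
  far <- paste(c("no", rep("w", 11), "pneumonia"), collapse = " ")
  s <- tokenize(far, "A1")
  hit <- kwic(s, "pneumonia", window = 10)
  expect_false(hit$negated)
  expect_equal(length(strsplit(hit$window_text, " ")[[1]]), 11L)
  # with an unbounded window and no punctuation, phrase = whole text
  hit_inf <- kwic(s, "pneumonia", window = Inf)
  expect_true(hit_inf$negated)
  expect_equal(hit_inf$phrase_text, far)
})

test_that("a newline between findings sections bounds the phrase", {
  corpus <- make_corpus(
    tibble::tibble(accession = "A1", gross = "no fractures identified",
                   histo = "pneumonia with bacterial colonies"),
    text_columns = c("gross", "histo"))
  s <- tokenize(corpus$documents$text, "A1")
  expect_false(kwic(s, "pneumonia")$negated)
})

test_that("positive_records counts non-negated mentions once per record", {
  corpus <- make_corpus(tibble::tibble(
    accession = c("A1", "A2", "A3", "A4"),
    body = c("no evidence of pneumonia.",
             "no nephritis. later, severe pneumonia.",
             "pneumonia and nephritis present.",
             "unremarkable lungs.")), text_columns = "body")
  rep <- positive_records(corpus, c("pneumonia", "nephritis"))
  counts <- stats::setNames(rep$counts$n_positive, rep$counts$term)
  expect_equal(counts[["pneumonia"]], 2L)   # A2, A3; A1 is negated-only
  expect_equal(counts[["nephritis"]], 1L)   # A3 only
  expect_setequal(rep$unique_records, c("A2", "A3"))
  expect_lte(length(rep$unique_records), sum(rep$counts$n_positive))
  # absent term is a zero count, not an error
  rep0 <- positive_records(corpus, "hepatitis")
  expect_equal(rep0$counts$n_positive, 0L)
  expect_length(rep0$unique_records, 0L)
})

test_that("reports extend incrementally without recomputing prior terms", {
  corpus <- make_corpus(tibble::tibble(
    accession = c("A1", "A2"),
    body = c("severe pneumonia.", "nephritis present.")), text_columns = "body")
  r1 <- positive_records(corpus, "pneumonia")
  r2 <- positive_records(corpus, c("pneumonia", "nephritis"), report = r1)
  expect_setequal(r2$counts$term, c("pneumonia", "nephritis"))
  expect_setequal(r2$unique_records, c("A1", "A2"))
  expect_identical(r2$positive_ids$pneumonia, r1$positive_ids$pneumonia)
  # adding terms never removes unique records
  expect_true(all(r1$unique_records %in% r2$unique_records))
  expect_error(positive_records(corpus, "x", window = 5, report = r1),
               "different window")
})

test_that("export_positive writes exactly the unique positive records and
           re-analysis of the export reproduces the counts", {
  gen <- generate_necropsy_data(generator_config(n_records = 40, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen$data, path)
  corpus <- read_export(path, default_mapping())
  terms <- c("pneumonia", "nephritis")
  rep <- positive_records(corpus, terms)
  out <- withr::local_tempfile(fileext = ".csv")
  n <- export_positive(corpus, rep, out)
  expect_equal(n, length(rep$unique_records))
  back <- read_export(out, roundtrip_mapping(corpus))
  rep2 <- positive_records(back, terms)
  expect_equal(rep2$counts, rep$counts)
  expect_setequal(rep2$unique_records, rep$unique_records)
})

test_that("no positive records exports an empty file", {
  corpus <- text_corpus("no evidence of pneumonia.")
  rep <- positive_records(corpus, "pneumonia")
  out <- withr::local_tempfile(fileext = ".csv")
  expect_equal(export_positive(corpus, rep, out), 0L)
})
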