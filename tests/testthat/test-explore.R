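test_that("phi is 1 for terms present in exactly the same documents", {
  counts <- cbind(x = c(1, 1, 0, 0, 0), y = c(2, 3, 0, 0, 0),
                  z = c(0, 0, 1, 1, 1))
  rownames(counts) <- sprintf("d%d", 1:5)
  edges <- word_correlations(as_dtm(counts), min_count = 1, min_corr = 0.9)
  xy <- edges[edges$term_a == "x" & edges$term_b == "y", ]
  expect_equal(xy$phi, 1)
})

test_that("phi reproduces the hand-computed 2x2 contingency formula", {
  # x in docs 1-3, y in docs {1,2,4}: n11=2, n10=1, n01=1, n00=6, N=10
  counts <- matrix(0, 10, 2, dimnames = list(sprintf("d%02d", 1:10), c("x", "y")))
  counts[1:3, "x"] <- 1
  counts[c(1, 2, 4), "y"] <- 1
  edges <- word_correlations(as_dtm(counts), min_count = 1, min_corr = 0)
  expect_equal(edges$phi, 11 / 21, tolerance = 1e-12)
  expect_equal(edges[, c("n11", "n10", "n01", "n00")],
               tibble::tibble(n11 = 2L, n10 = 1L, n01 = 1L, n00 = 6L))
  # and equals the Pearson correlation of the indicator vectors
  expect_equal(edges$phi, oracle_phi(as_dtm(counts), "x", "y"), tolerance = 1e-12)
})

test_that("edge sets shrink monotonically in min_corr and min_count", {
  set.seed(7)
  dtm <- random_binary_dtm(30, 25)
  key <- function(e) paste(e$term_a, e$term_b)
  lo <- word_correlations(dtm, min_count = 1, min_corr = 0.2)
  hi <- word_correlations(dtm, min_count = 1, min_corr = 0.5)
  expect_true(all(key(hi) %in% key(lo)))
  strict <- word_correlations(dtm, min_count = 5, min_corr = 0.2)
  expect_true(all(key(strict) %in% key(lo)))
})

test_that("undefined phi (term in every document) is skipped, and an empty
           eligible vocabulary errors", {
  counts <- cbind(everywhere = c(1, 1, 1), rare = c(1, 0, 0))
  rownames(counts) <- c("a", "b", "c")
  edges <- word_correlations(as_dtm(counts), min_count = 1, min_corr = 0)
  expect_equal(nrow(edges), 0L)
  expect_error(word_correlations(as_dtm(counts), min_count = 10, min_corr = 0),
               "no eligible terms")
})

test_that("fit_lda returns normalised distributions and is seed-deterministic", {
  set.seed(21)
  dtm <- random_dtm(12, 30, lambda = 0.6)
  m1 <- fit_lda(dtm, k = 3, iterations = 30, seed = 99)
  expect_equal(unname(rowSums(m1$phi)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(m1$theta)), rep(1, nrow(m1$theta)), tolerance = 1e-9)
  expect_true(all(m1$phi >= 0), all(m1$theta >= 0))
  m2 <- fit_lda(dtm, k = 3, iterations = 30, seed = 99)
  expect_identical(m1$z, m2$z)
  expect_equal(m1$phi, m2$phi)
  m3 <- fit_lda(dtm, k = 3, iterations = 30, seed = 100)
  expect_false(identical(m1$z, m3$z))
})

test_that("fit_lda rejects k < 2 or k > V and excludes empty documents", {
  dtm <- as_dtm(matrix(c(2, 1, 0, 0), 2, 2,
                       dimnames = list(c("d1", "d2"), c("a", "b"))))
  expect_error(fit_lda(dtm, k = 1), "k >= 2")
  expect_error(fit_lda(dtm, k = 5, iterations = 5), "vocabulary size")
  empty_doc <- as_dtm(matrix(c(2, 0, 1, 1, 0, 2), 3, 2,
                             dimnames = list(c("d1", "d2", "d3"), c("a", "b"))))
  expect_warning(m <- fit_lda(empty_doc, k = 2, iterations = 5), "zero tokens")
  expect_equal(m$excluded_docs, "d2")
  expect_equal(rownames(m$theta), c("d1", "d3"))
})

test_that("planted disjoint-vocabulary topics are recovered at k = 2", {
  cfg <- generator_config(
    n_records = 100, seed = 5,
    themes = list(
      renal = list(vocabulary = sprintf("renalword%02d", 1:10), prob = 0.5),
      hepatic = list(vocabulary = sprintf("liverword%02d", 1:10), prob = 0.5)),
    theme_mode = "exclusive", theme_tokens = 40,
    findings = data.frame(term = character(), positive_rate = numeric(),
                          negated_rate = numeric()),
    filler_max = 0)
  gen <- generate_necropsy_data(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen$data, path)
  corpus <- read_export(path, default_mapping())
  dtm <- build_dtm(corpus)
  model <- fit_lda(dtm, k = 2, iterations = 200, seed = 1)
  truth <- theme_word_distributions(cfg)
  expect_gte(best_permutation_cosine(model$phi, truth), 0.9)
})

test_that("topic_word_cloud ranks per topic and assigns each word once", {
  set.seed(3)
  dtm <- random_dtm(15, 20, lambda = 0.8)
  model <- fit_lda(dtm, k = 3, iterations = 30, seed = 2)
  cloud <- topic_word_cloud(model, words_per_topic = 5)
  expect_equal(nrow(cloud), 15L)
  for (kk in 1:3) {
    w <- cloud$weight[cloud$topic == kk]
    expect_true(all(diff(w) <= 0))
  }
  # a word's assignment is unique regardless of how many topics list it
  assign_by_term <- tapply(cloud$assigned_topic, cloud$term,
                           function(x) length(unique(x)))
  expect_true(all(assign_by_term == 1))
  # clipping: asking for more words than the vocabulary lists each term once
  big <- topic_word_cloud(model, words_per_topic = 10000)
  expect_equal(nrow(big), 3L * 20L)
})

test_that("several topic counts succeed on the same corpus", {
  gen <- generate_necropsy_data(generator_config(n_records = 60, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen$data, path)
  dtm <- build_dtm(read_export(path, default_mapping()))
  for (k in c(3, 6)) {
    m <- fit_lda(dtm, k = k, iterations = 50, seed = 4)
    expect_equal(nrow(m$phi), k)
    expect_equal(unname(rowSums(m$phi)), rep(1, k), tolerance = 1e-9)
  }
})
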