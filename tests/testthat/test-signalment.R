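sig_corpus <- function() {
  make_corpus(tibble::tibble(
    accession = sprintf("A%d", 1:8),
    body = letters[1:8],
    sex = c("male", "male", "female", NA, "female", "female", "male", "female"),
    age_class = c("adult", "adult", "adult", "juvenile", "juvenile",
                  "adult", "subadult", NA),
    submission_date = c("2019-07-14", "2019-08-02", "2020-01-05", "garbage",
                        "2020-01-20", NA, "2021-12-31", "2019-07-30")
  ), text_columns = "body")
}

test_that("frequency_table tallies raw levels, count-descending", {
  corpus <- make_corpus(tibble::tibble(
    accession = c("A1", "A2", "A3", "A4"), body = "x",
    sex = c("male", "male", "female", NA)), text_columns = "body")
  ft <- frequency_table(corpus, "sex")
  expect_equal(ft$level, c("male", "Not recorded", "female"))
  expect_equal(ft$count, c(2L, 1L, 1L))
  expect_equal(sum(ft$count), n_docs(corpus))
  expect_error(frequency_table(corpus, "plumage"), "available")
})

test_that("typographic variants are never merged", {
  corpus <- make_corpus(tibble::tibble(
    accession = c("A1", "A2", "A3"), body = "x",
    species = c("Fiordland Crested Penguin", "Fiordland crested penguin",
                "Fiordland Crested Penguin")), text_columns = "body")
  ft <- frequency_table(corpus, "species")
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$count[ft$level == "Fiordland crested penguin"], 1L)
})

test_that("extract_period formats months with year and flags garbage", {
  expect_equal(extract_period("2019-07-14", "month"), "2019-07")
  expect_equal(extract_period("2019-07-14", "year"), "2019")
  expect_equal(extract_period(NA_character_, "month"), "Not recorded")
  expect_warning(p <- extract_period("garbage", "month"), "unparseable")
  expect_equal(p, "Not recorded")
  # month labels never alias across years
  expect_equal(extract_period(c("2019-03-01", "2020-03-01"), "month"),
               c("2019-03", "2020-03"))
})

test_that("period_table is chronological with 'Not recorded' last", {
  corpus <- sig_corpus()
  pt <- suppressWarnings(period_table(corpus, "year"))
  expect_equal(pt$period, c("2019", "2020", "2021", "Not recorded"))
  expect_equal(sum(pt$count), n_docs(corpus))
})

test_that("cross_tab cells tally the 2-way contingency and normalise within bars", {
  corpus <- make_corpus(tibble::tibble(
    accession = sprintf("A%d", 1:4), body = "x",
    sex = c("male", "female", "male", "female"),
    age_class = c("adult", "adult", "juvenile", "juvenile")), text_columns = "body")
  ct <- cross_tab(corpus, "age_class", "sex")
  expect_true(all(abs(ct$proportion - 0.5) < 1e-12))
  expect_equal(sum(ct$count), n_docs(corpus))
  expect_error(cross_tab(corpus, "sex", "sex"), "differ")
})

test_that("cross_tab marginals reproduce the frequency tables", {
  corpus <- sig_corpus()
  ct <- cross_tab(corpus, "age_class", "sex")
  marg <- tapply(ct$count, ct$freq_level, sum)
  ft <- frequency_table(corpus, "age_class")
  expect_equal(as.integer(marg[ft$level]), ft$count)
  per_bar <- tapply(ct$proportion, ct$freq_level, sum)
  expect_true(all(abs(per_bar - 1) < 1e-9))
})

test_that("apply_filter is AND across roles, OR within, and idempotent", {
  corpus <- sig_corpus()
  spec <- filter_spec(sex = "female", age_class = c("adult", "juvenile"))
  filtered <- apply_filter(corpus, spec)
  manual <- corpus$metadata$sex %in% "female" &
    corpus$metadata$age_class %in% c("adult", "juvenile")
  expect_equal(filtered$documents$accession_id,
               corpus$documents$accession_id[manual])
  # idempotence
  twice <- apply_filter(filtered, spec)
  expect_equal(twice$documents, filtered$documents)
  expect_equal(twice$metadata, filtered$metadata)
  # provenance records every application
  expect_length(twice$provenance$filters, 2L)
  expect_match(filtered$provenance$filters[1], "sex in \\{female\\}")
  expect_error(apply_filter(corpus, filter_spec(plumage = "drab")), "unknown role")
})

test_that("all-level filter is the identity and empty results stay usable", {
  corpus <- sig_corpus()
  all_levels <- unique(corpus$metadata$sex)
  same <- apply_filter(corpus, filter_spec(sex = all_levels))
  expect_equal(same$documents, corpus$documents)
  none <- apply_filter(corpus, filter_spec(sex = "hermaphrodite"))
  expect_equal(n_docs(none), 0L)
  expect_error(build_dtm(none), "empty corpus")
})

test_that("filters commute with frequency tallies over random specs", {
  corpus <- sig_corpus()
  set.seed(4)
  for (i in 1:20) {
    role <- sample(c("sex", "age_class"), 1)
    levels <- sample(unique(corpus$metadata[[role]]),
                     sample.int(2, 1))
    filtered <- apply_filter(corpus, do.call(filter_spec,
                                             stats::setNames(list(levels), role)))
    keep <- corpus$metadata[[role]] %in% levels
    expect_equal(n_docs(filtered), sum(keep))
    if (n_docs(filtered) > 0) {
      ft <- frequency_table(filtered, "sex")
      expect_equal(sum(ft$count), sum(keep))
      brute <- table(corpus$metadata$sex[keep])
      expect_equal(ft$count[order(ft$level)], as.integer(brute[sort(names(brute))]))
    }
  }
})
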