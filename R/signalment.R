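# Describe stage: signalment summaries, submission-period grouping,
# proportion-by-frequency cross-tabs, and persistent corpus filtering.
#
# Levels are always reported verbatim: typographic variants of the same
# species, or an explicit "Not recorded" level, are data in their own right
# (they reveal how the register is being used) and are never merged
# automatically. Consolidation is left to the user via filters.

#' Frequency table of a signalment variable
#'
#' Tallies the raw levels of one metadata role. Levels are reported exactly
#' as recorded (no merging of typographic variants) and ordered by count
#' descending, ties broken lexicographically.
#'
#' @param corpus A `necropsy_corpus`.
#' @param variable Role name (see [metadata_roles()]).
#' @return A tibble with columns `level`, `count`; attribute `variable`.
#' @export
frequency_table <- function(corpus, variable) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  check_role(corpus, variable)
  v <- corpus$metadata[[variable]]
  tab <- table(v)
  out <- tibble::tibble(level = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$level), , drop = FALSE]
  attr(out, "variable") <- variable
  out
}

check_role <- function(corpus, variable) {
  roles <- metadata_roles(corpus)
  if (!variable %in% roles) {
    stop("unknown metadata variable '", variable, "'; available: ",
         paste(roles, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract submission periods from date strings
#'
#' Groups submission dates by month or year. Month labels carry the year
#' (`"YYYY-MM"`) so multi-year corpora do not alias the same calendar month
#' across years. Missing or unparseable values are binned as
#' `"Not recorded"`; unparseable non-missing values additionally raise a
#' warning naming the offending values.
#'
#' @param date_value Character vector of raw date strings.
#' @param granularity `"month"` or `"year"`.
#' @param format Date pattern in [base::strptime()] notation.
#' @return Character vector of period labels.
#' @examples
#' extract_period("2019-07-14", "month")  # "2019-07"
#' extract_period("2019-07-14", "year")   # "2019"
#' @export
extract_period <- function(date_value, granularity = c("month", "year"),
                           format = "%Y-%m-%d") {
  granularity <- match.arg(granularity)
  out <- rep(NOT_RECORDED, length(date_value))
  missing <- is.na(date_value) | !nzchar(trimws(date_value)) | date_value == NOT_RECORDED
  parsed <- as.Date(date_value[!missing], format = format)
  bad <- is.na(parsed)
  if (any(bad)) {
    warning("unparseable submission date(s) binned as '", NOT_RECORDED, "': ",
            paste(utils::head(unique(date_value[!missing][bad]), 5L), collapse = ", "),
            call. = FALSE)
  }
  fmt <- if (granularity == "month") "%Y-%m" else "%Y"
  lab <- rep(NOT_RECORDED, sum(!missing))
  lab[!bad] <- format(parsed[!bad], fmt)
  out[!missing] <- lab
  out
}

#' Submissions per period
#'
#' @param corpus A `necropsy_corpus`.
#' @param granularity `"month"` or `"year"`.
#' @param date_role Role holding the submission date (default
#'   `"submission_date"`).
#' @param format Date pattern; defaults to the mapping the corpus was read
#'   with.
#' @return Tibble `period`, `count`, ordered chronologically with
#'   `"Not recorded"` last.
#' @export
period_table <- function(corpus, granularity = c("month", "year"),
                         date_role = "submission_date", format = NULL) {
  granularity <- match.arg(granularity)
  check_role(corpus, date_role)
  format <- format %||% corpus$provenance$mapping$date_format %||% "%Y-%m-%d"
  periods <- extract_period(corpus$metadata[[date_role]], granularity, format)
  tab <- table(periods)
  out <- tibble::tibble(period = names(tab), count = as.integer(tab))
  nr <- out$period == NOT_RECORDED
  rbind(out[!nr, ][order(out$period[!nr]), ], out[nr, ])
}

#' Two-factor proportion-by-frequency cross-tabulation
#'
#' The display behind a stacked proportional bar chart: `freq_variable`
#' supplies the bars (heights = counts), `prop_variable` the within-bar
#' proportions. Useful for spotting, e.g., whether missing sex and missing
#' age classification fall on the same records.
#'
#' @param corpus A `necropsy_corpus`.
#' @param freq_variable Role whose levels form the bars.
#' @param prop_variable Role shown as proportions within each bar.
#' @return Tibble `freq_level`, `prop_level`, `count`, `proportion`
#'   (proportions normalised within each `freq_level`).
#' @export
cross_tab <- function(corpus, freq_variable, prop_variable) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  check_role(corpus, freq_variable)
  check_role(corpus, prop_variable)
  if (identical(freq_variable, prop_variable)) {
    stop("freq_variable and prop_variable must differ", call. = FALSE)
  }
  f <- corpus$metadata[[freq_variable]]
  p <- corpus$metadata[[prop_variable]]
  tab <- table(f, p)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("freq_level", "prop_level", "count")
  df <- df[df$count > 0L, , drop = FALSE]
  totals <- tapply(df$count, df$freq_level, sum)
  df$proportion <- df$count / as.numeric(totals[df$freq_level])
  out <- tibble::as_tibble(df[order(df$freq_level, df$prop_level), , drop = FALSE])
  out$count <- as.integer(out$count)
  attr(out, "freq_variable") <- freq_variable
  attr(out, "prop_variable") <- prop_variable
  out
}

#' Filter specification over metadata roles
#'
#' Clauses combine as AND across roles and OR within a role: a document is
#' retained when, for every clause, its value for that role is one of the
#' retained levels.
#'
#' @param ... Named arguments: each name is a role, each value a character
#'   vector of levels to retain.
#' @return A `filter_spec`.
#' @examples
#' filter_spec(sex = "female", age_class = c("adult", "subadult"))
#' @export
filter_spec <- function(...) {
  clauses <- list(...)
  if (length(clauses) && is.null(names(clauses)) || any(!nzchar(names(clauses)))) {
    if (length(clauses)) stop("all filter clauses must be named by role", call. = FALSE)
  }
  clauses <- lapply(clauses, as.character)
  if (any(lengths(clauses) == 0L)) {
    stop("each clause must retain at least one level", call. = FALSE)
  }
  structure(list(clauses = clauses), class = "filter_spec")
}

#' Apply a persistent filter to a corpus
#'
#' Returns the sub-corpus of documents satisfying every clause of `spec`.
#' Document order is preserved, and the filter is recorded in the corpus
#' provenance so every downstream stage (correlations, topics, TF-IDF,
#' finding counts) consumes the same filtered population.
#'
#' @param corpus A `necropsy_corpus`.
#' @param spec A [filter_spec()].
#' @return The filtered `necropsy_corpus`.
#' @export
apply_filter <- function(corpus, spec) {
  stopifnot(inherits(corpus, "necropsy_corpus"), inherits(spec, "filter_spec"))
  roles <- metadata_roles(corpus)
  for (role in names(spec$clauses)) {
    if (!role %in% roles) {
      stop("filter clause on unknown role '", role, "'", call. = FALSE)
    }
  }
  keep <- rep(TRUE, n_docs(corpus))
  for (role in names(spec$clauses)) {
    keep <- keep & corpus$metadata[[role]] %in% spec$clauses[[role]]
  }
  desc <- paste(vapply(names(spec$clauses), function(role) {
    paste0(role, " in {", paste(spec$clauses[[role]], collapse = ", "), "}")
  }, character(1)), collapse = " & ")
  new_corpus(
    documents = corpus$documents[keep, , drop = FALSE],
    metadata = corpus$metadata[keep, , drop = FALSE],
    provenance = utils::modifyList(
      corpus$provenance,
      list(filters = c(corpus$provenance$filters, desc))
    )
  )
}
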