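# Corpus construction from semi-structured CSV exports.

NOT_RECORDED <- "Not recorded"

#' Column mapping for a necropsy register export
#'
#' Describes how the columns of a CSV export map onto the roles the pipeline
#' needs: the unique accession identifier, the ordered free-text findings
#' sections that are merged into the document body, and the signalment /
#' metadata columns. Register exports differ between installations, so the
#' mapping is always explicit; [default_mapping()] matches the schema of the
#' bundled synthetic generator.
#'
#' @param id_column Column name holding the unique accession number.
#' @param text_columns Ordered character vector of free-text findings columns;
#'   their contents are joined in this order (separated by a newline) to form
#'   each document's text.
#' @param metadata_columns Named character vector mapping role names
#'   (`species`, `sex`, `age_class`, `submission_date`, ...) to column names.
#' @param date_format Date pattern (in [base::strptime()] notation) used to
#'   parse values of the `submission_date` role.
#' @return A `column_mapping` object.
#' @examples
#' column_mapping(
#'   id_column = "accession",
#'   text_columns = c("gross_findings", "histopathology"),
#'   metadata_columns = c(species = "species", sex = "sex")
#' )
#' @export
column_mapping <- function(id_column, text_columns, metadata_columns = character(),
                           date_format = "%Y-%m-%d") {
  stopifnot(is.character(id_column), length(id_column) == 1L, nzchar(id_column))
  if (length(text_columns) == 0L) {
    stop("`text_columns` must name at least one free-text column", call. = FALSE)
  }
  metadata_columns <- unlist(metadata_columns)
  if (length(metadata_columns) && is.null(names(metadata_columns))) {
    # role defaults to the column's own name
    names(metadata_columns) <- metadata_columns
  }
  all_cols <- c(id_column, text_columns, unname(metadata_columns))
  if (anyDuplicated(all_cols)) {
    stop("id_column, text_columns and metadata_columns must be disjoint; duplicated: ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(id_column = id_column,
         text_columns = as.character(text_columns),
         metadata_columns = metadata_columns,
         date_format = date_format),
    class = "column_mapping"
  )
}

#' @export
print.column_mapping <- function(x, ...) {
  cat("<column_mapping>\n")
  cat("  id:      ", x$id_column, "\n")
  cat("  text:    ", paste(x$text_columns, collapse = ", "), "\n")
  if (length(x$metadata_columns)) {
    cat("  metadata:", paste(names(x$metadata_columns), "=", x$metadata_columns,
                             collapse = ", "), "\n")
  }
  cat("  dates:   ", x$date_format, "\n")
  invisible(x)
}

#' Read a column mapping from a YAML file
#'
#' The file holds the fields of [column_mapping()] as top-level keys;
#' `metadata_columns` is a mapping of role name to column name.
#'
#' @param path Path to a YAML mapping file.
#' @return A `column_mapping` object.
#' @export
read_mapping <- function(path) {
  cfg <- yaml::read_yaml(path)
  column_mapping(
    id_column = cfg$id_column,
    text_columns = unlist(cfg$text_columns),
    metadata_columns = unlist(cfg$metadata_columns %||% character()),
    date_format = cfg$date_format %||% "%Y-%m-%d"
  )
}

#' Default mapping matching the synthetic generator schema
#'
#' @return A `column_mapping` for CSVs produced by [generate_necropsy_data()].
#' @export
default_mapping <- function() {
  column_mapping(
    id_column = "accession",
    text_columns = c("gross_findings", "histopathology", "ancillary_tests", "diagnosis"),
    metadata_columns = c(species = "species", sex = "sex",
                         age_class = "age_class", submission_date = "submission_date"),
    date_format = "%Y-%m-%d"
  )
}

new_corpus <- function(documents, metadata, provenance) {
  structure(list(documents = documents, metadata = metadata, provenance = provenance),
            class = "necropsy_corpus")
}

#' Number of documents in a corpus
#' @param corpus A `necropsy_corpus`.
#' @return Integer count of documents.
#' @export
n_docs <- function(corpus) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  nrow(corpus$documents)
}

#' Metadata roles attached to a corpus
#' @param corpus A `necropsy_corpus`.
#' @return Character vector of role names.
#' @export
metadata_roles <- function(corpus) {
  setdiff(names(corpus$metadata), "accession_id")
}

#' @export
print.necropsy_corpus <- function(x, ...) {
  cat("<necropsy_corpus> ", n_docs(x), " documents\n", sep = "")
  cat("  metadata roles: ", paste(metadata_roles(x), collapse = ", "), "\n", sep = "")
  cat("  source: ", x$provenance$source %||% "<in memory>", "\n", sep = "")
  if (length(x$provenance$filters)) {
    cat("  filters: ", paste(x$provenance$filters, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a necropsy register CSV export into a corpus
#'
#' One document is created per data row: the mapped free-text columns are
#' merged (in mapping order, separated by a single newline so that phrase
#' detection never bridges sections) into the document body, and every other
#' column is attached as document-level metadata. Columns not named in the
#' mapping are retained as metadata under their own column name, so nothing
#' in the export is silently dropped. Empty metadata cells become the
#' explicit level `"Not recorded"`: missingness is treated as data, not
#' discarded.
#'
#' @param path Path to a header-bearing CSV file (RFC 4180, UTF-8).
#' @param mapping A [column_mapping()] describing the export's schema.
#' @return A `necropsy_corpus`.
#' @details Rows with an empty accession id are dropped with a warning.
#'   Duplicate accession ids are an error: the register assigns a unique
#'   accession number on entry, so duplicates indicate a corrupt export.
#' @export
read_export <- function(path, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  header <- names(raw)
  mapped <- c(mapping$id_column, mapping$text_columns, unname(mapping$metadata_columns))
  missing_cols <- setdiff(mapped, header)
  if (length(missing_cols)) {
    stop("mapped column(s) not present in file header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  ids <- raw[[mapping$id_column]]
  empty_id <- is.na(ids) | !nzchar(trimws(ids))
  if (any(empty_id)) {
    warning(sum(empty_id), " row(s) with empty accession id rejected", call. = FALSE)
    raw <- raw[!empty_id, , drop = FALSE]
    ids <- ids[!empty_id]
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate accession id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }

  text_cols <- lapply(mapping$text_columns, function(cl) {
    v <- raw[[cl]]
    ifelse(is.na(v), "", v)
  })
  text <- do.call(paste, c(text_cols, sep = "\n"))

  # metadata: mapped roles first, then every remaining non-id, non-text column
  meta_cols <- mapping$metadata_columns
  extra <- setdiff(header, mapped)
  meta_cols <- c(meta_cols, stats::setNames(extra, extra))
  metadata <- tibble::tibble(accession_id = ids)
  for (role in names(meta_cols)) {
    v <- raw[[meta_cols[[role]]]]
    v <- ifelse(is.na(v) | !nzchar(trimws(v)), NOT_RECORDED, v)
    metadata[[role]] <- v
  }

  new_corpus(
    documents = tibble::tibble(accession_id = ids, text = text),
    metadata = metadata,
    provenance = list(source = path, mapping = mapping, filters = character())
  )
}

#' Write selected corpus records back to CSV
#'
#' Reconstitutes a CSV export for a subset of accessions: the accession id,
#' the merged document body (one `document_text` column) and every metadata
#' column. `"Not recorded"` levels are written as empty cells, matching how
#' the register exports missing values. The output re-reads cleanly with a
#' mapping whose single text column is `document_text`.
#'
#' @param corpus A `necropsy_corpus`.
#' @param ids Character vector of accession ids to write (order of the corpus
#'   is preserved; `ids` may be in any order).
#' @param path Output CSV path.
#' @return Invisibly, the number of rows written.
#' @export
write_records <- function(corpus, ids, path) {
  stopifnot(inherits(corpus, "necropsy_corpus"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, corpus$documents$accession_id)
  if (length(unknown)) {
    stop("unknown accession id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- corpus$documents$accession_id %in% ids
  out <- tibble::tibble(
    accession = corpus$documents$accession_id[keep],
    document_text = corpus$documents$text[keep]
  )
  meta <- corpus$metadata[keep, , drop = FALSE]
  for (role in metadata_roles(corpus)) {
    v <- meta[[role]]
    out[[role]] <- ifelse(v == NOT_RECORDED, "", v)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(nrow(out))
}

#' Mapping for files produced by [write_records()]
#'
#' @param corpus The corpus the file was written from (supplies role names).
#' @return A `column_mapping` whose single text column is `document_text`.
#' @export
roundtrip_mapping <- function(corpus) {
  roles <- metadata_roles(corpus)
  column_mapping(
    id_column = "accession",
    text_columns = "document_text",
    metadata_columns = stats::setNames(roles, roles),
    date_format = corpus$provenance$mapping$date_format %||% "%Y-%m-%d"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
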