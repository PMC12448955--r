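# Seeded generator of register-shaped necropsy CSVs with known ground truth.
#
# Emulates the awkward shape of a real register export — typographic
# variants of species names, explicit missing signalment, optional free-text
# sections, and findings mentioned both affirmatively and under negation —
# while keeping a machine-readable record of what was planted, so every
# downstream stage can be validated exactly.

#' Configuration for the synthetic necropsy-record generator
#'
#' Defaults mirror a plausible New Zealand wildlife caseload: native bird
#' species (with a planted typographic variant of the Fiordland Crested
#' Penguin, the classic register redundancy), three content themes — an
#' avian-malaria theme, a freeze--thaw artifact theme, and a poor
#' body-condition theme — and a handful of clinicopathologic finding terms
#' that appear either affirmed or under grammar-conforming negation
#' templates.
#'
#' @param n_records Number of records to generate.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   config.
#' @param species Named numeric vector: species name -> sampling weight.
#' @param species_variants Named character vector: species name -> its
#'   typographic variant, planted at `typo_rate`.
#' @param typo_rate Probability a species entry uses its variant spelling.
#' @param sex_levels,sex_weights,sex_missing_rate Sex classification levels,
#'   sampling weights, and the rate at which the field is left blank.
#' @param age_levels,age_weights,age_missing_rate Likewise for age
#'   classification.
#' @param date_start,date_end Submission-date range (ISO dates).
#' @param date_missing_rate Rate of blank submission dates.
#' @param themes Named list; each element a list with `vocabulary`
#'   (character, disjoint across themes) and `prob` (inclusion probability,
#'   or selection weight in exclusive mode).
#' @param theme_mode `"independent"` (each theme included independently with
#'   its `prob` — the realistic default) or `"exclusive"` (each record draws
#'   exactly one theme — used for planted-topic recovery).
#' @param theme_tokens Theme words sampled (with replacement) per included
#'   theme.
#' @param findings Data frame with columns `term`, `positive_rate`
#'   (probability of an affirmed mention) and `negated_rate` (probability of
#'   a negated mention); the two are independent, so a record can carry
#'   both (it is then positive).
#' @param affirm_templates,negation_templates Sentence templates with `{X}`
#'   standing for the finding term. Negation templates keep the cue and the
#'   term inside one punctuation-bounded phrase within the detection window.
#' @param filler_max Maximum neutral filler sentences per record (0 disables
#'   filler).
#' @param ancillary_empty_rate Rate at which the ancillary free-text section
#'   is left empty (the register's sections are all optional).
#' @param window,lexicon KWIC window and negation lexicon the planted
#'   phrases must conform to (checked at generation time).
#' @return A `generator_config`.
#' @export
generator_config <- function(
    n_records = 500,
    seed = 1,
    species = c("Fiordland Crested Penguin" = 3, "Little Blue Penguin" = 3,
                "Kakapo" = 1, "Kea" = 2, "Tui" = 2, "Morepork" = 1),
    species_variants = c("Fiordland Crested Penguin" = "Fiordland crested penguin",
                         "Little Blue Penguin" = "little blue penguin",
                         "Kakapo" = "kakapo", "Kea" = "kea", "Tui" = "tui",
                         "Morepork" = "morepork"),
    typo_rate = 0.06,
    sex_levels = c("male", "female", "unknown"),
    sex_weights = c(0.4, 0.45, 0.15),
    sex_missing_rate = 0.02,
    age_levels = c("adult", "juvenile", "subadult"),
    age_weights = c(0.6, 0.25, 0.15),
    age_missing_rate = 0.02,
    date_start = "2019-01-01",
    date_end = "2021-12-31",
    date_missing_rate = 0.01,
    themes = list(
      malaria = list(
        vocabulary = c("plasmodium", "plasmodial", "plasmodium-like",
                       "malaria", "malarial", "haemosiderin", "kupfer",
                       "spleen", "schizonts", "erythrocytic"),
        prob = 0.35),
      freeze_thaw = list(
        vocabulary = c("freeze", "thaw", "artifact", "autolysis",
                       "vacuolation", "crystallisation"),
        prob = 0.25),
      body_condition = list(
        vocabulary = c("poor", "body", "condition", "emaciated", "pectoral",
                       "musculature", "keel", "fat"),
        prob = 0.30)),
    theme_mode = c("independent", "exclusive"),
    theme_tokens = 8,
    findings = data.frame(
      term = c("pneumonia", "nephritis", "hepatitis", "aspergillosis"),
      positive_rate = c(0.20, 0.15, 0.10, 0.08),
      negated_rate = c(0.15, 0.10, 0.10, 0.05)),
    affirm_templates = c("severe {X} present.", "evidence of {X}.",
                         "marked {X} noted.", "findings consistent with {X}.",
                         "moderate {X} identified."),
    negation_templates = c("no evidence of {X}.", "no {X} seen.",
                           "there is no {X}.", "{X} absent.",
                           "without evidence of {X}.", "negative for {X}."),
    filler_max = 2,
    ancillary_empty_rate = 0.3,
    window = 10,
    lexicon = negation_lexicon()) {
  theme_mode <- match.arg(theme_mode)
  probs <- c(typo_rate, sex_missing_rate, age_missing_rate, date_missing_rate,
             ancillary_empty_rate,
             vapply(themes, function(t) t$prob, numeric(1)),
             if (nrow(findings)) c(findings$positive_rate, findings$negated_rate))
  if (any(probs < 0 | probs > 1)) {
    stop("generator config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  vocabs <- lapply(themes, `[[`, "vocabulary")
  all_words <- unlist(vocabs, use.names = FALSE)
  if (anyDuplicated(all_words)) {
    stop("generator config error: theme vocabularies must be disjoint", call. = FALSE)
  }
  if (nrow(findings) && any(findings$term %in% all_words)) {
    stop("generator config error: finding terms must not appear in theme vocabularies",
         call. = FALSE)
  }
  structure(
    list(n_records = n_records, seed = seed,
         species = species, species_variants = species_variants,
         typo_rate = typo_rate,
         sex_levels = sex_levels, sex_weights = sex_weights,
         sex_missing_rate = sex_missing_rate,
         age_levels = age_levels, age_weights = age_weights,
         age_missing_rate = age_missing_rate,
         date_start = as.Date(date_start), date_end = as.Date(date_end),
         date_missing_rate = date_missing_rate,
         themes = themes, theme_mode = theme_mode, theme_tokens = theme_tokens,
         findings = findings,
         affirm_templates = affirm_templates,
         negation_templates = negation_templates,
         filler_max = filler_max, ancillary_empty_rate = ancillary_empty_rate,
         window = window, lexicon = lexicon),
    class = "generator_config"
  )
}

FILLER_POOL <- c("carcass received chilled.", "standard dissection performed.",
                 "tissues fixed in formalin.", "sections examined routinely.",
                 "multiple organs sampled.")
ANCILLARY_POOL <- c("bacterial culture yielded mixed growth.",
                    "pcr testing pending.", "heavy metal screen performed.")

fill_template <- function(template, term) gsub("{X}", term, template, fixed = TRUE)

#' Generate a synthetic necropsy-record dataset with ground truth
#'
#' Produces a register-shaped table (and optionally a CSV file) together
#' with the exact planted truth: true signalment levels before typographic
#' corruption, themes included per record, and the status of every finding
#' term in every record (`positive`, `negated_only`, or `absent`). Every
#' planted finding sentence is verified at generation time to classify
#' correctly under the package's own keyword-in-context phrase rule, so the
#' truth is consistent with the emitted text by construction.
#'
#' @param config A [generator_config()].
#' @param path Optional CSV output path.
#' @param truth_path Optional path for a JSON sidecar of the ground truth.
#' @return List with `data` (tibble in export schema — see
#'   [default_mapping()]), `truth` (a `necropsy_truth`), and `path`.
#' @export
generate_necropsy_data <- function(config = generator_config(), path = NULL,
                                   truth_path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records
  ids <- sprintf("WB%05d", seq_len(n))
  theme_names <- names(config$themes)
  theme_probs <- vapply(config$themes, `[[`, numeric(1), "prob")
  dates <- seq(config$date_start, config$date_end, by = "day")
  nf <- nrow(config$findings)

  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  finding_rows <- vector("list", n)

  for (r in seq_len(n)) {
    sp_true <- sample(names(config$species), 1L, prob = config$species)
    sp_rec <- if (stats::runif(1) < config$typo_rate) {
      unname(config$species_variants[[sp_true]])
    } else sp_true
    sex_true <- sample(config$sex_levels, 1L, prob = config$sex_weights)
    sex_rec <- if (stats::runif(1) < config$sex_missing_rate) "" else sex_true
    age_true <- sample(config$age_levels, 1L, prob = config$age_weights)
    age_rec <- if (stats::runif(1) < config$age_missing_rate) "" else age_true
    date_true <- format(sample(dates, 1L), "%Y-%m-%d")
    date_rec <- if (stats::runif(1) < config$date_missing_rate) "" else date_true

    if (config$theme_mode == "exclusive") {
      included <- sample(theme_names, 1L, prob = theme_probs)
    } else {
      included <- theme_names[stats::runif(length(theme_names)) < theme_probs]
    }
    theme_sentences <- unlist(lapply(included, function(tn) {
      words <- sample(config$themes[[tn]]$vocabulary, config$theme_tokens,
                      replace = TRUE)
      # break into sentences of up to six words so phrases stay short
      grp <- ceiling(seq_along(words) / 6)
      vapply(split(words, grp), function(w) paste0(paste(w, collapse = " "), "."),
             character(1))
    }), use.names = FALSE)

    affirmed_sent <- character()
    negated_sent <- character()
    status <- character(nf)
    if (nf) {
      for (f in seq_len(nf)) {
        term <- config$findings$term[f]
        affirmed <- stats::runif(1) < config$findings$positive_rate[f]
        negated <- stats::runif(1) < config$findings$negated_rate[f]
        if (affirmed) {
          affirmed_sent <- c(affirmed_sent,
                             fill_template(sample(config$affirm_templates, 1L), term))
        }
        if (negated) {
          negated_sent <- c(negated_sent,
                            fill_template(sample(config$negation_templates, 1L), term))
        }
        status[f] <- if (affirmed) "positive" else if (negated) "negated_only" else "absent"
      }
    }

    filler <- if (config$filler_max > 0) {
      sample(FILLER_POOL, sample.int(config$filler_max, 1L))
    } else character()

    gross <- paste(c(filler, affirmed_sent), collapse = " ")
    histo <- paste(c(theme_sentences, negated_sent), collapse = " ")
    ancillary <- if (config$filler_max > 0 &&
                     stats::runif(1) >= config$ancillary_empty_rate) {
      sample(ANCILLARY_POOL, 1L)
    } else ""
    pos_terms <- if (nf) config$findings$term[status == "positive"] else character()
    diagnosis <- if (config$filler_max == 0) {
      ""
    } else if (length(pos_terms)) {
      paste0("morphologic diagnosis of ", pos_terms[1L], ".")
    } else {
      "open diagnosis."
    }

    # self-check: the planted text must classify exactly under the package's
    # own phrase rule, otherwise the truth labels would be unreliable
    if (nf) {
      merged <- paste(c(gross, histo, ancillary, diagnosis), collapse = "\n")
      stream <- tokenize(merged, ids[r])
      for (f in seq_len(nf)) {
        hits <- kwic(stream, config$findings$term[f], window = config$window,
                     lexicon = config$lexicon)
        detected <- if (nrow(hits) == 0L) "absent"
                    else if (any(!hits$negated)) "positive" else "negated_only"
        if (!identical(detected, status[f])) {
          stop("generator self-check failed for record ", ids[r], ", term '",
               config$findings$term[f], "': planted ", status[f],
               " but detected ", detected, call. = FALSE)
        }
      }
    }

    rows[[r]] <- tibble::tibble(
      accession = ids[r], species = sp_rec, sex = sex_rec, age_class = age_rec,
      submission_date = date_rec, gross_findings = gross,
      histopathology = histo, ancillary_tests = ancillary, diagnosis = diagnosis
    )
    truth_rows[[r]] <- tibble::tibble(
      accession_id = ids[r], species = sp_true, sex = sex_true,
      age_class = age_true, submission_date = date_true,
      themes = paste(included, collapse = ";")
    )
    if (nf) {
      finding_rows[[r]] <- tibble::tibble(
        accession_id = ids[r], term = config$findings$term, status = status
      )
    }
  }

  data <- dplyr::bind_rows(rows)
  truth <- structure(
    list(records = dplyr::bind_rows(truth_rows),
         findings = if (nf) dplyr::bind_rows(finding_rows) else
           tibble::tibble(accession_id = character(), term = character(),
                          status = character()),
         config = config),
    class = "necropsy_truth"
  )
  if (!is.null(path)) readr::write_csv(data, path, progress = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(records = truth$records, findings = truth$findings,
           seed = config$seed, n_records = config$n_records),
      truth_path, dataframe = "rows", auto_unbox = TRUE)
  }
  list(data = data, truth = truth, path = path)
}

#' Expected finding counts from generator ground truth
#'
#' Computes, without reading the generated CSV, the per-term positive-record
#' counts and the unique-record count that [positive_records()] must
#' reproduce on the same data.
#'
#' @param truth A `necropsy_truth` from [generate_necropsy_data()].
#' @param terms Finding terms to report (must be in the generating config).
#' @return List with `counts` (tibble `term`, `n_positive`) and
#'   `unique_records` (character vector of accession ids).
#' @export
truth_report <- function(truth, terms) {
  stopifnot(inherits(truth, "necropsy_truth"))
  known <- unique(truth$findings$term)
  unknown <- setdiff(terms, known)
  if (length(unknown)) {
    stop("term(s) not in generator config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pos <- truth$findings[truth$findings$term %in% terms &
                          truth$findings$status == "positive", , drop = FALSE]
  counts <- tibble::tibble(
    term = terms,
    n_positive = unname(vapply(terms, function(t) sum(pos$term == t), integer(1)))
  )
  list(counts = counts, unique_records = unique(pos$accession_id))
}

#' True topic-word distributions of a generator config
#'
#' For planted-topic recovery checks: each theme's true word distribution is
#' uniform over its (disjoint) vocabulary, expressed over the union
#' vocabulary of all themes.
#'
#' @param config A `generator_config`.
#' @return Matrix themes x words, rows summing to 1.
#' @export
theme_word_distributions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  vocab <- sort(unique(unlist(lapply(config$themes, `[[`, "vocabulary"))))
  mat <- matrix(0, nrow = length(config$themes), ncol = length(vocab),
                dimnames = list(names(config$themes), vocab))
  for (tn in names(config$themes)) {
    v <- config$themes[[tn]]$vocabulary
    mat[tn, v] <- 1 / length(v)
  }
  mat
}
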