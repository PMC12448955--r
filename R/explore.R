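# Explore stage: pairwise word-correlation edges over document co-occurrence
# and latent Dirichlet allocation fitted by a collapsed Gibbs sampler.

#' Word co-occurrence correlation edges
#'
#' For every pair of sufficiently frequent terms, computes the phi
#' coefficient of their binary document-presence indicators — the Pearson
#' correlation of the two indicator vectors, equivalently
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}}
#' on the 2x2 co-occurrence table. Position within a document is ignored:
#' the statistic captures which terms tend to appear in the same records.
#' Pairs with any zero marginal (phi undefined) are skipped.
#'
#' @param dtm A `necropsy_dtm`.
#' @param min_count Minimum number of documents a term must occur in to be
#'   eligible (default 5; guards against spurious perfect correlations
#'   between rare terms).
#' @param min_corr Minimum phi for an edge to be reported, in \[0, 1\].
#'   Lowering it densifies the network; raising it never adds edges.
#' @return Tibble of edges `term_a`, `term_b` (lexicographic, one row per
#'   unordered pair), `phi`, and the contingency counts `n11`, `n10`, `n01`,
#'   `n00`; sorted by `phi` descending.
#' @export
word_correlations <- function(dtm, min_count = 5, min_corr = 0.5) {
  stopifnot(inherits(dtm, "necropsy_dtm"), min_count >= 1,
            min_corr >= 0, min_corr <= 1)
  eligible <- dtm$doc_freq >= min_count
  if (!any(eligible)) stop("no eligible terms at min_count = ", min_count, call. = FALSE)
  X <- (dtm$counts[, eligible, drop = FALSE] > 0) * 1
  N <- nrow(X)
  V <- ncol(X)
  terms <- colnames(X)
  n1 <- Matrix::colSums(X)
  co <- as.matrix(Matrix::crossprod(X))   # n11 for every pair
  empty <- tibble::tibble(term_a = character(), term_b = character(),
                          phi = double(), n11 = integer(), n10 = integer(),
                          n01 = integer(), n00 = integer())
  if (V < 2) return(empty)
  ij <- which(upper.tri(co), arr.ind = TRUE)
  n11 <- unname(co[ij])
  na <- unname(n1[ij[, 1]])
  nb <- unname(n1[ij[, 2]])
  n10 <- na - n11
  n01 <- nb - n11
  n00 <- N - na - nb + n11
  denom <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  phi <- (n11 * n00 - n10 * n01) / denom
  ok <- is.finite(phi) & denom > 0 & phi >= min_corr
  if (!any(ok)) return(empty)
  out <- tibble::tibble(
    term_a = terms[ij[ok, 1]], term_b = terms[ij[ok, 2]],
    phi = phi[ok],
    n11 = as.integer(n11[ok]), n10 = as.integer(n10[ok]),
    n01 = as.integer(n01[ok]), n00 = as.integer(n00[ok])
  )
  swap <- out$term_a > out$term_b
  tmp <- out$term_a[swap]; out$term_a[swap] <- out$term_b[swap]; out$term_b[swap] <- tmp
  tmp <- out$n10[swap]; out$n10[swap] <- out$n01[swap]; out$n01[swap] <- tmp
  out[order(-out$phi, out$term_a, out$term_b), , drop = FALSE]
}

#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling over per-token topic assignments with symmetric
#' Dirichlet priors: `alpha` on document-topic mixtures, `beta` on
#' topic-word distributions. The topic-word matrix `phi` and document-topic
#' matrix `theta` are estimated from the final sweep's counts with prior
#' smoothing:
#' \deqn{\phi_{kw} = (n_{kw} + \beta) / (n_k + V\beta), \quad
#'       \theta_{dk} = (n_{dk} + \alpha) / (n_d + K\alpha)}
#' Runs are fully reproducible given `seed`. Token-count conservation is
#' asserted after every sweep inside the sampler.
#'
#' @param dtm A `necropsy_dtm`.
#' @param k Number of topics (>= 2); the only required modelling input.
#' @param alpha Document-topic concentration; default `50 / k`.
#' @param beta Topic-word concentration; default `0.1`.
#' @param iterations Gibbs sweeps; default 1000. The final state is the
#'   estimate (no averaging across sweeps).
#' @param seed RNG seed.
#' @return A `topic_model`: list with `k`, `alpha`, `beta`, `phi` (k x V,
#'   rows sum to 1), `theta` (docs x k, rows sum to 1), `z` (per-document
#'   integer topic assignments), `seed`, `iterations`, `excluded_docs`.
#' @details Documents left with zero tokens after stop-word filtering cannot
#'   inform the model and are excluded with a warning; `theta` has no row
#'   for them.
#' @export
fit_lda <- function(dtm, k, alpha = 50 / k, beta = 0.1, iterations = 1000, seed = 1) {
  stopifnot(inherits(dtm, "necropsy_dtm"), k >= 2, iterations >= 1,
            alpha > 0, beta > 0)
  V <- length(dtm$vocabulary)
  if (V == 0L) stop("empty vocabulary", call. = FALSE)
  if (k > V) stop("k = ", k, " exceeds vocabulary size ", V, call. = FALSE)
  counts <- as.matrix(dtm$counts)
  doc_tokens <- apply(counts, 1L, function(row) {
    idx <- which(row > 0)
    as.integer(rep(idx - 1L, row[idx]))
  }, simplify = FALSE)
  nonempty <- lengths(doc_tokens) > 0L
  if (!all(nonempty)) {
    warning(sum(!nonempty), " document(s) with zero tokens excluded from LDA: ",
            paste(utils::head(dtm$doc_ids[!nonempty], 5L), collapse = ", "),
            call. = FALSE)
  }
  docs <- doc_tokens[nonempty]
  doc_ids <- dtm$doc_ids[nonempty]
  if (length(docs) == 0L) stop("no non-empty documents", call. = FALSE)

  set.seed(seed)
  state <- lda_gibbs_cpp(docs, V, as.integer(k), alpha, beta, as.integer(iterations))

  nkw <- state$nkw
  phi <- (nkw + beta) / (rowSums(nkw) + V * beta)
  dimnames(phi) <- list(paste0("topic", seq_len(k)), dtm$vocabulary)
  ndk <- state$ndk
  theta <- (ndk + alpha) / (rowSums(ndk) + k * alpha)
  dimnames(theta) <- list(doc_ids, paste0("topic", seq_len(k)))

  structure(
    list(k = k, alpha = alpha, beta = beta,
         phi = phi, theta = theta,
         z = stats::setNames(lapply(state$z, function(v) v + 1L), doc_ids),
         seed = seed, iterations = iterations,
         total_tokens = state$total_tokens,
         conservation_checked = state$conservation_checked,
         excluded_docs = dtm$doc_ids[!nonempty]),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model> k = ", x$k, ", ", nrow(x$theta), " documents, ",
      ncol(x$phi), " terms\n", sep = "")
  cat("  alpha = ", format(x$alpha, digits = 4), ", beta = ", x$beta,
      ", iterations = ", x$iterations, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Word-cloud table for a fitted topic model
#'
#' The table behind a topic word cloud: per topic the top terms by
#' topic-word probability, and per term the single topic under which it is
#' most probable (its display colour). A term can rank highly in several
#' topics but is assigned to exactly one.
#'
#' @param model A `topic_model`.
#' @param words_per_topic Number of top terms listed per topic (clipped to
#'   the vocabulary size).
#' @return Tibble `topic`, `rank`, `term`, `weight` (phi), `assigned_topic`.
#' @export
topic_word_cloud <- function(model, words_per_topic = 20) {
  stopifnot(inherits(model, "topic_model"), words_per_topic >= 1)
  phi <- model$phi
  terms <- colnames(phi)
  n <- min(words_per_topic, length(terms))
  assigned <- apply(phi, 2L, which.max)
  rows <- lapply(seq_len(model$k), function(kk) {
    ord <- order(-phi[kk, ], terms)[seq_len(n)]
    tibble::tibble(topic = kk, rank = seq_len(n), term = terms[ord],
                   weight = phi[kk, ord],
                   assigned_topic = as.integer(assigned[ord]))
  })
  dplyr::bind_rows(rows)
}
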