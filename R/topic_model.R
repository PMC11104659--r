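#' Fit a latent Dirichlet allocation model by collapsed Gibbs sampling
#'
#' The sampler integrates out the topic-word and document-topic
#' distributions and resamples each token's topic from
#' `P(z = k) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta)`.
#' Point estimates of the topic-word matrix `phi` and document-topic
#' matrix `theta` are averages of the smoothed count ratios over
#' post-burn-in samples (every `thin` iterations). Sampling is
#' deterministic given `seed`. Empty documents are tolerated and get a
#' uniform `theta` row; an empty corpus is an error.
#'
#' @param bow A `bow_corpus` from [build_bow()].
#' @param K Number of topics (>= 2).
#' @param alpha Document-topic concentration (default `50 / K`).
#' @param beta Topic-word concentration (default 0.01).
#' @param iterations Total Gibbs sweeps (default 500).
#' @param burn_in Sweeps discarded before averaging (default 300).
#' @param thin Keep every `thin`-th post-burn-in sweep (default 10).
#' @param seed Integer seed.
#' @return An `lda_model`: list with `phi` (K x V, rows sum to 1),
#'   `theta` (D x K, rows sum to 1), `assignments` (final token-topic
#'   assignments per document), `nkw` (final topic-word counts, for
#'   conservation checks), `vocab`, `doc_ids` and `config`.
#' @export
lda_fit <- function(bow, K, alpha = 50 / K, beta = 0.01,
                    iterations = 500, burn_in = 300, thin = 10, seed = 1L) {
  stopifnot(inherits(bow, "bow_corpus"))
  if (K < 2) abort("K must be at least 2")
  if (!(iterations > burn_in && burn_in >= 0)) {
    abort("iterations must exceed burn_in and burn_in must be >= 0")
  }
  docs <- bow_token_lists(bow)
  if (length(docs) == 0L || sum(lengths(docs)) == 0L) {
    abort("cannot fit a topic model on an empty corpus")
  }
  V <- nrow(bow$vocab)
  fit <- .lda_gibbs_cpp(docs, V, as.integer(K), alpha, beta,
                        as.integer(iterations), as.integer(burn_in),
                        as.integer(thin), derive_seed(seed, "lda"))
  colnames(fit$phi) <- bow$vocab$term
  colnames(fit$nkw) <- bow$vocab$term
  rownames(fit$theta) <- bow$doc_ids
  structure(
    list(phi = fit$phi, theta = fit$theta,
         assignments = setNames(fit$assignments, bow$doc_ids),
         nkw = fit$nkw, vocab = bow$vocab, doc_ids = bow$doc_ids,
         n_samples = fit$n_samples,
         config = list(K = K, alpha = alpha, beta = beta,
                       iterations = iterations, burn_in = burn_in,
                       thin = thin, seed = seed)),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> K = ", x$config$K, ", ", length(x$doc_ids),
      " documents, ", nrow(x$vocab), " terms (",
      x$config$iterations, " sweeps, ", x$n_samples, " samples)\n", sep = "")
  invisible(x)
}

#' @export
tidy.lda_model <- function(x, ...) {
  tibble(topic = rep(seq_len(nrow(x$phi)), times = ncol(x$phi)),
         term = rep(colnames(x$phi), each = nrow(x$phi)),
         beta = as.numeric(x$phi))
}

#' @export
glance.lda_model <- function(x, ...) {
  tibble(K = x$config$K, alpha = x$config$alpha, beta = x$config$beta,
         iterations = x$config$iterations, n_docs = length(x$doc_ids),
         n_terms = nrow(x$vocab))
}

#' Held-out perplexity of a topic model
#'
#' Folds the held-out documents into the fitted model (topic-word matrix
#' fixed, document-topic counts resampled), then computes
#' `exp(-sum(log p(w|d)) / N)` with `p(w|d) = sum_k theta'_dk phi_kw`.
#' Held-out terms outside the model vocabulary are dropped and counted
#' in `attr(, "n_oov_dropped")`.
#'
#' @param model An `lda_model`.
#' @param heldout A `bow_corpus` of held-out documents.
#' @param foldin_iterations Gibbs sweeps for the fold-in (default 50).
#' @param completion If `TRUE`, document-completion scoring: `theta'` is
#'   estimated on every other token of each held-out document and the
#'   likelihood evaluated on the remaining tokens, so extra topics
#'   cannot pay for themselves by adapting to the scored tokens. With
#'   `FALSE` (default) `theta'` is folded in on the full document.
#' @param seed Integer seed for the fold-in sampler.
#' @return Positive number; lower is better. For a model whose rows are
#'   uniform over `V` words the perplexity is exactly `V`.
#' @export
lda_perplexity <- function(model, heldout, foldin_iterations = 50,
                           completion = FALSE, seed = 1L) {
  stopifnot(inherits(model, "lda_model"), inherits(heldout, "bow_corpus"))
  counts <- heldout$counts
  counts$model_index <- match(counts$term, colnames(model$phi))
  oov <- is.na(counts$model_index)
  n_oov <- sum(counts$count[oov])
  counts <- counts[!oov, , drop = FALSE]
  if (nrow(counts) == 0L) abort("no held-out tokens overlap the model vocabulary")
  split_counts <- split(counts, factor(counts$post_id, levels = heldout$doc_ids))
  docs <- lapply(split_counts, function(d) {
    if (nrow(d) == 0L) return(integer(0))
    rep(d$model_index - 1L, d$count)
  })
  if (completion) {
    est <- lapply(docs, function(t) t[seq_along(t) %% 2 == 0])
    score <- lapply(docs, function(t) t[seq_along(t) %% 2 == 1])
  } else {
    est <- docs
    score <- docs
  }
  theta <- .lda_foldin_cpp(unname(est), model$phi, model$config$alpha,
                           as.integer(foldin_iterations),
                           derive_seed(seed, "foldin"))
  loglik <- 0
  total <- 0
  for (d in seq_along(score)) {
    if (length(score[[d]]) == 0L) next
    pw <- as.numeric(theta[d, , drop = FALSE] %*%
                       model$phi[, score[[d]] + 1L, drop = FALSE])
    loglik <- loglik + sum(log(pw))
    total <- total + length(score[[d]])
  }
  if (total == 0L) abort("no tokens to score")
  out <- exp(-loglik / total)
  attr(out, "n_oov_dropped") <- n_oov
  out
}

#' NPMI coherence of a word list
#'
#' Mean normalised pointwise mutual information over all pairs of the
#' given top words, with document-level co-occurrence probabilities:
#' `NPMI(wi, wj) = log((p_ij + eps) / ((p_i + eps)(p_j + eps))) /
#' (-log(p_ij + eps))`. Words always co-occurring score 1, independent
#' words 0 (up to `eps`), words never co-occurring approach -1. Words
#' absent from the corpus are skipped and counted in
#' `attr(, "n_skipped_pairs")`.
#'
#' @param bow A `bow_corpus` supplying the reference document
#'   co-occurrence counts.
#' @param top_words Character vector of at least 2 words.
#' @param eps Smoothing constant (default 1e-12).
#' @return Number in `[-1, 1]`.
#' @export
npmi_coherence <- function(bow, top_words, eps = 1e-12) {
  stopifnot(inherits(bow, "bow_corpus"))
  top_words <- unique(top_words)
  if (length(top_words) < 2L) abort("need at least two top words")
  D <- length(bow$doc_ids)
  doc_sets <- lapply(top_words, function(w) {
    unique(bow$counts$post_id[bow$counts$term == w])
  })
  names(doc_sets) <- top_words
  present <- lengths(doc_sets) > 0
  vals <- c()
  skipped <- 0L
  n <- length(top_words)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!present[i] || !present[j]) {
        skipped <- skipped + 1L
        next
      }
      pi <- length(doc_sets[[i]]) / D
      pj <- length(doc_sets[[j]]) / D
      pij <- length(intersect(doc_sets[[i]], doc_sets[[j]])) / D
      npmi <- log((pij + eps) / ((pi + eps) * (pj + eps))) / (-log(pij + eps))
      vals <- c(vals, npmi)
    }
  }
  if (length(vals) == 0L) abort("no word pair present in the corpus")
  out <- mean(vals)
  attr(out, "n_skipped_pairs") <- skipped
  out
}

#' Summarise fitted topics: top words, coherence, word share
#'
#' For each topic: the `top_n` highest-probability words (ties broken
#' lexicographically), the NPMI coherence of that word list against the
#' corpus, and the percentage of distinct vocabulary words whose
#' highest-probability topic is this one (ties to the lowest topic
#' index) — so the word shares partition the vocabulary and sum to 100.
#' Topics are reported in decreasing coherence order.
#'
#' @param model An `lda_model`.
#' @param bow The `bow_corpus` used as coherence reference (typically
#'   the training corpus).
#' @param top_n Words per topic (default 12).
#' @param eps Coherence smoothing, see [npmi_coherence()].
#' @return A `topic_summary` tibble: `(topic, top_words, coherence,
#'   word_share_pct)` with `top_words` a list column.
#' @export
lda_summarize <- function(model, bow, top_n = 12, eps = 1e-12) {
  stopifnot(top_n >= 1)
  K <- nrow(model$phi)
  terms <- colnames(model$phi)
  argmax <- apply(model$phi, 2, which.max)  # ties -> lowest topic index
  share <- 100 * as.integer(table(factor(argmax, levels = seq_len(K)))) / length(terms)
  rows <- purrr::map_dfr(seq_len(K), function(k) {
    p <- model$phi[k, ]
    ord <- order(-p, terms)
    tw <- terms[ord[seq_len(min(top_n, length(terms)))]]
    tibble(topic = k,
           top_words = list(tw),
           coherence = as.numeric(npmi_coherence(bow, tw, eps)),
           word_share_pct = share[k])
  })
  rows <- rows[order(-rows$coherence), , drop = FALSE]
  structure(rows, class = c("topic_summary", class(rows)))
}

#' Choose the number of topics by held-out perplexity and coherence
#'
#' Splits the corpus into training and validation documents, fits one
#' model per candidate `K`, and reports validation perplexity and mean
#' NPMI coherence. The preferred `K` has the lowest validation
#' perplexity (and typically the highest coherence). Perplexity uses
#' document-completion scoring (see [lda_perplexity()]) so that larger
#' `K` is not rewarded merely for adapting the per-document mixture to
#' the scored tokens, and fits default to a sparse document prior
#' (`alpha = 0.1`), appropriate for short forum posts that touch only a
#' few themes each.
#'
#' @param bow A `bow_corpus`.
#' @param ks Integer vector of candidate topic counts.
#' @param val_fraction Fraction of documents held out (default 0.1).
#' @param top_n Words per topic for the coherence score.
#' @param alpha Document-topic concentration for the candidate fits.
#' @param seed Integer seed controlling the split and each fit.
#' @param ... Passed to [lda_fit()] (e.g. `iterations`, `beta`).
#' @return Tibble `(K, perplexity, coherence)` with one row per
#'   candidate, plus `attr(, "best_k")`.
#' @export
lda_select_k <- function(bow, ks, val_fraction = 0.1, top_n = 10,
                         alpha = 0.1, seed = 1L, ...) {
  stopifnot(inherits(bow, "bow_corpus"), length(ks) >= 1)
  D <- length(bow$doc_ids)
  n_val <- max(1L, floor(val_fraction * D))
  val_ids <- with_seed(derive_seed(seed, "val-split"), {
    sample(bow$doc_ids, n_val)
  })
  subset_bow <- function(ids) {
    counts <- bow$counts[bow$counts$post_id %in% ids, , drop = FALSE]
    structure(list(vocab = bow$vocab, counts = counts, doc_ids = ids,
                   n_tokens = sum(counts$count)),
              class = "bow_corpus")
  }
  train <- subset_bow(setdiff(bow$doc_ids, val_ids))
  val <- subset_bow(val_ids)
  res <- purrr::map_dfr(ks, function(k) {
    fit <- lda_fit(train, K = k, alpha = alpha,
                   seed = derive_seed(seed, "fit", k), ...)
    summ <- lda_summarize(fit, train, top_n = top_n)
    tibble(K = k,
           perplexity = as.numeric(lda_perplexity(fit, val, completion = TRUE,
                                                  seed = derive_seed(seed, "perp", k))),
           coherence = mean(summ$coherence))
  })
  attr(res, "best_k") <- res$K[which.min(res$perplexity)]
  res
}
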