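#' Train word embeddings by skip-gram with negative sampling
#'
#' Trains word vectors on tokenised posts so that words used in similar
#' contexts receive similar vectors (the distributional hypothesis that
#' underlies similarity-based lexicon expansion). The trainer is
#' single-threaded and fully deterministic given `seed`. The negative-
#' sampling distribution is unigram^0.75; no frequent-word subsampling is
#' applied.
#'
#' @param tokens Long tibble `(post_id, token)` from [tokenize_posts()].
#' @param dim Vector dimensionality (default 100).
#' @param window Maximum context window; the effective window per token
#'   is drawn uniformly from 1..`window` (default 5).
#' @param negatives Negative samples per positive pair (default 5).
#' @param epochs Training epochs (default 5).
#' @param learning_rate Initial learning rate, decayed linearly.
#' @param min_count Minimum corpus frequency for a word to be trained.
#' @param seed Integer seed.
#' @return A `word_embedding` object: list with `vocab` (tibble `term`,
#'   `index`, `count`), `input` and `output` matrices (V x dim, rownames
#'   are terms), `epoch_loss`, and the training configuration.
#'   Similarities use the input vectors.
#' @export
train_embeddings <- function(tokens, dim = 100, window = 5, negatives = 5,
                             epochs = 5, learning_rate = 0.025,
                             min_count = 5, seed = 1L) {
  stopifnot(dim >= 2, window >= 1, epochs >= 1)
  freq <- table(tokens$token)
  keep <- names(freq)[freq >= min_count]
  if (length(keep) == 0L) {
    abort("empty vocabulary: no token reaches min_count")
  }
  vocab <- tibble(term = sort(keep),
                  index = seq_along(keep),
                  count = as.integer(freq[sort(keep)]))
  tokens <- tokens[tokens$token %in% keep, , drop = FALSE]
  ids <- vocab$index[match(tokens$token, vocab$term)] - 1L
  docs <- unname(split(ids, factor(tokens$post_id, levels = unique(tokens$post_id))))
  fit <- .sgns_train_cpp(docs, vocab$count, as.integer(dim),
                         as.integer(window), as.integer(negatives),
                         as.integer(epochs), learning_rate,
                         derive_seed(seed, "sgns"))
  rownames(fit$input) <- vocab$term
  rownames(fit$output) <- vocab$term
  structure(
    list(vocab = vocab, input = fit$input, output = fit$output,
         epoch_loss = as.numeric(fit$epoch_loss),
         config = list(dim = dim, window = window, negatives = negatives,
                       epochs = epochs, learning_rate = learning_rate,
                       min_count = min_count, seed = seed)),
    class = "word_embedding"
  )
}

#' @export
print.word_embedding <- function(x, ...) {
  cat("<word_embedding> ", nrow(x$vocab), " terms, dim ", x$config$dim,
      ", ", x$config$epochs, " epochs (final loss ",
      signif(x$epoch_loss[length(x$epoch_loss)], 4), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.word_embedding <- function(x, ...) {
  tibble(n_terms = nrow(x$vocab), dim = x$config$dim,
         window = x$config$window, epochs = x$config$epochs,
         final_loss = x$epoch_loss[length(x$epoch_loss)])
}

embedding_vector <- function(model, term) {
  i <- match(term, model$vocab$term)
  if (is.na(i)) {
    abort(paste0("term not in embedding vocabulary: ", term),
          class = "cravingminer_oov")
  }
  model$input[i, ]
}

#' Cosine similarity between two embedded words
#'
#' @param model A `word_embedding` from [train_embeddings()].
#' @param w1,w2 Terms; both must be in the vocabulary (an
#'   out-of-vocabulary term raises an error of class
#'   `cravingminer_oov`).
#' @return Cosine similarity in `[-1, 1]`, symmetric in its arguments.
#' @export
embedding_similarity <- function(model, w1, w2) {
  a <- embedding_vector(model, w1)
  b <- embedding_vector(model, w2)
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Nearest neighbours of a word by cosine similarity
#'
#' @param model A `word_embedding`.
#' @param w Query term (must be in vocabulary).
#' @param k Number of neighbours (>= 1); truncated to V-1.
#' @return Tibble `(term, score)` ordered by non-increasing score, the
#'   query term excluded, ties broken lexicographically.
#' @export
most_similar <- function(model, w, k = 10) {
  stopifnot(k >= 1)
  v <- embedding_vector(model, w)
  m <- model$input
  norms <- unname(sqrt(rowSums(m * m)))
  scores <- as.numeric(m %*% v) / (norms * sqrt(sum(v * v)))
  out <- tibble(term = model$vocab$term, score = scores)
  out <- out[out$term != w, , drop = FALSE]
  out <- out[order(-out$score, out$term), , drop = FALSE]
  head(out, min(k, nrow(out)))
}

#' Report pairwise word similarities as percentages
#'
#' Cosine similarities scaled by 100 and reported to two decimals, the
#' form in which word-pair relatedness is usually quoted (e.g. a 45%
#' similarity between a weekday and a craving term). Out-of-vocabulary
#' probes are flagged, not fatal.
#'
#' @param model A `word_embedding`.
#' @param probes Tibble or data frame with columns `term1`, `term2`.
#' @return Tibble `(term1, term2, similarity_pct, oov)` with
#'   `similarity_pct` `NA` for flagged rows.
#' @export
similarity_report <- function(model, probes) {
  probes <- as_tibble(probes)
  stopifnot(all(c("term1", "term2") %in% names(probes)))
  res <- purrr::pmap_dfr(probes[, c("term1", "term2")], function(term1, term2) {
    ok <- all(c(term1, term2) %in% model$vocab$term)
    tibble(term1 = term1, term2 = term2,
           similarity_pct = if (ok) {
             round_half_up(100 * embedding_similarity(model, term1, term2), 2)
           } else NA_real_,
           oov = !ok)
  })
  res
}
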