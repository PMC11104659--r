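#' Configuration for the synthetic forum-corpus generator
#'
#' The defaults emulate the corpus statistics of a quit-drinking
#' sobriety forum: about 70% of authors write a single post, posts
#' average 105 words, roughly 16% of posts mention a craving, posting
#' intensity peaks between 13:00 and 23:00 local time, and sobriety
#' badges decay geometrically with excess mass on milestone days
#' (30/100/365). Default per-author context rates follow the per-category
#' author percentages observed in such a forum.
#'
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @param n_authors Number of distinct authors.
#' @param single_post_author_fraction Probability an author writes
#'   exactly one post (default 0.70).
#' @param multi_post_geom_prob Geometric parameter for the extra posts of
#'   multi-post authors (default 0.5, so ~15% of authors write two).
#' @param mean_post_words Mean words per post (Poisson, floored at 20).
#' @param craving_rate Per-post probability of a planted craving mention.
#' @param context_rates Named numeric vector, category -> per-author
#'   probability of that craving context.
#' @param inflection_probs Probabilities that a planted craving term
#'   appears as the bare stem, stem+"s", stem+"ing", or inside a
#'   hyphenated compound ("alcohol-<stem>").
#' @param n_topics_true,topic_word_concentration,doc_topic_concentration
#'   Parameters of the latent-topic model generating the filler text.
#' @param vocab_size Size of the synthetic filler vocabulary.
#' @param diurnal_peak_window Inclusive local-hour window `[start, end]`
#'   of elevated posting intensity (default `c(13, 23)`).
#' @param diurnal_peak_ratio Intensity ratio peak : off-peak (>= 1).
#' @param flair_present_rate Probability an author wears a sobriety badge.
#' @param flair_decay_rate Geometric parameter p of badge day counts.
#' @param milestone_days Days whose badge mass is boosted.
#' @param milestone_boost Multiplier (>= 1) on milestone-day mass.
#' @param craving_terms Craving lexicon used for injection (default the
#'   six seed synonyms).
#' @param registry Context registry supplying the category term lists.
#' @return A `generator_config` list, validated.
#' @export
corpus_config <- function(seed = 1L,
                          n_authors = 1000L,
                          single_post_author_fraction = 0.70,
                          multi_post_geom_prob = 0.5,
                          mean_post_words = 105,
                          craving_rate = 0.16,
                          context_rates = default_context_rates(),
                          inflection_probs = c(stem = 0.55, plural = 0.15,
                                               ing = 0.15, compound = 0.15),
                          n_topics_true = 5L,
                          topic_word_concentration = 0.1,
                          doc_topic_concentration = 0.5,
                          vocab_size = 300L,
                          diurnal_peak_window = c(13L, 23L),
                          diurnal_peak_ratio = 3,
                          flair_present_rate = 0.8,
                          flair_decay_rate = 0.02,
                          milestone_days = c(30L, 100L, 365L),
                          milestone_boost = 5,
                          craving_terms = craving_seed_terms(),
                          registry = default_context_registry()) {
  cfg <- list(
    seed = as.integer(seed),
    n_authors = as.integer(n_authors),
    single_post_author_fraction = single_post_author_fraction,
    multi_post_geom_prob = multi_post_geom_prob,
    mean_post_words = mean_post_words,
    craving_rate = craving_rate,
    context_rates = context_rates,
    inflection_probs = inflection_probs / sum(inflection_probs),
    n_topics_true = as.integer(n_topics_true),
    topic_word_concentration = topic_word_concentration,
    doc_topic_concentration = doc_topic_concentration,
    vocab_size = as.integer(vocab_size),
    diurnal_peak_window = as.integer(diurnal_peak_window),
    diurnal_peak_ratio = diurnal_peak_ratio,
    flair_present_rate = flair_present_rate,
    flair_decay_rate = flair_decay_rate,
    milestone_days = as.integer(milestone_days),
    milestone_boost = milestone_boost,
    craving_terms = craving_terms,
    registry = registry
  )
  probs <- c(cfg$single_post_author_fraction, cfg$multi_post_geom_prob,
             cfg$craving_rate, cfg$context_rates, cfg$flair_present_rate,
             cfg$flair_decay_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_authors < 1L) abort("n_authors must be at least 1")
  if (cfg$mean_post_words <= 0) abort("mean_post_words must be positive")
  if (any(cfg$diurnal_peak_window < 0L | cfg$diurnal_peak_window > 23L)) {
    abort("diurnal_peak_window hours must lie in 0..23")
  }
  if (cfg$diurnal_peak_ratio < 1) abort("diurnal_peak_ratio must be >= 1")
  if (cfg$milestone_boost < 1) abort("milestone_boost must be >= 1")
  structure(cfg, class = "generator_config")
}

#' @rdname corpus_config
#' @export
default_context_rates <- function() {
  c("partner" = 0.3641, "family" = 0.3583, "friend(s)" = 0.3362,
    "alone" = 0.1806, "colleague(s)" = 0.0371, "work" = 0.4961,
    "home" = 0.3899, "workout" = 0.1890, "restaurant/bar" = 0.1674,
    "supermarket" = 0.1607, "party" = 0.1300, "university/school" = 0.0981,
    "airport" = 0.0214, "anxious/worried" = 0.4501, "happy" = 0.3554,
    "sad" = 0.3044, "frustrated/angry" = 0.2619, "proud" = 0.1858,
    "tired" = 0.1811, "stressed" = 0.1676, "bored" = 0.1169)
}

# Terms unique to a category within the registry, so injections never
# spill over into another category's match counts. Falls back to the full
# list for categories with no unique term.
unique_category_terms <- function(registry) {
  counts <- table(unlist(lapply(split(registry$term, registry$category), unique)))
  lapply(split(registry$term, registry$category), function(terms) {
    u <- terms[counts[terms] == 1L]
    if (length(u) == 0L) terms else u
  })
}

#' Sample sobriety-badge day counts
#'
#' Draws badge day counts from a geometric distribution on 1..`max_days`
#' with the probability mass of milestone days multiplied by
#' `milestone_boost`. Because the boost acts multiplicatively on single
#' days, excluding the milestone bins leaves an exactly geometric shape.
#'
#' @param n Number of draws.
#' @param p Geometric parameter (per-day stopping probability).
#' @param milestone_days Integer days to boost.
#' @param milestone_boost Mass multiplier (>= 1).
#' @param max_days Support upper bound.
#' @return Integer vector of day counts in 1..`max_days`.
#' @export
sample_flair_days <- function(n, p = 0.02, milestone_days = c(30L, 100L, 365L),
                              milestone_boost = 5, max_days = 5000L) {
  days <- seq_len(max_days)
  mass <- (1 - p)^(days - 1) * p
  mass[days %in% milestone_days] <- mass[days %in% milestone_days] * milestone_boost
  sample(days, n, replace = TRUE, prob = mass / sum(mass))
}

# sample one post's filler words from the latent-topic model
sample_filler <- function(len, theta, phi, vocab) {
  if (len == 0L) return(character(0))
  z <- sample.int(nrow(phi), len, replace = TRUE, prob = theta)
  words <- character(len)
  for (k in unique(z)) {
    idx <- which(z == k)
    words[idx] <- vocab[sample.int(ncol(phi), length(idx), replace = TRUE,
                                   prob = phi[k, ])]
  }
  words
}

# one inflected surface form of a craving term
inflect_term <- function(term, probs) {
  form <- sample(names(probs), 1L, prob = probs)
  switch(form,
    stem = term,
    plural = paste0(term, "s"),
    ing = paste0(term, "ing"),
    compound = paste0("alcohol-", term)
  )
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Emulates the statistical structure of a sobriety-forum corpus: skewed
#' per-author post counts, ~105-word posts of latent-topic filler text,
#' planted craving mentions at a configured rate (with inflected and
#' compound surface forms), per-author context-term injections, diurnal
#' posting times, and geometric sobriety badges with milestone spikes.
#' Every post is labelled, so downstream filters and context matchers can
#' be scored exactly. Fully reproducible from `config$seed`; each
#' author's draws use an RNG stream keyed by (seed, author index), so
#' corpora are stable under author-count changes.
#'
#' @param config A [corpus_config()] object.
#' @return A list with `posts` (a posts tibble in [read_posts()] layout)
#'   and `truth`, itself a list: `post_labels` (tibble `post_id`,
#'   `author`, `craving_label`, `context_labels` list column, `theta`
#'   list column of true topic mixtures), `authors` (tibble `author`,
#'   `n_posts`, `flair_days`, `utc_offset_minutes`), and `topic_word`
#'   (the true topic-word matrix of the filler model).
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  vocab <- sprintf("w%04d", seq_len(cfg$vocab_size))
  K <- cfg$n_topics_true

  phi <- with_seed(derive_seed(cfg$seed, "topic-word"), {
    m <- matrix(stats::rgamma(K * cfg$vocab_size, cfg$topic_word_concentration),
                nrow = K)
    m / rowSums(m)
  })
  cat_terms <- unique_category_terms(cfg$registry)
  categories <- names(cfg$context_rates)
  unknown <- setdiff(categories, names(cat_terms))
  if (length(unknown) > 0L) {
    abort(paste0("context_rates name categories absent from the registry: ",
                 paste(unknown, collapse = ", ")))
  }

  base_utc <- 1491004800  # 2017-04-01 00:00:00 UTC
  n_days <- 1826          # through 2022-04-01
  peak <- cfg$diurnal_peak_window
  hour_w <- rep(1, 24)
  hour_w[(peak[1]:peak[2]) + 1L] <- cfg$diurnal_peak_ratio
  offsets <- c(-480L, -420L, -360L, -300L, -240L, 0L, 60L)

  all_posts <- vector("list", cfg$n_authors)
  all_labels <- vector("list", cfg$n_authors)
  authors <- vector("list", cfg$n_authors)

  for (i in seq_len(cfg$n_authors)) {
    with_seed(derive_seed(cfg$seed, "author", i), {
      author <- sprintf("author%06d", i)
      n_posts <- if (runif(1) < cfg$single_post_author_fraction) 1L else
        2L + rgeom(1, cfg$multi_post_geom_prob)
      flair <- if (runif(1) < cfg$flair_present_rate) {
        sample_flair_days(1L, cfg$flair_decay_rate, cfg$milestone_days,
                          cfg$milestone_boost)
      } else NA_integer_
      offset <- sample(offsets, 1L)
      craving <- runif(n_posts) < cfg$craving_rate
      ctx_pos <- categories[runif(length(categories)) < cfg$context_rates]
      ctx_post <- if (length(ctx_pos) > 0L) {
        sample.int(n_posts, length(ctx_pos), replace = TRUE)
      } else integer(0)

      hours <- sample(0:23, n_posts, replace = TRUE, prob = hour_w)
      local_epoch <- base_utc + (sample.int(n_days, n_posts, replace = TRUE) - 1L) * 86400 +
        hours * 3600 + floor(runif(n_posts) * 3600)
      created_utc <- local_epoch - offset * 60

      titles <- character(n_posts)
      bodies <- character(n_posts)
      thetas <- vector("list", n_posts)
      ctx_sets <- vector("list", n_posts)
      for (p in seq_len(n_posts)) {
        len <- max(20L, rpois(1, cfg$mean_post_words))
        theta <- stats::rgamma(K, cfg$doc_topic_concentration)
        theta <- theta / sum(theta)
        words <- sample_filler(len, theta, phi, vocab)
        inject <- character(0)
        ctx_here <- ctx_pos[ctx_post == p]
        if (craving[p]) {
          term <- sample(cfg$craving_terms, 1L)
          inject <- c(inject, inflect_term(term, cfg$inflection_probs))
        }
        for (cc in ctx_here) {
          inject <- c(inject, sample(cat_terms[[cc]], 1L))
        }
        if (length(inject) > 0L) {
          pos <- sort(sample.int(length(words) + 1L, length(inject),
                                 replace = TRUE))
          words <- append_at(words, inject, pos)
        }
        titles[p] <- paste(words[seq_len(min(3L, length(words)))], collapse = " ")
        bodies[p] <- paste(words[-seq_len(min(3L, length(words)))], collapse = " ")
        thetas[[p]] <- theta
        ctx_sets[[p]] <- sort(ctx_here)
      }
      post_ids <- sprintf("p%06d_%02d", i, seq_len(n_posts))
      flair_text <- if (is.na(flair)) NA_character_ else
        paste0(flair, if (flair == 1L) " day" else " days")
      all_posts[[i]] <- list(id = post_ids, author = rep(author, n_posts),
                             title = titles, body = bodies,
                             created_utc = created_utc,
                             utc_offset_minutes = rep(offset, n_posts),
                             flair_text = rep(flair_text, n_posts),
                             flair_days = rep(flair, n_posts))
      all_labels[[i]] <- list(post_id = post_ids,
                              author = rep(author, n_posts),
                              craving_label = craving,
                              context_labels = ctx_sets, theta = thetas)
      authors[[i]] <- list(author = author, n_posts = n_posts,
                           flair_days = flair, utc_offset_minutes = offset)
    })
  }

  cat_chr <- function(field) unlist(lapply(all_posts, `[[`, field))
  posts <- tibble(
    id = cat_chr("id"), author = cat_chr("author"),
    title = cat_chr("title"), body = cat_chr("body"),
    created_utc = as.numeric(cat_chr("created_utc")),
    utc_offset_minutes = as.integer(cat_chr("utc_offset_minutes")),
    flair_text = as.character(cat_chr("flair_text")),
    flair_days = as.integer(cat_chr("flair_days"))
  )
  post_labels <- tibble(
    post_id = unlist(lapply(all_labels, `[[`, "post_id")),
    author = unlist(lapply(all_labels, `[[`, "author")),
    craving_label = unlist(lapply(all_labels, `[[`, "craving_label")),
    context_labels = do.call(c, lapply(all_labels, `[[`, "context_labels")),
    theta = do.call(c, lapply(all_labels, `[[`, "theta"))
  )
  authors_tbl <- tibble(
    author = vapply(authors, `[[`, character(1), "author"),
    n_posts = vapply(authors, `[[`, integer(1), "n_posts"),
    flair_days = vapply(authors, `[[`, integer(1), "flair_days"),
    utc_offset_minutes = vapply(authors, `[[`, integer(1), "utc_offset_minutes")
  )
  list(
    posts = posts,
    truth = list(
      post_labels = post_labels,
      authors = authors_tbl,
      topic_word = phi
    )
  )
}

# insert values into x at (1-based, post-sorted) slot positions
append_at <- function(x, values, pos) {
  out <- character(length(x) + length(values))
  take <- rep(FALSE, length(out))
  take[pos + seq_along(pos) - 1L] <- TRUE
  out[take] <- values
  out[!take] <- x
  out
}

#' Generate a corpus from the standard LDA generative model
#'
#' Draws topic-word rows from a symmetric Dirichlet(`beta`), per-document
#' topic mixtures from Dirichlet(`alpha`), and `doc_len` tokens per
#' document, returning the bag-of-words corpus together with the true
#' matrices for recovery tests.
#'
#' @param K Number of topics (>= 2).
#' @param V Vocabulary size (> K).
#' @param D Number of documents.
#' @param doc_len Tokens per document.
#' @param alpha,beta Dirichlet concentrations.
#' @param seed Integer seed.
#' @return A list with `bow` (a `bow_corpus` whose vocabulary is the full
#'   `V` terms `w0001..`), `topic_word` (K x V, rows sum to 1) and
#'   `doc_topic` (D x K).
#' @export
generate_topic_corpus <- function(K, V, D, doc_len, alpha = 0.1, beta = 0.05,
                                  seed = 1L) {
  if (K < 2L) abort("K must be at least 2")
  if (V <= K) abort("V must exceed K")
  with_seed(derive_seed(seed, "topic-corpus"), {
    vocab <- sprintf("w%04d", seq_len(V))
    phi <- matrix(stats::rgamma(K * V, beta), nrow = K)
    phi <- phi / rowSums(phi)
    theta <- if (D > 0) {
      m <- matrix(stats::rgamma(D * K, alpha), nrow = D)
      m / rowSums(m)
    } else matrix(numeric(0), nrow = 0, ncol = K)
    doc_ids <- if (D > 0) sprintf("d%05d", seq_len(D)) else character(0)
    counts <- vector("list", D)
    for (d in seq_len(D)) {
      words <- sample_filler(doc_len, theta[d, ], phi, vocab)
      tab <- table(words)
      counts[[d]] <- tibble(post_id = doc_ids[d], term = names(tab),
                            count = as.integer(tab))
    }
    counts <- if (D > 0) dplyr::bind_rows(counts) else
      tibble(post_id = character(0), term = character(0), count = integer(0))
    corpus_freq <- integer(V)
    names(corpus_freq) <- vocab
    if (nrow(counts) > 0) {
      agg <- tapply(counts$count, counts$term, sum)
      corpus_freq[names(agg)] <- as.integer(agg)
    }
    doc_freq <- integer(V)
    names(doc_freq) <- vocab
    if (nrow(counts) > 0) {
      dfr <- table(counts$term)
      doc_freq[names(dfr)] <- as.integer(dfr)
    }
    vocab_tbl <- tibble(index = seq_len(V), term = vocab,
                        doc_freq = unname(doc_freq),
                        corpus_freq = unname(corpus_freq))
    counts$index <- match(counts$term, vocab)
    bow <- structure(
      list(vocab = vocab_tbl,
           counts = counts[, c("post_id", "term", "index", "count")],
           doc_ids = doc_ids,
           n_tokens = sum(counts$count)),
      class = "bow_corpus"
    )
    list(bow = bow, topic_word = phi, doc_topic = theta)
  })
}

#' Generate a corpus with a planted interchangeable-context pair
#'
#' Builds short themed sentences (each sentence draws its words from one
#' of `n_themes` disjoint theme vocabularies, with a power-law tilt
#' within the theme) and inserts one of the two `pair` tokens, chosen at
#' random, into every sentence. The two planted tokens are therefore
#' used interchangeably in identical contexts, while ordinary word pairs
#' are mostly cross-theme: an embedding that respects the distributional
#' hypothesis must score the planted pair far above random pairs.
#'
#' @param n_sentences Number of sentences.
#' @param n_themes Number of disjoint theme vocabularies.
#' @param words_per_theme Words per theme.
#' @param sentence_len Theme words per sentence.
#' @param pair The two interchangeable tokens.
#' @param seed Integer seed.
#' @return A long token tibble `(post_id, token)` for
#'   [train_embeddings()].
#' @export
generate_synonym_corpus <- function(n_sentences = 4000, n_themes = 30,
                                    words_per_theme = 12, sentence_len = 8,
                                    pair = c("syna", "synb"), seed = 1L) {
  stopifnot(length(pair) == 2)
  with_seed(derive_seed(seed, "synonym-corpus"), {
    themes <- lapply(seq_len(n_themes), function(t) {
      sprintf("t%02dw%02d", t, seq_len(words_per_theme))
    })
    wprob <- (1 / seq_len(words_per_theme))^0.8
    docs <- lapply(seq_len(n_sentences), function(i) {
      th <- sample(n_themes, 1)
      w <- sample(themes[[th]], sentence_len, replace = TRUE, prob = wprob)
      x <- sample(pair, 1)
      append(w, x, after = sample(sentence_len + 1, 1) - 1L)
    })
    tibble(post_id = rep(sprintf("d%05d", seq_len(n_sentences)),
                         each = sentence_len + 1L),
           token = unlist(docs))
  })
}

#' Sample a labelled test set from a synthetic corpus
#'
#' Uniformly samples `n` posts without replacement and copies their
#' ground-truth labels, mirroring how labelled evaluation sets are drawn
#' from a corpus.
#'
#' @param posts Posts tibble from [generate_corpus()].
#' @param truth Matching `truth` list from [generate_corpus()].
#' @param n Sample size (must not exceed the corpus size).
#' @param seed Integer seed.
#' @return A labels tibble (`post_id`, `craving_label`, `context_labels`)
#'   compatible with [read_labels()]/[write_labels()].
#' @export
generate_labeled_testset <- function(posts, truth, n, seed = 1L) {
  if (n > nrow(posts)) {
    abort("n exceeds the corpus size")
  }
  with_seed(derive_seed(seed, "testset"), {
    ids <- sample(posts$id, n, replace = FALSE)
  })
  labels <- truth$post_labels[match(ids, truth$post_labels$post_id), ]
  tibble(post_id = labels$post_id,
         craving_label = labels$craving_label,
         context_labels = labels$context_labels)
}
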