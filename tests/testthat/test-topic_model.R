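small_bow <- function(seed = 5) {
  generate_topic_corpus(K = 3, V = 40, D = 60, doc_len = 25, seed = seed)$bow
}

test_that("the sampler conserves token counts and normalises estimates", {
  bow <- small_bow()
  fit <- lda_fit(bow, K = 3, iterations = 60, burn_in = 30, seed = 2)
  # topic-word counts reconstruct the corpus counts of every word
  corpus_counts <- integer(nrow(bow$vocab))
  agg <- tapply(bow$counts$count, bow$counts$index, sum)
  corpus_counts[as.integer(names(agg))] <- agg
  expect_equal(unname(colSums(fit$nkw)), corpus_counts)
  # assignments cover every token
  expect_equal(sum(lengths(fit$assignments)), bow$n_tokens)
  expect_equal(rowSums(fit$phi), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$theta)), rep(1, length(bow$doc_ids)),
               tolerance = 1e-9)
})

test_that("fitting is deterministic given the seed", {
  bow <- small_bow()
  f1 <- lda_fit(bow, K = 3, iterations = 40, burn_in = 20, seed = 7)
  f2 <- lda_fit(bow, K = 3, iterations = 40, burn_in = 20, seed = 7)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$phi, f2$phi)
})

test_that("empty documents get a uniform mixture; empty corpora are fatal", {
  tok <- tibble::tibble(post_id = c("d1", "d1", "d2"),
                        token = c("aa", "bb", "aa"))
  bow <- build_bow(tok, min_count = 1, doc_ids = c("d1", "d2", "d3"))
  fit <- lda_fit(bow, K = 2, iterations = 30, burn_in = 10, seed = 1)
  expect_equal(unname(fit$theta["d3", ]), c(0.5, 0.5))
  empty <- build_bow(tok, min_count = 1, doc_ids = "d9")
  expect_error(lda_fit(empty, K = 2), "empty corpus")
  expect_error(lda_fit(bow, K = 1), "at least 2")
  expect_error(lda_fit(bow, K = 2, iterations = 10, burn_in = 10), "burn_in")
})

test_that("a single-theme corpus is recovered even when K is too large", {
  set.seed(3)
  V <- 50
  # ten clearly dominant words, the rest a flat low-probability tail
  phi0 <- c(rep(0.06, 10), rep(0.4 / 40, 40))
  vocab <- sprintf("w%04d", seq_len(V))
  tok <- tibble::tibble(
    post_id = rep(sprintf("d%03d", 1:80), each = 40),
    token = vocab[sample.int(V, 80 * 40, replace = TRUE, prob = phi0)])
  bow <- build_bow(tok, min_count = 1)
  # strong word-level smoothing: without it the surplus topic is free to
  # carve the vocabulary into an arbitrary bipartition (a likelihood-
  # equivalent solution on unigram data) instead of duplicating the theme
  fit <- lda_fit(bow, K = 2, iterations = 150, burn_in = 100, beta = 1,
                 seed = 3)
  true_top10 <- vocab[order(-phi0)][1:10]
  overlap <- vapply(1:2, function(k) {
    terms <- colnames(fit$phi)
    got <- terms[order(-fit$phi[k, ], terms)][1:10]
    length(intersect(got, true_top10))
  }, numeric(1))
  expect_gte(max(overlap), 9)
})

test_that("fitted topics recover the generating topic-word rows", {
  sim <- generate_topic_corpus(K = 5, V = 200, D = 1000, doc_len = 80,
                               seed = 41)
  fit <- lda_fit(sim$bow, K = 5, iterations = 400, burn_in = 250, seed = 41)
  expect_gte(greedy_match_cosine(fit$phi, sim$topic_word), 0.80)
})

test_that("perplexity has its closed form on a uniform model", {
  bow <- small_bow()
  fit <- lda_fit(bow, K = 2, iterations = 30, burn_in = 10, seed = 1)
  fit$phi[] <- 1 / ncol(fit$phi)
  expect_equal(as.numeric(lda_perplexity(fit, bow)), ncol(fit$phi),
               tolerance = 1e-9)
  expect_equal(as.numeric(lda_perplexity(fit, bow, completion = TRUE)),
               ncol(fit$phi), tolerance = 1e-9)
})

test_that("training documents score better than word-scrambled ones", {
  sim <- generate_topic_corpus(K = 4, V = 80, D = 300, doc_len = 50, seed = 13)
  fit <- lda_fit(sim$bow, K = 4, iterations = 200, burn_in = 120, seed = 13)
  real <- as.numeric(lda_perplexity(fit, sim$bow, seed = 5))
  # permute tokens across documents: same unigram mass, no co-occurrence
  counts <- sim$bow$counts
  tokens <- rep(counts$term, counts$count)
  set.seed(44)
  tokens <- sample(tokens)
  doc_id <- rep(sim$bow$doc_ids, each = 50)
  scrambled <- build_bow(tibble::tibble(post_id = doc_id, token = tokens),
                         min_count = 1, doc_ids = sim$bow$doc_ids)
  fake <- as.numeric(lda_perplexity(fit, scrambled, seed = 5))
  expect_lt(real, fake)
})

test_that("OOV held-out words are dropped and counted", {
  bow <- small_bow()
  fit <- lda_fit(bow, K = 3, iterations = 40, burn_in = 20, seed = 2)
  held <- build_bow(tibble::tibble(post_id = c("h1", "h1", "h1"),
                                   token = c(bow$vocab$term[1],
                                             bow$vocab$term[2], "unseenword")),
                    min_count = 1)
  p <- lda_perplexity(fit, held)
  expect_equal(attr(p, "n_oov_dropped"), 1L)
  expect_true(is.finite(p) && p > 0)
})

test_that("NPMI matches a brute-force counting oracle on a 4-document corpus", {
  # documents: {a b}, {a b c}, {c d}, {a d}
  tok <- tibble::tibble(
    post_id = c("d1", "d1", "d2", "d2", "d2", "d3", "d3", "d4", "d4"),
    token = c("a", "b", "a", "b", "c", "c", "d", "a", "d"))
  bow <- build_bow(tok, min_count = 1)
  eps <- 1e-12
  # independent oracle: explicit document counting
  oracle_pair <- function(di, dj) {
    pi <- di / 4; pj <- dj[1] / 4; pij <- dj[2] / 4
    log((pij + eps) / ((pi + eps) * (pj + eps))) / (-log(pij + eps))
  }
  # doc freqs: a in d1,d2,d4 (3); b in d1,d2 (2); ab together in d1,d2 (2)
  expected_ab <- oracle_pair(3, c(2, 2))
  expect_equal(as.numeric(npmi_coherence(bow, c("a", "b"), eps)), expected_ab,
               tolerance = 1e-9)
  # full three-word list: mean over pairs ab, ac, bc
  expected_ac <- oracle_pair(3, c(2, 1))  # c in d2,d3; ac together in d2
  expected_bc <- oracle_pair(2, c(2, 1))  # bc together in d2
  expect_equal(as.numeric(npmi_coherence(bow, c("a", "b", "c"), eps)),
               mean(c(expected_ab, expected_ac, expected_bc)),
               tolerance = 1e-9)
})

test_that("NPMI hits its analytic anchor points", {
  # always co-occurring pair -> exactly 1
  tok <- tibble::tibble(post_id = rep(c("d1", "d2", "d3"), each = 2),
                        token = rep(c("x", "y"), 3))
  bow <- build_bow(tok, min_count = 1)
  expect_equal(as.numeric(npmi_coherence(bow, c("x", "y"))), 1)

  # exact independence on a 4-document grid -> 0
  tok2 <- tibble::tibble(
    post_id = c("d1", "d1", "d2", "d3", "d4"),
    token = c("x", "y", "x", "y", "filler"))
  bow2 <- build_bow(tok2, min_count = 1)
  # p(x) = p(y) = 1/2, p(xy) = 1/4 = p(x) p(y)
  expect_lt(abs(as.numeric(npmi_coherence(bow2, c("x", "y")))), 1e-9)

  # never co-occurring -> close to -1
  tok3 <- tibble::tibble(post_id = c("d1", "d2", "d3", "d4"),
                         token = c("x", "x", "y", "y"))
  bow3 <- build_bow(tok3, min_count = 1)
  expect_lt(as.numeric(npmi_coherence(bow3, c("x", "y"))), -0.9)

  # absent words skip their pairs
  val <- npmi_coherence(bow3, c("x", "y", "ghost"))
  expect_equal(attr(val, "n_skipped_pairs"), 2L)
})

test_that("topic summaries partition the vocabulary and sort by coherence", {
  bow <- small_bow()
  fit <- lda_fit(bow, K = 3, iterations = 80, burn_in = 40, seed = 6)
  summ <- lda_summarize(fit, bow, top_n = 12)
  expect_equal(sum(summ$word_share_pct), 100, tolerance = 0.01)
  expect_true(all(lengths(summ$top_words) == 12))
  expect_true(all(diff(summ$coherence) <= 1e-12))
  expect_setequal(summ$topic, 1:3)
})

test_that("relabelling topics leaves perplexity and coherences invariant", {
  bow <- small_bow()
  fit <- lda_fit(bow, K = 3, iterations = 80, burn_in = 40, seed = 6)
  perm <- c(3, 1, 2)
  swapped <- fit
  swapped$phi <- fit$phi[perm, ]
  swapped$theta <- fit$theta[, perm]
  expect_equal(as.numeric(lda_perplexity(swapped, bow, seed = 3)),
               as.numeric(lda_perplexity(fit, bow, seed = 3)),
               tolerance = 0.02)
  s1 <- lda_summarize(fit, bow)
  s2 <- lda_summarize(swapped, bow)
  expect_equal(sort(s1$coherence), sort(s2$coherence), tolerance = 1e-12)
  expect_equal(sort(s1$word_share_pct), sort(s2$word_share_pct))
})

test_that("model selection prefers the generating number of topics", {
  sim <- generate_topic_corpus(K = 5, V = 200, D = 1000, doc_len = 80,
                               seed = 3)
  res <- lda_select_k(sim$bow, ks = c(2, 5, 10), iterations = 300,
                      burn_in = 200, seed = 3)
  expect_equal(attr(res, "best_k"), 5)
  expect_equal(res$K, c(2, 5, 10))
  expect_true(all(res$perplexity > 0))
})
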