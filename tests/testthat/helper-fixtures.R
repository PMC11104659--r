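# Shared fixtures and small oracles, built in code at test time.

# minimal posts tibble
make_posts <- function(ids, bodies, authors = paste0("u", seq_along(ids)),
                       titles = rep("", length(ids)),
                       created_utc = seq_along(ids),
                       offsets = rep(NA_integer_, length(ids)),
                       flair = rep(NA_integer_, length(ids))) {
  tibble::tibble(id = ids, author = authors, title = titles, body = bodies,
                 created_utc = created_utc, utc_offset_minutes = offsets,
                 flair_text = ifelse(is.na(flair), NA_character_,
                                     paste0(flair, " days")),
                 flair_days = flair)
}

# one medium synthetic corpus reused across files (built once per run)
.fixture_cache <- new.env(parent = emptyenv())

corpus_5000 <- function() {
  if (is.null(.fixture_cache$corpus_5000)) {
    .fixture_cache$corpus_5000 <-
      generate_corpus(corpus_config(seed = 20240501, n_authors = 5000))
  }
  .fixture_cache$corpus_5000
}

corpus_small <- function() {
  if (is.null(.fixture_cache$corpus_small)) {
    .fixture_cache$corpus_small <-
      generate_corpus(corpus_config(seed = 77, n_authors = 250))
  }
  .fixture_cache$corpus_small
}

# greedy one-to-one matching of fitted to true topic rows by cosine
greedy_match_cosine <- function(fitted, truth) {
  normalize <- function(m) m / sqrt(rowSums(m^2))
  M <- normalize(fitted) %*% t(normalize(truth))
  K <- nrow(M)
  used <- integer(0)
  total <- 0
  for (i in seq_len(K)) {
    avail <- setdiff(seq_len(K), used)
    j <- avail[which.max(M[i, avail])]
    total <- total + M[i, j]
    used <- c(used, j)
  }
  total / K
}

# exact binomial central interval for a proportion
binom_interval99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}

# craving-filter predictions for a posts tibble under the seed pattern
seed_pattern_predictions <- function(posts) {
  pat <- compile_pattern(lexicon("craving", craving_seed_terms()))
  tibble::tibble(post_id = posts$id,
                 predicted = pattern_matches(pat, paste(posts$title, posts$body)))
}
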