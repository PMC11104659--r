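#' The craving seed synonyms
#'
#' The six-term seed lexicon for craving mentions: craving, trigger,
#' relapse, urge, desire, temptation.
#'
#' @return Character vector of seed terms.
#' @export
craving_seed_terms <- function() {
  readr::read_csv(cm_extdata("craving_seeds.csv"),
                  col_types = readr::cols(.default = readr::col_character()))$term
}

#' Construct a lexicon
#'
#' A lexicon is a named term list for one concept, split into curated
#' seed terms and terms added by embedding expansion.
#'
#' @param name Lexicon name.
#' @param seed_terms Character vector of seed terms.
#' @param expanded_terms Terms added by expansion (default none).
#' @param curated Whether the expansion was intersected with a manual
#'   allowlist.
#' @return A `lexicon` object.
#' @export
lexicon <- function(name, seed_terms, expanded_terms = character(),
                    curated = FALSE) {
  seed_terms <- unique(tolower(seed_terms))
  expanded_terms <- setdiff(unique(tolower(expanded_terms)), seed_terms)
  structure(list(name = name, seed_terms = seed_terms,
                 expanded_terms = expanded_terms, curated = curated),
            class = "lexicon")
}

#' @rdname lexicon
#' @param x A `lexicon`.
#' @export
lexicon_terms <- function(x) {
  c(x$seed_terms, x$expanded_terms)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon '", x$name, "'> ", length(x$seed_terms), " seeds + ",
      length(x$expanded_terms), " expanded",
      if (x$curated) " (curated)", "\n", sep = "")
  invisible(x)
}

#' Expand a seed lexicon with embedding neighbours
#'
#' For each in-vocabulary seed, adds its top-`k` cosine neighbours with
#' score at least `min_score`. When an `allowlist` is supplied (manual
#' curation), only expansion terms on the list survive.
#' Out-of-vocabulary seeds are kept but flagged with a warning; if every
#' seed is out of vocabulary the expansion is an error.
#'
#' @param model A `word_embedding` from [train_embeddings()].
#' @param seeds Seed terms (default [craving_seed_terms()]).
#' @param k Neighbours per seed (default 10); `k = 0` returns the seeds.
#' @param min_score Minimum cosine for an expansion term (default 0.35).
#' @param allowlist Optional character vector of permitted expansion
#'   terms.
#' @param name Lexicon name (default `"craving"`).
#' @return A `lexicon`.
#' @export
expand_lexicon <- function(model, seeds = craving_seed_terms(), k = 10,
                           min_score = 0.35, allowlist = NULL,
                           name = "craving") {
  seeds <- tolower(seeds)
  in_vocab <- seeds %in% model$vocab$term
  if (!any(in_vocab)) {
    abort("all seed terms are out of the embedding vocabulary")
  }
  if (any(!in_vocab)) {
    warn(paste0("seed term(s) out of vocabulary, kept unexpanded: ",
                paste(seeds[!in_vocab], collapse = ", ")))
  }
  expanded <- character(0)
  if (k >= 1) {
    for (s in seeds[in_vocab]) {
      nb <- most_similar(model, s, k)
      expanded <- c(expanded, nb$term[nb$score >= min_score])
    }
  }
  expanded <- setdiff(unique(expanded), seeds)
  curated <- !is.null(allowlist)
  if (curated) {
    expanded <- intersect(expanded, tolower(allowlist))
  }
  lexicon(name, seeds, expanded, curated = curated)
}

# Word-form subpattern for one stem: optional morphological prefix,
# optional final-consonant doubling, optional inflectional suffix, and an
# e-drop alternative for stems ending in -e ("urge" -> "urging").
# Matching is bounded by non-alphanumerics, so hyphen-compound components
# ("alcohol-craving") match while mid-word substrings ("barely" vs "bar")
# do not.
affix_prefixes <- c("re", "un", "non", "anti", "pre", "de", "ex", "over", "self")
affix_suffixes <- c("ings", "ing", "ions", "ion", "ers", "er", "es", "ed", "s", "d")

term_subpattern <- function(term) {
  esc <- function(x) gsub("([^a-z0-9 _])", "\\\\\\1", x)
  core <- esc(term)
  # multiword terms match as adjacent tokens
  core <- gsub("[ _]+", "[^a-z0-9]+", core)
  last <- substr(term, nchar(term), nchar(term))
  suf <- paste0("(?:", paste(affix_suffixes, collapse = "|"), ")?")
  dbl <- if (grepl("[bdfglmnprt]$", term)) paste0("(?:", esc(last), ")?") else ""
  alts <- paste0(core, dbl, suf)
  if (grepl("e$", term) && nchar(term) >= 3) {
    edrop <- esc(substr(term, 1, nchar(term) - 1))
    alts <- paste0("(?:", alts, "|", edrop,
                   "(?:ings|ing|ions|ion|ers|er|ed)", ")")
  }
  alts
}

#' Compile a lexicon into a word-form pattern
#'
#' Builds a case-insensitive regular expression that matches any token
#' whose stem is a lexicon term, optionally carrying a morphological
#' prefix (re-, un-, non-, anti-, pre-, de-, ex-, over-, self-) or
#' inflectional suffix (-s, -es, -ed, -d, -ing(s), -er(s), -ion(s), with
#' final-consonant doubling and e-drop), or appearing as a component of
#' a hyphenated compound. Matching is word-boundary aware: a stem never
#' matches as an interior substring of an unrelated word ("barely" does
#' not match "bar").
#'
#' @param x A `lexicon` (or a character vector of terms).
#' @return A `word_form_pattern` object with fields `lexicon_name`,
#'   `terms` and `regex`.
#' @export
compile_pattern <- function(x) {
  terms <- if (inherits(x, "lexicon")) lexicon_terms(x) else unique(tolower(x))
  if (length(terms) == 0L) abort("cannot compile an empty lexicon")
  prefix <- paste0("(?:", paste(affix_prefixes, collapse = "|"), ")?")
  body <- paste(vapply(terms, term_subpattern, character(1)), collapse = "|")
  rx <- paste0("(?i)(?<![a-z0-9])", prefix, "(?:", body, ")(?![a-z0-9])")
  structure(
    list(lexicon_name = if (inherits(x, "lexicon")) x$name else "terms",
         terms = terms, regex = rx),
    class = "word_form_pattern"
  )
}

#' @export
print.word_form_pattern <- function(x, ...) {
  cat("<word_form_pattern '", x$lexicon_name, "'> over ",
      length(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' Test texts against a word-form pattern
#'
#' @param pattern A `word_form_pattern` from [compile_pattern()].
#' @param text Character vector.
#' @return Logical vector: does each text contain a matching word form?
#' @export
pattern_matches <- function(pattern, text) {
  stringr::str_detect(text, pattern$regex)
}

#' Filter a corpus down to craving posts
#'
#' Retains the posts whose combined title+body matches the word-form
#' pattern, and reports the retrieval rate (the share of posts the
#' pattern retrieves).
#'
#' @param posts A posts tibble (typically from [clean_posts()]).
#' @param pattern A `word_form_pattern`.
#' @return A `filter_result` list: `posts` (the matching subset),
#'   `n_matched`, `n_total`, and `rate` (`NA` for an empty corpus,
#'   flagged as 0 of 0).
#' @export
filter_corpus <- function(posts, pattern) {
  hits <- pattern_matches(pattern, post_text(posts))
  structure(
    list(posts = posts[hits, , drop = FALSE],
         n_matched = sum(hits),
         n_total = nrow(posts),
         rate = if (nrow(posts) == 0L) NA_real_ else sum(hits) / nrow(posts)),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", x$n_matched, " of ", x$n_total, " posts retrieved",
      if (!is.na(x$rate)) paste0(" (", round_half_up(100 * x$rate, 2), "%)")
      else " (rate undefined: 0 of 0)", "\n", sep = "")
  invisible(x)
}

#' Score binary predictions against labels
#'
#' Computes the confusion matrix and accuracy, precision and recall of a
#' binary craving classifier on a labelled post set. Ratios are formed
#' from exact integer counts and rounded to four decimals; an undefined
#' ratio (empty denominator) is reported as `NA`, never as 0.
#'
#' @param predictions Tibble with columns `post_id` and `predicted`
#'   (logical), or a logical vector named by post id. Every labelled id
#'   must have a prediction; an id mismatch is an error.
#' @param labels Labels tibble (`post_id`, `craving_label`), e.g. from
#'   [read_labels()] or [generate_labeled_testset()].
#' @return A `binary_eval` object with fields `confusion`
#'   (`tp`,`fp`,`fn`,`tn`), `accuracy`, `precision`, `recall`, `n`.
#'   [tidy()] returns the confusion counts, [glance()] the metrics.
#' @export
evaluate_binary <- function(predictions, labels) {
  if (is.logical(predictions)) {
    predictions <- tibble(post_id = names(predictions), predicted = unname(predictions))
  }
  stopifnot(all(c("post_id", "predicted") %in% names(predictions)))
  idx <- match(labels$post_id, predictions$post_id)
  if (anyNA(idx)) {
    abort(paste0("no prediction for labelled post(s): ",
                 paste(head(labels$post_id[is.na(idx)], 5), collapse = ", ")))
  }
  pred <- predictions$predicted[idx]
  truth <- labels$craving_label
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  n <- length(truth)
  ratio <- function(num, den) if (den == 0L) NA_real_ else round_half_up(num / den, 4)
  structure(
    list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         accuracy = ratio(tp + tn, n),
         precision = ratio(tp, tp + fp),
         recall = ratio(tp, tp + fn),
         n = n),
    class = "binary_eval"
  )
}

#' @export
print.binary_eval <- function(x, ...) {
  cat("<binary_eval> n = ", x$n,
      " | tp ", x$confusion["tp"], ", fp ", x$confusion["fp"],
      ", fn ", x$confusion["fn"], ", tn ", x$confusion["tn"], "\n",
      "  accuracy ", x$accuracy, ", precision ", x$precision,
      ", recall ", x$recall, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.binary_eval <- function(x, ...) {
  tibble(cell = names(x$confusion), count = as.integer(x$confusion))
}

#' @export
glance.binary_eval <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy, precision = x$precision,
         recall = x$recall)
}
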