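#' Read forum posts from a JSON-Lines submissions file
#'
#' Reads one submission record per line in the Pushshift submissions
#' dialect (`id`, `author`, `title`, `selftext`, `created_utc`,
#' `author_flair_text`, optional `utc_offset_minutes`). Unparseable lines
#' are skipped and counted, not fatal; a file with zero parseable records
#' is an error.
#'
#' @param path Path to a JSON-Lines file (UTF-8, one object per line).
#' @param dialect Input dialect; only `"pushshift_jsonl"` is supported.
#' @return A tibble with one row per post and columns `id`, `author`,
#'   `title`, `body`, `created_utc`, `utc_offset_minutes`, `flair_text`
#'   and `flair_days` (parsed from the flair text, `NA` when the badge is
#'   absent or unrecognised). The number of skipped lines is stored in
#'   `attr(, "skipped")`.
#' @seealso [parse_flair_days()], [clean_posts()]
#' @export
read_posts <- function(path, dialect = "pushshift_jsonl") {
  dialect <- match.arg(dialect, "pushshift_jsonl")
  if (!file.exists(path)) {
    abort(paste0("post file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- purrr::map(lines, function(line) {
    tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE), error = function(e) NULL)
  })
  ok <- !vapply(records, is.null, logical(1))
  # a record must at least carry a non-empty id
  ok[ok] <- vapply(records[ok], function(r) {
    is.list(r) && !is.null(r$id) && nzchar(paste0(r$id))
  }, logical(1))
  skipped <- sum(!ok)
  records <- records[ok]
  if (length(records) == 0L) {
    abort(paste0("no parseable submission records in ", path,
                 " (", skipped, " line(s) skipped)"))
  }
  fld <- function(r, name, default) {
    v <- r[[name]]
    if (is.null(v) || length(v) == 0L || is.na(v)[1]) default else v[[1]]
  }
  posts <- purrr::map_dfr(records, function(r) {
    tibble(
      id = paste0(fld(r, "id", "")),
      author = paste0(fld(r, "author", "")),
      title = paste0(fld(r, "title", "")),
      body = paste0(fld(r, "selftext", "")),
      created_utc = as.numeric(fld(r, "created_utc", 0)),
      utc_offset_minutes = {
        v <- fld(r, "utc_offset_minutes", NA_integer_)
        if (is.na(v)) NA_integer_ else as.integer(v)
      },
      flair_text = {
        v <- fld(r, "author_flair_text", NA_character_)
        if (is.na(v)) NA_character_ else paste0(v)
      }
    )
  })
  posts$flair_days <- parse_flair_days(posts$flair_text)
  attr(posts, "skipped") <- skipped
  posts
}

#' Parse a sobriety badge ("author flair") into a day count
#'
#' Sobriety forums let authors wear a badge counting days since their last
#' drink. Recognised templates are `"<int> day"` / `"<int> days"` (with
#' optional thousands separators, e.g. `"14,662 days"`) and a bare
#' integer. Anything else yields `NA`.
#'
#' @param flair_text Character vector of badge texts (may contain `NA`).
#' @return Integer vector of non-negative day counts, `NA` where the
#'   badge is absent or unrecognised.
#' @examples
#' parse_flair_days(c("1 day", "14662 days", "100 days", "quitting", ""))
#' @export
parse_flair_days <- function(flair_text) {
  flair_text <- as.character(flair_text)
  m <- stringr::str_match(
    flair_text,
    "^\\s*([0-9][0-9,]*)\\s*(?:days?\\b.*)?$"
  )
  days <- suppressWarnings(as.integer(gsub(",", "", m[, 2])))
  days[is.na(flair_text) | !nzchar(trimws(flair_text))] <- NA_integer_
  days
}

#' Remove deleted and too-short posts
#'
#' Drops posts whose body is a deletion sentinel (`"[deleted]"` or
#' `"[removed]"`, case-insensitive) and posts whose combined title+body
#' text is shorter than `min_chars` characters. Counts of removals per
#' rule are kept as provenance.
#'
#' @param posts A posts tibble as returned by [read_posts()].
#' @param min_chars Minimum combined character length (default 60).
#' @return The surviving posts, with `attr(, "provenance")` holding a
#'   named integer vector `c(deleted=, short=, kept=)`. Retrieve it with
#'   [cleaning_provenance()].
#' @export
clean_posts <- function(posts, min_chars = 60) {
  sentinels <- c("[deleted]", "[removed]")
  body_norm <- tolower(trimws(posts$body))
  is_deleted <- body_norm %in% sentinels
  combined <- post_text(posts)
  is_short <- !is_deleted & nchar(combined) < min_chars
  kept <- posts[!is_deleted & !is_short, , drop = FALSE]
  attr(kept, "provenance") <- c(
    deleted = sum(is_deleted),
    short = sum(is_short),
    kept = nrow(kept)
  )
  attr(kept, "skipped") <- attr(posts, "skipped")
  kept
}

#' @rdname clean_posts
#' @export
cleaning_provenance <- function(posts) {
  attr(posts, "provenance") %||%
    c(deleted = NA_integer_, short = NA_integer_, kept = nrow(posts))
}

# Combined analysis text of a post: title and body joined by one space.
post_text <- function(posts) {
  trimws(paste(posts$title, posts$body))
}

#' Default English stopword list
#'
#' A fixed ~180-term list shipped with the package so preprocessing is
#' reproducible across installations.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  lines <- readLines(cm_extdata("stopwords_en.txt"), warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Default lemmatiser rule table
#'
#' A deterministic suffix-stripping table (plural `-s`/`-es`/`-ies`,
#' `-ing` and `-ed` with consonant-doubling undo). Rules are regular
#' expressions tried in order; the first match is applied once per token.
#'
#' @return A tibble with columns `pattern` and `replacement`.
#' @export
default_lemma_rules <- function() {
  readr::read_csv(cm_extdata("lemma_rules.csv"),
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Lemmatise tokens with a rule table
#'
#' @param tokens Character vector of lowercase tokens.
#' @param rules Rule table from [default_lemma_rules()] (or a compatible
#'   tibble with `pattern`/`replacement` columns).
#' @return Character vector of lemmas, same length as `tokens`.
#' @examples
#' lemmatize_tokens(c("cravings", "triggered", "craving", "drinking"))
#' @export
lemmatize_tokens <- function(tokens, rules = default_lemma_rules()) {
  out <- tokens
  todo <- rep(TRUE, length(tokens))
  for (i in seq_len(nrow(rules))) {
    if (!any(todo)) break
    hits <- todo & stringr::str_detect(out, rules$pattern[i])
    if (any(hits)) {
      out[hits] <- stringr::str_replace(
        out[hits], rules$pattern[i],
        gsub("\\\\([0-9])", "\\\\\\1", rules$replacement[i])
      )
      todo[hits] <- FALSE
    }
  }
  out
}

#' Tokenise, lemmatise and de-stopword posts
#'
#' Lowercases the combined title+body text, splits on non-alphanumeric
#' characters, keeps tokens of length >= 2, lemmatises with the rule
#' table and removes stopwords (checked both before and after
#' lemmatisation). Multiword lexicon terms listed in `phrases` (e.g.
#' `"living room"`) are pre-joined into single underscore tokens so
#' embedding lookups for them are well defined.
#'
#' @param posts A posts tibble (cleaned or not).
#' @param stopwords Character vector; default [default_stopwords()].
#' @param lemma_rules Rule table; default [default_lemma_rules()].
#' @param phrases Character vector of multiword terms to pre-join.
#' @return A long tibble with columns `post_id` and `token`, one row per
#'   retained token, in document order. Posts whose tokens are all
#'   removed contribute no rows.
#' @export
tokenize_posts <- function(posts,
                           stopwords = default_stopwords(),
                           lemma_rules = default_lemma_rules(),
                           phrases = character()) {
  text <- stringr::str_to_lower(post_text(posts))
  for (ph in phrases) {
    ph <- stringr::str_to_lower(ph)
    joined <- gsub("[^a-z0-9]+", "_", ph)
    text <- stringr::str_replace_all(text, stringr::fixed(ph), joined)
  }
  token_lists <- stringr::str_split(text, "[^a-z0-9_]+")
  docs <- tibble(post_id = posts$id, token = token_lists)
  docs <- tidyr::unnest(docs, "token")
  docs <- docs[nchar(docs$token) >= 2, , drop = FALSE]
  docs <- docs[!docs$token %in% stopwords, , drop = FALSE]
  docs$token <- lemmatize_tokens(docs$token, lemma_rules)
  docs <- docs[!docs$token %in% stopwords, , drop = FALSE]
  docs
}

#' Build a bag-of-words corpus
#'
#' Builds a term-index vocabulary over tokens with corpus frequency at
#' least `min_count` and per-document sparse counts over the retained
#' terms.
#'
#' @param tokens Long tibble `(post_id, token)` from [tokenize_posts()],
#'   or any tibble with those columns.
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary (default 2).
#' @param doc_ids Optional character vector fixing the document set and
#'   order (documents emptied by filtering are kept as empty documents).
#' @return A `bow_corpus` object: a list with `vocab` (tibble `index`,
#'   `term`, `doc_freq`, `corpus_freq`; indices are the contiguous range
#'   `1..V`), `counts` (tibble `post_id`, `term`, `index`, `count`),
#'   `doc_ids`, and `n_tokens` (total retained token mass).
#' @export
build_bow <- function(tokens, min_count = 2, doc_ids = NULL) {
  stopifnot(all(c("post_id", "token") %in% names(tokens)))
  doc_ids <- doc_ids %||% unique(tokens$post_id)
  term_freq <- table(tokens$token)
  keep <- names(term_freq)[term_freq >= min_count]
  if (length(keep) == 0L) {
    abort("empty vocabulary: no term reaches min_count")
  }
  tokens <- tokens[tokens$token %in% keep, , drop = FALSE]
  counts <- dplyr::count(tokens, .data$post_id, .data$token, name = "count")
  names(counts)[names(counts) == "token"] <- "term"
  vocab <- tibble(
    term = sort(keep),
    index = seq_along(keep),
    corpus_freq = as.integer(term_freq[sort(keep)])
  )
  doc_freq <- dplyr::count(dplyr::distinct(counts, .data$post_id, .data$term),
                           .data$term, name = "doc_freq")
  vocab <- dplyr::left_join(vocab, doc_freq, by = "term")
  vocab$doc_freq[is.na(vocab$doc_freq)] <- 0L
  counts$index <- vocab$index[match(counts$term, vocab$term)]
  counts <- counts[order(match(counts$post_id, doc_ids), counts$index), ]
  structure(
    list(
      vocab = vocab[, c("index", "term", "doc_freq", "corpus_freq")],
      counts = as_tibble(counts[, c("post_id", "term", "index", "count")]),
      doc_ids = doc_ids,
      n_tokens = sum(counts$count)
    ),
    class = "bow_corpus"
  )
}

#' @export
print.bow_corpus <- function(x, ...) {
  cat("<bow_corpus> ", length(x$doc_ids), " documents, ",
      nrow(x$vocab), " terms, ", x$n_tokens, " tokens\n", sep = "")
  invisible(x)
}

# expand a bow_corpus into a list of integer token vectors (0-based term
# indices, counts unrolled) in doc_ids order -- the sampler input format
bow_token_lists <- function(bow) {
  split_counts <- split(bow$counts, factor(bow$counts$post_id, levels = bow$doc_ids))
  lapply(split_counts, function(d) {
    if (nrow(d) == 0L) return(integer(0))
    rep(d$index - 1L, d$count)
  })
}

#' Read or write labelled test-set posts
#'
#' Labelled test sets are CSV files with columns `post_id`,
#' `craving_label` (0/1 or TRUE/FALSE) and `context_labels`
#' (semicolon-joined category names, empty for none). Category names are
#' validated against a context registry; an unknown name is an error.
#'
#' @param path CSV file path.
#' @param registry Context registry tibble (default
#'   [default_context_registry()]); used to validate category names.
#' @return `read_labels()`: a tibble with columns `post_id`,
#'   `craving_label` (logical) and `context_labels` (list column of
#'   character vectors).
#' @export
read_labels <- function(path, registry = default_context_registry()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    post_id = readr::col_character(),
    craving_label = readr::col_logical(),
    context_labels = readr::col_character()
  ))
  df$context_labels[is.na(df$context_labels)] <- ""
  labels <- stringr::str_split(df$context_labels, ";")
  labels <- lapply(labels, function(x) x[nzchar(x)])
  known <- unique(registry$category)
  bad <- setdiff(unique(unlist(labels)), known)
  if (length(bad) > 0L) {
    abort(paste0("unregistered context categories in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  tibble(post_id = df$post_id,
         craving_label = df$craving_label,
         context_labels = labels)
}

#' @rdname read_labels
#' @param labels A labels tibble as returned by [read_labels()] (or
#'   [generate_labeled_testset()]).
#' @export
write_labels <- function(labels, path) {
  out <- tibble(
    post_id = labels$post_id,
    craving_label = labels$craving_label,
    context_labels = vapply(labels$context_labels, paste, collapse = ";",
                            FUN.VALUE = character(1))
  )
  readr::write_csv(out, path)
  invisible(path)
}
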