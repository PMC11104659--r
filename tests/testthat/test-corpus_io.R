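test_that("read_posts parses a submissions file, skipping malformed lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a1","author":"u1","title":"T","selftext":"hello world","created_utc":1600000000}',
    'this is not json {{{',
    '{"id":"a2","author":"u2","title":"","selftext":"more text","created_utc":1600000500,"author_flair_text":"100 days"}'
  ), path)
  posts <- read_posts(path)
  expect_equal(nrow(posts), 2L)
  expect_equal(attr(posts, "skipped"), 1L)
  expect_equal(posts$flair_days, c(NA_integer_, 100L))
  expect_equal(posts$body[1], "hello world")
})

test_that("read_posts fails on missing or empty files", {
  expect_error(read_posts(file.path(tempdir(), "no-such-file.jsonl")),
               "not found")
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), path)
  expect_error(read_posts(path), "no parseable")
})

test_that("flair badges parse to day counts", {
  expect_equal(parse_flair_days("14662 days"), 14662L)
  expect_equal(parse_flair_days("14,662 days"), 14662L)
  expect_equal(parse_flair_days("1 day"), 1L)
  expect_equal(parse_flair_days("250"), 250L)
  expect_equal(parse_flair_days(""), NA_integer_)
  expect_equal(parse_flair_days("quitting again"), NA_integer_)
  expect_equal(parse_flair_days(NA), NA_integer_)
})

test_that("cleaning removes deleted bodies and short posts, with provenance", {
  long60 <- strrep("x", 60)
  posts <- make_posts(
    ids = c("p1", "p2", "p3", "p4"),
    bodies = c("[deleted]", strrep("y", 59), long60, "[Removed]")
  )
  cleaned <- clean_posts(posts)
  prov <- cleaning_provenance(cleaned)
  expect_equal(cleaned$id, "p3")
  expect_equal(unname(prov[c("deleted", "short", "kept")]), c(2L, 1L, 1L))
})

test_that("the 60-character rule counts combined title+body text", {
  # title "abcd" + space + 55 body chars = 60 -> kept
  posts <- make_posts(c("k", "d"), bodies = c(strrep("b", 55), strrep("b", 54)),
                      titles = c("abcd", "abcd"))
  cleaned <- clean_posts(posts)
  expect_equal(cleaned$id, "k")
})

test_that("cleaning is idempotent and tolerates empty input", {
  corp <- corpus_small()
  once <- clean_posts(corp$posts)
  twice <- clean_posts(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  empty <- clean_posts(make_posts(character(0), character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("preprocessing lowercases, strips punctuation, lemmatises, de-stopwords", {
  posts <- make_posts(c("p1", "p2", "p3"),
                      bodies = c("Craving!!", "the and a", "cravings triggered"))
  tok <- tokenize_posts(posts)
  expect_equal(tok$token[tok$post_id == "p1"], "craving")
  expect_equal(sum(tok$post_id == "p2"), 0L)
  expect_equal(tok$token[tok$post_id == "p3"], c("craving", "trigger"))
})

test_that("tokens never contain uppercase, punctuation or stopwords", {
  corp <- corpus_small()
  tok <- tokenize_posts(clean_posts(corp$posts))
  expect_gt(nrow(tok), 0)
  expect_false(any(grepl("[^a-z0-9_]", tok$token)))
  expect_false(any(tok$token %in% default_stopwords()))
  expect_true(all(nchar(tok$token) >= 2))
})

test_that("suffix rules lemmatise as documented", {
  expect_equal(
    lemmatize_tokens(c("parties", "wishes", "classes", "drinking", "quitting",
                       "stopped", "triggered", "craving", "tired", "stress")),
    c("party", "wish", "class", "drink", "quit",
      "stop", "trigger", "craving", "tired", "stress"))
})

test_that("bag-of-words counts and vocabulary behave", {
  tok <- tibble::tibble(post_id = c("d1", "d1", "d1"),
                        token = c("aa", "bb", "aa"))
  bow <- build_bow(tok, min_count = 1)
  expect_equal(bow$counts$count[bow$counts$term == "aa"], 2L)
  expect_equal(bow$counts$count[bow$counts$term == "bb"], 1L)
  # below min_count the term leaves the vocabulary
  bow2 <- build_bow(tok, min_count = 2)
  expect_false("bb" %in% bow2$vocab$term)
  expect_error(build_bow(tok, min_count = 10), "empty vocabulary")
})

test_that("vocabulary indices form a bijection and BOW mass is conserved", {
  corp <- corpus_small()
  tok <- tokenize_posts(clean_posts(corp$posts))
  bow <- build_bow(tok, min_count = 2)
  expect_equal(sort(bow$vocab$index), seq_len(nrow(bow$vocab)))
  expect_equal(anyDuplicated(bow$vocab$term), 0L)
  # direct recount oracle: total mass = retained tokens
  retained <- sum(tok$token %in% bow$vocab$term)
  expect_equal(bow$n_tokens, retained)
  expect_equal(sum(bow$counts$count), retained)
})

test_that("labels round-trip through CSV and unknown categories are fatal", {
  corp <- corpus_small()
  labels <- generate_labeled_testset(corp$posts, corp$truth, n = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(labels, path)
  back <- read_labels(path)
  expect_equal(back$post_id, labels$post_id)
  expect_equal(back$craving_label, labels$craving_label)
  expect_equal(back$context_labels, labels$context_labels)

  bad <- labels
  bad$context_labels[[1]] <- c("casino")
  write_labels(bad, path)
  expect_error(read_labels(path), "casino")

  ok <- labels
  ok$context_labels[[1]] <- c("airport")
  write_labels(ok, path)
  expect_silent(read_labels(path))
})

test_that("posts round-trip through the JSON-Lines dialect", {
  corp <- corpus_small()
  posts <- head(corp$posts, 20)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(posts, path)
  back <- read_posts(path)
  expect_equal(back$id, posts$id)
  expect_equal(back$body, posts$body)
  expect_equal(back$flair_days, posts$flair_days)
  expect_equal(back$utc_offset_minutes, posts$utc_offset_minutes)
})
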