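test_that("lexicon expansion honours k, min_score and the allowlist", {
  tok <- generate_synonym_corpus(n_sentences = 2500,
                                 pair = c("craving", "urge"), seed = 6)
  m <- train_embeddings(tok, dim = 30, window = 3, epochs = 4, min_count = 5,
                        seed = 6)
  lex0 <- expand_lexicon(m, seeds = "craving", k = 0)
  expect_equal(lexicon_terms(lex0), "craving")

  # planted-synonym recovery: the interchangeable term joins the lexicon
  lex <- expand_lexicon(m, seeds = "craving", k = 5, min_score = 0.35)
  expect_true("urge" %in% lex$expanded_terms)

  curated <- expand_lexicon(m, seeds = "craving", k = 5, min_score = 0.35,
                            allowlist = "craving")
  expect_equal(length(curated$expanded_terms), 0L)
  expect_true(curated$curated)

  expect_error(expand_lexicon(m, seeds = c("zzz", "qqq")), "out of")
  expect_warning(expand_lexicon(m, seeds = c("craving", "qqq"), k = 2),
                 "qqq")
})

test_that("word-form patterns match affixed and compound forms at boundaries", {
  pat <- compile_pattern(lexicon("craving", craving_seed_terms()))
  expect_true(pattern_matches(pat, "I have strong cravings"))
  expect_true(pattern_matches(pat, "it triggered me"))
  expect_true(pattern_matches(pat, "alcohol-craving thoughts"))
  expect_true(pattern_matches(pat, "I keep urging and relapsing"))
  expect_true(pattern_matches(pat, "CRAVING"))
  expect_true(pattern_matches(pat, "temptations everywhere"))
  expect_false(pattern_matches(pat, "a plain sentence about tea"))

  # boundary rule: a stem never matches inside an unrelated word
  bar_pat <- compile_pattern(lexicon("place", "bar"))
  expect_true(pattern_matches(bar_pat, "at the bar"))
  expect_true(pattern_matches(bar_pat, "several bars"))
  expect_false(pattern_matches(bar_pat, "barely awake"))
  expect_false(pattern_matches(bar_pat, "embarrassing"))

  expect_error(compile_pattern(lexicon("empty", character(0))), "empty")
})

test_that("every stem matches itself", {
  terms <- c(craving_seed_terms(), "bored", "home", "living room")
  for (t in terms) {
    pat <- compile_pattern(lexicon("x", t))
    expect_true(pattern_matches(pat, paste("some", t, "here")), info = t)
  }
})

test_that("filtering reports rates and degenerate corpora are flagged", {
  pat <- compile_pattern(lexicon("craving", craving_seed_terms()))
  empty <- filter_corpus(make_posts(character(0), character(0)), pat)
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$rate))

  clean <- make_posts(c("a", "b"), c("tea and toast", "quiet night"))
  none <- filter_corpus(clean, pat)
  expect_equal(none$rate, 0)

  mixed <- make_posts(c("a", "b", "c"),
                      c("craving a drink", "nothing here", "urge to go"))
  got <- filter_corpus(mixed, pat)
  expect_equal(got$n_matched, 2L)
  # idempotence: filtering the craving subset returns it unchanged
  again <- filter_corpus(got$posts, pat)
  expect_equal(as.data.frame(again$posts), as.data.frame(got$posts))
  expect_equal(again$rate, 1)
})

test_that("enlarging the lexicon never shrinks the retrieved set", {
  corp <- corpus_small()
  cl <- clean_posts(corp$posts)
  small <- compile_pattern(lexicon("craving", c("craving", "urge")))
  large <- compile_pattern(lexicon("craving", craving_seed_terms()))
  expect_lte(filter_corpus(cl, small)$n_matched,
             filter_corpus(cl, large)$n_matched)
})

test_that("binary evaluation reproduces the worked example exactly", {
  # 200 posts, 41 true positives, 29 predicted positives, 24 correct
  ids <- sprintf("t%03d", 1:200)
  labels <- tibble::tibble(post_id = ids,
                           craving_label = c(rep(TRUE, 41), rep(FALSE, 159)))
  predicted_pos <- c(ids[1:24], ids[42:46])
  preds <- tibble::tibble(post_id = ids, predicted = ids %in% predicted_pos)
  ev <- evaluate_binary(preds, labels)
  expect_equal(unname(ev$confusion), c(24L, 5L, 17L, 154L))
  expect_equal(ev$accuracy, 0.89)
  expect_equal(ev$precision, 0.8276)
  expect_equal(ev$recall, 0.5854)
  expect_equal(glance(ev)$accuracy, 0.89)
})

test_that("evaluation handles perfect, empty-positive and mismatched inputs", {
  ids <- c("a", "b", "c", "d")
  labels <- tibble::tibble(post_id = ids,
                           craving_label = c(TRUE, TRUE, FALSE, FALSE))
  perfect <- evaluate_binary(
    tibble::tibble(post_id = ids, predicted = labels$craving_label), labels)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall),
               c(1, 1, 1))

  none <- evaluate_binary(tibble::tibble(post_id = ids,
                                         predicted = rep(FALSE, 4)), labels)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  expect_error(evaluate_binary(tibble::tibble(post_id = c("a", "b"),
                                              predicted = c(TRUE, FALSE)),
                               labels), "no prediction")
})

test_that("confusion-matrix totals are conserved on synthetic labels", {
  corp <- corpus_small()
  preds <- seed_pattern_predictions(corp$posts)
  labels <- tibble::tibble(post_id = corp$truth$post_labels$post_id,
                           craving_label = corp$truth$post_labels$craving_label)
  ev <- evaluate_binary(preds, labels)
  expect_equal(sum(ev$confusion), nrow(labels))
  expect_equal(ev$confusion[["tp"]] + ev$confusion[["fn"]],
               sum(labels$craving_label))
  expect_equal(ev$confusion[["tp"]] + ev$confusion[["fp"]],
               sum(preds$predicted))
})
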