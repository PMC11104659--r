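#' Write posts in the JSON-Lines submissions dialect
#'
#' Inverse of [read_posts()]: one submission object per line with fields
#' `id`, `author`, `title`, `selftext`, `created_utc`,
#' `author_flair_text` and `utc_offset_minutes`.
#'
#' @param posts A posts tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    rec <- list(
      id = posts$id[i], author = posts$author[i], title = posts$title[i],
      selftext = posts$body[i], created_utc = posts$created_utc[i]
    )
    if (!is.null(posts$flair_text) && !is.na(posts$flair_text[i])) {
      rec$author_flair_text <- posts$flair_text[i]
    }
    if (!is.null(posts$utc_offset_minutes) && !is.na(posts$utc_offset_minutes[i])) {
      rec$utc_offset_minutes <- posts$utc_offset_minutes[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a report tibble to CSV
#'
#' List columns (e.g. top-word lists or multi-label sets) are
#' semicolon-joined so reports round-trip as plain text.
#'
#' @param report A tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- as_tibble(report)
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) paste(unlist(x), collapse = ";"),
                           character(1))
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. All keys can be
#' overridden by arguments or by a YAML file via `config_file`; an
#' unknown key is rejected before any stage runs.
#'
#' @param ... Overrides of the default keys.
#' @param config_file Optional YAML file of overrides.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  defaults <- list(
    seed = 1L,
    n_authors = 400L,
    craving_rate = 0.16,
    embed_dim = 50L,
    embed_window = 5L,
    embed_epochs = 3L,
    embed_min_count = 5L,
    lexicon_k = 10L,
    lexicon_min_score = 0.35,
    bow_min_count = 2L,
    lda_k = 10L,
    lda_iterations = 200L,
    lda_burn_in = 100L,
    topics_top_n = 12L,
    testset_n = 200L,
    context_mode = "exact_word",
    stages = c("simulate", "clean", "embed", "lexicon", "filter",
               "contexts", "temporal", "topics", "evaluate")
  )
  overrides <- list(...)
  if (!is.null(config_file)) {
    overrides <- utils::modifyList(yaml::read_yaml(config_file), overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

#' Run the full analysis pipeline on a synthetic corpus
#'
#' Wires the stages end to end: simulate a corpus with ground truth,
#' clean it, train embeddings, build and compile the craving lexicon,
#' filter craving posts, compute per-author context percentages, build
#' the temporal/badge profile with its decay fit, fit the topic model,
#' and evaluate filter and contexts on a sampled labelled test set.
#' Each stage writes its outputs as plain-text files into `out_dir`,
#' and a `manifest.json` records the seed, package version and the MD5
#' digest of every artifact, so a rerun with the same configuration is
#' byte-identical. If a stage fails, a `<stage>.failed` marker is
#' written and the error propagates.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`corpus`, `clean`, `embedding`, `lexicon`, `filter`, `contexts`,
#'   `temporal`, `decay`, `topics`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, paste0(name, ".failed")))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  stage("simulate", {
    res$corpus <- generate_corpus(corpus_config(
      seed = config$seed, n_authors = config$n_authors,
      craving_rate = config$craving_rate))
    write_posts(res$corpus$posts, file.path(out_dir, "posts.jsonl"))
    write_labels(res$corpus$truth$post_labels, file.path(out_dir, "truth_labels.csv"))
  })
  stage("clean", {
    res$clean <- clean_posts(res$corpus$posts)
    prov <- cleaning_provenance(res$clean)
    write_report(tibble(rule = names(prov), n = as.integer(prov)),
                 file.path(out_dir, "cleaning_provenance.csv"))
  })
  stage("embed", {
    tokens <- tokenize_posts(res$clean)
    res$tokens <- tokens
    res$embedding <- train_embeddings(
      tokens, dim = config$embed_dim, window = config$embed_window,
      epochs = config$embed_epochs, min_count = config$embed_min_count,
      seed = config$seed)
  })
  stage("lexicon", {
    res$lexicon <- expand_lexicon(
      res$embedding, k = config$lexicon_k,
      min_score = config$lexicon_min_score)
    write_report(tibble(category = "craving", term = lexicon_terms(res$lexicon)),
                 file.path(out_dir, "lexicon.csv"))
  })
  stage("filter", {
    pattern <- compile_pattern(res$lexicon)
    res$filter <- filter_corpus(res$clean, pattern)
    write_report(tibble(post_id = res$filter$posts$id),
                 file.path(out_dir, "craving_post_ids.csv"))
    write_report(tibble(n_matched = res$filter$n_matched,
                        n_total = res$filter$n_total,
                        rate = res$filter$rate),
                 file.path(out_dir, "retrieval.csv"))
  })
  stage("contexts", {
    docs <- group_by_author(res$filter$posts)
    res$contexts <- author_percentages(docs, mode = config$context_mode)
    write_report(res$contexts, file.path(out_dir, "context_report.csv"))
  })
  stage("temporal", {
    res$temporal <- temporal_profile(res$filter$posts)
    write_report(res$temporal$hour, file.path(out_dir, "hourly_counts.csv"))
    write_report(res$temporal$flair, file.path(out_dir, "flair_counts.csv"))
    res$decay <- tryCatch(flair_decay_fit(res$temporal), error = function(e) NULL)
    if (!is.null(res$decay)) {
      write_report(glance(res$decay), file.path(out_dir, "flair_decay.csv"))
    }
  })
  stage("topics", {
    craving_tokens <- res$tokens[res$tokens$post_id %in% res$filter$posts$id, ]
    bow <- build_bow(craving_tokens, min_count = config$bow_min_count)
    res$lda <- lda_fit(bow, K = config$lda_k,
                        iterations = config$lda_iterations,
                        burn_in = config$lda_burn_in, seed = config$seed)
    res$topics <- lda_summarize(res$lda, bow, top_n = config$topics_top_n)
    write_report(res$topics, file.path(out_dir, "topics.csv"))
  })
  stage("evaluate", {
    testset <- generate_labeled_testset(
      res$corpus$posts, res$corpus$truth,
      n = min(config$testset_n, nrow(res$corpus$posts)), seed = config$seed)
    pattern <- compile_pattern(res$lexicon)
    preds <- tibble(
      post_id = res$corpus$posts$id,
      predicted = pattern_matches(pattern, post_text(res$corpus$posts)))
    res$evaluation <- evaluate_binary(preds, testset)
    write_report(glance(res$evaluation), file.path(out_dir, "filter_eval.csv"))

    test_posts <- res$corpus$posts[match(testset$post_id, res$corpus$posts$id), ]
    ctx <- match_contexts(
      tibble(post_id = test_posts$id, text = post_text(test_posts)),
      mode = config$context_mode)
    pred_sets <- tapply(ctx$category[ctx$matched],
                        factor(ctx$post_id[ctx$matched], levels = testset$post_id),
                        function(x) sort(x), simplify = FALSE)
    predicted <- tibble(
      post_id = testset$post_id,
      context_labels = lapply(testset$post_id, function(id) {
        s <- pred_sets[[id]]
        if (is.null(s)) character(0) else as.character(s)
      }))
    res$context_eval <- evaluate_contexts(predicted, testset)
    write_report(res$context_eval, file.path(out_dir, "context_eval.csv"))
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "cravingminer",
    version = as.character(utils::packageVersion("cravingminer")),
    seed = config$seed,
    stages = config$stages,
    artifacts = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
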