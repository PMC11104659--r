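#' The default craving-context registry
#'
#' The 21 curated context term lists (8 locations, 8 emotions, 5 social
#' categories) used to quantify where, with whom and in which emotional
#' state cravings are mentioned. Some terms deliberately belong to two
#' categories ('wife' to both family and partner, 'lonely' to both sad
#' and alone, 'sad' to both sad and anxious/worried), so multi-category
#' matches are expected. With `extended = TRUE`, additional substance
#' (nicotine) and mental-health (depression, anxiety) lists — this
#' package's own — are appended.
#'
#' @param extended Include the substance / mental-health groups?
#' @return Tibble with columns `group`, `category`, `term`.
#' @export
default_context_registry <- function(extended = FALSE) {
  reg <- readr::read_csv(cm_extdata("context_registry.csv"),
                         col_types = readr::cols(.default = readr::col_character()))
  if (extended) {
    ext <- readr::read_csv(cm_extdata("context_registry_extended.csv"),
                           col_types = readr::cols(.default = readr::col_character()))
    reg <- dplyr::bind_rows(reg, ext)
  }
  reg
}

#' Concatenate each author's posts into one document
#'
#' Groups posts by author and concatenates their combined title+body
#' texts in ascending `created_utc` order, so context occurrence can be
#' counted once per distinct author rather than once per post.
#'
#' @param posts A posts tibble.
#' @return Tibble with one row per author: `author`, `text`, `n_posts`,
#'   `first_utc`, `last_utc`, `flair_days` (the author's badge, `NA` if
#'   absent or inconsistent across posts).
#' @export
group_by_author <- function(posts) {
  posts$.__text <- post_text(posts)
  posts <- posts[order(posts$author, posts$created_utc), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(posts, .data$author),
    text = paste(.data$.__text, collapse = " "),
    n_posts = dplyr::n(),
    first_utc = min(.data$created_utc),
    last_utc = max(.data$created_utc),
    flair_days = if ("flair_days" %in% names(posts)) {
      u <- unique(.data$flair_days[!is.na(.data$flair_days)])
      if (length(u) == 1L) u else NA_integer_
    } else NA_integer_,
    .groups = "drop"
  )
  as_tibble(out)
}

# word-boundary pattern over a set of context terms; multiword terms
# match as adjacent tokens
context_pattern <- function(terms, mode = c("exact_word", "affix")) {
  mode <- match.arg(mode)
  if (mode == "affix") {
    return(compile_pattern(terms)$regex)
  }
  esc <- gsub("([^a-z0-9 _])", "\\\\\\1", tolower(terms))
  esc <- gsub("[ _]+", "[^a-z0-9]+", esc)
  paste0("(?i)(?<![a-z0-9])(?:", paste(esc, collapse = "|"), ")(?![a-z0-9])")
}

#' Match context categories in documents
#'
#' A document matches a category when at least one of the category's
#' terms occurs at word boundaries (multiword terms as adjacent tokens).
#' Matching defaults to exact word matching because the registry lists
#' already enumerate inflections; `mode = "affix"` applies the word-form
#' rules of [compile_pattern()] instead.
#'
#' @param docs Tibble with a `text` column and an id column (`author` or
#'   `post_id`), e.g. from [group_by_author()].
#' @param registry Context registry tibble (default
#'   [default_context_registry()]).
#' @param mode `"exact_word"` (default) or `"affix"`.
#' @return Long tibble `(id column, group, category, matched)` with one
#'   row per document x category.
#' @export
match_contexts <- function(docs, registry = default_context_registry(),
                           mode = c("exact_word", "affix")) {
  mode <- match.arg(mode)
  if (nrow(registry) == 0L) abort("context registry is empty")
  id_col <- intersect(c("author", "post_id", "id"), names(docs))[1]
  if (is.na(id_col)) abort("docs must have an 'author', 'post_id' or 'id' column")
  cats <- dplyr::distinct(registry, .data$group, .data$category)
  text <- tolower(docs$text)
  res <- purrr::map_dfr(seq_len(nrow(cats)), function(i) {
    terms <- registry$term[registry$category == cats$category[i]]
    rx <- context_pattern(terms, mode)
    tibble(doc_id = docs[[id_col]],
           group = cats$group[i],
           category = cats$category[i],
           matched = stringr::str_detect(text, rx))
  })
  names(res)[names(res) == "doc_id"] <- id_col
  res
}

#' Per-category author percentages
#'
#' The share of distinct authors whose concatenated posts mention at
#' least one term of each context category — the per-category "% of
#' authors" summary of a craving corpus.
#'
#' @inheritParams match_contexts
#' @return A `context_report`: tibble `(group, category, n_matched,
#'   n_authors, pct)` with `pct` rounded to two decimals; the author
#'   total is also stored in `attr(, "n_authors")`.
#' @export
author_percentages <- function(docs, registry = default_context_registry(),
                               mode = c("exact_word", "affix")) {
  if (nrow(docs) == 0L) abort("at least one author document is required")
  matches <- match_contexts(docs, registry, mode)
  rep <- dplyr::summarise(
    dplyr::group_by(matches, .data$group, .data$category),
    n_matched = sum(.data$matched), .groups = "drop"
  )
  rep$n_authors <- nrow(docs)
  rep$pct <- round_half_up(100 * rep$n_matched / rep$n_authors, 2)
  # report in registry order
  order_key <- match(rep$category, unique(registry$category))
  rep <- rep[order(order_key), , drop = FALSE]
  structure(as_tibble(rep), class = c("context_report", class(rep)),
            n_authors = nrow(docs))
}

#' Evaluate multi-label context predictions per category
#'
#' Scores each context category as an independent binary problem at post
#' level. Ratios come from exact counts, rounded to four decimals;
#' undefined precision/recall are `NA`. A category absent from both
#' predictions and labels scores accuracy 1 with `NA` precision/recall.
#'
#' @param predicted Tibble `(post_id, context_labels)` where
#'   `context_labels` is a list column of category names (as produced by
#'   [match_contexts()] reshaped, or directly by the pipeline).
#' @param labels Labels tibble with `post_id` and `context_labels`.
#' @param categories Categories to score (default: all categories in the
#'   default registry).
#' @return Tibble `(category, tp, fp, fn, tn, accuracy, precision,
#'   recall)`.
#' @export
evaluate_contexts <- function(predicted, labels,
                              categories = unique(default_context_registry()$category)) {
  idx <- match(labels$post_id, predicted$post_id)
  if (anyNA(idx)) {
    abort(paste0("no prediction for labelled post(s): ",
                 paste(head(labels$post_id[is.na(idx)], 5), collapse = ", ")))
  }
  pred_sets <- predicted$context_labels[idx]
  true_sets <- labels$context_labels
  n <- length(true_sets)
  ratio <- function(num, den) if (den == 0L) NA_real_ else round_half_up(num / den, 4)
  purrr::map_dfr(categories, function(cc) {
    p <- vapply(pred_sets, function(s) cc %in% s, logical(1))
    t <- vapply(true_sets, function(s) cc %in% s, logical(1))
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
    tibble(category = cc, tp = tp, fp = fp, fn = fn, tn = tn,
           accuracy = ratio(tp + tn, n),
           precision = ratio(tp, tp + fp),
           recall = ratio(tp, tp + fn))
  })
}

#' Temporal and sobriety-badge profile of a corpus
#'
#' Histograms of posting hour (24 local-time bins), weekday, month, and
#' sobriety-badge day counts. Local time is `created_utc` shifted by
#' `utc_offset_minutes` where present; posts without an offset are
#' binned in UTC and counted in `n_missing_offset`.
#'
#' @param posts A posts tibble.
#' @return A `temporal_profile` list: tibbles `hour` (`hour`, `n`),
#'   `weekday` (`weekday`, `n`; Monday first), `month` (`month`, `n`),
#'   `flair` (`days`, `n`), plus `n_posts` and `n_missing_offset`.
#'   Hour/weekday/month histograms sum to `n_posts`; the flair histogram
#'   sums to the number of posts wearing a badge.
#' @export
temporal_profile <- function(posts) {
  offset <- posts$utc_offset_minutes %||% rep(NA_integer_, nrow(posts))
  missing <- is.na(offset)
  local <- posts$created_utc + ifelse(missing, 0, offset * 60)
  hour <- floor(local / 3600) %% 24
  lt <- as.POSIXlt(as.POSIXct(local, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
  wday <- (lt$wday + 6L) %% 7L  # 0 = Monday
  month <- lt$mon + 1L
  wd_labels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  tab <- function(values, levels) {
    t <- table(factor(values, levels = levels))
    tibble(value = levels, n = as.integer(t))
  }
  hour_tbl <- tab(hour, 0:23); names(hour_tbl) <- c("hour", "n")
  wd_tbl <- tab(wday, 0:6); wd_tbl$value <- wd_labels
  names(wd_tbl) <- c("weekday", "n")
  mo_tbl <- tab(month, 1:12); names(mo_tbl) <- c("month", "n")
  flair <- posts$flair_days[!is.na(posts$flair_days)]
  flair_tbl <- if (length(flair) > 0) {
    t <- table(flair)
    tibble(days = as.integer(names(t)), n = as.integer(t))
  } else tibble(days = integer(0), n = integer(0))
  structure(
    list(hour = hour_tbl, weekday = wd_tbl, month = mo_tbl, flair = flair_tbl,
         n_posts = nrow(posts), n_missing_offset = sum(missing)),
    class = "temporal_profile"
  )
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat("<temporal_profile> ", x$n_posts, " posts (",
      x$n_missing_offset, " without utc offset), ",
      sum(x$flair$n), " with sobriety badge\n", sep = "")
  invisible(x)
}

#' Fit an exponential decay to sobriety-badge counts
#'
#' Posting frequency decays roughly exponentially with the number of
#' sober days, except for spikes on milestone days. The fit is a
#' least-squares regression of `log(count)` on day over bins with a
#' positive count, milestone days excluded, weighted by bin count (the
#' variance-stabilising weight for log counts under Poisson noise —
#' without it the long tail of single-post bins flattens the slope);
#' the decay rate is the negated slope. On exact geometric counts
#' `c * q^d` the fit returns `lambda = -log(q)` up to numerical
#' precision.
#'
#' @param x A `temporal_profile` or a tibble with columns `days`, `n`.
#' @param milestones Day bins excluded from the fit (default
#'   `c(30, 31, 100, 365, 366)`: the spike days and the day after the
#'   month/year marks).
#' @param min_bins Minimum distinct day bins required (default 10).
#' @return A `flair_decay_fit` with fields `lambda`, `r_squared`,
#'   `n_bins`, `fit` (the `lm`), and the excluded milestones. [tidy()]
#'   and [glance()] methods are provided.
#' @export
flair_decay_fit <- function(x, milestones = c(30L, 31L, 100L, 365L, 366L),
                            min_bins = 10) {
  flair <- if (inherits(x, "temporal_profile")) x$flair else as_tibble(x)
  stopifnot(all(c("days", "n") %in% names(flair)))
  keep <- flair$n > 0 & !(flair$days %in% milestones)
  dat <- flair[keep, , drop = FALSE]
  if (length(unique(dat$days)) < min_bins) {
    abort(paste0("decay fit needs at least ", min_bins,
                 " distinct non-milestone day bins with posts; got ",
                 length(unique(dat$days))))
  }
  fit <- lm(log(n) ~ days, data = dat, weights = dat$n)
  structure(
    list(lambda = -unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         n_bins = nrow(dat),
         milestones = milestones,
         fit = fit),
    class = "flair_decay_fit"
  )
}

#' @export
print.flair_decay_fit <- function(x, ...) {
  cat("<flair_decay_fit> lambda = ", signif(x$lambda, 6),
      " per day (R^2 ", round(x$r_squared, 4), ", ", x$n_bins, " bins)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.flair_decay_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2])
}

#' @export
glance.flair_decay_fit <- function(x, ...) {
  tibble(lambda = x$lambda, r_squared = x$r_squared, n_bins = x$n_bins)
}
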