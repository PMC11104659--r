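# autoplot() methods for the package's result types.

#' Plot a temporal profile
#'
#' @param object A `temporal_profile`.
#' @param what Which histogram: `"hour"` (default), `"weekday"`,
#'   `"month"` or `"flair"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.temporal_profile <- function(object, what = c("hour", "weekday",
                                                       "month", "flair"), ...) {
  what <- match.arg(what)
  if (what == "hour") {
    ggplot2::ggplot(object$hour, ggplot2::aes(x = .data$hour, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "local hour of day", y = "posts",
                    title = "Craving posts per hour (local time)")
  } else if (what == "weekday") {
    df <- object$weekday
    df$weekday <- factor(df$weekday, levels = df$weekday)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$weekday, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "posts")
  } else if (what == "month") {
    ggplot2::ggplot(object$month, ggplot2::aes(x = .data$month, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::scale_x_continuous(breaks = 1:12) +
      ggplot2::labs(x = "month", y = "posts")
  } else {
    ggplot2::ggplot(object$flair, ggplot2::aes(x = .data$days, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "days since last drink (badge)", y = "posts",
                    title = "Posts by sobriety-badge day count")
  }
}

#' Plot per-category author percentages
#'
#' @param object A `context_report` from [author_percentages()].
#' @param ... Ignored.
#' @return A ggplot object: categories ordered by percentage, coloured
#'   by group.
#' @export
autoplot.context_report <- function(object, ...) {
  df <- as_tibble(object)
  df$category <- factor(df$category, levels = df$category[order(df$pct)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$category,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of authors", y = NULL, fill = "group",
                  title = "Craving contexts by share of authors")
}

#' Plot a fitted sobriety-badge decay
#'
#' @param object A `flair_decay_fit`.
#' @param ... Ignored.
#' @return A ggplot of log counts per day with the fitted line.
#' @export
autoplot.flair_decay_fit <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("log_n", "days")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days, y = .data$log_n)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = coef(object$fit)[1],
                         slope = coef(object$fit)[2], colour = "firebrick") +
    ggplot2::labs(x = "days since last drink", y = "log posts",
                  title = paste0("Exponential decay, lambda = ",
                                 signif(object$lambda, 3), " per day"))
}

#' Plot a topic summary
#'
#' @param object A `topic_summary` from [lda_summarize()].
#' @param ... Ignored.
#' @return A ggplot of coherence and vocabulary share per topic.
#' @export
autoplot.topic_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- vapply(df$top_words, function(w) paste(head(w, 4), collapse = ", "),
                     character(1))
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coherence, y = .data$label,
                                   size = .data$word_share_pct)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "NPMI coherence", y = NULL, size = "% words",
                  title = "Topics by coherence and vocabulary share")
}
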