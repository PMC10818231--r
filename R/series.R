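#' Windowed fraud-proportion time series
#'
#' For each calendar day of the observation span and each classification
#' method, computes the proportion of responses labeled fraud within a
#' centered moving window of `window_days` days. Days whose window contains
#' no responses emit `NA`, so recruitment pauses appear as gaps rather than
#' zeros. This windowed series stands in for a locally weighted smoother as
#' the package's trend summary.
#'
#' @param labeled Tibble with columns `response_id`, `start_time`, `label`
#'   and `method` (stack several methods to compare them), e.g. the output
#'   of [tidy()] on a [run_pipeline()] result joined to timestamps.
#' @param window_days Width of the centered window in days (odd values keep
#'   the window symmetric). Default 7.
#' @return Tibble `date`, `method`, `n` (responses in window), `prop`
#'   (fraud proportion, `NA` on empty windows), of class
#'   `fraud_series`.
#' @export
fraud_proportion_series <- function(labeled, window_days = 7L) {
  stopifnot(all(c("start_time", "label", "method") %in% names(labeled)))
  if (anyNA(labeled$start_time)) {
    abort("fraud_proportion_series requires timestamps on every response.",
          class = "surveysieve_data_error")
  }
  day <- as.Date(labeled$start_time, tz = "UTC")
  days <- seq(min(day), max(day), by = "day")
  half <- (window_days - 1) / 2
  out <- lapply(unique(labeled$method), function(m) {
    sel <- labeled$method == m
    d <- as.numeric(day[sel])
    fraud <- labeled$label[sel] == "fraud"
    res <- lapply(as.numeric(days), function(d0) {
      inside <- abs(d - d0) <= half
      n <- sum(inside)
      tibble(date = as.Date(d0, origin = "1970-01-01"), method = m, n = n,
             prop = if (n == 0) NA_real_ else mean(fraud[inside]))
    })
    bind_rows(res)
  })
  structure(bind_rows(out), class = c("fraud_series", "tbl_df", "tbl",
                                      "data.frame"))
}

#' Plot a fraud-proportion series
#'
#' One line per classification method, with gaps where the moving window is
#' empty.
#'
#' @param object A `fraud_series` from [fraud_proportion_series()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fraud_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$date, y = .data$prop,
                               colour = .data$method)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion classified as fraud",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' @export
plot.fraud_series <- function(x, ...) print(autoplot(x, ...))
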