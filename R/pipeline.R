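#' Run the full two-system classification pipeline
#'
#' Orchestrates both classifiers over a batch and assembles the comparison
#' report: the real-time stage labels the batch, the post hoc stage screens
#' the stage-1 survivors (so every response ends in exactly one of
#' realtime-fraud, posthoc-fraud, or multilayer-valid), and the platform
#' adapter independently classifies *all* responses from their exported
#' scores. Agreement between the two complete systems is then summarized by
#' confusion matrices and Cohen's kappa, overall and per survey type, plus a
#' windowed fraud-proportion time series per method.
#'
#' Strata with degenerate marginals (e.g. an all-valid batch) report their
#' kappa as not computable rather than failing the run.
#'
#' @param responses Response tibble (see [read_responses()]).
#' @param g A [gazetteer()].
#' @param config An [fd_config()].
#' @param series_window_days Window for [fraud_proportion_series()]; `NULL`
#'   (or missing timestamps) skips the series. Default 7.
#' @return A `fraud_pipeline` object: `labels` (per-response multilayer and
#'   platform labels), `realtime`, `posthoc`, `platform` (the stage
#'   results), `confusion` and `kappa` (named lists over `overall` and each
#'   survey type), `series`, and `report` (the flowchart count summary).
#'   [tidy()] returns the label table, [glance()] the count summary,
#'   [autoplot()] the time series.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genuine = 40, seed = 3))
#' fit <- run_pipeline(cohort$responses, cohort$gazetteer, fd_config())
#' glance(fit)
#' @export
run_pipeline <- function(responses, g, config = fd_config(),
                         series_window_days = 7L) {
  stopifnot(nrow(responses) > 0)
  inform(sprintf("Stage 1 (real-time rules): %d responses", nrow(responses)))
  rt <- apply_realtime_stage(responses, g, config)
  survivors <- responses[responses$response_id %in%
                           rt$labels$response_id[rt$labels$label == "valid"], ]
  inform(sprintf("Stage 2 (post hoc, k = %d): %d survivors",
                 config$k_strike, nrow(survivors)))
  ph <- apply_posthoc_stage(survivors, g, config)
  pf <- classify_platform(responses, config)

  ml <- rt$labels %>%
    select("response_id", rt_label = "label", rt_stage = "stage",
           "rule_first") %>%
    left_join(select(ph$labels, "response_id", ph_label = "label",
                     "n_strikes"),
              by = "response_id") %>%
    mutate(
      label = ifelse(.data$rt_label == "fraud", "fraud",
                     ifelse(.data$ph_label == "fraud", "fraud", "valid")),
      stage = ifelse(.data$rt_label == "fraud", "realtime",
                     ifelse(.data$ph_label == "fraud", "posthoc", "none"))
    )
  labels <- tibble(
    response_id = responses$response_id,
    survey_type = responses$survey_type,
    start_time = responses$start_time
  ) %>%
    left_join(select(ml, "response_id", multilayer = "label",
                     multilayer_stage = "stage", "rule_first", "n_strikes"),
              by = "response_id") %>%
    left_join(select(pf$labels, "response_id", platform = "label"),
              by = "response_id")

  strata <- c(list(overall = labels),
              split(labels, labels$survey_type))
  confusion <- lapply(strata, function(s) {
    build_confusion(
      tibble(response_id = s$response_id, label = s$multilayer),
      tibble(response_id = s$response_id, label = s$platform))
  })
  kappa <- lapply(confusion, function(cm) {
    tryCatch(cohen_kappa(cm),
             surveysieve_degenerate_error = function(e) NULL)
  })

  series <- NULL
  if (!is.null(series_window_days) && !anyNA(labels$start_time)) {
    stacked <- bind_rows(
      labels %>% select("response_id", "start_time",
                        label = "multilayer") %>%
        mutate(method = "multilayer"),
      labels %>% select("response_id", "start_time",
                        label = "platform") %>%
        mutate(method = "platform")
    )
    series <- fraud_proportion_series(stacked, series_window_days)
  }

  report <- list(
    n_total = nrow(responses),
    realtime_fraud = sum(labels$multilayer_stage == "realtime"),
    realtime_by_rule = rt$counts_by_rule,
    posthoc_strike_counts = ph$counts_by_rule,
    posthoc_fraud = sum(labels$multilayer_stage == "posthoc"),
    multilayer_fraud = sum(labels$multilayer == "fraud"),
    multilayer_valid = sum(labels$multilayer == "valid"),
    platform_by_rule = pf$counts_by_rule,
    platform_fraud = sum(labels$platform == "fraud"),
    platform_valid = sum(labels$platform == "valid")
  )
  stopifnot(report$multilayer_valid ==
              report$n_total - report$realtime_fraud - report$posthoc_fraud)

  structure(
    list(labels = labels, realtime = rt, posthoc = ph, platform = pf,
         confusion = confusion, kappa = kappa, series = series,
         report = report, config = config),
    class = "fraud_pipeline"
  )
}

#' @export
print.fraud_pipeline <- function(x, ...) {
  r <- x$report
  cat("<fraud_pipeline>\n")
  cat(sprintf("  %d responses\n", r$n_total))
  cat(sprintf("  multilayer: %d fraud (%d real-time + %d post hoc), %d valid (%.2f%%)\n",
              r$multilayer_fraud, r$realtime_fraud, r$posthoc_fraud,
              r$multilayer_valid, 100 * r$multilayer_valid / r$n_total))
  cat(sprintf("  platform:   %d fraud, %d valid (%.2f%%)\n",
              r$platform_fraud, r$platform_valid,
              100 * r$platform_valid / r$n_total))
  if (!is.null(x$kappa$overall)) {
    k <- x$kappa$overall
    cat(sprintf("  agreement:  kappa = %.2f (%g%% CI %.2f-%.2f), \"%s\"/\"%s\"\n",
                k$kappa, 100 * k$confidence, k$ci_low, k$ci_high,
                k$landis_koch, k$mchugh))
  } else {
    cat("  agreement:  kappa not computable (degenerate marginals)\n")
  }
  invisible(x)
}

#' @export
tidy.fraud_pipeline <- function(x, ...) x$labels

#' @export
glance.fraud_pipeline <- function(x, ...) {
  r <- x$report
  tibble(
    n = r$n_total,
    realtime_fraud = r$realtime_fraud,
    posthoc_fraud = r$posthoc_fraud,
    multilayer_fraud = r$multilayer_fraud,
    multilayer_valid = r$multilayer_valid,
    multilayer_valid_pct = 100 * r$multilayer_valid / r$n_total,
    platform_fraud = r$platform_fraud,
    platform_valid = r$platform_valid,
    kappa = if (is.null(x$kappa$overall)) NA_real_ else
      x$kappa$overall$kappa
  )
}

#' @export
autoplot.fraud_pipeline <- function(object, ...) {
  if (is.null(object$series)) {
    abort("Pipeline was run without a time series.",
          class = "surveysieve_data_error")
  }
  autoplot(object$series, ...)
}

#' Write pipeline outputs to a directory
#'
#' Emits `labels.csv` (per-response multilayer and platform labels) and
#' `report.json` (flowchart counts, confusion matrices, kappa per stratum,
#' and the fraud-proportion series) for downstream tools. Re-running on
#' identical inputs reproduces identical files.
#'
#' @param x A `fraud_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(x, dir) {
  stopifnot(inherits(x, "fraud_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- x$labels
  out$start_time <- format(out$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, file.path(dir, "labels.csv"), na = "")
  report <- x$report
  report$confusion <- lapply(x$confusion, function(cm) {
    cm[c("a", "b", "c", "d", "n")]
  })
  report$kappa <- lapply(x$kappa, function(k) {
    if (is.null(k)) "not computable" else unclass(tidy(k))
  })
  if (!is.null(x$series)) {
    report$series <- as.data.frame(x$series)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
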