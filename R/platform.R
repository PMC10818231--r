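#' Platform-side fraud classification from exported scores
#'
#' Reproduces the survey platform's automated classification from the three
#' scores it attaches to each response: a reCAPTCHA v3 bot-likelihood score
#' in \[0, 1\] (fraud when strictly under 0.5), a RelevantID fraud score in
#' \[0, 130\] (fraud at >= 30) and a RelevantID duplicate score in \[0, 100\]
#' (duplicate at >= 75). A response is fraud when it breaches one or more
#' thresholds; every breached threshold is recorded. The scoring models
#' themselves are proprietary and opaque — only the exported scores and the
#' recommended cutoffs are modeled.
#'
#' Missing scores never flag: a response with all three scores absent is
#' labeled valid and counted in the result's `n_unscored` audit tally.
#' Scores outside their documented range raise a warning but are still
#' compared.
#'
#' @param responses Response tibble with `recaptcha_v3`, `relevantid_fraud`,
#'   `relevantid_dup` columns.
#' @param config An [fd_config()] supplying the three cutoffs.
#' @return A `platform_result`: `labels` (tibble `response_id`, `label`,
#'   `stage`, `rules_all`), `counts_by_rule` (each breached threshold counts,
#'   so the column can sum to more than the fraud total), and `n_unscored`.
#' @examples
#' resp <- tibble::tibble(
#'   response_id = c("a", "b", "c"),
#'   recaptcha_v3 = c(0.4, 0.9, 0.5),
#'   relevantid_fraud = c(0, 30, 29),
#'   relevantid_dup = c(0, 74, 74)
#' )
#' tidy(classify_platform(resp))
#' @export
classify_platform <- function(responses, config = fd_config()) {
  check_score_ranges(responses)
  fired <- cbind(
    platform_recaptcha = !is.na(responses$recaptcha_v3) &
      responses$recaptcha_v3 < config$recaptcha_cutoff,
    platform_fraud_score = !is.na(responses$relevantid_fraud) &
      responses$relevantid_fraud >= config$fraud_score_cutoff,
    platform_dup_score = !is.na(responses$relevantid_dup) &
      responses$relevantid_dup >= config$dup_score_cutoff
  )
  any_fired <- rowSums(fired) > 0
  unscored <- is.na(responses$recaptcha_v3) &
    is.na(responses$relevantid_fraud) & is.na(responses$relevantid_dup)
  if (any(unscored)) {
    inform(sprintf("%d response(s) carry no platform scores; labeled valid.",
                   sum(unscored)))
  }
  labels <- tibble(
    response_id = responses$response_id,
    label = ifelse(any_fired, "fraud", "valid"),
    stage = ifelse(any_fired, "platform", "none"),
    rules_all = vapply(seq_len(nrow(fired)), function(i) {
      paste(.platform_rules[fired[i, ]], collapse = ";")
    }, character(1))
  )
  counts <- tibble(rule_id = .platform_rules, n = colSums(fired))
  structure(
    list(labels = labels, counts_by_rule = counts,
         n_unscored = sum(unscored)),
    class = "platform_result"
  )
}

#' @export
print.platform_result <- function(x, ...) {
  g <- glance(x)
  cat("<platform_result>\n")
  cat(sprintf("  %d responses: %d fraud (%.2f%%), %d valid (%d unscored)\n",
              g$n, g$n_fraud, 100 * g$n_fraud / g$n, g$n_valid,
              x$n_unscored))
  for (i in seq_len(nrow(x$counts_by_rule))) {
    cat(sprintf("    %-22s %6d\n", x$counts_by_rule$rule_id[i],
                x$counts_by_rule$n[i]))
  }
  invisible(x)
}

#' @export
tidy.platform_result <- function(x, ...) x$labels

#' @export
glance.platform_result <- function(x, ...) {
  tibble(
    n = nrow(x$labels),
    n_fraud = sum(x$labels$label == "fraud"),
    n_valid = sum(x$labels$label == "valid"),
    n_unscored = x$n_unscored
  )
}
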