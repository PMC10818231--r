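#' Post hoc suspicion criteria and the k-strike rule
#'
#' The second layer screens the responses that survived real-time exclusion
#' with three automated criteria. Each criterion only marks a response as
#' *suspicious* (a "strike"); a response is labeled fraud when it collects at
#' least `k` strikes (default 2), balancing each criterion's false-positive
#' potential against the need to exclude strongly evidenced fraud.
#'
#' * `flag_duplicate_free_text()` — the free-text comment, after
#'   normalization, is identical to other respondents' text at tiered
#'   thresholds: 1+ words repeated >= 100 times, 2+ words repeated >= 10
#'   times, or 3+ words repeated >= 3 times. Every response whose text meets
#'   a tier is flagged, including the first submitter. Repeat counts are
#'   computed within the supplied batch (the stage-1 survivors).
#' * `flag_bad_ip()` — the IP belongs to a VPN or data center, or originates
#'   outside the allowed country, per longest-prefix match in the gazetteer's
#'   IP-intelligence table. IPs with no matching prefix are *not* flagged
#'   (the criterion needs positive evidence); malformed IPs raise a warning
#'   and are not flagged.
#' * `flag_screener_inconsistency()` — a key item answered in both the
#'   screener (`scr_<item>`) and the main survey (`main_<item>`) disagrees.
#'   Numeric-looking values compare numerically, otherwise after text
#'   normalization; items missing on either side are skipped.
#'
#' @param responses Response tibble restricted to stage-1 survivors.
#' @name posthoc_rules
NULL

#' @rdname posthoc_rules
#' @param tiers Data frame `min_words`, `min_repeats` (see [fd_config()]).
#' @return `flag_duplicate_free_text()`: character vector of flagged
#'   `response_id`s.
#' @export
flag_duplicate_free_text <- function(responses, tiers = default_text_tiers()) {
  text <- normalize_text(responses$free_text_comment)
  usable <- !is_blank(responses$free_text_comment)
  words <- ifelse(usable, lengths(strsplit(text, " ", fixed = TRUE)), 0L)
  reps <- stats::ave(seq_along(text), ifelse(usable, text, NA),
                     FUN = length)
  flagged <- rep(FALSE, length(text))
  for (i in seq_len(nrow(tiers))) {
    flagged <- flagged |
      (usable & words >= tiers$min_words[i] & reps >= tiers$min_repeats[i])
  }
  sort(responses$response_id[flagged])
}

#' @rdname posthoc_rules
#' @param g A [gazetteer()].
#' @param allowed_country IPs resolving to any other country are flagged.
#' @return `flag_bad_ip()`: logical vector aligned with `responses` rows.
#' @export
flag_bad_ip <- function(responses, g, allowed_country = "US") {
  ip <- responses$ip_address
  malformed <- !is.na(ip) & is.na(ipv4_to_num(ip))
  if (any(malformed)) {
    warn(sprintf("%d malformed IP address(es) left unflagged (e.g. \"%s\").",
                 sum(malformed), ip[which(malformed)[1]]))
  }
  hit <- ip_lookup(g, ip)
  (!is.na(hit$is_vpn) & hit$is_vpn) |
    (!is.na(hit$country) & hit$country != allowed_country)
}

#' @rdname posthoc_rules
#' @param key_items Item names checked for screener/main agreement.
#' @return `flag_screener_inconsistency()`: logical vector aligned with rows.
#' @export
flag_screener_inconsistency <- function(responses,
                                        key_items = fd_config()$key_items) {
  out <- rep(FALSE, nrow(responses))
  for (item in key_items) {
    scol <- paste0("scr_", item)
    mcol <- paste0("main_", item)
    if (!scol %in% names(responses) || !mcol %in% names(responses)) next
    s <- responses[[scol]]
    m <- responses[[mcol]]
    both <- !is.na(s) & !is.na(m) & trimws(as.character(s)) != "" &
      trimws(as.character(m)) != ""
    sn <- suppressWarnings(as.numeric(s))
    mn <- suppressWarnings(as.numeric(m))
    numeric_cmp <- both & !is.na(sn) & !is.na(mn)
    mismatch <- both &
      ifelse(numeric_cmp, sn != mn,
             normalize_text(s) != normalize_text(m))
    out <- out | mismatch
  }
  out
}

#' @rdname posthoc_rules
#' @param strikes Tibble `response_id`, `rule_id` (one row per strike), e.g.
#'   the `strikes` component of a [apply_posthoc_stage()] result.
#' @param k Strikes required for a fraud label (1, 2 or 3).
#' @return `apply_k_strike()`: tibble `response_id`, `n_strikes`, `label`
#'   covering every id in `strikes` (ids with zero rows must be added by the
#'   caller; [apply_posthoc_stage()] covers the full batch).
#' @export
apply_k_strike <- function(strikes, k = 2L) {
  if (!k %in% 1:3) {
    abort("`k` must be 1, 2 or 3.", class = "surveysieve_config_error")
  }
  strikes %>%
    distinct(.data$response_id, .data$rule_id) %>%
    count(.data$response_id, name = "n_strikes") %>%
    mutate(label = ifelse(.data$n_strikes >= k, "fraud", "valid"))
}

#' Apply the post hoc stage to the stage-1 survivors
#'
#' Computes the three suspicion criteria over the supplied batch (which the
#' pipeline restricts to responses the real-time stage labeled valid, so
#' duplicate-text repeat counts use the survivor denominator) and labels
#' fraud at `config$k_strike` strikes.
#'
#' @param responses Response tibble of stage-1 survivors.
#' @param g A [gazetteer()].
#' @param config An [fd_config()].
#' @return A `posthoc_result`: `strikes` (tibble `response_id`, `rule_id`),
#'   `labels` (tibble `response_id`, `n_strikes`, `label`, `stage`),
#'   `counts_by_rule`, and `k_used`. [tidy()] returns the label table.
#' @export
apply_posthoc_stage <- function(responses, g, config = fd_config()) {
  dup_ids <- flag_duplicate_free_text(responses, config$text_tiers)
  strikes <- bind_rows(
    tibble(response_id = dup_ids, rule_id = "dup_free_text"),
    tibble(response_id = responses$response_id[
      flag_bad_ip(responses, g, config$allowed_country)],
      rule_id = "bad_ip"),
    tibble(response_id = responses$response_id[
      flag_screener_inconsistency(responses, config$key_items)],
      rule_id = "screener_inconsistency")
  )
  verdict <- apply_k_strike(strikes, config$k_strike)
  labels <- tibble(response_id = responses$response_id) %>%
    left_join(verdict, by = "response_id") %>%
    mutate(
      n_strikes = ifelse(is.na(.data$n_strikes), 0L, .data$n_strikes),
      label = ifelse(is.na(.data$label), "valid", .data$label),
      stage = ifelse(.data$label == "fraud", "posthoc", "none")
    )
  counts <- tibble(rule_id = .posthoc_rules) %>%
    left_join(count(strikes, .data$rule_id), by = "rule_id") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(
    list(strikes = strikes, labels = labels, counts_by_rule = counts,
         k_used = config$k_strike),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  g <- glance(x)
  cat("<posthoc_result>\n")
  cat(sprintf("  %d stage-1 survivors, k = %d: %d fraud, %d valid\n",
              g$n, x$k_used, g$n_fraud, g$n_valid))
  for (i in seq_len(nrow(x$counts_by_rule))) {
    cat(sprintf("    %-24s %6d strike(s)\n", x$counts_by_rule$rule_id[i],
                x$counts_by_rule$n[i]))
  }
  invisible(x)
}

#' @export
tidy.posthoc_result <- function(x, ...) x$labels

#' @export
glance.posthoc_result <- function(x, ...) {
  tibble(
    n = nrow(x$labels),
    k_used = x$k_used,
    n_fraud = sum(x$labels$label == "fraud"),
    n_valid = sum(x$labels$label == "valid")
  )
}
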