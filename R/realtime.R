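#' Real-time exclusion rules
#'
#' The first layer of the multilayer classifier reproduces, as data rules
#' over an export, the checks study personnel applied to each submission as
#' it arrived. A response is excluded when any of these fires:
#'
#' 1. `rule_neighborhood_mismatch()` — the self-reported colloquial
#'    neighborhood name matches neither the neighborhood of the residential
#'    address (per the gazetteer) nor any adjacent neighborhood;
#' 2. `rule_invalid_address()` — the residential address does not match an
#'    existing address in the gazetteer index;
#' 3. `rule_rapid_submission()` — start AND stop times within +/- 1 minute of
#'    those of at least `min_others` other submissions (scripted completion);
#' 4. `rule_duplicate_email()` — the email address matches a previously
#'    enrolled respondent's (first user kept, later users flagged);
#' 5. `rule_nonstandard_zip()` — the zip code is a PO box or unique code;
#' 6. `rule_address_overuse()` — the residential address was already reported
#'    by at least `prior_count` earlier respondents (3rd+ users flagged);
#' 7. `rule_invalid_referral()` — the referral URL is not among the
#'    recruitment URLs distributed by the study team;
#' plus `rule_honeypot()` — any answer to the hidden honeypot item.
#'
#' Per-response rules return a logical vector aligned with the rows of
#' `responses`; batch rules (3, 4, 6) return the set of flagged
#' `response_id`s, evaluated in chronological order (start time, ties by id).
#'
#' @param responses Response tibble (see [read_responses()]).
#' @param g A [gazetteer()].
#' @name realtime_rules
NULL

#' @rdname realtime_rules
#' @export
rule_neighborhood_mismatch <- function(responses, g) {
  canonical <- lookup_neighborhood(g, responses$street_address)
  reported <- normalize_text(responses$neighborhood_name)
  out <- logical(nrow(responses))
  known <- !is.na(canonical)
  for (i in which(known)) {
    accepted <- c(canonical[i], g$adjacency[[canonical[i]]])
    out[i] <- !(reported[i] %in% accepted)
  }
  out  # unresolvable addresses are rule 2's case, never flagged here
}

#' @rdname realtime_rules
#' @export
rule_invalid_address <- function(responses, g) {
  norm <- normalize_text(responses$street_address, address = TRUE)
  is.na(responses$street_address) | norm == "" |
    !(norm %in% g$address_index$.norm)
}

#' @rdname realtime_rules
#' @param window_minutes Half-width of the shared-time window, minutes.
#' @param min_others Minimum number of other co-timed submissions.
#' @export
rule_rapid_submission <- function(responses, window_minutes = 1,
                                  min_others = 2L) {
  if (anyNA(responses$start_time) || anyNA(responses$end_time)) {
    abort("rapid-submission rule requires timestamps on every response.",
          class = "surveysieve_data_error")
  }
  s <- minute_of(responses$start_time)
  e <- minute_of(responses$end_time)
  n <- length(s)
  ord <- order(s)
  ss <- s[ord]
  ee <- e[ord]
  w <- window_minutes
  flagged <- logical(n)
  lo <- findInterval(ss - w, ss, left.open = TRUE) + 1L
  hi <- findInterval(ss + w, ss)
  for (k in seq_len(n)) {
    others <- sum(abs(ee[lo[k]:hi[k]] - ee[k]) <= w) - 1L
    flagged[ord[k]] <- others >= min_others
  }
  sort(responses$response_id[flagged])
}

#' @rdname realtime_rules
#' @export
rule_duplicate_email <- function(responses) {
  chron <- order_chronologically(responses)
  email <- normalize_email(chron$email)
  usable <- !is.na(chron$email) & email != ""
  dup <- usable & duplicated(ifelse(usable, email, NA))
  sort(chron$response_id[dup])
}

#' @rdname realtime_rules
#' @export
rule_nonstandard_zip <- function(responses, g) {
  !is.na(responses$zip_code) &
    trimws(responses$zip_code) %in% g$nonstandard_zips
}

#' @rdname realtime_rules
#' @param prior_count Number of earlier reporters of the same address that
#'   triggers the flag.
#' @export
rule_address_overuse <- function(responses, prior_count = 2L) {
  chron <- order_chronologically(responses)
  addr <- normalize_text(chron$street_address, address = TRUE)
  usable <- !is.na(chron$street_address) & addr != ""
  key <- ifelse(usable, addr, paste0(".na.", seq_along(addr)))
  prior <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  sort(chron$response_id[usable & prior >= prior_count])
}

#' @rdname realtime_rules
#' @export
rule_invalid_referral <- function(responses, g) {
  is.na(responses$referral_url) |
    !(normalize_url(responses$referral_url) %in% g$valid_urls)
}

#' @rdname realtime_rules
#' @export
rule_honeypot <- function(responses) {
  !is_blank(responses$honeypot_answer)
}

#' Apply the real-time exclusion stage to a batch
#'
#' Evaluates all real-time rules and labels each response `fraud` (any rule
#' fired) or `valid`. For reporting, each fraud case is attributed to the
#' *first* firing rule in the criterion order 1-7 then honeypot, so the
#' per-rule counts are mutually exclusive and sum to the fraud count; every
#' firing rule is nonetheless retained in the flag table as evidence.
#'
#' @param responses Response tibble.
#' @param g A [gazetteer()].
#' @param config An [fd_config()].
#' @return A `realtime_result`: list with `labels` (tibble `response_id`,
#'   `label`, `stage`, `rule_first`, `rules_all`), `flags` (tibble
#'   `response_id`, `rule_id`, `evidence`, one row per firing rule) and
#'   `counts_by_rule` (first-match attribution). [tidy()] returns the label
#'   table, [glance()] the stage totals.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genuine = 20, seed = 7))
#' res <- apply_realtime_stage(cohort$responses, cohort$gazetteer, fd_config())
#' glance(res)
#' @export
apply_realtime_stage <- function(responses, g, config = fd_config()) {
  stopifnot(nrow(responses) > 0)
  fired <- list(
    neighborhood_mismatch = rule_neighborhood_mismatch(responses, g),
    invalid_address = rule_invalid_address(responses, g),
    rapid_submission = responses$response_id %in%
      rule_rapid_submission(responses, config$rapid_window_minutes,
                            config$rapid_min_others),
    duplicate_email = responses$response_id %in%
      rule_duplicate_email(responses),
    nonstandard_zip = rule_nonstandard_zip(responses, g),
    address_overuse = responses$response_id %in%
      rule_address_overuse(responses, config$address_overuse_prior_count),
    invalid_url = rule_invalid_referral(responses, g),
    honeypot = rule_honeypot(responses)
  )
  fired_mat <- do.call(cbind, fired)
  any_fired <- rowSums(fired_mat) > 0
  first_rule <- apply(fired_mat, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) NA_character_ else .realtime_rules[hit[1]]
  })
  flags <- tibble(
    response_id = rep(responses$response_id, ncol(fired_mat)),
    rule_id = rep(.realtime_rules, each = nrow(responses)),
    fired = as.vector(fired_mat)
  ) %>%
    filter(.data$fired) %>%
    mutate(evidence = paste0("rule ", .data$rule_id, " fired")) %>%
    select("response_id", "rule_id", "evidence") %>%
    arrange(.data$response_id, match(.data$rule_id, .realtime_rules))
  labels <- tibble(
    response_id = responses$response_id,
    label = ifelse(any_fired, "fraud", "valid"),
    stage = ifelse(any_fired, "realtime", "none"),
    rule_first = first_rule,
    rules_all = vapply(seq_len(nrow(fired_mat)), function(i) {
      paste(.realtime_rules[fired_mat[i, ]], collapse = ";")
    }, character(1))
  )
  counts <- tibble(rule_id = .realtime_rules) %>%
    left_join(count(filter(labels, .data$label == "fraud"),
                    .data$rule_first),
              by = c(rule_id = "rule_first")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(
    list(labels = labels, flags = flags, counts_by_rule = counts),
    class = "realtime_result"
  )
}

#' @export
print.realtime_result <- function(x, ...) {
  g <- glance(x)
  cat("<realtime_result>\n")
  cat(sprintf("  %d responses: %d fraud (%.2f%%), %d valid\n",
              g$n, g$n_fraud, 100 * g$n_fraud / g$n, g$n_valid))
  nz <- filter(x$counts_by_rule, .data$n > 0)
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("    %-22s %6d\n", nz$rule_id[i], nz$n[i]))
  }
  invisible(x)
}

#' @export
tidy.realtime_result <- function(x, ...) x$labels

#' @export
glance.realtime_result <- function(x, ...) {
  tibble(
    n = nrow(x$labels),
    n_fraud = sum(x$labels$label == "fraud"),
    n_valid = sum(x$labels$label == "valid")
  )
}
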