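#' Detection configuration
#'
#' Bundles every tunable threshold of the multilayer classifier and the
#' platform adapter, plus the column mapping used when reading exports.
#' Defaults encode the deployed study protocol: a 2-strike post hoc rule,
#' a +/- 1 minute rapid-submission window requiring 2 or more co-submitters,
#' address overuse at 2 prior reporters, tiered duplicate-text thresholds
#' (1 word repeated >= 100 times, 2 words >= 10, 3 words >= 3), and platform
#' cutoffs reCAPTCHA v3 < 0.5, RelevantID fraud score >= 30, RelevantID
#' duplicate score >= 75.
#'
#' @param k_strike Number of post hoc criteria (of 3) required to label a
#'   response fraud; one of 1, 2, 3. Default 2.
#' @param rapid_window_minutes Half-width, in minutes, of the window within
#'   which start and stop times count as shared. Default 1.
#' @param rapid_min_others Minimum number of *other* responses sharing start
#'   and stop times for the rapid-submission rule to fire. Default 2.
#' @param address_overuse_prior_count A response is flagged when at least this
#'   many earlier responses reported the same residential address. Default 2
#'   (the 3rd and later users of an address are flagged).
#' @param text_tiers Data frame with columns `min_words`, `min_repeats`; a
#'   normalized free-text string is a duplicate when some tier has word count
#'   >= `min_words` and corpus repeat count >= `min_repeats`.
#' @param recaptcha_cutoff Platform bot threshold: fraud if score < cutoff
#'   (strict). Default 0.5, range \[0, 1\].
#' @param fraud_score_cutoff Platform RelevantID fraud threshold: fraud if
#'   score >= cutoff. Default 30, range \[0, 130\].
#' @param dup_score_cutoff Platform RelevantID duplicate threshold: fraud if
#'   score >= cutoff. Default 75, range \[0, 100\].
#' @param key_items Screener/main items expected to be stable; each must
#'   appear as columns `scr_<item>` and `main_<item>` in the response table.
#' @param allowed_country ISO country code whose IPs are not flagged as
#'   offshore. Default "US".
#' @param chi_square_correct Apply Yates continuity correction in
#'   [chi_square_test()]. Default FALSE.
#' @param column_map Named character vector canonical-field -> source column
#'   header, for exports whose headers differ from the canonical names.
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `fd_config` (a named list).
#' @seealso [read_config()], [apply_realtime_stage()], [apply_posthoc_stage()]
#' @examples
#' cfg <- fd_config(k_strike = 2)
#' cfg$text_tiers
#' @export
fd_config <- function(k_strike = 2L,
                      rapid_window_minutes = 1,
                      rapid_min_others = 2L,
                      address_overuse_prior_count = 2L,
                      text_tiers = default_text_tiers(),
                      recaptcha_cutoff = 0.5,
                      fraud_score_cutoff = 30,
                      dup_score_cutoff = 75,
                      key_items = c("age", "zip", "adults_home", "minors_home",
                                    "hispanic", "ever_tested", "vaccinated"),
                      allowed_country = "US",
                      chi_square_correct = FALSE,
                      column_map = NULL,
                      seed = 1L) {
  if (!k_strike %in% 1:3) {
    abort("`k_strike` must be 1, 2 or 3.", class = "surveysieve_config_error")
  }
  text_tiers <- as_tibble(text_tiers)
  stopifnot(all(c("min_words", "min_repeats") %in% names(text_tiers)))
  if (is.unsorted(text_tiers$min_words, strictly = TRUE)) {
    abort("`text_tiers` must be sorted by min_words ascending.",
          class = "surveysieve_config_error")
  }
  check_range <- function(val, lo, hi, what) {
    if (!is.numeric(val) || val < lo || val > hi) {
      abort(sprintf("`%s` must lie in [%s, %s].", what, lo, hi),
            class = "surveysieve_config_error")
    }
  }
  check_range(recaptcha_cutoff, 0, 1, "recaptcha_cutoff")
  check_range(fraud_score_cutoff, 0, 130, "fraud_score_cutoff")
  check_range(dup_score_cutoff, 0, 100, "dup_score_cutoff")
  structure(
    list(
      k_strike = as.integer(k_strike),
      rapid_window_minutes = rapid_window_minutes,
      rapid_min_others = as.integer(rapid_min_others),
      address_overuse_prior_count = as.integer(address_overuse_prior_count),
      text_tiers = text_tiers,
      recaptcha_cutoff = recaptcha_cutoff,
      fraud_score_cutoff = fraud_score_cutoff,
      dup_score_cutoff = dup_score_cutoff,
      key_items = key_items,
      allowed_country = allowed_country,
      chi_square_correct = isTRUE(chi_square_correct),
      column_map = column_map,
      seed = as.integer(seed)
    ),
    class = "fd_config"
  )
}

#' @rdname fd_config
#' @export
default_text_tiers <- function() {
  tibble(min_words = c(1L, 2L, 3L), min_repeats = c(100L, 10L, 3L))
}

#' Read a detection configuration from a YAML or JSON file
#'
#' Every key of [fd_config()] may appear in the file; absent keys keep their
#' defaults. `text_tiers` is given as a list of `[min_words, min_repeats]`
#' pairs, `column_map` as a mapping canonical-field: source-header.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `fd_config` object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$text_tiers)) {
    tiers <- raw$text_tiers
    if (is.list(tiers) && !is.data.frame(tiers)) {
      tiers <- do.call(rbind, lapply(tiers, function(p) {
        tibble(min_words = as.integer(p[[1]]), min_repeats = as.integer(p[[2]]))
      }))
    }
    raw$text_tiers <- as_tibble(tiers)
  }
  if (!is.null(raw$column_map)) raw$column_map <- unlist(raw$column_map)
  known <- names(formals(fd_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown config keys: ",
                paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(fd_config, raw)
}

#' @export
print.fd_config <- function(x, ...) {
  cat("<fd_config>\n")
  cat("  k-strike rule:      k =", x$k_strike, "\n")
  cat("  rapid submission:   +/-", x$rapid_window_minutes, "min, >=",
      x$rapid_min_others, "others\n")
  cat("  address overuse:    >=", x$address_overuse_prior_count,
      "prior reporters\n")
  cat("  text tiers:        ",
      paste(sprintf("(%d w, %d rep)", x$text_tiers$min_words,
                    x$text_tiers$min_repeats), collapse = " "), "\n")
  cat("  platform cutoffs:   recaptcha <", x$recaptcha_cutoff,
      "| fraud >=", x$fraud_score_cutoff, "| dup >=", x$dup_score_cutoff, "\n")
  cat("  key items:         ", paste(x$key_items, collapse = ", "), "\n")
  invisible(x)
}
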