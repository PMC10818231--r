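#' Read a survey-response export
#'
#' Reads a delimited export (CSV, one header row, UTF-8, one row per
#' submission) into the canonical response table used by every classifier
#' stage. The canonical columns are: `response_id`, `start_time`, `end_time`,
#' `email`, `street_address`, `zip_code`, `neighborhood_name`, `ip_address`,
#' `referral_url`, `free_text_comment`, `survey_type` (adult/parent/youth),
#' `honeypot_answer`, the platform scores `recaptcha_v3` (0-1),
#' `relevantid_fraud` (0-130), `relevantid_dup` (0-100), and `completed`.
#' Screener and main-survey key items travel as `scr_<item>` / `main_<item>`
#' columns; any further columns (demographics, outcomes) are carried through
#' untouched.
#'
#' A `column_map` in the configuration (canonical field -> source header)
#' absorbs exports whose headers differ, e.g. a platform's multi-header
#' dialect flattened upstream. Timestamps are parsed to at least minute
#' precision; missing optional fields become `NA`.
#'
#' @param path CSV file path.
#' @param config An [fd_config()]; its `column_map` is applied if non-NULL.
#' @return A tibble with one row per submission, in file order.
#' @export
read_responses <- function(path, config = fd_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  cmap <- config$column_map
  if (!is.null(cmap)) {
    missing_src <- cmap[!cmap %in% names(raw)]
    if (length(missing_src) > 0) {
      abort(paste0("column_map points at absent column(s): ",
                   paste(sprintf("%s -> %s", names(missing_src), missing_src),
                         collapse = ", ")),
            class = "surveysieve_config_error")
    }
    names(raw)[match(cmap, names(raw))] <- names(cmap)
  }
  absent <- setdiff(.mandatory_fields, names(raw))
  if (length(absent) > 0) {
    abort(paste0("Mandatory column(s) missing from export (map them via ",
                 "column_map): ", paste(absent, collapse = ", ")),
          class = "surveysieve_config_error")
  }
  for (f in setdiff(.canonical_fields, names(raw))) raw[[f]] <- NA_character_
  out <- as_tibble(raw)
  out$start_time <- parse_timestamp(out$start_time, "start_time")
  out$end_time <- parse_timestamp(out$end_time, "end_time")
  for (f in c("recaptcha_v3", "relevantid_fraud", "relevantid_dup")) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  out$completed <- if (all(is.na(out$completed))) {
    rep(NA, nrow(out))
  } else {
    tolower(out$completed) %in% c("true", "t", "1", "yes")
  }
  check_score_ranges(out)
  out
}

parse_timestamp <- function(x, what) {
  parsed <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(parsed) & !is.na(x)
    if (!any(todo)) break
    parsed[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  bad <- which(!is.na(x) & is.na(parsed))
  if (length(bad) > 0) {
    abort(sprintf("Unparseable %s at data row(s) %s (e.g. \"%s\").",
                  what, paste(utils::head(bad, 5), collapse = ", "),
                  x[bad[1]]),
          class = "surveysieve_data_error")
  }
  parsed
}

check_score_ranges <- function(responses) {
  ranges <- list(recaptcha_v3 = c(0, 1), relevantid_fraud = c(0, 130),
                 relevantid_dup = c(0, 100))
  for (f in names(ranges)) {
    v <- responses[[f]]
    out_of <- !is.na(v) & (v < ranges[[f]][1] | v > ranges[[f]][2])
    if (any(out_of)) {
      warn(sprintf("%d value(s) of %s outside [%s, %s]; kept as-is.",
                   sum(out_of), f, ranges[[f]][1], ranges[[f]][2]))
    }
  }
  invisible(responses)
}

#' @rdname read_responses
#' @param responses A response tibble (as returned by [read_responses()] or
#'   [generate_cohort()]).
#' @export
write_responses <- function(responses, path) {
  out <- responses
  for (f in intersect(c("start_time", "end_time"), names(out))) {
    out[[f]] <- format(out[[f]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# order used by every "earlier response" rule: start time, ties by id
order_chronologically <- function(responses) {
  responses[order(responses$start_time, responses$response_id), ]
}
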