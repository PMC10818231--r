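#' Normalize free text, addresses, emails and URLs for matching
#'
#' All duplicate-detection rules compare *normalized* strings: lowercased,
#' trimmed, with internal whitespace collapsed to single spaces. The address
#' variant is additionally punctuation-insensitive, so "123 Main St." and
#' "123 main st" compare equal. Normalization is idempotent.
#'
#' @param x Character vector (NA passes through as NA).
#' @param address If `TRUE`, strip punctuation before collapsing whitespace
#'   (used for street-address comparison).
#' @return Character vector of the same length.
#' @examples
#' normalize_text("  Great   Survey ")
#' normalize_text("123 Main St.", address = TRUE)
#' @export
normalize_text <- function(x, address = FALSE) {
  x <- tolower(as.character(x))
  if (address) x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# emails: lowercase + trim only; deliberately no plus-addressing collapse,
# the duplicate rule is exact match of the address as entered
normalize_email <- function(x) {
  trimws(tolower(as.character(x)))
}

# referral URLs compare scheme- and trailing-slash-insensitively
normalize_url <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x <- sub("^[a-z][a-z0-9+.-]*://", "", x)
  sub("/+$", "", x)
}

# empty-after-normalization test used by honeypot and free-text rules
is_blank <- function(x) {
  is.na(x) | normalize_text(x) == ""
}

# timestamps are compared at minute resolution; truncate to whole minutes
# since epoch
minute_of <- function(t) {
  as.numeric(floor(as.numeric(t) / 60))
}
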