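#' Reference gazetteer for address, URL and IP verification
#'
#' The gazetteer bundles the lookup tables the real-time and post hoc rules
#' check responses against: a residential address index mapping each known
#' address to its canonical neighborhood, a symmetric neighborhood adjacency
#' relation, the set of nonstandard (PO box / unique) zip codes, the set of
#' recruitment URLs distributed by the study team, and an IP-intelligence
#' table of IPv4 CIDR prefixes with VPN/data-center status and country code.
#'
#' Adjacency is symmetrized on construction: an edge A-B implies B-A. Every
#' neighborhood named in the address index receives an adjacency entry
#' (possibly empty).
#'
#' @param addresses Data frame with columns `address`, `neighborhood`.
#' @param adjacency Data frame with columns `neighborhood_a`, `neighborhood_b`
#'   (one row per edge; symmetrized automatically).
#' @param nonstandard_zips Character vector of zip codes.
#' @param valid_urls Character vector of distributed recruitment URLs.
#' @param ip_intel Data frame with columns `prefix` (IPv4 CIDR, e.g.
#'   `"203.0.113.0/24"`), `is_vpn` (logical), `country` (ISO code).
#' @return An object of class `gazetteer`.
#' @seealso [read_gazetteer()], [rule_invalid_address()], [flag_bad_ip()]
#' @export
gazetteer <- function(addresses = NULL, adjacency = NULL,
                      nonstandard_zips = character(),
                      valid_urls = character(), ip_intel = NULL) {
  if (is.null(addresses)) {
    addresses <- tibble(address = character(), neighborhood = character())
  }
  addresses <- as_tibble(addresses)
  stopifnot(all(c("address", "neighborhood") %in% names(addresses)))
  addresses$.norm <- normalize_text(addresses$address, address = TRUE)
  dup <- addresses %>%
    distinct(.data$.norm, .data$neighborhood) %>%
    count(.data$.norm) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Conflicting neighborhoods for address(es): ",
                 paste(utils::head(dup$.norm, 5), collapse = "; ")),
          class = "surveysieve_data_error")
  }
  addresses <- distinct(addresses, .data$.norm, .keep_all = TRUE)

  adj <- list()
  if (!is.null(adjacency) && nrow(as_tibble(adjacency)) > 0) {
    adjacency <- as_tibble(adjacency)
    stopifnot(all(c("neighborhood_a", "neighborhood_b") %in% names(adjacency)))
    a <- normalize_text(adjacency$neighborhood_a)
    b <- normalize_text(adjacency$neighborhood_b)
    asym <- !paste(b, a) %in% paste(a, b)
    if (any(asym)) {
      inform(sprintf(
        "Symmetrized %d one-directional adjacency edge(s) on load.",
        sum(asym)))
    }
    edges <- unique(data.frame(from = c(a, b), to = c(b, a)))
    adj <- split(edges$to, edges$from)
  }
  for (nb in unique(normalize_text(addresses$neighborhood))) {
    if (is.null(adj[[nb]])) adj[[nb]] <- character()
  }

  ipt <- parse_ip_intel(ip_intel)

  structure(
    list(
      address_index = addresses,
      adjacency = adj,
      nonstandard_zips = as.character(nonstandard_zips),
      valid_urls = normalize_url(valid_urls),
      ip_intel = ipt
    ),
    class = "gazetteer"
  )
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer>\n")
  cat("  addresses:       ", nrow(x$address_index), "\n")
  cat("  neighborhoods:   ", length(x$adjacency), "\n")
  cat("  nonstandard zips:", length(x$nonstandard_zips), "\n")
  cat("  valid URLs:      ", length(x$valid_urls), "\n")
  cat("  IP prefixes:     ", nrow(x$ip_intel), "\n")
  invisible(x)
}

#' Read or write a gazetteer directory
#'
#' A gazetteer is stored as a directory of five CSV files:
#' `addresses.csv` (address, neighborhood), `adjacency.csv`
#' (neighborhood_a, neighborhood_b), `zips.csv` (zip, status),
#' `urls.csv` (url) and `ip_intel.csv` (prefix, is_vpn, country).
#' Missing files yield empty tables (e.g. an absent `ip_intel.csv` means all
#' IP lookups report unknown).
#'
#' @param dir Directory path.
#' @return `read_gazetteer()` returns a `gazetteer`; `write_gazetteer()`
#'   returns `dir` invisibly.
#' @export
read_gazetteer <- function(dir) {
  rd <- function(file, col_names) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      return(as_tibble(setNames(
        rep(list(character()), length(col_names)), col_names)))
    }
    readr::read_csv(p, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  addresses <- rd("addresses.csv", c("address", "neighborhood"))
  adjacency <- rd("adjacency.csv", c("neighborhood_a", "neighborhood_b"))
  zips <- rd("zips.csv", c("zip", "status"))
  urls <- rd("urls.csv", "url")
  ipt <- rd("ip_intel.csv", c("prefix", "is_vpn", "country"))
  if (nrow(ipt) > 0) {
    ipt$is_vpn <- tolower(ipt$is_vpn) %in% c("true", "t", "1", "yes")
  }
  gazetteer(
    addresses = addresses,
    adjacency = adjacency,
    nonstandard_zips = zips$zip,
    valid_urls = urls$url,
    ip_intel = if (nrow(ipt) > 0) ipt else NULL
  )
}

#' @rdname read_gazetteer
#' @param g A `gazetteer` object.
#' @export
write_gazetteer <- function(g, dir) {
  stopifnot(inherits(g, "gazetteer"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(g$address_index[c("address", "neighborhood")],
                   file.path(dir, "addresses.csv"))
  edges <- adjacency_edges(g)
  readr::write_csv(edges, file.path(dir, "adjacency.csv"))
  readr::write_csv(tibble(zip = g$nonstandard_zips, status = "nonstandard"),
                   file.path(dir, "zips.csv"))
  readr::write_csv(tibble(url = g$valid_urls), file.path(dir, "urls.csv"))
  ipt <- g$ip_intel
  readr::write_csv(ipt[c("prefix", "is_vpn", "country")],
                   file.path(dir, "ip_intel.csv"))
  invisible(dir)
}

adjacency_edges <- function(g) {
  from <- rep(names(g$adjacency), lengths(g$adjacency))
  to <- unlist(g$adjacency, use.names = FALSE)
  if (is.null(from)) from <- character()
  if (is.null(to)) to <- character()
  keep <- from < to   # one row per undirected edge
  tibble(neighborhood_a = from[keep], neighborhood_b = to[keep])
}

# address -> canonical neighborhood (normalized); NA when not in the index
lookup_neighborhood <- function(g, address) {
  norm <- normalize_text(address, address = TRUE)
  idx <- match(norm, g$address_index$.norm)
  normalize_text(g$address_index$neighborhood[idx])
}

## ---- IPv4 CIDR longest-prefix matching ------------------------------------

ipv4_to_num <- function(ip) {
  parts <- strsplit(as.character(ip), ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 4) return(NA_real_)
    o <- suppressWarnings(as.numeric(p))
    if (anyNA(o) || any(o < 0 | o > 255 | o != floor(o))) return(NA_real_)
    sum(o * 256^(3:0))
  }, numeric(1))
}

parse_ip_intel <- function(ip_intel) {
  if (is.null(ip_intel) || nrow(as_tibble(ip_intel)) == 0) {
    return(tibble(prefix = character(), is_vpn = logical(),
                  country = character(), .base = numeric(), .bits = integer()))
  }
  ipt <- as_tibble(ip_intel)
  stopifnot(all(c("prefix", "is_vpn", "country") %in% names(ipt)))
  m <- regmatches(ipt$prefix, regexec("^([0-9.]+)/([0-9]+)$", ipt$prefix))
  base <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  bits <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else
                   NA_integer_, integer(1))
  ipt$.base <- ipv4_to_num(base)
  ipt$.bits <- bits
  bad <- is.na(ipt$.base) | is.na(ipt$.bits) | ipt$.bits < 0 | ipt$.bits > 32
  if (any(bad)) {
    warn(sprintf("Dropping %d malformed IP prefix(es) from ip_intel.",
                 sum(bad)))
    ipt <- ipt[!bad, ]
  }
  ipt$is_vpn <- as.logical(ipt$is_vpn)
  # truncate base to its prefix so "1.2.3.4/24" behaves as "1.2.3.0/24"
  ipt$.base <- floor(ipt$.base / 2^(32 - ipt$.bits)) * 2^(32 - ipt$.bits)
  ipt
}

# longest-prefix lookup; returns a tibble row (is_vpn, country) or NA row
ip_lookup <- function(g, ip) {
  n <- length(ip)
  out <- tibble(is_vpn = rep(NA, n), country = rep(NA_character_, n))
  if (nrow(g$ip_intel) == 0) return(out)
  num <- ipv4_to_num(ip)
  for (i in seq_len(n)) {
    if (is.na(num[i])) next
    hit <- which(floor(num[i] / 2^(32 - g$ip_intel$.bits)) *
                   2^(32 - g$ip_intel$.bits) == g$ip_intel$.base)
    if (length(hit) == 0) next
    best <- hit[which.max(g$ip_intel$.bits[hit])]
    out$is_vpn[i] <- g$ip_intel$is_vpn[best]
    out$country[i] <- g$ip_intel$country[best]
  }
  out
}
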