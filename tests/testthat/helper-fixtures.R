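# shared fixtures: a 4-address gazetteer and a clean-response factory

tiny_gazetteer <- function() {
  suppressMessages(gazetteer(
    addresses = tibble::tibble(
      address = c("1 Oak St", "2 Oak St", "3 Elm St", "4 Pine St"),
      neighborhood = c("Fishtown", "Fishtown", "Kensington", "Chestnut Hill")
    ),
    adjacency = tibble::tibble(
      neighborhood_a = "Fishtown", neighborhood_b = "Kensington"
    ),
    nonstandard_zips = "19901",
    valid_urls = "https://study.example.org/fb",
    ip_intel = tibble::tibble(
      prefix = c("198.51.100.0/24", "192.0.2.0/24", "203.0.113.0/24"),
      is_vpn = c(TRUE, FALSE, FALSE),
      country = c("US", "CA", "US")
    )
  ))
}

# n clean responses against tiny_gazetteer(); override any column by name
make_responses <- function(n = 1, ...) {
  base_start <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  out <- tibble::tibble(
    response_id = sprintf("r%03d", seq_len(n)),
    start_time = base_start + (seq_len(n) - 1) * 180,
    end_time = base_start + (seq_len(n) - 1) * 180 + 20 * 60,
    email = sprintf("person%03d@mail.example.com", seq_len(n)),
    street_address = "1 Oak St",
    zip_code = "19104",
    neighborhood_name = "Fishtown",
    ip_address = "203.0.113.5",
    referral_url = "https://study.example.org/fb",
    free_text_comment = "",
    survey_type = "adult",
    honeypot_answer = "",
    recaptcha_v3 = 0.9,
    relevantid_fraud = 5,
    relevantid_dup = 10,
    completed = TRUE,
    scr_age = 34, main_age = 34,
    scr_zip = "19104", main_zip = "19104"
  )
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

label_frame <- function(ids, labels) {
  tibble::tibble(response_id = ids, label = labels)
}
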