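#' Specify a synthetic respondent cohort
#'
#' Parameters of a seeded synthetic survey-response stream: genuine
#' respondents plus six fraud archetypes, each of which violates the
#' detection rule(s) it is named for. The defaults emulate a city-wide
#' web-survey recruitment: a roughly 110-day field period with three social
#' media campaign windows, genuine completion times lognormal around a
#' 23.5-minute median, and a fraud mix dominated by scripted bursts.
#'
#' Archetypes:
#' * `bot_burst` — clusters of 3 submissions sharing start and stop times
#'   (within the rapid-submission window), with low reCAPTCHA scores;
#' * `duplicate_farm` — re-submitters reusing the email address of an
#'   earlier genuine respondent (and posting shared boilerplate comments);
#' * `vpn_actor` — IPs inside VPN/data-center or offshore prefixes, plus
#'   boilerplate duplicate free text (so they carry the 2 strikes the
#'   default k-strike rule requires);
#' * `inconsistent_screener` — a key item answered differently in screener
#'   and main survey, plus boilerplate duplicate free text;
#' * `address_reuser` — reuses the residential address of a two-respondent
#'   genuine household, making the reuser the 3rd+ reporter;
#' * `url_spoofer` — referral URL not among the distributed recruitment URLs.
#'
#' @param n_genuine Number of genuine respondents. Default 500.
#' @param archetype_counts Named integer vector over the six archetypes.
#' @param study_start First day of the field period (Date or string).
#' @param study_days Length of the field period in days.
#' @param campaign_windows List of `c(start_day, end_day)` pairs (1-based
#'   days) during which recruitment is active; genuine arrivals concentrate
#'   inside these windows.
#' @param household_fraction Fraction of genuine respondents recruited as
#'   two-person households sharing an address (legitimate address sharing;
#'   also the substrate the `address_reuser` archetype exploits).
#' @param genuine_contamination Probability that a genuine respondent draws a
#'   platform score breaching a threshold (models platform false positives
#'   and produces method disagreement). Default 0.05.
#' @param archetype_flag_prob Probability that a fraud response (other than
#'   `bot_burst`, which always draws a low reCAPTCHA score) breaches a
#'   RelevantID threshold. Default 0.7.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_genuine = 500L,
                        archetype_counts = c(bot_burst = 60L,
                                             duplicate_farm = 40L,
                                             vpn_actor = 40L,
                                             inconsistent_screener = 40L,
                                             address_reuser = 40L,
                                             url_spoofer = 40L),
                        study_start = as.Date("2021-11-01"),
                        study_days = 110L,
                        campaign_windows = list(c(3L, 18L), c(29L, 52L),
                                                c(99L, 102L)),
                        household_fraction = 0.2,
                        genuine_contamination = 0.05,
                        archetype_flag_prob = 0.7,
                        seed = 1L) {
  known <- c("bot_burst", "duplicate_farm", "vpn_actor",
             "inconsistent_screener", "address_reuser", "url_spoofer")
  counts <- setNames(rep(0L, length(known)), known)
  counts[names(archetype_counts)] <- as.integer(archetype_counts)
  if (any(counts < 0) || n_genuine < 0) {
    abort("Cohort counts must be nonnegative.",
          class = "surveysieve_config_error")
  }
  for (w in campaign_windows) {
    if (w[1] < 1 || w[2] > study_days || w[1] > w[2]) {
      abort("Campaign windows must lie within the study period.",
            class = "surveysieve_config_error")
    }
  }
  structure(
    list(n_genuine = as.integer(n_genuine), archetype_counts = counts,
         study_start = as.Date(study_start), study_days = as.integer(study_days),
         campaign_windows = campaign_windows,
         household_fraction = household_fraction,
         genuine_contamination = genuine_contamination,
         archetype_flag_prob = archetype_flag_prob,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic respondent cohort with ground truth
#'
#' Draws a full response stream per a [cohort_spec()]: genuine respondents
#' with valid gazetteer addresses, matching neighborhood names, distinct
#' emails (except legitimate households, which share only an address),
#' consistent screener/main answers, in-country IPs, distributed referral
#' URLs, and completion durations lognormal around a 23.5-minute median;
#' plus each requested fraud archetype, violating exactly its targeted
#' rules. Platform scores are drawn so genuine respondents score clean up to
#' a contamination rate while archetype responses breach thresholds with the
#' configured probability.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `responses` (tibble in the
#'   canonical response shape, chronological order), `truth` (tibble
#'   `response_id`, `is_fraud`, `archetype`), and `gazetteer` (a matching
#'   [gazetteer()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genuine = 30, seed = 42))
#' table(cohort$truth$is_fraud)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, build_cohort(spec))
}

build_cohort <- function(spec) {
  counts <- spec$archetype_counts
  n_gen <- spec$n_genuine
  n_total <- n_gen + sum(counts)

  neighborhoods <- paste0("district ", sprintf("%02d", 1:12))
  n_addr <- n_total + 50L
  streets <- c("Maple St", "Cedar Ave", "Birch Rd", "Walnut Ln", "Spruce Dr",
               "Chestnut Ct", "Poplar Way", "Sycamore Ter")
  addresses <- tibble(
    address = paste(100 + seq_len(n_addr),
                    streets[(seq_len(n_addr) - 1) %% length(streets) + 1]),
    neighborhood = neighborhoods[(seq_len(n_addr) - 1) %% 12 + 1]
  )
  # ring adjacency: each district borders its two neighbors (both edge
  # directions listed so the gazetteer loads without symmetrization notes)
  adjacency <- tibble(
    neighborhood_a = c(neighborhoods, neighborhoods[c(2:12, 1)]),
    neighborhood_b = c(neighborhoods[c(2:12, 1)], neighborhoods)
  )
  standard_zips <- sprintf("191%02d", 1:48)
  nonstandard_zips <- c("19901", "19902", "19903")
  valid_urls <- c("https://study.example.org/fb", "https://study.example.org/ig",
                  "https://study.example.org/tw", "https://study.example.org/cp")
  ip_intel <- tibble(
    prefix = c("203.0.113.0/24", "198.51.100.0/24", "192.0.2.0/24"),
    is_vpn = c(FALSE, TRUE, FALSE),
    country = c("US", "US", "CA")
  )
  g <- gazetteer(addresses, adjacency, nonstandard_zips, valid_urls, ip_intel)

  zip_of <- function(k) standard_zips[(k - 1) %% 48 + 1]
  draw_times <- function(n) {
    day_w <- rep(0.12, spec$study_days)
    for (w in spec$campaign_windows) day_w[w[1]:w[2]] <- 1
    day <- sample.int(spec$study_days, n, replace = TRUE, prob = day_w) - 1L
    minute <- sample.int(1440L, n, replace = TRUE) - 1L
    as.POSIXct(spec$study_start, tz = "UTC") + (day * 1440 + minute) * 60
  }
  draw_duration <- function(n) {
    # median 23.5 min, IQR ratio ~2.1 -> lognormal(meanlog 3.157, sdlog 0.54)
    pmax(5, round(stats::rlnorm(n, meanlog = log(23.5), sdlog = 0.54)))
  }
  base_row <- function(n, archetype) {
    k <- seq_len(n)
    start <- draw_times(n)
    tibble(
      archetype = archetype,
      start_time = start,
      end_time = start + draw_duration(n) * 60,
      email = NA_character_, street_address = NA_character_,
      zip_code = NA_character_, neighborhood_name = NA_character_,
      ip_address = sprintf("203.0.113.%d", sample.int(254, n, replace = TRUE)),
      referral_url = sample(valid_urls, n, replace = TRUE),
      free_text_comment = "", survey_type = sample(
        c("adult", "parent", "youth"), n, replace = TRUE,
        prob = c(0.35, 0.5, 0.15)),
      honeypot_answer = "", completed = TRUE
    )
  }
  addr_pool <- addresses
  next_addr <- 0L
  take_addresses <- function(n) {
    idx <- next_addr + seq_len(n)
    next_addr <<- next_addr + n
    addr_pool[idx, ]
  }

  ## genuine respondents -----------------------------------------------------
  gen <- base_row(n_gen, NA_character_)
  n_house <- floor(n_gen * spec$household_fraction / 2)
  house_addr <- take_addresses(n_house)
  solo_addr <- take_addresses(n_gen - 2 * n_house)
  gen_addr <- bind_rows(house_addr[rep(seq_len(n_house), each = 2), ],
                        solo_addr)
  gen$street_address <- gen_addr$address
  gen$neighborhood_name <- gen_addr$neighborhood
  gen$zip_code <- zip_of(seq_len(n_gen))
  gen$email <- sprintf("resident%04d@mail.example.com", seq_len(n_gen))
  # free text: mostly empty or unique; a small Zipf-like pool of short
  # pleasantries repeats, deliberately kept below the duplicate-text tiers
  # for 1-word strings (2-word pool strings may occasionally cross a tier,
  # a realistic single-strike coincidence)
  pool1 <- c("thanks", "good", "none", "no", "ok", "fine", "done", "great")
  pool2 <- c("great survey", "no questions")
  kind <- sample(c("empty", "unique", "pool1", "pool2"), n_gen, replace = TRUE,
                 prob = c(0.55, 0.25, 0.16, 0.04))
  gen$free_text_comment <- ifelse(
    kind == "empty", "",
    ifelse(kind == "unique",
           sprintf("detailed comment number %d", seq_len(n_gen)),
           ifelse(kind == "pool1", sample(pool1, n_gen, replace = TRUE),
                  sample(pool2, n_gen, replace = TRUE))))
  # occasional unmatched private-range IPs: unknown origin is not flagged
  unk <- stats::runif(n_gen) < 0.05
  gen$ip_address[unk] <- sprintf("172.16.0.%d",
                                 sample.int(254, sum(unk), replace = TRUE))

  rows <- list(genuine = gen)

  ## bot_burst: clusters of 3 sharing start and stop minutes ----------------
  if (counts["bot_burst"] > 0) {
    n <- counts["bot_burst"]
    if (n < 3) {
      abort("bot_burst needs at least 3 responses to form a cluster.",
            class = "surveysieve_config_error")
    }
    # clusters of 3; a remainder enlarges the last cluster so no burst
    # response falls below the min_others threshold
    sizes <- rep(3L, n %/% 3)
    sizes[length(sizes)] <- sizes[length(sizes)] + n %% 3
    n_clusters <- length(sizes)
    ct <- draw_times(n_clusters)
    cd <- draw_duration(n_clusters)
    bot <- base_row(n, "bot_burst")
    bot$start_time <- rep(ct, sizes)
    bot$end_time <- bot$start_time + rep(cd, sizes) * 60
    ba <- take_addresses(n)
    bot$street_address <- ba$address
    bot$neighborhood_name <- ba$neighborhood
    bot$zip_code <- zip_of(seq_len(n))
    bot$email <- sprintf("burst%04d@botmail.example.net", seq_len(n))
    rows$bot_burst <- bot
  }

  ## duplicate_farm: reuse genuine emails, post boilerplate ------------------
  if (counts["duplicate_farm"] > 0) {
    n <- counts["duplicate_farm"]
    if (n > n_gen) {
      abort("duplicate_farm cannot exceed n_genuine (each reuses a distinct genuine email).",
            class = "surveysieve_config_error")
    }
    farm <- base_row(n, "duplicate_farm")
    victims <- sample.int(n_gen, n, replace = FALSE)
    farm$email <- gen$email[victims]
    farm$start_time <- pmin(gen$start_time[victims] +
                              stats::runif(n, 120, 10000) * 60,
                            max(gen$start_time) + 1440 * 60)
    farm$end_time <- farm$start_time + draw_duration(n) * 60
    fa <- take_addresses(n)
    farm$street_address <- fa$address
    farm$neighborhood_name <- fa$neighborhood
    farm$zip_code <- zip_of(seq_len(n))
    farm$free_text_comment <- boilerplate(n, "compensation please send card")
    rows$duplicate_farm <- farm
  }

  ## vpn_actor: VPN/offshore IP + boilerplate text ---------------------------
  if (counts["vpn_actor"] > 0) {
    n <- counts["vpn_actor"]
    vpn <- base_row(n, "vpn_actor")
    offshore <- stats::runif(n) < 0.5
    vpn$ip_address <- ifelse(
      offshore,
      sprintf("192.0.2.%d", sample.int(254, n, replace = TRUE)),
      sprintf("198.51.100.%d", sample.int(254, n, replace = TRUE)))
    va <- take_addresses(n)
    vpn$street_address <- va$address
    vpn$neighborhood_name <- va$neighborhood
    vpn$zip_code <- zip_of(seq_len(n))
    vpn$email <- sprintf("relay%04d@proxy.example.net", seq_len(n))
    vpn$free_text_comment <- boilerplate(n, "very nice survey thanks")
    rows$vpn_actor <- vpn
  }

  ## inconsistent_screener: key-item mismatch + boilerplate text -------------
  if (counts["inconsistent_screener"] > 0) {
    n <- counts["inconsistent_screener"]
    inc <- base_row(n, "inconsistent_screener")
    ia <- take_addresses(n)
    inc$street_address <- ia$address
    inc$neighborhood_name <- ia$neighborhood
    inc$zip_code <- zip_of(seq_len(n))
    inc$email <- sprintf("applicant%04d@mail.example.net", seq_len(n))
    inc$free_text_comment <- boilerplate(n, "looking forward to payment")
    rows$inconsistent_screener <- inc
  }

  ## address_reuser: 3rd+ reporter of a genuine household address ------------
  if (counts["address_reuser"] > 0) {
    n <- counts["address_reuser"]
    if (n_house == 0) {
      abort("address_reuser archetype needs household_fraction > 0.",
            class = "surveysieve_config_error")
    }
    reuse <- base_row(n, "address_reuser")
    hh <- (seq_len(n) - 1) %% n_house + 1
    reuse$street_address <- house_addr$address[hh]
    reuse$neighborhood_name <- house_addr$neighborhood[hh]
    reuse$zip_code <- zip_of(seq_len(n))
    reuse$email <- sprintf("mover%04d@mail.example.net", seq_len(n))
    # must postdate both genuine household members
    latest <- vapply(hh, function(h) {
      max(as.numeric(gen$start_time[c(2 * h - 1, 2 * h)]))
    }, numeric(1))
    reuse$start_time <- as.POSIXct(
      latest + stats::runif(n, 120, 10000) * 60,
      origin = "1970-01-01", tz = "UTC")
    reuse$end_time <- reuse$start_time + draw_duration(n) * 60
    rows$address_reuser <- reuse
  }

  ## url_spoofer: referral URL never distributed -----------------------------
  if (counts["url_spoofer"] > 0) {
    n <- counts["url_spoofer"]
    spoof <- base_row(n, "url_spoofer")
    sa <- take_addresses(n)
    spoof$street_address <- sa$address
    spoof$neighborhood_name <- sa$neighborhood
    spoof$zip_code <- zip_of(seq_len(n))
    spoof$email <- sprintf("clicker%04d@mail.example.net", seq_len(n))
    spoof$referral_url <- sample(
      c("https://gift-card-fast.example.net/go",
        "https://paid-surveys.example.net/list"), n, replace = TRUE)
    rows$url_spoofer <- spoof
  }

  resp <- bind_rows(rows)

  ## screener / main key items ----------------------------------------------
  n_all <- nrow(resp)
  age <- sample(16:75, n_all, replace = TRUE)
  items <- tibble(
    scr_age = age, main_age = age,
    scr_zip = resp$zip_code, main_zip = resp$zip_code,
    scr_adults_home = sample(1:4, n_all, replace = TRUE),
    scr_minors_home = sample(0:3, n_all, replace = TRUE),
    scr_hispanic = sample(c("yes", "no"), n_all, replace = TRUE,
                          prob = c(0.15, 0.85)),
    scr_ever_tested = sample(c("yes", "no"), n_all, replace = TRUE,
                             prob = c(0.88, 0.12)),
    scr_vaccinated = sample(c("yes", "no"), n_all, replace = TRUE,
                            prob = c(0.9, 0.1))
  )
  items$main_adults_home <- items$scr_adults_home
  items$main_minors_home <- items$scr_minors_home
  items$main_hispanic <- items$scr_hispanic
  items$main_ever_tested <- items$scr_ever_tested
  items$main_vaccinated <- items$scr_vaccinated
  bad <- which(resp$archetype %in% "inconsistent_screener")
  items$main_age[bad] <- items$scr_age[bad] +
    sample(c(-20:-5, 5:20), length(bad), replace = TRUE)

  ## demographics and outcome ------------------------------------------------
  race <- sample(c("White", "Black or African American", "Hispanic or Latinx",
                   "Asian", "Multiracial or others"),
                 n_all, replace = TRUE,
                 prob = c(0.5, 0.23, 0.14, 0.06, 0.07))
  genuine_mask <- is.na(resp$archetype)
  conf_p <- ifelse(genuine_mask, 0.85, 0.55)
  demo <- tibble(
    age = age, race_ethnicity = race,
    gender = sample(c("Woman", "Man", "Transgender or gender diverse"),
                    n_all, replace = TRUE, prob = c(0.55, 0.43, 0.02)),
    education = sample(c("High school or equivalent", "Some college",
                         "College graduate", "Graduate degree"),
                       n_all, replace = TRUE),
    vaccine_confident = stats::rbinom(n_all, 1, conf_p)
  )

  ## platform scores ---------------------------------------------------------
  recaptcha <- round(0.6 + 0.4 * stats::rbeta(n_all, 8, 1.5), 2)
  fraud_sc <- round(stats::runif(n_all, 0, 20))
  dup_sc <- round(stats::runif(n_all, 0, 40))
  contaminated <- genuine_mask & stats::runif(n_all) <
    spec$genuine_contamination
  fraud_sc[contaminated] <- round(stats::runif(sum(contaminated), 30, 80))
  is_bot <- resp$archetype %in% "bot_burst"
  recaptcha[is_bot] <- round(stats::runif(sum(is_bot), 0, 0.45), 2)
  other_fraud <- !genuine_mask & !is_bot
  breach <- other_fraud & stats::runif(n_all) < spec$archetype_flag_prob
  fraud_sc[breach] <- round(stats::runif(sum(breach), 30, 110))
  dup_dup <- resp$archetype %in% c("duplicate_farm", "address_reuser") &
    stats::runif(n_all) < spec$archetype_flag_prob
  dup_sc[dup_dup] <- round(stats::runif(sum(dup_dup), 75, 100))

  resp <- resp %>%
    mutate(recaptcha_v3 = recaptcha, relevantid_fraud = fraud_sc,
           relevantid_dup = dup_sc)
  resp <- as_tibble(cbind(resp, items, demo))

  ## chronological ids -------------------------------------------------------
  ord <- order(resp$start_time, resp$email)
  resp <- resp[ord, ]
  resp$response_id <- sprintf("S%d-R%05d", spec$seed, seq_len(n_all))
  resp <- resp %>% select("response_id", dplyr::everything())

  truth <- tibble(
    response_id = resp$response_id,
    is_fraud = !is.na(resp$archetype),
    archetype = resp$archetype
  )
  resp$archetype <- NULL

  structure(list(responses = resp, truth = truth, gazetteer = g),
            class = "synthetic_cohort")
}

# boilerplate free-text strings repeated >= 3 times per string (>= 3 words),
# so every user of a string crosses the 3-word duplicate tier
boilerplate <- function(n, stem) {
  grp <- ceiling(seq_len(n) / 3)
  if (n %% 3 > 0 && max(grp) > 1) grp[grp == max(grp)] <- max(grp) - 1
  sprintf("%s %03d", stem, grp)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  responses:", nrow(x$responses), "| true fraud:",
      sum(x$truth$is_fraud), "\n")
  tab <- table(x$truth$archetype, useNA = "no")
  for (a in names(tab)) cat(sprintf("    %-22s %5d\n", a, tab[[a]]))
  invisible(x)
}

#' Sensitivity/specificity of a classifier against ground truth
#'
#' Scores predicted labels against the ground truth of a synthetic cohort:
#' sensitivity = TP / (TP + FN) over true fraud, specificity = TN / (TN + FP)
#' over true genuine, plus positive and negative predictive values.
#' Undefined ratios (empty denominators) are reported as `NA`.
#'
#' @param predictions Label frame (`response_id`, `label`) or a result
#'   object; `"fraud"` is the positive class.
#' @param truth Tibble `response_id`, `is_fraud` (see [generate_cohort()]).
#' @return One-row tibble `sensitivity`, `specificity`, `ppv`, `npv`, plus
#'   the four underlying counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_classifier <- function(predictions, truth) {
  pred <- as_label_frame(predictions)
  if (!setequal(pred$response_id, truth$response_id)) {
    abort("Prediction and truth id sets differ.",
          class = "surveysieve_data_error")
  }
  m <- left_join(truth, pred, by = "response_id")
  tp <- sum(m$is_fraud & m$label == "fraud")
  fn <- sum(m$is_fraud & m$label == "valid")
  fp <- sum(!m$is_fraud & m$label == "fraud")
  tn <- sum(!m$is_fraud & m$label == "valid")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}
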