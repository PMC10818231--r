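#' Build a planted-violation cohort with exact rule-hit counts
#'
#' Deterministically constructs a response stream in which each detection
#' rule fires on an exactly specified number of responses, together with a
#' consistent gazetteer. Where [generate_cohort()] draws a random mixture,
#' this builder *plants* violations: every requested real-time rule count is
#' realized by responses violating exactly that rule (so first-match
#' attribution reproduces the counts), post hoc strikes follow an explicit
#' pattern over the stage-1 survivors, and survey type plus platform-score
#' labels follow explicit joint counts. It is the tool for reconstructing a
#' published flowchart or classification table as an executable data set:
#' feed it the printed counts and run the pipeline over the result.
#'
#' @param n_total Total number of responses.
#' @param realtime_counts Named vector over the seven real-time rules
#'   (`neighborhood_mismatch`, `invalid_address`, `rapid_submission`,
#'   `duplicate_email`, `nonstandard_zip`, `address_overuse`,
#'   `invalid_url`): responses planted to violate exactly that rule.
#' @param strike_patterns Named vector over strike combinations among the
#'   stage-1 survivors: `dup_ip_inc` (all three criteria), `dup_ip`,
#'   `dup_inc`, `ip_inc` (pairs), `dup`, `ip`, `inc` (singletons). The
#'   remaining survivors are clean. Criterion totals and k-strike counts
#'   follow from these.
#' @param joint_counts Tibble `survey_type`, `multilayer`, `platform`, `n`
#'   giving the joint distribution of survey type, multilayer label and
#'   platform label; must be consistent with the planted multilayer counts.
#'   `NULL` labels every response `adult` with clean platform scores.
#' @param platform_rule_counts Named vector (`platform_recaptcha`,
#'   `platform_fraud_score`, `platform_dup_score`): how many responses
#'   breach each platform threshold. Overlaps are resolved by nesting the
#'   reCAPTCHA breaches, then the needed duplicate-score breaches, inside
#'   the fraud-score breaches; infeasible combinations error.
#' @param study_start,study_days Field period; submissions are spread evenly
#'   (at least 2 minutes apart except planted rapid clusters).
#' @param seed Seed for the shuffles that decorrelate planted categories
#'   from time, stratum and platform assignment.
#' @return A `synthetic_cohort` (see [generate_cohort()]) whose `truth`
#'   marks planted realtime violators and 2+-strike responses as fraud;
#'   single-strike rows model coincidental suspicion among genuine
#'   respondents.
#' @examples
#' cohort <- generate_planted_cohort(
#'   n_total = 60,
#'   realtime_counts = c(invalid_address = 5, rapid_submission = 6),
#'   strike_patterns = c(dup_ip = 4, dup = 3),
#'   joint_counts = NULL, platform_rule_counts = NULL, seed = 1)
#' glance(apply_realtime_stage(cohort$responses, cohort$gazetteer))
#' @export
generate_planted_cohort <- function(
    n_total = 7950L,
    realtime_counts = c(neighborhood_mismatch = 1242L, invalid_address = 648L,
                        rapid_submission = 1397L, duplicate_email = 42L,
                        nonstandard_zip = 77L, address_overuse = 398L,
                        invalid_url = 403L),
    strike_patterns = c(dup_ip_inc = 12L, dup_ip = 200L, dup_inc = 250L,
                        ip_inc = 53L, dup = 1099L, ip = 129L, inc = 304L),
    joint_counts = default_joint_counts(),
    platform_rule_counts = c(platform_recaptcha = 498L,
                             platform_fraud_score = 2776L,
                             platform_dup_score = 938L),
    study_start = as.Date("2021-11-01"),
    study_days = 110L,
    seed = 1L) {
  rt_names <- setdiff(.realtime_rules, "honeypot")
  rt <- setNames(rep(0L, length(rt_names)), rt_names)
  rt[names(realtime_counts)] <- as.integer(realtime_counts)
  pat_names <- c("dup_ip_inc", "dup_ip", "dup_inc", "ip_inc",
                 "dup", "ip", "inc")
  pat <- setNames(rep(0L, length(pat_names)), pat_names)
  pat[names(strike_patterns)] <- as.integer(strike_patterns)
  n_surv <- n_total - sum(rt)
  n_clean <- n_surv - sum(pat)
  if (n_clean < 0) {
    abort("Planted counts exceed n_total.", class = "surveysieve_config_error")
  }
  if (rt["rapid_submission"] %in% 1:2) {
    abort("rapid_submission needs 0 or >= 3 planted responses.",
          class = "surveysieve_config_error")
  }
  need_donors <- rt["duplicate_email"] + 2 * ceiling(rt["address_overuse"] / 2)
  if (n_clean < need_donors) {
    abort(sprintf(
      "Need %d clean survivors to donate emails/addresses, have %d.",
      need_donors, n_clean), class = "surveysieve_config_error")
  }
  with_seed(seed, build_planted(n_total, rt, pat, n_clean, joint_counts,
                                platform_rule_counts, study_start,
                                study_days, seed))
}

#' @rdname generate_planted_cohort
#' @export
default_joint_counts <- function() {
  tibble(
    survey_type = rep(c("adult", "parent", "youth"), each = 4),
    multilayer = rep(c("fraud", "fraud", "valid", "valid"), 3),
    platform = rep(c("fraud", "valid", "fraud", "valid"), 3),
    n = c(299L, 174L, 166L, 904L,
          2184L, 1848L, 710L, 1102L,
          144L, 73L, 58L, 288L)
  )
}

build_planted <- function(n_total, rt, pat, n_clean, joint_counts,
                          platform_rule_counts, study_start, study_days,
                          seed) {
  category <- c(rep(names(rt), rt), rep(names(pat), pat),
                rep("clean", n_clean))
  n <- length(category)
  ml_fraud <- category %in% names(rt) |
    category %in% c("dup_ip_inc", "dup_ip", "dup_inc", "ip_inc")

  ## gazetteer ---------------------------------------------------------------
  neighborhoods <- paste0("district ", sprintf("%02d", 1:12))
  n_addr <- n + 10L
  addresses <- tibble(
    address = paste(100 + seq_len(n_addr), "Planted Ave"),
    neighborhood = neighborhoods[(seq_len(n_addr) - 1) %% 12 + 1]
  )
  adjacency <- tibble(
    neighborhood_a = c(neighborhoods, neighborhoods[c(2:12, 1)]),
    neighborhood_b = c(neighborhoods[c(2:12, 1)], neighborhoods))
  standard_zips <- sprintf("191%02d", 1:48)
  nonstandard_zips <- c("19901", "19902")
  valid_urls <- c("https://study.example.org/fb", "https://study.example.org/ig")
  ip_intel <- tibble(
    prefix = c("203.0.113.0/24", "198.51.100.0/24", "192.0.2.0/24"),
    is_vpn = c(FALSE, TRUE, FALSE),
    country = c("US", "US", "CA")
  )
  g <- gazetteer(addresses, adjacency, nonstandard_zips, valid_urls, ip_intel)

  ## default (clean) fields --------------------------------------------------
  addr_idx <- seq_len(n)
  street_address <- addresses$address[addr_idx]
  neighborhood_name <- addresses$neighborhood[addr_idx]
  zip_code <- standard_zips[(seq_len(n) - 1) %% 48 + 1]
  email <- sprintf("resp%05d@mail.example.com", seq_len(n))
  referral_url <- valid_urls[(seq_len(n) - 1) %% 2 + 1]
  ip_address <- sprintf("203.0.113.%d", (seq_len(n) - 1) %% 254 + 1)
  free_text <- rep("", n)
  scr_age <- 20 + (seq_len(n) %% 50)
  main_age <- scr_age

  idx_of <- function(what) which(category == what)

  ## real-time violations ----------------------------------------------------
  i <- idx_of("neighborhood_mismatch")
  neighborhood_name[i] <- neighborhoods[((addr_idx[i] - 1 + 6) %% 12) + 1]
  i <- idx_of("invalid_address")
  street_address[i] <- sprintf("%d Nowhere Rd", seq_along(i))
  i <- idx_of("nonstandard_zip")
  zip_code[i] <- nonstandard_zips[(seq_along(i) - 1) %% 2 + 1]
  i <- idx_of("invalid_url")
  referral_url[i] <- "https://gift-card-fast.example.net/go"

  clean_idx <- idx_of("clean")
  n_dup_email <- rt[["duplicate_email"]]
  email_donors <- clean_idx[seq_len(n_dup_email)]
  i <- idx_of("duplicate_email")
  email[i] <- email[email_donors]

  n_over <- rt[["address_overuse"]]
  n_over_addr <- ceiling(n_over / 2)
  addr_donors <- clean_idx[n_dup_email + seq_len(2 * n_over_addr)]
  donor_pair_addr <- addresses$address[addr_idx[addr_donors[
    seq(1, length(addr_donors), by = 2)]]]
  # both donors of a pair share the first donor's address
  street_address[addr_donors[seq(2, length(addr_donors), by = 2)]] <-
    donor_pair_addr
  neighborhood_name[addr_donors[seq(2, length(addr_donors), by = 2)]] <-
    neighborhood_name[addr_donors[seq(1, length(addr_donors), by = 2)]]
  i <- idx_of("address_overuse")
  use_addr <- rep(seq_len(n_over_addr), each = 2)[seq_len(n_over)]
  street_address[i] <- donor_pair_addr[use_addr]
  neighborhood_name[i] <-
    neighborhood_name[addr_donors[2 * use_addr - 1]]

  ## post hoc strikes --------------------------------------------------------
  dup_rows <- which(category %in% c("dup_ip_inc", "dup_ip", "dup_inc", "dup"))
  free_text[dup_rows] <- boilerplate(length(dup_rows),
                                     "thank you for the chance")
  ip_rows <- which(category %in% c("dup_ip_inc", "dup_ip", "ip_inc", "ip"))
  vpnish <- seq_along(ip_rows) %% 2 == 0
  ip_address[ip_rows] <- ifelse(
    vpnish, sprintf("198.51.100.%d", (seq_along(ip_rows) - 1) %% 254 + 1),
    sprintf("192.0.2.%d", (seq_along(ip_rows) - 1) %% 254 + 1))
  inc_rows <- which(category %in% c("dup_ip_inc", "dup_inc", "ip_inc", "inc"))
  main_age[inc_rows] <- scr_age[inc_rows] + 7

  ## timestamps: one slot per unit; rapid clusters share a slot --------------
  rapid_idx <- idx_of("rapid_submission")
  n_rapid <- length(rapid_idx)
  sizes <- integer(0)
  if (n_rapid >= 3) {
    sizes <- rep(3L, n_rapid %/% 3)
    sizes[length(sizes)] <- sizes[length(sizes)] + n_rapid %% 3
  }
  cluster_of <- rep(seq_along(sizes), sizes)
  other_idx <- setdiff(seq_len(n), rapid_idx)
  # donors must submit before the rows that reuse their email/address
  donor_idx <- c(email_donors, addr_donors)
  unit_members <- c(as.list(donor_idx),
                    sample(c(as.list(setdiff(other_idx, donor_idx)),
                             split(rapid_idx, cluster_of))))
  n_units <- length(unit_members)
  spacing <- max(2, floor(study_days * 1440 / (n_units + 1)))
  start_min <- (seq_len(n_units) - 1) * spacing
  start_time <- rep(as.POSIXct(study_start, tz = "UTC"), n)
  for (u in seq_len(n_units)) {
    start_time[unit_members[[u]]] <-
      as.POSIXct(study_start, tz = "UTC") + start_min[u] * 60
  }
  duration <- 18 + (seq_len(n) %% 23)
  duration[rapid_idx] <- 20 + (cluster_of %% 15)  # shared within cluster
  end_time <- start_time + duration * 60

  ## stratum and platform labels ---------------------------------------------
  survey_type <- rep("adult", n)
  platform_fraud <- rep(FALSE, n)
  if (!is.null(joint_counts)) {
    jc <- as_tibble(joint_counts)
    for (ml in c("fraud", "valid")) {
      rows_ml <- which(if (ml == "fraud") ml_fraud else !ml_fraud)
      cells <- filter(jc, .data$multilayer == ml)
      if (sum(cells$n) != length(rows_ml)) {
        abort(sprintf(
          "joint_counts give %d multilayer-%s responses; planted %d.",
          sum(cells$n), ml, length(rows_ml)),
          class = "surveysieve_config_error")
      }
      assign_to <- sample(rows_ml)
      survey_type[assign_to] <- rep(cells$survey_type, cells$n)
      platform_fraud[assign_to] <- rep(cells$platform == "fraud", cells$n)
    }
  }

  recaptcha <- rep(0.9, n)
  fraud_sc <- rep(5, n)
  dup_sc <- rep(10, n)
  if (!is.null(platform_rule_counts) && any(platform_fraud)) {
    pf_rows <- sample(which(platform_fraud))
    P <- length(pf_rows)
    r <- platform_rule_counts[["platform_recaptcha"]]
    f <- platform_rule_counts[["platform_fraud_score"]]
    d <- platform_rule_counts[["platform_dup_score"]]
    excess <- r + f + d - P
    o1 <- min(r, excess)          # reCAPTCHA breaches nested in fraud-score
    o2 <- excess - o1             # duplicate-score overlap with fraud-score
    feasible <- excess >= 0 && o2 >= 0 && o2 <= min(d, f - o1) &&
      (r - o1) >= 0 && (f - o1 - o2) >= 0 && (d - o2) >= 0
    if (!feasible) {
      abort("platform_rule_counts incompatible with the platform-fraud total.",
            class = "surveysieve_config_error")
    }
    kinds <- rep(c("rc", "rc_fs", "fs", "fs_dup", "dup"),
                 c(r - o1, o1, f - o1 - o2, o2, d - o2))
    rc_hit <- kinds %in% c("rc", "rc_fs")
    fs_hit <- kinds %in% c("rc_fs", "fs", "fs_dup")
    dup_hit <- kinds %in% c("fs_dup", "dup")
    recaptcha[pf_rows] <- ifelse(rc_hit, 0.3, 0.9)
    fraud_sc[pf_rows] <- ifelse(fs_hit, 45, 5)
    dup_sc[pf_rows] <- ifelse(dup_hit, 80, 10)
  } else if (any(platform_fraud)) {
    fraud_sc[platform_fraud] <- 45
  }

  resp <- tibble(
    response_id = sprintf("P%d-R%05d", seed, seq_len(n)),
    start_time = start_time, end_time = end_time,
    email = email, street_address = street_address, zip_code = zip_code,
    neighborhood_name = neighborhood_name, ip_address = ip_address,
    referral_url = referral_url, free_text_comment = free_text,
    survey_type = survey_type, honeypot_answer = "",
    recaptcha_v3 = recaptcha, relevantid_fraud = fraud_sc,
    relevantid_dup = dup_sc, completed = TRUE,
    scr_age = scr_age, main_age = main_age,
    scr_zip = zip_code, main_zip = zip_code
  )
  resp <- order_chronologically(resp)

  ids <- sprintf("P%d-R%05d", seed, seq_len(n))
  perm <- match(resp$response_id, ids)
  truth <- tibble(
    response_id = resp$response_id,
    is_fraud = ml_fraud[perm],
    archetype = ifelse(ml_fraud[perm], category[perm], NA_character_)
  )

  structure(list(responses = resp, truth = truth, gazetteer = g),
            class = c("planted_cohort", "synthetic_cohort"))
}
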