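g <- tiny_gazetteer()

test_that("neighborhood rule accepts the address neighborhood and adjacents", {
  r <- make_responses(3,
    street_address = c("1 Oak St", "1 Oak St", "9 Ghost St"),
    neighborhood_name = c("Kensington", "Chestnut Hill", "Chestnut Hill"))
  # address resolves to Fishtown; Kensington is adjacent, Chestnut Hill not;
  # unresolvable addresses are the invalid-address rule's case
  expect_equal(rule_neighborhood_mismatch(r, g), c(FALSE, TRUE, FALSE))
})

test_that("invalid-address rule flags unknown and empty addresses", {
  r <- make_responses(3, street_address = c("2 oak st.", "9 Ghost St", ""))
  expect_equal(rule_invalid_address(r, g), c(FALSE, TRUE, TRUE))
})

test_that("rapid submission needs start AND stop shared with min_others", {
  s <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  r3 <- make_responses(3, start_time = rep(s, 3),
                       end_time = rep(s + 20 * 60, 3))
  expect_setequal(rule_rapid_submission(r3), r3$response_id)
  # a pair is below the default min_others = 2
  r2 <- make_responses(2, start_time = rep(s, 2),
                       end_time = rep(s + 20 * 60, 2))
  expect_length(rule_rapid_submission(r2), 0)
})

test_that("rapid submission equals the pairwise brute-force oracle", {
  oracle <- function(resp, w = 1, min_others = 2) {
    s <- floor(as.numeric(resp$start_time) / 60)
    e <- floor(as.numeric(resp$end_time) / 60)
    flagged <- vapply(seq_along(s), function(i) {
      sum(abs(s[-i] - s[i]) <= w & abs(e[-i] - e[i]) <= w) >= min_others
    }, logical(1))
    sort(resp$response_id[flagged])
  }
  s0 <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  # staircase of starts with a common end: the inner responses are flagged
  r <- make_responses(4, start_time = s0 + c(0, 1, 2, 3) * 60,
                      end_time = rep(s0 + 30 * 60, 4))
  expect_equal(rule_rapid_submission(r), oracle(r))
  expect_equal(rule_rapid_submission(r), c("r002", "r003"))

  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    r <- make_responses(n,
      start_time = s0 + sample(0:15, n, replace = TRUE) * 60,
      end_time = s0 + (20 + sample(0:10, n, replace = TRUE)) * 60)
    expect_equal(rule_rapid_submission(r), oracle(r))
  }
})

test_that("rapid submission is invariant under input permutation", {
  set.seed(99)
  s0 <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  r <- make_responses(25,
    start_time = s0 + sample(0:8, 25, replace = TRUE) * 60,
    end_time = s0 + (15 + sample(0:6, 25, replace = TRUE)) * 60)
  shuffled <- r[sample(nrow(r)), ]
  expect_equal(rule_rapid_submission(r), rule_rapid_submission(shuffled))
})

test_that("duplicate-email rule keeps the first user, case-insensitively", {
  r <- make_responses(3, email = c("A@x.com", "b@x.com", "a@x.com"))
  expect_equal(rule_duplicate_email(r), "r003")
  expect_length(rule_duplicate_email(make_responses(3)), 0)
  # empty emails never match each other
  r0 <- make_responses(3, email = c("", "", NA))
  expect_length(rule_duplicate_email(r0), 0)
})

test_that("nonstandard-zip rule checks the gazetteer list only", {
  r <- make_responses(3, zip_code = c("19901", "19104", ""))
  expect_equal(rule_nonstandard_zip(r, g), c(TRUE, FALSE, FALSE))
})

test_that("address overuse flags the 3rd+ chronological user", {
  r <- make_responses(4)  # all share "1 Oak St", in time order
  expect_equal(rule_address_overuse(r), c("r003", "r004"))
  expect_length(rule_address_overuse(make_responses(2)), 0)
})

test_that("address overuse equals the prefix-count oracle when interleaved", {
  r <- make_responses(6, street_address = rep(c("1 Oak St", "3 Elm St"), 3))
  oracle <- function(resp, prior = 2) {
    resp <- resp[order(resp$start_time, resp$response_id), ]
    key <- normalize_text(resp$street_address, address = TRUE)
    flagged <- vapply(seq_len(nrow(resp)), function(i) {
      sum(key[seq_len(i - 1)] == key[i]) >= prior
    }, logical(1))
    sort(resp$response_id[flagged])
  }
  expect_equal(rule_address_overuse(r), oracle(r))
  expect_equal(rule_address_overuse(r), c("r005", "r006"))
})

test_that("referral and honeypot rules normalize before comparing", {
  r <- make_responses(3, referral_url = c("https://study.example.org/fb/",
                                          "HTTP://study.example.org/fb",
                                          "https://evil.example.net/x"))
  expect_equal(rule_invalid_referral(r, g), c(FALSE, FALSE, TRUE))
  r2 <- make_responses(3, honeypot_answer = c("", "x", "   "))
  expect_equal(rule_honeypot(r2), c(FALSE, TRUE, FALSE))
})

test_that("stage labels fraud on any rule with first-match attribution", {
  clean <- make_responses(5)
  res <- apply_realtime_stage(clean, g, fd_config())
  expect_true(all(res$labels$label[1:2] == "valid"))
  # rows 3+ of a shared address are overused; use distinct addresses instead
  clean$street_address <- c("1 Oak St", "2 Oak St", "3 Elm St", "4 Pine St",
                            "1 Oak St")
  clean$neighborhood_name <- c("Fishtown", "Fishtown", "Kensington",
                               "Chestnut Hill", "Fishtown")
  res <- apply_realtime_stage(clean, g, fd_config())
  expect_true(all(res$labels$label == "valid"))
  expect_true(all(res$counts_by_rule$n == 0))

  # one response violating both the neighborhood and rapid rules is
  # attributed to the earlier-listed criterion but keeps both flags
  s0 <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  batch <- make_responses(4,
    street_address = c("1 Oak St", "2 Oak St", "2 Oak St", "2 Oak St"),
    neighborhood_name = c("Chestnut Hill", "Fishtown", "Fishtown",
                          "Fishtown"),
    start_time = rep(s0, 4), end_time = rep(s0 + 10 * 60, 4))
  res <- apply_realtime_stage(batch, g, fd_config())
  expect_equal(sum(res$labels$label == "fraud"), 4)
  first <- res$labels$rule_first[res$labels$response_id == "r001"]
  expect_equal(first, "neighborhood_mismatch")
  flags1 <- res$flags$rule_id[res$flags$response_id == "r001"]
  expect_setequal(flags1, c("neighborhood_mismatch", "rapid_submission"))
  # first-match counts are mutually exclusive and sum to the fraud count
  expect_equal(sum(res$counts_by_rule$n), sum(res$labels$label == "fraud"))
})

test_that("stage equals per-rule brute-force evaluation on a mixed batch", {
  co <- generate_cohort(cohort_spec(n_genuine = 60,
                                    archetype_counts = c(bot_burst = 9,
                                                         url_spoofer = 6,
                                                         address_reuser = 5),
                                    seed = 123))
  resp <- co$responses
  res <- apply_realtime_stage(resp, co$gazetteer, fd_config())
  expected_fraud <-
    resp$response_id[rule_neighborhood_mismatch(resp, co$gazetteer) |
                       rule_invalid_address(resp, co$gazetteer) |
                       rule_nonstandard_zip(resp, co$gazetteer) |
                       rule_invalid_referral(resp, co$gazetteer) |
                       rule_honeypot(resp)]
  expected_fraud <- union(expected_fraud, rule_rapid_submission(resp))
  expected_fraud <- union(expected_fraud, rule_duplicate_email(resp))
  expected_fraud <- union(expected_fraud, rule_address_overuse(resp))
  got <- res$labels$response_id[res$labels$label == "fraud"]
  expect_setequal(got, expected_fraud)
  # conservation
  expect_equal(sum(res$labels$label == "fraud") +
                 sum(res$labels$label == "valid"), nrow(resp))
})

test_that("batch-rule flagged sets grow monotonically as responses append", {
  s0 <- as.POSIXct("2021-11-05 10:00:00", tz = "UTC")
  r <- make_responses(8,
    email = c("a@x", "b@x", "a@x", "c@x", "b@x", "d@x", "a@x", "e@x"),
    street_address = rep(c("1 Oak St", "2 Oak St"), 4),
    neighborhood_name = "Fishtown",
    start_time = s0 + (0:7) * 600, end_time = s0 + (0:7) * 600 + 1200)
  for (rule in list(rule_duplicate_email,
                    function(x) rule_address_overuse(x, 2L))) {
    prev <- character()
    for (n in seq_len(nrow(r))) {
      cur <- rule(r[seq_len(n), ])
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})
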